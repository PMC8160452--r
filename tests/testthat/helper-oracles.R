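# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately coded from first principles (sorting, explicit
# formulas, normal equations) rather than through the package's own code
# paths.

# Type-7 quantile by explicit order-statistic interpolation.
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_fences <- function(x, k = 3) {
  q1 <- oracle_quantile7(x, 0.25)
  q3 <- oracle_quantile7(x, 0.75)
  c(lower = q1 - k * (q3 - q1), upper = q3 + k * (q3 - q1))
}

# Restricted cubic spline reference: same function space, coded from the
# truncated-power definition with the linearity constraints solved as a
# linear system rather than substituted analytically. For knots t and basis
# index j, the nonlinear term is sum_m c_m (x - t_m)_+^3 with c_j = 1 and
# c_{k-1}, c_k chosen so that sum c_m = 0 and sum c_m t_m = 0 (these two
# conditions force the cubic and quadratic tail terms to vanish).
oracle_rcs <- function(x, knots) {
  k <- length(knots)
  out <- matrix(NA_real_, length(x), k - 1)
  out[, 1] <- x
  for (j in seq_len(k - 2)) {
    A <- rbind(c(1, 1), knots[c(k - 1, k)])
    b <- -c(1, knots[j])
    cc <- solve(A, b)
    coefs <- c(1, cc)
    terms <- sapply(c(j, k - 1, k), function(m) pmax(x - knots[m], 0)^3)
    out[, j + 1] <- as.numeric(terms %*% coefs) / (knots[k] - knots[1])^2
  }
  out
}

# Explicit residualize-on-ranks partial Spearman (per-candidate least
# squares), the reference for the precision-matrix implementation.
oracle_partial_spearman <- function(df, candidates, adjust_for, ga_var = "ga_weeks") {
  num <- function(v) if (is.numeric(v)) v else as.numeric(factor(v))
  ranks <- sapply(c(ga_var, candidates, adjust_for),
                  function(v) rank(num(df[[v]])))
  sapply(candidates, function(a) {
    z <- cbind(1, ranks[, setdiff(c(candidates, adjust_for), a), drop = FALSE])
    ry <- stats::lm.fit(z, ranks[, ga_var])$residuals
    ra <- stats::lm.fit(z, ranks[, a])$residuals
    stats::cor(ry, ra)
  })
}

# Tiny hand-checkable cohort for exclusion tests: three clean records, one
# late collection (50 h), one screen positive, one missing birth weight.
exclusion_fixture <- function() {
  data.frame(
    id = paste0("x", 1:6), site = "toy",
    sex = c("M", "F", "M", "F", "M", "F"),
    birth_weight_g = c(3400, 3100, 3600, 2900, NA, 3200),
    ga_weeks = c(39.5, 40.1, 38.2, 37.9, 39.0, 41.0),
    collection_age_hours = c(30, 50, 24, 36, 28, 40),
    screen_positive = c(0L, 0L, 1L, 0L, 0L, 0L),
    ALA = c(250, 260, 240, 255, 245, 252),
    stringsAsFactors = FALSE
  )
}

small_cohort <- function(n = 400, seed = 5) {
  generate_cohort(synthetic_config(n_infants = n, seed = seed))
}
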