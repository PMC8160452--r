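# Cohort splitting, knot computation, the restricted cubic spline basis,
# partial Spearman screening, and design matrix construction.

test_that("stratified split honors fractions within each stratum and reassembles", {
  co <- generate_cohort(synthetic_config(n_infants = 4000, seed = 31))
  subs <- suppressWarnings(
    split_cohort(co, c(development = 0.5, validation = 0.25, test = 0.25),
                 seed = 3))
  sizes <- vapply(subs, nrow, integer(1))
  expect_equal(sum(sizes), nrow(co))
  expect_lt(abs(sizes[["development"]] - 2000), 60)  # stratum rounding only
  expect_lt(abs(sizes[["validation"]] - 1000), 60)

  # union reconstructs the input exactly
  all_ids <- sort(unname(unlist(lapply(subs, `[[`, "id"))))
  expect_equal(all_ids, sort(co$id))

  # per-stratum fractions within one record
  strata <- interaction(floor(co$ga_weeks), co$sex, drop = TRUE)
  big <- names(which(table(strata) >= 40))
  for (s in big) {
    m <- sum(strata == s)
    in_dev <- sum(subs$development$id %in% co$id[strata == s])
    expect_lte(abs(in_dev - 0.5 * m), 1)
  }

  # reproducibility and degenerate fractions
  subs2 <- suppressWarnings(split_cohort(co, c(0.5, 0.25, 0.25), seed = 3))
  expect_equal(subs2[[1]]$id, subs$development$id)
  all_in_one <- suppressWarnings(split_cohort(co, c(1, 0, 0), seed = 1))
  expect_equal(nrow(all_in_one[[1]]), nrow(co))
})

test_that("spline knots sit at the configured percentiles", {
  x <- seq(0, 100, by = 0.5)
  kn <- compute_knots(x)
  expect_equal(kn, sapply(c(0.05, 0.275, 0.5, 0.725, 0.95),
                          function(p) oracle_quantile7(x, p)),
               tolerance = 1e-12)
  # invariant to duplicating the data
  expect_equal(compute_knots(c(x, x)), kn, tolerance = 1e-9)
  expect_error(compute_knots(rep(3, 50)), "knot_error")
})

test_that("rcs basis has k-1 columns, vanishes below the first knot, and is linear in the tails", {
  knots <- c(-1.2, -0.4, 0.1, 0.8, 1.7)
  x <- seq(-3, 4, length.out = 500)
  b <- rcs_basis(x, knots)
  expect_equal(ncol(b), 4)
  below <- x <= knots[1]
  expect_true(all(b[below, 2:4] == 0))

  # agreement with the independently coded reference implementation
  set.seed(8)
  xr <- runif(1000, -5, 5)
  expect_lt(max(abs(rcs_basis(xr, knots) - oracle_rcs(xr, knots))), 1e-8)

  # numerical linearity beyond the last knot: second differences of any
  # linear combination of the basis vanish
  beta <- c(0.7, -1.1, 2.3, 0.4)
  xt <- seq(knots[5] + 0.01, knots[5] + 3, length.out = 200)
  f <- rcs_basis(xt, knots) %*% beta
  expect_lt(max(abs(diff(diff(f)))), 1e-9)
  # missing inputs propagate
  expect_true(all(is.na(rcs_basis(c(NA, 1), knots)[1, ])))
})

test_that("precision-matrix screening equals explicit rank residualization", {
  set.seed(12)
  n <- 400
  df <- data.frame(ga_weeks = rnorm(n), sex = sample(c("M", "F"), n, TRUE),
                   birth_weight_g = rnorm(n))
  for (a in paste0("a", 1:5)) df[[a]] <- rlnorm(n, 0, 0.4)
  df$a1 <- df$a1 * exp(0.3 * df$ga_weeks)
  sc <- partial_spearman_screen(df, paste0("a", 1:5), top_k = 2)
  or <- oracle_partial_spearman(df, paste0("a", 1:5),
                                c("sex", "birth_weight_g"))
  expect_equal(sc$partial_rho[match(paste0("a", 1:5), sc$analyte)],
               unname(or), tolerance = 1e-10)
  expect_equal(attr(sc, "top_k")[1], "a1")

  # rank statistic: invariant under strictly monotone transforms
  df2 <- df
  df2$a2 <- exp(df2$a2); df2$a3 <- df2$a3^3
  sc2 <- partial_spearman_screen(df2, paste0("a", 1:5), top_k = 2)
  expect_equal(sc2$partial_rho, sc$partial_rho, tolerance = 1e-10)
})

test_that("screening ranks a planted signal above pure noise", {
  hits <- 0L
  for (rep in 1:10) {
    set.seed(100 + rep)
    n <- 5000
    ga <- rnorm(n, 39, 1.5)
    df <- data.frame(ga_weeks = ga, sex = sample(c("M", "F"), n, TRUE),
                     birth_weight_g = 3300 + 150 * (ga - 39) + rnorm(n, 0, 400),
                     A = exp(0.12 * ga + rnorm(n, 0, 0.3)),
                     B = rlnorm(n, 2, 0.3))
    sc <- partial_spearman_screen(df, c("A", "B"), top_k = 1)
    hits <- hits + (attr(sc, "top_k") == "A")
  }
  expect_equal(hits, 10L)
})

test_that("design matrices follow the declared structure", {
  co <- preprocess_cohort(small_cohort(500, seed = 32), label = "t")$cohort
  bw_knots <- list(birth_weight_g = compute_knots(co$birth_weight_g))
  m1 <- model_spec(1, "birth_weight_g", bw_knots,
                   interactions = "sex_by_spline")
  d1 <- build_design_matrix(co, m1)
  expect_equal(ncol(d1$values), 10)  # intercept, sex, 4 spline, 4 sex:spline
  expect_equal(d1$column_names[1:2], c("(Intercept)", "sex"))

  bare <- model_spec(2, character(0), interactions = character(0))
  d0 <- build_design_matrix(co, bare)
  expect_equal(d0$column_names, c("(Intercept)", "sex"))

  spec3 <- model_spec(3, c("birth_weight_g", "ALA", "TSH"),
                      bw_knots)
  d3 <- build_design_matrix(co, spec3)
  # every interaction column is the product of its two named parent columns
  prov <- d3$provenance
  for (i in which(prov$type == "interaction")) {
    parents <- strsplit(prov$column[i], ":", fixed = TRUE)[[1]]
    expect_equal(unname(d3$values[, i]),
                 unname(d3$values[, parents[1]] * d3$values[, parents[2]]),
                 tolerance = 1e-12)
  }
  # purity: same inputs give the identical matrix
  expect_identical(build_design_matrix(co, spec3)$values, d3$values)
  # absent analyte named in the error
  bad <- model_spec(2, c("ALA", "NOPE"))
  expect_error(build_design_matrix(co, bad), "NOPE")
})

test_that("panel restriction removes hemoglobin terms and shrinks the spline set", {
  co <- preprocess_cohort(small_cohort(600, seed = 33), label = "t")$cohort
  cand <- modeling_analytes(co)
  top <- c("hb_ratio", "17OHP", "C4DC", "TYR", "ALA", "C5", "C5DC")
  kn <- stats::setNames(lapply(top, function(v) compute_knots(co[[v]])), top)
  spec <- model_spec(3, c("birth_weight_g", cand),
                     c(list(birth_weight_g = compute_knots(co$birth_weight_g)),
                       kn), top_k_splined = 7)

  expect_identical(restrict_model_spec(spec, cand)$quantitative,
                   spec$quantitative)

  no_hb <- setdiff(cand, "hb_ratio")
  r <- restrict_model_spec(spec, no_hb)
  expect_false("hb_ratio" %in% r$quantitative)
  expect_equal(r$top_k_splined, 6)
  d <- build_design_matrix(co, r)
  expect_false(any(grepl("hb_ratio", d$column_names)))
  # removing an analyte removes every interaction naming it
  r2 <- restrict_model_spec(spec, setdiff(cand, "ALA"))
  d2 <- build_design_matrix(co, r2)
  expect_false(any(grepl("(^|:)ALA($|:|_)", d2$column_names)))
  analyte_only <- model_spec(2, cand)
  expect_error(restrict_model_spec(analyte_only, character(0)), "spec_error")
})
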