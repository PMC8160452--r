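# Synthetic multi-site newborn screening cohorts.
#
# The generator emulates the statistical structure the downstream analysis
# relies on: a right-skewed gestational age (GA) distribution with a
# configurable preterm fraction, birth weight rising with GA (with a
# growth-restricted subpopulation whose weight is decoupled from GA),
# log-normal analytes whose log-levels move linearly with GA, a fetal
# hemoglobin fraction that declines with maturity, later sample collection in
# preterm infants, and screen-positive / outlier records that exercise the
# exclusion and winsorization logic.

#' Configuration for a synthetic newborn screening cohort
#'
#' The GA distribution is a two-component mixture: a term Gaussian truncated
#' to `[37, ga_max]` and an exponential-tail preterm component below 37 weeks
#' whose mixture weight *is* `preterm_target_fraction`, so the preterm rate is
#' a direct parameter. The term-component location is solved numerically so
#' the overall mean equals `ga_mean`.
#'
#' Default analyte effect sizes are calibrated analytically so that the
#' conditional standard deviation of GA given all predictors (birth weight,
#' hemoglobin ratio and the informative analytes) equals
#' `target_conditional_sd` weeks; see the methods vignette for the
#' information-accounting argument.
#'
#' @param n_infants number of records to draw.
#' @param seed integer RNG seed; a fixed seed gives byte-identical cohorts.
#' @param site_label site stamp written to the `site` column.
#' @param ga_mean,ga_sd target overall GA mean and term-component SD (weeks).
#' @param preterm_target_fraction probability that a record is drawn from the
#'   preterm (<37 weeks) component.
#' @param ga_min,ga_max truncation bounds (weeks).
#' @param preterm_tail_rate rate (per week) of the exponential preterm tail;
#'   smaller values give deeper prematurity.
#' @param male_fraction Bernoulli probability of male sex.
#' @param bw_curve named numeric: `intercept` (expected weight in g at 40
#'   weeks, sex-averaged), `slope` (g/week at 40 weeks), `quad` (curvature,
#'   g/week^2), `sex_diff` (male minus female gap in g).
#' @param bw_log_noise_sd,bw_noise_sd multiplicative (log-scale) and additive
#'   (g) birth weight noise.
#' @param growth_restricted_fraction proportion of infants whose expected
#'   weight is multiplied by `growth_restriction_deficit` (in (0,1)).
#' @param growth_restriction_deficit multiplicative weight deficit.
#' @param analyte_effects data frame with columns `analyte`, `base` (log-level
#'   intercept at GA 0), `slope` (log-level change per GA week) and `sd`
#'   (residual log-scale SD); `NULL` requests the calibrated defaults.
#' @param n_null_analytes how many of the default no-signal analytes to keep
#'   on the panel (0..33).
#' @param target_conditional_sd calibration target (weeks) for the residual SD
#'   of GA given all predictors; only used when `analyte_effects` is `NULL`.
#' @param hb_model named numeric for the fetal hemoglobin fraction:
#'   `logit40` (logit fraction at 40 weeks), `slope` (logit units/week,
#'   negative), `sd` (residual logit SD), `total_log_mean`, `total_log_sd`
#'   (total hemoglobin level), `f1_share` (share of fetal signal reported as
#'   HbF1).
#' @param outlier_rate proportion of records given an extreme analyte spike
#'   (unflagged; exercises winsorization).
#' @param screen_positive_rate proportion flagged screen-positive and given
#'   very large spikes (>= 10 fenced IQRs on the log scale).
#' @param collection_age_model named numeric: `meanlog`, `sdlog` (log-normal
#'   hours at collection), `preterm_delay_hours` (additive shift in the
#'   preterm stratum), `min_hours`.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_infants = 10000,
                             seed = 1L,
                             site_label = "site1",
                             ga_mean = 39.3,
                             ga_sd = 1.6,
                             preterm_target_fraction = 0.056,
                             ga_min = 24,
                             ga_max = 43,
                             preterm_tail_rate = 0.5,
                             male_fraction = 0.512,
                             bw_curve = c(intercept = 3500, slope = 175,
                                          quad = -5, sex_diff = 130),
                             bw_log_noise_sd = 0.08,
                             bw_noise_sd = 150,
                             growth_restricted_fraction = 0.10,
                             growth_restriction_deficit = 0.75,
                             analyte_effects = NULL,
                             n_null_analytes = length(ga_null_analytes),
                             target_conditional_sd = 0.6,
                             hb_model = c(logit40 = 1.73, slope = -0.18,
                                          sd = 0.25, total_log_mean = log(200),
                                          total_log_sd = 0.15, f1_share = 0.12),
                             outlier_rate = 0.003,
                             screen_positive_rate = 0.015,
                             collection_age_model = c(meanlog = log(28),
                                                      sdlog = 0.35,
                                                      preterm_delay_hours = 18,
                                                      min_hours = 1)) {
  num_ok <- function(x) is.numeric(x) && all(is.finite(x))
  if (!num_ok(n_infants) || n_infants < 0 ||
      !num_ok(ga_mean) || !num_ok(ga_sd) || ga_sd <= 0 ||
      !num_ok(ga_min) || !num_ok(ga_max) ||
      !num_ok(bw_curve) || !num_ok(hb_model) || !num_ok(collection_age_model)) {
    stop("config_error: non-finite or invalid numeric configuration value",
         call. = FALSE)
  }
  props <- c(preterm_target_fraction = preterm_target_fraction,
             male_fraction = male_fraction,
             growth_restricted_fraction = growth_restricted_fraction,
             outlier_rate = outlier_rate,
             screen_positive_rate = screen_positive_rate)
  if (!num_ok(props) || any(props < 0) || any(props > 1)) {
    stop("config_error: proportions must lie in [0, 1]", call. = FALSE)
  }
  if (!(ga_min < 37 && 37 < ga_max)) {
    stop("config_error: need ga_min < 37 < ga_max", call. = FALSE)
  }
  if (!num_ok(growth_restriction_deficit) ||
      growth_restriction_deficit <= 0 || growth_restriction_deficit >= 1) {
    stop("config_error: growth_restriction_deficit must be in (0, 1)",
         call. = FALSE)
  }
  if (n_null_analytes > length(ga_null_analytes) || n_null_analytes < 0) {
    stop("config_error: n_null_analytes out of range", call. = FALSE)
  }

  mixture <- solve_ga_mixture(ga_mean, ga_sd, preterm_target_fraction,
                              ga_min, ga_max, preterm_tail_rate)

  cfg <- list(
    n_infants = as.integer(n_infants), seed = as.integer(seed),
    site_label = site_label,
    ga_mean = ga_mean, ga_sd = ga_sd,
    preterm_target_fraction = preterm_target_fraction,
    ga_min = ga_min, ga_max = ga_max,
    preterm_tail_rate = preterm_tail_rate,
    male_fraction = male_fraction,
    bw_curve = bw_curve, bw_log_noise_sd = bw_log_noise_sd,
    bw_noise_sd = bw_noise_sd,
    growth_restricted_fraction = growth_restricted_fraction,
    growth_restriction_deficit = growth_restriction_deficit,
    n_null_analytes = as.integer(n_null_analytes),
    target_conditional_sd = target_conditional_sd,
    hb_model = hb_model,
    outlier_rate = outlier_rate,
    screen_positive_rate = screen_positive_rate,
    collection_age_model = collection_age_model,
    ga_mixture = mixture
  )
  if (is.null(analyte_effects)) {
    analyte_effects <- default_analyte_effects(cfg)
  } else {
    need <- c("analyte", "base", "slope", "sd")
    if (!is.data.frame(analyte_effects) || !all(need %in% names(analyte_effects))) {
      stop("config_error: analyte_effects needs columns analyte/base/slope/sd",
           call. = FALSE)
    }
    if (nrow(analyte_effects) == 0) {
      stop("config_error: empty analyte panel", call. = FALSE)
    }
    if (!num_ok(analyte_effects$base) || !num_ok(analyte_effects$slope) ||
        !num_ok(analyte_effects$sd)) {
      stop("config_error: non-finite analyte effect values", call. = FALSE)
    }
  }
  cfg$analyte_effects <- analyte_effects
  cfg$analyte_panel <- c(analyte_effects$analyte, hemoglobin_columns)
  class(cfg) <- "synthetic_config"
  cfg
}

# Truncated-normal helpers (term component, support [lo, hi]).
.tn_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  z <- if (a > 0) {
    stats::pnorm(a, lower.tail = FALSE) - stats::pnorm(b, lower.tail = FALSE)
  } else {
    stats::pnorm(b) - stats::pnorm(a)
  }
  pa <- stats::dnorm(a); pb <- stats::dnorm(b)
  m <- mu + sigma * (pa - pb) / z
  v <- sigma^2 * (1 + (a * pa - b * pb) / z - ((pa - pb) / z)^2)
  list(mean = m, var = v)
}

# Truncated exponential on [0, L], rate lambda: moments by quadrature.
.texp_moments <- function(lambda, L) {
  z <- 1 - exp(-lambda * L)
  dens <- function(x) lambda * exp(-lambda * x) / z
  m <- stats::integrate(function(x) x * dens(x), 0, L)$value
  e2 <- stats::integrate(function(x) x^2 * dens(x), 0, L)$value
  list(mean = m, var = e2 - m^2)
}

# Solve the term-component location so the mixture mean hits ga_mean; the
# preterm component has weight exactly p (GA = 37 - TruncExp(rate, 37-ga_min)).
solve_ga_mixture <- function(ga_mean, ga_sd, p, ga_min, ga_max, rate) {
  L <- 37 - ga_min
  ex <- .texp_moments(rate, L)
  pre_mean <- 37 - ex$mean
  pre_var <- ex$var
  term_target <- (ga_mean - p * pre_mean) / (1 - p)
  if (term_target <= 37 || term_target >= ga_max) {
    stop("config_error: ga_mean unreachable with this preterm fraction",
         call. = FALSE)
  }
  f <- function(mu) .tn_moments(mu, ga_sd, 37, ga_max)$mean - term_target
  mu <- stats::uniroot(f, lower = 37 - 6 * ga_sd, upper = ga_max + 6 * ga_sd,
                       tol = 1e-10)$root
  tn <- .tn_moments(mu, ga_sd, 37, ga_max)
  overall_var <- p * (pre_var + (pre_mean - ga_mean)^2) +
    (1 - p) * (tn$var + (tn$mean - ga_mean)^2)
  list(term_mu = mu, term_mean = tn$mean, term_var = tn$var,
       pre_mean = pre_mean, pre_var = pre_var,
       overall_var = overall_var, tail_L = L)
}

# Baseline analyte levels (order-of-magnitude realistic, arbitrary units).
.analyte_level40 <- c(
  "17OHP" = 30, C4DC = 0.15, TYR = 80, ALA = 250, C5 = 0.12, C5DC = 0.08,
  TSH = 5, PHE = 55, LEU = 120, MET = 25, CIT = 14, ARG = 10, VAL = 130,
  GLY = 350, ORN = 70, PRO = 150, SER = 120, C0 = 25, C2 = 15, C3 = 2,
  C4 = 0.3, C6 = 0.08, C8 = 0.08, C10 = 0.12, C12 = 0.1, C14 = 0.25,
  C16 = 3, C18 = 1, C3DC = 0.08, C5OH = 0.2, C6DC = 0.06, C8DC = 0.05,
  C14OH = 0.03, C16OH = 0.03, C18OH = 0.02, GALT = 60, BIO = 120,
  IRT = 20, SUAC = 1
)

#' Calibrated default analyte effects
#'
#' Distributes GA signal over the six informative analytes so that, together
#' with birth weight and the hemoglobin ratio, the implied conditional SD of
#' GA given all predictors equals `cfg$target_conditional_sd` (Gaussian
#' information approximation; see vignette). Null analytes get slope 0.
#'
#' @param cfg a partially built `synthetic_config` list (mixture solved).
#' @return data frame of per-analyte (base, slope, sd).
#' @keywords internal
default_analyte_effects <- function(cfg) {
  var_ga <- cfg$ga_mixture$overall_var
  # birth weight information: local slope at ga_mean over residual SD
  bw <- cfg$bw_curve
  mu_bw <- bw[["intercept"]] + bw[["slope"]] * (cfg$ga_mean - 40) +
    bw[["quad"]] * (cfg$ga_mean - 40)^2
  bw_slope <- bw[["slope"]] + 2 * bw[["quad"]] * (cfg$ga_mean - 40)
  bw_resid <- sqrt((mu_bw * cfg$bw_log_noise_sd)^2 + cfg$bw_noise_sd^2)
  info_bw <- (bw_slope / bw_resid)^2
  hb <- cfg$hb_model
  info_hb <- (hb[["slope"]] / hb[["sd"]])^2
  info_total <- 1 / cfg$target_conditional_sd^2 - 1 / var_ga - info_bw - info_hb
  if (info_total <= 0) {
    stop("config_error: target_conditional_sd already met without analytes",
         call. = FALSE)
  }
  # graded weights reproduce the expected screening order
  w <- c(1.35, 1.2, 1.05, 0.95, 0.85, 0.6)
  info_j <- info_total * w / sum(w)
  sd_inf <- 0.25
  slopes <- sign_pattern <- c(-1, 1, -1, 1, 1, 1)
  slopes <- sign_pattern * sd_inf * sqrt(info_j)
  informative <- data.frame(
    analyte = ga_informative_analytes,
    base = log(.analyte_level40[ga_informative_analytes]) - slopes * 40,
    slope = slopes,
    sd = sd_inf,
    stringsAsFactors = FALSE
  )
  nulls <- ga_null_analytes[seq_len(cfg$n_null_analytes)]
  null_df <- data.frame(
    analyte = nulls,
    base = log(.analyte_level40[nulls]),
    slope = 0,
    sd = rep_len(c(0.30, 0.25, 0.35), length(nulls)),
    stringsAsFactors = FALSE
  )
  out <- rbind(informative, null_df)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic newborn screening cohort
#'
#' @param config a [synthetic_config()].
#' @return a cohort data frame (schema: `id, site, sex, birth_weight_g,
#'   ga_weeks, collection_age_hours, screen_positive`, then one column per
#'   analyte including `HbF`, `HbF1`, `HbA`). Ground-truth generator state
#'   (mixture component, growth restriction flag, latent fetal fraction) is
#'   attached as the `"truth"` attribute; it is not part of the CSV schema.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop("config_error: not a synthetic_config", call. = FALSE)
  }
  n <- config$n_infants
  eff <- config$analyte_effects
  cols <- c(cohort_core_columns, eff$analyte, hemoglobin_columns)
  if (n == 0) {
    empty <- stats::setNames(
      as.data.frame(matrix(numeric(0), nrow = 0, ncol = length(cols))), cols)
    empty$id <- character(0); empty$site <- character(0); empty$sex <- character(0)
    return(empty[, cols])
  }
  set.seed(config$seed)
  mx <- config$ga_mixture

  preterm_comp <- stats::runif(n) < config$preterm_target_fraction
  ga <- numeric(n)
  n_pre <- sum(preterm_comp)
  if (n_pre > 0) {
    # inverse-CDF truncated exponential tail below 37 weeks
    u <- stats::runif(n_pre)
    z <- 1 - exp(-config$preterm_tail_rate * mx$tail_L)
    ga[preterm_comp] <- 37 - (-log(1 - u * z) / config$preterm_tail_rate)
  }
  n_term <- n - n_pre
  if (n_term > 0) {
    a <- stats::pnorm((37 - mx$term_mu) / config$ga_sd)
    b <- stats::pnorm((config$ga_max - mx$term_mu) / config$ga_sd)
    u <- stats::runif(n_term)
    ga[!preterm_comp] <- mx$term_mu +
      config$ga_sd * stats::qnorm(a + u * (b - a))
  }

  male <- stats::runif(n) < config$male_fraction
  restricted <- stats::runif(n) < config$growth_restricted_fraction

  bw <- config$bw_curve
  mu_bw <- bw[["intercept"]] + bw[["slope"]] * (ga - 40) +
    bw[["quad"]] * (ga - 40)^2 + bw[["sex_diff"]] * (male - 0.5)
  mu_bw <- pmax(mu_bw, 250)
  deficit <- ifelse(restricted, config$growth_restriction_deficit, 1)
  birth_weight <- mu_bw * deficit *
    exp(stats::rnorm(n, 0, config$bw_log_noise_sd)) +
    stats::rnorm(n, 0, config$bw_noise_sd)
  birth_weight <- round(pmax(birth_weight, 150))

  cam <- config$collection_age_model
  hours <- stats::rlnorm(n, cam[["meanlog"]], cam[["sdlog"]])
  hours <- hours + ifelse(ga < 37, cam[["preterm_delay_hours"]], 0)
  hours <- pmax(hours, cam[["min_hours"]])

  analytes <- matrix(NA_real_, n, nrow(eff), dimnames = list(NULL, eff$analyte))
  for (j in seq_len(nrow(eff))) {
    analytes[, j] <- exp(eff$base[j] + eff$slope[j] * ga +
                           stats::rnorm(n, 0, eff$sd[j]))
  }

  # hemoglobins: fetal fraction declines with GA on the logit scale
  hb <- config$hb_model
  logit_f <- hb[["logit40"]] + hb[["slope"]] * (ga - 40) +
    stats::rnorm(n, 0, hb[["sd"]])
  f <- stats::plogis(logit_f)
  total_hb <- stats::rlnorm(n, hb[["total_log_mean"]], hb[["total_log_sd"]])
  f1_share <- stats::plogis(stats::qlogis(hb[["f1_share"]]) +
                              stats::rnorm(n, 0, 0.1))
  HbF1 <- f * total_hb * f1_share
  HbF <- f * total_hb * (1 - f1_share)
  HbA <- (1 - f) * total_hb

  screen_positive <- stats::runif(n) < config$screen_positive_rate
  # screen positives carry grossly abnormal profiles (>= 10 fenced IQRs up)
  for (i in which(screen_positive)) {
    k <- sample.int(nrow(eff), 2)
    analytes[i, k] <- analytes[i, k] * exp(5 + stats::rexp(2, 1))
  }
  outlier <- !screen_positive & stats::runif(n) < config$outlier_rate
  for (i in which(outlier)) {
    k <- sample.int(nrow(eff), 1)
    analytes[i, k] <- analytes[i, k] * exp(3.5)
  }

  cohort <- data.frame(
    id = sprintf("%s-%07d", config$site_label, seq_len(n)),
    site = config$site_label,
    sex = ifelse(male, "M", "F"),
    birth_weight_g = birth_weight,
    ga_weeks = ga,
    collection_age_hours = hours,
    screen_positive = as.integer(screen_positive),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  cohort <- cbind(cohort, as.data.frame(analytes, check.names = FALSE))
  cohort$HbF <- HbF; cohort$HbF1 <- HbF1; cohort$HbA <- HbA
  attr(cohort, "truth") <- data.frame(
    id = cohort$id,
    component = ifelse(preterm_comp, "preterm_tail", "term"),
    growth_restricted = restricted,
    fetal_fraction = f,
    outlier_spiked = outlier,
    stringsAsFactors = FALSE
  )
  cohort
}

#' Site shift descriptor
#'
#' Describes how one screening laboratory's measurements differ from the
#' reference site: panel availability, multiplicative/additive analyte biases
#' on the log scale, residual dispersion inflation, delayed sample collection,
#' and the GA reporting convention.
#'
#' @param site_id site label stamped onto shifted cohorts.
#' @param panel analyte names measured at the site (subset of the full panel).
#' @param multiplicative_bias scalar or named per-analyte factor (> 0).
#' @param additive_log_shift scalar or named per-analyte offset (log scale).
#' @param dispersion_factor scalar or named per-analyte multiplier of the
#'   marginal log-scale SD (> 0). Values above 1 add independent measurement
#'   noise; values below 1 shrink log values toward the cohort mean.
#' @param collection_delay_hours hours added to every collection age.
#' @param ga_reporting `"decimal_weeks"` or `"completed_weeks"` (reference GA
#'   floored to the integer week, as in registries reporting completed weeks).
#' @return an object of class `site_shift`.
#' @export
site_shift <- function(site_id, panel,
                       multiplicative_bias = 1,
                       additive_log_shift = 0,
                       dispersion_factor = 1,
                       collection_delay_hours = 0,
                       ga_reporting = c("decimal_weeks", "completed_weeks")) {
  ga_reporting <- match.arg(ga_reporting)
  stopifnot(length(panel) > 0, all(multiplicative_bias > 0),
            all(dispersion_factor > 0))
  structure(list(site_id = site_id, panel = panel,
                 multiplicative_bias = multiplicative_bias,
                 additive_log_shift = additive_log_shift,
                 dispersion_factor = dispersion_factor,
                 collection_delay_hours = collection_delay_hours,
                 ga_reporting = ga_reporting),
            class = "site_shift")
}

.per_analyte <- function(x, panel, what) {
  if (is.null(names(x))) {
    if (length(x) != 1 && length(x) != length(panel)) {
      stop(sprintf("site_shift %s must be scalar or per-analyte", what),
           call. = FALSE)
    }
    stats::setNames(rep_len(x, length(panel)), panel)
  } else {
    out <- stats::setNames(rep(if (what == "additive_log_shift") 0 else 1,
                               length(panel)), panel)
    unknown <- setdiff(names(x), panel)
    if (length(unknown)) {
      stop(sprintf("unknown analyte in site_shift %s: %s", what,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    out[names(x)] <- x
    out
  }
}

#' Apply a site shift to a cohort
#'
#' Analytes outside the site's panel are dropped; remaining analytes are
#' transformed on the log scale by the additive shift plus the log of the
#' multiplicative bias, with marginal dispersion rescaled by
#' `dispersion_factor`. Collection ages are delayed and, for sites reporting
#' completed weeks, the reference GA is floored to the integer week.
#'
#' @param cohort a cohort data frame.
#' @param shift a [site_shift()].
#' @param seed RNG seed for the added dispersion noise.
#' @return the shifted cohort, with `site` stamped.
#' @export
apply_site_shift <- function(cohort, shift, seed = 1L) {
  stopifnot(inherits(shift, "site_shift"))
  have <- analyte_columns(cohort)
  unknown <- setdiff(shift$panel, have)
  if (length(unknown)) {
    stop(sprintf("unknown analyte in site panel: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  truth <- attr(cohort, "truth")
  drop <- setdiff(have, shift$panel)
  out <- cohort[, setdiff(names(cohort), drop), drop = FALSE]

  bias <- .per_analyte(shift$multiplicative_bias, shift$panel, "multiplicative_bias")
  add <- .per_analyte(shift$additive_log_shift, shift$panel, "additive_log_shift")
  disp <- .per_analyte(shift$dispersion_factor, shift$panel, "dispersion_factor")

  set.seed(seed)
  for (a in shift$panel) {
    x <- out[[a]]
    pos <- !is.na(x) & x > 0
    lx <- log(x[pos])
    lx <- lx + add[[a]] + log(bias[[a]])
    d <- disp[[a]]
    if (d > 1) {
      s <- stats::sd(lx)
      if (is.finite(s) && s > 0) {
        lx <- lx + stats::rnorm(length(lx), 0, s * sqrt(d^2 - 1))
      }
    } else if (d < 1) {
      m <- mean(lx)
      lx <- m + d * (lx - m)
    }
    x[pos] <- exp(lx)
    out[[a]] <- x
  }
  out$collection_age_hours <- out$collection_age_hours + shift$collection_delay_hours
  if (shift$ga_reporting == "completed_weeks") {
    out$ga_weeks <- floor(out$ga_weeks)
  }
  out$site <- shift$site_id
  attr(out, "truth") <- truth
  attr(out, "ga_reporting") <- shift$ga_reporting
  out
}
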