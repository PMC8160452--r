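# Data preparation: exclusions, the derived hemoglobin ratio, Tukey-fence
# winsorization (k = 3), natural log transform, and pareto scaling
# (subtract the mean, divide by the square root of the SD). Order is fixed:
# fences are fitted and applied on the raw scale, the log follows, scaling is
# last. Birth weight is pareto-scaled without a log.

#' Apply cohort exclusion rules
#'
#' Removes records collected later than `max_collection_hours` after birth,
#' screen-positive records, and records missing sex, birth weight, GA or any
#' panel analyte. Each removed record is attributed to the *first* matching
#' rule in the order late collection, screen positive, missing field.
#'
#' @param cohort cohort data frame.
#' @param max_collection_hours threshold in hours (48 for model derivation,
#'   72 for the external cohorts by convention).
#' @return list with `cohort` (retained records) and `log` (named counts:
#'   `late_collection`, `screen_positive`, `missing_field`, `retained`).
#' @export
apply_exclusions <- function(cohort, max_collection_hours = 48) {
  stopifnot(is.numeric(max_collection_hours), max_collection_hours > 0)
  n <- nrow(cohort)
  if (n == 0) {
    return(list(cohort = cohort,
                log = c(late_collection = 0L, screen_positive = 0L,
                        missing_field = 0L, retained = 0L)))
  }
  panel <- analyte_columns(cohort)
  late <- !is.na(cohort$collection_age_hours) &
    cohort$collection_age_hours > max_collection_hours
  pos <- !late & !is.na(cohort$screen_positive) & cohort$screen_positive == 1
  core_missing <- is.na(cohort$sex) | is.na(cohort$birth_weight_g) |
    is.na(cohort$ga_weeks) | is.na(cohort$collection_age_hours)
  if (length(panel)) {
    core_missing <- core_missing |
      rowSums(is.na(cohort[, panel, drop = FALSE])) > 0
  }
  miss <- !late & !pos & core_missing
  keep <- !(late | pos | miss)
  out <- cohort[keep, , drop = FALSE]
  truth <- attr(cohort, "truth")
  if (!is.null(truth)) attr(out, "truth") <- truth[keep, , drop = FALSE]
  attr(out, "ga_reporting") <- attr(cohort, "ga_reporting")
  list(cohort = out,
       log = c(late_collection = sum(late), screen_positive = sum(pos),
               missing_field = sum(miss), retained = sum(keep)))
}

#' Fetal-to-adult hemoglobin ratio
#'
#' `(HbF + HbF1) / (HbF + HbF1 + HbA)`: the proportion of normal fetal
#' hemoglobin relative to total fetal + adult hemoglobin. Declines with
#' maturity.
#'
#' @param HbF,HbF1,HbA nonnegative hemoglobin levels (vectorized).
#' @return ratio in `[0, 1]`; `NA` where all three are zero (flagged via the
#'   `"all_zero"` attribute) or any input is missing/negative.
#' @export
compute_hb_ratio <- function(HbF, HbF1, HbA) {
  neg <- (!is.na(HbF) & HbF < 0) | (!is.na(HbF1) & HbF1 < 0) |
    (!is.na(HbA) & HbA < 0)
  denom <- HbF + HbF1 + HbA
  ratio <- (HbF + HbF1) / denom
  zero <- !is.na(denom) & denom == 0
  ratio[zero | neg] <- NA_real_
  attr(ratio, "all_zero") <- which(zero)
  ratio
}

# Adds the hb_ratio column when the hemoglobin triplet is on the panel.
add_hb_ratio <- function(cohort) {
  if (all(hemoglobin_columns %in% names(cohort)) &&
      !"hb_ratio" %in% names(cohort)) {
    r <- compute_hb_ratio(cohort$HbF, cohort$HbF1, cohort$HbA)
    attributes(r) <- NULL
    cohort$hb_ratio <- r
  }
  cohort
}

#' Tukey fences with multiplier 3
#'
#' Lower fence `Q1 - 3 IQR`, upper fence `Q3 + 3 IQR`, with quartiles from
#' linear interpolation of order statistics (the type-7 quantile convention).
#'
#' @param values numeric vector (NAs dropped); needs at least 4 non-missing.
#' @param k fence multiplier (3 per the adapted Tukey fence rule).
#' @return named numeric `c(lower, upper)`.
#' @export
fit_tukey_fences <- function(values, k = 3) {
  v <- values[!is.na(values)]
  if (length(v) < 4) {
    stop("fence_error: need at least 4 non-missing values", call. = FALSE)
  }
  q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  c(lower = q[1] - k * iqr, upper = q[2] + k * iqr)
}

#' Winsorize to fitted fences
#'
#' Values beyond a fence are assigned the fence value; in-range values pass
#' through unchanged. Idempotent.
#'
#' @param values numeric vector.
#' @param fences named `c(lower, upper)` from [fit_tukey_fences()].
#' @return clamped vector.
#' @export
winsorize <- function(values, fences) {
  pmin(pmax(values, fences[["lower"]]), fences[["upper"]])
}

#' Pareto scaling
#'
#' Subtract the mean and divide by the square root of the standard deviation,
#' so the scaled column has mean 0 and variance equal to the pre-scaling SD.
#'
#' @param values numeric vector.
#' @param center,spread mean and SD to use; default to the sample values.
#' @return scaled vector.
#' @export
pareto_scale <- function(values, center = mean(values, na.rm = TRUE),
                         spread = stats::sd(values, na.rm = TRUE)) {
  if (!is.finite(spread) || spread <= 0) {
    stop("scaling_error: zero or non-finite standard deviation", call. = FALSE)
  }
  (values - center) / sqrt(spread)
}

#' Fit (or apply) the winsorize/log/pareto preprocessing
#'
#' For each analyte: fit Tukey fences on the raw scale, winsorize, replace
#' zero readings by half the smallest positive observed value, take natural
#' logs, then pareto-scale (subtract the mean, divide by the square root of
#' the SD). Birth weight is pareto-scaled on the raw scale without a log.
#' The derived `hb_ratio` column is added first when the hemoglobin triplet
#' is present, and is treated as an analyte.
#'
#' With `params` supplied, the stored fences, offsets and scaling constants
#' are applied unchanged (the "training standardization" contract); otherwise
#' everything is refitted on this cohort ("local standardization").
#'
#' @param cohort cohort data frame (post-exclusion).
#' @param params a `preprocess_params` object to reuse, or `NULL` to fit.
#' @param label cohort label recorded as `fitted_on` when fitting.
#' @return list with `cohort` (transformed) and `params`.
#' @export
preprocess_cohort <- function(cohort, params = NULL, label = "cohort") {
  cohort <- add_hb_ratio(cohort)
  vars <- c(intersect("hb_ratio", names(cohort)), analyte_columns(cohort))
  fitting <- is.null(params)
  if (fitting) {
    params <- list(fitted_on = label, variables = list())
  } else {
    stopifnot(inherits(params, "preprocess_params"))
    absent <- setdiff(c(vars, "birth_weight_g"), names(params$variables))
    if (length(absent)) {
      stop(sprintf("scaling_error: no fitted params for: %s",
                   paste(absent, collapse = ", ")), call. = FALSE)
    }
  }
  for (v in vars) {
    x <- cohort[[v]]
    if (fitting) {
      fences <- fit_tukey_fences(x)
      pos <- x[!is.na(x) & x > 0]
      offset <- if (length(pos)) min(pos) / 2 else NA_real_
      xw <- winsorize(x, fences)
      xw[!is.na(xw) & xw <= 0] <- offset
      lx <- log(xw)
      m <- mean(lx, na.rm = TRUE)
      s <- stats::sd(lx, na.rm = TRUE)
      if (!is.finite(s) || s == 0) {
        stop(sprintf("scaling_error: zero variance for variable '%s'", v),
             call. = FALSE)
      }
      params$variables[[v]] <- list(lower_fence = fences[["lower"]],
                                    upper_fence = fences[["upper"]],
                                    log_applied = TRUE, zero_offset = offset,
                                    pareto_mean = m, pareto_sd = s)
    }
    p <- params$variables[[v]]
    xw <- winsorize(x, c(lower = p$lower_fence, upper = p$upper_fence))
    xw[!is.na(xw) & xw <= 0] <- p$zero_offset
    cohort[[v]] <- (log(xw) - p$pareto_mean) / sqrt(p$pareto_sd)
  }
  bw <- cohort$birth_weight_g
  if (fitting) {
    m <- mean(bw, na.rm = TRUE)
    s <- stats::sd(bw, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      stop("scaling_error: zero variance for variable 'birth_weight_g'",
           call. = FALSE)
    }
    params$variables$birth_weight_g <- list(
      lower_fence = -Inf, upper_fence = Inf, log_applied = FALSE,
      zero_offset = NA_real_, pareto_mean = m, pareto_sd = s)
  }
  p <- params$variables$birth_weight_g
  cohort$birth_weight_g <- (bw - p$pareto_mean) / sqrt(p$pareto_sd)
  class(params) <- "preprocess_params"
  attr(cohort, "preprocess") <- params$fitted_on
  list(cohort = cohort, params = params)
}

#' Serialize fitted preprocessing parameters to JSON
#' @param params a `preprocess_params` object.
#' @param path output path.
#' @export
write_preprocess_params <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_preprocess_params
#' @export
read_preprocess_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  class(p) <- "preprocess_params"
  p
}

#' Round gestational age down to completed weeks
#'
#' 37 weeks and 6 days (37.857) becomes 37; the same rule is applied to
#' model estimates before comparison in completed-weeks cohorts.
#'
#' @param ga_weeks nonnegative decimal weeks.
#' @return integer completed weeks.
#' @export
round_down_completed_weeks <- function(ga_weeks) {
  floor(ga_weeks)
}
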