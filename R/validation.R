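# Validation metrics: MAE = (1/n) sum |GA_ref - GA_est|,
# RMSE = sqrt((1/n) sum (GA_ref - GA_est)^2), and the percentage of infants
# estimated within +/-7 and +/-14 days (|residual| <= 1 and <= 2 weeks,
# closed bounds). Uncertainty is by 95% bootstrap percentile confidence
# intervals (2.5th/97.5th percentiles over seeded replicates, resampling
# infants so reference and estimate move together).

#' Point accuracy metrics
#'
#' @param ga_ref,ga_est reference and estimated GA (weeks), equal length.
#' @return one-row data frame: `n`, `mae`, `rmse`, `pct_within_1wk`,
#'   `pct_within_2wk` (percentages on the 0-100 scale).
#' @export
compute_metrics <- function(ga_ref, ga_est) {
  if (length(ga_ref) != length(ga_est)) {
    stop("metric_error: length mismatch", call. = FALSE)
  }
  if (length(ga_ref) == 0) stop("metric_error: empty input", call. = FALSE)
  r <- abs(ga_ref - ga_est)
  data.frame(n = length(r), mae = mean(r), rmse = sqrt(mean(r^2)),
             pct_within_1wk = 100 * mean(r <= 1),
             pct_within_2wk = 100 * mean(r <= 2))
}

#' Bootstrap percentile confidence interval
#'
#' Resamples rows of `data` with replacement, applies `statistic`, and
#' returns the 2.5th and 97.5th percentiles of the replicate distribution.
#' A replicate on which the statistic fails is redrawn (count reported via
#' the `"n_redrawn"` attribute).
#'
#' @param statistic function of a data frame returning one number.
#' @param data data frame; the row (infant) is the resampling unit.
#' @param n_replicates number of bootstrap replicates (paper default 1000).
#' @param seed RNG seed; same seed, same interval.
#' @param level confidence level.
#' @return named numeric `c(lower, upper)`.
#' @export
bootstrap_ci <- function(statistic, data, n_replicates = 1000, seed = 1L,
                         level = 0.95) {
  stopifnot(n_replicates >= 2)
  set.seed(seed)
  n <- nrow(data)
  reps <- numeric(n_replicates)
  redrawn <- 0L
  for (b in seq_len(n_replicates)) {
    for (try in 1:100) {
      idx <- sample.int(n, n, replace = TRUE)
      val <- tryCatch(statistic(data[idx, , drop = FALSE]),
                      error = function(e) NULL)
      if (!is.null(val) && is.finite(val)) break
      redrawn <- redrawn + 1L
      val <- NA_real_
    }
    reps[b] <- val
  }
  a <- (1 - level) / 2
  ci <- stats::quantile(reps, c(a, 1 - a), names = FALSE, na.rm = TRUE)
  structure(c(lower = ci[1], upper = ci[2]), n_redrawn = redrawn)
}

# All four metrics with bootstrap CIs from a single replicate stream.
.metrics_with_ci <- function(ga_ref, ga_est, n_replicates, seed, level = 0.95) {
  pt <- compute_metrics(ga_ref, ga_est)
  set.seed(seed)
  n <- length(ga_ref)
  r <- abs(ga_ref - ga_est)
  reps <- matrix(NA_real_, n_replicates, 4)
  for (b in seq_len(n_replicates)) {
    rb <- r[sample.int(n, n, replace = TRUE)]
    reps[b, ] <- c(mean(rb), sqrt(mean(rb^2)),
                   100 * mean(rb <= 1), 100 * mean(rb <= 2))
  }
  a <- (1 - level) / 2
  ci <- apply(reps, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  for (j in seq_along(c("mae", "rmse", "pct_within_1wk", "pct_within_2wk"))) {
    nm <- c("mae", "rmse", "pct_within_1wk", "pct_within_2wk")[j]
    pt[[paste0(nm, "_lower")]] <- ci[1, j]
    pt[[paste0(nm, "_upper")]] <- ci[2, j]
    if (ci[1, j] > pt[[nm]] + 1e-12 || ci[2, j] < pt[[nm]] - 1e-12) {
      warning(sprintf("percentile CI excludes the point estimate for %s", nm))
    }
  }
  pt
}

.empty_metrics <- function() {
  out <- data.frame(n = 0L, mae = NA_real_, rmse = NA_real_,
                    pct_within_1wk = NA_real_, pct_within_2wk = NA_real_)
  for (nm in c("mae", "rmse", "pct_within_1wk", "pct_within_2wk")) {
    out[[paste0(nm, "_lower")]] <- NA_real_
    out[[paste0(nm, "_upper")]] <- NA_real_
  }
  out
}

#' Full validation report for one cohort
#'
#' Accuracy metrics with bootstrap CIs overall and in the preterm, SGA10 and
#' SGA3 subgroups, the preterm-rate calibration-in-the-large (estimated rate
#' of GA < 37 weeks with bootstrap CI versus the rate observed from reference
#' GA), and residual summaries per completed week.
#'
#' For completed-weeks cohorts, residuals are computed as
#' `floor(est) - floor(ref)` and the estimated preterm flag uses the floored
#' estimate, mirroring the reporting convention of the reference GA.
#'
#' @param cohort cohort with subgroup flag columns from
#'   [classify_subgroups()].
#' @param estimates GA estimates aligned with `cohort` rows.
#' @param n_replicates bootstrap replicates.
#' @param seed RNG seed.
#' @param completed_weeks logical; `NULL` reads the cohort's
#'   `"ga_reporting"` attribute (set by [apply_site_shift()]).
#' @param cohort_label label stored in the report.
#' @return object of class `validation_report`.
#' @export
build_validation_report <- function(cohort, estimates, n_replicates = 1000,
                                    seed = 1L, completed_weeks = NULL,
                                    cohort_label = cohort$site[1]) {
  stopifnot(nrow(cohort) == length(estimates))
  need <- c("preterm", "sga10", "sga3")
  absent <- setdiff(need, names(cohort))
  if (length(absent)) {
    stop(sprintf("report_error: missing subgroup flag(s): %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  if (is.null(completed_weeks)) {
    completed_weeks <- identical(attr(cohort, "ga_reporting"),
                                 "completed_weeks")
  }
  ref <- cohort$ga_weeks
  est <- estimates
  if (completed_weeks) {
    ref <- round_down_completed_weeks(ref)
    est <- round_down_completed_weeks(est)
  }
  subsets <- list(overall = rep(TRUE, nrow(cohort)),
                  preterm = cohort$preterm,
                  sga10 = cohort$sga10,
                  sga3 = cohort$sga3)
  sub_metrics <- lapply(seq_along(subsets), function(i) {
    sel <- subsets[[i]]
    if (!any(sel)) return(.empty_metrics())
    .metrics_with_ci(ref[sel], est[sel], n_replicates, seed + i)
  })
  names(sub_metrics) <- names(subsets)

  est_pre <- est < 37
  obs_rate <- 100 * mean(ref < 37)
  rate_ci <- bootstrap_ci(function(d) 100 * mean(d$x), data.frame(x = est_pre),
                          n_replicates, seed + 99)
  resid_week <- residual_by_week(cohort, estimates,
                                 completed_weeks = completed_weeks)
  structure(list(cohort_label = cohort_label,
                 completed_weeks = completed_weeks,
                 subgroups = sub_metrics,
                 preterm_rate_estimated = 100 * mean(est_pre),
                 preterm_rate_estimated_ci = unname(rate_ci),
                 preterm_rate_observed = obs_rate,
                 residual_by_week = resid_week,
                 n_replicates = n_replicates, seed = seed),
            class = "validation_report")
}

#' Residual summary per completed gestational week
#'
#' @param cohort cohort data frame.
#' @param estimates aligned GA estimates.
#' @param completed_weeks apply the completed-weeks rounding rule to both
#'   arms before differencing.
#' @return data frame: `week`, `n`, `mean_residual` (est - ref), `mae`.
#' @export
residual_by_week <- function(cohort, estimates, completed_weeks = FALSE) {
  ref <- cohort$ga_weeks
  est <- estimates
  if (completed_weeks) {
    ref <- round_down_completed_weeks(ref)
    est <- round_down_completed_weeks(est)
  }
  week <- floor(cohort$ga_weeks)
  resid <- est - ref
  rows <- lapply(split(seq_along(resid), week), function(idx) {
    data.frame(week = week[idx[1]], n = length(idx),
               mean_residual = mean(resid[idx]), mae = mean(abs(resid[idx])))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$week), , drop = FALSE]
}

#' Flatten a validation report to a table
#'
#' One row per subgroup, mirroring the published performance-table layout
#' (MAE, RMSE and agreement bands with their CIs).
#'
#' @param x a `validation_report`.
#' @param ... unused.
#' @return data frame.
#' @export
as.data.frame.validation_report <- function(x, ...) {
  rows <- Map(function(nm, m) cbind(cohort = x$cohort_label, subgroup = nm, m),
              names(x$subgroups), x$subgroups)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize a validation report to JSON
#' @param report a `validation_report`.
#' @param path output path.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation report: %s%s\n", x$cohort_label,
              if (x$completed_weeks) " (completed weeks)" else ""))
  ov <- x$subgroups$overall
  cat(sprintf("  overall n=%d MAE=%.3f (%.3f, %.3f) RMSE=%.3f; within 1wk %.1f%%, 2wk %.1f%%\n",
              ov$n, ov$mae, ov$mae_lower, ov$mae_upper, ov$rmse,
              ov$pct_within_1wk, ov$pct_within_2wk))
  for (nm in c("preterm", "sga10", "sga3")) {
    m <- x$subgroups[[nm]]
    if (m$n > 0) {
      cat(sprintf("  %-7s n=%d MAE=%.3f (%.3f, %.3f)\n", nm, m$n, m$mae,
                  m$mae_lower, m$mae_upper))
    } else {
      cat(sprintf("  %-7s n=0 (metrics absent)\n", nm))
    }
  }
  cat(sprintf("  preterm rate: estimated %.2f%% (%.2f, %.2f) vs observed %.2f%%\n",
              x$preterm_rate_estimated, x$preterm_rate_estimated_ci[1],
              x$preterm_rate_estimated_ci[2], x$preterm_rate_observed))
  invisible(x)
}
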