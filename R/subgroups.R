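# Subgroup classification: preterm (<37 weeks), small- and large-for-
# gestational-age by birth weight percentile within completed-GA-week x sex
# strata. Reference centiles are empirical, computed from a designated
# reference cohort (by default the model-derivation cohort) and applied
# uniformly to every validation cohort.

#' Empirical birth-weight centiles by sex and completed gestational week
#'
#' @param cohort cohort data frame with raw (unscaled) `birth_weight_g`.
#' @param min_stratum_n strata with fewer records than this are omitted from
#'   the reference (their infants become unclassifiable downstream).
#' @return data frame with columns `sex`, `week`, `n`, `p3`, `p10`, `p90`.
#' @export
compute_bw_percentiles <- function(cohort, min_stratum_n = 10) {
  week <- floor(cohort$ga_weeks)
  key <- interaction(cohort$sex, week, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(cohort)), key), function(idx) {
    if (length(idx) < min_stratum_n) return(NULL)
    bw <- cohort$birth_weight_g[idx]
    q <- stats::quantile(bw, c(0.03, 0.10, 0.90), type = 7, names = FALSE,
                         na.rm = TRUE)
    data.frame(sex = cohort$sex[idx[1]], week = week[idx[1]],
               n = length(idx), p3 = q[1], p10 = q[2], p90 = q[3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sex = character(0), week = integer(0), n = integer(0),
                      p3 = numeric(0), p10 = numeric(0), p90 = numeric(0))
  }
  out <- out[order(out$sex, out$week), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify preterm and size-for-gestational-age subgroups
#'
#' Adds logical columns: `preterm` (reference GA < 37 weeks), `sga10` / `sga3`
#' (birth weight strictly below the stratum 10th / 3rd centile), `lga`
#' (strictly above the 90th), and `unclassifiable` (stratum absent from the
#' reference table). SGA3 implies SGA10 by construction.
#'
#' @param cohort cohort data frame with raw `birth_weight_g`.
#' @param reference_percentiles table from [compute_bw_percentiles()].
#' @return the cohort with flag columns added; the number of unclassifiable
#'   records is attached as attribute `"n_unclassifiable"`.
#' @export
classify_subgroups <- function(cohort, reference_percentiles) {
  week <- floor(cohort$ga_weeks)
  ref_key <- paste(reference_percentiles$sex, reference_percentiles$week)
  idx <- match(paste(cohort$sex, week), ref_key)
  p3 <- reference_percentiles$p3[idx]
  p10 <- reference_percentiles$p10[idx]
  p90 <- reference_percentiles$p90[idx]
  cohort$preterm <- !is.na(cohort$ga_weeks) & cohort$ga_weeks < 37
  cohort$sga10 <- !is.na(p10) & cohort$birth_weight_g < p10
  cohort$sga3 <- !is.na(p3) & cohort$birth_weight_g < p3
  cohort$lga <- !is.na(p90) & cohort$birth_weight_g > p90
  cohort$unclassifiable <- is.na(idx)
  attr(cohort, "n_unclassifiable") <- sum(is.na(idx))
  cohort
}
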