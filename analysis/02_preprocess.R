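#!/usr/bin/env Rscript

# Stage 2 — exclusions and data preparation.
#
# Applies the collection-age / screen-positive / missing-field exclusions
# (48 h at the derivation site, relaxed to 72 h externally), classifies
# preterm/SGA/LGA subgroups against empirical sex-by-week birth-weight
# centiles from the derivation cohort (applied uniformly), then runs the
# winsorize -> log -> pareto pipeline with local standardization per site.
# Writes prepared cohorts, exclusion logs and fitted preprocessing
# parameters under results/prepared/.

suppressPackageStartupMessages(library(nbsga))

indir <- "results/cohorts"
outdir <- "results/prepared"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

thresholds <- c(internal = 48, siteB = 72, siteC = 72)
logs <- list()
prepared <- list()

for (nm in names(thresholds)) {
  co <- read_cohort(file.path(indir, paste0(nm, "_raw.csv")))
  res <- apply_exclusions(co, thresholds[[nm]])
  logs[[nm]] <- data.frame(site = nm, t(res$log),
                           threshold_hours = thresholds[[nm]])
  prepared[[nm]] <- res$cohort
  message(sprintf("%-8s retained %d/%d (late %d, screen+ %d, missing %d)",
                  nm, res$log[["retained"]], nrow(co),
                  res$log[["late_collection"]], res$log[["screen_positive"]],
                  res$log[["missing_field"]]))
}
utils::write.csv(do.call(rbind, logs), file.path(outdir, "exclusion_log.csv"),
                 row.names = FALSE)

# SGA/LGA reference centiles from the derivation cohort, applied everywhere
ref_pct <- compute_bw_percentiles(prepared$internal)
utils::write.csv(ref_pct, file.path(outdir, "bw_reference_percentiles.csv"),
                 row.names = FALSE)

for (nm in names(prepared)) {
  flagged <- classify_subgroups(prepared[[nm]], ref_pct)
  pp <- preprocess_cohort(flagged, label = nm)
  write_preprocess_params(pp$params,
                          file.path(outdir, paste0("preprocess_params_", nm,
                                                   ".json")))
  utils::write.csv(pp$cohort, file.path(outdir, paste0(nm, "_prepared.csv")),
                   row.names = FALSE)
  message(sprintf("%-8s prepared: %d records, SGA10 %.1f%%, preterm %.1f%%",
                  nm, nrow(pp$cohort), 100 * mean(pp$cohort$sga10),
                  100 * mean(pp$cohort$preterm)))
}

message("prepared cohorts written to ", outdir)
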