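#!/usr/bin/env Rscript

# Stage 1 — simulate the three-site newborn screening study.
#
# One derivation site ("internal", decimal-week GA, full analyte panel) and
# two external validation sites: siteB reports GA in completed weeks and
# lacks two enzyme markers; siteC lacks the hemoglobin fractions entirely,
# collects samples about a day later, and shows inflated analyte dispersion.
# Writes raw cohort CSVs plus the generator ground truth (mixture component,
# growth-restriction flag) as sidecar CSVs under results/cohorts/.

suppressPackageStartupMessages(library(nbsga))

seed <- 20260923L
outdir <- "results/cohorts"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

internal_cfg <- synthetic_config(n_infants = 20000, seed = seed,
                                 site_label = "internal")
full_panel <- internal_cfg$analyte_panel

sites <- list(
  internal = list(cfg = internal_cfg, shift = NULL),
  siteB = list(
    cfg = synthetic_config(n_infants = 6000, seed = seed + 1L,
                           site_label = "siteB"),
    shift = site_shift("siteB", panel = setdiff(full_panel, c("GALT", "SUAC")),
                       multiplicative_bias = 1.1, additive_log_shift = 0.1,
                       dispersion_factor = 1.15, collection_delay_hours = 6,
                       ga_reporting = "completed_weeks")),
  siteC = list(
    cfg = synthetic_config(n_infants = 6000, seed = seed + 2L,
                           site_label = "siteC"),
    shift = site_shift("siteC",
                       panel = setdiff(full_panel,
                                       c("HbF", "HbF1", "HbA", "GALT", "BIO",
                                         "IRT", "SUAC")),
                       multiplicative_bias = 0.9, additive_log_shift = -0.05,
                       dispersion_factor = 1.2, collection_delay_hours = 24,
                       ga_reporting = "decimal_weeks"))
)

for (nm in names(sites)) {
  s <- sites[[nm]]
  co <- generate_cohort(s$cfg)
  if (!is.null(s$shift)) {
    co <- apply_site_shift(co, s$shift, seed = s$cfg$seed + 100L)
  }
  write_cohort(co, file.path(outdir, paste0(nm, "_raw.csv")))
  utils::write.csv(attr(co, "truth"),
                   file.path(outdir, paste0(nm, "_truth.csv")),
                   row.names = FALSE)
  message(sprintf(
    "%-8s n=%5d | GA mean %.2f wk (SD %.2f) | preterm %.1f%% | analytes %d",
    nm, nrow(co), mean(co$ga_weeks), sd(co$ga_weeks),
    100 * mean(co$ga_weeks < 37), length(analyte_columns(co))))
}

message("raw cohorts written to ", outdir)
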