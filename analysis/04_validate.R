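#!/usr/bin/env Rscript

# Stage 4 — internal and external validation.
#
# Applies the derivation-cohort model equations to the held-out internal
# test sub-cohort and to both external sites (restricted variants where the
# panel demands it), then reports MAE/RMSE and +/-1/+/-2-week agreement with
# bootstrap percentile CIs, overall and in the preterm/SGA10/SGA3 subgroups,
# preterm-rate calibration-in-the-large, and residuals by completed week.
# siteB reports GA in completed weeks, so both arms are floored there.

suppressPackageStartupMessages(library(nbsga))

prepdir <- "results/prepared"
modeldir <- "results/models"
outdir <- "results/validation"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
B <- 200
boot_seed <- 20260925L

read_prepared <- function(nm) {
  co <- utils::read.csv(file.path(prepdir, paste0(nm, "_prepared.csv")),
                        check.names = FALSE)
  attr(co, "preprocess") <- nm
  co
}

internal <- read_prepared("internal")
assign_tab <- utils::read.csv(file.path(modeldir, "split_assignment.csv"))
test <- internal[assign_tab$subcohort[match(internal$id, assign_tab$id)] ==
                   "test", ]

validate <- function(cohort, model_file, label, completed_weeks) {
  model <- read_ga_model(file.path(modeldir, model_file))
  est <- predict_ga(model, cohort, check_scaling = FALSE)
  utils::write.csv(data.frame(id = cohort$id, ga_ref = cohort$ga_weeks,
                              ga_est = est),
                   file.path(outdir, paste0("predictions_", label, ".csv")),
                   row.names = FALSE)
  rep <- build_validation_report(cohort, est, n_replicates = B,
                                 seed = boot_seed,
                                 completed_weeks = completed_weeks,
                                 cohort_label = label)
  write_validation_report(rep, file.path(outdir, paste0("report_", label,
                                                        ".json")))
  utils::write.csv(as.data.frame(rep),
                   file.path(outdir, paste0("report_", label, ".csv")),
                   row.names = FALSE)
  utils::write.csv(rep$residual_by_week,
                   file.path(outdir, paste0("residual_by_week_", label,
                                            ".csv")),
                   row.names = FALSE)
  print(rep)
  invisible(rep)
}

message("== internal test sub-cohort ==")
for (nm in c("model1", "model2", "model3")) {
  validate(test, paste0(nm, ".json"), paste0("internal_", nm),
           completed_weeks = FALSE)
}

message("== external sites ==")
for (site in c("siteB", "siteC")) {
  co <- read_prepared(site)
  completed <- site == "siteB"
  validate(co, "model1.json", paste0(site, "_model1"), completed)
  for (nm in c("model2", "model3")) {
    validate(co, paste0(nm, "_", site, ".json"), paste0(site, "_", nm),
             completed)
  }
}

message("validation artifacts written to ", outdir)
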