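#!/usr/bin/env Rscript

# Stage 3 — split, screen, and fit the three model families.
#
# Splits the prepared derivation cohort 50/25/25 (stratified by completed GA
# week and sex), ranks analytes by partial Spearman correlation with GA,
# places 5-knot restricted cubic splines on birth weight and the top seven
# analytes (percentile knots from the development sub-cohort), then fits:
#   Model 1  OLS: sex, splined birth weight, sex x spline interaction
#   Model 2  elastic net: sex + analytes + pairwise interactions
#   Model 3  elastic net: sex + birth weight + analytes + interactions
# with the elastic-net penalty chosen on the internal validation sub-cohort.
# Panel-restricted variants of Models 2/3 are retrained for each external
# site. Everything is written under results/models/.

suppressPackageStartupMessages(library(nbsga))

indir <- "results/prepared"
outdir <- "results/models"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
split_seed <- 20260924L

read_prepared <- function(nm) {
  utils::read.csv(file.path(indir, paste0(nm, "_prepared.csv")),
                  check.names = FALSE)
}
internal <- read_prepared("internal")
attr(internal, "preprocess") <- "internal"

subs <- split_cohort(internal, seed = split_seed)
dev <- subs$development; val <- subs$validation
message(sprintf("split: dev %d / val %d / test %d",
                nrow(dev), nrow(val), nrow(subs$test)))
utils::write.csv(data.frame(id = internal$id,
                            subcohort = rep(names(subs),
                                            vapply(subs, nrow, 1L))[
                              match(internal$id, unlist(lapply(subs, `[[`, "id")))]),
                 file.path(outdir, "split_assignment.csv"), row.names = FALSE)

candidates <- modeling_analytes(dev)
screen <- partial_spearman_screen(dev, candidates, top_k = 7)
utils::write.csv(screen, file.path(outdir, "screening.csv"), row.names = FALSE)
top <- attr(screen, "top_k")
message("top-7 screened analytes: ", paste(top, collapse = ", "))

knots_for <- function(vars) {
  stats::setNames(lapply(vars, function(v) compute_knots(dev[[v]])), vars)
}
specs <- list(
  model1 = model_spec(1, "birth_weight_g", knots_for("birth_weight_g"),
                      interactions = "sex_by_spline", top_k_splined = 0),
  model2 = model_spec(2, candidates, knots_for(top)),
  model3 = model_spec(3, c("birth_weight_g", candidates),
                      knots_for(c("birth_weight_g", top)))
)

fit_one <- function(spec, tag) {
  dd <- build_design_matrix(dev, spec)
  if (spec$model_id == 1) {
    fit <- fit_baseline_model(dd, dev$ga_weeks, spec = spec,
                              preprocess_ref = "internal")
  } else {
    dv <- build_design_matrix(val, spec)
    pp <- select_hyperparameters(dd, dev$ga_weeks, dv, val$ga_weeks)
    utils::write.csv(pp$grid,
                     file.path(outdir, paste0("penalty_path_", tag, ".csv")),
                     row.names = FALSE)
    message(sprintf("  %s: alpha %.1f, lambda %.5f (val MSE %.4f)", tag,
                    pp$chosen$l1_fraction, pp$chosen$penalty_strength,
                    pp$chosen$val_mse))
    fit <- fit_elastic_net(dd, dev$ga_weeks, pp$chosen$l1_fraction,
                           pp$chosen$penalty_strength, spec = spec,
                           preprocess_ref = "internal")
  }
  write_ga_model(fit, file.path(outdir, paste0(tag, ".json")))
  fit
}

for (nm in names(specs)) fit_one(specs[[nm]], nm)

# restricted variants for the external panels
for (site in c("siteB", "siteC")) {
  avail <- modeling_analytes(read_prepared(site))
  for (nm in c("model2", "model3")) {
    rspec <- restrict_model_spec(specs[[nm]], avail)
    if (identical(rspec$quantitative, specs[[nm]]$quantitative)) {
      file.copy(file.path(outdir, paste0(nm, ".json")),
                file.path(outdir, paste0(nm, "_", site, ".json")),
                overwrite = TRUE)
      message(sprintf("  %s/%s: full panel available, reusing full model",
                      site, nm))
    } else {
      message(sprintf("  %s/%s: restricted to %d splined analytes",
                      site, nm, rspec$top_k_splined))
      fit_one(rspec, paste0(nm, "_", site))
    }
  }
}

message("models written to ", outdir)
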