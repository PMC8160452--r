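# Synthetic cohort generator: distributional targets, reproducibility,
# hemoglobin structure, site shifts and CSV round trips.

test_that("generated GA distribution hits the configured mean and preterm fraction", {
  cfg <- synthetic_config(n_infants = 20000, seed = 101, ga_mean = 39.3,
                          ga_sd = 1.6)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co), 20000)
  se <- sd(co$ga_weeks) / sqrt(nrow(co))
  expect_lt(abs(mean(co$ga_weeks) - 39.3), 3 * se)

  cfg2 <- synthetic_config(n_infants = 10000, seed = 102,
                           preterm_target_fraction = 0.056)
  co2 <- generate_cohort(cfg2)
  n_pre <- sum(co2$ga_weeks < 37)
  # exact binomial 99% interval around 0.056 at n = 10000
  bounds <- qbinom(c(0.005, 0.995), 10000, 0.056)
  expect_gte(n_pre, bounds[1])
  expect_lte(n_pre, bounds[2])
})

test_that("an empty cohort still carries the full schema header", {
  co <- generate_cohort(synthetic_config(n_infants = 0, seed = 1))
  expect_equal(nrow(co), 0)
  expect_true(all(cohort_core_columns %in% names(co)))
  expect_true(all(c("HbF", "HbF1", "HbA", "17OHP", "TSH") %in% names(co)))
})

test_that("a fixed seed reproduces the cohort exactly", {
  cfg <- synthetic_config(n_infants = 500, seed = 77)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("invalid configurations are rejected with a configuration error", {
  expect_error(synthetic_config(male_fraction = 1.2), "config_error")
  expect_error(synthetic_config(ga_mean = NaN), "config_error|missing value")
  expect_error(synthetic_config(growth_restriction_deficit = 1.5), "config_error")
  expect_error(
    synthetic_config(analyte_effects = data.frame(analyte = character(0),
                                                  base = numeric(0),
                                                  slope = numeric(0),
                                                  sd = numeric(0))),
    "config_error")
})

test_that("the fetal hemoglobin fraction declines with GA in expectation", {
  co <- generate_cohort(synthetic_config(n_infants = 12000, seed = 103))
  ratio <- compute_hb_ratio(co$HbF, co$HbF1, co$HbA)
  bins <- cut(co$ga_weeks, breaks = c(28, 33, 35, 37, 39, 41, 43))
  m <- tapply(ratio, bins, mean)
  m <- m[!is.na(m)]
  expect_true(all(diff(m) < 0))
})

test_that("null analytes are uncorrelated with GA; informative ones are not", {
  co <- generate_cohort(synthetic_config(n_infants = 10000, seed = 104))
  for (a in c("TSH", "PHE", "C10", "GALT")) {
    expect_lt(abs(cor(co[[a]], co$ga_weeks, method = "spearman")), 0.03)
  }
  expect_gt(abs(cor(co[["17OHP"]], co$ga_weeks, method = "spearman")), 0.3)
})

test_that("growth-restricted infants weigh less within every well-filled GA-week stratum", {
  co <- generate_cohort(synthetic_config(n_infants = 15000, seed = 105))
  gr <- attr(co, "truth")$growth_restricted
  wk <- floor(co$ga_weeks)
  for (w in unique(wk)) {
    sel <- wk == w
    if (sum(sel & gr) >= 30 && sum(sel & !gr) >= 30) {
      expect_lt(mean(co$birth_weight_g[sel & gr]),
                mean(co$birth_weight_g[sel & !gr]))
    }
  }
})

test_that("preterm infants are sampled later than term infants", {
  co <- generate_cohort(synthetic_config(n_infants = 10000, seed = 106))
  pre <- co$ga_weeks < 37
  expect_gt(mean(co$collection_age_hours[pre]),
            mean(co$collection_age_hours[!pre]) + 10)
})

test_that("an identity site shift only restamps the site label", {
  co <- small_cohort(300, seed = 9)
  sh <- site_shift("elsewhere", panel = analyte_columns(co))
  out <- apply_site_shift(co, sh, seed = 4)
  expect_equal(out$site, rep("elsewhere", nrow(co)))
  out$site <- co$site
  attr(out, "ga_reporting") <- NULL
  expect_equal(out, co, tolerance = 1e-12)
})

test_that("panel restriction drops unmeasured analytes (hemoglobin-free site)", {
  co <- small_cohort(200, seed = 10)
  panel <- setdiff(analyte_columns(co), c("HbF", "HbF1", "HbA"))
  out <- apply_site_shift(co, site_shift("noHb", panel = panel), seed = 1)
  expect_false(any(c("HbF", "HbF1", "HbA") %in% names(out)))
  expect_true(all(panel %in% names(out)))
  expect_error(
    apply_site_shift(co, site_shift("bad", panel = c(panel, "NOT_AN_ANALYTE"))),
    "unknown analyte")
})

test_that("an additive log shift moves the analyte log-mean by the stated amount", {
  co <- generate_cohort(synthetic_config(n_infants = 8000, seed = 107))
  sh <- site_shift("s", panel = analyte_columns(co),
                   additive_log_shift = c(ALA = 0.5))
  out <- apply_site_shift(co, sh, seed = 2)
  expect_equal(mean(log(out$ALA)) - mean(log(co$ALA)), 0.5, tolerance = 1e-10)
  expect_equal(mean(log(out$TYR)), mean(log(co$TYR)), tolerance = 1e-12)
})

test_that("dispersion inflation scales the marginal log-SD and completed weeks floor GA", {
  co <- generate_cohort(synthetic_config(n_infants = 8000, seed = 108))
  sh <- site_shift("s", panel = analyte_columns(co),
                   dispersion_factor = c(ALA = 1.5),
                   collection_delay_hours = 24,
                   ga_reporting = "completed_weeks")
  out <- apply_site_shift(co, sh, seed = 3)
  expect_equal(sd(log(out$ALA)) / sd(log(co$ALA)), 1.5, tolerance = 0.05)
  expect_equal(out$ga_weeks, floor(co$ga_weeks))
  expect_equal(out$collection_age_hours, co$collection_age_hours + 24)
})

test_that("cohort CSV round trip is lossless and schema violations are caught", {
  co <- small_cohort(150, seed = 11)
  co$ALA[3] <- NA  # a missing analyte cell survives the round trip
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  attr(co, "truth") <- NULL
  expect_equal(back, co, tolerance = 0)

  # header without ga_weeks
  bad <- co
  names(bad)[names(bad) == "ga_weeks"] <- "gest_age"
  write_cohort_path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, write_cohort_path, row.names = FALSE, na = "")
  expect_error(read_cohort(write_cohort_path), "schema_error.*ga_weeks")

  # a non-numeric analyte cell is reported with its location
  lines <- readLines(path)
  lines[4] <- sub("^([^,]*,[^,]*,[^,]*,)[^,]*", "\\1abc", lines[4])
  writeLines(lines, path)
  expect_error(read_cohort(path), "parse_error.*birth_weight_g.*row 3")
})
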