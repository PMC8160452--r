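# Exclusion rules, hemoglobin ratio, Tukey fences, winsorization, the
# log/pareto scaling pipeline and subgroup classification.

test_that("exclusions partition removals by first matching rule", {
  fx <- exclusion_fixture()
  res <- apply_exclusions(fx, max_collection_hours = 48)
  expect_equal(unname(res$log[c("late_collection", "screen_positive",
                                "missing_field", "retained")]),
               c(1L, 1L, 1L, 3L))
  expect_equal(res$cohort$id, c("x1", "x4", "x6"))
  expect_equal(sum(res$log) - res$log[["retained"]] + res$log[["retained"]],
               nrow(fx))

  # relaxing to 72 h readmits the 50 h record
  res72 <- apply_exclusions(fx, max_collection_hours = 72)
  expect_equal(res72$log[["retained"]], 4L)
  expect_true("x2" %in% res72$cohort$id)

  clean <- fx[c(1, 4, 6), ]
  expect_equal(apply_exclusions(clean, 48)$cohort, clean)
  empty <- apply_exclusions(fx[0, ], 48)
  expect_equal(nrow(empty$cohort), 0)
  expect_true(all(empty$log == 0))
})

test_that("hemoglobin ratio follows its defining arithmetic", {
  expect_equal(compute_hb_ratio(5, 1, 0), 1.0, ignore_attr = TRUE)
  expect_equal(compute_hb_ratio(0, 0, 3), 0.0, ignore_attr = TRUE)
  expect_equal(compute_hb_ratio(70, 10, 20), 0.8, ignore_attr = TRUE)
  r <- compute_hb_ratio(c(0, 70), c(0, 10), c(0, 20))
  expect_true(is.na(r[1]))
  expect_equal(attr(r, "all_zero"), 1L)
})

test_that("Tukey fences match the order-statistic oracle and cap spikes", {
  x <- as.numeric(1:100)
  expect_equal(fit_tukey_fences(x), oracle_fences(x))
  expect_true(all(x >= fit_tukey_fences(x)[1] & x <= fit_tukey_fences(x)[2]))

  expect_equal(unname(fit_tukey_fences(rep(4.2, 10))), c(4.2, 4.2))

  spiked <- c(1:100, 1e6)
  f <- fit_tukey_fences(spiked)
  expect_lt(f[["upper"]], 1e6)
  expect_equal(max(winsorize(spiked, f)), f[["upper"]])
  expect_error(fit_tukey_fences(c(1, 2, 3)), "fence_error")
})

test_that("winsorization equals brute-force clamping and is idempotent", {
  set.seed(42)
  for (i in 1:25) {
    x <- rlnorm(200, meanlog = runif(1, 0, 3), sdlog = runif(1, 0.2, 1.5))
    f <- fit_tukey_fences(x)
    of <- oracle_fences(x)
    expect_equal(f, of)
    w <- winsorize(x, f)
    expect_equal(w, pmin(pmax(x, of["lower"]), of["upper"]),
                 ignore_attr = TRUE)
    expect_identical(winsorize(w, f), w)
  }
  inside <- runif(50, 10, 20)
  expect_identical(winsorize(inside, c(lower = 0, upper = 100)), inside)
})

test_that("pareto scaling centers to zero and leaves variance equal to the raw SD", {
  set.seed(7)
  x <- rlnorm(500, 1, 0.6)
  lx <- log(x)
  s <- pareto_scale(lx)
  expect_lt(abs(mean(s)), 1e-10)
  expect_equal(var(s), sd(lx), tolerance = 1e-8)
  # hand-checkable case: ln {e, e^2, e^3} -> {1,2,3} -> {-1, 0, 1}
  expect_equal(pareto_scale(log(c(exp(1), exp(2), exp(3)))), c(-1, 0, 1))
  expect_error(pareto_scale(rep(2, 5)), "scaling_error")
})

test_that("the preprocessing pipeline is ordered, centered and reusable across cohorts", {
  co <- small_cohort(600, seed = 21)
  res <- preprocess_cohort(co, label = "A")
  pp <- res$cohort
  for (a in c("17OHP", "ALA", "TSH", "hb_ratio", "birth_weight_g")) {
    expect_lt(abs(mean(pp[[a]])), 1e-10)
    p <- res$params$variables[[a]]
    expect_true(p$lower_fence <= p$upper_fence)
  }
  expect_equal(attr(pp, "preprocess"), "A")

  # same params applied to the same cohort reproduce the transform exactly
  again <- preprocess_cohort(co, params = res$params)
  expect_equal(again$cohort[["ALA"]], pp[["ALA"]], tolerance = 1e-12)

  # a site-shifted cohort scaled with cohort-A params has nonzero means
  sh <- site_shift("B", panel = analyte_columns(co),
                   additive_log_shift = 0.4)
  co_b <- apply_site_shift(co, sh, seed = 5)
  pp_b <- preprocess_cohort(co_b, params = res$params)$cohort
  expect_gt(abs(mean(pp_b[["ALA"]])), 0.2)
  # whereas local standardization re-centers it
  local_b <- preprocess_cohort(co_b, label = "B")$cohort
  expect_lt(abs(mean(local_b[["ALA"]])), 1e-10)
})

test_that("zero analyte readings get the half-minimum offset before the log", {
  co <- small_cohort(300, seed = 22)
  co$ALA[5] <- 0
  res <- preprocess_cohort(co, label = "z")
  expect_true(is.finite(res$cohort$ALA[5]))
  expect_equal(res$params$variables$ALA$zero_offset,
               min(co$ALA[co$ALA > 0]) / 2)
  # the zero record maps to the smallest transformed value
  expect_equal(which.min(res$cohort$ALA), 5L)
})

test_that("scaling degenerate variables names the offender", {
  co <- small_cohort(300, seed = 23)
  co$TSH <- 7.7
  expect_error(preprocess_cohort(co, label = "d"), "scaling_error.*TSH")
})

test_that("preprocessing parameters survive a JSON round trip", {
  co <- small_cohort(200, seed = 24)
  params <- preprocess_cohort(co, label = "io")$params
  path <- withr::local_tempfile(fileext = ".json")
  write_preprocess_params(params, path)
  back <- read_preprocess_params(path)
  expect_equal(back$fitted_on, "io")
  expect_equal(back$variables$ALA$pareto_mean,
               params$variables$ALA$pareto_mean, tolerance = 1e-12)
  expect_equal(back$variables$ALA$upper_fence,
               params$variables$ALA$upper_fence, tolerance = 1e-12)
})

test_that("subgroup classification respects the 37-week boundary and nesting", {
  ref <- data.frame(sex = c("M", "M"), week = c(36, 37), n = 100,
                    p3 = c(2000, 2200), p10 = c(2300, 2500),
                    p90 = c(3600, 3800))
  co <- data.frame(id = c("a", "b"), site = "s", sex = "M",
                   birth_weight_g = c(3000, 3000),
                   ga_weeks = c(36.9, 37.1), collection_age_hours = 24,
                   screen_positive = 0L)
  out <- classify_subgroups(co, ref)
  expect_equal(out$preterm, c(TRUE, FALSE))

  co2 <- generate_cohort(synthetic_config(n_infants = 8000, seed = 25))
  ref2 <- compute_bw_percentiles(co2)
  out2 <- classify_subgroups(co2, ref2)
  expect_true(all(out2$sga10[out2$sga3]))       # SGA3 nests inside SGA10
  # empirical centiles flag ~10% SGA10 inside each large stratum
  wk <- floor(co2$ga_weeks)
  for (w in 38:40) for (sx in c("M", "F")) {
    sel <- wk == w & co2$sex == sx
    n <- sum(sel)
    if (n >= 400) {
      frac <- mean(out2$sga10[sel])
      expect_lt(abs(frac - 0.10), 3 * sqrt(0.1 * 0.9 / n) + 2 / n)
    }
  }
  # order invariance
  perm <- sample(nrow(co2))
  out_perm <- classify_subgroups(co2[perm, ], ref2)
  expect_equal(out_perm$sga10, out2$sga10[perm])

  # absent stratum -> unclassifiable, counted
  tiny <- co[1, ]
  tiny$ga_weeks <- 24.5
  flagged <- classify_subgroups(tiny, ref)
  expect_true(flagged$unclassifiable)
  expect_equal(attr(flagged, "n_unclassifiable"), 1L)
})

test_that("completed-weeks rounding floors decimal gestational ages", {
  expect_equal(round_down_completed_weeks(37 + 6 / 7), 37)
  expect_equal(round_down_completed_weeks(37.0), 37)
  expect_equal(round_down_completed_weeks(36.999), 36)
})
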