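test_that("configuration validation names offending fields", {
  expect_error(cohort_config(missing_rate = 1.5), "missing_rate",
               class = "ocorm_invalid_input")
  expect_error(cohort_config(n_cont = 0), class = "ocorm_invalid_input")
  expect_error(cohort_config(noise_sd = -1), class = "ocorm_invalid_input")
  expect_error(
    cohort_config(ref_curve = c(`3` = 100, `6` = 101, `8` = 100,
                                `10` = 100, `12` = 100, `15` = 100)),
    class = "ocorm_invalid_input")
  expect_error(
    cohort_config(efsev_offset = c(`3` = 1, `6` = 1, `8` = 1,
                                   `10` = 1, `12` = 1, `15` = 1)),
    class = "ocorm_invalid_input")
})

test_that("subject sampling is reproducible and respects degenerate SDs", {
  cfg <- cohort_config(n_cont = 20, n_efsev = 20)
  a <- sample_subjects(cfg, seed = 99)
  b <- sample_subjects(cfg, seed = 99)
  expect_identical(a, b)

  degen <- cohort_config(
    n_cont = 5, n_efsev = 5,
    hbmass_per_kg_sd = c(CONT = 0, EFsev = 0),
    bmi_sd = c(CONT = 0, EFsev = 0), hct_sd = c(CONT = 0, EFsev = 0),
    mchc_sd = 0, height_sd = c(f = 0, m = 0),
    prop_female = c(CONT = 0, EFsev = 0))
  d <- sample_subjects(degen, seed = 1)
  cont <- d[d$group == "CONT", ]
  expect_equal(length(unique(cont$hbmass_true_g)), 1)
  expect_equal(unique(cont$hbmass_per_kg), 12.0)
  expect_equal(unique(d$hct_pct[d$group == "EFsev"]), 44.2)
})

test_that("group means match the configured subject distributions", {
  cfg <- cohort_config(n_cont = 2000, n_efsev = 2000)
  subj <- sample_subjects(cfg, seed = 3)
  for (g in c("CONT", "EFsev")) {
    x <- subj$hbmass_per_kg[subj$group == g]
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - cfg$hbmass_per_kg_mean[[g]]), 3 * se)
    h <- subj$hct_pct[subj$group == g]
    expect_lt(abs(mean(h) - cfg$hct_mean[[g]]), 3 * sd(h) / sqrt(length(h)))
  }
  # derived panel is internally consistent
  expect_equal(subj$hb_g_dl, subj$mchc_g_dl * subj$hct_pct / 100)
})

test_that("dose_for_target inverts the mass balance", {
  d <- dose_for_target(655, 4.30, 0.923)
  expect_equal(d$mco_ml, 42.4, tolerance = 0.002)
  expect_equal(dose_for_target(100, 1.0, 1.0)$mco_ml, 1.39)
  set.seed(12)
  for (i in 1:20) {
    hb <- runif(1, 300, 1500); tgt <- runif(1, 3, 6)
    k <- runif(1, 0.88, 1.0); up <- runif(1, 0.85, 0.98)
    d <- dose_for_target(hb, tgt, k, up)
    expect_equal(compute_hbmass(k, d$mco_ml, tgt), hb, tolerance = 1e-12)
    expect_equal(d$co_administered_ml - d$co_residual_ml, d$mco_ml)
  }
  expect_error(dose_for_target(600, -1, 0.93), class = "ocorm_invalid_input")
  expect_error(dose_for_target(600, 4, 0.93, uptake_fraction = 0),
               class = "ocorm_invalid_input")
})

test_that("noiseless cohorts round-trip the true hemoglobin mass exactly", {
  coh <- simulate_cohort(noiseless_config(30, 30), seed = 42)
  res <- analyze_sessions(coh$sessions)
  truth <- coh$subjects$hbmass_true_g[match(res$subject_id,
                                            coh$subjects$subject_id)]
  expect_lt(max(abs(res$hbmass_g - truth) / truth), 1e-9)
  # measured uptake fraction reproduces the drawn one
  expect_true(all(res$uptake_fraction > 0 & res$uptake_fraction <= 1))
})

test_that("normalized group difference equals the programmed offset exactly", {
  # one noiseless subject per group with no subject-level mixing spread
  cfg <- noiseless_config(1, 1, mixing_sd = 0,
                          target_delta_cohb_sd = 0,
                          baseline_cohb_range = c(1.1, 1.1))
  coh <- simulate_cohort(cfg, seed = 13)
  norm <- normalize_cohb(sessions_to_long(coh$sessions))
  wide <- tidyr::pivot_wider(norm, names_from = "subject_id",
                             values_from = "normalized_cohb",
                             id_cols = "time_min")
  eff <- wide[[3]] - wide[[2]]  # EFsev - CONT at each time
  expect_equal(eff, unname(cfg$efsev_offset), tolerance = 1e-9)
})

test_that("simulated cohorts are deterministic under seed", {
  cfg <- cohort_config(n_cont = 8, n_efsev = 8)
  a <- simulate_cohort(cfg, seed = 77)
  b <- simulate_cohort(cfg, seed = 77)
  expect_identical(a$sessions, b$sessions)
  c <- simulate_cohort(cfg, seed = 78)
  expect_false(identical(a$sessions$cohb_3, c$sessions$cohb_3))
})

test_that("unphysical configurations are rejected during simulation", {
  cfg <- cohort_config(n_cont = 2, n_efsev = 2,
                       target_delta_cohb_mean = 120,
                       target_delta_cohb_sd = 0,
                       target_delta_cohb_limits = c(119, 121))
  expect_error(simulate_cohort(cfg, seed = 1), class = "ocorm_invalid_input")
})

test_that("missingness and leakage are applied at the configured rates", {
  coh <- simulate_cohort(cohort_config(n_cont = 400, n_efsev = 400),
                         seed = 15)
  unchanged <- apply_missingness(coh$sessions, 0, 0, seed = 1)
  expect_equal(unchanged$cohb_3, coh$sessions$cohb_3)
  expect_false(any(unchanged$leakage_failure))

  all_leak <- apply_missingness(coh$sessions, 0, 1, seed = 1)
  expect_true(all(all_leak$leakage_failure))

  m <- apply_missingness(coh$sessions, 0.3, 0.143, seed = 2)
  frac_missing <- mean(!stats::complete.cases(
    m[, c("cohb_3", "cohb_10", "cohb_12", "cohb_15")]))
  expect_lt(abs(frac_missing - 0.3), 3 * sqrt(0.3 * 0.7 / nrow(m)))
  # conventional 6/8-min samples are never blanked
  expect_false(anyNA(m$cohb_6))
  expect_false(anyNA(m$cohb_8))
  expect_identical(apply_missingness(coh$sessions, 0.3, 0.1, seed = 9),
                   apply_missingness(coh$sessions, 0.3, 0.1, seed = 9))
  expect_error(apply_missingness(coh$sessions, 1.2, 0, seed = 1),
               class = "ocorm_invalid_input")
})

test_that("incomplete exams are excluded from kinetics but not hemoglobin mass", {
  coh <- simulate_cohort(cohort_config(n_cont = 30, n_efsev = 30), seed = 19)
  m <- apply_missingness(coh$sessions, missing_rate = 0.5, leakage_rate = 0,
                         seed = 3)
  res <- analyze_sessions(m)
  expect_equal(nrow(res), 60)  # 6/8-min samples always present
  suppressMessages(norm <- normalize_cohb(sessions_to_long(m)))
  n_excluded <- nrow(kinetics_exclusions(norm))
  expect_equal(length(unique(norm$subject_id)) + n_excluded, 60)
  expect_gt(n_excluded, 0)
})
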