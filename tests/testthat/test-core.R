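test_that("correction factor K follows both conventions", {
  expect_equal(compute_k(760, 0), 1.0)
  expect_equal(compute_k(760, 20), 1.07322, tolerance = 1e-6)
  expect_equal(compute_k(760, 20, "stpd"), 1 / 1.07322, tolerance = 1e-6)
  # the two conventions are reciprocal in the temperature term
  p <- c(705, 740, 760); tmp <- c(15, 21, 25)
  expect_equal(compute_k(p, tmp) * compute_k(p, tmp, "stpd"), (p / 760)^2)
  expect_error(compute_k(0, 20), class = "ocorm_invalid_input")
  expect_error(compute_k(-10, 20), class = "ocorm_invalid_input")
})

test_that("CO mass balance subtracts losses and rejects impossible input", {
  expect_equal(compute_mco(35.0, 2.7), 32.3)
  expect_equal(compute_mco(42.5, 0), 42.5)
  expect_equal(compute_mco(82.9 + 5.0, 5.0), 82.9)
  # itemized losses are summed
  expect_equal(compute_mco(40, c(2, 1, 0.5)), 36.5)
  expect_error(compute_mco(30, 30), class = "ocorm_invalid_input")
  expect_error(compute_mco(30, -1), class = "ocorm_invalid_input")
})

test_that("delta-COHb averages the sampling times then subtracts baseline", {
  s1 <- make_session(cohb_baseline = 1.35,
                     cohb_series = c(`6` = 6.40, `8` = 6.40))
  expect_equal(compute_delta_cohb(s1), 5.05)
  s2 <- make_session(cohb_baseline = 0.90,
                     cohb_series = c(`6` = 5.30, `8` = 5.10))
  expect_equal(compute_delta_cohb(s2), 4.30)
  s3 <- make_session(cohb_baseline = 1.0, cohb_series = c(`6` = 1.0))
  expect_equal(compute_delta_cohb(s3, sample_times = 6), 0)
  err <- expect_error(compute_delta_cohb(s1, sample_times = c(6, 8, 10)),
                      class = "ocorm_missing_data")
  expect_match(conditionMessage(err), "10")
})

test_that("hemoglobin mass matches the worked session values within 0.5%", {
  expect_equal(compute_hbmass(1.0, 1.39, 1.0), 100.0)
  for (s in example_subject_inputs()) {
    hb <- compute_hbmass(s$k, s$mco, (s$c6 + s$c8) / 2 - s$pre)
    expect_equal(hb, s$hbmass, tolerance = 0.005)
  }
  expect_error(compute_hbmass(0.93, 40, 0),
               class = "ocorm_degenerate_measurement")
  expect_error(compute_hbmass(0.93, -1, 4), class = "ocorm_invalid_input")
})

test_that("hemoglobin mass is linear in K and MCO, decreasing in delta-COHb", {
  set.seed(42)
  for (i in 1:25) {
    k <- runif(1, 0.85, 1.1); mco <- runif(1, 20, 100)
    d <- runif(1, 2, 7); a <- runif(1, 0.5, 3)
    expect_equal(compute_hbmass(k, a * mco, d),
                 a * compute_hbmass(k, mco, d))
    expect_equal(compute_hbmass(a * k, mco, d),
                 a * compute_hbmass(k, mco, d))
    expect_lt(compute_hbmass(k, mco, d + 0.5), compute_hbmass(k, mco, d))
  }
})

test_that("intravascular volumes conserve PV + RCV = BV and match hand values", {
  v <- compute_volumes(901, hematology_panel(hct = 44.2, mchc = 34.0))
  expect_equal(v$rcv_ml, 901 / 34 * 100)
  expect_equal(v$bv_ml, v$rcv_ml * 100 / (44.2 * 0.91))
  expect_equal(v$rcv_ml, 2650, tolerance = 1e-3)
  expect_equal(v$bv_ml, 6589, tolerance = 1e-3)
  expect_equal(v$pv_ml, 3939, tolerance = 1e-3)
  # unit-factor case, hand arithmetic
  v2 <- compute_volumes(100, list(mchc = 25, hct = 50), body_hct_factor = 1)
  expect_equal(unlist(v2), c(rcv_ml = 400, bv_ml = 800, pv_ml = 400))
  expect_error(compute_volumes(-5, list(mchc = 34, hct = 44)),
               class = "ocorm_invalid_input")
  expect_error(compute_volumes(900, list(mchc = 0, hct = 44)),
               class = "ocorm_invalid_input")
})

test_that("volume conservation holds exactly on randomized valid inputs", {
  set.seed(7)
  for (i in 1:100) {
    hb <- runif(1, 300, 1500)
    panel <- hematology_panel(hct = runif(1, 30, 55),
                              mchc = runif(1, 30, 38))
    fac <- runif(1, 0.85, 1.0)
    v <- compute_volumes(hb, panel, body_hct_factor = fac)
    expect_identical(v$pv_ml + v$rcv_ml, v$bv_ml)
    expect_lt(v$rcv_ml, v$bv_ml)
  }
})

test_that("uptake fraction covers its full range and rejects excess residual", {
  expect_equal(compute_uptake_fraction(40, 3.2), 0.92)
  expect_equal(compute_uptake_fraction(40, 0), 1.0)
  expect_equal(compute_uptake_fraction(40, 40), 0.0)
  expect_error(compute_uptake_fraction(40, 41), class = "ocorm_invalid_input")
})

test_that("analyze_session composes the calculations and flags safety", {
  s <- example_subject_inputs()$S1
  res <- analyze_session(make_session(
    subject_id = "S1", group = "EFsev",
    co_administered = s$mco, co_lost = 0, k_factor = s$k,
    cohb_baseline = s$pre, cohb_series = c(`6` = s$c6, `8` = s$c8)))
  expect_s3_class(res, "hbmass_result")
  expect_equal(res$hbmass_g, 429, tolerance = 0.005)
  expect_length(res$warnings, 0)
  expect_true(is.na(res$rcv_ml))

  hot <- analyze_session(make_session(
    cohb_series = c(`3` = 11.0, `6` = 9.5, `8` = 9.4, `10` = 9.3,
                    `12` = 9.2, `15` = 9.1)))
  expect_true("cohb_above_safety_threshold" %in% hot$warnings)

  low <- analyze_session(make_session(
    cohb_baseline = 2.0,
    cohb_series = c(`6` = 1.5, `8` = 5.0, `10` = 4.9, `15` = 4.8)))
  expect_true("cohb_below_baseline" %in% low$warnings)
})

test_that("volumes are attached when a hematology panel is supplied", {
  res <- analyze_session(make_session(),
                         panel = hematology_panel(hb_conc = 15.2, hct = 41.9))
  expect_equal(res$pv_ml + res$rcv_ml, res$bv_ml)
  expect_gt(res$rcv_ml, 0)
})

test_that("session and panel constructors validate their invariants", {
  expect_error(make_session(co_administered = -1),
               class = "ocorm_invalid_input")
  expect_error(make_session(co_lost = 50), class = "ocorm_invalid_input")
  expect_error(make_session(cohb_series = c(`6` = 101)),
               class = "ocorm_invalid_input")
  expect_error(make_session(cohb_series = c(`6` = 5, `7` = 5)),
               class = "ocorm_invalid_input")
  expect_error(make_session(k_factor = NULL), class = "ocorm_invalid_input")
  expect_error(hematology_panel(hct = 0), class = "ocorm_invalid_input")
  expect_error(hematology_panel(hb_conc = 15, hct = 42, mchc = 24),
               class = "ocorm_invalid_input")
  # mchc inconsistent with hb/hct by > 15%
  expect_error(hematology_panel(hb_conc = 15, hct = 42, mchc = 30),
               class = "ocorm_invalid_input")
  expect_silent(hematology_panel(hb_conc = 15, hct = 42, mchc = 36))
})
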