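#' Configuration of a synthetic two-group rebreathing cohort
#'
#' Defines the distributions from which synthetic CONT (normal ejection
#' fraction) and EFsev (ejection fraction below 30 percent) subjects and
#' their oCORM exams are drawn. The defaults encode the published group
#' characteristics of a heart-failure rebreathing cohort: hemoglobin mass
#' per kg, BMI, hematocrit, sex ratios, the 2-min CO uptake fraction
#' (92 +/- 3 percent), baseline COHb between 0.8 and 1.4 percent, and a
#' normalized kinetics profile whose EFsev excess over CONT is
#' 2.8 / 1.0 / 0.4 / 0.5 / 0.3 / 0 normalized points at
#' 3 / 6 / 8 / 10 / 12 / 15 min. The reference normalized washout curve
#' `ref_curve`, the height distributions, the subject-level mixing spread
#' and the measurement noise are not published quantities; they are
#' package defaults chosen to reproduce the published absolute COHb means
#' (6.0 percent at 3 min, 5.6 percent at 6 min) and the scale of the
#' reported group comparison (see the methods vignette), and every one of
#' them is exposed here.
#'
#' @param n_cont,n_efsev Number of subjects per group.
#' @param hbmass_per_kg_mean,hbmass_per_kg_sd Named per-group mean/SD of
#'   true hemoglobin mass per body mass, g/kg.
#' @param bmi_mean,bmi_sd Named per-group BMI distributions, kg/m^2.
#' @param hct_mean,hct_sd Named per-group hematocrit distributions, percent.
#' @param mchc_mean,mchc_sd MCHC distribution, g/dL; hemoglobin
#'   concentration is derived as `mchc * hct / 100` so the panel is
#'   internally consistent.
#' @param prop_female Named per-group proportion of female subjects.
#' @param height_mean,height_sd Height distributions by sex (`f`, `m`), cm.
#' @param baseline_cohb_range Uniform range of pre-rebreathing COHb,
#'   percent.
#' @param target_delta_cohb_mean,target_delta_cohb_sd,target_delta_cohb_limits
#'   Distribution (Normal, truncated to the limits) of the targeted
#'   COHb increase at the 6/8-min sampling times, percentage points; the CO
#'   dose of each exam is chosen to hit it.
#' @param uptake_mean,uptake_sd 2-min CO uptake fraction distribution
#'   (truncated to (0, 1]).
#' @param pressure_mean,pressure_sd,temperature_mean,temperature_sd
#'   Ambient conditions, mmHg and degrees Celsius.
#' @param k_convention Convention used to compute K for synthetic exams;
#'   default `"stpd"`, which yields the sub-unity K values (about 0.93)
#'   typical of session reports.
#' @param ref_curve Named reference normalized COHb curve r(t) of the CONT
#'   group, percent of the 15-min value at t = 3, 6, 8, 10, 12, 15 min;
#'   must be non-increasing with r(15) = 100.
#' @param efsev_offset Named EFsev excess delta(t) over `ref_curve` in
#'   normalized points; delta(15) = 0.
#' @param mixing_sd SD of the subject-level mixing offset added to the
#'   normalized curve at all pre-reference times, normalized points.
#' @param noise_sd SD of the additive Gaussian measurement noise per
#'   recorded COHb sample, percentage points. Set to 0 for noiseless data.
#' @param resolution Recording resolution of COHb values, percentage
#'   points (0.01 mirrors two-decimal hemoximeter output); 0 disables
#'   rounding.
#' @param missing_rate Probability that an exam lacks one of the
#'   non-conventional sampling times (3, 10, 12 or 15 min).
#' @param leakage_rate Probability that an exam is flagged as a CO leakage
#'   failure.
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(
    n_cont = 25L, n_efsev = 21L,
    hbmass_per_kg_mean = c(CONT = 12.0, EFsev = 10.6),
    hbmass_per_kg_sd = c(CONT = 2.5, EFsev = 1.6),
    bmi_mean = c(CONT = 22.7, EFsev = 27.6),
    bmi_sd = c(CONT = 2.6, EFsev = 3.2),
    hct_mean = c(CONT = 41.9, EFsev = 44.2),
    hct_sd = c(CONT = 3.7, EFsev = 4.0),
    mchc_mean = 36.3, mchc_sd = 1.2,
    prop_female = c(CONT = 10 / 25, EFsev = 6 / 21),
    height_mean = c(f = 165, m = 175),
    height_sd = c(f = 6, m = 7),
    baseline_cohb_range = c(0.8, 1.4),
    target_delta_cohb_mean = 4.5, target_delta_cohb_sd = 0.9,
    target_delta_cohb_limits = c(2.0, 7.5),
    uptake_mean = 0.92, uptake_sd = 0.03,
    pressure_mean = 755, pressure_sd = 5,
    temperature_mean = 19, temperature_sd = 2,
    k_convention = "stpd",
    ref_curve = c(`3` = 108.6, `6` = 102.4, `8` = 102.2,
                  `10` = 101.6, `12` = 100.8, `15` = 100),
    efsev_offset = c(`3` = 2.8, `6` = 1.0, `8` = 0.4,
                     `10` = 0.5, `12` = 0.3, `15` = 0),
    mixing_sd = 4.5,
    noise_sd = 0.05, resolution = 0.01,
    missing_rate = 0, leakage_rate = 0) {
  cfg <- as.list(environment())

  sds <- c(hbmass_per_kg_sd, bmi_sd, hct_sd, mchc_sd, height_sd,
           target_delta_cohb_sd, uptake_sd, pressure_sd, temperature_sd,
           mixing_sd, noise_sd)
  if (any(sds < 0)) {
    stop_ocorm("All standard deviations must be non-negative.",
               "ocorm_invalid_input")
  }
  if (n_cont < 1 || n_efsev < 1) {
    stop_ocorm("`n_cont` and `n_efsev` must be at least 1.",
               "ocorm_invalid_input")
  }
  for (fld in c("missing_rate", "leakage_rate")) {
    v <- cfg[[fld]]
    if (v < 0 || v > 1) {
      stop_ocorm(sprintf("`%s` must lie within [0, 1].", fld),
                 "ocorm_invalid_input")
    }
  }
  tms <- as.character(COHB_TIMES)
  if (!identical(names(ref_curve), tms) ||
      !identical(names(efsev_offset), tms)) {
    stop_ocorm(
      "`ref_curve` and `efsev_offset` must be named by the times 3..15.",
      "ocorm_invalid_input")
  }
  if (ref_curve[["15"]] != 100 || any(diff(ref_curve) > 0)) {
    stop_ocorm("`ref_curve` must be non-increasing with r(15) = 100.",
               "ocorm_invalid_input")
  }
  if (efsev_offset[["15"]] != 0) {
    stop_ocorm("`efsev_offset` must vanish at the 15-min reference.",
               "ocorm_invalid_input")
  }
  if (resolution < 0) {
    stop_ocorm("`resolution` must be non-negative.", "ocorm_invalid_input")
  }
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> %d CONT + %d EFsev subjects\n",
              x$n_cont, x$n_efsev))
  cat(sprintf("  target dCOHb %.1f +/- %.1f pts; noise SD %.2f pts\n",
              x$target_delta_cohb_mean, x$target_delta_cohb_sd, x$noise_sd))
  cat(sprintf("  EFsev normalized offsets: %s\n",
              paste(x$efsev_offset, collapse = "/")))
  invisible(x)
}

# Normal sampling truncated to [lower, upper] by resampling.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

#' Sample synthetic subject profiles
#'
#' Draws per-group subject characteristics: sex, height (by sex), BMI,
#' body mass (from BMI and height), true hemoglobin mass (g/kg times body
#' mass), hematocrit, MCHC and the derived hemoglobin concentration.
#' All quantities are truncated to physiologic ranges by resampling.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the same seed yields an identical cohort.
#'
#' @return Tibble with one row per subject: `subject_id`, `group`, `sex`,
#'   `height_cm`, `bmi`, `body_mass_kg`, `hbmass_per_kg`, `hbmass_true_g`,
#'   `hct_pct`, `mchc_g_dl`, `hb_g_dl`.
#' @export
sample_subjects <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(seed, {
    groups <- rep(c("CONT", "EFsev"), c(config$n_cont, config$n_efsev))
    n <- length(groups)
    sex <- character(n)
    height <- bmi <- perkg <- hct <- mchc <- numeric(n)
    for (g in c("CONT", "EFsev")) {
      idx <- which(groups == g)
      ng <- length(idx)
      if (ng == 0) next
      sex[idx] <- ifelse(runif(ng) < config$prop_female[[g]], "f", "m")
      bmi[idx] <- rnorm_trunc(ng, config$bmi_mean[[g]], config$bmi_sd[[g]],
                              14, 50)
      perkg[idx] <- rnorm_trunc(ng, config$hbmass_per_kg_mean[[g]],
                                config$hbmass_per_kg_sd[[g]], 1, Inf)
      hct[idx] <- rnorm_trunc(ng, config$hct_mean[[g]], config$hct_sd[[g]],
                              20, 60)
    }
    for (s in c("f", "m")) {
      idx <- which(sex == s)
      if (length(idx) == 0) next
      height[idx] <- rnorm_trunc(length(idx), config$height_mean[[s]],
                                 config$height_sd[[s]], 120, 220)
    }
    mchc <- rnorm_trunc(n, config$mchc_mean, config$mchc_sd, 30, 40)
    mass <- bmi * (height / 100)^2
    tibble::tibble(
      subject_id = sprintf("SYN%04d", seq_len(n)),
      group = groups, sex = sex,
      height_cm = height, bmi = bmi, body_mass_kg = mass,
      hbmass_per_kg = perkg, hbmass_true_g = perkg * mass,
      hct_pct = hct, mchc_g_dl = mchc,
      hb_g_dl = mchc * hct / 100)
  })
}

#' CO dose that hits a target COHb increase
#'
#' Inverts the oCORM mass balance: the circulating CO volume needed so
#' that a subject with the given hemoglobin mass shows the target
#' delta-COHb at the 6/8-min sampling times is
#' `MCO = Hbmass * 1.39 * target / (100 * K)`. The administered volume
#' follows from the 2-min uptake fraction and the circuit residual is
#' their difference, so [compute_hbmass()] recovers the hemoglobin mass
#' exactly in noiseless data.
#'
#' @param hbmass_g True hemoglobin mass, g.
#' @param target_delta_cohb Target COHb increase, percentage points.
#' @param k_factor Correction factor K of the exam.
#' @param uptake_fraction 2-min CO uptake fraction in (0, 1].
#'
#' @return List with `mco_ml`, `co_administered_ml`, `co_residual_ml`.
#' @export
#' @examples
#' dose_for_target(655, 4.30, 0.923)  # MCO about 42.4 ml
dose_for_target <- function(hbmass_g, target_delta_cohb, k_factor,
                            uptake_fraction = 0.92) {
  if (any(target_delta_cohb <= 0)) {
    stop_ocorm("`target_delta_cohb` must be positive.", "ocorm_invalid_input")
  }
  if (any(uptake_fraction <= 0) || any(uptake_fraction > 1)) {
    stop_ocorm("`uptake_fraction` must lie within (0, 1].",
               "ocorm_invalid_input")
  }
  mco <- hbmass_g * HUFNER * target_delta_cohb / (100 * k_factor)
  adm <- mco / uptake_fraction
  list(mco_ml = mco, co_administered_ml = adm, co_residual_ml = adm - mco)
}

# Simulate the recorded COHb values of one exam. `profile_row` is one row
# of sample_subjects(); draws (baseline, target delta, mixing offset,
# conditions) are made by the caller so the whole cohort sits under one
# seed envelope.
simulate_cohb_series <- function(baseline, target_delta, mixing_offset,
                                 group, config) {
  curve <- config$ref_curve +
    if (group == "EFsev") config$efsev_offset else 0
  pre_ref <- COHB_TIMES != 15
  curve[pre_ref] <- curve[pre_ref] + mixing_offset
  mean_68 <- (curve[["6"]] + curve[["8"]]) / 2
  cohb_15 <- 100 * (baseline + target_delta) / mean_68
  true_vals <- cohb_15 * curve / 100

  noisy <- c(pre = baseline, true_vals) + rnorm(7, 0, config$noise_sd)
  if (config$resolution > 0) {
    noisy <- round(noisy / config$resolution) * config$resolution
  }
  noisy <- pmax(noisy, 0)
  if (any(noisy > 100)) {
    stop_ocorm("Simulated COHb above 100%: unphysical configuration.",
               "ocorm_invalid_input")
  }
  noisy
}

#' Simulate a complete synthetic rebreathing cohort
#'
#' Draws subjects via [sample_subjects()], then per subject an exam: a
#' baseline COHb, a target delta-COHb (the CO dose is chosen with
#' [dose_for_target()] to hit it), ambient conditions and the resulting K,
#' a subject-level mixing offset, the group kinetics profile, measurement
#' noise and recording resolution. With `noise_sd = 0` and
#' `resolution = 0` the recorded COHb values are exact and
#' [analyze_session()] recovers every subject's true hemoglobin mass to
#' machine precision; the EFsev kinetics excess lives on the normalized
#' curve shape, where [group_contrasts()] can measure it.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#'
#' @return An object of class `ocorm_cohort`: list with `subjects` (see
#'   [sample_subjects()]), `sessions` (wide session tibble as consumed by
#'   [analyze_sessions()] and [sessions_to_long()]) and `config`.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_config(n_cont = 3, n_efsev = 3), seed = 7)
#' analyze_sessions(coh$sessions)
simulate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  subjects <- sample_subjects(config, seed = seed)
  n <- nrow(subjects)
  sessions <- withr::with_seed(seed + 10000L, {
    baseline <- runif(n, config$baseline_cohb_range[1],
                      config$baseline_cohb_range[2])
    target <- rnorm_trunc(n, config$target_delta_cohb_mean,
                          config$target_delta_cohb_sd,
                          config$target_delta_cohb_limits[1],
                          config$target_delta_cohb_limits[2])
    mixing <- rnorm(n, 0, config$mixing_sd)
    pressure <- rnorm_trunc(n, config$pressure_mean, config$pressure_sd,
                            500, 800)
    temperature <- rnorm_trunc(n, config$temperature_mean,
                               config$temperature_sd, 10, 30)
    uptake <- rnorm_trunc(n, config$uptake_mean, config$uptake_sd,
                          1e-3, 1)
    k <- compute_k(pressure, temperature, config$k_convention)

    rows <- lapply(seq_len(n), function(i) {
      dose <- dose_for_target(subjects$hbmass_true_g[i], target[i], k[i],
                              uptake[i])
      cohb <- simulate_cohb_series(baseline[i], target[i], mixing[i],
                                   subjects$group[i], config)
      tibble::tibble(
        subject_id = subjects$subject_id[i],
        group = subjects$group[i],
        pressure_mmhg = pressure[i], temperature_c = temperature[i],
        k_factor = k[i],
        co_administered_ml = dose$co_administered_ml,
        co_lost_ml = dose$co_residual_ml,
        co_residual_ml = dose$co_residual_ml,
        cohb_pre = cohb[["pre"]],
        cohb_3 = cohb[["3"]], cohb_6 = cohb[["6"]], cohb_8 = cohb[["8"]],
        cohb_10 = cohb[["10"]], cohb_12 = cohb[["12"]],
        cohb_15 = cohb[["15"]],
        hb_g_dl = subjects$hb_g_dl[i], hct_pct = subjects$hct_pct[i],
        mchc_g_dl = subjects$mchc_g_dl[i],
        body_mass_kg = subjects$body_mass_kg[i])
    })
    dplyr::bind_rows(rows)
  })
  structure(list(subjects = subjects, sessions = sessions, config = config,
                 seed = seed),
            class = "ocorm_cohort")
}

#' @export
print.ocorm_cohort <- function(x, ...) {
  cat(sprintf("<ocorm_cohort> %d subjects (%d CONT, %d EFsev), seed %d\n",
              nrow(x$subjects), sum(x$subjects$group == "CONT"),
              sum(x$subjects$group == "EFsev"), x$seed))
  invisible(x)
}

#' Apply missingness and leakage failures to a session table
#'
#' Emulates the data losses of real rebreathing campaigns: a fraction of
#' exams fail CO leakage quality control (flagged, to be excluded from all
#' analyses) and a fraction lack one of the non-conventional sampling
#' times (3, 10, 12 or 15 min; the conventional 6- and 8-min samples are
#' always retained), which excludes those subjects from the kinetics
#' analysis but not from hemoglobin-mass determination.
#'
#' @param sessions Wide session tibble.
#' @param missing_rate Probability that an exam loses one random
#'   non-conventional timepoint; default 0.114.
#' @param leakage_rate Probability of a leakage failure; default 0.143.
#' @param seed Integer seed.
#'
#' @return The session tibble with NA-ed timepoints and a logical
#'   `leakage_failure` column.
#' @export
apply_missingness <- function(sessions, missing_rate = 0.114,
                              leakage_rate = 0.143, seed = 1L) {
  if (missing_rate < 0 || missing_rate > 1 ||
      leakage_rate < 0 || leakage_rate > 1) {
    stop_ocorm("`missing_rate` and `leakage_rate` must lie within [0, 1].",
               "ocorm_invalid_input")
  }
  withr::with_seed(seed, {
    n <- nrow(sessions)
    sessions$leakage_failure <- runif(n) < leakage_rate
    hit <- runif(n) < missing_rate
    droppable <- c("cohb_3", "cohb_10", "cohb_12", "cohb_15")
    droppable <- droppable[droppable %in% names(sessions)]
    for (i in which(hit)) {
      col <- sample(droppable, 1)
      sessions[i, col] <- NA_real_
    }
    sessions
  })
}
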