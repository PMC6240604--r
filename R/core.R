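#' Barometric pressure and temperature correction factor K
#'
#' Normalizes the administered CO gas volume for ambient conditions.
#' Two conventions are provided. `"as_printed"` follows the formula as it
#' is usually written for oCORM, `K = (pressure/760) * (1 + 0.003661 * T)`.
#' `"stpd"` is the standard temperature-pressure-dry gas conversion, which
#' divides by the temperature term, `K = (pressure/760) / (1 + 0.003661 * T)`;
#' only this convention yields the sub-unity K values (about 0.93) seen on
#' typical session reports at room temperature near sea level. Both are kept
#' because written sources and worked session values disagree on the
#' direction of the temperature term; see the methods vignette.
#'
#' @param pressure Barometric pressure, mmHg; must be positive.
#' @param temperature Ambient temperature, degrees Celsius.
#' @param convention `"as_printed"` (default) or `"stpd"`.
#'
#' @return Dimensionless correction factor (vectorized).
#' @export
#' @examples
#' compute_k(760, 20)           # 1.07322
#' compute_k(760, 20, "stpd")   # 0.93178
compute_k <- function(pressure, temperature,
                      convention = c("as_printed", "stpd")) {
  convention <- match.arg(convention)
  if (any(!is.finite(pressure)) || any(pressure <= 0)) {
    stop_ocorm("`pressure` must be positive (mmHg).", "ocorm_invalid_input")
  }
  f <- 1 + 0.003661 * temperature
  if (convention == "as_printed") pressure / 760 * f else pressure / 760 / f
}

#' CO volume circulating in blood
#'
#' The CO mass balance of the exam: administered volume minus the losses to
#' the spirometer system, the lung and exhalation up to blood sampling.
#'
#' @param co_administered CO volume administered into the circuit, ml.
#' @param co_lost Total CO lost, ml; itemized loss components may be passed
#'   as a vector and are summed.
#'
#' @return Circulating CO volume (MCO), ml.
#' @export
#' @examples
#' compute_mco(35.0, 2.7)  # 32.3
compute_mco <- function(co_administered, co_lost) {
  co_lost <- sum(co_lost)
  if (!is.finite(co_administered) || co_administered <= 0) {
    stop_ocorm("`co_administered` must be positive (ml).",
               "ocorm_invalid_input")
  }
  if (!is.finite(co_lost) || co_lost < 0 || co_lost >= co_administered) {
    stop_ocorm("`co_lost` must satisfy 0 <= co_lost < co_administered.",
               "ocorm_invalid_input")
  }
  co_administered - co_lost
}

#' COHb increase attributable to the administered CO
#'
#' Mean COHb at the requested sampling times minus the pre-rebreathing
#' baseline, in percentage points. The conventional oCORM protocol samples
#' at 6 and 8 min.
#'
#' @param session A [rebreathing_session()].
#' @param sample_times Sampling minutes to average; default `c(6, 8)`.
#'
#' @return Delta-COHb, percentage points.
#' @export
compute_delta_cohb <- function(session, sample_times = c(6, 8)) {
  stopifnot(inherits(session, "rebreathing_session"))
  ser <- session$cohb_series
  missing_t <- setdiff(sample_times, ser$time_min)
  if (length(missing_t) > 0) {
    stop_ocorm(
      sprintf("Subject %s: no COHb value at %s min.",
              session$subject_id, paste(missing_t, collapse = ", ")),
      "ocorm_missing_data")
  }
  vals <- ser$cohb_percent[match(sample_times, ser$time_min)]
  mean(vals) - session$cohb_baseline
}

#' Total hemoglobin mass from the oCORM mass balance
#'
#' `Hbmass = K * MCO * 100 / (deltaCOHb * 1.39)`, where 1.39 ml/g is
#' Hufner's number, the CO binding capacity of hemoglobin.
#'
#' @param k_factor Pressure/temperature correction factor (dimensionless).
#' @param mco Circulating CO volume, ml.
#' @param delta_cohb COHb increase above baseline, percentage points.
#'
#' @return Hemoglobin mass, g (vectorized over its arguments).
#' @export
#' @examples
#' compute_hbmass(0.934, 32.3, 5.05)  # about 430 g
compute_hbmass <- function(k_factor, mco, delta_cohb) {
  if (any(!is.finite(delta_cohb)) || any(delta_cohb <= 0)) {
    stop_ocorm(
      "`delta_cohb` must be positive: no CO uptake detected.",
      "ocorm_degenerate_measurement")
  }
  if (any(!is.finite(mco)) || any(mco <= 0) ||
      any(!is.finite(k_factor)) || any(k_factor <= 0)) {
    stop_ocorm("`mco` and `k_factor` must be positive.",
               "ocorm_invalid_input")
  }
  k_factor * mco * 100 / (delta_cohb * HUFNER)
}

#' Intravascular volumes from hemoglobin mass
#'
#' Red cell volume follows from hemoglobin mass and MCHC; blood volume from
#' red cell volume and the hematocrit after correction to whole-body
#' hematocrit (venous/capillary Hct times 0.91); plasma volume is the
#' difference, so `pv + rcv == bv` holds exactly by construction.
#'
#' @param hbmass_g Hemoglobin mass, g.
#' @param panel A [hematology_panel()] (or list with `mchc` and `hct`).
#' @param body_hct_factor Whole-body hematocrit correction factor applied to
#'   the measured hematocrit; default 0.91.
#'
#' @return A list with `rcv_ml`, `bv_ml`, `pv_ml`.
#' @export
#' @examples
#' compute_volumes(901, hematology_panel(hct = 44.2, mchc = 34.0))
compute_volumes <- function(hbmass_g, panel, body_hct_factor = 0.91) {
  if (!is.finite(hbmass_g) || hbmass_g <= 0) {
    stop_ocorm("`hbmass_g` must be positive.", "ocorm_invalid_input")
  }
  mchc <- panel$mchc
  hct <- panel$hct
  if (is.null(mchc) || is.na(mchc) || mchc <= 0 ||
      is.null(hct) || is.na(hct) || hct <= 0) {
    stop_ocorm("`panel` must provide positive `mchc` and `hct`.",
               "ocorm_invalid_input")
  }
  rcv <- hbmass_g / mchc * 100
  hct_body <- hct * body_hct_factor
  bv <- rcv * 100 / hct_body
  pv <- bv - rcv
  # re-derive bv from its parts so pv + rcv == bv holds bit-exactly
  list(rcv_ml = rcv, bv_ml = pv + rcv, pv_ml = pv)
}

#' Two-minute CO uptake fraction
#'
#' Fraction of the administered CO that left the spirometer circuit during
#' the 2-min rebreathing period, `(administered - residual) / administered`.
#' Proportional to pulmonary CO diffusion capacity and therefore a coarse
#' check that group differences in COHb kinetics are not driven by
#' differences in CO diffusion.
#'
#' @param co_administered CO volume administered, ml.
#' @param co_residual_after_2min CO remaining in the circuit after 2 min, ml.
#'
#' @return Uptake fraction in `[0, 1]`.
#' @export
compute_uptake_fraction <- function(co_administered, co_residual_after_2min) {
  if (any(co_administered <= 0) || any(co_residual_after_2min < 0) ||
      any(co_residual_after_2min > co_administered)) {
    stop_ocorm(
      "`co_residual_after_2min` must lie within [0, co_administered].",
      "ocorm_invalid_input")
  }
  (co_administered - co_residual_after_2min) / co_administered
}

#' Analyze one rebreathing session
#'
#' Composes the oCORM calculations for a single exam: correction factor K
#' (a supplied `k_factor` is used verbatim, otherwise it is computed from
#' pressure and temperature), CO mass balance, delta-COHb at the configured
#' sampling times, hemoglobin mass, intravascular volumes (when a
#' hematology panel is available) and the 2-min CO uptake fraction (when
#' the circuit residual is available). A safety flag is raised when any
#' recorded COHb exceeds the threshold (default 10 percent).
#'
#' @param session A [rebreathing_session()].
#' @param panel Optional [hematology_panel()]; without it the volumes are
#'   `NA`.
#' @param sample_times Sampling minutes for delta-COHb; default `c(6, 8)`.
#' @param k_convention Convention for [compute_k()] when no `k_factor` is
#'   supplied.
#' @param body_hct_factor Whole-body hematocrit factor; default 0.91.
#' @param safety_threshold COHb level (percent) above which a safety
#'   warning flag is attached; default 10.
#'
#' @return An object of class `hbmass_result`: a list with `subject_id`,
#'   `group`, `k_factor`, `mco`, `delta_cohb`, `hbmass_g`, `rcv_ml`,
#'   `bv_ml`, `pv_ml`, `uptake_fraction` and a character vector `warnings`.
#' @export
analyze_session <- function(session, panel = NULL, sample_times = c(6, 8),
                            k_convention = c("as_printed", "stpd"),
                            body_hct_factor = 0.91, safety_threshold = 10) {
  stopifnot(inherits(session, "rebreathing_session"))
  k_convention <- match.arg(k_convention)
  warnings <- session$flags

  k <- session$k_factor %||%
    compute_k(session$pressure, session$temperature, k_convention)
  mco <- compute_mco(session$co_administered, session$co_lost)
  delta <- compute_delta_cohb(session, sample_times)
  hbm <- compute_hbmass(k, mco, delta)

  if (any(session$cohb_series$cohb_percent > safety_threshold)) {
    warnings <- c(warnings, "cohb_above_safety_threshold")
  }

  vols <- list(rcv_ml = NA_real_, bv_ml = NA_real_, pv_ml = NA_real_)
  if (!is.null(panel)) {
    vols <- compute_volumes(hbm, panel, body_hct_factor)
  }
  uptake <- NA_real_
  if (!is.null(session$co_residual) && !is.na(session$co_residual)) {
    uptake <- compute_uptake_fraction(session$co_administered,
                                      session$co_residual)
  }

  structure(
    list(
      subject_id = session$subject_id, group = session$group,
      k_factor = k, mco = mco, delta_cohb = delta, hbmass_g = hbm,
      rcv_ml = vols$rcv_ml, bv_ml = vols$bv_ml, pv_ml = vols$pv_ml,
      uptake_fraction = uptake, warnings = warnings
    ),
    class = "hbmass_result"
  )
}

#' @export
print.hbmass_result <- function(x, ...) {
  cat(sprintf("<hbmass_result> subject %s (%s)\n", x$subject_id, x$group))
  cat(sprintf("  K %.3f, MCO %.1f ml, dCOHb %.2f pts\n",
              x$k_factor, x$mco, x$delta_cohb))
  cat(sprintf("  Hbmass %.0f g", x$hbmass_g))
  if (!is.na(x$rcv_ml)) {
    cat(sprintf("; RCV %.0f, BV %.0f, PV %.0f ml", x$rcv_ml, x$bv_ml, x$pv_ml))
  }
  cat("\n")
  if (length(x$warnings)) {
    cat("  warnings:", paste(x$warnings, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Analyze a table of rebreathing sessions
#'
#' Row-wise [analyze_session()] over a wide session table as read by
#' [read_sessions()]. Rows that cannot be analyzed (e.g. a missing sampling
#' time) are skipped with a message and reported in the `skipped` attribute.
#'
#' @param sessions Wide session tibble (see [read_sessions()] for the
#'   column layout).
#' @inheritParams analyze_session
#'
#' @return A tibble with one row per analyzable session mirroring the
#'   `hbmass_result` fields, warnings collapsed with `";"`. The attribute
#'   `"skipped"` holds a tibble of skipped rows and reasons.
#' @export
analyze_sessions <- function(sessions, sample_times = c(6, 8),
                             k_convention = "as_printed",
                             body_hct_factor = 0.91, safety_threshold = 10) {
  if (nrow(sessions) == 0) {
    stop_ocorm("The session table is empty.", "ocorm_invalid_input")
  }
  out <- vector("list", nrow(sessions))
  skipped <- list()
  for (i in seq_len(nrow(sessions))) {
    row <- sessions[i, ]
    res <- tryCatch({
      sess <- session_from_row(row)
      panel <- panel_from_row(row)
      analyze_session(sess, panel, sample_times = sample_times,
                      k_convention = k_convention,
                      body_hct_factor = body_hct_factor,
                      safety_threshold = safety_threshold)
    }, ocorm_error = function(e) e)
    if (inherits(res, "error")) {
      message(sprintf("Skipping subject %s: %s",
                      row$subject_id, conditionMessage(res)))
      skipped[[length(skipped) + 1]] <-
        tibble::tibble(subject_id = as.character(row$subject_id),
                       reason = conditionMessage(res))
    } else {
      out[[i]] <- tibble::tibble(
        subject_id = res$subject_id, group = res$group,
        k_factor = res$k_factor, mco_ml = res$mco,
        delta_cohb = res$delta_cohb, hbmass_g = res$hbmass_g,
        rcv_ml = res$rcv_ml, bv_ml = res$bv_ml, pv_ml = res$pv_ml,
        uptake_fraction = res$uptake_fraction,
        warnings = paste(res$warnings, collapse = ";")
      )
    }
  }
  result <- dplyr::bind_rows(out)
  if (nrow(result) == 0) {
    stop_ocorm("No session row could be analyzed.", "ocorm_invalid_input")
  }
  attr(result, "skipped") <- dplyr::bind_rows(skipped)
  result
}

# Build a rebreathing_session from one wide table row.
session_from_row <- function(row) {
  cohb_cols <- paste0("cohb_", COHB_TIMES)
  present <- cohb_cols[cohb_cols %in% names(row)]
  vals <- as.numeric(row[1, present])
  names(vals) <- sub("^cohb_", "", present)
  co_lost <- if ("co_lost_ml" %in% names(row) && !is.na(row$co_lost_ml)) {
    row$co_lost_ml
  } else {
    sum(row$co_residual_ml %||% 0, row$co_exhaled_ml %||% 0,
        row$co_myoglobin_ml %||% 0, na.rm = TRUE)
  }
  k <- if ("k_factor" %in% names(row) && !is.na(row$k_factor)) {
    row$k_factor
  }
  rebreathing_session(
    subject_id = row$subject_id, group = row$group,
    pressure = if ("pressure_mmhg" %in% names(row)) row$pressure_mmhg,
    temperature = if ("temperature_c" %in% names(row)) row$temperature_c,
    k_factor = k,
    co_administered = row$co_administered_ml, co_lost = co_lost,
    co_residual = if ("co_residual_ml" %in% names(row)) row$co_residual_ml,
    cohb_baseline = row$cohb_pre, cohb_series = vals[!is.na(vals)]
  )
}

panel_from_row <- function(row) {
  has <- function(col) col %in% names(row) && !is.na(row[[col]])
  if (!has("hct_pct") || !(has("mchc_g_dl") || has("hb_g_dl"))) {
    return(NULL)
  }
  hematology_panel(
    hb_conc = if (has("hb_g_dl")) row$hb_g_dl,
    hct = row$hct_pct,
    mchc = if (has("mchc_g_dl")) row$mchc_g_dl
  )
}
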