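#' Construct a rebreathing session record
#'
#' Bundles the environmental conditions, CO dose accounting and capillary
#' COHb time series of one oCORM exam. Either a precomputed pressure and
#' temperature correction factor `k_factor` (as printed on session report
#' sheets) or the raw `pressure` and `temperature` must be supplied.
#'
#' @param subject_id Identifier for the subject.
#' @param group Group label, `"CONT"` (normal ejection fraction) or
#'   `"EFsev"` (ejection fraction below 30 percent).
#' @param co_administered CO volume administered into the spirometer
#'   circuit, ml.
#' @param co_lost CO lost to the system, lung and exhalation up to blood
#'   sampling, ml. Supply either the total or a numeric vector of itemized
#'   components (they are summed).
#' @param cohb_baseline Pre-rebreathing carboxyhemoglobin, percent of total
#'   hemoglobin.
#' @param cohb_series Post-rebreathing COHb values: either a named numeric
#'   vector (names are sampling minutes) or a two-column data frame with
#'   columns `time_min` and `cohb_percent`. Times must come from the
#'   sampling grid 3, 6, 8, 10, 12, 15 min.
#' @param pressure Barometric pressure, mmHg (required unless `k_factor`
#'   is given).
#' @param temperature Ambient temperature, degrees Celsius.
#' @param k_factor Optional precomputed pressure/temperature correction
#'   factor; when supplied it is used verbatim and the formula is bypassed.
#' @param co_residual Optional CO remaining in the spirometer circuit at the
#'   end of the 2-min rebreathing period, ml; enables the CO uptake
#'   fraction, a proxy for pulmonary CO diffusion.
#'
#' @return An object of class `rebreathing_session`.
#' @export
#' @examples
#' rebreathing_session(
#'   subject_id = "S1", group = "EFsev",
#'   co_administered = 32.3, co_lost = 0, k_factor = 0.934,
#'   cohb_baseline = 1.35, cohb_series = c(`6` = 6.40, `8` = 6.40)
#' )
rebreathing_session <- function(subject_id, group = c("CONT", "EFsev"),
                                co_administered, co_lost,
                                cohb_baseline, cohb_series,
                                pressure = NULL, temperature = NULL,
                                k_factor = NULL, co_residual = NULL) {
  group <- match.arg(group)
  co_lost <- sum(co_lost)
  if (!is.numeric(co_administered) || co_administered <= 0) {
    stop_ocorm("`co_administered` must be a positive CO volume (ml).",
               "ocorm_invalid_input")
  }
  if (co_lost < 0 || co_lost >= co_administered) {
    stop_ocorm("`co_lost` must satisfy 0 <= co_lost < co_administered.",
               "ocorm_invalid_input")
  }
  if (is.null(k_factor)) {
    if (is.null(pressure) || is.null(temperature) ||
        is.na(pressure) || is.na(temperature)) {
      stop_ocorm(
        "Supply either `k_factor` or both `pressure` and `temperature`.",
        "ocorm_invalid_input")
    }
    if (pressure <= 0) {
      stop_ocorm("`pressure` must be positive (mmHg).", "ocorm_invalid_input")
    }
    if (temperature < -10 || temperature > 45) {
      stop_ocorm("`temperature` must lie within [-10, 45] degrees C.",
                 "ocorm_invalid_input")
    }
  } else if (!is.numeric(k_factor) || k_factor <= 0) {
    stop_ocorm("`k_factor` must be a positive number.", "ocorm_invalid_input")
  }

  series <- as_cohb_series(cohb_series)
  vals <- c(cohb_baseline, series$cohb_percent)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 100)) {
    stop_ocorm("COHb values must lie within [0, 100] percent.",
               "ocorm_invalid_input")
  }
  flags <- character(0)
  if (any(series$cohb_percent < cohb_baseline)) {
    flags <- "cohb_below_baseline"
  }
  if (!is.null(co_residual) && !is.na(co_residual)) {
    if (co_residual < 0 || co_residual > co_administered) {
      stop_ocorm("`co_residual` must lie within [0, co_administered].",
                 "ocorm_invalid_input")
    }
  }

  structure(
    list(
      subject_id = as.character(subject_id), group = group,
      pressure = pressure, temperature = temperature, k_factor = k_factor,
      co_administered = co_administered, co_lost = co_lost,
      co_residual = co_residual,
      cohb_baseline = cohb_baseline, cohb_series = series,
      flags = flags
    ),
    class = "rebreathing_session"
  )
}

# Coerce a named vector or data frame to the canonical series data frame
# with strictly increasing, duplicate-free times from the sampling grid.
as_cohb_series <- function(x) {
  if (is.data.frame(x)) {
    ser <- data.frame(time_min = as.numeric(x$time_min),
                      cohb_percent = as.numeric(x$cohb_percent))
  } else if (is.numeric(x) && !is.null(names(x))) {
    ser <- data.frame(time_min = as.numeric(names(x)),
                      cohb_percent = as.numeric(unname(x)))
  } else {
    stop_ocorm(paste(
      "`cohb_series` must be a named numeric vector or a data frame",
      "with columns time_min and cohb_percent."), "ocorm_invalid_input")
  }
  ser <- ser[!is.na(ser$cohb_percent), , drop = FALSE]
  if (nrow(ser) == 0) {
    stop_ocorm("`cohb_series` contains no COHb values.", "ocorm_invalid_input")
  }
  if (!all(ser$time_min %in% COHB_TIMES)) {
    stop_ocorm(sprintf("Sampling times must come from {%s} min.",
                       paste(COHB_TIMES, collapse = ", ")),
               "ocorm_invalid_input")
  }
  if (anyDuplicated(ser$time_min)) {
    stop_ocorm("Duplicate sampling times in `cohb_series`.",
               "ocorm_invalid_input")
  }
  ser[order(ser$time_min), , drop = FALSE]
}

#' @export
print.rebreathing_session <- function(x, ...) {
  cat(sprintf("<rebreathing_session> subject %s (%s)\n", x$subject_id, x$group))
  cat(sprintf("  CO administered %.1f ml, lost %.1f ml\n",
              x$co_administered, x$co_lost))
  k <- x$k_factor
  if (is.null(k)) {
    cat(sprintf("  pressure %.0f mmHg, temperature %.1f C\n",
                x$pressure, x$temperature))
  } else {
    cat(sprintf("  K = %.3f (supplied)\n", k))
  }
  cat(sprintf("  COHb baseline %.2f%%; samples at %s min\n", x$cohb_baseline,
              paste(x$cohb_series$time_min, collapse = ", ")))
  invisible(x)
}

#' Construct a hematology panel
#'
#' Hemoglobin concentration, hematocrit and mean corpuscular hemoglobin
#' concentration of one subject, used to derive the intravascular volumes
#' from hemoglobin mass. When `mchc` is omitted it is derived as
#' `hb_conc / (hct / 100)`.
#'
#' @param hb_conc Hemoglobin concentration, g/dL.
#' @param hct Venous or capillary hematocrit, percent.
#' @param mchc Mean corpuscular hemoglobin concentration, g/dL (of red
#'   cells); derived from `hb_conc` and `hct` when missing.
#'
#' @return An object of class `hematology_panel`.
#' @export
#' @examples
#' hematology_panel(hb_conc = 15.2, hct = 41.9)
hematology_panel <- function(hb_conc = NULL, hct, mchc = NULL) {
  if (is.null(hct) || is.na(hct) || hct <= 0 || hct >= 100) {
    stop_ocorm("`hct` must lie strictly within (0, 100) percent.",
               "ocorm_invalid_input")
  }
  if (!is.null(hb_conc) && !is.na(hb_conc) && (hb_conc <= 0 || hb_conc >= 25)) {
    stop_ocorm("`hb_conc` must lie within (0, 25) g/dL.", "ocorm_invalid_input")
  }
  if (is.null(mchc) || is.na(mchc)) {
    if (is.null(hb_conc) || is.na(hb_conc)) {
      stop_ocorm("Supply `mchc` or both `hb_conc` and `hct`.",
                 "ocorm_invalid_input")
    }
    mchc <- hb_conc / (hct / 100)
  }
  if (mchc < 25 || mchc > 40) {
    stop_ocorm("`mchc` must lie within [25, 40] g/dL.", "ocorm_invalid_input")
  }
  if (!is.null(hb_conc) && !is.na(hb_conc)) {
    implied <- hb_conc / (hct / 100)
    if (abs(mchc - implied) / implied > 0.15) {
      stop_ocorm(
        "`mchc` is inconsistent with hb_conc/(hct/100) by more than 15%.",
        "ocorm_invalid_input")
    }
  }
  structure(list(hb_conc = hb_conc, hct = hct, mchc = mchc),
            class = "hematology_panel")
}

#' @export
print.hematology_panel <- function(x, ...) {
  cat(sprintf("<hematology_panel> Hb %s g/dL, Hct %.1f%%, MCHC %.1f g/dL\n",
              if (is.null(x$hb_conc)) "NA" else sprintf("%.1f", x$hb_conc),
              x$hct, x$mchc))
  invisible(x)
}
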