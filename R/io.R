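#' Read a wide session table
#'
#' One row per rebreathing exam. Expected columns: `subject_id`, `group`,
#' `pressure_mmhg`, `temperature_c`, `co_administered_ml`, `co_lost_ml`
#' (or itemized `co_residual_ml` + `co_exhaled_ml` + `co_myoglobin_ml`),
#' optional `k_factor` (used verbatim when present), `cohb_pre`, `cohb_3`,
#' `cohb_6`, `cohb_8`, `cohb_10`, `cohb_12`, `cohb_15` (blank = missing),
#' `hb_g_dl`, `hct_pct`, `mchc_g_dl`, `body_mass_kg`. UTF-8, comma
#' separated, point decimal.
#'
#' @param path Path to the CSV file.
#' @return A tibble.
#' @export
read_sessions <- function(path) {
  if (!file.exists(path)) {
    stop_ocorm(sprintf("Session file not found: %s", path),
               "ocorm_invalid_input")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) {
    stop_ocorm(sprintf("Session file is empty: %s", path),
               "ocorm_invalid_input")
  }
  required <- c("subject_id", "group", "co_administered_ml", "cohb_pre")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_ocorm(sprintf("Session file lacks required column(s): %s",
                       paste(missing_cols, collapse = ", ")),
               "ocorm_invalid_input")
  }
  df
}

#' Write hemoglobin-mass results to CSV
#'
#' @param results Result tibble from [analyze_sessions()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_hbmass_results <- function(results, path) {
  readr::write_csv(results, path)
  invisible(path)
}

#' Convert a wide session table to long kinetics format
#'
#' Extracts the post-rebreathing COHb series into rows
#' `(subject_id, group, time_min, cohb_pct)`. The pre-rebreathing baseline
#' is not part of the kinetics series. Sessions flagged as leakage failures
#' (column `leakage_failure`, if present) are dropped.
#'
#' @param sessions Wide session tibble.
#' @return Long tibble with columns `subject_id`, `group`, `time_min`,
#'   `cohb_pct`.
#' @export
sessions_to_long <- function(sessions) {
  if ("leakage_failure" %in% names(sessions)) {
    sessions <- dplyr::filter(sessions, !.data$leakage_failure)
  }
  cols <- paste0("cohb_", COHB_TIMES)
  cols <- cols[cols %in% names(sessions)]
  sessions |>
    dplyr::select("subject_id", "group", dplyr::all_of(cols)) |>
    tidyr::pivot_longer(dplyr::all_of(cols), names_to = "time_min",
                        values_to = "cohb_pct",
                        names_prefix = "cohb_") |>
    dplyr::mutate(time_min = as.numeric(.data$time_min)) |>
    dplyr::arrange(.data$subject_id, .data$time_min)
}

#' Read / write a long-format kinetics table
#'
#' Long format: one row per subject and sampling time with columns
#' `subject_id`, `group`, `time_min`, `cohb_pct` (or `normalized_cohb`
#' after [normalize_cohb()]).
#'
#' @param path CSV path.
#' @return A tibble (`read_kinetics_long`) or `path` invisibly.
#' @export
read_kinetics_long <- function(path) {
  if (!file.exists(path)) {
    stop_ocorm(sprintf("Kinetics file not found: %s", path),
               "ocorm_invalid_input")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("subject_id", "group", "time_min")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_ocorm(sprintf("Kinetics file lacks required column(s): %s",
                       paste(missing_cols, collapse = ", ")),
               "ocorm_invalid_input")
  }
  df
}

#' @rdname read_kinetics_long
#' @param x Long kinetics tibble.
#' @export
write_kinetics_long <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' Worked-example sessions of three subjects
#'
#' Session records of three exemplary subjects spanning low, medium and
#' high hemoglobin mass, with the precomputed correction factor K, the net
#' circulating CO volume (entered as `co_administered_ml` with zero loss)
#' and COHb at baseline, 6 and 8 min. These are the demonstration inputs
#' used throughout the package's tests and for the Monte Carlo error
#' examples.
#'
#' @return Wide session tibble with three rows.
#' @export
#' @examples
#' analyze_sessions(example_sessions())
example_sessions <- function() {
  read_sessions(system.file("extdata", "table2_sessions.csv",
                            package = "ocorm", mustWork = TRUE))
}
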