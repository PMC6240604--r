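#' Normalize COHb time courses to the 15-min value
#'
#' By 15 min after commencement of rebreathing the slow, nearly linear CO
#' washout has been reached in both groups, so each subject's series is
#' expressed as a percentage of their own 15-min value. This removes the
#' between-subject (and between-group) offset in absolute COHb and leaves
#' only the shape of the mixing/washout kinetics, on which the group
#' comparison is defined. Subjects lacking any of the six post-rebreathing
#' timepoints are excluded listwise; the exclusions and their reasons are
#' attached as the `"excluded"` attribute (see [kinetics_exclusions()]).
#'
#' @param long Long kinetics tibble with columns `subject_id`, `group`,
#'   `time_min` and `cohb_pct` (or already-normalized `normalized_cohb`,
#'   in which case normalization is idempotent).
#' @param required_times Sampling grid every subject must provide;
#'   default `c(3, 6, 8, 10, 12, 15)`.
#' @param reference_time Normalization reference; default 15 min.
#'
#' @return Tibble `subject_id`, `group`, `time_min`, `normalized_cohb`
#'   (percent of the reference value; exactly 100 at the reference time),
#'   with attribute `"excluded"`.
#' @export
normalize_cohb <- function(long, required_times = COHB_TIMES,
                           reference_time = 15) {
  value_col <- if ("cohb_pct" %in% names(long)) {
    "cohb_pct"
  } else if ("normalized_cohb" %in% names(long)) {
    "normalized_cohb"
  } else {
    stop_ocorm("`long` must contain a `cohb_pct` or `normalized_cohb` column.",
               "ocorm_invalid_input")
  }
  if (!reference_time %in% required_times) {
    stop_ocorm("`reference_time` must be one of `required_times`.",
               "ocorm_invalid_input")
  }

  out <- list()
  excluded <- list()
  for (sid in unique(long$subject_id)) {
    sub <- long[long$subject_id == sid, ]
    sub <- sub[!is.na(sub[[value_col]]), ]
    missing_t <- setdiff(required_times, sub$time_min)
    if (length(missing_t) > 0) {
      excluded[[length(excluded) + 1]] <- tibble::tibble(
        subject_id = sid,
        reason = sprintf("missing COHb at %s min",
                         paste(missing_t, collapse = ", ")))
      next
    }
    sub <- sub[sub$time_min %in% required_times, ]
    ref <- sub[[value_col]][sub$time_min == reference_time]
    if (!is.finite(ref) || ref <= 0) {
      stop_ocorm(
        sprintf("Subject %s: missing or non-positive %g-min reference value.",
                sid, reference_time),
        "ocorm_missing_data")
    }
    out[[length(out) + 1]] <- tibble::tibble(
      subject_id = sid, group = sub$group[1],
      time_min = sub$time_min,
      normalized_cohb = 100 * sub[[value_col]] / ref)
  }
  if (length(out) == 0) {
    stop_ocorm("No subject has a complete post-rebreathing series.",
               "ocorm_missing_data")
  }
  res <- dplyr::arrange(dplyr::bind_rows(out), .data$subject_id,
                        .data$time_min)
  attr(res, "excluded") <- dplyr::bind_rows(excluded)
  if (length(excluded) > 0) {
    message(sprintf("%d subject(s) excluded from kinetics (incomplete series).",
                    length(excluded)))
  }
  res
}

#' Subjects excluded during normalization
#'
#' @param x Result of [normalize_cohb()].
#' @return Tibble with columns `subject_id` and `reason` (zero rows when
#'   nothing was excluded).
#' @export
kinetics_exclusions <- function(x) {
  attr(x, "excluded") %||% tibble::tibble(subject_id = character(),
                                          reason = character())
}

# Common model data preparation: drop the normalization reference (it is
# identically 100 and carries no information) and set factor codings.
kinetics_model_data <- function(normalized, reference_time = 15) {
  d <- normalized[normalized$time_min != reference_time, ]
  d$group <- factor(d$group, levels = c("CONT", "EFsev"))
  if (any(is.na(d$group))) {
    stop_ocorm("`group` must be CONT or EFsev.", "ocorm_invalid_input")
  }
  if (nlevels(droplevels(d$group)) < 2) {
    stop_ocorm("Both groups are required to fit the kinetics model.",
               "ocorm_model_fit")
  }
  n_per <- table(d$group[!duplicated(d$subject_id)])
  if (any(n_per < 2)) {
    stop_ocorm("At least 2 subjects per group are required.",
               "ocorm_model_fit")
  }
  d$time_f <- factor(d$time_min)
  d
}

#' Mixed model for normalized COHb kinetics
#'
#' Fits a linear mixed model to the normalized COHb values with orthogonal
#' polynomial trends in time (degrees 1 to `max_degree`), a group main
#' effect, their interactions, and a random intercept per subject:
#' `normalized_cohb ~ poly(time, k) * group + (1 | subject)`.
#' The time-by-group interaction coefficients test whether the shape of
#' the COHb kinetics differs between the groups; with delayed vascular
#' mixing the EFsev curve starts higher and converges onto the control
#' curve. The 15-min normalization reference (identically 100) is excluded
#' from the fit. Per-timepoint group contrasts come from a companion
#' cell-means model, see [group_contrasts()].
#'
#' @param normalized Result of [normalize_cohb()] (or a long tibble with a
#'   `normalized_cohb` column).
#' @param max_degree Highest polynomial degree of the time trend; default 3.
#' @param reference_time Normalization reference excluded from the fit.
#'
#' @return An object of class `kinetics_fit`: list with the fitted
#'   `lmerMod` (`model`), a tibble `interactions` (one row per polynomial
#'   degree: estimate, SE, t, Satterthwaite df, p), a tibble `contrasts`
#'   (per-timepoint group effects from [group_contrasts()]), and
#'   `n_per_group`.
#' @export
fit_time_group_model <- function(normalized, max_degree = 3,
                                 reference_time = 15) {
  d <- kinetics_model_data(normalized, reference_time)
  n_times <- length(unique(d$time_min))
  if (max_degree >= n_times) {
    stop_ocorm("`max_degree` must be smaller than the number of timepoints.",
               "ocorm_model_fit")
  }
  P <- poly(d$time_min, degree = max_degree)
  colnames(P) <- paste0("ptime", seq_len(max_degree))
  d <- cbind(d, as.data.frame(P))
  terms <- paste0("ptime", seq_len(max_degree))
  fml <- as.formula(paste(
    "normalized_cohb ~ (", paste(terms, collapse = " + "),
    ") * group + (1 | subject_id)"))
  fit <- lmerTest::lmer(fml, data = d)

  cf <- coef(summary(fit))
  inter_rows <- paste0(terms, ":groupEFsev")
  interactions <- tibble::tibble(
    polynomial_degree = seq_len(max_degree),
    estimate = cf[inter_rows, "Estimate"],
    std_error = cf[inter_rows, "Std. Error"],
    statistic = cf[inter_rows, "t value"],
    df = cf[inter_rows, "df"],
    p_value = cf[inter_rows, "Pr(>|t|)"]
  )

  contrasts <- group_contrasts(normalized,
                               times = sort(unique(d$time_min)),
                               reference_time = reference_time)
  n_per_group <- table(d$group[!duplicated(d$subject_id)])
  structure(
    list(model = fit, interactions = interactions, contrasts = contrasts,
         n_per_group = n_per_group,
         excluded = kinetics_exclusions(normalized)),
    class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("<kinetics_fit> n = %s\n",
              paste(sprintf("%s %d", names(x$n_per_group), x$n_per_group),
                    collapse = ", ")))
  cat("Time x group interaction (orthogonal polynomial trends):\n")
  print(as.data.frame(x$interactions), digits = 3, row.names = FALSE)
  cat("Per-timepoint group contrasts (EFsev - CONT, normalized points):\n")
  print(as.data.frame(x$contrasts), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Per-timepoint group contrasts of normalized COHb
#'
#' Model-based EFsev minus CONT differences of the normalized COHb values
#' at the requested sampling times, with standard errors and two-sided
#' p-values from the model's t statistics (Satterthwaite degrees of
#' freedom). The underlying model is a cell-means mixed model,
#' `normalized_cohb ~ time * group + (1 | subject)` with time as a factor,
#' fitted to all non-reference timepoints.
#'
#' @inheritParams fit_time_group_model
#' @param times Sampling minutes at which to report contrasts; default all
#'   non-reference times present in the data.
#' @param alpha Significance level for the reported flag; default 0.05.
#'
#' @return Tibble with columns `time_min`, `estimate` (normalized
#'   percentage points), `std_error`, `df`, `statistic`, `p_value`,
#'   `significant`, `n_cont`, `n_efsev`.
#' @export
group_contrasts <- function(normalized, times = NULL, reference_time = 15,
                            alpha = 0.05) {
  d <- kinetics_model_data(normalized, reference_time)
  avail <- sort(unique(d$time_min))
  times <- times %||% avail
  missing_t <- setdiff(times, avail)
  if (length(missing_t) > 0) {
    stop_ocorm(sprintf("No data at requested time(s): %s min.",
                       paste(missing_t, collapse = ", ")),
               "ocorm_missing_data")
  }
  fit <- lmerTest::lmer(
    normalized_cohb ~ time_f * group + (1 | subject_id), data = d)
  emm <- emmeans::emmeans(fit, ~ group | time_f, lmer.df = "satterthwaite")
  ctr <- summary(emmeans::contrast(emm, method = "revpairwise"),
                 infer = c(FALSE, TRUE))
  n_per <- table(d$group[!duplicated(d$subject_id)])
  out <- tibble::tibble(
    time_min = as.numeric(as.character(ctr$time_f)),
    estimate = ctr$estimate,
    std_error = ctr$SE,
    df = ctr$df,
    statistic = ctr$t.ratio,
    p_value = ctr$p.value,
    significant = ctr$p.value < alpha,
    n_cont = as.integer(n_per[["CONT"]]),
    n_efsev = as.integer(n_per[["EFsev"]])
  )
  out[out$time_min %in% times, ]
}

#' Plot group mean normalized COHb curves
#'
#' Mean and standard error of the normalized COHb values per group over
#' the sampling grid.
#'
#' @param normalized Result of [normalize_cohb()].
#' @return A ggplot object.
#' @export
plot_kinetics <- function(normalized) {
  summ <- normalized |>
    dplyr::group_by(.data$group, .data$time_min) |>
    dplyr::summarise(
      mean = mean(.data$normalized_cohb),
      se = sd(.data$normalized_cohb) / sqrt(dplyr::n()),
      .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$time_min, .data$mean,
                                     colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      width = 0.3) +
    ggplot2::labs(
      x = "Time after commencement of rebreathing (min)",
      y = "COHb, % of 15-min value",
      colour = "Group") +
    ggplot2::theme_minimal()
}
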