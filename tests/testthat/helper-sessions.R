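# Shared fixtures built in code.

# Quick session constructor with sensible defaults.
make_session <- function(subject_id = "T1", group = "CONT",
                         co_administered = 40, co_lost = 3,
                         cohb_baseline = 1.0,
                         cohb_series = c(`3` = 6.0, `6` = 5.6, `8` = 5.5,
                                         `10` = 5.45, `12` = 5.4,
                                         `15` = 5.35),
                         k_factor = 0.93, ...) {
  rebreathing_session(
    subject_id = subject_id, group = group,
    co_administered = co_administered, co_lost = co_lost,
    cohb_baseline = cohb_baseline, cohb_series = cohb_series,
    k_factor = k_factor, ...)
}

# The three worked-example subjects as plain argument lists
# (baseline, 6-min, 8-min COHb, circulating CO, K, printed hemoglobin mass).
example_subject_inputs <- function() {
  list(
    S1 = list(pre = 1.35, c6 = 6.40, c8 = 6.40, mco = 32.3, k = 0.934,
              hbmass = 429),
    S2 = list(pre = 0.90, c6 = 5.30, c8 = 5.10, mco = 42.5, k = 0.923,
              hbmass = 655),
    S3 = list(pre = 0.85, c6 = 5.40, c8 = 5.30, mco = 82.9, k = 0.931,
              hbmass = 1234))
}

# Small noiseless cohort configuration for fast exact round trips.
noiseless_config <- function(n_cont = 10, n_efsev = 10, ...) {
  cohort_config(n_cont = n_cont, n_efsev = n_efsev,
                noise_sd = 0, resolution = 0, ...)
}

zero_offset <- c(`3` = 0, `6` = 0, `8` = 0, `10` = 0, `12` = 0, `15` = 0)
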