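# shared fixtures and independent oracles, built in code at test time

# brute-force double-loop autocovariance: the independent oracle for the
# pairwise-normalized estimator
brute_acov <- function(r, idx, lag) {
  tot <- 0
  np <- 0L
  for (i in seq_along(r)) {
    for (j in seq_along(r)) {
      if (idx[j] - idx[i] == lag) {
        tot <- tot + r[i] * r[j]
        np <- np + 1L
      }
    }
  }
  if (lag == 0L) tot / length(r) else if (np > 0L) tot / np else NA_real_
}

# exact two-sided Fisher p for a 2x2 table by hypergeometric enumeration
brute_fisher_2x2 <- function(tab) {
  m <- sum(tab[1, ])  # row 1 total
  n <- sum(tab[2, ])  # row 2 total
  k <- sum(tab[, 1])  # column 1 total
  p_obs <- dhyper(tab[1, 1], m, n, k)
  xs <- max(0, k - n):min(k, m)
  ps <- dhyper(xs, m, n, k)
  sum(ps[ps <= p_obs * (1 + 1e-7)])
}

# deterministic hand-built externally-paced session from tap times
make_ext_session <- function(taps, n_stim = NULL, target = 1500,
                             id = "p1", group = "g") {
  n_stim <- n_stim %||% length(taps)
  tap_session(id, group, "externally_paced",
              stimulus_onsets_ms = (seq_len(n_stim) - 1) * target,
              tap_times_ms = taps, target_interval_ms = target)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small synthetic fits + cohort pair for the stats module; metrics are
# drawn directly so the tests isolate the inference layer from the fitter
make_fits_cohort <- function(n1 = 30, n2 = 20, seed = 1,
                             iri_shift2 = 0, drift_sd = 100,
                             groups = c("control", "bvFTD")) {
  withr::with_seed(seed, {
    n <- n1 + n2
    cohort <- as_cohort_table(data.frame(
      participant_id = sprintf("P%03d", seq_len(n)),
      group = rep(groups, c(n1, n2)),
      age = round(rnorm(n, 63, 8), 1),
      gender = sample(c("M", "F"), n, TRUE),
      stroop_interference_s = round(rnorm(n, 60, 15), 1),
      digit_span_backwards = sample(3:11, n, TRUE),
      stringsAsFactors = FALSE))
    G0 <- rnorm(n, 5000, 600)
    G1 <- rnorm(n, -900, 150)
    fits <- data.frame(
      participant_id = cohort$participant_id, group = cohort$group,
      condition = "self_paced", estimator = "acf",
      G0 = G0, G1 = G1, rho1 = G1 / G0,
      clock_var = G0 + 2 * G1, motor_var = -G1, total_var = G0,
      mean_iri = 1500 + ifelse(cohort$group == groups[2], iri_shift2, 0) +
        rnorm(n, 0, 80),
      drift_ms = rnorm(n, 0, drift_sd),
      n_used = 42L, n_excluded = 2L, stringsAsFactors = FALSE)
    fits$abs_drift_ms <- abs(fits$drift_ms)
    list(fits = fits, cohort = cohort)
  })
}
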