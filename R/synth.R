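# synthetic tapping sessions under the two-process timing model -----------

#' Generative parameters for a simulated tapping session
#'
#' The generative model is the Wing-Kristofferson two-process account of
#' repetitive timed movement: a central timekeeper emits triggers separated by
#' independent clock intervals `C_j` (mean equal to the target interval plus an
#' optional polynomial drift in stimulus number), and each response lags its
#' trigger by an independent motor delay `D_j`.  The j-th inter-response
#' interval is then `I_j = C_j - D_{j-1} + D_j`.  Both processes are Gaussian
#' here; the model itself only requires independence, but Gaussian noise is the
#' conventional choice and makes the residual-exclusion rate analytic.
#'
#' @param target_interval_ms Target interval (ms). Default 1500 (0.67 Hz).
#' @param n_taps Number of analysed taps (externally paced: also the number of
#'   stimuli; self paced: continuation taps after the synchronization phase).
#' @param n_practice Number of pacing stimuli in the self-paced
#'   synchronization phase. Default 6.
#' @param clock_sd_ms Standard deviation of the clock intervals (ms).
#' @param motor_sd_ms Standard deviation of the motor delays (ms).
#' @param drift_coeffs_ms Polynomial drift added to the mean clock interval:
#'   up to three coefficients `(b1, b2, b3)` applied as
#'   `b1*(j-1) + b2*(j-1)^2 + b3*(j-1)^3` for stimulus number `j` (so the first
#'   analysed interval is undrifted and a linear drift totalling `X` ms over
#'   `n` stimuli corresponds to `b1 = X/(n-1)`).
#' @param mean_shift_ms Constant offset of the participant's mean produced
#'   interval from the target (ms); the stimulus train is unaffected.
#'   Self-paced tapping in patient groups is typically faster than target
#'   (negative shift).
#' @param p_miss Probability that a produced tap is not recorded.
#' @param p_double Probability that a spurious extra tap is inserted inside an
#'   inter-response interval.
#' @param seed Optional integer seed making the session reproducible.
#'
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(target_interval_ms = 1500, n_taps = 50, n_practice = 6,
                       clock_sd_ms = 50, motor_sd_ms = 20,
                       drift_coeffs_ms = c(0, 0, 0), mean_shift_ms = 0,
                       p_miss = 0, p_double = 0, seed = NULL) {
  stopifnot(is_scalar_num(target_interval_ms), target_interval_ms > 0,
            is_count(n_taps), is_count(n_practice, min = 1L),
            is_scalar_num(clock_sd_ms), clock_sd_ms >= 0,
            is_scalar_num(motor_sd_ms), motor_sd_ms >= 0)
  if (n_taps < 10) wk_stop("wktap_invalid_params", "n_taps must be >= 10")
  drift_coeffs_ms <- as.numeric(drift_coeffs_ms)
  if (length(drift_coeffs_ms) > 3L || anyNA(drift_coeffs_ms))
    wk_stop("wktap_invalid_params", "drift_coeffs_ms: up to cubic, no NAs")
  drift_coeffs_ms <- c(drift_coeffs_ms, rep(0, 3L - length(drift_coeffs_ms)))
  for (p in c(p_miss, p_double))
    if (!is_scalar_num(p) || p < 0 || p >= 1)
      wk_stop("wktap_invalid_params", "p_miss and p_double must lie in [0, 1)")
  stopifnot(is_scalar_num(mean_shift_ms))
  structure(list(target_interval_ms = target_interval_ms, n_taps = n_taps,
                 n_practice = n_practice, clock_sd_ms = clock_sd_ms,
                 motor_sd_ms = motor_sd_ms, drift_coeffs_ms = drift_coeffs_ms,
                 mean_shift_ms = mean_shift_ms,
                 p_miss = p_miss, p_double = p_double, seed = seed),
            class = "sim_params")
}

drift_mean <- function(params, j) {
  b <- params$drift_coeffs_ms
  params$target_interval_ms + params$mean_shift_ms +
    b[1] * (j - 1) + b[2] * (j - 1)^2 + b[3] * (j - 1)^3
}

#' Generate the stimulus train for a condition
#'
#' Externally paced sessions present `n_taps` stimuli at exactly the target
#' interval; self-paced sessions present only the `n_practice` pacing stimuli
#' of the synchronization phase.
#'
#' @param condition `"externally_paced"` or `"self_paced"`.
#' @param params A [sim_params()] object.
#' @param start_ms Time of the first onset (ms).
#' @return Numeric vector of onset times (ms).
#' @export
generate_stimulus_train <- function(condition, params = sim_params(),
                                    start_ms = 0) {
  condition <- match.arg(condition, CONDITIONS)
  n <- if (condition == "externally_paced") params$n_taps else params$n_practice
  start_ms + (seq_len(n) - 1) * params$target_interval_ms
}

#' Theoretical autocovariance of inter-response intervals
#'
#' Under the two-process model (drift excluded) the autocovariance of the
#' inter-response intervals is `G(0) = sigma_C^2 + 2 sigma_D^2`,
#' `G(1) = -sigma_D^2`, and zero at all lags beyond 1.
#'
#' @param params A [sim_params()] object.
#' @param lag Non-negative lag (vectorised).
#' @return Autocovariance in ms^2.
#' @export
theoretical_acf <- function(params, lag) {
  stopifnot(all(lag >= 0), all(lag == round(lag)))
  sC2 <- params$clock_sd_ms^2
  sD2 <- params$motor_sd_ms^2
  ifelse(lag == 0, sC2 + 2 * sD2, ifelse(lag == 1, -sD2, 0))
}

# apply recording artifacts to a realized tap train (first tap always kept so
# the session origin survives); resamples the deletion mask rather than ever
# dropping more than half the taps
apply_artifacts <- function(taps, params) {
  n <- length(taps)
  if (params$p_miss > 0) {
    repeat {
      keep <- c(TRUE, rbinom(n - 1L, 1L, 1 - params$p_miss) == 1L)
      if (sum(keep) >= ceiling(n / 2)) break
    }
    taps <- taps[keep]
  }
  if (params$p_double > 0 && length(taps) >= 2L) {
    gaps <- which(rbinom(length(taps) - 1L, 1L, params$p_double) == 1L)
    if (length(gaps)) {
      # keep inserted taps clear of the neighbours so 0.1 ms rounding can
      # never collapse them onto an existing tap
      width <- taps[gaps + 1L] - taps[gaps] - 0.4
      extra <- taps[gaps] + 0.2 + runif(length(gaps)) * pmax(width, 0)
      taps <- sort(c(taps, extra))
    }
  }
  taps
}

#' Simulate one tapping session
#'
#' Draws clock intervals and motor delays, accumulates tap times by
#' `t_j = t_(j-1) + C_j - D_(j-1) + D_j`, applies recording artifacts last, and
#' rounds all times to 0.1 ms (the storage granularity of the tap-log format).
#' Self-paced sessions contain taps for the whole session, including the
#' synchronization phase; [compute_iri()] separates the phases downstream.
#'
#' @param params A [sim_params()] object.
#' @param condition `"externally_paced"` or `"self_paced"`.
#' @param participant_id,group Labels stored on the session.
#' @return A [tap_session()].
#' @export
#' @examples
#' s <- simulate_wk_series(sim_params(clock_sd_ms = 50, motor_sd_ms = 20, seed = 1),
#'                         "externally_paced")
#' length(s$tap_times_ms)
simulate_wk_series <- function(params, condition,
                               participant_id = "sim", group = "sim") {
  condition <- match.arg(condition, CONDITIONS)
  sim <- function() {
    lead_in <- 4 * params$motor_sd_ms + 10  # keeps all times non-negative
    onsets <- generate_stimulus_train(condition, params, start_ms = lead_in)
    if (condition == "externally_paced") {
      n <- params$n_taps
      D <- rnorm(n, 0, params$motor_sd_ms)
      C <- rnorm(n, drift_mean(params, seq_len(n)), params$clock_sd_ms)
      taps <- onsets[1] + D[1] +
        cumsum(c(0, C[-1] + D[-1] - D[-n]))
    } else {
      # clock process runs through the synchronization phase (undrifted) and
      # continues unpaced; drift indexes the continuation stimulus number
      n_sync <- params$n_practice
      n <- n_sync + params$n_taps
      D <- rnorm(n, 0, params$motor_sd_ms)
      mu <- c(rep(params$target_interval_ms, n_sync - 1L),
              drift_mean(params, seq_len(params$n_taps)))
      C <- rnorm(n - 1L, mu, params$clock_sd_ms)
      taps <- onsets[1] + D[1] + cumsum(c(0, C + D[-1] - D[-n]))
    }
    taps <- round(apply_artifacts(taps, params), 1)
    taps <- taps[c(TRUE, diff(taps) > 0)]  # rounding safety net
    tap_session(participant_id, group, condition,
                stimulus_onsets_ms = round(onsets, 1),
                tap_times_ms = taps,
                target_interval_ms = params$target_interval_ms)
  }
  if (!is.null(params$seed)) withr::with_seed(params$seed, sim()) else sim()
}

# cohort-level simulation -------------------------------------------------

#' Per-group simulation settings for a synthetic cohort
#'
#' Describes one participant group: its size, demographic distributions,
#' cognitive-score distributions, and the distribution of per-participant
#' generative parameters for each condition.  Per-participant clock and motor
#' SDs are drawn from normal distributions truncated below at 1 ms; drift is
#' parameterised by the total modelled change across the task (ms), from which
#' the linear coefficient is derived; `iri_shift_ms` shifts the participant's
#' mean produced interval away from the 1500 ms target (self-paced tapping is
#' typically faster than target).
#'
#' @param label Group label.
#' @param n Number of participants.
#' @param age_mean,age_sd Age distribution (years).
#' @param p_male Probability a participant is male.
#' @param stroop_mean,stroop_sd Stroop interference time distribution (s).
#' @param digit_span_mean,digit_span_sd Digit span backwards distribution.
#' @param externally,self Named lists of condition-level settings with fields
#'   `clock_sd_mean`, `clock_sd_sd`, `motor_sd_mean`, `motor_sd_sd`,
#'   `drift_total_mean`, `drift_total_sd`, `iri_shift_mean`, `iri_shift_sd`,
#'   `p_miss`, `p_double`. Missing fields fall back to quiet defaults.
#' @return A list of class `group_spec`.
#' @export
group_spec <- function(label, n, age_mean = 63, age_sd = 8, p_male = 0.5,
                       stroop_mean = 55, stroop_sd = 13,
                       digit_span_mean = 7, digit_span_sd = 2,
                       externally = list(), self = list()) {
  stopifnot(is.character(label), is_count(n, min = 1L))
  defaults <- list(clock_sd_mean = 60, clock_sd_sd = 10,
                   motor_sd_mean = 40, motor_sd_sd = 10,
                   drift_total_mean = 0, drift_total_sd = 30,
                   iri_shift_mean = 0, iri_shift_sd = 10,
                   p_miss = 0.02, p_double = 0.01)
  structure(list(label = label, n = n, age_mean = age_mean, age_sd = age_sd,
                 p_male = p_male, stroop_mean = stroop_mean, stroop_sd = stroop_sd,
                 digit_span_mean = digit_span_mean, digit_span_sd = digit_span_sd,
                 externally = modifyList(defaults, externally),
                 self = modifyList(defaults, self)),
            class = "group_spec")
}

#' Default synthetic cohort: healthy controls and a bvFTD-like patient group
#'
#' Emulates the study conditions this package targets: a control group with
#' moderate clock variance and small drift, and a behavioural-variant
#' frontotemporal dementia (bvFTD)-like group with substantially larger clock
#' variance and absolute drift on externally-paced tapping, and faster-than-
#' target, more drifting self-paced tapping.  Magnitudes follow the group
#' summaries typical of synchronization-continuation studies in dementia
#' cohorts (clock variance of a few thousand ms^2 in controls versus an order
#' of magnitude more in bvFTD; self-paced mean intervals roughly 150-300 ms
#' faster than the 1500 ms target in patients).
#'
#' @param n_control,n_patient Group sizes.
#' @return A list of `group_spec` objects.
#' @export
default_cohort_spec <- function(n_control = 31, n_patient = 20) {
  list(
    group_spec("control", n_control, age_mean = 62.6, age_sd = 7.2,
               p_male = 14 / 31, stroop_mean = 54.3, stroop_sd = 12.7,
               digit_span_mean = 7.2, digit_span_sd = 2.0,
               externally = list(clock_sd_mean = 58, clock_sd_sd = 15,
                                 motor_sd_mean = 55, motor_sd_sd = 15,
                                 drift_total_mean = 19, drift_total_sd = 32),
               self = list(clock_sd_mean = 65, clock_sd_sd = 15,
                           motor_sd_mean = 10, motor_sd_sd = 5,
                           drift_total_mean = -28, drift_total_sd = 150,
                           iri_shift_mean = -90, iri_shift_sd = 150)),
    group_spec("bvFTD", n_patient, age_mean = 63.6, age_sd = 9.6,
               p_male = 17 / 20, stroop_mean = 93.1, stroop_sd = 41.0,
               digit_span_mean = 5.7, digit_span_sd = 2.3,
               externally = list(clock_sd_mean = 120, clock_sd_sd = 40,
                                 motor_sd_mean = 35, motor_sd_sd = 15,
                                 drift_total_mean = 10, drift_total_sd = 90),
               self = list(clock_sd_mean = 115, clock_sd_sd = 40,
                           motor_sd_mean = 10, motor_sd_sd = 5,
                           drift_total_mean = -129, drift_total_sd = 280,
                           iri_shift_mean = -250, iri_shift_sd = 220)))
}

rtruncnorm_low <- function(n, mean, sd, low) pmax(low, rnorm(n, mean, sd))

draw_participant_params <- function(cspec, n_taps, target) {
  clock_sd <- rtruncnorm_low(1, cspec$clock_sd_mean, cspec$clock_sd_sd, 1)
  motor_sd <- rtruncnorm_low(1, cspec$motor_sd_mean, cspec$motor_sd_sd, 1)
  drift_total <- rnorm(1, cspec$drift_total_mean, cspec$drift_total_sd)
  iri_shift <- rnorm(1, cspec$iri_shift_mean, cspec$iri_shift_sd)
  sim_params(target_interval_ms = target, n_taps = n_taps,
             clock_sd_ms = clock_sd, motor_sd_ms = motor_sd,
             drift_coeffs_ms = c(drift_total / (n_taps - 1), 0, 0),
             mean_shift_ms = iri_shift,
             p_miss = cspec$p_miss, p_double = cspec$p_double)
}

#' Simulate a full cohort of tapping sessions
#'
#' One session per participant per condition, plus a matching cohort table
#' with demographics and cognitive scores.  Fixed seed gives identical output.
#'
#' @param spec List of [group_spec()] objects (see [default_cohort_spec()]).
#' @param seed Integer seed.
#' @param conditions Conditions to simulate per participant.
#' @param n_taps,target_interval_ms Task constants.
#' @return A list with elements `sessions` (list of [tap_session()]) and
#'   `cohort` (a `cohort_table`).
#' @export
simulate_cohort <- function(spec = default_cohort_spec(), seed = 1,
                            conditions = CONDITIONS,
                            n_taps = 50, target_interval_ms = 1500) {
  stopifnot(length(spec) >= 1L)
  conditions <- match.arg(conditions, CONDITIONS, several.ok = TRUE)
  withr::with_seed(seed, {
    sessions <- list()
    rows <- list()
    idx <- 0L
    for (g in spec) {
      for (i in seq_len(g$n)) {
        idx <- idx + 1L
        pid <- sprintf("P%03d", idx)
        rows[[idx]] <- tibble::tibble(
          participant_id = pid, group = g$label,
          age = round(rtruncnorm_low(1, g$age_mean, g$age_sd, 30), 1),
          gender = if (runif(1) < g$p_male) "M" else "F",
          stroop_interference_s = round(rtruncnorm_low(1, g$stroop_mean, g$stroop_sd, 10), 1),
          digit_span_backwards = round(pmin(12, rtruncnorm_low(1, g$digit_span_mean, g$digit_span_sd, 0))))
        for (cond in conditions) {
          cs <- if (cond == "externally_paced") g$externally else g$self
          pp <- draw_participant_params(cs, n_taps, target_interval_ms)
          sessions[[length(sessions) + 1L]] <-
            simulate_wk_series(pp, cond, participant_id = pid, group = g$label)
        }
      }
    }
    list(sessions = sessions,
         cohort = as_cohort_table(do.call(rbind, rows), source = "simulated cohort"))
  })
}
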