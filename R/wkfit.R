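# drift-detrended lag-1 fit and the clock/motor decomposition -------------

#' Lag autocovariance over contributing pairs
#'
#' Sample autocovariance of a (detrended) series observed at integer indices,
#' possibly with gaps.  At lag 0 the sum of squares is divided by the number
#' of observations (bias-uncorrected); at lag `L > 0` the sum of products over
#' all pairs whose indices differ by exactly `L` is divided by the number of
#' such pairs.  Gaps simply contribute no pairs.
#'
#' @param residuals Numeric residuals.
#' @param index Integer observation indices (same length).
#' @param lag Non-negative integer lag.
#' @return Autocovariance (ms^2 when residuals are ms); `NA` if no pairs
#'   contribute.
#' @export
lag_autocovariance <- function(residuals, index, lag) {
  stopifnot(length(residuals) == length(index), is_count(lag))
  if (lag == 0L) {
    if (!length(residuals)) return(NA_real_)
    return(sum(residuals^2) / length(residuals))
  }
  pos <- match(index + lag, index)
  i <- which(!is.na(pos))
  if (!length(i)) return(NA_real_)
  sum(residuals[i] * residuals[pos[i]]) / length(i)
}

trend_degree <- function(condition) if (condition == "externally_paced") 2L else 3L

# evaluate the fitted trend (internal centred/scaled basis, numerically stable)
trend_values <- function(fit, index) {
  z <- (index - fit$x_center) / fit$x_scale
  y <- numeric(length(index))
  for (k in seq_along(fit$coefs)) y <- y + fit$coefs[k] * z^(k - 1L)
  y
}

#' Fit the polynomial drift trend and lag-1 autocovariance
#'
#' Fits a polynomial in stimulus index — quadratic for externally-paced,
#' cubic for self-paced tapping — to the valid inter-response intervals, and
#' estimates the lag-0 and lag-1 autocovariance of the detrended series.
#'
#' Two estimators are available. `"acf"` (default) fits the trend by least
#' squares and takes `G0`, `G1` as sample autocovariances of the residuals
#' over contributing pairs (see [lag_autocovariance()]); this permits lag-1
#' autocorrelations outside `[-0.5, 0]` and hence the negative clock or motor
#' variance estimates real participants produce. `"ar1"` fits the trend
#' jointly with a lag-1 autoregressive error by maximum likelihood (missing
#' intervals handled by the state-space filter); `G0` is the stationary error
#' variance and `G1 = phi * G0`.
#'
#' Stimulus indices are centred (and, for the cubic model, scaled to
#' `[-1, 1]`) before powers are formed; reported raw-basis coefficients and
#' all drift metrics are on the original index scale.
#'
#' @param iri An `iri_series`, normally after [prefilter()].
#' @param condition Condition; defaults to the series' own.
#' @param estimator `"acf"` or `"ar1"`.
#' @param min_valid Minimum number of valid intervals.
#' @return An object of class `wk_fit` with trend, autocovariance, variance
#'   decomposition and drift fields populated.
#' @export
fit_trend_lag1 <- function(iri, condition = NULL,
                           estimator = c("acf", "ar1"), min_valid = 10L) {
  stopifnot(inherits(iri, "iri_series"))
  condition <- match.arg(condition %||% attr(iri, "condition"), CONDITIONS)
  estimator <- match.arg(estimator)
  v <- iri[iri$valid & !is.na(iri$stimulus_index), , drop = FALSE]
  v <- v[order(v$stimulus_index), , drop = FALSE]
  if (nrow(v) < min_valid)
    wk_stop("wktap_too_few_taps", "only %d valid intervals (need >= %d)",
            nrow(v), min_valid)
  x <- as.numeric(v$stimulus_index)
  y <- v$iri_ms
  p <- trend_degree(condition)
  m <- mean(x)
  s <- if (p >= 3L) max(abs(x - m)) else 1
  z <- (x - m) / s
  X <- outer(z, 0:p, `^`)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    wk_stop("wktap_singular_design",
            "singular trend design: %d distinct stimulus indices for degree %d",
            length(unique(x)), p)

  fit <- list(participant_id = attr(iri, "participant_id"),
              group = attr(iri, "group"),
              condition = condition, estimator = estimator,
              x_center = m, x_scale = s, degree = p,
              analysed_index = x, n_used = nrow(v))

  if (estimator == "acf") {
    b <- qr.coef(qrX, y)
    r <- y - X %*% b
    fit$coefs <- as.numeric(b)
    fit$G0 <- lag_autocovariance(as.numeric(r), v$stimulus_index, 0L)
    fit$G1 <- lag_autocovariance(as.numeric(r), v$stimulus_index, 1L)
  } else {
    full <- seq(min(v$stimulus_index), max(v$stimulus_index))
    yy <- rep(NA_real_, length(full))
    yy[match(v$stimulus_index, full)] <- y
    zz <- (full - m) / s
    XX <- outer(zz, 0:p, `^`)[, -1L, drop = FALSE]
    colnames(XX) <- paste0("z", 1:p)
    af <- tryCatch(
      arima(yy, order = c(1L, 0L, 0L), xreg = XX, include.mean = TRUE,
            method = "ML"),
      error = function(e) wk_stop("wktap_fit_error", "AR(1) fit failed: %s",
                                  conditionMessage(e)))
    phi <- unname(coef(af)["ar1"])
    fit$coefs <- unname(coef(af)[c("intercept", paste0("z", 1:p))])
    fit$G0 <- af$sigma2 / (1 - phi^2)
    fit$G1 <- phi * fit$G0
  }

  fit$trend_coeffs <- poly_raw_coefs(fit$coefs, center = m, scale = s)
  fit <- c(fit, decompose_variance(fit$G0, fit$G1))
  fit$excluded <- excluded_table(iri)
  class(fit) <- "wk_fit"
  dm <- drift_metrics(fit)
  fit[names(dm)] <- dm
  fit
}

excluded_table <- function(iri) {
  e <- iri[!iri$valid, c("tap_index", "exclusion_reason")]
  names(e) <- c("tap_index", "reason")
  tibble::as_tibble(e)
}

#' Decompose total variance into clock and motor components
#'
#' Implements the two-process identities `rho1 = G1/G0`,
#' `motor_var = -G1`, `clock_var = G0 + 2 G1`, `total_var = G0`.  Negative
#' component estimates are retained, never clamped: they arise whenever the
#' estimated lag-1 autocorrelation falls outside `[-0.5, 0]` and are part of
#' the reported output.  For `G0 <= 0` the decomposition is undefined and all
#' fields are `NA` with `var_defined = FALSE`.
#'
#' @param G0,G1 Lag-0 and lag-1 autocovariance (ms^2).
#' @return List with `rho1`, `clock_var`, `motor_var`, `total_var`,
#'   `var_defined`.
#' @export
decompose_variance <- function(G0, G1) {
  if (is_scalar_num(G0) && G0 == 0 && (is.na(G1) || G1 == 0)) {
    # degenerate noiseless series: zero variance throughout, rho1 undefined
    return(list(rho1 = NA_real_, clock_var = 0, motor_var = 0,
                total_var = 0, var_defined = TRUE))
  }
  if (!is_scalar_num(G0) || !is_scalar_num(G1) || G0 <= 0) {
    return(list(rho1 = NA_real_, clock_var = NA_real_, motor_var = NA_real_,
                total_var = NA_real_, var_defined = FALSE))
  }
  list(rho1 = G1 / G0, clock_var = G0 + 2 * G1, motor_var = -G1,
       total_var = G0, var_defined = TRUE)
}

#' Modelled mean interval and drift
#'
#' `mean_iri` is the mean of the fitted trend over the analysed stimulus
#' indices; `drift_ms` is the modelled inter-response interval at the final
#' analysed stimulus minus that at the first analysed stimulus (positive:
#' getting slower; negative: getting faster); `abs_drift_ms` is its modulus.
#'
#' @param fit A `wk_fit`.
#' @return List with `mean_iri`, `drift_ms`, `abs_drift_ms`.
#' @export
drift_metrics <- function(fit) {
  stopifnot(inherits(fit, "wk_fit"))
  idx <- fit$analysed_index
  tv <- trend_values(fit, idx)
  drift <- trend_values(fit, max(idx)) - trend_values(fit, min(idx))
  list(mean_iri = mean(tv), drift_ms = drift, abs_drift_ms = abs(drift))
}

#' Exclude intervals far from the fitted trend
#'
#' Marks intervals whose absolute residual exceeds `sd_threshold` times the
#' residual standard deviation as `outlier`, refits the trend, and iterates to
#' a fixed point (at most `max_iter` rounds). The threshold scale
#' `sqrt(G0)` is taken from the initial fit and held fixed across rounds:
#' re-estimating the scale from already-truncated residuals would shrink it
#' every round and cascade the exclusion well past the nominal two-sided
#' normal tail rate.  Iterations therefore only propagate the effect of the
#' refitted trend, and previously flagged intervals are re-admitted if the
#' refitted trend no longer rejects them.
#'
#' @param iri An `iri_series` (after [prefilter()]).
#' @param fit The initial [fit_trend_lag1()] fit.
#' @param sd_threshold Threshold in residual SD units (default 2).
#' @param max_iter Maximum exclusion-refit rounds (default 5).
#' @param min_valid Minimum surviving intervals.
#' @return The series with outlier flags; the final `wk_fit` is attached as
#'   attribute `"fit"` (carrying `iterations`).
#' @export
exclude_outliers <- function(iri, fit, sd_threshold = 2, max_iter = 5L,
                             min_valid = 10L) {
  stopifnot(inherits(iri, "iri_series"), inherits(fit, "wk_fit"))
  scale0 <- sqrt(max(fit$G0, 0))
  if (!is.finite(scale0) || scale0 < 1e-6) {
    # residual scale below timing resolution: nothing to exclude
    fit$iterations <- 0L
    attr(iri, "fit") <- fit
    return(iri)
  }
  candidates <- which((iri$valid | iri$exclusion_reason == "outlier") &
                        !is.na(iri$stimulus_index))
  current <- fit
  out_prev <- integer(0)
  iterations <- 0L
  repeat {
    r <- iri$iri_ms[candidates] - trend_values(current, iri$stimulus_index[candidates])
    out <- candidates[abs(r) > sd_threshold * scale0]
    if (length(candidates) - length(out) < min_valid)
      wk_stop("wktap_too_few_taps",
              "outlier exclusion would leave %d valid intervals (need >= %d)",
              length(candidates) - length(out), min_valid)
    iri$valid[candidates] <- TRUE
    iri$exclusion_reason[candidates] <- "none"
    iri <- reflag(iri, out, "outlier")
    iterations <- iterations + 1L
    if (setequal(out, out_prev) || iterations >= max_iter) break
    out_prev <- out
    current <- fit_trend_lag1(iri, condition = current$condition,
                              estimator = current$estimator,
                              min_valid = min_valid)
  }
  final <- fit_trend_lag1(iri, condition = current$condition,
                          estimator = current$estimator, min_valid = min_valid)
  final$iterations <- iterations
  attr(iri, "fit") <- final
  iri
}

#' Fit the full per-participant pipeline
#'
#' Runs interval extraction, prefiltering, the drift-detrended lag-1 fit,
#' iterated residual-based exclusion, the clock/motor decomposition and drift
#' metrics for one session, logging one line per stage when `verbose` (or
#' `options(wktap.verbose = TRUE)`) is set.
#'
#' @param session A [tap_session()].
#' @param estimator `"acf"` or `"ar1"`.
#' @param outlier_sd Residual-SD threshold for exclusion (default 2).
#' @param max_iter Maximum exclusion-refit rounds (default 5).
#' @param n_remove Override for prefiltered tap count (default 2 externally
#'   paced, 7 self paced).
#' @param min_valid Minimum analysable intervals at every stage.
#' @param verbose Emit structured log lines.
#' @return A `wk_fit`.
#' @export
fit_participant <- function(session, estimator = c("acf", "ar1"),
                            outlier_sd = 2, max_iter = 5L, n_remove = NULL,
                            min_valid = 10L, verbose = NULL) {
  estimator <- match.arg(estimator)
  tag <- function(e) {
    wk_stop("wktap_fit_error", "participant %s (%s): %s",
            session$participant_id, session$condition, conditionMessage(e))
  }
  tryCatch({
    iri <- compute_iri(session)
    wk_log("participant=%s condition=%s stage=compute_iri intervals=%d invalid=%d",
           session$participant_id, session$condition, nrow(iri), sum(!iri$valid),
           verbose = verbose)
    iri <- prefilter(iri, n_remove = n_remove, min_remaining = min_valid)
    wk_log("participant=%s condition=%s stage=prefilter analysable=%d",
           session$participant_id, session$condition, sum(iri$valid),
           verbose = verbose)
    fit0 <- fit_trend_lag1(iri, estimator = estimator, min_valid = min_valid)
    iri <- exclude_outliers(iri, fit0, sd_threshold = outlier_sd,
                            max_iter = max_iter, min_valid = min_valid)
    fit <- attr(iri, "fit")
    wk_log("participant=%s condition=%s stage=exclude_outliers estimator=%s outliers=%d iterations=%d n_used=%d",
           session$participant_id, session$condition, estimator,
           sum(iri$exclusion_reason == "outlier"), fit$iterations, fit$n_used,
           verbose = verbose)
    fit
  }, wktap_error = tag, error = tag)
}

#' Fit many sessions into a metrics table
#'
#' @param sessions List of [tap_session()] objects.
#' @param ... Passed to [fit_participant()].
#' @param on_error `"stop"` or `"skip"` (skipped sessions are logged and
#'   reported in the `skipped` attribute).
#' @return A tibble with one row per fitted session carrying all scalar
#'   `wk_fit` fields.
#' @export
fit_sessions <- function(sessions, ..., on_error = c("stop", "skip")) {
  on_error <- match.arg(on_error)
  rows <- list()
  skipped <- character(0)
  for (s in sessions) {
    f <- if (on_error == "skip") {
      tryCatch(fit_participant(s, ...), error = function(e) {
        wk_log("skipped participant=%s condition=%s: %s",
               s$participant_id, s$condition, conditionMessage(e), verbose = TRUE)
        skipped <<- c(skipped, sprintf("%s/%s", s$participant_id, s$condition))
        NULL
      })
    } else fit_participant(s, ...)
    if (!is.null(f)) rows[[length(rows) + 1L]] <- as_tibble_row_wk(f)
  }
  out <- if (length(rows)) do.call(rbind, rows) else as_tibble_row_wk(NULL)
  attr(out, "skipped") <- skipped
  out
}

as_tibble_row_wk <- function(f) {
  if (is.null(f)) {
    return(tibble::tibble(participant_id = character(), group = character(),
                          condition = character(), estimator = character(),
                          G0 = numeric(), G1 = numeric(), rho1 = numeric(),
                          clock_var = numeric(), motor_var = numeric(),
                          total_var = numeric(), mean_iri = numeric(),
                          drift_ms = numeric(), abs_drift_ms = numeric(),
                          n_used = integer(), n_excluded = integer()))
  }
  tibble::tibble(
    participant_id = f$participant_id %||% NA_character_,
    group = f$group %||% NA_character_,
    condition = f$condition, estimator = f$estimator,
    G0 = f$G0, G1 = f$G1, rho1 = f$rho1,
    clock_var = f$clock_var, motor_var = f$motor_var, total_var = f$total_var,
    mean_iri = f$mean_iri, drift_ms = f$drift_ms, abs_drift_ms = f$abs_drift_ms,
    n_used = f$n_used, n_excluded = nrow(f$excluded))
}

#' @export
print.wk_fit <- function(x, ...) {
  cat(sprintf("<wk_fit> %s / %s (%s estimator)\n",
              x$participant_id %||% "?", x$condition, x$estimator))
  cat(sprintf("  n_used = %d, excluded = %d\n", x$n_used, nrow(x$excluded)))
  cat(sprintf("  G0 = %.1f, G1 = %.1f, rho1 = %s\n", x$G0, x$G1,
              if (is.na(x$rho1)) "undefined" else sprintf("%.3f", x$rho1)))
  cat(sprintf("  clock_var = %.1f, motor_var = %.1f, total_var = %.1f ms^2\n",
              x$clock_var, x$motor_var, x$total_var))
  cat(sprintf("  mean_iri = %.1f ms, drift = %.1f ms (|drift| = %.1f)\n",
              x$mean_iri, x$drift_ms, x$abs_drift_ms))
  invisible(x)
}
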