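# end-to-end pipeline and validation suite --------------------------------

#' Default run configuration
#'
#' Defaults reproduce the analysis settings this package is built around:
#' 2-SD residual exclusion, removal of the first 2 (externally-paced) or 7
#' (self-paced) taps, `acf` estimator, 2000 bootstrap replications.
#'
#' @return Named list of configuration values.
#' @export
default_run_config <- function() {
  list(taps = NULL, cohort = NULL, out_dir = "wktap_out",
       simulate = FALSE, n_control = 31, n_patient = 20,
       estimator = "acf", outlier_sd = 2, max_iter = 5,
       prefilter_externally = 2, prefilter_self = 7,
       reference_group = "control", comparison_groups = NULL,
       n_boot = 2000, seed = 1, verbose = FALSE)
}

#' Read a flat key=value run configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment; numeric and logical
#' values are coerced; unknown keys are rejected.
#'
#' @param path Path to the config file.
#' @return Configuration list merged over [default_run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) wk_format_error("config not found: %s", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- default_run_config()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) wk_format_error("config line not key=value: '%s'", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    if (!key %in% names(cfg))
      wk_format_error("unknown config key '%s'", key)
    cur <- cfg[[key]]
    cfg[[key]] <- if (is.logical(cur)) as.logical(val)
      else if (is.numeric(cur)) as.numeric(val)
      else if (key == "comparison_groups") strsplit(val, "[, ]+")[[1]]
      else val
  }
  cfg
}

write_resolved_config <- function(cfg, path) {
  vals <- vapply(cfg, function(v)
    if (is.null(v)) "" else paste(as.character(v), collapse = ","), "")
  writeLines(c(sprintf("package_version = %s", as.character(packageVersion("wktap"))),
               sprintf("%s = %s", names(vals), vals)), path)
  invisible(path)
}

pipeline_metrics <- function(condition) {
  if (condition == "externally_paced")
    c("clock_var", "motor_var", "mean_iri", "drift_ms", "abs_drift_ms")
  else
    c("total_var", "clock_var", "motor_var", "mean_iri", "drift_ms", "abs_drift_ms")
}

#' Run the full analysis pipeline
#'
#' Optionally simulates a cohort, fits every session (per-session failures are
#' logged and skipped), and compares every comparison group against the
#' reference group on the condition-appropriate metrics, writing `fits.csv`,
#' `comparisons.csv` and the resolved configuration (with the package version)
#' into the output directory.  Identical config and seed give byte-identical
#' outputs.
#'
#' @param config A configuration list (see [default_run_config()]) or the path
#'   to a key=value config file.
#' @return Invisibly, a list with output paths, the fits table, comparisons
#'   and skipped sessions.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- modifyList(default_run_config(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (isTRUE(cfg$simulate)) {
    sim <- simulate_cohort(default_cohort_spec(cfg$n_control, cfg$n_patient),
                           seed = cfg$seed)
    sessions <- sim$sessions
    cohort <- sim$cohort
    write_tap_log(sessions, file.path(cfg$out_dir, "taps.csv"))
    write_cohort(cohort, file.path(cfg$out_dir, "cohort.csv"))
  } else {
    if (is.null(cfg$taps) || is.null(cfg$cohort))
      wk_stop("wktap_invalid_params",
              "config needs 'taps' and 'cohort' paths (or simulate = TRUE)")
    sessions <- read_tap_log(cfg$taps)
    cohort <- read_cohort(cfg$cohort)
  }

  fits <- fit_sessions(sessions, estimator = cfg$estimator,
                       outlier_sd = cfg$outlier_sd, max_iter = cfg$max_iter,
                       verbose = cfg$verbose, on_error = "skip")
  if (nrow(fits) == 0L)
    wk_stop("wktap_fit_error", "no fittable sessions")
  fits_path <- file.path(cfg$out_dir, "fits.csv")
  utils::write.csv(as.data.frame(fits), fits_path, row.names = FALSE)

  groups <- unique(cohort$group)
  ref <- cfg$reference_group
  cmp_groups <- cfg$comparison_groups %||% setdiff(groups, ref)
  comp_rows <- list()
  if (ref %in% groups && length(cmp_groups)) {
    for (cond in intersect(CONDITIONS, unique(fits$condition))) {
      for (cmp in cmp_groups) {
        for (metric in pipeline_metrics(cond)) {
          res <- tryCatch(
            compare_groups(fits, cohort, metric, ref, cmp, condition = cond,
                           adjust = TRUE, n_boot = cfg$n_boot, seed = cfg$seed),
            error = function(e) {
              wk_log("comparison %s/%s/%s failed: %s", cond, cmp, metric,
                     conditionMessage(e), verbose = TRUE)
              NULL
            })
          if (is.null(res)) next
          comp_rows[[length(comp_rows) + 1L]] <- tibble::tibble(
            condition = cond, metric = metric,
            reference = ref, comparison = cmp,
            n_reference = res$n_reference, n_comparison = res$n_comparison,
            unadjusted_diff = res$unadjusted_diff,
            adjusted_diff = res$adjusted_diff,
            ci_low = res$ci_low, ci_high = res$ci_high,
            robust_se = res$robust_se, robust_p = res$robust_p,
            flag = res$flag)
        }
      }
    }
  }
  comparisons <- if (length(comp_rows)) do.call(rbind, comp_rows) else NULL
  comp_path <- file.path(cfg$out_dir, "comparisons.csv")
  if (!is.null(comparisons))
    utils::write.csv(as.data.frame(comparisons), comp_path, row.names = FALSE)
  write_resolved_config(cfg, file.path(cfg$out_dir, "resolved_config.txt"))
  invisible(list(out_dir = cfg$out_dir, fits_path = fits_path,
                 comparisons_path = if (!is.null(comparisons)) comp_path,
                 fits = fits, comparisons = comparisons,
                 skipped = attr(fits, "skipped")))
}

# exact finite-sample expectation of the detrended autocovariance estimators
# under a lag-1 process: E[r r'] = (I - H) Gamma (I - H) with Gamma banded
expected_detrended_acov <- function(index, degree, G0, G1) {
  n <- length(index)
  Gam <- diag(G0, n)
  adj <- which(diff(index) == 1)
  Gam[cbind(adj, adj + 1)] <- G1
  Gam[cbind(adj + 1, adj)] <- G1
  m <- mean(index)
  s <- if (degree >= 3L) max(abs(index - m)) else 1
  X <- outer((index - m) / s, 0:degree, `^`)
  H <- X %*% solve(crossprod(X), t(X))
  S <- (diag(n) - H) %*% Gam %*% (diag(n) - H)
  list(EG0 = sum(diag(S)) / n,
       EG1 = sum(S[cbind(adj, adj + 1)]) / length(adj))
}

#' Run the package's internal validation suite
#'
#' Re-runs the core property checks on freshly simulated data: the two
#' analytic limits of the lag-1 autocorrelation, the stimulus-train constants,
#' the variance-decomposition identity, equivalence of the autocovariance
#' estimator with a brute-force double-loop computation, recovery of injected
#' drift and of the estimator's exact finite-sample expectation, the
#' residual-exclusion rate, and (optionally) BCa coverage.
#'
#' @param seed Integer seed.
#' @param n_recovery Participants in the recovery experiment.
#' @param n_coverage Replications in the coverage experiment (0 skips it).
#' @param n_boot Bootstrap replications for the coverage experiment.
#' @return A tibble with columns `check`, `value`, `target`, `pass`.
#' @export
validate_pipeline <- function(seed = 1, n_recovery = 100, n_coverage = 100,
                              n_boot = 599) {
  checks <- list()
  add <- function(check, value, target, pass)
    checks[[length(checks) + 1L]] <<- tibble::tibble(
      check = check, value = value, target = target, pass = pass)

  # lag-1 autocorrelation limits
  rho_of <- function(clock_sd, motor_sd, sd_seed) {
    s <- simulate_wk_series(sim_params(n_taps = 5003, clock_sd_ms = clock_sd,
                                       motor_sd_ms = motor_sd, seed = sd_seed),
                            "externally_paced")
    fit_trend_lag1(prefilter(compute_iri(s)))$rho1
  }
  r1 <- rho_of(50, 0, seed)
  add("rho1 limit, no motor delay", r1, "0 +/- 0.03", abs(r1) <= 0.03)
  r2 <- rho_of(0, 40, seed + 1)
  add("rho1 limit, no clock variability", r2, "-0.5 +/- 0.03",
      abs(r2 + 0.5) <= 0.03)

  # stimulus-train constants
  tr <- generate_stimulus_train("externally_paced", sim_params())
  ok_train <- length(tr) == 50 && all(diff(tr) == 1500)
  add("stimulus train: 50 onsets at exactly 1500 ms", as.numeric(ok_train),
      "1", ok_train)

  # decomposition identity
  ident <- withr::with_seed(seed, {
    g0 <- runif(1000, 1e-6, 1e5); g1 <- runif(1000, -5e4, 5e4)
    max(vapply(seq_along(g0), function(i) {
      d <- decompose_variance(g0[i], g1[i])
      abs(d$clock_var + 2 * d$motor_var - g0[i])
    }, 0))
  })
  add("identity clock + 2*motor = total (max abs error)", ident,
      "< 1e-9", ident < 1e-9)

  # estimator vs brute-force double loop
  brute <- function(r, idx, lag) {
    tot <- 0; np <- 0L
    for (i in seq_along(r)) for (j in seq_along(r))
      if (idx[j] - idx[i] == lag) { tot <- tot + r[i] * r[j]; np <- np + 1L }
    if (lag == 0L) tot / length(r) else tot / np
  }
  oracle_err <- withr::with_seed(seed, {
    max(vapply(1:20, function(k) {
      n <- sample(10:30, 1)
      idx <- sort(sample(1:60, n))
      r <- rnorm(n)
      max(abs(lag_autocovariance(r, idx, 0L) - brute(r, idx, 0L)),
          abs(lag_autocovariance(r, idx, 1L) - brute(r, idx, 1L)))
    }, 0))
  })
  add("autocovariance equals brute-force double loop (max abs error)",
      oracle_err, "< 1e-12", oracle_err < 1e-12)

  # recovery: injected drift, and autocovariances against their exact
  # finite-sample expectation (no exclusion, so the expectation is exact)
  rec <- withr::with_seed(seed + 2, {
    res <- vapply(seq_len(n_recovery), function(i) {
      p <- sim_params(clock_sd_ms = 60, motor_sd_ms = 30,
                      drift_coeffs_ms = c(60 / 49, 0, 0))
      s <- simulate_wk_series(p, "externally_paced")
      f <- fit_participant(s)
      iri <- prefilter(compute_iri(s))
      f0 <- fit_trend_lag1(iri)
      c(drift = f$drift_ms, G0 = f0$G0, G1 = f0$G1)
    }, numeric(3))
    rowMeans(res)
  })
  exp_ac <- expected_detrended_acov(4:50, 2L, 3600 + 2 * 900, -900)
  drift_truth <- 60 / 49 * 46  # modelled change across the analysed stimuli
  add("mean recovered drift (injected linear drift)", rec[["drift"]],
      sprintf("%.1f +/- 10", drift_truth),
      abs(rec[["drift"]] - drift_truth) <= 10)
  add("mean G0 vs exact finite-sample expectation", rec[["G0"]],
      sprintf("%.0f +/- 10%%", exp_ac$EG0),
      abs(rec[["G0"]] - exp_ac$EG0) <= 0.10 * exp_ac$EG0)
  add("mean G1 vs exact finite-sample expectation", rec[["G1"]],
      sprintf("%.0f +/- 15%%", abs(exp_ac$EG1)),
      abs(rec[["G1"]] - exp_ac$EG1) <= 0.15 * abs(exp_ac$EG1))

  # exclusion calibration
  s <- simulate_wk_series(sim_params(n_taps = 5003, clock_sd_ms = 60,
                                     motor_sd_ms = 30, seed = seed + 3),
                          "externally_paced")
  iri <- prefilter(compute_iri(s))
  iri2 <- exclude_outliers(iri, fit_trend_lag1(iri))
  frac <- sum(iri2$exclusion_reason == "outlier") / sum(iri$valid)
  add("2-SD exclusion rate on Gaussian series", frac, "0.046 +/- 0.01",
      abs(frac - 2 * pnorm(-2)) <= 0.01)

  # BCa coverage of a two-group mean difference
  if (n_coverage > 0) {
    cov <- withr::with_seed(seed + 4, {
      hits <- vapply(seq_len(n_coverage), function(i) {
        d <- data.frame(y = c(rnorm(25, 0), rnorm(25, 1)),
                        g = rep(c("a", "b"), each = 25))
        ci <- bca_ci(d, function(dd) {
          mean(dd$y[dd$g == "b"]) - mean(dd$y[dd$g == "a"])
        }, n_boot = n_boot, seed = i, strata = d$g)
        ci$low <= 1 && 1 <= ci$high
      }, NA)
      mean(hits)
    })
    add("BCa 95% coverage of a known mean difference", cov, "[0.88, 1.00]",
        cov >= 0.88)
  }
  do.call(rbind, checks)
}
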