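# group-level inference: BCa bootstrap, adjusted comparisons, associations

METRICS <- c("clock_var", "motor_var", "total_var", "mean_iri",
             "drift_ms", "abs_drift_ms", "rho1", "G0", "G1")

#' Bias-corrected and accelerated bootstrap confidence interval
#'
#' Nonparametric BCa interval for a statistic of a participant table. Rows are
#' resampled with replacement (within `strata` when given, preserving stratum
#' sizes), the bias correction `z0` comes from the fraction of bootstrap
#' statistics below the point estimate, and the acceleration `a` from the
#' jackknife skewness.  The statistic may return a vector; all outputs are
#' then per component.
#'
#' Degenerate situations are flagged rather than silently patched: if every
#' bootstrap statistic is identical the interval has zero width
#' (`flag = "zero_width"`); if the bias-correction fraction is 0 or 1 the
#' percentile interval is returned (`flag = "percentile_fallback"`).
#'
#' @param data Data frame of independent units (participants).
#' @param statistic Function `data -> numeric` (scalar or fixed-length vector).
#' @param n_boot Number of bootstrap replications (>= 199).
#' @param seed Integer seed; results are reproducible bit-for-bit given
#'   `(seed, n_boot)`.
#' @param strata Optional factor of length `nrow(data)` for stratified
#'   resampling.
#' @param conf Confidence level (default 0.95).
#' @return List with `estimate`, `low`, `high`, `z0`, `accel`, `flag`
#'   (per-component character), `n_boot`, `seed`, `n_dropped` (bootstrap
#'   replicates whose statistic was `NA`).
#' @export
bca_ci <- function(data, statistic, n_boot = 2000, seed = 1, strata = NULL,
                   conf = 0.95) {
  stopifnot(is.data.frame(data), nrow(data) >= 3L)
  if (n_boot < 199) wk_stop("wktap_invalid_params", "n_boot must be >= 199")
  t0 <- statistic(data)
  k <- length(t0)
  n <- nrow(data)
  if (!is.null(strata)) {
    strata <- as.factor(strata)
    stopifnot(length(strata) == n)
    groups_idx <- split(seq_len(n), strata)
  }
  boot_mat <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- if (is.null(strata)) {
        sample.int(n, n, replace = TRUE)
      } else {
        unlist(lapply(groups_idx, function(g) g[sample.int(length(g), length(g), replace = TRUE)]),
               use.names = FALSE)
      }
      out <- tryCatch(statistic(data[idx, , drop = FALSE]),
                      error = function(e) rep(NA_real_, k))
      if (length(out) != k) rep(NA_real_, k) else as.numeric(out)
    }, numeric(k))
  })
  boot_mat <- matrix(boot_mat, nrow = k)

  # jackknife acceleration
  jack <- vapply(seq_len(n), function(i) {
    out <- tryCatch(statistic(data[-i, , drop = FALSE]),
                    error = function(e) rep(NA_real_, k))
    if (length(out) != k) rep(NA_real_, k) else as.numeric(out)
  }, numeric(k))
  jack <- matrix(jack, nrow = k)

  alpha <- (1 - conf) / 2
  za <- qnorm(c(alpha, 1 - alpha))
  low <- high <- z0v <- av <- numeric(k)
  flag <- character(k)
  n_dropped <- 0L
  for (j in seq_len(k)) {
    tb <- boot_mat[j, ]
    drop <- is.na(tb)
    n_dropped <- max(n_dropped, sum(drop))
    tb <- tb[!drop]
    if (!length(tb)) {
      low[j] <- high[j] <- NA_real_; z0v[j] <- av[j] <- NA_real_
      flag[j] <- "no_replicates"; next
    }
    if (all(tb == tb[1]) && tb[1] == t0[j]) {
      low[j] <- high[j] <- t0[j]; z0v[j] <- 0; av[j] <- 0
      flag[j] <- "zero_width"; next
    }
    frac <- (sum(tb < t0[j]) + 0.5 * sum(tb == t0[j])) / length(tb)
    jj <- jack[j, ]; jj <- jj[!is.na(jj)]
    u <- mean(jj) - jj
    denom <- sum(u^2)^1.5
    a <- if (denom > 0) sum(u^3) / (6 * denom) else 0
    if (frac <= 0 || frac >= 1) {
      ci <- unname(stats::quantile(tb, c(alpha, 1 - alpha), type = 6))
      z0v[j] <- if (frac <= 0) -Inf else Inf
      av[j] <- a
      flag[j] <- "percentile_fallback"
    } else {
      z0 <- qnorm(frac)
      adj <- pnorm(z0 + (z0 + za) / (1 - a * (z0 + za)))
      ci <- unname(stats::quantile(tb, adj, type = 6))
      z0v[j] <- z0; av[j] <- a
      flag[j] <- "ok"
    }
    low[j] <- ci[1]; high[j] <- ci[2]
  }
  list(estimate = t0, low = low, high = high, z0 = z0v, accel = av,
       flag = flag, n_boot = n_boot, seed = seed, n_dropped = n_dropped)
}

merge_fits_cohort <- function(fits, cohort, condition = NULL) {
  stopifnot(is.data.frame(fits), is.data.frame(cohort))
  if (!is.null(condition)) {
    condition <- match.arg(condition, CONDITIONS)
    fits <- fits[fits$condition == condition, , drop = FALSE]
  }
  if (anyDuplicated(fits$participant_id))
    wk_stop("wktap_invalid_params",
            "fits table has several rows per participant; pass `condition` to disambiguate")
  keep <- c("participant_id", "age", "gender", "group",
            intersect(COHORT_SCORE_COLS, names(cohort)))
  merged <- merge(fits[, setdiff(names(fits), "group"), drop = FALSE],
                  as.data.frame(cohort)[, keep, drop = FALSE],
                  by = "participant_id")
  merged[order(merged$participant_id, method = "radix"), , drop = FALSE]
}

diff_statistic <- function(metric, adjust) {
  function(d) {
    fm <- if (adjust) {
      # guard: gender may collapse to one level in a bootstrap replicate
      if (length(unique(d$gender)) > 1L)
        stats::as.formula(paste(metric, "~ .grp + age + gender"))
      else stats::as.formula(paste(metric, "~ .grp + age"))
    } else stats::as.formula(paste(metric, "~ .grp"))
    unname(coef(lm(fm, data = d))[".grpcomparison"])
  }
}

#' Compare one timing metric between two groups
#'
#' Point estimate is the group-indicator coefficient from a least-squares
#' regression of the metric on group (plus age and gender when `adjust`),
#' with a heteroskedasticity-robust (HC1) standard error reported alongside;
#' the confidence interval is a BCa bootstrap interval over participant-level
#' resampling stratified by group, refitting the regression per replicate.
#'
#' @param fits Per-participant metrics table from [fit_sessions()].
#' @param cohort A `cohort_table`.
#' @param metric Metric column name (e.g. `"clock_var"`).
#' @param reference,comparison Group labels; the estimate is
#'   comparison minus reference.
#' @param condition Condition to select from `fits` (required when the table
#'   holds both).
#' @param adjust Adjust for age and gender (default `TRUE`).
#' @param n_boot,seed Bootstrap settings.
#' @return An object of class `group_comparison`.
#' @export
compare_groups <- function(fits, cohort, metric, reference, comparison,
                           condition = NULL, adjust = TRUE,
                           n_boot = 2000, seed = 1) {
  if (!metric %in% names(fits))
    wk_stop("wktap_invalid_params", "metric '%s' not present in fits table", metric)
  d <- merge_fits_cohort(fits, cohort, condition)
  d <- d[d$group %in% c(reference, comparison), , drop = FALSE]
  d <- d[complete.cases(d[, c(metric, "age", "gender")]), , drop = FALSE]
  n_per <- table(factor(d$group, levels = c(reference, comparison)))
  if (any(n_per < 2L))
    wk_stop("wktap_invalid_params",
            "need >= 2 participants per group (got %s)",
            paste(sprintf("%s=%d", names(n_per), n_per), collapse = ", "))
  d$.grp <- factor(ifelse(d$group == reference, "reference", "comparison"),
                   levels = c("reference", "comparison"))

  unadj <- diff_statistic(metric, adjust = FALSE)(d)
  adj <- diff_statistic(metric, adjust = TRUE)(d)
  est <- if (adjust) adj else unadj

  fm <- if (adjust) stats::as.formula(paste(metric, "~ .grp + age + gender"))
        else stats::as.formula(paste(metric, "~ .grp"))
  fit_lm <- lm(fm, data = d)
  ct <- lmtest::coeftest(fit_lm, vcov. = sandwich::vcovHC(fit_lm, type = "HC1"))
  robust_se <- ct[".grpcomparison", "Std. Error"]
  robust_p <- ct[".grpcomparison", "Pr(>|t|)"]

  ci <- bca_ci(d, diff_statistic(metric, adjust), n_boot = n_boot, seed = seed,
               strata = d$.grp)
  structure(list(
    metric = metric, reference_group = reference, comparison_group = comparison,
    condition = condition, n_reference = unname(n_per[reference]),
    n_comparison = unname(n_per[comparison]),
    unadjusted_diff = unadj, adjusted_diff = adj, adjusted = adjust,
    estimate = est, ci_low = ci$low, ci_high = ci$high,
    robust_se = robust_se, robust_p = robust_p,
    estimate_outside_ci = est < ci$low || est > ci$high,
    flag = ci$flag, n_boot = n_boot, seed = seed),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %s vs %s (%s)\n", x$metric,
              x$comparison_group, x$reference_group,
              if (x$adjusted) "age/gender adjusted" else "unadjusted"))
  cat(sprintf("  estimate %.2f (95%% BCa CI %.2f, %.2f), robust SE %.2f, p = %.3g\n",
              x$estimate, x$ci_low, x$ci_high, x$robust_se, x$robust_p))
  if (x$flag != "ok") cat(sprintf("  flag: %s\n", x$flag))
  invisible(x)
}

#' Interaction between drift direction and group for absolute drift
#'
#' Regresses absolute drift on group, drift direction (negative: getting
#' faster; positive: getting slower) and their interaction, with age and
#' gender covariates, and reports the per-stratum group differences and the
#' interaction with BCa intervals (participant resampling stratified by
#' group).
#'
#' @param fits,cohort As in [compare_groups()].
#' @param groups Length-2 character vector `(reference, comparison)`.
#' @param condition Condition to select.
#' @param n_boot,seed Bootstrap settings.
#' @return List with estimates and CIs for `diff_negative`, `diff_positive`
#'   and `interaction` (positive-stratum difference minus negative-stratum
#'   difference).
#' @export
drift_direction_interaction <- function(fits, cohort, groups, condition = NULL,
                                        n_boot = 2000, seed = 1) {
  stopifnot(length(groups) == 2L)
  d <- merge_fits_cohort(fits, cohort, condition)
  d <- d[d$group %in% groups, , drop = FALSE]
  d$.grp <- factor(ifelse(d$group == groups[1], "reference", "comparison"),
                   levels = c("reference", "comparison"))
  d$.sign <- factor(ifelse(d$drift_ms < 0, "negative", "positive"),
                    levels = c("negative", "positive"))
  counts <- table(d$.grp, d$.sign)
  if (any(counts == 0L)) {
    empty <- which(counts == 0L, arr.ind = TRUE)[1, ]
    wk_stop("wktap_invalid_params",
            "empty stratum: group '%s' has no %s-drift participants",
            groups[if (empty[1] == 1) 1 else 2],
            dimnames(counts)[[2]][empty[2]])
  }
  statistic <- function(dd) {
    if (length(unique(dd$gender)) > 1L) {
      f <- abs_drift_ms ~ .grp * .sign + age + gender
    } else f <- abs_drift_ms ~ .grp * .sign + age
    b <- coef(lm(f, data = dd))
    diff_neg <- unname(b[".grpcomparison"])
    inter <- unname(b[".grpcomparison:.signpositive"])
    c(diff_negative = diff_neg, diff_positive = diff_neg + inter,
      interaction = inter)
  }
  est <- statistic(d)
  ci <- bca_ci(d, statistic, n_boot = n_boot, seed = seed, strata = d$.grp)
  list(reference_group = groups[1], comparison_group = groups[2],
       estimates = est,
       ci_low = setNames(ci$low, names(est)),
       ci_high = setNames(ci$high, names(est)),
       flag = setNames(ci$flag, names(est)),
       counts = counts, n_boot = n_boot, seed = seed)
}

#' Association between a tapping metric and a cognitive score
#'
#' Linear regression of the metric on the score for two groups with age and
#' gender covariates.  With `with_interaction = TRUE` the model contains
#' score, group and their interaction, giving per-group slopes and the
#' difference of slopes; otherwise a single pooled slope is fitted.
#' Participants with a missing score are dropped listwise and counted.
#'
#' @param fits,cohort As in [compare_groups()].
#' @param metric Metric column name.
#' @param score `"stroop_interference_s"` or `"digit_span_backwards"`.
#' @param groups Length-2 character vector `(reference, comparison)`.
#' @param condition Condition to select.
#' @param with_interaction Fit per-group slopes and their difference.
#' @param n_boot,seed Bootstrap settings.
#' @return List of class `association_result` with slopes, interaction (when
#'   fitted) and BCa CIs.
#' @export
association <- function(fits, cohort, metric, score, groups,
                        condition = NULL, with_interaction = TRUE,
                        n_boot = 2000, seed = 1) {
  stopifnot(length(groups) == 2L)
  if (!score %in% names(cohort))
    wk_stop("wktap_invalid_params", "score '%s' not present in cohort", score)
  d <- merge_fits_cohort(fits, cohort, condition)
  d <- d[d$group %in% groups, , drop = FALSE]
  n_all <- nrow(d)
  d <- d[complete.cases(d[, c(metric, score, "age", "gender")]), , drop = FALSE]
  n_dropped <- n_all - nrow(d)
  if (n_dropped > 0)
    wk_log("association %s ~ %s: dropped %d participants with missing values",
           metric, score, n_dropped, verbose = TRUE)
  n_per <- table(factor(d$group, levels = groups))
  if (any(n_per < 5L))
    wk_stop("wktap_invalid_params",
            "need >= 5 scored participants per group (got %s)",
            paste(sprintf("%s=%d", names(n_per), n_per), collapse = ", "))
  if (length(unique(d[[score]])) == 1L)
    wk_stop("wktap_invalid_params", "score '%s' is constant", score)
  d$.grp <- factor(ifelse(d$group == groups[1], "reference", "comparison"),
                   levels = c("reference", "comparison"))
  d$.score <- d[[score]]
  d$.metric <- d[[metric]]

  statistic <- if (with_interaction) {
    function(dd) {
      f <- if (length(unique(dd$gender)) > 1L)
        .metric ~ .score * .grp + age + gender else .metric ~ .score * .grp + age
      b <- coef(lm(f, data = dd))
      s_ref <- unname(b[".score"])
      inter <- unname(b[".score:.grpcomparison"])
      c(slope_reference = s_ref, slope_comparison = s_ref + inter,
        interaction = inter)
    }
  } else {
    function(dd) {
      f <- if (length(unique(dd$gender)) > 1L)
        .metric ~ .score + .grp + age + gender else .metric ~ .score + .grp + age
      c(pooled_slope = unname(coef(lm(f, data = dd))[".score"]))
    }
  }
  est <- statistic(d)
  ci <- bca_ci(d, statistic, n_boot = n_boot, seed = seed, strata = d$.grp)
  structure(list(metric = metric, score = score,
                 reference_group = groups[1], comparison_group = groups[2],
                 with_interaction = with_interaction,
                 estimates = est,
                 ci_low = setNames(ci$low, names(est)),
                 ci_high = setNames(ci$high, names(est)),
                 flag = setNames(ci$flag, names(est)),
                 n_used = nrow(d), n_dropped = n_dropped,
                 n_boot = n_boot, seed = seed),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("<association_result> %s ~ %s (%s vs %s), n = %d (%d dropped)\n",
              x$metric, x$score, x$comparison_group, x$reference_group,
              x$n_used, x$n_dropped))
  for (nm in names(x$estimates)) {
    cat(sprintf("  %-17s %8.2f (95%% BCa CI %.2f, %.2f)%s\n", nm,
                x$estimates[[nm]], x$ci_low[[nm]], x$ci_high[[nm]],
                if (x$flag[[nm]] != "ok") paste0(" [", x$flag[[nm]], "]") else ""))
  }
  invisible(x)
}

#' Test whether lag-1 autocorrelation violations differ between groups
#'
#' A violation is an estimated lag-1 autocorrelation greater than zero (the
#' two-process model confines it to `[-0.5, 0]`).  Counts violating and
#' non-violating participants per group and applies Fisher's exact test to the
#' resulting r-by-2 table: full exact enumeration when the table total is at
#' most `exact_limit`, otherwise a seeded Monte Carlo p-value.
#'
#' @param fits Per-participant metrics table (one condition).
#' @param groups Optional subset/order of group labels.
#' @param cohort Optional cohort table supplying group labels.
#' @param exact_limit Largest table total for full enumeration (default 60).
#' @param seed Seed for the Monte Carlo branch.
#' @return List with the contingency `table`, `p_value`, `method` and the
#'   number of participants with undefined rho1 (excluded).
#' @export
violation_test <- function(fits, groups = NULL, cohort = NULL,
                           exact_limit = 60L, seed = 1) {
  d <- tibble::as_tibble(fits)
  if (!is.null(cohort)) {
    d$group <- NULL
    d <- merge(d, as.data.frame(cohort)[, c("participant_id", "group")],
               by = "participant_id")
  }
  if (is.null(groups)) groups <- sort(unique(d$group))
  if (length(groups) < 2L)
    wk_stop("wktap_invalid_params", "need at least 2 groups")
  d <- d[d$group %in% groups, , drop = FALSE]
  n_undefined <- sum(is.na(d$rho1))
  d <- d[!is.na(d$rho1), , drop = FALSE]
  counts <- table(factor(d$group, levels = groups),
                  factor(d$rho1 > 0, levels = c(TRUE, FALSE),
                         labels = c("violating", "non_violating")))
  if (any(rowSums(counts) == 0L))
    wk_stop("wktap_invalid_params", "empty group: %s",
            rownames(counts)[rowSums(counts) == 0L][1])
  if (all(counts[, "violating"] == 0L) || all(counts[, "non_violating"] == 0L)) {
    return(list(table = counts, p_value = 1, method = "degenerate",
                n_undefined = n_undefined))
  }
  if (sum(counts) <= exact_limit) {
    p <- fisher.test(counts)$p.value
    method <- "exact"
  } else {
    p <- withr::with_seed(seed,
      fisher.test(counts, simulate.p.value = TRUE, B = 1e5)$p.value)
    method <- "monte_carlo"
  }
  list(table = counts, p_value = min(p, 1), method = method,
       n_undefined = n_undefined)
}
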