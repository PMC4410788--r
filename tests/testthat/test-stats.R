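test_that("BCa interval behaves like the percentile interval under symmetry", {
  d <- withr::with_seed(5, data.frame(y = rnorm(60)))
  ci <- bca_ci(d, function(dd) mean(dd$y), n_boot = 1999, seed = 2)
  expect_lt(abs(ci$z0), 0.15)
  boots <- withr::with_seed(2, {
    vapply(1:1999, function(b) mean(d$y[sample.int(60, 60, TRUE)]), 0)
  })
  perc <- unname(quantile(boots, c(0.025, 0.975), type = 6))
  # z0 and a are small, so BCa and percentile endpoints nearly coincide
  expect_equal(ci$low, perc[1], tolerance = 0.15)
  expect_equal(ci$high, perc[2], tolerance = 0.15)
})

test_that("degenerate bootstrap inputs are flagged, not patched", {
  d <- data.frame(y = rep(5, 12))
  ci <- bca_ci(d, function(dd) mean(dd$y), n_boot = 199, seed = 1)
  expect_identical(ci$flag, "zero_width")
  expect_identical(c(ci$low, ci$high), c(5, 5))
  expect_error(bca_ci(d, mean, n_boot = 50, seed = 1),
               class = "wktap_invalid_params")
})

test_that("bootstrap results are reproducible bit-for-bit", {
  d <- withr::with_seed(3, data.frame(y = rnorm(30),
                                      g = rep(c("a", "b"), 15)))
  stat <- function(dd) mean(dd$y[dd$g == "b"]) - mean(dd$y[dd$g == "a"])
  c1 <- bca_ci(d, stat, n_boot = 499, seed = 11, strata = d$g)
  c2 <- bca_ci(d, stat, n_boot = 499, seed = 11, strata = d$g)
  expect_identical(c1, c2)
  c3 <- bca_ci(d, stat, n_boot = 499, seed = 12, strata = d$g)
  expect_false(identical(c1$low, c3$low))
})

test_that("identically simulated groups give a null-covering comparison", {
  mc <- make_fits_cohort(n1 = 30, n2 = 30, seed = 8, iri_shift2 = 0)
  cg <- compare_groups(mc$fits, mc$cohort, "mean_iri", "control", "bvFTD",
                       condition = "self_paced", n_boot = 499, seed = 4)
  expect_true(cg$ci_low <= 0 && 0 <= cg$ci_high)
  expect_lt(abs(cg$adjusted_diff), 60)
})

test_that("an injected mean-interval deficit is recovered with its CI", {
  mc <- make_fits_cohort(n1 = 30, n2 = 20, seed = 2, iri_shift2 = -175)
  cg <- compare_groups(mc$fits, mc$cohort, "mean_iri", "control", "bvFTD",
                       condition = "self_paced", n_boot = 999, seed = 4)
  expect_true(cg$ci_low <= -175 && -175 <= cg$ci_high)
  expect_true(cg$ci_low <= cg$adjusted_diff & cg$adjusted_diff <= cg$ci_high)
  expect_false(cg$estimate_outside_ci)
  # unadjusted and adjusted estimates agree broadly when covariates are noise
  expect_lt(abs(cg$adjusted_diff - cg$unadjusted_diff), 80)
})

test_that("constant metrics yield a zero-width flagged comparison", {
  mc <- make_fits_cohort(n1 = 10, n2 = 10, seed = 5)
  mc$fits$mean_iri <- 1500
  cg <- suppressWarnings(  # lm warns about the (intentionally) perfect fit
    compare_groups(mc$fits, mc$cohort, "mean_iri", "control", "bvFTD",
                   condition = "self_paced", adjust = FALSE,
                   n_boot = 299, seed = 1))
  expect_equal(cg$estimate, 0, tolerance = 1e-10)
  expect_identical(cg$flag, "zero_width")
})

test_that("tiny groups are rejected", {
  mc <- make_fits_cohort(n1 = 10, n2 = 10, seed = 5)
  keep <- mc$fits$group == "control" | mc$fits$participant_id == "P011"
  expect_error(compare_groups(mc$fits[keep, ], mc$cohort, "mean_iri",
                              "control", "bvFTD", condition = "self_paced",
                              n_boot = 299),
               "2 participants", class = "wktap_invalid_params")
})

test_that("drift-direction interaction detects a one-sided inflation", {
  mc <- make_fits_cohort(n1 = 100, n2 = 100, seed = 12, drift_sd = 80)
  f <- mc$fits
  # inflate only the negative-drift magnitudes of the patient group
  neg_pat <- f$group == "bvFTD" & f$drift_ms < 0
  f$drift_ms[neg_pat] <- f$drift_ms[neg_pat] * 4
  f$abs_drift_ms <- abs(f$drift_ms)
  di <- drift_direction_interaction(f, mc$cohort, c("control", "bvFTD"),
                                    condition = "self_paced",
                                    n_boot = 499, seed = 3)
  expect_gt(di$ci_low[["diff_negative"]], 0)       # inflated stratum detected
  expect_gt(abs(di$estimates[["interaction"]]), 0)
  expect_true(di$ci_high[["interaction"]] < 0 || di$ci_low[["interaction"]] > 0)

  # symmetric null: interaction CI covers zero
  di0 <- drift_direction_interaction(mc$fits, mc$cohort, c("control", "bvFTD"),
                                     condition = "self_paced",
                                     n_boot = 499, seed = 3)
  expect_true(di0$ci_low[["interaction"]] <= 0 &&
                0 <= di0$ci_high[["interaction"]])

  # degenerate stratum: all-positive drift in one group
  f2 <- mc$fits
  f2$drift_ms[f2$group == "bvFTD"] <- abs(f2$drift_ms[f2$group == "bvFTD"])
  err <- tryCatch(drift_direction_interaction(f2, mc$cohort,
                                              c("control", "bvFTD"),
                                              condition = "self_paced"),
                  error = identity)
  expect_s3_class(err, "wktap_invalid_params")
  expect_match(conditionMessage(err), "bvFTD")
})

test_that("associations recover a shared slope and detect a group-specific one", {
  mc <- make_fits_cohort(n1 = 50, n2 = 50, seed = 9)
  f <- mc$fits
  span <- mc$cohort$digit_span_backwards[match(f$participant_id,
                                               mc$cohort$participant_id)]
  f$mean_iri <- withr::with_seed(1, 1300 + 39.3 * span + rnorm(nrow(f), 0, 40))
  a_pool <- association(f, mc$cohort, "mean_iri", "digit_span_backwards",
                        c("control", "bvFTD"), condition = "self_paced",
                        with_interaction = FALSE, n_boot = 499, seed = 6)
  expect_true(a_pool$ci_low[["pooled_slope"]] <= 39.3 &&
                39.3 <= a_pool$ci_high[["pooled_slope"]])
  a_int <- association(f, mc$cohort, "mean_iri", "digit_span_backwards",
                       c("control", "bvFTD"), condition = "self_paced",
                       with_interaction = TRUE, n_boot = 499, seed = 6)
  expect_true(a_int$ci_low[["interaction"]] <= 0 &&
                0 <= a_int$ci_high[["interaction"]])
  expect_equal(a_int$estimates[["interaction"]],
               a_int$estimates[["slope_comparison"]] -
                 a_int$estimates[["slope_reference"]], tolerance = 1e-10)

  # slope present only in the patient group
  f2 <- mc$fits
  f2$mean_iri <- withr::with_seed(2, 1500 +
    ifelse(f2$group == "bvFTD", 40 * span, 0) + rnorm(nrow(f2), 0, 40))
  a2 <- association(f2, mc$cohort, "mean_iri", "digit_span_backwards",
                    c("control", "bvFTD"), condition = "self_paced",
                    with_interaction = TRUE, n_boot = 499, seed = 6)
  expect_gt(a2$ci_low[["interaction"]], 0)

  # missing scores are dropped and counted
  ch <- mc$cohort
  ch$digit_span_backwards[1:7] <- NA
  a3 <- association(f, ch, "mean_iri", "digit_span_backwards",
                    c("control", "bvFTD"), condition = "self_paced",
                    with_interaction = FALSE, n_boot = 299, seed = 1)
  expect_identical(a3$n_dropped, 7L)

  ch$digit_span_backwards <- 5
  expect_error(association(f, ch, "mean_iri", "digit_span_backwards",
                           c("control", "bvFTD"), condition = "self_paced"),
               "constant", class = "wktap_invalid_params")
})

test_that("violation counts are tested against an exact enumeration oracle", {
  # construct fits with known violation counts: [[1, 9], [8, 2]]
  rho <- c(rep(0.2, 1), rep(-0.2, 9), rep(0.2, 8), rep(-0.2, 2))
  f <- data.frame(participant_id = sprintf("P%02d", 1:20),
                  group = rep(c("a", "b"), c(10, 10)), rho1 = rho)
  vt <- violation_test(f, groups = c("a", "b"))
  expect_identical(unclass(vt$table)[1:4], c(1L, 8L, 9L, 2L))
  expect_identical(vt$method, "exact")
  expect_equal(vt$p_value, brute_fisher_2x2(matrix(c(1, 9, 8, 2), 2, byrow = TRUE)),
               tolerance = 1e-9)

  # balanced duplicate rows: p = 1
  f2 <- data.frame(participant_id = sprintf("Q%02d", 1:20),
                   group = rep(c("a", "b"), c(10, 10)),
                   rho1 = rep(c(0.1, 0.1, -0.1, -0.1, -0.1), 4))
  expect_equal(violation_test(f2, groups = c("a", "b"))$p_value, 1)

  # no violations anywhere: degenerate, p = 1
  f3 <- f
  f3$rho1 <- -0.3
  vt3 <- violation_test(f3, groups = c("a", "b"))
  expect_identical(vt3$method, "degenerate")
  expect_identical(vt3$p_value, 1)

  expect_error(violation_test(f[f$group == "a", ], groups = "a"),
               class = "wktap_invalid_params")
})

test_that("large tables fall back to a seeded Monte Carlo Fisher test", {
  rho <- withr::with_seed(4, runif(120, -0.4, 0.3))
  f <- data.frame(participant_id = sprintf("R%03d", 1:120),
                  group = rep(c("a", "b", "c"), 40), rho1 = rho)
  v1 <- violation_test(f, seed = 9)
  v2 <- violation_test(f, seed = 9)
  expect_identical(v1$p_value, v2$p_value)
  expect_identical(v1$method, "monte_carlo")
  expect_true(v1$p_value > 0 && v1$p_value <= 1)
})
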