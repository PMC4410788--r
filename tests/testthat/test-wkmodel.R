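test_that("interval extraction matches hand-constructed sessions", {
  s <- make_ext_session(c(0, 1500, 3000), n_stim = 3)
  iri <- compute_iri(s)
  expect_identical(nrow(iri), 2L)
  expect_equal(iri$iri_ms, c(1500, 1500))
  expect_true(all(iri$valid))
  expect_equal(iri$stimulus_index, c(2L, 3L))

  # a missed tap: the 3000 ms span is flagged, never emitted as one interval
  s2 <- make_ext_session(c(0, 1500, 4500), n_stim = 4)
  iri2 <- compute_iri(s2)
  expect_equal(iri2$iri_ms, c(1500, 3000))
  expect_true(iri2$valid[1])
  expect_false(iri2$valid[2])
  expect_identical(iri2$exclusion_reason[2], "missing_neighbor")

  # count preservation: 50 taps, none missing -> 49 intervals
  s3 <- simulate_wk_series(sim_params(clock_sd_ms = 40, seed = 1),
                           "externally_paced")
  expect_identical(nrow(compute_iri(s3)), 49L)
  expect_error(compute_iri(make_ext_session(0)), class = "wktap_too_few_taps")
})

test_that("double-tap candidates lose their stimulus slot", {
  s <- make_ext_session(c(0, 1500, 1600, 3000, 4500, 6000, 7500, 9000, 10500,
                          12000, 13500, 15000, 16500, 18000), n_stim = 14)
  iri <- compute_iri(s)
  # the 1600 tap is farther from onset 1500 than the 1500 tap: unassigned
  un <- iri[iri$exclusion_reason == "unassigned", ]
  expect_true(nrow(un) >= 1L)
  expect_true(100 %in% un$iri_ms)
})

test_that("prefiltering removes the first taps and guards small series", {
  s <- simulate_wk_series(sim_params(clock_sd_ms = 40, seed = 2),
                          "externally_paced")
  iri <- compute_iri(s)
  pf <- prefilter(iri)
  expect_identical(sum(pf$valid), 47L)
  expect_identical(sum(pf$exclusion_reason == "prefilter"), 2L)

  s2 <- simulate_wk_series(sim_params(clock_sd_ms = 40, seed = 3), "self_paced")
  iri2 <- compute_iri(s2)
  expect_identical(sum(iri2$valid), 49L)  # post-synchronization intervals
  expect_identical(sum(prefilter(iri2)$valid), 42L)

  s3 <- simulate_wk_series(sim_params(n_taps = 15, clock_sd_ms = 40, seed = 4),
                           "self_paced")
  expect_error(prefilter(compute_iri(s3)), "too few",
               class = "wktap_too_few_taps")

  # exact count bookkeeping
  expect_identical(sum(pf$valid),
                   nrow(pf) - sum(pf$exclusion_reason != "none"))
})

test_that("trend fit recovers exact polynomial series", {
  s <- make_ext_session((0:49) * 1500)
  f <- fit_trend_lag1(prefilter(compute_iri(s)))
  expect_equal(unname(f$trend_coeffs), c(1500, 0, 0), tolerance = 1e-9)
  expect_equal(f$G0, 0)
  expect_equal(f$clock_var, 0)
  expect_equal(f$motor_var, 0)

  # iri = 1400 + 2 j: linear coefficient recovered to machine precision
  taps <- cumsum(c(0, 1400 + 2 * (2:50)))
  s2 <- make_ext_session(taps)
  f2 <- fit_trend_lag1(prefilter(compute_iri(s2)))
  expect_equal(unname(f2$trend_coeffs[2]), 2, tolerance = 1e-8)
  expect_equal(unname(f2$trend_coeffs[1]), 1400, tolerance = 1e-6)
  expect_equal(unname(f2$trend_coeffs[3]), 0, tolerance = 1e-9)
})

test_that("pairwise autocovariances equal the brute-force double loop", {
  # frozen alternating-residual case: G0 = 100, G1 = -100, rho = -1
  r <- c(10, -10, 10, -10, 10)
  expect_identical(lag_autocovariance(r, 1:5, 0L), 100)
  expect_identical(lag_autocovariance(r, 1:5, 1L), -100)
  expect_identical(brute_acov(r, 1:5, 0L), 100)
  expect_identical(brute_acov(r, 1:5, 1L), -100)

  withr::with_seed(99, {
    for (k in 1:20) {
      n <- sample(8:25, 1)
      idx <- sort(sample(1:50, n))
      res <- rnorm(n)
      for (lag in 0:2) {
        expect_equal(lag_autocovariance(res, idx, lag),
                     brute_acov(res, idx, lag), tolerance = 1e-12)
      }
    }
  })
})

test_that("variance decomposition follows the model identities, unclamped", {
  d <- decompose_variance(100, 0)
  expect_equal(d[c("rho1", "clock_var", "motor_var")],
               list(rho1 = 0, clock_var = 100, motor_var = 0))
  d2 <- decompose_variance(100, -50)
  expect_equal(d2[c("rho1", "clock_var", "motor_var")],
               list(rho1 = -0.5, clock_var = 0, motor_var = 50))
  d3 <- decompose_variance(100, -70)
  expect_equal(d3$clock_var, -40)  # negative estimates are retained
  expect_false(decompose_variance(-5, 2)$var_defined)
  expect_true(is.na(decompose_variance(-5, 2)$clock_var))

  withr::with_seed(7, {
    for (i in 1:200) {
      g0 <- runif(1, 1e-6, 1e5)
      g1 <- runif(1, -6e4, 6e4)
      d <- decompose_variance(g0, g1)
      expect_equal(d$clock_var + 2 * d$motor_var, g0, tolerance = 1e-12)
    }
  })
})

test_that("drift metrics follow the fitted trend in closed form", {
  s <- make_ext_session((0:49) * 1500)
  f <- fit_trend_lag1(prefilter(compute_iri(s)))
  expect_equal(f$mean_iri, 1500)
  expect_equal(f$drift_ms, 0)

  slope <- -1.6
  taps <- cumsum(c(0, 1520 + slope * (2:50)))
  f2 <- fit_trend_lag1(prefilter(compute_iri(make_ext_session(taps))))
  k <- length(f2$analysed_index)
  expect_equal(f2$drift_ms, slope * (k - 1), tolerance = 1e-8)
  expect_equal(f2$abs_drift_ms, abs(f2$drift_ms))
})

test_that("outlier exclusion removes gross outliers and nothing else", {
  p <- sim_params(clock_sd_ms = 50, motor_sd_ms = 0, seed = 23)
  s <- simulate_wk_series(p, "externally_paced")
  iri <- prefilter(compute_iri(s))
  fit0 <- fit_trend_lag1(iri)
  # inject a single gross outlier at predicted + 5 sd
  j <- which(iri$valid)[20]
  iri$iri_ms[j] <- iri$iri_ms[j] + 5 * sqrt(fit0$G0)
  fit1 <- fit_trend_lag1(iri)
  out <- exclude_outliers(iri, fit1)
  expect_identical(which(out$exclusion_reason == "outlier"), j)

  # noiseless series: zero exclusions
  s0 <- make_ext_session((0:49) * 1500)
  iri0 <- prefilter(compute_iri(s0))
  out0 <- exclude_outliers(iri0, fit_trend_lag1(iri0))
  expect_identical(sum(out0$exclusion_reason == "outlier"), 0L)
})

test_that("estimates are invariant to a time-origin shift", {
  p <- sim_params(clock_sd_ms = 60, motor_sd_ms = 25,
                  drift_coeffs_ms = c(1, 0, 0), seed = 31)
  s <- simulate_wk_series(p, "externally_paced")
  shifted <- tap_session(s$participant_id, s$group, s$condition,
                         s$stimulus_onsets_ms + 5000, s$tap_times_ms + 5000,
                         s$target_interval_ms)
  f <- fit_participant(s)
  fs <- fit_participant(shifted)
  for (field in c("G0", "G1", "rho1", "clock_var", "motor_var", "mean_iri",
                  "drift_ms")) {
    expect_equal(f[[field]], fs[[field]], tolerance = 1e-9)
  }
})

test_that("the AR(1) estimator recovers a true lag-1 autoregressive error", {
  # build a session whose intervals are 1500 + AR(1) noise by construction
  phi <- -0.3
  sw <- 30
  y <- withr::with_seed(17, {
    e <- as.numeric(stats::arima.sim(list(ar = phi), n = 800, sd = sw))
    1500 + e
  })
  s <- make_ext_session(cumsum(c(0, y)), n_stim = 801)
  f <- fit_trend_lag1(prefilter(compute_iri(s)), estimator = "ar1")
  expect_identical(f$estimator, "ar1")
  expect_equal(f$rho1, phi, tolerance = 0.2)
  stat_var <- sw^2 / (1 - phi^2)
  expect_equal(f$total_var, stat_var, tolerance = 0.15)
  expect_equal(f$G1, f$rho1 * f$G0, tolerance = 1e-10)
})

test_that("degenerate designs are rejected", {
  s <- simulate_wk_series(sim_params(clock_sd_ms = 40, seed = 8),
                          "externally_paced")
  iri <- prefilter(compute_iri(s))
  iri$stimulus_index <- rep(5L, nrow(iri))
  expect_error(fit_trend_lag1(iri), "singular",
               class = "wktap_singular_design")
})

test_that("fit_participant tags stage errors with participant and condition", {
  s <- make_ext_session(c(0, 1500, 3000), n_stim = 3, id = "px")
  err <- tryCatch(fit_participant(s), error = identity)
  expect_s3_class(err, "wktap_fit_error")
  expect_match(conditionMessage(err), "px")
  expect_match(conditionMessage(err), "externally_paced")
})
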