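# Estimators: hand-computed values, the defining rescaling invariance of
# the operational variant, typed undefined-estimate errors, and the
# bias/variance approximations against simulation.

test_that("intensity and Fano estimators reproduce hand computations", {
  s <- toy_set()  # counts 2, 0, 1, 1 on (0, 2]
  expect_equal(estimate_intensity(s), 0.5)
  expect_equal(estimate_fano(s)$value, 2 / 3)
  expect_equal(estimate_fano(set_from_counts(c(3, 3, 3, 3), 1))$value, 0)
  expect_equal(estimate_intensity(spike_train_set(list(numeric(0),
                                                       numeric(0)), 1)), 0)
})

test_that("the Fano estimator equals a brute-force two-pass variance/mean computation", {
  set.seed(31)
  for (rep in 1:5) {
    counts <- rpois(20, 3)
    if (mean(counts) == 0) counts[1] <- 1
    s <- set_from_counts(counts, window = 4)
    mean_c <- sum(counts) / length(counts)
    ss <- 0
    for (c_i in counts) ss <- ss + (c_i - mean_c)^2
    expect_equal(estimate_fano(s)$value,
                 (ss / (length(counts) - 1)) / mean_c)
  }
})

test_that("undefined estimates raise typed errors instead of NaN", {
  empty <- spike_train_set(list(numeric(0), numeric(0)), 1)
  expect_error(estimate_fano(empty), class = "fanotime_undefined_estimate")
  expect_error(estimate_fano_operational(empty, 0.5),
               class = "fanotime_undefined_estimate")
  expect_error(estimate_fano(spike_train_set(list(0.5), 1)), "2 trials")
  expect_error(common_operational_window(list(empty)),
               class = "fanotime_undefined_estimate")
})

test_that("common operational window is the minimum of w * lambda_hat", {
  s1 <- set_from_counts(c(1, 2), 3)       # lambda_hat = 0.5, w = 3 -> 1.5
  s2 <- set_from_counts(c(6, 6), 3)       # lambda_hat = 2,   w = 3 -> 6
  expect_equal(common_operational_window(list(s1, s2)), 1.5)
  expect_equal(common_operational_window(list(s1)), 1.5)
  s3 <- set_from_counts(c(2, 2), 2)       # lambda_hat = 1
  expect_equal(common_operational_window(list(s3)), 2)
  # (w = 1, lambda = 1) and (w = 5, lambda = 0.1) -> min(1, 0.5)
  expect_equal(common_operational_window(
    list(set_from_counts(c(1, 1), 1), set_from_counts(c(0, 1), 5))), 0.5)
})

test_that("operational estimate with lambda_hat = 1 equals the standard estimate at w = w_o", {
  s <- set_from_counts(c(2, 3, 1, 2), window = 2)  # mean count 2 -> rate 1
  expect_equal(estimate_intensity(s), 1)
  expect_equal(estimate_fano_operational(s, 1.5)$value,
               estimate_fano(s, window = 1.5)$value)
})

test_that("operational Fano estimate is exactly invariant under time rescaling", {
  models <- list(isi_gamma(2, 1.5), isi_invgauss(0.5, 0.5),
                 mpp_model(1, 1.5, 0.1))
  for (i in seq_along(models)) {
    s <- simulate_spike_trains(models[[i]], 8 / models[[i]]$rate, 100,
                               seed = 20 + i)
    f0 <- estimate_fano_operational(s, w_o = 4)
    fs0 <- estimate_fano_operational_shifted(s, w_o = 3)
    for (c in c(0.001, 0.5, 3, 1e4)) {
      sc <- rescale_time(s, c)
      expect_equal(estimate_fano_operational(sc, w_o = 4)$value, f0$value,
                   tolerance = 1e-12)
      expect_equal(estimate_fano_operational_shifted(sc, w_o = 3)$value,
                   fs0$value, tolerance = 1e-12)
    }
  }
})

test_that("shifted-window estimator averages evenly spaced windows", {
  s <- set_from_counts(c(2, 3, 1, 2), window = 2)  # lambda_hat = 1
  # w_eff = w: single window, identical to the plain operational variant
  expect_equal(estimate_fano_operational_shifted(s, 2)$value,
               estimate_fano_operational(s, 2)$value)
  # w_eff = w/2: two disjoint halves, direct recomputation
  half1 <- estimate_fano(s, window = 1, start = 0)$value
  half2 <- estimate_fano(s, window = 1, start = 1)$value
  expect_equal(estimate_fano_operational_shifted(s, 1)$value,
               (half1 + half2) / 2)
  expect_error(estimate_fano_operational(s, 5), "exceeds")
})

test_that("ratios: identity, exact rate invariance, and agreement with theory", {
  s <- simulate_spike_trains(isi_gamma(1, 1.5), 10, 200, seed = 8)
  r_same <- fano_ratio(s, s)
  expect_equal(r_same$r_standard, 1)
  expect_equal(r_same$r_operational, 1)
  expect_equal(r_same$r_operational_shifted, 1)
  # a rescaled copy has identical variability: operational ratio exactly 1
  r_sc <- fano_ratio(s, rescale_time(s, 2.7))
  expect_equal(r_sc$r_operational, 1, tolerance = 1e-12)
  expect_equal(r_sc$common_operational_window,
               10 * estimate_intensity(s), tolerance = 1e-9)
  # standard ratio across F1 = 0.5 vs F2 = 1.5 arms matches the theory curves
  s1 <- simulate_spike_trains(isi_gamma(1, 0.5), 10, 1e4, seed = 81)
  s2 <- simulate_spike_trains(isi_gamma(1, 1.5), 10, 1e4, seed = 82)
  r <- fano_ratio(s1, s2, "standard")
  f1 <- fano_curve(isi_gamma(1, 0.5), 10)$fano
  f2 <- fano_curve(isi_gamma(1, 1.5), 10)$fano
  se1 <- fano_standard_error(spike_counts(s1))
  se2 <- fano_standard_error(spike_counts(s2))
  se_ratio <- (f2 / f1) * sqrt((se1 / f1)^2 + (se2 / f2)^2)
  expect_within_se(r$r_standard, f2 / f1, se_ratio)
})

test_that("MAE and the MSE decomposition match hand values and the algebraic identity", {
  expect_equal(mae(c(1, 1, 1), 1), 0)
  expect_equal(mae(c(0, 2), 1), 1)
  d <- mse_decomposition(c(0, 2), 1)
  expect_equal(unname(d["bias2"]), 0)
  expect_equal(unname(d["variance"]), 1)
  set.seed(4)
  for (rep in 1:5) {
    x <- rnorm(20); truth <- 0.3
    d <- mse_decomposition(x, truth)
    expect_equal(unname(d["bias2"] + d["variance"]),
                 mean((x - truth)^2), tolerance = 1e-12)
  }
  expect_error(mae(numeric(0), 1), "at least one")
})

test_that("bias/variance approximations: arithmetic and simulation-level accuracy", {
  expect_equal(approx_bias(1, 1, 10, 1, cov_term = 0), 0.1)
  # both correction terms vanish as the window grows
  expect_lt(abs(approx_bias(1.0001, 1, 1, 1e6, cov_term = 5) - 1e-4), 1e-5)
  expect_error(approx_bias(1, 1, 0, 1, 0), "positive")
  # exponential model: empirical bias/variance of the estimator vs the
  # approximations fed with Monte-Carlo moments
  m <- isi_exponential(5); w <- 1; n <- 50
  mom <- count_moments(m, w, n_trials = 2e5, seed = 61)
  set.seed(62)
  reps <- 4000
  vals <- replicate(reps, {
    estimate_fano(simulate_spike_trains(m, w, n))$value
  })
  b_hat <- mean(vals) - 1
  b_approx <- approx_bias(mom$fano_w, 1, 5, 1, mom$cov_term)
  expect_lt(abs(b_hat - b_approx), 0.02)
  v_approx <- approx_var(mom$fano_w, 5, 1, mom$var_s2, mom$var_count,
                         mom$cov_term)
  expect_lt(abs(n * var(vals) - v_approx) / v_approx, 0.2)
})

test_that("the influence-function standard error matches the Poisson asymptotic sqrt(2/n)", {
  set.seed(71)
  counts <- rpois(2e4, 5)
  expect_equal(fano_standard_error(counts), sqrt(2 / 2e4),
               tolerance = 0.2)
})
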