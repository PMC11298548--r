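test_that("baseline percentile matches interpolation oracle and closed forms", {
  expect_equal(compute_baseline(rep(7.5, 20)), 7.5)
  expect_equal(compute_baseline(0:100, percentile = 35), 35.0)
  set.seed(42)
  for (i in 1:25) {
    x <- rnorm(sample(5:200, 1), mean = 100, sd = 20)
    p <- runif(1, 5, 95)
    expect_equal(compute_baseline(x, p), oracle_percentile(x, p))
  }
  b <- compute_baseline(c(1, 2, 3, 4), 35)
  expect_gte(b, 1); expect_lte(b, 4)
  expect_equal(b, oracle_percentile(c(1, 2, 3, 4), 35))
  expect_error(compute_baseline(c(1, NA, 3)), "frame 2")
  expect_error(compute_baseline(1:10, percentile = 0), "between")
})

test_that("dff conversion is the elementwise ratiometric formula", {
  f0 <- 50
  expect_equal(compute_dff(rep(f0, 10), f0)$values, rep(0, 10))
  x <- rep(f0, 10); x[4] <- 2 * f0
  expect_equal(compute_dff(x, f0)$values[4], 1.0)
  ramp <- seq(10, 200, length.out = 37)
  expect_equal(compute_dff(ramp, 40)$values, (ramp - 40) / 40)
  expect_error(compute_dff(ramp, 0), "positive")
  expect_error(compute_dff(ramp, -3), "positive")
})

test_that("noise SD estimators are calibrated on pure Gaussian noise", {
  set.seed(7)
  x <- 100 * (1 + rnorm(20000, 0, 0.2))
  for (est in c("lower_half", "mad", "full")) {
    d <- compute_dff(x, 100, estimator = est)
    expect_equal(d$noise_sd, 0.2, tolerance = 0.03)
  }
})

test_that("transient power follows the mean-squared-amplitude formula", {
  expect_equal(transient_power(rep(3, 8)), 9)
  expect_equal(transient_power(rep(0, 5)), 0)
  expect_equal(transient_power(c(1, 2, 3)), 14 / 3)
  expect_error(transient_power(numeric(0)), "empty")
  set.seed(1)
  for (i in 1:30) {
    x <- rnorm(sample(1:50, 1)); cc <- runif(1, 0.1, 10)
    expect_equal(transient_power(x), oracle_power(x))
    expect_equal(transient_power(cc * x), cc^2 * transient_power(x))
  }
})

test_that("pearson and cosine correlations match their printed equations", {
  x <- c(1, 2, 3)
  expect_equal(pearson_correlation(x, x), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_error(pearson_correlation(x, rep(2, 3)), "constant")

  expect_equal(cosine_correlation(x, x), 1)
  expect_equal(cosine_correlation(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_correlation(c(1, 2), c(2, 1)), 0.8)
  expect_error(cosine_correlation(x, rep(0, 3)), "zero-norm")

  set.seed(11)
  for (i in 1:50) {
    a <- rnorm(sample(3:100, 1)); b <- rnorm(length(a))
    expect_equal(pearson_correlation(a, b), oracle_pearson(a, b))
    expect_equal(cosine_correlation(a, b), oracle_cosine(a, b))
    expect_lte(abs(cosine_correlation(a, b)), 1)
    # positive rescaling leaves the cosine unchanged
    expect_equal(cosine_correlation(a, b), cosine_correlation(3.7 * a, b))
    # centered inputs collapse the two definitions
    a0 <- a - mean(a); b0 <- b - mean(b)
    expect_equal(cosine_correlation(a0, b0), pearson_correlation(a0, b0),
                 tolerance = 1e-12)
  }
})

test_that("transient detection finds rectangular pulses at their edges", {
  z <- make_dff(rep(0, 100), noise_sd = 0.1)
  expect_equal(nrow(detect_transients(z)), 0)

  v <- rep(0, 100); v[40:44] <- 1.0   # 10 x noise SD
  ev <- detect_transients(make_dff(v, 0.1))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset_frame, 40)
  expect_equal(ev$offset_frame, 45)
  expect_equal(ev$peak, 1.0)
  expect_equal(ev$power, transient_power(v[40:44]))

  # translation covariance: shifting the trace shifts onsets identically
  v2 <- c(rep(0, 17), v)[1:100]
  ev2 <- detect_transients(make_dff(v2, 0.1))
  expect_equal(ev2$onset_frame, ev$onset_frame + 17)

  expect_error(detect_transients(make_dff(v, 0)), "noise SD")
  expect_error(detect_transients(z, sd_multiplier = 1, offset_multiplier = 2),
               "offset_multiplier")
})

test_that("detection recovers injected well-separated events", {
  cfg <- trace_sim_config(n_rois = 1, shared_rate = 0, private_rate = 0.02,
                          min_event_gap = 10, noise_sd = 0.05, seed = 91)
  sim <- simulate_traces(cfg)
  tr <- sim$traces[[1]]
  dff <- compute_dff(tr, compute_baseline(tr))
  ev <- detect_transients(dff, min_duration_frames = 3)
  truth_frames <- floor(sim$truth$event_times[[1]] / cfg$frame_interval) + 1
  expect_equal(nrow(ev), length(truth_frames))
  expect_true(all(abs(ev$onset_frame - truth_frames) <= 1))
  # events are disjoint and ordered
  expect_true(all(diff(ev$onset_frame) > 0))
  expect_true(all(ev$offset_frame > ev$onset_frame))
  expect_true(all(ev$peak > 2 * dff$noise_sd))
})

test_that("transient frequency is count over duration", {
  expect_equal(transient_frequency(data.frame()[0, ], 300), 0)
  expect_equal(transient_frequency(6, 300), 0.02)
  expect_error(transient_frequency(6, 0), "positive")
})

test_that("pairwise synchrony covers all pairs and flags undefined ones", {
  x <- abs(rnorm(100)) + 0.1
  s <- pairwise_synchrony(list(x, x, x))
  expect_true(all(s$matrix == 1))
  expect_equal(s$mean, 1)

  s3 <- pairwise_synchrony(list(rnorm(50), rnorm(50), rnorm(50)))
  expect_equal(sum(upper.tri(s3$matrix)), 3)   # 3 unique pairs
  expect_true(isSymmetric(s3$matrix))
  expect_true(all(abs(s3$matrix) <= 1))

  # null level: independent noise stays near zero
  set.seed(5)
  noise <- lapply(1:10, function(i) rnorm(558))
  expect_lt(abs(pairwise_synchrony(noise)$mean), 0.1)

  # zero-norm member: pair recorded as missing, excluded from the mean
  sz <- pairwise_synchrony(list(c(1, 2, 1), c(0, 0, 0), c(2, 1, 2)))
  expect_equal(sz$n_undefined, 2)
  expect_false(is.na(sz$mean))
  expect_error(pairwise_synchrony(list(rnorm(5))), "at least 2")
})

test_that("session standardization maps the pre-session to 1", {
  out <- standardize_to_pre(c(Pre = 0.4, POD2 = 0.2))
  expect_equal(out$standardized, c(1.0, 0.5))
  out2 <- standardize_to_pre(c(Pre = 0.3, POD2 = 0.3, POD7 = 0.3))
  expect_equal(out2$standardized, c(1, 1, 1))
  expect_equal(standardize_to_pre(c(Pre = 0.7))$standardized, 1)
  expect_error(standardize_to_pre(c(Pre = 0, POD2 = 0.1)), "zero")
  expect_error(standardize_to_pre(c(POD2 = 0.1)), "not present")
  d <- standardize_to_pre(c(Pre = 0.4, POD2 = 0.2), mode = "difference")
  expect_equal(d$standardized, c(0, -0.2))
})
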