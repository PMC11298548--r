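test_that("trace generator honours its degenerate closed forms", {
  # shared events only, no noise: every ROI is frame-identical
  cfg <- trace_sim_config(n_rois = 4, shared_rate = 0.1, private_rate = 0,
                          noise_sd = 0, seed = 3)
  sim <- simulate_traces(cfg)
  for (r in 2:4)
    expect_identical(sim$traces[[r]]$values, sim$traces[[1]]$values)
  expect_equal(sim$truth$synchrony_fraction, 1)

  # no events, no noise: flat at the baseline level
  cfg0 <- trace_sim_config(n_rois = 2, shared_rate = 0, private_rate = 0,
                           noise_sd = 0, baseline_level = 120, seed = 3)
  sim0 <- simulate_traces(cfg0)
  expect_equal(sim0$traces[[1]]$values, rep(120, cfg0$n_frames))
  expect_true(is.na(sim0$truth$synchrony_fraction))

  # session length matches the configured frame count
  expect_length(sim$traces[[1]]$values, 558)
})

test_that("trace generator is deterministic and validates parameters", {
  cfg <- trace_sim_config(n_rois = 3, seed = 77)
  a <- simulate_traces(cfg)
  b <- simulate_traces(cfg)
  expect_identical(a, b)
  c_ <- simulate_traces(trace_sim_config(n_rois = 3, seed = 78))
  expect_false(identical(a$traces[[1]]$values, c_$traces[[1]]$values))

  expect_error(trace_sim_config(noise_sd = -1), "noise_sd")
  expect_error(trace_sim_config(noise_sd = NaN), "noise_sd")
  expect_error(trace_sim_config(amplitude = -2), "amplitude")
  expect_error(trace_sim_config(decay_tau = 0), "decay_tau")
  expect_error(trace_sim_config(n_frames = 1), "n_frames")
  expect_error(trace_sim_config(private_rate = 0.2, min_event_gap = 10),
               "min_event_gap")
})

test_that("renewal event trains respect the dead time and nominal rate", {
  cfg <- trace_sim_config(n_rois = 40, shared_rate = 0, private_rate = 0.05,
                          min_event_gap = 8, noise_sd = 0, seed = 5)
  sim <- simulate_traces(cfg)
  gaps <- unlist(lapply(sim$truth$event_times, diff))
  expect_true(all(gaps >= 8))
  n_events <- sum(lengths(sim$truth$event_times))
  duration <- cfg$n_frames * cfg$frame_interval * cfg$n_rois
  expect_equal(n_events / duration, 0.05, tolerance = 0.15)
})

test_that("stack metadata reproduces the acquisition pixel size", {
  cfg <- stack_sim_config(field_size = 264.90, resolution = 512)
  expect_equal(cfg$field_size / cfg$resolution, 264.90 / 512)
  st <- simulate_stack(stack_sim_config(resolution = 128, n_frames = 2,
                                        n_cells = 2, axon_count = 1,
                                        n_processes_per_cell = 0,
                                        process_length = 5, seed = 1))
  expect_equal(st$stack$pixel_size_um, 264.90 / 128)
})

test_that("rendered somas form the configured number of components", {
  st <- simulate_stack(stack_sim_config(n_cells = 10, snr = Inf, n_frames = 2,
                                        seed = 21))
  expect_equal(count_components8(st$truth$soma_mask), 10)
  # noise-free channel 1 at a frame: somas are exactly the bright pixels
  frame <- st$stack$ch1[, , 1]
  expect_equal(unname(frame[st$truth$soma_mask][1] > 0), TRUE)
})

test_that("rendered overlap matches the requested fraction up to pixelation", {
  for (target in c(0.05, 0.2, 0.5)) {
    st <- simulate_stack(stack_sim_config(resolution = 256, n_frames = 2,
                                          n_cells = 4,
                                          overlap_fraction_target = target,
                                          seed = 31))
    expect_equal(st$truth$true_overlap_fraction, target, tolerance = 0.02)
    got <- sum(st$truth$microglia_mask & st$truth$axon_mask) /
      sum(st$truth$axon_mask)
    expect_equal(got, st$truth$true_overlap_fraction)
  }
})

test_that("stack generator is deterministic under a fixed seed", {
  cfg <- stack_sim_config(resolution = 96, n_frames = 3, n_cells = 2,
                          process_length = 6, seed = 9)
  a <- simulate_stack(cfg)
  b <- simulate_stack(cfg)
  expect_identical(a$stack$ch1, b$stack$ch1)
  expect_identical(a$truth$process_angles, b$truth$process_angles)
})

test_that("von Mises sampler hits its stated mean and limits", {
  set.seed(2)
  a <- rvonmises_deg(1000, 45, 2)
  expect_true(all(a >= 0 & a < 360))
  rad <- a * pi / 180
  circ_mean <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  expect_lt(abs(circ_mean - 45), 5)

  # kappa = 0 is uniform on the circle
  set.seed(3)
  u <- rvonmises_deg(2000, 10, 0)
  expect_gt(stats::ks.test(u / 360, "punif")$p.value, 0.01)

  # large kappa degenerates onto the mean direction
  set.seed(4)
  tight <- rvonmises_deg(500, 90, 500)
  expect_lt(stats::sd(tight), 3)
  expect_error(rvonmises_deg(5, 0, -1), "kappa")
})

test_that("grouped angle samples are labelled, bounded and reproducible", {
  specs <- list(sham = list(n = 40, mean_direction = 10, kappa = 1),
                sci = list(n = 25, mean_direction = 80, kappa = 3))
  a <- simulate_angle_samples(specs, seed = 6)
  b <- simulate_angle_samples(specs, seed = 6)
  expect_identical(a, b)
  expect_equal(table(a$group)[["sham"]], 40)
  expect_equal(table(a$group)[["sci"]], 25)
  expect_true(all(a$angle_deg >= 0 & a$angle_deg < 360))
  expect_error(simulate_angle_samples(list(list(n = 1, mean_direction = 0,
                                                kappa = 1))), "n >= 2")
})

test_that("tip tracks drift along their process directions", {
  st <- simulate_stack(stack_sim_config(resolution = 256, n_frames = 2,
                                        n_cells = 3, process_kappa = 50,
                                        seed = 41))
  tracks <- simulate_tracks(st$truth, tip_jitter_sd = 0.05, seed = 8)
  expect_identical(simulate_tracks(st$truth, tip_jitter_sd = 0.05, seed = 8),
                   tracks)
  expect_named(tracks, c("track_id", "t_min", "x_um", "y_um"))
  one <- tracks[tracks$track_id == "track_1", ]
  drift <- c(one$x_um[nrow(one)] - one$x_um[1],
             one$y_um[nrow(one)] - one$y_um[1])
  ang <- (atan2(drift[2], drift[1]) * 180 / pi) %% 360
  diff_deg <- abs(((ang - st$truth$process_angles[1]) + 180) %% 360 - 180)
  expect_lt(diff_deg, 20)
})
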