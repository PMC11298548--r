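test_that("SD projection equals the per-pixel population SD", {
  # identical frames: zero everywhere
  frames <- replicate(5, matrix(runif(64), 8, 8), simplify = FALSE)
  frames <- lapply(frames, function(f) frames[[1]])
  expect_true(all(sd_projection(frames)$pixels == 0))

  # alternating 0/2 has population SD exactly 1
  alt <- lapply(1:6, function(i) matrix(if (i %% 2) 0 else 2, 4, 4))
  expect_equal(sd_projection(alt)$pixels, matrix(1, 4, 4))

  # random stack vs direct per-pixel computation (divisor N)
  set.seed(13)
  arr <- array(rnorm(6 * 7 * 9), c(6, 7, 9))
  want <- apply(arr, c(1, 2), function(v) sqrt(mean((v - mean(v))^2)))
  expect_equal(sd_projection(arr)$pixels, want)

  expect_error(sd_projection(arr[, , 1, drop = FALSE]), "2 frames")
})

test_that("half-maximum growth recovers a uniform disc exactly", {
  img <- matrix(0, 60, 60)
  disc <- render_ellipse_mask(12, 12)          # 33 x 33
  img[14:(13 + nrow(disc)), 14:(13 + ncol(disc))][disc] <- 100
  regs <- extract_cell_bodies(img, seed_min_intensity = 50,
                              min_seed_separation_px = 10)
  expect_length(regs, 1)
  expect_false(regs[[1]]$excluded)
  got <- matrix(FALSE, 60, 60); got[regs[[1]]$pixel_idx] <- TRUE
  expect_equal(sum(got), sum(disc))
  expect_true(all(which(got) == which(img == 100)))
})

test_that("merged half-max regions are excluded as indistinguishable", {
  img <- matrix(0, 80, 120)
  disc <- render_ellipse_mask(10, 10)
  # two discs joined by a bright bridge: half-max regions merge
  img[30:(29 + nrow(disc)), 20:(19 + ncol(disc))][disc] <- 100
  img[30:(29 + nrow(disc)), 70:(69 + ncol(disc))][disc] <- 100
  img[39:41, 20:97] <- pmax(img[39:41, 20:97], 80)
  regs <- extract_cell_bodies(img, seed_min_intensity = 50,
                              min_seed_separation_px = 20)
  expect_gte(length(regs), 2)
  expect_true(all(vapply(regs, `[[`, TRUE, "excluded")))
  expect_true(all(vapply(regs, `[[`, "", "reason") ==
                    "indistinguishable neighbors"))
  # the two disc seeds grew into one and the same merged region
  disc_regs <- Filter(function(r) r$seed_intensity == 100, regs)
  expect_length(disc_regs, 2)
  expect_identical(disc_regs[[1]]$pixel_idx, disc_regs[[2]]$pixel_idx)
})

test_that("border-touching regions are excluded", {
  img <- matrix(0, 40, 40)
  disc <- render_ellipse_mask(8, 8)
  half <- disc[(nrow(disc) %/% 2):nrow(disc), ]   # truncated at the border
  img[1:nrow(half), 10:(9 + ncol(half))][half] <- 100
  regs <- extract_cell_bodies(img, seed_min_intensity = 50,
                              min_seed_separation_px = 10)
  expect_true(any(vapply(regs, function(r)
    isTRUE(r$excluded) && r$reason == "touches field border", TRUE)))
})

test_that("ellipse metrics match analytic values for rendered shapes", {
  disc <- render_ellipse_mask(20, 20)
  md <- ellipse_metrics(disc)
  expect_equal(md$aspect_ratio, 1, tolerance = 0.02)
  expect_gte(md$circularity, 0.95)
  expect_equal(md$roundness, 1, tolerance = 0.02)

  ell <- render_ellipse_mask(20, 10)
  me <- ellipse_metrics(ell, pixel_size_um = 0.5)
  expect_equal(me$aspect_ratio, 2, tolerance = 0.05)
  expect_equal(me$roundness, 0.5, tolerance = 0.05)
  expect_equal(me$area_um2, pi * 20 * 10 * 0.5^2, tolerance = 0.05)
  expect_equal(me$major_um, 40 * 0.5, tolerance = 0.05)

  # rotation leaves the shape descriptors within 3%
  rot <- ellipse_metrics(render_ellipse_mask(20, 10, orientation_deg = 30))
  for (m in c("aspect_ratio", "circularity", "roundness"))
    expect_equal(rot[[m]], me[[m]], tolerance = 0.03)
  expect_equal(rot$orientation_deg, 30, tolerance = 2)

  # doubling the scale: dimensionless metrics stable, pixel area x4
  big <- ellipse_metrics(render_ellipse_mask(40, 20))
  for (m in c("aspect_ratio", "roundness"))
    expect_equal(big[[m]], me[[m]], tolerance = 0.03)
  expect_equal(big$area_um2 / ellipse_metrics(ell)$area_um2, 4,
               tolerance = 0.03)

  line <- matrix(FALSE, 10, 10); line[5, 3:8] <- TRUE
  expect_error(ellipse_metrics(line), "degenerate")
  expect_error(ellipse_metrics(matrix(c(TRUE, rep(FALSE, 24)), 5, 5)),
               "4 pixels")
})

test_that("generator soma axes are recovered from the noisy stack", {
  cfg <- stack_sim_config(n_cells = 6, snr = 10, seed = 3)
  st <- simulate_stack(cfg)
  proj <- sd_projection(st$stack, channel = 1)
  thr <- (median(proj$pixels) + max(proj$pixels)) / 2
  regs <- extract_cell_bodies(proj, seed_min_intensity = thr)
  inc <- regs[!vapply(regs, `[[`, TRUE, "excluded")]
  expect_length(inc, 6)
  mets <- do.call(rbind, lapply(inc, ellipse_metrics,
                                pixel_size_um = proj$pixel_size_um))
  expect_true(all(abs(mets$major_um - cfg$soma_major) / cfg$soma_major < 0.05))
  expect_true(all(abs(mets$minor_um - cfg$soma_minor) / cfg$soma_minor < 0.05))
})

test_that("cell density counts included regions per field and per mm2", {
  mk <- function(excluded) structure(list(excluded = excluded),
                                     class = "cell_body_region")
  expect_equal(cell_density(list(), 264.9)$per_mm2, 0)
  regs <- c(replicate(10, mk(FALSE), simplify = FALSE),
            replicate(3, mk(TRUE), simplify = FALSE))
  d <- cell_density(regs, 264.9)
  expect_equal(d$count, 10)
  expect_equal(d$per_field, 10)
  expect_equal(d$per_mm2, 10 / 0.2649^2, tolerance = 1e-6)
  expect_error(cell_density(regs, 0), "field_size")
})
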