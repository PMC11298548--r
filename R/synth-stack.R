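#' Configuration for the two-channel stack generator
#'
#' Geometry defaults follow the emulated spinal-cord acquisition: a
#' 264.90 um square field at 512 x 512 pixels (pixel size 0.517 um),
#' 90 frames at 2 min per frame (3 h). Channel 1 holds microglia (somas
#' rendered as filled ellipses plus straight processes), channel 2 holds
#' straight axon bands at a common orientation; process directions
#' concentrate around the axon orientation with von Mises concentration
#' `process_kappa`.
#'
#' Per-pixel Gaussian noise has SD `soma_intensity/snr` (channel 1) and
#' `axon_intensity/snr` (channel 2). Each frame additionally carries a
#' per-channel multiplicative brightness modulation with SD `fluct_sd`,
#' which gives the temporal-SD projection structural contrast for these
#' otherwise static scenes (in vivo, motile processes play that role).
#'
#' @param field_size Field edge length, um.
#' @param resolution Pixels per side (> 0).
#' @param n_frames Frames in the time-lapse (>= 2).
#' @param frame_interval Minutes per frame.
#' @param n_cells Number of microglial somas.
#' @param soma_major,soma_minor Full ellipse axes of somas, um
#'   (`soma_major >= soma_minor > 0`).
#' @param n_processes_per_cell Processes per soma (>= 0).
#' @param process_length,process_width Process segment length and width, um.
#' @param axon_orientation Axon direction, degrees CCW from +x
#'   (image convention, +y down).
#' @param process_kappa von Mises concentration of process directions
#'   around `axon_orientation` (>= 0; 0 = uniform).
#' @param axon_count Number of parallel axon bands.
#' @param axon_width Axon band width, um.
#' @param overlap_fraction_target Desired fraction of axon-mask pixels also
#'   covered by microglia, in `[0, 1]`. The generator calibrates the
#'   microglia mask (adding or carving process pixels along the axons) so
#'   the rendered-mask overlap hits this target up to pixelation.
#' @param snr Peak-intensity-to-noise-SD ratio (> 0); `Inf` for noise-free.
#' @param fluct_sd SD of the per-frame brightness modulation (>= 0).
#' @param soma_intensity,process_intensity,axon_intensity Rendered
#'   intensities (arbitrary units). Keeping `process_intensity` below half
#'   of `soma_intensity` lets half-maximum soma extraction stop at process
#'   roots; setting it equal gives a cleanly bimodal channel for
#'   threshold-based colocalization.
#' @param seed Integer seed.
#' @return A `stack_sim_config` list.
#' @export
stack_sim_config <- function(field_size = 264.90, resolution = 512,
                             n_frames = 90, frame_interval = 2,
                             n_cells = 10, soma_major = 12, soma_minor = 7,
                             n_processes_per_cell = 4,
                             process_length = 15, process_width = 1.5,
                             axon_orientation = 30, process_kappa = 8,
                             axon_count = 4, axon_width = 2,
                             overlap_fraction_target = 0.2,
                             snr = 10, fluct_sd = 0.3,
                             soma_intensity = 1, process_intensity = 0.35,
                             axon_intensity = 1,
                             seed = 1L) {
  cfg <- as.list(environment())
  cfg$resolution <- as.integer(resolution)
  cfg$n_frames <- as.integer(n_frames)
  cfg$n_cells <- as.integer(n_cells)
  cfg$n_processes_per_cell <- as.integer(n_processes_per_cell)
  cfg$axon_count <- as.integer(axon_count)
  cfg$seed <- as.integer(seed)
  validate_stack_sim_config(cfg)
  structure(cfg, class = "stack_sim_config")
}

validate_stack_sim_config <- function(cfg) {
  with(cfg, {
    if (resolution <= 0L) stop("resolution must be > 0", call. = FALSE)
    if (field_size <= 0) stop("field_size must be > 0", call. = FALSE)
    if (n_frames < 2L) stop("n_frames must be >= 2", call. = FALSE)
    if (!(soma_major >= soma_minor && soma_minor > 0))
      stop("need soma_major >= soma_minor > 0", call. = FALSE)
    if (process_kappa < 0) stop("process_kappa must be >= 0", call. = FALSE)
    if (overlap_fraction_target < 0 || overlap_fraction_target > 1)
      stop("overlap_fraction_target must be in [0, 1]", call. = FALSE)
    if (snr <= 0) stop("snr must be > 0", call. = FALSE)
    if (fluct_sd < 0) stop("fluct_sd must be >= 0", call. = FALSE)
  })
  invisible(cfg)
}

#' Render a filled ellipse as a pixel mask
#'
#' A pixel belongs to the mask when its center lies inside the ellipse.
#' Exposed because digitized ellipses/discs are the reference shapes for
#' morphometry validation.
#'
#' @param semi_major,semi_minor Semi-axes in pixels.
#' @param orientation_deg Major-axis direction, degrees CCW from +x.
#' @param pad Background margin in pixels around the shape.
#' @return A logical matrix (rows = y, columns = x).
#' @export
render_ellipse_mask <- function(semi_major, semi_minor, orientation_deg = 0,
                                pad = 4) {
  n <- ceiling(2 * max(semi_major, semi_minor)) + 2 * pad
  ctr <- (n + 1) / 2
  xs <- matrix(rep(seq_len(n), each = n), n, n)   # column index = x
  ys <- matrix(rep(seq_len(n), times = n), n, n)  # row index = y
  th <- orientation_deg * pi / 180
  dx <- xs - ctr; dy <- ys - ctr
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  (u / semi_major)^2 + (v / semi_minor)^2 <= 1
}

# paint an ellipse into a logical field mask; center (cx, cy) and axes in px
paint_ellipse <- function(mask, cx, cy, a, b, theta_deg) {
  n <- nrow(mask)
  r <- ceiling(max(a, b)) + 1L
  x0 <- max(1L, floor(cx - r)); x1 <- min(n, ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(n, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(mask)
  xs <- x0:x1; ys <- y0:y1
  th <- theta_deg * pi / 180
  dx <- matrix(rep(xs - cx, each = length(ys)), length(ys))
  dy <- matrix(rep(ys - cy, times = length(xs)), length(ys))
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  hit <- (u / a)^2 + (v / b)^2 <= 1
  mask[ys, xs] <- mask[ys, xs] | hit
  mask
}

# paint a thick segment from (x0,y0) along direction theta (deg) of given
# length/width (px)
paint_segment <- function(mask, x0, y0, theta_deg, length_px, width_px) {
  n <- nrow(mask)
  th <- theta_deg * pi / 180
  ux <- cos(th); uy <- sin(th)
  xe <- x0 + length_px * ux; ye <- y0 + length_px * uy
  half <- width_px / 2
  bx0 <- max(1L, floor(min(x0, xe) - half - 1)); bx1 <- min(n, ceiling(max(x0, xe) + half + 1))
  by0 <- max(1L, floor(min(y0, ye) - half - 1)); by1 <- min(n, ceiling(max(y0, ye) + half + 1))
  if (bx0 > bx1 || by0 > by1) return(mask)
  xs <- bx0:bx1; ys <- by0:by1
  dx <- matrix(rep(xs - x0, each = length(ys)), length(ys))
  dy <- matrix(rep(ys - y0, times = length(xs)), length(ys))
  t_ <- dx * ux + dy * uy          # along-segment coordinate
  d_ <- abs(-dx * uy + dy * ux)    # perpendicular distance
  hit <- t_ >= 0 & t_ <= length_px & d_ <= half
  mask[ys, xs] <- mask[ys, xs] | hit
  mask
}

# boundary radius of an ellipse along direction phi (relative to major axis)
ellipse_radius_at <- function(a, b, phi) {
  (a * b) / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
}

#' Simulate a two-channel microglia/axon time-lapse stack
#'
#' Renders ground-truth masks (axon bands; elliptical somas with straight
#' processes), calibrates the microglia/axon overlap to
#' `overlap_fraction_target`, then emits noisy frames for both channels.
#' Identical configs and seeds reproduce bit-identical output.
#'
#' @param config A [stack_sim_config()].
#' @param max_place_tries Bounded retries per soma placement before erroring.
#' @return A list with `stack` (class `two_channel_stack`: arrays `ch1`,
#'   `ch2` of dim `resolution x resolution x n_frames`, plus `pixel_size_um`
#'   and `frame_interval_min`) and `truth` (class `synth_truth`): soma
#'   centers/axes/orientations (um and degrees), per-process angles (degrees
#'   in `[0, 360)`), `axon_orientation`, achieved `true_overlap_fraction`,
#'   and the ground-truth pixel masks (`soma_mask`, `microglia_mask`,
#'   `axon_mask`).
#' @export
simulate_stack <- function(config, max_place_tries = 200L) {
  stopifnot(inherits(config, "stack_sim_config"))
  validate_stack_sim_config(config)
  list2env(unclass(config), environment())
  px <- field_size / resolution
  n <- resolution
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  ## channel 2 ground truth: parallel axon bands
  th <- axon_orientation * pi / 180
  ux <- cos(th); uy <- sin(th)            # along-axon unit vector
  nx <- -uy; ny <- ux                     # perpendicular
  axon_mask <- matrix(FALSE, n, n)
  xs <- matrix(rep(seq_len(n), each = n), n, n)
  ys <- matrix(rep(seq_len(n), times = n), n, n)
  ctr <- (n + 1) / 2
  perp <- (xs - ctr) * nx + (ys - ctr) * ny   # signed perpendicular offset, px
  if (axon_count > 0) {
    offsets <- (seq_len(axon_count) / (axon_count + 1) - 0.5) * n
    half_w <- (axon_width / px) / 2
    for (o in offsets) axon_mask <- axon_mask | (abs(perp - o) <= half_w)
  }

  ## channel 1 ground truth: somas + processes
  a_px <- (soma_major / 2) / px
  b_px <- (soma_minor / 2) / px
  margin <- a_px + (process_length / px) + 2
  min_sep <- 3.5 * a_px   # keeps each soma's half-max region and seed isolated
  centers <- matrix(numeric(0), 0, 2)
  for (k in seq_len(n_cells)) {
    placed <- FALSE
    for (try in seq_len(max_place_tries)) {
      cand <- stats::runif(2, min = margin, max = n - margin)
      if (!nrow(centers) ||
          min(sqrt(rowSums((centers - matrix(cand, nrow(centers), 2,
                                             byrow = TRUE))^2))) >= min_sep) {
        centers <- rbind(centers, cand); placed <- TRUE; break
      }
    }
    if (!placed)
      stop("could not place somas inside the field; reduce n_cells or soma size",
           call. = FALSE)
  }
  soma_theta <- stats::runif(n_cells, 0, 180)
  soma_mask <- matrix(FALSE, n, n)
  for (k in seq_len(n_cells))
    soma_mask <- paint_ellipse(soma_mask, centers[k, 1], centers[k, 2],
                               a_px, b_px, soma_theta[k])

  process_mask <- matrix(FALSE, n, n)
  process_angles <- numeric(0)
  process_base <- matrix(numeric(0), 0, 2)
  if (n_processes_per_cell > 0) {
    for (k in seq_len(n_cells)) {
      ang <- rvonmises_deg(n_processes_per_cell, axon_orientation,
                           process_kappa)
      for (a_deg in ang) {
        phi <- (a_deg - soma_theta[k]) * pi / 180
        r0 <- ellipse_radius_at(a_px, b_px, phi)
        bx <- centers[k, 1] + r0 * cos(a_deg * pi / 180)
        by <- centers[k, 2] + r0 * sin(a_deg * pi / 180)
        process_mask <- paint_segment(process_mask, bx, by, a_deg,
                                      process_length / px, process_width / px)
        process_angles <- c(process_angles, a_deg %% 360)
        process_base <- rbind(process_base, c(bx, by))
      }
    }
  }

  ## calibrate microglia-over-axon overlap to the target fraction
  microglia_mask <- soma_mask | process_mask
  axon_px_total <- sum(axon_mask)
  if (axon_px_total > 0) {
    target <- round(overlap_fraction_target * axon_px_total)
    overlap_idx <- which(microglia_mask & axon_mask)
    if (length(overlap_idx) < target) {
      # paint additional process-intensity microglia onto axon pixels,
      # filling contiguously along the axon direction
      cand <- which(axon_mask & !microglia_mask)
      along <- (xs[cand] - ctr) * ux + (ys[cand] - ctr) * uy
      o <- order(perp[cand], along)      # walk each band end-to-end
      add <- cand[o][seq_len(target - length(overlap_idx))]
      microglia_mask[add] <- TRUE
      process_mask[add] <- TRUE
    } else if (length(overlap_idx) > target) {
      # carve process pixels (never soma pixels) off the axons
      rem_pool <- overlap_idx[!soma_mask[overlap_idx]]
      nrem <- min(length(rem_pool), length(overlap_idx) - target)
      if (nrem > 0) {
        rem <- rem_pool[seq_len(nrem)]
        microglia_mask[rem] <- FALSE
        process_mask[rem] <- FALSE
      }
    }
  }
  true_overlap <- if (axon_px_total > 0)
    sum(microglia_mask & axon_mask) / axon_px_total else NA_real_

  ## render noisy frames
  base1 <- matrix(0, n, n)
  base1[process_mask] <- process_intensity
  base1[soma_mask] <- soma_intensity     # somas override process roots
  base2 <- matrix(0, n, n)
  base2[axon_mask] <- axon_intensity
  sd1 <- if (is.finite(snr)) soma_intensity / snr else 0
  sd2 <- if (is.finite(snr)) axon_intensity / snr else 0
  mod1 <- pmax(0.2, 1 + stats::rnorm(n_frames, 0, fluct_sd))
  mod2 <- pmax(0.2, 1 + stats::rnorm(n_frames, 0, fluct_sd))
  render_channel <- function(base, mod, sd_noise) {
    npx <- n * n
    ch <- if (sd_noise > 0) stats::rnorm(npx * n_frames, 0, sd_noise)
          else numeric(npx * n_frames)
    fg <- which(base > 0)                 # foreground is sparse
    for (f in seq_len(n_frames))
      ch[fg + (f - 1L) * npx] <- ch[fg + (f - 1L) * npx] + base[fg] * mod[f]
    array(ch, c(n, n, n_frames))
  }
  ch1 <- render_channel(base1, mod1, sd1)
  ch2 <- render_channel(base2, mod2, sd2)

  stack <- structure(list(ch1 = ch1, ch2 = ch2,
                          pixel_size_um = px,
                          frame_interval_min = frame_interval),
                     class = "two_channel_stack")
  truth <- structure(list(
    soma_centers_um = centers * px,
    soma_axes_um = c(major = soma_major, minor = soma_minor),
    soma_orientations_deg = soma_theta,
    process_angles = process_angles,
    process_base_um = process_base * px,
    axon_orientation = axon_orientation %% 360,
    true_overlap_fraction = true_overlap,
    soma_mask = soma_mask,
    microglia_mask = microglia_mask,
    axon_mask = axon_mask,
    config = config), class = "synth_truth")
  list(stack = stack, truth = truth)
}

#' @export
print.two_channel_stack <- function(x, ...) {
  d <- dim(x$ch1)
  cat(sprintf("<two_channel_stack: %d x %d px, %d frames, %.4g um/px, %.3g min/frame>\n",
              d[1], d[2], d[3], x$pixel_size_um, x$frame_interval_min))
  invisible(x)
}

#' Simulate microglial process-tip trajectories
#'
#' Each process tip starts at its base on the soma boundary and drifts
#' outward along the process direction at `tip_speed`, with isotropic
#' Gaussian positional jitter per time point. These trajectories feed the
#' moving-vector polarity analysis.
#'
#' @param truth A `synth_truth` from [simulate_stack()] (uses
#'   `process_angles` and `process_base_um`).
#' @param n_points Time points per track (>= 2).
#' @param frame_interval_min Minutes between points.
#' @param tip_speed Outward drift speed, um/min.
#' @param tip_jitter_sd Positional jitter SD, um.
#' @param seed Integer seed.
#' @return A data frame with columns `track_id`, `t_min`, `x_um`, `y_um`.
#' @export
simulate_tracks <- function(truth, n_points = 31, frame_interval_min = 2,
                            tip_speed = 0.1, tip_jitter_sd = 0.3, seed = 1L) {
  stopifnot(inherits(truth, "synth_truth"))
  if (!length(truth$process_angles))
    stop("truth contains no processes", call. = FALSE)
  if (n_points < 2L) stop("need at least 2 time points", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  tt <- (seq_len(n_points) - 1L) * frame_interval_min
  out <- lapply(seq_along(truth$process_angles), function(i) {
    th <- truth$process_angles[i] * pi / 180
    p0 <- truth$process_base_um[i, ]
    data.frame(track_id = sprintf("track_%d", i),
               t_min = tt,
               x_um = p0[1] + tip_speed * tt * cos(th) +
                 stats::rnorm(n_points, 0, tip_jitter_sd),
               y_um = p0[2] + tip_speed * tt * sin(th) +
                 stats::rnorm(n_points, 0, tip_jitter_sd),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
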