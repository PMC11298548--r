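#' Configuration for the calcium-trace generator
#'
#' Defaults describe the emulated recording: 558-frame sessions at 4 Hz
#' (frame_interval 0.25 s), a fast indicator with instantaneous rise and
#' single-exponential decay (decay_tau 2.5 s), unit event amplitude in
#' \eqn{\Delta F/F_0} and additive Gaussian noise at SNR 5
#' (noise_sd 0.2). Event trains are renewal processes whose mean interval is
#' exactly `1/rate`; `min_event_gap` inserts a dead time (keeping the rate
#' unbiased) so that events stay resolvable by threshold detection.
#'
#' The synchrony fraction `s = shared_rate/(shared_rate + private_rate)`
#' controls how much of each ROI's activity is driven by population-wide
#' shared events versus ROI-private events.
#'
#' @param n_rois Number of ROIs (>= 1).
#' @param n_frames Frames per session (>= 2).
#' @param frame_interval Seconds per frame (> 0).
#' @param shared_rate,private_rate Event rates in events/s (>= 0).
#' @param amplitude Event amplitude in \eqn{\Delta F/F_0} units (>= 0, finite).
#' @param decay_tau Exponential decay constant in seconds (> 0).
#' @param noise_sd Gaussian noise SD in \eqn{\Delta F/F_0} units (>= 0, finite).
#' @param baseline_level Baseline fluorescence in arbitrary units (> 0).
#' @param min_event_gap Dead time between consecutive events of one train,
#'   seconds (>= 0, and `< 1/rate` for any non-zero rate).
#' @param amplitude_jitter_sdlog SD of optional log-normal amplitude jitter
#'   (0 disables it; default 0).
#' @param seed Integer seed; all randomness in [simulate_traces()] flows
#'   from it.
#' @return A `trace_sim_config` list.
#' @export
trace_sim_config <- function(n_rois = 10, n_frames = 558,
                             frame_interval = 0.25,
                             shared_rate = 0.01, private_rate = 0.01,
                             amplitude = 1.0, decay_tau = 2.5,
                             noise_sd = 0.2, baseline_level = 100,
                             min_event_gap = 0,
                             amplitude_jitter_sdlog = 0,
                             seed = 1L) {
  cfg <- list(n_rois = as.integer(n_rois), n_frames = as.integer(n_frames),
              frame_interval = frame_interval, shared_rate = shared_rate,
              private_rate = private_rate, amplitude = amplitude,
              decay_tau = decay_tau, noise_sd = noise_sd,
              baseline_level = baseline_level, min_event_gap = min_event_gap,
              amplitude_jitter_sdlog = amplitude_jitter_sdlog,
              seed = as.integer(seed))
  validate_trace_sim_config(cfg)
  structure(cfg, class = "trace_sim_config")
}

validate_trace_sim_config <- function(cfg) {
  with(cfg, {
    if (n_rois < 1L) stop("n_rois must be >= 1", call. = FALSE)
    if (n_frames < 2L) stop("n_frames must be >= 2", call. = FALSE)
    if (!is.finite(frame_interval) || frame_interval <= 0)
      stop("frame_interval must be > 0", call. = FALSE)
    for (nm in c("shared_rate", "private_rate"))
      if (!is.finite(cfg[[nm]]) || cfg[[nm]] < 0)
        stop(sprintf("%s must be a finite non-negative rate", nm), call. = FALSE)
    if (!is.finite(decay_tau) || decay_tau <= 0)
      stop("decay_tau must be > 0", call. = FALSE)
    if (!is.finite(amplitude) || amplitude < 0)
      stop("amplitude must be finite and non-negative", call. = FALSE)
    if (!is.finite(noise_sd) || noise_sd < 0)
      stop("noise_sd must be finite and non-negative", call. = FALSE)
    if (!is.finite(baseline_level) || baseline_level <= 0)
      stop("baseline_level must be > 0", call. = FALSE)
    if (!is.finite(min_event_gap) || min_event_gap < 0)
      stop("min_event_gap must be >= 0", call. = FALSE)
    for (r in c(shared_rate, private_rate))
      if (r > 0 && min_event_gap >= 1 / r)
        stop("min_event_gap must be smaller than the mean event interval 1/rate",
             call. = FALSE)
  })
  invisible(cfg)
}

# renewal event train on [0, t_end): interval = gap + Exp(mean 1/rate - gap),
# so the mean interval is exactly 1/rate and events are >= gap apart
sample_event_times <- function(rate, t_end, gap = 0) {
  if (rate <= 0) return(numeric(0))
  times <- numeric(0)
  t <- 0
  exp_mean <- 1 / rate - gap
  repeat {
    t <- t + gap + stats::rexp(1L, rate = 1 / exp_mean)
    if (t >= t_end) break
    times <- c(times, t)
  }
  times
}

#' Simulate correlated calcium traces with known ground truth
#'
#' Each ROI's raw fluorescence is
#' `baseline_level * (1 + sum_events a * exp(-(t - t_e)/tau) + noise)`,
#' where the event train is the union of one shared train (identical timing
#' in every ROI) and one private train per ROI. Identical configs and seeds
#' reproduce bit-identical output.
#'
#' @param config A [trace_sim_config()].
#' @return A list with `traces` (list of [fluorescence_trace()]) and `truth`
#'   (class `synth_truth`): per-ROI event times (seconds), the shared event
#'   times, and the synchrony fraction.
#' @export
simulate_traces <- function(config) {
  stopifnot(inherits(config, "trace_sim_config"))
  validate_trace_sim_config(config)
  list2env(unclass(config), environment())
  t_end <- n_frames * frame_interval
  tt <- (seq_len(n_frames) - 1L) * frame_interval
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  shared <- sample_event_times(shared_rate, t_end, min_event_gap)
  traces <- vector("list", n_rois)
  event_times <- vector("list", n_rois)
  for (r in seq_len(n_rois)) {
    private <- sample_event_times(private_rate, t_end, min_event_gap)
    ev <- sort(c(shared, private))
    event_times[[r]] <- ev
    amps <- if (length(ev) && amplitude_jitter_sdlog > 0)
      amplitude * stats::rlnorm(length(ev), -amplitude_jitter_sdlog^2 / 2,
                                amplitude_jitter_sdlog)
    else rep(amplitude, length(ev))
    sig <- rep(0, n_frames)
    for (k in seq_along(ev)) {
      i <- tt >= ev[k]
      sig[i] <- sig[i] + amps[k] * exp(-(tt[i] - ev[k]) / decay_tau)
    }
    noise <- if (noise_sd > 0) stats::rnorm(n_frames, 0, noise_sd) else 0
    f <- baseline_level * (1 + sig + noise)
    traces[[r]] <- fluorescence_trace(f, frame_interval,
                                      roi_id = sprintf("roi_%d", r - 1L))
  }
  denom <- shared_rate + private_rate
  truth <- structure(list(
    event_times = event_times,
    shared_event_times = shared,
    synchrony_fraction = if (denom > 0) shared_rate / denom else NA_real_,
    config = config), class = "synth_truth")
  list(traces = traces, truth = truth)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
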