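#' Construct a fluorescence trace
#'
#' Bundles one region of interest's raw fluorescence time series with its
#' sampling interval. This is the substrate for all downstream calcium
#' analytics: baseline estimation, \eqn{\Delta F/F_0} conversion, transient
#' detection and pairwise synchrony.
#'
#' @param values Numeric vector of raw fluorescence (arbitrary units), one
#'   entry per frame. Must be finite and of length at least 2.
#' @param frame_interval Sampling interval in seconds (> 0).
#' @param roi_id Optional label for the ROI.
#' @return An object of class `fluorescence_trace`.
#' @export
fluorescence_trace <- function(values, frame_interval, roi_id = "roi") {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a fluorescence trace needs at least 2 frames", call. = FALSE)
  bad <- which(!is.finite(values))
  if (length(bad))
    stop(sprintf("non-finite fluorescence at frame %d (roi '%s')",
                 bad[1L], roi_id), call. = FALSE)
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      !is.finite(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be a positive scalar (seconds)", call. = FALSE)
  structure(list(values = values, frame_interval = frame_interval,
                 roi_id = as.character(roi_id)),
            class = "fluorescence_trace")
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf("<fluorescence_trace '%s': %d frames @ %.4g s>\n",
              x$roi_id, length(x$values), x$frame_interval))
  invisible(x)
}

#' Baseline fluorescence as an intensity-histogram percentile
#'
#' The baseline \eqn{F_0} is the 35th percentile (by default) of all frame
#' intensities recorded during the imaging period, computed with linear
#' interpolation between order statistics ([stats::quantile()] type 7).
#'
#' @param trace A `fluorescence_trace`, or a bare numeric vector.
#' @param percentile Percentile in (0, 100); default 35.
#' @return The baseline \eqn{F_0} in the trace's intensity units.
#' @export
compute_baseline <- function(trace, percentile = 35) {
  values <- if (inherits(trace, "fluorescence_trace")) trace$values
            else as.numeric(trace)
  bad <- which(!is.finite(values))
  if (length(bad))
    stop(sprintf("non-finite fluorescence at frame %d", bad[1L]), call. = FALSE)
  if (length(values) < 1L) stop("empty trace", call. = FALSE)
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must lie strictly between 0 and 100", call. = FALSE)
  stats::quantile(values, percentile / 100, names = FALSE, type = 7)
}

#' Convert a trace to \eqn{\Delta F/F_0}
#'
#' Computes `(F - F0)/F0` framewise and attaches a noise-SD estimate used by
#' [detect_transients()]. The default estimator takes the standard deviation
#' of the below-median residuals of \eqn{\Delta F/F_0} and rescales it by the
#' half-normal consistency factor \eqn{1/\sqrt{1 - 2/\pi}}, so that frames
#' carrying transients (which live in the upper tail) do not inflate the
#' noise estimate while the result still estimates the full noise SD.
#'
#' @param trace A `fluorescence_trace` or numeric vector.
#' @param f0 Baseline \eqn{F_0} (> 0), e.g. from [compute_baseline()].
#' @param estimator Noise-SD estimator: `"lower_half"` (default, rescaled
#'   below-median SD), `"mad"` (median absolute deviation, Gaussian-consistent)
#'   or `"full"` (plain SD of the whole \eqn{\Delta F/F_0} trace).
#' @return An object of class `dff_trace` with fields `values`, `baseline`,
#'   `noise_sd`, `frame_interval` and `roi_id`.
#' @export
compute_dff <- function(trace, f0,
                        estimator = c("lower_half", "mad", "full")) {
  estimator <- match.arg(estimator)
  if (!is.numeric(f0) || length(f0) != 1L || !is.finite(f0) || f0 <= 0)
    stop("F0 must be a positive scalar; trace unusable for ratiometric normalization",
         call. = FALSE)
  if (inherits(trace, "fluorescence_trace")) {
    values <- trace$values; fi <- trace$frame_interval; roi <- trace$roi_id
  } else {
    values <- as.numeric(trace); fi <- NA_real_; roi <- "roi"
  }
  dff <- (values - f0) / f0
  med <- stats::median(dff)
  noise_sd <- switch(estimator,
    lower_half = {
      resid <- dff[dff <= med] - med
      stats::sd(resid) / sqrt(1 - 2 / pi)
    },
    mad  = stats::mad(dff),
    full = stats::sd(dff))
  structure(list(values = dff, baseline = f0, noise_sd = noise_sd,
                 frame_interval = fi, roi_id = roi),
            class = "dff_trace")
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf("<dff_trace '%s': %d frames, F0 = %.4g, noise SD = %.4g>\n",
              x$roi_id, length(x$values), x$baseline, x$noise_sd))
  invisible(x)
}

#' Detect calcium transients
#'
#' A transient is a contiguous excursion of \eqn{\Delta F/F_0} above
#' `offset_multiplier * noise_sd` (relative to the trace median) that
#' contains at least `min_duration_frames` frames exceeding the detection
#' threshold `sd_multiplier * noise_sd`. The two-level (hysteresis) rule
#' keeps a slowly decaying transient in one piece while it hovers around
#' the detection threshold; setting `offset_multiplier = sd_multiplier`
#' recovers a plain runs-above-threshold rule.
#'
#' Events are disjoint, ordered, and reported with half-open frame bounds
#' `[onset, offset)`, the peak \eqn{\Delta F/F_0} and the mean-squared
#' amplitude (power) over the event, per [transient_power()].
#'
#' @param dff A `dff_trace` from [compute_dff()].
#' @param sd_multiplier Detection threshold in noise SDs above the trace
#'   median (default 2).
#' @param min_duration_frames Minimum number of frames above the detection
#'   threshold for an excursion to count as a transient (default 2).
#' @param offset_multiplier Event-boundary threshold in noise SDs (default
#'   0.5); must not exceed `sd_multiplier`.
#' @param bridge_frames Sub-threshold gaps of at most this many frames
#'   inside an excursion are bridged (default 2), so a single noisy dip
#'   does not split one transient in two.
#' @return A data frame with one row per event: `onset_frame`,
#'   `offset_frame` (1-based, half-open), `peak`, `power`.
#' @export
detect_transients <- function(dff, sd_multiplier = 2, min_duration_frames = 2,
                              offset_multiplier = 0.5, bridge_frames = 2) {
  stopifnot(inherits(dff, "dff_trace"))
  if (!is.finite(dff$noise_sd) || dff$noise_sd <= 0)
    stop("dff trace has non-positive noise SD; cannot threshold", call. = FALSE)
  if (offset_multiplier > sd_multiplier)
    stop("offset_multiplier must not exceed sd_multiplier", call. = FALSE)
  x <- dff$values
  centre <- stats::median(x)
  hi <- x > centre + sd_multiplier * dff$noise_sd
  lo <- x > centre + offset_multiplier * dff$noise_sd
  if (bridge_frames > 0) {            # debounce: ignore brief dips
    g <- rle(lo)
    ge <- cumsum(g$lengths); gs <- ge - g$lengths + 1L
    for (k in seq_along(g$values))
      if (!g$values[k] && g$lengths[k] <= bridge_frames &&
          k > 1L && k < length(g$values))
        lo[gs[k]:ge[k]] <- TRUE
  }
  runs <- rle(lo)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  out <- list()
  for (k in keep) {
    i0 <- starts[k]; i1 <- ends[k]
    if (sum(hi[i0:i1]) < min_duration_frames) next
    # the transient starts where the detection threshold is first exceeded;
    # the excursion end keeps the decay within the event
    i0h <- i0 - 1L + which(hi[i0:i1])[1L]
    seg <- x[i0h:i1]
    out[[length(out) + 1L]] <- data.frame(
      onset_frame = i0h, offset_frame = i1 + 1L,
      peak = max(seg), power = transient_power(seg))
  }
  if (!length(out))
    return(data.frame(onset_frame = integer(), offset_frame = integer(),
                      peak = numeric(), power = numeric()))
  do.call(rbind, out)
}

#' Transient frequency
#'
#' Number of detected transients divided by the imaging duration in seconds.
#'
#' @param events Event data frame from [detect_transients()] (or anything
#'   with `nrow()`), or a plain event count.
#' @param duration_s Imaging duration in seconds (> 0).
#' @return Events per second.
#' @export
transient_frequency <- function(events, duration_s) {
  if (!is.numeric(duration_s) || length(duration_s) != 1L ||
      !is.finite(duration_s) || duration_s <= 0)
    stop("duration_s must be a positive scalar", call. = FALSE)
  n <- if (is.data.frame(events)) nrow(events) else as.numeric(events)
  n / duration_s
}

#' Transient power (mean squared amplitude)
#'
#' For a transient segment \eqn{x_1,\dots,x_T} of \eqn{\Delta F/F_0} values,
#' the power is \eqn{p_x = \frac{1}{T}\sum_{i=1}^{T} x_i^2}.
#'
#' @param segment Numeric vector of \eqn{\Delta F/F_0} values (length >= 1).
#' @return The scalar power \eqn{p_x \ge 0}.
#' @export
transient_power <- function(segment) {
  segment <- as.numeric(segment)
  if (!length(segment)) stop("empty transient segment", call. = FALSE)
  mean(segment^2)
}

#' Pearson correlation of two activity vectors
#'
#' The usual centered, normalized inner product. Because a calcium trace is
#' near zero whenever a neuron is silent, centering turns long shared silences
#' into agreement, which inflates the correlation of sparsely active pairs;
#' [cosine_correlation()] avoids this by not centering.
#'
#' @param x,y Equal-length numeric vectors (length >= 2), neither constant.
#' @return \eqn{r_p \in [-1, 1]}.
#' @export
pearson_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("vectors must have equal length", call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  dx <- x - mean(x); dy <- y - mean(y)
  nx <- sqrt(sum(dx^2)); ny <- sqrt(sum(dy^2))
  if (nx == 0 || ny == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  r <- sum(dx * dy) / (nx * ny)
  min(1, max(-1, r))
}

#' Cosine (non-centered) correlation of two activity vectors
#'
#' \deqn{r_c = \frac{\sum_i x_i y_i}{\sqrt{\sum_i x_i^2}\,\sqrt{\sum_i y_i^2}}}
#' i.e. the cosine of the angle between the two vectors. \eqn{r_c} is large
#' when the neurons fire together, near zero when either is silent, and can
#' go negative only through noise or oscillatory components.
#'
#' @param x,y Equal-length numeric vectors (length >= 1) with non-zero norm.
#' @return \eqn{r_c \in [-1, 1]}.
#' @export
cosine_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("vectors must have equal length", call. = FALSE)
  if (!length(x)) stop("need at least 1 sample", call. = FALSE)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0)
    stop("correlation undefined for a zero-norm vector", call. = FALSE)
  r <- sum(x * y) / (nx * ny)
  min(1, max(-1, r))
}

#' Pairwise synchrony matrix
#'
#' Computes the correlation between every unordered pair of
#' \eqn{\Delta F/F_0} traces. Pairs whose correlation is undefined (zero-norm
#' or constant member) are recorded as `NA`, excluded from the mean, and
#' counted in the result.
#'
#' @param traces A list of `dff_trace` objects (or plain numeric vectors),
#'   all of equal length; at least 2.
#' @param kind `"cosine"` (default) or `"pearson"`.
#' @return An object of class `synchrony_matrix`: list with the symmetric
#'   `matrix` (unit diagonal where defined), `kind`, `mean` over defined
#'   off-diagonal pairs, and `n_undefined` pair count.
#' @export
pairwise_synchrony <- function(traces, kind = c("cosine", "pearson")) {
  kind <- match.arg(kind)
  vals <- lapply(traces, function(t)
    if (inherits(t, "dff_trace")) t$values else as.numeric(t))
  n <- length(vals)
  if (n < 2L) stop("need at least 2 ROIs", call. = FALSE)
  len <- unique(vapply(vals, length, 1L))
  if (length(len) != 1L) stop("all traces must have equal length", call. = FALSE)
  ids <- vapply(seq_along(vals), function(i) {
    t <- traces[[i]]
    if (inherits(t, "dff_trace") && nzchar(t$roi_id)) t$roi_id else paste0("roi_", i)
  }, "")
  fun <- if (kind == "cosine") cosine_correlation else pearson_correlation
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    m[i, i] <- tryCatch(fun(vals[[i]], vals[[i]]), error = function(e) NA_real_)
    if (i == n) break
    for (j in seq(i + 1L, n)) {
      m[i, j] <- m[j, i] <-
        tryCatch(fun(vals[[i]], vals[[j]]), error = function(e) NA_real_)
    }
  }
  off <- m[upper.tri(m)]
  structure(list(matrix = m, kind = kind,
                 mean = mean(off, na.rm = TRUE),
                 n_undefined = sum(is.na(off))),
            class = "synchrony_matrix")
}

#' @export
print.synchrony_matrix <- function(x, ...) {
  cat(sprintf("<synchrony_matrix (%s): %d ROIs, mean pairwise r = %.4f, %d undefined pair(s)>\n",
              x$kind, nrow(x$matrix), x$mean, x$n_undefined))
  invisible(x)
}

#' Standardize session synchrony to a pre-session
#'
#' Divides each session's mean pairwise correlation by the pre-session value,
#' so the pre-session maps to 1 and later sessions express synchrony relative
#' to the pre-operative level. A difference mode (`session - pre`) is
#' available for sensitivity analyses.
#'
#' @param session_means Named numeric vector of per-session mean pairwise
#'   correlations (e.g. `c(Pre = 0.4, POD2 = 0.2)`).
#' @param pre_label Name of the reference session (default `"Pre"`).
#' @param mode `"ratio"` (default) or `"difference"`.
#' @return Data frame with columns `session`, `mean_r`, `standardized`.
#' @export
standardize_to_pre <- function(session_means, pre_label = "Pre",
                               mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  if (is.null(names(session_means)) || any(!nzchar(names(session_means))))
    stop("session_means must be a fully named vector", call. = FALSE)
  if (!pre_label %in% names(session_means))
    stop(sprintf("pre-session '%s' not present", pre_label), call. = FALSE)
  pre <- session_means[[pre_label]]
  if (mode == "ratio" && pre == 0)
    stop("pre-session mean is zero; ratio standardization undefined", call. = FALSE)
  std <- if (mode == "ratio") session_means / pre else session_means - pre
  data.frame(session = names(session_means),
             mean_r = unname(session_means),
             standardized = unname(std),
             row.names = NULL, stringsAsFactors = FALSE)
}
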