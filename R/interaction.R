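#' Otsu binarization
#'
#' Builds a 256-bin histogram over the observed min-max intensity range and
#' picks the threshold (a bin upper edge) that maximizes the between-class
#' variance; pixels strictly above the threshold are foreground. Operating
#' on the observed range rather than a fixed 8-bit scale lets the same rule
#' apply to 16-bit or floating-point projections.
#'
#' @param image A `projected_image` or numeric matrix with at least two
#'   distinct values.
#' @param channel Optional label stored in the result
#'   (e.g. `"microglia"`, `"axon"`).
#' @param n_bins Histogram resolution (default 256).
#' @return An object of class `binary_mask`: list with logical `mask`,
#'   `threshold`, and `channel`.
#' @export
otsu_binarize <- function(image, channel = NA_character_, n_bins = 256L) {
  img <- if (inherits(image, "projected_image")) image$pixels else image
  rng <- range(img)
  if (!all(is.finite(rng))) stop("image has non-finite pixels", call. = FALSE)
  if (rng[1] == rng[2])
    stop("constant image: no threshold exists", call. = FALSE)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(
    pmin(pmax(findInterval(img, breaks, rightmost.closed = TRUE), 1L), n_bins),
    nbins = n_bins)
  p <- counts / sum(counts)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  w1 <- cumsum(p)
  mu1 <- cumsum(p * mids)
  mu_t <- mu1[n_bins]
  # between-class variance for a cut after bin k
  valid <- w1 > 0 & w1 < 1
  bcv <- rep(-Inf, n_bins)
  bcv[valid] <- (mu_t * w1[valid] - mu1[valid])^2 /
    (w1[valid] * (1 - w1[valid]))
  k <- which.max(bcv)
  threshold <- breaks[k + 1L]
  structure(list(mask = img > threshold, threshold = threshold,
                 channel = channel), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask%s: %d / %d foreground px, threshold %.4g>\n",
              if (!is.na(x$channel)) paste0(" (", x$channel, ")") else "",
              sum(x$mask), length(x$mask), x$threshold))
  invisible(x)
}

#' Microglia-axon colocalization ratio
#'
#' The merged area is the pixelwise AND of the two foreground masks; the
#' colocalization ratio is the merged area divided by the axon foreground
#' area.
#'
#' @param microglia_mask,axon_mask `binary_mask` objects (or logical
#'   matrices) of identical shape; the axon mask must have foreground.
#' @return List with `axon_px`, `merged_px`, `microglia_px`, and `ratio`
#'   in `[0, 1]`.
#' @export
colocalization_ratio <- function(microglia_mask, axon_mask) {
  gm <- if (inherits(microglia_mask, "binary_mask")) microglia_mask$mask
        else microglia_mask
  ax <- if (inherits(axon_mask, "binary_mask")) axon_mask$mask else axon_mask
  if (!identical(dim(gm), dim(ax)))
    stop("masks must have identical shape", call. = FALSE)
  axon_px <- sum(ax)
  if (axon_px == 0)
    stop("empty axon mask: colocalization ratio undefined", call. = FALSE)
  merged <- sum(gm & ax)
  list(axon_px = axon_px, merged_px = merged, microglia_px = sum(gm),
       ratio = merged / axon_px)
}

#' Moving vector of a process-tip track
#'
#' Within the analysis window, the moving vector points from the first
#' position to the in-window position at maximum Euclidean distance from it
#' (earliest such point on ties). Its direction defines the polarity angle
#' of the process, measured CCW from +x in image coordinates (+y down),
#' in `[0, 360)`.
#'
#' @param track Data frame with columns `t_min`, `x_um`, `y_um`
#'   (timestamps strictly increasing).
#' @param window_minutes Window length from the first timestamp (default 60).
#' @return List with `vector` (dx, dy in um), `distance_um`, `angle_deg`
#'   (NA when the tip never leaves its start), and `zero_displacement` flag.
#' @export
moving_vector <- function(track, window_minutes = 60) {
  stopifnot(all(c("t_min", "x_um", "y_um") %in% names(track)))
  if (any(diff(track$t_min) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  inw <- track$t_min <= track$t_min[1L] + window_minutes
  if (sum(inw) < 2L)
    stop("need at least 2 points inside the window", call. = FALSE)
  x <- track$x_um[inw]; y <- track$y_um[inw]
  d2 <- (x - x[1L])^2 + (y - y[1L])^2
  i <- which.max(d2)            # which.max returns the earliest maximum
  v <- c(dx = x[i] - x[1L], dy = y[i] - y[1L])
  dist <- sqrt(d2[i])
  if (dist == 0)
    return(list(vector = v, distance_um = 0, angle_deg = NA_real_,
                zero_displacement = TRUE))
  ang <- atan2(v[2L], v[1L]) * 180 / pi
  list(vector = v, distance_um = dist, angle_deg = unname(ang %% 360),
       zero_displacement = FALSE)
}

#' Fold an angle difference into [0, 90] degrees
#'
#' Takes the absolute difference of two direction angles modulo 180 (axial
#' identification: a line at \eqn{\theta} equals one at \eqn{\theta+180})
#' and reflects results above 90 back, so the output is the acute angle
#' between the two axes.
#'
#' @param theta1,theta2 Angles in degrees (finite; any range).
#' @return Folded difference in `[0, 90]`.
#' @export
fold_angle_difference <- function(theta1, theta2) {
  if (any(!is.finite(theta1)) || any(!is.finite(theta2)))
    stop("angles must be finite", call. = FALSE)
  d <- abs(theta1 - theta2) %% 180
  ifelse(d <= 90, d, 180 - d)
}

#' Axial orientation of an axon segment
#'
#' Linear approximation of an axon by the chord joining its two visible
#' endpoints (bouton to bouton); returns the axial orientation with period
#' 180 degrees.
#'
#' @param p1,p2 Numeric length-2 endpoints `(x, y)`; must be distinct.
#' @return Orientation in degrees in `[0, 180)`.
#' @export
axon_axis <- function(p1, p2) {
  d <- as.numeric(p2) - as.numeric(p1)
  if (all(d == 0)) stop("coincident endpoints", call. = FALSE)
  (atan2(d[2L], d[1L]) * 180 / pi) %% 180
}

#' Empirical cumulative distribution of folded angles
#'
#' Right-continuous empirical CDF of a `[0, 90]`-folded angle sample, the
#' form in which process-polarity distributions are compared across groups.
#'
#' @param angles Numeric vector of angles in `[0, 90]` (length >= 1).
#' @return Data frame with `angle_deg` (sorted unique values) and
#'   `cum_proportion` (reaching 1 at the largest angle).
#' @export
angle_cdf <- function(angles) {
  angles <- as.numeric(angles)
  if (!length(angles)) stop("need at least one angle", call. = FALSE)
  if (any(angles < 0 | angles > 90))
    stop("angles must lie in [0, 90]", call. = FALSE)
  u <- sort(unique(angles))
  data.frame(angle_deg = u,
             cum_proportion = vapply(u, function(a) mean(angles <= a), 1))
}

#' Folded process-axon angle sample from tip tracks
#'
#' Runs [moving_vector()] over every track, drops zero-displacement tracks
#' (their polarity is undefined), and folds each moving-vector angle against
#' the axon axis into `[0, 90]`.
#'
#' @param tracks Data frame with columns `track_id`, `t_min`, `x_um`,
#'   `y_um` (as produced by [simulate_tracks()] or imported tracking
#'   tables).
#' @param axon_angle_deg Axon axis orientation in degrees.
#' @param window_minutes Analysis window (default 60).
#' @param group Label attached to the sample.
#' @return A data frame with columns `group` and `angle_deg` (folded), one
#'   row per track with defined polarity; attribute `n_zero_displacement`
#'   counts dropped tracks.
#' @export
process_axon_angles <- function(tracks, axon_angle_deg, window_minutes = 60,
                                group = "sample") {
  ids <- unique(tracks$track_id)
  angles <- numeric(0)
  n_zero <- 0L
  for (id in ids) {
    mv <- moving_vector(tracks[tracks$track_id == id, , drop = FALSE],
                        window_minutes)
    if (mv$zero_displacement) n_zero <- n_zero + 1L
    else angles <- c(angles, fold_angle_difference(mv$angle_deg, axon_angle_deg))
  }
  out <- data.frame(group = group, angle_deg = angles,
                    stringsAsFactors = FALSE)
  attr(out, "n_zero_displacement") <- n_zero
  out
}
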