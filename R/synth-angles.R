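#' Sample from the von Mises distribution
#'
#' Best & Fisher (1979) rejection sampler. With `kappa = 0` the distribution
#' is uniform on the circle.
#'
#' @param n Number of draws.
#' @param mu Mean direction in degrees.
#' @param kappa Concentration parameter (>= 0).
#' @return Angles in degrees in `[0, 360)`.
#' @export
rvonmises_deg <- function(n, mu, kappa) {
  if (kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  if (kappa == 0) return(stats::runif(n, 0, 360))
  mu_rad <- mu * pi / 180
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u2 > 0 || log(c_ / u2) + 1 - c_ >= 0) {
      theta <- mu_rad + sign(u3 - 0.5) * acos(f)
      out[i] <- theta %% (2 * pi)
      i <- i + 1L
    }
  }
  out * 180 / pi
}

#' Simulate grouped circular angle samples
#'
#' Draws one von Mises sample per group specification; feeds calibration and
#' power studies of [mww_test()].
#'
#' @param group_specs A list of specs, each a list/vector with elements
#'   `n` (>= 2), `mean_direction` (degrees) and `kappa` (>= 0). Names of
#'   `group_specs` become group labels (defaults `group_1`, ...).
#' @param seed Integer seed.
#' @return A data frame with columns `group` and `angle_deg` (in `[0, 360)`).
#' @export
simulate_angle_samples <- function(group_specs, seed = 1L) {
  if (!length(group_specs)) stop("need at least one group spec", call. = FALSE)
  labels <- names(group_specs)
  if (is.null(labels)) labels <- rep("", length(group_specs))
  labels <- ifelse(nzchar(labels), labels,
                   sprintf("group_%d", seq_along(group_specs)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  out <- lapply(seq_along(group_specs), function(i) {
    spec <- as.list(group_specs[[i]])
    n <- as.integer(spec$n)
    if (is.na(n) || n < 2L) stop("each group needs n >= 2", call. = FALSE)
    if (spec$kappa < 0) stop("kappa must be >= 0", call. = FALSE)
    data.frame(group = labels[i],
               angle_deg = rvonmises_deg(n, spec$mean_direction, spec$kappa),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
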