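#' Temporal standard-deviation projection
#'
#' Collapses a time-lapse sequence to one image by taking the per-pixel
#' standard deviation across frames (population SD, divisor N). Structures
#' whose brightness varies over time stand out against steady background.
#'
#' @param stack A 3-D array (`rows x cols x frames`), a list of equal-sized
#'   matrices, or a `two_channel_stack` (then `channel` selects 1 or 2).
#' @param channel Channel to project when `stack` is a `two_channel_stack`.
#' @param pixel_size_um Pixel size carried into the result; taken from the
#'   stack when available.
#' @return An object of class `projected_image`: list with `pixels` (matrix)
#'   and `pixel_size_um`.
#' @export
sd_projection <- function(stack, channel = 1, pixel_size_um = NULL) {
  if (inherits(stack, "two_channel_stack")) {
    if (is.null(pixel_size_um)) pixel_size_um <- stack$pixel_size_um
    stack <- if (channel == 1) stack$ch1 else stack$ch2
  }
  if (is.list(stack)) {
    if (length(stack) < 2L) stop("need at least 2 frames", call. = FALSE)
    stack <- simplify2array(stack)
  }
  if (length(dim(stack)) != 3L || dim(stack)[3] < 2L)
    stop("need at least 2 frames", call. = FALSE)
  d <- dim(stack)
  flat <- matrix(stack, d[1] * d[2], d[3])
  m1 <- rowMeans(flat)
  m2 <- rowMeans(flat^2)
  px <- matrix(pmax(m2 - m1^2, 0), d[1], d[2])
  structure(list(pixels = sqrt(px),
                 pixel_size_um = if (is.null(pixel_size_um)) 1 else pixel_size_um),
            class = "projected_image")
}

#' @export
print.projected_image <- function(x, ...) {
  cat(sprintf("<projected_image: %d x %d px, %.4g um/px>\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um))
  invisible(x)
}

# local maxima: pixels equal to the running max over a (2r+1)^2 window
local_maxima <- function(img, radius) {
  n <- nrow(img); m <- ncol(img)
  mx <- img
  # separable max filter
  run_max <- function(mat, r, margin) {
    out <- mat
    for (d in seq_len(r)) {
      if (margin == 1L) {
        out[(1 + d):n, ] <- pmax(out[(1 + d):n, ], mat[1:(n - d), ])
        out[1:(n - d), ] <- pmax(out[1:(n - d), ], mat[(1 + d):n, ])
      } else {
        out[, (1 + d):m] <- pmax(out[, (1 + d):m], mat[, 1:(m - d)])
        out[, 1:(m - d)] <- pmax(out[, 1:(m - d)], mat[, (1 + d):m])
      }
    }
    out
  }
  mx <- run_max(mx, radius, 1L)
  mx <- run_max(mx, radius, 2L)
  which(img == mx, arr.ind = TRUE)
}

# 8-connected flood fill on a logical mask from a start pixel; returns linear
# indices of the component
flood_fill8 <- function(mask, start_row, start_col) {
  n <- nrow(mask); m <- ncol(mask)
  if (!mask[start_row, start_col]) return(integer(0))
  visited <- matrix(FALSE, n, m)
  queue <- integer(2048); head <- 1L; tail <- 1L
  queue[1L] <- (start_col - 1L) * n + start_row
  visited[start_row, start_col] <- TRUE
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  while (head <= tail) {
    idx <- queue[head]; head <- head + 1L
    r <- ((idx - 1L) %% n) + 1L
    cc <- ((idx - 1L) %/% n) + 1L
    for (k in 1:8) {
      rr <- r + dr[k]; c2 <- cc + dc[k]
      if (rr >= 1L && rr <= n && c2 >= 1L && c2 <= m &&
          mask[rr, c2] && !visited[rr, c2]) {
        visited[rr, c2] <- TRUE
        tail <- tail + 1L
        if (tail > length(queue)) queue <- c(queue, integer(length(queue)))
        queue[tail] <- (c2 - 1L) * n + rr
      }
    }
  }
  which(visited)
}

#' Count 8-connected components of a binary mask
#'
#' @param mask Logical matrix.
#' @return Integer component count.
#' @export
count_components8 <- function(mask) {
  remaining <- mask
  count <- 0L
  repeat {
    idx <- which(remaining)
    if (!length(idx)) break
    r <- ((idx[1L] - 1L) %% nrow(mask)) + 1L
    cc <- ((idx[1L] - 1L) %/% nrow(mask)) + 1L
    comp <- flood_fill8(remaining, r, cc)
    remaining[comp] <- FALSE
    count <- count + 1L
  }
  count
}

#' Extract microglial cell bodies by half-maximum region growing
#'
#' Re-creation of the ImageJ wand rule with the tolerance set at half the
#' maximum-intensity point: each accepted seed (a local intensity maximum at
#' or above `seed_min_intensity`) grows into the 8-connected region of
#' pixels whose intensity is at least half the seed intensity. Regions that
#' contain more than one accepted seed cannot be told apart from an adjacent
#' cell and are marked excluded, as are regions touching the field border
#' (truncated shapes bias the ellipse fit).
#'
#' Local maxima closer together than `min_seed_separation_px` are treated as
#' duplicate peaks of one cell; only the strongest survives. A manual seed
#' list can be supplied instead of automatic seeding.
#'
#' @param image A `projected_image` (or plain matrix).
#' @param seed_min_intensity Minimum intensity for an automatic seed; must
#'   exceed the background level.
#' @param seeds Optional manual seeds: two-column matrix of (row, col)
#'   pixel coordinates; bypasses automatic seeding.
#' @param seed_window_px Radius of the local-maximum window (default 5).
#' @param min_seed_separation_px Seeds closer than this are merged
#'   (default 30, about one soma diameter).
#' @param halfmax Interpretation of "half the maximum intensity point":
#'   `"seed"` (default; half of the seed intensity) or `"midpoint"`
#'   (halfway between seed intensity and the image median background).
#' @return A list of `cell_body_region` objects: `pixel_idx` (linear
#'   indices), `dim`, `seed` (row, col), `seed_intensity`, `threshold`,
#'   `excluded` flag and `reason`.
#' @export
extract_cell_bodies <- function(image, seed_min_intensity, seeds = NULL,
                                seed_window_px = 5L,
                                min_seed_separation_px = 30,
                                halfmax = c("seed", "midpoint")) {
  halfmax <- match.arg(halfmax)
  img <- if (inherits(image, "projected_image")) image$pixels else image
  n <- nrow(img); m <- ncol(img)
  if (is.null(seeds)) {
    lm <- local_maxima(img, seed_window_px)
    lm <- lm[img[lm] >= seed_min_intensity, , drop = FALSE]
    if (!nrow(lm)) {
      message("no seeds found at or above seed_min_intensity")
      return(list())
    }
    # a uniform plateau is one peak, not many: keep a single representative
    # (nearest the centroid) per 8-connected component of maximum pixels
    if (nrow(lm) > 1L) {
      cand <- matrix(FALSE, n, m)
      cand[lm] <- TRUE
      reps <- list()
      while (any(cand)) {
        first <- which(cand)[1L]
        comp <- flood_fill8(cand, ((first - 1L) %% n) + 1L,
                            ((first - 1L) %/% n) + 1L)
        cand[comp] <- FALSE
        rows <- ((comp - 1L) %% n) + 1L
        cols <- ((comp - 1L) %/% n) + 1L
        i <- which.min((rows - mean(rows))^2 + (cols - mean(cols))^2)
        reps[[length(reps) + 1L]] <- c(rows[i], cols[i])
      }
      lm <- do.call(rbind, reps)
    }
    # strongest-first dedupe of nearby peaks
    ord <- order(img[lm], decreasing = TRUE)
    lm <- lm[ord, , drop = FALSE]
    keep <- rep(TRUE, nrow(lm))
    for (i in seq_len(nrow(lm))) {
      if (!keep[i]) next
      if (i < nrow(lm)) {
        later <- (i + 1L):nrow(lm)
        d <- sqrt((lm[later, 1] - lm[i, 1])^2 + (lm[later, 2] - lm[i, 2])^2)
        keep[later[d < min_seed_separation_px]] <- FALSE
      }
    }
    seeds <- lm[keep, , drop = FALSE]
  } else {
    seeds <- as.matrix(seeds)
    seeds <- seeds[order(img[seeds], decreasing = TRUE), , drop = FALSE]
  }
  bg <- stats::median(img)
  seed_lin <- (seeds[, 2] - 1L) * n + seeds[, 1]
  regions <- vector("list", nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    si <- img[seeds[i, 1], seeds[i, 2]]
    thr <- if (halfmax == "seed") si / 2 else (si + bg) / 2
    comp <- flood_fill8(img >= thr, seeds[i, 1], seeds[i, 2])
    rows <- ((comp - 1L) %% n) + 1L
    cols <- ((comp - 1L) %/% n) + 1L
    excluded <- FALSE; reason <- NA_character_
    if (sum(seed_lin %in% comp) > 1L) {
      excluded <- TRUE; reason <- "indistinguishable neighbors"
    } else if (any(rows == 1L | rows == n | cols == 1L | cols == m)) {
      excluded <- TRUE; reason <- "touches field border"
    }
    regions[[i]] <- structure(list(
      pixel_idx = comp, dim = c(n, m),
      seed = c(row = seeds[i, 1], col = seeds[i, 2]),
      seed_intensity = si, threshold = thr,
      excluded = excluded, reason = reason),
      class = "cell_body_region")
  }
  regions
}

#' @export
print.cell_body_region <- function(x, ...) {
  cat(sprintf("<cell_body_region: %d px, seed (%d, %d)%s>\n",
              length(x$pixel_idx), x$seed[1], x$seed[2],
              if (isTRUE(x$excluded)) paste0(", excluded: ", x$reason) else ""))
  invisible(x)
}

# Moore-neighbour contour tracing; returns the Freeman chain (direction codes
# 1..8, odd = axis move, even = diagonal) around an 8-connected region
trace_contour8 <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  idx <- which(mask, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  start <- idx[ord[1L], ]
  # clockwise Moore neighbourhood starting W: (dr, dc)
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  inmask <- function(r, c) r >= 1L && r <= n && c >= 1L && c <= m && mask[r, c]
  cur <- start; back <- 1L
  moves <- integer(0)
  first_move <- NA_integer_
  limit <- 8L * length(mask)
  repeat {
    found <- FALSE
    for (k in 0:7) {
      d <- ((back - 1L + k) %% 8L) + 1L
      r <- cur[1L] + dr[d]; c2 <- cur[2L] + dc[d]
      if (inmask(r, c2)) {
        moves <- c(moves, d)
        back <- ((d - 1L + 6L) %% 8L) + 1L  # resume after the backtrack pixel
        cur <- c(r, c2)
        found <- TRUE
        break
      }
    }
    if (!found) return(integer(0))  # isolated pixel
    if (is.na(first_move)) first_move <- moves[1L]
    # Jacob's criterion: back at start about to repeat the initial move
    if (length(moves) > 1L && all(cur == start)) {
      # peek: would the next move equal the first?
      for (k in 0:7) {
        d <- ((back - 1L + k) %% 8L) + 1L
        r <- cur[1L] + dr[d]; c2 <- cur[2L] + dc[d]
        if (inmask(r, c2)) break
      }
      if (d == first_move) break
    }
    if (length(moves) > limit) stop("contour tracing failed to terminate")
  }
  moves
}

# Kulpa-corrected digitized perimeter from a Freeman chain
perimeter_from_chain <- function(moves) {
  if (!length(moves)) return(0)
  diag <- moves %% 2L == 0L
  0.948 * sum(!diag) + 1.340 * sum(diag)
}

#' Equivalent-ellipse shape metrics of a cell-body region
#'
#' Fits the equivalent ellipse from second-order central moments of the
#' pixel set and reports the morphological descriptors used for microglial
#' activation state: area, aspect ratio (major/minor), roundness
#' (`4 A / (pi major^2)`) and circularity (`4 pi A / P^2`, clamped at 1;
#' the perimeter P uses a Kulpa-corrected Freeman chain length, which keeps
#' digitized discs at circularity ~1).
#'
#' @param region A `cell_body_region`, or a logical matrix mask.
#' @param pixel_size_um Pixel size in um (default 1 = report in pixels).
#' @return A data.frame row: `area_um2`, `major_um`, `minor_um`,
#'   `orientation_deg`, `aspect_ratio`, `circularity`, `roundness`.
#' @export
ellipse_metrics <- function(region, pixel_size_um = 1) {
  if (inherits(region, "cell_body_region")) {
    mask <- matrix(FALSE, region$dim[1], region$dim[2])
    mask[region$pixel_idx] <- TRUE
  } else mask <- region
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 4L) stop("region must have at least 4 pixels", call. = FALSE)
  x <- idx[, 2]; y <- idx[, 1]
  mu20 <- mean(x^2) - mean(x)^2
  mu02 <- mean(y^2) - mean(y)^2
  mu11 <- mean(x * y) - mean(x) * mean(y)
  disc <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- (mu20 + mu02) / 2 + disc
  l2 <- (mu20 + mu02) / 2 - disc
  if (l2 <= 0) stop("degenerate (collinear) pixel set", call. = FALSE)
  major_px <- 4 * sqrt(l1)
  minor_px <- 4 * sqrt(l2)
  orientation <- (atan2(2 * mu11, mu20 - mu02) / 2) * 180 / pi
  area_px <- nrow(idx)
  perim_px <- perimeter_from_chain(trace_contour8(mask))
  circ <- if (perim_px > 0) min(1, 4 * pi * area_px / perim_px^2) else NA_real_
  data.frame(
    area_um2 = area_px * pixel_size_um^2,
    major_um = major_px * pixel_size_um,
    minor_um = minor_px * pixel_size_um,
    orientation_deg = orientation %% 180,
    aspect_ratio = major_px / minor_px,
    circularity = circ,
    roundness = 4 * area_px / (pi * major_px^2))
}

#' Cell density of a field
#'
#' Counts non-excluded cell-body regions and converts to density per field
#' and per square millimetre.
#'
#' @param regions List of `cell_body_region` objects (excluded regions are
#'   not counted).
#' @param field_size_um Field edge length in um (> 0).
#' @return List with `count`, `per_field`, `per_mm2`.
#' @export
cell_density <- function(regions, field_size_um) {
  if (field_size_um <= 0) stop("field_size_um must be > 0", call. = FALSE)
  count <- sum(!vapply(regions, function(r) isTRUE(r$excluded), TRUE))
  list(count = count, per_field = count,
       per_mm2 = count / (field_size_um / 1000)^2)
}

#' Per-field morphometry summary
#'
#' Applies [ellipse_metrics()] to every included region and combines the
#' per-cell table with the field density.
#'
#' @param regions List of `cell_body_region` objects.
#' @param pixel_size_um Pixel size in um.
#' @param field_size_um Field edge length in um.
#' @return List with `cells` (per-cell metric data.frame, includes excluded
#'   cells flagged), `density`, and `metric_summary` (mean and SD per metric
#'   over included cells).
#' @export
morphometry_summary <- function(regions, pixel_size_um, field_size_um) {
  rows <- lapply(seq_along(regions), function(i) {
    r <- regions[[i]]
    met <- tryCatch(ellipse_metrics(r, pixel_size_um),
                    error = function(e) NULL)
    if (is.null(met))
      met <- data.frame(area_um2 = NA_real_, major_um = NA_real_,
                        minor_um = NA_real_, orientation_deg = NA_real_,
                        aspect_ratio = NA_real_, circularity = NA_real_,
                        roundness = NA_real_)
    cbind(data.frame(id = i, excluded = isTRUE(r$excluded),
                     reason = if (isTRUE(r$excluded)) r$reason else NA_character_),
          met)
  })
  cells <- do.call(rbind, rows)
  inc <- cells[!cells$excluded, c("area_um2", "aspect_ratio",
                                  "circularity", "roundness"), drop = FALSE]
  metric_summary <- data.frame(
    metric = names(inc),
    mean = vapply(inc, mean, 1, na.rm = TRUE),
    sd = vapply(inc, stats::sd, 1, na.rm = TRUE),
    row.names = NULL)
  list(cells = cells,
       density = cell_density(regions, field_size_um),
       metric_summary = metric_summary)
}
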