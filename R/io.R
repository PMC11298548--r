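#' Write and read trace tables
#'
#' Traces are stored as CSV with a `frame` column plus one column per ROI
#' (`roi_0 ...`), and a JSON sidecar (`<file>.json`) carrying the frame
#' interval in seconds and the generator seed, when known.
#'
#' @param traces List of [fluorescence_trace()] objects of equal length.
#' @param path CSV file path.
#' @param seed Optional seed recorded in the sidecar.
#' @return `write_traces_csv` returns `path` invisibly; `read_traces_csv`
#'   returns a list of `fluorescence_trace` objects.
#' @export
write_traces_csv <- function(traces, path, seed = NULL) {
  stopifnot(length(traces) >= 1L)
  vals <- lapply(traces, function(t) t$values)
  len <- unique(vapply(vals, length, 1L))
  stopifnot(length(len) == 1L)
  df <- data.frame(frame = seq_len(len) - 1L)
  for (i in seq_along(vals)) df[[sprintf("roi_%d", i - 1L)]] <- vals[[i]]
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- list(frame_interval = traces[[1L]]$frame_interval)
  if (!is.null(seed)) sidecar$seed <- seed
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path)
  sidecar_path <- paste0(path, ".json")
  fi <- if (file.exists(sidecar_path))
    jsonlite::read_json(sidecar_path)$frame_interval else 1
  cols <- setdiff(names(df), "frame")
  lapply(cols, function(cn)
    fluorescence_trace(df[[cn]], frame_interval = fi, roi_id = cn))
}

#' Write and read two-channel stacks as multi-page TIFF
#'
#' Pages are channel-interleaved (channel 1 frame 1, channel 2 frame 1,
#' channel 1 frame 2, ...) and intensities are rescaled to `[0, 1]` for
#' 16-bit storage; the JSON sidecar records the pixel size (um), frame
#' interval (min) and the rescaling factor, so reading restores the
#' original intensity scale up to 16-bit quantization.
#'
#' @param stack A `two_channel_stack`.
#' @param path TIFF file path.
#' @param truth Optional `synth_truth`; scalar ground-truth fields are
#'   copied into the sidecar.
#' @return `write_stack_tiff` returns `path` invisibly; `read_stack_tiff`
#'   returns a `two_channel_stack`.
#' @export
write_stack_tiff <- function(stack, path, truth = NULL) {
  stopifnot(inherits(stack, "two_channel_stack"))
  n_frames <- dim(stack$ch1)[3]
  hi <- max(max(stack$ch1), max(stack$ch2), .Machine$double.eps)
  lo <- min(min(stack$ch1), min(stack$ch2), 0)
  scale <- hi - lo
  pages <- vector("list", 2L * n_frames)
  for (f in seq_len(n_frames)) {
    pages[[2L * f - 1L]] <- (stack$ch1[, , f] - lo) / scale
    pages[[2L * f]] <- (stack$ch2[, , f] - lo) / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sidecar <- list(pixel_size_um = stack$pixel_size_um,
                  frame_interval_min = stack$frame_interval_min,
                  intensity_offset = lo, intensity_scale = scale,
                  channel_order = c("microglia", "axon"))
  if (!is.null(truth)) {
    keep <- c("soma_axes_um", "process_angles", "axon_orientation",
              "true_overlap_fraction")
    sidecar$truth <- truth[intersect(keep, names(truth))]
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  sidecar_path <- paste0(path, ".json")
  meta <- if (file.exists(sidecar_path)) jsonlite::read_json(sidecar_path)
          else list(pixel_size_um = 1, frame_interval_min = 1,
                    intensity_offset = 0, intensity_scale = 1)
  n_frames <- length(pages) %/% 2L
  d <- dim(pages[[1L]])
  ch1 <- array(0, c(d[1L], d[2L], n_frames))
  ch2 <- array(0, c(d[1L], d[2L], n_frames))
  for (f in seq_len(n_frames)) {
    ch1[, , f] <- pages[[2L * f - 1L]] * meta$intensity_scale +
      meta$intensity_offset
    ch2[, , f] <- pages[[2L * f]] * meta$intensity_scale +
      meta$intensity_offset
  }
  structure(list(ch1 = ch1, ch2 = ch2,
                 pixel_size_um = meta$pixel_size_um,
                 frame_interval_min = meta$frame_interval_min),
            class = "two_channel_stack")
}

#' Write and read angle samples
#'
#' Plain CSV with columns `group` and `angle_deg`.
#'
#' @param angles Data frame with columns `group`, `angle_deg`.
#' @param path CSV file path.
#' @return `write_angles_csv` returns `path` invisibly; `read_angles_csv`
#'   returns the data frame.
#' @export
write_angles_csv <- function(angles, path) {
  stopifnot(all(c("group", "angle_deg") %in% names(angles)))
  utils::write.csv(angles[, c("group", "angle_deg")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_angles_csv
#' @export
read_angles_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write and read tip-track tables
#'
#' Plain CSV with columns `track_id`, `t_min`, `x_um`, `y_um`.
#'
#' @param tracks Track data frame.
#' @param path CSV file path.
#' @return `write_tracks_csv` returns `path` invisibly; `read_tracks_csv`
#'   returns the data frame.
#' @export
write_tracks_csv <- function(tracks, path) {
  stopifnot(all(c("track_id", "t_min", "x_um", "y_um") %in% names(tracks)))
  utils::write.csv(tracks[, c("track_id", "t_min", "x_um", "y_um")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
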