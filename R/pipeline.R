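#' Build a pipeline run configuration
#'
#' Central, validated parameter set for [run_pipeline()]. Unknown keys are
#' rejected so typos cannot silently fall back to defaults; the resolved
#' configuration is echoed into every run's output directory
#' (`config.json`) for provenance.
#'
#' @param ... Key-value overrides of the defaults listed below.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    schema_version = 1L,
    seed = 1L,
    # calcium stage
    percentile = 35, sd_multiplier = 2, min_duration_frames = 2,
    offset_multiplier = 0.5, noise_estimator = "lower_half",
    synchrony_kind = "cosine",
    # morpho stage
    seed_min_intensity = NA_real_, field_size_um = 264.90,
    # polarity stage
    window_minutes = 60, axon_angle_deg = NA_real_,
    # simulate stage
    trace_sim = list(), stack_sim = list(),
    # file paths (inputs for the analysis stages)
    traces_csv = NA_character_, stack_tiff = NA_character_,
    tracks_csv = NA_character_, angles_csv = NA_character_)
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad))
      stop("unknown config key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    defaults[names(overrides)] <- overrides
  }
  structure(defaults, class = "run_config")
}

read_input <- function(path, what, reader) {
  if (is.na(path)) stop(sprintf("missing input path for %s", what), call. = FALSE)
  if (!file.exists(path))
    stop(sprintf("%s input not found: %s", what, path), call. = FALSE)
  tryCatch(reader(path),
           error = function(e)
             stop(sprintf("corrupt %s input '%s': %s", what, path,
                          conditionMessage(e)), call. = FALSE))
}

stage_simulate <- function(cfg, out_dir) {
  tcfg <- do.call(trace_sim_config,
                  utils::modifyList(list(seed = cfg$seed), cfg$trace_sim))
  tr <- simulate_traces(tcfg)
  write_traces_csv(tr$traces, file.path(out_dir, "traces.csv"),
                   seed = tcfg$seed)
  scfg <- do.call(stack_sim_config,
                  utils::modifyList(list(seed = cfg$seed + 1L), cfg$stack_sim))
  st <- simulate_stack(scfg)
  write_stack_tiff(st$stack, file.path(out_dir, "stack.tif"), truth = st$truth)
  tracks <- simulate_tracks(st$truth, seed = cfg$seed + 2L)
  write_tracks_csv(tracks, file.path(out_dir, "tracks.csv"))
  list(traces_csv = file.path(out_dir, "traces.csv"),
       stack_tiff = file.path(out_dir, "stack.tif"),
       tracks_csv = file.path(out_dir, "tracks.csv"),
       axon_angle_deg = st$truth$axon_orientation,
       trace_truth = list(
         synchrony_fraction = tr$truth$synchrony_fraction,
         n_events = vapply(tr$truth$event_times, length, 1L)),
       stack_truth = list(
         true_overlap_fraction = st$truth$true_overlap_fraction,
         n_cells = scfg$n_cells))
}

stage_calcium <- function(cfg, out_dir) {
  traces <- read_input(cfg$traces_csv, "traces", read_traces_csv)
  duration <- length(traces[[1L]]$values) * traces[[1L]]$frame_interval
  events <- list(); flagged <- character(0); dffs <- list()
  for (tr in traces) {
    res <- tryCatch({
      f0 <- compute_baseline(tr, cfg$percentile)
      dff <- compute_dff(tr, f0, estimator = cfg$noise_estimator)
      ev <- detect_transients(dff, cfg$sd_multiplier, cfg$min_duration_frames,
                              cfg$offset_multiplier)
      list(dff = dff, ev = ev)
    }, error = function(e) e)
    if (inherits(res, "error")) { flagged <- c(flagged, tr$roi_id); next }
    dffs[[tr$roi_id]] <- res$dff
    if (nrow(res$ev))
      events[[tr$roi_id]] <- cbind(roi = tr$roi_id, res$ev)
  }
  ev_df <- if (length(events)) do.call(rbind, events) else
    data.frame(roi = character(), onset_frame = integer(),
               offset_frame = integer(), peak = numeric(), power = numeric())
  utils::write.csv(ev_df, file.path(out_dir, "events.csv"), row.names = FALSE)
  sync <- if (length(dffs) >= 2L) pairwise_synchrony(dffs, cfg$synchrony_kind)
          else NULL
  if (!is.null(sync))
    utils::write.csv(as.data.frame(sync$matrix),
                     file.path(out_dir, "synchrony.csv"))
  per_roi <- data.frame(
    roi = names(dffs),
    n_transients = vapply(names(dffs), function(id)
      sum(ev_df$roi == id), 1L),
    frequency_hz = vapply(names(dffs), function(id)
      transient_frequency(sum(ev_df$roi == id), duration), 1),
    mean_power = vapply(names(dffs), function(id) {
      p <- ev_df$power[ev_df$roi == id]
      if (length(p)) mean(p) else NA_real_
    }, 1), row.names = NULL)
  utils::write.csv(per_roi, file.path(out_dir, "calcium_per_roi.csv"),
                   row.names = FALSE)
  list(duration_s = duration, flagged_rois = flagged,
       n_rois = length(dffs),
       mean_frequency_hz = mean(per_roi$frequency_hz),
       mean_synchrony = if (!is.null(sync)) sync$mean else NA_real_,
       n_undefined_pairs = if (!is.null(sync)) sync$n_undefined else NA_integer_)
}

stage_morpho <- function(cfg, out_dir) {
  stack <- read_input(cfg$stack_tiff, "stack", read_stack_tiff)
  proj <- sd_projection(stack, channel = 1)
  thr <- cfg$seed_min_intensity
  if (is.na(thr)) # default: halfway between median background and maximum
    thr <- (stats::median(proj$pixels) + max(proj$pixels)) / 2
  regions <- extract_cell_bodies(proj, seed_min_intensity = thr)
  summ <- morphometry_summary(regions, proj$pixel_size_um, cfg$field_size_um)
  utils::write.csv(summ$cells, file.path(out_dir, "cells.csv"),
                   row.names = FALSE)
  list(n_regions = length(regions),
       n_included = summ$density$count,
       density_per_mm2 = summ$density$per_mm2,
       metric_summary = summ$metric_summary)
}

stage_coloc <- function(cfg, out_dir) {
  stack <- read_input(cfg$stack_tiff, "stack", read_stack_tiff)
  pg <- sd_projection(stack, channel = 1)
  pa <- sd_projection(stack, channel = 2)
  mg <- otsu_binarize(pg, channel = "microglia")
  ax <- otsu_binarize(pa, channel = "axon")
  res <- colocalization_ratio(mg, ax)
  utils::write.csv(data.frame(axon_px = res$axon_px,
                              merged_px = res$merged_px,
                              ratio = res$ratio),
                   file.path(out_dir, "coloc.csv"), row.names = FALSE)
  res
}

stage_polarity <- function(cfg, out_dir) {
  tracks <- read_input(cfg$tracks_csv, "tracks", read_tracks_csv)
  if (is.na(cfg$axon_angle_deg))
    stop("polarity stage needs axon_angle_deg in the config", call. = FALSE)
  ang <- process_axon_angles(tracks, cfg$axon_angle_deg, cfg$window_minutes)
  write_angles_csv(ang, file.path(out_dir, "angles.csv"))
  cdf <- angle_cdf(ang$angle_deg)
  utils::write.csv(cdf, file.path(out_dir, "angle_cdf.csv"), row.names = FALSE)
  list(n_tracks = length(unique(tracks$track_id)),
       n_zero_displacement = attr(ang, "n_zero_displacement"),
       median_angle_deg = stats::median(ang$angle_deg))
}

stage_mww <- function(cfg, out_dir) {
  angles <- read_input(cfg$angles_csv, "angles", read_angles_csv)
  res <- mww_test(angles, seed = cfg$seed)
  out <- list(W = res$W, df = res$df, p_value = res$p_value,
              method = res$method, n = as.list(res$n))
  jsonlite::write_json(out, file.path(out_dir, "mww.json"),
                       auto_unbox = TRUE, digits = NA)
  out
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages as subcommands over standard-format files
#' (traces CSV, two-channel TIFF, track/angle CSV). `"simulate"` emits a
#' complete synthetic dataset; `"all"` simulates and then runs every
#' analysis stage on the emitted files. Runs are deterministic given
#' config + seed; the resolved config and a machine-readable report with
#' input checksums are written into `out_dir`. On any stage error the
#' partially written output directory is removed before the error
#' propagates.
#'
#' @param subcommand One of `"simulate"`, `"calcium"`, `"morpho"`,
#'   `"coloc"`, `"polarity"`, `"mww"`, `"all"`.
#' @param config A [run_config()].
#' @param out_dir Output directory (created; must not already contain a
#'   `report.json`).
#' @return The report, invisibly (also written to `out_dir/report.json`).
#' @export
run_pipeline <- function(subcommand = c("all", "simulate", "calcium",
                                        "morpho", "coloc", "polarity", "mww"),
                         config = run_config(), out_dir) {
  subcommand <- match.arg(subcommand)
  stopifnot(inherits(config, "run_config"))
  created <- !dir.exists(out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok && created) unlink(out_dir, recursive = TRUE), add = TRUE)

  report <- list(subcommand = subcommand, seed = config$seed)
  cfg <- config
  if (subcommand %in% c("simulate", "all")) {
    sim <- stage_simulate(cfg, out_dir)
    report$simulate <- sim[c("trace_truth", "stack_truth", "axon_angle_deg")]
    cfg$traces_csv <- sim$traces_csv
    cfg$stack_tiff <- sim$stack_tiff
    cfg$tracks_csv <- sim$tracks_csv
    if (is.na(cfg$axon_angle_deg)) cfg$axon_angle_deg <- sim$axon_angle_deg
  }
  if (subcommand %in% c("calcium", "all"))
    report$calcium <- stage_calcium(cfg, out_dir)
  if (subcommand %in% c("morpho", "all"))
    report$morpho <- stage_morpho(cfg, out_dir)
  if (subcommand %in% c("coloc", "all"))
    report$coloc <- stage_coloc(cfg, out_dir)
  if (subcommand %in% c("polarity", "all")) {
    report$polarity <- stage_polarity(cfg, out_dir)
    if (subcommand == "all") cfg$angles_csv <- file.path(out_dir, "angles.csv")
  }
  if (subcommand %in% c("mww", "all")) {
    # with a single simulated condition there is only one group; the test
    # needs >= 2, so 'all' runs it only when the angle table provides them
    angles_path <- cfg$angles_csv
    run_it <- !is.na(angles_path) && file.exists(angles_path) &&
      length(unique(read_angles_csv(angles_path)$group)) >= 2L
    if (subcommand == "mww" && !run_it)
      stop("mww stage needs an angle table with at least 2 groups",
           call. = FALSE)
    if (run_it) report$mww <- stage_mww(cfg, out_dir)
  }

  inputs <- unlist(cfg[c("traces_csv", "stack_tiff", "tracks_csv",
                         "angles_csv")])
  inputs <- inputs[!is.na(inputs) & file.exists(inputs)]
  md5 <- tools::md5sum(inputs)
  names(md5) <- basename(names(md5))   # keep the report path-independent
  report$provenance <- list(input_md5 = as.list(md5))
  echo_config(cfg, file.path(out_dir, "config.json"))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  ok <- TRUE
  invisible(report)
}

echo_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  path
}

#' Re-read an echoed pipeline configuration
#'
#' Inverse of the `config.json` echo written by [run_pipeline()]:
#' `parse_config(echo) `reconstructs the `run_config` that produced a run.
#'
#' @param path Path to a `config.json`.
#' @return A `run_config`.
#' @export
parse_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("traces_csv", "stack_tiff", "tracks_csv", "angles_csv"))
    if (is.null(raw[[nm]])) raw[[nm]] <- NA_character_
  for (nm in c("seed_min_intensity", "axon_angle_deg"))
    if (is.null(raw[[nm]])) raw[[nm]] <- NA_real_
  for (nm in c("trace_sim", "stack_sim"))
    raw[[nm]] <- as.list(raw[[nm]])
  raw$seed <- as.integer(raw$seed)
  raw$schema_version <- as.integer(raw$schema_version)
  do.call(run_config, raw)
}
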