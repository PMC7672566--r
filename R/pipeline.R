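#' Pipeline configuration
#'
#' Bundles every tunable parameter of the analysis with its documented
#' default. The configuration round-trips through JSON unchanged
#' ([save_run_config()] / [load_run_config()]).
#'
#' @param frame_rate,pixel_size calibration defaults applied when loading
#'   stacks from paths ([default_calibration()] values).
#' @param box_t,box_h,box_w 3-D box filter windows (frames, px, px).
#' @param k_sigma noise multiplier of the adaptive threshold.
#' @param smoothing_sigma,h_min_frac,min_cell_area watershed parameters.
#' @param eps_t,min_pts,spatial_window event clustering parameters.
#' @param min_event_size smallest per-cell event in voxels (see
#'   [assign_events()]).
#' @param window_w detrending window (frames).
#' @param max_lag largest probed lag (frames).
#' @param threshold fixed correlation threshold.
#' @param calibrate if `TRUE`, calibrate the threshold on distant pairs
#'   instead of using the fixed value.
#' @param baseline_distance_um distance defining "distant" calibration pairs.
#' @param long_distance_um long-distance band edge for network statistics.
#' @param adjacent_um,distant_um distance-profile band edges.
#' @param min_lag_frames smallest lag treated as a resolvable delay.
#' @param seed seed recorded in the manifest.
#' @return A `run_config` list.
#' @export
run_config <- function(frame_rate = 2, pixel_size = 420 / 512,
                       box_t = 3L, box_h = 3L, box_w = 3L,
                       k_sigma = 3,
                       smoothing_sigma = 2, h_min_frac = 0.10,
                       min_cell_area = 30L,
                       eps_t = 2L, min_pts = 5L, spatial_window = 16L,
                       min_event_size = 50L,
                       window_w = 12L, max_lag = 20L,
                       threshold = 0.3, calibrate = FALSE,
                       baseline_distance_um = 100,
                       long_distance_um = 100,
                       adjacent_um = 40, distant_um = 300,
                       min_lag_frames = 1L,
                       resting_correction = TRUE,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
save_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, vals)
}

#' Run the full analysis pipeline on an activity / cell-free pair
#'
#' Executes the complete sequence: offset subtraction, denoising, baseline
#' and adaptive threshold from the cell-free stack, activity masking,
#' spatiotemporal event clustering, watershed segmentation on the
#' long-exposure image, event-to-cell assignment, per-cell traces, activity
#' and spectral statistics, lagged-correlation analysis and network
#' construction for both trace kinds. With `out_dir` set, every product is
#' written (CSV / GraphML / JSON) together with a manifest; reruns with the
#' same inputs and configuration are byte-identical.
#'
#' @param activity,cellfree [image_stack()]s, or paths to TIFF stacks.
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return A `pipeline_result` list: `cells`, `events`, `traces`
#'   (intensity), `traces_event_size`, `activity_summary`, `spectral`,
#'   `pairs`, `network`, `stats`, and the event-size-trace counterparts
#'   `pairs_event_size`, `network_event_size`, `stats_event_size`, plus
#'   `threshold_used` and `config`.
#' @export
run_pipeline <- function(activity, cellfree, config = run_config(),
                         out_dir = NULL) {
  if (is.character(activity))
    activity <- load_stack(activity, config$frame_rate, config$pixel_size, "activity")
  if (is.character(cellfree))
    cellfree <- load_stack(cellfree, config$frame_rate, config$pixel_size, "cellfree")
  check_paired(activity, cellfree)
  box <- c(config$box_t, config$box_h, config$box_w)
  fr <- attr(activity, "frame_rate")
  ps <- attr(activity, "pixel_size")

  off <- subtract_offset(activity, cellfree)
  den <- denoise(off, box)
  rm(off)
  baseline <- estimate_baseline(cellfree, box)
  rel <- relative_signal(den, baseline, already_offset = TRUE)
  if (isTRUE(config$resting_correction))
    rel <- subtract_resting(rel, resting_level(rel))
  thr <- adaptive_threshold(cellfree, baseline, config$k_sigma, box)
  mask <- detect_activity(rel, thr)

  cells <- segment_astrocytes(long_exposure(den), ps,
                              smoothing_sigma = config$smoothing_sigma,
                              h_min_frac = config$h_min_frac,
                              min_cell_area = config$min_cell_area)
  rm(den); invisible(gc(verbose = FALSE))
  events <- cluster_events(mask, rel, eps_t = config$eps_t,
                           min_pts = config$min_pts,
                           spatial_window = config$spatial_window)
  events <- assign_events(events, cells, rel, min_size = config$min_event_size)
  rm(mask); invisible(gc(verbose = FALSE))

  minutes <- dim(activity)[1] / fr / 60
  n_cells <- nrow(cells$cells)
  tr_int <- build_traces(rel, cells, kind = "intensity")
  tr_ev <- build_traces(rel, cells, events, kind = "event_size")
  rm(rel); invisible(gc(verbose = FALSE))
  summary <- if (n_cells > 0)
    oscillation_stats(events, n_cells, minutes, fr) else NULL
  spectral <- if (n_cells > 0 && dim(activity)[1] >= 32 &&
                  any(apply(unclass(tr_int), 2, stats::sd) > 0))
    spectral_bounds(tr_int, fr) else NULL

  analyse_kind <- function(tr) {
    if (n_cells < 2) return(list(pairs = NULL, network = NULL, stats = NULL,
                                 threshold = config$threshold))
    pairs <- pair_correlations(tr, cells, config$window_w, config$max_lag)
    th <- calibrate_threshold(pairs, config$baseline_distance_um,
                              default = config$threshold,
                              enabled = isTRUE(config$calibrate))
    net <- build_network(pairs, cells, threshold = as.numeric(th),
                         min_lag_frames = config$min_lag_frames)
    list(pairs = pairs, network = net,
         stats = network_stats(net, config$long_distance_um, fr),
         threshold = as.numeric(th))
  }
  a_int <- analyse_kind(tr_int)
  a_ev <- analyse_kind(tr_ev)

  res <- structure(list(cells = cells, events = events,
                        traces = tr_int, traces_event_size = tr_ev,
                        activity_summary = summary, spectral = spectral,
                        pairs = a_int$pairs, network = a_int$network,
                        stats = a_int$stats,
                        pairs_event_size = a_ev$pairs,
                        network_event_size = a_ev$network,
                        stats_event_size = a_ev$stats,
                        threshold_used = a_int$threshold,
                        frame_rate = fr, pixel_size = ps,
                        config = config),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

stats_as_list <- function(s) lapply(unclass(s), function(v) if (is.null(v)) NA else v)

#' Write every pipeline product to a directory
#'
#' @param res `pipeline_result`.
#' @param out_dir directory (created if needed).
#' @return Invisibly the manifest list.
#' @export
write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  files <- character(0)
  wcsv <- function(df, f) {
    utils::write.csv(df, p(f), row.names = FALSE)
    files <<- c(files, f)
  }
  wcsv(res$cells$cells, "cells.csv")
  if (nrow(res$cells$cells) > 0) {
    tiff::writeTIFF(res$cells$labels / 65535, p("cell_labels.tif"),
                    bits.per.sample = 16L)
    files <- c(files, "cell_labels.tif")
  }
  wcsv(events_table(res$events, res$frame_rate), "events.csv")
  tr <- as.data.frame(unclass(res$traces))
  names(tr) <- paste0("cell_", seq_len(ncol(tr)))
  wcsv(cbind(frame = seq_len(nrow(tr)), tr), "traces_intensity.csv")
  if (!is.null(res$pairs)) {
    wcsv(as.data.frame(res$pairs), "pair_correlations.csv")
    wcsv(distance_correlation_profile(res$pairs,
                                      res$config$adjacent_um,
                                      res$config$distant_um),
         "distance_correlation_profile.csv")
  }
  for (kind in c("", "_event_size")) {
    net <- res[[paste0("network", kind)]]
    if (is.null(net)) next
    wcsv(net$edges, paste0("network_edges", kind, ".csv"))
    gml <- paste0("network", kind, ".graphml")
    igraph::write_graph(as_igraph(net, directed = TRUE), p(gml),
                        format = "graphml")
    files <- c(files, gml)
  }
  st <- list()
  if (!is.null(res$stats)) st$intensity <- stats_as_list(res$stats)
  if (!is.null(res$stats_event_size))
    st$event_size <- stats_as_list(res$stats_event_size)
  if (!is.null(res$activity_summary)) {
    a <- res$activity_summary
    st$activity <- list(pct_working_cells = a$pct_working_cells,
                        n_cells = a$n_cells, n_events = a$n_events,
                        freq = a$freq_desc, duration = a$duration_desc)
  }
  if (!is.null(res$spectral))
    st$spectral <- list(f_low = res$spectral$f_low, f_high = res$spectral$f_high)
  st$threshold_used <- res$threshold_used
  jsonlite::write_json(st, p("stats.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, "stats.json")
  manifest <- list(package = "astronet",
                   version = as.character(utils::packageVersion("astronet")),
                   config = unclass(res$config), outputs = sort(files))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Simulate a culture and (optionally) write it as an on-disk fixture
#'
#' Thin wrapper over [regime_presets()] / [generate_culture()] with the same
#' determinism contract: the seed fully determines the fixture.
#'
#' @param preset preset name or a [culture_config()].
#' @param seed integer seed (ignored when a full config is given).
#' @param out_dir optional directory: writes `activity.tif`, `cellfree.tif`,
#'   ground-truth tables, the generator config and a manifest.
#' @param n_cells number of cells for preset configs.
#' @return The [generate_culture()] result.
#' @export
simulate_culture <- function(preset = "control", seed = 1L, out_dir = NULL,
                             n_cells = 30L) {
  cfg <- if (inherits(preset, "culture_config")) preset
         else regime_presets(preset, n_cells = n_cells, seed = seed)
  sim <- generate_culture(cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    write_stack(sim$activity, p("activity.tif"))
    write_stack(sim$cellfree, p("cellfree.tif"))
    utils::write.csv(sim$truth$cells, p("truth_cells.csv"), row.names = FALSE)
    utils::write.csv(sim$truth$events, p("truth_events.csv"), row.names = FALSE)
    utils::write.csv(sim$truth$coupling, p("truth_coupling.csv"), row.names = FALSE)
    jsonlite::write_json(unclass(cfg), p("culture_config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(list(package = "astronet",
                              version = as.character(utils::packageVersion("astronet")),
                              seed = cfg$seed, regime = cfg$regime,
                              outputs = c("activity.tif", "cellfree.tif",
                                          "truth_cells.csv", "truth_events.csv",
                                          "truth_coupling.csv",
                                          "culture_config.json")),
                         p("manifest.json"), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  sim
}
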