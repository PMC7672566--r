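#' Configuration of a synthetic astrocyte culture
#'
#' Describes a simulated recording: field geometry, cell placement, calcium
#' transient kinetics, sensor noise and the ground-truth coupling structure.
#' Coupling is modelled as *assemblies*: groups of cells that fire as a unit.
#' Each assembly initiates events as a Poisson process; at each initiation
#' every member participates independently with probability `participation`
#' and fires with a fixed member-specific delay (`delay_step_frames` times
#' its activation rank), so every coupled pair has a single exact
#' ground-truth lag and a leader. The ground-truth coupling graph is the
#' transitive closure of the activation order within each assembly — a
#' correlation method cannot distinguish direct from relayed coupling, so the
#' closure is the fair reference for edge recovery.
#'
#' @param n_cells number of cells.
#' @param field_px field side in pixels (square field).
#' @param field_um field side in micrometres.
#' @param frame_rate Hz.
#' @param duration_s recording length in seconds.
#' @param cell_radius_um cell footprint radius (compact Gaussian support).
#' @param min_separation_um smallest allowed centre distance.
#' @param event_rate_per_min expected calcium events per cell per minute.
#' @param amplitude_dff transient peak amplitude in dF/F units.
#' @param rise_s,decay_s double-exponential transient time constants.
#' @param noise_sigma sensor noise sd in relative (dF/F) units; the
#'   transient SNR is `amplitude_dff / noise_sigma`.
#' @param baseline_level mean fluorescence of the cell-free medium (a.u.).
#' @param cell_brightness static cell brightness at the footprint centre, as
#'   a fraction of `baseline_level` (makes cells visible in the
#'   long-exposure image).
#' @param layout `"uniform"` or `"clustered"` cell placement.
#' @param n_groups number of spatial groups / assemblies.
#' @param group_spread_um disc radius of a clustered group.
#' @param coupling `"none"`, `"groups"` (assemblies = spatial groups) or
#'   `"random_groups"` (assemblies drawn irrespective of position).
#' @param participation per-event member participation probability.
#' @param delay_step_frames frames between consecutive activation ranks.
#' @param regime free-text regime tag.
#' @param seed integer; fully determines the generated culture.
#' @return A `culture_config` list.
#' @export
culture_config <- function(n_cells = 30L,
                           field_px = 160L,
                           field_um = 420,
                           frame_rate = 2,
                           duration_s = 600,
                           cell_radius_um = 16,
                           min_separation_um = 36,
                           event_rate_per_min = 2,
                           amplitude_dff = 1,
                           rise_s = 1,
                           decay_s = 6,
                           noise_sigma = 0.2,
                           baseline_level = 100,
                           cell_brightness = 0.5,
                           layout = c("uniform", "clustered"),
                           n_groups = 0L,
                           group_spread_um = 110,
                           coupling = c("none", "groups", "random_groups"),
                           participation = 0.9,
                           delay_step_frames = 2L,
                           regime = "custom",
                           seed = 1L) {
  cfg <- list(n_cells = as.integer(n_cells), field_px = as.integer(field_px),
              field_um = field_um, frame_rate = frame_rate,
              duration_s = duration_s, cell_radius_um = cell_radius_um,
              min_separation_um = min_separation_um,
              event_rate_per_min = event_rate_per_min,
              amplitude_dff = amplitude_dff, rise_s = rise_s, decay_s = decay_s,
              noise_sigma = noise_sigma, baseline_level = baseline_level,
              cell_brightness = cell_brightness,
              layout = match.arg(layout), n_groups = as.integer(n_groups),
              group_spread_um = group_spread_um,
              coupling = match.arg(coupling),
              participation = participation,
              delay_step_frames = as.integer(delay_step_frames),
              regime = regime, seed = as.integer(seed))
  stopifnot(cfg$n_cells >= 1, cfg$field_px >= 8, cfg$field_um > 0,
            cfg$frame_rate > 0, cfg$duration_s > 0,
            cfg$event_rate_per_min >= 0, cfg$noise_sigma >= 0,
            cfg$participation > 0, cfg$participation <= 1)
  if (cfg$min_separation_um < 2 * cfg$cell_radius_um)
    stopf("min_separation_um must be at least twice cell_radius_um (no overlap)")
  class(cfg) <- "culture_config"
  cfg
}

#' Regime presets for the synthetic generator
#'
#' Three study conditions, calibrated against the magnitudes reported for
#' cultured astrocytes. `"control"`: 2.0 events/min, three spatially
#' clustered assemblies — short-range coupling with the occasional pair
#' stretching beyond 100 um. `"atp"`: elevated rate (2.9 events/min) and two
#' field-spanning assemblies, i.e. abundant long-range coupling. `"ischemia"`:
#' events persist (1.6 events/min) but the coupling graph is empty.
#'
#' @param name `"control"`, `"atp"` or `"ischemia"`.
#' @param n_cells number of cells (default 30).
#' @param seed integer seed.
#' @return A [culture_config()].
#' @export
regime_presets <- function(name, n_cells = 30L, seed = 1L) {
  switch(name,
    control = culture_config(n_cells = n_cells, event_rate_per_min = 2.0,
                             layout = "clustered", n_groups = 3L,
                             group_spread_um = 110, coupling = "groups",
                             participation = 0.9, delay_step_frames = 2L,
                             regime = "control", seed = seed),
    atp = culture_config(n_cells = n_cells, event_rate_per_min = 2.9,
                         layout = "uniform", n_groups = 2L,
                         coupling = "random_groups",
                         participation = 0.9, delay_step_frames = 1L,
                         regime = "atp", seed = seed),
    ischemia = culture_config(n_cells = n_cells, event_rate_per_min = 1.6,
                              layout = "uniform", coupling = "none",
                              regime = "ischemia", seed = seed),
    stopf("unknown regime preset '%s'", name))
}

# Rejection-sample points with a minimum pairwise distance inside a window.
sample_separated <- function(n, lo_x, hi_x, lo_y, hi_y, min_sep,
                             center = NULL, radius = NULL, max_tries = 20000L) {
  pts <- matrix(NA_real_, n, 2)
  got <- 0L
  for (i in seq_len(max_tries)) {
    p <- c(stats::runif(1, lo_x, hi_x), stats::runif(1, lo_y, hi_y))
    if (!is.null(center) && sqrt(sum((p - center)^2)) > radius) next
    if (got > 0L) {
      d2 <- (pts[seq_len(got), 1] - p[1])^2 + (pts[seq_len(got), 2] - p[2])^2
      if (min(d2) < min_sep^2) next
    }
    got <- got + 1L
    pts[got, ] <- p
    if (got == n) return(pts)
  }
  stopf("infeasible geometry: could not place %d cells with %g um separation", n, min_sep)
}

# Double-exponential transient kernel sampled at the frame rate, peak = 1.
transient_kernel <- function(rise_s, decay_s, frame_rate) {
  tt <- seq(0, rise_s + 8 * decay_s, by = 1 / frame_rate)
  k <- (1 - exp(-tt / rise_s)) * exp(-tt / decay_s)
  k / max(k)
}

place_cells <- function(cfg) {
  margin <- cfg$cell_radius_um + 2 * cfg$field_um / cfg$field_px
  lo <- margin; hi <- cfg$field_um - margin
  if (cfg$layout == "uniform") {
    centers <- sample_separated(cfg$n_cells, lo, hi, lo, hi, cfg$min_separation_um)
    group <- rep(0L, cfg$n_cells)
  } else {
    ng <- max(1L, cfg$n_groups)
    anchors <- matrix(c(0.27, 0.30, 0.73, 0.30, 0.50, 0.75, 0.25, 0.72),
                      ncol = 2, byrow = TRUE)[seq_len(min(ng, 4L)), , drop = FALSE]
    if (ng > 4L) stopf("clustered layout supports at most 4 groups")
    sizes <- rep(cfg$n_cells %/% ng, ng)
    if (cfg$n_cells %% ng) sizes[seq_len(cfg$n_cells %% ng)] <-
        sizes[seq_len(cfg$n_cells %% ng)] + 1L
    centers <- NULL; group <- integer(0)
    for (g in seq_len(ng)) {
      ctr <- anchors[g, ] * cfg$field_um
      pg <- sample_separated(sizes[g],
                             max(lo, ctr[1] - cfg$group_spread_um),
                             min(hi, ctr[1] + cfg$group_spread_um),
                             max(lo, ctr[2] - cfg$group_spread_um),
                             min(hi, ctr[2] + cfg$group_spread_um),
                             cfg$min_separation_um,
                             center = ctr, radius = cfg$group_spread_um)
      # keep groups pairwise separated too
      if (!is.null(centers)) {
        d <- sqrt(outer(pg[, 1], centers[, 1], "-")^2 +
                    outer(pg[, 2], centers[, 2], "-")^2)
        if (min(d) < cfg$min_separation_um)
          return(NULL)   # retry from the caller
      }
      centers <- rbind(centers, pg)
      group <- c(group, rep(g, sizes[g]))
    }
    centers <- cbind(centers[, 1], centers[, 2])
  }
  list(centers = centers, group = group)
}

#' Generate a synthetic culture: movie, cell-free stack and ground truth
#'
#' Renders cells as compact 2-D Gaussian footprints on a homogeneous
#' background, schedules calcium transients (Poisson per cell, or per
#' assembly with fixed activation-order delays and Bernoulli participation),
#' adds i.i.d. Gaussian sensor noise, and produces a matched cell-free stack
#' drawn from the same noise law. The seed fully determines the output.
#'
#' @param config a [culture_config()].
#' @param render if `FALSE`, skip movie rendering and return ground truth
#'   only (placement, schedules, clean traces) — useful for statistical
#'   checks at scale.
#' @return List with `activity` and `cellfree` ([image_stack()]s; `NULL`
#'   when `render = FALSE`) and `truth`: `cells` (data.frame), `labels`
#'   (H x W), `events` (data.frame `event_id, cell_id, assembly, t_onset,
#'   t_start, t_end, amplitude`), `coupling` (data.frame `from, to,
#'   delay_frames, transfer_prob`), `traces` (clean T x N dF/F matrix),
#'   `config`.
#' @export
generate_culture <- function(config, render = TRUE) {
  cfg <- config
  set.seed(cfg$seed)
  ps <- cfg$field_um / cfg$field_px
  T_ <- as.integer(round(cfg$duration_s * cfg$frame_rate))
  H <- cfg$field_px; W <- cfg$field_px

  placement <- NULL
  for (try in 1:50) {
    placement <- place_cells(cfg)
    if (!is.null(placement)) break
  }
  if (is.null(placement)) stopf("infeasible geometry for clustered layout")
  centers <- placement$centers
  group <- placement$group

  # assemblies
  assembly <- rep(0L, cfg$n_cells)
  if (cfg$coupling == "groups") assembly <- group
  if (cfg$coupling == "random_groups")
    assembly <- as.integer(sample(rep(seq_len(max(1L, cfg$n_groups)),
                                      length.out = cfg$n_cells)))
  # activation rank within each assembly, in member-index order
  delay <- rep(0L, cfg$n_cells)
  for (g in setdiff(unique(assembly), 0L)) {
    mem <- which(assembly == g)
    delay[mem] <- (seq_along(mem) - 1L) * cfg$delay_step_frames
  }

  # Transient kernel. Ground-truth event extent: the transient's visible
  # support, frames where the clean kernel is at least 5% of its peak. An
  # extended event stays detectable while any of the cell's brighter pixels
  # still cross the activity threshold, which holds down to a few per cent
  # of the peak amplitude.
  ker <- transient_kernel(cfg$rise_s, cfg$decay_s, cfg$frame_rate)
  dur10 <- max(which(ker >= 0.05))

  # schedules
  ev <- list(); traces <- matrix(0, T_, cfg$n_cells)
  add_event <- function(cell, onset) {
    idx <- onset:min(T_, onset + length(ker) - 1L)
    traces[idx, cell] <<- traces[idx, cell] + cfg$amplitude_dff * ker[seq_along(idx)]
    ev[[length(ev) + 1L]] <<- c(cell, onset)
  }
  mins <- cfg$duration_s / 60
  for (g in setdiff(unique(assembly), 0L)) {
    mem <- which(assembly == g)
    n_init <- stats::rpois(1, cfg$event_rate_per_min / cfg$participation * mins)
    t_init <- sort(sample.int(T_, n_init, replace = TRUE))
    for (t0 in t_init) for (m in mem)
      if (stats::runif(1) <= cfg$participation) {
        on <- t0 + delay[m]
        if (on <= T_) add_event(m, on)
      }
  }
  for (cell in which(assembly == 0L)) {
    n_ev <- stats::rpois(1, cfg$event_rate_per_min * mins)
    for (t0 in sort(sample.int(T_, n_ev, replace = TRUE))) add_event(cell, t0)
  }
  events <- if (length(ev)) {
    m <- do.call(rbind, ev)
    o <- order(m[, 1], m[, 2])
    data.frame(event_id = seq_len(nrow(m)), cell_id = m[o, 1],
               assembly = assembly[m[o, 1]], t_onset = m[o, 2],
               t_start = m[o, 2],
               t_end = pmin(T_, m[o, 2] + dur10 - 1L),
               amplitude = cfg$amplitude_dff)
  } else data.frame(event_id = integer(), cell_id = integer(),
                    assembly = integer(), t_onset = integer(),
                    t_start = integer(), t_end = integer(),
                    amplitude = numeric())

  # ground-truth coupling graph: transitive closure of activation order
  cp <- list()
  for (g in setdiff(unique(assembly), 0L)) {
    mem <- which(assembly == g)
    if (length(mem) > 1L)
      for (i in mem) for (j in mem)
        if (delay[j] > delay[i])
          cp[[length(cp) + 1L]] <- c(i, j, delay[j] - delay[i])
  }
  coupling <- if (length(cp)) {
    m <- do.call(rbind, cp)
    data.frame(from = m[, 1], to = m[, 2], delay_frames = m[, 3],
               transfer_prob = cfg$participation)
  } else data.frame(from = integer(), to = integer(),
                    delay_frames = integer(), transfer_prob = numeric())

  # label map & cell table
  r_px <- cfg$cell_radius_um / ps
  sig_px <- r_px / 2
  crow <- centers[, 2] / ps + 1   # y -> row, 0-based um -> 1-based px
  ccol <- centers[, 1] / ps + 1
  labels <- matrix(0L, H, W)
  foot <- vector("list", cfg$n_cells)
  for (i in seq_len(cfg$n_cells)) {
    rr <- max(1L, floor(crow[i] - r_px)):min(H, ceiling(crow[i] + r_px))
    cc <- max(1L, floor(ccol[i] - r_px)):min(W, ceiling(ccol[i] + r_px))
    d2 <- outer((rr - crow[i])^2, (cc - ccol[i])^2, "+")
    inside <- d2 <= r_px^2
    pix <- (rep(cc, each = length(rr)) - 1L) * H + rep(rr, length(cc))
    pix <- pix[inside]
    labels[pix] <- i
    foot[[i]] <- list(pix = pix, w = exp(-d2[inside] / (2 * sig_px^2)))
  }
  cells <- data.frame(cell_id = seq_len(cfg$n_cells),
                      row = crow, col = ccol,
                      x_um = centers[, 1], y_um = centers[, 2],
                      area_px = vapply(foot, function(f) length(f$pix), integer(1)))

  truth <- list(cells = cells, labels = labels, events = events,
                coupling = coupling, traces = traces, assembly = assembly,
                delay = delay, config = cfg)
  if (!render)
    return(list(activity = NULL, cellfree = NULL, truth = truth))

  B <- cfg$baseline_level
  act <- matrix(0, T_, H * W)
  for (i in seq_len(cfg$n_cells)) {
    f <- foot[[i]]
    act[, f$pix] <- act[, f$pix] +
      outer(traces[, i], f$w) + rep(cfg$cell_brightness * f$w, each = T_)
  }
  act <- B * (1 + act) + stats::rnorm(length(act), 0, cfg$noise_sigma * B)
  dim(act) <- c(T_, H, W)
  cf <- B + stats::rnorm(T_ * H * W, 0, cfg$noise_sigma * B)
  dim(cf) <- c(T_, H, W)
  list(activity = image_stack(pmax(act, 0), cfg$frame_rate, ps, "activity"),
       cellfree = image_stack(pmax(cf, 0), cfg$frame_rate, ps, "cellfree"),
       truth = truth)
}
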