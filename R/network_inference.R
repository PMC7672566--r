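#' Detrend a calcium trace with a trailing moving average
#'
#' Removes slow baseline drift by subtracting, at every frame `k`, the mean
#' of the signal over the trailing window `[k - w, k]` (inclusive, `w + 1`
#' samples). The first `w` frames have no full window and are flagged as
#' warm-up (`NA`); correlation sums exclude them. A short window acts as a
#' high-pass that emphasises transient onsets, which sharpens lag
#' identification and suppresses spurious lagged correlations between
#' independent cells.
#'
#' @param x numeric trace (length T) or a single `cell_traces` column.
#' @param window_w window size in frames (>= 2, < T).
#' @return A `detrended_trace`: numeric vector of length T whose first
#'   `window_w` entries are `NA`, with attribute `window_w`.
#' @export
detrend_trace <- function(x, window_w = 12L) {
  x <- as.numeric(x)
  w <- as.integer(window_w)
  if (w < 2L) stopf("`window_w` must be at least 2 frames")
  n <- length(x)
  if (n <= w) stopf("trace too short for window_w = %d (T = %d)", w, n)
  cs <- cumsum(x)
  k <- (w + 1L):n
  out <- rep(NA_real_, n)
  out[k] <- x[k] - (cs[k] - c(0, cs)[k - w]) / (w + 1)
  structure(out, window_w = w, class = "detrended_trace")
}

# Detrend every column of a T x N trace matrix at once.
detrend_matrix <- function(tr, window_w) {
  w <- as.integer(window_w)
  n <- nrow(tr)
  if (n <= w) stopf("traces too short for window_w = %d", w)
  cs <- col_cumsum(tr)
  k <- (w + 1L):n
  top <- rbind(rep(0, ncol(tr)), cs[seq_len(n - w - 1L), , drop = FALSE])
  out <- matrix(NA_real_, n, ncol(tr))
  out[k, ] <- tr[k, , drop = FALSE] - (cs[k, , drop = FALSE] - top) / (w + 1)
  out
}

#' Uncentered correlation of two detrended traces
#'
#' The correlation statistic of the network method:
#' `rho = sum(a * b) / sqrt(sum(a^2) * sum(b^2))` over the common post-warm-up
#' samples — no additional mean subtraction beyond the detrending itself.
#'
#' @param a,b `detrended_trace` objects (or numeric vectors with `NA`
#'   warm-up prefixes) of equal length.
#' @param min_overlap smallest usable number of common samples.
#' @return Correlation in `[-1, 1]`, or `NA` if either input has zero norm
#'   (undefined correlation; such pairs are excluded upstream).
#' @export
trace_correlation <- function(a, b, min_overlap = 16L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stopf("traces must have equal length")
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < min_overlap) stopf("fewer than %d overlapping samples", min_overlap)
  aa <- a[ok]; bb <- b[ok]
  na2 <- sum(aa * aa); nb2 <- sum(bb * bb)
  if (na2 == 0 || nb2 == 0) return(NA_real_)
  sum(aa * bb) / sqrt(na2 * nb2)
}

#' Lag-maximised correlation between two cells
#'
#' Evaluates the uncentered correlation on lag-shifted overlapping segments
#' for every integer lag in `[-max_lag, max_lag]` and returns the maximising
#' lag and value. A positive `lag_star` means cell `i` (trace `a`) leads cell
#' `j` (trace `b`) by that many frames. Ties are broken toward the smallest
#' `|lag|`, then toward the negative lag.
#'
#' @param a,b `detrended_trace`s of equal length.
#' @param max_lag largest probed lag in frames (>= 0).
#' @param min_overlap smallest usable overlap after shifting.
#' @return List with `rho_max`, `lag_star`, `rho_zero`.
#' @export
lagged_max_correlation <- function(a, b, max_lag = 20L, min_overlap = 16L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stopf("traces must have equal length")
  n <- length(a)
  lags <- (-max_lag):max_lag
  lags <- lags[order(abs(lags), lags)]   # tie-break order
  s <- which(!is.na(a) & !is.na(b))[1]
  if (is.na(s)) stopf("no overlapping samples")
  rho_best <- -Inf; lag_best <- NA_integer_; rho0 <- NA_real_
  for (l in lags) {
    if (l >= 0) { ia <- s:(n - l); ib <- ia + l } else { ib <- s:(n + l); ia <- ib - l }
    if (length(ia) < min_overlap)
      stopf("overlap below %d samples at lag %d", min_overlap, l)
    aa <- a[ia]; bb <- b[ib]
    na2 <- sum(aa * aa); nb2 <- sum(bb * bb)
    r <- if (na2 == 0 || nb2 == 0) NA_real_ else sum(aa * bb) / sqrt(na2 * nb2)
    if (l == 0L) rho0 <- r
    if (!is.na(r) && r > rho_best) { rho_best <- r; lag_best <- l }
  }
  if (!is.finite(rho_best)) return(list(rho_max = NA_real_, lag_star = NA_integer_,
                                        rho_zero = NA_real_))
  list(rho_max = rho_best, lag_star = lag_best, rho_zero = rho0)
}

#' Lagged correlations for every cell pair
#'
#' Detrends all traces and computes the lag-maximised correlation and the
#' centroid distance for every unordered cell pair. Pairs with an undefined
#' correlation (a silent cell) are kept with `NA` entries and excluded from
#' network construction.
#'
#' @param traces `cell_traces` T x N matrix.
#' @param cells `cell_label_map` (for centroid distances), or `NULL` to skip
#'   distances.
#' @param window_w detrending window (frames).
#' @param max_lag largest probed lag (frames).
#' @return A `pair_correlations` data.frame: `cell_i, cell_j, rho_max,
#'   lag_star, rho_zero, distance_um`.
#' @export
pair_correlations <- function(traces, cells = NULL, window_w = 12L, max_lag = 20L) {
  tr <- unclass(traces)
  n <- ncol(tr)
  dt <- detrend_matrix(tr, window_w)
  dmat <- if (!is.null(cells)) cell_distances(cells) else matrix(NA_real_, n, n)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  out <- data.frame(cell_i = pairs[, 1], cell_j = pairs[, 2],
                    rho_max = NA_real_, lag_star = NA_integer_,
                    rho_zero = NA_real_, distance_um = dmat[pairs])
  for (k in seq_len(nrow(out))) {
    r <- lagged_max_correlation(dt[, out$cell_i[k]], dt[, out$cell_j[k]],
                                max_lag = max_lag)
    out$rho_max[k] <- r$rho_max
    out$lag_star[k] <- r$lag_star
    out$rho_zero[k] <- r$rho_zero
  }
  attr(out, "window_w") <- as.integer(window_w)
  attr(out, "max_lag") <- as.integer(max_lag)
  attr(out, "trace_kind") <- attr(traces, "kind")
  class(out) <- c("pair_correlations", "data.frame")
  out
}

#' Distance-calibrated correlation threshold
#'
#' Estimates the spurious-correlation baseline from cell pairs separated by
#' at least `min_baseline_distance_um` (beyond direct astrocyte contact) and
#' returns its 95th percentile. With calibration disabled, or with fewer than
#' 10 distant pairs, the documented fixed default 0.3 is returned.
#'
#' @param pairs `pair_correlations`.
#' @param min_baseline_distance_um baseline distance (default 100 um).
#' @param default fixed threshold when calibration is off or infeasible.
#' @param enabled logical; `FALSE` returns `default` unconditionally.
#' @return Threshold value; attribute `calibrated` records the path taken.
#' @export
calibrate_threshold <- function(pairs, min_baseline_distance_um = 100,
                                default = 0.3, enabled = TRUE) {
  if (!enabled) return(structure(default, calibrated = FALSE))
  far <- pairs$rho_max[!is.na(pairs$rho_max) &
                         !is.na(pairs$distance_um) &
                         pairs$distance_um >= min_baseline_distance_um]
  if (length(far) < 10L) {
    message("calibrate_threshold: fewer than 10 distant pairs; using default ", default)
    return(structure(default, calibrated = FALSE))
  }
  structure(as.numeric(stats::quantile(far, 0.95, type = 7)), calibrated = TRUE)
}

#' Build the functional astrocyte network
#'
#' Nodes are all segmented cells (isolated nodes retained); an edge joins
#' every pair whose lag-maximised correlation exceeds the threshold. An edge
#' is directed — from the leading cell to the lagging one — when
#' `|lag_star| >= min_lag_frames`; zero-lag (sub-resolution) edges stay
#' undirected.
#'
#' @param pairs `pair_correlations`.
#' @param cells `cell_label_map`.
#' @param threshold correlation threshold in (0, 1).
#' @param min_lag_frames smallest lag that counts as a resolvable delay.
#' @return An `astro_network`: list with `nodes`, `edges` (data.frame
#'   `from, to, rho_max, lag_frames, distance_um, directed`; `from` is the
#'   leader of a directed edge), `threshold`, `min_lag_frames`, `pairs`,
#'   `trace_kind`.
#' @export
build_network <- function(pairs, cells, threshold = 0.3, min_lag_frames = 1L) {
  if (!(threshold > 0 && threshold < 1)) stopf("threshold must lie in (0, 1)")
  sel <- !is.na(pairs$rho_max) & pairs$rho_max > threshold
  e <- pairs[sel, , drop = FALSE]
  directed <- abs(e$lag_star) >= min_lag_frames
  lead_i <- e$lag_star >= 0
  edges <- data.frame(
    from = ifelse(directed & !lead_i, e$cell_j, e$cell_i),
    to = ifelse(directed & !lead_i, e$cell_i, e$cell_j),
    rho_max = e$rho_max,
    lag_frames = abs(e$lag_star),
    distance_um = e$distance_um,
    directed = directed)
  rownames(edges) <- NULL
  structure(list(nodes = cells$cells, edges = edges,
                 threshold = as.numeric(threshold),
                 min_lag_frames = as.integer(min_lag_frames),
                 pairs = pairs,
                 trace_kind = attr(pairs, "trace_kind") %||% "intensity"),
            class = "astro_network")
}

#' @export
print.astro_network <- function(x, ...) {
  cat(sprintf("<astro_network> %d cells, %d edges (%d directed), threshold %.3g, %s traces\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$directed),
              x$threshold, x$trace_kind))
  invisible(x)
}

#' Convert an astro_network to an igraph graph
#'
#' @param net `astro_network`.
#' @param directed if `TRUE`, directed edges keep their orientation and
#'   undirected ones become mutual pairs; if `FALSE` (default) direction is
#'   ignored.
#' @return An igraph graph with node coordinates and edge attributes.
#' @export
as_igraph <- function(net, directed = FALSE) {
  g <- igraph::make_empty_graph(n = nrow(net$nodes), directed = directed)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(net$nodes$cell_id))
  g <- igraph::set_vertex_attr(g, "x_um", value = net$nodes$x_um)
  g <- igraph::set_vertex_attr(g, "y_um", value = net$nodes$y_um)
  e <- net$edges
  if (nrow(e) > 0) {
    el <- rbind(cbind(e$from, e$to),
                if (directed) cbind(e$to[!e$directed], e$from[!e$directed]))
    attrs <- rbind(e[, c("rho_max", "lag_frames", "distance_um", "directed")],
                   if (directed) e[!e$directed, c("rho_max", "lag_frames",
                                                  "distance_um", "directed")])
    g <- igraph::add_edges(g, t(el), rho_max = attrs$rho_max,
                           lag_frames = attrs$lag_frames,
                           distance_um = attrs$distance_um,
                           directed_edge = attrs$directed)
  }
  g
}

#' Summary statistics of a functional astrocyte network
#'
#' @param net `astro_network`.
#' @param long_distance_um distance from which an edge counts as
#'   long-distance (default 100 um, the beyond-direct-contact scale).
#' @param frame_rate Hz, for converting lags to propagation speeds.
#' @return A `network_stats` list: `n_edges_total`,
#'   `mean_connections_per_cell`, `mean_long_distance_connections_per_cell`,
#'   `mean_rho_max` (over all evaluated pairs), `giant_component_fraction`,
#'   `n_components`, `mean_propagation_speed_um_s` (over directed edges;
#'   `NA` when there are none).
#' @export
network_stats <- function(net, long_distance_um = 100, frame_rate = 2) {
  n <- nrow(net$nodes)
  e <- net$edges
  g <- as_igraph(net, directed = FALSE)
  comp <- igraph::components(g)
  long_e <- sum(!is.na(e$distance_um) & e$distance_um >= long_distance_um)
  dir_e <- e[e$directed & e$lag_frames > 0, , drop = FALSE]
  speed <- if (nrow(dir_e) > 0)
    mean(dir_e$distance_um / (dir_e$lag_frames / frame_rate)) else NA_real_
  structure(list(
    n_edges_total = nrow(e),
    mean_connections_per_cell = if (n > 0) 2 * nrow(e) / n else NA_real_,
    mean_long_distance_connections_per_cell = if (n > 0) 2 * long_e / n else NA_real_,
    mean_rho_max = mean(net$pairs$rho_max, na.rm = TRUE),
    giant_component_fraction = if (n > 0) max(comp$csize) / n else NA_real_,
    n_components = comp$no,
    mean_propagation_speed_um_s = speed,
    long_distance_um = long_distance_um),
    class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf(paste0("edges %d | connections/cell %.3g | long-distance (>=%g um)/cell %.3g\n",
                     "mean rho_max %.3g | giant component %.3g | components %d | speed %s um/s\n"),
              x$n_edges_total, x$mean_connections_per_cell, x$long_distance_um,
              x$mean_long_distance_connections_per_cell, x$mean_rho_max,
              x$giant_component_fraction, x$n_components,
              if (is.na(x$mean_propagation_speed_um_s)) "NA"
              else fmt_signif3(x$mean_propagation_speed_um_s)))
  invisible(x)
}

#' Distance-correlation profile with distance-band labels
#'
#' Annotates each cell pair as `adjacent` (closer than the typical astrocyte
#' size), `intermediate`, or `distant`, for distance-correlation scatter
#' reports. Band edges are half-open `[lo, hi)`: a pair exactly at the
#' adjacent edge is intermediate.
#'
#' @param pairs `pair_correlations`.
#' @param adjacent_um,distant_um band edges (defaults 40 and 300 um).
#' @return data.frame `cell_i, cell_j, distance_um, rho_max, lag_star, band`.
#' @export
distance_correlation_profile <- function(pairs, adjacent_um = 40, distant_um = 300) {
  band <- cut(pairs$distance_um, c(-Inf, adjacent_um, distant_um, Inf),
              labels = c("adjacent", "intermediate", "distant"), right = FALSE)
  data.frame(cell_i = pairs$cell_i, cell_j = pairs$cell_j,
             distance_um = pairs$distance_um, rho_max = pairs$rho_max,
             lag_star = pairs$lag_star, band = as.character(band))
}
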