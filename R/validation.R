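#' Match segmented cells to ground-truth cells by centroid distance
#'
#' Greedy one-to-one matching in order of increasing centroid distance, with
#' a distance cap. Used to compare pipeline output against the synthetic
#' generator's ground truth.
#'
#' @param truth_cells,detected_cells data.frames with `cell_id, x_um, y_um`.
#' @param max_dist_um largest allowed match distance.
#' @return data.frame `truth_id, det_id, dist_um`, one row per match.
#' @export
match_cells <- function(truth_cells, detected_cells, max_dist_um = 15) {
  if (nrow(truth_cells) == 0L || nrow(detected_cells) == 0L)
    return(data.frame(truth_id = integer(), det_id = integer(), dist_um = numeric()))
  d <- sqrt(outer(truth_cells$x_um, detected_cells$x_um, "-")^2 +
              outer(truth_cells$y_um, detected_cells$y_um, "-")^2)
  out <- list()
  repeat {
    m <- which.min(d)
    if (!length(m) || d[m] > max_dist_um || !is.finite(d[m])) break
    i <- (m - 1L) %% nrow(d) + 1L
    j <- (m - 1L) %/% nrow(d) + 1L
    out[[length(out) + 1L]] <- data.frame(truth_id = truth_cells$cell_id[i],
                                          det_id = detected_cells$cell_id[j],
                                          dist_um = d[m])
    d[i, ] <- Inf; d[, j] <- Inf
  }
  if (!length(out)) return(data.frame(truth_id = integer(), det_id = integer(),
                                      dist_um = numeric()))
  do.call(rbind, out)
}

# Canonical undirected pair keys "a-b" with a < b.
pair_keys <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "-")

#' Edge precision and recall against a ground-truth coupling graph
#'
#' Detected network edges are mapped onto ground-truth cell ids via a cell
#' match, then compared (as undirected pairs) with the coupling graph.
#' Direction accuracy is assessed on the detected directed edges that are
#' true couplings: the detected leader must be the ground-truth source.
#'
#' @param net `astro_network` (built on detected cells).
#' @param coupling ground-truth coupling data.frame `from, to, delay_frames`.
#' @param cell_match result of [match_cells()]; `NULL` if ids already agree.
#' @return List: `precision`, `recall`, `n_detected`, `n_true`,
#'   `direction_accuracy`, `lag_accuracy` (fraction of true detected directed
#'   edges with exactly the ground-truth delay).
#' @export
edge_recovery <- function(net, coupling, cell_match = NULL) {
  e <- net$edges
  if (!is.null(cell_match)) {
    to_truth <- stats::setNames(cell_match$truth_id, cell_match$det_id)
    e <- e[as.character(e$from) %in% names(to_truth) &
             as.character(e$to) %in% names(to_truth), , drop = FALSE]
    e$from <- unname(to_truth[as.character(e$from)])
    e$to <- unname(to_truth[as.character(e$to)])
  }
  det <- unique(pair_keys(e$from, e$to))
  tru <- unique(pair_keys(coupling$from, coupling$to))
  tp <- intersect(det, tru)
  dir_e <- e[e$directed, , drop = FALSE]
  dir_keys <- pair_keys(dir_e$from, dir_e$to)
  on_true <- dir_keys %in% tru
  truth_dir <- paste(coupling$from, coupling$to)
  dir_ok <- paste(dir_e$from, dir_e$to) %in% truth_dir
  lag_ok <- rep(FALSE, nrow(dir_e))
  key_truth <- paste(coupling$from, coupling$to)
  mt <- match(paste(dir_e$from, dir_e$to), key_truth)
  lag_ok[!is.na(mt)] <- dir_e$lag_frames[!is.na(mt)] ==
    coupling$delay_frames[mt[!is.na(mt)]]
  list(precision = if (length(det)) length(tp) / length(det) else NA_real_,
       recall = if (length(tru)) length(tp) / length(tru) else NA_real_,
       n_detected = length(det), n_true = length(tru),
       direction_accuracy = if (any(on_true)) mean(dir_ok[on_true]) else NA_real_,
       lag_accuracy = if (any(on_true)) mean(lag_ok[on_true]) else NA_real_)
}

#' Event recall and temporal IoU against ground-truth transients
#'
#' Each ground-truth event is matched to detected events of the same
#' (mapped) cell that overlap it in time; recall is the matched fraction and
#' the temporal intersection-over-union is taken against the best-overlapping
#' detected event. Ground-truth extents use the generator's 10%-amplitude
#' convention.
#'
#' @param events detected `calcium_events` (after [assign_events()]).
#' @param truth_events generator truth data.frame (`cell_id, t_start, t_end`).
#' @param cell_match result of [match_cells()] mapping truth to detected
#'   cells; `NULL` if ids agree.
#' @return List: `recall`, `mean_iou`, `median_iou`, `n_truth`, `n_detected`,
#'   `detected_per_cell` (counts indexed by truth cell id).
#' @export
event_recovery <- function(events, truth_events, cell_match = NULL) {
  det_cell <- events$cell_id
  if (!is.null(cell_match)) {
    to_truth <- stats::setNames(cell_match$truth_id, cell_match$det_id)
    ok <- as.character(det_cell) %in% names(to_truth)
    events <- events[ok, , drop = FALSE]
    det_cell <- unname(to_truth[as.character(events$cell_id)])
  }
  n_truth_cells <- max(c(truth_events$cell_id, det_cell, 1L))
  per_cell <- tabulate(det_cell, nbins = n_truth_cells)
  n_tr <- nrow(truth_events)
  if (n_tr == 0L)
    return(list(recall = NA_real_, mean_iou = NA_real_, median_iou = NA_real_,
                n_truth = 0L, n_detected = nrow(events),
                detected_per_cell = per_cell))
  iou <- rep(NA_real_, n_tr)
  for (k in seq_len(n_tr)) {
    same <- which(det_cell == truth_events$cell_id[k])
    if (!length(same)) next
    s1 <- truth_events$t_start[k]; e1 <- truth_events$t_end[k]
    inter <- pmin(e1, events$t_end[same]) - pmax(s1, events$t_start[same]) + 1
    hit <- inter > 0
    if (!any(hit)) next
    uni <- (e1 - s1 + 1) + (events$t_end[same] - events$t_start[same] + 1) - inter
    iou[k] <- max(inter[hit] / uni[hit])
  }
  matched <- !is.na(iou)
  list(recall = mean(matched),
       mean_iou = if (any(matched)) mean(iou[matched]) else NA_real_,
       median_iou = if (any(matched)) stats::median(iou[matched]) else NA_real_,
       n_truth = n_tr, n_detected = nrow(events),
       detected_per_cell = per_cell)
}
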