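#' Supra-threshold activity mask
#'
#' Marks every voxel whose relative signal exceeds the per-pixel adaptive
#' threshold. The comparison is strict (`>`); pixels with an invalid
#' threshold (masked baseline) are never active.
#'
#' @param relative relative-signal [image_stack()].
#' @param thresholds a `threshold_map` from [adaptive_threshold()].
#' @return An `activity_mask`: list with `mask` (logical T x H x W),
#'   `k_sigma`, `frame_rate`.
#' @export
detect_activity <- function(relative, thresholds) {
  d <- dim(relative)
  thr <- thresholds$value
  if (!identical(as.integer(dim(thr)), d[2:3]))
    stopf("threshold map shape does not match the stack")
  m <- unclass(relative)
  dim(m) <- c(d[1], d[2] * d[3])
  mask <- m > rep(as.vector(thr), each = d[1])
  mask[is.na(mask)] <- FALSE
  dim(mask) <- d
  structure(list(mask = mask, k_sigma = thresholds$k_sigma,
                 frame_rate = attr(relative, "frame_rate")),
            class = "activity_mask")
}

# Candidate tile indices along one axis for positions pos (1-based), given
# window w and stride: each position lies in at most two tile windows.
tile_candidates <- function(pos, w, stride, extent) {
  k1 <- (pos - 1L) %/% stride
  k0 <- k1 - 1L
  k_max <- (extent - 1L) %/% stride
  k1[k1 > k_max] <- k_max
  list(k0 = k0, k1 = k1)
}

#' Cluster active voxels into discrete calcium events
#'
#' Space is partitioned into square tiles of side `spatial_window` with
#' half-window overlap; within each tile the active voxels are clustered
#' densely over the time axis (voxels join a cluster while consecutive active
#' frames are at most `eps_t` apart). Tile clusters with fewer than `min_pts`
#' voxels are discarded as noise; clusters from overlapping tiles that share
#' voxels are merged by voxel-set union. The procedure is deterministic.
#'
#' @param activity an `activity_mask` from [detect_activity()].
#' @param relative the relative-signal stack (for peak amplitudes); optional.
#' @param eps_t temporal reachability in frames (>= 1).
#' @param min_pts minimum cluster size in voxels (>= 1).
#' @param spatial_window tile side in pixels (>= 1).
#' @return A `calcium_events` object: data.frame with `event_id, cell_id,
#'   t_start, t_end, size_vox, peak_amplitude` plus a `footprints` attribute
#'   (list of integer matrices with columns `t, row, col`). `cell_id` is 0
#'   until [assign_events()].
#' @export
cluster_events <- function(activity, relative = NULL,
                           eps_t = 2L, min_pts = 5L, spatial_window = 16L) {
  stopifnot(eps_t >= 1L, min_pts >= 1L, spatial_window >= 1L)
  mask <- activity$mask
  d <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0L) return(empty_events(activity$frame_rate))
  t <- (idx - 1L) %% d[1] + 1L
  p <- (idx - 1L) %/% d[1]
  row <- p %% d[2] + 1L
  col <- p %/% d[2] + 1L
  w <- as.integer(spatial_window)
  stride <- max(1L, w %/% 2L)
  kr <- tile_candidates(row, w, stride, d[2])
  kc <- tile_candidates(col, w, stride, d[3])
  n_kc <- (d[3] - 1L) %/% stride + 2L   # tile-key base along columns

  tiles_l <- vector("list", 4L)
  vox_l <- vector("list", 4L)
  i <- 0L
  for (r_opt in c("k0", "k1")) for (c_opt in c("k0", "k1")) {
    krv <- kr[[r_opt]]; kcv <- kc[[c_opt]]
    ok <- krv >= 0L & kcv >= 0L &
      (krv * stride + w) >= row & (kcv * stride + w) >= col &
      (krv * stride) < row & (kcv * stride) < col
    i <- i + 1L
    tiles_l[[i]] <- as.integer(krv[ok] * n_kc + kcv[ok])
    vox_l[[i]] <- which(ok)
  }
  # the four (row, col) tile-offset combinations are distinct by
  # construction, so no (tile, voxel) pair repeats
  tile_m <- unlist(tiles_l, use.names = FALSE)
  vox_m <- unlist(vox_l, use.names = FALSE)
  rm(tiles_l, vox_l, kr, kc)

  ord <- order(tile_m, t[vox_m])
  tile_o <- tile_m[ord]
  vox_o <- vox_m[ord]
  rm(tile_m, vox_m, ord)
  t_o <- t[vox_o]

  # DBSCAN over the time axis within each tile: a frame is "core" when the
  # tile holds >= min_pts active voxels within +-eps_t of it; core frames
  # within eps_t of each other share a cluster; border frames attach to the
  # nearest core frame (ties toward the earlier one).
  tile_start <- c(TRUE, tile_o[-1] != tile_o[-length(tile_o)])
  tile_id <- cumsum(tile_start)
  clus <- integer(length(vox_o))
  n_clusters <- 0L
  idx_by_tile <- split(seq_along(vox_o), tile_id)
  for (ii in idx_by_tile) {
    tf <- t_o[ii]
    f <- unique(tf)              # sorted: voxels are time-ordered per tile
    c_f <- tabulate(match(tf, f))
    cs <- cumsum(c_f)
    hi <- findInterval(f + eps_t, f)
    lo <- findInterval(f - eps_t - 1L, f)
    m <- cs[hi] - c(0, cs)[lo + 1L]
    core <- m >= min_pts
    if (!any(core)) next
    fc <- f[core]
    lab_core <- cumsum(c(TRUE, diff(fc) > eps_t)) + n_clusters
    frame_lab <- integer(length(f))
    frame_lab[core] <- lab_core
    if (any(!core)) {
      nc <- which(!core)
      pos <- findInterval(f[nc], fc)            # nearest core frame at/left
      d_left <- ifelse(pos >= 1L, f[nc] - fc[pmax(pos, 1L)], Inf)
      d_right <- ifelse(pos < length(fc), fc[pmin(pos + 1L, length(fc))] - f[nc], Inf)
      use_left <- d_left <= d_right & d_left <= eps_t
      use_right <- !use_left & d_right <= eps_t
      frame_lab[nc[use_left]] <- lab_core[pmax(pos[use_left], 1L)]
      frame_lab[nc[use_right]] <- lab_core[pmin(pos[use_right] + 1L, length(fc))]
    }
    n_clusters <- max(lab_core)
    clus[ii] <- frame_lab[match(tf, f)]
  }
  keep <- clus > 0L
  if (!any(keep)) return(empty_events(activity$frame_rate))
  clus <- clus[keep]; vox_o <- vox_o[keep]

  # merge clusters sharing voxels (overlapping tiles) via a cluster graph
  ov <- order(vox_o, clus)
  vv <- vox_o[ov]; cc_ <- clus[ov]
  rm(ov)
  same <- which(vv[-1] == vv[-length(vv)])
  K <- max(clus)
  comp_of <- if (length(same)) {
    a <- cc_[same]; b <- cc_[same + 1L]
    uu <- !duplicated(a * (K + 1) + b)     # numeric key, no row-wise matrix op
    g <- igraph::graph_from_edgelist(cbind(a[uu], b[uu]), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, K - igraph::vcount(g)))
    igraph::components(g)$membership
  } else seq_len(K)
  rm(vv, cc_, same)
  ev <- comp_of[clus]
  dup <- duplicated(ev * (length(t) + 1) + vox_o)
  ev <- ev[!dup]; vox_f <- vox_o[!dup]
  big <- tabulate(ev)[ev] >= min_pts      # final noise rejection
  if (!any(big)) return(empty_events(activity$frame_rate))
  ev <- ev[big]; vox_f <- vox_f[big]

  build_events(ev, vox_f, t, row, col, idx_lookup = NULL,
               relative = relative, frame_rate = activity$frame_rate)
}

empty_events <- function(frame_rate = NA_real_) {
  structure(data.frame(event_id = integer(), cell_id = integer(),
                       t_start = integer(), t_end = integer(),
                       size_vox = integer(), peak_amplitude = numeric()),
            footprints = list(), frame_rate = frame_rate,
            class = c("calcium_events", "data.frame"))
}

# Assemble a calcium_events object from (event id, voxel) assignments.
build_events <- function(ev, vox, t, row, col, idx_lookup, relative, frame_rate,
                         cell_of_event = NULL) {
  # `t`, `row`, `col` are per-voxel lookups aligned with the original voxel
  # ordering; `vox` indexes into them.
  fid <- match(ev, sort(unique(ev)))
  o <- order(fid, t[vox])
  fid <- fid[o]; vox <- vox[o]
  tt <- t[vox]; rr <- row[vox]; cc <- col[vox]
  vals <- if (!is.null(relative)) {
    d <- dim(relative)
    relative[(cc - 1) * (d[1] * d[2]) + (rr - 1) * d[1] + tt]
  } else rep(NA_real_, length(vox))
  n_ev <- max(fid)
  f <- factor(fid, levels = seq_len(n_ev))   # keep numeric group order
  t_start <- as.integer(tapply(tt, f, min))
  t_end <- as.integer(tapply(tt, f, max))
  size <- tabulate(fid)
  peak <- if (!is.null(relative)) as.numeric(tapply(vals, f, max)) else rep(NA_real_, n_ev)
  fp <- split.data.frame(cbind(t = tt, row = rr, col = cc), f)
  cell <- if (is.null(cell_of_event)) integer(n_ev) else cell_of_event
  df <- data.frame(event_id = seq_len(n_ev), cell_id = cell,
                   t_start = t_start, t_end = t_end,
                   size_vox = size, peak_amplitude = peak)
  structure(df, footprints = unname(fp), frame_rate = frame_rate,
            class = c("calcium_events", "data.frame"))
}

#' Cut events by astrocyte boundaries
#'
#' Each event footprint is intersected with the labelled cell regions: voxels
#' on background are dropped, and an event overlapping several cells is split
#' into one event per cell (start/end/size/peak recomputed per part). Events
#' left empty vanish. In-cell voxels are conserved: the per-cell parts
#' partition exactly the in-cell voxels of the parent event.
#'
#' @param events `calcium_events` from [cluster_events()].
#' @param cells a `cell_label_map` from [segment_astrocytes()].
#' @param relative optional relative-signal stack to recompute peaks.
#' @param min_size smallest credible per-cell event, in voxels. Correlated
#'   residual noise crosses the threshold in clumps of up to roughly the box
#'   filter support (~27 voxels); genuine transients cover a cell body for
#'   seconds (thousands of voxels at default calibration). The default sits
#'   between the two scales.
#' @return `calcium_events` with `cell_id` filled, ordered by cell and onset.
#' @export
assign_events <- function(events, cells, relative = NULL, min_size = 50L) {
  fps <- attr(events, "footprints")
  if (length(fps) == 0L) return(events)
  lab <- cells$labels
  H <- nrow(lab)
  nv <- vapply(fps, nrow, integer(1))
  all_fp <- do.call(rbind, fps)
  parent <- rep(seq_along(fps), nv)
  cell <- lab[(all_fp[, "col"] - 1L) * H + all_fp[, "row"]]
  keep <- cell > 0L
  if (!any(keep)) return(empty_events(attr(events, "frame_rate")))
  all_fp <- all_fp[keep, , drop = FALSE]
  parent <- parent[keep]; cell <- cell[keep]
  key <- parent * (max(cell) + 1L) + cell
  sz <- tabulate(match(key, sort(unique(key))))
  ok <- sz[match(key, sort(unique(key)))] >= min_size
  if (!any(ok)) return(empty_events(attr(events, "frame_rate")))
  all_fp <- all_fp[ok, , drop = FALSE]
  parent <- parent[ok]; cell <- cell[ok]
  key <- key[ok]
  cell_of <- cell[match(sort(unique(key)), key)]
  out <- build_events(key, seq_len(nrow(all_fp)),
                      t = all_fp[, "t"], row = all_fp[, "row"], col = all_fp[, "col"],
                      idx_lookup = NULL, relative = relative,
                      frame_rate = attr(events, "frame_rate"),
                      cell_of_event = cell_of)
  # order by (cell, onset) with stable event ids
  o <- order(out$cell_id, out$t_start)
  fp <- attr(out, "footprints")[o]
  df <- out[o, , drop = FALSE]
  df$event_id <- seq_len(nrow(df))
  rownames(df) <- NULL
  structure(df, footprints = fp, frame_rate = attr(out, "frame_rate"),
            class = c("calcium_events", "data.frame"))
}

#' Events table in physical units
#'
#' @param events `calcium_events`.
#' @param frame_rate Hz; defaults to the rate recorded on the object.
#' @return data.frame with onset/offset/duration in seconds.
#' @export
events_table <- function(events, frame_rate = attr(events, "frame_rate")) {
  if (is.null(frame_rate) || is.na(frame_rate))
    stopf("frame_rate is needed to express events in seconds")
  data.frame(event_id = events$event_id, cell_id = events$cell_id,
             t_start_s = (events$t_start - 1) / frame_rate,
             t_end_s = (events$t_end - 1) / frame_rate,
             duration_s = (events$t_end - events$t_start + 1) / frame_rate,
             size_vox = events$size_vox,
             peak_amplitude = events$peak_amplitude)
}
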