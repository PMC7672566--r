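#' Per-cell calcium traces
#'
#' Two trace kinds summarise the calcium state of a cell at each frame:
#' `"intensity"` is the mean relative signal (dF/F) over the cell's pixels —
#' the average intracellular calcium level — and `"event_size"` counts the
#' cell's event voxels active at that frame (0 outside detected events).
#' Both feed the correlation analysis.
#'
#' @param relative relative-signal [image_stack()].
#' @param cells `cell_label_map`.
#' @param events `calcium_events` (required for `kind = "event_size"`).
#' @param kind `"intensity"` or `"event_size"`.
#' @return A `cell_traces` object: numeric `T x N` matrix (columns = cells in
#'   `cells$cells$cell_id` order) with attributes `kind` and `frame_rate`.
#' @export
build_traces <- function(relative, cells, events = NULL,
                         kind = c("intensity", "event_size")) {
  kind <- match.arg(kind)
  d <- dim(relative)
  lab <- cells$labels
  if (!identical(as.integer(dim(lab)), d[2:3]))
    stopf("label map geometry does not match the stack")
  n <- nrow(cells$cells)
  tr <- matrix(0, d[1], n)
  if (kind == "intensity") {
    m <- unclass(relative)
    dim(m) <- c(d[1], d[2] * d[3])
    labv <- as.vector(lab)
    for (i in seq_len(n)) {
      pix <- which(labv == i)
      tr[, i] <- rowMeans(m[, pix, drop = FALSE], na.rm = TRUE)
    }
  } else {
    if (is.null(events)) stopf("`events` are required for event_size traces")
    fps <- attr(events, "footprints")
    for (k in seq_len(nrow(events))) {
      ci <- events$cell_id[k]
      if (ci < 1L || ci > n) next
      cnt <- tabulate(fps[[k]][, "t"], nbins = d[1])
      tr[, ci] <- tr[, ci] + cnt
    }
  }
  structure(tr, kind = kind, frame_rate = attr(relative, "frame_rate"),
            class = c("cell_traces", "matrix", "array"))
}

#' Oscillation statistics of a recording
#'
#' The per-culture functional activity summary: per-cell oscillation
#' frequency (events per minute), per-event duration in seconds, and the
#' percentage of working cells (cells with at least one event). Summaries are
#' reported in the `"M [Q1; Q3]"` median/quartile format via [describe()].
#'
#' @param events `calcium_events` with cell assignments.
#' @param n_cells total number of segmented cells.
#' @param recording_minutes recording length in minutes (> 0).
#' @param frame_rate Hz; defaults to the rate recorded on `events`.
#' @return An `activity_summary` list: `pct_working_cells`, `osc_freq_per_min`
#'   (per cell), `osc_duration_s` (per event), `n_cells`, `n_events`, plus
#'   formatted `freq_desc` / `duration_desc`.
#' @export
oscillation_stats <- function(events, n_cells, recording_minutes,
                              frame_rate = attr(events, "frame_rate")) {
  if (n_cells <= 0) stopf("degenerate input: n_cells must be positive")
  if (recording_minutes <= 0) stopf("recording_minutes must be positive")
  if (is.null(frame_rate) || is.na(frame_rate))
    stopf("frame_rate is needed for durations")
  counts <- tabulate(events$cell_id[events$cell_id >= 1L], nbins = n_cells)
  freq <- counts / recording_minutes
  dur <- (events$t_end - events$t_start + 1) / frame_rate
  structure(list(
    pct_working_cells = 100 * sum(counts > 0) / n_cells,
    osc_freq_per_min = freq,
    osc_duration_s = dur,
    n_cells = n_cells,
    n_events = nrow(events),
    freq_desc = if (length(freq)) describe(freq) else NA_character_,
    duration_desc = if (length(dur)) describe(dur) else NA_character_),
    class = "activity_summary")
}

#' @export
print.activity_summary <- function(x, ...) {
  cat(sprintf("%d events in %d cells; working cells %s%%\n",
              x$n_events, x$n_cells, fmt_signif3(x$pct_working_cells)))
  cat(sprintf("frequency (osc/min): %s\nduration (s): %s\n",
              x$freq_desc, x$duration_desc))
  invisible(x)
}

#' Spectral energy percentile frequency bounds
#'
#' For each trace the one-sided periodogram power spectral density is
#' computed (linear detrending, no taper, DC bin excluded); the lower/upper
#' characteristic frequencies are where the cumulative normalised spectral
#' energy first reaches 10% and 90%. Bounds are then averaged over all
#' usable traces of the field. Constant traces have no spectrum and are
#' skipped (counted in `n_skipped`).
#'
#' @param traces `cell_traces` matrix (or plain T x N matrix).
#' @param frame_rate Hz; defaults to the rate recorded on `traces`.
#' @param lower,upper energy percentiles (defaults 0.10 / 0.90).
#' @return A `spectral_bounds` list: `f_low`, `f_high` (Hz, averaged),
#'   `per_cell` (N x 2), `n_skipped`.
#' @export
spectral_bounds <- function(traces, frame_rate = attr(traces, "frame_rate"),
                            lower = 0.10, upper = 0.90) {
  x <- unclass(traces)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (nrow(x) < 32L) stopf("traces too short for spectral estimates (T >= 32)")
  if (is.null(frame_rate) || is.na(frame_rate)) stopf("frame_rate required")
  per <- matrix(NA_real_, ncol(x), 2)
  skipped <- 0L
  for (i in seq_len(ncol(x))) {
    xi <- x[, i]
    if (stats::sd(xi) == 0) { skipped <- skipped + 1L; next }
    sp <- stats::spec.pgram(stats::ts(xi, frequency = frame_rate),
                            taper = 0, detrend = TRUE, fast = FALSE,
                            plot = FALSE)
    cum <- cumsum(sp$spec) / sum(sp$spec)
    per[i, 1] <- sp$freq[which(cum >= lower)[1]]
    per[i, 2] <- sp$freq[which(cum >= upper)[1]]
  }
  ok <- !is.na(per[, 1])
  if (!any(ok)) stopf("no usable (non-constant) traces")
  structure(list(f_low = mean(per[ok, 1]), f_high = mean(per[ok, 2]),
                 per_cell = per, n_skipped = skipped),
            class = "spectral_bounds")
}

#' Median and quartiles in "M [Q1; Q3]" form
#'
#' Formats the median and the first/third quartiles (inclusive
#' linear-interpolation definition) of a sample to three significant digits,
#' the descriptive-statistics convention used throughout reporting.
#'
#' @param sample non-empty numeric vector.
#' @return Character scalar like `"3 [2; 4]"`.
#' @export
describe <- function(sample) {
  if (length(sample) == 0L || all(is.na(sample)))
    stopf("describe() needs a non-empty sample")
  q <- stats::quantile(sample, c(0.5, 0.25, 0.75), na.rm = TRUE, names = FALSE,
                       type = 7)
  sprintf("%s [%s; %s]", fmt_signif3(q[1]), fmt_signif3(q[2]), fmt_signif3(q[3]))
}
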