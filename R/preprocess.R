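#' Subtract the camera/medium offset measured on the cell-free recording
#'
#' The constant (per-pixel) offset is the temporal mean of the cell-free
#' stack; subtracting it from every frame of the activity stack removes dark
#' counts and medium fluorescence so that later relative-signal estimates are
#' unbiased. Negative values are permitted in the result.
#'
#' @param activity,cellfree paired [image_stack()] objects of equal geometry.
#' @return The offset-subtracted activity stack.
#' @export
subtract_offset <- function(activity, cellfree) {
  check_paired(activity, cellfree)
  d <- dim(activity)
  off <- temporal_mean(cellfree)
  out <- unclass(activity)
  dim(out) <- c(d[1], d[2] * d[3])
  out <- out - rep(as.vector(off), each = d[1])
  dim(out) <- d
  restack(out, activity)
}

#' Denoise a stack with an optional video denoiser plus a 3-D box filter
#'
#' An optional plug-in video denoiser (any function `stack -> stack`) is
#' applied first; the mandatory stage is a separable spatiotemporal moving
#' average ("3-D box filter") with odd window sizes `box = c(t, h, w)` and
#' reflection padding at the edges so that boundary frames and pixels are not
#' dimmed.
#'
#' @param stack an [image_stack()].
#' @param box integer window sizes `(t, h, w)`, all odd and positive.
#' @param video_denoiser optional function applied before the box filter.
#' @return The denoised stack (same geometry and calibration).
#' @export
denoise <- function(stack, box = c(3L, 3L, 3L), video_denoiser = NULL) {
  box <- as.integer(box)
  if (length(box) != 3L || any(box < 1L) || any(box %% 2L == 0L))
    stopf("`box` must be three odd positive window sizes (t, h, w)")
  a <- unclass(stack)
  if (!is.null(video_denoiser)) {
    a <- unclass(video_denoiser(stack))
    if (!identical(dim(a), dim(unclass(stack))))
      stopf("video_denoiser changed the stack dimensions")
  }
  a <- box_filter_axis(a, box[1], 1L)
  a <- box_filter_axis(a, box[2], 2L)
  a <- box_filter_axis(a, box[3], 3L)
  restack(a, stack)
}

#' Estimate the per-pixel fluorescence baseline from the cell-free recording
#'
#' The baseline F0 used by the relative-signal (dF/F) conversion is the
#' per-pixel temporal mean of the denoised cell-free stack.
#'
#' @param cellfree cell-free [image_stack()].
#' @param box box-filter window passed to [denoise()].
#' @return A `baseline_map`: list with `value` (H x W matrix) and `source`.
#' @export
estimate_baseline <- function(cellfree, box = c(3L, 3L, 3L)) {
  v <- temporal_mean(unclass(denoise(cellfree, box)))
  if (all(v == 0)) stopf("degenerate input: the cell-free baseline is zero everywhere")
  structure(list(value = v, source = attr(cellfree, "origin")),
            class = "baseline_map")
}

#' Relative signal changes (dF/F) with respect to a baseline map
#'
#' Per pixel, `(stack - baseline) / baseline`. Pixels whose baseline does not
#' exceed `eps` are masked invalid (`NA`) since no relative change is defined
#' there.
#'
#' @param stack (denoised) activity [image_stack()].
#' @param baseline a `baseline_map` from [estimate_baseline()], or an H x W
#'   matrix.
#' @param eps smallest usable baseline, in intensity units.
#' @param already_offset logical; if `TRUE` the stack has had the offset
#'   (equal to the baseline map) subtracted already, so only the division is
#'   applied. Used by the pipeline, where offset subtraction is an explicit
#'   earlier step.
#' @return Stack of relative signal values.
#' @export
relative_signal <- function(stack, baseline, eps = 1e-9, already_offset = FALSE) {
  b <- if (inherits(baseline, "baseline_map")) baseline$value else baseline
  d <- dim(stack)
  if (!identical(as.integer(dim(b)), d[2:3]))
    stopf("baseline map shape does not match the stack")
  if (all(b <= eps)) stopf("degenerate input: all-zero baseline map")
  bv <- as.vector(b)
  bad <- bv <= eps
  bv[bad] <- NA_real_
  out <- unclass(stack)
  dim(out) <- c(d[1], d[2] * d[3])
  if (already_offset) {
    out <- out / rep(bv, each = d[1])
  } else {
    out <- (out - rep(bv, each = d[1])) / rep(bv, each = d[1])
  }
  dim(out) <- d
  restack(out, stack)
}

#' Per-pixel resting level of the relative signal
#'
#' Pixels inside cells carry resting dye fluorescence above the cell-free
#' medium, which appears as a static positive dF/F. The resting level is
#' estimated as the per-pixel temporal median of the relative signal — robust
#' to calcium transients as long as a pixel is active less than half the
#' time — and is subtracted before the activity threshold is applied, so that
#' only dynamic signal counts as activity.
#'
#' @param relative relative-signal [image_stack()].
#' @return H x W matrix of per-pixel resting dF/F levels.
#' @export
resting_level <- function(relative) {
  d <- dim(relative)
  m <- unclass(relative)
  dim(m) <- c(d[1], d[2] * d[3])
  matrix(apply(m, 2, stats::median, na.rm = TRUE), d[2], d[3])
}

#' Subtract a per-pixel resting map from a relative-signal stack
#'
#' @param relative relative-signal [image_stack()].
#' @param resting H x W matrix from [resting_level()].
#' @return Stack of dynamic relative signal (resting level removed).
#' @export
subtract_resting <- function(relative, resting) {
  d <- dim(relative)
  if (!identical(as.integer(dim(resting)), d[2:3]))
    stopf("resting map shape does not match the stack")
  out <- unclass(relative)
  dim(out) <- c(d[1], d[2] * d[3])
  out <- out - rep(as.vector(resting), each = d[1])
  dim(out) <- d
  restack(out, relative)
}

#' Noise-adaptive activity threshold calibrated on the cell-free recording
#'
#' The threshold that separates genuine calcium activity from residual noise
#' is `k_sigma` times the per-pixel temporal standard deviation of the
#' *denoised, offset-subtracted* cell-free signal expressed in relative
#' (dF/F) units. The cell-free stack must pass through the identical denoise
#' stage as the activity stack (same `box`), so the threshold reflects the
#' noise level that actually survives filtering.
#'
#' @param cellfree cell-free [image_stack()].
#' @param baseline `baseline_map` (or H x W matrix) used for the relative
#'   conversion.
#' @param k_sigma noise multiplier (default 3).
#' @param box box-filter window, identical to the one used on the activity
#'   stack.
#' @return A `threshold_map`: list with `value` (H x W, relative units,
#'   `NA` where the baseline is invalid) and `k_sigma`.
#' @export
adaptive_threshold <- function(cellfree, baseline, k_sigma = 3, box = c(3L, 3L, 3L)) {
  if (dim(cellfree)[1] < 8L)
    stopf("cell-free stack too short (T >= 8 needed for a usable noise estimate)")
  if (k_sigma < 0) stopf("`k_sigma` must be non-negative")
  b <- if (inherits(baseline, "baseline_map")) baseline$value else baseline
  cf0 <- subtract_offset(cellfree, cellfree)        # zero-mean noise
  cfd <- unclass(denoise(cf0, box))
  sdm <- temporal_sd(cfd)
  bv <- b
  bv[bv <= 1e-9] <- NA_real_
  structure(list(value = k_sigma * sdm / bv, k_sigma = k_sigma),
            class = "threshold_map")
}
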