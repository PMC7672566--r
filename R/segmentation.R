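#' Long-exposure intensity image
#'
#' The per-pixel temporal mean of the (denoised) activity stack: the image a
#' long camera exposure would have produced, on which individual astrocytes
#' appear as bright compact regions suitable for watershed delineation.
#'
#' @param stack an [image_stack()].
#' @return H x W numeric matrix.
#' @export
long_exposure <- function(stack) {
  temporal_mean(unclass(stack))
}

# Otsu threshold on the image's own intensity range (affine invariant).
otsu_threshold <- function(img, levels = 256L) {
  rng <- range(img)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- tabulate(findInterval(img, br, rightmost.closed = TRUE), nbins = levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (br[-1] + br[-length(br)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- -Inf
  mids[which.max(sb2)]
}

#' Delimit individual astrocytes by marker-controlled watershed
#'
#' The long-exposure image is Gaussian-smoothed, a background floor is set by
#' Otsu's method on the smoothed image, and the watershed transform is run on
#' the above-floor intensity relief. Catchment basins whose seed prominence is
#' below `h_min_frac` of the image dynamic range are merged with their
#' neighbours, and regions smaller than `min_cell_area` pixels are dropped to
#' background. Labels are relabelled `1..N`.
#'
#' @param image H x W intensity matrix (typically from [long_exposure()]).
#' @param pixel_size um/px, used for centroid coordinates.
#' @param smoothing_sigma Gaussian smoothing sigma in pixels.
#' @param h_min_frac seed prominence as a fraction of the smoothed image's
#'   dynamic range.
#' @param min_cell_area minimum region area in pixels.
#' @param intensity_floor optional absolute background floor on the smoothed
#'   image; default is Otsu's threshold.
#' @return A `cell_label_map`: list with `labels` (H x W integer matrix, 0 =
#'   background), `cells` (data.frame `cell_id, row, col, x_um, y_um,
#'   area_px`), `pixel_size`. Micrometre coordinates use a 0-based pixel
#'   origin.
#' @export
segment_astrocytes <- function(image, pixel_size,
                               smoothing_sigma = 2,
                               h_min_frac = 0.10,
                               min_cell_area = 30L,
                               intensity_floor = NULL) {
  stopifnot(is.matrix(image), all(is.finite(image)),
            smoothing_sigma > 0, h_min_frac > 0, min_cell_area > 0)
  empty <- function() {
    structure(list(labels = matrix(0L, nrow(image), ncol(image)),
                   cells = data.frame(cell_id = integer(), row = numeric(),
                                      col = numeric(), x_um = numeric(),
                                      y_um = numeric(), area_px = integer()),
                   pixel_size = pixel_size),
              class = "cell_label_map")
  }
  if (diff(range(image)) == 0) return(empty())
  s <- EBImage::gblur(image, sigma = smoothing_sigma)
  floor_val <- intensity_floor %||% otsu_threshold(s)
  relief <- s - floor_val
  relief[relief < 0] <- 0
  if (all(relief == 0)) return(empty())
  w <- EBImage::watershed(relief, tolerance = h_min_frac * diff(range(s)), ext = 1L)
  w <- matrix(as.integer(w), nrow(image), ncol(image))
  # drop undersized regions, relabel contiguously
  sizes <- tabulate(w[w > 0L])
  keep <- which(sizes >= min_cell_area)
  if (length(keep) == 0L) return(empty())
  remap <- integer(max(w))
  remap[keep] <- seq_along(keep)
  lab <- w
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  idx <- which(lab > 0L)
  if (length(idx) == 0L) return(empty())
  li <- factor(lab[idx], levels = seq_along(keep))
  rows <- (idx - 1L) %% nrow(image) + 1L
  cols <- (idx - 1L) %/% nrow(image) + 1L
  cr <- tapply(rows, li, mean)
  cc <- tapply(cols, li, mean)
  area <- tabulate(lab[idx])
  cells <- data.frame(cell_id = seq_along(keep),
                      row = as.numeric(cr), col = as.numeric(cc),
                      x_um = (as.numeric(cc) - 1) * pixel_size,
                      y_um = (as.numeric(cr) - 1) * pixel_size,
                      area_px = area)
  structure(list(labels = lab, cells = cells, pixel_size = pixel_size),
            class = "cell_label_map")
}

#' @export
print.cell_label_map <- function(x, ...) {
  cat(sprintf("<cell_label_map> %d cells on a %d x %d px field (%.4g um/px)\n",
              nrow(x$cells), nrow(x$labels), ncol(x$labels), x$pixel_size))
  invisible(x)
}

#' Pairwise centroid distances in micrometres
#'
#' @param cells a `cell_label_map` (or its `cells` data.frame).
#' @return Symmetric N x N matrix of Euclidean centroid distances (um).
#' @export
cell_distances <- function(cells) {
  df <- if (inherits(cells, "cell_label_map")) cells$cells else cells
  as.matrix(stats::dist(cbind(df$x_um, df$y_um)))
}
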