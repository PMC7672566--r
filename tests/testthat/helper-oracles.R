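# Brute-force reference implementations used as independent oracles.

# Trailing-moving-average detrend, direct loops.
brute_detrend <- function(x, w) {
  n <- length(x)
  out <- rep(NA_real_, n)
  for (k in (w + 1):n) out[k] <- x[k] - mean(x[(k - w):k])
  out
}

# Uncentered correlation over non-NA overlap, direct sums.
brute_corr <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  num <- 0; da <- 0; db <- 0
  for (k in seq_along(a)) {
    num <- num + a[k] * b[k]
    da <- da + a[k]^2
    db <- db + b[k]^2
  }
  num / sqrt(da * db)
}

# Lag-maximised correlation by explicit shifting (same tie-break order).
brute_lagmax <- function(a, b, L) {
  n <- length(a)
  s <- which(!is.na(a) & !is.na(b))[1]
  best <- -Inf; lag <- NA
  for (l in (-L):L) {
    if (l >= 0) { ia <- s:(n - l); ib <- ia + l } else { ib <- s:(n + l); ia <- ib - l }
    r <- brute_corr(a[ia], b[ib])
    better <- r > best + 1e-15 ||
      (abs(r - best) <= 1e-15 && (abs(l) < abs(lag) ||
                                    (abs(l) == abs(lag) && l < lag)))
    if (is.finite(r) && better) { best <- r; lag <- l }
  }
  list(rho_max = best, lag_star = lag)
}

# 3-D box filter by triple loops with symmetric reflection padding
# (edge sample repeated: ... x2 x1 | x1 x2 ...).
brute_box3d <- function(a, box) {
  d <- dim(a)
  reflect <- function(i, n) {
    while (i < 1L || i > n) {
      if (i < 1L) i <- 1L - i
      if (i > n) i <- 2L * n + 1L - i
    }
    i
  }
  h <- (box - 1L) %/% 2L
  out <- array(0, d)
  for (t in 1:d[1]) for (r in 1:d[2]) for (c in 1:d[3]) {
    acc <- 0
    for (dt in -h[1]:h[1]) for (dr in -h[2]:h[2]) for (dc in -h[3]:h[3])
      acc <- acc + a[reflect(t + dt, d[1]), reflect(r + dr, d[2]), reflect(c + dc, d[3])]
    out[t, r, c] <- acc / prod(box)
  }
  out
}

# Small stack constructor for tests.
mk_stack <- function(data, fr = 2, ps = 420 / 512, origin = "activity") {
  image_stack(data, frame_rate = fr, pixel_size = ps, origin = origin)
}

# A minimal synthetic culture that renders quickly.
tiny_culture <- function(seed = 3, n_cells = 3, duration_s = 180,
                         rate = 1, coupling = "none", ...) {
  culture_config(n_cells = n_cells, field_px = 48, field_um = 126,
                 duration_s = duration_s, event_rate_per_min = rate,
                 layout = "uniform", coupling = coupling,
                 min_separation_um = 34, cell_radius_um = 15,
                 seed = seed, ...)
}
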