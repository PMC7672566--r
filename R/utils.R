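# Internal numeric helpers shared across the pipeline.

# Column-wise cumulative sums of a matrix without apply(): cumsum the full
# vector, then remove the carry-over between columns.
col_cumsum <- function(m) {
  n <- nrow(m)
  cs <- matrix(cumsum(m), n, ncol(m))
  if (ncol(m) > 1L) {
    carry <- c(0, cs[n, -ncol(m)])
    cs <- cs - rep(carry, each = n)
  }
  cs
}

# Running mean of length k (odd) down the rows of a matrix, symmetric
# reflection padding (the edge sample is repeated: ... x2 x1 | x1 x2 ...).
row_running_mean <- function(m, k) {
  if (k == 1L) return(m)
  h <- (k - 1L) %/% 2L
  n <- nrow(m)
  if (n == 1L) return(m)
  pad_top <- pmin(h:1, n)
  pad_bot <- pmax(n:(n - h + 1L), 1L)
  mp <- m[c(pad_top, 1:n, pad_bot), , drop = FALSE]
  cs <- col_cumsum(mp)
  top <- rbind(rep(0, ncol(m)), cs[seq_len(nrow(mp) - k), , drop = FALSE])
  (cs[k:nrow(mp), , drop = FALSE] - top) / k
}

# Moving average of size k along one axis of a T x H x W array (reflection).
# axis: 1 = time, 2 = rows, 3 = cols.
box_filter_axis <- function(a, k, axis) {
  d <- dim(a)
  if (axis == 1L) {
    m <- a; dim(m) <- c(d[1], d[2] * d[3])
    out <- row_running_mean(m, k)
    dim(out) <- d
    return(out)
  }
  perm <- if (axis == 2L) c(2L, 3L, 1L) else c(3L, 1L, 2L)
  ap <- aperm(a, perm)
  dp <- dim(ap)
  dim(ap) <- c(dp[1], dp[2] * dp[3])
  out <- row_running_mean(ap, k)
  dim(out) <- dp
  aperm(out, order(perm))
}

# Temporal mean of a T x H x W array -> H x W matrix.
temporal_mean <- function(a) {
  d <- dim(a)
  m <- a; dim(m) <- c(d[1], d[2] * d[3])
  matrix(colMeans(m), d[2], d[3])
}

# Temporal sd (denominator n-1) of a T x H x W array -> H x W matrix.
temporal_sd <- function(a) {
  d <- dim(a)
  m <- a; dim(m) <- c(d[1], d[2] * d[3])
  mu <- colMeans(m)
  ss <- colSums(m * m) - d[1] * mu * mu
  matrix(sqrt(pmax(ss, 0) / (d[1] - 1)), d[2], d[3])
}

# Format one number with 3 significant digits, plain notation.
fmt_signif3 <- function(x) {
  format(signif(x, 3), trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
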