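test_that("detrending matches the trailing-mean definition", {
  const <- detrend_trace(rep(4, 50), 10)
  expect_true(all(is.na(const[1:10])))
  expect_true(all(const[11:50] == 0))
  # linear ramp of slope a: trailing mean lags by a*w/2
  a <- 0.3; w <- 8
  ramp <- detrend_trace(a * (1:100), w)
  expect_equal(unique(round(ramp[(w + 1):100], 12)), a * w / 2)
  set.seed(41)
  for (i in 1:5) {
    x <- rnorm(200)
    expect_equal(as.numeric(detrend_trace(x, 15)), brute_detrend(x, 15),
                 tolerance = 1e-12)
  }
  expect_error(detrend_trace(rnorm(10), 10), "short")
})

test_that("the uncentered correlation behaves like Eq-style cosine similarity", {
  a <- detrend_trace(c(rep(0, 5), sin(1:60)), 5)
  expect_equal(trace_correlation(a, a), 1)
  b <- a; b[] <- -as.numeric(a)
  expect_equal(trace_correlation(a, b), -1)
  x <- rep(c(1, 0, -1, 0), 10)
  y <- rep(c(0, 1, 0, -1), 10)
  expect_equal(sum(x * y), 0)
  expect_equal(trace_correlation(x, y), 0)
  expect_true(is.na(trace_correlation(x, rep(0, 40))))
})

test_that("lagged correlation recovers exact shifts and is antisymmetric", {
  t <- 1:400
  base <- sin(2 * pi * t / 40) + 0.5 * sin(2 * pi * t / 13)
  a <- detrend_trace(base, 12)
  b <- detrend_trace(c(rep(0, 4), base[1:396]), 12)   # b = a delayed 4 frames
  r <- lagged_max_correlation(a, b, max_lag = 10)
  expect_equal(r$lag_star, 4L)
  expect_gt(r$rho_max, 0.95)
  set.seed(51)
  for (i in 1:10) {
    x <- detrend_trace(rnorm(300), 12); y <- detrend_trace(rnorm(300), 12)
    f <- lagged_max_correlation(x, y, 8)
    g <- lagged_max_correlation(y, x, 8)
    expect_equal(f$lag_star, -g$lag_star)
    expect_equal(f$rho_max, g$rho_max, tolerance = 1e-12)
  }
})

test_that("lagged correlation agrees with a brute-force oracle", {
  set.seed(52)
  for (i in 1:20) {
    x <- detrend_trace(rnorm(150), 10); y <- detrend_trace(rnorm(150), 10)
    mine <- lagged_max_correlation(x, y, 6)
    ref <- brute_lagmax(as.numeric(x), as.numeric(y), 6)
    expect_equal(mine$rho_max, ref$rho_max, tolerance = 1e-12)
    expect_equal(mine$lag_star, ref$lag_star)
  }
})

fake_cells <- function(xy) {
  structure(list(labels = matrix(0L, 2, 2),
                 cells = data.frame(cell_id = seq_len(nrow(xy)),
                                    row = xy[, 2], col = xy[, 1],
                                    x_um = xy[, 1], y_um = xy[, 2],
                                    area_px = 10L),
                 pixel_size = 1), class = "cell_label_map")
}

fake_pairs <- function(i, j, rho, lag, dist) {
  structure(data.frame(cell_i = i, cell_j = j, rho_max = rho,
                       lag_star = lag, rho_zero = rho, distance_um = dist),
            class = c("pair_correlations", "data.frame"))
}

test_that("threshold calibration uses the distant-pair 95th percentile", {
  p <- fake_pairs(1, 2:31, seq(0.01, 0.25, length.out = 30), 0L, 150)
  expect_equal(as.numeric(calibrate_threshold(p, enabled = FALSE)), 0.3)
  th <- calibrate_threshold(p, 100)
  expect_lte(as.numeric(th), 0.25)
  expect_true(attr(th, "calibrated"))
  few <- fake_pairs(1, 2:6, runif(5), 0L, 150)
  expect_message(th2 <- calibrate_threshold(few, 100), "fewer than 10")
  expect_equal(as.numeric(th2), 0.3)
})

test_that("network construction applies threshold and lag-based direction", {
  cells <- fake_cells(cbind(c(0, 30, 60), c(0, 0, 0)))
  p <- fake_pairs(c(1, 1, 2), c(2, 3, 3), c(0.5, 0.1, 0.2), c(0L, 2L, -1L),
                  c(30, 60, 30))
  net <- build_network(p, cells, threshold = 0.3)
  expect_equal(nrow(net$edges), 1)
  expect_false(net$edges$directed[1])             # zero lag stays undirected
  st <- network_stats(net, long_distance_um = 100, frame_rate = 2)
  expect_equal(st$n_components, 2)
  # all below threshold -> edgeless graph with one component per cell
  net0 <- build_network(fake_pairs(c(1, 1, 2), c(2, 3, 3), c(0.1, 0.2, 0.25),
                                   0L, 30), cells, 0.3)
  expect_equal(nrow(net0$edges), 0)
  expect_equal(network_stats(net0, 100, 2)$n_components, 3)
  # a negative lag makes cell_j the leading (source) cell
  netd <- build_network(fake_pairs(1, 2, 0.6, -3L, 30), cells, 0.3)
  expect_equal(netd$edges$from, 2)
  expect_equal(netd$edges$to, 1)
  expect_true(netd$edges$directed)
})

test_that("the edge set is monotone non-increasing in the threshold", {
  set.seed(61)
  p <- fake_pairs(rep(1:9, times = 9:1),
                  unlist(lapply(2:10, function(k) k:10)),
                  runif(45), sample(-3:3, 45, TRUE), runif(45, 10, 400))
  cells <- fake_cells(cbind(runif(10, 0, 400), runif(10, 0, 400)))
  keys <- function(net) paste(pmin(net$edges$from, net$edges$to),
                              pmax(net$edges$from, net$edges$to))
  prev <- keys(build_network(p, cells, 0.1))
  for (th in c(0.3, 0.5, 0.7, 0.9)) {
    cur <- keys(build_network(p, cells, th))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("network statistics reproduce closed-form examples", {
  # path graph on 3 nodes
  cells <- fake_cells(cbind(c(0, 82, 164), c(0, 0, 0)))
  p <- fake_pairs(c(1, 2, 1), c(2, 3, 3), c(0.6, 0.6, 0.1), c(4L, 4L, 0L),
                  c(82, 82, 164))
  st <- network_stats(build_network(p, cells, 0.3), 100, frame_rate = 2)
  expect_equal(st$mean_connections_per_cell, 4 / 3)
  expect_equal(st$giant_component_fraction, 1)
  # 82 um at 4 frames lag and 2 Hz -> 41 um/s
  expect_equal(st$mean_propagation_speed_um_s, 41)
  expect_equal(st$mean_rho_max, mean(c(0.6, 0.6, 0.1)))
  # two disjoint 5-cliques among 20 nodes: giant fraction 0.25
  xy <- cbind(runif(20, 0, 400), runif(20, 0, 400))
  cells20 <- fake_cells(xy)
  cl <- function(m) t(combn(m, 2))
  ed <- rbind(cl(1:5), cl(6:10))
  p20 <- fake_pairs(ed[, 1], ed[, 2], 0.8, 0L, 50)
  st20 <- network_stats(build_network(p20, cells20, 0.3), 100, 2)
  expect_equal(st20$giant_component_fraction, 0.25)
  expect_equal(st20$n_components, 12)
  expect_true(is.na(st20$mean_propagation_speed_um_s))  # no lagged edges
})

test_that("distance bands follow the half-open [lo, hi) convention", {
  p <- fake_pairs(c(1, 1, 1, 1), c(2, 3, 4, 5), 0.5, 0L, c(30, 40, 350, 300))
  prof <- distance_correlation_profile(p)
  expect_equal(prof$band, c("adjacent", "intermediate", "distant", "distant"))
})

test_that("rho_max is invariant to trace scaling and constant offsets", {
  set.seed(71)
  base <- rnorm(300)
  shifted <- c(rep(0, 3), base[1:297])
  r0 <- lagged_max_correlation(detrend_trace(base, 12),
                               detrend_trace(shifted, 12), 8)
  r1 <- lagged_max_correlation(detrend_trace(5 * base + 2, 12),
                               detrend_trace(0.1 * shifted - 7, 12), 8)
  expect_equal(r1$rho_max, r0$rho_max, tolerance = 1e-10)
  expect_equal(r1$lag_star, r0$lag_star)
})
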