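mini_cells <- function() {
  lab <- matrix(0L, 8, 8)
  lab[2:3, 2:3] <- 1L
  lab[6:7, 6:7] <- 2L
  structure(list(labels = lab,
                 cells = data.frame(cell_id = 1:2, row = c(2.5, 6.5),
                                    col = c(2.5, 6.5), x_um = c(1.5, 5.5),
                                    y_um = c(1.5, 5.5), area_px = c(4L, 4L)),
                 pixel_size = 1), class = "cell_label_map")
}

test_that("intensity traces average the relative signal over cell pixels", {
  a <- array(0, c(5, 8, 8))
  a[3, 2:3, 2:3] <- 0.2
  tr <- build_traces(mk_stack(a), mini_cells(), kind = "intensity")
  expect_equal(tr[3, 1], 0.2)
  expect_equal(tr[1, 1], 0)
  expect_true(all(tr[, 2] == 0))
  expect_error(build_traces(mk_stack(a), mini_cells(), kind = "banana"))
})

test_that("event-size traces count active event voxels and conserve totals", {
  cells <- mini_cells()
  m <- array(FALSE, c(30, 8, 8))
  m[5:9, 2:3, 2:3] <- TRUE
  mask <- structure(list(mask = m, k_sigma = 3, frame_rate = 2),
                    class = "activity_mask")
  ev <- assign_events(cluster_events(mask), cells, min_size = 1L)
  a <- mk_stack(array(0, c(30, 8, 8)))
  tr <- build_traces(a, cells, ev, kind = "event_size")
  expect_equal(tr[5:9, 1], rep(4, 5))
  expect_true(all(tr[, 2] == 0))
  # per-frame sum over cells equals the per-frame in-cell active voxel count
  per_frame <- vapply(1:30, function(t) sum(m[t, , ] & cells$labels > 0), numeric(1))
  expect_equal(rowSums(tr), per_frame)
})

test_that("oscillation statistics reproduce hand-computed values", {
  ev <- structure(data.frame(event_id = 1:8,
                             cell_id = c(1, 1, 1, 1, 1, 1, 2, 2),
                             t_start = c(rep(1, 6), 10, 40),
                             t_end = c(rep(4, 6), 29, 49),
                             size_vox = 10L, peak_amplitude = 1),
                  frame_rate = 2, class = c("calcium_events", "data.frame"))
  s <- oscillation_stats(ev, n_cells = 4, recording_minutes = 3, frame_rate = 2)
  expect_equal(s$pct_working_cells, 50)             # 2 of 4 cells active
  expect_equal(s$osc_freq_per_min[1], 2.0)          # 6 events / 3 min
  expect_equal(s$osc_duration_s[7], 10.0)           # frames 10..29 at 2 Hz
  expect_error(oscillation_stats(ev, 0, 3), "n_cells")
  # invariant under time reversal of the event list
  rev <- ev[nrow(ev):1, ]
  attr(rev, "frame_rate") <- 2
  s2 <- oscillation_stats(rev, 4, 3, 2)
  expect_equal(s2$pct_working_cells, s$pct_working_cells)
  expect_equal(sort(s2$osc_duration_s), sort(s$osc_duration_s))
  expect_equal(s2$osc_freq_per_min, s$osc_freq_per_min)
})

test_that("spectral bounds localise a pure tone to one frequency bin", {
  t <- seq_len(2048)
  x <- matrix(sin(2 * pi * 0.25 * t / 2), ncol = 1)   # 0.25 Hz at 2 Hz sampling
  sb <- spectral_bounds(x, frame_rate = 2)
  bin <- 2 / 2048
  expect_lt(abs(sb$f_low - 0.25), bin + 1e-9)
  expect_lt(abs(sb$f_high - 0.25), bin + 1e-9)
})

test_that("white-noise spectra put the energy percentiles at 10/90% of Nyquist", {
  set.seed(21)
  x <- matrix(rnorm(4096 * 16), ncol = 16)
  sb <- spectral_bounds(x, frame_rate = 2)
  expect_lt(abs(sb$f_low - 0.1 * 1) / (0.1 * 1), 0.05)
  expect_lt(abs(sb$f_high - 0.9 * 1) / (0.9 * 1), 0.05)
})

test_that("a constructed two-line spectrum yields its component frequencies", {
  t <- seq_len(4096)
  # ~85% of the energy at 0.05 Hz, ~15% at 0.8 Hz (strictly inside the
  # 10/90 percentiles, so each bound lands on its own line)
  x <- matrix(2.38 * sin(2 * pi * 0.05 * t / 2) + sin(2 * pi * 0.8 * t / 2), ncol = 1)
  sb <- spectral_bounds(x, frame_rate = 2)
  bin <- 2 / 4096
  expect_lt(abs(sb$f_low - 0.05), bin + 1e-9)
  expect_lt(abs(sb$f_high - 0.8), bin + 1e-9)
  # scaling invariance of the energy normalisation
  sb2 <- spectral_bounds(100 * x, frame_rate = 2)
  expect_equal(sb2$f_low, sb$f_low)
  expect_equal(sb2$f_high, sb$f_high)
  # constant traces are skipped, not fatal
  sb3 <- spectral_bounds(cbind(x, 5), frame_rate = 2)
  expect_equal(sb3$n_skipped, 1L)
  expect_equal(sb3$f_low, sb$f_low)
})

test_that("describe() formats median and inclusive quartiles", {
  expect_equal(describe(c(1, 2, 3, 4, 5)), "3 [2; 4]")
  expect_equal(describe(7), "7 [7; 7]")
  expect_error(describe(numeric(0)), "non-empty")
  set.seed(31)
  u <- runif(10000)
  med <- as.numeric(sub(" .*", "", describe(u)))
  expect_lt(abs(med - 0.5), 0.02)
})
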