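# A threshold map of constant value v on an H x W grid.
thr_map <- function(v, H, W, k = 3) {
  structure(list(value = matrix(v, H, W), k_sigma = k), class = "threshold_map")
}

# Build an activity mask directly from a logical array (detector bypassed).
mask_from <- function(m, fr = 2) {
  structure(list(mask = m, k_sigma = 3, frame_rate = fr), class = "activity_mask")
}

test_that("activity detection compares voxelwise against the threshold map", {
  z <- mk_stack(array(0, c(4, 6, 6)))
  m0 <- detect_activity(z, thr_map(0.3, 6, 6))
  expect_false(any(m0$mask))
  a <- array(0, c(4, 6, 6)); a[2, 3, 3] <- 0.5
  m1 <- detect_activity(mk_stack(a), thr_map(0.3, 6, 6))
  expect_equal(sum(m1$mask), 1)
  expect_true(m1$mask[2, 3, 3])
})

test_that("active voxel count is non-increasing in k_sigma", {
  set.seed(3)
  d <- c(60, 10, 10)
  act <- mk_stack(array(rnorm(prod(d), 100, 3), d))
  cf <- mk_stack(array(rnorm(prod(d), 100, 3), d), origin = "cellfree")
  b <- estimate_baseline(cf)
  rel <- relative_signal(denoise(subtract_offset(act, cf)), b, already_offset = TRUE)
  counts <- vapply(1:4, function(k)
    sum(detect_activity(rel, adaptive_threshold(cf, b, k))$mask), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], counts[4])
})

test_that("a contiguous bright blob becomes exactly one event with exact extent", {
  m <- array(FALSE, c(80, 20, 20))
  m[10:20, 5:12, 5:12] <- TRUE
  ev <- cluster_events(mask_from(m))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$t_start, 10L)
  expect_equal(ev$t_end, 20L)
  expect_equal(ev$size_vox, 11L * 8L * 8L)
  # re-lighting the same pixels later splits into two events
  m[50:60, 5:12, 5:12] <- TRUE
  ev2 <- cluster_events(mask_from(m))
  expect_equal(nrow(ev2), 2)
  expect_equal(sort(ev2$t_start), c(10L, 50L))
})

test_that("scattered isolated voxels are rejected as noise", {
  set.seed(8)
  m <- array(FALSE, c(200, 24, 24))
  picks <- cbind(sample(seq(1, 200, by = 7), 25), sample(24, 25, TRUE),
                 sample(24, 25, TRUE))
  m[picks] <- TRUE
  expect_equal(nrow(cluster_events(mask_from(m), min_pts = 5)), 0)
})

test_that("event clustering is deterministic", {
  set.seed(4)
  m <- array(runif(40 * 24 * 24) < 0.02, c(40, 24, 24))
  m[5:15, 3:10, 3:10] <- TRUE
  e1 <- cluster_events(mask_from(m))
  e2 <- cluster_events(mask_from(m))
  expect_identical(as.data.frame(e1), as.data.frame(e2))
  expect_identical(attr(e1, "footprints"), attr(e2, "footprints"))
})

test_that("events are cut by cell boundaries with voxel conservation", {
  lab <- matrix(0L, 20, 20)
  lab[3:9, 3:9] <- 1L          # cell 1
  lab[3:9, 12:18] <- 2L        # cell 2
  cells <- structure(list(labels = lab,
                          cells = data.frame(cell_id = 1:2, row = c(6, 6),
                                             col = c(6, 15), x_um = c(5, 14),
                                             y_um = c(5, 5), area_px = c(49, 49)),
                          pixel_size = 1), class = "cell_label_map")
  # one event wholly inside cell 1
  m <- array(FALSE, c(30, 20, 20)); m[4:8, 4:8, 4:8] <- TRUE
  ev <- assign_events(cluster_events(mask_from(m)), cells, min_size = 1L)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$cell_id, 1L)
  expect_equal(ev$size_vox, 125L)
  # an event straddling both cells is split and in-cell voxels are conserved
  m2 <- array(FALSE, c(30, 20, 20)); m2[10:14, 5:8, 6:14] <- TRUE
  raw <- cluster_events(mask_from(m2))
  split <- assign_events(raw, cells, min_size = 1L)
  expect_equal(nrow(split), 2)
  expect_setequal(split$cell_id, 1:2)
  in_cell <- sum(lab[cbind(attr(raw, "footprints")[[1]][, "row"],
                           attr(raw, "footprints")[[1]][, "col"])] > 0)
  expect_equal(sum(split$size_vox), in_cell)
  # footprints of the parts never overlap
  fps <- attr(split, "footprints")
  keys <- lapply(fps, function(f) paste(f[, 1], f[, 2], f[, 3]))
  expect_equal(length(intersect(keys[[1]], keys[[2]])), 0)
})

test_that("conservation of in-cell voxels holds on random fixtures", {
  set.seed(12)
  lab <- matrix(sample(0:3, 24 * 24, TRUE), 24, 24)
  cells <- structure(list(labels = lab,
                          cells = data.frame(cell_id = 1:3, row = 1:3, col = 1:3,
                                             x_um = 1:3, y_um = 1:3,
                                             area_px = tabulate(lab[lab > 0]))),
                     class = "cell_label_map")
  m <- array(runif(60 * 24 * 24) < 0.15, c(60, 24, 24))
  raw <- cluster_events(mask_from(m), min_pts = 5, eps_t = 2)
  ev <- assign_events(raw, cells, min_size = 1L)
  fps_raw <- attr(raw, "footprints")
  n_in_cell <- sum(vapply(fps_raw, function(f)
    sum(lab[cbind(f[, "row"], f[, "col"])] > 0), numeric(1)))
  expect_equal(sum(ev$size_vox), n_in_cell)
})

test_that("the minimum event size filter drops sub-scale fragments", {
  lab <- matrix(1L, 12, 12)
  cells <- structure(list(labels = lab,
                          cells = data.frame(cell_id = 1L, row = 6, col = 6,
                                             x_um = 5, y_um = 5, area_px = 144)),
                     class = "cell_label_map")
  m <- array(FALSE, c(20, 12, 12)); m[5:7, 4:6, 4:6] <- TRUE  # 27 voxels
  ev_all <- assign_events(cluster_events(mask_from(m)), cells, min_size = 1L)
  ev_cut <- assign_events(cluster_events(mask_from(m)), cells, min_size = 50L)
  expect_equal(nrow(ev_all), 1)
  expect_equal(nrow(ev_cut), 0)
})
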