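test_that("offset subtraction removes the cell-free temporal mean per pixel", {
  set.seed(1)
  a <- mk_stack(array(runif(4 * 6 * 5, 10, 20), c(4, 6, 5)))
  cf_const <- mk_stack(array(5, c(4, 6, 5)), origin = "cellfree")
  expect_equal(as.vector(subtract_offset(a, cf_const)), as.vector(unclass(a)) - 5)
  cf_zero <- mk_stack(array(0, c(4, 6, 5)), origin = "cellfree")
  expect_equal(as.vector(subtract_offset(a, cf_zero)), as.vector(unclass(a)))
  # per-pixel means against an explicit loop oracle
  cf <- mk_stack(array(runif(4 * 6 * 5), c(4, 6, 5)), origin = "cellfree")
  out <- subtract_offset(a, cf)
  for (r in 1:6) for (c in 1:5)
    expect_equal(out[, r, c], a[, r, c] - mean(cf[, r, c]), tolerance = 1e-12)
})

test_that("the 3-D box filter matches a direct convolution oracle", {
  const <- mk_stack(array(7, c(5, 5, 5)))
  expect_equal(as.vector(denoise(const)), rep(7, 125))
  imp <- array(0, c(3, 7, 7)); imp[2, 4, 4] <- 1
  d <- denoise(mk_stack(imp), box = c(1, 3, 3))
  expect_equal(sum(d > 0), 9)
  expect_equal(max(d), 1 / 9)
  expect_equal(sum(d[2, , ]), 1)
  set.seed(42)
  a <- array(rnorm(6^3), c(6, 6, 6))
  expect_equal(as.vector(denoise(mk_stack(a), c(3, 3, 3))),
               as.vector(brute_box3d(a, c(3L, 3L, 3L))), tolerance = 1e-10)
  expect_error(denoise(const, box = c(2, 3, 3)), "odd")
})

test_that("denoise commutes with affine rescaling and accepts a plugin", {
  set.seed(7)
  a <- array(runif(4 * 6 * 6), c(4, 6, 6))
  d1 <- denoise(mk_stack(2 * a + 3))
  d2 <- 2 * unclass(denoise(mk_stack(a))) + 3
  expect_equal(as.vector(d1), as.vector(d2), tolerance = 1e-12)
  dh <- denoise(mk_stack(a), video_denoiser = function(s) mk_stack(unclass(s) / 2))
  expect_equal(as.vector(dh), as.vector(denoise(mk_stack(a))) / 2, tolerance = 1e-12)
})

test_that("baseline and relative signal follow the dF/F convention", {
  b <- structure(list(value = matrix(10, 2, 2), source = "cellfree"),
                 class = "baseline_map")
  s <- mk_stack(array(12, c(2, 2, 2)))
  expect_equal(as.vector(relative_signal(s, b)), rep(0.2, 8))
  s_eq <- mk_stack(array(10, c(2, 2, 2)))
  expect_equal(as.vector(relative_signal(s_eq, b)), rep(0, 8))
  expect_error(relative_signal(s, matrix(0, 2, 2)), "baseline")
  # baseline estimate approaches the true mean at CLT rate
  set.seed(5)
  T_ <- 500; mu <- 50; sd_ <- 4
  cf <- mk_stack(array(rnorm(T_ * 4 * 4, mu, sd_), c(T_, 4, 4)), origin = "cellfree")
  bl <- estimate_baseline(cf)
  # denoised pixels average ~27 raw samples; 3 sigma/sqrt(T) on the raw sd
  # is a conservative per-pixel bound
  expect_true(all(abs(bl$value - mu) < 3 * sd_ / sqrt(T_) * 3))
})

test_that("adaptive threshold scales with k_sigma and measures residual noise", {
  quiet <- mk_stack(array(10, c(16, 4, 4)), origin = "cellfree")
  b <- estimate_baseline(quiet)
  thr0 <- adaptive_threshold(quiet, b, k_sigma = 3)
  expect_true(all(thr0$value == 0))
  set.seed(9)
  T_ <- 2000
  cf <- mk_stack(array(rnorm(T_ * 4 * 4, 100, 5), c(T_, 4, 4)), origin = "cellfree")
  b <- estimate_baseline(cf)
  t1 <- adaptive_threshold(cf, b, k_sigma = 3)
  t2 <- adaptive_threshold(cf, b, k_sigma = 6)
  expect_equal(t2$value, 2 * t1$value, tolerance = 1e-12)
  # box 3x3x3 averages 27 roughly independent samples: sigma_rel ~ 0.05/sqrt(27)
  expect_equal(mean(t1$value), 3 * 0.05 / sqrt(27), tolerance = 0.05)
  short <- mk_stack(array(rnorm(4 * 16, 100, 5), c(4, 4, 4)), origin = "cellfree")
  expect_error(adaptive_threshold(short, b), "T >= 8")
})

test_that("the detected active set is invariant to a shared constant offset", {
  set.seed(11)
  d <- c(40, 8, 8)
  act <- array(rnorm(prod(d), 100, 2), d); act[15:25, 3:5, 3:5] <- 130
  cf <- array(rnorm(prod(d), 100, 2), d)
  run <- function(shift) {
    a <- mk_stack(act + shift); f <- mk_stack(cf + shift, origin = "cellfree")
    b <- estimate_baseline(f)
    rel <- relative_signal(denoise(subtract_offset(a, f)), b, already_offset = TRUE)
    thr <- adaptive_threshold(f, b, 3)
    detect_activity(rel, thr)$mask
  }
  expect_identical(run(0), run(250))
})
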