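test_that("boxcar kernels have exact width, symmetry and unit sum", {
  for (case in list(c(3, 1), c(4, 1), c(4, 1.5), c(4, 2), c(26, 2))) {
    w <- ctdr:::kernel_weights(filter_kernel("boxcar", case[1]), case[2])
    expect_equal(sum(w), 1)
    expect_equal(w, rev(w))                       # symmetric: no phase shift
    expect_equal(length(w) %% 2, 1)
  }
  # integer odd ratio: plain moving average
  expect_equal(ctdr:::kernel_weights(filter_kernel("boxcar", 3), 1), rep(1 / 3, 3))
  # even ratio: fractional end-weights keep the width exact in mm
  expect_equal(ctdr:::kernel_weights(filter_kernel("boxcar", 4), 1),
               c(0.5, 1, 1, 1, 0.5) / 4)
})

test_that("filtering leaves a uniform volume unchanged (normalization)", {
  u0 <- ct_volume(array(0, c(40, 40, 40)), c(1, 1, 1))
  ext <- array(TRUE, c(40, 40, 40))
  for (k in list(filter_kernel("boxcar", 8), filter_kernel("gaussian", 5))) {
    f <- apply_lowpass(u0, k, ext)$volume
    expect_equal(max(abs(f$data[11:30, 11:30, 11:30])), 0)  # interior
  }
  # width 0 is the identity everywhere
  f0 <- apply_lowpass(u0, filter_kernel("boxcar", 0), ext)
  expect_identical(f0$volume$data, u0$data)
})

test_that("impulse response matches discrete convolution arithmetic", {
  a <- array(0, c(21, 21, 21)); a[11, 11, 11] <- 999
  v <- ct_volume(a, c(1, 1, 1))
  f <- apply_lowpass(v, filter_kernel("boxcar", 3), array(TRUE, c(21, 21, 21)))$volume
  expect_equal(f$data[11, 11, 11], 999 / 27)
  inner <- f$data[5:17, 5:17, 5:17]   # away from the air-padded boundary
  expect_equal(sum(inner != 0), 27)
  expect_equal(f$data[10, 11, 12], 999 / 27)
  # 1D: three consecutive voxels at 999/3 along one axis
  f1 <- ctdr:::conv_axis(a, rep(1 / 3, 3), 1, pad = 0)
  expect_equal(f1[10:12, 11, 11], rep(333, 3))
})

test_that("filtered white-noise std matches the kernel-weight prediction", {
  set.seed(21)
  n <- 100
  v <- ct_volume(array(rnorm(n^3, 0, 12), c(n, n, n)), c(1, 1, 1))
  f <- apply_lowpass(v, filter_kernel("boxcar", 4), array(TRUE, c(n, n, n)))$volume
  w <- ctdr:::kernel_weights(filter_kernel("boxcar", 4), 1)
  predicted <- 12 * sum(w^2)^(3 / 2)
  measured <- sd(f$data[11:90, 11:90, 11:90])
  expect_lt(abs(measured - predicted) / predicted, 0.03)
})

test_that("boxcar and its Gaussian equivalent reduce noise variance alike", {
  # per-axis variance-reduction factor sum(w^2), finely sampled kernels
  wb <- ctdr:::kernel_weights(filter_kernel("boxcar", 6), 0.5)
  wg <- ctdr:::kernel_weights(
    filter_kernel("gaussian", boxcar_gaussian_equivalent(6)$fwhm), 0.5)
  expect_lt(abs(sum(wb^2) - sum(wg^2)) / sum(wg^2), 0.05)
  # and in a Monte-Carlo measurement of the filtered std
  set.seed(8)
  v <- ct_volume(array(rnorm(80^3, 0, 10), c(80, 80, 80)), c(0.5, 0.5, 0.5))
  ext <- array(TRUE, c(80, 80, 80))
  sb <- sd(apply_lowpass(v, filter_kernel("boxcar", 6), ext)$volume$data[21:60, 21:60, 21:60])
  sg <- sd(apply_lowpass(v, filter_kernel("gaussian", boxcar_gaussian_equivalent(6)$fwhm),
                         ext)$volume$data[21:60, 21:60, 21:60])
  expect_lt(abs(sb - sg) / sg, 0.05)
})

test_that("interior mean HU is preserved under any normalized kernel", {
  set.seed(13)
  v <- ct_volume(array(40 + rnorm(60^3, 0, 10), c(60, 60, 60)), c(1, 1, 1))
  ext <- array(TRUE, c(60, 60, 60))
  for (k in list(filter_kernel("boxcar", 6), filter_kernel("gaussian", 6))) {
    f <- apply_lowpass(v, k, ext)$volume
    inner <- 16:45
    expect_lt(abs(mean(f$data[inner, inner, inner]) -
                  mean(v$data[inner, inner, inner])), 0.1)
  }
})

test_that("additive noise: identity at zero, calibrated std, seeded, masked", {
  v <- ct_volume(array(0, c(50, 50, 50)), c(2, 2, 2))
  expect_identical(add_noise(v, noise_model(0, 1))$data, v$data)
  n1 <- add_noise(v, noise_model(15, 7))
  n2 <- add_noise(v, noise_model(15, 7))
  expect_identical(n1$data, n2$data)                 # same seed, same bytes
  expect_lt(abs(sd(n1$data) - 15) / 15, 0.01)        # 125k voxels
  ext <- array(FALSE, c(50, 50, 50)); ext[11:40, 11:40, 11:40] <- TRUE
  nm <- add_noise(v, noise_model(15, 7), ext)
  expect_true(all(nm$data[!ext] == 0))
  expect_gt(sd(nm$data[ext]), 14)
})

test_that("noise added after filtering keeps its full level (study ordering)", {
  set.seed(2)
  v <- ct_volume(array(rnorm(40^3, 0, 8), c(40, 40, 40)), c(1, 1, 1))
  ext <- array(TRUE, c(40, 40, 40))
  out <- degrade_ct(v, filter_kernel("boxcar", 6), ext, noise_model(20, 3))
  base <- apply_lowpass(v, filter_kernel("boxcar", 6), ext)$volume
  expect_lt(abs(sd(out$volume$data - base$data) - 20) / 20, 0.01)
})

test_that("boxcar-Gaussian width equivalence follows sigma = w / sqrt(12)", {
  eq <- boxcar_gaussian_equivalent(4)
  expect_equal(round(eq$fwhm, 1), 2.7)
  expect_equal(boxcar_gaussian_equivalent(0), list(sigma = 0, fwhm = 0))
  set.seed(31)
  x <- runif(2e5, -3, 3)     # uniform of width 6
  expect_lt(abs(sd(x) - 6 / sqrt(12)) / (6 / sqrt(12)), 0.01)
})

test_that("a kernel wider than the grid is rejected", {
  v <- ct_volume(array(0, c(10, 10, 10)), c(1, 1, 1))
  expect_error(apply_lowpass(v, filter_kernel("boxcar", 50), array(TRUE, c(10, 10, 10))),
               "wider than the grid")
})
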