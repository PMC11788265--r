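dose_vol <- function(a, spacing = c(1, 1, 1)) {
  v <- ct_volume(a, spacing)
  v$quantity <- "dose"
  v
}

ramp_pair <- function(shift = 0.5, d = c(24, 24, 24)) {
  ramp <- array(0, d)
  for (k in seq_len(d[1])) ramp[k, , ] <- seq(10, 60, length.out = d[1])[k]
  ref <- dose_vol(ramp)
  ev <- shift_volume(dose_vol(ramp), c(shift, 0, 0), fill = 10)
  ev$quantity <- "dose"
  list(ref = ref, ev = ev)
}

test_that("identical distributions give gamma 0 and a 100% pass rate", {
  p <- ramp_pair(0)
  gc_ <- gamma_criteria(threshold = 0)
  gr <- gamma_index(p$ref, p$ref, gc_)
  expect_equal(max(gr$map), 0)
  d <- dim(p$ref$data)
  rois <- roi_set(list(external = array(TRUE, d)), c(external = "external"), c(1, 1, 1))
  gr2 <- gamma_index(p$ref, p$ref, gc_, rois)
  expect_equal(pass_rate(gr2, "external"), 100)
})

test_that("a uniform 2% offset gives gamma = 2 everywhere (no DTA rescue)", {
  d <- c(16, 16, 16)
  ref <- dose_vol(array(50, d))
  ev <- dose_vol(array(51, d))      # +2% of the 50 Gy normalization
  gr <- gamma_index(ref, ev, gamma_criteria(dta = 1, dose_diff = 0.01, threshold = 0))
  inner <- gr$map[4:13, 4:13, 4:13]  # away from the grid edge
  expect_equal(max(abs(inner - 2)), 0, tolerance = 1e-9)
  rois <- roi_set(list(external = array(TRUE, d)), c(external = "external"), c(1, 1, 1))
  gr2 <- gamma_index(ref, ev, gamma_criteria(threshold = 0), rois)
  expect_equal(pass_rate(gr2, "external"), 0)
})

test_that("sub-millimetre shifts of a ramp resolve through the DTA term", {
  p <- ramp_pair(0.5)
  gr <- gamma_index(p$ref, p$ev, gamma_criteria(threshold = 0))
  inner <- gr$map[5:20, 5:20, 5:20]
  # gradient 50/23 Gy/mm ~ 2.2% of norm per mm: gamma ~ 0.5 * sqrt(2) scale
  expect_lt(max(inner), 0.5 * sqrt(2) + 0.05)
  expect_gt(mean(inner), 0.2)
})

test_that("production shell search equals the exhaustive dense oracle", {
  p <- ramp_pair(0.5)
  gc_ <- gamma_criteria(threshold = 0)
  gr <- gamma_index(p$ref, p$ev, gc_)
  set.seed(17)
  vox <- sample(which(!is.nan(gr$map)), 250)
  go <- gamma_index_exhaustive(p$ref, p$ev, gc_, vox, dnorm = gr$dnorm)
  expect_lt(max(abs(gr$map[vox] - go)), 0.02)
  # and on a noisy dose pair
  set.seed(18)
  d <- c(16, 16, 16)
  ref <- dose_vol(array(40 + rnorm(prod(d), 0, 0.3), d))
  ev <- dose_vol(ref$data + rnorm(prod(d), 0, 0.3))
  gr2 <- gamma_index(ref, ev, gc_)
  vox2 <- sample(which(!is.nan(gr2$map)), 150)
  go2 <- gamma_index_exhaustive(ref, ev, gc_, vox2, dnorm = gr2$dnorm,
                                max_radius = 3)
  expect_lt(max(abs(gr2$map[vox2] - go2)), 0.02)
})

test_that("gamma is invariant under common rescaling of both doses", {
  p <- ramp_pair(0.4)
  gc_ <- gamma_criteria(threshold = 0.1)
  g1 <- gamma_index(p$ref, p$ev, gc_)
  ref2 <- dose_vol(3 * p$ref$data); ev2 <- dose_vol(3 * p$ev$data)
  g2 <- gamma_index(ref2, ev2, gc_)   # max_reference normalization rescales too
  expect_equal(g1$map, g2$map, tolerance = 1e-12)
})

test_that("refining the interpolation sub-grid never increases gamma", {
  p <- ramp_pair(0.37)
  gc_ <- gamma_criteria(threshold = 0)
  g10 <- gamma_index(p$ref, p$ev, gc_, subdivision = 10)
  g20 <- gamma_index(p$ref, p$ev, gc_, subdivision = 20)
  expect_true(all(g20$map <= g10$map + 1e-9))
})

test_that("voxels below the dose threshold are excluded as NaN", {
  d <- c(16, 16, 16)
  a <- array(1, d); a[8:16, , ] <- 60
  ref <- dose_vol(a)
  gr <- gamma_index(ref, ref, gamma_criteria(threshold = 0.10))
  expect_true(all(is.nan(gr$map[1:6, , ])))   # ~1.7% of norm, below 10%
  expect_true(all(!is.nan(gr$map[9:16, , ])))
})

test_that("pass_rate matches a direct count and validates its ROI", {
  p <- ramp_pair(0.5)
  d <- dim(p$ref$data)
  half <- array(FALSE, d); half[1:12, , ] <- TRUE
  rois <- roi_set(list(external = array(TRUE, d), half = half),
                  c(external = "external", half = "OAR"), c(1, 1, 1))
  gr <- gamma_index(p$ref, p$ev, gamma_criteria(threshold = 0), rois)
  m <- half & !is.nan(gr$map)
  expect_equal(pass_rate(gr, "half"), 100 * sum(gr$map[m] <= 1) / sum(m))
  expect_error(pass_rate(gr, "nope"), "not scored")
})

test_that("geometry mismatches are rejected", {
  a <- dose_vol(array(1, c(8, 8, 8)))
  b <- dose_vol(array(1, c(8, 8, 9)))
  expect_error(gamma_index(a, b, gamma_criteria(threshold = 0)), "geometry")
})
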