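full_water_spec <- function(noise = 0, seed = 1L) {
  phantom_spec("watercube", c(24, 24, 24), c(2, 2, 2),
               tissue_layout = list(
                 phantom_primitive("slab", 0, axis = 3L, range = c(-1, 47))),
               target_def = list(center = c(23, 23, 23), radius = 6,
                                 location = "homogeneous"),
               baseline_noise_sigma = noise, seed = seed)
}

test_that("noiseless water cube is exactly 0 HU with a full external", {
  ph <- generate_phantom(full_water_spec(0))
  expect_true(all(ph$volume$data == 0))
  expect_true(all(roi_mask(ph$rois, "external")))
})

test_that("phantom generation is deterministic given the seed", {
  a <- generate_phantom(canonical_phantom("brain", c(32, 32, 32), c(4, 4, 4), seed = 9))
  b <- generate_phantom(canonical_phantom("brain", c(32, 32, 32), c(4, 4, 4), seed = 9))
  expect_identical(a$volume$data, b$volume$data)
  d <- generate_phantom(canonical_phantom("brain", c(32, 32, 32), c(4, 4, 4), seed = 10))
  expect_false(identical(a$volume$data, d$volume$data))
})

test_that("thorax phantom tissue statistics match the labels", {
  ph <- generate_phantom(canonical_phantom("thorax", c(64, 64, 64), c(3, 3, 3)))
  lung <- roi_mask(ph$rois, "lung")
  n <- sum(lung)
  sigma <- 2.3   # thorax baseline noise
  expect_lt(abs(mean(ph$volume$data[lung]) - (-750)), 3 * sigma / sqrt(n))
  # the CTV straddles a >= 500 HU density step (interface class)
  ctv <- roi_mask(ph$rois, "CTV")
  hu <- ph$noiseless$data[ctv]
  expect_gte(diff(range(hu)), 500)
})

test_that("later primitives overwrite earlier ones", {
  spec <- phantom_spec("ovr", c(20, 20, 20), c(2, 2, 2),
    tissue_layout = list(
      phantom_primitive("slab", 0, axis = 3L, range = c(-1, 39)),
      phantom_primitive("sphere", 500, center = c(19, 19, 19), radius = 8)),
    target_def = list(center = c(19, 19, 19), radius = 5, location = "homogeneous"),
    baseline_noise_sigma = 0)
  ph <- generate_phantom(spec)
  expect_setequal(unique(as.vector(ph$noiseless$data)), c(0, 500))
  expect_equal(ph$noiseless$data[10, 10, 10], 500)  # centre voxel: last primitive
})

test_that("baseline noise is white: lag-1 autocorrelation vanishes", {
  ph <- generate_phantom(full_water_spec(noise = 5, seed = 4L))
  eps <- ph$volume$data - ph$noiseless$data
  n <- length(eps)
  for (ax in 1:3) {
    idx <- lapply(dim(eps), seq_len)
    i1 <- idx; i1[[ax]] <- 1:(dim(eps)[ax] - 1)
    i2 <- idx; i2[[ax]] <- 2:dim(eps)[ax]
    r <- cor(as.vector(eps[i1[[1]], i1[[2]], i1[[3]]]),
             as.vector(eps[i2[[1]], i2[[2]], i2[[3]]]))
    expect_lt(abs(r), 4 / sqrt(n))
  }
})

test_that("a target outside the grid is rejected with a message naming it", {
  spec <- phantom_spec("bad", c(20, 20, 20), c(2, 2, 2),
    tissue_layout = list(phantom_primitive("slab", 0, axis = 3L, range = c(-1, 39))),
    target_def = list(center = c(36, 19, 19), radius = 6, location = "homogeneous"),
    baseline_noise_sigma = 0)
  expect_error(generate_phantom(spec), "CTV")
})

test_that("noiseless wire phantom peaks on the wire axis in plain water", {
  spec <- wire_phantom_spec(psf_fwhm = 0, noise_sigma = 0,
                            grid_shape = c(81, 81, 8), spacing = c(0.5, 0.5, 1))
  v <- generate_wire_phantom(spec)
  pk <- which(v$data == max(v$data), arr.ind = TRUE)
  expect_true(all(pk[, 1] == 41), all(pk[, 2] == 41))
  # away from the wire: plain water
  expect_equal(max(abs(v$data[1:30, , ])), 0)
  expect_gt(max(v$data), 100)  # wire visible despite sub-voxel diameter
})

test_that("two noise seeds differ only by independent noise", {
  s1 <- wire_phantom_spec(psf_fwhm = 1.5, noise_sigma = 5, seed = 1L)
  s2 <- wire_phantom_spec(psf_fwhm = 1.5, noise_sigma = 5, seed = 2L)
  d <- generate_wire_phantom(s1)$data - generate_wire_phantom(s2)$data
  expect_lt(abs(mean(d)), 0.1)
  expect_lt(abs(sd(d) - sqrt(2) * 5), 0.05)
})

test_that("a wire longer than the grid is rejected", {
  expect_error(
    generate_wire_phantom(wire_phantom_spec(wire_length = 500,
                                            grid_shape = c(41, 41, 8),
                                            spacing = c(0.5, 0.5, 1))),
    "longer than the grid")
})
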