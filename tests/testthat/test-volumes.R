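test_that("NIfTI round trip preserves data bit-exactly and geometry", {
  set.seed(11)
  v <- ct_volume(array(rnorm(20 * 18 * 16), c(20, 18, 16)),
                 spacing = c(1, 1, 3), origin = c(5, 0, 2.5))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_identical(as.vector(v2$data), as.vector(v$data))
  expect_lt(max(abs(v2$spacing - v$spacing)), 1e-6)
  expect_lt(max(abs(v2$origin - v$origin)), 1e-6)
})

test_that("non-3D input is rejected", {
  expect_error(ct_volume(matrix(0, 4, 4), c(1, 1, 1)), "3D")
  f <- tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(matrix(rnorm(16), 4, 4)), f)
  expect_error(read_volume(f), "3D")
  expect_error(read_volume("plan.json"), "format")
})

test_that("HU-to-RSP calibration hits anchors, is piecewise linear and clamps", {
  cur <- default_calibration()
  v <- ct_volume(array(c(0, -1000, 30, -2000, 5000, 700), c(6, 1, 1)), c(1, 1, 1))
  r <- hu_to_rsp(v, cur)
  expect_equal(r$data[1], 1.000)        # water anchor
  expect_equal(r$data[2], 0.001)        # air anchor
  expect_equal(r$data[3], (1.000 + 1.04) / 2)  # midway between anchors
  expect_equal(r$data[4], 0.001)        # clamped below
  expect_equal(r$data[5], 2.4)          # clamped above
  expect_equal(r$data[6], 1.30)
  expect_identical(r$quantity, "RSP")
})

test_that("calibration is monotone and rejects non-monotone anchors", {
  cur <- default_calibration()
  hu <- sort(runif(200, -1100, 3100))
  v <- ct_volume(array(hu, c(200, 1, 1)), c(1, 1, 1))
  r <- hu_to_rsp(v, cur)
  expect_true(all(diff(as.vector(r$data)) >= 0))
  expect_true(all(r$data >= 0))
  expect_error(calibration_curve(c(0, 100), c(1.0, 0.9)), "monotonically")
})

test_that("external contour: cylinder recovered, air rejected, single component", {
  d <- c(32, 32, 16)
  a <- array(-1000, d)
  xs <- (seq_len(d[1]) - 1); ys <- (seq_len(d[2]) - 1)
  r2 <- outer((xs - 15.5)^2, (ys - 15.5)^2, `+`)
  for (z in 1:16) a[, , z] <- ifelse(r2 <= 100, 0, -1000)
  v <- ct_volume(a, c(2, 2, 2))
  m <- external_from_hu(v, threshold = -300)
  inner2d <- r2 <= 81; outer2d <- r2 >= 144
  for (z in 1:16) {
    expect_true(all(m[, , z][inner2d]))   # interior well inside the cylinder
    expect_false(any(m[, , z][outer2d]))
  }
  lab <- array(ctdr:::label_components_cpp(m, as.integer(d)), d)
  expect_equal(max(lab), 1L)  # a single connected component
  expect_error(external_from_hu(ct_volume(array(-1000, d), c(2, 2, 2))), "no voxels")
})

test_that("external contour fills enclosed low-density cavities", {
  ph <- generate_phantom(canonical_phantom("thorax", c(48, 48, 48), c(4, 4, 4)))
  lung <- roi_mask(ph$rois, "lung")
  ext <- roi_mask(ph$rois, "external")
  expect_true(all(ext[lung]))
})

test_that("expand_external is monotone, identity at zero and adds margin", {
  set.seed(3)
  m <- array(FALSE, c(24, 24, 24))
  m[8:16, 8:16, 8:16] <- TRUE
  sp <- c(1, 1, 1)
  expect_identical(expand_external(m, 0, sp), m)
  e4 <- expand_external(m, 4, sp)   # radius ceil(4/2) = 2 voxels
  expect_true(all(e4[6:18, 8:16, 8:16]))
  for (k in 1:4) {
    a <- sort(runif(2, 0, 10))
    ea <- expand_external(m, a[1], sp); eb <- expand_external(m, a[2], sp)
    expect_true(all(eb[ea]))   # expand(m, small) inside expand(m, large)
    expect_true(all(ea[m]))    # original contained
  }
})

test_that("roi_set enforces shared geometry and CTV/PTV/external nesting", {
  d <- c(10, 10, 10)
  ctv <- array(FALSE, d); ctv[4:6, 4:6, 4:6] <- TRUE
  ptv <- array(FALSE, d); ptv[3:7, 3:7, 3:7] <- TRUE
  ext <- array(TRUE, d)
  rs <- roi_set(list(external = ext, CTV = ctv, PTV = ptv),
                c(external = "external", CTV = "CTV", PTV = "PTV"), c(1, 1, 1))
  expect_identical(roi_mask(rs, "CTV"), ctv)
  expect_error(
    roi_set(list(external = ext, CTV = ptv, PTV = ctv),
            c(external = "external", CTV = "CTV", PTV = "PTV"), c(1, 1, 1)),
    "contained")
})
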