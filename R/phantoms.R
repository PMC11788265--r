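# Synthetic digital phantoms: anatomical test cases with ROIs, and the
# wire-in-water resolution phantom. These stand in for clinical planning CTs
# so that every downstream stage is testable without external data.

#' Geometric primitive for phantom construction
#'
#' Supported shapes: `"slab"` (half-open range along one axis, full
#' cross-section), `"sphere"`, and `"cylinder"` (axis-aligned, optionally
#' limited in length). Later primitives overwrite earlier ones, so the paint
#' order is part of the phantom definition.
#'
#' @param shape `"slab"`, `"sphere"` or `"cylinder"`.
#' @param hu HU value painted by the primitive, in \[-1024, 3000\].
#' @param name optional name; named non-body primitives become OAR masks.
#' @param center sphere/cylinder centre, mm (cylinder: centre of its axis).
#' @param radius sphere/cylinder radius, mm.
#' @param axis slab/cylinder axis (1 = x, 2 = y, 3 = z).
#' @param range slab extent along `axis`, mm (length 2).
#' @param length cylinder length along `axis`, mm (`Inf` = through the grid).
#' @return A `phantom_primitive` list.
#' @export
phantom_primitive <- function(shape = c("slab", "sphere", "cylinder"), hu,
                              name = NULL, center = NULL, radius = NULL,
                              axis = 3L, range = NULL, length = Inf) {
  shape <- match.arg(shape)
  if (hu < -1024 || hu > 3000) stop("primitive HU outside [-1024, 3000]")
  structure(list(shape = shape, hu = hu, name = name, center = center,
                 radius = radius, axis = as.integer(axis), range = range,
                 length = length),
            class = "phantom_primitive")
}

#' Specification of an anatomical phantom
#'
#' @param name label.
#' @param grid_shape voxels per axis (length 3).
#' @param spacing mm per axis (length 3, > 0).
#' @param tissue_layout list of [phantom_primitive]s painted in order onto an
#'   air (-1000 HU) background.
#' @param target_def list with `center` (mm), `radius` (mm) and `location`
#'   (`"homogeneous"` or `"interface"`) describing the CTV.
#' @param ptv_margin_mm CTV-to-PTV expansion in mm.
#' @param baseline_noise_sigma baseline white-noise level of the emulated
#'   planning CT, HU.
#' @param seed RNG seed for the baseline noise.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(name, grid_shape = c(96, 96, 96), spacing = c(2, 2, 2),
                         tissue_layout, target_def, ptv_margin_mm = 3,
                         baseline_noise_sigma = 5, seed = 42L) {
  stopifnot(length(grid_shape) == 3, length(spacing) == 3, all(spacing > 0),
            baseline_noise_sigma >= 0)
  loc <- match.arg(target_def$location, c("homogeneous", "interface"))
  target_def$location <- loc
  structure(list(name = name, grid_shape = as.integer(grid_shape),
                 spacing = as.numeric(spacing), tissue_layout = tissue_layout,
                 target_def = target_def, ptv_margin_mm = ptv_margin_mm,
                 baseline_noise_sigma = baseline_noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

prim_mask <- function(p, coords, d) {
  switch(p$shape,
    slab = {
      m <- array(FALSE, d)
      ax <- coords[[p$axis]]
      sel <- which(ax >= p$range[1] & ax <= p$range[2])
      idx <- lapply(d, seq_len); idx[[p$axis]] <- sel
      if (length(sel)) m[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
      m
    },
    sphere = {
      dx2 <- outer(outer((coords[[1]] - p$center[1])^2,
                         (coords[[2]] - p$center[2])^2, `+`),
                   (coords[[3]] - p$center[3])^2, `+`)
      dx2 <= p$radius^2
    },
    cylinder = {
      tr <- setdiff(1:3, p$axis)
      r2 <- outer((coords[[tr[1]]] - p$center[tr[1]])^2,
                  (coords[[tr[2]]] - p$center[tr[2]])^2, `+`)
      m2 <- r2 <= p$radius^2
      along <- abs(coords[[p$axis]] - p$center[p$axis]) <= p$length / 2
      full <- array(FALSE, d)
      perm <- c(tr, p$axis)
      a3 <- outer(m2, along, `&`)           # dims tr1, tr2, axis
      aperm(array(a3, dim(a3)), order(perm))
    })
}

#' Generate an anatomical phantom volume with ROIs
#'
#' Paints the tissue primitives in order onto an air background, derives the
#' external contour, CTV and PTV masks (plus an OAR mask per named
#' primitive), and adds the baseline white Gaussian noise. Deterministic for
#' a fixed spec and seed.
#'
#' @param spec a [phantom_spec].
#' @return A list with `volume` (noisy [ct_volume]), `noiseless`
#'   ([ct_volume]), and `rois` ([roi_set] containing at least
#'   `external`, `CTV`, `PTV`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  extent <- (d - 1) * spec$spacing
  coords <- lapply(1:3, function(ax) (seq_len(d[ax]) - 1) * spec$spacing[ax])
  td <- spec$target_def
  if (any(td$center - td$radius < 0) || any(td$center + td$radius > extent))
    stop("generate_phantom: target 'CTV' (sphere r=", td$radius,
         " at ", paste(td$center, collapse = ","), ") extends outside the grid")
  vol <- array(-1000, d)
  named <- list()
  for (p in spec$tissue_layout) {
    m <- prim_mask(p, coords, d)
    vol[m] <- p$hu
    if (!is.null(p$name)) named[[p$name]] <- m
  }
  noiseless <- ct_volume(vol, spec$spacing, c(0, 0, 0), "HU")
  external <- external_from_hu(noiseless)
  ctv <- prim_mask(phantom_primitive("sphere", hu = 0, center = td$center,
                                     radius = td$radius), coords, d)
  if (any(ctv & !external))
    stop("generate_phantom: target 'CTV' is not strictly inside the external contour")
  ptv <- dilate_mm(ctv, spec$spacing, spec$ptv_margin_mm)
  masks <- list(external = external | ptv, CTV = ctv, PTV = ptv)
  roles <- c(external = "external", CTV = "CTV", PTV = "PTV")
  for (nm in names(named)) {
    masks[[nm]] <- named[[nm]]
    roles[nm] <- "OAR"
  }
  noisy <- if (spec$baseline_noise_sigma > 0)
    add_noise(noiseless, noise_model(spec$baseline_noise_sigma, spec$seed))
  else noiseless
  list(volume = noisy, noiseless = noiseless,
       rois = roi_set(masks, roles, spec$spacing))
}

#' Canonical phantom specifications
#'
#' Four synthetic cases spanning the homogeneous-vs-heterogeneous contrast of
#' typical proton treatment sites. Geometries are generic (spheres, cylinders,
#' slabs), not anthropomorphic:
#' * `brain`: homogeneous 40 HU brain inside a 1200 HU skull shell; CTV
#'   centred in homogeneous surroundings; baseline noise 6.0 HU.
#' * `thorax`: soft-tissue body cylinder with a -750 HU lung; CTV at the
#'   chest-wall/lung interface (>= 500 HU density step); baseline noise 2.3 HU.
#' * `abdomen`: soft tissue with a vertebral column; homogeneous CTV;
#'   baseline noise 8 HU.
#' * `pelvis`: soft tissue with femoral heads; homogeneous CTV; baseline
#'   noise 9.6 HU.
#'
#' @param name one of `"brain"`, `"thorax"`, `"abdomen"`, `"pelvis"`.
#' @param grid_shape,spacing grid geometry; the default 96^3 at 2 mm keeps
#'   run times desk-scale (1 mm is available by configuration).
#' @param seed RNG seed for the baseline noise.
#' @return A [phantom_spec].
#' @export
canonical_phantom <- function(name = c("brain", "thorax", "abdomen", "pelvis"),
                              grid_shape = c(96, 96, 96), spacing = c(2, 2, 2),
                              seed = 42L) {
  name <- match.arg(name)
  ctr <- (grid_shape - 1) * spacing / 2
  P <- phantom_primitive
  switch(name,
    brain = phantom_spec(
      "brain",
      grid_shape, spacing,
      tissue_layout = list(
        P("sphere", 1200, name = "skull", center = ctr, radius = 78),
        P("sphere", 40, center = ctr, radius = 72)),
      target_def = list(center = ctr, radius = 12, location = "homogeneous"),
      ptv_margin_mm = 3, baseline_noise_sigma = 6.0, seed = seed),
    thorax = phantom_spec(
      "thorax",
      grid_shape, spacing,
      tissue_layout = list(
        P("cylinder", 40, center = ctr, radius = 80, axis = 3L),
        P("cylinder", -750, name = "lung",
          center = ctr + c(-30, 0, 0), radius = 40, axis = 3L, length = 140)),
      target_def = list(center = ctr + c(10, 0, 0), radius = 12,
                        location = "interface"),
      ptv_margin_mm = 5, baseline_noise_sigma = 2.3, seed = seed),
    abdomen = phantom_spec(
      "abdomen",
      grid_shape, spacing,
      tissue_layout = list(
        P("cylinder", 30, center = ctr, radius = 85, axis = 3L),
        P("cylinder", 700, name = "vertebra",
          center = ctr + c(0, 45, 0), radius = 12, axis = 3L)),
      target_def = list(center = ctr, radius = 14, location = "homogeneous"),
      ptv_margin_mm = 5, baseline_noise_sigma = 8, seed = seed),
    pelvis = phantom_spec(
      "pelvis",
      grid_shape, spacing,
      tissue_layout = list(
        P("cylinder", 40, center = ctr, radius = 88, axis = 3L),
        P("sphere", 1000, name = "femur_left", center = ctr + c(-45, 0, 0), radius = 15),
        P("sphere", 1000, name = "femur_right", center = ctr + c(45, 0, 0), radius = 15)),
      target_def = list(center = ctr, radius = 14, location = "homogeneous"),
      ptv_margin_mm = 5, baseline_noise_sigma = 9.6, seed = seed))
}

#' Specification of the wire resolution phantom
#'
#' A thin copper wire (default 0.18 mm diameter) running along z in a water
#' cylinder (default 20 cm diameter; only the gridded central region is
#' represented), blurred by a known isotropic Gaussian scanner PSF and
#' overlaid with white noise. Used to measure the line-spread function.
#'
#' @param wire_diameter mm; may be smaller than the voxel spacing (sub-voxel
#'   wires are rasterized with area weighting).
#' @param cylinder_diameter mm.
#' @param wire_hu,water_hu HU values.
#' @param psf_fwhm scanner PSF FWHM to simulate, mm (>= 0).
#' @param grid_shape,spacing grid geometry; fine in-plane sampling by default.
#' @param noise_sigma HU.
#' @param wire_length mm (`Inf` = full grid extent along z).
#' @param seed RNG seed.
#' @return A `wire_phantom_spec` object.
#' @export
wire_phantom_spec <- function(wire_diameter = 0.18, cylinder_diameter = 200,
                              wire_hu = 3000, water_hu = 0, psf_fwhm = 1.45,
                              grid_shape = c(161, 161, 16),
                              spacing = c(0.25, 0.25, 1), noise_sigma = 0,
                              wire_length = Inf, seed = 42L) {
  stopifnot(psf_fwhm >= 0, noise_sigma >= 0, wire_diameter > 0)
  structure(list(wire_diameter = wire_diameter,
                 cylinder_diameter = cylinder_diameter, wire_hu = wire_hu,
                 water_hu = water_hu, psf_fwhm = psf_fwhm,
                 grid_shape = as.integer(grid_shape),
                 spacing = as.numeric(spacing), noise_sigma = noise_sigma,
                 wire_length = wire_length, seed = as.integer(seed)),
            class = "wire_phantom_spec")
}

#' Generate the wire resolution phantom
#'
#' The wire is rasterized with sub-voxel area weighting (each in-plane cell
#' receives the HU mix proportional to the wire cross-section it covers),
#' blurred by an isotropic Gaussian of FWHM `psf_fwhm`, then noise is added.
#'
#' @param spec a [wire_phantom_spec].
#' @return A [ct_volume] (HU).
#' @export
generate_wire_phantom <- function(spec) {
  stopifnot(inherits(spec, "wire_phantom_spec"))
  d <- spec$grid_shape
  sp <- spec$spacing
  zext <- (d[3] - 1) * sp[3]
  if (is.finite(spec$wire_length) && spec$wire_length > zext + sp[3])
    stop("generate_wire_phantom: wire (", spec$wire_length,
         " mm) longer than the grid (", zext, " mm)")
  cx <- (d[1] - 1) * sp[1] / 2
  cy <- (d[2] - 1) * sp[2] / 2
  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  # water cylinder (clipped by the grid)
  r2 <- outer((xs - cx)^2, (ys - cy)^2, `+`)
  slice <- array(-1000, d[1:2])
  slice[r2 <= (spec$cylinder_diameter / 2)^2] <- spec$water_hu
  # wire cross-section: area fraction by supersampling cells near the axis
  rw <- spec$wire_diameter / 2
  near <- which(r2 <= (rw + max(sp[1:2]))^2, arr.ind = TRUE)
  ss <- 16L
  off <- (seq_len(ss) - 0.5) / ss - 0.5
  for (k in seq_len(nrow(near))) {
    i <- near[k, 1]; j <- near[k, 2]
    sx <- xs[i] + off * sp[1]
    sy <- ys[j] + off * sp[2]
    frac <- mean(outer((sx - cx)^2, (sy - cy)^2, `+`) <= rw^2)
    slice[i, j] <- slice[i, j] + frac * (spec$wire_hu - spec$water_hu)
  }
  vol <- array(slice, d)
  if (is.finite(spec$wire_length)) {
    zc <- zext / 2
    zs <- (seq_len(d[3]) - 1) * sp[3]
    outside <- which(abs(zs - zc) > spec$wire_length / 2)
    for (z in outside) vol[, , z] <- slice * 0 + slice  # keep water, drop wire
    base <- array(-1000, d[1:2]); base[r2 <= (spec$cylinder_diameter / 2)^2] <- spec$water_hu
    for (z in outside) vol[, , z] <- base
  }
  v <- ct_volume(vol, sp, c(0, 0, 0), "HU")
  if (spec$psf_fwhm > 0) {
    ker <- filter_kernel("gaussian", spec$psf_fwhm)
    out <- v$data
    for (ax in 1:3) {
      wt <- kernel_weights(ker, sp[ax])
      if (length(wt) > 1) out <- conv_axis(out, wt, ax, pad = spec$water_hu)
    }
    v <- vol_like(v, out)
  }
  if (spec$noise_sigma > 0)
    v <- add_noise(v, noise_model(spec$noise_sigma, spec$seed))
  v
}
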