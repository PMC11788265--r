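# External-contour operations built on an exact Euclidean distance transform,
# so that dilation/erosion radii are isotropic in mm on anisotropic grids.

edt_sq <- function(mask, spacing) {
  d <- dim(mask)
  array(edt_sq_cpp(as.logical(mask), as.integer(d), as.numeric(spacing)), d)
}

dilate_mm <- function(mask, spacing, radius_mm) {
  if (radius_mm <= 0 || !any(mask)) return(mask)
  edt_sq(mask, spacing) <= radius_mm^2 + 1e-9
}

erode_mm <- function(mask, spacing, radius_mm) {
  if (radius_mm <= 0) return(mask)
  !dilate_mm(!mask, spacing, radius_mm)
}

close_mm <- function(mask, spacing, radius_mm) {
  erode_mm(dilate_mm(mask, spacing, radius_mm), spacing, radius_mm)
}

largest_component <- function(mask) {
  d <- dim(mask)
  lab <- array(label_components_cpp(as.logical(mask), as.integer(d)), d)
  lab == 1L
}

# Fill internal cavities: background components not connected to the grid
# border (e.g. lungs below the external threshold) belong to the body.
fill_holes <- function(mask) {
  d <- dim(mask)
  lab <- array(label_components_cpp(!mask, as.integer(d)), d)
  border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]))
  border <- setdiff(border, 0L)
  mask | !(lab %in% border | lab == 0L)
}

#' Derive the external (body) contour from an HU volume
#'
#' Thresholds the volume, keeps the largest 6-connected component, applies a
#' morphological closing and fills internal cavities (air- or lung-density
#' regions enclosed by the body belong to the patient), yielding a single
#' connected body mask.
#'
#' @param ct a [ct_volume] with quantity `"HU"`.
#' @param threshold HU threshold; voxels above it are body candidates.
#'   The default -300 HU is robust against lung tissue at the body surface.
#' @param closing_mm radius (mm) of the closing applied after component
#'   selection.
#' @return A logical mask congruent with `ct`.
#' @export
external_from_hu <- function(ct, threshold = -300, closing_mm = 2) {
  stopifnot(inherits(ct, "ct_volume"))
  m <- ct$data > threshold
  if (!any(m)) stop("external_from_hu: no voxels above ", threshold, " HU")
  m <- largest_component(m)
  m <- close_mm(m, ct$spacing, closing_mm)
  fill_holes(m)
}

#' Expand a mask by an isotropic margin
#'
#' Morphological dilation by `ceiling(kernel_width / 2)` mm, used to adapt the
#' external contour to low-pass-filtered image sets whose body surface is
#' smeared outward into air. The original mask is always contained in the
#' result, and expansion is monotone in the width.
#'
#' @param mask logical 3D array.
#' @param kernel_width filter width in mm (>= 0); the dilation radius is
#'   `ceiling(kernel_width / 2)` mm.
#' @param spacing voxel spacing in mm.
#' @return The expanded logical mask.
#' @export
expand_external <- function(mask, kernel_width, spacing) {
  stopifnot(kernel_width >= 0)
  if (kernel_width == 0) return(mask)
  dilate_mm(mask, spacing, ceiling(kernel_width / 2))
}
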