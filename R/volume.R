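#' Geometry-aware 3D scalar volume
#'
#' A `ct_volume` carries a 3D scalar array together with its voxel spacing,
#' origin (world position of the centre of voxel `[1,1,1]`, in mm) and the
#' physical quantity it stores. All package operations preserve the geometry
#' metadata exactly. World coordinates are in mm with axis order (x, y, z);
#' the world position of voxel `(i, j, k)` is `origin + (c(i,j,k) - 1) * spacing`.
#'
#' @param data 3D numeric array of finite values.
#' @param spacing numeric length-3, voxel spacing in mm (all > 0).
#' @param origin numeric length-3, mm. Default `c(0, 0, 0)`.
#' @param quantity one of `"HU"`, `"RSP"`, `"dose"`.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing, origin = c(0, 0, 0), quantity = "HU") {
  if (length(dim(data)) != 3L)
    stop("ct_volume: `data` must be a 3D array, got ", length(dim(data)), " dimensions")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("ct_volume: spacing must be three positive numbers (mm)")
  if (!all(is.finite(data))) stop("ct_volume: data contains non-finite values")
  quantity <- match.arg(quantity, c("HU", "RSP", "dose"))
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin),
                 quantity = quantity),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s  %d x %d x %d voxels @ (%g, %g, %g) mm\n",
              x$quantity, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%g, %g, %g) mm, range [%g, %g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

# Replace the data of a volume, keeping the geometry; validates shape.
vol_like <- function(vol, data, quantity = vol$quantity) {
  stopifnot(identical(dim(data), dim(vol$data)))
  ct_volume(data, vol$spacing, vol$origin, quantity)
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) && all(abs(a$origin - b$origin) < tol)
}

stop_if_geometry_differs <- function(a, b, what = "volumes") {
  if (!same_geometry(a, b)) stop("geometry mismatch between ", what)
  invisible(TRUE)
}

# World coordinates of all voxel centres along each axis.
axis_coords <- function(vol) {
  d <- dim(vol$data)
  lapply(1:3, function(ax) vol$origin[ax] + (seq_len(d[ax]) - 1) * vol$spacing[ax])
}

#' Read a volume from a NIfTI file
#'
#' Round trips written by [write_volume()] preserve voxel data bit-exactly and
#' spacing/origin to better than 1e-6 mm.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param quantity quantity label to attach (`"HU"`, `"RSP"`, `"dose"`).
#' @return A [ct_volume].
#' @export
read_volume <- function(path, quantity = "HU") {
  if (!grepl("\\.nii(\\.gz)?$", path))
    stop("read_volume: unknown format (expected NIfTI .nii/.nii.gz): ", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 3L)
    stop("read_volume: file is not a 3D volume (", length(dim(a)), "D)")
  sp <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  origin <- abs(xf[1:3, 4])  # package convention: axis-aligned, positive axes
  ct_volume(array(as.numeric(a), dim(a)), sp, origin, quantity)
}

#' Write a volume to a NIfTI file
#'
#' @param volume a [ct_volume].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  img <- RNifti::asNifti(volume$data,
                         reference = list(pixdim = c(-1, volume$spacing, 0, 0, 0, 0)),
                         datatype = "double")
  m <- diag(c(volume$spacing, 1))
  m[1:3, 4] <- volume$origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Named set of binary masks sharing one volume geometry
#'
#' Masks are logical arrays congruent with a reference [ct_volume]. Each mask
#' carries a role: `external` (body contour), `CTV`, `PTV`, or `OAR`.
#'
#' @param masks named list of logical 3D arrays of identical dimensions.
#' @param roles named character vector mapping mask names to roles.
#' @param spacing,origin geometry shared with the associated volume.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(masks, roles, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.list(masks), length(masks) >= 1, !is.null(names(masks)))
  d <- dim(masks[[1]])
  for (nm in names(masks)) {
    if (!identical(dim(masks[[nm]]), d))
      stop("roi_set: mask '", nm, "' has a different geometry")
    storage.mode(masks[[nm]]) <- "logical"
  }
  roles <- roles[names(masks)]
  ok <- roles %in% c("external", "CTV", "PTV", "OAR")
  if (any(!ok)) stop("roi_set: invalid role(s): ", paste(roles[!ok], collapse = ", "))
  # nesting: CTV inside PTV inside external, when present
  gm <- function(role) {
    nm <- names(roles)[roles == role]
    if (length(nm)) masks[[nm[1]]] else NULL
  }
  ctv <- gm("CTV"); ptv <- gm("PTV"); ext <- gm("external")
  if (!is.null(ctv) && !is.null(ptv) && any(ctv & !ptv))
    stop("roi_set: CTV must be contained in PTV")
  if (!is.null(ptv) && !is.null(ext) && any(ptv & !ext))
    stop("roi_set: PTV must be contained in the external contour")
  structure(list(masks = masks, roles = roles, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat("<roi_set>\n")
  for (nm in names(x$masks))
    cat(sprintf("  %-10s %-8s %d voxels\n", nm, x$roles[[nm]], sum(x$masks[[nm]])))
  invisible(x)
}

#' Fetch a mask from an ROI set by name or role
#'
#' @param rois a [roi_set].
#' @param name mask name, or a role (`"external"`, `"CTV"`, `"PTV"`) matched
#'   against the roles when no mask of that name exists.
#' @return A logical mask.
#' @export
roi_mask <- function(rois, name) {
  if (name %in% names(rois$masks)) return(rois$masks[[name]])
  nm <- names(rois$roles)[rois$roles == name]
  if (length(nm)) return(rois$masks[[nm[1]]])
  stop("roi '", name, "' not found")
}

#' Write an ROI set as one mask volume per ROI plus a JSON index
#'
#' @param rois a [roi_set].
#' @param dir output directory (created if missing).
#' @return The index file path, invisibly.
#' @export
write_roi_set <- function(rois, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  index <- list()
  for (nm in names(rois$masks)) {
    f <- file.path(dir, paste0(nm, ".nii.gz"))
    v <- ct_volume(array(as.numeric(rois$masks[[nm]]), dim(rois$masks[[nm]])),
                   rois$spacing, rois$origin, "HU")
    write_volume(v, f)
    index[[nm]] <- list(file = basename(f), role = unname(rois$roles[[nm]]))
  }
  idx <- file.path(dir, "rois.json")
  jsonlite::write_json(index, idx, auto_unbox = TRUE, pretty = TRUE)
  invisible(idx)
}

#' Read an ROI set written by [write_roi_set()]
#' @param dir directory containing `rois.json`.
#' @return A [roi_set].
#' @export
read_roi_set <- function(dir) {
  index <- jsonlite::read_json(file.path(dir, "rois.json"))
  masks <- list(); roles <- character()
  sp <- NULL; or <- NULL
  for (nm in names(index)) {
    v <- read_volume(file.path(dir, index[[nm]]$file))
    masks[[nm]] <- v$data > 0.5
    roles[nm] <- index[[nm]]$role
    sp <- v$spacing; or <- v$origin
  }
  roi_set(masks, roles, sp, or)
}
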