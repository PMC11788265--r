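#' Low-pass filter kernel for CT degradation
#'
#' Separable, isotropic (in mm) 3D low-pass kernels of two kinds: `boxcar`
#' (rect filter, `width` = full width in mm) and `gaussian` (`width` = FWHM in
#' mm, truncated at `truncation` standard deviations per side and
#' renormalized). Discrete per-axis weights always sum to 1.
#'
#' The boxcar is discretized as a symmetric, exact-width kernel: each tap
#' receives the fraction of the voxel cell covered by the continuous rect of
#' width `width` centred on the voxel, giving fractional end-weights when
#' `width/spacing` is even (e.g. 4 mm on 1 mm voxels yields
#' `c(.5, 1, 1, 1, .5)/4`). This keeps the width exact in mm and introduces no
#' phase shift.
#'
#' @param kind `"boxcar"` or `"gaussian"`.
#' @param width kernel width in mm (boxcar: full width; gaussian: FWHM); >= 0.
#'   Width 0 is the identity.
#' @param truncation Gaussian cut-off in multiples of sigma per side.
#' @return An object of class `filter_kernel`.
#' @export
filter_kernel <- function(kind = c("boxcar", "gaussian"), width, truncation = 4) {
  kind <- match.arg(kind)
  stopifnot(width >= 0, truncation > 0)
  structure(list(kind = kind, width = width, truncation = truncation),
            class = "filter_kernel")
}

#' @export
print.filter_kernel <- function(x, ...) {
  cat(sprintf("<filter_kernel> %s, width %g mm%s\n", x$kind, x$width,
              if (x$kind == "gaussian") sprintf(" (FWHM), cut-off %g sigma", x$truncation) else ""))
  invisible(x)
}

# Discrete per-axis weights of a kernel for voxel spacing `delta` (mm).
# Always odd length, symmetric, summing to 1.
kernel_weights <- function(kernel, delta) {
  w <- kernel$width
  if (w == 0) return(1)
  if (kernel$kind == "boxcar") {
    m <- ceiling((w / 2 + delta / 2) / delta - 1e-12) - 1L
    j <- seq(-m, m)
    lo <- pmax(j * delta - delta / 2, -w / 2)
    hi <- pmin(j * delta + delta / 2, w / 2)
    wt <- pmax(hi - lo, 0)
  } else {
    sigma <- fwhm_to_sigma(w)
    m <- max(1L, floor(kernel$truncation * sigma / delta))
    j <- seq(-m, m)
    wt <- exp(-(j * delta)^2 / (2 * sigma^2))
  }
  wt / sum(wt)
}

#' Apply a 3D low-pass filter to an HU volume
#'
#' Separable convolution in the image domain with the kernel discretized per
#' axis; out-of-grid values are padded with -1000 HU (air). The external
#' contour is expanded with [expand_external()] by the kernel width, since
#' smoothing smears the body surface into surrounding air.
#'
#' @param ct a [ct_volume] with quantity `"HU"`.
#' @param kernel a [filter_kernel]. Width 0 returns the input unchanged.
#' @param external logical mask of the body contour, congruent with `ct`.
#' @return A list with elements `volume` (filtered [ct_volume]) and
#'   `external` (expanded mask).
#' @export
apply_lowpass <- function(ct, kernel, external) {
  stopifnot(inherits(ct, "ct_volume"), inherits(kernel, "filter_kernel"))
  stopifnot(identical(dim(external), dim(ct$data)))
  if (kernel$width == 0)
    return(list(volume = ct, external = external))
  d <- dim(ct$data)
  out <- ct$data
  for (ax in 1:3) {
    wt <- kernel_weights(kernel, ct$spacing[ax])
    if (length(wt) >= 2 * d[ax])
      stop("apply_lowpass: kernel (", length(wt), " taps) wider than the grid on axis ", ax)
    if (length(wt) > 1) out <- conv_axis(out, wt, ax, pad = -1000)
  }
  list(volume = vol_like(ct, out),
       external = expand_external(external, kernel$width, ct$spacing))
}

#' Additive white Gaussian noise model
#'
#' Zero-mean, spatially uncorrelated Gaussian noise of standard deviation
#' `sigma` HU, reproducible through `seed`.
#'
#' @param sigma noise standard deviation in HU (>= 0).
#' @param seed integer RNG seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma, seed = 1L) {
  stopifnot(sigma >= 0)
  structure(list(sigma = sigma, seed = as.integer(seed)), class = "noise_model")
}

#' Add white Gaussian noise to a CT volume
#'
#' Noise is added after any smoothing filter, so the final noise level is
#' independent of the filter used. It is applied only inside the (expanded)
#' external contour; outside air is left clean, since dose is computed through
#' the external only.
#'
#' @param ct a [ct_volume].
#' @param model a [noise_model]. `sigma = 0` returns the input unchanged.
#' @param external logical mask limiting where noise is inserted; `NULL`
#'   applies noise everywhere.
#' @return The noisy [ct_volume]; deterministic given `model$seed`.
#' @export
add_noise <- function(ct, model, external = NULL) {
  stopifnot(inherits(ct, "ct_volume"), inherits(model, "noise_model"))
  if (model$sigma == 0) return(ct)
  out <- ct$data
  if (is.null(external)) {
    n <- length(out)
    out <- out + with_seed(model$seed, stats::rnorm(n, 0, model$sigma))
  } else {
    stopifnot(identical(dim(external), dim(out)))
    idx <- which(external)
    out[idx] <- out[idx] + with_seed(model$seed, stats::rnorm(length(idx), 0, model$sigma))
  }
  vol_like(ct, out)
}

#' Gaussian equivalent of a boxcar filter width
#'
#' A boxcar of full width `w` has standard deviation `w / sqrt(12)` (the
#' standard deviation of a uniform distribution); the matching Gaussian has
#' that sigma, i.e. FWHM `2 sqrt(2 log 2) w / sqrt(12)`. A 4 mm boxcar maps to
#' a 2.7 mm FWHM Gaussian.
#'
#' @param width_boxcar boxcar full width in mm (>= 0).
#' @return A list with `sigma` and `fwhm`, both in mm.
#' @export
boxcar_gaussian_equivalent <- function(width_boxcar) {
  stopifnot(width_boxcar >= 0)
  sigma <- width_boxcar / sqrt(12)
  list(sigma = sigma, fwhm = sigma_to_fwhm(sigma))
}

#' Degrade a CT: low-pass filter then additive noise
#'
#' Convenience wrapper combining [apply_lowpass()] and [add_noise()] in the
#' study's fixed order (noise after smoothing).
#'
#' @inheritParams apply_lowpass
#' @param noise a [noise_model] or `NULL`.
#' @return A list with `volume` and `external` as in [apply_lowpass()].
#' @export
degrade_ct <- function(ct, kernel, external, noise = NULL) {
  res <- apply_lowpass(ct, kernel, external)
  if (!is.null(noise) && noise$sigma > 0)
    res$volume <- add_noise(res$volume, noise, res$external)
  res
}
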