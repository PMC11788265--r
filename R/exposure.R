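# Algebraic noise-resolution-exposure model for tomographic scanning:
# Var c(x) is proportional to 1 / (E * slice_width * PSF_width^4), so
# accepting a broader PSF, more noise, or thicker slices lowers the required
# x-ray exposure E multiplicatively. The model is a scanner-level scaling
# law; it is deliberately not verified by image-domain smoothing, whose
# noise statistics differ from projection-domain tomographic noise.

#' PSF broadening factor under low-pass filtering
#'
#' Ratio of the broadened to the original PSF FWHM when a Gaussian PSF is
#' convolved with a low-pass kernel. The default `"quadrature"` method adds
#' the kernel's Gaussian-equivalent FWHM in quadrature (boxcars are converted
#' via [boxcar_gaussian_equivalent()]); `"moment"` convolves sampled 1D
#' profiles numerically and compares second-moment widths. The two agree
#' exactly for Gaussian PSFs, since variances add under convolution. (The
#' half-maximum width of a boxcar-convolved profile is not used: for kernels
#' much wider than the PSF it tends to the boxcar width itself rather than to
#' the quadrature value.)
#'
#' @param psf_fwhm scanner PSF FWHM, mm (> 0).
#' @param kernel a [filter_kernel].
#' @param method `"quadrature"` or `"moment"`.
#' @return Dimensionless broadening factor >= 1.
#' @export
broadening_factor <- function(psf_fwhm, kernel,
                              method = c("quadrature", "moment")) {
  stopifnot(psf_fwhm > 0, inherits(kernel, "filter_kernel"))
  method <- match.arg(method)
  fwhm_eq <- if (kernel$kind == "boxcar")
    boxcar_gaussian_equivalent(kernel$width)$fwhm else kernel$width
  if (method == "quadrature")
    return(sqrt(psf_fwhm^2 + fwhm_eq^2) / psf_fwhm)
  # numerical convolution of sampled profiles, second-moment widths
  sig_psf <- fwhm_to_sigma(psf_fwhm)
  sig_ker <- fwhm_to_sigma(fwhm_eq)
  step <- min(sig_psf, max(sig_ker, 1e-3)) / 40
  x <- seq(-8 * sqrt(sig_psf^2 + sig_ker^2), 8 * sqrt(sig_psf^2 + sig_ker^2),
           by = step)
  psf <- exp(-x^2 / (2 * sig_psf^2))
  ker <- exp(-x^2 / (2 * sig_ker^2))
  conv <- stats::convolve(psf, rev(ker), type = "open")
  xc <- seq(2 * x[1], 2 * x[length(x)], length.out = length(conv))
  profile_sigma(xc, conv) / profile_sigma(x, psf)
}

#' X-ray exposure sparing factor
#'
#' With the image variance held fixed, exposure scales as `1 / xi^4` in the
#' PSF width, as `1 / Var` in the tolerated noise variance and as `1 / slice`
#' in the slice width, so the admissible exposure reduction is
#' `b^4 * f^2 * d` for a PSF broadening `b`, a tolerated noise-std increase
#' `f` and a slice-width increase `d`. The factors combine multiplicatively.
#'
#' @param broadening PSF broadening factor b (>= 1).
#' @param noise_factor tolerated noise standard-deviation increase f (>= 1).
#' @param slice_factor slice-width increase d (>= 1).
#' @return Exposure sparing factor (>= 1).
#' @export
exposure_sparing <- function(broadening, noise_factor = 1, slice_factor = 1) {
  stopifnot(broadening >= 1, noise_factor >= 1, slice_factor >= 1)
  broadening^4 * noise_factor^2 * slice_factor
}

#' Quadrature combination of noise levels
#'
#' Standard deviation of the sum of the independent baseline and added noise
#' components: `sqrt(base^2 + added^2)`.
#'
#' @param base_sigma,added_sigma noise standard deviations in HU (>= 0).
#' @return Combined standard deviation in HU.
#' @export
noise_quadrature <- function(base_sigma, added_sigma) {
  stopifnot(base_sigma >= 0, added_sigma >= 0)
  sqrt(base_sigma^2 + added_sigma^2)
}
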