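#' HU to relative stopping power calibration curve
#'
#' A piecewise-linear calibration mapping CT numbers (HU) to proton relative
#' stopping power (RSP, water = 1). Anchors must be monotonically
#' non-decreasing in RSP and are expected to cover the clinical HU range
#' \[-1024, 3000\]; values outside the anchor range are clamped to the end
#' anchors.
#'
#' @param hu numeric vector of anchor HU values (strictly increasing).
#' @param rsp numeric vector of anchor RSP values (non-decreasing, >= 0).
#' @return An object of class `calibration_curve`.
#' @export
calibration_curve <- function(hu, rsp) {
  stopifnot(length(hu) == length(rsp), length(hu) >= 2)
  o <- order(hu)
  hu <- hu[o]; rsp <- rsp[o]
  if (any(diff(hu) <= 0)) stop("calibration_curve: duplicate HU anchors")
  if (any(diff(rsp) < 0))
    stop("calibration_curve: RSP anchors must be monotonically non-decreasing")
  if (any(rsp < 0)) stop("calibration_curve: RSP must be non-negative")
  structure(list(hu = hu, rsp = rsp), class = "calibration_curve")
}

#' Default HU-to-RSP calibration
#'
#' A generic clinically shaped curve with anchors at air (-1000 HU, 0.001),
#' lung (-750, 0.25), water (0, 1.000), soft tissue (60, 1.04) and bone
#' (700, 1.30; 1400, 1.60; 3000, 2.4). It is a stand-in for an institutional
#' stoichiometric calibration, not a reproduction of any scanner's curve.
#'
#' @return A [calibration_curve].
#' @export
default_calibration <- function() {
  calibration_curve(
    hu  = c(-1024, -1000, -750, 0, 60, 700, 1400, 3000),
    rsp = c(0.001, 0.001, 0.25, 1.000, 1.04, 1.30, 1.60, 2.4))
}

#' Convert an HU volume to relative stopping power
#'
#' Piecewise-linear interpolation between the calibration anchors; HU outside
#' the anchor range are clamped to the end anchors. The result is everywhere
#' non-negative and monotone in HU.
#'
#' @param ct a [ct_volume] with quantity `"HU"`.
#' @param curve a [calibration_curve]; default [default_calibration()].
#' @return A [ct_volume] with quantity `"RSP"`.
#' @export
hu_to_rsp <- function(ct, curve = default_calibration()) {
  stopifnot(inherits(ct, "ct_volume"), inherits(curve, "calibration_curve"))
  if (ct$quantity != "HU") stop("hu_to_rsp: input quantity must be HU")
  v <- stats::approx(curve$hu, curve$rsp, xout = as.vector(ct$data),
                     rule = 2, ties = "ordered")$y
  vol_like(ct, array(v, dim(ct$data)), "RSP")
}
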