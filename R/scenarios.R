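# Setup-shift and density perturbation scenarios (Dutch robust evaluation
# scheme): six rigid shifts of the patient along the cardinal axes combined
# with two mass-density scalings, plus the nominal scenario.

#' Perturbation scenario
#'
#' @param shift length-3 rigid patient shift in mm (axis-aligned).
#' @param density_scale multiplicative RSP scaling (1 = nominal).
#' @return A `dose_scenario` object.
#' @export
dose_scenario <- function(shift = c(0, 0, 0), density_scale = 1) {
  if (sum(shift != 0) > 1)
    stop("dose_scenario: shift must be along a single cardinal axis")
  structure(list(shift = as.numeric(shift), density_scale = density_scale),
            class = "dose_scenario")
}

#' Build the scenario set for robust optimization and evaluation
#'
#' Six cardinal shifts of magnitude `u` crossed with density scales
#' `1 - delta` and `1 + delta` (12 perturbed scenarios), plus the nominal:
#' 13 in total. With `u = 0` and `delta = 0` only the nominal remains. The
#' pairing of every shift with every density scale (6 x 2 rather than 6 + 2)
#' is one admissible reading of the protocol; it is the more conservative
#' one.
#'
#' @param u setup uncertainty, mm (>= 0).
#' @param delta density uncertainty, fraction (>= 0).
#' @return A list of [dose_scenario]s, nominal first.
#' @export
make_scenarios <- function(u, delta) {
  stopifnot(u >= 0, delta >= 0)
  out <- list(dose_scenario(c(0, 0, 0), 1))
  shifts <- list()
  if (u > 0)
    for (ax in 1:3) for (s in c(-1, 1)) {
      v <- c(0, 0, 0); v[ax] <- s * u
      shifts <- c(shifts, list(v))
    }
  scales <- if (delta > 0) c(1 - delta, 1 + delta) else 1
  if (length(shifts) == 0 && delta > 0)
    for (ds in scales) out <- c(out, list(dose_scenario(c(0, 0, 0), ds)))
  else
    for (sh in shifts) for (ds in scales)
      out <- c(out, list(dose_scenario(sh, ds)))
  out
}

#' Rigidly shift a volume
#'
#' Resamples the volume so its content moves by `shift` mm (the patient
#' displacement); sampling is trilinear, vacated regions are filled with
#' `fill`. Integer-voxel shifts reduce to an exact array roll.
#'
#' @param vol a [ct_volume].
#' @param shift length-3 shift in mm.
#' @param fill value for vacated regions (default -1000, air).
#' @return The shifted [ct_volume].
#' @export
shift_volume <- function(vol, shift, fill = -1000) {
  out <- vol$data
  for (ax in 1:3) {
    if (shift[ax] == 0) next
    t <- shift[ax] / vol$spacing[ax]
    k <- floor(t); f <- t - k
    if (f == 0) out <- shift_int(out, k, ax, fill)
    else out <- (1 - f) * shift_int(out, k, ax, fill) +
        f * shift_int(out, k + 1L, ax, fill)
  }
  vol_like(vol, out)
}

#' Apply a scenario to a CT volume
#'
#' Applies the rigid patient shift by trilinear resampling. The density scale
#' is not applied here: it multiplies the RSP map downstream (see
#' [scenario_rsp()]).
#'
#' @param ct a [ct_volume].
#' @param scenario a [dose_scenario].
#' @return The shifted [ct_volume].
#' @export
apply_scenario <- function(ct, scenario) {
  stopifnot(inherits(scenario, "dose_scenario"))
  shift_volume(ct, scenario$shift)
}

#' Scenario RSP map: shifted CT converted to RSP and density-scaled
#'
#' @param ct nominal [ct_volume] (HU).
#' @param scenario a [dose_scenario].
#' @param curve a [calibration_curve].
#' @return A [ct_volume] with quantity `"RSP"`.
#' @export
scenario_rsp <- function(ct, scenario, curve = default_calibration()) {
  r <- hu_to_rsp(apply_scenario(ct, scenario), curve)
  if (scenario$density_scale != 1)
    r <- vol_like(r, r$data * scenario$density_scale, "RSP")
  r
}

# Shift a binary mask with the patient (nearest-neighbour via >= 0.5).
shift_mask <- function(mask, shift, spacing) {
  v <- ct_volume(array(as.numeric(mask), dim(mask)), spacing, quantity = "HU")
  shift_volume(v, shift, fill = 0)$data >= 0.5
}
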