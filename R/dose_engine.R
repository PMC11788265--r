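# Deterministic analytic proton pencil-beam dose engine: WET ray tracing,
# an analytic Bragg depth-dose curve, lateral Gaussian spot spread with
# depth broadening, range-shifter bookkeeping and SOBP construction.
# Doses are physical-dose surrogates (arbitrary Gy); no Monte-Carlo noise.

# Range spread (mm): quadratic sum of beamline energy spread and straggling,
# together 2.5% of range (plans traverse 5-7 cm WET range shifters, which
# broaden the peak substantially); floored at 0.5 mm for very short ranges.
sigma_range <- function(R) pmax(0.025 * R, 0.5)

#' Analytic Bragg depth-dose curve
#'
#' Relative dose at water-equivalent depth `wet` for a beam of nominal range
#' `R` (mm water): a slowly rising entrance plateau multiplied by a distal
#' sigmoid, plus a Gaussian peak of width `sigma_range(R) = max(0.025 R, 0.5)`
#' mm. The curve is calibrated so its maximum lies at `wet = R`, is zero
#' beyond `R + 3 sigma`, and has a peak-to-entrance ratio well above 3.
#'
#' @param R nominal range in mm water (> 0).
#' @param wet water-equivalent depth(s) in mm.
#' @return Relative dose, same length as `wet`.
#' @export
depth_dose <- function(R, wet) {
  stopifnot(R > 0)
  s <- sigma_range(R)
  Rc <- R + 0.15 * s  # recentre: combined argmax sits at R
  d <- (0.30 + 0.45 * (wet / R)^2) * stats::pnorm((Rc - wet) / s) +
    2.2 * exp(-(wet - Rc)^2 / (2 * s^2))
  d[wet > R + 3 * s] <- 0
  d
}

#' Trace cumulative water-equivalent thickness along a ray
#'
#' Integrates the RSP map along `entry + t * direction` by sampling with
#' trilinear interpolation and trapezoidal accumulation. In uniform water
#' (RSP = 1) the result is `WET(t) = t` exactly; the profile is monotone
#' non-decreasing for non-negative RSP.
#'
#' @param rsp a [ct_volume] with quantity `"RSP"`.
#' @param entry ray entry point, mm world coordinates (must lie in the grid).
#' @param direction direction vector (normalized internally).
#' @param depth_samples depths `t` (mm) at which the cumulative WET is
#'   returned; alternatively a single number = maximum depth. The integration
#'   itself always runs on an internal grid of a quarter of the smallest
#'   voxel spacing, independent of the requested output depths.
#' @param step internal integration step, mm.
#' @return A data.frame with columns `t` (mm) and `wet` (mm).
#' @export
trace_wet <- function(rsp, entry, direction, depth_samples,
                      step = min(rsp$spacing) / 4) {
  stopifnot(inherits(rsp, "ct_volume"))
  d <- dim(rsp$data)
  lo <- rsp$origin; hi <- rsp$origin + (d - 1) * rsp$spacing
  if (any(entry < lo - 1e-9) || any(entry > hi + 1e-9))
    stop("trace_wet: entry point outside the grid")
  u <- direction / sqrt(sum(direction^2))
  if (length(depth_samples) == 1)
    depth_samples <- seq(0, depth_samples, by = step)
  tmax <- max(depth_samples)
  ts <- sort(unique(c(seq(0, tmax, by = step), depth_samples)))
  pts <- cbind(entry[1] + ts * u[1], entry[2] + ts * u[2], entry[3] + ts * u[3])
  vals <- interp3(rsp$data, rsp$spacing, rsp$origin, pts, fill = 0.001)
  dt <- diff(ts)
  wet <- c(0, cumsum(dt * (vals[-1] + vals[-length(vals)]) / 2))
  data.frame(t = depth_samples,
             wet = stats::approx(ts, wet, xout = depth_samples)$y)
}

#' Proton beam definition
#'
#' A scanned proton field along one cardinal axis: energy layers given as
#' nominal ranges in mm water, a rectangular lateral spot grid, and a weight
#' matrix over (layer, spot). The lateral spot width grows linearly with
#' water-equivalent depth from `sigma_air` at the surface to twice that value
#' at the deepest layer.
#'
#' @param direction unit vector along a cardinal axis, e.g. `c(1, 0, 0)`.
#' @param isocenter mm world coordinates.
#' @param layers numeric vector of nominal ranges R (mm water); each must
#'   exceed the range-shifter WET.
#' @param spot_u,spot_v lateral spot offsets (mm) from the isocenter along the
#'   two non-beam axes (lower axis index first).
#' @param weights matrix `length(layers) x (length(spot_u) * length(spot_v))`
#'   of non-negative spot weights (spot index runs over u fastest).
#' @param sigma_air lateral spot sigma at the surface, mm. The default 5 mm
#'   sigma (about 12 mm FWHM) matches the ~10 mm in-air width scale of
#'   clinical pencil beams.
#' @param range_shifter_wet range shifter water-equivalent thickness, cm.
#' @return A `proton_beam` object.
#' @export
proton_beam <- function(direction, isocenter, layers, spot_u = 0, spot_v = 0,
                        weights = NULL, sigma_air = 5, range_shifter_wet = 0) {
  ax <- which(abs(direction) > 1e-9)
  if (length(ax) != 1)
    stop("proton_beam: direction must be along a cardinal axis")
  if (any(layers <= 10 * range_shifter_wet))
    stop("proton_beam: nominal range must exceed the range-shifter WET (",
         10 * range_shifter_wet, " mm)")
  ns <- length(spot_u) * length(spot_v)
  if (is.null(weights)) weights <- matrix(1, length(layers), ns)
  weights <- as.matrix(weights)
  stopifnot(nrow(weights) == length(layers), ncol(weights) == ns,
            all(weights >= 0))
  structure(list(axis = ax, sign = sign(direction[ax]),
                 direction = direction / sqrt(sum(direction^2)),
                 isocenter = as.numeric(isocenter), layers = as.numeric(layers),
                 spot_u = as.numeric(spot_u), spot_v = as.numeric(spot_v),
                 weights = weights, sigma_air = sigma_air,
                 range_shifter_wet = range_shifter_wet),
            class = "proton_beam")
}

#' Proton treatment plan
#'
#' @param beams list of [proton_beam]s (>= 1).
#' @param prescription prescribed dose, Gy.
#' @param setup_uncertainty setup uncertainty u, mm (>= 0).
#' @param density_uncertainty density uncertainty delta, fraction in \[0, 0.2).
#' @return A `proton_plan` object.
#' @export
proton_plan <- function(beams, prescription, setup_uncertainty = 3,
                        density_uncertainty = 0.035) {
  stopifnot(length(beams) >= 1, prescription > 0, setup_uncertainty >= 0,
            density_uncertainty >= 0, density_uncertainty < 0.2)
  if (inherits(beams, "proton_beam")) beams <- list(beams)
  structure(list(beams = beams, prescription = prescription,
                 setup_uncertainty = setup_uncertainty,
                 density_uncertainty = density_uncertainty),
            class = "proton_plan")
}

# WET (mm) at every voxel centre for a beam along `axis` with `sign`,
# computed by cumulative summation of RSP * spacing from the entry face,
# with a half-voxel correction so the value refers to the voxel centre.
wet_volume <- function(rsp, axis, sgn) {
  d <- dim(rsp$data)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(rsp$data, perm)
  n1 <- d[axis]
  M <- matrix(ap, nrow = n1)
  if (sgn < 0) M <- M[n1:1, , drop = FALSE]
  dx <- rsp$spacing[axis]
  W <- apply(M, 2, cumsum) * dx - M * (dx / 2)
  if (sgn < 0) W <- W[n1:1, , drop = FALSE]
  aperm(array(W, d[perm]), order(perm))
}

# Dose of one beam on the nominal grid; `external` may be NULL.
beam_dose <- function(beam, rsp, external) {
  d <- dim(rsp$data)
  ax <- beam$axis
  lat <- setdiff(1:3, ax)
  wet <- wet_volume(rsp, ax, beam$sign)
  R_eff <- beam$layers - 10 * beam$range_shifter_wet
  Rmax <- max(R_eff)
  coords <- axis_coords(rsp)
  ucoord <- coords[[lat[1]]] - beam$isocenter[lat[1]]
  vcoord <- coords[[lat[2]]] - beam$isocenter[lat[2]]
  nu <- length(beam$spot_u); nv <- length(beam$spot_v)
  perm <- c(ax, lat)
  wet_ap <- aperm(wet, perm)
  ext_ap <- if (is.null(external)) NULL else aperm(external, perm)
  dose_ap <- array(0, dim(wet_ap))
  n1 <- d[ax]
  for (i in seq_len(n1)) {
    wslice <- wet_ap[i, , ]
    if (!is.null(ext_ap)) {
      esl <- ext_ap[i, , ]
      wbar <- if (any(esl)) mean(wslice[esl]) else 0
    } else wbar <- mean(wslice)
    sig <- beam$sigma_air * (1 + min(wbar / Rmax, 1))
    amp <- (beam$sigma_air / sig)^2
    Gu <- exp(-outer(ucoord, beam$spot_u, `-`)^2 / (2 * sig^2))
    Gv <- exp(-outer(vcoord, beam$spot_v, `-`)^2 / (2 * sig^2))
    acc <- matrix(0, d[lat[1]], d[lat[2]])
    for (l in seq_along(R_eff)) {
      Wl <- matrix(beam$weights[l, ], nu, nv)
      if (all(Wl == 0)) next
      B <- depth_dose(R_eff[l], wslice)
      acc <- acc + B * (Gu %*% Wl %*% t(Gv))
    }
    dose_ap[i, , ] <- amp * acc
  }
  aperm(dose_ap, order(perm))
}

#' Compute the dose distribution of a plan on a CT
#'
#' Deterministic pencil-beam superposition: for each beam the cumulative WET
#' is traced along the (cardinal) beam axis, each spot deposits
#' `weight * depth_dose(R_eff, WET) * Gaussian(lateral distance; sigma(depth))`
#' with `R_eff = R - 10 * range_shifter_wet`, and the lateral sigma grows
#' linearly from `sigma_air` at the surface to `2 sigma_air` at the deepest
#' layer. Dose is zeroed outside the external contour when one is supplied.
#'
#' @param plan a [proton_plan] (or [minimax_plan]).
#' @param ct a [ct_volume] with quantity `"HU"`.
#' @param curve a [calibration_curve].
#' @param rois optional [roi_set] providing the external contour.
#' @param rsp optional precomputed RSP [ct_volume] (overrides `ct`/`curve`;
#'   used by scenario evaluation to apply density scaling).
#' @return A [ct_volume] with quantity `"dose"`.
#' @export
compute_dose <- function(plan, ct, curve = default_calibration(), rois = NULL,
                         rsp = NULL) {
  if (inherits(plan, "minimax_plan")) plan <- plan$plan
  stopifnot(inherits(plan, "proton_plan"))
  if (is.null(rsp)) rsp <- hu_to_rsp(ct, curve)
  external <- if (!is.null(rois)) roi_mask(rois, "external") else NULL
  total <- array(0, dim(rsp$data))
  for (beam in plan$beams) {
    if (!is.null(external)) {
      # central-axis ray must intersect the external contour
      lat <- setdiff(1:3, beam$axis)
      ic_idx <- round((beam$isocenter[lat] - rsp$origin[lat]) / rsp$spacing[lat]) + 1
      ic_idx <- pmax(1, pmin(dim(rsp$data)[lat], ic_idx))
      idx <- lapply(dim(rsp$data), seq_len)
      idx[[lat[1]]] <- ic_idx[1]; idx[[lat[2]]] <- ic_idx[2]
      ray <- external[idx[[1]], idx[[2]], idx[[3]]]
      if (!any(ray)) {
        warning("compute_dose: beam central axis misses the external contour; zero dose")
        next
      }
    }
    total <- total + beam_dose(beam, rsp, external)
  }
  if (!is.null(external)) total[!external] <- 0
  vol_like(rsp, total, "dose")
}

#' Build spread-out Bragg peak layer weights
#'
#' Solves non-negative least squares on the engine's own depth-dose matrix so
#' the summed curve is flat over `range_span` in uniform water. Layers are
#' equally spaced with the distal layer placed `0.6 sigma_range` beyond the
#' span end (half-maximum, not peak, at the plateau edge). Weights are
#' normalized to a mean plateau of 1.
#'
#' @param range_span numeric length-2, proximal and distal plateau edge
#'   (mm water), proximal < distal.
#' @param n_layers number of energy layers (>= 1).
#' @param flatness_target maximum acceptable plateau max/min ratio reported
#'   through the `meets_target` flag (the achieved flatness is always
#'   returned).
#' @return A list with `ranges` (mm), `weights` (non-negative, length
#'   `n_layers`), `flatness` (plateau max/min) and `meets_target`.
#' @export
build_sobp <- function(range_span, n_layers, flatness_target = 1.04) {
  stopifnot(length(range_span) == 2, diff(range_span) >= 0, n_layers >= 1)
  if (n_layers == 1 || diff(range_span) == 0) {
    return(list(ranges = max(range_span), weights = 1, flatness = 1,
                meets_target = TRUE))
  }
  hi <- range_span[2] + 0.6 * sigma_range(range_span[2])
  ranges <- seq(range_span[1], hi, length.out = n_layers)
  z <- seq(range_span[1], range_span[2], by = 0.25)
  M <- sapply(ranges, function(R) depth_dose(R, z))
  w <- pracma::lsqnonneg(M, rep(1, length(z)))$x
  plateau <- as.vector(M %*% w)
  sc <- 1 / mean(plateau)
  flat <- max(plateau) / min(plateau)
  list(ranges = ranges, weights = w * sc, flatness = flat,
       meets_target = flat <= flatness_target)
}
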