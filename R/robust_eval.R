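# Scenario-based robustness evaluation of a fixed plan: per-scenario doses,
# worst-case and voxel-wise-minimum target coverage, the D-at-50%-of-
# scenarios statistic, and OAR dose deltas.

#' Compute scenario dose distributions for a fixed plan
#'
#' For each scenario the CT is rigidly shifted and density-scaled, dose is
#' recomputed with the unchanged plan, and the resulting grid is mapped back
#' to the patient frame (so ROI masks apply unchanged). No re-optimization
#' takes place.
#'
#' @param plan a [proton_plan] or [minimax_plan].
#' @param ct nominal [ct_volume] (HU).
#' @param scenarios list of [dose_scenario]s, nominal first.
#' @param curve a [calibration_curve].
#' @param rois a [roi_set] (external used for masking).
#' @return List of dose [ct_volume]s in the patient frame, one per scenario.
#' @export
scenario_doses <- function(plan, ct, scenarios, curve = default_calibration(),
                           rois = NULL) {
  if (inherits(plan, "minimax_plan")) plan <- plan$plan
  lapply(scenarios, function(sc) {
    rsp_s <- scenario_rsp(ct, sc, curve)
    rois_s <- rois
    if (!is.null(rois) && any(sc$shift != 0)) {
      ext <- shift_mask(roi_mask(rois, "external"), sc$shift, ct$spacing)
      rois_s <- roi_set(list(external = ext), c(external = "external"),
                        ct$spacing, ct$origin)
    }
    dg <- compute_dose(plan, ct, curve, rois_s, rsp = rsp_s)
    if (any(sc$shift != 0)) dg <- shift_volume(dg, -sc$shift, fill = 0)
    dg
  })
}

#' Voxel-wise minimum over scenario doses
#'
#' @param doses list of congruent dose [ct_volume]s (>= 1).
#' @return A dose [ct_volume], the elementwise minimum.
#' @export
voxelwise_min <- function(doses) {
  stopifnot(length(doses) >= 1)
  for (dg in doses[-1]) stop_if_geometry_differs(doses[[1]], dg, "scenario doses")
  out <- Reduce(pmin, lapply(doses, function(d) d$data))
  vol_like(doses[[1]], out, "dose")
}

#' Volume receiving at least a dose level
#'
#' `V_D` = percentage of mask voxels with dose >= D. `v_d(dose, mask, 0)` is
#' 100% by definition.
#'
#' @param dose a dose [ct_volume].
#' @param mask logical array congruent with `dose`.
#' @param D dose level, Gy.
#' @return Percentage in \[0, 100\].
#' @export
v_d <- function(dose, mask, D) {
  x <- if (inherits(dose, "ct_volume")) dose$data else dose
  stopifnot(any(mask))
  100 * sum(x[mask] >= D) / sum(mask)
}

#' D-at-50%-of-scenarios coverage statistic
#'
#' The largest dose D for which at least half of the perturbed scenarios
#' fulfil `V_D[CTV] > coverage`%, located by bisection (the passing-scenario
#' count is non-increasing in D). A more sensitive probe of coverage
#' degradation than worst-case V95.
#'
#' @param doses list of perturbed-scenario dose [ct_volume]s (>= 2; exclude
#'   the nominal).
#' @param ctv logical CTV mask.
#' @param coverage required `V_D` in percent (default 98).
#' @param tol bisection tolerance in Gy (use 0.1% of the prescription).
#' @return D in Gy.
#' @export
d50_statistic <- function(doses, ctv, coverage = 98, tol = 0.05) {
  stopifnot(length(doses) >= 2, any(ctv))
  vals <- lapply(doses, function(dg) dg$data[ctv])
  dmax <- max(vapply(vals, max, 0))
  if (dmax <= 0) stop("d50_statistic: all scenario doses are zero")
  need <- ceiling(length(doses) / 2)
  count_at <- function(D)
    sum(vapply(vals, function(v) 100 * mean(v >= D) > coverage, NA))
  lo <- 0; hi <- dmax + tol
  if (count_at(hi) >= need) return(hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (count_at(mid) >= need) lo <- mid else hi <- mid
  }
  lo
}

#' Full robustness evaluation of a plan on a CT
#'
#' Computes scenario doses, per-scenario V95\[CTV\], worst-case and
#' voxel-wise-minimum coverage, the D-at-50%-scenarios statistic, and OAR
#' metrics (mean dose and near-maximum D2%) per scenario.
#'
#' @param plan a [proton_plan] or [minimax_plan].
#' @param ct a [ct_volume] (HU).
#' @param rois a [roi_set] with `external` and `CTV` (OAR-role masks are
#'   scored as OARs).
#' @param scenarios list of [dose_scenario]s (nominal first); `NULL` derives
#'   them from the plan's uncertainties.
#' @param curve a [calibration_curve].
#' @param prescription prescription override (defaults to the plan's).
#' @return A `robustness_report`.
#' @export
robust_evaluate <- function(plan, ct, rois, scenarios = NULL,
                            curve = default_calibration(), prescription = NULL) {
  pp <- if (inherits(plan, "minimax_plan")) plan$plan else plan
  if (is.null(prescription)) prescription <- pp$prescription
  if (is.null(scenarios))
    scenarios <- make_scenarios(pp$setup_uncertainty, pp$density_uncertainty)
  ctv <- roi_mask(rois, "CTV")
  doses <- scenario_doses(pp, ct, scenarios, curve, rois)
  v95 <- vapply(doses, function(dg) v_d(dg, ctv, 0.95 * prescription), 0)
  vmin <- voxelwise_min(doses)
  perturbed <- doses[-1]
  d50 <- if (length(perturbed) >= 2)
    d50_statistic(perturbed, ctv, coverage = 98, tol = 0.001 * prescription)
  else NA_real_
  oar_names <- names(rois$roles)[rois$roles == "OAR"]
  oar <- list()
  for (nm in oar_names) {
    m <- roi_mask(rois, nm)
    oar[[nm]] <- data.frame(
      scenario = seq_along(doses),
      mean = vapply(doses, function(dg) mean(dg$data[m]), 0),
      d2 = vapply(doses, function(dg)
        stats::quantile(dg$data[m], 0.98, names = FALSE), 0))
  }
  structure(list(prescription = prescription, scenarios = scenarios,
                 v95 = v95, worst_v95 = min(v95),
                 voxelwise_min = vmin,
                 voxelwise_min_v95 = v_d(vmin, ctv, 0.95 * prescription),
                 d50 = d50, oar = oar, doses = doses),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf("<robustness_report> %d scenarios, prescription %g Gy\n",
              length(x$scenarios), x$prescription))
  cat(sprintf("  worst-case V95[CTV]      %.2f%%\n", x$worst_v95))
  cat(sprintf("  voxel-wise-min V95[CTV]  %.2f%%\n", x$voxelwise_min_v95))
  cat(sprintf("  D(50%% scenarios, V>98%%) %.2f Gy\n", x$d50))
  for (nm in names(x$oar))
    cat(sprintf("  OAR %-12s mean %.2f Gy, D2%% %.2f Gy (nominal)\n", nm,
                x$oar[[nm]]$mean[1], x$oar[[nm]]$d2[1]))
  invisible(x)
}

#' Maximum OAR metric deviation between two robustness reports
#'
#' The largest percentage deviation (relative to the prescription) of an
#' OAR's scenario dose metrics between two evaluations of the same plan,
#' typically on the clinical and on a degraded CT. Symmetric in its inputs.
#'
#' @param report_clinical,report_degraded `robustness_report`s with matching
#'   scenario sets.
#' @param oar OAR mask name.
#' @param metrics metrics to compare (columns `mean`, `d2`).
#' @return Maximum deviation in percent of the prescription.
#' @export
oar_delta <- function(report_clinical, report_degraded, oar,
                      metrics = c("mean", "d2")) {
  a <- report_clinical$oar[[oar]]; b <- report_degraded$oar[[oar]]
  if (is.null(a) || is.null(b)) stop("oar_delta: OAR '", oar, "' missing")
  if (nrow(a) != nrow(b)) stop("oar_delta: scenario sets differ")
  p <- report_clinical$prescription
  max(vapply(metrics, function(mm) max(abs(b[[mm]] - a[[mm]])) / p * 100, 0))
}
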