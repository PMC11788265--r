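# Minimax robust optimization of spot/layer weights: per iteration the worst
# scenario (largest quadratic CTV deviation from prescription) is selected
# and a projected gradient step with exact line search is taken on the
# non-negative spot weights.

# Factored influence of one beam at a set of sample points (patient frame):
# dose(i) = rowSums(L * (B %*% W)) for weight matrix W [layers x spots].
# B[i, l] = depth_dose(R_eff_l, wet_i), L[i, s] = lateral Gaussian at spot s.
beam_influence <- function(beam, rsp, pts) {
  wet_vol <- wet_volume(rsp, beam$axis, beam$sign)
  wet <- interp3(wet_vol, rsp$spacing, rsp$origin, pts, fill = 0)
  R_eff <- beam$layers - 10 * beam$range_shifter_wet
  Rmax <- max(R_eff)
  B <- sapply(R_eff, function(R) depth_dose(R, wet))
  if (is.null(dim(B))) B <- matrix(B, nrow = length(wet))
  lat <- setdiff(1:3, beam$axis)
  du <- pts[, lat[1]] - beam$isocenter[lat[1]]
  dv <- pts[, lat[2]] - beam$isocenter[lat[2]]
  sig <- beam$sigma_air * (1 + pmin(wet / Rmax, 1))
  amp <- (beam$sigma_air / sig)^2
  nu <- length(beam$spot_u); nv <- length(beam$spot_v)
  Gu <- exp(-(outer(du, beam$spot_u, `-`) / (sqrt(2) * sig))^2)
  Gv <- exp(-(outer(dv, beam$spot_v, `-`) / (sqrt(2) * sig))^2)
  L <- matrix(0, nrow(pts), nu * nv)
  for (iv in seq_len(nv))
    L[, (iv - 1) * nu + seq_len(nu)] <- Gu * Gv[, iv]
  list(B = B, L = amp * L)
}

factored_dose <- function(infl, W) rowSums(infl$L * (infl$B %*% W))

#' Minimax robust optimization of a proton plan
#'
#' Optimizes spot weights so that, in the worst of the setup-shift/density
#' scenarios, the CTV dose is as close to the prescription as possible
#' (quadratic deviation). Beam geometry (directions, range shifter, lateral
#' spot sigma) is fixed; energy layers and the lateral spot grid are derived
#' from the CTV extent, with layer weights initialized from [build_sobp()].
#' Weights stay non-negative throughout (projection). After optimization the
#' plan is renormalized so that the worst-scenario V95 of the CTV, computed
#' with the full dose engine, meets the 98% coverage requirement whenever the
#' renormalization stays within +/- 15%.
#'
#' @param ct planning [ct_volume] (HU).
#' @param rois a [roi_set] with at least `external` and `CTV`.
#' @param scenarios list of [dose_scenario]s (nominal first); `NULL` builds
#'   [make_scenarios]`(setup_uncertainty, density_uncertainty)`.
#' @param prescription prescribed CTV dose, Gy.
#' @param setup_uncertainty,density_uncertainty robustness parameters fed to
#'   the scenario generator (mm / fraction).
#' @param beam_directions list of cardinal unit vectors, one per field.
#' @param curve a [calibration_curve].
#' @param sigma_air lateral spot sigma in air, mm (spot spacing equals it).
#' @param range_shifter_wet range shifter WET, cm.
#' @param layer_spacing energy layer spacing, mm water.
#' @param max_iter maximum optimizer iterations.
#' @return A `minimax_plan` object: the optimized [proton_plan] plus
#'   per-scenario V95 report and convergence trace. Methods: `print`,
#'   `summary`, `coef`, `predict` (dose on a CT), `residuals` (nominal CTV
#'   dose minus prescription), `simulate` (scenario doses), `plot`.
#' @export
optimize_minimax <- function(ct, rois, scenarios = NULL, prescription,
                             setup_uncertainty = 3, density_uncertainty = 0.035,
                             beam_directions = list(c(1, 0, 0), c(0, 1, 0)),
                             curve = default_calibration(), sigma_air = 5,
                             range_shifter_wet = 7.4, layer_spacing = 4,
                             max_iter = 60) {
  stopifnot(inherits(ct, "ct_volume"), prescription > 0)
  if (is.null(scenarios))
    scenarios <- make_scenarios(setup_uncertainty, density_uncertainty)
  ctv <- roi_mask(rois, "CTV")
  if (!any(ctv)) stop("optimize_minimax: empty CTV")
  if (length(beam_directions) < 1) stop("optimize_minimax: no beam geometry given")
  d <- dim(ct$data)
  idx <- which(ctv)
  ii <- arrayInd(idx, d)
  pts <- sweep(sweep(ii - 1, 2, ct$spacing, `*`), 2, ct$origin, `+`)
  iso <- colMeans(pts)
  rsp_nom <- hu_to_rsp(ct, curve)
  u <- setup_uncertainty

  # beam construction from the nominal CT
  beams <- lapply(beam_directions, function(dir) {
    b0 <- list(axis = which(abs(dir) > 1e-9), sign = sign(sum(dir)))
    wet_vol <- wet_volume(rsp_nom, b0$axis, b0$sign)
    wet_ctv <- wet_vol[idx]
    span <- c(max(min(wet_ctv) - 3, 5), max(wet_ctv) + 3)
    n_layers <- max(2L, ceiling(diff(span) / layer_spacing) + 1L)
    sobp <- build_sobp(span, n_layers)
    lat <- setdiff(1:3, b0$axis)
    margin <- u + sigma_air
    su <- range(pts[, lat[1]] - iso[lat[1]])
    sv <- range(pts[, lat[2]] - iso[lat[2]])
    spot_u <- seq(su[1] - margin, su[2] + margin, by = sigma_air)
    spot_v <- seq(sv[1] - margin, sv[2] + margin, by = sigma_air)
    W0 <- outer(sobp$weights, rep(1, length(spot_u) * length(spot_v)))
    proton_beam(dir, iso, layers = sobp$ranges + 10 * range_shifter_wet,
                spot_u = spot_u, spot_v = spot_v, weights = W0,
                sigma_air = sigma_air, range_shifter_wet = range_shifter_wet)
  })

  # per-scenario factored influence at CTV voxels (patient frame: the dose at
  # patient point p under shift s is the grid dose at p + s)
  infl <- lapply(scenarios, function(sc) {
    rsp_s <- scenario_rsp(ct, sc, curve)
    q <- sweep(pts, 2, sc$shift, `+`)
    lapply(beams, beam_influence, rsp = rsp_s, pts = q)
  })

  nb <- length(beams)
  W <- lapply(beams, function(b) b$weights)
  dose_all <- function(fi, W) {
    out <- 0
    for (b in seq_len(nb)) out <- out + factored_dose(fi[[b]], W[[b]])
    out
  }
  # initial scale: nominal mean CTV dose = prescription
  d0 <- dose_all(infl[[1]], W)
  sc0 <- prescription / mean(d0)
  W <- lapply(W, function(w) w * sc0)

  n <- length(idx); p2 <- prescription^2
  trace_obj <- numeric(max_iter)
  for (it in seq_len(max_iter)) {
    objs <- vapply(infl, function(fi) mean((dose_all(fi, W) - prescription)^2) / p2,
                   0)
    trace_obj[it] <- max(objs)
    worst <- which.max(objs)
    fi <- infl[[worst]]
    r <- dose_all(fi, W) - prescription
    g <- lapply(seq_len(nb), function(b)
      (2 / (n * p2)) * crossprod(fi[[b]]$B, r * fi[[b]]$L))
    h <- 0
    for (b in seq_len(nb)) h <- h + factored_dose(fi[[b]], -g[[b]])
    hh <- sum(h * h)
    if (hh < 1e-30) break
    eta <- -sum(r * h) / hh  # exact line search for the quadratic objective
    for (b in seq_len(nb)) W[[b]] <- pmax(W[[b]] - eta * g[[b]], 0)
  }
  objs <- vapply(infl, function(fi) mean((dose_all(fi, W) - prescription)^2) / p2, 0)

  for (b in seq_len(nb)) beams[[b]]$weights <- W[[b]]
  plan <- proton_plan(beams, prescription, setup_uncertainty, density_uncertainty)

  # engine-based scenario evaluation and coverage renormalization
  doses <- scenario_doses(plan, ct, scenarios, curve, rois)
  # exact order statistic: the dose level that exactly 98% of CTV voxels
  # reach in each scenario; scaling it to 0.95 * prescription makes V95 >= 98
  q02 <- vapply(doses, function(dg) {
    v <- sort(dg$data[ctv], decreasing = TRUE)
    v[ceiling(0.98 * length(v))]
  }, 0)
  kappa <- 0.95 * prescription / min(q02) * (1 + 1e-9)
  kappa <- min(max(kappa, 0.85), 1.15)
  if (abs(kappa - 1) > 1e-6) {
    for (b in seq_len(nb)) plan$beams[[b]]$weights <- plan$beams[[b]]$weights * kappa
    doses <- lapply(doses, function(dg) vol_like(dg, dg$data * kappa, "dose"))
  }
  v95 <- vapply(doses, function(dg) v_d(dg, ctv, 0.95 * prescription), 0)

  structure(list(plan = plan, prescription = prescription,
                 setup_uncertainty = setup_uncertainty,
                 density_uncertainty = density_uncertainty,
                 scenarios = scenarios, v95 = v95,
                 worst_v95 = min(v95), kappa = kappa,
                 objective_trace = trace_obj[trace_obj > 0],
                 converged = length(trace_obj) >= 2 &&
                   abs(diff(utils::tail(trace_obj[trace_obj > 0], 2))) < 1e-8,
                 n_ctv = n, rois = rois, curve = curve, ct_dim = d),
            class = "minimax_plan")
}

#' @export
print.minimax_plan <- function(x, ...) {
  cat(sprintf("<minimax_plan> %d field(s), prescription %g Gy\n",
              length(x$plan$beams), x$prescription))
  cat(sprintf("  setup %g mm, density %g%%, %d scenarios\n",
              x$setup_uncertainty, 100 * x$density_uncertainty,
              length(x$scenarios)))
  cat(sprintf("  worst-scenario V95[CTV] = %.1f%% (nominal %.1f%%)\n",
              x$worst_v95, x$v95[1]))
  invisible(x)
}

#' @export
summary.minimax_plan <- function(object, ...) {
  cat("Minimax robust proton plan\n")
  print(object)
  cat(sprintf("  renormalization factor %.3f; final worst objective %.3e\n",
              object$kappa, utils::tail(object$objective_trace, 1)))
  sh <- vapply(object$scenarios, function(s) paste0(
    "(", paste(s$shift, collapse = ","), ")x", s$density_scale), "")
  df <- data.frame(scenario = sh, v95 = round(object$v95, 2))
  print(df, row.names = FALSE)
  invisible(object)
}

#' @export
coef.minimax_plan <- function(object, ...) {
  lapply(object$plan$beams, function(b) b$weights)
}

#' @export
predict.minimax_plan <- function(object, ct, rois = object$rois, ...) {
  compute_dose(object$plan, ct, object$curve, rois)
}

#' @export
residuals.minimax_plan <- function(object, ct, ...) {
  dg <- compute_dose(object$plan, ct, object$curve, object$rois)
  dg$data[roi_mask(object$rois, "CTV")] - object$prescription
}

#' @export
simulate.minimax_plan <- function(object, nsim = 1, seed = NULL, ct, ...) {
  scenario_doses(object$plan, ct, object$scenarios, object$curve, object$rois)
}

#' @export
plot.minimax_plan <- function(x, ...) {
  graphics::plot(seq_along(x$objective_trace), x$objective_trace, type = "b",
                 log = "y", xlab = "iteration",
                 ylab = "worst-scenario objective", main = "minimax convergence", ...)
  invisible(x)
}
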