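# Study orchestration: sweeps of filter width and added noise against a
# fixed clinical plan, and extraction of the maximum acceptable filter width.

#' Configuration for degradation sweeps
#'
#' The plan is optimized once on the clean CT and held fixed across all
#' degradations; only the dose is recomputed on each degraded image set, and
#' the external contour is the one expanded to the broadest filter of the
#' sweep.
#'
#' @param phantom a [phantom_spec] (e.g. from [canonical_phantom()]).
#' @param prescription prescribed dose, Gy.
#' @param setup_uncertainty,density_uncertainty robustness parameters for the
#'   one-off plan optimization (mm / fraction).
#' @param beam_directions list of cardinal beam directions.
#' @param range_shifter_wet cm.
#' @param kernel_kind `"boxcar"` or `"gaussian"`.
#' @param widths filter widths (mm), sorted ascending. The study grid is
#'   2-50 mm for boxcars and 1.2-37.6 mm FWHM for Gaussians; desk-scale
#'   subsets are fine.
#' @param noise_sigmas added-noise levels (HU) for [run_noise_sweep()]
#'   (the study range is 9-192 HU).
#' @param criteria a [gamma_criteria].
#' @param roi_names ROIs to score (default external and PTV).
#' @param pass_threshold required pass rate, percent.
#' @param seed base seed for noise realizations (one per cell).
#' @param optimizer_iterations iterations for [optimize_minimax()].
#' @return A `sweep_config` object.
#' @export
sweep_config <- function(phantom, prescription = 54, setup_uncertainty = 3,
                         density_uncertainty = 0.035,
                         beam_directions = list(c(1, 0, 0), c(0, 1, 0)),
                         range_shifter_wet = 7.4,
                         kernel_kind = c("boxcar", "gaussian"),
                         widths = c(2, 4, 6, 8, 10, 14, 18, 22, 26),
                         noise_sigmas = c(9, 24, 48, 96, 192),
                         criteria = gamma_criteria(),
                         roi_names = c("external", "PTV"),
                         pass_threshold = 98, seed = 1L,
                         optimizer_iterations = 60) {
  stopifnot(inherits(phantom, "phantom_spec"),
            pass_threshold > 0, pass_threshold < 100)
  widths <- sort(widths)
  structure(list(phantom = phantom, prescription = prescription,
                 setup_uncertainty = setup_uncertainty,
                 density_uncertainty = density_uncertainty,
                 beam_directions = beam_directions,
                 range_shifter_wet = range_shifter_wet,
                 kernel_kind = match.arg(kernel_kind), widths = widths,
                 noise_sigmas = noise_sigmas, criteria = criteria,
                 roi_names = roi_names, pass_threshold = pass_threshold,
                 seed = as.integer(seed),
                 optimizer_iterations = optimizer_iterations),
            class = "sweep_config")
}

# Shared setup: phantom, one-off robust plan, reference dose with the
# external expanded to the broadest filter of the sweep.
sweep_setup <- function(config, max_width) {
  ph <- generate_phantom(config$phantom)
  fit <- optimize_minimax(
    ph$volume, ph$rois, prescription = config$prescription,
    setup_uncertainty = config$setup_uncertainty,
    density_uncertainty = config$density_uncertainty,
    beam_directions = config$beam_directions,
    range_shifter_wet = config$range_shifter_wet,
    max_iter = config$optimizer_iterations)
  ext0 <- roi_mask(ph$rois, "external")
  ext_broad <- expand_external(ext0, max_width, ph$volume$spacing)
  masks <- ph$rois$masks
  masks$external <- ext_broad
  rois_b <- roi_set(masks, ph$rois$roles, ph$rois$spacing, ph$rois$origin)
  ref <- compute_dose(fit$plan, ph$volume, rois = rois_b)
  list(phantom = ph, fit = fit, rois = rois_b, ext0 = ext0, reference = ref)
}

sweep_provenance <- function(config) {
  list(config_hash = rlang::hash(unclass(config)), seed = config$seed,
       package_version = as.character(utils::packageVersion("ctdr")))
}

#' Run a filter-width sweep
#'
#' For each width: low-pass filter the CT, recompute the dose with the fixed
#' clinical plan, and run the gamma test against the clean-CT dose. Width 0
#' is the identity and scores 100%.
#'
#' @param config a [sweep_config].
#' @param noise_sigma added noise (HU) applied after filtering at every
#'   width (default 0, the pure width sweep).
#' @return A `ct_sweep` object: data.frame `results` with one row per
#'   (width, noise, ROI), plus provenance (config hash, seed, version).
#' @export
run_width_sweep <- function(config, noise_sigma = 0) {
  stopifnot(inherits(config, "sweep_config"))
  setup <- sweep_setup(config, max(config$widths))
  rows <- list()
  for (k in seq_along(config$widths)) {
    w <- config$widths[k]
    t0 <- proc.time()[3]
    if (w == 0 && noise_sigma == 0) {
      degr <- list(volume = setup$phantom$volume)
    } else {
      kern <- filter_kernel(config$kernel_kind, w)
      nm <- if (noise_sigma > 0)
        noise_model(noise_sigma, config$seed + k) else NULL
      degr <- degrade_ct(setup$phantom$volume, kern, setup$ext0, nm)
    }
    ev <- compute_dose(setup$fit$plan, degr$volume, rois = setup$rois)
    gr <- gamma_index(setup$reference, ev, config$criteria, setup$rois,
                      roi_names = config$roi_names)
    for (nm2 in config$roi_names)
      rows[[length(rows) + 1]] <- data.frame(
        width = w, noise_sigma = noise_sigma, roi = nm2,
        pass_rate = pass_rate(gr, nm2),
        n_voxels = unname(gr$n_evaluated[nm2]),
        elapsed_s = round(proc.time()[3] - t0, 2))
  }
  structure(list(results = do.call(rbind, rows),
                 provenance = sweep_provenance(config),
                 pass_threshold = config$pass_threshold,
                 setup = setup),
            class = "ct_sweep")
}

#' Run a combined filter-width / added-noise sweep
#'
#' Grid over (Gaussian FWHM, noise sigma) with one seeded noise realization
#' per cell; the sigma = 0 column coincides with the width sweep.
#'
#' @param config a [sweep_config] with `kernel_kind = "gaussian"` (the
#'   study's noise sweeps used Gaussian kernels).
#' @return A `ct_sweep` with one row per (width, noise, ROI).
#' @export
run_noise_sweep <- function(config) {
  stopifnot(inherits(config, "sweep_config"))
  if (config$kernel_kind != "gaussian")
    stop("run_noise_sweep: use a gaussian kernel (the noise-sweep design)")
  setup <- sweep_setup(config, max(config$widths))
  rows <- list()
  cell <- 0L
  for (w in config$widths) for (s in c(0, config$noise_sigmas)) {
    cell <- cell + 1L
    t0 <- proc.time()[3]
    if (w == 0 && s == 0) degr <- list(volume = setup$phantom$volume)
    else degr <- degrade_ct(setup$phantom$volume,
                            filter_kernel("gaussian", w), setup$ext0,
                            if (s > 0) noise_model(s, config$seed + cell) else NULL)
    ev <- compute_dose(setup$fit$plan, degr$volume, rois = setup$rois)
    gr <- gamma_index(setup$reference, ev, config$criteria, setup$rois,
                      roi_names = config$roi_names)
    for (nm2 in config$roi_names)
      rows[[length(rows) + 1]] <- data.frame(
        width = w, noise_sigma = s, roi = nm2,
        pass_rate = pass_rate(gr, nm2),
        n_voxels = unname(gr$n_evaluated[nm2]),
        elapsed_s = round(proc.time()[3] - t0, 2))
  }
  structure(list(results = do.call(rbind, rows),
                 provenance = sweep_provenance(config),
                 pass_threshold = config$pass_threshold,
                 setup = setup),
            class = "ct_sweep")
}

#' @export
print.ct_sweep <- function(x, ...) {
  cat("<ct_sweep>\n")
  print(x$results[, setdiff(names(x$results), "elapsed_s")], row.names = FALSE)
  invisible(x)
}

#' Maximum acceptable filter width
#'
#' The largest tested width whose pass rate, and the pass rates of all
#' smaller tested widths, meet the threshold (first-crossing rule;
#' non-monotone recoveries beyond the first failure are ignored).
#'
#' @param sweep a `ct_sweep` (or its `results` data.frame).
#' @param roi ROI name.
#' @param threshold required pass rate, percent (default 98).
#' @param noise_sigma select rows with this added-noise level (default 0).
#' @return Width in mm, with attribute `flag`: `"ok"`, `"never_fails"`
#'   (all widths pass; the true limit lies beyond the sweep) or
#'   `"never_passes"` (0 is returned).
#' @export
max_acceptable_width <- function(sweep, roi, threshold = 98, noise_sigma = 0) {
  df <- if (inherits(sweep, "ct_sweep")) sweep$results else sweep
  df <- df[df$roi == roi & df$noise_sigma == noise_sigma, , drop = FALSE]
  if (nrow(df) == 0) stop("max_acceptable_width: no rows for roi '", roi, "'")
  df <- df[order(df$width), ]
  ok <- df$pass_rate >= threshold
  if (all(ok)) return(structure(max(df$width), flag = "never_fails"))
  first_fail <- which(!ok)[1]
  if (first_fail == 1) return(structure(0, flag = "never_passes"))
  structure(df$width[first_fail - 1], flag = "ok")
}
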