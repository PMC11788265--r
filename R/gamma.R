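#' Gamma-index acceptance criteria
#'
#' @param dta distance-to-agreement, mm (> 0).
#' @param dose_diff dose-difference criterion as a fraction of the global
#'   normalization dose (> 0); 0.01 = 1%.
#' @param threshold lower dose cut as a fraction of the normalization; voxels
#'   with reference dose below it are excluded from the test.
#' @param normalization `"max_reference"` (maximum reference dose inside the
#'   scored region; the global-gamma default) or `"prescription"` (requires
#'   `prescription` in [gamma_index()]).
#' @return A `gamma_criteria` object.
#' @export
gamma_criteria <- function(dta = 1, dose_diff = 0.01, threshold = 0.10,
                           normalization = c("max_reference", "prescription")) {
  stopifnot(dta > 0, dose_diff > 0, threshold >= 0, threshold < 1)
  structure(list(dta = dta, dose_diff = dose_diff, threshold = threshold,
                 normalization = match.arg(normalization)),
            class = "gamma_criteria")
}

#' Global 3D gamma-index comparison of two dose distributions
#'
#' For each reference voxel above the dose threshold, the gamma index is the
#' minimum over nearby positions e of
#' `sqrt((|r - e| / dta)^2 + ((D_eval(e) - D_ref(r)) / (dose_diff * D_norm))^2)`,
#' with the evaluated dose trilinearly interpolated on a candidate lattice of
#' step `dta / subdivision` and the search extended outward in shells of
#' width `dta` until the distance term alone exceeds the running minimum.
#' Gamma values are capped at `cap`; voxels below the threshold are `NaN`.
#'
#' @param reference,evaluated congruent dose [ct_volume]s.
#' @param criteria a [gamma_criteria].
#' @param rois optional [roi_set]; pass rates are reported for each of
#'   `roi_names`, and the scored region (and normalization region) is their
#'   union. Without ROIs the whole grid is scored.
#' @param roi_names ROI names to score (default: all masks in `rois`).
#' @param prescription normalization dose when
#'   `criteria$normalization == "prescription"`.
#' @param subdivision candidate lattice subdivision of the DTA; the default
#'   10 gives a candidate step of a tenth of the DTA.
#' @param cap gamma storage cap.
#' @return A `gamma_result`: gamma map (array, `NaN` below threshold),
#'   per-ROI pass rates (%), evaluated voxel counts, and the normalization
#'   dose.
#' @export
gamma_index <- function(reference, evaluated, criteria = gamma_criteria(),
                        rois = NULL, roi_names = NULL, prescription = NULL,
                        subdivision = 10, cap = 10) {
  stop_if_geometry_differs(reference, evaluated, "reference and evaluated dose")
  d <- dim(reference$data)
  if (!is.null(rois)) {
    if (is.null(roi_names)) roi_names <- names(rois$masks)
    region <- Reduce(`|`, lapply(roi_names, function(nm) roi_mask(rois, nm)))
  } else {
    roi_names <- character()
    region <- array(TRUE, d)
  }
  dnorm <- switch(criteria$normalization,
    max_reference = max(reference$data[region]),
    prescription = {
      if (is.null(prescription)) stop("gamma_index: prescription normalization requires `prescription`")
      prescription
    })
  if (dnorm <= 0) stop("gamma_index: normalization dose must be positive")
  eval_mask <- region & (reference$data >= criteria$threshold * dnorm)
  idx <- which(eval_mask)
  if (length(idx) == 0) stop("gamma_index: no voxels above the dose threshold")
  g <- gamma_search_cpp(as.numeric(reference$data), as.numeric(evaluated$data),
                        as.integer(d), as.numeric(reference$spacing),
                        as.integer(idx), criteria$dta,
                        criteria$dose_diff * dnorm,
                        criteria$dta / subdivision, cap)
  map <- array(NaN, d)  # NaN below threshold / outside the scored region
  map[idx] <- pmin(g, cap)
  pass <- numeric(0); nev <- integer(0)
  for (nm in roi_names) {
    m <- roi_mask(rois, nm) & eval_mask
    nev[nm] <- sum(m)
    pass[nm] <- if (nev[nm] > 0) 100 * sum(map[m] <= 1) / nev[nm] else NA_real_
  }
  structure(list(map = map, spacing = reference$spacing,
                 origin = reference$origin,
                 pass_rates = pass, n_evaluated = nev,
                 criteria = criteria, dnorm = dnorm,
                 n_total = length(idx)),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %g mm / %g%%, threshold %g%%, D_norm %.3g\n",
              x$criteria$dta, 100 * x$criteria$dose_diff,
              100 * x$criteria$threshold, x$dnorm))
  for (nm in names(x$pass_rates))
    cat(sprintf("  %-10s pass %6.2f%%  (n = %d)\n", nm, x$pass_rates[nm],
                x$n_evaluated[nm]))
  invisible(x)
}

#' Gamma pass rate within an ROI
#'
#' Percentage of evaluated voxels (above the dose threshold) with gamma <= 1.
#'
#' @param result a `gamma_result` from [gamma_index()].
#' @param roi_name ROI name scored in the result.
#' @return Pass rate in percent.
#' @export
pass_rate <- function(result, roi_name) {
  stopifnot(inherits(result, "gamma_result"))
  if (!roi_name %in% names(result$pass_rates))
    stop("pass_rate: ROI '", roi_name, "' was not scored")
  if (result$n_evaluated[roi_name] == 0)
    stop("pass_rate: no evaluated voxels in ROI '", roi_name, "'")
  unname(result$pass_rates[roi_name])
}

#' Brute-force gamma oracle (exhaustive dense search)
#'
#' Independent reference implementation for small grids: for each requested
#' voxel the gamma index is minimized over every candidate on a dense lattice
#' of step `dta / subdivision` within `max_radius`, with no early
#' termination. Used to validate the production shell search.
#'
#' @param reference,evaluated congruent dose [ct_volume]s.
#' @param criteria a [gamma_criteria].
#' @param voxels linear indices of reference voxels to evaluate.
#' @param dnorm normalization dose.
#' @param max_radius search radius, mm (default `3 * dta`).
#' @param subdivision lattice subdivision of the DTA.
#' @return Numeric vector of gamma values for `voxels`.
#' @export
gamma_index_exhaustive <- function(reference, evaluated, criteria, voxels,
                                   dnorm, max_radius = 3 * criteria$dta,
                                   subdivision = 10) {
  stop_if_geometry_differs(reference, evaluated)
  d <- dim(reference$data)
  step <- criteria$dta / subdivision
  m <- ceiling(max_radius / step)
  offs <- as.matrix(expand.grid(x = (-m:m) * step, y = (-m:m) * step,
                                z = (-m:m) * step))
  offs <- offs[rowSums(offs^2) <= max_radius^2, , drop = FALSE]
  dd_abs <- criteria$dose_diff * dnorm
  dist2 <- rowSums(offs^2) / criteria$dta^2
  out <- numeric(length(voxels))
  for (q in seq_along(voxels)) {
    i <- voxels[q]
    ii <- arrayInd(i, d)
    pos <- reference$origin + (as.numeric(ii) - 1) * reference$spacing
    pts <- sweep(offs, 2, pos, `+`)
    ev <- interp3(evaluated$data, evaluated$spacing, evaluated$origin, pts,
                  fill = NA_real_)
    g2 <- dist2 + ((ev - reference$data[i]) / dd_abs)^2
    out[q] <- sqrt(min(g2, na.rm = TRUE))
  }
  out
}
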