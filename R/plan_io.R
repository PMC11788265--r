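# Plan serialization: JSON round trip for proton plans.

#' Write a proton plan to JSON
#'
#' @param plan a [proton_plan] (or [minimax_plan], whose inner plan is
#'   written).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  if (inherits(plan, "minimax_plan")) plan <- plan$plan
  stopifnot(inherits(plan, "proton_plan"))
  obj <- list(
    prescription = plan$prescription,
    setup_uncertainty = plan$setup_uncertainty,
    density_uncertainty = plan$density_uncertainty,
    beams = lapply(plan$beams, function(b) list(
      direction = b$direction, isocenter = b$isocenter, layers = b$layers,
      spot_u = b$spot_u, spot_v = b$spot_v,
      weights = as.vector(b$weights),
      sigma_air = b$sigma_air, range_shifter_wet = b$range_shifter_wet)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a proton plan from JSON
#'
#' @param path file written by [write_plan()].
#' @return A [proton_plan].
#' @export
read_plan <- function(path) {
  obj <- jsonlite::read_json(path)
  num <- function(x) as.numeric(unlist(x))
  beams <- lapply(obj$beams, function(b)
    proton_beam(num(b$direction), num(b$isocenter), num(b$layers),
                num(b$spot_u), num(b$spot_v),
                matrix(num(b$weights), nrow = length(num(b$layers))),
                num(b$sigma_air), num(b$range_shifter_wet)))
  proton_plan(beams, num(obj$prescription), num(obj$setup_uncertainty),
              num(obj$density_uncertainty))
}
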