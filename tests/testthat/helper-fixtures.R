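# Shared fixtures, built once per test run and cached across test files.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = fixture_cache, inherits = FALSE))
    assign(name, force(expr), envir = fixture_cache)
  get(name, envir = fixture_cache, inherits = FALSE)
}

# Brain-like study case at reduced resolution (64^3 @ 3 mm): phantom plus a
# two-field minimax plan with the brain study conditions (54 Gy, 3 mm setup,
# 3.5% density, 5.1 cm range shifter).
brain_case <- function() cached("brain_case", {
  spec <- canonical_phantom("brain", c(64, 64, 64), c(3, 3, 3), seed = 42)
  ph <- generate_phantom(spec)
  fit <- optimize_minimax(ph$volume, ph$rois, prescription = 54,
                          setup_uncertainty = 3, density_uncertainty = 0.035,
                          range_shifter_wet = 5.1, max_iter = 40)
  list(spec = spec, phantom = ph, fit = fit, prescription = 54, u = 3)
})

# Scenario dose grids of the brain case (13 scenarios, patient frame).
brain_scenario_doses <- function() cached("brain_scenario_doses", {
  bc <- brain_case()
  scenario_doses(bc$fit, bc$phantom$volume, bc$fit$scenarios,
                 rois = bc$phantom$rois)
})

# Boxcar width sweeps on the brain-like and thorax-like phantoms.
brain_width_sweep <- function() cached("brain_width_sweep", {
  cfg <- sweep_config(canonical_phantom("brain", c(64, 64, 64), c(3, 3, 3)),
                      prescription = 54, setup_uncertainty = 3,
                      density_uncertainty = 0.035, range_shifter_wet = 5.1,
                      widths = c(2, 4, 6, 8), seed = 7,
                      optimizer_iterations = 40)
  run_width_sweep(cfg)
})

thorax_width_sweep <- function() cached("thorax_width_sweep", {
  cfg <- sweep_config(canonical_phantom("thorax", c(64, 64, 64), c(3, 3, 3)),
                      prescription = 50.4, setup_uncertainty = 5,
                      density_uncertainty = 0.035, range_shifter_wet = 7.4,
                      beam_directions = list(c(-1, 0, 0), c(0, 1, 0)),
                      widths = c(2, 4, 6, 8), seed = 7,
                      optimizer_iterations = 40)
  run_width_sweep(cfg)
})

# Uniform water cylinder phantom (no noise) for engine-level checks.
water_phantom <- function(grid = c(48, 48, 48), spacing = c(3, 3, 3)) {
  ctr <- (grid - 1) * spacing / 2
  spec <- phantom_spec(
    "water", grid, spacing,
    tissue_layout = list(phantom_primitive("cylinder", 0, center = ctr,
                                           radius = 0.4 * (grid[1] - 1) * spacing[1],
                                           axis = 3L)),
    target_def = list(center = ctr, radius = 10, location = "homogeneous"),
    ptv_margin_mm = 3, baseline_noise_sigma = 0, seed = 1L)
  generate_phantom(spec)
}
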