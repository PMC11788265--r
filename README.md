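# ctdr — robustness of proton dose distributions to CT degradation

`ctdr` is an R package for studying how much image quality a planning CT
actually needs for proton-therapy dose calculation. It re-creates, on fully
synthetic digital phantoms, an in-silico experiment: degrade a planning CT by
low-pass filtering (lower spatial resolution) and additive white noise,
recompute the dose of a fixed, robustly optimized proton plan on the degraded
image, and quantify the dosimetric change with a global 3D gamma test and
scenario-based robustness metrics. The practical payoff is an exposure model:
if dose calculation tolerates a broader point-spread function and more noise,
the x-ray exposure spent on tomographic imaging can be reduced by orders of
magnitude.

The package is aimed at medical-physics researchers who want a reproducible,
dependency-light sandbox for resolution/noise requirements of dose engines —
not at clinical use.

## What is inside

* **Phantoms** — four canonical anatomical phantoms (brain-like homogeneous,
  thorax-like with a chest-wall/lung interface, abdomen-like, pelvis-like)
  with external/CTV/PTV/OAR masks, plus a wire-in-water resolution phantom
  (0.18 mm wire) for line-spread-function metrology.
* **Degradation** — separable, mm-exact 3D boxcar and truncated-Gaussian
  low-pass filters `p(s)` followed by additive white Gaussian noise (noise is
  added after filtering, so its level is filter-independent). The boxcar of
  width `w` maps to a Gaussian of `sigma = w / sqrt(12)`.
* **Dose engine** — a deterministic analytic pencil-beam engine:
  water-equivalent-thickness (WET) ray tracing through an HU→stopping-power
  calibration, an analytic Bragg curve with range-shifter bookkeeping,
  depth-broadened lateral Gaussian spots, and non-negative least-squares
  spread-out-Bragg-peak construction.
* **Robust planning** — minimax optimization of spot weights over 13
  scenarios (6 cardinal setup shifts of magnitude `u` × density scales
  `1 ± delta`, plus nominal), returning a classed `minimax_plan` with
  `print`, `summary`, `coef`, `predict`, `simulate`, `residuals` and `plot`
  methods.
* **Gamma evaluation** — global 3D gamma index `gamma(r) = min_e
  sqrt((|r-e|/DTA)^2 + ((D_e(e)-D_r(r))/(dd·D_norm))^2)` with sub-voxel
  interpolation (lattice step ≤ DTA/10), masked pass rates, and an
  independent brute-force oracle.
* **Robustness metrics** — per-scenario V95\[CTV\], worst-case and
  voxel-wise-minimum coverage, the dose D for which half of the perturbed
  scenarios keep `V_D[CTV] > 98%`, and OAR dose deltas.
* **Image-quality metrology** — LSF from nine transversal directions through
  the wire, FWHM, MTF with MTF50/MTF10, and noise in homogeneous regions.
* **Exposure model** — `Var c(x) ∝ 1 / (E · slice · PSF^4)`: a PSF broadening
  `b`, a tolerated noise increase `f` and a slice increase `d` allow an
  exposure reduction of `b^4 · f^2 · d`.

## Worked example

```r
library(ctdr)

spec <- canonical_phantom("brain", seed = 42)      # 96^3 voxels @ 2 mm
ph   <- generate_phantom(spec)

fit <- optimize_minimax(ph$volume, ph$rois, prescription = 54,
                        setup_uncertainty = 3, density_uncertainty = 0.035,
                        range_shifter_wet = 5.1)
fit
#> <minimax_plan> 2 field(s), prescription 54 Gy
#>   setup 3 mm, density 3.5%, 13 scenarios
#>   worst-scenario V95[CTV] = 98.0% (nominal 100.0%)

degr <- degrade_ct(ph$volume, filter_kernel("boxcar", 4),
                   roi_mask(ph$rois, "external"))
masks <- ph$rois$masks; masks$external <- degr$external
rois  <- roi_set(masks, ph$rois$roles, ph$rois$spacing)

ref <- compute_dose(fit, ph$volume, rois = rois)   # clean-CT dose
ev  <- compute_dose(fit, degr$volume, rois = rois) # dose on the degraded CT

gamma_index(ref, ev, gamma_criteria(dta = 1, dose_diff = 0.01, threshold = 0.10),
            rois, roi_names = c("external", "PTV"))
#> <gamma_result> 1 mm / 1%, threshold 10%, D_norm 59.3
#>   external   pass  99.10%  (n = 43430)
#>   PTV        pass 100.00%  (n = 1616)
```

Reading: after blurring the CT with a 4 mm boxcar — roughly a 2.7 mm FWHM
Gaussian PSF, i.e. about twice the width of a clinical scanner PSF — 99.1% of
the irradiated voxels still agree with the clean-CT dose within 1 mm / 1%.
The plan's worst-scenario target coverage (V95 of the CTV over all 13
setup/density scenarios) stays at or above 98%. The matching exposure
arithmetic:

```r
b <- broadening_factor(1.45, filter_kernel("boxcar", 4))  # 2.125 -> 2.1
exposure_sparing(b)                                       # 20.4  -> a factor of 20
```

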