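---
title: "How much CT image quality does proton dose calculation need?"
author: "ctdr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How much CT image quality does proton dose calculation need?}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ctdr)
```

## The question and the model

Proton dose calculation reads a CT-derived map of relative stopping power
(RSP) and integrates it into water-equivalent thickness (WET) along each
pencil beam. Intuition says dose accuracy should demand high-resolution,
low-noise CTs. For *robustly optimized* plans the opposite holds to first
order: a plan optimized to tolerate rigid setup shifts `s` with `|s| <= u`
satisfies `dD_i/ds ≈ 0` for target voxels, and a low-pass filtered CT is
exactly a weighted superposition of shifted copies of the patient,
`c_LR(x) = ∫ p(s) c(x - s) ds`. As long as the kernel `p` is narrower than
the setup margin, the first-order dose perturbation cancels and the dose
distribution is left nearly unchanged. `ctdr` turns that argument into a
testable pipeline: generate a phantom, optimize a robust plan, degrade the
CT, recompute the dose, and measure the disagreement.

Everything runs on synthetic inputs. No patient data, no commercial dose
engine: the package's own deterministic pencil-beam engine replaces the
Monte-Carlo system a clinic would use, which is appropriate because the
question under study concerns dose *shape stability* under image
degradation, not absolute dosimetry, and the first-order argument is
engine-agnostic.

## Synthetic phantoms: what they emulate, what they do not

`canonical_phantom()` ships four cases mirroring typical treatment sites:

* **brain** — a 40 HU sphere inside a 1200 HU skull shell; the CTV sits in
  homogeneous surroundings. Baseline noise 6.0 HU.
* **thorax** — a soft-tissue cylinder with a capped -750 HU lung; the CTV
  straddles the chest-wall/lung interface (a ≥ 500 HU density step).
  Baseline noise 2.3 HU.
* **abdomen**, **pelvis** — soft tissue with bony structures, homogeneous
  CTVs, baseline noise 8 and 9.6 HU.

The baseline noise levels are typical planning-CT values for those
anatomies; the lung is capped in the longitudinal direction so the external
contour encloses it, as a body outline does. Default grids are 96^3 voxels
at 2 mm — fine enough that a 1 mm distance-to-agreement gamma test is
meaningful after sub-voxel interpolation, small enough for desk-scale runs
(1 mm grids are available through `grid_shape`/`spacing`).

These phantoms are geometric primitives, not anatomy. Passing tests on them
demonstrates the mechanism (first-order invariance, interface sensitivity,
noise tolerance), not clinical performance on real CTs: real anatomy has
texture, oblique interfaces and calibration nonlinearity that primitives do
not exercise. The homogeneous-vs-interface contrast is the one qualitative
feature of real cohorts the phantoms are designed to reproduce.

## Degradation operators

`filter_kernel()` implements the two kernel families used throughout:
boxcars (full width in mm) and Gaussians (FWHM in mm, truncated at 4 sigma
per side and renormalized). Kernels are separable and isotropic in mm, and
discretized *symmetrically with exact width*: each tap receives the fraction
of its voxel cell covered by the continuous kernel support, so a 4 mm boxcar
on 1 mm voxels is `c(.5, 1, 1, 1, .5)/4`. The even-ratio alternative — a
plain 4-tap moving average — has exactly `1/n` noise-variance reduction per
axis but shifts the image by half a voxel, which is unacceptable upstream of
a 1 mm gamma test; the symmetric kernel pays for phase correctness with a
slightly stronger noise reduction (per-axis `sum(w^2) = (n - 1/2)/n^2`
instead of `1/n`). Filtering pads with -1000 HU (air) and expands the
external contour by the kernel width, since smoothing smears the body
surface into air.

Noise is zero-mean white Gaussian, added **after** filtering (so the final
noise level is filter-independent), only inside the expanded external
contour, and reproducibly seeded. `boxcar_gaussian_equivalent()` encodes the
width equivalence `sigma = w / sqrt(12)`; a 4 mm boxcar corresponds to a
2.7 mm FWHM Gaussian.

## The dose engine

The engine is deliberately simple and fully deterministic:

* **WET**: cumulative sum of RSP × spacing along the (cardinal) beam axis,
  half-voxel corrected; `trace_wet()` offers arbitrary-direction tracing by
  fine-step trilinear sampling (internal step = spacing/4; against a 10×
  finer oracle it agrees below 0.5 mm WET).
* **Depth dose**: `D(z; R) = (0.30 + 0.45 (z/R)^2) Φ((Rc - z)/s) +
  2.2 exp(-(z - Rc)^2 / (2 s^2))` with `s = max(0.025 R, 0.5)` mm and
  `Rc = R + 0.15 s` so the maximum sits at `z = R`; the curve is truncated
  at `R + 3 s`. The 2.5%-of-range peak width models beamline energy spread
  plus straggling, including the substantial broadening of the 5.1/7.4 cm
  WET range shifters every field uses; it also makes an 8-layer SOBP over a
  40 mm span flat to within ±2%, which is what clinical layer spacings
  achieve. The peak-to-entrance ratio (~8) is higher than physical pristine
  peaks; only relative dose shapes matter here.
* **Lateral spread**: Gaussian spots of sigma 5 mm in air (≈ 12 mm FWHM,
  the ~10 mm scale of clinical pencil beams), growing linearly with depth to
  twice the surface value at the deepest layer, amplitude-renormalized.
* **Range shifter**: `R_eff = R - 10 × WET(cm)`; energies are bookkept as
  ranges in mm water throughout (no MeV conversion).

Beams are restricted to the six cardinal directions, which keeps WET exact
and the engine fast; nothing in the study design needs oblique incidence.
Nuclear halo, secondaries and RBE are omitted; doses are physical-dose
surrogates in arbitrary Gy.

## Minimax robust optimization

`optimize_minimax()` optimizes the (layer × spot) weight matrix of each
field so the worst scenario's mean-squared CTV deviation from prescription
is minimized: per iteration the worst of the 13 scenarios is selected and a
projected gradient step (exact line search, non-negativity projection) is
taken. Scenario doses during optimization use a factored influence
representation (depth × lateral) at CTV voxels only, which makes the loop
cheap; the reported per-scenario V95 values are recomputed afterwards with
the full engine. A final renormalization (bounded to ±15%) scales the plan
so the worst-scenario V95\[CTV\] reaches the 98% coverage requirement —
the same prescription rescaling a clinic applies at plan normalization.

The 6 × 2 + nominal = 13 scenario reading of "six shifts combined with two
density perturbations" is one of two defensible interpretations (the other
is 6 + 2 = 8 perturbed scenarios); the crossed version is implemented
because it is the more conservative superset.

## Gamma evaluation

`gamma_index()` is a global gamma with dose differences normalized to the
maximum reference dose inside the scored region (prescription normalization
is available). For each reference voxel above the 10% dose threshold the
evaluated dose is interpolated trilinearly on a candidate lattice of step
DTA/10, searched outward in shells of width DTA until the distance term
alone exceeds the running minimum, capped at gamma = 10. The search is exact
on its lattice: `gamma_index_exhaustive()`, a brute-force dense-lattice
oracle with no early termination, agrees with it to machine precision on
small grids (the suite requires < 0.02). Refining the lattice can only
lower gamma (nested minima), which the suite also checks. Because the
engine is deterministic there is no Monte-Carlo noise floor under the 1%
dose criterion.

## Robustness metrics

`robust_evaluate()` recomputes scenario doses for a *fixed* plan (the study
never re-optimizes on degraded images), maps them back to the patient frame,
and reports per-scenario and worst-case V95[CTV], the voxel-wise-minimum
dose distribution, OAR mean and D2% per scenario, and the more sensitive
coverage statistic d50: the largest dose D such that at least half of the 12
perturbed scenarios keep `V_D[CTV] > 98%`, found by bisection (the passing
count is non-increasing in D) to 0.1% of the prescription and verified in
the suite against an exhaustive 0.01 Gy scan.

## Resolution and noise metrology

`generate_wire_phantom()` rasterizes a 0.18 mm wire with sub-voxel area
weighting (16 × 16 supersampling of the disc cross-section) in water on a
0.25 mm in-plane grid, blurs it with the simulated scanner PSF and adds
noise. `measure_lsf()` averages profiles along nine transversal directions
(20° apart) through the centroid-refined wire centre, subtracts the median
of a water annulus, and reports the FWHM by linear interpolation at half
maximum plus the MTF as the normalized Fourier modulus of the averaged LSF.
Parameter recovery is within 2% for PSFs around 1.5 mm FWHM; the Gaussian
closed forms (FWHM = 2.355 sigma, MTF50 at `sqrt(ln 2 / (2 pi^2 sigma^2))`)
are the test oracles.

## The exposure model

The scanner-level scaling `Var c(x) ∝ 1 / (E · Δ · ξ^4)` (exposure E, slice
width Δ, PSF width ξ) is treated as algebra, not verified by image-domain
smoothing — image-domain filtering of white noise scales differently from
projection-domain tomographic noise, and the model is deliberately the
simplest isotropic expression. Accepting a PSF broadening `b` at fixed
variance permits `E ÷ b^4`; tolerating `f`-fold noise std adds `f^2`;
thicker slices add `d`. For a 1.45 mm PSF (the midpoint of a typical
scanner's 1.4–1.5 mm) and the 4 mm boxcar found acceptable by the gamma
sweeps, `b = 2.1` and the sparing factor rounds to 20. The broadening is
computed by quadrature of the boxcar's Gaussian-equivalent FWHM and
cross-checked by numerical convolution compared on second-moment widths
(variances add exactly under convolution); a half-maximum reading of the
convolved profile would instead tend to the boxcar width itself for kernels
much wider than the PSF, which is why moments are used.

## Numerical choices and degenerate inputs

* Widths, margins and DTA are mm everywhere; voxel conversion is internal.
* Width-0 kernels, sigma-0 noise and zero-shift scenarios are exact
  identities.
* The external contour is the largest connected component above -300 HU,
  closed (2 mm) and cavity-filled; morphology uses an exact Euclidean
  distance transform, so dilation radii are isotropic in mm on anisotropic
  grids and expansion is exactly monotone.
* HU→RSP is piecewise-linear through a generic clinically shaped anchor set
  (air 0.001, lung 0.25, water 1.000, bone up to 2.4), clamped at the ends;
  it stands in for an unpublished institutional calibration.
* Scenario shifts resample trilinearly (air-filled); integer-voxel shifts
  reduce to exact rolls.
* Bisection tolerances: d50 at 0.1% of prescription; SOBP flatness target
  max/min ≤ 1.04 with the achieved value always reported.

## Problem sizes

The test suite runs the full chain at 64^3 voxels × 3 mm (the same 192 mm
physical extent as the default phantoms) with 40 optimizer iterations, and
the headline configuration once at the default 96^3 × 2 mm with 60
iterations; `scripts/acceptance.R` uses the 96^3 configuration. These sizes
were chosen so a complete run stays in the minutes range on a single core
while keeping the gamma test's 1 mm DTA well below the phantom extent.

## Known limitations

* The dose engine is a shape-faithful surrogate: no Monte-Carlo transport,
  no nuclear halo, no absolute dosimetry. No agreement with any commercial
  system is claimed.
* Cardinal-only beam incidence in `compute_dose()`.
* The degradation acts in the image domain; projection/sinogram-domain
  noise insertion, correlated noise and beam-hardening artifacts are out of
  scope.
* On these compact synthetic targets the PTV-restricted gamma pass rate
  exceeds the external-volume rate only for filter widths below twice the
  setup margin; beyond that limit the small PTV is dominated by distal-edge
  voxels and scores worse, unlike large clinical targets.
* Phantom realism: no organ atlases, no motion/4D, no texture.
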