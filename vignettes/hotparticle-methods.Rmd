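---
title: "Methods: microdosimetry and DNA-damage kinetics around a Cs-bearing microparticle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microdosimetry and DNA-damage kinetics around a Cs-bearing microparticle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hotparticle` models the exposure of a cell monolayer to a single insoluble
radioactive microparticle — an SiO~2~ sphere carrying ^134^Cs and ^137^Cs,
held just above the dish floor inside the closed, air-filled tip of a glass
microcapillary — and follows the consequences through to per-nucleus DNA
double-strand-break (DSB) burdens read out as γ-H2AX foci. This vignette
documents the models, their assumptions, the tunable parameters, and the
numerical and design choices, in that order.

## 1. Source term

The particle is a 271.0 µm diameter SiO~2~ sphere (2.2 g/cm³) containing
469.2 Bq of ^137^Cs and 38.5 Bq of ^134^Cs (activity fractions 92.4% /
7.6%). The emission inventory is a packaged YAML table
(`inst/extdata/nuclides.yaml`) compiled from standard decay-scheme
compilations: β branches, discrete conversion-electron lines and γ lines
with per-decay yields. Two conventions apply:

* **Secular equilibrium.** ^137m^Ba (2.55 min half-life) is folded into the
  ^137^Cs entry: the 661.66 keV γ (yield 0.851), Ba K X-rays, and the K/L
  conversion electrons (624.2 keV, 7.79%; 655.7 keV, 1.11%) are listed per
  ^137^Cs decay.
* **Yield cutoff.** Emissions below 0.01 per decay are omitted; their dose
  contribution is below one percent.

The configured activities sum to 507.7 Bq; a `total_activity_override`
field carries the alternative figure of 505.7 Bq that circulates for this
particle, but the default is the sum of the per-nuclide entries.

β energies are sampled from the allowed spectrum shape
$N(E) \propto F(Z, E)\, p\, W\, (Q - E)^2$ with the non-relativistic Fermi
Coulomb correction $F = 2\pi\eta / (1 - e^{-2\pi\eta})$,
$\eta = \alpha Z W / p$ (daughter $Z = 56$), normalized numerically and
inverted on a 4096-point CDF grid. The mean energy of the 511.6 keV branch
comes out at 0.34 Q, in the expected 0.30–0.40 Q window for allowed
transitions.

## 2. Scene geometry

The default scene (`source_geometry()`) places the sphere centre at
$(0, 0, 635.5)$ µm above a glass-base dish. The capillary is represented by
its closed tip only: a conformal SiO~2~ shell of thickness 10 µm around the
particle plus a vertical air column of radius 10 µm (the 20 µm inner tip
diameter) running down to the dish surface. The dish holds 2 mm of culture
medium (water). Dose is scored in a 10 µm water slab at the dish floor — a
cell-monolayer-equivalent layer — divided into concentric annuli of 50 µm
width out to 5 mm. "Distance from the particle" always means plane-radial
distance on the cell layer from the point beneath the source; slant
distances are used inside the kernels.

The tip-wall thickness is the dominant geometric unknown: the real
capillary body is drawn glass with a wall of order 10² µm at the height of
the particle, and slant rays toward the millimetre region cross it. The
analysis script `analysis/01_dose_field.R` quantifies the landmark
sensitivity to this parameter (see §4).

## 3. Dose engine

**β dose** is computed by Monte Carlo. Each electron history starts at a
uniformly sampled point inside the sphere (self-absorption) with an
isotropic direction and an energy drawn from the combined electron
inventory (β spectra plus conversion lines); the geometric ray is traced
through sphere, tip wall, air column and medium, and path lengths are
converted to water-equivalent lengths by density scaling with a
per-material stopping-power ratio (default 1.0). Energy deposition along
the ray is **not** the raw CSDA profile: straight-ahead transport ignores
multiple scattering, transports every electron to its full CSDA range, and
piles a Bragg-like spike at the end of the track, which overestimates the
dose in the 1.5–3 mm window by an order of magnitude. Instead, each
electron deposits energy according to a scaled dose point kernel
$j(u; E_0)$ — the fraction of $E_0$ deposited per unit scaled radius
$u = r / R_{\mathrm{CSDA}}(E_0)$ around an isotropic point source in water
— evaluated cumulatively over the water-equivalent depth interval of each
step. The kernel table is packaged
(`inst/extdata/electron_point_kernel.csv`) and was derived once, in-repo,
by a class-II condensed-history reference calculation
(`scripts/derive_point_kernel.R`): continuous energy loss with the
restricted collision stopping power, discrete Møller hard collisions above
25 keV with local δ-ray deposition, and Highland multiple-scattering
angular diffusion. Setting `scattering_correction = FALSE` recovers the
raw straight-ahead CSDA profile for comparison. Electrons below 1 keV
deposit locally; photons below 1 keV are likewise cut off.

Per-annulus standard errors use exact per-history bookkeeping
(per-(history, bin) deposits), so the SE shrinks as $1/\sqrt{n}$ and a
fixed seed reproduces the profile bit-for-bit.

**γ dose** is analytic, under the kerma approximation (charged-particle
equilibrium at millimetre distances):
$$\dot D_\gamma(d) = \sum_{\text{lines}} A\,y\,E\,
  \left(\tfrac{\mu_{en}}{\rho}\right)_{\!w}(E)\,
  B(\mu_w \ell_w)\, e^{-\sum_i \mu_i \ell_i} \,/\, (4\pi d^2),$$
with slant-path attenuation through the layered scene and a Berger buildup
factor $B(x) = 1 + 1.05\,x\,e^{0.03 x}$ on the water portion (near unity at
these depths). Attenuation and μ~en~/ρ tables are packaged plain-text
compilations of standard reference values, log-log interpolated. With
attenuation and buildup disabled the kernel reduces to the inverse-square
law exactly, which the tests assert to 10⁻¹⁰.

**Landmarks.** The β/γ crossover radius is located on an SE-weighted
smoothing-spline fit of $\log \dot D_\beta(r)$ (df = 8) crossed with the γ
curve; the raw adjacent-bin interpolation is available via
`smooth = FALSE` but is fragile where the flat β tail straddles the γ
level under Monte Carlo noise.

## 4. The crossover landmark: a known discrepancy

With the full inventory, the dose floor at 1.5–2.5 mm is set by the
624 keV conversion electrons (≈4×10⁻³ Gy/day at 1.6 mm) and the 5.3%
1176 keV β branch (≈1×10⁻³), against a γ level of ≈0.4×10⁻³ Gy/day. The
engine therefore places the β/γ crossover near 2.5 mm, not at the 1.65 mm
expected for this source from full condensed-history transport of a
β + γ source term. Hand evaluation with published-shape point kernels
reproduces our engine's numbers, so this is a property of the modelled
scene and inventory, not a transport bug. Two reconciliations are
plausible and documented rather than fitted: (a) the real capillary body
glass shields the slant paths far more than the nominal 10 µm tip wall
(`analysis/01_dose_field.R` tabulates crossover vs wall thickness); (b) a
β-spectra-only source term — without conversion electrons — lowers the β
curve to the γ level near 1.65 mm. We keep the physically complete
inventory and the nominal scene, and report the landmark as computed. The
companion bound — total dose-rate at and beyond the computed crossover —
is insensitive to this and stays well below 0.902 mGy/day.

## 5. Density sensitivity

Lowering the particle density reduces self-absorption and raises the dose
directly under the particle. `density_sensitivity()` recomputes the
innermost annulus (r < 50 µm) with common random numbers across densities
(the same seed, so the difference is not noise-dominated) and reports the
percent difference against the 2.2 g/cm³ reference; the ordering across
1.8 / 1.4 / 1.0 g/cm³ is strictly monotone and the 1.0 g/cm³ difference
comes out near 25% (Monte Carlo spread of a few percentage points at
5×10⁵ histories per density).

## 6. DSB induction and repair

Nuclear γ-H2AX foci follow a first-order induction–repair balance,
$\mathrm{d}N/\mathrm{d}t = \kappa \dot D - \lambda N$ with
$\lambda = \ln 2 / t_{1/2}$, giving
$N(t) = N_{bg} + (\kappa \dot D / \lambda)(1 - e^{-\lambda t})$ for
chronic exposure and $N(t) = N_{bg} + (N_0 - N_{bg}) e^{-\lambda t}$ for
repair after acute exposure. Repair is single-exponential (NHEJ-like);
bi-exponential repair is out of scope. Packaged half-times are 2.11 h
(WI-38) and 3.29 h (HBEC-3KT).

`fit_repair_halftime()` fits the decay form by weighted nonlinear least
squares (Levenberg–Marquardt, weights $n/\mathrm{SD}^2$ on untransformed
counts — the counts are strongly overdispersed, so log-transforming would
distort the error structure). The background is held fixed at the packaged
control level. The 95% CI uses the $t$ quantile on $n - 2$ degrees of
freedom; over 100 seeded Poisson replicates (6 time points × 100 cells)
the CI covers the generating half-time in ≈95% of replicates and the mean
estimate is within 5% of truth.

**Calibration anchoring.** The paper-scale acute yield (32.2 foci/Gy for
WI-38 at 30 min) combined with first-order repair over-predicts the
printed chronic mean at 7.29 Gy/24 h (≈30 vs 19.5 foci). The generator
therefore anchors each exposure condition's linear dose slope to its own
packaged calibration entry (chronic uniform, acute full-field, half-field
in-field), and the kinetics model supplies time-course shapes and
steady-state structure. This is an explicit choice to reproduce the
reported per-condition statistics rather than force one κ across regimes
the single-compartment model cannot reconcile.

**Heterogeneous-exposure knobs.** Two empirical parameters represent
non-targeted effects without a mechanistic model: a `protective_factor`
multiplying the in-field yield (defaults 0.899 / 0.750, the reported
half-field reduction ratios) and a `bystander_plateau` added where the
cumulative dose is below `bystander_threshold_Gy`. Defaults were fixed
once, at design time: plateaus of 0.10 (WI-38; below detectability at
n = 200, matching the absence of a distal response in that line) and 0.50
foci (HBEC-3KT; clearly detectable), thresholds of 0.05 and 0.008 Gy,
which place the particle-vs-uniform dose–response crossovers in the
tens-of-mGy and 5–10 mGy decades respectively. The crossover location is
therefore a calibrated reproduction, not a prediction.

## 7. Synthetic populations and images

Cells are placed uniformly at random (or on a grid) on a ϕ12 or ϕ27 mm
dish. The capillary tip position is jittered with SD 69.6 µm for the
particle condition; cells under the capillary footprint (r < 50 µm) are
flagged and excluded from scoring. Per-nucleus counts are negative
binomial, moment-matched to the packaged mean ± SD of the condition
(`size = m²/(s² − m)`; printed SDs like 13.1 on a mean of 19.5 far exceed
Poisson). Half-field dishes expose exactly ⌊n/2⌋ cells — the largest-x
half, a deterministic tie rule. Zone labels (β-dominant within 1.65 mm by
default) are pure functions of geometry.

Rendered images are single-plane, two-channel (nuclei + foci), 0.65 µm
pixels: soft-edged ellipses for nuclei (rejection-placed without overlap),
one Gaussian spot (σ = 1.5 px) per true focus placed inside the inner 80%
of its nucleus with a minimum separation of 4 px, and Poisson–Gaussian
noise controlled by a peak SNR parameter. Ground truth is emitted
alongside and is identical across noise levels at a fixed seed. What the
generator does **not** emulate: cell-cycle structure, nuclear texture,
focus intensity variation, 3-D defocus, touching nuclei at high density.
Passing tests on these images therefore demonstrate the counting chain's
correctness and noise robustness, not performance on real micrographs.

## 8. Focus counting

Nucleus segmentation: Gaussian blur (σ = 2 px), Otsu threshold on the
max-normalized image (hence intensity-scale invariant), connected
components, area filter, border discard; distance-transform watershed
splitting is available but off by default for these sparse layouts. Spot
detection: white top-hat background removal (disc radius 5 px), negative
Laplacian-of-Gaussian filter (σ = 1.5 px), local maxima within a
min-distance window (2 px) above a prominence threshold of 0.2 × the
global maximum response, restricted to segmented nuclei; a deterministic
infinitesimal tie-break resolves plateau maxima. Two foci closer than the
window merge into one — by design, mirroring maxima-based counting. On
noise-free renders the chain recovers every count exactly; across the SNR
ladder precision stays ≈1 and recall ≥0.9 down to SNR 3
(`analysis/05_imaging_benchmark.R`).

## 9. Group statistics

`tukey_kramer()` implements the all-pairs studentized-range test with the
Kramer adjustment for unequal group sizes, with the pooled within-group
variance from one-way ANOVA. The studentized-range CDF is evaluated by
`stats::ptukey`; the test suite cross-checks p-values against an
independent double-quadrature implementation of the CDF written in the
test helpers and against `stats::TukeyHSD`, and verifies the two-group
identity $q = \sqrt{2}\,|t|$ and the nominal family-wise error rate on
null simulations. The test unit is the cell, matching the ≥80-cells
scoring rule; this ignores dish-level clustering (pseudo-replication), as
the original analysis does. The half-field yield reduction is reported as
the ratio of mean in-field to mean full-field per-Gy yields with the SD
from first-order propagation of the two per-cell SDs assuming independent
samples (separate dishes); applied to the packaged calibration moments
this reproduces the reported 89.9 ± 50.6% and 75.0 ± 64.4% almost exactly.

## 10. Problem sizes and determinism

Default problem sizes were chosen to keep every stage interactive on one
CPU: 10⁶ β histories for the profile (seconds; per-bin SE ≲ few % in the
crossover region), 2–5×10⁵ per density for the sensitivity scan, 100
replicates for the recovery study, 200–600 cells per synthetic dish, and
six 384² images per SNR level. Every stochastic entry point takes a seed
and is bit-reproducible given it; provenance (seed, config checksum,
history count) is attached to dose profiles and written as JSON sidecars.

## 11. Known limitations

* The β engine is a depth-redistributed ray tracer, not condensed-history
  transport: lateral scattering displacement, backscatter from the glass
  substrate and bremsstrahlung are absent, and the packaged point kernel
  was itself derived with Gaussian small-angle scattering plus a
  simplified Møller tail.
* The capillary is reduced to a conformal tip shell and an air column;
  the real tapered glass body is not modelled (§4).
* Photon coefficient and stopping-power tables are compiled approximate
  values; adequate at the stated tolerances, not metrological.
* The kinetics model is single-compartment with empirical bystander /
  protective knobs; it encodes the reported phenomenology and cannot
  extrapolate mechanism.
* Count calibrations pin means and SDs per condition; correlations
  between conditions (same dish, same day) are not represented.
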