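---
title: "Models and methods for morphogen gradient analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for morphogen gradient analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphograd)
```

# The scientific problem

A morphogen secreted from a localized source forms a concentration
gradient whose decay length sets its signaling range. Three processes
shape that gradient: diffusion through a tissue packed with cells,
reversible binding to cell-surface receptors and extracellular
inhibitors, and clearance by degradation. `morphograd` provides the
measurement models (fluorescence correlation spectroscopy), the
equilibrium and transport theory, and the particle simulations needed
to connect single-molecule mobility measurements to tissue-scale
gradients — together with synthetic-data generators so that every
analysis stage can be validated against known ground truth.

Throughout, lengths are in micrometres, times in seconds,
concentrations in nanomolar, and diffusion coefficients in μm²/s.

# Correlation spectroscopy models

FCS records intensity fluctuations as labelled molecules transit a 3D
Gaussian confocal volume with lateral radius ω₀ and axial extent z₀
(`observation_volume()`; V_eff = π^{3/2} ω₀² z₀). The fluctuation
autocorrelation of a single species diffusing in 3D, with a fast
photophysical (triplet) component, is

$$G(\tau) = \frac{1}{N}\Big[1 + \tfrac{F_t}{1-F_t}e^{-\tau/\tau_t}\Big]
\Big(1+\tfrac{\tau}{\tau_d}\Big)^{-1}
\Big[1+\Big(\tfrac{\omega_0}{z_0}\Big)^2\tfrac{\tau}{\tau_d}\Big]^{-1/2}
+ G_\infty$$

(`acf_3d_1c_triplet()`), with the 2D variant for membrane-anchored
species lacking the axial factor (`acf_2d_1c_triplet()`), a
two-component 3D variant for mixed free/hindered populations
(`acf_3d_2c_triplet()`), and the two-channel cross-correlation model
(`ccf_model()`), which carries no triplet term because photophysics is
uncorrelated between spectrally distinct labels. The cross-correlation
model is implemented in its printed one-component 2D form. The
diffusion coefficient follows from the calibrated volume as
D = ω₀²/(4 τ_d).

**Fitting.** `fit_correlation()` solves the weighted least-squares
problem with the Levenberg–Marquardt algorithm (`minpack.lm`). Choices
that matter:

- *Weights.* Per-point standard errors are used as 1/σ weights when
  present, otherwise the fit is unweighted.
- *Two-stage solve.* Correlation-curve errors span many decades across
  the lag axis (short lags average few fluctuations), which makes the
  weighted problem badly conditioned: a cold-started weighted fit can
  strand in a local minimum in which the triplet term absorbs part of
  the diffusion decay. The fit therefore first solves the unweighted
  problem (which reliably finds the right basin) and then refines with
  weights from that optimum. With this scheme the reported standard
  errors match the Monte-Carlo scatter of repeated noisy fits.
- *Multi-start.* A deterministic schedule of jittered starts (diffusion
  time ×0.3/×3 with alternative triplet times) guards against
  triplet/diffusion exchange; no RNG is involved, so fits are
  reproducible.
- *Bounds.* F_t ∈ [0, 0.5] and τ_t ∈ [10⁻⁷, 10⁻⁴] s prevent the
  triplet term from impersonating slow diffusion; the structure ratio
  ω₀/z₀ is fixed by the calibrated volume, as is standard practice.
- *Tie-break.* Two-component fits are reported with components sorted
  by ascending diffusion time.
- *Failure handling.* Non-convergence after all restarts, or a
  constant (degenerate) curve, yields a result object with
  `converged = FALSE` rather than an error.

Defaults for synthetic work are ω₀ = 0.25 μm, z₀ = 1.25 μm (structure
ratio 0.2, V_eff ≈ 0.435 fL) — typical confocal calibration values —
and a logarithmic lag grid of 200 points spanning 10⁻⁶–1 s.

# Binding affinity and equilibrium

For a double-labelled complex, ideal FCCS relates zero-lag amplitudes
to particle numbers: N_g = 1/G_g(0), N_r = 1/G_r(0), and
N_gr = G_x(0)/(G_g(0)·G_r(0)); free numbers follow by subtraction and
concentrations as C = N/(V_eff·N_A)
(`concentrations_from_amplitudes()`). No spectral cross-talk or
background correction is applied — a documented limitation; inputs are
assumed pre-corrected.

Two estimators recover K_d from a cohort of per-embryo measurements:

- `kd_by_regression()`: at equilibrium C_g·C_r = K_d·C_gr, so the
  ordinary least-squares slope of the free-concentration product
  against the complex concentration estimates K_d (intercept left
  free). The slope estimator is unbiased in aggregate but individual
  small cohorts scatter (errors in the regressor attenuate single
  cohorts), so recovery tests assert on the median across seeds.
- `kd_by_histogram()`: a Gaussian is fitted to the frequency histogram
  of ln K_d (Freedman–Diaconis bin widths, least squares on bin
  counts), and exp(μ̂) reported — the mode/median of a log-normal K_d
  distribution. Reported affinities in this field rarely state which
  of the two estimators was used, so both are provided; on well-behaved
  data (CV of ln K_d < 0.5) they agree within ~20%.

The bound ligand fraction solves the bimolecular mass action
equilibrium exactly (physically valid quadratic root):

$$f_{bound} = \frac{K_d+L_t+R_t}{2L_t} -
\sqrt{\frac{(K_d+L_t+R_t)^2}{4L_t^2}-\frac{R_t}{L_t}}$$

(`bound_fraction()`; verified in the tests against an independent
bisection solver to 10⁻¹⁰). In the receptor-excess regime it approaches
R_t/(R_t+K_d): with K_d = 60 nM, L_t = 100 nM and R_t = 40 μM, 99.85%
of ligand is bound; at K_d = 120 nM, 99.7%.

Rapid equilibration between a free state diffusing at D and an
immobile bound state slows the population to D_eff = D·f_free
(`effective_diffusion()`), and the steady-state gradient of a cleared,
receptor-trapped morphogen decays with

$$\lambda = \sqrt{D/k}\,\Big/\,\sqrt{R/K_d+1}$$

(`gradient_length()`, inverted by `receptor_from_gradient()`). With
D = 60 μm²/s, R = 40 μM: λ ≈ 30 μm for K_d = 60 nM, k = 10⁻⁴ s⁻¹ and
λ ≈ 19 μm for K_d = 120 nM, k = 5×10⁻⁴ s⁻¹. Note a deliberate
parameterization point: this relation takes the *free* diffusion
coefficient together with the binding term R/K_d; substituting instead
the fully reduced effective coefficients (0.045/0.09 μm²/s) into
sqrt(D_eff/k) gives shorter lengths (21.2/13.4 μm) because the
tortuosity factor enters only one of the two routes. Both
parameterizations are available — `gradient_length()` accepts any D —
and the headline values quoted above use the free-D form.

# Hindered diffusion in a cell-packed slab

`simulate_slab()` releases particles on one face of a thin 3D slab
(defaults 2 × 44 × 86.7 μm, 1000 particles, 5 s at 5 ms steps,
D = 60 μm²/s) and walks them with independent Gaussian steps of
per-axis variance 2DΔt; x is reflected at both ends, y and z are
periodic. Cells are z-aligned cylinders (diameter 10 μm) on a square
lattice with pitch diameter + gap (gap 2 μm), so neighbouring membrane
surfaces are exactly one gap apart; collision tests use the modular
distance to the infinite lattice, which keeps the geometry exactly
periodic in y. A hexagonal variant was considered unnecessary: the
measured quantity (reduction factor) is already within the
effective-medium band on the square lattice.

**Collision rule.** A proposed move ending inside a cylinder is
handled by specular mirroring of the endpoint across the cylinder
surface (falling back to move rejection in the rare case the mirrored
point lands in another cylinder). Plain reject-and-stay is available
(`collision_rule = "reject"`) but is *not* the default: at the 5 ms
step size the per-axis RMS step (0.78 μm) is a large fraction of the
2 μm gap, and rejection then adds a spurious wall drag on top of
tortuosity — measured reduction factors exceed the theoretical
tortuosity ceiling of 2. The specular rule converges to reflected
diffusion and reproduces the expected physics: recovered D ≈ 61 free,
≈ 33 among obstacles, reduction factor ≈ 1.8–1.9 ≤ 2.

**Binding.** With `f_free < 1`, each particle moves in a given step
only with probability f_free (quasi-equilibrium binding; explicit
on/off kinetics are out of scope). This Bernoulli thinning scales the
long-time diffusion coefficient exactly by f_free.

**Recovering D_eff.** `concentration_profile()` bins final x positions
(1 μm bins by default) and normalizes to the maximum bin;
`fit_gaussian_profile()` fits the source-diffusion bell curve
C(x,t) = A·exp(−x²/(4 D_eff t)). The amplitude is a free parameter by
default: with 1000 particles the maximum bin is an upward-fluctuating
order statistic, and pinning A = 1 to it biases D_eff low by tens of
percent (A = 1 remains available via `amplitude = "fixed"`). For
strongly hindered runs whose 5 s spread stays below one lattice pitch
(e.g. f_free = 0.1, σ ≈ 5 μm < 12 μm), the histogram is dominated by
the discrete near-field — a spike in the source-adjacent free slit —
and is not a bell curve at all; for those conditions `slab_deff()`
offers a displacement-based estimator, D_eff = ⟨(x−x₀)²⟩/(2t), taken
from the same source-start run. Profile fitting remains the procedure
whenever the spread exceeds the pitch. At still smaller free fractions
(10⁻³ and below) the 5 s spread is under 1 μm and no profile-based
recovery is meaningful at this duration; the linear law
D_eff = f_free·D is instead verified directly (obstacle-free runs
across f_free ∈ {1, 0.1, 0.01}, R² > 0.99), which is the scaled-down
counterpart of those conditions.

# 1D gradient formation

`simulate_gradient_1d()` models the tissue-scale gradient: particles
are injected at x = 0 as a Poisson process with a chosen production
rate (0.07–0.7 s⁻¹ covers the regime of interest), take 1D Gaussian
steps with the pre-computed effective coefficient, and are removed
with probability 1 − e^{−kΔt} per step; both domain ends (extent
200 μm) reflect. Mean particle number equilibrates at production/k —
e.g. 0.7 s⁻¹ / 10⁻⁴ s⁻¹ = 7000 — and the steady profile decays with
λ = sqrt(D_eff/k). The closed-form steady state of the corresponding
reaction–diffusion equation on a finite reflecting domain,
C(x) ∝ cosh((L−x)/λ)/cosh(L/λ) (`steady_state_oracle()`), serves as an
independent oracle: the tests require per-bin agreement within three
Poisson standard deviations. Normalized gradient shape is invariant to
the production rate; only the amplitude changes.

Numerical choices: Δt = 1 s (per-step displacement ≈ 0.42 μm at
D_eff = 0.09 — well under the 2 μm guard enforced by
`gradient_config()`, and two orders below λ), a 16 hr 40 min default
duration so that even k = 10⁻⁴ s⁻¹ runs reach ≥ 99.7% of equilibrium, a
delta source at x = 0 (no source width is specified by the underlying
measurements), spatially uniform clearance, and particles moved with
the pre-computed D_eff rather than per-step Bernoulli thinning —
equivalent in distribution and faster. Steady state is summarized over
the final decile of the run (`steady_profile()` averages the recorded
profiles in that window before fitting, 2 μm bins).

`time_to_steady_fraction()` reports the time for the system to reach a
fraction f of steady state. The default readout is the deterministic
total-mass solution N(t) = (P/k)(1 − e^{−kt}), giving t = −ln(1−f)/k:
0.89 hr to 80% and 1.66 hr to 95% at k = 5×10⁻⁴ s⁻¹. A
simulation-based readout (first crossing of f × last-decile mean) is
also provided. Timing estimates of this kind depend on the chosen
readout — total mass versus concentration at a particular position —
and different choices shift the 80% time by tens of percent (a
probe-based readout can report ~0.7 hr where the total-mass form gives
0.89 hr); the closed-form total-mass value is the package's reference
readout precisely because it is unambiguous.

# Image-based gradient profiling

`extract_binned_profile()` reads a rectangular ROI adjacent to the
source-clone boundary and averages windows of 5 × 36 pixels. The pixel
size is interpreted as a 1.4 μm pixel *edge*, under which the default
window is exactly 7 × 50.4 μm — the geometry the binning is designed
around. Distances are bin centres measured from the source boundary
(first centre at half a bin). Scalar background (estimated from
uninjected embryos) is subtracted with clipping at zero
(`subtract_background()`), the profile is normalized to the bin
closest to the source (`normalize_profile()`), and
`fit_profile()` fits C(x) = A·e^{−x/λ} + C with amplitude, length and
offset free, making λ invariant to intensity scaling and residual
uniform background. Cohorts are combined either by pooling all points
into one fit or by averaging per-embryo λ (`aggregate_profiles()`);
the two agree within ~10% on synthetic cohorts, and both are exposed.
Background is treated as a scalar per image, not a spatial map.

# Clearance kinetics

Band intensities from blot-style time courses are normalized against a
loading control (removing per-lane loading and recovery factors) and
then to the t = 0 sample (`normalize_series()`; idempotent), and fitted
with A·e^{−kt} (`fit_decay()`). The amplitude is left free rather than
pinned to 1 so that noise in the t = 0 lane is absorbed by A instead of
biasing k; an optional plateau term is available but off by default.
Interface times are in hours (converted internally to seconds).
Identifiability is honest: at sampling out to 24 h, rates near
1.7×10⁻⁵ s⁻¹ are recovered within ~20% at 5% noise, whereas rates
around 3×10⁻⁷ s⁻¹ decay only ~2.6% over the window and carry very wide
confidence intervals — the ranking of rates (`compare_decay_order()`)
is then the robust statement, not the individual slow-rate values.

# Synthetic data and what the tests show

Each generator is a pure function of (parameters, seed) and attaches
its `ground_truth()`:

- `synth_correlation_curve()` adds heteroscedastic Gaussian noise
  σ(τ) = noise·G(τ)·sqrt(τ_min/τ) — larger at short lags, where a real
  correlator has averaged fewer fluctuations.
- `brownian_photon_oracle()` is a physical oracle: particles diffuse in
  a periodic box around the Gaussian detection volume, the summed
  intensity I(t) = Σ exp(−2r²/ω₀² − 2z²/z₀²) is correlated directly,
  and fitting the result with the analytic model recovers the input D
  within 20% — evidence that model and simulation describe the same
  physics, with neither derived from the other.
- `synth_fccs_dataset()` draws per-embryo totals, solves the exact
  equilibrium, and applies multiplicative log-normal noise.
- `synth_gradient_image()` renders A·e^{−x/λ} + background with
  Gaussian noise (SNR = 1/noise level) on a 512 × 512, 1.4 μm/px frame.
- `synth_decay_series()` emulates per-lane loading factors so that
  control normalization has real work to do.

Noise forms are the simplest consistent with each data type (no
published noise characterization exists to emulate). What passing
recovery tests establish is that the estimators are unbiased and
correctly calibrated *under these noise models*; real measurements add
effects deliberately out of scope — detector afterpulsing and spectral
cross-talk in FCS/FCCS, embryo curvature and segmentation error in
imaging, cell division and advection in the tissue, explicit
receptor-binding kinetics — so recovered tolerances here are lower
bounds on real-world uncertainty, not substitutes for controls.

# Reference study conditions

The defaults encode the early-gastrula conditions the package is
designed around: free D = 60 μm²/s; tortuosity-reduced D = 30 μm²/s;
receptor pool 40 μM; ligand ~100 nM; K_d 60/120 nM (receptor) and
29/50 nM (inhibitor) classes; clearance 10⁻⁴–5×10⁻⁴ s⁻¹ (plus blot
rates 0.003–0.166 ×10⁻⁴ s⁻¹); slab 2 × 44 × 86.7 μm with 10 μm cells
and 2 μm gaps; 1D extent 200 μm. Problem sizes in the test-suite were
chosen to probe these conditions at desk scale: slab runs use the full
1000 particles × 1000 steps; 1D equilibrium checks run 6000–8000 s at
accelerated clearance (10⁻³ s⁻¹) so the same physics equilibrates
quickly, while the flagship 0.7 s⁻¹ / 10⁻⁴ s⁻¹ / 60000 s condition is
run once in full.

# Known limitations

- Ideal-FCCS amplitude relations (no cross-talk/background correction).
- Quasi-equilibrium binding only; no explicit on/off rates or
  receptor depletion.
- Static cell geometry; no cell division or rearrangement.
- Scalar image background; no PSF or curvature modelling.
- Slow clearance rates (≲10⁻⁶ s⁻¹) are weakly identifiable from 24 h
  time courses; only their ordering is robust.
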