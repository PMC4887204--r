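# morphograd

Quantitative tools for studying how secreted morphogens form
concentration gradients in early embryos.

Morphogens such as the zebrafish Nodal ligands are produced at a
localized source, diffuse through a tissue packed with cells, bind
reversibly to cell-surface receptors and extracellular inhibitors, and
are cleared by degradation. The interplay of these processes sets the
decay length of the resulting concentration gradient and hence the
signaling range. `morphograd` implements the analysis chain a lab
working on this problem needs:

- **FCS/FCCS curve fitting** (`fit_correlation()`): Levenberg–Marquardt
  fits of the standard triplet-state diffusion models — one-component 3D

  G(τ) = (1/N) [1 + F·e^(−τ/τ_t)/(1−F)] (1+τ/τ_d)⁻¹ [1+(ω₀/z₀)² τ/τ_d]^(−1/2) + G∞,

  one-component 2D (membrane species), two-component 3D, and the
  cross-correlation model without triplet — yielding particle numbers,
  triplet parameters, diffusion times, and D = ω₀²/(4 τ_d).
- **Binding affinity** (`kd_by_regression()`, `kd_by_histogram()`,
  `concentrations_from_amplitudes()`): dissociation constants from FCCS
  concentration data via the mass-action relation C_g·C_r = K_d·C_gr
  (regression slope) and via a Gaussian fit to the ln K_d frequency
  histogram.
- **Binding equilibrium and transport theory** (`bound_fraction()`,
  `effective_diffusion()`, `gradient_length()`,
  `receptor_from_gradient()`): the quadratic mass-action bound fraction
  f_bound(K_d, L_t, R_t), effective diffusion D_eff = D·f_free, and the
  source–sink gradient length λ = sqrt(D/k) / sqrt(R/K_d + 1).
- **Hindered-diffusion simulation** (`simulate_slab()`,
  `fit_gaussian_profile()`): a 3D slab random walk among cylindrical
  cells (tortuosity) with optional per-step binding, and recovery of
  D_eff by fitting the spread profile C(x,t) = A·exp(−x²/(4 D_eff t)).
- **Gradient formation** (`simulate_gradient_1d()`,
  `steady_state_oracle()`, `fit_exponential_gradient()`,
  `time_to_steady_fraction()`): a 1D particle simulation with
  continuous production and first-order degradation, its closed-form
  reaction–diffusion steady state, and exponential decay-length fits
  C(x) = A·exp(−x/λ) + C.
- **Image profiling** (`extract_binned_profile()`, `fit_profile()`,
  `aggregate_profiles()`): intensity-vs-distance profiles from embryo
  images by ROI binning, background subtraction and source-boundary
  normalization.
- **Clearance kinetics** (`normalize_series()`, `fit_decay()`,
  `compare_decay_order()`): loading-control-normalized exponential
  decay fits of protein time courses.
- **Synthetic data** (`synth_correlation_curve()`,
  `brownian_photon_oracle()`, `synth_fccs_dataset()`,
  `synth_gradient_image()`, `synth_decay_series()`): generators with
  known ground truth for every pipeline stage, including an
  independent photon-trace simulation that produces correlation curves
  without ever touching the model equations.

## Worked example

```r
library(morphograd)

# Binding equilibrium at the measured affinities (nM), 40 uM receptor pool
round(100 * c(Sqt = bound_fraction(kd = 60,  l_total = 100, r_total = 40000),
              Cyc = bound_fraction(kd = 120, l_total = 100, r_total = 40000)), 2)
#>   Sqt   Cyc
#> 99.85 99.70

# Gradient lengths implied by source-sink transport theory (um)
c(Sqt = gradient_length(60, 1e-4, 40000, 60),
  Cyc = gradient_length(60, 5e-4, 40000, 120))
#>      Sqt      Cyc
#> 29.97753 18.94527

# Hindered diffusion: 1000 particles, 5 s among 10-um cells with 2-um gaps
free <- slab_deff(slab_config(obstacles_on = FALSE), seeds = 1:5)
obst <- slab_deff(slab_config(), seeds = 1:5)
round(c(free = free$d_eff, obstacles = obst$d_eff,
        reduction = mean(free$per_seed / obst$per_seed)), 2)
#>      free obstacles reduction
#>     61.42     32.93      1.87

# Recover a diffusion coefficient from a noisy synthetic FCS curve
vol <- observation_volume(omega0 = 0.25, z0 = 1.25)
curve <- synth_correlation_curve(d_true = 60, n_true = 10,
                                 noise_level = 0.02, seed = 11, volume = vol)
fit_correlation(curve, "3d1c", vol)
#> Correlation fit (3d1c), residual norm 173.1
#>   n_particles       9.99952  (se 0.00159)
#>   f_trip           0.145799  (se 0.00535)
#>   tau_trip      4.85886e-06  (se 2.34e-07)
#>   tau_d         0.000260409  (se 2.83e-08)
#>   g_inf         2.34515e-11  (se 3.46e-11)
#>   D [um^2/s]: 60
```

Almost all (99.85%, 99.7%) of a 100 nM ligand pool is receptor-bound at
these affinities, which is what slows an intrinsically fast diffuser
(60 μm²/s) down to effective coefficients below 0.1 μm²/s; combined
with the degradation rates this yields gradient lengths of ~30 μm
(slowly cleared ligand) versus ~19 μm (rapidly cleared ligand). Cell
obstacles alone account for only a factor ~1.9 ≤ 2 (tortuosity). The
FCS fit recovers the generator's ground truth (N = 10, D = 60 μm²/s,
triplet fraction 0.15) with calibrated standard errors.

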