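# Synthetic-data generators.
#
# Every analysis stage has a generator producing inputs from known ground
# truth, so the full pipeline can be exercised and validated without any
# measured data.  All generators are pure functions of (parameters, seed):
# the same call yields bit-identical output, and each result carries its
# ground truth in the "ground_truth" attribute for recovery tests.

truth_attr <- function(x, truth) {
  attr(x, "ground_truth") <- truth
  x
}

#' Ground truth of a synthetic dataset
#'
#' @param x An object returned by a `synth_*` generator.
#' @return The generator's parameter list.
#' @export
ground_truth <- function(x) attr(x, "ground_truth")

#' Synthetic noisy correlation curve
#'
#' Evaluates a correlation model on a logarithmic lag grid and adds
#' heteroscedastic Gaussian noise with standard deviation
#' `noise_level * G(tau) * sqrt(min(lag)/lag)` - larger at short lags,
#' as in measured correlation curves where few fluctuations average out.
#'
#' @param d_true Diffusion coefficient(s) (\eqn{\mu m^2/s}), one per
#'   component; converted to diffusion times through `volume`.
#' @param n_true Mean particle number.
#' @param model_kind One of `"3d1c"`, `"2d1c"`, `"3d2c"`, `"ccf"`.
#' @param volume An [observation_volume()].
#' @param noise_level Relative noise amplitude (0 = exact model curve).
#' @param seed RNG seed.
#' @param lag_grid Lag times (s); default 200 log-spaced points in
#'   \[1e-6, 1\] s.
#' @param f_trip,tau_trip,frac,g_inf Remaining model parameters, as in
#'   [triplet_params()].
#' @return A [correlation_curve()] with `sigma` set to the noise standard
#'   deviations; ground truth in `ground_truth()`.
#' @examples
#' vol <- observation_volume()
#' curve <- synth_correlation_curve(60, 10, noise_level = 0.02, seed = 1,
#'                                  volume = vol)
#' fit_correlation(curve, "3d1c", vol)$diffusion_coeff
#' @export
synth_correlation_curve <- function(d_true, n_true,
                                    model_kind = c("3d1c", "2d1c", "3d2c",
                                                   "ccf"),
                                    volume = observation_volume(),
                                    noise_level = 0.02, seed = 1L,
                                    lag_grid = logspace(1e-6, 1, 200),
                                    f_trip = 0.15, tau_trip = 5e-6,
                                    frac = NULL, g_inf = 0) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(volume, "observation_volume"))
  if (model_kind == "ccf") f_trip <- 0
  tau_d <- tau_from_diffusion(d_true, volume)
  params <- triplet_params(n_particles = n_true, tau_d = tau_d,
                           f_trip = f_trip, tau_trip = tau_trip,
                           frac = frac,
                           structure_ratio = volume$structure_ratio,
                           g_inf = g_inf)
  g0 <- fcs_model_fun(model_kind)(params, lag_grid)
  sd_g <- noise_level * g0 * sqrt(min(lag_grid) / lag_grid)
  g <- if (noise_level > 0)
    with_seed(seed, g0 + stats::rnorm(length(g0), 0, sd_g)) else g0
  kind <- if (model_kind == "ccf") "cross" else "auto_green"
  curve <- correlation_curve(lag_grid, g,
                             sigma = if (noise_level > 0) sd_g,
                             channel_kind = kind)
  truth_attr(curve, list(d_true = d_true, n_true = n_true,
                         params = params, model_kind = model_kind,
                         noise_level = noise_level, seed = seed))
}

#' Brownian photon-trace correlation oracle
#'
#' Independent physical check of the correlation models: `n` particles
#' diffuse in a periodic box around a 3D Gaussian detection volume, the
#' detected intensity \eqn{I(t) = \sum_i \exp(-2 r_i^2/\omega_0^2 -
#' 2 z_i^2/z_0^2)} is recorded every `dt`, and its normalised fluctuation
#' autocorrelation is evaluated on a logarithmic lag grid.  Fitting the
#' returned curve with the one-component 3D model must recover the input
#' diffusion coefficient (the generator never sees the model equations).
#'
#' @param d Diffusion coefficient (\eqn{\mu m^2/s}).
#' @param n Particle count in the box (<= a few hundred; the effective
#'   particle number in the focal volume is `n * v_eff / box volume`).
#' @param volume An [observation_volume()].
#' @param duration Trace length (s).
#' @param dt Sampling interval (s); must be well below the diffusion time.
#' @param seed RNG seed.
#' @param box_xy,box_z Periodic box dimensions (\eqn{\mu m}); default 10
#'   lateral radii and 6 axial radii.
#' @param n_lags Number of log-spaced lags between `dt` and
#'   `duration / 20`.
#' @return A [correlation_curve()]; ground truth in `ground_truth()`.
#' @export
brownian_photon_oracle <- function(d, n = 50, volume = observation_volume(),
                                   duration = 5, dt = 2e-5, seed = 1L,
                                   box_xy = 10 * volume$omega0,
                                   box_z = 6 * volume$z0, n_lags = 60) {
  stopifnot(inherits(volume, "observation_volume"))
  check_scalar(d, "d", lower = 0)
  check_scalar(n, "n", lower = 1, upper = 500)
  check_scalar(duration, "duration", lower = dt)
  n_steps <- round(duration / dt)
  sd_step <- sqrt(2 * d * dt)
  with_seed(seed, {
    intensity <- numeric(n_steps)
    for (i in seq_len(n)) {
      # per-particle trajectory by cumulated steps, wrapped periodically
      # into the centred box
      x <- wrap_periodic(stats::runif(1, -box_xy / 2, box_xy / 2) +
                           cumsum(stats::rnorm(n_steps, 0, sd_step)),
                         -box_xy / 2, box_xy / 2)
      y <- wrap_periodic(stats::runif(1, -box_xy / 2, box_xy / 2) +
                           cumsum(stats::rnorm(n_steps, 0, sd_step)),
                         -box_xy / 2, box_xy / 2)
      z <- wrap_periodic(stats::runif(1, -box_z / 2, box_z / 2) +
                           cumsum(stats::rnorm(n_steps, 0, sd_step)),
                         -box_z / 2, box_z / 2)
      intensity <- intensity +
        exp(-2 * (x^2 + y^2) / volume$omega0^2 - 2 * z^2 / volume$z0^2)
    }
    lags <- unique(pmax(1L, round(logspace(1, duration / 20 / dt, n_lags))))
    mean_i <- mean(intensity)
    g <- vapply(lags, function(k) {
      m <- n_steps - k
      a <- intensity[1:m]
      b <- intensity[(k + 1):(k + m)]
      (mean(a * b) - mean(a) * mean(b)) / mean_i^2
    }, numeric(1))
    curve <- correlation_curve(lags * dt, g, channel_kind = "auto_green")
    truth_attr(curve, list(d_true = d, n_box = n,
                           n_eff = n * volume$v_eff / (box_xy^2 * box_z),
                           duration = duration, dt = dt, seed = seed))
  })
}

#' Synthetic FCCS binding dataset
#'
#' Draws per-embryo total ligand and receptor concentrations, solves the
#' exact mass-action equilibrium at `kd_true` for the free and complex
#' concentrations, and applies multiplicative log-normal noise.
#'
#' @param kd_true Dissociation constant (nM).
#' @param c_g_range,c_r_range Ranges (nM) for the total green-/red-labelled
#'   concentrations, sampled uniformly.
#' @param n_samples Number of embryos.
#' @param noise_level Log-normal sigma of the multiplicative noise
#'   (0 = exact equilibrium values).
#' @param seed RNG seed.
#' @return A data frame with columns `embryo_id`, `c_g`, `c_r`, `c_gr`
#'   (free green, free red, complex; nM); ground truth in
#'   `ground_truth()`.
#' @examples
#' d <- synth_fccs_dataset(65, n_samples = 20, noise_level = 0.1, seed = 2)
#' kd_by_regression(d)$kd_regression
#' @export
synth_fccs_dataset <- function(kd_true, c_g_range = c(20, 200),
                               c_r_range = c(20, 200), n_samples = 20,
                               noise_level = 0.1, seed = 1L) {
  check_scalar(kd_true, "kd_true", lower = 0, open_lower = TRUE)
  with_seed(seed, {
    g_tot <- stats::runif(n_samples, c_g_range[1], c_g_range[2])
    r_tot <- stats::runif(n_samples, c_r_range[1], c_r_range[2])
    # exact bimolecular equilibrium for the complex concentration
    s <- kd_true + g_tot + r_tot
    c_gr <- (s - sqrt(s^2 - 4 * g_tot * r_tot)) / 2
    c_g <- g_tot - c_gr
    c_r <- r_tot - c_gr
    if (noise_level > 0) {
      c_g <- c_g * exp(stats::rnorm(n_samples, 0, noise_level))
      c_r <- c_r * exp(stats::rnorm(n_samples, 0, noise_level))
      c_gr <- c_gr * exp(stats::rnorm(n_samples, 0, noise_level))
    }
    out <- data.frame(embryo_id = sprintf("sim%03d", seq_len(n_samples)),
                      c_g = c_g, c_r = c_r, c_gr = c_gr,
                      stringsAsFactors = FALSE)
    truth_attr(out, list(kd_true = kd_true, noise_level = noise_level,
                         seed = seed, g_tot = g_tot, r_tot = r_tot))
  })
}

#' Synthetic exponential-gradient embryo image
#'
#' Renders \eqn{I(x, y) = A e^{-x/\lambda} + b} (x measured from a known
#' source-boundary column) plus Gaussian noise of standard deviation
#' `noise_level * amplitude`, emulating autofluorescence background and
#' shot noise of a gradient image.
#'
#' @param lambda_true Gradient decay length (\eqn{\mu m}).
#' @param amplitude Peak intensity above background.
#' @param background Additive background level.
#' @param noise_level Noise standard deviation relative to `amplitude`
#'   (SNR = 1 / noise_level).
#' @param shape_px Image size, rows x columns (default 512 x 512).
#' @param pixel_size Pixel edge (\eqn{\mu m}, default 1.4).
#' @param source_boundary Source-clone edge column.
#' @param seed RNG seed.
#' @return An [embryo_image()] (`background_level` set to the true
#'   background); ground truth in `ground_truth()`.
#' @examples
#' img <- synth_gradient_image(29.5, noise_level = 0.02, seed = 3)
#' pr <- normalize_profile(subtract_background(
#'   extract_binned_profile(img), img$background_level))
#' fit_profile(pr)$lambda_
#' @export
synth_gradient_image <- function(lambda_true, amplitude = 1000,
                                 background = 50, noise_level = 0.05,
                                 shape_px = c(512, 512), pixel_size = 1.4,
                                 source_boundary = 1L, seed = 1L) {
  check_scalar(lambda_true, "lambda_true", lower = 0, open_lower = TRUE)
  check_scalar(amplitude, "amplitude", lower = 0)
  check_scalar(background, "background", lower = 0)
  nr <- shape_px[1]
  nc <- shape_px[2]
  x_um <- (seq_len(nc) - source_boundary) * pixel_size
  clean <- matrix(amplitude * exp(-pmax(x_um, 0) / lambda_true) + background,
                  nrow = nr, ncol = nc, byrow = TRUE)
  px <- if (noise_level > 0)
    with_seed(seed, pmax(clean + matrix(stats::rnorm(nr * nc, 0,
                                                     noise_level * amplitude),
                                        nr, nc), 0))
  else clean
  img <- embryo_image(px, pixel_size = pixel_size,
                      source_boundary = source_boundary,
                      background_level = background)
  truth_attr(img, list(lambda_true = lambda_true, amplitude = amplitude,
                       background = background, noise_level = noise_level,
                       seed = seed))
}

#' Synthetic protein decay time course
#'
#' Emulates an immunoblot time series with per-lane loading factors: the
#' band intensity is `loading_factor * exp(-k t) * (1 + noise)` and the
#' loading control is `loading_factor * (1 + noise)`, so that
#' control-normalisation removes the loading factors.
#'
#' @param k_true Decay rate (1/s, >= 0).
#' @param timepoints_hr Sampling times (hours, starting at 0).
#' @param loading_factors Per-lane factors; default log-normal draws
#'   (sigma 0.2).
#' @param noise_level Relative Gaussian noise on each band (0 = exact).
#' @param label Protein name carried through to fits.
#' @param seed RNG seed.
#' @return A [decay_series()]; ground truth in `ground_truth()`.
#' @examples
#' s <- synth_decay_series(0.166e-4, noise_level = 0, seed = 1)
#' fit_decay(s)$k_deg
#' @export
synth_decay_series <- function(k_true, timepoints_hr = c(0, 6, 12, 24),
                               loading_factors = NULL, noise_level = 0.05,
                               label = NA_character_, seed = 1L) {
  check_scalar(k_true, "k_true", lower = 0)
  n <- length(timepoints_hr)
  with_seed(seed, {
    lf <- loading_factors %||% exp(stats::rnorm(n, 0, 0.2))
    if (length(lf) != n)
      stop_invalid("'loading_factors' must match the time points")
    decay <- exp(-k_true * timepoints_hr * 3600)
    noise1 <- if (noise_level > 0) 1 + stats::rnorm(n, 0, noise_level) else 1
    noise2 <- if (noise_level > 0) 1 + stats::rnorm(n, 0, noise_level) else 1
    series <- decay_series(timepoints_hr, pmax(lf * decay * noise1, 1e-12),
                           pmax(lf * noise2, 1e-12), label = label,
                           time_unit = "hr")
    truth_attr(series, list(k_true = k_true, loading_factors = lf,
                            noise_level = noise_level, seed = seed))
  })
}
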