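# FCS/FCCS correlation models.
#
# Fluorescence correlation spectroscopy infers diffusion times and particle
# numbers from the autocorrelation G(tau) of intensity fluctuations in a 3D
# Gaussian confocal volume.  The models implemented here are the standard
# triplet-state diffusion models: one-component 3D, one-component 2D (for
# membrane-anchored species), two-component 3D (for ligand populations with
# free and hindered fractions), and a one-component cross-correlation model
# without a triplet term.

#' Confocal observation volume
#'
#' Describes the 3D Gaussian detection volume of a confocal FCS instrument
#' by its lateral \eqn{1/e^2} radius \eqn{\omega_0} and axial \eqn{1/e^2}
#' half-length \eqn{z_0}.  The effective volume is
#' \eqn{V_{eff} = \pi^{3/2}\omega_0^2 z_0}.
#'
#' @param omega0 Lateral \eqn{1/e^2} radius (micrometres, > 0).
#' @param z0 Axial \eqn{1/e^2} distance (micrometres, > 0).
#'
#' @return An object of class `"observation_volume"`: a list with elements
#'   `omega0`, `z0`, `structure_ratio` (\eqn{\omega_0/z_0}) and `v_eff`
#'   (\eqn{\mu m^3}).
#' @examples
#' vol <- observation_volume(0.25, 1.25)
#' vol$v_eff # pi^(3/2) * 0.25^2 * 1.25
#' @export
observation_volume <- function(omega0 = 0.25, z0 = 1.25) {
  check_scalar(omega0, "omega0", lower = 0, open_lower = TRUE)
  check_scalar(z0, "z0", lower = 0, open_lower = TRUE)
  if (omega0 > z0)
    stop_invalid("'omega0' must not exceed 'z0' (structure ratio in (0, 1])")
  structure(
    list(omega0 = omega0, z0 = z0,
         structure_ratio = omega0 / z0,
         v_eff = pi^1.5 * omega0^2 * z0),
    class = "observation_volume")
}

#' Triplet-state diffusion model parameters
#'
#' Parameter container for the correlation models: mean particle number in
#' the observation volume, triplet-state fraction and relaxation time,
#' diffusion time(s), component amplitudes, the structure ratio
#' \eqn{\omega_0/z_0} and the long-lag offset \eqn{G_\infty}.
#'
#' @param n_particles Mean particle number N (> 0).
#' @param tau_d Diffusion time(s) in seconds (one per component, each > 0).
#' @param f_trip Triplet fraction, in \[0, 1).
#' @param tau_trip Triplet relaxation time (s, > 0). Ignored when
#'   `f_trip = 0`.
#' @param frac Component amplitude fractions, same length as `tau_d`,
#'   summing to 1.
#' @param structure_ratio \eqn{\omega_0/z_0}, in (0, 1].
#' @param g_inf Long-lag offset \eqn{G_\infty}.
#'
#' @return An object of class `"triplet_params"`.
#' @examples
#' triplet_params(n_particles = 10, tau_d = 5e-4)
#' triplet_params(n_particles = 1, tau_d = c(1e-4, 1e-2), frac = c(0.3, 0.7))
#' @export
triplet_params <- function(n_particles, tau_d, f_trip = 0, tau_trip = 1e-5,
                           frac = NULL, structure_ratio = 0.2, g_inf = 0) {
  check_scalar(n_particles, "n_particles", lower = 0, open_lower = TRUE)
  check_scalar(f_trip, "f_trip", lower = 0, upper = 1, open_upper = TRUE)
  check_scalar(tau_trip, "tau_trip", lower = 0, open_lower = TRUE)
  check_scalar(structure_ratio, "structure_ratio", lower = 0, upper = 1,
               open_lower = TRUE)
  check_scalar(g_inf, "g_inf")
  if (!is.numeric(tau_d) || length(tau_d) < 1L || any(!is.finite(tau_d)) ||
      any(tau_d <= 0))
    stop_invalid("'tau_d' must be positive and finite")
  if (is.null(frac)) {
    if (length(tau_d) == 1L) frac <- 1
    else stop_invalid("'frac' is required for multi-component models")
  }
  if (length(frac) != length(tau_d))
    stop_invalid("'frac' and 'tau_d' must have the same length")
  if (any(!is.finite(frac)) || any(frac < 0))
    stop_invalid("'frac' must be non-negative and finite")
  if (abs(sum(frac) - 1) > 1e-9)
    stop_invalid("'frac' must sum to 1 (within 1e-9)")
  structure(
    list(n_particles = n_particles, f_trip = f_trip, tau_trip = tau_trip,
         tau_d = tau_d, frac = frac, structure_ratio = structure_ratio,
         g_inf = g_inf),
    class = "triplet_params")
}

check_lag <- function(lag) {
  if (!is.numeric(lag) || length(lag) < 1L || any(!is.finite(lag)) ||
      any(lag <= 0))
    stop_invalid("'lag' must be positive and finite")
  lag
}

# Photophysics prefactor 1 + F/(1-F) * exp(-tau/tau_trip).
triplet_factor <- function(f_trip, tau_trip, lag) {
  if (f_trip == 0) return(rep(1, length(lag)))
  1 + f_trip / (1 - f_trip) * exp(-lag / tau_trip)
}

#' One-component 3D autocorrelation model with triplet state
#'
#' The standard FCS model for a single species freely diffusing in 3D
#' through a Gaussian observation volume:
#' \deqn{G(\tau) = \frac{1}{N}\left[1 + \frac{F_{t}}{1-F_{t}}
#'   e^{-\tau/\tau_{t}}\right] \left(1+\frac{\tau}{\tau_d}\right)^{-1}
#'   \left[1+\left(\frac{\omega_0}{z_0}\right)^2
#'   \frac{\tau}{\tau_d}\right]^{-1/2} + G_\infty}
#'
#' @param params A [triplet_params()] object with exactly one diffusion
#'   component.
#' @param lag Lag time(s) in seconds (> 0).
#' @return Correlation amplitude(s), same length as `lag`.
#' @examples
#' p <- triplet_params(n_particles = 1, tau_d = 1, structure_ratio = 1)
#' acf_3d_1c_triplet(p, 1) # (1/2) / sqrt(2)
#' @export
acf_3d_1c_triplet <- function(params, lag) {
  stopifnot(inherits(params, "triplet_params"))
  if (length(params$tau_d) != 1L)
    stop_invalid("one-component model requires exactly one 'tau_d'")
  check_lag(lag)
  x <- lag / params$tau_d
  (1 / params$n_particles) *
    triplet_factor(params$f_trip, params$tau_trip, lag) *
    (1 + x)^-1 * (1 + params$structure_ratio^2 * x)^-0.5 +
    params$g_inf
}

#' One-component 2D autocorrelation model with triplet state
#'
#' FCS model for membrane-confined diffusion (no axial term):
#' \deqn{G(\tau) = \frac{1}{N}\left[1 + \frac{F_{t}}{1-F_{t}}
#'   e^{-\tau/\tau_{t}}\right]\left(1+\frac{\tau}{\tau_d}\right)^{-1}
#'   + G_\infty}
#'
#' @inheritParams acf_3d_1c_triplet
#' @return Correlation amplitude(s).
#' @examples
#' p <- triplet_params(n_particles = 1, tau_d = 1)
#' acf_2d_1c_triplet(p, 1) # 0.5
#' @export
acf_2d_1c_triplet <- function(params, lag) {
  stopifnot(inherits(params, "triplet_params"))
  if (length(params$tau_d) != 1L)
    stop_invalid("one-component model requires exactly one 'tau_d'")
  check_lag(lag)
  (1 / params$n_particles) *
    triplet_factor(params$f_trip, params$tau_trip, lag) *
    (1 + lag / params$tau_d)^-1 +
    params$g_inf
}

#' Two-component 3D autocorrelation model with triplet state
#'
#' Sum of two 3D diffusion terms with amplitudes `frac`, sharing one
#' particle number and triplet term:
#' \deqn{G(\tau) = \frac{1}{N}\left[1 + \frac{F_{t}}{1-F_{t}}
#'   e^{-\tau/\tau_{t}}\right]\sum_i F_i
#'   \left(1+\frac{\tau}{\tau_{di}}\right)^{-1}
#'   \left[1+\left(\frac{\omega_0}{z_0}\right)^2
#'   \frac{\tau}{\tau_{di}}\right]^{-1/2} + G_\infty}
#'
#' @param params A [triplet_params()] object with two diffusion components
#'   (amplitudes summing to 1).
#' @inheritParams acf_3d_1c_triplet
#' @return Correlation amplitude(s).
#' @export
acf_3d_2c_triplet <- function(params, lag) {
  stopifnot(inherits(params, "triplet_params"))
  if (length(params$tau_d) != 2L)
    stop_invalid("two-component model requires exactly two 'tau_d' values")
  check_lag(lag)
  k2 <- params$structure_ratio^2
  comp <- rep(0, length(lag))
  for (i in seq_along(params$tau_d)) {
    x <- lag / params$tau_d[i]
    comp <- comp + params$frac[i] * (1 + x)^-1 * (1 + k2 * x)^-0.5
  }
  (1 / params$n_particles) *
    triplet_factor(params$f_trip, params$tau_trip, lag) * comp +
    params$g_inf
}

#' Cross-correlation model (one component, no triplet)
#'
#' The cross-correlation of two detection channels decays with the
#' diffusion of the double-labelled complex only; photophysics is
#' uncorrelated between channels, so there is no triplet term:
#' \deqn{G_x(\tau) = \frac{1}{N}\left(1+\frac{\tau}{\tau_d}\right)^{-1}
#'   + G_\infty}
#'
#' @inheritParams acf_3d_1c_triplet
#' @return Correlation amplitude(s).
#' @examples
#' p <- triplet_params(n_particles = 1, tau_d = 1)
#' ccf_model(p, 3) # 0.25
#' @export
ccf_model <- function(params, lag) {
  stopifnot(inherits(params, "triplet_params"))
  if (length(params$tau_d) != 1L)
    stop_invalid("one-component model requires exactly one 'tau_d'")
  if (params$f_trip != 0)
    stop_invalid("the cross-correlation model has no triplet term; set f_trip = 0")
  check_lag(lag)
  (1 / params$n_particles) * (1 + lag / params$tau_d)^-1 + params$g_inf
}

# Dispatch a model kind to its evaluator.
fcs_model_fun <- function(model_kind) {
  switch(model_kind,
         "3d1c" = acf_3d_1c_triplet,
         "2d1c" = acf_2d_1c_triplet,
         "3d2c" = acf_3d_2c_triplet,
         "ccf"  = ccf_model,
         stop_invalid("unknown model kind '", model_kind, "'"))
}

#' Diffusion coefficient from diffusion time
#'
#' Standard FCS relation \eqn{D = \omega_0^2 / (4\tau_d)} for a calibrated
#' observation volume.
#'
#' @param tau_d Diffusion time (s, > 0); vectorised.
#' @param volume An [observation_volume()].
#' @return Diffusion coefficient(s) in \eqn{\mu m^2/s}.
#' @examples
#' diffusion_from_tau(1e-3, observation_volume(0.2, 1)) # 10
#' @export
diffusion_from_tau <- function(tau_d, volume) {
  stopifnot(inherits(volume, "observation_volume"))
  if (any(!is.finite(tau_d)) || any(tau_d <= 0))
    stop_invalid("'tau_d' must be positive and finite")
  volume$omega0^2 / (4 * tau_d)
}

#' Diffusion time from diffusion coefficient
#'
#' Inverse of [diffusion_from_tau()]: \eqn{\tau_d = \omega_0^2 / (4D)}.
#'
#' @param d Diffusion coefficient (\eqn{\mu m^2/s}, > 0); vectorised.
#' @param volume An [observation_volume()].
#' @return Diffusion time(s) in seconds.
#' @export
tau_from_diffusion <- function(d, volume) {
  stopifnot(inherits(volume, "observation_volume"))
  if (any(!is.finite(d)) || any(d <= 0))
    stop_invalid("'d' must be positive and finite")
  volume$omega0^2 / (4 * d)
}
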