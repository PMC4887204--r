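# 1D gradient-formation simulation with production and degradation.
#
# Particles are injected at the source boundary as a Poisson process,
# perform 1D Brownian steps with the effective diffusion coefficient, and
# are removed by first-order degradation.  At steady state the mean
# particle number is production_rate / k_deg and the concentration profile
# decays exponentially with length sqrt(D_eff / k_deg).

#' 1D gradient simulation configuration
#'
#' @param extent Domain length (\eqn{\mu m}); source at x = 0, reflecting
#'   boundaries at both ends.
#' @param d_eff Effective diffusion coefficient (\eqn{\mu m^2/s}).
#' @param k_deg First-order degradation rate (1/s).
#' @param production_rate Particles created per second at the source (1/s).
#' @param dt Time step (s); must keep the per-step RMS displacement
#'   \eqn{\sqrt{2 D \Delta t}} below 2 \eqn{\mu m}.
#' @param duration Total simulated time (s); default 60000 s (16 hr 40
#'   min) so slow gradients reach equilibrium.
#' @param seed RNG seed.
#' @return An object of class `"gradient_config"`.
#' @export
gradient_config <- function(extent = 200, d_eff, k_deg, production_rate,
                            dt = 1, duration = 60000, seed = 1L) {
  check_scalar(extent, "extent", lower = 0, open_lower = TRUE)
  check_scalar(d_eff, "d_eff", lower = 0, open_lower = TRUE)
  check_scalar(k_deg, "k_deg", lower = 0, open_lower = TRUE)
  check_scalar(production_rate, "production_rate", lower = 0,
               open_lower = TRUE)
  check_scalar(dt, "dt", lower = 0, open_lower = TRUE)
  check_scalar(duration, "duration", lower = dt)
  if (sqrt(2 * d_eff * dt) >= 2)
    stop_invalid("'dt' too coarse: per-step RMS displacement must stay ",
                 "below 2 um")
  structure(list(extent = extent, d_eff = d_eff, k_deg = k_deg,
                 production_rate = production_rate, dt = dt,
                 duration = duration, seed = as.integer(seed)),
            class = "gradient_config")
}

#' Simulate 1D gradient formation
#'
#' Per step: new particles are injected at x = 0 (Poisson with mean
#' `production_rate * dt`), every particle takes a Gaussian step of
#' variance \eqn{2 D_{eff} \Delta t} folded back at the reflecting
#' boundaries, and each survives with probability
#' \eqn{e^{-k \Delta t}}.
#'
#' @param config A [gradient_config()].
#' @param record_times Times (s) at which to record binned profiles;
#'   default the final time.  Rounded to whole steps.
#' @param bin_width Profile bin width (\eqn{\mu m}), default 2.
#' @return An object of class `"gradient_sim"`: list with `profiles`
#'   (list of [concentration_profile()] at `record_times`), `n_t`
#'   (particle count after every step), `times` (step times), `final_x`,
#'   `config`.
#' @examples
#' cfg <- gradient_config(d_eff = 2, k_deg = 0.01, production_rate = 2,
#'                        dt = 0.5, duration = 500, seed = 1)
#' sim <- simulate_gradient_1d(cfg)
#' mean(utils::tail(sim$n_t, 100)) # ~ production / k = 200
#' @export
simulate_gradient_1d <- function(config, record_times = NULL,
                                 bin_width = 2) {
  stopifnot(inherits(config, "gradient_config"))
  n_steps <- round(config$duration / config$dt)
  record_times <- record_times %||% (n_steps * config$dt)
  record_steps <- pmin(pmax(round(record_times / config$dt), 1L), n_steps)
  sd_step <- sqrt(2 * config$d_eff * config$dt)
  p_surv <- exp(-config$k_deg * config$dt)
  lambda_inj <- config$production_rate * config$dt
  with_seed(config$seed, {
    x <- numeric(0)
    n_t <- integer(n_steps)
    profiles <- vector("list", length(record_steps))
    for (s in seq_len(n_steps)) {
      # inject at the source, then move, then degrade
      n_new <- stats::rpois(1, lambda_inj)
      if (n_new > 0) x <- c(x, numeric(n_new))
      if (length(x)) {
        x <- fold_reflect(x + stats::rnorm(length(x), 0, sd_step),
                          0, config$extent)
        x <- x[stats::runif(length(x)) < p_surv]
      }
      n_t[s] <- length(x)
      hit <- which(record_steps == s)
      for (j in hit)
        profiles[[j]] <- if (length(x))
          concentration_profile(x, t = s * config$dt,
                                length_x = config$extent,
                                bin_width = bin_width)
        else NULL
    }
    structure(list(profiles = profiles, n_t = n_t,
                   times = seq_len(n_steps) * config$dt,
                   record_times = record_steps * config$dt,
                   final_x = x, config = config),
              class = "gradient_sim")
  })
}

#' Time-averaged steady-state profile of a gradient simulation
#'
#' Averages binned profiles over the last `window_frac` fraction of the
#' recorded times (all recorded profiles whose time exceeds
#' `(1 - window_frac) * duration`), reducing Poisson noise before fitting.
#'
#' @param sim A `"gradient_sim"` with several recorded profiles.
#' @param window_frac Fraction of the run to average over (default 0.1).
#' @return A [concentration_profile()] (counts averaged, density
#'   re-normalised), or the single final profile if none fall in the
#'   window.
#' @export
steady_profile <- function(sim, window_frac = 0.1) {
  stopifnot(inherits(sim, "gradient_sim"))
  keep <- which(sim$record_times >=
                  (1 - window_frac) * sim$config$duration &
                  !vapply(sim$profiles, is.null, logical(1)))
  if (!length(keep))
    stop_invalid("no recorded profiles in the steady-state window")
  counts <- Reduce(`+`, lapply(sim$profiles[keep], `[[`, "counts")) /
    length(keep)
  ref <- sim$profiles[[keep[length(keep)]]]
  structure(list(x_centers = ref$x_centers, counts = counts,
                 density = counts / max(counts), t = ref$t),
            class = "concentration_profile")
}

#' Closed-form steady-state profile of the reaction-diffusion system
#'
#' Steady state of \eqn{\partial C/\partial t = D \partial^2 C/\partial x^2
#' - k C} with source flux at x = 0 and a reflecting boundary at
#' `extent`:
#' \deqn{C(x) \propto \cosh((L - x)/\lambda) / \cosh(L/\lambda), \quad
#'   \lambda = \sqrt{D/k}}
#' which reduces to \eqn{e^{-x/\lambda}} as \eqn{L \to \infty}.  The
#' returned profile is normalised to 1 at x = 0.
#'
#' @param d_eff Effective diffusion coefficient (\eqn{\mu m^2/s}).
#' @param k_deg Degradation rate (1/s).
#' @param extent Domain length (\eqn{\mu m}).
#' @param x Positions at which to evaluate; default 1-um bin centres.
#' @return An object of class `"concentration_profile"` with an extra
#'   element `lambda` (\eqn{\sqrt{D/k}}, \eqn{\mu m}).
#' @examples
#' steady_state_oracle(0.09, 1e-4, 200)$lambda # 30
#' @export
steady_state_oracle <- function(d_eff, k_deg, extent = 200, x = NULL) {
  check_scalar(d_eff, "d_eff", lower = 0, open_lower = TRUE)
  check_scalar(k_deg, "k_deg", lower = 0, open_lower = TRUE)
  check_scalar(extent, "extent", lower = 0, open_lower = TRUE)
  lam <- sqrt(d_eff / k_deg)
  x <- x %||% seq(0.5, extent - 0.5, by = 1)
  # cosh ratio computed via exponentials to stay finite for extent >> lambda
  num <- exp(-x / lam) * (1 + exp(-2 * (extent - x) / lam))
  den <- 1 + exp(-2 * extent / lam)
  structure(list(x_centers = x, counts = num / den, density = num / den,
                 t = Inf, lambda = lam),
            class = "concentration_profile")
}

#' Fit an exponential to a concentration gradient
#'
#' Least-squares fit of either the plain exponential
#' \eqn{C(x) = \exp(-x/\lambda)} (for normalised profiles) or the
#' offset form \eqn{C(x) = A\exp(-x/\lambda) + C} when
#' `with_offset = TRUE`.
#'
#' @param profile A `"concentration_profile"` or an
#'   `"intensity_profile"`; needs at least 5 bins with positive density.
#' @param with_offset Fit amplitude and offset too?
#' @return An object of class `"gradient_fit"`: list with `amplitude`,
#'   `lambda_`, `offset`, `residual_norm`, `converged`.
#' @examples
#' x <- seq(1, 199, by = 2)
#' pr <- structure(list(x_centers = x, density = exp(-x / 19), t = Inf),
#'                 class = "concentration_profile")
#' fit_exponential_gradient(pr)$lambda_
#' @export
fit_exponential_gradient <- function(profile, with_offset = FALSE) {
  x <- profile$x_centers %||% profile$distance
  y <- profile$density %||% profile$intensity
  if (is.null(x) || is.null(y))
    stop_invalid("'profile' must carry positions and densities")
  if (sum(y > 0) < 5L)
    stop_invalid("need at least 5 bins with positive density")
  # log-linear start over the informative range
  pos <- y > max(y) * 1e-6
  lam0 <- tryCatch({
    cf <- unname(stats::coef(stats::lm(log(y[pos]) ~ x[pos])))
    if (is.finite(cf[2]) && cf[2] < 0) -1 / cf[2] else diff(range(x)) / 3
  }, error = function(e) diff(range(x)) / 3)
  fail <- structure(list(amplitude = NA_real_, lambda_ = NA_real_,
                         offset = NA_real_, residual_norm = NA_real_,
                         converged = FALSE),
                    class = "gradient_fit")
  if (with_offset) {
    start <- c(a = max(y), lambda = lam0, c0 = min(y))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start,
                         lower = c(a = 0, lambda = 1e-9, c0 = -Inf),
                         fn = function(p)
                           p[["a"]] * exp(-x / p[["lambda"]]) + p[["c0"]] - y,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit) || !(fit$info %in% 1:4)) return(fail)
    structure(list(amplitude = unname(fit$par[["a"]]),
                   lambda_ = unname(fit$par[["lambda"]]),
                   offset = unname(fit$par[["c0"]]),
                   residual_norm = fit$deviance, converged = TRUE),
              class = "gradient_fit")
  } else {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(lambda = lam0), lower = c(lambda = 1e-9),
                         fn = function(p) exp(-x / p[["lambda"]]) - y,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit) || !(fit$info %in% 1:4)) return(fail)
    structure(list(amplitude = 1,
                   lambda_ = unname(fit$par[["lambda"]]),
                   offset = 0, residual_norm = fit$deviance,
                   converged = TRUE),
              class = "gradient_fit")
  }
}

#' @export
print.gradient_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Gradient fit: NOT converged\n")
    return(invisible(x))
  }
  cat(sprintf("Gradient fit: lambda = %.4g um (A = %.4g, offset = %.4g)\n",
              x$lambda_, x$amplitude, x$offset))
  invisible(x)
}

#' Time to reach a fraction of steady state
#'
#' For pure production-degradation kinetics the total particle number
#' approaches its plateau as \eqn{N(t) = (P/k)(1 - e^{-kt})}, so the time
#' to reach fraction f of steady state is \eqn{t = -\ln(1-f)/k}
#' (`method = "analytic"`, deterministic).  With `method = "simulation"`
#' the particle simulation is run and the first time the (single-run)
#' particle count reaches f times its last-decile mean is reported.
#'
#' @param config A [gradient_config()].
#' @param fraction Target fraction of steady state, in (0, 1).
#' @param method `"analytic"` or `"simulation"`.
#' @return Time in seconds, or `NA` with a warning when the fraction is
#'   not reached within `duration` (simulation method).
#' @examples
#' cfg <- gradient_config(d_eff = 0.09, k_deg = 5e-4, production_rate = 0.7)
#' time_to_steady_fraction(cfg, 0.8) / 3600 # ~0.89 hr
#' @export
time_to_steady_fraction <- function(config, fraction,
                                    method = c("analytic", "simulation")) {
  stopifnot(inherits(config, "gradient_config"))
  check_scalar(fraction, "fraction", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  method <- match.arg(method)
  if (method == "analytic")
    return(-log(1 - fraction) / config$k_deg)
  sim <- simulate_gradient_1d(config)
  steady <- mean(utils::tail(sim$n_t, max(1L, length(sim$n_t) %/% 10)))
  hit <- which(sim$n_t >= fraction * steady)
  if (!length(hit)) {
    warning("steady-state fraction not reached within the simulated time")
    return(NA_real_)
  }
  sim$times[hit[1]]
}
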