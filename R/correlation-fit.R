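# Correlation curves and Levenberg-Marquardt model fitting.

#' Correlation curve
#'
#' A measured (or synthetic) correlation function: lag times, correlation
#' amplitudes, optional per-point standard errors, and the channel kind.
#'
#' @param lag Lag times (s), strictly increasing and positive.
#' @param g Correlation amplitudes, same length as `lag`.
#' @param sigma Optional per-point standard errors (> 0).
#' @param channel_kind One of `"auto_green"`, `"auto_red"`, `"cross"`.
#' @return An object of class `"correlation_curve"`.
#' @export
correlation_curve <- function(lag, g, sigma = NULL,
                              channel_kind = c("auto_green", "auto_red",
                                               "cross")) {
  channel_kind <- match.arg(channel_kind)
  if (!is.numeric(lag) || !is.numeric(g) || length(lag) != length(g))
    stop_invalid("'lag' and 'g' must be numeric vectors of the same length")
  if (any(!is.finite(lag)) || any(lag <= 0) || any(diff(lag) <= 0))
    stop_invalid("'lag' must be strictly increasing and positive")
  if (any(!is.finite(g)))
    stop_invalid("'g' must be finite")
  if (!is.null(sigma)) {
    if (length(sigma) != length(lag) || any(!is.finite(sigma)) ||
        any(sigma <= 0))
      stop_invalid("'sigma' must be positive, finite, and match 'lag'")
  }
  structure(list(lag = lag, g = g, sigma = sigma,
                 channel_kind = channel_kind),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat("Correlation curve (", x$channel_kind, "): ", length(x$lag),
      " lags in [", format(min(x$lag)), ", ", format(max(x$lag)), "] s\n",
      sep = "")
  invisible(x)
}

#' Read or write a correlation curve as CSV
#'
#' The CSV layout has columns `lag_s`, `g`, optionally `sigma`, and
#' optionally `channel_kind` (constant; defaults to `"auto_green"`).
#'
#' @param path File path.
#' @return `read_correlation_csv()` returns a [correlation_curve()];
#'   `write_correlation_csv()` returns `path` invisibly.
#' @export
read_correlation_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("lag_s", "g") %in% names(df)))
    stop_invalid("correlation CSV needs columns 'lag_s' and 'g'")
  kind <- if ("channel_kind" %in% names(df)) df$channel_kind[1] else "auto_green"
  correlation_curve(df$lag_s, df$g,
                    sigma = if ("sigma" %in% names(df)) df$sigma else NULL,
                    channel_kind = kind)
}

#' @rdname read_correlation_csv
#' @param curve A [correlation_curve()].
#' @export
write_correlation_csv <- function(curve, path) {
  stopifnot(inherits(curve, "correlation_curve"))
  df <- data.frame(lag_s = curve$lag, g = curve$g)
  if (!is.null(curve$sigma)) df$sigma <- curve$sigma
  df$channel_kind <- curve$channel_kind
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Free parameter names per model kind (structure_ratio is fixed by the
# calibrated observation volume, as is standard FCS practice).
fit_par_names <- function(model_kind, fit_triplet) {
  base <- switch(model_kind,
    "3d1c" = c("n_particles", "f_trip", "tau_trip", "tau_d", "g_inf"),
    "2d1c" = c("n_particles", "f_trip", "tau_trip", "tau_d", "g_inf"),
    "3d2c" = c("n_particles", "f_trip", "tau_trip", "tau_d1", "tau_d2",
               "frac1", "g_inf"),
    "ccf"  = c("n_particles", "tau_d", "g_inf"),
    stop_invalid("unknown model kind '", model_kind, "'"))
  if (!fit_triplet) base <- setdiff(base, c("f_trip", "tau_trip"))
  base
}

# Assemble a triplet_params object from a named parameter vector
# (fit parameterization) plus fixed values.
par_vec_to_params <- function(p, model_kind, structure_ratio) {
  g <- function(nm, default = 0) if (nm %in% names(p)) unname(p[[nm]]) else default
  if (model_kind == "3d2c") {
    frac1 <- g("frac1", 0.5)
    triplet_params(n_particles = g("n_particles", 1),
                   tau_d = c(g("tau_d1", 1e-4), g("tau_d2", 1e-2)),
                   frac = c(frac1, 1 - frac1),
                   f_trip = g("f_trip", 0), tau_trip = g("tau_trip", 1e-5),
                   structure_ratio = structure_ratio, g_inf = g("g_inf", 0))
  } else {
    triplet_params(n_particles = g("n_particles", 1),
                   tau_d = g("tau_d", 1e-3),
                   f_trip = g("f_trip", 0), tau_trip = g("tau_trip", 1e-5),
                   structure_ratio = structure_ratio, g_inf = g("g_inf", 0))
  }
}

# Heuristic initial values from the data.
default_init <- function(curve, model_kind) {
  g0 <- max(curve$g[seq_len(max(1L, length(curve$g) %/% 20))])
  g_tail <- mean(utils::tail(curve$g, max(3L, length(curve$g) %/% 20)))
  amp <- max(g0 - g_tail, .Machine$double.eps)
  # lag at which the curve has decayed to half its amplitude
  half <- g_tail + amp / 2
  idx <- which(curve$g <= half)
  tau_half <- if (length(idx)) curve$lag[idx[1]] else stats::median(curve$lag)
  init <- c(n_particles = 1 / amp, tau_d = tau_half, g_inf = 0)
  if (model_kind %in% c("3d1c", "2d1c"))
    init <- c(init, f_trip = 0.05, tau_trip = 5e-6)
  if (model_kind == "3d2c")
    init <- c(n_particles = 1 / amp, f_trip = 0.05, tau_trip = 5e-6,
              tau_d1 = tau_half / 10, tau_d2 = tau_half * 10,
              frac1 = 0.5, g_inf = 0)
  init
}

default_bounds <- function(par_names) {
  lower <- c(n_particles = 1e-6, f_trip = 0, tau_trip = 1e-7,
             tau_d = 1e-9, tau_d1 = 1e-9, tau_d2 = 1e-9,
             frac1 = 0, g_inf = -1)
  upper <- c(n_particles = 1e9, f_trip = 0.5, tau_trip = 1e-4,
             tau_d = 1e3, tau_d1 = 1e3, tau_d2 = 1e3,
             frac1 = 1, g_inf = 1)
  list(lower = lower[par_names], upper = upper[par_names])
}

#' Fit a correlation model to a measured curve
#'
#' Weighted nonlinear least squares via the Levenberg-Marquardt algorithm
#' ([minpack.lm::nls.lm()]).  A small deterministic multi-start schedule
#' (data-driven start plus jittered diffusion/triplet starts) guards
#' against triplet/diffusion term exchange; the best solution by residual
#' norm is kept, and further jittered restarts run only if nothing
#' converged.  When the curve carries per-point standard errors the fit
#' is solved in two stages - unweighted first, then `1/sigma`-weighted
#' refinement from the unweighted optimum - because correlation-curve
#' errors span many decades across the lag axis and a cold-started
#' weighted fit can strand in a local minimum.  Without `sigma` the
#' unweighted solution is returned directly.
#'
#' @param curve A [correlation_curve()].
#' @param model_kind One of `"3d1c"`, `"2d1c"`, `"3d2c"`, `"ccf"`.
#' @param volume An [observation_volume()]; fixes the structure ratio and
#'   converts diffusion times to diffusion coefficients.
#' @param init Optional named numeric vector of initial values (any of
#'   `n_particles`, `tau_d` (or `tau_d1`/`tau_d2`, `frac1`), `f_trip`,
#'   `tau_trip`, `g_inf`); the rest are data-driven defaults.
#' @param lower,upper Optional named bound overrides (same names as `init`).
#' @param fixed Optional named list of parameters held fixed at the given
#'   values (e.g. `list(f_trip = 0)` for a species without triplet blinking).
#' @param fit_triplet Fit the triplet term? Ignored (always `FALSE`) for
#'   `"ccf"`.
#' @param n_restarts Maximum number of jittered restarts after a
#'   non-converged first fit.
#'
#' @return An object of class `"correlation_fit"`: list with `params`
#'   (a [triplet_params()], two-component fits sorted by ascending
#'   `tau_d`), `diffusion_coeff` (\eqn{\mu m^2/s}, one per component),
#'   `estimate` (named parameter vector), `param_errors` (standard errors
#'   from the fit covariance), `residual_norm` (sum of squared weighted
#'   residuals), `converged`, `model_kind`.  Fit failure is reported via
#'   `converged = FALSE`, not an error.
#' @examples
#' vol <- observation_volume()
#' p <- triplet_params(n_particles = 10, tau_d = 5e-4,
#'                     structure_ratio = vol$structure_ratio)
#' lag <- exp(seq(log(1e-6), log(1), length.out = 150))
#' curve <- correlation_curve(lag, acf_3d_1c_triplet(p, lag))
#' fit <- fit_correlation(curve, "3d1c", vol, fixed = list(f_trip = 0))
#' fit$estimate[["tau_d"]]
#' @export
fit_correlation <- function(curve, model_kind = c("3d1c", "2d1c", "3d2c",
                                                  "ccf"),
                            volume = observation_volume(),
                            init = NULL, lower = NULL, upper = NULL,
                            fixed = NULL, fit_triplet = TRUE,
                            n_restarts = 5L) {
  stopifnot(inherits(curve, "correlation_curve"),
            inherits(volume, "observation_volume"))
  model_kind <- match.arg(model_kind)
  if (model_kind == "ccf") fit_triplet <- FALSE
  model_fn <- fcs_model_fun(model_kind)

  fail <- function(msg) {
    structure(list(params = NULL, diffusion_coeff = NA_real_,
                   estimate = NULL, param_errors = NULL,
                   residual_norm = NA_real_, converged = FALSE,
                   model_kind = model_kind, message = msg),
              class = "correlation_fit")
  }
  if (stats::sd(curve$g) == 0) return(fail("degenerate curve: constant g"))

  par_names <- fit_par_names(model_kind, fit_triplet)
  fixed <- as.list(fixed)
  if ("f_trip" %in% names(fixed) && fixed$f_trip == 0)
    fixed$tau_trip <- fixed$tau_trip %||% 1e-5
  free_names <- setdiff(par_names, names(fixed))

  start <- default_init(curve, model_kind)
  if (!is.null(init)) start[names(init)] <- init
  bounds <- default_bounds(free_names)
  if (!is.null(lower)) bounds$lower[intersect(names(lower), free_names)] <-
      lower[intersect(names(lower), free_names)]
  if (!is.null(upper)) bounds$upper[intersect(names(upper), free_names)] <-
      upper[intersect(names(upper), free_names)]
  start <- pmin(pmax(start[free_names], bounds$lower), bounds$upper)

  w_unit <- rep(1, length(curve$g))
  w_sig <- if (!is.null(curve$sigma)) 1 / curve$sigma else w_unit
  resid_fn <- function(p, w) {
    pv <- c(as.list(p), fixed)
    params <- tryCatch(
      par_vec_to_params(pv, model_kind, volume$structure_ratio),
      error = function(e) NULL)
    if (is.null(params)) return(rep(1e6, length(curve$g)))
    w * (model_fn(params, curve$lag) - curve$g)
  }

  run_lm <- function(p0, w) {
    tryCatch(
      minpack.lm::nls.lm(par = p0, lower = bounds$lower,
                         upper = bounds$upper, fn = resid_fn, w = w,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
  }
  ok <- function(f) !is.null(f) && f$info %in% 1:4

  # deterministic multi-start: the base start plus a few jittered starts
  # guard against local minima (triplet/diffusion term exchange); further
  # jitters are tried only if nothing has converged yet
  clamp <- function(p) pmin(pmax(p, bounds$lower), bounds$upper)
  jitter_start <- function(tau_scale, trip_time) {
    p0 <- start
    scl <- intersect(c("tau_d", "tau_d1", "tau_d2"), free_names)
    p0[scl] <- p0[scl] * tau_scale
    if ("tau_trip" %in% free_names) p0[["tau_trip"]] <- trip_time
    clamp(p0)
  }
  starts <- list(clamp(start),
                 jitter_start(0.3, 1e-6),
                 jitter_start(3, 2e-5))
  pick_best <- function(fits) {
    fits <- Filter(ok, fits)
    if (!length(fits)) return(NULL)
    fits[[which.min(vapply(fits, `[[`, numeric(1), "deviance"))]]
  }
  # stage 1: unweighted multi-start (well conditioned; locates the basin)
  base <- pick_best(lapply(starts, run_lm, w = w_unit))
  if (is.null(base)) {
    for (jit in c(0.1, 10, 0.03)[seq_len(max(0, n_restarts - 2L))]) {
      f2 <- run_lm(jitter_start(jit, 5e-6), w = w_unit)
      if (ok(f2)) { base <- f2; break }
    }
  }
  if (is.null(base)) return(fail("Levenberg-Marquardt did not converge"))
  # stage 2: weighted refinement from the unweighted optimum (per-point
  # standard errors can span many decades, which strands a cold-started
  # weighted fit in a local minimum)
  fit <- if (is.null(curve$sigma)) base else {
    refined <- pick_best(list(run_lm(clamp(base$par), w = w_sig),
                              run_lm(clamp(start), w = w_sig)))
    if (is.null(refined)) return(fail("weighted refinement did not converge"))
    refined
  }

  est <- fit$par
  # standard errors from the covariance of the weighted least-squares fit
  dof <- length(curve$g) - length(est)
  se <- rep(NA_real_, length(est))
  names(se) <- names(est)
  if (dof > 0) {
    s2 <- fit$deviance / dof
    # covariance as in minpack.lm's own summary (hessian = J'J); pseudo-
    # inverse fallback for the singular case where a nuisance parameter
    # (e.g. tau_trip at vanishing triplet fraction) sits at a bound
    covm <- tryCatch(s2 * chol2inv(chol(fit$hessian)),
                     error = function(e)
                       tryCatch(s2 * MASS::ginv(fit$hessian),
                                error = function(e2) NULL))
    if (!is.null(covm)) {
      dg <- diag(covm)
      se <- ifelse(dg >= 0, sqrt(dg), NA_real_)
      names(se) <- names(est)
    }
  }

  # canonical ordering: two-component fits sorted by ascending tau_d
  if (model_kind == "3d2c" &&
      all(c("tau_d1", "tau_d2", "frac1") %in% names(est)) &&
      est[["tau_d1"]] > est[["tau_d2"]]) {
    est[c("tau_d1", "tau_d2")] <- est[c("tau_d2", "tau_d1")]
    est[["frac1"]] <- 1 - est[["frac1"]]
    se[c("tau_d1", "tau_d2")] <- se[c("tau_d2", "tau_d1")]
  }

  params <- par_vec_to_params(c(as.list(est), fixed), model_kind,
                              volume$structure_ratio)
  dcoef <- diffusion_from_tau(params$tau_d, volume)
  structure(
    list(params = params, diffusion_coeff = dcoef, estimate = est,
         param_errors = se, residual_norm = fit$deviance,
         converged = TRUE, model_kind = model_kind, message = fit$message),
    class = "correlation_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.correlation_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Correlation fit (", x$model_kind, "): NOT converged (",
        x$message, ")\n", sep = "")
    return(invisible(x))
  }
  cat("Correlation fit (", x$model_kind, "), residual norm ",
      format(x$residual_norm, digits = 4), "\n", sep = "")
  est <- x$estimate
  se <- x$param_errors
  for (nm in names(est))
    cat(sprintf("  %-12s %12.6g  (se %.3g)\n", nm, est[[nm]],
                if (is.null(se)) NA else se[[nm]]))
  cat("  D [um^2/s]:", paste(format(x$diffusion_coeff, digits = 4),
                             collapse = ", "), "\n")
  invisible(x)
}
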