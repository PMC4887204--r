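# Ligand-receptor binding equilibrium, dissociation-constant estimation
# from FCCS concentration data, effective diffusion and gradient length.
#
# All concentrations are in nM internally; helper arguments accept uM where
# noted.

#' Bound ligand fraction from mass-action equilibrium
#'
#' Solves the bimolecular equilibrium L + R <-> LR with conservation of
#' total ligand \eqn{L_t} and total receptor \eqn{R_t} at dissociation
#' constant \eqn{K_d}, and returns the bound fraction of ligand
#' \deqn{f_{bound} = \frac{K_d+L_t+R_t}{2L_t} -
#'   \sqrt{\frac{(K_d+L_t+R_t)^2}{4L_t^2} - \frac{R_t}{L_t}}}
#' the physically valid root of the quadratic (the complex concentration
#' never exceeds either total).
#'
#' @param kd Dissociation constant (nM, > 0); vectorised.
#' @param l_total Total ligand concentration (nM, > 0).
#' @param r_total Total receptor / binding-site concentration (nM, > 0).
#' @return Bound ligand fraction in \[0, 1\].
#' @examples
#' bound_fraction(60, 100, 40000)  # ~0.9985
#' bound_fraction(120, 100, 40000) # ~0.997
#' @export
bound_fraction <- function(kd, l_total, r_total) {
  if (any(!is.finite(kd)) || any(kd <= 0)) stop_invalid("'kd' must be > 0")
  if (any(!is.finite(l_total)) || any(l_total <= 0))
    stop_invalid("'l_total' must be > 0")
  if (any(!is.finite(r_total)) || any(r_total <= 0))
    stop_invalid("'r_total' must be > 0")
  s <- kd + l_total + r_total
  complex <- (s - sqrt(s^2 - 4 * l_total * r_total)) / 2
  pmin(pmax(complex / l_total, 0), 1)
}

#' Effective diffusion coefficient under quasi-equilibrium binding
#'
#' When ligand equilibrates rapidly between a free state (diffusing at
#' `d_base`) and an immobile bound state, the population spreads with
#' \eqn{D_{eff} = D \cdot f_{free}}.
#'
#' @param d_base Diffusion coefficient of the free state (\eqn{\mu m^2/s}).
#' @param f_free Free (mobile) fraction, in (0, 1\].
#' @return Effective diffusion coefficient (\eqn{\mu m^2/s}).
#' @examples
#' effective_diffusion(30, 0.0015) # 0.045
#' @export
effective_diffusion <- function(d_base, f_free) {
  if (any(!is.finite(d_base)) || any(d_base <= 0))
    stop_invalid("'d_base' must be > 0")
  if (any(!is.finite(f_free)) || any(f_free <= 0) || any(f_free > 1))
    stop_invalid("'f_free' must be in (0, 1]")
  d_base * f_free
}

#' Gradient decay length of a source-sink morphogen gradient
#'
#' For a morphogen produced at a boundary, diffusing with free coefficient
#' D, cleared at constant rate k, and reversibly trapped by receptors at
#' concentration R with dissociation constant Kd, the steady-state gradient
#' is exponential with decay length
#' \deqn{\lambda = \sqrt{D/k} \, / \, \sqrt{R/K_d + 1}}
#'
#' @param d_free Free diffusion coefficient (\eqn{\mu m^2/s}, > 0).
#' @param k_clear Clearance/degradation rate (1/s, > 0).
#' @param r_total Receptor concentration (nM, > 0).
#' @param kd Dissociation constant (nM, > 0).
#' @return Gradient length \eqn{\lambda} (\eqn{\mu m}).
#' @examples
#' gradient_length(60, 1e-4, 40000, 60)  # ~30
#' gradient_length(60, 5e-4, 40000, 120) # ~19
#' @export
gradient_length <- function(d_free, k_clear, r_total, kd) {
  for (v in list(d_free = d_free, k_clear = k_clear, r_total = r_total,
                 kd = kd))
    if (any(!is.finite(v)) || any(v <= 0))
      stop_invalid("all gradient_length() inputs must be > 0")
  sqrt(d_free / k_clear) / sqrt(r_total / kd + 1)
}

#' Receptor concentration implied by an observed gradient length
#'
#' Inverts the gradient-length relation:
#' \eqn{R = K_d (D/(k\lambda^2) - 1)}.  Requires
#' \eqn{\lambda < \sqrt{D/k}}: binding can only shorten a source-sink
#' gradient, never lengthen it.
#'
#' @param lambda_ Observed gradient length (\eqn{\mu m}).
#' @param d_free Free diffusion coefficient (\eqn{\mu m^2/s}).
#' @param k_clear Clearance rate (1/s).
#' @param kd Dissociation constant (nM).
#' @return Receptor concentration (nM).
#' @examples
#' receptor_from_gradient(30, 60, 1e-4, 60) / 1000 # ~40 uM
#' @export
receptor_from_gradient <- function(lambda_, d_free, k_clear, kd) {
  for (v in list(lambda_ = lambda_, d_free = d_free, k_clear = k_clear,
                 kd = kd))
    if (any(!is.finite(v)) || any(v <= 0))
      stop_invalid("all receptor_from_gradient() inputs must be > 0")
  lam_free <- sqrt(d_free / k_clear)
  if (any(lambda_ >= lam_free))
    stop_invalid("no solution: 'lambda_' must be smaller than sqrt(D/k) = ",
                 format(lam_free), " (binding cannot lengthen a gradient)")
  kd * (d_free / (k_clear * lambda_^2) - 1)
}

#' Concentrations from FCCS zero-lag amplitudes
#'
#' Ideal-FCCS relations (no cross-talk or background correction): the
#' total particle numbers in the observation volume are
#' \eqn{N_g = 1/G_g(0)}, \eqn{N_r = 1/G_r(0)}, the complex number is
#' \eqn{N_{gr} = G_x(0)/(G_g(0) G_r(0))}, free numbers follow by
#' subtraction, and concentrations are \eqn{C = N/(V_{eff} N_A)}.
#'
#' @param g_auto_green0,g_auto_red0,g_cross0 Zero-lag amplitudes of the
#'   green/red autocorrelations and the cross-correlation (all > 0;
#'   `g_cross0` must not exceed either autocorrelation amplitude).
#' @param volume An [observation_volume()].
#' @param embryo_id Optional sample label.
#' @return A one-row data frame of class `"binding_measurement"` with
#'   columns `embryo_id`, `c_g`, `c_r`, `c_gr` (free green, free red and
#'   complex concentrations, nM).
#' @examples
#' vol <- observation_volume() # V_eff ~0.435 fL
#' concentrations_from_amplitudes(0.1, 0.05, 0.025, vol)
#' @export
concentrations_from_amplitudes <- function(g_auto_green0, g_auto_red0,
                                           g_cross0, volume,
                                           embryo_id = NA_character_) {
  stopifnot(inherits(volume, "observation_volume"))
  check_scalar(g_auto_green0, "g_auto_green0", lower = 0, open_lower = TRUE)
  check_scalar(g_auto_red0, "g_auto_red0", lower = 0, open_lower = TRUE)
  check_scalar(g_cross0, "g_cross0", lower = 0)
  if (g_cross0 > min(g_auto_green0, g_auto_red0) * (1 + 1e-12))
    stop_invalid("inconsistent amplitudes: g_cross0 exceeds an ",
                 "autocorrelation amplitude")
  n_g_tot <- 1 / g_auto_green0
  n_r_tot <- 1 / g_auto_red0
  n_gr <- g_cross0 / (g_auto_green0 * g_auto_red0)
  # nM per particle in a volume given in um^3 (1 um^3 = 1e-15 L)
  nm_per_particle <- 1e9 / (volume$v_eff * 1e-15 * N_AVOGADRO)
  out <- data.frame(embryo_id = embryo_id,
                    c_g = (n_g_tot - n_gr) * nm_per_particle,
                    c_r = (n_r_tot - n_gr) * nm_per_particle,
                    c_gr = n_gr * nm_per_particle,
                    stringsAsFactors = FALSE)
  class(out) <- c("binding_measurement", class(out))
  out
}

check_measurements <- function(measurements) {
  req <- c("c_g", "c_r", "c_gr")
  if (!is.data.frame(measurements) || !all(req %in% names(measurements)))
    stop_invalid("'measurements' must be a data frame with columns ",
                 paste(req, collapse = ", "))
  if (any(!is.finite(unlist(measurements[req]))) ||
      any(unlist(measurements[req]) < 0))
    stop_invalid("concentrations must be finite and non-negative")
  measurements
}

#' Dissociation constant from the concentration regression
#'
#' At equilibrium \eqn{C_g C_r = K_d \, C_{gr}}, so across a set of
#' per-embryo measurements the slope of the ordinary least-squares
#' regression of the product of free concentrations on the complex
#' concentration estimates Kd.  The intercept is left free.  The log-Kd
#' histogram estimator ([kd_by_histogram()]) is also evaluated on the
#' per-sample ratios when at least five are available.
#'
#' @param measurements Data frame with columns `c_g`, `c_r`, `c_gr` (nM),
#'   e.g. rows from [concentrations_from_amplitudes()] or
#'   [synth_fccs_dataset()].  At least 3 rows with positive `c_gr`.
#' @return An object of class `"kd_estimate"`: list with `kd_regression`,
#'   `kd_se`, `kd_hist_mode` (NA when fewer than 5 positive per-sample
#'   values), `n_points`, and the underlying `fit`.
#' @examples
#' d <- data.frame(c_g = c(10, 20, 40), c_r = c(65, 65, 65),
#'                 c_gr = c(10, 20, 40)) # exact Kd = 65
#' kd_by_regression(d)$kd_regression
#' @export
kd_by_regression <- function(measurements) {
  measurements <- check_measurements(measurements)
  pos <- measurements$c_gr > 0
  if (!any(pos))
    stop_invalid("no binding: all complex concentrations are zero")
  if (sum(pos) < 3L)
    stop_invalid("need at least 3 measurements with positive c_gr")
  m <- measurements[pos, ]
  fit <- stats::lm(I(c_g * c_r) ~ c_gr, data = m)
  slope <- unname(stats::coef(fit)["c_gr"])
  # vcov warns about "essentially perfect fit" on exact synthetic data
  se <- suppressWarnings(unname(sqrt(diag(stats::vcov(fit)))["c_gr"]))
  if (!is.finite(slope) || slope <= 0)
    stop_invalid("regression slope is not positive; data show no ",
                 "mass-action binding trend")
  per_sample <- m$c_g * m$c_r / m$c_gr
  hist_mode <- NA_real_
  if (sum(per_sample > 0) >= 5L)
    hist_mode <- kd_by_histogram(per_sample[per_sample > 0])$kd_hist_mode
  structure(list(kd_regression = slope, kd_se = se,
                 kd_hist_mode = hist_mode, n_points = nrow(m), fit = fit),
            class = "kd_estimate")
}

#' Dissociation constant from the log-Kd histogram
#'
#' Builds a frequency histogram of ln(Kd) over per-sample estimates
#' (Freedman-Diaconis bin widths), fits a Gaussian to the bin counts by
#' least squares, and reports \eqn{\exp(\hat\mu)} - the mode of the
#' log-normal Kd distribution.
#'
#' @param per_sample_kd Per-sample Kd values (nM, > 0), at least 5.
#' @return An object of class `"kd_estimate"`: list with `kd_hist_mode`,
#'   `kd_se` (delta-method standard error of the mode), `kd_regression`
#'   (NA), `n_points`, `mu`, `sigma`.
#' @examples
#' set.seed(1)
#' kd_by_histogram(exp(rnorm(200, log(29), 0.3)))$kd_hist_mode
#' @export
kd_by_histogram <- function(per_sample_kd) {
  if (!is.numeric(per_sample_kd) || any(!is.finite(per_sample_kd)) ||
      any(per_sample_kd <= 0))
    stop_invalid("'per_sample_kd' must be positive and finite")
  if (length(per_sample_kd) < 5L)
    stop_invalid("need at least 5 per-sample Kd values")
  lk <- log(per_sample_kd)
  n <- length(lk)
  if (stats::sd(lk) < 1e-9) {
    # degenerate histogram: a single spike
    return(structure(list(kd_hist_mode = per_sample_kd[1], kd_se = 0,
                          kd_regression = NA_real_, n_points = n,
                          mu = lk[1], sigma = 0),
                     class = "kd_estimate"))
  }
  bw <- 2 * stats::IQR(lk) / n^(1 / 3)
  if (bw <= 0) bw <- diff(range(lk)) / ceiling(log2(n) + 1)
  breaks <- seq(min(lk) - bw / 2, max(lk) + bw, by = bw)
  h <- graphics::hist(lk, breaks = breaks, plot = FALSE)
  centers <- h$mids
  counts <- h$counts
  start <- c(a = max(counts), mu = mean(lk), sigma = stats::sd(lk))
  fit <- minpack.lm::nls.lm(
    par = start,
    lower = c(a = 0, mu = -Inf, sigma = 1e-12),
    fn = function(p) p[["a"]] *
      exp(-(centers - p[["mu"]])^2 / (2 * p[["sigma"]]^2)) - counts,
    control = minpack.lm::nls.lm.control(maxiter = 500))
  mu <- fit$par[["mu"]]
  sigma <- abs(fit$par[["sigma"]])
  dof <- max(length(counts) - 3L, 1L)
  covm <- tryCatch(fit$deviance / dof * chol2inv(chol(fit$hessian)),
                   error = function(e) NULL)
  mu_var <- if (!is.null(covm)) covm[2, 2] else NA_real_ # par order a, mu, sigma
  mu_se <- if (is.finite(mu_var) && mu_var >= 0) sqrt(mu_var) else NA_real_
  structure(list(kd_hist_mode = exp(mu), kd_se = exp(mu) * mu_se,
                 kd_regression = NA_real_, n_points = n,
                 mu = mu, sigma = sigma),
            class = "kd_estimate")
}

#' @export
print.kd_estimate <- function(x, ...) {
  cat("Kd estimate (n =", x$n_points, "):\n")
  if (is.finite(x$kd_regression %||% NA))
    cat(sprintf("  regression slope: %.4g nM (se %.3g)\n",
                x$kd_regression, x$kd_se))
  if (is.finite(x$kd_hist_mode %||% NA))
    cat(sprintf("  ln-Kd histogram mode: %.4g nM\n", x$kd_hist_mode))
  invisible(x)
}

#' Read per-sample binding measurements from CSV
#'
#' Expects columns `embryo_id`, `c_g_nM`, `c_r_nM`, `c_gr_nM` (or the bare
#' names `c_g`, `c_r`, `c_gr`).
#'
#' @param path File path.
#' @return Data frame with columns `embryo_id`, `c_g`, `c_r`, `c_gr` (nM).
#' @export
read_binding_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ren <- c(c_g_nM = "c_g", c_r_nM = "c_r", c_gr_nM = "c_gr")
  for (nm in names(ren))
    if (nm %in% names(df)) names(df)[names(df) == nm] <- ren[[nm]]
  if (!"embryo_id" %in% names(df)) df$embryo_id <- seq_len(nrow(df))
  check_measurements(df)
}
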