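# Clearance kinetics: exponential decay fitting of protein time courses.
#
# Band intensities from immunoblot time courses are normalised against a
# loading control and against the t = 0 sample, then fitted with
# A * exp(-k t) to estimate the first-order clearance rate.

#' Protein decay time series
#'
#' @param t Time points, starting at 0 and strictly increasing.
#' @param intensity Band intensities (> 0), one per time point.
#' @param control Loading-control intensities (> 0), one per time point.
#' @param label Protein name.
#' @param time_unit `"hr"` (default, as on blot time courses) or `"s"`;
#'   stored internally in seconds.
#' @return An object of class `"decay_series"` with elements `t_s`,
#'   `intensity`, `control`, `label`, `normalized` (flag).
#' @export
decay_series <- function(t, intensity, control = rep(1, length(t)),
                         label = NA_character_, time_unit = c("hr", "s")) {
  time_unit <- match.arg(time_unit)
  if (length(t) != length(intensity) || length(t) != length(control))
    stop_invalid("'t', 'intensity' and 'control' must have equal lengths")
  if (t[1] != 0 || any(diff(t) <= 0))
    stop_invalid("'t' must start at 0 and be strictly increasing")
  if (any(!is.finite(intensity)) || any(intensity <= 0))
    stop_invalid("'intensity' must be positive")
  if (any(!is.finite(control)) || any(control <= 0))
    stop_invalid("'control' must be positive (zero loading control)")
  structure(list(t_s = if (time_unit == "hr") t * 3600 else t,
                 intensity = intensity, control = control, label = label,
                 normalized = FALSE),
            class = "decay_series")
}

#' Normalise a decay series
#'
#' Divides each band intensity by its loading control (correcting
#' per-lane loading/recovery differences) and then by the t = 0 value, so
#' the first point is exactly 1.  Idempotent.
#'
#' @param series A [decay_series()].
#' @return A normalised `"decay_series"` (`control` all 1).
#' @export
normalize_series <- function(series) {
  stopifnot(inherits(series, "decay_series"))
  ratio <- series$intensity / series$control
  out <- series
  out$intensity <- ratio / ratio[1]
  out$control <- rep(1, length(ratio))
  out$normalized <- TRUE
  out
}

#' Fit an exponential decay to a normalised time series
#'
#' Least-squares fit of \eqn{A e^{-k t}} (amplitude free, near 1 after
#' normalisation) or \eqn{A e^{-k t} + C} when `with_offset = TRUE`.
#' Series that have not been normalised are normalised first.
#'
#' @param series A [decay_series()] with at least 3 time points.
#' @param with_offset Add a plateau term?
#' @return An object of class `"decay_fit"`: list with `k_deg` (1/s),
#'   `half_life` (s, \eqn{\ln 2 / k}), `amplitude`, `offset`,
#'   `residual_norm`, `converged`, `label`.  A fit returning
#'   \eqn{k \le 0} or failing to converge has `converged = FALSE`.
#' @examples
#' t_hr <- c(0, 6, 12, 24)
#' s <- decay_series(t_hr, exp(-0.166e-4 * t_hr * 3600))
#' fit_decay(s)$k_deg
#' @export
fit_decay <- function(series, with_offset = FALSE) {
  stopifnot(inherits(series, "decay_series"))
  if (length(series$t_s) < 3L)
    stop_invalid("need at least 3 time points")
  if (!series$normalized) series <- normalize_series(series)
  t <- series$t_s
  y <- series$intensity
  # log-linear start (guards against non-decaying data)
  k0 <- tryCatch({
    cf <- stats::coef(stats::lm(log(pmax(y, 1e-12)) ~ t))
    max(-cf[[2]], 1e-9)
  }, error = function(e) 1e-5)
  fail <- structure(list(k_deg = NA_real_, half_life = NA_real_,
                         amplitude = NA_real_, offset = NA_real_,
                         residual_norm = NA_real_, converged = FALSE,
                         label = series$label),
                    class = "decay_fit")
  par0 <- c(a = 1, k = k0)
  lower <- c(a = 0, k = 0)
  if (with_offset) {
    par0 <- c(par0, c0 = min(y))
    lower <- c(lower, c0 = 0)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, lower = lower,
                       fn = function(p) {
                         m <- p[["a"]] * exp(-p[["k"]] * t)
                         if (with_offset) m <- m + p[["c0"]]
                         m - y
                       },
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:4)) return(fail)
  k <- unname(fit$par[["k"]])
  if (!is.finite(k) || k <= 0) return(fail)
  structure(list(k_deg = k, half_life = log(2) / k,
                 amplitude = unname(fit$par[["a"]]),
                 offset = if (with_offset) unname(fit$par[["c0"]]) else 0,
                 residual_norm = fit$deviance, converged = TRUE,
                 label = series$label),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Decay fit: NOT converged\n")
    return(invisible(x))
  }
  cat(sprintf("Decay fit%s: k = %.4g /s, half-life = %.3g hr\n",
              if (is.na(x$label)) "" else paste0(" (", x$label, ")"),
              x$k_deg, x$half_life / 3600))
  invisible(x)
}

#' Rank decay fits by clearance rate
#'
#' Orders fitted proteins by descending degradation rate (fastest-cleared
#' first).  Exact ties are broken by label order and flagged.
#'
#' @param fits List of `"decay_fit"` objects (>= 1).
#' @return A data frame with columns `label`, `k_deg`, `half_life`,
#'   `rank`, `tied`.
#' @export
compare_decay_order <- function(fits) {
  if (inherits(fits, "decay_fit")) fits <- list(fits)
  if (!length(fits) || !all(vapply(fits, inherits, logical(1), "decay_fit")))
    stop_invalid("'fits' must be a list of decay_fit objects")
  k <- vapply(fits, `[[`, numeric(1), "k_deg")
  lab <- vapply(fits, function(f) as.character(f$label), character(1))
  ord <- order(-k, lab)
  out <- data.frame(label = lab[ord], k_deg = k[ord],
                    half_life = log(2) / k[ord],
                    rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  out$tied <- duplicated(out$k_deg) | duplicated(out$k_deg, fromLast = TRUE)
  out
}

#' Read decay time courses from CSV
#'
#' Expects columns `t_hr` (or `t_s`), `intensity`, optionally `control`
#' and `label`; one series per label.
#'
#' @param path File path.
#' @return A named list of [decay_series()].
#' @export
read_decay_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  unit <- if ("t_hr" %in% names(df)) "hr"
          else if ("t_s" %in% names(df)) "s"
          else stop_invalid("decay CSV needs a 't_hr' or 't_s' column")
  tcol <- paste0("t_", unit)
  if (!"intensity" %in% names(df))
    stop_invalid("decay CSV needs an 'intensity' column")
  if (!"label" %in% names(df)) df$label <- "series1"
  if (!"control" %in% names(df)) df$control <- 1
  out <- lapply(split(df, df$label), function(d)
    decay_series(d[[tcol]], d$intensity, d$control, label = d$label[1],
                 time_unit = unit))
  out
}
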