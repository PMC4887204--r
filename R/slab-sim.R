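# 3D slab random-walk simulation of hindered diffusion.
#
# Morphogen particles are released on one face of a thin 3D slab packed
# with cylindrical cells and perform a Gaussian random walk.  Tortuosity
# (longer paths around cells) and quasi-equilibrium binding (a per-step
# probability of being mobile) both reduce the apparent spread, which is
# quantified by fitting the 1D concentration profile with the diffusion
# bell curve exp(-x^2 / (4 D_eff t)).

#' Slab simulation configuration
#'
#' Geometry, transport and binding parameters of the 3D hindered-diffusion
#' simulation.  Defaults are the early-gastrula conditions: a
#' 2 x 44 x 86.7 um slab, cells of 10 um diameter with 2 um intercellular
#' gaps, free diffusion coefficient 60 um^2/s, 1000 particles walked for
#' 5 s at 5 ms resolution.
#'
#' @param height_z,width_y,length_x Slab dimensions (\eqn{\mu m}); x is the
#'   gradient axis with the source at x = 0.
#' @param d_free Input diffusion coefficient (\eqn{\mu m^2/s}).
#' @param dt Time step (s).
#' @param duration Total simulated time (s).
#' @param n_particles Number of particles released at the x = 0 face.
#' @param cell_diameter Cylindrical cell diameter (\eqn{\mu m}).
#' @param gap Membrane-to-membrane spacing between cells (\eqn{\mu m}).
#' @param f_free Probability that a particle is mobile in a given step
#'   (quasi-equilibrium binding); 1 disables binding.
#' @param obstacles_on Place the cell lattice? `FALSE` gives free diffusion.
#' @param collision_rule What happens when a proposed move ends inside a
#'   cylinder: `"specular"` (default) mirrors the endpoint across the
#'   cylinder surface, which converges to reflected diffusion and leaves
#'   tortuosity as the only slowdown; `"reject"` cancels the move, which
#'   at finite step size adds extra wall drag.
#' @param seed RNG seed; every simulation is reproducible given the seed.
#'
#' @return An object of class `"slab_config"`.
#' @export
slab_config <- function(height_z = 2, width_y = 44, length_x = 86.7,
                        d_free = 60, dt = 0.005, duration = 5,
                        n_particles = 1000, cell_diameter = 10, gap = 2,
                        f_free = 1, obstacles_on = TRUE,
                        collision_rule = c("specular", "reject"),
                        seed = 1L) {
  collision_rule <- match.arg(collision_rule)
  check_scalar(height_z, "height_z", lower = 0, open_lower = TRUE)
  check_scalar(width_y, "width_y", lower = 0, open_lower = TRUE)
  check_scalar(length_x, "length_x", lower = 0, open_lower = TRUE)
  check_scalar(d_free, "d_free", lower = 0)
  check_scalar(dt, "dt", lower = 0, open_lower = TRUE)
  check_scalar(duration, "duration", lower = dt)
  check_scalar(n_particles, "n_particles", lower = 1)
  check_scalar(cell_diameter, "cell_diameter", lower = 0, open_lower = TRUE)
  check_scalar(gap, "gap", lower = 0, open_lower = TRUE)
  check_scalar(f_free, "f_free", lower = 0, upper = 1, open_lower = TRUE)
  if (obstacles_on && cell_diameter + gap > min(width_y, length_x))
    stop_invalid("cell_diameter + gap must fit inside the slab cross-section")
  structure(list(height_z = height_z, width_y = width_y,
                 length_x = length_x, d_free = d_free, dt = dt,
                 duration = duration, n_particles = as.integer(n_particles),
                 cell_diameter = cell_diameter, gap = gap, f_free = f_free,
                 obstacles_on = isTRUE(obstacles_on),
                 collision_rule = collision_rule,
                 seed = as.integer(seed)),
            class = "slab_config")
}

#' Cylindrical cell lattice of a slab configuration
#'
#' Cells are z-aligned cylinders of diameter `cell_diameter` on a square
#' lattice with pitch `cell_diameter + gap`, centred at
#' ((i + 1/2) pitch, (j + 1/2) pitch), so that neighbouring cylinder
#' surfaces are exactly `gap` apart and no cylinder crosses the x = 0
#' source plane.
#'
#' @param config A [slab_config()].
#' @return A list with `centers` (two-column matrix of x,y cylinder
#'   centres inside the slab), `radius`, `pitch`, and `free_area_fraction`
#'   (analytic free cross-section fraction of one lattice cell,
#'   \eqn{1 - \pi r^2 / pitch^2}).  Empty `centers` when
#'   `obstacles_on = FALSE`.
#' @examples
#' lat <- build_cell_lattice(slab_config())
#' lat$free_area_fraction # 1 - pi * 25 / 144
#' @export
build_cell_lattice <- function(config) {
  stopifnot(inherits(config, "slab_config"))
  if (!config$obstacles_on)
    return(list(centers = matrix(numeric(0), ncol = 2,
                                 dimnames = list(NULL, c("x", "y"))),
                radius = config$cell_diameter / 2,
                pitch = config$cell_diameter + config$gap,
                free_area_fraction = 1))
  pitch <- config$cell_diameter + config$gap
  r <- config$cell_diameter / 2
  frac <- 1 - pi * r^2 / pitch^2
  if (frac <= 0)
    stop_invalid("invalid geometry: cylinders leave no free space")
  cx <- seq(pitch / 2, config$length_x + r, by = pitch)
  cy <- seq(pitch / 2, config$width_y + r, by = pitch)
  centers <- as.matrix(expand.grid(x = cx, y = cy))
  list(centers = centers, radius = r, pitch = pitch,
       free_area_fraction = frac)
}

# TRUE where (x, y) lies inside a cylinder of the (periodic) square
# lattice.  Modular distance to the nearest lattice centre; exact for the
# infinite lattice and consistent with periodic y boundaries.
inside_obstacle <- function(x, y, pitch, radius) {
  dx <- (x %% pitch) - pitch / 2
  dy <- (y %% pitch) - pitch / 2
  dx * dx + dy * dy < radius * radius
}

#' Run the 3D slab random-walk simulation
#'
#' All particles start on the x = 0 face (uniform in y and z, outside
#' obstacles).  Each step every mobile particle receives an independent
#' Gaussian displacement of per-axis variance \eqn{2 D \Delta t}; x is
#' reflected at both ends, y and z are periodic.  A proposed move ending
#' inside a cylinder is handled by the configured `collision_rule`:
#' specular mirroring across the cylinder surface (default; falls back to
#' rejection in the rare case the mirrored point lands inside another
#' cylinder), or plain rejection (the particle keeps its position for
#' that step).  With `f_free < 1`, each particle moves in a given step
#' only with probability `f_free` (quasi-equilibrium binding).
#'
#' @param config A [slab_config()].
#' @param start `"source"` (default, x = 0 face) or `"center"` (the
#'   mid-slab plane x = length_x / 2, uniform in y and z; use with
#'   [estimate_deff_msd()] to keep the reflecting x walls out of reach).
#' @return An object of class `"slab_sim"`: list with `x`, `y`, `z` (final
#'   positions), `x0`, `y0`, `z0` (start positions), `time` (elapsed
#'   simulated time), `config`, `lattice`.
#' @examples
#' sim <- simulate_slab(slab_config(n_particles = 100, duration = 0.5,
#'                                  obstacles_on = FALSE, seed = 7))
#' mean(sim$x)
#' @export
simulate_slab <- function(config, start = c("source", "center")) {
  stopifnot(inherits(config, "slab_config"))
  start <- match.arg(start)
  lattice <- build_cell_lattice(config)
  n <- config$n_particles
  pitch <- lattice$pitch
  radius <- lattice$radius
  obst <- config$obstacles_on
  with_seed(config$seed, {
    x <- rep(if (start == "source") 0 else config$length_x / 2, n)
    y <- stats::runif(n, 0, config$width_y)
    z <- stats::runif(n, 0, config$height_z)
    if (obst) {
      # resample transverse starting points that fall inside a cylinder
      for (i in 1:100) {
        bad <- inside_obstacle(x, y, pitch, radius)
        if (!any(bad)) break
        y[bad] <- stats::runif(sum(bad), 0, config$width_y)
      }
      if (any(inside_obstacle(x, y, pitch, radius)))
        stop_invalid("could not place particles outside obstacles")
    }
    x0 <- x; y0 <- y; z0 <- z
    n_steps <- round(config$duration / config$dt)
    sd_step <- sqrt(2 * config$d_free * config$dt)
    for (s in seq_len(n_steps)) {
      dx <- stats::rnorm(n, 0, sd_step)
      dy <- stats::rnorm(n, 0, sd_step)
      dz <- stats::rnorm(n, 0, sd_step)
      if (config$f_free < 1) {
        frozen <- stats::runif(n) >= config$f_free
        dx[frozen] <- 0; dy[frozen] <- 0; dz[frozen] <- 0
      }
      nx <- fold_reflect(x + dx, 0, config$length_x)
      ny <- wrap_periodic(y + dy, 0, config$width_y)
      nz <- wrap_periodic(z + dz, 0, config$height_z)
      if (obst) {
        bad <- inside_obstacle(nx, ny, pitch, radius)
        if (any(bad) && config$collision_rule == "specular") {
          # mirror the endpoint across the cylinder surface along the
          # radial direction from the nearest cylinder axis
          cx <- (floor(nx[bad] / pitch) + 0.5) * pitch
          cy <- (floor(ny[bad] / pitch) + 0.5) * pitch
          ddx <- nx[bad] - cx
          ddy <- ny[bad] - cy
          rho <- sqrt(ddx^2 + ddy^2)
          rho[rho == 0] <- 1e-12
          scl <- (2 * radius - rho) / rho
          mx <- fold_reflect(cx + ddx * scl, 0, config$length_x)
          my <- wrap_periodic(cy + ddy * scl, 0, config$width_y)
          still <- inside_obstacle(mx, my, pitch, radius)
          nx[bad] <- ifelse(still, x[bad], mx)
          ny[bad] <- ifelse(still, y[bad], my)
          nz[bad][still] <- z[bad][still]
          bad <- rep(FALSE, n)
        }
        x <- ifelse(bad, x, nx); y <- ifelse(bad, y, ny)
        z <- ifelse(bad, z, nz)
      } else {
        x <- nx; y <- ny; z <- nz
      }
    }
    structure(list(x = x, y = y, z = z, x0 = x0, y0 = y0, z0 = z0,
                   time = n_steps * config$dt, config = config,
                   lattice = lattice),
              class = "slab_sim")
  })
}

#' Concentration profile along the gradient axis
#'
#' Histogram of particle x positions in bins of `bin_width`, normalised to
#' the maximum bin (so the profile peaks at 1).
#'
#' @param positions Particle x coordinates (\eqn{\mu m}), or a
#'   `"slab_sim"` object.
#' @param t Profile time (s); taken from the simulation when `positions`
#'   is a `"slab_sim"`.
#' @param length_x Domain length (\eqn{\mu m}); ditto.
#' @param bin_width Bin width (\eqn{\mu m}), default 1.
#' @param normalize Divide counts by the maximum bin?
#' @return An object of class `"concentration_profile"`: list with
#'   `x_centers`, `counts` (raw), `density` (normalised), `t`.
#' @export
concentration_profile <- function(positions, t = NULL, length_x = NULL,
                                  bin_width = 1, normalize = TRUE) {
  if (inherits(positions, "slab_sim")) {
    t <- t %||% positions$time
    length_x <- length_x %||% positions$config$length_x
    positions <- positions$x
  }
  if (length(positions) == 0L)
    stop_invalid("no particle positions to bin")
  if (is.null(t) || is.null(length_x))
    stop_invalid("'t' and 'length_x' are required for raw positions")
  if (any(positions < 0) || any(positions > length_x))
    stop_invalid("positions must lie within [0, length_x]")
  breaks <- seq(0, bin_width * ceiling(length_x / bin_width),
                by = bin_width)
  counts <- graphics::hist(positions, breaks = breaks, plot = FALSE)$counts
  structure(list(x_centers = breaks[-length(breaks)] + bin_width / 2,
                 counts = counts,
                 density = if (normalize) counts / max(counts) else counts,
                 t = t),
            class = "concentration_profile")
}

#' Fit the diffusion bell curve to a concentration profile
#'
#' Least-squares fit of the source-diffusion profile
#' \deqn{C(x, t) = A \exp[-x^2 / (4 D_{eff} t)]}
#' over \eqn{x \ge 0}, returning the effective diffusion coefficient.
#' By default the amplitude A is a free parameter: the empirical profile
#' is normalised to its (noisy) maximum bin, so pinning A to 1 would tie
#' the whole fit to a single upward-fluctuating bin and bias
#' \eqn{D_{eff}} low.  `amplitude = "fixed"` pins A = 1, the idealised
#' normalised form.  The initial value of \eqn{D_{eff}} comes from the
#' second moment of the profile.
#'
#' @param profile A [concentration_profile()] with `t > 0`.
#' @param amplitude `"free"` (default) or `"fixed"`.
#' @return An object of class `"profile_fit"`: list with `d_eff`
#'   (\eqn{\mu m^2/s}), `amplitude`, `residual_norm`, `converged`.
#' @examples
#' x <- seq(0.5, 80, by = 1)
#' pr <- structure(list(x_centers = x,
#'                      density = exp(-x^2 / (4 * 33.8 * 5)), t = 5),
#'                 class = "concentration_profile")
#' fit_gaussian_profile(pr)$d_eff
#' @export
fit_gaussian_profile <- function(profile, amplitude = c("free", "fixed")) {
  stopifnot(inherits(profile, "concentration_profile"))
  amplitude <- match.arg(amplitude)
  if (is.null(profile$t) || profile$t <= 0)
    stop_invalid("profile time 't' must be > 0")
  x <- profile$x_centers
  y <- profile$density
  # second-moment start: for a half-Gaussian <x^2> = 2 D t
  d0 <- sum(y * x^2) / sum(y) / (2 * profile$t)
  if (!is.finite(d0) || d0 <= 0) d0 <- 1
  if (amplitude == "free") {
    par0 <- c(a = max(y), d_eff = d0)
    lower <- c(a = 0, d_eff = 1e-12)
    resid <- function(p)
      p[["a"]] * exp(-x^2 / (4 * p[["d_eff"]] * profile$t)) - y
  } else {
    par0 <- c(d_eff = d0)
    lower <- c(d_eff = 1e-12)
    resid <- function(p)
      exp(-x^2 / (4 * p[["d_eff"]] * profile$t)) - y
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, lower = lower, fn = resid,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:4))
    return(structure(list(d_eff = NA_real_, amplitude = NA_real_,
                          residual_norm = NA_real_, converged = FALSE),
                     class = "profile_fit"))
  structure(list(d_eff = unname(fit$par[["d_eff"]]),
                 amplitude = if (amplitude == "free")
                   unname(fit$par[["a"]]) else 1,
                 residual_norm = fit$deviance, converged = TRUE),
            class = "profile_fit")
}

#' Effective diffusion coefficient of a slab run
#'
#' Convenience wrapper: run [simulate_slab()] for each seed and estimate
#' \eqn{D_{eff}}, then average over seeds.  The `"profile"` estimator bins
#' the final x positions ([concentration_profile()]) and fits the bell
#' curve ([fit_gaussian_profile()]); it is the estimator of choice when
#' the spread \eqn{\sqrt{2 D_{eff} t}} exceeds the cell pitch.  The
#' `"msd"` estimator uses \eqn{\langle (x - x_0)^2 \rangle / (2t)} of the
#' same run; it remains meaningful for strongly hindered runs whose
#' spread stays below one cell pitch, where the histogram is dominated by
#' the discrete lattice near-field and is no longer bell-shaped.
#'
#' @param config A [slab_config()]; its `seed` is replaced by each element
#'   of `seeds`.
#' @param seeds Integer vector of seeds.
#' @param estimator `"profile"` (default) or `"msd"`.
#' @param bin_width Profile bin width (\eqn{\mu m}).
#' @return List with `d_eff` (mean over seeds), `per_seed` (named vector),
#'   `seeds`, `estimator`.
#' @export
slab_deff <- function(config, seeds = 1:5,
                      estimator = c("profile", "msd"), bin_width = 1) {
  stopifnot(inherits(config, "slab_config"))
  estimator <- match.arg(estimator)
  per_seed <- vapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    sim <- simulate_slab(cfg)
    if (estimator == "msd")
      return(mean((sim$x - sim$x0)^2) / (2 * sim$time))
    fit <- fit_gaussian_profile(concentration_profile(sim,
                                                      bin_width = bin_width))
    if (!fit$converged) return(NA_real_)
    fit$d_eff
  }, numeric(1))
  names(per_seed) <- seeds
  list(d_eff = mean(per_seed, na.rm = TRUE), per_seed = per_seed,
       seeds = seeds, estimator = estimator)
}

#' Effective diffusion coefficient from mean-squared displacement
#'
#' Runs the slab simulation with particles started uniformly in the slab
#' interior and estimates \eqn{D_{eff} = \langle \Delta x^2\rangle / (2t)}
#' from the x displacement (the unbounded gradient axis is used; y and z
#' wrap).  Used for short-displacement conditions where a profile fit is
#' not informative.
#'
#' @param config A [slab_config()].
#' @param start Start distribution, as in [simulate_slab()]; `"center"`
#'   (default) avoids boundary effects for unhindered checks.
#' @return \eqn{D_{eff}} (\eqn{\mu m^2/s}).
#' @export
estimate_deff_msd <- function(config, start = c("center", "source")) {
  stopifnot(inherits(config, "slab_config"))
  start <- match.arg(start)
  sim <- simulate_slab(config, start = start)
  mean((sim$x - sim$x0)^2) / (2 * sim$time)
}
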