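# Correlation model evaluation and curve fitting.

test_that("autocorrelation models match closed-form and direct-substitution values", {
  # 3D one-component: amplitude 1/N at zero lag, closed form at tau = tau_d
  p <- triplet_params(n_particles = 1, tau_d = 1, structure_ratio = 1)
  expect_equal(acf_3d_1c_triplet(p, 1e-12), 1, tolerance = 1e-9)
  expect_equal(acf_3d_1c_triplet(p, 1), 0.5 / sqrt(2), tolerance = 1e-12)
  # frozen term-by-term substitution value (independent arithmetic):
  # N=2, F=0.2, tau_trip=1e-5, tau_d=1e-3, w0/z0=0.2, tau=1e-4
  p3 <- triplet_params(2, tau_d = 1e-3, f_trip = 0.2, tau_trip = 1e-5,
                       structure_ratio = 0.2)
  expect_equal(acf_3d_1c_triplet(p3, 1e-4), 0.453644230645499,
               tolerance = 1e-12)

  # 2D one-component
  p2 <- triplet_params(1, tau_d = 1)
  expect_equal(acf_2d_1c_triplet(p2, 1), 0.5, tolerance = 1e-12)
  p2b <- triplet_params(1, tau_d = 1, g_inf = 0.007)
  expect_equal(acf_2d_1c_triplet(p2b, 1e12), 0.007, tolerance = 1e-9)
  # frozen: N=4, F=0.1, tau_trip=5e-6, tau_d=2e-3, G_inf=0.001, tau=2e-3
  p4 <- triplet_params(4, tau_d = 2e-3, f_trip = 0.1, tau_trip = 5e-6,
                       g_inf = 0.001)
  expect_equal(acf_2d_1c_triplet(p4, 2e-3), 0.126, tolerance = 1e-12)

  # two-component: frozen frac = (0.3, 0.7), tau_d = (1e-4, 1e-2), N=1,
  # no triplet, w0/z0 = 0.2, tau = 1e-3
  p5 <- triplet_params(1, tau_d = c(1e-4, 1e-2), frac = c(0.3, 0.7),
                       structure_ratio = 0.2)
  expect_equal(acf_3d_2c_triplet(p5, 1e-3), 0.658144376082436,
               tolerance = 1e-12)

  # cross-correlation
  pc <- triplet_params(1, tau_d = 1)
  expect_equal(ccf_model(pc, 1e-12), 1, tolerance = 1e-9)
  expect_equal(ccf_model(pc, 3), 0.25, tolerance = 1e-12)
})

test_that("degenerate multi-component parameter sets collapse to one-component curves", {
  lag <- test_lag_grid(50)
  p1 <- triplet_params(3, tau_d = 2e-4, f_trip = 0.1, tau_trip = 1e-5,
                       structure_ratio = 0.2)
  # one component with zero weight on the second
  p2 <- triplet_params(3, tau_d = c(2e-4, 5e-2), frac = c(1, 0),
                       f_trip = 0.1, tau_trip = 1e-5, structure_ratio = 0.2)
  expect_equal(acf_3d_2c_triplet(p2, lag), acf_3d_1c_triplet(p1, lag),
               tolerance = 1e-12)
  # identical components collapse
  p3 <- triplet_params(3, tau_d = c(2e-4, 2e-4), frac = c(0.5, 0.5),
                       f_trip = 0.1, tau_trip = 1e-5, structure_ratio = 0.2)
  expect_equal(acf_3d_2c_triplet(p3, lag), acf_3d_1c_triplet(p1, lag),
               tolerance = 1e-12)
  # cross-correlation model is the 2D model without triplet
  p4 <- triplet_params(3, tau_d = 2e-4, g_inf = 0.002)
  expect_equal(ccf_model(p4, lag), acf_2d_1c_triplet(p4, lag),
               tolerance = 1e-12)
})

test_that("all models obey the short- and long-lag limits and decrease monotonically", {
  lag <- test_lag_grid(120)
  cases <- list(
    list(fn = acf_3d_1c_triplet,
         p = triplet_params(5, tau_d = 1e-3, f_trip = 0.2, tau_trip = 1e-6,
                            structure_ratio = 0.2, g_inf = 0.003)),
    list(fn = acf_2d_1c_triplet,
         p = triplet_params(2, tau_d = 5e-4, f_trip = 0.1, tau_trip = 2e-6,
                            structure_ratio = 0.25, g_inf = -0.001)),
    list(fn = acf_3d_2c_triplet,
         p = triplet_params(8, tau_d = c(1e-4, 1e-2), frac = c(0.4, 0.6),
                            f_trip = 0.05, tau_trip = 1e-6,
                            structure_ratio = 0.2, g_inf = 0.002)),
    list(fn = ccf_model,
         p = triplet_params(4, tau_d = 2e-3, g_inf = 0.001)))
  for (cs in cases) {
    p <- cs$p
    g <- cs$fn(p, lag)
    # tau -> 0+: 1/(N (1 - F_trip)) + G_inf
    expect_equal(cs$fn(p, 1e-12),
                 1 / (p$n_particles * (1 - p$f_trip)) + p$g_inf,
                 tolerance = 1e-6)
    # tau -> Inf: G_inf
    expect_equal(cs$fn(p, 1e12), p$g_inf, tolerance = 1e-9)
    # strictly decreasing (after removing the offset)
    expect_true(all(diff(g - p$g_inf) < 0))
  }
})

test_that("invalid model parameters and lags are rejected", {
  expect_error(triplet_params(0, tau_d = 1e-3), "n_particles")
  expect_error(triplet_params(1, tau_d = -1), "tau_d")
  expect_error(triplet_params(1, tau_d = 1e-3, f_trip = 1), "f_trip")
  expect_error(triplet_params(1, tau_d = c(1e-3, 1e-2), frac = c(0.6, 0.6)),
               "sum to 1")
  expect_error(triplet_params(1, tau_d = c(1e-3, 1e-2)), "frac")
  p <- triplet_params(1, tau_d = 1e-3)
  expect_error(acf_3d_1c_triplet(p, -1), "lag")
  expect_error(acf_3d_1c_triplet(p, 0), "lag")
  p2 <- triplet_params(1, tau_d = c(1e-3, 1e-2), frac = c(0.5, 0.5))
  expect_error(acf_3d_1c_triplet(p2, 1), "one-component")
  pt <- triplet_params(1, tau_d = 1e-3, f_trip = 0.2, tau_trip = 1e-5)
  expect_error(ccf_model(pt, 1), "triplet")
  expect_error(observation_volume(omega0 = 2, z0 = 1), "structure ratio")
})

test_that("observation volume and diffusion-time conversions are exact", {
  vol <- observation_volume(0.25, 1.25)
  expect_equal(vol$v_eff, pi^1.5 * 0.25^2 * 1.25, tolerance = 1e-12)
  expect_equal(diffusion_from_tau(1e-3, observation_volume(0.2, 1)), 10,
               tolerance = 1e-12)
  # tau_d = 2.604e-4 s at omega0 = 0.25 um corresponds to ~60 um^2/s
  expect_equal(diffusion_from_tau(2.604e-4, vol), 60, tolerance = 1e-4)
  # doubling omega0 quadruples D at fixed tau_d
  expect_equal(diffusion_from_tau(1e-3, observation_volume(0.4, 2)),
               4 * diffusion_from_tau(1e-3, observation_volume(0.2, 1)),
               tolerance = 1e-12)
  # round trip
  expect_equal(tau_from_diffusion(diffusion_from_tau(3.7e-4, vol), vol),
               3.7e-4, tolerance = 1e-12)
})

test_that("fitting exact model-generated curves recovers the inputs", {
  vol <- observation_volume()
  lag <- test_lag_grid()
  truths <- list(
    list(kind = "3d1c", p = triplet_params(10, tau_d = 5e-4, f_trip = 0.15,
                                           tau_trip = 5e-6,
                                           structure_ratio = 0.2)),
    list(kind = "2d1c", p = triplet_params(4, tau_d = 2e-3, f_trip = 0.1,
                                           tau_trip = 5e-6,
                                           structure_ratio = 0.2)),
    list(kind = "3d2c", p = triplet_params(5, tau_d = c(1e-4, 1e-2),
                                           frac = c(0.3, 0.7), f_trip = 0.1,
                                           tau_trip = 5e-6,
                                           structure_ratio = 0.2)),
    list(kind = "ccf", p = triplet_params(4, tau_d = 2e-3,
                                          structure_ratio = 0.2)))
  for (tr in truths) {
    model_fn <- switch(tr$kind,
                       "3d1c" = acf_3d_1c_triplet,
                       "2d1c" = acf_2d_1c_triplet,
                       "3d2c" = acf_3d_2c_triplet,
                       "ccf" = ccf_model)
    g <- model_fn(tr$p, lag)
    curve <- correlation_curve(lag, g)
    fit <- fit_correlation(curve, tr$kind, vol)
    expect_true(fit$converged)
    expect_equal(fit$params$n_particles, tr$p$n_particles,
                 tolerance = 1e-6)
    expect_equal(fit$params$tau_d, tr$p$tau_d, tolerance = 1e-6)
    if (tr$kind != "ccf")
      expect_equal(fit$params$f_trip, tr$p$f_trip, tolerance = 1e-5)
    # diffusion coefficients are tied to tau_d through the volume
    expect_equal(fit$diffusion_coeff,
                 vol$omega0^2 / (4 * fit$params$tau_d), tolerance = 1e-9)
  }
})

test_that("a noise-free one-component curve without triplet is recovered with a fixed triplet", {
  vol <- observation_volume()
  lag <- test_lag_grid(150)
  p <- triplet_params(10, tau_d = 5e-4, structure_ratio = 0.2)
  curve <- correlation_curve(lag, acf_3d_1c_triplet(p, lag))
  fit <- fit_correlation(curve, "3d1c", vol, fixed = list(f_trip = 0))
  expect_equal(fit$estimate[["n_particles"]], 10, tolerance = 1e-6)
  expect_equal(fit$estimate[["tau_d"]], 5e-4, tolerance = 1e-6)
})

test_that("the richer two-component model fits its own data better than the one-component model", {
  vol <- observation_volume()
  lag <- test_lag_grid()
  p2 <- triplet_params(5, tau_d = c(1e-4, 1e-2), frac = c(0.5, 0.5),
                       structure_ratio = 0.2)
  curve <- correlation_curve(lag, acf_3d_2c_triplet(p2, lag))
  fit2 <- fit_correlation(curve, "3d2c", vol, fixed = list(f_trip = 0))
  fit1 <- fit_correlation(curve, "3d1c", vol, fixed = list(f_trip = 0))
  expect_true(fit2$converged && fit1$converged)
  expect_gt(fit1$residual_norm, fit2$residual_norm)
  # canonical component order: ascending diffusion time
  expect_lt(fit2$estimate[["tau_d1"]], fit2$estimate[["tau_d2"]])
})

test_that("a constant curve yields a fit-failure result, not an error", {
  curve <- correlation_curve(test_lag_grid(50), rep(0.2, 50))
  fit <- fit_correlation(curve, "3d1c")
  expect_false(fit$converged)
  expect_true(is.na(fit$residual_norm))
})

test_that("diffusion recovery from noisy synthetic curves is accurate", {
  vol <- observation_volume()
  # 2% relative noise: recovered D within 10%
  curve <- synth_correlation_curve(60, 10, volume = vol,
                                   noise_level = 0.02, seed = 11)
  fit <- fit_correlation(curve, "3d1c", vol)
  expect_true(fit$converged)
  expect_lt(abs(fit$diffusion_coeff - 60) / 60, 0.10)
  # property: median relative error < 5% at 1% noise across many seeds
  errs <- vapply(1:100, function(s) {
    cv <- synth_correlation_curve(60, 10, volume = vol,
                                  noise_level = 0.01, seed = s)
    ft <- fit_correlation(cv, "3d1c", vol)
    abs(ft$diffusion_coeff - 60) / 60
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
})

test_that("correlation curves survive a CSV round trip", {
  curve <- synth_correlation_curve(30, 5, noise_level = 0.02, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_correlation_csv(curve, path)
  back <- read_correlation_csv(path)
  expect_equal(back$lag, curve$lag, tolerance = 1e-9)
  expect_equal(back$g, curve$g, tolerance = 1e-9)
  expect_equal(back$sigma, curve$sigma, tolerance = 1e-9)
  expect_identical(back$channel_kind, curve$channel_kind)
})
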