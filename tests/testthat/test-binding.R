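# Binding equilibrium, Kd estimation, and gradient-length theory.

test_that("bound fraction matches the bisection mass-action oracle", {
  # frozen oracle value for the reference receptor-excess condition
  expect_equal(bound_fraction(60, 100, 40000), 0.998498504140365,
               tolerance = 1e-12)
  # property: agreement with brute-force bisection across a parameter grid
  set.seed(42)
  for (i in 1:50) {
    kd <- 10^stats::runif(1, -1, 3)
    lt <- 10^stats::runif(1, 0, 3)
    rt <- 10^stats::runif(1, 0, 5)
    expect_equal(bound_fraction(kd, lt, rt),
                 oracle_bound_fraction_bisect(kd, lt, rt),
                 tolerance = 1e-10)
  }
})

test_that("bound fraction approaches the excess-receptor limit and is monotone", {
  # receptor-excess limit R/(R + Kd) within 0.2% when R >= 100 L
  for (kd in c(10, 60, 120, 500)) {
    lt <- 50
    rt <- 100 * lt
    expect_equal(bound_fraction(kd, lt, rt), rt / (rt + kd),
                 tolerance = 2e-3)
  }
  # increasing in receptor, decreasing in Kd, bounded in [0, 1]
  rts <- c(10, 100, 1000, 1e4, 1e5)
  fb_r <- bound_fraction(60, 100, rts)
  expect_true(all(diff(fb_r) > 0))
  kds <- c(1, 10, 100, 1000)
  fb_k <- bound_fraction(kds, 100, 1e4)
  expect_true(all(diff(fb_k) < 0))
  expect_true(all(fb_r >= 0 & fb_r <= 1))
})

test_that("effective diffusion scales the base coefficient by the free fraction", {
  expect_equal(effective_diffusion(30, 0.003), 0.09, tolerance = 1e-12)
  expect_equal(effective_diffusion(30, 0.0015), 0.045, tolerance = 1e-12)
  expect_equal(effective_diffusion(17.3, 1), 17.3, tolerance = 1e-12)
  expect_error(effective_diffusion(30, 0), "f_free")
  expect_error(effective_diffusion(30, 1.2), "f_free")
})

test_that("gradient length reproduces the source-sink relation and its limits", {
  expect_equal(gradient_length(60, 1e-4, 40000, 60),
               sqrt(60 / 1e-4) / sqrt(40000 / 60 + 1), tolerance = 1e-12)
  # vanishing receptor: unhindered source-sink length sqrt(D/k)
  expect_equal(gradient_length(60, 1e-4, 1e-9, 60), sqrt(60 / 1e-4),
               tolerance = 1e-6)
  # monotone: decreasing in receptor and clearance, increasing in D and Kd
  expect_true(all(diff(gradient_length(60, 1e-4, c(1e3, 1e4, 1e5), 60)) < 0))
  expect_true(all(diff(gradient_length(60, c(1e-5, 1e-4, 1e-3), 1e4, 60)) < 0))
  expect_true(all(diff(gradient_length(c(10, 60, 120), 1e-4, 1e4, 60)) > 0))
  expect_true(all(diff(gradient_length(60, 1e-4, 1e4, c(10, 60, 120))) > 0))
})

test_that("receptor concentration inverts the gradient-length relation", {
  # algebraic check: lambda = sqrt(D/k)/sqrt(2) and Kd = 1 give R = 1
  d <- 60; k <- 1e-4
  expect_equal(receptor_from_gradient(sqrt(d / k) / sqrt(2), d, k, 1), 1,
               tolerance = 1e-9)
  # round trip with gradient_length is the identity
  for (r in c(100, 5000, 40000)) {
    lam <- gradient_length(d, k, r, 60)
    expect_equal(receptor_from_gradient(lam, d, k, 60), r,
                 tolerance = 1e-9)
  }
  # a gradient at least as long as sqrt(D/k) has no binding solution
  expect_error(receptor_from_gradient(sqrt(d / k), d, k, 60),
               "no solution")
})

test_that("amplitude-to-concentration conversion follows the ideal FCCS relations", {
  vol <- observation_volume()
  # complete overlap: all particles are double-labelled complexes
  m <- concentrations_from_amplitudes(0.1, 0.1, 0.1, vol)
  expect_equal(m$c_g, 0, tolerance = 1e-9)
  expect_equal(m$c_r, 0, tolerance = 1e-9)
  expect_gt(m$c_gr, 0)
  # vanishing cross-correlation: no complexes
  m0 <- concentrations_from_amplitudes(0.1, 0.05, 1e-12, vol)
  expect_equal(m0$c_gr, 0, tolerance = 1e-6)
  # frozen unit-conversion oracle: V_eff = 0.35 fL, N_g = 10, N_r = 20,
  # N_gr = 5; C = N / (V_eff N_A), checked by hand
  vol35 <- observation_volume(omega0 = sqrt(0.35 / (pi^1.5 * 1.25)),
                              z0 = 1.25)
  expect_equal(vol35$v_eff, 0.35, tolerance = 1e-12)
  m2 <- concentrations_from_amplitudes(1 / 10, 1 / 20, 5 / 200, vol35)
  nm1 <- 1e9 / (0.35e-15 * 6.02214076e23) # nM per particle in 0.35 fL
  expect_equal(m2$c_g, 5 * nm1, tolerance = 1e-9)
  expect_equal(m2$c_r, 15 * nm1, tolerance = 1e-9)
  expect_equal(m2$c_gr, 5 * nm1, tolerance = 1e-9)
  # inconsistent amplitudes are rejected
  expect_error(concentrations_from_amplitudes(0.1, 0.05, 0.2, vol),
               "inconsistent")
})

test_that("regression estimator recovers Kd from exact and scaled data", {
  # exact mass-action data: product of free concentrations = 65 * complex
  d <- data.frame(c_g = c(10, 20, 40, 80), c_r = 65 * c(1, 1, 1, 1),
                  c_gr = c(10, 20, 40, 80))
  est <- kd_by_regression(d)
  expect_equal(est$kd_regression, 65, tolerance = 1e-9)
  # dimensional scaling: concentrations x10 scale Kd x10
  d10 <- d
  d10[c("c_g", "c_r", "c_gr")] <- d[c("c_g", "c_r", "c_gr")] * 10
  expect_equal(kd_by_regression(d10)$kd_regression, 650, tolerance = 1e-9)
  # degenerate inputs
  expect_error(kd_by_regression(data.frame(c_g = 1:4, c_r = 1:4,
                                           c_gr = rep(0, 4))),
               "no binding")
  expect_error(kd_by_regression(d[1:2, ]), "at least 3")
})

test_that("histogram estimator recovers the log-normal median and shifts exactly in log space", {
  # degenerate histogram: identical values
  est0 <- kd_by_histogram(rep(50, 10))
  expect_equal(est0$kd_hist_mode, 50, tolerance = 1e-12)
  # recovery of the log-normal median (1000 draws, median 29 nM)
  kds <- withr::with_seed(7, exp(stats::rnorm(1000, log(29), 0.4)))
  est <- kd_by_histogram(kds)
  expect_lt(abs(est$kd_hist_mode - 29) / 29, 0.05)
  # multiplying all values by c shifts the fitted mean by log(c)
  est_c <- kd_by_histogram(kds * 3.7)
  expect_equal(est_c$mu, est$mu + log(3.7), tolerance = 1e-6)
  expect_error(kd_by_histogram(c(-1, 2, 3, 4, 5)), "positive")
  expect_error(kd_by_histogram(c(10, 20)), "at least 5")
})

test_that("regression and histogram estimators agree on well-behaved data", {
  d <- synth_fccs_dataset(100, n_samples = 40, noise_level = 0.15,
                          seed = 5)
  est <- kd_by_regression(d)
  expect_false(is.na(est$kd_hist_mode))
  expect_lt(abs(est$kd_regression - est$kd_hist_mode) /
              est$kd_regression, 0.20)
})

test_that("binding measurements survive a CSV round trip", {
  d <- synth_fccs_dataset(65, n_samples = 8, noise_level = 0.1, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(embryo_id = d$embryo_id, c_g_nM = d$c_g,
                              c_r_nM = d$c_r, c_gr_nM = d$c_gr),
                   path, row.names = FALSE)
  back <- read_binding_csv(path)
  expect_equal(back$c_g, d$c_g, tolerance = 1e-9)
  expect_equal(kd_by_regression(back)$kd_regression,
               kd_by_regression(d)$kd_regression, tolerance = 1e-9)
})
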