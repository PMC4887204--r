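# Independent oracles used to generate and cross-check expected values.
# These deliberately avoid the package's own code paths.

# Brute-force bisection solve of the mass-action equilibrium
# [L][R]/[LR] = Kd under conservation; returns the bound ligand fraction.
oracle_bound_fraction_bisect <- function(kd, l_total, r_total,
                                         iter = 200L) {
  f <- function(lr) (l_total - lr) * (r_total - lr) / lr - kd
  lo <- .Machine$double.xmin
  hi <- min(l_total, r_total) * (1 - 1e-15)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2 / l_total
}

# Analytic average of exp(-x / lambda) over a bin [a, b].
oracle_bin_averaged_exp <- function(lambda, a, b) {
  lambda * (exp(-a / lambda) - exp(-b / lambda)) / (b - a)
}

# Standard log-spaced lag grid used across fitting tests.
test_lag_grid <- function(n = 200) exp(seq(log(1e-6), log(1),
                                           length.out = n))
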