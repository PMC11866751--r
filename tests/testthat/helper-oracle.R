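# Shared helpers: PERM-vs-enumeration comparison with empirical stochastic
# standard errors from independent replicate runs.

perm_replicates <- function(lattice, N, beta, n_reps = 5, tours = 2000,
                            seed = 1, bias_depth = 0,
                            population_control = TRUE) {
  lapply(seq_len(n_reps), function(r)
    perm_run(lattice, N = N, temp = 1 / beta_safe(beta), tours = tours,
             seed = 1000 * seed + r, bias_depth = bias_depth,
             population_control = population_control))
}

beta_safe <- function(beta) if (beta == 0) 1e-9 else beta

# mean +- 3 * sd/sqrt(n_reps) interval must cover `exact`
expect_covers <- function(values, exact, label = "") {
  m <- mean(values)
  se <- sd(values) / sqrt(length(values))
  tol <- 3 * se + 1e-9 * abs(exact)  # guard exact-agreement case
  expect_lt(abs(m - exact), max(tol, 1e-8),
            label = sprintf("%s: |%.5g - %.5g| vs 3se = %.3g", label, m,
                            exact, tol))
}

# Pooled ratio estimate over sub-runs with a jackknife standard error.
# Weighted observables are ratios of weighted sums; pooling numerators and
# denominators before dividing avoids the small-sample skew of per-run
# ratios, and the leave-one-run-out jackknife gives an honest error.
pooled_jackknife <- function(num, den) {
  est <- sum(num) / sum(den)
  R <- length(num)
  loo <- vapply(seq_len(R), function(i)
    sum(num[-i]) / sum(den[-i]), numeric(1))
  se <- sqrt((R - 1) / R * sum((loo - mean(loo))^2))
  list(est = est, se = se)
}

expect_pooled <- function(num, den, exact, label = "") {
  pj <- pooled_jackknife(num, den)
  tol <- 3 * pj$se + 1e-9 * abs(exact) + 1e-10
  expect_lt(abs(pj$est - exact), max(tol, 1e-8),
            label = sprintf("%s: |%.5g - %.5g| vs 3se_jk = %.3g", label,
                            pj$est, exact, tol))
}
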