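# The sampler's central property is unbiasedness: every estimate must agree
# with exhaustive enumeration within stochastic error, in every mode.

test_that("PERM reproduces exact partition sums and contact averages at small length", {
  lat <- tiny_lattice("checker", L = 11)
  for (beta in c(0, 1)) {
    ex <- enumerate_dual_walks(4, lat, beta = beta)
    for (pc in c(TRUE, FALSE)) {
      reps <- perm_replicates(lat, N = 4, beta = beta, n_reps = 5,
                              tours = 4000, seed = 11 + beta,
                              population_control = pc)
      Z <- vapply(reps, function(r) exp(r$log_Z[5]), numeric(1))
      nc <- vapply(reps, function(r) r$mean_nc[5], numeric(1))
      expect_covers(Z, ex$Z[5], sprintf("Z4 beta=%g pc=%s", beta, pc))
      expect_covers(nc, ex$mean_nc[5], sprintf("nc beta=%g pc=%s", beta, pc))
    }
  }
})

test_that("athermal Z_n equals the dual-walk count on the full lattice", {
  lat <- full_lattice(11)
  ex <- enumerate_dual_walks(4, lat, beta = 0)
  reps <- perm_replicates(lat, N = 4, beta = 0, n_reps = 5, tours = 4000,
                          seed = 3)
  for (n in 2:4) {
    Zn <- vapply(reps, function(r) exp(r$log_Z[n + 1]), numeric(1))
    expect_covers(Zn, ex$Z[n + 1], sprintf("athermal Z_%d", n))
  }
})

test_that("tours on a dead lattice still count as started", {
  dead <- tiny_lattice("blocked")
  r <- perm_run(dead, N = 3, temp = 1, tours = 50, seed = 1)
  expect_equal(r$tours, 50)
  expect_equal(r$log_Z[2], -Inf)   # no branch survives step 1
  expect_equal(exp(r$log_Z[1]), 1) # W_0 = 1 per tour
})

test_that("identical seeds give identical accumulators; different seeds differ", {
  lat <- full_lattice(15)
  a <- perm_run(lat, N = 6, temp = 0.9, tours = 500, seed = 42)
  b <- perm_run(lat, N = 6, temp = 0.9, tours = 500, seed = 42)
  expect_identical(a, b)
  c <- perm_run(lat, N = 6, temp = 0.9, tours = 500, seed = 43)
  expect_false(identical(a$log_Z, c$log_Z))
})

test_that("lattice occupancy does not leak across tours or runs", {
  lat <- tiny_lattice("checker", L = 11)
  before <- lat$state
  invisible(perm_run(lat, N = 5, temp = 0.8, tours = 300, seed = 9))
  expect_identical(lat$state, before)
  # a second run from the same lattice object is statistically identical
  r1 <- perm_run(lat, N = 5, temp = 0.8, tours = 300, seed = 10)
  r2 <- perm_run(lat, N = 5, temp = 0.8, tours = 300, seed = 10)
  expect_identical(r1, r2)
})

test_that("log-domain bookkeeping survives strongly bound chains", {
  # at T = 0.3 the weight at N = 120 is ~ exp(N / T) ~ 10^170; linear-space
  # accumulation would overflow
  mc <- melt_curve(N = 120, temps = 0.3, tours = 300, seed = 5)
  expect_true(is.finite(mc$log_Z[1]))
  expect_gt(mc$log_Z[1], 120 / 0.3 * 0.8)
  expect_gt(mc$frac_bound[1], 0.9)   # T -> 0: fully zipped dominates
})

test_that("contact distribution and bubble histogram agree with enumeration", {
  lat <- full_lattice(11)
  beta <- 1
  ex <- enumerate_dual_walks(4, lat, beta = beta)
  reps <- perm_replicates(lat, N = 4, beta = beta, n_reps = 5, tours = 4000,
                          seed = 21)
  for (m in c(2, 4, 5)) {  # P(n_c = m)
    est <- vapply(reps, function(r) r$p_nc[m + 1], numeric(1))
    expect_covers(est, ex$p_nc$prob[m + 1], sprintf("P(n_c = %d)", m))
  }
  # bubbles of size 2 and 3 are the only ones possible at n = 4
  for (s in c(2, 3)) {
    est <- vapply(reps, function(r) r$p_bubble[s + 1], numeric(1))
    expect_covers(est, ex$bubble$prob[s + 1], sprintf("P(l_b = %d)", s))
  }
  nb <- vapply(reps, function(r) r$mean_nb, numeric(1))
  expect_covers(nb, ex$mean_nb, "<n_b>")
})

test_that("the tour-weight diagnostic separates healthy from glitched sampling", {
  d_equal <- tour_weight_diagnostic(rep(2.5, 500))
  expect_equal(d_equal$overlap, 1)
  set.seed(1)
  d_ok <- tour_weight_diagnostic(rnorm(5000, sd = 1))
  d_bad <- tour_weight_diagnostic(rnorm(5000, sd = 10))
  expect_gt(d_ok$overlap, 0.8)
  expect_lt(d_bad$overlap, d_ok$overlap)
  expect_false(tour_weight_diagnostic(rnorm(50))$reliable)
})

test_that("tour weights are recorded on request and feed the diagnostic", {
  mc <- melt_curve(N = 30, temps = 0.75, tours = 3000, seed = 8,
                   keep_tour_weights = TRUE)
  lnw <- mc$ln_W[[1]]
  expect_gt(length(lnw), 100)
  diag <- tour_weight_diagnostic(lnw)
  expect_true(diag$reliable)
  expect_gt(diag$overlap, 0.3)
})
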