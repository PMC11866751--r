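make_ensemble <- function(log_Z, mean_nc, mean_nc2 = mean_nc^2) {
  tibble::tibble(realization = seq_along(log_Z), temp = 1, n = 4,
                 log_Z = log_Z, mean_nc = mean_nc, mean_nc2 = mean_nc2)
}

test_that("identical realizations reduce both averages to the single-lattice value", {
  ens <- make_ensemble(log_Z = c(2, 2, 2), mean_nc = c(1.5, 1.5, 1.5),
                       mean_nc2 = c(3, 3, 3))
  a <- annealed_average(ens)
  q <- quenched_average(ens)
  expect_equal(a$mean_nc, 1.5)
  expect_equal(q$mean_nc, 1.5)
  expect_equal(a$var_nc, 3 - 1.5^2)
  expect_equal(q$var_nc, a$var_nc)
})

test_that("annealed pooling weights by Z, quenched weights equally", {
  ens <- make_ensemble(log_Z = log(c(1, 3)), mean_nc = c(0, 1),
                       mean_nc2 = c(0, 1))
  expect_equal(annealed_average(ens)$mean_nc, 0.75)
  expect_equal(quenched_average(ens)$mean_nc, 0.5)
})

test_that("quenched averaging excludes zero-weight realizations and counts them", {
  ens <- make_ensemble(log_Z = c(0, -Inf, 0), mean_nc = c(1, NaN, 3))
  q <- quenched_average(ens)
  expect_equal(q$mean_nc, 2)
  expect_equal(q$n_real, 2)
  expect_equal(q$n_excluded, 1)
})

test_that("free energies follow their defining transforms", {
  ens <- make_ensemble(log_Z = log(c(2, 8)), mean_nc = c(1, 1))
  a <- annealed_average(ens)   # f_a = -T ln mean(Z) = -ln 5 at T = 1
  q <- quenched_average(ens)   # f_q = -T mean(ln Z)
  expect_equal(a$free_energy, -log(5))
  expect_equal(q$free_energy, -mean(log(c(2, 8))))
})

test_that("pooled annealed average matches pooled exact enumeration on two fixtures", {
  lats <- list(tiny_lattice("checker", L = 11), tiny_lattice("two_diluted", L = 11))
  beta <- 1
  ex <- lapply(lats, function(l) enumerate_dual_walks(4, l, beta = beta))
  Zs <- vapply(ex, function(e) e$Z[5], numeric(1))
  ncs <- vapply(ex, function(e) e$mean_nc[5], numeric(1))
  exact_pooled <- sum(Zs * ncs) / sum(Zs)

  rows <- purrr::map2_dfr(lats, c(1, 2), function(l, i) {
    reps <- perm_replicates(l, N = 4, beta = beta, n_reps = 1, tours = 20000,
                            seed = 40 + i)
    r <- reps[[1]]
    tibble::tibble(realization = i, temp = 1, n = 4, log_Z = r$log_Z[5],
                   mean_nc = r$mean_nc[5], mean_nc2 = r$mean_nc2[5])
  })
  a <- annealed_average(rows)
  expect_lt(abs(a$mean_nc - exact_pooled), 0.03)
  # quenched differs by construction here (equal weights over unequal Z)
  expect_lt(abs(quenched_average(rows)$mean_nc - mean(ncs)), 0.03)
})

test_that("a disorder ensemble runs end to end and both averages nearly coincide", {
  ens <- run_disorder_ensemble(p = 0.8, L = 101, N = 50,
                               temps = c(0.85, 0.95), realizations = 3,
                               tours = 3000, seed = 12)
  expect_s3_class(ens, "disorder_ensemble")
  avg <- disorder_average(ens)
  wide <- tidyr::pivot_wider(
    dplyr::select(avg, "mode", "temp", "n", "mean_nc"),
    names_from = "mode", values_from = "mean_nc")
  expect_true(all(abs(wide$annealed - wide$quenched) /
                    pmax(wide$annealed, 1) < 0.25))
})
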