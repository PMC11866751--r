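test_that("collapse fit recovers known parameters from exact synthetic curves", {
  syn <- synthetic_collapse_curves(t_m = 0.75, phi = 1, N = c(50, 100, 200),
                                   temps = seq(0.70, 0.80, by = 0.004))
  fit <- fit_collapse(syn, "n_c")
  expect_lt(abs(fit$t_m - 0.75) / 0.75, 0.01)
  expect_lt(abs(fit$phi - 1), 0.01)
  expect_lt(fit$quality, 1e-4)

  syn2 <- synthetic_collapse_curves(t_m = 0.9, phi = 0.6, N = c(80, 160, 320),
                                    temps = seq(0.80, 1.00, by = 0.004),
                                    observable = "C_c")
  fit2 <- fit_collapse(syn2, "C_c")
  expect_lt(abs(fit2$t_m - 0.9) / 0.9, 0.01)
  expect_lt(abs(fit2$phi - 0.6), 0.02)
})

test_that("collapse fit tolerates noise and reports parameters within uncertainty", {
  syn <- synthetic_collapse_curves(t_m = 0.75, phi = 1, N = c(50, 100, 200),
                                   temps = seq(0.70, 0.80, by = 0.004),
                                   noise_sd = 0.02, seed = 4)
  fit <- fit_collapse(syn, "n_c")
  expect_lt(abs(fit$t_m - 0.75), 0.01)
  expect_lt(abs(fit$phi - 1), 0.15)
})

test_that("collapse quality is invariant under relabeling and common rescaling", {
  syn <- synthetic_collapse_curves(t_m = 0.75, phi = 1, N = c(50, 100, 200),
                                   temps = seq(0.71, 0.79, by = 0.005),
                                   noise_sd = 0.05, seed = 9)
  q1 <- collapse_quality(syn, 0.75, 1, 1)$q
  shuffled <- syn[sample(nrow(syn)), ]
  expect_equal(collapse_quality(shuffled, 0.75, 1, 1)$q, q1)
  scaled <- dplyr::mutate(syn, value = value * 37)
  expect_equal(collapse_quality(scaled, 0.75, 1, 1)$q, q1, tolerance = 1e-10)
})

test_that("collapse fit refuses single curves and degenerate windows", {
  one <- synthetic_collapse_curves(N = 100, temps = seq(0.7, 0.8, 0.01))
  expect_error(fit_collapse(one, "n_c"), "two chain lengths")
})

test_that("tidy and glance expose collapse results in broom shape", {
  syn <- synthetic_collapse_curves(t_m = 0.75, phi = 1, N = c(50, 100),
                                   temps = seq(0.71, 0.79, by = 0.005))
  fit <- fit_collapse(syn, "n_c")
  td <- tidy(fit)
  expect_equal(td$term, c("t_m", "phi"))
  gl <- glance(fit)
  expect_equal(gl$n_curves, 2)
  expect_true(gl$converged)
})

test_that("bubble exponent fit recovers a known power law", {
  s <- synthetic_powerlaw(n = 2e5, c_true = 2.5, seed = 7)
  fit <- fit_bubble_exponent(s$dist)
  expect_lt(abs(fit$c - 2.5), 2 * fit$se + 0.05)
  expect_error(fit_bubble_exponent(tibble::tibble(size = 20:23,
                                                  prob = rep(0.25, 4))),
               "refused")
})

test_that("fluctuation peaks are located by quadratic interpolation", {
  grid <- seq(0.6, 0.9, by = 0.01)
  curves <- dplyr::bind_rows(
    tibble::tibble(N = 100, temp = grid, value = 1 - (grid - 0.75)^2),
    tibble::tibble(N = 200, temp = grid,
                   value = 5 / (1 + ((grid - 0.762) / 0.02)^2)))
  pk <- cc_peak_scaling(curves)
  expect_equal(pk$t_peak[pk$N == 100], 0.75, tolerance = 1e-6)
  expect_lt(abs(pk$t_peak[pk$N == 200] - 0.762), 0.01)
  expect_equal(pk$inv_N, 1 / pk$N)
  flat <- tibble::tibble(N = 50, temp = grid, value = 1)
  expect_true(cc_peak_scaling(flat)$no_peak)
  mono <- tibble::tibble(N = 50, temp = grid, value = grid)
  expect_true(cc_peak_scaling(mono)$no_peak)
})

test_that("phase-line fit recovers generating parameters and flags nonlinearity", {
  p <- seq(0.32, 1, by = 0.04)
  pts <- tibble::tibble(p = p, t_m = 1 / log(3.85 * p + 0.009))
  fit <- fit_phase_line(pts)
  expect_lt(abs(fit$c1 - 3.85) / 3.85, 0.01)
  expect_lt(abs(fit$c2 - 0.009), 0.005)
  # power law fitted on the weak-disorder window misses strongly diluted points
  strong <- abs(fit$residuals$power_law[fit$residuals$p < 0.5])
  weak <- abs(fit$residuals$power_law[fit$residuals$p >= 0.7])
  expect_gt(min(strong), max(weak))

  pow <- tibble::tibble(p = seq(0.6, 1, by = 0.05), t_m = 0.75 / seq(0.6, 1, by = 0.05))
  expect_equal(fit_phase_line(pow)$alpha, 1, tolerance = 1e-8)
  expect_error(fit_phase_line(pts[1:2, ]), "at least 3")
})

test_that("inflection estimator finds the steepest descent of the order parameter", {
  temps <- seq(0.6, 0.9, by = 0.005)
  curve <- tibble::tibble(temp = temps,
                          mean_nc = 100 / (1 + exp((temps - 0.77) / 0.01)))
  est <- estimate_tm_inflection(curve)
  expect_lt(abs(est$t_m - 0.77), 0.005)
})
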