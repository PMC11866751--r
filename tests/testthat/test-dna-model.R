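# Contact energetics, the Cartesian-product step set, and legal growth moves,
# probed through the exact enumerator at length 1 where counts are hand-derived.

test_that("the first step set on a full lattice has 36 pairs, 6 of them contacts", {
  ex0 <- enumerate_dual_walks(1, beta = 0)
  expect_equal(ex0$Z[2], 36)        # 6 x 6 ordered neighbour pairs
  expect_equal(ex0$n_configs, 36)
  # 6 contact pairs have n_c = 2 (origin + new pair), 30 have n_c = 1
  expect_equal(ex0$mean_nc[2], (30 * 1 + 6 * 2) / 36)

  ex1 <- enumerate_dual_walks(1, beta = 1)
  expect_equal(ex1$Z[2], 30 + 6 * exp(1))
})

test_that("Boltzmann factor per contact is exp(beta)", {
  # ratio of contact weight to non-contact weight in Z_1 decomposition
  for (beta in c(0.5, 1, 1.5)) {
    ex <- enumerate_dual_walks(1, beta = beta)
    expect_equal(ex$Z[2], 30 + 6 * exp(beta), tolerance = 1e-12)
  }
})

test_that("diluted neighbours shrink the step set to the product of free sets", {
  two_gone <- tiny_lattice("two_diluted")
  expect_equal(enumerate_dual_walks(1, two_gone, beta = 0)$Z[2], 16)  # 4 x 4
  blocked <- tiny_lattice("blocked")
  expect_equal(enumerate_dual_walks(1, blocked, beta = 0)$Z[2], 0)
})

test_that("partition sums grow with beta and never fall below the athermal count", {
  lat <- tiny_lattice("checker", L = 11)
  betas <- c(0, 0.5, 1, 1.5)
  Z3 <- vapply(betas, function(b) enumerate_dual_walks(3, lat, beta = b)$Z[4],
               numeric(1))
  expect_true(all(diff(Z3) > 0))
  expect_equal(Z3[1], enumerate_dual_walks(3, lat, beta = 0)$n_configs)
})

test_that("contact number is bounded by n + 1 and index 0 is always bound", {
  ex <- enumerate_dual_walks(3, beta = 2)
  p <- ex$p_nc
  expect_equal(sum(p$prob), 1, tolerance = 1e-12)
  expect_equal(p$prob[p$n_c == 0], 0)           # origin always paired
  expect_true(all(p$prob[p$n_c > 4] == 0))      # n_c <= n + 1
  expect_gt(p$prob[p$n_c == 4], 0)              # fully zipped exists
})

test_that("beta -> infinity concentrates the contact distribution at full zipping", {
  ex <- enumerate_dual_walks(3, beta = 12)
  expect_gt(ex$p_nc$prob[ex$p_nc$n_c == 4], 0.99)
  expect_equal(ex$mean_nc[4], 4, tolerance = 0.01)
})

test_that("pyramid layers have the stated geometry", {
  lat <- full_lattice(21)
  apex <- c(10L, 10L, 10L)
  s1 <- pyramid_scan_cpp(lat$state, lat$L, apex, 0L, 1L)
  expect_equal(length(s1$x), 9)                 # one 3x3 layer
  s3 <- pyramid_scan_cpp(lat$state, lat$L, apex, 0L, 3L)
  expect_equal(length(s3$x), 9 + 25 + 49)       # sum (2k+1)^2, k = 1..3
  expect_equal(s3$n_as, 83)
  expect_equal(s3$f_bias, 83)                   # empty lattice: 83 / (1 + 0)
  # apex excluded from every layer
  expect_false(any(s3$x == 10 & s3$y == 10 & s3$z == 10))
  # same count in all six directions in the bulk (symmetry)
  for (d in 1:5)
    expect_equal(length(pyramid_scan_cpp(lat$state, lat$L, apex, d, 3L)$x), 83)
})

test_that("pyramids clip at faces and fully diluted scans hit the floor", {
  lat <- full_lattice(9)
  edge <- c(8L, 4L, 4L)
  out <- pyramid_scan_cpp(lat$state, lat$L, edge, 0L, 3L)  # +x points outward
  expect_equal(length(out$x), 0)
  expect_equal(out$f_bias, 1e-6)

  dead <- tiny_lattice("blocked")
  ctr <- c(4L, 4L, 4L)
  sc <- pyramid_scan_cpp(dead$state, dead$L, ctr, 0L, 1L)
  expect_lt(sc$n_as, 9)                         # diluted sites not available
})

test_that("bias factor arithmetic follows n_as / (1 + n_os)", {
  # occupy 9 sites inside a +x pyramid of depth 3 and count
  lat <- full_lattice(21)
  st <- array(lat$state, dim = c(21, 21, 21))
  for (i in -1:1) for (j in -1:1)
    st[10 + 1 + 1, 10 + i + 1, 10 + j + 1] <- 2L   # the whole depth-1 layer
  lat$state <- as.integer(st)
  sc <- pyramid_scan_cpp(lat$state, lat$L, c(10L, 10L, 10L), 0L, 3L)
  expect_equal(sc$n_os, 9)
  expect_equal(sc$f_bias, sc$n_as / (1 + 9))
})
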