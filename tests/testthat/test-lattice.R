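test_that("certain retention fills the box and spans; certain dilution leaves the seed alone", {
  full <- leath_lattice(5, p = 1, seed = 1)
  expect_equal(sum(full$state == 1), 125)
  expect_true(is_spanning(full))

  lone <- leath_lattice(5, p = 0, seed = 1)
  expect_equal(sum(lone$state == 1), 1)
  expect_equal(lone$cluster_size, 1)
  # the seed's 6 neighbours were visited and rejected
  expect_equal(sum(lone$visited), 7)
  expect_false(is_spanning(lone))
})

test_that("invalid parameters are rejected", {
  expect_error(leath_lattice(4, 0.5), "odd")
  expect_error(leath_lattice(9, 1.5), "probability")
  expect_error(leath_lattice(1, 0.5), "odd|>= 3")
})

test_that("disorder is quenched: same seed reproduces the lattice bit for bit", {
  for (m in c("depth_first", "breadth_first")) {
    a <- leath_lattice(21, 0.45, seed = 99, method = m)
    b <- leath_lattice(21, 0.45, seed = 99, method = m)
    expect_identical(a$state, b$state)
    expect_identical(a$visited, b$visited)
  }
  expect_false(identical(leath_lattice(21, 0.45, seed = 1)$state,
                         leath_lattice(21, 0.45, seed = 2)$state))
})

test_that("dilution is calibrated: available fraction among visited non-seed sites is p", {
  for (p in c(0.3116, 0.6, 0.8)) {
    avail <- 0; visited <- 0
    for (i in 1:60) {
      lat <- leath_lattice(49, p, seed = 7000 + i)
      visited <- visited + sum(lat$visited) - 1  # exclude the seed
      avail <- avail + sum(lat$state == 1) - 1
    }
    expect_gt(visited, 1e5)
    se <- sqrt(p * (1 - p) / visited)
    expect_lt(abs(avail / visited - p), 3 * se + 1e-12)
  }
})

test_that("well-subcritical media almost never span", {
  spans <- sum(vapply(1:1000, function(i)
    is_spanning(leath_lattice(49, 0.2, seed = i)), logical(1)))
  expect_lte(spans, 1)
})

test_that("depth- and breadth-first growth give the same cluster-mass statistics", {
  m_df <- vapply(1:1000, function(i)
    leath_lattice(33, 0.3116, seed = i, method = "depth_first")$cluster_size,
    numeric(1))
  m_bf <- vapply(1:1000, function(i)
    leath_lattice(33, 0.3116, seed = i + 5000,
                  method = "breadth_first")$cluster_size, numeric(1))
  ks <- suppressWarnings(stats::ks.test(m_df, m_bf))
  expect_gt(ks$p.value, 0.001)
})

test_that("spanning generation retries and reports attempts; exhaustion raises", {
  lat <- spanning_lattice(5, 1, seed = 1)
  expect_equal(lat$attempts, 1)
  lat2 <- spanning_lattice(33, 0.35, seed = 2, max_attempts = 2000)
  expect_true(is_spanning(lat2))
  err <- expect_error(spanning_lattice(49, 0.05, seed = 3, max_attempts = 50),
                      class = "crowdmelt_spanning_failure")
  expect_equal(err$attempts, 50)
})

test_that("mass-radius slope recovers the Euclidean dimension on the full box", {
  fit <- fractal_dimension(full_lattice(41), r_min = 2, r_max = 10)
  expect_lt(abs(fit$d_f - 3), 0.1)
})

test_that("a planar site set has mass-radius dimension 2", {
  plane <- tiny_lattice("plane", L = 41)
  fit <- fractal_dimension(plane, r_min = 2, r_max = 10)
  expect_lt(abs(fit$d_f - 2), 0.1)
})

test_that("mass-radius profile is nondecreasing and bounded by cluster size", {
  lat <- spanning_lattice(33, 0.4, seed = 5)
  prof <- mass_radius(lat)
  expect_true(all(diff(prof$mass) >= 0))
  expect_lte(max(prof$mass), lat$cluster_size)
  expect_error(fractal_dimension(lat, r_min = 2, r_max = 2.5), "fewer than 3")
})

test_that("spanning curves fall with L below threshold and rise above", {
  cur <- spanning_curve(p = c(0.26, 0.40), L = c(9, 17), realizations = 400,
                        seed = 3)
  below <- dplyr::filter(cur, p == 0.26)
  above <- dplyr::filter(cur, p == 0.40)
  # larger boxes span less often below p_c, at least as often above
  expect_lt(below$spanning_frac[below$L == 17],
            below$spanning_frac[below$L == 9] + 0.02)
  expect_gt(above$spanning_frac[above$L == 17] + 0.05,
            above$spanning_frac[above$L == 9])
  expect_error(estimate_threshold(dplyr::filter(cur, L == 9)), "two L")
})

test_that("lattices round-trip through run-length text serialization", {
  lat <- leath_lattice(21, 0.45, seed = 31)
  path <- tempfile(fileext = ".txt")
  write_lattice(lat, path)
  back <- read_lattice(path)
  expect_identical(back$state, lat$state)
  expect_equal(back$L, lat$L)
  expect_equal(back$p, lat$p)
  expect_equal(back$seed, lat$seed)
  expect_equal(back$method, lat$method)
  # sampler results are identical on the restored lattice
  expect_identical(perm_run(lat, N = 4, temp = 1, tours = 200, seed = 2),
                   perm_run(back, N = 4, temp = 1, tours = 200, seed = 2))
  # loader validates invariants
  writeLines("garbage", path)
  expect_error(read_lattice(path), "not a crowdmelt lattice")
})
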