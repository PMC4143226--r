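test_that("basis sets are regular and carry the advertised mass", {
  arr <- small_array()
  cfg <- basis_config(arr, span = c(0, 1500))
  bas <- build_basis(cfg, arr)
  expect_length(bas$centers, cfg$n_bases)
  expect_lt(diff(range(diff(bas$centers))), 1e-10)

  # Gaussian basis integrates to its closed-form mass (error-function)
  i <- 12
  num <- integrate(function(x) bas$value(x, i), 0, 1500,
                   rel.tol = 1e-10)$value
  w <- cfg$width; c0 <- bas$centers[i]
  analytic <- sqrt(2 * pi) * w *
    (pnorm(1500, c0, w) - pnorm(0, c0, w))
  expect_lt(abs(num - analytic) / analytic, 1e-6)

  # step bases tile the span disjointly
  cfg_s <- basis_config(arr, type = "step", span = c(0, 1500))
  bas_s <- build_basis(cfg_s, arr)
  xs <- seq(0.1, 1499.9, length.out = 500)
  cover <- rowSums(vapply(seq_along(bas_s$centers),
                          function(i) bas_s$value(xs, i),
                          numeric(length(xs))))
  expect_true(all(cover == 1))

  expect_error(basis_config(arr, n_bases = 3) |> build_basis(arr),
               "at least")
  expect_error(build_basis(basis_config(arr, span = c(400, 700)), arr),
               "cover")
})

test_that("basis potentials match Monte Carlo disc integration and scaling", {
  arr <- electrode_array(c(300, 500, 900))
  cfg <- basis_config(arr, n_bases = 10, width = 100, span = c(0, 1200),
                      disc_radius = 150)
  bas <- build_basis(cfg, arr)
  bp <- basis_potentials(bas, cfg, arr, sigma = 0.3)
  expect_equal(dim(bp), c(10, 3))
  expect_true(all(bp > 0))
  # each basis potential peaks at the contact nearest its center
  for (i in c(3, 5, 8)) {
    expect_equal(which.max(bp[i, ]),
                 which.min(abs(arr$depths - bas$centers[i])))
  }
  # conductivity scaling: sigma -> c sigma divides potentials by c
  bp2 <- basis_potentials(bas, cfg, arr, sigma = 0.6)
  expect_equal(bp2, bp / 2, tolerance = 1e-10)

  # Monte Carlo oracle: sample the 3D disc-smeared source density of one
  # basis element and average point-source potentials at one contact
  set.seed(99)
  n_mc <- 1e6
  i <- 5
  # importance sample depth from the (normalized) Gaussian basis profile,
  # uniform over the disc
  zs <- rnorm(n_mc, bas$centers[i], cfg$width)
  rr <- cfg$disc_radius * sqrt(runif(n_mc))
  th <- runif(n_mc, 0, 2 * pi)
  contact <- c(0, 0, arr$depths[2])
  d <- sqrt((rr * cos(th))^2 + (rr * sin(th))^2 + (zs - contact[3])^2)
  # total source mass of the element: integral of the profile over depth
  # times unity volume density (per unit area spread over the disc)
  mass_depth <- sqrt(2 * pi) * cfg$width
  disc_area <- pi * cfg$disc_radius^2
  mc <- mass_depth * disc_area * mean(1 / (4 * pi * 0.3 * d))
  expect_lt(abs(mc - bp[i, 2]) / bp[i, 2], 0.005)
})

test_that("the kernel matrices are symmetric positive semidefinite", {
  arr <- small_array()
  eng <- kcsd_engine(arr, 0.3, basis_config(arr, span = c(0, 1500),
                                            n_grid = 60))
  expect_equal(eng$K, t(eng$K))
  ev <- eigen(eng$K, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10 * max(ev))
})

test_that("kCSD reconstruction inverts basis-consistent potentials", {
  arr <- laminar_array()
  cfg <- basis_config(arr)
  eng <- kcsd_engine(arr, 0.3, cfg)
  bas <- build_basis(cfg, arr)

  # all-zero potentials give an all-zero estimate
  zero <- potential_recording(arr, matrix(0, 26, 4), 0.3, 0.1)
  expect_true(all(reconstruct_csd(zero, lambda = 1e-8,
                                  engine = eng)$values == 0))

  # potentials of a single basis element inside the electrode span are
  # reconstructed to that element
  i <- 24   # center ~ 800 um
  rec <- potential_recording(arr, matrix(eng$b_pot[i, ], ncol = 1), 0.3, 0.1)
  est <- reconstruct_csd(rec, lambda = 1e-8, engine = eng)
  expect_gte(cor(est$values[, 1], bas$value(eng$grid, i)), 0.99)

  # reconstruction is linear in the measured potentials
  v1 <- matrix(eng$b_pot[20, ], ncol = 1)
  v2 <- matrix(eng$b_pot[30, ], ncol = 1)
  ra <- reconstruct_csd(potential_recording(arr, v1, 0.3, 0.1),
                        lambda = 1e-4, engine = eng)$values
  rb <- reconstruct_csd(potential_recording(arr, v2, 0.3, 0.1),
                        lambda = 1e-4, engine = eng)$values
  rab <- reconstruct_csd(potential_recording(arr, 2 * v1 - 5 * v2, 0.3, 0.1),
                         lambda = 1e-4, engine = eng)$values
  expect_equal(rab, 2 * ra - 5 * rb, tolerance = 1e-9)

  # ridge shrinkage: Frobenius norm decreases monotonically in lambda
  ds <- realize_scenario(two_pop_scenario())
  lams <- mean(diag(eng$K)) * 10^seq(-8, 0, length.out = 9)
  norms <- vapply(lams, function(l) {
    fn <- reconstruct_csd(ds$lfp, lambda = l, engine = eng)$values
    sqrt(sum(fn^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))

  # at lambda -> 0 the estimate maps forward to the measured potentials
  lam <- 1e-12 * mean(diag(eng$K))
  coefs <- eng$b_pot %*% solve(eng$K + lam * diag(26), ds$lfp$values)
  v_hat <- t(eng$b_pot) %*% coefs
  expect_lt(sqrt(sum((v_hat - ds$lfp$values)^2) / sum(ds$lfp$values^2)),
            1e-6)
})

test_that("reconstruction is stable under basis refinement", {
  arr <- laminar_array()
  ds <- realize_scenario(two_pop_scenario())
  cfg1 <- basis_config(arr)                         # M = 78
  cfg2 <- basis_config(arr, n_bases = 2 * cfg1$n_bases)
  # the kernel scales with basis density, so hold the penalty fixed
  # relative to the kernel diagonal
  lam_rel <- 1e-6
  eng1 <- kcsd_engine(arr, 0.3, cfg1)
  eng2 <- kcsd_engine(arr, 0.3, cfg2)
  r1 <- reconstruct_csd(ds$lfp, engine = eng1,
                        lambda = lam_rel * mean(diag(eng1$K)))
  r2 <- reconstruct_csd(ds$lfp, engine = eng2,
                        lambda = lam_rel * mean(diag(eng2$K)))
  # kernels scale with M; compare shapes, not raw amplitudes
  a <- r1$values / sqrt(sum(r1$values^2))
  b <- r2$values / sqrt(sum(r2$values^2))
  expect_lt(sqrt(sum((a - b)^2)), 0.01)
})

test_that("leave-one-out cross-validation picks sensible penalties", {
  arr <- laminar_array()
  cfg <- basis_config(arr)
  eng <- kcsd_engine(arr, 0.3, cfg)
  cands <- mean(diag(eng$K)) * 10^seq(-8, 0, length.out = 9)

  # the selection equals the argmin of an independently computed
  # leave-one-out error table
  rec <- potential_recording(arr, matrix(eng$b_pot[24, ], ncol = 1), 0.3, 0.1)
  cv_table <- vapply(cands, function(lam) {
    tot <- 0
    for (i in seq_len(26)) {
      ki <- eng$K[-i, -i] + lam * diag(25)
      pred <- eng$K[i, -i, drop = FALSE] %*%
        solve(ki, rec$values[-i, , drop = FALSE])
      tot <- tot + sum((pred - rec$values[i, ])^2)
    }
    tot
  }, numeric(1))
  sel <- choose_lambda(rec, engine = eng, lambdas = cands)
  expect_equal(sel, cands[which.min(cv_table)])
  # noise-free consistent data sits at the light end of the grid
  expect_lte(sel, cands[3])

  # pure-noise data needs at least as much regularization
  set.seed(4)
  noise <- potential_recording(arr, matrix(rnorm(26 * 50), 26), 0.3, 0.1)
  expect_gte(choose_lambda(noise, engine = eng, lambdas = cands), sel)

  expect_equal(choose_lambda(rec, engine = eng, lambdas = 3.14), 3.14)

  tiny <- potential_recording(electrode_array(c(100, 200)),
                              matrix(0, 2, 3), 0.3, 0.1)
  expect_error(choose_lambda(tiny, config = basis_config(tiny$array)),
               "insufficient")
})

test_that("traditional CSD matches closed forms and kCSD on smooth sources", {
  sigma <- 0.3
  z <- seq(100, 1000, by = 100)
  arr <- electrode_array(z)
  # linear potential profile: zero curvature, zero CSD
  lin <- potential_recording(arr, matrix(rep(0.002 * z, 2), ncol = 2), sigma,
                             0.1)
  expect_lt(max(abs(traditional_csd(lin)$values)), 1e-15)

  # quadratic profile V = z^2 -> constant CSD -2 sigma
  quad <- potential_recording(arr, matrix(z^2, ncol = 1), sigma, 0.1)
  expect_equal(traditional_csd(quad)$values[, 1],
               rep(-2 * sigma, length(z) - 2), tolerance = 1e-9)

  # Smooth dipolar source sampled densely: the finite-difference estimator
  # assumes laterally uniform sources, which is the wide-disc limit of the
  # kernel estimator, so the two agree when kCSD uses a wide disc radius.
  dense <- electrode_array(seq(100, 1400, by = 25))
  src <- build_population(
    population_spec("s", c(400, 1000), n_sources = 200, rank = 1,
                    dipole_extent = 400),
    column_geometry(), seed = 3)
  rec <- potential_from_points(src, dense, sigma)
  trad <- traditional_csd(rec)
  cfg <- basis_config(dense, span = c(100, 1400), disc_radius = 500,
                      n_grid = length(dense$depths))
  eng_d <- kcsd_engine(dense, sigma, cfg)
  kc <- reconstruct_csd(rec, engine = eng_d,
                        lambda = 1e-8 * mean(diag(eng_d$K)))
  inner <- 2:(length(dense$depths) - 1)
  expect_gte(cor(as.vector(trad$values), as.vector(kc$values[inner, ])),
             0.95)

  uneven <- potential_recording(electrode_array(c(0, 100, 250)),
                                matrix(1, 3, 2), sigma, 0.1)
  expect_error(traditional_csd(uneven), "invalid geometry")
})
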