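test_that("truncated PCA is the Eckart-Young optimum with consistent energy", {
  x <- random_lowrank(60, 300, rank = 8, seed = 2, noise = 0.3)
  pca <- pca_truncate(x, 4)

  # orthonormal factors, non-increasing singular values
  expect_equal(crossprod(pca$eigenimages), diag(4), tolerance = 1e-12)
  expect_equal(tcrossprod(pca$eigensequences), diag(4), tolerance = 1e-12)
  expect_true(all(diff(pca$singular_values) <= 0))

  # singular values are square roots of Gram-matrix eigenvalues
  gram_eigs <- eigen(x %*% t(x), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(pca$singular_values, sqrt(gram_eigs[1:4]), tolerance = 1e-9)

  # truncation error^2 equals the sum of squared discarded singular values
  full_d <- svd(x)$d
  err2 <- sum((x - pca_reconstruct(pca))^2)
  expect_equal(err2, sum(full_d[-(1:4)]^2), tolerance = 1e-9)

  # total energy conservation
  expect_equal(sum(pca$all_singular_values^2), sum(x^2), tolerance = 1e-9)

  # sign convention: largest-magnitude eigenimage entry is positive
  for (k in 1:4) {
    expect_gt(pca$eigenimages[which.max(abs(pca$eigenimages[, k])), k], 0)
  }

  # exact rank-1 input reconstructs exactly at K = 1
  r1 <- outer(rnorm(30), rnorm(50))
  p1 <- pca_truncate(r1, 1)
  expect_lt(max(abs(pca_reconstruct(p1) - r1)), 1e-12 * max(abs(r1)))

  expect_error(pca_truncate(x, 0), "invalid")
  expect_error(pca_truncate(x, 100), "invalid")
})

test_that("the infomax objective gradient matches finite differences", {
  set.seed(42)
  k <- 3
  ut_t <- matrix(rnorm(k * 40), k)
  vt <- matrix(rnorm(k * 60), k)
  for (alpha in c(0, 0.5, 1)) {
    par <- as.vector(diag(k) + 0.2 * matrix(rnorm(k * k), k))
    vg <- lampop:::stica_value_grad(par, ut_t, vt, alpha)
    num <- vapply(seq_along(par), function(i) {
      h <- 1e-6
      p1 <- par; p1[i] <- p1[i] + h
      p2 <- par; p2[i] <- p2[i] - h
      (lampop:::stica_value_grad(p1, ut_t, vt, alpha)$value -
         lampop:::stica_value_grad(p2, ut_t, vt, alpha)$value) / (2 * h)
    }, numeric(1))
    expect_equal(vg$grad, num, tolerance = 1e-5)
  }
})

test_that("spatial ICA recovers independent heavy-tailed maps", {
  set.seed(7)
  n_sp <- 200; n_t <- 500
  s1 <- rexp(n_sp) * sign(rnorm(n_sp))   # Laplacian-like sparse maps
  s2 <- rexp(n_sp) * sign(rnorm(n_sp))
  x <- outer(s1, rnorm(n_t)) + outer(s2, rnorm(n_t)) +
    0.4 * outer(s1, rnorm(n_t))
  pca <- pca_truncate(x, 2)

  for (seed in 1:5) {
    ica <- spatial_ica(pca, 2, seed = seed)
    expect_true(all(match_abs_cor(ica$spatial, rbind(s1, s2)) >= 0.95))
  }

  # K = 1: single component equals the first principal component up to sign
  p1 <- pca_truncate(x, 1)
  i1 <- spatial_ica(p1, 1, seed = 1)
  expect_gte(abs(cor(i1$spatial[1, ], p1$eigenimages[, 1])), 1 - 1e-10)

  # unmixed spatial maps are mutually near-uncorrelated
  ica <- spatial_ica(pca, 2, seed = 1)
  expect_lt(abs(cor(ica$spatial[1, ], ica$spatial[2, ])), 0.05)

  # bitwise reproducibility given the same seed
  again <- spatial_ica(pca, 2, seed = 1)
  expect_identical(ica$spatial, again$spatial)
  expect_identical(ica$unmixing, again$unmixing)

  expect_error(spatial_ica(pca, 3), "truncation order")
})

test_that("temporal ICA recovers independent light-tailed sequences", {
  set.seed(11)
  n_sp <- 150; n_t <- 800
  t1 <- runif(n_t, -1, 1); t2 <- runif(n_t, -1, 1)
  x <- outer(rnorm(n_sp), t1) + outer(rnorm(n_sp), t2) +
    0.3 * outer(rnorm(n_sp), t1)
  pca <- pca_truncate(x, 2)
  tica <- temporal_ica(pca, 2, seed = 5)
  expect_true(all(match_abs_cor(tica$temporal, rbind(t1, t2)) >= 0.95))

  # K = 1 equals the first eigensequence up to sign
  p1 <- pca_truncate(x, 1)
  t_one <- temporal_ica(p1, 1, seed = 2)
  expect_gte(abs(cor(t_one$temporal[1, ], p1$eigensequences[1, ])),
             1 - 1e-10)

  # the dual profiles reconstruct the truncated data exactly
  maps <- components_to_maps(tica)
  expect_lt(max(abs(Reduce(`+`, maps) - pca_reconstruct(pca))),
            1e-8 * max(abs(pca_reconstruct(pca))))
})

test_that("the fixed-point backend agrees with infomax on clean mixtures", {
  set.seed(21)
  s1 <- rexp(180) * sign(rnorm(180)); s2 <- rexp(180) * sign(rnorm(180))
  x <- outer(s1, rnorm(400)) + outer(s2, rnorm(400)) +
    0.3 * outer(s2, rnorm(400))
  pca <- pca_truncate(x, 2)
  im <- spatial_ica(pca, 2, seed = 3)
  fp <- spatial_ica(pca, 2, seed = 3, backend = "fixedpoint")
  expect_true(all(match_abs_cor(fp$spatial, im$spatial) >= 0.95))
  # fixed-point factorization is also exact
  expect_lt(max(abs(Reduce(`+`, components_to_maps(fp)) -
                      pca_reconstruct(pca))),
            1e-8 * max(abs(pca_reconstruct(pca))))

  t1 <- runif(500, -1, 1); t2 <- runif(500, -1, 1)
  y <- outer(rnorm(120), t1) + outer(rnorm(120), t2)
  pcy <- pca_truncate(y, 2)
  imt <- temporal_ica(pcy, 2, seed = 4)
  fpt <- temporal_ica(pcy, 2, seed = 4, backend = "fixedpoint")
  expect_true(all(match_abs_cor(fpt$temporal, imt$temporal) >= 0.95))
})

test_that("spatiotemporal ICA interpolates between its endpoint objectives", {
  set.seed(9)
  s1 <- rexp(150) * sign(rnorm(150)); s2 <- rexp(150) * sign(rnorm(150))
  t1 <- runif(400, -1, 1); t2 <- runif(400, -1, 1)
  x <- outer(s1, t1) + 0.8 * outer(s2, t2)
  pca <- pca_truncate(x, 2)

  sic <- spatial_ica(pca, 2, seed = 6)
  st1 <- spatiotemporal_ica(pca, 2, alpha = 1, seed = 6)
  expect_true(all(match_abs_cor(st1$spatial, sic$spatial) >= 0.99))

  tic <- temporal_ica(pca, 2, seed = 6)
  st0 <- spatiotemporal_ica(pca, 2, alpha = 0, seed = 6)
  expect_true(all(match_abs_cor(st0$temporal, tic$temporal) >= 0.99))

  # intermediate alpha still factorizes the truncated data exactly
  st <- spatiotemporal_ica(pca, 2, alpha = 0.5, seed = 6)
  xk <- pca_reconstruct(pca)
  expect_lte(sqrt(sum((Reduce(`+`, components_to_maps(st)) - xk)^2)),
             1.01 * sqrt(sum((x - xk)^2)) + 1e-8)

  expect_error(spatiotemporal_ica(pca, 2, alpha = 2), "alpha")
})

test_that("component maps are rank-1, sign-invariant and sum to the input", {
  x <- random_lowrank(50, 200, rank = 3, seed = 13, noise = 0.1)
  pca <- pca_truncate(x, 3)
  ica <- spatial_ica(pca, 3, seed = 2)
  maps <- components_to_maps(ica)
  expect_length(maps, 3)
  for (m in maps) {
    d <- svd(m)$d
    expect_lt(d[2], 1e-10 * d[1])
  }
  xk <- pca_reconstruct(pca)
  expect_lt(max(abs(Reduce(`+`, maps) - xk)), 1e-8 * max(abs(xk)))

  # negating a profile and its course leaves the map unchanged
  m1 <- outer(ica$spatial[1, ], ica$temporal[1, ])
  m1_flip <- outer(-ica$spatial[1, ], -ica$temporal[1, ])
  expect_identical(m1, m1_flip)

  # components are ordered by map variance
  vars <- vapply(maps, function(m) var(as.vector(m)), numeric(1))
  expect_true(all(diff(vars) <= 1e-12))
})

test_that("a numerically degenerate PCA subspace is rejected for ICA", {
  x <- outer(rnorm(40), rnorm(80))          # exact rank 1
  pca <- pca_truncate(x, 2)
  expect_error(spatial_ica(pca, 2, seed = 1), "degenerate")
})
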