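test_that("point-source potential reproduces the closed form and superposes", {
  sigma <- 0.3
  arr <- electrode_array(c(100, 200))
  # unit identity: I = 4*pi*sigma at distance 1 um -> potential exactly 1
  src <- point_source_set(matrix(c(0, 1, 100), 1), matrix(4 * pi * sigma, 1, 1),
                          dt = 0.1)
  expect_equal(potential_from_points(src, arr, sigma)$values[1, 1], 1)

  # zero currents -> zero potentials
  src0 <- point_source_set(matrix(c(0, 50, 150), 1), matrix(0, 1, 5), dt = 0.1)
  expect_true(all(potential_from_points(src0, arr, sigma)$values == 0))

  # two sources equal the scalar-loop sum of single-source evaluations
  set.seed(1)
  pos <- cbind(runif(2, -50, 50), runif(2, 20, 80), runif(2, 50, 400))
  cur <- matrix(rnorm(6), 2, 3)
  both <- potential_from_points(point_source_set(pos, cur, 0.1), arr, sigma)
  oracle <- matrix(0, 2, 3)
  for (j in 1:2) {
    for (i in 1:2) {
      contact <- c(0, 0, arr$depths[i])
      r <- sqrt(sum((contact - pos[j, ])^2))
      oracle[i, ] <- oracle[i, ] + cur[j, ] / (4 * pi * sigma * r)
    }
  }
  expect_equal(both$values, oracle, tolerance = 1e-14)

  # superposition over an arbitrary partition of a larger source set
  set.seed(2)
  pos <- cbind(runif(10, -100, 100), runif(10, 30, 150), runif(10, 0, 1000))
  cur <- matrix(rnorm(40), 10, 4)
  all_v <- potential_from_points(point_source_set(pos, cur, 0.1), arr, sigma)
  part1 <- potential_from_points(point_source_set(pos[1:4, ], cur[1:4, ], 0.1),
                                 arr, sigma)
  part2 <- potential_from_points(point_source_set(pos[5:10, ], cur[5:10, ], 0.1),
                                 arr, sigma)
  expect_equal(all_v$values, part1$values + part2$values,
               tolerance = 1e-14)
})

test_that("potential follows 1/r for a monopole and decays faster for a dipole", {
  sigma <- 0.3
  src <- point_source_set(matrix(c(0, 0, 0), 1), matrix(1, 1, 1), dt = 0.1)
  arr <- electrode_array(c(100, 200))   # second contact at twice the distance
  v <- potential_from_points(src, arr, sigma)$values
  expect_equal(v[1, 1] / v[2, 1], 2)

  # current-conserving pair: far-field decay strictly faster than 1/r
  dip <- point_source_set(rbind(c(0, 0, 0), c(0, 0, 20)),
                          rbind(1, -1), dt = 0.1)
  arr2 <- electrode_array(c(500, 1000))
  vd <- potential_from_points(dip, arr2, sigma)$values
  expect_lt(abs(vd[2, 1] / vd[1, 1]), 0.5)
})

test_that("degenerate source-contact geometry is rejected", {
  arr <- electrode_array(c(100, 200))
  src <- point_source_set(matrix(c(0, 0, 100), 1), matrix(1, 1, 1), dt = 0.1)
  expect_error(potential_from_points(src, arr, 0.3), "degenerate")
})

test_that("line sources agree with dense point quadrature and the far field", {
  sigma <- 0.3
  ds <- 100
  a <- c(0, 0, 450); b <- c(0, 0, 450 + ds)
  cur <- matrix(2.5, 1, 1)
  lines <- line_source_set(rbind(a), rbind(b), cur, dt = 0.1)
  # contacts at lateral distances beyond one segment length
  arr <- electrode_array(c(500, 700, 1200), lateral = c(150, 0))
  v_line <- potential_from_lines(lines, arr, sigma)$values

  # oracle: the same current spread over 1000 point sources along the segment
  n_pt <- 1000
  zs <- seq(450 + ds / (2 * n_pt), 450 + ds - ds / (2 * n_pt),
            length.out = n_pt)
  pts <- point_source_set(cbind(0, 0, zs),
                          matrix(2.5 / n_pt, n_pt, 1), dt = 0.1)
  v_pts <- potential_from_points(pts, arr, sigma)$values
  expect_lt(max(abs(v_line - v_pts) / abs(v_pts)), 0.005)

  # far field: line -> point source of the summed current within 1%
  far <- electrode_array(3000, lateral = c(2000, 0))
  v_far_line <- potential_from_lines(lines, far, sigma)$values
  v_far_pt <- potential_from_points(
    point_source_set(rbind((a + b) / 2), cur, 0.1), far, sigma)$values
  expect_lt(abs(v_far_line - v_far_pt) / abs(v_far_pt), 0.01)

  # zero currents -> zero potentials
  z <- potential_from_lines(line_source_set(rbind(a), rbind(b),
                                            matrix(0, 1, 3), 0.1),
                            arr, sigma)
  expect_true(all(z$values == 0))

  # a contact on the segment is degenerate
  on_seg <- electrode_array(c(500), lateral = c(0, 0))
  expect_error(potential_from_lines(lines, on_seg, sigma), "degenerate")
})

test_that("zero-phase Butterworth LFP filter has the expected gain structure", {
  dt <- 0.1                     # ms -> fs = 10 kHz
  n <- 8192
  arr <- electrode_array(c(100))
  const <- potential_recording(arr, matrix(5, 1, n), 0.3, dt)
  expect_equal(lowpass_lfp(const, 500)$values, const$values,
               tolerance = 1e-10)

  # sinusoid at the cutoff: zero-phase gain = squared half-power = 0.5
  f <- 500
  t <- (seq_len(n) - 1) * dt / 1000
  x <- sin(2 * pi * f * t)
  rec <- potential_recording(arr, matrix(x, 1), 0.3, dt)
  y <- lowpass_lfp(rec, f)$values[1, ]
  core <- 2000:6000              # avoid filter edge transients
  gain_fft <- function(sig) {
    sp <- Mod(stats::fft(sig[core]))
    max(sp)
  }
  expect_equal(gain_fft(y) / gain_fft(x), 0.5, tolerance = 0.01)

  # linearity to machine precision
  x2 <- cos(2 * pi * 120 * t)
  ra <- potential_recording(arr, matrix(x, 1), 0.3, dt)
  rb <- potential_recording(arr, matrix(x2, 1), 0.3, dt)
  rab <- potential_recording(arr, matrix(2 * x - 3 * x2, 1), 0.3, dt)
  expect_equal(lowpass_lfp(rab, 500)$values,
               2 * lowpass_lfp(ra, 500)$values -
                 3 * lowpass_lfp(rb, 500)$values,
               tolerance = 1e-12)

  # idempotent on an already band-limited signal (far below cutoff, where
  # the squared magnitude response is 1 to better than 1e-6)
  lo <- sin(2 * pi * 5 * t)
  r1 <- lowpass_lfp(potential_recording(arr, matrix(lo, 1), 0.3, dt), 500)
  r2 <- lowpass_lfp(r1, 500)
  expect_lt(sqrt(sum((r2$values - r1$values)^2) / sum(r1$values^2)), 1e-6)

  # cutoff at or above Nyquist is invalid
  expect_error(lowpass_lfp(const, 5000), "Nyquist")
})

test_that("coarse-grained CSD smooths currents and conserves total current", {
  dt <- 0.1
  grid <- seq(0, 1000, by = 5)
  src <- point_source_set(matrix(c(0, 0, 500), 1), matrix(2, 1, 1), dt)
  m <- coarse_grain_csd(src, grid, sigma_kernel = 50)
  expect_s3_class(m, "csd_estimate")
  expect_equal(grid[which.max(m$values[, 1])], 500)
  # kernel is normalized: trapezoid integral over depth ~ total current
  integral <- sum((m$values[-1, 1] + m$values[-length(grid), 1]) / 2 * diff(grid))
  expect_equal(integral, 2, tolerance = 1e-6)

  # multiple sources at grid points, narrow kernel -> binned histogram
  src2 <- point_source_set(cbind(0, 0, c(200, 200, 600)),
                           matrix(c(1, 2, -1), 3, 1), dt)
  h <- coarse_grain_csd(src2, seq(0, 1000, by = 100), sigma_kernel = 1)
  expect_equal(h$values[3, 1] * sqrt(2 * pi) * 1, 3, tolerance = 1e-10)
  expect_equal(h$values[7, 1] * sqrt(2 * pi) * 1, -1, tolerance = 1e-10)

  # empty source set warns and returns zeros
  empty <- point_source_set(matrix(numeric(0), 0, 3),
                            matrix(numeric(0), 0, 4), dt)
  expect_warning(z <- coarse_grain_csd(empty, grid), "empty")
  expect_true(all(z$values == 0))
})
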