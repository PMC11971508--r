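make_field_echoes <- function(f_hz, dte_ms = 2.39, mag = 1) {
  e1 <- mag * array(1 + 0i, dim(f_hz))
  e2 <- e1 * exp(1i * 2 * pi * f_hz * dte_ms / 1000)
  list(e1 = e1, e2 = e2)
}

test_that("B0 mapping recovers uniform and linear fields", {
  d <- c(24, 24, 1)
  z <- make_field_echoes(array(0, d))
  b0 <- compute_b0(z$e1, z$e2, 2.39, noise_sd = 1e-9)
  expect_true(all(abs(b0$offres_hz) < 1e-9))
  # uniform phase difference of pi: 0.5 / 0.00239 s = 209.2 Hz
  p <- make_field_echoes(array(209.205 * 0.999999, d))
  b0p <- compute_b0(p$e1, p$e2, 2.39, noise_sd = 1e-9, unwrap = FALSE)
  expect_equal(mean(b0p$offres_hz), 209.2, tolerance = 0.01)
  # wrapped linear field recovered within 1 Hz RMS
  f <- array(rep(seq(-300, 300, length.out = 24), each = 24), d)
  l <- make_field_echoes(f)
  b0l <- compute_b0(l$e1, l$e2, 2.39, noise_sd = 1e-9)
  expect_lt(sqrt(mean((b0l$offres_hz - f)^2)), 1)
})

test_that("low-magnitude voxels are masked in the B0 map", {
  d <- c(16, 16, 1)
  mag <- array(1, d); mag[1:4, 1:4, 1] <- 0.001
  e1 <- mag * (1 + 0i)
  e2 <- e1
  b0 <- compute_b0(e1, e2, 2.39, noise_sd = 0.01)
  expect_equal(b0$n_masked, 16)
  expect_true(all(is.na(b0$offres_hz[1:4, 1:4, 1])))
})

test_that("EPI unwarp is the identity at zero field and round-trips", {
  img <- array(0, c(32, 32, 1))
  img[, , 1] <- outer(dnorm(1:32, 14, 4), dnorm(1:32, 18, 5))
  zero <- array(0, dim(img))
  expect_equal(unwarp_epi(img, zero, 0.3, 52)$data, img)
  # uniform 50 Hz: shift = 50 * 0.3 ms * 52 lines = 0.78 voxels
  f <- array(50, dim(img))
  warped <- unwarp_epi(img, f, 0.3, 52, direction = "warp")$data
  back <- unwarp_epi(warped, f, 0.3, 52)$data
  inner <- img[, 5:28, ]
  expect_lt(max(abs(back[, 5:28, ] - inner)), 0.02 * max(img))
  # landmark displacement matches the analytic shift
  peak_shifted <- which.max(warped[14, , 1])
  expect_lt(abs(peak_shifted - (18 + 0.78)), 0.75)
})

test_that("3D DAM inverts the double-angle ratio exactly", {
  # forward sin-law generation is inverted to b1 = 0.8:
  # sin(104) / (2 sin(52)) = 0.6157 -> acos -> 52 deg
  s1 <- array(sin(52 * pi / 180), c(2, 2, 1))
  s2 <- array(sin(104 * pi / 180), c(2, 2, 1))
  b1 <- dam_b1_3d(s1, s2, 65)
  expect_equal(b1$b1_factor[1, 1, 1], 0.8, tolerance = 1e-9)
  expect_equal(sin(104 * pi / 180) / sin(52 * pi / 180), 1.2313,
               tolerance = 1e-4)
  # identity property across the supported range (noiseless)
  for (b in seq(0.4, 1.3, by = 0.1)) {
    a <- 65 * pi / 180
    est <- dam_b1_3d(array(sin(b * a), c(1, 1, 1)),
                     array(sin(2 * b * a), c(1, 1, 1)), 65)
    expect_equal(est$b1_factor[1], b, tolerance = 1e-6)
  }
  # zero signal is masked and counted
  z <- dam_b1_3d(array(0, c(1, 1, 1)), array(0, c(1, 1, 1)), 65)
  expect_true(is.na(z$b1_factor[1]))
  expect_equal(z$n_masked, 1)
})

test_that("DAM lookup ratio is strictly monotone over its range", {
  lk <- get_dam_lookup()
  for (j in seq_along(lk$g_grid)) {
    expect_true(all(diff(lk$ratio[, j]) < 0))
  }
})

test_that("corrected 2D DAM recovers B1 where the naive inversion is biased", {
  lk <- get_dam_lookup()
  pulse <- pulse_descriptor()
  gen <- function(b1, g = 0) {
    p1 <- slice_profile(pulse, 65, b1, 8)
    p2 <- slice_profile(pulse, 130, b1, 8)
    w <- exp(1i * 2 * pi * g * p1$z_mm * 11 / 1000)
    c(abs(sum(sin(p1$alpha_deg * pi / 180) * w)),
      abs(sum(sin(p2$alpha_deg * pi / 180) * w)))
  }
  as_img <- function(x) array(x, c(1, 1, 1))
  for (b1 in c(0.6, 0.8, 1.0, 1.2)) {
    s <- gen(b1)
    corrected <- dam_b1_2d(as_img(s[1]), as_img(s[2]), lk)
    naive <- dam_b1_2d(as_img(s[1]), as_img(s[2]), lk, correct = FALSE)
    expect_lt(abs(corrected$b1_factor[1] - b1), 0.01)
    expect_gt(abs(naive$b1_factor[1] - b1), 0.015)
    # with an imposed through-slice gradient of 2 Hz/mm
    sg <- gen(b1, g = 2)
    with_g <- dam_b1_2d(as_img(sg[1]), as_img(sg[2]), lk, g_hz_mm = 2)
    expect_lt(abs(with_g$b1_factor[1] - b1), 0.01)
  }
})

test_that("through-slice gradient estimation uses slice differences", {
  f <- array(0, c(4, 4, 3))
  for (s in 1:3) f[, , s] <- 10 * s    # 10 Hz per 10 mm = 1 Hz/mm
  g <- b0_gradient_z(f, 10)
  expect_equal(as.vector(g), rep(1, 48), tolerance = 1e-12)
  g1 <- b0_gradient_z(array(5, c(2, 2, 1)), 10)
  expect_true(all(g1 == 0))
})

test_that("B1 resampling is exact for identity, constant, linear maps", {
  g <- list(spacing = c(2, 2, 2), origin = c(0, 0, 0))
  arr <- array(rnorm(5 * 5 * 5), c(5, 5, 5))
  same <- resample_b1_to_spgr(arr, g, c(g, list(dim = c(5, 5, 5))))
  expect_equal(same$b1_factor, arr, tolerance = 1e-12)
  const <- resample_b1_to_spgr(array(0.9, c(5, 5, 5)), g,
                               list(spacing = c(1, 1, 1),
                                    origin = c(1, 1, 1),
                                    dim = c(5, 5, 5)))
  expect_true(all(abs(const$b1_factor - 0.9) < 1e-12))
  lin <- array(0, c(5, 5, 5))
  for (k in 1:5) lin[, , k] <- k
  half <- resample_b1_to_spgr(lin, g,
                              list(spacing = c(2, 2, 1),
                                   origin = c(0, 0, 0),
                                   dim = c(5, 5, 9)))
  expect_equal(half$b1_factor[1, 1, ], seq(1, 5, by = 0.5),
               tolerance = 1e-12)
  # out-of-coverage voxels are masked and counted
  out <- resample_b1_to_spgr(lin, g,
                             list(spacing = c(2, 2, 4),
                                  origin = c(0, 0, 0),
                                  dim = c(5, 5, 4)))
  expect_gt(out$n_masked, 0)
})

test_that("smooth-field hole filling is local and value-preserving", {
  f <- array(1, c(8, 8, 1))
  f[4, 4, 1] <- NA
  filled <- fill_na_nearest(f, 1)
  expect_equal(filled[4, 4, 1], 1)
  far <- array(NA_real_, c(8, 8, 1)); far[1, 1, 1] <- 2
  part <- fill_na_nearest(far, 1)
  expect_true(is.na(part[4, 4, 1]))   # beyond reach stays masked
})
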