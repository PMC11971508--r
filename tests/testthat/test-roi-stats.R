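test_that("weighted subject summary matches the brute-force sums", {
  for (seed in 1:5) {
    px <- random_pixel_fixture(seed = seed)
    got <- weighted_subject_summary(px)
    want <- brute_subject_summary(px)
    expect_equal(got$mean, want$mean, tolerance = 1e-12)
    expect_equal(got$sd, want$sd, tolerance = 1e-12)
    expect_equal(roi_level_homogeneity(px), brute_roi_dispersion(px),
                 tolerance = 1e-12)
  }
})

test_that("degenerate ROI inputs behave as defined", {
  # identical pixel values: mean v, SD 0 (weights capped with warning)
  px <- data.frame(subject = 1, run = 1,
                   slice = rep(1:2, each = 8),
                   roi = rep(rep(1:2, each = 4), 2), t1 = 950)
  expect_warning(s <- weighted_subject_summary(px), "capped")
  expect_equal(s$mean, 950)
  expect_equal(s$sd, 0)
  # equal weights, equal sizes: arithmetic pixel mean
  set.seed(2)
  a <- rnorm(10, 900, 10); a <- (a - mean(a)) / sd(a) * 10 + 900
  b <- rnorm(10, 950, 10); b <- (b - mean(b)) / sd(b) * 10 + 950
  px2 <- data.frame(subject = 1, run = 1, slice = 1,
                    roi = rep(1:2, each = 10), t1 = c(a, b))
  expect_equal(weighted_subject_summary(px2)$mean, mean(c(a, b)),
               tolerance = 1e-12)
  expect_error(roi_level_homogeneity(px2[px2$roi == 1, ]), "two ROIs")
})

test_that("ROI-level dispersion of two equal-weight ROIs is the
           half-distance", {
  # means 900 and 910 with equal weights: sqrt(mean((x - 905)^2)) = 5
  a <- c(898, 900, 902); a <- (a - mean(a)) / sd(a) * 5 + 900
  b <- c(908, 910, 912); b <- (b - mean(b)) / sd(b) * 5 + 910
  px <- data.frame(subject = 1, run = 1, slice = 1,
                   roi = rep(1:2, each = 3), t1 = c(a, b))
  expect_equal(roi_level_homogeneity(px), 5, tolerance = 1e-12)
  # all ROI means equal -> zero dispersion
  px0 <- data.frame(subject = 1, run = 1, slice = 1,
                    roi = rep(1:2, each = 3),
                    t1 = c(899, 900, 901, 899.5, 900, 900.5))
  expect_lt(roi_level_homogeneity(px0), 1e-9)
})

test_that("inaccuracy is the signed mean relative difference", {
  v <- data.frame(volunteer = 1:3, run = 1, t1 = c(950, 800, 1000))
  r <- data.frame(volunteer = 1:3, run = 1, t1 = c(1000, 800, 1000))
  expect_equal(inaccuracy(v, v)$delta, 0)
  one <- inaccuracy(v[1, ], r[1, ])
  expect_equal(one$delta, -0.05)
  expect_equal(inaccuracy(v, r)$delta, mean(c(-0.05, 0, 0)),
               tolerance = 1e-12)
  # unmatched pairs are skipped with a message
  r2 <- r[1:2, ]
  expect_message(sk <- inaccuracy(v, r2), "skipped")
  expect_equal(sk$n_pairs, 2)
  expect_equal(sk$n_skipped, 1)
})

test_that("B1 sensitivity regression matches an exact line", {
  b1 <- seq(0.7, 0.9, length.out = 9)
  df <- data.frame(mean_t1 = 500 + 400 * b1, mean_b1 = b1)
  r <- b1_sensitivity(df, b1_range = 0.2)
  expect_equal(r$slope, 400, tolerance = 1e-9)
  expect_equal(r$delta_t1_b1, 80, tolerance = 1e-9)
  expect_equal(diff(r$ci95), 0, tolerance = 1e-9)
  expect_lt(r$p_value, 1e-10)
  # flat data: zero slope, p near 1
  set.seed(4)
  flat <- data.frame(mean_t1 = 900 + rnorm(9, 0, 1e-8) +
                       c(1e-6, rep(0, 8)), mean_b1 = b1)
  rf <- b1_sensitivity(flat)
  expect_lt(abs(rf$delta_t1_b1), 1e-4)
  expect_error(b1_sensitivity(df[1:2, ]), "three")
  expect_error(b1_sensitivity(data.frame(mean_t1 = 1:5,
                                         mean_b1 = rep(1, 5))),
               "variance")
})

test_that("slope CI has near-nominal coverage", {
  set.seed(99)
  b1 <- seq(0.6, 1.1, length.out = 12)
  hits <- 0
  n_mc <- 1000
  for (i in seq_len(n_mc)) {
    y <- 700 + 300 * b1 + rnorm(12, 0, 25)
    r <- b1_sensitivity(data.frame(mean_t1 = y, mean_b1 = b1),
                        b1_range = 1)
    if (r$ci95[1] <= 300 && 300 <= r$ci95[2]) hits <- hits + 1
  }
  expect_gt(hits / n_mc, 0.93)
  expect_lt(hits / n_mc, 0.97)
})

test_that("repeatability statistics follow their definitions", {
  run_a <- c(820, 950, 1010, 890, 760, 1040, 930, 880, 990, 910)
  # identical runs: all dispersion metrics vanish (perfect-fit ANOVA
  # warnings are expected here)
  same <- suppressWarnings(repeatability(run_a, run_a))
  expect_equal(same$sigma_within, 0, tolerance = 1e-9)
  expect_equal(same$rc, 0, tolerance = 1e-9)
  expect_equal(same$ba_bias, 0)
  # RC = 1.96 sqrt(2) sigma: 27.72 ms at sigma = 10 ms
  expect_equal(1.96 * sqrt(2) * 10, 27.72, tolerance = 1e-3)
  set.seed(5)
  run_b <- run_a + rnorm(10, 0, 14)
  r <- repeatability(run_a, run_b)
  expect_equal(r$rc, 1.96 * sqrt(2) * r$sigma_within,
               tolerance = 1e-12)
  # ANOVA residual MS equals the pooled two-run variance
  expect_equal(r$sigma_within^2, mean((run_a - run_b)^2) / 2,
               tolerance = 1e-12)
  expect_equal(r$ba_bias, mean(run_a - run_b), tolerance = 1e-12)
  expect_equal(r$ba_loa_halfwidth, 1.96 * sd(run_a - run_b),
               tolerance = 1e-12)
  expect_error(repeatability(run_a, run_b[1:9]), "unequal")
})

test_that("RC estimate is unbiased in a two-run mixed model", {
  set.seed(17)
  rcs <- replicate(400, {
    truth <- rnorm(10, 950, 90)
    a <- truth + rnorm(10, 0, 21)
    b <- truth + rnorm(10, 0, 21)
    repeatability(a, b)$rc
  })
  expect_lt(abs(median(rcs) - 1.96 * sqrt(2) * 21) /
              (1.96 * sqrt(2) * 21), 0.1)
})

test_that("ROI pixel extraction pulls circular regions with B1", {
  map <- array(1000, c(20, 20, 2))
  map[, , 2] <- 1200
  b1 <- array(0.9, c(20, 20, 2))
  rois <- data.frame(slice = c(1, 2), roi = c(1, 1), cx = 10, cy = 10,
                     radius_px = 2)
  px <- extract_roi_pixels(map, rois, b1 = b1, subject = 3, run = 2)
  expect_setequal(unique(px$t1), c(1000, 1200))
  expect_true(all(px$b1 == 0.9))
  expect_equal(unique(px$subject), 3)
  expect_equal(sum(px$slice == 1), 13)  # 2-pixel-radius disc
})
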