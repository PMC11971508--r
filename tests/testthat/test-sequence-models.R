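test_that("SPGR signal matches the Bloch-recursion steady state", {
  # frozen from bloch_spgr_oracle(800, 15, 4.1): 0.03391414
  expect_equal(spgr_signal(800, 15, 4.1), 0.03391414, tolerance = 1e-6)
  expect_identical(spgr_signal(800, 0, 4.1), 0)
  # full-relaxation limit used by the long-TR double-angle method
  expect_equal(spgr_signal(367, 65, 10000), sin(65 * pi / 180),
               tolerance = 1e-6)
  set.seed(1)
  for (i in 1:100) {
    t1 <- runif(1, 200, 2500)
    tr <- runif(1, 2, 50)
    fa <- runif(1, 1, 90)
    m0 <- runif(1, 0.5, 200)
    expect_equal(spgr_signal(t1, fa, tr, m0),
                 bloch_spgr_oracle(t1, fa, tr, m0, 5000L),
                 tolerance = 1e-8)
  }
  expect_error(spgr_signal(-1, 15, 4.1), "positive")
  expect_error(spgr_signal(800, 15, 0), "positive")
})

test_that("SPGR signal is maximal at the Ernst angle", {
  for (p in list(c(367, 4.1), c(800, 4.1), c(1699, 4.1),
                 c(800, 15), c(1200, 8))) {
    ea <- ernst_angle(p[1], p[2])
    fa <- seq(0.2, 40, by = 0.05)
    s <- spgr_signal(p[1], fa, p[2])
    expect_lt(abs(fa[which.max(s)] - ea), 0.06)
  }
})

test_that("SPGR signal increases monotonically with M0", {
  m0 <- seq(0.5, 5, by = 0.5)
  s <- vapply(m0, function(m) spgr_signal(900, 10, 4.1, m), numeric(1))
  expect_true(all(diff(s) > 0))
})

test_that("IR model has the expected limits and a single zero", {
  expect_equal(ir_signal(0, 1, 2, 1000), -1)
  expect_equal(ir_signal(1e9, 1, 2, 1000), 1)
  # null point at T1 log(2); frozen: 1000 * log(2) = 693.147
  expect_equal(ir_signal(693.1472, 1, 2, 1000), 0, tolerance = 1e-6)
  root <- uniroot(function(ti) ir_signal(ti, 1.3, 2.2, 800),
                  c(0, 20000))$root
  expect_equal(root, 800 * log(2.2 / 1.3), tolerance = 1e-6)
  # single sign change for B > A > 0
  ti <- seq(0, 20000, by = 1)
  s <- ir_signal(ti, 1.3, 2.2, 800)
  expect_equal(sum(diff(sign(s)) != 0), 1)
})

test_that("slice profile behaves for hard, shaped and zero-B1 pulses", {
  hard <- slice_profile(pulse_descriptor("hard"), 65, 0.9, 8)
  expect_true(all(hard$alpha_deg == 0.9 * 65))
  zero <- slice_profile(pulse_descriptor(), 65, 0, 8)
  expect_true(all(abs(zero$alpha_deg) < 1e-12))
  # FWHM of the windowed-sinc excitation within 5% of the nominal
  # slice thickness
  pr <- slice_profile(pulse_descriptor(), 65, 1, 8, n_z = 513)
  expect_lt(abs(profile_fwhm(pr$z_mm, pr$alpha_deg) - 8) / 8, 0.05)
  expect_gte(diff(range(pr$z_mm)), 3 * 8)
  expect_error(slice_profile(list(shape = "mystery"), 65, 1, 8))
})

test_that("small-angle profile matches the pulse envelope transform", {
  p <- pulse_descriptor()
  pr <- slice_profile(p, 2, 1, 8, n_z = 257)
  env <- vfat1:::pulse_envelope(p)
  n <- length(env)
  tt <- ((seq_len(n) - 0.5) / n - 0.5) * p$duration_ms
  bw <- p$tbw / p$duration_ms
  ft <- vapply(pr$z_mm, function(z) {
    f <- bw * z / 8
    2 * abs(sum(env * exp(1i * 2 * pi * f * tt))) / sum(env)
  }, numeric(1))
  sel <- pr$alpha_deg > 0.2   # in-slice region
  expect_lt(max(abs(pr$alpha_deg[sel] - ft[sel]) / 2), 0.02)
})

test_that("fat-water signal reduces and dephases correctly", {
  fm1 <- fat_model("singlepeak")
  expect_equal(fm1$freq_hz, -3.4 * 42.5774785 * 3, tolerance = 1e-6)
  fm6 <- fat_model("multipeak")
  expect_equal(sum(fm6$amp), 1)
  # pdff = 0 reduces to the pure SPGR signal
  tw <- tissue_params(800, 800, 800, pdff = 0)
  s <- fat_water_signal(tw, fm1, 15, 4.1, te = 0.9, b0_hz = 0)
  expect_equal(Mod(s), spgr_signal(800, 15, 4.1) * exp(-0.9 / 800),
               tolerance = 1e-10)
  # pure fat at TE = 1.15 ms is close to opposed phase
  tf <- tissue_params(800, 800, 800, pdff = 1)
  fm_eq <- fat_model("singlepeak", t1_ms = 800)
  sf <- fat_water_signal(tf, fm_eq, 15, 4.1, te = 1.15)
  expect_lt(abs(abs(Arg(sf)) - pi), 0.01)
  # in-phase TE with equal relaxation: |S| equals the pdff = 0 case
  te_ip <- 1000 / abs(fm_eq$freq_hz)    # one full cycle
  t5 <- tissue_params(800, 800, 800, pdff = 0.5)
  s5 <- fat_water_signal(t5, fm_eq, 15, 4.1, te = te_ip)
  s0 <- fat_water_signal(tw, fm_eq, 15, 4.1, te = te_ip)
  expect_equal(Mod(s5), Mod(s0), tolerance = 1e-6)
})

test_that("tissue and sequence parameter invariants are enforced", {
  expect_error(tissue_params(800, 900), "t2")
  expect_error(tissue_params(-1, 30), "positive")
  expect_error(tissue_params(800, 45, pdff = 1.2), "pdff")
  expect_error(seq_params(2, te = c(1.2, 2.5), fa = 15), "tr")
  expect_error(seq_params(10, te = 2, fa = 200), "flip")
  sp <- seq_params(4.1, c(1.23, 2.46), c(2, 2, 15, 15))
  expect_s3_class(sp$pulse, "pulse_descriptor")
})
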