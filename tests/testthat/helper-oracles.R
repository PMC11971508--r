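# Independent oracles used to check the implementation. These are kept
# deliberately naive (brute-force sums, isochromat Bloch integration)
# and share no code with the package internals they validate.

# Steady-state SPGR via the longitudinal Bloch recursion
# Mz(n+1) = Mz(n) cos(a) E1 + M0 (1 - E1), iterated to convergence.
bloch_spgr_oracle <- function(t1, fa_deg, tr, m0 = 1, n = 100000L) {
  a <- fa_deg * pi / 180
  e1 <- exp(-tr / t1)
  mz <- m0
  for (i in seq_len(n)) mz <- mz * cos(a) * e1 + m0 * (1 - e1)
  mz * sin(a)
}

# RF- and gradient-spoiled SPGR steady state by brute-force isochromat
# summation: `nspins` spins uniformly spread over one spoiler-gradient
# cycle, quadratic RF phase, full 3D rotations.
isochromat_spgr_oracle <- function(t1, t2, fa_deg, tr, phi_inc_deg = 50,
                                   nspins = 2000L, npulses = NULL) {
  if (is.null(npulses)) npulses <- max(800L, ceiling(10 * t1 / tr))
  a <- fa_deg * pi / 180
  psi <- 2 * pi * (seq_len(nspins) - 0.5) / nspins
  e1 <- exp(-tr / t1)
  e2 <- exp(-tr / t2)
  dps <- exp(1i * psi)
  mxy <- complex(length.out = nspins)
  mz <- rep(1, nspins)
  ca2 <- cos(a / 2)^2; sa2 <- sin(a / 2)^2; sa <- sin(a); ca <- cos(a)
  s <- NA_complex_
  for (n in seq_len(npulses)) {
    phi <- (phi_inc_deg * pi / 180) * n * (n - 1) / 2
    ep <- exp(1i * phi)
    mxy_new <- ca2 * mxy + sa2 * ep^2 * Conj(mxy) - 1i * ep * sa * mz
    mz <- sa * Im(Conj(ep) * mxy) + ca * mz
    mxy <- mxy_new
    s <- mean(mxy) * Conj(ep)
    mxy <- mxy * e2 * dps
    mz <- mz * e1 + (1 - e1)
  }
  Mod(s)
}

# Brute-force weighted subject mean / SD: direct triple sums over
# slices, ROIs and pixels with w = n / sd^2.
brute_subject_summary <- function(pixels) {
  groups <- split(pixels, interaction(pixels$slice, pixels$roi,
                                      drop = TRUE))
  num <- 0; den <- 0
  for (g in groups) {
    w <- nrow(g) / stats::sd(g$t1)^2
    num <- num + sum(w * g$t1)
    den <- den + nrow(g) * w
  }
  mu <- num / den
  num2 <- 0
  for (g in groups) {
    w <- nrow(g) / stats::sd(g$t1)^2
    num2 <- num2 + sum(w * (g$t1 - mu)^2)
  }
  list(mean = mu, sd = sqrt(num2 / den))
}

# Brute-force ROI-level dispersion (denominator sum of w, not n w).
brute_roi_dispersion <- function(pixels) {
  groups <- split(pixels, interaction(pixels$slice, pixels$roi,
                                      drop = TRUE))
  mu <- brute_subject_summary(pixels)$mean
  num <- 0; den <- 0
  for (g in groups) {
    w <- nrow(g) / stats::sd(g$t1)^2
    num <- num + w * (mean(g$t1) - mu)^2
    den <- den + w
  }
  sqrt(num / den)
}

# random pixel-level fixture: slices x rois, variable pixel counts
random_pixel_fixture <- function(n_slices = 3, n_rois = 3, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_slices), function(s) {
    do.call(rbind, lapply(seq_len(n_rois), function(r) {
      n <- sample(5:30, 1)
      data.frame(subject = 1, run = 1, slice = s, roi = r,
                 t1 = stats::rnorm(n, 700 + 150 * r + 20 * s, 30))
    }))
  }))
}

# full width at half maximum of a sampled profile, via interpolation
profile_fwhm <- function(z, a) {
  half <- max(a) / 2
  f <- stats::approxfun(z, a - half)
  lo <- stats::uniroot(f, c(min(z), z[which.max(a)]))$root
  hi <- stats::uniroot(f, c(z[which.max(a)], max(z)))$root
  hi - lo
}
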