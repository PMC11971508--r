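#' MOLLI 5(1)1(1)1 acquisition scheme
#'
#' Timing of the modified Look-Locker inversion recovery used for
#' single-slice liver T1: five readouts after the first inversion at
#' TIs 100, 100+RR, ..., 100+4RR ms, one pause beat, a second inversion
#' with a readout at TI 180 ms, another pause, and a third inversion
#' with a readout at TI 260 ms. Readouts are single-shot bSSFP blocks.
#'
#' @param rr simulated R-R interval (ms), around 1000 for liver work.
#' @param ti_min first inversion's minimum TI (ms).
#' @param ti_extra TIs of the second and third inversion groups (ms).
#' @param readout_fa bSSFP readout flip angle (degrees).
#' @param readout_tr,readout_te bSSFP repetition / echo time (ms).
#' @param n_pe phase-encode lines per single-shot readout (k-space
#'   center at line `n_pe / 2`, linear ordering).
#' @return Object of class `molli_scheme`.
#' @export
molli_scheme <- function(rr = 1000, ti_min = 100, ti_extra = c(180, 260),
                         readout_fa = 35, readout_tr = 2.6,
                         readout_te = 1.05, n_pe = 72) {
  tis <- c(ti_min + (0:4) * rr, ti_extra)
  structure(list(pattern = "5(1)1(1)1", rr = rr, tis = tis,
                 group = c(rep(1L, 5), 2L, 3L),
                 readout_fa = readout_fa, readout_tr = readout_tr,
                 readout_te = readout_te, n_pe = n_pe),
            class = "molli_scheme")
}

#' Confounder inputs of the MOLLI forward simulation
#'
#' @param b0_hz off-resonance of the ROI (Hz).
#' @param t2star_ms effective T2* (ms; shortened by hepatic iron).
#' @param pdff proton-density fat fraction in [0, 1].
#' @param mt_bound_fraction bound-pool (macromolecular) fraction.
#' @param mt_exchange_s exchange rate (per s) between pools.
#' @param mt_sat_per_pulse fractional bound-pool saturation per readout
#'   RF pulse.
#' @param inversion_efficiency adiabatic inversion efficiency in (0, 1].
#' @return Object of class `molli_confounders`.
#' @export
molli_confounders <- function(b0_hz = 0, t2star_ms = Inf, pdff = 0,
                              mt_bound_fraction = 0.07,
                              mt_exchange_s = 40,
                              mt_sat_per_pulse = 0.02,
                              inversion_efficiency = 0.96) {
  stopifnot(pdff >= 0, pdff <= 1, inversion_efficiency > 0,
            inversion_efficiency <= 1)
  structure(list(b0_hz = b0_hz, t2star_ms = t2star_ms, pdff = pdff,
                 mt_bound_fraction = mt_bound_fraction,
                 mt_exchange_s = mt_exchange_s,
                 mt_sat_per_pulse = mt_sat_per_pulse,
                 inversion_efficiency = inversion_efficiency),
            class = "molli_confounders")
}

# One longitudinal free-relaxation step. Pool 1 (free water) exchanges
# with the bound pool `zb` (equilibrium f); any further pools (fat
# peaks) relax mono-exponentially.
relax_z <- function(za, zb, t_ms, t1, t1b, kf, kr, f) {
  if (t_ms <= 0) return(list(za = za, zb = zb))
  out <- 1 + (za - 1) * exp(-t_ms / t1)
  if (f <= 0) return(list(za = out, zb = zb))
  n <- max(1L, ceiling(t_ms / 5))
  dt <- t_ms / n / 1000              # s
  zw <- za[1]
  for (i in seq_len(n)) {
    dzw <- (1 - zw) / (t1[1] / 1000) - kf * zw + kr * zb
    dzb <- (f - zb) / (t1b / 1000) + kf * zw - kr * zb
    zw <- zw + dzw * dt
    zb <- zb + dzb * dt
  }
  out[1] <- zw
  list(za = out, zb = zb)
}

#' Bloch simulation of a MOLLI acquisition
#'
#' Time-stepped Bloch simulation of the 5(1)1(1)1 scheme from a known
#' water T1: instantaneous (efficiency-scaled) adiabatic inversions,
#' free relaxation between beats, and single-shot bSSFP readout blocks
#' (alternating +/- readout flip with an alpha/2 preparation pulse)
#' whose k-space-center transverse signal is recorded. A fat pool is
#' simulated in parallel at its own frequency offsets and summed at
#' PDFF weight; iron enters as exp(-TE/T2*) echo decay plus Lorentzian
#' intravoxel broadening of the transverse decay during the readout;
#' magnetization transfer as a two-pool saturation term. Deterministic.
#'
#' @param water_t1 water longitudinal relaxation time (ms), > 0.
#' @param scheme a [molli_scheme()].
#' @param conf a [molli_confounders()].
#' @param fat a [fat_model()]; only used when `conf$pdff > 0`.
#' @param water_t2 water transverse relaxation time (ms).
#' @return Data frame with `ti` (ms), `group`, `signal` (complex) and
#'   `signal_real` (polarity-bearing projection used for fitting).
#' @export
simulate_molli <- function(water_t1, scheme = molli_scheme(),
                           conf = molli_confounders(),
                           fat = fat_model(), water_t2 = 34) {
  stopifnot(inherits(scheme, "molli_scheme"),
            inherits(conf, "molli_confounders"))
  if (water_t1 <= 0 || water_t2 <= 0) stop("unphysical relaxation times")
  rr <- scheme$rr
  # pools: water + one per fat peak
  if (conf$pdff > 0) {
    freqs <- c(conf$b0_hz, conf$b0_hz + fat$freq_hz)
    weights <- c(1 - conf$pdff, conf$pdff * fat$amp)
    t1s <- c(water_t1, rep(fat$t1_ms, length(fat$freq_hz)))
    t2s <- c(water_t2, rep(min(water_t2, 60), length(fat$freq_hz)))
  } else {
    freqs <- conf$b0_hz; weights <- 1; t1s <- water_t1; t2s <- water_t2
  }
  np <- length(freqs)
  # Lorentzian intravoxel broadening from T2'
  r2p <- if (is.finite(conf$t2star_ms)) {
    max(1 / conf$t2star_ms - 1 / water_t2, 0)
  } else 0
  t2eff <- 1 / (1 / t2s + r2p)
  f_mt <- conf$mt_bound_fraction
  kr <- conf$mt_exchange_s
  kf <- kr * f_mt
  t1b <- 1000                        # bound-pool T1 (ms)
  # absolute event times: group 1 inversion at t = 0, centers at tis;
  # pause beat, inversion g TI before its readout center
  centers <- c(scheme$tis[1:5],
               6 * rr + scheme$tis[1],     # beat 6 center, group 2
               8 * rr + scheme$tis[1])     # beat 8 center, group 3
  centers[6] <- 6 * rr + 100
  centers[7] <- 8 * rr + 100
  inv_times <- c(0, centers[6] - scheme$tis[6], centers[7] - scheme$tis[7])
  n_center <- floor(scheme$n_pe / 2)
  # k-space center excitation falls exactly at the nominal TI: the
  # block runs -alpha/2 prep, TR/2 gap, then pulses every TR
  block_lead <- scheme$readout_tr / 2 + n_center * scheme$readout_tr
  mz <- rep(1, np)                    # per-pool, unit equilibrium
  mzb <- f_mt                         # bound pool (water only)
  t_now <- 0
  out <- data.frame(ti = scheme$tis, group = scheme$group,
                    signal = complex(length.out = 7))
  alpha <- scheme$readout_fa * pi / 180
  for (g in 1:3) {
    # relax up to this inversion
    st <- relax_z(mz, mzb, inv_times[g] - t_now, t1s, t1b, kf, kr, f_mt)
    mz <- st$za; mzb <- st$zb
    t_now <- inv_times[g]
    mz <- -conf$inversion_efficiency * mz
    mzb <- -conf$inversion_efficiency * mzb
    for (j in which(scheme$group == g)) {
      t_start <- inv_times[g] + scheme$tis[j] - block_lead
      st <- relax_z(mz, mzb, t_start - t_now, t1s, t1b, kf, kr, f_mt)
      mz <- st$za; mzb <- st$zb
      t_now <- t_start
      # bSSFP block: -alpha/2 catalyzation places the magnetization on
      # the steady-state cone, TR/2 gap, then alternating +/- alpha
      mxy <- complex(length.out = np)
      sgn <- 1
      rot <- -alpha / 2
      tmp_y <- Im(mxy) * cos(rot) + mz * sin(rot)
      mz <- mz * cos(rot) - Im(mxy) * sin(rot)
      mxy <- Re(mxy) + 1i * tmp_y
      evolve <- function(dt_ms) {
        mxy <<- mxy * exp(-dt_ms / t2eff) *
          exp(1i * 2 * pi * freqs * dt_ms / 1000)
        mz <<- 1 + (mz - 1) * exp(-dt_ms / t1s)
        mzb <<- f_mt + (mzb - f_mt) * exp(-dt_ms / t1b)
      }
      evolve(scheme$readout_tr / 2)
      for (p in seq_len(scheme$n_pe)) {
        rot <- sgn * alpha
        tmp_y <- Im(mxy) * cos(rot) + mz * sin(rot)
        mz <- mz * cos(rot) - Im(mxy) * sin(rot)
        mxy <- Re(mxy) + 1i * tmp_y
        mzb <- mzb * (1 - conf$mt_sat_per_pulse)
        sgn <- -sgn
        if (p == n_center + 1L) {
          dec <- if (is.finite(conf$t2star_ms)) {
            exp(-scheme$readout_te / conf$t2star_ms)
          } else 1
          out$signal[j] <- sum(weights * mxy *
            exp(1i * 2 * pi * freqs * scheme$readout_te / 1000)) * dec
        }
        if (p < scheme$n_pe) evolve(scheme$readout_tr)
      }
      t_now <- t_start + scheme$readout_tr / 2 +
        (scheme$n_pe - 1) * scheme$readout_tr
    }
  }
  # polarity-bearing projection: phase of the most-recovered sample
  ref <- out$signal[which.max(out$ti)]
  out$signal_real <- Re(out$signal * Conj(ref) / Mod(ref))
  out
}

#' Look-Locker-corrected inversion-recovery fit of MOLLI samples
#'
#' Three-parameter fit S(TI) = A - B exp(-TI/T1*) to the (signed)
#' samples, followed by the Deichmann-Haase apparent-to-true correction
#' T1 = T1* (B/A - 1).
#'
#' @param samples data frame from [simulate_molli()] (or with columns
#'   `ti`, `signal_real`, `group`).
#' @param use_first_five fit only the five samples of the first
#'   inversion group (the reference protocol's choice).
#' @return List with `a`, `b`, `t1_star`, `t1_ll`, `converged`.
#' @export
fit_molli <- function(samples, use_first_five = TRUE) {
  df <- samples
  if (use_first_five && "group" %in% names(df)) {
    df <- df[df$group == 1L, ]
  }
  if (nrow(df) < 3) stop("at least three TIs required")
  df <- df[order(df$ti), ]
  y <- df$signal_real
  a0 <- max(y); b0 <- a0 - min(y)
  t10 <- max(df$ti[which.min(abs(y))] / log(2), 100)
  fit <- minpack.lm::nls.lm(
    par = c(a0, b0, t10),
    fn = function(p) y - ir_signal(df$ti, p[1], p[2], p[3]),
    lower = c(0, 0, 1), upper = c(Inf, Inf, 10000),
    control = minpack.lm::nls.lm.control(ptol = 1e-10, ftol = 1e-10,
                                         maxiter = 200))
  a <- fit$par[1]; b <- fit$par[2]; t1s <- fit$par[3]
  list(a = a, b = b, t1_star = t1s, t1_ll = t1s * (b / a - 1),
       converged = fit$info %in% 1:4)
}

#' Forward-map a VFA water T1 into a comparable MOLLI T1
#'
#' Composition of [simulate_molli()] and [fit_molli()]: the mean VFA
#' water T1 of the ROIs matching the MOLLI slice is forward-simulated
#' through the MOLLI acquisition with the subject's confounders
#' (off-resonance, T2*, PDFF, MT) and refitted, yielding the
#' Look-Locker-corrected T1 that an actual MOLLI scan of that tissue
#' would report.
#'
#' @param vfa_t1 VFA water T1 input (ms) - typically the mean over the
#'   nine ROIs on the three VFA slices matching the MOLLI slice.
#' @param conf a [molli_confounders()].
#' @param scheme a [molli_scheme()].
#' @param fat a [fat_model()].
#' @param ... passed to [simulate_molli()].
#' @return Simulated MOLLI T1 (ms).
#' @export
forward_map_vfa_to_molli <- function(vfa_t1, conf = molli_confounders(),
                                     scheme = molli_scheme(),
                                     fat = fat_model(), ...) {
  sim <- simulate_molli(vfa_t1, scheme, conf, fat, ...)
  fit_molli(sim)$t1_ll
}
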