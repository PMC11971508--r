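#' Tissue relaxation parameters
#'
#' Bundle of per-voxel (or per-vial) tissue properties used by the signal
#' models: longitudinal relaxation time T1, transverse relaxation T2,
#' effective transverse relaxation T2*, equilibrium magnetization M0 and
#' proton-density fat fraction (PDFF).
#'
#' @param t1 longitudinal relaxation time (ms), > 0.
#' @param t2 transverse relaxation time (ms), > 0 and <= t1.
#' @param t2star effective transverse relaxation time (ms), <= t2.
#'   Defaults to `t2`.
#' @param m0 equilibrium magnetization (arbitrary units).
#' @param pdff proton-density fat fraction in [0, 1].
#' @return An object of class `tissue_params`.
#' @examples
#' liver <- tissue_params(t1 = 800, t2 = 34, t2star = 20, pdff = 0.05)
#' @export
tissue_params <- function(t1, t2, t2star = t2, m0 = 1, pdff = 0) {
  stopifnot(is.numeric(t1), is.numeric(t2), is.numeric(t2star))
  if (t1 <= 0 || t2 <= 0) stop("t1 and t2 must be positive")
  if (t2 > t1) stop("t2 must not exceed t1")
  if (t2star > t2) stop("t2star must not exceed t2")
  if (pdff < 0 || pdff > 1) stop("pdff must lie in [0, 1]")
  structure(list(t1 = t1, t2 = t2, t2star = t2star, m0 = m0, pdff = pdff),
            class = "tissue_params")
}

#' Sequence parameters
#'
#' Acquisition constants of a gradient-echo sequence: repetition time,
#' echo times, nominal flip angles, RF-spoiling phase increment and the
#' slice-selection settings used for 2D acquisitions.
#'
#' @param tr repetition time (ms).
#' @param te echo time(s) (ms).
#' @param fa nominal flip angle(s) (degrees), each in (0, 180].
#' @param rf_spoil_increment quadratic RF-spoiling phase increment
#'   (degrees). The vendor-typical default is 50.
#' @param slice_thickness slice thickness (mm), `NA` for 3D non-selective.
#' @param pulse a [pulse_descriptor()] for the excitation pulse.
#' @return An object of class `seq_params`.
#' @export
seq_params <- function(tr, te, fa, rf_spoil_increment = 50,
                       slice_thickness = NA_real_,
                       pulse = pulse_descriptor()) {
  if (any(te <= 0) || tr <= max(te)) stop("need tr > max(te) > 0")
  if (any(fa <= 0) || any(fa > 180)) stop("flip angles must be in (0, 180]")
  structure(list(tr = tr, te = te, fa = fa,
                 rf_spoil_increment = rf_spoil_increment,
                 slice_thickness = slice_thickness, pulse = pulse),
            class = "seq_params")
}

#' Excitation pulse descriptor
#'
#' Named shaped-pulse description used by [slice_profile()]. The default is
#' a Hanning-windowed sinc with time-bandwidth product 8; a `"hard"`
#' (non-selective) pulse is also available.
#'
#' @param shape `"hsinc"` (Hanning-windowed sinc) or `"hard"`.
#' @param tbw time-bandwidth product of the shaped pulse.
#' @param duration_ms pulse duration (ms).
#' @param n_samples number of time samples used in Bloch integration.
#' @return An object of class `pulse_descriptor`.
#' @export
pulse_descriptor <- function(shape = c("hsinc", "hard"), tbw = 8,
                             duration_ms = 1, n_samples = 256) {
  shape <- match.arg(shape)
  structure(list(shape = shape, tbw = tbw, duration_ms = duration_ms,
                 n_samples = n_samples),
            class = "pulse_descriptor")
}

#' Fat spectral model
#'
#' Multi-peak fat spectrum used for Dixon simulation and fat-bias
#' modelling. The default is a six-peak liver triglyceride spectrum
#' (Hamilton-type relative amplitudes); a single-peak model at -3.4 ppm
#' is available for back-of-envelope work. Frequencies are stored in Hz
#' relative to water at the given field strength.
#'
#' @param type `"multipeak"` (default) or `"singlepeak"`.
#' @param field_strength main field (T); default 3.
#' @param t1_ms fat longitudinal relaxation time (ms) at 3T.
#' @return An object of class `fat_model` with elements `ppm`, `amp`
#'   (normalised to sum 1), `freq_hz`, `t1_ms`, `field_strength`.
#' @export
fat_model <- function(type = c("multipeak", "singlepeak"),
                      field_strength = 3, t1_ms = 400) {
  type <- match.arg(type)
  gamma_mhz <- 42.5774785  # 1H gyromagnetic ratio, MHz/T
  if (type == "multipeak") {
    # liver triglyceride peaks, ppm relative to water at 4.7 ppm
    ppm <- c(5.30, 4.20, 2.75, 2.10, 1.30, 0.90) - 4.70
    amp <- c(0.048, 0.039, 0.004, 0.128, 0.693, 0.087)
  } else {
    ppm <- -3.40
    amp <- 1
  }
  amp <- amp / sum(amp)
  structure(list(type = type, ppm = ppm, amp = amp,
                 freq_hz = ppm * gamma_mhz * field_strength,
                 t1_ms = t1_ms, field_strength = field_strength),
            class = "fat_model")
}

#' Ideal-spoiling steady-state SPGR signal
#'
#' The Ernst steady state S = M0 sin(a) (1 - E1) / (1 - E1 cos(a)),
#' E1 = exp(-TR/T1), for a perfectly spoiled gradient-recalled echo.
#' Vectorised over `fa_deg` and `t1`.
#'
#' @param t1 longitudinal relaxation time (ms), > 0.
#' @param fa_deg true flip angle (degrees) in [0, 180).
#' @param tr repetition time (ms), > 0.
#' @param m0 equilibrium magnetization.
#' @return Signal in the units of `m0` (no TE decay applied).
#' @examples
#' spgr_signal(800, 15, 4.1)
#' @export
spgr_signal <- function(t1, fa_deg, tr, m0 = 1) {
  if (any(t1 <= 0)) stop("t1 must be positive")
  if (tr <= 0) stop("tr must be positive")
  if (any(fa_deg < 0) || any(fa_deg >= 180)) {
    stop("fa_deg must lie in [0, 180)")
  }
  a <- fa_deg * pi / 180
  e1 <- exp(-tr / t1)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Ernst angle
#'
#' Flip angle maximising the steady-state SPGR signal, acos(exp(-TR/T1)).
#'
#' @inheritParams spgr_signal
#' @return Angle in degrees.
#' @export
ernst_angle <- function(t1, tr) {
  acos(exp(-tr / t1)) * 180 / pi
}

#' Inversion-recovery signal model
#'
#' Three-parameter inversion recovery S(TI) = A - B exp(-TI/T1). With
#' B = 2A this is perfect inversion of a fully relaxed magnetization.
#'
#' @param ti inversion time(s) (ms), >= 0.
#' @param a recovered amplitude A.
#' @param b inversion amplitude B.
#' @param t1 longitudinal relaxation time (ms), > 0.
#' @return Model signal (signed; take `abs()` for magnitude data).
#' @export
ir_signal <- function(ti, a, b, t1) {
  if (any(ti < 0)) stop("ti must be non-negative")
  if (any(t1 <= 0)) stop("t1 must be positive")
  a - b * exp(-ti / t1)
}

# Shaped-pulse envelope on [0, 1], area-normalised later.
pulse_envelope <- function(pulse) {
  n <- pulse$n_samples
  tt <- (seq_len(n) - 0.5) / n
  if (pulse$shape == "hard") return(rep(1, n))
  x <- pulse$tbw * (tt - 0.5)
  env <- ifelse(abs(x) < 1e-12, 1, sin(pi * x) / (pi * x))
  env * 0.5 * (1 + cos(2 * pi * (tt - 0.5)))
}

#' Through-slice excitation profile
#'
#' Bloch simulation of the selective excitation: the shaped RF pulse is
#' discretised into hard-pulse segments interleaved with precession under
#' the slice-select gradient, followed by the standard half-area rephasing
#' gradient. The achieved flip angle is atan2(|Mxy|, Mz).
#'
#' @param pulse a [pulse_descriptor()].
#' @param nominal_fa nominal flip angle (degrees).
#' @param b1_factor transmit scale (achieved / nominal), >= 0.
#' @param slice_thickness nominal slice thickness (mm).
#' @param n_z number of through-slice positions.
#' @param z_span_factor half-width of the z grid in units of
#'   `slice_thickness` (grid spans `2 * z_span_factor` thicknesses).
#' @param df_dz additional through-slice off-resonance gradient (Hz/mm),
#'   e.g. from a macroscopic B0 gradient, applied during the pulse.
#' @return A list with `z_mm` (symmetric grid) and `alpha_deg` (achieved
#'   flip angle at each position).
#' @examples
#' p <- slice_profile(pulse_descriptor(), 65, 1, slice_thickness = 8)
#' @export
slice_profile <- function(pulse, nominal_fa, b1_factor = 1,
                          slice_thickness = 8, n_z = 129,
                          z_span_factor = 1.5, df_dz = 0) {
  if (!inherits(pulse, "pulse_descriptor")) {
    stop("unknown pulse descriptor")
  }
  if (b1_factor < 0) stop("b1_factor must be >= 0")
  z <- seq(-z_span_factor, z_span_factor, length.out = n_z) * slice_thickness
  if (pulse$shape == "hard") {
    return(list(z_mm = z,
                alpha_deg = rep(b1_factor * nominal_fa, length(z))))
  }
  env <- pulse_envelope(pulse)
  n <- length(env)
  dt_ms <- pulse$duration_ms / n
  # per-segment flip (rad); total on-resonance flip = b1 * nominal
  dalpha <- env / sum(env) * b1_factor * nominal_fa * pi / 180
  # slice-select gradient: pulse bandwidth maps onto the slice thickness
  bw_khz <- pulse$tbw / pulse$duration_ms
  f_khz <- bw_khz * z / slice_thickness + df_dz * z / 1000
  dphi <- 2 * pi * f_khz * dt_ms          # precession per segment (rad)
  mxy <- complex(real = rep(0, n_z), imaginary = rep(0, n_z))
  mz <- rep(1, n_z)
  for (i in seq_len(n)) {
    ca <- cos(dalpha[i] / 2)^2
    sa <- sin(dalpha[i] / 2)^2
    s <- sin(dalpha[i])
    mxy_new <- ca * mxy + sa * Conj(mxy) - 1i * s * mz
    mz <- Im(mxy) * s + cos(dalpha[i]) * mz
    mxy <- mxy_new * exp(1i * dphi)
  }
  mxy <- mxy * exp(-1i * dphi * n / 2)    # rephasing gradient (half area)
  list(z_mm = z, alpha_deg = atan2(Mod(mxy), mz) * 180 / pi)
}

#' Complex water + fat SPGR signal
#'
#' Steady-state SPGR signal of a voxel containing water and fat pools.
#' Each pool follows its own Ernst steady state (water at `tissue$t1`,
#' fat at `fat$t1_ms`); at echo time TE each fat peak is dephased by
#' exp(i 2 pi (df_peak + b0) TE) and both pools decay as exp(-TE/T2*).
#'
#' @param tissue a [tissue_params()]; `pdff` sets the fat weight.
#' @param fat a [fat_model()].
#' @param fa_deg true flip angle (degrees).
#' @param tr repetition time (ms).
#' @param te echo time(s) (ms); vectorised.
#' @param b0_hz off-resonance of the voxel (Hz).
#' @return Complex signal, one value per `te`.
#' @export
fat_water_signal <- function(tissue, fat, fa_deg, tr, te, b0_hz = 0) {
  stopifnot(inherits(tissue, "tissue_params"), inherits(fat, "fat_model"))
  te_s <- te / 1000
  r2s <- if (is.finite(tissue$t2star)) 1 / tissue$t2star else 0
  w <- spgr_signal(tissue$t1, fa_deg, tr, tissue$m0) * (1 - tissue$pdff)
  f0 <- spgr_signal(fat$t1_ms, fa_deg, tr, tissue$m0) * tissue$pdff
  sig <- w * exp(1i * 2 * pi * b0_hz * te_s - te * r2s)
  if (tissue$pdff > 0) {
    for (k in seq_along(fat$freq_hz)) {
      sig <- sig + f0 * fat$amp[k] *
        exp(1i * 2 * pi * (fat$freq_hz[k] + b0_hz) * te_s - te * r2s)
    }
  }
  sig
}
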