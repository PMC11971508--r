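#' Two-echo Dixon water-fat separation
#'
#' Separates water and fat from an opposed-phase / in-phase echo pair
#' (TEs 1.23 / 2.46 ms at 3T). Complex inputs are combined after
#' removal of the B0-induced phase at each echo:
#' W = |S_ip e^{-i phi_ip} + S_op e^{-i phi_op}| / 2 and
#' F = |S_ip e^{-i phi_ip} - S_op e^{-i phi_op}| / 2.
#' Magnitude-only inputs use W = (|S_ip| + |S_op|) / 2,
#' F = (|S_ip| - |S_op|) / 2 under the water-dominant assumption
#' (liver context); voxels where F > W are ambiguous and flagged.
#'
#' @param echo_op opposed-phase echo (complex or magnitude array/vector).
#' @param echo_ip in-phase echo, same geometry.
#' @param b0_hz per-voxel off-resonance (Hz), used for phase removal on
#'   complex inputs; ignored for magnitude inputs.
#' @param te_ms the two echo times (opposed, in-phase) in ms.
#' @return List with `water`, `fat` (same shape as inputs) and `flagged`
#'   (logical, fat-dominant/ambiguous voxels) plus `n_flagged`.
#' @export
dixon_separate <- function(echo_op, echo_ip, b0_hz = NULL,
                           te_ms = c(1.23, 2.46)) {
  if (!identical(dim(echo_op), dim(echo_ip)) ||
      length(echo_op) != length(echo_ip)) {
    stop("echo geometries do not match")
  }
  if (is.complex(echo_op) && is.complex(echo_ip)) {
    if (is.null(b0_hz)) b0_hz <- 0
    ph_op <- exp(-1i * 2 * pi * b0_hz * te_ms[1] / 1000)
    ph_ip <- exp(-1i * 2 * pi * b0_hz * te_ms[2] / 1000)
    s_op <- echo_op * ph_op
    s_ip <- echo_ip * ph_ip
    # residual common phase (coil/receiver) taken from the in-phase echo
    s_op <- s_op * exp(-1i * Arg(s_ip))
    s_ip <- Mod(s_ip)
    water <- Mod(s_ip + s_op) / 2
    fat <- Mod(s_ip - s_op) / 2
  } else {
    water <- (Mod(echo_ip) + Mod(echo_op)) / 2
    fat <- (Mod(echo_ip) - Mod(echo_op)) / 2
  }
  flagged <- fat > water
  if (!is.null(dim(echo_op))) {
    dim(water) <- dim(fat) <- dim(flagged) <- dim(echo_op)
  }
  list(water = water, fat = fat, flagged = flagged,
       n_flagged = sum(flagged))
}

#' Two-point DESPOT1 linearised T1 estimate
#'
#' Closed-form linearisation of the SPGR steady state: regressing
#' S/sin(a) on S/tan(a) gives slope E1 = exp(-TR/T1). Used as the
#' initialiser of the non-linear fit.
#'
#' @param s signals at each flip angle.
#' @param fa_deg true flip angles (degrees), same length as `s`.
#' @param tr repetition time (ms).
#' @return List with `t1` (ms) and `m0`; `t1` is `NA` when the slope is
#'   outside (0, 1).
#' @export
despot1_t1 <- function(s, fa_deg, tr) {
  a <- fa_deg * pi / 180
  x <- s / tan(a)
  y <- s / sin(a)
  slope <- stats::cov(x, y) / stats::var(x)
  if (!is.finite(slope) || slope <= 0 || slope >= 1) {
    return(list(t1 = NA_real_, m0 = NA_real_))
  }
  t1 <- -tr / log(slope)
  m0 <- (mean(y) - slope * mean(x)) / (1 - slope)
  list(t1 = t1, m0 = m0)
}

fit_vfa_voxel <- function(s, fa_deg, tr, correction, t1_bounds, tol) {
  init <- despot1_t1(s, fa_deg, tr)
  t1_0 <- min(max(ifelse(is.na(init$t1), 800, init$t1), t1_bounds[1]),
              t1_bounds[2])
  m0_0 <- ifelse(is.na(init$m0) || init$m0 <= 0, max(s) * 20, init$m0)
  res_fn <- function(p) {
    s - corrected_spgr_signal(p[1], fa_deg, tr, p[2], correction)
  }
  fit <- try(minpack.lm::nls.lm(
    par = c(t1_0, m0_0), fn = res_fn,
    lower = c(t1_bounds[1], 0), upper = c(t1_bounds[2], Inf),
    control = minpack.lm::nls.lm.control(ptol = tol, ftol = tol,
                                         maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(c(NA_real_, NA_real_, NA_real_, 0))
  }
  c(fit$par[1], fit$par[2], fit$deviance, as.numeric(fit$info %in% 1:4))
}

#' Non-linear least-squares VFA T1 fit
#'
#' Per-voxel fit of the (optionally spoiling-corrected) SPGR steady-state
#' model to water signals acquired at several nominal flip angles. The
#' nominal angles are multiplied by the per-voxel B1+ factor to obtain
#' the true excitation angles; repeated flip angles enter as separate
#' observations. A Levenberg-Marquardt optimizer is initialised from the
#' linearised DESPOT1 solution.
#'
#' @param signals numeric vector (one voxel) or matrix (voxels in rows,
#'   one column per flip-angle volume).
#' @param fa_nominal nominal flip angles (degrees), one per column.
#' @param tr repetition time (ms).
#' @param b1 per-voxel B1+ factor (scalar or vector); `NA` masks a voxel.
#' @param correction optional [build_spoiling_correction()] table applied
#'   inside the model.
#' @param t1_bounds fit bounds for T1 (ms).
#' @param tol parameter/function tolerance of the optimizer.
#' @return A data frame with one row per voxel: `t1`, `m0`, `resnorm`,
#'   `converged`, `masked`.
#' @examples
#' s <- spgr_signal(900, 0.85 * c(2, 2, 15, 15), 4.1)
#' fit_vfa_t1(s, c(2, 2, 15, 15), 4.1, b1 = 0.85)
#' @export
fit_vfa_t1 <- function(signals, fa_nominal, tr, b1 = 1, correction = NULL,
                       t1_bounds = c(100, 5000), tol = 1e-8) {
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1)
  nv <- nrow(signals)
  if (ncol(signals) != length(fa_nominal)) {
    stop("one signal column per nominal flip angle required")
  }
  if (length(unique(fa_nominal)) < 2) {
    stop("at least two distinct flip angles required")
  }
  b1 <- rep_len(b1, nv)
  out <- matrix(NA_real_, nv, 4)
  for (v in seq_len(nv)) {
    if (is.na(b1[v]) || anyNA(signals[v, ]) || all(signals[v, ] <= 0)) next
    out[v, ] <- fit_vfa_voxel(signals[v, ], b1[v] * fa_nominal, tr,
                              correction, t1_bounds, tol)
  }
  data.frame(t1 = out[, 1], m0 = out[, 2], resnorm = out[, 3],
             converged = out[, 4] == 1,
             masked = is.na(out[, 1]))
}

fit_ir_voxel <- function(s, tis, magnitude, tol) {
  ord <- order(tis)
  s <- s[ord]; tis <- tis[ord]
  imin <- which.min(abs(s))
  cand <- if (magnitude) {
    unique(pmax(pmin(c(imin - 1, imin, imin + 1), length(s)), 0))
  } else 0
  best <- NULL
  for (k in cand) {
    ss <- s
    if (k > 0) ss[seq_len(k)] <- -ss[seq_len(k)]
    a0 <- max(ss); b0 <- a0 - min(ss)
    t10 <- max(tis[imin] / log(2), 50)
    fit <- try(minpack.lm::nls.lm(
      par = c(a0, b0, t10),
      fn = function(p) ss - ir_signal(tis, p[1], p[2], p[3]),
      lower = c(0, 0, 1), upper = c(Inf, Inf, 10000),
      control = minpack.lm::nls.lm.control(ptol = tol, ftol = tol,
                                           maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) return(c(NA_real_, NA_real_, NA_real_, NA_real_, 0))
  c(best$par[3], best$par[1], best$par[2], best$deviance,
    as.numeric(best$info %in% 1:4))
}

#' Inversion-recovery spin-echo T1 fit (gold standard)
#'
#' Per-voxel three-parameter magnitude fit S(TI) = |A - B exp(-TI/T1)|.
#' Polarity of the pre-null samples is restored by trying the sign flips
#' around the minimum-signal TI and keeping the lowest-residual fit. This
#' is the phantom gold-standard T1.
#'
#' @param signals numeric vector (one voxel) or matrix (voxels in rows,
#'   one column per TI).
#' @param tis inversion times (ms), strictly increasing.
#' @param magnitude treat data as magnitude (polarity restoration); set
#'   `FALSE` for signed/real data.
#' @param tol optimizer tolerance.
#' @return Data frame per voxel: `t1`, `a`, `b`, `resnorm`, `converged`.
#' @export
fit_ir_t1 <- function(signals, tis, magnitude = TRUE, tol = 1e-10) {
  if (is.unsorted(tis, strictly = TRUE)) {
    stop("tis must be strictly increasing")
  }
  if (length(tis) < 4) stop("at least 4 TIs required")
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1)
  nv <- nrow(signals)
  out <- matrix(NA_real_, nv, 5)
  for (v in seq_len(nv)) {
    if (anyNA(signals[v, ])) next
    out[v, ] <- fit_ir_voxel(signals[v, ], tis, magnitude, tol)
  }
  data.frame(t1 = out[, 1], a = out[, 2], b = out[, 3],
             resnorm = out[, 4], converged = out[, 5] == 1)
}

#' Logarithmic inversion-time schedule
#'
#' The gold-standard IR-SE schedule: TIs spaced logarithmically.
#'
#' @param n number of inversion times.
#' @param ti_min,ti_max first and last TI (ms).
#' @return Numeric vector of TIs (ms).
#' @export
ir_ti_schedule <- function(n = 10, ti_min = 25, ti_max = 5000) {
  exp(seq(log(ti_min), log(ti_max), length.out = n))
}
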