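wrap_to_pi <- function(x) {
  (x + pi) %% (2 * pi) - pi
}

# Quality-guided 2D phase unwrapping of one slice. Flood fill from the
# highest-quality voxel; each frontier voxel is unwrapped against its
# highest-quality already-unwrapped neighbour by adding the multiple of
# 2*pi closest to that reference.
unwrap_phase_2d <- function(phase, mask = NULL, quality = NULL) {
  d <- dim(phase)
  if (is.null(mask)) mask <- array(TRUE, d)
  if (is.null(quality)) quality <- array(1, d)
  out <- array(NA_real_, d)
  todo <- which(mask)
  if (!length(todo)) return(out)
  done <- array(FALSE, d)
  seed <- todo[which.max(quality[todo])]
  out[seed] <- phase[seed]
  done[seed] <- TRUE
  nb <- function(idx) {
    i <- (idx - 1L) %% d[1] + 1L
    j <- (idx - 1L) %/% d[1] + 1L
    cand <- rbind(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))
    ok <- cand[, 1] >= 1L & cand[, 1] <= d[1] &
      cand[, 2] >= 1L & cand[, 2] <= d[2]
    cand <- cand[ok, , drop = FALSE]
    (cand[, 2] - 1L) * d[1] + cand[, 1]
  }
  frontier <- setdiff(nb(seed), seed)
  frontier <- frontier[mask[frontier]]
  while (length(frontier)) {
    k <- frontier[which.max(quality[frontier])]
    nbk <- nb(k)
    ref <- nbk[done[nbk]]
    ref <- ref[which.max(quality[ref])]
    out[k] <- out[ref] + wrap_to_pi(phase[k] - phase[ref])
    done[k] <- TRUE
    new_nb <- nb(k)
    new_nb <- new_nb[mask[new_nb] & !done[new_nb]]
    frontier <- unique(c(frontier[frontier != k], new_nb))
  }
  out
}

#' B0 map from a dual-echo gradient-echo acquisition
#'
#' Off-resonance is the phase of echo2 * conj(echo1) divided by
#' 2 pi * delta TE, spatially unwrapped slice by slice with a
#' quality-guided (magnitude-weighted) algorithm inside the validity
#' mask. Voxels whose magnitude falls below `thresh_factor` times the
#' background noise SD are masked out.
#'
#' @param echo1,echo2 complex image volumes (2D or 3D arrays), same
#'   geometry, at the two echo times.
#' @param delta_te_ms echo-time difference (ms); the reference protocol
#'   uses 7.17 - 4.78 = 2.39 ms.
#' @param noise_sd background noise SD for masking; estimated from the
#'   darkest decile of the magnitude image when `NULL`.
#' @param thresh_factor mask threshold in units of `noise_sd`.
#' @param unwrap apply 2D per-slice phase unwrapping.
#' @return An object of class `b0_map`: list with `offres_hz`, `mask`,
#'   `delta_te_ms`, `n_masked`.
#' @export
compute_b0 <- function(echo1, echo2, delta_te_ms, noise_sd = NULL,
                       thresh_factor = 5, unwrap = TRUE) {
  if (!identical(dim(echo1), dim(echo2))) stop("echo geometries differ")
  mag <- Mod(echo1)
  if (is.null(noise_sd)) {
    bg <- mag[mag <= stats::quantile(mag, 0.1)]
    noise_sd <- sqrt(mean(bg^2) / 2)   # Rayleigh background
  }
  mask <- mag > thresh_factor * noise_sd
  dphi <- Arg(echo2 * Conj(echo1))
  d <- dim(echo1)
  if (length(d) == 2) {
    dim(dphi) <- dim(mask) <- c(d, 1L)
  }
  if (unwrap) {
    qual <- Mod(echo1) * Mod(echo2)
    if (length(d) == 2) dim(qual) <- c(d, 1L)
    for (s in seq_len(dim(dphi)[3])) {
      dphi[, , s] <- unwrap_phase_2d(dphi[, , s], mask[, , s],
                                     qual[, , s])
    }
  } else {
    dphi[!mask] <- NA_real_
  }
  dim(dphi) <- dim(mask) <- d
  offres <- dphi / (2 * pi * delta_te_ms / 1000)
  offres[!mask] <- NA_real_
  if (unwrap && any(mask)) {
    # unwrapping fixes relative phase only; anchor the global 2*pi
    # multiple so the FOV-median off-resonance is within +-1/(2*dTE)
    # (the shim convention)
    cyc <- round(stats::median(offres, na.rm = TRUE) *
                   delta_te_ms / 1000)
    offres <- offres - cyc / (delta_te_ms / 1000)
  }
  structure(list(offres_hz = offres, mask = mask,
                 delta_te_ms = delta_te_ms, n_masked = sum(!mask)),
            class = "b0_map")
}

#' EPI distortion correction along the phase-encode axis
#'
#' Off-resonance shifts an EPI voxel along the phase-encode direction by
#' f * esp * n_pe voxels (echo spacing `esp`, `n_pe` phase-encode lines).
#' This resamples each phase-encode column with 1-D linear interpolation
#' to undo (`direction = "unwarp"`) or apply (`"warp"`) that shift; a
#' zero field map is the identity.
#'
#' @param vol image array (2D or 3D).
#' @param b0 a [compute_b0()] object or an off-resonance array (Hz) on
#'   the EPI grid.
#' @param esp_ms effective echo spacing (ms).
#' @param n_pe number of phase-encode lines.
#' @param pe_axis array axis of phase encoding (1 or 2).
#' @param direction `"unwarp"` to correct a distorted image, `"warp"` to
#'   simulate the distortion.
#' @param max_shift_frac voxels shifted by more than this fraction of the
#'   FOV are flagged.
#' @return List with `data` (resampled array) and `n_flagged`.
#' @export
unwarp_epi <- function(vol, b0, esp_ms, n_pe, pe_axis = 2,
                       direction = c("unwarp", "warp"),
                       max_shift_frac = 0.25) {
  direction <- match.arg(direction)
  offres <- if (inherits(b0, "b0_map")) b0$offres_hz else b0
  if (!identical(dim(offres), dim(vol))) {
    stop("b0 must be resampled to the EPI grid")
  }
  shift <- offres * esp_ms / 1000 * n_pe
  shift[is.na(shift)] <- 0
  if (direction == "warp") shift <- -shift
  d <- dim(vol)
  n_flagged <- sum(abs(shift) > max_shift_frac * d[pe_axis])
  out <- vol
  d3 <- if (length(d) == 2) 1L else d[3]
  for (s in seq_len(d3)) {
    sl <- if (length(d) == 2) vol else vol[, , s]
    sh <- if (length(d) == 2) shift else shift[, , s]
    if (pe_axis == 1) {
      sl <- t(sl); sh <- t(sh)
    }
    for (i in seq_len(nrow(sl))) {
      y <- seq_len(ncol(sl))
      sl[i, ] <- stats::approx(y, sl[i, ], xout = y + sh[i, ],
                               rule = 2)$y
    }
    if (pe_axis == 1) sl <- t(sl)
    if (length(d) == 2) out <- sl else out[, , s] <- sl
  }
  list(data = out, n_flagged = n_flagged)
}

#' 3D double-angle B1+ map (long-TR gold standard)
#'
#' With full relaxation (TR >> T1) the GRE signal is proportional to
#' sin(alpha), so the achieved angle follows from the double-angle ratio:
#' alpha = acos(S(2a) / (2 S(a))). The B1+ factor is alpha divided by the
#' nominal angle. Voxels where the ratio leaves the acos domain or the
#' single-angle signal is below threshold are masked and counted.
#'
#' @param img_alpha,img_2alpha magnitude images at nominal angles a, 2a.
#' @param nominal_alpha nominal flip angle a (degrees), default 65.
#' @param min_signal mask threshold on `img_alpha`.
#' @return Object of class `b1_map`: `b1_factor`, `mask`, `source`,
#'   `n_masked`.
#' @export
dam_b1_3d <- function(img_alpha, img_2alpha, nominal_alpha = 65,
                      min_signal = 0) {
  if (!identical(dim(img_alpha), dim(img_2alpha))) {
    stop("image geometries differ")
  }
  ratio <- img_2alpha / (2 * img_alpha)
  bad <- !is.finite(ratio) | abs(ratio) > 1 | img_alpha <= min_signal
  ratio[bad] <- 0
  b1 <- acos(ratio) * 180 / pi / nominal_alpha
  b1[bad] <- NA_real_
  structure(list(b1_factor = b1, mask = !bad, source = "3D-GS",
                 n_masked = sum(bad)),
            class = "b1_map")
}

#' Through-slice-integrated double-angle signal-ratio lookup
#'
#' Builds the forward model used by the corrected 2D DAM inversion: for
#' each candidate B1+ factor, the selective excitation profiles at the
#' two nominal angles are Bloch-simulated and integrated through slice
#' with a complex dephasing weight exp(i 2 pi g z TE) encoding a
#' through-slice B0 gradient g, giving the expected signal ratio
#' R(b1; g) = |int sin(a2(z)) w(z) dz| / |int sin(a1(z)) w(z) dz|.
#' Monotonicity of R over the supported b1 range is asserted at build.
#'
#' @param pulse a [pulse_descriptor()].
#' @param nominal_alpha nominal single angle (degrees).
#' @param slice_thickness slice thickness (mm).
#' @param te_ms EPI echo time (ms) at which dephasing acts.
#' @param b1_grid candidate B1+ factors (strictly increasing).
#' @param g_grid through-slice B0 gradients (Hz/mm) tabulated.
#' @return Object of class `dam_lookup`.
#' @export
build_dam_lookup <- function(pulse = pulse_descriptor(),
                             nominal_alpha = 65, slice_thickness = 8,
                             te_ms = 11,
                             b1_grid = seq(0.3, 1.3, by = 0.025),
                             g_grid = seq(-4, 4, by = 1)) {
  profs1 <- lapply(b1_grid, function(b1) {
    slice_profile(pulse, nominal_alpha, b1, slice_thickness)
  })
  profs2 <- lapply(b1_grid, function(b1) {
    slice_profile(pulse, 2 * nominal_alpha, b1, slice_thickness)
  })
  z <- profs1[[1]]$z_mm
  nz <- length(z)
  ratio <- s1m <- s2m <- matrix(NA_real_, length(b1_grid),
                                length(g_grid))
  for (j in seq_along(g_grid)) {
    w <- exp(1i * 2 * pi * g_grid[j] * z * te_ms / 1000)
    for (i in seq_along(b1_grid)) {
      s1 <- abs(sum(sin(profs1[[i]]$alpha_deg * pi / 180) * w)) / nz
      s2 <- abs(sum(sin(profs2[[i]]$alpha_deg * pi / 180) * w)) / nz
      ratio[i, j] <- s2 / s1
      s1m[i, j] <- s1
      s2m[i, j] <- s2
    }
  }
  for (j in seq_along(g_grid)) {
    if (any(diff(ratio[, j]) >= 0)) {
      stop("non-monotone DAM lookup segment; narrow b1_grid")
    }
  }
  structure(list(b1_grid = b1_grid, g_grid = g_grid, ratio = ratio,
                 s1 = s1m, s2 = s2m, nominal_alpha = nominal_alpha,
                 slice_thickness = slice_thickness, te_ms = te_ms),
            class = "dam_lookup")
}

#' 2D double-angle B1+ map with slice-profile and B0-gradient correction
#'
#' Inverts the measured double-angle EPI signal ratio through the
#' Bloch-simulated through-slice lookup of [build_dam_lookup()]: per
#' voxel, the B1+ factor is the value whose predicted profile-integrated
#' ratio (at that voxel's through-slice B0 gradient) matches the
#' measurement. With `correct = FALSE` the naive acos inversion of
#' [dam_b1_3d()] is used instead (for quantifying the slice-profile
#' bias).
#'
#' @param img_alpha,img_2alpha distortion-corrected magnitude EPI images
#'   at nominal angles a and 2a.
#' @param lookup a [build_dam_lookup()] table.
#' @param g_hz_mm through-slice B0 gradient (Hz/mm): scalar or array
#'   matching the images, e.g. from [b0_gradient_z()].
#' @param min_signal mask threshold on `img_alpha`.
#' @param correct apply the slice-profile/B0-gradient correction.
#' @return Object of class `b1_map` with `source = "2D-corrected"`.
#' @export
dam_b1_2d <- function(img_alpha, img_2alpha, lookup,
                      g_hz_mm = 0, min_signal = 0, correct = TRUE) {
  if (!identical(dim(img_alpha), dim(img_2alpha))) {
    stop("image geometries differ")
  }
  if (!correct) {
    res <- dam_b1_3d(img_alpha, img_2alpha, lookup$nominal_alpha,
                     min_signal)
    res$source <- "2D-uncorrected"
    return(res)
  }
  stopifnot(inherits(lookup, "dam_lookup"))
  ratio <- img_2alpha / img_alpha
  g <- rep_len(as.vector(g_hz_mm), length(ratio))
  g <- pmin(pmax(g, lookup$g_grid[1]),
            lookup$g_grid[length(lookup$g_grid)])
  b1 <- rep(NA_real_, length(ratio))
  jg <- pmin(findInterval(g, lookup$g_grid),
             length(lookup$g_grid) - 1L)
  for (j in sort(unique(jg))) {
    sel <- which(jg == j)
    v <- (g[sel] - lookup$g_grid[j]) /
      (lookup$g_grid[j + 1L] - lookup$g_grid[j])
    # interpolate the lookup column to each voxel's gradient, then
    # invert the monotone-decreasing R(b1)
    for (k in seq_along(sel)) {
      rcol <- (1 - v[k]) * lookup$ratio[, j] +
        v[k] * lookup$ratio[, j + 1L]
      rv <- ratio[sel[k]]
      if (!is.finite(rv) || rv > max(rcol) || rv < min(rcol)) next
      b1[sel[k]] <- stats::approx(rcol, lookup$b1_grid, xout = rv)$y
    }
  }
  b1[as.vector(img_alpha) <= min_signal] <- NA_real_
  bad <- is.na(b1)
  if (!is.null(dim(img_alpha))) dim(b1) <- dim(img_alpha)
  structure(list(b1_factor = b1, mask = !is.na(b1),
                 source = "2D-corrected", n_masked = sum(bad)),
            class = "b1_map")
}

#' Fill masked voxels of a smooth field from valid neighbours
#'
#' Iteratively replaces `NA` voxels that touch valid ones by the mean
#' of their valid 6-neighbours. Intended for smooth field maps (B0,
#' B1+) whose masked holes and one-to-two-voxel edge losses would
#' otherwise propagate through conservative resampling; `n_iter` bounds
#' how far the fill can extrapolate.
#'
#' @param arr numeric array (2D or 3D) with `NA` holes.
#' @param n_iter maximum fill distance in voxels.
#' @return Array with (reachable) holes filled.
#' @export
fill_na_nearest <- function(arr, n_iter = 3) {
  orig_d <- dim(arr)
  d <- orig_d
  if (length(d) == 2) dim(arr) <- d <- c(d, 1L)
  for (it in seq_len(n_iter)) {
    nas <- which(is.na(arr))
    if (!length(nas)) break
    acc <- array(0, d); cnt <- array(0L, d)
    add <- function(src_idx, dst_idx) {
      v <- arr[src_idx]
      ok <- !is.na(v)
      acc[dst_idx[ok]] <<- acc[dst_idx[ok]] + v[ok]
      cnt[dst_idx[ok]] <<- cnt[dst_idx[ok]] + 1L
    }
    n1 <- d[1]; n2 <- d[2]; n3 <- d[3]
    idx <- array(seq_along(arr), d)
    add(idx[-1, , , drop = FALSE], idx[-n1, , , drop = FALSE])
    add(idx[-n1, , , drop = FALSE], idx[-1, , , drop = FALSE])
    add(idx[, -1, , drop = FALSE], idx[, -n2, , drop = FALSE])
    add(idx[, -n2, , drop = FALSE], idx[, -1, , drop = FALSE])
    if (n3 > 1) {
      add(idx[, , -1, drop = FALSE], idx[, , -n3, drop = FALSE])
      add(idx[, , -n3, drop = FALSE], idx[, , -1, drop = FALSE])
    }
    fill <- nas[cnt[nas] > 0]
    arr[fill] <- acc[fill] / cnt[fill]
  }
  dim(arr) <- orig_d
  arr
}

#' Through-slice B0 gradient from a multi-slice B0 map
#'
#' Central finite differences of the off-resonance field across
#' neighbouring slice centers; one-sided differences at the end slices.
#' The gradient is taken constant within a slice.
#'
#' @param b0 a [compute_b0()] object or off-resonance array (Hz),
#'   slices along the third axis.
#' @param slice_center_spacing_mm distance between slice centers (mm);
#'   8 mm slices with 2 mm gaps give 10 mm.
#' @return Array of through-slice gradients (Hz/mm), same shape.
#' @export
b0_gradient_z <- function(b0, slice_center_spacing_mm = 10) {
  f <- if (inherits(b0, "b0_map")) b0$offres_hz else b0
  d <- dim(f)
  ns <- d[3]
  g <- array(NA_real_, d)
  if (ns == 1) {
    g[] <- 0
    return(g)
  }
  for (s in seq_len(ns)) {
    lo <- max(s - 1, 1); hi <- min(s + 1, ns)
    g[, , s] <- (f[, , hi] - f[, , lo]) /
      ((hi - lo) * slice_center_spacing_mm)
  }
  g
}

#' Trilinear resampling of a B1+ map to a target grid
#'
#' Interpolates in physical coordinates (axis-aligned geometry given by
#' voxel spacing and origin). Mask propagation is conservative: a target
#' voxel is valid only if all contributing source voxels are valid.
#'
#' @param b1 a `b1_map` (or numeric array).
#' @param src_geom,dst_geom lists with `spacing` (mm, length 3), `origin`
#'   (mm, length 3) and for `dst_geom` a `dim` (target array dimension).
#' @return A `b1_map` on the target grid; masked-voxel count in
#'   `n_masked`.
#' @export
resample_b1_to_spgr <- function(b1, src_geom, dst_geom) {
  arr <- if (inherits(b1, "b1_map")) b1$b1_factor else b1
  out <- trilinear_resample(arr, src_geom, dst_geom)
  structure(list(b1_factor = out, mask = !is.na(out),
                 source = if (inherits(b1, "b1_map")) b1$source else "map",
                 n_masked = sum(is.na(out))),
            class = "b1_map")
}

trilinear_resample <- function(arr, src_geom, dst_geom) {
  d <- dim(arr)
  dd <- dst_geom$dim
  out <- array(NA_real_, dd)
  # physical coordinate of target voxel (0-based index convention)
  cx <- dst_geom$origin[1] + (seq_len(dd[1]) - 1) * dst_geom$spacing[1]
  cy <- dst_geom$origin[2] + (seq_len(dd[2]) - 1) * dst_geom$spacing[2]
  cz <- dst_geom$origin[3] + (seq_len(dd[3]) - 1) * dst_geom$spacing[3]
  # fractional source indices (1-based)
  fx <- (cx - src_geom$origin[1]) / src_geom$spacing[1] + 1
  fy <- (cy - src_geom$origin[2]) / src_geom$spacing[2] + 1
  fz <- (cz - src_geom$origin[3]) / src_geom$spacing[3] + 1
  eps <- 1e-9
  idx <- function(f, dmax) {
    i <- pmin(pmax(floor(f), 1), dmax - 1)
    i[f < 1 - eps | f > dmax + eps] <- NA_integer_
    i
  }
  ix <- idx(fx, d[1]); iy <- idx(fy, d[2]); iz <- idx(fz, d[3])
  for (k in seq_len(dd[3])) {
    if (is.na(iz[k])) next
    wz <- fz[k] - iz[k]
    for (j in seq_len(dd[2])) {
      if (is.na(iy[j])) next
      wy <- fy[j] - iy[j]
      for (i in seq_len(dd[1])) {
        if (is.na(ix[i])) next
        wx <- fx[i] - ix[i]
        c00 <- arr[ix[i], iy[j], iz[k]] * (1 - wx) +
          arr[ix[i] + 1, iy[j], iz[k]] * wx
        c10 <- arr[ix[i], iy[j] + 1, iz[k]] * (1 - wx) +
          arr[ix[i] + 1, iy[j] + 1, iz[k]] * wx
        c01 <- arr[ix[i], iy[j], iz[k] + 1] * (1 - wx) +
          arr[ix[i] + 1, iy[j], iz[k] + 1] * wx
        c11 <- arr[ix[i], iy[j] + 1, iz[k] + 1] * (1 - wx) +
          arr[ix[i] + 1, iy[j] + 1, iz[k] + 1] * wx
        out[i, j, k] <- (c00 * (1 - wy) + c10 * wy) * (1 - wz) +
          (c01 * (1 - wy) + c11 * wy) * wz
      }
    }
  }
  out
}
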