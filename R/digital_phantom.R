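#' Digital phantom specification
#'
#' Describes the synthetic object and fields from which all acquisitions
#' are generated. The default `"vials"` layout mimics a 14-vial agar T1
#' phantom (T1 367-1699 ms in approximately 100 ms steps, T2 45 ms, no
#' fat); the `"abdomen"` layout is a uniform liver-like ellipse
#' (T1 800 ms, T2 34 ms). The transmit field is a smooth 2D Gaussian
#' depression (vendor-body-coil-like) whose depth sets the B1+ range;
#' B0 is a smooth in-plane gradient with an optional through-slice
#' gradient. All randomness (Rician noise) is fixed by `seed`.
#'
#' @param layout `"vials"` or `"abdomen"`.
#' @param dim in-plane and slice dimensions of the SPGR grid.
#' @param spacing SPGR voxel spacing (mm).
#' @param vial_t1s vial T1 values (ms).
#' @param t1_abdomen uniform tissue T1 (ms) for the abdomen layout.
#' @param bg_t1 T1 (ms) of the gel body holding the vials (gives the
#'   field-mapping acquisitions signal across the whole object).
#' @param t2 transverse relaxation (ms): 45 for the agar vials.
#' @param t2star effective T2* (ms).
#' @param pdff proton-density fat fraction of the object.
#' @param b1_range approximate (min, max) of the B1+ field.
#' @param b0_amp_hz peak-to-peak in-plane B0 variation (Hz).
#' @param b0_gradient_z_hz_mm through-slice B0 gradient (Hz/mm).
#' @param snr signal-to-noise ratio of the 15-degree SPGR acquisition
#'   (peak vial signal over Rician noise sigma); `Inf` for noiseless.
#' @param m0 proton density scale.
#' @param seed RNG seed fixing every noise realization.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(layout = c("vials", "abdomen"),
                         dim = c(64, 64, 4), spacing = c(3.5, 3.5, 3),
                         vial_t1s = seq(367, 1699, length.out = 14),
                         t1_abdomen = 800, bg_t1 = 1000,
                         t2 = if (match.arg(layout) == "vials") 45 else 34,
                         t2star = t2, pdff = 0,
                         b1_range = c(0.8, 1.05), b0_amp_hz = 60,
                         b0_gradient_z_hz_mm = 0, snr = Inf, m0 = 100,
                         seed = 42) {
  layout <- match.arg(layout)
  structure(list(layout = layout, dim = dim, spacing = spacing,
                 vial_t1s = vial_t1s, t1_abdomen = t1_abdomen,
                 bg_t1 = bg_t1, t2 = t2,
                 t2star = t2star, pdff = pdff, b1_range = b1_range,
                 b0_amp_hz = b0_amp_hz,
                 b0_gradient_z_hz_mm = b0_gradient_z_hz_mm,
                 snr = snr, m0 = m0, seed = seed),
            class = "phantom_spec")
}

#' Rician-corrupted magnitude data
#'
#' Adds complex Gaussian noise of SD `sigma` per channel to a (real)
#' noiseless signal and returns the modulus, i.e. Rician-distributed
#' magnitudes.
#'
#' @param x noiseless signal array.
#' @param sigma per-channel noise SD; 0 returns `x` unchanged.
#' @return Array like `x`.
#' @export
add_rician <- function(x, sigma) {
  if (sigma <= 0) return(x)
  n <- length(x)
  out <- sqrt((x + stats::rnorm(n, 0, sigma))^2 +
                stats::rnorm(n, 0, sigma)^2)
  dim(out) <- dim(x)
  out
}

# ground-truth object maps + ROI table on the SPGR grid
phantom_truth <- function(spec) {
  d <- spec$dim
  xs <- seq_len(d[1]); ys <- seq_len(d[2])
  t1 <- array(NA_real_, d)
  rois <- NULL
  cx0 <- (d[1] + 1) / 2; cy0 <- (d[2] + 1) / 2
  if (spec$layout == "vials") {
    nv <- length(spec$vial_t1s)
    ring_r <- 0.33 * min(d[1], d[2])
    vial_r <- max(3, round(0.055 * min(d[1], d[2])))
    body_r <- 0.47 * min(d[1], d[2])
    body <- outer((xs - cx0)^2, (ys - cy0)^2, `+`) <= body_r^2
    ang <- 2 * pi * (seq_len(nv) - 1) / nv
    cx <- cx0 + ring_r * cos(ang)
    cy <- cy0 + ring_r * sin(ang)
    for (s in seq_len(d[3])) {
      sl <- t1[, , s]
      sl[body] <- spec$bg_t1
      for (v in seq_len(nv)) {
        dist2 <- outer((xs - cx[v])^2, (ys - cy[v])^2, `+`)
        sl[dist2 <= vial_r^2] <- spec$vial_t1s[v]
      }
      t1[, , s] <- sl
    }
    rois <- do.call(rbind, lapply(seq_len(d[3]), function(s) {
      data.frame(slice = s, roi = seq_len(nv), cx = cx, cy = cy,
                 radius_px = vial_r - 1, vial = seq_len(nv),
                 true_t1 = spec$vial_t1s)
    }))
  } else {
    a <- 0.42 * d[1]; b <- 0.34 * d[2]
    el <- outer(((xs - cx0) / a)^2, ((ys - cy0) / b)^2, `+`)
    for (s in seq_len(d[3])) {
      sl <- t1[, , s]
      sl[el <= 1] <- spec$t1_abdomen
      t1[, , s] <- sl
    }
    # 3 ROIs per slice spread across the ellipse
    rcx <- cx0 + c(-0.5, 0, 0.5) * a
    rcy <- cy0 + c(-0.3, 0.45, -0.3) * b
    rois <- do.call(rbind, lapply(seq_len(d[3]), function(s) {
      data.frame(slice = s, roi = 1:3, cx = rcx, cy = rcy,
                 radius_px = 4, vial = NA_integer_,
                 true_t1 = spec$t1_abdomen)
    }))
  }
  # smooth transmit depression reaching b1_range[1] at one corner
  sig <- 0.55 * max(d[1], d[2])
  g2 <- outer((xs - 0.15 * d[1])^2, (ys - 0.2 * d[2])^2, `+`)
  b1_2d <- spec$b1_range[2] -
    (spec$b1_range[2] - spec$b1_range[1]) * exp(-g2 / (2 * sig^2))
  b1 <- array(rep(b1_2d, d[3]), d)
  b0_2d <- spec$b0_amp_hz *
    (outer((xs - cx0) / d[1], 0 * ys, `+`) +
       outer(0 * xs, (ys - cy0) / d[2], `+`))
  zc <- (seq_len(d[3]) - (d[3] + 1) / 2) * spec$spacing[3]
  b0 <- array(NA_real_, d)
  for (s in seq_len(d[3])) {
    b0[, , s] <- b0_2d + spec$b0_gradient_z_hz_mm * zc[s]
  }
  pdff <- array(spec$pdff, d)
  pdff[is.na(t1)] <- 0
  geom <- list(dim = d, spacing = spec$spacing,
               origin = -(d - 1) / 2 * spec$spacing)
  list(t1 = t1, b1 = b1, b0 = b0, b0_2d = b0_2d, pdff = pdff,
       mask = !is.na(t1), rois = rois, geom = geom, zc = zc)
}

# EPI/B0 grid covering the same FOV at half in-plane resolution and
# 10 mm slice centers
phantom_epi_geom <- function(spec) {
  d <- spec$dim
  de <- c(d[1] %/% 2, d[2] %/% 2, max(3L, d[3] %/% 2 + 1L))
  sp <- c(spec$spacing[1] * 2, spec$spacing[2] * 2, 10)
  list(dim = de, spacing = sp, origin = -(de - 1) / 2 * sp)
}

#' Generate synthetic acquisitions from a digital phantom
#'
#' Emits, for a [phantom_spec()], the image volumes each pipeline stage
#' consumes, in the same structure the scanner protocols would provide:
#' the VFA SPGR dual-echo Dixon series (EPG-simulated RF spoiling, fat
#' via the spectral model, complex echoes), the double-angle EPI pair
#' (slice-profile-integrated, B0-distorted), the dual-echo B0-mapping
#' GRE, the long-TR 3D DAM pair, and the gold-standard IR-SE series.
#' Ground-truth maps and the ROI table ride along. Rician noise is
#' applied to magnitude data (complex Gaussian to complex data) at the
#' SNR stated in the spec; the seed makes everything reproducible.
#'
#' @param spec a [phantom_spec()].
#' @param which subset of
#'   `c("vfa_dixon", "dam_epi", "b0_gre", "dam_3d", "ir_se")`.
#' @param fa_nominal nominal VFA flip angles (degrees).
#' @param tr repetition time (ms) of the SPGR.
#' @param te echo times (ms) of the Dixon pair.
#' @param phi_inc_deg RF-spoiling increment used in the EPG generation.
#' @param epg_spoiling simulate incomplete spoiling via EPG (otherwise
#'   ideal Ernst signals).
#' @param fat a [fat_model()].
#' @param lookup optional precomputed [build_dam_lookup()] reused for
#'   the EPI generation.
#' @param n_ti number of IR-SE inversion times.
#' @return List with one element per requested acquisition plus
#'   `truth`, `params` (sidecar-style sequence parameters) and `spec`.
#' @export
generate_acquisitions <- function(spec,
                                  which = c("vfa_dixon", "dam_epi",
                                            "b0_gre", "dam_3d",
                                            "ir_se"),
                                  fa_nominal = c(2, 2, 15, 15),
                                  tr = 4.1, te = c(1.23, 2.46),
                                  phi_inc_deg = 50, epg_spoiling = TRUE,
                                  fat = fat_model(), lookup = NULL,
                                  n_ti = 10) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  truth <- phantom_truth(spec)
  d <- spec$dim
  sigma <- if (is.finite(spec$snr)) {
    max(spgr_signal(stats::median(truth$t1, na.rm = TRUE), 15, tr,
                    spec$m0)) / spec$snr
  } else 0
  out <- list(truth = truth, spec = spec,
              params = list(tr = tr, te = te, fa_nominal = fa_nominal,
                            phi_inc_deg = phi_inc_deg,
                            dam_nominal = 65, epi_esp_ms = 0.3,
                            b0_te_ms = c(4.78, 7.17),
                            ir_tis = ir_ti_schedule(n_ti),
                            sigma = sigma))
  t1v <- as.vector(truth$t1); b1v <- as.vector(truth$b1)
  b0v <- as.vector(truth$b0); pdv <- as.vector(truth$pdff)
  inside <- !is.na(t1v)
  t1s_used <- sort(unique(t1v[inside]))

  if ("vfa_dixon" %in% which) {
    fas <- unique(fa_nominal)
    # per (vial T1, nominal FA): water-pool signal vs true flip angle,
    # EPG-simulated on a B1 grid and spline-interpolated per voxel
    water_sig <- function(t1, fa_nom) {
      if (!epg_spoiling) {
        return(function(b1) spgr_signal(t1, b1 * fa_nom, tr, spec$m0))
      }
      b1g <- seq(max(min(b1v[inside]) - 0.03, 0.05),
                 max(b1v[inside]) + 0.03, length.out = 9)
      s <- vapply(b1g, function(b1) {
        epg_spgr_steady_state(t1, spec$t2, b1 * fa_nom, tr,
                              phi_inc_deg)$magnitude * spec$m0
      }, numeric(1))
      stats::splinefun(b1g, s)
    }
    vols <- list()
    for (k in seq_along(fa_nominal)) {
      fns <- lapply(t1s_used, water_sig, fa_nom = fa_nominal[k])
      names(fns) <- as.character(t1s_used)
      e <- matrix(0 + 0i, length(t1v), length(te))
      for (ti in t1s_used) {
        sel <- inside & t1v == ti
        w <- fns[[as.character(ti)]](b1v[sel])
        r2s <- 1 / spec$t2star
        for (m in seq_along(te)) {
          sig <- w * (1 - pdv[sel]) *
            exp(1i * 2 * pi * b0v[sel] * te[m] / 1000 - te[m] * r2s)
          if (any(pdv[sel] > 0)) {
            ffat <- spgr_signal(fat$t1_ms, b1v[sel] * fa_nominal[k],
                                tr, spec$m0) * pdv[sel]
            for (p in seq_along(fat$freq_hz)) {
              sig <- sig + ffat * fat$amp[p] *
                exp(1i * 2 * pi * (fat$freq_hz[p] + b0v[sel]) *
                      te[m] / 1000 - te[m] * r2s)
            }
          }
          e[sel, m] <- sig
        }
      }
      if (sigma > 0) {
        e <- e + complex(real = stats::rnorm(length(e), 0, sigma),
                         imaginary = stats::rnorm(length(e), 0, sigma))
      }
      vols[[k]] <- lapply(seq_along(te), function(m) {
        arr <- array(e[, m], d)
        arr
      })
    }
    out$vfa_dixon <- list(volumes = vols, fa_nominal = fa_nominal,
                          te = te, tr = tr, geom = truth$geom)
  }

  if (any(c("dam_epi", "b0_gre") %in% which)) {
    eg <- phantom_epi_geom(spec)
    # ground truth resampled onto the EPI grid; the object extends
    # axially past the thin SPGR slab, so z is clamped to the slab
    zq <- eg$origin[3] + (seq_len(eg$dim[3]) - 1) * eg$spacing[3]
    zq_cl <- pmin(pmax(zq, truth$geom$origin[3]),
                  truth$geom$origin[3] +
                    (d[3] - 1) * spec$spacing[3])
    rs <- function(arr) {
      out <- array(NA_real_, eg$dim)
      for (k in seq_len(eg$dim[3])) {
        g1 <- list(dim = c(eg$dim[1:2], 1L), spacing = eg$spacing,
                   origin = c(eg$origin[1:2], zq_cl[k]))
        out[, , k] <- trilinear_resample(arr, truth$geom, g1)
      }
      out
    }
    t1e <- rs(truth$t1); b1e <- rs(truth$b1)
    # B0 continues its through-slice gradient outside the slab
    b0e <- rs(truth$b0) +
      rep(spec$b0_gradient_z_hz_mm * (zq - zq_cl),
          each = prod(eg$dim[1:2]))
    dim(b0e) <- eg$dim
    ins_e <- !is.na(t1e)
    b0e_f <- b0e; b0e_f[!ins_e] <- 0
    if ("b0_gre" %in% which) {
      mag <- array(0, eg$dim); mag[ins_e] <- spec$m0 / 10
      tes <- out$params$b0_te_ms
      mk <- function(te_ms) {
        e <- mag * exp(1i * 2 * pi * b0e_f * te_ms / 1000)
        if (sigma > 0) {
          e <- e + complex(real = stats::rnorm(length(e), 0, sigma),
                           imaginary = stats::rnorm(length(e), 0,
                                                    sigma))
          dim(e) <- eg$dim
        }
        e
      }
      out$b0_gre <- list(echo1 = mk(tes[1]), echo2 = mk(tes[2]),
                         delta_te_ms = diff(tes), geom = eg)
    }
    if ("dam_epi" %in% which) {
      if (is.null(lookup)) lookup <- build_dam_lookup()
      gz <- array(spec$b0_gradient_z_hz_mm, eg$dim)
      b1c <- pmin(pmax(b1e, min(lookup$b1_grid)), max(lookup$b1_grid))
      s1 <- array(NA_real_, eg$dim); s2 <- array(NA_real_, eg$dim)
      gcl <- pmin(pmax(gz, min(lookup$g_grid)), max(lookup$g_grid))
      for (v in which(ins_e)) {
        i <- min(findInterval(b1c[v], lookup$b1_grid),
                 length(lookup$b1_grid) - 1L)
        j <- min(findInterval(gcl[v], lookup$g_grid),
                 length(lookup$g_grid) - 1L)
        u <- (b1c[v] - lookup$b1_grid[i]) /
          diff(lookup$b1_grid[i + 0:1])
        w <- (gcl[v] - lookup$g_grid[j]) / diff(lookup$g_grid[j + 0:1])
        bl <- function(m) {
          (1 - u) * (1 - w) * m[i, j] + u * (1 - w) * m[i + 1, j] +
            (1 - u) * w * m[i, j + 1] + u * w * m[i + 1, j + 1]
        }
        s1[v] <- bl(lookup$s1); s2[v] <- bl(lookup$s2)
      }
      s1[!ins_e] <- 0; s2[!ins_e] <- 0
      s1 <- s1 * spec$m0; s2 <- s2 * spec$m0
      # EPI geometric distortion from the B0 field
      n_pe <- eg$dim[2]
      s1 <- unwarp_epi(s1, b0e_f, out$params$epi_esp_ms, n_pe, 2,
                       "warp")$data
      s2 <- unwarp_epi(s2, b0e_f, out$params$epi_esp_ms, n_pe, 2,
                       "warp")$data
      out$dam_epi <- list(img_alpha = add_rician(s1, sigma),
                          img_2alpha = add_rician(s2, sigma),
                          nominal = 65, geom = eg,
                          n_pe = n_pe, esp_ms = out$params$epi_esp_ms)
    }
  }

  if ("dam_3d" %in% which) {
    a <- 65 * pi / 180
    s1 <- array(0, d); s2 <- array(0, d)
    s1[inside] <- spec$m0 * sin(b1v[inside] * a)
    s2[inside] <- spec$m0 * sin(2 * b1v[inside] * a)
    out$dam_3d <- list(img_alpha = add_rician(s1, sigma),
                       img_2alpha = add_rician(abs(s2), sigma),
                       nominal = 65, geom = truth$geom)
  }

  if ("ir_se" %in% which) {
    tis <- out$params$ir_tis
    vols <- lapply(tis, function(ti) {
      s <- array(0, d)
      s[inside] <- abs(ir_signal(ti, spec$m0, 2 * spec$m0,
                                 t1v[inside]))
      add_rician(s, sigma)
    })
    out$ir_se <- list(volumes = vols, tis = tis, geom = truth$geom)
  }
  out
}
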