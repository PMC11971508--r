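#' Per-ROI samples from pixel-level values
#'
#' Collapses a long pixel-level table into one row per
#' (subject, run, slice, roi): pixel count, mean, SD and the inverse
#' standard-error-squared weight w = n / sd^2 used by the weighted
#' subject summaries.
#'
#' @param pixels data frame with columns `subject`, `run`, `slice`,
#'   `roi`, `t1` (ms) and optionally `b1`.
#' @param weight_cap_quantile ROIs with zero SD (possible on noiseless
#'   synthetic data) get their weight capped at this quantile of the
#'   finite weights, with a warning.
#' @return Data frame with one row per ROI: `subject`, `run`, `slice`,
#'   `roi`, `n_pixels`, `mean_t1`, `sd`, `weight`, `mean_b1`.
#' @export
roi_samples <- function(pixels, weight_cap_quantile = 0.99) {
  req <- c("subject", "run", "slice", "roi", "t1")
  if (!all(req %in% names(pixels))) {
    stop("pixels must have columns ", paste(req, collapse = ", "))
  }
  if (!"b1" %in% names(pixels)) pixels$b1 <- NA_real_
  key <- interaction(pixels$subject, pixels$run, pixels$slice,
                     pixels$roi, drop = TRUE)
  agg <- do.call(rbind, lapply(split(pixels, key), function(g) {
    data.frame(subject = g$subject[1], run = g$run[1],
               slice = g$slice[1], roi = g$roi[1],
               n_pixels = nrow(g), mean_t1 = mean(g$t1),
               sd = stats::sd(g$t1),
               mean_b1 = mean(g$b1))
  }))
  agg$sd[agg$n_pixels == 1] <- NA_real_
  agg$weight <- agg$n_pixels / agg$sd^2
  inf_w <- !is.finite(agg$weight)
  if (any(inf_w)) {
    cap <- stats::quantile(agg$weight[!inf_w], weight_cap_quantile,
                           na.rm = TRUE)
    # all-degenerate (e.g. fully noiseless) input: fall back to equal
    # weights
    if (!is.finite(cap)) cap <- 1
    agg$weight[inf_w] <- cap
    warning(sum(inf_w), " ROI(s) with zero/undefined SD; weight capped")
  }
  rownames(agg) <- NULL
  agg
}

#' Weighted subject mean and SD of T1
#'
#' The subject-level summary: pixel T1s from every ROI on every slice
#' are pooled with per-ROI weights w = n_pixels / sd^2 (inverse squared
#' standard error of the ROI mean):
#' mean = sum_{s,r,p} w_{s,r} T1_{s,r,p} / sum_{s,r} n_{s,r} w_{s,r},
#' and the weighted SD uses the same pixel-level weighting and the same
#' denominator.
#'
#' @param pixels pixel-level data frame (see [roi_samples()]) for one
#'   subject/run.
#' @param samples optionally, the precomputed [roi_samples()] of those
#'   pixels (to reuse capped weights).
#' @return List with `mean` (ms) and `sd` (ms).
#' @export
weighted_subject_summary <- function(pixels, samples = NULL) {
  if (is.null(samples)) samples <- roi_samples(pixels)
  key_p <- interaction(pixels$subject, pixels$run, pixels$slice,
                       pixels$roi, drop = TRUE)
  key_s <- interaction(samples$subject, samples$run, samples$slice,
                       samples$roi, drop = TRUE)
  w <- samples$weight[match(key_p, key_s)]
  if (all(!is.finite(w))) stop("no ROI carries a positive weight")
  denom <- sum(samples$n_pixels * samples$weight)
  m <- sum(w * pixels$t1) / denom
  s <- sqrt(sum(w * (pixels$t1 - m)^2) / denom)
  list(mean = m, sd = s)
}

#' ROI-level T1 homogeneity (weighted dispersion of ROI means)
#'
#' Dispersion of the weighted ROI-mean T1s around the weighted subject
#' mean: sqrt(sum_{s,r} w_{s,r} (mu_{s,r} - mu)^2 / sum_{s,r} w_{s,r}).
#' Note the denominator is sum(w), not sum(n w) as in the pixel-level
#' SD.
#'
#' @inheritParams weighted_subject_summary
#' @return Weighted ROI-level SD (ms).
#' @export
roi_level_homogeneity <- function(pixels, samples = NULL) {
  if (is.null(samples)) samples <- roi_samples(pixels)
  if (nrow(samples) < 2) stop("at least two ROIs required")
  mu <- weighted_subject_summary(pixels, samples)$mean
  sqrt(sum(samples$weight * (samples$mean_t1 - mu)^2) /
         sum(samples$weight))
}

#' Mean relative inaccuracy against a reference method
#'
#' Signed mean of the per-(volunteer, run) relative differences
#' (T1_vfa - T1_ref) / T1_ref. Pairs missing on either side are skipped
#' with a message (the reference methods are not always acquired on
#' every run).
#'
#' @param vfa data frame with `volunteer`, `run`, `t1`.
#' @param reference data frame with `volunteer`, `run`, `t1`.
#' @return List with `delta` (signed fraction), `n_pairs`, `n_skipped`.
#' @export
inaccuracy <- function(vfa, reference) {
  key_v <- paste(vfa$volunteer, vfa$run)
  key_r <- paste(reference$volunteer, reference$run)
  common <- intersect(key_v, key_r)
  skipped <- length(union(key_v, key_r)) - length(common)
  if (skipped > 0) {
    message(skipped, " volunteer/run pair(s) without both methods skipped")
  }
  if (!length(common)) stop("no paired measurements")
  t1v <- vfa$t1[match(common, key_v)]
  t1r <- reference$t1[match(common, key_r)]
  list(delta = mean((t1v - t1r) / t1r), n_pairs = length(common),
       n_skipped = skipped)
}

#' Residual B1+ sensitivity of a T1 map
#'
#' Ordinary least-squares regression of ROI-mean T1 on ROI-mean B1+
#' factor. The B1+-related T1 variation is slope * delta-B1 (the range
#' of B1+ factors across the liver); its 95% CI uses the slope standard
#' error sqrt(s2 / sum((B1_i - mean)^2)) and a t quantile whose degrees
#' of freedom default to n - 2 (see `df`). The no-relationship null is
#' tested via the correlation t-statistic with n - 2 d.o.f.
#'
#' @param roi_means data frame with `mean_t1` and `mean_b1` per ROI
#'   (e.g. from [roi_samples()]).
#' @param b1_range delta-B1 over which to express the T1 variation;
#'   default is the observed range of `mean_b1`.
#' @param alpha significance level.
#' @param df degrees of freedom for the CI t quantile; default n - 2.
#' @return List with `intercept`, `slope` (ms per unit B1+), `slope_se`,
#'   `delta_t1_b1` (ms), `ci95` (on delta_t1_b1), `r`, `p_value`, `n`.
#' @export
b1_sensitivity <- function(roi_means, b1_range = NULL, alpha = 0.05,
                           df = NULL) {
  x <- roi_means$mean_b1
  y <- roi_means$mean_t1
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("at least three ROI points required")
  if (stats::var(x) == 0) stop("zero B1+ variance; slope undefined")
  if (is.null(b1_range)) b1_range <- diff(range(x))
  fit <- stats::lm(y ~ x)
  b <- stats::coef(fit)[[2]]
  s2 <- sum(stats::residuals(fit)^2) / (n - 2)
  se_b <- sqrt(s2 / sum((x - mean(x))^2))
  if (is.null(df)) df <- n - 2
  tq <- stats::qt(1 - alpha / 2, df)
  dt1 <- b * b1_range
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  pval <- 2 * stats::pt(-abs(tstat), n - 2)
  list(intercept = stats::coef(fit)[[1]], slope = b, slope_se = se_b,
       delta_t1_b1 = dt1,
       ci95 = dt1 + c(-1, 1) * tq * b1_range * se_b,
       r = r, p_value = pval, n = n)
}

#' Scan-rescan repeatability of subject-level T1
#'
#' One-way ANOVA with subjects as groups on the two runs' subject means;
#' the within-subject SD is the square root of the residual mean square
#' and the repeatability coefficient is RC = 1.96 sqrt(2) sigma_within.
#' Also returns the paired mean difference with its 95% CI
#' (t, N - 1 d.o.f.), Pearson correlation, regression slope with SE and
#' Bland-Altman bias with 95% limits of agreement (the half-width
#' 1.96 SD of the differences).
#'
#' @param run_a,run_b numeric vectors of subject-level T1 (ms), same
#'   subject order; names (if present) must agree.
#' @param alpha significance level.
#' @return Object of class `repeatability_result`.
#' @export
repeatability <- function(run_a, run_b, alpha = 0.05) {
  if (length(run_a) != length(run_b)) stop("unequal subject sets")
  if (!is.null(names(run_a)) && !is.null(names(run_b)) &&
      !identical(names(run_a), names(run_b))) {
    stop("unequal subject sets")
  }
  n <- length(run_a)
  if (n < 3) stop("at least three subjects required")
  subject <- factor(rep(seq_len(n), 2))
  t1 <- c(run_a, run_b)
  av <- stats::anova(stats::lm(t1 ~ subject))
  sigma_within <- sqrt(av[["Mean Sq"]][2])
  rc <- 1.96 * sqrt(2) * sigma_within
  d <- run_a - run_b
  mean_diff <- mean(d)
  ci <- mean_diff + c(-1, 1) * stats::qt(1 - alpha / 2, n - 1) *
    stats::sd(d) / sqrt(n)
  tt <- stats::t.test(run_a, run_b, paired = TRUE)
  fit <- stats::lm(run_b ~ run_a)
  slope_se <- summary(fit)$coefficients[2, 2]
  structure(list(
    sigma_within = sigma_within, rc = rc,
    mean_diff = mean_diff, mean_diff_ci95 = ci,
    p_value = tt$p.value,
    pearson_r = stats::cor(run_a, run_b),
    regression_slope = stats::coef(fit)[[2]],
    regression_slope_se = slope_se,
    ba_bias = mean_diff,
    ba_loa_halfwidth = 1.96 * stats::sd(d),
    n_subjects = n), class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat("Repeatability over", x$n_subjects, "subjects\n")
  cat(sprintf("  within-subject SD: %.1f ms   RC: %.1f ms\n",
              x$sigma_within, x$rc))
  cat(sprintf("  bias: %+.1f ms  95%% CI [%.1f, %.1f] ms  (p = %.3f)\n",
              x$ba_bias, x$mean_diff_ci95[1], x$mean_diff_ci95[2],
              x$p_value))
  cat(sprintf("  Pearson r: %.3f   slope: %.3f +- %.3f   LoA: %.1f ms\n",
              x$pearson_r, x$regression_slope, x$regression_slope_se,
              x$ba_loa_halfwidth))
  invisible(x)
}

#' Circular ROI pixel extraction from a map volume
#'
#' Extracts pixel values inside circular ROIs (given as center + radius
#' in voxels, per slice) from a T1 map and optionally a matching B1+
#' map, in the long format consumed by the ROI statistics.
#'
#' @param map 3D array (e.g. T1 in ms).
#' @param rois data frame with `slice`, `roi`, `cx`, `cy` (voxel
#'   centers, 1-based) and `radius_px`.
#' @param b1 optional 3D array matching `map`.
#' @param subject,run identifiers attached to the output.
#' @return Pixel-level data frame (`subject`, `run`, `slice`, `roi`,
#'   `t1`, `b1`).
#' @export
extract_roi_pixels <- function(map, rois, b1 = NULL, subject = 1,
                               run = 1) {
  out <- list()
  for (k in seq_len(nrow(rois))) {
    s <- rois$slice[k]
    xs <- seq_len(dim(map)[1]); ys <- seq_len(dim(map)[2])
    dist2 <- outer((xs - rois$cx[k])^2, (ys - rois$cy[k])^2, `+`)
    sel <- which(dist2 <= rois$radius_px[k]^2, arr.ind = TRUE)
    vals <- map[cbind(sel, s)]
    keep <- is.finite(vals)
    out[[k]] <- data.frame(
      subject = subject, run = run, slice = s, roi = rois$roi[k],
      t1 = vals[keep],
      b1 = if (is.null(b1)) NA_real_ else b1[cbind(sel, s)][keep])
  }
  do.call(rbind, out)
}
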