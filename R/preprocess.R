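# Phase-1 spectral processing: referencing to TSP, baseline correction,
# quality control, equal-width binning with water exclusion, total-integral
# normalization, cubic-root transform and autoscaling.

# robust spectral noise estimate from first differences
noise_estimate <- function(spectrum) {
  mad(diff(spectrum$intensities)) / sqrt(2)
}

#' Reference a spectrum to the TSP signal
#'
#' Shifts the ppm axis so the apex of the TSP reference peak sits at
#' exactly 0.0 ppm.  Intensities are unchanged; only the grid origin
#' moves.  If no peak rises sufficiently above the noise inside the
#' search window the spectrum cannot be referenced and a classed error
#' (`nephroNMR_referencing_failure`) is thrown so callers can flag and
#' exclude it.
#'
#' @param spectrum An [nmr_spectrum()].
#' @param window Search window for the TSP apex (ppm).
#' @param snr_min Minimum apex height above the window median, in units
#'   of the spectral noise sd.
#' @return The referenced spectrum.
#' @export
reference_to_tsp <- function(spectrum, window = c(-0.2, 0.2), snr_min = 10) {
  w <- spectrum_window(spectrum, window[1], window[2])
  if (length(w$y) == 0L)
    stop(errorCondition("TSP search window outside spectrum grid",
                        class = c("nephroNMR_referencing_failure", "error")))
  noise <- max(noise_estimate(spectrum), .Machine$double.eps)
  apex_i <- which.max(w$y)
  if ((w$y[apex_i] - median(w$y)) < snr_min * noise)
    stop(errorCondition(
      sprintf("no TSP peak above noise in [%.2f, %.2f] ppm for '%s'",
              window[1], window[2], spectrum$sample_id),
      class = c("nephroNMR_referencing_failure", "error")))
  out <- spectrum
  out$ppm_start <- spectrum$ppm_start - w$ppm[apex_i]
  out
}

#' Baseline correction by asymmetric least squares
#'
#' Estimates a smooth baseline z minimizing
#' \eqn{\sum_i w_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^2 z_i)^2},
#' then subtracts it.  Points rising clearly above the current baseline
#' (more than two noise sd) are treated as signal and down-weighted to
#' `p`; everything else keeps full weight, so the baseline runs through
#' the middle of the noise band instead of hugging its lower envelope.
#' The second-difference penalty leaves constant and linear trends in
#' the null space, so offsets and drifts are removed exactly while
#' narrow peaks are preserved.
#'
#' The smooth baseline is estimated on a thinned grid (every `thin`-th
#' point) and interpolated back, which changes nothing for baselines
#' this stiff but makes the solve several times faster.
#'
#' @param spectrum An [nmr_spectrum()].
#' @param lambda Stiffness of the baseline (larger = smoother), on the
#'   thinned grid.
#' @param p Weight of signal points.
#' @param niter Number of reweighting iterations.
#' @param thin Thinning factor for the estimation grid.
#' @return The corrected spectrum; the estimated baseline is attached as
#'   element `baseline`.
#' @export
correct_baseline <- function(spectrum, lambda = 1e7, p = 0.001, niter = 8,
                             thin = 4L) {
  y_full <- spectrum$intensities
  n_full <- length(y_full)
  idx <- unique(c(seq(1L, n_full, by = thin), n_full))
  y <- y_full[idx]
  n <- length(y)
  noise <- noise_estimate(spectrum)
  D <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                          diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                           rep(1, n - 2L)))
  P <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(niter)) {
    C <- Matrix::Diagonal(n, w) + P
    z <- as.numeric(Matrix::solve(C, w * y))
    w_new <- ifelse(y - z > 2 * noise, p, 1)
    if (all(w_new == w)) break
    w <- w_new
  }
  z_full <- approx(idx, z, xout = seq_len(n_full))$y
  out <- spectrum
  out$intensities <- y_full - z_full
  out$baseline <- z_full
  out
}

#' Default quality-control thresholds
#'
#' The "selected spectral regions" inspected by the QC filter are project
#' choices: two signal-free stretches at the spectrum edges for baseline
#' offset/slope, and the TSP reference signal for position, width and
#' shape.  All thresholds are configurable.
#'
#' @param baseline_regions List of ppm intervals expected to be signal-free.
#' @param offset_max Max |mean intensity| per region (intensity units).
#' @param slope_max Max |fitted slope| per region (intensity / ppm).
#' @param tsp_window Window containing the TSP signal (ppm).
#' @param tsp_pos_max Max |TSP apex position| after referencing (ppm).
#' @param tsp_fwhm_max Max TSP full width at half maximum (ppm).
#' @param tsp_asym_max Max TSP area-asymmetry |L-R|/(L+R).
#' @return List of thresholds for [qc_filter()].
#' @export
qc_thresholds <- function(baseline_regions = list(c(9.70, 9.95), c(-0.45, -0.25)),
                          offset_max = 0.5, slope_max = 10,
                          tsp_window = c(-0.05, 0.05),
                          tsp_pos_max = 0.01, tsp_fwhm_max = 0.008,
                          tsp_asym_max = 0.3) {
  list(baseline_regions = baseline_regions, offset_max = offset_max,
       slope_max = slope_max, tsp_window = tsp_window,
       tsp_pos_max = tsp_pos_max, tsp_fwhm_max = tsp_fwhm_max,
       tsp_asym_max = tsp_asym_max)
}

# FWHM of the highest peak in (ppm, y) by half-maximum crossing, linear interp
measure_fwhm <- function(ppm, y) {
  base <- min(y)
  apex <- which.max(y)
  hm <- base + (y[apex] - base) / 2
  left <- apex
  while (left > 1L && y[left] > hm) left <- left - 1L
  right <- apex
  while (right < length(y) && y[right] > hm) right <- right + 1L
  if (left == apex || right == apex) return(NA_real_)
  xl <- approx(y[c(left, left + 1L)], ppm[c(left, left + 1L)], xout = hm)$y
  xr <- approx(y[c(right - 1L, right)], ppm[c(right - 1L, right)], xout = hm)$y
  xr - xl
}

#' Spectrum quality-control filter
#'
#' Deterministic pass/fail with itemized reasons, mirroring instrument QC:
#' baseline offset and slope in configured signal-free regions, and
#' position, width and shape (area asymmetry) of the TSP reference.
#'
#' @param spectrum A referenced (and usually baseline-corrected)
#'   [nmr_spectrum()].
#' @param thresholds See [qc_thresholds()].
#' @return Object of class `qc_report`: list with `passed`, `reasons`
#'   (character codes of failed checks) and the measured `metrics`.
#' @export
qc_filter <- function(spectrum, thresholds = qc_thresholds()) {
  reasons <- character()
  metrics <- list()
  for (reg in thresholds$baseline_regions) {
    w <- spectrum_window(spectrum, reg[1], reg[2])
    tag <- sprintf("%.2f_%.2f", reg[1], reg[2])
    if (length(w$y) < 5L) next
    off <- mean(w$y)
    slope <- unname(coef(lm(w$y ~ w$ppm))[2])
    metrics[[paste0("baseline_offset_", tag)]] <- off
    metrics[[paste0("baseline_slope_", tag)]] <- slope
    if (abs(off) > thresholds$offset_max)
      reasons <- c(reasons, paste0("baseline_offset:", tag))
    if (abs(slope) > thresholds$slope_max)
      reasons <- c(reasons, paste0("baseline_slope:", tag))
  }
  w <- spectrum_window(spectrum, thresholds$tsp_window[1], thresholds$tsp_window[2])
  if (length(w$y) < 5L) {
    reasons <- c(reasons, "tsp_missing")
  } else {
    apex <- which.max(w$y)
    pos <- w$ppm[apex]
    fwhm <- measure_fwhm(w$ppm, w$y)
    yl <- w$y[w$ppm < pos] - min(w$y)
    yr <- w$y[w$ppm > pos] - min(w$y)
    asym <- abs(sum(yl) - sum(yr)) / max(sum(yl) + sum(yr), .Machine$double.eps)
    metrics$tsp_position <- pos
    metrics$tsp_fwhm <- fwhm
    metrics$tsp_asymmetry <- asym
    if (abs(pos) > thresholds$tsp_pos_max)
      reasons <- c(reasons, "tsp_position")
    if (is.na(fwhm) || fwhm > thresholds$tsp_fwhm_max)
      reasons <- c(reasons, "tsp_width")
    if (asym > thresholds$tsp_asym_max)
      reasons <- c(reasons, "tsp_shape")
  }
  structure(list(passed = length(reasons) == 0L, reasons = reasons,
                 metrics = metrics, sample_id = spectrum$sample_id),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report '%s'> %s", x$sample_id,
              if (x$passed) "PASSED\n"
              else paste0("FAILED: ", paste(x$reasons, collapse = ", "), "\n")))
  invisible(x)
}

#' Equal-width binning configuration
#'
#' Default analysis region 0.716--9.516 ppm with 0.022-ppm bins: the
#' residual-water region 4.5--5.0 ppm then falls exactly on bin edges,
#' and dropping the 23 bins overlapping it leaves 377 retained bins.
#' The count is a consequence of the configuration, not hard-coded; a
#' conformance test asserts it.
#'
#' @param range Analysis interval `c(lo, hi)` (ppm).
#' @param width Bin width (ppm).
#' @param exclude List of ppm intervals whose overlapping bins are dropped.
#' @return List of class `bin_config`: `edges` (all raw bin edges),
#'   `keep` (logical, retained bins), `lo`/`hi` (retained bin bounds),
#'   `exclude`.
#' @export
bin_config <- function(range = c(0.716, 9.516), width = 0.022,
                       exclude = list(c(4.5, 5.0))) {
  stopifnot(width > 0, diff(range) > 0)
  n_raw <- round(diff(range) / width)
  edges <- range[1] + width * (0:n_raw)
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  keep <- rep(TRUE, n_raw)
  eps <- 1e-9
  for (ex in exclude)
    keep <- keep & !(lo < ex[2] - eps & hi > ex[1] + eps)
  structure(list(edges = edges, keep = keep, lo = lo[keep], hi = hi[keep],
                 exclude = exclude, width = width, range = range),
            class = "bin_config")
}

#' Bin one spectrum
#'
#' Each bin value is the integral (trapezoidal) of intensity over the bin
#' interval; bins overlapping excluded regions were dropped by the
#' configuration.
#'
#' @param spectrum An [nmr_spectrum()] covering the analysis range.
#' @param config A [bin_config()].
#' @return Named numeric vector of bin integrals (names `bin_<center ppm>`).
#' @export
bin_spectrum <- function(spectrum, config = bin_config()) {
  ppm <- ppm_grid(spectrum)
  if (config$range[1] < ppm[1] - 1e-9 ||
      config$range[2] > ppm[length(ppm)] + 1e-9)
    stop("input error: analysis range outside spectrum grid")
  y <- spectrum$intensities
  # cumulative trapezoid integral, then difference at bin edges
  cum <- c(0, cumsum((y[-1] + y[-length(y)]) / 2 * diff(ppm)))
  at <- approx(ppm, cum, xout = config$edges)$y
  vals <- diff(at)[config$keep]
  names(vals) <- sprintf("bin_%.4f", (config$lo + config$hi) / 2)
  vals
}

#' Bin a list of spectra into a feature table
#'
#' @param spectra List of [nmr_spectrum()] objects.
#' @param config A [bin_config()].
#' @return A samples x bins matrix with attributes `bin_lo`, `bin_hi`,
#'   `excluded_regions` and `stage = "raw"`.
#' @export
bin_spectra <- function(spectra, config = bin_config()) {
  m <- t(vapply(spectra, bin_spectrum, numeric(sum(config$keep)),
                config = config))
  rownames(m) <- vapply(spectra, function(s) s$sample_id, character(1))
  attr(m, "bin_lo") <- config$lo
  attr(m, "bin_hi") <- config$hi
  attr(m, "excluded_regions") <- config$exclude
  attr(m, "stage") <- "raw"
  m
}

#' Total-integral normalization
#'
#' Divides each sample's bins by their sum so every row sums to 1,
#' compensating for urine-concentration differences.  Rows with zero
#' total integral cannot be normalized; they are set to `NA` and listed
#' in the `invalid_samples` attribute.
#'
#' @param bins Matrix (samples x bins) or a single bin vector.
#' @return Normalized bins, `stage = "normalized"`.
#' @export
normalize_total_integral <- function(bins) {
  vec <- is.null(dim(bins))
  m <- if (vec) matrix(bins, nrow = 1, dimnames = list(NULL, names(bins))) else bins
  tot <- rowSums(m)
  bad <- !is.finite(tot) | tot == 0
  out <- m / tot
  out[bad, ] <- NA_real_
  for (a in c("bin_lo", "bin_hi", "excluded_regions"))
    attr(out, a) <- attr(bins, a)
  attr(out, "stage") <- "normalized"
  attr(out, "invalid_samples") <- rownames(m)[bad]
  if (vec) {
    nm <- colnames(out)
    out <- out[1, ]
    names(out) <- nm
  }
  out
}

#' Cubic-root transform and autoscaling
#'
#' Applies the signed real cube root elementwise (bins can be slightly
#' negative after baseline correction), then centers and scales each bin.
#' Scaling statistics are estimated on training data and must be frozen
#' and re-applied to test data via `training_stats`; zero-variance bins
#' get unit scale and are flagged rather than producing a division by
#' zero.
#'
#' @param bins Normalized bin matrix.
#' @param training_stats Optional stats from a previous (training) call;
#'   when supplied they are applied unchanged.
#' @return Autoscaled matrix, `stage = "autoscaled"`, with attribute
#'   `training_stats` = list(center, scale, zero_variance).
#' @export
transform_bins <- function(bins, training_stats = NULL) {
  m <- sign(bins) * abs(bins)^(1 / 3)
  if (is.null(training_stats)) {
    ctr <- colMeans(m, na.rm = TRUE)
    scl <- apply(m, 2, sd, na.rm = TRUE)
    zv <- !is.finite(scl) | scl == 0
    scl[zv] <- 1
    training_stats <- list(center = ctr, scale = scl, zero_variance = zv)
  }
  out <- sweep(sweep(m, 2, training_stats$center), 2, training_stats$scale, "/")
  for (a in c("bin_lo", "bin_hi", "excluded_regions", "invalid_samples"))
    attr(out, a) <- attr(bins, a)
  attr(out, "stage") <- "autoscaled"
  attr(out, "training_stats") <- training_stats
  out
}
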