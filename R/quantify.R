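# Phase-2 quantification: bounded least-squares pseudo-Voigt fits of the
# 11-signal panel with goodness-of-fit gating, then creatinine
# normalization, log transform, centering and scaling.

# residuals of a joint multiplet model: one (center, area) per signal,
# shared fwhm/eta, local linear background
multiplet_model <- function(p, ppm, tpl_rows, mid) {
  k <- nrow(tpl_rows)
  y <- p[[2 * k + 3]] + p[[2 * k + 4]] * (ppm - mid)
  for (j in seq_len(k))
    y <- y + multiplet(ppm, p[[2 * j - 1]], tpl_rows$offsets[[j]],
                       tpl_rows$weights[[j]], p[[2 * j]],
                       p[[2 * k + 1]], p[[2 * k + 2]])
  y
}

# one bounded Levenberg-Marquardt fit from a given start
run_lm_fit <- function(start, lower, upper, ppm, y, tpl_rows, mid) {
  minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper,
    fn = function(p) y - multiplet_model(p, ppm, tpl_rows, mid),
    control = minpack.lm::nls.lm.control(maxiter = 200))
}

# joint fit of all signals sharing one window; returns one row per signal
fit_window <- function(spectrum, tpl_rows, gof_threshold = 0.05,
                       fwhm_bounds = c(5e-4, 0.02), center_slack = 0.01) {
  ppm_all <- ppm_grid(spectrum)
  lo <- min(tpl_rows$fit_lo); hi <- max(tpl_rows$fit_hi)
  if (lo < ppm_all[1] || hi > ppm_all[length(ppm_all)])
    stop("input error: fit window [", lo, ", ", hi, "] outside spectrum")
  w <- spectrum_window(spectrum, lo, hi)
  mid <- (lo + hi) / 2
  k <- nrow(tpl_rows)
  amp <- diff(range(w$y))
  area0 <- max(sum(pmax(w$y - min(w$y), 0)) * spectrum$ppm_step / k, 1e-8)

  lower <- c(rbind(tpl_rows$center - center_slack, 0),
             fwhm_bounds[1], 0, -Inf, -Inf)
  upper <- c(rbind(tpl_rows$center + center_slack, Inf),
             fwhm_bounds[2], 1, Inf, Inf)
  best <- NULL
  for (shift in c(-center_slack / 2, 0, center_slack / 2)) {
    start <- c(rbind(tpl_rows$center + shift, area0),
               0.003, 0.5, median(w$y), 0)
    start <- pmin(pmax(start, lower), upper)
    fit <- tryCatch(run_lm_fit(start, lower, upper, w$ppm, w$y, tpl_rows, mid),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  fail_row <- function() data.frame(
    metabolite = tpl_rows$metabolite, center = NA_real_, area = NA_real_,
    fwhm = NA_real_, eta = NA_real_, gof = NA_real_, valid = FALSE)
  if (is.null(best)) return(fail_row())

  p <- best$par
  converged <- best$info %in% 1:4
  gof <- sqrt(mean(best$fvec^2)) / max(amp, .Machine$double.eps)
  at_bound <- function(v, b) abs(v - b) < 1e-8 * (1 + abs(b))
  out <- lapply(seq_len(k), function(j) {
    ctr <- p[[2 * j - 1]]; area <- p[[2 * j]]
    fwhm <- p[[2 * k + 1]]; eta <- p[[2 * k + 2]]
    bad_bound <- at_bound(area, 0) ||
      at_bound(ctr, tpl_rows$center[j] - center_slack) ||
      at_bound(ctr, tpl_rows$center[j] + center_slack) ||
      at_bound(fwhm, fwhm_bounds[1]) || at_bound(fwhm, fwhm_bounds[2])
    data.frame(metabolite = tpl_rows$metabolite[j], center = ctr, area = area,
               fwhm = fwhm, eta = eta, gof = gof,
               valid = converged && gof <= gof_threshold && !bad_bound)
  })
  do.call(rbind, out)
}

#' Fit one metabolite signal
#'
#' Bounded Levenberg-Marquardt least squares of the template's multiplet
#' (pseudo-Voigt components with fixed splitting, shared width and mixing
#' fraction) plus a local linear background, inside the template's fit
#' window.  The fit is restarted from a grid of three starting centers
#' and the best solution kept, making the result deterministic.
#'
#' Goodness of fit is the root-mean-square residual normalized by the
#' in-window signal amplitude; `valid` is `FALSE` on non-convergence,
#' `gof` above threshold, or area/center/width pinned at a bound.
#'
#' @param spectrum A QC-passed [nmr_spectrum()].
#' @param template One row of [signal_templates()] (data.frame).
#' @param gof_threshold Normalized RMS residual above which the
#'   quantification is declared unreliable (default 0.05).
#' @param ... Passed to the internal fitter (`fwhm_bounds`, `center_slack`).
#' @return One-row data.frame: `metabolite, center, area, fwhm, eta, gof,
#'   valid`.
#' @export
fit_signal <- function(spectrum, template, gof_threshold = 0.05, ...) {
  stopifnot(nrow(template) == 1L)
  fit_window(spectrum, template, gof_threshold = gof_threshold, ...)
}

#' Quantify the full metabolite panel of one spectrum
#'
#' Fits every panel signal (ten candidate metabolites plus creatinine).
#' Signals sharing a template `group` -- glucose and glucuronate, whose
#' signals are immediate neighbours -- are fitted jointly in one window
#' to avoid interference between them.
#'
#' @param spectrum A QC-passed [nmr_spectrum()].
#' @param templates [signal_templates()] table.
#' @param gof_threshold Passed to the fitter.
#' @return data.frame, one row per panel metabolite: `sample_id,
#'   metabolite, center, area, fwhm, eta, gof, valid`.
#' @export
quantify_panel <- function(spectrum, templates = signal_templates(),
                           gof_threshold = 0.05) {
  panel <- templates[templates$role == "panel", ]
  key <- ifelse(is.na(panel$group) | panel$group == "",
                paste0("single_", panel$metabolite), panel$group)
  out <- lapply(split(panel, key), fit_window, spectrum = spectrum,
                gof_threshold = gof_threshold)
  out <- do.call(rbind, out)
  out <- out[match(panel$metabolite, out$metabolite), ]
  rownames(out) <- NULL
  cbind(sample_id = spectrum$sample_id, out)
}

#' Quantify a list of spectra
#'
#' @param spectra List of QC-passed [nmr_spectrum()] objects.
#' @param ... Passed to [quantify_panel()].
#' @return Long data.frame stacking the per-spectrum panel tables.
#' @export
quantify_spectra <- function(spectra, ...) {
  do.call(rbind, lapply(spectra, quantify_panel, ...))
}

#' Creatinine-normalized, log-transformed, standardized features
#'
#' Computes \eqn{I_x = standardized(\log(area_x / area_{creatinine}))} per
#' sample and metabolite.  A sample whose creatinine quantification is
#' invalid (or non-positive) is unusable: normalization is impossible and
#' all its features are `NA`.  Invalid metabolite quantifications
#' propagate as `NA` features.  Standardization statistics are estimated
#' on training data and must be frozen and re-applied to test data.
#'
#' @param quants Long table from [quantify_spectra()] (or any data.frame
#'   with `sample_id, metabolite, area, valid`).
#' @param training_stats Optional stats from a previous training call.
#' @return List: `features` (samples x metabolites matrix of I_x),
#'   `training_stats` (center/scale/zero_variance), `unusable`
#'   (sample ids without valid creatinine).
#' @export
process_features <- function(quants, training_stats = NULL) {
  bad <- quants$valid & !is.na(quants$area) & quants$area <= 0
  if (any(bad))
    stop("internal error: valid quantification with non-positive area")
  ids <- unique(quants$sample_id)
  mets <- setdiff(unique(quants$metabolite), "Creatinine")
  area <- matrix(NA_real_, length(ids), length(mets) + 1L,
                 dimnames = list(ids, c(mets, "Creatinine")))
  ok <- quants$valid
  area[cbind(match(quants$sample_id[ok], ids),
             match(quants$metabolite[ok], colnames(area)))] <- quants$area[ok]
  crea <- area[, "Creatinine"]
  unusable <- ids[is.na(crea) | crea <= 0]
  logratio <- log(area[, mets, drop = FALSE] / crea)
  logratio[ids %in% unusable, ] <- NA_real_
  if (is.null(training_stats)) {
    ctr <- colMeans(logratio, na.rm = TRUE)
    scl <- apply(logratio, 2, sd, na.rm = TRUE)
    zv <- !is.finite(scl) | scl == 0
    scl[zv] <- 1
    training_stats <- list(center = ctr, scale = scl, zero_variance = zv)
  }
  feats <- sweep(sweep(logratio, 2, training_stats$center), 2,
                 training_stats$scale, "/")
  list(features = feats, training_stats = training_stats, unusable = unusable)
}
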