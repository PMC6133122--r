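# Phase-1 feature selection: iterative random-forest permutation
# importance over bin features, with programmatic bin-quality flags
# standing in for manual visual assessment of candidate bins.

#' Iterative random-forest feature selection
#'
#' Repeats of k-fold random-forest fits (permutation importance) produce
#' per-bin importance ranks, aggregated by median rank across all fits.
#' Bins failing quality flags are eliminated upfront with reason codes;
#' bins outside the top `top_n` by aggregated rank are eliminated as
#' low-importance.  The procedure re-ranks the surviving set until it is
#' stable or `max_iter` is reached.  Fully deterministic given `seed`.
#'
#' @param features Autoscaled samples x bins matrix.
#' @param labels Binary labels (two classes required).
#' @param repeats Number of fold-assignment repeats (default 20).
#' @param folds Folds per repeat (default 5).
#' @param top_n Aggregated-rank threshold below which bins are retained.
#' @param max_iter Maximum re-ranking iterations.
#' @param num_trees Trees per forest.
#' @param quality_flags Optional result of [assess_bin_quality()];
#'   flagged bins are eliminated before ranking.
#' @param seed Integer seed.
#' @return Object of class `selection_result`: `ranked` (data.frame of
#'   bin, median_rank, mean_importance), `selected`, `eliminated`
#'   (data.frame bin/reason), `iterations`, `seed`.
#' @export
rf_feature_selection <- function(features, labels, repeats = 20, folds = 5,
                                 top_n = 20, max_iter = 3, num_trees = 300,
                                 quality_flags = NULL, seed = 1L) {
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("input error: labels contain a single class")
  stopifnot(nrow(features) == length(labels))
  bins <- colnames(features)
  eliminated <- data.frame(bin = character(), reason = character())
  if (!is.null(quality_flags)) {
    flagged <- quality_flags$bin[quality_flags$flagged]
    flagged <- intersect(flagged, bins)
    if (length(flagged)) {
      why <- vapply(flagged, function(b) {
        r <- quality_flags[quality_flags$bin == b, ]
        paste(c("low_signal", "baseline_dominated",
                "peak_straddling")[c(r$low_signal, r$baseline_dominated,
                                     r$peak_straddling)], collapse = "+")
      }, character(1))
      eliminated <- rbind(eliminated, data.frame(bin = flagged, reason = why))
      bins <- setdiff(bins, flagged)
    }
  }
  current <- bins
  ranked <- NULL
  iterations <- 0L
  with_seed(seed, {
    for (it in seq_len(max_iter)) {
      iterations <- it
      n <- nrow(features)
      rank_mat <- NULL
      imp_mat <- NULL
      fit_id <- 0L
      for (r in seq_len(repeats)) {
        fold <- sample(rep_len(seq_len(folds), n))
        for (k in seq_len(folds)) {
          idx <- fold != k
          if (nlevels(droplevels(y[idx])) < 2L) next
          fit_id <- fit_id + 1L
          rf <- ranger::ranger(
            x = features[idx, current, drop = FALSE], y = y[idx],
            num.trees = num_trees, importance = "permutation",
            num.threads = 1L, seed = seed + 1000L * it + fit_id)
          imp <- rf$variable.importance[current]
          rank_mat <- cbind(rank_mat, rank(-imp, ties.method = "average"))
          imp_mat <- cbind(imp_mat, imp)
        }
      }
      med_rank <- apply(rank_mat, 1, median)
      ranked <- data.frame(bin = current, median_rank = med_rank,
                            mean_importance = rowMeans(imp_mat))
      ranked <- ranked[order(ranked$median_rank, -ranked$mean_importance), ]
      keep <- ranked$bin[ranked$median_rank <= top_n]
      if (setequal(keep, current)) break
      dropped <- setdiff(current, keep)
      eliminated <- rbind(eliminated,
                           data.frame(bin = dropped, reason = "low_importance"))
      current <- keep
      if (length(current) == 0L) break   # nothing clears the rank threshold
    }
  })
  rownames(ranked) <- NULL
  structure(list(ranked = ranked, selected = current, eliminated = eliminated,
                 iterations = iterations, seed = seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d selected / %d eliminated after %d iteration(s)\n",
              length(x$selected), nrow(x$eliminated), x$iterations))
  invisible(x)
}

#' Programmatic bin-quality assessment
#'
#' Quantitative stand-in for visual inspection of candidate bins.  For
#' every retained bin, across the supplied (baseline-corrected) spectra:
#' \describe{
#'   \item{low_signal}{the median (across spectra) in-bin peak height --
#'     maximum intensity above the bin's median level -- stays below
#'     `snr_min` times the spectral noise: the bin covers noise floor;}
#'   \item{baseline_dominated}{the estimated baseline (element
#'     `baseline` of spectra processed by [correct_baseline()]) carries
#'     more than `baseline_frac_max` of the bin's total integral;}
#'   \item{peak_straddling}{a real peak apex sits in the bin but the
#'     intensity at a bin edge still exceeds half the apex height - the
#'     peak is cut by the bin boundary.}
#' }
#'
#' @param spectra List of baseline-corrected [nmr_spectrum()] objects.
#' @param config The [bin_config()] used for binning.
#' @param snr_min Peak-height threshold in noise-sd units.
#' @param baseline_frac_max Maximum tolerated baseline fraction.
#' @return data.frame: `bin`, the three logical flags, `flagged` (any),
#'   and the underlying metric values.
#' @export
assess_bin_quality <- function(spectra, config = bin_config(), snr_min = 5,
                               baseline_frac_max = 0.5) {
  noise <- median(vapply(spectra, noise_estimate, numeric(1)))
  nb <- length(config$lo)
  ns <- length(spectra)
  height <- matrix(NA_real_, ns, nb)
  edge_ratio <- matrix(NA_real_, ns, nb)
  base_frac <- matrix(NA_real_, ns, nb)
  for (s in seq_len(ns)) {
    sp <- spectra[[s]]
    ppm <- ppm_grid(sp)
    for (b in seq_len(nb)) {
      sel <- ppm >= config$lo[b] & ppm <= config$hi[b]
      y <- sp$intensities[sel]
      if (length(y) < 3L) next
      height[s, b] <- max(y) - median(y)
      floor_ <- min(y)
      edge_ratio[s, b] <- (max(y[1], y[length(y)]) - floor_) /
        max(max(y) - floor_, .Machine$double.eps)
      if (!is.null(sp$baseline)) {
        bint <- sum(abs(sp$baseline[sel]))
        base_frac[s, b] <- bint / max(bint + sum(abs(y)), .Machine$double.eps)
      }
    }
  }
  med_h <- apply(height, 2, median, na.rm = TRUE)
  med_e <- apply(edge_ratio, 2, median, na.rm = TRUE)
  med_b <- apply(base_frac, 2, function(v)
    if (all(is.na(v))) 0 else median(v, na.rm = TRUE))
  low_signal <- med_h < snr_min * noise
  straddle <- !low_signal & med_e > 0.5
  base_dom <- med_b > baseline_frac_max
  data.frame(bin = sprintf("bin_%.4f", (config$lo + config$hi) / 2),
             low_signal = low_signal, baseline_dominated = base_dom,
             peak_straddling = straddle,
             flagged = low_signal | base_dom | straddle,
             median_height = med_h, median_edge_ratio = med_e,
             median_baseline_fraction = med_b)
}
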