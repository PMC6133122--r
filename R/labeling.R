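# Case/control definitions: BANFF mapping, the 7-day biopsy window,
# the late-phase filter, and the strict/extended test settings.
#
# BANFF categories: 1 no rejection, 2 antibody-mediated, 3 borderline,
# 4 acute cellular rejection (the case definition), 5 chronic.  A biopsy
# may report several categories (comma-separated); one reporting BANFF 4
# in conjunction with others is still a case.

banff_categories <- function(banff) {
  cats <- suppressWarnings(as.integer(strsplit(as.character(banff), ",")[[1]]))
  if (length(cats) == 0L || anyNA(cats) || !all(cats %in% 1:5))
    stop("input error: invalid BANFF category '", banff, "'")
  cats
}

# label implied by one biopsy result
biopsy_label <- function(banff) {
  cats <- banff_categories(banff)
  if (4L %in% cats) "case"
  else if (all(cats == 1L)) "control"
  else "excluded"
}

# index (into biopsies) of the biopsy attached to a sample, or NA.
# Eligible: biopsy 0..7 days after the sample (sample up to 7 days before
# the biopsy, day of biopsy included).  Nearest biopsy wins; tie -> later.
link_biopsy <- function(sample_date, biopsy_dates) {
  d <- as.numeric(biopsy_dates - sample_date)
  ok <- which(d >= 0 & d <= 7)
  if (length(ok) == 0L) return(NA_integer_)
  best <- ok[d[ok] == min(d[ok])]
  best[length(best)]
}

label_one <- function(sample_date, tx_date, patient_biopsies, mode, setting) {
  day <- as.numeric(sample_date - tx_date)
  if (day < 0) stop("input error: sample taken before transplant date")
  link <- link_biopsy(sample_date, patient_biopsies$biopsy_date)
  if (!is.na(link)) {
    label <- biopsy_label(patient_biopsies$banff[link])
    basis <- "biopsy"
  } else if (mode == "training") {
    all_negative <- nrow(patient_biopsies) == 0L ||
      all(vapply(patient_biopsies$banff,
                 function(b) identical(biopsy_label(b), "control"), logical(1)))
    label <- if (all_negative) "control" else "excluded"
    basis <- "no_biopsy_control"
  } else if (setting == "extended") {
    label <- "control"
    basis <- "no_biopsy_control"
  } else {
    label <- "excluded"
    basis <- "no_biopsy_control"
  }
  list(label = label, basis = basis, days_post_tx = day)
}

label_samples <- function(samples, biopsies, mode, setting = NA_character_) {
  need <- c("sample_id", "patient_id", "tx_date", "sample_date")
  if (!all(need %in% names(samples)))
    stop("samples table must have columns: ", paste(need, collapse = ", "))
  by_patient <- split(biopsies, biopsies$patient_id)
  empty <- biopsies[0, ]
  res <- lapply(seq_len(nrow(samples)), function(i) {
    pb <- by_patient[[samples$patient_id[i]]]
    if (is.null(pb)) pb <- empty
    label_one(samples$sample_date[i], samples$tx_date[i], pb, mode, setting)
  })
  out <- data.frame(
    sample_id = samples$sample_id,
    patient_id = samples$patient_id,
    sample_date = samples$sample_date,
    days_post_tx = vapply(res, `[[`, numeric(1), "days_post_tx"),
    label = vapply(res, `[[`, character(1), "label"),
    basis = vapply(res, `[[`, character(1), "basis"))
  out$phase <- ifelse(out$days_post_tx >= 15, "late", "early")
  out
}

#' Label samples under the training-cohort definition
#'
#' A sample taken within 7 days before a biopsy (day of biopsy included)
#' inherits that biopsy's outcome: case for acute cellular rejection
#' (BANFF 4, alone or in conjunction with other categories), control for
#' a negative biopsy (BANFF 1), excluded for isolated antibody-mediated
#' rejection, borderline changes or chronic rejection (BANFF 2/3/5).
#' When several biopsies are eligible the nearest wins (tie: the later
#' one).  Samples without an attached biopsy are controls when the
#' patient was never biopsied or all their biopsies were negative, and
#' excluded otherwise.
#'
#' @param samples data.frame with `sample_id, patient_id, tx_date,
#'   sample_date` (Date columns).
#' @param biopsies data.frame with `patient_id, biopsy_date, banff`
#'   (BANFF categories, comma-separated when a biopsy reports several).
#' @return data.frame: `sample_id, patient_id, sample_date, days_post_tx,
#'   label` (case/control/excluded), `basis` (biopsy /
#'   no_biopsy_control), `phase` (early/late; late = day >= 15 after
#'   transplant, with transplant day counted as day 0).
#' @export
label_training <- function(samples, biopsies) {
  label_samples(samples, biopsies, mode = "training")
}

#' Label samples under the test-cohort definitions
#'
#' In the `strict` setting only biopsy-linked samples receive a label
#' (case/control per the biopsy; everything else excluded).  The
#' `extended` setting additionally counts samples not supported by any
#' biopsy as controls.
#'
#' @inheritParams label_training
#' @param setting `"strict"` or `"extended"`.
#' @return Same layout as [label_training()].
#' @export
label_test <- function(samples, biopsies, setting = c("strict", "extended")) {
  setting <- match.arg(setting)
  label_samples(samples, biopsies, mode = "test", setting = setting)
}

#' Late-phase filter
#'
#' Keeps samples taken on day >= 15 after transplantation (transplant day
#' = day 0); earlier samples are prone to hematuria interference.
#'
#' @param labeled A labeled-sample table from [label_training()] /
#'   [label_test()].
#' @return The late-phase subset.
#' @export
phase_filter <- function(labeled) {
  labeled[labeled$days_post_tx >= 15, , drop = FALSE]
}

#' Label a synthetic cohort
#'
#' Convenience wrapper applying the training or test definition to a
#' [generate_cohort()] result.
#'
#' @param cohort An `nmr_cohort`.
#' @param mode `"training"`, `"strict"` or `"extended"`.
#' @param late_only Apply the late-phase filter (default TRUE).
#' @return Labeled-sample table.
#' @export
label_cohort <- function(cohort, mode = c("training", "strict", "extended"),
                         late_only = TRUE) {
  mode <- match.arg(mode)
  lab <- if (mode == "training") label_training(cohort$samples, cohort$biopsies)
         else label_test(cohort$samples, cohort$biopsies, setting = mode)
  if (late_only) phase_filter(lab) else lab
}
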