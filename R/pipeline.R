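# End-to-end orchestration on synthetic data: simulate -> preprocess ->
# quantify -> label -> search -> filter -> score.

#' Construct a rejection-score model from fitted coefficients
#'
#' Packages an intercept and named coefficients (plus the feature
#' standardization of the training run) in the same object layout as the
#' shipped published model, so [compute_score()] / [score_cohort()]
#' accept either.
#'
#' @param intercept Numeric intercept.
#' @param coefficients Named numeric feature weights.
#' @param standardization Optional list(center, scale) used to build I_x.
#' @param version Version tag.
#' @return A `final_model` object.
#' @export
new_final_model <- function(intercept, coefficients, standardization = NULL,
                            version = "fitted") {
  m <- list(intercept = unname(intercept),
            coefficients = coefficients,
            feature_order = names(coefficients),
            standardization = standardization,
            version = version)
  class(m) <- "final_model"
  m
}

preprocess_spectra <- function(spectra, config_bins, thresholds) {
  out <- list(spectra = list(), qc = list(), referencing_failed = character())
  for (sp in spectra) {
    spr <- tryCatch(reference_to_tsp(sp), nephroNMR_referencing_failure =
                      function(e) NULL)
    if (is.null(spr)) {
      out$referencing_failed <- c(out$referencing_failed, sp$sample_id)
      next
    }
    spb <- correct_baseline(spr)
    rep <- qc_filter(spb, thresholds)
    out$qc[[spb$sample_id]] <- rep
    if (rep$passed) out$spectra[[spb$sample_id]] <- spb
  }
  out
}

#' Run the full two-phase pipeline on synthetic cohorts
#'
#' Simulates a training and a test cohort, generates and preprocesses
#' their spectra (referencing, baseline correction, QC), quantifies the
#' metabolite panel, builds creatinine-normalized standardized features
#' (training statistics frozen and applied to the test cohort), labels
#' samples (training definition for the training cohort; strict and
#' extended settings for the test cohort; late phase only), runs the
#' exhaustive model search with patient-grouped cross-validation,
#' applies the filtering cascade, refits the best surviving candidate
#' and scores the test cohort with it.
#'
#' @param config [generator_config()] for the training cohort.
#' @param test_config Config for the test cohort; defaults to the same
#'   conditions with `seed + 1`.
#' @param max_size Maximum model size (default 5).
#' @param folds,repeats Cross-validation scheme for the search.
#' @param rules Filtering rule list (default [default_filter_rules()]).
#' @param thresholds QC thresholds.
#' @return List: `cohorts`, `qc`, `features` (train/test matrices),
#'   `labels` (train/strict/extended tables), `candidates`, `filtered`
#'   (per-setting survivors + `final_ids`), `chosen_id`, `model`
#'   (refitted `final_model`), `test_scores` (strict-setting
#'   [score_cohort()] result).
#' @export
run_synthetic_pipeline <- function(config,
                                   test_config = NULL,
                                   max_size = 5, folds = 3, repeats = 1,
                                   rules = default_filter_rules(),
                                   thresholds = qc_thresholds()) {
  if (is.null(test_config)) {
    test_config <- config
    test_config$seed <- config$seed + 1L
  }
  cohorts <- list(train = generate_cohort(config),
                  test = generate_cohort(test_config))
  prep <- lapply(names(cohorts), function(nm) {
    cfg <- if (nm == "train") config else test_config
    spectra <- generate_cohort_spectra(cohorts[[nm]], cfg)
    preprocess_spectra(spectra, bin_config(), thresholds)
  })
  names(prep) <- names(cohorts)

  quant_train <- quantify_spectra(prep$train$spectra)
  quant_test <- quantify_spectra(prep$test$spectra)
  pf_train <- process_features(quant_train)
  pf_test <- process_features(quant_test, pf_train$training_stats)

  labels <- list(train = label_cohort(cohorts$train, "training"),
                 strict = label_cohort(cohorts$test, "strict"),
                 extended = label_cohort(cohorts$test, "extended"))
  pick <- function(features, lab) {
    lab <- lab[lab$label != "excluded", ]
    lab <- lab[lab$sample_id %in% rownames(features), ]
    list(features = features[lab$sample_id, , drop = FALSE],
         labels = as.integer(lab$label == "case"),
         groups = lab$patient_id)
  }
  tr <- pick(pf_train$features, labels$train)
  te_s <- pick(pf_test$features, labels$strict)
  te_e <- pick(pf_test$features, labels$extended)

  candidates <- search_models(tr$features, tr$labels, tr$groups,
                              test = list(strict = te_s, extended = te_e),
                              max_size = max_size, folds = folds,
                              repeats = repeats, seed = config$seed)
  filtered <- run_filter_cascade(candidates, rules)
  pool <- if (length(filtered$final_ids) > 0) filtered$final_ids
          else candidates$id[which.max(candidates$cv_auc_train)]
  in_pool <- candidates[candidates$id %in% pool, ]
  chosen <- in_pool$id[which.max(in_pool$cv_auc_train)]
  feats <- strsplit(in_pool$features[in_pool$id == chosen], "+", fixed = TRUE)[[1]]
  refit <- fit_logistic(tr$features[, feats, drop = FALSE], tr$labels)
  coefs <- refit$coefficients[-1]
  names(coefs) <- feats
  model <- new_final_model(refit$coefficients[1], coefs,
                           standardization = pf_train$training_stats)
  test_scores <- score_cohort(te_s$features, model, te_s$labels,
                              ci_method = "none")
  list(cohorts = cohorts,
       qc = lapply(prep, function(p)
         list(n_passed = length(p$spectra),
              n_failed = length(p$qc) - length(p$spectra),
              referencing_failed = p$referencing_failed)),
       features = list(train = pf_train, test = pf_test),
       labels = labels, candidates = candidates, filtered = filtered,
       chosen_id = chosen, model = model, test_scores = test_scores)
}
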