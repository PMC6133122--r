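# The final published rejection-score model: omega and Score for new
# samples from processed features.

#' Compute the rejection score of one sample
#'
#' \deqn{Score = 100 / (1 + e^{-\omega})}, with \eqn{\omega} the model's
#' linear predictor over the standardized, creatinine-normalized,
#' log-transformed intensities \eqn{I_x}.  The score rises with lactate
#' and urea and falls with alanine and citrate.  A sample missing any
#' required feature yields no score -- missing inputs are never imputed.
#'
#' @param features Named numeric vector (or one-row data.frame) of I_x
#'   values; must contain every feature of the model.
#' @param model A [final_model()].
#' @return Object of class `rejection_score`: `score` (in (0,100)),
#'   `omega`, `inputs_valid`, `missing_features`.
#' @export
#' @examples
#' compute_score(c(Alanine = 0, Citrate = 0, Lactate = 0, Urea = 0))
compute_score <- function(features, model = final_model()) {
  if (is.data.frame(features) || is.matrix(features)) {
    stopifnot(nrow(features) == 1L)
    features <- setNames(as.numeric(features[1, ]), colnames(features))
  }
  need <- model$feature_order
  missing_features <- need[!(need %in% names(features)) |
                             !is.finite(features[need])]
  if (length(missing_features) > 0L) {
    out <- list(score = NA_real_, omega = NA_real_, inputs_valid = FALSE,
                missing_features = missing_features)
  } else {
    omega <- model$intercept +
      sum(model$coefficients[need] * features[need])
    out <- list(score = 100 * plogis(omega), omega = unname(omega),
                inputs_valid = TRUE, missing_features = character())
  }
  class(out) <- "rejection_score"
  out
}

#' @export
print.rejection_score <- function(x, ...) {
  if (x$inputs_valid)
    cat(sprintf("Rejection score: %.1f (omega = %.4f)\n", x$score, x$omega))
  else
    cat("Rejection score: not computable; missing features:",
        paste(x$missing_features, collapse = ", "), "\n")
  invisible(x)
}

#' Score a whole cohort and optionally assess discrimination
#'
#' One rejection score per sample with all required features valid;
#' samples with missing features are reported with `inputs_valid =
#' FALSE` and no score.  When labels are supplied, ROC/AUC of the score
#' is computed over the scored samples.
#'
#' @param features Samples x metabolites matrix of I_x values
#'   (e.g. `process_features()$features`), rownames = sample ids.
#' @param model A [final_model()].
#' @param labels Optional binary labels aligned with the rows.
#' @param ... Passed to [roc_auc()] (e.g. `ci_method`, `seed`).
#' @return List: `scores` (data.frame `sample_id, omega, score,
#'   inputs_valid`), `roc` (a [roc_auc()] result, or NULL without
#'   labels).
#' @export
score_cohort <- function(features, model = final_model(), labels = NULL, ...) {
  features <- as.matrix(features)
  need <- model$feature_order
  if (!all(need %in% colnames(features)))
    stop("input error: features lack model columns: ",
         paste(setdiff(need, colnames(features)), collapse = ", "))
  X <- features[, need, drop = FALSE]
  valid <- apply(is.finite(X), 1, all)
  if (!any(valid)) stop("input error: no sample has all model features valid")
  omega <- rep(NA_real_, nrow(X))
  omega[valid] <- model$intercept +
    as.numeric(X[valid, , drop = FALSE] %*% model$coefficients[need])
  scores <- data.frame(
    sample_id = if (is.null(rownames(X))) seq_len(nrow(X)) else rownames(X),
    omega = omega, score = 100 * plogis(omega), inputs_valid = valid)
  roc <- NULL
  if (!is.null(labels)) {
    ok <- valid & !is.na(labels)
    roc <- roc_auc(scores$score[ok], labels[ok], ...)
  }
  list(scores = scores, roc = roc)
}
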