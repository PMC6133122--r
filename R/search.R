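# Exhaustive logistic model search over metabolite subsets, with
# patient-grouped cross-validated AUC, test-set AUC, ROC with confidence
# bands, and a random-forest comparison arm.

#' Enumerate all feature subsets up to a maximum size
#'
#' All subsets of size 1..`max_size`, each exactly once, in a
#' deterministic order (by size, then lexicographic within size).  With
#' 10 features and `max_size = 5` this yields the 637 candidate models.
#'
#' @param n_features Number of available features, or a character vector
#'   of feature names.
#' @param max_size Maximum subset size (1 <= max_size <= n_features).
#' @return List of integer vectors (or character vectors when names were
#'   supplied).
#' @export
#' @examples
#' length(enumerate_subsets(10, 5))  # 637
enumerate_subsets <- function(n_features, max_size) {
  feats <- if (is.character(n_features)) n_features
           else seq_len(n_features)
  n <- length(feats)
  if (max_size < 1 || max_size > n)
    stop("input error: need 1 <= max_size <= n_features")
  unlist(lapply(seq_len(max_size), function(k)
    combn(feats, k, simplify = FALSE)), recursive = FALSE)
}

# fast tie-aware AUC (Mann-Whitney with half credit for ties)
auc_rank <- function(scores, labels) {
  y <- as.integer(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("input error: AUC requires both classes")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit a logistic regression on a feature subset
#'
#' Maximum-likelihood logistic regression (stats::glm).  Rows with any
#' missing feature are dropped (complete-case analysis: quantification
#' failures shrink the usable n per candidate).  Quasi-separated fits are
#' flagged, not errored.
#'
#' @param features data.frame/matrix of predictors.
#' @param labels Binary labels (0/1), both classes required.
#' @return List of class `logistic_fit`: `coefficients`, `separable`
#'   (logical flag), `n_used`, and the underlying `glm` object (`fit`).
#' @export
fit_logistic <- function(features, labels) {
  d <- as.data.frame(features)
  keep <- complete.cases(d) & !is.na(labels)
  d <- d[keep, , drop = FALSE]
  y <- as.integer(labels[keep])
  if (length(unique(y)) < 2L)
    stop("input error: logistic fit requires both classes")
  d$.y <- y
  separable <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = d, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separable <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (any(abs(coef(fit)[-1]) > 15, na.rm = TRUE)) separable <- TRUE
  structure(list(coefficients = coef(fit), separable = separable,
                 n_used = nrow(d), fit = fit),
            class = "logistic_fit")
}

# one repeat of patient-grouped fold assignment; NULL if a training part
# would be single-class
grouped_folds <- function(groups, labels, folds) {
  g <- unique(groups)
  assign_g <- setNames(sample(rep_len(seq_len(folds), length(g))), g)
  fold <- assign_g[as.character(groups)]
  for (k in seq_len(folds)) {
    if (length(unique(labels[fold != k])) < 2L) return(NULL)
    if (sum(fold == k) == 0L) return(NULL)
  }
  fold
}

#' Patient-grouped cross-validated AUC of a logistic model
#'
#' Repeated k-fold cross-validation in which folds are assigned per
#' patient, never splitting one patient's samples across folds (repeated
#' samples per patient would otherwise leak).  Held-out predicted
#' probabilities are pooled within each repeat, the AUC computed, and
#' the mean over repeats returned.  Deterministic given `seed`; fold
#' draws leaving a training part single-class are redrawn (up to 20
#' times, then error).
#'
#' @param features Predictor data.frame/matrix (complete cases used).
#' @param labels Binary labels.
#' @param groups Grouping factor (patient ids), same length as labels.
#' @param folds Number of folds (>= 2).
#' @param repeats Number of repeats.
#' @param seed Integer seed.
#' @return Mean cross-validated AUC, with per-repeat AUCs as attribute
#'   `per_repeat`.
#' @export
cv_auc <- function(features, labels, groups, folds = 5, repeats = 10,
                   seed = 1L) {
  stopifnot(folds >= 2)
  d <- as.data.frame(features)
  keep <- complete.cases(d) & !is.na(labels)
  d <- d[keep, , drop = FALSE]
  y <- as.integer(labels[keep])
  g <- groups[keep]
  if (length(unique(y)) < 2L)
    stop("input error: cv_auc requires both classes")
  with_seed(seed, {
    aucs <- vapply(seq_len(repeats), function(r) {
      fold <- NULL
      for (try in 1:20) {
        fold <- grouped_folds(g, y, folds)
        if (!is.null(fold)) break
      }
      if (is.null(fold))
        stop("could not draw grouped folds with both classes in every ",
             "training part")
      pred <- numeric(length(y))
      for (k in seq_len(folds)) {
        tr <- fold != k
        dtr <- d[tr, , drop = FALSE]; dtr$.y <- y[tr]
        fit <- suppressWarnings(glm(.y ~ ., data = dtr, family = binomial()))
        pred[!tr] <- predict(fit, newdata = d[!tr, , drop = FALSE],
                             type = "response")
      }
      auc_rank(pred, y)
    }, numeric(1))
    structure(mean(aucs), per_repeat = aucs)
  })
}

#' ROC curve with AUC and bootstrap confidence interval
#'
#' ROC/AUC via pROC; the AUC equals the tie-aware Mann-Whitney
#' U-statistic.  The 95% CI uses stratified bootstrap (default 2000
#' draws) and is deterministic given `seed`.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Binary labels.
#' @param ci_method `"bootstrap"`, `"delong"` or `"none"`.
#' @param boot_n Bootstrap draws.
#' @param seed Seed for the bootstrap.
#' @return Object of class `roc_result`: `thresholds`, `sensitivities`,
#'   `specificities`, `auc`, `ci_low`, `ci_high`.
#' @export
roc_auc <- function(scores, labels, ci_method = c("bootstrap", "delong", "none"),
                    boot_n = 2000, seed = 1L) {
  ci_method <- match.arg(ci_method)
  y <- as.integer(labels)
  if (length(unique(y[!is.na(y)])) < 2L)
    stop("input error: ROC requires both classes")
  r <- pROC::roc(response = y, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- c(NA_real_, NA_real_)
  if (ci_method == "bootstrap") {
    ci_obj <- with_seed(seed,
      pROC::ci.auc(r, method = "bootstrap", boot.n = boot_n,
                   boot.stratified = TRUE))
    ci <- as.numeric(ci_obj)[c(1, 3)]
  } else if (ci_method == "delong") {
    ci_obj <- pROC::ci.auc(r, method = "delong")
    ci <- as.numeric(ci_obj)[c(1, 3)]
  }
  structure(list(thresholds = r$thresholds, sensitivities = r$sensitivities,
                 specificities = r$specificities,
                 auc = as.numeric(pROC::auc(r)),
                 ci_low = ci[1], ci_high = ci[2]),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f", x$auc))
  if (!is.na(x$ci_low))
    cat(sprintf(" (95%% CI %.3f-%.3f)", x$ci_low, x$ci_high))
  cat("\n")
  invisible(x)
}

#' Compare random forest and logistic regression on identical folds
#'
#' Fits both learners on the same patient-grouped fold assignments and
#' returns the paired cross-validated AUCs, supporting the parsimony
#' decision between the two.
#'
#' @inheritParams cv_auc
#' @param num_trees Trees for the random forest.
#' @return List: `logistic`, `rf` (mean pooled AUCs), `per_repeat`
#'   (2-column matrix).
#' @export
compare_rf_vs_logistic <- function(features, labels, groups, folds = 5,
                                   repeats = 5, seed = 1L, num_trees = 500) {
  d <- as.data.frame(features)
  keep <- complete.cases(d) & !is.na(labels)
  d <- d[keep, , drop = FALSE]
  y <- as.integer(labels[keep])
  g <- groups[keep]
  if (length(unique(y)) < 2L)
    stop("input error: both classes required")
  with_seed(seed, {
    per <- t(vapply(seq_len(repeats), function(r) {
      fold <- NULL
      for (try in 1:20) {
        fold <- grouped_folds(g, y, folds)
        if (!is.null(fold)) break
      }
      if (is.null(fold)) stop("could not draw valid grouped folds")
      pl <- pr <- numeric(length(y))
      for (k in seq_len(folds)) {
        tr <- fold != k
        dtr <- d[tr, , drop = FALSE]; dtr$.y <- y[tr]
        fit <- suppressWarnings(glm(.y ~ ., data = dtr, family = binomial()))
        pl[!tr] <- predict(fit, newdata = d[!tr, , drop = FALSE],
                           type = "response")
        rf <- ranger::ranger(x = d[tr, , drop = FALSE], y = factor(y[tr]),
                             probability = TRUE, num.trees = num_trees,
                             num.threads = 1L, seed = seed + 100L * r + k)
        pr[!tr] <- predict(rf, data = d[!tr, , drop = FALSE],
                           num.threads = 1L)$predictions[, "1"]
      }
      c(logistic = auc_rank(pl, y), rf = auc_rank(pr, y))
    }, numeric(2)))
    list(logistic = mean(per[, "logistic"]), rf = mean(per[, "rf"]),
         per_repeat = per)
  })
}

# canonical candidate id: sorted features joined by "+"
candidate_id <- function(features) {
  vapply(features, function(f) paste(sort(f), collapse = "+"), character(1))
}

#' Exhaustive model search over all metabolite subsets
#'
#' Enumerates every subset of up to `max_size` features, fits a logistic
#' regression per subset (complete-case), computes the patient-grouped
#' cross-validated training AUC and, when test data are supplied, the
#' test-set AUC per labeling setting using the training-fitted model.
#'
#' @param features Training feature matrix/data.frame (columns = the
#'   candidate metabolites).
#' @param labels Training binary labels.
#' @param groups Training patient ids.
#' @param test Optional named list of test sets, each
#'   `list(features =, labels =)`; names become `auc_test_<name>` columns
#'   (e.g. `strict`, `extended`).
#' @param max_size Maximum subset size (default 5).
#' @param folds,repeats,seed Cross-validation scheme.
#' @return A `model_candidates` data.frame: `id`, `features`
#'   (`+`-joined), `n_features`, `cv_auc_train`, `auc_test_*`,
#'   `n_used`, `separable`.
#' @export
search_models <- function(features, labels, groups, test = NULL, max_size = 5,
                          folds = 5, repeats = 10, seed = 1L) {
  feats <- colnames(features)
  subsets <- enumerate_subsets(feats, max_size)
  rows <- lapply(seq_along(subsets), function(i) {
    s <- subsets[[i]]
    X <- features[, s, drop = FALSE]
    fit <- fit_logistic(X, labels)
    # one shared fold seed across candidates: paired model comparisons
    # then contrast identical held-out splits
    cv <- tryCatch(
      as.numeric(cv_auc(X, labels, groups, folds = folds, repeats = repeats,
                        seed = seed)),
      error = function(e) NA_real_)
    row <- data.frame(id = candidate_id(list(s)),
                      features = paste(s, collapse = "+"),
                      n_features = length(s), cv_auc_train = cv,
                      n_used = fit$n_used, separable = fit$separable)
    for (setting in names(test)) {
      ts <- test[[setting]]
      Xt <- as.data.frame(ts$features)[, s, drop = FALSE]
      ok <- complete.cases(Xt) & !is.na(ts$labels)
      a <- if (sum(ts$labels[ok] == 1) > 0 && sum(ts$labels[ok] == 0) > 0) {
        p <- predict(fit$fit, newdata = Xt[ok, , drop = FALSE],
                     type = "response")
        auc_rank(p, ts$labels[ok])
      } else NA_real_
      row[[paste0("auc_test_", setting)]] <- a
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "trace") <- list()
  class(out) <- c("model_candidates", "data.frame")
  out
}
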