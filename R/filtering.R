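# The automated and manual filtering cascade narrowing the 637 candidate
# models to the final one.  Every step records a FilterTrace entry so the
# whole cascade reconciles: no candidate disappears without a reason.

features_of <- function(candidates) strsplit(candidates$features, "+", fixed = TRUE)

add_trace <- function(candidates, survivors, stage, rule) {
  tr <- attr(candidates, "trace")
  if (is.null(tr)) tr <- list()
  tr[[length(tr) + 1L]] <- list(stage = stage, rule = rule,
                                candidates_in = nrow(candidates),
                                candidates_out = nrow(survivors),
                                survivors = survivors$id)
  attr(survivors, "trace") <- tr
  class(survivors) <- c("model_candidates", "data.frame")
  survivors
}

#' Audit trail of a filtering cascade
#'
#' @param candidates A `model_candidates` table that went through one or
#'   more filter steps.
#' @return data.frame with one row per stage: `stage, rule,
#'   candidates_in, candidates_out`; per-stage survivor ids are kept in
#'   the underlying attribute.
#' @export
filter_trace <- function(candidates) {
  tr <- attr(candidates, "trace")
  if (is.null(tr) || length(tr) == 0L)
    return(data.frame(stage = character(), rule = character(),
                      candidates_in = integer(), candidates_out = integer()))
  do.call(rbind, lapply(tr, function(e)
    data.frame(stage = e$stage, rule = e$rule,
               candidates_in = e$candidates_in,
               candidates_out = e$candidates_out)))
}

# select the AUC column for a setting
auc_column <- function(candidates, setting) {
  col <- if (setting == "train") "cv_auc_train" else paste0("auc_test_", setting)
  if (!col %in% names(candidates))
    stop("input error: no AUC column for setting '", setting, "'")
  col
}

#' Filter candidates by training-cohort AUC
#'
#' Retains candidates whose cross-validated training AUC reaches the
#' threshold (inclusive; default 0.75).
#'
#' @param candidates `model_candidates` table.
#' @param threshold Minimum cv AUC (>=).
#' @return Surviving candidates with an updated [filter_trace()].
#' @export
filter_by_train_auc <- function(candidates, threshold = 0.75) {
  keep <- !is.na(candidates$cv_auc_train) & candidates$cv_auc_train >= threshold
  add_trace(candidates, candidates[keep, , drop = FALSE],
            "train_auc", sprintf("cv_auc_train >= %g", threshold))
}

#' Filter candidates by test-set AUC in one setting
#'
#' Retains candidates whose test AUC in the given labeling setting
#' reaches the threshold (inclusive; default 0.70).  Candidates with a
#' missing test AUC are dropped; the rule string records that.
#'
#' @param candidates `model_candidates` table.
#' @param setting `"strict"` or `"extended"`.
#' @param threshold Minimum test AUC (>=).
#' @return Surviving candidates with updated trace.
#' @export
filter_by_test_auc <- function(candidates, setting = c("strict", "extended"),
                               threshold = 0.70) {
  setting <- match.arg(setting)
  col <- auc_column(candidates, setting)
  keep <- !is.na(candidates[[col]]) & candidates[[col]] >= threshold
  add_trace(candidates, candidates[keep, , drop = FALSE],
            paste0("test_auc_", setting),
            sprintf("%s >= %g (NA dropped)", col, threshold))
}

#' Exclude all candidates using a named feature
#'
#' Encodes judgment-call removals (e.g. trigonelline, whose urinary level
#' tracks coffee intake and would couple the test to diet).
#'
#' @param candidates `model_candidates` table.
#' @param feature Feature name; must be a known feature (in the candidate
#'   table or in `universe`).
#' @param universe Known feature names (defaults to the metabolite panel).
#' @return Surviving candidates with updated trace.
#' @export
exclude_feature <- function(candidates, feature,
                            universe = panel_metabolites()) {
  known <- union(universe, unlist(features_of(candidates)))
  if (!feature %in% known)
    stop("input error: unknown feature '", feature, "'")
  uses <- vapply(features_of(candidates), function(f) feature %in% f, logical(1))
  surv <- add_trace(candidates, candidates[!uses, , drop = FALSE],
                    "exclude_feature", paste0("drop models containing ", feature))
  if (nrow(surv) == 0L)
    warning("exclude_feature('", feature, "') left no candidates")
  surv
}

#' Keep only candidates using a named feature
#'
#' @inheritParams exclude_feature
#' @return Surviving candidates with updated trace.
#' @export
require_feature <- function(candidates, feature,
                            universe = panel_metabolites()) {
  known <- union(universe, unlist(features_of(candidates)))
  if (!feature %in% known)
    stop("input error: unknown feature '", feature, "'")
  uses <- vapply(features_of(candidates), function(f) feature %in% f, logical(1))
  add_trace(candidates, candidates[uses, , drop = FALSE],
            "require_feature", paste0("keep models containing ", feature))
}

#' Paired AUC difference from adding one feature
#'
#' Matches every candidate S not containing `feature` with its exact
#' counterpart S + feature and reports the per-pair AUC difference
#' (with minus without) and the median absolute difference -- the
#' statistic behind the "does lactate help" style decisions.
#'
#' @param candidates `model_candidates` table.
#' @param feature Feature whose addition is assessed.
#' @param setting `"train"`, `"strict"` or `"extended"`.
#' @return List: `pairs` (data.frame `without_id, with_id, auc_without,
#'   auc_with, delta`), `median_abs_delta`.
#' @export
paired_delta_auc <- function(candidates, feature,
                             setting = c("strict", "extended", "train")) {
  setting <- match.arg(setting)
  col <- auc_column(candidates, setting)
  feats <- features_of(candidates)
  ids <- candidates$id
  without <- which(vapply(feats, function(f) !feature %in% f, logical(1)))
  pairs <- lapply(without, function(i) {
    mate_id <- paste(sort(c(feats[[i]], feature)), collapse = "+")
    j <- match(mate_id, ids)
    if (is.na(j)) return(NULL)
    data.frame(without_id = ids[i], with_id = ids[j],
               auc_without = candidates[[col]][i],
               auc_with = candidates[[col]][j],
               delta = candidates[[col]][j] - candidates[[col]][i])
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || nrow(pairs) == 0L) {
    warning("no matched pairs for feature '", feature, "'")
    return(list(pairs = data.frame(), median_abs_delta = NA_real_))
  }
  list(pairs = pairs, median_abs_delta = median(abs(pairs$delta), na.rm = TRUE))
}

#' Paired AUC difference from swapping two features
#'
#' Matches candidates containing `feature_a` (and not `feature_b`) with
#' the counterpart in which a is replaced by b -- the statistic behind
#' the alanine-vs-hippurate decision.
#'
#' @param candidates `model_candidates` table.
#' @param feature_a,feature_b The swapped features.
#' @param setting `"train"`, `"strict"` or `"extended"`.
#' @return List: `pairs` (data.frame `a_id, b_id, auc_a, auc_b, delta` =
#'   a-version minus b-version), `median_abs_delta`.
#' @export
paired_swap_auc <- function(candidates, feature_a, feature_b,
                            setting = c("strict", "extended", "train")) {
  setting <- match.arg(setting)
  col <- auc_column(candidates, setting)
  feats <- features_of(candidates)
  ids <- candidates$id
  a_only <- which(vapply(feats, function(f)
    feature_a %in% f && !feature_b %in% f, logical(1)))
  pairs <- lapply(a_only, function(i) {
    mate <- sort(c(setdiff(feats[[i]], feature_a), feature_b))
    j <- match(paste(mate, collapse = "+"), ids)
    if (is.na(j)) return(NULL)
    data.frame(a_id = ids[i], b_id = ids[j],
               auc_a = candidates[[col]][i], auc_b = candidates[[col]][j],
               delta = candidates[[col]][i] - candidates[[col]][j])
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || nrow(pairs) == 0L) {
    warning("no matched swap pairs for '", feature_a, "' vs '", feature_b, "'")
    return(list(pairs = data.frame(), median_abs_delta = NA_real_))
  }
  list(pairs = pairs, median_abs_delta = median(abs(pairs$delta), na.rm = TRUE))
}

#' Intersect the survivor lists of the two test settings
#'
#' Set intersection by feature-set identity (canonical sorted ids).
#'
#' @param strict_survivors,extended_survivors `model_candidates` tables
#'   or character id vectors.
#' @return Character vector of ids in both lists.
#' @export
intersect_settings <- function(strict_survivors, extended_survivors) {
  ids <- function(x) if (is.character(x)) x else x$id
  out <- intersect(ids(strict_survivors), ids(extended_survivors))
  if (length(out) == 0L)
    warning("settings have no common surviving model")
  out
}

#' The default declarative filtering rule list
#'
#' The ordered cascade mirroring the published selection: automated AUC
#' thresholds (cv >= 0.75 on training, >= 0.70 on the test setting),
#' then the judgment-call rules -- drop trigonelline (coffee
#' confounding), require lactate, prefer alanine over hippurate, drop
#' DMA (negligible gain), drop glucose (glucosuria interference) and
#' glucuronate (xenobiotic conjugation).  Editable: it is data, not code.
#'
#' @return List of rule specifications for [run_filter_cascade()].
#' @export
default_filter_rules <- function() {
  list(
    list(type = "train_auc", threshold = 0.75),
    list(type = "test_auc", threshold = 0.70),
    list(type = "exclude_feature", feature = "Trigonelline"),
    list(type = "require_feature", feature = "Lactate"),
    list(type = "exclude_feature", feature = "Hippurate"),
    list(type = "exclude_feature", feature = "DMA"),
    list(type = "exclude_feature", feature = "Glucose"),
    list(type = "exclude_feature", feature = "Glucuronate"))
}

#' Run the full filtering cascade
#'
#' Applies the rule list per test setting (the `test_auc` rule uses that
#' setting's AUC column), then intersects the settings' survivor lists.
#'
#' @param candidates `model_candidates` table from [search_models()].
#' @param rules Rule list; see [default_filter_rules()].
#' @param settings Test settings to run (default strict + extended).
#' @return List: per-setting surviving `model_candidates` (with traces),
#'   and `final_ids` = the intersection.
#' @export
run_filter_cascade <- function(candidates, rules = default_filter_rules(),
                               settings = c("strict", "extended")) {
  per_setting <- lapply(settings, function(s) {
    cur <- candidates
    for (r in rules) {
      cur <- switch(r$type,
        train_auc = filter_by_train_auc(cur, r$threshold),
        test_auc = filter_by_test_auc(cur, s, r$threshold),
        exclude_feature = suppressWarnings(exclude_feature(cur, r$feature)),
        require_feature = require_feature(cur, r$feature),
        stop("unknown rule type: ", r$type))
    }
    cur
  })
  names(per_setting) <- settings
  out <- per_setting
  out$final_ids <- Reduce(intersect_settings, per_setting)
  out
}
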