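# The filtering cascade: AUC thresholds, feature rules, paired AUC
# contrasts, setting intersection, audit-trail reconciliation.

mk_candidates <- function(features, cv = NULL, strict = NULL, extended = NULL) {
  ids <- vapply(features, function(f) paste(sort(f), collapse = "+"), character(1))
  d <- data.frame(id = ids,
                  features = vapply(features, paste, character(1), collapse = "+"),
                  n_features = lengths(features),
                  cv_auc_train = if (is.null(cv)) 0.8 else cv,
                  auc_test_strict = if (is.null(strict)) 0.8 else strict,
                  auc_test_extended = if (is.null(extended)) 0.8 else extended,
                  n_used = 100, separable = FALSE)
  attr(d, "trace") <- list()
  class(d) <- c("model_candidates", "data.frame")
  d
}

test_that("training-AUC threshold is inclusive at exactly 0.75", {
  cand <- mk_candidates(list("A", "B", "C"), cv = c(0.75, 0.7499, 0.9))
  out <- filter_by_train_auc(cand)
  expect_setequal(out$id, c("A", "C"))
  tr <- filter_trace(out)
  expect_equal(tr$candidates_in, 3)
  expect_equal(tr$candidates_out, 2)
  empty <- filter_by_train_auc(mk_candidates(list("A"))[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("test-AUC threshold is inclusive, per setting, NA dropped", {
  cand <- mk_candidates(list("A", "B", "C", "D"),
                        strict = c(0.70, 0.69, 0.9, NA),
                        extended = c(0.65, 0.95, 0.9, 0.8))
  s <- filter_by_test_auc(cand, "strict")
  expect_setequal(s$id, c("A", "C"))
  e <- filter_by_test_auc(cand, "extended")
  expect_setequal(e$id, c("B", "C", "D"))
  # survivors differ by setting: B survives extended only
  expect_false("B" %in% s$id)
})

test_that("feature exclusion and requirement behave as set operations", {
  cand <- mk_candidates(list("Alanine", c("Alanine", "Trigonelline"),
                             c("Lactate", "Urea")))
  out <- exclude_feature(cand, "Trigonelline")
  expect_setequal(out$id, c("Alanine", "Lactate+Urea"))
  # no candidate uses the feature: identity
  out2 <- exclude_feature(cand, "DMA")
  expect_setequal(out2$id, cand$id)
  # all candidates use it: empty, with a warning
  all_trig <- mk_candidates(list("Trigonelline", c("Trigonelline", "Urea")))
  expect_warning(out3 <- exclude_feature(all_trig, "Trigonelline"), "left no")
  expect_equal(nrow(out3), 0)
  expect_error(exclude_feature(cand, "Caffeine"), "unknown feature")
  req <- require_feature(cand, "Lactate")
  expect_equal(req$id, "Lactate+Urea")
})

test_that("paired delta-AUC matches exact with/without counterparts", {
  cand <- mk_candidates(list("x", c("x", "f")), strict = c(0.70, 0.80))
  res <- paired_delta_auc(cand, "f", "strict")
  expect_equal(nrow(res$pairs), 1)
  expect_equal(res$pairs$delta, 0.10)
  expect_equal(res$median_abs_delta, 0.10)
  expect_warning(none <- paired_delta_auc(cand, "zzz", "strict"), "no matched")
  expect_true(is.na(none$median_abs_delta))
})

test_that("paired swaps match a<->b counterparts; collinear duplicates tie", {
  cand <- mk_candidates(list(c("a", "x"), c("b", "x")), strict = c(0.78, 0.74))
  res <- paired_swap_auc(cand, "a", "b", "strict")
  expect_equal(res$pairs$delta, 0.04)

  # duplicated feature columns: identical fits, delta exactly zero
  set.seed(5)
  n <- 300
  X <- data.frame(a = rnorm(n), x = rnorm(n))
  X$b <- X$a
  y <- rbinom(n, 1, plogis(X$a + 0.5 * X$x))
  g <- paste0("P", rep(1:75, 4))
  cand2 <- search_models(as.matrix(X), y, g, max_size = 2, folds = 3,
                         repeats = 1, seed = 2)
  res2 <- paired_swap_auc(cand2, "a", "b", "train")
  expect_lt(res2$median_abs_delta, 1e-12)
})

test_that("a planted dominant feature shows a positive paired delta", {
  set.seed(21)
  n <- 400
  X <- matrix(rnorm(n * 4), n, dimnames = list(NULL, c("f", "u", "v", "w")))
  y <- rbinom(n, 1, plogis(2 * X[, "f"] + 0.2 * X[, "u"]))
  g <- paste0("P", rep(1:100, 4))
  cand <- search_models(X, y, g, max_size = 3, folds = 3, repeats = 1, seed = 9)
  res <- paired_delta_auc(cand, "f", "train")
  expect_gt(nrow(res$pairs), 3)
  expect_true(median(res$pairs$delta) > 0)
  expect_true(all(res$pairs$delta > 0))
})

test_that("setting intersection is set algebra on feature-set identity", {
  expect_setequal(intersect_settings(c("m1", "m2"), c("m2", "m3")), "m2")
  expect_setequal(intersect_settings(c("m1", "m2"), c("m1", "m2", "m3")),
                  c("m1", "m2"))
  expect_warning(out <- intersect_settings(c("m1"), c("m2")), "no common")
  expect_length(out, 0)
})

test_that("the full cascade reconciles its audit trail on a 637 leaderboard", {
  mets <- panel_metabolites()
  subsets <- enumerate_subsets(mets, 5)
  set.seed(40)
  cand <- mk_candidates(subsets,
                        cv = runif(637, 0.6, 0.9),
                        strict = runif(637, 0.6, 0.9),
                        extended = runif(637, 0.6, 0.9))
  expect_equal(nrow(cand), 637)
  res <- run_filter_cascade(cand)
  for (s in c("strict", "extended")) {
    tr <- filter_trace(res[[s]])
    expect_equal(tr$candidates_in[1], 637)
    # chain reconciles: out of stage k = in of stage k+1, all accounted
    expect_equal(tr$candidates_in[-1], tr$candidates_out[-nrow(tr)])
    expect_equal(tr$candidates_out[nrow(tr)], nrow(res[[s]]))
    # every stage's survivors are a subset of the previous stage's
    surv <- lapply(attr(res[[s]], "trace"), `[[`, "survivors")
    for (k in seq_along(surv)[-1])
      expect_true(all(surv[[k]] %in% surv[[k - 1]]))
  }
  # independent set-algebra check of each rule and the intersection
  keep <- function(setting) {
    ok <- cand$cv_auc_train >= 0.75 &
      cand[[paste0("auc_test_", setting)]] >= 0.70
    f <- strsplit(cand$features, "+", fixed = TRUE)
    has <- function(m) vapply(f, function(x) m %in% x, logical(1))
    ok & !has("Trigonelline") & has("Lactate") & !has("Hippurate") &
      !has("DMA") & !has("Glucose") & !has("Glucuronate")
  }
  expect_setequal(res$strict$id, cand$id[keep("strict")])
  expect_setequal(res$extended$id, cand$id[keep("extended")])
  expect_setequal(res$final_ids,
                  intersect(cand$id[keep("strict")], cand$id[keep("extended")]))
})
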