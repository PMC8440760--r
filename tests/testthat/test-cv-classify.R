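test_that("CV plans partition patients without leakage", {
  lopo <- build_cv(c("A", "B", "C"), "lopo")
  expect_equal(nrow(lopo), 3)
  expect_true(all(lengths(lopo$test) == 1))

  kf <- build_cv(sprintf("P%02d", 1:10), "grouped_kfold", k = 5, seed = 3)
  expect_equal(nrow(kf), 5)
  expect_true(all(lengths(kf$test) == 2))
  all_test <- unlist(kf$test)
  expect_setequal(all_test, sprintf("P%02d", 1:10))
  expect_equal(anyDuplicated(all_test), 0)
  for (i in 1:5) {
    expect_length(intersect(kf$train[[i]], kf$test[[i]]), 0)
  }
  expect_error(build_cv(c("A", "B"), "grouped_kfold", k = 3), "cannot exceed")
  expect_error(build_cv("A", "lopo"), "at least 2")
})

test_that("grouped k-fold is reproducible from its seed", {
  a <- build_cv(sprintf("P%02d", 1:9), "grouped_kfold", k = 4, seed = 7)
  b <- build_cv(sprintf("P%02d", 1:9), "grouped_kfold", k = 4, seed = 7)
  expect_identical(a$test, b$test)
})

test_that("train_eval separates a well-separated cohort and is deterministic", {
  coh <- make_feature_cohort(12, 6, seed = 41)
  cv <- build_cv(unique(coh$patient_id), "lopo")
  rep1 <- train_eval(coh, cv, classifiers = c("knn9", "random_forest",
                                              "ensemble_voting"),
                     top_k = 10, seed = 2)
  expect_s3_class(rep1, "eval_report")
  expect_equal(nrow(rep1), 3)
  expect_true(all(rep1$auc > 0.8))
  expect_equal(rep1$tp + rep1$fn + rep1$tn + rep1$fp, rep(nrow(coh), 3))
  # internal consistency of the percentage arithmetic
  expect_equal(rep1$sensitivity, 100 * rep1$tp / (rep1$tp + rep1$fn))
  expect_equal(rep1$specificity, 100 * rep1$tn / (rep1$tn + rep1$fp))

  rep2 <- train_eval(coh, cv, classifiers = c("knn9", "random_forest",
                                              "ensemble_voting"),
                     top_k = 10, seed = 2)
  expect_equal(tidy(rep1), tidy(rep2))
})

test_that("folds whose training side lacks a class are skipped with a warning", {
  coh <- make_feature_cohort(4, 3, seed = 43)
  # make one class rare: relabel all but one patient to the same class
  pats <- unique(coh$patient_id)
  coh$label[coh$patient_id != pats[1]] <- "benign"
  coh$label[coh$patient_id == pats[1]] <- "suspicious"
  cv <- build_cv(pats, "lopo")
  # with a single-patient class, the fold testing that patient must be
  # skipped, which in turn empties the pooled positive class
  expect_error(
    suppressWarnings(train_eval(coh, cv, classifiers = "knn9",
                                select = FALSE)),
    "single class")
  expect_warning(
    try(train_eval(coh, cv, classifiers = "knn9", select = FALSE),
        silent = TRUE),
    "lacks a class")
})

test_that("tidy and glance expose the report as plain tibbles", {
  coh <- make_feature_cohort(8, 5, seed = 47)
  cv <- build_cv(unique(coh$patient_id), "lopo")
  rep <- train_eval(coh, cv, classifiers = c("decision_tree", "bagging"),
                    select = FALSE)
  td <- tidy(rep)
  expect_false(inherits(td, "eval_report"))
  g <- glance(rep)
  expect_equal(nrow(g), 1)
  expect_equal(g$auc, max(td$auc))
})

test_that("two-round classification chains candidate and BI-RADS stages", {
  set.seed(51)
  coh <- make_feature_cohort(12, 5, seed = 53)
  # round-1 ground truth: half the rows are true lesions
  coh$is_true_mc <- rep(c(TRUE, FALSE), length.out = nrow(coh))
  coh$label[!coh$is_true_mc] <- NA
  cv <- build_cv(unique(coh$patient_id), "lopo")
  out <- classify_two_round(coh, cv, classifiers = c("knn9", "random_forest"),
                            select = FALSE)
  expect_s3_class(out$round1, "eval_report")
  # round 2 consumed only annotated true lesions
  if (!is.null(out$round2)) {
    expect_equal(out$round2$tp + out$round2$fn + out$round2$tn + out$round2$fp,
                 rep(sum(coh$is_true_mc & !is.na(coh$label)),
                     nrow(out$round2)))
  }
})
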