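#' Area under the ROC curve
#'
#' Trapezoidal AUC, computed through its Mann-Whitney identity: the
#' probability that a random positive scores above a random negative,
#' with ties counted as 1/2.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Logical or two-level vector; `TRUE` / second level =
#'   positive.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  pos <- as.logical_labels(labels)
  if (!any(pos) || all(pos)) abort("Both classes must be present to compute AUC.")
  r <- rank(scores)
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as.logical_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  f <- factor(labels)
  if (nlevels(f) > 2) abort("Labels must have two levels.")
  f == levels(f)[nlevels(f)]
}

#' Score threshold balancing false positives against false negatives
#'
#' Scans every candidate threshold (the pooled unique scores) and
#' returns the one minimising `|FP - FN|`, i.e. the crossing point of
#' the positive and negative score distributions; ties are broken by
#' the smaller total error `FP + FN`, then by the lower threshold.
#' Scores at or above the threshold are called positive.
#'
#' @param scores_pos Scores of the positive class.
#' @param scores_neg Scores of the negative class.
#' @return The selected threshold (scalar).
#' @export
optimal_cutoff <- function(scores_pos, scores_neg) {
  if (length(scores_pos) == 0 || length(scores_neg) == 0) {
    abort("Both score sets must be non-empty.")
  }
  cand <- sort(unique(c(scores_pos, scores_neg)))
  cand <- c(cand, max(cand) + 1)  # also allow "call everything negative"
  fp <- vapply(cand, function(t) sum(scores_neg >= t), numeric(1))
  fn <- vapply(cand, function(t) sum(scores_pos < t), numeric(1))
  bal <- abs(fp - fn)
  tot <- fp + fn
  ord <- order(bal, tot, cand)
  cand[ord[1]]
}

#' Fisher exact comparison of two classifier outcomes
#'
#' Two-sided Fisher exact test on the 2 x 2 table of correct/incorrect
#' decision counts of two pipeline variants, used to decide whether one
#' variant classifies significantly better than the other.
#'
#' @param counts_a,counts_b Length-2 vectors `c(correct, incorrect)`
#'   for the two variants.
#' @return The two-sided p-value.
#' @export
fisher_compare <- function(counts_a, counts_b) {
  tab <- rbind(as.numeric(counts_a), as.numeric(counts_b))
  if (any(tab < 0) || any(!is.finite(tab)) || length(tab) != 4) {
    abort("Counts must be two non-negative pairs (correct, incorrect).")
  }
  stats::fisher.test(round(tab))$p.value
}

metrics_from_counts <- function(tp, fn, tn, fp) {
  tibble(tp = tp, fn = fn, tn = tn, fp = fp,
         sensitivity = 100 * tp / (tp + fn),
         specificity = 100 * tn / (tn + fp),
         accuracy = 100 * (tp + tn) / (tp + fn + tn + fp))
}

#' Train and evaluate classifiers under a patient-grouped CV plan
#'
#' For every fold: standardises the features with train-fold statistics
#' only, optionally re-runs feature selection on the train fold, fits
#' each requested classifier, and scores the held-out patients. The
#' pooled out-of-fold scores of each classifier are thresholded at the
#' FP/FN-balancing [optimal_cutoff()] and summarised as counts,
#' sensitivity, specificity, accuracy (percent), and trapezoidal AUC.
#' Folds whose training side lacks a class are skipped with a warning;
#' if all folds are skipped an error is raised.
#'
#' @param features Tibble containing `patient_id`, a two-level `label`
#'   column, and numeric feature columns.
#' @param cv A [build_cv()] plan.
#' @param classifiers Subset of [classifier_names()];
#'   `"ensemble_voting"` soft-votes (averages the probabilities of) the
#'   base classifiers in the set.
#' @param positive Label value treated as the positive class.
#' @param select Re-run [select_features()] inside each training fold.
#' @param p_cut,top_k Selection parameters (when `select = TRUE`).
#' @param balance_train Equalise class priors in every training fold by
#'   cyclically replicating minority-class rows. Holding out a whole
#'   patient shifts the training prior towards the opposite class,
#'   which systematically anti-correlates LOPO predictions with the
#'   held-out class; balanced folds remove that bias.
#' @param seed Seed controlling the stochastic classifiers.
#' @return An `eval_report`: a tibble with one row per classifier
#'   (counts, percentages, `auc`, `cutoff`, `n_folds_used`). The pooled
#'   out-of-fold scores are attached as attribute `"scores"`.
#' @export
train_eval <- function(features, cv, classifiers = classifier_names(),
                       positive = "suspicious", select = TRUE,
                       p_cut = 0.05, top_k = 20, balance_train = TRUE,
                       seed = 1L) {
  stopifnot(inherits(cv, "cv_plan"))
  unknown <- setdiff(classifiers, classifier_names())
  if (length(unknown) > 0) {
    abort(sprintf("Unknown classifier(s): %s", paste(unknown, collapse = ", ")))
  }
  base_cls <- intersect(BASE_CLASSIFIERS, classifiers)
  want_vote <- "ensemble_voting" %in% classifiers
  if (want_vote && length(base_cls) == 0) base_cls <- BASE_CLASSIFIERS

  feat_cols <- setdiff(names(features)[vapply(features, is.numeric, logical(1))],
                       c("candidate_id"))
  y_all <- factor(features$label == positive, levels = c(FALSE, TRUE),
                  labels = c("neg", "pos"))
  pid <- as.character(features$patient_id)

  oof <- list()
  used_folds <- 0L
  for (f in seq_len(nrow(cv))) {
    tr <- pid %in% cv$train[[f]]
    te <- pid %in% cv$test[[f]]
    if (!any(te)) next
    if (length(unique(y_all[tr])) < 2) {
      warn(sprintf("Fold %d skipped: training side lacks a class.", f))
      next
    }
    used_folds <- used_folds + 1L
    tr_idx <- which(tr)
    if (balance_train) {
      by_class <- split(tr_idx, y_all[tr_idx])
      n_max <- max(lengths(by_class))
      tr_idx <- sort(unlist(lapply(by_class, function(ix) {
        rep(ix, length.out = n_max)
      }), use.names = FALSE))
    }
    ytr <- y_all[tr_idx]
    Xtr <- as.matrix(features[tr_idx, feat_cols])
    Xte <- as.matrix(features[te, feat_cols])
    cols <- feat_cols
    if (select) {
      rep <- select_features(Xtr, ytr,
                             p_cut = p_cut, top_k = top_k, seed = seed)
      cols <- rep$feature[rep$selected]
      Xtr <- Xtr[, cols, drop = FALSE]
      Xte <- Xte[, cols, drop = FALSE]
    }
    mu <- colMeans(Xtr)
    sg <- apply(Xtr, 2, sd); sg[sg == 0] <- 1
    Xtr <- scale(Xtr, center = mu, scale = sg)
    Xte <- scale(Xte, center = mu, scale = sg)
    probs <- purrr::map(base_cls, function(cl) {
      model <- fit_one_classifier(cl, Xtr, ytr, seed = seed)
      pmin(pmax(model(Xte), 0), 1)
    })
    names(probs) <- base_cls
    if (want_vote) probs$ensemble_voting <- Reduce(`+`, probs) / length(probs)
    oof[[length(oof) + 1]] <- tibble(
      fold = f, row = which(te), truth = y_all[te] == "pos",
      !!!probs)
  }
  if (used_folds == 0) abort("All folds were skipped; cannot evaluate.")
  oof <- dplyr::bind_rows(oof)
  if (!any(oof$truth) || all(oof$truth)) {
    abort("Pooled out-of-fold scores contain a single class (skipped folds removed the other); cannot evaluate.")
  }

  report <- purrr::map_dfr(intersect(classifiers, names(oof)), function(cl) {
    sc <- oof[[cl]]
    truth <- oof$truth
    cut <- optimal_cutoff(sc[truth], sc[!truth])
    pred <- sc >= cut
    m <- metrics_from_counts(tp = sum(pred & truth), fn = sum(!pred & truth),
                             tn = sum(!pred & !truth), fp = sum(pred & !truth))
    dplyr::bind_cols(tibble(classifier = cl), m,
                     tibble(auc = auc_score(sc, truth), cutoff = cut,
                            n_folds_used = used_folds))
  })
  attr(report, "scores") <- oof
  class(report) <- c("eval_report", class(report))
  report
}

#' Two-round classification: true-lesion detection, then BI-RADS call
#'
#' Round 1 separates candidate regions into normal tissue versus true
#' microcalcifications; round 2 classifies true microcalcifications as
#' benign versus suspicious. By default round 2 is evaluated on the
#' ground-truth true lesions (`round2_input = "truth"`); with
#' `"round1"` it instead consumes only the candidates that round 1
#' called positive, chaining the stages as deployed.
#'
#' @param features Tibble with `patient_id`, logical `is_true_mc`,
#'   `label` (`benign` / `suspicious`, `NA` for non-lesions), and
#'   feature columns.
#' @param cv A [build_cv()] plan (built on all patients; each round
#'   restricts it to its own rows).
#' @param round2_input `"truth"` or `"round1"`.
#' @param ... Passed to [train_eval()].
#' @return List with elements `round1` and `round2` (both
#'   `eval_report`s; `round2` is `NULL` if too few lesions remain).
#' @export
classify_two_round <- function(features, cv, round2_input = c("truth", "round1"),
                               ...) {
  round2_input <- match.arg(round2_input)
  f1 <- features
  f1$label <- ifelse(f1$is_true_mc, "true_mc", "tissue")
  r1 <- train_eval(f1, cv, positive = "true_mc", ...)

  if (round2_input == "truth") {
    f2 <- features[features$is_true_mc & !is.na(features$label), ]
  } else {
    sc <- attr(r1, "scores")
    vote_col <- intersect(c("ensemble_voting", rev(names(sc))), names(sc))[1]
    cut <- r1$cutoff[r1$classifier == vote_col][1]
    keep_rows <- sc$row[sc[[vote_col]] >= cut]
    f2 <- features[keep_rows, ]
    f2 <- f2[!is.na(f2$label), ]
  }
  r2 <- NULL
  if (nrow(f2) >= 4 && length(unique(f2$label)) == 2 &&
      length(unique(f2$patient_id)) >= 2) {
    r2 <- train_eval(f2, cv, positive = "suspicious", ...)
  }
  list(round1 = r1, round2 = r2)
}
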