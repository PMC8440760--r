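#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @describeIn train_eval `tidy()` returns the per-classifier metric
#'   table as a plain tibble.
#' @param x An `eval_report`.
#' @param ... Unused.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) {
  out <- x
  attr(out, "scores") <- NULL
  class(out) <- class(tibble())
  out
}

#' @describeIn train_eval `glance()` returns the single best classifier
#'   row (highest AUC, accuracy as tie-break).
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tb <- tidy(x)
  tb[order(-tb$auc, -tb$accuracy), ][1, ]
}

#' @describeIn select_features `tidy()` returns the per-feature report
#'   sorted by p-value.
#' @param x A `selection_report`.
#' @param ... Unused.
#' @method tidy selection_report
#' @export
tidy.selection_report <- function(x, ...) {
  out <- x
  class(out) <- class(tibble())
  out[order(out$p_value), ]
}

#' @describeIn subtract `tidy()` returns the scalar summaries as a
#'   one-row tibble.
#' @param x A `subtraction_result`.
#' @param ... Unused.
#' @method tidy subtraction_result
#' @export
tidy.subtraction_result <- function(x, ...) {
  tibble(contrast_ratio_recent = x$contrast_ratio_recent,
         contrast_ratio_diff = x$contrast_ratio_diff,
         contrast_gain = x$contrast_ratio_diff / x$contrast_ratio_recent,
         intensity_reduction_pct = x$intensity_reduction_pct)
}

#' @describeIn removal_stats `tidy()` returns counts and percentages as
#'   a one-row tibble.
#' @param x A `removal_stats`.
#' @param ... Unused.
#' @method tidy removal_stats
#' @export
tidy.removal_stats <- function(x, ...) {
  tibble(n_recent_mcs = x$n_recent_mcs, n_prior_mcs = x$n_prior_mcs,
         n_overlapping = x$n_overlapping, overlap_pct = x$overlap_pct,
         reduction_pct = x$reduction_pct, n_new_removed = x$n_new_removed)
}

#' @describeIn match_candidates `tidy()` returns the matched pairs with
#'   counts attached.
#' @param x A `match_result`.
#' @param ... Unused.
#' @method tidy match_result
#' @export
tidy.match_result <- function(x, ...) {
  tibble(tp = x$tp, fp = x$fp, fn = x$fn)
}
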