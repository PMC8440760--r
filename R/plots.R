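raster_df <- function(px, panel) {
  tibble(row = rep(seq_len(nrow(px)), times = ncol(px)),
         col = rep(seq_len(ncol(px)), each = nrow(px)),
         value = as.vector(px), panel = panel)
}

#' Plot a phantom pair and its difference image
#'
#' Side-by-side rasters of the recent round, the prior round, and
#' (optionally) a difference image, with the ground-truth
#' microcalcification centres overlaid on the recent panel.
#'
#' @param object A `phantom_pair`.
#' @param diff Optional difference matrix (e.g. from [subtract()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phantom_pair <- function(object, diff = NULL, ...) {
  df <- dplyr::bind_rows(
    raster_df(object$recent$pixels, "recent"),
    raster_df(object$prior$pixels, "prior"),
    if (!is.null(diff)) raster_df(as_pixels(diff), "difference"))
  df$panel <- factor(df$panel, levels = c("recent", "prior", "difference"))
  pts <- object$truth
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_point(data = tibble(col = pts$x + 1, row = pts$y + 1,
                                      status = pts$status, panel = factor("recent")),
                        ggplot2::aes(colour = .data$status), shape = 1, size = 3) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~panel, nrow = 1) +
    ggplot2::coord_fixed() +
    ggplot2::labs(colour = "finding", fill = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot per-classifier evaluation metrics
#'
#' Dot plot of sensitivity, specificity, accuracy, and (scaled) AUC per
#' classifier, ordered by AUC.
#'
#' @param object An `eval_report` from [train_eval()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  tb <- tidy(object)
  long <- tidyr::pivot_longer(
    dplyr::mutate(tb, auc_pct = 100 * .data$auc),
    c("sensitivity", "specificity", "accuracy", "auc_pct"),
    names_to = "metric", values_to = "value")
  long$classifier <- factor(long$classifier,
                            levels = tb$classifier[order(tb$auc)])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$classifier,
                                     colour = .data$metric)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = "percent", y = NULL) +
    ggplot2::theme_minimal()
}

#' ROC curves from pooled out-of-fold scores
#'
#' @param report An `eval_report` from [train_eval()].
#' @param classifiers Which classifiers to draw (default: all present).
#' @return A ggplot object.
#' @export
plot_roc <- function(report, classifiers = NULL) {
  sc <- attr(report, "scores")
  if (is.null(sc)) abort("This report carries no pooled scores.")
  cls <- classifiers %||% setdiff(names(sc), c("fold", "row", "truth"))
  df <- purrr::map_dfr(cls, function(cl) {
    ts <- sort(unique(sc[[cl]]), decreasing = TRUE)
    purrr::map_dfr(c(Inf, ts), function(t) {
      tibble(classifier = cl,
             fpr = mean(sc[[cl]][!sc$truth] >= t),
             tpr = mean(sc[[cl]][sc$truth] >= t))
    })
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr,
                                   colour = .data$classifier)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dotted") +
    ggplot2::labs(x = "false-positive rate", y = "sensitivity") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
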