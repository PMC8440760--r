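#' Temporal subtraction of a registered pair
#'
#' Subtracts the warped prior view from the recent view inside the
#' breast mask, clipping negative differences to zero (new findings are
#' brighter than their background; darkening is not a detection signal).
#' Reports the contrast ratio — maximum divided by mean intensity over
#' the mask — of both the recent image and the difference image, and
#' the percentage reduction of mean intensity achieved by subtraction.
#'
#' @param recent Preprocessed recent image ([mammo_image()] or matrix).
#' @param prior_warped Prior image registered into the recent frame.
#' @param mask A [breast_mask()] (or logical matrix) confining the
#'   statistics to tissue.
#' @return An object of class `subtraction_result` with fields `diff`
#'   (matrix, >= 0, zero outside the mask), `contrast_ratio_recent`,
#'   `contrast_ratio_diff`, and `intensity_reduction_pct`. A contrast
#'   ratio is `NA` when the corresponding image is identically zero over
#'   the mask.
#' @export
subtract <- function(recent, prior_warped, mask) {
  r <- as_pixels(recent); p <- as_pixels(prior_warped)
  m <- if (inherits(mask, "breast_mask")) mask$mask else
    matrix(as.logical(mask), nrow(r), ncol(r))
  if (!identical(dim(r), dim(p)) || !identical(dim(r), dim(m))) {
    abort("`recent`, `prior_warped`, and `mask` must be congruent.")
  }
  if (!any(m)) abort("Cannot subtract over an empty mask.")
  d <- pmax(r - p, 0)
  d[!m] <- 0
  cr <- function(x) {
    mu <- mean(x[m])
    if (mu <= 0) NA_real_ else max(x[m]) / mu
  }
  mean_recent <- mean(r[m])
  red <- if (mean_recent > 0) 100 * (1 - mean(d[m]) / mean_recent) else NA_real_
  structure(list(diff = d,
                 contrast_ratio_recent = cr(r),
                 contrast_ratio_diff = cr(d),
                 intensity_reduction_pct = red),
            class = "subtraction_result")
}

#' @export
print.subtraction_result <- function(x, ...) {
  cat(sprintf("<subtraction_result> CR recent %.2f -> diff %.2f (gain %.1fx), intensity reduction %.1f%%\n",
              x$contrast_ratio_recent, x$contrast_ratio_diff,
              x$contrast_ratio_diff / x$contrast_ratio_recent,
              x$intensity_reduction_pct))
  invisible(x)
}

#' Overlap percentages from removal counts
#'
#' Given the number of microcalcifications in the recent round, in the
#' prior round, and the number of unchanged ("overlapping") ones
#' eliminated by subtraction, computes the elimination percentages:
#' overlap relative to the prior count and reduction relative to the
#' recent count.
#'
#' @param n_recent_mcs,n_prior_mcs,n_overlapping Non-negative counts;
#'   `n_overlapping <= min(n_recent_mcs, n_prior_mcs)`.
#' @return An object of class `removal_stats`.
#' @export
#' @examples
#' removal_summary(646, 543, 118)  # 21.7% overlap, 18.3% reduction
removal_summary <- function(n_recent_mcs, n_prior_mcs, n_overlapping) {
  if (any(c(n_recent_mcs, n_prior_mcs, n_overlapping) < 0)) {
    abort("Counts must be non-negative.")
  }
  if (n_overlapping > min(n_recent_mcs, n_prior_mcs)) {
    abort("`n_overlapping` cannot exceed either round's count.")
  }
  structure(list(
    n_recent_mcs = n_recent_mcs, n_prior_mcs = n_prior_mcs,
    n_overlapping = n_overlapping,
    overlap_pct = if (n_prior_mcs > 0) 100 * n_overlapping / n_prior_mcs else NA_real_,
    reduction_pct = if (n_recent_mcs > 0) 100 * n_overlapping / n_recent_mcs else NA_real_,
    n_new_removed = NA_integer_
  ), class = "removal_stats")
}

#' @export
print.removal_stats <- function(x, ...) {
  cat(sprintf("<removal_stats> recent %d, prior %d, removed %d (overlap %.1f%%, reduction %.1f%%)\n",
              x$n_recent_mcs, x$n_prior_mcs, x$n_overlapping,
              x$overlap_pct, x$reduction_pct))
  if (!is.na(x$n_new_removed)) {
    cat(sprintf("  new findings counted as removed: %d\n", x$n_new_removed))
  }
  invisible(x)
}

#' Elimination accounting for unchanged microcalcifications
#'
#' Scores how many "old" (present in both rounds) microcalcifications
#' were eliminated by the subtraction: an old finding counts as removed
#' when its residual peak in the difference image, within a small window
#' around its centre, falls below `residual_frac_threshold` times its
#' peak in the recent image. New findings are scored with the same rule
#' to verify they are NOT removed.
#'
#' @param diff Difference image (matrix or `subtraction_result`).
#' @param recent Preprocessed recent image.
#' @param truth Annotation tibble with 0-based `x`, `y` columns and a
#'   `status` column (`old` / `new`), as produced by the phantom
#'   generator.
#' @param residual_frac_threshold Removal threshold on the residual
#'   fraction.
#' @param window_px Half-width of the inspection window, in pixels.
#' @return A `removal_stats` object; `n_new_removed` counts new findings
#'   (wrongly) scored as removed. With empty truth all counts are 0 and
#'   percentages are `NA`.
#' @export
removal_stats <- function(diff, recent, truth, residual_frac_threshold = 0.5,
                          window_px = 5) {
  d <- if (inherits(diff, "subtraction_result")) diff$diff else as_pixels(diff)
  r <- as_pixels(recent)
  if (nrow(truth) == 0) {
    out <- removal_summary(0, 0, 0)
    out$n_new_removed <- 0L
    return(out)
  }
  H <- nrow(d); W <- ncol(d)
  peak <- function(img, row, col) {
    r0 <- max(1, row - window_px); r1 <- min(H, row + window_px)
    c0 <- max(1, col - window_px); c1 <- min(W, col + window_px)
    max(img[r0:r1, c0:c1])
  }
  removed <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    row <- round(truth$y[i]) + 1L; col <- round(truth$x[i]) + 1L
    pk_recent <- peak(r, row, col)
    pk_diff <- peak(d, row, col)
    removed[i] <- pk_recent > 0 && pk_diff < residual_frac_threshold * pk_recent
  }
  is_old <- truth$status == "old"
  out <- removal_summary(
    n_recent_mcs = nrow(truth),
    n_prior_mcs = sum(is_old),
    n_overlapping = sum(removed & is_old)
  )
  out$n_new_removed <- sum(removed & !is_old)
  out
}
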