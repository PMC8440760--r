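pad_replicate <- function(px, k) {
  H <- nrow(px); W <- ncol(px)
  ri <- c(rep(1L, k), seq_len(H), rep(H, k))
  ci <- c(rep(1L, k), seq_len(W), rep(W, k))
  px[ri, ci, drop = FALSE]
}

#' Local range filter
#'
#' Replaces every pixel by the local intensity range (maximum minus
#' minimum) over a `window x window` neighbourhood, with replicated
#' borders. Small bright specks on smooth backgrounds produce strong
#' responses, making this the first stage of candidate segmentation.
#'
#' @param img Image ([mammo_image()] or matrix).
#' @param window Odd window size >= 3.
#' @return Same type as `img`, containing the local range.
#' @export
range_filter <- function(img, window = 3) {
  if (window %% 2 != 1 || window < 3) abort("`window` must be an odd integer >= 3.")
  px <- as_pixels(img)
  k <- (window - 1L) / 2L
  pp <- pad_replicate(px, k)
  br <- EBImage::makeBrush(window, shape = "box")
  hi <- EBImage::dilate(pp, br)
  lo <- EBImage::erode(pp, br)
  H <- nrow(px); W <- ncol(px)
  out <- (hi - lo)[(k + 1):(k + H), (k + 1):(k + W), drop = FALSE]
  rewrap(out, img)
}

#' Binarise an image at an intensity threshold
#'
#' @param img Unit-interval image.
#' @param threshold Threshold in (0, 1); pixels `>= threshold` map to
#'   `TRUE`.
#' @return Logical matrix.
#' @export
binarise <- function(img, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1) {
    abort("`threshold` must be a scalar in (0, 1).")
  }
  as_pixels(img) >= threshold
}

#' Morphological cleaning into candidate regions
#'
#' Bridges small gaps by morphological closing with a disc, removes
#' connected components smaller than `min_area`, and labels the
#' remaining 8-connected components as candidate microcalcification
#' regions.
#'
#' @param binary Logical matrix from [binarise()].
#' @param min_area Minimum component area in pixels.
#' @param gap_close_radius Disc radius (pixels) for the gap-bridging
#'   closing; 0 disables it.
#' @param source Provenance tag stored on each candidate
#'   (`"subtracted"` or `"recent_only"`).
#' @param patient_id,view Metadata copied onto each candidate.
#' @return A tibble of candidate regions: `candidate_id`, 1-based
#'   bounding box (`row0`, `col0`, `row1`, `col1`, inclusive),
#'   `centroid_row`, `centroid_col`, `area_px`, `mask` (list-column of
#'   logical matrices over the bounding box), `source`, `patient_id`,
#'   `view`.
#' @export
morph_clean <- function(binary, min_area = 4, gap_close_radius = 1,
                        source = "subtracted", patient_id = NA_character_,
                        view = NA_character_) {
  b <- matrix(as.numeric(binary), nrow(binary), ncol(binary))
  if (gap_close_radius > 0) {
    b <- EBImage::closing(b, disc_brush(gap_close_radius))
  }
  lab <- label8(b > 0)
  st <- label_stats(lab)
  st <- st[st$area >= min_area, , drop = FALSE]
  if (nrow(st) == 0) {
    return(tibble(candidate_id = integer(), row0 = integer(), col0 = integer(),
                  row1 = integer(), col1 = integer(),
                  centroid_row = numeric(), centroid_col = numeric(),
                  area_px = integer(), mask = list(),
                  source = character(), patient_id = character(),
                  view = character()))
  }
  masks <- purrr::map(seq_len(nrow(st)), function(i) {
    lab[st$row0[i]:st$row1[i], st$col0[i]:st$col1[i], drop = FALSE] == st$label[i]
  })
  tibble(candidate_id = seq_len(nrow(st)),
         row0 = st$row0, col0 = st$col0, row1 = st$row1, col1 = st$col1,
         centroid_row = st$centroid_row, centroid_col = st$centroid_col,
         area_px = as.integer(st$area), mask = masks,
         source = source, patient_id = patient_id, view = view)
}

#' Detect candidate microcalcification regions
#'
#' Full candidate segmentation chain: local range filtering,
#' thresholding, morphological cleaning, connected-component labelling.
#' When a breast mask is given, responses outside it are suppressed.
#'
#' @param img Difference image (subtracted arm) or preprocessed recent
#'   image (recent-only arm).
#' @param mask Optional [breast_mask()] or logical matrix.
#' @param threshold Binarisation threshold in (0, 1).
#' @param window Range-filter window.
#' @inheritParams morph_clean
#' @return Candidate tibble as in [morph_clean()].
#' @export
detect_candidates <- function(img, mask = NULL, threshold = 0.2, window = 3,
                              min_area = 4, gap_close_radius = 1,
                              source = "subtracted",
                              patient_id = NA_character_,
                              view = NA_character_) {
  rf <- as_pixels(range_filter(img, window))
  if (!is.null(mask)) {
    m <- if (inherits(mask, "breast_mask")) mask$mask else mask
    rf[!m] <- 0
  }
  bin <- rf >= threshold
  morph_clean(bin, min_area = min_area, gap_close_radius = gap_close_radius,
              source = source, patient_id = patient_id, view = view)
}

#' Match candidates to point annotations
#'
#' Greedy nearest-first one-to-one matching: a (candidate, annotation)
#' pair is eligible when the annotation point falls inside the
#' candidate's mask (distance scored as 0) or within `tol_px` of its
#' centroid; eligible pairs are accepted in order of increasing
#' distance, each candidate and each annotation at most once.
#'
#' @param cands Candidate tibble from [detect_candidates()].
#' @param annotations Tibble with 0-based `x` (column) and `y` (row)
#'   point coordinates.
#' @param tol_px Centroid distance tolerance in pixels.
#' @return An object of class `match_result`: counts `tp`, `fp`, `fn`
#'   and a `pairs` tibble of (candidate index, annotation index).
#' @export
match_candidates <- function(cands, annotations, tol_px = 8) {
  nc <- nrow(cands); na <- nrow(annotations)
  elig <- list()
  if (nc > 0 && na > 0) {
    arow <- round(annotations$y) + 1L
    acol <- round(annotations$x) + 1L
    for (i in seq_len(nc)) {
      msk <- cands$mask[[i]]
      for (j in seq_len(na)) {
        inside <- arow[j] >= cands$row0[i] && arow[j] <= cands$row1[i] &&
          acol[j] >= cands$col0[i] && acol[j] <= cands$col1[i] &&
          msk[arow[j] - cands$row0[i] + 1L, acol[j] - cands$col0[i] + 1L]
        dist <- sqrt((cands$centroid_row[i] - arow[j])^2 +
                     (cands$centroid_col[i] - acol[j])^2)
        if (inside) {
          elig[[length(elig) + 1]] <- c(i, j, 0)
        } else if (dist <= tol_px) {
          elig[[length(elig) + 1]] <- c(i, j, dist)
        }
      }
    }
  }
  pairs <- tibble(candidate = integer(), annotation = integer())
  if (length(elig) > 0) {
    em <- do.call(rbind, elig)
    em <- em[order(em[, 3], em[, 1], em[, 2]), , drop = FALSE]
    used_c <- logical(nc); used_a <- logical(na)
    for (k in seq_len(nrow(em))) {
      i <- em[k, 1]; j <- em[k, 2]
      if (!used_c[i] && !used_a[j]) {
        used_c[i] <- TRUE; used_a[j] <- TRUE
        pairs <- dplyr::bind_rows(pairs, tibble(candidate = i, annotation = j))
      }
    }
  }
  tp <- nrow(pairs)
  structure(list(tp = tp, fp = nc - tp, fn = na - tp, pairs = pairs),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> tp=%d fp=%d fn=%d\n", x$tp, x$fp, x$fn))
  invisible(x)
}

#' Choose the binarisation threshold on a labelled development set
#'
#' Scans a finite threshold grid, running the full detect-and-match
#' path on every labelled image, and returns the grid value maximising
#' the pooled objective `tp - lambda * fp`. Ties are broken towards the
#' higher threshold (fewer, more confident candidates).
#'
#' @param labelled A list whose elements are lists with fields `img`,
#'   `annotations`, and optionally `mask`.
#' @param grid Numeric vector of candidate thresholds in (0, 1).
#' @param lambda False-positive penalty.
#' @param tol_px Matching tolerance passed to [match_candidates()].
#' @param ... Further arguments passed to [detect_candidates()].
#' @return The selected threshold (scalar).
#' @export
optimise_threshold <- function(labelled, grid, lambda = 1, tol_px = 8, ...) {
  if (length(grid) == 0) abort("Threshold grid must be non-empty.")
  scores <- vapply(grid, function(th) {
    sum(vapply(labelled, function(el) {
      cands <- detect_candidates(el$img, mask = el$mask, threshold = th, ...)
      mr <- match_candidates(cands, el$annotations, tol_px = tol_px)
      mr$tp - lambda * mr$fp
    }, numeric(1)))
  }, numeric(1))
  best <- max(scores)
  max(grid[scores == best])
}
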