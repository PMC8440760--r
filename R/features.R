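SHAPE_NAMES <- c("shape_area", "shape_perimeter", "shape_eccentricity",
                 "shape_solidity", "shape_extent", "shape_major_axis",
                 "shape_minor_axis", "shape_aspect_ratio",
                 "shape_equiv_diameter", "shape_circularity",
                 "shape_convex_area", "shape_orientation")
INTENSITY_NAMES <- c("int_mean", "int_sd", "int_min", "int_max", "int_median",
                     "int_skewness", "int_kurtosis", "int_energy",
                     "int_entropy", "int_range", "int_p10", "int_p90")

#' Canonical names of the 96 per-candidate features
#'
#' 12 shape descriptors, 12 first-order intensity statistics, and the
#' 72-value GLCM texture block, in the fixed order used throughout the
#' package (feature tables, cohorts, classifiers).
#'
#' @return Character vector of length 96.
#' @export
feature_names <- function() {
  glcm_names <- as.vector(vapply(GLCM_OFFSETS, function(off) {
    as.vector(rbind(sprintf("glcm_%s_off%d_mean", GLCM_PROPS, off),
                    sprintf("glcm_%s_off%d_sd", GLCM_PROPS, off)))
  }, character(24)))
  c(SHAPE_NAMES, INTENSITY_NAMES, glcm_names)
}

## Perimeter of a binary mask: length of the closed 8-connected boundary
## chain (unit steps for axial moves, sqrt(2) for diagonal). Falls back
## to the background-adjacency edge count for degenerate masks.
mask_perimeter <- function(mask) {
  padded <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
  padded[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- as.numeric(mask)
  oc <- tryCatch(EBImage::ocontour(padded), error = function(e) NULL)
  if (!is.null(oc) && length(oc) > 0 && nrow(oc[[1]]) > 1) {
    pts <- rbind(oc[[1]], oc[[1]][1, ])
    sum(sqrt(rowSums(diff(pts)^2)))
  } else {
    4  # single pixel
  }
}

## Convex hull area of mask pixel centres, counted in lattice points
## via Pick's theorem: points = A + B/2 + 1 with B the number of
## boundary lattice points (gcd per hull edge). For a convex mask this
## equals the mask's own pixel count, giving solidity exactly 1.
convex_hull_area <- function(rows, cols) {
  if (length(rows) < 3) return(length(rows))
  gcd2 <- function(a, b) mapply(function(x, y) {
    while (y != 0) { t <- y; y <- x %% y; x <- t }
    x
  }, a, b)
  h <- grDevices::chull(cols, rows)
  xs <- cols[h]; ys <- rows[h]
  x2 <- c(xs[-1], xs[1]); y2 <- c(ys[-1], ys[1])
  A <- abs(sum(xs * y2 - x2 * ys)) / 2
  B <- sum(gcd2(abs(x2 - xs), abs(y2 - ys)))
  A + B / 2 + 1
}

#' Shape descriptors of a candidate mask
#'
#' Region descriptors computed from the binary mask alone: area,
#' boundary perimeter, eccentricity and axis lengths from the second
#' central moments (with a 1/12 pixel-extent correction), solidity and
#' convex area from the convex hull, extent relative to the bounding
#' box, equivalent diameter, circularity `4*pi*A/P^2`, and orientation
#' of the major axis in radians.
#'
#' @param mask Logical matrix (the candidate's bounding-box mask).
#' @return Named numeric vector of length 12.
#' @export
shape_features <- function(mask) {
  idx <- which(mask)
  area <- length(idx)
  rows <- ((idx - 1) %% nrow(mask)) + 1
  cols <- ((idx - 1) %/% nrow(mask)) + 1
  per <- mask_perimeter(mask)
  mu_r <- mean(rows); mu_c <- mean(cols)
  m20 <- mean((rows - mu_r)^2) + 1 / 12
  m02 <- mean((cols - mu_c)^2) + 1 / 12
  m11 <- mean((rows - mu_r) * (cols - mu_c))
  tr <- m20 + m02
  det_ <- m20 * m02 - m11^2
  disc <- sqrt(max(tr^2 / 4 - det_, 0))
  l1 <- tr / 2 + disc; l2 <- max(tr / 2 - disc, 0)
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  conv <- convex_hull_area(rows, cols)
  c(shape_area = area,
    shape_perimeter = per,
    shape_eccentricity = if (l1 > 0) sqrt(1 - l2 / l1) else 0,
    shape_solidity = min(area / conv, 1),
    shape_extent = area / (diff(range(rows)) + 1) / (diff(range(cols)) + 1),
    shape_major_axis = major,
    shape_minor_axis = minor,
    shape_aspect_ratio = if (minor > 0) major / minor else 1,
    shape_equiv_diameter = sqrt(4 * area / pi),
    shape_circularity = 4 * pi * area / per^2,
    shape_convex_area = conv,
    shape_orientation = 0.5 * atan2(2 * m11, m20 - m02))
}

#' First-order intensity statistics
#'
#' Distributional statistics of the pixel values under the candidate
#' mask: mean, standard deviation, extremes, median, skewness and
#' excess kurtosis (0 for zero-variance samples), mean energy
#' (mean squared intensity), Shannon entropy of a 32-bin histogram on
#' \[0, 1\], range, and the 10th / 90th percentiles.
#'
#' @param vals Numeric vector of unit-interval intensities.
#' @return Named numeric vector of length 12.
#' @export
intensity_features <- function(vals) {
  s <- sd(vals)
  h <- tabulate(pmin(floor(pmin(pmax(vals, 0), 1) * 32) + 1, 32), nbins = 32)
  p <- h / sum(h); p <- p[p > 0]
  c(int_mean = mean(vals),
    int_sd = s,
    int_min = min(vals),
    int_max = max(vals),
    int_median = median(vals),
    int_skewness = if (s > 0) e1071::skewness(vals) else 0,
    int_kurtosis = if (s > 0) e1071::kurtosis(vals) else 0,
    int_energy = mean(vals^2),
    int_entropy = -sum(p * log2(p)),
    int_range = diff(range(vals)),
    int_p10 = unname(quantile(vals, 0.10)),
    int_p90 = unname(quantile(vals, 0.90)))
}

#' Extract the 96 features of one candidate region
#'
#' Computes 12 shape descriptors from the candidate mask, 12 first-order
#' intensity statistics from the image values under the mask, and the
#' 72-value GLCM texture block from the bounding-box patch dilated by
#' `pad` pixels. Patches smaller than `min_patch` in either dimension
#' are zero-padded (bottom/right) so that all co-occurrence offsets are
#' computable.
#'
#' @param candidate One-row slice of a candidate tibble from
#'   [detect_candidates()].
#' @param img The image the candidate was detected in ([mammo_image()]
#'   or matrix, unit interval).
#' @param pad Bounding-box dilation in pixels before patch extraction.
#' @param min_patch Minimum patch side length for the GLCM block.
#' @param glcm_levels Grey levels for GLCM quantisation.
#' @return Named numeric vector of length 96 in [feature_names()]
#'   order.
#' @export
extract_features <- function(candidate, img, pad = 2, min_patch = 32,
                             glcm_levels = 32) {
  px <- as_pixels(img)
  mask <- candidate$mask[[1]]
  if (sum(mask) < 2) {
    abort(sprintf("Candidate %s has a degenerate mask (area %d < 2).",
                  candidate$candidate_id[1], sum(mask)))
  }
  r0 <- max(1, candidate$row0[1] - pad); r1 <- min(nrow(px), candidate$row1[1] + pad)
  c0 <- max(1, candidate$col0[1] - pad); c1 <- min(ncol(px), candidate$col1[1] + pad)
  patch <- px[r0:r1, c0:c1, drop = FALSE]
  if (nrow(patch) < min_patch || ncol(patch) < min_patch) {
    padded <- matrix(0, max(nrow(patch), min_patch), max(ncol(patch), min_patch))
    padded[seq_len(nrow(patch)), seq_len(ncol(patch))] <- patch
    patch <- padded
  }
  mrows <- candidate$row0[1]:candidate$row1[1]
  mcols <- candidate$col0[1]:candidate$col1[1]
  vals <- px[mrows, mcols, drop = FALSE][mask]
  out <- c(shape_features(mask), intensity_features(vals),
           glcm_feature_block(patch, levels = glcm_levels))
  stopifnot(identical(names(out), feature_names()))
  if (any(!is.finite(out))) {
    abort(sprintf("Non-finite feature value for candidate %s.",
                  candidate$candidate_id[1]))
  }
  out
}

#' Feature table for a set of candidates
#'
#' @param cands Candidate tibble from [detect_candidates()].
#' @param img The source image.
#' @param ... Passed to [extract_features()].
#' @return A tibble with `candidate_id`, `patient_id`, `view`, `source`
#'   and the 96 feature columns; one row per candidate.
#' @export
extract_features_table <- function(cands, img, ...) {
  if (nrow(cands) == 0) {
    empty <- matrix(numeric(0), 0, 96, dimnames = list(NULL, feature_names()))
    return(dplyr::bind_cols(
      tibble(candidate_id = integer(), patient_id = character(),
             view = character(), source = character()),
      as_tibble(empty)))
  }
  feats <- purrr::map(seq_len(nrow(cands)), function(i) {
    extract_features(cands[i, ], img, ...)
  })
  fm <- do.call(rbind, feats)
  dplyr::bind_cols(
    cands[, c("candidate_id", "patient_id", "view", "source")],
    as_tibble(fm))
}

#' Univariate screening plus importance-ranked feature selection
#'
#' Two-stage selection mirroring a hypothesis-test-then-importance
#' workflow: every feature is screened with a two-sample
#' unequal-variance t-test; survivors (`p < p_cut`) are ranked by
#' permutation importance from a random-forest surrogate, and the
#' `top_k` best become the selected set. If no feature survives the
#' screen, all features enter the ranking stage so the selected set is
#' never empty.
#'
#' @param features Tibble or matrix whose columns are features (any
#'   non-numeric columns are dropped).
#' @param labels Two-level factor or character vector, one per row.
#' @param p_cut Screening threshold on the t-test p-value.
#' @param top_k Maximum size of the selected set.
#' @param seed Seed for the forest surrogate.
#' @param num_trees Trees in the surrogate forest.
#' @return An object of class `selection_report`: a tibble with
#'   `feature`, `p_value`, `importance`, `selected`.
#' @export
select_features <- function(features, labels, p_cut = 0.05, top_k = 20,
                            seed = 1L, num_trees = 300) {
  X <- as.data.frame(features)
  X <- X[vapply(X, is.numeric, logical(1))]
  y <- factor(labels)
  if (nlevels(y) != 2) abort("`labels` must contain exactly two classes.")
  if (min(table(y)) < 2) abort("Need at least 2 samples per class.")
  pvals <- vapply(X, function(col) {
    tryCatch(t.test(col[y == levels(y)[1]], col[y == levels(y)[2]])$p.value,
             error = function(e) 1)
  }, numeric(1))
  survivors <- names(pvals)[pvals < p_cut]
  if (length(survivors) == 0) {
    warn("No feature passed the t-test screen; ranking all features by importance.")
    survivors <- names(pvals)
  }
  rf <- ranger::ranger(x = X[survivors], y = y, num.trees = num_trees,
                       importance = "permutation", seed = seed)
  imp <- rf$variable.importance
  ranked <- names(sort(imp, decreasing = TRUE))
  sel <- head(ranked, top_k)
  rep <- tibble(feature = names(pvals), p_value = unname(pvals),
                importance = unname(imp[names(pvals)]),
                selected = names(pvals) %in% sel)
  class(rep) <- c("selection_report", class(rep))
  rep
}
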