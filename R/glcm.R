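GLCM_PROPS <- c("contrast", "correlation", "energy", "homogeneity",
                "dissimilarity", "entropy", "maximum_probability",
                "sum_average", "sum_variance", "sum_entropy",
                "difference_variance", "difference_entropy")
GLCM_ANGLES <- c(0, 45, 90, 135)
GLCM_OFFSETS <- c(5, 15, 25)

## Displacement (drow, dcol) of the second pixel of a co-occurring pair,
## for angles measured counter-clockwise from the +column axis with image
## rows increasing downward.
glcm_displacement <- function(angle, offset) {
  switch(as.character(angle),
         "0" = c(0, offset),
         "45" = c(-offset, offset),
         "90" = c(-offset, 0),
         "135" = c(-offset, -offset),
         abort("`angle` must be one of 0, 45, 90, 135."))
}

#' Quantise a unit-interval patch to discrete grey levels
#'
#' @param patch Numeric matrix with values in \[0, 1\].
#' @param levels Number of grey levels.
#' @return Integer matrix with values in `0 .. levels - 1`.
#' @export
quantise_grey <- function(patch, levels = 32) {
  q <- floor(pmin(pmax(patch, 0), 1) * levels)
  q[q == levels] <- levels - 1L
  matrix(as.integer(q), nrow(patch), ncol(patch))
}

#' Grey-level co-occurrence matrix
#'
#' Counts ordered pairs of grey levels `(i, j)` co-occurring at the
#' displacement given by `angle` (0, 45, 90, or 135 degrees) and
#' `offset` pixels, over all pixel positions where both ends of the
#' displacement fall inside the patch. The matrix is NOT symmetrised;
#' with `normalise = TRUE` (the default) entries sum to 1.
#'
#' @param patch Numeric matrix; unit-interval values are quantised to
#'   `levels` grey levels unless `quantise = FALSE`, in which case the
#'   patch must already contain integers in `0 .. levels - 1`.
#' @param levels Number of grey levels.
#' @param angle Direction in degrees, one of 0, 45, 90, 135.
#' @param offset Pair distance in pixels; must be smaller than both
#'   patch dimensions.
#' @param quantise Whether to quantise the patch first.
#' @param normalise Whether to normalise counts to probabilities.
#' @return A `levels x levels` matrix.
#' @export
glcm <- function(patch, levels = 32, angle = 0, offset = 5,
                 quantise = TRUE, normalise = TRUE) {
  patch <- as.matrix(patch)
  if (offset < 1) abort("`offset` must be >= 1.")
  if (offset >= nrow(patch) || offset >= ncol(patch)) {
    abort(sprintf("`offset` (%d) must be smaller than both patch dimensions (%d x %d).",
                  offset, nrow(patch), ncol(patch)))
  }
  q <- if (quantise) quantise_grey(patch, levels) else {
    if (any(patch != round(patch)) || min(patch) < 0 || max(patch) > levels - 1) {
      abort("With `quantise = FALSE` the patch must hold integers in 0 .. levels-1.")
    }
    patch
  }
  d <- glcm_displacement(angle, offset)
  H <- nrow(q); W <- ncol(q)
  r_src <- seq_len(H); c_src <- seq_len(W)
  r_src <- r_src[r_src + d[1] >= 1 & r_src + d[1] <= H]
  c_src <- c_src[c_src + d[2] >= 1 & c_src + d[2] <= W]
  a <- q[r_src, c_src, drop = FALSE]
  b <- q[r_src + d[1], c_src + d[2], drop = FALSE]
  counts <- tabulate(as.vector(a) * levels + as.vector(b) + 1L,
                     nbins = levels * levels)
  P <- matrix(counts, levels, levels, byrow = TRUE)  # rows = first level i
  if (normalise && sum(P) > 0) P <- P / sum(P)
  P
}

#' Haralick-style texture properties of a co-occurrence matrix
#'
#' Computes 12 scalar texture properties from a normalised GLCM:
#' contrast, correlation, energy (angular second moment), homogeneity,
#' dissimilarity, entropy, maximum probability, sum average, sum
#' variance, sum entropy, difference variance, and difference entropy.
#' Level indices are 0-based; entropies use base-2 logarithms; the
#' correlation of a zero-variance (single-level) matrix is defined
#' as 1.
#'
#' @param P Normalised GLCM from [glcm()].
#' @return Named numeric vector of length 12.
#' @export
glcm_props <- function(P) {
  L <- nrow(P)
  if (sum(P) <= 0) return(setNames(rep(0, 12), GLCM_PROPS))
  P <- P / sum(P)
  i <- matrix(0:(L - 1), L, L)
  j <- matrix(0:(L - 1), L, L, byrow = TRUE)
  pxs <- rowSums(P); pys <- colSums(P)
  mux <- sum((0:(L - 1)) * pxs); muy <- sum((0:(L - 1)) * pys)
  sdx <- sqrt(sum(((0:(L - 1)) - mux)^2 * pxs))
  sdy <- sqrt(sum(((0:(L - 1)) - muy)^2 * pys))
  correlation <- if (sdx > 0 && sdy > 0) {
    sum((i - mux) * (j - muy) * P) / (sdx * sdy)
  } else 1
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  ## distributions of i+j (0 .. 2L-2) and |i-j| (0 .. L-1)
  psum <- vapply(0:(2 * L - 2), function(k) sum(P[i + j == k]), numeric(1))
  pdif <- vapply(0:(L - 1), function(k) sum(P[abs(i - j) == k]), numeric(1))
  sum_avg <- sum((0:(2 * L - 2)) * psum)
  dif_avg <- sum((0:(L - 1)) * pdif)
  c(contrast = sum((i - j)^2 * P),
    correlation = correlation,
    energy = sum(P^2),
    homogeneity = sum(P / (1 + (i - j)^2)),
    dissimilarity = sum(abs(i - j) * P),
    entropy = ent(P),
    maximum_probability = max(P),
    sum_average = sum_avg,
    sum_variance = sum(((0:(2 * L - 2)) - sum_avg)^2 * psum),
    sum_entropy = ent(psum),
    difference_variance = sum(((0:(L - 1)) - dif_avg)^2 * pdif),
    difference_entropy = ent(pdif))
}

#' The 72-value GLCM texture block
#'
#' Computes every texture property on the co-occurrence matrices of the
#' 4 angles x 3 offsets grid, then summarises each property as its mean
#' and standard deviation across the 4 angles, separately per offset:
#' 12 properties x 3 offsets x 2 statistics = 72 features.
#'
#' @param patch Unit-interval patch; must be at least
#'   `max(offsets) + 1` pixels in each dimension.
#' @param levels Grey levels for quantisation.
#' @param offsets Pixel offsets of the co-occurrence grid.
#' @return Named numeric vector of length 72, in canonical order.
#' @export
glcm_feature_block <- function(patch, levels = 32, offsets = GLCM_OFFSETS) {
  q <- quantise_grey(patch, levels)
  out <- numeric(0)
  for (off in offsets) {
    props <- vapply(GLCM_ANGLES, function(a) {
      glcm_props(glcm(q, levels = levels, angle = a, offset = off,
                      quantise = FALSE))
    }, numeric(12))
    mu <- rowMeans(props)
    sdv <- apply(props, 1, sd)
    v <- as.vector(rbind(mu, sdv))
    names(v) <- as.vector(rbind(
      sprintf("glcm_%s_off%d_mean", GLCM_PROPS, off),
      sprintf("glcm_%s_off%d_sd", GLCM_PROPS, off)))
    out <- c(out, v)
  }
  out
}
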