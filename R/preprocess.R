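#' Min-max intensity normalisation
#'
#' Rescales an image linearly so its minimum maps to 0 and its maximum
#' to 1. Constant images (zero dynamic range) map to all zeros. The
#' operation is idempotent on already-normalised images.
#'
#' @param img A [mammo_image()] or numeric matrix, 8-bit or real.
#' @return The same type of object with unit-interval pixels.
#' @export
normalise <- function(img) {
  px <- as_pixels(img)
  rng <- range(px)
  out <- if (rng[2] > rng[1]) (px - rng[1]) / (rng[2] - rng[1]) else px * 0
  rewrap(out, img)
}

#' Breast mask container
#'
#' @param mask Logical matrix marking breast tissue.
#' @return An object of class `breast_mask` with fields `mask` and
#'   `area_px`.
#' @export
breast_mask <- function(mask) {
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  area <- sum(mask)
  if (area == 0) abort("Breast mask is empty.")
  structure(list(mask = mask, area_px = area), class = "breast_mask")
}

#' @export
print.breast_mask <- function(x, ...) {
  cat(sprintf("<breast_mask> %d x %d, %d px (%.1f%%)\n",
              nrow(x$mask), ncol(x$mask), x$area_px,
              100 * x$area_px / length(x$mask)))
  invisible(x)
}

#' Segment the breast from the background
#'
#' Thresholds the normalised image at a small global level, clears a
#' fixed border margin (film edges, markers), morphologically closes the
#' result, and keeps the largest connected component. This removes
#' view labels and off-breast artifacts while retaining the breast as a
#' single region.
#'
#' @param img Normalised image ([mammo_image()] or matrix).
#' @param fg_threshold Global foreground threshold on the unit scale.
#' @param border_margin_px Border margin cleared before labelling.
#' @param close_radius Disc radius for morphological closing.
#' @return A [breast_mask()].
#' @export
segment_breast <- function(img, fg_threshold = 0.05, border_margin_px = 4,
                           close_radius = 5) {
  px <- as_pixels(img)
  H <- nrow(px); W <- ncol(px)
  fg <- px > fg_threshold
  m <- border_margin_px
  if (m > 0) {
    fg[seq_len(min(m, H)), ] <- FALSE
    fg[seq(max(1, H - m + 1), H), ] <- FALSE
    fg[, seq_len(min(m, W))] <- FALSE
    fg[, seq(max(1, W - m + 1), W)] <- FALSE
  }
  if (!any(fg)) abort("Breast segmentation failed: no foreground above threshold.")
  fgc <- EBImage::closing(matrix(as.numeric(fg), H, W), disc_brush(close_radius))
  lab <- label8(fgc > 0)
  if (max(lab) == 0) abort("Breast segmentation failed: no foreground after closing.")
  areas <- tabulate(lab[lab > 0])
  keep <- which.max(areas)
  breast_mask(lab == keep)
}

#' Gamma correction
#'
#' Pixelwise power-law mapping `out = in^gamma` on the unit interval;
#' `gamma > 1` darkens mid-tones and accentuates the brightest
#' structures (microcalcifications), `gamma < 1` lifts shadows.
#'
#' @param img Unit-interval image.
#' @param gamma Positive exponent.
#' @return The same type of object, still on \[0, 1\].
#' @export
gamma_correct <- function(img, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0) {
    abort("`gamma` must be a positive scalar.")
  }
  px <- as_pixels(img)
  rewrap(px^gamma, img)
}

#' Preprocess a temporal image pair
#'
#' Applies the standard preprocessing chain — normalisation, breast
#' segmentation, gamma correction — identically to both rounds so the
#' subtraction compares like with like. Pixels outside the breast mask
#' (taken from the recent view) are set to zero.
#'
#' @param recent,prior The two rounds ([mammo_image()] or matrix).
#' @param gamma Gamma-correction exponent applied to both.
#' @param fg_threshold,border_margin_px Passed to [segment_breast()].
#' @return A list with elements `recent`, `prior` (preprocessed, same
#'   type as the inputs) and `mask` (a [breast_mask()]).
#' @export
preprocess_pair <- function(recent, prior, gamma = 2,
                            fg_threshold = 0.05, border_margin_px = 4) {
  r <- normalise(recent)
  p <- normalise(prior)
  msk <- segment_breast(r, fg_threshold = fg_threshold,
                        border_margin_px = border_margin_px)
  r <- gamma_correct(r, gamma)
  p <- gamma_correct(p, gamma)
  rpx <- as_pixels(r) * msk$mask
  ppx <- as_pixels(p) * msk$mask
  list(recent = rewrap(rpx, recent), prior = rewrap(ppx, prior), mask = msk)
}
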