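#' Dense 2-D deformation field
#'
#' Per-pixel displacement `(dx, dy)` in pixels, defined on the fixed
#' (recent) image grid under the backward-warp convention: the warped
#' image samples the source at `(row + dy, col + dx)`.
#'
#' @param dx,dy Numeric matrices of column-wise and row-wise
#'   displacements, congruent with the image.
#' @param level_count Number of pyramid levels used to estimate the
#'   field (metadata).
#' @param final_metric Mean squared intensity difference after
#'   registration (metadata).
#' @param level_metrics Optional tibble of per-level initial/final
#'   metrics.
#' @return An object of class `deformation_field`.
#' @export
deformation_field <- function(dx, dy, level_count = NA_integer_,
                              final_metric = NA_real_,
                              level_metrics = NULL) {
  dx <- as.matrix(dx); dy <- as.matrix(dy)
  if (!identical(dim(dx), dim(dy))) abort("`dx` and `dy` must be congruent.")
  if (anyNA(dx) || anyNA(dy) || any(!is.finite(dx)) || any(!is.finite(dy))) {
    abort("Deformation field must be finite everywhere.")
  }
  structure(list(dx = dx, dy = dy, level_count = level_count,
                 final_metric = final_metric, level_metrics = level_metrics),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  mag <- sqrt(x$dx^2 + x$dy^2)
  cat(sprintf("<deformation_field> %d x %d  |u| mean %.3f max %.3f px  final MSD %.3g\n",
              nrow(x$dx), ncol(x$dx), mean(mag), max(mag), x$final_metric))
  invisible(x)
}

## Backward bilinear warp of a plain matrix; out-of-bounds samples are 0.
warp_bilinear <- function(img, dx, dy) {
  H <- nrow(img); W <- ncol(img)
  r <- matrix(seq_len(H), H, W)
  c <- matrix(seq_len(W), H, W, byrow = TRUE)
  sr <- r + dy; sc <- c + dx
  inb <- sr >= 1 & sr <= H & sc >= 1 & sc <= W
  sr <- pmin(pmax(sr, 1), H); sc <- pmin(pmax(sc, 1), W)
  r0 <- pmin(floor(sr), H - 1); c0 <- pmin(floor(sc), W - 1)
  fr <- sr - r0; fc <- sc - c0
  i00 <- r0 + (c0 - 1) * H
  v <- (1 - fr) * (1 - fc) * img[i00] + fr * (1 - fc) * img[i00 + 1] +
       (1 - fr) * fc * img[i00 + H] + fr * fc * img[i00 + H + 1]
  v[!inb] <- 0
  matrix(v, H, W)
}

## Central-difference gradient with one-sided borders.
grad2 <- function(img) {
  H <- nrow(img); W <- ncol(img)
  gy <- img; gx <- img
  gy[2:(H - 1), ] <- (img[3:H, ] - img[1:(H - 2), ]) / 2
  gy[1, ] <- img[2, ] - img[1, ]
  gy[H, ] <- img[H, ] - img[H - 1, ]
  gx[, 2:(W - 1)] <- (img[, 3:W] - img[, 1:(W - 2)]) / 2
  gx[, 1] <- img[, 2] - img[, 1]
  gx[, W] <- img[, W] - img[, W - 1]
  list(gx = gx, gy = gy)
}

smooth_or_id <- function(x, sigma) if (sigma > 0) EBImage::gblur(x, sigma) else x

## Quantile-based histogram matching of `moving` onto `fixed` over
## `region` (logical). Demons assumes intensity constancy; matching
## removes global brightness/contrast differences between rounds that
## would otherwise be converted into spurious displacement.
match_intensity_to <- function(moving, fixed, region = NULL) {
  if (is.null(region)) region <- moving > 0 | fixed > 0
  if (!any(region)) return(moving)
  v <- moving[region]
  q <- rank(v, ties.method = "average") / (length(v) + 1)
  moving[region] <- quantile(fixed[region], q, names = FALSE, type = 8)
  moving
}

#' Demons registration parameters
#'
#' @param field_sigma Gaussian smoothing (pixels) applied to the
#'   accumulated field every iteration (diffusion-like regularisation).
#' @param update_sigma Gaussian smoothing applied to each iteration's
#'   update (fluid-like regularisation).
#' @param levels Pyramid downsampling factors, coarse to fine.
#' @param iterations Iterations per pyramid level.
#' @param tol Early-stopping tolerance: stop a level when the relative
#'   metric improvement over 5 iterations falls below `tol`.
#' @return A named list of parameters.
#' @export
demons_params <- function(field_sigma = 1.5, update_sigma = 1.0,
                          levels = c(4, 2, 1), iterations = c(100, 60, 30),
                          tol = 1e-5) {
  stopifnot(length(levels) == length(iterations), all(levels >= 1))
  list(field_sigma = field_sigma, update_sigma = update_sigma,
       levels = levels, iterations = iterations, tol = tol)
}

demons_one_level <- function(fixed, moving, dx, dy, iters, params, mask = NULL) {
  g <- grad2(fixed)
  den0 <- g$gx^2 + g$gy^2
  m0 <- mean((warp_bilinear(moving, dx, dy) - fixed)^2)
  scale <- max(m0, 1e-12)
  best <- list(dx = dx, dy = dy, m = Inf)
  best_it <- 0L
  for (it in seq_len(iters)) {
    w <- warp_bilinear(moving, dx, dy)
    d <- w - fixed
    m <- mean(d^2)
    if (m < best$m) {
      # count as progress only if the improvement is material
      if (m < best$m - params$tol * scale) best_it <- it
      best <- list(dx = dx, dy = dy, m = m)
    }
    if (it - best_it >= 5L) break
    den <- den0 + d^2
    u <- ifelse(den > 1e-9, d / den, 0)
    ux <- smooth_or_id(-u * g$gx, params$update_sigma)
    uy <- smooth_or_id(-u * g$gy, params$update_sigma)
    if (!is.null(mask)) { ux <- ux * mask; uy <- uy * mask }
    dx <- smooth_or_id(dx + ux, params$field_sigma)
    dy <- smooth_or_id(dy + uy, params$field_sigma)
  }
  w <- warp_bilinear(moving, dx, dy)
  m <- mean((w - fixed)^2)
  if (m < best$m) best <- list(dx = dx, dy = dy, m = m)
  list(dx = best$dx, dy = best$dy, initial = m0, final = best$m)
}

#' Non-rigid Demons registration
#'
#' Registers the `moving` image (prior round) onto the `fixed` image
#' (recent round) with the classic intensity-driven Demons scheme: each
#' iteration moves every pixel along the fixed-image gradient by
#' `(m - f) * grad(f) / (|grad(f)|^2 + (m - f)^2)` (so single steps are
#' bounded by half a pixel), the update and the accumulated field are
#' Gaussian-smoothed, and the whole procedure runs coarse-to-fine over
#' an image pyramid. When a breast `mask` is supplied, updates outside
#' the (smoothed) mask are damped towards zero so the field is driven by
#' tissue only.
#'
#' @param fixed,moving Preprocessed unit-interval images
#'   ([mammo_image()] or matrix) of identical shape.
#' @param params A [demons_params()] list.
#' @param mask Optional logical matrix restricting the registration
#'   forces to the breast.
#' @param match_intensity Histogram-match the moving image onto the
#'   fixed one before iterating, so residual global brightness
#'   differences between rounds are not converted into displacement.
#' @return A [deformation_field()]; `final_metric` is the mean squared
#'   difference after warping and is never larger than the initial one,
#'   and `level_metrics` records the per-level metric decrease.
#' @export
demons_register <- function(fixed, moving, params = demons_params(),
                            mask = NULL, match_intensity = TRUE) {
  f <- as_pixels(fixed); m <- as_pixels(moving)
  if (!identical(dim(f), dim(m))) abort("`fixed` and `moving` must have identical shape.")
  if (anyNA(f) || anyNA(m) || any(!is.finite(f)) || any(!is.finite(m))) {
    abort("Images must be finite everywhere.")
  }
  if (match_intensity) {
    m <- match_intensity_to(m, f, region = if (!is.null(mask)) mask else NULL)
  }
  H <- nrow(f); W <- ncol(f)
  dx <- dy <- NULL
  h_prev <- NULL
  lm <- list()
  for (li in seq_along(params$levels)) {
    fac <- params$levels[li]
    h <- max(8L, round(H / fac)); w <- max(8L, round(W / fac))
    if (fac > 1) {
      ff <- EBImage::resize(EBImage::gblur(f, fac / 2), w = h, h = w)
      mm <- EBImage::resize(EBImage::gblur(m, fac / 2), w = h, h = w)
    } else {
      ff <- f; mm <- m
    }
    mk <- NULL
    if (!is.null(mask)) {
      mk <- EBImage::gblur(matrix(as.numeric(mask), H, W), 4)
      if (fac > 1) mk <- EBImage::resize(mk, w = h, h = w)
      mk <- pmin(pmax(mk, 0), 1)
    }
    if (is.null(dx)) {
      dx <- matrix(0, h, w); dy <- matrix(0, h, w)
    } else {
      sc <- h / h_prev
      dx <- EBImage::resize(dx, w = h, h = w) * sc
      dy <- EBImage::resize(dy, w = h, h = w) * sc
    }
    res <- demons_one_level(ff, mm, dx, dy, params$iterations[li], params, mk)
    dx <- res$dx; dy <- res$dy; h_prev <- h
    lm[[li]] <- tibble(level = fac, initial_msd = res$initial,
                       final_msd = res$final)
  }
  if (!identical(dim(dx), dim(f))) {
    sc <- nrow(f) / nrow(dx)
    dx <- EBImage::resize(dx, w = nrow(f), h = ncol(f)) * sc
    dy <- EBImage::resize(dy, w = nrow(f), h = ncol(f)) * sc
  }
  deformation_field(dx, dy, level_count = length(params$levels),
                    final_metric = lm[[length(lm)]]$final_msd,
                    level_metrics = dplyr::bind_rows(lm))
}

#' Warp an image by a deformation field
#'
#' Backward (pull) warping with bilinear interpolation; samples falling
#' outside the source image take the value 0.
#'
#' @param img Image ([mammo_image()] or matrix).
#' @param field A [deformation_field()] congruent with `img`.
#' @return Warped image of the same type as `img`.
#' @export
warp <- function(img, field) {
  px <- as_pixels(img)
  if (!identical(dim(px), dim(field$dx))) {
    abort("Image and deformation field must have identical shape.")
  }
  rewrap(warp_bilinear(px, field$dx, field$dy), img)
}

#' Mean endpoint error between two deformation fields
#'
#' @param field Estimated [deformation_field()].
#' @param reference Reference [deformation_field()] (e.g. a phantom's
#'   `true_field`).
#' @param mask Optional logical matrix restricting the average.
#' @return Mean Euclidean displacement error in pixels.
#' @export
mean_endpoint_error <- function(field, reference, mask = NULL) {
  e <- sqrt((field$dx - reference$dx)^2 + (field$dy - reference$dy)^2)
  if (is.null(mask)) mean(e) else mean(e[mask])
}
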