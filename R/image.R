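#' Mammographic image container
#'
#' A `mammo_image` wraps a 2-D grayscale pixel matrix together with the
#' patient / view / screening-round metadata needed to pair it with its
#' temporal counterpart and its annotations. Pixels are either 8-bit
#' integers in \[0, 255\] (as read from disk) or unit-interval reals
#' (after [normalise()]).
#'
#' @param pixels Numeric matrix (rows = image rows, columns = image
#'   columns), values in \[0, 255\] or \[0, 1\].
#' @param patient_id Character scalar identifying the patient.
#' @param view Mammographic projection, `"CC"` or `"MLO"`.
#' @param round Screening round, `"recent"` or `"prior"`.
#' @param pixel_spacing Optional pixel spacing in mm/pixel.
#'
#' @return An object of class `mammo_image`.
#' @export
#' @examples
#' img <- mammo_image(matrix(0L, 16, 16), patient_id = "P1")
#' dim(img$pixels)
mammo_image <- function(pixels, patient_id = NA_character_,
                        view = c("CC", "MLO"),
                        round = c("recent", "prior"),
                        pixel_spacing = NULL) {
  view <- match.arg(view)
  round <- match.arg(round)
  pixels <- as.matrix(pixels)
  if (length(dim(pixels)) != 2L || any(dim(pixels) < 1L)) {
    abort("`pixels` must be a 2-D matrix with positive extent in both dimensions.")
  }
  storage.mode(pixels) <- "double"
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    abort("`pixels` must be finite and non-missing everywhere.")
  }
  if (min(pixels) < 0 || max(pixels) > 255) {
    abort("`pixels` must lie in [0, 255] (8-bit) or [0, 1] (normalised).")
  }
  structure(
    list(pixels = pixels, patient_id = patient_id, view = view,
         round = round, pixel_spacing = pixel_spacing),
    class = "mammo_image"
  )
}

#' @export
print.mammo_image <- function(x, ...) {
  cat(sprintf("<mammo_image> %d x %d  patient=%s view=%s round=%s  range=[%.3g, %.3g]\n",
              nrow(x$pixels), ncol(x$pixels), x$patient_id, x$view, x$round,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.mammo_image <- function(x) dim(x$pixels)

## Accept either a mammo_image or a bare matrix everywhere in the pipeline.
as_pixels <- function(img) {
  if (inherits(img, "mammo_image")) img$pixels else as.matrix(img)
}

## Rebuild an object of the same flavour as `template` around new pixels.
rewrap <- function(pixels, template) {
  if (inherits(template, "mammo_image")) {
    out <- template
    out$pixels <- pixels
    out
  } else {
    pixels
  }
}
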