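#' Read a grayscale mammographic image
#'
#' Reads a single-frame grayscale image from PNG, TIFF, or single-frame
#' monochrome DICOM. Pixel values are returned untouched on the 8-bit
#' scale (integers in \[0, 255\] for 8-bit sources). Colour or
#' multi-frame inputs are rejected.
#'
#' @param path Path to the image file.
#' @param format Image format; `"auto"` infers it from the file
#'   extension.
#' @inheritParams mammo_image
#' @return A [mammo_image()].
#' @export
read_image <- function(path, format = c("auto", "png", "tiff", "dicom"),
                       patient_id = NA_character_, view = "CC",
                       round = "recent") {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("Image file does not exist: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      png = "png", tif = "tiff", tiff = "tiff", dcm = "dicom", dicom = "dicom",
      abort(sprintf("Cannot infer image format from extension '.%s'.", ext)))
  }
  spacing <- NULL
  px <- switch(format,
    png = {
      a <- png::readPNG(path)
      if (length(dim(a)) == 3L) {
        abort(sprintf("Expected a grayscale image but '%s' has %d channels.",
                      path, dim(a)[3]))
      }
      round(a * 255)
    },
    tiff = {
      a <- tiff::readTIFF(path, as.is = TRUE)
      if (is.list(a)) abort(sprintf("Multi-frame TIFF not supported: %s", path))
      if (length(dim(a)) == 3L) {
        abort(sprintf("Expected a grayscale image but '%s' has %d channels.",
                      path, dim(a)[3]))
      }
      a
    },
    dicom = {
      d <- read_dicom_minimal(path)
      spacing <- d$pixel_spacing
      d$pixels
    })
  mammo_image(px, patient_id = patient_id, view = view, round = round,
              pixel_spacing = spacing)
}

#' Write a grayscale image
#'
#' Writes a [mammo_image()] (or bare matrix) to PNG, TIFF, or a minimal
#' single-frame monochrome DICOM. 8-bit integer pixel values survive a
#' write/read round trip exactly; unit-interval images are quantised to
#' 8 bits on write.
#'
#' @param img A [mammo_image()] or numeric matrix.
#' @param path Output path.
#' @param format Output format; `"auto"` infers from extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, format = c("auto", "png", "tiff", "dicom")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      png = "png", tif = "tiff", tiff = "tiff", dcm = "dicom", dicom = "dicom",
      abort(sprintf("Cannot infer image format from extension '.%s'.", ext)))
  }
  px <- as_pixels(img)
  px8 <- if (max(px) <= 1 && any(px != round(px))) round(px * 255) else round(px)
  px8 <- pmin(pmax(px8, 0), 255)
  switch(format,
    png = png::writePNG(px8 / 255, target = path),
    tiff = tiff::writeTIFF(px8 / 255, where = path, bits.per.sample = 8L),
    dicom = write_dicom_minimal(px8, path,
      pixel_spacing = if (inherits(img, "mammo_image")) img$pixel_spacing else NULL))
  invisible(path)
}

#' Read per-microcalcification point annotations
#'
#' Annotations are CSV files with one row per marked microcalcification:
#' columns `patient_id`, `view`, `round`, `x` (0-based column index),
#' `y` (0-based row index), and `label` in `{benign, suspicious}`.
#' Phantom truth tables carry an additional `status` column
#' (`old` / `new`) which is kept when present.
#'
#' @param path Path to the annotation CSV.
#' @return A tibble with one row per annotation, in file order.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort(sprintf("Annotation file does not exist: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "view", "round", "x", "y", "label")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("Annotation file is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  bad <- which(!df$label %in% c("benign", "suspicious"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown annotation label(s) %s at row(s) %s; allowed: benign, suspicious.",
                  paste(unique(df$label[bad]), collapse = ", "),
                  paste(bad, collapse = ", ")))
  }
  as_tibble(df)
}

#' Write annotations to CSV
#'
#' @param annotations Tibble as returned by [read_annotations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations, path, row.names = FALSE)
  invisible(path)
}

#' Read a patient manifest
#'
#' The manifest is a YAML file with a top-level `records` list; each
#' record carries `patient_id`, `view`, `recent_path`, `prior_path`,
#' `annotation_path`, and `population` (`normal` / `suspicious`). Paths
#' are resolved relative to the manifest's directory. Each
#' `(patient_id, view)` pair may appear at most once and all referenced
#' files must exist.
#'
#' @param path Path to the manifest YAML file.
#' @return A tibble with one row per record, in file order.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("Manifest does not exist: %s", path))
  y <- yaml::read_yaml(path)
  if (is.null(y$records) || length(y$records) == 0) {
    abort("Manifest has no `records` entry.")
  }
  base <- dirname(normalizePath(path))
  recs <- purrr::map_dfr(y$records, function(r) {
    tibble(patient_id = as.character(r$patient_id),
           view = as.character(r$view),
           recent_path = file.path(base, r$recent_path),
           prior_path = file.path(base, r$prior_path),
           annotation_path = file.path(base, r$annotation_path),
           population = as.character(r$population))
  })
  if (anyDuplicated(recs[c("patient_id", "view")]) > 0) {
    abort("Manifest lists the same (patient_id, view) more than once.")
  }
  if (!all(recs$population %in% c("normal", "suspicious"))) {
    abort("Manifest `population` must be 'normal' or 'suspicious'.")
  }
  paths <- c(recs$recent_path, recs$prior_path, recs$annotation_path)
  gone <- paths[!file.exists(paths)]
  if (length(gone) > 0) {
    abort(sprintf("Manifest references missing file(s): %s",
                  paste(unique(gone), collapse = ", ")))
  }
  recs
}
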