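## Minimal single-frame monochrome DICOM support (explicit VR little
## endian, uncompressed). Only the handful of attributes the pipeline
## needs are interpreted: Rows, Columns, BitsAllocated, SamplesPerPixel,
## NumberOfFrames, PixelSpacing, PixelData. Everything else is skipped.
## No installed R package reads DICOM, so this is written in-package and
## kept deliberately narrow; compressed transfer syntaxes, sequences of
## undefined length, and colour images are rejected with clear errors.

EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"

read_u16 <- function(raw, off) {
  as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
}
read_u32 <- function(raw, off) {
  as.numeric(raw[off + 1]) + 256 * as.numeric(raw[off + 2]) +
    65536 * as.numeric(raw[off + 3]) + 16777216 * as.numeric(raw[off + 4])
}

read_dicom_minimal <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM") {
    abort(sprintf("Not a DICOM part-10 file (missing DICM marker): %s", path))
  }
  off <- 132L  # 0-based offset just past "DICM"
  n <- length(raw)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  fields <- list()
  transfer_syntax <- NULL
  while (off + 8 <= n) {
    group <- read_u16(raw, off); elem <- read_u16(raw, off + 2L)
    vr <- rawToChar(raw[(off + 5L):(off + 6L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      abort(sprintf("Implicit-VR or corrupted DICOM stream at offset %d in %s; only explicit VR little endian is supported.", off, path))
    }
    if (vr %in% long_vrs) {
      len <- read_u32(raw, off + 8L)
      body <- off + 12L
    } else {
      len <- read_u16(raw, off + 6L)
      body <- off + 8L
    }
    if (len == 4294967295) {
      abort(sprintf("Undefined-length element (%04x,%04x) in %s is not supported (compressed or sequence data).", group, elem, path))
    }
    key <- sprintf("%04x%04x", group, elem)
    if (key == "00020010") {
      v <- raw[(body + 1L):(body + len)]
      transfer_syntax <- trimws(rawToChar(v[v != as.raw(0)]))
    } else if (key %in% c("00280010", "00280011", "00280100", "00280002")) {
      fields[[key]] <- read_u16(raw, body)
    } else if (key %in% c("00280030", "00280008")) {
      fields[[key]] <- trimws(rawToChar(raw[(body + 1L):(body + len)]))
    } else if (key == "7fe00010") {
      fields[["pixeldata"]] <- raw[(body + 1L):(body + len)]
      off <- body + len
      break
    }
    off <- body + len
  }
  if (!is.null(transfer_syntax) && transfer_syntax != EXPLICIT_VR_LE) {
    abort(sprintf("Unsupported DICOM transfer syntax '%s' in %s (only explicit VR little endian).", transfer_syntax, path))
  }
  rows <- fields[["00280010"]]; cols <- fields[["00280011"]]
  bits <- fields[["00280100"]] %||% 8L
  spp <- fields[["00280002"]] %||% 1L
  nframes <- suppressWarnings(as.integer(fields[["00280008"]] %||% "1"))
  if (is.null(rows) || is.null(cols) || is.null(fields$pixeldata)) {
    abort(sprintf("DICOM file %s lacks Rows/Columns/PixelData.", path))
  }
  if (spp != 1L) abort(sprintf("DICOM %s has SamplesPerPixel=%d; only monochrome is supported.", path, spp))
  if (!is.na(nframes) && nframes > 1L) {
    abort(sprintf("DICOM %s has NumberOfFrames=%d; only single-frame images are supported.", path, nframes))
  }
  pd <- fields$pixeldata
  vals <- if (bits <= 8) {
    as.integer(pd[seq_len(rows * cols)])
  } else {
    readBin(pd, "integer", n = rows * cols, size = 2L, signed = FALSE,
            endian = "little")
  }
  pixels <- t(matrix(vals, nrow = cols, ncol = rows))  # stored row-major
  spacing <- NULL
  if (!is.null(fields[["00280030"]])) {
    spacing <- suppressWarnings(as.numeric(strsplit(fields[["00280030"]], "\\\\")[[1]][1]))
    if (is.na(spacing)) spacing <- NULL
  }
  list(pixels = pixels, pixel_spacing = spacing)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

u16_raw <- function(x) as.raw(c(x %% 256, x %/% 256))
u32_raw <- function(x) {
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

dcm_element <- function(group, elem, vr, value_raw) {
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  len <- length(value_raw)
  if (len %% 2 == 1) {
    pad <- if (vr %in% c("UI", "OB")) as.raw(0L) else charToRaw(" ")
    value_raw <- c(value_raw, pad); len <- len + 1
  }
  hdr <- c(u16_raw(group), u16_raw(elem), charToRaw(vr))
  if (vr %in% long_vrs) {
    c(hdr, as.raw(c(0, 0)), u32_raw(len), value_raw)
  } else {
    c(hdr, u16_raw(len), value_raw)
  }
}

write_dicom_minimal <- function(pixels8, path, pixel_spacing = NULL) {
  pixels8 <- round(pixels8)
  if (min(pixels8) < 0 || max(pixels8) > 255) {
    abort("Minimal DICOM writer only supports 8-bit pixel values.")
  }
  rows <- nrow(pixels8); cols <- ncol(pixels8)
  meta_body <- c(
    dcm_element(2L, 16L, "UI", charToRaw(EXPLICIT_VR_LE)),
    dcm_element(2L, 19L, "SH", charToRaw("tsmammo"))
  )
  meta <- c(dcm_element(2L, 0L, "UL", u32_raw(length(meta_body))), meta_body)
  pd <- as.raw(as.integer(t(pixels8)))  # row-major
  ds <- c(
    dcm_element(8L, 22L, "UI", charToRaw("1.2.840.10008.5.1.4.1.1.1.2")),
    dcm_element(40L, 2L, "US", u16_raw(1L)),               # SamplesPerPixel
    dcm_element(40L, 4L, "CS", charToRaw("MONOCHROME2")),
    dcm_element(40L, 16L, "US", u16_raw(rows)),
    dcm_element(40L, 17L, "US", u16_raw(cols)),
    if (!is.null(pixel_spacing)) {
      dcm_element(40L, 48L, "DS",
                  charToRaw(sprintf("%g\\%g", pixel_spacing, pixel_spacing)))
    },
    dcm_element(40L, 256L, "US", u16_raw(8L)),             # BitsAllocated
    dcm_element(40L, 257L, "US", u16_raw(8L)),             # BitsStored
    dcm_element(40L, 258L, "US", u16_raw(7L)),             # HighBit
    dcm_element(40L, 259L, "US", u16_raw(0L)),             # PixelRepresentation
    dcm_element(32736L, 16L, "OB", pd)
  )
  out <- c(raw(128), charToRaw("DICM"), meta, ds)
  writeBin(out, path)
  invisible(path)
}
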