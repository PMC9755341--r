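# Planar image and ROI-set I/O.
#
# Two image dialects are supported: a tab-delimited plain-text matrix (one
# row per line, no header, dot decimal separator, locale independent) with a
# JSON sidecar for metadata, and a minimal single-frame DICOM file
# (explicit VR little endian, 16-bit unsigned pixel data, acquisition phase
# stored in Series Description, subject id in Patient ID).

#' Planar count image
#'
#' @param counts Numeric matrix of nonnegative counts.
#' @param phase Acquisition phase, `"early"` or `"late"`.
#' @param subject Optional subject identifier (character).
#' @param pixel_spacing Optional pixel spacing in mm (length-2 numeric).
#' @return An object of class `planar_image`.
#' @export
planar_image <- function(counts, phase = c("early", "late"), subject = NULL,
                         pixel_spacing = NULL) {
  phase <- match.arg(phase)
  if (!is.matrix(counts) || !is.numeric(counts) || !length(counts)) {
    stop_mibg("mibg_format", "counts must be a non-empty numeric matrix")
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop_mibg("mibg_format", "counts must be nonnegative and finite")
  }
  structure(
    list(counts = counts, phase = phase,
         subject = if (is.null(subject)) NULL else as.character(subject),
         pixel_spacing = pixel_spacing),
    class = "planar_image"
  )
}

#' @export
print.planar_image <- function(x, ...) {
  cat(sprintf("<planar_image> %dx%d, phase=%s%s, total counts=%.0f\n",
              nrow(x$counts), ncol(x$counts), x$phase,
              if (is.null(x$subject)) "" else paste0(", subject=", x$subject),
              sum(x$counts)))
  invisible(x)
}

#' @export
dim.planar_image <- function(x) dim(x$counts)

#' Read a planar image
#'
#' @param path File path.
#' @param format `"text"` (tab-delimited matrix plus optional `.json`
#'   sidecar) or `"dicom"` (single-frame explicit-VR little-endian).
#' @param phase Override for the acquisition phase (required for text files
#'   without a sidecar).
#' @return A [planar_image()].
#' @export
read_planar <- function(path, format = c("text", "dicom"), phase = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_mibg("mibg_format", "file not found: %s", path)
  }
  if (format == "text") {
    read_planar_text(path, phase)
  } else {
    read_planar_dicom(path, phase)
  }
}

#' Write a planar image
#'
#' Lossless for integer counts in both dialects; the DICOM dialect stores
#' 16-bit unsigned integers and refuses counts outside `[0, 65535]`.
#'
#' @param image A [planar_image()].
#' @param path Output file path.
#' @param format `"text"` or `"dicom"`.
#' @return The path, invisibly.
#' @export
write_planar <- function(image, path, format = c("text", "dicom")) {
  stopifnot(inherits(image, "planar_image"))
  format <- match.arg(format)
  if (format == "text") {
    write_planar_text(image, path)
  } else {
    write_planar_dicom(image, path)
  }
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

read_planar_text <- function(path, phase = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1L) {
    stop_mibg("mibg_format", "ragged rows in text matrix %s", path)
  }
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals)) {
    stop_mibg("mibg_format", "non-numeric cell in text matrix %s", path)
  }
  if (any(vals < 0)) {
    stop_mibg("mibg_format", "negative count in text matrix %s", path)
  }
  m <- matrix(vals, nrow = length(rows), ncol = ncols, byrow = TRUE)
  meta <- list()
  sp <- sidecar_path(path)
  if (file.exists(sp)) meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  phase <- phase %||% meta$phase %||% "early"
  planar_image(m, phase = phase, subject = meta$subject,
               pixel_spacing = meta$pixel_spacing)
}

write_planar_text <- function(image, path) {
  m <- image$counts
  lines <- apply(m, 1L, function(r) {
    paste(format(r, trim = TRUE, scientific = FALSE, digits = 15),
          collapse = "\t")
  })
  writeLines(lines, path)
  meta <- list(phase = image$phase)
  if (!is.null(image$subject)) meta$subject <- image$subject
  if (!is.null(image$pixel_spacing)) meta$pixel_spacing <- image$pixel_spacing
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

# ---- minimal DICOM dialect -------------------------------------------------
# Single-frame secondary-capture-like object, explicit VR little endian.
# Only the tags the package needs are written; the reader is a generic
# explicit-VR walker that rejects other transfer syntaxes and multi-frame
# objects.

UID_EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"
UID_SC_STORAGE <- "1.2.840.10008.5.1.4.1.1.7"

dcm_pad <- function(s) {
  b <- charToRaw(s)
  if (length(b) %% 2L) b <- c(b, as.raw(0L)) # pad strings to even length
  b
}

dcm_element <- function(group, elem, vr, value_raw) {
  tag <- writeBin(c(as.integer(group), as.integer(elem)), raw(),
                  size = 2L, endian = "little")
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    len <- writeBin(length(value_raw), raw(), size = 4L, endian = "little")
    c(tag, charToRaw(vr), as.raw(c(0L, 0L)), len, value_raw)
  } else {
    len <- writeBin(length(value_raw), raw(), size = 2L, endian = "little")
    c(tag, charToRaw(vr), len, value_raw)
  }
}

dcm_us <- function(group, elem, value) {
  dcm_element(group, elem, "US",
              writeBin(as.integer(value), raw(), size = 2L, endian = "little"))
}

write_planar_dicom <- function(image, path) {
  m <- image$counts
  if (any(m != floor(m))) {
    stop_mibg("mibg_format", "DICOM dialect requires integer counts")
  }
  if (any(m > 65535)) {
    stop_mibg("mibg_range",
              "counts exceed the 16-bit range of the DICOM dialect (max %d)",
              max(m))
  }
  # deterministic instance UID derived from content
  uid <- sprintf("1.2.826.0.1.3680043.9.7433.%d.%d.%.0f",
                 nrow(m), ncol(m), sum(m) %% 1e8)

  meta <- c(
    dcm_element(2L, 2L, "UI", dcm_pad(UID_SC_STORAGE)),
    dcm_element(2L, 3L, "UI", dcm_pad(uid)),
    dcm_element(2L, 16L, "UI", dcm_pad(UID_EXPLICIT_VR_LE))
  )
  grouplen <- dcm_element(2L, 0L, "UL",
                          writeBin(length(meta), raw(), size = 4L,
                                   endian = "little"))

  # pixel data: DICOM is row-major (row by row); R matrices are col-major
  px <- as.integer(t(m))
  px[px > 32767L] <- px[px > 32767L] - 65536L # reinterpret as signed for writeBin
  pixraw <- writeBin(px, raw(), size = 2L, endian = "little")

  body <- c(
    dcm_element(8L, 0x16L, "UI", dcm_pad(UID_SC_STORAGE)),
    dcm_element(8L, 0x18L, "UI", dcm_pad(uid)),
    dcm_element(8L, 0x103EL, "LO", dcm_pad(image$phase)),
    dcm_element(16L, 0x20L, "LO",
                dcm_pad(image$subject %||% "anonymous")),
    dcm_us(0x28L, 0x02L, 1L),                       # SamplesPerPixel
    dcm_element(0x28L, 0x04L, "CS", dcm_pad("MONOCHROME2")),
    dcm_us(0x28L, 0x10L, nrow(m)),                  # Rows
    dcm_us(0x28L, 0x11L, ncol(m)),                  # Columns
    if (!is.null(image$pixel_spacing)) {
      dcm_element(0x28L, 0x30L, "DS",
                  dcm_pad(paste(format(image$pixel_spacing, digits = 10),
                                collapse = "\\")))
    },
    dcm_us(0x28L, 0x100L, 16L),                     # BitsAllocated
    dcm_us(0x28L, 0x101L, 16L),                     # BitsStored
    dcm_us(0x28L, 0x102L, 15L),                     # HighBit
    dcm_us(0x28L, 0x103L, 0L),                      # PixelRepresentation
    dcm_element(0x7FE0L, 0x10L, "OW", pixraw)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(grouplen, meta, body), con)
  invisible(path)
}

read_u16 <- function(raw2) {
  sum(as.integer(raw2) * c(1L, 256L))
}

read_u32 <- function(raw4) {
  sum(as.numeric(raw4) * c(1, 256, 65536, 16777216))
}

read_planar_dicom <- function(path, phase = NULL) {
  buf <- readBin(path, raw(), n = file.info(path)$size)
  if (length(buf) < 140L ||
      !identical(rawToChar(buf[129:132]), "DICM")) {
    stop_mibg("mibg_format", "%s is not a DICOM file", path)
  }
  pos <- 133L
  tags <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 8L <= length(buf) + 1L) {
    group <- read_u16(buf[pos:(pos + 1L)])
    elem <- read_u16(buf[(pos + 2L):(pos + 3L)])
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- read_u32(buf[(pos + 8L):(pos + 11L)])
      vstart <- pos + 12L
    } else {
      len <- read_u16(buf[(pos + 6L):(pos + 7L)])
      vstart <- pos + 8L
    }
    value <- if (len > 0) buf[vstart:(vstart + len - 1L)] else raw(0L)
    key <- sprintf("%04x,%04x", group, elem)
    tags[[key]] <- list(vr = vr, value = value)
    pos <- vstart + len
    if (group == 0x7FE0 && elem == 0x10) break
  }
  ts <- tags[["0002,0010"]]
  if (!is.null(ts) &&
      trimws(rawToChar(ts$value)) != UID_EXPLICIT_VR_LE) {
    stop_mibg("mibg_unsupported", "unsupported DICOM transfer syntax")
  }
  nf <- tags[["0028,0008"]]
  if (!is.null(nf) && as.integer(trimws(rawToChar(nf$value))) > 1L) {
    stop_mibg("mibg_unsupported", "multi-frame DICOM is not supported")
  }
  need <- c("0028,0010", "0028,0011", "7fe0,0010")
  if (!all(need %in% names(tags))) {
    stop_mibg("mibg_format", "missing required DICOM tags in %s", path)
  }
  nr <- read_u16(tags[["0028,0010"]]$value)
  nc <- read_u16(tags[["0028,0011"]]$value)
  pix <- tags[["7fe0,0010"]]$value
  if (length(pix) != 2L * nr * nc) {
    stop_mibg("mibg_format", "pixel data length mismatch in %s", path)
  }
  vals <- read_u16_vec(pix)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  sd_tag <- tags[["0008,103e"]]
  phase <- phase %||%
    (if (!is.null(sd_tag)) trimws(rawToChar(sd_tag$value)) else "early")
  if (!phase %in% c("early", "late")) phase <- "early"
  subj <- tags[["0010,0020"]]
  spacing <- tags[["0028,0030"]]
  planar_image(
    m, phase = phase,
    subject = if (!is.null(subj)) trimws(rawToChar(subj$value)) else NULL,
    pixel_spacing = if (!is.null(spacing)) {
      as.numeric(strsplit(trimws(rawToChar(spacing$value)), "\\",
                          fixed = TRUE)[[1L]])
    }
  )
}

read_u16_vec <- function(rawv) {
  ints <- readBin(rawv, integer(), n = length(rawv) %/% 2L, size = 2L,
                  endian = "little", signed = FALSE)
  as.numeric(ints)
}

# ---- ROI set JSON ----------------------------------------------------------

roi_to_list <- function(roi) {
  if (inherits(roi, "rect_roi")) {
    list(type = "rect", x0 = roi$x0, y0 = roi$y0, w = roi$w, h = roi$h)
  } else if (inherits(roi, "oval_roi")) {
    list(type = "oval", cx = roi$cx, cy = roi$cy, rx = roi$rx, ry = roi$ry)
  } else if (inherits(roi, "polygon_roi")) {
    list(type = "polygon", x = roi$x, y = roi$y)
  } else {
    stop_mibg("mibg_schema", "unknown ROI class: %s", class(roi)[1L])
  }
}

roi_from_list <- function(l) {
  if (is.null(l$type)) stop_mibg("mibg_schema", "ROI entry lacks a type tag")
  switch(
    as.character(l$type),
    rect = rect_roi(l$x0, l$y0, l$w, l$h),
    oval = oval_roi(l$cx, l$cy, l$rx, l$ry),
    polygon = polygon_roi(unlist(l$x), unlist(l$y)),
    stop_mibg("mibg_schema", "unknown ROI type tag: %s", l$type)
  )
}

#' Write an ROI set to JSON
#'
#' An ROI set pairs a cardiac and a mediastinal ROI with the placement
#' method and rater label that produced them.
#'
#' @param roiset List with elements `cardiac`, `mediastinal` (ROI objects),
#'   `method` and `rater`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_roiset <- function(roiset, path) {
  out <- list(
    method = roiset$method %||% NA_character_,
    rater = roiset$rater %||% NA_character_,
    cardiac = roi_to_list(roiset$cardiac),
    mediastinal = roi_to_list(roiset$mediastinal)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ROI set from JSON
#'
#' @param path File path.
#' @return List with elements `cardiac`, `mediastinal`, `method`, `rater`.
#' @export
read_roiset <- function(path) {
  if (!file.exists(path)) stop_mibg("mibg_schema", "file not found: %s", path)
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(l$cardiac) || is.null(l$mediastinal)) {
    stop_mibg("mibg_schema", "ROI set must contain cardiac and mediastinal entries")
  }
  list(
    cardiac = roi_from_list(l$cardiac),
    mediastinal = roi_from_list(l$mediastinal),
    method = l$method,
    rater = l$rater
  )
}
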