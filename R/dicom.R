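# Minimal multi-frame DICOM I/O (little-endian; explicit and implicit VR on
# read, explicit VR on write). Covers the attributes an echocardiography
# width pipeline needs: pixel geometry, photometric interpretation,
# PixelSpacing and the ultrasound-region calibration sequence. Not a general
# DICOM toolkit: no compressed transfer syntaxes, no big-endian.

u16le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32le <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
f64le <- function(x) writeBin(as.numeric(x), raw(), size = 8, endian = "little")

LONG_VRS <- c("OB", "OW", "OF", "OD", "SQ", "UT", "UN")

dcm_element <- function(group, elem, vr, value) {
  if (is.character(value)) {
    value <- charToRaw(paste(value, collapse = "\\"))
    if (length(value) %% 2L == 1L) {
      pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
      value <- c(value, pad)
    }
  }
  if (length(value) %% 2L == 1L) value <- c(value, as.raw(0L))
  hdr <- c(u16le(group), u16le(elem), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(hdr, as.raw(c(0L, 0L)), u32le(length(value)), value)
  } else {
    if (length(value) > 65535L) stop("value too long for short VR")
    c(hdr, u16le(length(value)), value)
  }
}

dcm_item <- function(content) {
  c(u16le(0xFFFE), u16le(0xE000), u32le(length(content)), content)
}

#' Write a synthetic multi-frame DICOM file
#'
#' Serialises a grayscale clip as an uncompressed explicit-VR
#' little-endian ultrasound multi-frame DICOM file with 8-bit MONOCHROME2
#' pixels. Calibration can be carried as the PixelSpacing attribute (in
#' mm/px, the DICOM convention), as an ultrasound-region calibration
#' sequence with physical deltas in cm/px, or omitted entirely to exercise
#' downstream calibration-missing handling. Round-trips exactly through
#' [read_dicom()].
#'
#' @param frames List of numeric matrices with values in 0–255 (rounded on
#'   write), or the `frames` element of [make_effusion_video()] output.
#' @param path Output file path.
#' @param spacing_row,spacing_col Pixel spacing in cm/px.
#' @param calibration How to encode calibration: `"pixel_spacing"`,
#'   `"region"`, or `"none"`.
#' @return `path`, invisibly.
#' @export
write_synthetic_dicom <- function(frames, path, spacing_row = 0.01,
                                  spacing_col = spacing_row,
                                  calibration = c("pixel_spacing", "region", "none")) {
  calibration <- match.arg(calibration)
  if (inherits(frames, "echo_video")) frames <- frames$frames
  if (!length(frames)) stop("need at least one frame")
  nr <- nrow(frames[[1]]); nc <- ncol(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), c(nr, nc)), logical(1)))) {
    stop("all frames must share the same shape")
  }
  pix <- unlist(lapply(frames, function(f) as.integer(round(t(f)))))  # row-major
  if (any(pix < 0 | pix > 255)) stop("pixel intensities must lie in 0-255")

  sop_class <- "1.2.840.10008.5.1.4.1.1.3.1"   # US multi-frame image storage
  # content-derived instance UID: deterministic, does not touch the RNG
  sop_inst <- paste0("1.2.826.0.1.3680043.9590.1.", length(frames), ".",
                     nr, ".", nc, ".", sum(pix) %% 1e9)
  ts <- "1.2.840.10008.1.2.1"                  # explicit VR little endian

  meta_body <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    dcm_element(0x0002, 0x0002, "UI", sop_class),
    dcm_element(0x0002, 0x0003, "UI", sop_inst),
    dcm_element(0x0002, 0x0010, "UI", ts))
  meta <- c(dcm_element(0x0002, 0x0000, "UL", u32le(length(meta_body))), meta_body)

  ds <- c(
    dcm_element(0x0008, 0x0016, "UI", sop_class),
    dcm_element(0x0008, 0x0018, "UI", sop_inst))
  if (calibration == "region") {
    region <- c(
      dcm_element(0x0018, 0x6024, "US", u16le(3L)),   # PhysicalUnitsX: cm
      dcm_element(0x0018, 0x6026, "US", u16le(3L)),   # PhysicalUnitsY: cm
      dcm_element(0x0018, 0x602C, "FD", f64le(spacing_col)),
      dcm_element(0x0018, 0x602E, "FD", f64le(spacing_row)))
    ds <- c(ds, dcm_element(0x0018, 0x6011, "SQ", dcm_item(region)))
  }
  ds <- c(ds,
    dcm_element(0x0028, 0x0002, "US", u16le(1L)),
    dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_element(0x0028, 0x0008, "IS", as.character(length(frames))),
    dcm_element(0x0028, 0x0010, "US", u16le(nr)),
    dcm_element(0x0028, 0x0011, "US", u16le(nc)))
  if (calibration == "pixel_spacing") {
    ds <- c(ds, dcm_element(0x0028, 0x0030, "DS",
                            sprintf("%.8g\\%.8g", spacing_row * 10, spacing_col * 10)))
  }
  ds <- c(ds,
    dcm_element(0x0028, 0x0100, "US", u16le(8L)),
    dcm_element(0x0028, 0x0101, "US", u16le(8L)),
    dcm_element(0x0028, 0x0102, "US", u16le(7L)),
    dcm_element(0x0028, 0x0103, "US", u16le(0L)),
    dcm_element(0x7FE0, 0x0010, "OB", as.raw(pix)))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, ds), con)
  invisible(path)
}

# --- reading ---------------------------------------------------------------

rd_u16 <- function(bytes, at) {
  sum(as.integer(bytes[at:(at + 1)]) * c(1, 256))
}
rd_u32 <- function(bytes, at) {
  sum(as.numeric(bytes[at:(at + 3)]) * c(1, 256, 65536, 16777216))
}

# parse one dataset (or sequence-item body) from `at` to `end`;
# returns list(elements = named list "gggg,eeee" -> value, next_at)
parse_dataset <- function(bytes, at, end, explicit) {
  els <- list()
  while (at + 7 <= end) {
    group <- rd_u16(bytes, at); elem <- rd_u16(bytes, at + 2)
    at <- at + 4
    if (group == 0xFFFE) {            # delimiters inside sequences
      len <- rd_u32(bytes, at); at <- at + 4
      if (elem == 0xE00D || elem == 0xE0DD) break
      stop("unexpected item tag outside a sequence")
    }
    if (explicit) {
      vr <- rawToChar(bytes[at:(at + 1)]); at <- at + 2
      if (vr %in% LONG_VRS) {
        len <- rd_u32(bytes, at + 2); at <- at + 6
      } else {
        len <- rd_u16(bytes, at); at <- at + 2
      }
    } else {
      vr <- implicit_vr(group, elem)
      len <- rd_u32(bytes, at); at <- at + 4
    }
    key <- sprintf("%04X,%04X", group, elem)
    if (vr == "SQ" || (len == 0xFFFFFFFF)) {
      sq_end <- if (len == 0xFFFFFFFF) end else at + len
      items <- list()
      while (at + 7 <= sq_end) {
        ig <- rd_u16(bytes, at); ie <- rd_u16(bytes, at + 2)
        ilen <- rd_u32(bytes, at + 4)
        at <- at + 8
        if (ig == 0xFFFE && ie == 0xE0DD) break
        if (!(ig == 0xFFFE && ie == 0xE000)) stop("malformed sequence item")
        item_end <- if (ilen == 0xFFFFFFFF) sq_end else at + ilen
        parsed <- parse_dataset(bytes, at, item_end, explicit)
        items[[length(items) + 1L]] <- parsed$elements
        at <- parsed$next_at
      }
      els[[key]] <- items
    } else {
      val <- if (len > 0) bytes[at:(at + len - 1)] else raw(0)
      at <- at + len
      els[[key]] <- decode_value(vr, val)
    }
  }
  list(elements = els, next_at = at)
}

implicit_vr <- function(group, elem) {
  key <- sprintf("%04X,%04X", group, elem)
  switch(key,
    "0028,0002" = , "0028,0010" = , "0028,0011" = , "0028,0100" = ,
    "0028,0101" = , "0028,0102" = , "0028,0103" = , "0028,0006" = ,
    "0018,6024" = , "0018,6026" = "US",
    "0028,0030" = , "0018,1063" = "DS",
    "0028,0008" = "IS",
    "0028,0004" = "CS",
    "0018,602C" = , "0018,602E" = "FD",
    "0018,6011" = "SQ",
    "7FE0,0010" = "OW",
    "UN")
}

decode_value <- function(vr, val) {
  if (vr %in% c("US")) {
    readBin(val, "integer", n = length(val) / 2, size = 2, signed = FALSE,
            endian = "little")
  } else if (vr == "UL") {
    readBin(val, "integer", n = length(val) / 4, size = 4, endian = "little")
  } else if (vr == "FD") {
    readBin(val, "double", n = length(val) / 8, size = 8, endian = "little")
  } else if (vr %in% c("DS", "IS", "CS", "UI", "LO", "SH", "PN", "DA", "TM", "AE")) {
    trimws(rawToChar(val))
  } else {
    val   # raw payloads (pixel data etc.)
  }
}

#' Read a multi-frame DICOM echocardiography clip
#'
#' Parses an uncompressed little-endian DICOM file (explicit or implicit
#' VR) into an `echo_video`: a list of single-channel intensity matrices
#' plus physical pixel spacing in cm/px. RGB payloads are converted to
#' luma; MONOCHROME1 images are inverted so brighter always means more
#' echogenic. Calibration is taken from the PixelSpacing attribute (mm/px,
#' converted to cm) when present, otherwise from the first ultrasound
#' calibration region whose physical deltas are expressed in cm. A file
#' with neither yields an explicit calibration-missing error: widths are
#' never reported off an assumed default spacing.
#'
#' @param path DICOM file path.
#' @return List of class `echo_video`: `frames` (numeric matrices),
#'   `spacing_row`, `spacing_col` (cm/px), `source_id`, `frame_rate`
#'   (Hz or `NA`), `spacing_source` (`"pixel_spacing"` or `"region"`).
#' @export
read_dicom <- function(path) {
  if (!file.exists(path)) stop("cannot open DICOM file: ", path)
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM") {
    stop("not a DICOM file (missing DICM magic): ", path)
  }
  at <- 133
  # file meta group is always explicit VR little endian
  meta_end <- length(bytes)
  # read just the group length element first
  if (!(rd_u16(bytes, at) == 2 && rd_u16(bytes, at + 2) == 0)) {
    stop("malformed DICOM meta header")
  }
  glen <- rd_u32(bytes, at + 8)
  meta <- parse_dataset(bytes, at, at + 12 + glen, explicit = TRUE)
  ts <- meta$elements[["0002,0010"]]
  explicit <- TRUE
  if (!is.null(ts)) {
    if (ts == "1.2.840.10008.1.2") {
      explicit <- FALSE
    } else if (ts != "1.2.840.10008.1.2.1") {
      stop("unsupported transfer syntax: ", ts)
    }
  }
  ds <- parse_dataset(bytes, meta$next_at, length(bytes), explicit)$elements

  rows <- ds[["0028,0010"]]; cols <- ds[["0028,0011"]]
  if (is.null(rows) || is.null(cols)) stop("not an image DICOM (no Rows/Columns)")
  nfr <- if (!is.null(ds[["0028,0008"]])) as.integer(ds[["0028,0008"]]) else 1L
  spp <- if (!is.null(ds[["0028,0002"]])) ds[["0028,0002"]] else 1L
  bits <- if (!is.null(ds[["0028,0100"]])) ds[["0028,0100"]] else 8L
  photo <- if (!is.null(ds[["0028,0004"]])) ds[["0028,0004"]] else "MONOCHROME2"
  pix <- ds[["7FE0,0010"]]
  if (is.null(pix)) stop("not an image DICOM (no pixel data)")

  nbytes_px <- bits / 8
  vals <- if (bits == 8) {
    as.integer(pix)
  } else if (bits == 16) {
    readBin(pix, "integer", n = length(pix) / 2, size = 2, signed = FALSE,
            endian = "little")
  } else stop("unsupported BitsAllocated: ", bits)
  need <- rows * cols * nfr * spp
  if (length(vals) < need) stop("pixel data shorter than declared geometry")
  vals <- vals[seq_len(need)]

  frames <- vector("list", nfr)
  per <- rows * cols * spp
  for (f in seq_len(nfr)) {
    v <- vals[((f - 1) * per + 1):(f * per)]
    if (spp == 3L) {
      # interleaved RGB -> luma
      r <- v[seq(1, per, by = 3)]; g <- v[seq(2, per, by = 3)]; b <- v[seq(3, per, by = 3)]
      v <- 0.299 * r + 0.587 * g + 0.114 * b
    } else if (spp != 1L) stop("unsupported SamplesPerPixel: ", spp)
    m <- matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
    if (identical(photo, "MONOCHROME1")) m <- (2^bits - 1) - m
    frames[[f]] <- m
  }

  spacing <- NULL; src <- NULL
  psp <- ds[["0028,0030"]]
  if (!is.null(psp)) {
    parts <- as.numeric(strsplit(psp, "\\\\")[[1]])
    if (length(parts) == 2 && all(parts > 0)) {
      spacing <- parts / 10   # mm -> cm
      src <- "pixel_spacing"
    }
  }
  if (is.null(spacing) && !is.null(ds[["0018,6011"]])) {
    for (reg in ds[["0018,6011"]]) {
      ux <- reg[["0018,6024"]]; uy <- reg[["0018,6026"]]
      dx <- reg[["0018,602C"]]; dy <- reg[["0018,602E"]]
      if (!is.null(ux) && !is.null(uy) && ux == 3 && uy == 3 &&
          !is.null(dx) && !is.null(dy) && dx > 0 && dy > 0) {
        spacing <- c(dy, dx)   # deltas are (x = col, y = row), already cm
        src <- "region"
        break
      }
    }
  }
  if (is.null(spacing)) {
    stop("no pixel calibration found in ", basename(path),
         " (neither PixelSpacing nor a cm-calibrated ultrasound region)")
  }

  fr <- NA_real_
  if (!is.null(ds[["0018,1063"]])) {
    ft <- as.numeric(ds[["0018,1063"]])
    if (is.finite(ft) && ft > 0) fr <- 1000 / ft
  }
  structure(list(frames = frames, spacing_row = spacing[1],
                 spacing_col = spacing[2], source_id = basename(path),
                 frame_rate = fr, spacing_source = src),
            class = "echo_video")
}

#' @export
print.echo_video <- function(x, ...) {
  cat(sprintf("<echo_video> %s: %d frame(s) of %d x %d px, spacing %.4g x %.4g cm/px (%s)\n",
              x$source_id, length(x$frames), nrow(x$frames[[1]]),
              ncol(x$frames[[1]]), x$spacing_row, x$spacing_col,
              x$spacing_source))
  invisible(x)
}
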