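#' Segment every frame of a clip with a pluggable segmenter
#'
#' Applies a per-frame segmenter to each frame and validates the contract:
#' one [segmentation_result()] per frame, in order, all sharing the frame's
#' grid shape. A segmenter is any function `f(frame, index)` — the trained
#' instance-segmentation network the pipeline is designed around, the
#' reference intensity-band segmenter shipped here, or an identity fixture
#' replaying precomputed masks.
#'
#' @param frames List of 2D grayscale matrices (or an `echo_video`).
#' @param segmenter Function `(frame, index) -> segmentation_result`.
#' @return List of `segmentation_result`, one per frame.
#' @export
segment_video <- function(frames, segmenter) {
  if (inherits(frames, "echo_video")) frames <- frames$frames
  n <- length(frames)
  if (!n) stop("no frames to segment")
  shp <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), shp), logical(1)))) {
    stop("all frames must share the same shape")
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    res <- segmenter(frames[[i]], i)
    if (!inherits(res, "segmentation_result")) {
      stop(sprintf("segmenter must return a segmentation_result (frame %d)", i))
    }
    if (!identical(dim(res$masks$PE), shp)) {
      stop(sprintf("mask shape %s does not match frame shape %s (frame %d)",
                   paste(dim(res$masks$PE), collapse = "x"),
                   paste(shp, collapse = "x"), i))
    }
    res$frame_index <- i
    out[[i]] <- res
  }
  out
}

#' Reference intensity-band segmenter
#'
#' A deterministic, non-learned stand-in segmenter for phantoms and
#' rendered synthetic clips: the PE mask is the set of pixels whose
#' intensity lies in `(low, high]`, morphologically closed with a 3x3 box,
#' with connected components smaller than `min_area` removed. Chamber masks
#' are left empty. The reported PE confidence is the fraction of in-band
#' pixels retained after filtering (0 when the band is empty).
#'
#' @param frame 2D numeric intensity matrix.
#' @param low,high Band limits, `0 <= low < high`.
#' @param min_area Minimum component area in pixels.
#' @param spacing_row,spacing_col Pixel spacing, cm/px, attached to the masks.
#' @param frame_index Frame label for the result.
#' @return A [segmentation_result()].
#' @export
segment_threshold <- function(frame, low, high = Inf, min_area = 10L,
                              spacing_row = 0.01, spacing_col = spacing_row,
                              frame_index = 1L) {
  if (!is.matrix(frame)) stop("frame must be a matrix")
  if (low < 0 || low >= high) stop("need 0 <= low < high")
  band <- (frame > low) & (frame <= high)
  n_band <- sum(band)
  m <- EBImage::closing(band * 1, EBImage::makeBrush(3, "box"))
  m <- matrix(as.integer(m > 0), nrow(frame), ncol(frame))
  if (min_area > 0 && any(m == 1L)) {
    lab <- EBImage::bwlabel(m)
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < min_area)
    if (length(drop)) m[matrix(lab, nrow(frame)) %in% drop] <- 0L
  }
  conf <- if (n_band > 0) min(1, sum(m) / n_band) else 0
  segmentation_result(
    frame_index = frame_index,
    masks = list(PE = binary_mask(m, spacing_row, spacing_col)),
    confidences = c(PE = conf)
  )
}

#' @rdname segment_threshold
#' @return `threshold_segmenter()`: a segmenter function for
#'   [segment_video()] with the band parameters bound.
#' @export
threshold_segmenter <- function(low, high = Inf, min_area = 10L,
                                spacing_row = 0.01, spacing_col = spacing_row) {
  function(frame, index) {
    segment_threshold(frame, low = low, high = high, min_area = min_area,
                      spacing_row = spacing_row, spacing_col = spacing_col,
                      frame_index = index)
  }
}

#' Identity fixture segmenter replaying precomputed results
#'
#' @param results List of [segmentation_result()], one per frame.
#' @return A segmenter function for [segment_video()].
#' @export
identity_segmenter <- function(results) {
  function(frame, index) {
    if (index > length(results)) stop("no precomputed result for frame ", index)
    results[[index]]
  }
}

#' Write / read a mask annotation
#'
#' On-disk format: one single-channel 8-bit PNG per structure (0/255) named
#' `<basename>_<STRUCTURE>.png`, plus a JSON sidecar `<basename>.json`
#' holding the frame index, pixel spacings and per-structure confidences.
#' The round trip is bit-exact.
#'
#' @param result A [segmentation_result()].
#' @param dir Directory for the files.
#' @param basename File stem.
#' @return `write_mask_annotation()`: the sidecar path, invisibly.
#' @export
write_mask_annotation <- function(result, dir, basename = "frame") {
  stopifnot(inherits(result, "segmentation_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- mask_spacing(result$masks[[1]])
  for (s in names(result$masks)) {
    png::writePNG(as_mask_matrix(result$masks[[s]]) * 1.0,
                  file.path(dir, sprintf("%s_%s.png", basename, s)))
  }
  side <- list(frame_index = result$frame_index,
               spacing_row = unname(sp["row"]), spacing_col = unname(sp["col"]),
               structures = as.list(names(result$masks)))
  if (!is.null(result$confidences)) side$confidences <- as.list(result$confidences)
  path <- file.path(dir, paste0(basename, ".json"))
  jsonlite::write_json(side, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask_annotation
#' @param path Path to the JSON sidecar written by `write_mask_annotation()`.
#' @return `read_mask_annotation()`: the reconstructed
#'   [segmentation_result()].
#' @export
read_mask_annotation <- function(path) {
  side <- jsonlite::read_json(path, simplifyVector = TRUE)
  structures <- as.character(side$structures)
  bad <- setdiff(structures, STRUCTURE_CLASSES)
  if (length(bad)) stop("unknown structure class(es) in annotation: ",
                        paste(bad, collapse = ", "))
  dir <- dirname(path)
  base <- sub("\\.json$", "", basename(path))
  masks <- lapply(structures, function(s) {
    img <- png::readPNG(file.path(dir, sprintf("%s_%s.png", base, s)))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    binary_mask(matrix(as.integer(img > 0.5), nrow(img), ncol(img)),
                side$spacing_row, side$spacing_col)
  })
  names(masks) <- structures
  conf <- if (!is.null(side$confidences)) unlist(side$confidences) else NULL
  segmentation_result(side$frame_index, masks, conf)
}

#' Write / read a mask annotation in the run-length CSV dialect
#'
#' Columns `structure,row,col_start,col_end` (1-based, inclusive), one row
#' per horizontal foreground run. Grid shape and spacings are carried in a
#' `# shape` / `# spacing` comment header so the round trip is exact.
#'
#' @param result A [segmentation_result()].
#' @param path CSV file path.
#' @export
write_mask_annotation_csv <- function(result, path) {
  stopifnot(inherits(result, "segmentation_result"))
  sp <- mask_spacing(result$masks[[1]])
  shp <- dim(result$masks[[1]])
  rows <- list()
  for (s in names(result$masks)) {
    g <- as_mask_matrix(result$masks[[s]])
    for (r in seq_len(nrow(g))) {
      rl <- rle(g[r, ])
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1L
      keep <- rl$values == 1L
      if (any(keep)) {
        rows[[length(rows) + 1L]] <- data.frame(
          structure = s, row = r, col_start = starts[keep], col_end = ends[keep])
      }
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# shape,%d,%d", shp[1], shp[2]),
    sprintf("# spacing,%.17g,%.17g", sp["row"], sp["col"]),
    sprintf("# frame_index,%d", result$frame_index),
    "structure,row,col_start,col_end"), con)
  if (length(rows)) {
    df <- do.call(rbind, rows)
    utils::write.table(df, con, sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_mask_annotation_csv
#' @export
read_mask_annotation_csv <- function(path) {
  hdr <- readLines(path, n = 3L)
  parse_hdr <- function(line, tag) {
    if (!startsWith(line, paste0("# ", tag))) {
      stop("malformed annotation CSV header: expected '# ", tag, "'")
    }
    as.numeric(strsplit(line, ",")[[1]][-1])
  }
  shp <- as.integer(parse_hdr(hdr[1], "shape"))
  sp <- parse_hdr(hdr[2], "spacing")
  fi <- as.integer(parse_hdr(hdr[3], "frame_index"))
  df <- utils::read.csv(path, comment.char = "#")
  bad <- setdiff(unique(df$structure), STRUCTURE_CLASSES)
  if (length(bad)) stop("unknown structure class(es) in annotation: ",
                        paste(bad, collapse = ", "))
  if (nrow(df) && (any(df$row < 1 | df$row > shp[1]) ||
                   any(df$col_start < 1 | df$col_end > shp[2] |
                       df$col_start > df$col_end))) {
    stop("annotation runs fall outside the declared grid shape")
  }
  structures <- unique(c("PE", df$structure))
  masks <- lapply(structures, function(s) {
    g <- matrix(0L, shp[1], shp[2])
    sub <- df[df$structure == s, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      g[sub$row[i], sub$col_start[i]:sub$col_end[i]] <- 1L
    }
    binary_mask(g, sp[1], sp[2])
  })
  names(masks) <- structures
  segmentation_result(fi, masks)
}
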