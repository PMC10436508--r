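#' Echocardiographic view classes
#'
#' The five view classes used throughout the package: the four primary
#' echocardiographic views — parasternal long-axis (PLAX), parasternal
#' short-axis (PSAX), apical four-chamber (A4C) and subcostal (SC) — plus
#' OTHER, which absorbs all remaining and low-quality views.
#'
#' @format Character vector of length 5. The order is the fixed tie-break
#'   order used by [frame_top_view()] and [select_window()].
#' @export
VIEW_CLASSES <- c("PLAX", "PSAX", "A4C", "SC", "OTHER")

#' The four primary views (all classes except OTHER)
#' @rdname VIEW_CLASSES
#' @export
PRIMARY_VIEWS <- VIEW_CLASSES[1:4]

#' Segmentation structure classes
#'
#' Structures a per-frame segmenter may report: pericardial effusion (PE)
#' and the four cardiac chambers (right/left ventricle, right/left atrium).
#' PE is mandatory in every segmentation result; chambers are optional.
#'
#' @format Character vector of length 5.
#' @export
STRUCTURE_CLASSES <- c("PE", "RV", "LV", "RA", "LA")

#' Create a binary mask with physical pixel spacing
#'
#' A `binary_mask` is a 2D 0/1 grid for one structure in one frame. Rows are
#' the vertical image axis (row 1 at the top), columns the horizontal axis.
#' Physical calibration is carried as centimetres per pixel along each axis,
#' possibly anisotropic.
#'
#' @param grid Matrix coercible to 0/1 integer (logical accepted).
#' @param spacing_row,spacing_col Physical size of one pixel, cm/px; must be
#'   positive.
#' @return An integer 0/1 matrix of class `binary_mask` with attributes
#'   `spacing_row` and `spacing_col`.
#' @examples
#' m <- binary_mask(matrix(c(0, 1, 1, 0), 2, 2), spacing_row = 0.01)
#' mask_spacing(m)
#' @export
binary_mask <- function(grid, spacing_row = 0.01, spacing_col = spacing_row) {
  if (!is.matrix(grid)) stop("grid must be a matrix")
  if (is.logical(grid)) grid <- grid * 1L
  g <- grid
  storage.mode(g) <- "integer"
  if (anyNA(g) || !all(g %in% c(0L, 1L))) stop("grid must contain only 0/1")
  if (!is.numeric(spacing_row) || !is.numeric(spacing_col) ||
      spacing_row <= 0 || spacing_col <= 0) {
    stop("pixel spacings must be positive (cm/px)")
  }
  structure(g, spacing_row = as.numeric(spacing_row),
            spacing_col = as.numeric(spacing_col), class = c("binary_mask", "matrix"))
}

#' @rdname binary_mask
#' @param x A `binary_mask`.
#' @return `mask_spacing()`: named numeric `c(row =, col =)` in cm/px.
#' @export
mask_spacing <- function(x) {
  c(row = attr(x, "spacing_row"), col = attr(x, "spacing_col"))
}

is_binary_mask <- function(x) inherits(x, "binary_mask")

as_mask_matrix <- function(x) {
  m <- unclass(x)
  attr(m, "spacing_row") <- NULL
  attr(m, "spacing_col") <- NULL
  m
}

#' @export
print.binary_mask <- function(x, ...) {
  sp <- mask_spacing(x)
  cat(sprintf("<binary_mask> %d x %d px, %d foreground, spacing %.4g x %.4g cm/px\n",
              nrow(x), ncol(x), sum(x), sp["row"], sp["col"]))
  invisible(x)
}

#' Construct a per-frame segmentation result
#'
#' Bundles the masks one segmenter produced for one frame. The PE mask is
#' required; chamber masks are optional. All masks must share grid shape and
#' pixel spacing.
#'
#' @param frame_index Integer frame identifier (1-based within a clip).
#' @param masks Named list of [binary_mask()] objects; names drawn from
#'   [STRUCTURE_CLASSES], `PE` mandatory.
#' @param confidences Optional named numeric in \[0, 1\], same names as `masks`.
#' @return List of class `segmentation_result`.
#' @export
segmentation_result <- function(frame_index, masks, confidences = NULL) {
  if (!is.list(masks) || is.null(names(masks))) {
    stop("masks must be a named list of binary_mask objects")
  }
  bad <- setdiff(names(masks), STRUCTURE_CLASSES)
  if (length(bad)) stop("unknown structure class(es): ", paste(bad, collapse = ", "))
  if (!"PE" %in% names(masks)) stop("segmentation result must include a PE mask")
  if (!all(vapply(masks, is_binary_mask, logical(1)))) {
    stop("all masks must be binary_mask objects")
  }
  ref <- masks[[1]]
  same <- vapply(masks, function(m) {
    identical(dim(m), dim(ref)) && identical(mask_spacing(m), mask_spacing(ref))
  }, logical(1))
  if (!all(same)) stop("all masks must share grid shape and pixel spacing")
  if (!is.null(confidences)) {
    if (is.null(names(confidences)) || !all(names(confidences) %in% names(masks))) {
      stop("confidences must be named after masks")
    }
    if (any(confidences < 0 | confidences > 1)) stop("confidences must lie in [0, 1]")
  }
  structure(list(frame_index = as.integer(frame_index), masks = masks,
                 confidences = confidences),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> frame %d, structures: %s\n",
              x$frame_index, paste(names(x$masks), collapse = ", ")))
  invisible(x)
}
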