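#' Numerical configuration for the maximal width calculator
#'
#' @param tangent_half_window Contour points on each side of a boundary
#'   point used for the central-difference tangent estimate. 3 balances
#'   pixelation noise against corner rounding.
#' @param ray_step Ray-marching step in pixels. 0.05 px keeps chord
#'   discretization error well below 1 px and resolves grazing chords that
#'   skim a concave boundary, where a coarse stride can hop over a
#'   boundary sliver.
#' @param max_ray_length Cap on chord search length, px; `NULL` means the
#'   grid diagonal of the mask at hand.
#' @param min_region_area Connected components smaller than this (px) are
#'   ignored: segmentation specks should not drive the reported width.
#' @param collinear_run_px A foreground run at least this long lying flat
#'   along a horizontal stretch of boundary is treated as an edge-on
#'   (degenerate) intersection and yields no crossings; shorter flat runs
#'   (rounded tips) keep theirs.
#' @return List of class `width_config`.
#' @export
width_config <- function(tangent_half_window = 3L, ray_step = 0.05,
                         max_ray_length = NULL, min_region_area = 10L,
                         collinear_run_px = 12L) {
  if (tangent_half_window < 1 || ray_step <= 0 || min_region_area < 0 ||
      collinear_run_px < 2 ||
      (!is.null(max_ray_length) && max_ray_length <= 0)) {
    stop("width_config parameters must be positive")
  }
  structure(list(tangent_half_window = as.integer(tangent_half_window),
                 ray_step = ray_step, max_ray_length = max_ray_length,
                 min_region_area = as.integer(min_region_area),
                 collinear_run_px = as.integer(collinear_run_px)),
            class = "width_config")
}

#' Trace the contours of a binary mask
#'
#' One ordered 8-connected boundary trace per connected foreground
#' component with area at least `min_region_area`, plus one trace per
#' interior hole. Points are 1-based (row, col) pixel coordinates;
#' consecutive points are 8-neighbours and the loop closes.
#'
#' @param mask A [binary_mask()] or 0/1 matrix.
#' @param config A [width_config()].
#' @return List of contours; each contour is a list with `points`
#'   (n x 2 matrix, columns row/col), `hole` (logical) and `component`
#'   (integer id of the owning foreground component).
#' @export
trace_contours <- function(mask, config = width_config()) {
  g <- if (is_binary_mask(mask)) as_mask_matrix(mask) else mask
  if (!any(g == 1L)) return(list())
  lab <- matrix(as.integer(EBImage::bwlabel(g)), nrow(g), ncol(g))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= config$min_region_area)
  if (!length(keep)) return(list())
  kept <- matrix(0L, nrow(g), ncol(g))
  kept[lab %in% keep] <- lab[lab %in% keep]
  out <- list()
  oc <- EBImage::ocontour(kept)
  for (nm in names(oc)) {
    out[[length(out) + 1L]] <- list(points = unname(oc[[nm]]) + 1L,
                                    hole = FALSE, component = as.integer(nm))
  }
  # interior holes: background enclosed by a kept component
  km <- (kept > 0L) * 1L
  filled <- matrix(as.integer(EBImage::fillHull(km)), nrow(g), ncol(g))
  holes <- filled - km
  if (any(holes == 1L)) {
    hlab <- matrix(as.integer(EBImage::bwlabel(holes)), nrow(g), ncol(g))
    brush <- EBImage::makeBrush(3, "box")
    for (h in seq_len(max(hlab))) {
      hm <- (hlab == h) * 1
      # the hole contour is represented by the ring of *foreground* pixels
      # bordering the hole: the trace of (dilated hole) & mask, so inner
      # boundary points carry usable tangents
      ring <- matrix(as.integer(EBImage::dilate(hm, brush)), nrow(g), ncol(g)) & km
      ring <- matrix(as.integer(ring), nrow(g), ncol(g))
      if (!any(ring == 1L)) next
      rc <- EBImage::ocontour(ring)
      # owning component: any foreground neighbour of a hole pixel
      idx <- which(ring == 1L)[1]
      owner <- kept[idx]
      for (nm in names(rc)) {
        out[[length(out) + 1L]] <- list(points = unname(rc[[nm]]) + 1L,
                                        hole = TRUE,
                                        component = as.integer(owner))
      }
    }
  }
  out
}

#' Scanline crossings of a mask row
#'
#' The hypothetical horizontal line at row `row` crosses the mask at every
#' background-to-foreground and foreground-to-background transition; each
#' crossing is reported at the boundary foreground pixel (first or last
#' pixel of a run). Out-of-grid is background, so a run touching the image
#' border still yields a crossing at its border pixel. Runs of length 1
#' yield a single crossing point (entry and exit coincide).
#'
#' @param mask A [binary_mask()] or 0/1 matrix.
#' @param row Row index, 1-based.
#' @return data.frame with columns `row`, `col`, `side` ("entry"/"exit");
#'   zero rows when the scanline misses the mask.
#' @export
scanline_crossings <- function(mask, row) {
  g <- if (is_binary_mask(mask)) as_mask_matrix(mask) else mask
  if (row < 1 || row > nrow(g)) stop("row out of range")
  v <- g[row, ]
  rl <- rle(v)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  keep <- rl$values == 1L
  if (!any(keep)) {
    return(data.frame(row = integer(), col = integer(), side = character()))
  }
  s <- starts[keep]; e <- ends[keep]
  data.frame(row = row,
             col = as.integer(as.vector(rbind(s, e))),
             side = rep(c("entry", "exit"), length(s)))
}

# Gaussian-smoothed mask indicator. Its gradient at a boundary pixel is
# the inward boundary normal to within a few degrees, robust both to
# staircase jitter (which corrupts raw finite differences of the mask or
# of its distance transform) and at medial-axis shoulders (where a
# distance-transform gradient rotates to point along a protrusion instead
# of across the local boundary).
smoothed_indicator <- function(g, sigma = 2) {
  # pad so the Gaussian brush always fits, and so border foreground is
  # smoothed against background rather than reflected
  pad <- 2L * ceiling(3 * sigma) + 2L
  nr <- nrow(g); nc <- ncol(g)
  big <- matrix(0, nr + 2L * pad, nc + 2L * pad)
  big[pad + seq_len(nr), pad + seq_len(nc)] <- g
  sm <- matrix(EBImage::gblur(big, sigma = sigma), nrow(big), ncol(big))
  sm[pad + seq_len(nr), pad + seq_len(nc)]
}

# Exit-side consistency: a chord that hits the far boundary obliquely is
# an inflated secant (the signature of a misoriented entry normal, e.g.
# near a corner), whereas a genuine normal chord lands roughly along the
# exit's own normal. Re-measure from the chord's last inside pixel along
# the exit boundary's normal and keep the shorter chord — the local width
# where the ray landed.
exit_consistent_chord <- function(ch, g, dist, config) {
  if (ch$width_px <= 0 || isTRUE(ch$capped)) return(ch)
  q <- ch$last_inside
  back <- normal_chord_length(g, q, field_gradient_normal(dist, q), config)
  if (back$width_px > 0 && back$width_px < ch$width_px) back else ch
}

# Inward normal from the gradient of a scalar field increasing toward the
# mask interior (the smoothed indicator), at an integer pixel.
field_gradient_normal <- function(dist, point) {
  nr <- nrow(dist); nc <- ncol(dist)
  r <- point[1]; co <- point[2]
  gr <- dist[min(r + 1, nr), co] - dist[max(r - 1, 1), co]
  gc <- dist[r, min(co + 1, nc)] - dist[r, max(co - 1, 1)]
  n <- sqrt(gr^2 + gc^2)
  if (n < 1e-12) {
    # flat or single-pixel neighbourhood: point toward the deepest neighbour
    best <- c(0, 0); bv <- dist[r, co]
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; cc <- co + dc
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && dist[rr, cc] > bv) {
        bv <- dist[rr, cc]; best <- c(dr, dc)
      }
    }
    n <- sqrt(sum(best^2))
    if (n < 1e-12) return(c(1, 0))  # isolated pixel: arbitrary unit vector
    return(best / n)
  }
  c(gr, gc) / n
}

#' Inward unit normal at a contour point
#'
#' The tangent is the principal direction of the contour points within
#' `tangent_half_window` positions of the query point (cyclic), signed by
#' the window's endpoint difference; the normal is the unit perpendicular,
#' oriented so that a 1-px step from the point lands inside the mask. When
#' the tangent degenerates or the orientation test is ambiguous (neither
#' or both directions land inside), the direction falls back to the
#' gradient of the Gaussian-smoothed mask indicator, the smooth inward
#' normal field [frame_max_width()] itself measures along.
#'
#' @param contour One contour from [trace_contours()].
#' @param point Integer `c(row, col)` lying on the contour.
#' @param mask The owning [binary_mask()] (or 0/1 matrix).
#' @param config A [width_config()].
#' @param dist Optional precomputed smoothed-indicator field of the mask.
#' @return Unit 2-vector `c(d_row, d_col)` pointing into the mask.
#' @export
boundary_normal <- function(contour, point, mask, config = width_config(),
                            dist = NULL) {
  g <- if (is_binary_mask(mask)) as_mask_matrix(mask) else mask
  pts <- contour$points
  np <- nrow(pts)
  i <- which(pts[, 1] == point[1] & pts[, 2] == point[2])[1]
  if (is.na(i)) stop("point does not lie on the contour")
  if (is.null(dist)) dist <- smoothed_indicator(g)
  h <- config$tangent_half_window
  fallback <- function() field_gradient_normal(dist, point)
  if (np <= 2L * h) return(fallback())
  # tangent = principal direction of the contour points in the window,
  # anchored by the endpoint difference's sign; less sensitive to
  # single-pixel staircase jitter than a two-point difference
  win <- pts[((i - 1 + (-h:h)) %% np) + 1L, , drop = FALSE]
  ctr_ <- colMeans(win)
  cv <- crossprod(sweep(win, 2, ctr_))
  eg <- eigen(cv, symmetric = TRUE)
  tg <- eg$vectors[, 1]
  ia <- ((i - 1 + h) %% np) + 1L
  ib <- ((i - 1 - h) %% np) + 1L
  sec <- pts[ia, ] - pts[ib, ]
  if (sum(tg * sec) < 0) tg <- -tg
  tn <- sqrt(sum(tg^2))
  if (tn < 1e-12 || eg$values[1] < 1e-12) return(fallback())
  nrm <- c(-tg[2], tg[1]) / tn
  inside <- function(v) {
    r <- as.integer(round(point[1] + v[1]))
    co <- as.integer(round(point[2] + v[2]))
    r >= 1 && r <= nrow(g) && co >= 1 && co <= ncol(g) && g[r, co] == 1L
  }
  a <- inside(nrm); b <- inside(-nrm)
  if (a && !b) return(nrm)
  if (b && !a) return(-nrm)
  fallback()
}

#' Chord length through the mask along a normal
#'
#' Marches from a boundary point along the given inward normal in steps of
#' `ray_step`, sampling the mask by nearest neighbour (out-of-grid is
#' background, interior holes terminate the chord). The exit position is
#' refined to the midpoint between the last inside and first outside
#' samples. If no sample beyond the starting pixel ever lies inside the
#' mask — e.g. a normal pointing away from the mask — the width is 0.
#'
#' @param mask A [binary_mask()] or 0/1 matrix.
#' @param point `c(row, col)` boundary point (foreground).
#' @param normal Unit 2-vector, inward orientation.
#' @param config A [width_config()].
#' @return List with `width_px`, `entry` and `exit` (subpixel
#'   `c(row, col)`).
#' @export
normal_chord_length <- function(mask, point, normal, config = width_config()) {
  g <- if (is_binary_mask(mask)) as_mask_matrix(mask) else mask
  nr <- nrow(g); nc <- ncol(g)
  maxlen <- if (is.null(config$max_ray_length)) sqrt(nr^2 + nc^2) else config$max_ray_length
  t <- seq(0, maxlen, by = config$ray_step)
  rr <- as.integer(round(point[1] + t * normal[1]))
  cc <- as.integer(round(point[2] + t * normal[2]))
  inside <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  inside[inside] <- g[cbind(rr[inside], cc[inside])] == 1L
  if (!inside[1]) {
    return(list(width_px = 0, entry = as.numeric(point), exit = as.numeric(point),
                last_inside = as.integer(point), capped = FALSE))
  }
  first_out <- which(!inside)[1]
  width <- if (is.na(first_out)) maxlen else (t[first_out - 1L] + t[first_out]) / 2
  li <- if (is.na(first_out)) length(t) else first_out - 1L
  # a ray that never leaves the starting pixel saw nothing of the interior
  beyond <- inside & (rr != point[1] | cc != point[2])
  if (!is.na(first_out) && !any(beyond[seq_len(first_out - 1L)])) {
    width <- 0
  }
  list(width_px = width,
       entry = as.numeric(point),
       exit = as.numeric(point) + width * normal,
       last_inside = c(rr[li], cc[li]),
       capped = is.na(first_out))
}

#' Maximal normal-chord width of one mask
#'
#' The per-frame width measurement: for every row of the grid, find the
#' scanline crossings; at each crossing, take the inward boundary normal
#' from the smoothed-indicator gradient field, measure the chord through
#' the mask along it, and enforce exit-side consistency (a chord that hits
#' the far boundary obliquely is an inflated secant and is replaced by the
#' chord measured back from its landing point). Long foreground runs lying
#' flat along the boundary are edge-on intersections and yield no
#' crossings. The maximum over all crossings is the frame's width; ties go
#' to the smallest row, then the leftmost crossing.
#'
#' @param mask A [binary_mask()] (spacing used for the cm value) or 0/1
#'   matrix (width_cm then `NA`).
#' @param config A [width_config()].
#' @param frame_index Frame label attached to the measurement.
#' @return A list of class `width_measurement` with `width_px`, `width_cm`,
#'   `entry`, `exit`, `source_row`, `frame_index`; or `NULL` when the mask
#'   has no component of at least `min_region_area` pixels.
#' @export
frame_max_width <- function(mask, config = width_config(), frame_index = NA_integer_) {
  g <- if (is_binary_mask(mask)) as_mask_matrix(mask) else mask
  contours <- trace_contours(g, config)
  if (!length(contours)) return(NULL)
  # only components that survived the area filter contribute crossings
  keepg <- matrix(0L, nrow(g), ncol(g))
  lab <- matrix(as.integer(EBImage::bwlabel(g)), nrow(g), ncol(g))
  comps <- unique(vapply(contours, `[[`, integer(1), "component"))
  keepg[lab %in% comps] <- 1L
  dist <- smoothed_indicator(keepg)
  nr_ <- nrow(keepg)
  best <- NULL
  for (r in seq_len(nr_)) {
    cr <- scanline_crossings(keepg, r)
    if (!nrow(cr)) next
    # degenerate collinear runs: a run lying along a horizontal stretch of
    # the boundary (background all along its top or bottom side) crosses
    # the scanline edge-on; its normals are vertical and the same width is
    # captured by crossings on the perpendicular edges, so it yields no
    # crossing here
    drop <- logical(nrow(cr))
    for (k in seq(1, nrow(cr), by = 2)) {
      cols <- cr$col[k]:cr$col[k + 1]
      if (length(cols) < config$collinear_run_px) next  # a short tip keeps its crossings
      above <- if (r == 1) rep(0L, length(cols)) else keepg[r - 1, cols]
      below <- if (r == nr_) rep(0L, length(cols)) else keepg[r + 1, cols]
      if (all(above == 0L) || all(below == 0L)) drop[k:(k + 1)] <- TRUE
    }
    cr <- cr[!drop, , drop = FALSE]
    if (!nrow(cr)) next
    for (k in seq_len(nrow(cr))) {
      pt <- c(cr$row[k], cr$col[k])
      # one smooth inward normal field drives every crossing: the same
      # per-point chord definition an exhaustive boundary sweep would use,
      # so the frame maximum is stable under the choice of point set
      nrm <- field_gradient_normal(dist, pt)
      ch <- normal_chord_length(keepg, pt, nrm, config)
      ch <- exit_consistent_chord(ch, keepg, dist, config)
      if (is.null(best) || ch$width_px > best$width_px + 1e-9) {
        best <- list(width_px = ch$width_px, entry = ch$entry, exit = ch$exit,
                     source_row = r)
      }
    }
  }
  if (is.null(best)) {
    # every run was edge-on (e.g. a 1-px-high region): report zero width
    p0 <- contours[[1]]$points[1, ]
    best <- list(width_px = 0, entry = as.numeric(p0), exit = as.numeric(p0),
                 source_row = p0[1])
  }
  sp <- if (is_binary_mask(mask)) mask_spacing(mask) else c(row = NA_real_, col = NA_real_)
  wcm <- if (anyNA(sp)) NA_real_ else {
    calibrate_width(best$width_px, best$entry, best$exit, sp["row"], sp["col"])
  }
  structure(list(width_px = best$width_px, width_cm = wcm,
                 entry = best$entry, exit = best$exit,
                 source_row = best$source_row,
                 frame_index = as.integer(frame_index)),
            class = "width_measurement")
}

#' @export
print.width_measurement <- function(x, ...) {
  cat(sprintf("<width_measurement> %.2f px%s at row %d (frame %s)\n",
              x$width_px,
              if (is.na(x$width_cm)) "" else sprintf(" = %.3f cm", x$width_cm),
              x$source_row,
              if (is.na(x$frame_index)) "?" else x$frame_index))
  invisible(x)
}

#' Maximal width over a segmented clip
#'
#' Applies [frame_max_width()] to the PE mask of every frame and takes the
#' maximum over frames (ties to the earliest frame). Frames without a
#' measurable PE region contribute width 0.
#'
#' @param results List of [segmentation_result()] (from [segment_video()]).
#' @param config A [width_config()].
#' @return List with `per_frame` (data.frame: frame_index, width_px,
#'   width_cm, source_row), `max` (the winning `width_measurement`, or
#'   `NULL` when every frame is empty), and `max_frame`.
#' @export
video_max_width <- function(results, config = width_config()) {
  if (!length(results)) stop("need at least one segmented frame")
  n <- length(results)
  pf <- data.frame(frame_index = integer(n), width_px = numeric(n),
                   width_cm = numeric(n), source_row = NA_integer_)
  best <- NULL
  for (i in seq_len(n)) {
    res <- results[[i]]
    fi <- if (!is.null(res$frame_index)) res$frame_index else i
    m <- frame_max_width(res$masks$PE, config, frame_index = fi)
    pf$frame_index[i] <- fi
    if (is.null(m)) {
      pf$width_px[i] <- 0; pf$width_cm[i] <- 0
    } else {
      pf$width_px[i] <- m$width_px
      pf$width_cm[i] <- ifelse(is.na(m$width_cm), 0, m$width_cm)
      pf$source_row[i] <- m$source_row
      if (is.null(best) || m$width_px > best$width_px + 1e-9) best <- m
    }
  }
  list(per_frame = pf, max = best,
       max_frame = if (is.null(best)) NA_integer_ else best$frame_index)
}

#' Calibrate a pixel chord to centimetres
#'
#' Applies the (possibly anisotropic) pixel spacing to the chord's endpoint
#' displacement: `sqrt((drow * spacing_row)^2 + (dcol * spacing_col)^2)`.
#'
#' @param width_px Chord length in pixels (used for the zero case).
#' @param entry,exit Subpixel `c(row, col)` chord endpoints.
#' @param spacing_row,spacing_col Pixel spacing, cm/px; must be positive.
#' @return Width in cm.
#' @export
calibrate_width <- function(width_px, entry, exit, spacing_row, spacing_col) {
  if (spacing_row <= 0 || spacing_col <= 0) stop("pixel spacings must be positive")
  if (width_px == 0) return(0)
  d <- exit - entry
  unname(sqrt((d[1] * spacing_row)^2 + (d[2] * spacing_col)^2))
}

#' Read a width table / write per-frame widths as CSV
#'
#' Columns: `frame_index,row,width_px,width_cm,entry_row,entry_col,
#' exit_row,exit_col`.
#'
#' @param measurements List of `width_measurement` objects.
#' @param path CSV path.
#' @export
write_width_csv <- function(measurements, path) {
  measurements <- measurements[!vapply(measurements, is.null, logical(1))]
  df <- do.call(rbind, lapply(measurements, function(m) {
    data.frame(frame_index = m$frame_index, row = m$source_row,
               width_px = m$width_px, width_cm = m$width_cm,
               entry_row = m$entry[1], entry_col = m$entry[2],
               exit_row = m$exit[1], exit_col = m$exit[2])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
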