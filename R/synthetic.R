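#' Synthetic phantom masks with analytically known maximal width
#'
#' Rasterises a shape on a pixel grid (a pixel is foreground when its
#' centre lies inside the analytic shape) and, where the maximal
#' boundary-normal chord has a closed form, attaches it as ground truth:
#' a disc's widest normal chord is its diameter `2 R`, a full annulus's is
#' its rim thickness `R - r`, an axis-aligned rectangle's is its smaller
#' side (horizontal width for the tall rectangles used here). Crescents
#' (disc minus offset disc) and random blobs carry no analytic truth and
#' are oracle-tested.
#'
#' @param shape One of `"disc"`, `"rectangle"`, `"annulus"`, `"crescent"`,
#'   `"blob"`.
#' @param grid `c(n_rows, n_cols)` of the mask.
#' @param center `c(row, col)` of the shape centre; defaults to the grid
#'   centre.
#' @param radius Disc/crescent radius, px.
#' @param outer_radius,inner_radius Annulus radii, px (`inner < outer`).
#' @param width,height Rectangle sides, px (columns x rows).
#' @param notch_offset,notch_radius Crescent: centre offset and radius of
#'   the subtracted disc.
#' @param blob_seed,blob_fill Blob: RNG seed and target foreground
#'   fraction; the blob is the largest component of thresholded smoothed
#'   Gaussian noise.
#' @param spacing_row,spacing_col Pixel spacing, cm/px.
#' @return List with `mask` (a [binary_mask()]) and `true_width_px`
#'   (numeric or `NA` when no analytic truth exists).
#' @export
make_phantom <- function(shape = c("disc", "rectangle", "annulus", "crescent", "blob"),
                         grid = c(256L, 256L), center = (grid + 1) / 2,
                         radius = 100, outer_radius = 120, inner_radius = 90,
                         width = 40, height = 200,
                         notch_offset = c(0, 30), notch_radius = 70,
                         blob_seed = 1L, blob_fill = 0.15,
                         spacing_row = 0.01, spacing_col = spacing_row) {
  shape <- match.arg(shape)
  nr <- as.integer(grid[1]); nc <- as.integer(grid[2])
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d2 <- (rr - center[1])^2 + (cc - center[2])^2
  truth <- NA_real_
  g <- switch(shape,
    disc = {
      if (center[1] - radius < 1 || center[1] + radius > nr ||
          center[2] - radius < 1 || center[2] + radius > nc) {
        stop("disc does not fit inside the grid")
      }
      truth <- 2 * radius
      d2 <= radius^2
    },
    annulus = {
      if (inner_radius >= outer_radius) stop("need inner_radius < outer_radius")
      if (center[1] - outer_radius < 1 || center[1] + outer_radius > nr ||
          center[2] - outer_radius < 1 || center[2] + outer_radius > nc) {
        stop("annulus does not fit inside the grid")
      }
      truth <- outer_radius - inner_radius
      d2 <= outer_radius^2 & d2 > inner_radius^2
    },
    rectangle = {
      r0 <- round(center[1] - height / 2 + 0.5); r1 <- r0 + height - 1
      c0 <- round(center[2] - width / 2 + 0.5); c1 <- c0 + width - 1
      if (r0 < 1 || r1 > nr || c0 < 1 || c1 > nc) {
        stop("rectangle does not fit inside the grid")
      }
      truth <- width   # scanline crossings sit on the vertical edges
      rr >= r0 & rr <= r1 & cc >= c0 & cc <= c1
    },
    crescent = {
      if (center[1] - radius < 1 || center[1] + radius > nr ||
          center[2] - radius < 1 || center[2] + radius > nc) {
        stop("crescent does not fit inside the grid")
      }
      d2n <- (rr - center[1] - notch_offset[1])^2 + (cc - center[2] - notch_offset[2])^2
      d2 <= radius^2 & d2n > notch_radius^2
    },
    blob = {
      # like every other phantom, the blob must fit inside the field of
      # view: draws whose largest component touches an 8-px border margin
      # are rejected and redrawn from a derived seed
      marg <- 8L
      g <- NULL
      for (try in 0:49) {
        noise <- withr_seed(blob_seed + 7919L * try,
                            matrix(stats::rnorm(nr * nc), nr, nc))
        sm <- matrix(EBImage::gblur(noise, sigma = max(3, min(nr, nc) / 16)), nr, nc)
        thr <- stats::quantile(sm, 1 - blob_fill)
        lab <- matrix(as.integer(EBImage::bwlabel((sm > thr) * 1)), nr, nc)
        sizes <- tabulate(lab[lab > 0])
        cand <- lab == which.max(sizes)
        pr <- range(which(rowSums(cand) > 0)); pc <- range(which(colSums(cand) > 0))
        if (pr[1] > marg && pr[2] <= nr - marg && pc[1] > marg && pc[2] <= nc - marg) {
          g <- cand
          break
        }
      }
      if (is.null(g)) stop("could not draw a blob clear of the grid border")
      g
    })
  list(mask = binary_mask(matrix(as.integer(g), nr, nc), spacing_row, spacing_col),
       true_width_px = truth)
}

# evaluate expr under a temporary seed, restoring RNG state afterwards
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Synthetic "beating" effusion clip with known maximal width
#'
#' Emulates a clip whose pericardial rim thickness varies over a
#' cardiac-cycle-like period: frame `f` (1-based) carries a full annulus of
#' inner radius `inner_radius` and thickness
#' `t(f) = t0 + a * sin(2 * pi * (f - 1) / period)`, so the clip's true
#' maximal width is `t0 + a`, attained first at frame `period/4 + 1`.
#'
#' With `render = TRUE`, frames are 0–255 grayscale with a dark background,
#' a mid-intensity inner "heart" disc and a bright effusion band,
#' multiplied by uniform speckle noise (deterministic in `noise_seed`), so
#' the reference intensity-band segmenter can be exercised; with
#' `render = FALSE` (default) per-frame binary ground-truth masks are
#' returned directly.
#'
#' @param n_frames Number of frames (clips of 48 are the pipeline's unit).
#' @param t0 Base rim thickness, px.
#' @param a Modulation amplitude, px (`a < t0`).
#' @param period Modulation period in frames.
#' @param inner_radius Inner rim radius, px.
#' @param grid `c(n_rows, n_cols)`.
#' @param render Render grayscale speckle frames instead of binary masks.
#' @param bg,heart,band Intensities (0–255) of background, inner disc and
#'   effusion band when rendering.
#' @param speckle_amp Amplitude of the multiplicative uniform speckle
#'   (intensity is scaled by `1 + U(-amp, amp)`).
#' @param noise_seed RNG seed for the speckle.
#' @param spacing_row,spacing_col Pixel spacing, cm/px.
#' @return List with `frames` (grayscale matrices) or `masks`
#'   ([binary_mask()] per frame), and `truth` (list: `thickness_px` per
#'   frame, `max_width_px`, `max_frame`, `spacing_row`, `spacing_col`).
#' @export
make_effusion_video <- function(n_frames = 48L, t0 = 20, a = 10, period = 24L,
                                inner_radius = 60, grid = c(220L, 220L),
                                render = FALSE, bg = 30, heart = 120, band = 200,
                                speckle_amp = 0.15, noise_seed = 1L,
                                spacing_row = 0.01, spacing_col = spacing_row) {
  if (a >= t0) stop("modulation amplitude must be smaller than base thickness")
  if (n_frames < 1) stop("need at least one frame")
  nr <- as.integer(grid[1]); nc <- as.integer(grid[2])
  ctr <- (c(nr, nc) + 1) / 2
  if (ctr[1] + inner_radius + t0 + a > nr || ctr[2] + inner_radius + t0 + a > nc) {
    stop("annulus does not fit inside the grid")
  }
  f <- seq_len(n_frames)
  th <- t0 + a * sin(2 * pi * (f - 1) / period)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d <- sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2)
  masks <- lapply(f, function(i) {
    g <- d <= inner_radius + th[i] & d > inner_radius
    binary_mask(matrix(as.integer(g), nr, nc), spacing_row, spacing_col)
  })
  truth <- list(thickness_px = th, max_width_px = t0 + a,
                max_frame = as.integer(round(period / 4) + 1L),
                spacing_row = spacing_row, spacing_col = spacing_col)
  if (!render) return(list(masks = masks, truth = truth))
  frames <- withr_seed(noise_seed, lapply(f, function(i) {
    img <- matrix(bg, nr, nc)
    img[d <= inner_radius] <- heart
    img[as_mask_matrix(masks[[i]]) == 1L] <- band
    speck <- matrix(stats::runif(nr * nc, 1 - speckle_amp, 1 + speckle_amp), nr, nc)
    pmin(pmax(img * speck, 0), 255)
  }))
  list(frames = frames, masks = masks, truth = truth)
}

#' Synthetic per-frame view-score stream with a planted window
#'
#' Background frames score `background_confidence` for `background_view`;
#' frames `start .. start + length - 1` score `confidence` for `view`. The
#' remaining probability mass is spread uniformly over the other four
#' classes, so each row sums to 1 exactly.
#'
#' @param total_frames Stream length.
#' @param start,length,view,confidence The planted qualifying run
#'   (1-based start).
#' @param background_view,background_confidence Scores outside the run.
#' @return A [frame_scores()] stream.
#' @export
make_score_stream <- function(total_frames, start, length, view = "A4C",
                              confidence = 0.95, background_view = "OTHER",
                              background_confidence = 0.9) {
  view <- match.arg(view, VIEW_CLASSES)
  background_view <- match.arg(background_view, VIEW_CLASSES)
  if (start < 1 || start + length - 1 > total_frames) {
    stop("planted window must fit inside the stream")
  }
  row_for <- function(v, conf) {
    p <- rep((1 - conf) / 4, 5)
    p[match(v, VIEW_CLASSES)] <- conf
    p
  }
  prob <- matrix(rep(row_for(background_view, background_confidence),
                     each = total_frames), total_frames, 5)
  idx <- start:(start + length - 1L)
  prob[idx, ] <- matrix(rep(row_for(view, confidence), each = length(idx)),
                        length(idx), 5)
  frame_scores(prob)
}
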