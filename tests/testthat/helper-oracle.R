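# Brute-force reference for the scanline width measurand, independent of
# the package's contour/crossing/marching code: exhaustive sweep of every
# row's crossing pixels, freshly recomputed smoothed-indicator normals,
# 0.02-px ray marching, no subpixel refinement.
oracle_max_width <- function(g, step = 0.02, sigma = 2, flat_run = 12L) {
  nr <- nrow(g); nc <- ncol(g)
  ds <- matrix(EBImage::gblur(g + 0, sigma = sigma), nr, nc)
  maxlen <- sqrt(nr^2 + nc^2)
  t <- seq(0, maxlen, by = step)
  grad_at <- function(p) {
    gr <- ds[min(p[1] + 1, nr), p[2]] - ds[max(p[1] - 1, 1), p[2]]
    gc <- ds[p[1], min(p[2] + 1, nc)] - ds[p[1], max(p[2] - 1, 1)]
    nn <- sqrt(gr^2 + gc^2)
    if (nn < 1e-9) NULL else c(gr, gc) / nn
  }
  march <- function(p, n) {
    rr <- as.integer(round(p[1] + t * n[1]))
    cc <- as.integer(round(p[2] + t * n[2]))
    inside <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    inside[inside] <- g[cbind(rr[inside], cc[inside])] == 1L
    fo <- which(!inside)[1]
    if (is.na(fo)) list(w = maxlen, q = p)
    else list(w = t[fo - 1], q = c(rr[fo - 1], cc[fo - 1]))
  }
  value_at <- function(p) {
    n <- grad_at(p)
    if (is.null(n)) return(0)
    f <- march(p, n)
    w <- f$w
    nq <- grad_at(f$q)
    if (!is.null(nq)) {
      b <- march(f$q, nq)
      if (b$w > 0 && b$w < w) w <- b$w
    }
    w
  }
  best <- 0
  for (r in seq_len(nr)) {
    rl <- rle(g[r, ])
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    ok <- rl$values == 1L
    if (!any(ok)) next
    for (j in which(ok)) {
      cols <- starts[j]:ends[j]
      if (length(cols) >= flat_run) {
        above <- if (r == 1) rep(0L, length(cols)) else g[r - 1, cols]
        below <- if (r == nr) rep(0L, length(cols)) else g[r + 1, cols]
        if (all(above == 0L) || all(below == 0L)) next
      }
      for (co in unique(c(starts[j], ends[j]))) {
        w <- value_at(c(r, co))
        if (w > best) best <- w
      }
    }
  }
  best
}

# plain matrix view of a binary_mask
mask_grid <- function(m) {
  g <- unclass(m)
  attr(g, "spacing_row") <- NULL
  attr(g, "spacing_col") <- NULL
  g
}
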