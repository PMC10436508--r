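test_that("contours are traced per component with holes represented", {
  g <- matrix(0L, 40, 40); g[10:29, 10:29] <- 1L
  ct <- trace_contours(g)
  expect_length(ct, 1)
  expect_equal(nrow(ct[[1]]$points), 76)  # 4 * 20 - 4 perimeter pixels
  # consecutive points are 8-neighbours and the loop closes
  pts <- ct[[1]]$points
  steps <- rbind(diff(pts), pts[1, ] - pts[nrow(pts), ])
  expect_true(all(abs(steps) <= 1))

  an <- make_phantom("annulus", grid = c(120, 120), outer_radius = 45,
                     inner_radius = 30)
  ct2 <- trace_contours(mask_grid(an$mask))
  expect_length(ct2, 2)
  expect_equal(sum(vapply(ct2, `[[`, logical(1), "hole")), 1)

  expect_length(trace_contours(matrix(0L, 10, 10)), 0)
  # components below min_region_area are dropped
  dot <- matrix(0L, 10, 10); dot[5, 5] <- 1L
  expect_length(trace_contours(dot, width_config(min_region_area = 4)), 0)
})

test_that("scanline crossings appear at every run transition", {
  m <- matrix(c(0, 0, 0, 1, 1, 1, 1, 0, 0, 0), 1, 10)
  cr <- scanline_crossings(m, 1)
  expect_equal(nrow(cr), 2)
  expect_equal(cr$col, c(4L, 7L))
  m2 <- matrix(c(0, 1, 1, 0, 0, 1, 1, 0, 0, 0), 1, 10)
  expect_equal(nrow(scanline_crossings(m2, 1)), 4)
  expect_equal(nrow(scanline_crossings(matrix(0L, 1, 10), 1)), 0)
  expect_error(scanline_crossings(m, 5), "out of range")
})

test_that("boundary normals point inward along the local perpendicular", {
  disc <- make_phantom("disc", grid = c(220, 220), radius = 90)
  g <- mask_grid(disc$mask)
  ct <- trace_contours(g)
  # leftmost contour point nearest the equator: normal points right (0, +1)
  pts <- ct[[1]]$points
  cand <- pts[pts[, 2] == min(pts[, 2]), , drop = FALSE]
  left <- cand[which.min(abs(cand[, 1] - 110.5)), ]
  n <- boundary_normal(ct[[1]], left, g)
  ang <- acos(sum(n * c(0, 1))) * 180 / pi
  expect_lt(ang, 10)

  rect <- matrix(0L, 60, 60); rect[10:49, 20:39] <- 1L
  ctr <- trace_contours(rect)
  n2 <- boundary_normal(ctr[[1]], c(30, 20), rect)
  expect_equal(n2, c(0, 1), tolerance = 1e-9)

  # degenerate 3-pixel region exercises the gradient fallback
  tri <- matrix(0L, 10, 10); tri[5, 5:6] <- 1L; tri[6, 5] <- 1L
  ct3 <- trace_contours(tri, width_config(min_region_area = 1))
  n3 <- boundary_normal(ct3[[1]], ct3[[1]]$points[1, ], tri,
                        width_config(min_region_area = 1))
  expect_equal(sqrt(sum(n3^2)), 1, tolerance = 1e-9)
  expect_error(boundary_normal(ct3[[1]], c(1, 1), tri), "lie on the contour")
})

test_that("normal chords traverse discs and annuli at their analytic width", {
  disc <- make_phantom("disc", grid = c(256, 256), radius = 100)
  g <- mask_grid(disc$mask)
  pts <- trace_contours(g)[[1]]$points
  left <- pts[which.min(pts[, 2]), ]
  ch <- normal_chord_length(g, left, c(0, 1))
  expect_equal(ch$width_px, 200, tolerance = 2)
  expect_equal(ch$exit[2] - ch$entry[2], ch$width_px, tolerance = 1e-9)

  an <- make_phantom("annulus", grid = c(300, 300), outer_radius = 120,
                     inner_radius = 90)
  ga <- mask_grid(an$mask)
  ctr <- c(150.5, 150.5)
  outer_left <- c(round(ctr[1]), round(ctr[2] - 120) + 1)
  ch2 <- normal_chord_length(ga, outer_left, c(0, 1))
  expect_equal(ch2$width_px, 30, tolerance = 2)

  # a normal pointing away from the mask yields zero width
  ch3 <- normal_chord_length(g, left, c(0, -1))
  expect_equal(ch3$width_px, 0)
})

test_that("frame_max_width recovers analytic phantom widths", {
  disc <- make_phantom("disc", grid = c(256, 256), radius = 100)
  m <- frame_max_width(disc$mask)
  expect_equal(m$width_px, 200, tolerance = 2)
  expect_equal(m$width_cm, 2, tolerance = 0.02)

  rect <- make_phantom("rectangle", grid = c(256, 256), width = 40, height = 200)
  expect_equal(frame_max_width(rect$mask)$width_px, 40, tolerance = 2)

  an <- make_phantom("annulus", grid = c(300, 300), outer_radius = 120,
                     inner_radius = 90)
  expect_equal(frame_max_width(an$mask)$width_px, 30, tolerance = 2)

  expect_null(frame_max_width(matrix(0L, 50, 50)))
})

test_that("width measurement is invariant to translation and 90-degree rotation", {
  base <- make_phantom("annulus", grid = c(200, 200), outer_radius = 70,
                       inner_radius = 50)
  w0 <- frame_max_width(base$mask)$width_px
  for (off in list(c(15, -20), c(-10, 5))) {
    shifted <- make_phantom("annulus", grid = c(200, 200), outer_radius = 70,
                            inner_radius = 50,
                            center = c(100.5, 100.5) + off)
    expect_equal(frame_max_width(shifted$mask)$width_px, w0, tolerance = 0.5)
  }
  disc <- make_phantom("disc", grid = c(160, 160), radius = 60)
  g <- mask_grid(disc$mask)
  rot <- t(g)[ncol(g):1, ]
  expect_equal(frame_max_width(rot)$width_px,
               frame_max_width(g)$width_px, tolerance = 1e-9)
  ga <- mask_grid(base$mask)
  rot_a <- t(ga)[ncol(ga):1, ]
  expect_equal(frame_max_width(rot_a)$width_px, w0, tolerance = 2)
})

test_that("upscaling a mask scales the measured width proportionally", {
  an <- make_phantom("annulus", grid = c(150, 150), outer_radius = 55,
                     inner_radius = 40)
  w1 <- frame_max_width(an$mask)$width_px
  big <- make_phantom("annulus", grid = c(300, 300), outer_radius = 110,
                      inner_radius = 80)
  w2 <- frame_max_width(big$mask)$width_px
  expect_equal(w2 / w1, 2, tolerance = 0.02 * 2)
})

test_that("annulus thickness recovery is monotone and accurate over a sweep", {
  ts <- seq(5, 50, by = 5)
  ws <- vapply(ts, function(t) {
    an <- make_phantom("annulus", grid = c(320, 320), outer_radius = 90 + t,
                       inner_radius = 90)
    frame_max_width(an$mask)$width_px
  }, numeric(1))
  expect_true(all(diff(ws) > 0))
  expect_true(all(abs(ws - ts) <= pmax(2, 0.02 * ts)))
})

test_that("measured widths never exceed the bounding-box diagonal", {
  for (b in 1:5) {
    ph <- make_phantom("blob", grid = c(80, 80), blob_seed = 100 + b)
    g <- mask_grid(ph$mask)
    m <- frame_max_width(ph$mask)
    rr <- range(which(rowSums(g) > 0)); cc <- range(which(colSums(g) > 0))
    diag_ <- sqrt(diff(rr)^2 + diff(cc)^2)
    expect_gte(m$width_px, 0)
    expect_lte(m$width_px, diag_ + 1)
  }
})

test_that("frame widths agree with the exhaustive brute-force reference", {
  for (b in 1:10) {
    ph <- make_phantom("blob", grid = c(96, 96), blob_seed = b, blob_fill = 0.2)
    g <- mask_grid(ph$mask)
    w_impl <- frame_max_width(ph$mask)$width_px
    w_ref <- oracle_max_width(g)
    expect_lt(abs(w_impl - w_ref) / w_ref, 0.05)
  }
})

test_that("crescent phantoms are measured consistently with the reference", {
  ph <- make_phantom("crescent", grid = c(200, 200), radius = 70,
                     notch_offset = c(0, 25), notch_radius = 55)
  expect_true(is.na(ph$true_width_px))
  w_impl <- frame_max_width(ph$mask)$width_px
  w_ref <- oracle_max_width(mask_grid(ph$mask))
  expect_lt(abs(w_impl - w_ref) / w_ref, 0.05)
})

test_that("video maximum is the per-frame maximum with earliest-frame ties", {
  vid <- make_effusion_video(n_frames = 48, t0 = 20, a = 10, period = 24)
  res <- lapply(seq_along(vid$masks), function(i) {
    segmentation_result(i, list(PE = vid$masks[[i]]))
  })
  vm <- video_max_width(res)
  expect_equal(nrow(vm$per_frame), 48)
  expect_equal(vm$max$width_px, 30, tolerance = 2)
  expect_equal(vm$max_frame, 7, tolerance = 1)

  empty <- lapply(1:3, function(i) {
    segmentation_result(i, list(PE = binary_mask(matrix(0L, 30, 30))))
  })
  vm0 <- video_max_width(empty)
  expect_null(vm0$max)
  expect_true(all(vm0$per_frame$width_px == 0))

  single <- video_max_width(res[7])
  expect_equal(single$max$width_px, frame_max_width(vid$masks[[7]])$width_px)
})

test_that("pixel-to-cm calibration respects anisotropic spacing", {
  expect_equal(calibrate_width(200, c(10, 10), c(10, 210), 0.01, 0.01), 2)
  expect_equal(calibrate_width(0, c(1, 1), c(1, 1), 0.01, 0.01), 0)
  d <- 100 / sqrt(2)
  expect_equal(calibrate_width(100, c(0, 0), c(d, d), 0.02, 0.01),
               sqrt((d * 0.02)^2 + (d * 0.01)^2), tolerance = 1e-9)
  expect_equal(calibrate_width(100, c(0, 0), c(d, d), 0.02, 0.01),
               1.5811, tolerance = 1e-4)
  expect_error(calibrate_width(10, c(0, 0), c(0, 10), -0.01, 0.01), "positive")
})

test_that("per-frame width tables are written as CSV", {
  vid <- make_effusion_video(n_frames = 3, t0 = 15, a = 5, period = 24)
  ms <- lapply(seq_along(vid$masks), function(i) {
    frame_max_width(vid$masks[[i]], frame_index = i)
  })
  f <- tempfile(fileext = ".csv")
  write_width_csv(ms, f)
  df <- read.csv(f)
  expect_equal(nrow(df), 3)
  expect_named(df, c("frame_index", "row", "width_px", "width_cm",
                     "entry_row", "entry_col", "exit_row", "exit_col"))
})
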