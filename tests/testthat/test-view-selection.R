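test_that("frame_top_view takes the argmax with the fixed tie-break order", {
  expect_equal(frame_top_view(c(0.1, 0.1, 0.6, 0.1, 0.1)),
               list(view = "A4C", probability = 0.6))
  expect_equal(frame_top_view(c(0.2, 0.2, 0.2, 0.2, 0.2)),
               list(view = "PLAX", probability = 0.2))
  expect_equal(frame_top_view(c(0, 0, 0, 0, 1)),
               list(view = "OTHER", probability = 1))
  expect_error(frame_top_view(c(0.5, 0.5)), "5 values")
  expect_error(frame_top_view(c(0.5, 0.5, 0.5, 0.5, 0.5)), "sum")
})

test_that("frame quality requires a primary view at or above the floor", {
  cfg <- selection_config()
  plax_high <- c(0.9, 0.025, 0.025, 0.025, 0.025)
  other_high <- c(0.0125, 0.0125, 0.0125, 0.0125, 0.95)
  a4c_low <- c(0.13, 0.13, 0.49, 0.12, 0.13)
  expect_true(frame_meets_quality(plax_high, cfg))
  expect_false(frame_meets_quality(other_high, cfg))
  expect_false(frame_meets_quality(a4c_low, cfg))
})

test_that("a uniform primary-view stream accepts the earliest window", {
  s <- make_score_stream(60, 1, 60, view = "PLAX", confidence = 0.9)
  out <- select_window(s)
  expect_equal(out$status, "ACCEPTED")
  expect_equal(out$window$start_frame, 1L)
  expect_equal(out$window$view, "PLAX")
  expect_equal(out$window$mean_confidence, 0.9, tolerance = 1e-12)
  expect_equal(out$window$majority_count, 48L)
})

test_that("the best fully-qualifying window is found among all candidates", {
  # 40 low-quality frames then 60 A4C frames: the window must start at the
  # first A4C frame
  s <- make_score_stream(100, 41, 60, view = "A4C", confidence = 0.95,
                         background_view = "OTHER", background_confidence = 0.9)
  out <- select_window(s)
  expect_equal(out$status, "ACCEPTED")
  expect_equal(out$window$start_frame, 41L)
  expect_equal(out$window$view, "A4C")
  expect_equal(out$window$mean_confidence, 0.95, tolerance = 1e-12)

  # independent check: enumerate all 53 windows by brute force
  p <- as.matrix(s[, VIEW_CLASSES])
  top_i <- max.col(p, ties.method = "first")
  top_p <- p[cbind(seq_len(100), top_i)]
  ok <- top_i <= 4 & top_p >= 0.5
  cand <- which(vapply(1:53, function(st) all(ok[st:(st + 47)]), logical(1)))
  expect_equal(min(cand), 41L)
})

test_that("clips without 48 consecutive qualifying frames are excluded", {
  s47 <- make_score_stream(100, 41, 47, view = "PSAX", confidence = 0.9)
  expect_equal(select_window(s47)$status, "NO_QUALIFYING_WINDOW")
  short <- make_score_stream(30, 1, 30, view = "PLAX", confidence = 0.9)
  expect_equal(select_window(short)$status, "NO_QUALIFYING_WINDOW")
  expect_null(select_window(s47)$window)
})

test_that("the mean-confidence gate rejects low-confidence windows", {
  s <- make_score_stream(60, 1, 60, view = "PLAX", confidence = 0.7)
  expect_equal(select_window(s)$status, "CONFIDENCE_GATE_FAILED")
  # lowering the gate admits the same stream
  out <- select_window(s, selection_config(mean_confidence_gate = 0.6))
  expect_equal(out$status, "ACCEPTED")
})

test_that("selection is deterministic and shift-equivariant", {
  base <- make_score_stream(80, 11, 60, view = "SC", confidence = 0.92)
  ref <- select_window(base)
  expect_identical(select_window(base), ref)
  other_row <- c(0.025, 0.025, 0.025, 0.025, 0.9)
  set.seed(42)
  for (k in sample(1:40, 20, replace = TRUE)) {
    padded <- frame_scores(rbind(matrix(rep(other_row, k), k, 5, byrow = TRUE),
                                 as.matrix(base[, VIEW_CLASSES])))
    out <- select_window(padded)
    expect_equal(out$status, "ACCEPTED")
    expect_equal(out$window$start_frame, ref$window$start_frame + k)
    expect_equal(out$window$mean_confidence, ref$window$mean_confidence)
    expect_equal(out$window$view, ref$window$view)
  }
})

test_that("raising the confidence gate never converts a rejection into acceptance", {
  set.seed(1)
  confs <- c(0.55, 0.72, 0.95, runif(7, 0.5, 1))
  monotone_ok <- vapply(confs, function(conf) {
    s <- make_score_stream(70, sample(1:20, 1), 50,
                           view = sample(PRIMARY_VIEWS, 1), confidence = conf)
    lo <- select_window(s, selection_config(mean_confidence_gate = 0.6))
    hi <- select_window(s, selection_config(mean_confidence_gate = 0.9))
    !(lo$status != "ACCEPTED" && hi$status == "ACCEPTED")
  }, logical(1))
  expect_true(all(monotone_ok))
  # and the gates genuinely separate these streams
  s_mid <- make_score_stream(70, 5, 60, view = "PLAX", confidence = 0.72)
  expect_equal(select_window(s_mid, selection_config(mean_confidence_gate = 0.6))$status,
               "ACCEPTED")
  expect_equal(select_window(s_mid, selection_config(mean_confidence_gate = 0.9))$status,
               "CONFIDENCE_GATE_FAILED")
})

test_that("every accepted window satisfies the per-frame quality criterion", {
  s <- make_score_stream(120, 31, 70, view = "A4C", confidence = 0.88)
  out <- select_window(s)
  expect_equal(out$status, "ACCEPTED")
  cfg <- selection_config()
  idx <- out$window$start_frame + seq_len(out$window$length) - 1L
  p <- as.matrix(s[, VIEW_CLASSES])
  for (i in idx) expect_true(frame_meets_quality(p[i, ], cfg))
})

test_that("a single-frame window with open gates picks the global best primary frame", {
  set.seed(99)
  n <- 50
  prob <- t(vapply(seq_len(n), function(i) {
    x <- runif(5); x / sum(x)
  }, numeric(5)))
  s <- frame_scores(prob)
  cfg <- selection_config(window_length = 1, frame_quality_floor = 0,
                          mean_confidence_gate = 0)
  out <- select_window(s, cfg)
  # oracle: linear scan for the top-confidence primary-view frame
  top_i <- max.col(prob, ties.method = "first")
  top_p <- prob[cbind(seq_len(n), top_i)]
  prim <- which(top_i <= 4)
  best <- prim[which.max(top_p[prim])]
  expect_equal(out$status, "ACCEPTED")
  expect_equal(out$window$start_frame, best)
  expect_equal(out$window$mean_confidence, top_p[best])
})

test_that("run_classifier preserves order and surfaces frame-level failures", {
  frames <- replicate(10, matrix(0, 4, 4), simplify = FALSE)
  s <- run_classifier(frames, function(f, i) c(0, 0, 1, 0, 0))
  expect_s3_class(s, "frame_scores")
  expect_equal(nrow(s), 10)
  expect_true(all(s$A4C == 1))

  failing <- function(f, i) if (i == 3) stop("boom") else c(1, 0, 0, 0, 0)
  expect_error(run_classifier(frames, failing), "frame 3")
  bad_arity <- function(f, i) c(0.5, 0.5)
  expect_error(run_classifier(frames, bad_arity), "expected 5")

  tbl <- make_score_stream(10, 2, 5, view = "PSAX", confidence = 0.8)
  replay <- run_classifier(frames, table_classifier(tbl))
  expect_equal(as.matrix(replay[, VIEW_CLASSES]), as.matrix(tbl[, VIEW_CLASSES]))
})

test_that("score streams validate their invariants and round-trip as CSV", {
  expect_error(frame_scores(matrix(0.3, 3, 5)), "sum to 1")
  expect_error(frame_scores(matrix(0.2, 3, 5), frame_index = c(1, 3, 4)),
               "consecutive")
  s <- make_score_stream(20, 5, 10, view = "SC", confidence = 0.85)
  f <- tempfile(fileext = ".csv")
  write_score_stream(s, f)
  s2 <- read_score_stream(f)
  expect_equal(as.matrix(s2[, VIEW_CLASSES]), as.matrix(s[, VIEW_CLASSES]))
  expect_equal(s2$frame_index, s$frame_index)
})
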