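#' Build a per-frame view-score stream
#'
#' A score stream holds, for each frame of a clip, the classifier's
#' probability over the five view classes. Probabilities in each row must
#' sum to 1 (tolerance 1e-6) and frame indices must be consecutive.
#'
#' @param prob Numeric matrix with one row per frame and 5 columns in the
#'   order of [VIEW_CLASSES], or a data.frame with those columns.
#' @param frame_index Integer vector of frame labels; defaults to `1:n`.
#'   Must be consecutive (step 1).
#' @return A data.frame of class `frame_scores` with columns `frame_index`,
#'   `PLAX`, `PSAX`, `A4C`, `SC`, `OTHER`.
#' @export
frame_scores <- function(prob, frame_index = NULL) {
  prob <- as.matrix(prob)
  if (ncol(prob) != 5L) stop("score matrix must have 5 columns (one per view class)")
  colnames(prob) <- VIEW_CLASSES
  if (anyNA(prob) || any(prob < 0) || any(prob > 1)) {
    stop("probabilities must lie in [0, 1] with no missing values")
  }
  if (any(abs(rowSums(prob) - 1) > 1e-6)) {
    stop("each frame's probabilities must sum to 1 (tolerance 1e-6)")
  }
  n <- nrow(prob)
  if (is.null(frame_index)) frame_index <- seq_len(n)
  frame_index <- as.integer(frame_index)
  if (length(frame_index) != n) stop("frame_index length must match rows")
  if (n > 1L && any(diff(frame_index) != 1L)) {
    stop("frame_index must be consecutive")
  }
  if (anyDuplicated(frame_index)) stop("frame_index must be unique")
  out <- data.frame(frame_index = frame_index, prob)
  class(out) <- c("frame_scores", "data.frame")
  out
}

#' Read / write a score stream as CSV
#'
#' The on-disk dialect has columns `frame_index, p_plax, p_psax, p_a4c,
#' p_sc, p_other`.
#'
#' @param path File path.
#' @return `read_score_stream()`: a [frame_scores()] object.
#' @export
read_score_stream <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame_index", "p_plax", "p_psax", "p_a4c", "p_sc", "p_other")
  if (!all(need %in% names(df))) {
    stop("score CSV must have columns: ", paste(need, collapse = ", "))
  }
  frame_scores(as.matrix(df[, need[-1]]), frame_index = df$frame_index)
}

#' @rdname read_score_stream
#' @param scores A [frame_scores()] object.
#' @export
write_score_stream <- function(scores, path) {
  df <- data.frame(frame_index = scores$frame_index,
                   p_plax = scores$PLAX, p_psax = scores$PSAX,
                   p_a4c = scores$A4C, p_sc = scores$SC, p_other = scores$OTHER)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Configuration for moving-window view selection
#'
#' Houses the clip-selection constants: a 48-frame window, a per-frame
#' quality floor of 0.5 (the frame's top view must be a primary view with at
#' least 50% confidence) and a 0.8 gate on the mean confidence of the
#' selected window.
#'
#' @param window_length Frames per window (>= 1).
#' @param frame_quality_floor Minimum top-1 probability for a frame to
#'   qualify; also requires the top-1 class to be a primary view.
#' @param mean_confidence_gate Minimum mean top-1 probability of the
#'   selected window.
#' @param stride Window start step in frames.
#' @return List of class `selection_config`.
#' @export
selection_config <- function(window_length = 48L, frame_quality_floor = 0.5,
                             mean_confidence_gate = 0.8, stride = 1L) {
  window_length <- as.integer(window_length)
  stride <- as.integer(stride)
  if (window_length < 1L) stop("window_length must be >= 1")
  if (stride < 1L) stop("stride must be >= 1")
  if (frame_quality_floor < 0 || mean_confidence_gate > 1 ||
      frame_quality_floor > mean_confidence_gate) {
    stop("need 0 <= frame_quality_floor <= mean_confidence_gate <= 1")
  }
  structure(list(window_length = window_length,
                 frame_quality_floor = frame_quality_floor,
                 mean_confidence_gate = mean_confidence_gate,
                 stride = stride),
            class = "selection_config")
}

score_matrix <- function(scores) {
  as.matrix(scores[, VIEW_CLASSES, drop = FALSE])
}

#' Top view class of a single frame
#'
#' Argmax over the five class probabilities; ties broken by the fixed class
#' order PLAX < PSAX < A4C < SC < OTHER.
#'
#' @param probabilities Numeric vector of 5 probabilities summing to 1.
#' @return List with `view` (character) and `probability`.
#' @examples
#' frame_top_view(c(0.1, 0.1, 0.6, 0.1, 0.1))  # A4C, 0.6
#' @export
frame_top_view <- function(probabilities) {
  if (length(probabilities) != 5L || anyNA(probabilities) ||
      any(probabilities < 0 | probabilities > 1) ||
      abs(sum(probabilities) - 1) > 1e-6) {
    stop("probabilities must be 5 values in [0, 1] summing to 1")
  }
  i <- which.max(probabilities)  # which.max takes the first maximum: fixed order
  list(view = VIEW_CLASSES[i], probability = as.numeric(probabilities[i]))
}

#' Does a frame meet the per-frame quality criterion?
#'
#' True iff the frame's top class is one of the four primary views and its
#' probability is at least `frame_quality_floor`.
#'
#' @param probabilities Numeric vector of 5 probabilities.
#' @param config A [selection_config()].
#' @return Logical scalar.
#' @export
frame_meets_quality <- function(probabilities, config = selection_config()) {
  top <- frame_top_view(probabilities)
  top$view %in% PRIMARY_VIEWS && top$probability >= config$frame_quality_floor
}

#' Moving-window view selection (MWVS)
#'
#' Scans a per-frame view-score stream with a sliding window (default 48
#' frames, stride 1) and selects the best-quality window of a primary view.
#' A window is a candidate iff every frame in it individually meets the
#' quality criterion (top view primary, probability >= floor). The window's
#' view label is the majority vote of its frames' top classes (ties broken
#' by larger summed probability for the class, then fixed class order).
#' Candidates are ranked by majority count, then mean top-1 probability;
#' the earliest start wins remaining ties. Finally the winner's mean top-1
#' probability must reach `mean_confidence_gate` (default 0.8) or the clip
#' is rejected.
#'
#' @param scores A [frame_scores()] stream (or matrix acceptable to it).
#' @param config A [selection_config()].
#' @return List of class `selection_outcome` with elements
#'   * `status`: `"ACCEPTED"`, `"NO_QUALIFYING_WINDOW"` or
#'     `"CONFIDENCE_GATE_FAILED"`,
#'   * `window`: when accepted, a list with `start_frame` (the frame_index
#'     label of the first frame), `length`, `view`, `mean_confidence`,
#'     `majority_count`; otherwise `NULL`.
#'
#' Streams shorter than the window are rejected with
#' `NO_QUALIFYING_WINDOW` (clips lacking enough consecutive frames are
#' excluded, not padded).
#' @export
select_window <- function(scores, config = selection_config()) {
  if (!inherits(scores, "frame_scores")) scores <- frame_scores(scores)
  n <- nrow(scores)
  w <- config$window_length
  outcome <- function(status, window = NULL) {
    structure(list(status = status, window = window), class = "selection_outcome")
  }
  if (n < w) return(outcome("NO_QUALIFYING_WINDOW"))

  p <- score_matrix(scores)
  top_i <- max.col(p, ties.method = "first")
  top_p <- p[cbind(seq_len(n), top_i)]
  ok <- top_i <= 4L & top_p >= config$frame_quality_floor

  starts <- seq.int(1L, n - w + 1L, by = config$stride)
  # candidate iff all frames qualify: windowed sum of ok
  cok <- cumsum(c(0L, ok))
  all_ok <- (cok[starts + w] - cok[starts]) == w
  starts <- starts[all_ok]
  if (!length(starts)) return(outcome("NO_QUALIFYING_WINDOW"))

  best <- NULL
  for (s in starts) {
    idx <- s:(s + w - 1L)
    votes <- tabulate(top_i[idx], nbins = 5L)
    mc <- max(votes)
    tied <- which(votes == mc)
    if (length(tied) > 1L) {
      mass <- vapply(tied, function(k) sum(p[idx, k]), numeric(1))
      tied <- tied[mass == max(mass)]   # then fixed class order: first of remaining
    }
    view_i <- tied[1L]
    conf <- mean(top_p[idx])
    # strict improvement beyond float jitter, so exact ties keep the
    # earliest window
    if (is.null(best) || mc > best$majority_count ||
        (mc == best$majority_count && conf > best$conf + 1e-12)) {
      best <- list(start = s, view = VIEW_CLASSES[view_i],
                   majority_count = mc, conf = conf)
    }
  }
  if (best$conf < config$mean_confidence_gate) {
    return(outcome("CONFIDENCE_GATE_FAILED"))
  }
  outcome("ACCEPTED", window = list(
    start_frame = scores$frame_index[best$start],
    length = w,
    view = best$view,
    mean_confidence = best$conf,
    majority_count = as.integer(best$majority_count)
  ))
}

#' @export
print.selection_outcome <- function(x, ...) {
  if (x$status == "ACCEPTED") {
    cat(sprintf("<selection_outcome> ACCEPTED: %s window of %d frames from frame %d, mean confidence %.3f\n",
                x$window$view, x$window$length, x$window$start_frame,
                x$window$mean_confidence))
  } else {
    cat(sprintf("<selection_outcome> %s\n", x$status))
  }
  invisible(x)
}

#' Run a per-frame view classifier over a clip
#'
#' Applies a pluggable classifier to every frame and assembles the score
#' stream. The classifier is any function `f(frame, index)` returning 5
#' probabilities in the order of [VIEW_CLASSES]; the trained network the
#' pipeline was designed around is one such function, as is a fixture that
#' replays scores from a table.
#'
#' @param frames List of 2D grayscale matrices (or an `echo_video`).
#' @param classifier Function of `(frame, index)` returning a numeric
#'   5-vector.
#' @return A [frame_scores()] stream with indices `1:n`.
#' @export
run_classifier <- function(frames, classifier) {
  if (inherits(frames, "echo_video")) frames <- frames$frames
  n <- length(frames)
  if (!n) stop("no frames to classify")
  prob <- matrix(NA_real_, n, 5L)
  for (i in seq_len(n)) {
    res <- tryCatch(classifier(frames[[i]], i), error = function(e) {
      stop(sprintf("classifier failed on frame %d: %s", i, conditionMessage(e)),
           call. = FALSE)
    })
    if (!is.numeric(res) || length(res) != 5L) {
      stop(sprintf("classifier returned %d value(s) for frame %d; expected 5",
                   length(res), i))
    }
    prob[i, ] <- res
  }
  frame_scores(prob)
}

#' Constant-score fixture classifier
#'
#' Returns a classifier that assigns probability `confidence` to `view` on
#' every frame, spreading the remaining mass uniformly over the other four
#' classes. Useful for exercising the pipeline without a trained network.
#'
#' @param view One of [VIEW_CLASSES].
#' @param confidence Probability assigned to `view`.
#' @return A classifier function for [run_classifier()].
#' @export
constant_classifier <- function(view = "PLAX", confidence = 0.95) {
  view <- match.arg(view, VIEW_CLASSES)
  p <- rep((1 - confidence) / 4, 5)
  p[match(view, VIEW_CLASSES)] <- confidence
  function(frame, index) p
}

#' Fixture classifier replaying a score table
#'
#' @param scores A [frame_scores()] object with one row per frame.
#' @return A classifier function for [run_classifier()].
#' @export
table_classifier <- function(scores) {
  p <- score_matrix(scores)
  function(frame, index) {
    if (index > nrow(p)) stop("no scores for frame ", index)
    p[index, ]
  }
}
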