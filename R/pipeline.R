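#' Run the end-to-end effusion measurement pipeline
#'
#' For each input clip: read the DICOM, score every frame with the view
#' classifier, select the best window by moving-window view selection; when
#' a window is accepted, segment its frames, measure the maximal
#' boundary-normal chord width per frame, take the clip maximum, calibrate
#' to centimetres using the clip's pixel spacing and grade the severity.
#' Rejected clips carry their rejection status and no width. Failures are
#' isolated per file: one unreadable input yields one error entry and the
#' pipeline continues.
#'
#' @param paths Character vector of DICOM paths, or a list of `echo_video`
#'   objects.
#' @param classifier Per-frame view classifier for [run_classifier()].
#' @param segmenter Per-frame segmenter for [segment_video()]; when `NULL`
#'   the masks carried by `segment_with` cannot be derived and an error is
#'   raised for accepted clips.
#' @param selection A [selection_config()].
#' @param width A [width_config()].
#' @param grading A [grading_config()].
#' @param verbose Log per-step timings via [message()].
#' @return List of `effusion_report` objects (one per input, error entries
#'   included with `status = "ERROR"`).
#' @export
run_pipeline <- function(paths, classifier, segmenter,
                         selection = selection_config(),
                         width = width_config(),
                         grading = grading_config(),
                         verbose = FALSE) {
  if (!length(paths)) stop("need at least one input")
  lapply(seq_along(paths), function(i) {
    src <- if (is.character(paths)) paths[[i]] else
      paths[[i]]$source_id %||% paste0("video_", i)
    tryCatch({
      t0 <- proc.time()[["elapsed"]]
      video <- if (is.character(paths)) read_dicom(paths[[i]]) else paths[[i]]
      scores <- run_classifier(video, classifier)
      sel <- select_window(scores, selection)
      if (verbose) {
        message(sprintf("[%s] selection: %s (%.2fs)", src, sel$status,
                        proc.time()[["elapsed"]] - t0))
      }
      if (sel$status != "ACCEPTED") {
        return(effusion_report(src, sel))
      }
      s <- match(sel$window$start_frame, scores$frame_index)
      idx <- s:(s + sel$window$length - 1L)
      segs <- segment_video(video$frames[idx], segmenter)
      for (j in seq_along(segs)) segs[[j]]$frame_index <- idx[j]
      vm <- video_max_width(segs, width)
      wcm <- if (is.null(vm$max)) 0 else {
        calibrate_width(vm$max$width_px, vm$max$entry, vm$max$exit,
                        video$spacing_row, video$spacing_col)
      }
      if (verbose) {
        message(sprintf("[%s] width %.3f cm (%.2fs)", src, wcm,
                        proc.time()[["elapsed"]] - t0))
      }
      effusion_report(src, sel, per_frame = vm$per_frame,
                      video_width_cm = wcm,
                      grade = as.character(grade_effusion(wcm, grading)),
                      spacing = c(video$spacing_row, video$spacing_col),
                      spacing_source = video$spacing_source %||% "input",
                      max_frame = vm$max_frame)
    }, error = function(e) {
      structure(list(source_id = src, status = "ERROR",
                     error = conditionMessage(e)),
                class = "effusion_report")
    })
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-clip effusion report
#'
#' @param source_id Clip identifier.
#' @param selection A `selection_outcome`.
#' @param per_frame Optional per-frame width data.frame.
#' @param video_width_cm Calibrated clip maximum width.
#' @param grade Severity label.
#' @param spacing `c(row, col)` cm/px used for calibration.
#' @param spacing_source Where the calibration came from.
#' @param max_frame Frame index attaining the maximum.
#' @return List of class `effusion_report`.
#' @export
effusion_report <- function(source_id, selection, per_frame = NULL,
                            video_width_cm = NA_real_, grade = NA_character_,
                            spacing = NULL, spacing_source = NULL,
                            max_frame = NA_integer_) {
  structure(list(source_id = source_id, status = selection$status,
                 window = selection$window, per_frame = per_frame,
                 video_width_cm = video_width_cm, grade = grade,
                 spacing = spacing, spacing_source = spacing_source,
                 max_frame = max_frame),
            class = "effusion_report")
}

#' @export
print.effusion_report <- function(x, ...) {
  if (identical(x$status, "ERROR")) {
    cat(sprintf("<effusion_report> %s: ERROR (%s)\n", x$source_id, x$error))
  } else if (identical(x$status, "ACCEPTED")) {
    cat(sprintf("<effusion_report> %s: %s view, width %.3f cm (%s), max at frame %s\n",
                x$source_id, x$window$view, x$video_width_cm, x$grade,
                x$max_frame))
  } else {
    cat(sprintf("<effusion_report> %s: %s\n", x$source_id, x$status))
  }
  invisible(x)
}

#' Write pipeline reports to CSV and JSON
#'
#' The CSV summary has one row per clip
#' (`source_id,status,view,mean_confidence,width_cm,grade`); the JSON file
#' carries the full per-frame detail and round-trips through
#' [read_report_json()].
#'
#' @param reports List of `effusion_report`.
#' @param csv_path,json_path Output paths (`NULL` to skip either).
#' @return Invisible list of written paths.
#' @export
write_report <- function(reports, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    df <- do.call(rbind, lapply(reports, function(r) {
      data.frame(source_id = r$source_id, status = r$status,
                 view = if (!is.null(r$window)) r$window$view else NA_character_,
                 mean_confidence = if (!is.null(r$window)) r$window$mean_confidence else NA_real_,
                 width_cm = if (is.null(r$video_width_cm)) NA_real_ else r$video_width_cm,
                 grade = if (is.null(r$grade)) NA_character_ else r$grade)
    }))
    utils::write.csv(df, csv_path, row.names = FALSE, na = "")
  }
  if (!is.null(json_path)) {
    payload <- lapply(reports, function(r) {
      r <- unclass(r)
      if (!is.null(r$per_frame)) r$per_frame <- as.data.frame(r$per_frame)
      r
    })
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", na = "null")
  }
  invisible(list(csv = csv_path, json = json_path))
}

#' @rdname write_report
#' @param path JSON path written by `write_report()`.
#' @export
read_report_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(payload, function(r) {
    if (!is.null(r$per_frame)) r$per_frame <- as.data.frame(r$per_frame)
    if (!is.null(r$spacing)) r$spacing <- as.numeric(r$spacing)
    structure(r, class = "effusion_report")
  })
}
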