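#' Keypoint streams
#'
#' A keypoint stream holds one video's multi-person 2D pose detections in long
#' form: one row per detected (frame, person, keypoint) with pixel coordinates
#' and a detection confidence. Keypoint indices follow the OpenPose BODY_25
#' layout (0-based: 1 = neck, 4 = right wrist, 8 = mid hip). A keypoint with
#' confidence 0 is undetected; undetected slots are not stored as rows, they
#' re-appear as zero-filled placeholders when the stream is written out.
#'
#' @param detections data frame with columns `frame` (0-based), `person`
#'   (0-based index within frame), `keypoint` (0-24), `x`, `y`, `confidence`.
#' @param fps frames per second (> 0).
#' @param n_frames total number of frames, including frames with no people.
#' @return a `keypoint_stream` tibble with `fps` and `n_frames` attributes.
#' @export
keypoint_stream <- function(detections, fps, n_frames) {
  detections <- tibble::as_tibble(detections)
  required <- c("frame", "person", "keypoint", "x", "y", "confidence")
  miss <- setdiff(required, names(detections))
  if (length(miss) > 0) stop("detections lack column(s): ", paste(miss, collapse = ", "))
  stopifnot(fps > 0, n_frames >= 0)
  if (nrow(detections) > 0) {
    if (any(detections$frame < 0) || any(detections$frame >= n_frames)) {
      stop("frame indices must lie in [0, n_frames)")
    }
    if (any(detections$keypoint < 0 | detections$keypoint > 24)) {
      stop("keypoint indices must lie in 0..24 (BODY_25)")
    }
    if (any(detections$confidence < 0 | detections$confidence > 1)) {
      stop("confidence must lie in [0, 1]")
    }
  }
  out <- detections[required]
  out$frame <- as.integer(out$frame)
  out$person <- as.integer(out$person)
  out$keypoint <- as.integer(out$keypoint)
  attr(out, "fps") <- fps
  attr(out, "n_frames") <- as.integer(n_frames)
  class(out) <- c("keypoint_stream", class(out))
  out
}

#' @export
print.keypoint_stream <- function(x, ...) {
  cat("<keypoint_stream> ", attr(x, "n_frames"), " frames @ ", attr(x, "fps"),
      " fps, ", nrow(x), " detected keypoints\n", sep = "")
  NextMethod()
}

#' @rdname keypoint_stream
#' @param x a `keypoint_stream`.
#' @export
stream_fps <- function(x) attr(x, "fps")

#' @rdname keypoint_stream
#' @export
stream_n_frames <- function(x) attr(x, "n_frames")

#' Read an OpenPose BODY_25 keypoint stream
#'
#' Accepts either a single concatenated stream file (a JSON array of frame
#' objects, each `{"frame_index": i, "people": [{"pose_keypoints_2d": [75
#' floats]}]}`) or a directory of per-frame OpenPose demo output files
#' (`*_keypoints.json`, ordered by filename, each holding one frame's
#' `people`). Person arrays whose length is not 75 (25 keypoints times x, y,
#' confidence) are rejected with the offending frame identified. Zero-confidence
#' triples are dropped (undetected keypoints).
#'
#' @param path stream file or directory of per-frame files.
#' @param fps frames per second of the source video.
#' @return a [keypoint_stream()].
#' @export
read_keypoint_stream <- function(path, fps) {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "_keypoints\\.json$", full.names = TRUE))
    if (length(files) == 0) stop("no *_keypoints.json files in ", path)
    frames <- lapply(seq_along(files), function(i) {
      doc <- jsonlite::fromJSON(files[i], simplifyVector = FALSE)
      list(frame_index = i - 1L, people = doc$people)
    })
  } else {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    frames <- doc
    idx <- vapply(frames, function(f) as.integer(f$frame_index), integer(1))
    if (any(diff(idx) <= 0)) stop("non-monotone frame indices in ", path)
  }
  rows <- vector("list", length(frames))
  n_frames <- 0L
  for (f in frames) {
    fi <- as.integer(f$frame_index)
    n_frames <- max(n_frames, fi + 1L)
    people <- f$people
    if (length(people) == 0) next
    per_person <- vector("list", length(people))
    for (p in seq_along(people)) {
      kp <- as.numeric(unlist(people[[p]]$pose_keypoints_2d, use.names = FALSE))
      if (length(kp) != 75) {
        stop("frame ", fi, ", person ", p - 1,
             ": pose_keypoints_2d has length ", length(kp), ", expected 75")
      }
      m <- matrix(kp, ncol = 3, byrow = TRUE)
      keep <- which(m[, 3] > 0)
      if (length(keep) == 0) next
      per_person[[p]] <- data.frame(
        frame = fi, person = p - 1L, keypoint = keep - 1L,
        x = m[keep, 1], y = m[keep, 2], confidence = m[keep, 3]
      )
    }
    rows[[fi + 1L]] <- do.call(rbind, per_person)
  }
  det <- do.call(rbind, rows)
  if (is.null(det)) {
    det <- data.frame(frame = integer(), person = integer(), keypoint = integer(),
                      x = numeric(), y = numeric(), confidence = numeric())
  }
  keypoint_stream(det, fps = fps, n_frames = n_frames)
}

#' Write a keypoint stream as a concatenated OpenPose JSON file
#'
#' Emits one JSON array with one object per frame (including frames with no
#' detections) in the BODY_25 dialect [read_keypoint_stream()] accepts.
#' Undetected keypoint slots are written as (0, 0, 0) placeholder triples so
#' every person array has the full 75 floats.
#'
#' @param stream a [keypoint_stream()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_keypoint_stream <- function(stream, path) {
  stopifnot(inherits(stream, "keypoint_stream"))
  n <- stream_n_frames(stream)
  by_frame <- split(seq_len(nrow(stream)), factor(stream$frame, levels = 0:(n - 1)))
  frames <- vector("list", n)
  for (fi in seq_len(n)) {
    rows <- by_frame[[fi]]
    people <- list()
    if (length(rows) > 0) {
      sub <- stream[rows, ]
      for (p in sort(unique(sub$person))) {
        ps <- sub[sub$person == p, ]
        flat <- numeric(75)
        flat[3 * ps$keypoint + 1] <- ps$x
        flat[3 * ps$keypoint + 2] <- ps$y
        flat[3 * ps$keypoint + 3] <- ps$confidence
        people[[length(people) + 1]] <- list(pose_keypoints_2d = flat)
      }
    }
    frames[[fi]] <- list(frame_index = fi - 1L, people = people)
  }
  jsonlite::write_json(frames, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Video metadata
#'
#' Frame rate, resolution and the origin point A: the centre of the table's
#' edge next to the participant, from which pixel distances are measured.
#'
#' @param fps frames per second (> 0).
#' @param origin_a numeric length-2, pixel coordinates (x rightward, y
#'   downward) of point A; must lie inside the frame.
#' @param width,height frame resolution in pixels.
#' @return a `video_meta` list.
#' @export
video_meta <- function(fps, origin_a, width, height) {
  stopifnot(fps > 0, length(origin_a) == 2, width > 0, height > 0)
  if (origin_a[1] < 0 || origin_a[1] > width || origin_a[2] < 0 || origin_a[2] > height) {
    stop("origin_a must lie inside the frame resolution")
  }
  structure(list(fps = fps, origin_a = as.numeric(origin_a),
                 width = width, height = height),
            class = "video_meta")
}

#' Read an activity manifest and video metadata
#'
#' The manifest is a CSV with columns `activity`, `start_s`, `end_s`; metadata
#' is a JSON file with fields `fps`, `origin_A_x`, `origin_A_y`, `width`,
#' `height`. The Table-play composite (the five table activities) is
#' materialised automatically when all its members are present.
#'
#' @param manifest_path manifest CSV.
#' @param meta_path metadata JSON.
#' @return list with elements `timeline` and `meta`.
#' @export
read_manifest <- function(manifest_path, meta_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  miss <- setdiff(c("activity", "start_s", "end_s"), names(man))
  if (length(miss) > 0) {
    stop("manifest lacks column(s): ", paste(miss, collapse = ", "))
  }
  comps <- list()
  if (all(.table_play_members() %in% man$activity)) {
    comps[["Table-play"]] <- .table_play_members()
  }
  tl <- timeline(data.frame(activity = man$activity, start = man$start_s,
                            end = man$end_s),
                 composites = comps)
  meta_raw <- jsonlite::fromJSON(meta_path)
  need <- c("fps", "origin_A_x", "origin_A_y", "width", "height")
  miss <- setdiff(need, names(meta_raw))
  if (length(miss) > 0) stop("meta lacks field(s): ", paste(miss, collapse = ", "))
  meta <- video_meta(meta_raw$fps, c(meta_raw$origin_A_x, meta_raw$origin_A_y),
                     meta_raw$width, meta_raw$height)
  list(timeline = tl, meta = meta)
}

#' @rdname read_manifest
#' @param tl a `timeline`.
#' @param meta a `video_meta`.
#' @param path output path (CSV for the manifest, JSON for metadata).
#' @export
write_manifest <- function(tl, path) {
  utils::write.csv(data.frame(activity = tl$activity, start_s = tl$start,
                              end_s = tl$end),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_manifest
#' @export
write_video_meta <- function(meta, path) {
  jsonlite::write_json(list(fps = meta$fps, origin_A_x = meta$origin_a[1],
                            origin_A_y = meta$origin_a[2], width = meta$width,
                            height = meta$height),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write clinician score tables
#'
#' The score table is a CSV with columns `child_id`, `activity_level_score`
#' (integer 0, 1 or 2: the clinician's rating of whether the child could sit
#' or stand appropriately during the assessment) and optionally `ados_total`.
#'
#' @param path CSV file.
#' @return tibble with columns `child_id`, `activity_level_score`,
#'   `ados_total` (NA when absent).
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("child_id", "activity_level_score"), names(df))
  if (length(miss) > 0) stop("score table lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(df$activity_level_score %in% 0:2)) {
    bad <- df$child_id[!df$activity_level_score %in% 0:2]
    stop("activity_level_score must be 0, 1 or 2 (violated for: ",
         paste(bad, collapse = ", "), ")")
  }
  if (is.null(df$ados_total)) df$ados_total <- NA_integer_
  tibble::as_tibble(df[c("child_id", "activity_level_score", "ados_total")])
}

#' @rdname read_scores
#' @param scores data frame as returned by [read_scores()].
#' @export
write_scores <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}
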