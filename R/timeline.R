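#' Activity timelines
#'
#' A timeline is the activity segmentation of one assessment video: a set of
#' named time intervals (seconds from video start) plus optional composite
#' activities defined as unions of named segments. Segments may overlap
#' (Response-to-name sits inside Free-play); features are computed per named
#' segment independently. Frames are assigned to a segment with the half-open
#' convention: a frame at time t belongs to [start, end) iff start <= t < end.
#'
#' @param segments data frame with columns `activity`, `start`, `end`
#'   (seconds; `start < end` per row).
#' @param composites named list; each element is a character vector of member
#'   activity names that must all appear in `segments`.
#' @return A `timeline` object: a tibble of segments with a `composites`
#'   attribute.
#' @examples
#' tl <- timeline(data.frame(activity = c("a", "b"), start = c(0, 10), end = c(10, 20)),
#'                composites = list(ab = c("a", "b")))
#' timeline_activities(tl)
#' @export
timeline <- function(segments, composites = list()) {
  segments <- as.data.frame(segments)
  required <- c("activity", "start", "end")
  missing_cols <- setdiff(required, names(segments))
  if (length(missing_cols) > 0) {
    stop("timeline segments lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(segments) == 0) stop("timeline must contain at least one segment")
  segments$activity <- as.character(segments$activity)
  segments$start <- as.numeric(segments$start)
  segments$end <- as.numeric(segments$end)
  bad <- which(!(segments$start < segments$end))
  if (length(bad) > 0) {
    stop("segment end must exceed start (violated by: ",
         paste(segments$activity[bad], collapse = ", "), ")")
  }
  if (anyDuplicated(segments$activity)) {
    stop("duplicate segment names: ",
         paste(unique(segments$activity[duplicated(segments$activity)]), collapse = ", "))
  }
  if (!is.list(composites)) stop("composites must be a named list")
  for (nm in names(composites)) {
    unknown <- setdiff(composites[[nm]], segments$activity)
    if (length(unknown) > 0) {
      stop("composite '", nm, "' references unknown segment(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  out <- tibble::as_tibble(segments[c("activity", "start", "end")])
  attr(out, "composites") <- composites
  class(out) <- c("timeline", class(out))
  out
}

#' @export
print.timeline <- function(x, ...) {
  cat("<timeline> ", nrow(x), " segments, ",
      length(attr(x, "composites")), " composite(s)\n", sep = "")
  NextMethod()
  comps <- attr(x, "composites")
  for (nm in names(comps)) {
    cat("composite ", nm, " = {", paste(comps[[nm]], collapse = ", "), "}\n", sep = "")
  }
  invisible(x)
}

#' @rdname timeline
#' @param x a `timeline`.
#' @export
timeline_composites <- function(x) attr(x, "composites")

#' @rdname timeline
#' @export
timeline_activities <- function(x) {
  c(x$activity, names(attr(x, "composites")))
}

#' Frames covered by a timeline activity
#'
#' Resolves an activity name (plain segment or composite) to the 0-based frame
#' indices it covers at a given frame rate, using the half-open [start, end)
#' convention. For composites, member segments are resolved independently; the
#' result keeps members separate so downstream velocity steps never span
#' disjoint members.
#'
#' @param tl a `timeline`.
#' @param activity segment or composite name.
#' @param fps frames per second (> 0).
#' @param n_frames total frames available; frames at or beyond this are dropped.
#' @return list of integer vectors, one per contributing segment (a single
#'   element for plain segments), each a sorted vector of 0-based frame indices.
#' @export
activity_frames <- function(tl, activity, fps, n_frames = Inf) {
  stopifnot(inherits(tl, "timeline"), fps > 0)
  comps <- attr(tl, "composites")
  members <- if (activity %in% names(comps)) comps[[activity]] else activity
  unknown <- setdiff(members, tl$activity)
  if (length(unknown) > 0) stop("unknown activity: ", paste(unknown, collapse = ", "))
  lapply(members, function(m) {
    row <- tl[tl$activity == m, ]
    # frame at index i has time i / fps; keep start <= i/fps < end
    lo <- ceiling(row$start * fps - 1e-9)
    hi <- ceiling(row$end * fps - 1e-9) - 1
    hi <- min(hi, n_frames - 1)
    if (hi < lo) integer(0) else as.integer(lo:hi)
  })
}

# Mean (and SD) activity durations in minutes. Table-play's published total of
# 11.89 (5.68) min is split across its five member activities: Joint-attention
# and Birthday-party keep their published means; the remaining 5.48 min is
# divided over the other three table activities.
.activity_duration_table <- function() {
  data.frame(
    activity = c("Free-play", "Joint-attention", "Anticipation-routine",
                 "Balloon-play", "Bubble-play", "Imitation", "Birthday-party",
                 "Social-routine", "Snack"),
    mean_min = c(4.00, 1.08, 1.83, 2.73, 2.96, 1.83, 5.33, 1.82, 2.00),
    sd_min   = c(1.50, 0.87, 0.90, 1.12, 1.17, 0.90, 2.22, 0.90, 0.80),
    stringsAsFactors = FALSE
  )
}

.table_play_members <- function() {
  c("Joint-attention", "Anticipation-routine", "Imitation",
    "Birthday-party", "Social-routine")
}

#' Default assessment timeline
#'
#' Builds the canonical activity timeline: Free-play (with Response-to-name
#' nested inside it), five table activities interleaved with Balloon-play and
#' Bubble-play, then Snack, plus the "Table-play" composite consolidating the
#' five table activities. Durations are the published means, multiplied by
#' `duration_scale` so that test cohorts run quickly (default 1/10 of the
#' full-length assessment; full scale is `duration_scale = 1`).
#'
#' @param duration_scale multiplier applied to all durations (> 0).
#' @return a `timeline`.
#' @export
default_timeline <- function(duration_scale = 0.1) {
  tab <- .activity_duration_table()
  .build_timeline(stats::setNames(tab$mean_min, tab$activity) * 60 * duration_scale)
}

#' Sample a per-child timeline around the canonical durations
#'
#' Draws each activity duration from a normal distribution with the published
#' mean and SD (truncated below at 20% of the mean), scaled by
#' `duration_scale`, and lays the activities out in the canonical order.
#'
#' @inheritParams default_timeline
#' @return a `timeline`.
#' @keywords internal
sample_timeline <- function(duration_scale = 0.1) {
  tab <- .activity_duration_table()
  dur <- pmax(stats::rnorm(nrow(tab), tab$mean_min, tab$sd_min), 0.2 * tab$mean_min)
  .build_timeline(stats::setNames(dur, tab$activity) * 60 * duration_scale)
}

.build_timeline <- function(durations_s) {
  order_names <- c("Free-play", "Joint-attention", "Anticipation-routine",
                   "Balloon-play", "Bubble-play", "Imitation", "Birthday-party",
                   "Social-routine", "Snack")
  ends <- cumsum(durations_s[order_names])
  starts <- ends - durations_s[order_names]
  seg <- data.frame(activity = order_names, start = unname(starts), end = unname(ends))
  # Response-to-name is a short probe nested inside Free-play
  fp <- seg[seg$activity == "Free-play", ]
  rtn_len <- 0.15 * (fp$end - fp$start)
  seg <- rbind(seg, data.frame(activity = "Response-to-name",
                               start = fp$start + 0.3 * (fp$end - fp$start),
                               end = fp$start + 0.3 * (fp$end - fp$start) + rtn_len))
  timeline(seg, composites = list("Table-play" = .table_play_members()))
}
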