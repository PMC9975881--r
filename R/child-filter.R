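#' Filter parameters for child selection
#'
#' The filter tracks the participating child among multi-person detections by
#' nearest-neighbour gating on the neck keypoint: per frame, the candidate
#' skeleton whose neck (at or above `min_confidence`) lies closest to the last
#' confirmed child neck position is selected, provided that distance is at
#' most `gate_radius`. Frames with no valid candidate are gaps; the last
#' confirmed position stays the anchor for up to `max_gap` consecutive gap
#' frames, after which the track re-initialises to the candidate nearest
#' `init_position` (the child's expected seat, from the manifest).
#'
#' @param init_position numeric length-2, pixel coordinates used to start the
#'   track and to re-acquire it after a long gap.
#' @param gate_radius maximum allowed neck jump between consecutive
#'   selections, pixels (> 0). Default 15% of the image diagonal when built
#'   via [default_filter_params()].
#' @param min_confidence minimum neck detection confidence in [0, 1].
#' @param max_gap longest tolerated run of gap frames before re-initialising.
#' @return a `filter_params` list.
#' @export
filter_params <- function(init_position, gate_radius = 120,
                          min_confidence = 0.1, max_gap = 20) {
  stopifnot(length(init_position) == 2, gate_radius > 0, max_gap >= 0,
            min_confidence >= 0, min_confidence <= 1)
  structure(list(init_position = as.numeric(init_position),
                 gate_radius = gate_radius, min_confidence = min_confidence,
                 max_gap = as.integer(max_gap)),
            class = "filter_params")
}

#' @rdname filter_params
#' @param meta a [video_meta()]; the gate radius defaults to 15% of the image
#'   diagonal and the initial position to the origin point A.
#' @export
default_filter_params <- function(meta) {
  filter_params(init_position = meta$origin_a,
                gate_radius = 0.15 * sqrt(meta$width^2 + meta$height^2))
}

#' Select the child's keypoints frame by frame
#'
#' Runs the nearest-neighbour gating filter over a multi-person keypoint
#' stream and extracts the child's neck, right-wrist and mid-hip trajectories.
#' Wrist and hip samples are taken from the skeleton selected on the neck; a
#' missing wrist or hip in a selected frame becomes a gap in that trajectory
#' only, without invalidating the neck track.
#'
#' @param stream a [keypoint_stream()].
#' @param params a [filter_params()].
#' @param keypoints keypoint ids to extract trajectories for.
#' @return list with `trajectories` (named list of `trajectory` tibbles with
#'   columns `frame`, `x`, `y`) and `selection` (tibble `frame`,
#'   `selected_person` (NA on gaps), `distance` to the anchor, `gap`,
#'   `reinit`). An all-gap selection is flagged via the `all_gap` attribute of
#'   the selection record, not an error.
#' @export
filter_stream <- function(stream, params, keypoints = c(1, 4, 8)) {
  stopifnot(inherits(stream, "keypoint_stream"), inherits(params, "filter_params"))
  n_frames <- stream_n_frames(stream)
  if (n_frames == 0 || nrow(stream) == 0) stop("empty keypoint stream")
  n_people <- max(stream$person) + 1L
  # per-keypoint (frame x person) coordinate matrices; NA = not detected
  kp_mat <- function(kp, min_conf = 0) {
    sel <- stream$keypoint == kp & stream$confidence >= min_conf
    mx <- matrix(NA_real_, n_frames, n_people)
    my <- matrix(NA_real_, n_frames, n_people)
    idx <- cbind(stream$frame[sel] + 1L, stream$person[sel] + 1L)
    mx[idx] <- stream$x[sel]
    my[idx] <- stream$y[sel]
    list(x = mx, y = my)
  }
  neck <- kp_mat(1, params$min_confidence)
  anchor <- params$init_position
  confirmed <- FALSE       # anchor comes from a confirmed selection
  gap_run <- 0L
  sel_person <- rep(NA_integer_, n_frames)
  sel_dist <- rep(NA_real_, n_frames)
  reinit <- rep(FALSE, n_frames)
  for (f in seq_len(n_frames)) {
    if (confirmed && gap_run > params$max_gap) {
      anchor <- params$init_position
      confirmed <- FALSE
      reinit[f] <- TRUE
    }
    dx <- neck$x[f, ] - anchor[1]
    dy <- neck$y[f, ] - anchor[2]
    d2 <- dx * dx + dy * dy
    if (all(is.na(d2))) {
      gap_run <- gap_run + 1L
      next
    }
    p <- which.min(d2)
    d <- sqrt(d2[p])
    if (d <= params$gate_radius) {
      sel_person[f] <- p - 1L
      sel_dist[f] <- d
      anchor <- c(neck$x[f, p], neck$y[f, p])
      confirmed <- TRUE
      gap_run <- 0L
    } else {
      gap_run <- gap_run + 1L
    }
  }
  selection <- tibble::tibble(frame = 0:(n_frames - 1),
                              selected_person = sel_person,
                              distance = sel_dist,
                              gap = is.na(sel_person),
                              reinit = reinit)
  attr(selection, "all_gap") <- all(selection$gap)
  if (all(selection$gap)) {
    warning("filter selected no skeleton in any frame (all-gap track)")
  }
  trajectories <- lapply(stats::setNames(keypoints, keypoints), function(kp) {
    km <- kp_mat(kp, if (kp == 1) params$min_confidence else 0)
    ok <- which(!is.na(sel_person))
    idx <- cbind(ok, sel_person[ok] + 1L)
    x <- km$x[idx]; y <- km$y[idx]
    present <- !is.na(x)
    traj <- tibble::tibble(frame = (ok - 1L)[present], x = x[present],
                           y = y[present])
    attr(traj, "keypoint") <- kp
    class(traj) <- c("trajectory", class(traj))
    traj
  })
  list(trajectories = trajectories, selection = selection)
}

#' Audit the selection against ground-truth identities
#'
#' Estimates the identity mismatch rate the way a manual audit would: sample
#' up to `n_audit` frames (default cap 100 per stream) uniformly without
#' replacement among frames where a skeleton was selected, and count the
#' fraction whose selected skeleton is not the child.
#'
#' @param selection selection record from [filter_stream()].
#' @param truth ground-truth tibble (`frame`, `person`, `identity`), as
#'   produced by the synthetic generator.
#' @param n_audit number of frames to audit; capped at the number of selected
#'   frames.
#' @param seed integer seed for the audit sample.
#' @return fraction in [0, 1] of audited frames with a non-child selection;
#'   NA if no frame has a selection.
#' @export
mismatch_rate <- function(selection, truth, n_audit = 100, seed = 1L) {
  sel <- selection[!selection$gap, ]
  if (nrow(sel) == 0) return(NA_real_)
  set.seed(seed)
  n_audit <- min(n_audit, nrow(sel))
  audit <- sel[sample.int(nrow(sel), n_audit), ]
  key_truth <- paste(truth$frame, truth$person)
  child <- key_truth[truth$identity == "child"]
  mean(!paste(audit$frame, audit$selected_person) %in% child)
}

#' Export a selection record for manual audit
#'
#' @param selection selection record from [filter_stream()].
#' @param path output CSV.
#' @export
write_selection_record <- function(selection, path) {
  utils::write.csv(as.data.frame(selection), path, row.names = FALSE)
  invisible(path)
}
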