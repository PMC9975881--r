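#' Score-dependent motion model for synthetic children
#'
#' The synthetic child moves as a discrete-time mean-reverting (AR(1)) random
#' walk around a home position (the seat next to the table). The model is
#' parameterised by two score-indexed scales that can be tuned independently:
#' the stationary spread of the excursion from home (`excursion_scale`, pixels
#' — drives the pixel-distance features) and the per-frame step SD
#' (`step_scale`, pixels/frame — drives the instantaneous-velocity features).
#' Both must strictly increase with the activity-level score: a score-2 child
#' ("almost impossible to hold still") roams wider and faster than a score-0
#' child. The right wrist adds independent per-frame jitter on top of the body
#' trajectory; keypoints are dropped (occlusion) with probability
#' `missingness_prob` per keypoint per frame. During activities in
#' `activity_gain` (by default Balloon-play and Bubble-play, where children
#' are encouraged to move around) the excursion amplitude is multiplied by the
#' named gain.
#'
#' @param home_position numeric length-2; pixel coordinates of the child's seat.
#' @param excursion_scale_by_score named numeric, stationary excursion SD in
#'   pixels for scores "0", "1", "2"; strictly increasing.
#' @param step_scale_by_score named numeric, per-frame step SD in pixels;
#'   strictly increasing; each entry must be < 2 x the matching excursion scale.
#' @param wrist_jitter_scale median SD in pixels of independent per-frame
#'   wrist jitter; each child's own jitter SD is drawn log-normally around it
#'   with log-SD `wrist_jitter_sdlog` (children differ in hand fidgetiness).
#' @param wrist_jitter_sdlog log-SD of the per-child wrist jitter scale.
#' @param detection_noise_scale median SD in pixels of per-frame keypoint
#'   detection noise, independent per keypoint; each (child, keypoint) gets
#'   its own SD drawn log-normally with log-SD `detection_noise_sdlog` —
#'   pose-estimation jitter differs with clothing, size and lighting. This is
#'   what keeps velocity features keypoint-specific while distance features
#'   stay keypoint-redundant.
#' @param detection_noise_sdlog log-SD of the per-(child, keypoint) noise SD.
#' @param missingness_prob probability in [0, 1] that a keypoint is undetected
#'   in a given frame; either one number for all keypoints or a named vector
#'   per keypoint id. The default reflects visibility in seated assessments:
#'   the neck is rarely lost, the wrist (obscured by toys and the table) most
#'   often.
#' @param distractor_stations list of
#'   `list(position = c(x, y), scale = s, on_mean = a, off_mean = b)` entries:
#'   other people (clinician, parent) moving gently around fixed spots. They
#'   are detected intermittently — present in bursts governed by a two-state
#'   chain with mean on-run `on_mean` and mean off-run `off_mean` frames —
#'   mirroring how other people enter and leave the child's cropped view.
#' @param activity_gain named numeric: excursion multipliers per activity name.
#' @return a `motion_model` list.
#' @export
motion_model <- function(home_position = c(320, 330),
                         excursion_scale_by_score = c("0" = 25, "1" = 50, "2" = 100),
                         step_scale_by_score = c("0" = 8, "1" = 14, "2" = 24),
                         wrist_jitter_scale = 4,
                         wrist_jitter_sdlog = 0.6,
                         detection_noise_scale = 2,
                         detection_noise_sdlog = 0.7,
                         missingness_prob = c("1" = 0.02, "4" = 0.08, "8" = 0.04),
                         distractor_stations = list(
                           list(position = c(300, 100), scale = 10,
                                on_mean = 15, off_mean = 90),
                           list(position = c(560, 400), scale = 8,
                                on_mean = 15, off_mean = 90)
                         ),
                         activity_gain = c("Balloon-play" = 1.6, "Bubble-play" = 1.6)) {
  ex <- excursion_scale_by_score
  st <- step_scale_by_score
  stopifnot(length(home_position) == 2,
            all(c("0", "1", "2") %in% names(ex)),
            all(c("0", "1", "2") %in% names(st)))
  ex <- ex[c("0", "1", "2")]; st <- st[c("0", "1", "2")]
  if (any(ex < 0) || any(st < 0) || wrist_jitter_scale < 0 ||
      detection_noise_scale < 0) {
    stop("motion scales must be non-negative")
  }
  if (any(diff(ex) <= 0) || any(diff(st) <= 0)) {
    stop("excursion and step scales must strictly increase with score")
  }
  if (any(missingness_prob < 0) || any(missingness_prob > 1)) {
    stop("missingness_prob must lie in [0, 1]")
  }
  if (length(missingness_prob) > 1 &&
      !all(c("1", "4", "8") %in% names(missingness_prob))) {
    stop("per-keypoint missingness_prob needs names \"1\", \"4\", \"8\"")
  }
  ok <- st == 0 | (ex > 0 & st < 2 * ex)
  if (!all(ok)) {
    stop("step scale must be below twice the excursion scale (AR(1) feasibility)")
  }
  structure(list(home_position = as.numeric(home_position),
                 excursion_scale_by_score = ex,
                 step_scale_by_score = st,
                 wrist_jitter_scale = wrist_jitter_scale,
                 wrist_jitter_sdlog = wrist_jitter_sdlog,
                 detection_noise_scale = detection_noise_scale,
                 detection_noise_sdlog = detection_noise_sdlog,
                 missingness_prob = missingness_prob,
                 distractor_stations = distractor_stations,
                 activity_gain = activity_gain),
            class = "motion_model")
}

#' Cohort specification
#'
#' Describes a synthetic study cohort: the number of children per
#' activity-level score (default 18 / 25 / 9 at scores 0 / 1 / 2, N = 52), the
#' frame rate (default 10 fps) and the timeline template scale. Per-child
#' timelines are drawn around the canonical activity durations, scaled by
#' `duration_scale` so a default cohort simulates in seconds.
#'
#' @param group_sizes named integer vector: children per score "0", "1", "2".
#' @param fps frames per second (> 0).
#' @param duration_scale multiplier on activity durations (1 = full length).
#' @param seed integer seed controlling the whole cohort.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(group_sizes = c("0" = 18, "1" = 25, "2" = 9),
                        fps = 10, duration_scale = 0.1, seed = 1L) {
  stopifnot(all(c("0", "1", "2") %in% names(group_sizes)),
            all(group_sizes >= 0), sum(group_sizes) >= 1, fps > 0,
            duration_scale > 0)
  structure(list(group_sizes = group_sizes[c("0", "1", "2")],
                 n_children = sum(group_sizes),
                 fps = fps, duration_scale = duration_scale,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Unit AR(1) path: phi chosen so a path scaled by `excursion` has per-frame
# step SD `step` at stationarity: step_sd^2 = 2 * excursion^2 * (1 - phi).
# init = 0 starts the walk at its mean (the child seated at home); init = NULL
# draws a stationary start (distractors already mid-fidget).
.unit_ar1 <- function(n, phi, init = NULL) {
  if (is.null(init)) init <- stats::rnorm(1)
  innov <- stats::rnorm(n) * sqrt(1 - phi^2)
  as.numeric(stats::filter(innov, phi, method = "recursive", init = init))
}

.ar1_phi <- function(excursion, step) {
  if (step == 0) return(1)
  1 - step^2 / (2 * excursion^2)
}

# Per-frame excursion gain from the timeline's activity_gain entries; where
# segments overlap the largest gain wins; uncovered frames get gain 1.
.frame_gain <- function(timeline, fps, n_frames, activity_gain) {
  gain <- rep(1, n_frames)
  for (act in names(activity_gain)) {
    if (!act %in% timeline$activity) next
    for (fr in activity_frames(timeline, act, fps, n_frames)) {
      gain[fr + 1] <- pmax(gain[fr + 1], activity_gain[[act]])
    }
  }
  gain
}

# Skeleton layout relative to the body (neck) position, desk-scale pixels.
.kp_offsets <- function() {
  list("1" = c(0, 0), "4" = c(20, 8), "8" = c(0, 30))
}

# The child's seat sits this far below the origin point A (the table edge).
.home_origin_offset <- function() c(0, 90)

.miss_p <- function(model, kp) {
  mp <- model$missingness_prob
  if (length(mp) == 1) unname(mp) else unname(mp[[as.character(kp)]])
}

#' Simulate one child's keypoint stream
#'
#' Emits one BODY_25 skeleton per frame for the whole timeline. The neck
#' follows the mean-reverting body trajectory; the mid hip is a rigid offset
#' below it; the right wrist adds independent per-frame jitter. Only keypoints
#' 1, 4 and 8 are populated (the remaining BODY_25 slots appear as
#' zero-confidence placeholders on write-out). Each keypoint is independently
#' dropped with the model's missingness probability.
#'
#' @param score activity-level score (0, 1 or 2).
#' @param timeline a [timeline()] covering the assessment.
#' @param model a [motion_model()].
#' @param fps frames per second.
#' @param seed integer seed; identical arguments reproduce the stream exactly.
#' @return list with `stream` (a [keypoint_stream()] holding one person,
#'   index 0) and `truth` (tibble `frame`, `person`, `identity` = "child").
#' @export
generate_child_stream <- function(score, timeline, model, fps = 10, seed = 1L) {
  stopifnot(inherits(model, "motion_model"), inherits(timeline, "timeline"))
  score_key <- as.character(score)
  if (!score_key %in% c("0", "1", "2")) stop("unknown score level: ", score)
  n_frames <- as.integer(ceiling(max(timeline$end) * fps - 1e-9))
  if (n_frames < 1) stop("timeline spans no frames at this fps")
  sx <- model$excursion_scale_by_score[[score_key]]
  sd_step <- model$step_scale_by_score[[score_key]]
  set.seed(seed)
  if (sd_step == 0) {
    bx <- rep(0, n_frames); by <- rep(0, n_frames)
  } else {
    phi <- .ar1_phi(sx, sd_step)
    # the assessment starts with the child seated at home next to the table
    bx <- sx * .unit_ar1(n_frames, phi, init = 0)
    by <- sx * .unit_ar1(n_frames, phi, init = 0)
  }
  gain <- .frame_gain(timeline, fps, n_frames, model$activity_gain)
  bx <- bx * gain + model$home_position[1]
  by <- by * gain + model$home_position[2]
  offs <- .kp_offsets()
  rows <- lapply(names(offs), function(kp) {
    o <- offs[[kp]]
    x <- bx + o[1]; y <- by + o[2]
    if (model$detection_noise_scale > 0) {
      ns <- stats::rlnorm(1, log(model$detection_noise_scale),
                          model$detection_noise_sdlog)
      x <- x + stats::rnorm(n_frames, 0, ns)
      y <- y + stats::rnorm(n_frames, 0, ns)
    }
    if (kp == "4" && model$wrist_jitter_scale > 0) {
      wj <- stats::rlnorm(1, log(model$wrist_jitter_scale),
                          model$wrist_jitter_sdlog)
      x <- x + stats::rnorm(n_frames, 0, wj)
      y <- y + stats::rnorm(n_frames, 0, wj)
    }
    keep <- which(stats::runif(n_frames) >= .miss_p(model, kp))
    conf <- stats::runif(n_frames, 0.5, 1)
    data.frame(frame = keep - 1L, person = rep(0L, length(keep)),
               keypoint = rep(as.integer(kp), length(keep)),
               x = x[keep], y = y[keep], confidence = conf[keep])
  })
  det <- do.call(rbind, rows)
  det <- det[order(det$frame, det$keypoint), ]
  stream <- keypoint_stream(det, fps = fps, n_frames = n_frames)
  truth <- tibble::tibble(frame = sort(unique(det$frame)), person = 0L,
                          identity = "child")
  list(stream = stream, truth = truth)
}

#' Simulate distractor skeletons (clinician, parent)
#'
#' One skeleton per distractor station per frame, moving as a small-amplitude
#' AR(1) fluctuation around its station. Distractors share the child's
#' skeleton layout and missingness probability and are labelled
#' `"distractor<i>"` in the ground truth.
#'
#' @inheritParams generate_child_stream
#' @param n_frames number of frames to emit.
#' @return list with `stream` (person indices 0, 1, ... in station order) and
#'   `truth` tibble; both empty (zero people) when the model has no stations.
#' @export
generate_distractors <- function(model, n_frames, fps = 10, seed = 1L) {
  stopifnot(inherits(model, "motion_model"), n_frames >= 1)
  stations <- model$distractor_stations
  set.seed(seed)
  offs <- .kp_offsets()
  det_all <- list(); truth_all <- list()
  for (i in seq_along(stations)) {
    st <- stations[[i]]
    phi <- 0.95
    cx <- st$position[1] + st$scale * .unit_ar1(n_frames, phi)
    cy <- st$position[2] + st$scale * .unit_ar1(n_frames, phi)
    # intermittent presence: two-state chain over on/off runs
    on_mean <- if (is.null(st$on_mean)) 40 else st$on_mean
    off_mean <- if (is.null(st$off_mean)) 80 else st$off_mean
    present <- logical(n_frames)
    state <- stats::runif(1) < on_mean / (on_mean + off_mean)
    for (f in seq_len(n_frames)) {
      present[f] <- state
      flip_p <- if (state) 1 / on_mean else 1 / off_mean
      if (stats::runif(1) < flip_p) state <- !state
    }
    rows <- lapply(names(offs), function(kp) {
      o <- offs[[kp]]
      keep <- which(present & stats::runif(n_frames) >= .miss_p(model, kp))
      conf <- stats::runif(n_frames, 0.5, 1)
      data.frame(frame = keep - 1L, person = rep(i - 1L, length(keep)),
                 keypoint = rep(as.integer(kp), length(keep)),
                 x = (cx + o[1])[keep], y = (cy + o[2])[keep],
                 confidence = conf[keep])
    })
    det_all[[i]] <- do.call(rbind, rows)
    emitted <- sort(unique(det_all[[i]]$frame))
    truth_all[[i]] <- tibble::tibble(frame = emitted, person = i - 1L,
                                     identity = paste0("distractor", i))
  }
  det <- if (length(det_all) > 0) do.call(rbind, det_all) else
    data.frame(frame = integer(), person = integer(), keypoint = integer(),
               x = numeric(), y = numeric(), confidence = numeric())
  stream <- keypoint_stream(det, fps = fps, n_frames = n_frames)
  truth <- if (length(truth_all) > 0) do.call(rbind, truth_all) else
    tibble::tibble(frame = integer(), person = integer(), identity = character())
  list(stream = stream, truth = truth)
}

#' Merge a child stream with distractor skeletons into one scene
#'
#' Person indices are shuffled independently per frame (a fresh random
#' permutation each frame), so the child's slot is not constant — as in real
#' multi-person pose output, where detection order carries no identity.
#'
#' @param child,distractors results of [generate_child_stream()] and
#'   [generate_distractors()] over the same frame range.
#' @param seed integer seed for the per-frame permutation.
#' @return list with merged `stream` and `truth` (one identity label per
#'   emitted skeleton per frame).
#' @export
merge_streams <- function(child, distractors, seed = 1L) {
  fps <- stream_fps(child$stream)
  n_frames <- max(stream_n_frames(child$stream), stream_n_frames(distractors$stream))
  n_child_people <- 1L
  det_d <- distractors$stream
  det_d$person <- det_d$person + n_child_people
  truth_d <- distractors$truth
  truth_d$person <- truth_d$person + n_child_people
  det <- rbind(as.data.frame(child$stream), as.data.frame(det_d))
  truth <- rbind(child$truth, truth_d)
  n_people <- max(truth$person) + 1L
  set.seed(seed)
  # per-frame random relabelling of person slots
  perm <- matrix(0L, nrow = n_frames, ncol = n_people)
  for (f in seq_len(n_frames)) perm[f, ] <- sample.int(n_people) - 1L
  det$person <- perm[cbind(det$frame + 1L, det$person + 1L)]
  truth$person <- perm[cbind(truth$frame + 1L, truth$person + 1L)]
  det <- det[order(det$frame, det$person, det$keypoint), ]
  truth <- truth[order(truth$frame, truth$person), ]
  list(stream = keypoint_stream(det, fps = fps, n_frames = n_frames),
       truth = truth)
}

#' Generate a full synthetic cohort
#'
#' Instantiates one scene (child plus distractors) per child: per-child seeds
#' are derived deterministically from the cohort seed, the score table matches
#' the requested group sizes, and each child's timeline is drawn around the
#' canonical activity durations. The result carries complete ground-truth
#' identity labels, so filtering accuracy is measurable exactly.
#'
#' @param spec a [cohort_spec()].
#' @param model a [motion_model()].
#' @return a `synthetic_cohort` list: `children` (named list with `stream`,
#'   `truth`, `timeline` per child), `scores` tibble, `meta` ([video_meta()]),
#'   `spec`, `model`.
#' @export
generate_cohort <- function(spec, model = motion_model()) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(model, "motion_model"))
  n <- spec$n_children
  scores <- rep(0:2, times = spec$group_sizes)
  ids <- sprintf("child%02d", seq_len(n))
  set.seed(spec$seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, 3 * n)
  children <- vector("list", n)
  names(children) <- ids
  for (i in seq_len(n)) {
    set.seed(child_seeds[3 * i - 2])
    tl <- sample_timeline(spec$duration_scale)
    ch <- generate_child_stream(scores[i], tl, model, fps = spec$fps,
                                seed = child_seeds[3 * i - 1])
    if (length(model$distractor_stations) > 0) {
      di <- generate_distractors(model, stream_n_frames(ch$stream),
                                 fps = spec$fps, seed = child_seeds[3 * i])
      scene <- merge_streams(ch, di, seed = child_seeds[3 * i])
    } else {
      scene <- ch
    }
    children[[i]] <- list(stream = scene$stream, truth = scene$truth,
                          timeline = tl)
  }
  meta <- video_meta(spec$fps, origin_a = model$home_position - .home_origin_offset(),
                     width = 640, height = 480)
  structure(list(children = children,
                 scores = tibble::tibble(child_id = ids,
                                         activity_level_score = scores,
                                         ados_total = NA_integer_),
                 meta = meta, spec = spec, model = model),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(x$scores$activity_level_score)
  cat("<synthetic_cohort> ", length(x$children), " children (scores: ",
      paste(names(tab), tab, sep = "x", collapse = ", "), "), ",
      x$spec$fps, " fps, seed ", x$spec$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to disk in the package's file formats
#'
#' Creates one directory per child (keypoint stream JSON plus manifest CSV),
#' a cohort-level score table CSV and metadata JSON — the exact formats the
#' file-mode pipeline reads back.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_scores(cohort$scores, file.path(dir, "scores.csv"))
  write_video_meta(cohort$meta, file.path(dir, "meta.json"))
  for (id in names(cohort$children)) {
    cdir <- file.path(dir, id)
    dir.create(cdir, showWarnings = FALSE)
    ch <- cohort$children[[id]]
    write_keypoint_stream(ch$stream, file.path(cdir, "keypoints.json"))
    write_manifest(ch$timeline, file.path(cdir, "manifest.csv"))
  }
  invisible(dir)
}
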