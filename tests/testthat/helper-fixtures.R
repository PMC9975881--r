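# Shared fixtures: everything is generated in code at test time.

# A short two-activity timeline with a composite (seconds).
tiny_timeline <- function() {
  timeline(
    data.frame(activity = c("a", "b", "c"),
               start = c(0, 10, 20), end = c(10, 20, 30)),
    composites = list(ab = c("a", "b"))
  )
}

# Noise-free motion model: the only randomness left is the body walk itself.
quiet_model <- function(...) {
  motion_model(wrist_jitter_scale = 0, detection_noise_scale = 0,
               missingness_prob = 0, distractor_stations = list(), ...)
}

# A hand-built trajectory from (frame, x, y) triples.
make_traj <- function(frames, x, y, keypoint = 1L) {
  traj <- tibble::tibble(frame = as.integer(frames), x = x, y = y)
  attr(traj, "keypoint") <- keypoint
  class(traj) <- c("trajectory", class(traj))
  traj
}

# Random gappy trajectory for oracle comparisons.
random_traj <- function(n, gap_prob = 0.2) {
  frames <- which(stats::runif(n) >= gap_prob) - 1L
  make_traj(frames, stats::rnorm(length(frames), 100, 30),
            stats::rnorm(length(frames), 100, 30))
}

# A one-person keypoint stream where the neck follows (x, y) exactly.
stream_from_path <- function(x, y, fps = 10, conf = 0.9) {
  n <- length(x)
  det <- data.frame(frame = rep(0:(n - 1), times = 3),
                    person = 0L,
                    keypoint = rep(c(1L, 4L, 8L), each = n),
                    x = c(x, x + 20, x),
                    y = c(y, y + 8, y + 30),
                    confidence = conf)
  keypoint_stream(det, fps = fps, n_frames = n)
}
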