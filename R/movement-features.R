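#' Pixel-distance series
#'
#' For a keypoint trajectory, the pixel distance (PD) at sample n is the
#' Euclidean distance between the keypoint position B and the origin point A
#' (the centre of the table's edge next to the participant):
#' L_n = sqrt(X_n^2 + Y_n^2) with X_n = x_n - A_x, Y_n = y_n - A_y.
#'
#' @param traj a trajectory tibble (`frame`, `x`, `y`) from [filter_stream()].
#' @param origin numeric length-2: origin point A in pixels.
#' @return tibble `frame`, `X`, `Y`, `L` — one row per valid sample.
#' @export
pd_series <- function(traj, origin) {
  stopifnot(length(origin) == 2)
  if (nrow(traj) == 0) stop("empty trajectory")
  X <- traj$x - origin[1]
  Y <- traj$y - origin[2]
  tibble::tibble(frame = traj$frame, X = X, Y = Y, L = sqrt(X^2 + Y^2))
}

#' PD-based movement features
#'
#' `L_mean` is the mean pixel distance over all valid samples; `L_std` its
#' standard deviation with the population denominator n. Returns NA (feature
#' absent, not zero) below the minimum sample counts: 1 sample for the mean,
#' 2 for the SD.
#'
#' @param series a [pd_series()].
#' @return named list `L_mean`, `L_std`, `n` (sample count).
#' @export
pd_features <- function(series) {
  L <- series$L
  n <- length(L)
  list(L_mean = if (n >= 1) mean(L) else NA_real_,
       L_std = if (n >= 2) sqrt(sum((L - mean(L))^2) / n) else NA_real_,
       n = n)
}

#' Instantaneous-pixel-velocity series
#'
#' The IPV at step n is the Euclidean pixel displacement of the keypoint
#' between consecutive frames: dL_n = sqrt(dX_n^2 + dY_n^2) with
#' dX_n = x_{n+1} - x_n. Steps are computed only between samples whose frame
#' indices differ by exactly 1; steps across gaps (occlusions) are excluded —
#' velocity across an unobserved interval is itself unobserved.
#'
#' @inheritParams pd_series
#' @return tibble `frame` (step start), `dX`, `dY`, `dL`; zero rows when no
#'   two samples are at consecutive frames.
#' @export
ipv_series <- function(traj) {
  if (nrow(traj) < 2) {
    return(tibble::tibble(frame = integer(), dX = numeric(), dY = numeric(),
                          dL = numeric()))
  }
  consec <- which(diff(traj$frame) == 1L)
  dX <- traj$x[consec + 1L] - traj$x[consec]
  dY <- traj$y[consec + 1L] - traj$y[consec]
  tibble::tibble(frame = traj$frame[consec], dX = dX, dY = dY,
                 dL = sqrt(dX^2 + dY^2))
}

#' IPV-based movement features
#'
#' `dL_mean` is the mean absolute IPV over the observed steps; `dL_std` its
#' standard deviation, both with the step count as denominator. NA below the
#' minimums (1 step for the mean, 2 for the SD).
#'
#' @param series an [ipv_series()].
#' @return named list `dL_mean`, `dL_std`, `n` (step count).
#' @export
ipv_features <- function(series) {
  dL <- abs(series$dL)
  n <- length(dL)
  list(dL_mean = if (n >= 1) mean(dL) else NA_real_,
       dL_std = if (n >= 2) sqrt(sum((dL - mean(dL))^2) / n) else NA_real_,
       n = n)
}

#' Movement features per activity segment and keypoint
#'
#' Computes the four movement features {L_mean, L_std, dL_mean, dL_std} for
#' every (activity, keypoint) combination of a timeline, including composite
#' activities. Composite features pool the member segments' samples; IPV
#' steps are taken within members only, never across the boundary between
#' disjoint members. Features with fewer than `min_samples` PD samples (or
#' IPV steps) are emitted as NA: below that they would be noise-dominated.
#'
#' @param trajectories named list of trajectories from [filter_stream()].
#' @param tl a [timeline()].
#' @param origin origin point A (pixels).
#' @param fps frames per second.
#' @param activities activity (or composite) names to evaluate; defaults to
#'   every name in the timeline.
#' @param min_samples minimum PD samples / IPV steps for a feature value.
#' @return tibble with one row per (activity, keypoint): `activity`,
#'   `keypoint`, `L_mean`, `L_std`, `dL_mean`, `dL_std`, `n_pd_samples`,
#'   `n_ipv_samples`.
#' @export
segment_features <- function(trajectories, tl, origin, fps,
                             activities = timeline_activities(tl),
                             min_samples = 10) {
  stopifnot(inherits(tl, "timeline"))
  # precompute, per trajectory: the full PD series and the per-step IPV series
  # (steps between consecutive frames only); activity features then reduce to
  # index lookups into these vectors
  pre <- lapply(trajectories, function(traj) {
    fr <- traj$frame
    L <- sqrt((traj$x - origin[1])^2 + (traj$y - origin[2])^2)
    consec <- which(diff(fr) == 1L)
    dL <- sqrt((traj$x[consec + 1L] - traj$x[consec])^2 +
                 (traj$y[consec + 1L] - traj$y[consec])^2)
    list(frame = fr, L = L, step_frame = fr[consec], dL = dL)
  })
  # index range of sorted vector v falling in [lo, hi]
  range_idx <- function(v, lo, hi) {
    b <- findInterval(c(lo - 1L, hi), v)
    if (b[2] > b[1]) (b[1] + 1L):b[2] else integer(0)
  }
  out <- list(activity = character(), keypoint = integer(),
              L_mean = numeric(), L_std = numeric(), dL_mean = numeric(),
              dL_std = numeric(), n_pd_samples = integer(),
              n_ipv_samples = integer())
  for (act in activities) {
    members <- activity_frames(tl, act, fps)
    for (kp in names(trajectories)) {
      p <- pre[[kp]]
      L_all <- numeric(0); dL_all <- numeric(0)
      for (fr in members) {
        if (length(fr) == 0) next
        lo <- fr[1]; hi <- fr[length(fr)]
        L_all <- c(L_all, p$L[range_idx(p$frame, lo, hi)])
        # a step belongs to the member iff both its endpoints do
        dL_all <- c(dL_all, p$dL[range_idx(p$step_frame, lo, hi - 1L)])
      }
      n_pd <- length(L_all); n_ipv <- length(dL_all)
      out$activity <- c(out$activity, act)
      out$keypoint <- c(out$keypoint, as.integer(kp))
      out$L_mean <- c(out$L_mean,
                      if (n_pd >= min_samples) mean(L_all) else NA_real_)
      out$L_std <- c(out$L_std, if (n_pd >= min_samples)
        sqrt(sum((L_all - mean(L_all))^2) / n_pd) else NA_real_)
      out$dL_mean <- c(out$dL_mean,
                       if (n_ipv >= min_samples) mean(dL_all) else NA_real_)
      out$dL_std <- c(out$dL_std, if (n_ipv >= min_samples)
        sqrt(sum((dL_all - mean(dL_all))^2) / n_ipv) else NA_real_)
      out$n_pd_samples <- c(out$n_pd_samples, n_pd)
      out$n_ipv_samples <- c(out$n_ipv_samples, n_ipv)
    }
  }
  tibble::as_tibble(out)
}
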