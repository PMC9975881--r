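test_that("identical spec and seed reproduce streams exactly", {
  tl <- default_timeline(0.05)
  m <- motion_model()
  a <- generate_child_stream(1, tl, m, fps = 10, seed = 11)
  b <- generate_child_stream(1, tl, m, fps = 10, seed = 11)
  expect_identical(as.data.frame(a$stream), as.data.frame(b$stream))
  expect_identical(a$truth, b$truth)
  ca <- generate_cohort(cohort_spec(group_sizes = c("0" = 2, "1" = 2, "2" = 1),
                                    seed = 4), m)
  cb <- generate_cohort(cohort_spec(group_sizes = c("0" = 2, "1" = 2, "2" = 1),
                                    seed = 4), m)
  expect_identical(lapply(ca$children, function(x) as.data.frame(x$stream)),
                   lapply(cb$children, function(x) as.data.frame(x$stream)))
})

test_that("degenerate motion pins every keypoint to the skeleton at home", {
  # all noise sources off: zero step scale leaves the child seated exactly
  m <- quiet_model(step_scale_by_score = c("0" = 0, "1" = 0.5, "2" = 1),
                   excursion_scale_by_score = c("0" = 1, "1" = 2, "2" = 3))
  tl <- tiny_timeline()
  ch <- generate_child_stream(0, tl, m, fps = 10, seed = 1)
  st <- ch$stream
  neck <- st[st$keypoint == 1, ]
  expect_true(all(neck$x == m$home_position[1]))
  expect_true(all(neck$y == m$home_position[2]))
  # and the downstream velocity feature is exactly zero
  fp <- filter_params(init_position = m$home_position, gate_radius = 50)
  traj <- filter_stream(st, fp)$trajectories[["1"]]
  expect_equal(ipv_features(ipv_series(traj))$dL_mean, 0)
})

test_that("invalid scores and non-monotone scale tables are rejected", {
  expect_error(generate_child_stream(3, tiny_timeline(), motion_model()),
               "unknown score")
  expect_error(motion_model(excursion_scale_by_score = c("0" = 50, "1" = 50, "2" = 100)),
               "strictly increase")
  expect_error(motion_model(step_scale_by_score = c("0" = 9, "1" = 8, "2" = 10)),
               "strictly increase")
  expect_error(motion_model(missingness_prob = 1.2), "\\[0, 1\\]")
})

test_that("stationary excursion separates score groups (Monte-Carlo)", {
  # oracle: replicate downstream L_mean at scores 0 and 2 and compare means
  tl <- timeline(data.frame(activity = "all", start = 0, end = 100))
  m <- quiet_model()
  origin <- m$home_position - c(0, 90)
  lmean <- function(score, seed) {
    ch <- generate_child_stream(score, tl, m, fps = 10, seed = seed)
    st <- ch$stream
    neck <- st[st$keypoint == 1, ]
    mean(sqrt((neck$x - origin[1])^2 + (neck$y - origin[2])^2))
  }
  n_rep <- 200
  l0 <- vapply(1:n_rep, function(s) lmean(0, s), numeric(1))
  l2 <- vapply(1:n_rep, function(s) lmean(2, 10000 + s), numeric(1))
  expect_gt(mean(l2), mean(l0))
  # difference exceeds 3 standard errors of the comparison
  se <- sqrt(var(l0) / n_rep + var(l2) / n_rep)
  expect_gt(mean(l2) - mean(l0), 3 * se)
})

test_that("distractor generation respects stations and labels", {
  m <- motion_model()
  # distractors are present in bursts, so use a window long enough that both
  # stations appear
  d <- generate_distractors(m, n_frames = 2000, seed = 3)
  expect_setequal(unique(d$truth$identity), c("distractor1", "distractor2"))
  # intermittency: each distractor is visible in only part of the stream
  expect_lt(nrow(d$truth), 2 * 2000)
  # every emitted skeleton has exactly one identity label
  emitted <- unique(d$stream[c("frame", "person")])
  expect_equal(nrow(merge(emitted, d$truth, by = c("frame", "person"))),
               nrow(emitted))
  m0 <- motion_model(distractor_stations = list())
  d0 <- generate_distractors(m0, n_frames = 50, seed = 3)
  expect_equal(nrow(d0$stream), 0L)
  expect_equal(nrow(d0$truth), 0L)
})

test_that("merged scenes keep ground truth aligned under person shuffling", {
  tl <- default_timeline(0.02)
  m <- motion_model()
  ch <- generate_child_stream(2, tl, m, fps = 10, seed = 5)
  d <- generate_distractors(m, stream_n_frames(ch$stream), seed = 6)
  sc <- merge_streams(ch, d, seed = 7)
  emitted <- unique(as.data.frame(sc$stream)[c("frame", "person")])
  labelled <- merge(emitted, sc$truth, by = c("frame", "person"))
  expect_equal(nrow(labelled), nrow(emitted))
  # at most one child label per frame
  child_truth <- sc$truth[sc$truth$identity == "child", ]
  expect_false(any(duplicated(child_truth$frame)))
  # child person index varies across frames (shuffling really happened)
  child_idx <- sc$truth$person[sc$truth$identity == "child"]
  expect_gt(length(unique(child_idx)), 1)
})

test_that("default cohort matches the study group structure", {
  cohort <- generate_cohort(cohort_spec(seed = 2))
  expect_length(cohort$children, 52)
  tab <- table(cohort$scores$activity_level_score)
  expect_equal(unname(tab[c("0", "1", "2")]), c(18L, 25L, 9L),
               ignore_attr = TRUE)
  one <- generate_cohort(cohort_spec(group_sizes = c("0" = 1, "1" = 0, "2" = 0),
                                     seed = 9))
  expect_length(one$children, 1)
  expect_s3_class(one$children[[1]]$timeline, "timeline")
})
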