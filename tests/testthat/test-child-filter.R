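test_that("a lone confident skeleton is selected in every frame", {
  x <- cumsum(rnorm(50)) + 300
  y <- cumsum(rnorm(50)) + 300
  st <- stream_from_path(x, y, conf = 1)
  fp <- filter_params(init_position = c(300, 300), gate_radius = 100)
  got <- filter_stream(st, fp)
  expect_false(any(got$selection$gap))
  expect_true(all(got$selection$selected_person == 0))
  expect_equal(got$trajectories[["1"]]$x, x)
  expect_equal(got$trajectories[["1"]]$y, y)
})

test_that("the nearest in-gate candidate wins", {
  # previous neck (102, 98); candidates at (100, 100) and (300, 300); gate 50
  det <- data.frame(
    frame = c(0L, 1L, 1L), person = c(0L, 0L, 1L), keypoint = 1L,
    x = c(102, 100, 300), y = c(98, 100, 300), confidence = 1)
  st <- keypoint_stream(det, fps = 10, n_frames = 2)
  fp <- filter_params(init_position = c(102, 98), gate_radius = 50)
  got <- filter_stream(st, fp)
  expect_equal(got$selection$selected_person, c(0L, 0L))
  expect_equal(got$trajectories[["1"]]$x[2], 100)
})

test_that("low-confidence necks are never selected", {
  det <- data.frame(frame = 0:4, person = 0L, keypoint = 1L,
                    x = 100, y = 100,
                    confidence = c(1, 0.05, 1, 0.02, 1))
  st <- keypoint_stream(det, fps = 10, n_frames = 5)
  fp <- filter_params(init_position = c(100, 100), gate_radius = 50,
                      min_confidence = 0.1)
  got <- filter_stream(st, fp)
  expect_equal(got$selection$gap, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(got$trajectories[["1"]]$frame, c(0L, 2L, 4L))
})

test_that("gaps beyond max_gap trigger re-initialisation near the seat", {
  # child sits at (100, 100), vanishes for 8 frames, reappears at (100, 100);
  # an impostor at (400, 400) is visible throughout
  frames_child <- c(0:4, 13:19)
  det <- rbind(
    data.frame(frame = frames_child, person = 0L, keypoint = 1L,
               x = 100, y = 100, confidence = 1),
    data.frame(frame = 0:19, person = 1L, keypoint = 1L,
               x = 400, y = 400, confidence = 1))
  st <- keypoint_stream(det, fps = 10, n_frames = 20)
  fp <- filter_params(init_position = c(100, 100), gate_radius = 60,
                      max_gap = 5)
  got <- filter_stream(st, fp)
  expect_true(all(got$selection$gap[6:13]))
  expect_true(any(got$selection$reinit))
  # after re-initialisation the child, not the impostor, is re-acquired
  expect_equal(got$selection$selected_person[14:20], rep(0L, 7))
})

test_that("recovered trajectory matches ground truth with a far distractor", {
  tl <- default_timeline(0.05)
  m <- motion_model(distractor_stations = list(
    list(position = c(600, 60), scale = 3, on_mean = 40, off_mean = 40)))
  ch <- generate_child_stream(1, tl, m, fps = 10, seed = 21)
  d <- generate_distractors(m, stream_n_frames(ch$stream), fps = 10, seed = 22)
  sc <- merge_streams(ch, d, seed = 23)
  meta <- video_meta(10, m$home_position - c(0, 90), 640, 480)
  got <- filter_stream(sc$stream, default_filter_params(meta))
  expect_equal(mismatch_rate(got$selection, sc$truth, n_audit = 1e6, seed = 1), 0)
  # neck trajectory equals the child's ground-truth neck wherever selected
  child_necks <- as.data.frame(sc$stream)
  child_key <- paste(sc$truth$frame[sc$truth$identity == "child"],
                     sc$truth$person[sc$truth$identity == "child"])
  child_necks <- child_necks[child_necks$keypoint == 1 &
    paste(child_necks$frame, child_necks$person) %in% child_key, ]
  traj <- got$trajectories[["1"]]
  ref <- child_necks[match(traj$frame, child_necks$frame), ]
  expect_equal(traj$x, ref$x)
  expect_equal(traj$y, ref$y)
})

test_that("a distractor parked on the seat causes mismatches when it moves enough", {
  tl <- default_timeline(0.05)
  m <- motion_model(distractor_stations = list(
    list(position = c(320, 330), scale = 25, on_mean = 60, off_mean = 20)))
  rates <- vapply(1:8, function(s) {
    ch <- generate_child_stream(1, tl, m, fps = 10, seed = 100 + s)
    d <- generate_distractors(m, stream_n_frames(ch$stream), fps = 10,
                              seed = 200 + s)
    sc <- merge_streams(ch, d, seed = 300 + s)
    meta <- video_meta(10, m$home_position - c(0, 90), 640, 480)
    got <- filter_stream(sc$stream, default_filter_params(meta))
    mismatch_rate(got$selection, sc$truth, n_audit = 1e6, seed = s)
  }, numeric(1))
  expect_gt(mean(rates), 0)
})

test_that("mismatch arithmetic is the audited fraction", {
  selection <- tibble::tibble(frame = 0:99, selected_person = 0L,
                              distance = 1, gap = FALSE, reinit = FALSE)
  # in 3 of 100 frames the skeleton at person slot 0 is not the child
  truth <- tibble::tibble(frame = 0:99, person = 0L, identity = "child")
  truth$identity[c(5, 50, 95) + 1] <- "distractor1"
  expect_equal(mismatch_rate(selection, truth, n_audit = 100, seed = 1), 0.03)
  # perfect selection
  truth_ok <- tibble::tibble(frame = 0:99, person = 0L, identity = "child")
  expect_equal(mismatch_rate(selection, truth_ok, n_audit = 100, seed = 1), 0)
  # n_audit above the stream size audits everything
  expect_equal(mismatch_rate(selection, truth_ok, n_audit = 1000, seed = 1), 0)
})

test_that("empty streams error and all-gap streams warn", {
  det <- data.frame(frame = integer(), person = integer(), keypoint = integer(),
                    x = numeric(), y = numeric(), confidence = numeric())
  st <- keypoint_stream(det, fps = 10, n_frames = 0)
  fp <- filter_params(init_position = c(0, 0), gate_radius = 10)
  expect_error(filter_stream(st, fp), "empty")
  far <- stream_from_path(rep(500, 5), rep(500, 5))
  expect_warning(got <- filter_stream(far, fp), "all-gap")
  expect_true(attr(got$selection, "all_gap"))
  expect_true(is.na(mismatch_rate(got$selection,
                                  tibble::tibble(frame = 0:4, person = 0L,
                                                 identity = "child"))))
})
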