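# independent brute-force oracles, deliberately naive
oracle_pd <- function(traj, origin) {
  L <- numeric(nrow(traj))
  for (i in seq_len(nrow(traj))) {
    L[i] <- sqrt((traj$x[i] - origin[1])^2 + (traj$y[i] - origin[2])^2)
  }
  m <- sum(L) / length(L)
  s <- sqrt(sum((L - m)^2) / length(L))
  list(L = L, mean = m, std = s)
}

oracle_ipv <- function(traj) {
  dL <- c()
  for (i in seq_len(nrow(traj) - 1)) {
    if (traj$frame[i + 1] - traj$frame[i] == 1) {
      dL <- c(dL, sqrt((traj$x[i + 1] - traj$x[i])^2 +
                         (traj$y[i + 1] - traj$y[i])^2))
    }
  }
  if (length(dL) == 0) return(list(dL = numeric(0), mean = NA, std = NA))
  m <- sum(abs(dL)) / length(dL)
  s <- sqrt(sum((dL - m)^2) / length(dL))
  list(dL = dL, mean = m, std = s)
}

test_that("pixel distances follow the Euclidean worked examples", {
  traj <- make_traj(0:2, c(0, 3, 6), c(0, 4, 8))
  s <- pd_series(traj, origin = c(0, 0))
  expect_equal(s$L, c(0, 5, 10))
  expect_equal(pd_series(make_traj(0, 7, 9), origin = c(7, 9))$L, 0)
  f <- pd_features(s)
  expect_equal(f$L_mean, 5)
  expect_equal(f$L_std, sqrt(50 / 3))
  # constant series: SD exactly zero
  cf <- pd_features(pd_series(make_traj(0:4, rep(3, 5), rep(4, 5)), c(0, 0)))
  expect_equal(cf$L_mean, 5)
  expect_equal(cf$L_std, 0)
  expect_error(pd_series(make_traj(integer(), numeric(), numeric()), c(0, 0)),
               "empty")
})

test_that("velocity steps exist only between consecutive frames", {
  s <- ipv_series(make_traj(c(0, 1), c(0, 3), c(0, 4)))
  expect_equal(s$dL, 5)
  # a gap at frame 1 removes the only step
  expect_equal(nrow(ipv_series(make_traj(c(0, 2), c(0, 3), c(0, 4)))), 0)
  s3 <- ipv_series(make_traj(0:2, c(0, 3, 3), c(0, 4, 4)))
  expect_equal(s3$dL, c(5, 0))
  f <- ipv_features(s3)
  expect_equal(f$dL_mean, 2.5)
  expect_equal(f$dL_std, 2.5)
  # constant-velocity walk has zero IPV spread
  cv <- ipv_features(ipv_series(make_traj(0:9, 2 * (0:9), rep(0, 10))))
  expect_equal(cv$dL_mean, 2)
  expect_equal(cv$dL_std, 0)
})

test_that("features match the brute-force oracle on random trajectories", {
  set.seed(404)
  for (i in 1:1000) {
    traj <- random_traj(30)
    if (nrow(traj) == 0) next
    origin <- runif(2, 0, 200)
    pd <- pd_features(pd_series(traj, origin))
    o <- oracle_pd(traj, origin)
    expect_equal(pd$L_mean, o$mean, tolerance = 1e-9)
    if (nrow(traj) >= 2) expect_equal(pd$L_std, o$std, tolerance = 1e-9)
    iv <- ipv_features(ipv_series(traj))
    oi <- oracle_ipv(traj)
    if (length(oi$dL) >= 1) {
      expect_equal(iv$dL_mean, oi$mean, tolerance = 1e-9)
    } else {
      expect_true(is.na(iv$dL_mean))
    }
    if (length(oi$dL) >= 2) expect_equal(iv$dL_std, oi$std, tolerance = 1e-9)
  }
})

test_that("translating trajectory and origin together preserves all features", {
  set.seed(7)
  traj <- random_traj(50, gap_prob = 0.1)
  origin <- c(50, 60)
  shift <- c(-31.5, 12.25)
  shifted <- make_traj(traj$frame, traj$x + shift[1], traj$y + shift[2])
  a <- pd_features(pd_series(traj, origin))
  b <- pd_features(pd_series(shifted, origin + shift))
  expect_equal(a, b)
  # trajectory-only shift changes PD but not IPV
  c_ <- pd_features(pd_series(shifted, origin))
  expect_false(isTRUE(all.equal(a$L_mean, c_$L_mean)))
  expect_equal(ipv_features(ipv_series(traj)),
               ipv_features(ipv_series(shifted)))
})

test_that("rotation about the origin preserves PD features", {
  set.seed(8)
  traj <- random_traj(50, gap_prob = 0.1)
  origin <- c(20, -10)
  th <- 0.7
  dx <- traj$x - origin[1]; dy <- traj$y - origin[2]
  rot <- make_traj(traj$frame,
                   origin[1] + cos(th) * dx - sin(th) * dy,
                   origin[2] + sin(th) * dx + cos(th) * dy)
  expect_equal(pd_features(pd_series(traj, origin)),
               pd_features(pd_series(rot, origin)))
})

test_that("frame re-indexing that preserves order and adjacency changes nothing", {
  set.seed(9)
  traj <- random_traj(40, gap_prob = 0.15)
  shifted <- make_traj(traj$frame + 1000L, traj$x, traj$y)
  expect_equal(pd_features(pd_series(traj, c(0, 0)))$L_mean,
               pd_features(pd_series(shifted, c(0, 0)))$L_mean)
  expect_equal(ipv_features(ipv_series(traj)),
               ipv_features(ipv_series(shifted)))
})

test_that("composite activity features pool members without crossing boundaries", {
  tl <- tiny_timeline()
  # 300 frames at 10 fps covering a [0,100), b [100,200), c [200,300)
  set.seed(10)
  x <- cumsum(rnorm(300)); y <- cumsum(rnorm(300))
  trajs <- list("1" = make_traj(0:299, x, y))
  out <- segment_features(trajs, tl, origin = c(0, 0), fps = 10)
  ab <- out[out$activity == "ab", ]
  a <- out[out$activity == "a", ]
  b <- out[out$activity == "b", ]
  # union accounting: composite sample count is the sum over members
  expect_equal(ab$n_pd_samples, a$n_pd_samples + b$n_pd_samples)
  expect_equal(ab$n_ipv_samples, a$n_ipv_samples + b$n_ipv_samples)
  # no IPV step spans the a|b boundary: composite mean equals pooled means
  dLa <- ipv_series(make_traj(0:99, x[1:100], y[1:100]))$dL
  dLb <- ipv_series(make_traj(100:199, x[101:200], y[101:200]))$dL
  expect_equal(ab$dL_mean, mean(c(dLa, dLb)))
  # a single segment spanning the stream equals whole-stream features
  whole <- timeline(data.frame(activity = "w", start = 0, end = 30))
  w <- segment_features(trajs, whole, origin = c(0, 0), fps = 10)
  direct <- pd_features(pd_series(trajs[["1"]], c(0, 0)))
  expect_equal(w$L_mean, direct$L_mean)
  expect_equal(w$L_std, direct$L_std)
})

test_that("features fall back to NA below the minimum sample count", {
  tl <- timeline(data.frame(activity = "short", start = 0, end = 0.5))
  trajs <- list("1" = make_traj(0:4, rnorm(5), rnorm(5)))
  out <- segment_features(trajs, tl, origin = c(0, 0), fps = 10,
                          min_samples = 10)
  expect_true(is.na(out$L_mean))
  expect_true(is.na(out$dL_mean))
  expect_equal(out$n_pd_samples, 5L)
})
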