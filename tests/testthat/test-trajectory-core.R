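# Track data model, I/O and preprocessing

test_that("read_tracks parses, groups, sorts and infers dt", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- make_track_df("a", c(0, 1, 2), cbind(c(0, 1, 2), c(0, 0, 0)))
  write.csv(df, f, row.names = FALSE)
  ts <- read_tracks(f)
  expect_s3_class(ts, "track_set")
  expect_length(ts, 1)
  expect_equal(ts$dt, 1)
  expect_equal(ts$dim, 2L)

  # two interleaved ids, out of time order -> 2 tracks, each sorted
  df2 <- make_track_df(c("a", "b", "a", "b", "a", "b"),
                       c(2, 0, 0, 1, 1, 2),
                       cbind(c(2, 10, 0, 11, 1, 12), rep(0, 6)))
  write.csv(df2, f, row.names = FALSE)
  ts2 <- read_tracks(f)
  expect_length(ts2, 2)
  expect_equal(ts2$tracks[[1]]$positions[, 1], c(0, 1, 2))
  expect_equal(ts2$tracks[[2]]$positions[, 1], c(10, 11, 12))

  # missing column -> format error; duplicate times -> validation error
  write.csv(df[, -3], f, row.names = FALSE)
  expect_error(read_tracks(f), "missing column")
  df3 <- make_track_df("dup", c(0, 1, 1), cbind(0:2, 0:2))
  write.csv(df3, f, row.names = FALSE)
  expect_error(read_tracks(f), "dup")
})

test_that("write/read round-trips coordinates, ids and empty sets", {
  set.seed(42)
  ts <- track_set(lapply(1:4, function(i) random_track(paste0("c", i), n = 15)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_tracks(ts, f)
  back <- read_tracks(f)
  expect_equal(length(back), length(ts))
  for (i in seq_along(ts$tracks)) {
    expect_equal(back$tracks[[i]]$id, ts$tracks[[i]]$id)
    expect_equal(back$tracks[[i]]$positions, ts$tracks[[i]]$positions,
                 tolerance = 1e-9)
    expect_equal(back$tracks[[i]]$times, ts$tracks[[i]]$times)
  }
  # empty set -> header-only file, readable as a data frame with 0 rows
  empty <- track_set(list(), dt = 1)
  write_tracks(empty, f)
  expect_equal(nrow(read.csv(f)), 0)
})

test_that("track validation enforces the invariants", {
  expect_error(track("x", c(0, 1), cbind(0:2, 0:2)), "differ in length")
  expect_error(track("x", c(0, 1, 1), cbind(0:2, 0:2)), "strictly increasing")
  expect_error(track("x", c(0, 1, 2), cbind(c(0, NA, 2), 0:2)), "non-finite")
  expect_error(track_set(list(straight_track(dim = 2), straight_track(dim = 3))),
               "dimensionality")
})

test_that("tracks with acquisition gaps are split, not interpolated", {
  tr <- track("g", c(0, 1, 2, 5, 6, 7), cbind(0:5, 0:5))
  ts <- track_set(list(tr), dt = 1)
  expect_length(ts, 2)
  expect_equal(ts$tracks[[1]]$times, c(0, 1, 2))
  expect_equal(ts$tracks[[2]]$times, c(5, 6, 7))
  expect_match(ts$tracks[[1]]$id, "^g\\.1$")
})

test_that("filter_short_tracks applies the path-length rule", {
  short <- straight_track("short", n = 11, step = c(2, 0))   # 20 um
  still <- track("still", 0:9, matrix(5, 10, 2))             # 0 um
  long <- straight_track("long", n = 11, step = c(4, 0))     # 40 um
  ts <- track_set(list(short, still, long), dt = 1)
  kept <- filter_short_tracks(ts, 30)
  expect_equal(vapply(kept$tracks, `[[`, character(1), "id"), "long")
  # stationary track removed for any positive threshold
  expect_length(filter_short_tracks(track_set(list(still), dt = 1), 1e-9), 0)
  expect_error(filter_short_tracks(ts, -1), "non-negative")

  # brute-force check on random sets + idempotence + subset property
  set.seed(7)
  rts <- track_set(lapply(1:20, function(i) random_track(paste0("r", i))))
  thr <- 5
  kept2 <- filter_short_tracks(rts, thr)
  manual <- vapply(rts$tracks, function(tr) {
    s <- 0
    for (t in 2:nrow(tr$positions))
      s <- s + sqrt(sum((tr$positions[t, ] - tr$positions[t - 1, ])^2))
    s >= thr
  }, logical(1))
  expect_equal(vapply(kept2$tracks, `[[`, character(1), "id"),
               vapply(rts$tracks[manual], `[[`, character(1), "id"))
  expect_equal(filter_short_tracks(kept2, thr), kept2)
})

test_that("project_to_2d drops z and never increases the MSD", {
  th <- seq(0, 4 * pi, length.out = 41)
  helix <- track("h", seq_along(th) - 1, cbind(cos(th), sin(th), th))
  ts <- track_set(list(helix), dt = 1)
  p <- project_to_2d(ts)
  expect_equal(p$dim, 2L)
  expect_equal(p$tracks[[1]]$positions, cbind(cos(th), sin(th)))
  expect_warning(project_to_2d(p), "already 2D")

  zonly <- track("z", 0:9, cbind(rep(0, 10), rep(0, 10), 0:9))
  pz <- project_to_2d(track_set(list(zonly), dt = 1))
  expect_true(all(pz$tracks[[1]]$positions == 0))

  set.seed(11)
  for (i in 1:5) {
    tr3 <- random_track(dim = 3, n = 25)
    m3 <- track_msd(tr3)
    m2 <- track_msd(project_to_2d(track_set(list(tr3), dt = 1))$tracks[[1]])
    expect_true(all(m2$values <= m3$values + 1e-12))
  }
})

test_that("truncate_tracks gates by time and drops stubs", {
  tr <- track("t", 0:71, cbind(0:71, 0:71))
  ts <- track_set(list(tr), dt = 1)
  expect_equal(truncate_tracks(ts, 0), ts)
  cut <- truncate_tracks(ts, 30)
  expect_equal(length(cut$tracks[[1]]$times), 42)
  expect_equal(range(cut$tracks[[1]]$times), c(30, 71))
  short <- track("s", 0:20, cbind(0:20, 0:20))
  expect_length(
    suppressWarnings(truncate_tracks(track_set(list(short), dt = 1), 30))$tracks,
    0)
  expect_warning(truncate_tracks(track_set(list(short), dt = 1), 30), "empty")
})

test_that("project_to_2d and truncate_tracks commute", {
  set.seed(3)
  ts <- track_set(lapply(1:4, function(i) random_track(paste0("c", i),
                                                       n = 30, dim = 3)))
  a <- truncate_tracks(project_to_2d(ts), 10)
  b <- suppressWarnings(project_to_2d(truncate_tracks(ts, 10)))
  expect_equal(a$tracks, b$tracks)
})

test_that("speed_vs_time reports windowed population mean step speeds", {
  v <- 3
  ts <- track_set(lapply(1:3, function(i)
    straight_track(paste0("c", i), n = 21, step = c(v, 0))), dt = 1)
  prof <- speed_vs_time(ts, window = 4)
  expect_true(all(abs(prof$speed - v) < 1e-12))

  still <- track_set(list(track("s", 0:20, matrix(1, 21, 2))), dt = 1)
  expect_true(all(speed_vs_time(still, 4)$speed == 0))

  # piecewise speed: v1 for t < 10, v2 after -> step in the profile
  pos <- cumsum(c(0, rep(1, 10), rep(5, 10)))
  pw <- track_set(list(track("p", 0:20, cbind(pos, 0))), dt = 1)
  prof2 <- speed_vs_time(pw, window = 2)
  expect_true(all(abs(prof2$speed[prof2$time < 10] - 1) < 1e-12))
  expect_true(all(abs(prof2$speed[prof2$time > 11] - 5) < 1e-12))
})
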