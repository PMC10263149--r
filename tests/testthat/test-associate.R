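test_that("a single gap-free object yields one track covering all frames", {
  path <- cbind(10 + 2 * (0:29), 20 + 0.5 * (0:29))
  det <- detections_from_paths(list(path))
  tr <- associate_detections(det)
  expect_identical(length(unique(tr$track_id)), 1L)
  expect_identical(sort(tr$frame), 1:30)
  # detection conservation: every input detection appears exactly once
  expect_identical(nrow(tr), nrow(det))
  expect_identical(track_partition(tr, "track_id")[[1]],
                   sort(paste(det$frame, round(det$x_px, 6),
                              round(det$y_px, 6))))
})

test_that("crossing objects match the brute-force assignment oracle", {
  n <- 40
  a <- cbind(5 + 2 * (0:(n - 1)), 10 + 1.5 * (0:(n - 1)))
  b <- cbind(90 - 2 * (0:(n - 1)), 70 - 1.2 * (0:(n - 1)))
  det <- detections_from_paths(list(a, b))
  tr <- associate_detections(det, gate_px = 12)
  orc <- oracle_track(det, gate = 12)
  expect_identical(length(unique(tr$track_id)), 2L)
  expect_setequal(track_partition(tr, "track_id"),
                  track_partition(orc, "oracle_id"))
  # each recovered track is one ground-truth object
  truth <- lapply(list(a, b), function(p) {
    sort(paste(seq_len(n), round(p[, 1], 6), round(p[, 2], 6)))
  })
  expect_setequal(track_partition(tr, "track_id"), truth)
})

test_that("three-object instances equal the exhaustive assignment oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    paths <- lapply(1:3, function(i) {
      start <- runif(2, 20, 200)
      vel <- runif(2, -3, 3)
      cbind(start[1] + vel[1] * (0:49) + rnorm(50, 0, 0.3),
            start[2] + vel[2] * (0:49) + rnorm(50, 0, 0.3))
    })
    det <- detections_from_paths(paths)
    tr <- associate_detections(det, gate_px = 15)
    orc <- oracle_track(det, gate = 15)
    expect_setequal(track_partition(tr, "track_id"),
                    track_partition(orc, "oracle_id"))
  }
})

test_that("a gap longer than max_missed splits the track", {
  path <- cbind(10 + 2 * (0:29), rep(15, 30))
  frames <- c(1:12, 17:34)  # gap of 4 frames
  det <- detections_from_paths(list(path), frames = frames)
  tr <- associate_detections(det, max_missed = 3)
  expect_identical(length(unique(tr$track_id)), 2L)
  tr2 <- associate_detections(det, max_missed = 4)
  expect_identical(length(unique(tr2$track_id)), 1L)
})

test_that("empty input gives empty output", {
  det <- detections_from_paths(list(cbind(1, 1)))[0, ]
  expect_identical(nrow(associate_detections(det)), 0L)
})
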