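helix_path <- function(n = 40) {
  t <- seq(0, 1, length.out = n)
  data.frame(x_m = 0.2 + 0.6 * t, y_m = 0.1 + 0.05 * sin(4 * t),
             z_m = 0.1 + 0.05 * t)
}

# Exact (noise-free) pixel tracks from forward projection.
project_tracks <- function(pair, path, id = 1L) {
  pa <- beeflight:::project_pinhole(pair$a$P, cbind(path$x_m, path$y_m,
                                                    path$z_m))
  pb <- beeflight:::project_pinhole(pair$b$P, cbind(path$x_m, path$y_m,
                                                    path$z_m))
  list(a = data.frame(track_id = id, frame = seq_len(nrow(path)),
                      x_px = pa$col, y_px = pa$row),
       b = data.frame(track_id = id, frame = seq_len(nrow(path)),
                      x_px = pb$col, y_px = pb$row))
}

test_that("forward-project / triangulate round trip is exact to < 1e-3 m", {
  pair <- stereo_camera_pair()
  path <- helix_path()
  tks <- project_tracks(pair, path)
  out <- triangulate_tracks(tks$a, tks$b, pair, frame_rate = 50)
  expect_length(out, 1L)
  err <- sqrt((out[[1]]$x_m - path$x_m)^2 + (out[[1]]$y_m - path$y_m)^2 +
                (out[[1]]$z_m - path$z_m)^2)
  expect_lt(sqrt(mean(err^2)), 1e-3)
  expect_true(all(out[[1]]$residual_px >= 0))
})

test_that("two well-separated bees are paired correctly", {
  pair <- stereo_camera_pair()
  p1 <- helix_path()
  p2 <- helix_path(); p2$y_m <- p2$y_m + 0.15; p2$z_m <- p2$z_m + 0.15
  t1 <- project_tracks(pair, p1, id = 1L)
  t2 <- project_tracks(pair, p2, id = 2L)
  out <- triangulate_tracks(rbind(t1$a, t2$a), rbind(t2$b, t1$b), pair)
  expect_length(out, 2L)
  # every accepted pairing reconstructs one true path (residual ~ 0)
  expect_true(all(vapply(out, function(d) mean(d$residual_px), 1) < 1e-6))
})

test_that("mismatched or missing tracks give empty results", {
  pair <- stereo_camera_pair()
  tks <- project_tracks(pair, helix_path())
  none <- tks$b[0, ]
  expect_identical(triangulate_tracks(tks$a, none, pair), list())
  # no temporal overlap
  tb <- tks$b; tb$frame <- tb$frame + 1000L
  expect_identical(triangulate_tracks(tks$a, tb, pair), list())
})

test_that("single common frame yields a 1-point 3D trajectory", {
  pair <- stereo_camera_pair()
  tks <- project_tracks(pair, helix_path(1))
  out <- triangulate_tracks(tks$a, tks$b, pair)
  expect_length(out, 1L)
  expect_identical(nrow(out[[1]]), 1L)
})

test_that("degenerate identical camera placements are rejected", {
  expect_error(stereo_camera_pair(center_a = c(0, 0, 1),
                                  center_b = c(0, 0, 1)), "degenerate")
})

test_that("a floor-level 3D path is flagged as walking downstream", {
  pair <- stereo_camera_pair()
  path <- helix_path()
  path$z_m <- 0.010  # 1 cm above the floor everywhere
  tks <- project_tracks(pair, path)
  out <- triangulate_tracks(tks$a, tks$b, pair, frame_rate = 50)
  d <- out[[1]]
  rec <- summarize_flight(
    data.frame(t_s = d$t_s, x_m = d$x_m, y_m = d$y_m, z_m = d$z_m),
    u = 0, heading = "no_flow")
  flagged <- apply_flight_filters(rec)
  expect_true(flagged$walking)
  expect_false(flagged$retained)
})
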