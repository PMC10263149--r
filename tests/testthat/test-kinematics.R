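test_that("sinuosity: analytic cases", {
  expect_identical(path_sinuosity(1:10, rep(2, 10)), 1)
  th <- seq(0, pi, length.out = 1000)
  expect_equal(path_sinuosity(cos(th), sin(th)), pi / 2, tolerance = 1e-4)
  # out-and-back inflates without bound as the net displacement shrinks
  s_eps <- function(eps) path_sinuosity(c(0, 1, eps), c(0, 0, 0))
  expect_gt(s_eps(0.01), s_eps(0.1))
  expect_gt(s_eps(0.001), 1000)
  expect_warning(s <- path_sinuosity(c(0, 1, 0), c(0, 1, 0)), "coincide")
  expect_true(is.na(s))
  expect_error(path_sinuosity(1, 1), "2 points")
})

test_that("axial speed series: uniform motion and edge cases", {
  t <- seq(0, 1, by = 0.01)
  expect_equal(axial_speed_series(0.8 * t, t), rep(0.8, length(t)))
  # travel-positive convention: motion toward -x still reports +0.8
  expect_equal(axial_speed_series(1.4 - 0.8 * t, t), rep(0.8, length(t)))
  expect_equal(mean(axial_speed_series(rep(0.5, 11), t[1:11])), 0)
  expect_error(axial_speed_series(1, 0), "2 samples")
})

test_that("air speed adds flow upwind and subtracts it downwind", {
  expect_equal(air_speed_series(0.70, 2.0, "upwind")$mean, 2.70)
  expect_equal(air_speed_series(0.90, 0.75, "downwind")$mean, 0.15)
  expect_equal(air_speed_series(0.83, 2.0, "downwind")$mean, -1.17)
  vg <- c(0.5, 0.7, 0.9)
  expect_equal(air_speed_series(vg, 0, "upwind")$va, vg)
  # SD is invariant under the constant flow offset
  expect_equal(air_speed_series(vg, 2, "downwind")$sd, sd(vg))
  expect_error(air_speed_series(0.5, 1, "sideways"), "direction")
  expect_error(air_speed_series(0.5, -1, "upwind"), ">= 0")
})

test_that("body angle statistics use the sample SD", {
  s <- body_angle_stats(c(33.8, 33.8, 33.8))
  expect_equal(s$mean, 33.8)
  expect_equal(s$sd, 0)
  s2 <- body_angle_stats(c(40, 44))
  expect_equal(s2$mean, 42)
  expect_equal(s2$sd, sqrt(8))  # n-1 convention
  expect_error(body_angle_stats(numeric(0)), "empty")
})

test_that("flapping frequency: spectral peak within fs/N", {
  fs <- 5000
  t <- (0:4095) / fs
  f1 <- flapping_frequency(sin(2 * pi * 200 * t), fs)
  expect_true(f1$defined)
  expect_lt(abs(f1$freq_hz - 200), fs / 4096)
  # wingbeat + slow drift + noise, as in a real silhouette velocity
  set.seed(101)
  t2 <- (0:3999) / fs
  v <- 0.6 * t2 + sin(2 * pi * 196.2 * t2) + rnorm(4000, 0, 0.1)
  f2 <- flapping_frequency(v, fs)
  expect_lt(abs(f2$freq_hz - 196.2), fs / 4000)
  # constant series has no peak
  f3 <- flapping_frequency(rep(1, 1000), fs)
  expect_false(f3$defined)
  expect_true(is.na(f3$freq_hz))
})

test_that("central-section restriction keeps the longest inside run", {
  traj <- data.frame(x_m = seq(0, 1.4, by = 0.01), y_m = 0)
  seg <- restrict_to_central_section(traj)
  expect_true(all(seg$x_m >= 0.55 & seg$x_m <= 0.85))
  expect_identical(nrow(seg), sum(traj$x_m >= 0.55 & traj$x_m <= 0.85))
  inside <- data.frame(x_m = seq(0.6, 0.8, by = 0.01))
  expect_identical(restrict_to_central_section(inside), inside)
  outside <- data.frame(x_m = seq(1.0, 1.4, by = 0.01))
  expect_identical(nrow(restrict_to_central_section(outside)), 0L)
})

test_that("flight filters: boundary behaviour and partition", {
  recs <- data.frame(
    sinuosity = c(1.05, 1.1, 1.2, 1.0, NA),
    mean_vg = c(0.5, 0.3, 0.4, 0.01, 0.02),
    max_z_m = c(0.05, 0.02, 0.10, 0.05, 0.01),
    n_frames = c(50, 6, 50, 50, 5))
  out <- apply_flight_filters(recs)
  expect_identical(out$retained, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_true(out$high_sinuosity[3])
  expect_true(out$low_speed[4])
  expect_true(out$walking[5] && out$short[5] && out$high_sinuosity[5])
  # boundary values are retained: S = 1.1 and vg = 0.02 pass
  expect_false(out$high_sinuosity[2])
  expect_false(out$low_speed[5])  # vg = 0.02 sits on the boundary: kept
  # partition + idempotence
  expect_identical(out$retained, !(out$high_sinuosity | out$low_speed |
                                     out$walking | out$short))
  again <- apply_flight_filters(out)
  expect_identical(again$retained, out$retained)
})

test_that("direction and channel classification", {
  arena <- list(divider_y = 0.2, flow_dir = c(left = -1, right = 1))
  up <- classify_direction_and_channel(
    data.frame(x_m = seq(0, 1, 0.1), y_m = 0.1), arena)
  expect_identical(up$channel, "left")
  expect_identical(up$heading, "upwind")   # +x travel against -x flow
  down <- classify_direction_and_channel(
    data.frame(x_m = seq(0, 1, 0.1), y_m = 0.3), arena)
  expect_identical(down$channel, "right")
  expect_identical(down$heading, "downwind")
  amb <- classify_direction_and_channel(
    data.frame(x_m = c(0.5, 0.52), y_m = 0.1), arena)
  expect_true(amb$ambiguous)
})
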