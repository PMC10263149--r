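test_that("noiseless flight holds the set-point exactly and flies straight", {
  p <- simulation_params(ground_speed_setpoint = 0.8, flow_velocity = 0,
                         pitch_noise_sd = 0, speed_noise_sd = 0,
                         lateral_noise_sd = 0, vertical_noise_sd = 0,
                         seed = 1)
  tr <- simulate_trajectory(p)
  expect_equal(mean(tr$vg_mps), 0.8, tolerance = 1e-12)
  expect_true(all(abs(tr$vg_mps - 0.8) < 1e-12))
  expect_equal(path_sinuosity(tr$x_m, tr$y_m), 1)
  expect_equal(tr$va_mps, tr$vg_mps)
  expect_equal(diff(tr$t_s), rep(1 / p$frame_rate, nrow(tr) - 1))
  expect_true(all(tr$z_m >= 0))
})

test_that("air-speed identity holds on truth for head- and tailwinds", {
  # headwind: set-point 0.70 against 2.0 m/s flow -> air speed 2.70
  p <- simulation_params(ground_speed_setpoint = 0.70, flow_velocity = 2.0,
                         direction = "toward_hive", pitch_noise_sd = 0,
                         speed_noise_sd = 0, seed = 2)
  tr <- simulate_trajectory(p)
  expect_equal(mean(tr$va_mps), 2.70, tolerance = 1e-12)
  # identity at every sample, also under noise
  pn <- simulation_params(ground_speed_setpoint = 0.9, flow_velocity = 2.0,
                          direction = "toward_feeder", seed = 3)
  trn <- simulate_trajectory(pn)
  expect_equal(trn$va_mps, trn$vg_mps - 2.0)
  # tailwind faster than the set-point -> negative air speed
  expect_lt(mean(trn$va_mps), 0)
})

test_that("pitch follows air-speed demand: down in headwind, up in tailwind", {
  base <- function(u, dir) {
    p <- simulation_params(flow_velocity = u, direction = dir,
                           pitch_noise_sd = 0, speed_noise_sd = 0,
                           ground_speed_setpoint = 0.8, seed = 4)
    mean(simulate_trajectory(p)$pitch_deg)
  }
  expect_equal(base(0, "toward_feeder"), 33.8, tolerance = 1e-12)
  expect_equal(base(2.0, "toward_feeder"), 42.4, tolerance = 1e-12)
  expect_lt(base(2.0, "toward_hive"), 33.8)
})

test_that("tailwind runs show greater within-flight pitch variability", {
  sd_pitch <- function(dir, seed) {
    p <- simulation_params(flow_velocity = 2.0, direction = dir,
                           duration = 0.5, seed = seed)
    sd(simulate_trajectory(p)$pitch_deg)
  }
  seeds <- 1:100
  tail_sd <- vapply(seeds, function(s) sd_pitch("toward_feeder", s), 1)
  head_sd <- vapply(seeds, function(s) sd_pitch("toward_hive", s), 1)
  expect_gt(mean(tail_sd), mean(head_sd))
})

test_that("generation is seed-deterministic and rejects invalid inputs", {
  p <- simulation_params(seed = 77)
  expect_identical(simulate_trajectory(p), simulate_trajectory(p))
  p2 <- simulation_params(seed = 78)
  expect_false(isTRUE(all.equal(simulate_trajectory(p)$vg_mps,
                                simulate_trajectory(p2)$vg_mps)))
  expect_error(simulation_params(duration = -1), "positive")
  expect_error(simulation_params(frame_rate = 0), "positive")
  expect_error(simulation_params(frame_rate = NaN), "finite")
})
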