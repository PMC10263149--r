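# Short lateral clips keep the refinement tests fast: 0.08 s at 5000 Hz
# is ~16 wingbeats at 196.2 Hz. The known background texture is supplied
# directly so these tests isolate orientation refinement from background
# estimation.
lateral_clip <- function(pitch, wings, setpoint = 0.6, duration = 0.08,
                         seed = 11, noise_sd = 0.002,
                         stationary_frames = 10L) {
  cam <- lateral_cam()
  p <- stationary_params(pitch, duration = duration, frame_rate = 5000,
                         seed = seed)
  p$ground_speed_setpoint <- setpoint
  tr <- simulate_trajectory(p)
  st <- render_frames(tr, cam, p, wings = wings, noise_sd = noise_sd)
  bg <- beeflight:::make_background_texture(cam$nrow, cam$ncol, p$seed)
  tt <- track_frame_stack(st, background = bg, stationary_eps = 0.1,
                          stationary_frames = stationary_frames)
  main <- names(which.max(table(tt$track_id)))  # dominant track = the body
  list(stack = st, params = p, background = bg,
       track = tt[tt$track_id == main, , drop = FALSE])
}

test_that("refinement of a wingless body reproduces the raw ellipse angle", {
  # noiseless render of a hovering bee: with no wings, no sensor noise
  # and no motion there is nothing for the temporal filter to remove,
  # so refined == raw (stationary pruning disabled to keep the track)
  clip <- lateral_clip(35, wings = FALSE, setpoint = 0, noise_sd = 0,
                       stationary_frames = 100000L)
  tr <- clip$track
  ref <- refine_body_orientation(tr, clip$stack, window = 0.005,
                                 background = clip$background)
  raw <- vapply(tr$ellipse_angle_deg,
                beeflight:::axial_to_pitch, numeric(1), travel_sign = 1)
  expect_true(all(abs(ref$pitch_deg - raw) < 0.1))
  expect_lt(abs(mean(raw) - 35), 1)
})

test_that("temporal filtering suppresses the wingbeat orientation wobble", {
  clip <- lateral_clip(35, wings = TRUE)
  tr <- clip$track
  raw <- vapply(tr$ellipse_angle_deg,
                beeflight:::axial_to_pitch, numeric(1), travel_sign = 1)
  expect_gt(diff(range(raw)), 5)        # raw angle oscillates
  ref <- refine_body_orientation(tr, clip$stack, window = 0.005,
                                 background = clip$background)
  m <- mean(ref$pitch_deg, na.rm = TRUE)
  expect_lt(abs(m - 35), 2)
  expect_lt(sd(ref$pitch_deg, na.rm = TRUE), diff(range(raw)) / 4)
})

test_that("reported pitch is mirror-invariant in the travel direction", {
  clip <- lateral_clip(28, wings = TRUE, seed = 13)
  ref <- refine_body_orientation(clip$track, clip$stack, window = 0.005,
                                 background = clip$background)
  # mirror the whole scene left-right: travel flips, pitch must not
  mirror <- clip$stack
  mirror$frames <- lapply(mirror$frames, function(f) f[, ncol(f):1])
  tr_m <- clip$track
  tr_m$x_px <- mirror$ncol + 1 - tr_m$x_px
  bg_m <- clip$background[, ncol(clip$background):1]
  ref_m <- refine_body_orientation(tr_m, mirror, window = 0.005,
                                   background = bg_m)
  expect_equal(ref_m$pitch_deg, ref$pitch_deg, tolerance = 1e-6)
})

test_that("windows shorter than 2 frames are rejected, multi-track input too", {
  clip <- lateral_clip(30, wings = FALSE, duration = 0.01)
  expect_error(refine_body_orientation(clip$track, clip$stack,
                                       window = 1e-4), "2 frames")
  two <- rbind(transform(clip$track, track_id = 1),
               transform(clip$track, track_id = 2))
  expect_error(refine_body_orientation(two, clip$stack, window = 0.005),
               "single track")
})
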