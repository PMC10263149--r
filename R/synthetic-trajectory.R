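#' Simulate a ground-truth flight trajectory
#'
#' Generates one flight along the tunnel under a simple speed-control
#' model: ground speed relaxes to the set-point with Gaussian
#' perturbations (first-order autoregressive), while body pitch is slaved
#' to the commanded air speed through a linear gain plus its own noise.
#' The commanded air speed is the set-point plus the flow the bee must
#' overcome, so pitch drops below \code{base_pitch} in headwinds (high
#' air-speed demand) and rises above it when braking against a tailwind.
#' Downwind runs with a tailwind have their pitch and speed noise inflated
#' by \code{tailwind_variability}.
#'
#' At every sample the true air speed equals \code{vg + |u|} when flying
#' against the flow and \code{vg - |u|} when flying with it; with a
#' tailwind faster than the set-point the air speed is negative (the bee
#' flies backwards relative to the air).
#'
#' @param params a [simulation_params()] object.
#' @return a \code{data.frame} of class \code{"true_trajectory"} with
#'   columns \code{t_s, x_m, y_m, z_m, pitch_deg, vg_mps, va_mps} and the
#'   generating parameters attached as attribute \code{"params"}.
#' @examples
#' p <- simulation_params(ground_speed_setpoint = 0.7, flow_velocity = 2,
#'                        direction = "toward_hive", seed = 7)
#' traj <- simulate_trajectory(p)
#' mean(traj$va_mps)  # close to 2.7 m/s
#' @export
simulate_trajectory <- function(params) {
  if (!inherits(params, "simulation_params")) {
    stop("`params` must be created by simulation_params()", call. = FALSE)
  }
  stopifnot_scalar_number(params$frame_rate, "frame_rate", positive = TRUE)
  stopifnot_scalar_number(params$duration, "duration", positive = TRUE)

  fs <- params$frame_rate
  dt <- 1 / fs
  n <- max(2L, as.integer(round(params$duration * fs)))
  d <- travel_sign(params$direction)
  u <- params$flow_velocity
  mult <- if (is_tailwind(params)) params$tailwind_variability else 1

  # Air speed the controller must command to hold the set-point:
  # set-point minus the signed flow component along the travel direction.
  va_cmd <- params$ground_speed_setpoint - d * u
  pitch_cmd <- params$base_pitch -
    params$pitch_flow_gain * (va_cmd - params$ground_speed_setpoint)

  with_seed(params$seed, {
    vg <- ou_series(n, dt, params$ground_speed_setpoint, params$speed_relax,
                    params$speed_noise_sd * mult,
                    init = params$ground_speed_setpoint)
    pitch <- ou_series(n, dt, pitch_cmd, params$pitch_relax,
                       params$pitch_noise_sd * mult, init = pitch_cmd)
    y <- ou_series(n, dt, params$start_y, 2, params$lateral_noise_sd,
                   init = params$start_y)
    z <- ou_series(n, dt, params$start_z, 2, params$vertical_noise_sd,
                   init = params$start_z)
  })

  x <- params$start_x + c(0, cumsum(d * vg[-n] * dt))
  z <- abs(z)  # height never below the floor
  t_s <- (seq_len(n) - 1L) * dt

  traj <- data.frame(
    t_s = t_s, x_m = x, y_m = y, z_m = z,
    pitch_deg = pitch, vg_mps = vg,
    va_mps = vg - d * u
  )
  attr(traj, "params") <- params
  class(traj) <- c("true_trajectory", "data.frame")
  traj
}

#' Write / read a trajectory as CSV
#'
#' The on-disk format keeps the documented header
#' \code{time_s, x_m, y_m, z_m, pitch_deg, vg_mps}.
#'
#' @param traj a trajectory data.frame.
#' @param path CSV file path.
#' @return \code{read_trajectory} returns a data.frame with the columns
#'   named as in [simulate_trajectory()].
#' @export
write_trajectory <- function(traj, path) {
  out <- data.frame(time_s = traj$t_s, x_m = traj$x_m, y_m = traj$y_m,
                    z_m = traj$z_m, pitch_deg = traj$pitch_deg,
                    vg_mps = traj$vg_mps)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path)
  need <- c("time_s", "x_m", "y_m", "z_m")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("trajectory file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  names(df)[names(df) == "time_s"] <- "t_s"
  df
}
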