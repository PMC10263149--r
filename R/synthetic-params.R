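#' Parameters for the synthetic flight generator
#'
#' Bundles the ground-truth quantities from which a synthetic foraging
#' flight is generated. The defaults describe the wind-tunnel conditions
#' the package targets: a bee holding a preferred ground speed of about
#' 0.8 m/s, a no-flow body pitch of 33.8 deg that is raised by roughly
#' 4.3 deg for every m/s of tailwind (and lowered likewise in headwinds,
#' reaching 42.4 deg in a 2 m/s tailwind), and a wingbeat frequency of
#' 196.2 Hz. Flights flown downwind with a tailwind inflate their pitch
#' and speed noise by \code{tailwind_variability}, reproducing the higher
#' kinematic variability observed for downwind flight.
#'
#' @param ground_speed_setpoint preferred ground speed, m/s.
#' @param flow_velocity signed flow velocity \code{u} along the tunnel
#'   x-axis (positive toward the feeder), m/s.
#' @param direction direction of travel, \code{"toward_feeder"} (+x) or
#'   \code{"toward_hive"} (-x).
#' @param base_pitch body pitch at zero air-speed demand offset, deg
#'   (nose-up positive).
#' @param pitch_flow_gain pitch change per m/s of air-speed demand, deg
#'   s/m. Pitch decreases below \code{base_pitch} when the commanded air
#'   speed exceeds the set-point (headwind) and increases when the bee
#'   must brake against a tailwind.
#' @param pitch_noise_sd,speed_noise_sd stationary SDs of the pitch (deg)
#'   and ground-speed (m/s) fluctuations.
#' @param lateral_noise_sd,vertical_noise_sd stationary SDs of lateral and
#'   vertical position wander, m.
#' @param tailwind_variability multiplier (> 1) applied to
#'   \code{pitch_noise_sd} and \code{speed_noise_sd} for downwind runs
#'   with a tailwind.
#' @param wingbeat_freq wingbeat frequency \code{f}, Hz.
#' @param wingbeat_amp amplitude of the silhouette x-oscillation caused by
#'   the flapping wings, m.
#' @param duration flight duration, s.
#' @param frame_rate sampling/camera rate \code{fs}, Hz.
#' @param start_x,start_y,start_z start position, m. \code{start_x = NULL}
#'   places the bee 0.1 m from whichever tunnel end it departs.
#' @param tunnel_length,tunnel_width working-section dimensions, m.
#' @param speed_relax,pitch_relax first-order relaxation rates (1/s) of
#'   ground speed toward the set-point and pitch toward its command.
#' @param seed integer seed; identical seeds give identical output.
#'
#' @return an object of class \code{"simulation_params"} (a validated list).
#' @seealso [simulate_trajectory()], [render_frames()]
#' @export
simulation_params <- function(ground_speed_setpoint = 0.8,
                              flow_velocity = 0,
                              direction = c("toward_feeder", "toward_hive"),
                              base_pitch = 33.8,
                              pitch_flow_gain = 4.3,
                              pitch_noise_sd = 2,
                              speed_noise_sd = 0.1,
                              lateral_noise_sd = 0.005,
                              vertical_noise_sd = 0.005,
                              tailwind_variability = 2,
                              wingbeat_freq = 196.2,
                              wingbeat_amp = 0.005,
                              duration = 1.2,
                              frame_rate = 100,
                              start_x = NULL,
                              start_y = NULL,
                              start_z = 0.2,
                              tunnel_length = 1.4,
                              tunnel_width = 0.45,
                              speed_relax = 5,
                              pitch_relax = 20,
                              seed = 1L) {
  direction <- match.arg(direction)
  stopifnot_scalar_number(frame_rate, "frame_rate", positive = TRUE)
  stopifnot_scalar_number(duration, "duration", positive = TRUE)
  stopifnot_scalar_number(ground_speed_setpoint, "ground_speed_setpoint")
  stopifnot_scalar_number(flow_velocity, "flow_velocity")
  stopifnot_scalar_number(wingbeat_freq, "wingbeat_freq", positive = TRUE)
  for (nm in c("pitch_noise_sd", "speed_noise_sd", "lateral_noise_sd",
               "vertical_noise_sd")) {
    v <- get(nm)
    stopifnot_scalar_number(v, nm)
    if (v < 0) stop(sprintf("`%s` must be >= 0", nm), call. = FALSE)
  }
  if (tailwind_variability < 1) {
    stop("`tailwind_variability` must be >= 1", call. = FALSE)
  }
  if (is.null(start_y)) start_y <- tunnel_width / 2
  if (is.null(start_x)) {
    start_x <- if (direction == "toward_feeder") 0.1 else tunnel_length - 0.1
  }
  p <- list(
    ground_speed_setpoint = ground_speed_setpoint,
    flow_velocity = flow_velocity,
    direction = direction,
    base_pitch = base_pitch,
    pitch_flow_gain = pitch_flow_gain,
    pitch_noise_sd = pitch_noise_sd,
    speed_noise_sd = speed_noise_sd,
    lateral_noise_sd = lateral_noise_sd,
    vertical_noise_sd = vertical_noise_sd,
    tailwind_variability = tailwind_variability,
    wingbeat_freq = wingbeat_freq,
    wingbeat_amp = wingbeat_amp,
    duration = duration,
    frame_rate = frame_rate,
    start_x = start_x, start_y = start_y, start_z = start_z,
    tunnel_length = tunnel_length, tunnel_width = tunnel_width,
    speed_relax = speed_relax, pitch_relax = pitch_relax,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(p) <- "simulation_params"
  p
}

#' @export
print.simulation_params <- function(x, ...) {
  cat("Synthetic flight parameters\n")
  cat(sprintf("  set-point %.2f m/s, flow u = %+.2f m/s, %s\n",
              x$ground_speed_setpoint, x$flow_velocity, x$direction))
  cat(sprintf("  pitch %.1f deg (gain %.2f deg per m/s), wingbeat %.1f Hz\n",
              x$base_pitch, x$pitch_flow_gain, x$wingbeat_freq))
  cat(sprintf("  %.2f s at %g Hz, seed %s\n", x$duration, x$frame_rate,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

# Sign of travel along x: +1 toward the feeder, -1 toward the hive.
travel_sign <- function(direction) {
  if (identical(direction, "toward_feeder")) 1 else -1
}

# TRUE when the run is downwind with a tailwind (flow aligned with travel).
is_tailwind <- function(params) {
  travel_sign(params$direction) * params$flow_velocity > 0
}
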