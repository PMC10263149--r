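#' Path sinuosity
#'
#' Total distance travelled along the 2D flight path divided by the
#' straight-line distance between its start and end points. 1 for a
#' straight monotone path; grows without bound for out-and-back paths.
#'
#' @param x,y coordinates of the path (same units); \code{y} may be
#'   omitted if \code{x} is a two-column matrix or data.frame.
#' @return sinuosity \code{S >= 1}, or \code{NA} with a warning when the
#'   start and end coincide (undefined sinuosity; such flights are
#'   flagged rather than crashing the pipeline).
#' @examples
#' path_sinuosity(1:10, rep(0, 10))  # 1
#' @export
path_sinuosity <- function(x, y = NULL) {
  if (is.null(y)) {
    y <- x[, 2]
    x <- x[, 1]
  }
  if (length(x) < 2L) stop("sinuosity needs at least 2 points", call. = FALSE)
  seg <- sum(sqrt(diff(x)^2 + diff(y)^2))
  chord <- sqrt((x[length(x)] - x[1])^2 + (y[length(y)] - y[1])^2)
  if (chord == 0) {
    warning("start and end points coincide: sinuosity undefined")
    return(NA_real_)
  }
  max(seg / chord, 1)
}

#' Ground-speed series along the tunnel axis
#'
#' Signed instantaneous speed along the tunnel's long axis (x) from
#' calibrated positions, by central finite differences (one-sided at the
#' ends). The series is reported as positive speed of travel: the sign
#' convention follows the net direction of motion, so a bee progressing
#' steadily toward either tunnel end has a positive mean.
#'
#' @param x axial positions, m.
#' @param t_s sample times, s (uniform spacing assumed).
#' @param signed return the raw signed d(x)/dt instead of
#'   travel-positive speeds.
#' @return numeric vector of speeds, m/s, same length as \code{x}.
#' @export
axial_speed_series <- function(x, t_s, signed = FALSE) {
  n <- length(x)
  if (n < 2L) stop("speed needs at least 2 samples", call. = FALSE)
  v <- numeric(n)
  v[1] <- (x[2] - x[1]) / (t_s[2] - t_s[1])
  v[n] <- (x[n] - x[n - 1]) / (t_s[n] - t_s[n - 1])
  if (n > 2L) {
    v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (t_s[3:n] - t_s[1:(n - 2)])
  }
  if (signed) return(v)
  d <- sign(x[n] - x[1])
  if (d == 0) d <- 1
  d * v
}

#' Air-speed series from ground speed and flow condition
#'
#' Air speed is the flow velocity added to the ground speed for upwind
#' flight, or subtracted from it for downwind flight. Negative values are
#' permitted: a bee flying downwind in a tailwind faster than its ground
#' speed moves backwards relative to the air.
#'
#' @param vg ground-speed series (travel-positive), m/s.
#' @param u flow speed magnitude, m/s (>= 0).
#' @param direction \code{"upwind"} or \code{"downwind"}.
#' @return list with \code{va} (series), \code{mean}, \code{sd}
#'   (sample SD).
#' @examples
#' air_speed_series(0.7, 2, "upwind")$mean   # 2.7
#' air_speed_series(0.9, 0.75, "downwind")$mean  # 0.15
#' @export
air_speed_series <- function(vg, u, direction = c("upwind", "downwind")) {
  if (length(direction) != 1L || !direction %in% c("upwind", "downwind")) {
    stop("`direction` must be \"upwind\" or \"downwind\"", call. = FALSE)
  }
  if (u < 0) stop("`u` is a flow speed magnitude and must be >= 0",
                  call. = FALSE)
  va <- if (direction == "upwind") vg + u else vg - u
  list(va = va, mean = mean(va),
       sd = if (length(va) > 1L) sd(va) else 0)
}

#' Body-angle summary
#'
#' Arithmetic mean and sample SD of a pitch-angle series. Flight pitch
#' spans far less than 180 degrees, so ordinary (non-circular) statistics
#' apply.
#'
#' @param angles pitch angles in degrees, ambiguity already resolved.
#' @return list with \code{mean} and \code{sd} (deg).
#' @export
body_angle_stats <- function(angles) {
  angles <- angles[is.finite(angles)]
  if (!length(angles)) stop("empty angle series", call. = FALSE)
  list(mean = mean(angles),
       sd = if (length(angles) > 1L) sd(angles) else 0)
}

#' Wingbeat frequency by FFT peak detection
#'
#' The silhouette x-velocity of a flying bee carries a slow component
#' (centre-of-mass motion) and a fast component at the wingbeat
#' frequency. After mean removal, the estimator takes the FFT of the
#' series and returns the frequency of maximum power within a search
#' band that excludes the slow/DC component. The spectral resolution
#' \code{fs/N} is reported alongside. When no in-band peak rises above
#' the noise floor (peak power < \code{peak_factor} times the median
#' in-band power), the frequency is flagged undefined.
#'
#' @param v x-velocity series (any consistent units).
#' @param fs sampling rate, Hz.
#' @param band search band \code{c(f_lo, f_hi)} in Hz.
#' @param peak_factor peak-to-median power ratio below which the result
#'   is flagged undefined.
#' @return list with \code{freq_hz} (NA when undefined),
#'   \code{resolution_hz} (= fs/N), \code{defined} (logical), and
#'   \code{power} (the in-band power spectrum as a data.frame).
#' @export
flapping_frequency <- function(v, fs, band = c(50, 400), peak_factor = 5) {
  n <- length(v)
  if (n < 8L) stop("series too short for spectral estimation", call. = FALSE)
  v <- v - mean(v)
  pw <- Mod(fft(v))^2 / n
  freqs <- (seq_len(n) - 1L) * fs / n
  half <- seq_len(floor(n / 2))
  freqs <- freqs[half]; pw <- pw[half]
  sel <- which(freqs >= band[1] & freqs <= band[2])
  res <- fs / n
  if (!length(sel)) {
    return(list(freq_hz = NA_real_, resolution_hz = res, defined = FALSE,
                power = data.frame(freq_hz = numeric(0), power = numeric(0))))
  }
  spec <- data.frame(freq_hz = freqs[sel], power = pw[sel])
  peak <- which.max(spec$power)
  defined <- spec$power[peak] > peak_factor * median(spec$power) &&
    spec$power[peak] > 0
  list(freq_hz = if (defined) spec$freq_hz[peak] else NA_real_,
       resolution_hz = res, defined = defined, power = spec)
}

#' Restrict a trajectory to the central tunnel section
#'
#' Keeps the longest contiguous sub-trajectory whose axial position lies
#' inside \code{bounds} (default: the central 30 cm of a 1.4 m tunnel,
#' where bees are in steady translation rather than taking off or
#' landing).
#'
#' @param traj data.frame with a column \code{x_m}.
#' @param bounds numeric length 2, inclusive x-range in metres.
#' @return the sub-trajectory (possibly 0 rows).
#' @export
restrict_to_central_section <- function(traj, bounds = c(0.55, 0.85)) {
  inside <- traj$x_m >= bounds[1] & traj$x_m <= bounds[2]
  if (!any(inside)) return(traj[0, , drop = FALSE])
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  traj[starts[best]:ends[best], , drop = FALSE]
}

#' Apply the standard flight inclusion filters
#'
#' Sets exclusion flags per flight: \code{high_sinuosity} when sinuosity
#' exceeds \code{sinuosity_max} (1.1: flights with reversals or loops
#' experience fluctuating optic flow), \code{low_speed} when mean ground
#' speed falls below \code{min_ground_speed} (0.02 m/s: the low mode of
#' the bimodal speed distribution, i.e. walking), \code{walking} when the
#' whole 3D track stays below \code{min_height} (1.5 cm above the floor),
#' and \code{short} when the flight has fewer than \code{min_frames}
#' samples. Retained flights carry no flag; boundary values (S = 1.1,
#' vg = 0.02) are retained. The filter is idempotent and partitions the
#' input.
#'
#' @param records data.frame of flight records with columns
#'   \code{sinuosity}, \code{mean_vg} and optionally \code{max_z_m},
#'   \code{n_frames}.
#' @param sinuosity_max,min_ground_speed,min_height,min_frames cutoffs.
#' @return the input with logical flag columns \code{high_sinuosity},
#'   \code{low_speed}, \code{walking}, \code{short} and \code{retained}
#'   added, plus an attribute \code{"filter_counts"}.
#' @export
apply_flight_filters <- function(records, sinuosity_max = 1.1,
                                 min_ground_speed = 0.02,
                                 min_height = 0.015,
                                 min_frames = 6L) {
  n <- nrow(records)
  records$high_sinuosity <-
    !is.na(records$sinuosity) & records$sinuosity > sinuosity_max |
    is.na(records$sinuosity)
  records$low_speed <- records$mean_vg < min_ground_speed
  records$walking <- if ("max_z_m" %in% names(records)) {
    !is.na(records$max_z_m) & records$max_z_m < min_height
  } else rep(FALSE, n)
  records$short <- if ("n_frames" %in% names(records)) {
    records$n_frames < min_frames
  } else rep(FALSE, n)
  records$retained <- !(records$high_sinuosity | records$low_speed |
                          records$walking | records$short)
  attr(records, "filter_counts") <- c(
    input = n,
    high_sinuosity = sum(records$high_sinuosity),
    low_speed = sum(records$low_speed),
    walking = sum(records$walking),
    short = sum(records$short),
    retained = sum(records$retained)
  )
  records
}

#' Classify travel direction and channel of a flight
#'
#' Channel membership comes from the mean lateral position relative to
#' the divider; travel direction from the sign of the net axial
#' displacement; the flight is upwind when its travel direction opposes
#' the flow direction configured for its channel. Flights whose net
#' axial displacement is below \code{min_displacement} are flagged
#' ambiguous instead of being guessed.
#'
#' @param traj data.frame with \code{x_m}, \code{y_m}.
#' @param arena list with \code{divider_y} (m) and \code{flow_dir}, a
#'   named vector like \code{c(left = -1, right = 1)} giving the signed
#'   flow direction along x in each channel (0 = no flow).
#' @param min_displacement minimum |net dx| in metres.
#' @return list with \code{channel} (\code{"left"}/\code{"right"}),
#'   \code{travel} (+1 toward feeder, -1 toward hive), \code{heading}
#'   (\code{"upwind"}/\code{"downwind"}/\code{"no_flow"}) and
#'   \code{ambiguous} (logical).
#' @export
classify_direction_and_channel <- function(traj, arena,
                                           min_displacement = 0.05) {
  dx <- traj$x_m[nrow(traj)] - traj$x_m[1]
  channel <- if (mean(traj$y_m) < arena$divider_y) "left" else "right"
  ambiguous <- abs(dx) < min_displacement
  travel <- sign(dx)
  flow <- arena$flow_dir[[channel]]
  heading <- if (ambiguous || flow == 0) {
    if (flow == 0) "no_flow" else NA_character_
  } else if (travel * flow < 0) "upwind" else "downwind"
  list(channel = channel, travel = travel, heading = heading,
       ambiguous = ambiguous)
}
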