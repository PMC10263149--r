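#' Track every object in a frame stack
#'
#' Convenience chain: median background, per-frame detection, Kalman
#' association and pruning, returning an analysis-ready track table with
#' time stamps.
#'
#' @param stack a [frame_stack()].
#' @param threshold,min_area segmentation parameters
#'   (see [detect_objects()]).
#' @param gate_px,max_missed association parameters
#'   (see [associate_detections()]).
#' @param min_len,stationary_eps,stationary_frames pruning parameters
#'   (see [prune_tracks()]).
#' @param background optional precomputed background (reused across
#'   stacks sharing a scene).
#' @param background_sample_every see [compute_background()].
#' @return data.frame with columns \code{track_id, frame, t_s, x_px,
#'   y_px, area_px, ellipse_major_px, ellipse_minor_px, ellipse_angle_deg,
#'   kalman_vx, kalman_vy}.
#' @export
track_frame_stack <- function(stack, threshold = 0.2, min_area = 9L,
                              gate_px = 30, max_missed = 3L,
                              min_len = 6L, stationary_eps = 0.5,
                              stationary_frames = 10L,
                              background = NULL,
                              background_sample_every = 1L) {
  if (is.null(background)) {
    background <- compute_background(stack, background_sample_every)
  }
  det <- detect_stack(stack, background, threshold, min_area)
  tr <- associate_detections(det, gate_px, max_missed)
  tr <- prune_tracks(tr, min_len, stationary_eps, stationary_frames)
  if (!nrow(tr)) {
    return(data.frame(track_id = integer(0), frame = integer(0),
                      t_s = numeric(0), x_px = numeric(0), y_px = numeric(0),
                      area_px = numeric(0), ellipse_major_px = numeric(0),
                      ellipse_minor_px = numeric(0),
                      ellipse_angle_deg = numeric(0),
                      kalman_vx = numeric(0), kalman_vy = numeric(0)))
  }
  data.frame(track_id = tr$track_id, frame = tr$frame,
             t_s = (tr$frame - 1) / stack$frame_rate,
             x_px = tr$x_px, y_px = tr$y_px, area_px = tr$area_px,
             ellipse_major_px = tr$major_px, ellipse_minor_px = tr$minor_px,
             ellipse_angle_deg = tr$angle_deg,
             kalman_vx = tr$kalman_vx, kalman_vy = tr$kalman_vy)
}

#' Convert a pixel track to calibrated metres
#'
#' Applies the planar camera calibration: for an overhead view columns
#' map to x and rows to y; for a lateral view columns map to x and rows
#' (inverted) to z.
#'
#' @param track a track table in pixels.
#' @param cam the [camera_overhead()] / [camera_lateral()] model.
#' @return the track with columns \code{x_m} and \code{y_m} (overhead)
#'   or \code{x_m} and \code{z_m} (lateral) added.
#' @export
calibrate_track <- function(track, cam) {
  ppm <- cam$px_per_m
  track$x_m <- (track$x_px - 1) / ppm + cam$origin_x
  if (cam$view == "overhead") {
    track$y_m <- (track$y_px - 1) / ppm + cam$origin_y
  } else {
    track$z_m <- (cam$nrow - track$y_px) / ppm + cam$origin_z
  }
  track
}

#' Summarise one tracked flight
#'
#' Computes the per-flight kinematic summary from a calibrated track:
#' travel-positive mean/SD ground speed along x (central differences, or
#' the Kalman state velocity if \code{velocity = "kalman"}), mean/SD air
#' speed under the declared flow, 2D path sinuosity, optional body-pitch
#' statistics and wingbeat frequency.
#'
#' @param track calibrated track (needs \code{t_s}, \code{x_m} and
#'   \code{y_m} or \code{z_m}).
#' @param u flow speed magnitude, m/s.
#' @param heading \code{"upwind"}, \code{"downwind"} or \code{"no_flow"}.
#' @param velocity \code{"central"} (finite differences, default) or
#'   \code{"kalman"} (filter state, converted with \code{px_per_m}).
#' @param px_per_m needed for \code{velocity = "kalman"}.
#' @param frame_rate frames per second (for Kalman velocity conversion).
#' @param pitch_deg optional refined pitch series for the same frames.
#' @param flap_from optional x-velocity series for wingbeat estimation
#'   (defaults to none).
#' @return one-row data.frame with columns \code{direction, u_mps,
#'   mean_vg, sd_vg, mean_va, sd_va, sinuosity, mean_pitch, sd_pitch,
#'   flap_hz, n_frames, max_z_m}.
#' @export
summarize_flight <- function(track, u, heading = c("no_flow", "upwind",
                                                   "downwind"),
                             velocity = c("central", "kalman"),
                             px_per_m = NULL, frame_rate = NULL,
                             pitch_deg = NULL, flap_from = NULL) {
  heading <- match.arg(heading)
  velocity <- match.arg(velocity)
  track <- track[order(track$t_s), , drop = FALSE]
  lat <- if ("y_m" %in% names(track)) track$y_m else track$z_m
  vg <- if (velocity == "kalman") {
    if (is.null(px_per_m) || is.null(frame_rate)) {
      stop("kalman velocity needs `px_per_m` and `frame_rate`", call. = FALSE)
    }
    d <- sign(track$x_m[nrow(track)] - track$x_m[1]); if (d == 0) d <- 1
    d * track$kalman_vx / px_per_m * frame_rate
  } else {
    axial_speed_series(track$x_m, track$t_s)
  }
  va <- if (heading == "no_flow") {
    list(va = vg, mean = mean(vg), sd = if (length(vg) > 1) sd(vg) else 0)
  } else {
    air_speed_series(vg, u, heading)
  }
  sinu <- tryCatch(path_sinuosity(track$x_m, lat),
                   warning = function(w) NA_real_)
  pit <- if (!is.null(pitch_deg) && any(is.finite(pitch_deg))) {
    body_angle_stats(pitch_deg)
  } else list(mean = NA_real_, sd = NA_real_)
  flap <- if (!is.null(flap_from) && !is.null(frame_rate)) {
    flapping_frequency(flap_from, frame_rate)$freq_hz
  } else NA_real_
  data.frame(direction = heading, u_mps = u,
             mean_vg = mean(vg), sd_vg = if (length(vg) > 1) sd(vg) else 0,
             mean_va = va$mean, sd_va = va$sd,
             sinuosity = sinu,
             mean_pitch = pit$mean, sd_pitch = pit$sd,
             flap_hz = flap,
             n_frames = nrow(track),
             max_z_m = if ("z_m" %in% names(track)) max(track$z_m) else
               NA_real_)
}

#' Run the full tracking + kinematics chain on one stack
#'
#' simulate -> render -> \strong{track -> kinematics}: estimates the
#' background, tracks all objects, calibrates to metres, optionally
#' restricts to the central tunnel section, summarises each track as a
#' flight record and applies the standard inclusion filters.
#'
#' @param stack a [frame_stack()] whose \code{camera} is a planar model.
#' @param u flow speed magnitude, m/s.
#' @param flow_dir signed flow direction along x (+1 toward feeder,
#'   -1 toward hive, 0 none).
#' @param central_bounds optional x-range (m) for
#'   [restrict_to_central_section()]; NULL to skip.
#' @param background optional precomputed background.
#' @param ... tracking parameters passed to [track_frame_stack()].
#' @return data.frame of flight records (one per track) with filter
#'   flags, as from [apply_flight_filters()].
#' @export
analyze_stack <- function(stack, u = 0, flow_dir = 0,
                          central_bounds = NULL, background = NULL, ...) {
  cam <- stack$camera
  if (is.null(cam)) stop("stack carries no planar camera model", call. = FALSE)
  tracks <- track_frame_stack(stack, background = background, ...)
  if (!nrow(tracks)) return(apply_flight_filters(empty_flight_table()))
  recs <- lapply(split(tracks, tracks$track_id), function(tr) {
    tr <- calibrate_track(tr, cam)
    if (!is.null(central_bounds)) {
      tr <- restrict_to_central_section(tr, central_bounds)
      if (nrow(tr) < 2L) return(NULL)
    }
    d <- sign(tr$x_m[nrow(tr)] - tr$x_m[1]); if (d == 0) d <- 1
    heading <- if (u == 0 || flow_dir == 0) "no_flow" else
      if (d * flow_dir < 0) "upwind" else "downwind"
    rec <- summarize_flight(tr, u, heading)
    rec$flight_id <- tr$track_id[1]
    rec
  })
  recs <- recs[!vapply(recs, is.null, TRUE)]
  if (!length(recs)) return(apply_flight_filters(empty_flight_table()))
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  apply_flight_filters(out[, c("flight_id",
                               setdiff(names(out), "flight_id"))])
}

empty_flight_table <- function() {
  data.frame(flight_id = integer(0), direction = character(0),
             u_mps = numeric(0), mean_vg = numeric(0), sd_vg = numeric(0),
             mean_va = numeric(0), sd_va = numeric(0),
             sinuosity = numeric(0), mean_pitch = numeric(0),
             sd_pitch = numeric(0), flap_hz = numeric(0),
             n_frames = integer(0), max_z_m = numeric(0))
}
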