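# Shared fixture builders. Everything is generated in code; no files.

# A flat frame with one (or more) rendered soft-edged ellipses.
render_test_frame <- function(nrow = 120, ncol = 160, bg = 0.75,
                              ellipses = list()) {
  img <- matrix(bg, nrow, ncol)
  for (e in ellipses) {
    img <- beeflight:::draw_ellipse_px(img, e$cx, e$cy, e$a, e$b,
                                       e$angle, e$value %||% 0.1)
  }
  img
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Noiseless stationary simulation parameters at a given pitch.
stationary_params <- function(pitch, duration = 0.01, frame_rate = 5000,
                              seed = 5, ...) {
  simulation_params(ground_speed_setpoint = 0, flow_velocity = 0,
                    base_pitch = pitch, pitch_noise_sd = 0,
                    speed_noise_sd = 0, lateral_noise_sd = 0,
                    vertical_noise_sd = 0, duration = duration,
                    frame_rate = frame_rate, start_x = 0.7, start_z = 0.2,
                    seed = seed, ...)
}

lateral_cam <- function() camera_lateral(origin_x = 0.65, origin_z = 0.15)

# Detection table for synthetic point objects: `paths` is a list of
# n x 2 position matrices (one per object), one row per frame.
detections_from_paths <- function(paths, frames = NULL) {
  out <- list()
  for (p in paths) {
    n <- nrow(p)
    fr <- if (is.null(frames)) seq_len(n) else frames
    out[[length(out) + 1L]] <- data.frame(
      frame = fr, x_px = p[, 1], y_px = p[, 2], area_px = 20,
      major_px = 5, minor_px = 2, angle_deg = 0)
  }
  df <- do.call(rbind, out)
  df[order(df$frame), , drop = FALSE]
}

# Independent brute-force tracker: global minimum-total-distance
# assignment per frame by explicit permutation enumeration, predicting
# with the object's last position plus its last observed displacement.
# Written without reference to the package's Kalman machinery so it can
# serve as an oracle for association.
oracle_track <- function(detections, gate) {
  det <- detections[order(detections$frame), , drop = FALSE]
  det$oracle_id <- NA_integer_
  tracks <- list()  # each: list(id, pos, vel)
  next_id <- 1L
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  for (f in unique(det$frame)) {
    rows <- which(det$frame == f)
    m <- length(rows)
    nt <- length(tracks)
    assigned_det <- rep(NA_integer_, m)
    if (nt && m) {
      pred <- t(vapply(tracks, function(tr) tr$pos + tr$vel, numeric(2)))
      best <- NULL; best_cost <- Inf
      k <- min(nt, m)
      # enumerate which tracks take which detections (incl. unmatched)
      cand_sets <- if (nt <= m) list(seq_len(nt)) else
        utils::combn(nt, m, simplify = FALSE)
      for (trs in cand_sets) {
        for (pp in perms(seq_len(m))) {
          dd <- sqrt(rowSums((pred[trs, , drop = FALSE] -
                                cbind(det$x_px[rows][pp[seq_along(trs)]],
                                      det$y_px[rows][pp[seq_along(trs)]]))^2))
          if (any(dd > gate)) next
          cost <- sum(dd)
          if (cost < best_cost) {
            best_cost <- cost
            best <- list(trs = trs, pp = pp)
          }
        }
      }
      if (!is.null(best)) {
        for (ii in seq_along(best$trs)) {
          ti <- best$trs[ii]; di <- best$pp[ii]
          j <- rows[di]
          newpos <- c(det$x_px[j], det$y_px[j])
          tracks[[ti]]$vel <- newpos - tracks[[ti]]$pos
          tracks[[ti]]$pos <- newpos
          det$oracle_id[j] <- tracks[[ti]]$id
          assigned_det[di] <- ti
        }
      }
    }
    for (di in which(is.na(assigned_det))) {
      j <- rows[di]
      tracks[[length(tracks) + 1L]] <- list(
        id = next_id, pos = c(det$x_px[j], det$y_px[j]), vel = c(0, 0))
      det$oracle_id[j] <- next_id
      next_id <- next_id + 1L
    }
  }
  det
}

# Partition of detection row keys by track, for label-free comparison.
track_partition <- function(df, id_col) {
  key <- paste(df$frame, round(df$x_px, 6), round(df$y_px, 6))
  unname(lapply(split(key, df[[id_col]]), sort))
}
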