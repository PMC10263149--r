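#' Frame stacks
#'
#' A frame stack is the package's in-memory representation of a grayscale
#' video: a list of numeric matrices in \code{[0, 1]} (rows by columns)
#' plus the frame rate, spatial calibration and view label. Stacks are
#' produced by the synthetic renderer and consumed by the tracking stage;
#' [write_frame_stack()] stores them as numbered PNG files with a sidecar
#' JSON metadata file.
#'
#' @param frames list of numeric matrices with identical dimensions.
#' @param frame_rate frames per second.
#' @param px_per_m pixels per metre (NA for perspective views).
#' @param view label, e.g. \code{"overhead"}, \code{"lateral"}.
#' @param camera optional camera model used to produce the stack.
#' @return an object of class \code{"frame_stack"}.
#' @export
frame_stack <- function(frames, frame_rate, px_per_m = NA_real_,
                        view = "unknown", camera = NULL) {
  if (!length(frames)) stop("empty frame stack", call. = FALSE)
  d <- dim(frames[[1]])
  structure(list(frames = frames, frame_rate = frame_rate,
                 px_per_m = px_per_m, view = view, camera = camera,
                 nrow = d[1], ncol = d[2]),
            class = "frame_stack")
}

#' @export
length.frame_stack <- function(x) length(x$frames)

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("Frame stack: %d frame(s) of %dx%d px, %g Hz, view '%s'\n",
              length(x$frames), x$nrow, x$ncol, x$frame_rate, x$view))
  invisible(x)
}

# Blend a flat-shaded ellipse into an image. `theta_deg` is measured
# counter-clockwise from the +column axis with "up" meaning decreasing
# row index. Edges are anti-aliased by 2x2 subsampling so that moment-
# based ellipse fits recover subpixel geometry.
draw_ellipse_px <- function(img, c_col, c_row, a_px, b_px, theta_deg, value) {
  ext <- max(a_px, b_px) + 1
  rows <- max(1L, floor(c_row - ext)):min(nrow(img), ceiling(c_row + ext))
  cols <- max(1L, floor(c_col - ext)):min(ncol(img), ceiling(c_col + ext))
  if (!length(rows) || !length(cols)) return(img)
  th <- deg2rad(theta_deg)
  ct <- cos(th); st <- sin(th)
  cover <- matrix(0, length(rows), length(cols))
  for (or in c(-0.25, 0.25)) {
    for (oc in c(-0.25, 0.25)) {
      dx <- outer(rep(1, length(rows)), cols + oc - c_col)
      dy <- outer(c_row - (rows + or), rep(1, length(cols)))  # up positive
      uu <- (dx * ct + dy * st) / a_px
      vv <- (-dx * st + dy * ct) / b_px
      cover <- cover + (uu * uu + vv * vv <= 1)
    }
  }
  cover <- cover / 4
  img[rows, cols] <- img[rows, cols] * (1 - cover) + value * cover
  img
}

# Deterministic speckled background texture for a given image geometry.
make_background_texture <- function(nrow, ncol, seed) {
  with_seed(seed, matrix(runif(nrow * ncol, 0.55, 0.95), nrow, ncol))
}

#' Render a trajectory into camera frames
#'
#' Draws, for every trajectory sample, a dark elliptical body silhouette
#' at the projected position and pitch over a fixed speckled background,
#' plus (lateral view, optional) two smaller wing ellipses whose
#' x-offset oscillates sinusoidally at the wingbeat frequency. The
#' silhouette x-centroid therefore carries a slow component from body
#' translation and a fast component from the flapping wings. Rendering is
#' deterministic given the parameter seed.
#'
#' @param traj a trajectory from [simulate_trajectory()].
#' @param cam a planar [camera_overhead()] or [camera_lateral()] model.
#' @param params the [simulation_params()] used to generate \code{traj}
#'   (supplies wingbeat frequency/amplitude and the seed).
#' @param body_len,body_width body silhouette axes, m.
#' @param body_intensity grayscale value of the body (dark on light).
#' @param wings render flapping wing ellipses (default: lateral view only).
#' @param wing_len,wing_width,wing_intensity wing ellipse geometry and shade.
#' @param noise_sd per-pixel Gaussian sensor noise SD.
#' @param background optional fixed background matrix; default is a
#'   seeded speckle texture.
#' @return a [frame_stack()].
#' @export
render_frames <- function(traj, cam, params,
                          body_len = 0.013, body_width = 0.005,
                          body_intensity = 0.08,
                          wings = NULL,
                          wing_len = 0.008, wing_width = 0.003,
                          wing_intensity = 0.25,
                          noise_sd = 0.002,
                          background = NULL) {
  if (!inherits(cam, "camera_model")) {
    stop("`cam` must be a planar camera model", call. = FALSE)
  }
  if (is.null(wings)) wings <- identical(cam$view, "lateral")
  n <- nrow(traj)
  px <- project_planar(cam, traj$x_m, traj$y_m, traj$z_m)
  vis <- in_fov(cam, px)
  if (!any(vis)) {
    stop("trajectory entirely outside the camera field of view",
         call. = FALSE)
  }
  d <- travel_sign(params$direction)
  ppm <- cam$px_per_m
  a_px <- body_len / 2 * ppm
  b_px <- body_width / 2 * ppm

  # Image-plane orientation of the body axis per frame.
  if (cam$view == "lateral") {
    th <- rad2deg(atan2(sin(deg2rad(traj$pitch_deg)),
                        d * cos(deg2rad(traj$pitch_deg))))
  } else {
    dx <- c(diff(traj$x_m), 0); dy <- c(diff(traj$y_m), 0)
    dx[n] <- dx[max(1, n - 1)]; dy[n] <- dy[max(1, n - 1)]
    th <- rad2deg(atan2(-dy, dx))  # row grows with y, so flip for "up"
    th[!is.finite(th)] <- 0
  }

  seed <- params$seed
  with_seed(seed, {
    bg <- if (is.null(background)) {
      matrix(runif(cam$nrow * cam$ncol, 0.55, 0.95), cam$nrow, cam$ncol)
    } else background
    noise <- if (noise_sd > 0) {
      rnorm(as.numeric(cam$nrow) * cam$ncol * n, 0, noise_sd)
    } else NULL
    frames <- vector("list", n)
    npix <- cam$nrow * cam$ncol
    for (i in seq_len(n)) {
      img <- bg
      if (vis[i]) {
        img <- draw_ellipse_px(img, px$col[i], px$row[i], a_px, b_px,
                               th[i], body_intensity)
        if (wings) {
          osc <- params$wingbeat_amp *
            sin(2 * pi * params$wingbeat_freq * traj$t_s[i])
          wa <- wing_len / 2 * ppm
          wb <- wing_width / 2 * ppm
          up_off <- 0.6 * b_px  # wing root sits on the dorsal body edge
          along <- 0.0015 * ppm
          thr <- deg2rad(th[i])
          for (s in c(-1, 1)) {
            wc_col <- px$col[i] + s * along * cos(thr) + osc * ppm
            wc_row <- px$row[i] - s * along * sin(thr) - up_off
            img <- draw_ellipse_px(img, wc_col, wc_row, wa, wb,
                                   th[i] + 70, wing_intensity)
          }
        }
      }
      if (!is.null(noise)) {
        img <- img + noise[((i - 1) * npix + 1):(i * npix)]
      }
      frames[[i]] <- pmin(pmax(img, 0), 1)
    }
  })
  frame_stack(frames, params$frame_rate, ppm, cam$view, camera = cam)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a synchronized stereo scene
#'
#' Projects a 3D trajectory into both cameras of an ideal pinhole stereo
#' pair and renders a circular body silhouette in each view, returning
#' the two synchronized stacks together with the exact calibration used,
#' so triangulation can be tested against ground truth.
#'
#' @param traj trajectory with columns \code{x_m, y_m, z_m} (metres).
#' @param pair a [stereo_camera_pair()].
#' @param params a [simulation_params()] (frame rate, seed).
#' @param body_diam silhouette diameter, m.
#' @param body_intensity,noise_sd as in [render_frames()].
#' @return list with elements \code{a}, \code{b} (frame stacks) and
#'   \code{calibration} (the stereo pair).
#' @export
make_stereo_scene <- function(traj, pair, params, body_diam = 0.012,
                              body_intensity = 0.08, noise_sd = 0.002) {
  if (!inherits(pair, "stereo_pair")) {
    stop("`pair` must be a stereo_camera_pair()", call. = FALSE)
  }
  X <- cbind(traj$x_m, traj$y_m, traj$z_m)
  n <- nrow(X)
  pa <- project_pinhole(pair$a$P, X)
  pb <- project_pinhole(pair$b$P, X)
  visible <- function(p, cam) {
    p$depth > 0 & p$col >= 1 & p$col <= cam$ncol &
      p$row >= 1 & p$row <= cam$nrow
  }
  vis <- visible(pa, pair$a) & visible(pb, pair$b)
  if (!any(vis)) {
    stop("trajectory entirely outside the common field of view",
         call. = FALSE)
  }
  render_one <- function(p, cam, seed) {
    with_seed(seed, {
      bg <- matrix(runif(cam$nrow * cam$ncol, 0.55, 0.95), cam$nrow, cam$ncol)
      frames <- vector("list", n)
      for (i in seq_len(n)) {
        img <- bg
        if (vis[i]) {
          r_px <- body_diam / 2 * cam$f_px / p$depth[i]
          img <- draw_ellipse_px(img, p$col[i], p$row[i], r_px, 0.75 * r_px,
                                 0, body_intensity)
        }
        if (noise_sd > 0) {
          img <- img + matrix(rnorm(cam$nrow * cam$ncol, 0, noise_sd),
                              cam$nrow, cam$ncol)
        }
        frames[[i]] <- pmin(pmax(img, 0), 1)
      }
      frames
    })
  }
  base_seed <- params$seed %||% 0L
  sa <- frame_stack(render_one(pa, pair$a, base_seed),
                    params$frame_rate, NA_real_, "stereo_a")
  sb <- frame_stack(render_one(pb, pair$b, base_seed + 1L),
                    params$frame_rate, NA_real_, "stereo_b")
  list(a = sa, b = sb, calibration = pair)
}

#' Write / read a frame stack as a PNG sequence
#'
#' Frames are written as zero-padded numbered grayscale PNG files
#' (\code{frame_000001.png}, ...) with a sidecar \code{meta.json}
#' recording \code{frame_rate_hz}, \code{px_per_m}, \code{view} and
#' \code{n_frames}.
#'
#' @param stack a [frame_stack()].
#' @param dir output directory (created if needed).
#' @return \code{read_frame_stack} returns a [frame_stack()].
#' @export
write_frame_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(stack$frames)) {
    png::writePNG(stack$frames[[i]],
                  file.path(dir, sprintf("frame_%06d.png", i)))
  }
  meta <- list(frame_rate_hz = stack$frame_rate, px_per_m = stack$px_per_m,
               view = stack$view, n_frames = length(stack$frames))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.(png|PNG)$",
                           full.names = TRUE))
  if (!length(files)) stop("no frame images found in ", dir, call. = FALSE)
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(frame_rate_hz = NA_real_, px_per_m = NA_real_, view = "unknown")
  }
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img
  })
  frame_stack(frames, meta$frame_rate_hz, meta$px_per_m, meta$view)
}
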