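#' Refine body orientation by suppressing the wings
#'
#' The raw per-frame ellipse orientation of a flying bee oscillates at
#' the wingbeat frequency because the wing silhouette is fused with the
#' body. Applying a per-pixel temporal quantile filter over a window of
#' at least one wingbeat period to the track's image neighbourhood
#' (motion-compensated on the low-passed track) removes the fast-moving
#' wings while the slow-moving body survives: the body darkens a pixel
#' throughout the window, a sweeping wing only a fraction of it, so an
#' upper quantile (default 0.75; 0.5 is the plain temporal median)
#' restores the background wherever wing coverage stays below that
#' fraction. Re-thresholding and re-fitting the ellipse on the filtered
#' crop then recovers the body axis alone. The 180-degree axial ambiguity is resolved nose-forward using
#' the track's direction of travel, giving a signed pitch in degrees
#' (positive nose-up), identical for a bee flying left-to-right and its
#' mirror image flying right-to-left.
#'
#' @param track one track's rows from [associate_detections()] (a single
#'   \code{track_id}).
#' @param stack the [frame_stack()] the track was measured in.
#' @param window temporal filter window in seconds (>= 2 frames; at least
#'   one wingbeat period for effective wing removal).
#' @param background optional precomputed background.
#' @param threshold,min_area as in [detect_objects()].
#' @param crop_px half-size of the neighbourhood around the tracked
#'   position that is filtered and refitted.
#' @param q temporal quantile of the filter in (0, 1).
#' @return data.frame with columns \code{frame}, \code{pitch_deg}
#'   (NA where the filtered detection is lost).
#' @export
refine_body_orientation <- function(track, stack, window,
                                    background = NULL, threshold = 0.2,
                                    min_area = 9L, crop_px = 40L,
                                    q = 0.75) {
  fs <- stack$frame_rate
  w <- as.integer(round(window * fs))
  if (w < 2L) stop("`window` must span at least 2 frames", call. = FALSE)
  if ("track_id" %in% names(track) &&
      length(unique(track$track_id)) > 1L) {
    stop("`track` must contain a single track; subset by track_id first",
         call. = FALSE)
  }
  if (is.null(background)) background <- compute_background(stack)
  nfr <- length(stack$frames)
  track <- track[order(track$frame), , drop = FALSE]
  d <- sign(track$x_px[nrow(track)] - track$x_px[1])
  if (is.na(d) || d == 0) d <- 1
  half <- w %/% 2L
  pitch <- rep(NA_real_, nrow(track))
  # Registration centers for the motion-compensated median: the track
  # positions low-passed over the window (the raw centroid wobbles at the
  # wingbeat frequency; only the slow body motion must be followed),
  # interpolated to every stack frame.
  xs <- running_mean(track$x_px, w)
  ys <- running_mean(track$y_px, w)
  px_at <- stats::approx(track$frame, xs, xout = seq_len(nfr), rule = 2)$y
  py_at <- stats::approx(track$frame, ys, xout = seq_len(nfr), rule = 2)$y
  crop_range <- function(center, limit) {
    c0 <- round(center) - crop_px
    c0 <- max(1L, min(c0, limit - 2L * crop_px))
    c0:(c0 + 2L * crop_px)
  }
  for (k in seq_len(nrow(track))) {
    f <- track$frame[k]
    lo <- max(1L, f - half); hi <- min(nfr, f + half)
    if (hi - lo + 1L < 3L) next
    # integer offsets relative to the anchor frame keep perfectly still
    # scenes perfectly registered (offset 0 until drift exceeds half a px)
    ranges <- lapply(lo:hi, function(j) {
      list(r = crop_range(py_at[f], stack$nrow) +
             as.integer(round(py_at[j] - py_at[f])),
           c = crop_range(px_at[f], stack$ncol) +
             as.integer(round(px_at[j] - px_at[f])))
    })
    ok <- vapply(ranges, function(rc) {
      min(rc$r) >= 1 && max(rc$r) <= stack$nrow &&
        min(rc$c) >= 1 && max(rc$c) <= stack$ncol
    }, TRUE)
    ranges <- ranges[ok]
    fr_idx <- (lo:hi)[ok]
    if (length(fr_idx) < 3L) next
    crops <- lapply(seq_along(fr_idx), function(i) {
      stack$frames[[fr_idx[i]]][ranges[[i]]$r, ranges[[i]]$c]
    })
    med <- temporal_quantile(crops, q)
    # reference: the same registered filter applied to the static scene
    ref <- temporal_quantile(lapply(ranges, function(rc) {
      background[rc$r, rc$c]
    }), q)
    det <- detect_objects(med, ref, threshold, min_area)
    if (!nrow(det)) next
    cx <- track$x_px[k] - crop_range(px_at[f], stack$ncol)[1] + 1
    cy <- track$y_px[k] - crop_range(py_at[f], stack$nrow)[1] + 1
    j <- which.min((det$x_px - cx)^2 + (det$y_px - cy)^2)
    pitch[k] <- axial_to_pitch(det$angle_deg[j], d)
  }
  data.frame(frame = track$frame, pitch_deg = pitch)
}

# Centered running mean with shrinking windows at the edges.
running_mean <- function(x, w) {
  half <- w %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Convert an axial image orientation in [0, 180) to a signed nose-forward
# pitch given the horizontal travel sign (+1 right, -1 left).
axial_to_pitch <- function(angle_deg, travel_sign) {
  th <- wrap_axial(angle_deg)
  if (travel_sign >= 0) {
    if (th <= 90) th else th - 180
  } else {
    if (th >= 90) 180 - th else -th
  }
}
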