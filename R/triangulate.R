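#' Match tracks across a stereo pair and triangulate 3D flight paths
#'
#' Candidate pairs of tracks (one per camera) with temporal overlap are
#' scored by their mean reprojection residual after linear triangulation
#' of every common frame. Pairs are accepted greedily in order of
#' ascending residual, each track used at most once, and only while the
#' residual stays at or below \code{residual_max} pixels. Each accepted
#' pair yields one 3D trajectory over the overlapping frames.
#'
#' @param tracks_a,tracks_b track tables from [associate_detections()]
#'   for the two synchronized cameras.
#' @param calibration a [stereo_camera_pair()].
#' @param residual_max reprojection residual ceiling, px.
#' @param frame_rate frames per second, used to derive \code{t_s}.
#' @return list of data.frames (class \code{"trajectory3d"}), each with
#'   columns \code{frame, t_s, x_m, y_m, z_m, residual_px} and attributes
#'   \code{track_a}, \code{track_b}. Empty list when nothing overlaps.
#' @export
triangulate_tracks <- function(tracks_a, tracks_b, calibration,
                               residual_max = 5, frame_rate = 50) {
  if (!inherits(calibration, "stereo_pair")) {
    stop("`calibration` must be a stereo_camera_pair()", call. = FALSE)
  }
  if (!nrow(tracks_a) || !nrow(tracks_b)) return(list())
  la <- split(tracks_a, tracks_a$track_id)
  lb <- split(tracks_b, tracks_b$track_id)
  cand <- list()
  for (ia in names(la)) {
    for (ib in names(lb)) {
      common <- intersect(la[[ia]]$frame, lb[[ib]]$frame)
      if (!length(common)) next
      ta <- la[[ia]][match(common, la[[ia]]$frame), ]
      tb <- lb[[ib]][match(common, lb[[ib]]$frame), ]
      pts <- vapply(seq_along(common), function(k) {
        tri <- triangulate_point(calibration,
                                 c(ta$x_px[k], ta$y_px[k]),
                                 c(tb$x_px[k], tb$y_px[k]))
        c(tri$point, tri$residual_px)
      }, numeric(4))
      cand[[length(cand) + 1L]] <- list(
        a = ia, b = ib, frames = common,
        xyz = t(pts[1:3, , drop = FALSE]),
        residual = pts[4, ],
        score = mean(pts[4, ])
      )
    }
  }
  if (!length(cand)) return(list())
  scores <- vapply(cand, `[[`, numeric(1), "score")
  used_a <- character(0); used_b <- character(0)
  out <- list()
  for (k in order(scores)) {
    ck <- cand[[k]]
    if (ck$score > residual_max) break
    if (ck$a %in% used_a || ck$b %in% used_b) next
    used_a <- c(used_a, ck$a); used_b <- c(used_b, ck$b)
    df <- data.frame(frame = ck$frames,
                     t_s = (ck$frames - 1) / frame_rate,
                     x_m = ck$xyz[, 1], y_m = ck$xyz[, 2], z_m = ck$xyz[, 3],
                     residual_px = ck$residual)
    attr(df, "track_a") <- ck$a
    attr(df, "track_b") <- ck$b
    class(df) <- c("trajectory3d", "data.frame")
    out[[length(out) + 1L]] <- df
  }
  out
}
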