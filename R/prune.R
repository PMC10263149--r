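#' Prune short and stationary tracks
#'
#' Applies the standard track-quality rules: leading and trailing runs of
#' at least \code{stationary_frames} points whose displacement over the
#' whole run stays below \code{stationary_eps} pixels are removed (points that
#' became stationary, e.g. a bee landing or a spurious static blob), and
#' tracks shorter than \code{min_len} frames are dropped (the length
#' filter is re-applied after trimming). Surviving tracks are otherwise
#' unmodified.
#'
#' @param tracks data.frame from [associate_detections()].
#' @param min_len minimum track length in frames (a track of exactly
#'   \code{min_len} frames is retained).
#' @param stationary_eps displacement threshold, px.
#' @param stationary_frames minimum run length counted in points.
#' @return the pruned data.frame, same columns.
#' @export
prune_tracks <- function(tracks, min_len = 6L, stationary_eps = 0.5,
                         stationary_frames = 10L) {
  if (!nrow(tracks)) return(tracks)
  pieces <- split(tracks, tracks$track_id)
  pieces <- lapply(pieces, function(tr) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    # trailing stationary run: points within eps of the track's last point
    run <- stationary_run(rev(tr$x_px), rev(tr$y_px), stationary_eps)
    if (run >= stationary_frames) {
      tr <- tr[seq_len(nrow(tr) - run), , drop = FALSE]
    }
    if (nrow(tr)) {
      run <- stationary_run(tr$x_px, tr$y_px, stationary_eps)
      if (run >= stationary_frames) {
        tr <- tr[-seq_len(run), , drop = FALSE]
      }
    }
    tr
  })
  pieces <- pieces[vapply(pieces, nrow, 1L) >= min_len]
  if (!length(pieces)) return(tracks[0, , drop = FALSE])
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

# Length of the leading run of points all within `eps` of the first
# point (displacement measured over the run, not per step).
stationary_run <- function(x, y, eps) {
  d <- sqrt((x - x[1])^2 + (y - y[1])^2)
  beyond <- which(d >= eps)
  if (!length(beyond)) length(x) else beyond[1] - 1L
}
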