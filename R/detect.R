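#' Detect foreground objects in one frame
#'
#' Background removal, absolute-difference thresholding, connected-
#' component labelling and moment-based ellipse fitting. Each retained
#' component is summarised by its intensity-weighted centroid, pixel
#' area, and the least-squares ellipse whose second moments match the
#' component's (semi-axes \code{major_px >= minor_px}, orientation in
#' \code{[0, 180)} degrees, measured counter-clockwise from the image
#' x-axis with "up" meaning decreasing row index, i.e. the mathematical
#' convention after flipping the row axis). Weighting by the difference
#' image makes the orientation independent of any uniform intensity
#' rescaling of the frame (with a correspondingly scaled threshold).
#'
#' @param frame numeric matrix, same geometry as \code{background}.
#' @param background matrix from [compute_background()].
#' @param threshold absolute difference threshold (> 0).
#' @param min_area minimum component area in pixels.
#' @return data.frame with one row per detection: \code{x_px} (column),
#'   \code{y_px} (row), \code{area_px}, \code{major_px}, \code{minor_px},
#'   \code{angle_deg}.
#' @export
detect_objects <- function(frame, background, threshold = 0.2,
                           min_area = 9L) {
  if (!all(dim(frame) == dim(background))) {
    stop("geometry mismatch between frame and background", call. = FALSE)
  }
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("`threshold` must be > 0", call. = FALSE)
  }
  dif <- abs(frame - background)
  mask <- dif > threshold
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      area_px = numeric(0), major_px = numeric(0),
                      minor_px = numeric(0), angle_deg = numeric(0))
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(mask)
  idx <- which(lab > 0)
  if (!length(idx)) return(empty)
  labs <- lab[idx]
  areas <- tabulate(labs)
  keep <- which(areas >= min_area)
  if (!length(keep)) return(empty)
  nr <- nrow(frame)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  w <- dif[idx]
  out <- lapply(keep, function(l) {
    sel <- labs == l
    fit_ellipse_moments(cols[sel], rows[sel], w[sel], areas[l])
  })
  do.call(rbind, out)
}

# Ellipse parameters from intensity-weighted first/second moments of a
# pixel set. Returns the same columns as detect_objects().
fit_ellipse_moments <- function(cols, rows, w, area) {
  sw <- sum(w)
  cx <- sum(w * cols) / sw
  cy <- sum(w * rows) / sw
  dx <- cols - cx
  dy <- cy - rows  # up-positive
  cxx <- sum(w * dx * dx) / sw
  cyy <- sum(w * dy * dy) / sw
  cxy <- sum(w * dx * dy) / sw
  tr <- cxx + cyy
  det <- cxx * cyy - cxy * cxy
  disc <- sqrt(max(0, tr * tr / 4 - det))
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, 0)
  # A uniform ellipse with semi-axes (a, b) has variances (a^2/4, b^2/4).
  a <- 2 * sqrt(l1)
  b <- 2 * sqrt(l2)
  ang <- if (abs(cxy) < 1e-12 && cxx >= cyy) {
    0
  } else if (abs(cxy) < 1e-12) {
    90
  } else {
    rad2deg(atan2(l1 - cxx, cxy))
  }
  data.frame(x_px = cx, y_px = cy, area_px = area,
             major_px = max(a, 1e-6), minor_px = max(b, 1e-6),
             angle_deg = wrap_axial(ang))
}

#' Detect objects in every frame of a stack
#'
#' Convenience wrapper running [detect_objects()] per frame and adding a
#' \code{frame} column (1-based).
#'
#' @inheritParams detect_objects
#' @param stack a [frame_stack()].
#' @return data.frame of detections sorted by frame.
#' @export
detect_stack <- function(stack, background = NULL, threshold = 0.2,
                         min_area = 9L) {
  if (is.null(background)) background <- compute_background(stack)
  out <- lapply(seq_along(stack$frames), function(i) {
    di <- detect_objects(stack$frames[[i]], background, threshold, min_area)
    if (nrow(di)) di$frame <- i
    di
  })
  out <- out[vapply(out, nrow, 1L) > 0]
  if (!length(out)) {
    return(data.frame(x_px = numeric(0), y_px = numeric(0),
                      area_px = numeric(0), major_px = numeric(0),
                      minor_px = numeric(0), angle_deg = numeric(0),
                      frame = integer(0)))
  }
  do.call(rbind, out)
}
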