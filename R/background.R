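#' Median background model
#'
#' Estimates the static scene as the per-pixel temporal median of the
#' stack. Because the median has a 50% breakdown point, any pixel covered
#' by moving foreground in fewer than half of the frames recovers the
#' static scene exactly; a single corrupted frame cannot perturb it.
#' For an even number of frames the mean of the two central values is
#' used (the usual median convention).
#'
#' @param frames a [frame_stack()] or a plain list of matrices.
#' @param sample_every use every k-th frame only (k >= 1); the median of a
#'   regular temporal subsample, useful for long stacks.
#' @return a numeric matrix with the geometry of the input frames.
#' @export
compute_background <- function(frames, sample_every = 1L) {
  lst <- if (inherits(frames, "frame_stack")) frames$frames else frames
  if (!is.list(lst)) stop("`frames` must be a frame stack or list of matrices",
                          call. = FALSE)
  if (sample_every > 1L) {
    lst <- lst[seq(1L, length(lst), by = as.integer(sample_every))]
  }
  k <- length(lst)
  if (k < 3L) {
    stop("background estimation needs at least 3 frames", call. = FALSE)
  }
  d <- dim(lst[[1]])
  ms <- sort_pixelwise(lst)
  med <- if (k %% 2L == 1L) {
    ms[, (k + 1L) %/% 2L]
  } else {
    (ms[, k %/% 2L] + ms[, k %/% 2L + 1L]) / 2
  }
  matrix(med, d[1], d[2])
}

# Pixels x frames matrix with each pixel's time series sorted, via the
# vectorised order(row, value) trick.
sort_pixelwise <- function(lst) {
  d <- dim(lst[[1]])
  k <- length(lst)
  m <- matrix(unlist(lst, use.names = FALSE), nrow = d[1] * d[2], ncol = k)
  ord <- order(rep(seq_len(nrow(m)), k), m)
  matrix(m[ord], nrow = nrow(m), ncol = k, byrow = TRUE)
}

# Per-pixel temporal quantile (type-1, i.e. an order statistic).
temporal_quantile <- function(lst, q) {
  d <- dim(lst[[1]])
  ms <- sort_pixelwise(lst)
  j <- min(max(1L, as.integer(ceiling(q * length(lst)))), length(lst))
  matrix(ms[, j], d[1], d[2])
}
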