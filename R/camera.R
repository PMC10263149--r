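#' Camera models for the synthetic renderer
#'
#' Two flavours are used. Planar cameras (\code{"overhead"} or
#' \code{"lateral"} view) are scaled orthographic maps with a fixed
#' pixels-per-metre calibration: the overhead view images the (x, y)
#' floor plane of the tunnel, the lateral view images the (x, z) plane of
#' a small window. Stereo pairs (see [stereo_camera_pair()]) are ideal
#' pinhole cameras with exact, known projection matrices standing in for
#' a physical checkerboard calibration.
#'
#' Pixel conventions: column index grows with world x; for the overhead
#' view the row index grows with y, for the lateral view the row index
#' grows downward (z up). Continuous pixel coordinates place the centre
#' of pixel (1, 1) at (1, 1).
#'
#' @param px_per_m calibration scale, pixels per metre (> 0).
#' @param width_m,height_m extent of the imaged world window, m.
#' @param origin_x world x mapped to image column 1.
#' @param origin_y world y (overhead) mapped to image row 1.
#' @param origin_z world z (lateral) mapped to the bottom image row.
#' @return an object of class \code{"camera_model"}.
#' @export
camera_overhead <- function(px_per_m = 500, width_m = 1.4, height_m = 0.45,
                            origin_x = 0, origin_y = 0) {
  stopifnot_scalar_number(px_per_m, "px_per_m", positive = TRUE)
  structure(list(view = "overhead", px_per_m = px_per_m,
                 ncol = as.integer(ceiling(width_m * px_per_m)) + 1L,
                 nrow = as.integer(ceiling(height_m * px_per_m)) + 1L,
                 origin_x = origin_x, origin_y = origin_y),
            class = "camera_model")
}

#' @rdname camera_overhead
#' @export
camera_lateral <- function(px_per_m = 2000, width_m = 0.1, height_m = 0.1,
                           origin_x = 0, origin_z = 0) {
  stopifnot_scalar_number(px_per_m, "px_per_m", positive = TRUE)
  structure(list(view = "lateral", px_per_m = px_per_m,
                 ncol = as.integer(ceiling(width_m * px_per_m)) + 1L,
                 nrow = as.integer(ceiling(height_m * px_per_m)) + 1L,
                 origin_x = origin_x, origin_z = origin_z),
            class = "camera_model")
}

# Project world trajectory samples into a planar camera.
# Returns data.frame(col, row) in continuous pixel units.
project_planar <- function(cam, x, y, z) {
  col <- (x - cam$origin_x) * cam$px_per_m + 1
  if (cam$view == "overhead") {
    row <- (y - cam$origin_y) * cam$px_per_m + 1
  } else {
    row <- cam$nrow - (z - cam$origin_z) * cam$px_per_m
  }
  data.frame(col = col, row = row)
}

in_fov <- function(cam, px) {
  px$col >= 1 & px$col <= cam$ncol & px$row >= 1 & px$row <= cam$nrow
}

#' Ideal pinhole stereo pair
#'
#' Builds two pinhole cameras from centres, look-at targets and focal
#' lengths, returning exact 3x4 projection matrices. The synthetic
#' calibration record returned with rendered scenes is exactly these
#' matrices, so triangulation can be tested against ground truth.
#'
#' @param center_a,center_b 3-vectors, camera centres in world metres.
#' @param lookat 3-vector both cameras point at.
#' @param f_px focal length in pixels.
#' @param nrow,ncol image size in pixels.
#' @return object of class \code{"stereo_pair"}: a list with elements
#'   \code{a} and \code{b}, each containing \code{P} (3x4 projection),
#'   \code{center}, \code{f_px}, \code{nrow}, \code{ncol}.
#' @export
stereo_camera_pair <- function(center_a = c(0.5, -0.35, 0.6),
                               center_b = c(0.5, 0.55, 0.6),
                               lookat = c(0.5, 0.1, 0.1),
                               f_px = 900, nrow = 240L, ncol = 320L) {
  if (sqrt(sum((center_a - center_b)^2)) < 1e-9) {
    stop("degenerate stereo pair: identical camera placements", call. = FALSE)
  }
  mk <- function(C) {
    zc <- lookat - C
    zc <- zc / sqrt(sum(zc^2))
    up <- c(0, 0, 1)
    if (abs(sum(up * zc)) > 0.999) up <- c(0, 1, 0)
    xc <- c(zc[2] * up[3] - zc[3] * up[2],
            zc[3] * up[1] - zc[1] * up[3],
            zc[1] * up[2] - zc[2] * up[1])
    xc <- xc / sqrt(sum(xc^2))
    yc <- c(zc[2] * xc[3] - zc[3] * xc[2],
            zc[3] * xc[1] - zc[1] * xc[3],
            zc[1] * xc[2] - zc[2] * xc[1])
    R <- rbind(xc, yc, zc)
    K <- rbind(c(f_px, 0, (ncol + 1) / 2),
               c(0, f_px, (nrow + 1) / 2),
               c(0, 0, 1))
    P <- K %*% cbind(R, -R %*% C)
    list(P = P, center = C, f_px = f_px, nrow = as.integer(nrow),
         ncol = as.integer(ncol))
  }
  structure(list(a = mk(center_a), b = mk(center_b)), class = "stereo_pair")
}

# Project 3D world points (n x 3 matrix) with a 3x4 projection matrix.
# Returns data.frame(col, row, depth).
project_pinhole <- function(P, X) {
  X <- rbind(t(X), 1)
  h <- P %*% X
  data.frame(col = h[1, ] / h[3, ], row = h[2, ] / h[3, ], depth = h[3, ])
}

#' Triangulate one image correspondence
#'
#' Linear (DLT) triangulation of a single point seen in both cameras of a
#' stereo pair, with the mean reprojection residual in pixels.
#'
#' @param pair a [stereo_camera_pair()].
#' @param uv_a,uv_b length-2 vectors \code{c(col, row)} in each image.
#' @return list with \code{point} (length-3, metres) and \code{residual_px}.
#' @export
triangulate_point <- function(pair, uv_a, uv_b) {
  A <- rbind(
    uv_a[1] * pair$a$P[3, ] - pair$a$P[1, ],
    uv_a[2] * pair$a$P[3, ] - pair$a$P[2, ],
    uv_b[1] * pair$b$P[3, ] - pair$b$P[1, ],
    uv_b[2] * pair$b$P[3, ] - pair$b$P[2, ]
  )
  v <- svd(A)$v[, 4]
  X <- v[1:3] / v[4]
  ra <- project_pinhole(pair$a$P, matrix(X, 1))
  rb <- project_pinhole(pair$b$P, matrix(X, 1))
  res <- (sqrt((ra$col - uv_a[1])^2 + (ra$row - uv_a[2])^2) +
            sqrt((rb$col - uv_b[1])^2 + (rb$row - uv_b[2])^2)) / 2
  list(point = X, residual_px = res)
}
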