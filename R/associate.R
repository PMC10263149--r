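# Constant-velocity Kalman filtering and frame-to-frame data association.

# Minimum-total-cost assignment of rows (tracks) to columns (detections).
# Pairs with cost > gate are forbidden. Returns an integer vector of
# length nrow(cost): the matched column or NA. Exact (global optimum by
# enumeration with dummy padding) when the padded problem is small;
# greedy nearest-neighbour otherwise. Scenes here carry few simultaneous
# animals, so the exact branch covers practical instances.
solve_assignment <- function(cost, gate, exact_limit = 8L) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) return(rep(NA_integer_, n))
  feasible <- cost <= gate
  if (!any(feasible)) return(rep(NA_integer_, n))
  if (n + m <= exact_limit) {
    return(assign_exact(cost, gate))
  }
  assign_greedy(cost, gate)
}

assign_greedy <- function(cost, gate) {
  n <- nrow(cost); m <- ncol(cost)
  match <- rep(NA_integer_, n)
  cost[cost > gate] <- Inf
  repeat {
    if (!any(is.finite(cost))) break
    k <- arrayInd(which.min(cost), dim(cost))
    match[k[1]] <- k[2]
    cost[k[1], ] <- Inf
    cost[, k[2]] <- Inf
  }
  match
}

# Exact assignment: pad to a square (n+m) problem where each track/
# detection may instead match a dummy at cost `gate`, then enumerate
# permutations. Minimising total cost with this padding implements
# gated global-nearest-neighbour exactly.
assign_exact <- function(cost, gate) {
  n <- nrow(cost); m <- ncol(cost)
  size <- n + m
  big <- matrix(0, size, size)
  big[seq_len(n), seq_len(m)] <- pmin(cost, Inf)
  big[seq_len(n), seq_len(m)][cost > gate] <- Inf
  big[seq_len(n), m + seq_len(n)] <- Inf
  for (i in seq_len(n)) big[i, m + i] <- gate
  big[n + seq_len(m), seq_len(m)] <- Inf
  for (j in seq_len(m)) big[n + j, j] <- gate
  pp <- all_perms(size)
  tot <- rep(0, nrow(pp))
  for (i in seq_len(size)) tot <- tot + big[i, pp[, i]]
  best <- pp[which.min(tot), ]
  match <- rep(NA_integer_, n)
  hit <- best[seq_len(n)]
  match[hit <= m] <- hit[hit <= m]
  match
}

# Cached permutation matrices (rows = permutations).
perm_cache <- new.env(parent = emptyenv())
all_perms <- function(k) {
  key <- as.character(k)
  if (!is.null(perm_cache[[key]])) return(perm_cache[[key]])
  p <- if (k == 1L) matrix(1L, 1, 1) else {
    sub <- all_perms(k - 1L)
    do.call(rbind, lapply(seq_len(k), function(i) {
      cbind(i, sub + (sub >= i))
    }))
  }
  storage.mode(p) <- "integer"
  perm_cache[[key]] <- p
  p
}

kf_defaults <- function() {
  list(q = 0.5,  # process noise (px^2 per frame) on the CV model
       r = 1,    # measurement noise (px^2)
       p0_pos = 4, p0_vel = 100)
}

kf_new <- function(x, y, kf) {
  list(state = c(x, y, 0, 0),
       P = diag(c(kf$p0_pos, kf$p0_pos, kf$p0_vel, kf$p0_vel)))
}

kf_predict <- function(tr, kf) {
  F <- rbind(c(1, 0, 1, 0), c(0, 1, 0, 1), c(0, 0, 1, 0), c(0, 0, 0, 1))
  G <- rbind(c(0.5, 0), c(0, 0.5), c(1, 0), c(0, 1))
  Q <- kf$q * (G %*% t(G))
  tr$state <- as.numeric(F %*% tr$state)
  tr$P <- F %*% tr$P %*% t(F) + Q
  tr
}

kf_update <- function(tr, z, kf) {
  H <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  S <- H %*% tr$P %*% t(H) + kf$r * diag(2)
  K <- tr$P %*% t(H) %*% solve(S)
  tr$state <- as.numeric(tr$state + K %*% (z - H %*% tr$state))
  tr$P <- (diag(4) - K %*% H) %*% tr$P
  tr
}

#' Link detections into tracks with a Kalman filter
#'
#' Runs a constant-velocity Kalman filter per track. At each frame,
#' detections are assigned to active tracks by minimising the total
#' predicted-position error, with assignments farther than \code{gate_px}
#' forbidden (exact global matching on small instances). Unassigned
#' detections seed new tracks; a track ends after more than
#' \code{max_missed} consecutive frames without a detection. Every input
#' detection is placed in exactly one track.
#'
#' @param detections data.frame from [detect_stack()] (columns
#'   \code{frame, x_px, y_px} plus any others, which are carried through).
#' @param gate_px gating radius in pixels.
#' @param max_missed tolerated consecutive missed frames.
#' @param q,r Kalman process / measurement noise parameters (px^2).
#' @return data.frame of the input detections with columns
#'   \code{track_id}, \code{kalman_x}, \code{kalman_y}, \code{kalman_vx},
#'   \code{kalman_vy} (filtered state, px and px/frame) appended; sorted
#'   by track then frame.
#' @export
associate_detections <- function(detections, gate_px = 30, max_missed = 3L,
                                 q = 0.5, r = 1) {
  out_cols <- c("track_id", "kalman_x", "kalman_y", "kalman_vx", "kalman_vy")
  if (!nrow(detections)) {
    for (cc in out_cols) detections[[cc]] <- numeric(0)
    return(detections)
  }
  stopifnot(all(c("frame", "x_px", "y_px") %in% names(detections)))
  kf <- kf_defaults(); kf$q <- q; kf$r <- r
  det <- detections[order(detections$frame), , drop = FALSE]
  n <- nrow(det)
  track_id <- integer(n)
  kx <- ky <- kvx <- kvy <- numeric(n)
  active <- list()   # each: list(id, state, P, missed)
  next_id <- 1L
  frames <- seq(min(det$frame), max(det$frame))
  for (f in frames) {
    rows <- which(det$frame == f)
    active <- lapply(active, kf_predict, kf = kf)
    nt <- length(active); nd <- length(rows)
    match <- rep(NA_integer_, nt)
    if (nt && nd) {
      cost <- matrix(Inf, nt, nd)
      for (i in seq_len(nt)) {
        cost[i, ] <- sqrt((active[[i]]$state[1] - det$x_px[rows])^2 +
                            (active[[i]]$state[2] - det$y_px[rows])^2)
      }
      match <- solve_assignment(cost, gate_px)
    }
    used <- rep(FALSE, nd)
    keep <- logical(nt)
    for (i in seq_len(nt)) {
      if (!is.na(match[i])) {
        j <- rows[match[i]]
        used[match[i]] <- TRUE
        active[[i]] <- kf_update(active[[i]], c(det$x_px[j], det$y_px[j]), kf)
        active[[i]]$missed <- 0L
        track_id[j] <- active[[i]]$id
        kx[j] <- active[[i]]$state[1]; ky[j] <- active[[i]]$state[2]
        kvx[j] <- active[[i]]$state[3]; kvy[j] <- active[[i]]$state[4]
        keep[i] <- TRUE
      } else {
        active[[i]]$missed <- active[[i]]$missed + 1L
        keep[i] <- active[[i]]$missed <= max_missed
      }
    }
    active <- active[keep]
    for (jj in which(!used)) {
      j <- rows[jj]
      tr <- kf_new(det$x_px[j], det$y_px[j], kf)
      tr$id <- next_id; tr$missed <- 0L
      next_id <- next_id + 1L
      track_id[j] <- tr$id
      kx[j] <- tr$state[1]; ky[j] <- tr$state[2]
      kvx[j] <- 0; kvy[j] <- 0
      active <- c(active, list(tr))
    }
  }
  det$track_id <- track_id
  det$kalman_x <- kx; det$kalman_y <- ky
  det$kalman_vx <- kvx; det$kalman_vy <- kvy
  det[order(det$track_id, det$frame), , drop = FALSE]
}
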