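# Independent oracles and fixture builders. Everything here is deliberately
# written without using the package's C++ primitives, so the tests compare
# two independent routes.

# even-odd point-in-polygon by crossing count, plain R
pip_oracle <- function(px, py, rings) {
  crossings <- 0L
  for (ring in rings) {
    n <- nrow(ring)
    j <- n
    for (i in seq_len(n)) {
      yi <- ring[i, 2]; yj <- ring[j, 2]
      if ((yi > py) != (yj > py)) {
        xint <- ring[i, 1] + (py - yi) / (yj - yi) * (ring[j, 1] - ring[i, 1])
        if (px < xint) crossings <- crossings + 1L
      }
      j <- i
    }
  }
  crossings %% 2L == 1L
}

# rasterize by scanning every pixel center in the polygon's bounds
raster_oracle <- function(mask, W, H) {
  rings <- unclass(mask)
  allv <- do.call(rbind, rings)
  xs <- max(0L, floor(min(allv[, 1]))):min(W - 1L, ceiling(max(allv[, 1])))
  ys <- max(0L, floor(min(allv[, 2]))):min(H - 1L, ceiling(max(allv[, 2])))
  px <- integer(0)
  for (iy in ys) for (ix in xs) {
    if (pip_oracle(ix + 0.5, iy + 0.5, rings))
      px <- c(px, ix + iy * W)
  }
  px
}

mask_iou_oracle <- function(a, b, W, H) {
  pa <- raster_oracle(a, W, H)
  pb <- raster_oracle(b, W, H)
  u <- length(union(pa, pb))
  if (u == 0) return(0)
  length(intersect(pa, pb)) / u
}

# exhaustive maximum total IoU over all injective detection -> track maps
best_total_iou_oracle <- function(iou) {
  n <- nrow(iou); m <- ncol(iou)
  if (n == 0 || m == 0) return(0)
  rec <- function(i, used) {
    if (i > n) return(0)
    best <- rec(i + 1, used)  # leave detection i unmatched
    for (j in seq_len(m)) {
      if (!used[j]) {
        used[j] <- TRUE
        best <- max(best, iou[i, j] + rec(i + 1, used))
        used[j] <- FALSE
      }
    }
    best
  }
  rec(1, logical(m))
}

# textbook Kalman recursion on the 7-state constant-velocity model, written
# with explicit matrix algebra (no package functions)
kalman_recursion_oracle <- function(boxes, p0, q, r) {
  to_z <- function(b) c(b[1] + b[3] / 2, b[2] + b[4] / 2,
                        b[3] * b[4], b[3] / b[4])
  F <- diag(7); F[1, 5] <- F[2, 6] <- F[3, 7] <- 1
  H <- cbind(diag(4), matrix(0, 4, 3))
  Q <- diag(q); R <- diag(r)
  x <- c(to_z(boxes[1, ]), 0, 0, 0)
  P <- diag(p0)
  for (i in seq_len(nrow(boxes))[-1]) {
    x <- F %*% x
    P <- F %*% P %*% t(F) + Q
    z <- to_z(boxes[i, ])
    S <- H %*% P %*% t(H) + R
    K <- P %*% t(H) %*% solve(S)
    x <- x + K %*% (z - H %*% x)
    P <- (diag(7) - K %*% H) %*% P
  }
  # one-step-ahead predicted center
  xp <- F %*% x
  c(xp[1], xp[2])
}

# fixture builders -----------------------------------------------------------

rect_mask <- function(x, y, w, h) mask_poly(rect_ring(x, y, w, h))

# detections from a data.frame of (frame, x, y, w, h[, score]) with
# rectangular masks matching the boxes
make_dets <- function(df, fps = 10, frame_w = 200, frame_h = 100) {
  if (is.null(df$score)) df$score <- rep(1, nrow(df))
  df$label <- rep("b", nrow(df))
  df$mask <- lapply(seq_len(nrow(df)),
                    function(i) rect_mask(df$x[i], df$y[i], df$w[i], df$h[i]))
  det_sequence(df, fps, frame_w, frame_h)
}

make_gt <- function(df, fps = 10, frame_w = 200, frame_h = 100,
                    n_frames = NULL) {
  df$label <- rep("b", nrow(df))
  df$mask <- lapply(seq_len(nrow(df)),
                    function(i) rect_mask(df$x[i], df$y[i], df$w[i], df$h[i]))
  gt_sequence(df, fps, frame_w, frame_h, n_frames)
}

make_result <- function(df, fps = 10, frame_w = 200, frame_h = 100,
                        n_frames = NULL) {
  if (is.null(df$score)) df$score <- rep(1, nrow(df))
  if (is.null(df$mask))
    df$mask <- lapply(seq_len(nrow(df)),
                      function(i) rect_mask(df$x[i], df$y[i], df$w[i],
                                            df$h[i]))
  tracking_result(df, fps, frame_w, frame_h, n_frames)
}

# random simple (convex) polygon around a center: a noisy ellipse
random_poly <- function(cx, cy, rmax = 12, nv = 10) {
  th <- sort(runif(nv, 0, 2 * pi))
  rad <- runif(nv, rmax / 2, rmax)
  cbind(cx + rad * cos(th), cy + rad * sin(th))
}
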