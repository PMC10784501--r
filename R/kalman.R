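# Constant-velocity Kalman filter over the box state
# x = (u, v, s, r, u', v', s'):
#   u, v  box center (column px, row px)
#   s     box area in px^2
#   r     aspect ratio w/h (assumed constant: no velocity component)
#   u', v', s'  per-frame velocities
# The observation picks (u, v, s, r) linearly. Default covariances follow the
# usual online-tracking convention: large initial uncertainty on the
# unobservable velocities, small process noise on the area velocity.

kf_dim <- 7L

kf_F <- function() {
  F <- diag(7)
  F[1, 5] <- 1; F[2, 6] <- 1; F[3, 7] <- 1
  F
}

kf_H <- function() {
  H <- matrix(0, 4, 7)
  H[1, 1] <- 1; H[2, 2] <- 1; H[3, 3] <- 1; H[4, 4] <- 1
  H
}

kf_default_p0 <- c(10, 10, 10, 10, 1e4, 1e4, 1e4)
kf_default_q <- c(1, 1, 1, 1, 0.01, 0.01, 1e-4)
kf_default_r <- c(1, 1, 10, 10)

#' Convert a bounding box to a Kalman state vector
#'
#' The state parameterization is center `(u, v)`, area `s = w * h`, aspect
#' ratio `r` (width over height), plus per-frame velocities of `u`, `v`, `s` (initialized
#' to zero). `bbox_from_state()` is the exact inverse on the observed
#' components: `w = sqrt(s * r)`, `h = s / w`.
#'
#' @param b a [bbox()].
#' @return `state_from_bbox()`: a length-7 numeric state vector;
#'   `bbox_from_state()`: a [bbox()].
#' @export
#' @examples
#' state_from_bbox(bbox(0, 0, 10, 20))  # u = 5, v = 10, s = 200, r = 0.5
state_from_bbox <- function(b) {
  b <- as_bbox(b)
  c(u = b[[1]] + b[[3]] / 2, v = b[[2]] + b[[4]] / 2,
    s = b[[3]] * b[[4]], r = b[[3]] / b[[4]],
    du = 0, dv = 0, ds = 0)
}

#' @rdname state_from_bbox
#' @param x a length-7 state vector or a Kalman state from [kf_init()].
#' @export
bbox_from_state <- function(x) {
  if (is.list(x)) x <- x$x
  s <- max(x[3], 1e-9); r <- max(x[4], 1e-9)
  w <- sqrt(s * r)
  h <- s / w
  bbox(x[1] - w / 2, x[2] - h / 2, w, h)
}

#' Initialize a Kalman track state from a detection box
#'
#' @param b a [bbox()].
#' @param p0 initial covariance diagonal (length 7); defaults put large
#'   uncertainty on the unobserved velocities.
#' @return A Kalman state: `list(x = <7-vector>, P = <7x7 covariance>)`.
#' @export
kf_init <- function(b, p0 = kf_default_p0) {
  assert_that(length(p0) == 7L && all(p0 > 0),
              "p0 must be 7 positive variances")
  list(x = unname(state_from_bbox(b)), P = diag(p0))
}

#' Kalman predict step
#'
#' Advances the state one frame under the constant-velocity transition
#' (`x <- F x`, `P <- F P F' + Q`). If the predicted area `s + s'` would be
#' nonpositive, the area velocity is clamped to zero before the transition so
#' the state always converts to a valid box.
#'
#' @param state a Kalman state from [kf_init()].
#' @param q process noise diagonal (length 7).
#' @return `list(state = <predicted state>, bbox = <predicted box>)`.
#' @export
kf_predict <- function(state, q = kf_default_q) {
  x <- state$x; P <- state$P
  if (x[3] + x[7] <= 0) x[7] <- 0
  F <- kf_F()
  x <- drop(F %*% x)
  P <- F %*% P %*% t(F) + diag(q)
  P <- (P + t(P)) / 2
  st <- list(x = x, P = P)
  list(state = st, bbox = bbox_from_state(st))
}

#' Kalman measurement update
#'
#' Standard linear-Gaussian update with the observation `z = (u, v, s, r)`
#' taken from a detection box. Uses the Joseph-form covariance update, which
#' keeps `P` symmetric positive semidefinite.
#'
#' @param state a Kalman state (typically after [kf_predict()]).
#' @param z a measurement: a [bbox()] or a length-4 numeric `(u, v, s, r)`.
#' @param r measurement noise diagonal (length 4).
#' @return The updated Kalman state.
#' @export
kf_update <- function(state, z, r = kf_default_r) {
  if (inherits(z, "bbox")) {
    z <- unname(state_from_bbox(z)[1:4])
  } else if (is.numeric(z) && length(z) == 4L) {
    z <- as.numeric(z)
  } else {
    stop("z must be a bbox or a length-4 measurement (u, v, s, r)",
         call. = FALSE)
  }
  assert_that(all(is.finite(z)), "measurement must be finite")
  H <- kf_H(); R <- diag(r)
  x <- state$x; P <- state$P
  S <- H %*% P %*% t(H) + R
  K <- P %*% t(H) %*% solve(S)
  x <- drop(x + K %*% (z - drop(H %*% x)))
  IKH <- diag(7) - K %*% H
  P <- IKH %*% P %*% t(IKH) + K %*% R %*% t(K)
  P <- (P + t(P)) / 2
  list(x = x, P = P)
}
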