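#' Per-fly Kalman filter
#'
#' Each tracked fly carries a 6-dimensional state
#' `(x, y, Vx, Vy, theta, w)`: position in px, linear velocity in
#' px/frame, body-axis orientation in radians (stored in (-pi, pi\]) and
#' angular velocity in rad/frame. The transition model is constant
#' velocity with `dt` in frames; the full state is measured
#' (`H = I6`), with the velocity components supplied by a smoothed
#' finite-difference estimator rather than raw one-frame differences.
#'
#' @name kalman
NULL

wrap_pi <- function(a) {
  # wrap to (-pi, pi]
  a <- (a + pi) %% (2 * pi) - pi
  a[a == -pi] <- pi
  a
}

# unwrap a measured axis orientation (defined modulo pi) to the
# representative nearest the predicted value
unwrap_axis <- function(theta_meas, theta_pred) {
  k <- round((theta_pred - theta_meas) / pi)
  theta_meas + k * pi
}

transition_matrix <- function(dt = 1) {
  A <- diag(6)
  A[1, 3] <- dt # x <- x + Vx dt
  A[2, 4] <- dt # y <- y + Vy dt
  A[5, 6] <- dt # theta <- theta + w dt
  A
}

#' Kalman prediction step
#'
#' Propagates the state with the constant-velocity transition and grows
#' the covariance by the process noise `Q`. The predicted orientation is
#' wrapped back into (-pi, pi\].
#'
#' @param t a tracker (see [make_tracker()]).
#' @param dt time step in frames (> 0).
#' @param Q 6x6 process-noise covariance; defaults to the tracker's.
#' @return the tracker with predicted `x_state` and `P`.
#' @export
kalman_predict <- function(t, dt = 1, Q = t$Q) {
  if (dt <= 0) stop("dt must be positive")
  A <- transition_matrix(dt)
  t$x_state <- as.numeric(A %*% t$x_state)
  t$x_state[5] <- wrap_pi(t$x_state[5])
  P <- A %*% t$P %*% t(A) + Q
  t$P <- (P + t(P)) / 2
  t$predicted <- TRUE
  t
}

#' Kalman correction step
#'
#' Standard optimal-gain update with full-state measurement. The
#' measurement's angle component must already be unwrapped to within
#' pi/2 of the predicted orientation (see [unwrap_axis()]). When the
#' identity assignment was ambiguous the caller inflates `R` so the
#' prediction dominates the correction.
#'
#' @param t a tracker after [kalman_predict()].
#' @param z measurement 6-vector `(x, y, Vx, Vy, theta, w)`.
#' @param R 6x6 positive-definite measurement covariance.
#' @return the corrected tracker.
#' @export
kalman_update <- function(t, z, R = t$R) {
  ok <- tryCatch(
    {
      chol(R)
      TRUE
    },
    error = function(e) FALSE
  )
  if (!ok) stop("measurement covariance R must be positive definite")
  y <- as.numeric(z) - t$x_state
  S <- t$P + R
  K <- t$P %*% solve(S)
  t$x_state <- t$x_state + as.numeric(K %*% y)
  t$x_state[5] <- wrap_pi(t$x_state[5])
  P <- (diag(6) - K) %*% t$P
  t$P <- (P + t(P)) / 2
  t$predicted <- FALSE
  t
}

#' Smoothed velocity measurement
#'
#' Velocities fed to the filter are not raw one-frame differences
#' (which amplify pixel noise at low resolution or frame rate) but a
#' weighted moving average of the finite differences over a recent
#' window. Weights combine recency with a robustness term that
#' down-weights differences far from the window median, so a single
#' outlier jump corrects the estimate toward the median rather than
#' following the jump.
#'
#' @param history matrix with columns `x`, `y`, `theta`; one row per
#'   frame, most recent last. Orientation differences are taken modulo
#'   pi (axis convention).
#' @param window number of trailing differences to average; `1`
#'   degenerates to the raw last difference.
#' @return numeric `c(vx, vy, w)` in px/frame and rad/frame.
#' @export
smooth_velocity <- function(history, window = 5) {
  history <- as.matrix(history)
  n <- nrow(history)
  if (n < 2L) return(c(vx = 0, vy = 0, w = 0))
  d <- diff(history)
  # axis orientation differences wrapped to (-pi/2, pi/2]
  d[, 3] <- wrap_pi(2 * d[, 3]) / 2
  m <- min(window, nrow(d))
  d <- d[seq(nrow(d) - m + 1, nrow(d)), , drop = FALSE]
  if (m == 1L) return(c(vx = d[1, 1], vy = d[1, 2], w = d[1, 3]))
  rec <- seq_len(m) # linear recency weights
  v <- vapply(1:3, function(j) {
    med <- stats::median(d[, j])
    scale <- stats::median(abs(d[, j] - med)) + 1e-6
    rob <- 1 / (1 + (abs(d[, j] - med) / (3 * scale))^2)
    sum(rec * rob * d[, j]) / sum(rec * rob)
  }, numeric(1))
  c(vx = v[1], vy = v[2], w = v[3])
}
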