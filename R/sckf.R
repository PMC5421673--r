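# Generic third-degree square-root cubature Kalman filter (SCKF) for
# additive-noise nonlinear discrete-time state-space models
#
#   x_{k+1} = f_d(x_k, u_k) + n_k,   n_k ~ N(0, Q = S_Q S_Q')
#   y_k     = h_d(x_k)      + m_k,   m_k ~ N(0, R = S_R S_R')
#
# The error covariance is carried as a lower-triangular factor S with
# P = S S', updated exclusively through QR triangularisations and triangular
# solves — no explicit inverses, no Cholesky downdates, no negative weights.

#' Third-degree spherical-radial cubature rule
#'
#' Generates the 2n cubature points \eqn{\xi_i = \sqrt{n}\,[1]_i} (all
#' permutations and sign changes of the scaled unit vectors) with uniform
#' weights \eqn{1/(2n)}.  The rule integrates Gaussian-weighted integrands
#' exactly up to third degree: weights sum to one, the point mean is zero and
#' the point covariance is the identity.
#'
#' @param n State dimension (>= 1).
#' @return List with `points` (n x 2n matrix) and `weights` (length 2n).
#' @export
cubature_points <- function(n) {
  if (n < 1) stop("state dimension must be >= 1", call. = FALSE)
  pts <- cbind(diag(sqrt(n), n), diag(-sqrt(n), n))
  list(points = pts, weights = rep(1 / (2 * n), 2 * n))
}

#' Triangularisation operator
#'
#' `tria(A)` returns the lower-triangular factor S with `S %*% t(S)` equal to
#' `A %*% t(A)`, computed through the QR decomposition of `t(A)`.  The sign
#' of each row of the R factor is normalised so that the diagonal of S is
#' non-negative, making the result deterministic across platforms.
#'
#' @param A An n x m matrix with `m >= n`.
#' @return Lower-triangular n x n matrix with non-negative diagonal.
#' @export
triangularise <- function(A) {
  n <- nrow(A)
  if (ncol(A) < n) stop("tria() needs at least as many columns as rows",
                        call. = FALSE)
  R <- qr.R(qr(t(A)))[seq_len(n), , drop = FALSE]
  sgn <- sign(diag(R))
  sgn[sgn == 0] <- 1
  t(R * sgn)
}

#' Square-root filter state
#'
#' @param x_hat Mean estimate (n-vector).
#' @param S Lower-triangular square-root factor of the error covariance
#'   (`P = S %*% t(S)`); a vector is interpreted as diagonal standard
#'   deviations.
#' @return Object of class `sckf_state`.
#' @export
sckf_state <- function(x_hat, S) {
  n <- length(x_hat)
  if (!is.matrix(S)) S <- diag(S, n)
  stopifnot(nrow(S) == n, ncol(S) == n)
  structure(list(x_hat = as.numeric(x_hat), S = S), class = "sckf_state")
}

# cubature points of the current state: X_i = S xi_i + x_hat
.sckf_points <- function(state) {
  n <- length(state$x_hat)
  state$S %*% cubature_points(n)$points + state$x_hat
}

#' SCKF prediction step
#'
#' Propagates the cubature points through the state transition, forms the
#' predicted mean as their average, and triangularises the weighted centred
#' point deviations augmented with the process-noise factor to obtain the
#' predicted square-root covariance.
#'
#' @param state An [sckf_state()].
#' @param f_d State-transition function `f_d(x, u)` returning an n-vector.
#' @param u_k Input passed to `f_d`.
#' @param S_Q Square-root factor of the process-noise covariance (matrix or
#'   vector of standard deviations).
#' @param clamp_fn Optional function applied to every cubature point before
#'   propagation (state-constraint handling, e.g. clipping activations into
#'   `[0, 1]`); clamping events can be counted by the closure itself.
#' @return The predicted [sckf_state()].
#' @export
sckf_predict <- function(state, f_d, u_k, S_Q, clamp_fn = NULL) {
  n <- length(state$x_hat)
  if (!is.matrix(S_Q)) S_Q <- diag(S_Q, n)
  X <- .sckf_points(state)
  l <- 2 * n
  Xp <- matrix(0, n, l)
  for (i in seq_len(l)) {
    xi <- X[, i]
    if (!is.null(clamp_fn)) xi <- clamp_fn(xi)
    Xp[, i] <- tryCatch(f_d(xi, u_k), error = function(e)
      stop(sprintf("state transition failed on cubature point %d: %s",
                   i, conditionMessage(e)), call. = FALSE))
  }
  x_pred <- rowMeans(Xp)
  Xc <- (Xp - x_pred) / sqrt(l)
  sckf_state(x_pred, triangularise(cbind(Xc, S_Q)))
}

#' SCKF measurement-update step
#'
#' Evaluates the measurement map on the predicted cubature points, forms the
#' innovation-covariance square root by triangularisation, computes the
#' Kalman gain with two triangular solves (right divisions, never an explicit
#' inverse), and updates mean and square-root covariance.
#'
#' @param state Predicted [sckf_state()].
#' @param y_k Measurement vector (length p).
#' @param h_d Measurement function `h_d(x)` returning a p-vector.
#' @param S_R Square-root factor of the measurement-noise covariance.
#' @return List with `state` (the posterior [sckf_state()]), `innovation`
#'   (y - y_hat) and `S_yy` (innovation-covariance square root).
#' @export
sckf_update <- function(state, y_k, h_d, S_R) {
  n <- length(state$x_hat)
  p <- length(y_k)
  if (!is.matrix(S_R)) S_R <- diag(S_R, p)
  l <- 2 * n
  X <- .sckf_points(state)
  Y <- matrix(0, p, l)
  for (i in seq_len(l)) Y[, i] <- h_d(X[, i])
  y_hat <- rowMeans(Y)
  Yc <- (Y - y_hat) / sqrt(l)
  Xc <- (X - state$x_hat) / sqrt(l)

  S_yy <- triangularise(cbind(Yc, S_R))
  if (any(abs(diag(S_yy)) < 1e-12))
    stop("singular innovation covariance", call. = FALSE)
  P_xy <- Xc %*% t(Yc)
  # K = (P_xy / S_yy') / S_yy  via two triangular solves
  K <- t(forwardsolve(S_yy, t(P_xy)))        # K1 with K1 S_yy' = P_xy
  K <- t(backsolve(t(S_yy), t(K)))           # K  with K  S_yy  = K1
  innov <- y_k - y_hat
  x_post <- state$x_hat + drop(K %*% innov)
  S_post <- triangularise(cbind(Xc - K %*% Yc, K %*% S_R))
  list(state = sckf_state(x_post, S_post), innovation = innov, S_yy = S_yy)
}

#' Run the SCKF over a measurement sequence
#'
#' Convenience driver: alternate prediction and update over the columns of
#' `Y` and rows of `U`.
#'
#' @param x0,S0 Initial mean and square-root covariance.
#' @param f_d,h_d Transition and measurement maps.
#' @param U Matrix of inputs (one row per step, passed as a vector to `f_d`),
#'   or `NULL`.
#' @param Y Matrix of measurements (one column per step).
#' @param S_Q,S_R Noise square-root factors.
#' @param clamp_fn Optional cubature-point constraint function.
#' @return List with matrices `X` (posterior means, one column per step),
#'   `innovations`, and the final `state`.
#' @export
sckf_filter <- function(x0, S0, f_d, h_d, U = NULL, Y, S_Q, S_R,
                        clamp_fn = NULL) {
  state <- sckf_state(x0, S0)
  n <- length(x0)
  N <- ncol(Y)
  X <- matrix(0, n, N)
  innov <- matrix(0, nrow(Y), N)
  for (k in seq_len(N)) {
    u_k <- if (is.null(U)) NULL else U[k, ]
    state <- sckf_predict(state, f_d, u_k, S_Q, clamp_fn)
    up <- sckf_update(state, Y[, k], h_d, S_R)
    state <- up$state
    X[, k] <- state$x_hat
    innov[, k] <- up$innovation
  }
  list(X = X, innovations = innov, state = state)
}
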