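# Square-root cubature Kalman filter: rule identities, triangularisation,
# prediction/update against independent oracles

test_that("cubature rule satisfies its moment identities", {
  expect_error(cubature_points(0))
  r1 <- cubature_points(1)
  expect_equal(sort(drop(r1$points)), c(-1, 1))
  expect_equal(r1$weights, c(0.5, 0.5))

  r3 <- cubature_points(3)
  expect_equal(ncol(r3$points), 6)
  expect_equal(max(abs(r3$points)), sqrt(3))

  for (n in c(2, 5, 16, 32)) {
    r <- cubature_points(n)
    expect_equal(sum(r$weights), 1)
    expect_true(all(r$weights > 0))               # no negative weights
    expect_equal(drop(r$points %*% r$weights), numeric(n))
    emp_cov <- r$points %*% diag(r$weights) %*% t(r$points)
    expect_equal(emp_cov, diag(n), tolerance = 1e-12)
  }
})

test_that("triangularisation preserves the outer product", {
  A <- cbind(matrix(c(2, 1, 0, 3), 2), matrix(0, 2, 2))
  expect_equal(triangularise(A), matrix(c(2, 1, 0, 3), 2))

  set.seed(2)
  for (i in 1:20) {
    n <- sample(2:8, 1); m <- n + sample(0:8, 1)
    A <- matrix(rnorm(n * m), n)
    S <- triangularise(A)
    expect_equal(S %*% t(S), A %*% t(A), tolerance = 1e-12)
    expect_true(all(S[upper.tri(S)] == 0))
    expect_true(all(diag(S) >= 0))
  }
  expect_error(triangularise(matrix(1, 3, 2)))
})

test_that("prediction is exact for identity and linear transitions", {
  st <- sckf_state(c(1, -2), diag(c(0.5, 0.2)))
  pred <- sckf_predict(st, function(x, u) x, NULL, diag(0, 2))
  expect_equal(pred$x_hat, st$x_hat)
  expect_equal(pred$S %*% t(pred$S), st$S %*% t(st$S), tolerance = 1e-12)

  set.seed(14)
  F <- matrix(rnorm(9, sd = 0.4), 3); diag(F) <- 0.9
  Q <- crossprod(matrix(rnorm(9), 3)) / 10
  x0 <- rnorm(3); P0 <- crossprod(matrix(rnorm(9), 3)) / 2
  st <- sckf_state(x0, t(chol(P0)))
  pred <- sckf_predict(st, function(x, u) drop(F %*% x), NULL, t(chol(Q)))
  expect_equal(pred$x_hat, drop(F %*% x0), tolerance = 1e-12)
  expect_equal(pred$S %*% t(pred$S), F %*% P0 %*% t(F) + Q,
               tolerance = 1e-10)
})

test_that("predicted moments match Monte-Carlo propagation for a nonlinear map", {
  f <- function(x, u) c(x[1] + 0.1 * sin(x[2]), 0.95 * x[2] + 0.05 * x[1]^2)
  x0 <- c(0.3, -0.5); P0 <- diag(c(0.04, 0.09))
  st <- sckf_state(x0, t(chol(P0)))
  pred <- sckf_predict(st, f, NULL, diag(1e-9, 2))

  set.seed(99)
  Xs <- x0 + t(chol(P0)) %*% matrix(rnorm(2e5), 2)
  Ys <- apply(Xs, 2, f, u = NULL)
  mc_mean <- rowMeans(Ys)
  mc_cov <- stats::cov(t(Ys))
  expect_equal(pred$x_hat, mc_mean, tolerance = 0.01)
  expect_equal(pred$S %*% t(pred$S), mc_cov, tolerance = 0.05)
})

test_that("update matches the textbook Kalman update in the linear case", {
  set.seed(8)
  n <- 4; p <- 2
  H <- matrix(rnorm(p * n), p)
  R <- crossprod(matrix(rnorm(p * p), p)) / 5
  x0 <- rnorm(n); P0 <- crossprod(matrix(rnorm(n * n), n)) / 2
  y <- rnorm(p)

  st <- sckf_state(x0, t(chol(P0)))
  up <- sckf_update(st, y, function(x) drop(H %*% x), t(chol(R)))

  S <- H %*% P0 %*% t(H) + R
  K <- P0 %*% t(H) %*% solve(S)
  x_kf <- x0 + drop(K %*% (y - drop(H %*% x0)))
  P_kf <- (diag(n) - K %*% H) %*% P0
  expect_equal(up$state$x_hat, x_kf, tolerance = 1e-10)
  expect_equal(up$state$S %*% t(up$state$S), P_kf, tolerance = 1e-10)

  # exact predicted measurement gives zero innovation, unchanged mean
  y_hat <- drop(H %*% x0)
  up0 <- sckf_update(st, y_hat, function(x) drop(H %*% x), t(chol(R)))
  expect_equal(up0$innovation, numeric(p))
  expect_equal(up0$state$x_hat, x0, tolerance = 1e-12)

  # measurement never inflates the covariance in the linear-Gaussian case
  expect_true(all(eigen(P0 - up$state$S %*% t(up$state$S),
                        symmetric = TRUE, only.values = TRUE)$values > -1e-10))
})

test_that("square-root and covariance-form CKFs agree along a nonlinear run", {
  # parallel non-square-root CKF as the oracle
  ckf_oracle <- function(x, P, f, h, Q, R, y) {
    n <- length(x)
    cp <- cubature_points(n)
    Sx <- t(chol(P))
    X <- Sx %*% cp$points + x
    Xp <- apply(X, 2, f)
    xp <- rowMeans(Xp)
    Pp <- tcrossprod(Xp - xp) / (2 * n) + Q
    Sx <- t(chol(Pp))
    X <- Sx %*% cp$points + xp
    Y <- rbind(apply(X, 2, h))
    yh <- rowMeans(Y)
    Pyy <- tcrossprod(Y - yh) / (2 * n) + R
    Pxy <- (X - xp) %*% t(Y - yh) / (2 * n)
    K <- Pxy %*% solve(Pyy)
    list(x = xp + drop(K %*% (y - yh)), P = Pp - K %*% Pyy %*% t(K))
  }

  f <- function(x) c(0.9 * x[1] + 0.2 * tanh(x[2]), 0.95 * x[2] - 0.1 * x[1])
  h <- function(x) x[1] + 0.05 * x[2]^2
  Q <- diag(c(0.01, 0.02)); R <- matrix(0.05)
  set.seed(31)
  x <- c(0.5, -0.3); P <- diag(0.2, 2)
  st <- sckf_state(x, t(chol(P)))
  for (k in 1:50) {
    y <- h(c(rnorm(1), rnorm(1))) + rnorm(1, 0, 0.2)
    o <- ckf_oracle(x, P, f, h, Q, R, y)
    st <- sckf_predict(st, function(x, u) f(x), NULL, t(chol(Q)))
    up <- sckf_update(st, y, h, t(chol(R)))
    st <- up$state
    x <- o$x; P <- o$P
    expect_equal(st$x_hat, x, tolerance = 1e-8)
    expect_equal(st$S %*% t(st$S), P, tolerance = 1e-8)
  }
})

test_that("the filter runs on nonsmooth dynamics without failure", {
  # dry-friction style piecewise model with a sign() discontinuity
  f <- function(x, u) c(x[1] + 0.01 * x[2],
                        0.98 * x[2] - 0.05 * sign(x[2]) + u)
  h <- function(x) x[1]
  set.seed(6)
  st <- sckf_state(c(0, 0), diag(0.1, 2))
  x <- c(0, 0.5)
  for (k in 1:100) {
    u <- 0.02 * sin(k / 10)
    x <- f(x, u) + c(0, rnorm(1, 0, 0.01))
    st <- sckf_predict(st, f, u, diag(c(1e-4, 0.01)))
    up <- sckf_update(st, x[1] + rnorm(1, 0, 0.02), h, matrix(0.02))
    st <- up$state
  }
  expect_true(all(is.finite(st$x_hat)))
  expect_true(all(is.finite(st$S)))
  expect_lt(abs(st$x_hat[1] - x[1]), 0.1)
})

test_that("cubature-point clamping is applied and logged", {
  counter <- new.env(); counter$n <- 0L
  clamp <- function(x) { xc <- pmax(x, 0); if (any(xc != x)) counter$n <- counter$n + 1L; xc }
  st <- sckf_state(c(0.01), matrix(1))
  pred <- sckf_predict(st, function(x, u) x, NULL, matrix(0), clamp_fn = clamp)
  expect_gt(counter$n, 0)
  expect_gte(pred$x_hat, 0)
})
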