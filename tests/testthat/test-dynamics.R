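# Euler-Lagrange dynamics, passive torques and state-space assembly

test_that("inertia matrix is symmetric positive definite and has correct limits", {
  m <- cached_model()
  set.seed(21)
  for (i in 1:20) {
    q <- c(runif(1, -0.3, 2.6), runif(1, -2, 0.17), runif(1, -1, 0.3))
    M <- inertia_matrix(q, m$segments)
    expect_equal(M, t(M))
    expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), 0)
  }

  # with (near) massless shank and foot the 1-1 entry reduces to the thigh
  # single-pendulum inertia
  tiny <- 1e-12
  segs <- list(
    thigh = segment_params(8, 0.44, 0.18, 0.1),
    shank = segment_params(tiny, 0.44, 0.2, tiny),
    foot = segment_params(tiny, 0.27, c(0.06, -0.04), tiny)
  )
  M <- inertia_matrix(c(0.5, -0.4, 0.1), segs)
  expect_equal(M[1, 1], 0.1 + 8 * 0.18^2, tolerance = 1e-9)
})

test_that("Coriolis matrix is linear in rates and satisfies the skew identity", {
  m <- cached_model()
  q <- c(0.4, -0.6, -0.2)
  expect_equal(coriolis_matrix(q, c(0, 0, 0), m$segments),
               matrix(0, 3, 3))
  D1 <- coriolis_matrix(q, c(0.3, -0.2, 0.5), m$segments)
  D2 <- coriolis_matrix(q, 2 * c(0.3, -0.2, 0.5), m$segments)
  expect_equal(D2, 2 * D1, tolerance = 1e-9)

  # analytic partials agree with the central-difference route
  dA <- anklestiff:::.dM_dq(q, m$segments)
  dF <- anklestiff:::.dM_dq(q, m$segments, method = "fd")
  for (i in 1:3) expect_equal(dA[[i]], dF[[i]], tolerance = 1e-7)

  # (Mdot - 2D) skew-symmetric along random trajectories
  set.seed(5)
  for (i in 1:10) {
    q <- c(runif(1, 0, 2), runif(1, -1.8, 0), runif(1, -0.9, 0.3))
    qd <- rnorm(3)
    D <- coriolis_matrix(q, qd, m$segments)
    dM <- anklestiff:::.dM_dq(q, m$segments)
    Mdot <- dM[[1]] * qd[1] + dM[[2]] * qd[2] + dM[[3]] * qd[3]
    S <- Mdot - 2 * D
    expect_lt(max(abs(S + t(S))), 1e-6)
  }
})

test_that("gravity vector is the potential-energy gradient", {
  m <- cached_model()
  expect_equal(gravity_vector(c(0.3, -0.5, 0.1), m$segments, g = 0),
               numeric(3))
  set.seed(9)
  for (i in 1:10) {
    q <- c(runif(1, 0, 2), runif(1, -1.8, 0), runif(1, -0.9, 0.3))
    k <- gravity_vector(q, m$segments)
    h <- 1e-6
    kn <- vapply(1:3, function(j) {
      qp <- q; qm <- q; qp[j] <- qp[j] + h; qm[j] <- qm[j] - h
      (potential_energy(qp, m$segments) -
         potential_energy(qm, m$segments)) / (2 * h)
    }, 0)
    expect_equal(k, kn, tolerance = 1e-5)
  }

  # hanging equilibrium: minimising P over the foot angle zeroes k3
  q3_star <- stats::optimize(function(q3)
    potential_energy(c(0, 0, q3), m$segments),
    interval = c(-1.5, 0.5))$minimum
  expect_lt(abs(gravity_vector(c(0, 0, q3_star), m$segments)[3]), 1e-4)
})

test_that("viscous torque is odd and matches direct substitution", {
  expect_equal(viscous_torque(0, 2, 1.3), 0)
  expect_equal(viscous_torque(-0.7, 2, 1.3), -viscous_torque(0.7, 2, 1.3))
  expect_equal(viscous_torque(2, 1, 1), 2)
})

test_that("elastic torques follow the printed double-exponential forms", {
  # degenerate parameters: all exponentials off, offset survives
  off <- list(a1k = -Inf, b1k = 0, c1k = 0, d1k = 0,
              a2k = -Inf, b2k = 0, c2k = 0, d2k = 0,
              ek = 5, fk = -Inf, gk = 0)
  expect_equal(elastic_torque_knee(0.1, -0.4, 0.1, off), 5)
  offa <- list(a1a = -Inf, b1a = 0, c1a = 0, a2a = -Inf, b2a = 0, c2a = 0,
               da = -1)
  expect_equal(elastic_torque_ankle(-0.4, 0.1, offa), -1)

  # independent re-derivation on random coefficient draws
  set.seed(17)
  for (i in 1:25) {
    p <- as.list(stats::setNames(rnorm(11, 0, 0.8),
                                 c("a1k", "b1k", "c1k", "d1k", "a2k", "b2k",
                                   "c2k", "d2k", "ek", "fk", "gk")))
    q1 <- runif(1, -0.3, 2); q2 <- runif(1, -2, 0); q3 <- runif(1, -1, 0.3)
    oracle <- exp(p$a1k + p$b1k * q1 + p$c1k * q2 + p$d1k * q3) -
      exp(p$a2k + p$b2k * q1 + p$c2k * q2 + p$d2k * q3) +
      p$ek - exp(p$fk + p$gk * q2)
    expect_equal(elastic_torque_knee(q1, q2, q3, p), oracle)
  }

  # biarticular couplings: neighbouring joint angles change the torque
  m <- cached_model()
  pk <- m$passive$knee
  expect_false(elastic_torque_knee(0, -0.5, 0, pk) ==
                 elastic_torque_knee(0.5, -0.5, 0, pk))
  pa <- m$passive$ankle
  expect_false(elastic_torque_ankle(0, -0.1, pa) ==
                 elastic_torque_ankle(-0.8, -0.1, pa))

  # ankle partial derivative matches finite differences
  h <- 1e-6
  fd <- (elastic_torque_ankle(-0.3, -0.1 + h, pa) -
           elastic_torque_ankle(-0.3, -0.1 - h, pa)) / (2 * h)
  ana <- pa$c1a * exp(pa$a1a + pa$b1a * -0.3 + pa$c1a * -0.1) -
    pa$c2a * exp(pa$a2a + pa$b2a * -0.3 + pa$c2a * -0.1)
  expect_equal(fd, ana, tolerance = 1e-6)

  # overflow guard
  expect_error(elastic_torque_ankle(0, 100, pa), "overflow")
})

test_that("active and ground-reaction torques compose as stated", {
  expect_equal(active_torque(c(0.05, -0.04), c(0, 0)), 0)
  expect_equal(active_torque(0.05, 100), 5)
  expect_equal(active_torque(c(0.05, -0.05), c(100, 100)), 0)
  expect_error(active_torque(c(1, 2), 1), "mismatch")

  expect_equal(grf_torque(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0), c(0, 0, 0)), 0)
  # force line through the joint centre
  expect_equal(grf_torque(c(0.2, 0, 0), c(0, 0, 1), c(0.2, -0.5, 0),
                          c(0, 300, 0)), 0)
  expect_equal(grf_torque(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0), c(0, 10, 0)),
               10)
  expect_error(grf_torque(c(0, 0, 0), c(0, 0, 2), c(1, 0, 0), c(0, 1, 0)),
               "unit")
})

test_that("reduced dynamics matches the full three-joint system", {
  m <- cached_model()
  # equilibrium: torques exactly balancing gravity give zero acceleration
  q_hat <- c(-0.5, -0.2); hip <- c(0.3, 0, 0)
  k <- gravity_vector(c(hip[1], q_hat), m$segments)
  acc <- reduced_dynamics(q_hat, c(0, 0), hip, k[2:3], m$segments)
  expect_equal(acc, c(0, 0), tolerance = 1e-10)

  # with a moving hip, the reduced solution satisfies rows 2-3 of the full
  # Euler-Lagrange equations with the hip trajectory imposed
  set.seed(33)
  for (i in 1:5) {
    q_hat <- c(runif(1, -1.5, 0), runif(1, -0.8, 0.2))
    qd_hat <- rnorm(2)
    hip <- c(runif(1, 0, 1.5), rnorm(1), rnorm(1))
    tau <- rnorm(2, 0, 5)
    acc <- reduced_dynamics(q_hat, qd_hat, hip, tau, m$segments)
    q <- c(hip[1], q_hat); qd <- c(hip[2], qd_hat)
    qdd <- c(hip[3], acc)
    M <- inertia_matrix(q, m$segments)
    D <- coriolis_matrix(q, qd, m$segments)
    k <- gravity_vector(q, m$segments)
    resid <- (M %*% qdd + D %*% qd + k)[2:3] - tau
    expect_equal(drop(resid), c(0, 0), tolerance = 1e-8)
  }
})

test_that("state derivative assembles the structural blocks of the model", {
  m <- cached_model()
  set.seed(4)
  x <- c(-0.4, -0.15, 0.3, -0.2, runif(6, 0, 0.5), runif(6, 0, 0.5))
  u <- c(runif(6, 0, 0.5), 0.4, 0.3, -0.1, rep(0, 6))
  dx <- state_derivative(x, u, m)
  expect_equal(dx[1], x[3])
  expect_equal(dx[2], x[4])

  # removing the GRF input equals dropping the external component
  u_grf <- u; u_grf[10:15] <- c(0.1, -0.9, 0, 20, 150, 0)
  d_all <- state_derivative(x, u_grf, m)
  d_noext <- state_derivative(x, u_grf, m,
                              components = c("active", "elastic", "viscous"))
  d_zero <- state_derivative(x, u, m)
  expect_equal(d_noext, state_derivative(x, u, m,
               components = c("active", "elastic", "viscous")))
  expect_false(isTRUE(all.equal(d_all[3:4], d_zero[3:4])))
})

test_that("passive equilibrium is a fixed point of the state derivative", {
  m <- cached_model()
  u <- numeric(15)
  # locate the passive equilibrium (zero EMG, hip fixed at 0) numerically
  obj <- function(q) {
    x <- c(q, 0, 0, numeric(12))
    sum(state_derivative(x, u, m)[3:4]^2)
  }
  opt <- stats::optim(c(-0.1, -0.05), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  expect_lt(opt$value, 1e-8)
  x_eq <- c(opt$par, 0, 0, numeric(12))
  expect_equal(state_derivative(x_eq, u, m)[5:16], numeric(12))
})

test_that("explicit Euler step converges at first order to a reference solution", {
  m <- cached_model()
  u <- numeric(15)
  x0 <- c(-0.3, -0.1, 0, 0, numeric(12))

  expect_equal(discretise_step(x0, u, 0.01, m),
               x0 + 0.01 * state_derivative(x0, u, m))

  # deSolve reference for the torque-free (gravity-only) swing
  f_free <- function(t, y, parms)
    list(state_derivative(y, u, m, components = character(0)))
  ref <- deSolve::ode(y = x0, times = c(0, 0.5), func = f_free,
                      parms = NULL, method = "ode45",
                      atol = 1e-10, rtol = 1e-10)
  x_ref <- as.numeric(ref[2, -1])

  err <- sapply(c(0.005, 0.0025), function(h) {
    x <- x0
    for (i in seq_len(round(0.5 / h)))
      x <- discretise_step(x, u, h, m, components = character(0))
    max(abs(x[1:4] - x_ref[1:4]))
  })
  expect_gt(err[1] / err[2], 1.6)  # first-order: halving h halves the error
  expect_lt(err[1] / err[2], 2.6)
})
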