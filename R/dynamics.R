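# Three-segment (thigh, shank, foot) sagittal Euler-Lagrange dynamics with
# active muscle torques, nonlinear passive elastic and viscous joint torques,
# ground-reaction torques, and assembly of the 16-state model
#
#   x = (phi_knee, phi_ankle, phi_knee_dot, phi_ankle_dot,
#        a_RF..a_TA, Fbar_RF..Fbar_TA)
#   u = (s_RF..s_TA, phi_hip, phi_hip_dot, phi_hip_ddot, CoP xyz, GRF xyz)
#
# Generalised coordinates q = (q1, q2, q3) = (hip, knee, ankle); the hip is
# an exogenous input, so the equations of motion are reduced to the lower
# 2x2 block with hip coupling terms moved to the right-hand side.

#' Segment inertial parameters
#'
#' @param mass Segment mass (kg).
#' @param length Segment length (m) — hip-to-knee for the thigh, knee-to-ankle
#'   for the shank, heel-to-toe scale for the foot.
#' @param com Centre-of-mass location: for thigh/shank the distance from the
#'   proximal joint along the segment (m); for the foot a 2-vector in the
#'   foot frame (x forward, y up).
#' @param inertia Moment of inertia about the sagittal axis through the
#'   centre of mass (kg m^2).
#' @return A list of class `segment_params`.
#' @export
segment_params <- function(mass, length, com, inertia) {
  stopifnot(mass > 0, inertia > 0, length > 0)
  structure(list(mass = mass, length = length, com = com, inertia = inertia),
            class = "segment_params")
}

# unit vectors: u(theta) points along a hanging segment, w = du/dtheta
.seg_u <- function(th) c(sin(th), -cos(th))
.seg_w <- function(th) c(cos(th), sin(th))

# centre-of-mass Jacobians of the three segments; returns list(Jv = list of
# 2x3, com_y = vector of CoM heights) for mass-matrix / gravity assembly
.chain_jacobians <- function(q, segs) {
  q1 <- q[1]; q12 <- q[1] + q[2]; q123 <- q[1] + q[2] + q[3]
  t1 <- segs$thigh; t2 <- segs$shank; t3 <- segs$foot
  w1 <- .seg_w(q1); w2 <- .seg_w(q12)
  u1 <- .seg_u(q1); u2 <- .seg_u(q12)
  cf <- t3$com
  c_ <- cos(q123); s_ <- sin(q123)
  Rcf  <- c(c_ * cf[1] - s_ * cf[2], s_ * cf[1] + c_ * cf[2])
  dRcf <- c(-s_ * cf[1] - c_ * cf[2], c_ * cf[1] - s_ * cf[2])

  Jv1 <- cbind(t1$com * w1, c(0, 0), c(0, 0))
  Jv2 <- cbind(t1$length * w1 + t2$com * w2, t2$com * w2, c(0, 0))
  col3 <- dRcf
  Jv3 <- cbind(t1$length * w1 + t2$length * w2 + dRcf,
               t2$length * w2 + dRcf, col3)
  com_y <- c(t1$com * u1[2],
             t1$length * u1[2] + t2$com * u2[2],
             t1$length * u1[2] + t2$length * u2[2] + Rcf[2])
  list(Jv = list(Jv1, Jv2, Jv3), com_y = com_y)
}

#' Inertia matrix of the three-segment chain
#'
#' Closed-form planar-chain inertia matrix, equivalent to
#' \eqn{M(q) = \sum_i m_i J_i^T J_i + I_i J_{\omega,i}^T J_{\omega,i}} with
#' the centre-of-mass Jacobians of the three segments; symmetric positive
#' definite for all admissible configurations.
#'
#' @param q Generalised coordinates `(hip, knee, ankle)` in radians.
#' @param segs Named list with `thigh`, `shank`, `foot` [segment_params()].
#' @return Symmetric positive definite 3x3 matrix (kg m^2).
#' @export
inertia_matrix <- function(q, segs) {
  t1 <- segs$thigh; t2 <- segs$shank; t3 <- segs$foot
  A <- t1$length; B <- t2$length
  r1 <- t1$com; r2 <- t2$com; cf <- t3$com
  m1 <- t1$mass; m2 <- t2$mass; m3 <- t3$mass
  rf2 <- sum(cf^2)
  c2 <- cos(q[2])
  e23 <- -cf[1] * sin(q[2] + q[3]) - cf[2] * cos(q[2] + q[3])
  e3  <- -cf[1] * sin(q[3]) - cf[2] * cos(q[3])
  I1 <- t1$inertia; I2 <- t2$inertia; I3 <- t3$inertia

  M <- matrix(0, 3, 3)
  M[1, 1] <- I1 + I2 + I3 + m1 * r1^2 +
    m2 * (A^2 + r2^2 + 2 * A * r2 * c2) +
    m3 * (A^2 + B^2 + rf2 + 2 * A * B * c2 + 2 * A * e23 + 2 * B * e3)
  M[1, 2] <- M[2, 1] <- I2 + I3 + m2 * (r2^2 + A * r2 * c2) +
    m3 * (B^2 + rf2 + A * B * c2 + A * e23 + 2 * B * e3)
  M[1, 3] <- M[3, 1] <- I3 + m3 * (A * e23 + B * e3 + rf2)
  M[2, 2] <- I2 + I3 + m2 * r2^2 + m3 * (B^2 + rf2 + 2 * B * e3)
  M[2, 3] <- M[3, 2] <- I3 + m3 * (B * e3 + rf2)
  M[3, 3] <- I3 + m3 * rf2
  M
}

# Partials of M(q): analytic closed forms (default) or central finite
# differences on inertia_matrix(); the two routes are cross-checked in the
# test suite.  M is cyclic in q1, so dM/dq1 = 0.
.dM_dq <- function(q, segs, h = 1e-6, method = c("analytic", "fd")) {
  method <- match.arg(method)
  if (method == "fd") {
    return(lapply(1:3, function(i) {
      qp <- q; qm <- q
      qp[i] <- qp[i] + h; qm[i] <- qm[i] - h
      (inertia_matrix(qp, segs) - inertia_matrix(qm, segs)) / (2 * h)
    }))
  }
  t1 <- segs$thigh; t2 <- segs$shank; t3 <- segs$foot
  A <- t1$length; B <- t2$length; r2 <- t2$com; cf <- t3$com
  m2 <- t2$mass; m3 <- t3$mass
  s2 <- sin(q[2])
  f23 <- -cf[1] * cos(q[2] + q[3]) + cf[2] * sin(q[2] + q[3])
  f3  <- -cf[1] * cos(q[3]) + cf[2] * sin(q[3])

  d2 <- matrix(0, 3, 3)
  d2[1, 1] <- -2 * m2 * A * r2 * s2 + m3 * (-2 * A * B * s2 + 2 * A * f23)
  d2[1, 2] <- d2[2, 1] <- -m2 * A * r2 * s2 + m3 * (-A * B * s2 + A * f23)
  d2[1, 3] <- d2[3, 1] <- m3 * A * f23

  d3 <- matrix(0, 3, 3)
  d3[1, 1] <- m3 * (2 * A * f23 + 2 * B * f3)
  d3[1, 2] <- d3[2, 1] <- m3 * (A * f23 + 2 * B * f3)
  d3[1, 3] <- d3[3, 1] <- m3 * (A * f23 + B * f3)
  d3[2, 2] <- m3 * 2 * B * f3
  d3[2, 3] <- d3[3, 2] <- m3 * B * f3

  list(matrix(0, 3, 3), d2, d3)
}

#' Coriolis/centrifugal matrix
#'
#' Christoffel-symbol form
#' \eqn{d_{kj} = \sum_i \frac12 (\partial m_{kj}/\partial q_i +
#' \partial m_{ki}/\partial q_j - \partial m_{ij}/\partial q_k) \dot q_i}.
#' The inertia-matrix partials are analytic by default, with a central
#' finite-difference route (`method = "fd"`) retained as the independent
#' cross-check; either way \eqn{\dot M - 2D} is skew-symmetric.
#'
#' @inheritParams inertia_matrix
#' @param q_dot Generalised velocities (rad/s).
#' @param h Finite-difference step (rad), used by `method = "fd"`.
#' @param method Partial-derivative route.
#' @return 3x3 matrix.
#' @export
coriolis_matrix <- function(q, q_dot, segs, h = 1e-6,
                            method = c("analytic", "fd")) {
  dM <- .dM_dq(q, segs, h, method = method)
  D <- matrix(0, 3, 3)
  for (k in 1:3) for (j in 1:3) {
    s <- 0
    for (i in 1:3)
      s <- s + 0.5 * (dM[[i]][k, j] + dM[[j]][k, i] - dM[[k]][i, j]) * q_dot[i]
    D[k, j] <- s
  }
  D
}

#' Gravity vector
#'
#' Analytic gradient of the total potential energy of the three segment
#' masses.
#'
#' @inheritParams inertia_matrix
#' @param g Gravitational acceleration (m/s^2).
#' @return 3-vector (N m).
#' @export
gravity_vector <- function(q, segs, g = 9.81) {
  t1 <- segs$thigh; t2 <- segs$shank; t3 <- segs$foot
  cf <- t3$com
  s1 <- sin(q[1]); s12 <- sin(q[1] + q[2])
  q123 <- q[1] + q[2] + q[3]
  dy3 <- cos(q123) * cf[1] - sin(q123) * cf[2]
  a <- (t1$mass * t1$com + (t2$mass + t3$mass) * t1$length) * s1
  b <- (t2$mass * t2$com + t3$mass * t2$length) * s12
  cc <- t3$mass * dy3
  g * c(a + b + cc, b + cc, cc)
}

#' Total potential energy of the chain (for conservation checks)
#' @inheritParams gravity_vector
#' @return Potential energy (J), gauge at the hip.
#' @export
potential_energy <- function(q, segs, g = 9.81) {
  J <- .chain_jacobians(q, segs)
  m <- c(segs$thigh$mass, segs$shank$mass, segs$foot$mass)
  g * sum(m * J$com_y)
}

#' Power-law viscous joint torque
#'
#' \eqn{\tau^V = -K_V \,\mathrm{sgn}(\dot q)\, |\dot q|^{n_V}} applied
#' resistively; the returned value is the raw odd-symmetric magnitude term
#' \eqn{K_V \mathrm{sgn}(\dot q) |\dot q|^{n_V}} — callers subtract it from
#' the joint torque balance.
#'
#' @param q_dot Joint rate (rad/s).
#' @param K_V Damping coefficient (N m (s/rad)^n).
#' @param n_V Power-law exponent (> 0).
#' @return Torque magnitude term (N m), odd in `q_dot`.
#' @export
viscous_torque <- function(q_dot, K_V, n_V) {
  stopifnot(K_V >= 0, n_V > 0)
  K_V * sign(q_dot) * abs(q_dot)^n_V
}

.safe_exp <- function(z) {
  if (any(z > 50))
    stop("elastic-torque exponent overflow: angle far outside model validity",
         call. = FALSE)
  exp(z)
}

#' Passive elastic knee torque
#'
#' Double-exponential characteristic with an offset and an extra
#' extension-limit exponential, coupled to the neighbouring hip and ankle
#' angles through the biarticular muscle groups:
#' \deqn{\tau_2^E = e^{a_{1k}+b_{1k}q_1+c_{1k}q_2+d_{1k}q_3}
#'   - e^{a_{2k}+b_{2k}q_1+c_{2k}q_2+d_{2k}q_3} + e_k - e^{f_k+g_k q_2}.}
#'
#' @param q1,q2,q3 Hip, knee, ankle angles (radians).
#' @param p Named list of coefficients `a1k, b1k, c1k, d1k, a2k, b2k, c2k,
#'   d2k, ek, fk, gk` (per-radian exponential slopes).
#' @return Torque (N m).
#' @export
elastic_torque_knee <- function(q1, q2, q3, p) {
  .safe_exp(p$a1k + p$b1k * q1 + p$c1k * q2 + p$d1k * q3) -
    .safe_exp(p$a2k + p$b2k * q1 + p$c2k * q2 + p$d2k * q3) +
    p$ek - .safe_exp(p$fk + p$gk * q2)
}

#' Passive elastic ankle torque
#'
#' Two opposed exponentials plus a constant, with knee coupling through the
#' biarticular gastrocnemius:
#' \deqn{\tau_3^E = e^{a_{1a}+b_{1a}q_2+c_{1a}q_3}
#'   - e^{a_{2a}+b_{2a}q_2+c_{2a}q_3} + d_a.}
#'
#' @param q2,q3 Knee and ankle angles (radians).
#' @param p Named list of coefficients `a1a, b1a, c1a, a2a, b2a, c2a, da`.
#' @return Torque (N m).
#' @export
elastic_torque_ankle <- function(q2, q3, p) {
  .safe_exp(p$a1a + p$b1a * q2 + p$c1a * q3) -
    .safe_exp(p$a2a + p$b2a * q2 + p$c2a * q3) + p$da
}

#' Active joint torque from muscle forces
#'
#' \eqn{\tau_j^T = \sum_i r_{ma_{i,j}} F_i^T} with signed moment arms
#' (positive torque increases the joint angle).
#'
#' @param lever_arms Signed moment arms (m).
#' @param tendon_forces Tendon forces (N), same length and order.
#' @return Torque (N m).
#' @export
active_torque <- function(lever_arms, tendon_forces) {
  if (length(lever_arms) != length(tendon_forces))
    stop("lever arm / force length mismatch", call. = FALSE)
  sum(lever_arms * tendon_forces)
}

#' Ground-reaction torque about a joint axis
#'
#' Scalar triple product \eqn{((p_{GRF} - o_j) \times f_{GRF}) \cdot e_{z_j}}.
#'
#' @param o_j Joint centre, 3-vector (m).
#' @param e_zj Unit vector along the joint rotation axis.
#' @param p_grf Point of action of the ground-reaction force (m).
#' @param f_grf Ground-reaction force vector (N).
#' @return Torque (N m).
#' @export
grf_torque <- function(o_j, e_zj, p_grf, f_grf) {
  if (abs(sqrt(sum(e_zj^2)) - 1) > 1e-8)
    stop("joint axis must be a unit vector", call. = FALSE)
  r <- p_grf - o_j
  cr <- c(r[2] * f_grf[3] - r[3] * f_grf[2],
          r[3] * f_grf[1] - r[1] * f_grf[3],
          r[1] * f_grf[2] - r[2] * f_grf[1])
  sum(cr * e_zj)
}

#' Reduced knee/ankle dynamics with exogenous hip motion
#'
#' Solves the lower 2x2 block of the Euler-Lagrange equations with the hip
#' coupling moved to the right-hand side:
#' \eqn{\hat\tau = (\tau_2, \tau_3)^T - \ddot q_1 (m_{21}, m_{31})^T -
#' \dot q_1 (d_{21}, d_{31})^T}.
#'
#' @param q_hat Knee and ankle angles (rad).
#' @param q_hat_dot Knee and ankle rates (rad/s).
#' @param hip Numeric 3-vector `(q1, q1_dot, q1_ddot)`.
#' @param tau Joint torques `(tau2, tau3)` (N m).
#' @param segs Segment parameter list.
#' @param g Gravitational acceleration (m/s^2).
#' @return Accelerations `(knee, ankle)` (rad/s^2).
#' @export
reduced_dynamics <- function(q_hat, q_hat_dot, hip, tau, segs, g = 9.81) {
  q <- c(hip[1], q_hat)
  q_dot <- c(hip[2], q_hat_dot)
  M <- inertia_matrix(q, segs)
  D <- coriolis_matrix(q, q_dot, segs)
  k <- gravity_vector(q, segs, g)
  tau_hat <- tau - hip[3] * M[2:3, 1] - hip[2] * D[2:3, 1]
  rhs <- tau_hat - k[2:3] - D[2:3, 2:3] %*% q_hat_dot
  drop(solve(M[2:3, 2:3], rhs))
}

## ---- full state-space assembly --------------------------------------------

# Muscle kinetics and joint torques at state x, input u.  Returns the pieces
# needed by both the state derivative and the torque/stiffness reconstruction.
.model_forces <- function(x, u, model,
                          components = c("active", "elastic", "viscous",
                                         "external")) {
  q <- c(hip = u[[7]], knee = x[[1]], ankle = x[[2]])
  rates <- c(hip = u[[8]], knee = x[[3]], ankle = x[[4]])
  a <- pmin(pmax(x[5:10], 0), 1)
  Fb <- pmax(x[11:16], 0)
  s <- pmin(pmax(u[1:6], 0), 1)

  nm <- length(MUSCLES)
  FT <- numeric(nm); da <- numeric(nm); dF <- numeric(nm)
  r_knee <- numeric(nm); r_ankle <- numeric(nm)
  for (i in seq_len(nm)) {
    mus <- MUSCLES[i]
    tabl <- model$tables[[mus]]
    path <- model$paths[[mus]]
    par <- model$muscle_params[[mus]]
    lmt <- .table_eval(tabl$length, q, clamp = TRUE)
    v <- 0
    for (jn in tabl$length$vars)
      v <- v + rates[[jn]] * .table_eval(tabl$length, q, deriv = jn,
                                         clamp = TRUE)
    v_M <- v / cos(path$alpha_p)
    l_M <- (lmt - path$l_T) / cos(path$alpha_p)
    da[i] <- activation_rate(a[i], s[i], par)
    dF[i] <- contraction_rate(Fb[i], a[i], l_M, v_M, par)
    FT[i] <- tendon_force(Fb[i], a[i], l_M, v_M, par)
    if (!is.null(tabl$lever$knee))
      r_knee[i] <- .table_eval(tabl$lever$knee, q, clamp = TRUE)
    if (!is.null(tabl$lever$ankle))
      r_ankle[i] <- .table_eval(tabl$lever$ankle, q, clamp = TRUE)
  }

  tau2 <- 0; tau3 <- 0
  if ("active" %in% components) {
    tau2 <- tau2 + active_torque(r_knee, FT)
    tau3 <- tau3 + active_torque(r_ankle, FT)
  }
  if ("elastic" %in% components) {
    tau2 <- tau2 + elastic_torque_knee(q[1], q[2], q[3], model$passive$knee)
    tau3 <- tau3 + elastic_torque_ankle(q[2], q[3], model$passive$ankle)
  }
  if ("viscous" %in% components) {
    vp <- model$passive$viscous
    tau2 <- tau2 - viscous_torque(rates[["knee"]], vp$knee$K_V, vp$knee$n_V)
    tau3 <- tau3 - viscous_torque(rates[["ankle"]], vp$ankle$K_V, vp$ankle$n_V)
  }
  if ("external" %in% components && any(u[13:15] != 0)) {
    L1 <- model$segments$thigh$length
    L2 <- model$segments$shank$length
    o_knee <- c(L1 * .seg_u(q[1]), 0)
    o_ankle <- c(o_knee[1:2] + L2 * .seg_u(q[1] + q[2]), 0)
    ax <- .rot_z(q[1] + q[2]) %*% .rot_y(model$geom$beta) %*%
      .rot_x(model$geom$gamma) %*% c(0, 0, 1)
    tau2 <- tau2 + grf_torque(o_knee, c(0, 0, 1), u[10:12], u[13:15])
    tau3 <- tau3 + grf_torque(o_ankle, drop(ax) / sqrt(sum(ax^2)),
                              u[10:12], u[13:15])
  }
  list(q = q, rates = rates, tau = c(tau2, tau3), FT = FT,
       r_knee = r_knee, r_ankle = r_ankle, da = da, dF = dF)
}

#' Time derivative of the 16-dimensional model state
#'
#' Assembles the kinematic block, the reduced Euler-Lagrange dynamics and the
#' muscle activation/contraction dynamics into the continuous-time vector
#' field of the state-space model.
#'
#' @param x State vector (length 16): knee/ankle angles, knee/ankle rates,
#'   six activations, six normalised isometric forces.
#' @param u Input vector (length 15): six EMG envelopes, hip angle/rate/
#'   acceleration, CoP coordinates, GRF components.
#' @param model A `lower_limb_model`.
#' @param components Which torque contributions to include (used by tests and
#'   conservative-system checks).
#' @return Numeric length-16 derivative.
#' @export
state_derivative <- function(x, u, model,
                             components = c("active", "elastic", "viscous",
                                            "external")) {
  fr <- .model_forces(x, u, model, components)
  acc <- reduced_dynamics(x[1:2], x[3:4], u[7:9], fr$tau,
                          model$segments, model$g)
  c(x[3], x[4], acc, fr$da, fr$dF)
}

#' Explicit-Euler discretisation step
#'
#' The filter-internal one-step state transition
#' \eqn{x_{k+1} = x_k + T_s f(x_k, u_k)}; process noise is added by the
#' caller.
#'
#' @inheritParams state_derivative
#' @param T_s Sampling period (s), positive.
#' @return Next state vector.
#' @export
discretise_step <- function(x, u, T_s, model, ...) {
  stopifnot(T_s > 0)
  x + T_s * state_derivative(x, u, model, ...)
}
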