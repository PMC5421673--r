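# The user-facing estimator: run the square-root cubature Kalman filter over
# a (simulated or measured) record with the lower-extremity model as the
# filter-internal state transition, and package the result as a classed fit
# object with the usual accessor methods.

#' Filter configuration
#'
#' Initialisation and noise settings of the square-root cubature Kalman
#' filter.  All covariances are supplied as standard deviations of diagonal
#' square-root factors (full factors may be passed as matrices).
#'
#' @param x0 Initial mean (length 16); defaults to the all-zero state of the
#'   in-silico protocol.
#' @param sd0 Initial standard deviations: named `angle`, `rate`,
#'   `activation`, `force` blocks or a full length-16 vector.
#' @param q_sd Process-noise standard deviations (same block convention).
#' @param r_sd Measurement-noise standard deviation (rad), scalar or
#'   length 2.
#' @param clamp Clamp cubature points to the physically admissible state
#'   region (activations and normalised forces) before propagation.
#' @return Object of class `sckf_control`.
#' @export
sckf_control <- function(x0 = numeric(16),
                         sd0 = c(angle = 0.02, rate = 0.1,
                                 activation = 0.05, force = 0.05),
                         q_sd = c(angle = 1e-3, rate = 5e-3,
                                  activation = 2e-3, force = 2e-3),
                         r_sd = 0.3 * pi / 180,
                         clamp = TRUE) {
  expand <- function(v) {
    if (length(v) == 16) return(as.numeric(v))
    c(rep(v[["angle"]], 2), rep(v[["rate"]], 2),
      rep(v[["activation"]], 6), rep(v[["force"]], 6))
  }
  structure(list(x0 = x0, sd0 = expand(sd0), q_sd = expand(q_sd),
                 r_sd = if (length(r_sd) == 1) rep(r_sd, 2) else r_sd,
                 clamp = clamp),
            class = "sckf_control")
}

# cubature-point constraint: activations in [0,1], forces >= 0, angles and
# rates within (generous) physical bounds so the geometry tables stay valid
.make_clamp <- function(counter) {
  function(x) {
    xc <- x
    xc[5:10] <- pmin(pmax(xc[5:10], 0), 1)
    xc[11:16] <- pmin(pmax(xc[11:16], 0), 1.5)
    xc[1] <- min(max(xc[1], JOINT_RANGES$knee[1]), JOINT_RANGES$knee[2])
    xc[2] <- min(max(xc[2], JOINT_RANGES$ankle[1]), JOINT_RANGES$ankle[2])
    if (any(xc != x)) counter$n <- counter$n + 1L
    xc
  }
}

#' Fit the square-root cubature Kalman state estimator to a record
#'
#' Runs the SCKF with the lower-extremity model as its internal
#' explicit-Euler state transition over the record's noisy angle
#' measurements and inputs.  Returns a classed fit object carrying the state
#' estimates, innovations, reconstructed joint torques, and (when the record
#' contains simulation truth) estimation errors.
#'
#' @param record A `sim_record` from [forward_simulate()], or any list with
#'   fields `time`, `u` (N x 15), `y` (N x 2) and optionally truth `x`.
#' @param model A [lower_limb_model()].
#' @param control An [sckf_control()].
#' @return Object of class `ankle_sckf`.
#' @export
ankle_sckf <- function(record, model, control = sckf_control()) {
  Ts <- record$time[2] - record$time[1]
  N <- length(record$time)
  f_d <- function(x, u) discretise_step(x, u, Ts, model)
  h_d <- function(x) x[1:2]
  counter <- new.env()
  counter$n <- 0L
  clamp_fn <- if (control$clamp) .make_clamp(counter) else NULL

  state <- sckf_state(control$x0, control$sd0)
  S_Q <- diag(control$q_sd, 16)
  S_R <- diag(control$r_sd, 2)
  X <- matrix(0, N, 16)
  innov <- matrix(0, N, 2)
  X[1, ] <- state$x_hat
  for (k in 2:N) {
    state <- sckf_predict(state, f_d, record$u[k - 1, ], S_Q, clamp_fn)
    up <- sckf_update(state, record$y[k, ], h_d, S_R)
    state <- up$state
    X[k, ] <- state$x_hat
    innov[k, ] <- up$innovation
  }
  colnames(X) <- state_names()

  tau_hat <- matrix(0, N, 2, dimnames = list(NULL, c("tau_knee", "tau_ankle")))
  for (k in seq_len(N))
    tau_hat[k, ] <- reconstruct_torque(X[k, ], record$u[k, ], model)

  fit <- list(time = record$time, estimates = X, innovations = innov,
              torque = tau_hat, record = record, model = model,
              control = control, final_state = state,
              clamp_events = counter$n, rate = 1 / Ts)
  class(fit) <- "ankle_sckf"
  fit
}

#' @export
print.ankle_sckf <- function(x, ...) {
  cat(sprintf("SCKF state estimate: %d steps at %g Hz (16 states, 2 measured angles)\n",
              length(x$time), x$rate))
  if (!is.null(x$record$x)) {
    s <- summary(x)
    cat(sprintf("  angle RMS error [deg]:  knee %.3f, ankle %.3f\n",
                s$rms_angle_deg[1], s$rms_angle_deg[2]))
    cat(sprintf("  rate RMS error [rad/s]: knee %.3f, ankle %.3f\n",
                s$rms_rate[1], s$rms_rate[2]))
  }
  cat(sprintf("  cubature-point clamp events: %d\n", x$clamp_events))
  invisible(x)
}

#' Summarise an SCKF fit
#'
#' @param object An `ankle_sckf` fit.
#' @param burn_in Seconds discarded at the start before computing RMS errors
#'   (filter convergence transient).
#' @param ... Unused.
#' @return List with per-joint RMS errors of angles (deg), angular rates
#'   (rad/s) and reconstructed torques (N m) where truth is available, plus
#'   innovation statistics.
#' @export
summary.ankle_sckf <- function(object, burn_in = 1, ...) {
  sel <- object$time >= burn_in
  out <- list(n = length(object$time), rate = object$rate,
              clamp_events = object$clamp_events,
              innovation_sd = apply(object$innovations[sel, , drop = FALSE],
                                    2, stats::sd))
  if (!is.null(object$record$x)) {
    err_ang <- object$estimates[sel, 1:2] - object$record$x[sel, 1:2]
    err_rate <- object$estimates[sel, 3:4] - object$record$x[sel, 3:4]
    err_tau <- object$torque[sel, ] - object$record$tau[sel, ]
    rms <- function(e) sqrt(colMeans(e^2))
    out$rms_angle_deg <- rms(err_ang) * 180 / pi
    names(out$rms_angle_deg) <- c("knee", "ankle")
    out$rms_rate <- rms(err_rate)
    names(out$rms_rate) <- c("knee", "ankle")
    out$rms_torque <- rms(err_tau)
    names(out$rms_torque) <- c("knee", "ankle")
  }
  class(out) <- "summary.ankle_sckf"
  out
}

#' @export
print.summary.ankle_sckf <- function(x, ...) {
  cat(sprintf("SCKF fit: %d steps at %g Hz, %d clamp events\n",
              x$n, x$rate, x$clamp_events))
  if (!is.null(x$rms_angle_deg)) {
    cat(sprintf("  angle RMS error [deg]:  knee %.4f, ankle %.4f\n",
                x$rms_angle_deg[1], x$rms_angle_deg[2]))
    cat(sprintf("  rate RMS error [rad/s]: knee %.4f, ankle %.4f\n",
                x$rms_rate[1], x$rms_rate[2]))
    cat(sprintf("  torque RMS error [N m]: knee %.4f, ankle %.4f\n",
                x$rms_torque[1], x$rms_torque[2]))
  }
  invisible(x)
}

#' @export
coef.ankle_sckf <- function(object, ...) {
  c(q_sd = object$control$q_sd, r_sd = object$control$r_sd)
}

#' @export
fitted.ankle_sckf <- function(object, ...) {
  object$estimates[, 1:2]
}

#' @export
residuals.ankle_sckf <- function(object, ...) {
  object$innovations
}

#' Plot an SCKF fit
#'
#' Panels of estimated vs. (if available) true knee and ankle angles,
#' angular rates and ankle torque.
#'
#' @param x An `ankle_sckf` fit.
#' @param which Panels to draw, subset of `c("angles", "rates", "torque")`.
#' @param ... Passed to `matplot`.
#' @return `x`, invisibly.
#' @export
plot.ankle_sckf <- function(x, which = c("angles", "rates", "torque"), ...) {
  op <- graphics::par(mfrow = c(length(which), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  truth <- x$record$x
  for (w in which) {
    if (w == "angles") {
      graphics::matplot(x$time, x$estimates[, 1:2] * 180 / pi, type = "l",
                        lty = 1, col = c(2, 4), xlab = "time [s]",
                        ylab = "angle [deg]", main = "joint angles", ...)
      if (!is.null(truth))
        graphics::matlines(x$time, truth[, 1:2] * 180 / pi, lty = 3,
                           col = c(2, 4))
      graphics::legend("topright", c("knee", "ankle"), col = c(2, 4),
                       lty = 1, bty = "n")
    } else if (w == "rates") {
      graphics::matplot(x$time, x$estimates[, 3:4], type = "l", lty = 1,
                        col = c(2, 4), xlab = "time [s]",
                        ylab = "rate [rad/s]", main = "angular rates", ...)
      if (!is.null(truth))
        graphics::matlines(x$time, truth[, 3:4], lty = 3, col = c(2, 4))
    } else if (w == "torque") {
      graphics::plot(x$time, x$torque[, 2], type = "l", col = 4,
                     xlab = "time [s]", ylab = "torque [N m]",
                     main = "ankle torque")
      if (!is.null(x$record$tau))
        graphics::lines(x$time, x$record$tau[, 2], lty = 3, col = 4)
    }
  }
  invisible(x)
}
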