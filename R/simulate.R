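# Forward simulator and synthetic-input generator: the in-silico protocol
# that provides ground truth for every estimator test without external data.
#
# By default the truth trajectory uses the same explicit-Euler
# discretisation as the filter's internal model, with white Gaussian noise
# added to the states once per period and to the angle measurements — the
# simulation model and the filter model then differ only by the noise.  A
# fixed-step classical Runge-Kutta integrator at 10x the estimator rate is
# available as an alternative truth model for studying the effect of a
# genuine integrator mismatch.

#' In-silico experiment protocol
#'
#' Describes the synthetic experiment: a sinusoidal hip angle, block-wise
#' muscle activation schedules (5 s on / 5 s off by default), and the noise
#' configuration.
#'
#' @param duration Total duration (s).
#' @param rate Estimator sampling rate (Hz).
#' @param hip_amplitude Hip sine amplitude (degrees).
#' @param hip_omega Hip angular frequency (rad/s).
#' @param blocks Data frame with columns `muscle`, `level`, `start`,
#'   `duration` (s) describing smooth activation blocks; the default
#'   activates the plantar flexors, the dorsiflexor, the knee muscles and a
#'   final antagonist-coactivation phase in turn.
#' @param rise_time Half-cosine ramp time of the activation edges (s).
#' @param emg_noise_sd Multiplicative noise on the synthetic envelopes.
#' @param process_noise Named standard deviations (per estimator step) for
#'   the state blocks: `angle` (rad), `rate` (rad/s), `activation`, `force`.
#' @param measurement_noise Angle measurement noise standard deviation (rad).
#' @param integrator Truth-model integrator: `"euler"` (default) uses the
#'   same one-step explicit-Euler discretisation as the filter model, so
#'   truth and filter differ only by the injected noise; `"rk4"` integrates
#'   the continuous dynamics with classical Runge-Kutta at `substeps`
#'   sub-intervals per period, introducing a genuine discretisation mismatch.
#' @param substeps Truth-integration substeps per estimator period
#'   (`"rk4"` only).
#' @return Object of class `sim_protocol`.
#' @export
sim_protocol <- function(duration = 40, rate = 100,
                         hip_amplitude = 20, hip_omega = pi / 2,
                         blocks = default_activation_blocks(),
                         rise_time = 0.3,
                         emg_noise_sd = 0.02,
                         process_noise = c(angle = 1e-3, rate = 5e-3,
                                           activation = 2e-3, force = 2e-3),
                         measurement_noise = 0.3 * pi / 180,
                         integrator = c("euler", "rk4"),
                         substeps = 10) {
  integrator <- match.arg(integrator)
  stopifnot(duration > 0, rate > 0, all(blocks$level >= 0),
            all(blocks$level <= 1), substeps >= 1)
  structure(list(duration = duration, rate = rate,
                 hip_amplitude = hip_amplitude * pi / 180,
                 hip_omega = hip_omega, blocks = blocks,
                 rise_time = rise_time, emg_noise_sd = emg_noise_sd,
                 process_noise = process_noise,
                 measurement_noise = measurement_noise,
                 integrator = integrator, substeps = substeps),
            class = "sim_protocol")
}

#' Default block-activation schedule
#'
#' Activates each muscle group in a 5 s-on / 5 s-off pattern — plantar
#' flexors, then the dorsiflexor, then the knee muscles — and closes with an
#' ankle antagonist-coactivation block, mirroring the phases of a
#' plantar-flexion / dorsiflexion / coactivation experiment.
#'
#' @return Data frame with columns `muscle`, `level`, `start`, `duration`.
#' @export
default_activation_blocks <- function() {
  data.frame(
    muscle   = c("SOL", "GAS", "TA", "RF", "VM", "HAMS",
                 "TA", "SOL", "GAS"),
    level    = c(0.15, 0.10, 0.20, 0.20, 0.15, 0.20,
                 0.25, 0.18, 0.10),
    start    = c(0, 0, 10, 20, 20, 20, 30, 30, 30),
    duration = c(5, 5, 5, 5, 5, 5, 5, 5, 5)
  )
}

# smooth 0..1 edge: half-cosine over the rise time
.smooth_edge <- function(t, t0, rise) {
  u <- (t - t0) / rise
  u <- pmin(pmax(u, 0), 1)
  0.5 - 0.5 * cos(pi * u)
}

#' Generate synthetic sEMG envelopes from a protocol
#'
#' Smooth block activations (half-cosine rise and fall) with optional
#' multiplicative Gaussian noise, clipped to `[0, 1]`.  Uses the R random
#' number stream; fix the seed for reproducibility.
#'
#' @param protocol A [sim_protocol()].
#' @return N x 6 matrix of envelopes, columns ordered as the state-model
#'   muscles (RF, HAMS, VM, GAS, SOL, TA), sampled at the protocol rate.
#' @export
synth_emg <- function(protocol) {
  N <- round(protocol$duration * protocol$rate)
  t <- (seq_len(N) - 1) / protocol$rate
  S <- matrix(0, N, length(MUSCLES), dimnames = list(NULL, MUSCLES))
  for (b in seq_len(nrow(protocol$blocks))) {
    blk <- protocol$blocks[b, ]
    on <- .smooth_edge(t, blk$start, protocol$rise_time) -
      .smooth_edge(t, blk$start + blk$duration, protocol$rise_time)
    S[, blk$muscle] <- S[, blk$muscle] + blk$level * on
  }
  if (protocol$emg_noise_sd > 0) {
    S <- S * (1 + matrix(stats::rnorm(length(S), 0, protocol$emg_noise_sd),
                         nrow(S)))
  }
  pmin(pmax(S, 0), 1)
}

# classical fixed-step RK4 for the truth trajectory; u interpolated linearly
# between the endpoints of the estimator period
.rk4_step <- function(x, u0, u1, h, model) {
  um <- (u0 + u1) / 2
  k1 <- state_derivative(x, u0, model)
  k2 <- state_derivative(x + h / 2 * k1, um, model)
  k3 <- state_derivative(x + h / 2 * k2, um, model)
  k4 <- state_derivative(x + h * k3, u1, model)
  x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Forward-simulate the full 16-state model
#'
#' Integrates the lower-extremity dynamics under a protocol's synthetic
#' inputs and emits truth states, noisy angle measurements, the filter-facing
#' input matrix and the truth joint torques.  All angles start at zero.  The
#' hip velocity and acceleration supplied to the estimator are derived from
#' the hip angle with the band-limited differentiation filter, while the
#' truth integration uses the analytic derivatives of the hip sinusoid —
#' a deliberate, realistic model mismatch.
#'
#' @param model A [lower_limb_model()].
#' @param protocol A [sim_protocol()].
#' @return Object of class `sim_record`: list with `time`, truth states `x`
#'   (N x 16), filter inputs `u` (N x 15), measurements `y` (N x 2), truth
#'   torques `tau` (N x 2, knee and ankle), and metadata.
#' @export
forward_simulate <- function(model, protocol = sim_protocol()) {
  N <- round(protocol$duration * protocol$rate)
  Ts <- 1 / protocol$rate
  t <- (seq_len(N) - 1) * Ts
  A <- protocol$hip_amplitude; om <- protocol$hip_omega

  S <- synth_emg(protocol)
  hip <- A * sin(om * t)
  hip_d_true <- A * om * cos(om * t)
  hip_dd_true <- -A * om^2 * sin(om * t)
  hip_d_filt <- differentiate_filtered(hip, Ts)
  hip_dd_filt <- differentiate_filtered(hip, Ts, order = 2)

  u_true <- cbind(S, hip, hip_d_true, hip_dd_true,
                  matrix(0, N, 6))
  u_filt <- cbind(S, hip, hip_d_filt, hip_dd_filt,
                  matrix(0, N, 6))
  colnames(u_true) <- colnames(u_filt) <-
    c(MUSCLES, "phi_hip", "phi_hip_dot", "phi_hip_ddot",
      "CoP_x", "CoP_y", "CoP_z", "GRF_x", "GRF_y", "GRF_z")

  pn <- protocol$process_noise
  noise_sd <- c(rep(pn[["angle"]], 2), rep(pn[["rate"]], 2),
                rep(pn[["activation"]], 6), rep(pn[["force"]], 6))

  x <- numeric(16)
  X <- matrix(0, N, 16)
  TAU <- matrix(0, N, 2)
  X[1, ] <- x
  fr <- .model_forces(x, u_true[1, ], model)
  TAU[1, ] <- fr$tau
  euler <- protocol$integrator == "euler"
  h <- Ts / protocol$substeps
  for (k in seq_len(N - 1)) {
    u0 <- u_true[k, ]; u1 <- u_true[k + 1, ]
    x <- tryCatch({
      if (euler) {
        discretise_step(x, u0, Ts, model)
      } else {
        xs <- x
        for (s in seq_len(protocol$substeps)) {
          w <- (s - 1) / protocol$substeps
          ua <- u0 * (1 - w) + u1 * w
          w2 <- s / protocol$substeps
          ub <- u0 * (1 - w2) + u1 * w2
          xs <- .rk4_step(xs, ua, ub, h, model)
        }
        xs
      }
    }, error = function(e)
      stop(sprintf("forward integration diverged at t = %.2f s (%s)",
                   t[k], conditionMessage(e)), call. = FALSE))
    if (any(noise_sd > 0))
      x <- x + stats::rnorm(16, 0, noise_sd)
    x[5:10] <- pmin(pmax(x[5:10], 0), 1)
    x[11:16] <- pmax(x[11:16], 0)
    if (!all(is.finite(x)))
      stop(sprintf("forward integration diverged at t = %.2f s", t[k + 1]),
           call. = FALSE)
    X[k + 1, ] <- x
    TAU[k + 1, ] <- .model_forces(x, u_true[k + 1, ], model)$tau
  }
  Y <- X[, 1:2] + matrix(stats::rnorm(2 * N, 0, protocol$measurement_noise),
                         N, 2)
  colnames(X) <- state_names()
  colnames(Y) <- c("phi_knee_meas", "phi_ankle_meas")
  colnames(TAU) <- c("tau_knee", "tau_ankle")
  structure(list(time = t, x = X, u = u_filt, y = Y, tau = TAU,
                 protocol = protocol,
                 meta = list(rate = protocol$rate)),
            class = "sim_record")
}

#' Write / read a protocol as YAML
#'
#' @param protocol A [sim_protocol()].
#' @param path YAML file path.
#' @return `path` (write) or a `sim_protocol` (read).
#' @export
write_protocol <- function(protocol, path) {
  cfg <- list(duration = protocol$duration, rate = protocol$rate,
              hip_amplitude_deg = protocol$hip_amplitude * 180 / pi,
              hip_omega = protocol$hip_omega,
              rise_time = protocol$rise_time,
              emg_noise_sd = protocol$emg_noise_sd,
              process_noise = as.list(protocol$process_noise),
              measurement_noise = protocol$measurement_noise,
              integrator = protocol$integrator,
              substeps = protocol$substeps,
              blocks = lapply(seq_len(nrow(protocol$blocks)), function(i)
                as.list(protocol$blocks[i, ])))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  cfg <- yaml::read_yaml(path)
  blocks <- do.call(rbind, lapply(cfg$blocks, as.data.frame))
  sim_protocol(duration = cfg$duration, rate = cfg$rate,
               hip_amplitude = cfg$hip_amplitude_deg,
               hip_omega = cfg$hip_omega, blocks = blocks,
               rise_time = cfg$rise_time, emg_noise_sd = cfg$emg_noise_sd,
               process_noise = unlist(cfg$process_noise),
               measurement_noise = cfg$measurement_noise,
               integrator = cfg$integrator, substeps = cfg$substeps)
}

#' State-vector channel names
#' @return Character vector of the 16 state names, in model order.
#' @export
state_names <- function() {
  c("phi_knee", "phi_ankle", "phi_knee_dot", "phi_ankle_dot",
    paste0("a_", MUSCLES), paste0("Fbar_", MUSCLES))
}

#' Simulate from a lower-extremity model
#'
#' `simulate()` method: forward-simulates `nsim` independent noisy records
#' under a protocol.
#'
#' @param object A [lower_limb_model()].
#' @param nsim Number of records.
#' @param seed Optional RNG seed.
#' @param protocol A [sim_protocol()].
#' @param ... Unused.
#' @return A `sim_record` (if `nsim = 1`) or list of records.
#' @export
simulate.lower_limb_model <- function(object, nsim = 1, seed = NULL,
                                      protocol = sim_protocol(), ...) {
  if (!is.null(seed)) set.seed(seed)
  recs <- lapply(seq_len(nsim), function(i)
    forward_simulate(object, protocol))
  if (nsim == 1) recs[[1]] else recs
}

#' @export
print.sim_record <- function(x, ...) {
  cat(sprintf("Forward-simulation record: %.1f s at %g Hz (%d samples)\n",
              max(x$time) + 1 / x$meta$rate, x$meta$rate, length(x$time)))
  cat(sprintf("  knee angle range  [%.1f, %.1f] deg\n",
              min(x$x[, 1]) * 180 / pi, max(x$x[, 1]) * 180 / pi))
  cat(sprintf("  ankle angle range [%.1f, %.1f] deg\n",
              min(x$x[, 2]) * 180 / pi, max(x$x[, 2]) * 180 / pi))
  cat(sprintf("  ankle torque range [%.2f, %.2f] N m\n",
              min(x$tau[, 2]), max(x$tau[, 2])))
  invisible(x)
}

#' Write a simulation record to a CSV bundle with JSON metadata
#'
#' @param record A `sim_record`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return The directory, invisibly.
#' @export
write_sim_record <- function(record, dir, prefix = "record") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(time = record$time, record$x, record$u, record$y,
                   record$tau, check.names = FALSE)
  utils::write.csv(df, file.path(dir, paste0(prefix, ".csv")),
                   row.names = FALSE)
  meta <- list(rate = record$meta$rate,
               duration = record$protocol$duration,
               hip_amplitude_deg = record$protocol$hip_amplitude * 180 / pi,
               hip_omega = record$protocol$hip_omega,
               measurement_noise = record$protocol$measurement_noise,
               process_noise = as.list(record$protocol$process_noise))
  jsonlite::write_json(meta, file.path(dir, paste0(prefix, "_meta.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the full in-silico estimation experiment
#'
#' Forward-simulates the protocol, runs the square-root cubature Kalman
#' filter on the noisy measurements and inputs, and reports RMS errors of
#' the angle, angular-rate and reconstructed-torque estimates against the
#' simulation truth.
#'
#' @param model A [lower_limb_model()].
#' @param protocol A [sim_protocol()].
#' @param control An [sckf_control()].
#' @param seed Optional RNG seed.
#' @param report_file Optional path: write the error report as JSON.
#' @return List of class `estimation_report`: the fitted `ankle_sckf`
#'   object plus RMS error summaries (`rms_angle_deg`, `rms_rate`,
#'   `rms_torque`).
#' @export
run_estimation_experiment <- function(model, protocol = sim_protocol(),
                                      control = sckf_control(), seed = NULL,
                                      report_file = NULL) {
  if (!is.null(seed)) set.seed(seed)
  record <- forward_simulate(model, protocol)
  fit <- ankle_sckf(record, model, control)
  s <- summary(fit)
  out <- structure(list(fit = fit, record = record,
                        rms_angle_deg = s$rms_angle_deg,
                        rms_rate = s$rms_rate,
                        rms_torque = s$rms_torque),
                   class = "estimation_report")
  if (!is.null(report_file)) {
    jsonlite::write_json(
      list(rms_angle_deg = as.list(s$rms_angle_deg),
           rms_rate = as.list(s$rms_rate),
           rms_torque = as.list(s$rms_torque),
           clamp_events = s$clamp_events,
           n_steps = s$n, rate = s$rate),
      report_file, auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.estimation_report <- function(x, ...) {
  cat("In-silico estimation experiment\n")
  cat(sprintf("  angle RMS error [deg]:  knee %.3f, ankle %.3f\n",
              x$rms_angle_deg[1], x$rms_angle_deg[2]))
  cat(sprintf("  rate RMS error [rad/s]: knee %.3f, ankle %.3f\n",
              x$rms_rate[1], x$rms_rate[2]))
  cat(sprintf("  torque RMS error [N m]: knee %.3f, ankle %.3f\n",
              x$rms_torque[1], x$rms_torque[2]))
  invisible(x)
}
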