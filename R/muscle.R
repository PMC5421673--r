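# Activation dynamics and rigid-tendon Hill-type contraction dynamics.
#
# Each muscle contributes two states: the activation a in [0,1] and the
# normalised isometric force Fbar_isom >= 0.  Six muscles (RF, HAMS, VM,
# GAS, SOL, TA) give the 12-dimensional muscle state block of the model.

MUSCLES <- c("RF", "HAMS", "VM", "GAS", "SOL", "TA")

#' Muscle parameter set
#'
#' Bundles the Hill-model and activation-dynamics constants of one muscle.
#' Force-length is Gaussian in normalised fibre length, force-velocity is the
#' classic hyperbolic characteristic with an eccentric plateau, and the tendon
#' is rigid (constant slack length), so the fibre carries all MTC length
#' change.
#'
#' @param F_max Maximal isometric force (N).
#' @param l_opt Optimal fibre length (m).
#' @param v_max Maximal shortening velocity (m/s); default `10 * l_opt` per
#'   second.
#' @param tau_act,tau_deact Activation / deactivation time constants (s);
#'   activation must be the faster of the two.
#' @param tau_c Contraction-dynamics time constant (s).
#' @param fl_width Width of the Gaussian force-length curve (dimensionless).
#' @param af Hill force-velocity shape parameter.
#' @param f_ecc Eccentric force plateau (multiple of isometric force).
#' @return A list of class `muscle_params`.
#' @export
muscle_params <- function(F_max, l_opt, v_max = 10 * l_opt,
                          tau_act = 0.015, tau_deact = 0.05, tau_c = 0.04,
                          fl_width = 0.45, af = 0.25, f_ecc = 1.5) {
  stopifnot(F_max > 0, l_opt > 0, v_max > 0,
            tau_act > 0, tau_deact > 0, tau_act <= tau_deact, tau_c > 0)
  structure(list(F_max = F_max, l_opt = l_opt, v_max = v_max,
                 tau_act = tau_act, tau_deact = tau_deact, tau_c = tau_c,
                 fl_width = fl_width, af = af, f_ecc = f_ecc),
            class = "muscle_params")
}

#' Activation dynamics
#'
#' First-order bilinear excitation-to-activation lag with a shorter time
#' constant during activation than deactivation.  The effective rate constant
#' interpolates between `1/tau_act` (s = 1) and `1/tau_deact` (s = 0), so the
#' fixed point is `a = s` for any constant envelope `s`.
#'
#' @param a Current activation in `[0, 1]`.
#' @param s EMG envelope sample in `[0, 1]`.
#' @param params A [muscle_params()] object.
#' @return Time derivative `da/dt` (1/s).
#' @export
activation_rate <- function(a, s, params) {
  if (any(s < 0 | s > 1)) stop("EMG envelope outside [0, 1]", call. = FALSE)
  (s / params$tau_act + (1 - s) / params$tau_deact) * (s - a)
}

# Gaussian active force-length characteristic, 1 at the optimal fibre length
force_length <- function(l_norm, params) {
  exp(-((l_norm - 1) / params$fl_width)^2)
}

# Hyperbolic force-velocity characteristic; v_norm = v_M / v_max,
# positive = lengthening.  Monotone non-decreasing in v_norm, 1 at zero,
# 0 at -1 (maximal shortening), saturating at f_ecc for fast lengthening.
force_velocity <- function(v_norm, params) {
  if (length(v_norm) == 1L) {
    if (v_norm <= 0) {
      v <- if (v_norm < -1) -1 else v_norm
      return((1 + v) / (1 - v / params$af))
    }
    b <- 0.15
    return((1 + params$f_ecc * v_norm / b) / (1 + v_norm / b))
  }
  out <- numeric(length(v_norm))
  sh <- v_norm <= 0
  vs <- pmax(v_norm[sh], -1)
  out[sh] <- (1 + vs) / (1 - vs / params$af)
  if (any(!sh)) {
    vl <- v_norm[!sh]
    b <- 0.15
    out[!sh] <- (1 + params$f_ecc * vl / b) / (1 + vl / b)
  }
  out
}

#' Contraction dynamics
#'
#' Drives the normalised isometric force state toward the current
#' activation-scaled force-length capacity, `a * f_l(l_M / l_opt)`, with a
#' first-order lag.  Rest (`a = 0`, zero force) is an equilibrium; under
#' constant activation at the optimal fibre length the state converges to the
#' activation itself.
#'
#' @param F_isom_bar Normalised isometric force state (>= 0).
#' @param a Activation in `[0, 1]`.
#' @param l_M Fibre length (m).
#' @param v_M Fibre velocity (m/s) — not used by the first-order capacity
#'   tracking itself but part of the muscle-state interface.
#' @param params A [muscle_params()].
#' @return Time derivative of the normalised isometric force (1/s).
#' @export
contraction_rate <- function(F_isom_bar, a, l_M, v_M, params) {
  target <- a * force_length(l_M / params$l_opt, params)
  (target - F_isom_bar) / params$tau_c
}

#' Tendon force
#'
#' With a rigid tendon the tendon force equals the fibre force along the
#' tendon: the maximal isometric force scaled by the normalised isometric
#' force state and the force-velocity characteristic.  Passive joint
#' elasticity and viscosity are modelled at joint level, not here, so the
#' force is zero at zero activation state.
#'
#' @inheritParams contraction_rate
#' @return Tendon force (N), non-negative.
#' @export
tendon_force <- function(F_isom_bar, a, l_M, v_M, params) {
  f <- params$F_max * F_isom_bar * force_velocity(v_M / params$v_max, params)
  if (length(f) == 1L) {
    if (f < 0) 0 else f
  } else {
    pmax(0, f)
  }
}

#' Default muscle parameter table
#'
#' Plausible literature-style values for the six modelled muscles (maximal
#' isometric forces, optimal fibre lengths, pennation handled in the paths).
#' These are configurable placeholders, not canonical constants.
#'
#' @return Named list of [muscle_params()] keyed by muscle name.
#' @export
default_muscle_params <- function() {
  list(
    RF   = muscle_params(F_max = 1200, l_opt = 0.081),
    HAMS = muscle_params(F_max = 1300, l_opt = 0.100),
    VM   = muscle_params(F_max = 1400, l_opt = 0.090),
    GAS  = muscle_params(F_max = 1500, l_opt = 0.055),
    SOL  = muscle_params(F_max = 3500, l_opt = 0.040),
    TA   = muscle_params(F_max = 900,  l_opt = 0.070)
  )
}
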