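# Joint-torque reconstruction from estimated states and ankle
# quasi-stiffness: the product-rule derivative of the active ankle torque
# with respect to the ankle angle at frozen muscle states.

#' Reconstruct joint torques from a (estimated) state
#'
#' Evaluates the model's torque composition — active muscle torques through
#' the moment-arm tables, passive elastic and viscous torques and external
#' (ground-reaction) torques — at the given state and input.
#'
#' @param x State vector (length 16).
#' @param u Input vector (length 15).
#' @param model A [lower_limb_model()].
#' @param components Torque contributions to include.
#' @return Named numeric `c(knee, ankle)` torque (N m).
#' @export
reconstruct_torque <- function(x, u, model,
                               components = c("active", "elastic",
                                              "viscous", "external")) {
  fr <- .model_forces(x, u, model, components)
  c(knee = fr$tau[1], ankle = fr$tau[2])
}

# active ankle torque at frozen muscle states (helper for the stiffness
# derivative): angles enter through the moment arms and, via the fibre
# velocity, through the force-velocity characteristic
.active_ankle_torque <- function(x, u, model) {
  fr <- .model_forces(x, u, model, components = "active")
  active_torque(fr$r_ankle, fr$FT)
}

#' Ankle quasi-stiffness from the model state
#'
#' Product-rule evaluation of \eqn{\kappa_{ankle} = \partial \tau^T_{ankle} /
#' \partial \varphi_{ankle} = \sum_i (\partial r_{ma_i}/\partial \varphi)
#' F_i^T + r_{ma_i} (\partial F_i^T/\partial \varphi)} over the ankle
#' muscles.  The moment-arm derivative is analytic (from the fitted quartic
#' table); the tendon-force derivative is evaluated by central perturbation
#' of the ankle angle with the muscle activation and normalised-force states
#' frozen — quasi-stiffness is an instantaneous mechanical property, not a
#' closed-loop one.  The passive elastic torque derivative is reported as a
#' separate additive component.
#'
#' @param x State vector (length 16).
#' @param u Input vector (length 15).
#' @param model A [lower_limb_model()].
#' @param h Ankle-angle perturbation step (rad).
#' @return Named numeric with `active`, `passive` and `total` stiffness
#'   (N m/rad).
#' @export
quasi_stiffness <- function(x, u, model, h = 1e-4) {
  q <- c(hip = u[[7]], knee = x[[1]], ankle = x[[2]])
  rates <- c(hip = u[[8]], knee = x[[3]], ankle = x[[4]])
  Fb <- unname(pmax(x[11:16], 0))
  x <- unname(x)
  kappa <- 0
  for (i in seq_along(MUSCLES)) {
    mus <- MUSCLES[i]
    tabl <- model$tables[[mus]]
    if (is.null(tabl$lever$ankle)) next
    path <- model$paths[[mus]]
    par <- model$muscle_params[[mus]]
    r <- .table_eval(tabl$lever$ankle, q, clamp = TRUE)
    dr <- .table_eval(tabl$lever$ankle, q, deriv = "ankle", clamp = TRUE)
    FT_at <- function(phi) {
      qq <- q; qq[["ankle"]] <- phi
      v <- 0
      for (jn in tabl$length$vars)
        v <- v + rates[[jn]] * .table_eval(tabl$length, qq, deriv = jn,
                                           clamp = TRUE)
      v_M <- v / cos(path$alpha_p)
      l_M <- (.table_eval(tabl$length, qq, clamp = TRUE) - path$l_T) /
        cos(path$alpha_p)
      tendon_force(Fb[i], x[4 + i], l_M, v_M, par)
    }
    dF <- (FT_at(q[["ankle"]] + h) - FT_at(q[["ankle"]] - h)) / (2 * h)
    kappa <- kappa + dr * FT_at(q[["ankle"]]) + r * dF
  }
  pa <- model$passive$ankle
  d_passive <- pa$c1a * .safe_exp(pa$a1a + pa$b1a * q[["knee"]] +
                                    pa$c1a * q[["ankle"]]) -
    pa$c2a * .safe_exp(pa$a2a + pa$b2a * q[["knee"]] + pa$c2a * q[["ankle"]])
  c(active = kappa, passive = d_passive, total = kappa + d_passive)
}

#' Quasi-stiffness time series from an SCKF fit
#'
#' @param fit An `ankle_sckf` fit.
#' @param h Perturbation step (rad).
#' @return Object of class `stiffness_series`: data frame with `time`,
#'   `kappa_active`, `kappa_passive`, `kappa_total` (N m/rad) and the
#'   companion ankle torque.
#' @export
quasi_stiffness_series <- function(fit, h = 1e-4) {
  N <- length(fit$time)
  K <- matrix(0, N, 3)
  for (k in seq_len(N))
    K[k, ] <- quasi_stiffness(fit$estimates[k, ], fit$record$u[k, ],
                              fit$model, h)
  structure(data.frame(time = fit$time,
                       kappa_active = K[, 1], kappa_passive = K[, 2],
                       kappa_total = K[, 3],
                       tau_ankle = fit$torque[, 2]),
            class = c("stiffness_series", "data.frame"))
}

#' Moving-average smoothing of a stiffness series
#'
#' The raw quasi-stiffness series can exhibit short unphysiological peaks
#' driven by noisy EMG input; a moving average yields the physiologically
#' interpretable mean stiffness while the raw series is retained for
#' inspection.
#'
#' @param series A `stiffness_series` (or any data frame with `kappa_*`
#'   columns).
#' @param window Window length in samples (odd values centre exactly;
#'   `window = 1` is the identity).
#' @return The series with additional `*_smooth` columns.
#' @export
smooth_stiffness <- function(series, window = 51) {
  stopifnot(window >= 1)
  ma <- function(v) {
    if (window == 1) return(v)
    sm <- stats::filter(v, rep(1 / window, window), sides = 2)
    # fill edge NAs with shrinking one-sided windows
    idx <- which(is.na(sm))
    half <- (window - 1) %/% 2
    for (i in idx) {
      lo <- max(1, i - half); hi <- min(length(v), i + half)
      sm[i] <- mean(v[lo:hi])
    }
    as.numeric(sm)
  }
  for (col in intersect(c("kappa_active", "kappa_passive", "kappa_total"),
                        names(series)))
    series[[paste0(col, "_smooth")]] <- ma(series[[col]])
  series
}

#' Antagonist-coactivation stiffness sweep
#'
#' Holds the joint configuration fixed, ramps the ankle antagonist pair
#' (dorsiflexor TA against plantar flexors SOL and GAS) jointly through a
#' scale sequence, and evaluates the quasi-stiffness and the net active
#' ankle torque at each level with muscle states set to their steady values.
#' Demonstrates the core property that coactivation raises joint stiffness
#' while changing the net torque comparatively little.
#'
#' @param model A [lower_limb_model()].
#' @param scales Increasing activation scale factors.
#' @param base Named base activation levels of the ramped muscles; the
#'   default ratio balances dorsiflexor and plantar-flexor torques at the
#'   default held posture so the net torque stays near zero as the drive
#'   ramps.
#' @param q Held joint configuration (radians, named).
#' @return Data frame with `scale`, `kappa_active`, `kappa_total`,
#'   `tau_active`.
#' @export
coactivation_sweep <- function(model, scales = seq(0.1, 1, by = 0.1),
                               base = c(TA = 0.60, SOL = 0.080, GAS = 0.077),
                               q = c(hip = 0, knee = -0.2, ankle = -0.1)) {
  out <- data.frame(scale = scales, kappa_active = NA_real_,
                    kappa_total = NA_real_, tau_active = NA_real_)
  for (r in seq_along(scales)) {
    a <- numeric(6); names(a) <- MUSCLES
    a[names(base)] <- pmin(scales[r] * base, 1)
    x <- numeric(16)
    x[1] <- q[["knee"]]; x[2] <- q[["ankle"]]
    x[5:10] <- a
    # steady normalised force at held posture: Fbar = a * f_l
    for (i in seq_along(MUSCLES)) {
      mus <- MUSCLES[i]
      lmt <- .table_eval(model$tables[[mus]]$length, .full_q(q), clamp = TRUE)
      l_M <- (lmt - model$paths[[mus]]$l_T) / cos(model$paths[[mus]]$alpha_p)
      x[10 + i] <- a[mus] *
        force_length(l_M / model$muscle_params[[mus]]$l_opt,
                     model$muscle_params[[mus]])
    }
    u <- numeric(15)
    u[1:6] <- a; u[7] <- q[["hip"]]
    ks <- quasi_stiffness(x, u, model)
    out$kappa_active[r] <- ks[["active"]]
    out$kappa_total[r] <- ks[["total"]]
    out$tau_active[r] <- .active_ankle_torque(x, u, model)
  }
  out
}
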