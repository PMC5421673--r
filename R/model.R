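# Assembly of the full lower-extremity model object: ankle-axis geometry,
# muscle paths, segment anthropometry, passive joint-torque coefficients and
# the fitted polynomial geometry tables.
#
# All shipped numeric defaults (axis tilts, nodal points, passive-torque
# coefficients, muscle constants) are plausible literature-style values and
# are configurable — they are NOT canonical constants of any particular
# subject or source.  Anthropometry is scaled from body mass and height with
# de Leva-style relative segment data.

#' Default segment anthropometry from body mass and height
#'
#' Relative segment masses, lengths, centre-of-mass positions and radii of
#' gyration follow de Leva-style adjusted Zatsiorsky data for adult males.
#'
#' @param body_mass Body mass (kg).
#' @param body_height Body height (m).
#' @return Named list of [segment_params()] for `thigh`, `shank`, `foot`.
#' @export
default_segment_params <- function(body_mass = 79.2, body_height = 1.816) {
  L_th <- 0.2425 * body_height
  L_sh <- 0.2465 * body_height
  L_ft <- 0.1475 * body_height
  m_th <- 0.1416 * body_mass
  m_sh <- 0.0433 * body_mass
  m_ft <- 0.0137 * body_mass
  list(
    thigh = segment_params(m_th, L_th, com = 0.4095 * L_th,
                           inertia = m_th * (0.329 * L_th)^2),
    shank = segment_params(m_sh, L_sh, com = 0.4459 * L_sh,
                           inertia = m_sh * (0.255 * L_sh)^2),
    foot  = segment_params(m_ft, L_ft, com = c(0.25 * L_ft, -0.18 * L_ft),
                           inertia = m_ft * (0.257 * L_ft)^2)
  )
}

#' Default passive joint-torque coefficients
#'
#' Exponential elastic characteristics for knee and ankle (with biarticular
#' coupling to the neighbouring joints) and power-law viscous damping.
#' Exponential slopes are per radian; magnitudes give a few N m in mid-range
#' and a few tens of N m at the range limits.  Sign convention: positive
#' torque increases the joint angle (knee flexion is negative, ankle
#' dorsiflexion positive).
#'
#' @return List with elements `knee`, `ankle` (elastic coefficient lists) and
#'   `viscous` (per-joint `K_V`, `n_V`).
#' @export
default_passive_params <- function() {
  list(
    knee = list(a1k = 0.5, b1k = 0.35, c1k = -1.8, d1k = -0.5,
                a2k = -2.0, b2k = -0.3, c2k = 1.5, d2k = 0.1,
                ek = -1.0, fk = 1.0, gk = 14.0),
    ankle = list(a1a = -0.3, b1a = -0.2, c1a = -4.0,
                 a2a = -2.0, b2a = 1.0, c2a = 12.0, da = -0.15),
    viscous = list(knee = list(K_V = 1.2, n_V = 1.0),
                   ankle = list(K_V = 0.8, n_V = 1.0))
  )
}

#' Default muscle-path nodal points
#'
#' Line-segment muscle paths for the six modelled muscles.  Nodal-point
#' coordinates (metres, segment frames) are plausible placeholder values in
#' the style of musculoskeletal geometry datasets; the tibialis anterior is
#' guided by a retinaculum pair defining its effective origin and contact
#' point, and the gastrocnemius is biarticular over knee and ankle.
#'
#' @param L_shank Shank length (m) used to place distal shank nodal points.
#' @return Named list of [muscle_path()] objects.
#' @export
default_muscle_paths <- function(L_shank = 0.4476) {
  pt <- function(frame, x, y, z = 0) list(frame = frame, p = c(x, y, z))
  yd <- L_shank  # distal shank y-offset
  list(
    RF = muscle_path("RF",
      points = list(pt("pelvis", 0.030, 0.030),
                    pt("thigh", 0.040, -0.360),
                    pt("shank", 0.050, 0.025),   # patellar pulley point
                    pt("shank", 0.040, -0.070)),
      lever_line = c(2, 3), joints = c(knee = 1),
      drives = c("hip", "knee"), alpha_p = 0.09),
    HAMS = muscle_path("HAMS",
      points = list(pt("pelvis", -0.060, 0.000),
                    pt("shank", -0.025, -0.060)),
      lever_line = c(1, 2), joints = c(knee = -1),
      drives = c("hip", "knee"), alpha_p = 0.0),
    VM = muscle_path("VM",
      points = list(pt("thigh", 0.025, -0.250),
                    pt("thigh", 0.040, -0.360),
                    pt("shank", 0.050, 0.025),   # patellar pulley point
                    pt("shank", 0.040, -0.070)),
      lever_line = c(2, 3), joints = c(knee = 1),
      drives = "knee", alpha_p = 0.09),
    GAS = muscle_path("GAS",
      points = list(pt("thigh", -0.025, -0.420),
                    pt("foot", -0.050, -0.050)),
      lever_line = c(1, 2), joints = c(knee = -1, ankle = -1),
      drives = c("knee", "ankle"), alpha_p = 0.30),
    SOL = muscle_path("SOL",
      points = list(pt("shank", -0.025, -0.100),
                    pt("foot", -0.050, -0.050)),
      lever_line = c(1, 2), joints = c(ankle = -1),
      drives = "ankle", alpha_p = 0.44),
    TA = muscle_path("TA",
      points = list(pt("shank", 0.020, -0.080),
                    pt("shank", 0.035, -(yd - 0.055)),
                    pt("foot", 0.035, -0.045, -0.010),
                    pt("foot", 0.055, -0.055, -0.015)),
      lever_line = c(2, 3), joints = c(ankle = 1),
      drives = "ankle", alpha_p = 0.09)
  )
}

#' Build the full lower-extremity model
#'
#' Assembles geometry, muscle paths, muscle parameters, segment inertial
#' parameters and passive torque coefficients, fits the fourth-order
#' polynomial geometry tables over the admissible joint ranges, and derives
#' rigid-tendon slack lengths so every muscle sits near its optimal fibre
#' length in a mid-range reference posture.
#'
#' @param body_mass,body_height Anthropometric scaling inputs (kg, m).
#' @param geom An [ankle_axis_geometry()]; default ties the malleolar offset
#'   to the shank length.
#' @param paths Muscle paths, default [default_muscle_paths()].
#' @param muscle_params Named list of [muscle_params()].
#' @param segments Named list of [segment_params()].
#' @param passive Passive torque coefficients, default
#'   [default_passive_params()].
#' @param g Gravitational acceleration (m/s^2).
#' @param grid_step Geometry-table grid increment (degrees).
#' @param q_ref Reference posture (radians) at which tendon slack lengths are
#'   calibrated so the fibre is at its optimal length.
#' @return An object of class `lower_limb_model`.
#' @export
lower_limb_model <- function(body_mass = 79.2, body_height = 1.816,
                             geom = NULL, paths = NULL,
                             muscle_params = default_muscle_params(),
                             segments = default_segment_params(body_mass,
                                                               body_height),
                             passive = default_passive_params(),
                             g = 9.81, grid_step = 1,
                             q_ref = c(hip = 0, knee = -0.3, ankle = -0.1)) {
  if (is.null(geom))
    geom <- ankle_axis_geometry(y_trans = -segments$shank$length)
  if (is.null(paths))
    paths <- default_muscle_paths(L_shank = segments$shank$length)
  stopifnot(setequal(names(paths), MUSCLES),
            setequal(names(muscle_params), MUSCLES))
  L_thigh <- segments$thigh$length

  tables <- lapply(paths[MUSCLES], fit_geometry_polynomials,
                   geom = geom, L_thigh = L_thigh, step = grid_step)

  # rigid-tendon slack length: l_T = l_MT(q_ref) - l_opt * cos(alpha_p)
  for (mus in MUSCLES) {
    if (is.na(paths[[mus]]$l_T)) {
      lmt_ref <- .table_eval(tables[[mus]]$length, q_ref, clamp = TRUE)
      paths[[mus]]$l_T <- lmt_ref -
        muscle_params[[mus]]$l_opt * cos(paths[[mus]]$alpha_p)
    }
  }

  model <- list(geom = geom, paths = paths, muscle_params = muscle_params,
                segments = segments, passive = passive, g = g,
                tables = tables,
                meta = list(body_mass = body_mass, body_height = body_height,
                            grid_step = grid_step, q_ref = q_ref))
  class(model) <- "lower_limb_model"
  model
}

#' @export
print.lower_limb_model <- function(x, ...) {
  cat("Sagittal-plane lower-extremity model (EMG-driven, 16 states)\n")
  cat(sprintf("  segments: thigh %.3f m / %.1f kg, shank %.3f m / %.1f kg, foot %.3f m / %.1f kg\n",
              x$segments$thigh$length, x$segments$thigh$mass,
              x$segments$shank$length, x$segments$shank$mass,
              x$segments$foot$length, x$segments$foot$mass))
  cat(sprintf("  ankle axis: alpha_TC_tla %.1f deg, alpha_TC_fml %.1f deg\n",
              x$geom$alpha_TC_tla, x$geom$alpha_TC_fml))
  res <- vapply(x$tables, function(t) t$length$max_resid, 0)
  cat(sprintf("  geometry tables (quartic, %g deg grid): max length fit residual %.2e m\n",
              x$meta$grid_step, max(res)))
  cat("  muscles:", paste(MUSCLES, collapse = ", "), "\n")
  invisible(x)
}

## ---- configuration file I/O ------------------------------------------------

#' Write a model configuration to YAML
#'
#' Serialises the numeric configuration of a model (angles in degrees,
#' lengths in metres) so it can be edited and re-read with
#' [read_model_config()].  The fitted tables are not stored; they are rebuilt
#' on loading.
#'
#' @param model A `lower_limb_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  cfg <- list(
    body_mass = model$meta$body_mass,
    body_height = model$meta$body_height,
    g = model$g,
    ankle_axis = list(alpha_TC_tla = model$geom$alpha_TC_tla,
                      alpha_TC_fml = model$geom$alpha_TC_fml,
                      x_trans = model$geom$x_trans,
                      y_trans = model$geom$y_trans),
    segments = lapply(model$segments, function(s)
      list(mass = s$mass, length = s$length, com = as.numeric(s$com),
           inertia = s$inertia)),
    passive = model$passive,
    muscles = lapply(MUSCLES, function(m) {
      p <- model$paths[[m]]; mp <- model$muscle_params[[m]]
      list(name = m,
           points = lapply(p$points, function(pt)
             list(frame = pt$frame, p = as.numeric(pt$p))),
           lever_line = as.integer(p$lever_line),
           joints = as.list(p$joints),
           drives = p$drives,
           alpha_p_deg = p$alpha_p * 180 / pi,
           l_T = p$l_T,
           F_max = mp$F_max, l_opt = mp$l_opt, v_max = mp$v_max,
           tau_act = mp$tau_act, tau_deact = mp$tau_deact, tau_c = mp$tau_c)
    })
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a model configuration from YAML and rebuild the model
#'
#' @param path YAML file written by [write_model_config()] (or hand-edited in
#'   the same layout).
#' @param grid_step Geometry grid increment (degrees) for table refitting.
#' @return A `lower_limb_model`.
#' @export
read_model_config <- function(path, grid_step = 1) {
  cfg <- yaml::read_yaml(path)
  geom <- ankle_axis_geometry(cfg$ankle_axis$alpha_TC_tla,
                              cfg$ankle_axis$alpha_TC_fml,
                              cfg$ankle_axis$x_trans,
                              cfg$ankle_axis$y_trans)
  segments <- lapply(cfg$segments, function(s)
    segment_params(s$mass, s$length,
                   if (length(s$com) == 2) as.numeric(s$com) else s$com,
                   s$inertia))
  paths <- list(); mpars <- list()
  for (mc in cfg$muscles) {
    paths[[mc$name]] <- muscle_path(
      mc$name,
      points = lapply(mc$points, function(pt)
        list(frame = pt$frame, p = as.numeric(pt$p))),
      lever_line = mc$lever_line,
      joints = unlist(mc$joints),
      drives = mc$drives,
      alpha_p = mc$alpha_p_deg * pi / 180,
      l_T = if (is.null(mc$l_T)) NA_real_ else mc$l_T)
    mpars[[mc$name]] <- muscle_params(mc$F_max, mc$l_opt, mc$v_max,
                                      mc$tau_act, mc$tau_deact, mc$tau_c)
  }
  lower_limb_model(body_mass = cfg$body_mass, body_height = cfg$body_height,
                   geom = geom, paths = paths, muscle_params = mpars,
                   segments = segments, passive = cfg$passive, g = cfg$g,
                   grid_step = grid_step)
}
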