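# Sagittal-plane musculoskeletal geometry: frames, the tilted talocrural
# rotation axis, muscle paths, moment arms and polynomial geometry tables.
#
# Conventions (used throughout the package):
#   * global frame at the hip: x anterior, y superior, z mediolateral (right);
#     the sagittal projection drops z.
#   * joint angles in radians internally; degrees in configuration files.
#   * hip flexion positive, range (-20, 150) deg;
#     knee flexion NEGATIVE (0 = full extension, +10 deg physiological
#     hyperextension allowance), range (-120, 10) deg;
#     ankle dorsiflexion positive, range (-60, 20) deg.
#   * segment frames: origin at the proximal joint, axes aligned with the
#     global frame at upright standing (all angles zero).

JOINTS <- c("hip", "knee", "ankle")

JOINT_RANGES <- list(
  hip   = c(-20, 150) * pi / 180,
  knee  = c(-120, 10) * pi / 180,
  ankle = c(-60, 20) * pi / 180
)

#' Ankle rotation-axis geometry
#'
#' Describes the single fixed talocrural (TC) hinge axis: its inclination
#' against the tibia axis (`alpha_TC_tla`, frontal plane) and against the foot
#' mid-line (`alpha_TC_fml`, transverse plane), plus the position of the foot
#' frame origin (between the malleoli) in the shank/knee frame.  The derived
#' tilt angles are `beta = alpha_TC_fml - 90` and `gamma = 90 - alpha_TC_tla`.
#'
#' The default numeric values are plausible literature-style placeholders
#' (axis inclined roughly 80 deg to the tibia and 84 deg to the foot
#' mid-line); they are configuration data, not canonical constants.
#'
#' @param alpha_TC_tla Angle between tibia axis and rotation axis (degrees).
#' @param alpha_TC_fml Angle between foot mid-line and rotation axis (degrees).
#' @param x_trans,y_trans Origin of the foot frame in the knee (shank) frame
#'   (metres).
#' @return An object of class `ankle_axis_geometry` with fields
#'   `alpha_TC_tla`, `alpha_TC_fml`, `beta`, `gamma` (radians) and the
#'   translation components.
#' @export
ankle_axis_geometry <- function(alpha_TC_tla = 80, alpha_TC_fml = 84,
                                x_trans = 0, y_trans = -0.43) {
  stopifnot(is.finite(alpha_TC_tla), is.finite(alpha_TC_fml))
  g <- list(
    alpha_TC_tla = alpha_TC_tla,
    alpha_TC_fml = alpha_TC_fml,
    beta  = (alpha_TC_fml - 90) * pi / 180,
    gamma = (90 - alpha_TC_tla) * pi / 180,
    x_trans = x_trans,
    y_trans = y_trans
  )
  class(g) <- "ankle_axis_geometry"
  g
}

.rot_z <- function(phi) {
  c_ <- cos(phi); s_ <- sin(phi)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
}
.rot_y <- function(phi) {
  c_ <- cos(phi); s_ <- sin(phi)
  matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3)
}
.rot_x <- function(phi) {
  c_ <- cos(phi); s_ <- sin(phi)
  matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3)
}

#' Homogeneous foot-to-knee transform
#'
#' Maps homogeneous foot-frame coordinates into the knee (shank) frame for a
#' given ankle angle.  The rotation about the body-fixed foot axis `z_foot` is
#' composed with the fixed axis tilts `beta` (about y) and `gamma` (about x)
#' and the malleolar translation, so that at `phi_ankle = 0` only the fixed
#' tilt and translation remain.
#'
#' @param phi_ankle Ankle angle (radians, dorsiflexion positive).
#' @param geom An [ankle_axis_geometry()] object.
#' @param clamp If `TRUE`, out-of-range angles are clamped to the admissible
#'   range instead of raising an error (used inside the filter loop where
#'   cubature points may transiently leave the range).
#' @return A 4x4 homogeneous transformation matrix.
#' @export
foot_transform <- function(phi_ankle, geom, clamp = FALSE) {
  phi_ankle <- check_joint_angle(phi_ankle, "ankle", clamp = clamp)
  .foot_transform_raw(phi_ankle, geom)
}

.foot_transform_raw <- function(phi_ankle, geom) {
  R <- .rot_y(geom$beta) %*% .rot_x(geom$gamma) %*% .rot_z(phi_ankle)
  T <- diag(4)
  T[1:3, 1:3] <- R
  T[1:2, 4] <- c(geom$x_trans, geom$y_trans)
  T
}

#' Validate (or clamp) a joint angle against its admissible range
#'
#' @param phi Angle(s) in radians.
#' @param joint One of `"hip"`, `"knee"`, `"ankle"`.
#' @param clamp Clamp instead of erroring.
#' @return The (possibly clamped) angle.
#' @export
check_joint_angle <- function(phi, joint = c("ankle", "knee", "hip"),
                              clamp = FALSE) {
  joint <- match.arg(joint)
  rng <- JOINT_RANGES[[joint]]
  out <- phi < rng[1] | phi > rng[2]
  if (any(out)) {
    if (!clamp) {
      stop(sprintf("%s angle %.1f deg outside admissible range (%.0f, %.0f) deg",
                   joint, phi[which(out)[1]] * 180 / pi,
                   rng[1] * 180 / pi, rng[2] * 180 / pi), call. = FALSE)
    }
    phi <- pmin(pmax(phi, rng[1]), rng[2])
  }
  phi
}

#' Project a 3-D global point into the sagittal plane
#'
#' Drops the mediolateral (z) coordinate of the global frame.
#'
#' @param p Numeric 3-vector, or a 3-row matrix of points.
#' @return A 2-vector (or 2-row matrix).
#' @export
project_sagittal <- function(p) {
  if (is.matrix(p)) p[1:2, , drop = FALSE] else p[1:2]
}

#' Muscle moment arm as distance from the rotation centre to the line of action
#'
#' The effective direction of a muscle's force is the straight line through
#' the sagittal projections of its (effective) origin and (effective) contact
#' point; the moment arm is the perpendicular distance of the projected
#' rotation centre from that line — always non-negative.
#'
#' @param p_ic Projected rotation centre (2-vector).
#' @param p_o Projected (effective) origin (2-vector).
#' @param p_i Projected (effective) contact/insertion point (2-vector).
#' @return Moment arm in metres (non-negative scalar).
#' @export
lever_arm <- function(p_ic, p_o, p_i) {
  d <- p_i - p_o
  nd <- sqrt(sum(d^2))
  if (nd < 1e-12)
    stop("degenerate line of action: origin and contact point coincide",
         call. = FALSE)
  v <- p_ic - p_o
  abs(v[1] * d[2] - v[2] * d[1]) / nd
}

#' Instantaneous centre of rotation from a small angle change
#'
#' Tracks two (or more) foot-fixed points over a small ankle rotation
#' `delta_phi`, projects their displacements into the sagittal plane, and
#' intersects the perpendicular bisectors of the displacement chords.  For the
#' tilted TC axis the projected centre migrates with the ankle angle; for a
#' pure planar rotation the true centre is recovered exactly.
#'
#' @param phi_ankle Ankle angle (radians).
#' @param delta_phi Small probe rotation (radians), non-zero.
#' @param geom An [ankle_axis_geometry()].
#' @param path_points 3 x m matrix (m >= 2) of tracked foot-frame points.
#' @param clamp Clamp out-of-range angles.
#' @return Sagittal 2-vector of the centre, in knee-frame coordinates.
#' @export
instantaneous_centre <- function(phi_ankle, delta_phi = 0.5 * pi / 180, geom,
                                 path_points = cbind(c(0.10, -0.02, 0),
                                                     c(-0.05, -0.05, 0)),
                                 clamp = FALSE) {
  stopifnot(delta_phi != 0, ncol(path_points) >= 2)
  phi_ankle <- check_joint_angle(phi_ankle, "ankle", clamp = clamp)
  T0 <- .foot_transform_raw(phi_ankle, geom)
  # the probe rotation is a virtual displacement; never range-checked
  T1 <- .foot_transform_raw(phi_ankle + delta_phi, geom)
  ph <- rbind(path_points, 1)
  a <- (T0 %*% ph)[1:2, , drop = FALSE]
  b <- (T1 %*% ph)[1:2, , drop = FALSE]
  mid <- (a + b) / 2
  chord <- b - a
  # bisector of chord j: points x with chord_j . (x - mid_j) = 0
  A <- t(chord[, 1:2])
  rhs <- c(sum(chord[, 1] * mid[, 1]), sum(chord[, 2] * mid[, 2]))
  if (abs(det(A)) < 1e-14)
    stop("perpendicular bisectors are parallel: no finite rotation centre",
         call. = FALSE)
  drop(solve(A, rhs))
}

## ---- muscle paths ----------------------------------------------------------

#' Define a muscle path as frame-tagged line segments
#'
#' A muscle-tendon complex is approximated by straight line segments through
#' ordered nodal points (origin, via/retinaculum points, insertion), each
#' expressed in a body frame (`"pelvis"`, `"thigh"`, `"shank"`, `"foot"`).
#' The line of action used for moment arms runs through the effective origin
#' and effective contact point (nodal-point indices), which for retinaculum-
#' guided muscles such as the tibialis anterior differ from the anatomical
#' origin and insertion.
#'
#' @param name Muscle short name (e.g. `"TA"`).
#' @param points List of `list(frame = , p = c(x, y, z))` nodal points, in
#'   order from origin to insertion (metres).
#' @param lever_line Integer pair: indices of the effective origin and
#'   effective contact nodal points.
#' @param joints Named numeric vector of actuated joints with torque signs
#'   (+1 if the muscle's torque increases the joint angle).
#' @param drives Character vector of joints whose angles affect the path.
#' @param alpha_p Pennation angle (radians, in `[0, pi/2)`).
#' @param l_T Tendon slack length (metres); `NA` to derive it from a neutral
#'   posture when muscle parameters are attached.
#' @return An object of class `muscle_path`.
#' @export
muscle_path <- function(name, points, lever_line, joints, drives,
                        alpha_p = 0, l_T = NA_real_) {
  stopifnot(length(points) >= 2, alpha_p >= 0, alpha_p < pi / 2,
            length(lever_line) == 2, is.na(l_T) || l_T >= 0)
  frames <- vapply(points, `[[`, "", "frame")
  stopifnot(all(frames %in% c("pelvis", "thigh", "shank", "foot")))
  structure(list(name = name, points = points, lever_line = lever_line,
                 joints = joints, drives = drives, alpha_p = alpha_p,
                 l_T = l_T),
            class = "muscle_path")
}

# Vectorised mapping of one nodal point into global sagittal coordinates.
# q1, q2, q3 are equal-length (or scalar) vectors of hip/knee/ankle angles.
.point_xy <- function(p, frame, q1, q2, q3, geom, L_thigh) {
  x <- p[1]; y <- p[2]; z <- p[3]
  if (frame == "foot") {
    # rotate about the (tilted) foot axis, then fixed tilts + translation
    c3 <- cos(q3); s3 <- sin(q3)
    xr <- c3 * x - s3 * y
    yr <- s3 * x + c3 * y
    zr <- z
    cg <- cos(geom$gamma); sg <- sin(geom$gamma)
    y2 <- cg * yr - sg * zr
    z2 <- sg * yr + cg * zr
    cb <- cos(geom$beta); sb <- sin(geom$beta)
    x3 <- cb * xr + sb * z2
    # z dropped later; only x, y needed beyond this point
    x <- x3 + geom$x_trans
    y <- y2 + geom$y_trans
    frame <- "shank"
  }
  if (frame == "shank") {
    c2 <- cos(q2); s2 <- sin(q2)
    xs <- c2 * x - s2 * y
    ys <- s2 * x + c2 * y
    x <- xs
    y <- ys - L_thigh
    frame <- "thigh"
  }
  if (frame == "thigh") {
    c1 <- cos(q1); s1 <- sin(q1)
    xt <- c1 * x - s1 * y
    yt <- s1 * x + c1 * y
    x <- xt; y <- yt
  }
  n <- max(length(q1), length(q2), length(q3))
  list(x = rep_len(x, n), y = rep_len(y, n))
}

# All nodal points of a path in global sagittal coordinates (vectorised).
.path_xy <- function(path, q1, q2, q3, geom, L_thigh) {
  lapply(path$points, function(pt)
    .point_xy(pt$p, pt$frame, q1, q2, q3, geom, L_thigh))
}

#' Muscle-tendon complex length
#'
#' Sum of the Euclidean lengths of the sagittal-projected line segments of a
#' muscle path at a given joint configuration.
#'
#' @param path A [muscle_path()].
#' @param q Named numeric vector with elements `hip`, `knee`, `ankle`
#'   (radians); missing joints default to 0.
#' @param geom An [ankle_axis_geometry()].
#' @param L_thigh Thigh segment length (m).
#' @param clamp Clamp out-of-range angles.
#' @return MTC length in metres.
#' @export
mtc_length <- function(path, q, geom, L_thigh = 0.44, clamp = FALSE) {
  q <- .full_q(q)
  for (j in JOINTS) q[j] <- check_joint_angle(q[[j]], j, clamp = clamp)
  xy <- .path_xy(path, q[["hip"]], q[["knee"]], q[["ankle"]], geom, L_thigh)
  len <- 0
  for (i in seq_len(length(xy) - 1))
    len <- len + sqrt((xy[[i + 1]]$x - xy[[i]]$x)^2 +
                      (xy[[i + 1]]$y - xy[[i]]$y)^2)
  len
}

.full_q <- function(q) {
  out <- c(hip = 0, knee = 0, ankle = 0)
  if (is.null(names(q))) {
    out[seq_along(q)] <- q
  } else {
    out[names(q)] <- q
  }
  out
}

# Signed moment arm of `path` about `joint` at configuration q (scalar).
# Magnitude from the distance-to-line rule, sign from the path's convention.
.lever_arm_at <- function(path, joint, q, geom, L_thigh, delta_phi = 0.5 * pi / 180) {
  q <- .full_q(q)
  xy <- .path_xy(path, q[["hip"]], q[["knee"]], q[["ankle"]], geom, L_thigh)
  o <- xy[[path$lever_line[1]]]
  i <- xy[[path$lever_line[2]]]
  p_o <- c(o$x[1], o$y[1]); p_i <- c(i$x[1], i$y[1])
  p_ic <- .joint_centre_xy(joint, q, geom, L_thigh, delta_phi)
  unname(path$joints[joint]) * lever_arm(p_ic, p_o, p_i)
}

# Sagittal rotation-centre of a joint in global coordinates.  Hip and knee are
# fixed hinges at the frame origins; the ankle centre comes from the
# instantaneous-centre construction in the shank frame, mapped up the chain.
.joint_centre_xy <- function(joint, q, geom, L_thigh, delta_phi = 0.5 * pi / 180) {
  if (joint == "hip") return(c(0, 0))
  knee <- c(sin(q[["hip"]]), -cos(q[["hip"]])) * L_thigh
  if (joint == "knee") return(knee)
  pc <- instantaneous_centre(q[["ankle"]], delta_phi, geom, clamp = TRUE)
  c2 <- cos(q[["knee"]]); s2 <- sin(q[["knee"]])
  p_sh <- c(c2 * pc[1] - s2 * pc[2], s2 * pc[1] + c2 * pc[2] - L_thigh)
  c1 <- cos(q[["hip"]]); s1 <- sin(q[["hip"]])
  c(c1 * p_sh[1] - s1 * p_sh[2], s1 * p_sh[1] + c1 * p_sh[2])
}

## ---- polynomial geometry tables -------------------------------------------

.poly1_design <- function(x) outer(x, 0:4, `^`)

.poly2_exponents <- local({
  e <- expand.grid(i = 0:4, j = 0:4)
  e[e$i + e$j <= 4, ]
})

.poly2_design <- function(x, y) {
  e <- .poly2_exponents
  m <- matrix(0, length(x), nrow(e))
  for (k in seq_len(nrow(e))) m[, k] <- x^e$i[k] * y^e$j[k]
  m
}

.poly2_ei <- as.integer(.poly2_exponents$i)
.poly2_ej <- as.integer(.poly2_exponents$j)

.fit_poly <- function(design, values) {
  fit <- stats::lm.fit(design, values)
  list(coef = unname(fit$coefficients),
       max_resid = max(abs(fit$residuals)))
}

# Horner evaluation of a 1-D quartic and its derivative
.polyval1 <- function(coef, x) {
  ((((coef[5] * x + coef[4]) * x + coef[3]) * x + coef[2]) * x) + coef[1]
}
.polyder1 <- function(coef, x) {
  ((4 * coef[5] * x + 3 * coef[4]) * x + 2 * coef[3]) * x + coef[2]
}

.polyval2 <- function(coef, x, y) {
  xp <- c(1, x, x * x, x * x * x, x * x * x * x)
  yp <- c(1, y, y * y, y * y * y, y * y * y * y)
  sum(coef * xp[.poly2_ei + 1L] * yp[.poly2_ej + 1L])
}
.polyder2 <- function(coef, x, y, wrt = 1L) {
  xp <- c(1, x, x * x, x * x * x, x * x * x * x)
  yp <- c(1, y, y * y, y * y * y, y * y * y * y)
  if (wrt == 1L) {
    keep <- .poly2_ei > 0L
    sum(coef[keep] * .poly2_ei[keep] * xp[.poly2_ei[keep]] *
          yp[.poly2_ej[keep] + 1L])
  } else {
    keep <- .poly2_ej > 0L
    sum(coef[keep] * .poly2_ej[keep] * xp[.poly2_ei[keep] + 1L] *
          yp[.poly2_ej[keep]])
  }
}

#' Fit fourth-order polynomial geometry tables for one muscle
#'
#' Evaluates the direct geometric MTC length and signed moment arms on dense
#' 1-degree joint-angle grids over the admissible ranges and approximates both
#' by fourth-order polynomials (univariate, or a bivariate fourth-order
#' surface when the quantity depends on two joint angles).  The maximum
#' absolute fit residual over the grid is stored with every table so that
#' fidelity against the direct computation can always be audited.
#'
#' @param path A [muscle_path()].
#' @param geom An [ankle_axis_geometry()].
#' @param L_thigh Thigh length (m).
#' @param step Grid increment in degrees (default 1).
#' @return An object of class `muscle_geometry_table` with components
#'   `length` (polynomial for l_MT) and `lever` (one polynomial per actuated
#'   joint, signed), each carrying coefficients, variable names, ranges and
#'   `max_resid`.
#' @export
fit_geometry_polynomials <- function(path, geom, L_thigh = 0.44, step = 1) {
  grids <- lapply(JOINT_RANGES, function(r)
    seq(r[1], r[2], by = step * pi / 180))

  len_vars <- path$drives
  tab <- list(muscle = path$name, length = NULL, lever = list())

  qfun <- function(h, k, a) c(hip = h, knee = k, ankle = a)

  make_grid <- function(vars) {
    if (length(vars) == 1) {
      data.frame(v1 = grids[[vars]])
    } else {
      expand.grid(v1 = grids[[vars[1]]], v2 = grids[[vars[2]]])
    }
  }
  grid_q <- function(g, vars) {
    q1 <- if ("hip" %in% vars) g[[which(vars == "hip")]] else 0
    q2 <- if ("knee" %in% vars) g[[which(vars == "knee")]] else 0
    q3 <- if ("ankle" %in% vars) g[[which(vars == "ankle")]] else 0
    list(q1 = q1, q2 = q2, q3 = q3)
  }

  if (length(len_vars) > 2)
    stop("at most two driving joints are supported per table")

  g <- make_grid(len_vars)
  qq <- grid_q(g, len_vars)
  xy <- .path_xy(path, qq$q1, qq$q2, qq$q3, geom, L_thigh)
  lmt <- 0
  for (i in seq_len(length(xy) - 1))
    lmt <- lmt + sqrt((xy[[i + 1]]$x - xy[[i]]$x)^2 +
                      (xy[[i + 1]]$y - xy[[i]]$y)^2)
  if (length(len_vars) == 1) {
    fit <- .fit_poly(.poly1_design(g$v1), lmt)
  } else {
    fit <- .fit_poly(.poly2_design(g$v1, g$v2), lmt)
  }
  tab$length <- c(fit, list(vars = len_vars,
                            ranges = JOINT_RANGES[len_vars]))

  for (joint in names(path$joints)) {
    # The lever arm about `joint` depends on exactly the joint angles lying
    # between the most proximal and most distal frames involved in the
    # construction (the two line-of-action endpoints and the joint centre);
    # rotations proximal to all of them move the whole construction rigidly.
    frame_idx <- c(pelvis = 0, thigh = 1, shank = 2, foot = 3)
    centre_frame <- c(hip = 0, knee = 1, ankle = 2)[joint]
    idx <- c(frame_idx[vapply(path$points[path$lever_line], `[[`, "", "frame")],
             centre_frame)
    lvars <- if (max(idx) > min(idx)) JOINTS[(min(idx) + 1):max(idx)]
             else character(0)
    if (joint == "ankle") lvars <- union(lvars, "ankle")  # centre migrates
    if (length(lvars) == 0) lvars <- joint
    g <- make_grid(lvars)
    qq <- grid_q(g, lvars)
    n <- nrow(g)
    r <- numeric(n)
    for (ii in seq_len(n)) {
      r[ii] <- .lever_arm_at(path, joint,
                             qfun(qq$q1[min(ii, length(qq$q1))],
                                  qq$q2[min(ii, length(qq$q2))],
                                  qq$q3[min(ii, length(qq$q3))]),
                             geom, L_thigh)
    }
    fit <- if (length(lvars) == 1) .fit_poly(.poly1_design(g$v1), r)
           else .fit_poly(.poly2_design(g$v1, g$v2), r)
    tab$lever[[joint]] <- c(fit, list(vars = lvars,
                                      ranges = JOINT_RANGES[lvars]))
  }
  class(tab) <- "muscle_geometry_table"
  tab
}

# Evaluate a fitted table entry (length or lever) at configuration q.
# q must carry hip/knee/ankle names (use .full_q() for user input).
# deriv: NULL for the value, or a joint name for the partial derivative.
.table_eval <- function(entry, q, deriv = NULL, clamp = TRUE) {
  vars <- entry$vars
  v1 <- q[[vars[1L]]]
  r <- entry$ranges[[1L]]
  if (v1 < r[1L] || v1 > r[2L]) {
    if (!clamp)
      stop(sprintf("angle for joint '%s' outside fitted range", vars[1L]),
           call. = FALSE)
    v1 <- if (v1 < r[1L]) r[1L] else r[2L]
  }
  if (length(vars) == 1L) {
    if (is.null(deriv)) return(.polyval1(entry$coef, v1))
    if (deriv != vars[1L]) return(0)
    return(.polyder1(entry$coef, v1))
  }
  v2 <- q[[vars[2L]]]
  r <- entry$ranges[[2L]]
  if (v2 < r[1L] || v2 > r[2L]) {
    if (!clamp)
      stop(sprintf("angle for joint '%s' outside fitted range", vars[2L]),
           call. = FALSE)
    v2 <- if (v2 < r[1L]) r[1L] else r[2L]
  }
  if (is.null(deriv)) return(.polyval2(entry$coef, v1, v2))
  if (deriv == vars[1L]) return(.polyder2(entry$coef, v1, v2, 1L))
  if (deriv == vars[2L]) return(.polyder2(entry$coef, v1, v2, 2L))
  0
}

#' Evaluate a geometry table
#'
#' @param table A `muscle_geometry_table` from [fit_geometry_polynomials()].
#' @param what `"length"` for l_MT or a joint name for that joint's signed
#'   moment arm.
#' @param q Named joint configuration (radians).
#' @param deriv `NULL`, or a joint name to get the partial derivative with
#'   respect to that joint angle.
#' @param clamp Clamp out-of-range angles to the fitted range (default) or
#'   raise an error.
#' @return Length (m), moment arm (m), or derivative (m/rad).
#' @export
geometry_eval <- function(table, what = "length", q, deriv = NULL,
                          clamp = TRUE) {
  entry <- if (what == "length") table$length else table$lever[[what]]
  if (is.null(entry))
    stop(sprintf("table for muscle %s has no entry '%s'", table$muscle, what),
         call. = FALSE)
  .table_eval(entry, .full_q(q), deriv = deriv, clamp = clamp)
}

#' Moment arm from the principle of virtual displacements
#'
#' Returns the derivative-based moment arm `d l_MT / d phi_joint` evaluated
#' from the fitted length polynomial.  This is the cross-validation companion
#' to the distance-to-line moment arm: the two agree in sign and overall
#' shape but are not numerically identical (the projected rotation centre
#' migrates with the tilted ankle axis).
#'
#' @inheritParams geometry_eval
#' @param joint Joint name.
#' @return Moment arm (m/rad ~ m); positive when the MTC lengthens with the
#'   joint angle.
#' @export
lever_arm_virtual <- function(table, joint, q, clamp = TRUE) {
  .table_eval(table$length, .full_q(q), deriv = joint, clamp = clamp)
}

#' Fibre contraction velocity of a uniarticular muscle
#'
#' With a rigid (constant-length) tendon the fibre velocity is the joint-rate
#' times the slope of the MTC length, divided by the cosine of the pennation
#' angle.
#'
#' @param phi_dot Joint angular rate (rad/s).
#' @param dlMT_dphi Slope of MTC length w.r.t. the joint angle (m/rad).
#' @param alpha_p Pennation angle (radians, `< pi/2`).
#' @return Fibre velocity (m/s); positive = lengthening.
#' @export
contraction_velocity_uni <- function(phi_dot, dlMT_dphi, alpha_p = 0) {
  if (alpha_p < 0 || alpha_p >= pi / 2)
    stop("pennation angle must lie in [0, pi/2)")
  phi_dot * dlMT_dphi / cos(alpha_p)
}

#' Fibre contraction velocity of a biarticular (knee/ankle) muscle
#'
#' @param phi_dot_ankle,phi_dot_knee Joint rates (rad/s).
#' @param dl_dankle,dl_dknee Partial derivatives of MTC length (m/rad).
#' @param alpha_p Pennation angle (radians).
#' @return Fibre velocity (m/s).
#' @export
contraction_velocity_bi <- function(phi_dot_ankle, phi_dot_knee,
                                    dl_dankle, dl_dknee, alpha_p = 0) {
  if (alpha_p < 0 || alpha_p >= pi / 2)
    stop("pennation angle must lie in [0, pi/2)")
  (phi_dot_ankle * dl_dankle + phi_dot_knee * dl_dknee) / cos(alpha_p)
}
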