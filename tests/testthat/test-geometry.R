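# Sagittal kinematics: transforms, moment arms, polynomial geometry tables

test_that("foot transform reduces to identity and is invertible", {
  g0 <- ankle_axis_geometry(alpha_TC_tla = 90, alpha_TC_fml = 90,
                            x_trans = 0, y_trans = 0)
  expect_equal(foot_transform(0, g0), diag(4))

  g <- ankle_axis_geometry()
  for (phi in c(-0.9, -0.3, 0, 0.3)) {
    T <- foot_transform(phi, g)
    expect_equal(T %*% solve(T), diag(4), tolerance = 1e-12)
  }
  expect_error(foot_transform(1.5, g), "outside admissible range")
  expect_silent(foot_transform(1.5, g, clamp = TRUE))
})

test_that("small rotations of the foot move points at the rigid-body speed", {
  # untilted axis: the rotation axis is the z-axis through the foot origin,
  # so the tangential speed equals the distance from that origin
  g <- ankle_axis_geometry(alpha_TC_tla = 90, alpha_TC_fml = 90,
                           x_trans = 0.01, y_trans = -0.4)
  p <- c(0.08, -0.05, 0, 1)
  d <- 1e-6
  for (phi in c(-0.5, 0, 0.2)) {
    v <- (foot_transform(phi + d, g, clamp = TRUE) %*% p -
            foot_transform(phi, g, clamp = TRUE) %*% p) / d
    speed <- sqrt(sum(v[1:2]^2))
    expect_equal(speed, sqrt(sum(p[1:2]^2)), tolerance = 1e-5)
  }
})

test_that("sagittal projection drops the mediolateral coordinate", {
  expect_equal(project_sagittal(c(1, 2, 3)), c(1, 2))
  expect_equal(project_sagittal(c(1, 2, 3)), project_sagittal(c(1, 2, -3)))
  m <- matrix(1:6, 3)
  expect_equal(project_sagittal(m), m[1:2, ])
})

test_that("moment arm equals the point-to-line distance", {
  expect_equal(lever_arm(c(0.5, 0), c(0, 0), c(1, 0)), 0)   # collinear
  expect_equal(lever_arm(c(0, 0), c(1, 0), c(1, 1)), 1.0)
  expect_error(lever_arm(c(0, 0), c(1, 1), c(1, 1)), "degenerate")

  set.seed(11)
  for (i in 1:50) {
    p_ic <- rnorm(2); p_o <- rnorm(2); p_i <- rnorm(2)
    d <- p_i - p_o
    t_par <- sum((p_ic - p_o) * d) / sum(d^2)   # orthogonal projection
    oracle <- sqrt(sum((p_ic - p_o - t_par * d)^2))
    expect_equal(lever_arm(p_ic, p_o, p_i), oracle, tolerance = 1e-12)
  }
})

test_that("instantaneous centre recovers a planar rotation centre exactly", {
  g <- ankle_axis_geometry(alpha_TC_tla = 90, alpha_TC_fml = 90,
                           x_trans = 0.013, y_trans = -0.41)
  pc <- instantaneous_centre(-0.2, 0.01, g)
  expect_equal(pc, c(0.013, -0.41), tolerance = 1e-9)

  # Richardson-style convergence for the tilted axis
  gt <- ankle_axis_geometry()
  c1 <- instantaneous_centre(-0.3, 2e-2, gt)
  c2 <- instantaneous_centre(-0.3, 1e-2, gt)
  c3 <- instantaneous_centre(-0.3, 5e-3, gt)
  expect_lt(sqrt(sum((c3 - c2)^2)), sqrt(sum((c2 - c1)^2)))

  # independence of the tracked points: exact for a planar rotation
  cA <- instantaneous_centre(-0.3, 1e-3, g,
                             path_points = cbind(c(0.1, 0, 0),
                                                 c(0, -0.08, 0)))
  cB <- instantaneous_centre(-0.3, 1e-3, g,
                             path_points = cbind(c(-0.05, -0.05, 0),
                                                 c(0.12, -0.02, 0)))
  expect_equal(cA, cB, tolerance = 1e-9)

  # with the tilted axis the projection is not an isometry, so different
  # tracked points may disagree by a few millimetres at most
  tA <- instantaneous_centre(-0.3, 1e-3, gt,
                             path_points = cbind(c(0.1, 0, 0),
                                                 c(0, -0.08, 0)))
  tB <- instantaneous_centre(-0.3, 1e-3, gt,
                             path_points = cbind(c(-0.05, -0.05, 0),
                                                 c(0.12, -0.02, 0)))
  expect_lt(sqrt(sum((tA - tB)^2)), 5e-3)
})

test_that("MTC length sums projected segments and respects via points", {
  g <- ankle_axis_geometry()
  two <- muscle_path("X", list(list(frame = "shank", p = c(0, 0, 0)),
                               list(frame = "shank", p = c(0, -0.3, 0))),
                     lever_line = c(1, 2), joints = c(ankle = 1),
                     drives = "ankle")
  expect_equal(mtc_length(two, c(ankle = -0.1), g), 0.3)

  via <- muscle_path("X", list(list(frame = "shank", p = c(0, 0, 0)),
                               list(frame = "shank", p = c(0, -0.12, 0)),
                               list(frame = "shank", p = c(0, -0.3, 0))),
                     lever_line = c(1, 3), joints = c(ankle = 1),
                     drives = "ankle")
  expect_equal(mtc_length(via, c(ankle = -0.1), g), 0.3)
  expect_error(mtc_length(two, c(ankle = -2), g), "outside admissible")
})

test_that("plantar flexors shorten in plantar flexion", {
  m <- cached_model()
  phis <- seq(-0.9, 0.3, by = 0.02)
  lens <- vapply(phis, function(p)
    mtc_length(m$paths$SOL, c(ankle = p), m$geom,
               m$segments$thigh$length), 0)
  expect_true(all(diff(lens) > 0))  # SOL lengthens with dorsiflexion
})

test_that("quartic fits recover exact quartics and match direct geometry", {
  # polynomial identity: synthetic exactly-quartic data
  x <- seq(-1, 0.4, by = 0.01)
  cf <- c(0.38, 0.05, -0.02, 0.01, -0.004)
  y <- drop(anklestiff:::.poly1_design(x) %*% cf)
  fit <- anklestiff:::.fit_poly(anklestiff:::.poly1_design(x), y)
  expect_equal(fit$coef, cf, tolerance = 1e-10)
  expect_lt(fit$max_resid, 1e-12)

  # every fitted table reproduces the direct computation to tolerance
  m <- cached_model()
  for (mus in c("RF", "HAMS", "VM", "GAS", "SOL", "TA")) {
    expect_lt(m$tables[[mus]]$length$max_resid, 1e-3)
    for (lv in m$tables[[mus]]$lever)
      expect_lt(lv$max_resid, 1e-3)
  }
})

test_that("fitted length slope matches finite differences of direct lengths", {
  m <- cached_model()
  h <- 1e-4
  for (phi in seq(-0.8, 0.2, by = 0.2)) {
    direct <- (mtc_length(m$paths$TA, c(ankle = phi + h), m$geom,
                          m$segments$thigh$length) -
               mtc_length(m$paths$TA, c(ankle = phi - h), m$geom,
                          m$segments$thigh$length)) / (2 * h)
    fitted <- geometry_eval(m$tables$TA, "length", c(ankle = phi),
                            deriv = "ankle")
    expect_equal(fitted, direct, tolerance = 1e-3)
  }
})

test_that("contraction velocities follow the rigid-tendon chain rule", {
  expect_equal(contraction_velocity_uni(0, 0.05, 0.2), 0)
  expect_equal(contraction_velocity_uni(1, 0.05, 0), 0.05)
  expect_equal(contraction_velocity_uni(-1, 0.05, 0),
               -contraction_velocity_uni(1, 0.05, 0))
  expect_error(contraction_velocity_uni(1, 0.05, pi / 2))

  expect_equal(contraction_velocity_bi(0, 0, 0.05, 0.02, 0.1), 0)
  expect_equal(contraction_velocity_bi(1.2, 0, 0.05, 0.02, 0.3),
               contraction_velocity_uni(1.2, 0.05, 0.3))

  # total derivative along a sampled biarticular trajectory (GAS)
  m <- cached_model()
  tt <- seq(0, 1, by = 1e-3)
  qk <- -0.4 + 0.2 * sin(2 * pi * tt)
  qa <- -0.2 + 0.15 * cos(2 * pi * tt)
  lmt <- vapply(seq_along(tt), function(i)
    geometry_eval(m$tables$GAS, "length",
                  c(knee = qk[i], ankle = qa[i])), 0)
  i <- 500
  dqk <- 0.2 * 2 * pi * cos(2 * pi * tt[i])
  dqa <- -0.15 * 2 * pi * sin(2 * pi * tt[i])
  ap <- m$paths$GAS$alpha_p
  v <- contraction_velocity_bi(
    dqa, dqk,
    geometry_eval(m$tables$GAS, "length", c(knee = qk[i], ankle = qa[i]),
                  deriv = "ankle"),
    geometry_eval(m$tables$GAS, "length", c(knee = qk[i], ankle = qa[i]),
                  deriv = "knee"), ap)
  fd <- (lmt[i + 1] - lmt[i - 1]) / (2e-3) / cos(ap)
  expect_equal(v, fd, tolerance = 1e-3)
})

test_that("virtual-displacement moment arm agrees in sign with the geometric one", {
  m <- cached_model()
  # constant length -> zero lever arm
  const_entry <- list(coef = c(0.3, 0, 0, 0, 0), vars = "ankle",
                      ranges = list(c(-1, 0.3)))
  tab <- list(muscle = "X", length = const_entry)
  expect_equal(lever_arm_virtual(tab, "ankle", c(ankle = -0.2)), 0)

  # quartic derivative equals the analytic cubic
  cf <- c(0.4, 0.03, -0.01, 0.005, -0.002)
  ent <- list(coef = cf, vars = "ankle", ranges = list(c(-1, 0.3)))
  x <- -0.37
  expect_equal(anklestiff:::.polyder1(cf, x),
               cf[2] + 2 * cf[3] * x + 3 * cf[4] * x^2 + 4 * cf[5] * x^3)

  # GAS: derivative-based and distance-based ankle lever arms agree in sign
  # (plantar flexor: MTC lengthens with dorsiflexion, signed lever negative)
  for (qk in c(-0.8, -0.4, 0)) {
    for (qa in seq(-0.9, 0.3, by = 0.1)) {
      q <- c(knee = qk, ankle = qa)
      r55 <- lever_arm_virtual(m$tables$GAS, "ankle", q)
      r2 <- geometry_eval(m$tables$GAS, "ankle", q)
      expect_true(sign(-r55) == sign(r2))
    }
  }
})
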