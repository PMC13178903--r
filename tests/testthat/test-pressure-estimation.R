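test_that("tracking-quality thresholding masks exactly the low-TQ samples", {
  g <- make_grid(nx = 11, nt = 3)
  set.seed(21)
  tq <- array(runif(prod(relpress:::grid_dim(g))),
              dim = relpress:::grid_dim(g))
  f <- velocity_field(g, ux = 1, uy = 0, tq = tq)
  out <- apply_tq_threshold(f, 0.4)
  expect_identical(sum(out$valid), sum(tq > 0.4))
  expect_identical(out$ux, f$ux)
  expect_true(all(apply_tq_threshold(velocity_field(g, 1, 0, tq = 1))$valid))
  expect_false(any(apply_tq_threshold(velocity_field(g, 1, 0,
                                                     tq = 0))$valid))
  # monotonicity: raising the threshold never increases coverage
  cov <- vapply(seq(0, 1, by = 0.1), function(th)
    mean(apply_tq_threshold(f, th)$valid), numeric(1))
  expect_true(all(diff(cov) <= 0))
})

test_that("finite differences are exact on linear fields and second order on quadratic", {
  g <- make_grid(nx = 21, nt = 5)
  d <- relpress:::grid_dim(g)
  xx <- aperm(array(rep(g$x, each = d[1] * d[2]), dim = d), c(1, 2, 3))
  f_lin <- sample_analytic_field(analytic_field("stagnation",
                                                strain_rate = 3), g)
  dv <- velocity_derivatives(f_lin)
  expect_equal(dv$duxdx[2, 5, 5], 3, tolerance = 1e-12)
  expect_equal(dv$duydy[2, 5, 5], -3, tolerance = 1e-12)
  expect_true(all(dv$valid_duxdx))
  # linear in t: exact at interior frames
  f_t <- sample_analytic_field(analytic_field("uniform_unsteady", ax = 2), g)
  dvt <- velocity_derivatives(f_t)
  expect_equal(dvt$duxdt[3, 4, 4], 2, tolerance = 1e-12)
  expect_equal(dvt$duxdt[1, 4, 4], 2, tolerance = 1e-12)  # one-sided, linear
  # quadratic ux = x^2: interior error ~ h^2 (central diff of x^2 is exact,
  # so probe with x^3 which has error h^2 * x)
  err_at <- function(nx) {
    gq <- make_grid(nx = nx, nt = 3)
    dq <- relpress:::grid_dim(gq)
    xq <- aperm(array(rep(gq$x, each = dq[1] * dq[2]), dim = dq), c(1, 2, 3))
    fq <- velocity_field(gq, ux = xq^3, uy = 0 * xq)
    dvq <- velocity_derivatives(fq)
    i <- ceiling(length(gq$x) / 2) + 2L
    abs(dvq$duxdx[2, 3, i] - 3 * gq$x[i]^2)
  }
  e1 <- err_at(21)
  e2 <- err_at(41)
  slope <- log(e1 / e2) / log(2)
  expect_gt(slope, 1.8)
})

test_that("inviscid pressure gradient matches closed forms", {
  g <- make_grid(nx = 21, nt = 5)
  fl <- bmf
  # steady uniform flow: zero gradient
  f0 <- sample_analytic_field(analytic_field("uniform_unsteady", u0 = 1), g)
  g0 <- pressure_gradient(f0, fl)
  expect_equal(max(abs(g0$dpdx[g0$valid])), 0, tolerance = 1e-12)
  # uniform acceleration: only the temporal term survives
  fa <- sample_analytic_field(analytic_field("uniform_unsteady", ax = 3), g)
  ga <- pressure_gradient(fa, fl)
  expect_equal(ga$dpdx[3, 5, 5], -fl$rho * 3, tolerance = 1e-10)
  expect_equal(ga$dpdy[3, 5, 5], 0, tolerance = 1e-10)
  # stagnation flow: dp/dx = -rho k^2 x at interior nodes
  k <- 5
  fs <- sample_analytic_field(analytic_field("stagnation", strain_rate = k),
                              g)
  gs <- pressure_gradient(fs, fl)
  expect_equal(gs$dpdx[2, 10, 15], -fl$rho * k^2 * g$x[15],
               tolerance = 1e-8)
  expect_equal(gs$dpdy[2, 10, 15], -fl$rho * k^2 * g$y[10],
               tolerance = 1e-8)
})

test_that("path integration is exact for constant gradients and antisymmetric", {
  g <- make_grid(nx = 21, nt = 3)
  d <- relpress:::grid_dim(g)
  # constant gradient aligned with a straight path of length L
  fa <- sample_analytic_field(analytic_field("uniform_unsteady", ax = 4), g)
  grad <- pressure_gradient(fa, bmf)  # dpdx = -rho*4 everywhere
  L <- 0.03
  p_fwd <- path_spec(rbind(c(-0.015, 0), c(0.015, 0)))
  s_fwd <- integrate_along_path(grad, p_fwd)
  expect_equal(s_fwd$dp, rep(pa_to_mmhg(bmf$rho * 4 * L), d[1]),
               tolerance = 1e-10)
  expect_true(all(s_fwd$coverage == 1))
  # reversal flips the sign
  p_rev <- path_spec(rbind(c(0.015, 0), c(-0.015, 0)))
  s_rev <- integrate_along_path(grad, p_rev)
  expect_equal(s_rev$dp, -s_fwd$dp, tolerance = 1e-12)
  # zero gradient
  f0 <- sample_analytic_field(analytic_field("uniform_unsteady", u0 = 1), g)
  s0 <- integrate_along_path(pressure_gradient(f0, bmf), p_fwd)
  expect_equal(s0$dp, rep(0, d[1]), tolerance = 1e-12)
  expect_error(integrate_along_path(grad,
                                    path_spec(rbind(c(0.5, 0), c(0.6, 0)))),
               "bounding box")
})

test_that("the estimator is path independent on conservative fields", {
  g <- make_grid(nx = 41, nt = 5)
  spec <- analytic_field("stagnation", strain_rate = 5)
  f <- sample_analytic_field(spec, g)
  a <- c(-0.015, -0.01)
  b <- c(0.015, 0.012)
  direct <- estimate_delta_p(f, path_spec(rbind(a, b)))
  dogleg <- estimate_delta_p(f, path_spec(rbind(a, c(0.0, 0.015), b)))
  expect_equal(direct$dp, dogleg$dp, tolerance = 0.02 * max(abs(direct$dp)))
  exact <- pa_to_mmhg(exact_pressure_drop(spec, a, b, g$t))
  expect_equal(direct$dp, exact, tolerance = 0.02 * max(abs(exact)))
})

test_that("estimated pressure drop converges to the oracle under refinement", {
  # linear-velocity oracles (stagnation, rotation) are reproduced exactly:
  # every discrete step (stencil, bilinear sampling, trapezoid) is exact on
  # them, so their error sits at roundoff for any grid
  a <- c(-0.015, 0)
  b <- c(0.015, 0.01)
  for (spec in list(analytic_field("stagnation", strain_rate = 5),
                    analytic_field("solid_body_rotation", omega = 10))) {
    g <- make_grid(nx = 21, nt = 3)
    est <- estimate_delta_p(sample_analytic_field(spec, g),
                            path_spec(rbind(a, b)))
    exact <- pa_to_mmhg(exact_pressure_drop(spec, a, b, g$t[2]))
    expect_lt(abs(est$dp[2] - exact), 1e-10)
  }
  # measurable truncation error needs a nonlinear velocity: steady
  # potential flow u = grad(A (x^3 - 3 x y^2) / 3) with Bernoulli pressure
  # P = p0 - rho |u|^2 / 2 as the closed-form oracle
  A <- 2000
  exact_dp <- function(p, q) {
    u2 <- function(p) (A * (p[1]^2 - p[2]^2))^2 + (-2 * A * p[1] * p[2])^2
    0.5 * bmf$rho * (u2(q) - u2(p))
  }
  err_at <- function(nx) {
    g <- make_grid(nx = nx, nt = 3)
    d <- relpress:::grid_dim(g)
    xx <- array(rep(g$x, each = d[1] * d[2]), dim = d)
    yy <- aperm(array(rep(g$y, times = d[1] * d[3]),
                      dim = c(d[2], d[1], d[3])), c(2, 1, 3))
    f <- velocity_field(g, ux = A * (xx^2 - yy^2), uy = -2 * A * xx * yy)
    est <- estimate_delta_p(f, path_spec(rbind(a, b)))
    abs(mmhg_to_pa(est$dp[2]) - exact_dp(a, b))
  }
  errs <- vapply(c(21, 41, 81), err_at, numeric(1))
  orders <- log(errs[-3] / errs[-1]) / log(2)
  expect_gt(min(orders), 1.8)  # interior path: second order
})

test_that("dropout at the inlet lowers coverage as counted and flags frames", {
  g <- make_grid(nx = 41, nt = 3)
  spec <- analytic_field("stagnation", strain_rate = 5)
  f <- sample_analytic_field(spec, g)
  # kill a band around the inlet end of the path
  deg <- bsi_degradation(dropout_regions = list(c(-0.02, -0.01,
                                                  -0.02, 0.02)))
  fd <- emulate_bsi(f, deg)
  a <- c(-0.015, 0)
  b <- c(0.015, 0)
  # strict coverage: frames invalid
  expect_error(estimate_delta_p(fd, path_spec(rbind(a, b)),
                                min_coverage = 0.95),
               "no valid support")
  # relaxed coverage: frames valid, dp still near the oracle because the
  # filled-in gradient is smooth
  est <- estimate_delta_p(fd, path_spec(rbind(a, b)), min_coverage = 0.5)
  expect_true(all(est$frame_valid))
  # the invalidated band is ~ the dropout share of the path, plus the
  # stencil widening at its edge
  expect_lt(mean(est$coverage), 0.82)
  expect_gt(mean(est$coverage), 0.55)
})

test_that("streamlines follow the flow geometry", {
  g <- make_grid(nx = 41, nt = 3)
  # uniform flow: straight line
  fu <- sample_analytic_field(analytic_field("uniform_unsteady", u0 = 1,
                                             v0 = 1), g)
  sl <- trace_streamline(fu, 1, c(-0.015, -0.015), step = 1e-3,
                         max_steps = 30)
  seg <- diff(sl$points)
  ang <- atan2(seg[, 2], seg[, 1])
  expect_equal(unname(ang), rep(pi / 4, nrow(seg)), tolerance = 1e-10)
  # solid-body rotation: closed circle of constant radius
  fr <- sample_analytic_field(analytic_field("solid_body_rotation",
                                             omega = 10), g)
  r0 <- 0.01
  sl2 <- trace_streamline(fr, 1, c(r0, 0), step = 2e-4, max_steps = 400)
  rr <- sqrt(rowSums(sl2$points^2))
  expect_lt(max(abs(rr - r0)), 5e-4)
  # stagnation point seed: error
  fs <- sample_analytic_field(analytic_field("stagnation", strain_rate = 5),
                              g)
  expect_error(trace_streamline(fs, 1, c(0, 0), step = 1e-3),
               "stagnation")
})

test_that("viscous omission on Womersley flow is bounded by the analytic viscous term", {
  hs <- harmonic_set(omega = 2 * pi / 1.7, k = 400 + 0i)
  R <- 0.005
  tube <- tube_spec(radius = R, length = 1, fluid = bmf)
  spec <- analytic_field("womersley_axial", radius = R, harmonics = hs,
                         fluid = bmf)
  g <- scan_grid(seq(-0.02, 0.02, length.out = 21),
                 seq(-0.8 * R, 0.8 * R, length.out = 33),
                 seq(0, 0.2, by = 0.02))
  f <- sample_analytic_field(spec, g)
  y0 <- g$y[25]  # off-axis row, clear of the |y| kink at the centre
  a <- c(-0.015, y0)
  b <- c(0.015, y0)
  est <- estimate_delta_p(f, path_spec(rbind(a, b)))
  exact <- pa_to_mmhg(exact_pressure_drop(spec, a, b, g$t))
  # analytic viscous term mu * (u'' + u'/r) at r = y0, by tight central
  # differences of the closed-form profile
  h <- 1e-6
  visc <- vapply(g$t, function(t) {
    up <- womersley_velocity(tube, hs, y0 + h, t)
    um <- womersley_velocity(tube, hs, y0 - h, t)
    u0 <- womersley_velocity(tube, hs, y0, t)
    bmf$mu * ((up - 2 * u0 + um) / h^2 + (up - um) / (2 * h) / y0)
  }, numeric(1))
  bias <- pa_to_mmhg(visc * (b[1] - a[1]))
  # removing the known viscous bias leaves only discretisation error
  resid <- est$dp - (exact + bias)
  expect_lt(max(abs(resid[2:10])), 0.05 * max(abs(exact)))
  # and the raw error is indeed dominated by that bias
  expect_gt(max(abs(est$dp - exact)), max(abs(resid[2:10])))
})
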