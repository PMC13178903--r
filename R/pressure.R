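# ---- validity-aware finite differences on [frame, y, x] arrays ----

# neighbour view: out[..i..] = a[..i+by..] along `axis`, NA outside
shift3 <- function(a, axis, by) {
  d <- dim(a)
  idx <- seq_len(d[axis]) + by
  ok <- idx >= 1L & idx <= d[axis]
  out <- array(if (is.logical(a)) NA else NA_real_, dim = d)
  dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  src <- dst
  dst[[axis]] <- which(ok)
  src[[axis]] <- idx[ok]
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# first derivative along one axis: second-order central where both
# neighbours are valid, first-order one-sided next to boundaries or
# invalid nodes, invalid where no stencil can be formed
fd_axis <- function(a, valid, h, axis) {
  ap <- shift3(a, axis, +1L)
  am <- shift3(a, axis, -1L)
  vp <- shift3(valid, axis, +1L)
  vm <- shift3(valid, axis, -1L)
  vp[is.na(vp)] <- FALSE
  vm[is.na(vm)] <- FALSE
  central <- valid & vp & vm
  fwd <- valid & vp & !central
  bwd <- valid & vm & !central & !fwd
  d <- array(NA_real_, dim = dim(a))
  d[central] <- ((ap - am) / (2 * h))[central]
  d[fwd] <- ((ap - a) / h)[fwd]
  d[bwd] <- ((a - am) / h)[bwd]
  list(d = d, valid = central | fwd | bwd)
}

#' Restrict a velocity field to samples above a tracking-quality threshold
#'
#' Sets the validity mask to `tq > threshold` AND the previous mask;
#' velocities are untouched. The default threshold 0.4 is the reported
#' cut-off above which tracking quality correlates well with velocity
#' accuracy.
#'
#' @param field a `velocity_field2d`.
#' @param threshold TQ threshold in \[0, 1\].
#' @return a `velocity_field2d` with the tightened mask.
#' @export
apply_tq_threshold <- function(field, threshold = 0.4) {
  stopifnot(inherits(field, "velocity_field2d"))
  if (threshold < 0 || threshold > 1)
    stop("`threshold` must lie in [0, 1]", call. = FALSE)
  field$valid <- field$valid & (field$tq > threshold)
  field
}

#' Spatial and temporal derivatives of a masked velocity field
#'
#' Computes all first derivatives of `ux` and `uy` needed by the inviscid
#' pressure gradient, with validity propagated through the stencils:
#' second-order central differences at interior valid nodes, first-order
#' one-sided at valid nodes adjacent to a boundary or an invalid node, and
#' invalid where no stencil exists. The temporal scheme mirrors the spatial
#' one across frames.
#'
#' @param field a `velocity_field2d` with at least 2 frames.
#' @return a list with arrays `duxdx, duxdy, duydx, duydy` (1/s),
#'   `duxdt, duydt` (m/s^2) and matching `valid_*` masks.
#' @export
velocity_derivatives <- function(field) {
  stopifnot(inherits(field, "velocity_field2d"))
  g <- field$grid
  if (length(g$t) < 2L)
    stop("temporal derivatives require at least 2 frames", call. = FALSE)
  v <- field$valid
  dxx <- fd_axis(field$ux, v, g$dx, 3L)
  dxy <- fd_axis(field$ux, v, g$dy, 2L)
  dyx <- fd_axis(field$uy, v, g$dx, 3L)
  dyy <- fd_axis(field$uy, v, g$dy, 2L)
  dxt <- fd_axis(field$ux, v, g$dt, 1L)
  dyt <- fd_axis(field$uy, v, g$dt, 1L)
  list(duxdx = dxx$d, valid_duxdx = dxx$valid,
       duxdy = dxy$d, valid_duxdy = dxy$valid,
       duydx = dyx$d, valid_duydx = dyx$valid,
       duydy = dyy$d, valid_duydy = dyy$valid,
       duxdt = dxt$d, valid_duxdt = dxt$valid,
       duydt = dyt$d, valid_duydt = dyt$valid)
}

#' Inviscid pressure gradient from a velocity field
#'
#' Applies the inviscid momentum balance to a masked 2D velocity field:
#' \deqn{\partial P/\partial x = -\rho\,(\partial u_x/\partial t +
#'   u_x \partial u_x/\partial x + u_y \partial u_x/\partial y)}
#' and analogously for y. The viscous term is deliberately omitted (the
#' estimator targets flows where inertia dominates; the Womersley benchmark
#' quantifies the omission). A node is valid only when every derivative in
#' its stencil is valid.
#'
#' @param field a `velocity_field2d` (>= 2 frames).
#' @param fluid a [fluid_properties()].
#' @return an object of class `pressure_gradient_field` with arrays `dpdx`,
#'   `dpdy` (Pa/m, NA where invalid) and a combined `valid` mask.
#' @export
pressure_gradient <- function(field, fluid = fluid_properties()) {
  stopifnot(inherits(field, "velocity_field2d"),
            inherits(fluid, "fluid_properties"))
  dv <- velocity_derivatives(field)
  rho <- fluid$rho
  valid_x <- dv$valid_duxdt & dv$valid_duxdx & dv$valid_duxdy & field$valid
  valid_y <- dv$valid_duydt & dv$valid_duydx & dv$valid_duydy & field$valid
  valid <- valid_x & valid_y
  dpdx <- -rho * (dv$duxdt + field$ux * dv$duxdx + field$uy * dv$duxdy)
  dpdy <- -rho * (dv$duydt + field$ux * dv$duydx + field$uy * dv$duydy)
  dpdx[!valid] <- NA_real_
  dpdy[!valid] <- NA_real_
  structure(list(grid = field$grid, dpdx = dpdx, dpdy = dpdy, valid = valid),
            class = "pressure_gradient_field")
}

#' Integration path between inlet and outlet points
#'
#' Ordered polyline from point `a` (inlet, first row) to `b` (outlet, last
#' row), held fixed across all frames of a scan. The default analysis mode
#' is a fixed polyline; `mode = "streamline"` labels paths produced by
#' [trace_streamline()].
#'
#' @param points numeric matrix (>= 2 rows) of `(x, y)` positions, m.
#' @param mode `"fixed_polyline"` or `"streamline"`.
#' @return an object of class `path_spec`.
#' @export
path_spec <- function(points, mode = c("fixed_polyline", "streamline")) {
  mode <- match.arg(mode)
  points <- as.matrix(points)
  if (nrow(points) < 2L || ncol(points) != 2L)
    stop("`points` must be a matrix of >= 2 (x, y) rows", call. = FALSE)
  if (any(!is.finite(points)))
    stop("path points must be finite", call. = FALSE)
  structure(list(points = unname(points), mode = mode), class = "path_spec")
}

#' @export
print.path_spec <- function(x, ...) {
  n <- nrow(x$points)
  cat(sprintf("Path (%s): %d vertices, a = (%.4g, %.4g) -> b = (%.4g, %.4g)\n",
              x$mode, n, x$points[1, 1], x$points[1, 2],
              x$points[n, 1], x$points[n, 2]))
  invisible(x)
}

# densify a polyline to ~uniform arclength samples; returns coords + s
resample_polyline <- function(points, step) {
  seg <- diff(points)
  len <- sqrt(rowSums(seg^2))
  s <- c(0, cumsum(len))
  total <- s[length(s)]
  if (total <= 0) stop("path has zero length", call. = FALSE)
  ns <- max(3L, ceiling(total / step) + 1L)
  ss <- seq(0, total, length.out = ns)
  list(x = approx(s, points[, 1], xout = ss)$y,
       y = approx(s, points[, 2], xout = ss)$y,
       s = ss)
}

# validity-aware bilinear interpolation of one frame matrix [y, x];
# weights of invalid corners are dropped and the rest renormalised;
# NA where no valid corner supports the sample or the point is outside
interp_valid <- function(mat, valid, gx, gy, xs, ys) {
  nx <- length(gx)
  ny <- length(gy)
  ix <- pmin(pmax(findInterval(xs, gx), 1L), nx - 1L)
  iy <- pmin(pmax(findInterval(ys, gy), 1L), ny - 1L)
  fx <- (xs - gx[ix]) / (gx[ix + 1L] - gx[ix])
  fy <- (ys - gy[iy]) / (gy[iy + 1L] - gy[iy])
  outside <- fx < -1e-9 | fx > 1 + 1e-9 | fy < -1e-9 | fy > 1 + 1e-9
  fx <- pmin(pmax(fx, 0), 1)
  fy <- pmin(pmax(fy, 0), 1)
  c00 <- cbind(iy, ix); c01 <- cbind(iy, ix + 1L)
  c10 <- cbind(iy + 1L, ix); c11 <- cbind(iy + 1L, ix + 1L)
  w00 <- (1 - fy) * (1 - fx) * valid[c00]
  w01 <- (1 - fy) * fx * valid[c01]
  w10 <- fy * (1 - fx) * valid[c10]
  w11 <- fy * fx * valid[c11]
  wt <- w00 + w01 + w10 + w11
  val <- function(idx) {
    z <- mat[idx]
    z[is.na(z)] <- 0
    z
  }
  num <- w00 * val(c00) + w01 * val(c01) + w10 * val(c10) + w11 * val(c11)
  out <- ifelse(wt > 1e-12, num / pmax(wt, 1e-300), NA_real_)
  out[outside] <- NA_real_
  out
}

#' Integrate a pressure-gradient field along a path
#'
#' Per frame, samples the gradient along the path by validity-aware
#' bilinear interpolation and accumulates the line integral by the
#' trapezoid rule. The sign follows the inlet-minus-outlet convention:
#' a field with higher pressure at `a` than `b` yields positive pressure
#' drop. Output is in mmHg.
#'
#' Path samples with no valid support count against coverage; within a
#' frame that still meets `min_coverage`, their integrand is filled by
#' linear interpolation along the path. Frames below `min_coverage` are
#' flagged invalid (`dp = NA`) rather than extrapolated.
#'
#' @param grad a [pressure_gradient()] result.
#' @param path a [path_spec()].
#' @param min_coverage minimum valid fraction of path samples per frame,
#'   in (0, 1\].
#' @param step path sampling step, m (default half the finer grid spacing).
#' @return an object of class `delta_p_series` with `time` (s), `dp`
#'   (mmHg), `coverage` and `frame_valid`.
#' @export
integrate_along_path <- function(grad, path, min_coverage = 0.9,
                                 step = NULL) {
  stopifnot(inherits(grad, "pressure_gradient_field"),
            inherits(path, "path_spec"))
  if (min_coverage <= 0 || min_coverage > 1)
    stop("`min_coverage` must lie in (0, 1]", call. = FALSE)
  g <- grad$grid
  if (is.null(step)) step <- 0.5 * min(g$dx, g$dy)
  pts <- resample_polyline(path$points, step)
  if (any(pts$x < min(g$x) - 1e-9 | pts$x > max(g$x) + 1e-9 |
          pts$y < min(g$y) - 1e-9 | pts$y > max(g$y) + 1e-9))
    stop("path leaves the grid bounding box", call. = FALSE)
  nt <- length(g$t)
  ns <- length(pts$s)
  dxs <- diff(pts$x)
  dys <- diff(pts$y)
  dp <- coverage <- numeric(nt)
  for (k in seq_len(nt)) {
    gx <- interp_valid(grad$dpdx[k, , ], grad$valid[k, , ],
                       g$x, g$y, pts$x, pts$y)
    gy <- interp_valid(grad$dpdy[k, , ], grad$valid[k, , ],
                       g$x, g$y, pts$x, pts$y)
    ok <- !is.na(gx) & !is.na(gy)
    coverage[k] <- mean(ok)
    if (coverage[k] < min_coverage || !any(ok)) {
      dp[k] <- NA_real_
      next
    }
    if (!all(ok)) {
      gx <- approx(pts$s[ok], gx[ok], xout = pts$s, rule = 2)$y
      gy <- approx(pts$s[ok], gy[ok], xout = pts$s, rule = 2)$y
    }
    # trapezoid rule for int_a^b grad P . dl = P(b) - P(a)
    integral <- sum(0.5 * (gx[-ns] + gx[-1]) * dxs +
                      0.5 * (gy[-ns] + gy[-1]) * dys)
    dp[k] <- pa_to_mmhg(-integral)  # delta P = P(a) - P(b)
  }
  frame_valid <- coverage >= min_coverage & !is.na(dp)
  if (!any(frame_valid))
    stop("path has no valid support at any frame", call. = FALSE)
  structure(list(time = g$t, dp = dp, coverage = coverage,
                 frame_valid = frame_valid),
            class = "delta_p_series")
}

#' @export
print.delta_p_series <- function(x, ...) {
  cat(sprintf("Pressure-drop series: %d frames, %d valid\n",
              length(x$time), sum(x$frame_valid)))
  if (any(x$frame_valid))
    cat(sprintf("  dp: max %.3f mmHg, min %.3f mmHg; mean coverage %.2f\n",
                max(x$dp[x$frame_valid]), min(x$dp[x$frame_valid]),
                mean(x$coverage)))
  invisible(x)
}

#' @export
plot.delta_p_series <- function(x, ...) {
  plot(x$time, x$dp, type = "l", xlab = "time (s)",
       ylab = expression(Delta * P ~ "(mmHg)"), ...)
  points(x$time[!x$frame_valid], rep(0, sum(!x$frame_valid)),
         pch = 4, col = 2)
  abline(h = 0, lty = 3)
  invisible(x)
}

#' @export
as.data.frame.delta_p_series <- function(x, ...) {
  data.frame(t = x$time, dp_mmHg = x$dp, coverage = x$coverage,
             valid = x$frame_valid)
}

#' Estimate the pressure-drop series from a velocity field
#'
#' Full estimation pipeline: tracking-quality thresholding
#' ([apply_tq_threshold()]), inviscid pressure gradient
#' ([pressure_gradient()]), and path integration
#' ([integrate_along_path()]) between the fixed inlet point `a` and outlet
#' point `b` of `path`. Deterministic for fixed inputs.
#'
#' @inheritParams integrate_along_path
#' @param field a `velocity_field2d`.
#' @param fluid a [fluid_properties()].
#' @param tq_threshold tracking-quality threshold (default 0.4).
#' @return a `delta_p_series` (mmHg).
#' @examples
#' g <- scan_grid(seq(-0.02, 0.02, length.out = 21),
#'                seq(-0.02, 0.02, length.out = 21),
#'                seq(0, 0.02, by = 0.005))
#' spec <- analytic_field("stagnation", strain_rate = 5)
#' f <- sample_analytic_field(spec, g)
#' p <- path_spec(rbind(c(-0.015, 0), c(0.015, 0.01)))
#' est <- estimate_delta_p(f, p)
#' exact <- pa_to_mmhg(exact_pressure_drop(spec, c(-0.015, 0),
#'                                         c(0.015, 0.01), g$t))
#' max(abs(est$dp - exact))  # discretisation error, mmHg
#' @export
estimate_delta_p <- function(field, path, fluid = fluid_properties(),
                             tq_threshold = 0.4, min_coverage = 0.9,
                             step = NULL) {
  field <- apply_tq_threshold(field, tq_threshold)
  grad <- pressure_gradient(field, fluid)
  integrate_along_path(grad, path, min_coverage = min_coverage, step = step)
}

#' Trace a streamline through one frame of a velocity field
#'
#' Integrates the instantaneous direction field `u/|u|` of the chosen frame
#' from `seed_point` with a fixed-step fourth-order Runge-Kutta scheme and
#' validity-aware bilinear interpolation. Tracing stops on reaching the
#' neighbourhood of `target` (if given), a domain boundary, an invalid
#' region, or `max_steps`. A stop before the target marks the returned path
#' as truncated (attribute `"truncated"`).
#'
#' @param field a `velocity_field2d`.
#' @param frame frame index (1-based).
#' @param seed_point numeric `c(x, y)`, m; speed there must exceed
#'   `min_speed`.
#' @param step integration step, m.
#' @param max_steps maximum number of steps.
#' @param target optional `c(x, y)` end point; tracing stops within
#'   `target_radius` of it.
#' @param target_radius capture radius around `target`, m.
#' @param min_speed stagnation floor, m/s.
#' @return a [path_spec()] with `mode = "streamline"`.
#' @export
trace_streamline <- function(field, frame, seed_point, step,
                             max_steps = 1000L, target = NULL,
                             target_radius = 2 * step, min_speed = 1e-9) {
  stopifnot(inherits(field, "velocity_field2d"), length(seed_point) == 2L)
  g <- field$grid
  if (frame < 1L || frame > length(g$t))
    stop("`frame` out of range", call. = FALSE)
  ux <- field$ux[frame, , ]
  uy <- field$uy[frame, , ]
  valid <- field$valid[frame, , ]
  vel <- function(p) {
    c(interp_valid(ux, valid, g$x, g$y, p[1], p[2]),
      interp_valid(uy, valid, g$x, g$y, p[1], p[2]))
  }
  dir <- function(p) {
    u <- vel(p)
    if (anyNA(u)) return(NULL)
    sp <- sqrt(sum(u^2))
    if (sp < min_speed) return(NULL)
    u / sp
  }
  u0 <- vel(seed_point)
  if (anyNA(u0) || sqrt(sum(u0^2)) < min_speed)
    stop("seed point speed is below the stagnation floor", call. = FALSE)
  pts <- matrix(NA_real_, nrow = max_steps + 1L, ncol = 2L)
  pts[1L, ] <- seed_point
  p <- seed_point
  n <- 1L
  reached <- FALSE
  for (i in seq_len(max_steps)) {
    k1 <- dir(p)
    if (is.null(k1)) break
    k2 <- dir(p + 0.5 * step * k1)
    if (is.null(k2)) break
    k3 <- dir(p + 0.5 * step * k2)
    if (is.null(k3)) break
    k4 <- dir(p + step * k3)
    if (is.null(k4)) break
    pn <- p + step * (k1 + 2 * k2 + 2 * k3 + k4) / 6
    if (pn[1] < min(g$x) || pn[1] > max(g$x) ||
        pn[2] < min(g$y) || pn[2] > max(g$y)) break
    p <- pn
    n <- n + 1L
    pts[n, ] <- p
    if (!is.null(target) &&
        sqrt(sum((p - target)^2)) <= target_radius) {
      reached <- TRUE
      break
    }
  }
  if (n < 2L)
    stop("streamline could not advance from the seed point", call. = FALSE)
  out <- path_spec(pts[seq_len(n), , drop = FALSE], mode = "streamline")
  attr(out, "truncated") <- !is.null(target) && !reached
  out
}
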