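#' Fluid properties
#'
#' Density and dynamic viscosity of the working fluid. Defaults are the
#' blood-mimicking fluid used with ultrasound flow imaging:
#' rho = 1037 kg/m^3, mu = 4.1 mPa.s.
#'
#' @param rho mass density, kg/m^3 (> 0).
#' @param mu dynamic viscosity, Pa.s (> 0).
#' @return an object of class `fluid_properties`.
#' @examples
#' bmf <- fluid_properties()
#' bmf$rho / bmf$mu  # inverse kinematic viscosity, s/m^2
#' @export
fluid_properties <- function(rho = 1037, mu = 4.1e-3) {
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho <= 0)
    stop("`rho` must be a single positive number (kg/m^3)", call. = FALSE)
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0)
    stop("`mu` must be a single positive number (Pa.s)", call. = FALSE)
  structure(list(rho = rho, mu = mu), class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("Fluid: rho = %g kg/m^3, mu = %g Pa.s (nu = %.3g m^2/s)\n",
              x$rho, x$mu, x$mu / x$rho))
  invisible(x)
}

# internal: check a coordinate axis is strictly increasing and uniform
check_axis <- function(v, name, min_n = 3L, rel_tol = 1e-6) {
  if (!is.numeric(v) || length(v) < min_n)
    stop(sprintf("`%s` needs at least %d numeric values", name, min_n),
         call. = FALSE)
  d <- diff(v)
  if (any(d <= 0))
    stop(sprintf("`%s` must be strictly increasing", name), call. = FALSE)
  h <- mean(d)
  if (max(abs(d - h)) > rel_tol * max(abs(h), .Machine$double.eps))
    stop(sprintf("`%s` must be uniformly spaced (rel. tol %g)", name, rel_tol),
         call. = FALSE)
  h
}

#' Scan grid for a 2D time-resolved velocity field
#'
#' Uniform rectilinear grid: x (rightward) and y (upward) coordinates in
#' metres, frame times in seconds. All axes must be strictly increasing and
#' uniformly spaced; arrays built on this grid are indexed `[frame, y, x]`.
#'
#' @param x,y spatial coordinates, m (>= 3 samples each, uniform).
#' @param t frame times, s (>= 3 frames, uniform).
#' @param rel_tol relative tolerance for uniform-spacing check.
#' @return an object of class `scan_grid` with elements `x`, `y`, `t` and
#'   stored spacings `dx`, `dy`, `dt`.
#' @export
scan_grid <- function(x, y, t, rel_tol = 1e-6) {
  dx <- check_axis(x, "x", rel_tol = rel_tol)
  dy <- check_axis(y, "y", rel_tol = rel_tol)
  dt <- check_axis(t, "t", rel_tol = rel_tol)
  structure(list(x = as.numeric(x), y = as.numeric(y), t = as.numeric(t),
                 dx = dx, dy = dy, dt = dt),
            class = "scan_grid")
}

#' @export
print.scan_grid <- function(x, ...) {
  cat(sprintf("Scan grid: %d x %d nodes, %d frames\n",
              length(x$x), length(x$y), length(x$t)))
  cat(sprintf("  x: [%g, %g] m (dx = %g)\n", min(x$x), max(x$x), x$dx))
  cat(sprintf("  y: [%g, %g] m (dy = %g)\n", min(x$y), max(x$y), x$dy))
  cat(sprintf("  t: [%g, %g] s (dt = %g, %.0f fps)\n",
              min(x$t), max(x$t), x$dt, 1 / x$dt))
  invisible(x)
}

grid_dim <- function(grid) c(length(grid$t), length(grid$y), length(grid$x))

as_field_array <- function(v, dim, name) {
  if (length(v) == 1L) v <- array(v, dim = dim)
  if (is.null(dim(v)) || !identical(as.integer(dim(v)), as.integer(dim)))
    stop(sprintf("`%s` must be an array of dim [frames, y, x] = [%s]",
                 name, paste(dim, collapse = ", ")), call. = FALSE)
  v
}

#' Time-resolved 2D velocity field with tracking quality
#'
#' Container for a blood-speckle-imaging-style velocity field: velocity
#' components `ux`, `uy` (m/s), a per-sample tracking-quality score `tq` in
#' \[0, 1\], and a validity mask, all indexed `[frame, y, x]` on a
#' [scan_grid()].
#'
#' @param grid a [scan_grid()].
#' @param ux,uy velocity components, m/s; arrays `[frame, y, x]` (scalars
#'   are recycled).
#' @param tq tracking quality in \[0, 1\]; array or scalar.
#' @param valid logical validity mask; array or scalar.
#' @return an object of class `velocity_field2d`.
#' @export
velocity_field <- function(grid, ux, uy, tq = 1, valid = TRUE) {
  stopifnot(inherits(grid, "scan_grid"))
  d <- grid_dim(grid)
  ux <- as_field_array(ux, d, "ux")
  uy <- as_field_array(uy, d, "uy")
  tq <- as_field_array(tq, d, "tq")
  valid <- as_field_array(valid, d, "valid")
  storage.mode(valid) <- "logical"
  if (anyNA(tq) || any(tq < 0 | tq > 1))
    stop("`tq` must lie within [0, 1]", call. = FALSE)
  if (any(!is.finite(ux[valid])) || any(!is.finite(uy[valid])))
    stop("velocities must be finite wherever `valid` is TRUE", call. = FALSE)
  structure(list(grid = grid, ux = ux, uy = uy, tq = tq, valid = valid),
            class = "velocity_field2d")
}

#' @export
print.velocity_field2d <- function(x, ...) {
  d <- grid_dim(x$grid)
  sp <- sqrt(x$ux^2 + x$uy^2)
  cat(sprintf("2D velocity field: %d frames of %d x %d nodes\n",
              d[1], d[2], d[3]))
  cat(sprintf("  valid: %.1f%%; speed (valid): %.3g-%.3g m/s; tq: %.2f-%.2f\n",
              100 * mean(x$valid), suppressWarnings(min(sp[x$valid])),
              suppressWarnings(max(sp[x$valid])), min(x$tq), max(x$tq)))
  invisible(x)
}

#' @export
as.data.frame.velocity_field2d <- function(x, ...) {
  g <- x$grid
  d <- grid_dim(g)
  idx <- expand.grid(frame = seq_len(d[1]), iy = seq_len(d[2]),
                     ix = seq_len(d[3]))
  data.frame(frame = idx$frame,
             t = g$t[idx$frame],
             x = g$x[idx$ix],
             y = g$y[idx$iy],
             ux = as.vector(x$ux),
             uy = as.vector(x$uy),
             tq = as.vector(x$tq),
             valid = as.vector(x$valid))
}
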