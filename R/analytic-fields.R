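#' Analytic flow fields with closed-form pressure
#'
#' Defines a 2D flow with a known closed-form velocity and, for every kind,
#' a closed-form pressure consistent with its governing balance. These
#' fields are the ground-truth oracles for the pressure-drop estimator:
#'
#' * `uniform_unsteady` — spatially uniform flow `u = (u0 + ax t, v0 + ay t)`;
#'   inviscid balance gives `P = p0 - rho (ax x + ay y)`.
#' * `stagnation` — planar stagnation flow with strain rate `k`:
#'   `u = (k x, -k y)`, Bernoulli pressure `P = p0 - rho k^2 (x^2 + y^2) / 2`.
#' * `solid_body_rotation` — `u = (-omega y, omega x)`; radial balance gives
#'   `P = p0 + rho omega^2 r^2 / 2`.
#' * `poiseuille_channel` — steady viscous channel flow
#'   `ux = umax (1 - (y/h)^2)` with `P = p0 - 2 mu umax x / h^2`. Its
#'   pressure gradient is purely viscous, so the inviscid estimator should
#'   return zero on it; the oracle quantifies that omission.
#' * `womersley_axial` — planar slice of fully developed pulsatile tube flow:
#'   `ux(y, t)` is the Womersley axial profile at radius `|y|`,
#'   `P = p0 - k(t) x` where `k(t)` is the (favourable) driving gradient of
#'   the supplied [harmonic_set()]. Viscous, so the inviscid estimator
#'   carries a quantifiable bias equal to the viscous term.
#'
#' @param kind one of `"uniform_unsteady"`, `"stagnation"`,
#'   `"solid_body_rotation"`, `"poiseuille_channel"`, `"womersley_axial"`.
#' @param ... kind-specific named parameters:
#'   `u0, v0, ax, ay, p0` (uniform_unsteady); `strain_rate, p0` (stagnation);
#'   `omega, p0` (solid_body_rotation); `umax, half_width, p0`
#'   (poiseuille_channel); `radius, harmonics, p0` (womersley_axial).
#' @param fluid a [fluid_properties()].
#' @return an object of class `analytic_field`.
#' @seealso [sample_analytic_field()], [exact_pressure_drop()]
#' @export
analytic_field <- function(kind, ..., fluid = fluid_properties()) {
  kinds <- c("uniform_unsteady", "stagnation", "solid_body_rotation",
             "poiseuille_channel", "womersley_axial")
  if (!is.character(kind) || length(kind) != 1L || !(kind %in% kinds))
    stop("unknown analytic field `kind`; must be one of: ",
         paste(kinds, collapse = ", "), call. = FALSE)
  stopifnot(inherits(fluid, "fluid_properties"))
  p <- list(...)
  defaults <- switch(kind,
    uniform_unsteady = list(u0 = 0, v0 = 0, ax = 0, ay = 0, p0 = 0),
    stagnation = list(strain_rate = 1, p0 = 0),
    solid_body_rotation = list(omega = 1, p0 = 0),
    poiseuille_channel = list(umax = 1, half_width = 0.01, p0 = 0),
    womersley_axial = list(radius = 0.005, harmonics = NULL, p0 = 0))
  unknown <- setdiff(names(p), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s) for kind '", kind, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  p <- modifyList(defaults, p)
  if (kind == "womersley_axial") {
    if (is.null(p$harmonics))
      stop("womersley_axial requires a `harmonics` (harmonic_set)",
           call. = FALSE)
    stopifnot(inherits(p$harmonics, "harmonic_set"), p$radius > 0)
  }
  structure(list(kind = kind, parameters = p, fluid = fluid),
            class = "analytic_field")
}

#' @export
print.analytic_field <- function(x, ...) {
  cat("Analytic field:", x$kind, "\n")
  scal <- Filter(function(v) is.numeric(v) && length(v) == 1L, x$parameters)
  cat(" ", paste(sprintf("%s = %g", names(scal), unlist(scal)),
                 collapse = ", "), "\n")
  invisible(x)
}

# closed-form velocity; x, y, t conformable arrays -> list(ux, uy)
af_velocity <- function(spec, x, y, t) {
  p <- spec$parameters
  switch(spec$kind,
    uniform_unsteady = list(ux = (p$u0 + p$ax * t) + 0 * x,
                            uy = (p$v0 + p$ay * t) + 0 * x),
    stagnation = list(ux = p$strain_rate * x + 0 * t,
                      uy = -p$strain_rate * y + 0 * t),
    solid_body_rotation = list(ux = -p$omega * y + 0 * t,
                               uy = p$omega * x + 0 * t),
    poiseuille_channel = list(ux = p$umax * (1 - (y / p$half_width)^2) +
                                0 * x + 0 * t,
                              uy = 0 * x + 0 * t),
    womersley_axial = {
      tube <- tube_spec(radius = p$radius, length = 1, fluid = spec$fluid)
      ux <- mapply(function(ri, ti)
        womersley_velocity(tube, p$harmonics, r = abs(ri), t = ti),
        y + 0 * x + 0 * t, t + 0 * x + 0 * y)
      dim(ux) <- dim(x + 0 * y + 0 * t)
      list(ux = ux, uy = 0 * x + 0 * y + 0 * t)
    })
}

# closed-form pressure, Pa
af_pressure <- function(spec, x, y, t) {
  p <- spec$parameters
  rho <- spec$fluid$rho
  mu <- spec$fluid$mu
  switch(spec$kind,
    uniform_unsteady = p$p0 - rho * (p$ax * x + p$ay * y) + 0 * t,
    stagnation = p$p0 - 0.5 * rho * p$strain_rate^2 * (x^2 + y^2) + 0 * t,
    solid_body_rotation = p$p0 + 0.5 * rho * p$omega^2 * (x^2 + y^2) + 0 * t,
    poiseuille_channel = p$p0 - 2 * mu * p$umax * x / p$half_width^2 + 0 * t,
    womersley_axial = {
      k <- driving_gradient(p$harmonics, t)
      p$p0 - k * x + 0 * y
    })
}

#' Sample an analytic field on a scan grid
#'
#' Evaluates the closed-form velocity of an [analytic_field()] at every grid
#' node and frame time. The result is a pristine [velocity_field()]:
#' `tq = 1` and `valid = TRUE` everywhere. Pass it through [emulate_bsi()]
#' to obtain a scanner-degraded version.
#'
#' @param spec an [analytic_field()].
#' @param grid a [scan_grid()].
#' @return a `velocity_field2d`.
#' @examples
#' g <- scan_grid(seq(-0.02, 0.02, length.out = 9),
#'                seq(-0.02, 0.02, length.out = 9),
#'                seq(0, 0.02, by = 0.005))
#' f <- sample_analytic_field(analytic_field("stagnation", strain_rate = 5), g)
#' range(f$ux)
#' @export
sample_analytic_field <- function(spec, grid) {
  stopifnot(inherits(spec, "analytic_field"), inherits(grid, "scan_grid"))
  d <- grid_dim(grid)
  # broadcast coordinates to [frame, y, x]
  tt <- array(rep(grid$t, times = d[2] * d[3]), dim = d)
  yy <- aperm(array(rep(grid$y, times = d[1] * d[3]),
                    dim = c(d[2], d[1], d[3])), c(2, 1, 3))
  xx <- aperm(array(rep(grid$x, times = d[1] * d[2]),
                    dim = c(d[3], d[1], d[2])), c(2, 3, 1))
  u <- af_velocity(spec, xx, yy, tt)
  velocity_field(grid, ux = u$ux, uy = u$uy, tq = 1, valid = TRUE)
}

#' Exact pressure drop between two points of an analytic field
#'
#' Ground-truth oracle: evaluates the closed-form pressure of an
#' [analytic_field()] and returns `P(a, t) - P(b, t)` in Pa (inlet minus
#' outlet convention) for each requested time.
#'
#' @param spec an [analytic_field()].
#' @param a,b points `c(x, y)` in metres.
#' @param times numeric vector of times, s.
#' @return numeric vector of pressure drops, Pa.
#' @export
exact_pressure_drop <- function(spec, a, b, times) {
  stopifnot(inherits(spec, "analytic_field"),
            length(a) == 2L, length(b) == 2L, is.numeric(times))
  af_pressure(spec, a[1], a[2], times) - af_pressure(spec, b[1], b[2], times)
}
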