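# shared fixture builders (all data generated in code)

# square grid centred on the origin, nx nodes per side, nt frames
make_grid <- function(nx = 21, half = 0.02, nt = 5, dt = 0.005) {
  scan_grid(seq(-half, half, length.out = nx),
            seq(-half, half, length.out = nx),
            seq(0, dt * (nt - 1), by = dt))
}

bmf <- fluid_properties()  # blood-mimicking fluid defaults

# straight two-point path used across estimator tests
default_path <- function(a = c(-0.015, 0), b = c(0.015, 0.01)) {
  path_spec(rbind(a, b))
}

# inviscid momentum residual of a closed-form field at one point,
# derivatives taken by tight central differences (independent of the
# package's grid stencils)
balance_residual <- function(spec, x, y, t, h = 1e-5) {
  vel <- function(x, y, t) relpress:::af_velocity(spec, x, y, t)
  pr <- function(x, y, t) relpress:::af_pressure(spec, x, y, t)
  u <- vel(x, y, t)
  dudt <- list(ux = (vel(x, y, t + h)$ux - vel(x, y, t - h)$ux) / (2 * h),
               uy = (vel(x, y, t + h)$uy - vel(x, y, t - h)$uy) / (2 * h))
  dudx <- list(ux = (vel(x + h, y, t)$ux - vel(x - h, y, t)$ux) / (2 * h),
               uy = (vel(x + h, y, t)$uy - vel(x - h, y, t)$uy) / (2 * h))
  dudy <- list(ux = (vel(x, y + h, t)$ux - vel(x, y - h, t)$ux) / (2 * h),
               uy = (vel(x, y + h, t)$uy - vel(x, y - h, t)$uy) / (2 * h))
  dpdx <- (pr(x + h, y, t) - pr(x - h, y, t)) / (2 * h)
  dpdy <- (pr(x, y + h, t) - pr(x, y - h, t)) / (2 * h)
  rho <- spec$fluid$rho
  c(rho * (dudt$ux + u$ux * dudx$ux + u$uy * dudy$ux) + dpdx,
    rho * (dudt$uy + u$ux * dudx$uy + u$uy * dudy$uy) + dpdy)
}
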