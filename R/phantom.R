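#' Lumped-parameter model of the compliant flow phantom
#'
#' Reduced-order surrogate of the gel phantom and its flow loop: the cavity
#' is a single compliant chamber (compliance `c`) fed through an inlet
#' branch (resistance `r_in`, inertance `l_in`) by the pump and drained
#' through an outlet branch (resistance `r_out`, inertance `l_out`, plus a
#' downstream measurement resistance `r_down`) into a reservoir at constant
#' pressure `p_down`. The inlet catheter reads upstream of the inlet branch,
#' the outlet catheter at the measurement node between `r_out` and `r_down`.
#'
#' The shipped defaults are illustrative, not fitted to any physical
#' phantom: they are chosen so that one default pump pulse produces a
#' pressure-drop curve with a positive peak of a few mmHg during ramp-up and
#' a negative undershoot after the pulse — the qualitative shape catheter
#' measurements show on compliant phantoms.
#'
#' @param r_in,r_out flow resistances, Pa.s/m^3 (> 0).
#' @param c chamber compliance, m^3/Pa (> 0).
#' @param l_in,l_out inertances, Pa.s^2/m^3 (>= 0).
#' @param r_down downstream measurement-node resistance, Pa.s/m^3 (>= 0).
#' @param p_down downstream reservoir pressure, Pa.
#' @return an object of class `rcr_phantom`.
#' @seealso [simulate_phantom()], [mass_balance_check()]
#' @export
rcr_phantom <- function(r_in = 3.6e6, r_out = 2.4e6, c = 2e-8,
                        l_in = 1.5e5, l_out = 0, r_down = 1.2e6,
                        p_down = mmhg_to_pa(10)) {
  if (r_in <= 0) stop("`r_in` must be > 0", call. = FALSE)
  if (r_out <= 0) stop("`r_out` must be > 0", call. = FALSE)
  if (c <= 0) stop("`c` must be > 0", call. = FALSE)
  if (l_in < 0) stop("`l_in` must be >= 0", call. = FALSE)
  if (l_out < 0) stop("`l_out` must be >= 0", call. = FALSE)
  if (r_down < 0) stop("`r_down` must be >= 0", call. = FALSE)
  structure(list(r_in = r_in, r_out = r_out, c = c, l_in = l_in,
                 l_out = l_out, r_down = r_down, p_down = p_down),
            class = "rcr_phantom")
}

#' @export
print.rcr_phantom <- function(x, ...) {
  cat("Lumped phantom (R-C-R network):\n")
  cat(sprintf("  r_in = %.3g, r_out = %.3g, r_down = %.3g Pa.s/m^3\n",
              x$r_in, x$r_out, x$r_down))
  cat(sprintf("  c = %.3g m^3/Pa, l_in = %.3g, l_out = %.3g Pa.s^2/m^3\n",
              x$c, x$l_in, x$l_out))
  cat(sprintf("  p_down = %.3g Pa (%.2f mmHg)\n", x$p_down,
              pa_to_mmhg(x$p_down)))
  invisible(x)
}

#' Simulate catheter pressure traces from the lumped phantom
#'
#' Integrates the network ODEs with the pump waveform prescribed as inflow,
#' repeated `n_pulses` times, starting from rest (chamber at `p_down`):
#' `c dP_c/dt = q_in - q_out`, with the outlet flow either algebraic
#' (`l_out = 0`) or governed by its own inertance ODE. Cumulative inflow
#' and outflow volumes are integrated as extra states so mass-balance
#' diagnostics are solver-consistent. Integration uses an adaptive solver
#' with maximum step 5 ms.
#'
#' Measured pressures:
#' `p_in = P_c + r_in q_in + l_in dq_in/dt` and
#' `p_out = p_down + r_down q_out`. Optional Gaussian measurement noise
#' (SD `noise_sd`, reproducible from `seed`) is added to both traces.
#'
#' @param phantom an [rcr_phantom()].
#' @param waveform a [make_pulse_waveform()].
#' @param n_pulses number of pump pulses to simulate (>= 1).
#' @param dt output sampling interval, s (<= period/100).
#' @param noise_sd measurement noise SD, Pa (0 = noiseless).
#' @param seed integer seed for the measurement noise.
#' @return an object of class `phantom_sim`: time, `p_in`, `p_out` (Pa),
#'   `q_in`, `q_out` (m^3/s), `v_chamber` (m^3 above the `p_down`
#'   reference) and cumulative branch volumes `v_in_cum`, `v_out_cum`.
#' @examples
#' sim <- simulate_phantom(rcr_phantom(), make_pulse_waveform(), n_pulses = 1)
#' max(pa_to_mmhg(sim$p_in - sim$p_out))  # peak pressure drop, mmHg
#' @export
simulate_phantom <- function(phantom, waveform, n_pulses = 6L, dt = 1e-3,
                             noise_sd = 0, seed = 1L) {
  stopifnot(inherits(phantom, "rcr_phantom"),
            inherits(waveform, "pulse_waveform"))
  if (n_pulses < 1) stop("`n_pulses` must be >= 1", call. = FALSE)
  if (dt > waveform$period / 100)
    stop("`dt` must be <= period/100", call. = FALSE)
  ph <- phantom
  with_inertance <- ph$l_out > 0
  times <- seq(0, n_pulses * waveform$period, by = dt)
  state <- c(pc = ph$p_down, vin = 0, vout = 0,
             if (with_inertance) c(qout = 0))
  deriv <- function(t, y, parms) {
    qin <- waveform_flow(waveform, t)
    if (with_inertance) {
      qout <- y[["qout"]]
      dqout <- (y[["pc"]] - ph$p_down -
                  (ph$r_out + ph$r_down) * qout) / ph$l_out
    } else {
      qout <- (y[["pc"]] - ph$p_down) / (ph$r_out + ph$r_down)
      dqout <- NULL
    }
    list(c((qin - qout) / ph$c, qin, qout, dqout))
  }
  sol <- deSolve::ode(y = state, times = times, func = deriv, parms = NULL,
                      method = "lsoda", hmax = 0.005,
                      rtol = 1e-9, atol = 1e-12)
  if (any(!is.finite(sol)))
    stop(sprintf("phantom integration failed near t = %.4g s",
                 times[which(!is.finite(rowSums(sol)))[1]]), call. = FALSE)
  pc <- sol[, "pc"]
  qin <- waveform_flow(waveform, times)
  qout <- if (with_inertance) sol[, "qout"]
          else (pc - ph$p_down) / (ph$r_out + ph$r_down)
  p_in <- pc + ph$r_in * qin + ph$l_in * waveform_flow_derivative(waveform,
                                                                  times)
  p_out <- ph$p_down + ph$r_down * qout
  if (noise_sd > 0) {
    n <- length(times)
    eps <- with_seed(seed, rnorm(2 * n, sd = noise_sd))
    p_in <- p_in + eps[seq_len(n)]
    p_out <- p_out + eps[n + seq_len(n)]
  }
  structure(list(time = times, p_in = p_in, p_out = p_out,
                 q_in = qin, q_out = qout,
                 v_chamber = ph$c * (pc - ph$p_down),
                 v_in_cum = sol[, "vin"], v_out_cum = sol[, "vout"],
                 phantom = ph, waveform = waveform,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_sim")
}

#' @export
print.phantom_sim <- function(x, ...) {
  dp <- pa_to_mmhg(x$p_in - x$p_out)
  cat(sprintf("Phantom simulation: %.3g s (%d samples), noise SD %.3g Pa\n",
              max(x$time), length(x$time), x$noise_sd))
  cat(sprintf("  pressure drop: max %.2f mmHg, min %.2f mmHg\n",
              max(dp), min(dp)))
  invisible(x)
}

#' @export
plot.phantom_sim <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  plot(x$time, pa_to_mmhg(x$p_in), type = "l", xlab = "time (s)",
       ylab = "pressure (mmHg)", ...)
  lines(x$time, pa_to_mmhg(x$p_out), col = 2)
  legend("topright", c("inlet", "outlet"), col = 1:2, lty = 1, bty = "n")
  plot(x$time, pa_to_mmhg(x$p_in - x$p_out), type = "l", xlab = "time (s)",
       ylab = expression(Delta * P ~ "(mmHg)"))
  abline(h = 0, lty = 3)
  invisible(x)
}

#' @export
as.data.frame.phantom_sim <- function(x, ...) {
  data.frame(t = x$time, p_in = x$p_in, p_out = x$p_out,
             q_in = x$q_in, q_out = x$q_out, v_chamber = x$v_chamber)
}

#' Relative mass-balance residual over a cycle
#'
#' Computes the conservation diagnostic
#' `(net accumulated mass + net mass out - net mass in) / net mass out`
#' over the cycle `[t_start, t_end]`, with masses taken as density times the
#' volume integrals of the flows. When the simulation carries
#' solver-integrated cumulative volumes (as [simulate_phantom()] results
#' do), those are used; otherwise the flows are integrated by the trapezoid
#' rule. The density cancels in the ratio.
#'
#' @param result a `phantom_sim`, or any list with `time`, `q_in`, `q_out`
#'   and `v_chamber`.
#' @param cycle numeric `c(t_start, t_end)` within the simulated span.
#' @return the dimensionless relative residual.
#' @examples
#' sim <- simulate_phantom(rcr_phantom(), make_pulse_waveform(), n_pulses = 1)
#' mass_balance_check(sim, c(0, 1.7))
#' @export
mass_balance_check <- function(result, cycle) {
  stopifnot(length(cycle) == 2L, cycle[1] < cycle[2])
  tt <- result$time
  if (cycle[1] < min(tt) - 1e-9 || cycle[2] > max(tt) + 1e-9)
    stop("`cycle` must lie within the simulated time span", call. = FALSE)
  at <- function(v, t0) approx(tt, v, xout = t0, rule = 2)$y
  if (!is.null(result$v_in_cum)) {
    v_in <- at(result$v_in_cum, cycle[2]) - at(result$v_in_cum, cycle[1])
    v_out <- at(result$v_out_cum, cycle[2]) - at(result$v_out_cum, cycle[1])
  } else {
    win <- tt >= cycle[1] - 1e-12 & tt <= cycle[2] + 1e-12
    v_in <- pracma::trapz(tt[win], result$q_in[win])
    v_out <- pracma::trapz(tt[win], result$q_out[win])
  }
  dv <- at(result$v_chamber, cycle[2]) - at(result$v_chamber, cycle[1])
  if (v_out == 0)
    stop("net outflow over the cycle is zero; residual undefined",
         call. = FALSE)
  (dv + v_out - v_in) / v_out
}
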