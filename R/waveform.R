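#' Pulsatile pump waveform: square wave with sine-like ramps
#'
#' Builds the volumetric flow-rate waveform of the pulsatile pump: one flow
#' pulse per period, shaped as a plateau at `peak_flow` joined to zero by
#' half-cosine ("sine-like") ramps, followed by a zero-flow delay for the
#' rest of the period. Defaults reproduce the infant-scale pump programme:
#' peak flow 2.5 L/min, 0.2 s pulse, 1.7 s period (1.5 s delay between
#' pulses).
#'
#' Each ramp occupies `ramp_fraction * pulse_duration`, so the closed-form
#' stroke volume is `peak_flow * pulse_duration * (1 - ramp_fraction)`.
#'
#' @param peak_flow plateau flow rate, m^3/s (use [lpm_to_m3s()] for L/min).
#' @param pulse_duration duration of the flow pulse, s.
#' @param period pulse repetition period, s.
#' @param ramp_fraction fraction of `pulse_duration` spent in each ramp,
#'   in (0, 0.5].
#' @param dt sample spacing for the stored trace, s; must divide `period`.
#' @return an object of class `pulse_waveform` with elements `time`, `q`
#'   (one sampled period) and the defining parameters.
#' @examples
#' wf <- make_pulse_waveform()
#' stroke_volume(wf) * 1e6  # mL per pulse
#' @export
make_pulse_waveform <- function(peak_flow = lpm_to_m3s(2.5),
                                pulse_duration = 0.2,
                                period = 1.7,
                                ramp_fraction = 0.25,
                                dt = 1e-3) {
  if (!is.numeric(period) || length(period) != 1L || period <= 0)
    stop("`period` must be a single positive duration (s)", call. = FALSE)
  if (!is.numeric(pulse_duration) || length(pulse_duration) != 1L ||
      pulse_duration <= 0 || pulse_duration >= period)
    stop("`pulse_duration` must satisfy 0 < pulse_duration < period",
         call. = FALSE)
  if (!is.numeric(ramp_fraction) || length(ramp_fraction) != 1L ||
      ramp_fraction <= 0 || ramp_fraction > 0.5)
    stop("`ramp_fraction` must lie in (0, 0.5]", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("`dt` must be a single positive step (s)", call. = FALSE)
  if (!is.numeric(peak_flow) || length(peak_flow) != 1L || peak_flow < 0)
    stop("`peak_flow` must be a single non-negative flow rate (m^3/s)",
         call. = FALSE)
  n <- period / dt
  if (abs(n - round(n)) > 1e-6 * n)
    stop("`dt` must divide `period` to within rounding", call. = FALSE)
  wf <- structure(list(period = period, pulse_duration = pulse_duration,
                       ramp_fraction = ramp_fraction, peak_flow = peak_flow,
                       dt = dt),
                  class = "pulse_waveform")
  wf$time <- seq(0, period - dt, by = dt)
  wf$q <- waveform_flow(wf, wf$time)
  wf
}

#' Evaluate a pulse waveform at arbitrary times
#'
#' `waveform_flow()` returns the flow rate Q(t), m^3/s, treating the
#' waveform as periodic; `waveform_flow_derivative()` returns dQ/dt, m^3/s^2
#' (piecewise closed form of the half-cosine ramps).
#'
#' @param wf a [make_pulse_waveform()] object.
#' @param t numeric vector of times, s (any real values; reduced mod period).
#' @return numeric vector, same length as `t`.
#' @export
waveform_flow <- function(wf, t) {
  stopifnot(inherits(wf, "pulse_waveform"))
  tp <- t %% wf$period
  tr <- wf$ramp_fraction * wf$pulse_duration
  pd <- wf$pulse_duration
  q <- numeric(length(tp))
  up <- tp < tr
  q[up] <- wf$peak_flow * 0.5 * (1 - cos(pi * tp[up] / tr))
  plateau <- tp >= tr & tp <= pd - tr
  q[plateau] <- wf$peak_flow
  down <- tp > pd - tr & tp < pd
  q[down] <- wf$peak_flow * 0.5 * (1 - cos(pi * (pd - tp[down]) / tr))
  q
}

#' @rdname waveform_flow
#' @export
waveform_flow_derivative <- function(wf, t) {
  stopifnot(inherits(wf, "pulse_waveform"))
  tp <- t %% wf$period
  tr <- wf$ramp_fraction * wf$pulse_duration
  pd <- wf$pulse_duration
  dq <- numeric(length(tp))
  up <- tp < tr
  dq[up] <- wf$peak_flow * 0.5 * (pi / tr) * sin(pi * tp[up] / tr)
  down <- tp > pd - tr & tp < pd
  dq[down] <- -wf$peak_flow * 0.5 * (pi / tr) * sin(pi * (pd - tp[down]) / tr)
  dq
}

#' Stroke volume of a pulse waveform
#'
#' Closed-form time integral of Q over one period:
#' `peak_flow * pulse_duration * (1 - ramp_fraction)` (each half-cosine ramp
#' integrates to half a plateau-equivalent ramp duration).
#'
#' @param wf a [make_pulse_waveform()] object.
#' @return stroke volume, m^3.
#' @export
stroke_volume <- function(wf) {
  stopifnot(inherits(wf, "pulse_waveform"))
  wf$peak_flow * wf$pulse_duration * (1 - wf$ramp_fraction)
}

#' @export
print.pulse_waveform <- function(x, ...) {
  cat(sprintf(paste0("Pulse waveform: peak %.3g L/min, pulse %.3g s ",
                     "(ramps %.0f%%), period %.3g s\n"),
              x$peak_flow * 6e4, x$pulse_duration, 100 * x$ramp_fraction,
              x$period))
  cat(sprintf("  stroke volume %.3g mL, %.3g s zero-flow delay per period\n",
              stroke_volume(x) * 1e6, x$period - x$pulse_duration))
  invisible(x)
}

#' @export
plot.pulse_waveform <- function(x, ...) {
  plot(x$time, x$q * 6e4, type = "l", xlab = "time (s)",
       ylab = "flow (L/min)", main = "Pump waveform", ...)
  invisible(x)
}
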