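#' Catheter-style pressure trace
#'
#' Uniformly sampled pressure signal (mmHg) with a free-text label such as
#' "inlet" or "outlet".
#'
#' @param time strictly increasing, uniformly sampled times, s.
#' @param pressure finite pressures, mmHg.
#' @param label free-text label.
#' @return an object of class `pressure_trace`.
#' @export
pressure_trace <- function(time, pressure, label = "") {
  if (length(time) != length(pressure))
    stop("`time` and `pressure` must have equal length", call. = FALSE)
  check_axis(time, "time", min_n = 2L, rel_tol = 1e-6)
  if (any(!is.finite(pressure)))
    stop("pressures must be finite", call. = FALSE)
  structure(list(time = as.numeric(time), pressure = as.numeric(pressure),
                 label = as.character(label)[1]),
            class = "pressure_trace")
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat(sprintf("Pressure trace '%s': %d samples over %.3g s, [%.3g, %.3g] mmHg\n",
              x$label, length(x$time), diff(range(x$time)),
              min(x$pressure), max(x$pressure)))
  invisible(x)
}

#' @export
plot.pressure_trace <- function(x, ...) {
  plot(x$time, x$pressure, type = "l", xlab = "time (s)",
       ylab = "pressure (mmHg)", main = x$label, ...)
  invisible(x)
}

#' @export
as.data.frame.pressure_trace <- function(x, ...) {
  data.frame(t = x$time, pressure_mmHg = x$pressure, label = x$label)
}

trace_dt <- function(trace) mean(diff(trace$time))

#' Segment a pressure trace into pump pulses
#'
#' Locates pulse starts and cuts the trace into aligned non-overlapping
#' segments of one period each. Trigger options:
#' * a [make_pulse_waveform()] — pulse onsets are taken at multiples of the
#'   period from the trace start (the pump and recording share a clock);
#' * a numeric threshold — upward crossings, with hysteresis (crossings
#'   are re-armed only after the signal falls below
#'   `threshold - hysteresis`);
#' * `NULL` (default) — automatic threshold at the midrange of the trace
#'   with hysteresis of 10% of the range.
#'
#' @param trace a [pressure_trace()].
#' @param period pulse period, s; the trace must span at least 2 periods.
#' @param trigger `NULL`, a numeric threshold (mmHg) or a `pulse_waveform`.
#' @param hysteresis re-arm margin for threshold triggering, mmHg.
#' @return an object of class `pulse_ensemble`: matrix `segments`
#'   `[n_pulses, samples_per_period]`, `starts` (indices), `rel_time` and
#'   the source label.
#' @export
segment_pulses <- function(trace, period, trigger = NULL,
                           hysteresis = NULL) {
  stopifnot(inherits(trace, "pressure_trace"))
  dt <- trace_dt(trace)
  if (diff(range(trace$time)) < 2 * period - dt / 2)
    stop("trace must span at least 2 periods", call. = FALSE)
  nseg <- round(period / dt)
  n <- length(trace$time)
  if (inherits(trigger, "pulse_waveform")) {
    starts <- seq(1L, n - nseg + 1L, by = nseg)
  } else {
    p <- trace$pressure
    if (is.null(trigger)) {
      rng <- range(p)
      if (diff(rng) == 0)
        stop("cannot segment a constant trace: no trigger crossings",
             call. = FALSE)
      level <- mean(rng)
      hyst <- 0.1 * diff(rng)
    } else {
      level <- trigger
      hyst <- if (is.null(hysteresis)) 0 else hysteresis
    }
    armed <- TRUE
    starts <- integer(0)
    for (i in 2:n) {
      if (armed && p[i - 1] < level && p[i] >= level) {
        starts <- c(starts, i - 1L)
        armed <- FALSE
      }
      if (!armed && p[i] < level - hyst) armed <- TRUE
    }
    if (!length(starts))
      stop("no trigger crossings found; cannot segment", call. = FALSE)
    # keep non-overlapping, full segments
    keep <- integer(0)
    last_end <- 0L
    for (s in starts) {
      if (s > last_end && s + nseg - 1L <= n) {
        keep <- c(keep, s)
        last_end <- s + nseg - 1L
      }
    }
    starts <- keep
    if (!length(starts))
      stop("no full pulse segments fit inside the trace", call. = FALSE)
  }
  seg <- t(vapply(starts, function(s) trace$pressure[s:(s + nseg - 1L)],
                  numeric(nseg)))
  structure(list(segments = seg, starts = starts,
                 rel_time = dt * (seq_len(nseg) - 1L),
                 period = period, dt = dt, label = trace$label),
            class = "pulse_ensemble")
}

#' @export
print.pulse_ensemble <- function(x, ...) {
  cat(sprintf("Pulse ensemble '%s': %d pulses of %.3g s (%d samples each)\n",
              x$label, nrow(x$segments), x$period, ncol(x$segments)))
  invisible(x)
}

#' Representative single-period curve from repeated pulses
#'
#' Implements the acquisition protocol: discard the first `discard` pulses
#' (flow and pressure establishment), then average the next `use` pulses
#' pointwise. Defaults reproduce the recorded-six / discard-three /
#' average-three protocol.
#'
#' @param ensemble a [segment_pulses()] result.
#' @param discard number of initial pulses to drop.
#' @param use number of subsequent pulses to average; `NULL` = all
#'   remaining.
#' @return a [pressure_trace()] of one period (time starting at 0).
#' @export
representative_curve <- function(ensemble, discard = 3L, use = 3L) {
  stopifnot(inherits(ensemble, "pulse_ensemble"))
  np <- nrow(ensemble$segments)
  if (is.null(use)) use <- np - discard
  if (discard < 0 || use < 1 || discard + use > np)
    stop(sprintf("protocol needs discard + use <= pulses (%d + %d > %d)",
                 discard, use, np), call. = FALSE)
  rows <- (discard + 1L):(discard + use)
  avg <- colMeans(ensemble$segments[rows, , drop = FALSE])
  pressure_trace(ensemble$rel_time, avg,
                 label = sprintf("%s (mean of pulses %d-%d)", ensemble$label,
                                 discard + 1L, discard + use))
}

#' Pressure drop between inlet and outlet traces
#'
#' Pointwise inlet minus outlet. Traces must share the sampling interval
#' (clocks may be offset by a fraction of a sample, which is removed by
#' linear interpolation of the outlet onto the inlet clock over the
#' overlapping support); different sampling rates require explicit
#' resampling by the caller.
#'
#' @param inlet,outlet [pressure_trace()] objects, mmHg.
#' @return a `pressure_trace` of the pressure drop, mmHg.
#' @export
delta_p <- function(inlet, outlet) {
  stopifnot(inherits(inlet, "pressure_trace"),
            inherits(outlet, "pressure_trace"))
  dt <- trace_dt(inlet)
  t0 <- max(min(inlet$time), min(outlet$time))
  t1 <- min(max(inlet$time), max(outlet$time))
  if (t0 >= t1)
    stop("inlet and outlet traces have disjoint time ranges", call. = FALSE)
  keep <- inlet$time >= t0 - 1e-12 & inlet$time <= t1 + 1e-12
  ti <- inlet$time[keep]
  if (abs(trace_dt(outlet) - dt) > 1e-6 * dt)
    stop("sampling intervals differ; resample explicitly", call. = FALSE)
  po <- approx(outlet$time, outlet$pressure, xout = ti, rule = 1)$y
  if (anyNA(po))
    stop("outlet trace does not cover the overlap after alignment",
         call. = FALSE)
  pressure_trace(ti, inlet$pressure[keep] - po, label = "delta_p")
}

#' Extrema of a pressure-drop curve
#'
#' Global maximum and minimum with their times; ties are broken by the
#' earliest time.
#'
#' @param curve a [pressure_trace()] (typically the averaged representative
#'   pressure-drop curve).
#' @return a list with `max`, `t_max`, `min`, `t_min` (mmHg, s).
#' @export
extrema <- function(curve) {
  stopifnot(inherits(curve, "pressure_trace"))
  imax <- which.max(curve$pressure)
  imin <- which.min(curve$pressure)
  list(max = curve$pressure[imax], t_max = curve$time[imax],
       min = curve$pressure[imin], t_min = curve$time[imin])
}

#' Timing shift between two pressure-drop curves
#'
#' Lag maximising the normalised cross-correlation of the demeaned curves,
#' refined by parabolic interpolation of the correlation peak. Sign
#' convention: if `curve_b` lags `curve_a` (same events later in time), the
#' returned lag is positive.
#'
#' @param curve_a,curve_b [pressure_trace()] objects on a common sampling
#'   interval with overlapping support.
#' @param max_lag largest lag searched, s (default: half the overlap).
#' @return lag, s.
#' @export
timing_shift <- function(curve_a, curve_b, max_lag = NULL) {
  stopifnot(inherits(curve_a, "pressure_trace"),
            inherits(curve_b, "pressure_trace"))
  dt <- trace_dt(curve_a)
  t0 <- max(min(curve_a$time), min(curve_b$time))
  t1 <- min(max(curve_a$time), max(curve_b$time))
  if (t0 >= t1) stop("curves do not overlap in time", call. = FALSE)
  tt <- seq(t0, t1, by = dt)
  a <- approx(curve_a$time, curve_a$pressure, xout = tt, rule = 2)$y
  b <- approx(curve_b$time, curve_b$pressure, xout = tt, rule = 2)$y
  if (sd(a) == 0 || sd(b) == 0)
    stop("zero-variance input: correlation undefined", call. = FALSE)
  n <- length(tt)
  ml <- if (is.null(max_lag)) floor((n - 2) / 2)
        else min(floor(max_lag / dt), n - 2L)
  lags <- -ml:ml
  # normalised cross-correlation, each window demeaned on its own support
  cc <- vapply(lags, function(s) {
    if (s >= 0) {
      ai <- a[seq_len(n - s)]
      bi <- b[seq_len(n - s) + s]
    } else {
      ai <- a[seq_len(n + s) - s]
      bi <- b[seq_len(n + s)]
    }
    if (sd(ai) == 0 || sd(bi) == 0) return(-Inf)
    stats::cor(ai, bi)
  }, numeric(1))
  i <- which.max(cc)
  s <- lags[i]
  # parabolic refinement on the three points around the peak
  if (i > 1L && i < length(lags) && is.finite(cc[i - 1]) &&
      is.finite(cc[i + 1])) {
    denom <- cc[i - 1] - 2 * cc[i] + cc[i + 1]
    if (denom < 0) s <- s + 0.5 * (cc[i - 1] - cc[i + 1]) / denom
  }
  s * dt
}

#' Replicate comparison summary in the style of the phantom tables
#'
#' Group means and SDs of per-replicate extrema, an across-group one-way
#' ANOVA, and pairwise two-sample Welch t-tests, all two-sided at
#' alpha = 0.05. Tests requiring more replication than a group has are
#' flagged as skipped, never silently dropped. No multiple-testing
#' correction is applied by default (per-comparison reporting); set
#' `p_adjust` to any [p.adjust()] method to correct the pairwise p-values.
#'
#' @param values named list of numeric vectors (one per group, e.g. per
#'   depth or per method), or a data.frame with columns `group`, `value`.
#' @param p_adjust p-value adjustment method for the pairwise tests
#'   (default `"none"`).
#' @return an object of class `method_summary`: per-group `n`, `mean`,
#'   `sd` (NA when n < 2), `anova_p`, matrix `pairwise_p`, `alpha`,
#'   `skipped` flags and the choices made.
#' @importFrom stats p.adjust
#' @export
compare_methods <- function(values, p_adjust = "none") {
  if (is.data.frame(values)) {
    stopifnot(all(c("group", "value") %in% names(values)))
    values <- split(values$value, values$group)
  }
  stopifnot(is.list(values), length(values) >= 1L,
            !is.null(names(values)), all(nzchar(names(values))))
  n <- vapply(values, length, 1L)
  if (any(n < 1L)) stop("every group needs >= 1 replicate", call. = FALSE)
  means <- vapply(values, mean, 1)
  sds <- ifelse(n >= 2L, vapply(values, sd, 1), NA_real_)
  groups <- names(values)
  k <- length(groups)
  skipped <- character(0)
  anova_p <- NA_real_
  if (k >= 2L && all(n >= 2L)) {
    df <- data.frame(group = factor(rep(groups, n)), value = unlist(values))
    anova_p <- summary(aov(value ~ group, data = df))[[1]][["Pr(>F)"]][1]
  } else if (k >= 2L) {
    skipped <- c(skipped, "anova: some group has < 2 replicates")
  }
  pw <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    if (n[i] >= 2L && n[j] >= 2L) {
      pw[i, j] <- pw[j, i] <- t.test(values[[i]], values[[j]],
                                     var.equal = FALSE)$p.value
    } else {
      skipped <- c(skipped,
                   sprintf("t-test %s vs %s: < 2 replicates",
                           groups[i], groups[j]))
    }
  }
  if (p_adjust != "none") {
    up <- pw[upper.tri(pw)]
    pw[upper.tri(pw)] <- p.adjust(up, method = p_adjust)
    pw[lower.tri(pw)] <- t(pw)[lower.tri(pw)]
  }
  structure(list(n = n, mean = means, sd = sds, anova_p = anova_p,
                 pairwise_p = pw, alpha = 0.05, p_adjust = p_adjust,
                 tests = c(across = "one-way ANOVA",
                           pairwise = "Welch two-sample t-test (two-sided)"),
                 skipped = skipped),
            class = "method_summary")
}

#' @export
print.method_summary <- function(x, ...) {
  cat("Replicate comparison (mean +/- SD):\n")
  for (g in names(x$mean))
    cat(sprintf("  %-12s n = %d: %.3f %s\n", g, x$n[g], x$mean[g],
                if (is.na(x$sd[g])) "(SD n/a)"
                else sprintf("+/- %.3f", x$sd[g])))
  if (!is.na(x$anova_p))
    cat(sprintf("across groups (%s): p = %.4g%s\n", x$tests["across"],
                x$anova_p, if (x$anova_p < x$alpha) " *" else ""))
  if (any(is.finite(x$pairwise_p))) {
    cat(sprintf("pairwise (%s, p_adjust = %s):\n", x$tests["pairwise"],
                x$p_adjust))
    print(round(x$pairwise_p, 4))
  }
  if (length(x$skipped))
    cat("skipped:", paste(x$skipped, collapse = "; "), "\n")
  invisible(x)
}
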