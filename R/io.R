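# Delimited-text dialect at every text interface: comma-separated,
# '.' decimal, mandatory header row, UTF-8.

#' Write / read a velocity field
#'
#' Two interchange layouts are supported:
#' * `"csv"` — long-format delimited text with header columns
#'   `frame,t,x,y,ux,uy,tq,valid` (SI units);
#' * `"rds"` — a single-file container holding the named arrays
#'   `x, y, t, ux, uy, tq, valid` plus a metadata block (units and the
#'   coordinate-convention string), written with [saveRDS()].
#'
#' `read_velocity_field()` validates the result against the field
#' invariants (uniform grid, `tq` in \[0, 1\], finite valid velocities)
#' and fails with a descriptive error otherwise.
#'
#' @param field a `velocity_field2d`.
#' @param path file path; format is inferred from the extension unless
#'   `format` is given.
#' @param format `"csv"` or `"rds"`.
#' @return `write_velocity_field()` returns `path` invisibly;
#'   `read_velocity_field()` returns a `velocity_field2d`.
#' @export
write_velocity_field <- function(field, path, format = NULL) {
  stopifnot(inherits(field, "velocity_field2d"))
  format <- format %||% guess_format(path)
  if (format == "csv") {
    write.csv(as.data.frame(field), path, row.names = FALSE,
              fileEncoding = "UTF-8")
  } else if (format == "rds") {
    g <- field$grid
    saveRDS(list(x = g$x, y = g$y, t = g$t,
                 ux = field$ux, uy = field$uy,
                 tq = field$tq, valid = field$valid,
                 metadata = list(units = list(x = "m", y = "m", t = "s",
                                              ux = "m/s", uy = "m/s"),
                                 convention = paste("x rightward, y upward,",
                                                    "arrays [frame, y, x]"),
                                 writer = "relpress")),
            path)
  } else stop("unknown format '", format, "'", call. = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "txt")) "csv"
  else if (ext == "rds") "rds"
  else stop("cannot infer format from extension '", ext, "'", call. = FALSE)
}

#' @rdname write_velocity_field
#' @export
read_velocity_field <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- format %||% guess_format(path)
  if (format == "csv") {
    df <- read.csv(path, fileEncoding = "UTF-8")
    need <- c("frame", "t", "x", "y", "ux", "uy", "tq", "valid")
    if (!all(need %in% names(df)))
      stop("malformed header: need columns ", paste(need, collapse = ","),
           call. = FALSE)
    xs <- sort(unique(df$x))
    ys <- sort(unique(df$y))
    ts <- sort(unique(df$t))
    grid <- scan_grid(xs, ys, ts)
    d <- grid_dim(grid)
    if (nrow(df) != prod(d))
      stop("long-format field is not a complete grid", call. = FALSE)
    o <- order(match(df$x, xs), match(df$y, ys), match(df$t, ts))
    shape <- function(v) array(v[o], dim = d)
    velocity_field(grid, ux = shape(df$ux), uy = shape(df$uy),
                   tq = shape(df$tq), valid = shape(as.logical(df$valid)))
  } else if (format == "rds") {
    obj <- readRDS(path)
    grid <- scan_grid(obj$x, obj$y, obj$t)
    velocity_field(grid, ux = obj$ux, uy = obj$uy, tq = obj$tq,
                   valid = obj$valid)
  } else stop("unknown format '", format, "'", call. = FALSE)
}

#' Write / read a pulse waveform
#'
#' Two-column delimited text `t,Q` (s, m^3/s) plus a JSON sidecar
#' `<path>.json` holding the defining parameters, from which the waveform
#' is reconstructed exactly on read.
#'
#' @param wf a [make_pulse_waveform()].
#' @param path CSV file path.
#' @return `write_pulse_waveform()` returns `path` invisibly;
#'   `read_pulse_waveform()` returns a `pulse_waveform`.
#' @export
write_pulse_waveform <- function(wf, path) {
  stopifnot(inherits(wf, "pulse_waveform"))
  write.csv(data.frame(t = wf$time, Q = wf$q), path, row.names = FALSE,
            fileEncoding = "UTF-8")
  jsonlite::write_json(wf[c("period", "pulse_duration", "ramp_fraction",
                            "peak_flow", "dt")],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pulse_waveform
#' @export
read_pulse_waveform <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("missing JSON sidecar ", side, call. = FALSE)
  p <- jsonlite::read_json(side, simplifyVector = TRUE)
  make_pulse_waveform(peak_flow = p$peak_flow,
                      pulse_duration = p$pulse_duration,
                      period = p$period, ramp_fraction = p$ramp_fraction,
                      dt = p$dt)
}

#' Write / read a pressure trace
#'
#' Delimited text with header `t,pressure_mmHg,label`.
#'
#' @param trace a [pressure_trace()].
#' @param path CSV file path.
#' @return `write_pressure_trace()` returns `path` invisibly;
#'   `read_pressure_trace()` returns a `pressure_trace`.
#' @export
write_pressure_trace <- function(trace, path) {
  stopifnot(inherits(trace, "pressure_trace"))
  write.csv(as.data.frame(trace), path, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_pressure_trace
#' @export
read_pressure_trace <- function(path) {
  df <- read.csv(path, fileEncoding = "UTF-8")
  if (!all(c("t", "pressure_mmHg") %in% names(df)))
    stop("malformed header: need columns t,pressure_mmHg", call. = FALSE)
  pressure_trace(df$t, df$pressure_mmHg,
                 label = if ("label" %in% names(df)) df$label[1] else "")
}

#' Run a configured pipeline step reproducibly
#'
#' Executes one named step with all parameters taken from a configuration
#' (an R list, or a path to a JSON/YAML file), writes its outputs, and
#' returns a run log with the full parameter echo and a checksummed output
#' manifest — enough to re-execute the run byte-identically. Inputs are
#' never mutated; outputs are new files only. Steps that draw random
#' numbers refuse to run without an explicit `seed`.
#'
#' Steps and their parameters:
#' * `generate-field`: `kind`, `params` (list), `grid` (list x, y, t as
#'   `c(from, to, n)`), `out`.
#' * `emulate-bsi`: `field` (input path), `noise_sd`, `v_reject`, `seed`,
#'   `out`.
#' * `simulate-phantom`: phantom fields (`r_in`, ...), waveform fields
#'   (`peak_flow_lpm`, `pulse_duration`, `period`), `n_pulses`, `dt`,
#'   `noise_sd`, `seed`, `out` (CSV `t,p_in,p_out,q_in,q_out` with
#'   pressures in mmHg).
#' * `estimate-dp`: `field` (path), `path_points` (2-column matrix or
#'   list), `tq_threshold`, `min_coverage`, `out`
#'   (CSV `t,dp_mmHg,coverage,valid`).
#' * `womersley-benchmark`: `radius`, `length`, `frequency`, `k_amp`,
#'   `n_radial`, `dt`, `n_periods`, `out` (JSON report).
#' * `fit-material`: `data` (CSV `lam,stress_Pa`), `fix_c3_zero`, `out`
#'   (JSON parameters).
#' * `analyze-pulses`: `inlet`, `outlet` (trace CSVs), `period`,
#'   `discard`, `use`, `out` (JSON summary).
#'
#' @param config list or path to a JSON/YAML config with elements `step`
#'   and the step parameters.
#' @return invisibly, the run log: `step`, `params`, `outputs`
#'   (named md5 checksums), `warnings`, `started`, `finished`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    ext <- tolower(tools::file_ext(config))
    config <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config), !is.null(config$step))
  step <- config$step
  params <- config[setdiff(names(config), "step")]
  started <- Sys.time()
  stochastic <- c("emulate-bsi", "simulate-phantom")
  if (step %in% stochastic && is.null(params$seed))
    stop("step '", step, "' is stochastic and requires an explicit seed",
         call. = FALSE)
  outputs <- character(0)
  warnings <- character(0)
  grab <- function(path) outputs <<- c(outputs, path)
  switch(step,
    "generate-field" = {
      gr <- params$grid
      grid <- scan_grid(seq(gr$x[1], gr$x[2], length.out = gr$x[3]),
                        seq(gr$y[1], gr$y[2], length.out = gr$y[3]),
                        seq(gr$t[1], gr$t[2], length.out = gr$t[3]))
      spec <- do.call(analytic_field, c(list(kind = params$kind),
                                        params$params))
      write_velocity_field(sample_analytic_field(spec, grid), params$out)
      grab(params$out)
    },
    "emulate-bsi" = {
      f <- read_velocity_field(params$field)
      deg <- bsi_degradation(noise_sd = params$noise_sd %||% 0,
                             v_reject = params$v_reject %||% 0,
                             seed = params$seed)
      write_velocity_field(emulate_bsi(f, deg), params$out)
      grab(params$out)
    },
    "simulate-phantom" = {
      ph <- do.call(rcr_phantom, params[intersect(names(params),
        c("r_in", "r_out", "c", "l_in", "l_out", "r_down", "p_down"))])
      wf <- make_pulse_waveform(
        peak_flow = lpm_to_m3s(params$peak_flow_lpm %||% 2.5),
        pulse_duration = params$pulse_duration %||% 0.2,
        period = params$period %||% 1.7)
      sim <- simulate_phantom(ph, wf, n_pulses = params$n_pulses %||% 6L,
                              dt = params$dt %||% 1e-3,
                              noise_sd = params$noise_sd %||% 0,
                              seed = params$seed)
      df <- as.data.frame(sim)
      df$p_in <- pa_to_mmhg(df$p_in)
      df$p_out <- pa_to_mmhg(df$p_out)
      names(df)[2:3] <- c("p_in_mmHg", "p_out_mmHg")
      write.csv(df, params$out, row.names = FALSE, fileEncoding = "UTF-8")
      grab(params$out)
    },
    "estimate-dp" = {
      f <- read_velocity_field(params$field)
      pts <- params$path_points
      if (is.list(pts) && !is.matrix(pts)) pts <- do.call(rbind, pts)
      est <- estimate_delta_p(f, path_spec(pts),
                              tq_threshold = params$tq_threshold %||% 0.4,
                              min_coverage = params$min_coverage %||% 0.9)
      write.csv(as.data.frame(est), params$out, row.names = FALSE,
                fileEncoding = "UTF-8")
      grab(params$out)
      if (!all(est$frame_valid))
        warnings <- c(warnings,
                      sprintf("%d frame(s) below min coverage",
                              sum(!est$frame_valid)))
    },
    "womersley-benchmark" = {
      tube <- tube_spec(radius = params$radius %||% 0.005,
                        length = params$length %||% 0.1)
      omega <- 2 * pi * (params$frequency %||% (1 / 1.7))
      hs <- harmonic_set(omega = omega,
                         k = complex(real = params$k_amp %||% 200))
      sol <- solve_tube_numeric(tube, hs,
                                n_radial = params$n_radial %||% 64,
                                dt = params$dt %||% 2.5e-3,
                                n_periods = params$n_periods %||% 8)
      last <- sol$times > max(sol$times) - sol$period
      num_amp <- (max(sol$dp[last]) - min(sol$dp[last])) / 2
      ana_amp <- Mod(hs$k[1]) * tube$length
      report <- list(
        alpha = womersley_number(tube, omega),
        analytic_dp_amplitude_pa = ana_amp,
        numeric_dp_amplitude_pa = num_amp,
        relative_amplitude_error_pct = 100 * abs(num_amp - ana_amp) / ana_amp)
      jsonlite::write_json(report, params$out, auto_unbox = TRUE,
                           digits = NA)
      grab(params$out)
    },
    "fit-material" = {
      df <- read.csv(params$data, fileEncoding = "UTF-8")
      fit <- fit_yeoh(df$lam, df$stress_Pa,
                      fix_c3_zero = isTRUE(params$fix_c3_zero))
      jsonlite::write_json(list(coefficients = as.list(coef(fit)),
                                residual_se = fit$sigma),
                           params$out, auto_unbox = TRUE, digits = NA)
      grab(params$out)
    },
    "analyze-pulses" = {
      inlet <- read_pressure_trace(params$inlet)
      outlet <- read_pressure_trace(params$outlet)
      dp <- delta_p(inlet, outlet)
      period <- params$period %||% 1.7
      # traces from the pump loop share its clock; segment on it unless a
      # threshold trigger is requested
      trig <- if (identical(params$trigger, "threshold")) NULL
              else make_pulse_waveform(period = period)
      ens <- segment_pulses(dp, period = period, trigger = trig)
      rep_curve <- representative_curve(ens,
                                        discard = params$discard %||% 3L,
                                        use = params$use %||% 3L)
      ex <- extrema(rep_curve)
      jsonlite::write_json(c(ex, list(n_pulses = nrow(ens$segments))),
                           params$out, auto_unbox = TRUE, digits = NA)
      grab(params$out)
    },
    stop("unknown step '", step, "'", call. = FALSE))
  log <- list(step = step, params = params,
              outputs = vapply(outputs, function(p)
                unname(tools::md5sum(p)), character(1)),
              warnings = warnings,
              started = format(started, "%Y-%m-%dT%H:%M:%OS3"),
              finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"))
  invisible(log)
}
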