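# one synthetic period: half-sine bump then flat, mmHg
bump_period <- function(dt = 0.01, period = 1.7, amp = 3) {
  tt <- seq(0, period - dt, by = dt)
  amp * sin(pi * tt / 0.4) * (tt < 0.4)
}

test_that("segmentation recovers constructed pulses and rejects flat traces", {
  dt <- 0.01
  one <- bump_period(dt)
  trace <- pressure_trace(dt * (seq_len(6 * length(one)) - 1),
                          rep(one, 6), "inlet")
  # threshold trigger fires part-way up the first bump, so 5 full periods
  # fit; all segments are aligned copies at period spacing
  ens <- segment_pulses(trace, period = 1.7)
  expect_equal(nrow(ens$segments), 5L)
  expect_equal(diff(ens$starts), rep(length(one), 4))
  expect_equal(unname(ens$segments[2, ]), unname(ens$segments[5, ]),
               tolerance = 1e-12)
  # phase-shifted copy: starts shifted by the known lag
  shift <- 23L
  shifted <- pressure_trace(trace$time,
                            c(rep(0, shift), rep(one, 6))[
                              seq_along(trace$time)], "shifted")
  ens2 <- segment_pulses(shifted, period = 1.7)
  expect_equal(ens2$starts[1] - ens$starts[1], shift)
  # constant trace: no crossings
  flat <- pressure_trace(trace$time, rep(2, length(trace$time)), "flat")
  expect_error(segment_pulses(flat, period = 1.7), "constant|crossings")
  expect_error(segment_pulses(pressure_trace(seq(0, 1, by = dt),
                                             seq(0, 1, by = dt)),
                              period = 1.7), "2 periods")
})

test_that("waveform-triggered segmentation uses the shared clock", {
  dt <- 0.01
  one <- bump_period(dt)
  trace <- pressure_trace(dt * (seq_len(6 * length(one)) - 1),
                          rep(one, 6), "inlet")
  ens <- segment_pulses(trace, period = 1.7,
                        trigger = make_pulse_waveform())
  expect_equal(nrow(ens$segments), 6L)
  expect_equal(ens$starts[1], 1L)
})

test_that("the representative curve implements discard/average and its linearity", {
  dt <- 0.01
  one <- bump_period(dt)
  n <- length(one)
  # pulses 4-6 constructed as known distinct curves
  pulses <- rbind(one, one, one, 2 * one, 3 * one, 4 * one)
  trace <- pressure_trace(dt * (seq_len(6 * n) - 1),
                          as.vector(t(pulses)) + 1, "inlet")
  ens <- segment_pulses(trace, period = 1.7,
                        trigger = make_pulse_waveform())
  rc <- representative_curve(ens, discard = 3, use = 3)
  expect_equal(rc$pressure, 3 * one + 1, tolerance = 1e-12)
  # identical pulses: representative curve equals any single pulse
  tr2 <- pressure_trace(dt * (seq_len(6 * n) - 1), rep(one, 6), "inlet")
  ens2 <- segment_pulses(tr2, period = 1.7, trigger = make_pulse_waveform())
  expect_equal(representative_curve(ens2)$pressure, one, tolerance = 1e-12)
  # discard = 0, use = all: plain ensemble mean
  rc_all <- representative_curve(ens, discard = 0, use = NULL)
  expect_equal(rc_all$pressure, colMeans(pulses) + 1, tolerance = 1e-12)
  expect_error(representative_curve(ens, discard = 4, use = 3), "protocol")
  # linearity: adding a constant to all pulses shifts the curve by it
  tr3 <- pressure_trace(tr2$time, tr2$pressure + 5, "inlet")
  ens3 <- segment_pulses(tr3, period = 1.7, trigger = make_pulse_waveform())
  expect_equal(representative_curve(ens3)$pressure,
               representative_curve(ens2)$pressure + 5, tolerance = 1e-12)
})

test_that("delta_p is pointwise inlet minus outlet and antisymmetric", {
  tt <- seq(0, 2, by = 0.01)
  pin <- pressure_trace(tt, 10 + sin(tt), "inlet")
  pout <- pressure_trace(tt, 8 + cos(tt), "outlet")
  dp <- delta_p(pin, pout)
  expect_equal(dp$pressure, pin$pressure - pout$pressure)
  expect_equal(delta_p(pout, pin)$pressure, -dp$pressure)
  expect_equal(delta_p(pin, pin)$pressure, rep(0, length(tt)))
  # constant 2 mmHg offset
  pc <- pressure_trace(tt, pin$pressure - 2, "outlet")
  expect_equal(delta_p(pin, pc)$pressure, rep(2, length(tt)))
  # disjoint ranges and mismatched sampling rates are refused
  late <- pressure_trace(tt + 10, pin$pressure, "late")
  expect_error(delta_p(pin, late), "disjoint")
  coarse <- pressure_trace(seq(0, 2, by = 0.025), 0.1 * seq(0, 2, by = 0.025),
                           "coarse")
  expect_error(delta_p(pin, coarse), "resample")
  # sub-sample clock offset is interpolated away
  subs <- pressure_trace(tt + 0.004, pin$pressure, "subsample")
  dps <- delta_p(pin, subs)
  expect_lt(max(abs(dps$pressure)), 0.005)
})

test_that("phantom-derived pressure drop keeps its catheter-curve shape", {
  sim <- simulate_phantom(rcr_phantom(), make_pulse_waveform(),
                          n_pulses = 6, noise_sd = 2, seed = 7)
  dp <- delta_p(pressure_trace(sim$time, pa_to_mmhg(sim$p_in), "inlet"),
                pressure_trace(sim$time, pa_to_mmhg(sim$p_out), "outlet"))
  ens <- segment_pulses(dp, period = 1.7, trigger = sim$waveform)
  rc <- representative_curve(ens, discard = 3, use = 3)
  ex <- extrema(rc)
  expect_gt(ex$max, 0)
  expect_lt(ex$min, 0)
  expect_lt(ex$t_max, ex$t_min)  # rise first, undershoot after the pulse
})

test_that("extrema report planted values with the earliest-time tie rule", {
  tt <- seq(0, 1, by = 0.01)
  p <- sin(2 * pi * tt)
  cv <- pressure_trace(tt, p, "half-sine")
  ex <- extrema(cv)
  expect_equal(ex$max, max(p))
  expect_equal(ex$t_max, 0.25)
  expect_equal(ex$t_min, 0.75)
  # two equal maxima: earlier time wins
  twin <- pressure_trace(tt, pmin(p, 0.5), "clipped")
  expect_equal(extrema(twin)$t_max, tt[which(pmin(p, 0.5) >= 0.5)][1])
  # planted point extrema
  pl <- rep(0, length(tt))
  pl[31] <- 4.2
  pl[77] <- -1.9
  expl <- extrema(pressure_trace(tt, pl, "planted"))
  expect_equal(expl$max, 4.2)
  expect_equal(expl$t_max, tt[31])
  expect_equal(expl$min, -1.9)
  expect_equal(expl$t_min, tt[77])
})

test_that("timing shift recovers planted lags with sub-sample refinement", {
  dt <- 0.01
  tt <- seq(0, 1.7 - dt, by = dt)
  a <- pressure_trace(tt, bump_period(dt), "a")
  expect_equal(timing_shift(a, a), 0)
  # planted 0.13 s lag (b later than a -> positive)
  b <- pressure_trace(tt + 0.13, a$pressure, "b")
  expect_equal(timing_shift(a, b), 0.13, tolerance = dt)
  expect_equal(timing_shift(b, a), -0.13, tolerance = dt)
  # sub-sample lag via parabolic refinement on a smooth curve
  smooth_a <- pressure_trace(tt, sin(2 * pi * tt / 1.7), "sa")
  smooth_b <- pressure_trace(tt, sin(2 * pi * (tt - 0.133) / 1.7), "sb")
  expect_equal(timing_shift(smooth_a, smooth_b), 0.133, tolerance = dt / 2)
  flat <- pressure_trace(tt, rep(1, length(tt)), "flat")
  expect_error(timing_shift(a, flat), "variance")
})

test_that("replicate comparison computes the table statistics honestly", {
  # identical groups: pairwise p = 1
  same <- list(d1 = c(2.1, 2.3, 2.2), d2 = c(2.1, 2.3, 2.2))
  ms <- compare_methods(same)
  expect_equal(unname(ms$pairwise_p["d1", "d2"]), 1, tolerance = 1e-10)
  expect_equal(unname(ms$mean["d1"]), mean(same$d1))
  expect_equal(unname(ms$sd["d1"]), sd(same$d1))
  # overwhelming separation: significant at alpha = 0.05
  set.seed(77)
  far <- list(direct = rnorm(4, 0, 0.1), bsi = rnorm(4, 1, 0.1))
  ms2 <- compare_methods(far)
  expect_lt(ms2$pairwise_p["direct", "bsi"], 0.05)
  expect_lt(ms2$anova_p, 0.05)
  # single-replicate group: SD absent, tests flagged skipped
  ms3 <- compare_methods(list(d1 = 2.5, d2 = c(2.0, 2.2)))
  expect_true(is.na(ms3$sd["d1"]))
  expect_false(is.na(ms3$sd["d2"]))
  expect_gt(length(ms3$skipped), 0)
  expect_true(all(is.na(ms3$pairwise_p)))
  # data.frame interface and p adjustment run through
  df <- data.frame(group = rep(c("a", "b", "c"), each = 3),
                   value = c(1, 1.1, 0.9, 5, 5.2, 4.9, 1, 1.05, 0.95))
  ms4 <- compare_methods(df, p_adjust = "holm")
  ms4_raw <- compare_methods(df)
  expect_true(all(ms4$pairwise_p >= ms4_raw$pairwise_p, na.rm = TRUE))
  expect_equal(ms4$p_adjust, "holm")
})

test_that("the full seeded protocol is bit-reproducible", {
  run_once <- function() {
    sim <- simulate_phantom(rcr_phantom(), make_pulse_waveform(),
                            n_pulses = 6, noise_sd = 3, seed = 11)
    dp <- delta_p(pressure_trace(sim$time, pa_to_mmhg(sim$p_in), "inlet"),
                  pressure_trace(sim$time, pa_to_mmhg(sim$p_out), "outlet"))
    ens <- segment_pulses(dp, period = 1.7, trigger = sim$waveform)
    rc <- representative_curve(ens, discard = 3, use = 3)
    ex <- extrema(rc)
    compare_methods(list(run = c(ex$max, ex$min),
                         ref = c(ex$max + 0.1, ex$min - 0.1)))
  }
  expect_identical(run_once(), run_once())
})
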