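test_that("extrema of a known sinusoid are located precisely", {
  t <- seq(0, 100, by = 0.01)
  y <- sin(2 * pi * t / 24)
  ex <- extrema(t, values = y, discard = 0)
  pk <- ex$time[ex$type == "peak"]
  expect_equal(pk[1:3], c(6, 30, 54), tolerance = 0.01)
  # strictly alternating
  expect_true(all(ex$type[-1] != ex$type[-nrow(ex)]))
})

test_that("a constant signal has no extrema and is not rhythmic", {
  t <- seq(0, 100, by = 0.1)
  ex <- extrema(t, values = rep(2, length(t)), discard = 0)
  expect_equal(nrow(ex), 0)
  traj <- quick_conceptual(dt = 0.05, t_end = 60)
  flat <- traj
  flat$states[, "R1"] <- 1
  s <- osc_stats(flat, "R1", discard = 0)
  expect_false(s$is_rhythmic)
})

test_that("quadratic refinement recovers peak times from a coarse grid", {
  tc <- seq(0, 100, by = 0.5)            # coarse
  tf <- seq(0, 100, by = 0.001)          # fine-grid oracle
  y <- function(t) sin(2 * pi * (t - 1.3) / 24)
  exc <- extrema(tc, values = y(tc), discard = 0)
  exf <- extrema(tf, values = y(tf), discard = 0)
  pkc <- exc$time[exc$type == "peak"][1:3]
  pkf <- exf$time[exf$type == "peak"][1:3]
  expect_lt(max(abs(pkc - pkf)), 0.02)
})

test_that("plateaued (clipped) signals still yield alternating extrema", {
  t <- seq(0, 100, by = 0.05)
  y <- pmin(0.8, pmax(-0.8, sin(2 * pi * t / 24)))
  ex <- extrema(t, values = y, discard = 0)
  pk <- ex$time[ex$type == "peak"]
  expect_gte(length(pk), 3)
  expect_equal(mean(diff(pk)), 24, tolerance = 0.05)
})

test_that("period and amplitude of a unit sinusoid are exact", {
  t <- seq(0, 200, by = 0.01)
  traj <- structure(list(time = t,
                         states = cbind(x = sin(2 * pi * t / 24)),
                         signals = NULL, derivs = cbind(x = 0), dt = 0.01,
                         t_span = c(0, 200), history = 0, params = NULL),
                    class = "clock_trajectory")
  s <- osc_stats(traj, "x", discard = 24)
  expect_equal(s$period, 24, tolerance = 0.01)
  expect_equal(s$amplitude, 2, tolerance = 0.01)
  # linear observable scaling: amplitude scales, period does not
  traj$states[, "x"] <- 3.5 * traj$states[, "x"]
  s2 <- osc_stats(traj, "x", discard = 24)
  expect_equal(s2$amplitude, 3.5 * s$amplitude, tolerance = 1e-6)
  expect_equal(s2$period, s$period)
})

test_that("wild-type calibration anchors the conceptual period and ratio", {
  traj <- quick_conceptual(dt = 0.01)
  sR <- osc_stats(traj, "R1")
  sP <- osc_stats(traj, "PLBS")
  sA <- osc_stats(traj, "ALBS")
  expect_equal(sR$period, 23.92, tolerance = 0.02)
  expect_equal(sP$amplitude / sA$amplitude, 1.3764, tolerance = 0.01)
})

test_that("the transcriptional delay behaves as the auxiliary-loop theory demands", {
  # without the auxiliary loop the drive is the PLBS alone: zero delay
  tr0 <- quick_conceptual(conceptual_params(al_enabled = FALSE))
  expect_lt(transcriptional_delay(tr0), 0.1)
  # raising the auxiliary modulation strictly increases the delay
  gAs <- c(0.3, 0.5, 0.7, 1)
  taus <- vapply(gAs, function(g) {
    transcriptional_delay(quick_conceptual(conceptual_params(amp_scale_A = g)))
  }, numeric(1))
  expect_true(all(diff(taus) > 0))
  # delay plus post-transcriptional delay approximates the half period
  p <- conceptual_params()
  traj <- quick_conceptual(p)
  Thalf <- osc_stats(traj, "R1")$period / 2
  expect_lt(abs(taus[4] + p$tau_P - Thalf) / Thalf, 0.15)
})

test_that("detrending removes offsets and drifts but keeps the oscillation", {
  t <- seq(0, 120, by = 1 / 6)
  osc <- sin(2 * pi * t / 24)
  # constant offset removed, sinusoid preserved within 2% RMS
  d <- detrend(t, osc + 7)
  ref <- sin(2 * pi * d$time / 24)
  expect_lt(sqrt(mean((d$value - ref)^2)), 0.02 * sqrt(mean(ref^2)) + 0.02)
  expect_lt(abs(mean(d$value)), 0.02)
  # linear drift suppressed well below its per-window growth
  b <- 0.5
  d2 <- detrend(t, osc + b * t)
  trend <- stats::coef(stats::lm(d2$value ~ d2$time))[2]
  expect_lt(abs(trend) * 24, 0.02 * b * 24)
  # white noise comes out approximately centred
  set.seed(5)
  d3 <- detrend(t, stats::rnorm(length(t)))
  expect_lt(abs(mean(d3$value)), 0.05)
  # a record shorter than the window is refused
  expect_error(detrend(t[t <= 20], osc[t <= 20]), "window")
})

test_that("the damped sine fit recovers known periods", {
  t <- seq(0, 120, by = 1 / 6)
  y <- 50 * exp(-0.01 * t) * sin(2 * pi * t / 22.6 + 0.4)
  f <- sine_fit_period(t, y)
  expect_equal(f$period, 22.6, tolerance = 0.05)
  expect_true(f$rhythmic)
  # synthetic luminometry trace with generator ground truth
  tr <- generate_trace(trace_config(seed = 1))
  d <- detrend(tr$trace$time, tr$trace$value)
  f2 <- sine_fit_period(d$time, d$value)
  expect_lt(abs(f2$period - tr$truth$period), 0.2)
  # pure noise never yields a confident period
  set.seed(3)
  f3 <- tryCatch(sine_fit_period(t, stats::rnorm(length(t))),
                 error = function(e) list(rhythmic = FALSE))
  expect_false(f3$rhythmic)
})

test_that("peak-to-peak and sine-fit periods agree on noiseless model output", {
  traj <- quick_conceptual(dt = 0.02)
  s <- osc_stats(traj, "R1")
  keep <- traj$time >= 240
  d <- detrend(traj$time[keep], traj$states[keep, "R1"])
  f <- sine_fit_period(d$time, d$value)
  expect_lt(abs(f$period - s$period), 0.1)
})
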