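test_that("displacement evaluation matches the closed form", {
  p <- ref152()
  ## snout at t = 0: cos term is 1, value is a + c
  expect_equal(evaluate_displacement(0, 0, p), 0.0187 + 0.0063)
  ## direct evaluation of the envelope at x = 0.4
  expect_equal(envelope(0.4, p),
               0.0187 * exp(-5.96 * 0.4) + 0.0063 * exp(2.65 * 0.4))
  ## zero envelope
  p0 <- bodywave_params(0, -1, 0, 1, 1, 2)
  expect_equal(evaluate_displacement(c(0, 0.3, 1.1), 0.2, p0), rep(0, 3))
  ## constant envelope
  p1 <- bodywave_params(1, 0, 0, 1, 1, 2)
  expect_equal(envelope(c(0, 0.5, 1), p1), rep(1, 3))
  ## periodicity in 1/f
  xs <- c(0, 0.3, 0.8, 1.13); ts <- c(0.11, 0.47)
  for (t in ts)
    expect_equal(evaluate_displacement(xs, t, p),
                 evaluate_displacement(xs, t + 1 / p$f, p))
  expect_error(evaluate_displacement(NaN, 0, p), "non-finite")
  expect_error(evaluate_displacement(-0.1, 0, p), "nonnegative")
})

test_that("envelope is the supremum of |displacement| over a period", {
  set.seed(42)
  for (i in 1:100) {
    p <- bodywave_params(a = runif(1, 0, 0.05), b = runif(1, -8, 0),
                         c = runif(1, 1e-4, 0.02), d = runif(1, 0.5, 4),
                         lambda = runif(1, 0.5, 2), f = runif(1, 1, 4))
    x <- runif(1, 0, 1.2)
    tg <- seq(0, 1 / p$f, length.out = 2001)
    expect_equal(envelope(x, p),
                 max(abs(evaluate_displacement(x, tg, p))),
                 tolerance = 1e-4)
  }
})

test_that("frequency estimation recovers known frequencies", {
  trk <- make_track()
  expect_equal(estimate_frequency(trk), 2.12, tolerance = 1e-6)
  ## constructed 1 Hz sinusoid
  tt <- seq(0, 3.98, by = 1 / 50)
  h <- outer(tt, c(0.2, 0.5, 0.9), function(t, x) 0.03 * cos(2 * pi * t + x))
  expect_equal(estimate_frequency(midline_track(c(0.2, 0.5, 0.9), tt, h)),
               1, tolerance = 1e-6)
  ## invariance to doubling the sampling rate
  trk2 <- make_track(fps = 120)
  expect_equal(estimate_frequency(trk2), estimate_frequency(trk),
               tolerance = 1e-6)
  ## flat track errors; short track errors
  flat <- midline_track(c(0.1, 0.5), seq(0, 1, by = 0.02),
                        matrix(0.01, 51, 2))
  expect_error(estimate_frequency(flat), "flat")
  short <- make_track(duration = 2.1)
  short <- midline_track(short$stations, short$times[1:40],
                         short$displacements[1:40, ])
  expect_error(estimate_frequency(short), "2 oscillation periods")
})

test_that("per-station amplitudes match the generating envelope", {
  p <- ref152()
  trk <- make_track()
  prof <- estimate_point_amplitudes(trk)
  expect_equal(prof$amplitudes, envelope(fit_stations, p),
               tolerance = 1e-8)
  ## all-zero displacements
  z <- midline_track(c(0.1, 0.5), seq(0, 2, by = 0.02),
                     matrix(0, 101, 2))
  expect_equal(estimate_point_amplitudes(z)$amplitudes, c(0, 0))
  ## single station, known amplitude
  tt <- seq(0, 2.99, by = 0.01)
  one <- midline_track(0.5, tt,
                       matrix(0.05 * cos(2 * pi * 1.7 * tt + 0.3), ncol = 1))
  expect_equal(estimate_point_amplitudes(one)$amplitudes, 0.05,
               tolerance = 1e-8)
})

test_that("wavelength recovery by phase regression", {
  trk <- make_track()
  f <- estimate_frequency(trk)
  expect_equal(estimate_wavelength(trk, f), 1.05, tolerance = 1e-6)
  ## constructed wavelength 2.0
  p2 <- bodywave_params(0.0187, -5.96, 0.0063, 2.65, 2.0, 2.12)
  trk2 <- make_track(p2)
  expect_equal(estimate_wavelength(trk2, 2.12), 2.0, tolerance = 1e-6)
  ## standing wave: all stations in phase
  tt <- seq(0, 2.99, by = 0.01)
  st <- c(0.2, 0.5, 0.8, 1.1)
  h <- outer(tt, st, function(t, x) (0.01 + 0.02 * x) * cos(2 * pi * 2 * t))
  lam <- estimate_wavelength(midline_track(st, tt, h), 2)
  expect_true(is.infinite(lam))
  expect_true(isTRUE(attr(lam, "standing_wave")))
  ## too few usable stations
  h1 <- outer(tt, st, function(t, x)
    ifelse(x < 0.4, 0.02 * cos(2 * pi * 2 * t - x), 0))
  expect_error(estimate_wavelength(midline_track(st, tt, h1), 2), ">= 3")
  ## invariance to a uniform time shift
  h3 <- outer(tt + 0.37, fit_stations,
              function(t, x) evaluate_displacement(x, t, ref152()))
  trk3 <- midline_track(fit_stations, tt, h3)
  expect_equal(estimate_wavelength(trk3, estimate_frequency(trk3)), 1.05,
               tolerance = 1e-6)
})

test_that("two-stage envelope fit: exact cases and convergence", {
  ## pure tail term, no head stations: machine-precision recovery
  st <- c(0.45, 0.6, 0.75, 0.85, 1.0, 1.13)
  prof <- amplitude_profile(st, 0.0063 * exp(2.65 * st))
  ef <- fit_envelope(prof)
  expect_equal(ef$c, 0.0063, tolerance = 1e-12)
  expect_equal(ef$d, 2.65, tolerance = 1e-12)
  expect_equal(ef$a, 0)
  ## full profile: converged iteration recovers all four constants
  p <- ref152()
  prof2 <- amplitude_profile(fit_stations, envelope(fit_stations, p))
  ef2 <- fit_envelope(prof2)
  expect_true(ef2$converged)
  expect_equal(ef2$a, p$a, tolerance = 1e-8)
  expect_equal(ef2$b, p$b, tolerance = 1e-8)
  expect_equal(ef2$c, p$c, tolerance = 1e-8)
  expect_equal(ef2$d, p$d, tolerance = 1e-8)
  ## a = 0: one-pass and converged fits agree exactly
  prof3 <- amplitude_profile(fit_stations,
                             0.0063 * exp(2.65 * fit_stations))
  e1 <- fit_envelope(prof3, iterations = 1)
  ec <- fit_envelope(prof3)
  expect_identical(c(e1$a, e1$b, e1$c, e1$d), c(ec$a, ec$b, ec$c, ec$d))
  ## region preconditions
  expect_error(fit_envelope(amplitude_profile(c(0.5, 0.6), c(1, 2))),
               NA)  # no head stations allowed
  expect_error(fit_envelope(amplitude_profile(c(0.1, 0.5, 0.6),
                                              c(1, 1, 2))),
               ">= 2 stations with x <")
  expect_error(fit_envelope(amplitude_profile(c(0.1, 0.2, 0.5),
                                              c(1, 1, 2))),
               ">= 2 stations with x >")
})

test_that("one-pass fit is tail-biased; nonlinear LSQ oracle agrees with truth", {
  p <- ref152()
  amps <- envelope(fit_stations, p)
  e1 <- fit_envelope(amplitude_profile(fit_stations, amps), iterations = 1)
  ## head-term contamination biases the one-pass stage-1 slope low
  expect_lt(e1$d, p$d)
  ## independent oracle: direct nonlinear least squares on the same samples
  ## (Levenberg-Marquardt handles the zero-residual noiseless case)
  df <- data.frame(x = fit_stations, y = amps)
  nl <- minpack.lm::nlsLM(y ~ a * exp(b * x) + c * exp(d * x), data = df,
                          start = list(a = 0.01, b = -4, c = 0.005,
                                       d = 2.5))
  cf <- coef(nl)
  expect_equal(unname(cf["d"]), p$d, tolerance = 1e-6)
  ## the converged two-stage fit agrees with the oracle; one-pass sits below
  ec <- fit_envelope(amplitude_profile(fit_stations, amps))
  expect_equal(ec$d, unname(cf["d"]), tolerance = 1e-6)
  expect_lt(e1$d, unname(cf["d"]))
})

test_that("stage-2 residual failure identifies offending stations", {
  ## amplitudes below the tail-term extrapolation at the head
  st <- c(0.05, 0.1, 0.5, 0.7, 0.9)
  amps <- c(0.001, 0.001, 0.0063 * exp(2.65 * 0.5),
            0.0063 * exp(2.65 * 0.7), 0.0063 * exp(2.65 * 0.9))
  amps[1:2] <- 0.0001
  expect_error(fit_envelope(amplitude_profile(st, amps)),
               "nonpositive stage-2 residuals")
})

test_that("full body-wave fit: round trip across all reference speeds", {
  tab <- bodywave_reference()
  for (i in seq_len(nrow(tab))) {
    p <- bodywave_reference(tab$speed_bl[i])
    trk <- make_track(p, duration = max(4, 2.5 / p$f * 2))
    fit <- fit_bodywave(trk)
    q <- fit$params
    expect_equal(q$a, p$a, tolerance = 1e-6)
    expect_equal(q$b, p$b, tolerance = 1e-6)
    expect_equal(q$c, p$c, tolerance = 1e-6)
    expect_equal(q$d, p$d, tolerance = 1e-6)
    expect_equal(q$lambda, p$lambda, tolerance = 1e-6)
    expect_equal(q$f, p$f, tolerance = 1e-6)
    expect_gt(fit$r2, 1 - 1e-8)
  }
})

test_that("fit quality degrades gracefully with digitization noise", {
  trk <- make_track(noise_sd = 0.002, seed = 7)
  fit <- fit_bodywave(trk)
  expect_lt(fit$r2, 1)
  expect_gt(fit$r2, 0.9)
  ## flat track propagates an error
  z <- midline_track(fit_stations, seq(0, 2, by = 1 / 60),
                     matrix(0, 121, length(fit_stations)))
  expect_error(fit_bodywave(z), "flat")
})

test_that("track and parameter serialization round-trip", {
  trk <- make_track(noise_sd = 0.001, seed = 3)
  csv <- tempfile(fileext = ".csv")
  write_track_csv(trk, csv)
  back <- read_track_csv(csv)
  expect_equal(back$stations, trk$stations)
  expect_equal(back$displacements, trk$displacements, tolerance = 1e-12,
               ignore_attr = TRUE)
  fit <- fit_bodywave(make_track())
  js <- tempfile(fileext = ".json")
  write_bodywave_json(fit, js)
  obj <- jsonlite::read_json(js)
  expect_equal(obj$lambda_bl, fit$params$lambda, tolerance = 1e-9)
  expect_equal(obj$f_hz, fit$params$f, tolerance = 1e-9)
  expect_named(obj, c("a", "b", "c", "d", "lambda_bl", "f_hz", "r2"))
})
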