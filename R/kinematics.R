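#' Body-wave parameters of subcarangiform swimming
#'
#' Container for the six constants of the swimming-motion function
#' \deqn{h(x,t) = (a e^{bx} + c e^{dx}) \cos\{2\pi(ft - x/\lambda)\},}
#' where \eqn{x} is the body-axis position in body lengths (BL) measured from
#' the snout opposite to the direction of travel, and \eqn{h} is the lateral
#' displacement in BL.  The envelope is the sum of a head term \eqn{a e^{bx}}
#' (decaying tailward, \eqn{b < 0} in fitted data) and a tail term
#' \eqn{c e^{dx}} that grows toward the caudal fin.
#'
#' @param a head-term coefficient (BL), \eqn{a \ge 0}.
#' @param b head-term exponent (per BL).
#' @param c tail-term coefficient (BL), \eqn{c > 0}.
#' @param d tail-term exponent (per BL), \eqn{d > 0}.
#' @param lambda wavelength of the traveling wave (BL), \eqn{> 0}.
#' @param f tail-beat frequency (Hz), \eqn{> 0}.
#' @param phase0 global phase offset (rad); 0 for the canonical wave.
#'
#' @return An object of class `bodywave_params`.
#' @examples
#' p <- bodywave_params(a = 0.0187, b = -5.96, c = 0.0063, d = 2.65,
#'                      lambda = 1.05, f = 2.12)
#' evaluate_displacement(0, 0, p)  # = a + c at the snout, t = 0
#' @export
bodywave_params <- function(a, b, c, d, lambda, f, phase0 = 0) {
  vals <- c(a = a, b = b, c = c, d = d, lambda = lambda, f = f,
            phase0 = phase0)
  if (!all(is.finite(vals)))
    stop("all body-wave parameters must be finite")
  if (a < 0) stop("'a' must be nonnegative")
  if (c < 0) stop("'c' must be nonnegative")
  if (lambda <= 0) stop("'lambda' must be positive")
  if (f <= 0) stop("'f' must be positive")
  structure(list(a = a, b = b, c = c, d = d, lambda = lambda, f = f,
                 phase0 = phase0),
            class = "bodywave_params")
}

#' @export
print.bodywave_params <- function(x, ...) {
  cat("Body-wave parameters (subcarangiform traveling wave)\n")
  cat(sprintf("  envelope: %.4g*exp(%.4g x) + %.4g*exp(%.4g x)  [BL]\n",
              x$a, x$b, x$c, x$d))
  cat(sprintf("  wavelength: %.4g BL   frequency: %.4g Hz\n", x$lambda, x$f))
  if (x$phase0 != 0) cat(sprintf("  phase offset: %.4g rad\n", x$phase0))
  invisible(x)
}

#' Published body-wave constants for a station-holding Biwa salmon
#'
#' Fitted constants of the swimming-motion function at five steady swimming
#' speeds, obtained from 60-fps video digitization of body-axis landmarks of
#' a Biwa salmon (*Oncorhynchus* sp., body length 0.397 m) holding station in
#' a circulating flume.  These serve as reference kinematics for simulations
#' and as ground truth for synthetic-track round trips.
#'
#' @param speed_bl optional swimming speed in BL/s; one of 1.01, 1.26, 1.52,
#'   1.76, 2.02.  If given, returns a [bodywave_params] object for that row;
#'   otherwise returns the full data frame.
#' @return A data frame (`speed_bl`, `a`, `b`, `c`, `d`, `lambda`, `f`) or a
#'   `bodywave_params` object.
#' @export
bodywave_reference <- function(speed_bl = NULL) {
  tab <- data.frame(
    speed_bl = c(1.01, 1.26, 1.52, 1.76, 2.02),
    a      = c(0.0105, 0.0175, 0.0187, 0.0173, 0.0235),
    b      = c(-5.13, -5.30, -5.96, -4.01, -4.51),
    c      = c(0.00440, 0.00460, 0.00630, 0.00490, 0.00530),
    d      = c(2.69, 2.72, 2.65, 2.73, 2.86),
    lambda = c(1.00, 1.02, 1.05, 1.03, 1.03),
    f      = c(2.00, 1.89, 2.12, 2.55, 2.55))
  if (is.null(speed_bl)) return(tab)
  i <- match(TRUE, abs(tab$speed_bl - speed_bl) < 1e-6)
  if (is.na(i))
    stop("no reference kinematics at speed ", speed_bl,
         " BL/s; available: ", paste(tab$speed_bl, collapse = ", "))
  with(tab[i, ], bodywave_params(a, b, c, d, lambda, f))
}

#' Evaluate the lateral displacement of the body wave
#'
#' @param x body-axis position (BL), \eqn{\ge 0}; vectorized.
#' @param t time (s); vectorized (recycled against `x`).
#' @param params a [bodywave_params] object.
#' @return Lateral displacement \eqn{h(x,t)} in BL.
#' @export
evaluate_displacement <- function(x, t, params) {
  stopifnot(inherits(params, "bodywave_params"))
  if (!all(is.finite(x)) || !all(is.finite(t)))
    stop("non-finite 'x' or 't'")
  if (any(x < 0)) stop("'x' must be nonnegative")
  envelope(x, params) *
    cos(2 * pi * (params$f * t - x / params$lambda) + params$phase0)
}

#' Lateral velocity of the body wave (analytic time derivative)
#'
#' @inheritParams evaluate_displacement
#' @return \eqn{\partial h/\partial t} in BL/s.
#' @export
displacement_velocity <- function(x, t, params) {
  stopifnot(inherits(params, "bodywave_params"))
  -2 * pi * params$f * envelope(x, params) *
    sin(2 * pi * (params$f * t - x / params$lambda) + params$phase0)
}

#' Amplitude envelope of the body wave
#'
#' The position-dependent amplitude \eqn{a e^{bx} + c e^{dx}} (BL), equal to
#' the maximum over time of the absolute lateral displacement at `x`.
#'
#' @inheritParams evaluate_displacement
#' @return Envelope amplitude in BL.
#' @export
envelope <- function(x, params) {
  stopifnot(inherits(params, "bodywave_params"))
  if (!all(is.finite(x))) stop("non-finite 'x'")
  if (any(x < 0)) stop("'x' must be nonnegative")
  params$a * exp(params$b * x) + params$c * exp(params$d * x)
}

#' Midline track: lateral displacement at fixed body-axis stations
#'
#' A stand-in for digitized-video time series: lateral displacement sampled
#' at fixed body-axis stations of a station-holding fish, at a uniform frame
#' rate.
#'
#' @param stations body-axis positions (BL, from the snout), strictly
#'   increasing, all \eqn{\ge 0}.
#' @param times sample instants (s), strictly increasing, uniformly spaced.
#' @param displacements numeric matrix, `length(times)` rows by
#'   `length(stations)` columns, lateral displacement (BL).
#' @param point_ids optional landmark labels, one per station.
#' @return An object of class `midline_track`.
#' @export
midline_track <- function(stations, times, displacements, point_ids = NULL) {
  stations <- as.numeric(stations); times <- as.numeric(times)
  displacements <- as.matrix(displacements)
  if (any(diff(stations) <= 0)) stop("'stations' must be strictly increasing")
  if (any(stations < 0)) stop("'stations' must be nonnegative")
  if (length(times) < 2 || any(diff(times) <= 0))
    stop("'times' must be strictly increasing")
  dt <- diff(times)
  if (max(dt) - min(dt) > 1e-8 * mean(dt))
    stop("'times' must be uniformly spaced")
  if (!all(dim(displacements) == c(length(times), length(stations))))
    stop("'displacements' must be length(times) x length(stations)")
  if (!all(is.finite(displacements))) stop("non-finite displacements")
  if (!is.null(point_ids) && length(point_ids) != length(stations))
    stop("'point_ids' must match 'stations'")
  structure(list(stations = stations, times = times,
                 displacements = displacements, point_ids = point_ids),
            class = "midline_track")
}

#' @export
print.midline_track <- function(x, ...) {
  cat(sprintf(paste0("Midline track: %d stations x %d frames ",
                     "(%.4g s at %.4g fps)\n"),
              length(x$stations), length(x$times),
              diff(range(x$times)), 1 / mean(diff(x$times))))
  cat("  stations (BL):", paste(signif(x$stations, 4), collapse = " "), "\n")
  invisible(x)
}

#' Amplitude profile along the body axis
#'
#' @param stations body-axis positions (BL), increasing.
#' @param amplitudes half peak-to-peak lateral excursion at each station (BL).
#' @return An object of class `amplitude_profile`.
#' @export
amplitude_profile <- function(stations, amplitudes) {
  if (length(stations) != length(amplitudes))
    stop("'stations' and 'amplitudes' must have the same length")
  if (any(amplitudes < 0)) stop("amplitudes must be nonnegative")
  if (any(diff(stations) <= 0)) stop("'stations' must be strictly increasing")
  structure(list(stations = as.numeric(stations),
                 amplitudes = as.numeric(amplitudes)),
            class = "amplitude_profile")
}

## Per-station least-squares sinusoid fit at a fixed frequency.
## Returns C, S such that h ~ C cos(2 pi f t) + S sin(2 pi f t), plus SSE.
sinusoid_fit <- function(track, f) {
  w <- 2 * pi * f
  X <- cbind(cos(w * track$times), sin(w * track$times))
  cf <- qr.coef(qr(X), track$displacements)   # 2 x n_stations
  res <- track$displacements - X %*% cf
  list(C = cf[1, ], S = cf[2, ], sse = sum(res^2))
}

#' Estimate the common tail-beat frequency of a midline track
#'
#' Finds the dominant oscillation frequency shared across stations: an initial
#' estimate from the peak of the station-averaged periodogram is refined by
#' nonlinear least squares (a golden-section search on the pooled residual sum
#' of squares of per-station single-frequency sinusoid fits).
#'
#' @param track a [midline_track].
#' @return Frequency in Hz.
#' @export
estimate_frequency <- function(track) {
  stopifnot(inherits(track, "midline_track"))
  h <- sweep(track$displacements, 2, colMeans(track$displacements))
  if (sum(h^2) == 0) stop("flat track: no oscillation to estimate")
  n <- nrow(h)
  dt <- mean(diff(track$times))
  pw <- rowSums(Mod(stats::mvfft(h))^2)
  nf <- floor(n / 2)
  freqs <- (seq_len(nf)) / (n * dt)        # exclude the DC bin
  k <- which.max(pw[2:(nf + 1)])
  f0 <- freqs[k]
  df <- 1 / (n * dt)
  lo <- max(f0 - 1.5 * df, 0.25 * df)
  hi <- min(f0 + 1.5 * df, 1 / (2 * dt))
  opt <- stats::optimize(function(f) sinusoid_fit(track, f)$sse,
                         interval = c(lo, hi), tol = 1e-12)
  f_hat <- opt$minimum
  if (diff(range(track$times)) < 2 / f_hat)
    stop("track shorter than 2 oscillation periods (f ~ ",
         signif(f_hat, 3), " Hz)")
  f_hat
}

#' Estimate per-station oscillation amplitudes
#'
#' Half peak-to-peak lateral excursion at each station, taken as the amplitude
#' of the best-fit single-frequency sinusoid (least squares) at the common
#' dominant frequency.
#'
#' @param track a [midline_track].
#' @param f common frequency (Hz); estimated with [estimate_frequency()]
#'   when `NULL`.
#' @return An [amplitude_profile].
#' @export
estimate_point_amplitudes <- function(track, f = NULL) {
  stopifnot(inherits(track, "midline_track"))
  if (all(track$displacements == 0))
    return(amplitude_profile(track$stations,
                             rep(0, length(track$stations))))
  if (is.null(f)) f <- estimate_frequency(track)
  if (diff(range(track$times)) < 2 / f)
    stop("track shorter than 2 oscillation periods")
  sf <- sinusoid_fit(track, f)
  amplitude_profile(track$stations, sqrt(sf$C^2 + sf$S^2))
}

## Per-station phase psi such that h ~ A cos(2 pi f t + psi).
station_phases <- function(track, f) {
  sf <- sinusoid_fit(track, f)
  list(psi = -atan2(sf$S, sf$C), amp = sqrt(sf$C^2 + sf$S^2))
}

#' Estimate the traveling-wave wavelength by phase regression
#'
#' Fits per-station sinusoid phases at the common frequency, unwraps them
#' tailward (a traveling wave toward the tail has phase decreasing with
#' station position), and regresses phase on station position; the slope is
#' \eqn{-2\pi/\lambda}.
#'
#' @param track a [midline_track].
#' @param f common frequency (Hz).
#' @param min_amplitude stations with fitted amplitude at or below this value
#'   (BL) are excluded from the regression.
#' @return Wavelength in BL.  A zero phase slope (all stations in phase, a
#'   standing wave) yields `Inf` with attribute `standing_wave = TRUE`.
#' @export
estimate_wavelength <- function(track, f, min_amplitude = 1e-9) {
  stopifnot(inherits(track, "midline_track"))
  ph <- station_phases(track, f)
  use <- ph$amp > min_amplitude
  if (sum(use) < 3)
    stop("need >= 3 stations with nonzero amplitude (have ", sum(use), ")")
  x <- track$stations[use]
  psi <- signal::unwrap(ph$psi[use])
  slope <- stats::cov(x, psi) / stats::var(x)
  if (abs(slope) < 1e-8)
    return(structure(Inf, standing_wave = TRUE))
  -2 * pi / slope
}

## Phase regression returning slope and intercept (for reconstruction).
phase_regression <- function(track, f, min_amplitude = 1e-9) {
  ph <- station_phases(track, f)
  use <- ph$amp > min_amplitude
  x <- track$stations[use]
  psi <- signal::unwrap(ph$psi[use])
  cf <- stats::coef(stats::lm(psi ~ x))
  list(intercept = unname(cf[1]), slope = unname(cf[2]))
}

#' Two-stage exponential fit of the amplitude envelope
#'
#' Fits \eqn{a e^{bx} + c e^{dx}} to an amplitude profile by the two-stage
#' log-linear procedure: stage 1 fits the tail term \eqn{(c, d)} by
#' least squares on log-amplitude at stations \eqn{x > } `tail_min`; stage 2
#' subtracts \eqn{c e^{dx}} from the amplitudes at stations
#' \eqn{x < } `head_max` and fits \eqn{(a, b)} on the log of the positive
#' residuals.  With `iterations > 1` stage 1 is repeated on the amplitudes
#' minus the current head term until the largest relative parameter change
#' falls below `tol`; `iterations = 1` is the literal one-pass procedure.
#'
#' @param profile an [amplitude_profile].
#' @param iterations iteration cap; 1 reproduces the one-pass procedure.
#' @param head_max stations below this position (BL) feed stage 2.
#' @param tail_min stations above this position (BL) feed stage 1.
#' @param tol relative-change convergence tolerance for iterated fits.
#' @return A list with `a`, `b`, `c`, `d`, `iterations_used`, `converged`.
#' @export
fit_envelope <- function(profile, iterations = 50, head_max = 0.25,
                         tail_min = 0.4, tol = 1e-10) {
  stopifnot(inherits(profile, "amplitude_profile"))
  x <- profile$stations; amp <- profile$amplitudes
  tail_i <- which(x > tail_min)
  head_i <- which(x < head_max)
  if (length(tail_i) < 2)
    stop("need >= 2 stations with x > ", tail_min, " (have ",
         length(tail_i), ")")
  if (length(head_i) == 1)
    stop("need >= 2 stations with x < ", head_max,
         " (or none, for a pure tail-term fit)")
  if (any(amp[tail_i] <= 0))
    stop("nonpositive amplitudes at tail stations ",
         paste(signif(x[tail_i][amp[tail_i] <= 0], 3), collapse = ", "))

  loglin <- function(xs, ys) {   # ys > 0; returns coef k, expo m of k*e^{mx}
    cf <- stats::coef(stats::lm(log(ys) ~ xs))
    c(exp(unname(cf[1])), unname(cf[2]))
  }

  a <- 0; b <- 0; cc <- NA_real_; d <- NA_real_
  used <- 0; converged <- FALSE
  for (it in seq_len(max(1, iterations))) {
    used <- it
    tail_amp <- amp[tail_i] - a * exp(b * x[tail_i])
    if (any(tail_amp <= 0))
      stop("head-term subtraction left nonpositive tail amplitudes at x = ",
           paste(signif(x[tail_i][tail_amp <= 0], 3), collapse = ", "))
    cd <- loglin(x[tail_i], tail_amp)
    cc_new <- cd[1]; d_new <- cd[2]

    a_new <- 0; b_new <- 0
    if (length(head_i) >= 2) {
      r <- amp[head_i] - cc_new * exp(d_new * x[head_i])
      if (all(abs(r) < 1e-12 * pmax(amp[head_i], 1e-12))) {
        a_new <- 0; b_new <- 0       # no detectable head term
      } else if (any(r <= 0)) {
        stop("nonpositive stage-2 residuals at head stations x = ",
             paste(signif(x[head_i][r <= 0], 3), collapse = ", "),
             "; head term not resolvable")
      } else {
        ab <- loglin(x[head_i], r)
        a_new <- ab[1]; b_new <- ab[2]
      }
    }

    delta <- max(abs(c(cc_new - cc, d_new - d, a_new - a, b_new - b)) /
                   pmax(abs(c(cc_new, d_new, a_new, b_new)), 1e-12),
                 na.rm = TRUE)
    a <- a_new; b <- b_new; cc <- cc_new; d <- d_new
    if (!is.na(delta) && delta < tol) { converged <- TRUE; break }
  }
  list(a = a, b = b, c = cc, d = d, iterations_used = used,
       converged = converged || iterations == 1)
}

#' Fit the full body-wave model to a midline track
#'
#' Composes the component estimators: common frequency, per-station
#' amplitudes, wavelength by phase regression, and the two-stage envelope
#' fit; reports the pooled goodness of fit \eqn{R^2 = 1 - SSE/SST} between
#' the track and the reconstructed \eqn{h(x,t)} (a global phase offset is
#' estimated from the phase-regression intercept).
#'
#' @param track a [midline_track].
#' @param iterations envelope-fit iteration cap (see [fit_envelope()]).
#' @param ... passed to [fit_envelope()].
#' @return A list of class `bodywave_fit`: `params` ([bodywave_params]),
#'   `r2`, `frequency_hz`, `wavelength_bl`, `amplitude_profile`,
#'   `envelope_fit`.
#' @export
fit_bodywave <- function(track, iterations = 50, ...) {
  stopifnot(inherits(track, "midline_track"))
  f <- estimate_frequency(track)
  prof <- estimate_point_amplitudes(track, f)
  lambda <- estimate_wavelength(track, f)
  if (!is.finite(lambda))
    stop("standing wave detected: wavelength is not finite")
  env_fit <- fit_envelope(prof, iterations = iterations, ...)
  pr <- phase_regression(track, f)
  ## model phase: psi(x) = phase0 - 2 pi x / lambda; intercept estimates phase0
  params <- bodywave_params(env_fit$a, env_fit$b, env_fit$c, env_fit$d,
                            lambda, f, phase0 = pr$intercept)
  pred <- outer(track$times, track$stations,
                function(t, x) evaluate_displacement(x, t, params))
  sse <- sum((track$displacements - pred)^2)
  sst <- sum((track$displacements - mean(track$displacements))^2)
  structure(list(params = params, r2 = 1 - sse / sst,
                 frequency_hz = f, wavelength_bl = lambda,
                 amplitude_profile = prof, envelope_fit = env_fit),
            class = "bodywave_fit")
}

#' @export
print.bodywave_fit <- function(x, ...) {
  cat("Body-wave fit\n")
  print(x$params)
  cat(sprintf("  R-squared (pooled): %.5f\n", x$r2))
  invisible(x)
}

#' Read a midline track from CSV
#'
#' Expects columns `time_s`, `point_id`, `x_bl`, `y_bl`: one row per landmark
#' per frame, `x_bl` the (fixed) body-axis station and `y_bl` the lateral
#' displacement, both in BL.
#'
#' @param path CSV file path.
#' @return A [midline_track].
#' @export
read_track_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "point_id", "x_bl", "y_bl")
  if (!all(need %in% names(df)))
    stop("track CSV must have columns ", paste(need, collapse = ", "))
  st <- unique(df[, c("point_id", "x_bl")])
  st <- st[order(st$x_bl), ]
  times <- sort(unique(df$time_s))
  disp <- matrix(NA_real_, length(times), nrow(st))
  key_t <- match(df$time_s, times)
  key_s <- match(df$point_id, st$point_id)
  disp[cbind(key_t, key_s)] <- df$y_bl
  if (anyNA(disp)) stop("track CSV is not a complete station x frame grid")
  midline_track(st$x_bl, times, disp, point_ids = st$point_id)
}

#' Write a midline track to CSV
#'
#' @param track a [midline_track].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(track, path) {
  ids <- track$point_ids
  if (is.null(ids)) ids <- paste0("s", seq_along(track$stations))
  df <- data.frame(
    time_s = rep(track$times, times = length(track$stations)),
    point_id = rep(ids, each = length(track$times)),
    x_bl = rep(track$stations, each = length(track$times)),
    y_bl = as.vector(track$displacements))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize fitted body-wave parameters to JSON
#'
#' Writes keys `a`, `b`, `c`, `d`, `lambda_bl`, `f_hz`, `r2`.
#'
#' @param fit a `bodywave_fit` (or [bodywave_params], with `r2 = NA`).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_bodywave_json <- function(fit, path) {
  if (inherits(fit, "bodywave_fit")) {
    p <- fit$params; r2 <- fit$r2
  } else if (inherits(fit, "bodywave_params")) {
    p <- fit; r2 <- NA_real_
  } else stop("'fit' must be a bodywave_fit or bodywave_params")
  obj <- list(a = p$a, b = p$b, c = p$c, d = p$d,
              lambda_bl = p$lambda, f_hz = p$f, r2 = r2)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
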