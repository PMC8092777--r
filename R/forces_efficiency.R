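#' Decompose simulated surface forces into thrust, drag, and lateral parts
#'
#' Per element and timestep: the thrust component \eqn{F_{Ti}} is the
#' thrust-direction (-x) part of the pressure force where it points in the
#' thrust direction; the pressure-drag component accumulates the opposite
#' (+x) part; friction is carried separately and counts toward drag; the
#' lateral component \eqn{F_{Si}} is the lateral force the element exerts on
#' the fluid (the reaction to the pressure force), so that the lateral power
#' \eqn{\sum F_{Si} v_i} is the power expended against the fluid.  The
#' decomposition is exact: `drag_pressure - thrust` recombines to the x
#' pressure force and `-lateral` to the y pressure force.
#'
#' @param result a `sim_result` from [simulate_swimmers()].
#' @param body body index (1 or 2).
#' @return A list of class `element_forces` with per-step-by-panel matrices
#'   `thrust`, `drag_pressure`, `lateral`, `friction_x`, `friction_y`,
#'   element velocities `u` (travel-direction, m/s) and `v` (lateral, m/s),
#'   plus `times`, `period`, `transient_periods`.
#' @export
decompose_forces <- function(result, body = 1) {
  stopifnot(inherits(result, "sim_result"))
  if (body < 1 || body > result$n_bodies) stop("no body ", body)
  b <- result$bodies[[body]]
  structure(list(
    thrust = pmax(-b$fp_x, 0),
    drag_pressure = pmax(b$fp_x, 0),
    lateral = -b$fp_y,
    friction_x = b$ff_x,
    friction_y = b$ff_y,
    u = matrix(result$u_element, nrow(b$fp_x), ncol(b$fp_x)),
    v = b$v_el,
    times = result$times, period = result$period,
    transient_periods = result$config$transient_periods),
    class = "element_forces")
}

## Index of post-transient steps covering an integer number of periods.
analysis_window <- function(times, period, transient_periods, dt) {
  t0 <- transient_periods * period
  avail <- max(times) + dt - t0
  n_per <- floor(avail / period + 1e-9)
  if (n_per < 1)
    stop("window shorter than one period after discarding ",
         transient_periods, " transient periods")
  keep <- which(times >= t0 - 1e-12 & times < t0 + n_per * period - 1e-12)
  attr(keep, "n_periods") <- n_per
  keep
}

#' Thrust and drag time series and period averages
#'
#' Sums the decomposed element forces per timestep; time averages are taken
#' over an integer number of tail-beat periods after the transient discard.
#'
#' @param x an `element_forces` object or a `sim_result` (body 1 taken).
#' @param body body index when `x` is a `sim_result`.
#' @return A list of class `force_series`: `times`, `F_T`, `F_D`, `F_lat`
#'   (instantaneous, N), `F_T_mean`, `F_D_mean`, `ratio`, `n_periods_avg`.
#' @export
thrust_drag_series <- function(x, body = 1) {
  if (inherits(x, "sim_result")) x <- decompose_forces(x, body)
  stopifnot(inherits(x, "element_forces"))
  FT <- rowSums(x$thrust)
  FDp <- rowSums(x$drag_pressure)
  FDf <- rowSums(x$friction_x)
  Flat <- rowSums(-x$lateral)            # fluid-on-body lateral force
  dt <- mean(diff(x$times))
  keep <- analysis_window(x$times, x$period, x$transient_periods, dt)
  FT_m <- mean(FT[keep]); FD_m <- mean(FDp[keep] + FDf[keep])
  structure(list(times = x$times, F_T = FT, F_D = FDp + FDf, F_lat = Flat,
                 F_T_mean = FT_m, F_D_mean = FD_m,
                 ratio = FT_m / FD_m,
                 n_periods_avg = attr(keep, "n_periods"),
                 window = keep),
            class = "force_series")
}

#' @export
print.force_series <- function(x, ...) {
  cat(sprintf(paste0("Force series: <F_T> = %.4g N, <F_D> = %.4g N, ",
                     "F_T/F_D = %.4g (%d-period average)\n"),
              x$F_T_mean, x$F_D_mean, x$ratio, x$n_periods_avg))
  invisible(x)
}

#' Froude propulsive efficiency
#'
#' \eqn{\eta = P_T / (P_T + P_S)} with the thrust power
#' \eqn{P_T = \overline{\sum_i F_{Ti} u_i}} (positively thrusting elements
#' only, as the definition is written) and the lateral power
#' \eqn{P_S = \overline{\sum_i F_{Si} v_i}}, both time-averaged over an
#' integer number of periods after the transient discard.
#'
#' @param x an `element_forces` object or a `sim_result`.
#' @param body body index when `x` is a `sim_result`.
#' @return A list of class `efficiency_result`: `eta`, `P_T` (W), `P_S` (W),
#'   `n_periods_avg`.
#' @export
froude_efficiency <- function(x, body = 1) {
  if (inherits(x, "sim_result")) x <- decompose_forces(x, body)
  stopifnot(inherits(x, "element_forces"))
  PT_t <- rowSums(x$thrust * x$u)
  PS_t <- rowSums(x$lateral * x$v)
  dt <- mean(diff(x$times))
  keep <- analysis_window(x$times, x$period, x$transient_periods, dt)
  PT <- mean(PT_t[keep]); PS <- mean(PS_t[keep])
  if (PT + PS <= 0)
    stop("unphysical window: P_T + P_S = ", signif(PT + PS, 3), " W <= 0")
  structure(list(eta = PT / (PT + PS), P_T = PT, P_S = PS,
                 n_periods_avg = attr(keep, "n_periods")),
            class = "efficiency_result")
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf("Froude efficiency: eta = %.4f (P_T = %.4g W, P_S = %.4g W)\n",
              x$eta, x$P_T, x$P_S))
  invisible(x)
}

#' Froude efficiency from raw element histories
#'
#' Computes \eqn{\eta} directly from caller-supplied element thrust and
#' lateral force histories and element velocities; used for hand-checkable
#' toy cases and by [froude_efficiency()] internally-equivalent logic.
#'
#' @param thrust matrix (steps x elements) of thrust-direction forces (N).
#' @param lateral matrix of lateral body-on-fluid forces (N).
#' @param u matrix of travel-direction element velocities (m/s).
#' @param v matrix of lateral element velocities (m/s).
#' @return A list with `eta`, `P_T`, `P_S`.
#' @export
froude_efficiency_raw <- function(thrust, lateral, u, v) {
  PT <- mean(rowSums(as.matrix(thrust) * as.matrix(u)))
  PS <- mean(rowSums(as.matrix(lateral) * as.matrix(v)))
  if (PT + PS <= 0) stop("P_T + P_S <= 0")
  list(eta = PT / (PT + PS), P_T = PT, P_S = PS)
}

#' Wake transect: apparent flow speed behind the swimmers
#'
#' Samples the time-averaged flow speed along a line parallel to the x axis
#' through the midpoint of the snouts (for a pair this is the symmetry
#' mid-line; for a solitary fish, set `solitary = TRUE` to sample behind the
#' single body's midline).  Averaged over the final `avg_periods` tail-beat
#' periods.
#'
#' @param result a `sim_result`.
#' @param range_L sampling interval as distance from the snout-midpoint
#'   origin, in model lengths L.
#' @param n_samples number of sample points.
#' @param solitary allow a single-body transect along the body midline.
#' @param avg_periods number of final periods to average over.
#' @return A list of class `wake_transect`: `distance_L`, `speed_bl`
#'   (apparent flow speed, BL/s), `ratio` (to inlet speed).
#' @export
wake_transect <- function(result, range_L = c(0.5, 2), n_samples = 31,
                          solitary = FALSE, avg_periods = 2) {
  stopifnot(inherits(result, "sim_result"))
  if (result$n_bodies == 1 && !solitary)
    stop("single-body result: use solitary = TRUE for the solitary ",
         "transect variant")
  geom <- result$config$geom
  L <- geom$length
  dist_L <- seq(range_L[1], range_L[2], length.out = n_samples)
  pts <- cbind(dist_L * L, 0)            # origin = snout midpoint at (0, 0)
  steps_per <- result$config$steps_per_period
  last <- result$n_steps - seq_len(min(avg_periods * steps_per,
                                       result$n_steps)) + 1L
  last <- last[seq(1, length(last), by = max(1L, length(last) %/% 60L))]
  acc <- matrix(0, n_samples, 2); cnt <- 0
  for (s in last) {
    fl <- sample_flow(result, pts, result$times[s])
    acc <- acc + cbind(fl$u, fl$v); cnt <- cnt + 1
  }
  um <- acc[, 1] / cnt; vm <- acc[, 2] / cnt
  speed <- sqrt(um^2 + vm^2)
  U <- result$u_element
  structure(list(distance_L = dist_L,
                 speed_bl = speed / geom$body_length,
                 ratio = speed / U,
                 u_mean = um, v_mean = vm),
            class = "wake_transect")
}

#' Separation-by-phase sweep of pair swimming efficiency
#'
#' For each combination of separation and phase relation: optionally
#' rebalance the tail-beat frequency to the self-propelled state, simulate,
#' and compute the Froude efficiency; a solitary reference run is included.
#' Individual cell failures are recorded and the sweep continues.
#'
#' @param separations pair separations in model lengths L.
#' @param phases subset of `c("inphase", "antiphase")`.
#' @param base a [sim_config] (its `n_fish`/`separation_L`/`phase_relation`
#'   are overridden per cell).
#' @param fluid a [fluid_properties].
#' @param rebalance rebalance the frequency per cell (and for the
#'   reference)?
#' @param bracket frequency bracket (Hz) for rebalancing.
#' @param verbose print per-cell progress.
#' @return A data frame of class `sweep_table`: one row per cell plus a
#'   solitary reference row (`separation_L = Inf`), with columns
#'   `separation_L`, `phase`, `f_hz`, `F_T`, `F_D`, `ratio`, `P_T`, `P_S`,
#'   `eta` (focal body 1), `eta_pooled`, `status`.
#' @export
parallel_sweep <- function(separations, phases = c("inphase", "antiphase"),
                           base, fluid = fluid_properties(),
                           rebalance = TRUE, bracket = c(1, 5),
                           verbose = FALSE) {
  stopifnot(inherits(base, "sim_config"))
  phases <- match.arg(phases, c("inphase", "antiphase"), several.ok = TRUE)

  run_cell <- function(cfg) {
    fq <- cfg$params$f
    if (rebalance) {
      fq <- as.numeric(balance_frequency(cfg, fluid, bracket = bracket))
      p <- cfg$params
      cfg$params <- bodywave_params(p$a, p$b, p$c, p$d, p$lambda, fq,
                                    phase0 = p$phase0)
    }
    res <- simulate_swimmers(cfg, fluid)
    ts <- thrust_drag_series(res, 1)
    eff1 <- froude_efficiency(res, 1)
    if (cfg$n_fish == 2) {
      f1 <- decompose_forces(res, 1); f2 <- decompose_forces(res, 2)
      pooled <- froude_efficiency_raw(
        cbind(f1$thrust, f2$thrust), cbind(f1$lateral, f2$lateral),
        cbind(f1$u, f2$u), cbind(f1$v, f2$v))$eta
    } else pooled <- eff1$eta
    list(f_hz = fq, F_T = ts$F_T_mean, F_D = ts$F_D_mean,
         ratio = ts$ratio, P_T = eff1$P_T, P_S = eff1$P_S,
         eta = eff1$eta, eta_pooled = pooled)
  }

  cells <- list(list(separation_L = Inf, phase = "solitary"))
  for (sp in separations) for (ph in phases)
    cells[[length(cells) + 1]] <- list(separation_L = sp, phase = ph)

  rows <- lapply(cells, function(cell) {
    cfg <- base
    if (is.finite(cell$separation_L)) {
      cfg$n_fish <- 2
      cfg$separation_L <- cell$separation_L
      cfg$phase_relation <- cell$phase
    } else {
      cfg$n_fish <- 1; cfg$separation_L <- NULL
    }
    if (verbose)
      message("sweep cell: separation ", cell$separation_L, " L, ",
              cell$phase)
    out <- tryCatch(c(run_cell(cfg), status = "ok"),
                    error = function(e)
                      list(f_hz = NA_real_, F_T = NA_real_, F_D = NA_real_,
                           ratio = NA_real_, P_T = NA_real_, P_S = NA_real_,
                           eta = NA_real_, eta_pooled = NA_real_,
                           status = conditionMessage(e)))
    data.frame(separation_L = cell$separation_L, phase = cell$phase,
               f_hz = out$f_hz, F_T = out$F_T, F_D = out$F_D,
               ratio = out$ratio, P_T = out$P_T, P_S = out$P_S,
               eta = out$eta, eta_pooled = out$eta_pooled,
               status = out$status)
  })
  tab <- do.call(rbind, rows)
  class(tab) <- c("sweep_table", class(tab))
  tab
}

#' Plot pair swimming efficiency against separation
#'
#' @param tab a `sweep_table` from [parallel_sweep()].
#' @param path optional PNG output path; plots to the active device when
#'   `NULL`.
#' @return `path` (or `NULL`), invisibly.
#' @export
plot_sweep <- function(tab, path = NULL) {
  stopifnot(inherits(tab, "sweep_table"))
  if (!is.null(path)) {
    grDevices::png(path, width = 800, height = 600)
    on.exit(grDevices::dev.off())
  }
  ok <- tab$status == "ok" & is.finite(tab$separation_L)
  ref <- tab$eta[tab$phase == "solitary"]
  graphics::plot(NA, xlim = range(tab$separation_L[ok]),
                 ylim = range(c(tab$eta[ok], ref), na.rm = TRUE),
                 xlab = "separation (L)", ylab = "Froude efficiency")
  for (ph in c("inphase", "antiphase")) {
    sel <- ok & tab$phase == ph
    if (!any(sel)) next
    o <- order(tab$separation_L[sel])
    graphics::lines(tab$separation_L[sel][o], tab$eta[sel][o],
                    lty = if (ph == "inphase") 1 else 2, type = "b")
  }
  if (length(ref))
    graphics::abline(h = ref, col = "grey50", lty = 3)
  graphics::legend("bottomright",
                   legend = c("inphase", "antiphase", "solitary"),
                   lty = c(1, 2, 3))
  invisible(path)
}
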