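#' Fluid properties
#'
#' @param density fluid density (kg/m^3), default 998 (water at 20 C).
#' @param viscosity dynamic viscosity (Pa s), default 1.02e-3.
#' @param temperature temperature (C), metadata only.
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 998, viscosity = 1.02e-3,
                             temperature = 20) {
  if (density <= 0 || viscosity <= 0)
    stop("'density' and 'viscosity' must be positive")
  structure(list(density = density, viscosity = viscosity,
                 temperature = temperature), class = "fluid_properties")
}

#' Simulation configuration for the unsteady vortex solver
#'
#' Describes a solitary or parallel-pair run: inlet speed in BL/s, body
#' kinematics and geometry, lateral pair separation in model lengths L,
#' tail-beat phase relation, and solver discretization.  The solver is a
#' two-dimensional unsteady lumped-vortex panel method on the horizontal
#' midplane with a free shed wake (see the methods vignette).
#'
#' @param speed_bl inlet flow speed (BL/s).
#' @param params a [bodywave_params] (body 1; body 2 inherits it with the
#'   phase relation applied).
#' @param geom a [fish_geometry].
#' @param n_fish 1 (solitary) or 2 (parallel pair).
#' @param separation_L lateral gap between the two midlines, in model
#'   lengths L (pair only).
#' @param phase_relation `"inphase"` or `"antiphase"` (pair only).
#' @param n_panels chordwise panels per body.
#' @param steps_per_period timesteps per tail-beat period (default 100).
#' @param n_periods simulated tail-beat periods (default 8).
#' @param transient_periods periods discarded as startup transient
#'   (default 2).
#' @param wake_cap_L wake truncation distance downstream of the tail, in L;
#'   truncated circulation is retained in the conservation bookkeeping.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(speed_bl, params, geom = fish_geometry(),
                       n_fish = 1, separation_L = NULL,
                       phase_relation = c("inphase", "antiphase"),
                       n_panels = 40, steps_per_period = 100, n_periods = 8,
                       transient_periods = 2, wake_cap_L = 10) {
  stopifnot(inherits(params, "bodywave_params"),
            inherits(geom, "fish_geometry"))
  phase_relation <- match.arg(phase_relation)
  if (speed_bl <= 0) stop("'speed_bl' must be positive")
  if (!n_fish %in% c(1, 2)) stop("'n_fish' must be 1 or 2")
  if (n_fish == 2) {
    if (is.null(separation_L) || separation_L <= 0)
      stop("pair runs need a positive 'separation_L'")
  }
  if (n_panels < 8) stop("'n_panels' must be >= 8")
  if (n_periods <= transient_periods)
    stop("'n_periods' must exceed 'transient_periods'")
  structure(list(speed_bl = speed_bl, params = params, geom = geom,
                 n_fish = n_fish, separation_L = separation_L,
                 phase_relation = phase_relation, n_panels = n_panels,
                 steps_per_period = steps_per_period, n_periods = n_periods,
                 transient_periods = transient_periods,
                 wake_cap_L = wake_cap_L),
            class = "sim_config")
}

#' Reynolds number of the fish model
#'
#' \eqn{Re = \rho (U \times BL) L / \mu}: the inlet speed in BL/s is
#' converted to m/s on the body-length basis; the length scale is the model
#' total length.
#'
#' @param speed_bl inlet speed (BL/s).
#' @param geom a [fish_geometry].
#' @param fluid a [fluid_properties].
#' @return Dimensionless Reynolds number.
#' @examples
#' reynolds_number(1.52)  # ~2.6e5 for the default model in water
#' @export
reynolds_number <- function(speed_bl, geom = fish_geometry(),
                            fluid = fluid_properties()) {
  if (speed_bl < 0) stop("'speed_bl' must be nonnegative")
  fluid$density * (speed_bl * geom$body_length) * geom$length /
    fluid$viscosity
}

#' Strouhal number of the undulating body
#'
#' \eqn{St = f A / U} with \eqn{A} the peak-to-peak tail-tip excursion
#' \eqn{2 \times} envelope(`x_tip`), all in BL units (BL cancels).
#'
#' @param params a [bodywave_params].
#' @param speed_bl swimming speed (BL/s).
#' @param x_tip tail-tip body-axis position (BL); default 1.13 (total length
#'   exceeds body length).
#' @return Dimensionless Strouhal number.
#' @export
strouhal_number <- function(params, speed_bl, x_tip = 1.13) {
  if (speed_bl <= 0) stop("'speed_bl' must be positive")
  params$f * 2 * envelope(x_tip, params) / speed_bl
}

#' Turbulent flat-plate friction coefficient
#'
#' \eqn{C_f = 0.074 \, Re^{-1/5}}, applied per element with the local
#' tangential velocity to model the frictional drag the inviscid solver
#' cannot resolve.
#'
#' @param Re Reynolds number (> 0); vectorized.
#' @return Dimensionless friction coefficient.
#' @export
friction_drag_coefficient <- function(Re) {
  if (any(Re <= 0)) stop("'Re' must be positive")
  0.074 * Re^(-1 / 5)
}

## Regularized induced velocity at targets from point vortices.
## core: per-source Lamb core radius (NULL = exact kernel).
induced_velocity_at <- function(tx, ty, sx, sy, gamma, core = NULL) {
  n <- length(tx); m <- length(sx)
  if (m == 0L) return(list(u = numeric(n), v = numeric(n)))
  dx <- outer(tx, sx, "-")
  dy <- outer(ty, sy, "-")
  r2 <- dx^2 + dy^2
  w <- ifelse(r2 < 1e-24, 0, 1 / r2)
  if (!is.null(core)) {
    c2 <- matrix(core^2, n, m, byrow = TRUE)
    w <- w * (1 - exp(-r2 / c2))
  }
  k <- gamma / (2 * pi)
  list(u = as.numeric(-(dy * w) %*% k),
       v = as.numeric((dx * w) %*% k))
}

## Unit influence matrices (exact kernel): velocity at targets per unit
## circulation at each source.  Returns n x m matrices Au, Av.
unit_influence <- function(tx, ty, sx, sy) {
  dx <- outer(tx, sx, "-")
  dy <- outer(ty, sy, "-")
  r2 <- dx^2 + dy^2
  w <- ifelse(r2 < 1e-24, 0, 1 / (2 * pi * r2))
  list(Au = -dy * w, Av = dx * w)
}

## Panel geometry of one body's midplane section at time t.
## shed_dist: distance behind the trailing edge (along the local tangent) at
## which the new wake vortex is released; commensurate with the per-step
## wake spacing U*dt rather than the (cosine-refined) trailing-edge panel.
body_panels <- function(cfg_body, t, shed_dist) {
  g <- cfg_body
  BL <- g$geom$body_length
  xe <- g$xe
  ye <- g$y0 + evaluate_displacement(xe / BL, t, g$params) * BL
  dx <- diff(xe); dy <- diff(ye)
  len <- sqrt(dx^2 + dy^2)
  tx <- dx / len; ty <- dy / len
  nx <- -ty; ny <- tx
  vx <- xe[-length(xe)] + 0.25 * dx
  vy <- ye[-length(ye)] + 0.25 * dy
  cx <- xe[-length(xe)] + 0.75 * dx
  cy <- ye[-length(ye)] + 0.75 * dy
  N <- length(len)
  vb <- displacement_velocity(cx / BL, t, g$params) * BL  # lateral only
  shed_x <- xe[length(xe)] + shed_dist * tx[N]
  shed_y <- ye[length(ye)] + shed_dist * ty[N]
  list(xe = xe, ye = ye, len = len, tx = tx, ty = ty, nx = nx, ny = ny,
       vx = vx, vy = vy, cx = cx, cy = cy, vb = vb,
       shed_x = shed_x, shed_y = shed_y, core = len)
}

#' Run the unsteady discrete-vortex simulation
#'
#' At each timestep the undulating midplane section(s) are deformed, the
#' no-penetration condition is enforced at collocation points by bound point
#' vortices (quarter/three-quarter lumped-vortex rule), the trailing-edge
#' Kutta condition is satisfied by shedding one point vortex per body whose
#' circulation enforces per-body Kelvin circulation conservation, the wake is
#' advected with the free-stream plus induced velocity (Lamb-core
#' regularized), surface pressure follows the unsteady Bernoulli equation,
#' and an empirical flat-plate friction force is added per element.
#'
#' The flow runs in +x; the fish swims toward -x, so thrust is the -x force
#' component and drag the +x component.  Forces are three-dimensionalized by
#' the model height.
#'
#' @param config a [sim_config].
#' @param fluid a [fluid_properties].
#' @param verbose print progress.
#' @return An object of class `sim_result` with per-step per-panel pressure
#'   and friction force components, element velocities, bound/wake vortex
#'   snapshots, per-body Kelvin residuals, and run metadata.
#' @export
simulate_swimmers <- function(config, fluid = fluid_properties(),
                              verbose = FALSE) {
  stopifnot(inherits(config, "sim_config"),
            inherits(fluid, "fluid_properties"))
  geom <- config$geom
  L <- geom$length; H <- geom$height; BL <- geom$body_length
  U <- config$speed_bl * BL
  rho <- fluid$density
  f <- config$params$f
  T_beat <- 1 / f
  dt <- T_beat / config$steps_per_period
  nsteps <- config$n_periods * config$steps_per_period
  N <- config$n_panels
  nb <- config$n_fish

  ## per-body static description; cosine clustering resolves the
  ## leading-edge pressure peak
  xe <- cosine_spacing(N, L)
  mk_body <- function(y0, phase) {
    p <- config$params
    list(geom = geom, xe = xe, y0 = y0,
         params = bodywave_params(p$a, p$b, p$c, p$d, p$lambda, p$f,
                                  phase0 = p$phase0 + phase))
  }
  if (nb == 1) {
    bodies_cfg <- list(mk_body(0, 0))
  } else {
    d <- config$separation_L * L
    amp_m <- envelope(max(xe) / BL, config$params) * BL
    if (d <= 2 * amp_m)
      stop("bodies overlap laterally: separation ", signif(d, 3),
           " m vs tail excursion envelope ", signif(2 * amp_m, 3), " m")
    ph2 <- if (config$phase_relation == "antiphase") pi else 0
    bodies_cfg <- list(mk_body(-d / 2, 0), mk_body(d / 2, ph2))
  }

  Re <- reynolds_number(config$speed_bl, geom, fluid)
  Cf <- friction_drag_coefficient(Re)
  wake_x_max <- max(xe) + config$wake_cap_L * L

  ## wake state per body
  wake <- lapply(seq_len(nb), function(i)
    list(x = numeric(0), y = numeric(0), g = numeric(0), core = numeric(0)))
  far_gamma <- numeric(nb)

  empty_mat <- function() matrix(NA_real_, nsteps, N)
  res_b <- lapply(seq_len(nb), function(i)
    list(fp_x = empty_mat(), fp_y = empty_mat(),
         ff_x = empty_mat(), ff_y = empty_mat(),
         dp = empty_mat(), gamma = empty_mat(), v_el = empty_mat()))
  kelvin <- matrix(NA_real_, nsteps, nb)
  snapshots <- vector("list", nsteps)
  times <- (seq_len(nsteps) - 1) * dt
  cum_prev <- vector("list", nb)
  for (i in seq_len(nb)) cum_prev[[i]] <- numeric(N)

  body_idx <- split(seq_len(nb * N), rep(seq_len(nb), each = N))

  for (s in seq_len(nsteps)) {
    t <- times[s]
    pans <- lapply(bodies_cfg, body_panels, t = t,
                   shed_dist = 0.25 * U * dt)
    cx <- unlist(lapply(pans, `[[`, "cx"))
    cy <- unlist(lapply(pans, `[[`, "cy"))
    nxv <- unlist(lapply(pans, `[[`, "nx"))
    nyv <- unlist(lapply(pans, `[[`, "ny"))
    vxp <- unlist(lapply(pans, `[[`, "vx"))
    vyp <- unlist(lapply(pans, `[[`, "vy"))
    vb <- unlist(lapply(pans, `[[`, "vb"))
    lens <- unlist(lapply(pans, `[[`, "len"))

    ## wake-induced velocity at collocation points (all bodies' wakes)
    wx <- unlist(lapply(wake, `[[`, "x"))
    wy <- unlist(lapply(wake, `[[`, "y"))
    wg <- unlist(lapply(wake, `[[`, "g"))
    wcore <- unlist(lapply(wake, `[[`, "core"))
    wv <- induced_velocity_at(cx, cy, wx, wy, wg, wcore)

    ## linear system: bound circulations + one shed vortex per body
    ui <- unit_influence(cx, cy, vxp, vyp)
    A <- ui$Au * nxv + ui$Av * nyv            # (nbN) x (nbN)
    shed_cols <- matrix(0, nb * N, nb)
    for (i in seq_len(nb)) {
      us <- unit_influence(cx, cy, pans[[i]]$shed_x, pans[[i]]$shed_y)
      shed_cols[, i] <- us$Au * nxv + us$Av * nyv
    }
    M <- rbind(cbind(A, shed_cols),
               matrix(0, nb, nb * N + nb))
    rhs <- c(-(U + wv$u) * nxv - (wv$v - vb) * nyv, numeric(nb))
    for (i in seq_len(nb)) {
      M[nb * N + i, c(body_idx[[i]], nb * N + i)] <- 1
      rhs[nb * N + i] <- -(sum(wake[[i]]$g) + far_gamma[i])
    }
    sol <- tryCatch(solve(M, rhs), error = function(e)
      stop("vortex system is singular (degenerate geometry): ",
           conditionMessage(e)))

    gam <- sol[seq_len(nb * N)]
    gshed <- sol[nb * N + seq_len(nb)]

    ## shed the new vortices into the wake
    for (i in seq_len(nb)) {
      p <- pans[[i]]
      wake[[i]]$x <- c(wake[[i]]$x, p$shed_x)
      wake[[i]]$y <- c(wake[[i]]$y, p$shed_y)
      wake[[i]]$g <- c(wake[[i]]$g, gshed[i])
      wake[[i]]$core <- c(wake[[i]]$core, mean(p$len))
    }
    wx <- unlist(lapply(wake, `[[`, "x"))
    wy <- unlist(lapply(wake, `[[`, "y"))
    wg <- unlist(lapply(wake, `[[`, "g"))
    wcore <- unlist(lapply(wake, `[[`, "core"))

    ## Kelvin residual per body (conservation enforced by the solve)
    for (i in seq_len(nb))
      kelvin[s, i] <- sum(gam[body_idx[[i]]]) + sum(wake[[i]]$g) +
        far_gamma[i]

    ## pressure: external tangential velocity at collocation points
    wv2 <- induced_velocity_at(cx, cy, wx, wy, wg, wcore)
    for (i in seq_len(nb)) {
      p <- pans[[i]]
      ii <- body_idx[[i]]
      ## induction from other bodies' bound vortices
      ou <- numeric(N); ov <- numeric(N)
      for (j in seq_len(nb)) {
        oi <- induced_velocity_at(p$cx, p$cy, pans[[j]]$vx, pans[[j]]$vy,
                                  gam[body_idx[[j]]],
                                  if (j == i) NULL else pans[[j]]$core)
        ou <- ou + oi$u; ov <- ov + oi$v
      }
      vt <- (U + wv2$u[ii] + ou) * p$tx + (wv2$v[ii] + ov - p$vb) * p$ty
      gb <- gam[ii]
      cum <- cumsum(gb)
      dcum <- (cum - cum_prev[[i]]) / dt
      cum_prev[[i]] <- cum
      dp <- -rho * (vt * gb / p$len + dcum)      # p_lower - p_upper
      fp_x <- dp * p$len * H * p$nx
      fp_y <- dp * p$len * H * p$ny
      ## friction: local tangential relative velocity, both sides wetted
      ff_mag <- 0.5 * rho * Cf * abs(vt) * vt * (2 * p$len * H)
      ff_x <- ff_mag * p$tx
      ff_y <- ff_mag * p$ty
      res_b[[i]]$fp_x[s, ] <- fp_x
      res_b[[i]]$fp_y[s, ] <- fp_y
      res_b[[i]]$ff_x[s, ] <- ff_x
      res_b[[i]]$ff_y[s, ] <- ff_y
      res_b[[i]]$dp[s, ] <- dp
      res_b[[i]]$gamma[s, ] <- gb
      res_b[[i]]$v_el[s, ] <- p$vb
    }

    snapshots[[s]] <- list(
      bx = vxp, by = vyp, bg = gam, bcore = lens,
      wx = wx, wy = wy, wg = wg, wcore = wcore,
      body_y = lapply(pans, `[[`, "ye"))

    ## advect the wake (free stream + all induced velocities), midpoint rule
    if (length(wx) > 0) {
      bw <- induced_velocity_at(wx, wy, vxp, vyp, gam, lens)
      ww <- induced_velocity_at(wx, wy, wx, wy, wg, wcore)
      sp <- sqrt((U + bw$u + ww$u)^2 + (bw$v + ww$v)^2)
      if (max(sp) > 50 * U)
        stop("wake blow-up: induced speed ", signif(max(sp), 3),
             " m/s exceeds 50x inlet speed at step ", s)
      mx <- wx + (U + bw$u + ww$u) * dt / 2
      my <- wy + (bw$v + ww$v) * dt / 2
      bw2 <- induced_velocity_at(mx, my, vxp, vyp, gam, lens)
      ww2 <- induced_velocity_at(mx, my, wx, wy, wg, wcore)
      newx <- wx + (U + bw2$u + ww2$u) * dt
      newy <- wy + (bw2$v + ww2$v) * dt
      off <- 0L
      for (i in seq_len(nb)) {
        ni <- length(wake[[i]]$x)
        sel <- off + seq_len(ni)
        wake[[i]]$x <- newx[sel]; wake[[i]]$y <- newy[sel]
        off <- off + ni
        drop <- wake[[i]]$x > wake_x_max
        if (any(drop)) {
          far_gamma[i] <- far_gamma[i] + sum(wake[[i]]$g[drop])
          wake[[i]] <- lapply(wake[[i]], function(v) v[!drop])
        }
      }
    }
    if (verbose && s %% config$steps_per_period == 0)
      message("period ", s / config$steps_per_period, " of ",
              config$n_periods)
  }

  structure(list(config = config, fluid = fluid, times = times, dt = dt,
                 period = T_beat, n_steps = nsteps, n_bodies = nb,
                 bodies = res_b, u_element = U, kelvin = kelvin,
                 snapshots = snapshots, far_gamma = far_gamma,
                 reynolds = Re, cf = Cf),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(paste0("Vortex-panel simulation: %d body(ies), %d panels, ",
                     "%d steps (%.3g s, %g periods)\n"),
              x$n_bodies, x$config$n_panels, x$n_steps,
              max(x$times), x$config$n_periods))
  cat(sprintf("  Re = %.3g, Cf = %.4g, wake vortices kept: %d\n",
              x$reynolds, x$cf,
              length(x$snapshots[[x$n_steps]]$wg)))
  invisible(x)
}

#' Sample the simulated velocity field
#'
#' Free-stream plus induced velocity from all bound panels and wake vortices
#' (Lamb-core regularized) at the saved timestep nearest `t`.  Points inside
#' a body section are flagged and their velocity set to `NA`.
#'
#' @param result a `sim_result`.
#' @param points numeric matrix (n x 2) of (x, y) positions in metres.
#' @param t query time (s), within the simulated window.
#' @return Data frame `x`, `y`, `u`, `v` (m/s), `inside` (logical).
#' @export
sample_flow <- function(result, points, t) {
  stopifnot(inherits(result, "sim_result"))
  points <- matrix(points, ncol = 2)
  if (t < 0 || t > max(result$times) + result$dt)
    stop("'t' outside the simulated window [0, ",
         signif(max(result$times), 4), "]")
  s <- min(result$n_steps, max(1L, round(t / result$dt) + 1L))
  sn <- result$snapshots[[s]]
  bv <- induced_velocity_at(points[, 1], points[, 2],
                            sn$bx, sn$by, sn$bg, sn$bcore)
  wv <- induced_velocity_at(points[, 1], points[, 2],
                            sn$wx, sn$wy, sn$wg, sn$wcore)
  u <- result$u_element + bv$u + wv$u
  v <- bv$v + wv$v
  inside <- rep(FALSE, nrow(points))
  geom <- result$config$geom
  xe <- seq(0, geom$length, length.out = result$config$n_panels + 1)
  yt <- naca_half_thickness(xe / geom$length,
                            geom$max_thickness / geom$length) * geom$length
  for (ye in sn$body_y) {
    px <- c(xe, rev(xe)); py <- c(ye + yt, rev(ye - yt))
    inside <- inside | as.logical(
      pracma::inpolygon(points[, 1], points[, 2], px, py))
  }
  u[inside] <- NA_real_; v[inside] <- NA_real_
  data.frame(x = points[, 1], y = points[, 2], u = u, v = v,
             inside = inside)
}

#' Find the thrust/drag-balancing tail-beat frequency
#'
#' Bisects on tail-beat frequency until the time-averaged thrust/drag ratio
#' satisfies \eqn{|F_T/F_D - 1| \le} `ratio_tol` (the self-propelled,
#' "largely balanced" state), holding every other parameter fixed.
#'
#' @param config a [sim_config]; its `params$f` is overridden.
#' @param fluid a [fluid_properties].
#' @param bracket frequency interval (Hz) containing a sign change of the
#'   mean thrust-drag difference.
#' @param ratio_tol balance tolerance on \eqn{|F_T/F_D - 1|} (default 0.05).
#' @param max_iter bisection cap.
#' @return The balanced frequency (Hz), with attributes `ratio`, `F_T`,
#'   `F_D`, `iterations`.
#' @export
balance_frequency <- function(config, fluid = fluid_properties(),
                              bracket = c(1, 5), ratio_tol = 0.05,
                              max_iter = 40) {
  stopifnot(inherits(config, "sim_config"))
  eval_f <- function(fq) {
    p <- config$params
    cfg <- config
    cfg$params <- bodywave_params(p$a, p$b, p$c, p$d, p$lambda, fq,
                                  phase0 = p$phase0)
    ts <- thrust_drag_series(simulate_swimmers(cfg, fluid))
    c(FT = ts$F_T_mean, FD = ts$F_D_mean)
  }
  lo <- bracket[1]; hi <- bracket[2]
  vlo <- eval_f(lo); vhi <- eval_f(hi)
  if (sign(vlo["FT"] - vlo["FD"]) == sign(vhi["FT"] - vhi["FD"]))
    stop("no thrust/drag sign change in bracket [", lo, ", ", hi,
         "] Hz; endpoint ratios ", signif(vlo["FT"] / vlo["FD"], 3),
         " and ", signif(vhi["FT"] / vhi["FD"], 3))
  best <- NULL
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    vm <- eval_f(mid)
    ratio <- unname(vm["FT"] / vm["FD"])
    best <- structure(mid, ratio = ratio, F_T = unname(vm["FT"]),
                      F_D = unname(vm["FD"]), iterations = it)
    if (abs(ratio - 1) <= ratio_tol) return(best)
    if (sign(vm["FT"] - vm["FD"]) == sign(vlo["FT"] - vlo["FD"])) {
      lo <- mid; vlo <- vm
    } else {
      hi <- mid; vhi <- vm
    }
  }
  warning("balance tolerance not reached after ", max_iter,
          " bisections; returning last midpoint (ratio ",
          signif(attr(best, "ratio"), 4), ")")
  best
}

#' Export wake-vortex snapshots to CSV
#'
#' One row per wake vortex per saved timestep: time, position, circulation,
#' and the shedding body.
#'
#' @param result a `sim_result`.
#' @param path output CSV path.
#' @param every write every `every`-th timestep (default: 10).
#' @return `path`, invisibly.
#' @export
write_wake_csv <- function(result, path, every = 10) {
  stopifnot(inherits(result, "sim_result"))
  steps <- seq(1, result$n_steps, by = every)
  rows <- do.call(rbind, lapply(steps, function(s) {
    sn <- result$snapshots[[s]]
    if (length(sn$wg) == 0) return(NULL)
    data.frame(t = result$times[s], x = sn$wx, y = sn$wy,
               circulation = sn$wg)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
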