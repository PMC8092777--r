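## Run entry points: each paper-analog analysis as one call, with a run
## manifest and atomic output writes.  The inst/cli/finwake.R script wraps
## these for shell use (subcommands fit, synth, sim, sweep, transect).

#' Write a file atomically (temp + rename)
#'
#' @param path final path.
#' @param writer function of one argument (a temporary path) that writes the
#'   content.
#' @return `path`, invisibly.
#' @export
atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not rename ", tmp, " to ", path)
  ok <- TRUE
  invisible(path)
}

#' Write a run manifest
#'
#' Records config hash, seed, package version, timestamp, and the output
#' files of a run; every run entry point emits exactly one manifest.
#'
#' @param dir output directory.
#' @param config_path path of the config file used (hashed), or `NULL`.
#' @param seed seed used (or `NA`).
#' @param outputs character vector of output file paths.
#' @param extra named list merged into the manifest.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, config_path = NULL, seed = NA,
                           outputs = character(), extra = list()) {
  man <- c(list(
    tool = "finwake",
    version = as.character(utils::packageVersion("finwake")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = if (is.null(config_path)) NA else config_path,
    config_md5 = if (is.null(config_path)) NA
                 else unname(tools::md5sum(config_path)),
    seed = seed,
    outputs = as.list(outputs)), extra)
  path <- file.path(dir, "manifest.json")
  atomic_write(path, function(p)
    jsonlite::write_json(man, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", na = "null"))
  invisible(path)
}

#' Fit the body-wave model to a track CSV
#'
#' Reads a track CSV (`time_s`, `point_id`, `x_bl`, `y_bl`), fits the
#' body-wave model, and writes the fitted parameters as JSON plus a
#' manifest.
#'
#' @param track_csv input track CSV path.
#' @param out_dir output directory (created if needed).
#' @param iterations envelope-fit iteration cap (1 = one-pass procedure).
#' @return The `bodywave_fit`, invisibly; writes `params.json` and
#'   `manifest.json`.
#' @export
run_fit <- function(track_csv, out_dir, iterations = 50) {
  if (!file.exists(track_csv)) stop("track file not found: ", track_csv)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fit <- fit_bodywave(read_track_csv(track_csv), iterations = iterations)
  pj <- file.path(out_dir, "params.json")
  atomic_write(pj, function(p) write_bodywave_json(fit, p))
  write_manifest(out_dir, config_path = track_csv, outputs = pj,
                 extra = list(iterations = iterations, r2 = fit$r2))
  invisible(fit)
}

#' Generate a synthetic track from a YAML config
#'
#' @param config_yaml YAML config path (see [read_track_gen_yaml()]).
#' @param out_dir output directory.
#' @return The [midline_track], invisibly; writes `track.csv` and
#'   `manifest.json`.
#' @export
run_synth <- function(config_yaml, out_dir) {
  if (!file.exists(config_yaml)) stop("config not found: ", config_yaml)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- read_track_gen_yaml(config_yaml)
  trk <- generate_track(cfg)
  tc <- file.path(out_dir, "track.csv")
  atomic_write(tc, function(p) write_track_csv(trk, p))
  write_manifest(out_dir, config_path = config_yaml,
                 seed = if (is.null(cfg$seed)) NA else cfg$seed,
                 outputs = tc)
  invisible(trk)
}

## Parse a simulation YAML into (sim_config, fluid).  Speeds in BL/s,
## separations in L, per the field's unit conventions; converted internally.
read_sim_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  params <- if (!is.null(y$params))
    bodywave_params(y$params$a, y$params$b, y$params$c, y$params$d,
                    y$params$lambda, y$params$f)
  else if (!is.null(y$reference_speed_bl))
    bodywave_reference(y$reference_speed_bl)
  else stop("config needs 'params' or 'reference_speed_bl'")
  ga <- y$geometry
  geom <- if (is.null(ga)) fish_geometry() else
    do.call(fish_geometry, ga)
  args <- list(speed_bl = y$speed_bl, params = params, geom = geom)
  for (k in c("n_fish", "separation_L", "phase_relation", "n_panels",
              "steps_per_period", "n_periods", "transient_periods",
              "wake_cap_L"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  fl <- y$fluid
  fluid <- if (is.null(fl)) fluid_properties() else
    do.call(fluid_properties, fl)
  list(config = do.call(sim_config, args), fluid = fluid, raw = y)
}

#' Run a solitary or pair simulation from a YAML config
#'
#' Simulates, writes per-body force histories to CSV, the Froude efficiency
#' to JSON, and a manifest.  Set `balance: true` in the config to rebalance
#' the tail-beat frequency first.
#'
#' @param config_yaml YAML config path.
#' @param out_dir output directory.
#' @return The `sim_result`, invisibly; writes `forces.csv`,
#'   `efficiency.json`, `manifest.json`.
#' @export
run_sim <- function(config_yaml, out_dir) {
  if (!file.exists(config_yaml)) stop("config not found: ", config_yaml)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sc <- read_sim_yaml(config_yaml)
  cfg <- sc$config
  if (isTRUE(sc$raw$balance)) {
    br <- if (!is.null(sc$raw$bracket)) unlist(sc$raw$bracket) else c(1, 5)
    fq <- as.numeric(balance_frequency(cfg, sc$fluid, bracket = br))
    p <- cfg$params
    cfg$params <- bodywave_params(p$a, p$b, p$c, p$d, p$lambda, fq,
                                  phase0 = p$phase0)
  }
  res <- simulate_swimmers(cfg, sc$fluid)
  fc <- file.path(out_dir, "forces.csv")
  rows <- do.call(rbind, lapply(seq_len(res$n_bodies), function(i) {
    ts <- thrust_drag_series(res, i)
    data.frame(t = ts$times, body = i, F_T = ts$F_T, F_D = ts$F_D,
               F_lat = ts$F_lat)
  }))
  atomic_write(fc, function(p)
    utils::write.csv(rows, p, row.names = FALSE, quote = FALSE))
  effs <- lapply(seq_len(res$n_bodies), function(i) {
    e <- froude_efficiency(res, i)
    list(body = i, eta = e$eta, P_T = e$P_T, P_S = e$P_S)
  })
  ts1 <- thrust_drag_series(res, 1)
  ej <- file.path(out_dir, "efficiency.json")
  atomic_write(ej, function(p)
    jsonlite::write_json(list(f_hz = cfg$params$f,
                              F_T = ts1$F_T_mean, F_D = ts1$F_D_mean,
                              ratio = ts1$ratio, bodies = effs),
                         p, auto_unbox = TRUE, digits = NA, pretty = TRUE))
  write_manifest(out_dir, config_path = config_yaml, outputs = c(fc, ej))
  invisible(res)
}

#' Run the separation-by-phase sweep from a YAML config
#'
#' Config keys: the [run_sim()] keys plus `separations` (list of L values),
#' `phases`, `rebalance`, `bracket`.  Completed cells found in an existing
#' `sweep.csv` in `out_dir` are reused (resume).
#'
#' @param config_yaml YAML config path.
#' @param out_dir output directory.
#' @param plot also write `efficiency.png`.
#' @return The sweep table, invisibly; writes `sweep.csv`, optional plot,
#'   `manifest.json`.
#' @export
run_sweep <- function(config_yaml, out_dir, plot = TRUE) {
  if (!file.exists(config_yaml)) stop("config not found: ", config_yaml)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sc <- read_sim_yaml(config_yaml)
  seps <- unlist(sc$raw$separations)
  if (is.null(seps)) stop("config needs 'separations'")
  phases <- unlist(sc$raw$phases)
  if (is.null(phases)) phases <- c("inphase", "antiphase")
  rebalance <- !isFALSE(sc$raw$rebalance)
  bracket <- if (!is.null(sc$raw$bracket)) unlist(sc$raw$bracket) else c(1, 5)

  sweep_csv <- file.path(out_dir, "sweep.csv")
  prev <- if (file.exists(sweep_csv))
    utils::read.csv(sweep_csv, stringsAsFactors = FALSE) else NULL
  done <- function(sp, ph) {
    !is.null(prev) && any(prev$status == "ok" &
                            (is.infinite(sp) & prev$phase == "solitary" |
                               abs(prev$separation_L - sp) < 1e-9 &
                               prev$phase == ph))
  }
  todo_sep <- c(); todo_ph <- c()
  for (sp in seps) for (ph in phases)
    if (!done(sp, ph)) { todo_sep <- c(todo_sep, sp); todo_ph <- c(todo_ph, ph) }

  tab <- parallel_sweep(unique(todo_sep),
                        phases = unique(todo_ph),
                        base = sc$config, fluid = sc$fluid,
                        rebalance = rebalance, bracket = bracket)
  if (!is.null(prev)) {
    keep <- prev[prev$status == "ok", , drop = FALSE]
    tab <- rbind(keep,
                 tab[!mapply(function(sp, ph) done(sp, ph),
                             tab$separation_L, tab$phase), ])
    class(tab) <- c("sweep_table", "data.frame")
  }
  atomic_write(sweep_csv, function(p)
    utils::write.csv(tab, p, row.names = FALSE, quote = FALSE))
  outs <- sweep_csv
  if (plot) {
    pp <- file.path(out_dir, "efficiency.png")
    plot_sweep(tab, pp)
    outs <- c(outs, pp)
  }
  n_fail <- sum(tab$status != "ok")
  write_manifest(out_dir, config_path = config_yaml, outputs = outs,
                 extra = list(n_cells = nrow(tab), n_failed = n_fail))
  attr(tab, "n_failed") <- n_fail
  invisible(tab)
}

#' Run a wake transect from a YAML config
#'
#' Config keys: the [run_sim()] keys plus optional `range_L` (two numbers)
#' and `n_samples`.
#'
#' @param config_yaml YAML config path.
#' @param out_dir output directory.
#' @return The `wake_transect`, invisibly; writes `transect.csv` and
#'   `manifest.json`.
#' @export
run_transect <- function(config_yaml, out_dir) {
  if (!file.exists(config_yaml)) stop("config not found: ", config_yaml)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sc <- read_sim_yaml(config_yaml)
  res <- simulate_swimmers(sc$config, sc$fluid)
  rg <- if (!is.null(sc$raw$range_L)) unlist(sc$raw$range_L) else c(0.5, 2)
  ns <- if (!is.null(sc$raw$n_samples)) sc$raw$n_samples else 31
  tr <- wake_transect(res, range_L = rg, n_samples = ns,
                      solitary = sc$config$n_fish == 1)
  tc <- file.path(out_dir, "transect.csv")
  atomic_write(tc, function(p)
    utils::write.csv(data.frame(distance_L = tr$distance_L,
                                speed_bl = tr$speed_bl, ratio = tr$ratio),
                     p, row.names = FALSE, quote = FALSE))
  write_manifest(out_dir, config_path = config_yaml, outputs = tc)
  invisible(tr)
}

#' Command-line dispatcher
#'
#' Dispatches `fit`, `synth`, `sim`, `sweep`, `transect` subcommands; used
#' by the `inst/cli/finwake.R` script.  Exit codes: 0 success, 1
#' computational failure, 2 usage or I/O error, 3 partial sweep failure.
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: finwake <fit|synth|sim|sweep|transect> <input> <out_dir>",
    "[--iterations N]", sep = "\n")
  if (length(args) < 3) { message(usage); return(invisible(2L)) }
  cmd <- args[1]; input <- args[2]; out_dir <- args[3]
  iters <- 50
  if (length(args) >= 5 && args[4] == "--iterations")
    iters <- as.integer(args[5])
  if (!cmd %in% c("fit", "synth", "sim", "sweep", "transect")) {
    message("unknown subcommand: ", cmd, "\n", usage)
    return(invisible(2L))
  }
  if (!file.exists(input)) {
    message("input not found: ", input)
    return(invisible(2L))
  }
  status <- tryCatch({
    out <- switch(cmd,
      fit = run_fit(input, out_dir, iterations = iters),
      synth = run_synth(input, out_dir),
      sim = run_sim(input, out_dir),
      sweep = run_sweep(input, out_dir),
      transect = run_transect(input, out_dir))
    if (cmd == "sweep" && isTRUE(attr(out, "n_failed") > 0)) {
      if (all(out$status != "ok")) 1L else 3L
    } else 0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
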