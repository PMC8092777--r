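#' Configuration for synthetic midline-track generation
#'
#' Describes a synthetic stand-in for 60-fps video digitization of body-axis
#' landmarks of a station-holding fish: the body-wave model is sampled at
#' fixed stations and frame instants, with i.i.d. Gaussian noise emulating
#' digitization error.
#'
#' The default stations are estimated anatomical fractions for the landmarks
#' used on the body axis (snout, eye midpoint, pectoral-fin base and rear
#' midpoints, dorsal-fin root and rear, adipose-fin root, caudal-fin root,
#' caudal-fin tip); the tail tip sits beyond 1 BL because total length
#' exceeds body length.
#'
#' @param params a [bodywave_params] object (ground truth).
#' @param stations body-axis positions (BL); default
#'   `c(0, 0.05, 0.15, 0.25, 0.45, 0.60, 0.75, 0.85, 1.13)`.
#' @param fps frames per second (default 60).
#' @param duration record length (s); must cover at least two tail-beat
#'   periods.
#' @param noise_sd digitization-noise standard deviation (BL); default
#'   0.002 BL (~0.8 mm on a 0.397 m fish).
#' @param seed optional integer seed for reproducible noise.
#' @return An object of class `track_gen_config`.
#' @export
track_gen_config <- function(params,
                             stations = c(0, 0.05, 0.15, 0.25, 0.45,
                                          0.60, 0.75, 0.85, 1.13),
                             fps = 60, duration = 4, noise_sd = 0.002,
                             seed = NULL) {
  stopifnot(inherits(params, "bodywave_params"))
  if (fps <= 0) stop("'fps' must be positive")
  if (noise_sd < 0) stop("'noise_sd' must be nonnegative")
  if (duration < 2 / params$f)
    stop("'duration' must cover at least 2 tail-beat periods (>= ",
         signif(2 / params$f, 3), " s)")
  if (any(diff(stations) <= 0) || any(stations < 0))
    stop("'stations' must be strictly increasing and nonnegative")
  structure(list(params = params, stations = stations, fps = fps,
                 duration = duration, noise_sd = noise_sd, seed = seed),
            class = "track_gen_config")
}

default_point_ids <- function(n) {
  ids <- c("a", "n", "o", "p", "h", "i", "j", "k", "q")
  if (n == length(ids)) ids else paste0("s", seq_len(n))
}

#' Generate a synthetic midline track
#'
#' Samples the body-wave model at the configured stations and frames and adds
#' i.i.d. Gaussian digitization noise.  With a seed set the result is fully
#' reproducible; the caller's random-number state is left untouched.
#'
#' @param config a [track_gen_config].
#' @return A [midline_track].
#' @export
generate_track <- function(config) {
  stopifnot(inherits(config, "track_gen_config"))
  times <- seq(0, config$duration - 1 / config$fps, by = 1 / config$fps)
  h <- outer(times, config$stations,
             function(t, x) evaluate_displacement(x, t, config$params))
  if (config$noise_sd > 0) {
    noise <- with_local_seed(config$seed,
      stats::rnorm(length(h), sd = config$noise_sd))
    h <- h + matrix(noise, nrow(h), ncol(h))
  }
  midline_track(config$stations, times, h,
                point_ids = default_point_ids(length(config$stations)))
}

## Evaluate `expr` under a temporary RNG state seeded with `seed` (if given),
## restoring the caller's state afterwards.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read a track-generation config from YAML
#'
#' Expected keys: `a`, `b`, `c`, `d`, `lambda`, `f` (or a nested `params`
#' map), plus optional `stations`, `fps`, `duration`, `noise_sd`, `seed`.
#'
#' @param path YAML file path.
#' @return A [track_gen_config].
#' @export
read_track_gen_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  pv <- if (!is.null(y$params)) y$params else y
  params <- bodywave_params(pv$a, pv$b, pv$c, pv$d, pv$lambda, pv$f)
  args <- list(params = params)
  for (k in c("stations", "fps", "duration", "noise_sd", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(args$stations)) args$stations <- unlist(args$stations)
  do.call(track_gen_config, args)
}
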