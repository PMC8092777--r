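## Shared fixtures: reference kinematics and synthetic tracks built in code.

ref152 <- function() bodywave_reference(1.52)

## Stations populating both envelope-fit regions, including the tail tip.
fit_stations <- c(0.05, 0.1, 0.15, 0.2, 0.45, 0.6, 0.75, 0.85, 1.0, 1.13)

make_track <- function(params = ref152(), stations = fit_stations,
                       fps = 60, duration = 4, noise_sd = 0, seed = NULL) {
  generate_track(track_gen_config(params, stations = stations, fps = fps,
                                  duration = duration, noise_sd = noise_sd,
                                  seed = seed))
}

## Small, fast solver configurations for unit tests.
quick_cfg <- function(params = ref152(), ...) {
  sim_config(1.52, params, n_panels = 30, steps_per_period = 40,
             n_periods = 3, ...)
}

rigid_params <- function(ref = ref152())
  bodywave_params(0, 0, 0, 0, ref$lambda, ref$f)

## Cache expensive simulations across test_that blocks within a file.
.sim_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache))
    assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}
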