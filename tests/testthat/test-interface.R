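write_synth_yaml <- function(path, noise_sd = 0, seed = NULL,
                             stations = fit_stations) {
  p <- ref152()
  obj <- list(a = p$a, b = p$b, c = p$c, d = p$d, lambda = p$lambda,
              f = p$f, stations = stations, fps = 60, duration = 4,
              noise_sd = noise_sd)
  if (!is.null(seed)) obj$seed <- seed
  yaml::write_yaml(obj, path)
  path
}

write_sim_yaml <- function(path, extra = list()) {
  obj <- c(list(speed_bl = 1.52, reference_speed_bl = 1.52,
                n_panels = 20, steps_per_period = 30, n_periods = 3),
           extra)
  yaml::write_yaml(obj, path)
  path
}

test_that("synth then fit round-trips the generating constants", {
  td <- tempfile(); dir.create(td)
  yml <- write_synth_yaml(file.path(td, "synth.yaml"))
  trk <- run_synth(yml, file.path(td, "synth_out"))
  track_csv <- file.path(td, "synth_out", "track.csv")
  expect_true(file.exists(track_csv))
  expect_equal(nrow(read.csv(track_csv)),
               length(trk$stations) * length(trk$times))
  fit <- run_fit(track_csv, file.path(td, "fit_out"))
  pj <- jsonlite::read_json(file.path(td, "fit_out", "params.json"))
  p <- ref152()
  expect_equal(pj$b, p$b, tolerance = 1e-4)
  expect_equal(pj$c, p$c, tolerance = 1e-4)
  expect_equal(pj$d, p$d, tolerance = 1e-4)
  expect_equal(pj$lambda_bl, p$lambda, tolerance = 1e-6)
  expect_equal(pj$f_hz, p$f, tolerance = 1e-6)
  ## one-pass mode differs only in the envelope constants
  fit1 <- run_fit(track_csv, file.path(td, "fit1_out"), iterations = 1)
  expect_equal(fit1$params$lambda, fit$params$lambda)
  expect_equal(fit1$params$f, fit$params$f)
  expect_false(isTRUE(all.equal(fit1$params$d, fit$params$d)))
  ## every run emits exactly one manifest recording the config hash
  man <- jsonlite::read_json(file.path(td, "fit_out", "manifest.json"))
  expect_equal(man$config_md5, unname(tools::md5sum(track_csv)))
  expect_true(file.exists(file.path(td, "synth_out", "manifest.json")))
})

test_that("synthetic generation from the CLI surface is seed-deterministic", {
  td <- tempfile(); dir.create(td)
  yml <- write_synth_yaml(file.path(td, "s.yaml"), noise_sd = 0.002,
                          seed = 21)
  run_synth(yml, file.path(td, "a"))
  run_synth(yml, file.path(td, "b"))
  expect_identical(readLines(file.path(td, "a", "track.csv")),
                   readLines(file.path(td, "b", "track.csv")))
})

test_that("simulation runner writes forces, efficiency, and manifest", {
  td <- tempfile(); dir.create(td)
  yml <- write_sim_yaml(file.path(td, "sim.yaml"))
  res <- run_sim(yml, file.path(td, "out"))
  expect_s3_class(res, "sim_result")
  fc <- read.csv(file.path(td, "out", "forces.csv"))
  expect_named(fc, c("t", "body", "F_T", "F_D", "F_lat"))
  expect_equal(nrow(fc), res$n_steps)
  ej <- jsonlite::read_json(file.path(td, "out", "efficiency.json"))
  expect_true(ej$bodies[[1]]$eta > 0 && ej$bodies[[1]]$eta < 1)
  ## repeated run is bit-identical (no hidden randomness)
  run_sim(yml, file.path(td, "out2"))
  expect_identical(readLines(file.path(td, "out", "forces.csv")),
                   readLines(file.path(td, "out2", "forces.csv")))
})

test_that("sweep runner writes the table and resumes completed cells", {
  td <- tempfile(); dir.create(td)
  yml <- write_sim_yaml(file.path(td, "sweep.yaml"),
                        extra = list(separations = list(1.6),
                                     phases = list("antiphase"),
                                     rebalance = FALSE))
  t_first <- system.time(tab <- run_sweep(yml, file.path(td, "sw"),
                                          plot = TRUE))[3]
  expect_true(file.exists(file.path(td, "sw", "sweep.csv")))
  expect_true(file.exists(file.path(td, "sw", "efficiency.png")))
  expect_equal(sum(tab$status == "ok"), nrow(tab))
  ## resume: completed cells are reused, so the rerun is much cheaper
  t_again <- system.time(tab2 <- run_sweep(yml, file.path(td, "sw"),
                                           plot = FALSE))[3]
  expect_setequal(tab2$phase, tab$phase)
  expect_lt(t_again, t_first)
  man <- jsonlite::read_json(file.path(td, "sw", "manifest.json"))
  expect_equal(man$n_failed, 0)
})

test_that("transect runner produces a monotone sampled profile", {
  td <- tempfile(); dir.create(td)
  yml <- write_sim_yaml(file.path(td, "tr.yaml"),
                        extra = list(n_fish = 2, separation_L = 0.8,
                                     phase_relation = "antiphase",
                                     range_L = list(0.5, 1.5),
                                     n_samples = 7))
  tr <- run_transect(yml, file.path(td, "out"))
  tc <- read.csv(file.path(td, "out", "transect.csv"))
  expect_equal(nrow(tc), 7)
  expect_true(all(diff(tc$distance_L) > 0))
  expect_true(all(is.finite(tc$ratio)))
})

test_that("CLI dispatcher maps failures to distinct exit codes", {
  td <- tempfile(); dir.create(td)
  expect_equal(cli_main(character()), 2L)                  # usage
  expect_equal(cli_main(c("bogus", "x", "y")), 2L)         # unknown command
  expect_equal(cli_main(c("fit", file.path(td, "nope.csv"),
                          file.path(td, "o"))), 2L)        # missing input
  ## computational failure: a rigid body has no defined efficiency
  yml <- file.path(td, "rigid.yaml")
  yaml::write_yaml(list(speed_bl = 1.52,
                        params = list(a = 0, b = 0, c = 0, d = 1,
                                      lambda = 1.05, f = 2.12),
                        n_panels = 20, steps_per_period = 30,
                        n_periods = 3), yml)
  expect_equal(suppressMessages(cli_main(c("sim", yml,
                                           file.path(td, "r")))), 1L)
  ## success path
  syml <- write_synth_yaml(file.path(td, "s.yaml"))
  expect_equal(cli_main(c("synth", syml, file.path(td, "s_out"))), 0L)
})

test_that("atomic writes leave no partial files behind", {
  td <- tempfile(); dir.create(td)
  target <- file.path(td, "out.txt")
  expect_error(atomic_write(target, function(p) {
    writeLines("partial", p)
    stop("writer failed")
  }), "writer failed")
  expect_false(file.exists(target))
  expect_equal(length(list.files(td)), 0)
  atomic_write(target, function(p) writeLines("done", p))
  expect_equal(readLines(target), "done")
})
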