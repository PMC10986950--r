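# frozen transcription of the figure settings the presets must reproduce
preset_reference <- list(
  fig1  = list(model = "dfm", r = 0.02, rho0 = 1, beta = 0.25, k0 = 1,
               c = 3, s0 = 10, N0 = 0.5, S0 = 0),
  fig2  = list(model = "dfm", r = 0.02, rho0 = 1, beta = 0.25, k0 = 1,
               c = 3, s0 = 10, N0 = 0.5, S0 = 0),
  fig3  = list(model = "dwm", r = 0.02, g = 0.15, alpha = 0.05, beta = 0.1,
               c = 0.5, k0 = 1, d = 1, N0 = 0.5, S0 = 0.01),
  fig8  = list(model = "dwm", r = 0.02, g = 0.15, alpha = 0.05, beta = 0.1,
               c = 0.5, k0 = 2, d = 1, N0 = 0.5, S0 = 0.01),
  fig9  = list(model = "dwm", r = 0.1, g = 0.15, alpha = 0.05, beta = 0.1,
               c = 0.5, k0 = 1, d = 1, N0 = 0.5, S0 = 0.01),
  fig10 = list(model = "dwm", r = 0.02, g = 0.15, alpha = 0.01, beta = 0.1,
               c = 0.5, k0 = 1, d = 1, N0 = 0.5, S0 = 0.01),
  fig11 = list(model = "dwm", r = 0.04, g = 0.16, alpha = 0.006, beta = 0.1,
               c = 0.5, k0 = 1, d = 1, N0 = 0.33, S0 = 0.01))

test_that("every preset matches the frozen transcription table", {
  for (nm in names(preset_reference)) {
    ref <- preset_reference[[nm]]
    ps <- preset(nm)
    expect_equal(ps$model, ref$model, info = nm)
    for (key in setdiff(names(ref), c("model", "N0", "S0")))
      expect_identical(ps$params[[key]], ref[[key]],
                       info = paste(nm, key))
    expect_identical(unname(ps$initial), c(ref$N0, ref$S0), info = nm)
  }
})

test_that("the DFM presets carry the documented variant values", {
  expect_identical(preset("fig1")$variants$beta, c(0.4, 0.25, 0.1, 0))
  expect_identical(preset("fig2")$variants$rho0, c(1, 2, 4))
  expect_identical(preset("dfm-beta-0")$params$beta, 0)
  expect_identical(preset("dfm-rho-4")$params$rho0, 4)
  expect_error(preset("fig99"), "available:")
})

test_that("configuration files round-trip exactly for both models", {
  path <- withr::local_tempfile(fileext = ".cfg")
  p <- fig3_params()
  write_config(p, path, initial = c(0.5, 0.01), t_end = 8000)
  got <- load_config(path)
  expect_identical(unclass(got$params), unclass(p))
  expect_identical(unname(got$initial), c(0.5, 0.01))
  expect_identical(got$t_end, 8000)
  q <- dfm_params(r = 0.02, rho0 = 1, beta = 0.25, k0 = 1, c = 3,
                  s0 = 1 / 3)   # non-terminating decimal must survive
  write_config(q, path)
  expect_identical(unclass(load_config(path)$params), unclass(q))
})

test_that("a hand-written config with the baseline values equals the
           preset", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("model: dwm", "r: 0.02", "alpha: 0.05", "g: 0.15",
               "beta: 0.1", "c: 0.5", "k0: 1", "d: 1"), path)
  expect_identical(unclass(load_config(path)$params),
                   unclass(preset("fig3")$params))
})

test_that("invalid configurations fail with informative messages", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("model: dwm", "r: 0.02", "alpha: 0.05", "g: 0.15",
               "beta: -1", "c: 0.5", "k0: 1", "d: 1"), path)
  expect_error(load_config(path), "strictly positive")
  writeLines(c("model: dfm", "r: 0.02", "rho0: 1", "beta: 0.25",
               "k0: 1", "c: 3"), path)
  expect_error(load_config(path), "s0")
  writeLines(c("model: dwm", "r: 0.02", "alpha: 0.05", "g: 0.15",
               "beta: 0.1", "c: 0.5", "k0: 1", "d: 1", "tau: 0.3"), path)
  expect_error(load_config(path), "valid keys")
  expect_error(load_config(file.path(tempdir(), "nope.cfg")), "no such file")
})

test_that("trajectory CSV carries events as comments and full precision
           values", {
  p <- preset("fig1")$params
  tr <- integrate_dfm(p, sim_config(c(0.5, 0), 600, sample_dt = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path, model = "dfm")
  lines <- readLines(path)
  expect_match(lines[1], "^# model: dfm")
  expect_match(lines[2], "^# event: state_collapse at t = ")
  got <- utils::read.csv(path, comment.char = "#")
  expect_equal(got$t, tr$t)
  expect_equal(got$N, tr$N, tolerance = 1e-15)
  expect_equal(got$S, tr$S, tolerance = 1e-15)
})

test_that("diagram CSV writes the branch and a companion points file", {
  d <- sweep_equilibria(fig3_params(), "g", 0.01, 2, n_grid = 401L)
  path <- file.path(withr::local_tempdir(), "diag.csv")
  write_diagram_csv(d, path)
  pts_path <- file.path(dirname(path), "diag_points.csv")
  expect_true(file.exists(pts_path))
  branch <- utils::read.csv(path, comment.char = "#")
  expect_equal(nrow(branch), 401L)
  pts <- utils::read.csv(pts_path)
  expect_setequal(pts$kind, c("transcritical", "hopf"))
  expect_equal(pts$param[pts$kind == "transcritical"], 0.1)
})

test_that("the command-line interface dispatches and reports", {
  expect_output(s <- cliodyn_main(character(0)), "subcommands")
  expect_identical(s, 0L)
  out <- capture.output(s2 <- cliodyn_main(c("equilibria", "--preset",
                                             "fig3")))
  expect_identical(s2, 0L)
  expect_length(out, 4L)   # header + three equilibria
  expect_match(out[1], "kind")
  expect_match(paste(out, collapse = "\n"), "coexistence")
  dir <- withr::local_tempdir()
  diag_csv <- file.path(dir, "diag.csv")
  expect_message(
    s3 <- cliodyn_main(c("bifurcate", "--preset", "fig3", "--sweep", "g",
                         "--lo", "0.01", "--hi", "2", "--n", "401",
                         "--out", diag_csv)),
    "hopf point at g")
  expect_identical(s3, 0L)
  pts <- utils::read.csv(file.path(dir, "diag_points.csv"))
  expect_equal(sum(pts$kind == "hopf"), 1L)
  expect_equal(sum(pts$kind == "transcritical"), 1L)
  traj_csv <- file.path(dir, "traj.csv")
  s4 <- suppressMessages(
    cliodyn_main(c("simulate", "--preset", "fig1", "--t-end", "600",
                   "--out", traj_csv)))
  expect_identical(s4, 0L)
  expect_match(readLines(traj_csv, n = 2L)[2L], "state_collapse")
  expect_message(s5 <- cliodyn_main("frobnicate"), "unknown subcommand")
  expect_identical(s5, 1L)
})
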