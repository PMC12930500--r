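test_that("demonstration configurations carry their reference parameters", {
  hab <- make_fixture("habituation_default")
  expect_identical(hab$circuit, "habituation")
  expect_equal(unclass(hab$params)[c("alpha", "beta", "gamma", "lambda", "mu")],
               list(alpha = 1.5, beta = 5, gamma = 0.01, lambda = 1, mu = 1))
  expect_equal(hab$schedule$dur_on, 1)
  expect_equal(hab$schedule$dur_off, 9)

  sens <- make_fixture("sensitization_default")
  expect_equal(sens$params$rho, 1.75)

  hyb <- make_fixture("hybrid_default")
  expect_equal(hyb$params$beta, 10)
  expect_equal(hyb$params$K_out, 1.5)

  sp <- make_fixture("msl_spaced")
  expect_identical(sp$circuit, "msl")
  expect_equal(sp$schedule$total_on_time, 10)
  expect_equal(sp$schedule$n_pulses, 5L)
  expect_equal(sp$schedule$gap, 50)
  expect_equal(make_fixture("msl_massed")$schedule$n_pulses, 1L)

  expect_error(make_fixture("nonesuch"), "available")
})

test_that("each demonstration reproduces its learning regime", {
  hab <- run_fixture("habituation_default")
  pk <- interval_peaks(hab)
  expect_true(all(diff(pk$peak[-1]) < 0))          # strictly decreasing
  expect_lt(fold_change(pk)$fc, 0)

  sens <- run_fixture("sensitization_default")
  pk2 <- interval_peaks(sens)
  expect_true(all(diff(pk2$peak) >= 0))            # nondecreasing
  expect_gt(fold_change(pk2)$fc, 0)

  hyb <- run_fixture("hybrid_default")
  r <- hybrid_fold_changes(interval_peaks(hyb))
  expect_gt(r$fc_sens, 0)
  expect_lt(r$fc_hab, 0)
  expect_gt(r$peak_argmax, 1)
  expect_lt(r$peak_argmax, nrow(interval_peaks(hyb)))

  fc <- msl_fold_change(run_fixture("msl_spaced"), run_fixture("msl_massed"))
  expect_gt(fc$fc, 0)
})

test_that("sweeps are consistent with direct simulation", {
  p <- fig_params("habituation")
  sched <- pulse_train(4, 1, 9)
  grid <- sweep_fc("habituation", p, sched,
                   sweep_axis("alpha", 1.5, 3, n = 2, scale = "linear"),
                   sweep_axis("gamma", 0.01, 0.02, n = 2, scale = "linear"))
  expect_s3_class(grid, "sweep_grid")
  expect_equal(nrow(grid), 4L)

  cell <- dplyr::filter(grid, alpha == 1.5, gamma == 0.01)
  direct <- fold_change(interval_peaks(simulate_protocol("habituation", p,
                                                         sched)))
  expect_identical(cell$fc, direct$fc)

  # degenerate 1-point-per-axis grids are rejected, as are shared axes
  expect_error(sweep_axis("alpha", 1, 2, n = 1))
  expect_error(sweep_fc("habituation", p, sched,
                        sweep_axis("alpha", 1, 2, n = 2),
                        sweep_axis("alpha", 1, 2, n = 2)),
               "distinct")
  expect_error(sweep_axis("delta", 1, 2), "must be one of")
})

test_that("habituation strengthens with the memory production rate", {
  p <- fig_params("habituation")
  sched <- pulse_train(5, 1, 9)
  grid <- sweep_fc("habituation", p, sched,
                   sweep_axis("alpha", 0.5, 4, n = 4),
                   sweep_axis("gamma", 0.005, 0.02, n = 2))
  by_gamma <- split(grid, grid$gamma)
  for (row in by_gamma) {
    ord <- order(row$alpha)
    expect_true(all(diff(row$fc[ord]) <= 1e-10))
  }
})

test_that("the massed-spaced sweep is anchored at zero for massed input", {
  p <- fig_params("msl")
  grid <- sweep_msl(p, total_on_time = 10, n_values = c(1, 5),
                    gap_values = c(2, 50))
  expect_equal(dplyr::filter(grid, n_pulses == 1)$fc, c(0, 0))
  expect_gt(dplyr::filter(grid, n_pulses == 5, gap == 50)$fc, 0)
  # short gaps approach the massed limit
  expect_lt(abs(dplyr::filter(grid, n_pulses == 5, gap == 2)$fc),
            abs(dplyr::filter(grid, n_pulses == 5, gap == 50)$fc))
})

test_that("threshold masks flag cells beyond the level in the metric direction", {
  p <- fig_params("habituation")
  sched <- pulse_train(5, 1, 9)
  grid <- sweep_fc("habituation", p, sched,
                   sweep_axis("alpha", 0.1, 4, n = 3),
                   sweep_axis("gamma", 0.005, 0.02, n = 2))
  m <- threshold_mask(grid, -1)
  expect_identical(m$beyond, grid$fc <= -1)
  expect_true(all(threshold_mask(grid, 0)$beyond))          # all habituated
  expect_false(any(threshold_mask(grid, min(grid$fc) - 1)$beyond))

  # a bisection refinement along alpha brackets the masked boundary
  row <- dplyr::filter(m, gamma == min(m$gamma)) |> dplyr::arrange(alpha)
  flip <- which(diff(row$beyond) != 0)
  if (length(flip)) {
    lo <- row$alpha[flip[1]]; hi <- row$alpha[flip[1] + 1]
    f <- function(a) {
      pp <- p; pp$alpha <- a; pp$gamma <- min(m$gamma)
      fold_change(interval_peaks(simulate_protocol("habituation", pp,
                                                   sched)))$fc + 1
    }
    for (i in 1:12) {
      mid <- sqrt(lo * hi)
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    expect_gte(sqrt(lo * hi), row$alpha[flip[1]])
    expect_lte(sqrt(lo * hi), row$alpha[flip[1] + 1])
  } else {
    fail("expected the fc = -1 contour to cross the sampled alpha range")
  }
})

test_that("trajectories and sweeps round-trip through CSV/JSON losslessly", {
  dir <- withr::local_tempdir()
  fx <- make_fixture("habituation_default", n_pulses = 3)
  traj <- simulate_protocol(fx$circuit, fx$params, fx$schedule)
  write_trajectory(traj, file.path(dir, "run"))
  back <- read_trajectory(file.path(dir, "run"))
  expect_same_samples(back, traj)
  expect_identical(fold_change(interval_peaks(back))$fc,
                   fold_change(interval_peaks(traj))$fc)

  p <- fig_params("habituation")
  grid <- sweep_fc("habituation", p, pulse_train(3, 1, 9),
                   sweep_axis("alpha", 1, 2, n = 2),
                   sweep_axis("gamma", 0.01, 0.02, n = 2))
  write_sweep(grid, file.path(dir, "sweep"))
  grid_back <- read_sweep(file.path(dir, "sweep"))
  expect_identical(grid_back$fc, grid$fc)
  expect_identical(attr(grid_back, "metric"), attr(grid, "metric"))
})

test_that("plots build without error", {
  fx <- make_fixture("habituation_default", n_pulses = 2)
  traj <- simulate_protocol(fx$circuit, fx$params, fx$schedule)
  pl <- autoplot(traj)
  expect_s3_class(pl, "ggplot")
  expect_no_error(ggplot2::ggplot_build(pl))

  p <- fig_params("habituation")
  grid <- sweep_fc("habituation", p, pulse_train(2, 1, 9),
                   sweep_axis("alpha", 1, 2, n = 2),
                   sweep_axis("gamma", 0.01, 0.02, n = 2))
  pl2 <- plot_sweep(grid)
  expect_s3_class(pl2, "ggplot")
  expect_no_error(ggplot2::ggplot_build(pl2))
})

test_that("the command-line front end simulates from a config file", {
  cli <- system.file("cli", "circlearn", package = "circlearn")
  expect_true(nzchar(cli))
  dir <- withr::local_tempdir()
  cfg <- file.path(dir, "cfg.yaml")
  yaml::write_yaml(list(
    circuit = list(kind = "habituation", alpha = 1.5, beta = 5,
                   gamma = 0.01, lambda = 1, mu = 1),
    protocol = list(n_pulses = 3, dur_on = 1, dur_off = 9)
  ), cfg)
  out <- file.path(dir, "run")
  res <- system2("Rscript", c(cli, "simulate", "--config", cfg,
                              "--out", out),
                 stdout = TRUE, stderr = TRUE)
  expect_null(attr(res, "status"))
  expect_true(file.exists(paste0(out, ".csv")))
  expect_true(file.exists(paste0(out, "_fc.json")))
  traj <- read_trajectory(out)
  fx <- make_fixture("habituation_default", n_pulses = 3)
  ref <- simulate_protocol(fx$circuit, fx$params, fx$schedule)
  expect_same_samples(traj, ref)
})
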