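# Population sampling, Brownian trajectory generation, contrast simulation,
# and the labelled sample generator.

test_that("population draws match the stated median and IQR", {
  ev <- population_presets("EV")$EV
  d <- sample_population(ev, 1e5, seed = 11)$diameter_nm
  expect_equal(median(d), 97, tolerance = 0.02)
  q <- unname(quantile(d, c(0.25, 0.75)))
  expect_equal(q[1], 79, tolerance = 0.05)
  expect_equal(q[2], 120, tolerance = 0.05)
})

test_that("degenerate IQR gives constant draws; draws are reproducible", {
  mono <- monodisperse(80, 1.4, 1e12)
  d <- sample_population(mono, 50, seed = 2)
  expect_true(all(d$diameter_nm == 80))
  expect_true(all(d$ri == 1.4))
  ev <- population_presets("EV")$EV
  expect_identical(sample_population(ev, 100, seed = 3),
                   sample_population(ev, 100, seed = 3))
})

test_that("inconsistent population parameters error", {
  expect_error(population_spec("x", 50, c(60, 40), 1.4, c(1.39, 1.41), 1e12),
               "q25")
  expect_error(population_spec("x", 50, c(55, 70), 1.4, c(1.39, 1.41), 1e12),
               "median")
})

test_that("an immobile particle never leaves the field of view", {
  opt <- optical_config(viscosity_Pa_s = 1e6) # D ~ 0
  instr <- instrument_spec(duration_s = 0.1)
  traj <- simulate_trajectory(100, opt, instr, seed = 4)
  expect_identical(nrow(traj), 500L) # duration * frame_rate
})

test_that("step variance matches 2*D*dt (Stokes-Einstein consistency)", {
  opt <- optical_config()
  instr <- instrument_spec(duration_s = 0.2, fov_um = 1e4,
                           focal_depth_um = 1e4) # no escape
  D <- stokes_einstein_diffusion(100, opt) # closed form, 4.907 um^2/s
  dt <- 1 / instr$frame_rate_hz
  withr::with_seed(5, {
    sq <- unlist(lapply(1:500, function(i) {
      diff(simulate_trajectory(100, opt, instr)$x_um)^2
    }))
  })
  se <- sd(sq) / sqrt(length(sq))
  expect_lt(abs(mean(sq) - 2 * D * dt), 3 * se)
})

test_that("faster-diffusing (smaller) particles leave the volume sooner", {
  opt <- optical_config()
  instr <- instrument_spec(duration_s = 2)
  len <- function(d, seeds) {
    vapply(seeds, function(s) {
      nrow(simulate_trajectory(d, opt, instr, seed = s))
    }, numeric(1))
  }
  expect_gt(median(len(200, 1:150)), median(len(40, 1:150)))
})

test_that("simulated contrasts follow A*sqrt(sigma) with Gaussian noise", {
  opt <- optical_config()
  cal <- contrast_calibration(0.01)
  c0 <- 0.01 * sqrt(mie_cross_section(100, 1.42, opt))
  expect_equal(simulate_contrasts(100, 1.42, cal, opt, 5, 0),
               rep(c0, 5))
  expect_identical(simulate_contrasts(80, 1.33, cal, opt, 4, 0), rep(0, 4))
  cc <- simulate_contrasts(100, 1.42, cal, opt, 1e4, 0.02, seed = 6)
  expect_equal(sd(cc), 0.02, tolerance = 0.05)
  expect_equal(mean(cc), c0, tolerance = 0.05)
})

test_that("sample generator labels, proportions and determinism", {
  instr <- instrument_spec(duration_s = 2)
  one <- simulate_sample(stock_ev(), instr, seed = 7)
  expect_true(all(one$truth$population == "EV"))
  expect_true(all(one$trajectories$x_um >= 0 &
                    one$trajectories$x_um <= instr$fov_um))

  # 3:1 EV:VLDL expected-count ratio within the binomial 99% CI
  pops <- list(dilute(population_presets("EV")$EV, 3),
               population_presets("EV")$EV)
  pops[[2]]$name <- "EVb"
  mixed <- simulate_sample(pops, instr, seed = 8)
  n <- nrow(mixed$truth)
  k <- sum(mixed$truth$population == "EV")
  ci <- qnorm(0.995) * sqrt(0.75 * 0.25 / n)
  expect_lt(abs(k / n - 0.75), ci)

  expect_error(simulate_sample(dilute(stock_ev(), 0), instr), "zero")
  expect_warning(
    empty <- simulate_sample(stock_ev(),
                             instrument_spec(duration_s = 0), seed = 1),
    "empty")
  expect_identical(nrow(empty$trajectories), 0L)
})

test_that("label proportions follow concentrations (chi-square, n = 1e4)", {
  instr <- instrument_spec(duration_s = 1)
  pops <- list(dilute(population_presets("EV")$EV, 1),
               dilute(population_presets("ULDL")$ULDL, 1 / 20),
               dilute(population_presets("VLDL")$VLDL, 1 / 10))
  smp <- simulate_sample(pops, instr, seed = 9, n_particles = 1e4)
  expect_identical(nrow(smp$truth), 10000L)
  conc <- vapply(pops, `[[`, numeric(1), "concentration")
  obs <- table(factor(smp$truth$population, c("EV", "ULDL", "VLDL")))
  p <- suppressWarnings(stats::chisq.test(obs, p = conc / sum(conc)))$p.value
  expect_gt(p, 0.01)
})

test_that("identical seeds reproduce identical samples, files included", {
  instr <- instrument_spec(duration_s = 1)
  a <- simulate_sample(stock_ev(), instr, seed = 10)
  b <- simulate_sample(stock_ev(), instr, seed = 10)
  expect_identical(a$trajectories, b$trajectories)
  pa <- file.path(withr::local_tempdir(), "a")
  pb <- file.path(withr::local_tempdir(), "b")
  write_sample(a, pa)
  write_sample(b, pb)
  expect_identical(readLines(paste0(pa, ".csv")),
                   readLines(paste0(pb, ".csv")))
  expect_identical(readLines(paste0(pa, ".json")),
                   readLines(paste0(pb, ".json")))
})
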