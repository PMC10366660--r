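# Diffusion estimation, sizing, cross-section and RI recovery, IQR_S.

make_free_trajectory <- function(d_nm, n_frames, opt, loc_noise_um = 0) {
  D <- stokes_einstein_diffusion(d_nm, opt)
  dt <- 1 / 5000
  sdstep <- sqrt(2 * D * dt)
  x <- cumsum(c(0, rnorm(n_frames - 1, sd = sdstep)))
  y <- cumsum(c(0, rnorm(n_frames - 1, sd = sdstep)))
  if (loc_noise_um > 0) {
    x <- x + rnorm(n_frames, sd = loc_noise_um)
    y <- y + rnorm(n_frames, sd = loc_noise_um)
  }
  tibble::tibble(frame = seq_len(n_frames) - 1L, x_um = x, y_um = y)
}

test_that("CVE recovers D without bias, with and without localization noise", {
  opt <- optical_config()
  D_true <- stokes_einstein_diffusion(100, opt)
  withr::with_seed(21, {
    d_hat <- vapply(1:1000, function(i) {
      estimate_diffusion(make_free_trajectory(100, 200, opt), 5000)$D_um2_s
    }, numeric(1))
    d_hat_noisy <- vapply(1:1000, function(i) {
      estimate_diffusion(make_free_trajectory(100, 200, opt, 0.02),
                         5000)$D_um2_s
    }, numeric(1))
  })
  expect_equal(mean(d_hat), D_true, tolerance = 0.02)
  # i.i.d. localization noise must not bias the estimate (3 se band)
  se <- sd(d_hat_noisy) / sqrt(length(d_hat_noisy))
  expect_lt(abs(mean(d_hat_noisy) - D_true), 3 * se)
})

test_that("degenerate trajectories are handled", {
  still <- tibble::tibble(frame = 0:10, x_um = 1, y_um = 2)
  expect_identical(estimate_diffusion(still, 5000)$D_um2_s, 0)
  gappy <- tibble::tibble(frame = c(0L, 5L, 9L), x_um = 1:3, y_um = 1:3)
  expect_error(estimate_diffusion(gappy, 5000), "consecutive")
})

test_that("Stokes-Einstein sizing matches the closed form", {
  opt <- optical_config()
  expect_equal(diameter_from_diffusion(4.907, opt), 100, tolerance = 5e-3)
  expect_equal(diameter_from_diffusion(2, opt) * 2,
               diameter_from_diffusion(1, opt))
  # round trip with the generator's D(d): shared implementation
  expect_equal(diameter_from_diffusion(
    stokes_einstein_diffusion(137, opt), opt), 137)
  expect_warning(na_d <- diameter_from_diffusion(c(-1, 2), opt), "NA")
  expect_identical(is.na(na_d), c(TRUE, FALSE))
})

test_that("cross-section from contrast inverts the calibration", {
  cal <- contrast_calibration(0.01)
  expect_equal(cross_section_from_contrast(0.01 * sqrt(7.3), cal), 7.3)
  expect_identical(cross_section_from_contrast(0, cal), 0)
  expect_identical(cross_section_from_contrast(-0.05, cal), 0)
  # median contrast over 200 noisy frames recovers sigma within 3%
  opt <- optical_config()
  c0 <- 0.01 * sqrt(mie_cross_section(100, 1.42, opt))
  withr::with_seed(22, {
    sig_hat <- vapply(1:200, function(i) {
      cc <- c0 + rnorm(200, 0, 0.1 * c0)
      cross_section_from_contrast(median(cc), cal)
    }, numeric(1))
  })
  expect_equal(mean(sig_hat), (c0 / 0.01)^2, tolerance = 0.03)
})

test_that("IQR_S vanishes at zero noise and responds to noise and size", {
  opt <- optical_config()
  cal <- contrast_calibration()
  sig <- function(d) mie_cross_section(d, 1.40, opt)
  expect_identical(simulated_ri_iqr(100, sig(100), 150, 0, opt, cal), 0)
  iqr <- function(d, noise) {
    simulated_ri_iqr(d, sig(d), 150, noise, opt, cal, n_sims = 400,
                     seed = 23)
  }
  # monotone in noise at fixed size; decreasing in size at fixed noise
  expect_true(iqr(80, 0.01) < iqr(80, 0.03))
  expect_true(iqr(80, 0.03) < iqr(80, 0.09))
  expect_true(iqr(60, 0.03) > iqr(120, 0.03))
  expect_error(simulated_ri_iqr(100, sig(100), 150, 0.03, opt, cal,
                                n_sims = 50), ">= 100")
})

test_that("precision gate applies a strict cutoff", {
  rec <- tibble::tibble(iqr_s = c(0.049, 0.051, 0.05))
  gated <- apply_precision_gate(rec, cutoff = 0.05)
  expect_identical(gated$passes_gate, c(TRUE, FALSE, FALSE))
  expect_true(all(apply_precision_gate(rec, cutoff = Inf)$passes_gate))
})

test_that("short trajectories never yield records", {
  instr <- instrument_spec(duration_s = 2)
  smp <- simulate_sample(stock_ev(), instr, seed = 24)
  rec <- estimate_particles(smp, compute_iqr = FALSE)
  expect_true(all(rec$n_localizations > instr$min_localizations))
  short_truth <- smp$truth$particle_id[smp$truth$n_localizations <= 100]
  expect_length(intersect(rec$particle_id, short_truth), 0)
})

test_that("RI spread of estimates narrows with true diameter", {
  opt <- optical_config()
  instr <- instrument_spec(duration_s = 8)
  iqr_at <- function(d, seed) {
    conc <- 4e11 * 100 / d # roughly equal kept counts across sizes
    smp <- simulate_sample(monodisperse(d, 1.40, conc), instr, opt,
                           seed = seed)
    rec <- estimate_particles(smp, compute_iqr = FALSE)
    unname(diff(quantile(rec$ri, c(0.25, 0.75))))
  }
  spreads <- c(iqr_at(50, 25), iqr_at(100, 26), iqr_at(200, 27))
  expect_true(all(diff(spreads) < 0),
              label = sprintf("RI IQR %.4f > %.4f > %.4f",
                              spreads[1], spreads[2], spreads[3]))
})
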