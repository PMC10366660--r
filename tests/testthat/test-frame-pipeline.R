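# Frame rendering, median background correction, the radial variance
# transform, and detection + linking.

static_traj <- function(x_um, y_um, n_frames, contrast = 0.05,
                        first_frame = 0L) {
  tibble::tibble(particle_id = 1L,
                 frame = first_frame + seq_len(n_frames) - 1L,
                 x_um = x_um, y_um = y_um, contrast = contrast)
}

test_that("rendering: empty input gives pure background, spots land on pixels", {
  empty <- tibble::tibble(particle_id = integer(0), frame = integer(0),
                          x_um = numeric(0), y_um = numeric(0),
                          contrast = numeric(0))
  st <- render_frames(empty, fov_um = 2.2, noise_sd = 0.005,
                      frame_ids = 0:4, seed = 51)
  expect_equal(mean(st$frames), 1, tolerance = 1e-3)
  expect_lt(max(abs(st$frames - 1)), 6 * 0.005)

  # noiseless static particle: frame maximum at the rendered pixel each frame
  traj <- static_traj(1.1, 0.75, 5)
  st2 <- render_frames(traj, fov_um = 2.2, noise_sd = 0, seed = 52)
  px <- round(1.1 / st2$pixel_size_um + 0.5)
  py <- round(0.75 / st2$pixel_size_um + 0.5)
  for (t in 1:5) {
    peak <- which(st2$frames[, , t] == max(st2$frames[, , t]), arr.ind = TRUE)
    expect_true(abs(peak[1, 1] - py) <= 1 && abs(peak[1, 2] - px) <= 1)
  }
  expect_error(render_frames(traj, pixel_size_um = 5, fov_um = 2.2),
               "field of view")
})

test_that("median background correction removes static structure", {
  traj <- static_traj(1.1, 1.1, 31)
  st <- render_frames(traj, fov_um = 2.2, noise_sd = 0, seed = 53)
  # temporally constant stack: subtractive output is exactly zero
  corr <- median_background_correct(st, window = 11)
  expect_equal(max(abs(corr$frames)), 0)
  # static spot sits below the noise floor after correction of a noisy stack
  stn <- render_frames(traj, fov_um = 2.2, noise_sd = 0.01, seed = 54)
  corrn <- median_background_correct(stn, window = 11)
  expect_lt(max(abs(corrn$frames)), 6 * 0.01)
  expect_error(median_background_correct(st, window = 4), "odd")
  expect_error(median_background_correct(st, window = 51), "stack length")
})

test_that("a fast-moving spot survives correction with <= 10% amplitude loss", {
  n <- 41
  traj <- tibble::tibble(particle_id = 1L, frame = seq_len(n) - 1L,
                         x_um = 0.3 + (seq_len(n) - 1) * 0.055, # 1 px/frame
                         y_um = 1.1, contrast = 0.05)
  st <- render_frames(traj, fov_um = 3.3, noise_sd = 0, seed = 55)
  corr <- median_background_correct(st, window = 11)
  mid <- 21
  expect_gt(max(corr$frames[, , mid]), 0.9 * 0.05)
})

test_that("radial variance transform responds to radial symmetry", {
  expect_equal(radial_variance_transform(matrix(3.7, 40, 40)),
               matrix(0, 40, 40))
  # offset invariance: adding a constant changes nothing
  withr::with_seed(56, f <- matrix(rnorm(1600, 1, 0.01), 40, 40))
  expect_equal(radial_variance_transform(f),
               radial_variance_transform(f + 5), tolerance = 1e-6)
  # synthetic concentric rings: global maximum at the pattern center
  ctr <- c(17L, 23L)
  r <- sqrt(outer((1:40 - ctr[1])^2, (1:40 - ctr[2])^2, "+"))
  rings <- cos(2 * pi * r / 4) * exp(-r / 10)
  resp <- radial_variance_transform(rings, 1, 6)
  peak <- which(resp == max(resp), arr.ind = TRUE)
  expect_identical(unname(peak[1, ]), ctr)
  expect_error(radial_variance_transform(f, 3, 2), "rmin")
  expect_error(radial_variance_transform(f, 1, 30), "half")
})

test_that("RVT localizes a rendered interferometric PSF within 1 px", {
  traj <- static_traj(1.073, 1.359, 15) # deliberately subpixel
  st <- render_frames(traj, fov_um = 2.2, noise_sd = 0.002, seed = 57)
  # RVT is offset-invariant, so it can run on the raw unit-background frame
  resp <- radial_variance_transform(st$frames[, , 8])
  peak <- which(resp == max(resp), arr.ind = TRUE)
  expect_lt(abs(peak[1, 2] - (1.073 / st$pixel_size_um + 0.5)), 1)
  expect_lt(abs(peak[1, 1] - (1.359 / st$pixel_size_um + 0.5)), 1)
})

test_that("detection keeps trajectories strictly longer than the filter", {
  # one moving particle, detectable for exactly N frames of the recording
  movie <- function(n_present) {
    traj <- tibble::tibble(
      particle_id = 1L, frame = 10L + seq_len(n_present) - 1L,
      x_um = 0.5 + (seq_len(n_present) - 1) * 0.0165, # 0.3 px/frame
      y_um = 1.76, contrast = 0.05)
    render_frames(traj, fov_um = 3.52, noise_sd = 0.002,
                  frame_ids = 0:139, seed = 58)
  }
  got <- function(st) {
    detect_and_link(st, threshold = 1e-5, min_localizations = 100,
                    background_window = Inf)
  }
  kept_101 <- got(movie(101))
  expect_identical(length(unique(kept_101$particle_id)), 1L)
  expect_identical(nrow(kept_101), 101L)
  expect_identical(nrow(got(movie(100))), 0L)
})

test_that("two well-separated particles link without identity swaps", {
  n <- 110
  x_path <- 0.5 + (seq_len(n) - 1) * 0.019 # ~0.35 px/frame
  t1 <- tibble::tibble(particle_id = 1L, frame = 10L + seq_len(n) - 1L,
                       x_um = x_path, y_um = 1.0, contrast = 0.06)
  t2 <- tibble::tibble(particle_id = 2L, frame = 10L + seq_len(n) - 1L,
                       x_um = x_path, y_um = 2.8, contrast = 0.06)
  st <- render_frames(dplyr::bind_rows(t1, t2), fov_um = 3.85,
                      noise_sd = 0.004, frame_ids = 0:129, seed = 60)
  found <- detect_and_link(st, threshold = "auto", max_disp_px = 4,
                           min_localizations = 100,
                           background_window = Inf)
  expect_identical(length(unique(found$particle_id)), 2L)
  # each found track stays near one true particle throughout
  for (id in unique(found$particle_id)) {
    tr <- found[found$particle_id == id, ]
    ref <- if (mean(tr$y_um) < 1.9) t1 else t2
    m <- match(tr$frame, ref$frame)
    expect_true(all(!is.na(m)))
    expect_lt(max(abs(tr$x_um - ref$x_um[m])), 0.15)
    expect_lt(max(abs(tr$y_um - ref$y_um[m])), 0.15)
  }
})
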