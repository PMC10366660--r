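#' Instrument specification
#'
#' Acquisition and filtering parameters of the tracking instrument: frame
#' rate, square field of view, focal (observation) depth, the
#' minimum-localization filter, per-frame contrast noise, recording duration,
#' and the entry rate constant that maps concentration to expected
#' trajectory counts.
#'
#' @param frame_rate_hz Acquisition rate, Hz. Default 5000 (5 kHz).
#' @param fov_um Side of the square field of view, um. Default 7.1.
#' @param focal_depth_um Thickness of the observation slab about the focal
#'   plane, um; a particle is tracked while `|z - z_focus| <= focal_depth/2`.
#' @param min_localizations Trajectories with *more than* this many
#'   localizations are kept downstream. Default 100.
#' @param contrast_noise_sd Per-frame additive Gaussian noise on the iSCAT
#'   contrast. Default 0.03 (see the methods vignette for the rationale).
#' @param duration_s Recording duration, s.
#' @param entry_rate_hz Expected trajectory starts per particle residing in
#'   the observation volume, per second. Together with concentration and
#'   volume it fixes expected trajectory counts; the constant is absorbed by
#'   the bead-series concentration calibration.
#' @return An `inta_instrument` list.
#' @export
instrument_spec <- function(frame_rate_hz = 5000, fov_um = 7.1,
                            focal_depth_um = 1.0, min_localizations = 100,
                            contrast_noise_sd = 0.03, duration_s = 60,
                            entry_rate_hz = 10) {
  check_number(frame_rate_hz, "frame_rate_hz", positive = TRUE, len = 1)
  check_number(fov_um, "fov_um", positive = TRUE, len = 1)
  check_number(focal_depth_um, "focal_depth_um", positive = TRUE, len = 1)
  check_number(min_localizations, "min_localizations", len = 1)
  if (min_localizations < 1) abort("`min_localizations` must be >= 1.")
  check_number(contrast_noise_sd, "contrast_noise_sd", nonneg = TRUE, len = 1)
  check_number(duration_s, "duration_s", nonneg = TRUE, len = 1)
  check_number(entry_rate_hz, "entry_rate_hz", positive = TRUE, len = 1)
  structure(
    list(frame_rate_hz = frame_rate_hz, fov_um = fov_um,
         focal_depth_um = focal_depth_um,
         min_localizations = as.integer(min_localizations),
         contrast_noise_sd = contrast_noise_sd, duration_s = duration_s,
         entry_rate_hz = entry_rate_hz),
    class = "inta_instrument"
  )
}

#' @export
print.inta_instrument <- function(x, ...) {
  cat(sprintf(
    paste0("<inta_instrument> %g Hz, FOV %g um, focal depth %g um, ",
           "keep > %d localizations, contrast noise sd %g, %g s\n"),
    x$frame_rate_hz, x$fov_um, x$focal_depth_um, x$min_localizations,
    x$contrast_noise_sd, x$duration_s))
  invisible(x)
}

# Brownian positions inside the observation volume. Returns an n x 3 matrix
# of positions (x, y, z), truncated *before* the first step that leaves the
# box [0,fov] x [0,fov] x [-fd/2, fd/2]; the entry position is row 1.
sim_positions <- function(D_um2_s, dt_s, fov_um, focal_depth_um, max_frames) {
  if (max_frames < 1) return(matrix(numeric(0), ncol = 3))
  half <- focal_depth_um / 2
  cur <- c(runif(2, 0, fov_um), runif(1, -half, half))
  step_sd <- sqrt(2 * D_um2_s * dt_s)
  out <- matrix(NA_real_, nrow = max_frames, ncol = 3)
  out[1, ] <- cur
  n <- 1L
  while (n < max_frames) {
    L <- min(256L, max_frames - n)
    steps <- matrix(rnorm(3L * L, sd = step_sd), nrow = L, ncol = 3)
    cums <- apply(steps, 2, cumsum)
    if (L == 1L) cums <- matrix(cums, nrow = 1)
    pos <- sweep(cums, 2, cur, "+")
    inside <- pos[, 1] >= 0 & pos[, 1] <= fov_um &
      pos[, 2] >= 0 & pos[, 2] <= fov_um & abs(pos[, 3]) <= half
    bad <- which(!inside)
    keep <- if (length(bad) > 0) bad[1] - 1L else L
    if (keep > 0) {
      out[(n + 1):(n + keep), ] <- pos[seq_len(keep), , drop = FALSE]
      n <- n + keep
      cur <- pos[keep, ]
    }
    if (length(bad) > 0) break
  }
  out[seq_len(n), , drop = FALSE]
}

#' Simulate a single Brownian trajectory
#'
#' Three-dimensional Brownian motion at the Stokes-Einstein diffusion
#' constant for the given diameter, sampled at the instrument frame rate.
#' The particle enters at a uniform random position in the observation
#' volume; the trajectory ends when it leaves the lateral field of view or
#' the focal slab, or when the recording ends. Only x and y are reported,
#' as in the measurement.
#'
#' @param diameter_nm Particle diameter, nm.
#' @param optics An [optical_config()].
#' @param instrument An [instrument_spec()].
#' @param seed Optional integer seed.
#' @param start_frame First frame index (0-based) of the trajectory.
#' @return A tibble with columns `frame`, `x_um`, `y_um`.
#' @export
simulate_trajectory <- function(diameter_nm, optics = optical_config(),
                                instrument = instrument_spec(),
                                seed = NULL, start_frame = 0L) {
  check_number(diameter_nm, "diameter_nm", positive = TRUE, len = 1)
  D <- stokes_einstein_diffusion(diameter_nm, optics)
  dt <- 1 / instrument$frame_rate_hz
  total <- round(instrument$duration_s * instrument$frame_rate_hz)
  max_frames <- total - as.integer(start_frame)
  pos <- with_seed_or_current(seed, {
    sim_positions(D, dt, instrument$fov_um, instrument$focal_depth_um,
                  max_frames)
  })
  tibble(frame = as.integer(start_frame) + seq_len(nrow(pos)) - 1L,
         x_um = pos[, 1], y_um = pos[, 2])
}

#' Simulate per-frame iSCAT contrasts
#'
#' The noise-free contrast of a particle is `A * sqrt(sigma)` with `A` the
#' calibration amplitude and `sigma` the Mie scattering cross-section of its
#' true diameter and refractive index; each frame adds independent Gaussian
#' noise of standard deviation `noise_sd`.
#'
#' @param diameter_nm,ri True particle diameter (nm) and refractive index.
#' @param calibration A [contrast_calibration()].
#' @param optics An [optical_config()].
#' @param n_frames Number of frames (>= 1).
#' @param noise_sd Per-frame contrast noise standard deviation (>= 0).
#' @param seed Optional integer seed.
#' @return Numeric vector of `n_frames` contrasts.
#' @export
simulate_contrasts <- function(diameter_nm, ri,
                               calibration = contrast_calibration(),
                               optics = optical_config(),
                               n_frames, noise_sd, seed = NULL) {
  check_number(n_frames, "n_frames", positive = TRUE, len = 1)
  check_number(noise_sd, "noise_sd", nonneg = TRUE, len = 1)
  c0 <- calibration$amplitude *
    sqrt(mie_cross_section(diameter_nm, ri, optics))
  with_seed_or_current(seed, c0 + rnorm(as.integer(n_frames), 0, noise_sd))
}

#' Simulate a full labelled iNTA sample
#'
#' Draws particles from one or more populations (expected trajectory counts
#' proportional to population concentrations), simulates each particle's
#' Brownian trajectory through the observation volume and its noisy
#' per-frame contrasts, and returns everything with ground-truth labels.
#' Trajectories shorter than the minimum-localization filter are still
#' emitted: filtering is the analysis pipeline's job.
#'
#' The expected number of trajectories for population k is
#' `concentration_k * fov^2 * focal_depth * duration * entry_rate`
#' (actual counts are Poisson), so counts are proportional to concentration
#' and linear in recording time; the overall constant is calibrated away by
#' [fit_concentration_calibration()], mirroring the bead-series calibration
#' of the instrument.
#'
#' @param populations A [population_spec()] or list of them.
#' @param instrument An [instrument_spec()].
#' @param optics An [optical_config()].
#' @param calibration A [contrast_calibration()].
#' @param seed Optional integer seed; fixed seeds reproduce the sample.
#' @param n_particles If supplied, overrides the Poisson draw: exactly this
#'   many trajectories, allocated to populations in proportion to their
#'   concentrations (multinomial).
#' @return An `inta_sample`: a list with tibbles `trajectories`
#'   (`particle_id`, `frame`, `x_um`, `y_um`, `contrast`) and `truth`
#'   (`particle_id`, `population`, `diameter_nm`, `ri`, `n_localizations`),
#'   plus the generating configuration.
#' @export
simulate_sample <- function(populations, instrument = instrument_spec(),
                            optics = optical_config(),
                            calibration = contrast_calibration(),
                            seed = NULL, n_particles = NULL) {
  if (inherits(populations, "inta_population")) populations <- list(populations)
  stopifnot(length(populations) >= 1,
            all(vapply(populations, inherits, logical(1), "inta_population")))
  conc <- vapply(populations, `[[`, numeric(1), "concentration")
  if (all(conc == 0)) abort("All population concentrations are zero.")
  total_frames <- round(instrument$duration_s * instrument$frame_rate_hz)
  dt <- 1 / instrument$frame_rate_hz

  empty <- function() {
    structure(list(
      trajectories = tibble(particle_id = integer(0), frame = integer(0),
                            x_um = numeric(0), y_um = numeric(0),
                            contrast = numeric(0)),
      truth = tibble(particle_id = integer(0), population = character(0),
                     diameter_nm = numeric(0), ri = numeric(0),
                     n_localizations = integer(0)),
      optics = optics, instrument = instrument, calibration = calibration,
      populations = populations, seed = seed), class = "inta_sample")
  }
  if (total_frames < 1) {
    warn("Zero-duration recording: returning an empty sample.")
    return(empty())
  }

  vol_mL <- instrument$fov_um^2 * instrument$focal_depth_um * 1e-12
  with_seed_or_current(seed, {
    if (is.null(n_particles)) {
      lambda <- conc * vol_mL * instrument$duration_s * instrument$entry_rate_hz
      counts <- rpois(length(lambda), lambda)
    } else {
      check_number(n_particles, "n_particles", nonneg = TRUE, len = 1)
      counts <- as.vector(stats::rmultinom(1, n_particles, conc / sum(conc)))
    }
    n_tot <- sum(counts)
    if (n_tot == 0) {
      warn("No trajectories drawn (expected counts too small).")
      return(empty())
    }
    pop_idx <- rep(seq_along(populations), counts)
    draws <- vector("list", length(populations))
    for (k in seq_along(populations)) {
      if (counts[k] > 0) {
        draws[[k]] <- sample_population(populations[[k]], counts[k], optics)
      }
    }
    dri <- dplyr::bind_rows(draws)
    # per-particle noise-free contrast, computed once
    c0 <- calibration$amplitude *
      sqrt(mie_cross_section(dri$diameter_nm, dri$ri, optics))
    starts <- sample.int(total_frames, n_tot, replace = TRUE) - 1L
    frames_l <- vector("list", n_tot)
    x_l <- vector("list", n_tot)
    y_l <- vector("list", n_tot)
    con_l <- vector("list", n_tot)
    lens <- integer(n_tot)
    for (i in seq_len(n_tot)) {
      D <- stokes_einstein_diffusion(dri$diameter_nm[i], optics)
      pos <- sim_positions(D, dt, instrument$fov_um,
                           instrument$focal_depth_um,
                           total_frames - starts[i])
      k <- nrow(pos)
      lens[i] <- k
      frames_l[[i]] <- starts[i] + seq_len(k) - 1L
      x_l[[i]] <- pos[, 1]
      y_l[[i]] <- pos[, 2]
      con_l[[i]] <- c0[i] + rnorm(k, 0, instrument$contrast_noise_sd)
    }
    trajectories <- tibble(
      particle_id = rep(seq_len(n_tot), lens),
      frame = as.integer(unlist(frames_l)),
      x_um = unlist(x_l), y_um = unlist(y_l), contrast = unlist(con_l))
    truth <- tibble(
      particle_id = seq_len(n_tot),
      population = vapply(populations, `[[`, character(1), "name")[pop_idx],
      diameter_nm = dri$diameter_nm, ri = dri$ri,
      n_localizations = lens)
    structure(list(trajectories = trajectories, truth = truth,
                   optics = optics, instrument = instrument,
                   calibration = calibration, populations = populations,
                   seed = seed),
              class = "inta_sample")
  })
}

#' @export
print.inta_sample <- function(x, ...) {
  kept <- sum(x$truth$n_localizations > x$instrument$min_localizations)
  cat(sprintf(
    "<inta_sample> %d trajectories (%d with > %d localizations), %d population(s)\n",
    nrow(x$truth), kept, x$instrument$min_localizations,
    length(x$populations)))
  invisible(x)
}
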