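#' Covariance-based diffusion estimator (CVE)
#'
#' Estimates the diffusion constant of one trajectory from its per-axis
#' frame-to-frame displacements:
#' `D = mean(dx^2)/(2*dt) + mean(dx_t * dx_(t+1))/dt`, averaged over x and y.
#' The covariance term cancels the bias that static localization noise adds
#' to the mean squared displacement, so the estimator is unbiased without
#' any fit or tuning parameter. The standard error follows the estimator's
#' known variance, `var(D)/D^2 = (6 + 4 e + 2 e^2)/N + 2 (1 + e)^2 / N^2`
#' per axis, with `e` the localization-to-motion variance ratio estimated
#' from the displacement covariance itself.
#'
#' @param traj A tibble with columns `frame`, `x_um`, `y_um` (one particle).
#' @param frame_rate_hz Acquisition rate, Hz.
#' @return A list with `D_um2_s`, `se_D`, `n_displacements`.
#' @references Vestergaard, Blainey & Flyvbjerg (2014) Phys. Rev. E 89,
#'   022726 (optimal estimation of diffusion coefficients from
#'   single-particle trajectories).
#' @export
estimate_diffusion <- function(traj, frame_rate_hz = 5000) {
  required_cols(traj, c("frame", "x_um", "y_um"), "`traj`")
  cve_stats(traj$frame, traj$x_um, traj$y_um, 1 / frame_rate_hz)
}

cve_stats <- function(frame, x, y, dt) {
  consec <- diff(frame) == 1L
  if (!any(consec)) {
    abort("No consecutive-frame displacement pairs: cannot estimate D.")
  }
  dx_all <- diff(x)
  dy_all <- diff(y)
  dx <- dx_all[consec]
  dy <- dy_all[consec]
  n <- length(dx)
  pair <- consec[-length(consec)] & consec[-1]
  msd <- (mean(dx^2) + mean(dy^2)) / 2
  if (any(pair)) {
    i <- which(pair)
    cov1 <- (mean(dx_all[i] * dx_all[i + 1]) +
               mean(dy_all[i] * dy_all[i + 1])) / 2
  } else {
    cov1 <- 0
  }
  D <- msd / (2 * dt) + cov1 / dt
  # localization variance from the covariance term (no motion blur, R = 0)
  loc_var <- max(-cov1, 0)
  eps <- if (D > 0) loc_var / (D * dt) else 0
  var_axis <- if (D > 0) {
    D^2 * ((6 + 4 * eps + 2 * eps^2) / n + 2 * (1 + eps)^2 / n^2)
  } else {
    0
  }
  list(D_um2_s = D, se_D = sqrt(var_axis / 2), n_displacements = n)
}

#' Hydrodynamic diameter from a diffusion constant
#'
#' Stokes-Einstein inversion `d = kB*T / (3*pi*eta*D)`. Non-positive
#' diffusion estimates (possible for very short, noisy trajectories) return
#' `NA` with a warning; such records are excluded downstream.
#'
#' @param D_um2_s Diffusion constant(s), um^2/s.
#' @param optics An [optical_config()].
#' @return Diameter(s), nm.
#' @export
diameter_from_diffusion <- function(D_um2_s, optics = optical_config()) {
  check_number(D_um2_s, "D_um2_s")
  out <- rep(NA_real_, length(D_um2_s))
  ok <- D_um2_s > 0
  if (any(!ok)) {
    warn(sprintf("%d trajectory(ies) with D <= 0: diameter set to NA.",
                 sum(!ok)))
  }
  out[ok] <- stokes_einstein_diameter(D_um2_s[ok], optics)
  out
}

#' Scattering cross-section from summarized iSCAT contrast
#'
#' Inverts the amplitude calibration `C = A * sqrt(sigma)`:
#' `sigma = (C / A)^2`. Negative contrast summaries (pure-noise
#' trajectories) map to `sigma = 0`.
#'
#' @param contrast Per-trajectory contrast summary (median over frames).
#' @param calibration A [contrast_calibration()].
#' @return Cross-section(s), nm^2.
#' @export
cross_section_from_contrast <- function(contrast,
                                        calibration = contrast_calibration()) {
  check_number(contrast, "contrast")
  (pmax(contrast, 0) / calibration$amplitude)^2
}

# ---- cached Mie inversion grid -------------------------------------------
# log sigma on a (log-spaced diameter) x (refractive index) grid; inversion
# interpolates ri against log(sigma) at the particle's diameter. Near the
# medium index sigma ~ (ri - n_m)^2, so below the first grid level the
# inversion uses that square-root law instead of the log grid.

build_ri_grid <- function(d_range, optics, ri_max = 2.5,
                          n_d = 60, n_ri = 235) {
  d_lo <- max(min(d_range) * 0.95, 5)
  d_hi <- max(d_range) * 1.05
  d_grid <- exp(seq(log(d_lo), log(d_hi), length.out = n_d))
  nm <- optics$medium_ri
  ri_grid <- seq(nm + (ri_max - nm) / n_ri, ri_max, length.out = n_ri)
  log_sigma <- matrix(NA_real_, n_d, n_ri)
  for (i in seq_len(n_d)) {
    log_sigma[i, ] <- log(mie_cross_section(d_grid[i], ri_grid, optics))
  }
  list(d_grid = d_grid, ri_grid = ri_grid, log_sigma = log_sigma,
       medium_ri = nm, ri_max = ri_max)
}

# Invert sigma -> ri at one diameter using the cached grid; clamps to
# [medium_ri, ri_max]. `sigma` may be a vector.
grid_invert_ri <- function(grid, diameter_nm, sigma) {
  d <- min(max(diameter_nm, grid$d_grid[1]), grid$d_grid[length(grid$d_grid)])
  ld <- log(d)
  lg <- log(grid$d_grid)
  i <- findInterval(ld, lg, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(lg) - 1L)
  w <- (ld - lg[i]) / (lg[i + 1] - lg[i])
  ls_d <- (1 - w) * grid$log_sigma[i, ] + w * grid$log_sigma[i + 1, ]
  out <- rep(grid$medium_ri, length(sigma))
  s1 <- exp(ls_d[1])
  small <- sigma > 0 & sigma < s1
  if (any(small)) {
    out[small] <- grid$medium_ri +
      (grid$ri_grid[1] - grid$medium_ri) * sqrt(sigma[small] / s1)
  }
  big <- sigma >= exp(ls_d[length(ls_d)])
  out[big] <- grid$ri_max
  mid <- sigma >= s1 & !big
  if (any(mid)) {
    out[mid] <- approx(ls_d, grid$ri_grid, xout = log(sigma[mid]),
                       ties = "ordered")$y
  }
  out
}

#' Simulated refractive-index interquartile range (IQR_S)
#'
#' Monte-Carlo estimate of the spread in refractive index arising
#' exclusively from the per-frame noise on iSCAT contrast, at the particle's
#' estimated diameter and cross-section. For each of `n_sims` replicates,
#' `n_localizations` per-frame contrasts are drawn about the particle's
#' noise-free contrast with standard deviation `contrast_noise_sd`; the
#' median is converted to a cross-section and inverted to a refractive index
#' at fixed diameter (diameter is treated as exact). IQR_S is the
#' interquartile range of the replicate refractive indices; inversions
#' falling outside the bracket clamp to its edges.
#'
#' @param diameter_nm,sigma_nm2 Per-particle diameter and cross-section
#'   estimates (vectors of equal length).
#' @param n_localizations Number of frames per trajectory (vectorized).
#' @param contrast_noise_sd Per-frame contrast noise standard deviation.
#' @param optics An [optical_config()].
#' @param calibration A [contrast_calibration()].
#' @param n_sims Monte-Carlo replicates (>= 100).
#' @param ri_max Upper inversion bracket.
#' @param seed Optional integer seed.
#' @param grid Optional precomputed inversion grid (internal reuse).
#' @return Numeric vector of IQR_S values.
#' @export
simulated_ri_iqr <- function(diameter_nm, sigma_nm2, n_localizations,
                             contrast_noise_sd,
                             optics = optical_config(),
                             calibration = contrast_calibration(),
                             n_sims = 200, ri_max = 2.5, seed = NULL,
                             grid = NULL) {
  check_number(diameter_nm, "diameter_nm", positive = TRUE)
  check_number(sigma_nm2, "sigma_nm2", nonneg = TRUE)
  check_number(contrast_noise_sd, "contrast_noise_sd", nonneg = TRUE, len = 1)
  check_number(n_sims, "n_sims", positive = TRUE, len = 1)
  if (n_sims < 100) abort("`n_sims` must be >= 100.")
  np <- length(diameter_nm)
  stopifnot(length(sigma_nm2) == np)
  n_loc <- rep_len(as.integer(n_localizations), np)
  if (contrast_noise_sd == 0) return(rep(0, np))
  if (is.null(grid)) {
    grid <- build_ri_grid(range(diameter_nm), optics, ri_max)
  }
  A <- calibration$amplitude
  c0 <- A * sqrt(sigma_nm2)
  with_seed_or_current(seed, {
    vapply(seq_len(np), function(i) {
      m <- matrix(rnorm(n_loc[i] * n_sims, c0[i], contrast_noise_sd),
                  nrow = n_loc[i])
      med <- col_medians(m)
      sig <- (pmax(med, 0) / A)^2
      ri <- grid_invert_ri(grid, diameter_nm[i], sig)
      unname(diff(quantile(ri, c(0.25, 0.75))))
    }, numeric(1))
  })
}

#' Gate particle records by simulated RI precision
#'
#' Marks records whose simulated refractive-index interquartile range
#' (`iqr_s`) is strictly below the cutoff. Downstream population RI
#' statistics use only passing records, so the reported median RI reflects
#' particles whose index is actually measurable at the given noise.
#'
#' @param records A particle record tibble with an `iqr_s` column.
#' @param cutoff Gate value; default 0.05.
#' @return `records` with a logical `passes_gate` column (re)set.
#' @export
apply_precision_gate <- function(records, cutoff = 0.05) {
  required_cols(records, "iqr_s", "`records`")
  check_number(cutoff, "cutoff", len = 1, finite = FALSE)
  dplyr::mutate(records, passes_gate = .data$iqr_s < cutoff)
}

#' Estimate per-particle records from trajectories
#'
#' The core analysis step: converts each trajectory with more than
#' `min_localizations` localizations into one particle record --
#' covariance-based diffusion constant, Stokes-Einstein diameter, median
#' per-frame contrast, scattering cross-section, effective refractive index
#' (Mie inversion), the simulated RI precision metric IQR_S, and the
#' precision gate. Ground truth is joined back when `x` is a simulated
#' sample.
#'
#' @param x An `inta_sample` from [simulate_sample()], or a trajectory
#'   tibble with columns `particle_id`, `frame`, `x_um`, `y_um`, `contrast`.
#' @param optics,instrument,calibration Configuration objects; defaulted
#'   from `x` when it is an `inta_sample`.
#' @param compute_iqr Compute IQR_S and the gate (default `TRUE`); skip for
#'   speed when only size/RI are needed.
#' @param contrast_noise_sd Noise level used for IQR_S. `NULL` (default)
#'   takes the instrument value; `"estimate"` uses each trajectory's
#'   per-frame contrast standard deviation.
#' @param n_sims Monte-Carlo replicates for IQR_S.
#' @param iqr_cutoff Precision gate cutoff.
#' @param ri_max Upper bracket for the RI inversion; estimates beyond it
#'   clamp to the bracket edge.
#' @param seed Optional integer seed (IQR_S simulation only).
#' @return A tibble with one row per kept trajectory: `particle_id`,
#'   `n_localizations`, `D_um2_s`, `se_D`, `diameter_nm`, `contrast`,
#'   `sigma_nm2`, `ri`, `iqr_s`, `passes_gate`, plus `population`,
#'   `true_diameter_nm`, `true_ri` for simulated input.
#' @export
estimate_particles <- function(x, optics = NULL, instrument = NULL,
                               calibration = NULL, compute_iqr = TRUE,
                               contrast_noise_sd = NULL, n_sims = 200,
                               iqr_cutoff = 0.05, ri_max = 2.5, seed = NULL) {
  truth <- NULL
  if (inherits(x, "inta_sample")) {
    optics <- optics %||% x$optics
    instrument <- instrument %||% x$instrument
    calibration <- calibration %||% x$calibration
    truth <- x$truth
    traj <- x$trajectories
  } else {
    traj <- x
    optics <- optics %||% optical_config()
    instrument <- instrument %||% instrument_spec()
    calibration <- calibration %||% contrast_calibration()
  }
  required_cols(traj, c("particle_id", "frame", "x_um", "y_um", "contrast"),
                "trajectory table")
  min_loc <- instrument$min_localizations
  dt <- 1 / instrument$frame_rate_hz

  traj <- dplyr::arrange(traj, .data$particle_id, .data$frame)
  ids <- traj$particle_id
  runs <- rle(ids)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$lengths > min_loc
  if (!any(keep)) {
    warn(sprintf("No trajectories with more than %d localizations.", min_loc))
    return(tibble(particle_id = integer(0), n_localizations = integer(0),
                  D_um2_s = numeric(0), se_D = numeric(0),
                  diameter_nm = numeric(0), contrast = numeric(0),
                  sigma_nm2 = numeric(0), ri = numeric(0),
                  iqr_s = numeric(0), passes_gate = logical(0)))
  }
  starts <- starts[keep]; ends <- ends[keep]
  pid <- runs$values[keep]
  n_kept <- length(pid)
  D <- se <- medc <- csd <- numeric(n_kept)
  nloc <- integer(n_kept)
  for (j in seq_len(n_kept)) {
    rows <- starts[j]:ends[j]
    st <- cve_stats(traj$frame[rows], traj$x_um[rows], traj$y_um[rows], dt)
    D[j] <- st$D_um2_s
    se[j] <- st$se_D
    nloc[j] <- length(rows)
    medc[j] <- median(traj$contrast[rows])
    csd[j] <- sd(traj$contrast[rows])
  }
  ok <- D > 0
  if (any(!ok)) {
    warn(sprintf("%d trajectory(ies) with non-positive D excluded.",
                 sum(!ok)))
  }
  rec <- tibble(particle_id = pid, n_localizations = nloc,
                D_um2_s = D, se_D = se, contrast = medc,
                contrast_sd = csd)[ok, ]
  rec$diameter_nm <- stokes_einstein_diameter(rec$D_um2_s, optics)
  rec$sigma_nm2 <- cross_section_from_contrast(rec$contrast, calibration)
  rec$ri <- invert_effective_ri(rec$diameter_nm, rec$sigma_nm2, optics,
                                ri_max = ri_max, clamp = TRUE)
  if (compute_iqr && nrow(rec) > 0) {
    noise <- contrast_noise_sd %||% instrument$contrast_noise_sd
    grid <- build_ri_grid(range(rec$diameter_nm), optics, ri_max)
    if (identical(noise, "estimate")) {
      # per-trajectory noise estimate: loop with particle-specific sd
      rec$iqr_s <- vapply(seq_len(nrow(rec)), function(i) {
        simulated_ri_iqr(rec$diameter_nm[i], rec$sigma_nm2[i],
                         rec$n_localizations[i], rec$contrast_sd[i],
                         optics, calibration, n_sims, ri_max, grid = grid)
      }, numeric(1))
    } else {
      rec$iqr_s <- simulated_ri_iqr(rec$diameter_nm, rec$sigma_nm2,
                                    rec$n_localizations, noise, optics,
                                    calibration, n_sims, ri_max, seed = seed,
                                    grid = grid)
    }
    rec <- apply_precision_gate(rec, iqr_cutoff)
  } else {
    rec$iqr_s <- NA_real_
    rec$passes_gate <- NA
  }
  rec$contrast_sd <- NULL
  if (!is.null(truth)) {
    rec <- dplyr::left_join(
      rec,
      dplyr::select(truth, "particle_id", "population",
                    true_diameter_nm = "diameter_nm", true_ri = "ri"),
      by = "particle_id")
  }
  rec
}
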