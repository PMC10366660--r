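#' Frame stack container
#'
#' In-memory stack of interferometric frames: a `ny x nx x nt` array on a
#' unit background, with pixel size, frame rate and the original frame
#' indices. Serialized as plain text by [write_frames()] / [read_frames()].
#'
#' @param frames Numeric 3-D array `[row, col, time]`.
#' @param pixel_size_um Pixel pitch, um (> 0).
#' @param frame_rate_hz Acquisition rate, Hz.
#' @param frame_ids Integer frame indices (length `dim(frames)[3]`).
#' @return An `inta_frames` list.
#' @export
frame_stack <- function(frames, pixel_size_um, frame_rate_hz = 5000,
                        frame_ids = NULL) {
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  check_number(pixel_size_um, "pixel_size_um", positive = TRUE, len = 1)
  frame_ids <- frame_ids %||% (seq_len(dim(frames)[3]) - 1L)
  stopifnot(length(frame_ids) == dim(frames)[3])
  structure(list(frames = frames, pixel_size_um = pixel_size_um,
                 frame_rate_hz = frame_rate_hz,
                 frame_ids = as.integer(frame_ids)),
            class = "inta_frames")
}

#' @export
print.inta_frames <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<inta_frames> %d x %d px, %d frames, %g nm/px, %g Hz\n",
              d[1], d[2], d[3], x$pixel_size_um * 1000, x$frame_rate_hz))
  invisible(x)
}

# interferometric PSF template: positive central lobe plus one negative
# ring, peak-normalized to 1 at r = 0 (ring contribution there is ~0).
ipsf_template <- function(r, psf) {
  exp(-r^2 / (2 * psf$sigma_core_px^2)) -
    psf$ring_amp * exp(-(r - psf$ring_radius_px)^2 / (2 * psf$sigma_ring_px^2))
}

#' Default interferometric PSF parameters
#'
#' Central Gaussian lobe (sd 1.5 px, about a 200 nm FWHM at 55 nm/px) with
#' one negative ring at 3.5 px, as interferometric point-spread functions
#' show near focus.
#' @param sigma_core_px,ring_radius_px,sigma_ring_px,ring_amp Shape
#'   parameters in pixels (amplitude dimensionless).
#' @return A list of PSF parameters for [render_frames()].
#' @export
psf_params <- function(sigma_core_px = 1.5, ring_radius_px = 3.5,
                       sigma_ring_px = 1.0, ring_amp = 0.4) {
  list(sigma_core_px = sigma_core_px, ring_radius_px = ring_radius_px,
       sigma_ring_px = sigma_ring_px, ring_amp = ring_amp)
}

#' Render trajectories into a synthetic frame stack
#'
#' Draws each localization as a radially symmetric interferometric spot
#' (amplitude = its per-frame contrast) on a unit background with additive
#' Gaussian pixel noise. Pixel `(i, j)` is centered at
#' `x = (j - 0.5) * pixel_size`, `y = (i - 0.5) * pixel_size`, origin at the
#' frame corner, x right / y down.
#'
#' @param x An `inta_sample` or a trajectory tibble (`particle_id`, `frame`,
#'   `x_um`, `y_um`, `contrast`).
#' @param pixel_size_um Pixel pitch, um; default 0.055 (129 px across the
#'   7.1 um field of view).
#' @param fov_um Field-of-view side, um; defaulted from the sample.
#' @param noise_sd Additive Gaussian pixel noise (on the unit background).
#' @param psf PSF shape, see [psf_params()].
#' @param frame_ids Frames to render; default spans the trajectory range.
#' @param seed Optional integer seed (pixel noise).
#' @return An `inta_frames` stack.
#' @export
render_frames <- function(x, pixel_size_um = 0.055, fov_um = NULL,
                          noise_sd = 0.01, psf = psf_params(),
                          frame_ids = NULL, seed = NULL) {
  if (inherits(x, "inta_sample")) {
    fov_um <- fov_um %||% x$instrument$fov_um
    frame_rate <- x$instrument$frame_rate_hz
    traj <- x$trajectories
  } else {
    traj <- x
    fov_um <- fov_um %||% 7.1
    frame_rate <- 5000
  }
  check_number(pixel_size_um, "pixel_size_um", positive = TRUE, len = 1)
  if (pixel_size_um > fov_um) {
    abort("`pixel_size_um` exceeds the field of view.")
  }
  npx <- round(fov_um / pixel_size_um)
  if (is.null(frame_ids)) {
    frame_ids <- if (nrow(traj) > 0) {
      seq(min(traj$frame), max(traj$frame))
    } else {
      0:0
    }
  }
  nt <- length(frame_ids)
  half_w <- ceiling(psf$ring_radius_px + 3 * psf$sigma_ring_px)
  with_seed_or_current(seed, {
    frames <- array(rnorm(npx * npx * nt, mean = 1, sd = noise_sd),
                    dim = c(npx, npx, nt))
    if (nrow(traj) > 0) {
      tmap <- match(traj$frame, frame_ids)
      cx <- traj$x_um / pixel_size_um + 0.5
      cy <- traj$y_um / pixel_size_um + 0.5
      for (k in which(!is.na(tmap))) {
        j0 <- max(1L, floor(cx[k]) - half_w)
        j1 <- min(npx, floor(cx[k]) + half_w)
        i0 <- max(1L, floor(cy[k]) - half_w)
        i1 <- min(npx, floor(cy[k]) + half_w)
        if (j0 > j1 || i0 > i1) next
        r <- sqrt(outer((i0:i1 - cy[k])^2, (j0:j1 - cx[k])^2, "+"))
        frames[i0:i1, j0:j1, tmap[k]] <-
          frames[i0:i1, j0:j1, tmap[k]] +
          traj$contrast[k] * ipsf_template(r, psf)
      }
    }
    frame_stack(frames, pixel_size_um, frame_rate, frame_ids)
  })
}

#' Median background correction
#'
#' Removes the static interferometric background by the pixel-wise rolling
#' median over a temporal window: each frame has the local median subtracted
#' (default) or is divided by it. Anything static -- the reference
#' reflection, fixed spots, constant offsets -- cancels, while particles
#' moving faster than the window survive.
#'
#' @param stack An `inta_frames`.
#' @param window Temporal window, odd, >= 3, at most the stack length.
#'   `Inf` (or the stack length) uses the global per-pixel median of the
#'   whole recording -- the right choice for a static background, and free
#'   of the self-subtraction trail a rolling window leaves when a particle
#'   dwells near one pixel for more than half the window (which biases
#'   localization away from the local path median and inflates diffusion
#'   estimates).
#' @param mode `"subtract"` (default) or `"divide"`.
#' @return An `inta_frames` of corrected frames (background ~0 for
#'   subtract, ~1 for divide).
#' @export
median_background_correct <- function(stack, window = 11,
                                      mode = c("subtract", "divide")) {
  stopifnot(inherits(stack, "inta_frames"))
  mode <- match.arg(mode)
  nt <- dim(stack$frames)[3]
  d <- dim(stack$frames)
  m <- matrix(stack$frames, d[1] * d[2], d[3])
  if (is.infinite(window) || window >= nt) {
    if (is.finite(window) && window > nt) {
      abort(sprintf("`window` (%d) exceeds the stack length (%d).",
                    window, nt))
    }
    bg <- matrix(apply(m, 1, median), d[1] * d[2], d[3])
  } else {
    if (window < 3 || window %% 2 != 1) {
      abort("`window` must be odd and >= 3.")
    }
    bg <- t(apply(m, 1, runmed, k = window))
  }
  out <- if (mode == "subtract") m - bg else m / bg
  frame_stack(array(out, d), stack$pixel_size_um, stack$frame_rate_hz,
              stack$frame_ids)
}

# cache of ring-kernel FFTs keyed by (ny, nx, rmin, rmax)
.rvt_cache <- new.env(parent = emptyenv())

rvt_kernels <- function(ny, nx, rmin, rmax) {
  key <- paste(ny, nx, rmin, rmax, sep = "_")
  if (!is.null(.rvt_cache[[key]])) return(.rvt_cache[[key]])
  offs <- expand.grid(di = -rmax:rmax, dj = -rmax:rmax)
  rr <- round(sqrt(offs$di^2 + offs$dj^2))
  khats <- lapply(rmin:rmax, function(r) {
    sel <- rr == r
    k <- matrix(0, ny, nx)
    k[cbind(offs$di[sel] %% ny + 1L, offs$dj[sel] %% nx + 1L)] <- 1 / sum(sel)
    fft(k)
  })
  .rvt_cache[[key]] <- khats
  khats
}

#' Radial variance transform
#'
#' For every pixel, computes the mean intensity on each integer-radius ring
#' `r` in `[rmin, rmax]` centered there and returns the variance of those
#' ring means. The response peaks at centers of radially symmetric patterns
#' (such as interferometric point-spread functions) and is invariant under
#' constant intensity offsets. Ring means are computed by FFT convolution,
#' so borders wrap circularly; detections are restricted away from the
#' border by the caller.
#'
#' @param frame A numeric matrix (one background-corrected frame).
#' @param rmin,rmax Ring radius range in pixels, `0 <= rmin < rmax`.
#' @return A matrix of the same size: the per-pixel ring-mean variance.
#' @export
radial_variance_transform <- function(frame, rmin = 1, rmax = 6) {
  stopifnot(is.matrix(frame))
  if (!(rmin >= 0 && rmin < rmax)) abort("Need 0 <= rmin < rmax.")
  if (rmax > min(dim(frame)) / 2) {
    abort("`rmax` exceeds half the frame size.")
  }
  khats <- rvt_kernels(nrow(frame), ncol(frame), rmin, rmax)
  fhat <- fft(frame)
  np <- length(frame)
  nr <- length(khats)
  s1 <- matrix(0, nrow(frame), ncol(frame))
  s2 <- matrix(0, nrow(frame), ncol(frame))
  for (k in khats) {
    cv <- Re(fft(fhat * k, inverse = TRUE)) / np
    s1 <- s1 + cv
    s2 <- s2 + cv^2
  }
  s2 / nr - (s1 / nr)^2
}

# parabolic subpixel refinement along one axis
parabolic_offset <- function(ym1, y0, yp1) {
  den <- ym1 - 2 * y0 + yp1
  off <- ifelse(den < 0, 0.5 * (ym1 - yp1) / den, 0)
  pmax(pmin(off, 0.5), -0.5)
}

#' Detect particles in a frame stack and link trajectories
#'
#' The image-level pipeline: median background correction (subtractive),
#' radial variance transform per frame, thresholded local maxima with
#' parabolic subpixel refinement, per-frame contrast read from the corrected
#' frame, and greedy nearest-neighbor frame-to-frame linking (no gap
#' closing). Trajectories with `min_localizations` or fewer points are
#' discarded, matching the analysis filter.
#'
#' @param stack An `inta_frames`.
#' @param threshold RVT detection threshold, or `"auto"` (default): median
#'   plus 10 robust standard deviations of a sample of RVT maps.
#' @param max_disp_px Maximum frame-to-frame displacement for linking, px.
#' @param min_localizations Keep trajectories with more than this many
#'   localizations (default 100).
#' @param rmin,rmax RVT ring radii, px.
#' @param background_window Temporal window of the median correction.
#' @param min_separation_px Only the strongest response within this radius
#'   becomes a detection; defaults to the PSF ring radius neighborhood so
#'   the ring's secondary response is not detected as a second particle.
#' @return A trajectory tibble (`particle_id`, `frame`, `x_um`, `y_um`,
#'   `contrast`) in the same schema the simulator emits; possibly empty.
#' @export
detect_and_link <- function(stack, threshold = "auto", max_disp_px = 5,
                            min_localizations = 100, rmin = 1, rmax = 6,
                            background_window = 11, min_separation_px = 6) {
  stopifnot(inherits(stack, "inta_frames"))
  check_number(max_disp_px, "max_disp_px", positive = TRUE, len = 1)
  corrected <- median_background_correct(stack, background_window, "subtract")
  d <- dim(corrected$frames)
  nt <- d[3]
  margin <- rmax + 1L
  rvts <- vector("list", nt)
  for (t in seq_len(nt)) {
    rvts[[t]] <- radial_variance_transform(corrected$frames[, , t],
                                           rmin, rmax)
  }
  if (identical(threshold, "auto")) {
    probe <- unlist(rvts[unique(c(1, ceiling(nt / 2), nt))])
    threshold <- median(probe) + 10 * mad(probe)
  }
  check_number(threshold, "threshold", len = 1)

  detections <- vector("list", nt)
  for (t in seq_len(nt)) {
    R <- rvts[[t]]
    core <- R[margin:(d[1] - margin + 1), margin:(d[2] - margin + 1)]
    cand <- which(core > threshold, arr.ind = TRUE)
    if (nrow(cand) == 0) {
      detections[t] <- list(NULL)
      next
    }
    ci <- cand[, 1] + margin - 1L
    cj <- cand[, 2] + margin - 1L
    vals <- R[cbind(ci, cj)]
    is_max <- rep(TRUE, length(ci))
    for (si in -1:1) for (sj in -1:1) {
      if (si == 0 && sj == 0) next
      is_max <- is_max & vals >= R[cbind(ci + si, cj + sj)]
    }
    ci <- ci[is_max]; cj <- cj[is_max]
    if (length(ci) == 0) {
      detections[t] <- list(NULL)
      next
    }
    # suppress secondary maxima: within 2 px keep only the strongest
    # (plateaus); within min_separation_px drop maxima that are much weaker
    # than their neighbor -- the PSF ring's secondary response is ~10% of
    # the central one, while two genuine particles respond comparably
    if (length(ci) > 1) {
      vals2 <- R[cbind(ci, cj)]
      o <- order(vals2, decreasing = TRUE)
      ci <- ci[o]; cj <- cj[o]; vals2 <- vals2[o]
      keep <- rep(TRUE, length(ci))
      for (a in seq_along(ci)) {
        if (!keep[a]) next
        later <- seq_along(ci) > a
        near <- later & abs(ci - ci[a]) <= 2 & abs(cj - cj[a]) <= 2
        ringlike <- later & abs(ci - ci[a]) <= min_separation_px &
          abs(cj - cj[a]) <= min_separation_px & vals2 < 0.5 * vals2[a]
        keep[near | ringlike] <- FALSE
      }
      ci <- ci[keep]; cj <- cj[keep]
    }
    oy <- parabolic_offset(R[cbind(ci - 1L, cj)], R[cbind(ci, cj)],
                           R[cbind(ci + 1L, cj)])
    ox <- parabolic_offset(R[cbind(ci, cj - 1L)], R[cbind(ci, cj)],
                           R[cbind(ci, cj + 1L)])
    # contrast: peak of the corrected frame near the detection
    con <- vapply(seq_along(ci), function(a) {
      max(corrected$frames[(ci[a] - 1):(ci[a] + 1),
                           (cj[a] - 1):(cj[a] + 1), t])
    }, numeric(1))
    detections[[t]] <- list(x = cj + ox, y = ci + oy, contrast = con)
  }

  # greedy nearest-neighbor linking on pixel coordinates
  next_id <- 1L
  active_id <- integer(0)
  active_x <- numeric(0)
  active_y <- numeric(0)
  out <- vector("list", nt)
  for (t in seq_len(nt)) {
    det <- detections[[t]]
    if (is.null(det)) {
      active_id <- integer(0)
      next
    }
    nd <- length(det$x)
    assigned <- rep(NA_integer_, nd)
    if (length(active_id) > 0) {
      dist <- outer(det$x, active_x, "-")^2 + outer(det$y, active_y, "-")^2
      lim <- max_disp_px^2
      repeat {
        m <- which.min(dist)
        if (length(m) == 0 || dist[m] > lim) break
        di <- (m - 1) %% nd + 1
        tj <- (m - 1) %/% nd + 1
        assigned[di] <- active_id[tj]
        dist[di, ] <- Inf
        dist[, tj] <- Inf
      }
    }
    new_mask <- is.na(assigned)
    if (any(new_mask)) {
      assigned[new_mask] <- next_id + seq_len(sum(new_mask)) - 1L
      next_id <- next_id + sum(new_mask)
    }
    active_id <- assigned
    active_x <- det$x
    active_y <- det$y
    out[[t]] <- tibble(particle_id = assigned,
                       frame = stack$frame_ids[t],
                       x_px = det$x, y_px = det$y, contrast = det$contrast)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(particle_id = integer(0), frame = integer(0),
                  x_um = numeric(0), y_um = numeric(0),
                  contrast = numeric(0)))
  }
  res <- dplyr::mutate(res,
                       x_um = (.data$x_px - 0.5) * stack$pixel_size_um,
                       y_um = (.data$y_px - 0.5) * stack$pixel_size_um)
  res <- dplyr::select(res, "particle_id", "frame", "x_um", "y_um", "contrast")
  counts <- table(res$particle_id)
  keep <- as.integer(names(counts)[counts > min_localizations])
  res <- dplyr::filter(res, .data$particle_id %in% keep)
  # renumber kept trajectories consecutively
  res$particle_id <- match(res$particle_id, sort(unique(res$particle_id)))
  dplyr::arrange(res, .data$particle_id, .data$frame)
}
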