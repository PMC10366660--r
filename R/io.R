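#' Write / read a simulated sample
#'
#' The trajectory table goes to `<path>.csv` (columns `particle_id`,
#' `frame`, `x_um`, `y_um`, `contrast`) and the ground truth plus
#' generating configuration to a JSON sidecar `<path>.json`, including the
#' seed and a content hash for provenance. Identical inputs produce
#' byte-identical files.
#'
#' @param sample An `inta_sample`.
#' @param path Output path stem (without extension).
#' @return `path`, invisibly (for `write_sample`); an `inta_sample` (for
#'   `read_sample`).
#' @export
write_sample <- function(sample, path) {
  stopifnot(inherits(sample, "inta_sample"))
  readr::write_csv(sample$trajectories, paste0(path, ".csv"))
  side <- list(
    truth = sample$truth,
    optics = unclass(sample$optics),
    instrument = unclass(sample$instrument),
    calibration = unclass(sample$calibration),
    populations = lapply(sample$populations, unclass),
    seed = sample$seed,
    config_hash = fnv1a_hash(list(unclass(sample$optics),
                                  unclass(sample$instrument),
                                  unclass(sample$calibration),
                                  sample$seed)))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_sample
#' @export
read_sample <- function(path) {
  traj <- read_trajectories(paste0(path, ".csv"))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  # jsonlite may simplify the population list to a data frame
  pp <- side$populations
  n_pops <- if (is.data.frame(pp)) nrow(pp) else length(pp)
  pops <- lapply(seq_len(n_pops), function(i) {
    p <- if (is.data.frame(pp)) lapply(pp, `[[`, i) else pp[[i]]
    population_spec(p$name, p$size_median, unlist(p$size_iqr), p$ri_median,
                    unlist(p$ri_iqr), p$concentration)
  })
  structure(list(
    trajectories = traj,
    truth = as_tibble(side$truth),
    optics = do.call(optical_config, side$optics[c(
      "wavelength_nm", "medium_ri", "temperature_K", "viscosity_Pa_s")]),
    instrument = do.call(instrument_spec, side$instrument),
    calibration = contrast_calibration(side$calibration$amplitude),
    populations = pops,
    seed = side$seed), class = "inta_sample")
}

#' Read a trajectory table from CSV
#'
#' Validates the documented schema (`particle_id`, `frame`, `x_um`, `y_um`,
#' `contrast`); malformed rows are reported with their row numbers.
#'
#' @param path CSV file path.
#' @return A trajectory tibble.
#' @export
read_trajectories <- function(path) {
  traj <- readr::read_csv(path, show_col_types = FALSE)
  required_cols(traj, c("particle_id", "frame", "x_um", "y_um", "contrast"),
                sprintf("'%s'", path))
  num <- c("frame", "x_um", "y_um", "contrast")
  for (col in num) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(traj[[col]]))))
    if (length(bad) > 0) {
      abort(sprintf("'%s': non-numeric or missing `%s` at row(s) %s.",
                    path, col, paste(head(bad, 5), collapse = ", ")))
    }
  }
  traj$particle_id <- as.integer(factor(traj$particle_id,
                                        levels = unique(traj$particle_id)))
  traj$frame <- as.integer(traj$frame)
  traj
}

#' Write / read a particle record table
#'
#' Plain CSV of the [estimate_particles()] output.
#' @param records A particle record tibble.
#' @param path CSV file path.
#' @export
write_records <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  rec <- readr::read_csv(path, show_col_types = FALSE)
  required_cols(rec, c("particle_id", "n_localizations", "diameter_nm",
                       "sigma_nm2", "ri"), sprintf("'%s'", path))
  rec
}

#' Write / read a frame stack as plain text
#'
#' One header line (`ny nx nt pixel_size_um frame_rate_hz`), one line of
#' frame ids, then one whitespace-separated line of row-major pixel values
#' per frame. A text stand-in for multi-page TIFF.
#'
#' @param stack An `inta_frames`.
#' @param path File path.
#' @export
write_frames <- function(stack, path) {
  stopifnot(inherits(stack, "inta_frames"))
  d <- dim(stack$frames)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(d[1], d[2], d[3], stack$pixel_size_um,
                   stack$frame_rate_hz), con)
  writeLines(paste(stack$frame_ids, collapse = " "), con)
  for (t in seq_len(d[3])) {
    writeLines(paste(format(t(stack$frames[, , t]), digits = 9),
                     collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  lines <- readLines(path)
  hdr <- as.numeric(strsplit(lines[1], " +")[[1]])
  ids <- as.integer(strsplit(lines[2], " +")[[1]])
  ny <- hdr[1]; nx <- hdr[2]; nt <- hdr[3]
  frames <- array(NA_real_, c(ny, nx, nt))
  for (t in seq_len(nt)) {
    frames[, , t] <- matrix(as.numeric(strsplit(lines[2 + t], " +")[[1]]),
                            ny, nx, byrow = TRUE)
  }
  frame_stack(frames, hdr[4], hdr[5], ids)
}

#' Pipeline configuration
#'
#' `default_config()` returns the full nested default configuration
#' (optics, instrument, calibration, estimation, detection, classifier,
#' quantification blocks and the global seed); `write_config()` /
#' `read_config()` serialize it as JSON.
#'
#' @return A named list of configuration blocks.
#' @export
default_config <- function() {
  list(
    optics = unclass(optical_config()),
    instrument = unclass(instrument_spec()),
    calibration = unclass(contrast_calibration()),
    estimation = list(iqr_cutoff = 0.05, n_sims = 200, ri_max = 2.5),
    detection = list(rmin = 1, rmax = 6, background_window = 11,
                     threshold = "auto", max_disp_px = 5,
                     pixel_size_um = 0.055, noise_sd = 0.01),
    classifier = list(n_trees = 200, confidence_threshold = 0.8),
    quantification = list(dilution_factor = 1, recovery = NULL),
    seed = 1L)
}

#' @rdname default_config
#' @param config A configuration list.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_config()
  for (blk in names(base)) {
    if (!is.null(cfg[[blk]]) && is.list(base[[blk]])) {
      base[[blk]][names(cfg[[blk]])] <- cfg[[blk]]
    } else if (!is.null(cfg[[blk]])) {
      base[[blk]] <- cfg[[blk]]
    }
  }
  base
}

config_objects <- function(config) {
  list(
    optics = do.call(optical_config, config$optics),
    instrument = do.call(instrument_spec, config$instrument),
    calibration = contrast_calibration(config$calibration$amplitude))
}
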