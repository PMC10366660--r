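#' Fit the trajectory-count to concentration calibration
#'
#' Least-squares line through the origin relating known bead concentrations
#' to trajectory counts normalized to a 10-minute recording, mirroring the
#' dilution-series calibration with 60 nm polystyrene beads. The slope is
#' the calibration factor in (particles/mL) per (trajectories/10 min).
#'
#' @param series A tibble with columns `known_conc` (particles/mL, > 0),
#'   `n_trajectories`, `duration_s`; at least 3 points spanning at least a
#'   factor of 10 in concentration.
#' @return An `inta_conc_cal` with `factor`, `r_squared`, `n_points`.
#' @export
fit_concentration_calibration <- function(series) {
  required_cols(series, c("known_conc", "n_trajectories", "duration_s"),
                "`series`")
  if (nrow(series) < 3) {
    abort(sprintf("Calibration needs >= 3 points, got %d.", nrow(series)))
  }
  check_number(series$known_conc, "known_conc", positive = TRUE)
  check_number(series$duration_s, "duration_s", positive = TRUE)
  if (max(series$known_conc) / min(series$known_conc) < 10) {
    abort("Calibration series must span at least a 10-fold concentration range.")
  }
  counts10 <- series$n_trajectories * 600 / series$duration_s
  factor <- sum(counts10 * series$known_conc) / sum(counts10^2)
  fitted <- factor * counts10
  ss_res <- sum((series$known_conc - fitted)^2)
  ss_tot <- sum((series$known_conc - mean(series$known_conc))^2)
  structure(list(factor = factor,
                 r_squared = 1 - ss_res / ss_tot,
                 n_points = nrow(series),
                 reference = "dilution series (counts per 10 min, through origin)"),
            class = "inta_conc_cal")
}

#' @export
print.inta_conc_cal <- function(x, ...) {
  cat(sprintf(
    "<inta_conc_cal> %.4g (particles/mL) per (trajectories/10 min), R^2 = %.4f, n = %d\n",
    x$factor, x$r_squared, x$n_points))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.inta_conc_cal <- function(x, ...) {
  tibble(factor = x$factor, r_squared = x$r_squared, n_points = x$n_points)
}

#' Convert a trajectory count to a number concentration
#'
#' `conc = count * (600 / duration_s) * factor * dilution_factor`: counts are
#' normalized to a 10-minute equivalent, scaled by the calibration factor,
#' and corrected for any dilution applied before the measurement.
#'
#' @param count Number of kept trajectories (those passing the
#'   minimum-localization filter).
#' @param duration_s Recording duration, s.
#' @param calibration An `inta_conc_cal` from
#'   [fit_concentration_calibration()].
#' @param dilution_factor Pre-measurement dilution (default 1).
#' @return Concentration, particles/mL.
#' @export
trajectories_to_concentration <- function(count, duration_s, calibration,
                                          dilution_factor = 1) {
  stopifnot(inherits(calibration, "inta_conc_cal"))
  check_number(count, "count", nonneg = TRUE)
  check_number(duration_s, "duration_s", positive = TRUE, len = 1)
  check_number(dilution_factor, "dilution_factor", positive = TRUE, len = 1)
  count * (600 / duration_s) * calibration$factor * dilution_factor
}

#' Recovery specification for EV enrichment protocols
#'
#' Recovery rate and volume metadata of an enrichment protocol, used to
#' back-calculate the EV concentration of the original plasma from the
#' concentration measured in the enriched sample.
#'
#' @param method Protocol name.
#' @param recovery_rate Fraction of EVs recovered, in (0, 1].
#' @param plasma_volume_ml Plasma input volume, mL.
#' @param final_volume_ml Final (enriched) sample volume, mL.
#' @return An `inta_recovery` list.
#' @seealso [recovery_presets()] for the shipped SEC/DMC/DG values.
#' @export
recovery_spec <- function(method, recovery_rate, plasma_volume_ml,
                          final_volume_ml) {
  stopifnot(is.character(method), length(method) == 1)
  check_number(recovery_rate, "recovery_rate", len = 1)
  if (recovery_rate <= 0 || recovery_rate > 1) {
    abort("`recovery_rate` must be in (0, 1].")
  }
  check_number(plasma_volume_ml, "plasma_volume_ml", positive = TRUE, len = 1)
  check_number(final_volume_ml, "final_volume_ml", positive = TRUE, len = 1)
  structure(list(method = method, recovery_rate = recovery_rate,
                 plasma_volume_ml = plasma_volume_ml,
                 final_volume_ml = final_volume_ml),
            class = "inta_recovery")
}

#' Shipped recovery presets
#'
#' Size-exclusion chromatography (SEC, 80% recovery, 0.5 mL plasma to
#' 0.1 mL), dual-mode chromatography (DMC, 33%, 0.5 to 0.1 mL) and density
#' gradient (DG, 25%, 6 mL to 0.1 mL).
#'
#' @param method One of "SEC", "DMC", "DG".
#' @return An `inta_recovery`.
#' @export
recovery_presets <- function(method = c("SEC", "DMC", "DG")) {
  method <- match.arg(method)
  switch(method,
         SEC = recovery_spec("SEC", 0.80, 0.5, 0.1),
         DMC = recovery_spec("DMC", 0.33, 0.5, 0.1),
         DG = recovery_spec("DG", 0.25, 6, 0.1))
}

#' Back-calculate the original plasma EV concentration
#'
#' Inverts the enrichment model: a protocol concentrates
#' `plasma_volume / final_volume` fold and recovers a fraction
#' `recovery_rate` of the EVs, so
#' `original = measured / (recovery_rate * plasma_volume / final_volume)`.
#'
#' @param measured_ev_conc EV concentration measured in the enriched sample,
#'   particles/mL.
#' @param recovery An `inta_recovery` (see [recovery_presets()]).
#' @return Estimated original plasma EV concentration, particles/mL.
#' @examples
#' # DMC-enriched sample measured at 9.8E10 particles/mL:
#' back_calculate_plasma_concentration(9.8e10, recovery_presets("DMC"))
#' @export
back_calculate_plasma_concentration <- function(measured_ev_conc, recovery) {
  stopifnot(inherits(recovery, "inta_recovery"))
  check_number(measured_ev_conc, "measured_ev_conc", nonneg = TRUE)
  measured_ev_conc /
    (recovery$recovery_rate *
       recovery$plasma_volume_ml / recovery$final_volume_ml)
}

#' Quantify a classified sample
#'
#' Combines classified particle records with the concentration calibration
#' into absolute and relative concentrations: total, EV and LP
#' concentrations (unclassified particles contribute to the total only),
#' the relative EV concentration, and optionally the back-calculated
#' original plasma EV concentration.
#'
#' @param classified Output of [classify_particles()].
#' @param duration_s Recording duration of the measurement, s.
#' @param calibration An `inta_conc_cal`.
#' @param dilution_factor Pre-measurement dilution (default 1).
#' @param recovery Optional `inta_recovery`; when supplied the EV
#'   concentration is back-calculated to the original plasma.
#' @return A one-row tibble: `n_trajectories`, `total_conc`, `ev_conc`,
#'   `lp_conc`, `relative_ev`, `fraction_classified`, `dilution_factor`, and
#'   `plasma_ev_conc` (NA without `recovery`).
#' @export
quantify_sample <- function(classified, duration_s, calibration,
                            dilution_factor = 1, recovery = NULL) {
  required_cols(classified, "label", "`classified`")
  n <- nrow(classified)
  conv <- function(count) {
    trajectories_to_concentration(count, duration_s, calibration,
                                  dilution_factor)
  }
  n_ev <- sum(classified$label == "EV")
  n_lp <- sum(classified$label == "LP")
  ev_conc <- conv(n_ev)
  tibble(
    n_trajectories = n,
    total_conc = conv(n),
    ev_conc = ev_conc,
    lp_conc = conv(n_lp),
    relative_ev = if (n_ev + n_lp > 0) n_ev / (n_ev + n_lp) else NA_real_,
    fraction_classified = if (n > 0) (n_ev + n_lp) / n else NA_real_,
    dilution_factor = dilution_factor,
    plasma_ev_conc = if (is.null(recovery)) NA_real_ else
      back_calculate_plasma_concentration(ev_conc, recovery))
}
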