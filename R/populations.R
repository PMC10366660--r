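#' Particle population specification
#'
#' Describes one particle class by the median and interquartile range (IQR)
#' of its size and refractive index distributions plus its number
#' concentration. Sizes are drawn from a lognormal matched to the stated
#' median and IQR (`meanlog = log(median)`,
#' `sdlog = log(q75/q25) / (2 * qnorm(0.75))`); refractive indices from a
#' normal matched the same way, truncated below at the medium index.
#'
#' @param name Population label, e.g. "EV", "ULDL", "VLDL".
#' @param size_median Median diameter, nm.
#' @param size_iqr Length-2 numeric, the (25%, 75%) diameter quantiles, nm.
#' @param ri_median Median effective refractive index.
#' @param ri_iqr Length-2 numeric, the (25%, 75%) RI quantiles.
#' @param concentration Number concentration, particles/mL (>= 0).
#' @return An `inta_population` list.
#' @seealso [population_presets()] for the shipped EV/ULDL/VLDL parameter
#'   sets, [sample_population()] to draw particles.
#' @export
population_spec <- function(name, size_median, size_iqr, ri_median, ri_iqr,
                            concentration) {
  stopifnot(is.character(name), length(name) == 1)
  check_number(size_median, "size_median", positive = TRUE, len = 1)
  check_number(size_iqr, "size_iqr", positive = TRUE, len = 2)
  check_number(ri_median, "ri_median", len = 1)
  check_number(ri_iqr, "ri_iqr", len = 2)
  check_number(concentration, "concentration", nonneg = TRUE, len = 1)
  validate_iqr(size_iqr, size_median, "size")
  validate_iqr(ri_iqr, ri_median, "ri")
  structure(
    list(name = name, size_median = size_median, size_iqr = size_iqr,
         ri_median = ri_median, ri_iqr = ri_iqr,
         concentration = concentration),
    class = "inta_population"
  )
}

validate_iqr <- function(iqr, med, what) {
  if (iqr[1] > iqr[2]) {
    abort(sprintf("Inconsistent %s IQR: q25 (%g) > q75 (%g).",
                  what, iqr[1], iqr[2]))
  }
  if (med < iqr[1] || med > iqr[2]) {
    abort(sprintf("%s median (%g) must lie within its IQR [%g, %g].",
                  what, med, iqr[1], iqr[2]))
  }
  invisible(iqr)
}

#' @export
print.inta_population <- function(x, ...) {
  cat(sprintf(
    "<inta_population> %s: d = %g (%g-%g) nm, RI = %g (%g-%g), %.3g /mL\n",
    x$name, x$size_median, x$size_iqr[1], x$size_iqr[2],
    x$ri_median, x$ri_iqr[1], x$ri_iqr[2], x$concentration))
  invisible(x)
}

#' Shipped population presets
#'
#' Size and refractive-index distributions (median and IQR) for
#' SKMEL37-derived extracellular vesicles, chylomicrons (ULDL) and very
#' low-density lipoproteins (VLDL), with iNTA-measured stock concentrations:
#' EVs 97 (79-120) nm, RI 1.37 (1.36-1.38), 1.58E12/mL;
#' ULDLs 57 (48-71) nm, RI 1.52 (1.48-1.57), 8.56E13/mL;
#' VLDLs 46 (41-52) nm, RI 1.49 (1.45-1.52), 2.80E13/mL.
#'
#' @param which Character vector of preset names to return.
#' @return A named list of [population_spec()] objects.
#' @export
population_presets <- function(which = c("EV", "ULDL", "VLDL")) {
  all <- list(
    EV = population_spec("EV", 97, c(79, 120), 1.37, c(1.36, 1.38), 1.58e12),
    ULDL = population_spec("ULDL", 57, c(48, 71), 1.52, c(1.48, 1.57), 8.56e13),
    VLDL = population_spec("VLDL", 46, c(41, 52), 1.49, c(1.45, 1.52), 2.80e13)
  )
  bad <- setdiff(which, names(all))
  if (length(bad) > 0) {
    abort(sprintf("Unknown preset(s): %s.", paste(bad, collapse = ", ")))
  }
  all[which]
}

#' Draw particle sizes and refractive indices for a population
#'
#' Diameters are lognormal with `meanlog = log(size_median)` and
#' `sdlog = log(q75/q25) / (2 * qnorm(0.75))`; refractive indices are normal
#' with mean `ri_median` and `sd = (q75 - q25) / (2 * qnorm(0.75))`,
#' truncated below at the medium index by rejection. A degenerate IQR
#' (both quantiles equal to the median) yields constant draws.
#'
#' @param spec A [population_spec()].
#' @param n Number of particles (>= 1).
#' @param optics An [optical_config()]; supplies the truncation floor for RI.
#' @param seed Optional integer seed; draws are reproducible given the seed.
#' @return A tibble with columns `diameter_nm`, `ri`.
#' @export
sample_population <- function(spec, n, optics = optical_config(),
                              seed = NULL) {
  stopifnot(inherits(spec, "inta_population"))
  check_number(n, "n", positive = TRUE, len = 1)
  n <- as.integer(n)
  z75 <- qnorm(0.75)
  sdlog <- log(spec$size_iqr[2] / spec$size_iqr[1]) / (2 * z75)
  ri_sd <- (spec$ri_iqr[2] - spec$ri_iqr[1]) / (2 * z75)
  nm <- optics$medium_ri
  with_seed_or_current(seed, {
    # degenerate IQRs mean a monodisperse quantity: return it exactly
    d <- if (sdlog == 0) rep(spec$size_median, n) else
      rlnorm(n, meanlog = log(spec$size_median), sdlog = sdlog)
    ri <- if (ri_sd == 0) rep(spec$ri_median, n) else
      rnorm(n, spec$ri_median, ri_sd)
    # truncate RI below the medium index by rejection
    while (any(bad <- ri < nm)) {
      ri[bad] <- rnorm(sum(bad), spec$ri_median, ri_sd)
      if (spec$ri_median < nm && ri_sd == 0) {
        abort("ri_median below the medium index with zero spread.")
      }
    }
    tibble(diameter_nm = d, ri = ri)
  })
}
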