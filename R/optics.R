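#' Optical and fluid configuration
#'
#' Bundles the optical context (vacuum wavelength, medium refractive index)
#' and the fluid state (temperature, viscosity) that size and refractive
#' index estimation require. Defaults are standard for aqueous iSCAT
#' measurements: a 525 nm laser, PBS-like buffer (n = 1.33), room
#' temperature, and the viscosity of water at 25 degrees C.
#'
#' @param wavelength_nm Vacuum wavelength of the illumination, nm.
#' @param medium_ri Refractive index of the suspension medium (>= 1).
#' @param temperature_K Absolute temperature, K.
#' @param viscosity_Pa_s Dynamic viscosity of the medium, Pa s.
#' @return An `inta_optics` list with the four fields above.
#' @examples
#' opt <- optical_config()
#' stokes_einstein_diffusion(100, opt) # ~4.9 um^2/s for a 100 nm sphere
#' @export
optical_config <- function(wavelength_nm = 525, medium_ri = 1.33,
                           temperature_K = 298.15,
                           viscosity_Pa_s = 8.9e-4) {
  check_number(wavelength_nm, "wavelength_nm", positive = TRUE, len = 1)
  check_number(medium_ri, "medium_ri", len = 1)
  if (medium_ri < 1) abort("`medium_ri` must be >= 1.")
  check_number(temperature_K, "temperature_K", positive = TRUE, len = 1)
  check_number(viscosity_Pa_s, "viscosity_Pa_s", positive = TRUE, len = 1)
  structure(
    list(wavelength_nm = wavelength_nm, medium_ri = medium_ri,
         temperature_K = temperature_K, viscosity_Pa_s = viscosity_Pa_s),
    class = "inta_optics"
  )
}

#' @export
print.inta_optics <- function(x, ...) {
  cat(sprintf(
    "<inta_optics> lambda = %g nm, n_medium = %g, T = %g K, eta = %g Pa s\n",
    x$wavelength_nm, x$medium_ri, x$temperature_K, x$viscosity_Pa_s))
  invisible(x)
}

#' Contrast calibration
#'
#' iSCAT contrast is proportional to the scattered field amplitude, i.e. to
#' the square root of the scattering cross-section: `C = amplitude * sqrt(sigma)`.
#' The proportionality constant comes from an instrument calibration and is
#' the single knob linking simulated cross-sections to simulated contrasts
#' (and measured contrasts back to cross-sections).
#'
#' @param amplitude Contrast per sqrt(nm^2), > 0. The default 0.01 gives a
#'   ~3% contrast for a 100 nm, RI 1.40 sphere in water at 525 nm.
#' @return An `inta_contrast_cal` list.
#' @export
contrast_calibration <- function(amplitude = 0.01) {
  check_number(amplitude, "amplitude", positive = TRUE, len = 1)
  structure(list(amplitude = amplitude), class = "inta_contrast_cal")
}

#' @export
print.inta_contrast_cal <- function(x, ...) {
  cat(sprintf("<inta_contrast_cal> amplitude = %g contrast/sqrt(nm^2)\n",
              x$amplitude))
  invisible(x)
}

kB_J_per_K <- 1.380649e-23

#' Stokes-Einstein relation
#'
#' `stokes_einstein_diffusion()` maps a hydrodynamic diameter to the
#' translational diffusion constant `D = kB*T / (3*pi*eta*d)`;
#' `stokes_einstein_diameter()` is its exact inverse. Both the trajectory
#' simulator and the diameter estimator call these two functions, so
#' generator and estimator share a single implementation of the relation.
#'
#' @param diameter_nm Hydrodynamic diameter, nm.
#' @param D_um2_s Diffusion constant, um^2/s.
#' @param optics An [optical_config()] (temperature and viscosity are used).
#' @return Diffusion constant in um^2/s, or diameter in nm.
#' @export
stokes_einstein_diffusion <- function(diameter_nm, optics = optical_config()) {
  check_number(diameter_nm, "diameter_nm", positive = TRUE)
  kB_J_per_K * optics$temperature_K * 1e21 /
    (3 * pi * optics$viscosity_Pa_s * diameter_nm)
}

#' @rdname stokes_einstein_diffusion
#' @export
stokes_einstein_diameter <- function(D_um2_s, optics = optical_config()) {
  check_number(D_um2_s, "D_um2_s", positive = TRUE)
  kB_J_per_K * optics$temperature_K * 1e21 /
    (3 * pi * optics$viscosity_Pa_s * D_um2_s)
}

# Mie scattering efficiency Q_sca for a homogeneous, non-absorbing sphere.
# x: size parameter pi*d*n_medium/lambda_vacuum; m: relative index n_p/n_m.
# Bohren & Huffman style: downward recurrence for the logarithmic derivative,
# upward recurrence for the Riccati-Bessel functions. Truncation at
# N = ceiling(x + 4 x^(1/3) + 2).
mie_q_sca <- function(x, m) {
  if (x <= 0) return(0)
  if (m == 1) return(0) # index-matched sphere scatters nothing
  nmax <- ceiling(x + 4 * x^(1/3) + 2)
  mx <- m * x
  nmx <- max(nmax, ceiling(abs(mx))) + 16
  D <- numeric(nmx)
  for (n in nmx:2) {
    k <- n / mx
    D[n - 1] <- k - 1 / (D[n] + k)
  }
  psi_nm2 <- cos(x) # psi_{-1}
  psi_nm1 <- sin(x) # psi_0
  chi_nm2 <- -sin(x) # chi_{-1}
  chi_nm1 <- cos(x)  # chi_0
  qsum <- 0
  for (n in seq_len(nmax)) {
    psi_n <- (2 * n - 1) / x * psi_nm1 - psi_nm2
    chi_n <- (2 * n - 1) / x * chi_nm1 - chi_nm2
    xi_n <- complex(real = psi_n, imaginary = -chi_n)
    xi_nm1 <- complex(real = psi_nm1, imaginary = -chi_nm1)
    ta <- D[n] / m + n / x
    tb <- D[n] * m + n / x
    a_n <- (ta * psi_n - psi_nm1) / (ta * xi_n - xi_nm1)
    b_n <- (tb * psi_n - psi_nm1) / (tb * xi_n - xi_nm1)
    qsum <- qsum + (2 * n + 1) * (Mod(a_n)^2 + Mod(b_n)^2)
    psi_nm2 <- psi_nm1; psi_nm1 <- psi_n
    chi_nm2 <- chi_nm1; chi_nm1 <- chi_n
  }
  2 / x^2 * qsum
}

#' Mie scattering cross-section of a homogeneous nanosphere
#'
#' Total scattering cross-section of a homogeneous sphere of diameter
#' `diameter_nm` and refractive index `particle_ri` suspended in the medium
#' described by `optics`, computed from the Mie partial-wave series
#' truncated at `N = ceiling(x + 4*x^(1/3) + 2)` terms (size parameter
#' `x = pi * d * n_medium / lambda`). An index-matched sphere
#' (`particle_ri == medium_ri`) returns exactly 0.
#'
#' @param diameter_nm Sphere diameter, nm (> 0); vectorized.
#' @param particle_ri Sphere refractive index (>= 1); vectorized.
#' @param optics An [optical_config()].
#' @return Scattering cross-section(s), nm^2.
#' @seealso [rayleigh_cross_section()] for the small-particle closed form,
#'   [invert_effective_ri()] for the inverse problem.
#' @examples
#' mie_cross_section(60, 1.59, optical_config()) # a 60 nm polystyrene bead
#' @export
mie_cross_section <- function(diameter_nm, particle_ri,
                              optics = optical_config()) {
  check_number(diameter_nm, "diameter_nm", positive = TRUE)
  check_number(particle_ri, "particle_ri")
  if (any(particle_ri < 1)) abort("`particle_ri` must be >= 1.")
  n <- max(length(diameter_nm), length(particle_ri))
  d <- rep_len(diameter_nm, n)
  np <- rep_len(particle_ri, n)
  x <- pi * d * optics$medium_ri / optics$wavelength_nm
  m <- np / optics$medium_ri
  q <- vapply(seq_len(n), function(i) mie_q_sca(x[i], m[i]), numeric(1))
  q * pi * (d / 2)^2
}

#' Rayleigh scattering cross-section (small-particle closed form)
#'
#' Closed-form dipole-limit cross-section
#' `sigma = (2 pi^5 / 3) d^6 / lambda_med^4 * ((m^2-1)/(m^2+2))^2`
#' with `m = particle_ri / medium_ri` and
#' `lambda_med = wavelength / medium_ri`. Valid for particles much smaller
#' than the wavelength; used as an independent check of the Mie series.
#'
#' @inheritParams mie_cross_section
#' @return Scattering cross-section(s), nm^2.
#' @export
rayleigh_cross_section <- function(diameter_nm, particle_ri,
                                   optics = optical_config()) {
  check_number(diameter_nm, "diameter_nm", positive = TRUE)
  check_number(particle_ri, "particle_ri")
  if (any(particle_ri < 1)) abort("`particle_ri` must be >= 1.")
  m <- particle_ri / optics$medium_ri
  lambda_med <- optics$wavelength_nm / optics$medium_ri
  (2 * pi^5 / 3) * diameter_nm^6 / lambda_med^4 * ((m^2 - 1) / (m^2 + 2))^2
}

#' Effective refractive index from size and scattering cross-section
#'
#' Solves the forward Mie model for the refractive index: returns the index
#' `n_p >= medium_ri` of a homogeneous sphere of the given diameter whose
#' total scattering cross-section equals `sigma_nm2`. The cross-section is
#' strictly increasing in `n_p` over the bracket in the sub-300 nm regime
#' used here, so the root is unique; it is found by bracketed root-finding
#' (Brent) to `tol` in the index. `sigma_nm2 = 0` maps to the medium index.
#'
#' @param diameter_nm Sphere diameter, nm (> 0); vectorized.
#' @param sigma_nm2 Measured scattering cross-section, nm^2 (>= 0); vectorized.
#' @param optics An [optical_config()].
#' @param ri_max Upper end of the search bracket (default 2.5).
#' @param tol Absolute tolerance on the refractive index.
#' @param clamp If `TRUE`, cross-sections above `sigma(diameter, ri_max)`
#'   return `ri_max` instead of erroring (used when propagating noisy
#'   contrast draws whose tails leave the bracket).
#' @return Effective refractive index (>= `medium_ri`).
#' @export
invert_effective_ri <- function(diameter_nm, sigma_nm2,
                                optics = optical_config(),
                                ri_max = 2.5, tol = 1e-9, clamp = FALSE) {
  check_number(diameter_nm, "diameter_nm", positive = TRUE)
  check_number(sigma_nm2, "sigma_nm2", nonneg = TRUE)
  n <- max(length(diameter_nm), length(sigma_nm2))
  d <- rep_len(diameter_nm, n)
  s <- rep_len(sigma_nm2, n)
  nm <- optics$medium_ri
  vapply(seq_len(n), function(i) {
    if (s[i] == 0) return(nm)
    smax <- mie_cross_section(d[i], ri_max, optics)
    if (s[i] > smax) {
      if (clamp) return(ri_max)
      abort(sprintf(
        paste0("sigma = %g nm^2 exceeds the cross-section %g nm^2 reachable ",
               "within the bracket [%g, %g] at d = %g nm; widen `ri_max`."),
        s[i], smax, nm, ri_max, d[i]))
    }
    uniroot(function(np) mie_cross_section(d[i], np, optics) - s[i],
            lower = nm, upper = ri_max,
            f.lower = -s[i], f.upper = smax - s[i], tol = tol)$root
  }, numeric(1))
}
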