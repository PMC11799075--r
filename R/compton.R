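# Compton kinematics and Klein-Nishina sampling.

.r_e_cm <- 2.8179403262e-13  # classical electron radius
.mec2_keV <- 511.0
.n_avogadro <- 6.02214076e23

#' Compton-scattered photon energy
#'
#' `E' = E / (1 + (E/511)(1 - cos theta))` for a photon of energy `E` keV
#' scattering through `theta`.
#'
#' @param energy_keV Incident photon energy (keV).
#' @param angle_rad Scattering angle in radians, in `[0, pi]`.
#' @return Scattered energy in keV (vectorised).
#' @examples
#' compton_energy(208.4, pi)  # backscatter
#' @export
compton_energy <- function(energy_keV, angle_rad) {
  abort_if(any(angle_rad < 0 | angle_rad > pi), "angle must be in [0, pi]")
  energy_keV / (1 + (energy_keV / .mec2_keV) * (1 - cos(angle_rad)))
}

#' Klein-Nishina differential cross-section
#'
#' Per-electron `d sigma / d Omega` in cm^2/sr at scattering angle
#' `angle_rad` for incident energy `energy_keV`.
#'
#' @inheritParams compton_energy
#' @return Differential cross-section (cm^2/sr).
#' @export
kn_differential <- function(energy_keV, angle_rad) {
  r <- compton_energy(energy_keV, angle_rad) / energy_keV  # E'/E
  0.5 * .r_e_cm^2 * r^2 * (r + 1 / r - sin(angle_rad)^2)
}

#' Klein-Nishina total cross-section
#'
#' Closed-form per-electron total Compton cross-section in cm^2.
#'
#' @param energy_keV Photon energy in keV.
#' @return Cross-section (cm^2), vectorised.
#' @export
kn_total <- function(energy_keV) {
  k <- energy_keV / .mec2_keV
  2 * pi * .r_e_cm^2 *
    ((1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k) +
       log(1 + 2 * k) / (2 * k) - (1 + 3 * k) / (1 + 2 * k)^2)
}

#' Sample Compton scattering angles
#'
#' Draws scattering angles from the Klein-Nishina angular distribution by
#' rejection sampling (uniform proposal in `cos theta`, envelope at the
#' forward-scatter maximum).
#'
#' @param energy_keV Incident energy; a scalar or a vector of length `n`
#'   (one energy per draw).
#' @param n Number of draws.
#' @param seed Optional integer seed for a self-contained draw.
#' @return `n` angles in radians.
#' @export
sample_compton_angle <- function(energy_keV, n, seed = NULL) {
  abort_if(any(energy_keV <= 0), "energy must be positive")
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))
  energy <- rep_len(energy_keV, n)
  with_seed_maybe(seed, {
    out <- numeric(n)
    todo <- seq_len(n)
    fmax <- .r_e_cm^2  # dsigma/dOmega at theta = 0
    while (length(todo) > 0) {
      th <- acos(stats::runif(length(todo), -1, 1))
      acc <- stats::runif(length(todo)) <
        kn_differential(energy[todo], th) / fmax
      out[todo[acc]] <- th[acc]
      todo <- todo[!acc]
    }
    out
  })
}

# incoherent (Compton) mass attenuation of a material from its electron
# density and the exact Klein-Nishina total cross-section
incoherent_mass_attenuation <- function(mat, energy_keV) {
  wf <- weight_fractions(mat)
  info <- mat$composition
  z_over_a <- sum(wf$mass_fraction * info$z[match(wf$symbol, info$symbol)] /
                    info$mass[match(wf$symbol, info$symbol)])
  z_over_a * .n_avogadro * kn_total(energy_keV)
}

# probability that an interaction in `mat` is a Compton scatter; the
# non-Compton remainder of the total attenuation is treated as absorption
compton_fraction <- function(mat, energy_keV) {
  pmin(1, incoherent_mass_attenuation(mat, energy_keV) /
         mass_attenuation(mat, energy_keV))
}
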