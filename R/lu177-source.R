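#' Lu-177 photon emission spectrum
#'
#' The photon source term of Lu-177 used throughout the package: the two
#' gamma lines (208.4 and 113.0 keV) and the four Yb/Lu K X-ray lines that
#' matter for gamma-camera imaging.  Intensities are expressed as photons
#' per decay (fractions, not percent); the six lines together carry 0.229
#' photons per decay.  Beta particles and weak high-energy gamma lines are
#' excluded: they do not reach the crystal through a parallel-hole
#' collimator in the regime modelled here.
#'
#' @return A tibble with columns `energy_keV`, `intensity` (photons/decay)
#'   and `type` (`"gamma"` or `"xray"`), one row per line, ordered by
#'   decreasing energy.
#' @examples
#' lu177_spectrum()
#' sum(lu177_spectrum()$intensity)  # 0.229
#' @export
lu177_spectrum <- function() {
  tibble::tibble(
    energy_keV = c(208.4, 113.0, 64.9, 63.2, 55.8, 54.6),
    intensity  = c(0.110, 0.064, 0.002, 0.009, 0.028, 0.016),
    type       = c("gamma", "gamma", "xray", "xray", "xray", "xray")
  )
}

#' Read an emission line table for another nuclide
#'
#' Lines are read from a two-column whitespace-separated text table
#' (`energy_keV`, `intensity_fraction`); lines starting with `#` are
#' comments.  Intensities must be fractions per decay, not percent.
#'
#' @param path Path to the table.
#' @return A tibble with columns `energy_keV`, `intensity`, `type` (set to
#'   `"line"`).
#' @export
read_emission_table <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("energy_keV", "intensity"))
  spec <- tibble::tibble(energy_keV = as.numeric(tab$energy_keV),
                         intensity = as.numeric(tab$intensity),
                         type = "line")
  validate_spectrum(spec)
  spec
}

validate_spectrum <- function(spectrum) {
  abort_if(nrow(spectrum) == 0L, "emission spectrum has no lines")
  abort_if(any(spectrum$energy_keV <= 0), "line energies must be positive")
  abort_if(any(spectrum$intensity <= 0 | spectrum$intensity > 1),
           "line intensities must be fractions in (0, 1]")
  abort_if(anyDuplicated(spectrum$energy_keV) > 0L,
           "line energies must be unique")
  invisible(spectrum)
}

#' Photon emission rate of a line
#'
#' `activity_bq * intensity`: the number of photons of one line emitted per
#' second by a source of the given activity.
#'
#' @param activity_bq Source activity in Bq (decays/s); must be >= 0.
#' @param intensity Photons per decay for the line (fraction).
#' @return Photons per second (vectorised over either argument).
#' @examples
#' photon_emission_rate(7.4e9, 0.110)  # 208-keV photons from 7.4 GBq
#' @export
photon_emission_rate <- function(activity_bq, intensity) {
  abort_if(any(activity_bq < 0), "activity must be non-negative")
  abort_if(any(intensity < 0 | intensity > 1),
           "intensity must be a fraction in [0, 1]")
  activity_bq * intensity
}

#' Emission rates for every line of a spectrum
#'
#' @param spectrum Emission spectrum tibble (see [lu177_spectrum()]).
#' @param activity_bq Source activity in Bq.
#' @return The spectrum with an added `rate_per_s` column.
#' @export
emission_rates <- function(spectrum, activity_bq) {
  validate_spectrum(spectrum)
  dplyr::mutate(spectrum,
                rate_per_s = photon_emission_rate(activity_bq, .data$intensity))
}

#' Sample emission line energies
#'
#' Draws `n` photon energies with probability proportional to line
#' intensity.  Used as the Monte Carlo source sampler.
#'
#' @param spectrum Emission spectrum tibble.
#' @param n Number of draws (>= 0).
#' @param seed Optional integer seed for a reproducible, self-contained
#'   draw; when `NULL` the current RNG stream is used.
#' @return Numeric vector of `n` energies in keV.
#' @export
sample_emission <- function(spectrum, n, seed = NULL) {
  validate_spectrum(spectrum)
  abort_if(!is_scalar_number(n) || n < 0, "n must be a non-negative count")
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))
  with_seed_maybe(seed, {
    idx <- sample.int(nrow(spectrum), n, replace = TRUE,
                      prob = spectrum$intensity)
    spectrum$energy_keV[idx]
  })
}
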