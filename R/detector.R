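# Detector response: intrinsic efficiency, Gaussian energy resolution,
# Poisson event streams, and event-level paralyzable dead time with
# optional pile-up.

#' Detector configuration
#'
#' @param crystal_thickness_cm NaI crystal thickness (default 0.95 cm).
#' @param resolution_fwhm Fractional FWHM of the energy response at the
#'   reference energy (default 0.094 at 208.4 keV).
#' @param reference_energy_keV Energy at which `resolution_fwhm` applies.
#' @param resolution_exponent Scaling of the fractional FWHM with energy,
#'   `FWHM(E)/E = resolution_fwhm * (E/ref)^exponent`; the default -0.5
#'   is the usual statistical 1/sqrt(E) law for scintillators.
#' @param full_window Full-energy window `c(low, high)` in keV over which
#'   every recorded event, regardless of analysis window, loads the
#'   electronics (default 20-400 keV).
#' @param tau_full_s Paralyzable dead time for the full window (default
#'   0.5 us).
#' @param pileup Whether coincident arrivals are summed into one recorded
#'   event (default `TRUE`).
#' @param integration_s Pulse integration window for pile-up summation
#'   (default equal to `tau_full_s`).
#' @return A `gc_detector`.
#' @export
detector_config <- function(crystal_thickness_cm = 0.95,
                            resolution_fwhm = 0.094,
                            reference_energy_keV = 208.4,
                            resolution_exponent = -0.5,
                            full_window = c(20, 400),
                            tau_full_s = 5e-7,
                            pileup = TRUE,
                            integration_s = tau_full_s) {
  abort_if(tau_full_s < 0, "dead time must be >= 0")
  abort_if(crystal_thickness_cm < 0, "crystal thickness must be >= 0")
  abort_if(full_window[1] >= full_window[2], "full window must be low < high")
  structure(list(crystal_thickness_cm = crystal_thickness_cm,
                 resolution_fwhm = resolution_fwhm,
                 reference_energy_keV = reference_energy_keV,
                 resolution_exponent = resolution_exponent,
                 full_window = full_window,
                 tau_full_s = tau_full_s, pileup = pileup,
                 integration_s = integration_s),
            class = "gc_detector")
}

#' Intrinsic photopeak-counting efficiency of the crystal
#'
#' Interaction probability `1 - exp(-mu_NaI(E) * d)` of a photon crossing
#' the crystal thickness `d`.
#'
#' @param energy_keV Photon energies (keV).
#' @param config A `gc_detector`.
#' @return Fraction in `[0, 1)`, vectorised.
#' @export
intrinsic_efficiency <- function(energy_keV, config = detector_config()) {
  mu <- mass_attenuation(material_nai(), energy_keV) *
    material_nai()$density_g_cm3
  1 - exp(-mu * config$crystal_thickness_cm)
}

# fractional FWHM at energy E
fwhm_fraction <- function(energy_keV, config) {
  config$resolution_fwhm *
    (energy_keV / config$reference_energy_keV)^config$resolution_exponent
}

#' Apply Gaussian energy blur
#'
#' Draws recorded energies from a Gaussian centred on the true energy with
#' `FWHM(E) = f(E) * E` where the fractional FWHM `f` follows the
#' configured scaling law; negative draws are redrawn.
#'
#' @param energy_keV True deposited energies (keV).
#' @param config A `gc_detector`.
#' @param seed Optional integer seed.
#' @return Blurred energies (keV).
#' @export
blur_energy <- function(energy_keV, config = detector_config(), seed = NULL) {
  if (config$resolution_fwhm == 0) return(energy_keV)
  sigma <- fwhm_fraction(energy_keV, config) * energy_keV / 2.3548200450309493
  with_seed_maybe(seed, {
    out <- stats::rnorm(length(energy_keV), energy_keV, sigma)
    bad <- which(out <= 0)
    while (length(bad) > 0) {
      out[bad] <- stats::rnorm(length(bad), energy_keV[bad], sigma[bad])
      bad <- bad[out[bad] <= 0]
    }
    out
  })
}

#' Generate a time-stamped event stream from an incident spectrum
#'
#' A homogeneous Poisson stream at the total detected rate
#' `sum(bin rate x intrinsic efficiency)`; each event carries a blurred
#' energy and a flag recording whether it came from the primary
#' (unscattered) or scattered component of its bin.
#'
#' @param incident A `gc_spectrum`.
#' @param config A `gc_detector`.
#' @param duration_s Stream duration in seconds.
#' @param seed Optional integer seed.
#' @return A tibble (`time_s`, `energy_keV`, `primary`) sorted in time.
#' @export
generate_event_stream <- function(incident, config = detector_config(),
                                  duration_s = 1, seed = NULL) {
  abort_if(duration_s <= 0, "duration must be positive")
  mid <- (incident$bin_low_keV + incident$bin_high_keV) / 2
  eff <- intrinsic_efficiency(mid, config)
  p_rate <- incident$primary_rate * eff
  s_rate <- incident$scatter_rate * eff
  lambda <- sum(p_rate) + sum(s_rate)
  empty <- tibble::tibble(time_s = numeric(0), energy_keV = numeric(0),
                          primary = logical(0))
  if (lambda <= 0) return(empty)
  with_seed_maybe(seed, {
    n <- stats::rpois(1, lambda * duration_s)
    if (n == 0) {
      empty
    } else {
      times <- sort(stats::runif(n, 0, duration_s))
      rates <- c(p_rate, s_rate)
      bin <- sample.int(length(rates), n, replace = TRUE, prob = rates)
      nb <- length(mid)
      primary <- bin <= nb
      bidx <- ifelse(primary, bin, bin - nb)
      true_e <- incident$bin_low_keV[bidx] +
        stats::runif(n) * (incident$bin_high_keV[bidx] - incident$bin_low_keV[bidx])
      tibble::tibble(time_s = times, energy_keV = blur_energy(true_e, config),
                     primary = primary)
    }
  })
}

#' Apply paralyzable dead time to an event stream
#'
#' Paralyzable rule: an arrival is recorded only if the gap since the
#' immediately preceding arrival (recorded or not) exceeds `tau_s` --
#' every arrival restarts the dead period.  With `pileup = TRUE`, arrivals
#' falling within `integration_s` of a recorded event have their energies
#' summed into that event's recorded energy (the triggering arrival keeps
#' the timestamp), which distorts the recorded spectrum at high rates.
#'
#' @param stream Event tibble from [generate_event_stream()].
#' @param tau_s Dead time in seconds.
#' @param pileup Sum coincident energies into the triggering event.
#' @param integration_s Pile-up integration window (default `tau_s`).
#' @return The recorded event tibble (subset of arrivals, possibly with
#'   summed energies).
#' @export
apply_paralyzable <- function(stream, tau_s, pileup = FALSE,
                              integration_s = tau_s) {
  abort_if(tau_s < 0, "dead time must be >= 0")
  n <- nrow(stream)
  if (n == 0 || tau_s == 0) return(stream)
  keep <- c(TRUE, diff(stream$time_s) > tau_s)
  rec <- stream[keep, , drop = FALSE]
  if (pileup && integration_s > 0) {
    rec_id <- cumsum(keep)                 # recorded event each arrival follows
    dt <- stream$time_s - rec$time_s[rec_id]
    inwin <- dt <= integration_s           # includes the trigger itself (dt = 0)
    summed <- rowsum(stream$energy_keV[inwin], rec_id[inwin])
    idx <- as.integer(rownames(summed))
    rec$energy_keV[idx] <- summed[, 1]
  }
  rec
}

#' Record a measurement second by second
#'
#' Simulates whole seconds of acquisition until the cumulative observed
#' counts in the main analysis window exceed `min_counts` (and at least
#' `min_seconds` seconds have been recorded), storing per-second true
#' (loss-free) and observed counts per window together with aggregated
#' true and observed spectra.
#'
#' @param incident A `gc_spectrum` of true incident rates.
#' @param config A `gc_detector`.
#' @param windows Tibble of analysis windows (`name`, `low_keV`,
#'   `high_keV`); the first row is the main window driving the stop rule.
#' @param seed Optional integer seed (each second gets a derived seed).
#' @param min_counts Stop once this many observed main-window counts have
#'   accumulated (default 10,000).
#' @param min_seconds Record at least this many seconds (default 1).
#' @param max_seconds Hard cap; reaching it without `min_counts` is an
#'   error.
#' @return A `gc_measurement`: list with `per_second` (tibble: `second`,
#'   `window`, `true_counts`, `observed_counts`), `per_second_primary`
#'   (true unscattered and TEW-ready counts per second),
#'   `spectra` (2-keV histogram of true and observed counts per second),
#'   and `duration_s`.
#' @export
record_measurement <- function(incident, config = detector_config(),
                               windows, seed = NULL, min_counts = 1e4,
                               min_seconds = 1, max_seconds = 600) {
  abort_if(nrow(windows) < 1, "need at least one analysis window")
  edges <- seq(config$full_window[1], config$full_window[2], by = 2)
  hist_counts <- function(e) {
    inside <- e >= edges[1] & e < edges[length(edges)]
    tabulate(findInterval(e[inside], edges), length(edges) - 1L)
  }
  win_rows <- dplyr::bind_rows(
    tibble::tibble(name = "full", low_keV = config$full_window[1],
                   high_keV = config$full_window[2]),
    windows
  )
  count_windows <- function(e) {
    vapply(seq_len(nrow(win_rows)), function(i)
      sum(e >= win_rows$low_keV[i] & e < win_rows$high_keV[i]), numeric(1))
  }
  true_spec <- numeric(length(edges) - 1L)
  obs_spec <- numeric(length(edges) - 1L)
  per_second <- list()
  primary_rows <- list()
  cum_main <- 0
  main_row <- 2L  # first analysis window, after the prepended full window
  sec <- 0L
  base_seed <- if (is.null(seed)) NULL else as.integer(seed)
  repeat {
    sec <- sec + 1L
    abort_if(sec > max_seconds,
             "stop rule unreachable: observed counts did not reach min_counts")
    sseed <- if (is.null(base_seed)) NULL else (base_seed + 7L * sec) %% 2147483647L
    stream <- generate_event_stream(incident, config, 1, seed = sseed)
    obs <- apply_paralyzable(stream, config$tau_full_s, config$pileup,
                             config$integration_s)
    tc <- count_windows(stream$energy_keV)
    oc <- count_windows(obs$energy_keV)
    per_second[[sec]] <- tibble::tibble(second = sec, window = win_rows$name,
                                        true_counts = tc, observed_counts = oc)
    # loss-free unscattered counts in the main analysis window
    main_lo <- win_rows$low_keV[main_row]; main_hi <- win_rows$high_keV[main_row]
    primary_rows[[sec]] <- tibble::tibble(
      second = sec,
      true_unscattered = sum(stream$primary & stream$energy_keV >= main_lo &
                               stream$energy_keV < main_hi),
      arrivals = nrow(stream), recorded = nrow(obs))
    true_spec <- true_spec + hist_counts(stream$energy_keV)
    obs_spec <- obs_spec + hist_counts(obs$energy_keV)
    cum_main <- cum_main + oc[main_row]
    if (cum_main >= min_counts && sec >= min_seconds) break
  }
  structure(list(
    per_second = dplyr::bind_rows(per_second),
    per_second_primary = dplyr::bind_rows(primary_rows),
    spectra = tibble::tibble(bin_low_keV = edges[-length(edges)],
                             bin_high_keV = edges[-1],
                             true_rate = true_spec / sec,
                             observed_rate = obs_spec / sec),
    duration_s = sec, windows = win_rows, config = config
  ), class = "gc_measurement")
}

#' @export
print.gc_measurement <- function(x, ...) {
  cat(sprintf("<measurement> %d s recorded, %d windows\n", x$duration_s,
              nrow(x$windows)))
  print(dplyr::summarise(
    dplyr::group_by(x$per_second, .data$window),
    true_cps = mean(.data$true_counts),
    observed_cps = mean(.data$observed_counts)))
  invisible(x)
}
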