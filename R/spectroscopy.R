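# Energy windows, window fractions, and TEW scatter correction.

#' Energy window
#'
#' @param low_keV,high_keV Window bounds in keV, `low < high`.
#' @return A `gc_window` (named numeric of length 2).
#' @export
energy_window <- function(low_keV, high_keV) {
  abort_if(low_keV >= high_keV, "window must satisfy low < high")
  structure(c(low = unname(low_keV), high = unname(high_keV)),
            class = "gc_window")
}

window_width <- function(w) unname(w["high"] - w["low"])

#' The standard Lu-177 main window, 208 keV +/- 10%
#'
#' By default the window is centred on the physical photopeak energy
#' 208.4 keV, giving 187.56-229.24 keV; `nominal = TRUE` uses the nominal
#' 208 keV setting (187.2-228.8 keV) instead.
#'
#' @param nominal Use the nominal 208 keV centre.
#' @return A `gc_window`.
#' @export
main_window_208 <- function(nominal = FALSE) {
  peak <- if (nominal) 208 else 208.4
  energy_window(0.9 * peak, 1.1 * peak)
}

#' TEW configuration
#'
#' Sub-windows for the triple-energy-window scatter correction abut the
#' main window.  Their width is 10% by default; whether "10%" means 10%
#' of the photopeak energy or 10% of the main-window width is selectable
#' (`basis`), defaulting to the photopeak-energy reading (20.84 keV for
#' the 208.4-keV peak).
#'
#' @param main Main `gc_window`.
#' @param subwidth_frac Sub-window width as a fraction (default 0.10).
#' @param basis `"photopeak"` or `"window"`.
#' @param peak_keV Photopeak energy used under the `"photopeak"` basis.
#' @return A `gc_tew` list with `main`, `lower`, `upper` windows.
#' @export
tew_config <- function(main = main_window_208(), subwidth_frac = 0.10,
                       basis = c("photopeak", "window"), peak_keV = 208.4) {
  basis <- match.arg(basis)
  abort_if(subwidth_frac <= 0, "sub-window width must be positive")
  w <- if (basis == "photopeak") subwidth_frac * peak_keV
       else subwidth_frac * window_width(main)
  structure(list(
    main = main,
    lower = energy_window(main["low"] - w, main["low"]),
    upper = energy_window(main["high"], main["high"] + w)
  ), class = "gc_tew")
}

#' Windows of a TEW configuration as a tibble
#'
#' @param tew A `gc_tew`.
#' @return Tibble (`name`, `low_keV`, `high_keV`) with rows `main`,
#'   `lower`, `upper` -- the layout [record_measurement()] expects.
#' @export
tew_windows <- function(tew = tew_config()) {
  tibble::tibble(
    name = c("main", "lower", "upper"),
    low_keV = c(tew$main["low"], tew$lower["low"], tew$upper["low"]),
    high_keV = c(tew$main["high"], tew$lower["high"], tew$upper["high"])
  )
}

#' Counts of a binned spectrum inside a window
#'
#' Bins partially covered by the window contribute fractionally.
#'
#' @param spectrum Tibble with `bin_low_keV`, `bin_high_keV` and one or
#'   more count/rate columns.
#' @param window A `gc_window`.
#' @param column Which column to sum (default `"counts"`).
#' @return Scalar sum.
#' @export
counts_in_window <- function(spectrum, window, column = "counts") {
  lo <- spectrum$bin_low_keV
  hi <- spectrum$bin_high_keV
  frac <- pmax(0, pmin(hi, window["high"]) - pmax(lo, window["low"])) / (hi - lo)
  sum(spectrum[[column]] * frac)
}

#' Window fraction
#'
#' `wf = counts in analysis window / counts in full window`, the quantity
#' that controls how much longer the apparent dead time is than the
#' full-window dead time.
#'
#' @param counts Counts (or rate) in the analysis window.
#' @param full_counts Counts (or rate) in the full window.
#' @return Tibble (`counts`, `full_counts`, `wf`); vectorised.
#' @export
window_fraction <- function(counts, full_counts) {
  abort_if(any(full_counts == 0), "window fraction undefined: empty full window")
  abort_if(any(counts > full_counts),
           "analysis window cannot hold more counts than the full window")
  tibble::tibble(counts = counts, full_counts = full_counts,
                 wf = counts / full_counts)
}

#' TEW primary counts
#'
#' Triple-energy-window scatter estimate
#' `S = (C_L / w_L + C_U / w_U) * w_M / 2` by trapezoidal interpolation
#' from the two flanking sub-windows; primary counts are
#' `max(C_M - S, 0)` with `clamped = TRUE` whenever the subtraction was
#' negative.
#'
#' @param main_counts,lower_counts,upper_counts Counts in the main and
#'   flanking sub-windows (vectorised).
#' @param tew A `gc_tew` supplying window widths, or `NULL` if widths are
#'   given directly.
#' @param main_width,lower_width,upper_width Widths in keV (taken from
#'   `tew` when supplied).
#' @return Tibble (`primary`, `scatter`, `clamped`).
#' @export
tew_primary <- function(main_counts, lower_counts, upper_counts,
                        tew = tew_config(), main_width = NULL,
                        lower_width = NULL, upper_width = NULL) {
  if (!is.null(tew)) {
    main_width <- main_width %||% window_width(tew$main)
    lower_width <- lower_width %||% window_width(tew$lower)
    upper_width <- upper_width %||% window_width(tew$upper)
  }
  abort_if(any(c(main_width, lower_width, upper_width) <= 0),
           "window widths must be positive")
  abort_if(any(c(main_counts, lower_counts, upper_counts) < 0),
           "counts must be non-negative")
  scatter <- (lower_counts / lower_width + upper_counts / upper_width) *
    main_width / 2
  primary <- main_counts - scatter
  clamped <- primary < 0
  tibble::tibble(primary = pmax(primary, 0), scatter = scatter,
                 clamped = clamped)
}
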