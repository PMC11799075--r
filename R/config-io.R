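# Declarative experiment configuration (YAML, schema version 1).
#
# Every field is optional; omitted fields take the packaged defaults, so a
# config file only states what it changes.  See
# inst/extdata/default-config.yaml for a fully spelled-out example.

#' Read an experiment configuration from YAML
#'
#' Schema (version 1): top-level keys `n_histories`, `max_scatters`,
#' `min_counts`, `min_seconds`, `eta`, `injected_activity_bq`,
#' `tfp_density_g_cm3`, `filters` (subset of `none`, `tfp`, `lead`),
#' `organs` (list of `name`, `shape`, `center`, `half_size`,
#' `percent_ia`), `detector` (`tau_full_us`, `resolution_fwhm`, `pileup`,
#' `full_window`), `tew` (`subwidth_frac`, `basis`), `retention`
#' (`kind`, `half_life_h`, `anchor` or `table`), and `time_grid`
#' (`from`, `to`, `by`).
#'
#' @param path YAML file path.
#' @return A `gc_experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  abort_if(!is.null(y$schema) && y$schema != 1, "unknown config schema version")

  organs <- if (is.null(y$organs)) default_phantom()$organs else
    dplyr::bind_rows(lapply(y$organs, function(o)
      organ_source(o$name, o$shape, as.numeric(o$center),
                   as.numeric(o$half_size), o$percent_ia)))
  phantom <- phantom_config(
    organs,
    injected_activity_bq = y$injected_activity_bq %||% 7.4e9)

  det_y <- y$detector %||% list()
  detector <- detector_config(
    tau_full_s = (det_y$tau_full_us %||% 0.5) * 1e-6,
    resolution_fwhm = det_y$resolution_fwhm %||% 0.094,
    pileup = det_y$pileup %||% TRUE,
    full_window = as.numeric(det_y$full_window %||% c(20, 400)))

  tew_y <- y$tew %||% list()
  tew <- tew_config(subwidth_frac = tew_y$subwidth_frac %||% 0.10,
                    basis = tew_y$basis %||% "photopeak")

  ret_y <- y$retention %||% list()
  retention <- if (identical(ret_y$kind, "table")) {
    retention_curve("table",
                    table = tibble::tibble(
                      time_h = vapply(ret_y$table, `[[`, numeric(1), 1),
                      fraction = vapply(ret_y$table, `[[`, numeric(1), 2)))
  } else {
    retention_curve(ret_y$kind %||% "monoexp",
                    half_life_h = ret_y$half_life_h %||% 80,
                    anchor = as.numeric(ret_y$anchor %||% c(24, 0.52)))
  }

  tfp_density <- y$tfp_density_g_cm3 %||% 3.4
  stock <- list(none = NULL, tfp = filter_tfp_12(tfp_density),
                lead = filter_lead_05())
  wanted <- unlist(y$filters) %||% names(stock)
  abort_if(!all(wanted %in% names(stock)),
           "filters must be drawn from: none, tfp, lead")
  tg <- y$time_grid %||% list()
  experiment_config(
    phantom = phantom, detector = detector, filters = stock[wanted],
    tew = tew, eta = y$eta %||% 1.4, retention = retention,
    n_histories = y$n_histories %||% 2e4,
    max_scatters = y$max_scatters %||% 2,
    min_counts = y$min_counts %||% 1e4,
    min_seconds = y$min_seconds %||% 5,
    time_grid = seq(tg$from %||% 24, tg$to %||% 120, by = tg$by %||% 8))
}
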