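# Orchestration of the full comparison: three filter configurations on two
# detectors, per-second statistics, significance tests, and the time-course
# assessment.

#' Experiment configuration
#'
#' Bundles every stage parameter of the default comparison (no filter vs
#' 1.2-mm tungsten functional paper vs 0.5-mm lead sheet, anterior and
#' posterior detectors).
#'
#' @param phantom A `gc_phantom` (default [default_phantom()]).
#' @param detector A `gc_detector`.
#' @param filters Named list of `gc_filter`s (`NULL` = no filter); names
#'   label the configurations.
#' @param tew A `gc_tew`.
#' @param eta Window-fraction exponent used when predicting apparent dead
#'   times from Eq.-style scaling (the simulation also fits eta itself).
#' @param retention A `gc_retention` for the time course.
#' @param n_histories Decay histories per transport run.
#' @param max_scatters Maximum Compton order.
#' @param min_counts Observed main-window counts required before the
#'   per-second recording stops.
#' @param min_seconds Minimum seconds recorded (>= 2 gives the per-second
#'   distributions the significance tests need).
#' @param time_grid Assessment grid in hours (within 24-120).
#' @return A `gc_experiment_config`.
#' @export
experiment_config <- function(phantom = default_phantom(),
                              detector = detector_config(),
                              filters = list(none = NULL,
                                             tfp = filter_tfp_12(),
                                             lead = filter_lead_05()),
                              tew = tew_config(),
                              eta = 1.4,
                              retention = retention_curve(),
                              n_histories = 2e4,
                              max_scatters = 2,
                              min_counts = 1e4,
                              min_seconds = 5,
                              time_grid = seq(24, 120, by = 8)) {
  abort_if(is.null(names(filters)) || any(!nzchar(names(filters))),
           "filters must be a named list")
  structure(list(phantom = phantom, detector = detector, filters = filters,
                 tew = tew, eta = eta, retention = retention,
                 n_histories = n_histories, max_scatters = max_scatters,
                 min_counts = min_counts, min_seconds = min_seconds,
                 time_grid = time_grid),
            class = "gc_experiment_config")
}

#' Welch's unequal-variance t-test
#'
#' Thin tibble wrapper around [stats::t.test()] with
#' Welch-Satterthwaite degrees of freedom, two-sided.
#'
#' @param a,b Numeric samples, each of length >= 2 with some variance.
#' @return One-row tibble (`statistic`, `df`, `p_value`).
#' @export
welch_t <- function(a, b) {
  abort_if(length(a) < 2 || length(b) < 2, "each sample needs >= 2 values")
  abort_if(stats::var(a) + stats::var(b) <= 0,
           "degenerate samples: no variance")
  ht <- stats::t.test(a, b, var.equal = FALSE)
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value)
}

#' Bonferroni correction
#'
#' `min(1, p * m)` elementwise for a family of `m` comparisons.
#'
#' @param p P-values in `[0, 1]`.
#' @param m Number of comparisons in the family, `>= length(p)`.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  abort_if(any(p < 0 | p > 1), "p-values must lie in [0, 1]")
  abort_if(m < length(p), "m must be at least the number of p-values")
  stats::p.adjust(p, method = "bonferroni", n = m)
}

# per-second analysis metrics of one recorded measurement
per_second_metrics <- function(meas, tew) {
  wide <- tidyr::pivot_wider(meas$per_second, names_from = "window",
                             values_from = c("true_counts", "observed_counts"))
  prim <- meas$per_second_primary
  tp <- tew_primary(wide$observed_counts_main, wide$observed_counts_lower,
                    wide$observed_counts_upper, tew)
  obs_primary <- tp$primary
  true_primary <- prim$true_unscattered
  tibble::tibble(
    second = wide$second,
    wf = wide$observed_counts_main / wide$observed_counts_full,
    tau_w_s = solve_tau(wide$true_counts_main,
                        pmin(wide$observed_counts_main, wide$true_counts_main)),
    true_primary = true_primary,
    obs_primary = obs_primary,
    loss_pct = deadtime_loss(true_primary, pmin(obs_primary, true_primary))
  )
}

#' Run the full filter-comparison experiment
#'
#' Transports shared decay histories to both detectors under every filter,
#' records per-second measurements through the paralyzable detector model,
#' computes per-second window fractions, apparent dead times
#' (single-pair solve per second) and TEW dead-time losses, fits the
#' window-fraction exponent per detector, runs Welch's t-tests
#' (filters vs none, Bonferroni-corrected per metric family), and
#' assembles the 24-120 h time-course assessment.  Deterministic for a
#' fixed seed.
#'
#' @param config A `gc_experiment_config`.
#' @param seed Integer seed; every stage derives its substream from it.
#' @return A `gc_experiment` with tibbles `summary`, `eta`, `tests`,
#'   `timecourse`, plus the incident `spectra` and raw `per_second`
#'   metrics.
#' @export
run_experiment <- function(config = experiment_config(), seed = 1) {
  placements <- list(detector1 = detector_placement("anterior"),
                     detector2 = detector_placement("posterior"))
  incidents <- simulate_incident_multi(config$phantom, placements,
                                       config$filters, config$n_histories,
                                       config$max_scatters, seed = seed)
  windows <- tew_windows(config$tew)
  summary_rows <- list()
  per_second <- list()
  k <- 0L
  for (d in seq_along(placements)) {
    for (f in seq_along(config$filters)) {
      k <- k + 1L
      meas <- record_measurement(
        incidents[[d]][[f]], config$detector, windows,
        seed = (as.integer(seed) + 7919L * d + 104729L * f) %% 2147483647L,
        min_counts = config$min_counts, min_seconds = config$min_seconds)
      met <- per_second_metrics(meas, config$tew)
      met$detector <- d
      met$filter <- names(config$filters)[f]
      per_second[[k]] <- met
      summary_rows[[k]] <- tibble::tibble(
        detector = d, filter = names(config$filters)[f],
        incident_rate = total_rate(incidents[[d]][[f]]),
        wf_mean = mean(met$wf), wf_sd = stats::sd(met$wf),
        tau_w_us_mean = mean(met$tau_w_s) * 1e6,
        tau_w_us_sd = stats::sd(met$tau_w_s) * 1e6,
        true_primary_cps = mean(met$true_primary),
        obs_primary_cps = mean(met$obs_primary),
        loss_pct_mean = mean(met$loss_pct),
        loss_pct_sd = stats::sd(met$loss_pct),
        duration_s = meas$duration_s)
    }
  }
  summary <- dplyr::bind_rows(summary_rows)
  per_second <- dplyr::bind_rows(per_second)

  eta_fits <- dplyr::bind_rows(lapply(unique(summary$detector), function(d) {
    s <- dplyr::filter(summary, .data$detector == d)
    ef <- fit_eta(s$wf_mean, s$tau_w_us_mean * 1e-6, config$detector$tau_full_s)
    tibble::tibble(detector = d, eta = ef$eta, se = ef$se)
  }))

  # Welch tests: each filter against none, per detector, per metric;
  # Bonferroni within each metric family
  non_ref <- setdiff(names(config$filters), "none")
  tests <- list()
  if ("none" %in% names(config$filters) && length(non_ref) > 0) {
    for (metric in c("wf", "tau_w_s", "loss_pct")) {
      rows <- list()
      for (d in unique(per_second$detector)) {
        ref_v <- per_second[[metric]][per_second$detector == d &
                                        per_second$filter == "none"]
        for (f in non_ref) {
          v <- per_second[[metric]][per_second$detector == d &
                                      per_second$filter == f]
          wt <- welch_t(v, ref_v)
          rows[[length(rows) + 1L]] <-
            dplyr::mutate(wt, detector = d, filter = f, metric = metric,
                          .before = 1)
        }
      }
      fam <- dplyr::bind_rows(rows)
      fam$m <- nrow(fam)
      fam$p_adjusted <- bonferroni(fam$p_value, nrow(fam))
      tests[[metric]] <- fam
    }
  }
  tests <- dplyr::bind_rows(tests)

  tc <- dplyr::bind_rows(lapply(unique(summary$detector), function(d) {
    s <- dplyr::filter(summary, .data$detector == d)
    res <- loss_curve(tibble::tibble(config = s$filter,
                                     rate_true_24 = s$true_primary_cps,
                                     tau_w_s = s$tau_w_us_mean * 1e-6),
                      config$retention, config$time_grid)
    dplyr::mutate(res, detector = d)
  }))
  class(tc) <- c("gc_timecourse", class(tc))

  structure(list(summary = summary, eta = eta_fits, tests = tests,
                 timecourse = tc, spectra = incidents,
                 per_second = per_second, config = config, seed = seed),
            class = "gc_experiment")
}

#' @export
print.gc_experiment <- function(x, ...) {
  cat(sprintf("<gc_experiment> seed %s, %g histories\n", x$seed,
              x$config$n_histories))
  print(dplyr::select(x$summary, "detector", "filter", "wf_mean",
                      "tau_w_us_mean", "true_primary_cps", "loss_pct_mean"))
  invisible(x)
}

#' Tidy / glance an experiment
#'
#' `tidy()` returns the per-configuration summary (one row per detector
#' and filter); `glance()` a one-row overview.
#'
#' @param x A `gc_experiment`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.gc_experiment <- function(x, ...) x$summary

#' @rdname tidy.gc_experiment
#' @export
glance.gc_experiment <- function(x, ...) {
  tibble::tibble(n_histories = x$config$n_histories,
                 n_configurations = nrow(x$summary),
                 seconds_recorded = sum(x$summary$duration_s),
                 m_per_family = if (nrow(x$tests)) x$tests$m[1] else NA_integer_,
                 seed = x$seed)
}
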