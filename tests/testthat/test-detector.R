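test_that("intrinsic efficiency follows the crystal interaction probability", {
  cfg0 <- detector_config(crystal_thickness_cm = 0)
  expect_equal(intrinsic_efficiency(208.4, cfg0), 0)
  # hand evaluation with the packaged NaI tables at the default 0.95 cm
  w_na <- 22.990 / (22.990 + 126.904)
  mu <- w_na * hand_interp("na", 208.4) + (1 - w_na) * hand_interp("i", 208.4)
  expect_equal(intrinsic_efficiency(208.4),
               1 - exp(-mu * 3.67 * 0.95), tolerance = 1e-6)
  # thick-crystal limit saturates towards 1
  thick <- detector_config(crystal_thickness_cm = 100)
  expect_gt(intrinsic_efficiency(60, thick), 0.999999)
  # lower energies interact more readily across the imaging range
  expect_gt(intrinsic_efficiency(113), intrinsic_efficiency(208.4))
})

test_that("energy blur has the configured resolution and scaling law", {
  cfg <- detector_config()
  draws <- blur_energy(rep(208.4, 1e6), cfg, seed = 21)
  expect_equal(stats::sd(draws), 0.094 * 208.4 / 2.3548, tolerance = 0.01)
  expect_equal(mean(draws), 208.4, tolerance = 1e-3)
  # zero-width configuration is exact
  none <- detector_config(resolution_fwhm = 0)
  expect_identical(blur_energy(c(100, 208.4), none), c(100, 208.4))
  # fractional FWHM scales as 1/sqrt(E): ~12.8% at 113 keV
  expect_equal(gcdeadtime:::fwhm_fraction(113, cfg), 0.128, tolerance = 0.005)
  # blur conserves the number of events and never returns negatives
  out <- blur_energy(rep(30, 1e4), cfg, seed = 22)
  expect_length(out, 1e4)
  expect_true(all(out > 0))
})

test_that("event streams are Poisson at the detected rate and reproducible", {
  spec <- tibble::tibble(bin_low_keV = 205, bin_high_keV = 212,
                         primary_rate = 1e5, scatter_rate = 0)
  class(spec) <- c("gc_spectrum", class(spec))
  cfg <- detector_config()
  lambda <- 1e5 * intrinsic_efficiency(208.5, cfg)
  st <- generate_event_stream(spec, cfg, duration_s = 10, seed = 23)
  expect_lt(abs(nrow(st) - lambda * 10), 3 * sqrt(lambda * 10))
  expect_true(!is.unsorted(st$time_s))
  expect_true(all(st$primary))
  expect_identical(st, generate_event_stream(spec, cfg, 10, seed = 23))
  # zero spectrum gives an empty stream
  zero <- dplyr::mutate(spec, primary_rate = 0)
  expect_equal(nrow(generate_event_stream(zero, cfg, 1, seed = 1)), 0)
})

test_that("paralyzable dead time removes the analytic fraction of arrivals", {
  lambda <- 1e5; tau <- 5e-7; dur <- 20
  set.seed(31)
  times <- cumsum(stats::rexp(2.2e6, lambda))
  times <- times[times < dur]
  stream <- tibble::tibble(time_s = times,
                           energy_keV = rep(208, length(times)),
                           primary = TRUE)
  rec <- apply_paralyzable(stream, tau)
  expected <- lambda * exp(-lambda * tau) * dur
  expect_lt(abs(nrow(rec) - expected), 3 * sqrt(expected))
  # tau = 0 keeps the stream unchanged
  expect_identical(apply_paralyzable(stream, 0), stream)
})

test_that("pile-up sums coincident energies into the triggering event", {
  stream <- tibble::tibble(time_s = c(0, 2e-7), energy_keV = c(100, 50),
                           primary = c(TRUE, FALSE))
  off <- apply_paralyzable(stream, 5e-7, pileup = FALSE)
  expect_equal(nrow(off), 1)
  expect_equal(off$energy_keV, 100)
  on <- apply_paralyzable(stream, 5e-7, pileup = TRUE, integration_s = 5e-7)
  expect_equal(nrow(on), 1)
  expect_equal(on$energy_keV, 150)
  expect_equal(on$time_s, 0)
})

test_that("recorded rate over a rate sweep recovers the configured dead time", {
  tau <- 5e-7
  sweep <- c(1e4, 5e4, 1e5, 2e5, 5e5)
  set.seed(41)
  obs <- vapply(sweep, function(lambda) {
    dur <- max(1, 2e5 / lambda)
    times <- cumsum(stats::rexp(lambda * dur * 1.1 + 5 * sqrt(lambda * dur),
                                lambda))
    times <- times[times < dur]
    st <- tibble::tibble(time_s = times, energy_keV = 208, primary = TRUE)
    nrow(apply_paralyzable(st, tau)) / dur
  }, numeric(1))
  fit <- fit_tau(tibble::tibble(rate_true = sweep, rate_obs = obs))
  expect_equal(fit$tau_s, tau, tolerance = 0.02)
})

test_that("measurements record whole seconds until 10 kcounts are observed", {
  cfg <- detector_config(pileup = FALSE)
  windows <- tew_windows(tew_config())
  # main-window observed rate around 5 kcps -> about 3 s
  rate <- 5000 / intrinsic_efficiency(208.5, cfg) / 0.92
  spec <- tibble::tibble(bin_low_keV = 205, bin_high_keV = 212,
                         primary_rate = rate, scatter_rate = 0)
  class(spec) <- c("gc_spectrum", class(spec))
  m <- record_measurement(spec, cfg, windows, seed = 51)
  expect_true(m$duration_s %in% 2:4)
  # a huge rate stops after the one-second minimum
  spec2 <- dplyr::mutate(spec, primary_rate = 1e6)
  class(spec2) <- c("gc_spectrum", class(spec2))
  m2 <- record_measurement(spec2, cfg, windows, seed = 52)
  expect_equal(m2$duration_s, 1)
  # observed counts never exceed true counts in any window
  expect_true(all(m$per_second$observed_counts <= m$per_second$true_counts))
  # unreachable stop rule errors out at the cap
  spec0 <- dplyr::mutate(spec, primary_rate = 1)
  class(spec0) <- c("gc_spectrum", class(spec0))
  expect_error(record_measurement(spec0, cfg, windows, seed = 53,
                                  max_seconds = 3),
               "stop rule")
})

test_that("a restricted window stretches the dead time by 1/wf when pile-up is off", {
  ex <- experiment_pileup_off()
  s <- ex$summary
  expect_equal(s$tau_w_us_mean * s$wf_mean, rep(0.5, nrow(s)),
               tolerance = 0.03)
})
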