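test_that("the paralyzable forward law reproduces published observed rates", {
  expect_equal(paralyzable_observed(1.1e3, 9.3e-6), 1.0888e3, tolerance = 1e-4)
  expect_equal(paralyzable_observed(5.6e3, 9.3e-6), 5.316e3, tolerance = 1e-4)
  expect_equal(paralyzable_observed(0, 9.3e-6), 0)
  # maximum of the response sits at R = 1/tau with value 1/(e tau)
  tau <- 9.3e-6
  grid <- seq(0.5, 2, by = 0.01) / tau
  vals <- paralyzable_observed(grid, tau)
  expect_equal(grid[which.max(vals)], 1 / tau, tolerance = 0.011)
  expect_equal(max(vals), 1 / (exp(1) * tau), tolerance = 1e-4)
})

test_that("inversion returns the physical branch and round-trips exactly", {
  tau <- 9.3e-6
  expect_equal(paralyzable_true(0, tau), 0)
  expect_equal(paralyzable_true(1 / (exp(1) * tau), tau), 1 / tau,
               tolerance = 1e-10)
  expect_equal(paralyzable_true(1.0888e3, tau), 1.1e3, tolerance = 1e-4)
  rates <- c(10, 1e3, 1e4, 5e4, 0.9 / (exp(1) * tau))
  back <- paralyzable_true(paralyzable_observed(rates, tau), tau)
  expect_equal(back, rates, tolerance = 1e-10)
  # sub-peak branch only
  expect_true(all(back * tau <= 1))
  expect_error(paralyzable_true(1.01 / (exp(1) * tau), tau), "no physical")
  # independent cross-check against the principal-branch product-log
  skip_if_not_installed("pracma")
  obs <- c(500, 5e3, 2e4)
  expect_equal(paralyzable_true(obs, tau),
               -pracma::lambertWp(-obs * tau) / tau, tolerance = 1e-10)
})

test_that("apparent dead time scales as tau over wf to the eta", {
  expect_equal(apparent_dead_time(0.5e-6, 1, 0.7), 0.5e-6)
  expect_equal(apparent_dead_time(0.5e-6, 0.12, 1.0), 4.1667e-6,
               tolerance = 1e-4)
  expect_equal(apparent_dead_time(0.5e-6, 0.12, 1.4), 9.73e-6,
               tolerance = 1e-3)
  # the published no-filter values 8.7-9.8 us bracket the eta = 1.4 value
  expect_true(apparent_dead_time(0.5e-6, 0.12, 1.4) > 8.7e-6 &&
                apparent_dead_time(0.5e-6, 0.12, 1.4) < 9.8e-6)
  # strictly decreasing in the window fraction
  wf <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(apparent_dead_time(0.5e-6, wf, 1.4)) < 0))
  expect_error(apparent_dead_time(0.5e-6, 0, 1.4), "\\(0, 1\\]")
})

test_that("dead-time loss is the percent deficit and grows with rate", {
  expect_equal(deadtime_loss(100, 100), 0)
  expect_equal(deadtime_loss(100, 95), 5)
  expect_equal(deadtime_loss(5.6e3, paralyzable_observed(5.6e3, 9.3e-6)),
               5.07, tolerance = 1e-3)
  tau <- 9.3e-6
  rates <- seq(1e3, 0.9 / tau, length.out = 20)
  loss <- deadtime_loss(rates, paralyzable_observed(rates, tau))
  expect_true(all(diff(loss) > 0))
  expect_error(deadtime_loss(0, 0), "positive")
  expect_error(deadtime_loss(100, 101), "exceed")
})

test_that("tau fitting recovers noiseless and Poisson-noised sweeps", {
  tau <- 9.3e-6
  rates <- seq(1e3, 2e4, length.out = 10)
  exact <- tibble::tibble(rate_true = rates,
                          rate_obs = paralyzable_observed(rates, tau))
  fit <- fit_tau(exact)
  expect_equal(fit$tau_s, tau, tolerance = 1e-12)
  td <- tidy(fit)
  expect_equal(td$estimate, fit$tau_s)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_true(all(c("r.squared", "nobs") %in% names(glance(fit))))
  # Poisson counting noise, about 1e5 counts per point
  set.seed(61)
  noisy <- dplyr::mutate(exact,
    rate_obs = stats::rpois(length(rates), rate_obs * (1e5 / rate_obs)) /
      (1e5 / rate_obs))
  expect_equal(fit_tau(noisy)$tau_s, tau, tolerance = 0.02)
  expect_error(fit_tau(exact[c(1, 1), ]), "distinct")
})

test_that("eta fitting recovers planted exponents and published values", {
  tau <- 0.5e-6
  wf <- c(0.1, 0.2, 0.4, 0.8)
  tw <- apparent_dead_time(tau, wf, 1.4)
  expect_equal(fit_eta(wf, tw, tau)$eta, 1.4, tolerance = 1e-12)
  # closed-form single-point solve
  single <- fit_eta(0.12, 8.7e-6, tau)
  expect_equal(single$eta, log(17.4) / log(1 / 0.12), tolerance = 1e-12)
  expect_equal(single$eta, 1.35, tolerance = 0.005)
  # published detector-1 window fractions and dead times give eta ~ 1.39
  ref <- dplyr::filter(lu177_reference_values(), detector == 1)
  expect_equal(fit_eta(ref$wf, ref$tau_w_us * 1e-6, tau)$eta, 1.39,
               tolerance = 0.005)
  expect_error(fit_eta(c(1, 0.5), c(1e-6, 2e-6), 0.5e-6), "inconsistent")
})
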