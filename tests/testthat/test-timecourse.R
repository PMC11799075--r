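test_that("retention curves are anchored and non-increasing", {
  cur <- retention_curve()
  expect_equal(retention(cur, 24), 0.52, tolerance = 1e-12)
  t <- seq(24, 120, by = 4)
  expect_true(all(diff(retention(cur, t)) < 0))
  tab <- retention_curve("table",
                         table = tibble::tibble(time_h = c(24, 72, 120),
                                                fraction = c(0.5, 0.3, 0.2)))
  expect_equal(retention(tab, 72), 0.3)
  expect_equal(retention(tab, 48), 0.4)  # linear interpolation
  expect_error(retention_curve("table",
                               table = tibble::tibble(time_h = c(24, 48),
                                                      fraction = c(0.2, 0.5))),
               "non-increasing")
})

test_that("true rates scale with retention from the 24-h anchor", {
  cur <- retention_curve()
  expect_equal(scale_true_rate(123, cur, 24), 123)
  # hand arithmetic: mono-exponential with 80-h effective half-life
  mono <- retention_curve("monoexp", half_life_h = 80, anchor = NULL)
  expect_equal(scale_true_rate(1e4, mono, 120), 1e4 * 2^(-96 / 80),
               tolerance = 1e-12)
  expect_equal(scale_true_rate(1e4, mono, 120), 4.353e3, tolerance = 1e-4)
  # a constant curve leaves the rate unchanged
  const <- retention_curve("table",
                           table = tibble::tibble(time_h = c(24, 120),
                                                  fraction = c(0.5, 0.5)))
  expect_equal(scale_true_rate(77, const, c(24, 60, 120)), rep(77, 3))
  expect_error(scale_true_rate(1, cur, 12), "t >= 24")
})

test_that("loss curves apply the paralyzable law pointwise and self-consistently", {
  configs <- tibble::tibble(config = c("none", "tfp", "lead"),
                            rate_true_24 = c(5.6e3, 5.6e3 / 1.075, 5.6e3 / 1.45),
                            tau_w_s = c(9.3e-6, 5.8e-6, 3.0e-6))
  res <- loss_curve(configs, retention_curve(), seq(24, 120, by = 8))
  expect_s3_class(res, "gc_timecourse")
  # self-consistency with the forward law and loss definition to 1e-10
  tau_of <- stats::setNames(configs$tau_w_s, configs$config)
  expect_equal(res$rate_obs,
               paralyzable_observed(res$rate_true, unname(tau_of[res$config])),
               tolerance = 1e-10)
  expect_equal(res$loss_pct, (res$rate_true - res$rate_obs) / res$rate_true * 100,
               tolerance = 1e-10)
  # ordered tau and rates give ordered losses at every time point
  by_t <- split(res, res$time_h)
  for (chunk in by_t) {
    expect_gt(chunk$loss_pct[chunk$config == "none"],
              chunk$loss_pct[chunk$config == "tfp"])
    expect_gt(chunk$loss_pct[chunk$config == "tfp"],
              chunk$loss_pct[chunk$config == "lead"])
  }
  # loss decreases with time as activity clears
  expect_true(all(tapply(res$loss_pct, res$config, function(x) all(diff(x) < 0))))
  # a constant retention keeps loss constant
  const <- retention_curve("table",
                           table = tibble::tibble(time_h = c(24, 120),
                                                  fraction = c(0.4, 0.4)))
  resc <- loss_curve(configs[1, ], const)
  expect_equal(diff(range(resc$loss_pct)), 0, tolerance = 1e-12)
  expect_error(loss_curve(configs, grid = c(12, 48)), "\\[24, 120\\]")
})

test_that("loss ratios reduce to the small-loss first-order expansion", {
  # identical configurations give a ratio of one
  same <- tibble::tibble(config = c("none", "copy"),
                         rate_true_24 = c(1e3, 1e3),
                         tau_w_s = c(9.3e-6, 9.3e-6))
  rs <- loss_ratio_summary(loss_curve(same, retention_curve()))
  expect_equal(rs$loss_ratio[rs$config == "copy"], 1, tolerance = 1e-12)
  # halving tau at the same rate halves the loss in the small-loss regime
  halved <- tibble::tibble(config = c("none", "half"),
                           rate_true_24 = c(1e3, 1e3),
                           tau_w_s = c(9.3e-6, 4.65e-6))
  rh <- loss_ratio_summary(loss_curve(halved, retention_curve()))
  expect_equal(rh$loss_ratio[rh$config == "half"], 0.5, tolerance = 0.01)
  expect_error(loss_ratio_summary(loss_curve(same, retention_curve()),
                                  reference = "missing"), "not present")
})
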