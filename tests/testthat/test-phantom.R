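test_that("the default phantom matches the documented patient conditions", {
  ph <- default_phantom()
  expect_equal(sum(ph$organs$percent_ia), 52)
  expect_equal(gcdeadtime:::phantom_activity(ph), 0.52 * 7.4e9)
  liver <- ph$organs[ph$organs$name == "liver", ]
  expect_gt(liver$cy, 0)  # anterior of the mid-coronal plane
  expect_gt(liver$percent_ia, max(ph$organs$percent_ia[-which(ph$organs$name == "liver")]))
  expect_error(phantom_config(organ_source("big", "box", c(0, 0, 0),
                                           c(99, 1, 1), 10)),
               "fit inside")
})

test_that("a point source in vacuum reproduces the solid-angle acceptance", {
  ph <- point_phantom(body_density = 0)
  sp <- simulate_incident(ph, detector_placement("anterior"), NULL,
                          n_histories = 5e3, seed = 2)
  emission <- 7.4e9 * 0.52 * 0.11
  expected <- emission * (1 - cos(3 * pi / 180)) / 2
  expect_equal(sum(sp$primary_rate), expected, tolerance = 1e-10)
  expect_equal(sum(sp$scatter_rate), 0)
  # adding a filter multiplies every bin by its transmission
  spf <- simulate_incident(ph, detector_placement("anterior"),
                           filter_lead_05(), n_histories = 5e3, seed = 2)
  expect_equal(sum(spf$primary_rate),
               expected * transmission(filter_lead_05(), 208.4),
               tolerance = 1e-10)
})

test_that("zero activity yields an all-zero spectrum", {
  ph <- phantom_config(organ_source("pt", "box", c(0, 0, 0),
                                    c(0.1, 0.1, 0.1), 0))
  sp <- simulate_incident(ph, detector_placement("anterior"),
                          n_histories = 100, seed = 1)
  expect_true(all(sp$primary_rate == 0) && all(sp$scatter_rate == 0))
})

test_that("a mid-plane source illuminates both detectors equally", {
  ph <- point_phantom(body_density = 1)
  pair <- spectrum_pair(ph, NULL, n_histories = 2e4, seed = 3)
  r1 <- total_rate(pair$detector1)
  r2 <- total_rate(pair$detector2)
  expect_equal(r1, r2, tolerance = 0.05)
})

test_that("the anterior detector sees more than the posterior one by design", {
  pair <- spectrum_pair(default_phantom(), NULL, n_histories = 5e3, seed = 4)
  expect_gt(total_rate(pair$detector1), total_rate(pair$detector2))
})

test_that("filters never increase any spectral bin under common histories", {
  ph <- default_phantom()
  pl <- detector_placement("anterior")
  none <- simulate_incident(ph, pl, NULL, n_histories = 3e3, seed = 5)
  lead <- simulate_incident(ph, pl, filter_lead_05(), n_histories = 3e3,
                            seed = 5)
  tot_n <- none$primary_rate + none$scatter_rate
  tot_l <- lead$primary_rate + lead$scatter_rate
  expect_true(all(tot_l <= tot_n + 1e-12))
})

test_that("scatter vanishes without scattering orders and shrinks with filtering", {
  ph <- point_phantom(body_density = 1)
  sp0 <- simulate_incident(ph, detector_placement("anterior"), NULL,
                           n_histories = 3e3, max_scatters = 0, seed = 6)
  expect_equal(sum(sp0$scatter_rate), 0)
  sp2 <- simulate_incident(ph, detector_placement("anterior"), NULL,
                           n_histories = 3e3, max_scatters = 2, seed = 6)
  expect_gt(sum(sp2$scatter_rate), 0)
  # scattered photons arrive below the emission line
  expect_true(all(sp2$bin_low_keV[sp2$scatter_rate > 0] < 208.4))
})

test_that("Monte Carlo error scales roughly as one over root histories", {
  ph <- default_phantom()
  pl <- detector_placement("anterior")
  rates <- function(n, seeds) vapply(seeds, function(s)
    total_rate(simulate_incident(ph, pl, NULL, n_histories = n, seed = s)),
    numeric(1))
  sd_small <- stats::sd(rates(500, 1:10))
  sd_large <- stats::sd(rates(2000, 1:10))
  expect_lt(sd_large, sd_small)
  expect_equal(sd_small / sd_large, 2, tolerance = 0.5)
})

test_that("spectra round-trip through the CSV dialect", {
  ph <- point_phantom()
  sp <- simulate_incident(ph, detector_placement("anterior"),
                          n_histories = 500, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(sp, path)
  back <- read_spectrum_csv(path)
  expect_equal(back$primary_rate, sp$primary_rate)
  expect_equal(back$bin_low_keV, sp$bin_low_keV)
})
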