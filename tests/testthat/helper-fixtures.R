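# shared fixtures; expensive objects are built once and cached

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  .fixture_cache[[name]]
}

# default experiment, modest history count, pile-up on (headline setting)
experiment_pileup_on <- function() {
  cached_fixture("exp_on",
    run_experiment(experiment_config(n_histories = 8e3, min_seconds = 4),
                   seed = 11))
}

# same but pile-up disabled, for the eta ~ 1 regime
experiment_pileup_off <- function() {
  cached_fixture("exp_off",
    run_experiment(experiment_config(
      n_histories = 6e3, min_seconds = 3,
      detector = detector_config(pileup = FALSE)), seed = 12))
}

# independent hand log-log interpolation of a packaged element table
hand_interp <- function(symbol, energy) {
  path <- system.file("extdata", "attenuation", paste0(symbol, ".tsv"),
                      package = "gcdeadtime")
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("e", "mu"))
  i <- findInterval(energy, tab$e)
  if (tab$e[i] == energy) return(tab$mu[i])
  f <- (log(energy) - log(tab$e[i])) / (log(tab$e[i + 1]) - log(tab$e[i]))
  exp((1 - f) * log(tab$mu[i]) + f * log(tab$mu[i + 1]))
}

# a point-like source of a pure 208.4-keV emitter
point_phantom <- function(body_density = 0, percent_ia = 52) {
  phantom_config(
    organ_source("point", "box", c(0, 0, 0), c(0.1, 0.1, 0.1), percent_ia),
    body_density_g_cm3 = body_density,
    spectrum = tibble::tibble(energy_keV = 208.4, intensity = 0.11,
                              type = "gamma"))
}
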