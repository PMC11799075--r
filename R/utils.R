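# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_if <- function(cond, msg) {
  if (isTRUE(cond)) rlang::abort(msg)
  invisible(NULL)
}

# run expr under a local RNG state when seed is given, untouched otherwise
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# log-log interpolation of a (energy, value) table; errors outside the span
loglog_interp <- function(energy_keV, value, xout) {
  rng <- range(energy_keV)
  abort_if(any(xout < rng[1] | xout > rng[2]),
           sprintf("energy outside tabulated span [%g, %g] keV", rng[1], rng[2]))
  exp(stats::approx(log(energy_keV), log(value), xout = log(xout),
                    ties = "ordered")$y)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
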