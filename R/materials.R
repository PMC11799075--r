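# Materials and photon attenuation.
#
# Per-element mass attenuation coefficients are packaged as two-column text
# tables (inst/extdata/attenuation) on a 20-500 keV grid, with duplicated
# grid points straddling the K edges of I, W and Pb so that interpolation
# never crosses an edge.  Tables are interpolated log-log, the standard
# treatment for photon cross sections in this energy range.

.attenuation_cache <- new.env(parent = emptyenv())

element_info <- function() {
  tibble::tibble(
    symbol = c("H", "C", "O", "Na", "Al", "I", "W", "Pb"),
    z      = c(1, 6, 8, 11, 13, 53, 74, 82),
    mass   = c(1.008, 12.011, 15.999, 22.990, 26.982, 126.904, 183.84, 207.2)
  )
}

#' Read a two-column attenuation table
#'
#' @param path Text file with columns `energy_keV`, `mu_rho_cm2_g`;
#'   `#` starts a comment.
#' @return Tibble with columns `energy_keV`, `mu_rho_cm2_g`.
#' @export
read_attenuation_table <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("energy_keV", "mu_rho_cm2_g"))
  abort_if(is.unsorted(tab$energy_keV, strictly = TRUE),
           "table energies must be strictly increasing")
  abort_if(any(tab$mu_rho_cm2_g <= 0), "attenuation coefficients must be > 0")
  tibble::as_tibble(tab)
}

#' Packaged mass-attenuation table for an element
#'
#' @param symbol Element symbol; one of H, C, O, Na, Al, I, W, Pb.
#' @return Tibble with columns `energy_keV`, `mu_rho_cm2_g` spanning
#'   20-500 keV.
#' @export
element_attenuation <- function(symbol) {
  key <- tolower(symbol)
  cached <- .attenuation_cache[[key]]
  if (!is.null(cached)) return(cached)
  path <- system.file("extdata", "attenuation", paste0(key, ".tsv"),
                      package = "gcdeadtime")
  abort_if(!nzchar(path), sprintf("no packaged attenuation table for '%s'", symbol))
  tab <- read_attenuation_table(path)
  assign(key, tab, envir = .attenuation_cache)
  tab
}

#' Define a material
#'
#' A material is a named mixture of elements with mole fractions and a bulk
#' density.  Mole fractions must sum to 1 (within 1e-9).
#'
#' @param name Material name.
#' @param composition Named numeric vector of mole fractions, e.g.
#'   `c(H = 2/3, O = 1/3)` for water.
#' @param density_g_cm3 Bulk density in g/cm^3.
#' @return A `gc_material` object.
#' @examples
#' material("water", c(H = 2/3, O = 1/3), 1.0)
#' @export
material <- function(name, composition, density_g_cm3) {
  abort_if(is.null(names(composition)) || any(!nzchar(names(composition))),
           "composition must be a named vector of mole fractions")
  abort_if(abs(sum(composition) - 1) > 1e-9, "mole fractions must sum to 1")
  abort_if(any(composition < 0), "mole fractions must be non-negative")
  abort_if(!is_scalar_number(density_g_cm3) || density_g_cm3 <= 0,
           "density must be a positive number")
  info <- element_info()
  unknown <- setdiff(names(composition), info$symbol)
  abort_if(length(unknown) > 0,
           paste0("no attenuation data for element(s): ",
                  paste(unknown, collapse = ", ")))
  comp <- tibble::tibble(symbol = names(composition),
                         mole_fraction = as.numeric(composition))
  comp <- dplyr::left_join(comp, info, by = "symbol")
  structure(list(name = name, composition = comp,
                 density_g_cm3 = density_g_cm3),
            class = "gc_material")
}

#' @export
print.gc_material <- function(x, ...) {
  cat(sprintf("<material> %s  (%.3g g/cm3)\n", x$name, x$density_g_cm3))
  print(x$composition[, c("symbol", "mole_fraction")])
  invisible(x)
}

#' Stock materials
#'
#' Convenience constructors for the materials used by the default pipeline:
#' lead (density 11.35), tungsten functional paper (H 24.2 / C 40.4 /
#' O 20.2 / W 15.2 mol%, about 77% tungsten by weight), water, and NaI.
#' The density of tungsten functional paper is not a settled literature
#' value; the packaged default of 3.4 g/cm^3 can be overridden.
#'
#' @param density_g_cm3 Override for the TFP bulk density.
#' @return A `gc_material`.
#' @export
material_lead <- function() material("lead", c(Pb = 1), 11.35)

#' @rdname material_lead
#' @export
material_tfp <- function(density_g_cm3 = 3.4) {
  material("tungsten functional paper",
           c(H = 0.242, C = 0.404, O = 0.202, W = 0.152), density_g_cm3)
}

#' @rdname material_lead
#' @export
material_water <- function() material("water", c(H = 2 / 3, O = 1 / 3), 1.0)

#' @rdname material_lead
#' @export
material_nai <- function() material("NaI", c(Na = 0.5, I = 0.5), 3.67)

#' Per-element mass fractions of a material
#'
#' `w_i = x_i M_i / sum_j x_j M_j` from mole fractions `x` and atomic
#' masses `M`.
#'
#' @param mat A `gc_material`.
#' @return Tibble with columns `symbol`, `mass_fraction` (summing to 1).
#' @examples
#' weight_fractions(material_tfp())  # tungsten carries ~0.77 of the mass
#' @export
weight_fractions <- function(mat) {
  abort_if(!inherits(mat, "gc_material"), "expected a gc_material")
  comp <- mat$composition
  w <- comp$mole_fraction * comp$mass
  tibble::tibble(symbol = comp$symbol, mass_fraction = w / sum(w))
}

#' Mass attenuation coefficient of a material
#'
#' Mixture rule: the mass-fraction weighted sum of the per-element
#' coefficients, each interpolated log-log on its packaged table.
#'
#' @param mat A `gc_material`.
#' @param energy_keV Photon energies in keV (vectorised); must lie within
#'   the 20-500 keV tabulated span.
#' @return Coefficients in cm^2/g.
#' @export
mass_attenuation <- function(mat, energy_keV) {
  wf <- weight_fractions(mat)
  out <- numeric(length(energy_keV))
  for (i in seq_len(nrow(wf))) {
    tab <- element_attenuation(wf$symbol[i])
    out <- out + wf$mass_fraction[i] *
      loglog_interp(tab$energy_keV, tab$mu_rho_cm2_g, energy_keV)
  }
  out
}

#' Shielding filter specification
#'
#' A slab of material of given thickness placed over the collimator face.
#' `filter_lead_05()` and `filter_tfp_12()` build the two stock filters
#' (0.5-mm lead sheet, 1.2-mm tungsten functional paper); `NULL` stands
#' for "no filter" throughout the package.
#'
#' @param mat A `gc_material`.
#' @param thickness_cm Slab thickness in cm (>= 0).
#' @return A `gc_filter` object.
#' @export
filter_spec <- function(mat, thickness_cm) {
  abort_if(!inherits(mat, "gc_material"), "expected a gc_material")
  abort_if(!is_scalar_number(thickness_cm) || thickness_cm < 0,
           "thickness must be >= 0")
  structure(list(material = mat, thickness_cm = thickness_cm),
            class = "gc_filter")
}

#' @rdname filter_spec
#' @export
filter_lead_05 <- function() filter_spec(material_lead(), 0.05)

#' @rdname filter_spec
#' @param density_g_cm3 TFP bulk density override.
#' @export
filter_tfp_12 <- function(density_g_cm3 = 3.4) {
  filter_spec(material_tfp(density_g_cm3), 0.12)
}

#' @export
print.gc_filter <- function(x, ...) {
  cat(sprintf("<filter> %.3g mm %s\n", x$thickness_cm * 10, x$material$name))
  invisible(x)
}

#' Filter transmission
#'
#' Narrow-beam transmission `exp(-(mu/rho)(E) * rho * d)` of a filter slab.
#' A `NULL` filter transmits everything.
#'
#' @param filt A `gc_filter`, or `NULL` for no filter.
#' @param energy_keV Photon energies in keV (vectorised).
#' @return Transmitted fraction in (0, 1].
#' @examples
#' transmission(filter_lead_05(), c(208.4, 113))
#' @export
transmission <- function(filt, energy_keV) {
  if (is.null(filt)) return(rep(1, length(energy_keV)))
  abort_if(!inherits(filt, "gc_filter"), "expected a gc_filter or NULL")
  mu <- mass_attenuation(filt$material, energy_keV)
  exp(-mu * filt$material$density_g_cm3 * filt$thickness_cm)
}
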