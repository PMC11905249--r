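# Bundled photon interaction data and the operations built directly on it:
# material mixing (Bragg additivity), HVL <-> effective energy, and the
# elemental registry used everywhere else.
#
# Tables live in inst/extdata/attenuation/ as TSV (energy_keV, mu_total,
# mu_en, mu_pe, mu_incoh, mu_coh; all cm^2/g). Energies are strictly
# increasing except at K absorption edges, where a duplicated energy row
# carries the below-edge and above-edge values.

ALUMINUM_DENSITY <- 2.699   # g/cm^3
ELECTRON_REST_KEV <- 511.0

# elements known to the bundled data: symbol -> (Z, A)
.element_registry <- list(
  H = c(1, 1.008),  C = c(6, 12.011),  N = c(7, 14.007),  O = c(8, 15.999),
  F = c(9, 18.998), Na = c(11, 22.990), Mg = c(12, 24.305),
  Al = c(13, 26.982), P = c(15, 30.974), S = c(16, 32.06),
  Cl = c(17, 35.45), Ar = c(18, 39.948), K = c(19, 39.098),
  Ca = c(20, 40.078), Ti = c(22, 47.867), I = c(53, 126.904)
)

# K-fluorescence data for elements the engine treats as fluorescers (Z >= 20)
.fluorescence_registry <- data.frame(
  element = c("Ca", "Ti", "I"),
  Z = c(20, 22, 53),
  k_edge_keV = c(4.0381, 4.9664, 33.1694),
  fluorescence_yield = c(0.163, 0.219, 0.884),
  kalpha_keV = c(3.691, 4.509, 28.612)
)

att_data_dir <- function() {
  system.file("extdata", "attenuation", package = "kvcert", mustWork = TRUE)
}

load_att_table <- function(name) {
  key <- paste0("att_", name)
  if (!is.null(.kv[[key]])) return(.kv[[key]])
  path <- file.path(att_data_dir(), paste0(name, ".tsv"))
  if (!file.exists(path)) {
    abort(sprintf("no bundled attenuation table for '%s'", name),
          class = "kvcert_composition_error")
  }
  tab <- read.delim(path, check.names = FALSE)
  manifest <- read.delim(file.path(att_data_dir(), "MANIFEST.tsv"))
  n_expect <- manifest$rows[manifest$table == name]
  if (length(n_expect) != 1L || nrow(tab) != n_expect) {
    abort(sprintf("attenuation table '%s' fails its manifest check", name))
  }
  .kv[[key]] <- tab
  tab
}

#' Bundled photon interaction table
#'
#' Returns the bundled mass attenuation / energy-absorption table for an
#' element symbol (e.g. `"Al"`, `"I"`) or a bundled compound
#' (`"water"`, `"air"`, `"pmma"`, `"teflon"`, `"soft_tissue"`, `"lung"`,
#' `"cortical_bone"`). Energies are in keV, coefficients in cm^2/g; total
#' attenuation includes coherent scattering. K absorption edges appear as
#' duplicated energy rows (below-edge first).
#'
#' @param name element symbol or compound name
#' @return a tibble with columns `energy_keV`, `mu_total`, `mu_en`,
#'   `mu_pe`, `mu_incoh`, `mu_coh`
#' @export
attenuation_table <- function(name) {
  as_tibble(load_att_table(name))
}

# log-log interpolation on a bundled table; duplicated edge energies are
# split by a relative epsilon so queries on either side pick the right
# branch. Exact edge queries take `side` ("above" by default).
att_interp <- function(table, energy, column = "mu_total", side = "above") {
  x <- table$energy_keV
  if (any(energy < min(x) | energy > max(x))) {
    abort(sprintf("energy out of table range [%g, %g] keV", min(x), max(x)),
          class = "kvcert_range_error")
  }
  dup <- duplicated(x)
  lx <- log(x)
  lx[dup] <- lx[dup] + 1e-9
  e <- energy
  if (any(dup)) {
    edges <- x[dup]
    hit <- e %in% edges
    if (any(hit)) {
      e[hit] <- e[hit] * if (side == "above") (1 + 1e-8) else (1 - 1e-8)
    }
  }
  exp(approx(lx, log(pmax(table[[column]], 1e-300)), xout = log(e),
             rule = 2)$y)
}

#' Define a material by elemental mass fractions
#'
#' @param name material name
#' @param elements named numeric vector of elemental mass fractions
#'   (symbols must be in the bundled elemental data); must sum to 1
#' @param density mass density in g/cm^3
#' @return a `material_composition` object
#' @export
material_composition <- function(name, elements, density) {
  if (is.null(names(elements)) || any(!nzchar(names(elements)))) {
    abort("`elements` must be a named vector of mass fractions",
          class = "kvcert_composition_error")
  }
  unknown <- setdiff(names(elements), names(.element_registry))
  if (length(unknown)) {
    abort(paste0("unknown element(s): ", paste(unknown, collapse = ", ")),
          class = "kvcert_composition_error")
  }
  if (abs(sum(elements) - 1) > 1e-6) {
    abort("mass fractions must sum to 1 (within 1e-6)",
          class = "kvcert_composition_error")
  }
  if (!is.numeric(density) || density <= 0) {
    abort("density must be positive", class = "kvcert_composition_error")
  }
  structure(list(name = name, elements = elements, density = density),
            class = "material_composition")
}

#' @export
print.material_composition <- function(x, ...) {
  cat(sprintf("<material: %s, rho = %.4g g/cm^3>\n", x$name, x$density))
  print(round(x$elements, 5))
  invisible(x)
}

# registry of bundled reference materials with reference densities
.standard_materials <- list(
  air = list(density = 0.0012048,
             elements = c(C = 0.000124, N = 0.755268, O = 0.231781,
                          Ar = 0.012827)),
  water = list(density = 1.0,
               elements = c(H = 0.111894, O = 0.888106)),
  pmma = list(density = 1.19,
              elements = c(H = 0.080538, C = 0.599848, O = 0.319614)),
  teflon = list(density = 2.2,
                elements = c(C = 0.240183, F = 0.759817)),
  aluminum = list(density = 2.699, elements = c(Al = 1)),
  titanium = list(density = 4.506, elements = c(Ti = 1)),
  iodine = list(density = 4.93, elements = c(I = 1)),
  soft_tissue = list(density = 1.06,
                     elements = c(H = 0.102, C = 0.143, N = 0.034, O = 0.708,
                                  Na = 0.002, P = 0.003, S = 0.003,
                                  Cl = 0.002, K = 0.003)),
  lung = list(density = 0.26,
              elements = c(H = 0.103, C = 0.105, N = 0.031, O = 0.749,
                           Na = 0.002, P = 0.002, S = 0.003, Cl = 0.003,
                           K = 0.002)),
  cortical_bone = list(density = 1.92,
                       elements = c(H = 0.034, C = 0.155, N = 0.042,
                                    O = 0.435, Na = 0.001, Mg = 0.002,
                                    P = 0.103, S = 0.003, Ca = 0.225))
)

#' Reference material by name
#'
#' @param name one of `r paste0('"', names(kvcert:::.standard_materials), '"', collapse = ", ")`
#' @param density optional density override (g/cm^3)
#' @return a [material_composition()] object
#' @export
standard_material <- function(name, density = NULL) {
  m <- .standard_materials[[name]]
  if (is.null(m)) {
    abort(sprintf("unknown standard material '%s'", name),
          class = "kvcert_composition_error")
  }
  material_composition(name, m$elements,
                       if (is.null(density)) m$density else density)
}

as_material <- function(x) {
  if (inherits(x, "material_composition")) return(x)
  if (is.character(x) && length(x) == 1) return(standard_material(x))
  abort("expected a material_composition or a standard material name",
        class = "kvcert_composition_error")
}

#' Mass attenuation coefficient of a mixture
#'
#' Bragg-additivity sum of elemental coefficients,
#' \eqn{\sum_i w_i (\mu/\rho)_i(E)}, with log-log interpolation per element.
#'
#' @param composition a [material_composition()] or standard material name
#' @param energy photon energy (keV), vectorised; must lie in `[1, 150]`
#' @param kind which coefficient: total attenuation (with coherent), mass
#'   energy-absorption, or a single interaction channel
#' @param side branch to take when `energy` falls exactly on an absorption
#'   edge
#' @return coefficient(s) in cm^2/g
#' @export
mixture_mu <- function(composition, energy,
                       kind = c("total", "mu_en", "photoelectric",
                                "incoherent", "coherent"),
                       side = c("above", "below")) {
  kind <- match.arg(kind)
  side <- match.arg(side)
  comp <- as_material(composition)
  col <- switch(kind, total = "mu_total", mu_en = "mu_en",
                photoelectric = "mu_pe", incoherent = "mu_incoh",
                coherent = "mu_coh")
  if (any(!is.finite(energy)) || any(energy < 1) || any(energy > 150)) {
    abort("energy must lie within the table range [1, 150] keV",
          class = "kvcert_range_error")
  }
  out <- 0
  for (sym in names(comp$elements)) {
    out <- out + comp$elements[[sym]] *
      att_interp(load_att_table(sym), energy, col, side)
  }
  unname(out)
}

#' Effective energy from an aluminum half-value layer
#'
#' Inverts the bundled aluminum total mass attenuation table (coherent
#' scattering included, the narrow-beam convention) to find the
#' monoenergetic energy with the same attenuation:
#' \eqn{\mu/\rho(\mathrm{Al}, E) = \ln 2 / (\mathrm{HVL} \cdot \rho_{Al})}.
#'
#' @param hvl_mm half-value layer in mm of aluminum
#' @return a tibble with `hvl_mm`, the interpolated `energy_keV`, and
#'   `energy_keV_nearest` rounded to the nearest keV
#' @export
effective_energy_from_hvl <- function(hvl_mm) {
  if (any(!is.finite(hvl_mm)) || any(hvl_mm <= 0)) {
    abort("hvl_mm must be positive", class = "kvcert_range_error")
  }
  mu <- log(2) / (hvl_mm / 10 * ALUMINUM_DENSITY)
  tab <- load_att_table("Al")
  # monotone branch above the K edge (energies above 2 keV)
  keep <- tab$energy_keV >= 2
  x <- log(tab$energy_keV[keep])
  y <- log(tab$mu_total[keep])
  if (any(log(mu) > max(y) | log(mu) < min(y))) {
    abort("HVL implies an attenuation outside the monotone table branch",
          class = "kvcert_inversion_error")
  }
  o <- order(y)
  energy <- exp(approx(y[o], x[o], xout = log(mu))$y)
  tibble(hvl_mm = hvl_mm, energy_keV = energy,
         energy_keV_nearest = round(energy))
}

#' Aluminum HVL of a monoenergetic beam
#'
#' Closed-form inverse of [effective_energy_from_hvl()]:
#' \eqn{\mathrm{HVL} = \ln 2 / (\mu/\rho(\mathrm{Al}, E)\,\rho_{Al})}.
#'
#' @param energy_keV photon energy in keV
#' @return HVL in mm of aluminum
#' @export
hvl_from_energy <- function(energy_keV) {
  mu <- mixture_mu("aluminum", energy_keV, "total")
  log(2) / (mu * ALUMINUM_DENSITY) * 10
}

#' K-fluorescence data bundled with the package
#'
#' @return a tibble of K-edge energy, fluorescence yield and K-alpha line
#'   energy for the elements the transport engine treats as fluorescers
#' @export
fluorescence_data <- function() {
  as_tibble(.fluorescence_registry)
}
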