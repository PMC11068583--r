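# Molar masses (g mol-1) and element content per mole of gas.
.gas_constants <- tibble::tibble(
  gas          = c("CO2", "CH4", "N2O"),
  element      = c("C", "C", "N"),
  molar_mass   = c(44, 16, 44),
  # grams of the reported element per mole of gas (N2O carries two N)
  element_g_mol = c(12, 12, 28))

.mass_to_kg <- c(ng = 1e-12, ug = 1e-9, mg = 1e-6, g = 1e-3, kg = 1,
                 Mg = 1e3, t = 1e3)
.mol_to_mol <- c(nmol = 1e-9, umol = 1e-6, mmol = 1e-3, mol = 1)
# hectares per area unit and years per time unit (365-day year, 8760 h)
.area_to_ha <- c(`m-2` = 1e4, `ha-1` = 1)
.time_to_yr <- c(`s-1` = 365 * 86400, `h-1` = 8760, `d-1` = 365, `yr-1` = 1)

.unit_rx <- paste0(
  "^(ng|ug|mg|g|kg|Mg|t|nmol|umol|mmol|mol)\\s+",
  "(CO2|CH4|N2O|C|N)",
  "(?:[ -](C|N|eq))?\\s+",
  "(m-2|ha-1)\\s+",
  "(s-1|h-1|d-1|yr-1)$")

#' Canonical unit string for a gas
#'
#' Fluxes are harmonized to kg of element per hectare per year: carbon for
#' CO2 and CH4, nitrogen for N2O.
#'
#' @param gas `"CO2"`, `"CH4"` or `"N2O"`.
#' @return The canonical unit string, e.g. `"kg C ha-1 yr-1"`.
#' @export
canonical_unit <- function(gas) {
  el <- .gas_constants$element[match(gas, .gas_constants$gas)]
  paste0("kg ", el, " ha-1 yr-1")
}

#' Parse a flux-unit string
#'
#' Recognizes the unit dialects used across chamber and eddy-covariance
#' studies of peatland gas exchange: mass of the element
#' (`"mg CO2-C m-2 h-1"`), mass of the gas molecule (`"g CO2 m-2 yr-1"`),
#' CO2-equivalent mass (`"t CO2-eq ha-1 yr-1"`), and molar amount
#' (`"umol N2O m-2 h-1"`).  Typographic micro signs, Unicode minus/dash
#' characters and a space in place of the element hyphen
#' (`"g CO2 C m-2 yr-1"`) are tolerated.  A molar unit carrying an element
#' suffix (`"nmol N2O-N m-2 s-1"`) is read as moles of the gas molecule.
#'
#' @param text Character vector of unit strings.
#' @param gas Gas the unit applies to (`"CO2"`, `"CH4"`, `"N2O"`); required
#'   for element-only strings such as `"kg C ha-1 yr-1"`, and checked for
#'   consistency when the string itself names the gas.  Recycled.
#' @return A tibble with columns `text`, `gas`, `basis` (`"element"`,
#'   `"molecule"`, `"co2_equivalent"`, `"mol"`), `prefix`, `area`, `time`,
#'   and `factor` — the multiplier taking a value in this unit to the
#'   canonical scale (kg element, or kg CO2-eq, per ha per yr).
#' @examples
#' parse_flux_unit("mg CO2-C m-2 h-1", "CO2")$factor  # 87.6
#' @export
parse_flux_unit <- function(text, gas) {
  stopifnot(length(text) >= 1)
  gas <- rep_len(gas, length(text))
  one <- function(txt, g) {
    force_scalar_parse(txt, g)
  }
  # each distinct (string, gas) pair is parsed once
  key <- paste(text, gas, sep = "\r")
  first <- !duplicated(key)
  uniq <- purrr::list_rbind(purrr::map2(text[first], gas[first], one))
  uniq[match(key, key[first]), ]
}

force_scalar_parse <- local({
  function(txt, g) {
    if (is.na(txt)) abort("missing unit string")
    s <- normalize_typography(txt)
    # "g CO2 C m-2 yr-1" -> "g CO2-C m-2 yr-1"
    s <- stringr::str_replace(s, "(CO2|CH4|N2O) (C|N|eq)\\b", "\\1-\\2")
    m <- stringr::str_match(s, .unit_rx)
    if (is.na(m[1, 1])) {
      abort(paste0("unrecognized flux unit: \"", txt, "\""))
    }
    prefix <- m[1, 2]; species <- m[1, 3]; suffix <- m[1, 4]
    area <- m[1, 5]; time <- m[1, 6]
    molar <- prefix %in% names(.mol_to_mol)
    if (species %in% c("C", "N")) {
      if (is.na(g)) abort(paste0("gas required for unit \"", txt, "\""))
      gi <- match(g, .gas_constants$gas)
      if (is.na(gi)) abort(paste0("unknown gas: ", g))
      if (.gas_constants$element[gi] != species) {
        abort(paste0("unit \"", txt, "\" reports element ", species,
                     " but gas ", g, " carries ",
                     .gas_constants$element[gi]))
      }
      if (molar) abort(paste0("molar prefix with bare element: \"", txt, "\""))
      basis <- "element"
    } else if (!is.na(suffix) && suffix == "eq") {
      # a CO2-equivalent mass may be attached to any gas column
      if (species != "CO2") {
        abort(paste0("-eq only valid for CO2: \"", txt, "\""))
      }
      if (molar) abort(paste0("molar prefix with -eq: \"", txt, "\""))
      if (is.na(g)) g <- "CO2"
      gi <- match(g, .gas_constants$gas)
      basis <- "co2_equivalent"
    } else {
      if (!is.na(g) && g != species) {
        abort(paste0("unit \"", txt, "\" names gas ", species,
                     " but was attached to a ", g, " value"))
      }
      g <- species
      gi <- match(g, .gas_constants$gas)
      if (molar) {
        basis <- "mol"
      } else if (!is.na(suffix)) {
        if (.gas_constants$element[gi] != suffix) {
          abort(paste0("element suffix ", suffix, " does not match gas ", g,
                       " in \"", txt, "\""))
        }
        basis <- "element"
      } else {
        basis <- "molecule"
      }
    }
    scale <- switch(basis,
      element        = .mass_to_kg[[prefix]],
      molecule       = .mass_to_kg[[prefix]] *
                         .gas_constants$element_g_mol[gi] /
                         .gas_constants$molar_mass[gi],
      co2_equivalent = .mass_to_kg[[prefix]],
      mol            = .mol_to_mol[[prefix]] *
                         .gas_constants$element_g_mol[gi] / 1000)
    tibble::tibble(
      text = txt, gas = g, basis = basis, prefix = prefix,
      area = area, time = time,
      factor = scale * .area_to_ha[[area]] * .time_to_yr[[time]])
  }
})

#' Convert a flux value to the canonical scale
#'
#' Multiplies values by the unit's conversion factor to obtain kg element
#' per hectare per year (kg C for CO2 and CH4, kg N for N2O).  Values whose
#' unit is a CO2-equivalent mass are rescaled in mass/area/time only and
#' flagged, since the greenhouse-gas weighting cannot be undone without
#' knowing the factors used upstream.
#'
#' @param value Numeric vector of flux values (negative = uptake).
#' @param unit Unit string(s) or a parsed tibble from [parse_flux_unit()].
#' @param gas Gas vector, recycled; see [parse_flux_unit()].
#' @return A tibble with columns `gas`, `value` (canonical),
#'   `was_co2_equivalent`.
#' @examples
#' convert_flux(1, "mg CO2-C m-2 h-1", "CO2")    # 87.6 kg C ha-1 yr-1
#' convert_flux(1, "t CO2 ha-1 yr-1", "CO2")     # 272.73 kg CO2-C ha-1 yr-1
#' @export
convert_flux <- function(value, unit, gas = NA_character_) {
  if (!all(is.finite(value) | is.na(value))) {
    abort("non-finite flux value")
  }
  parsed <- if (is.data.frame(unit)) unit else parse_flux_unit(unit, gas)
  n <- max(length(value), nrow(parsed))
  value <- rep_len(value, n)
  idx <- rep_len(seq_len(nrow(parsed)), n)
  tibble::tibble(
    gas = parsed$gas[idx],
    value = value * parsed$factor[idx],
    was_co2_equivalent = parsed$basis[idx] == "co2_equivalent")
}

#' Express a canonical flux in another unit
#'
#' Exact inverse of [convert_flux()] for mass and molar units; used by the
#' synthetic-table generator to re-express known canonical values in mixed
#' unit dialects.
#'
#' @param value Numeric vector on the canonical scale.
#' @inheritParams convert_flux
#' @return Numeric vector in the target unit.
#' @export
flux_from_canonical <- function(value, unit, gas = NA_character_) {
  parsed <- if (is.data.frame(unit)) unit else parse_flux_unit(unit, gas)
  idx <- rep_len(seq_len(nrow(parsed)), max(length(value), nrow(parsed)))
  rep_len(value, length(idx)) / parsed$factor[idx]
}

#' Catalog of the unit dialects in the packaged compilation
#'
#' Every distinct measurement-unit string attached to the packaged flux
#' table, with its parsed decomposition and conversion factor to the
#' canonical scale.  The same table ships as delimited text in
#' `inst/extdata/unit_conversions.csv`.
#'
#' @return A tibble, one row per distinct (unit string, gas) pair.
#' @export
flux_unit_catalog <- function() {
  tbl <- read_flux_table()
  long <- tidyr::pivot_longer(
    tbl[, c("nee_unit", "ch4_unit", "n2o_unit")],
    dplyr::everything(), names_to = "col", values_to = "text")
  long$gas <- c(nee_unit = "CO2", ch4_unit = "CH4", n2o_unit = "N2O")[long$col]
  long <- dplyr::distinct(dplyr::filter(long, !is.na(.data$text)),
                          .data$gas, .data$text)
  out <- parse_flux_unit(long$text, long$gas)
  dplyr::arrange(out, .data$gas, .data$text)
}
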