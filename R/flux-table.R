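#' Recognized rewetted-peatland categories
#'
#' The flux compilation groups sites into five restoration categories:
#' general rewetted peatlands (no finer classification in the source),
#' rewetted peatland forests, paludiculture, shallow lakes on flooded
#' extraction areas, and open bogs/fens.
#'
#' @return Character vector of the five category labels.
#' @export
flux_categories <- function() {
  c("rewetted_general", "rewetted_forest", "paludiculture",
    "shallow_lake", "open_bog_fen")
}

nutrient_levels <- function() c("rich", "poor", "mixed", "unknown")

#' Columns of the flux-table delimited-text schema
#'
#' @return Character vector of column names, in file order.
#' @export
flux_table_columns <- function() {
  c("site_name", "category", "subgroup", "country",
    "latitude", "longitude", "period", "nutrient_status", "treatment",
    "record_type", "nee", "ch4", "n2o",
    "nee_unit", "ch4_unit", "n2o_unit",
    "spread_kind", "flags", "note", "source")
}

#' Path to the packaged rewetted-peatland flux compilation
#'
#' A comma-separated UTF-8 encoding of a published compilation of annual
#' greenhouse-gas fluxes (NEE as CO2-C, CH4-C, N2O-N) measured on rewetted
#' boreal and temperate peatlands.  Values are stored exactly as tabulated in
#' the source compilation, with the per-study measurement-unit strings from
#' the table footnotes attached per gas; no unit conversion is applied at
#' encoding time.  Negative values are uptake by the ecosystem, positive
#' values are emission.
#'
#' @return Path to the CSV file.
#' @export
flux_table_path <- function() {
  system.file("extdata", "rewetted_flux_table.csv", package = "peatghg",
              mustWork = TRUE)
}

# Normalize typographic characters found in published tables: Unicode minus
# and dashes to ASCII "-", micro sign variants to "u", NBSP to space.
normalize_typography <- function(x) {
  x <- stringr::str_replace_all(
    x, c("−" = "-", "–" = "-", "—" = "-",
         "µ" = "u", "μ" = "u", " " = " "))
  stringr::str_squish(x)
}

# One plain number, optionally signed, with thousands separators or
# scientific notation.
.num_rx <- "[-+]?(?:\\d{1,3}(?:,\\d{3})+|\\d*\\.?\\d+)(?:[eE][-+]?\\d+)?"

parse_plain_number <- function(x) {
  x <- stringr::str_remove_all(x, ",")
  x <- stringr::str_remove_all(x, " ")
  suppressWarnings(as.numeric(x))
}

#' Parse a tabulated flux cell into a value-or-range record
#'
#' Flux compilations print cells in several shapes: a plain number
#' (`"-928"`), a range between annual means (`"-3970 to -5970"`), or a
#' central value with a spread (`"-1,609 ± 739"`).  This parser accepts
#' all three, tolerating typographic minus signs and thousands separators.
#' Ranges are normalized sign-aware so that `value <= high` regardless of
#' the printed order.
#'
#' @param x Character vector of cells; `NA` or empty cells yield a missing
#'   row (`kind = NA`).
#' @param spread Interpretation of a `±` spread: standard deviation
#'   (`"sd"`, default) or standard error (`"se"`).  Recycled along `x`.
#' @return A tibble with one row per cell and columns `kind`
#'   (`"point"`, `"range"`, `"point_with_sd"`, `"point_with_se"`, or `NA`),
#'   `value`, `high` (ranges only), `spread` (spreads only).
#' @examples
#' parse_value_or_range(c("-3970 to -5970", "90 ± 200", "28.1"))
#' @export
parse_value_or_range <- function(x, spread = "sd") {
  out <- parse_cells(x, spread)
  bad <- attr(out, "bad")
  if (length(bad) > 0) {
    abort(paste0("cannot parse flux cell: \"", x[bad[1]], "\""))
  }
  attr(out, "bad") <- NULL
  out
}

# Vectorized cell parser; unparseable cells are reported through the "bad"
# attribute (indices) instead of a condition, so callers can name the row.
parse_cells <- function(x, spread = "sd") {
  stopifnot(is.character(x) | all(is.na(x)))
  n <- length(x)
  spread <- rep_len(match.arg(spread, c("sd", "se"), several.ok = TRUE), n)
  kind <- rep(NA_character_, n)
  value <- high <- sprd <- rep(NA_real_, n)
  s <- normalize_typography(x)
  # allow a space between the sign and the digits, as typeset sources do
  s <- stringr::str_replace_all(s, "([+-])\\s+(?=[\\d.])", "\\1")
  blank <- is.na(s) | !nzchar(s)
  rng <- stringr::str_match(
    s, paste0("^(", .num_rx, ")\\s+to\\s+(", .num_rx, ")$"))
  is_rng <- !blank & !is.na(rng[, 1])
  if (any(is_rng)) {
    a <- parse_plain_number(rng[is_rng, 2])
    b <- parse_plain_number(rng[is_rng, 3])
    kind[is_rng] <- "range"
    value[is_rng] <- pmin(a, b)
    high[is_rng] <- pmax(a, b)
  }
  pm <- stringr::str_match(
    s, paste0("^(", .num_rx, ")\\s*±\\s*(", .num_rx, ")$"))
  is_pm <- !blank & !is_rng & !is.na(pm[, 1])
  if (any(is_pm)) {
    kind[is_pm] <- paste0("point_with_", spread[is_pm])
    value[is_pm] <- parse_plain_number(pm[is_pm, 2])
    sprd[is_pm] <- parse_plain_number(pm[is_pm, 3])
  }
  is_pt <- !blank & !is_rng & !is_pm &
    stringr::str_detect(s, paste0("^", .num_rx, "$"))
  if (any(is_pt)) {
    kind[is_pt] <- "point"
    value[is_pt] <- parse_plain_number(s[is_pt])
  }
  out <- tibble::new_tibble(
    list(kind = kind, value = value, high = high, spread = sprd))
  attr(out, "bad") <- which(!blank & !is_rng & !is_pm & !is_pt)
  out
}

#' Collapse a value-or-range to a single number
#'
#' Points and `±`-spread entries collapse to their central value; ranges
#' collapse to the arithmetic midpoint.  This is the convention used before
#' category-level averaging, where each table row contributes one number.
#'
#' @param parsed A tibble as returned by [parse_value_or_range()], or a
#'   character vector of cells (parsed first).
#' @return Numeric vector, `NA` where the cell was missing.
#' @export
collapse_value <- function(parsed) {
  if (is.character(parsed)) parsed <- parse_value_or_range(parsed)
  stopifnot(all(c("kind", "value", "high") %in% names(parsed)))
  dplyr::if_else(!is.na(parsed$kind) & parsed$kind == "range",
                 (parsed$value + parsed$high) / 2, parsed$value)
}

validate_flux_table <- function(tbl, file = "flux table") {
  missing_cols <- setdiff(flux_table_columns(), names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0(file, ": missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- which(!tbl$category %in% flux_categories())
  if (length(bad) > 0) {
    abort(paste0(file, ": unknown category \"", tbl$category[bad[1]],
                 "\" in row ", bad[1]))
  }
  bad <- which(!is.na(tbl$nutrient_status) &
                 !tbl$nutrient_status %in% nutrient_levels())
  if (length(bad) > 0) {
    abort(paste0(file, ": unknown nutrient_status \"",
                 tbl$nutrient_status[bad[1]], "\" in row ", bad[1]))
  }
  for (g in c("nee", "ch4", "n2o")) {
    parsed <- parse_cells(tbl[[g]])
    bad <- attr(parsed, "bad")
    if (length(bad) > 0) {
      abort(paste0(file, ": malformed value in row ", bad[1], ", column ", g,
                   ": \"", tbl[[g]][bad[1]], "\""))
    }
    unit <- tbl[[paste0(g, "_unit")]]
    no_unit <- which(!is.na(parsed$kind) & (is.na(unit) | !nzchar(unit)))
    if (length(no_unit) > 0) {
      abort(paste0(file, ": row ", no_unit[1], " has a ", g,
                   " value but no unit string"))
    }
  }
  if (any(!is.na(tbl$latitude) & abs(tbl$latitude) > 90) ||
      any(!is.na(tbl$longitude) & abs(tbl$longitude) > 180)) {
    abort(paste0(file, ": coordinates outside valid decimal-degree ranges"))
  }
  invisible(tbl)
}

#' Read a flux compilation from delimited text
#'
#' Reads a comma-separated flux table following the documented schema (see
#' [flux_table_columns()]).  Flux cells are kept as text exactly as stored —
#' including ranges and `±` spreads — so that provenance survives a
#' round trip; parsing to numbers happens downstream in
#' [harmonize_fluxes()].  Unknown category labels and malformed numbers are
#' rejected with the offending row identified.
#'
#' @param path Path to a CSV file; defaults to the packaged compilation.
#' @return A tibble with one row per site/treatment record.
#' @examples
#' fluxes <- read_flux_table()
#' dplyr::count(fluxes, category)
#' @export
read_flux_table <- function(path = flux_table_path()) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  tbl <- readr::read_csv(
    path, show_col_types = FALSE, progress = FALSE, na = c("", "NA"),
    col_types = readr::cols(
      .default = readr::col_character(),
      latitude = readr::col_double(),
      longitude = readr::col_double()))
  tbl <- tbl[, flux_table_columns()]
  for (col in c("nee", "ch4", "n2o")) {
    tbl[[col]] <- ifelse(is.na(tbl[[col]]), NA_character_,
                         normalize_typography(tbl[[col]]))
  }
  validate_flux_table(tbl, file = basename(path))
  tbl
}

#' Write a flux compilation to delimited text
#'
#' Inverse of [read_flux_table()]: writing then reading reproduces all
#' fields exactly, because flux cells are carried as text.
#'
#' @param tbl A flux table tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_flux_table <- function(tbl, path) {
  validate_flux_table(tbl)
  readr::write_csv(tbl[, flux_table_columns()], path, progress = FALSE)
  invisible(path)
}

# TRUE where the record's flags field contains the given token.
has_flag <- function(flags, token) {
  !is.na(flags) & stringr::str_detect(
    flags, paste0("(^|;)\\s*", token, "\\s*(;|$)"))
}
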