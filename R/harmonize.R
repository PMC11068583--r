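#' Harmonize a flux table to canonical units
#'
#' Pivots a flux table to one row per record and gas, parses the tabulated
#' cells, and converts values to the canonical kg element per hectare per
#' year scale.
#'
#' Two unit readings are supported because published compilations are not
#' always internally consistent.  The caption of the source table states
#' that tabulated values are already in kg C (or kg N) per hectare per
#' year, while the per-study footnotes list the original measurement units,
#' and for several studies the two disagree by orders of magnitude.
#' `mode = "tabulated"` (default) takes the caption at its word and treats
#' every value as canonical — this is the reading under which the
#' compilation's own category averages are reproduced.  `mode = "footnote"`
#' applies each study's footnote unit literally via [convert_flux()].
#'
#' Records flagged `season_only` (growing-season rates with no stated
#' season-to-year rule) are dropped from the result unless
#' `keep_season_only = TRUE`.  In footnote mode, values whose unit is a
#' CO2-equivalent mass are flagged `co2_equivalent` so that element-mass
#' aggregation can exclude them.
#'
#' @param tbl A flux table from [read_flux_table()] or
#'   [generate_flux_table()].
#' @param mode `"tabulated"` or `"footnote"`; see Details.
#' @param keep_season_only Keep growing-season-only records?
#' @return A tibble with one row per record and present gas: `row`,
#'   `site_name`, `category`, `record_type`, `nutrient_status`, `gas`,
#'   `kind`, `raw` (collapsed value as tabulated), `unit`, `value`
#'   (canonical, collapsed), `low`/`high` (canonical range ends, `NA` for
#'   points), `spread` (canonical), `co2_equivalent`, `season_only`,
#'   `flags`, `source`.  Absent gases yield no row.
#' @examples
#' harmonize_fluxes(read_flux_table())
#' @export
harmonize_fluxes <- function(tbl,
                             mode = c("tabulated", "footnote"),
                             keep_season_only = FALSE) {
  mode <- match.arg(mode)
  validate_flux_table(tbl)
  tbl$row <- seq_len(nrow(tbl))
  gases <- c(nee = "CO2", ch4 = "CH4", n2o = "N2O")
  out <- purrr::list_rbind(purrr::imap(gases, function(gas, col) {
    present <- which(!is.na(tbl[[col]]) & nzchar(tbl[[col]]))
    if (length(present) == 0) return(NULL)
    sub <- tbl[present, ]
    spread_kind <- ifelse(is.na(sub$spread_kind), "sd", sub$spread_kind)
    parsed <- parse_value_or_range(sub[[col]], spread = spread_kind)
    unit <- if (mode == "tabulated") {
      rep(canonical_unit(gas), nrow(sub))
    } else {
      sub[[paste0(col, "_unit")]]
    }
    conv <- tryCatch(
      parse_flux_unit(unit, gas),
      error = function(e) {
        # locate the offending record for the message
        for (j in seq_along(unit)) {
          ok <- tryCatch({parse_flux_unit(unit[j], gas); TRUE},
                         error = function(e2) FALSE)
          if (!ok) {
            abort(paste0("row ", sub$row[j], " (", sub$site_name[j], "), ",
                         col, ": ", conditionMessage(e)))
          }
        }
        abort(conditionMessage(e))
      })
    f <- conv$factor
    tibble::tibble(
      row = sub$row,
      site_name = sub$site_name,
      category = sub$category,
      record_type = sub$record_type,
      nutrient_status = sub$nutrient_status,
      gas = gas,
      kind = parsed$kind,
      raw = collapse_value(parsed),
      unit = unit,
      value = collapse_value(parsed) * f,
      low = parsed$value * ifelse(parsed$kind == "range", f, NA_real_),
      high = parsed$high * f,
      spread = parsed$spread * f,
      co2_equivalent = conv$basis == "co2_equivalent",
      season_only = has_flag(sub$flags, "season_only"),
      flags = sub$flags,
      source = sub$source)
  }))
  if (is.null(out) || nrow(out) == 0) {
    return(tibble::tibble(
      row = integer(), site_name = character(), category = character(),
      record_type = character(), nutrient_status = character(),
      gas = character(), kind = character(), raw = numeric(),
      unit = character(), value = numeric(), low = numeric(),
      high = numeric(), spread = numeric(), co2_equivalent = logical(),
      season_only = logical(), flags = character(), source = character()))
  }
  out <- dplyr::arrange(out, .data$row, match(.data$gas, gases))
  if (!keep_season_only) out <- dplyr::filter(out, !.data$season_only)
  out
}
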