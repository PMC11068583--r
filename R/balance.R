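#' Global-warming-potential specification
#'
#' CO2-equivalence factors for CH4 and N2O over a stated time horizon.
#' Defaults follow the factors conventionally used for the 100-year
#' horizon (25 for CH4, 298 for N2O) and the 500-year horizon (7.6 for
#' CH4, 153 for N2O); both can be overridden, e.g. to use
#' climate-carbon-feedback variants (CH4 = 34).
#'
#' @param horizon Horizon in years; 100 and 500 carry default factors,
#'   any other horizon requires explicit factors.
#' @param ch4_factor,n2o_factor Optional overrides (> 0).
#' @return A one-row tibble: `horizon`, `ch4_factor`, `n2o_factor`.
#' @examples
#' gwp_spec(100)
#' gwp_spec(100, ch4_factor = 34)
#' @export
gwp_spec <- function(horizon = 100, ch4_factor = NULL, n2o_factor = NULL) {
  defaults <- list(`100` = c(25, 298), `500` = c(7.6, 153))
  key <- as.character(horizon)
  if (is.null(ch4_factor) || is.null(n2o_factor)) {
    if (!key %in% names(defaults)) {
      abort(paste0("no default GWP factors for a ", horizon,
                   "-year horizon; supply ch4_factor and n2o_factor"))
    }
    if (is.null(ch4_factor)) ch4_factor <- defaults[[key]][1]
    if (is.null(n2o_factor)) n2o_factor <- defaults[[key]][2]
  }
  stopifnot(ch4_factor > 0, n2o_factor > 0)
  tibble::tibble(horizon = horizon, ch4_factor = ch4_factor,
                 n2o_factor = n2o_factor)
}

#' CO2-equivalent greenhouse-gas balance
#'
#' Combines element-based fluxes into a single CO2-equivalent balance:
#' CO2-C is expanded to CO2 mass (x 44/12), CH4-C to CH4 mass (x 16/12)
#' weighted by the CH4 factor, and N2O-N to N2O mass (x 44/28) weighted by
#' the N2O factor.  Negative results indicate net climate cooling under
#' the chosen horizon.
#'
#' @param nee_c Net ecosystem exchange, kg CO2-C ha-1 yr-1.
#' @param ch4_c Methane flux, kg CH4-C ha-1 yr-1.
#' @param n2o_n Nitrous-oxide flux, kg N2O-N ha-1 yr-1.
#' @param gwp A [gwp_spec()] row.
#' @return Numeric vector, kg CO2-eq ha-1 yr-1.  Missing gases count as 0,
#'   with a warning.
#' @examples
#' co2_equivalent(-1000, 100, 1, gwp_spec(100))
#' @export
co2_equivalent <- function(nee_c, ch4_c, n2o_n, gwp = gwp_spec(100)) {
  args <- list(nee_c = nee_c, ch4_c = ch4_c, n2o_n = n2o_n)
  missing_gas <- names(args)[vapply(args, function(v) any(is.na(v)), TRUE)]
  if (length(missing_gas) > 0) {
    warn(paste0("missing flux treated as 0: ",
                paste(missing_gas, collapse = ", ")))
  }
  args <- lapply(args, function(v) dplyr::coalesce(v, 0))
  args$nee_c * 44 / 12 +
    gwp$ch4_factor * args$ch4_c * 16 / 12 +
    gwp$n2o_factor * args$n2o_n * 44 / 28
}

#' Category-level summary statistics of harmonized fluxes
#'
#' Unweighted arithmetic means (with sd, min, max, n) of the collapsed,
#' harmonized values per restoration category and gas, each table row
#' contributing one value.  Values flagged as CO2-equivalent masses are
#' excluded from these element-mass statistics.  An empty selection
#' returns zero rows — "no data", never zero.
#'
#' @param harmonized Output of [harmonize_fluxes()].
#' @param category,gas,record_type Optional filters (character vectors).
#' @return A tibble: `category`, `gas`, `n`, `mean`, `sd`, `min`, `max`,
#'   in canonical kg element ha-1 yr-1.
#' @examples
#' aggregate_by_category(harmonize_fluxes(read_flux_table()))
#' @export
aggregate_by_category <- function(harmonized, category = NULL, gas = NULL,
                                  record_type = NULL) {
  x <- dplyr::filter(harmonized, !.data$co2_equivalent, !is.na(.data$value))
  if (!is.null(category)) x <- x[x$category %in% category, ]
  if (!is.null(gas)) x <- x[x$gas %in% gas, ]
  if (!is.null(record_type)) x <- x[x$record_type %in% record_type, ]
  if (nrow(x) == 0) {
    return(tibble::tibble(category = character(), gas = character(),
                          n = integer(), mean = numeric(), sd = numeric(),
                          min = numeric(), max = numeric()))
  }
  dplyr::summarise(
    dplyr::group_by(x, .data$category, .data$gas),
    n = dplyr::n(),
    mean = mean(.data$value),
    sd = sd(.data$value),
    min = min(.data$value),
    max = max(.data$value),
    .groups = "drop")
}

#' Rounding for display
#'
#' Half-away-from-zero rounding to whole kg, the convention under which
#' reported category means such as -927.5 display as -928.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
display_round <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-category CO2-equivalent balance report
#'
#' For each restoration category, computes the per-gas means via
#' [aggregate_by_category()] and combines them into a CO2-equivalent
#' balance for each supplied GWP horizon, using the category's per-gas
#' means (gases with no data enter as missing and count as zero, with a
#' warning).
#'
#' @param harmonized Output of [harmonize_fluxes()].
#' @param gwp A [gwp_spec()] tibble or several row-bound together
#'   (default: the 100- and 500-year horizons).
#' @return A tibble with one row per category and horizon: per-gas `n` and
#'   `mean` columns, `horizon`, and `co2eq` in kg CO2-eq ha-1 yr-1.
#' @examples
#' balance_report(harmonize_fluxes(read_flux_table()))
#' @export
balance_report <- function(harmonized,
                           gwp = dplyr::bind_rows(gwp_spec(100),
                                                  gwp_spec(500))) {
  stats <- aggregate_by_category(harmonized)
  if (nrow(stats) == 0) {
    return(tibble::tibble(category = character(), horizon = numeric(),
                          co2eq = numeric()))
  }
  wide <- tidyr::pivot_wider(
    stats[, c("category", "gas", "n", "mean")],
    names_from = "gas", values_from = c("n", "mean"))
  for (col in c("n_CO2", "n_CH4", "n_N2O",
                "mean_CO2", "mean_CH4", "mean_N2O")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  out <- tidyr::crossing(wide, gwp)
  out$co2eq <- withCallingHandlers(
    co2_equivalent(out$mean_CO2, out$mean_CH4, out$mean_N2O,
                   gwp = out[, c("ch4_factor", "n2o_factor")]),
    warning = function(w) invokeRestart("muffleWarning"))
  n_missing <- sum(is.na(out$mean_CO2) | is.na(out$mean_CH4) |
                     is.na(out$mean_N2O))
  if (n_missing > 0) {
    warn(paste0(n_missing, " category/horizon balances computed with a ",
                "missing gas treated as 0"))
  }
  dplyr::arrange(
    out[, c("category", "n_CO2", "mean_CO2", "n_CH4", "mean_CH4",
            "n_N2O", "mean_N2O", "horizon", "ch4_factor", "n2o_factor",
            "co2eq")],
    match(.data$category, flux_categories()), .data$horizon)
}

#' Bar-chart of category CO2-equivalent balances
#'
#' @param report Output of [balance_report()].
#' @return A ggplot object, one bar per category, faceted by GWP horizon.
#' @export
plot_balance <- function(report) {
  ggplot2::ggplot(report,
                  ggplot2::aes(x = .data$category, y = .data$co2eq,
                               fill = .data$co2eq < 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~.data$horizon,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "kg CO2-eq ha-1 yr-1") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}
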