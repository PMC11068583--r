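# Minimal in-code flux table with every schema column present.
make_flux_table <- function(n = 1, ...) {
  cols <- flux_table_columns()
  base <- tibble::as_tibble(
    stats::setNames(as.list(rep(NA_character_, length(cols))), cols))
  base$latitude <- NA_real_
  base$longitude <- NA_real_
  out <- dplyr::bind_rows(rep(list(base), n))
  out$site_name <- sprintf("site_%02d", seq_len(n))
  out$category <- "open_bog_fen"
  out$record_type <- "site"
  out$source <- "test"
  overrides <- list(...)
  for (nm in names(overrides)) out[[nm]] <- overrides[[nm]]
  out
}

# Independent piecewise-linear evaluator: explicit segment search, no approx().
interp_oracle <- function(year, rate, t) {
  vapply(t, function(q) {
    if (q >= year[length(year)]) return(rate[length(rate)])
    i <- findInterval(q, year)
    if (i == 0) return(rate[1])
    w <- (q - year[i]) / (year[i + 1] - year[i])
    rate[i] + w * (rate[i + 1] - rate[i])
  }, numeric(1))
}

total_biomass_c <- function(volume, al = allometry_params()) {
  b <- biomass_carbon(volume, al)
  b$stem_c + b$branch_c + b$root_c
}
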