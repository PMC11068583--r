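#' One-shot analysis report
#'
#' Runs the full pipeline — read, harmonize, category balances at each
#' requested GWP horizon, and the long-term scenario simulations with
#' their diagnostics — and writes the results to an output directory:
#'
#' * `balance.csv` / `balance.json` — per-category gas means and
#'   CO2-equivalent balances;
#' * `trajectory_<scenario>.csv` — one annual pool table per scenario;
#' * `diagnostics.json` — neutrality years and mean annual changes;
#' * `report.txt` — a human-readable summary.
#'
#' Every number in the report is read back from a stage output held in
#' the returned list; nothing is computed at formatting time.  Given the
#' same inputs the emitted JSON is byte-identical between runs.
#'
#' @param flux_path Flux table CSV (default: the packaged compilation).
#' @param out_dir Output directory, created if needed; `NULL` to skip
#'   writing files.
#' @param gwp_horizons GWP horizons to report (subset of those accepted
#'   by [gwp_spec()]).
#' @param scenarios Scenario names to simulate.
#' @param horizon Simulation horizon in years.
#' @param mode Unit reading passed to [harmonize_fluxes()].
#' @param windows Named list of `c(from, to)` diagnostic windows per
#'   scenario (defaults cover the post-transition windows of the
#'   restored and regenerated scenarios).
#' @param plots Also write `balance.png` and `trajectories.png`?
#' @return Invisibly, a list with elements `fluxes`, `harmonized`,
#'   `stats`, `balance`, `trajectories`, `diagnostics`.
#' @examples
#' rep <- run_report(out_dir = NULL, scenarios = "restored_bog")
#' rep$diagnostics
#' @export
run_report <- function(flux_path = flux_table_path(),
                       out_dir = NULL,
                       gwp_horizons = c(100, 500),
                       scenarios = scenario_names(),
                       horizon = 300,
                       mode = "tabulated",
                       windows = list(
                         restored_bog = c(20, 300),
                         regenerated_unmanaged_forest = c(160, 300)),
                       plots = FALSE) {
  fluxes <- read_flux_table(flux_path)
  empty <- nrow(fluxes) == 0
  harmonized <- if (empty) NULL else harmonize_fluxes(fluxes, mode = mode)
  stats <- if (empty) NULL else aggregate_by_category(harmonized)
  gwp <- purrr::list_rbind(purrr::map(gwp_horizons, gwp_spec))
  bal <- if (empty) NULL else
    suppressWarnings(balance_report(harmonized, gwp = gwp))
  trajectories <- purrr::map(
    setNames(scenarios, scenarios),
    function(s) simulate_carbon(s, horizon = horizon))
  diagnostics <- purrr::list_rbind(purrr::imap(trajectories, function(tr, s) {
    g <- glance(tr)
    w <- windows[[s]]
    g$window_from <- if (is.null(w)) NA_real_ else w[1]
    g$window_to <- if (is.null(w)) NA_real_ else w[2]
    g$window_mean_change <- if (is.null(w)) NA_real_ else
      mean_annual_change(tr, w[1], w[2])
    g
  }))
  out <- list(fluxes = fluxes, harmonized = harmonized, stats = stats,
              balance = bal, trajectories = trajectories,
              diagnostics = diagnostics)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(bal)) {
      readr::write_csv(bal, file.path(out_dir, "balance.csv"),
                       progress = FALSE)
      jsonlite::write_json(bal, file.path(out_dir, "balance.json"),
                           dataframe = "rows", digits = NA, pretty = TRUE)
    }
    for (s in names(trajectories)) {
      readr::write_csv(trajectories[[s]],
                       file.path(out_dir, paste0("trajectory_", s, ".csv")),
                       progress = FALSE)
    }
    jsonlite::write_json(diagnostics,
                         file.path(out_dir, "diagnostics.json"),
                         dataframe = "rows", digits = NA, pretty = TRUE)
    writeLines(format_report_text(out), file.path(out_dir, "report.txt"))
    if (plots) {
      ggplot2::ggsave(file.path(out_dir, "balance.png"),
                      plot_balance(bal), width = 7, height = 4, dpi = 150)
      panels <- patch_trajectories_plot(trajectories)
      ggplot2::ggsave(file.path(out_dir, "trajectories.png"), panels,
                      width = 9, height = 6, dpi = 150)
    }
  }
  invisible(out)
}

patch_trajectories_plot <- function(trajectories) {
  long <- purrr::list_rbind(purrr::imap(trajectories, function(tr, s) {
    tibble::tibble(scenario = s, year = tr$year, total_c = tr$total_c)
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$total_c,
                                     colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "year", y = "total ecosystem C (t ha-1)") +
    ggplot2::theme_minimal()
}

format_report_text <- function(out) {
  lines <- c("peatghg analysis report", "=======================", "")
  if (is.null(out$stats) || nrow(out$stats) == 0) {
    lines <- c(lines, "Flux table: no data.")
  } else {
    lines <- c(lines, "Category means (kg element ha-1 yr-1):")
    for (i in seq_len(nrow(out$stats))) {
      s <- out$stats[i, ]
      lines <- c(lines, sprintf("  %-18s %-4s n=%2d  mean %9.1f  [%9.1f, %9.1f]",
                                s$category, s$gas, s$n, s$mean, s$min, s$max))
    }
    lines <- c(lines, "", "CO2-equivalent balances (kg CO2-eq ha-1 yr-1):")
    for (i in seq_len(nrow(out$balance))) {
      b <- out$balance[i, ]
      lines <- c(lines, sprintf("  %-18s GWP%-3d  %9.0f",
                                b$category, b$horizon,
                                display_round(b$co2eq)))
    }
  }
  lines <- c(lines, "", "Scenario diagnostics (t C ha-1 yr-1):")
  for (i in seq_len(nrow(out$diagnostics))) {
    d <- out$diagnostics[i, ]
    lines <- c(lines, sprintf(
      "  %-30s neutrality yr %-4s mean dC %7.3f  peat dC %7.3f",
      d$scenario,
      ifelse(is.na(d$neutrality_year), "-", d$neutrality_year),
      d$mean_annual_change, d$mean_annual_peat_change))
    if (!is.na(d$window_mean_change)) {
      lines <- c(lines, sprintf(
        "  %-30s   window %d-%d mean dC %7.3f",
        "", d$window_from, d$window_to, d$window_mean_change))
    }
  }
  lines
}
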