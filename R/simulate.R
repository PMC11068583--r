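#' Simulate a 300-year ecosystem carbon trajectory
#'
#' Annual-step bookkeeping of five carbon pools — peat, stem, branch,
#' coarse root and harvest residue — plus cumulative timber export, for a
#' land-use [scenario_spec()].  Each year, in order: (1) stem volume grows
#' by the increment schedule (evaluated on stand age) and the stand pools
#' are re-derived through [biomass_carbon()]; (2) the peat pool receives
#' the peat-flux schedule (evaluated on calendar year); (3) the residue
#' pool decays first-order, the decayed mass leaving the ecosystem; (4) if
#' a clearcut falls on this year boundary, stem carbon moves to the export
#' ledger, branch and root carbon become residues, and the stand restarts
#' at age 0.  Harvests fall at whole multiples of the cycle strictly
#' inside the horizon; a harvest due exactly at the horizon is not applied,
#' so the final state describes the mature pre-harvest stand.
#'
#' The run is fully deterministic.  If the peat pool would be driven below
#' zero the simulation halts with a `peatghg_peat_exhausted` error naming
#' the year.
#'
#' @param spec A [scenario_spec()] or a scenario name understood by
#'   [peat_scenario()].
#' @param horizon Number of years to simulate (>= 1; default 300).
#' @return A tibble of class `peat_trajectory` with one row per year
#'   0..`horizon`: `year`, `stand_age`, `stand_volume`, `peat_c`,
#'   `stem_c`, `branch_c`, `root_c`, `residue_c`, `total_c` (all pools,
#'   excluding export), `export_c` (cumulative), in t C ha-1.
#' @examples
#' traj <- simulate_carbon("restored_bog")
#' neutrality_year(traj)
#' @export
simulate_carbon <- function(spec, horizon = 300) {
  if (is.character(spec)) spec <- peat_scenario(spec)
  stopifnot(inherits(spec, "scenario_spec"),
            is.numeric(horizon), horizon >= 1, horizon == round(horizon))
  n <- horizon + 1
  year <- 0:horizon
  age <- vol <- peat <- stem <- branch <- root <- residue <- export <-
    numeric(n)
  vol[1] <- spec$initial_stem_volume
  peat[1] <- spec$initial_peat_c
  al <- spec$allometry
  # scalar allometry coefficients (identical arithmetic to biomass_carbon)
  k_stem <- al$wood_density * al$carbon_fraction / 1000
  k_branch <- al$branch_ratio
  k_root <- al$coarse_root_ratio
  pools <- function(v) {
    s <- v * k_stem; b <- k_branch * s
    c(s, b, k_root * (s + b))
  }
  b0 <- pools(vol[1])
  stem[1] <- b0[1]; branch[1] <- b0[2]; root[1] <- b0[3]
  incr <- schedule_fun(spec$increment_schedule)
  pflux <- schedule_fun(spec$peat_flux_schedule)
  decay_factor <- exp(-spec$residue_decay_rate)
  for (t in seq_len(horizon)) {
    i <- t + 1
    a <- age[t] + 1
    v <- vol[t] + incr(a)
    b <- pools(v)
    p <- peat[t] + pflux(t)
    if (p < 0) {
      abort(paste0("peat pool exhausted at year ", t, " in scenario ",
                   spec$name),
            class = "peatghg_peat_exhausted")
    }
    r <- residue[t] * decay_factor
    e <- export[t]
    if (!is.null(spec$harvest_cycle) &&
        t %% spec$harvest_cycle == 0 && t < horizon) {
      e <- e + b[1]
      r <- r + b[2] + b[3]
      v <- 0; a <- 0
      b <- c(0, 0, 0)
    }
    age[i] <- a; vol[i] <- v; peat[i] <- p
    stem[i] <- b[1]; branch[i] <- b[2]; root[i] <- b[3]
    residue[i] <- r; export[i] <- e
  }
  out <- tibble::new_tibble(
    list(year = year, stand_age = age, stand_volume = vol,
         peat_c = peat, stem_c = stem, branch_c = branch, root_c = root,
         residue_c = residue,
         total_c = peat + stem + branch + root + residue,
         export_c = export),
    class = "peat_trajectory")
  attr(out, "spec") <- spec
  out
}

#' Carbon-neutrality year of a trajectory
#'
#' The first simulation year in which the annual change in total
#' ecosystem carbon (all pools, excluding exported timber) becomes
#' non-negative.
#'
#' @param traj A `peat_trajectory` from [simulate_carbon()].
#' @return Integer year, or `NA` if the ecosystem loses carbon every year
#'   of the horizon.
#' @examples
#' neutrality_year(simulate_carbon("restored_bog"))  # 20
#' @export
neutrality_year <- function(traj) {
  stopifnot(inherits(traj, "peat_trajectory"), nrow(traj) >= 2)
  d <- diff(traj$total_c)
  hit <- which(d >= 0)
  if (length(hit) == 0) return(NA_integer_)
  as.integer(traj$year[hit[1] + 1])
}

#' Mean annual change in total ecosystem carbon over a window
#'
#' @param traj A `peat_trajectory`.
#' @param from_year,to_year Window bounds in simulation years,
#'   `0 <= from_year < to_year <= horizon`.
#' @param pool Column to difference (default `"total_c"`; use `"peat_c"`
#'   for the peat pool alone).
#' @return Mean annual change, t C ha-1 yr-1 (negative = loss).
#' @examples
#' mean_annual_change(simulate_carbon("restored_bog"), 20, 300)  # 0.22
#' @export
mean_annual_change <- function(traj, from_year, to_year, pool = "total_c") {
  stopifnot(inherits(traj, "peat_trajectory"),
            pool %in% names(traj))
  horizon <- max(traj$year)
  if (!(from_year >= 0 && from_year < to_year && to_year <= horizon)) {
    abort(paste0("bad window [", from_year, ", ", to_year,
                 "] for a horizon of ", horizon, " years"))
  }
  i0 <- match(from_year, traj$year); i1 <- match(to_year, traj$year)
  if (is.na(i0) || is.na(i1)) abort("window bounds must be stored years")
  (traj[[pool]][i1] - traj[[pool]][i0]) / (to_year - from_year)
}

#' @export
tidy.peat_trajectory <- function(x, ...) {
  tidyr::pivot_longer(
    x[, c("year", "peat_c", "stem_c", "branch_c", "root_c", "residue_c",
          "export_c")],
    -"year", names_to = "pool", values_to = "carbon")
}

#' @export
glance.peat_trajectory <- function(x, ...) {
  spec <- attr(x, "spec")
  horizon <- max(x$year)
  tibble::tibble(
    scenario = if (is.null(spec)) NA_character_ else spec$name,
    horizon = horizon,
    neutrality_year = neutrality_year(x),
    mean_annual_change = mean_annual_change(x, 0, horizon),
    mean_annual_peat_change = mean_annual_change(x, 0, horizon,
                                                 pool = "peat_c"),
    final_total_c = x$total_c[nrow(x)],
    final_export_c = x$export_c[nrow(x)])
}

#' @export
autoplot.peat_trajectory <- function(object, ...) {
  long <- tidy(object)
  spec <- attr(object, "spec")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$year, y = .data$carbon,
                               colour = .data$pool)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(
      data = object, inherit.aes = FALSE,
      ggplot2::aes(x = .data$year, y = .data$total_c),
      linewidth = 0.9, colour = "black") +
    ggplot2::labs(
      title = if (is.null(spec)) NULL else spec$name,
      x = "year", y = "t C ha-1",
      caption = "black line: total ecosystem carbon (excl. export)") +
    ggplot2::theme_minimal()
}
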