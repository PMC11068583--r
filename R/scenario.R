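#' Tree-stand allometry parameters
#'
#' Fixed partitioning of stand biomass used to convert stem volume to
#' carbon pools: branches are a constant fraction of stem biomass and
#' coarse roots a constant fraction of above-ground (stem + branch)
#' biomass, in any age class.  Defaults are typical of hemiboreal Scots
#' pine on ombrotrophic peat: wood basic density 420 kg m-3, carbon
#' content 50 % of dry mass, branches 12 % of stem biomass, coarse roots
#' 19 % of above-ground biomass.  Fine roots are not a pool here; their
#' turnover is carried by the peat-flux schedule.
#'
#' @param wood_density Basic wood density, kg dry mass m-3.
#' @param carbon_fraction Carbon content of dry mass (0-1).
#' @param branch_ratio Branch biomass as a fraction of stem biomass.
#' @param coarse_root_ratio Coarse-root biomass as a fraction of
#'   above-ground biomass.
#' @return A one-row tibble of the four parameters.
#' @export
allometry_params <- function(wood_density = 420, carbon_fraction = 0.5,
                             branch_ratio = 0.12, coarse_root_ratio = 0.19) {
  stopifnot(wood_density > 0, carbon_fraction > 0, carbon_fraction < 1,
            branch_ratio > 0, branch_ratio < 1,
            coarse_root_ratio > 0, coarse_root_ratio < 1)
  tibble::tibble(wood_density = wood_density,
                 carbon_fraction = carbon_fraction,
                 branch_ratio = branch_ratio,
                 coarse_root_ratio = coarse_root_ratio)
}

#' Carbon pools of a stand from stem volume
#'
#' @param volume Stem volume, m3 ha-1 (>= 0); vectorized.
#' @param allometry An [allometry_params()] row.
#' @return A tibble with columns `stem_c`, `branch_c`, `root_c` in
#'   t C ha-1.
#' @examples
#' biomass_carbon(100)  # 21, 2.52, 4.4688 t C ha-1
#' @export
biomass_carbon <- function(volume, allometry = allometry_params()) {
  if (any(volume < 0)) abort("negative stem volume")
  stem_c <- volume * allometry$wood_density * allometry$carbon_fraction / 1000
  branch_c <- allometry$branch_ratio * stem_c
  root_c <- allometry$coarse_root_ratio * (stem_c + branch_c)
  tibble::tibble(stem_c = stem_c, branch_c = branch_c, root_c = root_c)
}

#' Peat carbon stock from peat depth
#'
#' @param depth Peat depth, m (>= 0).
#' @param volumetric_c Carbon density of peat, kg C m-3; the default
#'   34.3 makes a 2 m pristine-bog deposit hold 686 t C ha-1.
#' @return Carbon stock, t C ha-1.
#' @examples
#' peat_depth_to_c_stock(2)  # 686
#' @export
peat_depth_to_c_stock <- function(depth, volumetric_c = 34.3) {
  if (any(depth < 0)) abort("negative peat depth")
  stopifnot(volumetric_c > 0)
  depth * volumetric_c * 1e4 / 1000
}

#' Names of the packaged land-use scenarios
#'
#' @return Character vector of the six scenario names.
#' @export
scenario_names <- function() {
  c("pristine_open_bog", "pristine_bog_forest",
    "drained_managed_bog_forest", "restored_bog",
    "regenerated_unmanaged_forest", "managed_forest_on_cutover")
}

#' Build a land-use scenario specification
#'
#' Low-level constructor; most users start from [peat_scenario()] and
#' override fields.  A scenario bundles the initial stocks, the
#' stem-volume increment schedule, the peat carbon-flux schedule
#' (negative = mineralization loss), the harvest rule and the allometry.
#'
#' @param name Scenario name (free text for custom scenarios).
#' @param initial_peat_c Initial peat carbon stock, t C ha-1 (> 0).
#' @param initial_stem_volume Initial stem volume, m3 ha-1 (>= 0).
#' @param increment_schedule [schedule()] of stem-volume increment,
#'   m3 ha-1 yr-1, evaluated on stand age (restarts after a clearcut).
#' @param peat_flux_schedule [schedule()] of peat carbon flux,
#'   t C ha-1 yr-1, evaluated on calendar year.
#' @param harvest_cycle Years between clearcuts, or `NULL` for no
#'   harvesting.  Only stem carbon is exported; harvest residues
#'   (branches and coarse roots) enter the residue pool.
#' @param residue_decay_rate First-order decay rate of harvest residues,
#'   yr-1; decayed mass leaves the ecosystem.
#' @param allometry An [allometry_params()] row.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(name, initial_peat_c = 686,
                          initial_stem_volume = 0,
                          increment_schedule = schedule(0, 0),
                          peat_flux_schedule = schedule(0, 0),
                          harvest_cycle = NULL,
                          residue_decay_rate = 0.05,
                          allometry = allometry_params()) {
  stopifnot(is.character(name), length(name) == 1,
            initial_peat_c > 0, initial_stem_volume >= 0,
            inherits(increment_schedule, "peat_schedule"),
            inherits(peat_flux_schedule, "peat_schedule"),
            is.null(harvest_cycle) ||
              (is.numeric(harvest_cycle) && harvest_cycle >= 1),
            residue_decay_rate >= 0)
  structure(
    list(name = name, initial_peat_c = initial_peat_c,
         initial_stem_volume = initial_stem_volume,
         increment_schedule = increment_schedule,
         peat_flux_schedule = peat_flux_schedule,
         harvest_cycle = harvest_cycle,
         residue_decay_rate = residue_decay_rate,
         allometry = allometry),
    class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec>", x$name, "\n")
  cat("  initial peat C:", x$initial_peat_c, "t ha-1;",
      "initial stem volume:", x$initial_stem_volume, "m3 ha-1\n")
  cat("  harvest cycle:",
      if (is.null(x$harvest_cycle)) "none" else
        paste(x$harvest_cycle, "yr"), "\n")
  cat("  increment breakpoints:",
      paste0("(", x$increment_schedule$year, ", ",
             x$increment_schedule$rate, ")", collapse = " "), "\n")
  cat("  peat flux breakpoints:",
      paste0("(", x$peat_flux_schedule$year, ", ",
             x$peat_flux_schedule$rate, ")", collapse = " "), "\n")
  invisible(x)
}

#' Packaged default scenario parameterizations
#'
#' Six hemiboreal ombrotrophic peatland land-use scenarios sharing an
#' initial peat stock of 686 t C ha-1 (a 2 m deposit):
#'
#' * `pristine_open_bog` — treeless bog (a token 3 m3 ha-1 of stunted
#'   stems, no increment) accumulating peat at 0.22 t C ha-1 yr-1.
#' * `pristine_bog_forest` — continuous-cover bog forest at 100 m3 ha-1,
#'   increment 0.1 m3 ha-1 yr-1, peat accumulation 0.072 t C ha-1 yr-1
#'   (ecosystem gain about 0.1 t C ha-1 yr-1 including stand growth).
#' * `drained_managed_bog_forest` — drained for forestry; increment
#'   4 m3 ha-1 yr-1, peat mineralization loss 0.9 t C ha-1 yr-1,
#'   clearcut every 100 years.
#' * `restored_bog` — rewetted cutover; no stand; peat flux ramps
#'   linearly from -2 t C ha-1 yr-1 at year 0 to zero at year 20, then
#'   accumulates at 0.22 t C ha-1 yr-1 as a pristine bog.
#' * `regenerated_unmanaged_forest` — natural afforestation of a
#'   cutover: no increment until year 20, rising to 4 m3 ha-1 yr-1 by
#'   year 50, declining to 0.1 by year 160; peat flux -2 to 0 over
#'   years 0-50, rising to +0.072 by year 160; never harvested.
#' * `managed_forest_on_cutover` — afforested cutover on fertile
#'   residual fen peat: increment 6 m3 ha-1 yr-1, peat loss
#'   1.0 t C ha-1 yr-1, clearcut every 100 years.
#'
#' @param name One of [scenario_names()].
#' @param ... Field overrides passed to [scenario_spec()].
#' @return A `scenario_spec`.
#' @examples
#' peat_scenario("restored_bog")
#' @export
peat_scenario <- function(name = scenario_names(), ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    pristine_open_bog = list(
      initial_stem_volume = 3,
      increment_schedule = schedule(0, 0),
      peat_flux_schedule = schedule(0, 0.22)),
    pristine_bog_forest = list(
      initial_stem_volume = 100,
      increment_schedule = schedule(0, 0.1),
      peat_flux_schedule = schedule(0, 0.072)),
    drained_managed_bog_forest = list(
      increment_schedule = schedule(0, 4),
      peat_flux_schedule = schedule(0, -0.9),
      harvest_cycle = 100),
    restored_bog = list(
      increment_schedule = schedule(0, 0),
      peat_flux_schedule = schedule(year = c(0, 20, 21),
                                    rate = c(-2, 0, 0.22))),
    regenerated_unmanaged_forest = list(
      increment_schedule = schedule(year = c(0, 20, 50, 160),
                                    rate = c(0, 0, 4, 0.1)),
      peat_flux_schedule = schedule(year = c(0, 50, 160),
                                    rate = c(-2, 0, 0.072))),
    managed_forest_on_cutover = list(
      increment_schedule = schedule(0, 6),
      peat_flux_schedule = schedule(0, -1),
      harvest_cycle = 100))
  args <- utils::modifyList(c(list(name = name), defaults), list(...))
  do.call(scenario_spec, args)
}

#' Reported mineralization-loss presets for drained former bogs
#'
#' Long-term peat mineralization losses reported for drained afforested
#' former bogs span 1.8 and 1.0 t C ha-1 yr-1 depending on site
#' conditions; both are exposed here so either can be substituted into a
#' drained scenario's `peat_flux_schedule`.
#'
#' @return A tibble: `preset`, `loss` (t C ha-1 yr-1, positive = loss).
#' @export
peat_loss_presets <- function() {
  tibble::tibble(preset = c("drained_bog_high", "drained_bog_low"),
                 loss = c(1.8, 1.0))
}

#' Read or write a scenario as a YAML config file
#'
#' Scenario files mirror the `scenario_spec` fields; schedules are stored
#' as parallel `year`/`rate` lists.
#'
#' @param path File path.
#' @return `read_scenario()` returns a `scenario_spec`;
#'   `write_scenario()` returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  scenario_spec(
    name = x$name,
    initial_peat_c = x$initial_peat_c,
    initial_stem_volume = x$initial_stem_volume,
    increment_schedule = schedule(unlist(x$increment_schedule$year),
                                  unlist(x$increment_schedule$rate)),
    peat_flux_schedule = schedule(unlist(x$peat_flux_schedule$year),
                                  unlist(x$peat_flux_schedule$rate)),
    harvest_cycle = x$harvest_cycle,
    residue_decay_rate = x$residue_decay_rate,
    allometry = do.call(allometry_params, x$allometry))
}

#' @rdname read_scenario
#' @param spec A `scenario_spec`.
#' @export
write_scenario <- function(spec, path) {
  stopifnot(inherits(spec, "scenario_spec"))
  yaml::write_yaml(
    list(name = spec$name,
         initial_peat_c = spec$initial_peat_c,
         initial_stem_volume = spec$initial_stem_volume,
         increment_schedule = list(
           year = spec$increment_schedule$year,
           rate = spec$increment_schedule$rate),
         peat_flux_schedule = list(
           year = spec$peat_flux_schedule$year,
           rate = spec$peat_flux_schedule$rate),
         harvest_cycle = spec$harvest_cycle,
         residue_decay_rate = spec$residue_decay_rate,
         allometry = as.list(spec$allometry)),
    path)
  invisible(path)
}
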