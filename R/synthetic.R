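#' Specification for a synthetic flux table
#'
#' Defines the generating truth for [generate_flux_table()]: per category
#' and gas a canonical-scale mean and standard deviation, the number of
#' records per category, and per gas a mixture of measurement-unit
#' dialects with sampling probabilities.  The default truth is seeded at
#' magnitudes typical of the packaged compilation's category averages
#' (e.g. around -928 kg CO2-C ha-1 yr-1 for rewetted forests, 451 kg
#' CH4-C ha-1 yr-1 for shallow lakes), with the default dialect mixture
#' spanning element-mass, molecule-mass and molar unit families.
#'
#' @param truth Tibble with columns `category`, `gas`, `mean`, `sd`
#'   (canonical kg element ha-1 yr-1; `sd >= 0`).
#' @param n_per_category Records generated per category.
#' @param dialects Tibble with columns `gas`, `unit`, `prob`;
#'   probabilities must sum to 1 within each gas.
#' @param noise `"normal"` (default) or `"lognormal"` — the latter draws
#'   a log-normal magnitude with matched mean/sd and keeps the sign of
#'   the mean, for robustness checks against heavy tails.
#' @return A list of class `synthetic_flux_spec`.
#' @export
synthetic_flux_spec <- function(truth = default_synthetic_truth(),
                                n_per_category = 10,
                                dialects = default_unit_dialects(),
                                noise = c("normal", "lognormal")) {
  noise <- match.arg(noise)
  stopifnot(all(c("category", "gas", "mean", "sd") %in% names(truth)),
            all(truth$sd >= 0),
            all(truth$category %in% flux_categories()),
            all(c("gas", "unit", "prob") %in% names(dialects)),
            n_per_category >= 1)
  psum <- tapply(dialects$prob, dialects$gas, sum)
  if (any(abs(psum - 1) > 1e-8)) {
    abort("dialect probabilities must sum to 1 within each gas")
  }
  structure(list(truth = truth, n_per_category = n_per_category,
                 dialects = dialects, noise = noise),
            class = "synthetic_flux_spec")
}

#' @rdname synthetic_flux_spec
#' @export
default_synthetic_truth <- function() {
  tidyr::crossing(
    tibble::tibble(category = flux_categories()),
    tibble::tibble(gas = c("CO2", "CH4", "N2O"))) |>
    dplyr::mutate(
      mean = dplyr::case_when(
        gas == "CO2" & category == "rewetted_forest" ~ -928,
        gas == "CO2" & category == "paludiculture" ~ -528,
        gas == "CO2" & category == "open_bog_fen" ~ -534,
        gas == "CO2" & category == "shallow_lake" ~ -300,
        gas == "CO2" ~ -500,
        gas == "CH4" & category == "rewetted_forest" ~ 218,
        gas == "CH4" & category == "paludiculture" ~ 122,
        gas == "CH4" & category == "open_bog_fen" ~ 163,
        gas == "CH4" & category == "shallow_lake" ~ 451,
        gas == "CH4" ~ 150,
        .default = 1.5),
      sd = dplyr::case_when(gas == "CO2" ~ 300,
                            gas == "CH4" ~ 80,
                            .default = 0.8))
}

#' @rdname synthetic_flux_spec
#' @export
default_unit_dialects <- function() {
  tibble::tibble(
    gas = rep(c("CO2", "CH4", "N2O"), each = 4),
    unit = c("kg C ha-1 yr-1", "mg CO2-C m-2 h-1", "g CO2 m-2 yr-1",
             "t CO2 ha-1 yr-1",
             "kg C ha-1 yr-1", "ug CH4-C m-2 h-1", "g CH4 m-2 yr-1",
             "mmol CH4 m-2 h-1",
             "kg N ha-1 yr-1", "ug N2O-N m-2 h-1", "mg N2O m-2 yr-1",
             "umol N2O m-2 h-1"),
    prob = rep(c(0.4, 0.3, 0.2, 0.1), 3))
}

#' Generate a synthetic flux table with known category structure
#'
#' Draws canonical-scale values from the spec's per-category truth, then
#' re-expresses each value in a randomly chosen unit dialect through the
#' exact inverse of [convert_flux()], producing a table in the same
#' delimited-text schema as the packaged compilation.  Harmonizing the
#' result with `mode = "footnote"` recovers the canonical values exactly
#' (up to the 12 significant digits retained in the text cells),
#' whatever the dialect mixture.
#'
#' @param spec A [synthetic_flux_spec()].
#' @param seed Integer seed; same seed, same table.
#' @return A flux table tibble ([flux_table_columns()] schema).
#' @examples
#' synth <- generate_flux_table(synthetic_flux_spec(), seed = 1)
#' harmonize_fluxes(synth, mode = "footnote")
#' @export
generate_flux_table <- function(spec = synthetic_flux_spec(), seed = 1) {
  stopifnot(inherits(spec, "synthetic_flux_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  gases <- c(CO2 = "nee", CH4 = "ch4", N2O = "n2o")
  cats <- unique(spec$truth$category)
  n <- spec$n_per_category
  total <- length(cats) * n
  cols <- setNames(
    lapply(flux_table_columns(), function(x) rep(NA_character_, total)),
    flux_table_columns())
  cols$latitude <- rep(NA_real_, total)
  cols$longitude <- rep(NA_real_, total)
  cols$category <- rep(cats, each = n)
  cols$site_name <- sprintf("synthetic_%s_%02d", cols$category,
                            rep(seq_len(n), times = length(cats)))
  cols$record_type <- "site"
  cols$source <- "synthetic"
  truth_key <- paste(spec$truth$category, spec$truth$gas, sep = "\r")
  dial_units <- split(spec$dialects$unit, spec$dialects$gas)
  dial_probs <- split(spec$dialects$prob, spec$dialects$gas)
  # RNG order is per record, then per gas, so tables extend reproducibly
  for (i in seq_len(total)) {
    cat_i <- cols$category[i]
    for (g in names(gases)) {
      k <- match(paste(cat_i, g, sep = "\r"), truth_key)
      if (is.na(k)) next
      value <- draw_flux(1, spec$truth$mean[k], spec$truth$sd[k], spec$noise)
      unit <- sample(dial_units[[g]], 1, prob = dial_probs[[g]])
      raw <- value / .unit_factor_cached(unit, g)
      col <- gases[[g]]
      cols[[col]][i] <- sprintf("%.12g", raw)
      cols[[paste0(col, "_unit")]][i] <- unit
    }
  }
  tibble::as_tibble(cols)
}

# memoized unit factors for the generator's inner loop
.unit_factor_env <- new.env(parent = emptyenv())
.unit_factor_cached <- function(unit, gas) {
  key <- paste(unit, gas, sep = "\r")
  f <- .unit_factor_env[[key]]
  if (is.null(f)) {
    f <- parse_flux_unit(unit, gas)$factor
    .unit_factor_env[[key]] <- f
  }
  f
}

draw_flux <- function(n, mean, sd, noise) {
  if (sd == 0) return(rep(mean, n))
  if (noise == "normal") return(rnorm(n, mean, sd))
  # log-normal magnitude with matched mean/sd, sign taken from the mean
  m <- abs(mean)
  s2 <- log(1 + (sd / m)^2)
  sign(mean) * stats::rlnorm(n, log(m) - s2 / 2, sqrt(s2))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Randomly perturb a scenario's rates and ratios
#'
#' Multiplies every schedule rate, the allometry parameters and the
#' residue decay rate by independent uniform factors in
#' `[1 - amplitude, 1 + amplitude]`.  Structural fields — breakpoint
#' years, harvest cycle, initial stocks — are untouched, so zero rates
#' stay zero and sign structure is preserved.
#'
#' @param spec A [scenario_spec()].
#' @param relative_amplitude Amplitude `a` in `[0, 0.5]`.
#' @param seed Integer seed.
#' @return A perturbed `scenario_spec`.
#' @examples
#' perturb_scenario(peat_scenario("restored_bog"), 0.1, seed = 7)
#' @export
perturb_scenario <- function(spec, relative_amplitude, seed = 1) {
  stopifnot(inherits(spec, "scenario_spec"),
            relative_amplitude >= 0, relative_amplitude <= 0.5)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  a <- relative_amplitude
  jitter1 <- function(x) x * runif(length(x), 1 - a, 1 + a)
  al <- spec$allometry
  cf <- min(jitter1(al$carbon_fraction), 0.999)
  scenario_spec(
    name = spec$name,
    initial_peat_c = spec$initial_peat_c,
    initial_stem_volume = spec$initial_stem_volume,
    increment_schedule = schedule(spec$increment_schedule$year,
                                  jitter1(spec$increment_schedule$rate)),
    peat_flux_schedule = schedule(spec$peat_flux_schedule$year,
                                  jitter1(spec$peat_flux_schedule$rate)),
    harvest_cycle = spec$harvest_cycle,
    residue_decay_rate = jitter1(spec$residue_decay_rate),
    allometry = allometry_params(
      wood_density = jitter1(al$wood_density),
      carbon_fraction = cf,
      branch_ratio = min(jitter1(al$branch_ratio), 0.999),
      coarse_root_ratio = min(jitter1(al$coarse_root_ratio), 0.999)))
}
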