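test_that("GWP specs default to the standard horizon factors", {
  expect_equal(gwp_spec(100)[, c("ch4_factor", "n2o_factor")],
               tibble::tibble(ch4_factor = 25, n2o_factor = 298))
  expect_equal(gwp_spec(500)[, c("ch4_factor", "n2o_factor")],
               tibble::tibble(ch4_factor = 7.6, n2o_factor = 153))
  expect_equal(gwp_spec(100, ch4_factor = 34)$ch4_factor, 34)
  expect_error(gwp_spec(20), "no default")
})

test_that("CO2-equivalent combination matches hand arithmetic", {
  expect_equal(co2_equivalent(0, 0, 0, gwp_spec(100)), 0)
  # -1000*44/12 + 25*100*16/12 + 298*1*44/28
  expect_equal(co2_equivalent(-1000, 100, 1, gwp_spec(100)),
               -1000 * 44 / 12 + 25 * 100 * 16 / 12 + 298 * 44 / 28)
  expect_equal(co2_equivalent(-1000, 100, 1, gwp_spec(100)),
               134.95, tolerance = 1e-4)
  expect_equal(co2_equivalent(-1000, 100, 1, gwp_spec(500)),
               -2412.90, tolerance = 1e-4)
  expect_warning(co2_equivalent(NA, 1, 1, gwp_spec(100)), "treated as 0")
})

test_that("CO2-equivalent is linear and additive across gases", {
  g <- gwp_spec(100)
  set.seed(11)
  for (i in 1:10) {
    x <- runif(3, -1000, 1000); y <- runif(3, -1000, 1000)
    a <- runif(1, -2, 2)
    expect_equal(co2_equivalent(a * x[1], a * x[2], a * x[3], g),
                 a * co2_equivalent(x[1], x[2], x[3], g), tolerance = 1e-9)
    expect_equal(co2_equivalent(x[1] + y[1], x[2] + y[2], x[3] + y[3], g),
                 co2_equivalent(x[1], x[2], x[3], g) +
                   co2_equivalent(y[1], y[2], y[3], g), tolerance = 1e-9)
    expect_equal(co2_equivalent(x[1], x[2], x[3], g),
                 co2_equivalent(x[1], 0, 0, g) +
                   co2_equivalent(0, x[2], 0, g) +
                   co2_equivalent(0, 0, x[3], g), tolerance = 1e-9)
  }
})

test_that("the review rows of the rewetted-forest group average as reported", {
  h <- harmonize_fluxes(read_flux_table())
  stats <- aggregate_by_category(h, category = "rewetted_forest",
                                 record_type = "review")
  nee <- stats$mean[stats$gas == "CO2"]
  ch4 <- stats$mean[stats$gas == "CH4"]
  expect_equal(stats$n[stats$gas == "CO2"], 4)
  expect_equal(nee, mean(c(-1520, -1930, -1220, 960)))
  expect_equal(display_round(nee), -928)
  expect_equal(ch4, mean(c(73, 220, 160, 418)))
  expect_equal(display_round(ch4), 218)
})

test_that("display rounding is half-away-from-zero", {
  expect_equal(display_round(c(-927.5, 217.75, 0.5, -0.5, 2.45)),
               c(-928, 218, 1, -1, 2))
  expect_equal(display_round(2.345, digits = 2), 2.35)
})

test_that("aggregation handles single records and empty selections", {
  one <- make_flux_table(1, n2o = "-0.135", n2o_unit = "kg N ha-1 yr-1")
  s <- aggregate_by_category(harmonize_fluxes(one))
  expect_equal(s$mean, -0.135)
  expect_equal(s$n, 1)
  expect_true(s$mean >= s$min && s$mean <= s$max)
  # empty selection: an explicit no-data result, never zero
  s0 <- aggregate_by_category(harmonize_fluxes(one), gas = "CO2")
  expect_equal(nrow(s0), 0)
})

test_that("balance report covers categories and horizons coherently", {
  h <- harmonize_fluxes(read_flux_table())
  rep <- suppressWarnings(balance_report(h))
  expect_setequal(unique(rep$category), flux_categories())
  expect_setequal(unique(rep$horizon), c(100, 500))
  expect_true(all(is.finite(rep$co2eq)))
  # empty record set -> empty report
  empty <- harmonize_fluxes(make_flux_table(1))
  expect_equal(nrow(balance_report(empty)), 0)
})

test_that("a pure-CH4 source shrinks in CO2-eq on the 500-year horizon", {
  tbl <- make_flux_table(1, ch4 = "100", ch4_unit = "kg C ha-1 yr-1")
  rep <- suppressWarnings(balance_report(harmonize_fluxes(tbl)))
  expect_lt(abs(rep$co2eq[rep$horizon == 500]),
            abs(rep$co2eq[rep$horizon == 100]))
})

test_that("balance from means equals mean of per-record balances", {
  set.seed(3)
  n <- 6
  tbl <- make_flux_table(
    n,
    nee = sprintf("%.8f", runif(n, -2000, 500)),
    ch4 = sprintf("%.8f", runif(n, 0, 400)),
    n2o = sprintf("%.8f", runif(n, -1, 5)),
    nee_unit = "kg C ha-1 yr-1", ch4_unit = "kg C ha-1 yr-1",
    n2o_unit = "kg N ha-1 yr-1")
  h <- harmonize_fluxes(tbl)
  rep <- balance_report(h, gwp = gwp_spec(100))
  wide <- tidyr::pivot_wider(h[, c("row", "gas", "value")],
                             names_from = "gas", values_from = "value")
  per_record <- co2_equivalent(wide$CO2, wide$CH4, wide$N2O, gwp_spec(100))
  expect_equal(rep$co2eq, mean(per_record), tolerance = 1e-9)
})
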