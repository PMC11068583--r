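test_that("unit strings parse into their components", {
  u <- parse_flux_unit("mg CO2–C m−2 h−1", "CO2")  # typographic dashes
  expect_equal(u[, c("basis", "prefix", "area", "time")],
               tibble::tibble(basis = "element", prefix = "mg",
                              area = "m-2", time = "h-1"))
  u <- parse_flux_unit("t CO2-eq ha-1 yr-1", "CO2")
  expect_equal(u$basis, "co2_equivalent")
  expect_equal(u$factor, 1000)
  # a CO2-eq mass may be attached to a CH4 column (whole-row equivalents)
  expect_equal(parse_flux_unit("t CO2-eq ha-1 yr-1", "CH4")$gas, "CH4")
  u <- parse_flux_unit("kg C ha-1 yr-1", "CH4")
  expect_equal(u$factor, 1)
  # the spaced element form used by some chamber studies
  expect_equal(parse_flux_unit("g CO2 C m-2 yr-1", "CO2")$basis, "element")

  expect_error(parse_flux_unit("furlongs per fortnight", "CO2"),
               "furlongs per fortnight")
  expect_error(parse_flux_unit("kg N ha-1 yr-1", "CO2"), "element")
  expect_error(parse_flux_unit("mg CH4 m-2 h-1", "CO2"), "names gas")
})

test_that("conversion reproduces hand-computed factors", {
  # 1 mg m-2 h-1 of element = 1e-6 kg * 1e4 m2/ha * 8760 h/yr
  expect_equal(convert_flux(1, "mg CO2-C m-2 h-1", "CO2")$value, 87.6)
  # molecule basis: 12/44 of CO2 mass is carbon
  expect_equal(convert_flux(1, "t CO2 ha-1 yr-1", "CO2")$value,
               1000 * 12 / 44)
  # 1 umol N2O carries 28 ug N; per m2 per h
  expect_equal(convert_flux(1, "umol N2O m-2 h-1", "N2O")$value,
               2.4528, tolerance = 1e-12)
  expect_equal(convert_flux(0, "g CO2 m-2 d-1", "CO2")$value, 0)
  co2eq <- convert_flux(-1.52, "t CO2-eq ha-1 yr-1", "CO2")
  expect_equal(co2eq$value, -1520)
  expect_true(co2eq$was_co2_equivalent)
  expect_error(convert_flux(Inf, "kg C ha-1 yr-1", "CO2"), "non-finite")
})

test_that("conversion is linear and round-trips through every dialect", {
  catalog <- flux_unit_catalog()
  set.seed(7)
  for (i in seq_len(nrow(catalog))) {
    u <- catalog[i, ]
    x <- runif(1, -5000, 5000)
    a <- runif(1, 0.1, 10)
    v1 <- convert_flux(x, u$text, u$gas)$value
    expect_equal(convert_flux(a * x, u$text, u$gas)$value, a * v1,
                 tolerance = 1e-12)
    # canonical -> source unit -> canonical within 1e-9 relative
    back <- convert_flux(flux_from_canonical(v1, u$text, u$gas),
                         u$text, u$gas)$value
    expect_equal(back, v1, tolerance = 1e-9)
  }
})

test_that("every dialect factor equals the factorized brute-force product", {
  # independent factor tables, written out by hand
  mass_kg <- c(ng = 1e-12, ug = 1e-9, mg = 1e-6, g = 1e-3, kg = 1,
               Mg = 1000, t = 1000)
  mol_mol <- c(nmol = 1e-9, umol = 1e-6, mmol = 1e-3, mol = 1)
  per_area_to_per_ha <- c(`m-2` = 10000, `ha-1` = 1)
  per_time_to_per_yr <- c(`s-1` = 365 * 24 * 3600, `h-1` = 365 * 24,
                          `d-1` = 365, `yr-1` = 1)
  elem_per_molecule <- c(CO2 = 12 / 44, CH4 = 12 / 16, N2O = 28 / 44)
  elem_kg_per_mol <- c(CO2 = 0.012, CH4 = 0.012, N2O = 0.028)

  catalog <- flux_unit_catalog()
  for (i in seq_len(nrow(catalog))) {
    u <- catalog[i, ]
    mass_factor <- switch(u$basis,
      element = mass_kg[[u$prefix]],
      molecule = mass_kg[[u$prefix]] * elem_per_molecule[[u$gas]],
      co2_equivalent = mass_kg[[u$prefix]],
      mol = mol_mol[[u$prefix]] * elem_kg_per_mol[[u$gas]])
    oracle <- mass_factor * per_area_to_per_ha[[u$area]] *
      per_time_to_per_yr[[u$time]]
    expect_equal(u$factor, oracle, tolerance = 1e-12,
                 label = paste("factor for", u$text))
  }
})

test_that("the shipped conversion table matches the parser", {
  shipped <- readr::read_csv(
    system.file("extdata", "unit_conversions.csv", package = "peatghg"),
    show_col_types = FALSE)
  live <- flux_unit_catalog()
  expect_equal(nrow(shipped), nrow(live))
  expect_equal(shipped$factor, live$factor, tolerance = 1e-12)
})
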