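test_that("schedules validate and interpolate like an independent evaluator", {
  expect_error(schedule(c(1, 2), c(0, 0)), "start at year 0")
  expect_error(schedule(c(0, 10, 10), c(1, 2, 3)), "strictly increasing")
  expect_equal(schedule_rate(schedule(0, 0.22), c(0, 7, 300)),
               rep(0.22, 3))

  set.seed(99)
  year <- c(0, 20, 50, 160)
  rate <- c(0, 0, 4, 0.1)
  s <- schedule(year, rate)
  q <- runif(1000, 0, 300)
  expect_equal(schedule_rate(s, q), interp_oracle(year, rate, q),
               tolerance = 1e-12)
})

test_that("stand carbon pools follow the fixed allometric ratios", {
  expect_equal(unlist(biomass_carbon(0)), c(stem_c = 0, branch_c = 0,
                                            root_c = 0))
  b <- biomass_carbon(100)
  expect_equal(b$stem_c, 21)         # 100 m3 * 420 kg/m3 * 0.5 / 1000
  expect_equal(b$branch_c, 2.52)     # 12 % of stem
  expect_equal(b$root_c, 4.4688)     # 19 % of (stem + branch)
  expect_equal(total_biomass_c(400), 111.9552)
  expect_error(biomass_carbon(-1), "negative")
})

test_that("peat depth converts linearly to carbon stock", {
  expect_equal(peat_depth_to_c_stock(2), 686)
  expect_equal(peat_depth_to_c_stock(0), 0)
  expect_equal(peat_depth_to_c_stock(1), 343)
  expect_error(peat_depth_to_c_stock(-0.5), "negative")
})

test_that("a one-year horizon stores years 0 and 1", {
  tr <- simulate_carbon("pristine_open_bog", horizon = 1)
  expect_equal(tr$year, c(0, 1))
  expect_equal(tr$stand_volume[2], tr$stand_volume[1])  # no increment
  expect_equal(tr$peat_c[2] - tr$peat_c[1], 0.22)
})

test_that("a zero-flux, zero-increment, residue-free scenario is a fixed point", {
  still <- scenario_spec("static_stand", initial_stem_volume = 50)
  tr <- simulate_carbon(still, horizon = 40)
  expect_equal(unique(tr$total_c), tr$total_c[1])
  expect_equal(tr$export_c[41], 0)
})

test_that("per-step bookkeeping identity holds in every scenario", {
  for (nm in scenario_names()) {
    spec <- peat_scenario(nm)
    tr <- simulate_carbon(spec)
    horizon <- max(tr$year)
    for (t in seq_len(horizon)) {
      i <- t + 1
      flux <- schedule_rate(spec$peat_flux_schedule, t)
      v_grown <- tr$stand_volume[i - 1] +
        schedule_rate(spec$increment_schedule, tr$stand_age[i - 1] + 1)
      growth <- total_biomass_c(v_grown, spec$allometry) -
        total_biomass_c(tr$stand_volume[i - 1], spec$allometry)
      decay <- tr$residue_c[i - 1] * (1 - exp(-spec$residue_decay_rate))
      delta <- (tr$total_c[i] + tr$export_c[i]) -
        (tr$total_c[i - 1] + tr$export_c[i - 1])
      expect_equal(delta, flux + growth - decay, tolerance = 1e-9,
                   label = paste0(nm, " year ", t, " carbon balance"))
    }
  }
})

test_that("harvest moves stems to export and residues without carbon loss", {
  tr <- simulate_carbon("drained_managed_bog_forest")
  # stand grows 4 m3/yr from zero: 400 m3 at the year-100 clearcut
  b400 <- biomass_carbon(400)
  expect_equal(tr$export_c[101] - tr$export_c[100], b400$stem_c)
  expect_equal(tr$stand_volume[101], 0)
  expect_equal(tr$stand_age[101], 0)
  pre_decay_residue <- tr$residue_c[100] * exp(-0.05)
  expect_equal(tr$residue_c[101] - pre_decay_residue,
               b400$branch_c + b400$root_c, tolerance = 1e-12)
  # no harvest at the horizon itself: year 300 shows the mature stand
  expect_equal(tr$stand_volume[301], 400)
  expect_equal(tr$export_c[301], 2 * b400$stem_c)
})

test_that("trajectories are deterministic and peat declines under drainage", {
  a <- simulate_carbon("drained_managed_bog_forest")
  b <- simulate_carbon("drained_managed_bog_forest")
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_true(all(diff(a$peat_c) < 0))
})

test_that("peat exhaustion halts the run with the failing year", {
  doomed <- scenario_spec("fast_loss", initial_peat_c = 10,
                          peat_flux_schedule = schedule(0, -3))
  expect_error(simulate_carbon(doomed, horizon = 50),
               class = "peatghg_peat_exhausted")
  expect_error(simulate_carbon(doomed, horizon = 50), "year 4")
})

test_that("neutrality year equals a brute-force scan of the stored series", {
  for (nm in c("restored_bog", "drained_managed_bog_forest",
               "regenerated_unmanaged_forest")) {
    tr <- simulate_carbon(nm)
    scan <- NA_integer_
    for (t in 2:nrow(tr)) {
      if (tr$total_c[t] - tr$total_c[t - 1] >= 0) {
        scan <- as.integer(tr$year[t]); break
      }
    }
    expect_identical(neutrality_year(tr), scan, label = nm)
  }
  expect_equal(neutrality_year(simulate_carbon("restored_bog")), 20L)
  expect_equal(neutrality_year(simulate_carbon("pristine_open_bog")), 1L)
  # a scenario that loses carbon every year has no neutrality year
  sink_only <- scenario_spec("always_losing", peat_flux_schedule =
                               schedule(0, -0.5))
  expect_true(is.na(neutrality_year(simulate_carbon(sink_only, 100))))
})

test_that("windowed mean annual change matches its definition", {
  tr <- simulate_carbon("restored_bog")
  expect_equal(mean_annual_change(tr, 20, 300), 0.22, tolerance = 1e-12)
  expect_equal(mean_annual_change(tr, 0, 300),
               (tr$total_c[301] - tr$total_c[1]) / 300)
  still <- simulate_carbon(scenario_spec("static"), horizon = 10)
  expect_equal(mean_annual_change(still, 0, 10), 0)
  expect_error(mean_annual_change(tr, 100, 50), "bad window")
  expect_error(mean_annual_change(tr, 0, 301), "bad window")
})

test_that("scenario YAML files round-trip", {
  spec <- peat_scenario("regenerated_unmanaged_forest")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(spec, path)
  back <- read_scenario(path)
  expect_equal(back[names(back) != "allometry"],
               spec[names(spec) != "allometry"])
  expect_equal(as.data.frame(back$allometry), as.data.frame(spec$allometry))
  expect_identical(as.data.frame(simulate_carbon(back, 50)),
                   as.data.frame(simulate_carbon(spec, 50)))
})

test_that("trajectory tidiers expose pools and diagnostics", {
  tr <- simulate_carbon("restored_bog")
  long <- tidy(tr)
  expect_setequal(unique(long$pool),
                  c("peat_c", "stem_c", "branch_c", "root_c", "residue_c",
                    "export_c"))
  g <- glance(tr)
  expect_equal(g$scenario, "restored_bog")
  expect_equal(g$neutrality_year, 20L)
  p <- autoplot(tr)
  expect_s3_class(p, "ggplot")
})
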