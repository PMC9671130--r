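test_that("equilibrium metrics reproduce the two-parcel hand case", {
  eng <- engine_config()
  p <- parcel_table(
    parcel_id = c("slow", "fast"), watershed_id = "w1",
    year_built = c(2010L, 1950L), raw_load = 10, attenuation = 0,
    travel_time = c(30, 0), sewered = FALSE, buildout_delta = 0
  )
  m <- equilibrium_metrics(run_status_quo(p, eng), eng)
  expect_equal(m$current_load_kg, 10)
  expect_equal(m$max_future_load_kg, 20)
  expect_equal(m$ratio, 2)
  expect_false(m$in_equilibrium)
  expect_identical(m$years_to_equilibrium, 20L)
})

test_that("instant-travel watersheds are in equilibrium", {
  eng <- engine_config()
  p <- tiny_parcels()
  p$travel_time <- 0
  m <- equilibrium_metrics(run_status_quo(p, eng), eng)
  expect_true(all(m$in_equilibrium))
  expect_equal(m$ratio, rep(1, nrow(m)))
  expect_identical(m$years_to_equilibrium, rep(0L, nrow(m)))
})

test_that("equilibrium metrics are invariant to rescaling the series", {
  eng <- engine_config()
  s <- run_status_quo(random_parcels(17, n = 60), eng)
  m1 <- equilibrium_metrics(s, eng)
  s2 <- s
  s2$load_kg <- s2$load_kg * 3.7
  m2 <- equilibrium_metrics(s2, eng)
  expect_equal(m1$ratio, m2$ratio)
  expect_identical(m1$in_equilibrium, m2$in_equilibrium)
  expect_identical(m1$years_to_equilibrium, m2$years_to_equilibrium)
})

test_that("zero current load with future load flags non-equilibrium as infinite", {
  eng <- engine_config()
  p <- parcel_table("late", "w1", 2019, 10, 0, 50, FALSE, 0)
  m <- equilibrium_metrics(run_status_quo(p, eng), eng)
  expect_identical(m$ratio, Inf)
  expect_false(m$in_equilibrium)
})

test_that("status-quo ratios never fall below 1 - epsilon", {
  eng <- engine_config()
  for (seed in 81:85) {
    m <- equilibrium_metrics(run_status_quo(random_parcels(seed, 40), eng),
      eng, epsilon = 0.01)
    expect_true(all(m$ratio[is.finite(m$ratio)] >= 1 - 0.01))
  }
})

test_that("legacy summaries convert units and flag undefined multiples", {
  eng <- engine_config()
  mass <- tibble::tibble(
    watershed_id = c("w1", "w2"),
    legacy_mass_kg = c(50, 0),
    legacy_mass_from_shutoff_kg = c(50, 0)
  )
  sq <- tibble::tibble(
    watershed_id = rep(c("w1", "w2"), each = 271),
    year = rep(1880:2150, 2),
    load_kg = rep(c(10, 0), each = 271)
  )
  ls <- legacy_summary(mass, sq, tiny_watersheds(), eng)
  expect_equal(ls$legacy_mass_tons, c(0.05, 0))
  expect_equal(ls$multiples_of_current, c(5, NA))
  expect_identical(ls$tmdl_status, c("final", "none_or_pending"))
})

test_that("legacy mass is additive over disjoint parcel subsets", {
  eng <- engine_config()
  scenario <- scenario_config("legacy")
  p <- random_parcels(23, n = 60, n_watersheds = 1)
  whole <- run_legacy(p, scenario, eng)$legacy_mass$legacy_mass_kg
  half1 <- run_legacy(p[1:30, ], scenario, eng)$legacy_mass$legacy_mass_kg
  half2 <- run_legacy(p[31:60, ], scenario, eng)$legacy_mass$legacy_mass_kg
  expect_equal(whole, half1 + half2)
})

test_that("watershed summaries use sample sd and mark degenerate cases missing", {
  one <- tiny_parcels()[1, ]
  s <- summarize_watersheds(one)
  expect_identical(s$property_count, 1L)
  expect_equal(s$mean_year_built, 1950)
  expect_true(is.na(s$sd_year_built))

  # identical travel times: sd missing, as in the published table's "-"
  same <- tiny_parcels()
  same$watershed_id <- "w1"
  same$travel_time <- 5
  s <- summarize_watersheds(same)
  expect_true(is.na(s$sd_travel_time_yr))
  expect_equal(s$sd_year_built, sd(same$year_built))

  eng <- engine_config()
  p <- random_parcels(19, n = 50)
  sq <- run_status_quo(p, eng)
  s <- summarize_watersheds(p, sq)
  peak <- tapply(sq$load_kg, sq$watershed_id, max)
  expect_equal(s$annual_max_load_kg, as.numeric(peak[s$watershed_id]))
})

test_that("cagr matches its closed form and inverts total growth", {
  expect_equal(cagr(0, 13), 0)
  expect_equal(cagr(0.121, 20), 1.121^(1 / 20) - 1)
  for (g in c(-0.5, 0.02, 0.5, 2)) {
    expect_equal((1 + cagr(g, 7))^7 - 1, g)
  }
  expect_error(cagr(0.1, 0), "n_years")
  expect_error(cagr(-1.5, 5), "total_growth")
})

test_that("net concentration reduction subtracts and floors at zero", {
  expect_equal(net_concentration_reduction(8, 8), 0)
  expect_equal(net_concentration_reduction(3, 12.5), 0)
  expect_error(net_concentration_reduction(-1, 2), "non-negative")
})

test_that("attenuation chains multiply complements", {
  expect_equal(attenuate_concentration(35, numeric()), 35)
  expect_equal(attenuate_concentration(35, 1), 0)
  expect_equal(attenuate_concentration(50, c(0.3, 0.5)), 17.5)
  expect_error(attenuate_concentration(10, c(0.2, 1.4)), "factors")
})
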