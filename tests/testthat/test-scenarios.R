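test_that("buildout scheduling covers exactly the buildable parcels, reproducibly", {
  p <- tiny_parcels()
  sc <- scenario_config("buildout", seed = 5)
  ev <- schedule_buildout(p, sc)
  expect_identical(ev$parcel_id, "p2")
  expect_true(all(ev$year >= 2020 & ev$year <= 2039))

  none <- p
  none$buildout_delta <- 0
  expect_identical(nrow(schedule_buildout(none, sc)), 0L)

  big <- random_parcels(9, n = 100)
  expect_identical(
    schedule_buildout(big, sc),
    schedule_buildout(big, sc)
  )
})

test_that("buildout update years are uniform over the 20-year window", {
  p <- random_parcels(3, n = 12000)
  p$buildout_delta <- 1 # make every parcel buildable
  ev <- schedule_buildout(p, scenario_config("buildout", seed = 21))
  counts <- table(factor(ev$year, levels = 2020:2039))
  gof <- suppressWarnings(stats::chisq.test(counts))
  expect_gt(gof$p.value, 0.01)
})

test_that("source-control scheduling divides parcels evenly with the remainder first", {
  sc <- scenario_config("source_control", seed = 2)

  p40 <- random_parcels(4, n = 40)
  p40$sewered <- FALSE
  p40$raw_load <- pmax(p40$raw_load, 0.1)
  ev <- schedule_source_control(p40, sc)
  expect_equal(as.vector(table(factor(ev$year, levels = 2020:2039))),
    rep(2L, 20))

  p41 <- random_parcels(4, n = 41)
  p41$sewered <- FALSE
  p41$raw_load <- pmax(p41$raw_load, 0.1)
  ev <- schedule_source_control(p41, sc)
  expect_equal(as.vector(table(factor(ev$year, levels = 2020:2039))),
    c(3L, rep(2L, 19)))

  sewered <- p40
  sewered$sewered <- TRUE
  expect_identical(nrow(schedule_source_control(sewered, sc)), 0L)

  expect_identical(
    schedule_source_control(p41, sc),
    schedule_source_control(p41, sc)
  )
})

test_that("status quo is a step function matching the oracle", {
  eng <- engine_config()
  p <- parcel_table("a", "w1", 1990, 10, 0, 10, FALSE, 0)
  s <- run_status_quo(p, eng)
  expect_true(all(s$load_kg[s$year < 2000] == 0))
  expect_true(all(s$load_kg[s$year >= 2000] == 10))

  p <- random_parcels(8, n = 60)
  expect_equal(
    run_status_quo(p, eng),
    packet_oracle(build_windows(p, NULL, eng), eng,
      sort(unique(p$watershed_id))),
    tolerance = 1e-12
  )
})

test_that("a one-iteration envelope collapses to a single series", {
  p <- random_parcels(12, n = 40)
  mc <- run_monte_carlo(p,
    scenario_config("source_control", n_iterations = 1, seed = 4))
  expect_equal(mc$envelope$load_min_kg, mc$envelope$load_mean_kg)
  expect_equal(mc$envelope$load_mean_kg, mc$envelope$load_max_kg)
})

test_that("scenario ordering holds pointwise across iterations", {
  eng <- engine_config()
  p <- random_parcels(31, n = 120)
  sq <- run_status_quo(p, eng)
  bo <- run_monte_carlo(p,
    scenario_config("buildout", n_iterations = 8, seed = 6), eng)
  sc <- run_monte_carlo(p,
    scenario_config("source_control", n_iterations = 8, seed = 6), eng,
    keep_iterations = TRUE)

  # min over buildout iterations never drops below status quo
  expect_true(all(bo$envelope$load_min_kg >= sq$load_kg - 1e-9))
  # every source-control iteration stays at or below status quo
  per_iter <- dplyr::left_join(sc$iterations, sq,
    by = c("watershed_id", "year"), suffix = c("_it", "_sq"))
  expect_true(all(per_iter$load_kg_it <= per_iter$load_kg_sq + 1e-9))
})

test_that("source-control loading reaches zero once the slowest parcel drains", {
  eng <- engine_config()
  p <- random_parcels(55, n = 50, max_travel = 40)
  p$sewered <- FALSE
  scenario <- scenario_config("source_control", n_iterations = 3, seed = 9)
  mc <- run_monte_carlo(p, scenario, eng)
  drain <- 2039 + max(floor(p$travel_time)) + 1
  late <- mc$envelope[mc$envelope$year > drain, ]
  expect_true(all(late$load_max_kg <= 1e-9))
})

test_that("identical master seeds give identical envelopes, different seeds differ", {
  p <- random_parcels(2, n = 60)
  sc1 <- scenario_config("buildout", n_iterations = 4, seed = 10)
  a <- run_monte_carlo(p, sc1)
  b <- run_monte_carlo(p, sc1)
  expect_identical(a$envelope, b$envelope)
  c <- run_monte_carlo(p,
    scenario_config("buildout", n_iterations = 4, seed = 11))
  expect_false(identical(a$envelope, c$envelope))
})

test_that("single iterations replay in isolation from their sub-seed", {
  p <- random_parcels(14, n = 50)
  scenario <- scenario_config("source_control", n_iterations = 3, seed = 20)
  mc <- run_monte_carlo(p, scenario, keep_iterations = TRUE)
  ev2 <- schedule_source_control(p, scenario, seed = scenario$seed + 2)
  s2 <- delivered_series(build_windows(p, ev2, engine_config()),
    engine_config(), sort(unique(p$watershed_id)))
  got <- mc$iterations[mc$iterations$iteration == 2,
    c("watershed_id", "year", "load_kg")]
  expect_equal(got, s2)
})

test_that("legacy mass is zero when nothing is in transit after the gap", {
  p <- tiny_parcels()
  p$travel_time <- 0
  lg <- run_legacy(p, scenario_config("legacy"), engine_config())
  expect_true(all(lg$legacy_mass$legacy_mass_kg == 0))
})

test_that("legacy mass matches the worked single-parcel count", {
  # inputs 2015-2019 arrive 2025-2029: 5 years x 10 kg
  p <- parcel_table("x", "w1", 1990, 10, 0, 10, FALSE, 0)
  lg <- run_legacy(p, scenario_config("legacy"), engine_config())
  expect_equal(lg$legacy_mass$legacy_mass_kg, 50)
})

test_that("legacy mass never exceeds the total pre-shutoff input", {
  eng <- engine_config()
  scenario <- scenario_config("legacy")
  for (seed in 61:65) {
    p <- random_parcels(seed, n = 80)
    lg <- run_legacy(p, scenario, eng)
    input <- tapply(
      p$raw_load * (1 - p$attenuation) *
        pmax(0, scenario$legacy_shutoff_year -
          pmax(p$year_built, eng$start_year)),
      p$watershed_id, sum
    )
    expect_true(all(lg$legacy_mass$legacy_mass_kg <=
      as.numeric(input[lg$legacy_mass$watershed_id]) + 1e-9))
  }
})
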