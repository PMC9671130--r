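# fixture builders shared across test files

tiny_parcels <- function() {
  parcel_table(
    parcel_id = c("p1", "p2", "p3"),
    watershed_id = c("w1", "w1", "w2"),
    year_built = c(1950L, 2000L, 1990L),
    raw_load = c(10, 20, 5),
    attenuation = c(0, 0.5, 0.2),
    travel_time = c(0, 12, 30),
    sewered = c(TRUE, FALSE, FALSE),
    buildout_delta = c(0, 8, 0)
  )
}

tiny_watersheds <- function() {
  watershed_table(c("w1", "w2"), tmdl_status = c("final", "none_or_pending"))
}

# random parcels for property-style tests; travel times include fractional
# values so the flooring path is exercised
random_parcels <- function(seed, n = 50, n_watersheds = 3,
                           year_range = c(1880, 2020),
                           max_travel = 60) {
  withr::with_seed(seed, {
    parcel_table(
      parcel_id = sprintf("p%04d", seq_len(n)),
      watershed_id = sample(sprintf("w%d", seq_len(n_watersheds)), n,
        replace = TRUE
      ),
      year_built = sample(seq(year_range[1], year_range[2]), n,
        replace = TRUE
      ),
      raw_load = round(stats::rlnorm(n, log(8), 1), 3),
      attenuation = stats::runif(n),
      travel_time = stats::runif(n, 0, max_travel),
      sewered = stats::runif(n) < 0.2,
      buildout_delta = ifelse(stats::runif(n) < 0.12,
        round(stats::rlnorm(n, log(8), 1), 3), 0
      )
    )
  })
}

# random hand-built windows (not via build_windows), for engine-only tests
random_windows <- function(seed, n = 50, config = engine_config(),
                           n_watersheds = 3) {
  withr::with_seed(seed, {
    start <- sample(seq(config$start_year, config$end_year - 10), n,
      replace = TRUE
    )
    len <- sample(0:80, n, replace = TRUE)
    tibble::tibble(
      parcel_id = sprintf("p%04d", seq_len(n)),
      watershed_id = sample(sprintf("w%d", seq_len(n_watersheds)), n,
        replace = TRUE
      ),
      input_start = as.integer(start),
      input_end = as.integer(pmin(start + len, config$end_year)),
      delivered_rate = round(stats::rlnorm(n, log(8), 1), 3),
      travel_time = sample(0:60, n, replace = TRUE)
    )
  })
}

# independent closed-form legacy mass per watershed (per-parcel counting)
legacy_closed_form <- function(parcels, scenario, engine) {
  off <- if (identical(engine$arrival_rule, "strict")) 1L else 0L
  s <- pmax(parcels$year_built, engine$start_year)
  tau <- floor(parcels$travel_time)
  rate <- parcels$raw_load * (1 - parcels$attenuation)
  a <- pmax(s + tau + off, scenario$legacy_tally_start)
  b <- pmin(scenario$legacy_shutoff_year - 1 + tau + off,
    scenario$legacy_tally_end)
  n_years <- pmax(0, b - a + 1)
  out <- tapply(rate * n_years, parcels$watershed_id, sum)
  tibble::tibble(
    watershed_id = names(out),
    legacy_mass_kg = as.numeric(out)
  )
}
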