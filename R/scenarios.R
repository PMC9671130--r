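#' Load events
#'
#' A load event is a dated change to a parcel's groundwater input: a
#' `buildout_update` switches on the parcel's buildout increment, a
#' `source_control_shutoff` removes the parcel's input from the year of the
#' event onward (nitrogen already in groundwater keeps travelling).
#'
#' @param parcel_id Character parcel ids.
#' @param year Integer calendar year of each event.
#' @param kind `"buildout_update"` or `"source_control_shutoff"`.
#' @return A tibble with columns `parcel_id`, `year`, `kind`.
#' @export
load_events <- function(parcel_id = character(), year = integer(),
                        kind = character()) {
  as_load_events(tibble::tibble(
    parcel_id = as.character(parcel_id),
    year = as.integer(year),
    kind = as.character(kind)
  ))
}

as_load_events <- function(events) {
  events <- tibble::as_tibble(events)
  req <- c("parcel_id", "year", "kind")
  missing <- setdiff(req, names(events))
  if (length(missing) > 0) {
    stop("load events are missing columns: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  bad <- setdiff(unique(events$kind),
    c("buildout_update", "source_control_shutoff"))
  if (length(bad) > 0) {
    stop("unknown event kind: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  events[req]
}

#' Scenario configuration
#'
#' Four scenario kinds are supported. `status_quo` simulates existing
#' sources with no changes. `buildout` (upper bound) switches on every
#' parcel's buildout increment at a random year within the scenario window.
#' `source_control` (lower bound) shuts off every contributing unsewered
#' parcel in a random order spread evenly over the window. `legacy` shuts
#' off all input at `legacy_shutoff_year` and tallies what still arrives —
#' the nitrogen already in transit in groundwater.
#'
#' @param kind One of `"status_quo"`, `"buildout"`, `"source_control"`,
#'   `"legacy"`.
#' @param window_start,window_end Calendar window over which buildout or
#'   source-control events are scheduled (defaults 2020-2040, taken as the
#'   20 event years 2020-2039).
#' @param n_iterations Monte Carlo iterations (default 1000).
#' @param seed Master seed; iteration `i` uses sub-seed `seed + i` so single
#'   iterations can be replayed in isolation.
#' @param legacy_shutoff_year Year all input stops in the legacy scenario
#'   (default 2020).
#' @param legacy_tally_start,legacy_tally_end Years over which arriving
#'   legacy nitrogen is tallied (defaults 2025 and 2150).
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(kind = c("status_quo", "buildout",
                              "source_control", "legacy"),
                            window_start = 2020, window_end = 2040,
                            n_iterations = 1000, seed = 1L,
                            legacy_shutoff_year = 2020,
                            legacy_tally_start = 2025,
                            legacy_tally_end = 2150) {
  kind <- match.arg(kind)
  window_start <- check_number(window_start, "window_start",
    integerish = TRUE)
  window_end <- check_number(window_end, "window_end", integerish = TRUE)
  if (window_start > window_end) {
    abort_bad_arg("window_end", "must be >= window_start")
  }
  n_iterations <- check_number(n_iterations, "n_iterations",
    min = 1, integerish = TRUE)
  seed <- check_number(seed, "seed", integerish = TRUE)
  legacy_shutoff_year <- check_number(legacy_shutoff_year,
    "legacy_shutoff_year", integerish = TRUE)
  legacy_tally_start <- check_number(legacy_tally_start,
    "legacy_tally_start", integerish = TRUE)
  legacy_tally_end <- check_number(legacy_tally_end, "legacy_tally_end",
    integerish = TRUE)
  if (legacy_tally_start > legacy_tally_end) {
    abort_bad_arg("legacy_tally_end", "must be >= legacy_tally_start")
  }
  structure(
    list(
      kind = kind,
      window_start = as.integer(window_start),
      window_end = as.integer(window_end),
      n_iterations = as.integer(n_iterations),
      seed = as.integer(seed),
      legacy_shutoff_year = as.integer(legacy_shutoff_year),
      legacy_tally_start = as.integer(legacy_tally_start),
      legacy_tally_end = as.integer(legacy_tally_end)
    ),
    class = "scenario_config"
  )
}

# event years of a scheduling window: [window_start, window_end - 1],
# i.e. 2020..2039 for the default 2020-2040 window
scenario_event_years <- function(scenario) {
  if (scenario$window_end > scenario$window_start) {
    seq.int(scenario$window_start, scenario$window_end - 1L)
  } else {
    scenario$window_start
  }
}

#' Schedule buildout updates
#'
#' Every parcel with a positive buildout increment receives exactly one
#' `buildout_update` event at a year drawn uniformly from the event years
#' of the scenario window. Deterministic given `seed`.
#'
#' @param parcels A [parcel_table()].
#' @param scenario A [scenario_config()] with `kind = "buildout"`.
#' @param seed Seed for this schedule (default the scenario master seed).
#' @return A [load_events()] tibble.
#' @export
schedule_buildout <- function(parcels, scenario, seed = scenario$seed) {
  stopifnot(identical(scenario$kind, "buildout"))
  parcels <- new_parcel_table(parcels)
  ids <- parcels$parcel_id[parcels$buildout_delta > 0]
  if (length(ids) == 0) {
    return(load_events())
  }
  yrs <- scenario_event_years(scenario)
  withr::with_seed(seed, {
    load_events(
      parcel_id = ids,
      year = sample(yrs, length(ids), replace = TRUE),
      kind = "buildout_update"
    )
  })
}

#' Schedule source-control shutoffs
#'
#' All unsewered parcels with a positive raw load are shut off over the
#' scenario window: a uniform random permutation fixes the upgrade order,
#' and parcels are divided evenly across the event years — with `n` parcels
#' and `k` years, the earliest `n mod k` years take `ceiling(n / k)`
#' shutoffs and the rest take `floor(n / k)`. Deterministic given `seed`.
#'
#' @param parcels A [parcel_table()].
#' @param scenario A [scenario_config()] with `kind = "source_control"`.
#' @param seed Seed for this schedule (default the scenario master seed).
#' @return A [load_events()] tibble.
#' @export
schedule_source_control <- function(parcels, scenario,
                                    seed = scenario$seed) {
  stopifnot(identical(scenario$kind, "source_control"))
  parcels <- new_parcel_table(parcels)
  ids <- parcels$parcel_id[!parcels$sewered & parcels$raw_load > 0]
  n <- length(ids)
  if (n == 0) {
    return(load_events())
  }
  yrs <- scenario_event_years(scenario)
  k <- length(yrs)
  base <- n %/% k
  rem <- n %% k
  per_year <- rep.int(base, k) + c(rep.int(1L, rem), rep.int(0L, k - rem))
  withr::with_seed(seed, {
    order <- sample(ids, n)
    load_events(
      parcel_id = order,
      year = rep.int(yrs, per_year),
      kind = "source_control_shutoff"
    )
  })
}

#' Status-quo delivered-load series
#'
#' Simulates existing sources with no buildout and no abatement; the
#' resulting per-watershed series are non-decreasing in time and level off
#' once the slowest parcel's input has arrived.
#'
#' @param parcels A [parcel_table()].
#' @param engine An [engine_config()].
#' @return A tidy series tibble as from [delivered_series()], covering
#'   every watershed present in `parcels`.
#' @export
run_status_quo <- function(parcels, engine = engine_config()) {
  parcels <- new_parcel_table(parcels)
  windows <- build_windows(parcels, NULL, engine)
  delivered_series(windows, engine,
    watershed_ids = sort(unique(parcels$watershed_id)))
}

#' Monte Carlo scenario envelope
#'
#' Runs `n_iterations` random schedules of the requested scenario
#' (`buildout` or `source_control`), simulates each, and aggregates the
#' per-watershed, per-year minimum, mean, and maximum delivered load.
#' Iteration `i` uses sub-seed `seed + i`, so any single iteration can be
#' reproduced with [schedule_buildout()] / [schedule_source_control()].
#'
#' @param parcels A [parcel_table()].
#' @param scenario A [scenario_config()] with `kind` `"buildout"` or
#'   `"source_control"`.
#' @param engine An [engine_config()].
#' @param keep_iterations If `TRUE`, also return every iteration's series.
#' @return A list of class `mc_envelope` with elements `envelope` (tibble:
#'   `watershed_id`, `year`, `load_min_kg`, `load_mean_kg`, `load_max_kg`),
#'   `n_iterations`, `seed`, `kind`, and (optionally) `iterations` (tibble
#'   with an `iteration` column).
#' @export
run_monte_carlo <- function(parcels, scenario, engine = engine_config(),
                            keep_iterations = FALSE) {
  if (!scenario$kind %in% c("buildout", "source_control")) {
    abort_bad_arg("kind", "run_monte_carlo needs a buildout or source_control scenario")
  }
  parcels <- new_parcel_table(parcels)
  ws <- sort(unique(parcels$watershed_id))
  schedule_fun <- switch(scenario$kind,
    buildout = schedule_buildout,
    source_control = schedule_source_control
  )
  mn <- mx <- sm <- NULL
  iters <- if (keep_iterations) vector("list", scenario$n_iterations)
  for (i in seq_len(scenario$n_iterations)) {
    ev <- schedule_fun(parcels, scenario, seed = scenario$seed + i)
    m <- series_matrix(build_windows(parcels, ev, engine), engine, ws)
    if (is.null(mn)) {
      mn <- mx <- sm <- m
    } else {
      mn <- pmin(mn, m)
      mx <- pmax(mx, m)
      sm <- sm + m
    }
    if (keep_iterations) {
      iters[[i]] <- dplyr::mutate(matrix_to_series(m, engine),
        iteration = i, .before = 1)
    }
  }
  years <- engine_years(engine)
  envelope <- tibble::tibble(
    watershed_id = rep(ws, each = length(years)),
    year = rep.int(years, length(ws)),
    load_min_kg = as.vector(mn),
    load_mean_kg = as.vector(sm / scenario$n_iterations),
    load_max_kg = as.vector(mx)
  )
  structure(
    list(
      envelope = envelope,
      n_iterations = scenario$n_iterations,
      seed = scenario$seed,
      kind = scenario$kind,
      iterations = if (keep_iterations) dplyr::bind_rows(iters)
    ),
    class = "mc_envelope"
  )
}

#' Legacy nitrogen scenario
#'
#' Shuts off every parcel's input at `legacy_shutoff_year` and simulates
#' the nitrogen still in transit in groundwater as it continues to arrive.
#' The legacy mass per watershed is the delivered load summed over the
#' tally window; a companion total from the shutoff year to the end of the
#' tally window is also reported.
#'
#' @param parcels A [parcel_table()].
#' @param scenario A [scenario_config()] with `kind = "legacy"`.
#' @param engine An [engine_config()].
#' @return A list of class `legacy_run` with elements `series` (tidy
#'   delivered-load tibble under the shutoff) and `legacy_mass` (tibble:
#'   `watershed_id`, `legacy_mass_kg` over the tally window,
#'   `legacy_mass_from_shutoff_kg` over `[legacy_shutoff_year,
#'   legacy_tally_end]`).
#' @export
run_legacy <- function(parcels, scenario, engine = engine_config()) {
  stopifnot(identical(scenario$kind, "legacy"))
  parcels <- new_parcel_table(parcels)
  if (scenario$legacy_tally_start < engine$start_year ||
    scenario$legacy_tally_end > engine$end_year) {
    abort_bad_arg("legacy_tally_start",
      "tally window must lie within the engine year range")
  }
  contributing <- parcels[parcels$raw_load > 0 &
    pmax(parcels$year_built, engine$start_year) <
      scenario$legacy_shutoff_year, ]
  ws <- sort(unique(parcels$watershed_id))
  ev <- load_events(
    parcel_id = contributing$parcel_id,
    year = rep.int(scenario$legacy_shutoff_year, nrow(contributing)),
    kind = "source_control_shutoff"
  )
  m <- series_matrix(build_windows(contributing, ev, engine), engine, ws)
  years <- engine_years(engine)
  in_tally <- years >= scenario$legacy_tally_start &
    years <= scenario$legacy_tally_end
  from_shutoff <- years >= scenario$legacy_shutoff_year &
    years <= scenario$legacy_tally_end
  legacy_mass <- tibble::tibble(
    watershed_id = ws,
    legacy_mass_kg = unname(colSums(m[in_tally, , drop = FALSE])),
    legacy_mass_from_shutoff_kg =
      unname(colSums(m[from_shutoff, , drop = FALSE]))
  )
  structure(
    list(series = matrix_to_series(m, engine), legacy_mass = legacy_mass),
    class = "legacy_run"
  )
}
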