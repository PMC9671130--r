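#' Equilibrium diagnostics for status-quo loading series
#'
#' A watershed is in loading equilibrium when the annual load arriving at
#' the bay already equals the eventual maximum implied by existing sources
#' — no lagged increase remains in transit. For each watershed the ratio of
#' the maximum future load (over years after `current_year`) to the current
#' load is computed; ratios at or near 1 mean equilibrium. Years to
#' equilibrium is the first year the series reaches `(1 - epsilon)` of its
#' future maximum, counted from `current_year` (0 when already there).
#'
#' If the current load is zero but future load is positive the ratio is
#' `Inf` and the watershed is flagged not in equilibrium; an all-zero
#' series has ratio 1 by convention (nothing in transit).
#'
#' @param series A tidy status-quo series from [run_status_quo()] /
#'   [delivered_series()].
#' @param engine The [engine_config()] used to produce it.
#' @param epsilon Relative tolerance on the ratio (default 0.01: ratios up
#'   to 1.01 count as equilibrium).
#' @return A tibble with one row per watershed: `watershed_id`,
#'   `current_load_kg`, `max_future_load_kg`, `ratio`, `in_equilibrium`,
#'   `years_to_equilibrium`.
#' @export
equilibrium_metrics <- function(series, engine = engine_config(),
                                epsilon = 0.01) {
  epsilon <- check_number(epsilon, "epsilon", min = 0)
  one <- function(d) {
    d <- d[order(d$year), ]
    cur <- d$load_kg[d$year == engine$current_year]
    if (length(cur) != 1L || !is.finite(cur)) {
      stop("series must contain a finite load at the current year",
        call. = FALSE
      )
    }
    future <- d[d$year > engine$current_year, ]
    max_future <- if (nrow(future) == 0) cur else max(future$load_kg)
    if (cur > 0) {
      ratio <- max_future / cur
    } else if (max_future > 0) {
      ratio <- Inf
    } else {
      ratio <- 1
    }
    in_eq <- is.finite(ratio) && ratio <= 1 + epsilon
    if (max_future <= 0) {
      yrs <- 0L
    } else {
      hit <- d$year[d$load_kg >= (1 - epsilon) * max_future]
      yrs <- max(0L, as.integer(min(hit) - engine$current_year))
    }
    tibble::tibble(
      current_load_kg = cur,
      max_future_load_kg = max_future,
      ratio = ratio,
      in_equilibrium = in_eq,
      years_to_equilibrium = yrs
    )
  }
  series |>
    dplyr::group_by(.data$watershed_id) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
}

#' Summarise the legacy-nitrogen scenario per watershed
#'
#' Converts the tally-window legacy mass to metric tons and expresses it as
#' multiples of the current annual load — the number of years of loading at
#' current rates already committed in groundwater. Multiples are `NA` where
#' the current load is zero.
#'
#' @param legacy A `legacy_run` from [run_legacy()] (or its `legacy_mass`
#'   tibble).
#' @param status_quo A status-quo series from [run_status_quo()], used for
#'   the current annual load.
#' @param watersheds Optional [watershed_table()]; supplies `tmdl_status`.
#' @param engine The [engine_config()] shared by both runs.
#' @return A tibble: `watershed_id`, `legacy_mass_tons`,
#'   `multiples_of_current`, `current_load_kg`, `tmdl_status`.
#' @export
legacy_summary <- function(legacy, status_quo, watersheds = NULL,
                           engine = engine_config()) {
  mass <- if (inherits(legacy, "legacy_run")) legacy$legacy_mass else legacy
  current <- status_quo[status_quo$year == engine$current_year,
    c("watershed_id", "load_kg")]
  names(current)[2] <- "current_load_kg"
  out <- dplyr::left_join(mass, current, by = "watershed_id")
  out <- dplyr::mutate(out,
    legacy_mass_tons = .data$legacy_mass_kg / 1000,
    multiples_of_current = dplyr::if_else(
      .data$current_load_kg > 0,
      .data$legacy_mass_kg / .data$current_load_kg,
      NA_real_
    )
  )
  if (!is.null(watersheds)) {
    out <- dplyr::left_join(out,
      watersheds[c("watershed_id", "tmdl_status")],
      by = "watershed_id"
    )
  } else {
    out$tmdl_status <- NA_character_
  }
  out[c("watershed_id", "legacy_mass_tons", "multiples_of_current",
    "current_load_kg", "tmdl_status")]
}

#' Per-watershed summary statistics
#'
#' Property counts, mean and sample standard deviation (n - 1 denominator)
#' of year built and travel time, and the annual maximal load — the maximum
#' of the status-quo delivered series over the full horizon, i.e. the load
#' once the watershed reaches equilibrium. Standard deviations are `NA`
#' when a watershed has fewer than two distinct values.
#'
#' @param parcels A [parcel_table()] (one or more watersheds).
#' @param status_quo Optional status-quo series from [run_status_quo()];
#'   when omitted the load column is `NA`.
#' @return A tibble with one row per watershed: `watershed_id`,
#'   `property_count`, `mean_year_built`, `sd_year_built`,
#'   `mean_travel_time_yr`, `sd_travel_time_yr`, `annual_max_load_kg`.
#' @export
summarize_watersheds <- function(parcels, status_quo = NULL) {
  parcels <- new_parcel_table(parcels)
  sd_or_na <- function(x) {
    if (length(unique(x)) < 2) NA_real_ else stats::sd(x)
  }
  out <- parcels |>
    dplyr::group_by(.data$watershed_id) |>
    dplyr::summarise(
      property_count = dplyr::n(),
      mean_year_built = mean(.data$year_built),
      sd_year_built = sd_or_na(.data$year_built),
      mean_travel_time_yr = mean(.data$travel_time),
      sd_travel_time_yr = sd_or_na(.data$travel_time),
      .groups = "drop"
    )
  if (!is.null(status_quo)) {
    peak <- status_quo |>
      dplyr::group_by(.data$watershed_id) |>
      dplyr::summarise(annual_max_load_kg = max(.data$load_kg),
        .groups = "drop")
    out <- dplyr::left_join(out, peak, by = "watershed_id")
  } else {
    out$annual_max_load_kg <- NA_real_
  }
  out
}

#' Compound annual growth rate
#'
#' The constant annual rate that compounds to a given total growth over
#' `n_years`: `(1 + total_growth)^(1 / n_years) - 1`.
#'
#' @param total_growth Total fractional growth over the period (e.g. 0.025
#'   for 2.5%); must exceed -1.
#' @param n_years Length of the period in years; must be positive.
#' @return The annual rate as a fraction.
#' @examples
#' cagr(0.025, 8) # ~0.0031
#' @export
cagr <- function(total_growth, n_years) {
  if (any(n_years <= 0)) {
    abort_bad_arg("n_years", "must be positive")
  }
  if (any(total_growth <= -1)) {
    abort_bad_arg("total_growth", "must be greater than -1")
  }
  (1 + total_growth)^(1 / n_years) - 1
}

#' Net concentration reduction from source control
#'
#' Connecting a property to sewer replaces its delivered nitrogen
#' concentration (after soil, pond, and wetland attenuation en route to the
#' bay) with the treated-effluent concentration. The net reduction is the
#' difference, floored at zero: in this accounting treatment cannot add
#' net load.
#'
#' @param delivered_concentration mg/L reaching the bay today.
#' @param treated_concentration mg/L of the treated effluent.
#' @return Net reduction in mg/L.
#' @examples
#' net_concentration_reduction(12.5, 3) # 9.5
#' @export
net_concentration_reduction <- function(delivered_concentration,
                                        treated_concentration) {
  if (any(delivered_concentration < 0) || any(treated_concentration < 0)) {
    abort_bad_arg("delivered_concentration",
      "concentrations must be non-negative")
  }
  pmax(delivered_concentration - treated_concentration, 0)
}

#' Apply a chain of attenuation factors to a concentration
#'
#' Multiplies an initial concentration by `(1 - f)` for each removal
#' fraction `f` along the flow path (soil, ponds, wetlands).
#'
#' @param initial mg/L entering groundwater.
#' @param factors Numeric vector of removal fractions, each in `[0, 1]`.
#' @return The concentration after all removals, mg/L.
#' @examples
#' attenuate_concentration(50, c(0.3, 0.5)) # 17.5
#' @export
attenuate_concentration <- function(initial, factors = numeric()) {
  check_number(initial, "initial", min = 0)
  if (length(factors) > 0 &&
    (any(factors < 0) || any(factors > 1) || anyNA(factors))) {
    abort_bad_arg("factors", "each factor must lie in [0, 1]")
  }
  initial * prod(1 - factors)
}
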