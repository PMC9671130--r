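#' Construct a parcel table
#'
#' A parcel table holds one row per nitrogen source (a developed property):
#' its raw load to groundwater, the fraction removed by natural attenuation
#' en route to the bay, the groundwater travel time from the parcel's
#' recharge location to the bay, whether the parcel is sewered, and the
#' additional load it could contribute under a buildout scenario.
#'
#' @param parcel_id Character, unique parcel identifiers.
#' @param watershed_id Character, the contributing watershed of each parcel.
#' @param year_built Integer calendar year the property was built. Years
#'   earlier than a simulation's start year are clamped by the engine, not
#'   rejected here.
#' @param raw_load Non-negative, kg N per year entering groundwater.
#' @param attenuation Fraction in `[0, 1]` removed between the parcel and
#'   the bay (combined soil/pond/wetland removal).
#' @param travel_time Non-negative years for groundwater to carry the
#'   parcel's nitrogen to the bay. Fractional values are legal; the engine
#'   floors them to whole years.
#' @param sewered Logical, whether the parcel is connected to a sewer.
#' @param buildout_delta Non-negative, kg N per year of potential additional
#'   load if the parcel is developed further (0 for non-buildable parcels).
#' @param provenance A short string recording where the table came from
#'   (a file path or a generator seed).
#'
#' @return A tibble of class `parcel_table` with one row per parcel and a
#'   `provenance` attribute.
#' @examples
#' parcel_table(
#'   parcel_id = "p1", watershed_id = "w1", year_built = 1990,
#'   raw_load = 10, attenuation = 0.2, travel_time = 12,
#'   sewered = FALSE, buildout_delta = 0
#' )
#' @export
parcel_table <- function(parcel_id, watershed_id, year_built, raw_load,
                         attenuation, travel_time, sewered, buildout_delta,
                         provenance = "in-memory") {
  tbl <- tibble::tibble(
    parcel_id = as.character(parcel_id),
    watershed_id = as.character(watershed_id),
    year_built = as.integer(year_built),
    raw_load = as.double(raw_load),
    attenuation = as.double(attenuation),
    travel_time = as.double(travel_time),
    sewered = as.logical(sewered),
    buildout_delta = as.double(buildout_delta)
  )
  new_parcel_table(tbl, provenance)
}

new_parcel_table <- function(tbl, provenance = "in-memory") {
  stopifnot(is.data.frame(tbl))
  tbl <- tibble::as_tibble(tbl)
  req <- c(
    "parcel_id", "watershed_id", "year_built", "raw_load",
    "attenuation", "travel_time", "sewered", "buildout_delta"
  )
  missing <- setdiff(req, names(tbl))
  if (length(missing) > 0) {
    stop("parcel table is missing columns: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  out <- tbl[req]
  class(out) <- c("parcel_table", class(tibble::tibble()))
  attr(out, "provenance") <- provenance
  out
}

#' Construct a watershed metadata table
#'
#' @param watershed_id Character, unique watershed identifiers.
#' @param name Display names (defaults to the ids).
#' @param tmdl_status One of `"final"` or `"none_or_pending"` per watershed:
#'   whether a regulatory Total Maximum Daily Load is in place for the
#'   receiving bay.
#' @return A tibble with columns `watershed_id`, `name`, `tmdl_status`.
#' @export
watershed_table <- function(watershed_id, name = watershed_id,
                            tmdl_status = "none_or_pending") {
  watershed_id <- as.character(watershed_id)
  tmdl_status <- as.character(tmdl_status)
  bad <- setdiff(unique(tmdl_status), c("final", "none_or_pending"))
  if (length(bad) > 0) {
    abort_bad_arg("tmdl_status", paste(
      "must be 'final' or 'none_or_pending', got", paste(bad, collapse = ", ")
    ))
  }
  if (anyDuplicated(watershed_id)) {
    abort_bad_arg("watershed_id", "must be unique")
  }
  tibble::tibble(
    watershed_id = watershed_id,
    name = as.character(name),
    tmdl_status = tmdl_status
  )
}

# fixed, versioned on-disk schema: internal name -> CSV column name
parcel_csv_schema <- function(schema_version = "1") {
  if (!identical(schema_version, "1")) {
    stop("unknown parcel CSV schema version: ", schema_version, call. = FALSE)
  }
  c(
    parcel_id = "parcel_id",
    watershed_id = "watershed_id",
    year_built = "year_built",
    raw_load = "raw_load_kg_yr",
    attenuation = "attenuation_fraction",
    travel_time = "travel_time_yr",
    sewered = "sewered",
    buildout_delta = "buildout_delta_kg_yr"
  )
}

#' Read a parcel table from CSV
#'
#' The on-disk schema (version "1") has columns `parcel_id`, `watershed_id`,
#' `year_built`, `raw_load_kg_yr`, `attenuation_fraction`, `travel_time_yr`,
#' `sewered`, `buildout_delta_kg_yr`. The file is validated on read; any
#' violation aborts with a report naming the offending rows.
#'
#' @param path Path to a parcel CSV.
#' @param schema_version On-disk schema version (only `"1"` exists).
#' @param watersheds Optional watershed table; if given, watershed references
#'   are checked too.
#' @return A validated [parcel_table()].
#' @export
read_parcel_table <- function(path, schema_version = "1", watersheds = NULL) {
  if (!file.exists(path)) {
    stop("parcel file not found: ", path, call. = FALSE)
  }
  schema <- parcel_csv_schema(schema_version)
  header <- names(readr::read_csv(path,
    n_max = 0, col_types = readr::cols(.default = readr::col_character()),
    show_col_types = FALSE))
  missing <- setdiff(unname(schema), header)
  if (length(missing) > 0) {
    stop(
      "parcel CSV is missing required columns: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      parcel_id = readr::col_character(),
      watershed_id = readr::col_character(),
      year_built = readr::col_integer(),
      raw_load_kg_yr = readr::col_double(),
      attenuation_fraction = readr::col_double(),
      travel_time_yr = readr::col_double(),
      sewered = readr::col_logical(),
      buildout_delta_kg_yr = readr::col_double()
    ),
    show_col_types = FALSE
  )
  tbl <- raw[unname(schema)]
  names(tbl) <- names(schema)
  tbl <- new_parcel_table(tbl, provenance = path)
  report <- validate_parcels(tbl, watersheds)
  if (nrow(report) > 0) {
    stop(
      "parcel CSV failed validation:\n",
      paste(format_violations(report), collapse = "\n"),
      call. = FALSE
    )
  }
  tbl
}

#' Write a parcel table to CSV
#'
#' Writes the fixed schema produced by [read_parcel_table()]; a written
#' table re-reads to a field-for-field equal table.
#'
#' @param table A [parcel_table()].
#' @param path Output path.
#' @param schema_version On-disk schema version.
#' @return `path`, invisibly.
#' @export
write_parcel_table <- function(table, path, schema_version = "1") {
  table <- new_parcel_table(table)
  schema <- parcel_csv_schema(schema_version)
  out <- table[names(schema)]
  names(out) <- unname(schema)
  readr::write_csv(out, path)
  invisible(path)
}

#' Read / write watershed metadata CSV
#'
#' Columns: `watershed_id`, `name`, `tmdl_status`.
#'
#' @param path CSV path.
#' @return `read_watershed_table()`: a watershed tibble;
#'   `write_watershed_table()`: `path`, invisibly.
#' @export
read_watershed_table <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      watershed_id = readr::col_character(),
      name = readr::col_character(),
      tmdl_status = readr::col_character()
    ),
    show_col_types = FALSE
  )
  watershed_table(raw$watershed_id, raw$name, raw$tmdl_status)
}

#' @rdname read_watershed_table
#' @param watersheds A watershed tibble from [watershed_table()].
#' @export
write_watershed_table <- function(watersheds, path) {
  readr::write_csv(watersheds[c("watershed_id", "name", "tmdl_status")], path)
  invisible(path)
}

#' Validate a parcel table
#'
#' Validation is total: any input yields a report, never an error. The
#' report has one row per violation with the parcel id, the row number,
#' the offending field, and a message; an empty report means the table is
#' valid.
#'
#' @param table A [parcel_table()] (or a data frame with its columns).
#' @param watersheds Optional watershed table; when supplied, every
#'   `watershed_id` in `table` must resolve to one of its rows.
#' @return A tibble with columns `parcel_id`, `row`, `field`, `message`.
#' @export
validate_parcels <- function(table, watersheds = NULL) {
  table <- new_parcel_table(table)
  v <- list()
  add <- function(rows, field, message) {
    if (length(rows) == 0) {
      return()
    }
    v[[length(v) + 1L]] <<- tibble::tibble(
      parcel_id = table$parcel_id[rows],
      row = as.integer(rows),
      field = field,
      message = message
    )
  }

  add(which(duplicated(table$parcel_id)), "parcel_id",
    "duplicate parcel_id")

  bad <- function(x) !is.finite(x)
  add(which(bad(table$raw_load) | table$raw_load < 0), "raw_load",
    "raw_load must be a finite number >= 0")
  add(which(bad(table$buildout_delta) | table$buildout_delta < 0),
    "buildout_delta", "buildout_delta must be a finite number >= 0")
  add(which(bad(table$attenuation) | table$attenuation < 0 |
    table$attenuation > 1), "attenuation",
    "attenuation must lie in [0, 1]")
  add(which(bad(table$travel_time) | table$travel_time < 0), "travel_time",
    "travel_time must be a finite number >= 0")
  add(which(is.na(table$year_built)), "year_built",
    "year_built must not be missing")
  add(which(is.na(table$sewered)), "sewered", "sewered must not be missing")
  add(which(is.na(table$parcel_id) | table$parcel_id == ""), "parcel_id",
    "parcel_id must be non-empty")
  add(which(is.na(table$watershed_id) | table$watershed_id == ""),
    "watershed_id", "watershed_id must be non-empty")

  if (!is.null(watersheds)) {
    dangling <- which(!(table$watershed_id %in% watersheds$watershed_id))
    add(dangling, "watershed_id",
      "watershed_id does not resolve to a known watershed")
  }

  if (length(v) == 0) {
    tibble::tibble(
      parcel_id = character(), row = integer(),
      field = character(), message = character()
    )
  } else {
    dplyr::bind_rows(v)
  }
}

format_violations <- function(report) {
  sprintf(
    "row %d (parcel %s): %s [%s]",
    report$row, report$parcel_id, report$message, report$field
  )
}

#' Packaged 54-embayment summary fixture
#'
#' A machine-readable copy of the study region's published per-embayment
#' summary: property counts, mean and standard deviation of year built and
#' groundwater travel time, and the annual maximal (equilibrium) nitrogen
#' load. Standard-deviation cells published as "-" (fewer than two distinct
#' values) are `NA`.
#'
#' @return A 54-row tibble with columns `embayment`, `property_count`,
#'   `mean_year_built`, `sd_year_built`, `mean_travel_time_yr`,
#'   `sd_travel_time_yr`, `annual_max_load_kg`.
#' @export
embayment_summary_fixture <- function() {
  path <- system.file("extdata", "embayment_summary_54.csv",
    package = "nitrolag", mustWork = TRUE
  )
  readr::read_csv(
    path,
    col_types = readr::cols(
      embayment = readr::col_character(),
      property_count = readr::col_integer(),
      mean_year_built = readr::col_double(),
      sd_year_built = readr::col_double(),
      mean_travel_time_yr = readr::col_double(),
      sd_travel_time_yr = readr::col_double(),
      annual_max_load_kg = readr::col_double()
    ),
    show_col_types = FALSE
  )
}
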