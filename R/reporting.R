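#' Run scenarios end-to-end and write tidy outputs
#'
#' High-level driver: validates the inputs, runs the requested scenarios,
#' and writes tidy CSVs plus a JSON run manifest to `output_dir`. Outputs:
#' `series_status_quo.csv` (scenario, watershed_id, year, load_kg),
#' `envelope_<kind>.csv` for Monte Carlo scenarios (watershed_id, year,
#' load_min_kg, load_mean_kg, load_max_kg), `series_legacy.csv` and
#' `legacy_mass.csv` for the legacy scenario, `metrics.csv` (equilibrium
#' diagnostics joined with watershed summaries and, when run, legacy
#' summaries), and `manifest.json`. Files are written to a temporary name
#' and renamed, so a failed run leaves no partial outputs.
#'
#' @param parcels A [parcel_table()].
#' @param watersheds A [watershed_table()].
#' @param output_dir Directory to create/fill.
#' @param scenarios Character subset of
#'   `c("status_quo", "buildout", "source_control", "legacy")`.
#' @param engine An [engine_config()].
#' @param n_iterations Monte Carlo iterations for the bound scenarios.
#' @param seed Master seed for all scheduling randomness.
#' @param epsilon Equilibrium tolerance passed to [equilibrium_metrics()].
#' @return Invisibly, a list with the in-memory results (`status_quo`,
#'   `metrics`, optional `buildout`, `source_control`, `legacy`,
#'   `legacy_summary`) and the `manifest`.
#' @export
simulate_region <- function(parcels, watersheds, output_dir,
                            scenarios = c("status_quo", "buildout",
                              "source_control", "legacy"),
                            engine = engine_config(),
                            n_iterations = 1000, seed = 1L,
                            epsilon = 0.01) {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  parcels <- new_parcel_table(parcels)
  report <- validate_parcels(parcels, watersheds)
  if (nrow(report) > 0) {
    stop(
      "input parcels failed validation:\n",
      paste(format_violations(report), collapse = "\n"),
      call. = FALSE
    )
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  written <- character()
  emit <- function(df, file) {
    final <- file.path(output_dir, file)
    tmp <- paste0(final, ".tmp")
    readr::write_csv(df, tmp)
    file.rename(tmp, final)
    written <<- c(written, final)
    final
  }

  results <- list()

  status_quo <- run_status_quo(parcels, engine)
  results$status_quo <- status_quo
  if ("status_quo" %in% scenarios) {
    emit(dplyr::mutate(status_quo, scenario = "status_quo", .before = 1),
      "series_status_quo.csv")
  }

  metrics <- equilibrium_metrics(status_quo, engine, epsilon)
  metrics <- dplyr::left_join(metrics,
    summarize_watersheds(parcels, status_quo),
    by = "watershed_id"
  )

  for (kind in intersect(scenarios, c("buildout", "source_control"))) {
    sc <- scenario_config(kind, n_iterations = n_iterations, seed = seed)
    mc <- run_monte_carlo(parcels, sc, engine)
    results[[kind]] <- mc
    emit(mc$envelope, paste0("envelope_", kind, ".csv"))
  }

  if ("legacy" %in% scenarios) {
    sc <- scenario_config("legacy", seed = seed)
    lg <- run_legacy(parcels, sc, engine)
    results$legacy <- lg
    emit(dplyr::mutate(lg$series, scenario = "legacy", .before = 1),
      "series_legacy.csv")
    emit(lg$legacy_mass, "legacy_mass.csv")
    ls <- legacy_summary(lg, status_quo, watersheds, engine)
    results$legacy_summary <- ls
    metrics <- dplyr::left_join(metrics,
      ls[c("watershed_id", "legacy_mass_tons", "multiples_of_current",
        "tmdl_status")],
      by = "watershed_id"
    )
  }

  results$metrics <- metrics
  emit(metrics, "metrics.csv")

  manifest <- list(
    command = "simulate_region",
    package_version = as.character(utils::packageVersion("nitrolag")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    n_iterations = n_iterations,
    epsilon = epsilon,
    scenarios = scenarios,
    engine = unclass(engine),
    parcel_provenance = attr(parcels, "provenance") %||% "unknown",
    n_parcels = nrow(parcels),
    n_watersheds = length(unique(parcels$watershed_id)),
    outputs = basename(written)
  )
  manifest_path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path,
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest

  invisible(results)
}

#' Plot a watershed's delivered-load series
#'
#' Time series of annual delivered load with a dashed marker at the
#' current year; Monte Carlo envelopes (upper-bound buildout, lower-bound
#' source control) are drawn as ribbons and the legacy series as a dotted
#' line when supplied.
#'
#' @param status_quo Status-quo series tibble (one watershed, or supply
#'   `watershed_id` to pick one).
#' @param watershed_id Watershed to plot (default: the first present).
#' @param buildout,source_control Optional `mc_envelope` objects.
#' @param legacy Optional `legacy_run`.
#' @param engine The [engine_config()] used.
#' @return A ggplot object.
#' @export
plot_loading_series <- function(status_quo, watershed_id = NULL,
                                buildout = NULL, source_control = NULL,
                                legacy = NULL, engine = engine_config()) {
  if (is.null(watershed_id)) {
    watershed_id <- status_quo$watershed_id[1]
  }
  pick <- function(df) df[df$watershed_id == watershed_id, ]
  p <- ggplot2::ggplot(pick(status_quo),
    ggplot2::aes(x = .data$year, y = .data$load_kg)) +
    ggplot2::geom_vline(xintercept = engine$current_year,
      linetype = "dashed", colour = "grey40")
  band <- function(p, env, fill) {
    p + ggplot2::geom_ribbon(
      data = pick(env$envelope),
      ggplot2::aes(x = .data$year, ymin = .data$load_min_kg,
        ymax = .data$load_max_kg),
      inherit.aes = FALSE, fill = fill, alpha = 0.35
    )
  }
  if (!is.null(buildout)) p <- band(p, buildout, "firebrick")
  if (!is.null(source_control)) p <- band(p, source_control, "grey50")
  if (!is.null(legacy)) {
    p <- p + ggplot2::geom_line(
      data = pick(legacy$series),
      ggplot2::aes(x = .data$year, y = .data$load_kg),
      inherit.aes = FALSE, linetype = "dotted"
    )
  }
  p +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(
      title = watershed_id,
      x = "Year", y = "Delivered N load (kg/yr)"
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of equilibrium ratios
#'
#' Watersheds ordered by the ratio of maximum future load to current load,
#' descending; the horizontal line at 1 marks equilibrium.
#'
#' @param metrics Output of [equilibrium_metrics()].
#' @return A ggplot object.
#' @export
plot_equilibrium_ratio <- function(metrics) {
  finite <- metrics[is.finite(metrics$ratio), ]
  finite$watershed_id <- stats::reorder(finite$watershed_id, -finite$ratio)
  ggplot2::ggplot(finite,
    ggplot2::aes(x = .data$watershed_id, y = .data$ratio)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Max future load / current load") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
      vjust = 0.5, hjust = 1))
}

#' Bar charts of legacy nitrogen per watershed
#'
#' Legacy mass either in absolute metric tons or in multiples of the
#' current annual load, coloured by TMDL status when available.
#'
#' @param legacy_summary Output of [legacy_summary()].
#' @param units `"tons"` or `"multiples"`.
#' @return A ggplot object.
#' @export
plot_legacy_mass <- function(legacy_summary, units = c("tons", "multiples")) {
  units <- match.arg(units)
  ycol <- if (units == "tons") "legacy_mass_tons" else "multiples_of_current"
  ylab <- if (units == "tons") {
    "Legacy N in groundwater (metric tons)"
  } else {
    "Legacy N (years of current annual load)"
  }
  d <- legacy_summary[!is.na(legacy_summary[[ycol]]), ]
  d$watershed_id <- stats::reorder(d$watershed_id, -d[[ycol]])
  has_tmdl <- !all(is.na(d$tmdl_status))
  aes <- if (has_tmdl) {
    ggplot2::aes(x = .data$watershed_id, y = .data[[ycol]],
      fill = .data$tmdl_status)
  } else {
    ggplot2::aes(x = .data$watershed_id, y = .data[[ycol]])
  }
  p <- ggplot2::ggplot(d, aes) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = ylab, fill = "TMDL") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
      vjust = 0.5, hjust = 1))
  if (has_tmdl) {
    p <- p + ggplot2::scale_fill_manual(
      values = c(final = "firebrick", none_or_pending = "seagreen")
    )
  }
  p
}

#' Write the per-watershed summary table
#'
#' One row per watershed in the column order of the packaged 54-embayment
#' fixture: count, mean/sd year built, mean/sd travel time, annual maximal
#' load.
#'
#' @param parcels A [parcel_table()].
#' @param path Output CSV path.
#' @param engine An [engine_config()]; a status-quo run supplies the
#'   annual maximal load column.
#' @return `path`, invisibly.
#' @export
write_watershed_summary <- function(parcels, path,
                                    engine = engine_config()) {
  parcels <- new_parcel_table(parcels)
  status_quo <- run_status_quo(parcels, engine)
  out <- summarize_watersheds(parcels, status_quo)
  readr::write_csv(out, path)
  invisible(path)
}
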