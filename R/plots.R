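#' Plot daily water-level series
#'
#' One line per field with the soil surface at 0 cm; censored (below-tube)
#' days are marked. Useful for eyeballing archetypes and ingested data.
#'
#' @param water Water-series tibble.
#' @param fields Optional character vector of field ids to show (default:
#'   up to 12 fields).
#' @return A ggplot object.
#' @export
plot_water_series <- function(water, fields = NULL) {
  if (is.null(fields)) fields <- head(unique(water$field_id), 12)
  df <- water[water$field_id %in% fields, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$date, y = .data$level_cm)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(
      data = df[df$censored, ], colour = "firebrick", size = 0.6
    ) +
    ggplot2::facet_wrap(~field_id) +
    ggplot2::labs(x = NULL, y = "water level (cm)",
                  title = "Daily field water levels",
                  subtitle = "0 = soil surface; red points censored at tube depth") +
    ggplot2::theme_minimal()
}

#' Plot cluster centroid profiles
#'
#' Heatmap of centroid descriptor values (standardized scale) with clusters
#' ordered driest (1) to wettest (k).
#'
#' @param object A `paddy_clusters` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.paddy_clusters <- function(object, ...) {
  cent <- tibble::as_tibble(object$centroids) |>
    dplyr::mutate(cluster = factor(seq_len(object$k)), .before = 1) |>
    tidyr::pivot_longer(-"cluster", names_to = "descriptor",
                        values_to = "z")
  cent$descriptor <- factor(cent$descriptor, levels = DESCRIPTOR_NAMES)
  ggplot2::ggplot(cent, ggplot2::aes(x = .data$descriptor, y = .data$cluster,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "steelblue") +
    ggplot2::labs(x = "hydrologic descriptor", y = "cluster (driest to wettest)",
                  fill = "z-score",
                  title = "Cluster centroid descriptor profiles") +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity grid
#'
#' Emission change relative to the baseline cell (N multiplier 1, residue 0)
#' across the N-rate x residue grid, faceted by cluster.
#'
#' @param object A `paddy_sensitivity` tibble from [run_sensitivity_grid()].
#' @param gas `"ch4"` (default), `"n2o"` or `"gwp"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.paddy_sensitivity <- function(object, gas = c("ch4", "n2o", "gwp"),
                                       ...) {
  gas <- match.arg(gas)
  col <- switch(gas, ch4 = "delta_ch4_kg_ha", n2o = "delta_n2o_g_ha",
                gwp = "delta_gwp_mt_co2eq_ha")
  lab <- switch(gas, ch4 = "Δ CH4 (kg/ha)", n2o = "Δ N2O (g/ha)",
                gwp = "Δ GWP (mt CO2-eq/ha)")
  ggplot2::ggplot(object, ggplot2::aes(
    x = factor(.data$n_multiplier), y = factor(.data$residue_fraction),
    fill = .data[[col]]
  )) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~cluster, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "N-rate multiplier", y = "residue fraction",
                  fill = lab,
                  title = "Emission response on cluster medoid fields") +
    ggplot2::theme_minimal()
}

#' Histogram of seasonal emissions by season
#'
#' @param emissions Emissions tibble.
#' @param gas `"ch4"` (default) or `"n2o"`.
#' @return A ggplot object.
#' @export
plot_emission_histogram <- function(emissions, gas = c("ch4", "n2o")) {
  gas <- match.arg(gas)
  col <- if (gas == "ch4") "ch4_kg_ha" else "n2o_g_ha"
  lab <- if (gas == "ch4") "seasonal CH4 (kg/ha)" else "seasonal N2O (g/ha)"
  ggplot2::ggplot(emissions, ggplot2::aes(x = .data[[col]])) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~season_year, ncol = 1) +
    ggplot2::geom_vline(
      data = emissions |>
        dplyr::group_by(.data$season_year) |>
        dplyr::summarise(m = mean(.data[[col]])),
      ggplot2::aes(xintercept = .data$m), colour = "red", linetype = 2
    ) +
    ggplot2::labs(x = lab, y = "fields") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
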