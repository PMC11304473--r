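#' AR6 GWP100 conversion factors
#'
#' Default 100-year global warming potentials from IPCC AR6: 27 kg CO2-eq per
#' kg CH4 and 273 kg CO2-eq per kg N2O. Override only deliberately (e.g. to
#' use an earlier assessment report).
#'
#' @param ch4 kg CO2-eq per kg CH4.
#' @param n2o kg CO2-eq per kg N2O.
#' @return A `gwp_factors` list with a provenance label (`"AR6"` for the
#'   defaults, `"custom"` otherwise).
#' @export
gwp_factors <- function(ch4 = 27, n2o = 273) {
  stopifnot(ch4 > 0, n2o > 0)
  structure(
    list(ch4 = ch4, n2o = n2o,
         provenance = if (ch4 == 27 && n2o == 273) "AR6" else "custom"),
    class = "gwp_factors"
  )
}

#' Seasonal total of a daily flux record
#'
#' Inclusive sum of daily fluxes over the sowing-to-harvest window.
#'
#' @param daily A data frame with columns `date` and `flux`.
#' @param sowing,harvest Window bounds (dates, inclusive).
#' @return The seasonal total.
#' @export
seasonal_sum <- function(daily, sowing, harvest) {
  sowing <- as.Date(sowing)
  harvest <- as.Date(harvest)
  if (harvest < sowing) abort("harvest precedes sowing")
  if (sowing < min(daily$date) || harvest > max(daily$date)) {
    abort("season window exceeds the daily flux record")
  }
  sum(daily$flux[daily$date >= sowing & daily$date <= harvest])
}

#' Convert seasonal CH4 and N2O fluxes to CO2-equivalents
#'
#' `GWP (mt CO2-eq ha^-1) = (CH4_kg * 27 + N2O_g / 1000 * 273) / 1000` with
#' the default AR6 factors; factors apply to the mass of each gas as emitted.
#'
#' @param ch4_kg_ha Seasonal CH4, kg ha^-1 (>= 0).
#' @param n2o_g_ha Seasonal N2O, g ha^-1 (>= 0).
#' @param factors A [gwp_factors()] object.
#' @return GWP in metric tons CO2-eq ha^-1.
#' @examples
#' gwp_co2eq(1, 0)      # 0.027 mt = 27 kg CO2-eq
#' gwp_co2eq(0, 1000)   # 0.273 mt = 273 kg CO2-eq
#' @export
gwp_co2eq <- function(ch4_kg_ha, n2o_g_ha, factors = gwp_factors()) {
  stopifnot(inherits(factors, "gwp_factors"))
  if (any(ch4_kg_ha < 0) || any(n2o_g_ha < 0)) {
    abort("fluxes must be nonnegative")
  }
  (ch4_kg_ha * factors$ch4 + (n2o_g_ha / 1000) * factors$n2o) / 1000
}

#' Per-cluster and overall landscape emission summary
#'
#' Mean, minimum and maximum of each gas and of GWP per cluster (when cluster
#' assignments are supplied) plus an overall row, together with the CH4 share
#' of total CO2-eq emissions.
#'
#' @param emissions Emissions tibble (`field_id`, `ch4_kg_ha`, `n2o_g_ha`,
#'   `gwp_mt_co2eq_ha`).
#' @param assignments Optional tibble `field_id`, `cluster`.
#' @return A tibble with one row per cluster plus an `"all"` row; columns
#'   `cluster`, `n`, mean/min/max for `ch4_kg_ha`, `n2o_g_ha`,
#'   `gwp_mt_co2eq_ha`, and `ch4_share_pct` (share of total CO2-eq due to
#'   CH4).
#' @export
landscape_summary <- function(emissions, assignments = NULL) {
  f <- gwp_factors()
  em <- tibble::as_tibble(emissions)
  if (!is.null(assignments)) {
    em <- dplyr::inner_join(em, assignments[, c("field_id", "cluster")],
                            by = "field_id")
    missing <- setdiff(assignments$cluster, em$cluster)
    if (length(missing)) {
      warn(paste0("empty cluster(s) omitted: ", paste(missing, collapse = ", ")))
    }
  } else {
    em$cluster <- "all"
  }
  summarize_group <- function(df, label) {
    tibble::tibble(
      cluster = as.character(label),
      n = nrow(df),
      ch4_mean = mean(df$ch4_kg_ha), ch4_min = min(df$ch4_kg_ha),
      ch4_max = max(df$ch4_kg_ha),
      n2o_mean = mean(df$n2o_g_ha), n2o_min = min(df$n2o_g_ha),
      n2o_max = max(df$n2o_g_ha),
      gwp_mean = mean(df$gwp_mt_co2eq_ha), gwp_min = min(df$gwp_mt_co2eq_ha),
      gwp_max = max(df$gwp_mt_co2eq_ha),
      ch4_share_pct = 100 * sum(df$ch4_kg_ha * f$ch4 / 1000) /
        sum(df$gwp_mt_co2eq_ha)
    )
  }
  per_cluster <- em |>
    dplyr::group_by(.data$cluster) |>
    dplyr::group_map(~ summarize_group(.x, .y$cluster)) |>
    dplyr::bind_rows()
  if (!is.null(assignments)) {
    per_cluster <- dplyr::bind_rows(per_cluster, summarize_group(em, "all"))
  }
  per_cluster
}
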