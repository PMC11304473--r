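#' Find the representative (medoid) field of each cluster
#'
#' The medoid is the cluster member closest (Euclidean, standardized
#' descriptor space) to the cluster centroid; distance ties break to the
#' lexicographically smallest field id.
#'
#' @param model A `paddy_clusters` object.
#' @param xz The standardized descriptor matrix the model was fitted on.
#' @return Tibble `cluster`, `field_id`.
#' @export
find_medoids <- function(model, xz) {
  stopifnot(inherits(model, "paddy_clusters"))
  purrr::map_dfr(seq_len(model$k), function(kk) {
    members <- model$assignments$field_id[model$assignments$cluster == kk]
    sub <- xz[members, , drop = FALSE]
    d <- sqrt(rowSums(sweep(sub, 2, model$centroids[kk, ])^2))
    cands <- sort(members[d <= min(d) + 1e-12])
    tibble::tibble(cluster = kk, field_id = cands[1])
  })
}

#' Define an N-rate x residue-retention scenario grid
#'
#' Defaults replicate the published design: N multipliers from the baseline
#' rate in +25 % steps up to +100 % (1, 1.25, 1.5, 1.75, 2), and residue
#' retention from 0 to 100 % in 25 % steps.
#'
#' @param n_multipliers Multipliers (>= 1) of the baseline N rate; must
#'   include 1.
#' @param residue_fractions Residue fractions in \[0, 1\]; must include 0.
#' @param noise Logical; run the surrogate with lognormal noise.
#' @param replicates Replicates per grid cell when `noise = TRUE`
#'   (default 30).
#' @return A `scenario_grid` list.
#' @export
scenario_grid <- function(n_multipliers = c(1, 1.25, 1.5, 1.75, 2),
                          residue_fractions = c(0, 0.25, 0.5, 0.75, 1),
                          noise = FALSE, replicates = 30) {
  if (any(n_multipliers < 1) || !1 %in% n_multipliers) {
    abort("n_multipliers must be >= 1 and include 1")
  }
  if (any(residue_fractions < 0 | residue_fractions > 1) ||
      !0 %in% residue_fractions) {
    abort("residue_fractions must lie in [0, 1] and include 0")
  }
  structure(
    list(n_multipliers = sort(unique(n_multipliers)),
         residue_fractions = sort(unique(residue_fractions)),
         noise = noise, replicates = as.integer(replicates)),
    class = "scenario_grid"
  )
}

#' Run the sensitivity grid on cluster medoid fields
#'
#' For each medoid field, evaluates the surrogate emission model over every
#' N-multiplier x residue-fraction cell. All split N doses scale
#' proportionally with the multiplier. With noise on, each cell is the mean
#' (and sd) of `replicates` lognormal draws; with noise off, cells are
#' deterministic. Deltas are taken against the baseline cell (multiplier 1,
#' residue 0) of the same field.
#'
#' @param water Water-series tibble covering the medoid fields.
#' @param soils Soils tibble covering the medoid fields.
#' @param medoids Tibble `cluster`, `field_id` (see [find_medoids()]).
#' @param mgmt Baseline management list (`sowing_date`, `n_schedule`,
#'   `residue_fraction` ignored - the grid supplies it).
#' @param grid A [scenario_grid()].
#' @param params Surrogate parameters.
#' @param seed Integer RNG seed (noise draws).
#' @return A `paddy_sensitivity` tibble: `cluster`, `field_id`,
#'   `n_multiplier`, `n_rate_kg_ha`, `residue_fraction`, `ch4_kg_ha`,
#'   `ch4_sd`, `n2o_g_ha`, `n2o_sd`, `gwp_mt_co2eq_ha`, `delta_ch4_kg_ha`,
#'   `delta_n2o_g_ha`, `delta_gwp_mt_co2eq_ha`.
#' @export
run_sensitivity_grid <- function(water, soils, medoids, mgmt,
                                 grid = scenario_grid(),
                                 params = surrogate_params(), seed = 1L) {
  stopifnot(inherits(grid, "scenario_grid"))
  missing <- setdiff(medoids$field_id, unique(water$field_id))
  if (length(missing)) {
    abort(paste0("no water series for medoid field(s): ",
                 paste(missing, collapse = ", ")))
  }
  w <- water[water$field_id %in% medoids$field_id, ]
  s <- soils[soils$field_id %in% medoids$field_id, ]
  mgmt$residue_fraction <- 0
  comp <- surrogate_components(w, s, mgmt, params)
  comp <- comp[match(medoids$field_id, comp$field_id), ]
  base_rate <- total_n(mgmt$n_schedule)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  cells <- tidyr::expand_grid(
    medoids,
    n_multiplier = grid$n_multipliers,
    residue_fraction = grid$residue_fractions
  )
  out <- purrr::pmap_dfr(cells, function(cluster, field_id, n_multiplier,
                                         residue_fraction) {
    cf <- comp[comp$field_id == field_id, ]
    if (grid$noise) {
      e1 <- rnorm(grid$replicates, 0, params$ch4_noise_sd_log)
      e2 <- rnorm(grid$replicates, 0, params$n2o_noise_sd_log)
    } else {
      e1 <- e2 <- 0
    }
    ch4 <- surrogate_ch4(cf, residue_fraction, params, e1)
    n2o <- surrogate_n2o(cf, n_multiplier, params, e2)
    tibble::tibble(
      cluster = cluster, field_id = field_id,
      n_multiplier = n_multiplier,
      n_rate_kg_ha = n_multiplier * base_rate,
      residue_fraction = residue_fraction,
      ch4_kg_ha = mean(ch4), ch4_sd = if (grid$noise) sd(ch4) else 0,
      n2o_g_ha = mean(n2o), n2o_sd = if (grid$noise) sd(n2o) else 0,
      gwp_mt_co2eq_ha = gwp_co2eq(mean(ch4), mean(n2o))
    )
  })
  base <- out |>
    dplyr::filter(.data$n_multiplier == 1, .data$residue_fraction == 0) |>
    dplyr::select("field_id", base_ch4 = "ch4_kg_ha", base_n2o = "n2o_g_ha",
                  base_gwp = "gwp_mt_co2eq_ha")
  out <- out |>
    dplyr::left_join(base, by = "field_id") |>
    dplyr::mutate(
      delta_ch4_kg_ha = .data$ch4_kg_ha - .data$base_ch4,
      delta_n2o_g_ha = .data$n2o_g_ha - .data$base_n2o,
      delta_gwp_mt_co2eq_ha = .data$gwp_mt_co2eq_ha - .data$base_gwp
    ) |>
    dplyr::select(-"base_ch4", -"base_n2o", -"base_gwp")
  class(out) <- c("paddy_sensitivity", class(out))
  out
}
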