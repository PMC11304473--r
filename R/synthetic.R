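#' Generate daily water-level series from a hydrologic archetype
#'
#' Simulates `n_fields` independent fields: daily level = seasonal template
#' (linear interpolation between nodes) + stationary AR(1) noise + irrigation
#' pulses. Pulse count is Poisson with the archetype's weekly rate scaled to
#' the season length; each pulse adds `irrigation_pulse_cm` of ponding that
#' recedes linearly at `recession_cm_per_day`. Levels are clamped to
#' \[-15, +25\] cm, with days below the tube depth flagged `censored`.
#' Deterministic for a fixed `seed`.
#'
#' @param archetype An [archetype_spec()].
#' @param n_fields Number of fields (>= 1).
#' @param season_start,season_end Season window (>= 60 days).
#' @param seed Integer RNG seed.
#' @param field_prefix Prefix for generated field ids.
#' @return A water-series tibble (`field_id`, `date`, `level_cm`, `censored`,
#'   `observed`).
#' @export
generate_water_series <- function(archetype, n_fields, season_start, season_end,
                                  seed = 1L, field_prefix = archetype$name) {
  stopifnot(inherits(archetype, "archetype_spec"), n_fields >= 1)
  season_start <- as.Date(season_start)
  season_end <- as.Date(season_end)
  n_days <- as.integer(season_end - season_start) + 1L
  if (n_days < 60) abort("season must span at least 60 days")
  dates <- seq(season_start, season_end, by = "day")
  day0 <- seq_len(n_days) - 1L
  template <- stats::approx(archetype$template$day, archetype$template$level_cm,
                            xout = day0, rule = 2)$y
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  purrr::map_dfr(seq_len(n_fields), function(i) {
    lvl <- template +
      ar1_noise(n_days, archetype$noise_sd_cm, archetype$ar1_rho) +
      irrigation_pulses(n_days, archetype$irrigation_rate_per_week,
                        archetype$irrigation_pulse_cm,
                        archetype$recession_cm_per_day)
    censored <- lvl < TUBE_DEPTH_CM
    lvl <- pmin(pmax(lvl, TUBE_DEPTH_CM), MAX_POND_CM)
    tibble::tibble(
      field_id = sprintf("%s-%03d", field_prefix, i),
      date = dates, level_cm = lvl, censored = censored, observed = TRUE
    )
  })
}

ar1_noise <- function(n, sd_marginal, rho) {
  if (sd_marginal == 0) return(numeric(n))
  innov_sd <- sd_marginal * sqrt(1 - rho^2)
  e <- numeric(n)
  e[1] <- rnorm(1, 0, sd_marginal)
  for (t in seq_len(n)[-1]) e[t] <- rho * e[t - 1] + rnorm(1, 0, innov_sd)
  e
}

irrigation_pulses <- function(n_days, rate_per_week, pulse_cm, recession) {
  k <- rpois(1, rate_per_week * n_days / 7)
  out <- numeric(n_days)
  if (k == 0) return(out)
  t0 <- sample.int(n_days, k, replace = TRUE)
  t <- seq_len(n_days)
  for (tt in t0) {
    out <- out + pmax(0, pulse_cm - recession * (t - tt)) * (t >= tt)
  }
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic per-field soil table
#'
#' Draws textures on the simplex with clay in the 10-45 % alluvial-plain
#' range, organic carbon 0.3-1.5 %, pH 6-8.5, and a measured bulk density
#' (1.1-1.6 g/cm^3) present for a configurable fraction of fields so both the
#' measured-BD and the pedotransfer path are exercised downstream.
#'
#' @param n_fields Number of fields.
#' @param seed Integer RNG seed.
#' @param fraction_with_bd Probability that a field has a measured BD
#'   (default 0.8).
#' @param field_ids Optional field ids (recycled checks apply).
#' @return A soils tibble satisfying [validate_soils()].
#' @export
generate_soils <- function(n_fields, seed = 1L, fraction_with_bd = 0.8,
                           field_ids = NULL) {
  stopifnot(n_fields >= 1, fraction_with_bd >= 0, fraction_with_bd <= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  clay <- runif(n_fields, 10, 45)
  split <- runif(n_fields, 0.25, 0.75)
  silt <- (100 - clay) * split
  sand <- 100 - clay - silt
  bd <- runif(n_fields, 1.1, 1.6)
  bd[runif(n_fields) >= fraction_with_bd] <- NA_real_
  validate_soils(tibble::tibble(
    field_id = if (is.null(field_ids)) sprintf("F%03d", seq_len(n_fields)) else field_ids,
    clay_pct = clay, silt_pct = silt, sand_pct = sand,
    ph = runif(n_fields, 6, 8.5),
    oc_pct = runif(n_fields, 0.3, 1.5),
    bd_g_cm3 = bd
  ))
}

#' Surrogate emission model parameters
#'
#' Parameters of the declared surrogate seasonal emission model that stands in
#' for a process-based biogeochemistry simulator. The surrogate is NOT a
#' mechanistic model: it is a transparent functional form whose drivers mirror
#' the hydrologic controls identified for methane (total flooded fraction,
#' deep-water fraction, residue return) and nitrous oxide (N rate, wet-dry
#' transitions around fertilization, clay), calibrated only so seasonal totals
#' fall in realistic ranges (roughly 7-608 kg CH4 ha^-1).
#'
#' @param ch4_max_kg_ha Seasonal CH4 scale for a fully flooded field.
#' @param ch4_gamma Exponent on the flooded fraction (>= 1).
#' @param deepwater_boost Relative CH4 gain at full deep-water flooding.
#' @param residue_boost Relative CH4 gain at full residue return in a fully
#'   flooded field.
#' @param ch4_noise_sd_log Lognormal noise sd for CH4.
#' @param n2o_base_g Baseline seasonal N2O (g ha^-1) at zero effective N.
#' @param n2o_per_kgN_g N2O response (g ha^-1 per kg N applied to unflooded
#'   soil).
#' @param n2o_transition_weight Relative N2O gain per unit of the wet-dry
#'   transition index around fertilization.
#' @param clay_effect Relative N2O gain at 100 % clay.
#' @param n2o_noise_sd_log Lognormal noise sd for N2O.
#' @param fert_window_days Half-width (days) of the window around each N
#'   application in which wet-dry transitions are counted.
#' @return A `surrogate_params` list.
#' @export
surrogate_params <- function(ch4_max_kg_ha = 650, ch4_gamma = 1.4,
                             deepwater_boost = 0.5, residue_boost = 0.4,
                             ch4_noise_sd_log = 0.25,
                             n2o_base_g = 10, n2o_per_kgN_g = 1.2,
                             n2o_transition_weight = 2,
                             clay_effect = 0.5, n2o_noise_sd_log = 0.3,
                             fert_window_days = 7) {
  p <- list(
    ch4_max_kg_ha = ch4_max_kg_ha, ch4_gamma = ch4_gamma,
    deepwater_boost = deepwater_boost, residue_boost = residue_boost,
    ch4_noise_sd_log = ch4_noise_sd_log, n2o_base_g = n2o_base_g,
    n2o_per_kgN_g = n2o_per_kgN_g,
    n2o_transition_weight = n2o_transition_weight,
    clay_effect = clay_effect, n2o_noise_sd_log = n2o_noise_sd_log,
    fert_window_days = fert_window_days
  )
  if (any(unlist(p) < 0)) abort("surrogate parameters must be nonnegative")
  if (ch4_gamma < 1) abort("ch4_gamma must be >= 1")
  structure(p, class = "surrogate_params")
}

#' Surrogate seasonal emissions for a set of fields
#'
#' Computes seasonal CH4 and N2O for each field from its hydrologic
#' descriptors, soil and management, using the declared surrogate model
#' (see [surrogate_params()]):
#'
#' CH4 (kg ha^-1) = `ch4_max * a1^gamma * (1 + deepwater_boost * a4) *
#' (1 + residue_boost * R * a1) * exp(e1)`, where `a1`/`a4` are the flooded
#' fraction (A1/100) and deep-flood fraction of flooded days (A4/100) and `R`
#' the residue fraction.
#'
#' N2O (g ha^-1) = `(n2o_base + n2o_per_kgN * N_eff) * (1 +
#' n2o_transition_weight * T) * (1 + clay_effect * clay/100) * exp(e2)`, where
#' `N_eff` sums only doses applied on a day the field is not flooded (a dose
#' applied onto standing water produces no N2O) and `T` is the number of
#' drained-flooded day transitions within +-`fert_window_days` of any
#' application, divided by the number of applications.
#'
#' @param water Water-series tibble covering all fields.
#' @param soils Soils tibble (for `clay_pct`).
#' @param mgmt Management list with `sowing_date`, `n_schedule` (tibble with
#'   `day`, `kg_n_ha`) and `residue_fraction` in \[0, 1\].
#' @param params A [surrogate_params()] object.
#' @param seed Integer RNG seed (used when `noise = TRUE`).
#' @param noise Logical; `FALSE` sets both lognormal errors to zero.
#' @param season_year Integer tag stored on the output.
#' @return An emissions tibble: `field_id`, `season_year`, `ch4_kg_ha`,
#'   `n2o_g_ha`, `gwp_mt_co2eq_ha`.
#' @export
surrogate_emissions <- function(water, soils, mgmt, params = surrogate_params(),
                                seed = 1L, noise = TRUE, season_year = NA_integer_) {
  comp <- surrogate_components(water, soils, mgmt, params)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- nrow(comp)
  e1 <- if (noise) rnorm(n, 0, params$ch4_noise_sd_log) else numeric(n)
  e2 <- if (noise) rnorm(n, 0, params$n2o_noise_sd_log) else numeric(n)
  ch4 <- surrogate_ch4(comp, mgmt$residue_fraction, params, e1)
  n2o <- surrogate_n2o(comp, 1, params, e2)
  tibble::tibble(
    field_id = comp$field_id,
    season_year = as.integer(season_year),
    ch4_kg_ha = ch4,
    n2o_g_ha = n2o,
    gwp_mt_co2eq_ha = gwp_co2eq(ch4, n2o)
  )
}

# Per-field ingredients of the surrogate model, independent of the residue
# fraction and of proportional N-rate scaling (dose suppression on flooded
# application days is unaffected by a common multiplier).
surrogate_components <- function(water, soils, mgmt, params = surrogate_params()) {
  stopifnot(inherits(params, "surrogate_params"))
  R <- mgmt$residue_fraction
  if (is.null(R) || R < 0 || R > 1) abort("residue_fraction must lie in [0, 1]")
  sched <- validate_n_schedule(mgmt$n_schedule)
  desc <- compute_descriptors(water)
  soils <- validate_soils(soils)
  dat <- dplyr::left_join(desc, soils[, c("field_id", "clay_pct")], by = "field_id")
  if (anyNA(dat$clay_pct)) abort("every field needs a soil record (clay_pct)")
  by_field <- split(water, water$field_id)[dat$field_id]
  fert <- purrr::map_dfr(by_field, fert_context, mgmt = mgmt, sched = sched,
                         window = params$fert_window_days)
  tibble::tibble(
    field_id = dat$field_id,
    a1 = dat$A1 / 100, a4 = dat$A4 / 100,
    clay_pct = dat$clay_pct,
    n_eff_kg = fert$n_eff_kg,
    transition_index = fert$transition_index
  )
}

surrogate_ch4 <- function(comp, residue_fraction, params, eps = 0) {
  params$ch4_max_kg_ha * comp$a1^params$ch4_gamma *
    (1 + params$deepwater_boost * comp$a4) *
    (1 + params$residue_boost * residue_fraction * comp$a1) * exp(eps)
}

surrogate_n2o <- function(comp, n_multiplier, params, eps = 0) {
  (params$n2o_base_g + params$n2o_per_kgN_g * n_multiplier * comp$n_eff_kg) *
    (1 + params$n2o_transition_weight * comp$transition_index) *
    (1 + params$clay_effect * comp$clay_pct / 100) * exp(eps)
}

# Per-field fertilization context: effective (unflooded-day) N and the
# wet-dry transition index around application dates.
fert_context <- function(df, mgmt, sched, window) {
  df <- dplyr::arrange(df, .data$date)
  app_dates <- as.Date(mgmt$sowing_date) + sched$day
  flooded <- df$level_cm > 0
  lookup <- setNames(flooded, as.character(df$date))
  on_day <- lookup[as.character(app_dates)]
  on_day[is.na(on_day)] <- FALSE  # applications outside the record: dry soil
  n_eff <- sum(sched$kg_n_ha[!on_day])
  # transition day t+1 marks a drained<->flooded state change from day t
  trans_dates <- df$date[-1][flooded[-1] != flooded[-length(flooded)]]
  in_window <- purrr::map_lgl(trans_dates, function(d) {
    any(abs(as.integer(d - app_dates)) <= window)
  })
  tibble::tibble(
    field_id = df$field_id[1],
    n_eff_kg = n_eff,
    transition_index = sum(in_window) / nrow(sched)
  )
}

#' Generate a full synthetic landscape (series, soils, management, emissions)
#'
#' Draws `n_fields` fields from the scenario's five archetypes with the given
#' mixture weights, simulates their water-level series over the scenario
#' season, attaches synthetic soils and the standardized management, and
#' computes seasonal emissions through the surrogate model. Fully reproducible
#' for a fixed seed.
#'
#' @param scenario `"wet"` or `"dry"`.
#' @param n_fields Number of fields (>= 10).
#' @param seed Integer RNG seed.
#' @param weights Named archetype mixture weights summing to 1 (default
#'   [archetype_weights()]).
#' @param params Surrogate parameters.
#' @param noise Logical; passed to [surrogate_emissions()].
#' @return A `paddy_landscape` list: `water`, `soils`, `emissions`,
#'   `management`, `truth` (tibble `field_id`, `archetype`), `scenario`,
#'   `season`.
#' @export
generate_landscape <- function(scenario = c("wet", "dry"), n_fields, seed = 1L,
                               weights = NULL, params = surrogate_params(),
                               noise = TRUE) {
  scenario <- match.arg(scenario)
  if (n_fields < 10) abort("a landscape needs at least 10 fields")
  archetypes <- paddy_archetypes(scenario)
  if (is.null(weights)) weights <- archetype_weights(scenario)
  if (abs(sum(weights) - 1) > 1e-8) abort("mixture weights must sum to 1")
  if (!all(names(weights) %in% names(archetypes))) {
    abort("weights must be named after the scenario's archetypes")
  }
  season <- scenario_season(scenario)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  draw <- sample(names(weights), n_fields, replace = TRUE, prob = weights)
  field_seeds <- sample.int(.Machine$integer.max - 1L, n_fields)
  soil_seed <- sample.int(.Machine$integer.max - 1L, 1)
  em_seed <- sample.int(.Machine$integer.max - 1L, 1)

  ids <- sprintf("%s-F%03d", scenario, seq_len(n_fields))
  water <- purrr::map_dfr(seq_len(n_fields), function(i) {
    w <- generate_water_series(archetypes[[draw[i]]], 1, season$start,
                               season$end, seed = field_seeds[i])
    w$field_id <- ids[i]
    w
  })
  soils <- generate_soils(n_fields, seed = soil_seed, field_ids = ids)
  year <- as.integer(format(season$start, "%Y"))
  mgmt <- list(
    sowing_date = season$start, harvest_date = season$end,
    n_schedule = n_schedule_preset("standard-125"), residue_fraction = 0
  )
  emissions <- surrogate_emissions(water, soils, mgmt, params = params,
                                   seed = em_seed, noise = noise,
                                   season_year = year)
  structure(
    list(
      water = water, soils = soils, emissions = emissions, management = mgmt,
      truth = tibble::tibble(field_id = ids, archetype = draw),
      scenario = scenario, season = season
    ),
    class = "paddy_landscape"
  )
}

#' @export
print.paddy_landscape <- function(x, ...) {
  cat("<paddy_landscape>", x$scenario, "scenario,",
      nrow(x$truth), "fields,", format(x$season$start), "to",
      format(x$season$end), "\n")
  print(table(x$truth$archetype))
  invisible(x)
}
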