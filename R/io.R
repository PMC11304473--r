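#' Read daily water-tube records into complete field series
#'
#' Ingests a CSV of daily field water-level readings (one row per field-day)
#' and returns one complete daily series per field. Levels are in cm relative
#' to the soil surface: positive values are ponded floodwater height, negative
#' values the depth of the saturated front, and readings are censored at the
#' -15 cm depth of the monitoring tube. Interior gaps of at most
#' `max_gap_days` consecutive days are filled by linear interpolation and
#' flagged `observed = FALSE`; fields with longer gaps are dropped with a
#' warning (or raise an error, per `gap_policy`). Values below -15 are clamped
#' to -15 and flagged `censored`.
#'
#' @param path CSV with columns `field_id`, `date` (ISO-8601), `level_cm` and
#'   optionally `censored` (logical).
#' @param max_gap_days Longest interior gap (consecutive missing days) filled
#'   by interpolation. Default 3.
#' @param gap_policy `"drop"` (default) removes fields with longer gaps with a
#'   warning; `"error"` aborts.
#' @return A tibble with columns `field_id`, `date`, `level_cm`, `censored`,
#'   `observed`, one row per field-day on a gap-free daily grid.
#' @export
read_water_series <- function(path, max_gap_days = 3, gap_policy = c("drop", "error")) {
  gap_policy <- match.arg(gap_policy)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("field_id", "date", "level_cm")
  if (!all(need %in% names(raw))) {
    abort(paste0("water-level CSV must have columns ",
                 paste(need, collapse = ", ")))
  }
  lvl <- suppressWarnings(as.numeric(raw$level_cm))
  bad <- which(is.na(lvl) & !is.na(raw$level_cm) & raw$level_cm != "")
  if (length(bad)) {
    abort(paste0("non-numeric level_cm at data row(s) ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  dat <- tibble::tibble(
    field_id = raw$field_id,
    date = as.Date(raw$date),
    level_cm = lvl,
    censored = if ("censored" %in% names(raw)) {
      tolower(raw$censored) %in% c("true", "t", "1", "yes")
    } else FALSE
  )
  if (anyNA(dat$date)) abort("unparseable dates in water-level CSV")
  dup <- dat |>
    dplyr::count(.data$field_id, .data$date) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate field-date rows for field(s): ",
                 paste(unique(dup$field_id), collapse = ", ")))
  }

  out <- dat |>
    dplyr::group_by(.data$field_id) |>
    dplyr::group_split() |>
    purrr::map(complete_one_series, max_gap_days = max_gap_days,
               gap_policy = gap_policy) |>
    purrr::compact() |>
    dplyr::bind_rows()
  if (nrow(out) == 0) {
    return(tibble::tibble(
      field_id = character(), date = as.Date(character()),
      level_cm = numeric(), censored = logical(), observed = logical()
    ))
  }
  validate_water_series(out)
}

complete_one_series <- function(df, max_gap_days, gap_policy) {
  fid <- df$field_id[1]
  df <- dplyr::arrange(df, .data$date)
  span <- as.integer(max(df$date) - min(df$date)) + 1L
  if (span < 30) {
    warn(paste0("field ", fid, " rejected: monitoring span ", span, " days < 30"))
    return(NULL)
  }
  grid <- tibble::tibble(
    field_id = fid,
    date = seq(min(df$date), max(df$date), by = "day")
  )
  full <- dplyr::left_join(grid, df, by = c("field_id", "date"))
  miss <- is.na(full$level_cm)
  if (any(miss)) {
    runs <- rle(miss)
    if (max(runs$lengths[runs$values]) > max_gap_days) {
      msg <- paste0("field ", fid, " has a gap longer than ", max_gap_days, " days")
      if (gap_policy == "error") abort(msg)
      warn(paste0(msg, "; field dropped"))
      return(NULL)
    }
    idx <- seq_len(nrow(full))
    full$level_cm <- stats::approx(idx[!miss], full$level_cm[!miss], xout = idx)$y
    full$censored[miss] <- FALSE
  }
  full$censored[is.na(full$censored)] <- FALSE
  full$observed <- !miss
  below <- full$level_cm < TUBE_DEPTH_CM
  full$level_cm[below] <- TUBE_DEPTH_CM
  full$censored <- full$censored | below
  full$level_cm[full$censored] <- TUBE_DEPTH_CM
  full
}

#' Validate a water-level series table
#'
#' Checks the series invariants: gap-free strictly daily dates per field,
#' levels never below the -15 cm tube depth, censored days recorded at exactly
#' -15, and (for ingested monitoring data, `min_days = 30`) a minimum span per
#' field. Descriptor computation relaxes the span requirement to 2 days.
#'
#' @param water A water-series tibble (see [read_water_series()]).
#' @param min_days Minimum series length per field (default 30).
#' @return The input as a tibble.
#' @export
validate_water_series <- function(water, min_days = 30) {
  need <- c("field_id", "date", "level_cm", "censored", "observed")
  if (!all(need %in% names(water))) {
    abort(paste0("water series needs columns ", paste(need, collapse = ", ")))
  }
  water <- tibble::as_tibble(water)
  by_field <- split(water, water$field_id)
  for (df in by_field) {
    fid <- df$field_id[1]
    steps <- diff(as.integer(df$date[order(df$date)]))
    if (length(steps) && any(steps != 1)) {
      abort(paste0("field ", fid, ": dates are not a complete daily grid"))
    }
    if (nrow(df) < min_days) {
      abort(paste0("field ", fid, ": series shorter than ", min_days, " days"))
    }
  }
  if (any(water$level_cm < TUBE_DEPTH_CM - 1e-9)) {
    abort("levels below the -15 cm tube depth are impossible")
  }
  if (any(water$censored & abs(water$level_cm - TUBE_DEPTH_CM) > 1e-9)) {
    abort("censored days must be recorded at exactly -15 cm")
  }
  water
}

#' Write a water-level series table to CSV
#'
#' Inverse of [read_water_series()] for complete series: writing and re-reading
#' reproduces `field_id`, `date`, `level_cm` and `censored` exactly.
#'
#' @param water A water-series tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_water_series <- function(water, path) {
  validate_water_series(water)
  readr::write_csv(
    dplyr::select(water, "field_id", "date", "level_cm", "censored"), path
  )
  invisible(path)
}

#' Read a per-field soil properties table
#'
#' @param path CSV with columns `field_id`, `clay_pct`, `silt_pct`,
#'   `sand_pct`, `ph`, `oc_pct` and optionally `bd_g_cm3`.
#' @return A validated soils tibble (`bd_g_cm3` present, `NA` where missing).
#' @export
read_soils <- function(path) {
  soils <- readr::read_csv(path, show_col_types = FALSE)
  validate_soils(soils)
}

#' Validate a soils table
#'
#' Enforces the texture closure (clay + silt + sand within 100 +- 0.5), pH and
#' OC presence, and bulk density within (0, 2.65) where given.
#'
#' @param soils A soils data frame.
#' @return The soils tibble with a `bd_g_cm3` column guaranteed.
#' @export
validate_soils <- function(soils) {
  need <- c("field_id", "clay_pct", "silt_pct", "sand_pct", "ph", "oc_pct")
  if (!all(need %in% names(soils))) {
    abort(paste0("soils table needs columns ", paste(need, collapse = ", ")))
  }
  soils <- tibble::as_tibble(soils)
  if (!"bd_g_cm3" %in% names(soils)) soils$bd_g_cm3 <- NA_real_
  tot <- soils$clay_pct + soils$silt_pct + soils$sand_pct
  if (any(abs(tot - 100) > 0.5)) {
    abort("clay + silt + sand must equal 100 +- 0.5 % for every field")
  }
  bd <- soils$bd_g_cm3
  if (any(!is.na(bd) & (bd <= 0 | bd >= 2.65))) {
    abort("bulk density must lie in (0, 2.65) g/cm^3")
  }
  soils
}

#' Read a per-field seasonal emission table
#'
#' @param path CSV with columns `field_id`, `season_year`, `ch4_kg_ha`,
#'   `n2o_g_ha` and optionally `gwp_mt_co2eq_ha`. A missing GWP column is
#'   recomputed from the two fluxes with the AR6 factors.
#' @return An emissions tibble including `gwp_mt_co2eq_ha`.
#' @export
read_emissions <- function(path) {
  em <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("field_id", "season_year", "ch4_kg_ha", "n2o_g_ha")
  if (!all(need %in% names(em))) {
    abort(paste0("emissions table needs columns ", paste(need, collapse = ", ")))
  }
  if (any(em$ch4_kg_ha < 0) || any(em$n2o_g_ha < 0)) {
    abort("seasonal fluxes must be nonnegative")
  }
  em <- tibble::as_tibble(em)
  em$gwp_mt_co2eq_ha <- gwp_co2eq(em$ch4_kg_ha, em$n2o_g_ha)
  em
}

#' Write a descriptor table to CSV
#'
#' @param descriptors A tibble with `field_id` and the 17 descriptor columns
#'   `A1..A8`, `B1..B6`, `C1..C3`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_descriptors <- function(descriptors, path) {
  if (!all(c("field_id", DESCRIPTOR_NAMES) %in% names(descriptors))) {
    abort("descriptor table must contain field_id and A1..A8, B1..B6, C1..C3")
  }
  readr::write_csv(descriptors[, c("field_id", DESCRIPTOR_NAMES)], path)
  invisible(path)
}
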