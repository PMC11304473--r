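#' Classify each day of a water-level series into a flood or drainage band
#'
#' A day is flooded iff its level is strictly above the soil surface (> 0 cm);
#' level exactly 0 counts as drained. Flood bands are half-open on the left:
#' (0, 5] cm, (5, 10] cm, > 10 cm. Drainage bands partition the non-positive
#' levels: \[-5, 0\], \[-10, -5), < -10 cm; censored readings (-15) fall in the
#' < -10 cm band.
#'
#' @param water A water-series tibble (see [read_water_series()]).
#' @return The input with an added factor column `band` with levels
#'   `FLOOD_0_5`, `FLOOD_5_10`, `FLOOD_GT10`, `DRAIN_0_5`, `DRAIN_5_10`,
#'   `DRAIN_LT10`.
#' @export
classify_days <- function(water) {
  water <- validate_water_series(water, min_days = 2)
  water$band <- day_band(water$level_cm)
  water
}

day_band <- function(level) {
  factor(
    dplyr::case_when(
      level > 10 ~ "FLOOD_GT10",
      level > 5 ~ "FLOOD_5_10",
      level > 0 ~ "FLOOD_0_5",
      level >= -5 ~ "DRAIN_0_5",
      level >= -10 ~ "DRAIN_5_10",
      TRUE ~ "DRAIN_LT10"
    ),
    levels = c("FLOOD_0_5", "FLOOD_5_10", "FLOOD_GT10",
               "DRAIN_0_5", "DRAIN_5_10", "DRAIN_LT10")
  )
}

#' Segment a daily series into flood and dry events
#'
#' Maximal runs of flooded days form FLOOD events and maximal runs of drained
#' days form DRY events; together they cover every monitored day. Flood events
#' carry a duration class (1 day; 2-7 days "within a week"; 8-30 days "within
#' a month"; > 30 days "more than a month"). Dry events are assigned the
#' drainage band of their deepest (minimum) level.
#'
#' @param water A water-series tibble.
#' @return A tibble with one row per event: `field_id`, `kind` (`FLOOD`/`DRY`),
#'   `start_date`, `duration_days`, `extreme_level_cm` (max level for floods,
#'   min for dry spells), `duration_class` (floods; `NA` for dry events) and
#'   `band` (dry events; `NA` for floods).
#' @export
segment_events <- function(water) {
  water <- validate_water_series(water, min_days = 2)
  water |>
    dplyr::group_by(.data$field_id) |>
    dplyr::group_split() |>
    purrr::map(segment_one) |>
    dplyr::bind_rows()
}

segment_one <- function(df) {
  df <- dplyr::arrange(df, .data$date)
  flooded <- df$level_cm > 0
  runs <- rle(flooded)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  purrr::pmap_dfr(
    list(starts, ends, runs$values),
    function(s, e, is_flood) {
      lv <- df$level_cm[s:e]
      dur <- e - s + 1L
      tibble::tibble(
        field_id = df$field_id[1],
        kind = if (is_flood) "FLOOD" else "DRY",
        start_date = df$date[s],
        duration_days = dur,
        extreme_level_cm = if (is_flood) max(lv) else min(lv),
        duration_class = if (is_flood) flood_duration_class(dur) else NA_character_,
        band = if (is_flood) NA_character_ else as.character(day_band(min(lv)))
      )
    }
  )
}

flood_duration_class <- function(dur) {
  dplyr::case_when(
    dur == 1 ~ "ONE_DAY",
    dur <= 7 ~ "WITHIN_WEEK",
    dur <= 30 ~ "WITHIN_MONTH",
    TRUE ~ "OVER_MONTH"
  )
}

#' Compute the 17 hydrologic descriptors of a field-season
#'
#' Summarizes each field's daily water-level series into three descriptor
#' groups:
#' * A1: % of monitored days flooded (level > 0 cm); A2-A4: % of flooded days
#'   with ponding in (0, 5], (5, 10] and > 10 cm; A5-A8: % of flood events
#'   lasting one day, 2-7 days, 8-30 days, and more than 30 days.
#' * B1-B3: % of drained days with the water table in \[-5, 0\], \[-10, -5) and
#'   below -10 cm; B4-B6: mean duration (days) of dry events assigned to those
#'   bands (0 when a band has no event).
#' * C1: number of flood events; C2: days on which the level drops from
#'   >= +5 cm to <= -5 cm within 24 h; C3: days with a drop of more than 10 cm
#'   within 24 h.
#'
#' Percentage groups are computed on their own bases, so A2+A3+A4 = 100
#' whenever any day is flooded, A5+...+A8 = 100 whenever there is a flood
#' event, and B1+B2+B3 = 100 whenever any day is drained; groups with an empty
#' base are all 0.
#'
#' @param water A water-series tibble covering one or more fields.
#' @return A tibble with one row per field: `field_id`, `A1`..`A8`,
#'   `B1`..`B6`, `C1`..`C3`.
#' @export
compute_descriptors <- function(water) {
  water <- validate_water_series(water, min_days = 2)
  water |>
    dplyr::group_by(.data$field_id) |>
    dplyr::group_split() |>
    purrr::map(descriptors_one) |>
    dplyr::bind_rows()
}

descriptors_one <- function(df) {
  df <- dplyr::arrange(df, .data$date)
  n <- nrow(df)
  if (n < 2) abort("descriptors need at least 2 days (transitions undefined)")
  lv <- df$level_cm
  band <- day_band(lv)
  flooded <- lv > 0
  n_flood_days <- sum(flooded)
  n_drain_days <- n - n_flood_days

  pct <- function(x, base) if (base > 0) 100 * x / base else 0

  ev <- segment_one(df)
  fl <- ev[ev$kind == "FLOOD", ]
  dr <- ev[ev$kind == "DRY", ]
  c1 <- nrow(fl)

  mean_dur <- function(bd) {
    d <- dr$duration_days[dr$band == bd]
    if (length(d)) mean(d) else 0
  }

  drop <- lv[-n] - lv[-1]
  tibble::tibble(
    field_id = df$field_id[1],
    A1 = pct(n_flood_days, n),
    A2 = pct(sum(band == "FLOOD_0_5"), n_flood_days),
    A3 = pct(sum(band == "FLOOD_5_10"), n_flood_days),
    A4 = pct(sum(band == "FLOOD_GT10"), n_flood_days),
    A5 = pct(sum(fl$duration_class == "ONE_DAY"), c1),
    A6 = pct(sum(fl$duration_class == "WITHIN_WEEK"), c1),
    A7 = pct(sum(fl$duration_class == "WITHIN_MONTH"), c1),
    A8 = pct(sum(fl$duration_class == "OVER_MONTH"), c1),
    B1 = pct(sum(band == "DRAIN_0_5"), n_drain_days),
    B2 = pct(sum(band == "DRAIN_5_10"), n_drain_days),
    B3 = pct(sum(band == "DRAIN_LT10"), n_drain_days),
    B4 = mean_dur("DRAIN_0_5"),
    B5 = mean_dur("DRAIN_5_10"),
    B6 = mean_dur("DRAIN_LT10"),
    C1 = as.numeric(c1),
    C2 = sum(lv[-n] >= 5 & lv[-1] <= -5),
    C3 = sum(drop > 10)
  )
}
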