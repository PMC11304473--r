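#' Standard nitrogen fertilization schedules
#'
#' The regionally standardized rice N management is one basal dose of
#' 25 kg N ha^-1 at sowing (as DAP) plus two top-dressed doses of 50 kg N ha^-1
#' (as urea) at 25 and 55 days after sowing, for a baseline of 125 kg N ha^-1.
#' An alternative 90 kg N ha^-1 baseline preset keeps the same 25:50:50 dose
#' ratio and application days.
#'
#' @param preset `"standard-125"` (default) or `"low-90"`.
#' @return A tibble with columns `day` (days after sowing), `kg_n_ha`, `source`.
#' @examples
#' sum(n_schedule_preset()$kg_n_ha)       # 125
#' sum(n_schedule_preset("low-90")$kg_n_ha) # 90
#' @export
n_schedule_preset <- function(preset = c("standard-125", "low-90")) {
  preset <- match.arg(preset)
  base <- tibble::tibble(
    day = c(0L, 25L, 55L),
    kg_n_ha = c(25, 50, 50),
    source = c("DAP", "urea", "urea")
  )
  if (preset == "low-90") {
    base$kg_n_ha <- base$kg_n_ha * (90 / 125)
  }
  base
}

#' Scale every dose of an N schedule proportionally
#'
#' Multiplies each split dose by `multiplier` without changing the ratio
#' between doses or their timing.
#'
#' @param schedule A tibble with columns `day`, `kg_n_ha` (and optionally
#'   `source`).
#' @param multiplier Nonnegative scalar.
#' @return The schedule with `kg_n_ha` scaled.
#' @export
scale_n_schedule <- function(schedule, multiplier) {
  stopifnot(is.numeric(multiplier), length(multiplier) == 1, multiplier >= 0)
  schedule <- validate_n_schedule(schedule)
  schedule$kg_n_ha <- schedule$kg_n_ha * multiplier
  schedule
}

#' Total seasonal N rate of a schedule
#'
#' @param schedule A tibble with column `kg_n_ha`.
#' @return Total kg N ha^-1.
#' @export
total_n <- function(schedule) {
  schedule <- validate_n_schedule(schedule)
  sum(schedule$kg_n_ha)
}

validate_n_schedule <- function(schedule) {
  if (!is.data.frame(schedule) || !all(c("day", "kg_n_ha") %in% names(schedule))) {
    abort("an N schedule needs columns `day` and `kg_n_ha`")
  }
  if (nrow(schedule) == 0) abort("the N schedule must contain at least one dose")
  if (any(schedule$kg_n_ha < 0)) abort("N doses must be >= 0 kg N ha^-1")
  if (any(schedule$day < 0)) abort("application days (after sowing) must be >= 0")
  tibble::as_tibble(schedule)
}

#' Default run configuration
#'
#' Replicates the study setup: a July-November monsoon season, the standardized
#' 25+50+50 kg N ha^-1 schedule with zero residue return, five hydrologic
#' clusters selected over k = 2..8 with 50 restarts, five methane emission
#' levels with an 80:20 stratified split, and a 5 x 5 nitrogen-by-residue
#' sensitivity grid (N multipliers 1 to 2 in steps of 0.25; residue fractions
#' 0 to 1 in steps of 0.25).
#'
#' @return A `paddy_config` list with components `season`, `management`,
#'   `clustering`, `classifier`, `sensitivity`.
#' @export
default_config <- function() {
  cfg <- list(
    season = list(start = as.Date("2021-07-07"), end = as.Date("2021-11-11")),
    management = list(
      sowing_date = as.Date("2021-07-07"),
      harvest_date = as.Date("2021-11-11"),
      n_schedule = n_schedule_preset("standard-125"),
      residue_fraction = 0
    ),
    clustering = list(
      k = "auto", k_range = 2:8, restarts = 50L, seed = 1L, min_size = 3L
    ),
    classifier = list(
      n_levels = 5L, split_ratio = 0.8, seed = 1L,
      n_trees = 500L, min_leaf = 5L
    ),
    sensitivity = list(
      n_multipliers = c(1, 1.25, 1.5, 1.75, 2),
      residue_fractions = c(0, 0.25, 0.5, 0.75, 1),
      noise = TRUE, replicates = 30L
    )
  )
  structure(cfg, class = "paddy_config")
}

#' Load a run configuration from a YAML file
#'
#' Reads a YAML key-value file and merges it over [default_config()]. Unknown
#' keys at any level are an error (no silent typos); invariant violations are
#' reported with the offending field names. An empty (or `NULL`) file yields
#' the full defaults.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A validated `paddy_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- unclass(default_config())
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.null(user)) {
      if (!is.list(user)) abort("config file must be a YAML mapping")
      cfg <- merge_config(cfg, user, prefix = character())
    }
  }
  cfg <- coerce_config(cfg)
  validate_config(structure(cfg, class = "paddy_config"))
}

merge_config <- function(base, user, prefix) {
  leaf_override <- c("n_schedule", "k_range", "n_multipliers", "residue_fractions")
  for (key in names(user)) {
    full <- paste(c(prefix, key), collapse = ".")
    if (!key %in% names(base)) {
      abort(paste0("unknown config key: `", full, "`"))
    }
    if (is.list(base[[key]]) && !key %in% leaf_override) {
      if (!is.list(user[[key]])) {
        abort(paste0("config key `", full, "` must be a mapping"))
      }
      base[[key]] <- merge_config(base[[key]], user[[key]], c(prefix, key))
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

coerce_config <- function(cfg) {
  cfg$season$start <- as.Date(cfg$season$start)
  cfg$season$end <- as.Date(cfg$season$end)
  cfg$management$sowing_date <- as.Date(cfg$management$sowing_date)
  cfg$management$harvest_date <- as.Date(cfg$management$harvest_date)
  ns <- cfg$management$n_schedule
  if (is.list(ns) && !is.data.frame(ns)) {
    ns <- purrr::map_dfr(ns, function(d) {
      tibble::tibble(
        day = as.integer(d$day), kg_n_ha = as.numeric(d$kg_n_ha),
        source = if (is.null(d$source)) NA_character_ else as.character(d$source)
      )
    })
  }
  cfg$management$n_schedule <- tibble::as_tibble(ns)
  cfg$clustering$k_range <- as.integer(cfg$clustering$k_range)
  cfg
}

#' @export
print.paddy_config <- function(x, ...) {
  cat("<paddy_config>\n")
  cat("  season:", format(x$season$start), "to", format(x$season$end), "\n")
  cat("  N schedule:", paste(x$management$n_schedule$kg_n_ha, collapse = " + "),
      "=", total_n(x$management$n_schedule), "kg N ha^-1\n")
  cat("  residue fraction:", x$management$residue_fraction, "\n")
  cat("  clustering: k =", paste(x$clustering$k, collapse = ""),
      "(range", paste(range(x$clustering$k_range), collapse = ".."), ")\n")
  cat("  classifier:", x$classifier$n_levels, "levels, split",
      x$classifier$split_ratio, "\n")
  invisible(x)
}

validate_config <- function(cfg) {
  bad <- character()
  if (cfg$season$end <= cfg$season$start) bad <- c(bad, "season.end <= season.start")
  validate_n_schedule(cfg$management$n_schedule)
  rf <- cfg$management$residue_fraction
  if (!is.numeric(rf) || rf < 0 || rf > 1) bad <- c(bad, "management.residue_fraction not in [0, 1]")
  sr <- cfg$classifier$split_ratio
  if (!is.numeric(sr) || sr <= 0 || sr >= 1) bad <- c(bad, "classifier.split_ratio not in (0, 1)")
  if (cfg$classifier$n_levels < 2) bad <- c(bad, "classifier.n_levels < 2")
  if (!(identical(cfg$clustering$k, "auto") || (is.numeric(cfg$clustering$k) && cfg$clustering$k >= 1)))
    bad <- c(bad, "clustering.k must be \"auto\" or a positive integer")
  if (cfg$clustering$min_size < 1) bad <- c(bad, "clustering.min_size < 1")
  if (any(cfg$sensitivity$n_multipliers < 1) || !1 %in% cfg$sensitivity$n_multipliers)
    bad <- c(bad, "sensitivity.n_multipliers must be >= 1 and include 1")
  frs <- cfg$sensitivity$residue_fractions
  if (any(frs < 0 | frs > 1) || !0 %in% frs)
    bad <- c(bad, "sensitivity.residue_fractions must lie in [0, 1] and include 0")
  if (length(bad)) {
    abort(paste0("invalid configuration:\n", paste0("  - ", bad, collapse = "\n")))
  }
  cfg
}
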