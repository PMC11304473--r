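std_mgmt <- function(start = as.Date("2022-07-01"), residue = 0,
                     sched = n_schedule_preset()) {
  list(sowing_date = start, harvest_date = start + 100,
       n_schedule = sched, residue_fraction = residue)
}

# n flooded days at `depth` followed by drained days at -3 cm
step_series <- function(n_flood, n_total = 100, depth = 3, field_id = "F1") {
  make_series(c(rep(depth, n_flood), rep(-3, n_total - n_flood)),
              field_id = field_id)
}

test_that("water-series generation is deterministic and respects bounds", {
  arch <- paddy_archetypes("dry")[["dry-c3"]]
  a <- generate_water_series(arch, 3, "2022-07-06", "2022-11-02", seed = 5)
  b <- generate_water_series(arch, 3, "2022-07-06", "2022-11-02", seed = 5)
  expect_identical(a, b)
  expect_true(all(a$level_cm >= -15 & a$level_cm <= 25))
  expect_s3_class(validate_water_series(a), "tbl_df")
  expect_error(generate_water_series(arch, 1, "2022-07-06", "2022-08-01"),
               "60 days")
})

test_that("a never-irrigated archetype below the surface never floods", {
  arch <- archetype_spec("drysink",
                         tibble::tibble(day = c(0, 119), level_cm = c(-12, -12)),
                         noise_sd_cm = 0.5, ar1_rho = 0.3,
                         irrigation_rate_per_week = 0,
                         irrigation_pulse_cm = 0, recession_cm_per_day = 1)
  w <- generate_water_series(arch, 10, "2022-07-06", "2022-11-02", seed = 2)
  d <- compute_descriptors(w)
  expect_true(all(d$A1 == 0))
})

test_that("wet ponded archetypes are flooded longer than dry drained ones", {
  season <- scenario_season("wet")
  wet5 <- generate_water_series(paddy_archetypes("wet")[["wet-c5"]], 50,
                                season$start, season$end, seed = 31)
  season <- scenario_season("dry")
  dry1 <- generate_water_series(paddy_archetypes("dry")[["dry-c1"]], 50,
                                season$start, season$end, seed = 31)
  expect_gt(mean(compute_descriptors(wet5)$A1),
            mean(compute_descriptors(dry1)$A1))
})

test_that("synthetic soils satisfy the soil invariants and the BD fraction", {
  s <- generate_soils(100, seed = 4)
  expect_equal(nrow(s), 100)
  expect_true(all(abs(s$clay_pct + s$silt_pct + s$sand_pct - 100) < 1e-9))
  expect_true(all(s$clay_pct >= 10 & s$clay_pct <= 45))
  expect_identical(s, generate_soils(100, seed = 4))
  none <- generate_soils(20, seed = 4, fraction_with_bd = 0)
  expect_true(all(is.na(none$bd_g_cm3)))
})

test_that("surrogate CH4 vanishes for never-flooded fields and is monotone", {
  soils <- generate_soils(1, seed = 1, field_ids = "F1")
  dry <- make_series(rep(-3, 100))
  em <- surrogate_emissions(dry, soils, std_mgmt(), noise = FALSE)
  expect_equal(em$ch4_kg_ha, 0)

  # increasing flooded fraction, deep-water fraction, residue all raise CH4
  p <- surrogate_params()
  ch4_at <- function(n_flood, depth, residue) {
    w <- step_series(n_flood, depth = depth)
    surrogate_emissions(w, soils, std_mgmt(residue = residue),
                        params = p, noise = FALSE)$ch4_kg_ha
  }
  expect_lt(ch4_at(30, 3, 0), ch4_at(50, 3, 0))
  expect_lt(ch4_at(50, 3, 0), ch4_at(50, 12, 0))
  expect_lt(ch4_at(50, 3, 0), ch4_at(50, 3, 1))
})

test_that("the flooded-fraction exponent is recovered by log-log regression", {
  soils <- generate_soils(8, seed = 2, field_ids = sprintf("F%03d", 1:8))
  w <- dplyr::bind_rows(purrr::map(1:8, function(i) {
    step_series(10 * i, depth = 3, field_id = sprintf("F%03d", i))
  }))
  em <- surrogate_emissions(w, soils, std_mgmt(), noise = FALSE)
  a1 <- compute_descriptors(w)$A1 / 100
  fit <- lm(log(em$ch4_kg_ha) ~ log(a1))
  expect_equal(unname(coef(fit)[2]), surrogate_params()$ch4_gamma,
               tolerance = 1e-6)
  expect_equal(unname(exp(coef(fit)[1])),
               surrogate_params()$ch4_max_kg_ha, tolerance = 1e-6)
})

test_that("N2O responds to rate, suppresses flooded doses, and scales with clay", {
  soils <- generate_soils(1, seed = 1, field_ids = "F1")
  dry <- make_series(rep(-3, 100))  # never flooded: all doses effective
  base <- surrogate_emissions(dry, soils, std_mgmt(), noise = FALSE)
  doubled <- surrogate_emissions(
    dry, soils, std_mgmt(sched = scale_n_schedule(n_schedule_preset(), 2)),
    noise = FALSE
  )
  expect_gt(doubled$n2o_g_ha, base$n2o_g_ha)

  # permanently flooded on all application days: only the baseline term remains
  wet <- make_series(rep(4, 100))
  em_wet <- surrogate_emissions(wet, soils, std_mgmt(), noise = FALSE)
  em_wet2 <- surrogate_emissions(
    wet, soils, std_mgmt(sched = scale_n_schedule(n_schedule_preset(), 2)),
    noise = FALSE
  )
  expect_equal(em_wet$n2o_g_ha, em_wet2$n2o_g_ha)
  expect_lt(em_wet$n2o_g_ha, base$n2o_g_ha)

  clay_hi <- soils
  clay_hi$clay_pct <- soils$clay_pct + 20
  clay_hi$silt_pct <- soils$silt_pct - 20
  expect_gt(surrogate_emissions(dry, clay_hi, std_mgmt(), noise = FALSE)$n2o_g_ha,
            base$n2o_g_ha)
})

test_that("wet-dry transitions near fertilization amplify N2O", {
  soils <- generate_soils(1, seed = 1, field_ids = "F1")
  calm <- make_series(rep(-3, 100))
  # flood/drain cycling in the +-7 day windows around days 0, 25, 55
  lv <- rep(-3, 100)
  lv[c(2, 4, 6, 24, 26, 28, 54, 56, 58)] <- 3
  flashy <- make_series(lv)
  em_calm <- surrogate_emissions(calm, soils, std_mgmt(), noise = FALSE)
  em_flashy <- surrogate_emissions(flashy, soils, std_mgmt(), noise = FALSE)
  expect_gt(em_flashy$n2o_g_ha, em_calm$n2o_g_ha)
})

test_that("landscapes have the requested size, are reproducible, and rank wet > dry", {
  wet <- generate_landscape("wet", 15, seed = 3)
  dry <- generate_landscape("dry", 15, seed = 3)
  expect_equal(nrow(wet$truth), 15)
  expect_equal(length(unique(wet$water$field_id)), 15)
  expect_equal(nrow(wet$emissions), 15)
  expect_gt(mean(wet$emissions$ch4_kg_ha), mean(dry$emissions$ch4_kg_ha))

  again <- generate_landscape("wet", 15, seed = 3)
  expect_identical(wet$water, again$water)
  expect_identical(wet$emissions, again$emissions)

  expect_error(generate_landscape("wet", 15, seed = 1,
                                  weights = c(`wet-c1` = 0.6, `wet-c2` = 0.6)),
               "sum to 1")
  expect_error(generate_landscape("wet", 5, seed = 1), "at least 10")
})
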