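mgmt_for <- function(start, residue = 0) {
  list(sowing_date = start, harvest_date = start + 100,
       n_schedule = n_schedule_preset(), residue_fraction = residue)
}

# two hand-built medoid fields: a dry one and a deeply flooded one, neither
# flooded on the N application days (0, 25, 55)
two_field_fixture <- function() {
  start <- as.Date("2022-07-01")
  lv_dry <- rep(-3, 100); lv_dry[30:45] <- 3          # short shallow flood
  lv_wet <- rep(-3, 100); lv_wet[c(3:24, 57:95)] <- 12  # long deep floods
  water <- dplyr::bind_rows(
    make_series(lv_dry, "dry-f", start),
    make_series(lv_wet, "wet-f", start)
  )
  soils <- generate_soils(2, seed = 5, field_ids = c("dry-f", "wet-f"))
  medoids <- tibble::tibble(cluster = 1:2, field_id = c("dry-f", "wet-f"))
  list(water = water, soils = soils, medoids = medoids,
       mgmt = mgmt_for(start))
}

test_that("medoids are the members nearest their centroid, ties to smallest id", {
  set.seed(14)
  d <- synthetic_descriptor_table(9, c(rnorm(4, 0), rnorm(5, 50)))
  fit <- cluster_fields(d, k = 2, seed = 1)
  sc <- standardize_descriptors(d)
  med <- find_medoids(fit, sc$xz)
  expect_equal(nrow(med), 2)
  for (i in 1:2) {
    members <- fit$assignments$field_id[fit$assignments$cluster == i]
    dists <- sqrt(rowSums(sweep(sc$xz[members, , drop = FALSE], 2,
                                fit$centroids[i, ])^2))
    expect_equal(med$field_id[i], members[which.min(dists)])
  }

  # symmetric pair equidistant from the centroid: smaller id wins
  d2 <- tibble::tibble(field_id = c("b", "a"))
  for (nm in paddyghg:::DESCRIPTOR_NAMES) d2[[nm]] <- c(1, -1)
  fit2 <- suppressWarnings(cluster_fields(d2, k = 1, seed = 1))
  sc2 <- suppressWarnings(standardize_descriptors(d2))
  expect_equal(find_medoids(fit2, sc2$xz)$field_id, "a")

  # singleton cluster returns its only member
  d3 <- synthetic_descriptor_table(5, c(0, 0, 0, 0, 80))
  fit3 <- cluster_fields(d3, k = 2, seed = 1)
  sc3 <- standardize_descriptors(d3)
  med3 <- find_medoids(fit3, sc3$xz)
  single <- names(which(table(fit3$assignments$cluster) == 1))
  if (length(single)) {
    expect_equal(
      med3$field_id[med3$cluster == as.integer(single)],
      fit3$assignments$field_id[fit3$assignments$cluster == as.integer(single)]
    )
  }
})

test_that("grid construction validates its design points", {
  g <- scenario_grid()
  expect_equal(g$n_multipliers, c(1, 1.25, 1.5, 1.75, 2))
  expect_equal(g$residue_fractions, c(0, 0.25, 0.5, 0.75, 1))
  expect_error(scenario_grid(n_multipliers = c(1.25, 1.5)), "include 1")
  expect_error(scenario_grid(residue_fractions = c(0.5, 1.5)), "\\[0, 1\\]")
})

test_that("the noise-free grid is complete, anchored, and follows the model structure", {
  fx <- two_field_fixture()
  out <- run_sensitivity_grid(fx$water, fx$soils, fx$medoids, fx$mgmt,
                              grid = scenario_grid(noise = FALSE), seed = 1)
  expect_equal(nrow(out), 2 * 25)
  expect_equal(dplyr::count(out, field_id)$n, c(25, 25))

  base <- out[out$n_multiplier == 1 & out$residue_fraction == 0, ]
  expect_equal(base$delta_ch4_kg_ha, c(0, 0))
  expect_equal(base$delta_n2o_g_ha, c(0, 0))

  # CH4 does not respond to N rate; N2O rises strictly with it at every cell
  for (f in c("dry-f", "wet-f")) {
    sub <- out[out$field_id == f, ]
    for (r in unique(sub$residue_fraction)) {
      cells <- sub[sub$residue_fraction == r, ]
      cells <- cells[order(cells$n_multiplier), ]
      expect_equal(diff(cells$ch4_kg_ha), rep(0, 4))
      expect_true(all(diff(cells$n2o_g_ha) > 0))
    }
    # CH4 rises with residue retention at fixed N
    cells <- sub[sub$n_multiplier == 1, ]
    cells <- cells[order(cells$residue_fraction), ]
    expect_true(all(diff(cells$ch4_kg_ha) > 0))
  }

  # the wetter medoid gains more CH4 from full residue return
  gain <- function(f) {
    sub <- out[out$field_id == f & out$n_multiplier == 1, ]
    sub$ch4_kg_ha[sub$residue_fraction == 1] -
      sub$ch4_kg_ha[sub$residue_fraction == 0]
  }
  expect_gt(gain("wet-f"), gain("dry-f"))

  # determinism with noise off
  again <- run_sensitivity_grid(fx$water, fx$soils, fx$medoids, fx$mgmt,
                                grid = scenario_grid(noise = FALSE), seed = 99)
  expect_equal(out$ch4_kg_ha, again$ch4_kg_ha)

  expect_error(
    run_sensitivity_grid(fx$water, fx$soils,
                         tibble::tibble(cluster = 1, field_id = "ghost"),
                         fx$mgmt),
    "ghost"
  )
})

test_that("replicated noisy cells agree with the noise-free mean within sampling error", {
  fx <- two_field_fixture()
  noisy <- run_sensitivity_grid(
    fx$water, fx$soils, fx$medoids, fx$mgmt,
    grid = scenario_grid(noise = TRUE, replicates = 200), seed = 7
  )
  clean <- run_sensitivity_grid(fx$water, fx$soils, fx$medoids, fx$mgmt,
                                grid = scenario_grid(noise = FALSE), seed = 7)
  m <- dplyr::inner_join(
    noisy, clean, by = c("field_id", "n_multiplier", "residue_fraction"),
    suffix = c("_n", "_c")
  )
  m <- m[m$ch4_kg_ha_c > 0, ]
  # lognormal mean exceeds the median by exp(sd^2/2); allow 2 SE around that
  infl <- exp(surrogate_params()$ch4_noise_sd_log^2 / 2)
  expect_true(all(
    abs(m$ch4_kg_ha_n - m$ch4_kg_ha_c * infl) <=
      2.5 * m$ch4_sd_n / sqrt(200) + 0.02 * m$ch4_kg_ha_c
  ))
})
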