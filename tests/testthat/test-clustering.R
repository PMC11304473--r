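# descriptor table whose fields form k Gaussian blobs along several descriptors
blob_descriptors <- function(n_per, centers, sd = 0.5) {
  k <- length(centers)
  purrr::map_dfr(seq_len(k), function(i) {
    out <- tibble::tibble(field_id = sprintf("B%d-%03d", i, seq_len(n_per)))
    for (nm in paddyghg:::DESCRIPTOR_NAMES) {
      out[[nm]] <- rnorm(n_per, centers[i], sd)
    }
    out
  })
}

test_that("standardization centers, scales, and flags degenerate columns", {
  d <- blob_descriptors(10, c(0, 5))
  sc <- standardize_descriptors(d)
  expect_equal(unname(colMeans(sc$xz)), rep(0, 17), tolerance = 1e-12)
  expect_equal(unname(apply(sc$xz, 2, sd)), rep(1, 17), tolerance = 1e-12)

  # two-point column standardizes to +-1/sqrt(2) with the n-1 denominator
  d2 <- d[1:2, ]
  d2$A1 <- c(0, 100)
  z <- standardize_descriptors(d2)$xz[, "A1"]
  expect_equal(unname(z), c(-1, 1) / sqrt(2))

  # standardizing an already standardized table is idempotent
  dz <- d
  dz[paddyghg:::DESCRIPTOR_NAMES] <- as.data.frame(sc$xz)
  expect_equal(standardize_descriptors(dz)$xz, sc$xz, tolerance = 1e-12)

  dc <- d
  dc$C3 <- 5
  expect_warning(scc <- standardize_descriptors(dc), "C3")
  expect_true(all(scc$xz[, "C3"] == 0))

  dm <- d
  dm$A2[3] <- NA
  expect_error(standardize_descriptors(dm), d$field_id[3])
})

test_that("K-means separates blobs and hits the degenerate pseudo-R2 limits", {
  set.seed(42)
  d <- blob_descriptors(20, c(0, 6))
  sc <- standardize_descriptors(d)
  scl <- list(center = sc$center, scale = sc$scale)
  fit <- kmeans_fit(sc$xz, 2, seed = 1, scaling = scl)
  expect_gt(fit$pseudo_r2, 0.9)
  expect_gt(fit$mean_silhouette, 0.6)
  expect_equal(sort(fit$sizes), c(20, 20))

  expect_equal(kmeans_fit(sc$xz[1:8, ], 8, seed = 1)$pseudo_r2, 1)
  expect_equal(kmeans_fit(sc$xz, 1, seed = 1)$pseudo_r2, 0)
})

test_that("pseudo-R2 is nondecreasing in k on the same data", {
  set.seed(17)
  d <- blob_descriptors(15, c(0, 3, 7))
  sc <- standardize_descriptors(d)
  r2 <- purrr::map_dbl(1:6, ~ kmeans_fit(sc$xz, .x, seed = 3)$pseudo_r2)
  expect_true(all(diff(r2) >= -1e-9))
})

test_that("cluster labels are ordered driest to wettest by centroid A1", {
  set.seed(33)
  d <- blob_descriptors(12, c(8, 1, 4))  # blob order deliberately scrambled
  fit <- cluster_fields(d, k = 3, seed = 2)
  a1_by_cluster <- dplyr::inner_join(d, fit$assignments, by = "field_id") |>
    dplyr::group_by(cluster) |>
    dplyr::summarise(a1 = mean(A1))
  expect_equal(a1_by_cluster$cluster[order(a1_by_cluster$a1)], 1:3)
  expect_equal(unname(diff(fit$centroids_raw[, "A1"]) > 0), c(TRUE, TRUE))
})

test_that("assignments are stable under permutation of the input rows", {
  set.seed(12)
  d <- blob_descriptors(15, c(0, 4, 9))
  f1 <- cluster_fields(d, k = 3, seed = 5)
  d_shuf <- d[sample(nrow(d)), ]
  f2 <- cluster_fields(d_shuf, k = 3, seed = 5)
  merged <- dplyr::inner_join(f1$assignments, f2$assignments, by = "field_id")
  expect_equal(merged$cluster.x, merged$cluster.y)
})

test_that("silhouette-based selection finds the true number of blobs", {
  set.seed(7)
  d <- blob_descriptors(20, c(0, 6))
  sc <- standardize_descriptors(d)
  sel <- select_k(sc$xz, k_range = 2:6, restarts = 20, seed = 9)
  expect_equal(sel$k, 2)
  expect_true(all(sel$silhouettes$mean_silhouette >= -1 &
                    sel$silhouettes$mean_silhouette <= 1))

  d3 <- blob_descriptors(15, c(0, 5, 10))
  sc3 <- standardize_descriptors(d3)
  expect_equal(select_k(sc3$xz, k_range = 2:6, restarts = 20, seed = 9)$k, 3)

  # a single structureless blob: silhouettes uniformly weak, any feasible k
  set.seed(5)
  x1 <- matrix(rnorm(40 * 17), 40, 17,
               dimnames = list(sprintf("F%02d", 1:40),
                               paddyghg:::DESCRIPTOR_NAMES))
  sel1 <- select_k(x1, k_range = 2:6, restarts = 20, seed = 3)
  expect_true(all(sel1$silhouettes$mean_silhouette < 0.2))
  expect_true(sel1$k %in% 2:6)
})

test_that("permutation importance singles out the informative descriptor", {
  # one informative dimension (A1, bimodal) among low-variance nuisance dims
  set.seed(21)
  n <- 60
  xz <- matrix(rnorm(n * 17, 0, 0.3), n, 17,
               dimnames = list(sprintf("F%03d", 1:n),
                               paddyghg:::DESCRIPTOR_NAMES))
  xz[, "A1"] <- xz[, "A1"] + rep(c(-1, 1), each = n / 2)
  xz[, "B6"] <- 0  # a constant descriptor cannot matter
  fit <- kmeans_fit(xz, 2, seed = 4)
  imp <- cluster_feature_importance(fit, xz, permutations = 100, seed = 1)
  expect_equal(imp$descriptor[1], "A1")
  expect_true(all(imp$importance >= 0 & imp$importance <= 1))
  expect_equal(imp$importance[imp$descriptor == "B6"], 0)

  # Monte-Carlo stability across permutation seeds
  imp2 <- cluster_feature_importance(fit, xz, permutations = 200, seed = 11)
  imp3 <- cluster_feature_importance(fit, xz, permutations = 200, seed = 12)
  m <- dplyr::inner_join(imp2, imp3, by = "descriptor")
  expect_true(all(abs(m$importance.x - m$importance.y) <= 0.02))
})

test_that("ANOVA + LSD letters separate clusters as the pooled-t arithmetic dictates", {
  # identical data in every cluster: single shared letter
  vals <- tibble::tibble(field_id = sprintf("F%02d", 1:12),
                         value = rep(5, 12))
  asg <- tibble::tibble(field_id = vals$field_id, cluster = rep(1:3, each = 4))
  res <- anova_lsd(vals, asg)
  expect_true(all(res$letters == "a"))

  # two far-separated clusters: different letters
  set.seed(3)
  vals2 <- tibble::tibble(field_id = sprintf("G%02d", 1:20),
                          value = c(rnorm(10, 0), rnorm(10, 100)))
  asg2 <- tibble::tibble(field_id = vals2$field_id,
                         cluster = rep(1:2, each = 10))
  res2 <- anova_lsd(vals2, asg2)
  expect_equal(res2$letters, c("a", "b"))
  expect_lt(attr(res2, "p_value"), 1e-10)

  # constructed a / ab / b case: unit pooled SD, means 10 / 9 / 8, n = 5:
  # LSD = t(.975, 12) * sqrt(2/5) ~= 1.38, so only the extremes differ
  base <- 0.6324555320336759 * c(-2, -1, 0, 1, 2)  # mean 0, sd exactly 1
  vals3 <- tibble::tibble(
    field_id = sprintf("H%02d", 1:15),
    value = c(base + 10, base + 9, base + 8)
  )
  asg3 <- tibble::tibble(field_id = vals3$field_id,
                         cluster = rep(c("hi", "mid", "lo"), each = 5))
  res3 <- anova_lsd(vals3, asg3)
  expect_equal(res3$cluster, factor(c("hi", "mid", "lo"),
                                    levels = c("hi", "lo", "mid")))
  expect_equal(res3$letters, c("a", "ab", "b"))

  # singleton clusters are dropped with a warning
  asg4 <- asg2
  asg4$cluster[1] <- 99
  expect_warning(anova_lsd(vals2, asg4), "excluded")
})

test_that("descriptor-emission correlations handle linear, constant and short input", {
  set.seed(6)
  d <- blob_descriptors(10, c(0, 5))
  em <- tibble::tibble(
    field_id = d$field_id,
    ch4_kg_ha = 2 * d$A1 + 7,  # exact linear function of A1
    n2o_g_ha = runif(20, 10, 400)
  )
  r <- descriptor_emission_correlations(d, em)
  expect_equal(r$r_ch4[r$descriptor == "A1"], 1, tolerance = 1e-12)

  dc <- d
  dc$C2 <- 3
  rc <- descriptor_emission_correlations(dc, em)
  expect_true(is.na(rc$r_ch4[rc$descriptor == "C2"]))

  expect_error(descriptor_emission_correlations(d[1:2, ], em), "3 matched")
})
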