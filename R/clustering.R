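#' Standardize a descriptor table for clustering
#'
#' Centers and scales each of the 17 descriptor columns to zero mean and unit
#' standard deviation (denominator n - 1). Zero-variance columns are left at
#' 0 with a warning; missing descriptor values are an error naming the fields.
#'
#' @param descriptors Tibble with `field_id` and columns `A1..A8`, `B1..B6`,
#'   `C1..C3`.
#' @return A list with `xz` (fields x 17 matrix, rownames = field ids),
#'   `center` and `scale` (named per-descriptor vectors).
#' @export
standardize_descriptors <- function(descriptors) {
  if (!all(DESCRIPTOR_NAMES %in% names(descriptors))) {
    abort("descriptor table must contain A1..A8, B1..B6, C1..C3")
  }
  if (nrow(descriptors) < 2) abort("need at least 2 fields to standardize")
  x <- as.matrix(descriptors[, DESCRIPTOR_NAMES])
  rownames(x) <- descriptors$field_id
  if (anyNA(x)) {
    bad <- descriptors$field_id[apply(x, 1, anyNA)]
    abort(paste0("missing descriptors for field(s): ",
                 paste(bad, collapse = ", ")))
  }
  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  flat <- scale == 0
  if (any(flat)) {
    warn(paste0("zero-variance descriptor(s) left at 0: ",
                paste(names(scale)[flat], collapse = ", ")))
    scale[flat] <- 1
  }
  xz <- sweep(sweep(x, 2, center), 2, scale, "/")
  list(xz = xz, center = center, scale = scale)
}

mean_silhouette <- function(xz, cl) {
  if (length(unique(cl)) < 2 || length(unique(cl)) == length(cl)) {
    return(NA_real_)  # undefined for k = 1 and for all-singleton clusterings
  }
  tryCatch(
    mean(cluster::silhouette(cl, stats::dist(xz))[, "sil_width"]),
    error = function(e) NA_real_
  )
}

#' Fit K-means hydrologic clusters in standardized descriptor space
#'
#' Lloyd's algorithm with `restarts` random initializations (centers sampled
#' from the data rows), keeping the solution with the smallest within-cluster
#' sum of squares. Restarts that end with an empty cluster are counted as
#' failed; if all restarts fail an error is raised. Cluster labels are
#' relabeled 1..k from driest to wettest by the centroids' unstandardized A1
#' (percent of season flooded).
#'
#' @param xz Standardized descriptor matrix (from
#'   [standardize_descriptors()]).
#' @param k Number of clusters (1 <= k <= number of fields).
#' @param restarts Number of seeded restarts (default 50).
#' @param seed Integer RNG seed.
#' @param scaling Optional list with `center`/`scale` used to unstandardize
#'   centroids (for A1-based label ordering and reporting).
#' @return A `paddy_clusters` object: `k`, `assignments` (tibble `field_id`,
#'   `cluster`), `centroids` (standardized), `centroids_raw` (descriptor
#'   units, when `scaling` given), `pseudo_r2` (1 - WCSS/TSS),
#'   `mean_silhouette`, `sizes`, `scaling`.
#' @export
kmeans_fit <- function(xz, k, restarts = 50, seed = 1L, scaling = NULL) {
  n <- nrow(xz)
  stopifnot(k >= 1, k <= n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- xz[sample.int(n, k), , drop = FALSE]
    fit <- tryCatch(
      suppressWarnings(
        stats::kmeans(xz, centers = centers, iter.max = 300,
                      algorithm = "Lloyd")
      ),
      error = function(e) NULL
    )
    if (is.null(fit) || any(fit$size == 0)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) abort("all K-means restarts failed (empty clusters)")

  pseudo_r2 <- if (best$totss > 0) 1 - best$tot.withinss / best$totss else 1

  # relabel driest -> wettest by unstandardized centroid A1
  cent <- best$centers
  a1 <- if (!is.null(scaling)) {
    cent[, "A1"] * scaling$scale["A1"] + scaling$center["A1"]
  } else cent[, 1]
  ord <- order(a1)
  relabel <- match(seq_len(k), ord)
  cl <- relabel[best$cluster]
  cent <- cent[ord, , drop = FALSE]
  rownames(cent) <- seq_len(k)

  centroids_raw <- if (!is.null(scaling)) {
    sweep(sweep(cent, 2, scaling$scale[colnames(cent)], "*"),
          2, scaling$center[colnames(cent)], "+")
  } else NULL

  structure(
    list(
      k = k,
      assignments = tibble::tibble(field_id = rownames(xz), cluster = cl),
      centroids = cent,
      centroids_raw = centroids_raw,
      pseudo_r2 = pseudo_r2,
      mean_silhouette = mean_silhouette(xz, cl),
      sizes = tabulate(cl, k),
      scaling = scaling
    ),
    class = "paddy_clusters"
  )
}

#' @export
print.paddy_clusters <- function(x, ...) {
  cat("<paddy_clusters> k =", x$k,
      " pseudo-R2 =", round(x$pseudo_r2, 3),
      " mean silhouette =", round(x$mean_silhouette, 3), "\n")
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Choose the number of clusters by mean silhouette
#'
#' Fits K-means for each k in `k_range` and returns the k maximizing the mean
#' silhouette width (Euclidean distance in standardized space) among
#' solutions whose smallest cluster has at least `min_size` members; ties go
#' to the smallest k.
#'
#' @inheritParams kmeans_fit
#' @param k_range Candidate cluster counts (default 2:8).
#' @param min_size Minimum admissible cluster size (default 3).
#' @return List with `k` (chosen), `silhouettes` (tibble `k`,
#'   `mean_silhouette`, `min_size_ok`) and `fits` (the fitted models, named by
#'   k).
#' @export
select_k <- function(xz, k_range = 2:8, restarts = 50, seed = 1L,
                     min_size = 3, scaling = NULL) {
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 2 & k_range <= floor(nrow(xz) / 1)]
  if (!length(k_range)) abort("no feasible k in k_range")
  fits <- purrr::map(k_range, function(k) {
    tryCatch(kmeans_fit(xz, k, restarts = restarts, seed = seed,
                        scaling = scaling),
             error = function(e) NULL)
  })
  names(fits) <- k_range
  sil <- tibble::tibble(
    k = k_range,
    mean_silhouette = purrr::map_dbl(fits, ~ if (is.null(.x)) NA_real_ else .x$mean_silhouette),
    min_size_ok = purrr::map_lgl(fits, ~ !is.null(.x) && min(.x$sizes) >= min_size)
  )
  ok <- sil$min_size_ok & !is.na(sil$mean_silhouette)
  if (!any(ok)) abort("no k in k_range yields clusters of the minimum size")
  best <- sil$k[ok][which.max(sil$mean_silhouette[ok])]  # which.max: first max -> smallest k
  list(k = best, silhouettes = sil, fits = fits)
}

#' Cluster fields from their hydrologic descriptors
#'
#' High-level wrapper: standardizes the 17 descriptors, selects k by mean
#' silhouette when `k = "auto"`, and fits the final K-means model with labels
#' ordered driest (1) to wettest (k).
#'
#' @param descriptors Descriptor tibble from [compute_descriptors()].
#' @param k `"auto"` (silhouette-based selection) or an integer.
#' @param k_range Candidate k values when `k = "auto"`.
#' @param restarts Random restarts per fit.
#' @param seed Integer RNG seed.
#' @param min_size Minimum admissible cluster size for selection.
#' @return A `paddy_clusters` object (see [kmeans_fit()]); when `k = "auto"`
#'   the per-k silhouette table is attached as `$selection`.
#' @export
cluster_fields <- function(descriptors, k = "auto", k_range = 2:8,
                           restarts = 50, seed = 1L, min_size = 3) {
  sc <- standardize_descriptors(descriptors)
  scaling <- list(center = sc$center, scale = sc$scale)
  if (identical(k, "auto")) {
    sel <- select_k(sc$xz, k_range = k_range, restarts = restarts, seed = seed,
                    min_size = min_size, scaling = scaling)
    model <- sel$fits[[as.character(sel$k)]]
    model$selection <- sel$silhouettes
    model
  } else {
    kmeans_fit(sc$xz, as.integer(k), restarts = restarts, seed = seed,
               scaling = scaling)
  }
}

nearest_centroid <- function(xz, centroids) {
  d2 <- outer(rowSums(xz^2), rowSums(centroids^2), "+") -
    2 * xz %*% t(centroids)
  max.col(-d2, ties.method = "first")
}

#' Permutation feature importance for cluster assignments
#'
#' Importance of a descriptor is the mean (over permutations) fraction of
#' fields whose nearest-centroid assignment changes when that descriptor's
#' column is randomly permuted across fields, in the spirit of
#' misclassification-based cluster feature importance.
#'
#' @param model A `paddy_clusters` object.
#' @param xz The standardized descriptor matrix the model was fitted on
#'   (e.g. `standardize_descriptors(descriptors)$xz`).
#' @param permutations Number of permutations per descriptor (default 200).
#' @param seed Integer RNG seed.
#' @return A tibble `descriptor`, `importance` (fraction in \[0, 1\]), sorted
#'   by decreasing importance.
#' @export
cluster_feature_importance <- function(model, xz, permutations = 200,
                                       seed = 1L) {
  stopifnot(inherits(model, "paddy_clusters"))
  base <- nearest_centroid(xz, model$centroids)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- nrow(xz)
  imp <- purrr::map_dbl(colnames(xz), function(j) {
    mean(purrr::map_dbl(seq_len(permutations), function(p) {
      xp <- xz
      xp[, j] <- xp[sample.int(n), j]
      mean(nearest_centroid(xp, model$centroids) != base)
    }))
  })
  tibble::tibble(descriptor = colnames(xz), importance = imp) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' One-way ANOVA with Fisher's LSD compact letter display
#'
#' Tests whether mean emissions differ between clusters and, when the overall
#' F-test is significant at `alpha`, separates cluster means by Fisher's
#' (unprotected-after-significant-F) Least Significant Difference using the
#' pooled error mean square. Letters are assigned by descending mean;
#' clusters sharing no letter differ at `alpha`. Clusters with a single
#' member are excluded with a warning.
#'
#' @param values Tibble with columns `field_id`, `value`.
#' @param assignments Tibble with columns `field_id`, `cluster`.
#' @param alpha Significance level (default 0.05).
#' @return A `paddy_lsd` tibble: `cluster`, `n`, `mean`, `letters`, with the
#'   ANOVA `f_value`, `p_value`, `alpha` as attributes.
#' @export
anova_lsd <- function(values, assignments, alpha = 0.05) {
  df <- dplyr::inner_join(values, assignments, by = "field_id")
  sizes <- table(df$cluster)
  if (any(sizes < 2)) {
    warn(paste0("cluster(s) with a single member excluded: ",
                paste(names(sizes)[sizes < 2], collapse = ", ")))
    df <- df[df$cluster %in% names(sizes)[sizes >= 2], ]
  }
  if (length(unique(df$cluster)) < 2) {
    abort("need at least 2 clusters with >= 2 members")
  }
  df$cluster <- factor(df$cluster)
  fit <- aov(value ~ cluster, data = df)
  an <- summary(fit)[[1]]
  f_value <- an[["F value"]][1]
  p_value <- an[["Pr(>F)"]][1]
  mse <- an[["Mean Sq"]][2]
  dfe <- an[["Df"]][2]

  stats_tbl <- df |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value)) |>
    dplyr::arrange(dplyr::desc(.data$mean))

  kk <- nrow(stats_tbl)
  differ <- matrix(FALSE, kk, kk)
  if (!is.na(p_value) && p_value < alpha && mse > 0) {
    tcrit <- qt(1 - alpha / 2, dfe)
    for (i in seq_len(kk - 1)) {
      for (j in (i + 1):kk) {
        lsd <- tcrit * sqrt(mse * (1 / stats_tbl$n[i] + 1 / stats_tbl$n[j]))
        differ[i, j] <- differ[j, i] <-
          abs(stats_tbl$mean[i] - stats_tbl$mean[j]) > lsd
      }
    }
  }
  stats_tbl$letters <- compact_letters(differ)
  out <- stats_tbl
  attr(out, "f_value") <- f_value
  attr(out, "p_value") <- p_value
  attr(out, "alpha") <- alpha
  class(out) <- c("paddy_lsd", class(out))
  out
}

# insert-and-absorb compact letter display; rows ordered by descending mean
compact_letters <- function(differ) {
  kk <- nrow(differ)
  groups <- list(seq_len(kk))
  for (i in seq_len(kk)) {
    for (j in seq_len(kk)) {
      if (j > i && differ[i, j]) {
        hit <- purrr::map_lgl(groups, ~ all(c(i, j) %in% .x))
        if (any(hit)) {
          split <- purrr::map(groups[hit], ~ list(setdiff(.x, i), setdiff(.x, j)))
          groups <- c(groups[!hit], purrr::flatten(split))
          # absorb groups contained in another
          keep <- purrr::map_lgl(seq_along(groups), function(g) {
            !any(purrr::map_lgl(seq_along(groups), function(h) {
              h != g && all(groups[[g]] %in% groups[[h]]) &&
                length(groups[[h]]) > length(groups[[g]])
            }))
          })
          groups <- unique(groups[keep])
        }
      }
    }
  }
  groups <- groups[order(purrr::map_dbl(groups, min))]
  out <- character(kk)
  for (g in seq_along(groups)) {
    out[groups[[g]]] <- paste0(out[groups[[g]]], letters[g])
  }
  out
}

#' @export
print.paddy_lsd <- function(x, ...) {
  cat("One-way ANOVA: F =", signif(attr(x, "f_value"), 4),
      " p =", signif(attr(x, "p_value"), 4),
      " (LSD letters at alpha =", attr(x, "alpha"), ")\n")
  NextMethod()
}

#' Pearson correlations between descriptors and seasonal emissions
#'
#' Correlates each of the 17 hydrologic descriptors with seasonal CH4 and N2O
#' across fields. Fields missing from either table are dropped listwise;
#' constant descriptors yield `NA` (undefined), never 0.
#'
#' @param descriptors Descriptor tibble.
#' @param emissions Emissions tibble.
#' @return A tibble `descriptor`, `r_ch4`, `r_n2o`.
#' @export
descriptor_emission_correlations <- function(descriptors, emissions) {
  df <- dplyr::inner_join(descriptors, emissions, by = "field_id")
  if (nrow(df) < 3) abort("need at least 3 matched fields")
  safe_cor <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
  }
  tibble::tibble(
    descriptor = DESCRIPTOR_NAMES,
    r_ch4 = purrr::map_dbl(DESCRIPTOR_NAMES, ~ safe_cor(df[[.x]], df$ch4_kg_ha)),
    r_n2o = purrr::map_dbl(DESCRIPTOR_NAMES, ~ safe_cor(df[[.x]], df$n2o_g_ha))
  )
}
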