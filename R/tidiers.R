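#' Tidy a fitted hydrologic clustering
#'
#' @param x A `paddy_clusters` object.
#' @param what `"assignments"` (default) for per-field cluster labels or
#'   `"centroids"` for a long tibble of centroid descriptor values.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.paddy_clusters <- function(x, what = c("assignments", "centroids"), ...) {
  what <- match.arg(what)
  if (what == "assignments") return(x$assignments)
  cent <- if (!is.null(x$centroids_raw)) x$centroids_raw else x$centroids
  tibble::as_tibble(cent) |>
    dplyr::mutate(cluster = seq_len(x$k), .before = 1) |>
    tidyr::pivot_longer(-"cluster", names_to = "descriptor",
                        values_to = "value")
}

#' One-row summary of a fitted hydrologic clustering
#'
#' @param x A `paddy_clusters` object.
#' @param ... Unused.
#' @return Tibble with `k`, `n`, `pseudo_r2`, `mean_silhouette`,
#'   `min_cluster_size`.
#' @export
glance.paddy_clusters <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n = nrow(x$assignments),
    pseudo_r2 = x$pseudo_r2,
    mean_silhouette = x$mean_silhouette,
    min_cluster_size = min(x$sizes)
  )
}

#' Tidy an emission-level classifier (Gini importances)
#'
#' @param x A `paddy_classifier` object.
#' @param ... Unused.
#' @return Tibble `descriptor`, `gini_importance`, sorted descending.
#' @export
tidy.paddy_classifier <- function(x, ...) {
  x$gini_importance
}

#' One-row summary of an emission-level classifier
#'
#' @param x A `paddy_classifier` object.
#' @param ... Unused.
#' @return Tibble with `oob_error`, `test_accuracy`, `n_train`, `n_test`,
#'   `tree_leaves`.
#' @export
glance.paddy_classifier <- function(x, ...) {
  tibble::tibble(
    oob_error = x$oob_error,
    test_accuracy = x$test_accuracy,
    n_train = x$n_train,
    n_test = x$n_test,
    tree_leaves = sum(x$tree$frame$var == "<leaf>")
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
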