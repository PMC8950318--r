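#' Cosine distance between profile rows
#'
#' `1 - cosine similarity` between every pair of rows. Profiles that are
#' positive multiples of one another are at distance 0, orthogonal profiles
#' at 1, opposite profiles at 2.
#'
#' @param profiles Numeric matrix, one profile per row; no all-zero rows.
#' @return A [stats::dist] object.
#' @export
cosine_distance <- function(profiles) {
  profiles <- as.matrix(profiles)
  norms <- sqrt(rowSums(profiles^2))
  if (any(norms == 0)) abort("cosine distance undefined for all-zero profile")
  sim <- tcrossprod(profiles / norms)
  sim <- pmin(pmax(sim, -1), 1)
  as.dist(1 - sim)
}

#' Hierarchically cluster temporal response profiles
#'
#' Agglomerative clustering of per-feature log2 fold-change profiles across
#' (dose, time) conditions, under cosine distance with complete linkage:
#' profiles group by the *shape* of their dose-time response, not its
#' magnitude. Deterministic given input order ([stats::hclust()] ties break
#' by merge order).
#'
#' @param profiles Numeric matrix (features x conditions, e.g. from
#'   [profile_matrix()]), at least 2 rows, no all-zero row.
#' @return An [stats::hclust()] merge record.
#' @export
cluster_profiles <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2) abort("need >= 2 profiles to cluster")
  hclust(cosine_distance(profiles), method = "complete")
}

#' Davies-Bouldin cluster-validity index
#'
#' `DB = mean_i max_{j != i} (S_i + S_j) / M_ij` where `S_i` is the mean
#' Euclidean distance of cluster i's points to their centroid and `M_ij`
#' the distance between centroids i and j. Lower is better. Coincident
#' centroids give `Inf` with a warning.
#'
#' @param points Numeric matrix, one point per row.
#' @param labels Cluster assignment per row; every cluster non-empty,
#'   at least 2 clusters.
#' @return The index (non-negative scalar).
#' @examples
#' davies_bouldin(matrix(c(0, 1, 10, 11)), c(1, 1, 2, 2))
#' @export
davies_bouldin <- function(points, labels) {
  points <- as.matrix(points)
  if (nrow(points) != length(labels)) {
    abort("labels must match the number of points")
  }
  groups <- split(seq_len(nrow(points)), labels)
  k <- length(groups)
  if (k < 2) abort("Davies-Bouldin requires >= 2 clusters")

  centroids <- do.call(rbind, lapply(groups, function(i) {
    colMeans(points[i, , drop = FALSE])
  }))
  scatter <- vapply(seq_len(k), function(i) {
    d <- sweep(points[groups[[i]], , drop = FALSE], 2, centroids[i, ])
    mean(sqrt(rowSums(d^2)))
  }, numeric(1))

  sep <- as.matrix(dist(centroids))
  if (any(sep[upper.tri(sep)] == 0)) {
    warn("coincident cluster centroids: Davies-Bouldin index is infinite")
  }
  ratio <- outer(scatter, scatter, `+`) / sep
  ratio[sep == 0] <- Inf  # coincident centroids dominate regardless of scatter
  diag(ratio) <- -Inf
  mean(apply(ratio, 1, max))
}

#' Choose the optimal clustering partition by Davies-Bouldin
#'
#' Cuts the linkage from [cluster_profiles()] at every candidate number of
#' clusters and keeps the cut with the lowest Davies-Bouldin index
#' (ties go to the smallest k). The index is evaluated on the profile
#' coordinates with Euclidean geometry.
#'
#' @param profiles Feature-by-condition matrix, as for [cluster_profiles()].
#' @param k_range Candidate cluster counts, a subset of
#'   `2:(nrow(profiles) - 1)`. Default `2:min(12, n - 1)`.
#' @return A `cf_partition` list: `k`, `labels` (named by feature),
#'   `db_index`, `db_by_k` (tibble of all candidates), `linkage`
#'   (the hclust record) and `profiles`.
#' @export
optimal_partition <- function(profiles, k_range = NULL) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  k_range <- k_range %||% seq(2, min(12, n - 1))
  if (length(k_range) == 0) abort("k_range is empty")
  if (any(k_range < 2) || any(k_range > n - 1)) {
    abort("k_range must lie within [2, n_features - 1]")
  }
  hc <- cluster_profiles(profiles)
  db_by_k <- purrr::map_dfr(sort(unique(k_range)), function(k) {
    tibble(k = k, db_index = davies_bouldin(profiles, cutree(hc, k = k)))
  })
  best <- db_by_k$k[which.min(db_by_k$db_index)]
  structure(
    list(k = best, labels = cutree(hc, k = best),
         db_index = db_by_k$db_index[db_by_k$k == best],
         db_by_k = db_by_k, linkage = hc, profiles = profiles),
    class = "cf_partition"
  )
}

#' @export
print.cf_partition <- function(x, ...) {
  cat(sprintf(
    "Optimal partition: k = %d clusters (Davies-Bouldin %.3f) over %d profiles\n",
    x$k, x$db_index, nrow(x$profiles)))
  print(table(x$labels))
  invisible(x)
}

#' @export
tidy.cf_partition <- function(x, ...) {
  tibble(feature = names(x$labels), cluster = unname(x$labels))
}

#' @export
glance.cf_partition <- function(x, ...) {
  tibble(k = x$k, db_index = x$db_index, n_profiles = nrow(x$profiles))
}

#' @export
autoplot.cf_partition <- function(object, ...) {
  ord <- object$linkage$order
  long <- as_tibble(object$profiles, rownames = "feature") |>
    dplyr::mutate(cluster = factor(object$labels[.data$feature]),
                  feature = factor(.data$feature,
                                   levels = rownames(object$profiles)[ord])) |>
    tidyr::pivot_longer(-c("feature", "cluster"),
                        names_to = "condition", values_to = "lfc")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$feature,
                                     fill = .data$lfc)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$cluster),
                        scales = "free_y", space = "free_y") +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 FC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
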