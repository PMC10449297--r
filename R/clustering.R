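#' Standardized feature matrix for clustering
#'
#' Builds the cells x features matrix the clustering works on:
#' `log2(FPKM + 1)` of the selected genes, then a per-gene z-score across
#' cells. Zero-variance genes cannot be standardized and are dropped with
#' a warning.
#'
#' @param m An [fpkm_matrix].
#' @param feature_genes Gene symbols (intersected with the matrix).
#' @return Numeric matrix, cells as rows, retained features as columns.
#' @export
feature_matrix <- function(m, feature_genes) {
  stopifnot(inherits(m, "fpkm_matrix"))
  feature_genes <- intersect(feature_genes, rownames(m$values))
  if (!length(feature_genes)) stop("No feature genes present in the matrix.",
                                   call. = FALSE)
  x <- t(log2(m$values[feature_genes, , drop = FALSE] + 1))
  sds <- apply(x, 2, stats::sd)
  if (all(sds == 0)) stop("All feature genes have zero variance.", call. = FALSE)
  if (any(sds == 0)) {
    warning("Dropping zero-variance feature(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Agglomerative clustering of cells at a fixed cluster number
#'
#' Ward-linkage hierarchical clustering (`ward.D2`) on Euclidean distances
#' over the feature matrix, cut at `k` clusters. Deterministic for a fixed
#' input. Cluster indices are assigned by decreasing cluster size, ties
#' broken by the lexicographically smallest member cell id, so labels are
#' stable under permutations of the input cells.
#'
#' @param features Cells x features matrix (rownames = cell ids), e.g.
#'   from [feature_matrix()].
#' @param k Number of clusters, `1 <= k <= n_cells`.
#' @param method `"ward"` (default) or `"kmeans"` (Hartigan-Wong with a
#'   fixed internal seed).
#' @return Named integer vector: cluster index in `1..k` per cell.
#' @export
cluster_cells <- function(features, k, method = c("ward", "kmeans")) {
  method <- match.arg(method)
  n <- nrow(features)
  if (k < 1 || k > n) stop("`k` must be in 1..n_cells.", call. = FALSE)
  if (k == 1) {
    return(stats::setNames(rep(1L, n), rownames(features)))
  }
  raw <- if (method == "ward") {
    stats::cutree(stats::hclust(stats::dist(features), method = "ward.D2"), k)
  } else {
    withr::with_seed(1L, stats::kmeans(features, centers = k, nstart = 10)$cluster)
  }
  names(raw) <- rownames(features)
  canonicalize_labels(raw)
}

# relabel clusters: 1 = largest, ties by smallest member cell id
canonicalize_labels <- function(raw) {
  first_member <- vapply(split(names(raw), raw),
                         function(ids) min(ids), character(1))
  ord <- order(-tabulate(raw, nbins = max(raw)), first_member)
  new <- integer(max(raw))
  new[as.integer(names(first_member))[ord]] <- seq_along(ord)
  stats::setNames(new[raw], names(raw))
}

# mean silhouette width for a labelling (cluster::silhouette)
avg_silhouette <- function(d, labels) {
  if (length(unique(labels)) < 2) return(0)
  mean(cluster::silhouette(as.integer(labels), d)[, "sil_width"])
}

#' Silhouette-selected clustering
#'
#' Clusters the cells at every candidate `k`, scores each partition by the
#' average silhouette width `s(i) = (b(i) - a(i)) / max(a(i), b(i))` under
#' Euclidean distance, and keeps the `k` with the largest average width.
#' `k = 1` has no defined silhouette and is assigned width 0 by
#' convention, so any real structure at `k >= 2` wins; ties go to the
#' smallest `k`. Candidates outside `[2, n_cells - 1]` cannot be scored
#' and only participate through the `k = 1` convention.
#'
#' @inheritParams cluster_cells
#' @param k_range Integer candidates (default `1:10`).
#' @return An object of class `cluster_model`: list with `k_selected`,
#'   `labels` (named integer vector), `silhouette` (tibble `k`,
#'   `avg_silhouette`), `feature_genes`, `embedding` (tibble `cell_id`,
#'   `PC1`, `PC2`, `cluster` -- 2-D principal components, for plotting
#'   only), `method`.
#' @export
select_k_silhouette <- function(features, k_range = 1:10,
                                method = c("ward", "kmeans")) {
  method <- match.arg(method)
  n <- nrow(features)
  if (n < 3) stop("Need >= 3 cells to select a cluster number.", call. = FALSE)
  k_range <- sort(unique(as.integer(k_range)))
  ks <- k_range[k_range >= 1 & k_range <= n - 1]
  if (!length(ks)) stop("No feasible k in `k_range`.", call. = FALSE)
  d <- stats::dist(features)
  labels_by_k <- lapply(ks, function(k) cluster_cells(features, k, method))
  widths <- vapply(seq_along(ks), function(i) {
    if (ks[i] == 1) 0 else avg_silhouette(d, labels_by_k[[i]])
  }, numeric(1))
  best <- which.max(widths)   # first maximum = smallest k on ties
  labels <- labels_by_k[[best]]
  pc <- stats::prcomp(features, rank. = min(2L, ncol(features)))$x
  embedding <- tibble::tibble(cell_id = rownames(features),
                              PC1 = pc[, 1],
                              PC2 = if (ncol(pc) > 1) pc[, 2] else 0,
                              cluster = unname(labels[rownames(features)]))
  structure(list(k_selected = ks[best], labels = labels,
                 silhouette = tibble::tibble(k = ks, avg_silhouette = widths),
                 feature_genes = colnames(features),
                 embedding = embedding, method = method),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> %d cells, k = %d (avg silhouette %.3f)\n",
              length(x$labels), x$k_selected,
              x$silhouette$avg_silhouette[x$silhouette$k == x$k_selected]))
  print(table(cluster = x$labels))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
#' @rdname select_k_silhouette
#' @param x A `cluster_model`.
#' @param ... Unused.
tidy.cluster_model <- function(x, ...) {
  tibble::tibble(cell_id = names(x$labels), cluster = unname(x$labels))
}

#' @exportS3Method generics::glance
#' @rdname select_k_silhouette
glance.cluster_model <- function(x, ...) {
  tibble::tibble(k_selected = x$k_selected,
                 avg_silhouette = x$silhouette$avg_silhouette[
                   x$silhouette$k == x$k_selected],
                 n_cells = length(x$labels),
                 n_features = length(x$feature_genes),
                 method = x$method)
}

#' Label clusters as FAM46C-low or FAM46C-high
#'
#' The cluster with the highest mean FAM46C (`log2(FPKM + 1)`) is the high
#' group; every other cluster is merged into the low group (matching the
#' C1 + C3 vs C2 structure seen in three-cluster patients). The low-vs-high
#' difference is quantified by a two-sided unpaired t test on the merged
#' groups; the labelling itself never depends on significance.
#'
#' @param m The [fpkm_matrix] the labels refer to (BMMCs).
#' @param labels Named cluster vector, e.g. from a `cluster_model`.
#' @param fam46c_gene Gene symbol (default `"FAM46C"`).
#' @return A list of class `fam46c_grouping`: `group_of_cluster` (named
#'   "low"/"high" per cluster), `fam46c_mean_by_cluster`, `merged_low`,
#'   `merged_high` (cluster index vectors), `p_value_low_vs_high`.
#' @export
label_fam46c_groups <- function(m, labels, fam46c_gene = "FAM46C") {
  stopifnot(inherits(m, "fpkm_matrix"))
  if (!fam46c_gene %in% rownames(m$values)) {
    stop("Gene not found: ", fam46c_gene, call. = FALSE)
  }
  cells <- names(labels)
  stopifnot(all(cells %in% colnames(m$values)))
  lf <- log2(m$values[fam46c_gene, cells] + 1)
  means <- vapply(split(lf, labels), mean, numeric(1))
  high <- as.integer(names(means)[which.max(means)])
  clusters <- as.integer(names(means))
  group <- stats::setNames(ifelse(clusters == high, "high", "low"),
                           names(means))
  low_vals <- lf[labels[cells] != high]
  high_vals <- lf[labels[cells] == high]
  p <- if (length(low_vals) >= 2 && length(high_vals) >= 2) {
    two_group_t(low_vals, high_vals)$p
  } else {
    NA_real_
  }
  structure(list(group_of_cluster = group,
                 fam46c_mean_by_cluster = means,
                 merged_low = clusters[clusters != high],
                 merged_high = high,
                 p_value_low_vs_high = p),
            class = "fam46c_grouping")
}

#' @export
print.fam46c_grouping <- function(x, ...) {
  cat("<fam46c_grouping> high:", paste(x$merged_high, collapse = ","),
      " low:", paste(x$merged_low, collapse = ","), "\n")
  print(round(x$fam46c_mean_by_cluster, 3))
  cat(sprintf("low vs high t-test p = %.3g\n", x$p_value_low_vs_high))
  invisible(x)
}
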