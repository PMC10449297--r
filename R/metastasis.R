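#' Pearson correlation between every CPC and every BMMC
#'
#' Correlates `log2(FPKM + 1)` profiles over a shared gene set for every
#' CPC-BMMC pair of one patient. Cells whose profile has zero variance
#' over the gene set cannot be correlated; their entries are `NaN` and a
#' warning is raised (they are later excluded from the argmax).
#'
#' @param cpc,bmmc [fpkm_matrix] objects (typically compartment subsets of
#'   one patient's matrix).
#' @param genes Shared gene symbols to correlate over (`>= 3`).
#' @return Numeric matrix of Pearson r, CPCs as rows, BMMCs as columns.
#' @export
correlation_matrix <- function(cpc, bmmc, genes) {
  stopifnot(inherits(cpc, "fpkm_matrix"), inherits(bmmc, "fpkm_matrix"))
  genes <- intersect(intersect(genes, rownames(cpc$values)),
                     rownames(bmmc$values))
  if (length(genes) < 3) stop("Need >= 3 shared genes.", call. = FALSE)
  a <- log2(cpc$values[genes, , drop = FALSE] + 1)
  b <- log2(bmmc$values[genes, , drop = FALSE] + 1)
  flat_a <- apply(a, 2, stats::sd) == 0
  flat_b <- apply(b, 2, stats::sd) == 0
  if (any(flat_a) || any(flat_b)) {
    warning("Zero-variance cell profile(s): ",
            paste(c(colnames(a)[flat_a], colnames(b)[flat_b]), collapse = ", "),
            call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(a, b))  # columns of a (CPCs) x columns of b
  r[flat_a, ] <- NaN
  r[, flat_b] <- NaN
  r
}

#' Assign each CPC to its best-correlated BMMC
#'
#' Every CPC is assigned the BMMC with the largest finite Pearson r in its
#' row -- the "possible contributor" of that circulating cell. Ties are
#' broken deterministically towards the lexicographically smallest BMMC id
#' and flagged. A BMMC may receive zero, one, or many CPCs. CPCs whose row
#' holds no finite value are dropped with a warning (they do not count
#' towards C_p).
#'
#' @param corr CPC x BMMC correlation matrix from [correlation_matrix()].
#' @return Tibble: `cpc_id`, `bmmc_id`, `pearson_r`, `tie` (logical).
#' @export
assign_best_match <- function(corr) {
  stopifnot(is.matrix(corr), !is.null(rownames(corr)), !is.null(colnames(corr)))
  bmmc_order <- order(colnames(corr))
  rows <- lapply(rownames(corr), function(cpc) {
    r <- corr[cpc, bmmc_order]
    finite <- is.finite(r)
    if (!any(finite)) return(NULL)
    best <- max(r[finite])
    hits <- names(r)[finite & r == best]
    tibble::tibble(cpc_id = cpc, bmmc_id = hits[1], pearson_r = best,
                   tie = length(hits) > 1)
  })
  dropped <- rownames(corr)[vapply(rows, is.null, logical(1))]
  if (length(dropped)) {
    warning("CPC(s) with no finite correlation dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  dplyr::bind_rows(rows)
}

#' Per-BMMC metastasis rates M_j = C_j / C_p
#'
#' `C_j` counts the CPCs assigned to BMMC j (zero for BMMCs no CPC
#' matched) and `C_p` is the number of CPCs analysed, so the rates sum to
#' one over the BMMCs.
#'
#' @param assignments Tibble from [assign_best_match()].
#' @param bmmc_ids All BMMC cell ids of the patient (unmatched cells get
#'   `C_j = 0`).
#' @return Tibble: `bmmc_id`, `c_j`, `m_j`.
#' @export
metastasis_rates <- function(assignments, bmmc_ids) {
  c_p <- nrow(assignments)
  if (c_p == 0) stop("No assigned CPCs (C_p = 0).", call. = FALSE)
  counts <- table(factor(assignments$bmmc_id, levels = bmmc_ids))
  tibble::tibble(bmmc_id = bmmc_ids, c_j = as.integer(counts),
                 m_j = as.integer(counts) / c_p)
}

#' Contribution of each FAM46C group to extramedullary metastasis
#'
#' The contribution of a group (low/high) is the fraction of CPCs whose
#' assigned BMMC belongs to that group.
#'
#' @param assignments Tibble from [assign_best_match()].
#' @param grouping A `fam46c_grouping` from [label_fam46c_groups()].
#' @param labels Named cluster vector covering every assigned BMMC.
#' @return Tibble: `group`, `n_cpc`, `fraction`, `percent` (rounded to one
#'   decimal).
#' @export
cluster_contributions <- function(assignments, grouping, labels) {
  unlabeled <- setdiff(assignments$bmmc_id, names(labels))
  if (length(unlabeled)) {
    stop("Assigned BMMC(s) without a cluster label: ",
         paste(unlabeled, collapse = ", "), call. = FALSE)
  }
  cl <- labels[assignments$bmmc_id]
  grp <- grouping$group_of_cluster[as.character(cl)]
  counts <- table(factor(grp, levels = c("low", "high")))
  tibble::tibble(group = names(counts), n_cpc = as.integer(counts),
                 fraction = as.integer(counts) / nrow(assignments),
                 percent = round(100 * as.integer(counts) / nrow(assignments), 1))
}

#' Compare per-BMMC metastasis rates between FAM46C groups
#'
#' Two-sided Mann-Whitney test of the `M_j` values of low-group vs
#' high-group BMMCs; positive direction means the low group has the higher
#' median rate.
#'
#' @param rates Tibble from [metastasis_rates()].
#' @param grouping A `fam46c_grouping`.
#' @param labels Named cluster vector covering the BMMCs in `rates`.
#' @return One-row tibble: `test`, `statistic`, `p_value`, `direction`, or
#'   zero rows (with a warning) when a group is empty.
#' @export
compare_rates_by_group <- function(rates, grouping, labels) {
  grp <- grouping$group_of_cluster[as.character(labels[rates$bmmc_id])]
  low <- rates$m_j[grp == "low"]
  high <- rates$m_j[grp == "high"]
  if (!length(low) || !length(high)) {
    warning("A FAM46C group holds no BMMCs; rate comparison skipped.",
            call. = FALSE)
    return(tibble::tibble(test = character(0), statistic = numeric(0),
                          p_value = numeric(0), direction = numeric(0)))
  }
  if (isTRUE(all.equal(sort(low), sort(high)))) {
    ht <- list(statistic = NA_real_, p.value = 1)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(low, high))
  }
  tibble::tibble(test = "mann_whitney", statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 direction = sign(stats::median(low) - stats::median(high)))
}

#' Single-cell model of extramedullary metastasis for one patient
#'
#' Runs the full model: Pearson correlations between every CPC and BMMC,
#' best-match assignment, per-BMMC rates `M_j = C_j / C_p`, per-group
#' contribution fractions, and the low-vs-high rate comparison.
#'
#' @param m One patient's [fpkm_matrix] holding both compartments.
#' @param grouping A `fam46c_grouping` over the BMMC clusters.
#' @param labels Named cluster vector over the BMMCs.
#' @param genes Gene set for the correlations (default: all genes of `m`,
#'   which should already be the expressed set).
#' @return An object of class `metastasis_report`: list with
#'   `assignments`, `rates` (joined with cluster and group), `c_p`,
#'   `contributions`, `rate_comparison`, `patient_id`.
#' @export
metastasis_model <- function(m, grouping, labels,
                             genes = rownames(m$values)) {
  stopifnot(inherits(m, "fpkm_matrix"), inherits(grouping, "fam46c_grouping"))
  cpc_ids <- cells_of(m, "CPC")
  bmmc_ids <- cells_of(m, "BMMC")
  if (!length(cpc_ids)) stop("No CPC cells in the matrix.", call. = FALSE)
  if (!length(bmmc_ids)) stop("No BMMC cells in the matrix.", call. = FALSE)
  corr <- correlation_matrix(subset_matrix(m, cells = cpc_ids),
                             subset_matrix(m, cells = bmmc_ids), genes)
  assignments <- assign_best_match(corr)
  rates <- metastasis_rates(assignments, bmmc_ids)
  rates$cluster <- unname(labels[rates$bmmc_id])
  rates$group <- unname(grouping$group_of_cluster[as.character(rates$cluster)])
  structure(list(assignments = assignments, rates = rates,
                 c_p = nrow(assignments),
                 contributions = cluster_contributions(assignments, grouping,
                                                       labels),
                 rate_comparison = compare_rates_by_group(rates, grouping,
                                                          labels),
                 patient_id = unique(m$cell_meta$patient_id)[1]),
            class = "metastasis_report")
}

#' @export
print.metastasis_report <- function(x, ...) {
  cat(sprintf("<metastasis_report> patient %s: C_p = %d CPCs over %d BMMCs\n",
              x$patient_id, x$c_p, nrow(x$rates)))
  print(as.data.frame(x$contributions))
  invisible(x)
}

#' @exportS3Method generics::tidy
#' @rdname metastasis_model
#' @param x A `metastasis_report`.
#' @param ... Unused.
tidy.metastasis_report <- function(x, ...) x$rates

#' @exportS3Method generics::glance
#' @rdname metastasis_model
glance.metastasis_report <- function(x, ...) {
  low <- x$contributions[x$contributions$group == "low", ]
  high <- x$contributions[x$contributions$group == "high", ]
  tibble::tibble(patient_id = x$patient_id, c_p = x$c_p,
                 n_bmmc = nrow(x$rates),
                 n_bmmc_matched = sum(x$rates$c_j > 0),
                 low_percent = low$percent, high_percent = high$percent,
                 rate_p_value = if (nrow(x$rate_comparison)) {
                   x$rate_comparison$p_value
                 } else {
                   NA_real_
                 })
}

#' Export a metastasis report as a three-layer Sankey graph
#'
#' Writes (or returns) a layout-free node-link structure with layers
#' cluster -> BMMC -> CPC. Each assignment contributes weight one: a
#' cluster-to-BMMC link carries `C_j`, a BMMC-to-CPC link carries 1. Only
#' BMMCs matched by at least one CPC appear. Node metadata carries the
#' FAM46C group.
#'
#' @param report A `metastasis_report`.
#' @param path Optional JSON output path; when `NULL` the list is returned.
#' @return The node-link list (invisibly when written to `path`).
#' @export
export_sankey <- function(report, path = NULL) {
  stopifnot(inherits(report, "metastasis_report"))
  matched <- report$rates[report$rates$c_j > 0, , drop = FALSE]
  cluster_nodes <- unique(matched[, c("cluster", "group")])
  nodes <- rbind(
    data.frame(id = paste0("cluster_", cluster_nodes$cluster),
               layer = "cluster", group = cluster_nodes$group),
    data.frame(id = matched$bmmc_id, layer = "bmmc", group = matched$group),
    data.frame(id = report$assignments$cpc_id, layer = "cpc",
               group = NA_character_))
  links <- rbind(
    data.frame(source = paste0("cluster_", matched$cluster),
               target = matched$bmmc_id, value = matched$c_j),
    data.frame(source = report$assignments$bmmc_id,
               target = report$assignments$cpc_id, value = 1))
  graph <- list(nodes = nodes, links = links)
  if (is.null(path)) return(graph)
  jsonlite::write_json(graph, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(graph)
}
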