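#' Cell-level quality filtering
#'
#' Keeps cells with strictly more than `min_mapped_reads` mapped reads and
#' strictly more than `min_genes` detected genes. The detected-gene count
#' is taken from the metadata when present (as upstream pipelines define
#' it); cells with a missing count fall back to the number of genes with
#' `FPKM > 0` in the matrix.
#'
#' @param m An [fpkm_matrix].
#' @param min_mapped_reads,min_genes Strict lower thresholds.
#' @return A list with `matrix` (the filtered [fpkm_matrix], possibly with
#'   zero cells) and `report`, a one-row tibble with `n_cells_in`,
#'   `n_cells_kept`, `n_features_in`, the thresholds, and a list-column
#'   `kept_cell_ids`.
#' @export
filter_cells <- function(m, min_mapped_reads = 1e5, min_genes = 1e3) {
  stopifnot(inherits(m, "fpkm_matrix"))
  meta <- m$cell_meta
  n_det <- meta$n_genes_detected
  if (anyNA(n_det)) {
    n_det[is.na(n_det)] <- colSums(m$values[, is.na(n_det), drop = FALSE] > 0)
  }
  reads <- meta$mapped_reads
  keep <- !is.na(reads) & reads > min_mapped_reads & n_det > min_genes
  kept_ids <- meta$cell_id[keep]
  if (!length(kept_ids)) {
    warning("No cells pass the QC thresholds.", call. = FALSE)
  }
  out <- fpkm_matrix(m$values[, kept_ids, drop = FALSE],
                     meta[keep, , drop = FALSE])
  report <- tibble::tibble(n_cells_in = ncol(m$values),
                           n_cells_kept = length(kept_ids),
                           n_features_in = nrow(m$values),
                           min_mapped_reads = min_mapped_reads,
                           min_genes = min_genes,
                           kept_cell_ids = list(kept_ids))
  list(matrix = out, report = report)
}

#' Stably expressed transcript filter
#'
#' A transcript counts as stably expressed when its FPKM exceeds the cutoff
#' in at least one cell (strict `>`).
#'
#' @param m An [fpkm_matrix].
#' @param fpkm_cutoff Strict FPKM threshold (default 1).
#' @return Character vector of the retained gene symbols, in matrix order.
#' @export
expressed_features <- function(m, fpkm_cutoff = 1) {
  stopifnot(inherits(m, "fpkm_matrix"), ncol(m$values) > 0)
  rownames(m$values)[apply(m$values, 1, max) > fpkm_cutoff]
}

#' Apply both QC filters and return the analysis-ready matrix
#'
#' @inheritParams filter_cells
#' @param fpkm_cutoff Strict FPKM threshold for [expressed_features()].
#' @return A list with `matrix` (cells and features filtered) and `report`
#'   (the [filter_cells()] report extended with `n_features_expressed` and
#'   `fpkm_cutoff`).
#' @export
qc_filter <- function(m, min_mapped_reads = 1e5, min_genes = 1e3,
                      fpkm_cutoff = 1) {
  cells <- filter_cells(m, min_mapped_reads, min_genes)
  feats <- if (ncol(cells$matrix$values) > 0) {
    expressed_features(cells$matrix, fpkm_cutoff)
  } else {
    character(0)
  }
  out <- subset_matrix(cells$matrix, genes = feats)
  report <- dplyr::mutate(cells$report,
                          n_features_expressed = length(feats),
                          fpkm_cutoff = fpkm_cutoff,
                          .before = "kept_cell_ids")
  list(matrix = out, report = report)
}
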