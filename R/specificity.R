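#' Identify immunoglobulin genes by symbol
#'
#' Selects gene symbols from the IGH/IGK/IGL loci (variable segments and
#' constant regions, e.g. `IGHV4-28`, `IGHA1`, `IGKC`, `IGLL5`) by
#' case-insensitive prefix match.
#'
#' @param gene_ids Character vector of gene symbols.
#' @return The immunoglobulin subset, in input order.
#' @export
#' @examples
#' identify_ig_genes(c("IGKV1-33", "FAM46C", "IGHA1", "ACTB"))
identify_ig_genes <- function(gene_ids) {
  gene_ids[grepl("^IG[HKL]", gene_ids, ignore.case = TRUE)]
}

#' One-way ANOVA patient-specificity test for a single gene
#'
#' Classical one-way analysis of variance of a gene's FPKM values grouped
#' by patient: `F = (SSB/(k-1)) / (SSW/(N-k))` with the p-value from the F
#' distribution on `(k-1, N-k)` degrees of freedom. A gene is called
#' patient-specific when `p < p_cutoff`. The patients a specific gene is
#' attributed to are those whose group mean exceeds the grand mean by more
#' than twice the pooled within-group standard deviation; several patients
#' may qualify (immunoglobulin genes can mark two clones).
#'
#' @param m An [fpkm_matrix] containing cells from at least two patients.
#' @param gene Gene symbol present in `m`.
#' @param p_cutoff Specificity cutoff on the ANOVA p-value.
#' @param log_scale Run the ANOVA on `log2(FPKM + 1)` instead of raw FPKM
#'   (default `FALSE`: raw FPKM, the scale the expression is reported on).
#' @return One-row tibble: `gene`, `f_statistic`, `p_value`, `is_specific`,
#'   `specific_patients` (list-column), `per_patient_mean` (list-column of
#'   named means).
#' @export
anova_specificity <- function(m, gene, p_cutoff = 1e-6, log_scale = FALSE) {
  stopifnot(inherits(m, "fpkm_matrix"))
  if (!gene %in% rownames(m$values)) {
    stop("Gene not found: ", gene, call. = FALSE)
  }
  vals <- m$values[gene, ]
  if (log_scale) vals <- log2(vals + 1)
  patient <- m$cell_meta$patient_id
  sizes <- table(patient)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("Excluding patient(s) with < 2 cells: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !patient %in% small
    vals <- vals[keep]
    patient <- patient[keep]
  }
  groups <- split(vals, patient)
  if (length(groups) < 2) {
    stop("Need >= 2 patients with >= 2 cells each.", call. = FALSE)
  }
  means <- vapply(groups, mean, numeric(1))
  n <- length(vals)
  k <- length(groups)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (stats::var(vals) == 0) {
    f <- 0
    p <- 1
  } else if (ssw == 0) {
    f <- Inf
    p <- 0
  } else {
    ow <- stats::oneway.test(vals ~ factor(patient), var.equal = TRUE)
    f <- unname(ow$statistic)
    p <- ow$p.value
  }
  is_specific <- is.finite(p) && p < p_cutoff
  specific <- character(0)
  if (is_specific) {
    pooled_sd <- sqrt(ssw / (n - k))
    specific <- names(means)[means > mean(vals) + 2 * pooled_sd]
  }
  tibble::tibble(gene = gene, f_statistic = f, p_value = p,
                 is_specific = is_specific,
                 specific_patients = list(specific),
                 per_patient_mean = list(means))
}

#' Patient-specificity table over all detected immunoglobulin genes
#'
#' Runs [anova_specificity()] for every immunoglobulin gene present in the
#' (QC-filtered) matrix and returns the results sorted by p-value.
#'
#' @inheritParams anova_specificity
#' @return A tibble with one row per immunoglobulin gene (columns as in
#'   [anova_specificity()]), p-values nondecreasing. Zero rows when the
#'   matrix carries no immunoglobulin genes.
#' @export
specificity_table <- function(m, p_cutoff = 1e-6, log_scale = FALSE) {
  stopifnot(inherits(m, "fpkm_matrix"))
  ig <- identify_ig_genes(rownames(m$values))
  if (!length(ig)) {
    return(tibble::tibble(gene = character(0), f_statistic = numeric(0),
                          p_value = numeric(0), is_specific = logical(0),
                          specific_patients = list(),
                          per_patient_mean = list()))
  }
  res <- purrr::map_dfr(ig, function(g) {
    anova_specificity(m, g, p_cutoff = p_cutoff, log_scale = log_scale)
  })
  dplyr::arrange(res, .data$p_value)
}
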