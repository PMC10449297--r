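#' Per-gene two-group expression test
#'
#' Two-sided unpaired t test of a gene's FPKM values between two cell
#' groups (Welch's unequal-variance form by default), with the log2 fold
#' change defined as `log2((mean_a + 1) / (mean_b + 1))` -- a pseudocount
#' of one FPKM keeps the ratio stable under dropout zeros. Group A is the
#' test group (CPCs, or cluster 1), group B the reference (BMMCs, or
#' cluster 2).
#'
#' @param m An [fpkm_matrix].
#' @param gene Gene symbol.
#' @param cells_a,cells_b Character vectors of cell ids (each `>= 2`).
#' @param var_equal Use the pooled-variance t test instead of Welch.
#' @return One-row tibble: `gene`, `p_value`, `log2fc`, `mean_a`, `mean_b`.
#' @export
gene_test <- function(m, gene, cells_a, cells_b, var_equal = FALSE) {
  stopifnot(inherits(m, "fpkm_matrix"))
  if (!gene %in% rownames(m$values)) stop("Gene not found: ", gene, call. = FALSE)
  a <- m$values[gene, cells_a]
  b <- m$values[gene, cells_b]
  res <- two_group_t(a, b, var_equal)
  tibble::tibble(gene = gene, p_value = res$p,
                 log2fc = log2((mean(a) + 1) / (mean(b) + 1)),
                 mean_a = mean(a), mean_b = mean(b))
}

two_group_t <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2 || length(b) < 2) {
    stop("Each group needs >= 2 cells.", call. = FALSE)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # degenerate: no within-group variability; equal means are a perfect
    # null, unequal means an unambiguous difference
    return(list(p = if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0,
                stat = NA_real_))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(p = tt$p.value, stat = unname(tt$statistic))
}

#' Call differentially expressed genes under a conjunctive per-patient rule
#'
#' Evaluates [gene_test()] for every gene of the matrix in every patient
#' contrast, then flags as differentially expressed the genes that satisfy
#' `p < p_cutoff` and `|log2fc| > abs_log2fc` in *every* contrast
#' (the conjunctive rule: a metastasis-related gene must replicate across
#' patients). Benjamini-Hochberg q-values are reported per contrast for
#' transparency; they play no part in the call.
#'
#' @param m An [fpkm_matrix], features pre-filtered with
#'   [expressed_features()].
#' @param contrasts Named list (one element per patient) of lists with
#'   `cells_a` and `cells_b` character vectors.
#' @param p_cutoff,abs_log2fc Thresholds; `p_cutoff` may be a named vector
#'   giving a per-patient override (e.g. a stricter cutoff for one
#'   contrast).
#' @param var_equal Passed to [gene_test()].
#' @return A tibble with one row per gene x patient: `gene`, `patient`,
#'   `p_value`, `q_value`, `log2fc`, `mean_a`, `mean_b`, `passes`
#'   (this contrast) and `passes_conjunctive` (all contrasts; constant
#'   within gene).
#' @export
call_degs <- function(m, contrasts, p_cutoff = 0.05, abs_log2fc = 1,
                      var_equal = FALSE) {
  stopifnot(inherits(m, "fpkm_matrix"), length(contrasts) >= 1,
            !is.null(names(contrasts)))
  usable <- vapply(contrasts, function(ct) {
    length(ct$cells_a) >= 2 && length(ct$cells_b) >= 2
  }, logical(1))
  if (any(!usable)) {
    warning("Dropping contrast(s) with < 2 cells per group: ",
            paste(names(contrasts)[!usable], collapse = ", "), call. = FALSE)
    contrasts <- contrasts[usable]
  }
  if (!length(contrasts)) stop("No usable contrasts.", call. = FALSE)
  genes <- rownames(m$values)
  per_patient <- purrr::imap_dfr(contrasts, function(ct, patient) {
    a <- m$values[, ct$cells_a, drop = FALSE]
    b <- m$values[, ct$cells_b, drop = FALSE]
    p <- vapply(genes, function(g) two_group_t(a[g, ], b[g, ], var_equal)$p,
                numeric(1))
    ma <- rowMeans(a)
    mb <- rowMeans(b)
    cutoff <- if (!is.null(names(p_cutoff))) {
      if (!patient %in% names(p_cutoff)) p_cutoff[[1]] else p_cutoff[[patient]]
    } else {
      p_cutoff
    }
    tibble::tibble(gene = genes, patient = patient, p_value = unname(p),
                   q_value = stats::p.adjust(unname(p), "BH"),
                   log2fc = log2((ma + 1) / (mb + 1)),
                   mean_a = unname(ma), mean_b = unname(mb),
                   passes = p < cutoff & abs(log2fc) > abs_log2fc)
  })
  conj <- dplyr::summarise(dplyr::group_by(per_patient, .data$gene),
                           passes_conjunctive = all(.data$passes))
  dplyr::left_join(per_patient, conj, by = "gene")
}

#' Genes passing the conjunctive differential-expression rule
#'
#' @param degs Output of [call_degs()].
#' @return Character vector of gene symbols.
#' @export
deg_genes <- function(degs) {
  unique(degs$gene[degs$passes_conjunctive])
}

#' Whole-transcriptome level-shift test between two cell groups
#'
#' Summarises each gene by its mean `log2(FPKM + 1)` within each cell
#' group, then compares the two per-gene-mean distributions with the named
#' two-sample test: Kolmogorov-Smirnov for compartment comparisons
#' (CPC vs BMMC), Mann-Whitney for subcluster comparisons, or a t test.
#' The direction is the sign of `median(A) - median(B)`; a negative
#' direction means group A sits below group B, the signature of reduced
#' mRNA stability.
#'
#' @param m An [fpkm_matrix].
#' @param genes Gene symbols to aggregate over (nonempty).
#' @param cells_a,cells_b Cell id vectors.
#' @param test One of `"kolmogorov_smirnov"`, `"mann_whitney"`, `"t_test"`.
#' @param aggregate `"per_gene"` (default): one observation per gene, its
#'   mean over the group's cells -- a gene-level distribution shift.
#'   `"per_cell"`: one observation per cell, its mean over the genes --
#'   asks directly whether cells of group A sit at a lower overall level.
#' @return One-row tibble: `test`, `aggregate`, `statistic`, `p_value`,
#'   `direction` (-1, 0 or 1).
#' @export
transcriptome_shift <- function(m, genes, cells_a, cells_b,
                                test = c("kolmogorov_smirnov",
                                         "mann_whitney", "t_test"),
                                aggregate = c("per_gene", "per_cell")) {
  stopifnot(inherits(m, "fpkm_matrix"), length(genes) > 0)
  test <- match.arg(test)
  aggregate <- match.arg(aggregate)
  la <- log2(m$values[genes, cells_a, drop = FALSE] + 1)
  lb <- log2(m$values[genes, cells_b, drop = FALSE] + 1)
  if (aggregate == "per_gene") {
    a <- rowMeans(la)
    b <- rowMeans(lb)
  } else {
    a <- colMeans(la)
    b <- colMeans(lb)
  }
  if (isTRUE(all.equal(a, b))) {
    ht <- list(statistic = 0, p.value = 1)
  } else {
    ht <- switch(test,
      kolmogorov_smirnov = suppressWarnings(stats::ks.test(a, b)),
      mann_whitney = suppressWarnings(stats::wilcox.test(a, b)),
      t_test = stats::t.test(a, b))
  }
  tibble::tibble(test = test, aggregate = aggregate,
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 direction = sign(stats::median(a) - stats::median(b)))
}
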