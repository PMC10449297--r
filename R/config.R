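#' Analysis thresholds for the pipeline
#'
#' Bundles the filtering and testing thresholds used across the stages.
#' Defaults follow the study design the package implements: cells are kept
#' with more than `1e5` mapped reads and more than `1e3` detected genes
#' (strict inequalities); transcripts count as stably expressed when FPKM
#' exceeds 1 in at least one cell; immunoglobulin patient specificity is
#' called at one-way ANOVA `P < 1e-6`; a differentially expressed gene
#' requires `P < 0.05` (unpaired t test) and `|log2 fold change| > 1` in
#' every required patient; cluster number is chosen by average silhouette
#' width over one to ten clusters.
#'
#' @param min_mapped_reads,min_genes Cell-level QC thresholds (strict `>`).
#' @param expressed_fpkm_cutoff Transcript-level FPKM cutoff (strict `>`).
#' @param anova_p_cutoff Immunoglobulin specificity p-value cutoff.
#' @param deg_p_cutoff,deg_abs_log2fc Differential-expression thresholds.
#' @param k_range Integer range of candidate cluster numbers.
#' @param rng_seed Seed used by stages that draw random numbers.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(min_mapped_reads = 1e5,
                            min_genes = 1e3,
                            expressed_fpkm_cutoff = 1,
                            anova_p_cutoff = 1e-6,
                            deg_p_cutoff = 0.05,
                            deg_abs_log2fc = 1,
                            k_range = 1:10,
                            rng_seed = 1L) {
  stopifnot(min_mapped_reads > 0, min_genes > 0, expressed_fpkm_cutoff > 0,
            anova_p_cutoff > 0, deg_p_cutoff > 0, deg_abs_log2fc > 0,
            min(k_range) >= 1)
  structure(list(min_mapped_reads = min_mapped_reads,
                 min_genes = min_genes,
                 expressed_fpkm_cutoff = expressed_fpkm_cutoff,
                 anova_p_cutoff = anova_p_cutoff,
                 deg_p_cutoff = deg_p_cutoff,
                 deg_abs_log2fc = deg_abs_log2fc,
                 k_range = as.integer(k_range),
                 rng_seed = as.integer(rng_seed)),
            class = "analysis_config")
}
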