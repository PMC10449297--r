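#' Run the full per-patient analysis pipeline
#'
#' Orchestrates the stages on a matrix that may hold one or several
#' patients: (1) QC filtering of cells and transcripts; (2) immunoglobulin
#' patient-specificity ANOVA (needs >= 2 patients, otherwise skipped with a
#' message); (3) CPC-vs-BMMC differential expression with the conjunctive
#' rule across every patient that carries both compartments; (4) per
#' patient, silhouette-selected clustering of the BMMCs on the conjunctive
#' DEG + immunoglobulin feature space (when no DEG set exists the top-500
#' variance genes substitute, with a message), FAM46C low/high grouping,
#' whole-transcriptome shift tests, and -- when the patient has CPCs -- the
#' extramedullary-metastasis model.
#'
#' @param m An [fpkm_matrix], or a list of them (combined with
#'   [bind_cells()]).
#' @param config An [analysis_config()].
#' @param verbose Emit stage messages.
#' @return An object of class `pipeline_result`: list with `qc`
#'   (QC report tibble), `specificity` (tibble or `NULL`), `degs` (tibble
#'   or `NULL`), `deg_genes`, `feature_genes`, and `per_patient`, a named
#'   list with elements `clusters` (`cluster_model`), `grouping`
#'   (`fam46c_grouping`), `metastasis` (`metastasis_report` or `NULL`) and
#'   `shifts` (tibble of level-shift tests).
#' @export
#' @examples
#' sim <- simulate_patient(scenario_p17(seed = 1, noise_sd = 0.2,
#'                                      dropout_rate = 0.05))
#' res <- run_pipeline(sim$matrix, verbose = FALSE)
#' res$per_patient$P17$metastasis$contributions
run_pipeline <- function(m, config = analysis_config(), verbose = TRUE) {
  if (!inherits(m, "fpkm_matrix")) m <- bind_cells(m)
  say <- function(...) if (verbose) message(...)

  qc <- qc_filter(m, config$min_mapped_reads, config$min_genes,
                  config$expressed_fpkm_cutoff)
  mf <- qc$matrix
  say(sprintf("QC: kept %d/%d cells, %d/%d transcripts",
              qc$report$n_cells_kept, qc$report$n_cells_in,
              qc$report$n_features_expressed, qc$report$n_features_in))
  patients <- unique(mf$cell_meta$patient_id)

  spec <- NULL
  if (length(patients) >= 2) {
    spec <- specificity_table(mf, p_cutoff = config$anova_p_cutoff)
    say(sprintf("Specificity: %d immunoglobulin genes, %d patient-specific",
                nrow(spec), sum(spec$is_specific)))
  } else {
    say("Specificity: skipped (single patient)")
  }

  contrasts <- list()
  for (p in patients) {
    ca <- cells_of(mf, "CPC", p)
    cb <- cells_of(mf, "BMMC", p)
    if (length(ca) >= 2 && length(cb) >= 2) {
      contrasts[[p]] <- list(cells_a = ca, cells_b = cb)
    }
  }
  degs <- NULL
  dg <- character(0)
  if (length(contrasts)) {
    degs <- call_degs(mf, contrasts, p_cutoff = config$deg_p_cutoff,
                      abs_log2fc = config$deg_abs_log2fc)
    dg <- deg_genes(degs)
    say(sprintf("DEG: %d genes pass the conjunctive rule over %s",
                length(dg), paste(names(contrasts), collapse = " + ")))
  } else {
    say("DEG: skipped (no patient with both compartments)")
  }

  ig <- identify_ig_genes(rownames(mf$values))
  features <- union(dg, ig)
  if (length(dg) == 0) {
    vars <- apply(log2_fpkm(mf), 1, stats::var)
    features <- union(names(sort(vars, decreasing = TRUE))[
      seq_len(min(500L, length(vars)))], ig)
    say("Features: no DEG set available; using top-variance genes")
  }

  per_patient <- list()
  for (p in patients) {
    bm <- subset_matrix(mf, cells = cells_of(mf, "BMMC", p))
    if (ncol(bm$values) < 3) {
      say(sprintf("%s: skipped (fewer than 3 BMMCs)", p))
      next
    }
    feats <- feature_matrix(bm, features)
    cm <- select_k_silhouette(feats, k_range = config$k_range)
    grouping <- label_fam46c_groups(bm, cm$labels)
    say(sprintf("%s: k = %d clusters, high-FAM46C cluster %s",
                p, cm$k_selected, paste(grouping$merged_high, collapse = ",")))

    shift_genes <- if (length(dg)) dg else features
    shift_genes <- intersect(shift_genes, rownames(mf$values))
    shifts <- NULL
    low_cells <- names(cm$labels)[cm$labels %in% grouping$merged_low]
    high_cells <- names(cm$labels)[cm$labels %in% grouping$merged_high]
    if (length(low_cells) && length(high_cells) && length(shift_genes)) {
      shifts <- dplyr::mutate(
        transcriptome_shift(bm, shift_genes, low_cells, high_cells,
                            test = "mann_whitney"),
        comparison = "low_vs_high_cluster")
    }
    cpc <- cells_of(mf, "CPC", p)
    if (length(cpc) >= 2 && length(shift_genes)) {
      cs <- dplyr::mutate(
        transcriptome_shift(subset_matrix(mf, cells = c(cpc, colnames(bm$values))),
                            shift_genes, cpc, colnames(bm$values),
                            test = "kolmogorov_smirnov"),
        comparison = "cpc_vs_bmmc")
      shifts <- dplyr::bind_rows(shifts, cs)
    }

    metastasis <- NULL
    if (length(cpc) >= 1) {
      pm <- subset_matrix(mf, cells = c(colnames(bm$values), cpc))
      metastasis <- metastasis_model(pm, grouping, cm$labels)
      say(sprintf("%s: C_p = %d, low-group contribution %.1f%%",
                  p, metastasis$c_p,
                  metastasis$contributions$percent[
                    metastasis$contributions$group == "low"]))
    } else {
      say(sprintf("%s: metastasis model skipped (no CPCs)", p))
    }
    per_patient[[p]] <- list(clusters = cm, grouping = grouping,
                             shifts = shifts, metastasis = metastasis)
  }

  structure(list(qc = qc$report, specificity = spec, degs = degs,
                 deg_genes = dg, feature_genes = features,
                 per_patient = per_patient, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d patient(s): %s\n",
              length(x$per_patient), paste(names(x$per_patient), collapse = ", ")))
  cat(sprintf("QC kept %d cells; %d conjunctive DEGs\n",
              x$qc$n_cells_kept, length(x$deg_genes)))
  for (p in names(x$per_patient)) {
    pp <- x$per_patient[[p]]
    cat(sprintf("  %s: k = %d", p, pp$clusters$k_selected))
    if (!is.null(pp$metastasis)) {
      cat(sprintf(", low-group contribution %.1f%%",
                  pp$metastasis$contributions$percent[
                    pp$metastasis$contributions$group == "low"]))
    }
    cat("\n")
  }
  invisible(x)
}
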