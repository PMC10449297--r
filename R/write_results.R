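#' Serialize analysis results to a run directory
#'
#' Generic writer: each result type lands as documented TSV or JSON files
#' under `out_dir`, and a manifest tibble (`file`, `rows`) is returned. The
#' `pipeline_result` method writes every stage (per-patient files carry a
#' patient prefix) plus a `manifest.json`.
#'
#' @param x A result object (`pipeline_result`, `metastasis_report`,
#'   `cluster_model`, or a data frame).
#' @param out_dir Output directory (created if needed).
#' @param ... Method arguments; data frames take `name`, the file stem.
#' @return A tibble manifest of written files (invisibly for
#'   `pipeline_result`).
#' @export
write_results <- function(x, out_dir, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, mode = 2) != 0) {
    stop("Output directory is not writable: ", out_dir, call. = FALSE)
  }
  UseMethod("write_results")
}

write_tsv_flat <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.list(df[[j]])) {
      df[[j]] <- vapply(df[[j]], function(v) paste(format(v), collapse = ","),
                        character(1))
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  nrow(df)
}

#' @export
write_results.data.frame <- function(x, out_dir, name = "table", ...) {
  f <- file.path(out_dir, paste0(name, ".tsv"))
  tibble::tibble(file = basename(f), rows = write_tsv_flat(x, f))
}

#' @export
write_results.cluster_model <- function(x, out_dir, name = "", ...) {
  pre <- if (nzchar(name)) paste0(name, "_") else ""
  f1 <- file.path(out_dir, paste0(pre, "clusters.tsv"))
  f2 <- file.path(out_dir, paste0(pre, "silhouette.tsv"))
  tibble::tibble(
    file = basename(c(f1, f2)),
    rows = c(write_tsv_flat(tidy(x), f1),
             write_tsv_flat(x$silhouette, f2)))
}

#' @export
write_results.metastasis_report <- function(x, out_dir, name = "", ...) {
  pre <- if (nzchar(name)) paste0(name, "_") else ""
  f1 <- file.path(out_dir, paste0(pre, "rates.tsv"))
  f2 <- file.path(out_dir, paste0(pre, "contributions.json"))
  f3 <- file.path(out_dir, paste0(pre, "sankey.json"))
  jsonlite::write_json(x$contributions, f2, auto_unbox = TRUE, digits = NA)
  export_sankey(x, f3)
  tibble::tibble(
    file = basename(c(f1, f2, f3)),
    rows = c(write_tsv_flat(x$rates, f1), nrow(x$contributions),
             nrow(x$assignments)))
}

#' @export
write_results.pipeline_result <- function(x, out_dir, ...) {
  manifest <- write_results.data.frame(x$qc, out_dir, name = "qc")
  if (!is.null(x$specificity)) {
    manifest <- rbind(manifest,
                      write_results.data.frame(x$specificity, out_dir,
                                               name = "specificity"))
  }
  degs <- if (is.null(x$degs)) {
    tibble::tibble(gene = character(0), patient = character(0),
                   p_value = numeric(0), q_value = numeric(0),
                   log2fc = numeric(0), mean_a = numeric(0),
                   mean_b = numeric(0), passes = logical(0),
                   passes_conjunctive = logical(0))
  } else {
    x$degs
  }
  manifest <- rbind(manifest,
                    write_results.data.frame(degs, out_dir, name = "degs"))
  for (p in names(x$per_patient)) {
    pp <- x$per_patient[[p]]
    manifest <- rbind(manifest,
                      write_results.cluster_model(pp$clusters, out_dir, name = p))
    gf <- file.path(out_dir, paste0(p, "_grouping.json"))
    jsonlite::write_json(
      list(group_of_cluster = as.list(pp$grouping$group_of_cluster),
           fam46c_mean_by_cluster = as.list(pp$grouping$fam46c_mean_by_cluster),
           p_value_low_vs_high = pp$grouping$p_value_low_vs_high),
      gf, auto_unbox = TRUE, digits = NA, na = "null")
    manifest <- rbind(manifest,
                      tibble::tibble(file = basename(gf),
                                     rows = length(pp$grouping$group_of_cluster)))
    if (!is.null(pp$metastasis)) {
      manifest <- rbind(manifest,
                        write_results.metastasis_report(pp$metastasis, out_dir,
                                                        name = p))
    }
    if (!is.null(pp$shifts)) {
      manifest <- rbind(manifest,
                        write_results.data.frame(pp$shifts, out_dir,
                                                 name = paste0(p, "_shifts")))
    }
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
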