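#' Gene-by-cell FPKM expression matrix with per-cell metadata
#'
#' The carrier object for every pipeline stage: a dense non-negative
#' genes x cells matrix of FPKM values together with a per-cell metadata
#' table. FPKM values are stored untransformed; every downstream stage that
#' needs a log scale computes `log2(FPKM + 1)` on the fly and never writes
#' it back.
#'
#' @param values Numeric matrix, genes as rows and cells as columns, with
#'   unique, non-empty `rownames` (gene symbols) and `colnames` (cell ids).
#'   All entries must be finite and `>= 0`.
#' @param cell_meta Data frame with one row per cell and columns `cell_id`,
#'   `patient_id`, `compartment` (`"BMMC"` or `"CPC"`), `mapped_reads` and
#'   `n_genes_detected`. Missing `mapped_reads`/`n_genes_detected` columns
#'   are filled in (`NA` reads; detected genes counted as `FPKM > 0`).
#'   Every matrix column must have a metadata row; rows are reordered to
#'   the matrix column order.
#'
#' @return An object of class `fpkm_matrix`: a list with elements `values`
#'   (the matrix) and `cell_meta` (a tibble aligned with `colnames(values)`).
#' @export
#' @examples
#' m <- matrix(c(0, 2.5, 1, 0, 7, 3), nrow = 3,
#'             dimnames = list(c("FAM46C", "IGKC", "ACTB"), c("c1", "c2")))
#' meta <- data.frame(cell_id = c("c1", "c2"), patient_id = "P17",
#'                    compartment = c("BMMC", "CPC"),
#'                    mapped_reads = c(2e5, 3e5))
#' fpkm_matrix(m, meta)
fpkm_matrix <- function(values, cell_meta) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x cells).", call. = FALSE)
  }
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values)))) {
    stop("`values` must carry gene rownames and cell colnames.", call. = FALSE)
  }
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (is.null(colnames(values))) colnames(values) <- character(0)
  if (anyDuplicated(rownames(values))) {
    stop("Duplicate gene ids in `values` rownames.", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("Duplicate cell ids in `values` colnames.", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("FPKM values must be finite.", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("FPKM values must be non-negative.", call. = FALSE)
  }
  cell_meta <- tibble::as_tibble(cell_meta)
  required <- c("cell_id", "patient_id", "compartment")
  missing_cols <- setdiff(required, names(cell_meta))
  if (length(missing_cols)) {
    stop("`cell_meta` lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  absent <- setdiff(colnames(values), cell_meta$cell_id)
  if (length(absent)) {
    stop("Cells missing from `cell_meta`: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  cell_meta <- cell_meta[match(colnames(values), cell_meta$cell_id), , drop = FALSE]
  bad_comp <- !cell_meta$compartment %in% c("BMMC", "CPC")
  if (any(bad_comp)) {
    stop("`compartment` must be \"BMMC\" or \"CPC\" (offending cell: ",
         cell_meta$cell_id[which(bad_comp)[1]], ").", call. = FALSE)
  }
  if (!"mapped_reads" %in% names(cell_meta)) cell_meta$mapped_reads <- NA_real_
  if (!"n_genes_detected" %in% names(cell_meta)) {
    cell_meta$n_genes_detected <- unname(colSums(values > 0))
  }
  structure(list(values = values, cell_meta = cell_meta),
            class = "fpkm_matrix")
}

#' @export
print.fpkm_matrix <- function(x, ...) {
  comp <- table(x$cell_meta$compartment)
  cat(sprintf("<fpkm_matrix> %d genes x %d cells (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(comp), comp), collapse = ", ")))
  cat("patients:", paste(unique(x$cell_meta$patient_id), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.fpkm_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by genes and/or cells
#'
#' @param m An [fpkm_matrix].
#' @param genes,cells Character vectors of gene/cell ids to keep (default:
#'   all). Unknown ids are an error.
#' @return The subset [fpkm_matrix]; metadata follows the cells.
#' @export
subset_matrix <- function(m, genes = NULL, cells = NULL) {
  stopifnot(inherits(m, "fpkm_matrix"))
  if (is.null(genes)) genes <- rownames(m$values)
  if (is.null(cells)) cells <- colnames(m$values)
  bad_g <- setdiff(genes, rownames(m$values))
  if (length(bad_g)) stop("Unknown gene(s): ", paste(utils::head(bad_g, 5), collapse = ", "),
                          call. = FALSE)
  bad_c <- setdiff(cells, colnames(m$values))
  if (length(bad_c)) stop("Unknown cell(s): ", paste(utils::head(bad_c, 5), collapse = ", "),
                          call. = FALSE)
  fpkm_matrix(m$values[genes, cells, drop = FALSE],
              m$cell_meta[m$cell_meta$cell_id %in% cells, , drop = FALSE])
}

#' Combine expression matrices from several patients
#'
#' Column-binds matrices that share an identical gene panel, e.g. per-patient
#' simulations, so that cross-patient stages (immunoglobulin specificity,
#' the conjunctive differential-expression rule) can run on one object.
#'
#' @param ... [fpkm_matrix] objects, or a single list of them.
#' @return A combined [fpkm_matrix].
#' @export
bind_cells <- function(...) {
  ms <- list(...)
  if (length(ms) == 1L && !inherits(ms[[1]], "fpkm_matrix")) ms <- ms[[1]]
  stopifnot(length(ms) >= 1L, all(vapply(ms, inherits, logical(1), "fpkm_matrix")))
  genes <- rownames(ms[[1]]$values)
  for (m in ms[-1]) {
    if (!identical(rownames(m$values), genes)) {
      stop("All matrices must share an identical gene panel.", call. = FALSE)
    }
  }
  fpkm_matrix(do.call(cbind, lapply(ms, function(m) m$values)),
              dplyr::bind_rows(lapply(ms, function(m) m$cell_meta)))
}

#' Extract cell ids by compartment and/or patient
#'
#' @param m An [fpkm_matrix].
#' @param compartment Optional `"BMMC"` or `"CPC"`.
#' @param patient Optional patient id.
#' @return Character vector of cell ids.
#' @export
cells_of <- function(m, compartment = NULL, patient = NULL) {
  stopifnot(inherits(m, "fpkm_matrix"))
  meta <- m$cell_meta
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(compartment)) keep <- keep & meta$compartment %in% compartment
  if (!is.null(patient)) keep <- keep & meta$patient_id %in% patient
  meta$cell_id[keep]
}

#' Read an FPKM matrix and its cell metadata from TSV
#'
#' The expression file is tab-separated with a header `gene<TAB>cell ids...`
#' and one row per gene. The metadata file is tab-separated with columns
#' `cell_id`, `patient_id`, `compartment`, and optionally `mapped_reads`,
#' `n_genes_detected`. Cells present in the matrix but absent from the
#' metadata are an error; extra metadata rows are dropped.
#'
#' @param matrix_path,meta_path File paths.
#' @return An [fpkm_matrix] with cells in the matrix column order.
#' @export
read_fpkm_matrix <- function(matrix_path, meta_path) {
  tab <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("Expression TSV needs a gene column plus >= 1 cell.",
                           call. = FALSE)
  genes <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(tab[-1], is.numeric, logical(1)))[1]
    stop(sprintf("Non-numeric expression values in column '%s' of %s.",
                 names(tab)[-1][bad], matrix_path), call. = FALSE)
  }
  rownames(vals) <- genes
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  meta <- meta[meta$cell_id %in% colnames(vals), , drop = FALSE]
  fpkm_matrix(vals, meta)
}

#' Write an FPKM matrix and its metadata to TSV
#'
#' @param m An [fpkm_matrix].
#' @param matrix_path,meta_path Output file paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_fpkm_matrix <- function(m, matrix_path, meta_path) {
  stopifnot(inherits(m, "fpkm_matrix"))
  tab <- data.frame(gene = rownames(m$values), m$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(m$cell_meta), meta_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(matrix_path, meta_path))
}

#' Read an FPKM matrix from a MatrixMarket triple
#'
#' Interoperability reader for the `matrix.mtx` + `genes.tsv` +
#' `barcodes.tsv` convention; values are densified (this pipeline works at
#' the scale of hundreds of Smart-seq2 cells).
#'
#' @param mtx_path MatrixMarket file of FPKM values (genes x cells).
#' @param genes_path,barcodes_path One-column files of gene symbols and
#'   cell ids (no header).
#' @param meta_path Cell metadata TSV as in [read_fpkm_matrix()].
#' @return An [fpkm_matrix].
#' @export
read_fpkm_mtx <- function(mtx_path, genes_path, barcodes_path, meta_path) {
  if (!requireNamespace("Matrix", quietly = TRUE)) {
    stop("Package 'Matrix' is required to read MatrixMarket files.",
         call. = FALSE)
  }
  vals <- as.matrix(Matrix::readMM(mtx_path))
  rownames(vals) <- readLines(genes_path)
  colnames(vals) <- readLines(barcodes_path)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  meta <- meta[meta$cell_id %in% colnames(vals), , drop = FALSE]
  fpkm_matrix(vals, meta)
}

# log2(FPKM + 1) of the stored values; the only transform used downstream
log2_fpkm <- function(m) log2(m$values + 1)
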