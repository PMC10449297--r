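#' Scenario configuration for the synthetic FPKM generator
#'
#' Describes one simulated patient: the BMMC subcluster geometry, which
#' clusters are FAM46C-low, how many CPCs exist and which cluster each
#' CPC's source cell lies in, and the noise/dropout regime. Defaults plant
#' the structure the analysis is designed to detect: a -2 log2 FAM46C shift
#' and a 0.7x whole-transcriptome depression in low clusters, a -3.53 log2
#' FAM46C shift in CPCs (the fold change observed in the P20 patient), and
#' patient-specific immunoglobulin genes elevated by +4 log2.
#'
#' @param patient_id Patient label, e.g. `"P17"`.
#' @param n_genes Total gene panel size (background + immunoglobulin +
#'   FAM46C).
#' @param n_ig_genes Number of immunoglobulin genes on the panel.
#' @param own_ig Indices (into the immunoglobulin panel) of the genes
#'   specifically expressed by this patient.
#' @param cluster_sizes Integer vector of BMMC counts per subcluster.
#' @param low_clusters Integer indices (1-based) of FAM46C-low clusters.
#' @param n_cpc Number of circulating clonal plasma cells.
#' @param cpc_source_counts Integer vector, same length as `cluster_sizes`:
#'   how many CPCs originate from each cluster. Must sum to `n_cpc`.
#' @param fam46c_low_log2_shift Additive log2 FAM46C shift in low clusters.
#' @param global_low_scale Multiplicative FPKM factor (`0 < s <= 1`)
#'   applied to every gene of low-cluster cells and of CPCs copied from
#'   them, emulating the reduced whole-transcriptome level of FAM46C-low
#'   cells.
#' @param cpc_fam46c_log2_shift Additional log2 FAM46C shift in CPCs
#'   relative to their source cells.
#' @param n_deg_genes Number of background genes shifted between CPCs and
#'   BMMCs (half up, half down).
#' @param deg_log2_shift Magnitude of the planted CPC shift.
#' @param cluster_sep_log2 Magnitude of the per-cluster, per-gene two-point
#'   (+/-) expression offsets that give each BMMC subcluster its own
#'   transcriptional identity (background genes only).
#' @param noise_sd Standard deviation of the per-gene log2 noise a CPC adds
#'   to its source cell's profile.
#' @param dropout_rate Probability that an entry with FPKM below 5 is
#'   zeroed (technical dropout).
#' @param seed Integer seed for [simulate_patient()].
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(patient_id = "P01",
                            n_genes = 2000,
                            n_ig_genes = 12,
                            own_ig = 1:2,
                            cluster_sizes = c(20, 20),
                            low_clusters = 1L,
                            n_cpc = 20,
                            cpc_source_counts = NULL,
                            fam46c_low_log2_shift = -2.0,
                            global_low_scale = 0.7,
                            cpc_fam46c_log2_shift = -3.53,
                            n_deg_genes = 40,
                            deg_log2_shift = 1.5,
                            cluster_sep_log2 = 0.65,
                            noise_sd = 0.3,
                            dropout_rate = 0.1,
                            seed = 1L) {
  if (is.null(cpc_source_counts)) {
    cpc_source_counts <- diff(round(seq(0, n_cpc, length.out = length(cluster_sizes) + 1)))
  }
  cfg <- structure(list(patient_id = patient_id, n_genes = as.integer(n_genes),
                        n_ig_genes = as.integer(n_ig_genes),
                        own_ig = as.integer(own_ig),
                        cluster_sizes = as.integer(cluster_sizes),
                        low_clusters = as.integer(low_clusters),
                        n_cpc = as.integer(n_cpc),
                        cpc_source_counts = as.integer(cpc_source_counts),
                        fam46c_low_log2_shift = fam46c_low_log2_shift,
                        global_low_scale = global_low_scale,
                        cpc_fam46c_log2_shift = cpc_fam46c_log2_shift,
                        n_deg_genes = as.integer(n_deg_genes),
                        deg_log2_shift = deg_log2_shift,
                        cluster_sep_log2 = cluster_sep_log2,
                        noise_sd = noise_sd,
                        dropout_rate = dropout_rate,
                        seed = as.integer(seed)),
                   class = "scenario_config")
  validate_scenario(cfg)
  cfg
}

validate_scenario <- function(cfg) {
  stopifnot(sum(cfg$cluster_sizes) >= 2,
            length(cfg$cpc_source_counts) == length(cfg$cluster_sizes),
            sum(cfg$cpc_source_counts) == cfg$n_cpc,
            all(cfg$low_clusters %in% seq_along(cfg$cluster_sizes)),
            cfg$global_low_scale > 0, cfg$global_low_scale <= 1,
            cfg$dropout_rate >= 0, cfg$dropout_rate < 1,
            cfg$noise_sd >= 0,
            all(cfg$own_ig %in% seq_len(cfg$n_ig_genes)),
            cfg$n_genes > cfg$n_ig_genes + cfg$n_deg_genes + 1)
  empty <- cfg$cpc_source_counts > 0 & cfg$cluster_sizes == 0
  if (any(empty)) {
    stop("cpc_source_counts references an empty cluster: ",
         paste(which(empty), collapse = ", "), call. = FALSE)
  }
  invisible(cfg)
}

# Fixed immunoglobulin panel; extended systematically when more are asked for
ig_panel <- function(n) {
  base <- c("IGKV1-33", "IGHV4-28", "IGKV3D-7", "IGHA1", "IGHV1-24",
            "IGHV3-43", "IGKV3D-20", "IGKV4-1", "IGKC", "IGLV3-1",
            "IGLL5", "IGKV1-39")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, sprintf("IGHV9-%d", seq_len(n - length(base))))
}

#' Three-cluster scenario mirroring the P17 patient geometry
#'
#' Three BMMC subclusters (20, 14, 12 cells) with clusters 1 and 3
#' FAM46C-low, and 30 CPCs of which 25 originate in the low clusters
#' (source split 13/5/12) -- the configuration under which exact recovery
#' yields an 83.3% / 16.7% low/high contribution split.
#'
#' @param ... Overrides passed to [scenario_config()] (e.g. `noise_sd`,
#'   `seed`).
#' @return A `scenario_config`.
#' @export
scenario_p17 <- function(...) {
  defaults <- list(patient_id = "P17", cluster_sizes = c(20L, 14L, 12L),
                   low_clusters = c(1L, 3L), n_cpc = 30L,
                   cpc_source_counts = c(13L, 5L, 12L), own_ig = 5L)
  do.call(scenario_config, utils::modifyList(defaults, list(...)))
}

#' Two-cluster scenario mirroring the P20 patient geometry
#'
#' Two BMMC subclusters (24, 20 cells) with cluster 2 FAM46C-low, and 47
#' CPCs with a low-cluster source majority (12/35).
#'
#' @param ... Overrides passed to [scenario_config()].
#' @return A `scenario_config`.
#' @export
scenario_p20 <- function(...) {
  defaults <- list(patient_id = "P20", cluster_sizes = c(24L, 20L),
                   low_clusters = 2L, n_cpc = 47L,
                   cpc_source_counts = c(12L, 35L), own_ig = 3L)
  do.call(scenario_config, utils::modifyList(defaults, list(...)))
}

#' Simulate one patient's FPKM matrix with planted structure
#'
#' Generative model, all on the `log2(FPKM + 1)` scale unless noted:
#' background genes draw a baseline `b_g ~ N(3, 1.5)`; FAM46C has a fixed
#' baseline of 5; immunoglobulin genes sit at baseline -2 except the
#' patient's own, which gain +4. Each BMMC subcluster adds its own
#' per-gene offset `N(0, cluster_sep_log2)` on background genes, giving
#' clusters a recoverable identity. Cells add `N(0, 0.4)` noise; FAM46C in
#' low clusters gains `fam46c_low_log2_shift`. Values convert to FPKM via
#' `max(0, 2^x - 1)` and low-cluster cells are multiplied by
#' `global_low_scale` (the whole-transcriptome depression). Each CPC copies
#' the log2 profile of its designated source BMMC, adds `N(0, noise_sd)`
#' per gene, `cpc_fam46c_log2_shift` on FAM46C and +/- `deg_log2_shift` on
#' the planted DEG genes, and converts back to FPKM. Finally entries with
#' FPKM below 5 drop to zero with probability `dropout_rate`, mapped reads
#' draw from `Uniform[2e5, 2e6]`, and detected genes are counted as
#' `FPKM > 0`.
#'
#' @param cfg A [scenario_config()].
#' @return A list with elements `matrix` (an [fpkm_matrix] holding both
#'   compartments) and `truth` (a list with `bmmc_cluster_of_cell`,
#'   `source_bmmc_of_cpc`, `ig_genes_of_patient`, `planted_deg_genes`,
#'   `deg_direction`).
#' @export
#' @examples
#' sim <- simulate_patient(scenario_p17(seed = 7))
#' sim$matrix
#' head(sim$truth$source_bmmc_of_cpc)
simulate_patient <- function(cfg) {
  validate_scenario(cfg)
  withr::with_seed(cfg$seed, simulate_patient_impl(cfg))
}

simulate_patient_impl <- function(cfg) {
  ig_genes <- ig_panel(cfg$n_ig_genes)
  n_bg <- cfg$n_genes - cfg$n_ig_genes - 1L
  bg_genes <- sprintf("GENE%04d", seq_len(n_bg))
  genes <- c("FAM46C", ig_genes, bg_genes)

  n_bmmc <- sum(cfg$cluster_sizes)
  k <- length(cfg$cluster_sizes)
  bmmc_ids <- sprintf("%s_B%03d", cfg$patient_id, seq_len(n_bmmc))
  cpc_ids <- sprintf("%s_C%03d", cfg$patient_id, seq_len(cfg$n_cpc))
  cluster_of <- rep(seq_len(k), times = cfg$cluster_sizes)
  names(cluster_of) <- bmmc_ids

  # baselines on log2(FPKM+1) scale
  baseline <- c(5, rep(-2, cfg$n_ig_genes), stats::rnorm(n_bg, 3, 1.5))
  names(baseline) <- genes
  own_ig_genes <- ig_genes[cfg$own_ig]
  baseline[own_ig_genes] <- baseline[own_ig_genes] + 4

  # planted CPC-vs-BMMC differential genes, half up / half down; a fixed
  # slice of the panel so that every simulated patient plants the same
  # set, as the conjunctive cross-patient rule requires. Their baselines
  # are truncated to the solidly expressed range (>= 3.5 on log2(FPKM+1),
  # about 10 FPKM): a two-fold compartment change is only representable on
  # transcripts whose level survives the whole-transcriptome depression
  # and dropout with headroom above the +1 pseudocount
  deg_genes <- bg_genes[seq_len(cfg$n_deg_genes)]
  deg_dir <- rep(c(1, -1), length.out = cfg$n_deg_genes)
  names(deg_dir) <- deg_genes
  lo <- stats::pnorm(3.5, 3, 1.5)
  baseline[deg_genes] <- stats::qnorm(
    stats::runif(cfg$n_deg_genes, lo, 1), 3, 1.5)

  # per-cluster identity offsets, background genes only: each cluster
  # shifts each gene up or down by a fixed step with equal probability.
  # The bounded two-point form separates clusters as well as a Gaussian
  # of the same variance while keeping every per-gene offset finite
  delta <- matrix(0, cfg$n_genes, k, dimnames = list(genes, NULL))
  delta[bg_genes, ] <- sample(c(-1, 1), n_bg * k, replace = TRUE) *
    cfg$cluster_sep_log2

  x <- baseline + delta[, cluster_of, drop = FALSE] +
    stats::rnorm(cfg$n_genes * n_bmmc, 0, 0.4)
  dimnames(x) <- list(genes, bmmc_ids)
  low_cell <- cluster_of %in% cfg$low_clusters
  x["FAM46C", low_cell] <- x["FAM46C", low_cell] + cfg$fam46c_low_log2_shift
  fpkm_b <- 2^x - 1
  fpkm_b[fpkm_b < 0] <- 0
  fpkm_b[, low_cell] <- fpkm_b[, low_cell] * cfg$global_low_scale

  # pick source cells cluster by cluster (without replacement while the
  # cluster lasts, then with, since one BMMC may seed several CPCs)
  src <- unlist(lapply(seq_len(k), function(j) {
    pool <- bmmc_ids[cluster_of == j]
    n <- cfg$cpc_source_counts[j]
    if (n == 0L) return(character(0))
    sample(pool, n, replace = n > length(pool))
  }))
  y <- log2(fpkm_b[, src, drop = FALSE] + 1) +
    stats::rnorm(cfg$n_genes * cfg$n_cpc, 0, cfg$noise_sd)
  colnames(y) <- cpc_ids
  y["FAM46C", ] <- y["FAM46C", ] + cfg$cpc_fam46c_log2_shift
  y[deg_genes, ] <- y[deg_genes, ] + deg_dir * cfg$deg_log2_shift
  fpkm_c <- 2^y - 1
  fpkm_c[fpkm_c < 0] <- 0

  fpkm <- cbind(fpkm_b, fpkm_c)
  if (cfg$dropout_rate > 0) {
    cand <- which(fpkm > 0 & fpkm < 5)
    drop <- cand[stats::runif(length(cand)) < cfg$dropout_rate]
    fpkm[drop] <- 0
  }

  meta <- tibble::tibble(
    cell_id = c(bmmc_ids, cpc_ids),
    patient_id = cfg$patient_id,
    compartment = rep(c("BMMC", "CPC"), c(n_bmmc, cfg$n_cpc)),
    mapped_reads = round(stats::runif(n_bmmc + cfg$n_cpc, 2e5, 2e6)),
    n_genes_detected = unname(colSums(fpkm > 0)))

  truth <- list(bmmc_cluster_of_cell = cluster_of,
                source_bmmc_of_cpc = stats::setNames(src, cpc_ids),
                ig_genes_of_patient = own_ig_genes,
                planted_deg_genes = deg_genes,
                deg_direction = deg_dir,
                low_clusters = cfg$low_clusters)
  list(matrix = fpkm_matrix(fpkm, meta), truth = truth)
}

#' Simulate a multi-patient cohort with disjoint specific immunoglobulin genes
#'
#' Convenience wrapper: each patient gets its own seed and a disjoint slice
#' of the immunoglobulin panel, then the matrices are combined with
#' [bind_cells()]. Used to exercise the cross-patient stages.
#'
#' @param patient_ids Character vector of patient labels.
#' @param ig_per_patient How many panel genes each patient owns.
#' @param seed Base seed; patient `i` uses `seed + i - 1`.
#' @param ... Further overrides for every patient's [scenario_config()].
#' @return A list with `matrix` (combined [fpkm_matrix]) and `truths`
#'   (per-patient truth lists, named by patient).
#' @export
simulate_cohort <- function(patient_ids, ig_per_patient = 1L, seed = 1L, ...) {
  n_ig <- max(12L, length(patient_ids) * ig_per_patient)
  sims <- lapply(seq_along(patient_ids), function(i) {
    own <- (i - 1L) * ig_per_patient + seq_len(ig_per_patient)
    simulate_patient(scenario_config(patient_id = patient_ids[i],
                                     n_ig_genes = n_ig, own_ig = own,
                                     seed = seed + i - 1L, ...))
  })
  list(matrix = bind_cells(lapply(sims, `[[`, "matrix")),
       truths = stats::setNames(lapply(sims, `[[`, "truth"), patient_ids))
}
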