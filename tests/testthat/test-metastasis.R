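paired_matrices <- function(cpc_vals, bmmc_vals) {
  genes <- sprintf("g%02d", seq_len(nrow(cpc_vals)))
  rownames(cpc_vals) <- rownames(bmmc_vals) <- genes
  colnames(cpc_vals) <- sprintf("CPC%02d", seq_len(ncol(cpc_vals)))
  colnames(bmmc_vals) <- sprintf("B%02d", seq_len(ncol(bmmc_vals)))
  meta_c <- tibble::tibble(cell_id = colnames(cpc_vals), patient_id = "P1",
                           compartment = "CPC")
  meta_b <- tibble::tibble(cell_id = colnames(bmmc_vals), patient_id = "P1",
                           compartment = "BMMC")
  list(cpc = fpkm_matrix(cpc_vals, meta_c),
       bmmc = fpkm_matrix(bmmc_vals, meta_b))
}

test_that("Pearson correlations match a covariance oracle to 1e-12", {
  ms <- withr::with_seed(8, paired_matrices(
    matrix(stats::rexp(25, 0.2), 5, 5), matrix(stats::rexp(20, 0.2), 5, 4)))
  corr <- correlation_matrix(ms$cpc, ms$bmmc, rownames(ms$cpc$values))
  expect_equal(dim(corr), c(5L, 4L))
  for (i in rownames(corr)) {
    for (j in colnames(corr)) {
      expect_equal(corr[i, j],
                   oracle_pearson(log2(ms$cpc$values[, i] + 1),
                                  log2(ms$bmmc$values[, j] + 1)),
                   tolerance = 1e-12)
    }
  }
})

test_that("self- and anti-proportional profiles hit the correlation bounds", {
  b <- matrix(c(1, 3, 7, 15, 2, 2, 2, 4), 4, 2)
  cp <- cbind(b[, 1], 2^(5 - log2(b[, 1] + 1)) - 1)  # copy and log-mirror
  ms <- paired_matrices(cp, b)
  corr <- correlation_matrix(ms$cpc, ms$bmmc, rownames(ms$cpc$values))
  expect_equal(corr["CPC01", "B01"], 1, tolerance = 1e-12)
  expect_equal(corr["CPC02", "B01"], -1, tolerance = 1e-12)
})

test_that("zero-variance profiles turn into NaN with a warning", {
  b <- withr::with_seed(1, matrix(stats::rexp(12), 4, 3))
  cp <- cbind(b[, 1], rep(2, 4))
  ms <- paired_matrices(cp, b)
  expect_warning(corr <- correlation_matrix(ms$cpc, ms$bmmc,
                                            rownames(ms$cpc$values)),
                 "Zero-variance")
  expect_true(all(is.nan(corr["CPC02", ])))
  expect_warning(asn <- assign_best_match(corr), "dropped")
  expect_identical(asn$cpc_id, "CPC01")
})

test_that("assignment equals the brute-force argmax with the documented tie rule", {
  corr <- rbind(CPC1 = c(0.9, 0.2, 0.5), CPC2 = c(0.1, 0.8, 0.8))
  colnames(corr) <- c("B1", "B2", "B3")
  asn <- assign_best_match(corr)
  expect_identical(asn$bmmc_id, c("B1", "B2"))
  expect_identical(asn$tie, c(FALSE, TRUE))

  for (seed in 1:10) {
    corr <- withr::with_seed(seed, {
      x <- matrix(round(stats::runif(35, -1, 1), 2), 5, 7)
      dimnames(x) <- list(sprintf("CPC%d", 1:5), sprintf("B%02d", 1:7))
      x
    })
    asn <- assign_best_match(corr)
    expect_identical(stats::setNames(asn$bmmc_id, asn$cpc_id),
                     oracle_argmax(corr))
  }
})

test_that("assignments are invariant to BMMC column order", {
  corr <- withr::with_seed(4, {
    x <- matrix(stats::runif(24), 4, 6)
    dimnames(x) <- list(sprintf("CPC%d", 1:4), sprintf("B%02d", 1:6))
    x
  })
  asn <- assign_best_match(corr)
  perm <- withr::with_seed(5, sample(6))
  asn2 <- assign_best_match(corr[, perm])
  expect_equal(dplyr::arrange(asn, cpc_id), dplyr::arrange(asn2, cpc_id))

  single <- corr[, 1, drop = FALSE]
  expect_true(all(assign_best_match(single)$bmmc_id == "B01"))
})

test_that("metastasis rates implement M_j = C_j / C_p with conservation", {
  asn <- tibble::tibble(cpc_id = sprintf("CPC%02d", 1:30),
                        bmmc_id = c(rep("B01", 3), rep("B02", 27)))
  rates <- metastasis_rates(asn, c("B01", "B02", "B03"))
  expect_equal(rates$m_j[rates$bmmc_id == "B01"], 0.1)
  expect_equal(rates$c_j[rates$bmmc_id == "B03"], 0L)
  expect_equal(sum(rates$c_j), 30)
  expect_equal(sum(rates$m_j), 1)

  random_asn <- withr::with_seed(6, tibble::tibble(
    cpc_id = sprintf("CPC%02d", 1:47),
    bmmc_id = sample(sprintf("B%02d", 1:20), 47, replace = TRUE)))
  rates <- metastasis_rates(random_asn, sprintf("B%02d", 1:20))
  expect_equal(sum(rates$m_j), 1, tolerance = 1e-12)
  tally <- table(random_asn$bmmc_id)
  expect_equal(rates$c_j[match(names(tally), rates$bmmc_id)],
               as.integer(tally))
  expect_error(metastasis_rates(random_asn[0, ], "B01"), "C_p = 0")
})

test_that("group contributions sum to one and reproduce the 25-of-30 split", {
  labels <- stats::setNames(c(1L, 2L), c("B01", "B02"))
  grouping <- structure(list(group_of_cluster = c(`1` = "low", `2` = "high"),
                             merged_low = 1L, merged_high = 2L),
                        class = "fam46c_grouping")
  asn <- tibble::tibble(cpc_id = sprintf("CPC%02d", 1:30),
                        bmmc_id = c(rep("B01", 25), rep("B02", 5)))
  ct <- cluster_contributions(asn, grouping, labels)
  expect_equal(ct$percent[ct$group == "low"], 83.3)
  expect_equal(ct$percent[ct$group == "high"], 16.7)
  expect_equal(sum(ct$fraction), 1, tolerance = 1e-9)

  all_low <- cluster_contributions(
    dplyr::mutate(asn, bmmc_id = "B01"), grouping, labels)
  expect_equal(all_low$fraction, c(1, 0))
  expect_error(cluster_contributions(
    dplyr::mutate(asn, bmmc_id = "B99"), grouping, labels), "B99")
})

test_that("rate comparison follows an exact rank-sum oracle", {
  labels <- stats::setNames(c(1L, 1L, 1L, 2L, 2L, 2L), sprintf("B%02d", 1:6))
  grouping <- structure(list(group_of_cluster = c(`1` = "low", `2` = "high")),
                        class = "fam46c_grouping")
  # the archetypal split: all low-group cells matched, no high-group cell
  rates <- tibble::tibble(bmmc_id = sprintf("B%02d", 1:6),
                          c_j = c(2, 2, 1, 0, 0, 0),
                          m_j = c(0.2, 0.2, 0.1, 0, 0, 0))
  res <- suppressWarnings(compare_rates_by_group(rates, labels = labels,
                                                 grouping = grouping))
  expect_equal(res$direction, 1)
  # tie-free rates: the test is exact and must match full enumeration
  rates2 <- dplyr::mutate(rates, m_j = c(0.25, 0.2, 0.1, 0.15, 0.05, 0))
  res2 <- compare_rates_by_group(rates2, labels = labels, grouping = grouping)
  expect_equal(res2$p_value,
               oracle_ranksum_p(c(0.25, 0.2, 0.1), c(0.15, 0.05, 0)),
               tolerance = 1e-10)

  same <- dplyr::mutate(rates, m_j = rep(c(0.2, 0.1, 1 / 30), 2))
  res <- compare_rates_by_group(same, labels = labels, grouping = grouping)
  expect_gte(res$p_value, 0.99)
})

test_that("low-group BMMCs carry the higher metastasis rates in simulation", {
  hits <- vapply(1:10, function(s) {
    sim <- simulate_patient(scenario_p17(seed = 80 + s))
    cl <- sim$truth$bmmc_cluster_of_cell
    labels <- cl
    grouping <- structure(
      list(group_of_cluster = stats::setNames(
        ifelse(sort(unique(cl)) %in% sim$truth$low_clusters, "low", "high"),
        sort(unique(cl)))),
      class = "fam46c_grouping")
    rep <- metastasis_model(sim$matrix, structure(
      c(grouping, list(merged_low = sim$truth$low_clusters,
                       merged_high = setdiff(unique(cl), sim$truth$low_clusters))),
      class = "fam46c_grouping"), labels)
    grp <- grouping$group_of_cluster[as.character(labels[rep$rates$bmmc_id])]
    stats::median(rep$rates$m_j[grp == "low"]) >=
      stats::median(rep$rates$m_j[grp == "high"])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the Sankey export is a conserving three-layer node-link graph", {
  sim <- simulate_patient(scenario_p17(seed = 91, noise_sd = 0.2,
                                       dropout_rate = 0.05))
  res <- suppressWarnings(run_pipeline(sim$matrix, verbose = FALSE))
  rep <- res$per_patient$P17$metastasis
  path <- withr::local_tempfile(fileext = ".json")
  export_sankey(rep, path)
  graph <- jsonlite::read_json(path, simplifyVector = TRUE)
  n_matched <- sum(rep$rates$c_j > 0)
  n_clusters <- length(unique(rep$rates$cluster[rep$rates$c_j > 0]))
  expect_equal(nrow(graph$nodes), n_clusters + n_matched + rep$c_p)
  cpc_layer <- graph$links[graph$links$target %in%
                             graph$nodes$id[graph$nodes$layer == "cpc"], ]
  expect_equal(sum(cpc_layer$value), rep$c_p)
  cluster_layer <- graph$links[graph$links$source %in%
                                 graph$nodes$id[graph$nodes$layer == "cluster"], ]
  expect_equal(sum(cluster_layer$value), rep$c_p)
  expect_true(all(graph$links$source %in% graph$nodes$id))
  expect_true(all(graph$links$target %in% graph$nodes$id))
})
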