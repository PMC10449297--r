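blob_features <- function(centers, n_per, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
      matrix(stats::rnorm(n_per * ncol(centers), mean = 0, sd = sd),
             nrow = n_per) + matrix(centers[i, ], n_per, ncol(centers),
                                    byrow = TRUE)
    }))
    rownames(x) <- sprintf("c%03d", seq_len(nrow(x)))
    x
  })
}

test_that("the feature matrix is a z-scored log transform", {
  m <- random_fpkm(40, 15, seed = 11)
  f <- feature_matrix(m, rownames(m$values))
  expect_equal(unname(colMeans(f)), rep(0, ncol(f)), tolerance = 1e-9)
  expect_equal(unname(apply(f, 2, stats::sd)), rep(1, ncol(f)),
               tolerance = 1e-9)
  # oracle: explicit two-pass z-score of log2(FPKM + 1)
  g <- colnames(f)[3]
  v <- log2(m$values[g, ] + 1)
  expect_equal(unname(f[, g]), unname((v - mean(v)) / stats::sd(v)),
               tolerance = 1e-10)
})

test_that("zero-variance features are dropped with a warning", {
  m <- random_fpkm(10, 8, seed = 12)
  m$values["G001", ] <- 5
  expect_warning(f <- feature_matrix(m, rownames(m$values)), "G001")
  expect_false("G001" %in% colnames(f))
  m$values[] <- 2
  expect_error(feature_matrix(m, rownames(m$values)), "zero variance")
})

test_that("clustering recovers well-separated blobs exactly", {
  x <- blob_features(rbind(c(0, 0, 0), c(10, 10, 10)), n_per = 20)
  labels <- cluster_cells(x, 2)
  expect_equal(unname(labels), rep(c(1, 2), each = 20))
  expect_equal(unname(cluster_cells(x, 1)), rep(1L, 40))
  expect_error(cluster_cells(x, 41), "1..n_cells")
})

test_that("cluster labels are invariant to input order up to nothing", {
  x <- blob_features(rbind(c(0, 0), c(8, 8), c(-8, 8)), n_per = 12, seed = 5)
  labels <- cluster_cells(x, 3)
  perm <- withr::with_seed(2, sample(nrow(x)))
  labels_perm <- cluster_cells(x[perm, ], 3)
  expect_identical(labels_perm[names(labels)], labels)
})

test_that("average silhouette equals the O(n^2) definition to 1e-10", {
  for (seed in 1:5) {
    x <- withr::with_seed(seed, matrix(stats::rnorm(50 * 4), 50, 4))
    rownames(x) <- sprintf("c%02d", 1:50)
    for (k in 2:4) {
      labels <- cluster_cells(x, k)
      model <- select_k_silhouette(x, k_range = k)
      expect_equal(model$silhouette$avg_silhouette,
                   oracle_avg_silhouette(x, labels), tolerance = 1e-10)
    }
  }
})

test_that("silhouette selection finds the planted number of blobs", {
  x2 <- blob_features(rbind(c(0, 0, 0), c(9, 9, 9)), n_per = 20, seed = 7)
  expect_equal(select_k_silhouette(x2, 1:10)$k_selected, 2)
  x3 <- blob_features(rbind(c(0, 0, 0), c(9, 9, 9), c(-9, 9, -9)),
                      n_per = 15, seed = 8)
  m3 <- select_k_silhouette(x3, 1:10)
  expect_equal(m3$k_selected, 3)
  expect_true(all(m3$silhouette$avg_silhouette >= -1 &
                    m3$silhouette$avg_silhouette <= 1))
  expect_equal(m3$silhouette$avg_silhouette[m3$silhouette$k == 1], 0)
})

test_that("duplicated points give a perfect silhouette at the true k", {
  x <- rbind(matrix(0, 5, 3), matrix(4, 5, 3))
  rownames(x) <- sprintf("c%02d", 1:10)
  model <- select_k_silhouette(x, 1:5)
  expect_equal(model$k_selected, 2)
  expect_equal(max(model$silhouette$avg_silhouette), 1)
})

test_that("FAM46C grouping takes the max-mean cluster as high and merges the rest", {
  vals <- matrix(c(2^1 - 1, 2^1.2 - 1, 2^4 - 1, 2^3.9 - 1, 2^0.9 - 1, 2^1.1 - 1),
                 nrow = 1, dimnames = list("FAM46C", paste0("c", 1:6)))
  vals <- rbind(vals, OTHER = 1)
  meta <- tibble::tibble(cell_id = paste0("c", 1:6), patient_id = "P1",
                         compartment = "BMMC")
  m <- fpkm_matrix(vals, meta)
  labels <- stats::setNames(c(1L, 1L, 2L, 2L, 3L, 3L), paste0("c", 1:6))
  gr <- label_fam46c_groups(m, labels)
  expect_equal(gr$merged_high, 2L)
  expect_setequal(gr$merged_low, c(1L, 3L))
  expect_equal(unname(gr$group_of_cluster[c("1", "2", "3")]),
               c("low", "high", "low"))
  expect_error(label_fam46c_groups(m, labels, "MISSING"), "not found")
})

test_that("planted FAM46C-low clusters are recovered from simulated BMMCs", {
  hits <- vapply(1:10, function(s) {
    sim <- simulate_patient(scenario_p17(seed = 60 + s))
    bm <- subset_matrix(sim$matrix, cells = cells_of(sim$matrix, "BMMC"))
    feats <- suppressWarnings(
      feature_matrix(bm, union(sim$truth$planted_deg_genes,
                               identify_ig_genes(rownames(bm$values)))))
    cm <- select_k_silhouette(feats)
    gr <- label_fam46c_groups(bm, cm$labels)
    cl <- sim$truth$bmmc_cluster_of_cell
    truth_low <- names(cl)[cl %in% sim$truth$low_clusters]
    setequal(names(cm$labels)[cm$labels %in% gr$merged_low], truth_low)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("tidy and glance summarise a cluster model", {
  x <- blob_features(rbind(c(0, 0), c(7, 7)), n_per = 10, seed = 3)
  model <- select_k_silhouette(x, 1:5)
  td <- generics::tidy(model)
  expect_identical(names(td), c("cell_id", "cluster"))
  expect_equal(nrow(td), 20)
  gl <- generics::glance(model)
  expect_equal(gl$k_selected, 2)
  expect_equal(gl$n_cells, 20)
})
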