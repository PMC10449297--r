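# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive each quantity from first principles and do
# not share code with the package.

oracle_anova <- function(groups) {
  v <- unlist(groups)
  k <- length(groups)
  n <- length(v)
  gm <- mean(v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(f = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

oracle_welch <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                   (vb / length(b))^2 / (length(b) - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

# O(n^2) silhouette from the definition s(i) = (b_i - a_i)/max(a_i, b_i)
oracle_avg_silhouette <- function(features, labels) {
  n <- nrow(features)
  dmat <- as.matrix(stats::dist(features))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a_i <- mean(dmat[i, setdiff(own, i)])
    b_i <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(dmat[i, labels == cl])
    }, numeric(1)))
    s[i] <- (b_i - a_i) / max(a_i, b_i)
  }
  mean(s)
}

oracle_pearson <- function(x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# per-row argmax with ties to the lexicographically smallest column name
oracle_argmax <- function(corr) {
  out <- character(0)
  for (i in rownames(corr)) {
    r <- corr[i, ]
    r <- r[is.finite(r)]
    if (!length(r)) next
    best <- names(r)[r == max(r)]
    out[i] <- sort(best)[1]
  }
  out
}

# exact two-sided rank-sum p by enumeration of group assignments
oracle_ranksum_p <- function(a, b) {
  v <- c(a, b)
  r <- rank(v)
  obs <- sum(r[seq_along(a)])
  combos <- utils::combn(length(v), length(a))
  stats_all <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- mean(stats_all)
  mean(abs(stats_all - mu) >= abs(obs - mu) - 1e-12)
}

# small literal fixture used across io / qc tests
tiny_matrix <- function() {
  vals <- matrix(c(5, 0, 0.4,
                   2, 1.5, 0,
                   0, 3, 0.9),
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("FAM46C", "IGKC", "GENE0001"),
                                 c("c1", "c2", "c3")))
  meta <- tibble::tibble(cell_id = c("c1", "c2", "c3"),
                         patient_id = "P17",
                         compartment = c("BMMC", "BMMC", "CPC"),
                         mapped_reads = c(2e5, 3e5, 4e5),
                         n_genes_detected = c(2L, 2L, 2L))
  fpkm_matrix(vals, meta)
}

random_fpkm <- function(n_genes, n_cells, seed = 1, patients = "P01",
                        compartment = NULL) {
  withr::with_seed(seed, {
    vals <- matrix(round(stats::rexp(n_genes * n_cells, rate = 0.2), 4),
                   nrow = n_genes,
                   dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                                   sprintf("c%03d", seq_len(n_cells))))
    if (is.null(compartment)) {
      compartment <- sample(c("BMMC", "CPC"), n_cells, replace = TRUE)
    }
    meta <- tibble::tibble(cell_id = colnames(vals),
                           patient_id = rep_len(patients, n_cells),
                           compartment = rep_len(compartment, n_cells),
                           mapped_reads = round(stats::runif(n_cells, 2e5, 2e6)),
                           n_genes_detected = colSums(vals > 0))
    fpkm_matrix(vals, meta)
  })
}
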