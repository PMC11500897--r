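# Small in-code fixtures and independent oracles shared across the suite.

# Dataset tibble from a genotype matrix and phenotype vector.
toy_gwas <- function(geno, class, snp_names = NULL) {
  if (is.null(snp_names)) snp_names <- paste0("S", seq_len(ncol(geno)))
  out <- tibble::as_tibble(as.data.frame(geno), .name_repair = ~snp_names)
  out$Class <- as.integer(class)
  out
}

# Two-sample, one-SNP datasets realising a single contingency cell with the
# given class split.
cell_gwas <- function(n_control, n_case) {
  toy_gwas(matrix(0L, n_control + n_case, 1),
           c(rep(0L, n_control), rep(1L, n_case)))
}

# A 12-sample dataset whose first SNP equals the phenotype (perfect
# separation) and whose remaining SNPs are arbitrary.
separating_gwas <- function() {
  cls <- rep(c(0L, 1L), each = 6)
  g <- cbind(cls,
             rep(0:2, 4),
             c(rep(0L, 3), rep(1L, 3), rep(2L, 3), rep(0L, 3)))
  toy_gwas(g, cls, c("SEP", "CYC", "BLK"))
}

# Dataset realising an explicit per-combination class count table: one SNP
# column per needed arity is avoided by using two SNPs whose joint genotypes
# enumerate the rows. counts: matrix with columns (n_control, n_case).
table_gwas <- function(counts) {
  stopifnot(nrow(counts) <= 9)
  g1 <- (seq_len(nrow(counts)) - 1L) %% 3L
  g2 <- (seq_len(nrow(counts)) - 1L) %/% 3L
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    n0 <- counts[i, 1]; n1 <- counts[i, 2]
    cbind(g1 = rep(g1[i], n0 + n1), g2 = rep(g2[i], n0 + n1),
          cls = c(rep(0L, n0), rep(1L, n1)))
  })
  m <- do.call(rbind, rows)
  toy_gwas(m[, 1:2, drop = FALSE], m[, 3], c("A", "B"))
}

# Naive G-test of independence computed directly from a counts matrix
# (rows = genotype combinations, columns = classes); the independent oracle
# for g_test.
naive_g_test <- function(counts) {
  m <- sum(counts)
  stat <- 0
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      o <- counts[i, j]
      if (o > 0) {
        e <- sum(counts[i, ]) * sum(counts[, j]) / m
        stat <- stat + o * log(o / e)
      }
    }
  }
  stat <- 2 * stat
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

# Exhaustive minimum-K2 subset search over all nonempty subsets; the oracle
# for the greedy noise elimination.
exhaustive_min_k2 <- function(data, snps, ml) {
  ds <- epi_data(data)
  best <- NULL; best_k2 <- Inf
  for (sz in seq_along(snps)) {
    for (sub in utils::combn(snps, sz, simplify = FALSE)) {
      v <- k2_score(ds, sub, ml = ml)
      if (v < best_k2) { best_k2 <- v; best <- sub }
    }
  }
  sort(best)
}

# A small standard benchmark model shared by several tests.
test_model <- function(h2 = 0.2, maf = 0.2, k = 2, seed = 400) {
  find_dnme_model(k, rep(maf, k), h2, seed = seed, model_id = "M0")
}
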