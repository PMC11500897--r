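test_that("automatic order and table cap follow the sample-count formulas", {
  expect_identical(auto_mo(800, 800), 6L)    # floor(ln 800 - 0.5)
  expect_identical(auto_mo(1868, 2938), 7L)  # floor(ln 1868 - 0.5)
  expect_identical(auto_mo(20, 20), 2L)
  expect_error(auto_mo(3, 3), "too few samples")

  expect_identical(auto_ml(800, 800), 80L)
  expect_identical(auto_ml(1868, 2938), 186L)
  expect_identical(auto_ml(25, 99), 2L)
  expect_error(auto_ml(15, 99), "too few samples")
})

test_that("contingency tables enumerate observed combinations and conserve counts", {
  const <- toy_gwas(matrix(0L, 7, 1), c(0, 0, 0, 1, 1, 1, 1))
  tab <- snp_contingency(const, 1)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$n, 7L)

  four <- toy_gwas(cbind(c(0L, 1L, 2L, 0L), c(0L, 0L, 0L, 1L)),
                   c(0, 0, 1, 1))
  tab4 <- snp_contingency(four, c(1, 2))
  expect_equal(nrow(tab4), 4L)
  expect_true(all(tab4$n == 1L))

  sim <- simulate_gwas(test_model(), n_cases = 60, n_controls = 50,
                       n_snps = 8, seed = 5)
  tab_s <- snp_contingency(sim$data, c(2, 5, 7))
  expect_equal(sum(tab_s$n_control), 50L)
  expect_equal(sum(tab_s$n_case), 60L)

  expect_error(snp_contingency(four, integer(0)), "at least one SNP")
})

test_that("truncation is a no-op below the cap and pools weak cells above it", {
  four <- toy_gwas(cbind(c(0L, 1L, 2L, 0L), c(0L, 0L, 0L, 1L)),
                   c(0, 0, 1, 1))
  tab <- snp_contingency(four, c(1, 2))
  expect_identical(truncate_table(tab, 5, "k2"), tab)

  # cells with class splits (2,0), (5,0), (3,3), (4,4): K2 contributions
  # ln3, ln6, ln140, ln630 -- the two largest (weak-evidence) cells are
  # retained at ml = 3 and the two strong cells pooled into (7,0)
  counts <- rbind(c(2, 0), c(5, 0), c(3, 3), c(4, 4))
  dat <- table_gwas(counts)
  tt <- truncate_table(snp_contingency(dat, c("A", "B")), 3, "k2")
  expect_equal(nrow(tt), 3L)
  expect_true(any(tt$pooled))
  pooled <- tt[tt$pooled, ]
  expect_equal(pooled$n_control, 7L)
  expect_equal(pooled$n_case, 0L)
  kept <- tt[!tt$pooled, ]
  expect_setequal(kept$n, c(6L, 8L))
  # sample counts are conserved through pooling
  expect_equal(sum(tt$n), sum(counts))
  expect_equal(sum(tt$n_control), sum(counts[, 1]))
  # the truncated score equals the hand-computed cell sum
  expect_equal(k2_score(dat, c("A", "B"), ml = 3),
               log(140) + log(630) + (lgamma(9) - lgamma(8)),
               tolerance = 1e-12)
})

test_that("K2 cell values match factorial arithmetic and favour purity", {
  expect_equal(k2_score(cell_gwas(1, 1), 1), log(6), tolerance = 1e-12)
  expect_equal(k2_score(cell_gwas(2, 0), 1), log(3), tolerance = 1e-12)

  sep <- separating_gwas()
  base <- k2_score(sep, "SEP")
  set.seed(1)
  for (i in 1:20) {
    perm <- sep
    perm$Class <- sample(perm$Class)
    expect_gte(k2_score(perm, "SEP"), base)
  }
})

test_that("conditional entropy is 0 under perfect association and ln 2 under independence", {
  sep <- separating_gwas()
  expect_equal(ce_score(sep, "SEP"), 0, tolerance = 1e-12)
  # constant SNP, balanced classes: H(Y|X) = H(Y) = ln 2
  indep <- cell_gwas(6, 6)
  expect_equal(ce_score(indep, 1), log(2), tolerance = 1e-12)
  # entropy bound for balanced classes
  set.seed(2)
  for (i in 1:25) {
    g <- matrix(sample(0:2, 24, TRUE), 12, 2)
    d <- toy_gwas(g, rep(c(0, 1), 6))
    v <- ce_score(d, c(1, 2))
    expect_gte(v, 0)
    expect_lte(v, log(2) + 1e-12)
  }
})

test_that("Gini impurity is 0 under perfect association and 0.5 under independence", {
  expect_equal(gini_score(separating_gwas(), "SEP"), 0, tolerance = 1e-12)
  expect_equal(gini_score(cell_gwas(6, 6), 1), 0.5, tolerance = 1e-12)
  set.seed(3)
  for (i in 1:25) {
    g <- matrix(sample(0:2, 24, TRUE), 12, 2)
    d <- toy_gwas(g, sample(c(0, 1), 12, TRUE))
    v <- gini_score(d, c(1, 2))
    expect_gte(v, 0)
    expect_lte(v, 0.5 + 1e-12)
  }
})

test_that("all three objectives attain their minimum on the separating SNP over exhaustive permutations", {
  sep <- separating_gwas()[1:10, ]  # 5 controls + 5 cases
  base <- c(k2_score(sep, "SEP"), ce_score(sep, "SEP"),
            gini_score(sep, "SEP"))
  cls <- sep$Class
  perms <- utils::combn(10, 5, simplify = FALSE)
  for (case_rows in perms) {
    perm <- sep
    perm$Class <- 0L
    perm$Class[case_rows] <- 1L
    v <- c(k2_score(perm, "SEP"), ce_score(perm, "SEP"),
           gini_score(perm, "SEP"))
    expect_true(all(v >= base - 1e-12))
  }
})

test_that("truncated and untruncated scores agree when the table fits the cap", {
  sim <- simulate_gwas(test_model(), n_cases = 100, n_controls = 100,
                       n_snps = 10, seed = 6)
  set.seed(7)
  for (i in 1:15) {
    snps <- sample(10, sample(1:2, 1))
    n_combos <- nrow(snp_contingency(sim$data, snps))
    ml <- n_combos + sample(0:3, 1)
    expect_equal(k2_score(sim$data, snps, ml = ml),
                 k2_score(sim$data, snps, ml = Inf))
    expect_equal(ce_score(sim$data, snps, ml = ml),
                 ce_score(sim$data, snps, ml = Inf))
    expect_equal(gini_score(sim$data, snps, ml = ml),
                 gini_score(sim$data, snps, ml = Inf))
  }
})

test_that("scores stay finite in log space at large sample counts", {
  n <- 2e5
  dat <- toy_gwas(matrix(rep(0:1, n / 2), ncol = 1),
                  rep(c(0L, 0L, 1L, 1L), n / 4))
  expect_true(is.finite(k2_score(dat, 1)))
  expect_true(k2_score(dat, 1) > 0)
})

test_that("the G-test matches hand evaluation and a naive oracle", {
  flat <- table_gwas(rbind(c(30, 30), c(30, 30)))
  gt <- g_test(flat, c("A", "B"))
  expect_equal(gt$statistic, 0, tolerance = 1e-12)
  expect_equal(gt$p_value, 1)

  cross <- table_gwas(rbind(c(50, 10), c(10, 50)))
  gt2 <- g_test(cross, c("A", "B"))
  expect_equal(gt2$statistic, 58.2206, tolerance = 1e-4)
  expect_equal(gt2$df, 1L)
  expect_equal(gt2$p_value, pchisq(gt2$statistic, 1, lower.tail = FALSE))

  set.seed(8)
  for (i in 1:40) {
    nr <- sample(c(2, 3, 9), 1)
    counts <- matrix(sample(0:30, nr * 2, TRUE), nr, 2)
    counts[rowSums(counts) == 0, 1] <- 1  # every combination observed
    if (sum(counts[, 1]) == 0) counts[1, 1] <- 1
    if (sum(counts[, 2]) == 0) counts[1, 2] <- 1
    dat <- table_gwas(counts)
    got <- g_test(dat, c("A", "B"))
    oracle <- naive_g_test(counts)
    expect_equal(got$statistic, oracle$statistic, tolerance = 1e-10)
    expect_equal(got$df, oracle$df)
    expect_equal(got$p_value, oracle$p_value, tolerance = 1e-10)
  }
})

test_that("degenerate tables are rejected by the G-test", {
  one_combo <- cell_gwas(5, 5)
  expect_error(g_test(one_combo, 1), "degenerate")
  one_class <- toy_gwas(cbind(c(0L, 1L, 2L)), c(0, 0, 0))
  expect_error(g_test(one_class, 1), "degenerate")
})
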