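# Drivers for the internal engine operations.
make_engine <- function(data, control) {
  ds <- epi_data(data)
  ctl <- episparrow:::resolve_control(control, ds)
  episparrow:::new_engine(ds, ctl)
}

set_pop <- function(eng, positions) {
  storage.mode(positions) <- "integer"
  episparrow:::eng_init_pop(eng$ptr, positions)
  eng
}

pop_pos <- function(eng) episparrow:::eng_positions(eng$ptr)

# A 12-sample panel: SNP 1 separates the classes perfectly, the rest are
# noise-like.
panel_gwas <- function(n_snps = 20) {
  cls <- rep(c(0L, 1L), each = 6)
  set.seed(99)
  g <- cbind(cls, matrix(sample(0:2, 12 * (n_snps - 1), TRUE), 12))
  toy_gwas(g, cls)
}

check_pop_invariants <- function(eng, mo, N) {
  pos <- pop_pos(eng)
  expect_equal(ncol(pos), mo)
  for (i in seq_len(nrow(pos))) {
    row <- pos[i, ]
    expect_equal(length(unique(row)), mo)
    expect_true(all(row >= 1 & row <= N))
  }
  expect_false(anyDuplicated(episparrow:::eng_counters(eng$ptr)) > 0)
}

small_control <- function(n = 10, ...) {
  epi_ssa_control(n = n, max_iter = 5, mo = 3, ml = 40, seed = 1, ...)
}

test_that("initial populations are valid, seeded and handle the N = mo corner", {
  dat <- panel_gwas()
  eng <- make_engine(dat, small_control())
  withr::with_seed(4, episparrow:::init_population(eng))
  check_pop_invariants(eng, 3, 20)
  expect_equal(episparrow:::eng_size(eng$ptr), 10L)

  eng2 <- make_engine(dat, small_control())
  withr::with_seed(4, episparrow:::init_population(eng2))
  expect_identical(pop_pos(eng), pop_pos(eng2))

  tiny <- panel_gwas(3)
  eng3 <- make_engine(tiny, small_control())
  withr::with_seed(4, episparrow:::init_population(eng3))
  p3 <- pop_pos(eng3)
  for (i in 1:10) expect_setequal(p3[i, ], 1:3)

  expect_error(epi_ssa(panel_gwas(2), small_control()), "N >= mo")
})

test_that("keep-the-better insertion conserves size and rejects dominated proposals", {
  dat <- panel_gwas()
  eng <- make_engine(dat, small_control())
  # the best member contains the separating SNP; a noise proposal replacing
  # it is dominated and must be discarded
  set_pop(eng, rbind(c(1L, 2L, 3L), c(10L, 11L, 12L)))
  before <- pop_pos(eng)
  episparrow:::keep_better(eng, 1L, c(13L, 14L, 15L))
  expect_identical(pop_pos(eng), before)
  # a proposal containing the separating SNP displaces a noise incumbent
  episparrow:::keep_better(eng, 2L, c(1L, 14L, 15L))
  after <- pop_pos(eng)
  expect_equal(nrow(after), 2L)
  expect_true(any(apply(after, 1, function(r) 1L %in% r && 14L %in% r)))
})

test_that("producer updates conserve population size deterministically", {
  dat <- panel_gwas()
  run_producers <- function() {
    eng <- make_engine(dat, small_control())
    withr::with_seed(4, episparrow:::init_population(eng))
    withr::with_seed(5, episparrow:::update_producers(eng))
    eng
  }
  e1 <- run_producers()
  expect_equal(episparrow:::eng_size(e1$ptr), 10L)
  check_pop_invariants(e1, 3, 20)
  e2 <- run_producers()
  expect_identical(pop_pos(e1), pop_pos(e2))
})

test_that("scrounger pss draws are forced onto concentrated weights", {
  dat <- panel_gwas()
  eng <- make_engine(dat, small_control(n = 6))
  # incumbents built only from noise SNPs 10..20
  pos <- withr::with_seed(6, t(replicate(6, sample(10:20, 3))))
  set_pop(eng, pos)
  eng$pss[] <- 1e-12
  eng$pss[1:3] <- 1  # concentrate on {separating SNP, 2, 3}
  withr::with_seed(7, episparrow:::update_scroungers(eng))
  out <- pop_pos(eng)
  expect_equal(nrow(out), 6L)
  # scroungers in the pss branch must have proposed exactly {1,2,3}, which
  # contains the separating SNP and therefore displaced noise incumbents
  n_forced <- sum(apply(out, 1, function(r) setequal(r, 1:3)))
  expect_gte(n_forced, 3)
})

test_that("scout spawning enlarges the population by floor(n * sd)", {
  dat <- panel_gwas()
  eng <- make_engine(dat, epi_ssa_control(n = 20, max_iter = 1, mo = 3,
                                          ml = 5, seed = 1))
  withr::with_seed(8, episparrow:::init_population(eng))
  base <- pop_pos(eng)
  withr::with_seed(9, episparrow:::spawn_scouts(eng))
  expect_equal(episparrow:::eng_size(eng$ptr), 24L)  # 20 + floor(20 * 0.2)
  check_pop_invariants(eng, 3, 20)

  eng2 <- make_engine(dat, epi_ssa_control(n = 20, max_iter = 1, mo = 3,
                                           ml = 5, seed = 1))
  withr::with_seed(8, episparrow:::init_population(eng2))
  withr::with_seed(9, episparrow:::spawn_scouts(eng2))
  expect_identical(pop_pos(eng), pop_pos(eng2))
})

test_that("population diversity follows the distinct-SNP proportion", {
  same <- matrix(rep(c(1L, 5L, 9L, 2L, 7L, 3L), each = 20), 20)
  expect_equal(spas_chaos(same), 6 / 120)  # 1/n with n = 20
  disjoint <- matrix(1:120, 20, 6)
  expect_equal(spas_chaos(disjoint), 1)
  # capped denominator: with 120 slots over a 100-SNP panel, full coverage
  # of the panel counts as maximal diversity
  covering <- matrix(c(1:100, 1:20), 20, 6)
  expect_equal(spas_chaos(covering, n_snps = 100), 1)
  expect_lt(spas_chaos(covering), 1)
  set.seed(10)
  for (i in 1:10) {
    m <- matrix(sample(50, 24, TRUE), 4)
    v <- spas_chaos(m)
    expect_gt(v, 0); expect_lte(v, 1)
  }
})

test_that("trimming removes the right end and restores size n", {
  # SNP 1 separates the classes; every other SNP is constant, so members
  # without SNP 1 are uninformative and the one member holding it is the
  # unique best
  cls <- rep(c(0L, 1L), each = 6)
  dat <- toy_gwas(cbind(cls, matrix(0L, 12, 19)), cls)
  eng <- make_engine(dat, small_control())
  noise_pos <- withr::with_seed(11, t(replicate(10, sample(4:20, 3))))
  set_pop(eng, rbind(c(1L, 2L, 3L), noise_pos))
  best <- pop_pos(eng)[1, ]
  expect_true(1L %in% best)
  episparrow:::trim_population(eng, local_optimum = TRUE, 1L)
  expect_equal(episparrow:::eng_size(eng$ptr), 10L)
  expect_false(any(apply(pop_pos(eng), 1, function(r) 1L %in% r)))

  eng2 <- make_engine(dat, small_control())
  set_pop(eng2, rbind(c(1L, 2L, 3L), noise_pos))
  episparrow:::trim_population(eng2, local_optimum = FALSE, 1L)
  expect_equal(episparrow:::eng_size(eng2$ptr), 10L)
  expect_true(setequal(pop_pos(eng2)[1, ], best))
})

test_that("a full iteration cycle conserves size and member validity", {
  dat <- panel_gwas()
  eng <- make_engine(dat, epi_ssa_control(n = 10, max_iter = 3, mo = 3,
                                          ml = 5, seed = 1))
  ns <- floor(10 * 0.2)
  withr::with_seed(12, {
    episparrow:::init_population(eng)
    for (g in 1:3) {
      prev_best <- episparrow:::eng_scores(eng$ptr)[1, , drop = FALSE]
      episparrow:::update_producers(eng)
      expect_equal(episparrow:::eng_size(eng$ptr), 10L)
      episparrow:::update_scroungers(eng)
      expect_equal(episparrow:::eng_size(eng$ptr), 10L)
      # keep-the-better steps never worsen the incumbent best: the new best
      # weakly beats the previous best in a head-to-head ranking
      duel <- episparrow:::pop_rank_sums(
        rbind(episparrow:::eng_scores(eng$ptr)[1, ], prev_best))
      expect_lte(duel[1], duel[2])
      episparrow:::spawn_scouts(eng)
      expect_equal(episparrow:::eng_size(eng$ptr), 10L + ns)
      check_pop_invariants(eng, 3, 20)
      episparrow:::detect_in_population(eng, g)
      episparrow:::trim_population(
        eng, spas_chaos(pop_pos(eng), 20) < 0.6, ns)
      expect_equal(episparrow:::eng_size(eng$ptr), 10L)
    }
  })
  expect_true(all(eng$pss > 0 & eng$pss <= 1))
})

test_that("full runs are deterministic and empty at zero iterations", {
  sim <- simulate_gwas(test_model(), n_cases = 100, n_controls = 100,
                       n_snps = 15, seed = 20)
  ctl <- epi_ssa_control(n = 10, max_iter = 0, mo = 3, ml = 10, seed = 3)
  expect_equal(nrow(epi_ssa(sim$data, ctl)$findings), 0)

  ctl$max_iter <- 25L
  f1 <- epi_ssa(sim$data, ctl)
  f2 <- epi_ssa(sim$data, ctl)
  expect_identical(f1$findings, f2$findings)
  expect_identical(f1$population, f2$population)
  expect_identical(f1$pss, f2$pss)
  expect_true(all(f1$pss > 0 & f1$pss <= 1))
  # the caller's RNG state is untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(epi_ssa(sim$data, ctl)); after <- runif(1)
  expect_identical(before, after)
})

test_that("short searches recover an easy planted pair as the top finding", {
  model <- test_model(h2 = 0.2, maf = 0.2)
  hits <- 0
  for (s in 1:5) {
    sim <- simulate_gwas(model, n_cases = 400, n_controls = 400,
                         n_snps = 40, seed = 30 + s)
    fit <- epi_ssa(sim$data, epi_ssa_control(n = 20, max_iter = 60, seed = s))
    if (nrow(fit$findings) > 0 &&
        setequal(fit$findings$snps[[1]], sim$truth$snps[[1]])) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 4)
})
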