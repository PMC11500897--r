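#' Search parameters for the sparrow search engine
#'
#' Collects and validates the tunable parameters of [epi_ssa()]. Defaults
#' mirror the method's standard settings; `mo = 0` and `ml = 0` request
#' automatic resolution from the sample counts via [auto_mo()] and
#' [auto_ml()].
#'
#' @param n Population size (number of sparrows).
#' @param max_iter Number of search iterations (`maxG`).
#' @param pd Producer fraction of the population, in (0, 1).
#' @param sd Scout/detection fraction, in (0, 1): `floor(n * sd)` sparrows are
#'   spawned, inspected for epistasis and trimmed each iteration.
#' @param st Safety threshold in \[0.5, 1\] governing how aggressively
#'   producers mutate.
#' @param mo Maximum epistasis order (position-vector length); 0 = automatic.
#' @param ml Contingency-table cap; 0 = automatic.
#' @param cg Significance threshold for recording a finding (G-test p-value).
#' @param threshold_spas_chaos Population-diversity threshold below which a
#'   local optimum is declared (see [spas_chaos()]).
#' @param seed Integer seed; the whole run is deterministic given
#'   (dataset, seed).
#' @param bonferroni If `TRUE`, `cg` is divided by the number of SNP pairs
#'   `choose(N, 2)` before gating findings (off by default; the method applies
#'   `cg` raw).
#' @return A list of class `epi_ssa_control`.
#' @export
epi_ssa_control <- function(n = 20L, max_iter = 160L, pd = 0.4, sd = 0.2,
                            st = 0.8, mo = 0L, ml = 0L, cg = 0.05,
                            threshold_spas_chaos = 0.6, seed = 0L,
                            bonferroni = FALSE) {
  stopifnot(n >= 2, max_iter >= 0, pd > 0, pd < 1, sd > 0, sd < 1,
            st >= 0.5, st <= 1, mo >= 0, ml == 0 || ml >= 2,
            cg > 0, cg <= 1, threshold_spas_chaos > 0,
            threshold_spas_chaos <= 1)
  if (floor(pd * n) < 2)
    abort("need at least 2 producers: increase n or pd")
  if (floor(sd * n) < 1)
    abort("need at least 1 scout: increase n or sd")
  structure(list(n = as.integer(n), max_iter = as.integer(max_iter), pd = pd,
                 sd = sd, st = st, mo = as.integer(mo), ml = as.integer(ml),
                 cg = cg, threshold_spas_chaos = threshold_spas_chaos,
                 seed = as.integer(seed), bonferroni = isTRUE(bonferroni)),
            class = "epi_ssa_control")
}

# Resolve automatic mo/ml against a dataset; returns the control with mo/ml
# filled and checked against N.
resolve_control <- function(control, ds) {
  if (control$mo == 0L) control$mo <- auto_mo(ds$m0, ds$m1)
  if (control$ml == 0L) control$ml <- auto_ml(ds$m0, ds$m1)
  if (ds$N < control$mo)
    abort(paste0("dataset has ", ds$N, " SNPs but the epistasis order is ",
                 control$mo, ": need N >= mo"))
  control
}

#' Population diversity (spasChaos)
#'
#' The fraction of distinct SNP indices present across all position vectors of
#' the population, `distinct / (rows * mo)`. When every sparrow holds the same
#' combination this approaches `1 / n`; when all vectors are pairwise disjoint
#' it is 1. A value below the control's `threshold_spas_chaos` declares a
#' local optimum, which flips the trimming step to discard the best members
#' instead of the worst.
#'
#' @param positions Integer matrix of SNP indices, one row per population
#'   member.
#' @param n_snps Optional total number of SNPs in the dataset. When the
#'   population holds more position slots than there are SNPs (small panels),
#'   the denominator is capped at `n_snps`, since no population can show more
#'   distinct SNPs than exist; without the cap the statistic could never
#'   reach the local-optimum threshold on small panels and every iteration
#'   would read as converged.
#' @return A number in (0, 1\].
#' @export
spas_chaos <- function(positions, n_snps = NULL) {
  stopifnot(is.matrix(positions), nrow(positions) >= 1)
  slots <- length(positions)
  if (!is.null(n_snps)) slots <- min(slots, n_snps)
  length(unique(as.vector(positions))) / slots
}

# --- internal engine -------------------------------------------------------
#
# The population (position vectors of mo distinct 1-based SNP indices, their
# cached objective scores and insertion counters) lives in a compiled store
# (src/score.cpp) that keeps it sorted best-first by (rank sum, k2,
# insertion counter) and recomputes ranks in full after every insertion or
# removal. The R side owns every random draw and all algorithmic decisions;
# `eng` is an environment so the pss vector and the finding store can be
# updated in place.

new_engine <- function(ds, control) {
  env <- new.env(parent = emptyenv())
  env$ds <- ds
  env$ctl <- control
  env$ptr <- eng_new(ds$g0, ds$g1, control$ml, control$mo)
  env$pss <- rep(1, ds$N)
  env$store <- new.env(parent = emptyenv())
  env$gmemo <- new.env(parent = emptyenv())
  env
}

# Memoised (k2, ce, gini) of a SNP index set (deduplicated inside the store).
memo_score <- function(eng, idx) eng_score_set(eng$ptr, idx)

# Insert a proposal and keep the better of {incumbent at sorted row i,
# proposal}; ties keep the incumbent. Population size is unchanged.
keep_better <- function(eng, i, x) eng_keep_better(eng$ptr, i, x)

init_population <- function(eng) {
  ds <- eng$ds; ctl <- eng$ctl
  pos <- t(vapply(seq_len(ctl$n),
                  function(i) sample.int(ds$N, ctl$mo),
                  integer(ctl$mo)))
  eng_init_pop(eng$ptr, pos)
  invisible(eng)
}

# Replace the SNPs at vector positions `at` with fresh random SNPs, keeping
# all mo indices distinct (each draw is uniform over SNPs not already used
# elsewhere in the vector).
mutate_positions <- function(x, at, N) {
  for (j in at) {
    pool <- setdiff(seq_len(N), x[-j])
    x[j] <- pool[sample.int(length(pool), 1L)]
  }
  x
}

# Crossover: h indices drawn from `a` plus mo - h drawn from `b`; duplicates
# are resolved by redrawing from the union of both parents.
crossover <- function(a, b, mo) {
  h <- mo %/% 2L
  take_a <- if (h > 0L) a[sample.int(length(a), h)] else integer(0)
  pool_b <- setdiff(b, take_a)
  need <- mo - h
  if (length(pool_b) >= need) {
    take_b <- pool_b[sample.int(length(pool_b), need)]
  } else {
    rest <- setdiff(a, c(take_a, pool_b))
    extra <- rest[sample.int(length(rest), need - length(pool_b))]
    take_b <- c(pool_b, extra)
  }
  c(take_a, take_b)
}

update_producers <- function(eng) {
  ctl <- eng$ctl; N <- eng$ds$N
  np <- floor(ctl$pd * ctl$n)
  r <- runif(1)
  for (i in seq_len(np)) {
    x <- eng_row(eng$ptr, i)
    newx <- if (r < ctl$st) {
      mutate_positions(x, sample.int(ctl$mo, 1L), N)
    } else {
      mutate_positions(x, sample.int(ctl$mo, max(1L, ctl$mo %/% 2L)), N)
    }
    keep_better(eng, i, newx)
  }
  invisible(eng)
}

update_scroungers <- function(eng) {
  ctl <- eng$ctl
  np <- floor(ctl$pd * ctl$n)
  half <- ctl$n %/% 2L
  for (i in seq.int(np + 1L, ctl$n)) {
    if (i <= half) {
      pick <- sample.int(np, 2L)
      rs <- eng_rank_sums(eng$ptr)
      p <- pick[which.min(rs[pick])]
      newx <- crossover(eng_row(eng$ptr, i), eng_row(eng$ptr, p), ctl$mo)
    } else {
      newx <- sample.int(eng$ds$N, ctl$mo, prob = eng$pss)
    }
    keep_better(eng, i, newx)
  }
  invisible(eng)
}

# Add floor(n * sd) new sparrows (nothing removed): a scout derived from the
# current best member -- or from a member no producer strictly beats -- is a
# fresh pss-weighted draw; any other scout is a crossover with a strictly
# better producer. Scouts are selected and derived from a snapshot of the
# population at entry.
spawn_scouts <- function(eng) {
  ctl <- eng$ctl
  ns <- floor(ctl$n * ctl$sd)
  np <- floor(ctl$pd * ctl$n)
  sel <- sample.int(eng_size(eng$ptr), ns)
  rs <- eng_rank_sums(eng$ptr)
  pos0 <- eng_positions(eng$ptr)
  newx <- vector("list", ns)
  for (j in seq_len(ns)) {
    i <- sel[j]
    if (i == 1L) {
      newx[[j]] <- sample.int(eng$ds$N, ctl$mo, prob = eng$pss)
    } else {
      better <- which(rs[seq_len(np)] < rs[i])
      if (length(better) == 0L) {
        newx[[j]] <- sample.int(eng$ds$N, ctl$mo, prob = eng$pss)
      } else {
        b <- better[sample.int(length(better), 1L)]
        newx[[j]] <- crossover(pos0[i, ], pos0[b, ], ctl$mo)
      }
    }
  }
  for (x in newx) eng_add(eng$ptr, x)
  invisible(eng)
}

# Restore the population to size n: discard the `count` best members when a
# local optimum was declared, the `count` worst otherwise; re-sorted under
# recomputed ranks.
trim_population <- function(eng, local_optimum, count) {
  eng_trim(eng$ptr, local_optimum, count)
  invisible(eng)
}

#' Detect epistatic interactions with the sparrow search
#'
#' Runs the full multi-objective sparrow search over a case-control genotype
#' dataset. Each iteration updates producers and scroungers (rank-guided
#' mutation and crossover, keeping the better of incumbent and proposal),
#' spawns scouts, purifies the best candidates by K2 backward noise
#' elimination, gates them with a G-test at threshold `cg`, and trims the
#' population back to size `n` — from the top if the diversity statistic
#' [spas_chaos()] signals a local optimum, from the bottom otherwise.
#' Recorded SNP sets are deduplicated; after the last iteration the p-value
#' ratio filter ([filter_findings()]) strips the weak tail.
#'
#' The run is fully deterministic given the dataset and `control$seed`; the
#' caller's RNG state is left untouched.
#'
#' @param data A dataset tibble (see [read_gwas()]) or [epi_data()] object.
#' @param control Search parameters from [epi_ssa_control()].
#' @return An object of class `epi_ssa` with elements `findings` (tibble:
#'   `p_value`, `snps` list-column of SNP names, `n_snps`, `first_iteration`;
#'   sorted by p-value), `all_findings` (the pre-filter store), `control`
#'   (resolved parameters), `pss`, `population` (final population tibble),
#'   `trace` (per-iteration diagnostics) and `data_info`.
#' @examples
#' \donttest{
#' model <- find_dnme_model(2, mafs = c(0.4, 0.4), target_h2 = 0.2, seed = 7)
#' sim <- simulate_gwas(model, n_cases = 400, n_controls = 400, n_snps = 30,
#'                      seed = 7)
#' fit <- epi_ssa(sim$data, epi_ssa_control(n = 20, max_iter = 40, seed = 1))
#' tidy(fit)
#' }
#' @export
epi_ssa <- function(data, control = epi_ssa_control()) {
  ds <- epi_data(data)
  ctl <- resolve_control(control, ds)
  eng <- new_engine(ds, ctl)
  trace <- vector("list", ctl$max_iter)
  withr::with_seed(ctl$seed, {
    init_population(eng)
    ns <- floor(ctl$n * ctl$sd)
    for (g in seq_len(ctl$max_iter)) {
      update_producers(eng)
      update_scroungers(eng)
      spawn_scouts(eng)
      detect_in_population(eng, g)
      chaos <- eng_distinct(eng$ptr) /
        min(eng_size(eng$ptr) * ctl$mo, ds$N)
      local_opt <- chaos < ctl$threshold_spas_chaos
      trim_population(eng, local_opt, ns)
      trace[[g]] <- tibble::tibble(
        iteration = g, best_k2 = eng_scores(eng$ptr)[1L, 1L],
        spas_chaos = chaos, local_optimum = local_opt,
        n_found = length(ls(eng$store, sorted = FALSE)))
    }
  })
  all_findings <- store_to_tibble(eng$store, ds$snp_names)
  findings <- filter_findings(all_findings)
  structure(list(
    findings = findings,
    all_findings = all_findings,
    control = ctl,
    pss = setNames(eng$pss, ds$snp_names),
    population = population_tibble(eng, ds$snp_names),
    trace = dplyr::bind_rows(trace),
    data_info = list(m0 = ds$m0, m1 = ds$m1, N = ds$N)
  ), class = "epi_ssa")
}

population_tibble <- function(eng, snp_names) {
  pos <- eng_positions(eng$ptr)
  sc <- tibble::as_tibble(eng_scores(eng$ptr),
                          .name_repair = ~c("k2", "ce", "gini"))
  sc$snps <- lapply(seq_len(nrow(pos)), function(i) snp_names[pos[i, ]])
  ranked <- assign_ranks(sc)
  dplyr::relocate(ranked, "snps")
}

#' @export
print.epi_ssa <- function(x, ...) {
  cat("<epi_ssa> sparrow search on ", x$data_info$N, " SNPs (",
      x$data_info$m0, " controls + ", x$data_info$m1, " cases)\n", sep = "")
  cat("  mo = ", x$control$mo, ", ml = ", x$control$ml, ", n = ",
      x$control$n, ", iterations = ", x$control$max_iter, ", seed = ",
      x$control$seed, "\n", sep = "")
  cat("  findings: ", nrow(x$findings), " (", nrow(x$all_findings),
      " before the p-ratio filter)\n", sep = "")
  if (nrow(x$findings) > 0) {
    top <- head(x$findings, 5L)
    for (i in seq_len(nrow(top)))
      cat(sprintf("    p = %.3g  %s\n", top$p_value[i],
                  paste(top$snps[[i]], collapse = " ")))
  }
  invisible(x)
}
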