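#' Hardy-Weinberg genotype frequencies
#'
#' Genotype frequencies of a biallelic SNP under Hardy-Weinberg equilibrium,
#' indexed by minor-allele count: `((1-p)^2, 2p(1-p), p^2)`.
#'
#' @param maf Minor allele frequency, in (0, 0.5\].
#' @return A numeric vector of length 3 summing to 1.
#' @export
hwe_freqs <- function(maf) {
  stopifnot(maf > 0, maf <= 0.5)
  c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
}

#' Penetrance models
#'
#' A penetrance model specifies, for `k` interacting SNPs with given minor
#' allele frequencies, the probability of disease for each of the `3^k` joint
#' genotypes. Genotype combinations are indexed with the first SNP varying
#' fastest: entry `1 + sum(g_i * 3^(i-1))` of `table` is the penetrance of
#' genotype `(g_1, ..., g_k)`.
#'
#' @param mafs Numeric vector of `k` minor allele frequencies in (0, 0.5].
#' @param table Numeric vector of `3^k` penetrances in \[0, 1\] (a 3x3 matrix
#'   is accepted for `k = 2`, read column-major so SNP 1 is the row index).
#' @param model_id Identifier used in simulated file headers and manifests.
#' @return An object of class `penetrance_model`.
#' @seealso [model_stats()], [find_dnme_model()], [simulate_gwas()]
#' @export
penetrance_model <- function(mafs, table, model_id = "M0") {
  k <- length(mafs)
  stopifnot(k >= 1, all(mafs > 0), all(mafs <= 0.5))
  f <- as.numeric(table)
  if (length(f) != 3^k)
    abort(paste0("penetrance table must have 3^k = ", 3^k, " entries"))
  if (any(f < 0 | f > 1)) abort("penetrances must lie in [0, 1]")
  structure(list(k = k, mafs = mafs, table = f, model_id = model_id),
            class = "penetrance_model")
}

# Joint genotype probabilities (length 3^k, SNP 1 fastest) and the genotype
# index matrix (3^k x k).
model_grid <- function(model) {
  g <- as.matrix(expand.grid(rep(list(0:2), model$k)))
  colnames(g) <- NULL
  p <- rep(1, nrow(g))
  for (i in seq_len(model$k)) p <- p * hwe_freqs(model$mafs[i])[g[, i] + 1L]
  list(geno = g, prob = p)
}

#' Prevalence, heritability and marginal penetrances of a model
#'
#' Derived quantities of a penetrance model under Hardy-Weinberg genotype
#' frequencies: the population prevalence `K = sum(P(g) f(g))`, the
#' broad-sense heritability of the penetrance function
#' `h2 = sum(P(g) (f(g) - K)^2) / (K (1 - K))`, and each SNP's marginal
#' penetrance vector (the expected penetrance given that SNP's genotype,
#' averaging over the others). A model "without marginal effects" has all
#' three marginal penetrances equal to `K` for every SNP.
#'
#' @param model A [penetrance_model()].
#' @return A list with elements `prevalence`, `h2`, and `marginals`
#'   (a `k` x 3 matrix).
#' @export
model_stats <- function(model) {
  grid <- model_grid(model)
  f <- model$table
  K <- sum(grid$prob * f)
  if (K <= 0 || K >= 1)
    abort("degenerate model: prevalence is 0 or 1, heritability undefined")
  h2 <- sum(grid$prob * (f - K)^2) / (K * (1 - K))
  marg <- matrix(NA_real_, model$k, 3,
                 dimnames = list(NULL, c("g0", "g1", "g2")))
  for (i in seq_len(model$k)) {
    for (a in 0:2) {
      sel <- grid$geno[, i] == a
      marg[i, a + 1L] <- sum(grid$prob[sel] * f[sel]) / sum(grid$prob[sel])
    }
  }
  list(prevalence = K, h2 = h2, marginals = marg)
}

#' @export
print.penetrance_model <- function(x, ...) {
  st <- model_stats(x)
  cat("<penetrance_model> ", x$model_id, ": ", x$k, " SNPs, MAF ",
      paste(signif(x$mafs, 3), collapse = "/"), "\n", sep = "")
  cat(sprintf("  prevalence %.4f, heritability %.4f, marginal spread %.2g\n",
              st$prevalence, st$h2, max(abs(st$marginals - st$prevalence))))
  invisible(x)
}

# Maximum deviation of any marginal penetrance from prevalence.
marginal_spread <- function(model) {
  st <- model_stats(model)
  max(abs(st$marginals - st$prevalence))
}

#' Search for a penetrance model without marginal effects
#'
#' Finds a `k`-SNP penetrance model whose per-SNP marginal penetrances are
#' equal (no single-SNP signal) and whose heritability matches `target_h2`,
#' emulating the no-marginal-effect ("DNME") models produced by GAMETES.
#' Starting from a random table, the searcher alternates (a) projection onto
#' the equal-marginals affine subspace (iteratively subtracting each SNP's
#' marginal deviation, which preserves prevalence) and (b) an affine rescale
#' `f <- K + c (f - K)` toward the target heritability (affine maps preserve
#' marginal equality and scale `h2` by `c^2`), clipping to \[0, 1\] and
#' repeating until both constraints hold within `tol`. Failed starts are
#' re-randomised up to `max_tries` times.
#'
#' @param k Interaction order (2 or 3 in the benchmark models).
#' @param mafs Minor allele frequencies, length `k` (a scalar is recycled).
#' @param target_h2 Target heritability in (0, 1).
#' @param tol Tolerance on both the marginal spread and `|h2 - target_h2|`.
#' @param max_tries Maximum number of random restarts.
#' @param prevalence Target prevalence, enforced within `tol` (a uniform
#'   penetrance shift, which cannot disturb marginal equality). The default
#'   0.25 keeps models in the range typical of published complex-disease
#'   benchmark tables; `NULL` leaves the prevalence wherever the projection
#'   lands, which can drift toward 0.5 where a given heritability carries
#'   the least case-control contrast.
#' @param seed Optional seed for a self-contained deterministic search.
#' @param model_id Identifier for the returned model.
#' @return A [penetrance_model()] satisfying both constraints.
#' @export
find_dnme_model <- function(k, mafs, target_h2, tol = 1e-4, max_tries = 1000,
                            prevalence = 0.25, seed = NULL, model_id = "M0") {
  stopifnot(target_h2 > 0, target_h2 < 1, tol > 0)
  mafs <- rep_len(mafs, k)
  run <- function() {
    for (try in seq_len(max_tries)) {
      f <- if (is.null(prevalence)) runif(3^k)
           else pmin(1, pmax(0, prevalence +
                               runif(3^k, -1, 1) * min(prevalence, 1 - prevalence)))
      m <- dnme_refine(k, mafs, f, target_h2, tol, target_K = prevalence)
      if (!is.null(m)) {
        m$model_id <- model_id
        return(structure(m, class = "penetrance_model"))
      }
    }
    abort(paste0("no model without marginal effects found at h2 = ",
                 target_h2, " within ", max_tries, " restarts"))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# One refinement pass from a starting table; returns NULL on failure.
# target_K = NULL leaves the prevalence wherever the projection fixes it.
dnme_refine <- function(k, mafs, f, target_h2, tol, target_K = NULL,
                        max_rounds = 200L) {
  model <- list(k = k, mafs = mafs, table = f)
  grid <- model_grid(model)
  P <- grid$prob
  for (round in seq_len(max_rounds)) {
    # (a) alternating projection to equal marginals
    for (sweep in 1:100) {
      K <- sum(P * f)
      dev_max <- 0
      for (i in seq_len(k)) {
        gi <- grid$geno[, i]
        for (a in 0:2) {
          sel <- gi == a
          d <- sum(P[sel] * f[sel]) / sum(P[sel]) - K
          f[sel] <- f[sel] - d
          dev_max <- max(dev_max, abs(d))
        }
      }
      if (dev_max < tol / 10) break
    }
    # (b) shift to the target prevalence (a uniform shift moves every
    # marginal equally, so marginal equality is untouched)
    K <- sum(P * f)
    if (!is.null(target_K)) {
      f <- f + (target_K - K)
      K <- target_K
    }
    if (K <= 1e-6 || K >= 1 - 1e-6) return(NULL)
    # (c) rescale variance toward the target heritability (preserves K)
    h2 <- sum(P * (f - K)^2) / (K * (1 - K))
    if (h2 < 1e-10) return(NULL)
    f <- K + sqrt(target_h2 / h2) * (f - K)
    clipped <- any(f < 0 | f > 1)
    f <- pmin(1, pmax(0, f))
    if (!clipped) {
      model$table <- f
      st <- model_stats(model)
      if (marginal_spread(model) <= tol &&
          abs(st$h2 - target_h2) <= tol &&
          (is.null(target_K) || abs(st$prevalence - target_K) <= tol))
        return(model)
    }
  }
  NULL
}

#' Draw individuals from a penetrance model
#'
#' Samples genotypes for the model's `k` SNPs under Hardy-Weinberg equilibrium
#' and assigns disease status by a Bernoulli draw with the genotype's
#' penetrance. Useful for checking that the simulator reproduces the model's
#' prevalence and penetrances.
#'
#' @param model A [penetrance_model()].
#' @param n Number of individuals.
#' @param seed Optional seed.
#' @return A tibble with columns `g1..gk` and `disease` (0/1).
#' @export
sample_population <- function(model, n, seed = NULL) {
  draw <- function() {
    g <- vapply(model$mafs, function(p) rbinom(n, 2L, p), integer(n))
    if (n == 1L) g <- matrix(g, nrow = 1L)
    key <- as.vector(g %*% 3^(seq_len(model$k) - 1L)) + 1L
    disease <- rbinom(n, 1L, model$table[key])
    out <- tibble::as_tibble(g, .name_repair = ~paste0("g", seq_len(model$k)))
    out$disease <- disease
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate a case-control GWAS dataset with planted epistasis
#'
#' Generates a dataset in the GAMETES tabular dialect: functional genotypes
#' are drawn under Hardy-Weinberg equilibrium from the model's MAFs, disease
#' status is assigned with probability equal to the genotype's penetrance,
#' and individuals are accumulated by rejection until both the case and the
#' control quota are filled. Noise SNPs are independent Hardy-Weinberg draws
#' with per-SNP MAFs uniform over `noise_maf_range`. The functional SNPs are
#' placed at positions chosen uniformly at random and named
#' `<model_id>P0 ... <model_id>P<k-1>`; noise SNPs are named `N<j>` by column
#' position.
#'
#' @param model A [penetrance_model()].
#' @param n_cases,n_controls Samples per class.
#' @param n_snps Total number of SNP columns (functional + noise).
#' @param noise_maf_range Range for noise-SNP minor allele frequencies; the
#'   lower bound keeps columns away from monomorphic.
#' @param seed Integer seed; identical seeds give byte-identical files.
#' @return A list with `data` (dataset tibble, controls first) and `truth`
#'   (ground-truth manifest tibble, see [write_ground_truth()]).
#' @export
simulate_gwas <- function(model, n_cases = 800, n_controls = 800,
                          n_snps = 100, noise_maf_range = c(0.05, 0.5),
                          seed = 0L) {
  stopifnot(n_snps >= model$k, n_cases >= 1, n_controls >= 1)
  st <- model_stats(model)  # errors on degenerate prevalence
  k <- model$k
  withr::with_seed(as.integer(seed), {
    pos <- sample.int(n_snps, k)
    g_case <- matrix(0L, 0L, k)
    g_ctrl <- matrix(0L, 0L, k)
    total <- n_cases + n_controls
    while (nrow(g_case) < n_cases || nrow(g_ctrl) < n_controls) {
      b <- max(256L, 2L * total)
      d <- sample_population(model, b)
      g <- as.matrix(d[paste0("g", seq_len(k))])
      need1 <- n_cases - nrow(g_case)
      need0 <- n_controls - nrow(g_ctrl)
      is_case <- d$disease == 1L
      if (need1 > 0L)
        g_case <- rbind(g_case, head(g[is_case, , drop = FALSE], need1))
      if (need0 > 0L)
        g_ctrl <- rbind(g_ctrl, head(g[!is_case, , drop = FALSE], need0))
    }
    geno <- matrix(0L, total, n_snps)
    geno[, pos] <- rbind(g_ctrl, g_case)
    noise_cols <- setdiff(seq_len(n_snps), pos)
    for (j in noise_cols) {
      maf <- runif(1, noise_maf_range[1], noise_maf_range[2])
      geno[, j] <- rbinom(total, 2L, maf)
    }
    nm <- paste0("N", seq_len(n_snps) - 1L)
    nm[pos] <- paste0(model$model_id, "P", seq_len(k) - 1L)
    dat <- tibble::as_tibble(geno, .name_repair = ~nm)
    dat$Class <- c(rep(0L, n_controls), rep(1L, n_cases))
    truth <- tibble::tibble(model_id = model$model_id,
                            snps = list(nm[pos]))
    list(data = dat, truth = truth)
  })
}

#' Write a batch of simulated files
#'
#' Writes `n_files` datasets with companion ground-truth manifests, plus the
#' model's penetrance table, into a directory: `<prefix>_<i>.txt`,
#' `<prefix>_<i>.truth.txt` and `<prefix>_model.txt`. Per-file seeds are
#' `seed + i`, so the batch is reproducible file by file.
#'
#' @inheritParams simulate_gwas
#' @param n_files Number of replicate files.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; defaults to the model id.
#' @return A character vector of the dataset file paths, invisibly.
#' @export
simulate_gwas_files <- function(model, n_files, dir, prefix = model$model_id,
                                n_cases = 800, n_controls = 800, n_snps = 100,
                                noise_maf_range = c(0.05, 0.5), seed = 0L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_penetrance_table(model, file.path(dir, paste0(prefix, "_model.txt")))
  paths <- character(n_files)
  for (i in seq_len(n_files)) {
    sim <- simulate_gwas(model, n_cases, n_controls, n_snps,
                         noise_maf_range, seed = as.integer(seed) + i)
    stem <- file.path(dir, sprintf("%s_%03d", prefix, i))
    paths[i] <- paste0(stem, ".txt")
    write_gwas(sim$data, paths[i])
    write_ground_truth(sim$truth, paste0(stem, ".truth.txt"))
  }
  invisible(paths)
}

#' Read and write penetrance tables
#'
#' A penetrance table file is a headered TSV with one row per genotype
#' combination: columns `g1..gk` (minor-allele counts) and `penetrance`.
#' The MAFs are carried on a leading comment line `# mafs: ...` and the model
#' id on `# model_id: ...`. This is the format for loading externally
#' published tables (e.g. models with marginal effects) into the simulator.
#'
#' @param model A [penetrance_model()].
#' @param path File path.
#' @return `read_penetrance_table()` returns a [penetrance_model()];
#'   `write_penetrance_table()` returns `path` invisibly.
#' @export
write_penetrance_table <- function(model, path) {
  grid <- model_grid(model)
  tab <- tibble::as_tibble(grid$geno,
                           .name_repair = ~paste0("g", seq_len(model$k)))
  tab$penetrance <- model$table
  header <- c(paste0("# model_id: ", model$model_id),
              paste0("# mafs: ", paste(model$mafs, collapse = ",")))
  writeLines(c(header, paste(names(tab), collapse = "\t")), path)
  readr::write_tsv(tab, path, append = TRUE, progress = FALSE)
  invisible(path)
}

#' @rdname write_penetrance_table
#' @export
read_penetrance_table <- function(path) {
  lines <- readLines(path)
  mafs_line <- grep("^# mafs:", lines, value = TRUE)
  id_line <- grep("^# model_id:", lines, value = TRUE)
  if (length(mafs_line) != 1L)
    abort("penetrance table file must carry one '# mafs: ...' line")
  mafs <- as.numeric(strsplit(sub("^# mafs:\\s*", "", mafs_line), ",")[[1]])
  model_id <- if (length(id_line) == 1L)
    sub("^# model_id:\\s*", "", id_line) else "M0"
  tab <- readr::read_tsv(path, comment = "#", progress = FALSE,
                         show_col_types = FALSE)
  k <- length(mafs)
  gcols <- paste0("g", seq_len(k))
  stopifnot(all(c(gcols, "penetrance") %in% names(tab)))
  key <- as.matrix(tab[gcols]) %*% 3^(seq_len(k) - 1L) + 1L
  f <- numeric(3^k)
  f[key] <- tab$penetrance
  penetrance_model(mafs, f, model_id = model_id)
}
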