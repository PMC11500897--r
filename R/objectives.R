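#' Automatic maximum epistasis order
#'
#' The search evaluates SNP combinations of a fixed length `mo`, the maximum
#' epistasis order. Chosen automatically it is `floor(ln(min(m0, m1)) - 0.5)`,
#' which keeps the average number of samples per genotype combination at the
#' level of the natural constant e, so the contingency-table objectives stay
#' informative.
#'
#' @param m0,m1 Number of controls and cases.
#' @return An integer, the maximum epistasis order (>= 1).
#' @examples
#' auto_mo(800, 800)  # 6
#' @export
auto_mo <- function(m0, m1) {
  stopifnot(m0 >= 1, m1 >= 1)
  mo <- as.integer(floor(log(min(m0, m1)) - 0.5))
  if (mo < 1L)
    abort("too few samples: automatic epistasis order is below 1")
  mo
}

#' Automatic contingency-table length cap
#'
#' All three objectives are biased toward SNP combinations whose observed
#' genotype tables are long; capping the number of contributing table cells at
#' `ml = floor(min(m0, m1) / 10)` removes that bias (cells beyond the cap are
#' pooled, see [truncate_table()]).
#'
#' @inheritParams auto_mo
#' @return An integer cap (>= 2) on contributing contingency-table cells.
#' @examples
#' auto_ml(800, 800)  # 80
#' @export
auto_ml <- function(m0, m1) {
  stopifnot(m0 >= 1, m1 >= 1)
  ml <- as.integer(floor(min(m0, m1) / 10))
  if (ml < 2L)
    abort("too few samples: automatic contingency-table cap is below 2")
  ml
}

# Per-cell objective contributions; `n` is the total sample count. Each
# objective is a sum of these over contributing cells (lower = stronger
# association).
cell_contrib <- function(objective, n_control, n_case, n) {
  m <- n_control + n_case
  switch(objective,
    k2 = lgamma(m + 2) - lgamma(n_control + 1) - lgamma(n_case + 1),
    ce = {
      e0 <- ifelse(n_control > 0, -n_control * log(n_control / m), 0)
      e1 <- ifelse(n_case > 0, -n_case * log(n_case / m), 0)
      (e0 + e1) / n
    },
    gini = (m / n) * (1 - (n_control / m)^2 - (n_case / m)^2),
    abort(paste0("unknown objective: ", objective))
  )
}

#' Genotype-combination contingency table for a SNP subset
#'
#' Cross-tabulates the joint genotype of the given SNPs against case/control
#' status. Only combinations observed in at least one sample appear; the
#' genotype combination is reported as a comma-joined string of minor-allele
#' counts in the order of `snps`.
#'
#' @param data A dataset tibble (see [read_gwas()]) or [epi_data()] object.
#' @param snps SNP names (character) or 1-based column indices.
#' @return A tibble of class `epi_table` with columns `genotype`,
#'   `n_control`, `n_case`, `n` and `pooled` (all `FALSE` here), carrying the
#'   class totals as attributes `m0`/`m1`.
#' @export
snp_contingency <- function(data, snps) {
  ds <- epi_data(data)
  idx <- resolve_snps(ds, snps)
  cc <- combo_counts_cpp(ds$g0, ds$g1, idx - 1L)
  k <- length(idx)
  combos <- vapply(cc$key, function(key)
    paste((key %/% 3^(seq_len(k) - 1L)) %% 3L, collapse = ","), "")
  out <- tibble::tibble(
    genotype = combos,
    n_control = as.integer(cc$n_control),
    n_case = as.integer(cc$n_case),
    n = as.integer(cc$n_control + cc$n_case),
    pooled = FALSE
  )
  structure(out, class = c("epi_table", class(out)), m0 = ds$m0, m1 = ds$m1)
}

#' Truncate a contingency table for one objective
#'
#' All three objectives are biased downward on long genotype tables: the many
#' small cells a long table accumulates look spuriously pure and each
#' contributes less than its fair share. When a table has more than `ml`
#' rows, the `ml - 1` rows with the *largest* per-cell contribution to the
#' named objective — the weak-evidence cells, whose raw K2 factors are the
#' smallest — are retained individually and all remaining rows are merged
#' into a single pooled cell, which then contributes as one ordinary cell, so
#' at most `ml` rows contribute. Tables with at most `ml` rows are returned
#' unchanged. Each objective ranks cells by its own contribution, so the
#' retained set can differ between objectives.
#'
#' @param table An `epi_table` from [snp_contingency()].
#' @param ml Positive integer cap (>= 2), or `Inf` for no truncation.
#' @param objective One of `"k2"`, `"ce"`, `"gini"`.
#' @return An `epi_table`; a pooled row (if any) has `pooled = TRUE` and
#'   `genotype = "(pooled)"`.
#' @export
truncate_table <- function(table, ml, objective = c("k2", "ce", "gini")) {
  objective <- match.arg(objective)
  stopifnot(is.infinite(ml) || ml >= 2)
  if (nrow(table) <= ml) return(table)
  m0 <- attr(table, "m0"); m1 <- attr(table, "m1")
  n <- m0 + m1
  contrib <- cell_contrib(objective, table$n_control, table$n_case, n)
  ord <- order(-contrib, seq_len(nrow(table)))
  keep <- ord[seq_len(ml - 1L)]
  pool <- ord[ml:nrow(table)]
  pooled_row <- tibble::tibble(
    genotype = "(pooled)",
    n_control = sum(table$n_control[pool]),
    n_case = sum(table$n_case[pool]),
    n = sum(table$n[pool]),
    pooled = TRUE
  )
  out <- dplyr::bind_rows(table[sort(keep), ], pooled_row)
  structure(out, class = class(table), m0 = m0, m1 = m1)
}

score_one <- function(data, snps, ml, which) {
  ds <- epi_data(data)
  idx <- resolve_snps(ds, snps)
  ml <- if (is.infinite(ml)) 0L else as.integer(ml)
  unname(score_combo_cpp(ds$g0, ds$g1, idx - 1L, ml)[[which]])
}

#' Objective scores for a SNP combination
#'
#' The three association objectives driving the search, each computed on the
#' (per-objective truncated, see [truncate_table()]) genotype contingency
#' table; for all three, lower values mean stronger association with the
#' phenotype.
#'
#' * `k2_score()`: negative natural log of the Bayesian K2 (Cooper-Herskovits)
#'   score; for a binary phenotype each cell contributes
#'   `ln((m_x + 1)!) - ln(m_x0!) - ln(m_x1!)`, evaluated in log-gamma space.
#' * `ce_score()`: conditional entropy H(phenotype | genotype) in nats; 0 for
#'   a perfectly separating combination, `ln 2` under independence with
#'   balanced classes.
#' * `gini_score()`: expected Gini impurity of the phenotype within genotype
#'   cells; in `[0, 0.5]` for a binary phenotype.
#'
#' @inheritParams snp_contingency
#' @param ml Contingency-table cap (see [auto_ml()]); `Inf` disables
#'   truncation.
#' @return A single numeric score.
#' @export
k2_score <- function(data, snps, ml = Inf) score_one(data, snps, ml, "k2")

#' @rdname k2_score
#' @export
ce_score <- function(data, snps, ml = Inf) score_one(data, snps, ml, "ce")

#' @rdname k2_score
#' @export
gini_score <- function(data, snps, ml = Inf) score_one(data, snps, ml, "gini")

#' G-test of independence for a SNP combination
#'
#' Likelihood-ratio test of independence between the joint genotype of the
#' given SNPs and case/control status: `G = 2 * sum(O * ln(O / E))` over
#' observed genotype combinations (zero-count terms contribute 0), with
#' expected counts `E = m_x * m_y / m`, compared against a chi-square law.
#' No table truncation is applied here.
#'
#' Degrees of freedom: with `df = "observed"` (the default), the table's
#' observed genotype combinations set the df, `(observed - 1) * (classes -
#' 1)`, as in a generic test of a given table. With `df = "complete"` the
#' full genotype space sets it, `(3^k - 1) * (classes - 1)` for `k` SNPs —
#' the form the detection gate uses: a high-order combination that scatters
#' samples over hundreds of chance-pure cells is then charged for its whole
#' genotype space, which suppresses overfit high-order candidates without
#' affecting low-order combinations whose genotype space is fully observed.
#'
#' @inheritParams snp_contingency
#' @param df `"observed"` or `"complete"` (see Details).
#' @return A one-row tibble with columns `statistic`, `df`, `p_value`.
#' @export
g_test <- function(data, snps, df = c("observed", "complete")) {
  df <- match.arg(df)
  ds <- epi_data(data)
  idx <- resolve_snps(ds, snps)
  cc <- combo_counts_cpp(ds$g0, ds$g1, idx - 1L)
  g_test_counts(cc$n_control, cc$n_case,
                df_n = if (df == "complete") 3L^length(idx) else NULL)
}

# G-test from per-combination class counts (one row per observed
# combination); df_n overrides the number of table rows charged to the df.
g_test_counts <- function(n_control, n_case, df_n = NULL) {
  m0 <- sum(n_control); m1 <- sum(n_case)
  nc <- length(n_control)
  if (nc < 2L || m0 == 0 || m1 == 0)
    abort("degenerate table: need >= 2 observed genotype combinations and both classes")
  m <- m0 + m1
  mx <- n_control + n_case
  e0 <- mx * m0 / m
  e1 <- mx * m1 / m
  t0 <- ifelse(n_control > 0, n_control * log(n_control / e0), 0)
  t1 <- ifelse(n_case > 0, n_case * log(n_case / e1), 0)
  stat <- 2 * sum(t0 + t1)
  df <- (if (is.null(df_n)) nc else df_n) - 1L
  tibble::tibble(statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE))
}
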