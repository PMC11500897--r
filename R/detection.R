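#' K2 backward noise elimination
#'
#' Strips noise SNPs from a candidate combination by greedy steepest descent
#' on the K2 score: at each step every single-SNP removal is scored, and if
#' the best removal does not increase K2 (removing a noise SNP can only keep
#' or lower it) that removal is committed; ties go to the SNP with the lowest
#' column index. The loop stops when every removal strictly increases K2 —
#' meaning every remaining SNP carries association signal, alone or through
#' interaction — or when a single SNP remains.
#'
#' The descent uses the raw (untruncated) K2 by default, and the search
#' engine always does: the stopping rule rests on shorter tables scoring
#' lower when the dropped SNP is uninformative, which is a property of the
#' raw score — the table-length truncation is deliberately length-neutral
#' and would leave the rule undecided, stalling noise sets at full length.
#'
#' @inheritParams k2_score
#' @return The purified SNP set, as names if `snps` was names, else indices.
#' @export
eliminate_noise <- function(data, snps, ml = Inf) {
  ds <- epi_data(data)
  idx <- resolve_snps(ds, snps)
  mli <- if (is.infinite(ml)) 0L else as.integer(ml)
  score_fn <- function(s) score_combo_cpp(ds$g0, ds$g1, s - 1L, mli)[[1L]]
  out <- purify_idx(score_fn, idx)
  if (is.character(snps)) ds$snp_names[out] else out
}

# Greedy descent shared by the exported function and the engine.
purify_idx <- function(k2_fn, idx) {
  s <- sort.int(unique(idx))
  cur <- k2_fn(s)
  while (length(s) > 1L) {
    cand <- vapply(seq_along(s), function(j) k2_fn(s[-j]), numeric(1))
    j <- which.min(cand)  # ties: first = lowest SNP index (s is sorted)
    if (cand[j] <= cur) {
      cur <- cand[j]
      s <- s[-j]
    } else break
  }
  s
}

# Engine-side detection pass: purify the top floor(n*sd) sparrows, gate by
# G-test at cg, record deduplicated sets (first-seen kept). The pss weight of
# every SNP in a set is decayed by 0.9 when the set is first recorded, so the
# sampler's attention moves away from already-reported SNPs without
# extinguishing them (per-rediscovery decay would drive the weights of any
# strong sub-signal to zero within tens of iterations and block the assembly
# of higher-order interactions that share its SNPs).
detect_in_population <- function(eng, iteration) {
  ctl <- eng$ctl
  ns <- floor(ctl$n * ctl$sd)
  thr <- if (ctl$bonferroni) ctl$cg / choose(eng$ds$N, 2L) else ctl$cg
  for (i in seq_len(ns)) {
    r <- purify_idx(function(s) eng_raw_k2(eng$ptr, s), eng_row(eng$ptr, i))
    if (length(r) < 2L) next
    gt <- memo_gtest(eng, r)
    if (is.null(gt) || gt$p_value > thr) next
    key <- paste(r, collapse = " ")
    if (is.null(eng$store[[key]])) {
      eng$store[[key]] <- list(snps = r, p_value = gt$p_value,
                               first_iteration = iteration)
      eng$pss[r] <- eng$pss[r] * 0.9
    }
  }
  invisible(NULL)
}

memo_gtest <- function(eng, idx) {
  key <- paste(idx, collapse = " ")
  val <- eng$gmemo[[key]]
  if (is.null(val)) {
    cc <- combo_counts_cpp(eng$ds$g0, eng$ds$g1, idx - 1L)
    val <- tryCatch(
      g_test_counts(cc$n_control, cc$n_case, df_n = 3L^length(idx)),
      error = function(e) NA)
    eng$gmemo[[key]] <- val
  }
  if (identical(val, NA)) NULL else val
}

store_to_tibble <- function(store, snp_names) {
  keys <- ls(store, sorted = TRUE)
  if (length(keys) == 0L)
    return(tibble::tibble(p_value = numeric(0), snps = list(),
                          n_snps = integer(0), first_iteration = integer(0)))
  recs <- lapply(keys, function(k) store[[k]])
  tibble::tibble(
    p_value = vapply(recs, `[[`, numeric(1), "p_value"),
    snps = lapply(recs, function(r) snp_names[r$snps]),
    n_snps = vapply(recs, function(r) length(r$snps), integer(1)),
    first_iteration = vapply(recs, `[[`, integer(1), "first_iteration")
  )
}

#' Trim weak tail findings at the largest p-value ratio jump
#'
#' Final false-positive filter over a deduplicated finding list: findings are
#' sorted by ascending p-value (ties: smaller SNP set first, then
#' lexicographic names) and the ratio `p_i / p_(i-1)` of consecutive p-values
#' is computed (conventions: `0/0 := 1`, `x/0 := Inf` for `x > 0`). The cut
#' index `iBiggest` is the largest position attaining the maximal ratio —
#' the biggest jump in significance — and only findings before it are kept.
#' A single finding passes through unfiltered; with exactly two, the one
#' ratio decides and only the stronger survives. The output is always a
#' nonempty prefix of the sorted input when the input is nonempty.
#'
#' @param findings A tibble with a numeric `p_value` column and a `snps`
#'   list-column (as in an [epi_ssa()] fit).
#' @return The filtered, sorted findings tibble.
#' @export
filter_findings <- function(findings) {
  stopifnot(all(c("p_value", "snps") %in% names(findings)))
  ne <- nrow(findings)
  if (ne == 0L) return(findings)
  key <- vapply(findings$snps, paste, "", collapse = ",")
  findings <- findings[order(findings$p_value, lengths(findings$snps), key), ]
  if (ne == 1L) return(findings)
  p <- findings$p_value
  ratio <- p[-1L] / p[-ne]
  ratio[is.nan(ratio)] <- 1  # 0/0
  i_biggest <- max(which(ratio == max(ratio))) + 1L  # ratio[j] is position j+1
  findings[seq_len(i_biggest - 1L), ]
}

#' Write and read a findings report
#'
#' The report is a headered TSV with a `p_value` column followed by SNP name
#' columns `SNP1`, `SNP2`, ... (as many as the widest finding; narrower rows
#' are padded with empty fields), sorted by ascending p-value.
#'
#' @param x An `epi_ssa` fit or a findings tibble (`p_value` + `snps`
#'   list-column).
#' @param path File path.
#' @return `write_findings()` returns `path` invisibly; `read_findings()`
#'   returns a findings tibble.
#' @export
write_findings <- function(x, path) {
  findings <- if (inherits(x, "epi_ssa")) x$findings else x
  w <- max(c(1L, lengths(findings$snps)))
  cols <- lapply(seq_len(w), function(j)
    vapply(findings$snps, function(s) if (j <= length(s)) s[[j]] else "", ""))
  out <- tibble::as_tibble(setNames(cols, paste0("SNP", seq_len(w))))
  out <- dplyr::bind_cols(tibble::tibble(p_value = findings$p_value), out)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_findings
#' @export
read_findings <- function(path) {
  dat <- readr::read_tsv(path, col_types = readr::cols(
    p_value = readr::col_double(), .default = readr::col_character()
  ), progress = FALSE, show_col_types = FALSE, na = character())
  snp_cols <- grep("^SNP", names(dat), value = TRUE)
  snps <- lapply(seq_len(nrow(dat)), function(i) {
    v <- unlist(dat[i, snp_cols], use.names = FALSE)
    v[nzchar(v)]
  })
  tibble::tibble(p_value = dat$p_value, snps = snps,
                 n_snps = lengths(snps))
}
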