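#' Rank-sum aggregation of the three objectives
#'
#' The search never compares raw objective values across candidates; instead
#' each candidate is ranked within the population separately by K2, CE and
#' Gini (competition ranking: equal scores share a rank equal to 1 + the
#' number of strictly better candidates) and the three ranks are summed into
#' `rank_sum`, the scalar that drives every selection decision. Because only
#' ranks are used, the aggregation is invariant under any strictly increasing
#' transform of a whole objective column.
#'
#' @param scores A data frame with numeric columns `k2`, `ce`, `gini` (one row
#'   per population member, all finite).
#' @return The input with columns `rank_k2`, `rank_ce`, `rank_gini` and
#'   `rank_sum` appended. Row order is unchanged; use [sort_population()] to
#'   order by rank.
#' @export
assign_ranks <- function(scores) {
  stopifnot(nrow(scores) >= 1L,
            all(c("k2", "ce", "gini") %in% names(scores)))
  if (!all(is.finite(scores$k2), is.finite(scores$ce), is.finite(scores$gini)))
    abort("all objective scores must be finite")
  out <- tibble::as_tibble(scores)
  out$rank_k2 <- rank(out$k2, ties.method = "min")
  out$rank_ce <- rank(out$ce, ties.method = "min")
  out$rank_gini <- rank(out$gini, ties.method = "min")
  out$rank_sum <- out$rank_k2 + out$rank_ce + out$rank_gini
  out
}

#' Sort a ranked population
#'
#' Stable ascending sort by `(rank_sum, k2, insertion order)`: the rank sum is
#' the primary criterion, the raw K2 score breaks rank-sum ties (mirroring
#' K2's privileged role in noise elimination), and original row order breaks
#' exact ties so runs are reproducible. Idempotent on sorted input.
#'
#' @param pop A data frame carrying at least `rank_sum` and `k2` columns
#'   (see [assign_ranks()]).
#' @return The sorted tibble.
#' @export
sort_population <- function(pop) {
  stopifnot(all(c("rank_sum", "k2") %in% names(pop)))
  tibble::as_tibble(pop)[order(pop$rank_sum, pop$k2), , drop = FALSE]
}

# Competition rank ("min" ties): 1 + number of strictly smaller values.
# match() against the sorted vector finds the first occurrence, which is
# exactly that; much cheaper than rank() in the engine's hot loop.
rank_min <- function(x) match(x, sort.int(x))

# Engine path: total order over members given a score matrix (cols k2,ce,gini)
# and insertion counters (hot loop; compiled). Returns the permutation that
# sorts the population best-first.
pop_order <- function(scores, counter) pop_order_cpp(scores, counter)

# Rank sums only (same competition ranking as pop_order).
pop_rank_sums <- function(scores) rank_sums_cpp(scores)
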