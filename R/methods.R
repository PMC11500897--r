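#' Broom-style accessors for fitted searches and benchmarks
#'
#' `tidy()` on an [epi_ssa()] fit returns the filtered findings, one row per
#' detected interaction; on an [epi_benchmark()] it returns the per-file
#' results. `glance()` returns a one-row summary of the whole run.
#'
#' @param x An `epi_ssa` or `epi_benchmark` object.
#' @param ... Unused.
#' @return A tibble.
#' @name epi-tidiers
NULL

#' @rdname epi-tidiers
#' @export
tidy.epi_ssa <- function(x, ...) {
  out <- x$findings
  out$snp_set <- vapply(out$snps, paste, "", collapse = ",")
  out
}

#' @rdname epi-tidiers
#' @export
glance.epi_ssa <- function(x, ...) {
  tibble::tibble(
    n_findings = nrow(x$findings),
    n_candidates = nrow(x$all_findings),
    best_p = if (nrow(x$findings) > 0) min(x$findings$p_value) else NA_real_,
    mo = x$control$mo, ml = x$control$ml, n = x$control$n,
    max_iter = x$control$max_iter, seed = x$control$seed,
    n_snps = x$data_info$N, m0 = x$data_info$m0, m1 = x$data_info$m1
  )
}

#' @rdname epi-tidiers
#' @export
tidy.epi_benchmark <- function(x, ...) x$per_file

#' @rdname epi-tidiers
#' @export
glance.epi_benchmark <- function(x, ...) {
  tibble::tibble(
    n_files = nrow(x$per_file),
    n_models = nrow(x$summary),
    mean_f = mean(x$per_file$f_measure),
    power = mean(x$per_file$solved)
  )
}

#' Plot methods
#'
#' `autoplot()` on an [epi_ssa()] fit shows every candidate finding on a
#' `-log10(p)` scale in rank order, marking which survived the p-ratio tail
#' filter — the visual counterpart of the `iBiggest` cut. On an
#' [epi_benchmark()] it shows the per-file F-measure distribution by model
#' with the model means.
#'
#' @param object An `epi_ssa` or `epi_benchmark` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name epi-autoplot
NULL

#' @rdname epi-autoplot
#' @export
autoplot.epi_ssa <- function(object, ...) {
  sorted <- object$all_findings
  key <- vapply(sorted$snps, paste, "", collapse = ",")
  sorted <- sorted[order(sorted$p_value, lengths(sorted$snps), key), ]
  kept_keys <- vapply(object$findings$snps, paste, "", collapse = ",")
  df <- tibble::tibble(
    rank = seq_len(nrow(sorted)),
    neg_log10_p = -log10(pmax(sorted$p_value, .Machine$double.xmin)),
    kept = vapply(sorted$snps, paste, "", collapse = ",") %in% kept_keys
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$neg_log10_p,
                                   colour = .data$kept)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166ac",
                                            `FALSE` = "#b2182b"),
                                 name = "kept by p-ratio filter") +
    ggplot2::labs(x = "finding rank (ascending p)",
                  y = expression(-log[10](p)),
                  title = "Detected interactions and the tail filter cut") +
    ggplot2::theme_minimal()
}

#' @rdname epi-autoplot
#' @export
autoplot.epi_benchmark <- function(object, ...) {
  ggplot2::ggplot(object$per_file,
                  ggplot2::aes(x = .data$model_id, y = .data$f_measure)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18, size = 3,
                          colour = "#2166ac") +
    ggplot2::labs(x = "disease model", y = "per-file F-measure",
                  title = "Benchmark F-measure by model") +
    ggplot2::theme_minimal()
}
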