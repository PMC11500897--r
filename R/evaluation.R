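#' Match detected interactions against planted ground truth
#'
#' Scores a finding list against a manifest under exact set equality: a
#' finding counts as a true positive only if its SNP set equals a planted
#' interaction exactly — supersets and subsets are false positives, since the
#' method's noise-elimination step is designed to strip extraneous SNPs.
#'
#' @param findings A findings tibble (`snps` list-column), an [epi_ssa()]
#'   fit, or a list of character vectors.
#' @param truth A ground-truth manifest tibble (see [read_ground_truth()]) or
#'   a list of character vectors.
#' @return A one-row tibble with integer columns `tp`, `fp`, `fn`.
#' @export
match_findings <- function(findings, truth) {
  f_sets <- as_snp_sets(findings)
  t_sets <- as_snp_sets(truth)
  f_keys <- unique(vapply(f_sets, set_key, ""))
  t_keys <- unique(vapply(t_sets, set_key, ""))
  tp <- sum(f_keys %in% t_keys)
  tibble::tibble(tp = tp, fp = length(f_keys) - tp,
                 fn = length(t_keys) - tp)
}

as_snp_sets <- function(x) {
  if (inherits(x, "epi_ssa")) return(x$findings$snps)
  if (is.data.frame(x)) {
    stopifnot("snps" %in% names(x))
    return(x$snps)
  }
  x
}

set_key <- function(s) paste(sort(s), collapse = ",")

#' Recall, precision and F-measure from match counts
#'
#' `recall = TP / (TP + FN)`, `precision = TP / (TP + FP)`, and the F-measure
#' is their harmonic mean. Zero-denominator conventions: recall and precision
#' are 0 when their denominator is 0, and the F-measure is 0 when
#' `recall + precision = 0`. Vectorised over rows.
#'
#' @param tp,fp,fn Nonnegative counts (or a data frame with those columns as
#'   first argument).
#' @return A tibble with columns `recall`, `precision`, `f_measure`.
#' @export
detection_metrics <- function(tp, fp = NULL, fn = NULL) {
  if (is.data.frame(tp)) {
    fp <- tp$fp; fn <- tp$fn; tp <- tp$tp
  }
  stopifnot(all(tp >= 0), all(fp >= 0), all(fn >= 0))
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  f <- ifelse(recall + precision > 0,
              2 * recall * precision / (recall + precision), 0)
  tibble::tibble(recall = recall, precision = precision, f_measure = f)
}

#' Benchmark the detector over a directory of simulated files
#'
#' Runs [epi_ssa()] on every dataset in a directory produced by
#' [simulate_gwas_files()] (datasets `<stem>.txt` with manifests
#' `<stem>.truth.txt`), scores each run against its manifest, and aggregates
#' per model: the model F-measure is the mean of per-file F-measures, and
#' power is the fraction of files in which every planted interaction was
#' recovered exactly. Per-file seeds are derived as `base_seed + file index`
#' over the sorted file list, so a sweep is reproducible and can be sharded.
#'
#' @param dir Directory containing dataset and manifest files.
#' @param control Search parameters (the per-file seed overrides
#'   `control$seed`).
#' @param base_seed Base for per-file seed derivation.
#' @return An object of class `epi_benchmark`: list with `per_file` and
#'   `summary` tibbles. Files without a manifest are skipped with a warning.
#' @export
epi_benchmark <- function(dir, control = epi_ssa_control(), base_seed = 0L) {
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  files <- files[!grepl("\\.truth\\.txt$|_model\\.txt$", files)]
  rows <- vector("list", length(files))
  for (i in seq_along(files)) {
    manifest <- sub("\\.txt$", ".truth.txt", files[i])
    if (!file.exists(manifest)) {
      warn(paste0("no manifest for ", files[i], "; skipped"))
      next
    }
    truth <- read_ground_truth(manifest)
    dat <- read_gwas(files[i])
    ctl <- control
    ctl$seed <- as.integer(base_seed) + i
    fit <- epi_ssa(dat, ctl)
    counts <- match_findings(fit, truth)
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(model_id = truth$model_id[1], file = basename(files[i]),
                     seed = ctl$seed),
      counts, detection_metrics(counts),
      tibble::tibble(solved = counts$fn == 0 & counts$tp > 0))
  }
  per_file <- dplyr::bind_rows(rows)
  summary <- if (nrow(per_file) == 0) {
    tibble::tibble(model_id = character(0), mean_f = numeric(0),
                   sd_f = numeric(0), power = numeric(0),
                   n_files = integer(0))
  } else {
    dplyr::summarise(dplyr::group_by(per_file, .data$model_id),
                     mean_f = mean(.data$f_measure),
                     sd_f = stats::sd(.data$f_measure),
                     power = mean(.data$solved),
                     n_files = dplyr::n(), .groups = "drop")
  }
  structure(list(per_file = per_file, summary = summary, control = control),
            class = "epi_benchmark")
}

#' @export
print.epi_benchmark <- function(x, ...) {
  cat("<epi_benchmark> ", nrow(x$per_file), " files, ",
      nrow(x$summary), " models\n", sep = "")
  print(x$summary)
  invisible(x)
}
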