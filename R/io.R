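#' Read a case-control genotype dataset
#'
#' Reads the tabular dialect produced by GAMETES and by [simulate_gwas()]: one
#' header row naming each SNP plus a class column, then one row per sample.
#' Genotypes are coded 0/1/2 as minor-allele counts; the class column holds
#' 0 for controls and 1 for cases. The class column is recognised by name
#' (`"Class"`, case-insensitive) wherever it appears, so column reordering is
#' tolerated.
#'
#' @param path Path to a tab- or comma-delimited text file.
#' @param delim Field delimiter. `NULL` (default) auto-detects: tab is tried
#'   first, then comma.
#' @return A tibble with one integer column per SNP plus the class column
#'   (renamed to `Class`), validated: genotypes in `{0,1,2}`, phenotype in
#'   `{0,1}`, unique SNP names.
#' @seealso [write_gwas()], [epi_data()]
#' @export
read_gwas <- function(path, delim = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) abort(paste0("empty input file: ", path))
  if (is.null(delim)) delim <- if (grepl("\t", first[[1]])) "\t" else ","
  dat <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_integer()
  ), progress = FALSE, show_col_types = FALSE, name_repair = "minimal")
  if (nrow(dat) == 0L) abort(paste0("empty input file (no sample rows): ", path))
  validate_gwas(dat, context = path)
}

#' Write a case-control genotype dataset
#'
#' Writes the tab-delimited dialect read by [read_gwas()]: SNP columns first,
#' the class column last under the header `Class`. Output is byte-identical
#' for identical inputs, and `read_gwas(write_gwas(d))` reproduces `d` up to
#' the class column being moved last.
#'
#' @param data A validated dataset tibble (see [read_gwas()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gwas <- function(data, path) {
  data <- validate_gwas(data)
  cls <- class_column(data)
  out <- dplyr::relocate(data, !!rlang::sym(cls), .after = dplyr::last_col())
  names(out)[ncol(out)] <- "Class"
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

class_column <- function(data) {
  hit <- which(tolower(names(data)) == "class")
  if (length(hit) == 0L)
    abort("no class column: expected a column named 'Class' (case-insensitive)")
  if (length(hit) > 1L) abort("multiple class columns found")
  names(data)[hit]
}

validate_gwas <- function(data, context = NULL) {
  where <- if (is.null(context)) "" else paste0(" [", context, "]")
  if (ncol(data) < 2L)
    abort(paste0("dataset needs at least one SNP column and a class column", where))
  cls <- class_column(data)
  snp_names <- names(data)[names(data) != cls]
  if (anyDuplicated(snp_names))
    abort(paste0("duplicate SNP name(s) in header: ",
                 paste(unique(snp_names[duplicated(snp_names)]), collapse = ", "),
                 where))
  ph <- data[[cls]]
  bad <- which(is.na(ph) | !(ph %in% c(0L, 1L)))
  if (length(bad) > 0L)
    abort(paste0("malformed class value at row ", bad[[1]],
                 ": phenotype must be 0 (control) or 1 (case)", where))
  for (nm in snp_names) {
    g <- data[[nm]]
    bad <- which(is.na(g) | !(g %in% c(0L, 1L, 2L)))
    if (length(bad) > 0L)
      abort(paste0("malformed genotype at row ", bad[[1]], ", column '", nm,
                   "': values must be 0, 1 or 2 (minor-allele count)", where))
  }
  tibble::as_tibble(data)
}

#' Prepare a dataset for repeated scoring
#'
#' Converts a dataset tibble into the internal representation used by the
#' scoring functions and the search engine: an integer genotype matrix split
#' by class, plus the sample counts `m0` (controls), `m1` (cases) and the SNP
#' count `N`. All scoring functions accept either form; preparing once avoids
#' repeated validation in tight loops.
#'
#' @param data A dataset tibble (see [read_gwas()]) or an `epi_data` object
#'   (returned unchanged).
#' @return An object of class `epi_data`: a list with elements `geno`
#'   (samples x SNPs integer matrix, SNP names as colnames), `phenotype`,
#'   `snp_names`, `m0`, `m1`, `N`, and the class-split matrices `g0`, `g1`.
#' @export
epi_data <- function(data) {
  if (inherits(data, "epi_data")) return(data)
  data <- validate_gwas(data)
  cls <- class_column(data)
  snp_names <- setdiff(names(data), cls)
  geno <- as.matrix(data[snp_names])
  storage.mode(geno) <- "integer"
  ph <- as.integer(data[[cls]])
  structure(list(
    geno = geno, phenotype = ph, snp_names = snp_names,
    m0 = sum(ph == 0L), m1 = sum(ph == 1L), N = length(snp_names),
    g0 = geno[ph == 0L, , drop = FALSE], g1 = geno[ph == 1L, , drop = FALSE]
  ), class = "epi_data")
}

#' @export
print.epi_data <- function(x, ...) {
  cat("<epi_data> ", x$N, " SNPs, ", x$m0, " controls + ", x$m1, " cases\n",
      sep = "")
  invisible(x)
}

# Resolve SNP names or indices against an epi_data object; returns integer
# 1-based column indices.
resolve_snps <- function(ds, snps) {
  if (length(snps) == 0L) abort("'snps' must name at least one SNP")
  if (is.character(snps)) {
    idx <- match(snps, ds$snp_names)
    if (anyNA(idx))
      abort(paste0("unknown SNP name(s): ",
                   paste(snps[is.na(idx)], collapse = ", ")))
  } else {
    idx <- as.integer(snps)
    if (any(idx < 1L | idx > ds$N))
      abort(paste0("SNP index out of range 1..", ds$N))
  }
  if (anyDuplicated(idx)) abort("'snps' contains duplicates")
  idx
}

#' Read and write ground-truth manifests
#'
#' A ground-truth manifest records the pathogenic SNP interactions planted by
#' the simulator: a headered TSV with columns `model_id` and `snps` (the SNP
#' names of one interaction, comma-joined). In memory a manifest is a tibble
#' with a `model_id` character column and a `snps` list-column of character
#' vectors.
#'
#' @param truth A manifest tibble with columns `model_id` and `snps`
#'   (list-column of character vectors, each of length >= 2).
#' @param path File path.
#' @return `read_ground_truth()` returns the manifest tibble;
#'   `write_ground_truth()` returns `path` invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(all(c("model_id", "snps") %in% names(truth)))
  if (any(lengths(truth$snps) < 2L))
    abort("each planted interaction must contain at least 2 SNPs")
  out <- tibble::tibble(
    model_id = truth$model_id,
    snps = vapply(truth$snps, paste, "", collapse = ",")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  dat <- readr::read_tsv(path, col_types = "cc", progress = FALSE,
                         show_col_types = FALSE)
  stopifnot(all(c("model_id", "snps") %in% names(dat)))
  tibble::tibble(model_id = dat$model_id,
                 snps = strsplit(dat$snps, ",", fixed = TRUE))
}
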