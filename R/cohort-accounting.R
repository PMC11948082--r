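# Cohort bookkeeping and small text-format interfaces (per-cohort response
# counts, GMT gene sets).

#' Per-cohort pathological-response counts
#'
#' Reads a CSV of per-cohort response counts (`cohort`, `n_pcr`, `n_total`).
#' The package ships the published multicenter breast-cancer NAT enrollment
#' as its reference table: training 167/431, external validation 590/1595,
#' immunotherapy 55/88, multi-omics 92/165.
#'
#' @param path CSV path; defaults to the shipped reference table.
#' @return Tibble: cohort, n_pcr, n_total.
#' @export
read_cohort_counts <- function(path = system.file("extdata", "cohort_pcr_counts.csv",
                                 package = "habitatr"
                               )) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Pooled response rate across cohorts
#'
#' Sums the per-cohort response counts and divides by total enrollment.
#'
#' @param counts Tibble from [read_cohort_counts()].
#' @return Pooled rate as a percentage.
#' @export
pooled_pcr_rate <- function(counts = read_cohort_counts()) {
  stopifnot(all(c("n_pcr", "n_total") %in% names(counts)))
  100 * sum(counts$n_pcr) / sum(counts$n_total)
}

#' Read and write GMT gene-set files
#'
#' Minimal reader/writer for the tab-separated GMT gene-set format
#' (set name, description, member genes).
#'
#' @param path File path.
#' @return `read_gmt()`: named list of gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(x) x[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, character(1), 1)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of gene vectors.
#' @param description Description field per set.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
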