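# Synthetic expression matrices and cell-type composition tables carrying a
# planted marker-gene shift between model-score groups.

#' Generate a synthetic RNA-seq count matrix with planted marker shifts
#'
#' Draws negative-binomial counts with lognormal per-gene baselines and
#' per-sample library-size factors. Genes belonging to the marker sets named
#' in `shifted_sets` are up-shifted by `shift` log2 units in the samples with
#' `group == "high"`. Gene lengths (kb) are attached for TPM normalization.
#'
#' @param n_genes Number of genes in the universe.
#' @param n_samples Number of samples (at least 6, both groups present).
#' @param group Character/factor of length `n_samples` with levels
#'   `"low"`/`"high"`; generated balanced if `NULL`.
#' @param marker_sets Named list of marker gene vectors; every member must
#'   be in the gene universe.
#' @param gene_universe Optional character vector naming all genes. By
#'   default a synthetic universe `gene0001`... is built and the marker
#'   genes are placed in it; a marker gene absent from a user-supplied
#'   universe is an error naming the gene.
#' @param shift Log2 fold change planted in `shifted_sets` for the high group.
#' @param shifted_sets Names of the marker sets receiving the shift.
#' @param dispersion Negative-binomial dispersion (1/size).
#' @param seed Integer seed.
#' @return List with `counts` (genes x samples integer matrix),
#'   `gene_lengths_kb`, `group`, and `marker_sets`.
#' @export
generate_expression <- function(n_genes = 2000,
                                n_samples = 60,
                                group = NULL,
                                marker_sets = default_marker_sets(),
                                shift = 2,
                                shifted_sets = "B_cells",
                                dispersion = 0.2,
                                gene_universe = NULL,
                                seed = NULL) {
  if (n_samples < 6) stop("n_samples must be at least 6", call. = FALSE)
  if (is.null(group)) {
    group <- rep(c("low", "high"), length.out = n_samples)
  }
  group <- as.character(group)
  if (length(group) != n_samples || !all(group %in% c("low", "high")) ||
    length(unique(group)) < 2) {
    stop("group must contain both 'low' and 'high' labels", call. = FALSE)
  }
  with_local_seed(seed, {
    marker_genes <- unique(unlist(marker_sets))
    if (is.null(gene_universe)) {
      genes <- sprintf("gene%04d", seq_len(n_genes))
      named <- marker_genes[!grepl("^gene[0-9]+$", marker_genes)]
      if (length(named) > n_genes / 2) {
        stop("too many named marker genes for universe", call. = FALSE)
      }
      genes[seq_along(named)] <- named
    } else {
      genes <- unique(as.character(gene_universe))
      n_genes <- length(genes)
    }
    missing <- setdiff(marker_genes, genes)
    if (length(missing)) {
      stop("marker gene(s) not in expression universe: ",
        paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
    base_log2 <- stats::rnorm(n_genes, 5, 2)
    lib <- stats::rlnorm(n_samples, 0, 0.2)
    shift_vec <- rep(0, n_genes)
    for (s in intersect(shifted_sets, names(marker_sets))) {
      shift_vec[match(marker_sets[[s]], genes)] <- shift
    }
    mu <- 2^(outer(base_log2, rep(0, n_samples), "+") +
      outer(shift_vec, as.numeric(group == "high"), "*"))
    mu <- sweep(mu, 2, lib, "*")
    counts <- matrix(
      stats::rnbinom(n_genes * n_samples, mu = mu, size = 1 / dispersion),
      nrow = n_genes,
      dimnames = list(genes, sprintf("S%03d", seq_len(n_samples)))
    )
    lengths_kb <- stats::rlnorm(n_genes, 0.5, 0.4)
    names(lengths_kb) <- genes
    list(
      counts = counts, gene_lengths_kb = lengths_kb,
      group = stats::setNames(group, colnames(counts)),
      marker_sets = marker_sets
    )
  })
}

#' Built-in immune/stromal marker panels
#'
#' Compact marker panels for MCPcounter-style abundance indices. The B-cell
#' panel uses the canonical lineage markers CD19, CD79A and MS4A1 plus the
#' immunoglobulin genes IGHM, IGHG1 and IGHG2.
#'
#' @return Named list of marker gene vectors.
#' @export
default_marker_sets <- function() {
  list(
    B_cells = c("CD19", "CD79A", "MS4A1", "IGHM", "IGHG1", "IGHG2"),
    T_cells = c("CD3D", "CD3E", "CD2", "TRAC"),
    cytotoxic_lymphocytes = c("GZMB", "PRF1", "NKG7", "KLRD1"),
    myeloid = c("CD68", "CD163", "CSF1R", "ITGAM"),
    endothelial = c("PECAM1", "VWF", "CDH5"),
    fibroblasts = c("COL1A1", "COL1A2", "DCN", "PDGFRB")
  )
}

#' Generate a cell-type by patient count table
#'
#' Multinomial per-patient cell counts over seven annotated populations
#' (epithelial, basal, endothelial, fibroblast, myeloid, T, B), with the
#' B-cell probability scaled by `b_cell_enrichment` in high-group patients.
#'
#' @param n_patients Number of patients.
#' @param group Character vector of `"low"`/`"high"` per patient; balanced if
#'   `NULL`.
#' @param b_cell_enrichment Multiplier (> 0) on the B-cell probability in the
#'   high group.
#' @param cells_per_patient Mean number of cells captured per patient.
#' @param seed Integer seed.
#' @return List with `counts` (cell type x patient matrix) and `group`.
#' @export
generate_celltype_table <- function(n_patients = 20,
                                    group = NULL,
                                    b_cell_enrichment = 5,
                                    cells_per_patient = 2000,
                                    seed = NULL) {
  if (b_cell_enrichment <= 0) stop("b_cell_enrichment must be > 0", call. = FALSE)
  if (is.null(group)) group <- rep(c("low", "high"), length.out = n_patients)
  group <- as.character(group)
  stopifnot(length(group) == n_patients)
  types <- c("epithelial", "basal", "endothelial", "fibroblast", "myeloid", "T", "B")
  base <- c(0.30, 0.08, 0.07, 0.15, 0.12, 0.20, 0.08)
  with_local_seed(seed, {
    counts <- sapply(seq_len(n_patients), function(i) {
      p <- base
      if (group[i] == "high") p[7] <- p[7] * b_cell_enrichment
      p <- p / sum(p)
      n_cells <- stats::rpois(1, cells_per_patient)
      stats::rmultinom(1, n_cells, p)[, 1]
    })
    rownames(counts) <- types
    colnames(counts) <- sprintf("P%03d", seq_len(n_patients))
    list(counts = counts, group = stats::setNames(group, colnames(counts)))
  })
}
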