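#' Default per-class single-cell QC thresholds
#'
#' iHep-type samples: cells with fewer than 50,000 mapped reads, expressing
#' fewer than 4000 genes, or with more than 6% of UMIs from mitochondrial
#' genes are excluded. HFL_CMT-type samples: fewer than 2500 genes or more
#' than 10% mitochondrial UMIs (no mapped-read threshold). All comparisons
#' are strict, so boundary cells (exactly 4000 genes, exactly 6% mito) pass.
#'
#' @return Named list of per-class threshold lists (`min_mapped_reads`,
#'   `min_genes`, `max_mito_fraction`; `NA` disables a rule).
#' @export
qc_default_thresholds <- function() {
  list(
    iHep = list(min_mapped_reads = 50000, min_genes = 4000,
                max_mito_fraction = 0.06),
    HFL_CMT = list(min_mapped_reads = NA_real_, min_genes = 2500,
                   max_mito_fraction = 0.10)
  )
}

#' Build per-cell QC profiles from a count matrix
#'
#' @param counts Genes x cells matrix (raw counts / UMIs).
#' @param mapped_reads Named numeric vector of per-cell mapped reads (an
#'   upstream-supplied metric).
#' @param sample_class Per-cell class label (recycled).
#' @param mito_prefix Prefixes identifying mitochondrial genes.
#' @return Data frame: `cell_id`, `mapped_reads`, `genes_detected`,
#'   `mito_fraction`, `sample_class`.
#' @export
cell_profiles <- function(counts, mapped_reads, sample_class = "iHep",
                          mito_prefix = c("MT-", "mt-")) {
  counts <- as.matrix(counts)
  stopifnot(!is.null(colnames(counts)), !is.null(rownames(counts)))
  mito <- Reduce(`|`, lapply(mito_prefix, function(p)
    startsWith(rownames(counts), p)))
  totals <- colSums(counts)
  data.frame(
    cell_id = colnames(counts),
    mapped_reads = as.numeric(mapped_reads[colnames(counts)]),
    genes_detected = colSums(counts > 0),
    mito_fraction = colSums(counts[mito, , drop = FALSE]) / pmax(totals, 1),
    sample_class = rep_len(sample_class, ncol(counts)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Filter cells on per-class QC thresholds
#'
#' Exclusion uses strict inequalities ("fewer than", "greater than"):
#' a cell is removed when `mapped_reads < min_mapped_reads`,
#' `genes_detected < min_genes`, or `mito_fraction > max_mito_fraction` for
#' its class; boundary values are kept. `NA` thresholds are skipped.
#'
#' @param cells Data frame from [cell_profiles()].
#' @param thresholds Per-class thresholds, see [qc_default_thresholds()].
#' @param default_class Class assumed for cells whose `sample_class` has no
#'   entry in `thresholds`; an unknown class without a default is an error.
#' @return List with `kept` and `excluded` (the latter with a `reason`
#'   column, semicolon-separated when several rules fire).
#' @export
qc_filter <- function(cells, thresholds = qc_default_thresholds(),
                      default_class = NULL) {
  stopifnot(all(c("cell_id", "mapped_reads", "genes_detected", "mito_fraction",
                  "sample_class") %in% names(cells)))
  cls <- cells$sample_class
  unknown <- !(cls %in% names(thresholds))
  if (any(unknown)) {
    if (is.null(default_class))
      stop("unknown sample class(es): ",
           paste(unique(cls[unknown]), collapse = ", "),
           " (supply `default_class` to map them)", call. = FALSE)
    cls[unknown] <- default_class
  }
  reason <- character(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    th <- thresholds[[cls[i]]]
    r <- character(0)
    if (!is.na(th$min_mapped_reads) && cells$mapped_reads[i] < th$min_mapped_reads)
      r <- c(r, "low_mapped_reads")
    if (!is.na(th$min_genes) && cells$genes_detected[i] < th$min_genes)
      r <- c(r, "few_genes")
    if (!is.na(th$max_mito_fraction) && cells$mito_fraction[i] > th$max_mito_fraction)
      r <- c(r, "high_mito")
    reason[i] <- paste(r, collapse = ";")
  }
  keep <- reason == ""
  excluded <- cells[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  list(kept = cells[keep, , drop = FALSE], excluded = excluded)
}

#' Discard genes detected in too few cells
#'
#' Keeps genes with a nonzero count in at least `min_cells` cells (boundary
#' inclusive: detected in exactly `min_cells` cells is kept).
#'
#' @param counts Genes x cells matrix.
#' @param min_cells Minimum number of cells (default 5).
#' @return The row-subset matrix.
#' @export
gene_filter <- function(counts, min_cells = 5L) {
  counts[rowSums(counts > 0) >= min_cells, , drop = FALSE]
}

#' Down-sample cells per sample
#'
#' Uniformly samples `n` cells without replacement within each sample;
#' samples with at most `n` cells pass through whole. Column order of the
#' retained cells is preserved.
#'
#' @param counts Genes x cells matrix.
#' @param n Cells to retain per sample (default 500).
#' @param seed Integer seed.
#' @param samples Optional per-cell sample labels (single sample if `NULL`).
#' @return The column-subset matrix.
#' @export
downsample_cells <- function(counts, n = 500L, seed = 1L, samples = NULL) {
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  if (is.null(samples)) samples <- rep("sample1", ncol(counts))
  stopifnot(length(samples) == ncol(counts))
  with_seed(seed, {
    keep <- unlist(lapply(split(seq_len(ncol(counts)), samples), function(idx)
      if (length(idx) <= n) idx else sort(sample(idx, n))), use.names = FALSE)
    counts[, sort(keep), drop = FALSE]
  })
}

#' Library-size log-normalization
#'
#' `x' = ln(1 + scale * x / cell_total)`, the standard per-cell scaling
#' followed by log1p. Doubling every count of a cell leaves its normalized
#' vector unchanged.
#'
#' @param counts Genes x cells matrix with nonzero column totals.
#' @param scale Scale factor (default 10,000).
#' @return Normalized dense matrix.
#' @export
lognormalize <- function(counts, scale = 1e4) {
  counts <- as.matrix(counts)
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("cell(s) with zero total counts: ",
         paste(colnames(counts)[totals == 0], collapse = ", "), call. = FALSE)
  log1p(sweep(counts, 2, totals, "/") * scale)
}

.PHASES <- c("G1/S", "S", "G2/M", "M", "M/G1")

#' Five-phase cell-cycle scoring
#'
#' Scores each cell for the phases G1/S, S, G2/M, M, M/G1 as the mean over
#' the phase's marker genes of the gene's normalized expression standardized
#' across cells (z-score), so highly expressed markers do not dominate;
#' `standardize = FALSE` averages the normalized expression directly. Genes
#' with zero variance get z = 0. The assigned phase is the argmax, ties
#' resolved in the fixed order G1/S < S < G2/M < M < M/G1. Markers absent
#' from the matrix are dropped and reported; a phase with no present marker
#' is an error naming the phase.
#'
#' @param normalized Genes x cells normalized matrix ([lognormalize()]).
#' @param phase_markers Named list of five marker vectors (G1/S, S, G2/M, M,
#'   M/G1 order; names are matched when present).
#' @param standardize Use across-cell z-scores (default) or raw means.
#' @return Data frame of class `phase_scores`: `cell`, one score column per
#'   phase (`G1S`, `S`, `G2M`, `M`, `MG1`), `assigned_phase`; attribute
#'   `missing_markers`.
#' @export
cell_cycle_scores <- function(normalized, phase_markers, standardize = TRUE) {
  stopifnot(length(phase_markers) == 5L)
  if (!is.null(names(phase_markers)) && all(.PHASES %in% names(phase_markers)))
    phase_markers <- phase_markers[.PHASES]
  names(phase_markers) <- .PHASES
  normalized <- as.matrix(normalized)
  present <- lapply(phase_markers, intersect, rownames(normalized))
  missing <- Map(setdiff, phase_markers, present)
  empty <- lengths(present) == 0L
  if (any(empty))
    stop("no markers present for phase(s): ",
         paste(.PHASES[empty], collapse = ", "), call. = FALSE)

  expr <- normalized
  if (standardize) {
    mu <- rowMeans(expr)
    sd <- apply(expr, 1, stats::sd)
    sd[sd == 0] <- Inf  # constant genes contribute z = 0
    expr <- (expr - mu) / sd
  }
  scores <- vapply(present, function(g)
    colMeans(expr[g, , drop = FALSE]), numeric(ncol(expr)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  assigned <- .PHASES[apply(scores, 1, which.max)]
  out <- data.frame(cell = colnames(normalized), scores,
                    assigned_phase = assigned, row.names = NULL,
                    stringsAsFactors = FALSE)
  names(out)[2:6] <- c("G1S", "S", "G2M", "M", "MG1")
  attr(out, "missing_markers") <- missing
  class(out) <- c("phase_scores", class(out))
  out
}

#' Expression relative to the per-gene mean across cells
#'
#' `r(g, c) = expr(g, c) / mean_c' expr(g, c')`; each retained gene's row
#' mean is exactly 1. Genes with zero mean are excluded and reported.
#'
#' @param normalized Genes x cells matrix.
#' @return Matrix of ratios; attribute `excluded` names zero-mean genes.
#' @export
relative_expression <- function(normalized) {
  normalized <- as.matrix(normalized)
  means <- rowMeans(normalized)
  excluded <- rownames(normalized)[means == 0]
  out <- normalized[means != 0, , drop = FALSE] / means[means != 0]
  attr(out, "excluded") <- excluded
  out
}
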