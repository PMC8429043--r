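#' Simulation configuration
#'
#' Bundles the parameters of every synthetic-data generator into one validated
#' object. Defaults describe the study conditions the package's validation
#' suite exercises: 20x per-site read coverage with a log-likelihood-ratio
#' separation of 4 (sd 1) between methylated and unmethylated states, a small
#' fraction of fully-GC-methylated contaminant reads, negative-binomial bulk
#' counts for 5000 genes in two groups of 3 replicates with 10% of genes
#' differentially expressed at |log2FC| = 3 and gene-wise dispersion around
#' 0.05 (typical for cell-line triplicates), and 500-cell single-cell matrices
#' with five equally likely cell-cycle phases and 10% planted low-quality
#' cells.
#'
#' @param seed Integer seed; recorded in every generated output.
#' @param coverage Mean reads covering a site (per strand).
#' @param llr_mean_effect Mean |LLR| emitted at a site whose true state is
#'   known; the signed LLR is drawn from Normal(+effect) when methylated and
#'   Normal(-effect) when unmethylated.
#' @param llr_sd Standard deviation of the emitted LLR.
#' @param contamination_fraction Fraction of reads synthesized as
#'   fully-GC-methylated contaminants (cell-free DNA-like).
#' @param read_length Read length in bp.
#' @param n_genes,n_samples_per_group,de_fraction,lfc_scale,dispersion_scale
#'   Bulk count simulation: number of genes, replicates per group, fraction of
#'   genes with a planted effect, planted |log2 fold change|, and the central
#'   gene-wise NB dispersion.
#' @param n_cells Cells per simulated single-cell sample.
#' @param phase_proportions Numeric length-5 vector of cell-cycle phase
#'   probabilities (G1/S, S, G2/M, M, M/G1); normalized to sum to 1.
#' @param lowq_fraction Fraction of cells planted below the QC thresholds.
#' @param marker_fold Fold-change by which a cell overexpresses its own
#'   phase's marker genes.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       coverage = 20,
                       llr_mean_effect = 4,
                       llr_sd = 1,
                       contamination_fraction = 0.02,
                       read_length = 2000L,
                       n_genes = 5000L,
                       n_samples_per_group = 3L,
                       de_fraction = 0.1,
                       lfc_scale = 3,
                       dispersion_scale = 0.05,
                       n_cells = 500L,
                       phase_proportions = rep(0.2, 5),
                       lowq_fraction = 0.1,
                       marker_fold = 4) {
  check_fraction(contamination_fraction, "contamination_fraction")
  if (de_fraction > 1) stop("`de_fraction` must be in [0, 1]", call. = FALSE)
  check_fraction(de_fraction, "de_fraction")
  check_fraction(lowq_fraction, "lowq_fraction")
  stopifnot_scalar_number(llr_mean_effect, "llr_mean_effect")
  stopifnot_scalar_number(llr_sd, "llr_sd")
  if (llr_mean_effect < 0) stop("`llr_mean_effect` must be >= 0", call. = FALSE)
  if (llr_sd < 0) stop("`llr_sd` must be >= 0", call. = FALSE)
  if (length(phase_proportions) != 5L || any(phase_proportions < 0) ||
      sum(phase_proportions) <= 0)
    stop("`phase_proportions` must be 5 non-negative numbers with positive sum",
         call. = FALSE)
  if (n_samples_per_group < 2L)
    stop("`n_samples_per_group` must be >= 2", call. = FALSE)
  if (coverage < 1) stop("`coverage` must be >= 1", call. = FALSE)
  structure(list(
    seed = as.integer(seed),
    coverage = coverage,
    llr_mean_effect = llr_mean_effect,
    llr_sd = llr_sd,
    contamination_fraction = contamination_fraction,
    read_length = as.integer(read_length),
    n_genes = as.integer(n_genes),
    n_samples_per_group = as.integer(n_samples_per_group),
    de_fraction = de_fraction,
    lfc_scale = lfc_scale,
    dispersion_scale = dispersion_scale,
    n_cells = as.integer(n_cells),
    phase_proportions = phase_proportions / sum(phase_proportions),
    lowq_fraction = lowq_fraction,
    marker_fold = marker_fold
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration (seed ", x$seed, ")\n", sep = "")
  for (nm in setdiff(names(x), "seed"))
    cat("  ", nm, ": ", paste(signif(x[[nm]], 4), collapse = " "), "\n", sep = "")
  invisible(x)
}
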