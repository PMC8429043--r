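#' Simulate a bulk RNA-seq count matrix with planted differential expression
#'
#' Gene-wise means are log-normal, gene-wise negative-binomial dispersions are
#' centered on `dispersion_scale` with mild log-normal jitter, and per-sample
#' library-size factors are drawn around 1. A `de_fraction` of genes receive a
#' planted log2 fold change of +/-`lfc_scale` (random sign) in the second
#' group. Counts are `rnbinom(mu = sf_s * mu_g(group), size = 1/disp_g)`.
#'
#' @param cfg A [sim_config()]; uses `n_genes`, `n_samples_per_group`,
#'   `de_fraction`, `lfc_scale`, `dispersion_scale`, `seed`.
#' @return A list with `counts` (integer matrix, genes x samples), `groups`
#'   (factor of length 2n), `truth` (data frame `gene`, `true_l2fc`, `is_de`,
#'   `dispersion`, `base_mean`) and `size_factors_true`.
#' @export
simulate_counts_bulk <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    ng <- cfg$n_genes
    ns <- cfg$n_samples_per_group
    genes <- sprintf("GENE%05d", seq_len(ng))
    mu <- exp(stats::rnorm(ng, log(150), 1.5))
    disp <- cfg$dispersion_scale * exp(stats::rnorm(ng, 0, 0.3))
    n_de <- floor(cfg$de_fraction * ng)
    is_de <- rep(FALSE, ng)
    l2fc <- rep(0, ng)
    if (n_de > 0) {
      idx <- sample.int(ng, n_de)
      is_de[idx] <- TRUE
      l2fc[idx] <- cfg$lfc_scale * sample(c(-1, 1), n_de, replace = TRUE)
    }
    sf <- exp(stats::runif(2L * ns, log(0.75), log(4 / 3)))
    groups <- factor(rep(c("A", "B"), each = ns), levels = c("A", "B"))
    counts <- matrix(0L, ng, 2L * ns,
                     dimnames = list(genes, sprintf("S%02d_%s", seq_len(2L * ns), groups)))
    for (s in seq_len(2L * ns)) {
      m <- mu * if (groups[s] == "B") 2^l2fc else 1
      counts[, s] <- stats::rnbinom(ng, mu = sf[s] * m, size = 1 / disp)
    }
    list(counts = counts, groups = groups,
         truth = data.frame(gene = genes, true_l2fc = l2fc, is_de = is_de,
                            dispersion = disp, base_mean = mu,
                            stringsAsFactors = FALSE),
         size_factors_true = sf, seed = cfg$seed)
  })
}

#' Default five-phase cell-cycle marker sets for simulation
#'
#' Disjoint synthetic marker gene lists for the five phases G1/S, S, G2/M, M,
#' M/G1, named after the genes the single-cell simulator overexpresses.
#'
#' @param n_per_phase Markers per phase.
#' @return Named list of five character vectors.
#' @export
default_phase_markers <- function(n_per_phase = 20L) {
  phases <- c("G1/S", "S", "G2/M", "M", "M/G1")
  tags <- c("G1S", "S", "G2M", "M", "MG1")
  stats::setNames(lapply(seq_along(phases), function(i)
    sprintf("MK%s_%02d", tags[i], seq_len(n_per_phase))), phases)
}

#' Simulate a single-cell count matrix with planted phases and low-quality cells
#'
#' Cells are assigned one of the five cell-cycle phases by
#' `cfg$phase_proportions`; a cell overexpresses its own phase's markers by
#' `cfg$marker_fold`. Mitochondrial genes (`MT-*`) contribute a small baseline
#' fraction of counts. A `lowq_fraction` of cells are planted to violate the
#' iHep-style QC thresholds by one randomly chosen failure mode: too few
#' detected genes (counts thinned), too-high mitochondrial fraction, or too
#' few mapped reads.
#'
#' @param cfg A [sim_config()]; uses `n_cells`, `phase_proportions`,
#'   `lowq_fraction`, `marker_fold`, `seed`.
#' @param phase_markers Named list of five disjoint marker gene vectors
#'   (G1/S, S, G2/M, M, M/G1 order).
#' @param n_genes Number of non-mitochondrial background genes (the matrix
#'   additionally contains the markers and 13 `MT-*` genes).
#' @param sample_class QC class recorded for every cell.
#'
#' @return A list with `counts` (genes x cells integer matrix),
#'   `mapped_reads` (named vector), `truth` (data frame `cell`, `phase`,
#'   `lowq`, `failure_mode`, `mito_fraction`, `mapped_reads`), and
#'   `sample_class`.
#' @export
simulate_counts_sc <- function(cfg = sim_config(), phase_markers = default_phase_markers(),
                               n_genes = 6000L, sample_class = "iHep") {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(phase_markers) != 5L)
    stop("`phase_markers` must list five phases", call. = FALSE)
  all_mk <- unlist(phase_markers, use.names = FALSE)
  if (anyDuplicated(all_mk))
    stop("phase marker lists must be disjoint", call. = FALSE)
  phases <- c("G1/S", "S", "G2/M", "M", "M/G1")

  with_seed(cfg$seed, {
    nc <- cfg$n_cells
    mito <- sprintf("MT-%02d", 1:13)
    background <- sprintf("BG%05d", seq_len(n_genes))
    genes <- c(all_mk, mito, background)
    ng <- length(genes)

    phase_of <- phases[sample.int(5L, nc, replace = TRUE, prob = cfg$phase_proportions)]
    lowq <- stats::runif(nc) < cfg$lowq_fraction
    failure <- rep(NA_character_, nc)
    failure[lowq] <- sample(c("genes", "mito", "reads"), sum(lowq), replace = TRUE)

    # baseline means: detection ~92% per gene for a good cell
    base_mu <- stats::rgamma(ng, shape = 2, rate = 0.8)
    names(base_mu) <- genes
    base_mu[mito] <- 8  # ~2-3% of total counts

    counts <- matrix(0L, ng, nc, dimnames = list(genes, sprintf("CELL%04d", seq_len(nc))))
    for (j in seq_len(nc)) {
      mu <- base_mu
      mu[phase_markers[[phase_of[j]]]] <- mu[phase_markers[[phase_of[j]]]] * cfg$marker_fold
      x <- stats::rnbinom(ng, mu = mu, size = 10)
      if (lowq[j] && failure[j] == "genes")
        x <- stats::rbinom(ng, x, 0.12)  # thinning: few genes detected
      if (lowq[j] && failure[j] == "mito")
        x[match(mito, genes)] <- x[match(mito, genes)] + stats::rpois(13, sum(x) * 0.015)
      counts[, j] <- x
    }
    totals <- colSums(counts)
    mito_frac <- colSums(counts[mito, , drop = FALSE]) / pmax(totals, 1)
    mapped <- round(totals * stats::runif(nc, 20, 30))
    bad_reads <- lowq & failure == "reads"
    mapped[bad_reads] <- round(stats::runif(sum(bad_reads), 10000, 45000))

    list(counts = counts, mapped_reads = stats::setNames(mapped, colnames(counts)),
         truth = data.frame(cell = colnames(counts), phase = phase_of,
                            lowq = lowq, failure_mode = failure,
                            mito_fraction = mito_frac, mapped_reads = mapped,
                            stringsAsFactors = FALSE),
         sample_class = sample_class, seed = cfg$seed)
  })
}
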