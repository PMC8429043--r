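#' Median-of-ratios size factors
#'
#' Computes per-sample normalization factors against a geometric-mean
#' pseudo-reference: for each sample, the median over genes (with nonzero
#' counts in all samples) of `count / geometric_mean`. Factors are reported
#' unscaled.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @return Named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  log_geo <- rowMeans(log(counts))
  usable <- is.finite(log_geo)
  if (!any(usable))
    stop("no gene has nonzero counts in all samples; consider a pseudo-reference fallback",
         call. = FALSE)
  apply(counts, 2, function(col)
    exp(stats::median(log(col[usable]) - log_geo[usable])))
}

#' Negative-binomial Wald test for two-group differential expression
#'
#' A compact NB Wald test in the style of count-based DE tools. Counts are
#' normalized by median-of-ratios size factors; the log2 fold change is
#' computed from group means of normalized counts with a pseudocount of 0.5;
#' the gene-wise NB dispersion is a method-of-moments estimate from the
#' pooled within-group variance (floored at 1e-8); the standard error of the
#' log2 fold change follows from the NB variance by the delta method; and the
#' Wald statistic is referred to a t distribution with `n1 + n2 - 2` degrees
#' of freedom. The t reference (rather than a normal) is the package's
#' small-sample calibration choice: with triplicates the dispersion estimate
#' has 4 residual df, and a normal reference makes the test anti-conservative.
#' P values are Benjamini-Hochberg adjusted over the tested genes. No
#' dispersion or fold-change shrinkage across genes is applied; this is a
#' documented simplification relative to full empirical-Bayes DE packages.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @param groups Factor with two levels (fold changes are second vs first).
#' @param sf Optional size factors; computed with [size_factors()] if `NULL`.
#' @return Data frame of class `gene_stats` with columns `gene`, `baseMean`,
#'   `log2fc`, `se`, `stat`, `pvalue`, `padj`, `dispersion`; attribute
#'   `excluded` lists all-zero genes that were not tested.
#' @export
nb_wald_test <- function(counts, groups, sf = NULL) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L)
    stop("`groups` must have exactly two levels", call. = FALSE)
  if (length(groups) != ncol(counts))
    stop("`groups` length must match the number of samples", call. = FALSE)
  tab <- table(groups)
  if (any(tab < 2L)) stop("need >= 2 samples per group", call. = FALSE)
  if (is.null(sf)) sf <- size_factors(counts)

  all_zero <- rowSums(counts) == 0
  excluded <- rownames(counts)[all_zero]
  counts <- counts[!all_zero, , drop = FALSE]
  q <- sweep(counts, 2, sf, "/")

  g1 <- groups == levels(groups)[1]
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(q[, g1, drop = FALSE])
  m2 <- rowMeans(q[, g2, drop = FALSE])
  v1 <- apply(q[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(q[, g2, drop = FALSE], 1, stats::var)
  xi1 <- mean(1 / sf[g1]); xi2 <- mean(1 / sf[g2])

  # pooled within-group variance; MoM dispersion from
  # var(q) = xi * mu + alpha * mu^2 (size-factor-adjusted Poisson + NB terms)
  w1 <- (n1 - 1) / (n1 + n2 - 2); w2 <- (n2 - 1) / (n1 + n2 - 2)
  s2 <- w1 * v1 + w2 * v2
  disp <- (s2 - (w1 * xi1 * m1 + w2 * xi2 * m2)) / (w1 * m1^2 + w2 * m2^2)
  disp[!is.finite(disp)] <- 1e-8
  disp <- pmax(disp, 1e-8)

  l2fc <- log2((m2 + 0.5) / (m1 + 0.5))
  vlog2 <- function(m, xi, n) (xi * m + disp * m^2) / n / ((m + 0.5) * log(2))^2
  se <- sqrt(vlog2(m1, xi1, n1) + vlog2(m2, xi2, n2))
  stat <- l2fc / se
  pvalue <- 2 * stats::pt(-abs(stat), df = n1 + n2 - 2)
  out <- data.frame(
    gene = rownames(counts), baseMean = rowMeans(q), log2fc = l2fc, se = se,
    stat = stat, pvalue = pvalue, padj = stats::p.adjust(pvalue, "BH"),
    dispersion = disp, row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "excluded") <- excluded
  class(out) <- c("gene_stats", class(out))
  out
}

#' Threshold a differential-expression table into up/down gene sets
#'
#' Applies the strict cutoffs `baseMean > min_base_mean`, `padj < max_fdr`,
#' `|log2fc| > min_abs_l2fc` (all strict, exactly as stated) and splits the
#' survivors by fold-change sign. Tightening any threshold never adds genes.
#'
#' @param stats A `gene_stats` data frame.
#' @param min_base_mean,max_fdr,min_abs_l2fc Strict thresholds.
#' @return List with character vectors `up` and `down`.
#' @export
filter_de <- function(stats, min_base_mean = 50, max_fdr = 0.01,
                      min_abs_l2fc = 2) {
  stopifnot(all(c("gene", "baseMean", "log2fc", "padj") %in% names(stats)))
  pass <- stats$baseMean > min_base_mean & stats$padj < max_fdr &
    abs(stats$log2fc) > min_abs_l2fc
  pass[is.na(pass)] <- FALSE
  list(up = stats$gene[pass & stats$log2fc > 0],
       down = stats$gene[pass & stats$log2fc < 0])
}

#' Top-N genes in one direction after DE filtering
#'
#' Ranks the [filter_de()] survivors of the requested direction by adjusted p
#' ascending, ties by |log2fc| descending, remaining ties by gene identifier,
#' and returns the first `min(n, available)`. `rank_by = "lfc"` swaps the
#' first two keys.
#'
#' @param stats A `gene_stats` data frame.
#' @param direction `"up"` or `"down"`.
#' @param n Number of genes to keep.
#' @param rank_by `"padj"` (default) or `"lfc"`.
#' @param ... Thresholds passed to [filter_de()].
#' @return Character vector of gene identifiers, ranked.
#' @export
top_n_genes <- function(stats, direction = c("up", "down"), n = 500L,
                        rank_by = c("padj", "lfc"), ...) {
  direction <- match.arg(direction)
  rank_by <- match.arg(rank_by)
  sets <- filter_de(stats, ...)
  genes <- sets[[direction]]
  s <- stats[match(genes, stats$gene), , drop = FALSE]
  ord <- if (rank_by == "padj")
    order(s$padj, -abs(s$log2fc), s$gene)
  else
    order(-abs(s$log2fc), s$padj, s$gene)
  utils::head(genes[ord], n)
}
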