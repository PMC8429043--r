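#' Rank genes by signed significance for enrichment analysis
#'
#' Orders genes by the metric `-log10(p) * sign(log2fc)`, descending, with
#' ties broken by gene identifier. Zero p values are clipped to the smallest
#' positive representable double before taking the log; genes with missing p
#' are excluded and reported via the `excluded` attribute.
#'
#' @param stats A `gene_stats` data frame (`gene`, `pvalue`, `log2fc`).
#' @param p_column Which p value feeds the metric (`"pvalue"` by default;
#'   `"padj"` available).
#' @return Data frame of class `ranked_genes` with columns `gene`, `metric`,
#'   ordered by metric descending.
#' @export
rank_genes <- function(stats, p_column = c("pvalue", "padj")) {
  p_column <- match.arg(p_column)
  stopifnot(all(c("gene", "log2fc", p_column) %in% names(stats)))
  p <- stats[[p_column]]
  keep <- !is.na(p) & !is.na(stats$log2fc)
  excluded <- stats$gene[!keep]
  p <- pmax(p[keep], .Machine$double.xmin)
  metric <- -log10(p) * sign(stats$log2fc[keep])
  out <- data.frame(gene = stats$gene[keep], metric = metric,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$metric, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  class(out) <- c("ranked_genes", class(out))
  out
}

# ES from sorted hit positions only; O(|S|) given precomputed |metric|^p.
.es_from_hits <- function(absw, pos, N) {
  k <- length(pos)
  w <- absw[pos]
  W <- sum(w)
  cw <- if (W > 0) cumsum(w) / W else seq_len(k) / k
  d <- 1 / (N - k)
  after <- cw - (pos - seq_len(k)) * d
  before <- c(0, cw[-k]) - (pos - seq_len(k)) * d
  mx <- max(after)
  mn <- min(before, 0)
  if (mx >= abs(mn)) mx else mn
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list accumulating `|metric|^p / sum_hits |metric|^p` at
#' set members and `-1/(N - N_hits)` at non-members; the enrichment score is
#' the signed maximum deviation of this running sum from zero. The leading
#' edge is the set members at or before the extremum (after it for negative
#' scores).
#'
#' @param ranked A [rank_genes()] result (or data frame `gene`, `metric`,
#'   metric descending).
#' @param gene_set Character vector of gene identifiers.
#' @param p Weighting exponent (1 = classic weighted statistic).
#' @return List with `es`, `running` (length-N running sum), `hit_ranks`, and
#'   `leading_edge`.
#' @export
enrichment_score <- function(ranked, gene_set, p = 1) {
  stopifnot(all(c("gene", "metric") %in% names(ranked)))
  N <- nrow(ranked)
  hit <- ranked$gene %in% gene_set
  k <- sum(hit)
  if (k == 0L) stop("gene set has empty intersection with the ranked list",
                    call. = FALSE)
  if (k == N) stop("gene set contains every ranked gene; miss increment undefined",
                   call. = FALSE)
  absw <- abs(ranked$metric)^p
  W <- sum(absw[hit])
  incr <- rep(-1 / (N - k), N)
  incr[hit] <- if (W > 0) absw[hit] / W else 1 / k
  running <- cumsum(incr)
  i_max <- which.max(running); i_min <- which.min(pmin(running, 0))
  es <- if (running[i_max] >= abs(min(running[i_min], 0))) running[i_max]
        else running[i_min]
  hit_ranks <- which(hit)
  leading <- if (es >= 0) ranked$gene[hit_ranks[hit_ranks <= i_max]]
             else ranked$gene[hit_ranks[hit_ranks >= i_min]]
  list(es = es, running = running, hit_ranks = hit_ranks,
       leading_edge = leading)
}

#' Permutation-based enrichment testing with NES and FDR
#'
#' Builds a null for each gene set from random same-size gene-label sets
#' (gene permutation, appropriate for small per-group sample sizes where
#' phenotype permutation is degenerate). The normalized enrichment score
#' divides the observed score by the mean |null score| of matching sign;
#' the nominal p is `(1 + #same-sign nulls at least as extreme) /
#' (1 + #same-sign nulls)`; the FDR compares each NES against the pooled
#' sign-matched null NES distribution across all sets, GSEA-style.
#'
#' @param ranked A [rank_genes()] result.
#' @param gene_sets Named list of gene identifier vectors.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed; results are reproducible for a fixed seed.
#' @param weight Weighting exponent passed to the score.
#' @return Data frame of class `enrichment_results`: `set`, `size`, `es`,
#'   `nes`, `p_nominal`, `fdr`, `leading_edge` (comma-separated), `n_perm`,
#'   `degenerate_null`.
#' @export
permutation_test <- function(ranked, gene_sets, n_perm = 1000L, seed = 1L,
                             weight = 1) {
  stopifnot(all(c("gene", "metric") %in% names(ranked)))
  if (n_perm < 100L) stop("`n_perm` must be >= 100", call. = FALSE)
  if (is.null(names(gene_sets)))
    names(gene_sets) <- sprintf("set%03d", seq_along(gene_sets))
  N <- nrow(ranked)
  absw <- abs(ranked$metric)^weight

  with_seed(seed, {
    rows <- vector("list", length(gene_sets))
    null_nes_pool <- numeric(0)
    for (i in seq_along(gene_sets)) {
      obs <- enrichment_score(ranked, gene_sets[[i]], p = weight)
      k <- length(obs$hit_ranks)
      nulls <- vapply(seq_len(n_perm), function(b)
        .es_from_hits(absw, sort(sample.int(N, k)), N), numeric(1))
      pos <- nulls[nulls > 0]; neg <- nulls[nulls < 0]
      same <- if (obs$es >= 0) pos else neg
      degenerate <- length(same) == 0L
      p_nom <- if (degenerate) 1 / (n_perm + 1)
               else (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
      nes <- if (degenerate) NA_real_
             else obs$es / mean(abs(same))
      if (length(pos)) null_nes_pool <- c(null_nes_pool, pos / mean(pos))
      if (length(neg)) null_nes_pool <- c(null_nes_pool, neg / mean(abs(neg)))
      rows[[i]] <- data.frame(
        set = names(gene_sets)[i], size = k, es = obs$es, nes = nes,
        p_nominal = p_nom, fdr = NA_real_,
        leading_edge = paste(obs$leading_edge, collapse = ","),
        n_perm = n_perm, degenerate_null = degenerate,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    # sign-matched pooled-null FDR
    for (i in seq_len(nrow(out))) {
      nes <- out$nes[i]
      if (is.na(nes)) { out$fdr[i] <- NA_real_; next }
      if (nes >= 0) {
        pool <- null_nes_pool[null_nes_pool >= 0]
        obs_side <- out$nes[!is.na(out$nes) & out$nes >= 0]
      } else {
        pool <- abs(null_nes_pool[null_nes_pool < 0])
        obs_side <- abs(out$nes[!is.na(out$nes) & out$nes < 0])
        nes <- abs(nes)
      }
      num <- if (length(pool)) mean(pool >= nes) else 0
      den <- mean(obs_side >= nes)
      out$fdr[i] <- min(1, num / den)
    }
    attr(out, "seed") <- as.integer(seed)
    class(out) <- c("enrichment_results", class(out))
    out
  })
}
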