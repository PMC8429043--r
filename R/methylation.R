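#' Filter contaminant reads by runs of methylated GC calls
#'
#' Cell-free DNA that enters the library after methylase treatment is
#' GC-methylated along its whole length, so genuine nuclear reads are
#' separated from contaminants by looking for long runs of methylated
#' GC-context calls. A read is dropped when some window of exactly
#' `window_sites` consecutive GC-context calls (GCH and GCG, in read order,
#' ambiguous calls excluded from both the count and window membership)
#' contains at least `ceiling(min_frac * window_sites)` methylated calls.
#' Any longer qualifying stretch necessarily contains a qualifying window,
#' so "at least `window_sites`" is implied. Reads with fewer than
#' `window_sites` GC calls are always kept.
#'
#' @param calls Call table (data frame with `read_name`, `start`,
#'   `sequence_context`, and either a `call` column or `log_lik_ratio`).
#' @param window_sites Window length in GC sites (default 80).
#' @param min_frac Methylated fraction triggering removal (default 0.75, i.e.
#'   60 of 80).
#' @param threshold LLR call threshold used if `call` is absent.
#'
#' @return A list with `kept` and `dropped` (the call table split by read)
#'   and `dropped_reads` (character vector of read names).
#' @export
filter_contaminant_reads <- function(calls, window_sites = 80L, min_frac = 0.75,
                                     threshold = 2) {
  stopifnot(is.data.frame(calls),
            all(c("read_name", "start", "sequence_context") %in% names(calls)))
  if (!"call" %in% names(calls))
    calls$call <- call_methylation(calls$log_lik_ratio, threshold)
  need <- as.integer(ceiling(min_frac * window_sites))

  gc <- calls[calls$sequence_context %in% c("GCH", "GCG") &
                calls$call %in% c("methylated", "unmethylated"), , drop = FALSE]
  gc <- gc[order(gc$read_name, gc$start), , drop = FALSE]
  meth_by_read <- split(gc$call == "methylated", gc$read_name)
  is_contam <- vapply(meth_by_read, function(m) {
    n <- length(m)
    if (n < window_sites) return(FALSE)
    cs <- cumsum(m)
    win <- cs[window_sites:n] - c(0L, cs[seq_len(n - window_sites)])
    any(win >= need)
  }, logical(1))
  dropped_reads <- names(is_contam)[is_contam]
  keep <- !(calls$read_name %in% dropped_reads)
  list(kept = calls[keep, , drop = FALSE],
       dropped = calls[!keep, , drop = FALSE],
       dropped_reads = dropped_reads)
}

#' Aggregate per-read calls into per-site methylation proportions
#'
#' For every site covered by at least `min_coverage` unambiguous calls,
#' reports `proportion = n_meth / (n_meth + n_unmeth)`. Ambiguous calls
#' contribute to neither count nor coverage. Contaminant reads should be
#' removed first (the filter only changes read membership, never the
#' arithmetic of the remaining calls).
#'
#' @param calls Call table (data frame with `chrom`, `strand`, `start`,
#'   `sequence_context`, and `call` or `log_lik_ratio`).
#' @param min_coverage Minimum unambiguous calls per retained site.
#' @param threshold LLR call threshold used if `call` is absent.
#' @return Data frame of class `site_summary`: `chrom`, `pos`, `strand`,
#'   `context`, `n_meth`, `n_unmeth`, `proportion`, ordered by chrom,
#'   context, strand, position.
#' @export
aggregate_sites <- function(calls, min_coverage = 4L, threshold = 2) {
  stopifnot(is.data.frame(calls),
            all(c("chrom", "strand", "start", "sequence_context") %in% names(calls)))
  if (!"call" %in% names(calls))
    calls$call <- call_methylation(calls$log_lik_ratio, threshold)
  x <- calls[calls$call %in% c("methylated", "unmethylated"), , drop = FALSE]
  if (nrow(x) == 0L) {
    out <- data.frame(chrom = character(), pos = integer(), strand = character(),
                      context = character(), n_meth = integer(),
                      n_unmeth = integer(), proportion = numeric(),
                      stringsAsFactors = FALSE)
    class(out) <- c("site_summary", class(out))
    return(out)
  }
  key <- paste(x$chrom, x$start, x$strand, x$sequence_context, sep = "\r")
  n_meth <- tapply(x$call == "methylated", key, sum)
  n_tot <- tapply(key, key, length)
  parts <- do.call(rbind, strsplit(names(n_meth), "\r", fixed = TRUE))
  out <- data.frame(chrom = parts[, 1], pos = as.integer(parts[, 2]),
                    strand = parts[, 3], context = parts[, 4],
                    n_meth = as.integer(n_meth),
                    n_unmeth = as.integer(n_tot - n_meth),
                    stringsAsFactors = FALSE)
  out <- out[out$n_meth + out$n_unmeth >= min_coverage, , drop = FALSE]
  out$proportion <- out$n_meth / (out$n_meth + out$n_unmeth)
  out <- out[order(out$chrom, out$context, out$strand, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("site_summary", class(out))
  out
}

#' Triangular-kernel mean smoothing of an ordered methylation track
#'
#' Smooths per-site methylation levels with a triangular kernel `width` sites
#' wide (weights 1,2,3,2,1 for width 5). At the track edges the kernel is
#' renormalized over the in-range sites, so a constant track is returned
#' unchanged and the output never leaves `[min(x), max(x)]`.
#'
#' @param x Numeric vector of per-site levels, ordered by genomic position
#'   within one chrom/strand/context track.
#' @param width Odd kernel width in sites (>= 1).
#' @return Numeric vector of smoothed levels, same length as `x`.
#' @export
smooth_levels <- function(x, width = 5L) {
  width <- as.integer(width)
  if (is.na(width) || width < 1L || width %% 2L == 0L)
    stop("`width` must be a positive odd integer", call. = FALSE)
  n <- length(x)
  if (n == 0L) return(numeric(0))
  h <- (width - 1L) %/% 2L
  w <- h + 1L - abs(seq.int(-h, h))
  vapply(seq_len(n), function(i) {
    j <- seq.int(max(1L, i - h), min(n, i + h))
    wj <- w[j - i + h + 1L]
    sum(wj * x[j]) / sum(wj)
  }, numeric(1))
}

#' Add smoothed levels to a site summary, per track
#'
#' Applies [smooth_levels()] independently within each (chrom, strand,
#' context) track of a [aggregate_sites()] summary, in position order.
#'
#' @param summaries A `site_summary` data frame.
#' @param width Odd kernel width in sites.
#' @return The input with a `smoothed_level` column appended.
#' @export
smooth_summaries <- function(summaries, width = 5L) {
  stopifnot(is.data.frame(summaries),
            all(c("chrom", "pos", "strand", "context", "proportion") %in%
                  names(summaries)))
  summaries <- summaries[order(summaries$chrom, summaries$context,
                               summaries$strand, summaries$pos), , drop = FALSE]
  key <- paste(summaries$chrom, summaries$strand, summaries$context, sep = "\r")
  summaries$smoothed_level <- stats::ave(summaries$proportion, key,
                                         FUN = function(v) smooth_levels(v, width))
  rownames(summaries) <- NULL
  summaries
}

#' Mean methylation levels in promoter windows around TSSs
#'
#' For every gene, averages the per-site GCH level (chromatin accessibility)
#' and HCG level (endogenous CpG methylation) over sites within the inclusive
#' window `|pos - tss| <= flank`. GCG sites are excluded from both tracks
#' (ambiguous between enzymatic and endogenous methylation). Windows with no
#' site of a context report `NA` for that level, never 0.
#'
#' @param summaries A `site_summary` data frame (optionally smoothed).
#' @param tss Data frame with columns `gene`, `tss` (0-based position) and
#'   optionally `strand`.
#' @param flank Half-window in bp (inclusive; default 1500).
#' @param value Column of `summaries` to average (`"proportion"` or
#'   `"smoothed_level"`).
#' @return Data frame: `gene`, `tss`, `mean_gch_level`, `mean_hcg_level`,
#'   `n_gch_sites`, `n_hcg_sites`.
#' @export
promoter_profile <- function(summaries, tss, flank = 1500L, value = "proportion") {
  stopifnot(is.data.frame(summaries), is.data.frame(tss),
            all(c("gene", "tss") %in% names(tss)),
            value %in% names(summaries))
  res <- lapply(seq_len(nrow(tss)), function(i) {
    win <- summaries[abs(summaries$pos - tss$tss[i]) <= flank, , drop = FALSE]
    gch <- win[[value]][win$context == "GCH"]
    hcg <- win[[value]][win$context == "HCG"]
    data.frame(gene = tss$gene[i], tss = tss$tss[i],
               mean_gch_level = if (length(gch)) mean(gch) else NA_real_,
               mean_hcg_level = if (length(hcg)) mean(hcg) else NA_real_,
               n_gch_sites = length(gch), n_hcg_sites = length(hcg),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
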