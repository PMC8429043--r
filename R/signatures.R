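#' Gene signature container
#'
#' @param name Signature name.
#' @param up,down Character vectors of gene identifiers; must be disjoint.
#' @param provenance Optional list recording thresholds / sources.
#' @return Object of class `gene_signature`.
#' @export
gene_signature <- function(name, up, down, provenance = list()) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  conflict <- intersect(up, down)
  if (length(conflict))
    stop("genes in both up and down sets: ", paste(conflict, collapse = ", "),
         call. = FALSE)
  structure(list(name = name, up = up, down = down, provenance = provenance),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("Gene signature '", x$name, "': ", length(x$up), " up, ",
      length(x$down), " down\n", sep = "")
  invisible(x)
}

#' Common hepatocyte signature from two primary-hepatocyte DE tables
#'
#' Takes the top-`n` up- and downregulated genes from each sample's DE table
#' (both against the same reference condition) and keeps the genes present in
#' both samples, per direction. Genes that qualify in opposite directions in
#' the two samples are excluded and reported in the `conflicts` element of
#' the provenance.
#'
#' @param stats1,stats2 `gene_stats` tables for the two samples.
#' @param n Per-direction top-N cut before intersecting.
#' @param ... Thresholds passed to [filter_de()] / [top_n_genes()].
#' @return A [gene_signature()].
#' @export
build_hepatocyte_signature <- function(stats1, stats2, n = 500L, ...) {
  up1 <- top_n_genes(stats1, "up", n, ...); up2 <- top_n_genes(stats2, "up", n, ...)
  dn1 <- top_n_genes(stats1, "down", n, ...); dn2 <- top_n_genes(stats2, "down", n, ...)
  up <- intersect(up1, up2)
  down <- intersect(dn1, dn2)
  conflicts <- union(intersect(up1, dn2), intersect(dn1, up2))
  up <- setdiff(up, conflicts); down <- setdiff(down, conflicts)
  gene_signature("hepatocyte", up, down,
                 provenance = list(n = n, conflicts = conflicts))
}

#' HCC signature: capped up-set, uncapped down-set
#'
#' The up signature is the top-`n` significantly upregulated genes; the down
#' signature keeps all significantly downregulated genes with no top-N cap
#' (the asymmetry reflects how few genes pass the down filter in
#' tumor-vs-normal comparisons).
#'
#' @param stats A `gene_stats` table.
#' @param n Cap for the up set.
#' @param ... Thresholds passed to [filter_de()].
#' @return A [gene_signature()] named "HCC".
#' @export
build_hcc_signature <- function(stats, n = 500L, ...) {
  sets <- filter_de(stats, ...)
  up <- top_n_genes(stats, "up", n, ...)
  if (!length(up) && !length(sets$down))
    warning("no genes pass the DE filter; HCC signature is empty", call. = FALSE)
  gene_signature("HCC", up, sets$down, provenance = list(n_up_cap = n))
}

#' Consensus signature across studies (at-least-k rule)
#'
#' A gene enters the consensus up set when it appears in the up sets of at
#' least `k` studies (down analogous). Genes qualifying in both directions
#' are excluded from both and reported.
#'
#' @param study_sets List of per-study lists with elements `up` and `down`.
#' @param k Minimum number of supporting studies.
#' @param name Signature name.
#' @return A [gene_signature()]; provenance reports `conflicts`.
#' @export
consensus_signature <- function(study_sets, k = 3L, name = "consensus") {
  if (k > length(study_sets))
    stop("`k` exceeds the number of studies (", length(study_sets), ")",
         call. = FALSE)
  count_in <- function(dir) {
    tab <- table(unlist(lapply(study_sets, function(s) unique(s[[dir]]))))
    names(tab)[tab >= k]
  }
  up <- count_in("up"); down <- count_in("down")
  conflicts <- intersect(up, down)
  gene_signature(name, setdiff(up, conflicts), setdiff(down, conflicts),
                 provenance = list(k = k, n_studies = length(study_sets),
                                   conflicts = conflicts))
}
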