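#' Generate a synthetic genome with annotated promoters
#'
#' Draws an i.i.d. sequence with the requested GC content and places
#' `n_promoters` non-overlapping promoter windows, each with a TSS at its
#' center and a random strand. The genome stands in for a reference assembly
#' when exercising the methylation and insertion pipelines on data with known
#' truth.
#'
#' @param length Genome length in bp (>= 1000).
#' @param gc_fraction Target GC content, strictly between 0 and 1.
#' @param n_promoters Number of promoter windows to place.
#' @param seed Integer seed; the function is deterministic given its inputs.
#' @param promoter_width Width of each promoter window in bp.
#' @param name Chromosome name.
#'
#' @return An object of class `synthetic_genome`: a list with `name`,
#'   `sequence`, `tss` (data frame gene/tss/strand, 0-based TSS), `promoters`
#'   (data frame start/end, 0-based half-open), and the generating parameters.
#' @export
make_genome <- function(length, gc_fraction, n_promoters = 0L, seed = 1L,
                        promoter_width = 600L, name = "chrS") {
  stopifnot_scalar_number(length, "length")
  stopifnot_scalar_number(gc_fraction, "gc_fraction")
  length <- as.integer(length)
  if (length < 1000L) stop("`length` must be >= 1000", call. = FALSE)
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stop("`gc_fraction` must be strictly between 0 and 1 (degenerate alphabet otherwise)",
         call. = FALSE)
  n_promoters <- as.integer(n_promoters)
  promoter_width <- as.integer(promoter_width)
  if (n_promoters > 0 && n_promoters * 2L * promoter_width > length)
    stop("`length` too small to place ", n_promoters,
         " non-overlapping promoters of width ", promoter_width, call. = FALSE)

  with_seed(seed, {
    p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
           (1 - gc_fraction) / 2)
    sequence <- paste(sample(DNA_BASES, length, replace = TRUE, prob = p),
                      collapse = "")
    promoters <- data.frame(start = integer(), end = integer())
    tss <- data.frame(gene = character(), tss = integer(), strand = character(),
                      stringsAsFactors = FALSE)
    if (n_promoters > 0L) {
      starts <- integer(0)
      tries <- 0L
      while (length(starts) < n_promoters) {
        tries <- tries + 1L
        if (tries > 1000L * n_promoters)
          stop("failed to place ", n_promoters, " non-overlapping promoters",
               call. = FALSE)
        s <- sample.int(length - promoter_width, 1L) - 1L
        if (!any(abs(s - starts) < promoter_width)) starts <- c(starts, s)
      }
      starts <- sort(starts)
      promoters <- data.frame(start = starts, end = starts + promoter_width)
      tss <- data.frame(
        gene = sprintf("GENE%03d", seq_len(n_promoters)),
        tss = starts + promoter_width %/% 2L,
        strand = sample(c("+", "-"), n_promoters, replace = TRUE),
        stringsAsFactors = FALSE
      )
    }
    structure(list(name = name, sequence = sequence, tss = tss,
                   promoters = promoters, gc_fraction = gc_fraction,
                   promoter_width = promoter_width, seed = as.integer(seed)),
              class = "synthetic_genome")
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("Synthetic genome ", x$name, ": ", nchar(x$sequence), " bp, ",
      nrow(x$tss), " promoters (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Simulate a true methylome over a synthetic genome
#'
#' Assigns a binary true methylation state to every cytosine site of the
#' genome. GCH sites (accessibility readout) are methylated with
#' `promoter_open_prob` inside promoter windows and `background_open_prob`
#' elsewhere, emulating open promoter chromatin marked by a GpC methylase.
#' HCG sites (endogenous CpG readout) are methylated with `cpg_meth_prob`
#' everywhere. GCG sites are generated (state drawn with `cpg_meth_prob`) but
#' flagged ambiguous; HCH sites carry no methylation signal and are always
#' unmethylated.
#'
#' @param genome A `synthetic_genome`.
#' @param promoter_open_prob,background_open_prob,cpg_meth_prob Probabilities
#'   in \[0, 1\].
#' @param seed Integer seed.
#'
#' @return An object of class `true_methylome`: a data frame with columns
#'   `chrom`, `pos`, `strand`, `context`, `true_state` ("methylated" /
#'   "unmethylated"), `ambiguous`, `in_promoter`; attributes carry the genome
#'   name, its length, the promoter table and the seed.
#' @export
simulate_methylome <- function(genome, promoter_open_prob = 0.9,
                               background_open_prob = 0.1,
                               cpg_meth_prob = 0.7, seed = 1L) {
  stopifnot(inherits(genome, "synthetic_genome"))
  check_fraction(promoter_open_prob, "promoter_open_prob")
  check_fraction(background_open_prob, "background_open_prob")
  check_fraction(cpg_meth_prob, "cpg_meth_prob")

  sites <- catalog_sites(genome$sequence, genome$name)
  if (!any(sites$context == "GCH"))
    stop("genome contains no GCH sites; cannot simulate an accessibility readout",
         call. = FALSE)

  with_seed(seed, {
    in_prom <- rep(FALSE, nrow(sites))
    if (nrow(genome$promoters))
      for (i in seq_len(nrow(genome$promoters)))
        in_prom <- in_prom | (sites$pos >= genome$promoters$start[i] &
                              sites$pos < genome$promoters$end[i])
    p <- numeric(nrow(sites))
    p[sites$context == "GCH"] <- ifelse(in_prom[sites$context == "GCH"],
                                        promoter_open_prob, background_open_prob)
    p[sites$context == "HCG"] <- cpg_meth_prob
    p[sites$context == "GCG"] <- cpg_meth_prob
    p[sites$context == "HCH"] <- 0
    state <- ifelse(stats::runif(nrow(sites)) < p, "methylated", "unmethylated")
    out <- cbind(sites,
                 data.frame(true_state = state,
                            ambiguous = sites$context == "GCG",
                            in_promoter = in_prom,
                            stringsAsFactors = FALSE))
    attr(out, "genome_name") <- genome$name
    attr(out, "genome_length") <- nchar(genome$sequence)
    attr(out, "promoters") <- genome$promoters
    attr(out, "tss") <- genome$tss
    attr(out, "seed") <- as.integer(seed)
    class(out) <- c("true_methylome", class(out))
    out
  })
}
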