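#' Simulate a per-read methylation call table from a true methylome
#'
#' Emits nanopore-caller-like per-read, per-site log-likelihood ratios. Reads
#' are placed uniformly on one strand each and cover every cataloged site of
#' that strand inside a contiguous interval. At each covered site the LLR is
#' drawn from Normal(+`llr_mean_effect`, `llr_sd`) when the true state is
#' methylated and Normal(-`llr_mean_effect`, `llr_sd`) otherwise. A
#' `contamination_fraction` of reads are synthesized as cell-free-DNA-like
#' contaminants: each of their GC-context sites (GCH/GCG) is set methylated
#' with probability 0.9 before the LLR is drawn, producing long stretches of
#' methylated GC calls for the contaminant filter to catch.
#'
#' @param methylome A `true_methylome` from [simulate_methylome()].
#' @param cfg A [sim_config()]; uses `coverage`, `llr_mean_effect`, `llr_sd`,
#'   `contamination_fraction`, `read_length`, `seed`.
#'
#' @return A list with `calls` (data frame: `chrom`, `strand`, `start`, `end`,
#'   `read_name`, `log_lik_ratio`, `sequence_context`), `read_truth` (data
#'   frame: `read_name`, `start`, `end`, `strand`, `contaminant`) and
#'   `site_truth` (the input methylome).
#' @export
simulate_call_table <- function(methylome, cfg = sim_config()) {
  stopifnot(inherits(methylome, "true_methylome"), inherits(cfg, "sim_config"))
  L <- attr(methylome, "genome_length")
  chrom <- attr(methylome, "genome_name")
  rl <- min(cfg$read_length, L)
  n_reads_per_strand <- max(1L, ceiling(cfg$coverage * L / rl))

  with_seed(cfg$seed, {
    n_reads <- 2L * n_reads_per_strand
    read_strand <- rep(c("+", "-"), each = n_reads_per_strand)
    read_start <- sample.int(max(1L, L - rl + 1L), n_reads, replace = TRUE) - 1L
    read_end <- read_start + rl
    contaminant <- stats::runif(n_reads) < cfg$contamination_fraction
    read_name <- sprintf("read_%05d", seq_len(n_reads))

    meth <- as.data.frame(methylome)
    pieces <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      sel <- meth$strand == read_strand[i] & meth$pos >= read_start[i] &
        meth$pos < read_end[i]
      if (!any(sel)) next
      s <- meth[sel, , drop = FALSE]
      state <- s$true_state == "methylated"
      if (contaminant[i]) {
        gc <- s$context %in% c("GCH", "GCG")
        state[gc] <- stats::runif(sum(gc)) < 0.9
      }
      llr <- stats::rnorm(nrow(s),
                          mean = ifelse(state, cfg$llr_mean_effect, -cfg$llr_mean_effect),
                          sd = cfg$llr_sd)
      pieces[[i]] <- data.frame(
        chrom = chrom, strand = s$strand, start = s$pos, end = s$pos + 1L,
        read_name = read_name[i], log_lik_ratio = llr,
        sequence_context = s$context, stringsAsFactors = FALSE
      )
    }
    calls <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
    rownames(calls) <- NULL
    list(
      calls = calls,
      read_truth = data.frame(read_name = read_name, start = read_start,
                              end = read_end, strand = read_strand,
                              contaminant = contaminant, stringsAsFactors = FALSE),
      site_truth = methylome
    )
  })
}

#' Simulate labeled signal events for emission-model training
#'
#' Produces (k-mer, signal, label) records like those obtained from a control
#' pair of sequencing runs: a PCR-amplified (fully unmethylated) run and a
#' GpC-methylase-treated PCR product (fully methylated at GC). Each k-mer has
#' its own baseline current level; methylation shifts the level by
#' `mean_shift` signal units.
#'
#' @param kmers Character vector of k-mers (all the same length).
#' @param n_per_label Events per (k-mer, label).
#' @param mean_shift Signal shift between methylated and unmethylated states.
#' @param sd Event noise standard deviation.
#' @param seed Integer seed.
#'
#' @return A list with `events` (data frame `kmer`, `signal`, `label`) and
#'   `truth` (data frame `kmer`, `mean_unmeth`, `mean_meth`, `sd`).
#' @export
simulate_emission_events <- function(kmers, n_per_label = 1000L,
                                     mean_shift = 4, sd = 2, seed = 1L) {
  stopifnot(length(kmers) > 0, all(nchar(kmers) == nchar(kmers[1])))
  with_seed(seed, {
    base <- stats::runif(length(kmers), 80, 120)
    truth <- data.frame(kmer = kmers, mean_unmeth = base,
                        mean_meth = base + mean_shift, sd = sd,
                        stringsAsFactors = FALSE)
    ev <- do.call(rbind, lapply(seq_along(kmers), function(i) {
      data.frame(
        kmer = kmers[i],
        signal = c(stats::rnorm(n_per_label, base[i], sd),
                   stats::rnorm(n_per_label, base[i] + mean_shift, sd)),
        label = rep(c("unmeth", "meth"), each = n_per_label),
        stringsAsFactors = FALSE
      )
    }))
    rownames(ev) <- NULL
    list(events = ev, truth = truth)
  })
}
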