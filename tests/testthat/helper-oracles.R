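# Independent oracles used across the suite. Each reimplements the checked
# quantity by the most direct route available (enumeration, closed form,
# naive loops), sharing no code with the package internals.

# direct renormalized triangular convolution
oracle_smooth <- function(x, width = 5L) {
  h <- (width - 1L) %/% 2L
  w <- h + 1L - abs(-h:h)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0; den <- 0
    for (j in -h:h) {
      if (i + j >= 1 && i + j <= n) {
        num <- num + w[j + h + 1L] * x[i + j]
        den <- den + w[j + h + 1L]
      }
    }
    out[i] <- num / den
  }
  out
}

# naive O(N * |S|) weighted running-sum enrichment score
oracle_es <- function(genes, metrics, gene_set, p = 1) {
  N <- length(genes)
  hit <- genes %in% gene_set
  k <- sum(hit)
  W <- sum(abs(metrics[hit])^p)
  running <- numeric(N)
  acc <- 0
  for (i in seq_len(N)) {
    acc <- acc + if (hit[i]) abs(metrics[i])^p / W else -1 / (N - k)
    running[i] <- acc
  }
  pos <- max(running)
  neg <- min(c(running, 0))
  if (pos >= abs(neg)) pos else neg
}

# brute-force Benjamini-Hochberg
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# context lookup over the 16 (prev, next) flank pairs
oracle_context <- function(prev, nxt) {
  if (prev == "G" && nxt == "G") "GCG"
  else if (prev == "G") "GCH"
  else if (nxt == "G") "HCG"
  else "HCH"
}

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# minimal call-table row builder
call_rows <- function(read, contexts, calls, pos = seq_along(contexts),
                      chrom = "chr1", strand = "+") {
  llr <- ifelse(calls == "methylated", 5, ifelse(calls == "unmethylated", -5, 0))
  data.frame(chrom = chrom, strand = strand, start = pos, end = pos + 1L,
             read_name = read, log_lik_ratio = llr,
             sequence_context = contexts, call = calls,
             stringsAsFactors = FALSE)
}

# a read carrying `n` GC-context calls of which `n_meth` are methylated,
# methylated calls placed first
gc_read <- function(read, n, n_meth, context = "GCH") {
  call_rows(read, rep(context, n),
            c(rep("methylated", n_meth), rep("unmethylated", n - n_meth)))
}
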