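#' Classify the trinucleotide context of a cytosine
#'
#' In methyltransferase-footprinting (NOMe-type) experiments the two flanking
#' bases of a cytosine determine which signal it reports. A cytosine preceded
#' by G and not followed by G (`GCH`, H = A/C/T) carries the exogenous GpC
#' methylase mark and reports chromatin accessibility; a cytosine followed by
#' G and not preceded by G (`HCG`) reports endogenous CpG methylation. `GCG`
#' sites satisfy both patterns and are ambiguous between the two sources;
#' `HCH` sites carry neither signal. The context is read 5'->3' on the strand
#' that carries the cytosine, so minus-strand sites are classified on the
#' reverse complement.
#'
#' @param sequence Character scalar, the reference sequence (A/C/G/T).
#' @param pos Integer vector of 0-based positions of the cytosine(s). For
#'   minus-strand sites this is still the position in `sequence` coordinates
#'   (where the plus strand shows G).
#' @param strand Character vector, `"+"` or `"-"`, recycled against `pos`.
#'
#' @return Character vector of contexts (`"GCH"`, `"HCG"`, `"GCG"`, `"HCH"`),
#'   with `NA` for positions at the sequence edge where a flanking base is
#'   missing (no-context sites, excluded downstream).
#'
#' @examples
#' classify_context("AAGCAAA", 3, "+")  # GCH
#' classify_context("AAGCGAA", 3, "+")  # GCG
#' classify_context("AAGCAAA", 2, "-")  # GCH on the minus strand
#' @export
classify_context <- function(sequence, pos, strand = "+") {
  chars <- seq_chars(sequence)
  n <- length(chars)
  m <- max(length(pos), length(strand))
  pos <- rep_len(as.integer(pos), m)
  strand <- rep_len(strand, m)
  if (any(pos < 0L | pos >= n))
    stop("`pos` out of range for sequence of length ", n, call. = FALSE)
  if (!all(strand %in% c("+", "-")))
    stop("`strand` must be \"+\" or \"-\"", call. = FALSE)

  base <- chars[pos + 1L]
  plus <- strand == "+"
  bad <- (plus & base != "C") | (!plus & base != "G")
  if (any(bad))
    stop("base at position ", pos[which(bad)[1]], " (0-based) is not a cytosine on strand ",
         strand[which(bad)[1]], call. = FALSE)

  out <- rep(NA_character_, m)
  edge <- pos == 0L | pos == n - 1L
  idx <- which(!edge)
  if (length(idx)) {
    p <- pos[idx]
    prev <- ifelse(plus[idx], chars[p], comp_base(chars[p + 2L]))
    nxt  <- ifelse(plus[idx], chars[p + 2L], comp_base(chars[p]))
    out[idx] <- ifelse(prev == "G" & nxt == "G", "GCG",
                ifelse(prev == "G", "GCH",
                ifelse(nxt == "G", "HCG", "HCH")))
  }
  out
}

#' Catalog all cytosine sites of a sequence on both strands
#'
#' Enumerates every cytosine on the plus strand and every guanine position
#' (a cytosine on the minus strand) and classifies its context with
#' [classify_context()]. Edge positions lacking a flanking base are dropped.
#'
#' @param sequence Character scalar over A/C/G/T.
#' @param chrom Chromosome name attached to the output.
#' @return A data frame with columns `chrom`, `pos` (0-based), `strand`,
#'   `context`, ordered by position then strand.
#' @export
catalog_sites <- function(sequence, chrom = "chrS") {
  chars <- seq_chars(sequence)
  cpos <- which(chars == "C") - 1L
  gpos <- which(chars == "G") - 1L
  df <- rbind(
    data.frame(pos = cpos, strand = rep("+", length(cpos)), stringsAsFactors = FALSE),
    data.frame(pos = gpos, strand = rep("-", length(gpos)), stringsAsFactors = FALSE)
  )
  if (nrow(df) == 0L)
    return(data.frame(chrom = character(), pos = integer(), strand = character(),
                      context = character(), stringsAsFactors = FALSE))
  df$context <- classify_context(sequence, df$pos, df$strand)
  df <- df[!is.na(df$context), , drop = FALSE]
  df <- df[order(df$pos, df$strand), , drop = FALSE]
  data.frame(chrom = chrom, pos = df$pos, strand = df$strand,
             context = df$context, row.names = NULL, stringsAsFactors = FALSE)
}
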