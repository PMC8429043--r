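#' Describe a lentiviral construct
#'
#' A construct couples a vector backbone with a cloned insert (the transgene
#' coding sequence). When the insert is the cDNA of a host gene, its
#' `native_locus` records where that gene lives on the host genome: long reads
#' whose host anchor falls inside that interval are not evidence of a new
#' integration.
#'
#' @param name Construct name (e.g. "HNF4A", "Cas9").
#' @param backbone_sequence,insert_sequence DNA strings over ACGT.
#' @param native_locus Optional list/vector `c(start, end)` (0-based
#'   half-open) on the host, or `NULL` for non-host inserts.
#' @return An object of class `construct`.
#' @export
construct <- function(name, backbone_sequence, insert_sequence, native_locus = NULL) {
  stopifnot(nzchar(name), nzchar(backbone_sequence), nzchar(insert_sequence))
  if (!is.null(native_locus)) {
    native_locus <- as.integer(native_locus[1:2])
    stopifnot(native_locus[2] > native_locus[1])
  }
  structure(list(name = name, backbone_sequence = toupper(backbone_sequence),
                 insert_sequence = toupper(insert_sequence),
                 native_locus = native_locus),
            class = "construct")
}

#' Build synthetic constructs whose inserts are host-gene cDNAs
#'
#' Picks `n` disjoint intervals of the host genome as native loci, uses their
#' sequence as the inserts, and attaches a shared random vector backbone —
#' mirroring lineage-factor cDNA constructs cloned into one lentiviral vector.
#'
#' @param host A `synthetic_genome`.
#' @param n Number of constructs.
#' @param insert_length,backbone_length Lengths in bp.
#' @param seed Integer seed.
#' @return List of `construct` objects.
#' @export
simulate_constructs <- function(host, n = 2L, insert_length = 1200L,
                                backbone_length = 2000L, seed = 1L) {
  stopifnot(inherits(host, "synthetic_genome"))
  L <- nchar(host$sequence)
  if (n * insert_length * 3L > L)
    stop("host too short for ", n, " constructs of insert length ", insert_length,
         call. = FALSE)
  with_seed(seed, {
    backbone <- paste(sample(DNA_BASES, backbone_length, replace = TRUE),
                      collapse = "")
    # disjoint native loci, spaced across the host
    slot <- L %/% n
    lapply(seq_len(n), function(i) {
      start <- (i - 1L) * slot +
        sample.int(slot - insert_length, 1L) - 1L
      construct(sprintf("INS%02d", i), backbone,
                substr(host$sequence, start + 1L, start + insert_length),
                native_locus = c(start, start + insert_length))
    })
  })
}

#' Simulate long reads around planted transgene integrations
#'
#' Plants `n_loci` integration sites on the host (outside every construct's
#' native locus) and emits, per locus, `support_per_locus` chimeric reads of
#' the form host-left-flank + backbone fragment + insert fragment +
#' host-right-flank, with jittered flank lengths. Native-locus reads are
#' plain host reads spanning an insert gene's native locus (they contain the
#' insert sequence but no backbone); background reads are plain host
#' sequence away from any planted locus.
#'
#' @param host A `synthetic_genome`.
#' @param constructs List of [construct()] objects.
#' @param n_loci Number of integration loci to plant.
#' @param support_per_locus Chimeric reads per locus (>= 1).
#' @param n_native_reads,n_background_reads Counts of the two read classes.
#' @param seed Integer seed.
#' @param flank_len Mean host flank length per side, bp.
#'
#' @return A list with `reads` (named character vector of sequences),
#'   `truth_loci` (data frame `locus_id`, `chrom`, `position`, `construct`,
#'   `n_support`) and `truth_reads` (data frame `read_name`, `class`,
#'   `locus_id`).
#' @export
simulate_insertion_reads <- function(host, constructs, n_loci = 3L,
                                     support_per_locus = 4L,
                                     n_native_reads = 2L,
                                     n_background_reads = 10L, seed = 1L,
                                     flank_len = 400L) {
  stopifnot(inherits(host, "synthetic_genome"))
  if (support_per_locus < 1L)
    stop("`support_per_locus` must be >= 1", call. = FALSE)
  lapply(constructs, function(x) stopifnot(inherits(x, "construct")))
  L <- nchar(host$sequence)
  native <- do.call(rbind, lapply(constructs, function(cn)
    if (is.null(cn$native_locus)) NULL
    else data.frame(start = cn$native_locus[1], end = cn$native_locus[2])))
  margin <- flank_len + 100L
  if (n_loci > 0L && L < n_loci * 4L * margin)
    stop("host too short to place ", n_loci, " non-overlapping integration sites",
         call. = FALSE)

  with_seed(seed, {
    away_from_native <- function(p) {
      is.null(native) || !any(p >= native$start - margin & p < native$end + margin)
    }
    positions <- integer(0)
    tries <- 0L
    while (length(positions) < n_loci) {
      tries <- tries + 1L
      if (tries > 10000L) stop("failed to place integration loci", call. = FALSE)
      p <- sample.int(L - 2L * margin, 1L) + margin
      if (away_from_native(p) && !any(abs(p - positions) < 2L * margin))
        positions <- c(positions, p)
    }
    truth_loci <- if (n_loci > 0L)
      data.frame(locus_id = sprintf("locus%02d", seq_len(n_loci)),
                 chrom = host$name, position = positions,
                 construct = vapply(seq_len(n_loci), function(i)
                   constructs[[((i - 1L) %% length(constructs)) + 1L]]$name,
                   character(1)),
                 n_support = support_per_locus, stringsAsFactors = FALSE)
    else
      data.frame(locus_id = character(), chrom = character(),
                 position = integer(), construct = character(),
                 n_support = integer(), stringsAsFactors = FALSE)

    reads <- character(0)
    truth_reads <- NULL
    for (i in seq_len(n_loci)) {
      cn <- constructs[[((i - 1L) %% length(constructs)) + 1L]]
      for (j in seq_len(support_per_locus)) {
        lf <- flank_len + sample(-20:20, 1L)
        rf <- flank_len + sample(-20:20, 1L)
        bb_len <- sample(300:nchar(cn$backbone_sequence), 1L)
        ins_len <- sample(300:nchar(cn$insert_sequence), 1L)
        p <- positions[i]
        rd <- paste0(substr(host$sequence, p - lf + 1L, p),
                     substr(cn$backbone_sequence, 1L, bb_len),
                     substr(cn$insert_sequence, 1L, ins_len),
                     substr(host$sequence, p + 1L, p + rf))
        nm <- sprintf("chimeric_L%02d_%02d", i, j)
        reads[nm] <- rd
        truth_reads <- rbind(truth_reads,
                             data.frame(read_name = nm, class = "chimeric",
                                        locus_id = truth_loci$locus_id[i],
                                        stringsAsFactors = FALSE))
      }
    }
    with_native <- Filter(function(cn) !is.null(cn$native_locus), constructs)
    for (j in seq_len(n_native_reads)) {
      cn <- with_native[[((j - 1L) %% length(with_native)) + 1L]]
      s <- max(0L, cn$native_locus[1] - flank_len)
      e <- min(L, cn$native_locus[2] + flank_len)
      nm <- sprintf("native_%02d", j)
      reads[nm] <- substr(host$sequence, s + 1L, e)
      truth_reads <- rbind(truth_reads,
                           data.frame(read_name = nm, class = "native",
                                      locus_id = NA_character_,
                                      stringsAsFactors = FALSE))
    }
    bg_len <- 1500L
    pad <- 200L
    for (j in seq_len(n_background_reads)) {
      placed <- FALSE
      for (try in seq_len(10000L)) {
        s <- sample.int(L - bg_len, 1L) - 1L
        no_native <- is.null(native) ||
          !any(s < native$end + pad & s + bg_len > native$start - pad)
        ok <- no_native &&
          (n_loci == 0L || !any(s < positions + pad & s + bg_len > positions - pad))
        if (ok) { placed <- TRUE; break }
      }
      if (!placed)
        stop("host too crowded to place background reads away from loci",
             call. = FALSE)
      nm <- sprintf("background_%02d", j)
      reads[nm] <- substr(host$sequence, s + 1L, s + bg_len)
      truth_reads <- rbind(truth_reads,
                           data.frame(read_name = nm, class = "background",
                                      locus_id = NA_character_,
                                      stringsAsFactors = FALSE))
    }
    list(reads = reads, truth_loci = truth_loci,
         truth_reads = if (is.null(truth_reads))
           data.frame(read_name = character(), class = character(),
                      locus_id = character(), stringsAsFactors = FALSE)
         else truth_reads)
  })
}
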