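# Transgene integration-site detection from chimeric long reads.
#
# The aligner is a deliberately small seed-and-extend local aligner: exact
# k-mer seeds grouped by diagonal, then exact ungapped local alignment along
# each seeded diagonal (best-scoring contiguous segments by Kadane scan).
# Synthetic long reads here are exact concatenations of host and construct
# sequence, so ungapped diagonals capture every true alignment; gap penalties
# are accepted for interface completeness but no gapped extension is done.

.kmer_index <- function(target, k) {
  n <- nchar(target)
  if (n < k) return(list(env = new.env(parent = emptyenv()), k = k,
                         chars = seq_chars(target), n = n))
  starts <- seq_len(n - k + 1L)
  kmers <- substring(target, starts, starts + k - 1L)
  env <- list2env(split(starts, kmers), envir = new.env(parent = emptyenv()))
  list(env = env, k = k, chars = seq_chars(target), n = n)
}

# Best non-overlapping positive segments of a +match/-mismatch profile.
.segments_on_diagonal <- function(qchars, tchars, diag, match, mismatch,
                                  min_score, max_segments = 8L) {
  nq <- length(qchars); nt <- length(tchars)
  # query index range overlapping the target on this diagonal (1-based)
  q0 <- max(1L, 1L - diag); q1 <- min(nq, nt - diag)
  if (q1 - q0 + 1L < 2L) return(NULL)
  qs <- q0:q1
  sc <- ifelse(qchars[qs] == tchars[qs + diag], match, mismatch)
  out <- NULL
  for (iter in seq_len(max_segments)) {
    # Kadane with segment tracking
    best <- 0; cur <- 0; s <- 1L; bs <- 0L; be <- 0L
    for (i in seq_along(sc)) {
      if (cur <= 0) { cur <- sc[i]; s <- i } else cur <- cur + sc[i]
      if (cur > best) { best <- cur; bs <- s; be <- i }
    }
    if (best < min_score) break
    seg_q <- qs[bs:be]
    matches <- sum(sc[bs:be] == match)
    out <- rbind(out, data.frame(
      q_start = seg_q[1] - 1L, q_end = seg_q[length(seg_q)],
      t_start = seg_q[1] + diag - 1L, t_end = seg_q[length(seg_q)] + diag,
      aligned_length = length(seg_q),
      identity = matches / length(seg_q),
      score = best, stringsAsFactors = FALSE))
    sc[bs:be] <- -Inf
  }
  out
}

.align_oriented <- function(query, index, scoring, min_score) {
  k <- index$k
  nq <- nchar(query)
  if (nq < k || index$n < k) return(NULL)
  starts <- seq_len(nq - k + 1L)
  qk <- substring(query, starts, starts + k - 1L)
  diags <- integer(0)
  for (i in seq_along(qk)) {
    hit <- get0(qk[i], envir = index$env, inherits = FALSE)
    if (!is.null(hit)) diags <- c(diags, hit - starts[i])
  }
  diags <- unique(diags)
  if (!length(diags)) return(NULL)
  qchars <- seq_chars(query)
  res <- lapply(diags, function(d)
    .segments_on_diagonal(qchars, index$chars, d, scoring[1], scoring[2],
                          min_score))
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(NULL)
  do.call(rbind, res)
}

# greedy selection of query-non-overlapping alignments by descending score
.select_nonoverlapping <- function(aln) {
  aln <- aln[order(-aln$score), , drop = FALSE]
  keep <- logical(nrow(aln))
  for (i in seq_len(nrow(aln))) {
    ok <- TRUE
    if (any(keep)) {
      prev <- aln[keep, , drop = FALSE]
      ok <- !any(aln$q_start[i] < prev$q_end & aln$q_end[i] > prev$q_start)
    }
    keep[i] <- ok
  }
  aln[keep, , drop = FALSE]
}

#' Local alignment of a query against a target sequence
#'
#' Reports all non-overlapping (in the query) ungapped local alignments
#' scoring at least `min_score`, in both orientations. Coordinates are
#' 0-based half-open; for minus-orientation hits the query interval refers to
#' the original (un-complemented) query.
#'
#' @param query,target DNA strings over ACGT (non-empty).
#' @param scoring Numeric vector `(match, mismatch, gap_open, gap_extend)`;
#'   gap penalties are part of the interface but extension is ungapped.
#' @param min_score Minimum alignment score to report.
#' @param k Seed k-mer length.
#' @return Data frame with `q_start`, `q_end`, `t_start`, `t_end`,
#'   `aligned_length`, `identity`, `score`, `orientation`; zero rows when
#'   nothing aligns.
#' @export
local_align <- function(query, target, scoring = c(2, -4, -4, -2),
                        min_score = 40, k = 11L) {
  if (!nzchar(query) || !nzchar(target))
    stop("`query` and `target` must be non-empty sequences", call. = FALSE)
  index <- .kmer_index(toupper(target), k)
  .local_align_indexed(toupper(query), index, scoring, min_score)
}

.local_align_indexed <- function(query, index, scoring = c(2, -4, -4, -2),
                                 min_score = 40) {
  fwd <- .align_oriented(query, index, scoring, min_score)
  if (!is.null(fwd) && nrow(fwd)) fwd$orientation <- "+"
  rcq <- revcomp(query)
  rev <- .align_oriented(rcq, index, scoring, min_score)
  if (!is.null(rev) && nrow(rev)) {
    nq <- nchar(query)
    tmp <- rev$q_start
    rev$q_start <- nq - rev$q_end
    rev$q_end <- nq - tmp
    rev$orientation <- "-"
  }
  aln <- rbind(fwd, rev)
  if (is.null(aln) || !nrow(aln))
    return(data.frame(q_start = integer(), q_end = integer(),
                      t_start = integer(), t_end = integer(),
                      aligned_length = integer(), identity = numeric(),
                      score = numeric(), orientation = character(),
                      stringsAsFactors = FALSE))
  aln <- .select_nonoverlapping(aln)
  rownames(aln) <- NULL
  aln
}

#' Find reads carrying lentiviral construct sequence
#'
#' Aligns every read against each construct's backbone and insert and
#' tabulates all local alignments. Reads with no construct alignment are
#' absent from the output.
#'
#' @param reads Named character vector of read sequences.
#' @param constructs List of [construct()] objects.
#' @param min_score Minimum alignment score.
#' @param k Seed k-mer length.
#' @return Data frame with `read_name`, `construct`, `target` ("backbone" /
#'   "insert"), alignment coordinates, `aligned_length`, `identity`, `score`,
#'   `orientation`.
#' @export
find_construct_reads <- function(reads, constructs, min_score = 40, k = 11L) {
  if (!length(constructs)) stop("`constructs` must be non-empty", call. = FALSE)
  stopifnot(!is.null(names(reads)))
  targets <- list()
  for (cn in constructs) {
    targets[[paste0(cn$name, "\rbackbone")]] <- cn$backbone_sequence
    targets[[paste0(cn$name, "\rinsert")]] <- cn$insert_sequence
  }
  # index each distinct target sequence once (backbones are often shared)
  uniq <- !duplicated(unlist(targets))
  idx_of <- match(unlist(targets), unlist(targets)[uniq])
  indexes <- lapply(unlist(targets)[uniq], .kmer_index, k = k)
  out <- vector("list", length(reads) * length(targets))
  ptr <- 0L
  for (r in seq_along(reads)) {
    for (t in seq_along(targets)) {
      aln <- .local_align_indexed(toupper(reads[[r]]), indexes[[idx_of[t]]],
                                  min_score = min_score)
      if (nrow(aln)) {
        key <- strsplit(names(targets)[t], "\r", fixed = TRUE)[[1]]
        aln$read_name <- names(reads)[r]
        aln$construct <- key[1]
        aln$target <- key[2]
        ptr <- ptr + 1L
        out[[ptr]] <- aln
      }
    }
  }
  if (ptr == 0L)
    return(data.frame(read_name = character(), construct = character(),
                      target = character(), q_start = integer(),
                      q_end = integer(), t_start = integer(), t_end = integer(),
                      aligned_length = integer(), identity = numeric(),
                      score = numeric(), orientation = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out[seq_len(ptr)])
  res[, c("read_name", "construct", "target", "q_start", "q_end", "t_start",
          "t_end", "aligned_length", "identity", "score", "orientation")]
}

#' Classify reads as dual backbone+insert evidence
#'
#' A read is genuine vector-derived evidence when it aligns to both the
#' lentiviral backbone and an insert for at least `min_len` bp each
#' (boundary inclusive). Monotone in `min_len`: raising it never adds reads.
#'
#' @param alignments Output of [find_construct_reads()].
#' @param min_len Minimum aligned length per target, bp (default 30).
#' @return Named logical vector over the reads present in `alignments`.
#' @export
classify_dual <- function(alignments, min_len = 30) {
  stopifnot(all(c("read_name", "target", "aligned_length") %in% names(alignments)))
  reads <- unique(alignments$read_name)
  vapply(stats::setNames(reads, reads), function(r) {
    a <- alignments[alignments$read_name == r, , drop = FALSE]
    bb <- a$aligned_length[a$target == "backbone"]
    ins <- a$aligned_length[a$target == "insert"]
    length(bb) > 0 && length(ins) > 0 && max(bb) >= min_len && max(ins) >= min_len
  }, logical(1))
}

#' Locate transgene integration events from dual-evidence reads
#'
#' Host-flank segments of dual backbone+insert reads (the read minus its
#' construct-aligned intervals) are aligned to the host genome; the host
#' coordinate at the flank/construct junction is the anchor. Anchors within
#' `cluster_radius` bp are clustered into candidate events. An event is
#' `rejected_native` when its position falls inside its construct's native
#' locus (the insert gene's own genomic location is not integration
#' evidence), `rejected_singleton` when supported by fewer than `min_support`
#' reads, and `accepted` otherwise.
#'
#' @param reads Named character vector of read sequences.
#' @param host A `synthetic_genome` (or list with `name` and `sequence`).
#' @param constructs List of [construct()] objects.
#' @param alignments Optional precomputed [find_construct_reads()] table.
#' @param min_dual_len Minimum backbone and insert aligned length, bp.
#' @param min_flank Minimum host-flank segment length to attempt anchoring.
#' @param cluster_radius Anchor clustering radius, bp.
#' @param min_support Minimum supporting reads for acceptance.
#' @param min_score Minimum alignment score for flank-to-host alignment.
#' @param k Seed k-mer length.
#' @return Data frame of class `insertion_events`: `chrom`, `position`,
#'   `construct`, `n_support`, `supporting_reads`, `status`; attribute
#'   `unanchored` lists dual reads with no host-aligned flank.
#' @export
locate_insertions <- function(reads, host, constructs, alignments = NULL,
                              min_dual_len = 30, min_flank = 50L,
                              cluster_radius = 50L, min_support = 2L,
                              min_score = 40, k = 11L) {
  if (is.null(alignments))
    alignments <- find_construct_reads(reads, constructs, min_score = min_score, k = k)
  dual <- classify_dual(alignments, min_len = min_dual_len)
  dual_reads <- names(dual)[dual]
  host_index <- .kmer_index(toupper(host$sequence), k)
  native_of <- stats::setNames(lapply(constructs, `[[`, "native_locus"),
                               vapply(constructs, `[[`, character(1), "name"))

  anchors <- NULL
  unanchored <- character(0)
  for (r in dual_reads) {
    a <- alignments[alignments$read_name == r, , drop = FALSE]
    nq <- nchar(reads[[r]])
    # merge construct-covered intervals
    iv <- a[order(a$q_start), c("q_start", "q_end"), drop = FALSE]
    merged <- list()
    for (i in seq_len(nrow(iv))) {
      if (length(merged) && iv$q_start[i] <= merged[[length(merged)]][2])
        merged[[length(merged)]][2] <- max(merged[[length(merged)]][2], iv$q_end[i])
      else merged[[length(merged) + 1L]] <- c(iv$q_start[i], iv$q_end[i])
    }
    cov <- do.call(rbind, merged)
    # flank segments: complement of covered intervals
    bounds <- c(0L, as.vector(t(cov)), nq)
    flanks <- matrix(bounds, ncol = 2, byrow = TRUE)
    # identify the construct by its insert: backbones are shared across
    # constructs, so backbone alignments cannot distinguish them
    ins_a <- a[a$target == "insert", , drop = FALSE]
    main_construct <- if (nrow(ins_a))
      names(which.max(tapply(ins_a$aligned_length, ins_a$construct, max)))
    else names(which.max(tapply(a$aligned_length, a$construct, max)))
    got_anchor <- FALSE
    for (f in seq_len(nrow(flanks))) {
      fs <- flanks[f, 1]; fe <- flanks[f, 2]
      if (fe - fs < min_flank) next
      seg <- substr(reads[[r]], fs + 1L, fe)
      haln <- .local_align_indexed(toupper(seg), host_index, min_score = min_score)
      if (!nrow(haln)) next
      best <- haln[which.max(haln$score), ]
      touches_right <- any(abs(fe - cov[, 1]) <= 5L)  # construct after flank
      touches_left <- any(abs(fs - cov[, 2]) <= 5L)   # construct before flank
      if (touches_right) {
        pos <- if (best$orientation == "+") best$t_end else best$t_start
      } else if (touches_left) {
        pos <- if (best$orientation == "+") best$t_start else best$t_end
      } else next
      anchors <- rbind(anchors, data.frame(
        read_name = r, construct = main_construct, position = pos,
        orientation = best$orientation, stringsAsFactors = FALSE))
      got_anchor <- TRUE
    }
    if (!got_anchor) unanchored <- c(unanchored, r)
  }

  if (is.null(anchors) || !nrow(anchors)) {
    out <- data.frame(chrom = character(), position = integer(),
                      construct = character(), n_support = integer(),
                      supporting_reads = character(), status = character(),
                      stringsAsFactors = FALSE)
    attr(out, "unanchored") <- unanchored
    class(out) <- c("insertion_events", class(out))
    return(out)
  }

  anchors <- anchors[order(anchors$position), , drop = FALSE]
  gap <- c(0, diff(anchors$position))
  cluster_id <- cumsum(gap > cluster_radius)
  events <- lapply(split(anchors, cluster_id), function(cl) {
    pos <- as.integer(round(stats::median(cl$position)))
    cons <- names(which.max(table(cl$construct)))
    rds <- sort(unique(cl$read_name))
    nat <- native_of[[cons]]
    # breakpoints are resolved only to cluster_radius, and reads landing in
    # the native gene anchor at its boundary (the interior looks like
    # insert), so the native interval is padded by the same radius
    status <- if (!is.null(nat) && pos >= nat[1] - cluster_radius &&
                  pos < nat[2] + cluster_radius)
      "rejected_native"
    else if (length(rds) < min_support) "rejected_singleton"
    else "accepted"
    data.frame(chrom = host$name, position = pos, construct = cons,
               n_support = length(rds),
               supporting_reads = paste(rds, collapse = ","),
               status = status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, events)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unanchored") <- unanchored
  class(out) <- c("insertion_events", class(out))
  out
}

#' @export
print.insertion_events <- function(x, ...) {
  n_acc <- if (!is.null(x$status)) sum(x$status == "accepted") else NA_integer_
  cat("Insertion events: ", nrow(x), " (", n_acc, " accepted)\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}
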