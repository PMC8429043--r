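# Shared file I/O: the call-table TSV dialect, variableStep wiggle, GMT,
# BED6, FASTA and MatrixMarket matrices. Internal coordinates are 0-based
# half-open everywhere; conversion to 1-based happens only at the wiggle and
# BED-display boundaries that require it.

CALL_TABLE_COLUMNS <- c("chrom", "strand", "start", "end", "read_name",
                        "log_lik_ratio", "sequence_context")

.header_comment <- function(provenance) {
  if (is.null(provenance)) return(character(0))
  paste0("# ", names(provenance), "=", vapply(provenance, function(v)
    paste(format(v, trim = TRUE), collapse = ","), character(1)))
}

#' Write a per-read methylation call table
#'
#' Tab-separated with the documented column set (`chrom`, `strand`, `start`,
#' `end`, `read_name`, `log_lik_ratio`, `sequence_context`); `#`-prefixed
#' header comments record provenance (seed, parameters) ahead of the column
#' header.
#'
#' @param calls Call-table data frame.
#' @param path Output path.
#' @param provenance Optional named list written as `# key=value` comments.
#' @return `path`, invisibly.
#' @export
write_call_table <- function(calls, path, provenance = NULL) {
  stopifnot(all(CALL_TABLE_COLUMNS %in% names(calls)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.header_comment(provenance), con)
  utils::write.table(calls[, CALL_TABLE_COLUMNS], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-read methylation call table
#'
#' Validates the header and every row; rows with a non-numeric
#' log-likelihood ratio are rejected and reported with their line numbers
#' (attribute `malformed`, plus a warning). A missing required column is an
#' error naming the column. An empty file with a header yields an empty,
#' well-typed table.
#'
#' @param path Input path.
#' @return Call-table data frame; attribute `malformed` holds offending line
#'   numbers.
#' @export
read_call_table <- function(path) {
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  body <- lines[!is_comment]
  body_lineno <- which(!is_comment)
  if (!length(body)) stop("no header line in ", path, call. = FALSE)
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  missing <- setdiff(CALL_TABLE_COLUMNS, header)
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  rows <- body[-1]
  lineno <- body_lineno[-1]
  if (!length(rows)) {
    out <- data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      read_name = character(), log_lik_ratio = numeric(),
                      sequence_context = character(), stringsAsFactors = FALSE)
    attr(out, "malformed") <- integer(0)
    return(out)
  }
  parts <- strsplit(rows, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  llr_col <- match("log_lik_ratio", header)
  start_col <- match("start", header)
  end_col <- match("end", header)
  llr_raw <- vapply(parts, function(p)
    if (length(p) >= llr_col) p[llr_col] else NA_character_, character(1))
  llr <- suppressWarnings(as.numeric(llr_raw))
  bad <- nfield != length(header) | is.na(llr)
  if (any(bad))
    warning(sum(bad), " malformed row(s) rejected at line(s): ",
            paste(lineno[bad], collapse = ", "), call. = FALSE)
  parts <- parts[!bad]
  get_col <- function(name) {
    i <- match(name, header)
    vapply(parts, `[[`, character(1), i)
  }
  out <- data.frame(
    chrom = get_col("chrom"), strand = get_col("strand"),
    start = as.integer(get_col("start")), end = as.integer(get_col("end")),
    read_name = get_col("read_name"), log_lik_ratio = llr[!bad],
    sequence_context = get_col("sequence_context"), stringsAsFactors = FALSE
  )
  attr(out, "malformed") <- lineno[bad]
  out
}

#' Write site summaries as variableStep wiggle tracks
#'
#' One `track` block per (context, chrom), with 1-based positions (converted
#' from the internal 0-based convention). Input must be position-sorted
#' within each chrom and context.
#'
#' @param summaries A `site_summary` data frame.
#' @param path Output path.
#' @param value Column to export (`"proportion"` or `"smoothed_level"`).
#' @param track_name Base track name; the context is appended.
#' @return `path`, invisibly.
#' @export
write_wiggle <- function(summaries, path, value = "proportion",
                         track_name = "methylation") {
  stopifnot(value %in% names(summaries))
  con <- file(path, "w")
  on.exit(close(con))
  for (ctx in unique(summaries$context)) {
    s_ctx <- summaries[summaries$context == ctx, , drop = FALSE]
    writeLines(sprintf('track type=wiggle_0 name="%s_%s"', track_name, ctx), con)
    for (ch in unique(s_ctx$chrom)) {
      s <- s_ctx[s_ctx$chrom == ch, , drop = FALSE]
      if (is.unsorted(s$pos)) stop("summaries not sorted by position for ",
                                   ch, "/", ctx, call. = FALSE)
      writeLines(sprintf("variableStep chrom=%s", ch), con)
      writeLines(sprintf("%d\t%.6g", s$pos + 1L, s[[value]]), con)
    }
  }
  invisible(path)
}

#' Read and write GMT gene-set files
#'
#' One set per line: name, description, then member genes, tab-separated.
#' `write_gmt` accepts a named list of character vectors or a
#' [gene_signature()] (written as two lines, `NAME_UP` / `NAME_DOWN`).
#'
#' @param sets Named list of character vectors, or a `gene_signature`.
#' @param path File path.
#' @param description Description field (recycled).
#' @return `read_gmt`: named list of character vectors. `write_gmt`: `path`,
#'   invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (inherits(sets, "gene_signature"))
    sets <- stats::setNames(list(sets$up, sets$down),
                            paste0(toupper(sets$name), c("_UP", "_DOWN")))
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[[`, character(1), 1))
}

#' Write intervals as BED6
#'
#' BED is 0-based half-open, matching the package's internal convention, so
#' coordinates pass through unchanged.
#'
#' @param df Data frame with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(df, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  bed <- data.frame(
    chrom = df$chrom, start = df$start, end = df$end,
    name = if ("name" %in% names(df)) df$name else ".",
    score = if ("score" %in% names(df)) df$score else 0,
    strand = if ("strand" %in% names(df)) df$strand else ".",
    stringsAsFactors = FALSE
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed6
#' @export
read_bed6 <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(bed) <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(ncol(bed))]
  bed
}

#' Read and write FASTA via Biostrings
#'
#' Thin wrappers keeping the rest of the package on plain named character
#' vectors.
#'
#' @param sequences Named character vector of DNA sequences.
#' @param path File path.
#' @return `read_fasta`: named character vector. `write_fasta`: `path`,
#'   invisibly.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write and read a counts matrix as MatrixMarket plus dimension name files
#'
#' `<path>` gets the sparse matrix, `<path>.rownames` / `<path>.colnames`
#' the gene and sample identifiers, one per line.
#'
#' @param counts Matrix (genes x samples).
#' @param path Base path (conventionally `*.mtx`).
#' @return `read_counts_mtx`: dense integer matrix with dimnames.
#'   `write_counts_mtx`: `path`, invisibly.
#' @export
write_counts_mtx <- function(counts, path) {
  Matrix::writeMM(Matrix::Matrix(as.matrix(counts), sparse = TRUE), path)
  writeLines(rownames(counts), paste0(path, ".rownames"))
  writeLines(colnames(counts), paste0(path, ".colnames"))
  invisible(path)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(path) {
  m <- as.matrix(Matrix::readMM(path))
  dimnames(m) <- list(readLines(paste0(path, ".rownames")),
                      readLines(paste0(path, ".colnames")))
  m
}
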