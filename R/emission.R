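#' Train a per-k-mer Gaussian emission model from labeled signal events
#'
#' Fits, for every k-mer with enough events of both labels, the sample mean
#' and standard deviation of the signal under the unmethylated and methylated
#' states. The labeled events come from control runs of known state: a
#' PCR-amplified run (unmethylated truth) and a GpC-methylase-treated PCR
#' product (methylated truth). This is a per-site naive-Bayes emission model,
#' not a full signal-space HMM: events are treated as independent draws from
#' the k-mer's state-conditional Gaussian.
#'
#' @param events Data frame with columns `kmer`, `signal`, `label`
#'   (`"meth"` / `"unmeth"`).
#' @param min_events Minimum events per (k-mer, label); k-mers below this in
#'   either label are omitted and listed in the `omitted` attribute.
#' @param sd_floor Lower bound applied to fitted standard deviations; hitting
#'   it raises a warning (zero-variance guard).
#'
#' @return A data frame of class `emission_model` with columns `kmer`,
#'   `n_unmeth`, `mean_unmeth`, `sd_unmeth`, `n_meth`, `mean_meth`,
#'   `sd_meth`; attribute `omitted` names the under-supported k-mers.
#' @export
train_emission_model <- function(events, min_events = 20L, sd_floor = 1e-6) {
  stopifnot(all(c("kmer", "signal", "label") %in% names(events)))
  if (!all(events$label %in% c("meth", "unmeth")))
    stop("`label` must be \"meth\" or \"unmeth\"", call. = FALSE)
  agg <- function(lab) {
    e <- events[events$label == lab, , drop = FALSE]
    n <- tapply(e$signal, e$kmer, length)
    m <- tapply(e$signal, e$kmer, mean)
    s <- tapply(e$signal, e$kmer, stats::sd)
    data.frame(kmer = names(n), n = as.integer(n), mean = as.numeric(m),
               sd = as.numeric(s), stringsAsFactors = FALSE)
  }
  u <- agg("unmeth"); m <- agg("meth")
  all_kmers <- sort(unique(events$kmer))
  mdl <- merge(u, m, by = "kmer", suffixes = c("_unmeth", "_meth"), all = TRUE)
  keep <- !is.na(mdl$n_unmeth) & !is.na(mdl$n_meth) &
    mdl$n_unmeth >= min_events & mdl$n_meth >= min_events
  omitted <- mdl$kmer[!keep]
  mdl <- mdl[keep, , drop = FALSE]
  names(mdl) <- c("kmer", "n_unmeth", "mean_unmeth", "sd_unmeth",
                  "n_meth", "mean_meth", "sd_meth")
  floored <- is.na(mdl$sd_unmeth) | mdl$sd_unmeth < sd_floor |
    is.na(mdl$sd_meth) | mdl$sd_meth < sd_floor
  if (any(floored)) {
    warning(sum(floored), " k-mer(s) had (near-)zero signal variance; sd floored at ",
            sd_floor, call. = FALSE)
    mdl$sd_unmeth[is.na(mdl$sd_unmeth) | mdl$sd_unmeth < sd_floor] <- sd_floor
    mdl$sd_meth[is.na(mdl$sd_meth) | mdl$sd_meth < sd_floor] <- sd_floor
  }
  rownames(mdl) <- NULL
  attr(mdl, "omitted") <- omitted
  class(mdl) <- c("emission_model", class(mdl))
  mdl
}

#' Score one site's events against an emission model
#'
#' Computes the natural-log likelihood ratio (methylated over unmethylated)
#' of the events observed at one cytosine site, summing per-event Gaussian
#' log-density differences (independent-event naive Bayes):
#' `llr = sum(log N(signal; mean_meth, sd_meth) - log N(signal; mean_unmeth, sd_unmeth))`.
#'
#' @param events_at_site Data frame with columns `kmer`, `signal`.
#' @param model An [train_emission_model()] result.
#' @return The LLR (numeric scalar) with attribute `n_skipped`, the number of
#'   events whose k-mer was absent from the model; `NA` if every event was
#'   skipped.
#' @export
score_site <- function(events_at_site, model) {
  stopifnot(all(c("kmer", "signal") %in% names(events_at_site)),
            inherits(model, "emission_model"))
  i <- match(events_at_site$kmer, model$kmer)
  skipped <- is.na(i)
  if (all(skipped)) {
    out <- NA_real_
    attr(out, "n_skipped") <- sum(skipped)
    return(out)
  }
  x <- events_at_site$signal[!skipped]
  i <- i[!skipped]
  llr <- sum(stats::dnorm(x, model$mean_meth[i], model$sd_meth[i], log = TRUE) -
             stats::dnorm(x, model$mean_unmeth[i], model$sd_unmeth[i], log = TRUE))
  attr(llr, "n_skipped") <- sum(skipped)
  llr
}

#' Threshold log-likelihood ratios into methylation calls
#'
#' A site on one read is called methylated when `llr >= threshold`,
#' unmethylated when `llr <= -threshold`, and ambiguous in between. The
#' boundary is inclusive on both sides, following the upstream caller's
#' convention; the default cut of 2 nats leaves an ambiguous band for weak
#' evidence.
#'
#' @param llr Numeric vector of log-likelihood ratios (natural log).
#' @param threshold Positive call threshold (nats).
#' @return Character vector: `"methylated"`, `"unmethylated"`, `"ambiguous"`
#'   (`NA` llr propagates to `NA`).
#' @export
call_methylation <- function(llr, threshold = 2) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("`threshold` must be > 0", call. = FALSE)
  ifelse(llr >= threshold, "methylated",
         ifelse(llr <= -threshold, "unmethylated", "ambiguous"))
}
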