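# Internal helpers shared across modules.

# Evaluate `code` under a private RNG state seeded with `seed`; the caller's
# .Random.seed is untouched. Every stochastic function in the package routes
# its randomness through this so generators are pure functions of (args, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("`", name, "` must be a single finite number", call. = FALSE)
}

check_fraction <- function(x, name) {
  stopifnot_scalar_number(x, name)
  if (x < 0 || x > 1) stop("`", name, "` must be in [0, 1]", call. = FALSE)
}

DNA_BASES <- c("A", "C", "G", "T")

comp_base <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(comp_base(s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

seq_chars <- function(sequence) {
  strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
}
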