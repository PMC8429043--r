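rand_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("exact substrings align full-length at identity 1, in either orientation", {
  target <- rand_seq(5000, 1)
  q <- substr(target, 2001, 2100)
  aln <- local_align(q, target)
  expect_identical(nrow(aln), 1L)
  expect_identical(aln$aligned_length, 100L)
  expect_equal(aln$identity, 1.0)
  expect_identical(c(aln$t_start, aln$t_end), c(2000L, 2100L))
  expect_identical(aln$orientation, "+")

  rc <- revcomp_chr(q)
  aln2 <- local_align(rc, target)
  expect_identical(aln2$orientation, "-")
  expect_identical(c(aln2$t_start, aln2$t_end), c(2000L, 2100L))
  expect_error(local_align("", target), "non-empty")
})

test_that("unrelated random sequences rarely reach the score floor", {
  fp <- 0
  for (seed in 1:30) {
    q <- rand_seq(500, seed * 2)
    t <- rand_seq(5000, seed * 2 + 1)
    if (nrow(local_align(q, t, min_score = 40)) > 0) fp <- fp + 1
  }
  expect_lte(fp, 1)  # >= 99% of trials empty, desk-scale allowance
})

test_that("alignments agree with Smith-Waterman on embedded fragments", {
  # independent oracle: Biostrings local pairwiseAlignment
  target <- rand_seq(3000, 11)
  insert <- substr(target, 1001, 1400)
  query <- paste0(rand_seq(200, 12), insert, rand_seq(200, 13))
  aln <- local_align(query, target)
  best <- aln[which.max(aln$score), ]
  sw <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(target),
    type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(2, -4),
    gapOpening = 4, gapExtension = 2)
  expect_identical(best$aligned_length,
                   Biostrings::nchar(Biostrings::alignedPattern(sw)))
  expect_equal(best$score, Biostrings::score(sw))
})

make_fixture <- function(seed, n_loci = 3, support = 4, native = 2, bg = 10) {
  host <- make_genome(30000, 0.5, seed = seed)
  cons <- simulate_constructs(host, 2, seed = seed + 1)
  ir <- simulate_insertion_reads(host, cons, n_loci, support, native, bg,
                                 seed = seed + 2)
  list(host = host, cons = cons, ir = ir)
}

test_that("construct-read tagging finds exactly the chimeric and insert-bearing reads", {
  fx <- make_fixture(61)
  aln <- find_construct_reads(fx$ir$reads, fx$cons)
  tagged <- unique(aln$read_name)
  truth <- fx$ir$truth_reads
  # backgrounds never appear; chimerics always do
  expect_false(any(truth$read_name[truth$class == "background"] %in% tagged))
  expect_true(all(truth$read_name[truth$class == "chimeric"] %in% tagged))
  # native reads align to the insert (their own gene) but not the backbone
  nat <- truth$read_name[truth$class == "native"]
  expect_true(all(nat %in% tagged))
  expect_false(any(aln$target[aln$read_name %in% nat] == "backbone"))
})

test_that("dual classification is boundary-inclusive at 30 bp and monotone", {
  base <- data.frame(read_name = "r", construct = "C1",
                     q_start = 0L, q_end = 0L, t_start = 0L, t_end = 0L,
                     identity = 1, score = 100, orientation = "+",
                     stringsAsFactors = FALSE)
  mk <- function(bb, ins) {
    rbind(cbind(base, target = "backbone", aligned_length = bb),
          cbind(base, target = "insert", aligned_length = ins))
  }
  expect_true(classify_dual(mk(100, 30))[["r"]])
  expect_false(classify_dual(mk(100, 29))[["r"]])
  expect_false(classify_dual(mk(29, 100))[["r"]])
  only_ins <- cbind(base, target = "insert", aligned_length = 500)
  expect_false(classify_dual(only_ins)[["r"]])
  # monotone: raising min_len never adds reads
  for (ml in c(10, 30, 50, 200)) {
    lo <- classify_dual(mk(100, 45), min_len = ml)
    hi <- classify_dual(mk(100, 45), min_len = ml + 20)
    expect_true(all(names(hi)[hi] %in% names(lo)[lo]))
  }
})

test_that("planted loci are recovered; singletons and native-locus hits are rejected", {
  fx <- make_fixture(71)
  ev <- locate_insertions(fx$ir$reads, fx$host, fx$cons)
  acc <- ev[ev$status == "accepted", ]
  expect_identical(nrow(acc), 3L)
  d <- vapply(acc$position, function(p) min(abs(p - fx$ir$truth_loci$position)),
              numeric(1))
  expect_true(all(d <= 50))

  # singleton support
  fx1 <- make_fixture(81, support = 1)
  ev1 <- locate_insertions(fx1$ir$reads, fx1$host, fx1$cons)
  expect_true(all(ev1$status == "rejected_singleton"))

  # an integration planted inside the construct's own native locus; long
  # flanks reach past the native gene so the read is anchorable at all
  host <- fx$host; cons <- fx$cons
  cn <- cons[[2]]  # its native locus sits in the second half of the host
  nat <- cn$native_locus
  p <- nat[1] + 300L
  flank_l <- substr(host$sequence, p - 1499, p)
  flank_r <- substr(host$sequence, p + 1, p + 1500)
  rd <- paste0(flank_l, substr(cn$backbone_sequence, 1, 800),
               substr(cn$insert_sequence, 1, 600), flank_r)
  reads <- c(nat1 = rd, nat2 = rd)
  evn <- locate_insertions(reads, host, cons)
  expect_true(all(evn$status == "rejected_native"))
})

test_that("event calls are invariant to read input order", {
  fx <- make_fixture(91)
  ev1 <- locate_insertions(fx$ir$reads, fx$host, fx$cons)
  set.seed(5)
  ev2 <- locate_insertions(sample(fx$ir$reads), fx$host, fx$cons)
  expect_equal(ev1[, c("position", "construct", "n_support", "status")],
               ev2[, c("position", "construct", "n_support", "status")])
})
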