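test_that("genome generation is seed-deterministic and validates its inputs", {
  g1 <- make_genome(10000, 0.5, n_promoters = 2, seed = 7)
  g2 <- make_genome(10000, 0.5, n_promoters = 2, seed = 7)
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$tss, g2$tss)
  expect_error(make_genome(10000, 1.0, seed = 1), "strictly between")
  expect_error(make_genome(10000, 0, seed = 1), "strictly between")
  expect_error(make_genome(1000, 0.5, n_promoters = 5, seed = 1), "too small")
  # promoters non-overlapping
  g3 <- make_genome(20000, 0.5, n_promoters = 8, seed = 3)
  p <- g3$promoters[order(g3$promoters$start), ]
  expect_true(all(p$start[-1] >= p$end[-nrow(p)]))
  expect_true(all(g3$tss$tss >= 0 & g3$tss$tss < 20000))
})

test_that("genome GC content is within 3 sd of the binomial target", {
  g <- make_genome(10000, 0.6, seed = 1)
  gc <- sum(strsplit(g$sequence, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 6000), 3 * sqrt(10000 * 0.6 * 0.4))
})

test_that("methylome respects extreme probabilities and binomial sampling", {
  g <- make_genome(20000, 0.5, n_promoters = 4, seed = 2)
  m <- simulate_methylome(g, promoter_open_prob = 1, background_open_prob = 0,
                          cpg_meth_prob = 0, seed = 5)
  gch <- m[m$context == "GCH", ]
  expect_true(all(gch$true_state[gch$in_promoter] == "methylated"))
  expect_true(all(gch$true_state[!gch$in_promoter] == "unmethylated"))
  expect_true(all(m$true_state[m$context == "HCG"] == "unmethylated"))
  expect_true(all(m$ambiguous == (m$context == "GCG")))

  m2 <- simulate_methylome(g, promoter_open_prob = 0.8, seed = 6)
  gchp <- m2[m2$context == "GCH" & m2$in_promoter, ]
  n <- nrow(gchp)
  expect_gt(n, 150)  # enough promoter GC sites for a binomial check
  k <- sum(gchp$true_state == "methylated")
  expect_lt(abs(k - n * 0.8), 3 * sqrt(n * 0.8 * 0.2))
})

test_that("call tables carry truth, honor contamination_fraction = 0, and are exact in the noiseless limit", {
  g <- make_genome(6000, 0.5, n_promoters = 2, seed = 3)
  m <- simulate_methylome(g, seed = 4)
  cfg <- sim_config(seed = 9, coverage = 6, read_length = 1500,
                    contamination_fraction = 0, llr_mean_effect = 5,
                    llr_sd = 1e-9)
  sim <- simulate_call_table(m, cfg)
  expect_false(any(sim$read_truth$contaminant))
  # noiseless limit: calls at threshold 2 match the truth exactly
  calls <- sim$calls
  calls$call <- call_methylation(calls$log_lik_ratio, 2)
  key_m <- paste(m$pos, m$strand)
  truth_state <- m$true_state[match(paste(calls$start, calls$strand), key_m)]
  expect_identical(calls$call,
                   ifelse(truth_state == "methylated", "methylated", "unmethylated"))
  # reads cover contiguous intervals: positions strictly increasing per read
  by_read <- split(calls$start, calls$read_name)
  expect_true(all(vapply(by_read, function(p) all(diff(p) > 0), logical(1))))
})

test_that("per-site miscall probability matches the Gaussian tail oracle", {
  # llr ~ N(2, 1) for methylated sites at threshold 2: P(llr < 2) = 0.5
  g <- make_genome(8000, 0.5, n_promoters = 2, seed = 13)
  m <- simulate_methylome(g, promoter_open_prob = 1, background_open_prob = 1,
                          cpg_meth_prob = 1, seed = 14)
  cfg <- sim_config(seed = 15, coverage = 3, read_length = 2000,
                    contamination_fraction = 0, llr_mean_effect = 2, llr_sd = 1)
  sim <- simulate_call_table(m, cfg)
  # restrict to truly methylated sites (HCH sites carry no methylation)
  meth_calls <- sim$calls[sim$calls$sequence_context != "HCH", ]
  n <- nrow(meth_calls)
  frac_below <- mean(meth_calls$log_lik_ratio < 2)
  expect_gt(n, 1000)
  expect_lt(abs(frac_below - 0.5), 3 * sqrt(0.25 / n))
})

test_that("bulk count simulation plants what it claims", {
  cfg0 <- sim_config(seed = 21, n_genes = 500, de_fraction = 0)
  b0 <- simulate_counts_bulk(cfg0)
  expect_identical(sum(b0$truth$is_de), 0L)
  expect_true(all(b0$truth$true_l2fc == 0))
  # byte-identical rerun
  b0b <- simulate_counts_bulk(cfg0)
  expect_identical(b0$counts, b0b$counts)
  expect_error(sim_config(de_fraction = 1.5), "de_fraction")

  # library-size factor scales column sums proportionally
  cfg1 <- sim_config(seed = 22, n_genes = 4000, de_fraction = 0)
  b1 <- simulate_counts_bulk(cfg1)
  sums <- colSums(b1$counts)
  ratio <- (sums / b1$size_factors_true) / mean(sums / b1$size_factors_true)
  expect_true(all(abs(ratio - 1) < 0.1))
})

test_that("single-cell simulation plants phases, quality classes and proportions", {
  cfg <- sim_config(seed = 31, n_cells = 120, lowq_fraction = 0,
                    phase_proportions = c(1, 0, 0, 0, 0))
  sc <- simulate_counts_sc(cfg, n_genes = 1000)
  expect_true(all(sc$truth$phase == "G1/S"))
  expect_false(any(sc$truth$lowq))

  expect_error(
    simulate_counts_sc(cfg, phase_markers = list(a = "g1", b = "g1", c = "g2",
                                                 d = "g3", e = "g4")),
    "disjoint")

  cfg2 <- sim_config(seed = 32, n_cells = 500, lowq_fraction = 0)
  sc2 <- simulate_counts_sc(cfg2, n_genes = 1000)
  tab <- table(factor(sc2$truth$phase,
                      levels = c("G1/S", "S", "G2/M", "M", "M/G1")))
  expect_true(all(abs(tab - 100) < 3 * sqrt(500 * 0.2 * 0.8)))
})

test_that("insertion-read simulation matches its record-count contract", {
  host <- make_genome(30000, 0.5, seed = 41)
  cons <- simulate_constructs(host, 2, seed = 42)
  ir <- simulate_insertion_reads(host, cons, n_loci = 3, support_per_locus = 4,
                                 n_native_reads = 2, n_background_reads = 10,
                                 seed = 43)
  expect_identical(length(ir$reads), 3L * 4L + 2L + 10L)
  expect_identical(nrow(ir$truth_loci), 3L)
  expect_error(simulate_insertion_reads(host, cons, 3, 0, seed = 1), ">= 1")

  ir0 <- simulate_insertion_reads(host, cons, n_loci = 0, support_per_locus = 2,
                                  n_native_reads = 1, n_background_reads = 2,
                                  seed = 44)
  expect_identical(nrow(ir0$truth_loci), 0L)
  ir1 <- simulate_insertion_reads(host, cons, n_loci = 2, support_per_locus = 1,
                                  n_native_reads = 0, n_background_reads = 0,
                                  seed = 45)
  expect_true(all(ir1$truth_loci$n_support == 1L))
})
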