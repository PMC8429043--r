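test_that("contaminant filter honors the 60-of-80 boundary and the minimum stretch", {
  tbl <- rbind(gc_read("drop60", 80, 60),
               gc_read("keep59", 80, 59),
               gc_read("keep79", 79, 79))
  res <- filter_contaminant_reads(tbl)
  expect_identical(res$dropped_reads, "drop60")
  expect_true(all(c("keep59", "keep79") %in% res$kept$read_name))
})

test_that("ambiguous calls join neither the window nor the numerator", {
  # 59 methylated + 21 ambiguous + 21 unmethylated GC calls: only 80
  # unambiguous calls form windows, with at most 59 methylated -> kept
  tbl <- call_rows("r1", rep("GCH", 101),
                   c(rep("methylated", 59), rep("ambiguous", 21),
                     rep("unmethylated", 21)))
  expect_length(filter_contaminant_reads(tbl)$dropped_reads, 0)
  # upgrading one ambiguous call to methylated makes a 60/80 window
  tbl2 <- tbl
  tbl2$call[60] <- "methylated"
  expect_identical(filter_contaminant_reads(tbl2)$dropped_reads, "r1")
})

test_that("non-GC contexts do not interrupt a GC window", {
  ctx <- rep(c("GCH", "HCG"), 80)  # 80 GC calls interleaved with HCG calls
  tbl <- call_rows("r1", ctx, ifelse(ctx == "GCH", "methylated", "unmethylated"))
  expect_identical(filter_contaminant_reads(tbl)$dropped_reads, "r1")
})

test_that("filter sensitivity and specificity are perfect on separated planted reads", {
  set.seed(77)
  reads <- lapply(1:200, function(i) {
    if (i <= 100) gc_read(sprintf("contam%03d", i), 80, sample(62:80, 1))
    else gc_read(sprintf("clean%03d", i), 80, sample(0:40, 1))
  })
  res <- filter_contaminant_reads(do.call(rbind, reads))
  expect_setequal(res$dropped_reads, sprintf("contam%03d", 1:100))
})

test_that("site aggregation matches the proportion formula with coverage rules", {
  tbl <- rbind(
    call_rows("r1", rep("HCG", 3), rep("methylated", 3), pos = c(10, 20, 30)),
    call_rows("r2", rep("HCG", 3), c("methylated", "methylated", "ambiguous"),
              pos = c(10, 20, 30)),
    call_rows("r3", rep("HCG", 3), c("methylated", "unmethylated", "unmethylated"),
              pos = c(10, 20, 30)),
    call_rows("r4", rep("HCG", 3), c("unmethylated", "ambiguous", "unmethylated"),
              pos = c(10, 20, 30)),
    call_rows("r5", rep("HCG", 1), "methylated", pos = 30)
  )
  s <- aggregate_sites(tbl, min_coverage = 4)
  # site 10: m,m,m,u -> 0.75; site 20: m,m,a,u -> coverage 3, excluded;
  # site 30: a,u,u,m (r5) -> wait: r1 m, r2 a, r3 u, r4 u, r5 m -> cov 4, 0.5
  expect_identical(s$pos, c(10L, 30L))
  expect_equal(s$proportion, c(0.75, 0.5))
  expect_identical(s$n_meth + s$n_unmeth, c(4L, 4L))
})

test_that("removing contaminant reads never changes surviving sites' proportions", {
  g <- make_genome(5000, 0.5, n_promoters = 1, seed = 51)
  m <- simulate_methylome(g, seed = 52)
  sim <- simulate_call_table(m, sim_config(seed = 53, coverage = 8,
                                           read_length = 1500,
                                           contamination_fraction = 0.2))
  sim$calls$call <- call_methylation(sim$calls$log_lik_ratio, 2)
  res <- filter_contaminant_reads(sim$calls)
  a <- aggregate_sites(res$kept, min_coverage = 1)
  b <- aggregate_sites(sim$calls[!(sim$calls$read_name %in% res$dropped_reads), ],
                       min_coverage = 1)
  expect_equal(a, b)
})

test_that("triangular smoothing matches the renormalized-convolution oracle", {
  expect_equal(smooth_levels(rep(0.4, 7)), rep(0.4, 7))
  expect_equal(smooth_levels(c(0, 0, 1, 0, 0)),
               c(1 / 6, 2 / 8, 3 / 9, 2 / 8, 1 / 6))
  expect_equal(smooth_levels(0.3), 0.3)
  expect_error(smooth_levels(1:5, width = 4), "odd")
  expect_error(smooth_levels(1:5, width = 0), "odd")
  set.seed(99)
  for (rep in 1:20) {
    x <- runif(sample(1:40, 1))
    w <- sample(c(1, 3, 5, 7), 1)
    expect_equal(smooth_levels(x, w), oracle_smooth(x, w), tolerance = 1e-12)
    expect_true(all(smooth_levels(x, w) >= min(x) - 1e-12 &
                      smooth_levels(x, w) <= max(x) + 1e-12))
  }
})

test_that("smoothing respects track boundaries in a site summary", {
  s <- data.frame(chrom = "chr1", pos = c(1:5, 1:5),
                  strand = "+",
                  context = rep(c("GCH", "HCG"), each = 5),
                  n_meth = 1L, n_unmeth = 1L,
                  proportion = c(0, 0, 1, 0, 0, rep(0.5, 5)))
  out <- smooth_summaries(s, width = 5)
  expect_equal(out$smoothed_level[out$context == "GCH"],
               c(1 / 6, 2 / 8, 3 / 9, 2 / 8, 1 / 6))
  expect_equal(out$smoothed_level[out$context == "HCG"], rep(0.5, 5))
})

test_that("promoter windows are inclusive at +/- flank and report NA for empty tracks", {
  s <- data.frame(chrom = "chr1",
                  pos = c(8499L, 8500L, 10000L, 11500L, 11501L),
                  strand = "+", context = "GCH",
                  n_meth = 1L, n_unmeth = 1L,
                  proportion = c(0.9, 0.2, 0.4, 0.6, 0.9))
  tss <- data.frame(gene = "G1", tss = 10000L)
  prof <- promoter_profile(s, tss, flank = 1500)
  expect_identical(prof$n_gch_sites, 3L)       # 8500, 10000, 11500
  expect_equal(prof$mean_gch_level, mean(c(0.2, 0.4, 0.6)))
  expect_true(is.na(prof$mean_hcg_level))
  expect_identical(prof$n_hcg_sites, 0L)
})

test_that("GCG sites are excluded from both promoter tracks", {
  s <- data.frame(chrom = "chr1", pos = c(10000L, 10001L), strand = "+",
                  context = c("GCG", "GCH"), n_meth = 1L, n_unmeth = 1L,
                  proportion = c(1.0, 0.2))
  prof <- promoter_profile(s, data.frame(gene = "G1", tss = 10000L))
  expect_equal(prof$mean_gch_level, 0.2)
  expect_identical(prof$n_gch_sites, 1L)
})

test_that("open promoters separate from background in the profile", {
  hits <- 0
  for (seed in 1:10) {
    g <- make_genome(6000, 0.5, n_promoters = 1, seed = seed)
    m <- simulate_methylome(g, promoter_open_prob = 0.9,
                            background_open_prob = 0.1, seed = seed + 100)
    sim <- simulate_call_table(m, sim_config(seed = seed + 200, coverage = 8,
                                             read_length = 1500,
                                             contamination_fraction = 0))
    s <- aggregate_sites(sim$calls)
    prom <- promoter_profile(s, g$tss, flank = g$promoter_width / 2)
    bg <- s[s$context == "GCH" &
              (s$pos < g$promoters$start[1] | s$pos >= g$promoters$end[1]), ]
    if (prom$mean_gch_level[1] > mean(bg$proportion)) hits <- hits + 1
  }
  expect_gte(hits, 10 * 0.95 - 1)  # >= 95% of replicates (allow one failure)
})
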