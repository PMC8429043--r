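mk_cells <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  if (is.null(df$sample_class)) df$sample_class <- "iHep"
  df
}

test_that("QC exclusion is strict so boundary cells are kept", {
  cells <- mk_cells(
    cell_id = c("boundary", "mito_hi", "reads_lo", "genes_lo"),
    mapped_reads = c(50000, 1e6, 49999, 1e6),
    genes_detected = c(4000, 5000, 5000, 3999),
    mito_fraction = c(0.06, 0.061, 0.01, 0.01)
  )
  res <- qc_filter(cells)
  expect_identical(res$kept$cell_id, "boundary")
  expect_setequal(res$excluded$cell_id, c("mito_hi", "reads_lo", "genes_lo"))
  expect_identical(res$excluded$reason[res$excluded$cell_id == "mito_hi"],
                   "high_mito")
})

test_that("HFL_CMT cells have no mapped-read threshold and their own cutoffs", {
  cells <- mk_cells(
    cell_id = c("ok", "genes_lo", "mito_hi"),
    mapped_reads = c(49000, 49000, 49000),
    genes_detected = c(3000, 2499, 3000),
    mito_fraction = c(0.05, 0.05, 0.101),
    sample_class = "HFL_CMT"
  )
  res <- qc_filter(cells)
  expect_identical(res$kept$cell_id, "ok")
  # boundary: exactly 2500 genes and exactly 10% mito pass
  cells2 <- mk_cells(cell_id = "b", mapped_reads = 0, genes_detected = 2500,
                     mito_fraction = 0.10, sample_class = "HFL_CMT")
  expect_identical(qc_filter(cells2)$kept$cell_id, "b")
})

test_that("unknown sample classes error unless a default is supplied", {
  cells <- mk_cells(cell_id = "c1", mapped_reads = 1e6, genes_detected = 5000,
                    mito_fraction = 0.01, sample_class = "mystery")
  expect_error(qc_filter(cells), "mystery")
  expect_identical(qc_filter(cells, default_class = "iHep")$kept$cell_id, "c1")
})

test_that("QC tallies match a brute-force pass over random fixtures", {
  set.seed(18)
  n <- 300
  cells <- mk_cells(
    cell_id = sprintf("c%03d", 1:n),
    mapped_reads = round(runif(n, 30000, 80000)),
    genes_detected = round(runif(n, 3000, 5000)),
    mito_fraction = runif(n, 0, 0.12),
    sample_class = sample(c("iHep", "HFL_CMT"), n, TRUE)
  )
  res <- qc_filter(cells)
  th <- qc_default_thresholds()
  brute <- vapply(seq_len(n), function(i) {
    t <- th[[cells$sample_class[i]]]
    ok <- TRUE
    if (!is.na(t$min_mapped_reads)) ok <- ok && cells$mapped_reads[i] >= t$min_mapped_reads
    ok <- ok && cells$genes_detected[i] >= t$min_genes
    ok && cells$mito_fraction[i] <= t$max_mito_fraction
  }, logical(1))
  expect_setequal(res$kept$cell_id, cells$cell_id[brute])
})

test_that("gene filtering keeps genes detected in at least five cells", {
  m <- rbind(
    in5 = c(1, 1, 1, 1, 1, 0, 0, 0),
    in4 = c(1, 1, 1, 1, 0, 0, 0, 0),
    zero = rep(0, 8),
    dense = rep(2, 8)
  )
  colnames(m) <- paste0("c", 1:8)
  out <- gene_filter(m)
  expect_setequal(rownames(out), c("in5", "dense"))
})

test_that("downsampling is per-sample, seeded, and passes small samples through", {
  m <- matrix(1, nrow = 3, ncol = 30,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:30)))
  samples <- rep(c("s1", "s2"), c(10, 20))
  d1 <- downsample_cells(m, n = 15, seed = 4, samples = samples)
  expect_identical(ncol(d1), 25L)  # s1 whole (10) + s2 sampled to 15
  expect_true(all(paste0("c", 1:10) %in% colnames(d1)))
  d2 <- downsample_cells(m, n = 15, seed = 4, samples = samples)
  expect_identical(colnames(d1), colnames(d2))
  expect_error(downsample_cells(m, n = 0), ">= 1")
})

test_that("log-normalization matches its closed form and is depth-invariant", {
  m <- matrix(c(1, 9999, 3, 7), nrow = 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  norm <- lognormalize(m, scale = 1e4)
  expect_equal(norm["g1", "c1"], log(2))  # count 1 of total 1e4
  # doubling a cell's counts leaves its vector unchanged
  m2 <- m; m2[, 2] <- m2[, 2] * 2
  expect_equal(lognormalize(m2)[, 2], norm[, 2])
  # direct formula on a random matrix
  set.seed(19)
  r <- matrix(rpois(200, 5) + 1, nrow = 20,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("c%02d", 1:10)))
  expect_equal(lognormalize(r),
               log1p(sweep(r, 2, colSums(r), "/") * 1e4), tolerance = 1e-12)
  z <- m; z[, 1] <- 0
  expect_error(lognormalize(z), "zero total")
})

test_that("phase scoring recovers planted phases and breaks ties by phase order", {
  sc <- simulate_counts_sc(sim_config(seed = 107, n_cells = 200,
                                      lowq_fraction = 0),
                           n_genes = 1500)
  norm <- lognormalize(gene_filter(sc$counts))
  ph <- cell_cycle_scores(norm, default_phase_markers())
  agree <- mean(ph$assigned_phase ==
                  sc$truth$phase[match(ph$cell, sc$truth$cell)])
  expect_gte(agree, 0.9)

  # constant matrix: all z-scores zero, ties resolve to G1/S
  const <- matrix(1, nrow = 100, ncol = 5,
                  dimnames = list(c(unlist(default_phase_markers(2)),
                                    sprintf("f%02d", 1:90)),
                                  paste0("c", 1:5)))
  ph2 <- cell_cycle_scores(const, default_phase_markers(2))
  expect_true(all(ph2$assigned_phase == "G1/S"))

  # gene order is irrelevant
  perm <- norm[sample(nrow(norm)), ]
  ph3 <- cell_cycle_scores(perm, default_phase_markers())
  expect_identical(ph$assigned_phase, ph3$assigned_phase)

  # a phase with no present markers is a named error
  bad <- default_phase_markers()
  bad[["M/G1"]] <- c("NOT_A_GENE")
  expect_error(cell_cycle_scores(norm, bad), "M/G1")
})

test_that("relative expression normalizes every gene to unit mean", {
  set.seed(20)
  m <- matrix(runif(60, 0.5, 3), nrow = 6,
              dimnames = list(paste0("g", 1:6), paste0("c", 1:10)))
  m["g3", ] <- 2  # identical expression -> all ratios 1
  r <- relative_expression(m)
  expect_true(all(abs(rowMeans(r) - 1) < 1e-12))
  expect_true(all(r["g3", ] == 1))
  expect_equal(r, m / rowMeans(m), ignore_attr = TRUE)
  m0 <- rbind(m, dead = 0)
  r0 <- relative_expression(m0)
  expect_identical(attr(r0, "excluded"), "dead")
  expect_false("dead" %in% rownames(r0))
})
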