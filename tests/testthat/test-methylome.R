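make_cpg <- function(chrom, pos, meth, unmeth, sample) {
  data.table::data.table(chrom = chrom, pos = pos, meth_count = meth,
                         unmeth_count = unmeth, sample_id = sample)
}

test_that("pooling sums counts, filters on coverage and conserves reads", {
  cpg <- rbind(make_cpg("chr1", 100, 3, 2, "s1"),
               make_cpg("chr1", 100, 5, 0, "s2"),
               make_cpg("chr1", 500, 4, 4, "s1"))
  pooled <- pool_samples(cpg, min_coverage = 10)
  expect_equal(nrow(pooled), 1L)
  expect_equal(pooled$meth_count, 8)
  expect_equal(pooled$unmeth_count, 2)
  expect_equal(pooled$beta, 0.8)
  expect_equal(pooled$coverage, 10)
  ## coverage 9 dropped; coverage 10 kept (minimum pooled coverage rule)
  p9 <- pool_samples(rbind(make_cpg("chr1", 1, 5, 4, "s1")), 10)
  expect_equal(nrow(p9), 0L)
  ## read conservation before filtering
  p0 <- pool_samples(cpg, min_coverage = 0)
  expect_equal(sum(p0$meth_count + p0$unmeth_count),
               sum(cpg$meth_count + cpg$unmeth_count))
  ## single sample: identity up to the filter
  one <- make_cpg("chr1", c(10, 20), c(12, 1), c(3, 2), "s1")
  po <- pool_samples(one, min_coverage = 10)
  expect_equal(po$pos, 10)
  expect_equal(po$beta, 0.8)
  ## duplicate rows rejected
  expect_error(pool_samples(rbind(cpg, cpg[1])), "duplicate")
})

test_that("array beta follows the offset-100 intensity convention", {
  expect_equal(array_beta(100, 0), 0.5)
  expect_equal(array_beta(0, 12345), 0)
  expect_equal(array_beta(100, 100), 1 / 3)
  expect_error(array_beta(-1, 5), "non-negative")
})

test_that("segmentation calls planted regions with the 30-CpG class rule", {
  ## 50 consecutive low-beta CpGs flanked by high beta -> one UMR
  mk <- function(n_low, beta_low, n_flank = 60, seed = 1) {
    set.seed(seed)
    pos <- sort(sample.int(50000, n_low + 2 * n_flank))
    beta <- c(runif(n_flank, 0.85, 0.95), rep(beta_low, n_low),
              runif(n_flank, 0.85, 0.95))
    data.table::data.table(chrom = "chr1", pos = pos, beta = beta,
                           meth_count = round(beta * 50),
                           unmeth_count = 50 - round(beta * 50),
                           coverage = 50)
  }
  umr <- segment_hypomethylated(mk(50, 0.1), n_shuffles = 50, seed = 2)
  expect_equal(nrow(umr), 1L)
  expect_equal(umr$n_cpg, 50L)
  expect_equal(umr$klass, "UMR")
  lmr <- segment_hypomethylated(mk(10, 0.3), n_shuffles = 50, seed = 2)
  expect_equal(nrow(lmr), 1L)
  expect_equal(lmr$klass, "LMR")
  expect_lt(lmr$mean_beta, 0.5)
  ## fully hypermethylated input yields nothing
  hyper <- mk(0, 0.1)
  expect_equal(nrow(segment_hypomethylated(hyper, n_shuffles = 20)), 0L)
  ## boundary: exactly 30 CpGs classes as UMR (documented tie-break)
  b30 <- segment_hypomethylated(mk(30, 0.1), n_shuffles = 50, seed = 2)
  expect_equal(b30$klass, "UMR")
  ## unsorted input rejected
  bad <- mk(10, 0.3)[sample(.N)]
  expect_error(segment_hypomethylated(bad), "sorted")
})

test_that("every emitted region satisfies its class invariants", {
  cfg <- sim_config(seed = 31, genome_length = 5e5, n_chroms = 1)
  meth <- generate_methylome(cfg)
  pooled <- pool_samples(meth$cpg)
  regs <- segment_hypomethylated(pooled, seed = 7)
  expect_gt(nrow(regs), 10)
  expect_true(all(regs$mean_beta < 0.5))
  expect_true(all(regs$start < regs$end))
  expect_true(all((regs$n_cpg < 30) == (regs$klass == "LMR")))
  ## a beta-permuted methylome yields almost no accepted regions
  shuf <- data.table::copy(pooled)
  set.seed(8)
  shuf[, beta := sample(beta), by = chrom]
  regs_null <- segment_hypomethylated(shuf, seed = 7)
  expect_lt(nrow(regs_null), 0.05 * nrow(regs) + 1)
})

test_that("PPA capture applies the distance window and is monotone", {
  cs <- data.table::data.table(
    locus = "L1", snp_id = c("v1", "v2"), chrom = "chr1",
    pos = c(1500, 7000), ppa = c(0.6, 0.4))
  cpgs <- data.table::data.table(chrom = "chr1", pos = 2000)
  res <- ppa_capture(cs, cpgs, window = 1000)
  expect_equal(res$per_locus$captured_ppa, 0.6)
  ## CpGs covering everything capture the whole locus PPA
  all_cpg <- data.table::data.table(chrom = "chr1", pos = c(1500, 7000))
  expect_equal(ppa_capture(cs, all_cpg)$per_locus$captured_ppa, 1.0)
  ## superset platform captures at least as much, at every simulated locus
  set.seed(9)
  for (i in 1:20) {
    n <- 30
    cs_i <- data.table::data.table(
      locus = paste0("L", i), snp_id = paste0("v", 1:n), chrom = "chr1",
      pos = sort(sample.int(1e6, n)), ppa = {
        w <- rexp(n); w / sum(w)
      })
    big <- data.table::data.table(chrom = "chr1",
                                  pos = sort(sample.int(1e6, 400)))
    small <- big[sample(.N, 100)]
    c_small <- ppa_capture(cs_i, small)$per_locus$captured_ppa
    c_big <- ppa_capture(cs_i, big)$per_locus$captured_ppa
    expect_gte(c_big, c_small)
    ## monotone in window size
    c_wide <- ppa_capture(cs_i, small, window = 5000)$per_locus$captured_ppa
    expect_gte(c_wide, c_small)
    ## invariant to variant order
    expect_equal(ppa_capture(cs_i[sample(n)], small)$per_locus$captured_ppa,
                 c_small)
  }
})

test_that("KS comparison separates biased subsamples of a methylome", {
  expect_equal(compare_beta_distributions(c(0.1, 0.5, 0.9),
                                          c(0.1, 0.5, 0.9))$D, 0)
  set.seed(10)
  a <- runif(1e4, 0, 0.5)
  b <- runif(1e4, 0.5, 1)
  expect_gt(compare_beta_distributions(a, b)$D, 0.95)
  ## array-like subsample biased towards hypomethylated CpGs
  full <- c(runif(9e4, 0.7, 1), runif(1e4, 0, 0.5))
  wts <- ifelse(full < 0.5, 10, 1)
  arr <- sample(full, 2e4, prob = wts, replace = TRUE)
  r <- compare_beta_distributions(arr, full)
  expect_gt(r$D, 0)
  expect_lt(r$p_value, 1e-6)
})
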