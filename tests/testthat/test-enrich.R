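test_that("log ABF matches its closed form and limits", {
  ## z = 0, V = 1, W = 0.1: ln ABF = 0.5 ln(1/1.1)
  expect_equal(compute_abf(0, 1, prior_variances = 0.1),
               0.5 * log(1 / 1.1), tolerance = 1e-12)
  expect_equal(compute_abf(0, 1, prior_variances = 0.1), -0.047655,
               tolerance = 1e-4)
  ## W -> 0 gives ABF -> 1 (ln -> 0) for any z
  expect_lt(abs(compute_abf(0.5, 0.1, prior_variances = 1e-12)), 1e-6)
  ## strictly increasing in |z| at fixed V, W
  z <- seq(0, 6, by = 0.5)
  la <- compute_abf(z * 0.1, 0.1, prior_variances = 0.1)
  expect_true(all(diff(la) > 0))
  ## averaging over the default prior grid
  lab <- sapply(c(0.01, 0.1, 0.5), function(W) {
    0.5 * log(0.01 / (0.01 + W)) + 9 * W / (2 * (0.01 + W))
  })
  expect_equal(compute_abf(0.3, 0.1), log(mean(exp(lab))), tolerance = 1e-12)
  expect_error(compute_abf(Inf, 1), "non-finite")
  expect_error(compute_abf(1, 0), "positive")
})

test_that("genome segmentation cuts windows of k SNPs per chromosome", {
  snps <- data.table::data.table(chrom = "chr1", pos = seq_len(12000))
  r <- segment_genome(snps, k = 5000)
  expect_equal(as.vector(table(r$region_id)), c(5000, 5000, 2000))
  two <- data.table::data.table(chrom = rep(c("chr1", "chr2"), each = 3000),
                                pos = rep(seq_len(3000), 2))
  r2 <- segment_genome(two, k = 5000)
  expect_equal(length(unique(r2$region_id)), 2L)
  ## shuffled input yields identical segmentation
  shuf <- segment_genome(two[sample(.N)], k = 5000)
  expect_equal(shuf, r2)
})

test_that("window likelihood matches direct summation", {
  ## all ABFs of 1 carry no information: lnL exactly 0
  s1 <- data.table::data.table(region_id = "r", pos = 1:4, ln_abf = 0,
                               a = c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unname(region_ln_likelihood(s1, 0.3, c(a = 1.7))), 0)
  expect_equal(unname(region_ln_likelihood(s1, -2, c(a = -3))), 0)
  ## hand example: gamma = 0, ABFs (9, 1, 1), Pi = 0.5
  s2 <- data.table::data.table(region_id = "r", pos = 1:3,
                               ln_abf = c(log(9), 0, 0))
  expect_equal(unname(exp(region_ln_likelihood(s2, 0))), 0.5 + 0.5 * 11 / 3,
               tolerance = 1e-12)
  ## brute-force oracle on 5-SNP regions, 100 random draws
  set.seed(12)
  for (i in 1:100) {
    snps <- data.table::data.table(
      region_id = rep(c("r1", "r2"), each = 5), pos = rep(1:5, 2),
      ln_abf = rnorm(10, 0, 2),
      a1 = runif(10) < 0.4, a2 = runif(10) < 0.3)
    kappa <- rnorm(1)
    gam <- c(a1 = rnorm(1), a2 = rnorm(1))
    got <- region_ln_likelihood(snps, kappa, gam)
    for (r in c("r1", "r2")) {
      s <- snps[region_id == r]
      oracle <- brute_region(s$ln_abf, cbind(s$a1, s$a2), kappa, gam)
      expect_equal(unname(got[r]), oracle$ln_l, tolerance = 1e-10)
    }
  }
})

test_that("likelihood is invariant to SNP and annotation order", {
  set.seed(13)
  snps <- data.table::data.table(
    region_id = rep("r1", 8), pos = 1:8, ln_abf = rnorm(8),
    a1 = runif(8) < 0.5, a2 = runif(8) < 0.5)
  gam <- c(a1 = 0.7, a2 = -0.4)
  base <- region_ln_likelihood(snps, 0.2, gam)
  expect_equal(region_ln_likelihood(snps[sample(8)], 0.2, gam), base)
  expect_equal(region_ln_likelihood(snps, 0.2, gam[c("a2", "a1")]), base)
})

test_that("single-annotation fit recovers planted enrichment", {
  r <- sim_and_fit_single(seed = 1001)
  gln <- unname(r$fit$gamma)
  expect_gt(gln, 1.5)
  expect_lt(gln, 2.5)
  ## CI sanity: contains the point estimate, flags significance
  expect_lte(r$fit$ci_lo, r$fit$log2fe)
  expect_gte(r$fit$ci_hi, r$fit$log2fe)
  expect_true(r$fit$significant)
  ## region prior recovered at 1000 windows
  cfg <- sim_config(seed = 1002, n_regions = 1000, snps_per_region = 50,
                    gamma_true = c(annot = 2), region_prior_true = 0.5)
  ann <- generate_annotation(cfg, 0.05)
  g <- generate_gwas(cfg, annotations = list(annot = ann))
  snps <- g$snps
  snps[, ln_abf := compute_abf(beta_hat, se)]
  fit <- fit_single(snps, "annot")
  expect_lt(abs(fit$pi - 0.5), 0.05)
  ## null annotation: CI covers zero
  cfg0 <- sim_config(seed = 1003, n_regions = 300,
                     gamma_true = c(annot = 0))
  ann0 <- generate_annotation(cfg0, 0.05)
  g0 <- generate_gwas(cfg0, annotations = list(annot = ann0))
  s0 <- g0$snps
  s0[, ln_abf := compute_abf(beta_hat, se)]
  f0 <- fit_single(s0, "annot")
  expect_lte(f0$ci_lo, 0)
  expect_gte(f0$ci_hi, 0)
  ## unidentifiable annotations rejected
  s0[, all_on := TRUE]
  expect_error(fit_single(s0, "all_on"), "unidentifiable")
})

test_that("joint model selects the planted annotations", {
  hits <- 0L
  n_sims <- 6
  for (i in seq_len(n_sims)) {
    cfg <- sim_config(seed = 200 + i, n_regions = 200, snps_per_region = 80,
                      gamma_true = c(a1 = 2, a2 = 1.5))
    anns <- list(a1 = generate_annotation(cfg, 0.05, seed_offset = 111),
                 a2 = generate_annotation(cfg, 0.08, seed_offset = 112),
                 a3 = generate_annotation(cfg, 0.05, seed_offset = 113))
    g <- generate_gwas(cfg, annotations = anns)
    snps <- g$snps
    snps[, ln_abf := compute_abf(beta_hat, se)]
    fj <- fit_joint(snps, c("a1", "a2", "a3"), seed = 1)
    hits <- hits + setequal(fj$included, c("a1", "a2"))
  }
  expect_gte(hits, ceiling(0.8 * n_sims))
})

test_that("penalty-free single-candidate joint fit nests the single fit", {
  r <- sim_and_fit_single(seed = 1004, n_regions = 150)
  fj <- fit_joint(r$snps, "annot", penalty_grid = 0, seed = 1)
  expect_equal(unname(fj$gamma["annot"]), unname(r$fit$gamma["annot"]),
               tolerance = 1e-4)
  expect_equal(fj$ln_likelihood, r$fit$ln_likelihood, tolerance = 1e-6)
  ## a duplicate of an included annotation is not retained
  snps <- data.table::copy(r$snps)
  snps[, annot_dup := annot]
  fj2 <- fit_joint(snps, c("annot", "annot_dup"), seed = 1)
  expect_lte(length(fj2$included), 1L)
})

test_that("nested likelihood-ratio test behaves at null and alternative", {
  r <- sim_and_fit_single(seed = 1005, n_regions = 300)
  full <- fit_joint(r$snps, "annot", penalty_grid = 0, seed = 1,
                    prefiltered = TRUE)
  reduced <- fit_joint(r$snps, character(), seed = 1)
  reduced$data <- full$data
  lrt <- lrt_nested(full, reduced)
  expect_equal(lrt$df, 1L)
  expect_lt(lrt$p_value, 0.05)
  ## full model likelihood dominates the nested model
  expect_gte(lrt$lnl_full, lrt$lnl_reduced)
  ## reduced = full gives statistic 0, p 1
  same <- lrt_nested(full, full)
  expect_equal(same$statistic, 0, tolerance = 1e-6)
  expect_equal(same$p_value, 1)
  ## non-nested usage rejected
  s <- data.table::copy(r$snps)
  s[, other := !annot]
  other_fit <- fit_joint(s, "other", penalty_grid = 0, seed = 1,
                         prefiltered = TRUE)
  expect_error(lrt_nested(full, other_fit), "nested")
})
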