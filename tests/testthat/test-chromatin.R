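test_that("Poisson binarisation thresholds the upper tail", {
  ## P(X >= 30 | lambda = 5) ~ 2.2e-15 < 1e-4 -> 1; count at the mean -> 0
  counts <- c(rep(5, 999), 30)
  flags <- binarize_chip(counts, lambda = 5)
  expect_equal(flags[1000], 1L)
  expect_equal(flags[1], 0L)
  expect_lt(ppois(29, 5, lower.tail = FALSE), 1e-13)
  expect_warning(z <- binarize_chip(rep(0, 10)), "all-zero")
  expect_equal(z, integer(10))
  ## planted signal/background separation recovered near-perfectly
  cfg <- sim_config(seed = 41, n_marks = 2, n_states_true = 2)
  tp <- generate_state_path(cfg)
  tr <- generate_tracks(cfg, tp)
  truth_flag <- tp$chip_presence[tp$path$chr1, 1]
  got <- binarize_chip(tr$counts$chr1[, 1])
  expect_gt(mean(got == truth_flag), 0.99)
})

test_that("methylation and ATAC binarisation follow bin conventions", {
  sizes <- c(chr1 = 2000)
  pooled <- data.table::data.table(
    chrom = "chr1", pos = c(50, 150, 250, 450),
    beta = c(0.58, 0.60, 0.60, 0.9))
  flags <- binarize_methylation(pooled, sizes, bin_size = 200)$chr1
  expect_equal(flags[1], 1L)   # mean(0.58, 0.60) = 0.59 < 0.6
  expect_equal(flags[2], 0L)   # beta exactly 0.60 -> methylated
  expect_equal(flags[3], 0L)   # 0.9
  expect_equal(flags[4], 0L)   # no CpG -> 0
  expect_true(all(binarize_methylation(
    data.table::data.table(chrom = "chr1", pos = seq(0, 1999, 50),
                           beta = 0.9), sizes)$chr1 == 0L))
  ## ATAC: peak [1000, 1400) hits 0-based bins 5 and 6
  pk <- data.table::data.table(chrom = "chr1", start = 1000, end = 1400)
  fa <- binarize_atac(pk, sizes, 200)$chr1
  expect_equal(which(fa == 1L) - 1L, c(5L, 6L))
  expect_true(all(binarize_atac(pk[0], sizes, 200)$chr1 == 0L))
  ## peak equal to one bin sets exactly that bin
  one <- data.table::data.table(chrom = "chr1", start = 400, end = 600)
  expect_equal(which(binarize_atac(one, sizes, 200)$chr1 == 1L) - 1L, 2L)
})

test_that("Baum-Welch recovers a planted two-state model", {
  set.seed(1)
  emis <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  trans <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2)
  Tn <- 1e4
  st <- integer(Tn)
  st[1] <- 1
  for (t in 2:Tn) st[t] <- sample.int(2, 1, prob = trans[st[t - 1], ])
  O <- matrix(rbinom(Tn * 2, 1, emis[st, ]), Tn, 2,
              dimnames = list(NULL, c("m1", "m2")))
  m <- learn_model(O, n_states = 2, n_restarts = 3, seed = 2, tol = 1e-3)
  perm <- match_states(m, emis)
  expect_lt(max(abs(m$emissions[perm, ] - emis)), 0.05)
  ## EM log-likelihood non-decreasing on every run
  expect_true(all(diff(m$loglik_trace) > -1e-6))
  ## stochastic-matrix invariants
  expect_equal(rowSums(m$transitions), c(1, 1), tolerance = 1e-9)
  expect_equal(sum(m$initial), 1, tolerance = 1e-9)
  ## decoding beats the marginal classifier and is accurate
  dec <- decode_states(m, O)$chr
  acc <- mean(perm[st] == dec$path)
  expect_gt(acc, 0.95)
  marginal_acc <- max(mean(st == 1), mean(st == 2))
  expect_gt(acc, marginal_acc)
})

test_that("single-state data fit with two states matches the marginals", {
  ## with i.i.d. marks the two-state model is non-identifiable (any
  ## stationary mixture reproducing the marginals has equal likelihood);
  ## the identifiable quantity is the stationary-weighted emission mean
  set.seed(3)
  p_true <- c(0.3, 0.7)
  O <- cbind(rbinom(5000, 1, p_true[1]), rbinom(5000, 1, p_true[2]))
  colnames(O) <- c("a", "b")
  m <- learn_model(O, n_states = 2, n_restarts = 2, seed = 4, tol = 1e-3)
  ev <- eigen(t(m$transitions))
  w <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  w <- w / sum(w)
  expect_lt(max(abs(as.vector(w %*% m$emissions) - p_true)), 0.05)
})

test_that("posterior decoding matches exhaustive path enumeration", {
  set.seed(5)
  emis <- matrix(c(0.8, 0.3, 0.2, 0.6), 2, 2)
  trans <- matrix(c(0.7, 0.3, 0.4, 0.6), 2, 2, byrow = TRUE)
  init <- c(0.6, 0.4)
  O <- matrix(rbinom(20, 1, 0.5), 10, 2)
  model <- structure(list(n_states = 2L, emissions = emis,
                          transitions = trans, initial = init),
                     class = "state_model")
  dec <- decode_states(model, O)[[1]]
  oracle <- enumerate_posterior(O, emis, trans, init)
  expect_equal(dec$posterior, oracle, tolerance = 1e-10)
  ## deterministic emissions give 0/1 posteriors matching the planted path
  emis01 <- matrix(c(1 - 1e-12, 1e-12, 1e-12, 1 - 1e-12), 2, 2)
  path <- c(1, 1, 2, 2, 1)
  Od <- cbind(as.numeric(path == 1), as.numeric(path == 2))
  md <- structure(list(n_states = 2L, emissions = emis01, transitions = trans,
                       initial = init), class = "state_model")
  dd <- decode_states(md, Od)[[1]]
  expect_equal(dd$path, path)
  expect_true(all(abs(dd$posterior - round(dd$posterior)) < 1e-6))
  ## uniform model gives uniform posteriors
  mu <- structure(list(n_states = 2L,
                       emissions = matrix(0.5, 2, 2),
                       transitions = matrix(0.5, 2, 2),
                       initial = c(0.5, 0.5)), class = "state_model")
  du <- decode_states(mu, O)[[1]]
  expect_true(all(abs(du$posterior - 0.5) < 1e-12))
})

test_that("state labelling follows the enhancer subdivision scheme", {
  em <- rbind(
    open_strong = c(h3k4me1 = 0.9, h3k27ac = 0.9, atac = 0.9,
                    hypometh = 0.9),
    closed_weak = c(h3k4me1 = 0.9, h3k27ac = 0.1, atac = 0.1,
                    hypometh = 0.1),
    lowmeth_weak = c(h3k4me1 = 0.9, h3k27ac = 0.1, atac = 0.1,
                     hypometh = 0.9),
    quiescent = c(h3k4me1 = 0.1, h3k27ac = 0.1, atac = 0.1, hypometh = 0.1)
  )
  m <- structure(list(n_states = 4L, emissions = em,
                      transitions = diag(4), initial = rep(0.25, 4)),
                 class = "state_model")
  lab <- label_states(m)$labels
  expect_equal(lab[1], "open strong enhancer")
  expect_equal(lab[2], "closed weak enhancer")
  expect_equal(lab[3], "lowly-methylated weak enhancer")
  expect_equal(lab[4], "quiescent")
})

test_that("degenerate fits warn when states exceed distinct mark vectors", {
  O <- matrix(rep(c(0, 1), each = 50), 100, 1)
  colnames(O) <- "m"
  expect_warning(learn_model(O, n_states = 3, n_restarts = 1, seed = 1,
                             max_iter = 10),
                 "distinct mark vectors")
})
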