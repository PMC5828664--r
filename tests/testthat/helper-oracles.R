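## Independent brute-force oracles used across tests. These deliberately
## use naive direct computation (full enumeration / direct summation) so
## they share no code path with the package implementation.

## exact HMM posteriors by enumerating all S^T state paths
enumerate_posterior <- function(O, emissions, transitions, initial) {
  Tn <- nrow(O)
  S <- nrow(emissions)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), Tn)))
  probs <- apply(paths, 1L, function(st) {
    pr <- initial[st[1L]] * prod(ifelse(O[1L, ] == 1, emissions[st[1L], ],
                                        1 - emissions[st[1L], ]))
    for (t in seq_len(Tn)[-1L]) {
      pr <- pr * transitions[st[t - 1L], st[t]] *
        prod(ifelse(O[t, ] == 1, emissions[st[t], ], 1 - emissions[st[t], ]))
    }
    pr
  })
  post <- matrix(0, Tn, S)
  for (t in seq_len(Tn)) {
    for (s in seq_len(S)) {
      post[t, s] <- sum(probs[paths[, t] == s])
    }
  }
  post / rowSums(post)
}

## direct-summation window likelihood and per-SNP PPA for one region
brute_region <- function(ln_abf, X, kappa, gamma) {
  w <- if (length(gamma)) exp(as.vector(X %*% gamma)) else rep(1, length(ln_abf))
  pi_i <- w / sum(w)
  Pi <- stats::plogis(kappa)
  L <- (1 - Pi) + Pi * sum(pi_i * exp(ln_abf))
  list(ln_l = log(L), ppa = Pi * pi_i * exp(ln_abf) / L)
}

## base-level Jaccard index between two interval sets
interval_jaccard <- function(a, b) {
  a <- data.table::as.data.table(a)[, .(chrom, start, end)]
  b <- data.table::as.data.table(b)[, .(chrom, start, end)]
  cov_bp <- function(x) {
    m <- epifine:::.merge_bed(x)
    sum(m$end - m$start)
  }
  union_bp <- cov_bp(rbind(a, b))
  inter_bp <- cov_bp(a) + cov_bp(b) - union_bp
  inter_bp / union_bp
}

## simulate one GWAS enrichment dataset and fit a single annotation
sim_and_fit_single <- function(seed, n_regions = 300, snps_per_region = 100,
                               gamma_true = 2, fraction = 0.05) {
  cfg <- sim_config(seed = seed, n_regions = n_regions,
                    snps_per_region = snps_per_region,
                    gamma_true = c(annot = gamma_true))
  ann <- generate_annotation(cfg, fraction = fraction)
  g <- generate_gwas(cfg, annotations = list(annot = ann))
  snps <- g$snps
  snps[, ln_abf := compute_abf(beta_hat, se)]
  list(snps = snps, truth = g$truth, fit = fit_single(snps, "annot"))
}
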