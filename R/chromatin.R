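#' Tile a genome into fixed-size bins
#'
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param bin_size Bin size in bp (default 200).
#' @return `data.table` with `chrom`, `bin_index` (0-based), `start`, `end`.
#' @export
genome_bins <- function(chrom_sizes, bin_size = 200L) {
  data.table::rbindlist(lapply(names(chrom_sizes), function(cc) {
    n <- floor(chrom_sizes[[cc]] / bin_size)
    idx <- seq_len(n) - 1L
    data.table::data.table(chrom = cc, bin_index = idx,
                           start = idx * bin_size,
                           end = (idx + 1L) * bin_size)
  }))
}

#' Binarise a ChIP read-count track against a Poisson background
#'
#' A bin is called positive when the upper-tail Poisson probability
#' `P(X >= count)` under the genome-wide mean count per bin falls below
#' `threshold_p`.
#'
#' @param counts Non-negative per-bin read counts (one mark).
#' @param threshold_p Upper-tail significance threshold (default 1e-4).
#' @param lambda Optional background mean; defaults to `mean(counts)`.
#' @return Integer 0/1 vector, one entry per bin.
#' @export
binarize_chip <- function(counts, threshold_p = 1e-4, lambda = NULL) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (all(counts == 0)) {
    warning("all-zero track; returning all-zero binarisation")
    return(integer(length(counts)))
  }
  if (is.null(lambda)) lambda <- mean(counts)
  tail_p <- ppois(counts - 1, lambda, lower.tail = FALSE)
  as.integer(tail_p < threshold_p)
}

#' Binarise methylation status over genomic bins
#'
#' The hypomethylation flag is 1 when the mean pooled beta of the CpGs in a
#' bin is below `cutoff` (a bin mean of exactly `cutoff` is treated as
#' methylated), and 0 for bins without CpGs.
#'
#' @param pooled Pooled CpG table from [pool_samples()].
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param bin_size Bin size in bp (default 200).
#' @param cutoff Hypomethylation threshold on beta (default 0.6).
#' @return Named list (per chromosome) of integer 0/1 vectors.
#' @export
binarize_methylation <- function(pooled, chrom_sizes, bin_size = 200L,
                                 cutoff = 0.6) {
  pooled <- data.table::as.data.table(pooled)
  out <- lapply(names(chrom_sizes), function(cc) {
    n <- floor(chrom_sizes[[cc]] / bin_size)
    flags <- integer(n)
    sub <- pooled[chrom == cc]
    if (nrow(sub)) {
      b <- sub[, .(mb = mean(beta)), by = .(bin = pos %/% bin_size)]
      b <- b[bin < n]
      flags[b$bin + 1L] <- as.integer(b$mb < cutoff)
    }
    flags
  })
  stats::setNames(out, names(chrom_sizes))
}
utils::globalVariables(c("bin", "mb"))

#' Binarise ATAC peak presence over genomic bins
#'
#' A bin is flagged 1 when it overlaps any peak by at least 1 bp.
#'
#' @param peaks BED `data.table` of peaks (0-based half-open).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param bin_size Bin size in bp (default 200).
#' @return Named list (per chromosome) of integer 0/1 vectors.
#' @export
binarize_atac <- function(peaks, chrom_sizes, bin_size = 200L) {
  peaks <- data.table::as.data.table(peaks)
  out <- lapply(names(chrom_sizes), function(cc) {
    n <- floor(chrom_sizes[[cc]] / bin_size)
    flags <- integer(n)
    sub <- peaks[chrom == cc]
    for (i in seq_len(nrow(sub))) {
      b0 <- sub$start[i] %/% bin_size
      b1 <- (sub$end[i] - 1L) %/% bin_size
      b0 <- max(b0, 0L); b1 <- min(b1, n - 1L)
      if (b1 >= b0) flags[(b0:b1) + 1L] <- 1L
    }
    flags
  })
  stats::setNames(out, names(chrom_sizes))
}

#' Assemble binarised mark vectors into per-chromosome track matrices
#'
#' @param ... Named arguments, each a named list (per chromosome) of 0/1
#'   vectors as returned by the `binarize_*` functions, or a single named
#'   list of such lists.
#' @return Named list of per-chromosome binary matrices (bins x marks).
#' @export
bind_tracks <- function(...) {
  marks <- list(...)
  if (length(marks) == 1L && is.list(marks[[1L]]) &&
      !is.list(marks[[1L]][[1L]])) {
    ## a single mark passed bare
  } else if (length(marks) == 1L && is.null(names(marks))) {
    marks <- marks[[1L]]
  }
  chroms <- names(marks[[1L]])
  stats::setNames(lapply(chroms, function(cc) {
    m <- vapply(marks, function(x) as.numeric(x[[cc]]),
                numeric(length(marks[[1L]][[cc]])))
    colnames(m) <- names(marks)
    m
  }), chroms)
}

## log emission matrix (T x S) for binary observations O (T x M)
.hmm_log_emission <- function(O, emissions) {
  lp <- log(emissions)
  lq <- log1p(-emissions)
  O %*% t(lp) + (1 - O) %*% t(lq)
}

## scaled forward-backward for one sequence; returns posteriors, expected
## transition counts, and the log-likelihood
.hmm_forward_backward <- function(O, emissions, transitions, initial) {
  Tn <- nrow(O)
  S <- nrow(emissions)
  logB <- .hmm_log_emission(O, emissions)
  sh <- apply(logB, 1L, max)
  Bs <- exp(logB - sh)
  alpha <- matrix(0, Tn, S)
  cvec <- numeric(Tn)
  a <- initial * Bs[1L, ]
  cvec[1L] <- sum(a)
  alpha[1L, ] <- a / cvec[1L]
  if (Tn > 1L) {
    for (t in 2:Tn) {
      a <- as.vector(alpha[t - 1L, ] %*% transitions) * Bs[t, ]
      cvec[t] <- sum(a)
      alpha[t, ] <- a / cvec[t]
    }
  }
  beta_m <- matrix(0, Tn, S)
  beta_m[Tn, ] <- 1
  xi <- matrix(0, S, S)
  if (Tn > 1L) {
    for (t in (Tn - 1L):1L) {
      bb <- Bs[t + 1L, ] * beta_m[t + 1L, ]
      beta_m[t, ] <- as.vector(transitions %*% bb) / cvec[t + 1L]
      xi <- xi + (outer(alpha[t, ], bb) * transitions) / cvec[t + 1L]
    }
  }
  g <- alpha * beta_m
  g <- g / rowSums(g)
  list(gamma = g, xi = xi, loglik = sum(log(cvec)) + sum(sh))
}

#' Learn a multivariate Bernoulli-emission hidden Markov chromatin model
#'
#' Baum-Welch maximum-likelihood fit of an HMM whose emissions are
#' independent Bernoulli probabilities per binarised mark. Chromosomes are
#' treated as independent sequences sharing one parameter set. Restarts are
#' initialised by perturbing the mark marginal frequencies; the best restart
#' by final log-likelihood is returned. The per-iteration log-likelihood is
#' non-decreasing (an EM guarantee, asserted in tests).
#'
#' @param tracks Named list of per-chromosome binary matrices (bins x
#'   marks), e.g. from [bind_tracks()], or a single matrix.
#' @param n_states Number of hidden states (default 15).
#' @param n_restarts Random restarts (default 5).
#' @param seed Seed for initialisation.
#' @param tol Convergence tolerance on the log-likelihood improvement.
#' @param max_iter Maximum EM iterations per restart.
#' @return A `state_model` list: `n_states`, `emissions` (state x mark),
#'   `transitions`, `initial`, `labels` (NULL until [label_states()]),
#'   `loglik`, `loglik_trace`.
#' @export
learn_model <- function(tracks, n_states = 15L, n_restarts = 5L, seed = 1L,
                        tol = 1e-4, max_iter = 200L) {
  if (is.matrix(tracks)) tracks <- list(chr = tracks)
  stopifnot(n_states >= 2L)
  O_all <- do.call(rbind, tracks)
  n_distinct <- nrow(unique(O_all))
  if (n_states > n_distinct) {
    warning("n_states exceeds the number of distinct mark vectors (",
            n_distinct, "); fit may be degenerate")
  }
  marg <- colMeans(O_all)
  M <- ncol(O_all)
  eps <- 1e-3
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    emis <- matrix(pmin(1 - eps, pmax(eps,
      rep(marg, each = n_states) + runif(n_states * M, -0.35, 0.35))),
      n_states, M)
    trans <- matrix(0.5 / (n_states - 1), n_states, n_states)
    diag(trans) <- 0.5
    init <- rep(1 / n_states, n_states)
    trace <- numeric(0)
    prev <- -Inf
    for (it in seq_len(max_iter)) {
      fbs <- lapply(tracks, .hmm_forward_backward, emissions = emis,
                    transitions = trans, initial = init)
      ll <- sum(vapply(fbs, `[[`, numeric(1), "loglik"))
      trace <- c(trace, ll)
      ## M-step
      gsum <- Reduce(`+`, lapply(seq_along(tracks), function(i) {
        t(fbs[[i]]$gamma) %*% tracks[[i]]
      }))
      gtot <- Reduce(`+`, lapply(fbs, function(f) colSums(f$gamma)))
      emis <- gsum / gtot
      emis[] <- pmin(1 - eps, pmax(eps, emis))
      xisum <- Reduce(`+`, lapply(fbs, `[[`, "xi"))
      trans <- xisum / rowSums(xisum)
      init <- Reduce(`+`, lapply(fbs, function(f) f$gamma[1L, ]))
      init <- init / sum(init)
      if (is.finite(prev) && ll - prev < tol) break
      prev <- ll
    }
    if (is.null(best) || trace[length(trace)] > best$loglik) {
      best <- list(emissions = emis, transitions = trans, initial = init,
                   loglik = trace[length(trace)], loglik_trace = trace)
    }
  }
  colnames(best$emissions) <- colnames(O_all)
  rownames(best$emissions) <- paste0("S", seq_len(n_states))
  structure(list(n_states = as.integer(n_states),
                 emissions = best$emissions,
                 transitions = best$transitions, initial = best$initial,
                 labels = NULL, loglik = best$loglik,
                 loglik_trace = best$loglik_trace),
            class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat("Bernoulli-emission HMM with", x$n_states, "states over",
      ncol(x$emissions), "marks; logLik =", format(x$loglik), "\n")
  print(round(x$emissions, 3))
  if (!is.null(x$labels)) {
    cat("labels:", paste(x$labels, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Posterior state decoding by forward-backward
#'
#' @param model A `state_model` from [learn_model()].
#' @param tracks Named list of per-chromosome binary matrices, or a matrix.
#' @return Named list per chromosome: `posterior` (bins x states) and
#'   `path` (argmax state index per bin).
#' @export
decode_states <- function(model, tracks) {
  if (is.matrix(tracks)) tracks <- list(chr = tracks)
  stats::setNames(lapply(tracks, function(O) {
    fb <- .hmm_forward_backward(O, model$emissions, model$transitions,
                                model$initial)
    list(posterior = fb$gamma, path = max.col(fb$gamma, ties.method = "first"))
  }), names(tracks))
}

#' Label chromatin states from their emission profiles
#'
#' Emissions above `threshold` count as "mark present". Default rules follow
#' the usual regulatory vocabulary: H3K4me3 implies promoter; H3K4me1 with
#' H3K27ac implies strong enhancer, H3K4me1 alone weak enhancer; enhancer
#' states are subdivided by accessibility and methylation into "open" (ATAC
#' present), "lowly-methylated" (closed chromatin but hypomethylated) and
#' "closed" (neither); H3K36me3 marks transcription, CTCF insulators,
#' H3K27me3 polycomb repression; no marks at all is quiescent. Mark columns
#' are matched by name (case-insensitive); marks absent from the model are
#' ignored.
#'
#' @param model A `state_model`.
#' @param threshold Emission probability counting as mark presence.
#' @param atac_mark,meth_mark Column names of the accessibility and
#'   hypomethylation tracks (defaults "atac", "hypometh").
#' @return The model with a `labels` character vector filled in.
#' @export
label_states <- function(model, threshold = 0.5, atac_mark = "atac",
                         meth_mark = "hypometh") {
  em <- model$emissions
  nm <- tolower(colnames(em))
  has <- function(mark, s) {
    j <- which(nm == tolower(mark))
    length(j) == 1L && em[s, j] > threshold
  }
  enh_sub <- function(s) {
    if (has(atac_mark, s)) "open"
    else if (has(meth_mark, s)) "lowly-methylated"
    else "closed"
  }
  labels <- vapply(seq_len(model$n_states), function(s) {
    anym <- any(em[s, ] > threshold)
    if (!anym) return("quiescent")
    if (has("h3k4me3", s)) return("promoter")
    if (has("h3k4me1", s) && has("h3k27ac", s)) {
      return(paste(enh_sub(s), "strong enhancer"))
    }
    if (has("h3k4me1", s)) return(paste(enh_sub(s), "weak enhancer"))
    if (has("h3k36me3", s)) return("transcribed")
    if (has("ctcf", s)) return("insulator")
    if (has("h3k27me3", s)) return("polycomb repressed")
    if (has(atac_mark, s)) return("accessible chromatin")
    if (has(meth_mark, s)) return("low methylation")
    "other"
  }, character(1))
  model$labels <- labels
  model
}

#' Match estimated HMM states to a reference by emission similarity
#'
#' Resolves label switching by finding the state permutation minimising the
#' total L1 distance between emission vectors (exhaustive search up to 8
#' states, greedy beyond).
#'
#' @param model Fitted `state_model`.
#' @param reference Reference emission matrix (state x mark).
#' @return Integer permutation `perm` such that `model$emissions[perm[s], ]`
#'   corresponds to reference state `s`.
#' @export
match_states <- function(model, reference) {
  em <- model$emissions
  S <- nrow(reference)
  cost <- matrix(0, S, nrow(em))
  for (i in seq_len(S)) {
    for (j in seq_len(nrow(em))) {
      cost[i, j] <- sum(abs(reference[i, ] - em[j, ]))
    }
  }
  if (S <= 8L && nrow(em) == S) {
    perms <- .permutations(S)
    tot <- apply(perms, 1L, function(p) sum(cost[cbind(seq_len(S), p)]))
    perms[which.min(tot), ]
  } else {
    perm <- integer(S)
    used <- logical(nrow(em))
    for (i in seq_len(S)) {
      j <- order(cost[i, ])
      j <- j[!used[j]][1L]
      perm[i] <- j
      used[j] <- TRUE
    }
    perm
  }
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (i in seq_len(n)) {
    out <- rbind(out, cbind(i, sub + (sub >= i)))
  }
  unname(out)
}
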