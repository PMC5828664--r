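## per-chromosome merged target arrays for fast stab queries
.target_index <- function(target) {
  m <- .merge_bed(target)
  split(m, by = "chrom")
}

## does [s, e) overlap any merged target interval on its chromosome?
## ts/te: sorted merged starts/ends
.stab_any <- function(s, e, ts, te) {
  i <- findInterval(s, ts)
  hit1 <- i >= 1L & s < te[pmax(i, 1L)]
  i2 <- pmin(i + 1L, length(ts))
  hit2 <- i < length(ts) & ts[i2] < e
  hit1 | hit2
}

#' Shuffle intervals uniformly within their chromosomes
#'
#' Each interval is relocated to a uniform random start on its own
#' chromosome with its length preserved, never extending past the
#' chromosome end, and (if an exclusion mask is given) never overlapping an
#' excluded region (rejection sampling).
#'
#' @param intervals BED `data.table` (`chrom`, `start`, `end`).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param excluded Optional BED mask to avoid.
#' @param seed Seed (same seed, same shuffle).
#' @param max_tries Rejection-sampling cap per interval.
#' @return Shuffled BED `data.table`.
#' @export
shuffle_intervals <- function(intervals, chrom_sizes, excluded = NULL,
                              seed = NULL, max_tries = 1000L) {
  x <- data.table::as.data.table(intervals)
  if (!is.null(seed)) set.seed(seed)
  len <- x$end - x$start
  hi <- unname(chrom_sizes[x$chrom]) - len
  if (any(hi < 0)) stop("interval longer than its chromosome")
  s <- floor(runif(nrow(x)) * (hi + 1))
  if (!is.null(excluded)) {
    exi <- .target_index(excluded)
    for (tries in seq_len(max_tries)) {
      bad <- logical(nrow(x))
      for (cc in names(exi)) {
        sel <- which(x$chrom == cc)
        if (!length(sel)) next
        bad[sel] <- .stab_any(s[sel], s[sel] + len[sel],
                              exi[[cc]]$start, exi[[cc]]$end)
      }
      if (!any(bad)) break
      s[bad] <- floor(runif(sum(bad)) * (hi[bad] + 1))
    }
    if (any(bad)) stop("could not place intervals off the exclusion mask")
  }
  data.table::data.table(chrom = x$chrom, start = s, end = s + len)
}

#' Permutation test of interval overlap enrichment
#'
#' The observed statistic is the number of query intervals overlapping the
#' target by at least 1 bp. The null relocates each query interval
#' uniformly within its chromosome (length preserved) `n_perm` times; the
#' empirical p-value uses the add-one estimator
#' `(1 + #permutations >= observed) / (n_perm + 1)` and the fold enrichment
#' is `log2(observed / mean permuted overlap)`.
#'
#' @param query,target BED `data.table`s.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param n_perm Number of permutations (default 1000; production analyses
#'   use 100000).
#' @param seed Seed.
#' @param excluded Optional exclusion mask for placements.
#' @param n_tests Number of annotations tested in the batch, for Bonferroni
#'   (default 1).
#' @return List of class `overlap_enrichment`: `observed`, `perm_mean`,
#'   `log2fe`, `p_emp`, `p_adj`, `n_perm`, `n_query`, `perm_counts`.
#' @export
permutation_enrichment <- function(query, target, chrom_sizes,
                                   n_perm = 1000L, seed = 1L,
                                   excluded = NULL, n_tests = 1L) {
  query <- data.table::as.data.table(query)
  target <- data.table::as.data.table(target)
  if (!nrow(query) || !nrow(target)) stop("query and target must be non-empty")
  ti <- .target_index(target)
  exi <- if (!is.null(excluded)) .target_index(excluded) else NULL
  obs_hit <- logical(nrow(query))
  for (cc in names(ti)) {
    sel <- which(query$chrom == cc)
    if (!length(sel)) next
    obs_hit[sel] <- .stab_any(query$start[sel], query$end[sel],
                              ti[[cc]]$start, ti[[cc]]$end)
  }
  observed <- sum(obs_hit)
  set.seed(seed)
  perm_counts <- numeric(n_perm)
  len <- query$end - query$start
  hi <- unname(chrom_sizes[query$chrom]) - len
  for (cc in unique(query$chrom)) {
    sel <- which(query$chrom == cc)
    nq <- length(sel)
    s <- floor(runif(nq * n_perm) * rep(hi[sel] + 1, n_perm))
    e <- s + rep(len[sel], n_perm)
    if (!is.null(exi) && cc %in% names(exi)) {
      for (tries in 1:1000) {
        bad <- .stab_any(s, e, exi[[cc]]$start, exi[[cc]]$end)
        if (!any(bad)) break
        s[bad] <- floor(runif(sum(bad)) * rep(hi[sel] + 1, n_perm)[bad])
        e[bad] <- s[bad] + rep(len[sel], n_perm)[bad]
      }
    }
    hit <- if (cc %in% names(ti)) {
      .stab_any(s, e, ti[[cc]]$start, ti[[cc]]$end)
    } else logical(length(s))
    perm_counts <- perm_counts +
      as.vector(rowsum(as.numeric(hit), rep(seq_len(n_perm), each = nq)))
  }
  perm_mean <- mean(perm_counts)
  p_emp <- (1 + sum(perm_counts >= observed)) / (n_perm + 1)
  log2fe <- if (perm_mean > 0) log2(observed / perm_mean) else Inf
  structure(list(observed = observed, perm_mean = perm_mean,
                 log2fe = log2fe, p_emp = p_emp,
                 p_adj = min(1, p_emp * n_tests), n_perm = n_perm,
                 n_query = nrow(query), perm_counts = perm_counts),
            class = "overlap_enrichment")
}

#' @export
print.overlap_enrichment <- function(x, ...) {
  cat("overlap enrichment: observed", x$observed, "of", x$n_query,
      "query intervals; permuted mean", signif(x$perm_mean, 4),
      "\n  log2FE =", signif(x$log2fe, 3),
      " p_emp =", signif(x$p_emp, 3),
      " p_adj =", signif(x$p_adj, 3),
      " (", x$n_perm, "permutations )\n")
  invisible(x)
}

#' Batched overlap enrichment with Bonferroni correction
#'
#' Runs [permutation_enrichment()] of one query against each target
#' annotation and Bonferroni-corrects the empirical p-values within the
#' batch (the correction denominator is the number of targets tested).
#'
#' @param query BED `data.table`.
#' @param targets Named list of BED `data.table`s.
#' @inheritParams permutation_enrichment
#' @return `data.table` with one row per target: `target`, `observed`,
#'   `perm_mean`, `log2fe`, `p_emp`, `p_adj`.
#' @export
enrichment_batch <- function(query, targets, chrom_sizes, n_perm = 1000L,
                             seed = 1L, excluded = NULL) {
  nt <- length(targets)
  data.table::rbindlist(lapply(names(targets), function(nm) {
    e <- permutation_enrichment(query, targets[[nm]], chrom_sizes,
                                n_perm = n_perm, seed = seed,
                                excluded = excluded, n_tests = nt)
    data.table::data.table(target = nm, observed = e$observed,
                           perm_mean = e$perm_mean, log2fe = e$log2fe,
                           p_emp = e$p_emp, p_adj = e$p_adj)
  }))
}
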