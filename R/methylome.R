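#' Pool per-sample WGBS CpG counts into a single high-pass methylome
#'
#' Methylated and unmethylated read counts are summed across samples at each
#' CpG; sites whose pooled coverage falls below `min_coverage` are dropped
#' and beta is recomputed from the pooled counts.
#'
#' @param cpg Long `data.table` with columns `chrom`, `pos`, `meth_count`,
#'   `unmeth_count`, `sample_id` (one row per CpG per sample).
#' @param min_coverage Minimum pooled coverage to retain a CpG (default 10).
#' @return `data.table` with `chrom`, `pos`, `meth_count`, `unmeth_count`,
#'   `coverage`, `beta`, sorted by `(chrom, pos)`.
#' @export
pool_samples <- function(cpg, min_coverage = 10) {
  cpg <- data.table::as.data.table(cpg)
  need <- c("chrom", "pos", "meth_count", "unmeth_count", "sample_id")
  stopifnot(all(need %in% names(cpg)))
  if (anyDuplicated(cpg[, .(chrom, pos, sample_id)])) {
    stop("duplicate (chrom, pos, sample_id) rows in CpG input")
  }
  pooled <- cpg[, .(meth_count = sum(meth_count),
                    unmeth_count = sum(unmeth_count)),
                by = .(chrom, pos)]
  pooled[, coverage := meth_count + unmeth_count]
  pooled <- pooled[coverage >= min_coverage]
  pooled[, beta := meth_count / coverage]
  data.table::setkeyv(pooled, c("chrom", "pos"))
  pooled[]
}

#' Methylation array beta value
#'
#' The array convention adds a stabilising offset of 100 to the denominator:
#' `beta = M / (M + U + 100)`.
#'
#' @param meth_intensity Methylated signal intensity M (>= 0).
#' @param unmeth_intensity Unmethylated signal intensity U (>= 0).
#' @return Beta value(s) in `[0, 1)`.
#' @export
array_beta <- function(meth_intensity, unmeth_intensity) {
  if (any(meth_intensity < 0) || any(unmeth_intensity < 0)) {
    stop("intensities must be non-negative")
  }
  meth_intensity / (meth_intensity + unmeth_intensity + 100)
}

## candidate hypomethylated runs on one chromosome; smoothing by a centred
## running mean over `smooth_k` CpGs (edges fall back to the raw beta)
.hypo_candidates <- function(beta, cutoff, min_cpg, smooth_k) {
  sm <- data.table::frollmean(beta, smooth_k, align = "center")
  sm[is.na(sm)] <- beta[is.na(sm)]
  r <- rle(sm < cutoff)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values & r$lengths >= min_cpg)
  if (!length(sel)) {
    return(data.table::data.table(first = integer(), last = integer(),
                                  score = numeric()))
  }
  data.table::data.table(
    first = starts[sel], last = ends[sel],
    score = vapply(sel, function(i) {
      sum(cutoff - beta[starts[i]:ends[i]])
    }, numeric(1))
  )
}

#' Segment hypomethylated regulatory regions (LMRs and UMRs)
#'
#' Candidate regions are maximal runs of at least `min_cpg` consecutive CpGs
#' whose smoothed beta (running mean over `smooth_k` CpGs) falls below
#' `meth_cutoff`. Each candidate is scored by `sum(meth_cutoff - beta)` over
#' its CpGs; the empirical null takes the best candidate score of each
#' within-chromosome permutation of the beta values, and candidates passing
#' a Benjamini-Hochberg FDR threshold are classified by CpG count: fewer
#' than 30 CpGs makes an LMR (CpG-poor, enhancer-like), 30 or more a UMR
#' (CpG-rich, promoter-like; the boundary count 30 is classed UMR).
#'
#' Partially methylated domains are not detected here; callers mask them out
#' of `pooled` beforehand if required.
#'
#' @param pooled Pooled CpG table from [pool_samples()], sorted by
#'   `(chrom, pos)`.
#' @param meth_cutoff Hypomethylation cutoff on beta (default 0.5).
#' @param fdr FDR threshold on accepted regions (default 0.05).
#' @param n_shuffles Number of beta permutations for the null (default 100).
#' @param min_cpg Minimum CpGs per candidate run (default 4).
#' @param smooth_k Running-mean window in CpGs (default 3).
#' @param seed Seed for the permutation null.
#' @return `data.table` of regions: `chrom`, `start`, `end` (0-based
#'   half-open, covering the CpG dinucleotides), `n_cpg`, `mean_beta`,
#'   `klass` ("LMR"/"UMR"), `score`, `p_emp`, `q`.
#' @export
segment_hypomethylated <- function(pooled, meth_cutoff = 0.5, fdr = 0.05,
                                   n_shuffles = 100, min_cpg = 4,
                                   smooth_k = 3, seed = 1L) {
  pooled <- data.table::as.data.table(pooled)
  stopifnot(all(c("chrom", "pos", "beta") %in% names(pooled)))
  if (is.unsorted(pooled$pos) &&
      any(pooled[, is.unsorted(pos), by = chrom]$V1)) {
    stop("pooled CpG input must be sorted by (chrom, pos)")
  }
  chroms <- unique(pooled$chrom)
  cand_list <- null_scores <- vector("list", length(chroms))
  set.seed(seed)
  for (ci in seq_along(chroms)) {
    sub <- pooled[chrom == chroms[ci]]
    cand <- .hypo_candidates(sub$beta, meth_cutoff, min_cpg, smooth_k)
    if (nrow(cand)) {
      cand[, `:=`(chrom = chroms[ci],
                  start = sub$pos[first],
                  end = sub$pos[last] + 2L,
                  n_cpg = last - first + 1L,
                  mean_beta = vapply(seq_len(.N), function(i) {
                    mean(sub$beta[first[i]:last[i]])
                  }, numeric(1)))]
    }
    cand_list[[ci]] <- cand
    ## null statistic: best candidate score of each within-chromosome
    ## beta permutation (-Inf when a shuffle yields no candidate)
    nulls <- numeric(n_shuffles)
    for (s in seq_len(n_shuffles)) {
      bp <- sample(sub$beta)
      sc <- .hypo_candidates(bp, meth_cutoff, min_cpg, smooth_k)$score
      nulls[s] <- if (length(sc)) max(sc) else -Inf
    }
    null_scores[[ci]] <- nulls
  }
  cand <- data.table::rbindlist(cand_list, fill = TRUE)
  if (!nrow(cand)) {
    return(data.table::data.table(
      chrom = character(), start = integer(), end = integer(),
      n_cpg = integer(), mean_beta = numeric(), klass = character(),
      score = numeric(), p_emp = numeric(), q = numeric()
    ))
  }
  nulls <- unlist(null_scores)
  n_null <- length(nulls)
  cand[, p_emp := vapply(score, function(s) {
    (1 + sum(nulls >= s)) / (n_null + 1)
  }, numeric(1))]
  cand[, q := p.adjust(p_emp, method = "BH")]
  out <- cand[q <= fdr & mean_beta < meth_cutoff]
  out[, klass := ifelse(n_cpg < 30L, "LMR", "UMR")]
  out[order(chrom, start),
      .(chrom, start, end, n_cpg, mean_beta, klass, score, p_emp, q)]
}
utils::globalVariables(c("first", "last"))

#' Posterior probability of association captured near assayed CpG sites
#'
#' For each locus, sums the posterior probability (PPA) of credible-set
#' variants that lie within `window` bp of at least one assayed CpG site,
#' and reports the median captured PPA across loci. Used to compare how much
#' fine-mapping signal different methylation platforms can interrogate.
#'
#' @param credible_sets `data.table` with columns `locus`, `snp_id`,
#'   `chrom`, `pos`, `ppa`.
#' @param assayed_cpgs `data.table` with columns `chrom`, `pos`.
#' @param window Capture window in bp around each CpG (default 1000).
#' @return List with `per_locus` (`locus`, `captured_ppa`, `total_ppa`) and
#'   `median_captured`.
#' @export
ppa_capture <- function(credible_sets, assayed_cpgs, window = 1000) {
  cs <- data.table::as.data.table(credible_sets)
  cg <- data.table::as.data.table(assayed_cpgs)
  stopifnot(all(c("locus", "snp_id", "chrom", "pos", "ppa") %in% names(cs)))
  all_loci <- unique(cs$locus)
  cs <- cs[!is.na(ppa)]
  if (!nrow(cs)) stop("no credible-set variants with PPA")
  drop <- setdiff(all_loci, unique(cs$locus))
  if (length(drop)) warning("skipping empty credible sets: ",
                            paste(drop, collapse = ", "))
  cpg_win <- data.table::data.table(
    chrom = cg$chrom,
    start = pmax(0L, cg$pos - as.integer(window)),
    end = cg$pos + as.integer(window) + 2L
  )
  cs[, captured := .point_in_bed(chrom, pos, cpg_win)]
  per_locus <- cs[, .(captured_ppa = sum(ppa[captured]),
                      total_ppa = sum(ppa)), by = locus]
  list(per_locus = per_locus[],
       median_captured = stats::median(per_locus$captured_ppa))
}
utils::globalVariables(c("captured", "N"))

#' Compare two beta-value distributions with a Kolmogorov-Smirnov test
#'
#' @param betas_a,betas_b Numeric vectors of methylation beta values.
#' @return List with the KS statistic `D` and `p_value`.
#' @export
compare_beta_distributions <- function(betas_a, betas_b) {
  kt <- suppressWarnings(stats::ks.test(betas_a, betas_b))
  list(D = unname(kt$statistic), p_value = kt$p.value)
}
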