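#' Reweighted per-SNP posterior probabilities of association
#'
#' Given a fitted enrichment model, the posterior probability that SNP i is
#' the causal variant of its window is
#' `PPA_i = Pi * pi_i * ABF_i / L_r`, where `pi_i` is the
#' annotation-weighted conditional prior and `L_r` the window likelihood;
#' the regional PPA is the sum over the window's SNPs.
#'
#' @param snps `data.table` with `region_id`, `ln_abf` and the model's
#'   annotation columns.
#' @param fit An `enrichment_fit` (from [fit_single()] / [fit_joint()]), or
#'   a list with elements `kappa` and named `gamma` (natural-log scale).
#' @return List with `snps` (input plus `ppa` column) and `regions`
#'   (`region_id`, `regional_ppa`, `ln_likelihood`, `n_snps`).
#' @export
snp_ppa <- function(snps, fit) {
  snps <- data.table::as.data.table(snps)
  if (inherits(fit, "enrichment_fit")) {
    kappa <- fit$kappa
    gamma <- fit$gamma
  } else {
    kappa <- fit$kappa
    gamma <- fit$gamma
  }
  anns <- names(gamma)
  stopifnot(all(anns %in% names(snps)))
  lp <- if (length(anns)) {
    as.vector(vapply(anns, function(a) as.numeric(snps[[a]]),
                     numeric(nrow(snps))) %*% gamma)
  } else rep(0, nrow(snps))
  g <- match(snps$region_id, unique(snps$region_id))
  R <- max(g)
  idx <- split(seq_len(nrow(snps)), g)
  lpi <- plogis(kappa, log.p = TRUE)
  l1m <- plogis(-kappa, log.p = TRUE)
  ln_ppa <- numeric(nrow(snps))
  reg_ppa <- numeric(R)
  reg_ll <- numeric(R)
  for (r in seq_len(R)) {
    i <- idx[[r]]
    lse_lp <- .lse(lp[i])
    s_r <- .lse(lp[i] - lse_lp + snps$ln_abf[i])
    ll_r <- .lse2(l1m, lpi + s_r)
    ln_ppa[i] <- lpi + lp[i] - lse_lp + snps$ln_abf[i] - ll_r
    reg_ppa[r] <- exp(lpi + s_r - ll_r)
    reg_ll[r] <- ll_r
  }
  out <- data.table::copy(snps)
  out[, ppa := exp(ln_ppa)]
  regions <- data.table::data.table(
    region_id = unique(snps$region_id),
    regional_ppa = reg_ppa, ln_likelihood = reg_ll,
    n_snps = lengths(idx)
  )
  list(snps = out[], regions = regions)
}

#' Flag windows with significant association signal
#'
#' A window is flagged when its regional PPA reaches `ppa_threshold` or its
#' best single-variant p-value passes `p_threshold` (the conventional
#' genome-wide line); the PPA arm admits sub-threshold loci.
#'
#' @param regions Region table from [snp_ppa()] (`region_id`,
#'   `regional_ppa`).
#' @param snps SNP table with `region_id` and `p`.
#' @param ppa_threshold Regional PPA threshold (default 0.9).
#' @param p_threshold Single-variant p-value threshold (default 5e-8).
#' @return The region table plus `min_p` and logical `flagged`.
#' @export
significant_segments <- function(regions, snps, ppa_threshold = 0.9,
                                 p_threshold = 5e-8) {
  regions <- data.table::as.data.table(regions)
  snps <- data.table::as.data.table(snps)
  mp <- snps[, .(min_p = min(p)), by = region_id]
  out <- merge(regions, mp, by = "region_id", all.x = TRUE, sort = FALSE)
  out[, flagged := regional_ppa >= ppa_threshold |
        (!is.na(min_p) & min_p < p_threshold)]
  out[]
}

#' Build the 99% credible set of a window
#'
#' PPAs are renormalised by the regional PPA (so the set is conditional on
#' the window containing a signal), sorted in decreasing order with ties
#' broken by genomic position (leftmost first), and the minimal prefix whose
#' cumulative probability reaches `level` is returned.
#'
#' @param ppas Per-SNP PPA vector for one window.
#' @param pos Genomic positions (tie-break).
#' @param snp_id Optional SNP identifiers.
#' @param level Credible level (default 0.99).
#' @param normalize Renormalise by the regional PPA sum (default TRUE).
#' @return `data.table` with `snp_id`, `ppa`, `cumulative`, ordered by
#'   decreasing PPA; `nrow()` is the credible-set size.
#' @export
credible_set <- function(ppas, pos = seq_along(ppas), snp_id = NULL,
                         level = 0.99, normalize = TRUE) {
  if (all(ppas == 0)) stop("empty credible set: all PPAs are zero")
  if (is.null(snp_id)) snp_id <- sprintf("snp%d", seq_along(ppas))
  p <- if (normalize) ppas / sum(ppas) else ppas
  ord <- order(-p, pos)
  cum <- cumsum(p[ord])
  m <- which(cum >= level)[1L]
  if (is.na(m)) m <- length(ord)
  sel <- ord[seq_len(m)]
  data.table::data.table(snp_id = snp_id[sel], ppa = p[sel],
                         cumulative = cum[seq_len(m)])
}

#' Credible sets for every window of a fine-mapping result
#'
#' @param ppa_res Result of [snp_ppa()].
#' @param level Credible level (default 0.99).
#' @param regions Optional subset of region ids (e.g. flagged segments).
#' @param normalize Renormalise by regional PPA (default TRUE).
#' @return `data.table` with `region_id`, `snp_id`, `ppa`, `cumulative`,
#'   `rank_in_region`.
#' @export
credible_sets <- function(ppa_res, level = 0.99, regions = NULL,
                          normalize = TRUE) {
  snps <- data.table::copy(ppa_res$snps)
  if (!"snp_id" %in% names(snps)) {
    snps[, snp_id := sprintf("snp%d", seq_len(.N))]
  }
  if (!is.null(regions)) snps <- snps[region_id %in% regions]
  snps[, {
    cs <- credible_set(ppa, pos, snp_id, level = level,
                       normalize = normalize)
    cs[, rank_in_region := .I]
  }, by = region_id]
}

#' Compare credible sets and top-variant PPAs between two models
#'
#' Per window, reports the credible-set size reduction
#' `size(baseline) - size(full)` (positive when the annotation-informed
#' model shrinks the set) and the top-variant PPA increase
#' `max(full) - max(baseline)` (positive when it sharpens the peak), with
#' medians over windows.
#'
#' @param res_full,res_baseline Results of [snp_ppa()] under the two models
#'   (same SNPs/windows).
#' @param level Credible level (default 0.99).
#' @param regions Optional subset of region ids.
#' @return List with `per_region` and `medians` (`median_size_full`,
#'   `median_size_baseline`, `median_delta_size`, `median_top_full`,
#'   `median_top_baseline`, `median_delta_top`).
#' @export
compare_models <- function(res_full, res_baseline, level = 0.99,
                           regions = NULL) {
  szf <- credible_sets(res_full, level, regions)[, .N, by = region_id]
  szb <- credible_sets(res_baseline, level, regions)[, .N, by = region_id]
  topf <- res_full$snps[, .(top = max(ppa / sum(ppa))), by = region_id]
  topb <- res_baseline$snps[, .(top = max(ppa / sum(ppa))), by = region_id]
  if (!is.null(regions)) {
    topf <- topf[region_id %in% regions]
    topb <- topb[region_id %in% regions]
  }
  per <- merge(merge(szf, szb, by = "region_id", suffixes = c("_full",
                                                              "_baseline")),
               merge(topf, topb, by = "region_id",
                     suffixes = c("_full", "_baseline")),
               by = "region_id")
  per[, delta_size := N_baseline - N_full]
  per[, delta_top := top_full - top_baseline]
  list(per_region = per[],
       medians = list(
         median_size_full = stats::median(per$N_full),
         median_size_baseline = stats::median(per$N_baseline),
         median_delta_size = stats::median(per$delta_size),
         median_top_full = stats::median(per$top_full),
         median_top_baseline = stats::median(per$top_baseline),
         median_delta_top = stats::median(per$delta_top)
       ))
}
utils::globalVariables(c("N_baseline", "N_full", "delta_size", "delta_top",
                         "top_full", "top_baseline"))

#' Partition credible-set PPA across labelled state intervals
#'
#' Each variant takes the label of the state interval containing its
#' position ("Other" if none); the per-label PPA fractions of the set sum
#' to 1.
#'
#' @param cs Credible-set `data.table` with `chrom`, `pos`, `ppa`.
#' @param state_intervals Labelled BED `data.table` (`chrom`, `start`,
#'   `end`, `label`).
#' @return `data.table` with `label` and `fraction`, decreasing.
#' @export
partition_ppa_by_state <- function(cs, state_intervals) {
  cs <- data.table::as.data.table(cs)
  st <- data.table::as.data.table(state_intervals)
  stopifnot(all(c("chrom", "start", "end", "label") %in% names(st)))
  lab <- rep("Other", nrow(cs))
  for (lb in unique(st$label)) {
    inl <- .point_in_bed(cs$chrom, cs$pos, st[label == lb])
    lab[inl] <- lb
  }
  out <- data.table::data.table(label = lab, ppa = cs$ppa)[
    , .(fraction = sum(ppa) / sum(cs$ppa)), by = label]
  out[order(-fraction)]
}
utils::globalVariables("fraction")
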