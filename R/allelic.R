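#' Exact two-sided binomial test for allelic imbalance
#'
#' Tests whether the reference-allele read count departs from the null
#' ratio `p0`. The two-sided p-value is the total probability of outcomes
#' no more likely than the observed one (mass rule):
#' `p = sum over j with P(X=j) <= P(X=k) * (1 + 1e-7) of Binomial(n, p0)`,
#' which for `p0 = 0.5` equals doubling the smaller tail (capped at 1).
#'
#' @param k Reference-allele read count(s), `0 <= k <= n`.
#' @param n Total read count(s), > 0.
#' @param p0 Null reference ratio (default 0.5; a reference-bias estimate
#'   may be substituted).
#' @return Two-sided exact p-value(s).
#' @export
binomial_ai_test <- function(k, n, p0 = 0.5) {
  if (length(n) == 1L) n <- rep(n, length(k))
  if (any(n <= 0)) stop("total read count must be positive")
  if (any(k < 0 | k > n)) stop("k must lie in [0, n]")
  vapply(seq_along(k), function(i) {
    d <- dbinom(0:n[i], n[i], p0)
    min(1, sum(d[d <= d[k[i] + 1L] * (1 + 1e-7)]))
  }, numeric(1))
}

#' Allele ratio for reporting
#'
#' @param ref_count,alt_count Aggregated reads supporting each allele.
#' @param digits Rounding for presentation (default 2; use `Inf` for full
#'   precision).
#' @return `ref_count / (ref_count + alt_count)`, rounded.
#' @export
allele_ratio <- function(ref_count, alt_count, digits = 2) {
  r <- ref_count / (ref_count + alt_count)
  if (is.finite(digits)) round(r, digits) else r
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; output order
#' matches the input.
#'
#' @param p_values Vector of p-values.
#' @return Vector of q-values.
#' @export
fdr_adjust <- function(p_values) p.adjust(p_values, method = "BH")

#' Select variants eligible for allelic-imbalance testing
#'
#' A variant is eligible when (a) its reweighted PPA reaches `min_ppa`, (b)
#' it overlaps an annotation retained in the joint enrichment model, (c) at
#' least `min_het` samples are heterozygous, (d) its aggregate read depth
#' reaches `min_depth` and (e) each allele has at least `min_per_allele`
#' reads. PPA-eligible variants without count data are listed as untested
#' rather than erroring.
#'
#' @param variants `data.table` with `snp_id`, `ppa` and a logical
#'   `in_enriched_annotation` column.
#' @param counts Long per-sample count table (`snp_id`, `sample_id`,
#'   `ref_count`, `alt_count`, `het`).
#' @param min_ppa Minimum reweighted PPA (default 0.10).
#' @param min_het Minimum heterozygous samples (default 2).
#' @param min_depth Minimum aggregate depth (default 10).
#' @param min_per_allele Minimum reads per allele (default 5).
#' @return `data.table` per variant with aggregate counts and a `status`
#'   column: "eligible", "untested" (no counts) or "filtered".
#' @export
select_test_variants <- function(variants, counts, min_ppa = 0.10,
                                 min_het = 2L, min_depth = 10L,
                                 min_per_allele = 5L) {
  variants <- data.table::as.data.table(variants)
  counts <- data.table::as.data.table(counts)
  stopifnot(all(c("snp_id", "ppa", "in_enriched_annotation") %in%
                  names(variants)))
  agg <- counts[het == TRUE,
                .(ref_count = sum(ref_count), alt_count = sum(alt_count),
                  n_het_samples = .N), by = snp_id]
  out <- merge(variants, agg, by = "snp_id", all.x = TRUE, sort = FALSE)
  out[, depth := ref_count + alt_count]
  prior_ok <- out$ppa >= min_ppa & out$in_enriched_annotation
  has_counts <- !is.na(out$n_het_samples)
  counts_ok <- has_counts & out$n_het_samples >= min_het &
    out$depth >= min_depth & pmin(out$ref_count, out$alt_count) >=
    min_per_allele
  out[, status := data.table::fifelse(
    !prior_ok, "filtered",
    data.table::fifelse(!has_counts, "untested",
                        data.table::fifelse(counts_ok, "eligible",
                                            "filtered")))]
  out[]
}
utils::globalVariables("status")

#' Test allelic imbalance across eligible variants with FDR control
#'
#' Aggregates allele counts over heterozygous samples per variant, applies
#' the exact binomial test against `p0`, and controls FDR by
#' Benjamini-Hochberg.
#'
#' @param selected Output of [select_test_variants()] (only "eligible" rows
#'   are tested).
#' @param p0 Null reference ratio (default 0.5).
#' @param fdr Significance threshold on q (default 0.05).
#' @return `data.table` with `snp_id`, counts, `ratio` (full precision),
#'   `ratio_report` (2 dp), `p`, `q`, `significant`, `direction`
#'   ("ref_open"/"alt_open"/"balanced").
#' @export
ai_test <- function(selected, p0 = 0.5, fdr = 0.05) {
  el <- data.table::as.data.table(selected)[status == "eligible"]
  if (!nrow(el)) {
    return(data.table::data.table(
      snp_id = character(), ref_count = integer(), alt_count = integer(),
      n_het_samples = integer(), ratio = numeric(), ratio_report = numeric(),
      p = numeric(), q = numeric(), significant = logical(),
      direction = character()
    ))
  }
  el[, ratio := ref_count / (ref_count + alt_count)]
  el[, ratio_report := round(ratio, 2)]
  el[, p := binomial_ai_test(ref_count, ref_count + alt_count, p0)]
  el[, q := fdr_adjust(p)]
  el[, significant := q < fdr]
  el[, direction := data.table::fifelse(
    ratio > p0, "ref_open", data.table::fifelse(ratio < p0, "alt_open",
                                                "balanced"))]
  el[, .(snp_id, ref_count, alt_count, n_het_samples, ratio, ratio_report,
         p, q, significant, direction)]
}
utils::globalVariables(c("ratio", "ratio_report", "significant",
                         "direction", "n_het_samples"))
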