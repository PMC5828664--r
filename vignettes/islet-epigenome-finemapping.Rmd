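---
title: "Methods: integrative epigenome annotation and GWAS fine-mapping"
author: "epifine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative epigenome annotation and GWAS fine-mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epifine)
library(data.table)
```

This vignette documents the models behind `epifine`, the parameters that
matter, the design decisions taken where a choice was genuinely open, and
what the synthetic-data tests do and do not establish about real data.

## Scientific setting

Tissue-specific regulatory annotation sharpens the interpretation of GWAS
signals: disease-associated variants concentrate in the active enhancers
and promoters of the disease-relevant tissue, and hypomethylation and open
chromatin mark those elements. The package follows the analysis chain used
for pancreatic-islet interpretation of type 2 diabetes association data:
segment the methylome into regulatory regions, learn integrative chromatin
states, estimate how strongly each annotation is enriched for association
signal, reweight per-variant posteriors with those enrichments, and seek
orthogonal confirmation in allele-specific chromatin accessibility.

## Methylome segmentation

Pooling sums methylated/unmethylated read counts across samples per CpG and
recomputes β = M/(M+U); CpGs below the pooled-coverage floor (default 10x)
are dropped. Sequencing β and array β differ by convention: the array form
M/(M+U+100) shrinks low-intensity probes toward zero and is provided as
`array_beta()` for platform comparisons.

Hypomethylated-region calling is intentionally self-contained rather than a
wrapper around an external segmentation tool. β is smoothed with a centred
running mean over 3 CpGs (edge CpGs fall back to their raw β); candidates
are maximal runs of ≥ 4 consecutive CpGs with smoothed β below the cutoff
(default 0.5); each candidate is scored by Σ(cutoff − β) over its CpGs. The
null distribution takes the *best candidate score of each within-chromosome
permutation* of the β values (a permutation without candidates contributes
−∞). This max-null is always well defined — a pooled per-candidate null
degenerates when hypomethylated CpGs are too sparse to form candidates
under permutation — and is conservative. Empirical p-values use the add-one
estimator and are BH-adjusted; accepted regions are classified by CpG
count: < 30 CpGs → LMR, otherwise UMR. The count of exactly 30 is classed
UMR (an arbitrary but documented tie-break of the open "<30 / >30"
boundary). A reported 10% lower bound on LMR methylation appears in some
descriptions of such regions; it is deliberately not enforced here, as the
operative protocol statement is only "< 50%".

Coordinates are 0-based half-open (BED) throughout; a CpG is located by the
C position on the plus strand and a region's end extends to the last CpG's
dinucleotide end. Partially methylated domains are not detected; callers
mask them out of the pooled table before segmentation if needed.

## Chromatin-state model

Tracks are binarised over 200 bp bins. ChIP counts use a Poisson upper tail
against the genome-wide mean count per bin, flagging bins with
P(X ≥ count) < 1e-4; this threshold follows the common binarisation
convention and is exposed as an argument, since it is a convention rather
than a derived quantity. Open chromatin is peak overlap (≥ 1 bp);
methylation is the mean pooled β per bin against a 60% threshold, with a
bin mean of exactly 0.60 classed methylated and CpG-free bins classed
methylated (flag 0) — both documented tie-breaks.

`learn_model()` fits a hidden Markov model with independent Bernoulli
emissions per mark by Baum–Welch. Chromosomes are independent sequences
sharing one parameter set. Initialisation perturbs the mark marginal
frequencies (±0.35, clamped to [1e-3, 1−1e-3]) with near-uniform
transitions boosted to 0.5 on the diagonal; the best of `n_restarts`
(default 5) by final log-likelihood is kept, with the seed recorded.
Forward–backward uses per-position scaling plus a per-bin shift of the log
emission, so posteriors stay finite for sequences of at least 10⁶ bins.
Emissions are clamped away from 0/1 by 1e-3 to keep the likelihood finite
under rare observations. The EM log-likelihood trace is retained and tested
for monotonicity. Label switching is resolved for evaluation by exhaustive
permutation matching of emission vectors up to 8 states (greedy beyond).

State labels are rule-based on thresholded emissions (> 0.5 = mark
present): H3K4me3 → promoter; H3K4me1 with/without H3K27ac → strong/weak
enhancer, subdivided by accessibility and methylation into *open* (ATAC
present), *lowly-methylated* (closed but hypomethylated) and *closed*;
H3K36me3 → transcribed; CTCF → insulator; H3K27me3 → polycomb repressed; no
marks → quiescent.

The number of states is a user choice (production analyses of real islet
data use 15); nothing in the package selects it automatically.

## Hierarchical enrichment and fine-mapping

Per-SNP evidence is the Wakefield-style approximate Bayes factor computed
from the effect estimate and standard error, ln ABF = ½ln(V/(V+W)) +
z²W/(2(V+W)) with V = se², averaged (on the ABF scale) over prior variances
W ∈ {0.01, 0.1, 0.5} by default. Case-control effects enter as log odds
ratios with the same functional form. The genome is cut into windows of k
consecutive SNPs (default 5000, never spanning chromosomes, partial final
windows kept); each window contains at most one causal SNP. The window
likelihood is L_r = (1−Π) + Π·Σᵢπᵢ·ABFᵢ with annotation-dependent
conditional prior πᵢ ∝ exp(γ·xᵢ) and Π = logistic(κ).

Because annotation vectors are binary, the likelihood is evaluated through
a pattern-collapsed representation: per (window, annotation-pattern)
matrices of SNP counts and of shifted ABF sums reduce each evaluation to
two small matrix products, in log space with per-window shifts so that
arbitrary |z| cannot overflow. Tests verify exact agreement (1e-10) with
direct summation. Optimisation is quasi-Newton (BFGS) over (κ, γ) with
|γ| bounded at 20; CI endpoints that hit the bound are flagged rather than
reported as meaningful values. 95% CIs come from the profile likelihood
(drop of 1.92), profiling κ and any other included annotations. Estimates
are kept on the natural-log scale internally and reported as log₂ fold
enrichments.

The joint model performs forward selection among singly-significant
candidates by log-likelihood gain, chooses an L1 penalty over the default
grid {0, 0.05, 0.1, 0.2, 0.5} by 10-fold cross-validation across windows
(folds assigned by a recorded seed), then backward-eliminates while the
cross-validation likelihood improves. The nested likelihood-ratio test
always refits both models without penalty.

Reweighted per-SNP posteriors are PPAᵢ = Π·πᵢ·ABFᵢ/L_r; the regional PPA is
their sum. Windows are flagged at regional PPA ≥ 0.9 or best single-variant
p < 5e-8. Credible sets renormalise PPAs by the regional PPA — the set is
conditional on the window containing a signal — sort descending with ties
broken leftmost-first, and take the minimal prefix reaching the level
(default 99%). The renormalisation is switchable (`normalize = FALSE`)
since either convention is defensible.

## Overlap enrichment and allelic imbalance

Permutation overlap enrichment relocates each query interval uniformly
within its own chromosome (length preserved, optional exclusion mask by
rejection sampling) and counts query intervals overlapping the target by
≥ 1 bp; the unit is interval count, matching "% of regions overlapping"
semantics. Empirical p-values use the add-one estimator, so p ≥
1/(n_perm+1); fold enrichment is log₂(observed/permuted mean); Bonferroni
correction is applied within each invoked batch of targets and the batch
size is recorded. The inner loop uses a vectorised sorted-interval stab
(findInterval) so that 10⁵-permutation production runs stay cheap; the
same counts are verified against GenomicRanges overlaps in tests.

Allelic imbalance testing filters variants on reweighted PPA ≥ 10%,
overlap with a retained annotation, ≥ 2 heterozygous samples, aggregate
depth ≥ 10 and ≥ 5 reads per allele. The depth threshold pair deserves a
note: "depth > 9" and "≥ 5 per allele" both circulate as descriptions of
this protocol; since 5+5 implies ≥ 10, the per-allele rule dominates and
both are configurable. The test is the exact two-sided binomial mass rule
(outcomes no more likely than observed, tolerance factor 1+1e-7), which for
a balanced null equals doubling the smaller tail; FDR control is
Benjamini–Hochberg at 0.05. Read-mapping bias correction (re-mapping reads
with swapped alleles) requires an aligner and is out of scope; the
statistical contract instead accepts pre-filtered counts and allows a
reference-bias null p₀ ≠ 0.5 estimated from genome-wide heterozygous
sites. Ratios are reported at 2 decimals for presentation; tests use full
precision.

## The synthetic-data generator

The generator's defaults are the study conditions the pipeline targets,
chosen once:

* **Methylome**: 10 WGBS samples at mean 8.5x (pooled ≈ 85x, pooled-
  coverage floor 10x), a hypermethylated background (per-CpG β ~ U(0.8,
  0.95)) with planted CpG-rich UMRs (35–70 CpGs, β ~ U(0.05, 0.2)) and
  CpG-poor LMRs (10–25 CpGs, β ~ U(0.1, 0.4)); per sample and CpG, total
  reads are Poisson and methylated reads Binomial(total, β).
* **Chromatin**: a sticky Markov state path in which the quiescent state
  dominates (self-transition 0.99 vs 0.85 for marked states, leaving mass
  returning mostly to quiescent), so marked chromatin covers ~5–10% of
  bins as in real genomes — this also makes the genome-wide-mean Poisson
  background of the binarisation meaningful. Mark counts are Poisson with
  means 30 (present) / 5 (absent).
* **GWAS**: constant SNP standard error 0.03 (large case-control scale); a
  causal variant per window with probability Π (default 0.5), placed with
  probability ∝ exp(γ·x), effect ~ N(0, W). For the fine-mapping
  model contrast the scenario is an enhancer-like annotation covering 10%
  of SNPs with ln-enrichment 2.6 (log₂FE ≈ 3.8, the scale observed for
  open strong enhancers), a causal variant in every window, and W = 0.02 —
  i.e. log-OR sd ≈ 0.14, odds ratios around 1.15, the regime where single
  loci are genuinely ambiguous and annotations can help.
* **Allelic counts**: 17 samples, allele frequency 0.3 (heterozygosity
  2f(1−f) ≈ 0.42), heterozygote depth Poisson(18), giving mean aggregate
  depth ≈ 130.

Each generator seeds its own stream from `seed` plus a fixed offset, so
stages are reproducible independently; a fixed seed gives byte-identical
outputs.

What the generator does **not** emulate: linkage disequilibrium between
SNPs (the single-causal-variant model does not require it, but real
credible sets are inflated by LD partners, so absolute set sizes here are
not comparable to real loci); read-level artefacts (mapping bias, PCR
duplicates); PMDs and large-scale methylation domains; annotation
correlation structure (real enhancer marks co-occur). Passing tests
therefore establish correctness of the algorithms and calibration of the
statistics under the generative model, not performance claims about any
real dataset.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: all-zero ChIP tracks binarise to
zero with a warning; annotations covering all or no SNPs are rejected as
unidentifiable; all-zero PPA vectors refuse to form a credible set; empty
credible sets are skipped with a warning in platform-capture summaries;
windows never span chromosomes.

Test and acceptance problem sizes are chosen so the whole suite runs in a
few minutes while keeping Monte-Carlo error well below the asserted
margins: enrichment recovery uses 300 windows × 100 SNPs × 50 replicates;
the HMM recovery 10⁴ bins; segmentation two 1 Mb chromosomes at 85x; the
permutation null 100 replicates × 1000 permutations (production analyses
use 10⁵); binomial test calibration 10⁴ replicates. Stochastic assertions
are placed at ~3σ of their Monte-Carlo error. One fitting case deserves a
note: when all marks are i.i.d., a two-state HMM is non-identifiable (any
stationary mixture reproducing the marginals has identical likelihood), so
individual emission vectors are not testable quantities; the tests assert
the identifiable stationary-weighted emission mean instead.
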