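#' Simulation configuration with planted ground truth parameters
#'
#' Bundles every parameter of the synthetic-data generators. Defaults emulate
#' the study conditions the pipeline is designed for: 10 WGBS samples at
#' ~8.5x each (85x pooled), a mostly hypermethylated genome with planted
#' CpG-rich unmethylated regions (UMRs, promoter-like) and CpG-poor
#' low-methylated regions (LMRs, enhancer-like), ChIP/ATAC count tracks
#' emitted from a hidden chromatin-state path over 200 bp bins, GWAS summary
#' statistics under a single-causal-variant-per-window model with
#' annotation-dependent priors, and allele-specific ATAC read counts over 17
#' samples.
#'
#' @param genome_length Length of each simulated chromosome in bp.
#' @param n_chroms Number of chromosomes.
#' @param cpg_density Background CpG density, CpGs per kb.
#' @param n_wgbs_samples Number of WGBS samples pooled downstream.
#' @param per_sample_coverage Mean reads per CpG per sample (Poisson).
#' @param n_umr,n_lmr Number of planted UMRs / LMRs per chromosome.
#' @param n_marks Number of ChIP marks in the simulated track matrix.
#' @param bin_size Genomic bin size in bp for the state path and tracks.
#' @param n_states_true Number of hidden chromatin states in the generator.
#' @param n_regions Number of GWAS windows (regions).
#' @param snps_per_region SNPs per GWAS window.
#' @param region_prior_true Probability that a window contains a causal SNP
#'   (the region prior of the hierarchical model).
#' @param gamma_true Named vector of per-annotation log-enrichments (natural
#'   log) used to place causal SNPs preferentially inside annotations.
#' @param abf_prior_variance Effect-size prior variance W of the causal
#'   effect distribution.
#' @param se_gwas Constant per-SNP standard error of the observed effect.
#' @param n_atac_samples Number of ATAC samples for allele-specific counts.
#' @param allele_freq Allele frequency of allelic-imbalance variants; each
#'   sample is heterozygous with probability `2f(1-f)`.
#' @param n_ai_variants Number of variants with allele-specific counts.
#' @param ai_ratio_true True reference-allele ratio(s), recycled over
#'   variants; must lie strictly in (0, 1).
#' @param ai_mean_depth Mean per-heterozygote read depth (Poisson).
#' @param seed Integer seed; a fixed seed makes every generator
#'   byte-reproducible. Each generator uses `seed` plus a fixed per-generator
#'   offset so stages do not share a stream.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 1e6, n_chroms = 2L, cpg_density = 10,
                       n_wgbs_samples = 10L, per_sample_coverage = 8.5,
                       n_umr = 8L, n_lmr = 20L,
                       n_marks = 2L, bin_size = 200L, n_states_true = 3L,
                       n_regions = 300L, snps_per_region = 100L,
                       region_prior_true = 0.5,
                       gamma_true = c(annot = 2.0),
                       abf_prior_variance = 0.1, se_gwas = 0.03,
                       n_atac_samples = 17L, allele_freq = 0.3,
                       n_ai_variants = 20L, ai_ratio_true = 0.5,
                       ai_mean_depth = 18,
                       seed = 1L) {
  cfg <- list(
    genome_length = genome_length, n_chroms = as.integer(n_chroms),
    cpg_density = cpg_density, n_wgbs_samples = as.integer(n_wgbs_samples),
    per_sample_coverage = per_sample_coverage,
    n_umr = as.integer(n_umr), n_lmr = as.integer(n_lmr),
    n_marks = as.integer(n_marks), bin_size = as.integer(bin_size),
    n_states_true = as.integer(n_states_true),
    n_regions = as.integer(n_regions),
    snps_per_region = as.integer(snps_per_region),
    region_prior_true = region_prior_true, gamma_true = gamma_true,
    abf_prior_variance = abf_prior_variance, se_gwas = se_gwas,
    n_atac_samples = as.integer(n_atac_samples), allele_freq = allele_freq,
    n_ai_variants = as.integer(n_ai_variants), ai_ratio_true = ai_ratio_true,
    ai_mean_depth = ai_mean_depth, seed = as.integer(seed)
  )
  counts <- c("genome_length", "n_chroms", "n_wgbs_samples", "n_marks",
              "bin_size", "n_states_true", "n_regions", "snps_per_region",
              "n_atac_samples", "n_ai_variants")
  for (f in counts) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0) {
      stop("invalid config: '", f, "' must be positive")
    }
  }
  if (cfg$cpg_density <= 0) stop("invalid config: zero CpG density")
  if (cfg$per_sample_coverage <= 0) stop("invalid config: zero coverage")
  for (f in c("region_prior_true", "allele_freq")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop("invalid config: '", f, "' must be a probability in [0,1]")
    }
  }
  if (any(cfg$ai_ratio_true <= 0 | cfg$ai_ratio_true >= 1)) {
    stop("invalid config: 'ai_ratio_true' must lie strictly in (0,1)")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Chromosome sizes of a simulated genome
#' @param config A [sim_config()].
#' @return Named numeric vector of chromosome lengths.
#' @export
sim_chrom_sizes <- function(config) {
  stats::setNames(rep(config$genome_length, config$n_chroms),
                  paste0("chr", seq_len(config$n_chroms)))
}

## disjoint placement slots for planted regions along one chromosome
.plant_slots <- function(genome_length, n, margin = 2000) {
  width <- floor((genome_length - 2 * margin) / n)
  data.table::data.table(
    lo = margin + (seq_len(n) - 1L) * width,
    hi = margin + seq_len(n) * width
  )
}

#' Simulate a pooled-truth WGBS methylome with planted UMRs and LMRs
#'
#' Background CpGs are heavily methylated (per-CpG true beta ~ U(0.8, 0.95));
#' planted UMRs are CpG-rich with >30 CpGs and beta ~ U(0.05, 0.2); planted
#' LMRs are CpG-poor with <30 CpGs and beta ~ U(0.1, 0.4). Per sample and
#' CpG, total reads are Poisson(`per_sample_coverage`) and methylated reads
#' Binomial(total, beta_true).
#'
#' @param config A [sim_config()].
#' @return A list with `cpg` (long `data.table`: `chrom`, `pos`,
#'   `meth_count`, `unmeth_count`, `sample_id`), `truth` (planted intervals:
#'   `chrom`, `start`, `end`, `klass`, `n_cpg`, `beta_true`) and `cpg_truth`
#'   (per-CpG true beta).
#' @export
generate_methylome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 101L)
  sizes <- sim_chrom_sizes(config)
  cpg_list <- truth_list <- vector("list", length(sizes))
  for (ci in seq_along(sizes)) {
    cc <- names(sizes)[ci]
    gl <- sizes[[ci]]
    n_bg <- round(gl / 1000 * config$cpg_density)
    bg_pos <- sort(unique(floor(runif(n_bg, 0, gl - 1))))
    n_reg <- config$n_umr + config$n_lmr
    slots <- .plant_slots(gl, n_reg)
    klass <- sample(rep(c("UMR", "LMR"), c(config$n_umr, config$n_lmr)))
    regs <- vector("list", n_reg)
    for (ri in seq_len(n_reg)) {
      if (klass[ri] == "UMR") {
        len <- runif(1, 1500, 2500)
        ncp <- sample(35:70, 1)
        b <- runif(1, 0.05, 0.2)
      } else {
        len <- runif(1, 600, 1200)
        ncp <- sample(10:25, 1)
        b <- runif(1, 0.1, 0.4)
      }
      len <- min(len, slots$hi[ri] - slots$lo[ri] - 10)
      s <- floor(runif(1, slots$lo[ri], slots$hi[ri] - len))
      pos <- sort(sample(seq.int(s, s + len - 2L), ncp))
      regs[[ri]] <- data.table::data.table(
        pos = pos, beta_true = b, klass = klass[ri], region = ri
      )
    }
    reg_dt <- data.table::rbindlist(regs)
    truth <- reg_dt[, .(start = min(pos), end = max(pos) + 2L,
                        n_cpg = .N, beta_true = beta_true[1L],
                        klass = klass[1L]), by = region]
    ## drop background CpGs inside or within 100 bp of a planted region
    buf <- 100L
    keep <- !.point_in_bed(rep(cc, length(bg_pos)), bg_pos,
                           data.table::data.table(chrom = cc,
                                                  start = truth$start - buf,
                                                  end = truth$end + buf))
    bg <- data.table::data.table(pos = bg_pos[keep],
                                 beta_true = runif(sum(keep), 0.8, 0.95))
    all_cpg <- rbind(bg, reg_dt[, .(pos, beta_true)])[order(pos)]
    all_cpg[, chrom := cc]
    cpg_list[[ci]] <- all_cpg
    truth[, chrom := cc]
    truth_list[[ci]] <- truth[, .(chrom, start, end, klass, n_cpg, beta_true)]
  }
  cpg_truth <- data.table::rbindlist(cpg_list)[, .(chrom, pos, beta_true)]
  samples <- vector("list", config$n_wgbs_samples)
  n <- nrow(cpg_truth)
  for (s in seq_len(config$n_wgbs_samples)) {
    tot <- rpois(n, config$per_sample_coverage)
    m <- rbinom(n, tot, cpg_truth$beta_true)
    samples[[s]] <- data.table::data.table(
      chrom = cpg_truth$chrom, pos = cpg_truth$pos,
      meth_count = m, unmeth_count = tot - m,
      sample_id = sprintf("wgbs%02d", s)
    )
  }
  list(cpg = data.table::rbindlist(samples),
       truth = data.table::rbindlist(truth_list),
       cpg_truth = cpg_truth)
}

#' Simulate a hidden chromatin-state path and its emission truth
#'
#' States follow a sticky Markov chain over fixed-size bins, shared across
#' chromosomes. State 1 is quiescent (no marks) and dominates the
#' stationary distribution, as in real genomes where marked chromatin
#' covers a small fraction of bins; higher states switch on successively
#' more ChIP marks; the last state additionally has open chromatin (ATAC)
#' and hypomethylation.
#'
#' @param config A [sim_config()].
#' @param stay_quiescent Self-transition probability of the quiescent state
#'   (default 0.99).
#' @param stay_active Self-transition probability of marked states (default
#'   0.85; leaving mass returns mostly to quiescent, so marked states cover
#'   roughly 5-10% of bins).
#' @param lambda_signal,lambda_bg Poisson mean read count per bin for a mark
#'   that is present / absent in a state.
#' @return List with `path` (list of per-chromosome state index vectors),
#'   `chip_presence` (state x mark 0/1), `atac_state`, `hypometh_state`
#'   (logical per state), `lambda` (state x mark Poisson means) and the
#'   transition matrix used.
#' @export
generate_state_path <- function(config, stay_quiescent = 0.99,
                                stay_active = 0.85,
                                lambda_signal = 30, lambda_bg = 5) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 102L)
  S <- config$n_states_true
  M <- config$n_marks
  ## state s turns on marks 1..(s-1), capped at M; last state is "open"
  chip <- matrix(0L, S, M,
                 dimnames = list(paste0("S", seq_len(S)),
                                 paste0("mark", seq_len(M))))
  for (s in seq_len(S)[-1L]) chip[s, seq_len(min(s - 1L, M))] <- 1L
  atac <- seq_len(S) == S
  hypometh <- seq_len(S) == S
  trans <- matrix(0, S, S)
  trans[1L, ] <- c(stay_quiescent,
                   rep((1 - stay_quiescent) / (S - 1), S - 1L))
  for (s in seq_len(S)[-1L]) {
    row <- numeric(S)
    row[s] <- stay_active
    others <- setdiff(seq_len(S)[-1L], s)
    if (length(others)) {
      row[1L] <- (1 - stay_active) * 0.8
      row[others] <- (1 - stay_active) * 0.2 / length(others)
    } else {
      row[1L] <- 1 - stay_active
    }
    trans[s, ] <- row
  }
  sizes <- sim_chrom_sizes(config)
  path <- lapply(sizes, function(gl) {
    Tn <- floor(gl / config$bin_size)
    st <- integer(Tn)
    st[1L] <- 1L   # chains start in the dominant quiescent state
    for (t in seq_len(Tn)[-1L]) {
      st[t] <- sample.int(S, 1L, prob = trans[st[t - 1L], ])
    }
    st
  })
  lambda <- ifelse(chip == 1L, lambda_signal, lambda_bg)
  list(path = path, chip_presence = chip, atac_state = atac,
       hypometh_state = hypometh, lambda = lambda, transitions = trans)
}

#' Simulate per-bin ChIP count tracks and ATAC peaks from a planted path
#'
#' Per bin and mark, read counts are Poisson with the state's mean; ATAC
#' peaks are emitted over maximal runs of bins whose state has open
#' chromatin.
#'
#' @param config A [sim_config()].
#' @param truth Output of [generate_state_path()].
#' @return List with `counts` (list of per-chromosome bin x mark count
#'   matrices), `atac_peaks` (BED `data.table`) and `bins` (bin coordinate
#'   table).
#' @export
generate_tracks <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(c("path", "lambda") %in% names(truth))) {
    stop("truth must come from generate_state_path()")
  }
  if (ncol(truth$lambda) != config$n_marks ||
      nrow(truth$lambda) != config$n_states_true) {
    stop("dimension mismatch between truth state model and config")
  }
  set.seed(config$seed + 103L)
  sizes <- sim_chrom_sizes(config)
  if (length(truth$path) != length(sizes)) {
    stop("dimension mismatch: truth path has ", length(truth$path),
         " chromosomes, config has ", length(sizes))
  }
  counts <- vector("list", length(sizes))
  names(counts) <- names(sizes)
  peak_list <- list()
  for (ci in seq_along(sizes)) {
    st <- truth$path[[ci]]
    Tn <- length(st)
    lam <- truth$lambda[st, , drop = FALSE]
    cnt <- matrix(rpois(length(lam), lam), nrow = Tn,
                  dimnames = list(NULL, colnames(truth$lambda)))
    counts[[ci]] <- cnt
    open <- truth$atac_state[st]
    if (any(open)) {
      r <- rle(open)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      sel <- which(r$values)
      peak_list[[length(peak_list) + 1L]] <- data.table::data.table(
        chrom = names(sizes)[ci],
        start = (starts[sel] - 1L) * config$bin_size,
        end = ends[sel] * config$bin_size
      )
    }
  }
  bins <- genome_bins(sizes, config$bin_size)
  atac <- if (length(peak_list)) data.table::rbindlist(peak_list) else
    data.table::data.table(chrom = character(), start = integer(),
                           end = integer())
  list(counts = counts, atac_peaks = atac, bins = bins)
}

#' Simulate annotation intervals covering a target fraction of the genome
#'
#' @param config A [sim_config()].
#' @param fraction Fraction of each chromosome covered by the annotation.
#' @param n_intervals Number of intervals per chromosome.
#' @param seed_offset Offset added to `config$seed` for this draw.
#' @return BED `data.table`.
#' @export
generate_annotation <- function(config, fraction = 0.05, n_intervals = 50L,
                                seed_offset = 110L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + seed_offset)
  sizes <- sim_chrom_sizes(config)
  out <- lapply(names(sizes), function(cc) {
    gl <- sizes[[cc]]
    len <- max(1, floor(gl * fraction / n_intervals))
    slots <- .plant_slots(gl, n_intervals, margin = 0)
    s <- floor(runif(n_intervals, slots$lo, pmax(slots$lo + 1, slots$hi - len)))
    data.table::data.table(chrom = cc, start = s, end = s + len)
  })
  data.table::rbindlist(out)[order(chrom, start)]
}

#' Simulate GWAS summary statistics under a single-causal-variant model
#'
#' Each window (region of `snps_per_region` consecutive SNPs) contains a
#' causal SNP with probability `region_prior_true`. The causal SNP is chosen
#' with probability proportional to `exp(sum_k gamma_k x_ik)` over its
#' annotation memberships, its effect is Normal(0, `abf_prior_variance`),
#' and every observed effect adds Normal(0, `se_gwas`^2) noise.
#'
#' @param config A [sim_config()]; `names(config$gamma_true)` must match
#'   `names(annotations)` (annotations without a gamma get 0).
#' @param annotations Named list of BED `data.table`s.
#' @return List with `snps` (`data.table`: `snp_id`, `chrom`, `pos`,
#'   `beta_hat`, `se`, `z`, `p`, `region_id`, one logical column per
#'   annotation) and `truth` (`region_id`, `causal_snp`).
#' @export
generate_gwas <- function(config, annotations = list()) {
  stopifnot(inherits(config, "sim_config"))
  sizes <- sim_chrom_sizes(config)
  for (a in annotations) {
    a <- data.table::as.data.table(a)
    if (any(!a$chrom %in% names(sizes)) ||
        any(a$end > sizes[a$chrom] | a$start < 0)) {
      stop("annotation intervals outside the simulated genome")
    }
  }
  set.seed(config$seed + 104L)
  n_total <- config$n_regions * config$snps_per_region
  per_chrom <- diff(round(seq(0, n_total, length.out = config$n_chroms + 1L)))
  snps <- data.table::rbindlist(lapply(seq_len(config$n_chroms), function(ci) {
    data.table::data.table(
      chrom = names(sizes)[ci],
      pos = sort(sample.int(sizes[[ci]] - 1L, per_chrom[ci]))
    )
  }))
  snps[, snp_id := sprintf("snp%06d", seq_len(.N))]
  snps <- segment_genome(snps, k = config$snps_per_region)
  gam <- config$gamma_true
  X <- matrix(0, nrow(snps), length(annotations),
              dimnames = list(NULL, names(annotations)))
  for (nm in names(annotations)) {
    X[, nm] <- as.numeric(.point_in_bed(snps$chrom, snps$pos,
                                        annotations[[nm]]))
    data.table::set(snps, j = nm, value = X[, nm] > 0)
  }
  g <- rep(0, length(annotations))
  names(g) <- names(annotations)
  g[intersect(names(gam), names(g))] <- gam[intersect(names(gam), names(g))]
  w <- if (length(annotations)) exp(as.vector(X %*% g)) else rep(1, nrow(snps))
  se_const <- config$se_gwas
  snps[, beta_hat := rnorm(.N, 0, se_const)]
  regs <- split(seq_len(nrow(snps)), snps$region_id)
  causal <- rep(NA_character_, length(regs))
  names(causal) <- names(regs)
  for (r in names(regs)) {
    if (rbinom(1L, 1L, config$region_prior_true) == 1L) {
      idx <- regs[[r]]
      ci <- if (length(idx) == 1L) idx else
        sample(idx, 1L, prob = w[idx])
      eff <- rnorm(1L, 0, sqrt(config$abf_prior_variance))
      snps$beta_hat[ci] <- snps$beta_hat[ci] + eff
      causal[r] <- snps$snp_id[ci]
    }
  }
  snps[, se := se_const]
  snps[, z := beta_hat / se]
  snps[, p := 2 * pnorm(-abs(z))]
  list(snps = snps[],
       truth = data.table::data.table(region_id = names(causal),
                                      causal_snp = unname(causal)))
}

#' Simulate allele-specific ATAC read counts with planted imbalance
#'
#' Per variant, each sample is heterozygous with probability `2f(1-f)`;
#' heterozygote depth is Poisson(`ai_mean_depth`) and reference reads are
#' Binomial(depth, `ai_ratio_true`).
#'
#' @param config A [sim_config()].
#' @return List with `counts` (long `data.table`: `snp_id`, `sample_id`,
#'   `ref_count`, `alt_count`, `het`) and `truth` (`snp_id`, `ratio_true`).
#' @export
generate_allelic_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 105L)
  f <- config$allele_freq
  p_het <- 2 * f * (1 - f)
  ratio <- rep_len(config$ai_ratio_true, config$n_ai_variants)
  ids <- sprintf("var%04d", seq_len(config$n_ai_variants))
  out <- vector("list", config$n_ai_variants)
  for (v in seq_len(config$n_ai_variants)) {
    het <- rbinom(config$n_atac_samples, 1L, p_het) == 1L
    depth <- ifelse(het, rpois(config$n_atac_samples, config$ai_mean_depth), 0L)
    ref <- rbinom(config$n_atac_samples, depth, ratio[v])
    out[[v]] <- data.table::data.table(
      snp_id = ids[v],
      sample_id = sprintf("atac%02d", seq_len(config$n_atac_samples)),
      ref_count = ref, alt_count = depth - ref, het = het
    )
  }
  list(counts = data.table::rbindlist(out),
       truth = data.table::data.table(snp_id = ids, ratio_true = ratio))
}
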