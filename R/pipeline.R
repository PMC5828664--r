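#' Run the full synthetic-data analysis pipeline
#'
#' Exercises every stage end to end on one simulated dataset: methylome
#' simulation, pooling and LMR/UMR segmentation; state-path/track
#' simulation, binarisation and HMM chromatin-state learning, decoding and
#' labelling; GWAS simulation, ABFs, single and joint enrichment fits;
#' PPA reweighting, significant segments and credible sets under the
#' annotation model versus the annotation-free baseline; permutation
#' overlap enrichment of called LMRs in the planted enhancer annotation;
#' and allelic-imbalance testing. All stage artifacts are written as
#' TSV/BED into `outdir` together with a resolved-parameter record.
#'
#' @param config A [sim_config()]; its `seed` drives every stage.
#' @param outdir Output directory (created if missing); `NULL` to skip
#'   writing.
#' @param n_states Number of HMM states to learn (default
#'   `config$n_states_true`).
#' @param n_perm Permutations for the overlap enrichment stage.
#' @return Invisible list with every stage result.
#' @export
run_pipeline <- function(config = sim_config(), outdir = NULL,
                         n_states = config$n_states_true, n_perm = 500L) {
  sizes <- sim_chrom_sizes(config)

  ## methylome
  meth <- generate_methylome(config)
  pooled <- pool_samples(meth$cpg)
  regions_called <- segment_hypomethylated(pooled, seed = config$seed + 201L)

  ## chromatin states
  truth_path <- generate_state_path(config)
  tracks <- generate_tracks(config, truth_path)
  chip_bin <- lapply(seq_len(config$n_marks), function(m) {
    flags <- lapply(tracks$counts, function(cnt) binarize_chip(cnt[, m]))
    stats::setNames(flags, names(tracks$counts))
  })
  names(chip_bin) <- colnames(truth_path$lambda)
  atac_bin <- binarize_atac(tracks$atac_peaks, sizes, config$bin_size)
  meth_bin <- binarize_methylation(pooled, sizes, config$bin_size)
  bt <- bind_tracks(c(chip_bin, list(atac = atac_bin, hypometh = meth_bin)))
  model <- learn_model(bt, n_states = n_states, n_restarts = 3L,
                       seed = config$seed + 202L)
  model <- label_states(model)
  decoded <- decode_states(model, bt)

  ## GWAS enrichment + fine-mapping
  enhancer_ann <- generate_annotation(config, fraction = 0.05)
  gwas <- generate_gwas(config, annotations = list(annot = enhancer_ann))
  snps <- gwas$snps
  snps[, ln_abf := compute_abf(beta_hat, se)]
  fit1 <- fit_single(snps, "annot")
  res_full <- snp_ppa(snps, fit1)
  res_base <- snp_ppa(snps, list(kappa = fit1$kappa,
                                 gamma = stats::setNames(0, "annot")))
  segs <- significant_segments(res_full$regions, res_full$snps)
  cs <- credible_sets(res_full, regions = segs[flagged == TRUE, region_id])
  cmp <- compare_models(res_full, res_base,
                        regions = segs[flagged == TRUE, region_id])

  ## overlap enrichment of called LMRs in the planted enhancer annotation
  lmr_bed <- regions_called[klass == "LMR", .(chrom, start, end)]
  overlap <- if (nrow(lmr_bed)) {
    permutation_enrichment(lmr_bed, enhancer_ann, sizes, n_perm = n_perm,
                           seed = config$seed + 203L)
  } else NULL

  ## allelic imbalance
  ai <- generate_allelic_counts(config)
  variants <- data.table::data.table(
    snp_id = ai$truth$snp_id, ppa = 0.5, in_enriched_annotation = TRUE
  )
  sel <- select_test_variants(variants, ai$counts)
  ai_res <- ai_test(sel)

  out <- list(config = config, pooled = pooled,
              hypomethylated_regions = regions_called,
              state_model = model, decoded = decoded,
              enrichment_fit = fit1, ppa_full = res_full,
              ppa_baseline = res_base, segments = segs,
              credible_sets = cs, model_comparison = cmp,
              overlap_enrichment = overlap, ai_results = ai_res,
              truths = list(methylome = meth$truth,
                            state_path = truth_path,
                            gwas = gwas$truth, ai = ai$truth))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    w <- function(x, f) write_table_tsv(x, file.path(outdir, f))
    w(pooled, "pooled_cpg.tsv")
    w(regions_called, "hypomethylated_regions.tsv")
    write_bed(regions_called[, .(chrom, start, end, name = klass)],
              file.path(outdir, "hypomethylated_regions.bed"))
    w(data.table::as.data.table(model$emissions, keep.rownames = "state"),
      "state_emissions.tsv")
    w(data.table::as.data.table(model$transitions), "state_transitions.tsv")
    w(data.table::data.table(state = rownames(model$emissions),
                             label = model$labels), "state_labels.tsv")
    w(res_full$snps, "snp_ppa.tsv")
    w(segs, "segments.tsv")
    w(cs, "credible_sets.tsv")
    w(ai_res, "allelic_imbalance.tsv")
    cfg <- data.table::data.table(
      parameter = names(unclass(config)),
      value = vapply(unclass(config), function(v)
        paste(format(v), collapse = ","), character(1))
    )
    w(cfg, "resolved_config.tsv")
  }
  invisible(out)
}
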