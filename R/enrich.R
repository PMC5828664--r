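#' Log approximate Bayes factor for association at a SNP
#'
#' Wakefield-style approximate Bayes factor from an effect estimate and its
#' standard error under a Normal(0, W) effect-size prior, averaged over a
#' set of prior variances W:
#' `ln ABF_W = 0.5 ln(V/(V+W)) + z^2 W / (2(V+W))` with `V = se^2`, and the
#' returned value is the log of the arithmetic mean of `ABF_W` over
#' `prior_variances`. Values above 0 favour association. For case-control
#' traits `beta_hat` is the log odds ratio; the functional form is shared.
#'
#' @param beta_hat Effect estimate(s).
#' @param se Standard error(s), > 0.
#' @param prior_variances Prior variances averaged over (default
#'   `c(0.01, 0.1, 0.5)`).
#' @param trait_type `"case_control"` or `"quantitative"` (same ABF form;
#'   recorded for interface clarity).
#' @return Vector of log ABFs.
#' @export
compute_abf <- function(beta_hat, se, prior_variances = c(0.01, 0.1, 0.5),
                        trait_type = c("case_control", "quantitative")) {
  match.arg(trait_type)
  if (any(!is.finite(beta_hat)) || any(!is.finite(se))) {
    stop("non-finite inputs to compute_abf")
  }
  if (any(se <= 0)) stop("standard errors must be positive")
  V <- se^2
  z2 <- (beta_hat / se)^2
  lab <- vapply(prior_variances, function(W) {
    0.5 * log(V / (V + W)) + z2 * W / (2 * (V + W))
  }, numeric(length(beta_hat)))
  lab <- matrix(lab, nrow = length(beta_hat))
  m <- apply(lab, 1L, max)
  m + log(rowMeans(exp(lab - m)))
}

#' Partition SNPs into windows of k consecutive SNPs
#'
#' SNPs are sorted by `(chrom, pos)` and cut into consecutive blocks of `k`
#' per chromosome (windows never span chromosomes; the final partial block
#' on each chromosome is kept).
#'
#' @param snps `data.table` with at least `chrom`, `pos`.
#' @param k SNPs per window (default 5000).
#' @return The sorted table with a `region_id` column added.
#' @export
segment_genome <- function(snps, k = 5000L) {
  snps <- data.table::as.data.table(snps)[order(chrom, pos)]
  snps[, region_id := sprintf("%s_w%04d", chrom,
                              ceiling(seq_len(.N) / k)), by = chrom]
  snps[]
}

## Pattern-collapsed representation of the hierarchical likelihood.
## Within region r, the conditional causal prior is
##   pi_i = exp(g . x_i) / sum_j exp(g . x_j)
## and the region likelihood
##   L_r = (1 - Pi) + Pi * sum_i pi_i * ABF_i.
## Because x_i is binary over K annotations there are at most 2^K distinct
## linear predictors, so sum_j exp(g . x_j) = N[r, ] %*% exp(val) and
## sum_i exp(g . x_i) ABF_i = S[r, ] %*% exp(val) * exp(M_r), where N counts
## SNPs per (region, pattern), S sums exp(ln_abf - M_r) per (region,
## pattern) and M_r is the per-region max ln ABF (overflow guard). Each
## likelihood evaluation is then two small matrix products.
.enrich_data <- function(snps, annotations) {
  snps <- data.table::as.data.table(snps)
  stopifnot(all(c("region_id", "ln_abf") %in% names(snps)))
  K <- length(annotations)
  if (K) {
    X <- vapply(annotations, function(a) as.numeric(snps[[a]]),
                numeric(nrow(snps)))
    X <- matrix(X, nrow = nrow(snps), dimnames = list(NULL, annotations))
  } else {
    X <- matrix(0, nrow(snps), 0L)
  }
  key <- if (K) as.vector(X %*% 2^(seq_len(K) - 1L)) else rep(0, nrow(snps))
  pid <- match(key, sort(unique(key)))
  P <- max(pid)
  Xp <- matrix(0, P, K, dimnames = list(NULL, annotations))
  for (pp in seq_len(P)) Xp[pp, ] <- X[match(pp, pid), , drop = TRUE]
  g <- match(snps$region_id, unique(snps$region_id))
  R <- max(g)
  M <- as.vector(tapply(snps$ln_abf, factor(g, levels = seq_len(R)), max))
  w <- exp(snps$ln_abf - M[g])
  cell <- (g - 1L) * P + pid
  Nm <- matrix(0, R, P)
  Sm <- matrix(0, R, P)
  cnt <- rowsum(rep(1, length(cell)), cell)
  ws <- rowsum(w, cell)
  idx <- as.integer(rownames(cnt))
  Nm[cbind((idx - 1L) %/% P + 1L, (idx - 1L) %% P + 1L)] <- cnt[, 1L]
  Sm[cbind((idx - 1L) %/% P + 1L, (idx - 1L) %% P + 1L)] <- ws[, 1L]
  list(N = Nm, S = Sm, M = M, Xp = Xp, annotations = annotations,
       region_ids = unique(snps$region_id), snps = snps, X = X,
       region_index = g)
}

## per-region log-likelihood vector at (kappa, gamma)
.region_loglik <- function(dat, kappa, gamma) {
  val <- if (ncol(dat$Xp)) as.vector(dat$Xp %*% gamma) else 0
  vmax <- max(val)
  ev <- exp(val - vmax)
  denom <- log(as.vector(dat$N %*% ev)) + vmax
  num <- log(as.vector(dat$S %*% ev)) + vmax + dat$M
  s_r <- num - denom                      # log sum_i pi_i ABF_i
  lpi <- plogis(kappa, log.p = TRUE)
  l1m <- plogis(-kappa, log.p = TRUE)
  .lse2(rep(l1m, length(s_r)), lpi + s_r)
}

.enrich_loglik <- function(dat, kappa, gamma, penalty = 0) {
  sum(.region_loglik(dat, kappa, gamma)) - penalty * sum(abs(gamma))
}

## maximise over (kappa, gamma[include]); gamma outside `include` fixed at 0
.enrich_fit <- function(dat, include = dat$annotations, penalty = 0,
                        gamma_bound = 20) {
  K <- length(dat$annotations)
  ki <- match(include, dat$annotations)
  par0 <- c(qlogis(0.3), rep(0, length(ki)))
  obj <- function(par) {
    gamma <- rep(0, K)
    gamma[ki] <- pmin(gamma_bound, pmax(-gamma_bound, par[-1L]))
    -.enrich_loglik(dat, par[1L], gamma, penalty)
  }
  opt <- optim(par0, obj, method = "BFGS",
               control = list(maxit = 300, reltol = 1e-10))
  gamma <- rep(0, K)
  names(gamma) <- dat$annotations
  gamma[ki] <- pmin(gamma_bound, pmax(-gamma_bound, opt$par[-1L]))
  list(kappa = opt$par[1L], gamma = gamma,
       loglik = .enrich_loglik(dat, opt$par[1L], gamma, 0),
       loglik_pen = -opt$value, convergence = opt$convergence)
}

## profile-likelihood 95% CI for one annotation (natural-log scale),
## profiling kappa and the other included gammas
.profile_ci <- function(dat, include, ann, fit, gamma_bound = 20) {
  drop_chi <- qchisq(0.95, 1) / 2
  target <- fit$loglik - drop_chi
  ki <- match(include, dat$annotations)
  ai <- match(ann, dat$annotations)
  others <- setdiff(ki, ai)
  prof <- function(gfix) {
    if (!length(others)) {
      o <- optimize(function(kap) {
        gamma <- rep(0, length(dat$annotations))
        gamma[ai] <- gfix
        .enrich_loglik(dat, kap, gamma)
      }, interval = c(-20, 10), maximum = TRUE)
      o$objective
    } else {
      par0 <- c(fit$kappa, fit$gamma[others])
      o <- optim(par0, function(par) {
        gamma <- rep(0, length(dat$annotations))
        gamma[others] <- pmin(gamma_bound, pmax(-gamma_bound, par[-1L]))
        gamma[ai] <- gfix
        -.enrich_loglik(dat, par[1L], gamma)
      }, method = "BFGS", control = list(maxit = 200, reltol = 1e-9))
      -o$value
    }
  }
  ghat <- fit$gamma[ai]
  side <- function(bound) {
    f_end <- prof(bound) - target
    if (f_end > 0) return(c(bound, TRUE))   # boundary hit
    root <- uniroot(function(g) prof(g) - target,
                    interval = sort(c(ghat, bound)), tol = 1e-4)
    c(root$root, FALSE)
  }
  lo <- side(-gamma_bound)
  hi <- side(gamma_bound)
  list(lo = lo[1L], hi = hi[1L], boundary = c(lo[2L], hi[2L]) > 0)
}

#' Region log-likelihood of the hierarchical enrichment model
#'
#' Computes `ln L_r` for each window: each window either contains exactly
#' one causal SNP (with probability `Pi = plogis(kappa)`, the causal SNP
#' drawn with annotation-weighted conditional prior
#' `pi_i = exp(g.x_i)/sum_j exp(g.x_j)`) or none, so
#' `L_r = (1 - Pi) + Pi * sum_i pi_i ABF_i`, evaluated in log space.
#'
#' @param snps `data.table` with `region_id`, `ln_abf` and one
#'   logical/0-1 column per annotation.
#' @param kappa Region-prior intercept (`Pi = plogis(kappa)`).
#' @param gamma Named vector of annotation log-enrichments (natural log);
#'   names select the annotation columns of `snps`.
#' @return Named vector of per-region log-likelihoods.
#' @export
region_ln_likelihood <- function(snps, kappa, gamma = numeric()) {
  dat <- .enrich_data(snps, names(gamma))
  ll <- .region_loglik(dat, kappa, gamma[dat$annotations])
  stats::setNames(ll, dat$region_ids)
}

.new_enrichment_fit <- function(dat, fit, include, ci, penalty) {
  ln2 <- log(2)
  g <- fit$gamma[include]
  lo <- vapply(ci, `[[`, numeric(1), "lo")
  hi <- vapply(ci, `[[`, numeric(1), "hi")
  structure(list(
    kappa = fit$kappa, pi = plogis(fit$kappa),
    gamma = g,
    log2fe = g / ln2, ci_lo = lo / ln2, ci_hi = hi / ln2,
    boundary = lapply(ci, `[[`, "boundary"),
    significant = lo > 0,
    ln_likelihood = fit$loglik, penalty = penalty,
    included = include, data = dat
  ), class = "enrichment_fit")
}

#' @export
print.enrichment_fit <- function(x, ...) {
  cat("Hierarchical enrichment fit: Pi =", signif(x$pi, 3),
      " lnL =", format(x$ln_likelihood), "\n")
  if (length(x$included)) {
    print(data.frame(annotation = x$included,
                     log2FE = round(x$log2fe, 2),
                     ci_lo = round(x$ci_lo, 2), ci_hi = round(x$ci_hi, 2),
                     significant = x$significant, row.names = NULL))
  } else {
    cat("(intercept-only model)\n")
  }
  invisible(x)
}

#' Single-annotation enrichment fit
#'
#' Maximises the hierarchical window likelihood over the region-prior
#' intercept and one annotation's log-enrichment by quasi-Newton
#' optimisation; the 95% CI comes from the profile likelihood (bounds where
#' the profile log-likelihood drops by 1.92). An annotation is significant
#' when the lower CI bound is above zero. Estimates are reported as log2
#' fold enrichment (natural-log internally). Gamma is bounded to [-20, 20];
#' a CI endpoint at the bound is flagged in `boundary`.
#'
#' @param snps `data.table` with `region_id`, `ln_abf` and a logical
#'   annotation column.
#' @param annotation Name of the annotation column.
#' @return An `enrichment_fit` object.
#' @export
fit_single <- function(snps, annotation) {
  snps <- data.table::as.data.table(snps)
  if (!annotation %in% names(snps)) stop("unknown annotation: ", annotation)
  cov <- mean(as.numeric(snps[[annotation]]) > 0)
  if (cov == 0 || cov == 1) {
    stop("unidentifiable annotation '", annotation,
         "': covers ", if (cov == 0) "no" else "all", " SNPs")
  }
  dat <- .enrich_data(snps, annotation)
  fit <- .enrich_fit(dat, include = annotation)
  ci <- list(.profile_ci(dat, annotation, annotation, fit))
  names(ci) <- annotation
  .new_enrichment_fit(dat, fit, annotation, ci, penalty = 0)
}

## cross-validated log-likelihood of an annotation set at a given penalty
.cv_loglik <- function(dat, include, penalty, folds) {
  sum(vapply(seq_along(folds), function(f) {
    train <- .subset_dat(dat, setdiff(seq_along(dat$M), folds[[f]]))
    test <- .subset_dat(dat, folds[[f]])
    ft <- .enrich_fit(train, include, penalty)
    .enrich_loglik(test, ft$kappa, ft$gamma, 0)
  }, numeric(1)))
}

.subset_dat <- function(dat, rows) {
  list(N = dat$N[rows, , drop = FALSE], S = dat$S[rows, , drop = FALSE],
       M = dat$M[rows], Xp = dat$Xp, annotations = dat$annotations,
       region_ids = dat$region_ids[rows])
}

#' Joint multi-annotation enrichment model with penalised cross-validation
#'
#' Candidates (typically annotations significant in [fit_single()]) enter a
#' forward selection by maximum log-likelihood gain; an L1 penalty weight is
#' then chosen by 10-fold cross-validation over regions; finally backward
#' elimination drops annotations while the cross-validation likelihood
#' improves. Per-annotation estimates and profile CIs of the final model are
#' reported.
#'
#' @param snps `data.table` with `region_id`, `ln_abf` and logical
#'   annotation columns.
#' @param candidates Annotation column names to consider.
#' @param n_folds CV folds (default 10).
#' @param penalty_grid L1 penalty weights searched (default
#'   `c(0, 0.05, 0.1, 0.2, 0.5)`).
#' @param seed Seed for fold assignment.
#' @param prefiltered If `FALSE` (default), candidates are first screened
#'   with [fit_single()] and only significant ones enter selection.
#' @return An `enrichment_fit`; intercept-only if nothing is retained.
#' @export
fit_joint <- function(snps, candidates, n_folds = 10L,
                      penalty_grid = c(0, 0.05, 0.1, 0.2, 0.5), seed = 1L,
                      prefiltered = FALSE) {
  snps <- data.table::as.data.table(snps)
  if (!prefiltered) {
    keep <- vapply(candidates, function(a) {
      fs <- tryCatch(fit_single(snps, a), error = function(e) NULL)
      !is.null(fs) && fs$significant
    }, logical(1))
    candidates <- candidates[keep]
  }
  dat <- .enrich_data(snps, candidates)
  base <- .enrich_fit(dat, include = character())
  if (!length(candidates)) {
    return(.new_enrichment_fit(dat, base, character(), list(), penalty = 0))
  }
  ## forward selection by log-likelihood gain
  included <- character()
  cur_ll <- base$loglik
  remaining <- candidates
  while (length(remaining)) {
    lls <- vapply(remaining, function(a) {
      .enrich_fit(dat, include = c(included, a))$loglik
    }, numeric(1))
    best <- which.max(lls)
    if (lls[best] - cur_ll <= 1e-6) break
    included <- c(included, remaining[best])
    cur_ll <- lls[best]
    remaining <- remaining[-best]
  }
  if (!length(included)) {
    return(.new_enrichment_fit(dat, base, character(), list(), penalty = 0))
  }
  ## penalty by cross-validation over regions
  set.seed(seed)
  R <- length(dat$M)
  fold_of <- sample(rep_len(seq_len(n_folds), R))
  folds <- split(seq_len(R), fold_of)
  cv <- vapply(penalty_grid, function(lam) {
    .cv_loglik(dat, included, lam, folds)
  }, numeric(1))
  penalty <- penalty_grid[which.max(cv)]
  cur_cv <- max(cv)
  ## backward elimination while CV likelihood improves
  repeat {
    if (length(included) <= 1L) break
    cv_red <- vapply(included, function(a) {
      .cv_loglik(dat, setdiff(included, a), penalty, folds)
    }, numeric(1))
    if (max(cv_red) > cur_cv) {
      included <- setdiff(included, included[which.max(cv_red)])
      cur_cv <- max(cv_red)
    } else break
  }
  fit <- .enrich_fit(dat, include = included, penalty = penalty)
  ci <- lapply(included, function(a) .profile_ci(dat, included, a,
    .enrich_fit(dat, include = included, penalty = 0)))
  names(ci) <- included
  out <- .new_enrichment_fit(dat, fit, included, ci, penalty)
  out
}

#' Likelihood-ratio test between nested enrichment models
#'
#' Refits both annotation sets without penalty and compares
#' `2 (lnL_full - lnL_reduced)` to a chi-square with degrees of freedom
#' equal to the difference in annotation count.
#'
#' @param full,reduced `enrichment_fit` objects on the same data;
#'   `reduced$included` must be a subset of `full$included`.
#' @return List with `statistic`, `df`, `p_value`, and the two unpenalised
#'   log-likelihoods.
#' @export
lrt_nested <- function(full, reduced) {
  stopifnot(inherits(full, "enrichment_fit"),
            inherits(reduced, "enrichment_fit"))
  if (!all(reduced$included %in% full$included)) {
    stop("models are not nested: reduced annotations must be a subset")
  }
  dat <- full$data
  f_full <- .enrich_fit(dat, include = full$included, penalty = 0)
  f_red <- .enrich_fit(dat, include = reduced$included, penalty = 0)
  stat <- max(0, 2 * (f_full$loglik - f_red$loglik))
  df <- length(full$included) - length(reduced$included)
  p <- if (df == 0L) 1 else pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p,
       lnl_full = f_full$loglik, lnl_reduced = f_red$loglik)
}
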