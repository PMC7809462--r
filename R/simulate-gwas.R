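#' Simulate discovery-GWAS summary statistics with planted effects
#'
#' A random subset of variants is made causal with true log-odds effects
#' drawn from `N(0, effect_sd^2)`; every variant then receives an observed
#' effect equal to truth plus estimation noise at the standard error implied
#' by the discovery sample size and its allele frequency, an odds ratio, and
#' a two-sided Wald p-value. With `causal_fraction = 0` the p-values are
#' uniform on (0, 1).
#'
#' @param genotypes A [genotype_set()]; allele frequencies are taken from it.
#' @param causal_fraction Fraction of variants with nonzero true effect.
#' @param effect_sd SD of true causal log-odds-ratio effects.
#' @param n_gwas Effective discovery sample size (balanced case/control), used
#'   for the per-variant standard error `1 / sqrt(2 n maf (1-maf) * 0.25)`;
#'   `Inf` gives noiseless statistics (`OR = exp(beta_true)`, p
#'   vanishingly small for causal variants and 1 otherwise).
#' @param beta_override Optional named numeric vector (names = variant ids)
#'   forcing the true effect of specific variants.
#' @param seed Master seed ("sumstats" substream).
#' @return A tibble with one row per variant: `snp`, `chr`, `pos`, `a1`
#'   (effect allele), `a2`, `or`, `p`, plus generator ground truth
#'   `beta_true` and `se` (dropped by [write_summary_stats()]).
#' @export
simulate_summary_stats <- function(genotypes,
                                   causal_fraction = 0.02,
                                   effect_sd = 0.1,
                                   n_gwas = 150000,
                                   beta_override = NULL,
                                   seed = 1) {
  v <- genotypes$variants
  with_substream(seed, "sumstats", {
    m <- nrow(v)
    causal <- runif(m) < causal_fraction
    beta_true <- ifelse(causal, rnorm(m, 0, effect_sd), 0)
    if (!is.null(beta_override)) {
      hit <- match(names(beta_override), v$snp)
      if (anyNA(hit)) stop("beta_override names missing from panel",
                           call. = FALSE)
      beta_true[hit] <- beta_override
    }
    maf <- pmax(v$maf, 0.01)  # guard near-monomorphic SEs
    se <- 1 / sqrt(2 * n_gwas * maf * (1 - maf) * 0.25)
    if (all(se == 0)) {
      beta_hat <- beta_true
      p <- ifelse(beta_true == 0, 1, 1e-300)  # keep p in (0, 1]
    } else {
      beta_hat <- beta_true + rnorm(m, 0, se)
      p <- 2 * pnorm(-abs(beta_hat / se))
    }
    tibble::tibble(
      snp = v$snp, chr = v$chr, pos = v$pos, a1 = v$a1, a2 = v$a2,
      or = exp(beta_hat),
      p = p,
      beta_true = beta_true,
      se = se
    )
  })
}

#' Ground-truth polygenic score from simulated summary statistics
#'
#' Sums dosages weighted by the generator's true (not estimated) effects and
#' standardizes the result. This is the "true score" against which phenotype
#' effects are planted, so recovery of a planted beta is well defined.
#'
#' @param genotypes A [genotype_set()].
#' @param stats Output of [simulate_summary_stats()] (needs `beta_true`).
#' @return A tibble with columns `iid`, `score_raw`, `score_z`.
#' @export
true_polygenic_score <- function(genotypes, stats) {
  if (!"beta_true" %in% names(stats)) {
    stop("stats lacks beta_true; use simulate_summary_stats() output",
         call. = FALSE)
  }
  idx <- match(colnames(genotypes$dosage), stats$snp)
  if (anyNA(idx)) stop("stats does not cover the genotype panel", call. = FALSE)
  b <- stats$beta_true[idx]
  dos <- genotypes$dosage
  # mean-impute missing dosages for the ground-truth sum
  if (anyNA(dos)) {
    mu <- 2 * genotypes$variants$maf
    for (j in which(colSums(is.na(dos)) > 0)) {
      dos[is.na(dos[, j]), j] <- mu[j]
    }
  }
  raw <- drop(dos %*% b)
  z <- if (sd(raw) > 0) standardize(raw) else raw * 0
  tibble::tibble(iid = rownames(genotypes$dosage), score_raw = raw,
                 score_z = z)
}
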