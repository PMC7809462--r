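# ln(OR)-weighted polygenic scoring at nested p-value thresholds.

#' Standardize to Z-scores
#'
#' Centers and scales by the sample standard deviation (denominator n - 1).
#'
#' @param x Numeric vector of length >= 2 with nonzero variance.
#' @return A numeric vector with mean 0 and SD 1.
#' @export
standardize <- function(x) {
  if (length(x) < 2) stop("need at least 2 values to standardize",
                          call. = FALSE)
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot standardize: zero variance", call. = FALSE)
  }
  (x - mean(x)) / s
}

#' Polygenic scores at nested p-value thresholds
#'
#' For each threshold T, sums each individual's counted-allele dosages over
#' the clumped variants with discovery p < T, weighted by the aligned
#' log odds ratio, and standardizes the sums to Z-scores so downstream
#' effect sizes read as SD of phenotype per SD of score. Missing dosages are
#' mean-imputed as `2 * MAF`.
#'
#' @param genotypes A [genotype_set()] (post-QC).
#' @param aligned Clumped, aligned effects ([clump()] output or the
#'   `aligned` element of [align_alleles()]): columns `snp`, `effect`, `p`.
#' @param thresholds Numeric vector of p-value thresholds
#'   (default [prs_thresholds()]).
#' @return A tibble with columns `iid`, `threshold`, `n_variants`, `raw`,
#'   `z`. `z` is `NA` when the raw scores are constant (e.g. no variant
#'   passes the threshold, which also raises a warning).
#' @export
prs_score <- function(genotypes, aligned, thresholds = prs_thresholds()) {
  jdx <- match(aligned$snp, colnames(genotypes$dosage))
  if (anyNA(jdx)) {
    stop("aligned variants missing from genotype panel", call. = FALSE)
  }
  dos <- genotypes$dosage[, jdx, drop = FALSE]
  if (anyNA(dos)) {
    mu <- 2 * genotypes$variants$maf[jdx]
    for (j in which(colSums(is.na(dos)) > 0)) {
      dos[is.na(dos[, j]), j] <- mu[j]
    }
  }
  iid <- rownames(genotypes$dosage)
  purrr::map_dfr(thresholds, function(T) {
    sel <- aligned$p < T
    if (!any(sel)) {
      warning("no variants pass threshold ", T, "; scores are all zero",
              call. = FALSE)
      return(tibble::tibble(iid = iid, threshold = T, n_variants = 0L,
                            raw = 0, z = NA_real_))
    }
    raw <- unname(drop(dos[, sel, drop = FALSE] %*% aligned$effect[sel]))
    z <- if (length(raw) > 1 && isTRUE(sd(raw) > 0)) {
      standardize(raw)
    } else NA_real_
    tibble::tibble(iid = iid, threshold = T, n_variants = sum(sel),
                   raw = raw, z = z)
  })
}

#' Extract one variant as a standardized score
#'
#' Pulls a single variant's counted-allele dosage and standardizes it like a
#' one-variant polygenic score, so the trajectory machinery can be run on
#' individual loci.
#'
#' @param genotypes A [genotype_set()].
#' @param snp Variant id.
#' @return A tibble with columns `iid`, `dosage`, `z`.
#' @export
extract_variant <- function(genotypes, snp) {
  j <- match(snp, colnames(genotypes$dosage))
  if (is.na(j)) {
    near <- agrep(snp, colnames(genotypes$dosage), max.distance = 2,
                  value = TRUE)
    stop("variant '", snp, "' not in panel",
         if (length(near) > 0) {
           paste0("; near matches: ", paste(head(near, 5), collapse = ", "))
         } else "",
         call. = FALSE)
  }
  d <- unname(genotypes$dosage[, j])
  if (anyNA(d)) d[is.na(d)] <- 2 * genotypes$variants$maf[j]
  if (sd(d) == 0) {
    stop("variant '", snp, "' is monomorphic in this sample", call. = FALSE)
  }
  tibble::tibble(iid = rownames(genotypes$dosage), dosage = d,
                 z = standardize(d))
}
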