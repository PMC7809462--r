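# Variant quality control and allele alignment for polygenic scoring.

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Quality-control filter for a genotype panel
#'
#' Excludes imputed variants with low INFO, palindromic (A/T, C/G) variants
#' whose strand cannot be resolved, monomorphic variants, variants with poor
#' genotyping rate, Hardy-Weinberg failures, and rare variants. Each excluded
#' variant is logged with the first failing rule in the fixed order INFO,
#' palindromic, monomorphic, call rate, HWE, MAF.
#'
#' @param genotypes A [genotype_set()].
#' @param info_min Minimum imputation INFO score (default 0.30).
#' @param call_rate_min Minimum genotyping rate (default 0.95).
#' @param hwe_p_min Minimum Hardy-Weinberg exact/chi-square p-value
#'   (default 1e-6, conventional for imputed panels).
#' @param maf_min Minimum minor allele frequency (default 0.0005, i.e.
#'   0.05%).
#' @return A list with `genotypes` (the filtered [genotype_set()]) and
#'   `exclusions` (tibble `snp`, `reason`).
#' @export
qc_filter <- function(genotypes, info_min = 0.30, call_rate_min = 0.95,
                      hwe_p_min = 1e-6, maf_min = 0.0005) {
  v <- genotypes$variants
  reason <- rep(NA_character_, nrow(v))
  fail <- function(cond, label) {
    hit <- is.na(reason) & cond & !is.na(cond)
    reason[hit] <<- label
  }
  fail(v$info < info_min, "info")
  fail(is_palindromic(v$a1, v$a2), "palindromic")
  fail(v$maf == 0, "monomorphic")
  fail(v$call_rate < call_rate_min, "call_rate")
  fail(v$hwe_p < hwe_p_min, "hwe")
  fail(v$maf < maf_min, "maf")

  keep <- is.na(reason)
  if (!any(keep)) {
    warning("no variants survive QC", call. = FALSE)
  }
  filtered <- genotype_set(
    genotypes$dosage[, keep, drop = FALSE],
    v[keep, , drop = FALSE],
    genotypes$fam
  )
  list(genotypes = filtered,
       exclusions = tibble::tibble(snp = v$snp[!keep],
                                   reason = reason[!keep]))
}

#' Align summary-statistic effect alleles to the genotype panel
#'
#' Matches each summary record to a panel variant (by id, falling back to
#' chromosome:position) and orients the log odds ratio to the panel's
#' counted allele: if the effect allele is the counted allele the aligned
#' effect is `ln(OR)`; if it is the panel's other allele the effect is
#' `-ln(OR)`; palindromic records and records whose allele set does not
#' match the panel are excluded with a reason.
#'
#' @param stats Tibble of summary statistics with columns `snp`, `chr`,
#'   `pos`, `a1` (effect allele), `a2`, `or`, `p`.
#' @param genotypes A [genotype_set()] (post-QC).
#' @return A list with `aligned` (tibble `snp`, `chr`, `pos`, `effect`, `p`,
#'   `matched_by`) and `exclusions` (tibble `snp`, `reason` in
#'   {"palindromic", "allele_mismatch", "not_in_panel"}).
#' @export
align_alleles <- function(stats, genotypes) {
  v <- genotypes$variants
  by_id <- match(stats$snp, v$snp)
  key <- paste(v$chr, v$pos)
  by_pos <- match(paste(stats$chr, stats$pos), key)
  idx <- ifelse(!is.na(by_id), by_id, by_pos)
  matched_by <- dplyr::case_when(!is.na(by_id) ~ "id",
                                 !is.na(by_pos) ~ "position",
                                 TRUE ~ NA_character_)

  reason <- rep(NA_character_, nrow(stats))
  reason[is.na(idx)] <- "not_in_panel"
  pal <- !is.na(idx) & is_palindromic(stats$a1, stats$a2)
  reason[pal] <- "palindromic"

  effect <- rep(NA_real_, nrow(stats))
  ok <- is.na(reason)
  direct <- ok & stats$a1 == v$a1[idx] & stats$a2 == v$a2[idx]
  flipped <- ok & stats$a1 == v$a2[idx] & stats$a2 == v$a1[idx]
  effect[direct] <- log(stats$or[direct])
  effect[flipped] <- -log(stats$or[flipped])
  reason[ok & !direct & !flipped] <- "allele_mismatch"

  keep <- is.na(reason)
  list(
    aligned = tibble::tibble(
      snp = v$snp[idx[keep]],
      chr = v$chr[idx[keep]],
      pos = v$pos[idx[keep]],
      effect = effect[keep],
      p = stats$p[keep],
      matched_by = matched_by[keep]
    ),
    exclusions = tibble::tibble(snp = stats$snp[!keep],
                                reason = reason[!keep])
  )
}
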