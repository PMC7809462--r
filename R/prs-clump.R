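# Greedy LD clumping to an approximately independent variant set.

#' Pairwise linkage disequilibrium (r-squared) between two dosage vectors
#'
#' Squared Pearson correlation over the (typically founder) reference
#' individuals, using pairwise-complete observations.
#'
#' @param dos_a,dos_b Numeric dosage vectors of equal length.
#' @return r-squared in `[0, 1]`; 0 with a warning when either vector has
#'   zero variance.
#' @export
ld_r2 <- function(dos_a, dos_b) {
  ok <- !is.na(dos_a) & !is.na(dos_b)
  if (sum(ok) < 2) {
    stop("need at least 2 reference individuals with non-missing dosage ",
         "at both variants", call. = FALSE)
  }
  a <- dos_a[ok]; b <- dos_b[ok]
  if (var(a) == 0 || var(b) == 0) {
    warning("zero dosage variance at one variant; r2 treated as 0",
            call. = FALSE)
    return(0)
  }
  cor(a, b)^2
}

#' Greedy LD clumping of summary statistics
#'
#' Repeatedly takes the most significant remaining variant as an index and
#' removes every unselected variant on the same chromosome within the
#' physical window whose dosage r-squared with the index (computed in the
#' reference individuals, founders by default) meets the threshold. Variants
#' beyond the window are never removed regardless of r-squared. Ties in
#' p-value break to the lower (chromosome, position) for deterministic
#' output.
#'
#' @param aligned Aligned summary statistics (the `aligned` element of
#'   [align_alleles()]): columns `snp`, `chr`, `pos`, `effect`, `p`.
#' @param genotypes A [genotype_set()] supplying reference dosages.
#' @param window_bp Physical window (+/- bp) around each index
#'   (default 500 kb).
#' @param r2_threshold Variants with r-squared at or above this are clumped
#'   (default 0.1).
#' @param founders_only Compute r-squared over founders only (default TRUE).
#' @return A tibble of retained index variants (`snp`, `chr`, `pos`,
#'   `effect`, `p`, `n_clumped` removed by each index), sorted by
#'   (chr, pos).
#' @export
clump <- function(aligned, genotypes, window_bp = 500000,
                  r2_threshold = 0.1, founders_only = TRUE) {
  stopifnot(window_bp > 0, r2_threshold > 0, r2_threshold < 1)
  if (nrow(aligned) == 0) return(aligned[0, ])
  ref <- genotypes$dosage
  if (founders_only) ref <- ref[genotypes$fam$founder, , drop = FALSE]
  jdx <- match(aligned$snp, colnames(ref))
  if (anyNA(jdx)) {
    stop("aligned variants missing from genotype panel: ",
         paste(head(aligned$snp[is.na(jdx)], 5), collapse = ", "),
         call. = FALSE)
  }
  ord <- order(aligned$p, aligned$chr, aligned$pos)
  state <- rep(0L, nrow(aligned))  # 0 available, 1 index, -1 removed
  n_clumped <- integer(nrow(aligned))
  for (i in ord) {
    if (state[i] != 0L) next
    state[i] <- 1L
    cand <- which(state == 0L &
                    aligned$chr == aligned$chr[i] &
                    abs(aligned$pos - aligned$pos[i]) <= window_bp)
    for (k in cand) {
      r2 <- suppressWarnings(ld_r2(ref[, jdx[i]], ref[, jdx[k]]))
      if (r2 >= r2_threshold) {
        state[k] <- -1L
        n_clumped[i] <- n_clumped[i] + 1L
      }
    }
  }
  out <- aligned[state == 1L, , drop = FALSE]
  out$n_clumped <- n_clumped[state == 1L]
  dplyr::arrange(out, .data$chr, .data$pos)
}
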