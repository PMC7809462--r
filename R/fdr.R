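#' Benjamini-Hochberg significance mask
#'
#' Step-up procedure at level `q` over one family of tests: with sorted
#' p-values `p_(1) <= ... <= p_(m)`, find the largest `i` with
#' `p_(i) <= i q / m`; every p-value at or below that `p_(i)` is declared
#' significant. The implied p cutoff (the rejection boundary actually
#' attained) is reported alongside the mask, since downstream tables flag
#' cells against it.
#'
#' @param p Numeric vector of p-values in `(0, 1]`; `NA`s are allowed and
#'   never significant (they do not count toward the family size).
#' @param q FDR level (default 0.01).
#' @return A list with `mask` (logical, same length as `p`), `cutoff` (the
#'   implied p threshold, 0 when nothing is rejected), and `n_rejected`.
#' @export
#' @examples
#' fdr_mask(c(0.001, 0.01, 0.02, 0.04, 0.2), q = 0.05)
fdr_mask <- function(p, q = 0.01) {
  if (length(p) == 0) stop("empty p-value set", call. = FALSE)
  ok <- !is.na(p)
  if (!any(ok)) stop("all p-values are NA", call. = FALSE)
  pv <- p[ok]
  if (any(pv <= 0 | pv > 1)) stop("p-values must lie in (0, 1]",
                                  call. = FALSE)
  m <- length(pv)
  ord <- order(pv)
  sorted <- pv[ord]
  below <- which(sorted <= seq_len(m) * q / m)
  cutoff <- if (length(below) == 0) 0 else sorted[max(below)]
  mask <- rep(FALSE, length(p))
  mask[ok] <- pv <= cutoff & cutoff > 0
  list(mask = mask, cutoff = cutoff, n_rejected = sum(mask))
}
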