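#' The 27 bipolar-pair coherence definitions
#'
#' Coherence is computed between pairs of bipolar derivations (each the
#' difference of two adjacent 10-20 electrodes, anode minus cathode). The 27
#' representative pairs are grouped into four scalp-region classes:
#' frontal-central sagittal (pairs 1-10), central-parietal sagittal (11-20),
#' parietal-occipital sagittal (21) and intrahemispheric lateral (22-27).
#'
#' @return A tibble with columns `pair_id`, `a_anode`, `a_cathode`,
#'   `b_anode`, `b_cathode`, `region_class`.
#' @export
#' @examples
#' coherence_pairs()
coherence_pairs <- function() {
  path <- system.file("extdata", "coherence_pairs.tsv", package = "cohertraj")
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(pair_id = "i", .default = "c"))
}

#' Default EEG frequency bands
#'
#' Bands are half-open intervals `[f_lo, f_hi)` in Hz so that shared edges are
#' never double counted (7 Hz belongs to alpha, not theta). `high_alpha` is a
#' sub-band of `alpha` used for the headline developmental maps.
#'
#' @param which Optional character vector of band names to keep.
#' @return A tibble with columns `band`, `f_lo`, `f_hi`.
#' @export
#' @examples
#' eeg_bands()
#' eeg_bands("high_alpha")
eeg_bands <- function(which = NULL) {
  bands <- tibble::tibble(
    band = c("theta", "alpha", "high_alpha", "beta"),
    f_lo = c(3, 7, 9, 12),
    f_hi = c(7, 12, 12, 28)
  )
  if (!is.null(which)) {
    missing <- setdiff(which, bands$band)
    if (length(missing) > 0) {
      stop("unknown band(s): ", paste(missing, collapse = ", "), call. = FALSE)
    }
    bands <- bands[match(which, bands$band), ]
  }
  bands
}

#' The nine polygenic-score p-value thresholds
#'
#' Progressively more inclusive discovery-GWAS significance thresholds at
#' which scores are constructed.
#'
#' @return A numeric vector of length 9.
#' @export
prs_thresholds <- function() {
  c(0.0001, 0.001, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)
}
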