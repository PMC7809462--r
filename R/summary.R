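#' Default age bins for trajectory summaries
#'
#' Closed integer-age intervals 12-17, 18-25 and 26-31 years.
#'
#' @return A tibble with columns `bin`, `lo`, `hi`.
#' @export
age_bins <- function() {
  tibble::tibble(bin = c("12-17", "18-25", "26-31"),
                 lo = c(12, 18, 26), hi = c(17, 25, 31))
}

#' Age-binned quantile summary of a trajectory grid
#'
#' Within each age bin and sex x band x pair cell, reduces the grid-point
#' betas and -log10 p-values to a configured quantile (default the first
#' quartile), and flags cells whose summarized p-value meets the grid's
#' FDR-implied cutoff.
#'
#' @param grid A `trajectory_grid` from [trajectory_scan()].
#' @param bins Age-bin tibble (`bin`, `lo`, `hi`); closed intervals on the
#'   integer grid (default [age_bins()]).
#' @param prob Quantile level (default 0.25, the first quartile).
#' @return A tibble: `sex`, `band`, `pair_id`, `bin`, `n_points`, `beta_q`,
#'   `neglog10p_q`, `meets_fdr`.
#' @export
age_bin_summary <- function(grid, bins = age_bins(), prob = 0.25) {
  stopifnot(inherits(grid, "trajectory_grid") ||
              all(c("sex", "band", "pair_id", "age", "beta",
                    "neglog10p") %in% names(grid)))
  cutoffs <- attr(grid, "fdr_cutoffs")
  df <- tibble::as_tibble(grid)
  purrr::map_dfr(seq_len(nrow(bins)), function(i) {
    inbin <- df[df$age >= bins$lo[i] & df$age <= bins$hi[i], , drop = FALSE]
    out <- dplyr::summarise(
      dplyr::group_by(inbin, .data$sex, .data$band, .data$pair_id),
      n_points = sum(!is.na(.data$p)),
      beta_q = if (all(is.na(.data$beta))) NA_real_ else {
        quantile(.data$beta, prob, na.rm = TRUE, names = FALSE)
      },
      neglog10p_q = if (all(is.na(.data$neglog10p))) NA_real_ else {
        quantile(.data$neglog10p, prob, na.rm = TRUE, names = FALSE)
      },
      .groups = "drop"
    )
    out$bin <- bins$bin[i]
    out
  }) -> res
  if (!is.null(cutoffs)) {
    res <- dplyr::left_join(res, cutoffs, by = c("sex", "band"))
    res$meets_fdr <- !is.na(res$neglog10p_q) & !is.na(res$cutoff) &
      res$cutoff > 0 & res$neglog10p_q >= -log10(res$cutoff)
    res$cutoff <- NULL
  } else {
    res$meets_fdr <- NA
  }
  res[, c("sex", "band", "pair_id", "bin", "n_points", "beta_q",
          "neglog10p_q", "meets_fdr")]
}

#' Render an age-binned summary as a wide pairs-by-columns table
#'
#' Pairs appear as rows in grid order (1-27), grouped by scalp region and
#' labelled by their bipolar derivations; age-bin x sex combinations form
#' the columns; cells that meet the FDR criterion are marked with an
#' asterisk in the text rendering.
#'
#' @param summary Output of [age_bin_summary()].
#' @param value Which summarized value to tabulate: "neglog10p_q" (default)
#'   or "beta_q".
#' @param digits Rounding for display (default 2).
#' @return A wide tibble with one row per pair (columns `pair_id`,
#'   `region_class`, `pair_label`, then one column per bin x sex).
#' @export
render_table1 <- function(summary, value = c("neglog10p_q", "beta_q"),
                          digits = 2) {
  value <- match.arg(value)
  pairs <- coherence_pairs()
  pairs$pair_label <- paste0(pairs$a_anode, "-", pairs$a_cathode, "--",
                             pairs$b_anode, "-", pairs$b_cathode)
  df <- dplyr::mutate(
    summary,
    cell = ifelse(is.na(.data[[value]]), "",
                  paste0(format(round(.data[[value]], digits), nsmall = digits,
                                trim = TRUE),
                         ifelse(!is.na(.data$meets_fdr) & .data$meets_fdr,
                                "*", ""))),
    col = paste(.data$bin, .data$sex, sep = " | ")
  )
  wide <- tidyr::pivot_wider(df[, c("pair_id", "col", "cell")],
                             names_from = "col", values_from = "cell")
  out <- dplyr::left_join(pairs[, c("pair_id", "region_class", "pair_label")],
                          wide, by = "pair_id")
  tibble::as_tibble(out)
}
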