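#' Simulate a two-channel signal pair with known coherence
#'
#' Builds `x = sqrt(rho) s + sqrt(1 - rho) e1` and
#' `y = sqrt(rho) s + sqrt(1 - rho) e2` from mutually independent
#' unit-variance Gaussian white sources, with `rho = sqrt(target)`. Both
#' channels then have unit power, the cross-spectrum equals `rho` times the
#' shared-source spectrum, and the true magnitude-squared coherence equals
#' `target` at every frequency — the ground truth for the spectral estimator.
#'
#' @param coherence_target True magnitude-squared coherence in `[0, 1]`.
#' @param duration_s Signal duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed Master seed ("signals" substream).
#' @return A tibble with columns `time` (s), `x`, `y`; `fs` is stored as an
#'   attribute.
#' @export
#' @examples
#' sig <- simulate_eeg_pair(0.5, duration_s = 8, fs = 64, seed = 1)
#' head(sig)
simulate_eeg_pair <- function(coherence_target, duration_s = 256, fs = 256,
                              seed = 1) {
  if (coherence_target < 0 || coherence_target > 1) {
    stop("coherence_target must lie in [0, 1]", call. = FALSE)
  }
  n <- round(duration_s * fs)
  if (n < 2) stop("duration too short", call. = FALSE)
  rho <- sqrt(coherence_target)
  with_substream(seed, "signals", {
    s <- rnorm(n)
    e1 <- rnorm(n)
    e2 <- rnorm(n)
    x <- sqrt(rho) * s + sqrt(1 - rho) * e1
    y <- sqrt(rho) * s + sqrt(1 - rho) * e2
    out <- tibble::tibble(time = (seq_len(n) - 1) / fs, x = x, y = y)
    attr(out, "fs") <- fs
    out
  })
}
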