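# All randomness flows from one master seed through named substreams so that
# components can be re-run independently yet reproducibly.

#' Derive a named substream seed from a master seed
#'
#' Deterministically maps (master seed, stream name) to a 31-bit integer seed,
#' so that e.g. the pedigree and phenotype generators draw from independent,
#' individually reproducible streams.
#'
#' @param seed Integer master seed.
#' @param stream Character stream name (e.g. "pedigree", "phenotypes").
#' @return A single integer in `[0, 2^31)`.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  h <- 0
  for (code in utf8ToInt(stream)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer((abs(seed) %% 2147483647 + h * 7919) %% 2147483647)
}

with_substream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, stream))
  expr
}
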