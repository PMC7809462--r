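#' Simulate a longitudinal visit schedule
#'
#' Offspring enter the cohort at a uniform age between 12 and 22 and return
#' roughly every two years (with half-year jitter) until their drawn number
#' of visits is exhausted or they pass the upper age bound. The default
#' visit-count distribution `1 + Binomial(6, 5/12)` has mean 3.5 and range
#' 1-7.
#'
#' @param pedigree Output of [simulate_pedigree()]; visits are generated for
#'   offspring (non-founders) only.
#' @param first_age_range Range of the uniform first-visit age.
#' @param interval Target years between visits.
#' @param jitter Half-width of the uniform jitter on each interval.
#' @param max_age Visits beyond this age are dropped.
#' @param visit_count_fn Function of `n` returning `n` visit counts (>= 1).
#' @param seed Master seed ("visits" substream).
#' @return A tibble with columns `iid`, `visit`, `age` (years, fractional),
#'   ages strictly increasing within individual.
#' @export
simulate_visits <- function(pedigree,
                            first_age_range = c(12, 22),
                            interval = 2,
                            jitter = 0.5,
                            max_age = 31,
                            visit_count_fn = function(n) 1 + rbinom(n, 6, 5 / 12),
                            seed = 1) {
  ids <- pedigree$iid[!pedigree$founder]
  if (length(ids) == 0) stop("pedigree has no offspring", call. = FALSE)
  with_substream(seed, "visits", {
    n <- length(ids)
    k <- visit_count_fn(n)
    if (any(k < 1)) stop("visit_count_fn must return counts >= 1",
                         call. = FALSE)
    first <- runif(n, first_age_range[1], first_age_range[2])
    purrr::map_dfr(seq_len(n), function(i) {
      gaps <- interval + runif(k[i] - 1, -jitter, jitter)
      ages <- first[i] + c(0, cumsum(gaps))
      ages <- ages[ages <= max_age]
      tibble::tibble(iid = ids[i], visit = seq_along(ages), age = ages)
    })
  })
}
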