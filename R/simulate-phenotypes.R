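#' Default planted genetic effects on coherence
#'
#' One effect regime in the range reported for polygenic associations with
#' developmental EEG coherence: beta = 0.2 SD of coherence per SD of score,
#' localized to males aged 15-19, on the posterior (central-parietal and
#' parietal-occipital sagittal) pairs 11-21, in the high-alpha band.
#'
#' @param beta Effect size (SD coherence per SD score).
#' @param pair_ids Target pair ids.
#' @param band Target band name.
#' @param sex "male", "female" or "both".
#' @param age_window Two-element numeric `[lo, hi]` in years.
#' @return A tibble usable as the `effects` argument of
#'   [simulate_phenotypes()].
#' @export
planted_effects <- function(beta = 0.2, pair_ids = 11:21,
                            band = "high_alpha", sex = "male",
                            age_window = c(15, 19)) {
  tibble::tibble(pair_id = pair_ids, band = band, sex = sex,
                 age_lo = age_window[1], age_hi = age_window[2], beta = beta)
}

#' Simulate band-coherence phenotypes with localized genetic effects
#'
#' Coherence is generated on the variance-stabilizing Fisher-z scale,
#' `z = atanh(sqrt(C))`, as a linear model
#' `z = mu_pair(age) + sd_z * (sum(beta * score * 1[sex, age window, pair,
#' band]) + u_family + v_individual + eps)`
#' and back-transformed with `C = tanh(z)^2`, which keeps every coherence in
#' (0, 1). The variance components are relative proportions of the latent
#' unit-variance part; `sd_z` sets the absolute z-scale spread and is kept
#' small enough that the latent stays on the monotone branch of the
#' back-transform, so a planted `beta` is recovered as SD of coherence per
#' SD of score by the downstream standardized regression. Family and
#' individual random effects are drawn independently per pair x band,
#' inducing the within-family / within-person correlation the downstream
#' observation weights are designed for.
#'
#' @param visits Output of [simulate_visits()].
#' @param pedigree Output of [simulate_pedigree()] (supplies `fid`, `sex`).
#' @param score Tibble with `iid` and `score_z` (standardized score), e.g.
#'   [true_polygenic_score()] output.
#' @param effects Tibble of planted effects (see [planted_effects()]); may be
#'   empty for a global null.
#' @param pairs Pair definitions ([coherence_pairs()] or a subset).
#' @param bands Band definitions ([eeg_bands()] or a subset).
#' @param var_family,var_individual,var_residual Variance components of the
#'   latent (pre-`sd_z`) part; together with the largest per-pair planted
#'   effect variance they must not exceed 1.
#' @param sd_z Total z-scale standard deviation multiplying the latent part
#'   (default 0.18, a realistic between-visit spread for Fisher-z
#'   coherence).
#' @param mu0 Baseline z-scale intercept; the default `atanh(sqrt(0.35))`
#'   centers coherence near 0.35.
#' @param age_slope Linear drift of the z-scale baseline per year of age
#'   (centered at age 20).
#' @param seed Master seed ("phenotypes" substream).
#' @return A tibble with columns `iid`, `fid`, `sex`, `visit`, `age`,
#'   `pair_id`, `band`, `coherence`.
#' @export
simulate_phenotypes <- function(visits, pedigree, score,
                                effects = planted_effects(),
                                pairs = coherence_pairs(),
                                bands = eeg_bands(),
                                var_family = 0.10,
                                var_individual = 0.30,
                                var_residual = 0.55,
                                sd_z = 0.18,
                                mu0 = atanh(sqrt(0.35)),
                                age_slope = 0.005,
                                seed = 1) {
  vcs <- c(var_family, var_individual, var_residual)
  if (any(vcs < 0)) stop("variance components must be >= 0", call. = FALSE)
  eff_var <- 0
  if (nrow(effects) > 0) {
    if (any(effects$age_lo < 12 | effects$age_hi > 31)) {
      stop("planted age windows must lie within [12, 31]", call. = FALSE)
    }
    if (any(!is.finite(effects$beta))) {
      stop("planted betas must be finite", call. = FALSE)
    }
    eff_var <- max(dplyr::summarise(
      dplyr::group_by(effects, .data$pair_id, .data$band),
      v = sum(.data$beta^2), .groups = "drop")$v)
  }
  if (sum(vcs) + eff_var > 1) {
    stop("variance components plus planted effect variance exceed 1 ",
         "on the z scale", call. = FALSE)
  }

  obs <- dplyr::inner_join(visits,
                           pedigree[, c("iid", "fid", "sex")], by = "iid")
  obs <- dplyr::left_join(obs, score[, c("iid", "score_z")], by = "iid")
  if (anyNA(obs$score_z)) {
    stop("score is missing for some individuals with visits", call. = FALSE)
  }
  n <- nrow(obs)
  fids <- unique(obs$fid)
  iids <- unique(obs$iid)
  P <- nrow(pairs)

  with_substream(seed, "phenotypes", {
    # Stable per-pair baseline offsets (part of mu_pair, not noise).
    pair_offset <- runif(P, -0.08, 0.08)
    out <- purrr::map_dfr(seq_len(nrow(bands)), function(bi) {
      band_name <- bands$band[bi]
      u_f <- matrix(rnorm(length(fids) * P, 0, sqrt(var_family)),
                    length(fids), P, dimnames = list(fids, NULL))
      v_i <- matrix(rnorm(length(iids) * P, 0, sqrt(var_individual)),
                    length(iids), P, dimnames = list(iids, NULL))
      eps <- matrix(rnorm(n * P, 0, sqrt(var_residual)), n, P)
      mu <- outer(mu0 + age_slope * (obs$age - 20), rep(1, P)) +
        matrix(pair_offset, n, P, byrow = TRUE)
      lat <- u_f[obs$fid, , drop = FALSE] +
        v_i[obs$iid, , drop = FALSE] + eps
      eff_b <- effects[effects$band == band_name, , drop = FALSE]
      if (nrow(eff_b) > 0) {
        for (r in seq_len(nrow(eff_b))) {
          jp <- match(eff_b$pair_id[r], pairs$pair_id)
          if (is.na(jp)) next
          hit <- obs$age >= eff_b$age_lo[r] & obs$age <= eff_b$age_hi[r] &
            (eff_b$sex[r] == "both" | obs$sex == eff_b$sex[r])
          lat[hit, jp] <- lat[hit, jp] + eff_b$beta[r] * obs$score_z[hit]
        }
      }
      C <- tanh(mu + sd_z * lat)^2
      tibble::tibble(
        iid = rep(obs$iid, P), fid = rep(obs$fid, P),
        sex = rep(obs$sex, P), visit = rep(obs$visit, P),
        age = rep(obs$age, P),
        pair_id = rep(pairs$pair_id, each = n),
        band = band_name,
        coherence = as.vector(C)
      )
    })
    out
  })
}
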