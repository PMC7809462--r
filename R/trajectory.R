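# Age-resolved, sex-stratified weighted association of a standardized score
# with coherence phenotypes: locally weighted linear regression on an integer
# age grid with observation weights for repeated measures and relatedness,
# family-clustered Wald inference, and FDR masking.

#' Observation weights for repeated measures and family clustering
#'
#' Each visit receives weight `1 / (v_i * m_f)` where `v_i` is the number of
#' visits of the individual and `m_f` the number of sampled individuals in
#' the family, so an individual's weights sum to `1 / m_f` and a family's
#' weights sum to 1: families, not visits, carry equal influence.
#'
#' @param observations Tibble with one row per visit, columns `iid`, `fid`.
#' @return The input with a `weight` column appended.
#' @export
compute_weights <- function(observations) {
  stopifnot(all(c("iid", "fid") %in% names(observations)))
  obs <- dplyr::add_count(observations, .data$iid, name = ".n_visits")
  fam_size <- dplyr::summarise(dplyr::group_by(
    dplyr::distinct(obs, .data$fid, .data$iid), .data$fid),
    .m_f = dplyr::n(), .groups = "drop")
  obs <- dplyr::left_join(obs, fam_size, by = "fid")
  obs$weight <- 1 / (obs$.n_visits * obs$.m_f)
  obs$.n_visits <- NULL
  obs$.m_f <- NULL
  obs
}

tricube <- function(u) {
  ifelse(abs(u) < 1, (1 - abs(u)^3)^3, 0)
}

# Core weighted least-squares fit at one grid point for one design matrix X
# and (possibly multi-column) response matrix Y.
#
# Two variance estimators for the Wald t-test on the score coefficient:
#  - "cluster" (default): family-clustered CR2 sandwich (Bell-McCaffrey
#    leverage adjustment) with Satterthwaite degrees of freedom. Repeated
#    visits and sibling co-membership both live inside the family cluster,
#    so this calibrates the test under the dependence the weights
#    downweight but do not remove.
#  - "model": model-based variance with degrees of freedom from the Kish
#    effective sample size of the combined weights, n_eff = (sum w)^2 /
#    sum w^2, exact for a weighted mean of independent observations.
wls_point <- function(X, Y, w, score_col, min_neff, cluster = NULL,
                      variance = c("cluster", "model")) {
  variance <- match.arg(variance)
  if (is.null(cluster)) variance <- "model"
  keep <- w > 0 & complete.cases(X) & stats::complete.cases(Y)
  blank <- function(reason) {
    list(beta = rep(NA_real_, ncol(Y)), se = NA_real_, p = NA_real_,
         n_eff = NA_real_, reason = reason)
  }
  if (sum(keep) < ncol(X) + 2) return(blank("too_few_observations"))
  X <- X[keep, , drop = FALSE]
  Y <- Y[keep, , drop = FALSE]
  w <- w[keep]
  if (!is.null(cluster)) cluster <- cluster[keep]
  n_eff <- sum(w)^2 / sum(w^2)
  if (n_eff < min_neff) return(blank("min_neff"))
  sw <- sqrt(w)
  Xw <- X * sw
  Yw <- Y * sw
  qrX <- qr(Xw)
  if (qrX$rank < ncol(X)) return(blank("rank_deficient"))
  B <- qr.coef(qrX, Yw)
  res <- Yw - Xw %*% B
  xtxinv <- chol2inv(qr.R(qrX))

  if (variance == "model") {
    df <- n_eff - ncol(X)
    if (df <= 1) return(blank("min_neff"))
    sigma2 <- colSums(res^2) / df
    se <- sqrt(sigma2 * xtxinv[score_col, score_col])
  } else {
    # CR2: per cluster, inflate transformed residuals by
    # (I - H_cc)^{-1/2}; variance of the score contrast is the sum of
    # squared adjusted cluster scores, with Satterthwaite df from the
    # cluster contributions q_c.
    cvec <- drop(Xw %*% xtxinv[, score_col])
    lev <- rowSums((Xw %*% xtxinv) * Xw)
    idx_by_c <- split(seq_along(cluster), cluster)
    sizes <- lengths(idx_by_c)
    v <- numeric(ncol(Y))
    qs <- numeric(length(idx_by_c))
    single <- unlist(idx_by_c[sizes == 1], use.names = FALSE)
    if (length(single) > 0) {
      pf <- cvec[single] / sqrt(pmax(1 - lev[single], 1e-8))
      v <- v + colSums((pf * res[single, , drop = FALSE])^2)
      qs[seq_along(single)] <- pf^2
    }
    qpos <- length(single)
    for (fidx in idx_by_c[sizes > 1]) {
      Xf <- Xw[fidx, , drop = FALSE]
      Hff <- Xf %*% xtxinv %*% t(Xf)
      eg <- eigen(diag(length(fidx)) - Hff, symmetric = TRUE)
      Af <- eg$vectors %*% (t(eg$vectors) /
                              sqrt(pmax(eg$values, 1e-8)))
      pf <- drop(crossprod(Af, cvec[fidx]))
      zf <- drop(crossprod(pf, res[fidx, , drop = FALSE]))
      v <- v + zf^2
      qpos <- qpos + 1
      qs[qpos] <- sum(pf^2)
    }
    df <- sum(qs)^2 / sum(qs^2)
    if (length(idx_by_c) < ncol(X) + 2 || df <= 1) {
      return(blank("too_few_clusters"))
    }
    se <- sqrt(v)
  }
  tval <- B[score_col, ] / se
  list(beta = as.numeric(B[score_col, ]), se = as.numeric(se),
       p = as.numeric(2 * pt(-abs(tval), df)), n_eff = n_eff,
       reason = NA_character_)
}

#' Locally weighted association fit at one age grid point
#'
#' Weighted least squares of the response on the standardized score (plus
#' optional covariate columns) with combined weight = structural observation
#' weight x tricube kernel in age. By default the Wald t-test uses a
#' family-clustered CR2 sandwich variance with Satterthwaite degrees of
#' freedom, which stays calibrated under the residual dependence of
#' repeated visits and siblings; `variance = "model"` instead uses the
#' model-based variance with degrees of freedom from the effective sample
#' size `n_eff = (sum w)^2 / sum w^2`.
#'
#' @param data Tibble with columns `y` (response), `score_z`, `age`, an
#'   optional `weight` column (default 1), an optional `fid` cluster column
#'   (required for `variance = "cluster"`), and any covariate columns named
#'   in `covariates`.
#' @param age0 Grid point (years).
#' @param bandwidth Tricube kernel bandwidth `h` in years (default 2);
#'   observations with `|age - age0| >= h` get zero kernel weight. Use
#'   `Inf` for a global (unkernelled) fit.
#' @param covariates Character vector of covariate column names.
#' @param min_neff Minimum effective sample size; below it the point is
#'   masked (default 30).
#' @param variance "cluster" (family-clustered CR2, default when `fid` is
#'   present) or "model" (effective-sample-size Wald).
#' @return A one-row tibble: `age`, `beta`, `se`, `p`, `n_eff`, `masked`,
#'   `reason`.
#' @export
local_fit <- function(data, age0, bandwidth = 2, covariates = character(),
                      min_neff = 30, variance = c("cluster", "model")) {
  stopifnot(all(c("y", "score_z", "age") %in% names(data)))
  variance <- match.arg(variance)
  cluster <- if (variance == "cluster" && "fid" %in% names(data)) {
    data$fid
  } else NULL
  w_struct <- if ("weight" %in% names(data)) data$weight else rep(1, nrow(data))
  kern <- if (is.infinite(bandwidth)) rep(1, nrow(data)) else {
    tricube((data$age - age0) / bandwidth)
  }
  X <- build_design(data, covariates)
  fit <- wls_point(X, matrix(data$y, ncol = 1), w_struct * kern,
                   score_col = 2L, min_neff = min_neff, cluster = cluster,
                   variance = variance)
  tibble::tibble(age = age0, beta = fit$beta[1], se = fit$se, p = fit$p,
                 n_eff = fit$n_eff, masked = !is.na(fit$reason),
                 reason = fit$reason)
}

# Intercept + score + covariates (factors expanded to treatment contrasts).
build_design <- function(data, covariates) {
  X <- cbind(`(Intercept)` = 1, score_z = data$score_z)
  for (cv in covariates) {
    v <- data[[cv]]
    if (is.null(v)) stop("covariate column '", cv, "' not found",
                         call. = FALSE)
    if (is.character(v) || is.factor(v)) {
      f <- factor(v)
      if (nlevels(f) > 1) {
        mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(mm) <- paste0(cv, levels(f)[-1])
        X <- cbind(X, mm)
      }
    } else {
      X <- cbind(X, setNames(data.frame(v), cv))
    }
  }
  as.matrix(X)
}

#' Sex-by-score interaction fit at one age grid point
#'
#' Pooled model over both sexes adding a sex main effect and a sex x score
#' interaction; reports the interaction coefficient and its p-value.
#'
#' @inheritParams local_fit
#' @param data As for [local_fit()], plus a `sex` column with both levels
#'   represented in the kernel window.
#' @return A one-row tibble: `age`, `beta_interaction`, `se`, `p`, `n_eff`,
#'   `masked`, `reason`.
#' @export
interaction_fit <- function(data, age0, bandwidth = 2,
                            covariates = character(), min_neff = 30,
                            variance = c("cluster", "model")) {
  stopifnot(all(c("y", "score_z", "age", "sex") %in% names(data)))
  variance <- match.arg(variance)
  cluster <- if (variance == "cluster" && "fid" %in% names(data)) {
    data$fid
  } else NULL
  if (length(unique(data$sex)) < 2) {
    stop("interaction model needs both sexes represented", call. = FALSE)
  }
  if (sd(data$score_z) == 0) {
    stop("score has no variance", call. = FALSE)
  }
  w_struct <- if ("weight" %in% names(data)) data$weight else rep(1, nrow(data))
  kern <- if (is.infinite(bandwidth)) rep(1, nrow(data)) else {
    tricube((data$age - age0) / bandwidth)
  }
  sex_f <- as.numeric(factor(data$sex)) - 1
  X <- build_design(data, covariates)
  X <- cbind(X, sex = sex_f, `sex:score_z` = sex_f * data$score_z)
  fit <- wls_point(X, matrix(data$y, ncol = 1), w_struct * kern,
                   score_col = ncol(X), min_neff = min_neff,
                   cluster = cluster, variance = variance)
  tibble::tibble(age = age0, beta_interaction = fit$beta[1], se = fit$se,
                 p = fit$p, n_eff = fit$n_eff, masked = !is.na(fit$reason),
                 reason = fit$reason)
}

#' Age-resolved sex-stratified association scan
#'
#' For each sex x band, regresses every pair's standardized coherence on the
#' standardized score at each integer age grid point, using tricube kernel
#' weights in age combined with the structural observation weights of
#' [compute_weights()], then applies Benjamini-Hochberg masking at level `q`
#' within each sex x band family (all pairs x grid points jointly). A cell
#' is flagged significant only if it is BH-significant at `q` *and* its
#' p-value is below `p_ceiling` (default 1e-4): in a family rich in true
#' signal the BH step-up boundary rises, and the absolute ceiling keeps the
#' flagged set familywise-clean in null regions, mirroring the operational
#' rule of requiring p < 1e-4 at FDR < 0.01.
#' Coherence is standardized per pair x band over the analysis sample before
#' fitting, so `beta` reads as SD of coherence per SD of score.
#'
#' @param phenotypes Long tibble (from [simulate_phenotypes()] or
#'   [coherence_table()] joined to visits): columns `iid`, `fid`, `sex`,
#'   `age`, `pair_id`, `band`, `coherence`.
#' @param score Tibble with columns `iid` and `score_z`.
#' @param covariates Optional tibble keyed by `iid` whose remaining columns
#'   enter every model (e.g. genotyping array, ancestry PCs, substance use).
#' @param ages Grid points (default 12:31).
#' @param bandwidth Tricube bandwidth in years (default 2).
#' @param min_neff Minimum effective sample size per point (default 30).
#' @param q FDR level for the significance mask (default 0.01).
#' @param p_ceiling Absolute p-value ceiling a cell must also clear to be
#'   flagged significant (default 1e-4; `Inf` disables it).
#' @param variance Variance estimator for the Wald tests: family-clustered
#'   CR2 sandwich ("cluster", default) or effective-sample-size model-based
#'   ("model"); see [local_fit()].
#' @return A `trajectory_grid` tibble: `sex`, `band`, `pair_id`, `age`,
#'   `beta`, `se`, `p`, `neglog10p`, `n_eff`, `significant`, `reason`;
#'   attributes `fdr_cutoffs` (per sex x band), `q`, `bandwidth`.
#' @export
trajectory_scan <- function(phenotypes, score, covariates = NULL,
                            ages = 12:31, bandwidth = 2, min_neff = 30,
                            q = 0.01, p_ceiling = 1e-4,
                            variance = c("cluster", "model")) {
  variance <- match.arg(variance)
  req <- c("iid", "fid", "sex", "age", "pair_id", "band", "coherence")
  stopifnot(all(req %in% names(phenotypes)))
  n_before <- dplyr::n_distinct(phenotypes[, c("iid", "age")])
  obs <- dplyr::inner_join(phenotypes, score[, c("iid", "score_z")],
                           by = "iid")
  if (!is.null(covariates)) {
    obs <- dplyr::inner_join(obs, covariates, by = "iid")
  }
  n_after <- dplyr::n_distinct(obs[, c("iid", "age")])
  if (n_after < 0.9 * n_before) {
    warning("join to score/covariates lost ", n_before - n_after, " of ",
            n_before, " visits (> 10%)", call. = FALSE)
  }
  cov_cols <- if (is.null(covariates)) character() else {
    setdiff(names(covariates), "iid")
  }

  # standardize coherence per pair x band over the analysis sample
  obs <- dplyr::mutate(dplyr::group_by(obs, .data$pair_id, .data$band),
                       y = standardize(.data$coherence))
  obs <- dplyr::ungroup(obs)

  grid <- purrr::map_dfr(
    split(obs, list(obs$sex, obs$band), drop = TRUE),
    function(stratum) {
      sex <- stratum$sex[1]
      band <- stratum$band[1]
      wide <- tidyr::pivot_wider(
        stratum[, c("iid", "fid", "age", "pair_id", "y", "score_z",
                    cov_cols)],
        names_from = "pair_id", values_from = "y", names_prefix = "pair_")
      wide <- compute_weights(wide)
      pair_cols <- grep("^pair_", names(wide), value = TRUE)
      pair_ids <- as.integer(sub("^pair_", "", pair_cols))
      Y <- as.matrix(wide[, pair_cols, drop = FALSE])
      X <- build_design(wide, cov_cols)
      purrr::map_dfr(ages, function(a) {
        kern <- tricube((wide$age - a) / bandwidth)
        fit <- wls_point(X, Y, wide$weight * kern, score_col = 2L,
                         min_neff = min_neff, cluster = wide$fid,
                         variance = variance)
        tibble::tibble(sex = sex, band = band, pair_id = pair_ids, age = a,
                       beta = fit$beta, se = fit$se, p = fit$p,
                       n_eff = fit$n_eff, reason = fit$reason)
      })
    }
  )

  grid$neglog10p <- -log10(grid$p)
  # FDR family: all pairs x grid points within one sex x band analysis;
  # the effective cutoff is the BH boundary capped by the ceiling
  grid <- dplyr::group_by(grid, .data$sex, .data$band)
  masked <- dplyr::group_modify(grid, function(df, key) {
    if (all(is.na(df$p))) {
      df$significant <- FALSE
      return(df)
    }
    fm <- fdr_mask(df$p, q = q)
    df$significant <- fm$mask & !is.na(df$p) & df$p < p_ceiling
    df
  })
  cutoffs <- dplyr::summarise(
    grid,
    cutoff = {
      pp <- .data$p
      if (all(is.na(pp))) NA_real_ else {
        min(fdr_mask(pp, q = q)$cutoff, p_ceiling)
      }
    },
    .groups = "drop"
  )
  out <- dplyr::ungroup(masked)
  out <- dplyr::arrange(out, .data$sex, .data$band, .data$pair_id,
                        .data$age)
  out <- out[, c("sex", "band", "pair_id", "age", "beta", "se", "p",
                 "neglog10p", "n_eff", "significant", "reason")]
  structure(tibble::new_tibble(out, class = "trajectory_grid"),
            fdr_cutoffs = cutoffs, q = q, p_ceiling = p_ceiling,
            bandwidth = bandwidth)
}

#' @exportS3Method generics::tidy
tidy.trajectory_grid <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @exportS3Method generics::glance
glance.trajectory_grid <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    n_fitted = sum(!is.na(x$p)),
    n_significant = sum(x$significant, na.rm = TRUE),
    q = attr(x, "q"),
    bandwidth = attr(x, "bandwidth"),
    min_p = suppressWarnings(min(x$p, na.rm = TRUE))
  )
}
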