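# Observation weights, locally weighted fits, sex-interaction models, FDR
# masking and the full scan: reductions to closed forms, independent
# oracles, and the statistical invariants of the estimator.

test_that("observation weights downweight visits and family co-members", {
  obs <- tibble::tibble(iid = "A", fid = "F1", x = 1)
  expect_equal(compute_weights(obs)$weight, 1)
  sibs <- tibble::tibble(iid = rep(c("A", "B"), each = 2),
                         fid = "F1", visit = c(1, 2, 1, 2))
  expect_equal(compute_weights(sibs)$weight, rep(0.25, 4))
  # invariants on a simulated cohort: individual sums 1/m_f, family sums 1
  cohort <- make_cohort(n_families = 60, seed = 3,
                        pairs = coherence_pairs()[1, ])
  w <- compute_weights(dplyr::distinct(cohort$phenotypes, iid, fid, visit))
  fam_tot <- as.numeric(tapply(w$weight, w$fid, sum))
  expect_equal(fam_tot, rep(1, length(fam_tot)), tolerance = 1e-12)
  m_f <- tapply(w$iid, w$fid, function(x) length(unique(x)))
  ind_tot <- tapply(w$weight, w$iid, sum)
  fid_of <- tapply(w$fid, w$iid, function(x) x[1])
  expect_equal(as.numeric(ind_tot), as.numeric(1 / m_f[fid_of]),
               tolerance = 1e-12)
})

test_that("local_fit reduces to the global OLS slope", {
  set.seed(50)
  n <- 200
  dat <- tibble::tibble(score_z = rnorm(n), age = runif(n, 12, 31))
  dat$y <- 0.3 * dat$score_z + rnorm(n)
  fit <- local_fit(dat, age0 = 20, bandwidth = Inf, variance = "model")
  ols <- unname(coef(lm(y ~ score_z, dat))[2])
  expect_equal(fit$beta, ols, tolerance = 1e-10)
  # equal structural weights change nothing
  dat$weight <- 0.37
  expect_equal(local_fit(dat, 20, bandwidth = Inf,
                         variance = "model")$beta,
               ols, tolerance = 1e-10)
  # all ages at the grid point: kernel becomes flat
  dat2 <- dplyr::mutate(dat, age = 20)
  expect_equal(local_fit(dat2, 20, bandwidth = 2,
                         variance = "model")$beta,
               unname(coef(lm(y ~ score_z, dat2))[2]), tolerance = 1e-10)
})

test_that("local_fit masks underpowered and degenerate grid points", {
  set.seed(51)
  dat <- tibble::tibble(score_z = rnorm(40), age = runif(40, 12, 14))
  dat$y <- rnorm(40)
  far <- local_fit(dat, age0 = 30, bandwidth = 2)
  expect_true(far$masked)
  expect_equal(far$reason, "too_few_observations")
  thin <- local_fit(dat, age0 = 13, bandwidth = 2, min_neff = 1000)
  expect_true(thin$masked)
  expect_equal(thin$reason, "min_neff")
  const <- dplyr::mutate(dat, score_z = 1)
  expect_equal(local_fit(const, 13, bandwidth = 2)$reason,
               "rank_deficient")
})

test_that("covariates enter the design and absorb confounding", {
  set.seed(52)
  n <- 400
  batch <- sample(c("arrayA", "arrayB"), n, replace = TRUE)
  dat <- tibble::tibble(score_z = rnorm(n) + 0.8 * (batch == "arrayB"),
                        age = runif(n, 12, 31),
                        array = batch)
  dat$y <- 1.0 * (batch == "arrayB") + rnorm(n)
  naive <- local_fit(dat, 20, bandwidth = Inf, variance = "model")
  adj <- local_fit(dat, 20, bandwidth = Inf, covariates = "array",
                   variance = "model")
  expect_gt(abs(naive$beta), abs(adj$beta))
  ref <- unname(coef(lm(y ~ score_z + array, dat))["score_z"])
  expect_equal(adj$beta, ref, tolerance = 1e-10)
})

test_that("interaction_fit isolates sex-specific score effects", {
  set.seed(53)
  n <- 800
  dat <- tibble::tibble(score_z = rnorm(n), age = runif(n, 15, 19),
                        sex = rep(c("male", "female"), n / 2))
  # identical effect in both sexes: interaction indistinguishable from 0
  dat$y <- 0.2 * dat$score_z + rnorm(n)
  hom <- interaction_fit(dat, 17, bandwidth = Inf)
  expect_lt(abs(hom$beta_interaction), 2 * hom$se)
  expect_error(interaction_fit(dat[dat$sex == "male", ], 17),
               "both sexes")
  expect_error(interaction_fit(dplyr::mutate(dat, score_z = 0), 17),
               "no variance")
})

test_that("a male-only planted effect yields a powered interaction test", {
  hits <- sapply(1:10, function(r) {
    cohort <- make_cohort(n_families = 913, seed = 400 + r,
                          effects = planted_effects(pair_ids = 21),
                          pairs = coherence_pairs()[21, ])
    ph <- dplyr::inner_join(cohort$phenotypes, cohort$score, by = "iid")
    ph$y <- standardize(ph$coherence)
    ph <- compute_weights(ph)
    interaction_fit(ph, 17, bandwidth = 2)$p < 0.05
  })
  expect_gte(sum(hits), 7)  # nominal power > 0.8
})

test_that("fdr_mask enumerates the step-up rule and matches p.adjust", {
  ex <- fdr_mask(c(0.001, 0.01, 0.02, 0.04, 0.2), q = 0.05)
  expect_equal(ex$n_rejected, 4)
  expect_equal(ex$cutoff, 0.04)
  expect_equal(ex$mask, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(fdr_mask(rep(1, 10), q = 0.05)$n_rejected, 0)
  m <- 20
  expect_equal(fdr_mask(rep(0.05 / m, m), q = 0.05)$n_rejected, m)
  expect_error(fdr_mask(numeric(0)), "empty")
  expect_error(fdr_mask(c(0.5, 1.2)), "\\(0, 1\\]")
  set.seed(54)
  for (r in 1:50) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    got <- fdr_mask(p, q)
    expect_identical(got$mask, stats::p.adjust(p, "BH") <= q)
    expect_identical(got$mask, bh_oracle(p, q))
  }
})

test_that("trajectory_scan covers the full grid deterministically", {
  cohort <- make_cohort(n_families = 200, seed = 5)
  g <- trajectory_scan(cohort$phenotypes, cohort$score, min_neff = 10)
  expect_s3_class(g, "trajectory_grid")
  expect_equal(nrow(g), 2 * 27 * 20)
  expect_equal(sort(unique(g$pair_id)), 1:27)
  expect_equal(sort(unique(g$age)), 12:31)
  # -log10 p consistent with p
  ok <- !is.na(g$p)
  expect_equal(g$neglog10p[ok], -log10(g$p[ok]), tolerance = 1e-10)
  expect_true(all(g$p[ok] > 0 & g$p[ok] <= 1))
  g2 <- trajectory_scan(cohort$phenotypes, cohort$score, min_neff = 10)
  expect_identical(tibble::as_tibble(g), tibble::as_tibble(g2))
  gl <- glance(g)
  expect_equal(gl$n_cells, 1080)
})

test_that("scan warns when the score join loses visits", {
  cohort <- make_cohort(n_families = 60, seed = 6,
                        pairs = coherence_pairs()[1, ])
  partial <- cohort$score[seq_len(floor(nrow(cohort$score) * 0.5)), ]
  expect_warning(
    trajectory_scan(cohort$phenotypes, partial, min_neff = 5),
    "> 10%")
})

test_that("permuting scores destroys planted significance", {
  cohort <- make_cohort(n_families = 913, seed = 77,
                        pairs = coherence_pairs()[11:21, ])
  g <- trajectory_scan(cohort$phenotypes, cohort$score)
  expect_gt(sum(g$significant, na.rm = TRUE), 0)
  set.seed(78)
  null_counts <- sapply(1:10, function(r) {
    perm <- cohort$score
    perm$score_z <- sample(perm$score_z)
    gp <- trajectory_scan(cohort$phenotypes, perm)
    sum(gp$significant, na.rm = TRUE)
  })
  expect_gte(sum(null_counts == 0), 9)
})

test_that("narrower bandwidths inflate standard errors everywhere", {
  cohort <- make_cohort(n_families = 913, seed = 8,
                        effects = planted_effects()[0, ],
                        pairs = coherence_pairs()[21, ])
  ph <- dplyr::inner_join(cohort$phenotypes, cohort$score, by = "iid")
  ph$y <- standardize(ph$coherence)
  ph <- compute_weights(ph)
  for (vmeth in c("model", "cluster")) {
    ses <- sapply(c(1, 2, 4), function(h) {
      sapply(12:31, function(a) {
        local_fit(ph, a, bandwidth = h, variance = vmeth)$se
      })
    })
    full <- complete.cases(ses)
    expect_true(all(ses[full, 1] > ses[full, 2]))
    expect_true(all(ses[full, 2] > ses[full, 3]))
  }
})

test_that("age-bin summaries reduce grid cells by quantile", {
  cohort <- make_cohort(n_families = 200, seed = 9,
                        pairs = coherence_pairs()[1:5, ])
  g <- trajectory_scan(cohort$phenotypes, cohort$score, min_neff = 10)
  smry <- age_bin_summary(g)
  expect_equal(nrow(smry), 2 * 5 * 3)
  first_bin <- smry[smry$bin == "12-17", ]
  expect_true(all(first_bin$n_points == 6))
  # quantile equals an independent order-statistic computation
  cell <- tibble::as_tibble(g)
  cell <- cell[cell$sex == "male" & cell$pair_id == 1 &
                 cell$age >= 12 & cell$age <= 17 & !is.na(cell$p), ]
  x <- sort(cell$neglog10p)
  h <- (length(x) - 1) * 0.25 + 1
  manual <- x[floor(h)] + (h - floor(h)) * (x[ceiling(h)] - x[floor(h)])
  got <- smry$neglog10p_q[smry$sex == "male" & smry$pair_id == 1 &
                            smry$bin == "12-17"]
  expect_equal(got, manual, tolerance = 1e-12)
  # constant grid reduces to the constant
  gc <- g
  gc$neglog10p <- 3
  sc <- age_bin_summary(gc)
  expect_true(all(sc$neglog10p_q[!is.na(sc$neglog10p_q)] == 3))
})

test_that("render_table1 lays out 27 labelled pair rows", {
  cohort <- make_cohort(n_families = 150, seed = 10,
                        pairs = coherence_pairs()[1:3, ])
  g <- trajectory_scan(cohort$phenotypes, cohort$score, min_neff = 10)
  tab <- render_table1(age_bin_summary(g))
  expect_equal(nrow(tab), 27)
  expect_equal(tab$pair_label[21], "P4-O2--P3-O1")
  # pairs without fitted cells render as blank, not NA
  expect_true(all(is.na(tab[["12-17 | male"]][4:27]) |
                    tab[["12-17 | male"]][4:27] == ""))
  p <- plot_trajectory_heatmap(g, band = "high_alpha")
  expect_s3_class(p, "ggplot")
})
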