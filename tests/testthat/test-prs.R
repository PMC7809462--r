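# Quality control, allele alignment, LD clumping and ln(OR)-weighted
# scoring, each checked against independently coded oracles.

test_that("qc_filter logs one reason per exclusion in the fixed rule order", {
  g <- toy_genotypes(n_ind = 40, n_var = 7, seed = 1)
  v <- g$variants
  v$info[1] <- 0.2
  v$a1[2] <- "A"; v$a2[2] <- "T"
  v$maf[3] <- 0
  v$call_rate[4] <- 0.90
  v$hwe_p[5] <- 1e-8
  v$maf[6] <- 0.0001
  # variant 7 stays clean
  g <- genotype_set(g$dosage, v, g$fam)
  out <- qc_filter(g)
  expect_equal(ncol(out$genotypes$dosage), 1)
  expect_equal(out$genotypes$variants$snp, "rs007")
  expect_equal(out$exclusions$reason,
               c("info", "palindromic", "monomorphic", "call_rate", "hwe",
                 "maf"))
  # the first failing rule wins: info failure trumps a palindromic pair
  v$a1[1] <- "C"; v$a2[1] <- "G"
  out2 <- qc_filter(genotype_set(g$dosage, v, g$fam))
  expect_equal(out2$exclusions$reason[out2$exclusions$snp == "rs001"],
               "info")
})

test_that("align_alleles orients effects to the counted allele", {
  g <- toy_genotypes(n_ind = 10, n_var = 4, seed = 2)
  v <- g$variants
  v$a1 <- c("A", "G", "C", "A"); v$a2 <- c("G", "A", "T", "C")
  g <- genotype_set(g$dosage, v, g$fam)
  stats <- tibble::tibble(
    snp = c("rs001", "rs002", "rs003", "rs004", "rs999"),
    chr = 1L, pos = c(10000L, 20000L, 30000L, 40000L, 90000L),
    a1 = c("A", "A", "C", "C", "A"),
    a2 = c("G", "G", "G", "T", "G"),
    or = c(1.5, 1.5, 1.5, 2, 1.1),
    p = rep(0.01, 5))
  out <- align_alleles(stats, g)
  al <- out$aligned
  expect_equal(al$effect[al$snp == "rs001"], log(1.5))   # direct
  expect_equal(al$effect[al$snp == "rs002"], -log(1.5))  # swapped
  expect_equal(out$exclusions$reason[out$exclusions$snp == "rs003"],
               "palindromic")
  expect_equal(out$exclusions$reason[out$exclusions$snp == "rs004"],
               "allele_mismatch")
  expect_equal(out$exclusions$reason[out$exclusions$snp == "rs999"],
               "not_in_panel")
  # chr:pos fallback when the id differs
  stats2 <- stats[1, ]
  stats2$snp <- "chr1_variant"
  out2 <- align_alleles(stats2, g)
  expect_equal(out2$aligned$matched_by, "position")
  expect_equal(out2$aligned$snp, "rs001")
})

test_that("ld_r2 equals a brute-force correlation and handles degeneracies", {
  expect_equal(ld_r2(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1)
  a <- c(0, 2, 0, 2)
  b <- c(1, 1 + 1e-6, 1 + 1e-6, 1)  # orthogonal to a by construction
  expect_lt(ld_r2(a, b), 1e-10)
  expect_warning(r0 <- ld_r2(c(1, 1, 1), c(0, 1, 2)), "zero")
  expect_equal(r0, 0)
  expect_error(ld_r2(c(1, NA, NA), c(NA, 1, 2)), "at least 2")
  set.seed(30)
  x <- rbinom(50, 2, 0.3); y <- rbinom(50, 2, 0.4)
  # brute force from sums, no call to cor()
  n <- 50
  num <- sum(x * y) - sum(x) * sum(y) / n
  den <- sqrt((sum(x^2) - sum(x)^2 / n) * (sum(y^2) - sum(y)^2 / n))
  expect_equal(ld_r2(x, y), (num / den)^2, tolerance = 1e-12)
})

test_that("clump follows the greedy window rule on a constructed panel", {
  set.seed(31)
  n <- 60
  da <- rbinom(n, 2, 0.4)
  # B correlated with A above threshold; C essentially uncorrelated
  db <- ifelse(runif(n) < 0.55, da, rbinom(n, 2, 0.4))
  dc <- rbinom(n, 2, 0.4)
  stopifnot(cor(da, db)^2 >= 0.1, cor(da, dc)^2 < 0.1)
  dos <- cbind(A = da, B = db, C = dc)
  rownames(dos) <- sprintf("ID%02d", 1:n)
  v <- tibble::tibble(snp = c("A", "B", "C"), chr = 1L,
                      pos = c(1000000L, 1050000L, 1100000L),
                      a1 = "A", a2 = "G",
                      maf = pmin(colMeans(dos) / 2, 1 - colMeans(dos) / 2),
                      call_rate = 1, hwe_p = 0.5, info = 1)
  fam <- tibble::tibble(iid = rownames(dos), fid = rownames(dos),
                       sex = "male", founder = TRUE)
  g <- genotype_set(dos, v, fam)
  aligned <- tibble::tibble(snp = c("A", "B", "C"), chr = 1L,
                            pos = v$pos, effect = 0.1,
                            p = c(1e-8, 1e-5, 1e-6))
  kept <- clump(aligned, g)
  expect_setequal(kept$snp, c("A", "C"))
  # a single variant is always retained
  expect_equal(clump(aligned[1, ], g)$snp, "A")
  # identical dosages beyond the physical window are both retained
  far <- aligned[c(1, 2), ]
  far$pos[2] <- far$pos[1] + 600000L
  dos_far <- cbind(A = da, B = da)
  rownames(dos_far) <- rownames(dos)
  gfar <- genotype_set(dos_far,
                       dplyr::mutate(v[c(1, 1), ],
                                     snp = c("A", "B"),
                                     pos = far$pos), fam)
  expect_setequal(clump(far, gfar)$snp, c("A", "B"))
})

test_that("clump matches an exhaustive oracle and yields an independent set", {
  for (r in 1:30) {
    g <- toy_genotypes(n_ind = 50, n_var = 20, seed = 200 + r,
                       pos = sort(sample.int(2000000L, 20)))
    set.seed(300 + r)
    aligned <- tibble::tibble(snp = g$variants$snp, chr = g$variants$chr,
                              pos = g$variants$pos,
                              effect = rnorm(20, 0, 0.05),
                              p = runif(20))
    kept <- clump(aligned, g, window_bp = 250000, r2_threshold = 0.2)
    oracle <- clump_oracle(aligned, g$dosage[g$fam$founder, ],
                           window_bp = 250000, r2_threshold = 0.2)
    expect_identical(sort(kept$snp), oracle)
    # post-hoc independence: no retained pair within the window at r2 >=
    # threshold
    if (nrow(kept) > 1) {
      cmb <- utils::combn(nrow(kept), 2)
      for (j in seq_len(ncol(cmb))) {
        i1 <- cmb[1, j]; i2 <- cmb[2, j]
        if (kept$chr[i1] == kept$chr[i2] &&
            abs(kept$pos[i1] - kept$pos[i2]) <= 250000) {
          r2 <- suppressWarnings(
            ld_r2(g$dosage[g$fam$founder, kept$snp[i1]],
                  g$dosage[g$fam$founder, kept$snp[i2]]))
          expect_lt(r2, 0.2)
        }
      }
    }
  }
})

test_that("scores are the ln(OR)-weighted dosage sums", {
  dos <- matrix(c(2, 1), 1, 2, dimnames = list("ID1", c("rs1", "rs2")))
  v <- tibble::tibble(snp = c("rs1", "rs2"), chr = 1L, pos = c(1L, 2L),
                      a1 = "A", a2 = "G", maf = 0.3, call_rate = 1,
                      hwe_p = 0.5, info = 1)
  fam <- tibble::tibble(iid = "ID1", fid = "F1", sex = "male",
                       founder = TRUE)
  g <- genotype_set(dos, v, fam)
  aligned <- tibble::tibble(snp = c("rs1", "rs2"), effect = log(c(1.2, 0.8)),
                            p = c(0.001, 0.001))
  out <- prs_score(g, aligned, thresholds = 0.05)
  expect_equal(out$raw, 2 * log(1.2) + 1 * log(0.8), tolerance = 1e-12)
  # all OR = 1: zero for everyone, with the no-variance z warning upstream
  aligned0 <- dplyr::mutate(aligned, effect = 0)
  expect_equal(prs_score(g, aligned0, thresholds = 0.05)$raw, 0)
  # missing dosage imputes 2 * MAF
  dos_na <- dos; dos_na[1, 2] <- NA
  gna <- genotype_set(dos_na, v, fam)
  expect_equal(prs_score(gna, aligned, thresholds = 0.05)$raw,
               2 * log(1.2) + 2 * 0.3 * log(0.8), tolerance = 1e-12)
  # no variants below the threshold: all-zero scores with a warning
  expect_warning(z0 <- prs_score(g, aligned, thresholds = 1e-6),
                 "no variants")
  expect_equal(z0$raw, 0)
})

test_that("scores match a brute-force oracle and are flip-invariant", {
  g <- toy_genotypes(n_ind = 100, n_var = 200, seed = 44)
  set.seed(45)
  aligned <- tibble::tibble(snp = g$variants$snp,
                            effect = rnorm(200, 0, 0.1),
                            p = runif(200))
  out <- suppressWarnings(prs_score(g, aligned, thresholds = prs_thresholds()))
  # brute force: per-individual loop over variants
  for (T in c(0.01, 0.5)) {
    sel <- which(aligned$p < T)
    brute <- vapply(seq_len(100), function(i) {
      s <- 0
      for (j in sel) s <- s + g$dosage[i, aligned$snp[j]] * aligned$effect[j]
      s
    }, numeric(1))
    got <- out$raw[out$threshold == T]
    expect_lt(max(abs(got - brute)), 1e-12)
  }
  # n_variants is monotone non-decreasing in the threshold
  nv <- dplyr::distinct(out, threshold, n_variants)
  expect_true(all(diff(nv$n_variants[order(nv$threshold)]) >= 0))
  # allele-orientation flip: Z-scores and ranks unchanged
  gf <- flip_orientation(g)
  aligned_f <- dplyr::mutate(aligned, effect = -effect)
  outf <- prs_score(gf, aligned_f, thresholds = 0.5)
  base <- out[out$threshold == 0.5, ]
  expect_equal(outf$z, base$z, tolerance = 1e-10)
  expect_identical(rank(outf$raw), rank(base$raw))
  # variant reordering leaves scores unchanged
  perm <- sample(200)
  outp <- prs_score(g, aligned[perm, ], thresholds = 0.5)
  expect_equal(outp$raw, base$raw, tolerance = 1e-12)
})

test_that("standardize forces mean 0 / SD 1 and is affine-invariant", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(46)
  x <- rnorm(50, 10, 3)
  z <- standardize(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1)
  expect_equal(standardize(5 - 2 * x), -z)
  expect_error(standardize(rep(1, 5)), "zero variance")
  expect_error(standardize(1), "at least 2")
})

test_that("extract_variant behaves as a one-variant score", {
  g <- toy_genotypes(n_ind = 30, n_var = 5, seed = 47)
  g$dosage[, 1] <- rep(0:2, each = 10)
  ev <- extract_variant(g, "rs001")
  expect_equal(ev$z, unname(standardize(g$dosage[, 1])))
  g3 <- toy_genotypes(n_ind = 3, n_var = 2, seed = 48)
  g3$dosage[, 1] <- 0:2
  expect_equal(extract_variant(g3, "rs001")$z, c(-1, 0, 1))
  # equivalence with prs_score on that single variant (any OR > 1)
  aligned <- tibble::tibble(snp = "rs002", effect = log(1.4), p = 0.001)
  sc <- prs_score(g, aligned, thresholds = 0.05)
  expect_equal(extract_variant(g, "rs002")$z, sc$z, tolerance = 1e-12)
  g$dosage[, 3] <- 1
  expect_error(extract_variant(g, "rs003"), "monomorphic")
  expect_error(extract_variant(g, "rs00x"), "near matches")
})
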