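#' Simulate a multi-generation family cohort pedigree
#'
#' Generates nuclear families of two founder parents plus one or more
#' offspring. Offspring are the analysis cohort (the individuals with EEG
#' visits); founders serve as the linkage-disequilibrium reference for
#' clumping. The default family-size weights give a mean of about 1.56
#' offspring per family, so 900 families yield roughly 1,400 offspring.
#'
#' @param n_families Number of families.
#' @param offspring_weights Sampling weights for 1, 2, ... offspring per
#'   family (normalized internally).
#' @param sex_ratio Probability that an individual is female.
#' @param seed Master seed; the pedigree draws from its "pedigree" substream.
#' @return A tibble with columns `iid`, `fid`, `father`, `mother` (`NA` for
#'   founders), `sex` ("male"/"female") and `founder` (logical).
#' @export
#' @examples
#' ped <- simulate_pedigree(n_families = 5, seed = 1)
#' ped
simulate_pedigree <- function(n_families = 913,
                              offspring_weights = c(0.55, 0.34, 0.11),
                              sex_ratio = 0.5,
                              seed = 1) {
  if (n_families < 1) stop("n_families must be at least 1", call. = FALSE)
  if (any(offspring_weights < 0) || sum(offspring_weights) <= 0) {
    stop("offspring_weights must be non-negative and sum to > 0", call. = FALSE)
  }
  if (sex_ratio < 0 || sex_ratio > 1) {
    stop("sex_ratio must be in [0, 1]", call. = FALSE)
  }
  with_substream(seed, "pedigree", {
    fids <- sprintf("FAM%04d", seq_len(n_families))
    n_off <- sample(seq_along(offspring_weights), n_families, replace = TRUE,
                    prob = offspring_weights / sum(offspring_weights))
    fam_tbl <- purrr::map2_dfr(fids, n_off, function(fid, k) {
      father <- paste0(fid, "_P1")
      mother <- paste0(fid, "_P2")
      kids <- paste0(fid, "_O", seq_len(k))
      tibble::tibble(
        iid = c(father, mother, kids),
        fid = fid,
        father = c(NA, NA, rep(father, k)),
        mother = c(NA, NA, rep(mother, k)),
        founder = c(TRUE, TRUE, rep(FALSE, k))
      )
    })
    # Founder sexes are fixed by role; offspring sexes are random.
    sex <- ifelse(grepl("_P1$", fam_tbl$iid), "male",
                  ifelse(grepl("_P2$", fam_tbl$iid), "female",
                         ifelse(runif(nrow(fam_tbl)) < sex_ratio,
                                "female", "male")))
    dplyr::relocate(dplyr::mutate(fam_tbl, sex = sex), "sex",
                    .after = "mother")
  })
}

#' Construct a genotype set
#'
#' Container for a dosage matrix plus variant and sample metadata, the common
#' currency of the polygenic-scoring operations.
#'
#' @param dosage Numeric matrix, individuals x variants, entries in `[0, 2]`
#'   or `NA`; rownames are individual ids, colnames variant ids.
#' @param variants Tibble with one row per variant: `snp`, `chr`, `pos`,
#'   `a1` (counted allele: dosage counts copies of `a1`), `a2`, `maf`,
#'   `call_rate`, `hwe_p`, `info`.
#' @param fam Tibble with one row per individual: `iid`, `fid`, `sex`,
#'   `founder`.
#' @return An object of class `genotype_set`.
#' @export
genotype_set <- function(dosage, variants, fam) {
  stopifnot(is.matrix(dosage))
  if (is.null(rownames(dosage)) || is.null(colnames(dosage))) {
    stop("dosage matrix needs individual rownames and variant colnames",
         call. = FALSE)
  }
  req_v <- c("snp", "chr", "pos", "a1", "a2", "maf", "call_rate", "hwe_p",
             "info")
  if (!all(req_v %in% names(variants))) {
    stop("variants is missing columns: ",
         paste(setdiff(req_v, names(variants)), collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("iid", "fid", "sex", "founder") %in% names(fam))) {
    stop("fam needs columns iid, fid, sex, founder", call. = FALSE)
  }
  if (!identical(colnames(dosage), variants$snp)) {
    stop("dosage colnames must match variants$snp in order", call. = FALSE)
  }
  if (!identical(rownames(dosage), fam$iid)) {
    stop("dosage rownames must match fam$iid in order", call. = FALSE)
  }
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  structure(list(dosage = dosage, variants = tibble::as_tibble(variants),
                 fam = tibble::as_tibble(fam)),
            class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat("<genotype_set> ", nrow(x$dosage), " individuals x ",
      ncol(x$dosage), " variants (",
      sum(x$fam$founder), " founders)\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_set <- function(x) dim(x$dosage)

# Hardy-Weinberg chi-square p-value from hard genotype counts.
hwe_pvalue <- function(dosage) {
  d <- round(dosage[!is.na(dosage)])
  n <- length(d)
  if (n == 0) return(NA_real_)
  p <- mean(d) / 2
  if (p <= 0 || p >= 1) return(1)
  obs <- c(sum(d == 0), sum(d == 1), sum(d == 2))
  expc <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stat <- sum((obs - expc)^2 / expc)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

# Correlation of two threshold-Gaussian binary indicators with latent
# correlation rho and marginal frequencies p1, p2; the orthant probability
# P(Z1 < a, Z2 < b) is computed by one-dimensional integration.
binary_corr <- function(rho, p1, p2) {
  a <- stats::qnorm(p1)
  b <- stats::qnorm(p2)
  p11 <- stats::integrate(function(z) {
    stats::pnorm((b - rho * z) / sqrt(1 - rho^2)) * stats::dnorm(z)
  }, -8, a, rel.tol = 1e-8)$value
  (p11 - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
}

# Latent equicorrelation whose induced mean squared binary correlation,
# averaged over frequency pairs drawn across freq_range, matches r2_target.
calibrate_latent_rho <- function(r2_target, freq_range) {
  if (r2_target <= 0) return(0)
  # midpoint rule over independent frequency draws
  edges <- seq(freq_range[1], freq_range[2], length.out = 10)
  fr <- (edges[-1] + edges[-10]) / 2
  pairs <- t(as.matrix(expand.grid(fr, fr)))
  mean_r2 <- function(rho) {
    mean(apply(pairs, 2, function(pp) binary_corr(rho, pp[1], pp[2])^2))
  }
  hi <- 0.9999
  if (mean_r2(hi) <= r2_target) return(hi)  # target unreachable; saturate
  stats::uniroot(function(rho) mean_r2(rho) - r2_target,
                 c(1e-4, hi), tol = 1e-5)$root
}

# Non-palindromic allele pairs (palindromic = A/T or C/G, strand-ambiguous).
.allele_pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"),
                       c("C", "A"), c("G", "A"), c("T", "C"), c("T", "G"))

#' Simulate LD-structured family genotypes
#'
#' Draws founder haplotypes from a finite per-block ancestral haplotype pool
#' (a copying model) and transmits one haplotype per parent per block to each
#' offspring, so Mendelian consistency holds at every locus and within-block
#' linkage disequilibrium is tunable without coalescent machinery. Pool
#' haplotypes come from a latent equicorrelated Gaussian whose correlation
#' is calibrated (via bivariate-normal orthant probabilities) so the mean
#' within-block dosage r2 matches `r2_target`; smaller pools inflate
#' realized r2 (more haplotype sharing), larger pools converge to the
#' target.
#'
#' @param pedigree Output of [simulate_pedigree()].
#' @param n_blocks Number of independent LD blocks.
#' @param snps_per_block Variants per block.
#' @param block_length_bp Physical span of a block in bases; variants are
#'   evenly spaced within it. Blocks are separated by 1 Mb gaps.
#' @param n_haplotypes_per_block Ancestral pool size per block.
#' @param r2_target Desired mean within-block dosage r2 (realized value
#'   depends on pool size).
#' @param freq_range Range from which ancestral allele frequencies are drawn.
#' @param missing_rate Fraction of dosages set missing at random.
#' @param seed Master seed ("genotypes" substream).
#' @return A [genotype_set()].
#' @export
simulate_genotypes <- function(pedigree,
                               n_blocks = 20,
                               snps_per_block = 10,
                               block_length_bp = 100000,
                               n_haplotypes_per_block = 16,
                               r2_target = 0.4,
                               freq_range = c(0.1, 0.5),
                               missing_rate = 0,
                               seed = 1) {
  if (n_blocks < 1 || snps_per_block < 1) {
    stop("need at least one block and one SNP per block", call. = FALSE)
  }
  if (nrow(pedigree) == 0) stop("empty pedigree", call. = FALSE)
  with_substream(seed, "genotypes", {
    m <- n_blocks * snps_per_block
    rho <- calibrate_latent_rho(r2_target, freq_range)

    chr <- ((seq_len(n_blocks) - 1) %% 22) + 1
    spacing <- max(1, floor(block_length_bp / snps_per_block))
    founders <- pedigree$iid[pedigree$founder]
    offspring <- pedigree$iid[!pedigree$founder]
    n_f <- length(founders)

    # Per block: pool haplotypes (H x s), founder haplotype indices, then
    # transmission of whole block haplotypes to offspring.
    blocks <- purrr::map(seq_len(n_blocks), function(b) {
      s <- snps_per_block
      H <- n_haplotypes_per_block
      freqs <- runif(s, freq_range[1], freq_range[2])
      z_shared <- rnorm(H)
      z <- sqrt(rho) * matrix(z_shared, H, s) +
        sqrt(1 - rho) * matrix(rnorm(H * s), H, s)
      pool <- (z < matrix(stats::qnorm(freqs), H, s, byrow = TRUE)) * 1L

      hap_idx_f <- matrix(sample.int(H, 2 * n_f, replace = TRUE), n_f, 2,
                          dimnames = list(founders, NULL))
      hap <- array(0L, dim = c(nrow(pedigree), 2, s),
                   dimnames = list(pedigree$iid, NULL, NULL))
      hap[founders, 1, ] <- pool[hap_idx_f[, 1], , drop = FALSE]
      hap[founders, 2, ] <- pool[hap_idx_f[, 2], , drop = FALSE]
      ped_off <- pedigree[!pedigree$founder, ]
      pick_f <- sample.int(2, nrow(ped_off), replace = TRUE)
      pick_m <- sample.int(2, nrow(ped_off), replace = TRUE)
      for (i in seq_len(nrow(ped_off))) {
        hap[ped_off$iid[i], 1, ] <- hap[ped_off$father[i], pick_f[i], ]
        hap[ped_off$iid[i], 2, ] <- hap[ped_off$mother[i], pick_m[i], ]
      }
      dos <- hap[, 1, , drop = TRUE] + hap[, 2, , drop = TRUE]
      if (s == 1) dos <- matrix(dos, ncol = 1)
      list(dosage = dos, freqs = freqs)
    })

    dosage <- do.call(cbind, purrr::map(blocks, "dosage"))
    snp_ids <- sprintf("rs%d", seq_len(m) * 101 + 1000)
    colnames(dosage) <- snp_ids
    rownames(dosage) <- pedigree$iid

    if (missing_rate > 0) {
      drop <- runif(length(dosage)) < missing_rate
      dosage[drop] <- NA_real_
    }

    alleles <- .allele_pairs[sample.int(nrow(.allele_pairs), m,
                                        replace = TRUE), , drop = FALSE]
    block_of <- rep(seq_len(n_blocks), each = snps_per_block)
    pos_in_block <- rep(seq_len(snps_per_block), n_blocks)
    # 1 Mb between block starts on the same chromosome keeps blocks outside
    # each other's default clumping window.
    block_rank <- stats::ave(block_of, chr[block_of],
                             FUN = function(x) match(x, unique(x)))
    pos <- (block_rank - 1) * (block_length_bp + 1000000) +
      pos_in_block * spacing

    f_dos <- dosage[founders, , drop = FALSE]
    afreq <- colMeans(f_dos, na.rm = TRUE) / 2
    variants <- tibble::tibble(
      snp = snp_ids,
      chr = chr[block_of],
      pos = as.integer(pos),
      a1 = alleles[, 1],
      a2 = alleles[, 2],
      maf = unname(pmin(afreq, 1 - afreq)),
      call_rate = unname(colMeans(!is.na(dosage))),
      hwe_p = unname(apply(f_dos, 2, hwe_pvalue)),
      info = 1
    )
    fam <- pedigree[, c("iid", "fid", "sex", "founder")]
    genotype_set(dosage, variants, fam)
  })
}
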