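# Fixtures are built in code; nothing is read from disk.

# Unstructured genotype panel with explicit metadata, for PRS-level tests
# that do not need pedigree transmission.
toy_genotypes <- function(n_ind = 20, n_var = 10, seed = 1,
                          n_founders = n_ind, maf_range = c(0.1, 0.5),
                          chr = NULL, pos = NULL) {
  set.seed(seed)
  mafs <- runif(n_var, maf_range[1], maf_range[2])
  dosage <- sapply(mafs, function(p) rbinom(n_ind, 2, p))
  dosage <- matrix(as.numeric(dosage), n_ind, n_var)
  iid <- sprintf("ID%03d", seq_len(n_ind))
  snp <- sprintf("rs%03d", seq_len(n_var))
  rownames(dosage) <- iid
  colnames(dosage) <- snp
  pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))
  al <- pairs[sample.int(4, n_var, replace = TRUE), , drop = FALSE]
  afreq <- colMeans(dosage) / 2
  variants <- tibble::tibble(
    snp = snp,
    chr = if (is.null(chr)) rep(1L, n_var) else chr,
    pos = if (is.null(pos)) seq_len(n_var) * 10000L else pos,
    a1 = al[, 1], a2 = al[, 2],
    maf = unname(pmin(afreq, 1 - afreq)),
    call_rate = 1, hwe_p = 0.5, info = 1
  )
  fam <- tibble::tibble(iid = iid, fid = iid, sex = "female",
                       founder = seq_len(n_ind) <= n_founders)
  genotype_set(dosage, variants, fam)
}

# Flip the allele orientation of every variant: counted allele swapped,
# dosages reflected. Scores must be rank/Z-invariant under this.
flip_orientation <- function(genotypes) {
  v <- genotypes$variants
  genotype_set(2 - genotypes$dosage,
               dplyr::mutate(v, a1 = genotypes$variants$a2,
                             a2 = genotypes$variants$a1),
               genotypes$fam)
}

# Multichannel recording: common broadband source mixed into every
# electrode plus idiosyncratic noise, so all bipolar derivations have power.
make_recording <- function(n = 2^12, fs = 128, seed = 1,
                           electrodes = unique(c(
                             t(coherence_pairs()[, c("a_anode", "a_cathode",
                                                     "b_anode",
                                                     "b_cathode")])))) {
  set.seed(seed)
  common <- rnorm(n)
  rec <- sapply(electrodes, function(e) 0.5 * common + rnorm(n))
  colnames(rec) <- electrodes
  rec
}

# Small analysis-ready cohort: pedigree, visits, standardized score and
# single-band phenotypes.
make_cohort <- function(n_families = 300, seed = 1,
                        effects = planted_effects(),
                        pairs = coherence_pairs(),
                        bands = eeg_bands("high_alpha"), ...) {
  ped <- simulate_pedigree(n_families, seed = seed)
  vis <- simulate_visits(ped, seed = seed)
  set.seed(seed + 13)
  score <- tibble::tibble(iid = ped$iid,
                          score_z = standardize(rnorm(nrow(ped))))
  phen <- simulate_phenotypes(vis, ped, score, effects = effects,
                              pairs = pairs, bands = bands, seed = seed, ...)
  list(pedigree = ped, visits = vis, score = score, phenotypes = phen)
}

# Independently coded greedy clumping oracle: plain data-frame walk using
# cor()^2, no shared code with clump().
clump_oracle <- function(aligned, ref_dosage, window_bp, r2_threshold) {
  df <- as.data.frame(aligned)
  df$state <- "open"
  repeat {
    open <- which(df$state == "open")
    if (length(open) == 0) break
    o <- open[order(df$p[open], df$chr[open], df$pos[open])][1]
    df$state[o] <- "index"
    for (k in which(df$state == "open")) {
      if (df$chr[k] != df$chr[o]) next
      if (abs(df$pos[k] - df$pos[o]) > window_bp) next
      a <- ref_dosage[, df$snp[o]]
      b <- ref_dosage[, df$snp[k]]
      r2 <- if (stats::var(a) == 0 || stats::var(b) == 0) 0 else
        stats::cor(a, b)^2
      if (r2 >= r2_threshold) df$state[k] <- "removed"
    }
  }
  sort(df$snp[df$state == "index"])
}

# Independent Benjamini-Hochberg step-up enumeration.
bh_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  keep <- rep(FALSE, m)
  kmax <- 0
  for (i in seq_len(m)) {
    if (p[ord[i]] <= i * q / m) kmax <- i
  }
  if (kmax > 0) keep[ord[seq_len(kmax)]] <- TRUE
  keep
}
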