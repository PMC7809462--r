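# Plain-text interchange formats: GWAS summary TSV, genotype/fam/variant
# TSVs, phenotype and grid TSVs, VCF dosage import.

#' Write / read GWAS summary statistics
#'
#' The interchange format is a TSV with header
#' `SNP CHR BP A1 A2 OR P` (effect allele A1, odds ratio OR). Generator
#' ground-truth columns are dropped on write.
#'
#' @param stats Summary-statistic tibble (columns `snp`, `chr`, `pos`,
#'   `a1`, `a2`, `or`, `p`).
#' @param path File path.
#' @return `write_summary_stats()` returns `path` invisibly;
#'   `read_summary_stats()` returns a tibble with lower-case column names.
#' @export
write_summary_stats <- function(stats, path) {
  out <- tibble::tibble(SNP = stats$snp, CHR = stats$chr, BP = stats$pos,
                        A1 = stats$a1, A2 = stats$a2, OR = stats$or,
                        P = stats$p)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_summary_stats
#' @export
read_summary_stats <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  req <- c("SNP", "CHR", "BP", "A1", "A2", "OR", "P")
  if (!all(req %in% names(df))) {
    stop("summary-statistics file needs header columns ",
         paste(req, collapse = " "), call. = FALSE)
  }
  tibble::tibble(snp = as.character(df$SNP), chr = df$CHR, pos = df$BP,
                 a1 = toupper(df$A1), a2 = toupper(df$A2), or = df$OR,
                 p = df$P)
}

#' Write / read a genotype set as plain-text TSVs
#'
#' Three files in `dir`: `dosage.tsv` (first column `iid`, then one column
#' per variant), `variants.tsv` and `fam.tsv`.
#'
#' @param genotypes A [genotype_set()].
#' @param dir Directory (created if needed).
#' @return `write_genotypes()` returns `dir` invisibly; `read_genotypes()`
#'   returns a [genotype_set()].
#' @export
write_genotypes <- function(genotypes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dos <- tibble::as_tibble(genotypes$dosage)
  dos <- dplyr::bind_cols(tibble::tibble(iid = rownames(genotypes$dosage)),
                          dos)
  readr::write_tsv(dos, file.path(dir, "dosage.tsv"))
  readr::write_tsv(genotypes$variants, file.path(dir, "variants.tsv"))
  readr::write_tsv(genotypes$fam, file.path(dir, "fam.tsv"))
  invisible(dir)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(dir) {
  dos <- readr::read_tsv(file.path(dir, "dosage.tsv"),
                         show_col_types = FALSE)
  variants <- readr::read_tsv(file.path(dir, "variants.tsv"),
                              show_col_types = FALSE)
  fam <- readr::read_tsv(file.path(dir, "fam.tsv"), show_col_types = FALSE)
  m <- as.matrix(dos[, -1, drop = FALSE])
  rownames(m) <- dos$iid
  genotype_set(m, variants, fam)
}

#' Import dosages from a VCF
#'
#' Reads genotypes from a VCF via the vcfR package, preferring the `DS`
#' (dosage) FORMAT field and falling back to allele counts from `GT`. The
#' counted allele is the VCF ALT allele. Sample metadata beyond ids is not
#' carried in VCF, so every sample is recorded as an unrelated founder;
#' join a pedigree afterwards if one exists.
#'
#' @param path VCF file (plain text or bgzipped).
#' @return A [genotype_set()].
#' @export
read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("VCF import needs the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  has_ds <- "DS" %in% unlist(strsplit(unique(v@gt[, "FORMAT"]), ":"))
  if (has_ds) {
    d <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    d <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(gsub("\\|", "/", g), "/")[[1]]))
    })
  }
  dos <- t(d)  # individuals x variants
  ids <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"])
  colnames(dos) <- ids
  afreq <- colMeans(dos, na.rm = TRUE) / 2
  variants <- tibble::tibble(
    snp = ids,
    chr = suppressWarnings(as.integer(fix[, "CHROM"])),
    pos = as.integer(fix[, "POS"]),
    a1 = toupper(fix[, "ALT"]),
    a2 = toupper(fix[, "REF"]),
    maf = unname(pmin(afreq, 1 - afreq)),
    call_rate = unname(colMeans(!is.na(dos))),
    hwe_p = unname(apply(dos, 2, hwe_pvalue)),
    info = 1
  )
  fam <- tibble::tibble(iid = rownames(dos), fid = rownames(dos),
                        sex = NA_character_, founder = TRUE)
  genotype_set(dos, variants, fam)
}

#' Read a wide-format recording TSV
#'
#' One column per channel (10-20 labels as header), one row per sample.
#'
#' @param path TSV path.
#' @return A numeric matrix with channel labels as column names.
#' @export
read_recording_tsv <- function(path) {
  as.matrix(readr::read_tsv(path, show_col_types = FALSE))
}
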