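#' Construct a genotype study
#'
#' A `genotype_study` holds hard-call genotypes (minor-allele counts) for a
#' case-control cohort, together with SNP metadata, sample identifiers and,
#' optionally, phased haplotypes and risk-haplotype dosages.
#'
#' @param genotypes integer matrix, samples x SNPs, values in `{0,1,2,NA}`
#'   counting copies of the minor allele; `NA` is the missing code.
#' @param phenotype integer vector, one per sample: 1 = case, 0 = control.
#' @param snp_meta data frame with columns `snp`, `chr`, `pos`, `a1`, `a2`
#'   (a1 = counted/minor allele).
#' @param sample_ids character vector of unique sample identifiers.
#' @param phase optional list with 0/1 matrices `h1`, `h2` (samples x SNPs);
#'   wherever the genotype is non-missing, `h1 + h2` must equal it.
#' @param hla optional haplotype-dosage matrix (see [hla_dosage_matrix()]).
#'
#' @return An object of class `genotype_study`.
#' @export
genotype_study <- function(genotypes, phenotype, snp_meta, sample_ids,
                           phase = NULL, hla = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  phenotype <- as.integer(phenotype)
  stopifnot(nrow(genotypes) == length(phenotype),
            nrow(genotypes) == length(sample_ids),
            ncol(genotypes) == nrow(snp_meta))
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotypes must be in {0,1,2,NA}")
  if (!all(phenotype %in% c(0L, 1L)))
    stop("phenotype must be 0 (control) or 1 (case)")
  req <- c("snp", "chr", "pos", "a1", "a2")
  if (!all(req %in% names(snp_meta)))
    stop("snp_meta needs columns: ", paste(req, collapse = ", "))
  rownames(genotypes) <- sample_ids
  colnames(genotypes) <- snp_meta$snp
  if (!is.null(phase)) {
    stopifnot(is.list(phase), all(c("h1", "h2") %in% names(phase)))
    hs <- phase$h1 + phase$h2
    ok <- is.na(genotypes) | hs == genotypes
    if (!all(ok, na.rm = TRUE))
      stop("phase inconsistent with genotypes (h1 + h2 != genotype)")
  }
  structure(list(genotypes = genotypes, phenotype = phenotype,
                 snp_meta = as.data.frame(snp_meta), sample_ids = sample_ids,
                 phase = phase, hla = hla),
            class = "genotype_study")
}

#' @export
print.genotype_study <- function(x, ...) {
  cat(sprintf("genotype_study: %d samples (%d cases / %d controls) x %d SNPs\n",
              nrow(x$genotypes), sum(x$phenotype == 1L),
              sum(x$phenotype == 0L), ncol(x$genotypes)))
  if (!is.null(x$phase)) cat("  phased haplotypes present\n")
  if (!is.null(x$hla))
    cat(sprintf("  risk-haplotype dosages: %d alleles\n", ncol(x$hla$dosages)))
  invisible(x)
}

#' @export
dim.genotype_study <- function(x) dim(x$genotypes)

#' Subset a genotype study by samples and/or SNPs
#'
#' @param study a `genotype_study`.
#' @param samples,snps index vectors (logical or integer) on each axis;
#'   `NULL` keeps everything.
#' @return A `genotype_study`.
#' @export
subset_study <- function(study, samples = NULL, snps = NULL) {
  if (is.null(samples)) samples <- seq_len(nrow(study$genotypes))
  if (is.null(snps)) snps <- seq_len(ncol(study$genotypes))
  phase <- study$phase
  if (!is.null(phase))
    phase <- list(h1 = phase$h1[samples, snps, drop = FALSE],
                  h2 = phase$h2[samples, snps, drop = FALSE])
  hla <- study$hla
  if (!is.null(hla)) hla$dosages <- hla$dosages[samples, , drop = FALSE]
  genotype_study(study$genotypes[samples, snps, drop = FALSE],
                 study$phenotype[samples],
                 study$snp_meta[snps, , drop = FALSE],
                 study$sample_ids[samples], phase = phase, hla = hla)
}

#' Risk-haplotype dosage matrix
#'
#' Container for imputed multi-allelic risk-haplotype dosages (one column
#' per allele, values in `[0, 2]`), as produced by HLA imputation tools or
#' by the synthetic-cohort generator.
#'
#' @param dosages numeric matrix, samples x alleles, values in `[0, 2]`.
#' @param allele_names unique character vector naming the alleles.
#' @return An object of class `hla_dosage_matrix`.
#' @export
hla_dosage_matrix <- function(dosages, allele_names = colnames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(allele_names))
    allele_names <- paste0("allele", seq_len(ncol(dosages)))
  stopifnot(length(allele_names) == ncol(dosages),
            !anyDuplicated(allele_names),
            all(dosages >= 0 & dosages <= 2))
  colnames(dosages) <- allele_names
  structure(list(dosages = dosages, allele_names = allele_names),
            class = "hla_dosage_matrix")
}

# Minor-allele frequency per SNP from a genotype matrix (counted allele).
snp_af <- function(genotypes) colMeans(genotypes, na.rm = TRUE) / 2

# Orient every SNP to count the minor allele in the full sample; swaps
# a1/a2 in the metadata for flipped SNPs.  Done once per cohort so that
# encodings stay stable across any later subsetting.
orient_minor <- function(study) {
  af <- snp_af(study$genotypes)
  flip <- !is.na(af) & af > 0.5
  if (any(flip)) {
    study$genotypes[, flip] <- 2L - study$genotypes[, flip]
    a1 <- study$snp_meta$a1[flip]
    study$snp_meta$a1[flip] <- study$snp_meta$a2[flip]
    study$snp_meta$a2[flip] <- a1
    if (!is.null(study$phase)) {
      study$phase$h1[, flip] <- 1L - study$phase$h1[, flip]
      study$phase$h2[, flip] <- 1L - study$phase$h2[, flip]
    }
  }
  study
}
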