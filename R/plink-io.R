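# PLINK 1 binary (bed/bim/fam) input/output.
#
# bed v1.00, SNP-major: 3 magic bytes 0x6c 0x1b 0x01 then ceiling(n/4)
# bytes per SNP, two bits per sample (low bits = first sample):
#   00 -> two copies of A1, 10 -> one copy, 11 -> zero copies, 01 -> missing.
# fam phenotype on disk: 1 = control, 2 = case (0/-9 = missing, rejected).

.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))

# 256 x 4 lookup: byte value -> genotype codes of its 4 two-bit fields
# (A1-allele counts; NA = missing).
.bed_decode_table <- local({
  two_bit <- c(2L, NA_integer_, 1L, 0L)  # codes 00,01,10,11
  tab <- matrix(NA_integer_, 256, 4)
  for (b in 0:255) {
    v <- b
    for (k in 1:4) {
      tab[b + 1, k] <- two_bit[(v %% 4) + 1]
      v <- v %/% 4
    }
  }
  tab
})

#' Read a PLINK bed/bim/fam cohort
#'
#' Loads hard-call genotypes and re-orients every SNP so that the counted
#' allele is the minor allele in the full sample. Missing genotypes are
#' preserved as `NA`.
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim` and `.fam` must exist.
#' @return A [genotype_study()].
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("missing file: ", f)
  fam_df <- read.table(fam, header = FALSE, stringsAsFactors = FALSE,
                       col.names = c("fid", "iid", "pid", "mid", "sex", "pheno"))
  bim_df <- read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                       col.names = c("chr", "snp", "cm", "pos", "a1", "a2"),
                       colClasses = c("character", "character", "numeric",
                                      "numeric", "character", "character"))
  n <- nrow(fam_df); m <- nrow(bim_df)
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3 || !identical(raw[1:3], .bed_magic))
    stop("malformed bed file (bad magic bytes or not SNP-major): ", bed)
  body <- raw[-(1:3)]
  if (length(body) != bytes_per_snp * m)
    stop(sprintf("bed size inconsistent with fam/bim: %d bytes, expected %d",
                 length(body), bytes_per_snp * m))
  idx <- as.integer(body) + 1L
  geno <- .bed_decode_table[idx, , drop = FALSE]          # (bytes*m) x 4
  geno <- matrix(t(geno), nrow = 4L * bytes_per_snp)      # padded samples x m
  geno <- geno[seq_len(n), , drop = FALSE]
  if (!all(fam_df$pheno %in% c(1, 2)))
    stop("fam phenotype must be 1 (control) or 2 (case)")
  study <- genotype_study(geno, fam_df$pheno - 1L,
                          snp_meta = bim_df[, c("snp", "chr", "pos", "a1", "a2")],
                          sample_ids = fam_df$iid)
  orient_minor(study)
}

#' Write a cohort as PLINK bed/bim/fam
#'
#' @param study a [genotype_study()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(study, prefix) {
  g <- study$genotypes
  n <- nrow(g); m <- ncol(g)
  bytes_per_snp <- ceiling(n / 4)
  pad <- 4L * bytes_per_snp - n
  # genotype code -> two-bit value (counts of A1): 2->0, 1->2, 0->3, NA->1
  code <- matrix(3L, nrow = n + pad, ncol = m)
  v <- g; v[is.na(v)] <- -1L
  code[seq_len(n), ][v == 2L] <- 0L
  code[seq_len(n), ][v == 1L] <- 2L
  code[seq_len(n), ][v == -1L] <- 1L
  dim(code) <- c(4L, bytes_per_snp * m)
  bytes <- as.raw(code[1, ] + 4L * code[2, ] + 16L * code[3, ] + 64L * code[4, ])
  writeBin(c(.bed_magic, bytes), paste0(prefix, ".bed"))
  fam <- data.frame(fid = study$sample_ids, iid = study$sample_ids,
                    pid = 0L, mid = 0L, sex = 0L,
                    pheno = study$phenotype + 1L)
  write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = " ",
              row.names = FALSE, col.names = FALSE)
  sm <- study$snp_meta
  bim <- data.frame(chr = sm$chr, snp = sm$snp, cm = 0, pos = sm$pos,
                    a1 = sm$a1, a2 = sm$a2)
  write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  if (!is.null(study$phase)) write_phase(study, paste0(prefix, ".hap"))
  invisible(prefix)
}

#' Write phased haplotypes as a plain-text sidecar
#'
#' One line per haplotype: sample id, haplotype index (1 or 2), then one
#' 0/1 allele per SNP, space-separated.
#'
#' @param study a phased [genotype_study()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phase <- function(study, path) {
  if (is.null(study$phase)) stop("study has no phase information")
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(study$sample_ids)) {
    writeLines(paste(c(study$sample_ids[i], 1L, study$phase$h1[i, ]),
                     collapse = " "), con)
    writeLines(paste(c(study$sample_ids[i], 2L, study$phase$h2[i, ]),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read a phased haplotype sidecar
#'
#' @param path file written by [write_phase()].
#' @return list with matrices `h1`, `h2` and `sample_ids`.
#' @export
read_phase <- function(path) {
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  ids <- tab[[1]][tab[[2]] == 1L]
  h <- as.matrix(tab[, -(1:2), drop = FALSE])
  storage.mode(h) <- "integer"
  h1 <- h[tab[[2]] == 1L, , drop = FALSE]
  h2 <- h[tab[[2]] == 2L, , drop = FALSE]
  rownames(h1) <- rownames(h2) <- ids
  list(h1 = h1, h2 = h2, sample_ids = ids)
}

#' Write / read risk-haplotype dosages as TSV
#'
#' @param hla an [hla_dosage_matrix()].
#' @param path file path.
#' @return `path` (write) or an `hla_dosage_matrix` (read).
#' @export
write_hla_dosages <- function(hla, path) {
  df <- data.frame(sample_id = rownames(hla$dosages), hla$dosages,
                   check.names = FALSE)
  write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname write_hla_dosages
#' @export
read_hla_dosages <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  d <- as.matrix(df[, -1, drop = FALSE])
  rownames(d) <- df$sample_id
  hla_dosage_matrix(d)
}
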