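# Cohort quality control: SNP filters (autosome, MAF, missingness, exact
# HWE in controls) and sample filters (missingness, method-of-moments IBD).

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided conditional exact test: given the observed allele counts, the
#' p-value is the total probability of all heterozygote counts whose
#' conditional probability does not exceed that of the observed one
#' (Wigginton-style; no mid-p correction).
#'
#' @param n_hom1,n_het,n_hom2 genotype counts (major hom, het, minor hom).
#' @return p-value in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  stopifnot(n_hom1 >= 0, n_het >= 0, n_hom2 >= 0)
  n <- n_hom1 + n_het + n_hom2
  if (n == 0) return(1)
  n_minor <- 2 * n_hom2 + n_het        # rare-allele count (orientation-free)
  if (n_minor > n) n_minor <- 2 * n - n_minor
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  # conditional distribution: P(h) prop. n! / (n_AA! n_Aa! n_aa!) * 2^h
  n_aa <- (n_minor - hets) / 2
  n_AA <- n - n_aa - hets
  lp <- lgamma(n + 1) - lgamma(n_AA + 1) - lgamma(hets + 1) -
    lgamma(n_aa + 1) + hets * log(2)
  lp <- lp - max(lp)
  pr <- exp(lp); pr <- pr / sum(pr)
  p_obs <- pr[match(n_het, hets)]
  if (is.na(p_obs)) stop("observed heterozygote count inconsistent with alleles")
  min(1, sum(pr[pr <= p_obs + 1e-12]))
}

# Per-SNP summaries -----------------------------------------------------

snp_missingness <- function(genotypes) colMeans(is.na(genotypes))

snp_maf <- function(genotypes) {
  af <- snp_af(genotypes)
  pmin(af, 1 - af)
}

is_autosomal <- function(chr) {
  chr <- toupper(as.character(chr))
  suppressWarnings(num <- as.numeric(chr))
  !is.na(num) & num >= 1 & num <= 22
}

#' Apply SNP-level quality control
#'
#' Removes, in this priority order, non-autosomal SNPs, SNPs with minor
#' allele frequency below `maf_min`, SNPs with missingness above
#' `miss_max`, and SNPs deviating from Hardy-Weinberg equilibrium in
#' controls at `p < hwe_p_min`. Each removed SNP gets exactly one primary
#' reason code (the first failed check).
#'
#' @param study a [genotype_study()] with phenotype labels present.
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param miss_max maximum per-SNP missingness (default 0.01).
#' @param hwe_p_min exact-test HWE threshold in controls (default 5e-6).
#' @return list with elements `study` (filtered) and `report` (a
#'   `qc_report`).
#' @export
apply_snp_qc <- function(study, maf_min = 0.05, miss_max = 0.01,
                         hwe_p_min = 5e-6) {
  controls <- study$phenotype == 0L
  if (!any(controls)) stop("no controls present; HWE filter undefined")
  g <- study$genotypes
  reason <- rep(NA_character_, ncol(g))
  reason[!is_autosomal(study$snp_meta$chr)] <- "nonautosomal"
  ok <- is.na(reason)
  maf <- snp_maf(g)
  reason[ok & (is.na(maf) | maf < maf_min)] <- "maf"
  ok <- is.na(reason)
  reason[ok & snp_missingness(g) > miss_max] <- "missingness"
  ok <- is.na(reason)
  gc_ctrl <- g[controls, , drop = FALSE]
  for (j in which(ok)) {
    cnt <- tabulate(gc_ctrl[, j] + 1L, nbins = 3L)
    if (hwe_exact_test(cnt[1], cnt[2], cnt[3]) < hwe_p_min)
      reason[j] <- "hwe"
  }
  keep <- is.na(reason)
  report <- qc_report(
    removed_snps = data.frame(snp = study$snp_meta$snp[!keep],
                              reason = reason[!keep]),
    removed_samples = data.frame(sample_id = character(), reason = character()),
    thresholds = list(maf_min = maf_min, miss_max = miss_max,
                      hwe_p_min = hwe_p_min))
  list(study = subset_study(study, snps = keep), report = report)
}

#' Apply sample-level quality control
#'
#' Removes samples with genotype missingness above `miss_max`, then
#' resolves cryptic relatedness: for every remaining pair with
#' method-of-moments IBD estimate `pi-hat > pihat_max`, the member with
#' the higher missingness is dropped (ties broken by dropping the
#' lexicographically larger sample id).
#'
#' @param study a [genotype_study()].
#' @param miss_max maximum per-sample missingness (default 0.01).
#' @param pihat_max maximum tolerated pairwise pi-hat (default 0.05).
#' @param thin_r2 r-squared ceiling for LD thinning before IBD estimation.
#' @return list with `study` and `report`, as [apply_snp_qc()].
#' @export
apply_sample_qc <- function(study, miss_max = 0.01, pihat_max = 0.05,
                            thin_r2 = 0.2) {
  if (nrow(study$genotypes) < 2) stop("need at least 2 samples")
  miss <- rowMeans(is.na(study$genotypes))
  removed <- data.frame(sample_id = study$sample_ids[miss > miss_max],
                        reason = rep("missingness", sum(miss > miss_max)))
  keep <- miss <= miss_max
  sub <- subset_study(study, samples = keep)
  thin <- ld_thin(sub$genotypes, r2_max = thin_r2)
  ph <- pihat_matrix(sub$genotypes[, thin, drop = FALSE])
  sub_miss <- miss[keep]
  ids <- sub$sample_ids
  alive <- rep(TRUE, length(ids))
  repeat {
    ph_alive <- ph
    ph_alive[!alive, ] <- 0; ph_alive[, !alive] <- 0
    mx <- max(ph_alive)
    if (mx <= pihat_max) break
    w <- which(ph_alive == mx, arr.ind = TRUE)[1, ]
    i <- w[1]; j <- w[2]
    drop_i <- if (sub_miss[i] != sub_miss[j]) sub_miss[i] > sub_miss[j]
              else ids[i] > ids[j]
    d <- if (drop_i) i else j
    alive[d] <- FALSE
    removed <- rbind(removed,
                     data.frame(sample_id = ids[d], reason = "relatedness"))
  }
  report <- qc_report(
    removed_snps = data.frame(snp = character(), reason = character()),
    removed_samples = removed,
    thresholds = list(miss_max = miss_max, pihat_max = pihat_max))
  list(study = subset_study(sub, samples = alive), report = report)
}

#' @rdname apply_snp_qc
#' @param removed_snps,removed_samples data frames with reason codes.
#' @param thresholds named list of thresholds used.
#' @export
qc_report <- function(removed_snps, removed_samples, thresholds) {
  structure(list(removed_snps = removed_snps,
                 removed_samples = removed_samples,
                 thresholds = thresholds),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:", nrow(x$removed_snps), "SNPs and",
      nrow(x$removed_samples), "samples removed\n")
  if (nrow(x$removed_snps))
    print(table(x$removed_snps$reason))
  if (nrow(x$removed_samples))
    print(table(x$removed_samples$reason))
  invisible(x)
}

#' Greedy LD thinning
#'
#' Walks SNPs left to right and drops any SNP whose squared genotype
#' correlation with a previously kept SNP inside `window` exceeds
#' `r2_max`.
#'
#' @param genotypes samples x SNPs matrix.
#' @param r2_max r-squared ceiling.
#' @param window number of preceding kept SNPs to test against.
#' @return logical keep-mask over SNPs.
#' @export
ld_thin <- function(genotypes, r2_max = 0.2, window = 50L) {
  m <- ncol(genotypes)
  if (r2_max >= 1) return(rep(TRUE, m))
  keep <- logical(m)
  kept <- integer(0)
  for (j in seq_len(m)) {
    recent <- tail(kept, window)
    ok <- TRUE
    for (k in recent) {
      r <- suppressWarnings(
        stats::cor(genotypes[, j], genotypes[, k],
                   use = "pairwise.complete.obs"))
      if (!is.na(r) && r * r > r2_max) { ok <- FALSE; break }
    }
    if (ok) { keep[j] <- TRUE; kept <- c(kept, j) }
  }
  keep
}

#' Pairwise method-of-moments IBD (pi-hat) estimates
#'
#' Classic moment estimator: observed identity-by-state counts are
#' compared with their expectations under IBD sharing 0/1/2. The
#' expectation terms use unbiased factorial-moment estimates of the
#' allele-frequency powers (plug-in sample frequencies bias pi-hat
#' upward in small panels); `pi-hat = P(IBD=1)/2 + P(IBD=2)`. Intended
#' for use on LD-thinned SNPs.
#'
#' @param genotypes samples x SNPs matrix of `{0,1,2,NA}`.
#' @return symmetric samples x samples matrix (diagonal zeroed).
#' @export
pihat_matrix <- function(genotypes) {
  g <- genotypes
  n <- nrow(g)
  # polymorphic, sufficiently typed SNPs only (monomorphic SNPs are
  # trivially IBS2 and would inflate the IBD=2 component)
  k_all <- colSums(g, na.rm = TRUE)
  a_all <- 2 * colSums(!is.na(g))
  ok <- a_all >= 4 & k_all > 0 & k_all < a_all
  g <- g[, ok, drop = FALSE]
  I0 <- (!is.na(g) & g == 0L) * 1; I1 <- (!is.na(g) & g == 1L) * 1
  I2 <- (!is.na(g) & g == 2L) * 1
  V <- (!is.na(g)) * 1
  ibs2 <- tcrossprod(I0) + tcrossprod(I1) + tcrossprod(I2)
  ibs0 <- tcrossprod(I0, I2) + tcrossprod(I2, I0)
  valid <- tcrossprod(V)
  ibs1 <- valid - ibs2 - ibs0
  # unbiased estimates of p^r q^s per SNP via falling factorials of the
  # minor-allele count k out of a typed alleles
  k <- k_all[ok]; a <- a_all[ok]
  ff <- function(x, r) {
    out <- rep(1, length(x))
    for (i in seq_len(r) - 1) out <- out * (x - i)
    out
  }
  mono <- function(r, s)                    # E-hat of p^r q^s
    ff(k, r) * ff(a - k, s) / ff(a, r + s)
  e0_z0 <- sum(2 * mono(2, 2))
  e1_z0 <- sum(4 * mono(3, 1) + 4 * mono(1, 3))
  e2_z0 <- sum(mono(4, 0) + mono(0, 4) + 4 * mono(2, 2))
  e1_z1 <- sum(2 * mono(1, 1))
  e2_z1 <- sum(mono(2, 0) + mono(0, 2))
  L <- ncol(g)
  frac <- valid / L                     # scale expectations to observed loci
  z0 <- ibs0 / (e0_z0 * frac)
  z1 <- (ibs1 - z0 * e1_z0 * frac) / (e1_z1 * frac)
  z2 <- (ibs2 - z0 * e2_z0 * frac - z1 * e2_z1 * frac) / (L * frac)
  # clamp only the final estimate: clamping each component at zero first
  # would turn symmetric noise into a positive bias for unrelated pairs
  pihat <- pmin(pmax(z1 / 2 + z2, 0), 1)
  diag(pihat) <- 0
  pihat
}
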