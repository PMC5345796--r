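# Linkage disequilibrium between SNPs (r-squared, D-prime) and between
# SNP pairs (Hill's Q on the 4x4 haplotype table), plus greedy pruning of
# ranked interaction pairs to independent signals.

#' Biallelic LD from a 2x2 haplotype table
#'
#' `r^2 = chi^2 / (2n)` over the haplotype counts; `D' = |D| / D_max`
#' with the standard normalization.
#'
#' @param table 2x2 matrix of joint haplotype-allele counts (alleles 0/1
#'   of locus 1 in rows, locus 2 in columns) over `2n` haplotypes.
#' @return list with `r2` and `d_prime`, both in `[0, 1]`.
#' @export
pairwise_ld <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  N <- sum(table)
  pA <- sum(table[2, ]) / N              # freq of allele 1 at locus 1
  pB <- sum(table[, 2]) / N
  if (pA == 0 || pA == 1 || pB == 0 || pB == 1)
    stop("monomorphic locus")
  p11 <- table[2, 2] / N
  D <- p11 - pA * pB
  d_max <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
           else min(pA * pB, (1 - pA) * (1 - pB))
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  list(r2 = r2, d_prime = if (d_max == 0) 0 else abs(D) / d_max)
}

#' Biallelic LD from phased haplotypes
#'
#' @param h1,h2 0/1 allele vectors over the same haplotypes.
#' @return As [pairwise_ld()].
#' @export
pairwise_ld_haps <- function(h1, h2) {
  pairwise_ld(table(factor(h1, 0:1), factor(h2, 0:1)))
}

# 4-allele code of a SNP pair on one haplotype: 2*allele_a + allele_b.
pair_allele_codes <- function(phase_h, snp_a, snp_b) {
  2L * phase_h[, snp_a] + phase_h[, snp_b]
}

#' Hill's Q between two SNP pairs
#'
#' Each SNP pair is treated as one multi-allelic locus whose alleles are
#' the four haplotypes of its two SNPs; `Q = chi^2 / (2n)` on the joint
#' (up to 4x4) table of observed pair-haplotype counts over the `2n`
#' haplotypes of `n` control individuals. Cells with zero expectation
#' contribute zero. `Q` may exceed 1 for multi-allelic loci; thresholds
#' are applied on this scale.
#'
#' @param pair_a,pair_b integer length-2 SNP index vectors.
#' @param phase list with matrices `h1`, `h2` (samples x SNPs, 0/1).
#' @param controls logical mask: which samples to use (LD is
#'   conventionally computed in controls only); default all.
#' @param normalize `"none"` (the plain `chi^2/(2n)` form, default) or
#'   `"df"` (divide additionally by `(k-1)(l-1)`, Hill's original
#'   normalization).
#' @return non-negative number.
#' @export
hills_q <- function(pair_a, pair_b, phase, controls = NULL,
                    normalize = c("none", "df")) {
  normalize <- match.arg(normalize)
  if (is.null(phase)) stop("phased haplotypes required")
  if (is.null(controls)) controls <- rep(TRUE, nrow(phase$h1))
  h <- rbind(phase$h1[controls, , drop = FALSE],
             phase$h2[controls, , drop = FALSE])
  a <- pair_allele_codes(h, pair_a[1], pair_a[2])
  b <- pair_allele_codes(h, pair_b[1], pair_b[2])
  O <- table(factor(a, 0:3), factor(b, 0:3))
  O <- O[rowSums(O) > 0, colSums(O) > 0, drop = FALSE]
  N <- sum(O)                            # = 2n haplotypes
  E <- outer(rowSums(O), colSums(O)) / N
  term <- ifelse(E > 0, (O - E)^2 / E, 0)
  q <- sum(term) / N
  if (normalize == "df")
    q <- q / max(1, (nrow(O) - 1) * (ncol(O) - 1))
  q
}

#' Greedy pruning of ranked interaction pairs to independent signals
#'
#' Walks the pairs in the given order (most significant first), accepting
#' a pair only if its Hill's Q against every previously accepted pair is
#' at most `q_max`.
#'
#' @param pairs data frame with integer columns `snp_a`, `snp_b` (SNP
#'   indices into `phase`), ranked by decreasing adjusted significance.
#' @param phase phased haplotypes (list `h1`, `h2`).
#' @param controls logical control mask passed to [hills_q()].
#' @param q_max acceptance threshold (default 0.3).
#' @return the accepted subset of `pairs`, with a `q_max` attribute.
#' @export
prune_independent <- function(pairs, phase, controls = NULL, q_max = 0.3) {
  accepted <- integer(0)
  for (i in seq_len(nrow(pairs))) {
    ok <- TRUE
    for (j in accepted) {
      q <- hills_q(c(pairs$snp_a[i], pairs$snp_b[i]),
                   c(pairs$snp_a[j], pairs$snp_b[j]),
                   phase, controls = controls)
      if (q > q_max) { ok <- FALSE; break }
    }
    if (ok) accepted <- c(accepted, i)
  }
  out <- pairs[accepted, , drop = FALSE]
  attr(out, "q_max") <- q_max
  out
}
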