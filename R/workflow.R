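# Multi-cohort orchestration: scan ranking, cross-cohort replication
# (validated interaction pairs), rank-overlap curves, and region tallies.

#' Cohort scan container
#'
#' Wraps a scan result with its cohort id and Bonferroni cutoff, ranked
#' by adjusted then raw p, ties broken by (chr, pos) of the smaller SNP.
#'
#' @param cohort_id string.
#' @param scan data frame from [exhaustive_scan()], with a `p_adjusted`
#'   column (fall-back: `p_raw`).
#' @param n_snps SNP-panel size used for the Bonferroni cutoff.
#' @param alpha family-wise level (default 0.05).
#' @return A `cohort_scan`: list with `cohort_id`, `scan` (ranked, with
#'   `pair_id`), `cutoff`.
#' @export
cohort_scan <- function(cohort_id, scan, n_snps, alpha = 0.05) {
  if (is.null(scan$p_adjusted)) scan$p_adjusted <- scan$p_raw
  scan$pair_id <- pair_key(scan$snp_a, scan$snp_b)
  o <- order(scan$p_adjusted, scan$p_raw, scan$chr_a, scan$pos_a,
             scan$pos_b)
  scan <- scan[o, , drop = FALSE]
  structure(list(cohort_id = cohort_id, scan = scan,
                 cutoff = bonferroni_threshold(n_snps, alpha)),
            class = "cohort_scan")
}

#' Unordered pair identity from two SNP ids
#'
#' @param a,b SNP id vectors.
#' @return character key, invariant to argument order.
#' @export
pair_key <- function(a, b) {
  paste(pmin(as.character(a), as.character(b)),
        pmax(as.character(a), as.character(b)), sep = "|")
}

significant_pairs <- function(cs) {
  cs$scan$pair_id[cs$scan$p_adjusted <= cs$cutoff]
}

#' Validated interaction pairs across cohorts
#'
#' A pair is validated when it reaches Bonferroni-adjusted significance
#' in the discovery cohort AND in at least one other cohort (pair
#' identity matched by unordered SNP ids).
#'
#' @param discovery a [cohort_scan()].
#' @param others list of [cohort_scan()] objects (at least one).
#' @return the discovery scan rows of the validated pairs, ranked.
#' @export
define_vips <- function(discovery, others) {
  stopifnot(length(others) >= 1)
  disc_sig <- significant_pairs(discovery)
  other_sig <- unique(unlist(lapply(others, significant_pairs)))
  vip_ids <- intersect(disc_sig, other_sig)
  if (length(vip_ids) == 0 &&
      length(intersect(discovery$scan$pair_id,
                       unlist(lapply(others, function(o) o$scan$pair_id)))) == 0)
    warning("no shared pairs between cohorts (disjoint SNP panels?)")
  discovery$scan[discovery$scan$pair_id %in% vip_ids, , drop = FALSE]
}

#' Rank-overlap curve between two cohort rankings
#'
#' `|top-k(A) intersect top-k(B)| / k` for each depth `k`.
#'
#' @param ranking_a,ranking_b vectors of pair ids in rank order.
#' @param k_grid depths; values beyond the shorter list are truncated
#'   with a warning.
#' @return data frame `k`, `overlap` (fraction in `[0, 1]`).
#' @export
overlap_curve <- function(ranking_a, ranking_b, k_grid) {
  kmax <- min(length(ranking_a), length(ranking_b))
  if (any(k_grid > kmax)) {
    warning("k_grid truncated to ranking length ", kmax)
    k_grid <- unique(pmin(k_grid, kmax))
  }
  data.frame(k = k_grid, overlap = vapply(k_grid, function(k)
    length(intersect(ranking_a[seq_len(k)], ranking_b[seq_len(k)])) / k,
    numeric(1)))
}

#' Region tally of significant and replicated pairs
#'
#' Classifies pairs by position relative to a genomic interval
#' (conventionally the extended MHC, chr6:25.6-33.4 Mb) and counts
#' significant and replicated pairs per class.
#'
#' @param pairs data frame with `chr_a`, `pos_a`, `chr_b`, `pos_b` and a
#'   logical `replicated` column.
#' @param region list with `chr`, `start`, `end` (defaults to the
#'   extended MHC span).
#' @return 3x2 matrix: rows both-inside / one-inside / both-outside,
#'   columns significant / replicated.
#' @export
region_tally <- function(pairs,
                         region = list(chr = "6", start = 25.6e6,
                                       end = 33.4e6)) {
  inside <- function(chr, pos)
    as.character(chr) == as.character(region$chr) &
      pos >= region$start & pos <= region$end
  ia <- inside(pairs$chr_a, pairs$pos_a)
  ib <- inside(pairs$chr_b, pairs$pos_b)
  cls <- ifelse(ia & ib, "both_inside",
                ifelse(ia | ib, "one_inside", "both_outside"))
  lev <- c("both_inside", "one_inside", "both_outside")
  rep_flag <- if (is.null(pairs$replicated)) rep(FALSE, nrow(pairs))
              else pairs$replicated
  m <- cbind(significant = as.integer(table(factor(cls, lev))),
             replicated = as.integer(table(factor(cls[rep_flag], lev))))
  rownames(m) <- lev
  m
}

#' End-to-end single-cohort pipeline on synthetic data
#'
#' Simulate, QC, scan, calibrate against one permuted-label scan, test
#' haplotype independence, and prune to independent signals. Intended
#' for reproducible desk-scale runs and tests; every stage is seeded
#' from `config$seed`.
#'
#' @param config a [sim_config()].
#' @param report_threshold scan report cutoff passed through (default 1).
#' @param alpha family-wise level for the Bonferroni cutoff.
#' @param fdr_q FDR level of the haplotype-independence filter.
#' @param q_max Hill's Q pruning threshold.
#' @return list with `study`, `scan` (calibrated), `cutoff`,
#'   `significant`, `independent` (post-LRT), `signals` (post-pruning).
#' @export
run_cohort_pipeline <- function(config, report_threshold = 1, alpha = 0.05,
                                fdr_q = 0.05, q_max = 0.3) {
  study <- simulate_cohort(config)
  scan <- exhaustive_scan(study, report_threshold = report_threshold)
  null_scan <- permuted_scan(study, seed = config$seed + 1L)
  scan$p_adjusted <- calibrate_pvalues(scan$log10_p_raw,
                                       null_scan$log10_p_raw,
                                       log10_input = TRUE)
  cutoff <- bonferroni_threshold(ncol(study$genotypes), alpha)
  scan$pair_id <- pair_key(scan$snp_a, scan$snp_b)
  scan$snp_a_idx <- match(scan$snp_a, study$snp_meta$snp)
  scan$snp_b_idx <- match(scan$snp_b, study$snp_meta$snp)
  o <- order(scan$p_adjusted, scan$p_raw, scan$snp_a_idx, scan$snp_b_idx)
  scan <- scan[o, , drop = FALSE]
  sig <- scan[scan$p_adjusted <= cutoff, , drop = FALSE]
  independent <- sig
  if (!is.null(study$hla) && nrow(sig) > 0) {
    lrt_p <- vapply(seq_len(nrow(sig)), function(i)
      hla_independence_lrt(study$phenotype,
                           study$genotypes[, sig$snp_a_idx[i]],
                           study$genotypes[, sig$snp_b_idx[i]],
                           study$hla)$p, numeric(1))
    keep <- bh_fdr(lrt_p, fdr_q)$reject
    independent <- sig[keep, , drop = FALSE]
  }
  signals <- independent
  if (nrow(independent) > 0) {
    pr <- data.frame(snp_a = independent$snp_a_idx,
                     snp_b = independent$snp_b_idx)
    keep <- prune_independent(pr, study$phase,
                              controls = study$phenotype == 0L,
                              q_max = q_max)
    signals <- independent[as.integer(rownames(keep)), , drop = FALSE]
  }
  list(study = study, scan = scan, cutoff = cutoff, significant = sig,
       independent = independent, signals = signals)
}
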