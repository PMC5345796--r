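# Independent reference implementations used as oracles. Kept in plain,
# slow R, written from the documented construction rather than the
# package sources.

# tiny deterministic study builder
make_study <- function(genotypes, phenotype, chr = NULL, pos = NULL,
                       phase = NULL) {
  m <- ncol(genotypes)
  genotype_study(
    genotypes, phenotype,
    snp_meta = data.frame(snp = paste0("s", seq_len(m)),
                          chr = chr %||% rep("1", m),
                          pos = pos %||% seq_len(m) * 1000,
                          a1 = "A", a2 = "G", stringsAsFactors = FALSE),
    sample_ids = paste0("id", seq_len(nrow(genotypes))),
    phase = phase)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# naive per-sample counting oracle for pair tables
naive_pair_counts <- function(study, a, b) {
  counts <- matrix(0, 2, 9)
  for (i in seq_len(nrow(study$genotypes))) {
    ga <- study$genotypes[i, a]; gb <- study$genotypes[i, b]
    if (is.na(ga) || is.na(gb)) next
    v <- 3 * ga + gb + 1
    counts[study$phenotype[i] + 1, v] <- counts[study$phenotype[i] + 1, v] + 1
  }
  rownames(counts) <- c("control", "case")
  counts
}

# slow R reference for the discrimination-gain statistic (natural-log
# tails, log10 result), written directly from the construction in the
# vignette: odds-ordered merged prefixes, marginal hull baselines
# (vertices + interpolation at FP + pooled diagonal), max over the two
# SNPs of the min over prefix points.
r_gss_log10 <- function(cc, nn) {
  n1 <- sum(cc); n0 <- sum(nn)
  groups_of <- function(c9, n9) {
    occ <- which(c9 + n9 > 0)
    score <- sapply(occ, function(v)
      -sum(sapply(occ, function(w) sign(c9[v] * n9[w] - c9[w] * n9[v]))))
    ord <- occ[order(score, occ)]
    out <- list(); i <- 1
    while (i <= length(ord)) {
      g <- ord[i]; j <- i + 1
      while (j <= length(ord) &&
             c9[ord[i]] * n9[ord[j]] == c9[ord[j]] * n9[ord[i]]) {
        g <- c(g, ord[j]); j <- j + 1
      }
      out[[length(out) + 1]] <- g; i <- j
    }
    out
  }
  pts_of <- function(groups, c9, n9)
    cbind(tp = cumsum(sapply(groups, function(g) sum(c9[g]))),
          fp = cumsum(sapply(groups, function(g) sum(n9[g]))))
  attain <- function(TP, FP, sens, fpr)
    pbinom(TP - 1, n1, sens, lower.tail = FALSE, log.p = TRUE) +
    pbinom(FP, n0, fpr, log.p = TRUE)
  pair_pts <- pts_of(groups_of(cc, nn), cc, nn)
  per_m <- sapply(1:2, function(m) {
    cls <- if (m == 1) (0:8) %/% 3 else (0:8) %% 3
    mc <- as.numeric(tapply(cc, cls, sum))
    mn <- as.numeric(tapply(nn, cls, sum))
    mpts <- rbind(c(0, 0), pts_of(groups_of(mc, mn), mc, mn))
    min(sapply(seq_len(nrow(pair_pts)), function(q) {
      TP <- pair_pts[q, 1]; FP <- pair_pts[q, 2]
      cand <- apply(mpts, 1, function(s)
        attain(TP, FP, s[1] / n1, s[2] / n0))
      sens_i <- if (FP >= mpts[nrow(mpts), 2]) 1 else
        approx(mpts[, 2], mpts[, 1], xout = FP, ties = "ordered")$y / n1
      cand <- c(cand, attain(TP, FP, sens_i, FP / n0))
      tpool <- (TP + FP) / (n1 + n0)
      cand <- c(cand, attain(TP, FP, tpool, tpool))
      max(cand)
    }))
  })
  min(max(per_m), 0) / log(10)
}

# conditional HWE distribution oracle: exact probabilities of every
# heterozygote count given allele counts, via the hypergeometric-type
# conditioning of HWE genotype probabilities (any allele frequency gives
# the same conditional law; 0.5 used here)
hwe_oracle_p <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  n_minor <- 2 * n_hom2 + n_het
  if (n_minor > n) n_minor <- 2 * n - n_minor
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  pr <- sapply(hets, function(h) {
    naa <- (n_minor - h) / 2
    dmultinom(c(n - naa - h, h, naa), prob = c(0.25, 0.5, 0.25))
  })
  pr <- pr / sum(pr)
  obs <- pr[hets == n_het]
  sum(pr[pr <= obs + 1e-12])
}
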