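# Conditional analyses: are interaction pairs independent of known
# risk-haplotype dosages and strong marginal SNPs? Likelihood-ratio
# tests on nested logistic regressions, Fisher meta-analysis, BH-FDR,
# principal-component covariates, the INFO imputation-quality metric and
# the null-calibration simulation for the regression interaction test.

#' Logistic regression by IRLS
#'
#' Maximum-likelihood logistic fit with deterministic handling of rank
#' deficiency (aliased columns are dropped in order of appearance) and of
#' separation (refit with a small quadratic penalty on the slopes,
#' flagged).
#'
#' @param y binary 0/1 response.
#' @param X design matrix (no intercept column; one is added).
#' @param penalty quadratic penalty applied to slopes on separation
#'   (default 1e-4).
#' @param max_iter,tol IRLS controls.
#' @return list: `coef` (named, `NA` for aliased columns), `loglik`
#'   (unpenalized, at the returned fit), `converged`, `separation`,
#'   `rank` (non-aliased columns incl. intercept), `dropped` (names).
#' @export
logistic_mle <- function(y, X, penalty = 1e-4, max_iter = 100, tol = 1e-10) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  if (is.null(colnames(X)) && ncol(X) > 0)
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  D <- cbind(`(Intercept)` = 1, X)
  qrD <- qr(D)
  keep <- qrD$pivot[seq_len(qrD$rank)]
  keep <- sort(keep)                      # deterministic: order of appearance
  dropped <- colnames(D)[setdiff(seq_len(ncol(D)), keep)]
  Dk <- D[, keep, drop = FALSE]
  fit <- irls_logistic(y, Dk, ridge = 0, max_iter = max_iter, tol = tol)
  separation <- !fit$converged || any(abs(fit$eta) > 25)
  if (separation) {
    fit <- irls_logistic(y, Dk, ridge = penalty, max_iter = max_iter,
                         tol = tol)
  }
  coef <- setNames(rep(NA_real_, ncol(D)), colnames(D))
  coef[keep] <- fit$beta
  mu <- plogis(fit$eta)
  eps <- 1e-12
  ll <- sum(y * log(pmax(mu, eps)) + (1 - y) * log(pmax(1 - mu, eps)))
  list(coef = coef, loglik = ll, converged = fit$converged,
       separation = separation, rank = length(keep), dropped = dropped)
}

irls_logistic <- function(y, D, ridge = 0, max_iter = 100, tol = 1e-10) {
  p <- ncol(D)
  beta <- rep(0, p)
  pen <- diag(c(0, rep(ridge, p - 1)), p)  # intercept unpenalized
  converged <- FALSE
  eta <- drop(D %*% beta)
  for (it in seq_len(max_iter)) {
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    A <- crossprod(D, w * D) + 2 * pen
    b <- crossprod(D, w * z)
    beta_new <- tryCatch(drop(solve(A, b)), error = function(e) beta)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    eta <- drop(D %*% beta)
    if (!all(is.finite(beta))) break
    if (delta < tol) { converged <- TRUE; break }
  }
  list(beta = beta, eta = eta, converged = converged)
}

# Likelihood-ratio test of two nested logistic fits.
lrt_from_fits <- function(fit0, fit1) {
  stat <- max(0, 2 * (fit1$loglik - fit0$loglik))
  df <- max(1L, fit1$rank - fit0$rank)
  list(lrt_stat = stat, df = df,
       p = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Indicator encoding of a SNP pair (reference = most frequent control cell)
#'
#' The 9 genotype-combination cells are encoded as up to 8 binary
#' indicators, dropping the cell most frequent among controls as the
#' reference. Cells carried by fewer than `min_count` cases or fewer
#' than `min_count` controls are folded into the reference rather than
#' given their own indicator: near-empty indicator columns break the
#' chi-square approximation of the likelihood-ratio tests built on this
#' encoding (the test degrees of freedom are recomputed from the columns
#' actually present). Samples with a missing genotype get all-zero
#' indicators.
#'
#' @param ga,gb genotype vectors `{0,1,2,NA}`.
#' @param y phenotype (0/1) used to pick the control reference cell.
#' @param min_count minimum per-class carriers for a cell to get an
#'   indicator.
#' @return matrix samples x (number of encoded cells).
#' @export
pair_indicator_matrix <- function(ga, gb, y, min_count = 10L) {
  cell <- 3L * ga + gb + 1L
  case_counts <- tabulate(cell[y == 1L & !is.na(cell)], nbins = 9L)
  ctrl_counts <- tabulate(cell[y == 0L & !is.na(cell)], nbins = 9L)
  ref <- which.max(ctrl_counts)
  cells <- setdiff(which(case_counts >= min_count &
                           ctrl_counts >= min_count), ref)
  if (length(cells) == 0) cells <- setdiff(1:9, ref)[1]  # degenerate guard
  M <- vapply(cells, function(v) as.numeric(!is.na(cell) & cell == v),
              numeric(length(ga)))
  M <- matrix(M, nrow = length(ga))
  colnames(M) <- paste0("cell", cells)
  M
}

# 2-indicator encoding of one SNP (reference genotype 0). When the
# homozygote class is carried by fewer than min_count cases or controls
# it is collapsed into the carrier indicator (dominant coding): sparse
# marginal columns destabilize the chi-square approximation of the LRTs.
snp_indicator_matrix <- function(g, prefix = "g", y = NULL,
                                 min_count = 10L) {
  hom_sparse <- FALSE
  if (!is.null(y)) {
    hom_case <- sum(!is.na(g) & g == 2L & y == 1L)
    hom_ctrl <- sum(!is.na(g) & g == 2L & y == 0L)
    hom_sparse <- hom_case < min_count || hom_ctrl < min_count
  }
  if (hom_sparse) {
    M <- cbind(as.numeric(!is.na(g) & g >= 1L))
    colnames(M) <- paste0(prefix, "_carrier")
  } else {
    M <- cbind(as.numeric(!is.na(g) & g == 1L),
               as.numeric(!is.na(g) & g == 2L))
    colnames(M) <- paste0(prefix, c("_het", "_hom"))
  }
  M
}

#' Haplotype-independence likelihood-ratio test for a pair
#'
#' Compares a logistic regression of phenotype on the risk-haplotype
#' dosages (plus covariates) with one that additionally includes the
#' pair's 8 cell indicators. A pair whose cells are fully captured by the
#' haplotypes (the haplotype-induced artifact) adds no fit and is not
#' significant.
#'
#' @param y phenotype 0/1.
#' @param ga,gb genotype vectors of the pair.
#' @param hla an [hla_dosage_matrix()] (or plain dosage matrix).
#' @param pcs optional samples x k principal-component scores.
#' @return list: `lrt_stat`, `df` (non-aliased added columns), `p`,
#'   `conditioning_set`.
#' @export
hla_independence_lrt <- function(y, ga, gb, hla, pcs = NULL) {
  dos <- if (inherits(hla, "hla_dosage_matrix")) hla$dosages else as.matrix(hla)
  base <- cbind(dos, pcs)
  vip <- pair_indicator_matrix(ga, gb, y)
  fit0 <- logistic_mle(y, base)
  fit1 <- logistic_mle(y, cbind(base, vip))
  out <- lrt_from_fits(fit0, fit1)
  out$conditioning_set <- c(colnames(dos),
                            if (!is.null(pcs)) paste0("PC", seq_len(ncol(pcs))))
  out
}

#' Regression-based conditional interaction test for a pair
#'
#' Likelihood-ratio test of the pair's 8 interaction indicators over the
#' marginal SNPs alone, both models conditioned on the supplied
#' principal components, risk-haplotype dosages and strongly associated
#' single SNPs (each encoded with 2 indicators). Detects interaction on
#' the log-odds scale only.
#'
#' @param y phenotype 0/1.
#' @param ga,gb genotype vectors of the pair.
#' @param hla optional dosage matrix; `pcs` optional PC scores;
#'   `top_snps` optional genotype matrix of strong marginal SNPs.
#' @return As [hla_independence_lrt()].
#' @export
conditional_interaction_lrt <- function(y, ga, gb, hla = NULL, pcs = NULL,
                                        top_snps = NULL) {
  covars <- NULL
  if (!is.null(hla))
    covars <- cbind(covars,
                    if (inherits(hla, "hla_dosage_matrix")) hla$dosages
                    else as.matrix(hla))
  if (!is.null(pcs)) covars <- cbind(covars, pcs)
  if (!is.null(top_snps)) {
    ts <- as.matrix(top_snps)
    for (j in seq_len(ncol(ts)))
      covars <- cbind(covars, snp_indicator_matrix(ts[, j],
                                                   paste0("top", j), y))
  }
  marg <- cbind(snp_indicator_matrix(ga, "a", y),
                snp_indicator_matrix(gb, "b", y))
  vip <- pair_indicator_matrix(ga, gb, y)
  colnames(vip) <- paste0("int_", colnames(vip))
  fit0 <- logistic_mle(y, cbind(marg, covars))
  fit1 <- logistic_mle(y, cbind(marg, covars, vip))
  out <- lrt_from_fits(fit0, fit1)
  out$conditioning_set <- colnames(covars)
  out
}

#' Fisher's method for combining independent p-values
#'
#' @param p_values vector of p-values in `(0, 1]`.
#' @return list: `X2 = -2 sum log p`, `df = 2k`, `p` (upper chi-square
#'   tail).
#' @export
fisher_meta <- function(p_values) {
  if (any(p_values <= 0 | p_values > 1))
    stop("p-values must be in (0, 1]; floor log-space inputs upstream")
  X2 <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  list(X2 = X2, df = df, p = pchisq(X2, df = df, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up FDR control
#'
#' @param p_values vector of p-values.
#' @param q target false discovery rate (default 0.05).
#' @return list: `reject` (logical mask in input order), `cutoff` (largest
#'   rejected p, `NA` if none).
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  m <- length(p_values)
  o <- order(p_values)
  ps <- p_values[o]
  k <- which(ps <= q * seq_len(m) / m)
  reject <- logical(m)
  cutoff <- NA_real_
  if (length(k)) {
    kmax <- max(k)
    reject[o[seq_len(kmax)]] <- TRUE
    cutoff <- ps[kmax]
  }
  list(reject = reject, cutoff = cutoff)
}

#' INFO imputation-quality metric
#'
#' Dosage variance over its binomial expectation `2p(1-p)`, both
#' estimated in controls only; 1 for hard calls at Hardy-Weinberg
#' proportions, smaller for shrunken (uncertain) dosages.
#'
#' @param dosages per-sample dosages in `[0, 2]`.
#' @param controls logical mask of control samples.
#' @return non-negative number (0 when the allele is monomorphic).
#' @export
info_metric <- function(dosages, controls) {
  x <- dosages[controls]
  if (length(x) < 2) stop("need at least 2 control samples")
  p <- mean(x) / 2
  if (p <= 0 || p >= 1) return(0)
  v <- mean((x - mean(x))^2)             # population variance
  v / (2 * p * (1 - p))
}

#' Principal components of the genotype matrix
#'
#' LD-thins the SNPs, standardizes columns, and returns the top `k`
#' sample scores with a deterministic sign convention (the
#' largest-magnitude loading of each component is positive).
#'
#' @param study a [genotype_study()].
#' @param k number of components (default 5).
#' @param thin_r2 LD-thinning ceiling (default 0.2).
#' @return samples x k score matrix.
#' @export
compute_pcs <- function(study, k = 5, thin_r2 = 0.2) {
  if (nrow(study$genotypes) < k + 1) stop("need at least k+1 samples")
  g <- study$genotypes[, ld_thin(study$genotypes, r2_max = thin_r2),
                       drop = FALSE]
  mu <- colMeans(g, na.rm = TRUE)
  sdv <- apply(g, 2, sd, na.rm = TRUE)
  ok <- !is.na(sdv) & sdv > 0
  if (!any(ok)) stop("all SNPs have zero variance")
  Z <- sweep(g[, ok, drop = FALSE], 2, mu[ok], "-")
  Z <- sweep(Z, 2, sdv[ok], "/")
  Z[is.na(Z)] <- 0
  sv <- svd(Z, nu = k, nv = k)
  if (length(sv$d) < k) stop("k exceeds rank")
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  for (j in seq_len(k)) {
    ld <- sv$v[, j]
    if (ld[which.max(abs(ld))] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

#' Null-calibration simulation for the conditional interaction test
#'
#' Repeatedly builds SNP pairs carrying no interaction and records the
#' conditional-interaction LRT p-value, under two scenarios: a strong
#' marginal locus paired with a permuted null locus, and two permuted
#' null loci (permutation of all genotypes across cases and controls
#' destroys any association while keeping the allele frequency).
#'
#' @param study a case-control [genotype_study()]; the strong locus is
#'   the SNP with the smallest marginal chi-square p (must reach
#'   `strong_p_max` for the strong scenario to run).
#' @param n_pairs replicates per scenario.
#' @param seed RNG seed.
#' @param strong_p_max marginal significance defining a strong locus.
#' @return data frame `scenario`, `p`; per-scenario genomic-control
#'   lambda in attribute `lambda`.
#' @export
null_interaction_qq <- function(study, n_pairs = 1000, seed,
                                strong_p_max = 1e-10) {
  set.seed(seed)
  g <- study$genotypes
  y <- study$phenotype
  n <- length(y)
  marg_p <- vapply(seq_len(ncol(g)), function(j) {
    tab <- table(factor(g[, j], 0:2), factor(y, 0:1))
    suppressWarnings(stats::chisq.test(tab)$p.value)
  }, numeric(1))
  strong_idx <- which.min(marg_p)
  has_strong <- is.finite(marg_p[strong_idx]) &&
    marg_p[strong_idx] < strong_p_max
  run <- function(scenario) {
    vapply(seq_len(n_pairs), function(i) {
      j1 <- sample.int(ncol(g), 1)
      j2 <- sample.int(ncol(g), 1)
      ga <- if (scenario == "strong_random") g[, strong_idx]
            else g[sample.int(n), j1]
      gb <- g[sample.int(n), j2]
      conditional_interaction_lrt(y, ga, gb)$p
    }, numeric(1))
  }
  out <- data.frame(scenario = "random_random", p = run("random_random"),
                    stringsAsFactors = FALSE)
  if (has_strong)
    out <- rbind(out, data.frame(scenario = "strong_random",
                                 p = run("strong_random"),
                                 stringsAsFactors = FALSE))
  lam <- tapply(out$p, out$scenario, genomic_lambda)
  attr(out, "lambda") <- lam
  out
}
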