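# Synthetic case-control cohorts with LD-block haplotype structure,
# multi-allelic risk-haplotype effects, and planted two-locus penetrance
# models. Everything is seeded and reproducible; the generator stands in
# for controlled-access GWAS data in tests and examples.

#' Two-locus penetrance model
#'
#' A 3x3 table of disease probabilities indexed by the minor-allele counts
#' at two loci, together with the allele frequencies used when planting
#' the model into a simulated cohort.
#'
#' @param penetrance numeric 3x3 matrix in `[0,1]`; rows = genotype at
#'   locus A (0,1,2), columns = genotype at locus B.
#' @param maf_a,maf_b minor allele frequencies of the two loci.
#' @param label optional class tag.
#' @return An object of class `two_locus_model`.
#' @export
two_locus_model <- function(penetrance, maf_a, maf_b, label = NULL) {
  penetrance <- matrix(as.numeric(penetrance), 3, 3)
  stopifnot(all(penetrance >= 0 & penetrance <= 1),
            maf_a > 0, maf_a < 1, maf_b > 0, maf_b < 1)
  structure(list(penetrance = penetrance, maf_a = maf_a, maf_b = maf_b,
                 label = label),
            class = "two_locus_model")
}

#' Population prevalence implied by a two-locus model under HWE
#'
#' @param model a [two_locus_model()].
#' @return Sum of `penetrance[j,k] * P(gA=j) * P(gB=k)` under
#'   Hardy-Weinberg proportions at the model's allele frequencies.
#' @export
model_prevalence <- function(model) {
  pa <- hwe_probs(model$maf_a); pb <- hwe_probs(model$maf_b)
  as.numeric(t(pa) %*% model$penetrance %*% pb)
}

hwe_probs <- function(maf) c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)

#' Build a penetrance table from a set of high-risk cells
#'
#' Convenience constructor for the classical fully-penetrant patterns:
#' cells in `high_cells` (1..9, index `3*gA + gB + 1`) get `p_high`, the
#' rest `p_low`.
#'
#' @param high_cells integer subset of 1..9.
#' @param p_high,p_low penetrances of high/low cells.
#' @param maf_a,maf_b allele frequencies passed to [two_locus_model()].
#' @param label optional tag.
#' @return A [two_locus_model()].
#' @export
penetrance_from_cells <- function(high_cells, p_high, p_low,
                                  maf_a = 0.3, maf_b = 0.3, label = NULL) {
  stopifnot(all(high_cells %in% 1:9))
  pen <- matrix(p_low, 3, 3)
  for (v in high_cells) pen[(v - 1) %/% 3 + 1, (v - 1) %% 3 + 1] <- p_high
  two_locus_model(pen, maf_a, maf_b, label = label)
}

#' Simulation configuration
#'
#' Describes a synthetic cohort: cohort sizes, LD-block layout, risk
#' haplotypes and planted two-locus models. Block 1 plays the role of the
#' risk-haplotype region when `n_risk_alleles > 0`: its founder haplotypes
#' carry one of `n_risk_alleles` multi-allelic labels whose per-allele
#' log-odds drive disease, and block-1 SNPs consequently tag those
#' alleles (this is what makes haplotype-induced pair artifacts
#' generatable).
#'
#' @param n_cases,n_controls ascertained cohort sizes.
#' @param n_blocks,snps_per_block LD-block layout.
#' @param within_block_r2 target squared correlation of adjacent SNP
#'   alleles inside a block (founder copying chain; 1 gives identical
#'   alleles across the block).
#' @param planted_models list of entries `list(snp_a=, snp_b=, model=)`
#'   with SNP column indices and a [two_locus_model()].
#' @param n_risk_alleles number of multi-allelic risk-haplotype alleles
#'   (0 disables haplotype effects).
#' @param risk_log_odds per-allele log odds (length `n_risk_alleles`).
#' @param prevalence target population prevalence (default 1%).
#' @param n_founders founder haplotypes per block.
#' @param engineer_tagging if `TRUE` (requires `n_risk_alleles >= 5`),
#'   the first two SNPs of block 1 are rebuilt so that each alone tags a
#'   mixture of risk alleles while their AND tags exactly allele 1: the
#'   canonical haplotype-induced interaction artifact (a pair that is
#'   jointly associated through the haplotype with no two-locus effect
#'   of its own).
#' @param seed mandatory RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cases = 500, n_controls = 500, n_blocks = 10,
                       snps_per_block = 10, within_block_r2 = 0.5,
                       planted_models = list(), n_risk_alleles = 0,
                       risk_log_odds = NULL, prevalence = 0.01,
                       n_founders = 30, engineer_tagging = FALSE, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_cases > 0, n_controls > 0, n_blocks > 0, snps_per_block > 0,
            prevalence > 0, prevalence < 1,
            within_block_r2 >= 0, within_block_r2 <= 1)
  if (n_risk_alleles > 0) {
    if (is.null(risk_log_odds)) risk_log_odds <- rep(1, n_risk_alleles)
    stopifnot(length(risk_log_odds) == n_risk_alleles)
  }
  if (engineer_tagging)
    stopifnot(n_risk_alleles >= 5, snps_per_block >= 2)
  m <- n_blocks * snps_per_block
  for (pm in planted_models) {
    stopifnot(all(c("snp_a", "snp_b", "model") %in% names(pm)),
              pm$snp_a >= 1, pm$snp_a <= m, pm$snp_b >= 1, pm$snp_b <= m,
              pm$snp_a != pm$snp_b, inherits(pm$model, "two_locus_model"))
  }
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 n_blocks = n_blocks, snps_per_block = snps_per_block,
                 within_block_r2 = within_block_r2,
                 planted_models = planted_models,
                 n_risk_alleles = n_risk_alleles,
                 risk_log_odds = risk_log_odds,
                 prevalence = prevalence, n_founders = n_founders,
                 engineer_tagging = isTRUE(engineer_tagging),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Founder haplotype pools: per block, n_founders haplotypes generated by a
# first-order copying chain (adjacent allele kept with probability
# sqrt(r2), else redrawn at the block frequency). Individuals are mosaics
# of founders, recombining freely at block boundaries. Planted SNPs get
# their founder alleles redrawn at the model's MAF (independently of
# neighbours) so the planted allele frequency is controlled.
build_founders <- function(config) {
  K <- config$n_founders; L <- config$snps_per_block
  c_keep <- sqrt(config$within_block_r2)
  planted_cols <- integer(0); planted_maf <- numeric(0)
  for (pm in config$planted_models) {
    planted_cols <- c(planted_cols, pm$snp_a, pm$snp_b)
    planted_maf <- c(planted_maf, pm$model$maf_a, pm$model$maf_b)
  }
  founders <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    p <- runif(1, 0.1, 0.5)
    for (try in 1:100) {
      h <- matrix(0L, K, L)
      h[, 1] <- rbinom(K, 1, p)
      if (L > 1) for (j in 2:L) {
        keep <- runif(K) < c_keep
        h[, j] <- ifelse(keep, h[, j - 1], rbinom(K, 1, p))
      }
      cols <- (b - 1) * L + seq_len(L)
      hit <- match(cols, planted_cols)
      for (jj in which(!is.na(hit)))
        h[, jj] <- rbinom(K, 1, planted_maf[hit[jj]])
      cs <- colSums(h)
      if (all(cs > 0 & cs < K)) break
    }
    if (any(colSums(h) == 0 | colSums(h) == K))
      stop("could not generate polymorphic founders for block ", b)
    founders[[b]] <- h
  }
  labels <- NULL
  if (config$n_risk_alleles > 0) {
    # decreasing allele frequencies over founders of block 1
    w <- (config$n_risk_alleles:1); w <- w / sum(w)
    labels <- sample.int(config$n_risk_alleles, K, replace = TRUE, prob = w)
    labels[seq_len(min(K, config$n_risk_alleles))] <-
      seq_len(min(K, config$n_risk_alleles))  # every allele represented
    if (config$engineer_tagging) {
      # SNP 1 tags alleles {1} + evens, SNP 2 tags {1} + odds > 1: each
      # alone is a diluted tag, the AND identifies allele 1 exactly
      A <- config$n_risk_alleles
      s1 <- c(1, seq(2, A, by = 2))
      s2 <- c(1, seq(3, A, by = 2))
      founders[[1]][, 1] <- as.integer(labels %in% s1)
      founders[[1]][, 2] <- as.integer(labels %in% s2)
    }
  }
  list(founders = founders, labels = labels)
}

# Draw n individuals from the superpopulation: two founder mosaics each.
draw_individuals <- function(config, pool, n) {
  K <- config$n_founders; L <- config$snps_per_block
  m <- config$n_blocks * L
  h1 <- matrix(0L, n, m); h2 <- matrix(0L, n, m)
  f1_b1 <- f2_b1 <- NULL
  for (b in seq_len(config$n_blocks)) {
    cols <- (b - 1) * L + seq_len(L)
    f1 <- sample.int(K, n, replace = TRUE)
    f2 <- sample.int(K, n, replace = TRUE)
    h1[, cols] <- pool$founders[[b]][f1, , drop = FALSE]
    h2[, cols] <- pool$founders[[b]][f2, , drop = FALSE]
    if (b == 1) { f1_b1 <- f1; f2_b1 <- f2 }
  }
  g <- h1 + h2
  dos <- NULL
  if (!is.null(pool$labels)) {
    A <- config$n_risk_alleles
    dos <- matrix(0L, n, A)
    l1 <- pool$labels[f1_b1]; l2 <- pool$labels[f2_b1]
    for (a in seq_len(A)) dos[, a] <- (l1 == a) + (l2 == a)
  }
  list(h1 = h1, h2 = h2, g = g, dosages = dos)
}

# Disease probability on the logit scale: calibrated baseline + risk-
# haplotype log-odds + per-pair penetrance contributions (each relative to
# the configured prevalence, so an all-flat model contributes nothing).
liability_eta <- function(config, ind) {
  n <- nrow(ind$g)
  eta <- rep(qlogis(config$prevalence), n)
  if (!is.null(ind$dosages))
    eta <- eta + as.numeric(ind$dosages %*% config$risk_log_odds)
  for (pm in config$planted_models) {
    pen <- pm$model$penetrance
    pv <- pen[cbind(ind$g[, pm$snp_a] + 1L, ind$g[, pm$snp_b] + 1L)]
    eta <- eta + qlogis(pmin(pmax(pv, 1e-12), 1 - 1e-12)) -
      qlogis(config$prevalence)
  }
  eta
}

# Find the baseline offset delta so that the superpopulation prevalence
# matches config$prevalence (Monte-Carlo root finding on a calibration
# sample). Errors with the achievable range when the target is out of
# reach.
calibrate_offset <- function(config, pool, n_cal = 20000) {
  ind <- draw_individuals(config, pool, n_cal)
  eta <- liability_eta(config, ind)
  f <- function(d) mean(plogis(eta + d)) - config$prevalence
  lo <- f(-12); hi <- f(12)
  if (lo > 0 || hi < 0)
    stop(sprintf(
      "requested prevalence %.4g unattainable; achievable range [%.4g, %.4g]",
      config$prevalence, lo + config$prevalence, hi + config$prevalence))
  uniroot(f, c(-12, 12), tol = 1e-8)$root
}

#' Simulate a superpopulation sample
#'
#' Draws `n` individuals from the (unascertained) population defined by
#' `config`, labelling each with simulated disease status. Useful for
#' checking realized penetrances and prevalence without case-control
#' ascertainment bias.
#'
#' @param config a [sim_config()].
#' @param n number of individuals.
#' @return list with `g`, `h1`, `h2`, `dosages`, `disease`, `prob` and the
#'   calibration offset `delta`.
#' @export
simulate_superpopulation <- function(config, n) {
  set.seed(config$seed)
  pool <- build_founders(config)
  delta <- calibrate_offset(config, pool)
  ind <- draw_individuals(config, pool, n)
  prob <- plogis(liability_eta(config, ind) + delta)
  disease <- rbinom(n, 1, prob)
  c(ind, list(disease = disease, prob = prob, delta = delta, pool = pool))
}

#' Simulate a case-control cohort
#'
#' Builds per-block founder haplotype pools, calibrates the disease model
#' to the configured population prevalence, and ascertains the requested
#' numbers of cases and controls by rejection sampling from the
#' superpopulation. Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @param max_batches rejection-sampling cap; exceeded counts raise an
#'   error rather than silently biasing the sample.
#' @return A phased [genotype_study()]; when risk haplotypes are
#'   configured, the study carries an [hla_dosage_matrix()] in `$hla`.
#' @export
simulate_cohort <- function(config, max_batches = 400) {
  set.seed(config$seed)
  pool <- build_founders(config)
  delta <- calibrate_offset(config, pool)
  m <- config$n_blocks * config$snps_per_block
  need_case <- config$n_cases; need_ctrl <- config$n_controls
  batch <- max(2000, ceiling(need_case / config$prevalence / 50))
  got <- list()
  n_case <- 0L; n_ctrl <- 0L
  for (b in seq_len(max_batches)) {
    ind <- draw_individuals(config, pool, batch)
    prob <- plogis(liability_eta(config, ind) + delta)
    disease <- rbinom(batch, 1, prob)
    take_case <- which(disease == 1L)[seq_len(min(sum(disease == 1L),
                                                  need_case - n_case))]
    take_ctrl <- which(disease == 0L)[seq_len(min(sum(disease == 0L),
                                                  need_ctrl - n_ctrl))]
    take <- c(take_case, take_ctrl)
    if (length(take))
      got[[length(got) + 1L]] <-
        list(g = ind$g[take, , drop = FALSE],
             h1 = ind$h1[take, , drop = FALSE],
             h2 = ind$h2[take, , drop = FALSE],
             dosages = if (!is.null(ind$dosages))
               ind$dosages[take, , drop = FALSE],
             y = disease[take])
    n_case <- n_case + length(take_case); n_ctrl <- n_ctrl + length(take_ctrl)
    if (n_case >= need_case && n_ctrl >= need_ctrl) break
  }
  if (n_case < need_case || n_ctrl < need_ctrl)
    stop(sprintf(
      "rejection sampling cap hit: got %d/%d cases, %d/%d controls",
      n_case, need_case, n_ctrl, need_ctrl))
  g <- do.call(rbind, lapply(got, `[[`, "g"))
  h1 <- do.call(rbind, lapply(got, `[[`, "h1"))
  h2 <- do.call(rbind, lapply(got, `[[`, "h2"))
  y <- unlist(lapply(got, `[[`, "y"))
  dos <- if (config$n_risk_alleles > 0)
    do.call(rbind, lapply(got, `[[`, "dosages"))
  ids <- sprintf("S%05d", seq_along(y))
  L <- config$snps_per_block
  meta <- data.frame(
    snp = sprintf("snp%05d", seq_len(m)),
    chr = rep("6", m),
    pos = 25.6e6 + (seq_len(m) - 1L) * 5000 +
      (rep(seq_len(config$n_blocks), each = L) - 1L) * 50000,
    a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  hla <- NULL
  if (!is.null(dos)) {
    rownames(dos) <- ids
    hla <- hla_dosage_matrix(dos, paste0("RH", seq_len(ncol(dos))))
  }
  rownames(h1) <- rownames(h2) <- ids
  study <- genotype_study(g, y, meta, ids,
                          phase = list(h1 = h1, h2 = h2), hla = hla)
  attr(study, "sim_delta") <- delta
  attr(study, "sim_pool") <- pool
  study
}

#' Pick the block-1 SNP pair that jointly tags a risk allele
#'
#' Scans all SNP pairs of the risk-haplotype block for the pair whose
#' joint founder-haplotype pattern best classifies carriers of the given
#' risk allele, relative to the best single SNP (a pure design
#' computation on the founder pool: no phenotype data involved). Such a
#' pair produces a haplotype-induced interaction: jointly associated
#' through the allele, with no two-locus effect of its own.
#'
#' @param study a simulated cohort from [simulate_cohort()] with risk
#'   haplotypes configured.
#' @param allele index of the targeted risk allele (default 1, the
#'   largest-effect allele under the default configuration).
#' @param n_snps number of leading block-1 SNPs to search.
#' @return integer vector `c(snp_a, snp_b)`.
#' @export
tagging_pair <- function(study, allele = 1, n_snps = NULL) {
  pool <- attr(study, "sim_pool")
  if (is.null(pool) || is.null(pool$labels))
    stop("study was not simulated with risk haplotypes")
  h <- pool$founders[[1]]
  if (is.null(n_snps)) n_snps <- ncol(h)
  n_snps <- min(n_snps, ncol(h))
  lab <- pool$labels == allele
  # classification gain: best cell-subset accuracy of the pair pattern
  # over the best single-SNP split, on the founder pool
  acc <- function(groups) sum(vapply(split(lab, groups), function(z)
    max(sum(z), sum(!z)), numeric(1))) / length(lab)
  best <- c(1L, 2L); best_gain <- -Inf
  for (i in seq_len(n_snps - 1)) for (j in (i + 1):n_snps) {
    gain <- acc(paste(h[, i], h[, j])) - max(acc(h[, i]), acc(h[, j]))
    if (gain > best_gain) { best_gain <- gain; best <- c(i, j) }
  }
  best
}

#' Answer key for a simulated cohort
#'
#' Machine-readable truth records for parameter-recovery tests: one per
#' planted model, flagging whether the pair's effect is independent of the
#' risk haplotypes (a planted pair whose SNPs both lie inside the
#' risk-haplotype block is tagged as haplotype-mediated).
#'
#' @param config a [sim_config()].
#' @return list of records `list(snp_a, snp_b, model, independent)`.
#' @export
planted_truth <- function(config) {
  hla_snps <- if (config$n_risk_alleles > 0) seq_len(config$snps_per_block)
              else integer(0)
  lapply(config$planted_models, function(pm) {
    list(snp_a = pm$snp_a, snp_b = pm$snp_b, model = pm$model,
         independent = !(pm$snp_a %in% hla_snps && pm$snp_b %in% hla_snps))
  })
}

#' Serialize truth records to JSON
#'
#' @param config a [sim_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(config, path) {
  truth <- lapply(planted_truth(config), function(tr) {
    list(snp_a = tr$snp_a, snp_b = tr$snp_b,
         penetrance = tr$model$penetrance,
         maf_a = tr$model$maf_a, maf_b = tr$model$maf_b,
         label = tr$model$label, independent = tr$independent)
  })
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
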