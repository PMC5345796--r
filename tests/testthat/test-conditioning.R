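test_that("logistic IRLS recovers the 2x2 closed form and flags separation", {
  # counts (20,10 / 10,20): slope = log((20*20)/(10*10)) = log 4
  y <- c(rep(1, 30), rep(0, 30))
  x <- c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20))
  fit <- logistic_mle(y, cbind(x = x))
  expect_equal(unname(fit$coef["x"]), log(4), tolerance = 1e-6)
  expect_false(fit$separation)
  # null covariates: slopes near zero
  set.seed(31)
  X <- matrix(rnorm(200 * 3), ncol = 3)
  fit0 <- logistic_mle(rbinom(200, 1, 0.5), X)
  expect_true(all(abs(fit0$coef[-1]) < 3 * sqrt(4 / 200) * 3))
  # perfect separation: flagged, finite
  ys <- rep(c(0, 1), each = 25)
  xs <- c(rnorm(25, -3), rnorm(25, 3))
  fs <- logistic_mle(ys, cbind(x = xs))
  expect_true(fs$separation)
  expect_true(all(is.finite(fs$coef)))
  # aliased column dropped deterministically
  fa <- logistic_mle(y, cbind(a = x, b = x))
  expect_true("b" %in% fa$dropped)
  expect_equal(fa$rank, 2L)
})

test_that("nested log-likelihoods are ordered and LRT stats non-negative", {
  set.seed(32)
  for (r in 1:5) {
    y <- rbinom(80, 1, 0.5)
    X <- matrix(rnorm(80 * 4), ncol = 4)
    f0 <- logistic_mle(y, X[, 1:2])
    f1 <- logistic_mle(y, X)
    expect_gte(f1$loglik, f0$loglik - 1e-8)
  }
})

test_that("haplotype-independence LRT is calibrated under the null", {
  set.seed(33)
  n <- 2000   # finite-sample LRT calibration needs cohort-scale n
  dos <- matrix(pmin(2, rpois(n * 8, 0.3)), n, 8,
                dimnames = list(NULL, paste0("RH", 1:8)))
  ps <- vapply(1:200, function(r) {
    y <- rbinom(n, 1, plogis(-1 + dos %*% rnorm(8, 0, 0.3)))
    ga <- rbinom(n, 2, 0.3); gb <- rbinom(n, 2, 0.4)   # independent of y
    hla_independence_lrt(y, ga, gb, dos)$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_lte(mean(ps < 0.05), 0.06 + 2.58 * sqrt(0.05 * 0.95 / 200))
})

test_that("fully haplotype-captured pair is killed by the LRT", {
  set.seed(34)
  n <- 500
  a1 <- rbinom(n, 1, 0.4)                 # binary risk-haplotype carrier
  dos <- cbind(RH1 = a1, RH2 = 1 - a1,
               matrix(0, n, 6, dimnames = list(NULL, paste0("RH", 3:8))))
  # VIP genotypes an exact affine function of the dosage: the pair-cell
  # indicators are aliased with RH1 and must add nothing
  ga <- a1; gb <- 1L - a1
  y <- rbinom(n, 1, plogis(-2 + 1.5 * a1))
  res <- hla_independence_lrt(y, ga, gb, dos)
  expect_lt(res$lrt_stat, 1e-6)
  expect_gt(res$p, 0.99)
})

test_that("a planted haplotype-independent cell effect is detected", {
  set.seed(35)
  ps <- vapply(1:5, function(r) {
    n <- 2000
    dos <- matrix(pmin(2, rpois(n * 8, 0.2)), n, 8,
                  dimnames = list(NULL, paste0("RH", 1:8)))
    ga <- rbinom(n, 2, 0.4); gb <- rbinom(n, 2, 0.4)
    risk <- (ga >= 1) & (gb >= 1)
    y <- rbinom(n, 1, plogis(-1 + log(2.5) * risk))
    hla_independence_lrt(y, ga, gb, dos)$p
  }, numeric(1))
  expect_lt(median(ps), 1e-4)
})

test_that("conditional interaction LRT: null for multiplicative pairs,
           power for XOR", {
  set.seed(36)
  null_ps <- vapply(1:150, function(r) {
    n <- 400
    ga <- rbinom(n, 2, 0.4); gb <- rbinom(n, 2, 0.4)
    y <- rbinom(n, 1, plogis(-0.5 + 0.4 * ga + 0.4 * gb))  # log-odds additive
    conditional_interaction_lrt(y, ga, gb)$p
  }, numeric(1))
  expect_gt(ks.test(null_ps, "punif")$p.value, 0.01)
  xor_ps <- vapply(1:5, function(r) {
    n <- 2000
    ga <- rbinom(n, 2, 0.5); gb <- rbinom(n, 2, 0.5)
    risk <- xor(ga == 1, gb == 1)
    y <- rbinom(n, 1, plogis(-1.5 + 1.2 * risk))
    conditional_interaction_lrt(y, ga, gb)$p
  }, numeric(1))
  expect_lt(median(xor_ps), 1e-6)
})

test_that("fisher meta-analysis matches the chi-square oracle", {
  fm <- fisher_meta(rep(0.5, 5))
  expect_equal(fm$X2, -2 * 5 * log(0.5), tolerance = 1e-12)
  expect_equal(fm$df, 10L)
  expect_equal(fm$p, pchisq(6.931472, 10, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(fisher_meta(rep(1, 5))$X2, 0)
  expect_equal(fisher_meta(rep(1, 5))$p, 1)
  # monotone in each input
  expect_lt(fisher_meta(c(0.01, 0.5))$p, fisher_meta(c(0.05, 0.5))$p)
  expect_error(fisher_meta(c(0.5, 0)), "log-space")
})

test_that("bh_fdr implements the step-up rule", {
  r <- bh_fdr(c(0.01, 0.02, 0.9, 0.95), q = 0.05)
  expect_equal(r$reject, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$cutoff, 0.02)
  expect_true(all(bh_fdr(rep(0.001, 100))$reject))
  set.seed(37)
  expect_lte(sum(bh_fdr(runif(5454))$reject), 2)
})

test_that("info metric: HWE hard calls 1, constants 0, shrinkage c^2", {
  d <- c(rep(0, 25), rep(1, 50), rep(2, 25))
  ctrl <- rep(TRUE, 100)
  expect_equal(info_metric(d, ctrl), 1)
  expect_equal(info_metric(rep(1, 50), ctrl[1:50]), 0)
  p <- mean(d) / 2
  shrunk <- 2 * p + 0.6 * (d - 2 * p)
  expect_equal(info_metric(shrunk, ctrl), 0.36, tolerance = 1e-12)
})

test_that("principal components separate planted subpopulations", {
  set.seed(38)
  n <- 100; m <- 80
  pop <- rep(0:1, each = n / 2)
  p1 <- runif(m, 0.1, 0.5); p2 <- pmin(0.9, p1 + 0.4)
  g <- t(vapply(seq_len(n), function(i)
    rbinom(m, 2, if (pop[i] == 0) p1 else p2), numeric(m)))
  st <- make_study(g, rep(c(1L, 0L), n / 2))
  pcs <- compute_pcs(st, k = 3, thin_r2 = 1)
  expect_gt(abs(cor(pcs[, 1], pop)), 0.9)
  gram <- crossprod(pcs)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-6)
  # identical samples: zero variance everywhere -> error
  st_const <- make_study(matrix(1L, 10, 5), rep(c(1L, 0L), 5))
  expect_error(compute_pcs(st_const, k = 2), "zero variance")
})

test_that("null interaction QQ shows no inflation in either scenario", {
  # strong marginal locus via a row-effect penetrance model
  mod <- two_locus_model(matrix(c(0.005, 0.005, 0.005,
                                  0.05, 0.05, 0.05,
                                  0.05, 0.05, 0.05), 3, 3, byrow = TRUE),
                         0.3, 0.3)
  cfg <- sim_config(n_cases = 2000, n_controls = 2000, n_blocks = 10,
                    snps_per_block = 2, n_founders = 100,
                    planted_models = list(list(snp_a = 5, snp_b = 15,
                                               model = mod)),
                    seed = 99)
  st <- apply_snp_qc(simulate_cohort(cfg), maf_min = 0.1)$study
  qq <- null_interaction_qq(st, n_pairs = 250, seed = 40)
  expect_setequal(unique(qq$scenario), c("random_random", "strong_random"))
  for (sc in unique(qq$scenario)) {
    expect_gt(ks.test(qq$p[qq$scenario == sc], "punif")$p.value, 0.01)
  }
  qq2 <- null_interaction_qq(st, n_pairs = 50, seed = 41)
  qq3 <- null_interaction_qq(st, n_pairs = 50, seed = 41)
  expect_identical(qq2, qq3)              # seeded determinism
})
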