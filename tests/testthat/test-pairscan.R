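test_that("pair_contingency counts match the naive oracle", {
  g <- matrix(c(0L, 2L, 0L, 1L, NA, 2L,
                0L, 2L, 1L, 1L, 0L, 2L), ncol = 2)
  st <- make_study(g, c(1L, 0L, 1L, 1L, 0L, 0L))
  tb <- pair_contingency(st, 1, 2)
  expect_equal(unname(tb$counts), unname(naive_pair_counts(st, 1, 2)))
  # sample 5 (missing at snp_a) excluded from totals
  expect_equal(tb$n_cases + tb$n_controls, 5)
  expect_error(pair_contingency(st, 1, 1), "differ")
  # handful of random studies against the oracle
  set.seed(4)
  for (r in 1:5) {
    g <- matrix(sample(c(0:2, NA), 60, TRUE, prob = c(.4, .3, .2, .1)),
                ncol = 3)
    st <- make_study(g, sample(0:1, 20, TRUE))
    tb <- pair_contingency(st, 2, 3)
    expect_equal(unname(tb$counts), unname(naive_pair_counts(st, 2, 3)))
  }
})

test_that("single_snp_roc reaches perfect separation and collapses on ties", {
  tb <- pair_table(case_counts = c(10, 0, 0, 0, 0, 0, 0, 0, 0),
                   control_counts = c(0, 0, 0, 10, 0, 0, 0, 0, 0))
  roc <- single_snp_roc(tb, "A")
  expect_true(any(roc$sensitivity == 1 & roc$specificity == 1))
  tb2 <- pair_table(rep(2, 9), rep(4, 9))
  roc2 <- single_snp_roc(tb2, "B")
  expect_equal(nrow(roc2), 2)     # origin + full set only
  expect_equal(roc2$sensitivity, c(0, 1))
})

test_that("gss statistic matches the slow R reference on random tables", {
  set.seed(11)
  for (r in 1:40) {
    cc <- rmultinom(1, 120, runif(9, 0, 1))[, 1]
    nn <- rmultinom(1, 150, runif(9, 0, 1))[, 1]
    got <- gss_statistic(pair_table(cc, nn))$log10_p_raw
    expect_equal(got, r_gss_log10(cc, nn), tolerance = 1e-8,
                 label = paste("table", r))
  }
})

test_that("gss is symmetric in pair order and null for a duplicated locus", {
  set.seed(12)
  cc <- rmultinom(1, 100, runif(9))[, 1]
  nn <- rmultinom(1, 100, runif(9))[, 1]
  swap <- function(x) as.numeric(matrix(x, 3, 3, byrow = TRUE))
  expect_equal(gss_statistic(pair_table(cc, nn))$p_raw,
               gss_statistic(pair_table(swap(cc), swap(nn)))$p_raw,
               tolerance = 1e-10)
  # duplicated locus: only diagonal cells occupied, no gain possible
  ccd <- c(30, 0, 0, 0, 50, 0, 0, 0, 20)
  nnd <- c(45, 0, 0, 0, 40, 0, 0, 0, 15)
  expect_gt(gss_statistic(pair_table(ccd, nnd))$p_raw, 0.05)
})

test_that("an XOR-like table is extreme while its margins are not", {
  cc <- c(68, 0, 0, 0, 66, 0, 0, 0, 66)
  nn <- c(0, 0, 100, 0, 0, 0, 100, 0, 0)
  res <- gss_statistic(pair_table(cc, nn))
  expect_lt(res$log10_p_raw, -20)
  expect_setequal(res$high_risk_cells, c(1, 5, 9))
  expect_true(res$p_raw > 0)            # never underflows to exact zero
})

test_that("or_gss follows the printed formula and flags degeneracies", {
  # pi(1,HR)=0.6, pi(0,HR)=0.3 -> 3.5
  tb <- pair_table(c(60, 40, rep(0, 7)), c(30, 70, rep(0, 7)))
  expect_equal(or_gss(tb, 1), 3.5)
  tb_same <- pair_table(c(50, 50, rep(0, 7)), c(50, 50, rep(0, 7)))
  expect_equal(or_gss(tb_same, 1), 1)
  tb_deg <- pair_table(c(100, 0, rep(0, 7)), c(0, 100, rep(0, 7)))
  expect_identical(or_gss(tb_deg, 1), Inf)
  expect_error(or_gss(tb, integer(0)), "empty")
  expect_error(or_gss(tb, 1:2), "universal")
})

test_that("exhaustive scan touches C(m,2) pairs and ignores column order", {
  set.seed(13)
  g <- matrix(sample(0:2, 120, TRUE), ncol = 6)
  st <- make_study(g, rep(c(1L, 0L), 10))
  sc <- exhaustive_scan(st)
  expect_equal(attr(sc, "n_pairs_evaluated"), choose(6, 2))
  expect_equal(nrow(sc), choose(6, 2))
  # permute the SNP columns: same p per pair identity
  perm <- c(4, 2, 6, 1, 3, 5)
  st2 <- subset_study(st, snps = perm)
  sc2 <- exhaustive_scan(st2)
  key <- function(d) paste(pmin(d$snp_a, d$snp_b), pmax(d$snp_a, d$snp_b))
  expect_equal(sc2$log10_p_raw[order(key(sc2))],
               sc$log10_p_raw[order(key(sc))], tolerance = 1e-12)
  expect_error(exhaustive_scan(subset_study(st, snps = 1)), "2 SNPs")
})

test_that("bonferroni thresholds reproduce the published pair counts", {
  expect_equal(bonferroni_threshold(301546), 1.1e-12, tolerance = 0.01)
  expect_equal(bonferroni_threshold(2), 0.05)
  expect_equal(bonferroni_threshold(515413), 3.764e-13, tolerance = 0.001)
})

test_that("calibration map is near-identity on a uniform pool, monotone", {
  set.seed(14)
  null_pool <- runif(1e6)
  obs <- sort(runif(2000))
  adj <- calibrate_pvalues(obs, null_pool)
  expect_lt(max(abs(adj - obs)), 0.02)
  expect_true(all(diff(adj) >= -1e-12))        # monotone stays monotone
  # extrapolation beyond the deepest null quantile stays monotone, finite
  deep <- calibrate_pvalues(c(1e-30, 1e-60), null_pool)
  expect_true(all(deep > 0) && deep[2] < deep[1])
  expect_error(calibrate_pvalues(0.5, numeric(0)), "empty")
})

test_that("label-permuted ranks are uniform under the null", {
  set.seed(15)
  g <- matrix(rbinom(200 * 8, 2, 0.3), ncol = 8)
  y <- rep(c(1L, 0L), 100)
  st <- make_study(g, y)
  obs <- exhaustive_scan(st)$log10_p_raw
  pool <- unlist(lapply(1:40, function(k)
    permuted_scan(st, seed = 100 + k)$log10_p_raw))
  ranks <- vapply(obs, function(x) mean(pool <= x), numeric(1))
  expect_gt(suppressWarnings(ks.test(ranks, "punif"))$p.value, 0.01)
})
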