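test_that("pair indicator encoding puts one hot cell per complete sample", {
  g <- matrix(c(1L, 0L, NA, 2L,
                2L, 1L, 1L, 0L), ncol = 2)
  st <- make_study(g, c(1L, 0L, 1L, 0L))
  X <- encode_pair_indicators(st, data.frame(snp_a = "s1", snp_b = "s2"))
  expect_equal(ncol(X), 9)
  # (gA, gB) = (1, 2) -> cell 3*1+2+1 = 6
  expect_equal(unname(X[1, ]), as.numeric(1:9 == 6))
  expect_equal(unname(rowSums(X)), c(1, 1, 0, 1))  # missing row all-zero
  expect_equal(sum(X), 3)                           # complete samples
  expect_error(encode_pair_indicators(
    st, data.frame(snp_a = "nope", snp_b = "s2")), "unknown SNP")
})

test_that("encoding is identical across cohorts sharing orientation", {
  set.seed(51)
  g <- matrix(sample(0:2, 40, TRUE), ncol = 2)
  stA <- make_study(g, rep(c(1L, 0L), 10))
  stB <- make_study(g[1:10, ], rep(c(1L, 0L), 5))
  pairs <- data.frame(snp_a = "s1", snp_b = "s2")
  XA <- encode_pair_indicators(stA, pairs)
  XB <- encode_pair_indicators(stB, pairs)
  expect_equal(XA[1:10, ], XB)
})

test_that("solver matches a brute-force grid oracle on a toy problem", {
  X <- cbind(a = c(0.2, 1.4, -0.8, 2.1, -1.7, 0.4),
             b = c(1.0, -0.3, 0.9, -1.2, 0.5, -0.6))
  y <- c(1, 1, -1, 1, -1, -1)
  lambda <- 0.05
  fit <- fit_l1_squared_hinge(X, y, lambda, tol = 1e-9, max_iter = 50000)
  obj <- squared_hinge_objective(fit, X, y)
  # exhaustive grid over (beta_a, beta_b, beta0)
  grid <- seq(-3, 3, by = 0.02)
  best <- Inf
  for (b0 in seq(-2, 2, by = 0.02)) {
    f0 <- 1 - y * b0
    for (ba in grid) {
      f1 <- f0 - y * X[, "a"] * ba
      pen_a <- lambda * abs(ba)
      for (bb in grid) {
        r <- pmax(0, f1 - y * X[, "b"] * bb)
        o <- mean(r^2) / 2 + pen_a + lambda * abs(bb)
        if (o < best) best <- o
      }
    }
  }
  expect_lt(obj, best + 1e-4)
  expect_true(fit$converged)
})

test_that("penalty dominance, duplicated features, objective sanity", {
  set.seed(52)
  X <- matrix(rnorm(80 * 3), ncol = 3)
  y <- sign(X[, 1] + rnorm(80, 0, 0.5)); y[y == 0] <- 1
  lmax <- lambda_max_l1_hinge(X, y)
  expect_true(all(fit_l1_squared_hinge(X, y, lmax * 1.000001)$beta == 0))
  expect_true(any(fit_l1_squared_hinge(X, y, lmax * 0.9)$beta != 0))
  # duplicated feature: identical fitted scores regardless of the split
  Xd <- cbind(X, dup = X[, 1])
  f1 <- fit_l1_squared_hinge(X, y, 0.02, tol = 1e-8)
  f2 <- fit_l1_squared_hinge(Xd, y, 0.02, tol = 1e-8)
  s1 <- drop(X %*% f1$beta) + f1$beta0
  s2 <- drop(Xd %*% f2$beta) + f2$beta0
  expect_equal(s1, s2, tolerance = 1e-3)
  # never worse than the all-zero model
  null_obj <- squared_hinge_objective(
    list(beta = rep(0, 3), beta0 = 0, lambda = 0.02), X, y)
  expect_lte(squared_hinge_objective(f1, X, y), null_obj)
  expect_error(fit_l1_squared_hinge(matrix(c(1, NA), 1, 2), c(1), 0.1),
               "non-finite")
})

test_that("cross-validation selects signal and is seed-reproducible", {
  set.seed(53)
  n <- 120
  X <- cbind(sig = rnorm(n), matrix(rnorm(n * 5), ncol = 5))
  y <- ifelse(X[, "sig"] + rnorm(n, 0, 0.4) > 0, 1, -1)
  cv <- cv_select(X, y, n_lambdas = 25, folds = 5, reps = 2, seed = 9)
  expect_true(cv$model$beta["sig"] != 0)
  expect_gt(max(cv$cv_curve$mean_auc), 0.8)
  cv2 <- cv_select(X, y, n_lambdas = 25, folds = 5, reps = 2, seed = 9)
  expect_identical(cv$lambda, cv2$lambda)
  expect_identical(cv$model$beta, cv2$model$beta)
  # pure noise: held-out AUC hovers at chance
  Xn <- matrix(rnorm(n * 6), ncol = 6)
  cvn <- cv_select(Xn, y, n_lambdas = 10, folds = 5, reps = 2, seed = 10)
  expect_lt(abs(max(cvn$cv_curve$mean_auc) - 0.5), 0.12)
})

test_that("auc: perfect separation, hand example, tie convention", {
  expect_equal(auc(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(auc(c(0.9, 0.8, 0.7, 0.85), c(1, 1, 0, 0)), 0.75)
  expect_equal(auc(rep(1, 10), rep(c(1, 0), 5)), 0.5)
})

test_that("delong test: identity, type-I calibration, bootstrap agreement", {
  set.seed(54)
  y <- rep(c(1, 0), each = 40)
  s <- rnorm(80) + y
  expect_equal(delong_test(s, s, y)$p, 1)
  # type-I error at nominal level under no AUC difference
  rejections <- vapply(1:400, function(r) {
    yy <- rep(c(1, 0), each = 30)
    base <- rnorm(60) + 0.8 * yy
    s1 <- base + rnorm(60, 0, 0.3)
    s2 <- base + rnorm(60, 0, 0.3)
    delong_test(s1, s2, yy)$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.035)
  # paired bootstrap oracle on one fixture
  yy <- rep(c(1, 0), each = 50)
  s1 <- rnorm(100) + 1.0 * yy
  s2 <- rnorm(100) + 0.6 * yy
  dl <- delong_test(s1, s2, yy)
  boot <- vapply(1:2000, function(b) {
    i <- sample(100, replace = TRUE)
    if (length(unique(yy[i])) < 2) return(NA_real_)
    auc(s1[i], yy[i]) - auc(s2[i], yy[i])
  }, numeric(1))
  boot_se <- sd(boot, na.rm = TRUE)
  expect_equal(dl$se, boot_se, tolerance = 0.35)
  boot_p <- 2 * pnorm(-abs(dl$delta) / boot_se)
  expect_equal(log10(dl$p + 1e-12), log10(boot_p + 1e-12), tolerance = 0.7)
})

test_that("liability mapping reproduces the published variance/AUC pairs", {
  expect_equal(liability_variance_from_auc(0.5, 0.01), 0)
  # every printed (variance, AUC) row at 1% prevalence; tolerance reflects
  # the 3-decimal rounding of the published AUCs (dh2/dAUC ~ 2.4)
  tab <- rbind(c(0.329, 0.883), c(0.341, 0.888), c(0.339, 0.887),
               c(0.269, 0.855), c(0.288, 0.864), c(0.267, 0.854),
               c(0.323, 0.880), c(0.342, 0.888), c(0.320, 0.879),
               c(0.273, 0.857), c(0.295, 0.868), c(0.265, 0.853),
               c(0.271, 0.856), c(0.280, 0.860), c(0.266, 0.853))
  for (i in seq_len(nrow(tab)))
    expect_equal(liability_variance_from_auc(tab[i, 2], 0.01), tab[i, 1],
                 tolerance = 0.0015 / tab[i, 1], label = paste("row", i))
  # strictly increasing in AUC; forward/inverse roundtrip
  h <- vapply(c(0.6, 0.75, 0.9), liability_variance_from_auc, numeric(1),
              K = 0.01)
  expect_true(all(diff(h) > 0))
  for (a in c(0.6, 0.75, 0.9))
    expect_equal(auc_from_liability(
      liability_variance_from_auc(a, 0.01), 0.01), a, tolerance = 1e-6)
  expect_error(liability_variance_from_auc(0.4, 0.01), "AUC below")
})
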