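# Penalized predictive models: 9-indicator pair encoding, L1-penalized
# squared-hinge linear model (cyclic coordinate descent), cross-validated
# penalty selection by AUC, DeLong comparison of paired AUCs, and the
# liability-scale variance explained implied by an AUC at a given
# population prevalence.

#' 9-indicator encoding of SNP pairs
#'
#' Each pair contributes 9 binary columns over the genotype-combination
#' cells (`3*gA + gB + 1`); exactly one is hot for samples with both
#' genotypes present, all are zero otherwise. Consistent minor-allele
#' orientation across cohorts makes the encoding transferable.
#'
#' @param study a [genotype_study()].
#' @param pairs data frame with columns `snp_a`, `snp_b` (SNP ids or
#'   indices).
#' @return numeric matrix samples x (9 * nrow(pairs)); columns named
#'   `<snp_a>:<snp_b>_cell<v>`.
#' @export
encode_pair_indicators <- function(study, pairs) {
  g <- study$genotypes
  cols <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$snp_a[i]; b <- pairs$snp_b[i]
    if (is.character(a) || is.factor(a)) a <- match(a, study$snp_meta$snp)
    if (is.character(b) || is.factor(b)) b <- match(b, study$snp_meta$snp)
    if (is.na(a) || is.na(b)) stop("unknown SNP id in pairs row ", i)
    cell <- 3L * g[, a] + g[, b] + 1L
    M <- matrix(0, nrow(g), 9)
    ok <- !is.na(cell)
    M[cbind(which(ok), cell[ok])] <- 1
    colnames(M) <- sprintf("%s:%s_cell%d", study$snp_meta$snp[a],
                           study$snp_meta$snp[b], 1:9)
    cols[[i]] <- M
  }
  do.call(cbind, cols)
}

#' L1-penalized squared-hinge linear model
#'
#' Minimizes `1/(2N) sum_i max(0, 1 - y_i (x_i'b + b0))^2 + lambda ||b||_1`
#' by cyclic proximal coordinate descent (objective non-increasing per
#' sweep).
#'
#' @param X numeric feature matrix (finite entries).
#' @param y labels in `{+1, -1}` (0/1 input is mapped to -1/+1).
#' @param lambda L1 penalty (>= 0).
#' @param beta_init,beta0_init optional warm start.
#' @param tol,max_iter convergence controls.
#' @return A `sparse_linear_model`: list with `beta` (named), `beta0`,
#'   `lambda`, `converged`, `iterations`.
#' @export
fit_l1_squared_hinge <- function(X, y, lambda, beta_init = NULL,
                                 beta0_init = 0, tol = 1e-6,
                                 max_iter = 10000) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite entries in X")
  y <- normalize_labels(y)
  stopifnot(lambda >= 0)
  if (is.null(beta_init)) beta_init <- rep(0, ncol(X))
  fit <- .l1_hinge_cd_cpp(X, y, lambda, beta_init, beta0_init,
                          tol, as.integer(max_iter))
  beta <- setNames(as.numeric(fit$beta),
                   colnames(X) %||% paste0("x", seq_len(ncol(X))))
  structure(list(beta = beta, beta0 = fit$beta0, lambda = lambda,
                 converged = fit$converged, iterations = fit$iterations),
            class = "sparse_linear_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

normalize_labels <- function(y) {
  y <- as.numeric(y)
  if (all(y %in% c(0, 1))) y <- 2 * y - 1
  if (!all(y %in% c(-1, 1))) stop("y must be two-class (0/1 or -1/+1)")
  if (length(unique(y)) < 2) stop("y must contain both classes")
  y
}

#' Squared-hinge objective value
#'
#' @param model a `sparse_linear_model` (or list with `beta`, `beta0`,
#'   `lambda`).
#' @param X,y data as in [fit_l1_squared_hinge()].
#' @return objective value.
#' @export
squared_hinge_objective <- function(model, X, y) {
  y <- normalize_labels(y)
  f <- drop(as.matrix(X) %*% model$beta) + model$beta0
  mean(pmax(0, 1 - y * f)^2) / 2 + model$lambda * sum(abs(model$beta))
}

#' @rdname fit_l1_squared_hinge
#' @export
predict.sparse_linear_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  # align by feature name; features unseen in training contribute 0
  beta <- rep(0, ncol(X))
  hit <- match(colnames(X), names(object$beta))
  beta[!is.na(hit)] <- object$beta[hit[!is.na(hit)]]
  drop(X %*% beta) + object$beta0
}

#' Smallest penalty with an all-zero solution
#'
#' The intercept is first optimized with all slopes at zero; the bound is
#' the largest absolute slope gradient there.
#'
#' @param X,y data as in [fit_l1_squared_hinge()].
#' @return lambda_max.
#' @export
lambda_max_l1_hinge <- function(X, y) {
  y <- normalize_labels(y)
  X <- as.matrix(X)
  b0 <- uniroot(function(b) mean(pmax(0, 1 - y * b) * y),
                interval = c(-1, 1), extendInt = "yes", tol = 1e-10)$root
  r <- pmax(0, 1 - y * b0)
  max(abs(crossprod(X, r * y)) / nrow(X))
}

#' Cross-validated penalty selection
#'
#' Log-spaced penalty grid from `lambda_max` down; for each replication,
#' class-stratified folds are drawn, models are fitted along the path
#' with warm starts, and held-out AUC is recorded. The penalty with the
#' best mean AUC is refitted on the full data.
#'
#' @param X,y training data.
#' @param n_lambdas grid size (default 100).
#' @param folds,reps cross-validation layout (default 10 x 10).
#' @param seed RNG seed for fold assignment.
#' @param lambda_min_ratio lower end of the grid relative to
#'   `lambda_max` (default 1e-4).
#' @param tol,max_iter solver controls.
#' @return list: `model` (refit at the selected penalty), `lambda`,
#'   `cv_curve` (data frame `lambda`, `mean_auc`, `sd_auc`).
#' @export
cv_select <- function(X, y, n_lambdas = 100, folds = 10, reps = 10, seed,
                      lambda_min_ratio = 1e-4, tol = 1e-5,
                      max_iter = 2000) {
  set.seed(seed)
  X <- as.matrix(X)
  y <- normalize_labels(y)
  lmax <- lambda_max_l1_hinge(X, y)
  grid <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                  length.out = n_lambdas))
  auc_mat <- matrix(NA_real_, n_lambdas, folds * reps)
  col <- 0
  for (rep_i in seq_len(reps)) {
    fold_id <- integer(length(y))
    for (cls in c(-1, 1)) {
      idx <- which(y == cls)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    for (f in seq_len(folds)) {
      col <- col + 1
      tr <- fold_id != f
      if (length(unique(y[!tr])) < 2 || length(unique(y[tr])) < 2)
        stop("a fold contains a single class; reduce folds")
      beta <- rep(0, ncol(X)); b0 <- 0
      for (li in seq_len(n_lambdas)) {
        fit <- .l1_hinge_cd_cpp(X[tr, , drop = FALSE], y[tr], grid[li],
                                beta, b0, tol, as.integer(max_iter))
        beta <- as.numeric(fit$beta); b0 <- fit$beta0
        scores <- drop(X[!tr, , drop = FALSE] %*% beta) + b0
        auc_mat[li, col] <- auc(scores, y[!tr])
      }
    }
  }
  mean_auc <- rowMeans(auc_mat)
  best <- which.max(mean_auc)
  model <- fit_l1_squared_hinge(X, y, grid[best], tol = tol,
                                max_iter = max_iter)
  list(model = model, lambda = grid[best],
       cv_curve = data.frame(lambda = grid, mean_auc = mean_auc,
                             sd_auc = apply(auc_mat, 1, sd)))
}

#' Area under the ROC curve (Mann-Whitney estimator, ties credited 1/2)
#'
#' @param scores numeric predictions.
#' @param labels two-class labels (0/1 or -1/+1; larger = case).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  y <- normalize_labels(labels)
  n1 <- sum(y == 1); n0 <- sum(y == -1)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' DeLong two-sided test for paired AUCs
#'
#' Compares the AUCs of two score vectors on the same samples using the
#' DeLong placement-value covariance.
#'
#' @param scores1,scores2 paired predictions.
#' @param labels two-class labels.
#' @return list: `auc1`, `auc2`, `delta`, `se`, `p` (two-sided normal;
#'   `p = 1` when the variance of the difference degenerates).
#' @export
delong_test <- function(scores1, scores2, labels) {
  y <- normalize_labels(labels)
  case <- y == 1
  placements <- function(s) {
    x <- s[case]; z <- s[!case]
    # V10_i = P(score of control < x_i) + .5 P(=); V01_j analogous
    v10 <- vapply(x, function(xi) mean((z < xi) + 0.5 * (z == xi)),
                  numeric(1))
    v01 <- vapply(z, function(zj) mean((x > zj) + 0.5 * (x == zj)),
                  numeric(1))
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  p1 <- placements(scores1); p2 <- placements(scores2)
  m <- sum(case); n <- sum(!case)
  s10 <- var(cbind(p1$v10, p2$v10))
  s01 <- var(cbind(p1$v01, p2$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- p1$auc - p2$auc
  if (!is.finite(var_delta) || var_delta <= 0)
    return(list(auc1 = p1$auc, auc2 = p2$auc, delta = delta, se = 0, p = 1))
  z <- delta / sqrt(var_delta)
  list(auc1 = p1$auc, auc2 = p2$auc, delta = delta, se = sqrt(var_delta),
       p = 2 * pnorm(-abs(z)))
}

#' AUC implied by a liability-scale heritability
#'
#' Normal liability threshold model: a disease with prevalence `K` and a
#' predictor explaining `h2` of liability variance yields
#' `AUC = Phi( h2 (i - i2) / sqrt(h2 (1 - h2 i (i - t)) + h2 (1 - h2 i2 (i2 - t))) )`
#' where `t` is the liability threshold, `i` and `i2` the mean liabilities
#' of cases and non-cases.
#'
#' @param h2 liability variance explained, in `[0, 1)`.
#' @param K population prevalence.
#' @return AUC in `[0.5, 1)`.
#' @export
auc_from_liability <- function(h2, K) {
  stopifnot(h2 >= 0, h2 < 1, K > 0, K < 1)
  t <- qnorm(1 - K)
  z <- dnorm(t)
  i <- z / K
  i2 <- -z / (1 - K)
  if (h2 == 0) return(0.5)
  num <- h2 * (i - i2)
  den <- sqrt(h2 * (1 - h2 * i * (i - t)) + h2 * (1 - h2 * i2 * (i2 - t)))
  pnorm(num / den)
}

#' Liability-scale variance explained implied by an AUC
#'
#' Numerically inverts [auc_from_liability()] by bisection to 1e-6.
#'
#' @param auc observed AUC in `[0.5, 1)`.
#' @param K population prevalence (the conventional assumption here is
#'   1%).
#' @return `h2` in `[0, 1)`.
#' @export
liability_variance_from_auc <- function(auc, K) {
  stopifnot(K > 0, K < 1)
  if (auc < 0.5) stop("AUC below 0.5 has no liability interpretation")
  if (auc == 0.5) return(0)
  lo <- 0; hi <- 1 - 1e-12
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (auc_from_liability(mid, K) < auc) lo <- mid else hi <- mid
    if (hi - lo < 1e-9) break
  }
  (lo + hi) / 2
}
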