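# Exhaustive SNP-pair interaction scan: discrimination-gain statistic,
# interaction odds ratio, Bonferroni thresholds over pair counts, and
# permutation-based p-value calibration.

#' 2 x 9 case/control contingency table for a SNP pair
#'
#' Counts samples over the 9 genotype combinations of a pair, cell index
#' `3*gA + gB + 1`, using only samples with both genotypes non-missing.
#'
#' @param study a [genotype_study()].
#' @param snp_a,snp_b distinct SNP column indices (or names).
#' @return A `pair_table`: list with `counts` (2 x 9 matrix, rows
#'   control/case), `n_cases`, `n_controls`.
#' @export
pair_contingency <- function(study, snp_a, snp_b) {
  if (is.character(snp_a)) snp_a <- match(snp_a, study$snp_meta$snp)
  if (is.character(snp_b)) snp_b <- match(snp_b, study$snp_meta$snp)
  if (is.na(snp_a) || is.na(snp_b)) stop("unknown SNP")
  if (snp_a == snp_b) stop("snp_a and snp_b must differ")
  ga <- study$genotypes[, snp_a]; gb <- study$genotypes[, snp_b]
  ok <- !is.na(ga) & !is.na(gb)
  cell <- 3L * ga[ok] + gb[ok] + 1L
  y <- study$phenotype[ok]
  counts <- rbind(control = tabulate(cell[y == 0L], nbins = 9L),
                  case    = tabulate(cell[y == 1L], nbins = 9L))
  colnames(counts) <- paste0("c", 1:9)
  structure(list(counts = counts, n_cases = sum(counts["case", ]),
                 n_controls = sum(counts["control", ])),
            class = "pair_table")
}

#' Construct a pair table from raw counts
#'
#' @param case_counts,control_counts length-9 non-negative integer vectors
#'   over cells `3*gA + gB + 1`.
#' @return A `pair_table`.
#' @export
pair_table <- function(case_counts, control_counts) {
  stopifnot(length(case_counts) == 9, length(control_counts) == 9,
            all(case_counts >= 0), all(control_counts >= 0))
  counts <- rbind(control = as.numeric(control_counts),
                  case = as.numeric(case_counts))
  colnames(counts) <- paste0("c", 1:9)
  structure(list(counts = counts, n_cases = sum(counts["case", ]),
                 n_controls = sum(counts["control", ])),
            class = "pair_table")
}

# decreasing-odds ordering with exact-tie merging over k classes; returns
# list of groups (class indices) and cumulative (tp, fp) prefix points.
odds_prefix_groups <- function(case_counts, control_counts) {
  occ <- which(case_counts + control_counts > 0)
  # exact decreasing-odds ordering via cross-multiplication, stable in
  # cell index (Copeland score over pairwise comparisons)
  cmp <- function(a, b) case_counts[a] * control_counts[b] -
    case_counts[b] * control_counts[a]
  ord <- occ[order(sapply(occ, function(v) {
    -sum(sapply(occ, function(w) sign(cmp(v, w))))
  }), occ)]
  groups <- list(); pts <- NULL
  tp <- 0; fp <- 0
  i <- 1
  while (i <= length(ord)) {
    grp <- ord[i]
    j <- i + 1
    while (j <= length(ord) && cmp(ord[i], ord[j]) == 0) {
      grp <- c(grp, ord[j]); j <- j + 1
    }
    tp <- tp + sum(case_counts[grp]); fp <- fp + sum(control_counts[grp])
    groups[[length(groups) + 1]] <- grp
    pts <- rbind(pts, c(tp = tp, fp = fp))
    i <- j
  }
  list(groups = groups, points = pts)
}

#' Marginal ROC points of one SNP of a pair table
#'
#' The three marginal genotype classes are ordered by decreasing
#' case:control odds (exact ties merged); cumulative prefix sets give the
#' ROC points, which by likelihood-ratio ordering lie on the upper-left
#' convex hull.
#'
#' @param table a `pair_table`.
#' @param which `"A"` (rows) or `"B"` (columns).
#' @return data frame with `sensitivity` and `specificity` per point,
#'   including the (sens 0, spec 1) origin.
#' @export
single_snp_roc <- function(table, which = c("A", "B")) {
  which <- match.arg(which)
  cc <- table$counts["case", ]; nn <- table$counts["control", ]
  cls <- if (which == "A") (0:8) %/% 3 else (0:8) %% 3
  mc <- tapply(cc, cls, sum); mn <- tapply(nn, cls, sum)
  pr <- odds_prefix_groups(as.numeric(mc), as.numeric(mn))
  pts <- rbind(c(tp = 0, fp = 0), pr$points)
  data.frame(sensitivity = pts[, "tp"] / max(table$n_cases, 1),
             specificity = 1 - pts[, "fp"] / max(table$n_controls, 1))
}

#' Discrimination-gain statistic for one pair table
#'
#' Asks whether the pair's genotype combinations discriminate cases from
#' controls significantly better than either SNP alone; see the package
#' vignette for the construction. Computed in log space.
#'
#' @param table a `pair_table`.
#' @return A `gss_result`: list with `p_raw`, `log10_p_raw`,
#'   `high_risk_cells` (subset of 1..9), `gain_over` (`"A"` or `"B"`:
#'   the single SNP that bounded the statistic) and `or_gss`.
#' @export
gss_statistic <- function(table) {
  if (table$n_cases == 0 || table$n_controls == 0)
    stop("both cases and controls are required")
  res <- .gss_scan_cpp(matrix(table$counts["case", ], 1, 9),
                       matrix(table$counts["control", ], 1, 9))
  hr <- which(bitwAnd(res$hr_mask[1], 2^(0:8)) > 0)
  structure(list(p_raw = 10^res$log10_p[1],
                 log10_p_raw = res$log10_p[1],
                 high_risk_cells = hr,
                 gain_over = c("A", "B")[res$gain_over[1]],
                 or_gss = res$or_gss[1]),
            class = "gss_result")
}

#' Interaction odds ratio over a high-risk cell set
#'
#' `OR = (pi_{1,HR} * pi_{0,LR}) / (pi_{0,HR} * pi_{1,LR})` with `pi_{i,j}`
#' the within-phenotype proportion of samples in the high/low-risk
#' genotype combinations. Returns `+Inf` (flagged via `is.infinite`) when
#' a denominator proportion is zero.
#'
#' @param table a `pair_table`.
#' @param high_risk_cells non-empty proper subset of the occupied cells.
#' @return positive number or `+Inf`.
#' @export
or_gss <- function(table, high_risk_cells) {
  occ <- which(colSums(table$counts) > 0)
  if (length(high_risk_cells) == 0) stop("high-risk set is empty")
  if (all(occ %in% high_risk_cells)) stop("high-risk set is universal")
  p1 <- sum(table$counts["case", high_risk_cells]) / table$n_cases
  p0 <- sum(table$counts["control", high_risk_cells]) / table$n_controls
  if (p0 == 0 || p1 == 1) return(Inf)
  (p1 * (1 - p0)) / (p0 * (1 - p1))
}

#' Bonferroni threshold over all SNP pairs
#'
#' @param n_snps number of SNPs (>= 2).
#' @param alpha family-wise error rate (default 0.05).
#' @return `alpha / choose(n_snps, 2)`.
#' @export
bonferroni_threshold <- function(n_snps, alpha = 0.05) {
  stopifnot(n_snps >= 2)
  alpha / choose(n_snps, 2)
}

#' Exhaustive scan of all SNP pairs
#'
#' Evaluates the discrimination-gain statistic for every unordered SNP
#' pair, in lexicographic pair order. Cell counts for all pairs are
#' assembled with genotype-indicator cross-products; the per-pair
#' statistic runs in compiled code.
#'
#' @param study a QC'd [genotype_study()].
#' @param report_threshold only pairs with `p_raw` at or below this are
#'   returned (default 1, i.e. everything; the conventional scan setting
#'   is `1e-6`).
#' @param phenotype optional replacement phenotype vector (used for
#'   permuted-label scans).
#' @return data frame: `snp_a`, `snp_b`, `chr_a`, `pos_a`, `chr_b`,
#'   `pos_b`, `p_raw`, `log10_p_raw`, `or_gss`, `hr_mask`, `gain_over`,
#'   plus an attribute `n_pairs_evaluated`.
#' @export
exhaustive_scan <- function(study, report_threshold = 1, phenotype = NULL) {
  g <- study$genotypes
  m <- ncol(g)
  if (m < 2) stop("need at least 2 SNPs")
  y <- if (is.null(phenotype)) study$phenotype else as.integer(phenotype)
  case <- y == 1L
  Ic <- list(); In <- list()
  for (k in 0:2) {
    Ik <- (!is.na(g) & g == k) * 1
    Ic[[k + 1]] <- Ik[case, , drop = FALSE]
    In[[k + 1]] <- Ik[!case, , drop = FALSE]
  }
  ut <- which(upper.tri(matrix(0, m, m)))   # column-major upper triangle
  ia <- ((ut - 1L) %% m) + 1L               # row index = snp_a
  ib <- ((ut - 1L) %/% m) + 1L              # col index = snp_b
  # lexicographic pair order (a, b), a < b
  o <- order(ia, ib)
  ia <- ia[o]; ib <- ib[o]; ut <- ut[o]
  P <- length(ut)
  cc <- matrix(0, P, 9); nn <- matrix(0, P, 9)
  for (ja in 0:2) for (jb in 0:2) {
    v <- 3L * ja + jb + 1L
    cc[, v] <- crossprod(Ic[[ja + 1]], Ic[[jb + 1]])[ut]
    nn[, v] <- crossprod(In[[ja + 1]], In[[jb + 1]])[ut]
  }
  res <- .gss_scan_cpp(cc, nn)
  keep <- res$log10_p <= log10(report_threshold) + 1e-12
  sm <- study$snp_meta
  out <- data.frame(
    snp_a = sm$snp[ia[keep]], snp_b = sm$snp[ib[keep]],
    chr_a = sm$chr[ia[keep]], pos_a = sm$pos[ia[keep]],
    chr_b = sm$chr[ib[keep]], pos_b = sm$pos[ib[keep]],
    p_raw = 10^res$log10_p[keep], log10_p_raw = res$log10_p[keep],
    or_gss = res$or_gss[keep], hr_mask = res$hr_mask[keep],
    gain_over = c("A", "B")[res$gain_over[keep]],
    stringsAsFactors = FALSE)
  attr(out, "n_pairs_evaluated") <- P
  out
}

#' Permuted-label scan
#'
#' Runs [exhaustive_scan()] with case/control labels permuted, providing
#' the null p-value pool for [calibrate_pvalues()].
#'
#' @param study a [genotype_study()].
#' @param seed RNG seed for the permutation.
#' @param report_threshold passed through (default 1: keep all).
#' @return As [exhaustive_scan()].
#' @export
permuted_scan <- function(study, seed, report_threshold = 1) {
  set.seed(seed)
  exhaustive_scan(study, report_threshold = report_threshold,
                  phenotype = sample(study$phenotype))
}

#' Permutation-based p-value calibration
#'
#' Fits a monotone quantile map, on the -log10 scale, from the pooled
#' permuted-scan p-value distribution to Uniform(0,1) and applies it to
#' the observed p-values. Beyond the deepest null quantile the map is
#' extended linearly in -log10 (slope of the top percentile of the null
#' pool).
#'
#' @param observed p-values (or log10 p via `log10_input`).
#' @param null_pool p-values from one or more permuted-label scans.
#' @param log10_input if `TRUE`, both inputs are log10 p-values (the
#'   `log10_p_raw` column of [exhaustive_scan()], underflow-safe).
#' @return numeric vector of adjusted p-values; the fitted map is
#'   attached as attribute `map` (function on the -log10 scale).
#' @export
calibrate_pvalues <- function(observed, null_pool, log10_input = FALSE) {
  if (length(null_pool) == 0) stop("empty null pool")
  x_obs <- if (log10_input) -observed else -log10(observed)
  x_null <- sort(if (log10_input) -null_pool else -log10(null_pool))
  N <- length(x_null)
  u <- (N - seq_len(N) + 0.5) / N        # fraction of nulls >= x_(i)
  y <- -log10(u)
  # collapse tied x to their largest target, keep the map monotone
  agg <- tapply(y, x_null, max)
  xs <- as.numeric(names(agg)); ys <- cummax(as.numeric(agg))
  xs <- c(0, xs); ys <- c(0, ys)
  # tail slope from the top percentile (at least 2 points)
  i0 <- max(1L, length(xs) - max(2L, ceiling(0.01 * length(xs))))
  slope <- (ys[length(ys)] - ys[i0]) / max(xs[length(xs)] - xs[i0], 1e-12)
  if (!is.finite(slope) || slope <= 0) slope <- 1
  map <- function(x) {
    out <- approx(xs, ys, xout = pmin(x, max(xs)), ties = "ordered",
                  rule = 2)$y
    over <- x > max(xs)
    out[over] <- ys[length(ys)] + slope * (x[over] - max(xs))
    out
  }
  adj <- 10^(-map(x_obs))
  attr(adj, "map") <- map
  adj
}

#' Genomic-control inflation factor
#'
#' Median 1-df chi-square quantile of the p-values divided by the null
#' median.
#'
#' @param p p-values.
#' @return lambda.
#' @export
genomic_lambda <- function(p) {
  stats::median(qchisq(p, df = 1, lower.tail = FALSE)) /
    qchisq(0.5, df = 1, lower.tail = FALSE)
}
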