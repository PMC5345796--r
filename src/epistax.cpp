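#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------
// Discrimination-gain (GSS-style) pair statistic.
//
// The 9 genotype-combination cells of a SNP pair are ordered by
// decreasing case:control odds (ties merged into one step; unoccupied
// cells excluded); prefix sets of that ordering are the candidate
// high-risk (HR) sets and give the pair's ROC points. For each single
// SNP, the analogous 3-class ordering gives its marginal ROC hull. The
// gain p-value of a pair point q against SNP m is the probability that a
// classifier no better than m alone reaches q's sensitivity and
// specificity simultaneously:
//   g_m(q) = P[Bin(n1, sens_m(q)) >= TP_q] * P[Bin(n0, fpr_m(q)) <= FP_q]
// with (sens_m(q), fpr_m(q)) the best marginal point of m with FP <=
// FP_q. The pair statistic is max_m min_q g_m(q): the pair must beat
// BOTH single SNPs. All tail products are kept in log space.
// ---------------------------------------------------------------------

struct RocPoint { double tp, fp; };

// order k classes by decreasing case:control odds via cross-
// multiplication (exact for integer counts); merge exact ties; skip
// unoccupied classes. Returns prefix points and, optionally, the group
// membership of each class.
static void odds_prefixes(const std::vector<double>& cc,
                          const std::vector<double>& nn,
                          std::vector<RocPoint>& prefixes,
                          std::vector<std::vector<int> >& groups) {
  const int k = (int)cc.size();
  std::vector<int> idx;
  for (int v = 0; v < k; ++v)
    if (cc[v] + nn[v] > 0) idx.push_back(v);
  std::stable_sort(idx.begin(), idx.end(), [&](int a, int b) {
    return cc[a] * nn[b] > cc[b] * nn[a];
  });
  prefixes.clear(); groups.clear();
  double tp = 0, fp = 0;
  size_t i = 0;
  while (i < idx.size()) {
    std::vector<int> grp;
    grp.push_back(idx[i]);
    size_t j = i + 1;
    while (j < idx.size() &&
           cc[idx[i]] * nn[idx[j]] == cc[idx[j]] * nn[idx[i]]) {
      grp.push_back(idx[j]); ++j;
    }
    for (int v : grp) { tp += cc[v]; fp += nn[v]; }
    RocPoint p; p.tp = tp; p.fp = fp;
    prefixes.push_back(p);
    groups.push_back(grp);
    i = j;
  }
}

// log attainment probability of pair point (TP, FP) by a baseline
// classifier at ROC point (sens, fpr):
//   log P[Bin(n1, sens) >= TP] + log P[Bin(n0, fpr) <= FP]
static double attain_log(double TP, double FP, double n1, double n0,
                         double sens, double fpr) {
  return R::pbinom(TP - 1.0, n1, sens, 0, 1) +
         R::pbinom(FP, n0, fpr, 1, 1);
}

// single-pair evaluation; returns natural-log p and fills hr mask etc.
static void gss_one(const double* ccp, const double* nnp,
                    double& log_p, int& hr_mask, int& gain_over,
                    double& or_gss) {
  std::vector<double> cc(ccp, ccp + 9), nn(nnp, nnp + 9);
  double n1 = 0, n0 = 0;
  for (int v = 0; v < 9; ++v) { n1 += cc[v]; n0 += nn[v]; }
  std::vector<RocPoint> pair_pts;
  std::vector<std::vector<int> > pair_grp;
  odds_prefixes(cc, nn, pair_pts, pair_grp);

  double min_by_m[2] = {R_PosInf, R_PosInf};
  int argq_by_m[2] = {-1, -1};
  for (int m = 0; m < 2; ++m) {
    std::vector<double> mc(3, 0.0), mn(3, 0.0);
    for (int v = 0; v < 9; ++v) {
      int cls = (m == 0) ? v / 3 : v % 3;
      mc[cls] += cc[v]; mn[cls] += nn[v];
    }
    std::vector<RocPoint> mpts;
    std::vector<std::vector<int> > mgrp;
    odds_prefixes(mc, mn, mpts, mgrp);
    // marginal hull vertices incl. the (0,0) endpoint; likelihood-ratio
    // ordering puts the prefix points on the upper-left convex hull
    std::vector<RocPoint> cand;
    RocPoint origin; origin.tp = 0; origin.fp = 0;
    cand.push_back(origin);
    for (size_t s = 0; s < mpts.size(); ++s) cand.push_back(mpts[s]);

    double min_q = R_PosInf; int arg_q = -1;
    for (size_t q = 0; q < pair_pts.size(); ++q) {
      const double TP = pair_pts[q].tp, FP = pair_pts[q].fp;
      // g_m(q): best attainment probability over classifiers no better
      // than SNP m: maximize over hull vertices, the hull interpolation
      // at FP (randomized mixture of adjacent vertices), and the pooled
      // diagonal point (coin-flip classifier) -- the latter two keep the
      // baseline honest and the probability strictly positive.
      double best = R_NegInf;
      for (size_t t = 0; t < cand.size(); ++t) {
        double lg = attain_log(TP, FP, n1, n0,
                               n1 > 0 ? cand[t].tp / n1 : 0.0,
                               n0 > 0 ? cand[t].fp / n0 : 0.0);
        if (lg > best) best = lg;
      }
      // hull interpolation at FP
      double sens_i = 1.0;
      if (FP >= cand.back().fp) {
        sens_i = 1.0;  // beyond last vertex: (1,1)
      } else {
        for (size_t t = 0; t + 1 < cand.size(); ++t) {
          if (FP >= cand[t].fp && FP <= cand[t + 1].fp) {
            double span = cand[t + 1].fp - cand[t].fp;
            double w = (span > 0) ? (FP - cand[t].fp) / span : 0.0;
            sens_i = (cand[t].tp + w * (cand[t + 1].tp - cand[t].tp)) /
                     std::max(n1, 1.0);
            break;
          }
        }
      }
      double lg_i = attain_log(TP, FP, n1, n0, sens_i,
                               n0 > 0 ? FP / n0 : 0.0);
      if (lg_i > best) best = lg_i;
      double tpool = (TP + FP) / std::max(n1 + n0, 1.0);
      double lg_d = attain_log(TP, FP, n1, n0, tpool, tpool);
      if (lg_d > best) best = lg_d;
      if (best < min_q) { min_q = best; arg_q = (int)q; }
    }
    min_by_m[m] = min_q; argq_by_m[m] = arg_q;
  }
  // the pair must beat BOTH single SNPs: take the less favourable one
  int best_m = (min_by_m[1] > min_by_m[0]) ? 1 : 0;  // ties -> SNP A
  int best_q_all = argq_by_m[best_m];
  log_p = std::min(min_by_m[best_m], 0.0);

  // HR set: prefix groups up to the argmin point of the bounding SNP
  hr_mask = 0;
  double tp_hr = 0, fp_hr = 0;
  if (best_q_all >= 0) {
    for (int q = 0; q <= best_q_all; ++q)
      for (int v : pair_grp[q]) hr_mask |= (1 << v);
    tp_hr = pair_pts[best_q_all].tp;
    fp_hr = pair_pts[best_q_all].fp;
  }
  gain_over = best_m + 1;  // 1 = SNP A, 2 = SNP B
  // odds ratio over the HR/LR split (within-phenotype proportions)
  double p1 = (n1 > 0) ? tp_hr / n1 : NA_REAL;
  double p0 = (n0 > 0) ? fp_hr / n0 : NA_REAL;
  if (hr_mask == 0 || (p1 >= 1.0 && p0 >= 1.0)) {
    or_gss = NA_REAL;                    // HR empty or universal
  } else if (p0 == 0.0 || p1 == 1.0) {
    or_gss = R_PosInf;                   // degenerate, flagged +Inf
  } else if (p1 == 0.0) {
    or_gss = 0.0;
  } else {
    or_gss = (p1 * (1.0 - p0)) / (p0 * (1.0 - p1));
  }
}

// [[Rcpp::export(name = ".gss_scan_cpp")]]
List gss_scan_cpp(NumericMatrix case_counts, NumericMatrix ctrl_counts) {
  const int P = case_counts.nrow();
  if (case_counts.ncol() != 9 || ctrl_counts.ncol() != 9 ||
      ctrl_counts.nrow() != P)
    stop("count matrices must be P x 9");
  NumericVector log10_p(P), or_gss(P);
  IntegerVector hr_mask(P), gain_over(P);
  std::vector<double> cc(9), nn(9);
  const double ln10 = std::log(10.0);
  for (int i = 0; i < P; ++i) {
    for (int v = 0; v < 9; ++v) {
      cc[v] = case_counts(i, v); nn[v] = ctrl_counts(i, v);
    }
    double lp; int hm, go; double orv;
    gss_one(cc.data(), nn.data(), lp, hm, go, orv);
    log10_p[i] = lp / ln10;
    hr_mask[i] = hm; gain_over[i] = go; or_gss[i] = orv;
  }
  return List::create(_["log10_p"] = log10_p, _["hr_mask"] = hr_mask,
                      _["gain_over"] = gain_over, _["or_gss"] = or_gss);
}

// ---------------------------------------------------------------------
// L1-penalized squared hinge loss, cyclic proximal coordinate descent:
//   min 1/(2N) sum_i max(0, 1 - y_i (x_i'b + b0))^2 + lambda ||b||_1
// Each coordinate step uses the curvature bound L_j = (1/N) sum x_ij^2
// (the active-set curvature never exceeds it), so the objective is
// non-increasing.
// ---------------------------------------------------------------------

// [[Rcpp::export(name = ".l1_hinge_cd_cpp")]]
List l1_hinge_cd_cpp(NumericMatrix X, NumericVector y, double lambda,
                     NumericVector beta_init, double beta0_init,
                     double tol = 1e-6, int max_iter = 10000) {
  const int N = X.nrow(), p = X.ncol();
  std::vector<double> beta(beta_init.begin(), beta_init.end());
  double beta0 = beta0_init;
  std::vector<double> f(N, beta0);     // linear scores
  for (int j = 0; j < p; ++j) {
    if (beta[j] != 0.0)
      for (int i = 0; i < N; ++i) f[i] += X(i, j) * beta[j];
  }
  std::vector<double> L(p, 0.0);
  for (int j = 0; j < p; ++j) {
    double s = 0;
    for (int i = 0; i < N; ++i) s += X(i, j) * X(i, j);
    L[j] = s / N;
  }
  bool converged = false;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    double max_delta = 0.0;
    // intercept (unpenalized, curvature bound 1)
    double g0 = 0;
    for (int i = 0; i < N; ++i) {
      double r = 1.0 - y[i] * f[i];
      if (r > 0) g0 -= r * y[i];
    }
    g0 /= N;
    double d0 = -g0;
    if (d0 != 0.0) {
      beta0 += d0;
      for (int i = 0; i < N; ++i) f[i] += d0;
      max_delta = std::max(max_delta, std::fabs(d0));
    }
    for (int j = 0; j < p; ++j) {
      if (L[j] == 0.0) continue;
      double g = 0;
      for (int i = 0; i < N; ++i) {
        double r = 1.0 - y[i] * f[i];
        if (r > 0) g -= r * y[i] * X(i, j);
      }
      g /= N;
      double z = beta[j] - g / L[j];
      double thr = lambda / L[j];
      double nb = (z > thr) ? z - thr : ((z < -thr) ? z + thr : 0.0);
      double d = nb - beta[j];
      if (d != 0.0) {
        beta[j] = nb;
        for (int i = 0; i < N; ++i) f[i] += X(i, j) * d;
        max_delta = std::max(max_delta, std::fabs(d));
      }
    }
    if (max_delta < tol) { converged = true; ++it; break; }
  }
  return List::create(_["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["beta0"] = beta0, _["iterations"] = it,
                      _["converged"] = converged);
}
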