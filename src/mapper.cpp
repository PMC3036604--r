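// Correspondence search and weighted rigid superposition for pharmacophore
// fit scoring. Hypotheses carry at most 5 features, so the injective
// kind-compatible assignment search with pairwise-distance pruning stays
// small; the weighted Kabsch solve is a 3x3 SVD.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Weighted Kabsch: proper rotation R (det +1) and translation t minimising
// sum_i w_i ||R p_i + t - q_i||^2. P, Q are k x 3.
static void kabsch_core(const arma::mat& P, const arma::mat& Q,
                        const arma::vec& w, arma::mat& R, arma::vec& t) {
  const double W = arma::accu(w);
  arma::rowvec p0 = (w.t() * P) / W;
  arma::rowvec q0 = (w.t() * Q) / W;
  R.eye(3, 3);
  if (P.n_rows > 1) {
    arma::mat Pc = P.each_row() - p0;
    arma::mat Qc = Q.each_row() - q0;
    arma::mat H = Pc.t() * arma::diagmat(w) * Qc; // 3 x 3
    arma::mat U, V;
    arma::vec s;
    if (arma::svd(U, s, V, H, "std")) {
      double d = arma::det(V * U.t());
      arma::mat D = arma::eye(3, 3);
      D(2, 2) = (d < 0.0) ? -1.0 : 1.0;
      R = V * D * U.t();
    }
  }
  t = q0.t() - R * p0.t();
}

// Eigenvalues of a symmetric 3x3 matrix, descending (analytic, trig form).
static void sym3_eigenvalues(const double A[3][3], double ev[3]) {
  const double p1 = A[0][1] * A[0][1] + A[0][2] * A[0][2] +
                    A[1][2] * A[1][2];
  const double q = (A[0][0] + A[1][1] + A[2][2]) / 3.0;
  if (p1 < 1e-24) {
    ev[0] = std::max({A[0][0], A[1][1], A[2][2]});
    ev[2] = std::min({A[0][0], A[1][1], A[2][2]});
    ev[1] = 3.0 * q - ev[0] - ev[2];
    return;
  }
  const double b00 = A[0][0] - q, b11 = A[1][1] - q, b22 = A[2][2] - q;
  const double p2 = b00 * b00 + b11 * b11 + b22 * b22 + 2.0 * p1;
  const double p = std::sqrt(p2 / 6.0);
  // det(B) / 2 with B = (A - qI) / p
  const double c00 = b00 / p, c11 = b11 / p, c22 = b22 / p;
  const double c01 = A[0][1] / p, c02 = A[0][2] / p, c12 = A[1][2] / p;
  double detB = c00 * (c11 * c22 - c12 * c12) -
                c01 * (c01 * c22 - c12 * c02) +
                c02 * (c01 * c12 - c11 * c02);
  double r = detB / 2.0;
  if (r < -1.0) r = -1.0;
  if (r > 1.0) r = 1.0;
  const double phi = std::acos(r) / 3.0;
  ev[0] = q + 2.0 * p * std::cos(phi);
  ev[2] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
  ev[1] = 3.0 * q - ev[0] - ev[2];
}

// Minimum weighted SSD over all proper rigid transforms (no rotation
// matrix recovered): sum w (|pc|^2 + |qc|^2) - 2 (s1 + s2 +/- s3), with
// singular values of the weighted covariance and the sign fixed by its
// determinant.
static double min_wssd(const double* Pp, const double* Qp, const double* wp,
                       int k) {
  double W = 0, p0[3] = {0, 0, 0}, q0[3] = {0, 0, 0};
  for (int i = 0; i < k; ++i) {
    W += wp[i];
    for (int d = 0; d < 3; ++d) {
      p0[d] += wp[i] * Pp[3 * i + d];
      q0[d] += wp[i] * Qp[3 * i + d];
    }
  }
  for (int d = 0; d < 3; ++d) { p0[d] /= W; q0[d] /= W; }
  double H[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
  double Sp = 0, Sq = 0;
  for (int i = 0; i < k; ++i) {
    double pc[3], qc[3];
    for (int d = 0; d < 3; ++d) {
      pc[d] = Pp[3 * i + d] - p0[d];
      qc[d] = Qp[3 * i + d] - q0[d];
      Sp += wp[i] * pc[d] * pc[d];
      Sq += wp[i] * qc[d] * qc[d];
    }
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b)
        H[a][b] += wp[i] * pc[a] * qc[b];
  }
  const double detH =
    H[0][0] * (H[1][1] * H[2][2] - H[1][2] * H[2][1]) -
    H[0][1] * (H[1][0] * H[2][2] - H[1][2] * H[2][0]) +
    H[0][2] * (H[1][0] * H[2][1] - H[1][1] * H[2][0]);
  double M[3][3];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b)
      M[a][b] = H[0][a] * H[0][b] + H[1][a] * H[1][b] + H[2][a] * H[2][b];
  double ev[3];
  sym3_eigenvalues(M, ev);
  double s1 = std::sqrt(std::max(0.0, ev[0]));
  double s2 = std::sqrt(std::max(0.0, ev[1]));
  double s3 = std::sqrt(std::max(0.0, ev[2]));
  double tr = (detH < 0.0) ? (s1 + s2 - s3) : (s1 + s2 + s3);
  return std::max(0.0, Sp + Sq - 2.0 * tr);
}

// [[Rcpp::export]]
List cpp_kabsch(const arma::mat& P, const arma::mat& Q, const arma::vec& w) {
  arma::mat R;
  arma::vec t;
  kabsch_core(P, Q, w, R, t);
  arma::mat Pt = P * R.t();
  Pt.each_row() += t.t();
  arma::vec d2 = arma::sum(arma::square(Pt - Q), 1);
  double rmsd = std::sqrt(arma::dot(w, d2) / arma::accu(w));
  return List::create(_["rotation"] = R, _["translation"] = t,
                      _["rmsd"] = rmsd,
                      _["distances"] = arma::sqrt(d2));
}

struct MapBest {
  bool found = false;
  double fit = -1.0;
  double rmsd = R_PosInf;
  std::vector<int> assign; // length m, -1 = omitted, else 0-based point idx
  arma::mat R;
  arma::vec t;
  // best infeasible candidate (smallest max displacement/tolerance ratio)
  bool inf_found = false;
  double inf_ratio = R_PosInf;
  std::vector<int> inf_assign;
};

// -1 keeps a; +1 keeps b; 0 tie
static int cmp_assign(const std::vector<int>& a, const std::vector<int>& b) {
  for (size_t i = 0; i < a.size(); ++i) {
    if (a[i] != b[i]) return a[i] < b[i] ? -1 : +1;
  }
  return 0;
}

class Mapper {
public:
  const arma::mat& C;        // m x 3 feature centers
  const arma::vec& tol, &wt;
  const arma::ivec& kh, &kp;
  const arma::mat& P;        // n x 3 candidate points
  arma::mat Dh, Dp;          // pairwise distances
  int m, n;
  double slack;
  bool first_only = false; // existence check: stop at first feasible leaf
  bool stop = false;
  MapBest best;

  Mapper(const arma::mat& C_, const arma::vec& tol_, const arma::vec& wt_,
         const arma::ivec& kh_, const arma::mat& P_, const arma::ivec& kp_,
         double slack_)
    : C(C_), tol(tol_), wt(wt_), kh(kh_), kp(kp_), P(P_), slack(slack_) {
    m = C.n_rows;
    n = P.n_rows;
    Dh.set_size(m, m);
    for (int i = 0; i < m; ++i)
      for (int j = 0; j < m; ++j)
        Dh(i, j) = arma::norm(C.row(i) - C.row(j), 2);
    Dp.set_size(n, n);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        Dp(i, j) = arma::norm(P.row(i) - P.row(j), 2);
  }

  void evaluate(const std::vector<int>& keep, const std::vector<int>& assign) {
    const int k = keep.size();
    arma::mat Pk(k, 3), Qk(k, 3);
    arma::vec wk(k);
    for (int i = 0; i < k; ++i) {
      Pk.row(i) = C.row(keep[i]);
      Qk.row(i) = P.row(assign[keep[i]]);
      wk(i) = wt(keep[i]);
    }
    arma::mat R;
    arma::vec t;
    kabsch_core(Pk, Qk, wk, R, t);
    arma::mat Ck = Pk * R.t();
    Ck.each_row() += t.t();
    arma::vec d = arma::sqrt(arma::sum(arma::square(Ck - Qk), 1));
    double maxratio = 0.0, fit = 0.0, ss = 0.0;
    for (int i = 0; i < k; ++i) {
      double r = d(i) / tol(keep[i]);
      if (r > maxratio) maxratio = r;
      double term = 1.0 - r * r;
      fit += wk(i) * (term > 0.0 ? term : 0.0);
      ss += wk(i) * d(i) * d(i);
    }
    double rmsd = std::sqrt(ss / arma::accu(wk));
    if (maxratio <= 1.0 + slack) {
      bool better = false;
      if (!best.found) better = true;
      else if (fit > best.fit + 1e-12) better = true;
      else if (std::fabs(fit - best.fit) <= 1e-12) {
        if (rmsd < best.rmsd - 1e-12) better = true;
        else if (std::fabs(rmsd - best.rmsd) <= 1e-12 &&
                 cmp_assign(assign, best.assign) < 0) better = true;
      }
      if (better) {
        best.found = true;
        best.fit = fit;
        best.rmsd = rmsd;
        best.assign = assign;
        best.R = R;
        best.t = t;
      }
      if (first_only) stop = true;
    } else if (maxratio < best.inf_ratio) {
      best.inf_found = true;
      best.inf_ratio = maxratio;
      best.inf_assign = assign;
    }
  }

  // Branch-and-bound prune for partial assignments (>= 3 points): the
  // weighted SSD of the subset under its own optimal superposition lower-
  // bounds the SSD of any completion, so it caps the attainable fit and
  // certifies infeasibility (every feasible leaf has sum w (d/tol)^2 <=
  // sum w).
  bool prune_partial(const std::vector<int>& keep, size_t pos,
                     const std::vector<int>& assign, double w_total) {
    const size_t c = pos + 1;
    if (c < 3) return false;
    double Pk[24], Qk[24], wk[8];
    double maxtol2 = 0.0, w_sub = 0.0;
    for (size_t i = 0; i < c; ++i) {
      const int f = keep[i];
      for (int d = 0; d < 3; ++d) {
        Pk[3 * i + d] = C(f, d);
        Qk[3 * i + d] = P(assign[f], d);
      }
      wk[i] = wt(f);
      w_sub += wt(f);
      if (tol(f) * tol(f) > maxtol2) maxtol2 = tol(f) * tol(f);
    }
    double wssd = min_wssd(Pk, Qk, wk, (int)c);
    double norm_lb = wssd / maxtol2; // <= min over transforms of sum w (d/tol)^2
    if (norm_lb > w_sub + slack) return true;          // infeasible
    if (best.found && w_total - norm_lb < best.fit - 1e-9) return true;
    return false;
  }

  void dfs(const std::vector<int>& keep, size_t pos, std::vector<int>& assign,
           std::vector<bool>& used, double w_total) {
    if (pos == keep.size()) {
      evaluate(keep, assign);
      return;
    }
    const int f = keep[pos];
    for (int p = 0; p < n && !stop; ++p) {
      if (used[p] || kp(p) != kh(f)) continue;
      bool ok = true;
      for (size_t q = 0; q < pos && ok; ++q) {
        const int g = keep[q];
        if (std::fabs(Dh(f, g) - Dp(p, assign[g])) > tol(f) + tol(g) + slack)
          ok = false;
      }
      if (!ok) continue;
      assign[f] = p;
      if (!prune_partial(keep, pos, assign, w_total)) {
        used[p] = true;
        dfs(keep, pos + 1, assign, used, w_total);
        used[p] = false;
      }
      assign[f] = -1;
    }
  }

  void subsets(int omit) {
    const int k = m - omit;
    if (k < 1 || stop) return;
    std::vector<int> idx(k);
    for (int i = 0; i < k; ++i) idx[i] = i;
    while (!stop) {
      std::vector<int> assign(m, -1);
      std::vector<bool> used(n, false);
      double w_total = 0.0;
      for (int i = 0; i < k; ++i) w_total += wt(idx[i]);
      dfs(idx, 0, assign, used, w_total);
      int i = k - 1;
      while (i >= 0 && idx[i] == m - k + i) --i;
      if (i < 0) break;
      ++idx[i];
      for (int j = i + 1; j < k; ++j) idx[j] = idx[j - 1] + 1;
    }
  }
};

// [[Rcpp::export]]
List cpp_map_points(const arma::mat& centers, const arma::vec& tol,
                    const arma::vec& wt, const arma::ivec& kind_h,
                    const arma::mat& pts, const arma::ivec& kind_p,
                    int max_omitted, double slack = 1e-9,
                    bool first_only = false) {
  Mapper mp(centers, tol, wt, kind_h, pts, kind_p, slack);
  mp.first_only = first_only;
  for (int omit = 0; omit <= max_omitted && omit < mp.m; ++omit)
    mp.subsets(omit);
  const MapBest& b = mp.best;
  IntegerVector assign(mp.m, NA_INTEGER);
  int omitted = 0;
  if (b.found) {
    for (int i = 0; i < mp.m; ++i) {
      if (b.assign[i] >= 0) assign[i] = b.assign[i] + 1;
      else ++omitted;
    }
  }
  IntegerVector inf_assign(mp.m, NA_INTEGER);
  if (b.inf_found) {
    for (int i = 0; i < mp.m; ++i)
      if (b.inf_assign[i] >= 0) inf_assign[i] = b.inf_assign[i] + 1;
  }
  return List::create(
    _["found"] = b.found,
    _["assignment"] = assign,
    _["fit"] = b.found ? b.fit : NA_REAL,
    _["rmsd"] = b.found ? b.rmsd : NA_REAL,
    _["omitted"] = b.found ? omitted : NA_INTEGER,
    _["rotation"] = b.found ? wrap(b.R) : R_NilValue,
    _["translation"] = b.found ? wrap(b.t) : R_NilValue,
    _["infeasible_assignment"] = inf_assign,
    _["infeasible_ratio"] = b.inf_found ? b.inf_ratio : NA_REAL);
}
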