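// Batch least-squares superposition kernels.  The average-reference build
// runs Kabsch fits over 1e5-1e6 pooled conformations and several passes;
// the 3x3 SVDs and data movement are done here to keep that interactive.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// proper rotation R minimizing ||P R - Q||_F given H = P^T Q (3x3)
static inline void kabsch_rot_from_H(const arma::mat33& H, arma::mat33& R) {
  arma::mat33 U, V;
  arma::vec3 s;
  arma::svd(U, s, V, H);
  if (arma::det(U * V.t()) < 0) U.col(2) *= -1.0;  // reflection guard
  R = U * V.t();
}

// conf: K x Np x 3 array (R layout); ref: Np x 3; sel: 1-based indices.
// Returns aligned conformations and per-conformation rmsd over sel.
// [[Rcpp::export]]
List batch_superpose(NumericVector conf, NumericMatrix ref, IntegerVector sel) {
  IntegerVector dims = conf.attr("dim");
  const int K = dims[0], Np = dims[1];
  const int ns = sel.size();
  const double* src = conf.begin();
  NumericVector out(clone(conf));
  double* dst = out.begin();
  NumericVector rmsd(K);
  const R_xlen_t plane = (R_xlen_t)K * Np;

  // centered reference selection, column-major [ns x 3]
  std::vector<double> q(ns * 3);
  double cm_q[3];
  for (int a = 0; a < 3; ++a) {
    double s_ = 0.0;
    for (int i = 0; i < ns; ++i) s_ += ref(sel[i] - 1, a);
    cm_q[a] = s_ / ns;
    for (int i = 0; i < ns; ++i) q[i + ns * a] = ref(sel[i] - 1, a) - cm_q[a];
  }

  std::vector<double> p(ns * 3), m(Np * 3);
  arma::mat33 H, R;
  for (int k = 0; k < K; ++k) {
    double cm_p[3];
    for (int a = 0; a < 3; ++a) {
      const double* col = src + (R_xlen_t)a * plane;
      double s_ = 0.0;
      for (int i = 0; i < ns; ++i) {
        double v = col[k + (R_xlen_t)K * (sel[i] - 1)];
        p[i + ns * a] = v;
        s_ += v;
      }
      cm_p[a] = s_ / ns;
      for (int i = 0; i < ns; ++i) p[i + ns * a] -= cm_p[a];
      for (int j = 0; j < Np; ++j) m[j + Np * a] = col[k + (R_xlen_t)K * j] - cm_p[a];
    }
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) {
        double s_ = 0.0;
        const double* pa = &p[ns * a];
        const double* qb = &q[ns * b];
        for (int i = 0; i < ns; ++i) s_ += pa[i] * qb[i];
        H(a, b) = s_;
      }
    kabsch_rot_from_H(H, R);
    // moved = m * R + cm_q; write back and accumulate rmsd over sel
    for (int a = 0; a < 3; ++a) {
      double* col = dst + (R_xlen_t)a * plane;
      for (int j = 0; j < Np; ++j) {
        double v = m[j] * R(0, a) + m[j + Np] * R(1, a) + m[j + 2 * Np] * R(2, a) + cm_q[a];
        col[k + (R_xlen_t)K * j] = v;
      }
    }
    double ss = 0.0;
    for (int i = 0; i < ns; ++i) {
      int j = sel[i] - 1;
      for (int a = 0; a < 3; ++a) {
        double v = m[j] * R(0, a) + m[j + Np] * R(1, a) + m[j + 2 * Np] * R(2, a);
        double d = v - q[i + ns * a];
        ss += d * d;
      }
    }
    rmsd[k] = std::sqrt(ss / ns);
  }
  return List::create(_["conformations"] = out, _["rmsd"] = rmsd);
}

// rmsd between paired conformations after optimal superposition.
// confA, confB: K x Np x 3 arrays; sel: 1-based particle indices.
// [[Rcpp::export]]
NumericVector batch_pair_rmsd(NumericVector confA, NumericVector confB,
                              IntegerVector sel, bool superpose) {
  IntegerVector dims = confA.attr("dim");
  const int K = dims[0], Np = dims[1];
  const int ns = sel.size();
  const double* a_ = confA.begin();
  const double* b_ = confB.begin();
  NumericVector rmsd(K);
  const R_xlen_t plane = (R_xlen_t)K * Np;
  std::vector<double> p(ns * 3), q(ns * 3);
  arma::mat33 H, R;
  for (int k = 0; k < K; ++k) {
    for (int a = 0; a < 3; ++a) {
      const double* ca = a_ + (R_xlen_t)a * plane;
      const double* cb = b_ + (R_xlen_t)a * plane;
      double sp = 0.0, sq = 0.0;
      for (int i = 0; i < ns; ++i) {
        p[i + ns * a] = ca[k + (R_xlen_t)K * (sel[i] - 1)];
        q[i + ns * a] = cb[k + (R_xlen_t)K * (sel[i] - 1)];
        sp += p[i + ns * a];
        sq += q[i + ns * a];
      }
      if (superpose) {
        sp /= ns; sq /= ns;
        for (int i = 0; i < ns; ++i) { p[i + ns * a] -= sp; q[i + ns * a] -= sq; }
      }
    }
    double ss = 0.0;
    if (superpose) {
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b) {
          double s_ = 0.0;
          for (int i = 0; i < ns; ++i) s_ += p[i + ns * a] * q[i + ns * b];
          H(a, b) = s_;
        }
      kabsch_rot_from_H(H, R);
      for (int i = 0; i < ns; ++i)
        for (int b = 0; b < 3; ++b) {
          double v = p[i] * R(0, b) + p[i + ns] * R(1, b) + p[i + 2 * ns] * R(2, b);
          double d = v - q[i + ns * b];
          ss += d * d;
        }
    } else {
      for (int i = 0; i < ns * 3; ++i) {
        double d = p[i] - q[i];
        ss += d * d;
      }
    }
    rmsd[k] = std::sqrt(ss / ns);
  }
  return rmsd;
}
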