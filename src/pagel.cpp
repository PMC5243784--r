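#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/Lapack.h>
#ifndef FCONE
#define FCONE
#endif
#include <complex>
using namespace Rcpp;

// Likelihood machinery for Pagel's correlated-evolution test: Felsenstein
// pruning over a 4-state joint Markov chain (two binary characters), with
// the matrix exponential computed by scaling-and-squaring plus a Taylor
// series (adequate and fast for 4x4 generators), and a compact Nelder-Mead
// optimiser over log-rates. The independent model factorises into two
// 2-state chains, which use the closed-form 2-state transition probabilities.
//
// Joint state coding: 0=(A0,B0), 1=(A0,B1), 2=(A1,B0), 3=(A1,B1).
// Dependent-model rate vector (8): qA01|B0, qA01|B1, qA10|B0, qA10|B1,
//                                  qB01|A0, qB01|A1, qB10|A0, qB10|A1.

static const double LOGRATE_LO = -18.0, LOGRATE_HI = 9.0;

static void build_q4(const double *r, double Q[4][4]) {
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) Q[i][j] = 0.0;
  Q[0][2] = r[0]; Q[1][3] = r[1];   // A 0->1 given B
  Q[2][0] = r[2]; Q[3][1] = r[3];   // A 1->0 given B
  Q[0][1] = r[4]; Q[2][3] = r[5];   // B 0->1 given A
  Q[1][0] = r[6]; Q[3][2] = r[7];   // B 1->0 given A
  for (int i = 0; i < 4; ++i) {
    double s = 0.0;
    for (int j = 0; j < 4; ++j) if (j != i) s += Q[i][j];
    Q[i][i] = -s;
  }
}

static void matmul4(const double A[4][4], const double B[4][4],
                    double C[4][4]) {
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) {
      double s = 0.0;
      for (int k = 0; k < 4; ++k) s += A[i][k] * B[k][j];
      C[i][j] = s;
    }
}

// P = exp(Q t) by scaling-and-squaring + Taylor to machine precision
static void expm4(const double Q[4][4], double t, double P[4][4]) {
  double A[4][4];
  double nrm = 0.0;
  for (int i = 0; i < 4; ++i) {
    double row = 0.0;
    for (int j = 0; j < 4; ++j) row += std::fabs(Q[i][j] * t);
    if (row > nrm) nrm = row;
  }
  int s = 0;
  double scale = 1.0;
  while (nrm * scale > 0.5) { scale *= 0.5; ++s; }
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) A[i][j] = Q[i][j] * t * scale;
  // Taylor: P = I + A + A^2/2! + ...
  double term[4][4], tmp[4][4];
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) {
      P[i][j] = (i == j) ? 1.0 : 0.0;
      term[i][j] = (i == j) ? 1.0 : 0.0;
    }
  for (int k = 1; k <= 24; ++k) {
    matmul4(term, A, tmp);
    double mx = 0.0;
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) {
        term[i][j] = tmp[i][j] / (double)k;
        P[i][j] += term[i][j];
        double a = std::fabs(term[i][j]);
        if (a > mx) mx = a;
      }
    if (mx < 1e-18) break;
  }
  while (s-- > 0) {
    matmul4(P, P, tmp);
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) P[i][j] = tmp[i][j];
  }
}

// stationary distribution of Q: solve pi Q = 0, sum(pi) = 1 (Gaussian
// elimination on the transposed system with the last row replaced)
static void stationary4(const double Q[4][4], double pi[4]) {
  double M[4][5];
  for (int i = 0; i < 4; ++i) {
    for (int j = 0; j < 4; ++j) M[i][j] = Q[j][i];  // Q^T pi = 0
    M[i][4] = 0.0;
  }
  for (int j = 0; j < 4; ++j) M[3][j] = 1.0;
  M[3][4] = 1.0;
  for (int c = 0; c < 4; ++c) {
    int piv = c;
    for (int r2 = c + 1; r2 < 4; ++r2)
      if (std::fabs(M[r2][c]) > std::fabs(M[piv][c])) piv = r2;
    if (std::fabs(M[piv][c]) < 1e-300) { for (int k = 0; k < 4; ++k) pi[k] = 0.25; return; }
    if (piv != c)
      for (int k = 0; k <= 4; ++k) std::swap(M[piv][k], M[c][k]);
    for (int r2 = 0; r2 < 4; ++r2) {
      if (r2 == c) continue;
      double f = M[r2][c] / M[c][c];
      for (int k = c; k <= 4; ++k) M[r2][k] -= f * M[c][k];
    }
  }
  double s = 0.0;
  for (int i = 0; i < 4; ++i) { pi[i] = M[i][4] / M[i][i]; if (pi[i] < 0) pi[i] = 0; s += pi[i]; }
  for (int i = 0; i < 4; ++i) pi[i] = (s > 0) ? pi[i] / s : 0.25;
}

// Eigendecomposition-based transition probabilities: decompose Q once per
// likelihood evaluation (LAPACK dgeev; generators are generally
// non-symmetric so eigenvalues/vectors may be complex), then each edge only
// needs P(t) = Re(V exp(D t) V^-1). Falls back to scaling-and-squaring when
// Q is numerically defective.
struct EigQ {
  std::complex<double> V[4][4], Vinv[4][4], lam[4];
  double Q[4][4];
  bool ok;
};

static bool cinv4(const std::complex<double> A[4][4],
                  std::complex<double> out[4][4]) {
  std::complex<double> M[4][8];
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) {
      M[i][j] = A[i][j];
      M[i][4 + j] = (i == j) ? 1.0 : 0.0;
    }
  for (int c = 0; c < 4; ++c) {
    int piv = c;
    for (int r = c + 1; r < 4; ++r)
      if (std::abs(M[r][c]) > std::abs(M[piv][c])) piv = r;
    if (std::abs(M[piv][c]) < 1e-10) return false;
    if (piv != c)
      for (int k = 0; k < 8; ++k) std::swap(M[piv][k], M[c][k]);
    std::complex<double> d = M[c][c];
    for (int k = 0; k < 8; ++k) M[c][k] /= d;
    for (int r = 0; r < 4; ++r) {
      if (r == c) continue;
      std::complex<double> f = M[r][c];
      if (f == std::complex<double>(0.0)) continue;
      for (int k = c; k < 8; ++k) M[r][k] -= f * M[c][k];
    }
  }
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) out[i][j] = M[i][4 + j];
  return true;
}

static void eig_setup(const double Q[4][4], EigQ &E) {
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) E.Q[i][j] = Q[i][j];
  double A[16], wr[4], wi[4], vr[16], work[136];
  for (int j = 0; j < 4; ++j)
    for (int i = 0; i < 4; ++i) A[j * 4 + i] = Q[i][j];   // column-major
  int n = 4, lwork = 136, info = 0;
  F77_CALL(dgeev)("N", "V", &n, A, &n, wr, wi, (double *)0, &n, vr, &n,
                  work, &lwork, &info FCONE FCONE);
  if (info != 0) { E.ok = false; return; }
  for (int j = 0; j < 4; ++j) {
    if (wi[j] > 0.0) {
      for (int i = 0; i < 4; ++i) {
        E.V[i][j] = std::complex<double>(vr[j * 4 + i], vr[(j + 1) * 4 + i]);
        E.V[i][j + 1] = std::conj(E.V[i][j]);
      }
      E.lam[j] = std::complex<double>(wr[j], wi[j]);
      E.lam[j + 1] = std::conj(E.lam[j]);
      ++j;
    } else if (wi[j] == 0.0) {
      for (int i = 0; i < 4; ++i)
        E.V[i][j] = std::complex<double>(vr[j * 4 + i], 0.0);
      E.lam[j] = std::complex<double>(wr[j], 0.0);
    }
  }
  if (!cinv4(E.V, E.Vinv)) { E.ok = false; return; }
  // residual check: V diag(lam) Vinv must reproduce Q
  double err = 0.0, nrm = 0.0;
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) {
      std::complex<double> s = 0.0;
      for (int k = 0; k < 4; ++k) s += E.V[i][k] * E.lam[k] * E.Vinv[k][j];
      err = std::max(err, std::abs(s - std::complex<double>(Q[i][j])));
      nrm = std::max(nrm, std::fabs(Q[i][j]));
    }
  E.ok = err <= 1e-9 * (1.0 + nrm);
}

static void trans_prob(const EigQ &E, double t, double P[4][4]) {
  if (!E.ok) { expm4(E.Q, t, P); return; }
  std::complex<double> ed[4];
  for (int k = 0; k < 4; ++k) ed[k] = std::exp(E.lam[k] * t);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) {
      std::complex<double> s = 0.0;
      for (int k = 0; k < 4; ++k) s += E.V[i][k] * ed[k] * E.Vinv[k][j];
      double v = s.real();
      P[i][j] = (v > 0.0) ? v : 0.0;
    }
}

struct TreeData {
  std::vector<int> anc, des;      // postorder, 0-based node ids
  std::vector<double> blen;
  int ntot, root;
};

static TreeData make_treedata(const IntegerMatrix &edge,
                              const NumericVector &blen, int ntot) {
  TreeData td;
  int ne = edge.nrow();
  td.anc.resize(ne); td.des.resize(ne); td.blen.resize(ne);
  for (int e = 0; e < ne; ++e) {
    td.anc[e] = edge(e, 0) - 1;
    td.des[e] = edge(e, 1) - 1;
    td.blen[e] = blen[e];
  }
  td.ntot = ntot;
  td.root = td.anc[ne - 1];
  return td;
}

// 4-state pruning log-likelihood; states: 0..3 at tips, -1 internal
static double loglik4(const TreeData &td, const IntegerVector &states,
                      const double *rates, int root_type) {
  double Q[4][4];
  build_q4(rates, Q);
  EigQ E;
  eig_setup(Q, E);
  std::vector<double> part(4 * td.ntot);
  for (int i = 0; i < td.ntot; ++i) {
    if (states[i] >= 0) {
      for (int k = 0; k < 4; ++k) part[4 * i + k] = (k == states[i]) ? 1.0 : 0.0;
    } else {
      for (int k = 0; k < 4; ++k) part[4 * i + k] = 1.0;
    }
  }
  double logscale = 0.0;
  double P[4][4];
  for (size_t e = 0; e < td.anc.size(); ++e) {
    int a = td.anc[e], d = td.des[e];
    trans_prob(E, td.blen[e], P);
    double msg[4];
    for (int i = 0; i < 4; ++i) {
      double s = 0.0;
      for (int j = 0; j < 4; ++j) s += P[i][j] * part[4 * d + j];
      msg[i] = s;
    }
    double mx = 0.0;
    for (int i = 0; i < 4; ++i) {
      part[4 * a + i] *= msg[i];
      if (part[4 * a + i] > mx) mx = part[4 * a + i];
    }
    if (mx > 0 && mx < 1e-200) {
      for (int i = 0; i < 4; ++i) part[4 * a + i] /= mx;
      logscale += std::log(mx);
    }
  }
  double pi[4];
  if (root_type == 1) { for (int i = 0; i < 4; ++i) pi[i] = 0.25; }
  else stationary4(Q, pi);
  double lik = 0.0;
  for (int i = 0; i < 4; ++i) lik += pi[i] * part[4 * td.root + i];
  if (lik <= 0.0) return -1e300;
  return std::log(lik) + logscale;
}

// 2-state pruning log-likelihood with analytic P(t)
static double loglik2(const TreeData &td, const IntegerVector &states,
                      double q01, double q10, int root_type) {
  double q = q01 + q10;
  double pi1 = (q > 0) ? q01 / q : 0.5, pi0 = 1.0 - pi1;
  std::vector<double> p0(td.ntot), p1(td.ntot);
  for (int i = 0; i < td.ntot; ++i) {
    if (states[i] == 0) { p0[i] = 1.0; p1[i] = 0.0; }
    else if (states[i] == 1) { p0[i] = 0.0; p1[i] = 1.0; }
    else { p0[i] = 1.0; p1[i] = 1.0; }
  }
  double logscale = 0.0;
  for (size_t e = 0; e < td.anc.size(); ++e) {
    int a = td.anc[e], d = td.des[e];
    double w = std::exp(-q * td.blen[e]);
    double P00 = pi0 + pi1 * w, P01 = pi1 * (1.0 - w);
    double P10 = pi0 * (1.0 - w), P11 = pi1 + pi0 * w;
    double m0 = P00 * p0[d] + P01 * p1[d];
    double m1 = P10 * p0[d] + P11 * p1[d];
    p0[a] *= m0; p1[a] *= m1;
    double mx = (p0[a] > p1[a]) ? p0[a] : p1[a];
    if (mx > 0 && mx < 1e-200) {
      p0[a] /= mx; p1[a] /= mx;
      logscale += std::log(mx);
    }
  }
  double r0 = (root_type == 1) ? 0.5 : pi0;
  double r1 = (root_type == 1) ? 0.5 : pi1;
  double lik = r0 * p0[td.root] + r1 * p1[td.root];
  if (lik <= 0.0) return -1e300;
  return std::log(lik) + logscale;
}

// ---- Nelder-Mead over log-rates (minimising the negative log-likelihood,
// with a soft quadratic penalty outside the log-rate box) ------------------

template <typename F>
static double penalised(F &f, std::vector<double> &x) {
  double pen = 0.0;
  std::vector<double> xc(x);
  for (size_t i = 0; i < x.size(); ++i) {
    if (xc[i] < LOGRATE_LO) { pen += 1e3 * (LOGRATE_LO - xc[i]) * (LOGRATE_LO - xc[i]); xc[i] = LOGRATE_LO; }
    if (xc[i] > LOGRATE_HI) { pen += 1e3 * (xc[i] - LOGRATE_HI) * (xc[i] - LOGRATE_HI); xc[i] = LOGRATE_HI; }
  }
  return f(xc) + pen;
}

template <typename F>
static double nelder_mead(F f, std::vector<double> &x, int maxit,
                          double tol) {
  const int d = (int)x.size();
  const double a = 1.0, g = 2.0, r = 0.5, s = 0.5;
  std::vector<std::vector<double> > S(d + 1, x);
  std::vector<double> fv(d + 1);
  for (int i = 1; i <= d; ++i) S[i][i - 1] += 0.6;
  for (int i = 0; i <= d; ++i) fv[i] = penalised(f, S[i]);
  for (int it = 0; it < maxit; ++it) {
    // order
    std::vector<int> idx(d + 1);
    for (int i = 0; i <= d; ++i) idx[i] = i;
    std::sort(idx.begin(), idx.end(),
              [&](int i, int j) { return fv[i] < fv[j]; });
    std::vector<std::vector<double> > S2(d + 1);
    std::vector<double> fv2(d + 1);
    for (int i = 0; i <= d; ++i) { S2[i] = S[idx[i]]; fv2[i] = fv[idx[i]]; }
    S = S2; fv = fv2;
    if (fv[d] - fv[0] < tol) break;
    std::vector<double> cen(d, 0.0);
    for (int i = 0; i < d; ++i) {
      for (int j = 0; j < d; ++j) cen[j] += S[i][j];
    }
    for (int j = 0; j < d; ++j) cen[j] /= d;
    std::vector<double> xr(d);
    for (int j = 0; j < d; ++j) xr[j] = cen[j] + a * (cen[j] - S[d][j]);
    double fr = penalised(f, xr);
    if (fr < fv[0]) {
      std::vector<double> xe(d);
      for (int j = 0; j < d; ++j) xe[j] = cen[j] + g * (xr[j] - cen[j]);
      double fe = penalised(f, xe);
      if (fe < fr) { S[d] = xe; fv[d] = fe; }
      else { S[d] = xr; fv[d] = fr; }
    } else if (fr < fv[d - 1]) {
      S[d] = xr; fv[d] = fr;
    } else {
      std::vector<double> xc(d);
      for (int j = 0; j < d; ++j) xc[j] = cen[j] + r * (S[d][j] - cen[j]);
      double fc = penalised(f, xc);
      if (fc < fv[d]) { S[d] = xc; fv[d] = fc; }
      else {
        for (int i = 1; i <= d; ++i) {
          for (int j = 0; j < d; ++j)
            S[i][j] = S[0][j] + s * (S[i][j] - S[0][j]);
          fv[i] = penalised(f, S[i]);
        }
      }
    }
  }
  int best = 0;
  for (int i = 1; i <= d; ++i) if (fv[i] < fv[best]) best = i;
  x = S[best];
  for (size_t i = 0; i < x.size(); ++i) {
    if (x[i] < LOGRATE_LO) x[i] = LOGRATE_LO;
    if (x[i] > LOGRATE_HI) x[i] = LOGRATE_HI;
  }
  return fv[best];
}

// [[Rcpp::export]]
double pagel_loglik_cpp(IntegerMatrix edge, NumericVector blen,
                        IntegerVector states, NumericVector lograte8,
                        int root_type) {
  TreeData td = make_treedata(edge, blen, states.size());
  double r[8];
  for (int i = 0; i < 8; ++i) r[i] = std::exp(lograte8[i]);
  return loglik4(td, states, r, root_type);
}

// [[Rcpp::export]]
double mk2_loglik_cpp(IntegerMatrix edge, NumericVector blen,
                      IntegerVector states, NumericVector lograte2,
                      int root_type) {
  TreeData td = make_treedata(edge, blen, states.size());
  return loglik2(td, states, std::exp(lograte2[0]), std::exp(lograte2[1]),
                 root_type);
}

// [[Rcpp::export]]
List fit_mk2_cpp(IntegerMatrix edge, NumericVector blen, IntegerVector states,
                 NumericMatrix starts, int root_type, int maxit) {
  TreeData td = make_treedata(edge, blen, states.size());
  auto obj = [&](const std::vector<double> &x) {
    return -loglik2(td, states, std::exp(x[0]), std::exp(x[1]), root_type);
  };
  double bestf = 1e301;
  std::vector<double> bestx(2, 0.0);
  for (int s = 0; s < starts.nrow(); ++s) {
    std::vector<double> x(2);
    x[0] = starts(s, 0); x[1] = starts(s, 1);
    double fv = nelder_mead(obj, x, maxit, 1e-10);
    if (fv < bestf) { bestf = fv; bestx = x; }
  }
  double fv = nelder_mead(obj, bestx, maxit, 1e-12);   // polish
  if (fv < bestf) bestf = fv;
  return List::create(_["logL"] = -bestf,
                      _["logrates"] = NumericVector(bestx.begin(), bestx.end()));
}

// [[Rcpp::export]]
List fit_pagel_cpp(IntegerMatrix edge, NumericVector blen,
                   IntegerVector states, NumericMatrix starts, int root_type,
                   int maxit) {
  TreeData td = make_treedata(edge, blen, states.size());
  auto obj = [&](const std::vector<double> &x) {
    double r[8];
    for (int i = 0; i < 8; ++i) r[i] = std::exp(x[i]);
    return -loglik4(td, states, r, root_type);
  };
  double bestf = 1e301;
  std::vector<double> bestx(8, 0.0);
  for (int s = 0; s < starts.nrow(); ++s) {
    std::vector<double> x(8);
    for (int j = 0; j < 8; ++j) x[j] = starts(s, j);
    double fv = nelder_mead(obj, x, maxit, 1e-10);
    if (fv < bestf) { bestf = fv; bestx = x; }
  }
  double fv = nelder_mead(obj, bestx, maxit, 1e-12);   // polish
  if (fv < bestf) bestf = fv;
  return List::create(_["logL"] = -bestf,
                      _["logrates"] = NumericVector(bestx.begin(), bestx.end()));
}
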