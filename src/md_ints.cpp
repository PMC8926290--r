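// Gaussian integrals over contracted Cartesian shells (s, p, d) by the
// McMurchie-Davidson scheme: Hermite expansion coefficients E, Hermite
// Coulomb integrals R built on the Boys function.  All quantities in
// atomic units.  Cartesian component order within a shell: lx descending,
// then ly descending (s; x,y,z; xx,xy,xz,yy,yz,zz).
#include <RcppArmadillo.h>
#include <vector>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double PI = 3.14159265358979323846;

// ---------------------------------------------------------------- Boys F_m(T)
static void boys(int mmax, double T, double* F) {
  if (T < 1e-13) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0);
    return;
  }
  if (T > 35.0) {
    // upward recursion, exp(-T) negligible or harmless at these T
    F[0] = 0.5 * std::sqrt(PI / T);
    double eT = (T > 700.0) ? 0.0 : std::exp(-T);
    for (int m = 0; m < mmax; ++m) F[m + 1] = ((2 * m + 1) * F[m] - eT) / (2.0 * T);
    return;
  }
  // series for F_mmax, then downward recursion (stable)
  double eT = std::exp(-T);
  double denom = 2.0 * mmax + 1.0;
  double term = 1.0 / denom;
  double sum = term;
  for (int k = 1; k < 200; ++k) {
    denom += 2.0;
    term *= 2.0 * T / denom;
    sum += term;
    if (term < 1e-17 * sum) break;
  }
  F[mmax] = eT * sum;
  for (int m = mmax; m > 0; --m)
    F[m - 1] = (2.0 * T * F[m] + eT) / (2.0 * m - 1.0);
}

// ------------------------------------------------------- Hermite E coefficients
// E(i,j,t) for one Cartesian direction; includes the Gaussian product
// prefactor exp(-q Qx^2) in E(0,0,0).
struct ETable {
  // dims: (i <= la), (j <= lb), (t <= i+j); stored dense (la+1)*(lb+1)*(la+lb+1)
  int la, lb;
  std::vector<double> v;
  double& at(int i, int j, int t) { return v[(i * (lb + 1) + j) * (la + lb + 1) + t]; }
  double get(int i, int j, int t) const {
    if (t < 0 || t > i + j) return 0.0;
    return v[(i * (lb + 1) + j) * (la + lb + 1) + t];
  }
};

static void build_E(ETable& E, int la, int lb, double Qx, double a, double b) {
  E.la = la; E.lb = lb;
  E.v.assign((la + 1) * (lb + 1) * (la + lb + 1), 0.0);
  double p = a + b, q = a * b / p;
  E.at(0, 0, 0) = std::exp(-q * Qx * Qx);
  // increase i first (j = 0), X_PA = -(b/p) Qx
  double XPA = -(b / p) * Qx, XPB = (a / p) * Qx;
  for (int i = 1; i <= la; ++i)
    for (int t = 0; t <= i; ++t) {
      double val = 0.0;
      if (t > 0) val += E.get(i - 1, 0, t - 1) / (2.0 * p);
      val += XPA * E.get(i - 1, 0, t);
      val += (t + 1) * E.get(i - 1, 0, t + 1);
      E.at(i, 0, t) = val;
    }
  for (int j = 1; j <= lb; ++j)
    for (int i = 0; i <= la; ++i)
      for (int t = 0; t <= i + j; ++t) {
        double val = 0.0;
        if (t > 0) val += E.get(i, j - 1, t - 1) / (2.0 * p);
        val += XPB * E.get(i, j - 1, t);
        val += (t + 1) * E.get(i, j - 1, t + 1);
        E.at(i, j, t) = val;
      }
}

// ------------------------------------------------------------------ basis set
struct Shell {
  int l;
  double x, y, z;
  std::vector<double> exps;   // primitive exponents
  std::vector<double> coefs;  // contraction coefficients incl. primitive norms
  int ncart() const { return (l + 1) * (l + 2) / 2; }
};

static double dfact(int n) {  // (2n-1)!! with dfact(0)=1
  double r = 1.0;
  for (int k = 2 * n - 1; k > 1; k -= 2) r *= k;
  return r;
}

struct BasisSet {
  std::vector<Shell> shells;
  std::vector<int> off;                    // first basis-function index per shell
  std::vector<std::vector<double>> cfac;   // per-shell per-component norm factors
  int nbf;
  void finalize() {
    off.resize(shells.size());
    cfac.resize(shells.size());
    nbf = 0;
    for (size_t s = 0; s < shells.size(); ++s) {
      off[s] = nbf;
      nbf += shells[s].ncart();
      int l = shells[s].l;
      std::vector<double> f;
      for (int lx = l; lx >= 0; --lx)
        for (int ly = l - lx; ly >= 0; --ly) {
          int lz = l - lx - ly;
          f.push_back(std::sqrt(dfact(l) / (dfact(lx) * dfact(ly) * dfact(lz))));
        }
      cfac[s] = f;
    }
  }
};

// R basis representation: list(l=int vec, x=,y=,z=, nprim=int vec,
// pexp=list-flat double vec, pcoef=..., pstart=int vec 0-based)
static BasisSet basis_from_R(List b) {
  IntegerVector l = b["l"], nprim = b["nprim"], pstart = b["pstart"];
  NumericVector x = b["x"], y = b["y"], z = b["z"];
  NumericVector pexp = b["pexp"], pcoef = b["pcoef"];
  BasisSet bs;
  int ns = l.size();
  for (int s = 0; s < ns; ++s) {
    Shell sh;
    sh.l = l[s]; sh.x = x[s]; sh.y = y[s]; sh.z = z[s];
    for (int k = 0; k < nprim[s]; ++k) {
      sh.exps.push_back(pexp[pstart[s] + k]);
      sh.coefs.push_back(pcoef[pstart[s] + k]);
    }
    // primitive normalization for the (l,0,0) component
    for (size_t k = 0; k < sh.exps.size(); ++k) {
      double a = sh.exps[k];
      double nrm = std::pow(2.0 * a / PI, 0.75) *
                   std::sqrt(std::pow(4.0 * a, sh.l) / dfact(sh.l));
      sh.coefs[k] *= nrm;
    }
    // contracted normalization (same for every Cartesian component after
    // the per-component factors applied at evaluation time)
    double self = 0.0;
    for (size_t i = 0; i < sh.exps.size(); ++i)
      for (size_t j = 0; j < sh.exps.size(); ++j) {
        double p = sh.exps[i] + sh.exps[j];
        double s00 = std::pow(PI / p, 1.5) * dfact(sh.l) / std::pow(2.0 * p, sh.l);
        self += sh.coefs[i] * sh.coefs[j] * s00;
      }
    for (size_t k = 0; k < sh.coefs.size(); ++k) sh.coefs[k] /= std::sqrt(self);
    bs.shells.push_back(sh);
  }
  bs.finalize();
  return bs;
}

// enumerate Cartesian components of angular momentum l
static void comp_list(int l, std::vector<std::array<int,3>>& out) {
  out.clear();
  for (int lx = l; lx >= 0; --lx)
    for (int ly = l - lx; ly >= 0; --ly)
      out.push_back({lx, ly, l - lx - ly});
}

// ------------------------------------------------------------- one-electron
// generic driver over shell pairs of two (possibly different) basis sets
template <typename F>
static void for_shell_pairs(const BasisSet& A, const BasisSet& B, F f) {
  for (size_t sa = 0; sa < A.shells.size(); ++sa)
    for (size_t sb = 0; sb < B.shells.size(); ++sb) f(sa, sb);
}

// [[Rcpp::export]]
arma::mat cpp_overlap(List basisA, List basisB) {
  BasisSet A = basis_from_R(basisA), B = basis_from_R(basisB);
  arma::mat S(A.nbf, B.nbf, arma::fill::zeros);
  std::vector<std::array<int,3>> ca, cb;
  for_shell_pairs(A, B, [&](size_t sa, size_t sb) {
    const Shell& shA = A.shells[sa];
    const Shell& shB = B.shells[sb];
    comp_list(shA.l, ca); comp_list(shB.l, cb);
    double ABx = shA.x - shB.x, ABy = shA.y - shB.y, ABz = shA.z - shB.z;
    arma::mat blk(ca.size(), cb.size(), arma::fill::zeros);
    for (size_t i = 0; i < shA.exps.size(); ++i)
      for (size_t j = 0; j < shB.exps.size(); ++j) {
        double a = shA.exps[i], b = shB.exps[j], p = a + b;
        double cc = shA.coefs[i] * shB.coefs[j] * std::pow(PI / p, 1.5);
        ETable Ex, Ey, Ez;
        build_E(Ex, shA.l, shB.l, ABx, a, b);
        build_E(Ey, shA.l, shB.l, ABy, a, b);
        build_E(Ez, shA.l, shB.l, ABz, a, b);
        for (size_t u = 0; u < ca.size(); ++u)
          for (size_t v = 0; v < cb.size(); ++v)
            blk(u, v) += cc * Ex.get(ca[u][0], cb[v][0], 0) *
                              Ey.get(ca[u][1], cb[v][1], 0) *
                              Ez.get(ca[u][2], cb[v][2], 0);
      }
    for (size_t u = 0; u < ca.size(); ++u)
      for (size_t v = 0; v < cb.size(); ++v)
        S(A.off[sa] + u, B.off[sb] + v) = blk(u, v) * A.cfac[sa][u] * B.cfac[sb][v];
  });
  return S;
}

// 1D overlap from E table (includes exp prefactor), with sqrt(pi/p) factored out
static inline double s1d(const ETable& E, int i, int j) { return E.get(i, j, 0); }

// [[Rcpp::export]]
arma::mat cpp_kinetic(List basisA, List basisB) {
  BasisSet A = basis_from_R(basisA), B = basis_from_R(basisB);
  arma::mat T(A.nbf, B.nbf, arma::fill::zeros);
  std::vector<std::array<int,3>> ca, cb;
  for_shell_pairs(A, B, [&](size_t sa, size_t sb) {
    const Shell& shA = A.shells[sa];
    const Shell& shB = B.shells[sb];
    comp_list(shA.l, ca); comp_list(shB.l, cb);
    double AB[3] = {shA.x - shB.x, shA.y - shB.y, shA.z - shB.z};
    arma::mat blk(ca.size(), cb.size(), arma::fill::zeros);
    for (size_t i = 0; i < shA.exps.size(); ++i)
      for (size_t j = 0; j < shB.exps.size(); ++j) {
        double a = shA.exps[i], b = shB.exps[j], p = a + b;
        double cc = shA.coefs[i] * shB.coefs[j] * std::pow(PI / p, 1.5);
        ETable E[3];
        for (int d = 0; d < 3; ++d) build_E(E[d], shA.l, shB.l + 2, AB[d], a, b);
        for (size_t u = 0; u < ca.size(); ++u)
          for (size_t v = 0; v < cb.size(); ++v) {
            double Sd[3], Td[3];
            for (int d = 0; d < 3; ++d) {
              int ii = ca[u][d], jj = cb[v][d];
              Sd[d] = s1d(E[d], ii, jj);
              double t = -2.0 * b * b * s1d(E[d], ii, jj + 2) +
                         b * (2.0 * jj + 1.0) * s1d(E[d], ii, jj);
              if (jj >= 2) t -= 0.5 * jj * (jj - 1.0) * s1d(E[d], ii, jj - 2);
              Td[d] = t;
            }
            blk(u, v) += cc * (Td[0] * Sd[1] * Sd[2] + Sd[0] * Td[1] * Sd[2] +
                               Sd[0] * Sd[1] * Td[2]);
          }
      }
    for (size_t u = 0; u < ca.size(); ++u)
      for (size_t v = 0; v < cb.size(); ++v)
        T(A.off[sa] + u, B.off[sb] + v) = blk(u, v) * A.cfac[sa][u] * B.cfac[sb][v];
  });
  return T;
}

// Hermite Coulomb integrals R_{tuv} (n = 0 slice) for t+u+v <= L
struct RTable {
  int L;
  std::vector<double> v;  // (L+1)^3, indexed t*(L+1)^2 + u*(L+1) + w
  double get(int t, int u, int w) const {
    if (t < 0 || u < 0 || w < 0) return 0.0;
    return v[(t * (L + 1) + u) * (L + 1) + w];
  }
};

static void build_R(RTable& R, int L, double alpha, double X, double Y, double Z) {
  R.L = L;
  int n1 = L + 1;
  double T = alpha * (X * X + Y * Y + Z * Z);
  double F[24];
  boys(L, T, F);
  // Rn[n][t][u][v]; iterate n from L down to 0; scratch reused across calls
  static thread_local std::vector<double> cur, nxt;
  cur.assign(n1 * n1 * n1, 0.0);
  nxt.assign(n1 * n1 * n1, 0.0);
  auto idx = [n1](int t, int u, int w) { return (t * n1 + u) * n1 + w; };
  // start: n = L has only (0,0,0)
  for (int n = L; n >= 0; --n) {
    std::fill(nxt.begin(), nxt.end(), 0.0);
    nxt[idx(0, 0, 0)] = std::pow(-2.0 * alpha, n) * F[n];
    int maxo = L - n;  // max t+u+v at this level
    for (int t = 0; t <= maxo; ++t)
      for (int u = 0; u <= maxo - t; ++u)
        for (int w = 0; w <= maxo - t - u; ++w) {
          if (t + u + w == 0) continue;
          double val;
          if (t > 0) {
            val = X * cur[idx(t - 1, u, w)];
            if (t > 1) val += (t - 1) * cur[idx(t - 2, u, w)];
          } else if (u > 0) {
            val = Y * cur[idx(t, u - 1, w)];
            if (u > 1) val += (u - 1) * cur[idx(t, u - 2, w)];
          } else {
            val = Z * cur[idx(t, u, w - 1)];
            if (w > 1) val += (w - 1) * cur[idx(t, u, w - 2)];
          }
          nxt[idx(t, u, w)] = val;
        }
    std::swap(cur, nxt);
  }
  R.v.swap(cur);
}

// [[Rcpp::export]]
arma::mat cpp_nuclear(List basisA, List basisB, NumericVector Z, NumericMatrix coords) {
  // attraction matrix -sum_I Z_I <mu| 1/|r-R_I| |nu>, mu in A, nu in B
  BasisSet A = basis_from_R(basisA), B = basis_from_R(basisB);
  arma::mat V(A.nbf, B.nbf, arma::fill::zeros);
  std::vector<std::array<int,3>> ca, cb;
  int nq = Z.size();
  for_shell_pairs(A, B, [&](size_t sa, size_t sb) {
    const Shell& shA = A.shells[sa];
    const Shell& shB = B.shells[sb];
    comp_list(shA.l, ca); comp_list(shB.l, cb);
    int L = shA.l + shB.l;
    double AB[3] = {shA.x - shB.x, shA.y - shB.y, shA.z - shB.z};
    arma::mat blk(ca.size(), cb.size(), arma::fill::zeros);
    for (size_t i = 0; i < shA.exps.size(); ++i)
      for (size_t j = 0; j < shB.exps.size(); ++j) {
        double a = shA.exps[i], b = shB.exps[j], p = a + b;
        double Px = (a * shA.x + b * shB.x) / p;
        double Py = (a * shA.y + b * shB.y) / p;
        double Pz = (a * shA.z + b * shB.z) / p;
        double cc = shA.coefs[i] * shB.coefs[j] * 2.0 * PI / p;
        ETable E[3];
        for (int d = 0; d < 3; ++d) build_E(E[d], shA.l, shB.l, AB[d], a, b);
        for (int q = 0; q < nq; ++q) {
          RTable R;
          build_R(R, L, p, Px - coords(q, 0), Py - coords(q, 1), Pz - coords(q, 2));
          for (size_t u = 0; u < ca.size(); ++u)
            for (size_t v = 0; v < cb.size(); ++v) {
              double sum = 0.0;
              for (int t = 0; t <= ca[u][0] + cb[v][0]; ++t)
                for (int uu = 0; uu <= ca[u][1] + cb[v][1]; ++uu)
                  for (int w = 0; w <= ca[u][2] + cb[v][2]; ++w)
                    sum += E[0].get(ca[u][0], cb[v][0], t) *
                           E[1].get(ca[u][1], cb[v][1], uu) *
                           E[2].get(ca[u][2], cb[v][2], w) * R.get(t, uu, w);
              blk(u, v) -= Z[q] * cc * sum;
            }
        }
      }
    for (size_t u = 0; u < ca.size(); ++u)
      for (size_t v = 0; v < cb.size(); ++v)
        V(A.off[sa] + u, B.off[sb] + v) = blk(u, v) * A.cfac[sa][u] * B.cfac[sb][v];
  });
  return V;
}

// ----------------------------------------------------------------- ERI core
// precomputed primitive pair data for one shell pair
struct PairData {
  double p, Px, Py, Pz, cc;  // cc = cA*cB (primitive norms folded in)
  ETable Ex, Ey, Ez;
};

static void build_pairs(const Shell& A, const Shell& B, std::vector<PairData>& out,
                        double thresh) {
  out.clear();
  double AB[3] = {A.x - B.x, A.y - B.y, A.z - B.z};
  double r2 = AB[0]*AB[0] + AB[1]*AB[1] + AB[2]*AB[2];
  for (size_t i = 0; i < A.exps.size(); ++i)
    for (size_t j = 0; j < B.exps.size(); ++j) {
      double a = A.exps[i], b = B.exps[j], p = a + b, q = a * b / p;
      double pre = std::exp(-q * r2);
      double cc = A.coefs[i] * B.coefs[j];
      if (std::fabs(cc) * pre < thresh) continue;
      PairData pd;
      pd.p = p;
      pd.Px = (a * A.x + b * B.x) / p;
      pd.Py = (a * A.y + b * B.y) / p;
      pd.Pz = (a * A.z + b * B.z) / p;
      pd.cc = cc;
      build_E(pd.Ex, A.l, B.l, AB[0], a, b);
      build_E(pd.Ey, A.l, B.l, AB[1], a, b);
      build_E(pd.Ez, A.l, B.l, AB[2], a, b);
      out.push_back(pd);
    }
}

// compute shell-quartet ERI block (ab|cd); blk dims (na*nb, nc*nd)
static void eri_shell_quartet(const Shell& sA, const Shell& sB,
                              const std::vector<PairData>& bra,
                              const Shell& sC, const Shell& sD,
                              const std::vector<PairData>& ket,
                              arma::mat& blk) {
  static thread_local std::vector<std::array<int,3>> ca, cb, cc_, cd;
  comp_list(sA.l, ca); comp_list(sB.l, cb);
  comp_list(sC.l, cc_); comp_list(sD.l, cd);
  int nab = ca.size() * cb.size(), ncd = cc_.size() * cd.size();
  blk.zeros(nab, ncd);
  int Lb = sA.l + sB.l, Lk = sC.l + sD.l, L = Lb + Lk;
  RTable R;
  for (const PairData& P : bra) {
    for (const PairData& Q : ket) {
      double alpha = P.p * Q.p / (P.p + Q.p);
      double fac = P.cc * Q.cc * 2.0 * std::pow(PI, 2.5) /
                   (P.p * Q.p * std::sqrt(P.p + Q.p));
      build_R(R, L, alpha, P.Px - Q.Px, P.Py - Q.Py, P.Pz - Q.Pz);
      int ij = 0;
      for (size_t u = 0; u < ca.size(); ++u)
        for (size_t v = 0; v < cb.size(); ++v, ++ij) {
          int tx = ca[u][0] + cb[v][0], ty = ca[u][1] + cb[v][1],
              tz = ca[u][2] + cb[v][2];
          int kl = 0;
          for (size_t w = 0; w < cc_.size(); ++w)
            for (size_t x = 0; x < cd.size(); ++x, ++kl) {
              int sx = cc_[w][0] + cd[x][0], sy = cc_[w][1] + cd[x][1],
                  sz = cc_[w][2] + cd[x][2];
              double sum = 0.0;
              for (int t = 0; t <= tx; ++t) {
                double ex = P.Ex.get(ca[u][0], cb[v][0], t);
                if (ex == 0.0) continue;
                for (int uu = 0; uu <= ty; ++uu) {
                  double exy = ex * P.Ey.get(ca[u][1], cb[v][1], uu);
                  if (exy == 0.0) continue;
                  for (int ww = 0; ww <= tz; ++ww) {
                    double exyz = exy * P.Ez.get(ca[u][2], cb[v][2], ww);
                    if (exyz == 0.0) continue;
                    double inner = 0.0;
                    for (int tt = 0; tt <= sx; ++tt) {
                      double fx = Q.Ex.get(cc_[w][0], cd[x][0], tt);
                      if (fx == 0.0) continue;
                      for (int vv = 0; vv <= sy; ++vv) {
                        double fxy = fx * Q.Ey.get(cc_[w][1], cd[x][1], vv);
                        if (fxy == 0.0) continue;
                        for (int xx = 0; xx <= sz; ++xx) {
                          double fxyz = fxy * Q.Ez.get(cc_[w][2], cd[x][2], xx);
                          if (fxyz == 0.0) continue;
                          double sgn = ((tt + vv + xx) % 2) ? -1.0 : 1.0;
                          inner += sgn * fxyz * R.get(t + tt, uu + vv, ww + xx);
                        }
                      }
                    }
                    sum += exyz * inner;
                  }
                }
              }
              blk(ij, kl) += fac * sum;
            }
        }
    }
  }
}

static inline size_t ptri(size_t i, size_t j) {  // i >= j
  return i * (i + 1) / 2 + j;
}

// packed monomer ERI with 8-fold symmetry; index by composite pair indices
// [[Rcpp::export]]
NumericVector cpp_eri_packed(List basisA, double thresh = 1e-12) {
  BasisSet A = basis_from_R(basisA);
  size_t n = A.nbf, npair = n * (n + 1) / 2;
  NumericVector out(npair * (npair + 1) / 2);
  double* O = out.begin();
  size_t ns = A.shells.size();
  // precompute pair data + Schwarz bounds per shell pair (sa >= sb)
  std::vector<std::vector<PairData>> pairs(ns * (ns + 1) / 2);
  std::vector<double> schwarz(ns * (ns + 1) / 2);
  arma::mat blk;
  for (size_t sa = 0; sa < ns; ++sa)
    for (size_t sb = 0; sb <= sa; ++sb) {
      size_t sp = ptri(sa, sb);
      build_pairs(A.shells[sa], A.shells[sb], pairs[sp], thresh);
      eri_shell_quartet(A.shells[sa], A.shells[sb], pairs[sp],
                        A.shells[sa], A.shells[sb], pairs[sp], blk);
      schwarz[sp] = std::sqrt(std::max(0.0, blk.diag().max()));
    }
  std::vector<std::array<int,3>> cl;
  for (size_t sa = 0; sa < ns; ++sa)
    for (size_t sb = 0; sb <= sa; ++sb) {
      size_t spb = ptri(sa, sb);
      if (pairs[spb].empty()) continue;
      for (size_t sc = 0; sc <= sa; ++sc)
        for (size_t sd = 0; sd <= sc; ++sd) {
          size_t spk = ptri(sc, sd);
          if (spk > spb) continue;
          if (schwarz[spb] * schwarz[spk] < thresh) continue;
          if (pairs[spk].empty()) continue;
          eri_shell_quartet(A.shells[sa], A.shells[sb], pairs[spb],
                            A.shells[sc], A.shells[sd], pairs[spk], blk);
          int na = A.shells[sa].ncart(), nb = A.shells[sb].ncart();
          int nc = A.shells[sc].ncart(), nd = A.shells[sd].ncart();
          for (int u = 0; u < na; ++u)
            for (int v = 0; v < nb; ++v)
              for (int w = 0; w < nc; ++w)
                for (int x = 0; x < nd; ++x) {
                  size_t mu = A.off[sa] + u, nu = A.off[sb] + v;
                  size_t la = A.off[sc] + w, si = A.off[sd] + x;
                  if (mu < nu || la < si) continue;
                  size_t P = ptri(mu, nu), Q = ptri(la, si);
                  double val = blk(u * nb + v, w * nd + x) *
                               A.cfac[sa][u] * A.cfac[sb][v] *
                               A.cfac[sc][w] * A.cfac[sd][x];
                  // (mu nu|la si) = (la si|mu nu): store at canonical slot
                  O[(P >= Q) ? ptri(P, Q) : ptri(Q, P)] = val;
                }
        }
    }
  return out;
}

// J and K builds from a packed monomer ERI and a symmetric density matrix
// [[Rcpp::export]]
List cpp_fock_jk(NumericVector eri, arma::mat D) {
  size_t n = D.n_rows;
  arma::mat J(n, n, arma::fill::zeros), K(n, n, arma::fill::zeros);
  const double* E = eri.begin();
  for (size_t mu = 0; mu < n; ++mu)
    for (size_t nu = 0; nu <= mu; ++nu) {
      size_t P = ptri(mu, nu);
      for (size_t la = 0; la <= mu; ++la) {
        size_t simax = (la == mu) ? nu : la;
        for (size_t si = 0; si <= simax; ++si) {
          size_t Q = ptri(la, si);
          double v = E[ptri(P, Q)];
          if (v == 0.0) continue;
          // enumerate distinct index quadruples among the 8 permutations
          size_t quads[8][4] = {
            {mu, nu, la, si}, {nu, mu, la, si}, {mu, nu, si, la},
            {nu, mu, si, la}, {la, si, mu, nu}, {si, la, mu, nu},
            {la, si, nu, mu}, {si, la, nu, mu}};
          bool seen[8] = {false};
          for (int a = 0; a < 8; ++a) {
            bool dup = false;
            for (int b = 0; b < a; ++b)
              if (quads[a][0] == quads[b][0] && quads[a][1] == quads[b][1] &&
                  quads[a][2] == quads[b][2] && quads[a][3] == quads[b][3]) {
                dup = true; break;
              }
            seen[a] = dup;
            if (dup) continue;
            size_t aa = quads[a][0], bb = quads[a][1], cc = quads[a][2], dd = quads[a][3];
            J(aa, bb) += v * D(cc, dd);
            K(aa, cc) += v * D(bb, dd);
          }
          (void)seen;
        }
      }
    }
  return List::create(Named("J") = J, Named("K") = K);
}

// ------------------------------------------------- generalized MO-basis ERI
// (ij|kl) with each slot carrying its own basis and MO coefficient block.
// sym_bra: basis1 == basis2 and C1 == C2 (restrict mu >= nu, weight off-diag
// contributions to both orders); likewise sym_ket.
// [[Rcpp::export]]
NumericVector cpp_eri_mo(List basis1, arma::mat C1, List basis2, arma::mat C2,
                         List basis3, arma::mat C3, List basis4, arma::mat C4,
                         bool sym_bra, bool sym_ket, double thresh = 1e-12) {
  BasisSet B1 = basis_from_R(basis1), B2 = basis_from_R(basis2);
  BasisSet B3 = basis_from_R(basis3), B4 = basis_from_R(basis4);
  int m1 = C1.n_cols, m2 = C2.n_cols, m3 = C3.n_cols, m4 = C4.n_cols;
  // half-transformed buffer over bra AO pairs x (k,l) MO pairs
  size_t nao12 = (size_t)B1.nbf * B2.nbf;
  arma::mat half(nao12, (size_t)m3 * m4, arma::fill::zeros);

  // ket shell-pair data
  struct SP { size_t sc, sd; std::vector<PairData> pd; double qb; };
  std::vector<SP> ketp;
  {
    arma::mat blk;
    for (size_t sc = 0; sc < B3.shells.size(); ++sc) {
      size_t sd0 = 0, sd1 = B4.shells.size();
      for (size_t sd = sd0; sd < sd1; ++sd) {
        if (sym_ket && sd > sc) continue;
        SP sp; sp.sc = sc; sp.sd = sd;
        build_pairs(B3.shells[sc], B4.shells[sd], sp.pd, thresh);
        if (sp.pd.empty()) continue;
        eri_shell_quartet(B3.shells[sc], B4.shells[sd], sp.pd,
                          B3.shells[sc], B4.shells[sd], sp.pd, blk);
        sp.qb = std::sqrt(std::max(0.0, blk.diag().max()));
        ketp.push_back(sp);
      }
    }
  }
  arma::mat blk;
  for (size_t sa = 0; sa < B1.shells.size(); ++sa) {
    for (size_t sb = 0; sb < B2.shells.size(); ++sb) {
      if (sym_bra && sb > sa) continue;
      std::vector<PairData> bra;
      build_pairs(B1.shells[sa], B2.shells[sb], bra, thresh);
      if (bra.empty()) continue;
      eri_shell_quartet(B1.shells[sa], B2.shells[sb], bra,
                        B1.shells[sa], B2.shells[sb], bra, blk);
      double qbra = std::sqrt(std::max(0.0, blk.diag().max()));
      int na = B1.shells[sa].ncart(), nb = B2.shells[sb].ncart();
      for (const SP& sp : ketp) {
        if (qbra * sp.qb < thresh) continue;
        eri_shell_quartet(B1.shells[sa], B2.shells[sb], bra,
                          B3.shells[sp.sc], B4.shells[sp.sd], sp.pd, blk);
        int nc = B3.shells[sp.sc].ncart(), nd = B4.shells[sp.sd].ncart();
        for (int w = 0; w < nc; ++w)
          for (int x = 0; x < nd; ++x) {
            size_t la = B3.off[sp.sc] + w, si = B4.off[sp.sd] + x;
            if (sym_ket && sp.sc == sp.sd && (size_t)x > (size_t)w) continue;
            bool ket_dup = sym_ket && (la != si);
            for (int u = 0; u < na; ++u)
              for (int v = 0; v < nb; ++v) {
                size_t mu = B1.off[sa] + u, nu = B2.off[sb] + v;
                if (sym_bra && sa == sb && v > u) continue;
                double val = blk(u * nb + v, w * nd + x) *
                             B1.cfac[sa][u] * B2.cfac[sb][v] *
                             B3.cfac[sp.sc][w] * B4.cfac[sp.sd][x];
                if (val == 0.0) continue;
                // scatter into half[, (k,l)] with ket MO transform
                double* row = half.memptr() + (mu + nu * (size_t)B1.nbf);
                // contributions: (la,si) and, if duplicated, (si,la)
                for (int k = 0; k < m3; ++k) {
                  double c3a = C3(la, k), c3b = ket_dup ? C3(si, k) : 0.0;
                  if (c3a == 0.0 && c3b == 0.0) continue;
                  for (int l = 0; l < m4; ++l) {
                    double t = c3a * C4(si, l);
                    if (ket_dup) t += c3b * C4(la, l);
                    if (t == 0.0) continue;
                    row[((size_t)k + (size_t)l * m3) * nao12] += val * t;
                  }
                }
                if (sym_bra && mu != nu) {
                  double* row2 = half.memptr() + (nu + mu * (size_t)B1.nbf);
                  for (int k = 0; k < m3; ++k) {
                    double c3a = C3(la, k), c3b = ket_dup ? C3(si, k) : 0.0;
                    if (c3a == 0.0 && c3b == 0.0) continue;
                    for (int l = 0; l < m4; ++l) {
                      double t = c3a * C4(si, l);
                      if (ket_dup) t += c3b * C4(la, l);
                      if (t == 0.0) continue;
                      row2[((size_t)k + (size_t)l * m3) * nao12] += val * t;
                    }
                  }
                }
              }
          }
      }
    }
  }
  // bra transform: for each (k,l), C1^T M C2
  NumericVector out(Dimension(m1, m2, m3 * m4));
  arma::cube res((double*)out.begin(), m1, m2, (size_t)m3 * m4, false, true);
  for (size_t kl = 0; kl < (size_t)m3 * m4; ++kl) {
    arma::mat M(half.colptr(kl), B1.nbf, B2.nbf, false, true);
    res.slice(kl) = C1.t() * M * C2;
  }
  out.attr("dim") = IntegerVector::create(m1, m2, m3, m4);
  return out;
}

// direct generalized-Coulomb build: J[mu,mu'] = sum_{nu,nu'} (mu mu'|nu nu') D[nu,nu']
// bra AO pairs on basisA, ket AO pairs on basisB, D symmetric over basisB
// [[Rcpp::export]]
arma::mat cpp_cross_j(List basisA, List basisB, arma::mat D, double thresh = 1e-12) {
  BasisSet A = basis_from_R(basisA), B = basis_from_R(basisB);
  arma::mat J(A.nbf, A.nbf, arma::fill::zeros);
  size_t nsA = A.shells.size(), nsB = B.shells.size();
  arma::mat blk;
  // ket pair data
  struct SP { size_t sc, sd; std::vector<PairData> pd; double qb; };
  std::vector<SP> ketp;
  for (size_t sc = 0; sc < nsB; ++sc)
    for (size_t sd = 0; sd <= sc; ++sd) {
      SP sp; sp.sc = sc; sp.sd = sd;
      build_pairs(B.shells[sc], B.shells[sd], sp.pd, thresh);
      if (sp.pd.empty()) continue;
      eri_shell_quartet(B.shells[sc], B.shells[sd], sp.pd,
                        B.shells[sc], B.shells[sd], sp.pd, blk);
      sp.qb = std::sqrt(std::max(0.0, blk.diag().max()));
      ketp.push_back(sp);
    }
  for (size_t sa = 0; sa < nsA; ++sa)
    for (size_t sb = 0; sb <= sa; ++sb) {
      std::vector<PairData> bra;
      build_pairs(A.shells[sa], A.shells[sb], bra, thresh);
      if (bra.empty()) continue;
      eri_shell_quartet(A.shells[sa], A.shells[sb], bra,
                        A.shells[sa], A.shells[sb], bra, blk);
      double qbra = std::sqrt(std::max(0.0, blk.diag().max()));
      int na = A.shells[sa].ncart(), nb = A.shells[sb].ncart();
      for (const SP& sp : ketp) {
        if (qbra * sp.qb < thresh) continue;
        eri_shell_quartet(A.shells[sa], A.shells[sb], bra,
                          B.shells[sp.sc], B.shells[sp.sd], sp.pd, blk);
        int nc = B.shells[sp.sc].ncart(), nd = B.shells[sp.sd].ncart();
        for (int u = 0; u < na; ++u)
          for (int v = 0; v < nb; ++v) {
            size_t mu = A.off[sa] + u, nu = A.off[sb] + v;
            if (sa == sb && v > u) continue;
            double acc = 0.0;
            for (int w = 0; w < nc; ++w)
              for (int x = 0; x < nd; ++x) {
                size_t la = B.off[sp.sc] + w, si = B.off[sp.sd] + x;
                if (sp.sc == sp.sd && x > w) continue;
                double val = blk(u * nb + v, w * nd + x) *
                             A.cfac[sa][u] * A.cfac[sb][v] *
                             B.cfac[sp.sc][w] * B.cfac[sp.sd][x];
                double d = D(la, si);
                if (la != si) d += D(si, la);
                acc += val * d;
              }
            J(mu, nu) += acc;
            if (mu != nu) J(nu, mu) += acc;
          }
      }
    }
  return J;
}
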