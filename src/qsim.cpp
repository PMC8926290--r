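// Ideal real-arithmetic statevector simulation of an active space under the
// Jordan-Wigner encoding, plus determinant-space Slater-Condon machinery for
// CASCI.  Mode ordering is blocked alpha-then-beta: spin orbital (p, alpha)
// is qubit p, (p, beta) is qubit norb + p.  Basis state |bits> is the product
// of creation operators in increasing mode order applied to the vacuum, so
// the annihilator a_j picks up the parity of occupied modes below j.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline int popcnt(uint64_t x) {
#if defined(__GNUC__)
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

static inline double parity_below(uint64_t bits, int mode) {
  uint64_t mask = (mode == 0) ? 0ULL : ((1ULL << mode) - 1ULL);
  return (popcnt(bits & mask) % 2) ? -1.0 : 1.0;
}

// [[Rcpp::export]]
NumericVector cpp_sv_reference(int norb, int nalpha, int nbeta) {
  if (nalpha > norb || nbeta > norb || nalpha < 0 || nbeta < 0)
    stop("electron counts exceed orbital count");
  size_t dim = 1ULL << (2 * norb);
  NumericVector sv(dim);
  uint64_t a = (nalpha == 0) ? 0ULL : ((1ULL << nalpha) - 1ULL);
  uint64_t b = (nbeta == 0) ? 0ULL : ((1ULL << nbeta) - 1ULL);
  sv[a | (b << norb)] = 1.0;
  return sv;
}

// two-level rotation exp(theta (a^+_q a_p - a^+_p a_q)) applied for both
// spins (same angle); p, q are 0-based spatial orbital indices
// [[Rcpp::export]]
NumericVector cpp_apply_givens(NumericVector sv, int norb, int p, int q,
                               double theta) {
  NumericVector out = clone(sv);
  double c = std::cos(theta), s = std::sin(theta);
  size_t dim = sv.size();
  for (int spin = 0; spin < 2; ++spin) {
    int mp = p + spin * norb, mq = q + spin * norb;
    uint64_t bp = 1ULL << mp, bq = 1ULL << mq;
    int lo = std::min(mp, mq), hi = std::max(mp, mq);
    uint64_t between = ((1ULL << hi) - 1ULL) & ~((1ULL << (lo + 1)) - 1ULL);
    for (uint64_t n = 0; n < dim; ++n) {
      if ((n & bp) && !(n & bq)) {
        uint64_t m = (n ^ bp) | bq;
        double sgn = (popcnt(n & between) % 2) ? -1.0 : 1.0;
        double an = out[n], am = out[m];
        // a^+_q a_p |n> = sgn |m>
        out[n] = c * an - sgn * s * am;
        out[m] = sgn * s * an + c * am;
      }
    }
  }
  return out;
}

// four-qubit pair-exchange gate on spatial orbitals (t, t+1): rotates the
// doubly-occupied-t / doubly-occupied-(t+1) closed-shell pair, identity on
// every other sector.  Generator theta (T - T^+) with
// T = a^+_{t+1,a} a^+_{t+1,b} a_{t,b} a_{t,a}.
// [[Rcpp::export]]
NumericVector cpp_apply_pairx(NumericVector sv, int norb, int t, double theta) {
  if (t < 0 || t + 1 >= norb) stop("pair index out of range");
  NumericVector out = clone(sv);
  double c = std::cos(theta), s = std::sin(theta);
  size_t dim = sv.size();
  uint64_t pa = 1ULL << t, pb = 1ULL << (norb + t);
  uint64_t qa = 1ULL << (t + 1), qb = 1ULL << (norb + t + 1);
  for (uint64_t n = 0; n < dim; ++n) {
    if ((n & pa) && (n & pb) && !(n & qa) && !(n & qb)) {
      // sequential JW parities for a_{ta}, a_{tb}, a^+_{t+1,b}, a^+_{t+1,a}
      double sgn = 1.0;
      uint64_t cur = n;
      sgn *= parity_below(cur, t);            cur ^= pa;
      sgn *= parity_below(cur, norb + t);     cur ^= pb;
      sgn *= parity_below(cur, norb + t + 1); cur |= qb;
      sgn *= parity_below(cur, t + 1);        cur |= qa;
      uint64_t m = cur;
      double an = out[n], am = out[m];
      out[n] = c * an - sgn * s * am;
      out[m] = sgn * s * an + c * am;
    }
  }
  return out;
}

// E_pq |psi> for all (p,q): returns dim x norb^2 matrix, column p + q*norb
// (0-based), E_pq = sum_sigma a^+_{p sigma} a_{q sigma}
// [[Rcpp::export]]
NumericMatrix cpp_sv_epq_all(NumericVector sv, int norb) {
  size_t dim = sv.size();
  NumericMatrix W(dim, norb * norb);
  for (int q = 0; q < norb; ++q)
    for (int p = 0; p < norb; ++p) {
      int col = p + q * norb;
      double* w = &W(0, col);
      for (int spin = 0; spin < 2; ++spin) {
        int mp = p + spin * norb, mq = q + spin * norb;
        uint64_t bp = 1ULL << mp, bq = 1ULL << mq;
        if (mp == mq) {
          for (uint64_t n = 0; n < dim; ++n)
            if (n & bp) w[n] += sv[n];
          continue;
        }
        int lo = std::min(mp, mq), hi = std::max(mp, mq);
        uint64_t between = ((1ULL << hi) - 1ULL) & ~((1ULL << (lo + 1)) - 1ULL);
        for (uint64_t n = 0; n < dim; ++n) {
          if ((n & bq) && !(n & bp)) {
            uint64_t m = (n ^ bq) | bp;
            double sgn = (popcnt(n & between) % 2) ? -1.0 : 1.0;
            w[m] += sgn * sv[n];
          }
        }
      }
    }
  return W;
}

// spin-summed 1-RDM gamma_pq = <psi|E_pq|psi>
// [[Rcpp::export]]
NumericMatrix cpp_sv_gamma(NumericVector sv, int norb) {
  size_t dim = sv.size();
  NumericMatrix G(norb, norb);
  for (int p = 0; p < norb; ++p)
    for (int q = 0; q < norb; ++q) {
      double acc = 0.0;
      for (int spin = 0; spin < 2; ++spin) {
        int mp = p + spin * norb, mq = q + spin * norb;
        uint64_t bp = 1ULL << mp, bq = 1ULL << mq;
        if (mp == mq) {
          for (uint64_t n = 0; n < dim; ++n)
            if (n & bp) acc += sv[n] * sv[n];
          continue;
        }
        int lo = std::min(mp, mq), hi = std::max(mp, mq);
        uint64_t between = ((1ULL << hi) - 1ULL) & ~((1ULL << (lo + 1)) - 1ULL);
        for (uint64_t n = 0; n < dim; ++n) {
          if ((n & bq) && !(n & bp)) {
            uint64_t m = (n ^ bq) | bp;
            double sgn = (popcnt(n & between) % 2) ? -1.0 : 1.0;
            acc += sgn * sv[n] * sv[m];
          }
        }
      }
      G(p, q) = acc;
    }
  return G;
}

// generic a^+_{cre} a_{ann} on raw modes (0-based), for symmetry checks
// [[Rcpp::export]]
NumericVector cpp_apply_ccop(NumericVector sv, int cre, int ann) {
  size_t dim = sv.size();
  NumericVector out(dim);
  uint64_t bc = 1ULL << cre, ba = 1ULL << ann;
  for (uint64_t n = 0; n < dim; ++n) {
    if (!(n & ba)) continue;
    double sgn = parity_below(n, ann);
    uint64_t m = n ^ ba;
    if (m & bc) continue;
    sgn *= parity_below(m, cre);
    out[m | bc] += sgn * sv[n];
  }
  return out;
}

// ------------------------------------------------------------- determinants
// [[Rcpp::export]]
IntegerVector cpp_det_strings(int norb, int ne) {
  std::vector<int> out;
  for (int m = 0; m < (1 << norb); ++m)
    if (popcnt((uint64_t)m) == ne) out.push_back(m);
  return wrap(out);
}

static inline double ann_sign(uint64_t s, int p) { return parity_below(s, p); }

// single-excitation sign p -> q within one string (p occupied, q empty)
static inline double exc1_sign(uint64_t s, int p, int q) {
  double sg = ann_sign(s, p);
  uint64_t s1 = s ^ (1ULL << p);
  sg *= ann_sign(s1, q);  // creation parity below q on s1
  return sg;
}

// dense CASCI Hamiltonian over the (dets_a x dets_b) product basis.
// h: norb x norb active one-electron matrix; g: flat norb^4 chemists-order
// array g[p + q*n + r*n^2 + s*n^3] = (pq|rs).  Global index I = ia + ib*Na.
// [[Rcpp::export]]
NumericMatrix cpp_casci_h(NumericMatrix h, NumericVector g, IntegerVector dets_a,
                          IntegerVector dets_b, int norb) {
  int Na = dets_a.size(), Nb = dets_b.size();
  int dim = Na * Nb;
  int n = norb;
  NumericMatrix H(dim, dim);
  auto G = [&](int p, int q, int r, int s) -> double {
    return g[((size_t)s * n + r) * n * n + (size_t)q * n + p];
  };
  std::vector<std::vector<int>> occ_a(Na), occ_b(Nb);
  for (int i = 0; i < Na; ++i)
    for (int p = 0; p < n; ++p) if (dets_a[i] & (1 << p)) occ_a[i].push_back(p);
  for (int i = 0; i < Nb; ++i)
    for (int p = 0; p < n; ++p) if (dets_b[i] & (1 << p)) occ_b[i].push_back(p);

  for (int ib = 0; ib < Nb; ++ib)
    for (int ia = 0; ia < Na; ++ia) {
      int I = ia + ib * Na;
      for (int jb = ib; jb < Nb; ++jb)
        for (int ja = (jb == ib) ? ia : 0; ja < Na; ++ja) {
          int J = ja + jb * Na;
          uint64_t xa = (uint64_t)(dets_a[ia] ^ dets_a[ja]);
          uint64_t xb = (uint64_t)(dets_b[ib] ^ dets_b[jb]);
          int da = popcnt(xa) / 2, db = popcnt(xb) / 2;
          if (da + db > 2) continue;
          double val = 0.0;
          uint64_t sa = dets_a[ia], sb = dets_b[ib];
          uint64_t ta = dets_a[ja], tb = dets_b[jb];
          if (da == 0 && db == 0) {
            for (int p : occ_a[ia]) val += h(p, p);
            for (int p : occ_b[ib]) val += h(p, p);
            for (int p : occ_a[ia])
              for (int q : occ_a[ia]) val += 0.5 * (G(p, p, q, q) - G(p, q, p, q));
            for (int p : occ_b[ib])
              for (int q : occ_b[ib]) val += 0.5 * (G(p, p, q, q) - G(p, q, p, q));
            for (int p : occ_a[ia])
              for (int q : occ_b[ib]) val += G(p, p, q, q);
          } else if (da == 1 && db == 0) {
            int p = -1, q = -1;  // p occupied in I only, q in J only
            for (int k = 0; k < n; ++k) {
              if (xa & (1ULL << k)) {
                if (sa & (1ULL << k)) p = k; else q = k;
              }
            }
            double sg = exc1_sign(sa, p, q);
            double acc = h(p, q);
            for (int r : occ_a[ia]) {
              if (r == p) continue;
              acc += G(p, q, r, r) - G(p, r, q, r);
            }
            for (int r : occ_b[ib]) acc += G(p, q, r, r);
            val = sg * acc;
          } else if (da == 0 && db == 1) {
            int p = -1, q = -1;
            for (int k = 0; k < n; ++k) {
              if (xb & (1ULL << k)) {
                if (sb & (1ULL << k)) p = k; else q = k;
              }
            }
            double sg = exc1_sign(sb, p, q);
            double acc = h(p, q);
            for (int r : occ_b[ib]) {
              if (r == p) continue;
              acc += G(p, q, r, r) - G(p, r, q, r);
            }
            for (int r : occ_a[ia]) acc += G(p, q, r, r);
            val = sg * acc;
          } else if (da == 2 && db == 0) {
            int p1 = -1, p2 = -1, q1 = -1, q2 = -1;
            for (int k = 0; k < n; ++k) {
              if (xa & (1ULL << k)) {
                if (sa & (1ULL << k)) { if (p1 < 0) p1 = k; else p2 = k; }
                else { if (q1 < 0) q1 = k; else q2 = k; }
              }
            }
            // sign: annihilate p1 then p2, create q2 then q1 (sequential)
            double sg = ann_sign(sa, p1);
            uint64_t s1 = sa ^ (1ULL << p1);
            sg *= ann_sign(s1, p2); s1 ^= (1ULL << p2);
            sg *= ann_sign(s1, q2); s1 |= (1ULL << q2);
            sg *= ann_sign(s1, q1);
            // <J|H|I> with a^+_{q1} a^+_{q2} a_{p2} a_{p1} ordering:
            val = sg * (G(p1, q1, p2, q2) - G(p1, q2, p2, q1));
            (void)ta;
          } else if (da == 0 && db == 2) {
            int p1 = -1, p2 = -1, q1 = -1, q2 = -1;
            for (int k = 0; k < n; ++k) {
              if (xb & (1ULL << k)) {
                if (sb & (1ULL << k)) { if (p1 < 0) p1 = k; else p2 = k; }
                else { if (q1 < 0) q1 = k; else q2 = k; }
              }
            }
            double sg = ann_sign(sb, p1);
            uint64_t s1 = sb ^ (1ULL << p1);
            sg *= ann_sign(s1, p2); s1 ^= (1ULL << p2);
            sg *= ann_sign(s1, q2); s1 |= (1ULL << q2);
            sg *= ann_sign(s1, q1);
            val = sg * (G(p1, q1, p2, q2) - G(p1, q2, p2, q1));
            (void)tb;
          } else {  // da == 1 && db == 1
            int p = -1, q = -1, r = -1, s = -1;
            for (int k = 0; k < n; ++k) {
              if (xa & (1ULL << k)) {
                if (sa & (1ULL << k)) p = k; else q = k;
              }
              if (xb & (1ULL << k)) {
                if (sb & (1ULL << k)) r = k; else s = k;
              }
            }
            val = exc1_sign(sa, p, q) * exc1_sign(sb, r, s) * G(p, q, r, s);
          }
          H(I, J) = val;
          H(J, I) = val;
        }
    }
  return H;
}

// apply a compiled gate list in one pass: type 0 = spin-restricted Givens
// rotation on spatial orbitals (p, q); type 1 = pair-exchange on (p, p+1)
// [[Rcpp::export]]
NumericVector cpp_apply_ops(NumericVector sv, int norb, IntegerVector type,
                            IntegerVector p, IntegerVector q,
                            NumericVector theta) {
  NumericVector out = clone(sv);
  size_t dim = out.size();
  int nops = type.size();
  for (int o = 0; o < nops; ++o) {
    double c = std::cos(theta[o]), s = std::sin(theta[o]);
    if (type[o] == 0) {
      for (int spin = 0; spin < 2; ++spin) {
        int mp = p[o] + spin * norb, mq = q[o] + spin * norb;
        uint64_t bp = 1ULL << mp, bq = 1ULL << mq;
        int lo = std::min(mp, mq), hi = std::max(mp, mq);
        uint64_t between = ((1ULL << hi) - 1ULL) & ~((1ULL << (lo + 1)) - 1ULL);
        for (uint64_t n = 0; n < dim; ++n) {
          if ((n & bp) && !(n & bq)) {
            uint64_t m = (n ^ bp) | bq;
            double sgn = (popcnt(n & between) % 2) ? -1.0 : 1.0;
            double an = out[n], am = out[m];
            out[n] = c * an - sgn * s * am;
            out[m] = sgn * s * an + c * am;
          }
        }
      }
    } else {
      int t = p[o];
      uint64_t pa = 1ULL << t, pb = 1ULL << (norb + t);
      uint64_t qa = 1ULL << (t + 1), qb = 1ULL << (norb + t + 1);
      for (uint64_t n = 0; n < dim; ++n) {
        if ((n & pa) && (n & pb) && !(n & qa) && !(n & qb)) {
          double sgn = 1.0;
          uint64_t cur = n;
          sgn *= parity_below(cur, t);            cur ^= pa;
          sgn *= parity_below(cur, norb + t);     cur ^= pb;
          sgn *= parity_below(cur, norb + t + 1); cur |= qb;
          sgn *= parity_below(cur, t + 1);        cur |= qa;
          uint64_t m = cur;
          double an = out[n], am = out[m];
          out[n] = c * an - sgn * s * am;
          out[m] = sgn * s * an + c * am;
        }
      }
    }
  }
  return out;
}
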