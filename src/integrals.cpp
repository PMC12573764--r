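// McMurchie-Davidson Gaussian integral engine.
//
// Basis functions are contracted Cartesian Gaussians described by flat
// arrays (one entry per contracted function): center, Cartesian powers
// (l,m,n), primitive exponents and contraction coefficients (already
// multiplied by primitive norms; overall contraction normalized in R).
//
// Provides: overlap, kinetic, nuclear attraction, dipole integrals,
// packed two-electron integrals with Schwarz screening, and J/K builds
// from the packed list.

#include <RcppArmadillo.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static const double PI = 3.14159265358979323846;

// ---------------------------------------------------------------- Boys
// F_n(x) = int_0^1 t^{2n} exp(-x t^2) dt, downward recursion for x < 35,
// upward from the asymptotic form otherwise.
static void boys(int nmax, double x, double* F) {
  if (x < 1e-13) {
    for (int n = 0; n <= nmax; ++n) F[n] = 1.0 / (2.0 * n + 1.0);
    return;
  }
  if (x < 35.0) {
    // series for F_nmax, then downward
    double s = 0.0, term = 1.0 / (2.0 * nmax + 1.0);
    int k = 0;
    while (std::fabs(term) > 1e-17 && k < 200) {
      s += term;
      ++k;
      term *= (2.0 * x) / (2.0 * nmax + 2.0 * k + 1.0);
    }
    double ex = std::exp(-x);
    F[nmax] = s * ex;
    for (int n = nmax - 1; n >= 0; --n)
      F[n] = (2.0 * x * F[n + 1] + ex) / (2.0 * n + 1.0);
  } else {
    double ex = std::exp(-x);
    F[0] = 0.5 * std::sqrt(PI / x);
    for (int n = 0; n < nmax; ++n)
      F[n + 1] = ((2.0 * n + 1.0) * F[n] - ex) / (2.0 * x);
  }
}

// ------------------------------------------------- Hermite E coefficients
// E[t] for pair (i,j) along one dimension; E_t^{ij} with exponents a,b and
// separation Q = A - B.  emax = i + j.
static void ecoef(int i, int j, double a, double b, double Q, double* E) {
  const int MX = 13;  // supports l up to 6 per index
  double tab[MX][MX][2 * MX];
  double p = a + b, mu = a * b / p;
  for (int ii = 0; ii <= i; ++ii)
    for (int jj = 0; jj <= j; ++jj)
      for (int t = 0; t <= i + j + 1 && t < 2 * MX; ++t) tab[ii][jj][t] = 0.0;
  tab[0][0][0] = std::exp(-mu * Q * Q);
  for (int ii = 1; ii <= i; ++ii) {
    for (int t = 0; t <= ii; ++t) {
      double v = 0.0;
      if (t - 1 >= 0) v += tab[ii - 1][0][t - 1] / (2.0 * p);
      v += -(b / p) * Q * tab[ii - 1][0][t];
      if (t + 1 <= ii - 1) v += (t + 1.0) * tab[ii - 1][0][t + 1];
      tab[ii][0][t] = v;
    }
  }
  for (int jj = 1; jj <= j; ++jj) {
    for (int ii = 0; ii <= i; ++ii) {
      for (int t = 0; t <= ii + jj; ++t) {
        double v = 0.0;
        if (t - 1 >= 0) v += tab[ii][jj - 1][t - 1] / (2.0 * p);
        v += (a / p) * Q * tab[ii][jj - 1][t];
        if (t + 1 <= ii + jj - 1) v += (t + 1.0) * tab[ii][jj - 1][t + 1];
        tab[ii][jj][t] = v;
      }
    }
  }
  for (int t = 0; t <= i + j; ++t) E[t] = tab[i][j][t];
}

// ------------------------------------------------- Hermite Coulomb R_{tuv}
static void rtuv(int tmax, int umax, int vmax, double p, double X, double Y,
                 double Z, double* out /* (tmax+1)*(umax+1)*(vmax+1) */) {
  int nmax = tmax + umax + vmax;
  std::vector<double> F(nmax + 1);
  double r2 = X * X + Y * Y + Z * Z;
  boys(nmax, p * r2, F.data());
  // R^n_{tuv} stored in nested table
  int T = tmax + 1, U = umax + 1, V = vmax + 1;
  std::vector<double> R((nmax + 1) * T * U * V, 0.0);
  auto idx = [&](int n, int t, int u, int v) {
    return ((n * T + t) * U + u) * V + v;
  };
  double mp = 1.0;
  for (int n = 0; n <= nmax; ++n) {
    R[idx(n, 0, 0, 0)] = mp * F[n];
    mp *= -2.0 * p;
  }
  for (int t = 0; t <= tmax; ++t)
    for (int u = 0; u <= umax; ++u)
      for (int v = 0; v <= vmax; ++v) {
        if (t + u + v == 0) continue;
        for (int n = nmax - t - u - v; n >= 0; --n) {
          double val = 0.0;
          if (t > 0) {
            val = X * R[idx(n + 1, t - 1, u, v)];
            if (t > 1) val += (t - 1.0) * R[idx(n + 1, t - 2, u, v)];
          } else if (u > 0) {
            val = Y * R[idx(n + 1, t, u - 1, v)];
            if (u > 1) val += (u - 1.0) * R[idx(n + 1, t, u - 2, v)];
          } else {
            val = Z * R[idx(n + 1, t, u, v - 1)];
            if (v > 1) val += (v - 1.0) * R[idx(n + 1, t, u, v - 2)];
          }
          R[idx(n, t, u, v)] = val;
        }
      }
  for (int t = 0; t <= tmax; ++t)
    for (int u = 0; u <= umax; ++u)
      for (int v = 0; v <= vmax; ++v)
        out[(t * U + u) * V + v] = R[idx(0, t, u, v)];
}

// ----------------------------------------------------------- basis holder
struct Basis {
  int M;
  std::vector<double> cx, cy, cz;        // centers per function
  std::vector<int> l, m, n;              // cartesian powers
  std::vector<int> off, nprim;           // primitive offsets
  std::vector<double> alpha, coef;       // primitives (coef incl. norms)
};

static Basis unpack_basis(const List& b) {
  Basis B;
  NumericMatrix centers = b["centers"];   // M x 3
  IntegerMatrix pow = b["powers"];        // M x 3
  IntegerVector off = b["prim_offset"];   // M (0-based)
  IntegerVector npr = b["nprim"];
  NumericVector al = b["alpha"];
  NumericVector co = b["coef"];
  B.M = centers.nrow();
  for (int i = 0; i < B.M; ++i) {
    B.cx.push_back(centers(i, 0));
    B.cy.push_back(centers(i, 1));
    B.cz.push_back(centers(i, 2));
    B.l.push_back(pow(i, 0));
    B.m.push_back(pow(i, 1));
    B.n.push_back(pow(i, 2));
    B.off.push_back(off[i]);
    B.nprim.push_back(npr[i]);
  }
  B.alpha.assign(al.begin(), al.end());
  B.coef.assign(co.begin(), co.end());
  return B;
}

// one-dimensional overlap integral from E coefficients: S1d = E_0 * sqrt(pi/p)
static double s1d(int i, int j, double a, double b, double Q) {
  double E[13];
  ecoef(i, j, a, b, Q, E);
  return E[0] * std::sqrt(PI / (a + b));
}

// primitive overlap (unnormalized cartesian)
static double prim_overlap(int l1, int m1, int n1, double a, const double* A,
                           int l2, int m2, int n2, double b, const double* Bc) {
  return s1d(l1, l2, a, b, A[0] - Bc[0]) * s1d(m1, m2, a, b, A[1] - Bc[1]) *
         s1d(n1, n2, a, b, A[2] - Bc[2]);
}

static double prim_kinetic(int l1, int m1, int n1, double a, const double* A,
                           int l2, int m2, int n2, double b, const double* Bc) {
  // T = b(2(l2+m2+n2)+3) S - 2 b^2 (S_{l2+2} + S_{m2+2} + S_{n2+2})
  //     - 1/2 [ l2(l2-1) S_{l2-2} + m2(m2-1) S_{m2-2} + n2(n2-1) S_{n2-2} ]
  double S0 = prim_overlap(l1, m1, n1, a, A, l2, m2, n2, b, Bc);
  double t = b * (2.0 * (l2 + m2 + n2) + 3.0) * S0;
  t -= 2.0 * b * b * (prim_overlap(l1, m1, n1, a, A, l2 + 2, m2, n2, b, Bc) +
                      prim_overlap(l1, m1, n1, a, A, l2, m2 + 2, n2, b, Bc) +
                      prim_overlap(l1, m1, n1, a, A, l2, m2, n2 + 2, b, Bc));
  if (l2 >= 2)
    t -= 0.5 * l2 * (l2 - 1.0) *
         prim_overlap(l1, m1, n1, a, A, l2 - 2, m2, n2, b, Bc);
  if (m2 >= 2)
    t -= 0.5 * m2 * (m2 - 1.0) *
         prim_overlap(l1, m1, n1, a, A, l2, m2 - 2, n2, b, Bc);
  if (n2 >= 2)
    t -= 0.5 * n2 * (n2 - 1.0) *
         prim_overlap(l1, m1, n1, a, A, l2, m2, n2 - 2, b, Bc);
  return t;
}

// [[Rcpp::export(name = ".cpp_one_electron")]]
List cpp_one_electron(List basis, NumericMatrix atom_xyz, NumericVector atom_Z) {
  Basis B = unpack_basis(basis);
  int M = B.M;
  arma::mat S(M, M, arma::fill::zeros), T(M, M, arma::fill::zeros),
      V(M, M, arma::fill::zeros), DX(M, M, arma::fill::zeros),
      DY(M, M, arma::fill::zeros), DZ(M, M, arma::fill::zeros);
  int natom = atom_xyz.nrow();

  for (int i = 0; i < M; ++i) {
    double A[3] = {B.cx[i], B.cy[i], B.cz[i]};
    for (int j = 0; j <= i; ++j) {
      double Bc[3] = {B.cx[j], B.cy[j], B.cz[j]};
      double s = 0, t = 0, v = 0, dx = 0, dy = 0, dz = 0;
      for (int pi = 0; pi < B.nprim[i]; ++pi) {
        double a = B.alpha[B.off[i] + pi], ca = B.coef[B.off[i] + pi];
        for (int pj = 0; pj < B.nprim[j]; ++pj) {
          double b = B.alpha[B.off[j] + pj], cb = B.coef[B.off[j] + pj];
          double cc = ca * cb;
          double sp = prim_overlap(B.l[i], B.m[i], B.n[i], a, A, B.l[j], B.m[j],
                                   B.n[j], b, Bc);
          s += cc * sp;
          t += cc * prim_kinetic(B.l[i], B.m[i], B.n[i], a, A, B.l[j], B.m[j],
                                 B.n[j], b, Bc);
          // dipole about origin: <a| x |b> = S(l2+1) + Bx S(l2)
          double sx1 = prim_overlap(B.l[i], B.m[i], B.n[i], a, A, B.l[j] + 1,
                                    B.m[j], B.n[j], b, Bc);
          double sy1 = prim_overlap(B.l[i], B.m[i], B.n[i], a, A, B.l[j],
                                    B.m[j] + 1, B.n[j], b, Bc);
          double sz1 = prim_overlap(B.l[i], B.m[i], B.n[i], a, A, B.l[j],
                                    B.m[j], B.n[j] + 1, b, Bc);
          dx += cc * (sx1 + Bc[0] * sp);
          dy += cc * (sy1 + Bc[1] * sp);
          dz += cc * (sz1 + Bc[2] * sp);
          // nuclear attraction
          double p = a + b;
          double P[3] = {(a * A[0] + b * Bc[0]) / p, (a * A[1] + b * Bc[1]) / p,
                         (a * A[2] + b * Bc[2]) / p};
          int tmax = B.l[i] + B.l[j], umax = B.m[i] + B.m[j],
              vmax = B.n[i] + B.n[j];
          double E1[13], E2[13], E3[13];
          ecoef(B.l[i], B.l[j], a, b, A[0] - Bc[0], E1);
          ecoef(B.m[i], B.m[j], a, b, A[1] - Bc[1], E2);
          ecoef(B.n[i], B.n[j], a, b, A[2] - Bc[2], E3);
          std::vector<double> R((tmax + 1) * (umax + 1) * (vmax + 1));
          for (int at = 0; at < natom; ++at) {
            rtuv(tmax, umax, vmax, p, P[0] - atom_xyz(at, 0),
                 P[1] - atom_xyz(at, 1), P[2] - atom_xyz(at, 2), R.data());
            double acc = 0.0;
            for (int tt = 0; tt <= tmax; ++tt)
              for (int uu = 0; uu <= umax; ++uu)
                for (int vv = 0; vv <= vmax; ++vv)
                  acc += E1[tt] * E2[uu] * E3[vv] *
                         R[(tt * (umax + 1) + uu) * (vmax + 1) + vv];
            v += -atom_Z[at] * cc * (2.0 * PI / p) * acc;
          }
        }
      }
      S(i, j) = S(j, i) = s;
      T(i, j) = T(j, i) = t;
      V(i, j) = V(j, i) = v;
      DX(i, j) = DX(j, i) = dx;
      DY(i, j) = DY(j, i) = dy;
      DZ(i, j) = DZ(j, i) = dz;
    }
  }
  return List::create(Named("S") = S, Named("T") = T, Named("V") = V,
                      Named("dip_x") = DX, Named("dip_y") = DY,
                      Named("dip_z") = DZ);
}

// ----------------------------------------------------------------- ERIs
// contracted (ij|kl) via MD
static double eri_contracted(const Basis& B, int i, int j, int k, int l) {
  double A[3] = {B.cx[i], B.cy[i], B.cz[i]};
  double Bc[3] = {B.cx[j], B.cy[j], B.cz[j]};
  double C[3] = {B.cx[k], B.cy[k], B.cz[k]};
  double D[3] = {B.cx[l], B.cy[l], B.cz[l]};
  int t1 = B.l[i] + B.l[j], u1 = B.m[i] + B.m[j], v1 = B.n[i] + B.n[j];
  int t2 = B.l[k] + B.l[l], u2 = B.m[k] + B.m[l], v2 = B.n[k] + B.n[l];
  double val = 0.0;
  std::vector<double> R((t1 + t2 + 1) * (u1 + u2 + 1) * (v1 + v2 + 1));
  for (int pi = 0; pi < B.nprim[i]; ++pi) {
    double a = B.alpha[B.off[i] + pi], ca = B.coef[B.off[i] + pi];
    for (int pj = 0; pj < B.nprim[j]; ++pj) {
      double b = B.alpha[B.off[j] + pj], cb = B.coef[B.off[j] + pj];
      double p = a + b;
      double P[3] = {(a * A[0] + b * Bc[0]) / p, (a * A[1] + b * Bc[1]) / p,
                     (a * A[2] + b * Bc[2]) / p};
      double E1[13], E2[13], E3[13];
      ecoef(B.l[i], B.l[j], a, b, A[0] - Bc[0], E1);
      ecoef(B.m[i], B.m[j], a, b, A[1] - Bc[1], E2);
      ecoef(B.n[i], B.n[j], a, b, A[2] - Bc[2], E3);
      for (int pk = 0; pk < B.nprim[k]; ++pk) {
        double c = B.alpha[B.off[k] + pk], cc_ = B.coef[B.off[k] + pk];
        for (int pl = 0; pl < B.nprim[l]; ++pl) {
          double d = B.alpha[B.off[l] + pl], cd = B.coef[B.off[l] + pl];
          double q = c + d;
          double Q[3] = {(c * C[0] + d * D[0]) / q, (c * C[1] + d * D[1]) / q,
                         (c * C[2] + d * D[2]) / q};
          double F1[13], F2[13], F3[13];
          ecoef(B.l[k], B.l[l], c, d, C[0] - D[0], F1);
          ecoef(B.m[k], B.m[l], c, d, C[1] - D[1], F2);
          ecoef(B.n[k], B.n[l], c, d, C[2] - D[2], F3);
          double alpha = p * q / (p + q);
          rtuv(t1 + t2, u1 + u2, v1 + v2, alpha, P[0] - Q[0], P[1] - Q[1],
               P[2] - Q[2], R.data());
          double pref = 2.0 * std::pow(PI, 2.5) /
                        (p * q * std::sqrt(p + q)) * ca * cb * cc_ * cd;
          double acc = 0.0;
          for (int tt = 0; tt <= t1; ++tt) {
            if (E1[tt] == 0.0) continue;
            for (int uu = 0; uu <= u1; ++uu) {
              if (E2[uu] == 0.0) continue;
              for (int vv = 0; vv <= v1; ++vv) {
                if (E3[vv] == 0.0) continue;
                double e1 = E1[tt] * E2[uu] * E3[vv];
                double acc2 = 0.0;
                for (int t3 = 0; t3 <= t2; ++t3) {
                  if (F1[t3] == 0.0) continue;
                  for (int u3 = 0; u3 <= u2; ++u3) {
                    if (F2[u3] == 0.0) continue;
                    for (int v3 = 0; v3 <= v2; ++v3) {
                      if (F3[v3] == 0.0) continue;
                      double sgn = ((t3 + u3 + v3) % 2) ? -1.0 : 1.0;
                      acc2 += sgn * F1[t3] * F2[u3] * F3[v3] *
                              R[((tt + t3) * (u1 + u2 + 1) + (uu + u3)) *
                                    (v1 + v2 + 1) +
                                (vv + v3)];
                    }
                  }
                }
                acc += e1 * acc2;
              }
            }
          }
          val += pref * acc;
        }
      }
    }
  }
  return val;
}

// [[Rcpp::export(name = ".cpp_eri_packed")]]
NumericVector cpp_eri_packed(List basis, double screen_tol) {
  Basis B = unpack_basis(basis);
  int M = B.M;
  long npair = (long)M * (M + 1) / 2;
  NumericVector out((R_xlen_t)(npair * (npair + 1) / 2));
  // Schwarz factors
  std::vector<double> Q(npair);
  for (int i = 0; i < M; ++i)
    for (int j = 0; j <= i; ++j) {
      double v = eri_contracted(B, i, j, i, j);
      Q[(long)i * (i + 1) / 2 + j] = std::sqrt(std::fabs(v));
    }
  for (int i = 0; i < M; ++i) {
    for (int j = 0; j <= i; ++j) {
      long ij = (long)i * (i + 1) / 2 + j;
      for (int k = 0; k <= i; ++k) {
        for (int l = 0; l <= k; ++l) {
          long kl = (long)k * (k + 1) / 2 + l;
          if (kl > ij) continue;
          double v = 0.0;
          if (Q[ij] * Q[kl] > screen_tol) v = eri_contracted(B, i, j, k, l);
          out[(R_xlen_t)(ij * (ij + 1) / 2 + kl)] = v;
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// J[P]_{mn} = sum_{ls} (mn|ls) P_{ls};  K[P]_{mn} = sum_{ls} (ml|sn) P_{ls}
// [[Rcpp::export(name = ".cpp_jk_build")]]
List cpp_jk_build(NumericVector eri, int M, List Plist, double thresh) {
  int nd = Plist.size();
  std::vector<arma::mat> P(nd), J(nd), K(nd);
  for (int d = 0; d < nd; ++d) {
    P[d] = as<arma::mat>(Plist[d]);
    J[d] = arma::mat(M, M, arma::fill::zeros);
    K[d] = arma::mat(M, M, arma::fill::zeros);
  }
  const double* e = eri.begin();
  for (int i = 0; i < M; ++i) {
    for (int j = 0; j <= i; ++j) {
      long ij = (long)i * (i + 1) / 2 + j;
      const double* row = e + (R_xlen_t)(ij * (ij + 1) / 2);
      for (int k = 0; k <= i; ++k) {
        for (int l = 0; l <= k; ++l) {
          long kl = (long)k * (k + 1) / 2 + l;
          if (kl > ij) continue;
          double v = row[kl];
          if (std::fabs(v) < thresh) continue;
          // all 8 index permutations, scaled by their duplicity
          int dup = (i == j ? 2 : 1) * (k == l ? 2 : 1) * (ij == kl ? 2 : 1);
          double vs = v / dup;
          const int perms[8][4] = {{i, j, k, l}, {j, i, k, l}, {i, j, l, k},
                                   {j, i, l, k}, {k, l, i, j}, {l, k, i, j},
                                   {k, l, j, i}, {l, k, j, i}};
          for (int d = 0; d < nd; ++d) {
            const arma::mat& Pd = P[d];
            arma::mat& Jd = J[d];
            arma::mat& Kd = K[d];
            for (int s = 0; s < 8; ++s) {
              int p = perms[s][0], q = perms[s][1], r = perms[s][2],
                  w = perms[s][3];
              Jd(p, q) += vs * Pd(r, w);
              Kd(p, w) += vs * Pd(q, r);
            }
          }
        }
      }
    }
  }
  List Jl(nd), Kl(nd);
  for (int d = 0; d < nd; ++d) {
    Jl[d] = wrap(J[d]);
    Kl[d] = wrap(K[d]);
  }
  return List::create(Named("J") = Jl, Named("K") = Kl);
}

// single contracted ERI, for tests and small MO transforms
// [[Rcpp::export(name = ".cpp_eri_single")]]
double cpp_eri_single(List basis, int i, int j, int k, int l) {
  Basis B = unpack_basis(basis);
  return eri_contracted(B, i - 1, j - 1, k - 1, l - 1);
}

// AO values (and optionally gradients) at grid points, with radial screening
List ao_values_impl(const List& basis, const NumericMatrix& pts, bool deriv) {
  Basis B = unpack_basis(basis);
  int M = B.M, np = pts.nrow();
  arma::mat phi(np, M, arma::fill::zeros);
  arma::mat gx, gy, gz;
  if (deriv) {
    gx.zeros(np, M);
    gy.zeros(np, M);
    gz.zeros(np, M);
  }
  for (int f = 0; f < M; ++f) {
    // screening radius: smallest exponent governs decay
    double amin = 1e30, cmax = 0.0;
    for (int p = 0; p < B.nprim[f]; ++p) {
      amin = std::min(amin, B.alpha[B.off[f] + p]);
      cmax = std::max(cmax, std::fabs(B.coef[B.off[f] + p]));
    }
    // exp(-amin r2) * cmax < 1e-14  =>  r2 > -log(1e-14/cmax)/amin
    double r2max = -std::log(1e-14 / std::max(cmax, 1e-30)) / amin;
    int ltot = B.l[f] + B.m[f] + B.n[f];
    r2max *= (1.0 + 0.5 * ltot);  // slack for polynomial prefactor
    for (int ip = 0; ip < np; ++ip) {
      double x = pts(ip, 0) - B.cx[f], y = pts(ip, 1) - B.cy[f],
             z = pts(ip, 2) - B.cz[f];
      double r2 = x * x + y * y + z * z;
      if (r2 > r2max) continue;
      double radial = 0.0, dradial = 0.0;  // sum c e^{-a r2}, d/dr2
      for (int p = 0; p < B.nprim[f]; ++p) {
        double a = B.alpha[B.off[f] + p];
        double e = B.coef[B.off[f] + p] * std::exp(-a * r2);
        radial += e;
        dradial += -a * e;
      }
      double xl = 1, ym = 1, zn = 1;
      for (int t = 0; t < B.l[f]; ++t) xl *= x;
      for (int t = 0; t < B.m[f]; ++t) ym *= y;
      for (int t = 0; t < B.n[f]; ++t) zn *= z;
      double poly = xl * ym * zn;
      phi(ip, f) = poly * radial;
      if (deriv) {
        double dpx = (B.l[f] > 0)
                         ? B.l[f] * (B.l[f] > 1 ? std::pow(x, B.l[f] - 1) : 1.0) *
                               ym * zn
                         : 0.0;
        double dpy = (B.m[f] > 0)
                         ? B.m[f] * (B.m[f] > 1 ? std::pow(y, B.m[f] - 1) : 1.0) *
                               xl * zn
                         : 0.0;
        double dpz = (B.n[f] > 0)
                         ? B.n[f] * (B.n[f] > 1 ? std::pow(z, B.n[f] - 1) : 1.0) *
                               xl * ym
                         : 0.0;
        gx(ip, f) = dpx * radial + poly * 2.0 * x * dradial;
        gy(ip, f) = dpy * radial + poly * 2.0 * y * dradial;
        gz(ip, f) = dpz * radial + poly * 2.0 * z * dradial;
      }
    }
  }
  if (deriv)
    return List::create(Named("phi") = phi, Named("gx") = gx,
                        Named("gy") = gy, Named("gz") = gz);
  return List::create(Named("phi") = phi);
}

// [[Rcpp::export(name = ".cpp_ao_values")]]
List cpp_ao_values(List basis, NumericMatrix pts, bool deriv) {
  return ao_values_impl(basis, pts, deriv);
}
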