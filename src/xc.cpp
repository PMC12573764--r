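// Exchange-correlation evaluation on molecular quadrature grids.
//
// Semilocal pieces: Slater exchange, VWN5 correlation (LSDA), PBE
// exchange and correlation (GGA).  Spin resolved; potentials are
// analytic (VWN5/PBE-correlation derivative code machine-generated from
// the closed-form energy expressions).  Hybrid exact exchange is handled
// by the SCF layer through K builds; here only the semilocal part.

#include <RcppArmadillo.h>
#include <cmath>

using namespace Rcpp;

using std::atan;
using std::cbrt;
using std::exp;
using std::log;
using std::pow;
using std::sqrt;

#ifndef M_PI
#define M_PI 3.14159265358979323846
#endif

#include "xc_generated.h"
#include "engine.h"

// Slater exchange, spin channel: energy density (per volume) and potential
static void slater_x(double r, double* e, double* vr) {
  const double Cx = 0.9305257363491;  // (3/4)(3/pi)^{1/3} * 2^{1/3}
  // e = -Cx' sum rho_s^{4/3} with Cx' = (3/4)(3/pi)^{1/3} 2^{1/3}
  double r13 = cbrt(r);
  *e = -Cx * r * r13;
  *vr = -(4.0 / 3.0) * Cx * r13;
}

// PBE exchange for one spin channel: r = 2*rho_s, gg = 4*sigma_ss.
// Returns unpolarized-variable e, vr, vg; caller applies spin-scaling.
static void pbex_unpol(double r, double gg, double* e, double* vr,
                       double* vg) {
  const double Cx = 0.7385587663820224;  // (3/4)(3/pi)^{1/3}
  const double kappa = 0.804, mu = 0.2195149727645171;
  const double c23 = 9.570477545828612;  // (3 pi^2)^{2/3}
  double r13 = cbrt(r);
  double eps = -Cx * r13;               // per-particle unif exchange
  double r83 = r13 * r13 * r * r;       // r^{8/3}
  double s2 = gg / (4.0 * c23 * r83);
  double den = 1.0 + mu * s2 / kappa;
  double Fx = 1.0 + kappa - kappa / den;
  double Fx2 = mu / (den * den);        // dFx/ds2
  *e = r * eps * Fx;
  *vr = (4.0 / 3.0) * eps * (Fx - 2.0 * s2 * Fx2);
  *vg = eps * Fx2 / (4.0 * c23 * r13 * r13 * r);  // eps*Fx2/(4 c23 r^{5/3})
}

struct XCParams {
  double x_slater, x_pbe, c_vwn5, c_pbe;
  bool gga() const { return x_pbe != 0.0 || c_pbe != 0.0; }
};

static XCParams get_params(const List& par) {
  XCParams p;
  p.x_slater = as<double>(par["x_slater"]);
  p.x_pbe = as<double>(par["x_pbe"]);
  p.c_vwn5 = as<double>(par["c_vwn5"]);
  p.c_pbe = as<double>(par["c_pbe"]);
  return p;
}

// point evaluation: densities and contracted gradients ->
// energy density, vrho (2), vsigma (aa, ab, bb)
static void xc_point(const XCParams& p, double ra, double rb, double saa,
                     double sab, double sbb, double* e, double* va, double* vb,
                     double* vsaa, double* vsab, double* vsbb) {
  *e = *va = *vb = *vsaa = *vsab = *vsbb = 0.0;
  const double floor_ = 1e-12;
  double rac = std::max(ra, floor_), rbc = std::max(rb, floor_);
  if (p.x_slater != 0.0) {
    double ea, vba, eb, vbb_;
    slater_x(rac, &ea, &vba);
    slater_x(rbc, &eb, &vbb_);
    // slater_x as written already operates per spin channel:
    // e = -(3/4)(3/pi)^{1/3} 2^{1/3} rho_s^{4/3}
    *e += p.x_slater * (ea + eb);
    *va += p.x_slater * vba;
    *vb += p.x_slater * vbb_;
  }
  if (p.x_pbe != 0.0) {
    double eu, vru, vgu;
    pbex_unpol(2.0 * rac, 4.0 * std::max(saa, 0.0), &eu, &vru, &vgu);
    *e += p.x_pbe * 0.5 * eu;
    *va += p.x_pbe * vru;
    *vsaa += p.x_pbe * 2.0 * vgu;
    pbex_unpol(2.0 * rbc, 4.0 * std::max(sbb, 0.0), &eu, &vru, &vgu);
    *e += p.x_pbe * 0.5 * eu;
    *vb += p.x_pbe * vru;
    *vsbb += p.x_pbe * 2.0 * vgu;
  }
  if (p.c_vwn5 != 0.0) {
    double ec, va_, vb_;
    vwn5_cpot(rac, rbc, &ec, &va_, &vb_);
    *e += p.c_vwn5 * ec;
    *va += p.c_vwn5 * va_;
    *vb += p.c_vwn5 * vb_;
  }
  if (p.c_pbe != 0.0) {
    double g = std::max(saa + 2.0 * sab + sbb, 1e-24);
    double ec, va_, vb_, vg_;
    pbec_cpot(rac, rbc, g, &ec, &va_, &vb_, &vg_);
    *e += p.c_pbe * ec;
    *va += p.c_pbe * va_;
    *vb += p.c_pbe * vb_;
    // d/dsigma_aa = vg, d/dsigma_ab = 2 vg, d/dsigma_bb = vg
    *vsaa += p.c_pbe * vg_;
    *vsab += p.c_pbe * 2.0 * vg_;
    *vsbb += p.c_pbe * vg_;
  }
}

// [[Rcpp::export(name = ".cpp_xc_point")]]
List cpp_xc_point(double ra, double rb, double saa, double sab, double sbb,
                  List par) {
  XCParams p = get_params(par);
  double e, va, vb, vsaa, vsab, vsbb;
  xc_point(p, ra, rb, saa, sab, sbb, &e, &va, &vb, &vsaa, &vsab, &vsbb);
  return List::create(Named("e") = e, Named("vrho_a") = va,
                      Named("vrho_b") = vb, Named("vsigma_aa") = vsaa,
                      Named("vsigma_ab") = vsab, Named("vsigma_bb") = vsbb);
}

// Full grid pass: Exc and Vxc matrices for spin densities Pa, Pb.
// phi-values are recomputed per call in batches (memory-light).
// [[Rcpp::export(name = ".cpp_xc_eval")]]
List cpp_xc_eval(List basis, NumericMatrix pts, NumericVector wts,
                 const arma::mat& Pa, const arma::mat& Pb, List par) {
  XCParams p = get_params(par);
  bool gga = p.gga();
  int np = pts.nrow();
  int M = Pa.n_rows;
  arma::mat Va(M, M, arma::fill::zeros), Vb(M, M, arma::fill::zeros);
  double Exc = 0.0, Na = 0.0, Nb = 0.0;
  const int BATCH = 1024;

  for (int start = 0; start < np; start += BATCH) {
    int nb = std::min(BATCH, np - start);
    NumericMatrix sub(nb, 3);
    for (int i = 0; i < nb; ++i)
      for (int d = 0; d < 3; ++d) sub(i, d) = pts(start + i, d);
    // call the AO evaluator directly (C level)
    List av = ao_values_impl(basis, sub, gga);
    arma::mat phi_full = as<arma::mat>(av["phi"]);
    // active AO columns in this (spatially local) batch
    arma::uvec act = arma::find(arma::max(arma::abs(phi_full), 0).t() > 0.0);
    if (act.n_elem == 0) continue;
    arma::mat phi = phi_full.cols(act);
    arma::mat Pa_s = Pa.submat(act, act), Pb_s = Pb.submat(act, act);
    arma::mat APa = phi * Pa_s, APb = phi * Pb_s;
    arma::vec ra = arma::sum(APa % phi, 1), rb = arma::sum(APb % phi, 1);
    arma::mat gx, gy, gz;
    arma::vec gax, gay, gaz, gbx, gby, gbz;
    if (gga) {
      gx = as<arma::mat>(av["gx"]); gx = gx.cols(act);
      gy = as<arma::mat>(av["gy"]); gy = gy.cols(act);
      gz = as<arma::mat>(av["gz"]); gz = gz.cols(act);
      gax = 2.0 * arma::sum(APa % gx, 1);
      gay = 2.0 * arma::sum(APa % gy, 1);
      gaz = 2.0 * arma::sum(APa % gz, 1);
      gbx = 2.0 * arma::sum(APb % gx, 1);
      gby = 2.0 * arma::sum(APb % gy, 1);
      gbz = 2.0 * arma::sum(APb % gz, 1);
    }
    arma::vec wva(nb, arma::fill::zeros), wvb(nb, arma::fill::zeros);
    arma::vec fax(nb, arma::fill::zeros), fay(nb, arma::fill::zeros),
        faz(nb, arma::fill::zeros), fbx(nb, arma::fill::zeros),
        fby(nb, arma::fill::zeros), fbz(nb, arma::fill::zeros);
    for (int i = 0; i < nb; ++i) {
      double w = wts[start + i];
      double rai = std::max(ra[i], 0.0), rbi = std::max(rb[i], 0.0);
      Na += w * rai;
      Nb += w * rbi;
      if (rai + rbi < 1e-11) continue;
      double saa = 0, sab = 0, sbb = 0;
      if (gga) {
        saa = gax[i] * gax[i] + gay[i] * gay[i] + gaz[i] * gaz[i];
        sbb = gbx[i] * gbx[i] + gby[i] * gby[i] + gbz[i] * gbz[i];
        sab = gax[i] * gbx[i] + gay[i] * gby[i] + gaz[i] * gbz[i];
      }
      double e, va, vb, vsaa, vsab, vsbb;
      xc_point(p, rai, rbi, saa, sab, sbb, &e, &va, &vb, &vsaa, &vsab, &vsbb);
      Exc += w * e;
      wva[i] = w * va;
      wvb[i] = w * vb;
      if (gga) {
        fax[i] = w * (2.0 * vsaa * gax[i] + vsab * gbx[i]);
        fay[i] = w * (2.0 * vsaa * gay[i] + vsab * gby[i]);
        faz[i] = w * (2.0 * vsaa * gaz[i] + vsab * gbz[i]);
        fbx[i] = w * (2.0 * vsbb * gbx[i] + vsab * gax[i]);
        fby[i] = w * (2.0 * vsbb * gby[i] + vsab * gay[i]);
        fbz[i] = w * (2.0 * vsbb * gbz[i] + vsab * gaz[i]);
      }
    }
    // Vxc += phi' diag(wv) phi  (+ gradient terms for GGA)
    arma::mat wphia = phi.each_col() % wva;
    arma::mat wphib = phi.each_col() % wvb;
    Va.submat(act, act) += phi.t() * wphia;
    Vb.submat(act, act) += phi.t() * wphib;
    if (gga) {
      arma::mat Ga = gx.each_col() % fax;
      Ga += gy.each_col() % fay;
      Ga += gz.each_col() % faz;
      arma::mat Gb = gx.each_col() % fbx;
      Gb += gy.each_col() % fby;
      Gb += gz.each_col() % fbz;
      arma::mat Ta = phi.t() * Ga;
      arma::mat Tb = phi.t() * Gb;
      Va.submat(act, act) += Ta + Ta.t();
      Vb.submat(act, act) += Tb + Tb.t();
    }
  }
  return List::create(Named("Exc") = Exc, Named("Vxc_a") = Va,
                      Named("Vxc_b") = Vb, Named("n_alpha") = Na,
                      Named("n_beta") = Nb);
}
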