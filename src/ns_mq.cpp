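// Numerical two-site Bloch-McConnell propagation of methyl 1H-13C
// multiple-quantum coherence through a CPMG element with ideal 180
// degree 13C refocusing pulses. Each pulse swaps the coherence between
// the double-quantum (dwH + dwC) and zero-quantum (dwH - dwC)
// evolution frequencies of the minor state; exchange mixes the two
// states through the kinetic matrix K = [[-kAB, kBA], [kAB, -kBA]].

#include <Rcpp.h>
#include <complex>
using namespace Rcpp;

typedef std::complex<double> cd;

struct M2 { cd a, b, c, d; };  // [[a, b], [c, d]]

static inline M2 mul(const M2& x, const M2& y) {
  return { x.a * y.a + x.b * y.c, x.a * y.b + x.b * y.d,
           x.c * y.a + x.d * y.c, x.c * y.b + x.d * y.d };
}

// exp(M * dt) for a 2x2 complex matrix, via the Cayley-Hamilton
// closed form exp(M) = e^{tr/2} [cosh(s) I + sinch(s) (M - tr/2 I)],
// s^2 = (tr/2)^2 - det.
static M2 expm2(const M2& m, double dt) {
  cd a = m.a * dt, b = m.b * dt, c = m.c * dt, d = m.d * dt;
  cd tr2 = (a + d) * 0.5;
  cd s2 = tr2 * tr2 - (a * d - b * c);
  cd s = std::sqrt(s2);
  cd coshs, sinch;
  if (std::abs(s) < 1e-6) {  // series keeps accuracy near the branch point
    coshs = 1.0 + s2 * 0.5 + s2 * s2 / 24.0;
    sinch = 1.0 + s2 / 6.0 + s2 * s2 / 120.0;
  } else {
    coshs = std::cosh(s);
    sinch = std::sinh(s) / s;
  }
  cd e = std::exp(tr2);
  return { e * (coshs + sinch * (a - tr2)), e * sinch * b,
           e * sinch * c, e * (coshs + sinch * (d - tr2)) };
}

// Evolution generator for one coherence: exchange plus minor-state
// offset precession (major state defines the rotating frame).
static inline M2 gen(double kab, double kba, double dw_eff) {
  return { cd(-kab, 0.0), cd(kba, 0.0),
           cd(kab, 0.0), cd(-kba, dw_eff) };
}

static inline M2 conj2(const M2& m) {
  return { std::conj(m.a), std::conj(m.b), std::conj(m.c), std::conj(m.d) };
}

static M2 mpow(const M2& m, int n) {
  M2 u = { cd(1, 0), cd(0, 0), cd(0, 0), cd(1, 0) };
  for (int i = 0; i < n; ++i) u = mul(u, m);
  return u;
}

// Signal surviving the CPMG element when the coherence starts in the
// state with frequency dw1 and swaps to dw2 at every 13C pulse. One
// cycle = [delta/2] 180C [delta] 180C [delta/2], delta = 1/(2 nu). A
// 1H 180-degree pulse at T/2 negates the 1H part of the MQ frequency,
// which in this two-frequency picture turns every remaining segment
// into the complex conjugate of the other coherence's propagator.
static double survive(int ncyc, double delta, double kab, double kba,
                      double dw1, double dw2, double pa, double pb) {
  M2 e1h = expm2(gen(kab, kba, dw1), delta * 0.5);
  M2 e2h = expm2(gen(kab, kba, dw2), delta * 0.5);
  M2 e1 = expm2(gen(kab, kba, dw1), delta);
  M2 e2 = expm2(gen(kab, kba, dw2), delta);
  M2 cyc1 = mul(e1h, mul(e2, e1h));  // cycle starting in coherence 1
  M2 cyc2 = mul(e2h, mul(e1, e2h));  // cycle starting in coherence 2
  M2 u;
  if (ncyc % 2 == 0) {
    int m = ncyc / 2;
    u = mul(conj2(mpow(cyc2, m)), mpow(cyc1, m));
  } else {
    int m = (ncyc - 1) / 2;
    // the 1H pulse splits the central cycle at the middle of its
    // coherence-2 segment
    M2 q1 = mul(e2h, mul(e1h, mpow(cyc1, m)));
    M2 q2 = mul(mpow(cyc2, m), mul(e2h, e1h));
    u = mul(conj2(q2), q1);
  }
  cd ma = u.a * pa + u.b * pb;  // major-state component
  return ma.real();
}

NumericVector ns_mq_r2eff_cpp(NumericVector nu_cpmg, double t_relax,
                              double pb, double kex, double dwh_rad,
                              double dwc_rad, double r20) {
  if (kex <= 0.0) stop("kex must be > 0");
  if (pb <= 0.0 || pb >= 1.0) stop("pb must be in (0, 1)");
  double pa = 1.0 - pb;
  double kab = pb * kex;  // A -> B
  double kba = pa * kex;  // B -> A (detailed balance pa*kab = pb*kba)
  double dq = dwh_rad + dwc_rad;
  double zq = dwh_rad - dwc_rad;
  int n = nu_cpmg.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double nu = nu_cpmg[i];
    if (!(nu > 0.0)) stop("nu_cpmg must be positive");
    int ncyc = (int)std::lround(nu * t_relax);
    if (ncyc < 1) ncyc = 1;
    double delta = 1.0 / (2.0 * nu);
    // average over the two phase-cycled pathways (start in DQ or ZQ)
    double s = 0.5 * (survive(ncyc, delta, kab, kba, dq, zq, pa, pb) +
                      survive(ncyc, delta, kab, kba, zq, dq, pa, pb));
    if (s <= 0.0) s = 1e-12;  // fully dephased: report a very large rate
    out[i] = r20 - std::log(s / pa) / (ncyc * 2.0 * delta);
  }
  return out;
}
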