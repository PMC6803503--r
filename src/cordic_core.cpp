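// Fixed-point CORDIC arithmetic core and Purkinje-cell simulators.
//
// All fixed-point numbers are integer mantissas under a Q(int,frac) split;
// the single rounding mode is truncation toward -infinity (arithmetic right
// shift), matching shift-register hardware. Euler state accumulators carry
// the full precision of the dt-product (fraction 2*frac); every arithmetic
// tap reads the frac-bit truncation of the accumulator.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

typedef int64_t i64;

static inline i64 shr(i64 x, int s) { return x >> s; } // arithmetic shift, floor
static inline i64 qfloor(double x, int frac) {
  return (i64)std::floor(x * std::ldexp(1.0, frac));
}
static inline double unq(i64 x, int frac) {
  return (double)x * std::ldexp(1.0, -frac);
}

// ---- canonical signed digit decomposition of an integer mantissa ----
struct Csd {
  std::vector<int> pow;  // bit position within the mantissa
  std::vector<int> sgn;  // +1 / -1
};

static Csd csd_of(i64 m) {
  Csd c;
  bool neg = m < 0;
  if (neg) m = -m;
  int i = 0;
  while (m != 0) {
    if (m & 1) {
      int d = ((m & 3) == 3) ? -1 : 1; // ...11 -> -1 with carry
      c.pow.push_back(i);
      c.sgn.push_back(neg ? -d : d);
      m -= d;
    }
    m >>= 1;
    ++i;
  }
  return c;
}

// x * constant via its CSD terms; each right shift truncates
static inline i64 cmul(i64 x, const Csd &c, int frac) {
  i64 acc = 0;
  for (size_t j = 0; j < c.pow.size(); ++j) {
    int sh = c.pow[j] - frac;
    i64 t = (sh >= 0) ? (x << sh) : shr(x, -sh);
    acc += (c.sgn[j] > 0) ? t : -t;
  }
  return acc;
}

// functional shift multiplier: full-width summation of conditionally shifted
// copies (== exact mantissa product), single truncation into the output format
static inline i64 fsm(i64 a, i64 b, int frac) { return shr(a * b, frac); }

// ---- hyperbolic CORDIC tables -------------------------------------------
// schedule 1..iters with repeats at 4, 13, 40, ... (k -> 3k+1)
struct HypTab {
  std::vector<int> sched;
  std::vector<i64> atanh_raw;
  std::vector<double> atanh_d;
  i64 invAh_raw;
  double invAh;
  Csd invln2, ln2c;
  int frac;
  HypTab(int iters, int frac_) : frac(frac_) {
    int rep = 4;
    double Ah = 1.0;
    for (int i = 1; i <= iters; ++i) {
      int times = (i == rep) ? 2 : 1;
      if (i == rep) rep = 3 * rep + 1;
      for (int t = 0; t < times; ++t) {
        double th = std::atanh(std::ldexp(1.0, -i));
        sched.push_back(i);
        atanh_d.push_back(th);
        atanh_raw.push_back(qfloor(th, frac));
        Ah *= std::sqrt(1.0 - std::ldexp(1.0, -2 * i));
      }
    }
    invAh = 1.0 / Ah;
    invAh_raw = qfloor(invAh, frac);
    invln2 = csd_of(qfloor(1.0 / std::log(2.0), frac));
    ln2c = csd_of(qfloor(std::log(2.0), frac));
  }
};

// merged-iteration exponential core: S <- S + q*S*2^-i, |z| within the
// hyperbolic convergence bound
static inline i64 exp_core_fx(i64 z, const HypTab &T) {
  i64 S = T.invAh_raw, Z = z;
  for (size_t j = 0; j < T.sched.size(); ++j) {
    int i = T.sched[j];
    if (Z >= 0) { S += shr(S, i); Z -= T.atanh_raw[j]; }
    else        { S -= shr(S, i); Z += T.atanh_raw[j]; }
  }
  return S;
}

// full-range exponential: theta/ln2 = A + b, e^theta = 2^A * e^(b ln2)
static inline i64 exp_fx(i64 th, const HypTab &T) {
  i64 t = cmul(th, T.invln2, T.frac);
  i64 A = shr(t, T.frac); // floor
  i64 b = t - (A << T.frac);
  i64 S = exp_core_fx(cmul(b, T.ln2c, T.frac), T);
  if (A >= 0) {
    if (A > 62) return S; // far beyond any representable range; caller checks
    return S << A;
  }
  i64 s = -A;
  return (s > 62) ? (S < 0 ? -1 : 0) : shr(S, (int)s);
}

// linear-mode vectoring division with range exponent n: drive Y to zero,
// accumulate the quotient in Z with angle base 2^(n-i), i = 0..iters-1
static inline i64 div_fx(i64 numer, i64 denom, int frac, int iters, int n) {
  if (denom == 0) return 0;
  i64 X = denom, Y = numer, Z = 0;
  for (int i = 0; i < iters; ++i) {
    int q = ((Y >= 0) == (X >= 0)) ? -1 : 1;
    int sh = n - i;
    i64 xs = (sh >= 0) ? (X << sh) : shr(X, -sh);
    Y += q * xs;
    int zs = frac + n - i;
    if (zs >= 0) Z -= q * ((i64)1 << zs);
  }
  return Z;
}

// ---- fixed-point rate functions (Table-1 family) ------------------------
// Composed exclusively of exp_fx, div_fx, cmul, fsm, add/shift.
struct FxModel {
  int frac;
  int div_iters, nrange;
  i64 hinf_lim; // saturation bound of the h_inf exponential node
  HypTab T;
  // rate-law constants
  Csd c0p1, c1_10p7, c1_15, c0p072, c0p2, c1_18, c4p375, c1p15, c1p6, c0p02, c0p01;
  i64 q29p5, q10, q59p4, q33p5, q34p5, q5, q8p9, q20, q43;
  i64 q0p25, q0p15, q0p1, q1;
  // membrane constants (from parameter set)
  Csd cgK, cgNa, cgCa, cgM, cgL;
  i64 qEK, qENa, qECa, qEM, qEL;
  i64 dtm; // mantissa of dt/C: state accumulators advance by X * dtm at frac 2f
  // bookkeeping
  mutable i64 max_hinf_node;
  mutable long n_exp, n_div, n_fsm, n_cmul, n_hinf_sat;

  FxModel(const NumericVector &p, int frac_, int exp_iters, int div_iters_, int nrange_,
          int int_bits_hinf = 14)
    : frac(frac_), div_iters(div_iters_), nrange(nrange_), T(exp_iters, frac_),
      max_hinf_node(0), n_exp(0), n_div(0), n_fsm(0), n_cmul(0), n_hinf_sat(0) {
    hinf_lim = ((i64)1 << (int_bits_hinf - 1 + frac_)) - 1;
    c0p1 = csd_of(qfloor(0.1, frac));   c1_10p7 = csd_of(qfloor(1.0 / 10.7, frac));
    c1_15 = csd_of(qfloor(1.0 / 15.0, frac)); c0p072 = csd_of(qfloor(0.072, frac));
    c0p2 = csd_of(qfloor(0.2, frac));   c1_18 = csd_of(qfloor(1.0 / 18.0, frac));
    c4p375 = csd_of(qfloor(4.375, frac)); c1p15 = csd_of(qfloor(1.15, frac));
    c1p6 = csd_of(qfloor(1.6, frac));   c0p02 = csd_of(qfloor(0.02, frac));
    c0p01 = csd_of(qfloor(0.01, frac));
    q29p5 = qfloor(29.5, frac); q10 = qfloor(10.0, frac); q59p4 = qfloor(59.4, frac);
    q33p5 = qfloor(33.5, frac); q34p5 = qfloor(34.5, frac); q5 = qfloor(5.0, frac);
    q8p9 = qfloor(8.9, frac); q20 = qfloor(20.0, frac); q43 = qfloor(43.0, frac);
    q0p25 = qfloor(0.25, frac); q0p15 = qfloor(0.15, frac); q0p1 = qfloor(0.1, frac);
    q1 = (i64)1 << frac;
    cgK = csd_of(qfloor(p["g_K"], frac));  cgNa = csd_of(qfloor(p["g_Na"], frac));
    cgCa = csd_of(qfloor(p["g_Ca"], frac)); cgM = csd_of(qfloor(p["g_M"], frac));
    cgL = csd_of(qfloor(p["g_L"], frac));
    qEK = qfloor(p["E_K"], frac); qENa = qfloor(p["E_Na"], frac);
    qECa = qfloor(p["E_Ca"], frac); qEM = qfloor(p["E_M"], frac);
    qEL = qfloor(p["E_L"], frac);
    dtm = qfloor(p["dt"] / p["C"], frac);
  }

  i64 E(i64 z) const { ++n_exp; return exp_fx(z, T); }
  i64 D(i64 a, i64 b) const { ++n_div; return div_fx(a, b, frac, div_iters, nrange); }
  i64 M2(i64 a, i64 b) const { ++n_fsm; return fsm(a, b, frac); }
  i64 C2(i64 x, const Csd &c) const { ++n_cmul; return cmul(x, c, frac); }

  i64 sigm(i64 x) const { return D(q1, q1 + E(x)); } // 1/(1+e^x)

  i64 n_inf(i64 V) const { return sigm(-C2(V + q29p5, c0p1)); }
  i64 tau_n(i64 V) const {
    i64 arg = C2(V + q10, c0p1);
    if (arg > 0) arg = -arg; // both branches are 0.25 + 4.375 e^{-|V+10|/10}
    return q0p25 + C2(E(arg), c4p375);
  }
  i64 h_inf(i64 V) const {
    // the exponential node reaches ~8000 and is carried at the wide integer
    // width; past spike peaks it can exceed even that range, where the
    // monotone-saturating datapath clamps it (the effect on the reciprocal
    // is below one LSB)
    i64 e = E(C2(V + q59p4, c1_10p7));
    if (e > max_hinf_node) max_hinf_node = e;
    if (e > hinf_lim) { e = hinf_lim; ++n_hinf_sat; }
    return D(q1, q1 + e);
  }
  i64 tau_h(i64 V) const { return q0p15 + C2(sigm(C2(V + q33p5, c1_15)), c1p15); }
  i64 m_inf(i64 V) const { return sigm(-C2(V + q34p5, c0p1)); }
  i64 alpha_c(i64 V) const { return C2(sigm(-C2(V - q5, c0p072)), c1p6); }
  i64 beta_c(i64 V) const {
    i64 u = V + q8p9;
    i64 den = E(C2(u, c0p2)) - q1;
    if (den == 0) return q0p1; // removable singularity at V = -8.9
    return D(C2(u, c0p02), den);
  }
  i64 alpha_M(i64 V) const { return C2(sigm(-C2(V + q20, c0p2)), c0p02); }
  i64 beta_M(i64 V) const { return C2(E(-C2(V + q43, c1_18)), c0p01); }

  i64 rate(int kind, i64 V) const {
    switch (kind) {
      case 1: return n_inf(V);  case 2: return tau_n(V);
      case 3: return h_inf(V);  case 4: return tau_h(V);
      case 5: return m_inf(V);  case 6: return alpha_c(V);
      case 7: return beta_c(V); case 8: return alpha_M(V);
      case 9: return beta_M(V);
    }
    stop("unknown rate kind");
    return 0;
  }

  // one synchronous step at the frac-2f accumulator level; inputs are the
  // frac-f taps, outputs are accumulator increments
  void step(i64 V, i64 n, i64 h, i64 c, i64 Mg, i64 qI, i64 Isyn,
            i64 *dV, i64 *dn, i64 *dh, i64 *dc, i64 *dM) const {
    i64 m = m_inf(V);
    i64 n2 = M2(n, n), n4 = M2(n2, n2);
    i64 m2 = M2(m, m), m3 = M2(m2, m);
    i64 IK  = C2(M2(n4, V - qEK), cgK);
    i64 INa = C2(M2(M2(m3, h), V - qENa), cgNa);
    i64 ICa = C2(M2(M2(c, c), V - qECa), cgCa);
    i64 IM  = C2(M2(Mg, V - qEM), cgM);
    i64 IL  = C2(V - qEL, cgL);
    *dV = -(IK + INa + ICa + IM + IL + qI + Isyn) * dtm;
    *dn = D(n_inf(V) - n, tau_n(V)) * dtm;
    *dh = D(h_inf(V) - h, tau_h(V)) * dtm;
    *dc = (M2(alpha_c(V), q1 - c) - M2(beta_c(V), c)) * dtm;
    *dM = (M2(alpha_M(V), q1 - Mg) - M2(beta_M(V), Mg)) * dtm;
  }
};

// ---- double-precision reference model -----------------------------------
namespace ref {
static inline double n_inf(double V) { return 1.0 / (1.0 + std::exp(-(V + 29.5) / 10.0)); }
static inline double tau_n(double V) {
  return V <= -10.0 ? 0.25 + 4.375 * std::exp((V + 10.0) / 10.0)
                    : 0.25 + 4.375 * std::exp(-(V + 10.0) / 10.0);
}
static inline double h_inf(double V) { return 1.0 / (1.0 + std::exp((V + 59.4) / 10.7)); }
static inline double tau_h(double V) { return 0.15 + 1.15 / (1.0 + std::exp((V + 33.5) / 15.0)); }
static inline double m_inf(double V) { return 1.0 / (1.0 + std::exp(-(V + 34.5) / 10.0)); }
static inline double alpha_c(double V) { return 1.6 / (1.0 + std::exp(-0.072 * (V - 5.0))); }
static inline double beta_c(double V) {
  double u = V + 8.9;
  if (std::fabs(u) < 1e-6) return 0.1;
  return 0.02 * u / (std::exp(u / 5.0) - 1.0);
}
static inline double alpha_M(double V) { return 0.02 / (1.0 + std::exp(-(V + 20.0) / 5.0)); }
static inline double beta_M(double V) { return 0.01 * std::exp(-(V + 43.0) / 18.0); }
}

struct RefModel {
  double gK, EK, gNa, ENa, gCa, ECa, gM, EM, gL, EL, dtC;
  RefModel(const NumericVector &p) {
    gK = p["g_K"]; EK = p["E_K"]; gNa = p["g_Na"]; ENa = p["E_Na"];
    gCa = p["g_Ca"]; ECa = p["E_Ca"]; gM = p["g_M"]; EM = p["E_M"];
    gL = p["g_L"]; EL = p["E_L"]; dtC = p["dt"] / p["C"];
  }
  void step(double V, double n, double h, double c, double Mg, double I, double Isyn,
            double dt, double *Vn, double *nn, double *hn, double *cn, double *Mn) const {
    double m = ref::m_inf(V);
    double Iion = gK * n * n * n * n * (V - EK) + gNa * m * m * m * h * (V - ENa)
                + gCa * c * c * (V - ECa) + gM * Mg * (V - EM) + gL * (V - EL);
    *Vn = V - (Iion + I + Isyn) * dtC;
    *nn = n + (ref::n_inf(V) - n) / ref::tau_n(V) * dt;
    *hn = h + (ref::h_inf(V) - h) / ref::tau_h(V) * dt;
    *cn = c + (ref::alpha_c(V) * (1 - c) - ref::beta_c(V) * c) * dt;
    *Mn = Mg + (ref::alpha_M(V) * (1 - Mg) - ref::beta_M(V) * Mg) * dt;
  }
};

// ---- exported primitives -------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_exp_core_fx(NumericVector z, int frac, int iters) {
  HypTab T(iters, frac);
  NumericVector out(z.size());
  for (R_xlen_t k = 0; k < z.size(); ++k)
    out[k] = unq(exp_core_fx(qfloor(z[k], frac), T), frac);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_cordic_exp_fx(NumericVector theta, int frac, int iters) {
  HypTab T(iters, frac);
  NumericVector out(theta.size());
  for (R_xlen_t k = 0; k < theta.size(); ++k)
    out[k] = unq(exp_fx(qfloor(theta[k], frac), T), frac);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_cordic_div_fx(NumericVector numer, NumericVector denom,
                                int frac, int iters, int nrange) {
  NumericVector out(numer.size());
  for (R_xlen_t k = 0; k < numer.size(); ++k)
    out[k] = unq(div_fx(qfloor(numer[k], frac), qfloor(denom[k], frac),
                        frac, iters, nrange), frac);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_rate_cordic(int kind, NumericVector V, NumericVector params,
                              int frac, int exp_iters, int div_iters, int nrange,
                              int int_bits_hinf) {
  FxModel F(params, frac, exp_iters, div_iters, nrange, int_bits_hinf);
  NumericVector out(V.size());
  for (R_xlen_t k = 0; k < V.size(); ++k)
    out[k] = unq(F.rate(kind, qfloor(V[k], frac)), frac);
  return out;
}

// ---- simulators ----------------------------------------------------------

static void check_range(double v, double lim, const char *what, long step_idx,
                        int policy, double *slot) {
  if (std::fabs(v) < lim) return;
  if (policy == 0)
    stop("fixed-point overflow: |%s| = %g exceeds the declared integer range "
         "(%g) at step %ld", what, v, lim, step_idx);
  *slot += 1; // saturate policy just counts; the wide accumulator cannot wrap
}

// backend: 0 = reference (double), 1 = cordic fixed point
// [[Rcpp::export]]
List cpp_simulate(NumericVector params, double I, double duration, double discard,
                  NumericVector init, int backend,
                  int frac, int exp_iters, int div_iters, int nrange,
                  int int_bits, int int_bits_hinf, int policy,
                  bool freeze_M, double M_frozen) {
  double dt = params["dt"];
  long nstep = (long)std::llround(duration / dt);
  long nskip = (long)std::llround(discard / dt);
  if (nskip > nstep) nskip = nstep;
  long nrec = nstep - nskip + 1;
  NumericVector tv(nrec), Vv(nrec), nv(nrec), hv(nrec), cv(nrec), Mv(nrec);
  double lim_state = std::ldexp(1.0, int_bits - 1);
  double lim_hinf = std::ldexp(1.0, int_bits_hinf - 1);
  double ovf = 0, maxV = 0, maxg = 0;

  if (backend == 0) {
    RefModel Rm(params);
    double V = init[0], n = init[1], h = init[2], c = init[3], Mg = init[4];
    if (freeze_M) Mg = M_frozen;
    long r = 0;
    for (long k = 0; k <= nstep; ++k) {
      if (k >= nskip) { tv[r] = k * dt; Vv[r] = V; nv[r] = n; hv[r] = h; cv[r] = c; Mv[r] = Mg; ++r; }
      if (k == nstep) break;
      double Vn, nn, hn, cn, Mn;
      Rm.step(V, n, h, c, Mg, I, 0.0, dt, &Vn, &nn, &hn, &cn, &Mn);
      if (!std::isfinite(Vn))
        stop("non-finite membrane potential at step %ld", k + 1);
      V = Vn; n = nn; h = hn; c = cn; Mg = freeze_M ? M_frozen : Mn;
    }
    return List::create(_["t"] = tv, _["V"] = Vv, _["n"] = nv, _["h"] = hv,
                        _["c"] = cv, _["M"] = Mv, _["report"] = R_NilValue);
  }

  FxModel F(params, frac, exp_iters, div_iters, nrange, int_bits_hinf);
  int f2 = 2 * frac;
  i64 V30 = qfloor(init[0], f2), n30 = qfloor(init[1], f2), h30 = qfloor(init[2], f2),
      c30 = qfloor(init[3], f2), M30 = qfloor(freeze_M ? M_frozen : init[4], f2);
  i64 qI = qfloor(I, frac);
  long r = 0;
  for (long k = 0; k <= nstep; ++k) {
    i64 V = shr(V30, frac), n = shr(n30, frac), h = shr(h30, frac),
        c = shr(c30, frac), Mg = shr(M30, frac);
    double Vd = unq(V, frac);
    if (std::fabs(Vd) > maxV) maxV = std::fabs(Vd);
    double gm = std::max(std::max(std::fabs(unq(n, frac)), std::fabs(unq(h, frac))),
                         std::max(std::fabs(unq(c, frac)), std::fabs(unq(Mg, frac))));
    if (gm > maxg) maxg = gm;
    check_range(Vd, lim_state, "V", k, policy, &ovf);
    if (k >= nskip) {
      tv[r] = k * dt; Vv[r] = Vd; nv[r] = unq(n, frac); hv[r] = unq(h, frac);
      cv[r] = unq(c, frac); Mv[r] = unq(Mg, frac); ++r;
    }
    if (k == nstep) break;
    i64 dV, dn, dh, dc, dM;
    F.step(V, n, h, c, Mg, qI, 0, &dV, &dn, &dh, &dc, &dM);
    V30 += dV; n30 += dn; h30 += dh; c30 += dc;
    if (!freeze_M) M30 += dM;
  }
  (void)lim_hinf;
  List report = List::create(
    _["max_abs_V"] = maxV, _["max_abs_gate"] = maxg,
    _["max_hinf_node"] = unq(F.max_hinf_node, frac),
    _["overflow_events"] = ovf,
    _["hinf_saturations"] = (double)F.n_hinf_sat,
    _["ops"] = List::create(_["exp"] = (double)F.n_exp, _["div"] = (double)F.n_div,
                            _["fsm"] = (double)F.n_fsm, _["cmul"] = (double)F.n_cmul));
  return List::create(_["t"] = tv, _["V"] = Vv, _["n"] = nv, _["h"] = hv,
                      _["c"] = cv, _["M"] = Mv, _["report"] = report);
}

// Two coupled cells (Eq.-15-style synapses), either backend.
// Synaptic convention (see package vignette): with s(V) = (1+tanh(V/10))/2,
//   gate z_a (taus tau_a1/tau_a2) driven by the post cell feeds the pre cell:
//     I_syn->pre  = -W * z_a * (V_pre - V_inh)
//   gate z_b (taus tau_b1/tau_b2) driven by the pre cell feeds the post cell:
//     I_syn->post = +inh_scale * W * z_b * (V_post - V_inh)
// both entering the voltage equation through the same -(...)*dt/C sum as I.
// [[Rcpp::export]]
List cpp_simulate_pair(NumericVector params, double Ipre, double Ipost,
                       double duration, double discard, NumericVector init,
                       int backend, bool coupled,
                       double W, double Vinh, double inh_scale,
                       double tau_a1, double tau_a2, double tau_b1, double tau_b2,
                       int frac, int exp_iters, int div_iters, int nrange,
                       int int_bits, int int_bits_hinf, int policy) {
  double dt = params["dt"];
  long nstep = (long)std::llround(duration / dt);
  long nskip = (long)std::llround(discard / dt);
  if (nskip > nstep) nskip = nstep;
  long nrec = nstep - nskip + 1;
  NumericVector tv(nrec);
  NumericMatrix pre(nrec, 5), post(nrec, 5);
  NumericVector za(nrec), zb(nrec);

  if (backend == 0) {
    RefModel Rm(params);
    double V1 = init[0], n1 = init[1], h1 = init[2], c1 = init[3], M1 = init[4];
    double V2 = V1, n2 = n1, h2 = h1, c2 = c1, M2 = M1, z_a = 0, z_b = 0;
    long r = 0;
    for (long k = 0; k <= nstep; ++k) {
      if (k >= nskip) {
        tv[r] = k * dt;
        pre(r, 0) = V1; pre(r, 1) = n1; pre(r, 2) = h1; pre(r, 3) = c1; pre(r, 4) = M1;
        post(r, 0) = V2; post(r, 1) = n2; post(r, 2) = h2; post(r, 3) = c2; post(r, 4) = M2;
        za[r] = z_a; zb[r] = z_b; ++r;
      }
      if (k == nstep) break;
      double Is1 = coupled ? -W * z_a * (V1 - Vinh) : 0.0;
      double Is2 = coupled ? inh_scale * W * z_b * (V2 - Vinh) : 0.0;
      double V1n, n1n, h1n, c1n, M1n, V2n, n2n, h2n, c2n, M2n;
      Rm.step(V1, n1, h1, c1, M1, Ipre, Is1, dt, &V1n, &n1n, &h1n, &c1n, &M1n);
      Rm.step(V2, n2, h2, c2, M2, Ipost, Is2, dt, &V2n, &n2n, &h2n, &c2n, &M2n);
      double s1 = (1.0 + std::tanh(V1 / 10.0)) / 2.0;
      double s2 = (1.0 + std::tanh(V2 / 10.0)) / 2.0;
      double zan = z_a + (s2 * (1 - z_a) / tau_a1 - z_a / tau_a2) * dt;
      double zbn = z_b + (s1 * (1 - z_b) / tau_b1 - z_b / tau_b2) * dt;
      if (!std::isfinite(V1n) || !std::isfinite(V2n))
        stop("non-finite membrane potential at step %ld", k + 1);
      V1 = V1n; n1 = n1n; h1 = h1n; c1 = c1n; M1 = M1n;
      V2 = V2n; n2 = n2n; h2 = h2n; c2 = c2n; M2 = M2n;
      z_a = zan; z_b = zbn;
    }
  } else {
    FxModel F(params, frac, exp_iters, div_iters, nrange, int_bits_hinf);
    int f2 = 2 * frac;
    i64 q1 = (i64)1 << frac;
    i64 V1 = qfloor(init[0], f2), n1 = qfloor(init[1], f2), h1 = qfloor(init[2], f2),
        c1 = qfloor(init[3], f2), M1 = qfloor(init[4], f2);
    i64 V2 = V1, n2 = n1, h2 = h1, c2 = c1, M2 = M1, z_a = 0, z_b = 0;
    i64 qIpre = qfloor(Ipre, frac), qIpost = qfloor(Ipost, frac);
    i64 qW = qfloor(W, frac), qVinh = qfloor(Vinh, frac);
    Csd cscale = csd_of(qfloor(inh_scale, frac));
    Csd ca1 = csd_of(qfloor(1.0 / tau_a1, frac)), ca2 = csd_of(qfloor(1.0 / tau_a2, frac));
    Csd cb1 = csd_of(qfloor(1.0 / tau_b1, frac)), cb2 = csd_of(qfloor(1.0 / tau_b2, frac));
    Csd c0p2 = csd_of(qfloor(0.2, frac));
    long r = 0;
    double lim_state = std::ldexp(1.0, int_bits - 1), ovf = 0;
    for (long k = 0; k <= nstep; ++k) {
      i64 v1 = shr(V1, frac), nn1 = shr(n1, frac), hh1 = shr(h1, frac),
          cc1 = shr(c1, frac), mm1 = shr(M1, frac);
      i64 v2 = shr(V2, frac), nn2 = shr(n2, frac), hh2 = shr(h2, frac),
          cc2 = shr(c2, frac), mm2 = shr(M2, frac);
      i64 zza = shr(z_a, frac), zzb = shr(z_b, frac);
      if (k >= nskip) {
        tv[r] = k * dt;
        pre(r, 0) = unq(v1, frac); pre(r, 1) = unq(nn1, frac); pre(r, 2) = unq(hh1, frac);
        pre(r, 3) = unq(cc1, frac); pre(r, 4) = unq(mm1, frac);
        post(r, 0) = unq(v2, frac); post(r, 1) = unq(nn2, frac); post(r, 2) = unq(hh2, frac);
        post(r, 3) = unq(cc2, frac); post(r, 4) = unq(mm2, frac);
        za[r] = unq(zza, frac); zb[r] = unq(zzb, frac); ++r;
      }
      if (k == nstep) break;
      check_range(unq(v1, frac), lim_state, "V_pre", k, policy, &ovf);
      check_range(unq(v2, frac), lim_state, "V_post", k, policy, &ovf);
      i64 Is1 = coupled ? -F.M2(F.M2(qW, zza), v1 - qVinh) : 0;
      i64 Is2 = coupled ? F.C2(F.M2(F.M2(qW, zzb), v2 - qVinh), cscale) : 0;
      i64 dV1, dn1, dh1, dc1, dM1, dV2, dn2, dh2, dc2, dM2;
      F.step(v1, nn1, hh1, cc1, mm1, qIpre, Is1, &dV1, &dn1, &dh1, &dc1, &dM1);
      F.step(v2, nn2, hh2, cc2, mm2, qIpost, Is2, &dV2, &dn2, &dh2, &dc2, &dM2);
      i64 s1 = F.sigm(-F.C2(v1, c0p2)); // (1+tanh(V/10))/2 == 1/(1+e^{-V/5})
      i64 s2 = F.sigm(-F.C2(v2, c0p2));
      i64 dza = (F.C2(F.M2(s2, q1 - zza), ca1) - F.C2(zza, ca2)) * F.dtm;
      i64 dzb = (F.C2(F.M2(s1, q1 - zzb), cb1) - F.C2(zzb, cb2)) * F.dtm;
      V1 += dV1; n1 += dn1; h1 += dh1; c1 += dc1; M1 += dM1;
      V2 += dV2; n2 += dn2; h2 += dh2; c2 += dc2; M2 += dM2;
      z_a += dza; z_b += dzb;
    }
  }
  colnames(pre) = CharacterVector::create("V", "n", "h", "c", "M");
  colnames(post) = CharacterVector::create("V", "n", "h", "c", "M");
  return List::create(_["t"] = tv, _["pre"] = pre, _["post"] = post,
                      _["z_pre_gate"] = zb, _["z_post_gate"] = za);
}
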