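#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// 0D left-ventricle model: Hill-type calcium-driven activation feeding a
// cross-bridge low-pass stage, exponential passive pressure-volume law,
// constant-preload mitral filling and ejection into a three-element
// Windkessel whose distal pressure relaxes to the aortic pressure parameter.
// Units: kPa, microlitre, ms. z is expected in kPa ms / uL (converted in R).

struct HeartParams {
  double p, ap, z, c1, ca50, kxb, koff, Tref;
};
struct Protocol {
  double cycle, dt;
  int beats, nsteps;
  double caDia, caAmp, caTau;
  double rMitral, rPeriph, cArt, v0, beta, alpha;
};

static inline double ca_pulse(double tl, const Protocol& pr) {
  // single skewed pulse per beat: baseline + amp*(t/tau)*exp(1 - t/tau)
  return pr.caDia + pr.caAmp * (tl / pr.caTau) * std::exp(1.0 - tl / pr.caTau);
}

static inline double lv_pressure(double V, double X, const HeartParams& pm,
                                 const Protocol& pr) {
  double pass = pm.c1 * (std::exp(pr.beta * (V - pr.v0) / pr.v0) - 1.0);
  double act  = pr.alpha * pm.Tref * X * (V / pr.v0);
  return pass + act;
}

struct State { double A, X, V, Pwk; };

static inline void deriv(double tl, const State& s, int phase,
                         const HeartParams& pm, const Protocol& pr,
                         State& ds, double& qa_out) {
  double Ca = ca_pulse(tl, pr);
  double kon = pm.koff / (pm.ca50 * pm.ca50);
  double drive = kon * Ca * Ca;
  ds.A = drive * (1.0 - s.A) - pm.koff * s.A;
  ds.X = pm.kxb * (s.A - s.X);
  double P = lv_pressure(s.V, s.X, pm, pr);
  double qa = 0.0, dV = 0.0;
  if (phase == 0) {            // filling (mitral open)
    dV = (pm.p - P) / pr.rMitral;
  } else if (phase == 2) {     // ejection (aortic open)
    qa = (P - s.Pwk) / pm.z;
    dV = -qa;
  }                            // phases 1,3: isovolumic
  ds.V = dV;
  ds.Pwk = (qa - (s.Pwk - pm.ap) / pr.rPeriph) / pr.cArt;
  qa_out = qa;
}

static inline void rk4_step(double tl, State& s, int phase,
                            const HeartParams& pm, const Protocol& pr) {
  State k1, k2, k3, k4, tmp;
  double q;
  double h = pr.dt;
  deriv(tl, s, phase, pm, pr, k1, q);
  tmp.A = s.A + 0.5 * h * k1.A; tmp.X = s.X + 0.5 * h * k1.X;
  tmp.V = s.V + 0.5 * h * k1.V; tmp.Pwk = s.Pwk + 0.5 * h * k1.Pwk;
  deriv(tl + 0.5 * h, tmp, phase, pm, pr, k2, q);
  tmp.A = s.A + 0.5 * h * k2.A; tmp.X = s.X + 0.5 * h * k2.X;
  tmp.V = s.V + 0.5 * h * k2.V; tmp.Pwk = s.Pwk + 0.5 * h * k2.Pwk;
  deriv(tl + 0.5 * h, tmp, phase, pm, pr, k3, q);
  tmp.A = s.A + h * k3.A; tmp.X = s.X + h * k3.X;
  tmp.V = s.V + h * k3.V; tmp.Pwk = s.Pwk + h * k3.Pwk;
  deriv(tl + h, tmp, phase, pm, pr, k4, q);
  s.A   += h / 6.0 * (k1.A   + 2 * k2.A   + 2 * k3.A   + k4.A);
  s.X   += h / 6.0 * (k1.X   + 2 * k2.X   + 2 * k3.X   + k4.X);
  s.V   += h / 6.0 * (k1.V   + 2 * k2.V   + 2 * k3.V   + k4.V);
  s.Pwk += h / 6.0 * (k1.Pwk + 2 * k2.Pwk + 2 * k3.Pwk + k4.Pwk);
}

// [[Rcpp::export(name = ".simulate_lv")]]
List simulate_lv(NumericVector par, NumericVector proto) {
  HeartParams pm;
  pm.p = par[0]; pm.ap = par[1]; pm.z = par[2]; pm.c1 = par[3];
  pm.ca50 = par[4]; pm.kxb = par[5]; pm.koff = par[6]; pm.Tref = par[7];
  Protocol pr;
  pr.cycle = proto[0]; pr.dt = proto[1]; pr.beats = (int)proto[2];
  pr.caDia = proto[3]; pr.caAmp = proto[4]; pr.caTau = proto[5];
  pr.rMitral = proto[6]; pr.rPeriph = proto[7]; pr.cArt = proto[8];
  pr.v0 = proto[9]; pr.beta = proto[10]; pr.alpha = proto[11];
  pr.nsteps = (int)std::lround(pr.cycle / pr.dt);

  State s;
  // start at passive equilibrium with the preload
  s.A = 0.0; s.X = 0.0;
  s.V = pr.v0 * (1.0 + std::log(1.0 + pm.p / pm.c1) / pr.beta);
  s.Pwk = pm.ap;
  int phase = 0;

  int n = pr.nsteps + 1;
  NumericVector t_out(n), P_out(n), V_out(n);
  double ev_mc = NA_REAL, ev_ao = NA_REAL, ev_ac = NA_REAL, ev_mo = NA_REAL;
  double flow_int = 0.0;
  int status = 0; // 0 ok, 1 no_ejection, 2 numerical_failure

  for (int beat = 0; beat < pr.beats; ++beat) {
    bool final_beat = (beat == pr.beats - 1);
    if (final_beat) {
      ev_mc = ev_ao = ev_ac = ev_mo = NA_REAL;
      flow_int = 0.0;
    }
    for (int k = 0; k < pr.nsteps; ++k) {
      double tl = k * pr.dt;
      if (final_beat) {
        t_out[k] = tl;
        V_out[k] = s.V;
        P_out[k] = lv_pressure(s.V, s.X, pm, pr);
      }
      State s0 = s;
      double P0 = lv_pressure(s0.V, s0.X, pm, pr);
      double qa0 = (phase == 2) ? (P0 - s0.Pwk) / pm.z : 0.0;
      rk4_step(tl, s, phase, pm, pr);
      double P1 = lv_pressure(s.V, s.X, pm, pr);
      double qa1 = (phase == 2) ? (P1 - s.Pwk) / pm.z : 0.0;
      if (phase == 2 && final_beat)
        flow_int += 0.5 * pr.dt * (qa0 + qa1);
      if (!std::isfinite(s.V) || !std::isfinite(s.Pwk) ||
          !std::isfinite(s.A) || s.V <= 0.0) {
        status = 2;
        break;
      }
      // phase transitions, event time by linear interpolation of the trigger
      double tev = NA_REAL;
      if (phase == 0 && P1 >= pm.p) {
        double g0 = P0 - pm.p, g1 = P1 - pm.p;
        tev = tl + pr.dt * (g1 > g0 ? g0 / (g0 - g1) : 1.0);
        if (tev < tl) tev = tl;
        phase = 1;
        if (final_beat && !R_finite(ev_mc)) ev_mc = tev;
      } else if (phase == 1) {
        if (P1 >= s.Pwk) {
          double g0 = P0 - s0.Pwk, g1 = P1 - s.Pwk;
          tev = tl + pr.dt * (g1 > g0 ? g0 / (g0 - g1) : 1.0);
          phase = 2;
          if (final_beat && !R_finite(ev_ao) && R_finite(ev_mc)) ev_ao = tev;
        } else if (P1 < pm.p) {
          phase = 0; // weak beat: activation decayed, mitral reopens
        }
      } else if (phase == 2 && qa1 <= 0.0) {
        double g0 = qa0, g1 = qa1;
        tev = tl + pr.dt * (g0 > g1 ? g0 / (g0 - g1) : 1.0);
        phase = 3;
        if (final_beat && !R_finite(ev_ac) && R_finite(ev_ao)) ev_ac = tev;
      } else if (phase == 3 && P1 <= pm.p) {
        double g0 = P0 - pm.p, g1 = P1 - pm.p;
        tev = tl + pr.dt * (g0 > g1 ? g0 / (g0 - g1) : 1.0);
        phase = 0;
        if (final_beat && !R_finite(ev_mo) && R_finite(ev_ac)) ev_mo = tev;
      }
    }
    if (status == 2) break;
  }
  if (status == 0) {
    t_out[n - 1] = pr.cycle;
    V_out[n - 1] = s.V;
    P_out[n - 1] = lv_pressure(s.V, s.X, pm, pr);
    if (!R_finite(ev_ao)) status = 1; // aortic valve never opened: no ejection
    else if (!(R_finite(ev_mc) && R_finite(ev_ac) && R_finite(ev_mo)))
      status = 1;
  }
  return List::create(
    _["time"] = t_out, _["pressure"] = P_out, _["volume"] = V_out,
    _["events"] = NumericVector::create(
      _["mitral_close"] = ev_mc, _["aortic_open"] = ev_ao,
      _["aortic_close"] = ev_ac, _["mitral_open"] = ev_mo),
    _["flowIntegral"] = flow_int,
    _["status"] = status);
}
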