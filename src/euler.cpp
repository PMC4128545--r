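#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Fixed-step Euler integrator for the delayed-lysis chemostat model.
// The delayed quantities (B_L, P_GL, P_WL) are served from ring buffers of
// round(L/dt) + 1 records; delayed lookups read exactly round(L/dt) steps
// into the past. States driven below zero by the Euler update are clamped
// to zero and the events counted.
//
// State order: B, R, P_G, P_W, I_G, I_W, E.
// [[Rcpp::export]]
List sim_euler_cpp(NumericVector y0,
                   double k, double w, double bG, double bW,
                   double L, double v, double Z, double C,
                   double h_max, double shape, double decay,
                   double t_end, double dt,
                   bool zero_phage_history, int thin) {
  if (y0.size() != 7) stop("state must have 7 components");
  const long m = (long)std::lround(L / dt);
  if (std::fabs(m * dt - L) > 1e-9 * L)
    stop("dt must evenly divide the lysis time L");
  const long nsteps = (long)std::lround(t_end / dt);
  if (nsteps < 1) stop("t_end must cover at least one step");
  if (thin < 1) stop("thin must be >= 1");

  double B = y0[0], R = y0[1], PG = y0[2], PW = y0[3],
         IG = y0[4], IW = y0[5], E = y0[6];

  // history ring: slot (s % (m+1)) holds the state of step s
  const long cap = m + 1;
  std::vector<double> hB(cap), hPG(cap), hPW(cap);
  const double histPG = zero_phage_history ? 0.0 : PG;
  const double histPW = zero_phage_history ? 0.0 : PW;
  for (long i = 0; i < cap; ++i) {
    hB[i] = B; hPG[i] = histPG; hPW[i] = histPW;
  }
  hB[0] = B; hPG[0] = PG; hPW[0] = PW;  // the record at t = 0 is y0 itself

  const double surv = std::exp(-w * L);
  const long nout = nsteps / thin + 1;
  NumericMatrix out(nout, 7);
  NumericVector times(nout);
  out(0, 0) = B; out(0, 1) = R; out(0, 2) = PG; out(0, 3) = PW;
  out(0, 4) = IG; out(0, 5) = IW; out(0, 6) = E;
  times[0] = 0.0;
  long row = 1;
  long clamped = 0;

  for (long s = 1; s <= nsteps; ++s) {
    const long d = ((s - 1 - m) % cap + cap) % cap;  // step s-1-m
    const double BL = hB[d], PGL = hPG[d], PWL = hPW[d];

    const double h = h_max / (1.0 + shape * std::pow(decay, E));
    const double growth = v * (1.0 - (B + R) / C);
    const double burstG = k * PGL * BL * surv;
    const double burstW = k * PWL * BL * surv;
    const double sink = B + IG + IW;

    const double dB  = growth * B - k * PG * B - k * PW * B - w * B + h * R;
    const double dR  = growth * R - h * R;
    const double dPG = bG * burstG - k * PG * sink - w * PG;
    const double dPW = bW * burstW - k * PW * sink - w * PW;
    const double dIG = -burstG + k * PG * B - w * IG;
    const double dIW = -burstW + k * PW * B - w * IW;
    const double dE  = Z * burstG - w * E;

    B += dt * dB; R += dt * dR; PG += dt * dPG; PW += dt * dPW;
    IG += dt * dIG; IW += dt * dIW; E += dt * dE;

    if (B < 0)  { B = 0;  ++clamped; }
    if (R < 0)  { R = 0;  ++clamped; }
    if (PG < 0) { PG = 0; ++clamped; }
    if (PW < 0) { PW = 0; ++clamped; }
    if (IG < 0) { IG = 0; ++clamped; }
    if (IW < 0) { IW = 0; ++clamped; }
    if (E < 0)  { E = 0;  ++clamped; }

    if (!(R_finite(B) && R_finite(R) && R_finite(PG) && R_finite(PW) &&
          R_finite(IG) && R_finite(IW) && R_finite(E)))
      stop("non-finite state at t = %g (B=%g R=%g P_G=%g P_W=%g "
           "I_G=%g I_W=%g E=%g)", s * dt, B, R, PG, PW, IG, IW, E);

    const long slot = s % cap;
    hB[slot] = B; hPG[slot] = PG; hPW[slot] = PW;

    if (s % thin == 0) {
      out(row, 0) = B; out(row, 1) = R; out(row, 2) = PG; out(row, 3) = PW;
      out(row, 4) = IG; out(row, 5) = IW; out(row, 6) = E;
      times[row] = s * dt;
      ++row;
    }
  }

  return List::create(_["times"] = times,
                      _["states"] = out,
                      _["clamp_events"] = (double)clamped);
}
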