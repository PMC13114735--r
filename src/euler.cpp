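// Forward-Euler core for the network reaction-diffusion system.
// The three layer Laplacians arrive as dgCMatrix (CSC); being symmetric,
// column access doubles as row access.  Snapshots are taken every `stride`
// steps and the max-norm residual of the full right-hand side is evaluated
// at each snapshot, so early stopping does not depend on dt.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Csc {
  std::vector<int> p, i;
  std::vector<double> x;
  int n;
  explicit Csc(S4 m) {
    IntegerVector P = m.slot("p"), I = m.slot("i");
    NumericVector X = m.slot("x");
    IntegerVector dim = m.slot("Dim");
    n = dim[0];
    p.assign(P.begin(), P.end());
    i.assign(I.begin(), I.end());
    x.assign(X.begin(), X.end());
  }
  void mv(const std::vector<double>& v, std::vector<double>& out) const {
    std::fill(out.begin(), out.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      const double vj = v[j];
      if (vj != 0.0) {
        for (int k = p[j]; k < p[j + 1]; ++k) out[i[k]] += x[k] * vj;
      }
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".euler_core")]]
List euler_core(S4 Am, S4 Bm, S4 Cm, NumericVector params,
                NumericVector S0, NumericVector I0, NumericVector R0,
                double dt, int n_steps, int stride,
                bool stop_at_steady, double steady_tol) {
  const double r = params["r"], K = params["K"], beta = params["beta"],
    mu1 = params["mu1"], mu2 = params["mu2"], mu3 = params["mu3"],
    alpha = params["alpha"], d1 = params["d1"], d2 = params["d2"],
    d3 = params["d3"];
  const Csc A(Am), B(Bm), C(Cm);
  const int N = S0.size();

  std::vector<double> S(S0.begin(), S0.end()), I(I0.begin(), I0.end()),
    R(R0.begin(), R0.end());
  std::vector<double> LS(N), LI(N), LR(N);

  std::vector<double> times(1, 0.0);
  std::vector<std::vector<double> > snapS(1, S), snapI(1, I), snapR(1, R);

  long clipped = 0;
  bool converged = false;
  double resid = NA_REAL;

  for (int k = 1; k <= n_steps; ++k) {
    A.mv(S, LS); B.mv(I, LI); C.mv(R, LR);
    bool bad = false;
    for (int j = 0; j < N; ++j) {
      const double s = S[j], ii = I[j], inc = beta * s * ii * ii;
      double sn = s + dt * (d1 * LS[j] + r * s * (1.0 - s / K) - inc
                            - mu1 * s);
      double in = ii + dt * (d2 * LI[j] + inc - (mu2 + alpha) * ii);
      double rn = R[j] + dt * (d3 * LR[j] + alpha * ii - mu3 * R[j]);
      if (!std::isfinite(sn) || !std::isfinite(in) || !std::isfinite(rn))
        bad = true;
      if (sn < 0) { sn = 0; ++clipped; }
      if (in < 0) { in = 0; ++clipped; }
      if (rn < 0) { rn = 0; ++clipped; }
      S[j] = sn; I[j] = in; R[j] = rn;
    }
    if (bad)
      stop("integration diverged at step %d (t = %g); use a smaller dt",
           k, k * dt);
    if (k % stride == 0 || k == n_steps) {
      times.push_back(k * dt);
      snapS.push_back(S); snapI.push_back(I); snapR.push_back(R);
      A.mv(S, LS); B.mv(I, LI); C.mv(R, LR);
      double m = 0.0;
      for (int j = 0; j < N; ++j) {
        const double s = S[j], ii = I[j], inc = beta * s * ii * ii;
        m = std::max(m, std::fabs(d1 * LS[j] + r * s * (1.0 - s / K)
                                  - inc - mu1 * s));
        m = std::max(m, std::fabs(d2 * LI[j] + inc - (mu2 + alpha) * ii));
        m = std::max(m, std::fabs(d3 * LR[j] + alpha * ii - mu3 * R[j]));
      }
      resid = m;
      if (stop_at_steady && resid < steady_tol) {
        converged = true;
        break;
      }
    }
  }
  if (!stop_at_steady) converged = (resid < steady_tol);

  const int ns = times.size();
  NumericMatrix outS(N, ns), outI(N, ns), outR(N, ns);
  for (int j = 0; j < ns; ++j)
    for (int i2 = 0; i2 < N; ++i2) {
      outS(i2, j) = snapS[j][i2];
      outI(i2, j) = snapI[j][i2];
      outR(i2, j) = snapR[j][i2];
    }
  return List::create(_["times"] = wrap(times), _["S"] = outS,
                      _["I"] = outI, _["R"] = outR,
                      _["clipped"] = (double)clipped,
                      _["converged"] = converged,
                      _["final_residual"] = resid);
}

// Explicit-Euler core for the spatially homogeneous adoption model
// (S, I, R, N), with an optional recovery-rate switch at t_switch.
// Output rows are linear interpolations at the requested grid times.

// [[Rcpp::export(name = ".adoption_core")]]
NumericMatrix adoption_core(NumericVector params, NumericVector init,
                            NumericVector t_grid, double dt,
                            double t_switch, double alpha_new) {
  const double r = params["r"], K = params["K"], beta = params["beta"],
    mu1 = params["mu1"], mu2 = params["mu2"], mu3 = params["mu3"],
    alpha0 = params["alpha"];
  double S = init[0], I = init[1], R = init[2], N = init[3];
  const int ngrid = t_grid.size();
  NumericMatrix out(ngrid, 4);
  int gi = 0;
  double prev[4] = {S, I, R, N};
  double t_prev = 0.0;
  while (gi < ngrid && t_grid[gi] <= 0) {
    for (int c = 0; c < 4; ++c) out(gi, c) = prev[c];
    ++gi;
  }
  const double tmax = t_grid[ngrid - 1];
  const int n_steps = (int)std::ceil(tmax / dt - 1e-9);
  for (int k = 1; k <= n_steps; ++k) {
    const double t_now = k * dt;
    const double a = (t_prev >= t_switch) ? alpha_new : alpha0;
    const double inc = beta * S * I * I;
    const double dS = r * S * (1.0 - S / K) - inc - mu1 * S;
    const double dI = inc - (mu2 + a) * I;
    const double dR = a * I - mu3 * R;
    S = std::max(0.0, S + dt * dS);
    I = std::max(0.0, I + dt * dI);
    R = std::max(0.0, R + dt * dR);
    N += dt * inc;
    if (!std::isfinite(S) || !std::isfinite(I) || !std::isfinite(R) ||
        !std::isfinite(N))
      stop("forward model diverged at t = %g; use a smaller dt", t_now);
    const double cur[4] = {S, I, R, N};
    while (gi < ngrid && t_grid[gi] <= t_now + 1e-12) {
      const double w = (t_grid[gi] - t_prev) / dt;
      for (int c = 0; c < 4; ++c)
        out(gi, c) = prev[c] + w * (cur[c] - prev[c]);
      ++gi;
    }
    for (int c = 0; c < 4; ++c) prev[c] = cur[c];
    t_prev = t_now;
  }
  return out;
}
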