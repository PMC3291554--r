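// Core numerics: generic conductance-model drift evaluation, Euler-Maruyama
// integration, and the fixed-lag self-organising particle smoother.
//
// A model is passed down as a "descriptor": parameter *indices* into a flat
// parameter vector, so that per-particle parameter vectors can be evaluated
// without touching R.  All randomness comes from R's RNG (norm_rand /
// unif_rand), so set.seed() on the R side gives bit-identical replays.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct GateDesc {
  int state;                 // index into the state vector (dynamic gates)
  int comp;                  // compartment whose voltage drives the gate
  int vhalf, slope;          // param indices
  int tau_mode;              // 0 constant, 1 voltage-dependent bell
  int tau_const;             // param index (constant mode)
  int tau_base, tau_amp, tau_center, tau_width; // param indices (bell mode)
};

struct CurrentDesc {
  int comp;
  int g, e;                  // param indices
  int act_type;              // 0 none, 1 dynamic, 2 instantaneous
  int act_gate;              // row into gates (dynamic)
  int act_vhalf, act_slope;  // param indices (instantaneous activation)
  int act_power;
  int inact_gate;            // -1 if none
  int inact_power;
  int kd;                    // param index, -1 unless calcium-activated
  int is_ca;                 // 1 if the current carries calcium influx
};

struct CaDesc {
  int comp, state;
  int alpha, krem;           // param indices: influx scaling, removal rate
};

struct Model {
  int ncomp, nstate;
  std::vector<int> cm;       // param index per compartment
  int gc, rho;               // param indices, -1 for single compartment
  int sigma_sys, sigma_obs;  // param indices
  std::vector<GateDesc> gates;
  std::vector<CurrentDesc> currents;
  std::vector<CaDesc> pools;
  std::vector<int> pool_of_comp;
};

Model parseModel(const List& desc) {
  Model m;
  m.ncomp = as<int>(desc["ncomp"]);
  m.nstate = as<int>(desc["nstate"]);
  m.cm = as<std::vector<int>>(desc["cm"]);
  m.gc = as<int>(desc["gc_idx"]);
  m.rho = as<int>(desc["rho_idx"]);
  m.sigma_sys = as<int>(desc["sigma_sys_idx"]);
  m.sigma_obs = as<int>(desc["sigma_obs_idx"]);
  IntegerMatrix g = desc["gates"];
  for (int i = 0; i < g.nrow(); ++i) {
    GateDesc gd = {g(i,0), g(i,1), g(i,2), g(i,3), g(i,4), g(i,5), g(i,6),
                   g(i,7), g(i,8), g(i,9)};
    m.gates.push_back(gd);
  }
  IntegerMatrix cu = desc["currents"];
  for (int i = 0; i < cu.nrow(); ++i) {
    CurrentDesc cd = {cu(i,0), cu(i,1), cu(i,2), cu(i,3), cu(i,4), cu(i,5),
                      cu(i,6), cu(i,7), cu(i,8), cu(i,9), cu(i,10), cu(i,11)};
    m.currents.push_back(cd);
  }
  IntegerMatrix ca = desc["ca"];
  m.pool_of_comp.assign(m.ncomp, -1);
  for (int i = 0; i < ca.nrow(); ++i) {
    CaDesc pd = {ca(i,0), ca(i,1), ca(i,2), ca(i,3)};
    m.pools.push_back(pd);
    m.pool_of_comp[pd.comp] = i;
  }
  return m;
}

// Fast internal RNG for the smoother's hot loops (xoshiro256++ with polar
// normal variates).  Seeded from R's RNG, so set.seed() still controls every
// draw and replays are bit-identical.
struct FastRng {
  uint64_t s[4];
  bool haveSpare = false;
  double spare = 0.0;
  void seedFromR() {
    for (int i = 0; i < 4; ++i) {
      uint64_t hi = static_cast<uint64_t>(unif_rand() * 4294967296.0);
      uint64_t lo = static_cast<uint64_t>(unif_rand() * 4294967296.0);
      s[i] = (hi << 32) ^ lo;
    }
    if (!(s[0] | s[1] | s[2] | s[3])) s[0] = 0x9E3779B97F4A7C15ULL;
    for (int i = 0; i < 16; ++i) next();
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double uniform() { // in (0, 1)
    return (static_cast<double>(next() >> 11) + 0.5) * 1.1102230246251565e-16;
  }
  inline double normal() {
    if (haveSpare) { haveSpare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * uniform() - 1.0;
      v = 2.0 * uniform() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    const double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f;
    haveSpare = true;
    return u * f;
  }
};

// Adapter so the simulator keeps using R's RNG directly.
struct RRng {
  inline double uniform() { return unif_rand(); }
  inline double normal() { return norm_rand(); }
};

inline double sigmoid(double v, double vhalf, double slope) {
  return 1.0 / (1.0 + std::exp(-(v - vhalf) / slope));
}

inline double tauOf(const GateDesc& gd, double v, const double* p) {
  if (gd.tau_mode == 0) return p[gd.tau_const];
  const double z = (v - p[gd.tau_center]) / p[gd.tau_width];
  return p[gd.tau_base] + p[gd.tau_amp] / std::cosh(z);
}

inline double ipow(double x, int n) {
  double r = x;
  for (int i = 1; i < n; ++i) r *= x;
  return r;
}

// Deterministic drift of one state block; iinj has one entry per compartment.
void drift(const Model& m, const double* x, const double* iinj,
           const double* p, double* dx) {
  const int nc = m.ncomp;
  double itot[8], icat[8];
  for (int c = 0; c < nc; ++c) { itot[c] = 0.0; icat[c] = 0.0; }

  for (size_t j = 0; j < m.currents.size(); ++j) {
    const CurrentDesc& cd = m.currents[j];
    const double v = x[cd.comp];
    double open = 1.0;
    if (cd.act_type == 1)
      open = ipow(x[m.gates[cd.act_gate].state], cd.act_power);
    else if (cd.act_type == 2)
      open = ipow(sigmoid(v, p[cd.act_vhalf], p[cd.act_slope]), cd.act_power);
    if (cd.inact_gate >= 0)
      open *= ipow(x[m.gates[cd.inact_gate].state], cd.inact_power);
    if (cd.kd >= 0) {
      const double ca = x[m.pools[m.pool_of_comp[cd.comp]].state];
      open *= ca / (ca + p[cd.kd]);
    }
    const double cur = p[cd.g] * open * (v - p[cd.e]);
    itot[cd.comp] += cur;
    if (cd.is_ca) icat[cd.comp] += cur;
  }

  if (nc == 1) {
    dx[0] = (iinj[0] - itot[0]) / p[m.cm[0]];
  } else {
    // soma-dendrite coupling scaled by the soma area ratio rho; injected
    // current is a density relative to each compartment's share of the area
    const double gc = p[m.gc], rho = p[m.rho];
    dx[0] = (iinj[0] / rho - itot[0] - gc / rho * (x[0] - x[1])) / p[m.cm[0]];
    dx[1] = (iinj[1] / (1.0 - rho) - itot[1] -
             gc / (1.0 - rho) * (x[1] - x[0])) / p[m.cm[1]];
  }

  for (size_t j = 0; j < m.gates.size(); ++j) {
    const GateDesc& gd = m.gates[j];
    const double v = x[gd.comp];
    dx[gd.state] = (sigmoid(v, p[gd.vhalf], p[gd.slope]) - x[gd.state]) /
                   tauOf(gd, v, p);
  }
  for (size_t j = 0; j < m.pools.size(); ++j) {
    const CaDesc& pd = m.pools[j];
    dx[pd.state] = -p[pd.alpha] * icat[pd.comp] - p[pd.krem] * x[pd.state];
  }
}

// One Euler-Maruyama substep in place; returns false on voltage blow-up.
template <class RNG>
inline bool emSubstep(const Model& m, double* x, const double* iinj,
                      const double* p, double delta, double sqdelta,
                      double sigmaSys, const double* gateSd, bool anyGateSd,
                      RNG& rng) {
  double dx[32];
  drift(m, x, iinj, p, dx);
  for (int s = 0; s < m.nstate; ++s) x[s] += dx[s] * delta;
  if (sigmaSys > 0.0)
    for (int c = 0; c < m.ncomp; ++c)
      x[c] += sqdelta * sigmaSys * rng.normal();
  if (anyGateSd)
    for (size_t j = 0; j < m.gates.size(); ++j) {
      const int s = m.gates[j].state;
      if (gateSd[s] > 0.0) x[s] += sqdelta * gateSd[s] * rng.normal();
    }
  for (size_t j = 0; j < m.gates.size(); ++j) {
    const int s = m.gates[j].state;
    if (x[s] < 0.0) x[s] = 0.0; else if (x[s] > 1.0) x[s] = 1.0;
  }
  for (size_t j = 0; j < m.pools.size(); ++j) {
    const int s = m.pools[j].state;
    if (x[s] < 0.0) x[s] = 0.0;
  }
  for (int c = 0; c < m.ncomp; ++c)
    if (!std::isfinite(x[c]) || std::fabs(x[c]) > 500.0) return false;
  return true;
}

// Gates at their voltage-dependent steady state, calcium at the equilibrium
// of its linear removal dynamics.
void steadyStates(const Model& m, double* x, const double* p) {
  for (size_t j = 0; j < m.gates.size(); ++j) {
    const GateDesc& gd = m.gates[j];
    x[gd.state] = sigmoid(x[gd.comp], p[gd.vhalf], p[gd.slope]);
  }
  if (!m.pools.empty()) {
    double dx[32];
    double iinj0[8] = {0, 0, 0, 0, 0, 0, 0, 0};
    for (size_t j = 0; j < m.pools.size(); ++j) x[m.pools[j].state] = 0.0;
    drift(m, x, iinj0, p, dx);
    for (size_t j = 0; j < m.pools.size(); ++j) {
      const CaDesc& pd = m.pools[j];
      const double ca_eq = dx[pd.state] / p[pd.krem]; // -alpha*ICa/krem at Ca=0
      x[pd.state] = ca_eq > 0.0 ? ca_eq : 0.0;
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".cppDrift")]]
NumericVector cppDrift(List desc, NumericVector x, NumericVector iinj,
                       NumericVector pvec) {
  Model m = parseModel(desc);
  NumericVector out(m.nstate);
  drift(m, REAL(x), REAL(iinj), REAL(pvec), REAL(out));
  return out;
}

// [[Rcpp::export(name = ".cppSteadyInit")]]
NumericVector cppSteadyInit(List desc, NumericVector v0, NumericVector pvec) {
  Model m = parseModel(desc);
  NumericVector x(m.nstate);
  for (int c = 0; c < m.ncomp; ++c) x[c] = v0[c];
  steadyStates(m, REAL(x), REAL(pvec));
  return x;
}

// Simulate hidden states on the sample grid.  iinjSub holds the injected
// current for every solver substep (nrow = nsamp * k), one column per
// compartment.  Returns (nsamp + 1) x nstate states at sample times, row 0
// being the initial state.
// [[Rcpp::export(name = ".cppSimulate")]]
NumericMatrix cppSimulate(List desc, NumericVector pvec, NumericVector x0,
                          NumericMatrix iinjSub, double delta, int k,
                          double sigmaSys, NumericVector gateSd) {
  Model m = parseModel(desc);
  const int nsub = iinjSub.nrow();
  const int nsamp = nsub / k;
  const double sqdelta = std::sqrt(delta);
  bool anyGateSd = false;
  for (int s = 0; s < m.nstate; ++s) if (gateSd[s] > 0.0) anyGateSd = true;

  RRng rng;
  std::vector<double> x(REAL(x0), REAL(x0) + m.nstate);
  NumericMatrix out(nsamp + 1, m.nstate);
  for (int s = 0; s < m.nstate; ++s) out(0, s) = x[s];

  double iinj[8];
  for (int j = 0; j < nsamp; ++j) {
    for (int q = 0; q < k; ++q) {
      const int row = j * k + q;
      for (int c = 0; c < m.ncomp; ++c) iinj[c] = iinjSub(row, c);
      if (!emSubstep(m, x.data(), iinj, REAL(pvec), delta, sqdelta,
                     sigmaSys, REAL(gateSd), anyGateSd, rng))
        stop("numerical instability: |V| exceeded 500 mV at t = %.3f ms; "
             "use a smaller integration step delta", (row + 1) * delta);
    }
    for (int s = 0; s < m.nstate; ++s) out(j + 1, s) = x[s];
  }
  return out;
}

// [[Rcpp::export(name = ".cppSystematicResample")]]
IntegerVector cppSystematicResample(NumericVector w, double u) {
  const int n = w.size();
  IntegerVector idx(n);
  double cum = w[0];
  int i = 0;
  for (int j = 0; j < n; ++j) {
    const double target = (j + u) / n;
    while (cum < target && i < n - 1) { ++i; cum += w[i]; }
    idx[j] = i + 1; // 1-based for R
  }
  return idx;
}

// ---------------------------------------------------------------------------
// Fixed-lag self-organising smoother.
//
// recs: list of G recordings (groups); each a list with elements
//   y        : nobs x nchan observed voltages
//   chanComp : 0-based compartment index per channel
//   iinjSub  : (nobs - 1) * k x ncomp injected current per substep
// Free parameters are shared across groups; each group carries its own
// hidden-state block.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".cppSmoother")]]
List cppSmoother(List desc, List recs, IntegerVector freeIdx0,
                 NumericVector lo, NumericVector hi, NumericVector pbase,
                 List cfg) {
  Model m = parseModel(desc);
  const int G = recs.size();
  const int S = m.nstate;
  const int Stot = G * S;
  const int nf = freeIdx0.size();
  const int P = pbase.size();

  const int N = as<int>(cfg["n_particles"]);
  const int L = as<int>(cfg["lag"]);
  const double delta = as<double>(cfg["delta"]);
  const int k = as<int>(cfg["k"]);
  const double resThresh = as<double>(cfg["resample_threshold"]);
  const double a = as<double>(cfg["a"]);
  const double b = as<double>(cfg["b"]);
  const double c = as<double>(cfg["c"]);
  const double tauLo = as<double>(cfg["tau_lo"]);
  const double tauHi = as<double>(cfg["tau_hi"]);
  const double jitterRel = as<double>(cfg["jitter"]);
  const int maxDegen = as<int>(cfg["max_degenerate"]);
  NumericVector gateSd = cfg["gate_sd"];
  arma::mat C;
  if (nf > 0) C = as<arma::mat>(cfg["C0"]); else C.set_size(0, 0);

  bool anyGateSd = false;
  for (int s = 0; s < S; ++s) if (gateSd[s] > 0.0) anyGateSd = true;

  FastRng rng;
  rng.seedFromR();

  std::vector<int> freeIdx(freeIdx0.begin(), freeIdx0.end());

  std::vector<NumericMatrix> Y, Isub;
  std::vector<std::vector<int>> chanComp;
  int nobs = -1;
  for (int g = 0; g < G; ++g) {
    List r = recs[g];
    NumericMatrix y = r["y"];
    if (nobs < 0) nobs = y.nrow();
    else if (y.nrow() != nobs) stop("recordings have mismatched lengths");
    Y.push_back(y);
    Isub.push_back(as<NumericMatrix>(r["iinjSub"]));
    chanComp.push_back(as<std::vector<int>>(r["chanComp"]));
  }

  const int ring = L + 1;
  const int extDim = Stot + nf + 1; // states, free parameters, tau
  std::vector<double> X(static_cast<size_t>(N) * Stot);
  std::vector<double> par(static_cast<size_t>(N) * P);
  std::vector<double> theta(static_cast<size_t>(N) * std::max(nf, 1));
  std::vector<double> tau(N);
  std::vector<double> w(N, 1.0 / N), logw(N);
  std::vector<double> buf(static_cast<size_t>(N) * ring * extDim);
  // amap[slot*N + i]: buffer row holding the time-'slot' ancestor of the
  // current particle i; resampling composes indices instead of copying the
  // whole lag window
  std::vector<int> amap(static_cast<size_t>(N) * ring);
  std::vector<double> mi(std::max(nf, 1)), Evec(std::max(nf, 1));
  arma::mat Cov(nf, nf);

  NumericMatrix thetaMean(nobs, nf), thetaSd(nobs, nf);
  NumericMatrix smoothed(nobs, Stot);
  NumericVector essOut(nobs), tauMean(nobs), traceC(nobs);
  LogicalVector resampled(nobs);
  IntegerVector boundHits(nf);
  std::vector<char> smoothedDone(nobs, 0);

  const double sqdelta = std::sqrt(delta);

  // --- initialisation: parameters uniform in the prior box, voltages around
  // the first observation, gates at steady state ----------------------------
  for (int i = 0; i < N; ++i) {
    double* pv = &par[static_cast<size_t>(i) * P];
    std::copy(pbase.begin(), pbase.end(), pv);
    for (int f = 0; f < nf; ++f) {
      const double v = lo[f] + rng.uniform() * (hi[f] - lo[f]);
      theta[static_cast<size_t>(i) * nf + f] = v;
      pv[freeIdx[f]] = v;
    }
    tau[i] = tauLo + rng.uniform() * (tauHi - tauLo);
    const double sobs = pv[m.sigma_obs];
    // one jitter draw per compartment, shared across trace groups, so that
    // identical traces start from identical states
    double jit[8];
    for (int cc = 0; cc < m.ncomp; ++cc) jit[cc] = sobs * rng.normal();
    for (int g = 0; g < G; ++g) {
      double* x = &X[static_cast<size_t>(i) * Stot + g * S];
      for (int cc = 0; cc < m.ncomp; ++cc) {
        int ch = 0;
        for (size_t q = 0; q < chanComp[g].size(); ++q)
          if (chanComp[g][q] == cc) ch = static_cast<int>(q);
        x[cc] = Y[g](0, ch) + jit[cc];
      }
      steadyStates(m, x, pv);
    }
  }

  auto storeRing = [&](int slot) {
    for (int i = 0; i < N; ++i) {
      amap[static_cast<size_t>(slot) * N + i] = i;
      double* dst = &buf[(static_cast<size_t>(i) * ring + slot) * extDim];
      std::copy(&X[static_cast<size_t>(i) * Stot],
                &X[static_cast<size_t>(i) * Stot] + Stot, dst);
      if (nf > 0)
        std::copy(&theta[static_cast<size_t>(i) * nf],
                  &theta[static_cast<size_t>(i) * nf] + nf, dst + Stot);
      dst[Stot + nf] = tau[i];
    }
  };
  auto weightedStateMean = [&](int slot, int t) {
    const int* am = &amap[static_cast<size_t>(slot) * N];
    for (int s = 0; s < Stot; ++s) {
      double acc = 0.0;
      for (int i = 0; i < N; ++i)
        acc += w[i] *
               buf[(static_cast<size_t>(am[i]) * ring + slot) * extDim + s];
      smoothed(t, s) = acc;
    }
    smoothedDone[t] = 1;
  };
  auto recordTheta = [&](int t) {
    for (int f = 0; f < nf; ++f) {
      double mu = 0.0, m2 = 0.0;
      for (int i = 0; i < N; ++i)
        mu += w[i] * theta[static_cast<size_t>(i) * nf + f];
      for (int i = 0; i < N; ++i) {
        const double d = theta[static_cast<size_t>(i) * nf + f] - mu;
        m2 += w[i] * d * d;
      }
      thetaMean(t, f) = mu;
      thetaSd(t, f) = std::sqrt(m2);
    }
    double tm = 0.0;
    for (int i = 0; i < N; ++i) tm += w[i] * tau[i];
    tauMean[t] = tm;
  };

  storeRing(0);
  recordTheta(0);
  essOut[0] = N;
  traceC[0] = nf > 0 ? arma::trace(C) : 0.0;

  int degen = 0, nRes = 0;
  double iinj[8];

  for (int t = 1; t < nobs; ++t) {
    if (t % 256 == 0) Rcpp::checkUserInterrupt();

    // Step 1a: weighted mean and covariance of the parameter sample
    if (nf > 0) {
      for (int f = 0; f < nf; ++f) {
        double acc = 0.0;
        for (int i = 0; i < N; ++i)
          acc += w[i] * theta[static_cast<size_t>(i) * nf + f];
        Evec[f] = acc;
      }
      Cov.zeros();
      for (int i = 0; i < N; ++i) {
        const double* th = &theta[static_cast<size_t>(i) * nf];
        for (int f = 0; f < nf; ++f)
          for (int g2 = f; g2 < nf; ++g2)
            Cov(f, g2) += w[i] * (th[f] - Evec[f]) * (th[g2] - Evec[g2]);
      }
      for (int f = 0; f < nf; ++f)
        for (int g2 = 0; g2 < f; ++g2) Cov(f, g2) = Cov(g2, f);

      // Step 1d (shared across particles): slow covariance adaptation
      C = (1.0 - b) * C + b * Cov;
      double mdiag = arma::trace(C) / nf;
      double jit = jitterRel * mdiag;
      if (jit < 1e-300) jit = 1e-300;
      arma::mat R;
      bool ok = false;
      for (int attempt = 0; attempt < 8 && !ok; ++attempt) {
        ok = arma::chol(R, C + jit * arma::eye(nf, nf));
        if (!ok) jit *= 100.0;
      }
      if (!ok)
        stop("covariance factorisation failed (trace = %g)", arma::trace(C));

      // Steps 1b, 1c, 1e per particle: scale, mean, parameter sample
      std::vector<double> xi(nf);
      for (int i = 0; i < N; ++i) {
        double tnew = tau[i] * std::exp(c * rng.normal());
        if (tnew < tauLo) tnew = tauLo; else if (tnew > tauHi) tnew = tauHi;
        tau[i] = tnew;
        double* th = &theta[static_cast<size_t>(i) * nf];
        double* pv = &par[static_cast<size_t>(i) * P];
        for (int f = 0; f < nf; ++f) {
          mi[f] = th[f] + a * (Evec[f] - th[f]);
          xi[f] = rng.normal();
        }
        for (int f = 0; f < nf; ++f) {
          double v = mi[f];
          for (int g2 = 0; g2 <= f; ++g2) v += tnew * R(g2, f) * xi[g2];
          if (v < lo[f]) { v = lo[f]; ++boundHits[f]; }
          else if (v > hi[f]) { v = hi[f]; ++boundHits[f]; }
          th[f] = v;
          pv[freeIdx[f]] = v;
        }
      }
      traceC[t] = arma::trace(C);
    }

    // Step 1f: propagate hidden states through k Euler-Maruyama substeps
    // (proposal = transition density, so weights are untouched here)
    for (int i = 0; i < N; ++i) {
      double* pv = &par[static_cast<size_t>(i) * P];
      const double ssys = pv[m.sigma_sys];
      bool alive = true;
      for (int g = 0; g < G && alive; ++g) {
        double* x = &X[static_cast<size_t>(i) * Stot + g * S];
        const NumericMatrix& I = Isub[g];
        for (int q = 0; q < k && alive; ++q) {
          const int row = (t - 1) * k + q;
          for (int cc = 0; cc < m.ncomp; ++cc) iinj[cc] = I(row, cc);
          alive = emSubstep(m, x, iinj, pv, delta, sqdelta, ssys,
                            REAL(gateSd), anyGateSd, rng);
        }
      }
      // Steps 2-3: likelihood weighting (log domain)
      if (!alive) {
        logw[i] = -std::numeric_limits<double>::infinity();
        continue;
      }
      const double sobs = pv[m.sigma_obs];
      double ll = 0.0;
      for (int g = 0; g < G; ++g) {
        const double* x = &X[static_cast<size_t>(i) * Stot + g * S];
        for (size_t ch = 0; ch < chanComp[g].size(); ++ch) {
          const double r = Y[g](t, ch) - x[chanComp[g][ch]];
          ll += -0.918938533204672742 - std::log(sobs) -
                0.5 * r * r / (sobs * sobs);
        }
      }
      logw[i] = std::log(w[i]) + ll;
    }

    // normalise in the log domain
    double mx = -std::numeric_limits<double>::infinity();
    for (int i = 0; i < N; ++i) if (logw[i] > mx) mx = logw[i];
    if (!std::isfinite(mx)) {
      if (++degen > maxDegen)
        stop("degenerate ensemble at observation %d: all importance weights "
             "underflowed; check sigma_obs and the integration step", t + 1);
      for (int i = 0; i < N; ++i) w[i] = 1.0 / N;
    } else {
      double sum = 0.0;
      for (int i = 0; i < N; ++i) { w[i] = std::exp(logw[i] - mx); sum += w[i]; }
      for (int i = 0; i < N; ++i) w[i] /= sum;
      degen = 0;
    }

    // bookkeeping before any resampling
    storeRing(t % ring);
    recordTheta(t);
    double ess = 0.0;
    for (int i = 0; i < N; ++i) ess += w[i] * w[i];
    ess = 1.0 / ess;
    essOut[t] = ess;
    if (t >= L) weightedStateMean((t - L) % ring, t - L);

    // ESS-triggered systematic resampling of whole lag windows
    if (ess < resThresh * N) {
      resampled[t] = true;
      ++nRes;
      const double u = rng.uniform();
      std::vector<int> idx(N);
      {
        double cum = w[0];
        int i = 0;
        for (int j = 0; j < N; ++j) {
          const double target = (j + u) / N;
          while (cum < target && i < N - 1) { ++i; cum += w[i]; }
          idx[j] = i;
        }
      }
      std::vector<double> X2(X.size()), par2(par.size()), th2(theta.size());
      std::vector<double> tau2(N);
      for (int j = 0; j < N; ++j) {
        const int i = idx[j];
        std::copy(&X[static_cast<size_t>(i) * Stot],
                  &X[static_cast<size_t>(i) * Stot] + Stot,
                  &X2[static_cast<size_t>(j) * Stot]);
        std::copy(&par[static_cast<size_t>(i) * P],
                  &par[static_cast<size_t>(i) * P] + P,
                  &par2[static_cast<size_t>(j) * P]);
        if (nf > 0)
          std::copy(&theta[static_cast<size_t>(i) * nf],
                    &theta[static_cast<size_t>(i) * nf] + nf,
                    &th2[static_cast<size_t>(j) * nf]);
        tau2[j] = tau[i];
      }
      X.swap(X2); par.swap(par2); theta.swap(th2); tau.swap(tau2);
      // compose the ancestor maps of every stored time with the selection
      std::vector<int> arow(N);
      const int depth = std::min(t + 1, ring);
      for (int sl = 0; sl < depth; ++sl) {
        int* am = &amap[static_cast<size_t>(sl) * N];
        for (int j = 0; j < N; ++j) arow[j] = am[idx[j]];
        std::copy(arow.begin(), arow.end(), am);
      }
      std::fill(w.begin(), w.end(), 1.0 / N);
    }
  }

  // backfill smoothed estimates not yet produced (tail, and head of short runs)
  for (int s = nobs - 1; s >= 0; --s)
    if (!smoothedDone[s] && nobs - 1 - s <= L)
      weightedStateMean(s % ring, s);

  return List::create(
      _["theta_mean"] = thetaMean, _["theta_sd"] = thetaSd,
      _["smoothed_states"] = smoothed, _["ess"] = essOut,
      _["tau_mean"] = tauMean, _["trace_C"] = traceC,
      _["resampled"] = resampled, _["bound_hits"] = boundHits,
      _["n_resample"] = nRes, _["C_final"] = wrap(C));
}
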