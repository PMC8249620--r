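#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Signal-modulated edge rate. mode: 0 = no signal edge (basal k), 1 = enhance
// (k + b*s), 2 = suppress saturating (k / (1 + b*s)), 3 = suppress linear
// (k * max(0, 1 - b*s)).
static inline double edge_rate(double k, double b, double s, int mode) {
  switch (mode) {
    case 1: return k + b * s;
    case 2: return k / (1.0 + b * s);
    case 3: return k * std::max(0.0, 1.0 - b * s);
    default: return k;
  }
}

static inline double smooth_signal(double t, double r1, double r2) {
  return std::exp(-r1 * t) * (1.0 - std::exp(-r2 * t));
}

// Piecewise-constant signal lookup: value[j] on [times[j], times[j+1]).
static inline double table_signal(double t, const std::vector<double>& bt,
                                  const std::vector<double>& bv) {
  size_t j = std::upper_bound(bt.begin(), bt.end(), t) - bt.begin();
  if (j == 0) return bv[0];
  return bv[j - 1];
}

struct SigSpec {
  int mode;          // see edge_rate()
  double k, b;       // basal rate and signal coefficient of the signal edge
  double r1, r2;     // smooth two-exponential signal
  bool use_table;
  std::vector<double> bt, bv;  // step-table breakpoints and values
  double s(double t) const {
    if (use_table) return table_signal(t, bt, bv);
    return smooth_signal(t, r1, r2);
  }
  double rate(double t) const { return edge_rate(k, b, s(t), mode); }
};

// y' = A_base y + k_sig(t) E y ; sink' = leak . y   (CSC sparse matrices)
struct FspRhs {
  int n;
  const int *Ap, *Ai; const double *Ax;
  const int *Ep, *Ei; const double *Ex;
  const double *leak;
  SigSpec sig;

  void operator()(double t, const std::vector<double>& y,
                  std::vector<double>& dy) const {
    std::fill(dy.begin(), dy.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      const double yj = y[j];
      if (yj == 0.0) continue;
      for (int p = Ap[j]; p < Ap[j + 1]; ++p) dy[Ai[p]] += Ax[p] * yj;
    }
    if (sig.mode != 0) {
      const double ks = sig.rate(t);
      for (int j = 0; j < n; ++j) {
        const double v = ks * y[j];
        if (v == 0.0) continue;
        for (int p = Ep[j]; p < Ep[j + 1]; ++p) dy[Ei[p]] += Ex[p] * v;
      }
    }
    double ds = 0.0;
    for (int j = 0; j < n; ++j) ds += leak[j] * y[j];
    dy[n] = ds;
  }
};

// Dormand-Prince 5(4) adaptive step from t to t_end (t_end hit exactly).
static void dopri5_segment(const FspRhs& rhs, std::vector<double>& y,
                           double t, double t_end, double rtol, double atol,
                           double* h_io, long* n_accept, long* n_reject) {
  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                      a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                      a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                      b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                      e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

  const int m = (int)y.size();
  std::vector<double> k1(m), k2(m), k3(m), k4(m), k5(m), k6(m), k7(m), yt(m),
      ynew(m);
  double h = *h_io;
  if (h <= 0.0) h = (t_end - t) / 100.0;
  bool first = true;
  long iter = 0;
  const long max_iter = 100000000L;

  rhs(t, y, k1);
  while (t < t_end) {
    if (++iter > max_iter) stop("FSP integrator exceeded the step budget");
    if (h > t_end - t) h = t_end - t;
    for (int i = 0; i < m; ++i) yt[i] = y[i] + h * a21 * k1[i];
    rhs(t + c2 * h, yt, k2);
    for (int i = 0; i < m; ++i) yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    rhs(t + c3 * h, yt, k3);
    for (int i = 0; i < m; ++i)
      yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    rhs(t + c4 * h, yt, k4);
    for (int i = 0; i < m; ++i)
      yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    rhs(t + c5 * h, yt, k5);
    for (int i = 0; i < m; ++i)
      yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                          a64 * k4[i] + a65 * k5[i]);
    rhs(t + h, yt, k6);
    for (int i = 0; i < m; ++i)
      ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                            b5 * k5[i] + b6 * k6[i]);
    rhs(t + h, ynew, k7);

    double err = 0.0;
    for (int i = 0; i < m; ++i) {
      const double ei = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                             e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
      const double sc = atol + rtol * std::max(std::fabs(y[i]),
                                               std::fabs(ynew[i]));
      const double r = ei / sc;
      err += r * r;
    }
    err = std::sqrt(err / m);

    if (err <= 1.0 || h <= 1e-12 * std::max(1.0, t)) {
      t += h;
      y.swap(ynew);
      k1.swap(k7);  // FSAL
      first = false;
      ++*n_accept;
    } else {
      rhs(t, y, k1);  // k1 for retry from same point (swap-safe recompute)
      ++*n_reject;
    }
    double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
    fac = std::min(5.0, std::max(0.2, fac));
    h *= fac;
    if (first && err > 1.0) h = std::max(h, 1e-10);
  }
  *h_io = h;
}

// counting-sort triplets (1-based i, j) into CSC; duplicates are kept
// (matvec accumulates them), rows within a column stay unsorted
static void build_csc(int n, const IntegerVector& ti, const IntegerVector& tj,
                      const NumericVector& tx, std::vector<int>& Ap,
                      std::vector<int>& Ai, std::vector<double>& Ax) {
  const int nnz = ti.size();
  Ap.assign(n + 1, 0);
  for (int t = 0; t < nnz; ++t) Ap[tj[t]]++;
  for (int j = 0; j < n; ++j) Ap[j + 1] += Ap[j];
  Ai.resize(nnz);
  Ax.resize(nnz);
  std::vector<int> pos(Ap.begin(), Ap.end() - 1);
  for (int t = 0; t < nnz; ++t) {
    const int p = pos[tj[t] - 1]++;
    Ai[p] = ti[t] - 1;
    Ax[p] = tx[t];
  }
}

// [[Rcpp::export]]
List fsp_integrate_cpp(int n, IntegerVector Ati, IntegerVector Atj,
                       NumericVector Atx, IntegerVector Eti, IntegerVector Etj,
                       NumericVector Etx, NumericVector leak, List sig_spec,
                       NumericVector p0, NumericVector out_times, double rtol,
                       double atol) {
  std::vector<int> Ap, Ai, Ep, Ei;
  std::vector<double> Ax, Ex;
  build_csc(n, Ati, Atj, Atx, Ap, Ai, Ax);
  build_csc(n, Eti, Etj, Etx, Ep, Ei, Ex);
  SigSpec sig;
  sig.mode = as<int>(sig_spec["mode"]);
  sig.k = as<double>(sig_spec["k"]);
  sig.b = as<double>(sig_spec["b"]);
  sig.r1 = as<double>(sig_spec["r1"]);
  sig.r2 = as<double>(sig_spec["r2"]);
  sig.use_table = as<bool>(sig_spec["use_table"]);
  if (sig.use_table) {
    NumericVector bt = sig_spec["table_times"], bv = sig_spec["table_values"];
    sig.bt.assign(bt.begin(), bt.end());
    sig.bv.assign(bv.begin(), bv.end());
  }

  FspRhs rhs;
  rhs.n = n;
  rhs.Ap = Ap.data(); rhs.Ai = Ai.data(); rhs.Ax = Ax.data();
  rhs.Ep = Ep.data(); rhs.Ei = Ei.data(); rhs.Ex = Ex.data();
  rhs.leak = leak.begin();
  rhs.sig = sig;

  const int T = out_times.size();
  NumericMatrix prob(n, T);
  NumericVector sink(T);
  std::vector<double> y(p0.begin(), p0.end());
  y.push_back(0.0);  // sink mass

  // checkpoints: output times plus signal-table breakpoints (discontinuities)
  std::vector<double> cps(out_times.begin(), out_times.end());
  if (sig.use_table) {
    for (double b : sig.bt)
      if (b > out_times[0] && b < out_times[T - 1]) cps.push_back(b);
  }
  std::sort(cps.begin(), cps.end());
  cps.erase(std::unique(cps.begin(), cps.end()), cps.end());

  double t = out_times[0];
  int oi = 0;
  if (cps[0] == t) {
    for (int i = 0; i < n; ++i) prob(i, 0) = y[i];
    sink[0] = y[n];
    ++oi;
  }
  double h = 0.0;
  long n_accept = 0, n_reject = 0;
  for (size_t c = 1; c < cps.size(); ++c) {
    dopri5_segment(rhs, y, t, cps[c], rtol, atol, &h, &n_accept, &n_reject);
    t = cps[c];
    if (oi < T && out_times[oi] == t) {
      for (int i = 0; i < n; ++i) prob(i, oi) = y[i];
      sink[oi] = y[n];
      ++oi;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["prob"] = prob, _["sink"] = sink,
                      _["n_accept"] = (double)n_accept,
                      _["n_reject"] = (double)n_reject);
}

// ---------------------------------------------------------------------------
// Stationary distribution by shifted inverse iteration with a banded LU.
// The generator on (gene state, count) space has half-bandwidth kd =
// n_states (switching couples g +/- 1, transcription/degradation couples
// x +/- 1, i.e. index +/- n_states). The shifted matrix A - shift*I is
// strictly column diagonally dominant, so LU without pivoting is stable.

// [[Rcpp::export]]
NumericVector stationary_banded_cpp(int n, int kd, IntegerVector ti,
                                    IntegerVector tj, NumericVector tx,
                                    double shift, int iters) {
  const int ld = 2 * kd + 1;
  std::vector<double> ab((size_t)ld * n, 0.0);
  // band storage: entry (i, j) at ab[(i - j + kd) + ld * j]
  for (int t = 0; t < ti.size(); ++t) {
    int i = ti[t] - 1, j = tj[t] - 1;
    ab[(size_t)(i - j + kd) + (size_t)ld * j] += tx[t];
  }
  for (int j = 0; j < n; ++j) ab[(size_t)kd + (size_t)ld * j] -= shift;

  // in-place banded LU (no pivoting); L factors stored below the diagonal
  for (int j = 0; j < n; ++j) {
    const double piv = ab[(size_t)kd + (size_t)ld * j];
    if (piv == 0.0) stop("singular banded system");
    const int imax = std::min(n - 1, j + kd);
    for (int i = j + 1; i <= imax; ++i) {
      double &lij = ab[(size_t)(i - j + kd) + (size_t)ld * j];
      if (lij == 0.0) continue;
      lij /= piv;
      const int jmax = std::min(n - 1, j + kd);
      for (int c = j + 1; c <= jmax; ++c) {
        // a(i, c) -= l(i, j) * a(j, c), both within the band
        if (i - c >= -kd && i - c <= kd)
          ab[(size_t)(i - c + kd) + (size_t)ld * c] -=
              lij * ab[(size_t)(j - c + kd) + (size_t)ld * c];
      }
    }
  }

  std::vector<double> x(n, 1.0 / n);
  for (int it = 0; it < iters; ++it) {
    // forward substitution (unit lower triangular)
    for (int j = 0; j < n; ++j) {
      const double xj = x[j];
      if (xj == 0.0) continue;
      const int imax = std::min(n - 1, j + kd);
      for (int i = j + 1; i <= imax; ++i)
        x[i] -= ab[(size_t)(i - j + kd) + (size_t)ld * j] * xj;
    }
    // back substitution
    for (int j = n - 1; j >= 0; --j) {
      const int imax = std::min(n - 1, j + kd);
      for (int i = j + 1; i <= imax; ++i)
        x[j] -= ab[(size_t)(j - i + kd) + (size_t)ld * i] * x[i];
      x[j] /= ab[(size_t)kd + (size_t)ld * j];
    }
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += x[j];
    for (int j = 0; j < n; ++j) x[j] /= s;
  }
  NumericVector out(n);
  for (int j = 0; j < n; ++j) out[j] = std::max(x[j], 0.0);
  double s = 0.0;
  for (int j = 0; j < n; ++j) s += out[j];
  for (int j = 0; j < n; ++j) out[j] /= s;
  return out;
}

// ---------------------------------------------------------------------------
// Exact SSA for the time-inhomogeneous gene model, by thinning against a
// per-interval upper bound on the signal-edge rate. Uses R's RNG (seed with
// set.seed() on the R side).

struct SsaModel {
  int n_states;
  std::vector<int> efrom, eto;        // non-signal switching edges
  std::vector<double> erate;
  int sig_from, sig_to, sig_mode;     // signal edge (mode 0 = none)
  double sig_k, sig_b;
  double r1, r2, tpeak;
  std::vector<double> alpha;
  double delta;

  // extreme of s(t) over [t0, t1]: s is unimodal with peak at tpeak
  double s_max(double t0, double t1) const {
    double m = std::max(smooth_signal(t0, r1, r2), smooth_signal(t1, r1, r2));
    if (tpeak > t0 && tpeak < t1)
      m = std::max(m, smooth_signal(tpeak, r1, r2));
    return m;
  }
  double s_min(double t0, double t1) const {
    return std::min(smooth_signal(t0, r1, r2), smooth_signal(t1, r1, r2));
  }
  // upper bound on the signal-edge rate over [t0, t1]
  double sig_rate_bound(double t0, double t1) const {
    if (sig_mode == 1) return sig_k + sig_b * s_max(t0, t1);
    if (sig_mode == 2) return sig_k / (1.0 + sig_b * s_min(t0, t1));
    if (sig_mode == 3)
      return sig_k * std::max(0.0, 1.0 - sig_b * s_min(t0, t1));
    return 0.0;
  }
  double sig_rate_at(double t) const {
    return edge_rate(sig_k, sig_b, smooth_signal(t, r1, r2), sig_mode);
  }
};

// [[Rcpp::export]]
List ssa_cells_cpp(int n_cells, List model_spec, NumericVector t_obs,
                   NumericVector init_prob, int init_n_states,
                   double thin_dt) {
  SsaModel m;
  m.n_states = as<int>(model_spec["n_states"]);
  IntegerVector ef = model_spec["efrom"], et = model_spec["eto"];
  NumericVector er = model_spec["erate"];
  m.efrom.assign(ef.begin(), ef.end());
  m.eto.assign(et.begin(), et.end());
  m.erate.assign(er.begin(), er.end());
  m.sig_from = as<int>(model_spec["sig_from"]);
  m.sig_to = as<int>(model_spec["sig_to"]);
  m.sig_mode = as<int>(model_spec["sig_mode"]);
  m.sig_k = as<double>(model_spec["sig_k"]);
  m.sig_b = as<double>(model_spec["sig_b"]);
  m.r1 = as<double>(model_spec["r1"]);
  m.r2 = as<double>(model_spec["r2"]);
  m.tpeak = std::log(1.0 + m.r2 / m.r1) / m.r2;
  NumericVector al = model_spec["alpha"];
  m.alpha.assign(al.begin(), al.end());
  m.delta = as<double>(model_spec["delta"]);

  const int T = t_obs.size();
  IntegerMatrix Gout(n_cells, T), Xout(n_cells, T);
  const double t_end = t_obs[T - 1];

  // cumulative initial distribution over (state, count), column-major
  std::vector<double> cum(init_prob.size());
  double acc = 0.0;
  for (int i = 0; i < init_prob.size(); ++i) {
    acc += init_prob[i];
    cum[i] = acc;
  }

  const int n_edges = (int)m.efrom.size();
  std::vector<double> a(n_edges + 3);

  for (int cell = 0; cell < n_cells; ++cell) {
    // initial (g, x)
    double u = unif_rand() * acc;
    int idx = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (idx >= (int)cum.size()) idx = (int)cum.size() - 1;
    int g = idx % init_n_states;
    long x = idx / init_n_states;

    double t = 0.0;
    int oi = 0;
    while (oi < T && t_obs[oi] <= t) {
      Gout(cell, oi) = g;
      Xout(cell, oi) = (int)x;
      ++oi;
    }
    while (oi < T) {
      double seg_end = std::min(t + thin_dt, t_end);
      // make observation times segment boundaries
      if (oi < T && t_obs[oi] < seg_end) seg_end = t_obs[oi];
      const double ks_max = m.sig_rate_bound(t, seg_end);
      // events within [t, seg_end)
      for (;;) {
        double a_const = 0.0;
        for (int e = 0; e < n_edges; ++e)
          if (m.efrom[e] == g) a_const += m.erate[e];
        a_const += m.alpha[g] + m.delta * (double)x;
        const double B = a_const + (g == m.sig_from ? ks_max : 0.0);
        if (B <= 0.0) { t = seg_end; break; }
        const double tau = -std::log(unif_rand()) / B;
        if (t + tau >= seg_end) { t = seg_end; break; }
        t += tau;
        // build propensities at the proposed time
        int na = 0;
        double a_tot = 0.0;
        for (int e = 0; e < n_edges; ++e) {
          if (m.efrom[e] == g) {
            a[na++] = m.erate[e];
            a_tot += m.erate[e];
          }
        }
        int n_sw = na;
        double a_sig = (g == m.sig_from) ? m.sig_rate_at(t) : 0.0;
        a[na++] = a_sig; a_tot += a_sig;
        a[na++] = m.alpha[g]; a_tot += m.alpha[g];
        a[na++] = m.delta * (double)x; a_tot += m.delta * (double)x;
        const double u2 = unif_rand() * B;
        if (u2 >= a_tot) continue;  // thinned (no reaction)
        // select reaction
        double s = 0.0;
        int r = -1;
        for (int i = 0; i < na; ++i) {
          s += a[i];
          if (u2 < s) { r = i; break; }
        }
        if (r < n_sw) {
          int seen = 0;
          for (int e = 0; e < n_edges; ++e) {
            if (m.efrom[e] == g) {
              if (seen == r) { g = m.eto[e]; break; }
              ++seen;
            }
          }
        } else if (r == n_sw) {
          g = m.sig_to;       // signal edge fired
        } else if (r == n_sw + 1) {
          ++x;                // transcription
        } else {
          if (x > 0) --x;     // degradation
        }
      }
      while (oi < T && t_obs[oi] <= t + 1e-9) {
        Gout(cell, oi) = g;
        Xout(cell, oi) = (int)x;
        ++oi;
      }
    }
    if (cell % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["state"] = Gout, _["count"] = Xout);
}
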