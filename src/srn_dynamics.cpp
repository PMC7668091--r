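// Compiled kernels for scalable-reaction-network dynamics:
//  - evaluation of structured flux families (product / linear-combination / ratio)
//  - adaptive Dormand-Prince 5(4) integration of the biomass ODE and of the
//    rescaled composition dynamics on the unit simplex
//  - Euler-Maruyama integration of the simplex SDE (noise in composition)
// Networks whose rates are arbitrary R functions take the pure-R fallback path
// in R/dynamics.R; everything in the model zoo uses these kernels.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Flux {
  int type; // 0 = product, 1 = lincomb, 2 = ratio
  double r;
  std::vector<int> mono_i;
  std::vector<double> mono_e;
  double mono_deg;
  std::vector<int> sat_i;
  std::vector<double> sat_K, sat_th;
  std::vector<int> rep_i;
  std::vector<double> rep_K, rep_th;
  std::vector<int> lin_i;
  std::vector<double> lin_w;
  int ratio_j, ratio_k;
  double ratio_a, ratio_b, ratio_c;
};

struct Net {
  int n, m;
  std::vector<double> S; // column-major n x m
  std::vector<Flux> flux;
};

std::vector<int> as_idx0(SEXP x) {
  IntegerVector v(x);
  std::vector<int> out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = v[i] - 1;
  return out;
}

std::vector<double> as_dv(SEXP x) {
  NumericVector v(x);
  return std::vector<double>(v.begin(), v.end());
}

Net parse_net(const List& net) {
  Net N;
  N.n = as<int>(net["n"]);
  N.m = as<int>(net["m"]);
  NumericMatrix S = net["S"];
  N.S.assign(S.begin(), S.end());
  List fl = net["flux"];
  N.flux.resize(N.m);
  for (int a = 0; a < N.m; ++a) {
    List f = fl[a];
    Flux& F = N.flux[a];
    F.type = as<int>(f["type"]);
    F.r = as<double>(f["r"]);
    F.mono_deg = 0.0;
    F.ratio_j = F.ratio_k = 0;
    F.ratio_a = F.ratio_b = F.ratio_c = 0.0;
    if (F.type == 0) {
      F.mono_i = as_idx0(f["mono_i"]);
      F.mono_e = as_dv(f["mono_e"]);
      for (double e : F.mono_e) F.mono_deg += e;
      F.sat_i = as_idx0(f["sat_i"]);
      F.sat_K = as_dv(f["sat_K"]);
      F.sat_th = as_dv(f["sat_th"]);
      F.rep_i = as_idx0(f["rep_i"]);
      F.rep_K = as_dv(f["rep_K"]);
      F.rep_th = as_dv(f["rep_th"]);
    } else if (F.type == 1) {
      F.lin_i = as_idx0(f["lin_i"]);
      F.lin_w = as_dv(f["lin_w"]);
    } else {
      NumericVector rp = f["ratio"];
      F.ratio_j = (int)rp[0] - 1;
      F.ratio_k = (int)rp[1] - 1;
      F.ratio_a = rp[2];
      F.ratio_b = rp[3];
      F.ratio_c = rp[4];
    }
  }
  return N;
}

inline double eval_flux(const Flux& F, const double* X, double Ntot) {
  if (F.type == 1) {
    double s = 0.0;
    for (size_t i = 0; i < F.lin_i.size(); ++i) s += F.lin_w[i] * X[F.lin_i[i]];
    return F.r * s;
  }
  if (F.type == 2) {
    double Xj = X[F.ratio_j], Xk = X[F.ratio_k];
    double den = F.ratio_a * Xj + F.ratio_b * Xk + F.ratio_c * Ntot;
    return den > 0.0 ? F.r * Xj * Xk / den : 0.0;
  }
  double J = F.r;
  for (size_t i = 0; i < F.mono_i.size(); ++i) {
    double x = X[F.mono_i[i]];
    if (x <= 0.0) {
      if (F.mono_e[i] > 0.0) return 0.0;
    } else {
      J *= std::pow(x, F.mono_e[i]);
    }
  }
  if (F.mono_deg != 1.0) {
    if (Ntot <= 0.0) return 0.0;
    J *= std::pow(Ntot, 1.0 - F.mono_deg);
  }
  for (size_t i = 0; i < F.sat_i.size(); ++i) {
    double y = Ntot > 0.0 ? X[F.sat_i[i]] / Ntot : 0.0;
    double yt = (F.sat_th[i] == 1.0) ? y : std::pow(y, F.sat_th[i]);
    J *= yt / (F.sat_K[i] + yt);
  }
  for (size_t i = 0; i < F.rep_i.size(); ++i) {
    double y = Ntot > 0.0 ? X[F.rep_i[i]] / Ntot : 0.0;
    double yt = (F.rep_th[i] == 1.0) ? y : std::pow(y, F.rep_th[i]);
    J /= (1.0 + F.rep_K[i] * yt);
  }
  return J;
}

// dX = S J(X); returns mu = sum_k dX_k
inline double biomass_rhs(const Net& net, const double* X, double* dX,
                          double* Jbuf) {
  double Ntot = 0.0;
  for (int k = 0; k < net.n; ++k) Ntot += X[k];
  for (int a = 0; a < net.m; ++a) Jbuf[a] = eval_flux(net.flux[a], X, Ntot);
  double mu = 0.0;
  for (int k = 0; k < net.n; ++k) {
    double s = 0.0;
    for (int a = 0; a < net.m; ++a) s += net.S[k + (size_t)net.n * a] * Jbuf[a];
    dX[k] = s;
    mu += s;
  }
  return mu;
}

// simplex rhs: dY = S J(Y) - mu(Y) Y, with Y renormalized inside
inline double simplex_rhs(const Net& net, const double* Y, double* dY,
                          double* Jbuf) {
  double mu = biomass_rhs(net, Y, dY, Jbuf);
  for (int k = 0; k < net.n; ++k) dY[k] -= mu * Y[k];
  return mu;
}

// Dormand-Prince 5(4) coefficients
static const double dp_c[7] = {0.0, 1.0 / 5, 3.0 / 10, 4.0 / 5, 8.0 / 9, 1.0, 1.0};
static const double dp_a[7][6] = {
    {0, 0, 0, 0, 0, 0},
    {1.0 / 5, 0, 0, 0, 0, 0},
    {3.0 / 40, 9.0 / 40, 0, 0, 0, 0},
    {44.0 / 45, -56.0 / 15, 32.0 / 9, 0, 0, 0},
    {19372.0 / 6561, -25360.0 / 2187, 64448.0 / 6561, -212.0 / 729, 0, 0},
    {9017.0 / 3168, -355.0 / 33, 46732.0 / 5247, 49.0 / 176, -5103.0 / 18656, 0},
    {35.0 / 384, 0, 500.0 / 1113, 125.0 / 192, -2187.0 / 6784, 11.0 / 84}};
static const double dp_b5[7] = {35.0 / 384, 0, 500.0 / 1113, 125.0 / 192,
                                -2187.0 / 6784, 11.0 / 84, 0};
static const double dp_b4[7] = {5179.0 / 57600, 0, 7571.0 / 16695, 393.0 / 640,
                                -92097.0 / 339200, 187.0 / 2100, 1.0 / 40};

struct Work {
  std::vector<double> k[7], ytmp, yerr, J;
};

// one adaptive DP5 step attempt; returns error norm, fills ynew
template <typename RHS>
double dp_step(const RHS& rhs, const double* y, int n, double h, double* ynew,
               Work& w) {
  for (int s = 0; s < 7; ++s) {
    for (int i = 0; i < n; ++i) {
      double acc = y[i];
      for (int j = 0; j < s; ++j) acc += h * dp_a[s][j] * w.k[j][i];
      w.ytmp[i] = acc;
    }
    rhs(w.ytmp.data(), w.k[s].data());
  }
  for (int i = 0; i < n; ++i) {
    double y5 = y[i], y4 = y[i];
    for (int s = 0; s < 7; ++s) {
      y5 += h * dp_b5[s] * w.k[s][i];
      y4 += h * dp_b4[s] * w.k[s][i];
    }
    ynew[i] = y5;
    w.yerr[i] = y5 - y4;
  }
  return 0.0; // error norm computed by caller with tolerances
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_eval_fluxes(List net, NumericVector X) {
  Net N = parse_net(net);
  double Ntot = 0.0;
  for (double x : X) Ntot += x;
  NumericVector J(N.m);
  for (int a = 0; a < N.m; ++a) J[a] = eval_flux(N.flux[a], X.begin(), Ntot);
  return J;
}

// [[Rcpp::export]]
NumericMatrix cpp_eval_fluxes_path(List net, NumericMatrix Y) {
  Net N = parse_net(net);
  int T = Y.nrow();
  NumericMatrix J(T, N.m);
  std::vector<double> x(N.n);
  for (int t = 0; t < T; ++t) {
    double Ntot = 0.0;
    for (int k = 0; k < N.n; ++k) {
      x[k] = Y(t, k);
      Ntot += x[k];
    }
    for (int a = 0; a < N.m; ++a) J(t, a) = eval_flux(N.flux[a], x.data(), Ntot);
  }
  return J;
}

// [[Rcpp::export]]
List cpp_rhs(List net, NumericVector X, bool simplex) {
  Net N = parse_net(net);
  std::vector<double> dX(N.n), J(N.m);
  double mu;
  if (simplex)
    mu = simplex_rhs(N, X.begin(), dX.data(), J.data());
  else
    mu = biomass_rhs(N, X.begin(), dX.data(), J.data());
  return List::create(_["dX"] = NumericVector(dX.begin(), dX.end()),
                      _["mu"] = mu,
                      _["J"] = NumericVector(J.begin(), J.end()));
}

template <typename RHS>
static bool integrate_to(const RHS& rhs, std::vector<double>& y, double& t,
                         double t_target, double rtol, double atol, Work& w,
                         double& h) {
  int n = (int)y.size();
  std::vector<double> ynew(n);
  int max_steps = 10000000;
  while (t < t_target) {
    if (--max_steps <= 0) return false;
    if (h > t_target - t) h = t_target - t;
    dp_step(rhs, y.data(), n, h, ynew.data(), w);
    double err = 0.0;
    for (int i = 0; i < n; ++i) {
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double e = w.yerr[i] / sc;
      err += e * e;
    }
    err = std::sqrt(err / n);
    if (!std::isfinite(err)) { h *= 0.1; if (h < 1e-14) return false; continue; }
    if (err <= 1.0) {
      t += h;
      y = ynew;
      double fac = err > 0.0 ? 0.9 * std::pow(err, -0.2) : 5.0;
      h *= std::min(5.0, std::max(0.2, fac));
    } else {
      h *= std::max(0.1, 0.9 * std::pow(err, -0.2));
      if (h < 1e-14 * std::max(1.0, std::fabs(t))) return false;
    }
  }
  return true;
}

// Integrates the rescaled composition plus log N as an extra state
// (d logN / dt = mu(Y)), so logN carries the full ODE accuracy instead of a
// quadrature reconstruction.
// [[Rcpp::export]]
List cpp_simulate_simplex(List net, NumericVector Y0, double t_end, int nout,
                          double rtol, double atol) {
  Net N = parse_net(net);
  int n = N.n;
  int naug = n + 1;
  Work w;
  for (int s = 0; s < 7; ++s) w.k[s].resize(naug);
  w.ytmp.resize(naug);
  w.yerr.resize(naug);
  std::vector<double> J(N.m);
  auto rhs = [&](const double* y, double* dy) {
    // clamp transient negatives before flux evaluation (condition 2 makes
    // effluxes vanish at depleted nodes, so this is consistent)
    std::vector<double> yc(y, y + n);
    for (int i = 0; i < n; ++i) if (yc[i] < 0.0) yc[i] = 0.0;
    dy[n] = simplex_rhs(N, yc.data(), dy, J.data());
  };
  NumericMatrix Y(nout + 1, n);
  NumericVector tgrid(nout + 1), mu(nout + 1), logN(nout + 1);
  std::vector<double> y(naug, 0.0);
  for (int i = 0; i < n; ++i) y[i] = Y0[i];
  double t = 0.0, h = t_end / (100.0 * nout + 100.0);
  bool ok = true;
  std::vector<double> dy(naug);
  for (int i = 0; i <= nout; ++i) {
    double tt = t_end * i / nout;
    if (i > 0) ok = integrate_to(rhs, y, t, tt, rtol, atol, w, h);
    if (!ok) { tgrid[i] = NA_REAL; break; }
    // project back onto the simplex
    double s = 0.0;
    for (int k2 = 0; k2 < n; ++k2) {
      if (y[k2] < 0.0) y[k2] = 0.0;
      s += y[k2];
    }
    if (s > 0.0) for (int k2 = 0; k2 < n; ++k2) y[k2] /= s;
    tgrid[i] = tt;
    mu[i] = simplex_rhs(N, y.data(), dy.data(), J.data());
    logN[i] = y[n];
    for (int k2 = 0; k2 < n; ++k2) Y(i, k2) = y[k2];
  }
  return List::create(_["t"] = tgrid, _["Y"] = Y, _["mu"] = mu,
                      _["logN"] = logN, _["ok"] = ok);
}

// [[Rcpp::export]]
List cpp_simulate_biomass(List net, NumericVector X0, double t_end, int nout,
                          double rtol, double atol, double logN_guard) {
  Net N = parse_net(net);
  int n = N.n;
  Work w;
  for (int s = 0; s < 7; ++s) w.k[s].resize(n);
  w.ytmp.resize(n);
  w.yerr.resize(n);
  std::vector<double> J(N.m);
  auto rhs = [&](const double* x, double* dx) {
    std::vector<double> xc(x, x + n);
    for (int i = 0; i < n; ++i) if (xc[i] < 0.0) xc[i] = 0.0;
    biomass_rhs(N, xc.data(), dx, J.data());
  };
  NumericMatrix X(nout + 1, n);
  NumericVector tgrid(nout + 1, NA_REAL), mu(nout + 1, NA_REAL),
      logN(nout + 1, NA_REAL);
  std::vector<double> x(X0.begin(), X0.end()), dx(n);
  double t = 0.0, h = t_end / (100.0 * nout + 100.0);
  bool ok = true;
  double blow_t = NA_REAL;
  int last = nout;
  for (int i = 0; i <= nout; ++i) {
    double tt = t_end * i / nout;
    if (i > 0) ok = integrate_to(rhs, x, t, tt, rtol, atol, w, h);
    if (!ok) { last = i - 1; blow_t = t; break; }
    double s = 0.0;
    for (int k2 = 0; k2 < n; ++k2) {
      if (x[k2] < 0.0) x[k2] = 0.0;
      s += x[k2];
    }
    tgrid[i] = tt;
    logN[i] = s > 0.0 ? std::log(s) : R_NegInf;
    double m = biomass_rhs(N, x.data(), dx.data(), J.data());
    mu[i] = s > 0.0 ? m / s : NA_REAL;
    for (int k2 = 0; k2 < n; ++k2) X(i, k2) = x[k2];
    if (logN[i] > logN_guard) { blow_t = tt; last = i; break; }
  }
  return List::create(_["t"] = tgrid, _["X"] = X, _["mu"] = mu,
                      _["logN"] = logN, _["ok"] = ok, _["last"] = last + 1,
                      _["blowup_time"] = blow_t);
}

// Euler-Maruyama on the simplex. scheme 0: tangent-additive (zero-mean Gaussian
// increments); scheme 1: multiplicative (per-component noise scaled by Y_k,
// then recentred). Boundary handling: clamp to 0 and renormalize.
// [[Rcpp::export]]
List cpp_simulate_sde(List net, NumericVector Y0, double t_end, double dt,
                      double sigma, int scheme, int thin) {
  Net N = parse_net(net);
  int n = N.n;
  long nsteps = (long)std::ceil(t_end / dt);
  int nout = (int)(nsteps / thin);
  NumericMatrix Y(nout + 1, n);
  NumericVector tgrid(nout + 1), mu(nout + 1);
  std::vector<double> y(Y0.begin(), Y0.end()), dy(n), J(N.m);
  double sq = sigma * std::sqrt(dt);
  RNGScope scope;
  int row = 0;
  tgrid[0] = 0.0;
  mu[0] = simplex_rhs(N, y.data(), dy.data(), J.data());
  for (int k2 = 0; k2 < n; ++k2) Y(0, k2) = y[k2];
  bool step_ok = true;
  for (long s = 1; s <= nsteps && step_ok; ++s) {
    double m = simplex_rhs(N, y.data(), dy.data(), J.data());
    double emean = 0.0;
    std::vector<double> e(n, 0.0);
    if (sigma > 0.0) {
      for (int i = 0; i < n; ++i) {
        e[i] = sq * norm_rand();
        if (scheme == 1) e[i] *= y[i];
        emean += e[i];
      }
      emean /= n;
    }
    double tot = 0.0;
    for (int i = 0; i < n; ++i) {
      double incr = dt * dy[i] + (sigma > 0.0 ? e[i] - emean : 0.0);
      if (std::fabs(incr) > 0.1) step_ok = false; // dt too coarse for this flow
      y[i] += incr;
      if (y[i] < 0.0) y[i] = 0.0;
      tot += y[i];
    }
    if (tot > 0.0) for (int i = 0; i < n; ++i) y[i] /= tot;
    if (s % thin == 0 && row < nout) {
      ++row;
      tgrid[row] = s * dt;
      mu[row] = simplex_rhs(N, y.data(), dy.data(), J.data());
      for (int k2 = 0; k2 < n; ++k2) Y(row, k2) = y[k2];
    }
  }
  return List::create(_["t"] = tgrid, _["Y"] = Y, _["mu"] = mu,
                      _["ok"] = step_ok);
}
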