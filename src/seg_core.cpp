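// Functional-pruning dynamic program for exact L0-penalized segmentation and
// the exact fused-lasso (L1) recursion, over piecewise convex envelopes in the
// loss family's natural parameter.
//
// Every per-datum loss contributes a coefficient triple (a, b, c) so that any
// partial-sum objective restricted to one segment parameter theta is
//     a * g1(theta) + b * theta + c
// with g1 = theta^2 (Gaussian, theta = mean), exp(theta) (Poisson, theta =
// log-rate) or log(1 + exp(theta)) (binomial, theta = log-odds).  The family
// is closed under addition of data terms and constants, and each piece is
// convex, so the running envelope stays a piecewise member of the family.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

enum Fam { GAUSS = 0, POIS = 1, BINOM = 2 };

static inline double log1pexp_(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline double sigmoid_(double x) {
  if (x >= 0.0) {
    double e = std::exp(-x);
    return 1.0 / (1.0 + e);
  }
  double e = std::exp(x);
  return e / (1.0 + e);
}

struct Piece {
  double lo, hi;   // theta interval (tiles the domain, ordered)
  double a, b, c;  // value = a * g1(theta) + b * theta + c, a >= 0
  int tau;         // candidate start index of the current segment (L0 provenance)
};

typedef std::vector<Piece> Env;

static inline double g1(int fam, double t) {
  switch (fam) {
  case GAUSS: return t * t;
  case POIS:  return std::exp(t);
  default:    return log1pexp_(t);
  }
}

static inline double g1d(int fam, double t) {
  switch (fam) {
  case GAUSS: return 2.0 * t;
  case POIS:  return std::exp(t);
  default:    return sigmoid_(t);
  }
}

static inline double piece_val(int fam, const Piece& p, double t) {
  return p.a * g1(fam, t) + p.b * t + p.c;
}

static inline double piece_deriv(int fam, const Piece& p, double t) {
  return p.a * g1d(fam, t) + p.b;
}

// argmin of the piece on its own interval (unconstrained optimum clamped in)
static double piece_argmin(int fam, const Piece& p) {
  double t;
  if (p.a <= 0.0) {
    t = (p.b >= 0.0) ? p.lo : p.hi;  // linear piece
  } else if (fam == GAUSS) {
    t = -p.b / (2.0 * p.a);
  } else if (fam == POIS) {
    t = (p.b >= 0.0) ? p.lo : std::log(-p.b / p.a);
  } else {
    if (p.b >= 0.0) t = p.lo;
    else if (-p.b >= p.a) t = p.hi;
    else {
      double s = -p.b / p.a;
      t = std::log(s / (1.0 - s));
    }
  }
  if (t < p.lo) t = p.lo;
  if (t > p.hi) t = p.hi;
  return t;
}

// Solve piece_val(t) == target on [xl, xh] where the piece is monotone and the
// endpoint values bracket the target.  Closed form for Gaussian (quadratic),
// safeguarded Newton with bisection fallback otherwise (tolerance 1e-9).
static double piece_root(int fam, const Piece& p, double target, double xl, double xh) {
  if (fam == GAUSS && p.a > 0.0) {
    double A = p.a, B = p.b, C = p.c - target;
    double disc = B * B - 4.0 * A * C;
    if (disc < 0.0) disc = 0.0;
    double sq = std::sqrt(disc);
    // numerically stable pair of roots
    double q = (B >= 0.0) ? -0.5 * (B + sq) : -0.5 * (B - sq);
    double r1 = q / A;
    double r2 = (q != 0.0) ? C / q : r1;
    double lo = std::min(r1, r2), hi = std::max(r1, r2);
    double mid = 0.5 * (xl + xh);
    double r = (std::fabs(lo - mid) <= std::fabs(hi - mid)) ? lo : hi;
    // pick the root inside the bracket
    if (r < xl - 1e-8 || r > xh + 1e-8) r = (r == lo) ? hi : lo;
    if (r < xl) r = xl;
    if (r > xh) r = xh;
    return r;
  }
  if (p.a <= 0.0) {  // linear
    if (p.b == 0.0) return xl;
    double r = (target - p.c) / p.b;
    if (r < xl) r = xl;
    if (r > xh) r = xh;
    return r;
  }
  double fl = piece_val(fam, p, xl) - target;
  double fh = piece_val(fam, p, xh) - target;
  if (fl == 0.0) return xl;
  if (fh == 0.0) return xh;
  bool hpos = fh > 0.0;
  double x = 0.5 * (xl + xh);
  for (int it = 0; it < 200; ++it) {
    double f = piece_val(fam, p, x) - target;
    if (f == 0.0) break;
    if ((f > 0.0) == hpos) xh = x; else xl = x;
    double d = piece_deriv(fam, p, x);
    double xn = (d != 0.0) ? x - f / d : 0.5 * (xl + xh);
    if (!(xn > xl && xn < xh)) xn = 0.5 * (xl + xh);
    if (std::fabs(xn - x) < 1e-9) { x = xn; break; }
    x = xn;
  }
  return x;
}

static void env_min(int fam, const Env& env, double& mval, double& marg, int& mtau) {
  mval = R_PosInf;
  marg = env.empty() ? 0.0 : env.front().lo;
  mtau = 1;
  for (size_t k = 0; k < env.size(); ++k) {
    double t = piece_argmin(fam, env[k]);
    double v = piece_val(fam, env[k], t);
    if (v < mval) { mval = v; marg = t; mtau = env[k].tau; }
  }
}

static double env_eval_at(int fam, const Env& env, double t) {
  for (size_t k = 0; k < env.size(); ++k) {
    if (t <= env[k].hi || k + 1 == env.size()) return piece_val(fam, env[k], t);
  }
  return NA_REAL;
}

static inline void add_datum(Env& env, double da, double db, double dc) {
  for (size_t k = 0; k < env.size(); ++k) {
    env[k].a += da; env[k].b += db; env[k].c += dc;
  }
}

// Pointwise min(env, thresh) where thresh = delta + lambda.  Regions where the
// envelope is strictly above thresh become constant "restart" pieces tagged
// with tau = newtau; exact equality keeps the continue branch (fewer
// changepoints under ties).
static Env l0_step(int fam, const Env& env, double thresh, int newtau) {
  Env out;
  out.reserve(env.size() + 2);
  // merge adjacent restart constants as we push
  struct Pusher {
    Env& out; double thresh; int newtau;
    void constant(double lo, double hi) {
      if (!(hi > lo)) return;
      if (!out.empty() && out.back().a == 0.0 && out.back().b == 0.0 &&
          out.back().tau == newtau && out.back().c == thresh) {
        out.back().hi = hi;
      } else {
        Piece q; q.lo = lo; q.hi = hi; q.a = 0.0; q.b = 0.0; q.c = thresh; q.tau = newtau;
        out.push_back(q);
      }
    }
    void orig(const Piece& p, double lo, double hi) {
      if (!(hi > lo)) return;
      Piece q = p; q.lo = lo; q.hi = hi;
      out.push_back(q);
    }
  } push = { out, thresh, newtau };

  for (size_t k = 0; k < env.size(); ++k) {
    const Piece& p = env[k];
    double tm = piece_argmin(fam, p);
    double m = piece_val(fam, p, tm);
    if (m > thresh) { push.constant(p.lo, p.hi); continue; }
    double vlo = piece_val(fam, p, p.lo);
    double vhi = piece_val(fam, p, p.hi);
    double r1 = p.lo, r2 = p.hi;
    if (vlo > thresh) {
      r1 = piece_root(fam, p, thresh, p.lo, tm);
      push.constant(p.lo, r1);
    }
    if (vhi > thresh) r2 = piece_root(fam, p, thresh, tm, p.hi);
    push.orig(p, r1, r2);
    if (vhi > thresh) push.constant(r2, p.hi);
  }
  if (out.empty()) {  // degenerate single-point domain
    Piece q; q.lo = env.front().lo; q.hi = env.back().hi;
    q.a = 0.0; q.b = 0.0; q.c = thresh; q.tau = newtau;
    out.push_back(q);
  }
  return out;
}

// ------------------------------------------------------------------
// conversions between the R list representation and Env
// ------------------------------------------------------------------

static Env env_from_list(const List& x) {
  NumericVector lo = x["lo"], hi = x["hi"], a = x["a"], b = x["b"], c = x["c"];
  IntegerVector tau = x["tau"];
  Env env(lo.size());
  for (int k = 0; k < lo.size(); ++k) {
    env[k].lo = lo[k]; env[k].hi = hi[k];
    env[k].a = a[k]; env[k].b = b[k]; env[k].c = c[k];
    env[k].tau = tau[k];
  }
  return env;
}

static List env_to_list(const Env& env) {
  int n = (int) env.size();
  NumericVector lo(n), hi(n), a(n), b(n), c(n);
  IntegerVector tau(n);
  for (int k = 0; k < n; ++k) {
    lo[k] = env[k].lo; hi[k] = env[k].hi;
    a[k] = env[k].a; b[k] = env[k].b; c[k] = env[k].c;
    tau[k] = env[k].tau;
  }
  return List::create(_["lo"] = lo, _["hi"] = hi, _["a"] = a, _["b"] = b,
                      _["c"] = c, _["tau"] = tau);
}

// [[Rcpp::export]]
List env_new_cpp(double dlo, double dhi) {
  Env env;
  Piece q; q.lo = dlo; q.hi = dhi; q.a = 0.0; q.b = 0.0; q.c = 0.0; q.tau = 1;
  env.push_back(q);
  return env_to_list(env);
}

// [[Rcpp::export]]
List env_add_datum_cpp(List env, double da, double db, double dc) {
  Env e = env_from_list(env);
  add_datum(e, da, db, dc);
  return env_to_list(e);
}

// [[Rcpp::export]]
NumericVector env_eval_cpp(List env, NumericVector theta, int family) {
  Env e = env_from_list(env);
  NumericVector out(theta.size());
  for (int i = 0; i < theta.size(); ++i) out[i] = env_eval_at(family, e, theta[i]);
  return out;
}

// [[Rcpp::export]]
List env_min_cpp(List env, int family) {
  Env e = env_from_list(env);
  double mval, marg; int mtau;
  env_min(family, e, mval, marg, mtau);
  return List::create(_["min"] = mval, _["argmin"] = marg, _["tau"] = mtau);
}

// [[Rcpp::export]]
List env_l0_step_cpp(List env, double lambda, int family, int newtau) {
  Env e = env_from_list(env);
  double mval, marg; int mtau;
  env_min(family, e, mval, marg, mtau);
  if (!R_FINITE(mval)) stop("envelope minimum is not finite");
  Env stepped = l0_step(family, e, mval + lambda, newtau);
  int nres = 0;
  for (size_t k = 0; k < stepped.size(); ++k) if (stepped[k].tau == newtau) ++nres;
  NumericMatrix regions(nres, 2);
  int r = 0;
  for (size_t k = 0; k < stepped.size(); ++k) {
    if (stepped[k].tau == newtau) {
      regions(r, 0) = stepped[k].lo;
      regions(r, 1) = stepped[k].hi;
      ++r;
    }
  }
  return List::create(_["envelope"] = env_to_list(stepped),
                      _["restart_regions"] = regions,
                      _["min"] = mval, _["argmin"] = marg);
}

// ------------------------------------------------------------------
// L0 segmentation: forward functional recursion + backward assignment
// ------------------------------------------------------------------

// [[Rcpp::export]]
List l0_segment_cpp(NumericVector da, NumericVector db, NumericVector dc,
                    int family, double lambda, double dlo, double dhi) {
  int N = da.size();
  Env env;
  Piece q0; q0.lo = dlo; q0.hi = dhi; q0.a = 0.0; q0.b = 0.0; q0.c = 0.0; q0.tau = 1;
  env.push_back(q0);
  add_datum(env, da[0], db[0], dc[0]);

  std::vector<double> bestTheta(N + 1, 0.0);
  std::vector<int> bestTau(N + 1, 1);
  double pieceSum = (double) env.size();

  for (int i = 2; i <= N; ++i) {
    double mval, marg; int mtau;
    env_min(family, env, mval, marg, mtau);
    if (!R_FINITE(mval)) stop("non-finite envelope minimum at position %d", i - 1);
    bestTheta[i - 1] = marg;
    bestTau[i - 1] = mtau;
    env = l0_step(family, env, mval + lambda, i);
    add_datum(env, da[i - 1], db[i - 1], dc[i - 1]);
    pieceSum += (double) env.size();
  }

  double mval, marg; int mtau;
  env_min(family, env, mval, marg, mtau);
  bestTheta[N] = marg;
  bestTau[N] = mtau;

  std::vector<int> starts, ends;
  std::vector<double> thetas;
  int e = N;
  while (e >= 1) {
    int s = bestTau[e];
    if (s < 1 || s > e) stop("backtrace corrupted");  // defensive
    starts.push_back(s);
    ends.push_back(e);
    thetas.push_back(bestTheta[e]);
    e = s - 1;
  }
  std::reverse(starts.begin(), starts.end());
  std::reverse(ends.begin(), ends.end());
  std::reverse(thetas.begin(), thetas.end());

  return List::create(_["seg_start"] = wrap(starts),
                      _["seg_end"] = wrap(ends),
                      _["theta"] = wrap(thetas),
                      _["objective"] = mval,
                      _["mean_pieces"] = pieceSum / (double) N);
}

// ------------------------------------------------------------------
// L1 (fused lasso): forward derivative clipping + backward clamping
// ------------------------------------------------------------------

// leftmost theta with envelope derivative >= -lambda
static double clip_left(int fam, const Env& env, double lambda) {
  for (size_t k = 0; k < env.size(); ++k) {
    const Piece& p = env[k];
    if (piece_deriv(fam, p, p.lo) >= -lambda) return p.lo;
    if (piece_deriv(fam, p, p.hi) >= -lambda) {
      // derivative crosses -lambda inside this convex piece
      double s = -lambda - p.b;
      if (p.a <= 0.0) return p.lo;          // linear: cannot cross strictly inside
      if (fam == GAUSS) {
        double t = s / (2.0 * p.a);
        return std::min(std::max(t, p.lo), p.hi);
      } else if (fam == POIS) {
        if (s <= 0.0) return p.lo;
        double t = std::log(s / p.a);
        return std::min(std::max(t, p.lo), p.hi);
      } else {
        double frac = s / p.a;
        if (frac <= 0.0) return p.lo;
        if (frac >= 1.0) return p.hi;
        double t = std::log(frac / (1.0 - frac));
        return std::min(std::max(t, p.lo), p.hi);
      }
    }
  }
  return env.back().hi;  // derivative < -lambda everywhere
}

// rightmost theta with envelope derivative <= +lambda
static double clip_right(int fam, const Env& env, double lambda) {
  for (size_t k = env.size(); k-- > 0;) {
    const Piece& p = env[k];
    if (piece_deriv(fam, p, p.hi) <= lambda) return p.hi;
    if (piece_deriv(fam, p, p.lo) <= lambda) {
      double s = lambda - p.b;
      if (p.a <= 0.0) return p.hi;
      if (fam == GAUSS) {
        double t = s / (2.0 * p.a);
        return std::min(std::max(t, p.lo), p.hi);
      } else if (fam == POIS) {
        if (s <= 0.0) return p.lo;
        double t = std::log(s / p.a);
        return std::min(std::max(t, p.lo), p.hi);
      } else {
        double frac = s / p.a;
        if (frac <= 0.0) return p.lo;
        if (frac >= 1.0) return p.hi;
        double t = std::log(frac / (1.0 - frac));
        return std::min(std::max(t, p.lo), p.hi);
      }
    }
  }
  return env.front().lo;
}

// [[Rcpp::export]]
List l1_segment_cpp(NumericVector da, NumericVector db, NumericVector dc,
                    int family, double lambda, double dlo, double dhi) {
  int N = da.size();
  Env env;
  Piece q0; q0.lo = dlo; q0.hi = dhi; q0.a = 0.0; q0.b = 0.0; q0.c = 0.0; q0.tau = 1;
  env.push_back(q0);
  add_datum(env, da[0], db[0], dc[0]);

  std::vector<double> L(N + 1, dlo), U(N + 1, dhi);
  double pieceSum = (double) env.size();

  for (int i = 2; i <= N; ++i) {
    double l = clip_left(family, env, lambda);
    double u = clip_right(family, env, lambda);
    if (u < l) u = l;  // flat minimum collapses under lambda = 0
    L[i] = l; U[i] = u;
    double fl = env_eval_at(family, env, l);
    double fu = env_eval_at(family, env, u);
    Env ne;
    ne.reserve(env.size() + 2);
    if (l > dlo) {
      Piece p; p.lo = dlo; p.hi = l; p.a = 0.0; p.b = -lambda;
      p.c = fl + lambda * l; p.tau = 1;
      ne.push_back(p);
    }
    for (size_t k = 0; k < env.size(); ++k) {
      double lo = std::max(env[k].lo, l), hi = std::min(env[k].hi, u);
      if (hi > lo) {
        Piece p = env[k]; p.lo = lo; p.hi = hi;
        ne.push_back(p);
      }
    }
    if (u < dhi) {
      Piece p; p.lo = u; p.hi = dhi; p.a = 0.0; p.b = lambda;
      p.c = fu - lambda * u; p.tau = 1;
      ne.push_back(p);
    }
    if (ne.empty()) {  // l == u spanning the whole domain edge case
      Piece p; p.lo = dlo; p.hi = dhi; p.a = 0.0; p.b = 0.0; p.c = fl; p.tau = 1;
      ne.push_back(p);
    }
    env = ne;
    add_datum(env, da[i - 1], db[i - 1], dc[i - 1]);
    pieceSum += (double) env.size();
  }

  double mval, marg; int mtau;
  env_min(family, env, mval, marg, mtau);

  NumericVector theta(N);
  theta[N - 1] = marg;
  for (int i = N - 1; i >= 1; --i) {
    double t = theta[i];  // theta_{i+1} (0-based i holds position i+1)
    if (t < L[i + 1]) t = L[i + 1];
    if (t > U[i + 1]) t = U[i + 1];
    theta[i - 1] = t;
  }

  return List::create(_["theta"] = theta,
                      _["objective"] = mval,
                      _["mean_pieces"] = pieceSum / (double) N);
}
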