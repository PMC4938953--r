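// Steady-state kinetics core for the five-reaction linear pathway.
//
// Genotype layout (length-26 numeric vector): for each enzyme A..E the five
// kinetic parameters in order (conc, k_cat, K_M, k_catr, K_Mr), followed by
// the single inhibition constant K_I.  State x = (B, C, D, E, F); A is a
// fixed boundary species and F is drained by mass action (k_use * F).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int NSP = 5;   // free metabolites B..F
static const int NRX = 5;   // reactions 1..5
static const double SAT_CAP = 1e150;  // overflow guard on S/K ratios

struct PathEnv {
  double A;        // boundary concentration of A (mmol/l)
  double ku;       // mass-action utilization of F (1/s)
  double tol;      // steady-state residual tolerance (mmol/l/s)
  double max_time; // pseudo-time cap for the integration fallback (s)
  int inhib_rx;    // 0-based reaction carrying the K_I term
  int inhib_sp;    // 0-based index into x of the inhibitory metabolite
};

static inline double sat(double num, double den) {
  if (den <= 0.0) return SAT_CAP; // K underflowed to 0: fully saturating
  double r = num / den;
  if (!std::isfinite(r) || r > SAT_CAP) return SAT_CAP;
  return r;
}

// Net rates of the five reversible reactions at state x.
static void rates(const double *par, const PathEnv &env, const double *x,
                  double *v) {
  for (int i = 0; i < NRX; ++i) {
    const double *e = par + 5 * i;
    double S = (i == 0) ? env.A : x[i - 1];
    double P = x[i];
    double a = sat(S, e[2]);          // S / K_M
    double b = sat(P, e[4]);          // P / K_Mr
    double den = 1.0 + a + b;
    if (i == env.inhib_rx) den += sat(x[env.inhib_sp], par[25]);
    v[i] = e[0] * (e[1] * a - e[3] * b) / den;
  }
}

// Time derivatives dx/dt of B..F.
static void deriv(const double *par, const PathEnv &env, const double *x,
                  double *f) {
  double v[NRX];
  rates(par, env, x, v);
  for (int i = 0; i < NSP - 1; ++i) f[i] = v[i] - v[i + 1];
  f[NSP - 1] = v[NRX - 1] - env.ku * x[NSP - 1];
}

static double maxabs(const double *f, int n) {
  double m = 0.0;
  for (int i = 0; i < n; ++i) m = std::max(m, std::fabs(f[i]));
  return m;
}

// Solve J z = rhs (5x5) by Gaussian elimination with partial pivoting.
// Returns false on (near-)singular J.
static bool solve5(double J[NSP][NSP], double *rhs, double *z) {
  double a[NSP][NSP + 1];
  for (int i = 0; i < NSP; ++i) {
    for (int j = 0; j < NSP; ++j) a[i][j] = J[i][j];
    a[i][NSP] = rhs[i];
  }
  for (int c = 0; c < NSP; ++c) {
    int piv = c;
    for (int r = c + 1; r < NSP; ++r)
      if (std::fabs(a[r][c]) > std::fabs(a[piv][c])) piv = r;
    if (std::fabs(a[piv][c]) < 1e-300) return false;
    if (piv != c)
      for (int j = c; j <= NSP; ++j) std::swap(a[c][j], a[piv][j]);
    for (int r = c + 1; r < NSP; ++r) {
      double m = a[r][c] / a[c][c];
      for (int j = c; j <= NSP; ++j) a[r][j] -= m * a[c][j];
    }
  }
  for (int r = NSP - 1; r >= 0; --r) {
    double s = a[r][NSP];
    for (int j = r + 1; j < NSP; ++j) s -= a[r][j] * z[j];
    z[r] = s / a[r][r];
  }
  for (int i = 0; i < NSP; ++i)
    if (!std::isfinite(z[i])) return false;
  return true;
}

// Forward-difference Jacobian of `deriv` (or of the implicit-Euler residual
// when dt > 0: g(x) = x - x0 - dt * f(x), whose Jacobian is I - dt * J).
static void jacobian(const double *par, const PathEnv &env, const double *x,
                     const double *f0, double dt, double J[NSP][NSP]) {
  double xp[NSP], fp[NSP];
  for (int j = 0; j < NSP; ++j) {
    double h = 1e-7 * std::max(std::fabs(x[j]), 1e-3);
    for (int i = 0; i < NSP; ++i) xp[i] = x[i];
    xp[j] += h;
    deriv(par, env, xp, fp);
    for (int i = 0; i < NSP; ++i) {
      double d = (fp[i] - f0[i]) / h;
      J[i][j] = (dt > 0.0) ? ((i == j ? 1.0 : 0.0) - dt * d) : d;
    }
  }
}

// Damped Newton on the rate-balance system from x (in place).
// Returns true if max|f| < tol.
static bool newton(const double *par, const PathEnv &env, double *x,
                   double tol, int maxit) {
  double f[NSP], J[NSP][NSP], z[NSP], xn[NSP], fn[NSP];
  deriv(par, env, x, f);
  double r = maxabs(f, NSP);
  for (int it = 0; it < maxit && r >= tol; ++it) {
    jacobian(par, env, x, f, 0.0, J);
    if (!solve5(J, f, z)) return false;
    double lam = 1.0;
    bool ok = false;
    for (int h = 0; h < 40; ++h, lam *= 0.5) {
      for (int i = 0; i < NSP; ++i) {
        xn[i] = x[i] - lam * z[i];
        if (xn[i] < 0.0) xn[i] = 0.0;  // concentrations stay non-negative
      }
      deriv(par, env, xn, fn);
      double rn = maxabs(fn, NSP);
      if (std::isfinite(rn) && rn < r) {
        for (int i = 0; i < NSP; ++i) { x[i] = xn[i]; f[i] = fn[i]; }
        r = rn;
        ok = true;
        break;
      }
    }
    if (!ok) return r < tol;
  }
  return r < tol;
}

// Pseudo-transient continuation: implicit Euler with growing step, robust for
// the stiff systems extreme mutants produce.  Advances x toward steady state
// until the residual meets tol or accumulated pseudo-time exceeds max_time.
static bool pseudo_transient(const double *par, const PathEnv &env, double *x,
                             double tol, double max_time) {
  double f[NSP], g[NSP], J[NSP][NSP], z[NSP], y[NSP];
  double dt = 1e-4, t = 0.0;
  deriv(par, env, x, f);
  for (int step = 0; step < 2000; ++step) {
    if (maxabs(f, NSP) < tol) return true;
    if (t >= max_time) return false;
    // implicit Euler step: solve y - x - dt f(y) = 0, Newton from y = x
    for (int i = 0; i < NSP; ++i) y[i] = x[i];
    bool stepped = false;
    for (int it = 0; it < 30; ++it) {
      double fy[NSP];
      deriv(par, env, y, fy);
      for (int i = 0; i < NSP; ++i) g[i] = y[i] - x[i] - dt * fy[i];
      if (maxabs(g, NSP) < 1e-10 * (1.0 + dt)) { stepped = true; break; }
      jacobian(par, env, y, fy, dt, J);
      if (!solve5(J, g, z)) break;
      bool fin = true;
      for (int i = 0; i < NSP; ++i) {
        y[i] -= z[i];
        if (y[i] < 0.0) y[i] = 0.0;
        if (!std::isfinite(y[i])) fin = false;
      }
      if (!fin) break;
      if (it == 29) stepped = true;
    }
    if (stepped) {
      for (int i = 0; i < NSP; ++i) x[i] = y[i];
      t += dt;
      dt = std::min(dt * 3.0, 1e7);
      deriv(par, env, x, f);
    } else {
      dt *= 0.25;
      if (dt < 1e-12) return false;
    }
  }
  return maxabs(f, NSP) < tol;
}

static PathEnv as_env(const List &env) {
  PathEnv e;
  e.A = as<double>(env["conc_A"]);
  e.ku = as<double>(env["k_use"]);
  e.tol = as<double>(env["solver_tol"]);
  e.max_time = as<double>(env["max_time"]);
  e.inhib_rx = as<int>(env["inhib_reaction"]) - 1;
  e.inhib_sp = as<int>(env["inhib_species"]) - 1;
  return e;
}

// Core solve: warm start (if given and finite), direct Newton, then
// pseudo-transient fallback followed by a Newton polish.
static bool solve_core(const double *par, const PathEnv &env, double *x,
                       const double *warm) {
  if (warm) {
    for (int i = 0; i < NSP; ++i)
      x[i] = (std::isfinite(warm[i]) && warm[i] >= 0.0) ? warm[i] : 0.0;
    if (newton(par, env, x, env.tol, 50)) return true;
  }
  // default start: substrate pools near the consuming enzyme's K_M
  for (int i = 0; i < NSP - 1; ++i) x[i] = std::min(par[5 * (i + 1) + 2], 1.0);
  x[NSP - 1] = 1.0;
  if (newton(par, env, x, env.tol, 80)) return true;
  if (pseudo_transient(par, env, x, env.tol, env.max_time)) {
    newton(par, env, x, env.tol, 20);
    return true;
  }
  return false;
}

static double flux_at(const double *par, const PathEnv &env, const double *x) {
  double v[NRX];
  rates(par, env, x, v);
  return v[NRX - 1];
}

// [[Rcpp::export(name = ".ss_solve_cpp")]]
List ss_solve_cpp(NumericVector par, List env, Nullable<NumericVector> x0 =
                      R_NilValue) {
  PathEnv e = as_env(env);
  double x[NSP];
  const double *warm = NULL;
  NumericVector w;
  if (x0.isNotNull()) { w = x0.get(); warm = REAL(w); }
  bool conv = solve_core(REAL(par), e, x, warm);
  double v[NRX];
  rates(REAL(par), e, x, v);
  return List::create(_["concentrations"] = NumericVector(x, x + NSP),
                      _["rates"] = NumericVector(v, v + NRX),
                      _["flux"] = v[NRX - 1], _["converged"] = conv);
}

// Batch solve: one row per genotype; returns B,C,D,E,F, flux, converged.
// [[Rcpp::export(name = ".ss_batch_cpp")]]
NumericMatrix ss_batch_cpp(NumericMatrix P, List env) {
  PathEnv e = as_env(env);
  int n = P.nrow();
  NumericMatrix out(n, NSP + 2);
  double x[NSP], warm[NSP];
  bool have_warm = false;
  std::vector<double> par(26);
  for (int r = 0; r < n; ++r) {
    for (int j = 0; j < 26; ++j) par[j] = P(r, j);
    bool conv = solve_core(&par[0], e, x, have_warm ? warm : NULL);
    for (int i = 0; i < NSP; ++i) out(r, i) = x[i];
    out(r, NSP) = flux_at(&par[0], e, x);
    out(r, NSP + 1) = conv ? 1.0 : 0.0;
    if (conv) {  // genotypes in a population are similar: reuse solution
      for (int i = 0; i < NSP; ++i) warm[i] = x[i];
      have_warm = true;
    }
  }
  return out;
}

// Finite-perturbation sensitivities: scale each reaction's capacity by
// `factor` (enzyme concentration when mode = 0; k_cat and k_catr jointly
// when mode = 1) and report base flux minus perturbed flux per reaction.
// [[Rcpp::export(name = ".sensitivities_cpp")]]
List sensitivities_cpp(NumericVector par, List env, double factor = 0.9,
                       int mode = 0) {
  PathEnv e = as_env(env);
  double x[NSP];
  bool conv = solve_core(REAL(par), e, x, NULL);
  double base = flux_at(REAL(par), e, x);
  NumericVector sens(NRX, NA_REAL);
  if (conv) {
    std::vector<double> p(REAL(par), REAL(par) + 26);
    double xp[NSP];
    for (int i = 0; i < NRX; ++i) {
      std::vector<double> q(p);
      if (mode == 0) {
        q[5 * i] *= factor;
      } else {
        q[5 * i + 1] *= factor;
        q[5 * i + 3] *= factor;
      }
      bool c2 = solve_core(&q[0], e, xp, x);
      sens[i] = c2 ? (base - flux_at(&q[0], e, xp)) : NA_REAL;
    }
  }
  return List::create(_["flux"] = base, _["sensitivities"] = sens,
                      _["converged"] = conv);
}

// ---- mutation-effect means (percent), shared with the R layer -------------

// parameter classes: 0 conc, 1 k_cat, 2 K_M, 3 k_catr, 4 K_Mr, 5 K_I
static double effect_mean(int cls, double p, const double *cvals, int mode) {
  if (mode == 1) return 0.0;  // neutral
  double c = cvals[cls], m;
  if (cls == 2 || cls == 4 || cls == 5)
    m = -100.0 * std::exp(-c * p);      // 1 / (-0.01 e^{cK})
  else
    m = -0.01 * std::exp(c * p);
  if (m < -25.0) m = -25.0;
  if (m > 0.0) m = 0.0;
  return m;
}

static int param_class(int j) {
  if (j == 25) return 5;
  return j % 5;  // conc, k_cat, K_M, k_catr, K_Mr
}

static double fitness_of(int scheme, double flux, const double *x,
                         const double *par, const List &fcfg) {
  // scheme: 0 mutation_only, 1 flux_only, 2 flux_intermediate, 3 flux_cost,
  //         4 positive_control
  if (scheme == 0) return 1.0;
  double mid = as<double>(fcfg["flux_mid"]), slope = as<double>(fcfg["flux_slope"]);
  double fl = flux > 0.0 ? flux : 0.0;
  double F1 = 1.0 / (1.0 + std::exp(-slope * (fl - mid)));
  if (scheme == 1) return F1;
  if (scheme == 2 || scheme == 4) {
    double s = as<double>(fcfg["s_intermediate"]);
    return F1 * std::exp(-s * x[0]);  // x[0] = [B]
  }
  double s = as<double>(fcfg["s_cost"]);
  double cAA = as<double>(fcfg["cost_AA"]), cnuc = as<double>(fcfg["cost_nuc"]);
  NumericVector len = fcfg["lengths"];
  double cp = 0.0, cm = 0.0;
  for (int i = 0; i < 5; ++i) {
    cp += par[5 * i] * len[i];
    cm += 3.0 * len[i] * par[5 * i] / 1000.0;
  }
  return F1 / (1.0 + s * (cAA * cp + cnuc * cm));
}

static double kimura_psi(double s, double Ne, double c, double p) {
  double a = 2.0 * c * Ne * s;
  if (s == 0.0 || std::fabs(a) < 1e-12) return p;
  if (-a * p > 700.0) return std::exp(a * (1.0 - p));  // strongly deleterious
  if (a > 700.0) return 1.0;                           // strongly beneficial
  return std::expm1(-a * p) / std::expm1(-a);
}

// Fused origin-fixation run.  One proposal per generation; 3 RNG draws per
// generation in fixed order (param index, normal effect, acceptance), so an
// R-level re-implementation with runif/rnorm reproduces it exactly.
//
// mut_mode: 0 biological, 1 neutral, 2 haldane.
// In haldane mode k_catr is excluded from the proposal set and reprojected
// from Keq after any k_cat/K_M/K_Mr change.
// [[Rcpp::export(name = ".of_run_cpp")]]
List of_run_cpp(NumericVector par0, List env, int scheme, List fcfg,
                int mut_mode, NumericVector cvals, double effect_sd,
                double mult_floor, NumericVector Keq, double haldane_mean,
                double haldane_sd, double Ne, double ploidy, double p_init,
                int ngen, int thin) {
  PathEnv e = as_env(env);
  std::vector<double> par(REAL(par0), REAL(par0) + 26);

  std::vector<int> free_idx;
  for (int j = 0; j < 26; ++j)
    if (!(mut_mode == 2 && param_class(j) == 3)) free_idx.push_back(j);
  int nfree = (int)free_idx.size();

  double x[NSP];
  bool conv = solve_core(&par[0], e, x, NULL);
  double fl = conv ? flux_at(&par[0], e, x) : 0.0;
  if (!conv || fl < 0.0) fl = 0.0;
  double f0 = conv ? fitness_of(scheme, fl, x, &par[0], fcfg) : 0.0;
  if (f0 <= 0.0) stop("initial genotype has zero fitness; cannot scale selection coefficients");

  IntegerVector rl(ngen);
  NumericVector flux_tr(ngen), fit_tr(ngen);
  int nsnap = ngen / thin + 1;
  NumericMatrix snaps(nsnap, 26);
  IntegerVector snap_gen(nsnap);
  int isnap = 0;
  long accepted = 0;

  // current rate-limiting step (recomputed only when a mutation fixes)
  double xs[NSP];
  for (int i = 0; i < NSP; ++i) xs[i] = x[i];
  int cur_rl = 1;
  {
    double base = fl, best = -1e300;
    double xp[NSP];
    for (int i = 0; i < NRX; ++i) {
      std::vector<double> q(par);
      q[5 * i] *= 0.9;
      solve_core(&q[0], e, xp, xs);
      double s = base - flux_at(&q[0], e, xp);
      if (s > best + 1e-15) { best = s; cur_rl = i + 1; }
    }
  }

  for (int g = 0; g < ngen; ++g) {
    int j = free_idx[(int)(unif_rand() * nfree) % nfree];
    int cls = param_class(j);
    double mean, sd;
    if (mut_mode == 2 && (cls == 1 || cls == 2 || cls == 4)) {
      mean = haldane_mean; sd = haldane_sd;
    } else {
      mean = effect_mean(cls, par[j], REAL(cvals), mut_mode == 1 ? 1 : 0);
      sd = effect_sd;
    }
    double delta = mean + sd * norm_rand();
    double mult = std::max(1.0 + delta / 100.0, mult_floor);

    std::vector<double> q(par);
    q[j] *= mult;
    if (mut_mode == 2 && (cls == 1 || cls == 2 || cls == 4)) {
      int enz = j / 5;
      q[5 * enz + 3] = q[5 * enz + 1] * q[5 * enz + 4] /
                       (Keq[enz] * q[5 * enz + 2]);
    }
    double xm[NSP];
    bool cm = solve_core(&q[0], e, xm, xs);
    double flm = cm ? flux_at(&q[0], e, xm) : 0.0;
    if (!cm || flm < 0.0) flm = 0.0;
    double fm = cm ? fitness_of(scheme, flm, xm, &q[0], fcfg) : 0.0;
    double s = fm / f0 - 1.0;
    double psi = kimura_psi(s, Ne, ploidy, p_init);
    double u = unif_rand();
    if (u < psi) {
      par = q; f0 = fm; fl = flm;
      for (int i = 0; i < NSP; ++i) xs[i] = xm[i];
      ++accepted;
      // re-identify the rate-limiting step
      double best = -1e300;
      double xp[NSP];
      int arg = 1;
      for (int i = 0; i < NRX; ++i) {
        std::vector<double> qq(par);
        qq[5 * i] *= 0.9;
        solve_core(&qq[0], e, xp, xs);
        double sv = fl - flux_at(&qq[0], e, xp);
        if (sv > best + 1e-15) { best = sv; arg = i + 1; }
      }
      cur_rl = arg;
    }
    rl[g] = cur_rl;
    flux_tr[g] = fl;
    fit_tr[g] = f0;
    if ((g + 1) % thin == 0 && isnap < nsnap) {
      snap_gen[isnap] = g + 1;
      for (int k = 0; k < 26; ++k) snaps(isnap, k) = par[k];
      ++isnap;
    }
  }
  return List::create(_["rate_limiting"] = rl, _["flux"] = flux_tr,
                      _["fitness"] = fit_tr, _["accepted"] = (double)accepted,
                      _["snapshots"] = snaps(Range(0, std::max(isnap - 1, 0)),
                                             Range(0, 25)),
                      _["snapshot_generation"] =
                          snap_gen[Rcpp::Range(0, std::max(isnap - 1, 0))],
                      _["final"] = NumericVector(par.begin(), par.end()));
}
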