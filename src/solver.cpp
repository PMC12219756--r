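// Method-of-lines core for the Allen-Cahn setting model:
//   phi_t = D(t) * Lap(phi) + eps^-2 * phi (1 - phi) (phi - phibar)
// on the cell-centered N x N grid over [-L, L]^2 with homogeneous Neumann
// boundaries (mirror ghost cells), integrated by classical RK4.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

static inline double step_D(double t, double D0, double T) {
  // right-continuous switch-off: D0 on [0, T), 0 from T onwards
  return (t < T) ? D0 : 0.0;
}

// 5-point Laplacian with mirror (Neumann) ghosts; column-major N x N.
static void lap5(const double* u, double* out, int N, double inv_h2) {
  for (int j = 0; j < N; ++j) {
    const double* c = u + (size_t)j * N;
    const double* w = u + (size_t)((j == 0) ? 0 : j - 1) * N;
    const double* e = u + (size_t)((j == N - 1) ? N - 1 : j + 1) * N;
    double* o = out + (size_t)j * N;
    o[0] = (w[0] + e[0] + c[0] + c[1] - 4.0 * c[0]) * inv_h2;
    for (int i = 1; i < N - 1; ++i) {
      o[i] = (w[i] + e[i] + c[i - 1] + c[i + 1] - 4.0 * c[i]) * inv_h2;
    }
    o[N - 1] = (w[N - 1] + e[N - 1] + c[N - 2] + c[N - 1]
                - 4.0 * c[N - 1]) * inv_h2;
  }
}

// One fused RK4 stage: reads the stage state `s`, accumulates the stage
// slope into `acc` with weight `wacc`, and writes the next stage state
// `u + cdt * slope` into `nxt` (cdt = 0 skips that write; used by the
// final stage which instead completes the step into `unew`).
struct StageBufs {
  std::vector<double> s1, s2, acc;
  explicit StageBufs(size_t M) : s1(M), s2(M), acc(M) {}
};

static inline double cubic(double p, double inv_eps2, double phibar) {
  return inv_eps2 * p * (1.0 - p) * (p - phibar);
}

// Stage with diffusion: slope = D * lap(s) + reaction(s).
static void stage_diff(const double* u, const double* s, double* acc,
                       double* nxt, int N, double D, double inv_h2,
                       double inv_eps2, double phibar, double wacc,
                       double cdt, bool first) {
  for (int j = 0; j < N; ++j) {
    size_t off = (size_t)j * N;
    const double* c = s + off;
    const double* w = s + (size_t)((j == 0) ? 0 : j - 1) * N;
    const double* e = s + (size_t)((j == N - 1) ? N - 1 : j + 1) * N;
    const double* ub = u + off;
    double* a = acc + off;
    double* n = nxt + off;
    int i = 0;
    {
      double lap = (w[0] + e[0] + c[0] + c[1] - 4.0 * c[0]) * inv_h2;
      double k = D * lap + cubic(c[0], inv_eps2, phibar);
      a[0] = first ? k : a[0] + wacc * k;
      n[0] = ub[0] + cdt * k;
    }
    for (i = 1; i < N - 1; ++i) {
      double lap = (w[i] + e[i] + c[i - 1] + c[i + 1] - 4.0 * c[i]) * inv_h2;
      double k = D * lap + cubic(c[i], inv_eps2, phibar);
      a[i] = first ? k : a[i] + wacc * k;
      n[i] = ub[i] + cdt * k;
    }
    {
      double lap = (w[i] + e[i] + c[i - 1] + c[i] - 4.0 * c[i]) * inv_h2;
      double k = D * lap + cubic(c[i], inv_eps2, phibar);
      a[i] = first ? k : a[i] + wacc * k;
      n[i] = ub[i] + cdt * k;
    }
  }
}

// Stage without diffusion (t >= T): pointwise reaction only.
static void stage_react(const double* u, const double* s, double* acc,
                        double* nxt, size_t M, double inv_eps2,
                        double phibar, double wacc, double cdt,
                        bool first) {
  for (size_t m = 0; m < M; ++m) {
    double k = cubic(s[m], inv_eps2, phibar);
    acc[m] = first ? k : acc[m] + wacc * k;
    nxt[m] = u[m] + cdt * k;
  }
}

static void stage(const double* u, const double* s, double* acc,
                  double* nxt, int N, double D, double inv_h2,
                  double inv_eps2, double phibar, double wacc, double cdt,
                  bool first) {
  if (D != 0.0) {
    stage_diff(u, s, acc, nxt, N, D, inv_h2, inv_eps2, phibar, wacc, cdt,
               first);
  } else {
    stage_react(u, s, acc, nxt, (size_t)N * N, inv_eps2, phibar, wacc, cdt,
                first);
  }
}

// Classical RK4 update of `u` over [t, t + dt].
static void rk4_advance(std::vector<double>& u, double t, double dt, int N,
                        double D0, double T, double inv_h2, double inv_eps2,
                        double phibar, StageBufs& b) {
  size_t M = u.size();
  double Dh = step_D(t + 0.5 * dt, D0, T);
  // k1 from u; s1 = u + dt/2 k1; acc = k1
  stage(u.data(), u.data(), b.acc.data(), b.s1.data(), N,
        step_D(t, D0, T), inv_h2, inv_eps2, phibar, 1.0, 0.5 * dt, true);
  // k2 from s1; s2 = u + dt/2 k2; acc += 2 k2
  stage(u.data(), b.s1.data(), b.acc.data(), b.s2.data(), N, Dh, inv_h2,
        inv_eps2, phibar, 2.0, 0.5 * dt, false);
  // k3 from s2; s1 = u + dt k3; acc += 2 k3
  stage(u.data(), b.s2.data(), b.acc.data(), b.s1.data(), N, Dh, inv_h2,
        inv_eps2, phibar, 2.0, dt, false);
  // k4 from s1; acc += k4; u += dt/6 acc
  stage(u.data(), b.s1.data(), b.acc.data(), b.s2.data(), N,
        step_D(t + dt, D0, T), inv_h2, inv_eps2, phibar, 1.0, 0.0, false);
  double w = dt / 6.0;
  for (size_t m = 0; m < M; ++m) u[m] += w * b.acc[m];
}

static bool all_finite(const std::vector<double>& u) {
  for (double v : u) {
    if (!std::isfinite(v)) return false;
  }
  return true;
}

// [[Rcpp::export]]
NumericMatrix laplacian_neumann_cpp(NumericMatrix u, double h) {
  int N = u.nrow();
  NumericMatrix out(N, N);
  lap5(u.begin(), out.begin(), N, 1.0 / (h * h));
  return out;
}

// [[Rcpp::export]]
NumericMatrix rhs_cpp(NumericMatrix u, double t, double D0, double T,
                      double eps, double phibar, double h) {
  int N = u.nrow();
  size_t M = (size_t)N * N;
  NumericMatrix out(N, N);
  std::vector<double> dummy(M);
  stage(u.begin(), u.begin(), out.begin(), dummy.data(), N,
        step_D(t, D0, T), 1.0 / (h * h), 1.0 / (eps * eps), phibar, 1.0,
        0.0, true);
  return out;
}

// [[Rcpp::export]]
NumericMatrix rk4_step_cpp(NumericMatrix u, double t, double dt, double D0,
                           double T, double eps, double phibar, double h) {
  if (t < T && t + dt > T) {
    stop("RK4 step [%g, %g] straddles the diffusion switch-off time T = %g; "
         "split the step at T", t, t + dt, T);
  }
  int N = u.nrow();
  size_t M = (size_t)N * N;
  std::vector<double> v(u.begin(), u.end());
  StageBufs b(M);
  rk4_advance(v, t, dt, N, D0, T, 1.0 / (h * h), 1.0 / (eps * eps), phibar,
              b);
  NumericMatrix out(N, N);
  std::copy(v.begin(), v.end(), out.begin());
  return out;
}

// Fixed-step RK4 from t = 0 to t_end. Steps are aligned so that every
// snapshot time, the switch time T, and t_end fall exactly on step
// boundaries (the step before each is shortened); no RK4 step ever
// straddles the discontinuity of D(t).
// [[Rcpp::export]]
List integrate_cpp(NumericMatrix u0, double h, double D0, double T,
                   double eps, double phibar, double dt, double t_end,
                   NumericVector snapshot_times) {
  int N = u0.nrow();
  size_t M = (size_t)N * N;
  double inv_h2 = 1.0 / (h * h);
  double inv_eps2 = 1.0 / (eps * eps);
  const double tol = 1e-12;

  // segment breakpoints: snapshots, T (if interior), t_end
  std::vector<double> brk(snapshot_times.begin(), snapshot_times.end());
  if (T > tol && T < t_end - tol) brk.push_back(T);
  brk.push_back(t_end);
  std::sort(brk.begin(), brk.end());
  std::vector<double> bp;
  for (size_t q = 0; q < brk.size(); ++q) {
    double bq = brk[q];
    if (bq <= tol || bq > t_end + tol) continue;
    if (bp.empty() || bq - bp.back() > tol) bp.push_back(bq);
  }

  std::vector<double> u(u0.begin(), u0.end());
  StageBufs b(M);
  List snaps;
  NumericVector snap_t;
  double step_count = 0;

  double a = 0.0;
  for (size_t q = 0; q < bp.size(); ++q) {
    double bq = bp[q];
    long nsteps = (long)std::ceil((bq - a) / dt - 1e-9);
    if (nsteps < 1) nsteps = 1;
    for (long k = 0; k < nsteps; ++k) {
      double t = a + (double)k * dt;
      double step_dt = (k == nsteps - 1) ? (bq - t) : dt;
      rk4_advance(u, t, step_dt, N, D0, T, inv_h2, inv_eps2, phibar, b);
      step_count += 1;
      if (((long)step_count) % 5000 == 0 && !all_finite(u)) {
        stop("non-finite value in the field at step %.0f (t = %g); "
             "the integration diverged", step_count, t + step_dt);
      }
    }
    if (!all_finite(u)) {
      stop("non-finite value in the field at step %.0f (t = %g); "
           "the integration diverged", step_count, bq);
    }
    // record if bq is a requested snapshot time
    for (int si = 0; si < snapshot_times.size(); ++si) {
      if (std::fabs(snapshot_times[si] - bq) <= tol) {
        NumericMatrix s(N, N);
        std::copy(u.begin(), u.end(), s.begin());
        snaps.push_back(s);
        snap_t.push_back(bq);
        break;
      }
    }
    a = bq;
  }
  return List::create(_["times"] = snap_t, _["fields"] = snaps,
                      _["steps"] = step_count);
}

// 4-connected component labelling of a logical mask (iterative BFS).
// Labels are 1-based in discovery order (column-major scan); 0 = background.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<std::pair<int, int> > queue;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      queue.clear();
      queue.push_back(std::make_pair(i, j));
      while (!queue.empty()) {
        std::pair<int, int> p = queue.back();
        queue.pop_back();
        int pi = p.first, pj = p.second;
        const int di[4] = {-1, 1, 0, 0};
        const int dj[4] = {0, 0, -1, 1};
        for (int d = 0; d < 4; ++d) {
          int qi = pi + di[d], qj = pj + dj[d];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            queue.push_back(std::make_pair(qi, qj));
          }
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
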