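#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Euler-Maruyama integration of dx = A x dt + Fnoise dW.
// Noise per step: Fnoise %*% (sqrt(dt) * z), z iid standard normal (uses the
// R RNG, so set.seed() gives reproducible paths). Stores every `thin`-th
// state, starting with x0.
// [[Rcpp::export]]
NumericMatrix cpp_euler(const NumericMatrix& A, const NumericMatrix& Fn,
                        const NumericVector& x0, double dt, int n_steps,
                        int thin) {
  const int n = A.nrow();
  const int n_out = n_steps / thin + 1;
  NumericMatrix out(n_out, n);
  std::vector<double> x(x0.begin(), x0.end()), xn(n), z(n);
  const double sdt = std::sqrt(dt);
  for (int j = 0; j < n; ++j) out(0, j) = x[j];
  int row = 1;
  for (int s = 1; s <= n_steps; ++s) {
    for (int j = 0; j < n; ++j) z[j] = norm_rand() * sdt;
    for (int i = 0; i < n; ++i) {
      double drift = 0.0, noise = 0.0;
      for (int j = 0; j < n; ++j) {
        drift += A(i, j) * x[j];
        noise += Fn(i, j) * z[j];
      }
      xn[i] = x[i] + drift * dt + noise;
    }
    x = xn;
    if (s % thin == 0) {
      for (int j = 0; j < n; ++j) {
        if (!std::isfinite(x[j]))
          stop("trajectory blew up (non-finite state) at step %d", s);
        out(row, j) = x[j];
      }
      ++row;
    }
  }
  return out;
}

// Gillespie simulation of a continuous-time Markov jump process given in
// compressed sparse column form (off-diagonal rates only): for column j the
// outgoing targets are rows[p[j]..p[j+1]-1] with rates vals[...], and
// exit[j] is the total escape rate. Sites are 0-based here.
// [[Rcpp::export]]
List cpp_gillespie(const IntegerVector& p, const IntegerVector& rows,
                   const NumericVector& vals, const NumericVector& exit,
                   int start, double tau_obs, double max_jumps) {
  std::vector<int> sites;
  std::vector<double> times;
  sites.push_back(start);
  times.push_back(0.0);
  int cur = start;
  double t = 0.0;
  long long nj = 0;
  while (true) {
    const double r = exit[cur];
    if (r <= 0.0) break;  // absorbing site: remain forever
    t += exp_rand() / r;
    if (t >= tau_obs) break;
    double u = unif_rand() * r, acc = 0.0;
    int nxt = -1;
    for (int k = p[cur]; k < p[cur + 1]; ++k) {
      acc += vals[k];
      if (u <= acc) { nxt = rows[k]; break; }
    }
    if (nxt < 0) nxt = rows[p[cur + 1] - 1];  // guard against roundoff
    cur = nxt;
    sites.push_back(cur);
    times.push_back(t);
    if (++nj >= (long long)max_jumps)
      stop("jump budget exceeded (%d jumps before tau_obs)", (int)max_jumps);
  }
  return List::create(_["sites"] = wrap(sites), _["times"] = wrap(times));
}

// Index window of grid centers within `reach` of a point along one
// dimension. Centers along dim j: lo[j] + (i + 0.5) * h[j], i from 0.
static inline void dim_window(double xj, double lo, double h, int count,
                              double reach, int& i0, int& i1) {
  i0 = (int)std::ceil((xj - reach - lo) / h - 0.5);
  i1 = (int)std::floor((xj + reach - lo) / h - 0.5);
  if (i0 < 0) i0 = 0;
  if (i1 > count - 1) i1 = count - 1;
}

// Per-dimension kernel weights of one point against the grid centers inside
// its support window (separable product kernels, cached per dimension so
// the inner accumulation does no exp calls). type 0: gaussian
// exp(-(dx/b)^2), truncated at |dx| > 6 b; type 1: epanechnikov
// (1 - (dx/b)^2) on |dx| < b. Returns false when the window is empty.
static bool point_windows(const NumericMatrix& pts, int ipt,
                          const NumericVector& lo, const NumericVector& h,
                          const IntegerVector& counts,
                          const NumericVector& b, int type,
                          std::vector<int>& i0, std::vector<int>& i1,
                          std::vector<std::vector<double> >& wdim) {
  const int d = pts.ncol();
  for (int j = 0; j < d; ++j) {
    const double reach = (type == 0) ? 6.0 * b[j] : b[j];
    dim_window(pts(ipt, j), lo[j], h[j], counts[j], reach, i0[j], i1[j]);
    if (i0[j] > i1[j]) return false;
    wdim[j].resize(i1[j] - i0[j] + 1);
    for (int t = i0[j]; t <= i1[j]; ++t) {
      const double c = lo[j] + (t + 0.5) * h[j];
      const double u = (pts(ipt, j) - c) / b[j];
      wdim[j][t - i0[j]] = (type == 0) ? std::exp(-u * u) : (1.0 - u * u);
    }
  }
  return true;
}

// Exact kernel density sums at the grid bin centers:
// out[g] = sum_i K(x_i, center_g), K normalized to integrate to one
// (gaussian: 1/(b sqrt(pi)) per dim; epanechnikov: 3/(4b) per dim).
// [[Rcpp::export]]
NumericVector cpp_kernel_density_grid(const NumericMatrix& pts,
                                      const NumericVector& lo,
                                      const NumericVector& h,
                                      const IntegerVector& counts,
                                      const NumericVector& b, int type) {
  const int N = pts.nrow(), d = pts.ncol();
  long long G = 1;
  for (int j = 0; j < d; ++j) G *= counts[j];
  NumericVector out((R_xlen_t)G);
  std::vector<long long> stride(d);
  stride[0] = 1;
  for (int j = 1; j < d; ++j) stride[j] = stride[j - 1] * counts[j - 1];
  double normc = 1.0;
  for (int j = 0; j < d; ++j)
    normc *= (type == 0) ? 1.0 / (b[j] * std::sqrt(M_PI)) : 0.75 / b[j];
  std::vector<int> i0(d), i1(d), idx(d);
  std::vector<std::vector<double> > wdim(d);
  for (int ipt = 0; ipt < N; ++ipt) {
    if (!point_windows(pts, ipt, lo, h, counts, b, type, i0, i1, wdim))
      continue;
    for (int j = 0; j < d; ++j) idx[j] = i0[j];
    while (true) {  // odometer over the index window
      double w = normc;
      long long g = 0;
      for (int j = 0; j < d; ++j) {
        w *= wdim[j][idx[j] - i0[j]];
        g += idx[j] * stride[j];
      }
      if (w > 0.0) out[g] += w;
      int j = 0;
      while (j < d && ++idx[j] > i1[j]) { idx[j] = i0[j]; ++j; }
      if (j == d) break;
    }
  }
  return out;
}

// Kernel regression sums for the current estimator: for each grid center g,
// wsum[g] = sum_i L(x_i, center_g) and vsum[g, ] = sum_i L(.) * disp[i, ].
// Same product kernels as above (normalization cancels in the regression).
// [[Rcpp::export]]
List cpp_kernel_current_grid(const NumericMatrix& pts,
                             const NumericMatrix& disp,
                             const NumericVector& lo, const NumericVector& h,
                             const IntegerVector& counts,
                             const NumericVector& b, int type) {
  const int N = pts.nrow(), d = pts.ncol();
  long long G = 1;
  for (int j = 0; j < d; ++j) G *= counts[j];
  NumericVector wsum((R_xlen_t)G);
  NumericMatrix vsum((R_xlen_t)G, d);
  std::vector<long long> stride(d);
  stride[0] = 1;
  for (int j = 1; j < d; ++j) stride[j] = stride[j - 1] * counts[j - 1];
  std::vector<int> i0(d), i1(d), idx(d);
  std::vector<std::vector<double> > wdim(d);
  std::vector<double> dsp(d);
  for (int ipt = 0; ipt < N; ++ipt) {
    if (!point_windows(pts, ipt, lo, h, counts, b, type, i0, i1, wdim))
      continue;
    for (int j = 0; j < d; ++j) { idx[j] = i0[j]; dsp[j] = disp(ipt, j); }
    while (true) {
      double w = 1.0;
      long long g = 0;
      for (int j = 0; j < d; ++j) {
        w *= wdim[j][idx[j] - i0[j]];
        g += idx[j] * stride[j];
      }
      if (w > 0.0) {
        wsum[g] += w;
        for (int j = 0; j < d; ++j) vsum(g, j) += w * dsp[j];
      }
      int j = 0;
      while (j < d && ++idx[j] > i1[j]) { idx[j] = i0[j]; ++j; }
      if (j == d) break;
    }
  }
  return List::create(_["wsum"] = wsum, _["vsum"] = vsum);
}

// Accumulated generalized current for a *linear* weight field d(x) = B x,
// evaluated at step midpoints (Stratonovich): per window k of `win` steps,
// J_k = sum over steps in k of (B m_i) . (x_i - x_{i-1}),
// with m_i the step midpoint. Returns one J per complete window.
// [[Rcpp::export]]
NumericVector cpp_accumulate_linear(const NumericMatrix& traj,
                                    const NumericMatrix& B, int win) {
  const int N = traj.nrow(), n = traj.ncol();
  const int n_steps = N - 1;
  const int n_win = n_steps / win;
  NumericVector J(n_win);
  for (int k = 0; k < n_win; ++k) {
    double acc = 0.0;
    for (int s = k * win + 1; s <= (k + 1) * win; ++s) {
      for (int i = 0; i < n; ++i) {
        double Bm = 0.0;
        for (int j = 0; j < n; ++j)
          Bm += B(i, j) * 0.5 * (traj(s, j) + traj(s - 1, j));
        acc += Bm * (traj(s, i) - traj(s - 1, i));
      }
    }
    J[k] = acc;
  }
  return J;
}
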