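// Compiled kernels: lattice Metropolis MC, cluster analysis, sorted-distance
// collective variables, cut-profile accumulation, and the synthetic oracles'
// samplers. All randomness goes through R's RNG (unif_rand/norm_rand) so that
// set.seed() controls every kernel.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline double bond_energy(int o1, int o2, double psi_w, double xi) {
  return (o1 == o2) ? -xi * psi_w : -psi_w;
}

// 4-neighbor offsets with periodic wrap
static inline int wrap(int a, int L) { return (a + L) % L; }

// Sum of bond energies between molecule `id` at (x, y) with orientation `o`
// and its occupied 4-neighbors, skipping site `skip` (linear index, -1 none).
static double site_bond_sum(const std::vector<int>& occ,
                            const std::vector<int>& ori,
                            int x, int y, int o,
                            int L, double psi_w, double xi, int skip) {
  static const int dx[4] = {1, -1, 0, 0};
  static const int dy[4] = {0, 0, 1, -1};
  double e = 0.0;
  for (int k = 0; k < 4; ++k) {
    int nx = wrap(x + dx[k], L), ny = wrap(y + dy[k], L);
    int s = nx + L * ny;
    if (s == skip) continue;
    int id2 = occ[s];
    if (id2 >= 0) e += bond_energy(o, ori[id2], psi_w, xi);
  }
  return e;
}

// [[Rcpp::export]]
double lattice_total_energy_cpp(IntegerVector x, IntegerVector y,
                                IntegerVector o, int L,
                                double psi_w, double xi) {
  int N = x.size();
  std::vector<int> occ((size_t)L * L, -1), ori(N);
  for (int i = 0; i < N; ++i) {
    occ[x[i] + L * y[i]] = i;
    ori[i] = o[i];
  }
  double e = 0.0;
  for (int i = 0; i < N; ++i)
    e += site_bond_sum(occ, ori, x[i], y[i], o[i], L, psi_w, xi, -1);
  return e / 2.0; // each bond counted twice
}

// Run n_steps elementary Metropolis attempts, recording a frame every dt0
// attempts (plus the initial state when record_initial). One attempt: pick a
// molecule uniformly; with probability move_mix propose a move to a uniformly
// chosen 4-neighbor site (rejected outright if occupied), otherwise propose
// an orientation flip; accept with min(1, exp(-dE/T)).
// [[Rcpp::export]]
List lattice_run_cpp(int L, int N, double psi_w, double xi, double T,
                     double n_steps, int dt0, double move_mix,
                     IntegerVector x0, IntegerVector y0, IntegerVector o0,
                     bool record_initial) {
  std::vector<int> occ((size_t)L * L, -1);
  std::vector<int> px(N), py(N), ori(N);
  for (int i = 0; i < N; ++i) {
    px[i] = x0[i]; py[i] = y0[i]; ori[i] = o0[i];
    occ[px[i] + L * py[i]] = i;
  }
  long long steps = (long long)n_steps;
  long long nframes = steps / dt0 + (record_initial ? 1 : 0);
  IntegerMatrix fx(nframes, N), fy(nframes, N);
  IntegerMatrix fo(nframes, N);
  long long fr = 0;
  static const int dx[4] = {1, -1, 0, 0};
  static const int dy[4] = {0, 0, 1, -1};
  const double beta = 1.0 / T;
  double acc_flip = 0.0, n_flip = 0.0;

  if (record_initial) {
    for (int i = 0; i < N; ++i) { fx(fr, i) = px[i]; fy(fr, i) = py[i]; fo(fr, i) = ori[i]; }
    ++fr;
  }
  for (long long t = 1; t <= steps; ++t) {
    int i = (int)(unif_rand() * N);
    if (i >= N) i = N - 1;
    if (unif_rand() < move_mix) {
      int k = (int)(unif_rand() * 4); if (k >= 4) k = 3;
      int nx = wrap(px[i] + dx[k], L), ny = wrap(py[i] + dy[k], L);
      int snew = nx + L * ny;
      if (occ[snew] < 0) {
        int sold = px[i] + L * py[i];
        double e_old = site_bond_sum(occ, ori, px[i], py[i], ori[i], L, psi_w, xi, -1);
        // evaluate the destination with the origin site vacated
        occ[sold] = -1;
        double e_new = site_bond_sum(occ, ori, nx, ny, ori[i], L, psi_w, xi, -1);
        double dE = e_new - e_old;
        if (dE <= 0.0 || unif_rand() < std::exp(-beta * dE)) {
          occ[snew] = i; px[i] = nx; py[i] = ny;
        } else {
          occ[sold] = i;
        }
      }
    } else {
      int onew = 1 - ori[i];
      double e_old = site_bond_sum(occ, ori, px[i], py[i], ori[i], L, psi_w, xi, -1);
      double e_new = site_bond_sum(occ, ori, px[i], py[i], onew, L, psi_w, xi, -1);
      double dE = e_new - e_old;
      n_flip += 1.0;
      if (dE <= 0.0 || unif_rand() < std::exp(-beta * dE)) {
        ori[i] = onew;
        acc_flip += 1.0;
      }
    }
    if (t % dt0 == 0) {
      for (int j = 0; j < N; ++j) { fx(fr, j) = px[j]; fy(fr, j) = py[j]; fo(fr, j) = ori[j]; }
      ++fr;
    }
  }
  return List::create(_["x"] = fx, _["y"] = fy, _["o"] = fo,
                      _["flip_acceptance"] = n_flip > 0 ? acc_flip / n_flip : NA_REAL);
}

// Largest connected component (4-neighbor, periodic) per frame.
// [[Rcpp::export]]
IntegerVector largest_cluster_cpp(IntegerMatrix xs, IntegerMatrix ys, int L) {
  int T = xs.nrow(), N = xs.ncol();
  IntegerVector out(T);
  std::vector<int> occ((size_t)L * L, -1);
  std::vector<int> touched; touched.reserve(N);
  std::vector<int> stack; stack.reserve(N);
  std::vector<char> seen(N);
  static const int dx[4] = {1, -1, 0, 0};
  static const int dy[4] = {0, 0, 1, -1};
  for (int t = 0; t < T; ++t) {
    touched.clear();
    for (int i = 0; i < N; ++i) {
      int s = xs(t, i) + L * ys(t, i);
      occ[s] = i; touched.push_back(s);
    }
    std::fill(seen.begin(), seen.end(), 0);
    int best = 0;
    for (int i = 0; i < N; ++i) {
      if (seen[i]) continue;
      int size = 0;
      stack.clear(); stack.push_back(i); seen[i] = 1;
      while (!stack.empty()) {
        int j = stack.back(); stack.pop_back(); ++size;
        int xj = xs(t, j), yj = ys(t, j);
        for (int k = 0; k < 4; ++k) {
          int s = wrap(xj + dx[k], L) + L * wrap(yj + dy[k], L);
          int id2 = occ[s];
          if (id2 >= 0 && !seen[id2]) { seen[id2] = 1; stack.push_back(id2); }
        }
      }
      if (size > best) best = size;
    }
    out[t] = best;
    for (size_t k = 0; k < touched.size(); ++k) occ[touched[k]] = -1;
  }
  return out;
}

// Minimum-image distance matrix, column-sorted then row-sorted, for one frame.
static void sorted_dmat_frame(const int* x, const int* y, int N, int L,
                              std::vector<double>& d, std::vector<double>& row) {
  // d column-major N x N
  for (int j = 0; j < N; ++j) {
    for (int i = 0; i < N; ++i) {
      int ddx = std::abs(x[i] - x[j]); if (ddx > L - ddx) ddx = L - ddx;
      int ddy = std::abs(y[i] - y[j]); if (ddy > L - ddy) ddy = L - ddy;
      d[(size_t)j * N + i] = std::sqrt((double)ddx * ddx + (double)ddy * ddy);
    }
  }
  for (int j = 0; j < N; ++j)
    std::sort(d.begin() + (size_t)j * N, d.begin() + (size_t)(j + 1) * N);
  for (int i = 0; i < N; ++i) {
    for (int j = 0; j < N; ++j) row[j] = d[(size_t)j * N + i];
    std::sort(row.begin(), row.end());
    for (int j = 0; j < N; ++j) d[(size_t)j * N + i] = row[j];
  }
}

// Extract K sorted-distance channels (1-based (row, col) indices) for every
// frame in one pass; returns T x K matrix.
// [[Rcpp::export]]
NumericMatrix sorted_cv_extract_cpp(IntegerMatrix xs, IntegerMatrix ys, int L,
                                    IntegerMatrix idx) {
  int T = xs.nrow(), N = xs.ncol(), K = idx.nrow();
  NumericMatrix out(T, K);
  std::vector<double> d((size_t)N * N), row(N);
  std::vector<int> x(N), y(N);
  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < N; ++i) { x[i] = xs(t, i); y[i] = ys(t, i); }
    sorted_dmat_frame(x.data(), y.data(), N, L, d, row);
    for (int k = 0; k < K; ++k) {
      int ri = idx(k, 0) - 1, cj = idx(k, 1) - 1;
      out(t, k) = d[(size_t)cj * N + ri];
    }
  }
  return out;
}

// Streaming per-channel mean and variance of the sorted-distance matrix over
// all frames (Welford). Returns N x N mean and variance matrices.
// [[Rcpp::export]]
List sorted_cv_stats_cpp(IntegerMatrix xs, IntegerMatrix ys, int L) {
  int T = xs.nrow(), N = xs.ncol();
  std::vector<double> d((size_t)N * N), row(N);
  std::vector<double> mean((size_t)N * N, 0.0), m2((size_t)N * N, 0.0);
  std::vector<int> x(N), y(N);
  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < N; ++i) { x[i] = xs(t, i); y[i] = ys(t, i); }
    sorted_dmat_frame(x.data(), y.data(), N, L, d, row);
    for (size_t c = 0; c < d.size(); ++c) {
      double delta = d[c] - mean[c];
      mean[c] += delta / (t + 1);
      m2[c] += delta * (d[c] - mean[c]);
    }
  }
  NumericMatrix mn(N, N), vr(N, N);
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i) {
      mn(i, j) = mean[(size_t)j * N + i];
      vr(i, j) = T > 1 ? m2[(size_t)j * N + i] / (T - 1) : 0.0;
    }
  return List::create(_["mean"] = mn, _["var"] = vr);
}

// Cut-profile accumulation: for each within-segment pair (k, k+lag), a
// top-hat of height |dr| over (min, max) is bin-averaged onto the grid;
// result divided by lag (phase average). edges must be increasing & cover r.
// [[Rcpp::export]]
NumericVector zc1_cpp(NumericVector r, IntegerVector seg, int lag,
                      NumericVector edges) {
  int T = r.size(), nb = edges.size() - 1;
  double e0 = edges[0], h = (edges[nb] - edges[0]) / nb;
  NumericVector zc(nb);
  std::vector<double> diff(nb + 1, 0.0);
  for (int k = 0; k + lag < T; ++k) {
    if (seg[k] != seg[k + lag]) continue;
    double a = r[k], b = r[k + lag];
    double lo = std::min(a, b), hi = std::max(a, b);
    double w = hi - lo;
    if (w <= 0.0) continue;
    double u = (lo - e0) / h, v = (hi - e0) / h;
    if (u < 0) u = 0; if (v > nb) v = nb;
    if (v <= u) continue;
    int ilo = (int)u; if (ilo >= nb) ilo = nb - 1;
    int ihi = (int)v; if (ihi >= nb) ihi = nb - 1;
    if (ilo == ihi) {
      zc[ilo] += w * (v - u);
    } else {
      zc[ilo] += w * (ilo + 1 - u);
      zc[ihi] += w * (v - ihi);
      diff[ilo + 1] += w;
      diff[ihi] -= w;
    }
  }
  double run = 0.0;
  for (int b = 0; b < nb; ++b) { run += diff[b]; zc[b] += run; }
  for (int b = 0; b < nb; ++b) zc[b] /= lag;
  return zc;
}

// Seeded Markov-chain sampler; P row-stochastic, returns 1-based states.
// [[Rcpp::export]]
IntegerVector simulate_chain_cpp(NumericMatrix P, double n, int s0) {
  int S = P.nrow();
  long long T = (long long)n;
  IntegerVector out(T);
  int s = s0 - 1;
  for (long long t = 0; t < T; ++t) {
    out[t] = s + 1;
    double u = unif_rand(), c = 0.0;
    int nxt = S - 1;
    for (int j = 0; j < S; ++j) {
      c += P(s, j);
      if (u < c) { nxt = j; break; }
    }
    s = nxt;
  }
  return out;
}

// Overdamped Euler-Maruyama in the quartic double well
// V(x) = barrier * ((x/x0)^2 - 1)^2, reflecting walls at a and b
// (k_B T = 1, so x' = x - D0 V'(x) dt + sqrt(2 D0 dt) xi).
// [[Rcpp::export]]
NumericVector simulate_double_well_cpp(double barrier, double x0w,
                                       double a, double b,
                                       double D0, double dt, double n_steps,
                                       double x_init, int save_every) {
  long long steps = (long long)n_steps;
  long long nout = steps / save_every + 1;
  NumericVector out(nout);
  double x = x_init;
  double s = std::sqrt(2.0 * D0 * dt);
  double c = 4.0 * barrier / (x0w * x0w);
  long long k = 0;
  out[k++] = x;
  for (long long t = 1; t <= steps; ++t) {
    double force = -c * x * (x * x / (x0w * x0w) - 1.0);
    x += D0 * force * dt + s * norm_rand();
    while (x < a || x > b) {
      if (x < a) x = 2.0 * a - x;
      if (x > b) x = 2.0 * b - x;
    }
    if (t % save_every == 0) out[k++] = x;
  }
  return out;
}
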