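// Exact stochastic simulation engines for the molecule-number version of
// the leading-edge adhesion/protrusion model: First Reaction Method (FRM),
// Next Reaction Method (NRM, Gibson-Bruck) and the Next Subvolume Method
// (NSM) on a 1D periodic lattice in which only active Rac hops.
//
// The reaction network is the subset-resolved decomposition of the
// deterministic equations: turnover and maturation of a nascent adhesion
// remove a plain, phospho-only or PAK-bearing unit as separate channels, so
// summed channel drift equals the scaled deterministic rates at every state
// and the subset invariants P <= X <= N hold without clamping.
//
// All randomness comes from R's RNG (seeded via set.seed in the wrappers).

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

static const int N_CH = 18;
static const int N_SP = 6; // N, S, M, X, R, P

// stoichiometry[channel][species]
static const int STO[N_CH][N_SP] = {
  {+1, 0, 0, 0, 0, 0},  //  0 nascent formation
  {-1, 0, 0, 0, 0, 0},  //  1 turnover (plain)
  {-1, 0, 0, -1, 0, 0}, //  2 turnover (phospho)
  {-1, 0, 0, -1, 0, -1},//  3 turnover (PAK-bearing)
  {-1, +1, 0, 0, 0, 0}, //  4 maturation (plain)
  {-1, +1, 0, -1, 0, 0},//  5 maturation (phospho)
  {-1, +1, 0, -1, 0, -1},// 6 maturation (PAK-bearing)
  {0, -1, 0, 0, 0, 0},  //  7 stable disassembly
  {0, -1, 0, 0, 0, 0},  //  8 stable convective removal
  {0, 0, +1, 0, 0, 0},  //  9 myosin recruitment
  {0, 0, -1, 0, 0, 0},  // 10 myosin decay
  {0, 0, 0, +1, 0, 0},  // 11 paxillin phosphorylation
  {0, 0, 0, -1, 0, 0},  // 12 dephosphorylation (phospho-only)
  {0, 0, 0, -1, 0, -1}, // 13 dephosphorylation (PAK-bearing)
  {0, 0, 0, 0, +1, 0},  // 14 Rac activation
  {0, 0, 0, 0, -1, 0},  // 15 Rac deactivation
  {0, 0, 0, 0, 0, +1},  // 16 PAK activation
  {0, 0, 0, 0, 0, -1},  // 17 PAK deactivation
};

// which species each channel's propensity reads (for the NRM dependency
// graph); v reads (R, S), f reads M
static const bool READS[N_CH][N_SP] = {
  {false, true, false, false, true, false},  // 0: v
  {true, true, false, true, true, false},    // 1
  {false, true, false, true, true, true},    // 2
  {false, true, false, false, true, true},   // 3
  {true, false, true, true, false, false},   // 4
  {false, false, true, true, false, true},   // 5
  {false, false, true, false, false, true},  // 6
  {false, true, false, false, false, false}, // 7
  {false, true, false, false, true, false},  // 8
  {false, true, false, false, false, false}, // 9
  {false, false, true, false, false, false}, // 10
  {true, false, false, true, false, true},   // 11
  {false, false, false, true, false, true},  // 12
  {false, false, false, false, false, true}, // 13
  {false, false, false, true, false, false}, // 14
  {false, false, false, false, true, false}, // 15
  {false, false, false, true, true, true},   // 16
  {false, false, false, false, false, true}, // 17
};

struct Pars {
  double k_ecm, E_s, I_n, C_s, k_d_n, p0, v0, K_v;
  double k_a_s, k_d_s, k_a_m, k_d_m, k_a_x, k_d_x, k_a_r, k_d_r, k_a_p, k_d_p;
  double N_star, K_m, K_r;
};

static Pars unpack(const NumericVector& pv, double N_star, double K_m, double K_r) {
  Pars p;
  p.k_ecm = pv["k_ecm"]; p.E_s = pv["E_s"]; p.I_n = pv["I_n"]; p.C_s = pv["C_s"];
  p.k_d_n = pv["k_d_n"]; p.p0 = pv["p0"]; p.v0 = pv["v0"]; p.K_v = pv["K_v"];
  p.k_a_s = pv["k_a_s"]; p.k_d_s = pv["k_d_s"];
  p.k_a_m = pv["k_a_m"]; p.k_d_m = pv["k_d_m"];
  p.k_a_x = pv["k_a_x"]; p.k_d_x = pv["k_d_x"];
  p.k_a_r = pv["k_a_r"]; p.k_d_r = pv["k_d_r"];
  p.k_a_p = pv["k_a_p"]; p.k_d_p = pv["k_d_p"];
  p.N_star = N_star; p.K_m = K_m; p.K_r = K_r;
  return p;
}

static inline double velocity(const Pars& p, const double* X) {
  double r = X[4] / (p.K_r * p.N_star);
  double s = X[1] / p.N_star;
  return (p.v0 + r) / (p.v0 + r + p.K_v) / (1.0 + p.I_n * s);
}

static void propensities(const Pars& p, const double* X, double* a) {
  const double N = X[0], S = X[1], M = X[2], Xx = X[3], R = X[4], P = X[5];
  const double v = velocity(p, X);
  const double m = M / (p.K_m * p.N_star);
  const double f = 1.0 + p.E_s * m;
  a[0]  = p.N_star * p.k_ecm * v;
  a[1]  = p.k_d_n * v * (N - Xx);
  a[2]  = p.k_d_n * v * (Xx - P);
  a[3]  = p.k_d_n * v * P;
  a[4]  = p.k_a_s * f * (N - Xx);
  a[5]  = p.k_a_s * f * (Xx - P);
  a[6]  = p.k_a_s * f * P;
  a[7]  = p.k_d_s * S;
  a[8]  = p.k_d_s * p.C_s * v * S;
  a[9]  = p.k_a_m * S;
  a[10] = p.k_d_m * M;
  a[11] = p.k_a_x * (p.p0 + P / p.N_star) * (N - Xx);
  a[12] = p.k_d_x * (Xx - P);
  a[13] = p.k_d_x * P;
  a[14] = p.k_a_r * Xx;
  a[15] = p.k_d_r * R;
  a[16] = p.k_a_p * R * (Xx - P) / (p.K_r * p.N_star);
  a[17] = p.k_d_p * P;
}

static inline void check_state(const double* X) {
  for (int i = 0; i < N_SP; ++i)
    if (X[i] < 0) stop("stochastic engine: negative molecule count");
  if (X[3] > X[0]) stop("stochastic engine: invariant X <= N violated");
  if (X[5] > X[3]) stop("stochastic engine: invariant P <= X violated");
}

// [[Rcpp::export(name = ".eval_propensities_cpp")]]
NumericVector eval_propensities_cpp(NumericVector pv, double N_star,
                                    double K_m, double K_r,
                                    NumericVector state) {
  Pars p = unpack(pv, N_star, K_m, K_r);
  double X[N_SP];
  for (int i = 0; i < N_SP; ++i) X[i] = state[i];
  double a[N_CH];
  propensities(p, X, a);
  return NumericVector(a, a + N_CH);
}

// [[Rcpp::export(name = ".stoichiometry_cpp")]]
IntegerMatrix stoichiometry_cpp() {
  IntegerMatrix S(N_CH, N_SP);
  for (int c = 0; c < N_CH; ++c)
    for (int i = 0; i < N_SP; ++i) S(c, i) = STO[c][i];
  return S;
}

struct Recorder {
  std::vector<double> times;
  IntegerMatrix counts;
  NumericVector v;
  R_xlen_t next;
  Recorder(double t_end, double dt_out) : next(0) {
    for (double t = 0.0; t < t_end - 1e-12; t += dt_out) times.push_back(t);
    times.push_back(t_end);
    counts = IntegerMatrix((int)times.size(), N_SP);
    v = NumericVector((int)times.size());
  }
  // record all sample points strictly before time t
  void advance(double t, const Pars& p, const double* X) {
    while (next < (R_xlen_t)times.size() && times[next] < t) {
      for (int i = 0; i < N_SP; ++i) counts(next, i) = (int)X[i];
      v[next] = velocity(p, X);
      ++next;
    }
  }
  void finish(const Pars& p, const double* X) {
    advance(times.back() + 1.0, p, X);
  }
  List as_list(double n_events) {
    colnames(counts) = CharacterVector::create("N", "S", "M", "X", "R", "P");
    return List::create(_["t"] = NumericVector(times.begin(), times.end()),
                        _["counts"] = counts, _["v"] = v,
                        _["n_events"] = n_events);
  }
};

// ---------------------------------------------------------------- FRM ----

// [[Rcpp::export(name = ".simulate_frm_cpp")]]
List simulate_frm_cpp(NumericVector pv, double N_star, double K_m, double K_r,
                      IntegerVector state0, double t_end, double dt_out,
                      double max_events) {
  Pars p = unpack(pv, N_star, K_m, K_r);
  double X[N_SP];
  for (int i = 0; i < N_SP; ++i) X[i] = state0[i];
  check_state(X);
  Recorder rec(t_end, dt_out);
  double t = 0.0, a[N_CH], n_events = 0.0;
  while (t < t_end) {
    propensities(p, X, a);
    double tau_min = R_PosInf;
    int c_min = -1;
    for (int c = 0; c < N_CH; ++c) {
      if (a[c] <= 0.0) continue;
      double tau = R::rexp(1.0) / a[c];
      if (tau < tau_min) { tau_min = tau; c_min = c; } // ties: lowest index kept
    }
    if (c_min < 0) break; // no channel can fire: frozen until t_end
    double t_next = t + tau_min;
    if (t_next > t_end) { t = t_end; break; }
    rec.advance(t_next, p, X);
    for (int i = 0; i < N_SP; ++i) X[i] += STO[c_min][i];
    check_state(X);
    t = t_next;
    if (++n_events >= max_events) stop("event budget exceeded (max_events)");
  }
  rec.finish(p, X);
  return rec.as_list(n_events);
}

// ---------------------------------------------------------------- NRM ----

struct Heap { // indexed binary min-heap over absolute firing times
  std::vector<double> key;
  std::vector<int> heap, pos;
  Heap(int n) : key(n, R_PosInf), heap(n), pos(n) {
    for (int i = 0; i < n; ++i) { heap[i] = i; pos[i] = i; }
  }
  void swap_nodes(int i, int j) {
    std::swap(heap[i], heap[j]);
    pos[heap[i]] = i; pos[heap[j]] = j;
  }
  void up(int i) {
    while (i > 0) {
      int par = (i - 1) / 2;
      if (key[heap[i]] < key[heap[par]]) { swap_nodes(i, par); i = par; }
      else break;
    }
  }
  void down(int i) {
    int n = (int)heap.size();
    for (;;) {
      int l = 2 * i + 1, r = l + 1, m = i;
      if (l < n && key[heap[l]] < key[heap[m]]) m = l;
      if (r < n && key[heap[r]] < key[heap[m]]) m = r;
      if (m == i) break;
      swap_nodes(i, m); i = m;
    }
  }
  void update(int node, double k) {
    double old = key[node];
    key[node] = k;
    if (k < old) up(pos[node]); else down(pos[node]);
  }
  int top() const { return heap[0]; }
  double top_key() const { return key[heap[0]]; }
};

// [[Rcpp::export(name = ".simulate_nrm_cpp")]]
List simulate_nrm_cpp(NumericVector pv, double N_star, double K_m, double K_r,
                      IntegerVector state0, double t_end, double dt_out,
                      double max_events) {
  Pars p = unpack(pv, N_star, K_m, K_r);
  double X[N_SP];
  for (int i = 0; i < N_SP; ++i) X[i] = state0[i];
  check_state(X);

  // dependency graph: channels whose propensity reads a species changed by c
  std::vector<std::vector<int>> dep(N_CH);
  for (int c = 0; c < N_CH; ++c) {
    for (int c2 = 0; c2 < N_CH; ++c2) {
      bool affected = (c2 == c);
      for (int i = 0; i < N_SP && !affected; ++i)
        if (STO[c][i] != 0 && READS[c2][i]) affected = true;
      if (affected) dep[c].push_back(c2);
    }
  }

  Recorder rec(t_end, dt_out);
  double a[N_CH];
  propensities(p, X, a);
  Heap heap(N_CH);
  for (int c = 0; c < N_CH; ++c)
    heap.update(c, a[c] > 0.0 ? R::rexp(1.0) / a[c] : R_PosInf);

  double t = 0.0, n_events = 0.0;
  double a_new[N_CH];
  while (true) {
    int c = heap.top();
    double t_next = heap.top_key();
    if (!R_finite(t_next) || t_next > t_end) { t = t_end; break; }
    rec.advance(t_next, p, X);
    for (int i = 0; i < N_SP; ++i) X[i] += STO[c][i];
    check_state(X);
    t = t_next;
    propensities(p, X, a_new);
    for (int c2 : dep[c]) {
      double tn;
      if (a_new[c2] <= 0.0) tn = R_PosInf;
      else if (c2 == c || !R_finite(heap.key[c2]) || a[c2] <= 0.0)
        tn = t + R::rexp(1.0) / a_new[c2];
      else
        tn = t + (a[c2] / a_new[c2]) * (heap.key[c2] - t);
      heap.update(c2, tn);
      a[c2] = a_new[c2];
    }
    if (++n_events >= max_events) stop("event budget exceeded (max_events)");
  }
  rec.finish(p, X);
  return rec.as_list(n_events);
}

// ---------------------------------------------------------------- NSM ----

// [[Rcpp::export(name = ".simulate_nsm_cpp")]]
List simulate_nsm_cpp(NumericVector pv, double N_star, double K_m, double K_r,
                      IntegerMatrix state0, double hop_rate, double t_end,
                      double dt_out, double max_events) {
  Pars p = unpack(pv, N_star, K_m, K_r);
  const int ns = state0.nrow();
  std::vector<std::array<double, N_SP>> X(ns);
  for (int k = 0; k < ns; ++k) {
    for (int i = 0; i < N_SP; ++i) X[k][i] = state0(k, i);
    check_state(X[k].data());
  }

  // sampling grid
  std::vector<double> times;
  for (double tt = 0.0; tt < t_end - 1e-12; tt += dt_out) times.push_back(tt);
  times.push_back(t_end);
  const int nt = (int)times.size();
  List count_mats(N_SP);
  std::vector<IntegerMatrix> cm;
  for (int i = 0; i < N_SP; ++i) cm.push_back(IntegerMatrix(ns, nt));
  NumericMatrix vmat(ns, nt);
  int next_sample = 0;

  std::vector<std::array<double, N_CH>> a(ns);
  std::vector<double> a_tot(ns); // reactions + both hop directions
  auto refresh = [&](int k) {
    propensities(p, X[k].data(), a[k].data());
    double s = 0.0;
    for (int c = 0; c < N_CH; ++c) s += a[k][c];
    s += 2.0 * hop_rate * X[k][4];
    a_tot[k] = s;
  };
  Heap heap(ns);
  for (int k = 0; k < ns; ++k) {
    refresh(k);
    heap.update(k, a_tot[k] > 0.0 ? R::rexp(1.0) / a_tot[k] : R_PosInf);
  }

  double t = 0.0, n_events = 0.0;
  auto record_until = [&](double tnext) {
    while (next_sample < nt && times[next_sample] < tnext) {
      for (int k = 0; k < ns; ++k) {
        for (int i = 0; i < N_SP; ++i) cm[i](k, next_sample) = (int)X[k][i];
        vmat(k, next_sample) = velocity(p, X[k].data());
      }
      ++next_sample;
    }
  };

  while (true) {
    int k = heap.top();
    double t_next = heap.top_key();
    if (!R_finite(t_next) || t_next > t_end) { t = t_end; break; }
    record_until(t_next);
    t = t_next;
    // choose reaction vs diffusion within subvolume k
    double u = unif_rand() * a_tot[k];
    double acc = 0.0;
    int fired = -1;
    for (int c = 0; c < N_CH; ++c) {
      acc += a[k][c];
      if (u < acc) { fired = c; break; }
    }
    if (fired >= 0) {
      for (int i = 0; i < N_SP; ++i) X[k][i] += STO[fired][i];
      check_state(X[k].data());
      refresh(k);
      heap.update(k, a_tot[k] > 0.0 ? t + R::rexp(1.0) / a_tot[k] : R_PosInf);
    } else {
      // diffusion: one active Rac hops to a uniformly chosen neighbour
      int j = (unif_rand() < 0.5) ? (k + 1) % ns : (k - 1 + ns) % ns;
      X[k][4] -= 1.0;
      X[j][4] += 1.0;
      check_state(X[k].data());
      check_state(X[j].data());
      refresh(k);
      refresh(j);
      heap.update(k, a_tot[k] > 0.0 ? t + R::rexp(1.0) / a_tot[k] : R_PosInf);
      heap.update(j, a_tot[j] > 0.0 ? t + R::rexp(1.0) / a_tot[j] : R_PosInf);
    }
    if (++n_events >= max_events) stop("event budget exceeded (max_events)");
  }
  record_until(t_end + 1.0);
  for (int i = 0; i < N_SP; ++i) count_mats[i] = cm[i];
  count_mats.names() = CharacterVector::create("N", "S", "M", "X", "R", "P");
  return List::create(_["t"] = NumericVector(times.begin(), times.end()),
                      _["counts"] = count_mats, _["v"] = vmat,
                      _["n_events"] = n_events);
}
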