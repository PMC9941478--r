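#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// One explicit Euler step of the diffusion operator on the interior-cell
// vector. nbr holds, per interior cell, the interior index (0-based) of each
// lattice neighbour, or -1 where the neighbour is excluded (no-flux wall).
// The update c_i += alpha * sum_j (c_j - c_i) is symmetric in (i,j), so the
// total amount is conserved to round-off.
// [[Rcpp::export]]
NumericVector cpp_diffuse(NumericVector conc, IntegerMatrix nbr, double alpha) {
  const int n = conc.size(), m = nbr.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0, ci = conc[i];
    for (int j = 0; j < m; ++j) {
      int k = nbr(i, j);
      if (k >= 0) acc += conc[k] - ci;
    }
    out[i] = ci + alpha * acc;
  }
  return out;
}

// Multi-source breadth-first flood fill over the interior-cell graph.
// Returns logical vector: reachable from cell `start` (0-based).
// [[Rcpp::export]]
LogicalVector cpp_flood(IntegerMatrix nbr, int start) {
  const int n = nbr.nrow(), m = nbr.ncol();
  LogicalVector seen(n);
  std::vector<int> stack;
  stack.reserve(n);
  stack.push_back(start);
  seen[start] = true;
  while (!stack.empty()) {
    int i = stack.back();
    stack.pop_back();
    for (int j = 0; j < m; ++j) {
      int k = nbr(i, j);
      if (k >= 0 && !seen[k]) {
        seen[k] = true;
        stack.push_back(k);
      }
    }
  }
  return seen;
}

static inline double box_mean(const NumericVector &f, const IntegerVector &idx) {
  double s = 0.0;
  for (int j = 0; j < idx.size(); ++j) s += f[idx[j]];
  return s / idx.size();
}

// Full hybrid loop: operator splitting per step of
//   (1) IP3 diffusion + photorelease source (while t <= t_ph),
//   (2) Ca diffusion + leak/SERCA reactions + release flux at open clusters,
//   (3) one frozen-propensity stochastic update per cluster.
// Cluster states: 0 = C, 1 = O, 2 = I1, 3 = I2.
// Uses R's RNG (seed with set.seed() before calling).
//
// ctrl (named list) keys:
//   dt, n_steps, record_every (int), h_vol (cell volume, for audits only)
//   ip3_dynamic (bool), alpha_ip3, src_cells (int vec), src_rate, t_ph
//   ca_dynamic (bool), alpha_ca, vp, kp, j_leak, j_rel
//   stochastic (bool), k_co, k_ip, k_oc, k_oi1, k_i1o, k_i1i2, k_i2i1, k_i2c
//   ca_offset, threshold
//   stop_mode (0 none, 1 first opening, 2 first threshold crossing of cluster 1)
//   t0
// [[Rcpp::export]]
List cpp_sim(NumericVector ip3_init, NumericVector ca_init, IntegerMatrix nbr,
             IntegerVector cl_cell, List cl_det, IntegerVector cl_state,
             IntegerVector cl_clamp, List ctrl) {
  NumericVector ip3 = clone(ip3_init);
  NumericVector ca = clone(ca_init);
  const int n = ip3.size();
  const int ncl = cl_cell.size();

  const double dt = as<double>(ctrl["dt"]);
  const long n_steps = (long)as<double>(ctrl["n_steps"]);
  const int record_every = as<int>(ctrl["record_every"]);
  const bool ip3_dyn = as<bool>(ctrl["ip3_dynamic"]);
  const double a_ip3 = as<double>(ctrl["alpha_ip3"]);
  IntegerVector src = as<IntegerVector>(ctrl["src_cells"]);
  const double src_rate = as<double>(ctrl["src_rate"]);
  const double t_ph = as<double>(ctrl["t_ph"]);
  const bool ca_dyn = as<bool>(ctrl["ca_dynamic"]);
  const double a_ca = as<double>(ctrl["alpha_ca"]);
  const double vp = as<double>(ctrl["vp"]);
  const double kp = as<double>(ctrl["kp"]);
  const double j_leak = as<double>(ctrl["j_leak"]);
  const double j_rel = as<double>(ctrl["j_rel"]);
  const bool stoch = as<bool>(ctrl["stochastic"]);
  const double k_co = as<double>(ctrl["k_co"]);
  const double k_ip = as<double>(ctrl["k_ip"]);
  const double k_oc = as<double>(ctrl["k_oc"]);
  const double k_oi1 = as<double>(ctrl["k_oi1"]);
  const double k_i1o = as<double>(ctrl["k_i1o"]);
  const double k_i1i2 = as<double>(ctrl["k_i1i2"]);
  const double i1i2_hill = as<double>(ctrl["i1i2_hill"]);
  const double k_i2i1 = as<double>(ctrl["k_i2i1"]);
  const double k_i2c = as<double>(ctrl["k_i2c"]);
  const double ca_off = as<double>(ctrl["ca_offset"]);
  const double thr = as<double>(ctrl["threshold"]);
  const int stop_mode = as<int>(ctrl["stop_mode"]);
  const double t0 = as<double>(ctrl["t0"]);
  const double kp2 = kp * kp;

  std::vector<IntegerVector> det(ncl);
  for (int c = 0; c < ncl; ++c) det[c] = as<IntegerVector>(cl_det[c]);

  // Ca fast path: while no cluster is open and the Ca field sits at a
  // uniform value whose leak/SERCA terms balance, the deterministic Ca
  // update is the identity and is skipped. The field "wakes" on any opening
  // and goes back to sleep once the released Ca has relaxed to basal
  // (max deviation < 1e-7 uM, then snapped to the uniform value).
  double ca_base = ca[0];
  bool ca_uniform0 = true;
  for (int i = 1; i < n; ++i)
    if (std::fabs(ca[i] - ca_base) > 1e-12) { ca_uniform0 = false; break; }
  const double react_base =
      j_leak - vp * ca_base * ca_base / (kp2 + ca_base * ca_base);
  bool can_sleep = ca_uniform0 && std::fabs(react_base) < 1e-12;
  bool asleep = can_sleep;
  for (int c = 0; c < ncl; ++c) if (cl_state[c] == 1) asleep = false;
  int sleep_check = 0;

  const long n_rec = n_steps / record_every + 1;
  NumericVector rec_t(n_rec);
  NumericMatrix rec_ca(n_rec, ncl), rec_ip3(n_rec, ncl);
  NumericVector rec_dom(n_rec);
  std::vector<double> ev_t;
  std::vector<int> ev_cl, ev_from, ev_to;
  double max_adt = 0.0, stop_time = NA_REAL;
  bool neg = false;
  long irec = 0;

  RNGScope scope;

  // record initial state
  {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += ca[i];
    rec_t[0] = t0;
    rec_dom[0] = s / n;
    for (int c = 0; c < ncl; ++c) {
      rec_ca(0, c) = box_mean(ca, det[c]);
      rec_ip3(0, c) = box_mean(ip3, det[c]);
    }
    irec = 1;
  }

  long step = 0;
  bool stopped = false;
  for (step = 0; step < n_steps && !stopped; ++step) {
    const double t = t0 + step * dt; // state time at start of step

    // (1) IP3 field
    if (ip3_dyn) {
      if (a_ip3 > 0) ip3 = cpp_diffuse(ip3, nbr, a_ip3);
      if (src_rate > 0 && t <= t_ph) {
        for (int j = 0; j < src.size(); ++j) ip3[src[j]] += src_rate * dt;
      }
    }

    // (2) Ca field
    if (ca_dyn && !asleep) {
      if (a_ca > 0) ca = cpp_diffuse(ca, nbr, a_ca);
      for (int i = 0; i < n; ++i) {
        double c = ca[i];
        ca[i] = c + dt * (j_leak - vp * c * c / (kp2 + c * c));
      }
      bool any_open = false;
      for (int c = 0; c < ncl; ++c)
        if (cl_state[c] == 1) { ca[cl_cell[c]] += dt * j_rel; any_open = true; }
      if (can_sleep && !any_open && ++sleep_check >= 100) {
        sleep_check = 0;
        double dev = 0.0;
        for (int i = 0; i < n; ++i)
          dev = std::max(dev, std::fabs(ca[i] - ca_base));
        if (dev < 1e-7) {
          for (int i = 0; i < n; ++i) ca[i] = ca_base;
          asleep = true;
        }
      }
    }

    // (3) stochastic cluster transitions (frozen propensities over dt)
    if (stoch) {
      for (int c = 0; c < ncl; ++c) {
        if (cl_clamp[c] >= 0) continue;
        double cab = box_mean(ca, det[c]) + ca_off;
        double ipb = box_mean(ip3, det[c]);
        double a[3];
        int to[3];
        int nr = 0;
        switch (cl_state[c]) {
        case 0: { // C -> O
          double q = ipb / (ipb + k_ip);
          a[0] = k_co * cab * q * q * q * q;
          to[0] = 1;
          nr = 1;
          break;
        }
        case 1: // O -> C, O -> I1
          a[0] = k_oc;  to[0] = 0;
          a[1] = k_oi1; to[1] = 2;
          nr = 2;
          break;
        case 2: // I1 -> O, I1 -> I2 (Ca-dependent)
          a[0] = k_i1o;            to[0] = 1;
          a[1] = k_i1i2 * std::pow(cab, i1i2_hill); to[1] = 3;
          nr = 2;
          break;
        default: // I2 -> I1, I2 -> C
          a[0] = k_i2i1; to[0] = 2;
          a[1] = k_i2c;  to[1] = 0;
          nr = 2;
        }
        double atot = 0.0;
        for (int j = 0; j < nr; ++j) atot += a[j];
        if (atot <= 0) continue;
        double adt = atot * dt;
        if (adt > max_adt) max_adt = adt;
        if (unif_rand() < -std::expm1(-adt)) {
          double u = unif_rand() * atot, acc = 0.0;
          int pick = nr - 1;
          for (int j = 0; j < nr; ++j) {
            acc += a[j];
            if (u <= acc) { pick = j; break; }
          }
          int from = cl_state[c];
          cl_state[c] = to[pick];
          ev_t.push_back(t + dt);
          ev_cl.push_back(c + 1);
          ev_from.push_back(from);
          ev_to.push_back(to[pick]);
          if (to[pick] == 1) asleep = false;
          if (stop_mode == 1 && to[pick] == 1) {
            stop_time = t + dt;
            stopped = true;
          }
        }
      }
    }

    // stop on threshold crossing of cluster 1's detection volume
    if (stop_mode == 2 && !stopped) {
      if (box_mean(ca, det[0]) >= thr) {
        stop_time = t + dt;
        stopped = true;
      }
    }

    if ((step + 1) % record_every == 0 && irec < n_rec) {
      double s = 0.0;
      bool bad = false;
      for (int i = 0; i < n; ++i) {
        s += ca[i];
        if (ca[i] < 0 || ip3[i] < 0 || !R_finite(ca[i]) || !R_finite(ip3[i]))
          bad = true;
      }
      if (bad) neg = true;
      rec_t[irec] = t + dt;
      rec_dom[irec] = s / n;
      for (int c = 0; c < ncl; ++c) {
        rec_ca(irec, c) = box_mean(ca, det[c]);
        rec_ip3(irec, c) = box_mean(ip3, det[c]);
      }
      ++irec;
    }
  }

  return List::create(
    _["t"] = rec_t, _["ca_local"] = rec_ca, _["ip3_local"] = rec_ip3,
    _["ca_domain"] = rec_dom, _["n_recorded"] = (double)irec,
    _["ev_t"] = wrap(ev_t), _["ev_cluster"] = wrap(ev_cl),
    _["ev_from"] = wrap(ev_from), _["ev_to"] = wrap(ev_to),
    _["ip3"] = ip3, _["ca"] = ca, _["state"] = cl_state,
    _["stop_time"] = stop_time, _["max_adt"] = max_adt,
    _["negative"] = neg, _["t_end"] = t0 + step * dt);
}

// Flood fill directly on an occupancy array (column-major, dims d), starting
// from linear cell `start` (0-based, must be TRUE). Returns number of
// reachable TRUE cells.
// [[Rcpp::export]]
int cpp_flood_count(LogicalVector occ, IntegerVector d, int start) {
  const int nd = d.size();
  int stride[3] = {1, 0, 0};
  for (int k = 1; k < nd; ++k) stride[k] = stride[k - 1] * d[k - 1];
  std::vector<bool> seen(occ.size(), false);
  std::vector<int> stack;
  stack.push_back(start);
  seen[start] = true;
  int count = 0;
  while (!stack.empty()) {
    int i = stack.back();
    stack.pop_back();
    ++count;
    int rem = i;
    int coord[3] = {0, 0, 0};
    for (int k = 0; k < nd; ++k) {
      coord[k] = rem % d[k];
      rem /= d[k];
    }
    for (int k = 0; k < nd; ++k) {
      for (int s = -1; s <= 1; s += 2) {
        int c = coord[k] + s;
        if (c < 0 || c >= d[k]) continue;
        int j = i + s * stride[k];
        if (occ[j] && !seen[j]) {
          seen[j] = true;
          stack.push_back(j);
        }
      }
    }
  }
  return count;
}
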