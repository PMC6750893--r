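// Discrete RBC advection kernel.
//
// Per time step the flow field is frozen (quasi-static solve in R); this
// kernel moves every RBC by v_rbc * dt along its vessel subject to a minimum
// spacing of one RBC length behind its leader, routes RBCs that reach a node
// (divergent: empirical logit split for mothers >= dstar um, pressure-force
// bifurcation rule below; passive variants: Bernoulli on the bulk-flow
// fraction), merges convergent arrivals in arrival order, and removes RBCs at
// boundary outflows. All randomness is drawn from R's RNG so runs are
// reproducible from a single seed.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double GAP_EPS = 1e-9;

// variant codes (kept in sync with R)
enum { WITH_RBCS = 1, PASSIVE = 2, NO_PHASE_SEP = 3 };

static inline double logit(double x) { return std::log(x / (1.0 - x)); }

// Pries phase-separation logit law (network coefficients, 1990 family).
// Returns the RBC-flux fraction entering daughter 1 given the bulk-flow
// fraction fqb into daughter 1.
static double pries_fqe(double fqb, double d_mother, double d1, double d2,
                        double hd) {
  double oneh = 1.0 - hd;
  if (oneh < 0.0) oneh = 0.0;
  double x0 = 0.964 * oneh / d_mother;
  if (x0 > 0.499) x0 = 0.499;
  if (fqb <= x0) return 0.0;
  if (fqb >= 1.0 - x0) return 1.0;
  double r12 = (d1 * d1 - d2 * d2) / (d1 * d1 + d2 * d2);
  double A = -13.29 * r12 * oneh / d_mother;
  double B = 1.0 + 6.98 * oneh / d_mother;
  double xr = (fqb - x0) / (1.0 - 2.0 * x0);
  double lg = A + B * logit(xr);
  return 1.0 / (1.0 + std::exp(-lg));
}

// [[Rcpp::export(name = ".cf_pries_fqe")]]
NumericVector cf_pries_fqe(NumericVector fqb, double d_mother, double d1,
                           double d2, double hd) {
  NumericVector out(fqb.size());
  for (int i = 0; i < fqb.size(); ++i)
    out[i] = pries_fqe(fqb[i], d_mother, d1, d2, hd);
  return out;
}

struct Arrival {
  double t;
  int vessel; // 0-based
  bool operator<(const Arrival& o) const { return t > o.t; } // min-heap
};

// [[Rcpp::export(name = ".cf_advance")]]
List cf_advance(IntegerVector rbc_vessel, NumericVector rbc_s, IntegerVector rbc_id,
                IntegerVector ifrom, IntegerVector ito,
                NumericVector L, NumericVector D, NumericVector lrbc,
                NumericVector q, NumericVector vrbc_um_s, NumericVector hd,
                LogicalVector node_boundary, NumericVector node_p,
                IntegerVector adj_ptr, IntegerVector adj_ves,
                double dt, int variant, double dstar) {
  const int nE = L.size();
  const int nR = rbc_vessel.size();
  RNGScope rng;

  std::vector<int> dir(nE);
  for (int e = 0; e < nE; ++e) dir[e] = q[e] > 0 ? 1 : (q[e] < 0 ? -1 : 0);

  // flow coordinate (distance travelled from the upstream end)
  std::vector<double> pos(nR);
  std::vector<int> ves(nR);
  for (int r = 0; r < nR; ++r) {
    int e = rbc_vessel[r] - 1;
    ves[r] = e;
    pos[r] = dir[e] >= 0 ? rbc_s[r] : L[e] - rbc_s[r];
  }

  // per-vessel occupant lists, front (largest pos) first
  std::vector<std::vector<int>> occ(nE);
  {
    std::vector<int> idx(nR);
    for (int r = 0; r < nR; ++r) idx[r] = r;
    std::sort(idx.begin(), idx.end(), [&](int a, int b) {
      if (ves[a] != ves[b]) return ves[a] < ves[b];
      if (pos[a] != pos[b]) return pos[a] > pos[b];
      return rbc_id[a] < rbc_id[b];
    });
    for (int k = 0; k < nR; ++k) occ[ves[idx[k]]].push_back(idx[k]);
  }

  std::vector<bool> settled(nR, false); // position already final this step
  std::vector<bool> alive(nR, true);
  std::vector<int> crossings(nE, 0);
  std::vector<int> front_at(nE, 0); // index into occ[e] of current front
  int ejected = 0, blocked_events = 0;

  std::priority_queue<Arrival> pq;
  auto push_front_if_crossing = [&](int e) {
    if (dir[e] == 0 || vrbc_um_s[e] <= 0) return;
    if (front_at[e] >= (int)occ[e].size()) return;
    int r = occ[e][front_at[e]];
    double trem = (L[e] - pos[r]) / vrbc_um_s[e];
    if (vrbc_um_s[e] * dt > L[e] - pos[r]) {
      Arrival a; a.t = trem; a.vessel = e; pq.push(a);
    }
  };
  for (int e = 0; e < nE; ++e) push_front_if_crossing(e);

  // rear occupant position (current) of a vessel, or +inf if empty
  auto rear_pos = [&](int tv) {
    for (int k = (int)occ[tv].size() - 1; k >= 0; --k) {
      int r = occ[tv][k];
      if (!alive[r] || ves[r] != tv) continue;
      return pos[r];
    }
    return std::numeric_limits<double>::infinity();
  };
  auto rear_gap_ok = [&](int tv) {
    double rp = rear_pos(tv);
    return !std::isfinite(rp) || rp >= lrbc[tv] - GAP_EPS;
  };

  while (!pq.empty()) {
    Arrival a = pq.top(); pq.pop();
    int m = a.vessel;
    if (front_at[m] >= (int)occ[m].size()) continue;
    int r = occ[m][front_at[m]];
    // stale entry guard: recompute arrival feasibility
    if (settled[r] || !alive[r]) continue;
    double trem_chk = (L[m] - pos[r]) / vrbc_um_s[m];
    if (std::abs(trem_chk - a.t) > 1e-12) continue;
    int nd = dir[m] > 0 ? ito[m] - 1 : ifrom[m] - 1;

    if (node_boundary[nd]) {
      alive[r] = false;
      ejected++;
      crossings[m]++;
      front_at[m]++;
      push_front_if_crossing(m);
      continue;
    }
    // candidate outflow vessels at nd
    std::vector<int> cand;
    for (int k = adj_ptr[nd] - 1; k < adj_ptr[nd + 1] - 1; ++k) {
      int e = adj_ves[k] - 1;
      if (e == m) continue;
      bool outgoing = (q[e] > 0 && ifrom[e] - 1 == nd) ||
                      (q[e] < 0 && ito[e] - 1 == nd);
      if (outgoing) cand.push_back(e);
    }
    std::sort(cand.begin(), cand.end());

    int target = -1;
    if (cand.empty()) {
      // dead end under the instantaneous field: wait at the node
      pos[r] = L[m];
      settled[r] = true;
      blocked_events++;
      continue; // front stays; followers clamp behind it
    } else if (cand.size() == 1) {
      target = cand[0];
      if (!rear_gap_ok(target)) target = -2;
    } else if (cand.size() == 2) {
      int d1 = cand[0], d2 = cand[1];
      double q1 = std::fabs(q[d1]), q2 = std::fabs(q[d2]);
      double fqb = q1 / (q1 + q2);
      int pref;
      if (variant == WITH_RBCS && D[m] >= dstar) {
        double fqe = pries_fqe(fqb, D[m], D[d1], D[d2], hd[m]);
        pref = (unif_rand() < fqe) ? d1 : d2;
      } else if (variant == WITH_RBCS) {
        // bifurcation rule: largest pressure force (dp/L) * area
        int nd1 = (ifrom[d1] - 1 == nd) ? ito[d1] - 1 : ifrom[d1] - 1;
        int nd2 = (ifrom[d2] - 1 == nd) ? ito[d2] - 1 : ifrom[d2] - 1;
        double F1 = (node_p[nd] - node_p[nd1]) / L[d1] * D[d1] * D[d1];
        double F2 = (node_p[nd] - node_p[nd2]) / L[d2] * D[d2] * D[d2];
        double scale = std::max(std::fabs(F1), std::fabs(F2));
        if (scale > 0 && std::fabs(F1 - F2) <= 1e-12 * scale)
          pref = (unif_rand() < 0.5) ? d1 : d2; // exact tie: fair coin
        else
          pref = F1 > F2 ? d1 : d2;
      } else {
        // passive particles / no phase separation: follow the bulk flow
        pref = (unif_rand() < fqb) ? d1 : d2;
      }
      int other = (pref == d1) ? d2 : d1;
      if (rear_gap_ok(pref)) target = pref;
      else if (rear_gap_ok(other)) { target = other; blocked_events++; }
      else target = -2;
    } else {
      // node of degree > 3: split by bulk-flow fractions (legal but not a
      // bifurcation; excluded from analyses)
      double qt = 0;
      for (int e : cand) qt += std::fabs(q[e]);
      double u = unif_rand() * qt, acc = 0;
      target = cand.back();
      for (int e : cand) { acc += std::fabs(q[e]); if (u <= acc) { target = e; break; } }
      if (!rear_gap_ok(target)) target = -2;
    }

    if (target == -2) {
      // all admissible daughters at packing limit: traffic jam, wait
      pos[r] = L[m];
      settled[r] = true;
      blocked_events++;
      continue;
    }
    // enter target vessel
    double trem = dt - a.t;
    double entry = vrbc_um_s[target] * trem;
    double rp = rear_pos(target);
    if (std::isfinite(rp) && entry > rp - lrbc[target])
      entry = rp - lrbc[target];
    if (entry < 0) entry = 0;
    crossings[m]++;
    front_at[m]++;
    // move r into target
    ves[r] = target;
    pos[r] = entry;
    settled[r] = true;
    occ[target].push_back(r);
    push_front_if_crossing(m);
  }

  // advance everyone else, front to back, clamped behind the leader
  for (int e = 0; e < nE; ++e) {
    double lead = std::numeric_limits<double>::infinity();
    for (size_t k = 0; k < occ[e].size(); ++k) {
      int r = occ[e][k];
      if (!alive[r]) continue;
      if (ves[r] != e) continue; // moved to another vessel already
      if (!settled[r]) {
        double np = pos[r] + (dir[e] == 0 ? 0.0 : vrbc_um_s[e] * dt);
        if (np > L[e]) np = L[e];
        if (std::isfinite(lead) && np > lead - lrbc[e]) np = lead - lrbc[e];
        if (np < pos[r]) np = pos[r]; // never pushed backwards
        pos[r] = np;
        settled[r] = true;
      } else if (std::isfinite(lead) && pos[r] > lead - lrbc[e] + GAP_EPS) {
        pos[r] = lead - lrbc[e]; // entrant squeezed by a blocked leader
      }
      lead = pos[r];
    }
  }

  // spacing audit; occupant lists stay sorted front-to-back (entrants are
  // appended behind all residents by the entry rule), so one pass suffices
  double min_slack = std::numeric_limits<double>::infinity();
  for (int e = 0; e < nE; ++e) {
    double lead = std::numeric_limits<double>::infinity();
    for (int r : occ[e]) {
      if (!alive[r] || ves[r] != e) continue;
      if (std::isfinite(lead)) {
        double slack = lead - pos[r] - lrbc[e];
        if (slack < min_slack) min_slack = slack;
      }
      lead = pos[r];
    }
  }

  // pack results
  int nOut = 0;
  for (int r = 0; r < nR; ++r) if (alive[r]) nOut++;
  IntegerVector o_ves(nOut), o_id(nOut);
  NumericVector o_s(nOut);
  int j = 0;
  for (int r = 0; r < nR; ++r) {
    if (!alive[r]) continue;
    int e = ves[r];
    o_ves[j] = e + 1;
    o_s[j] = dir[e] >= 0 ? pos[r] : L[e] - pos[r];
    o_id[j] = rbc_id[r];
    j++;
  }
  return List::create(_["vessel"] = o_ves, _["s"] = o_s, _["id"] = o_id,
                      _["ejected"] = ejected,
                      _["crossings"] = IntegerVector(crossings.begin(), crossings.end()),
                      _["min_slack"] = min_slack,
                      _["blocked"] = blocked_events);
}

// [[Rcpp::export(name = ".cf_inject")]]
List cf_inject(IntegerVector rbc_vessel, NumericVector rbc_s, IntegerVector rbc_id,
               IntegerVector ifrom, IntegerVector ito,
               NumericVector L, NumericVector lrbc, NumericVector q,
               IntegerVector inflow_ves, NumericVector rate_per_s,
               NumericVector acc, double dt, int next_id) {
  const int nR = rbc_vessel.size();
  std::vector<int> v(rbc_vessel.begin(), rbc_vessel.end());
  std::vector<double> s(rbc_s.begin(), rbc_s.end());
  std::vector<int> id(rbc_id.begin(), rbc_id.end());
  NumericVector acc2 = clone(acc);
  int injected = 0;
  const int nI = inflow_ves.size();
  // one pass over the population: rearmost occupant per inflow vessel
  std::vector<int> slot(L.size(), -1);
  for (int k = 0; k < nI; ++k) slot[inflow_ves[k] - 1] = k;
  std::vector<double> rear(nI, std::numeric_limits<double>::infinity());
  for (size_t r = 0; r < v.size(); ++r) {
    int e = v[r] - 1;
    int k = slot[e];
    if (k < 0) continue;
    double pf = q[e] >= 0 ? s[r] : L[e] - s[r];
    if (pf < rear[k]) rear[k] = pf;
  }
  for (int k = 0; k < nI; ++k) {
    int e = inflow_ves[k] - 1;
    acc2[k] += rate_per_s[k] * dt;
    bool from_up = q[e] >= 0; // entrance is the upstream end
    while (acc2[k] >= 1.0) {
      if (std::isfinite(rear[k]) && rear[k] < lrbc[e] - GAP_EPS) break; // deferred
      v.push_back(e + 1);
      s.push_back(from_up ? 0.0 : L[e]);
      id.push_back(next_id++);
      rear[k] = 0.0;
      acc2[k] -= 1.0;
      injected++;
    }
  }
  return List::create(_["vessel"] = IntegerVector(v.begin(), v.end()),
                      _["s"] = NumericVector(s.begin(), s.end()),
                      _["id"] = IntegerVector(id.begin(), id.end()),
                      _["acc"] = acc2, _["next_id"] = next_id,
                      _["injected"] = injected);
}
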