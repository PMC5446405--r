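// Event-driven (discrete) molecular dynamics on step-wise pair potentials.
//
// Units: mass Da, length Angstrom, energy kcal/mol; the derived time unit
// is ~48.9 fs. Dynamics are exact between events: beads move ballistically,
// and velocities change only when a pair crosses a potential breakpoint,
// hits a bond wall, or an Anderson-thermostat ghost collision occurs.
//
// Scheduling uses lazy invalidation (per-bead collision counters), a
// time-horizon refresh per bead instead of neighbour cell lists (system
// sizes here are < ~1000 beads), and per-pair minimum-image re-examination
// events so periodic boundaries stay exact.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

enum EvKind { EV_PAIR = 0, EV_BOND = 1, EV_RECHECK = 2, EV_REFRESH = 3,
              EV_THERMO = 4 };

struct Event {
  double t;
  int i, j;        // j = -1 for single-bead events
  int kind;
  uint32_t ci, cj; // validity counters at scheduling time
  int bpidx;       // breakpoint index (PAIR) or bond index (BOND)
  int dir;         // 0 = inward crossing, 1 = outward crossing
};

struct EventCmp {
  // ties resolve physical events (pair, bond) before bookkeeping ones,
  // then by bead indices for reproducibility
  bool operator()(const Event& a, const Event& b) const {
    if (a.t != b.t) return a.t > b.t;
    if (a.kind != b.kind) return a.kind > b.kind;
    if (a.i != b.i) return a.i > b.i;
    return a.j > b.j;
  }
};

struct Pot {
  std::vector<double> bp;
  std::vector<double> lv; // lv.size() == bp.size() - 1; 0 beyond last bp
};

struct Engine {
  int N;
  std::vector<double> px, py, pz, vx, vy, vz, tloc, mass, winv, sigma;
  std::vector<uint32_t> cnt;
  std::vector<int> mol, ptype; // ptype 0-based
  std::vector<char> mobile, exposed;
  std::vector<int> mobile_idx;
  double box, halfbox;
  int T;                      // number of bead types
  std::vector<Pot> pots;      // full potentials, T*T
  std::vector<double> coremat; // hard-core distance per type pair
  // bonds
  std::vector<int> b_i, b_j;
  std::vector<double> b_lo, b_hi;
  std::vector<std::vector<int>> bonds_of;
  double horizon, kT_, th_rate, t_end;
  bool thermostat;
  std::priority_queue<Event, std::vector<Event>, EventCmp> q;
  double n_core = 0, n_well = 0, n_bond = 0, n_th = 0, n_stale = 0;

  const Pot& pot_for(int i, int j) const {
    return pots[ptype[i] * T + ptype[j]];
  }

  inline double wrap(double d) const {
    return d - box * std::nearbyint(d / box);
  }

  inline void advance(int i, double t) {
    double dt = t - tloc[i];
    if (dt != 0.0) {
      px[i] += vx[i] * dt; py[i] += vy[i] * dt; pz[i] += vz[i] * dt;
      tloc[i] = t;
    }
  }

  // relative state of pair (i, j) at time t, minimum image
  inline void rel(int i, int j, double t, double* dx, double* dv) const {
    double xi = px[i] + vx[i] * (t - tloc[i]);
    double yi = py[i] + vy[i] * (t - tloc[i]);
    double zi = pz[i] + vz[i] * (t - tloc[i]);
    double xj = px[j] + vx[j] * (t - tloc[j]);
    double yj = py[j] + vy[j] * (t - tloc[j]);
    double zj = pz[j] + vz[j] * (t - tloc[j]);
    dx[0] = wrap(xi - xj); dx[1] = wrap(yi - yj); dx[2] = wrap(zi - zj);
    dv[0] = vx[i] - vx[j]; dv[1] = vy[i] - vy[j]; dv[2] = vz[i] - vz[j];
  }

  void predict_pair(int i, int j, double tcur) {
    bool full = exposed[i] && exposed[j];
    const Pot& P = pot_for(i, j);
    int m = full ? (int)P.bp.size() : 1;
    double core = full ? P.bp[0] : coremat[ptype[i] * T + ptype[j]];

    double dx[3], dv[3];
    rel(i, j, tcur, dx, dv);
    double v2 = dv[0]*dv[0] + dv[1]*dv[1] + dv[2]*dv[2];
    if (v2 < 1e-20) return;
    double r2 = dx[0]*dx[0] + dx[1]*dx[1] + dx[2]*dx[2];
    double r = std::sqrt(r2);
    double b = dx[0]*dv[0] + dx[1]*dv[1] + dx[2]*dv[2];

    // time until the minimum image changes along any axis
    double t_img = R_PosInf;
    for (int a = 0; a < 3; ++a) {
      if (dv[a] > 1e-14) {
        double tt = (halfbox - dx[a]) / dv[a];
        if (tt < t_img) t_img = tt;
      } else if (dv[a] < -1e-14) {
        double tt = (-halfbox - dx[a]) / dv[a];
        if (tt < t_img) t_img = tt;
      }
    }

    // current region: number of breakpoints strictly below r, with a sign
    // rule exactly at a breakpoint (post-event states sit there)
    double tol = 1e-9 * (1.0 + r);
    int region = 0;
    {
      const double* bpp = full ? P.bp.data() : &core;
      int at = -1;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(r - bpp[k]) <= tol) { at = k; break; }
        if (r > bpp[k]) region = k + 1; else break;
      }
      if (at >= 0) region = (b > 0) ? at + 1 : at;
      if (region == 0) {
        if (at == 0) {
          // sitting exactly on the hard core moving inward: collide now
          Event e{tcur, i, j, EV_PAIR, cnt[i], cnt[j], 0, 0};
          q.push(e);
          return;
        }
        stop("hard-core overlap encountered (corrupt state)");
      }
    }

    const double* bp = full ? P.bp.data() : &core;
    double tbest = R_PosInf; int bidx = -1, dir = -1;
    if (region >= 1 && b < 0) { // inward crossing of bp[region-1]
      double d = bp[region - 1];
      double disc = b * b - v2 * (r2 - d * d);
      if (disc > 0) {
        double tt = (-b - std::sqrt(disc)) / v2;
        if (tt >= 0 && tt < tbest) { tbest = tt; bidx = region - 1; dir = 0; }
      }
    }
    if (region < m) { // outward crossing of bp[region]
      double d = bp[region];
      double disc = b * b - v2 * (r2 - d * d);
      if (disc > 0) {
        double tt = (-b + std::sqrt(disc)) / v2;
        if (tt >= 0 && tt < tbest) { tbest = tt; bidx = region; dir = 1; }
      }
    }

    // slack keeps crossings that land exactly on a refresh time scheduled
    double hrel = horizon * (1.0 + 1e-9) + 1e-9;
    if (bidx >= 0 && tbest <= t_img && tbest <= hrel) {
      Event e{tcur + tbest, i, j, EV_PAIR, cnt[i], cnt[j], bidx, dir};
      q.push(e);
    } else if (t_img <= hrel && t_img < R_PosInf) {
      // nudge past the image switch; the region tolerance absorbs the gap
      Event e{tcur + t_img + 1e-9, i, j, EV_RECHECK, cnt[i], cnt[j], 0, 0};
      q.push(e);
    }
  }

  void predict_bond(int bi, double tcur) {
    int i = b_i[bi], j = b_j[bi];
    if (!mobile[i] && !mobile[j]) return;
    double dx[3], dv[3];
    // bonds are intra-molecular; positions are unwrapped, plain difference
    double t = tcur;
    dx[0] = (px[i] + vx[i]*(t - tloc[i])) - (px[j] + vx[j]*(t - tloc[j]));
    dx[1] = (py[i] + vy[i]*(t - tloc[i])) - (py[j] + vy[j]*(t - tloc[j]));
    dx[2] = (pz[i] + vz[i]*(t - tloc[i])) - (pz[j] + vz[j]*(t - tloc[j]));
    dv[0] = vx[i]-vx[j]; dv[1] = vy[i]-vy[j]; dv[2] = vz[i]-vz[j];
    double v2 = dv[0]*dv[0] + dv[1]*dv[1] + dv[2]*dv[2];
    if (v2 < 1e-20) return;
    double r2 = dx[0]*dx[0] + dx[1]*dx[1] + dx[2]*dx[2];
    double b = dx[0]*dv[0] + dx[1]*dv[1] + dx[2]*dv[2];
    double lo = b_lo[bi], hi = b_hi[bi];
    double tbest = R_PosInf; int dir = -1;
    if (b < 0) { // maybe reach the inner wall
      double disc = b * b - v2 * (r2 - lo * lo);
      if (disc > 0) {
        double tt = (-b - std::sqrt(disc)) / v2;
        if (tt >= 0 && tt < tbest) { tbest = tt; dir = 0; }
      }
    }
    { // outer wall is always reachable
      double disc = b * b - v2 * (r2 - hi * hi);
      if (disc > 0) {
        double tt = (-b + std::sqrt(disc)) / v2;
        if (tt >= 0 && tt < tbest) { tbest = tt; dir = 1; }
      }
    }
    if (dir >= 0 && tbest <= horizon * (1.0 + 1e-9) + 1e-9) {
      Event e{tcur + tbest, i, j, EV_BOND, cnt[i], cnt[j], bi, dir};
      q.push(e);
    }
  }

  void predict_bead(int i, double tcur) {
    for (int j = 0; j < N; ++j) {
      if (j == i || mol[j] == mol[i]) continue;
      if (!mobile[i] && !mobile[j]) continue;
      predict_pair(i, j, tcur);
    }
    for (int bi : bonds_of[i]) predict_bond(bi, tcur);
    Event e{tcur + horizon, i, -1, EV_REFRESH, cnt[i], 0, 0, 0};
    q.push(e);
  }

  // level of a region (1..m) of a full potential; region m (outside) is 0
  static inline double level(const Pot& P, int region) {
    int m = (int)P.bp.size();
    if (region >= m) return 0.0;
    if (region >= 1) return P.lv[region - 1];
    return R_PosInf;
  }

  void resolve_pair(const Event& e) {
    int i = e.i, j = e.j;
    advance(i, e.t); advance(j, e.t);
    double dx[3], dv[3];
    rel(i, j, e.t, dx, dv);
    double r = std::sqrt(dx[0]*dx[0] + dx[1]*dx[1] + dx[2]*dx[2]);
    double nh[3] = { dx[0]/r, dx[1]/r, dx[2]/r };
    double vr = dv[0]*nh[0] + dv[1]*nh[1] + dv[2]*nh[2];
    double muinv = winv[i] + winv[j];

    bool full = exposed[i] && exposed[j];
    const Pot& P = pot_for(i, j);
    int qk = e.bpidx;
    double dU;
    bool hardcore = false;
    if (!full) {
      hardcore = true; dU = 0.0;
    } else if (e.dir == 1) { // outward at bp[qk]: region qk -> qk+1
      dU = level(P, qk + 1) - level(P, qk);
    } else {                  // inward at bp[qk]: region qk+1 -> qk
      if (qk == 0) { hardcore = true; dU = 0.0; }
      else dU = level(P, qk) - level(P, qk + 1);
    }

    double vrp;
    if (hardcore) {
      vrp = -vr;
      n_core += 1;
    } else {
      double ke_r = 0.5 * vr * vr / muinv;
      if (dU <= 0.0 || ke_r > dU) {
        double s = vr * vr - 2.0 * dU * muinv;
        vrp = (vr >= 0 ? 1.0 : -1.0) * std::sqrt(s > 0 ? s : 0);
      } else {
        vrp = -vr; // reflect off the barrier
      }
      n_well += 1;
    }
    double dvr = vrp - vr;
    double fi = winv[i] / muinv, fj = winv[j] / muinv;
    vx[i] += fi * dvr * nh[0]; vy[i] += fi * dvr * nh[1];
    vz[i] += fi * dvr * nh[2];
    vx[j] -= fj * dvr * nh[0]; vy[j] -= fj * dvr * nh[1];
    vz[j] -= fj * dvr * nh[2];
    if (mobile[i]) { cnt[i]++; predict_bead(i, e.t); }
    if (mobile[j]) { cnt[j]++; predict_bead(j, e.t); }
  }

  void resolve_bond(const Event& e) {
    int i = e.i, j = e.j;
    advance(i, e.t); advance(j, e.t);
    double dx[3] = { px[i]-px[j], py[i]-py[j], pz[i]-pz[j] };
    double r = std::sqrt(dx[0]*dx[0] + dx[1]*dx[1] + dx[2]*dx[2]);
    double nh[3] = { dx[0]/r, dx[1]/r, dx[2]/r };
    double dv[3] = { vx[i]-vx[j], vy[i]-vy[j], vz[i]-vz[j] };
    double vr = dv[0]*nh[0] + dv[1]*nh[1] + dv[2]*nh[2];
    double muinv = winv[i] + winv[j];
    double dvr = -2.0 * vr; // hard walls reflect
    double fi = winv[i] / muinv, fj = winv[j] / muinv;
    vx[i] += fi * dvr * nh[0]; vy[i] += fi * dvr * nh[1];
    vz[i] += fi * dvr * nh[2];
    vx[j] -= fj * dvr * nh[0]; vy[j] -= fj * dvr * nh[1];
    vz[j] -= fj * dvr * nh[2];
    n_bond += 1;
    if (mobile[i]) { cnt[i]++; predict_bead(i, e.t); }
    if (mobile[j]) { cnt[j]++; predict_bead(j, e.t); }
  }

  void sync_all(double t) {
    for (int i = 0; i < N; ++i) advance(i, t);
  }

  double kinetic() const {
    double k = 0;
    for (int i = 0; i < N; ++i) {
      k += 0.5 * mass[i] * (vx[i]*vx[i] + vy[i]*vy[i] + vz[i]*vz[i]);
    }
    return k;
  }

  double potential() const {
    double u = 0;
    for (int i = 0; i < N; ++i) {
      for (int j = i + 1; j < N; ++j) {
        if (mol[i] == mol[j]) continue;
        double dx = wrap(px[i]-px[j]), dy = wrap(py[i]-py[j]),
               dz = wrap(pz[i]-pz[j]);
        double r = std::sqrt(dx*dx + dy*dy + dz*dz);
        if (!(exposed[i] && exposed[j])) continue; // core only: level 0
        const Pot& P = pot_for(i, j);
        int m = (int)P.bp.size();
        if (r >= P.bp[m - 1]) continue;
        int region = 0;
        while (region < m && r > P.bp[region]) ++region;
        if (region >= 1 && region < m) u += P.lv[region - 1];
        // region 0 would be a core overlap; snapshots are generic times
      }
    }
    return u;
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_run_dmd(NumericMatrix x0, NumericMatrix v0, NumericVector mass,
                 LogicalVector mobile, IntegerVector mol, IntegerVector ptype,
                 LogicalVector exposed, double box, int n_types,
                 List pot_bp, List pot_lv, NumericMatrix coremat,
                 NumericMatrix bonds, double t_end, double snap_dt,
                 double kT, bool thermostat, double th_rate,
                 double horizon, double max_events) {
  Engine E;
  int N = x0.nrow();
  E.N = N; E.box = box; E.halfbox = box / 2.0;
  E.T = n_types; E.kT_ = kT; E.th_rate = th_rate; E.t_end = t_end;
  E.thermostat = thermostat; E.horizon = horizon;
  E.px.resize(N); E.py.resize(N); E.pz.resize(N);
  E.vx.resize(N); E.vy.resize(N); E.vz.resize(N);
  E.tloc.assign(N, 0.0); E.cnt.assign(N, 0u);
  E.mass.resize(N); E.winv.resize(N); E.sigma.resize(N);
  E.mol.resize(N); E.ptype.resize(N);
  E.mobile.resize(N); E.exposed.resize(N);
  for (int i = 0; i < N; ++i) {
    E.px[i] = x0(i,0); E.py[i] = x0(i,1); E.pz[i] = x0(i,2);
    E.vx[i] = v0(i,0); E.vy[i] = v0(i,1); E.vz[i] = v0(i,2);
    E.mass[i] = mass[i];
    E.mobile[i] = mobile[i];
    E.winv[i] = E.mobile[i] ? 1.0 / mass[i] : 0.0;
    E.sigma[i] = std::sqrt(kT / mass[i]);
    E.mol[i] = mol[i]; E.ptype[i] = ptype[i] - 1;
    E.exposed[i] = exposed[i];
    if (E.mobile[i]) E.mobile_idx.push_back(i);
  }
  int TT = n_types * n_types;
  E.pots.resize(TT);
  E.coremat.resize(TT);
  for (int a = 0; a < n_types; ++a) {
    for (int b = 0; b < n_types; ++b) {
      NumericVector bp = pot_bp[a * n_types + b];
      NumericVector lv = pot_lv[a * n_types + b];
      Pot P;
      P.bp.assign(bp.begin(), bp.end());
      P.lv.assign(lv.begin(), lv.end());
      E.pots[a * n_types + b] = P;
      E.coremat[a * n_types + b] = coremat(a, b);
    }
  }
  int M = bonds.nrow();
  E.bonds_of.resize(N);
  for (int k = 0; k < M; ++k) {
    int i = (int)bonds(k,0) - 1, j = (int)bonds(k,1) - 1;
    E.b_i.push_back(i); E.b_j.push_back(j);
    E.b_lo.push_back(bonds(k,2)); E.b_hi.push_back(bonds(k,3));
    E.bonds_of[i].push_back(k); E.bonds_of[j].push_back(k);
  }

  // initial validation: bonds in window, no inter-molecular core overlap
  for (int k = 0; k < M; ++k) {
    int i = E.b_i[k], j = E.b_j[k];
    double dx = E.px[i]-E.px[j], dy = E.py[i]-E.py[j], dz = E.pz[i]-E.pz[j];
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    if (r < E.b_lo[k] - 1e-9 || r > E.b_hi[k] + 1e-9) {
      stop("bond %d-%d outside its window at start (r = %.3f)",
           i + 1, j + 1, r);
    }
  }
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      if (E.mol[i] == E.mol[j]) continue;
      double dx = E.wrap(E.px[i]-E.px[j]), dy = E.wrap(E.py[i]-E.py[j]),
             dz = E.wrap(E.pz[i]-E.pz[j]);
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      double core = E.coremat[E.ptype[i] * n_types + E.ptype[j]];
      if (r < core - 1e-9) {
        stop("initial hard-core overlap between beads %d and %d", i+1, j+1);
      }
    }
  }

  for (int i : E.mobile_idx) E.predict_bead(i, 0.0);
  int n_mob = (int)E.mobile_idx.size();
  double next_th = R_PosInf;
  if (thermostat && n_mob > 0 && th_rate > 0) {
    next_th = R::exp_rand() / (th_rate * n_mob);
  }

  std::vector<double> snap_t, snap_ek, snap_ep;
  std::vector<NumericMatrix> frames;
  double next_snap = snap_dt > 0 ? snap_dt : R_PosInf;
  bool record0 = true;
  auto record = [&](double t) {
    NumericMatrix f(N, 3);
    for (int i = 0; i < N; ++i) {
      f(i,0) = E.px[i]; f(i,1) = E.py[i]; f(i,2) = E.pz[i];
    }
    frames.push_back(f);
    snap_t.push_back(t);
    snap_ek.push_back(E.kinetic());
    snap_ep.push_back(E.potential());
  };
  if (record0) record(0.0);

  double n_events = 0;
  bool starved = false;
  while (true) {
    double t_next;
    bool have_ev = false;
    Event ev{};
    while (!E.q.empty()) {
      ev = E.q.top();
      if (ev.kind == EV_PAIR || ev.kind == EV_BOND || ev.kind == EV_RECHECK) {
        if (ev.ci != E.cnt[ev.i] ||
            (ev.j >= 0 && ev.cj != E.cnt[ev.j])) {
          E.q.pop(); E.n_stale += 1; continue;
        }
      } else if (ev.kind == EV_REFRESH) {
        if (ev.ci != E.cnt[ev.i]) { E.q.pop(); E.n_stale += 1; continue; }
      }
      have_ev = true;
      break;
    }
    t_next = have_ev ? ev.t : R_PosInf;
    if (next_th < t_next) { t_next = next_th; ev.kind = EV_THERMO; have_ev = true; }
    if (!have_ev) { starved = true; break; }
    if (t_next > t_end) break;

    while (next_snap <= t_next && next_snap <= t_end) {
      E.sync_all(next_snap);
      record(next_snap);
      next_snap += snap_dt;
    }

    if (ev.kind == EV_THERMO) {
      int pick = E.mobile_idx[(int)(R::unif_rand() * n_mob) % n_mob];
      E.advance(pick, next_th);
      E.vx[pick] = R::norm_rand() * E.sigma[pick];
      E.vy[pick] = R::norm_rand() * E.sigma[pick];
      E.vz[pick] = R::norm_rand() * E.sigma[pick];
      E.cnt[pick]++;
      E.predict_bead(pick, next_th);
      E.n_th += 1;
      double tcur = next_th;
      next_th = tcur + R::exp_rand() / (th_rate * n_mob);
      n_events += 1;
    } else {
      E.q.pop();
      if (ev.kind == EV_PAIR) { E.resolve_pair(ev); n_events += 1; }
      else if (ev.kind == EV_BOND) { E.resolve_bond(ev); n_events += 1; }
      else if (ev.kind == EV_RECHECK) { E.predict_pair(ev.i, ev.j, ev.t); }
      else if (ev.kind == EV_REFRESH) { E.predict_bead(ev.i, ev.t); }
    }
    if (n_events >= max_events) {
      warning("maximum event count reached before t_end");
      break;
    }
    if (((long)n_events & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  double t_stop = std::min(t_end, starved ? t_end : t_end);
  while (next_snap <= t_stop) {
    E.sync_all(next_snap);
    record(next_snap);
    next_snap += snap_dt;
  }
  E.sync_all(t_stop);

  NumericMatrix xf(N, 3), vf(N, 3);
  for (int i = 0; i < N; ++i) {
    xf(i,0) = E.px[i]; xf(i,1) = E.py[i]; xf(i,2) = E.pz[i];
    vf(i,0) = E.vx[i]; vf(i,1) = E.vy[i]; vf(i,2) = E.vz[i];
  }
  List fr(frames.size());
  for (size_t k = 0; k < frames.size(); ++k) fr[k] = frames[k];

  return List::create(
    _["times"] = wrap(snap_t),
    _["frames"] = fr,
    _["e_kin"] = wrap(snap_ek),
    _["e_pot"] = wrap(snap_ep),
    _["x_final"] = xf,
    _["v_final"] = vf,
    _["t_final"] = t_stop,
    _["n_events"] = n_events,
    _["counts"] = List::create(
      _["core"] = E.n_core, _["well"] = E.n_well, _["bond"] = E.n_bond,
      _["thermostat"] = E.n_th, _["stale"] = E.n_stale),
    _["starved"] = starved);
}

// Earliest breakpoint-crossing time for an isolated pair (oracle helper):
// returns Inf when the relative motion never reaches a breakpoint before
// the minimum image changes.
// [[Rcpp::export]]
double cpp_pair_event_time(NumericVector xi, NumericVector vi,
                           NumericVector xj, NumericVector vj,
                           double box, NumericVector bp) {
  double dx[3], dv[3];
  for (int a = 0; a < 3; ++a) {
    dx[a] = xi[a] - xj[a];
    dx[a] -= box * std::nearbyint(dx[a] / box);
    dv[a] = vi[a] - vj[a];
  }
  double v2 = dv[0]*dv[0] + dv[1]*dv[1] + dv[2]*dv[2];
  if (v2 < 1e-20) return R_PosInf;
  double r2 = dx[0]*dx[0] + dx[1]*dx[1] + dx[2]*dx[2];
  double r = std::sqrt(r2);
  double b = dx[0]*dv[0] + dx[1]*dv[1] + dx[2]*dv[2];
  int m = bp.size();
  double t_img = R_PosInf;
  for (int a = 0; a < 3; ++a) {
    if (dv[a] > 1e-14) t_img = std::min(t_img, (box/2 - dx[a]) / dv[a]);
    else if (dv[a] < -1e-14) t_img = std::min(t_img, (-box/2 - dx[a]) / dv[a]);
  }
  int region = 0;
  for (int k = 0; k < m; ++k) if (r > bp[k]) region = k + 1; else break;
  double tbest = R_PosInf;
  if (region >= 1 && b < 0) {
    double d = bp[region - 1];
    double disc = b*b - v2*(r2 - d*d);
    if (disc > 0) {
      double tt = (-b - std::sqrt(disc)) / v2;
      if (tt >= 0) tbest = std::min(tbest, tt);
    }
  }
  if (region < m) {
    double d = bp[region];
    double disc = b*b - v2*(r2 - d*d);
    if (disc > 0) {
      double tt = (-b + std::sqrt(disc)) / v2;
      if (tt >= 0) tbest = std::min(tbest, tt);
    }
  }
  if (tbest > t_img) return R_PosInf;
  return tbest;
}
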