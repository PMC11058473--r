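// Continuous-time stochastic simulation of ribosome scanning, initiation,
// elongation and queuing on a single mRNA track.
//
// Species: 0 = scanning PIC without ternary complex (TC), 1 = TC-bound PIC,
// 2 = elongating 80S. Exponential waiting times; one event fires per
// iteration (Gillespie). All coordinates are 1-based P-site positions.
//
// Footprints: PIC covers [p - pic_up, p + pic_down - 1] (upstream excludes
// the P site, downstream includes it); 80S covers [p - fp80_up, p + fp80_down].
// A ribosome whose next move would push its leading edge into a folded
// stem-loop moves at the stall-release rate instead of its free rate; a
// stem-loop is folded whenever no ribosome footprint overlaps its span.
// A blocked or stalled TC-bound PIC may initiate at any start codon within
// +-mig of its P site, with its initiation rate multiplied by queue_boost.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Rib {
  int species;   // 0 PIC_noTC, 1 PIC_TC, 2 80S
  int psite;
  int origin;    // site index for 80S, -1 otherwise
};

struct Ev {
  double rate;
  int type;      // 0 load, 1 step, 2 tcbind, 3 init_here, 4 init_window,
                 // 5 terminate
  int rib;
  int aux;       // site index for initiations
};

}  // namespace

// [[Rcpp::export(name = ".simulate_track")]]
List simulate_track(List sim) {
  const int L = as<int>(sim["L"]);
  const IntegerVector site_pos = sim["site_pos"];
  const NumericVector site_lambda = sim["site_lambda"];
  const IntegerVector site_stop = sim["site_stop"];   // 0 => runoff ORF
  const NumericVector site_prei = sim["site_prei"];
  const IntegerVector sl_base = sim["sl_base"];
  const IntegerVector sl_end = sim["sl_end"];
  const NumericVector sl_k = sim["sl_k"];
  const NumericVector slow = sim["slow"];             // length L, divisor
  const double k_load = as<double>(sim["k_load"]);
  const double v_scan = as<double>(sim["v_scan"]);
  const double v_elong = as<double>(sim["v_elong"]);
  const double k_tc = as<double>(sim["k_tc_eff"]);
  const double p_tc_load = as<double>(sim["p_tc_load"]);
  const int pic_up = as<int>(sim["pic_up"]);
  const int pic_down = as<int>(sim["pic_down"]);
  const int fp80_up = as<int>(sim["fp80_up"]);
  const int fp80_down = as<int>(sim["fp80_down"]);
  const int mig = as<int>(sim["mig"]);
  const double qboost = as<double>(sim["queue_boost"]);
  const double mig_decay = as<double>(sim["mig_decay"]);
  const double t_max = as<double>(sim["t_max"]);
  const double burn_in = as<double>(sim["burn_in"]);
  const double dt_snap = as<double>(sim["dt_snap"]);
  const bool no_excl = as<bool>(sim["no_exclusion"]);
  const bool keep_log = as<bool>(sim["keep_log"]);

  const int nsite = site_pos.size();
  const int nsl = sl_base.size();
  std::vector<int> site_at(L + 2, -1);
  for (int s = 0; s < nsite; ++s)
    if (site_pos[s] >= 1 && site_pos[s] <= L) site_at[site_pos[s]] = s;

  std::vector<Rib> ribs;
  std::vector<double> occ((size_t)3 * (L + 1), 0.0);
  std::vector<int> init_counts(nsite, 0), protein(nsite, 0);
  long loads = 0, scanned_off = 0, recycled = 0, runoff = 0, n_events = 0;
  std::vector<double> log_t; std::vector<int> log_type, log_pos;
  const int LOG_CAP = 20000;

  std::vector<int> snap_id, snap_sp, snap_ps, snap_or;
  double next_snap = burn_in;
  int snap_counter = 0;

  const int load_psite = pic_up + 1;

  auto fp_lo = [&](const Rib& r) {
    return r.psite - (r.species == 2 ? fp80_up : pic_up);
  };
  auto fp_hi = [&](const Rib& r) {
    return r.species == 2 ? r.psite + fp80_down : r.psite + pic_down - 1;
  };

  RNGScope rng;
  double t = 0.0;

  while (t < t_max) {
    const int R = ribs.size();
    // stem-loop folded status
    std::vector<bool> folded(nsl, true);
    for (int q = 0; q < nsl; ++q)
      for (int r = 0; r < R; ++r)
        if (fp_hi(ribs[r]) >= sl_base[q] && fp_lo(ribs[r]) <= sl_end[q]) {
          folded[q] = false; break;
        }

    std::vector<Ev> evs;
    evs.reserve(4 * R + 4);
    double total = 0.0;

    // cap loading
    bool cap_free = true;
    if (!no_excl) {
      Rib probe{1, load_psite, -1};
      for (int r = 0; r < R; ++r)
        if (fp_lo(ribs[r]) <= fp_hi(probe) && fp_hi(ribs[r]) >= fp_lo(probe)) {
          cap_free = false; break;
        }
    }
    if (cap_free && k_load > 0) {
      evs.push_back({k_load, 0, -1, -1});
      total += k_load;
    }

    for (int r = 0; r < R; ++r) {
      Rib& rb = ribs[r];
      const bool is80 = rb.species == 2;
      const int step = is80 ? 3 : 1;
      const int hi = fp_hi(rb);

      bool at_stop = false;
      if (is80 && rb.origin >= 0 && site_stop[rb.origin] > 0 &&
          rb.psite >= site_stop[rb.origin])
        at_stop = true;

      // movement
      bool excl_blocked = false;
      if (!no_excl) {
        for (int r2 = 0; r2 < R; ++r2) {
          if (r2 == r) continue;
          if (fp_lo(ribs[r2]) > hi && fp_lo(ribs[r2]) <= hi + step) {
            excl_blocked = true; break;
          }
        }
      }
      bool sl_stalled = false;
      double unwind_rate = 0.0;
      for (int q = 0; q < nsl; ++q) {
        // in no-exclusion mode ribosomes are independent, so another
        // ribosome inside the stem must not count as having unfolded it
        bool is_folded = no_excl ? true : folded[q];
        if (is_folded && hi < sl_base[q] && hi + step >= sl_base[q]) {
          sl_stalled = true; unwind_rate = sl_k[q]; break;
        }
      }

      if (!at_stop) {
        double mv;
        if (is80) mv = v_elong;
        else {
          int np = rb.psite + 1;
          mv = v_scan / (np >= 1 && np <= L ? slow[np - 1] : 1.0);
        }
        // unwinding and stepping are serial: the expected crossing time
        // is the sum, so an infinitely fast release recovers free movement
        if (sl_stalled && mv > 0) mv = 1.0 / (1.0 / mv + 1.0 / unwind_rate);
        if (excl_blocked) mv = 0.0;
        if (mv > 0) { evs.push_back({mv, 1, r, -1}); total += mv; }
      } else {
        evs.push_back({v_elong, 5, r, -1});  // terminate
        total += v_elong;
      }

      if (rb.species == 0 && k_tc > 0) {
        evs.push_back({k_tc, 2, r, -1});
        total += k_tc;
      }

      if (rb.species == 1) {
        const bool blocked = excl_blocked || sl_stalled;
        const double boost = blocked ? qboost : 1.0;
        int s_here = (rb.psite >= 1 && rb.psite <= L) ? site_at[rb.psite] : -1;
        if (s_here >= 0 && site_lambda[s_here] > 0) {
          double rr = site_lambda[s_here] * boost;
          evs.push_back({rr, 3, r, s_here});
          total += rr;
        }
        if (blocked && qboost > 0) {
          int lo = std::max(1, rb.psite - mig);
          int hi2 = std::min(L, rb.psite + mig);
          for (int p = lo; p <= hi2; ++p) {
            int s = site_at[p];
            if (s < 0 || p == rb.psite || site_lambda[s] <= 0) continue;
            // jump feasibility: resulting 80S footprint must be free
            bool ok = true;
            if (!no_excl) {
              Rib probe{2, p, s};
              for (int r2 = 0; r2 < R && ok; ++r2) {
                if (r2 == r) continue;
                if (fp_lo(ribs[r2]) <= fp_hi(probe) &&
                    fp_hi(ribs[r2]) >= fp_lo(probe)) ok = false;
              }
            }
            if (!ok) continue;
            // migration is diffusive: occupancy of displaced registers
            // decays with distance from the anchored P site
            double rr = site_lambda[s] * qboost *
              std::pow(mig_decay, std::abs(p - rb.psite));
            if (rr <= 0) continue;
            evs.push_back({rr, 4, r, s});
            total += rr;
          }
        }
      }
    }

    if (total <= 0) {  // absorbing; jump to end
      double dt = t_max - t;
      for (int r = 0; r < R; ++r) {
        int a = std::max(1, fp_lo(ribs[r])), b = std::min(L, fp_hi(ribs[r]));
        for (int p = a; p <= b; ++p)
          occ[(size_t)ribs[r].species * (L + 1) + p] += dt;
      }
      while (next_snap <= t_max + 1e-12) {
        ++snap_counter;
        for (int r = 0; r < R; ++r) {
          snap_id.push_back(snap_counter);
          snap_sp.push_back(ribs[r].species);
          snap_ps.push_back(ribs[r].psite);
          snap_or.push_back(ribs[r].origin >= 0 ? site_pos[ribs[r].origin] : NA_INTEGER);
        }
        next_snap += dt_snap;
      }
      t = t_max;
      break;
    }

    double tau = R::exp_rand() / total;
    double t_new = std::min(t + tau, t_max);
    double dt = t_new - t;
    for (int r = 0; r < R; ++r) {
      int a = std::max(1, fp_lo(ribs[r])), b = std::min(L, fp_hi(ribs[r]));
      for (int p = a; p <= b; ++p)
        occ[(size_t)ribs[r].species * (L + 1) + p] += dt;
    }
    while (next_snap <= t_new + 1e-12 && next_snap <= t_max + 1e-12) {
      ++snap_counter;
      for (int r = 0; r < R; ++r) {
        snap_id.push_back(snap_counter);
        snap_sp.push_back(ribs[r].species);
        snap_ps.push_back(ribs[r].psite);
        snap_or.push_back(ribs[r].origin >= 0 ? site_pos[ribs[r].origin] : NA_INTEGER);
      }
      next_snap += dt_snap;
    }
    if (t + tau > t_max) { t = t_max; break; }
    t += tau;
    ++n_events;

    // pick event
    double u = unif_rand() * total;
    int chosen = -1;
    for (size_t e = 0; e < evs.size(); ++e) {
      u -= evs[e].rate;
      if (u <= 0) { chosen = e; break; }
    }
    if (chosen < 0) chosen = evs.size() - 1;
    Ev ev = evs[chosen];

    if (keep_log && (int)log_t.size() < LOG_CAP) {
      log_t.push_back(t);
      log_type.push_back(ev.type);
      log_pos.push_back(ev.rib >= 0 ? ribs[ev.rib].psite : 0);
    }

    switch (ev.type) {
    case 0: {  // load
      bool with_tc = unif_rand() < p_tc_load;
      ribs.push_back({with_tc ? 1 : 0, load_psite, -1});
      ++loads;
      break;
    }
    case 1: {  // move
      Rib& rb = ribs[ev.rib];
      rb.psite += (rb.species == 2 ? 3 : 1);
      if (rb.species == 2) {
        if (rb.psite + fp80_down > L) {  // runoff completion
          if (rb.origin >= 0) protein[rb.origin]++;
          ++runoff;
          ribs.erase(ribs.begin() + ev.rib);
        }
      } else {
        if (rb.psite > L - 2) {  // scanned off the 3' end
          ++scanned_off;
          ribs.erase(ribs.begin() + ev.rib);
        }
      }
      break;
    }
    case 2:
      ribs[ev.rib].species = 1;
      break;
    case 3: case 4: {  // initiation (in place or within migration window)
      Rib& rb = ribs[ev.rib];
      rb.species = 2;
      rb.psite = site_pos[ev.aux];
      rb.origin = ev.aux;
      init_counts[ev.aux]++;
      break;
    }
    case 5: {  // termination at a stop codon
      Rib& rb = ribs[ev.rib];
      if (rb.origin >= 0) protein[rb.origin]++;
      double prei = rb.origin >= 0 ? site_prei[rb.origin] : 0.0;
      if (unif_rand() < prei) {
        rb.species = 0;  // resumes scanning without TC
        rb.origin = -1;
      } else {
        ++recycled;
        ribs.erase(ribs.begin() + ev.rib);
      }
      break;
    }
    }
    std::sort(ribs.begin(), ribs.end(),
              [](const Rib& a, const Rib& b) { return a.psite < b.psite; });
  }

  NumericMatrix occm(3, L);
  for (int sp = 0; sp < 3; ++sp)
    for (int p = 1; p <= L; ++p)
      occm(sp, p - 1) = occ[(size_t)sp * (L + 1) + p] / t_max;

  IntegerVector alive_sp(ribs.size()), alive_ps(ribs.size());
  for (size_t r = 0; r < ribs.size(); ++r) {
    alive_sp[r] = ribs[r].species;
    alive_ps[r] = ribs[r].psite;
  }

  return List::create(
    _["loads"] = (double)loads,
    _["scanned_off"] = (double)scanned_off,
    _["recycled"] = (double)recycled,
    _["runoff"] = (double)runoff,
    _["alive_end"] = (int)ribs.size(),
    _["n_events"] = (double)n_events,
    _["init_counts"] = init_counts,
    _["protein"] = protein,
    _["occupancy"] = occm,
    _["snap"] = DataFrame::create(
      _["snapshot"] = wrap(snap_id), _["species"] = wrap(snap_sp),
      _["psite"] = wrap(snap_ps), _["origin"] = wrap(snap_or)),
    _["n_snapshots"] = snap_counter,
    _["alive_species"] = alive_sp,
    _["alive_psite"] = alive_ps,
    _["t_end"] = t,
    _["log"] = DataFrame::create(
      _["time"] = wrap(log_t), _["type"] = wrap(log_type),
      _["psite"] = wrap(log_pos)));
}
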