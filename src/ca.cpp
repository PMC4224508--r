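#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Three-state cellular automaton on a voxel lattice.
//
// States: 0 resting, 1 excited, 2 refractory.  A resting node accumulates an
// excitation counter e by `gain` per currently excited 6-connected (or
// 26-connected) neighbour per step; when e >= theta the node fires (counter
// reset).  An excited node excites neighbours for E steps, then is refractory
// for R steps, then rests (counter reset).  All nodes update synchronously
// from the previous step's states.

// [[Rcpp::export(name = ".ca_run_cpp")]]
List ca_run_cpp(IntegerVector state0, IntegerVector phase0, NumericVector e0,
                IntegerVector dims, IntegerVector active,
                NumericVector theta, NumericVector gain,
                IntegerVector E, IntegerVector R,
                int n_steps, int step0, int neighborhood, // 6 or 26
                IntegerVector probes, List stimuli) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int N = nx * ny * nz;
  const int sy = nx, sz = nx * ny;

  std::vector<int> st(state0.begin(), state0.end());
  std::vector<int> ph(phase0.begin(), phase0.end());
  std::vector<double> e(e0.begin(), e0.end());
  std::vector<int> st_new(N), ph_new(N);

  // neighbour offsets
  std::vector<int> offs;
  std::vector<int> di, dj, dk;
  for (int ck = -1; ck <= 1; ++ck)
    for (int cj = -1; cj <= 1; ++cj)
      for (int ci = -1; ci <= 1; ++ci) {
        if (ci == 0 && cj == 0 && ck == 0) continue;
        int manh = std::abs(ci) + std::abs(cj) + std::abs(ck);
        if (neighborhood == 6 && manh != 1) continue;
        di.push_back(ci); dj.push_back(cj); dk.push_back(ck);
      }
  const int n_off = di.size();

  // stimuli: list of (step, idx)
  struct Stim { int step; std::vector<int> idx; };
  std::vector<Stim> ev;
  for (int s = 0; s < stimuli.size(); ++s) {
    List x = stimuli[s];
    Stim sv;
    sv.step = as<int>(x["step"]);
    IntegerVector ix = x["idx"];
    sv.idx.assign(ix.begin(), ix.end());
    ev.push_back(sv);
  }

  const int n_probes = probes.size();
  std::vector<std::vector<int>> fires(n_probes);
  IntegerVector act(N, NA_INTEGER); // first firing step

  for (int step = 0; step < n_steps; ++step) {
    const int tstep = step0 + step;

    // external stimuli fire resting nodes at this step (refractory/excited
    // nodes are unaffected, matching the refractory branch of the automaton)
    for (size_t s = 0; s < ev.size(); ++s)
      if (ev[s].step == tstep)
        for (size_t q = 0; q < ev[s].idx.size(); ++q) {
          int id = ev[s].idx[q];
          if (active[id] && st[id] == 0) {
            st[id] = 1; ph[id] = 0; e[id] = 0.0;
            if (act[id] == NA_INTEGER) act[id] = tstep;
            for (int p = 0; p < n_probes; ++p)
              if (probes[p] == id &&
                  (fires[p].empty() || fires[p].back() != tstep))
                fires[p].push_back(tstep);
          }
        }

    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const int id = i + sy * j + sz * k;
          if (!active[id]) { st_new[id] = st[id]; ph_new[id] = ph[id]; continue; }
          if (st[id] == 0) {
            int n_exc = 0;
            for (int q = 0; q < n_off; ++q) {
              int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
              int nb = ii + sy * jj + sz * kk;
              if (active[nb] && st[nb] == 1) ++n_exc;
            }
            if (n_exc > 0) e[id] += gain[id] * n_exc;
            if (e[id] >= theta[id]) { st_new[id] = 1; ph_new[id] = 0; e[id] = 0.0; }
            else { st_new[id] = 0; ph_new[id] = 0; }
          } else if (st[id] == 1) {
            if (ph[id] + 1 >= E[id]) { st_new[id] = 2; ph_new[id] = 0; }
            else { st_new[id] = 1; ph_new[id] = ph[id] + 1; }
          } else { // refractory
            if (ph[id] + 1 >= R[id]) { st_new[id] = 0; ph_new[id] = 0; e[id] = 0.0; }
            else { st_new[id] = 2; ph_new[id] = ph[id] + 1; }
          }
        }

    for (int id = 0; id < N; ++id) {
      if (st[id] != 1 && st_new[id] == 1) {
        if (act[id] == NA_INTEGER) act[id] = tstep + 1;
      }
      st[id] = st_new[id]; ph[id] = ph_new[id];
    }
    for (int p = 0; p < n_probes; ++p) {
      // record the step at which the probe node fired
      int id = probes[p];
      if (st[id] == 1 && ph[id] == 0) {
        if (fires[p].empty() || fires[p].back() != tstep + 1) fires[p].push_back(tstep + 1);
      }
    }
  }

  List fl(n_probes);
  for (int p = 0; p < n_probes; ++p) fl[p] = IntegerVector(fires[p].begin(), fires[p].end());

  return List::create(
    _["state"] = IntegerVector(st.begin(), st.end()),
    _["phase"] = IntegerVector(ph.begin(), ph.end()),
    _["e"] = NumericVector(e.begin(), e.end()),
    _["step_end"] = step0 + n_steps,
    _["activation_step"] = act,
    _["fire_steps"] = fl);
}
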