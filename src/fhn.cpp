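#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Explicit forward-Euler integrator for the modified FitzHugh-Nagumo
// reaction-diffusion system on a voxel lattice.
//
// Per-voxel model codes:
//   0 = hole (excluded from the domain, no-flux wall)
//   1 = excitable FHN voxel (Rogers form, multiplicative recovery coupling):
//         du/dt = c1*u*(u-alpha)*(1-u) - c2*u*v + div(D grad u)
//         dv/dt = b*(d*u - v)
//   2 = passive voxel (block zone):
//         du/dt = -u/rb + div(D grad u),  v frozen
//   3 = pacemaking voxel (additive recovery coupling, threshold shifted
//       negative so rest is destabilized and a limit cycle appears):
//         du/dt = c1*u*(u-alpha)*(1-u) - c2*v + div(D grad u)
//         dv/dt = b*(d*u - v)
//
// Diffusion is a conservative flux form: for every lattice face between two
// tissue voxels the normal flux is
//   F = Dnn*(u_j - u_i) + sum over tangential axes Dnt * du/dt_tangential
// with the face tensor the arithmetic mean of the two voxel tensors and
// tangential gradients centred on the face.  Fluxes are applied
// antisymmetrically, so total u is conserved exactly (up to roundoff) and
// tissue boundaries are no-flux.  Tensor components are supplied already
// scaled by 1/dx^2 (units 1/ms).

struct StimEvent {
  double t_on, t_off, amp;
  int mode; // 0 = clamp u to amp, 1 = add amp to du/dt
  std::vector<int> idx;
};

// [[Rcpp::export(name = ".fhn_run_cpp")]]
List fhn_run_cpp(NumericVector u0, NumericVector v0,
                 IntegerVector dims, IntegerVector model,
                 NumericVector c1, NumericVector c2, NumericVector b,
                 NumericVector d, NumericVector alpha, NumericVector rb,
                 NumericVector j0,
                 NumericMatrix tensor, // N x 6: xx yy zz xy xz yz (1/ms)
                 double dt, int n_steps, double t0,
                 IntegerVector probes, int record_every,
                 List stimuli, double thresh,
                 int snapshot_every, bool diffusion_only) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int N = nx * ny * nz;
  const int sx = 1, sy = nx, sz = nx * ny;

  std::vector<double> u(u0.begin(), u0.end());
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> du(N), dv(N);

  // does any voxel carry off-diagonal tensor terms?
  bool mixed = false;
  for (int i = 0; i < N && !mixed; ++i)
    if (tensor(i, 3) != 0.0 || tensor(i, 4) != 0.0 || tensor(i, 5) != 0.0)
      mixed = true;
  std::vector<double> Dxx(N), Dyy(N), Dzz(N);
  for (int i = 0; i < N; ++i) {
    Dxx[i] = tensor(i, 0); Dyy[i] = tensor(i, 1); Dzz[i] = tensor(i, 2);
  }

  // parse stimuli
  std::vector<StimEvent> ev;
  for (int s = 0; s < stimuli.size(); ++s) {
    List e = stimuli[s];
    StimEvent se;
    se.t_on = as<double>(e["t_on"]);
    se.t_off = as<double>(e["t_off"]);
    se.amp = as<double>(e["amplitude"]);
    se.mode = as<int>(e["mode"]);
    IntegerVector ix = e["idx"];
    se.idx.assign(ix.begin(), ix.end());
    ev.push_back(se);
  }

  const int n_probes = probes.size();
  const int n_samples = (record_every > 0) ? (n_steps / record_every + 1) : 0;
  NumericMatrix trace_u(n_samples, n_probes), trace_v(n_samples, n_probes);
  NumericVector trace_t(n_samples);
  std::vector<std::vector<double>> events(n_probes);
  std::vector<double> probe_prev(n_probes);
  for (int p = 0; p < n_probes; ++p) probe_prev[p] = u[probes[p]];

  NumericVector act(N, NA_REAL); // first upward threshold crossing (ms)
  std::vector<double> uprev(u);

  int n_frames = (snapshot_every > 0) ? (n_steps / snapshot_every + 1) : 0;
  NumericMatrix frames(n_frames > 0 ? N : 1, n_frames > 0 ? n_frames : 1);
  NumericVector frame_t(n_frames > 0 ? n_frames : 1);
  int frame_i = 0;

  int status = 0;       // 0 ok, 1 instability
  double bad_t = NA_REAL;
  int sample_i = 0;

  auto record_sample = [&](double t) {
    if (record_every <= 0 || sample_i >= n_samples) return;
    trace_t[sample_i] = t;
    for (int p = 0; p < n_probes; ++p) {
      trace_u(sample_i, p) = u[probes[p]];
      trace_v(sample_i, p) = v[probes[p]];
    }
    ++sample_i;
  };
  record_sample(t0);
  if (n_frames > 0) {
    for (int i = 0; i < N; ++i) frames(i, 0) = u[i];
    frame_t[0] = t0;
    frame_i = 1;
  }

  for (int step = 0; step < n_steps; ++step) {
    const double t = t0 + step * dt;      // state time before update
    const double t_new = t0 + (step + 1) * dt;

    std::fill(du.begin(), du.end(), 0.0);

    // ---- diffusion fluxes -------------------------------------------------
    if (!mixed) {
      // diagonal tensors: plain face-conductance form, hot path
      const double *Dx = Dxx.data(), *Dy = Dyy.data(), *Dz = Dzz.data();
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j) {
          const int row = sy * j + sz * k;
          for (int i = 0; i < nx; ++i) {
            const int id = i + row;
            if (model[id] == 0) continue;
            if (i + 1 < nx && model[id + sx] != 0) {
              const double F = 0.5 * (Dx[id] + Dx[id + sx]) * (u[id + sx] - u[id]);
              du[id] += F; du[id + sx] -= F;
            }
            if (j + 1 < ny && model[id + sy] != 0) {
              const double F = 0.5 * (Dy[id] + Dy[id + sy]) * (u[id + sy] - u[id]);
              du[id] += F; du[id + sy] -= F;
            }
            if (k + 1 < nz && model[id + sz] != 0) {
              const double F = 0.5 * (Dz[id] + Dz[id + sz]) * (u[id + sz] - u[id]);
              du[id] += F; du[id + sz] -= F;
            }
          }
        }
    } else {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const int id = i + sy * j + sz * k;
          if (model[id] == 0) continue;
          // +x face
          if (i + 1 < nx && model[id + sx] != 0) {
            const int jd = id + sx;
            double F = 0.5 * (tensor(id, 0) + tensor(jd, 0)) * (u[jd] - u[id]);
            if (mixed) {
              double Dxy = 0.5 * (tensor(id, 3) + tensor(jd, 3));
              double Dxz = 0.5 * (tensor(id, 4) + tensor(jd, 4));
              if (Dxy != 0.0) {
                // du/dy on the x-face: average of centred differences at i, j
                double g = 0.0; int n = 0;
                if (j + 1 < ny && j > 0) {
                  if (model[id + sy] && model[id - sy]) { g += 0.5 * (u[id + sy] - u[id - sy]); ++n; }
                  if (model[jd + sy] && model[jd - sy]) { g += 0.5 * (u[jd + sy] - u[jd - sy]); ++n; }
                }
                if (n > 0) F += Dxy * g / n;
              }
              if (Dxz != 0.0) {
                double g = 0.0; int n = 0;
                if (k + 1 < nz && k > 0) {
                  if (model[id + sz] && model[id - sz]) { g += 0.5 * (u[id + sz] - u[id - sz]); ++n; }
                  if (model[jd + sz] && model[jd - sz]) { g += 0.5 * (u[jd + sz] - u[jd - sz]); ++n; }
                }
                if (n > 0) F += Dxz * g / n;
              }
            }
            du[id] += F; du[jd] -= F;
          }
          // +y face
          if (j + 1 < ny && model[id + sy] != 0) {
            const int jd = id + sy;
            double F = 0.5 * (tensor(id, 1) + tensor(jd, 1)) * (u[jd] - u[id]);
            if (mixed) {
              double Dxy = 0.5 * (tensor(id, 3) + tensor(jd, 3));
              double Dyz = 0.5 * (tensor(id, 5) + tensor(jd, 5));
              if (Dxy != 0.0) {
                double g = 0.0; int n = 0;
                if (i + 1 < nx && i > 0) {
                  if (model[id + sx] && model[id - sx]) { g += 0.5 * (u[id + sx] - u[id - sx]); ++n; }
                  if (model[jd + sx] && model[jd - sx]) { g += 0.5 * (u[jd + sx] - u[jd - sx]); ++n; }
                }
                if (n > 0) F += Dxy * g / n;
              }
              if (Dyz != 0.0) {
                double g = 0.0; int n = 0;
                if (k + 1 < nz && k > 0) {
                  if (model[id + sz] && model[id - sz]) { g += 0.5 * (u[id + sz] - u[id - sz]); ++n; }
                  if (model[jd + sz] && model[jd - sz]) { g += 0.5 * (u[jd + sz] - u[jd - sz]); ++n; }
                }
                if (n > 0) F += Dyz * g / n;
              }
            }
            du[id] += F; du[jd] -= F;
          }
          // +z face
          if (k + 1 < nz && model[id + sz] != 0) {
            const int jd = id + sz;
            double F = 0.5 * (tensor(id, 2) + tensor(jd, 2)) * (u[jd] - u[id]);
            if (mixed) {
              double Dxz = 0.5 * (tensor(id, 4) + tensor(jd, 4));
              double Dyz = 0.5 * (tensor(id, 5) + tensor(jd, 5));
              if (Dxz != 0.0) {
                double g = 0.0; int n = 0;
                if (i + 1 < nx && i > 0) {
                  if (model[id + sx] && model[id - sx]) { g += 0.5 * (u[id + sx] - u[id - sx]); ++n; }
                  if (model[jd + sx] && model[jd - sx]) { g += 0.5 * (u[jd + sx] - u[jd - sx]); ++n; }
                }
                if (n > 0) F += Dxz * g / n;
              }
              if (Dyz != 0.0) {
                double g = 0.0; int n = 0;
                if (j + 1 < ny && j > 0) {
                  if (model[id + sy] && model[id - sy]) { g += 0.5 * (u[id + sy] - u[id - sy]); ++n; }
                  if (model[jd + sy] && model[jd - sy]) { g += 0.5 * (u[jd + sy] - u[jd - sy]); ++n; }
                }
                if (n > 0) F += Dyz * g / n;
              }
            }
            du[id] += F; du[jd] -= F;
          }
        }
    }

    // ---- reaction ---------------------------------------------------------
    if (!diffusion_only) {
      for (int id = 0; id < N; ++id) {
        if (model[id] == 1) {
          const double ui = u[id], vi = v[id];
          du[id] += c1[id] * ui * (ui - alpha[id]) * (1.0 - ui) - c2[id] * ui * vi;
          dv[id] = b[id] * (d[id] * ui - vi);
        } else if (model[id] == 3) {
          const double ui = u[id], vi = v[id];
          du[id] += c1[id] * ui * (ui - alpha[id]) * (1.0 - ui) - c2[id] * vi + j0[id];
          dv[id] = b[id] * (d[id] * ui - vi);
        } else {
          dv[id] = 0.0;
          if (model[id] == 2) du[id] += -u[id] / rb[id];
        }
      }
    } else {
      std::fill(dv.begin(), dv.end(), 0.0);
    }

    // ---- stimuli (current injection) --------------------------------------
    for (size_t s = 0; s < ev.size(); ++s)
      if (ev[s].mode == 1 && t >= ev[s].t_on && t < ev[s].t_off)
        for (size_t q = 0; q < ev[s].idx.size(); ++q)
          du[ev[s].idx[q]] += ev[s].amp;

    // ---- update -----------------------------------------------------------
    for (int id = 0; id < N; ++id) {
      if (model[id] == 0) continue;
      uprev[id] = u[id];
      u[id] += dt * du[id];
      v[id] += dt * dv[id];
    }

    // voltage-clamp stimuli
    for (size_t s = 0; s < ev.size(); ++s)
      if (ev[s].mode == 0 && t_new >= ev[s].t_on && t_new <= ev[s].t_off)
        for (size_t q = 0; q < ev[s].idx.size(); ++q)
          u[ev[s].idx[q]] = ev[s].amp;

    // ---- activation detection --------------------------------------------
    for (int id = 0; id < N; ++id) {
      if (model[id] == 0) continue;
      if (ISNA(act[id]) && uprev[id] < thresh && u[id] >= thresh) {
        double frac = (thresh - uprev[id]) / (u[id] - uprev[id]);
        act[id] = t + frac * dt;
      }
    }
    for (int p = 0; p < n_probes; ++p) {
      const double un = u[probes[p]];
      if (probe_prev[p] < thresh && un >= thresh) {
        double frac = (thresh - probe_prev[p]) / (un - probe_prev[p]);
        events[p].push_back(t + frac * dt);
      }
      probe_prev[p] = un;
    }

    if (record_every > 0 && ((step + 1) % record_every == 0)) record_sample(t_new);
    if (snapshot_every > 0 && ((step + 1) % snapshot_every == 0) && frame_i < n_frames) {
      for (int i = 0; i < N; ++i) frames(i, frame_i) = u[i];
      frame_t[frame_i] = t_new;
      ++frame_i;
    }

    // ---- stability guard --------------------------------------------------
    if ((step & 63) == 0 || step == n_steps - 1) {
      for (int id = 0; id < N; ++id)
        if (!std::isfinite(u[id]) || std::fabs(u[id]) > 10.0) { status = 1; bad_t = t_new; break; }
      if (status != 0) break;
    }
  }

  List evlist(n_probes);
  for (int p = 0; p < n_probes; ++p) evlist[p] = NumericVector(events[p].begin(), events[p].end());

  return List::create(
    _["u"] = NumericVector(u.begin(), u.end()),
    _["v"] = NumericVector(v.begin(), v.end()),
    _["t_end"] = t0 + n_steps * dt,
    _["trace_t"] = trace_t, _["trace_u"] = trace_u, _["trace_v"] = trace_v,
    _["activation"] = act, _["events"] = evlist,
    _["frames"] = frames, _["frame_t"] = frame_t, _["n_frames"] = frame_i,
    _["status"] = status, _["bad_t"] = bad_t);
}
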