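#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Brownian-dynamics simulation of cAMP in a reflective box
// [0,lx] x [0,ly] x [0,lz] with a phosphodiesterase barrier plane at
// z = lstar.  Free particles take isotropic Gaussian steps (per-axis
// variance 2 D dt); a caveolar patch on the z = 0 face emits new particles
// as a Poisson process; a particle whose step straddles the barrier plane is
// tested against the PDE site occupying the lattice cell under the crossing
// point and binds with a calibrated probability; bound sites release (kb) or
// hydrolyse (kcat) as competing exponential events.  Uses R's RNG so runs
// are reproducible under set.seed().

static inline double fold(double v, double L) {
  // reflective fold into [0, L]; steps are small relative to L, so this
  // settles in at most a couple of iterations
  while (v < 0.0 || v > L) {
    if (v < 0.0) v = -v;
    if (v > L) v = 2.0 * L - v;
  }
  return v;
}

// [[Rcpp::export(name = ".particle_run_cpp")]]
List particle_run_cpp(double lx, double ly, double lz, double lstar,
                      double d, double dt, double duration,
                      double frame_interval,
                      double source_rate,
                      double patch_x0, double patch_x1,
                      double patch_y0, double patch_y1,
                      int nxs, int nys, IntegerVector cell_site,
                      double r_c, double p_bind,
                      double kb, double kcat,
                      int init_n, int nbins,
                      bool calibration) {
  const double step_sd = std::sqrt(2.0 * d * dt);
  const long nsteps = (long)std::ceil(duration / dt - 1e-9);
  const long frame_every = std::max(1L, (long)(frame_interval / dt + 0.5));
  const double ax = lx / nxs, ay = ly / nys;
  const double r_c2 = r_c * r_c;
  const int ncell = nxs * nys;

  std::vector<double> px, py, pz;
  px.reserve(1024); py.reserve(1024); pz.reserve(1024);
  // initial uniform population
  for (int i = 0; i < init_n; ++i) {
    px.push_back(unif_rand() * lx);
    py.push_back(unif_rand() * ly);
    pz.push_back(unif_rand() * lz);
  }

  std::vector<int> site_state(ncell, 0);      // 0 free, 1 bound (indexed by cell)
  std::vector<int> bound_cells;               // cells currently bound
  long produced = init_n, degraded = 0, bind_events = 0, crossings = 0;

  const double p_evt = 1.0 - std::exp(-(kb + kcat) * dt);
  const double p_cat = (kb + kcat) > 0 ? kcat / (kb + kcat) : 0.0;

  const long nframes = nsteps / frame_every;
  IntegerMatrix frames(nframes, nbins);
  NumericVector frame_time(nframes);
  IntegerVector frame_count(nframes), frame_bound(nframes);
  const double binw = lz / nbins;
  long fi = 0;

  for (long step = 1; step <= nsteps; ++step) {
    // emission from the caveolar patch on the z = 0 face
    if (source_rate > 0.0) {
      int nnew = (int)R::rpois(source_rate * dt);
      for (int k = 0; k < nnew; ++k) {
        px.push_back(patch_x0 + unif_rand() * (patch_x1 - patch_x0));
        py.push_back(patch_y0 + unif_rand() * (patch_y1 - patch_y0));
        pz.push_back(0.0);
        ++produced;
      }
    }

    // diffusive step with barrier test
    for (size_t i = 0; i < pz.size(); /* manual advance */) {
      double dxs = norm_rand() * step_sd;
      double dys = norm_rand() * step_sd;
      double dzs = norm_rand() * step_sd;
      double z0 = pz[i];
      double z1 = z0 + dzs;
      bool removed = false;
      if ((z0 - lstar) * (z1 - lstar) < 0.0) {
        ++crossings;
        double f = (lstar - z0) / (z1 - z0);
        double xc = fold(px[i] + f * dxs, lx);
        double yc = fold(py[i] + f * dys, ly);
        int ci = (int)(xc / ax); if (ci >= nxs) ci = nxs - 1;
        int cj = (int)(yc / ay); if (cj >= nys) cj = nys - 1;
        int cell = ci + nxs * cj;
        if (cell_site[cell] == 1 && site_state[cell] == 0) {
          double cx = (ci + 0.5) * ax, cy = (cj + 0.5) * ay;
          double ddx = xc - cx, ddy = yc - cy;
          if (ddx * ddx + ddy * ddy <= r_c2 && unif_rand() < p_bind) {
            ++bind_events;
            if (!calibration) {
              site_state[cell] = 1;
              bound_cells.push_back(cell);
              // swap-remove particle i
              px[i] = px.back(); px.pop_back();
              py[i] = py.back(); py.pop_back();
              pz[i] = pz.back(); pz.pop_back();
              removed = true;
            }
          }
        }
      }
      if (!removed) {
        px[i] = fold(px[i] + dxs, lx);
        py[i] = fold(py[i] + dys, ly);
        pz[i] = fold(z1, lz);
        ++i;
      }
    }

    // bound-site events: release or catalyse
    if (!bound_cells.empty() && p_evt > 0.0) {
      for (size_t b = 0; b < bound_cells.size(); /* manual */) {
        if (unif_rand() < p_evt) {
          int cell = bound_cells[b];
          site_state[cell] = 0;
          if (unif_rand() < p_cat) {
            ++degraded;
          } else {
            // re-release one diffusive step away from the plane, side uniform
            int ci = cell % nxs, cj = cell / nxs;
            double sgn = (unif_rand() < 0.5) ? 1.0 : -1.0;
            px.push_back(fold((ci + 0.5) * ax + norm_rand() * step_sd, lx));
            py.push_back(fold((cj + 0.5) * ay + norm_rand() * step_sd, ly));
            pz.push_back(fold(lstar + sgn * std::fabs(norm_rand()) * step_sd,
                              lz));
          }
          bound_cells[b] = bound_cells.back();
          bound_cells.pop_back();
        } else {
          ++b;
        }
      }
    }

    if (step % frame_every == 0 && fi < nframes) {
      for (size_t i = 0; i < pz.size(); ++i) {
        int b = (int)(pz[i] / binw);
        if (b >= nbins) b = nbins - 1;
        ++frames(fi, b);
      }
      frame_time[fi] = step * dt;
      frame_count[fi] = (int)pz.size();
      frame_bound[fi] = (int)bound_cells.size();
      ++fi;
    }
  }

  return List::create(
    _["frames"] = frames, _["frame_time"] = frame_time,
    _["frame_count"] = frame_count, _["frame_bound"] = frame_bound,
    _["produced"] = (double)produced, _["degraded"] = (double)degraded,
    _["bind_events"] = (double)bind_events,
    _["crossings"] = (double)crossings,
    _["free_count"] = (double)pz.size(),
    _["bound_count"] = (double)bound_cells.size());
}
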