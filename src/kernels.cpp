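// Compiled inner loops of the colony simulator.
//
// The steady-state cycle (diffusion -> active uptake -> table-served FBA,
// repeated for t_ss / dtau sub-steps) and the expansion relaxation are the
// only hot paths; everything else stays in R. All updates are Jacobi
// (simultaneous), so results are independent of site traversal order.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int T_AIR = 0, T_AGAR = 1, T_CELL = 2;

struct TableView {
  std::vector<std::vector<double> > axes;
  std::vector<const double*> ex;
  const double* g;
  std::vector<int> nd;
  int ntracked;

  // multilinear interpolation; uptake clamped to the queried constraint
  void query(const double* cons, double* v_out, double& g_out) const {
    int k = ntracked;
    int lo[8];
    double w[8];
    for (int d = 0; d < k; ++d) {
      const std::vector<double>& ax = axes[d];
      double x = cons[d];
      if (x < 0) x = 0;
      if (x > ax.back()) x = ax.back();
      int i = (int)(std::upper_bound(ax.begin(), ax.end(), x) - ax.begin()) - 1;
      if (i < 0) i = 0;
      if (i > (int)ax.size() - 2) i = (int)ax.size() - 2;
      lo[d] = i;
      w[d] = (x - ax[i]) / (ax[i + 1] - ax[i]);
    }
    g_out = 0.0;
    for (int s = 0; s < k; ++s) v_out[s] = 0.0;
    int ncorner = 1 << k;
    for (int c = 0; c < ncorner; ++c) {
      double wt = 1.0;
      int lin = 0, stride = 1;
      for (int d = 0; d < k; ++d) {
        int bit = (c >> d) & 1;
        wt *= bit ? w[d] : (1.0 - w[d]);
        lin += (lo[d] + bit) * stride;
        stride *= nd[d];
      }
      if (wt == 0.0) continue;
      g_out += wt * g[lin];
      for (int s = 0; s < k; ++s) v_out[s] += wt * ex[s][lin];
    }
    for (int s = 0; s < k; ++s)
      if (v_out[s] > cons[s]) v_out[s] = cons[s];
  }
};

// [[Rcpp::export]]
List cpp_steady_state(IntegerVector dims, IntegerVector site_type,
                      List ext, List intra, List rho,
                      List sub_info, List tables,
                      double lambda, double dtau, int nsub,
                      double m_cell, double V_cell) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  const int* typ = INTEGER(site_type);
  const int nsub_count = ext.size();
  const int nstate = rho.size();

  CharacterVector sub_names = ext.names();
  CharacterVector state_names = rho.names();

  // substrate parameters
  std::vector<double> D_aq(nsub_count), D_agar(nsub_count), airv(nsub_count),
      dirich(nsub_count), vmaxvol(nsub_count), km(nsub_count), cap(nsub_count);
  std::vector<int> hindered(nsub_count), active(nsub_count), has_dir(nsub_count);
  std::vector<int> intra_slot(nsub_count, -1);
  for (int s = 0; s < nsub_count; ++s) {
    List si = sub_info[s];
    D_aq[s] = as<double>(si["D_aq"]);
    D_agar[s] = as<double>(si["D_agar"]);
    hindered[s] = as<int>(si["hindered"]);
    airv[s] = as<double>(si["air_value"]);
    has_dir[s] = as<int>(si["has_dirichlet"]);
    dirich[s] = as<double>(si["dirichlet"]);
    active[s] = as<int>(si["active"]);
    vmaxvol[s] = as<double>(si["vmax_volumetric"]);
    km[s] = as<double>(si["km"]);
    cap[s] = as<double>(si["fba_cap"]);
    if (active[s]) {
      std::string nm = as<std::string>(sub_names[s]);
      CharacterVector inames = intra.names();
      for (int q = 0; q < intra.size(); ++q)
        if (as<std::string>(inames[q]) == nm) intra_slot[s] = q;
    }
  }

  // working copies of the fields
  std::vector<std::vector<double> > cur(nsub_count), nxt(nsub_count);
  for (int s = 0; s < nsub_count; ++s) {
    NumericVector v = ext[s];
    cur[s].assign(v.begin(), v.end());
    nxt[s] = cur[s];
  }
  std::vector<std::vector<double> > pool(intra.size());
  for (int q = 0; q < intra.size(); ++q) {
    NumericVector v = intra[q];
    pool[q].assign(v.begin(), v.end());
  }
  std::vector<const double*> rho_ptr(nstate);
  for (int k = 0; k < nstate; ++k) rho_ptr[k] = REAL((SEXP)rho[k]);

  // total cell volume fraction (static within a cycle)
  std::vector<double> rho_tot(N, 0.0);
  for (int k = 0; k < nstate; ++k)
    for (R_xlen_t i = 0; i < N; ++i) rho_tot[i] += rho_ptr[k][i];

  // active (non-air) and cell site lists with neighbor tables
  std::vector<int> act, cells;
  act.reserve(N / 2);
  for (R_xlen_t i = 0; i < N; ++i) {
    if (typ[i] != T_AIR) act.push_back((int)i);
    if (typ[i] == T_CELL && rho_tot[i] > 1e-14) cells.push_back((int)i);
  }
  const int nact = (int)act.size(), ncell = (int)cells.size();
  std::vector<int> nb((size_t)nact * 6, -1);
  const int sx = 1, sy = nx, sz = nx * ny;
  for (int a = 0; a < nact; ++a) {
    int i = act[a];
    int ix = i % nx, iy = (i / nx) % ny, iz = i / (nx * ny);
    if (ix > 0) nb[a * 6 + 0] = i - sx;
    if (ix < nx - 1) nb[a * 6 + 1] = i + sx;
    if (iy > 0) nb[a * 6 + 2] = i - sy;
    if (iy < ny - 1) nb[a * 6 + 3] = i + sy;
    if (iz > 0) nb[a * 6 + 4] = i - sz;
    if (iz < nz - 1) nb[a * 6 + 5] = i + sz;
  }

  // per-substrate diffusivity fields and Dirichlet site lists
  std::vector<std::vector<double> > D(nsub_count);
  std::vector<std::vector<int> > dir_idx(nsub_count);
  for (int s = 0; s < nsub_count; ++s) {
    D[s].assign(N, D_aq[s]);
    for (int a = 0; a < nact; ++a) {
      int i = act[a];
      if (typ[i] == T_AGAR) D[s][i] = D_agar[s];
      else if (hindered[s]) {
        double r = rho_tot[i];
        D[s][i] = D_aq[s] * (1.0 - r) / (1.0 + 0.5 * r);
      }
    }
    if (has_dir[s]) {
      for (int a = 0; a < nact; ++a) {
        int i = act[a];
        if (typ[i] != T_AGAR) continue;
        int ix = i % nx, iy = (i / nx) % ny, iz = i / (nx * ny);
        if (ix == 0 || ix == nx - 1 || iy == 0 || iy == ny - 1 || iz == 0)
          dir_idx[s].push_back(i);
      }
    }
  }

  // per-cell-site FBA outputs
  std::vector<std::vector<double> > growth(nstate);
  std::vector<std::vector<std::vector<double> > > exch(nstate);
  for (int k = 0; k < nstate; ++k) {
    growth[k].assign(N, 0.0);
    exch[k].assign(nsub_count, std::vector<double>(N, 0.0));
  }

  // table views (tracked order == substrate order, checked in R)
  std::vector<TableView> tv(nstate);
  for (int k = 0; k < nstate; ++k) {
    List tb = tables[k];
    List axes = tb["axes"];
    List exl = tb["ex"];
    TableView& t = tv[k];
    t.ntracked = axes.size();
    t.axes.resize(t.ntracked);
    t.nd.resize(t.ntracked);
    t.ex.resize(t.ntracked);
    for (int d = 0; d < t.ntracked; ++d) {
      NumericVector ax = axes[d];
      t.axes[d].assign(ax.begin(), ax.end());
      t.nd[d] = ax.size();
      t.ex[d] = REAL((SEXP)exl[d]);
    }
    t.g = REAL((SEXP)tb["g"]);
  }

  const double cdif = dtau / (lambda * lambda);
  const double conv_cap = (V_cell * 1e3) / (m_cell * dtau) * 3.6e6;
  const double unit_ded = 1e-3 / 3600.0 * m_cell * dtau / (V_cell * 1e3);
  const int tail_start = nsub - std::max(1, nsub / 10);
  long capped = 0;
  double maxrel = 0.0;
  std::vector<std::vector<double> > snap(nsub_count), rate(nsub_count);
  std::vector<double> cons(nsub_count), vq(nsub_count);

  for (int t = 0; t < nsub; ++t) {
    bool tail = (t >= tail_start);
    if (t == nsub - 1) snap = cur;

    // --- diffusion (Jacobi sweep per substrate) ---
    for (int s = 0; s < nsub_count; ++s) {
      const double* phi = cur[s].data();
      double* out = nxt[s].data();
      const double* Ds = D[s].data();
      bool vol = airv[s] > 0;
      double bad = 0.0;
      for (int a = 0; a < nact; ++a) {
        int i = act[a];
        double phi_i = phi[i], D_i = Ds[i], acc = 0.0;
        const int* nbi = &nb[(size_t)a * 6];
        for (int f = 0; f < 6; ++f) {
          int j = nbi[f];
          if (j < 0) continue;
          double flux = 0.5 * (D_i + Ds[j]) * (phi[j] - phi_i);
          if (typ[j] == T_AIR) {
            if (!vol) continue;
            if (flux < 0) flux = 0;
          }
          acc += flux;
        }
        double v = phi_i + cdif * acc;
        out[i] = v;
        if (v < bad) bad = v;
        if (tail) {
          // relative change with a 1 nM floor so empty tails do not dominate
          double rel = std::fabs(v - phi_i) / (std::fabs(phi_i) + 1e-9);
          if (rel > maxrel) maxrel = rel;
        }
      }
      for (size_t q = 0; q < dir_idx[s].size(); ++q) out[dir_idx[s][q]] = dirich[s];
      if (bad < -1e-15)
        stop("diffusion instability: negative concentration (min %g)", bad);
      std::swap(cur[s], nxt[s]);
    }

    // --- active Michaelis-Menten import ---
    for (int s = 0; s < nsub_count; ++s) {
      if (!active[s]) continue;
      double* phi = cur[s].data();
      double* pin = pool[intra_slot[s]].data();
      for (int c = 0; c < ncell; ++c) {
        int i = cells[c];
        double p = phi[i];
        if (p <= 0) continue;
        double kd = rho_tot[i] * vmaxvol[s] * p / (km[s] + p) * dtau;
        if (kd > p) { kd = p; ++capped; }
        phi[i] = p - kd;
        pin[i] += kd;
      }
    }

    // --- table-served FBA per cell site and state ---
    for (int c = 0; c < ncell; ++c) {
      int i = cells[c];
      double rt = rho_tot[i];
      for (int s = 0; s < nsub_count; ++s) {
        double avail = active[s] ? pool[intra_slot[s]][i] / rt : cur[s][i];
        double vm = avail * conv_cap;
        cons[s] = vm < cap[s] ? vm : cap[s];
        if (cons[s] < 0) cons[s] = 0;
      }
      for (int k = 0; k < nstate; ++k) {
        double rs = rho_ptr[k][i];
        if (rs < 1e-14) continue;
        double gq;
        tv[k].query(cons.data(), vq.data(), gq);
        for (int s = 0; s < nsub_count; ++s) {
          double v = vq[s];
          exch[k][s][i] = v;
          if (v == 0.0) continue;
          double d = v * unit_ded * rs;
          if (v > 0 && active[s]) {
            double& p = pool[intra_slot[s]][i];
            p -= d;
            if (p < -1e-15) stop("intracellular pool overdrawn");
            if (p < 0) p = 0;
          } else {
            double& p = cur[s][i];
            p -= d;
            if (p < -1e-15) stop("extracellular pool overdrawn");
            if (p < 0) p = 0;
          }
        }
        growth[k][i] = gq;
      }
    }

  }

  // net per-site field rates over the final sub-step (for forward projection)
  for (int s = 0; s < nsub_count; ++s) {
    rate[s].assign(N, 0.0);
    const double* a0 = snap[s].data();
    const double* a1 = cur[s].data();
    for (int a = 0; a < nact; ++a) {
      int i = act[a];
      rate[s][i] = (a1[i] - a0[i]) / dtau;
    }
  }

  List ext_out(nsub_count), rate_out(nsub_count);
  for (int s = 0; s < nsub_count; ++s) {
    ext_out[s] = NumericVector(cur[s].begin(), cur[s].end());
    rate_out[s] = NumericVector(rate[s].begin(), rate[s].end());
  }
  ext_out.names() = sub_names;
  rate_out.names() = sub_names;
  List intra_out(intra.size());
  for (int q = 0; q < intra.size(); ++q)
    intra_out[q] = NumericVector(pool[q].begin(), pool[q].end());
  intra_out.names() = intra.names();
  List growth_out(nstate), exch_out(nstate);
  for (int k = 0; k < nstate; ++k) {
    growth_out[k] = NumericVector(growth[k].begin(), growth[k].end());
    List e(nsub_count);
    for (int s = 0; s < nsub_count; ++s)
      e[s] = NumericVector(exch[k][s].begin(), exch[k][s].end());
    e.names() = sub_names;
    exch_out[k] = e;
  }
  growth_out.names() = state_names;
  exch_out.names() = state_names;

  return List::create(_["ext"] = ext_out, _["intra"] = intra_out,
                      _["growth"] = growth_out, _["exch"] = exch_out,
                      _["rate"] = rate_out, _["maxrel"] = maxrel,
                      _["uptake_capped"] = (double)capped);
}

// [[Rcpp::export]]
List cpp_relax_expansion(IntegerVector dims, IntegerVector site_type,
                         List rho, List intra,
                         double rho_max, double delta_rho, int max_sweeps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  const int nstate = rho.size();
  const int nintra = intra.size();

  IntegerVector typv = clone(site_type);
  int* typ = INTEGER(typv);
  std::vector<std::vector<double> > rs(nstate), pin(nintra);
  for (int k = 0; k < nstate; ++k) {
    NumericVector v = rho[k];
    rs[k].assign(v.begin(), v.end());
  }
  for (int q = 0; q < nintra; ++q) {
    NumericVector v = intra[q];
    pin[q].assign(v.begin(), v.end());
  }

  std::vector<int> colony;
  for (R_xlen_t i = 0; i < N; ++i)
    if (typ[i] == T_CELL) colony.push_back((int)i);

  std::vector<double> rho_tot(N, 0.0), over(N, 0.0);
  std::vector<std::vector<double> > drho(nstate, std::vector<double>(N, 0.0));
  std::vector<std::vector<double> > dint(nintra, std::vector<double>(N, 0.0));
  std::vector<int> touched;

  const int sx = 1, sy = nx, sz = nx * ny;
  const int off[6] = {-sx, sx, -sy, sy, -sz, sz};
  double volume_moved = 0.0;
  int converted = 0, sweeps = 0;
  double residual = 0.0;
  double prev_max = R_PosInf;

  auto recompute = [&](void) {
    double mx = 0.0;
    for (size_t c = 0; c < colony.size(); ++c) {
      int i = colony[c];
      double rt = 0.0;
      for (int k = 0; k < nstate; ++k) rt += rs[k][i];
      rho_tot[i] = rt;
      double o = rt - rho_max;
      over[i] = o > 0 ? o : 0;
      if (over[i] > mx) mx = over[i];
    }
    return mx;
  };

  residual = recompute();
  while (residual > delta_rho && sweeps < max_sweeps) {
    touched.clear();
    for (size_t c = 0; c < colony.size(); ++c) {
      int i = colony[c];
      double o_i = over[i];
      if (o_i <= 0) continue;
      int ix = i % nx, iy = (i / nx) % ny, iz = i / (nx * ny);
      for (int f = 0; f < 6; ++f) {
        if ((f == 0 && ix == 0) || (f == 1 && ix == nx - 1) ||
            (f == 2 && iy == 0) || (f == 3 && iy == ny - 1) ||
            (f == 4 && iz == 0) || (f == 5 && iz == nz - 1)) continue;
        int j = i + off[f];
        if (typ[j] == T_AGAR) continue;
        double o_j = (typ[j] == T_CELL) ? over[j] : 0.0;
        double T = (o_i - o_j) / 12.0;
        if (T <= 0) continue;  // each face handled once, from the donor side
        double frac = T / rho_tot[i];
        for (int k = 0; k < nstate; ++k) {
          double d = rs[k][i] * frac;
          drho[k][i] -= d;
          drho[k][j] += d;
        }
        for (int q = 0; q < nintra; ++q) {
          double d = pin[q][i] * frac;
          dint[q][i] -= d;
          dint[q][j] += d;
        }
        volume_moved += T;
        touched.push_back(i);
        touched.push_back(j);
      }
    }
    if (touched.empty()) break;
    for (size_t q = 0; q < touched.size(); ++q) {
      int i = touched[q];
      for (int k = 0; k < nstate; ++k) { rs[k][i] += drho[k][i]; drho[k][i] = 0.0; }
      for (int w = 0; w < nintra; ++w) { pin[w][i] += dint[w][i]; dint[w][i] = 0.0; }
      if (typ[i] == T_AIR) {
        double rt = 0.0;
        for (int k = 0; k < nstate; ++k) rt += rs[k][i];
        if (rt > 0) {
          typ[i] = T_CELL;
          colony.push_back(i);
          ++converted;
        }
      }
    }
    ++sweeps;
    residual = recompute();
    if (residual > prev_max + 1e-12)
      stop("expansion residual increased between sweeps (%g -> %g)",
           prev_max, residual);
    prev_max = residual;
  }

  List rho_out(nstate), intra_out(nintra);
  for (int k = 0; k < nstate; ++k)
    rho_out[k] = NumericVector(rs[k].begin(), rs[k].end());
  rho_out.names() = rho.names();
  for (int q = 0; q < nintra; ++q)
    intra_out[q] = NumericVector(pin[q].begin(), pin[q].end());
  intra_out.names() = intra.names();
  return List::create(_["site_type"] = typv, _["rho"] = rho_out,
                      _["intra"] = intra_out, _["sweeps"] = sweeps,
                      _["volume_moved"] = volume_moved,
                      _["converted"] = converted, _["residual"] = residual);
}
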