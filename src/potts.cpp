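// Minimal Cellular Potts model with a diffusing, decaying arrest signal.
// Lattice spins are cell ids (0 = medium). Energy = contact + volume
// constraint; dynamics = Metropolis pixel-copy attempts; cells grow by
// target-area inflation, divide along a random plane through the centroid,
// and on division each daughter arrests with a probability augmented by the
// local signal concentration through a Hill function. Arrested cells
// secrete the signal; the field obeys dc/dt = D lap(c) - k c + source with
// zero-flux boundaries (explicit sub-stepped Euler).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int DX8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DY8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// phase codes: 0 medium, 1 dividing, 2 arrested
static inline double contactJ(const NumericMatrix& J, int pa, int pb) {
  return J(pa, pb);
}

struct CellTab {
  std::vector<int> phase;        // 0 unused/dead, 1 dividing, 2 arrested
  std::vector<double> target;    // target area
  std::vector<double> grate;     // growth rate (px^2 / MCS)
  std::vector<double> divarea;   // division target area
  std::vector<int> area;         // current pixel count
  std::vector<double> sx, sy;    // coordinate sums for centroid
  std::vector<int> birth;        // MCS of birth
};

static inline int phaseOf(const std::vector<int>& phase, int id) {
  return id == 0 ? 0 : phase[id];
}

// full Hamiltonian (oracle for the incremental deltas)
// [[Rcpp::export]]
double cpp_full_hamiltonian(IntegerMatrix lat, IntegerVector phase_by_id,
                            NumericVector target_by_id, NumericMatrix J,
                            double lambda) {
  int nr = lat.nrow(), nc = lat.ncol();
  double H = 0.0;
  for (int i = 0; i < nr; ++i) for (int j = 0; j < nc; ++j) {
    int a = lat(i, j);
    int pa = a == 0 ? 0 : phase_by_id[a - 1];
    for (int t = 0; t < 8; ++t) {
      int ii = i + DX8[t], jj = j + DY8[t];
      if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
      // count each unordered pair once
      if (ii < i || (ii == i && jj < j)) continue;
      int b = lat(ii, jj);
      if (a == b) continue;
      int pb = b == 0 ? 0 : phase_by_id[b - 1];
      H += J(pa, pb);
    }
  }
  // volume term
  int nid = phase_by_id.size();
  std::vector<int> area(nid + 1, 0);
  for (int i = 0; i < nr; ++i) for (int j = 0; j < nc; ++j)
    if (lat(i, j) > 0) area[lat(i, j)]++;
  for (int id = 1; id <= nid; ++id)
    if (phase_by_id[id - 1] > 0) {
      double d = area[id] - target_by_id[id - 1];
      H += lambda * d * d;
    }
  return H;
}

static inline double deltaH(const IntegerMatrix& lat, const CellTab& cells,
                            int i, int j, int nid_new, const NumericMatrix& J,
                            double lambda, int nr, int nc) {
  int oid = lat(i, j);
  if (nid_new == oid) return 0.0;   // no-op copy
  double dH = 0.0;
  int p_old = phaseOf(cells.phase, oid);
  int p_new = phaseOf(cells.phase, nid_new);
  for (int t = 0; t < 8; ++t) {
    int ii = i + DX8[t], jj = j + DY8[t];
    if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
    int b = lat(ii, jj);
    int pb = phaseOf(cells.phase, b);
    double e_old = (b == oid) ? 0.0 : contactJ(J, p_old, pb);
    double e_new = (b == nid_new) ? 0.0 : contactJ(J, p_new, pb);
    dH += e_new - e_old;
  }
  if (oid > 0) {
    double a = cells.area[oid], tg = cells.target[oid];
    dH += lambda * ((a - 1 - tg) * (a - 1 - tg) - (a - tg) * (a - tg));
  }
  if (nid_new > 0) {
    double a = cells.area[nid_new], tg = cells.target[nid_new];
    dH += lambda * ((a + 1 - tg) * (a + 1 - tg) - (a - tg) * (a - tg));
  }
  return dH;
}

// incremental delta-H for one proposed copy (exported for testing)
// [[Rcpp::export]]
double cpp_delta_h(IntegerMatrix lat, IntegerVector phase_by_id,
                   NumericVector target_by_id, IntegerVector area_by_id,
                   int i, int j, int new_id, NumericMatrix J, double lambda) {
  CellTab cells;
  int nid = phase_by_id.size();
  cells.phase.assign(nid + 1, 0);
  cells.target.assign(nid + 1, 0.0);
  cells.area.assign(nid + 1, 0);
  for (int id = 1; id <= nid; ++id) {
    cells.phase[id] = phase_by_id[id - 1];
    cells.target[id] = target_by_id[id - 1];
    cells.area[id] = area_by_id[id - 1];
  }
  return deltaH(lat, cells, i - 1, j - 1, new_id, J, lambda,
                lat.nrow(), lat.ncol());
}

// explicit zero-flux diffusion-decay step(s) with a fixed source field
// [[Rcpp::export]]
NumericMatrix cpp_diffuse(NumericMatrix field, NumericMatrix source,
                          double D, double decay, double dt, int nsteps) {
  int nr = field.nrow(), nc = field.ncol();
  if (dt * (4.0 * D + decay) > 1.0)
    stop("diffusion sub-step violates stability (dt*(4D+k) > 1)");
  NumericMatrix cur(clone(field)), nxt(nr, nc);
  for (int s = 0; s < nsteps; ++s) {
    for (int i = 0; i < nr; ++i) for (int j = 0; j < nc; ++j) {
      double c = cur(i, j);
      double up = (i > 0) ? cur(i - 1, j) : c;       // zero-flux mirrors
      double dn = (i < nr - 1) ? cur(i + 1, j) : c;
      double lf = (j > 0) ? cur(i, j - 1) : c;
      double rt = (j < nc - 1) ? cur(i, j + 1) : c;
      nxt(i, j) = c + dt * (D * (up + dn + lf + rt - 4.0 * c)
                            - decay * c + source(i, j));
    }
    std::swap(cur, nxt);
  }
  return cur;
}

static void fieldStep(std::vector<double>& field, const IntegerMatrix& lat,
                      const CellTab& cells, int nr, int nc, double D,
                      double decay, double secretion, double dt, int nsub) {
  std::vector<double> nxt(field.size());
  for (int s = 0; s < nsub; ++s) {
    for (int i = 0; i < nr; ++i) for (int j = 0; j < nc; ++j) {
      int idx = i * nc + j;
      double c = field[idx];
      double up = (i > 0) ? field[idx - nc] : c;
      double dn = (i < nr - 1) ? field[idx + nc] : c;
      double lf = (j > 0) ? field[idx - 1] : c;
      double rt = (j < nc - 1) ? field[idx + 1] : c;
      int id = lat(i, j);
      double src = (id > 0 && cells.phase[id] == 2) ? secretion : 0.0;
      nxt[idx] = c + dt * (D * (up + dn + lf + rt - 4.0 * c)
                           - decay * c + src);
    }
    field.swap(nxt);
  }
}

// [[Rcpp::export]]
List cpp_run_potts(List state, List par, int n_mcs) {
  IntegerMatrix lat = clone(as<IntegerMatrix>(state["lattice"]));
  NumericMatrix fieldM = clone(as<NumericMatrix>(state["field"]));
  int nr = lat.nrow(), nc = lat.ncol();

  IntegerVector phase0 = state["phase"];
  NumericVector target0 = state["target_area"];
  NumericVector grate0 = state["growth_rate"];
  NumericVector divarea0 = state["division_area"];
  IntegerVector birth0 = state["birth_mcs"];
  int mcs0 = as<int>(state["mcs"]);

  NumericMatrix J = par["contact_energies"];
  double lambda = as<double>(par["volume_lambda"]);
  double temp = as<double>(par["temperature"]);
  double base_arrest = as<double>(par["baseline_arrest"]);
  double amp = as<double>(par["hill_amplitude"]);
  double Kc = as<double>(par["hill_half_max_conc"]);
  double hh = as<double>(par["hill_coeff"]);
  double D = as<double>(par["diffusion_coeff"]);
  double decay = as<double>(par["decay_rate"]);
  double secretion = as<double>(par["secretion_rate"]);
  int nsub = as<int>(par["field_substeps"]);
  NumericVector grates = par["growth_rates"];
  NumericVector divrange = par["division_area_range"];
  double dt = 1.0 / nsub;
  if (dt * (4.0 * D + decay) > 1.0)
    stop("field sub-step violates stability (dt*(4D+k) > 1); raise field_substeps");

  int n0 = phase0.size();
  CellTab cells;
  cells.phase.assign(n0 + 1, 0);
  cells.target.assign(n0 + 1, 0.0);
  cells.grate.assign(n0 + 1, 0.0);
  cells.divarea.assign(n0 + 1, 0.0);
  cells.area.assign(n0 + 1, 0);
  cells.sx.assign(n0 + 1, 0.0);
  cells.sy.assign(n0 + 1, 0.0);
  cells.birth.assign(n0 + 1, 0);
  for (int id = 1; id <= n0; ++id) {
    cells.phase[id] = phase0[id - 1];
    cells.target[id] = target0[id - 1];
    cells.grate[id] = grate0[id - 1];
    cells.divarea[id] = divarea0[id - 1];
    cells.birth[id] = birth0[id - 1];
  }
  for (int i = 0; i < nr; ++i) for (int j = 0; j < nc; ++j) {
    int id = lat(i, j);
    if (id > 0) { cells.area[id]++; cells.sx[id] += i; cells.sy[id] += j; }
  }

  std::vector<double> field(nr * nc);
  for (int i = 0; i < nr; ++i) for (int j = 0; j < nc; ++j)
    field[i * nc + j] = fieldM(i, j);

  std::vector<int> ev_mcs, ev_parent, ev_child, ev_interval, ev_arrested;
  std::vector<int> ev_parea, ev_carea;
  std::vector<double> ev_angle;
  std::vector<int> ts_mcs, ts_dividing, ts_arrested;

  RNGScope scope;
  int attempts_per_mcs = nr * nc;

  for (int step = 0; step < n_mcs; ++step) {
    int mcs = mcs0 + step + 1;
    // --- Metropolis pixel-copy attempts ---
    for (int a = 0; a < attempts_per_mcs; ++a) {
      int i = (int)(unif_rand() * nr); if (i == nr) i = nr - 1;
      int j = (int)(unif_rand() * nc); if (j == nc) j = nc - 1;
      int t = (int)(unif_rand() * 8); if (t == 8) t = 7;
      int ii = i + DX8[t], jj = j + DY8[t];
      if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
      int oid = lat(i, j), nid = lat(ii, jj);
      if (oid == nid) continue;
      if (oid > 0 && cells.area[oid] <= 1) continue;  // never annihilate
      double dH = deltaH(lat, cells, i, j, nid, J, lambda, nr, nc);
      if (dH <= 0.0 || unif_rand() < std::exp(-dH / temp)) {
        lat(i, j) = nid;
        if (oid > 0) { cells.area[oid]--; cells.sx[oid] -= i; cells.sy[oid] -= j; }
        if (nid > 0) { cells.area[nid]++; cells.sx[nid] += i; cells.sy[nid] += j; }
      }
    }
    // --- growth: inflate target up to the division area ---
    for (size_t id = 1; id < cells.phase.size(); ++id)
      if (cells.phase[id] == 1 && cells.target[id] < cells.divarea[id])
        cells.target[id] += cells.grate[id];
    // --- divisions: trigger on realized (pixel) area ---
    size_t ncell_now = cells.phase.size();
    for (size_t id = 1; id < ncell_now; ++id) {
      if (cells.phase[id] != 1) continue;
      if (cells.area[id] < cells.divarea[id]) continue;
      if (cells.area[id] < 2) continue;
      double cx = cells.sx[id] / cells.area[id];
      double cy = cells.sy[id] / cells.area[id];
      // random division plane through the centroid; retry degenerate splits
      bool ok = false; double ct = 0, st = 0, th_used = 0;
      for (int tries = 0; tries < 24 && !ok; ++tries) {
        double th = unif_rand() * M_PI;
        th_used = th;
        ct = std::cos(th); st = std::sin(th);
        int npos = 0, nneg = 0;
        for (int i = 0; i < nr; ++i) for (int j = 0; j < nc; ++j)
          if (lat(i, j) == (int)id) {
            if ((i - cx) * ct + (j - cy) * st > 0) npos++; else nneg++;
          }
        if (npos > 0 && nneg > 0) ok = true;
      }
      if (!ok) continue;  // postpone to next MCS
      int newid = cells.phase.size();
      cells.phase.push_back(1); cells.target.push_back(0);
      cells.grate.push_back(0); cells.divarea.push_back(0);
      cells.area.push_back(0); cells.sx.push_back(0); cells.sy.push_back(0);
      cells.birth.push_back(mcs);
      for (int i = 0; i < nr; ++i) for (int j = 0; j < nc; ++j)
        if (lat(i, j) == (int)id && (i - cx) * ct + (j - cy) * st > 0) {
          lat(i, j) = newid;
          cells.area[id]--; cells.sx[id] -= i; cells.sy[id] -= j;
          cells.area[newid]++; cells.sx[newid] += i; cells.sy[newid] += j;
        }
      ev_mcs.push_back(mcs); ev_parent.push_back(id);
      ev_child.push_back(newid);
      ev_interval.push_back(mcs - cells.birth[id]);
      ev_angle.push_back(th_used);
      ev_parea.push_back(cells.area[id]);
      ev_carea.push_back(cells.area[newid]);
      cells.birth[id] = mcs;
      // per-daughter arrest decision at the signal level at its centroid
      int ids[2] = {(int)id, newid};
      int arrested_now = 0;
      for (int d = 0; d < 2; ++d) {
        int cid = ids[d];
        cells.target[cid] = cells.area[cid];
        int ci = (int)std::lround(cells.sx[cid] / cells.area[cid]);
        int cj = (int)std::lround(cells.sy[cid] / cells.area[cid]);
        if (ci < 0) ci = 0; if (ci >= nr) ci = nr - 1;
        if (cj < 0) cj = 0; if (cj >= nc) cj = nc - 1;
        double conc = field[ci * nc + cj];
        double hillc = std::pow(conc, hh);
        double p = base_arrest + amp * hillc / (hillc + std::pow(Kc, hh));
        if (p > 1.0) p = 1.0;
        if (unif_rand() < p) {
          cells.phase[cid] = 2;  // permanent arrest; starts secreting
          arrested_now++;
        } else {
          int gi = (int)(unif_rand() * grates.size());
          if (gi == grates.size()) gi = grates.size() - 1;
          cells.grate[cid] = grates[gi];
          cells.divarea[cid] = divrange[0] +
            unif_rand() * (divrange[1] - divrange[0]);
        }
      }
      ev_arrested.push_back(arrested_now);
    }
    // --- signal field ---
    fieldStep(field, lat, cells, nr, nc, D, decay, secretion, dt, nsub);
    // --- bookkeeping ---
    int ndiv = 0, narr = 0;
    for (size_t id = 1; id < cells.phase.size(); ++id) {
      if (cells.phase[id] == 1 && cells.area[id] > 0) ndiv++;
      if (cells.phase[id] == 2 && cells.area[id] > 0) narr++;
    }
    ts_mcs.push_back(mcs); ts_dividing.push_back(ndiv);
    ts_arrested.push_back(narr);
    if (ndiv == 0) break;  // proliferation has ceased
  }

  int nidout = cells.phase.size() - 1;
  IntegerVector phase_out(nidout), area_out(nidout), birth_out(nidout);
  NumericVector target_out(nidout), grate_out(nidout), divarea_out(nidout);
  NumericVector cx_out(nidout), cy_out(nidout);
  for (int id = 1; id <= nidout; ++id) {
    phase_out[id - 1] = cells.phase[id];
    area_out[id - 1] = cells.area[id];
    birth_out[id - 1] = cells.birth[id];
    target_out[id - 1] = cells.target[id];
    grate_out[id - 1] = cells.grate[id];
    divarea_out[id - 1] = cells.divarea[id];
    cx_out[id - 1] = cells.area[id] > 0 ? cells.sx[id] / cells.area[id] : NA_REAL;
    cy_out[id - 1] = cells.area[id] > 0 ? cells.sy[id] / cells.area[id] : NA_REAL;
  }
  for (int i = 0; i < nr; ++i) for (int j = 0; j < nc; ++j)
    fieldM(i, j) = field[i * nc + j];

  return List::create(
    _["lattice"] = lat, _["field"] = fieldM,
    _["phase"] = phase_out, _["target_area"] = target_out,
    _["growth_rate"] = grate_out, _["division_area"] = divarea_out,
    _["area"] = area_out, _["birth_mcs"] = birth_out,
    _["centroid_x"] = cx_out, _["centroid_y"] = cy_out,
    _["mcs"] = ts_mcs.empty() ? mcs0 : ts_mcs.back(),
    _["events"] = DataFrame::create(
      _["mcs"] = wrap(ev_mcs), _["parent"] = wrap(ev_parent),
      _["child"] = wrap(ev_child), _["interval"] = wrap(ev_interval),
      _["angle"] = wrap(ev_angle),
      _["area_kept"] = wrap(ev_parea),
      _["area_split"] = wrap(ev_carea),
      _["n_arrested"] = wrap(ev_arrested)),
    _["series"] = DataFrame::create(
      _["mcs"] = wrap(ts_mcs), _["dividing"] = wrap(ts_dividing),
      _["arrested"] = wrap(ts_arrested)));
}
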