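#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Cell fates on a square lattice with 8-neighbourhoods. Status codes:
// 0 = empty site, 1 = proliferative cell, 2 = RCD (reproductively dead) cell.
// All randomness comes from R's RNG stream (unif_rand) so that set.seed()
// in R makes every simulation bit-reproducible.

static const int DX[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DY[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

static inline int runif_int(int n) {
  // uniform draw from 0..n-1
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

struct Lattice {
  int side;
  std::vector<int> occ;      // site -> cell id + 1, or 0 if empty
  std::vector<int> x, y;     // per-cell coordinates
  std::vector<int> status;   // per-cell status (1 or 2)
  std::vector<int> gen;      // per-cell generation
  bool boundary;

  Lattice(int side_) : side(side_), occ(side_ * side_, 0), boundary(false) {}

  int site(int cx, int cy) const { return cx * side + cy; }

  void add_cell(int cx, int cy, int st, int g) {
    x.push_back(cx); y.push_back(cy); status.push_back(st); gen.push_back(g);
    occ[site(cx, cy)] = (int)x.size();
    if (cx == 0 || cy == 0 || cx == side - 1 || cy == side - 1) boundary = true;
  }

  int free_neighbours(int id, int *out) const {
    int k = 0;
    for (int d = 0; d < 8; ++d) {
      int nx = x[id] + DX[d], ny = y[id] + DY[d];
      if (nx < 0 || ny < 0 || nx >= side || ny >= side) continue;
      if (occ[site(nx, ny)] == 0) out[k++] = site(nx, ny);
    }
    return k;
  }

  void move_cell(int id, int dest) {
    occ[site(x[id], y[id])] = 0;
    x[id] = dest / side; y[id] = dest % side;
    occ[dest] = id + 1;
    if (x[id] == 0 || y[id] == 0 || x[id] == side - 1 || y[id] == side - 1)
      boundary = true;
  }
};

static void shuffled_ids(int n, std::vector<int> &ids) {
  ids.resize(n);
  for (int i = 0; i < n; ++i) ids[i] = i;
  for (int i = n - 1; i > 0; --i) std::swap(ids[i], ids[runif_int(i + 1)]);
}

// One synchronized doubling step: division/RCD phase in random cell order,
// then a movement phase. Blocked proliferative cells defer their fate unless
// rcd_when_blocked is set, in which case they may still die.
static void do_step(Lattice &lat, const NumericVector &p1, double p_move,
                    bool rcd_when_blocked) {
  int free_sites[8];
  int n0 = (int)lat.x.size();  // daughters created this step do not act
  std::vector<int> ids;
  shuffled_ids(n0, ids);
  for (int i = 0; i < n0; ++i) {
    int id = ids[i];
    if (lat.status[id] != 1) continue;
    int g = lat.gen[id];
    if (g >= p1.size())
      stop("cell generation %d exceeds the schedule horizon g_max = %d",
           g, (int)p1.size() - 1);
    int nf = lat.free_neighbours(id, free_sites);
    if (nf == 0) {
      if (rcd_when_blocked && unif_rand() < p1[g]) lat.status[id] = 2;
      continue;  // contact inhibition: fate deferred
    }
    if (unif_rand() < p1[g]) {
      lat.status[id] = 2;  // RCD is absorbing
    } else {
      int dest = free_sites[runif_int(nf)];
      lat.gen[id] = g + 1;  // division replaces the cell by two daughters
      lat.add_cell(dest / lat.side, dest % lat.side, 1, g + 1);
    }
  }
  if (p_move > 0) {
    int n1 = (int)lat.x.size();
    shuffled_ids(n1, ids);
    for (int i = 0; i < n1; ++i) {
      int id = ids[i];
      if (unif_rand() >= p_move) continue;
      int nf = lat.free_neighbours(id, free_sites);
      if (nf > 0) lat.move_cell(id, free_sites[runif_int(nf)]);
    }
  }
}

static int n_proliferative(const Lattice &lat) {
  int k = 0;
  for (size_t i = 0; i < lat.status.size(); ++i) if (lat.status[i] == 1) ++k;
  return k;
}

// [[Rcpp::export]]
List cpp_lattice_step(IntegerMatrix status, IntegerMatrix gen,
                      NumericVector p1, double p_move, bool rcd_when_blocked) {
  int side = status.nrow();
  if (status.ncol() != side || gen.nrow() != side || gen.ncol() != side)
    stop("status and generation grids must be square and of equal size");
  Lattice lat(side);
  for (int cx = 0; cx < side; ++cx)
    for (int cy = 0; cy < side; ++cy)
      if (status(cx, cy) != 0) lat.add_cell(cx, cy, status(cx, cy), gen(cx, cy));
  do_step(lat, p1, p_move, rcd_when_blocked);
  IntegerMatrix st(side, side), gn(side, side);
  for (size_t i = 0; i < lat.x.size(); ++i) {
    st(lat.x[i], lat.y[i]) = lat.status[i];
    gn(lat.x[i], lat.y[i]) = lat.gen[i];
  }
  return List::create(_["status"] = st, _["generation"] = gn,
                      _["boundary"] = lat.boundary);
}

// [[Rcpp::export]]
List cpp_simulate_colony(NumericVector p1, int grid_side, int n_steps,
                         double p_move, bool rcd_when_blocked) {
  Lattice lat(grid_side);
  lat.add_cell(grid_side / 2, grid_side / 2, 1, 0);
  int steps_run = 0;
  for (int s = 0; s < n_steps; ++s) {
    if (n_proliferative(lat) == 0) break;
    do_step(lat, p1, p_move, rcd_when_blocked);
    ++steps_run;
  }
  int np = n_proliferative(lat);
  return List::create(_["size"] = (int)lat.x.size(),
                      _["n_proliferative"] = np,
                      _["n_rcd"] = (int)lat.x.size() - np,
                      _["boundary"] = lat.boundary,
                      _["steps"] = steps_run);
}

// [[Rcpp::export]]
IntegerMatrix cpp_run_inocula(NumericVector p1, int grid_side, int n_steps,
                              double p_move, bool rcd_when_blocked,
                              int n_inocula) {
  IntegerMatrix out(n_inocula, 4);  // size, n_proliferative, n_rcd, boundary
  for (int i = 0; i < n_inocula; ++i) {
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
    Lattice lat(grid_side);
    lat.add_cell(grid_side / 2, grid_side / 2, 1, 0);
    for (int s = 0; s < n_steps; ++s) {
      if (n_proliferative(lat) == 0) break;
      do_step(lat, p1, p_move, rcd_when_blocked);
    }
    int np = n_proliferative(lat);
    out(i, 0) = (int)lat.x.size();
    out(i, 1) = np;
    out(i, 2) = (int)lat.x.size() - np;
    out(i, 3) = lat.boundary ? 1 : 0;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_growth_curve(NumericVector p1, int grid_side, int n_steps,
                               double p_move, bool rcd_when_blocked,
                               double initial_density) {
  int n_sites = grid_side * grid_side;
  int n_init = (int)(initial_density * n_sites + 0.5);
  if (n_init < 1) n_init = 1;
  if (n_init > n_sites) n_init = n_sites;
  Lattice lat(grid_side);
  // uniform placement without replacement (partial Fisher-Yates over sites)
  std::vector<int> sites(n_sites);
  for (int i = 0; i < n_sites; ++i) sites[i] = i;
  for (int i = 0; i < n_init; ++i) {
    int j = i + runif_int(n_sites - i);
    std::swap(sites[i], sites[j]);
    lat.add_cell(sites[i] / grid_side, sites[i] % grid_side, 1, 0);
  }
  IntegerVector counts(n_steps + 1);
  counts[0] = n_init;
  for (int s = 0; s < n_steps; ++s) {
    do_step(lat, p1, p_move, rcd_when_blocked);
    counts[s + 1] = (int)lat.x.size();
  }
  return counts;
}
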