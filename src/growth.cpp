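#include <Rcpp.h>
using namespace Rcpp;

// Kinetic Monte Carlo growth of barcoded cells on a 3D cubic lattice.
//
// Every cell carries the same per-cell event rates (birth b, death d,
// mobility m), so picking the next event reduces to: choose a cell uniformly
// at random, then choose the event type with probabilities b:d:m. Birth
// places a daughter (inheriting the parent's barcode) on a uniformly chosen
// empty neighbor site; with no empty neighbor the division attempt is
// suppressed. Death frees the site for reuse. Mobility hops the cell to a
// uniformly chosen empty neighbor site.
//
// Uses R's RNG (unif_rand) so set.seed() in R makes trajectories
// bit-reproducible.

static inline int site_index(int x, int y, int z, int L) {
  return x + L * (y + L * z);
}

// [[Rcpp::export]]
List grow_lattice(IntegerMatrix coords, IntegerVector barcodes,
                  int extent, double birth, double death, double mobility,
                  int n_neigh, int n_target, double max_events) {
  const int L = extent;
  const int n0 = coords.nrow();

  // neighbor offsets: first 6 are the von Neumann set, the remaining 20
  // complete the Moore (26-connected) set
  static const int off6[6][3] = {
    {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}
  };
  int offs[26][3];
  int k = 0;
  for (int i = 0; i < 6; ++i) {
    offs[k][0] = off6[i][0]; offs[k][1] = off6[i][1]; offs[k][2] = off6[i][2];
    ++k;
  }
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        if (std::abs(dx) + std::abs(dy) + std::abs(dz) == 1) continue;
        offs[k][0] = dx; offs[k][1] = dy; offs[k][2] = dz;
        ++k;
      }

  std::vector<int> occ((size_t)L * L * L, 0);   // 0 = empty, else cell idx + 1
  std::vector<int> cx(n0), cy(n0), cz(n0), bc(n0);
  for (int i = 0; i < n0; ++i) {
    cx[i] = coords(i, 0); cy[i] = coords(i, 1); cz[i] = coords(i, 2);
    bc[i] = barcodes[i];
    occ[site_index(cx[i], cy[i], cz[i], L)] = i + 1;
  }
  int n = n0;
  cx.reserve(n_target); cy.reserve(n_target); cz.reserve(n_target);
  bc.reserve(n_target);

  const double total = birth + death + mobility;
  const double p_birth = birth / total;
  const double p_death = (birth + death) / total;

  double events = 0.0;
  int empty_nb[26];

  while (n < n_target && n > 0) {
    if (events >= max_events)
      stop("event budget exhausted before reaching the target size");
    events += 1.0;

    int i = (int)(unif_rand() * n);
    if (i >= n) i = n - 1;
    double u = unif_rand();

    if (u < p_birth || (u >= p_death)) {
      // birth or mobility: both need an empty neighbor
      int ne = 0;
      for (int j = 0; j < n_neigh; ++j) {
        int x = cx[i] + offs[j][0], y = cy[i] + offs[j][1],
            z = cz[i] + offs[j][2];
        if (x < 0 || y < 0 || z < 0 || x >= L || y >= L || z >= L) continue;
        int s = site_index(x, y, z, L);
        if (occ[s] == 0) empty_nb[ne++] = s;
      }
      if (ne == 0) continue;  // suppressed: crowded cell cannot divide or move
      int pick = (int)(unif_rand() * ne);
      if (pick >= ne) pick = ne - 1;
      int s = empty_nb[pick];
      int z = s / (L * L), y = (s / L) % L, x = s % L;
      if (u < p_birth) {
        cx.push_back(x); cy.push_back(y); cz.push_back(z);
        bc.push_back(bc[i]);
        occ[s] = ++n;
      } else {
        occ[site_index(cx[i], cy[i], cz[i], L)] = 0;
        cx[i] = x; cy[i] = y; cz[i] = z;
        occ[s] = i + 1;
      }
    } else {
      // death: swap-pop so the cell vector stays dense
      occ[site_index(cx[i], cy[i], cz[i], L)] = 0;
      int last = n - 1;
      if (i != last) {
        cx[i] = cx[last]; cy[i] = cy[last]; cz[i] = cz[last];
        bc[i] = bc[last];
        occ[site_index(cx[i], cy[i], cz[i], L)] = i + 1;
      }
      cx.pop_back(); cy.pop_back(); cz.pop_back(); bc.pop_back();
      --n;
    }
  }

  IntegerMatrix out_coords(n, 3);
  IntegerVector out_bc(n);
  for (int i = 0; i < n; ++i) {
    out_coords(i, 0) = cx[i]; out_coords(i, 1) = cy[i];
    out_coords(i, 2) = cz[i];
    out_bc[i] = bc[i];
  }
  return List::create(_["coords"] = out_coords, _["barcodes"] = out_bc,
                      _["n"] = n, _["events"] = events,
                      _["extinct"] = (n == 0));
}
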