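#include <Rcpp.h>
using namespace Rcpp;

// Impeded lattice random walk for a batch of virions.
//
// Coordinates are 0-based; linear node index = x + nx*(y + ny_cap*z).
// x (and z in 3D) wrap periodically; y < 0 is the solid substratum and
// y >= ny_cap the cap of the virtual off-top zone -- in both cases the
// attempted step is spent in place. Per step: (i) advective removal check
// when off the biofilm, with per-node probability `prem`; (ii) stay with
// probability p_stay, else pick one of the 2*dim axis directions uniformly;
// (iii) interaction check with probability 1 - efac[src]*efac[tgt] where
// efac = exp(-dtp * I_node); (iv) on interaction cease motion (recording the
// number of steps consumed), otherwise move. Uses R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export]]
List walk_phages_cpp(IntegerVector x, IntegerVector y, IntegerVector z,
                     int nx, int ny_cap, int nz, int dim, int n_steps,
                     double p_stay, NumericVector efac, LogicalVector occ,
                     NumericVector prem) {
  int np = x.size();
  IntegerVector xo = clone(x), yo = clone(y), zo = clone(z);
  LogicalVector removed(np), stopped(np);
  IntegerVector steps(np);
  int ndir = 2 * dim;

  for (int i = 0; i < np; ++i) {
    int xi = xo[i], yi = yo[i], zi = zo[i];
    bool stp = false, rem = false;
    int s = n_steps;
    for (int step = 0; step < n_steps; ++step) {
      int idx = xi + nx * (yi + ny_cap * zi);
      if (!occ[idx] && prem[idx] > 0.0 && unif_rand() < prem[idx]) {
        rem = true;
        s = step;
        break;
      }
      // choose a target node: stay with probability p_stay, else one of the
      // 2*dim axis directions uniformly
      int tx = xi, ty = yi, tz = zi;
      if (unif_rand() >= p_stay) {
        int dir = (int)(unif_rand() * ndir);
        if (dir >= ndir) dir = ndir - 1;
        switch (dir) {
          case 0: tx = (xi + 1) % nx; break;
          case 1: tx = (xi - 1 + nx) % nx; break;
          case 2: ty = yi + 1; break;
          case 3: ty = yi - 1; break;
          case 4: tz = (zi + 1) % nz; break;
          case 5: tz = (zi - 1 + nz) % nz; break;
        }
        if (ty < 0 || ty >= ny_cap) continue;  // blocked: step spent in place
      }
      // interaction check against source + target rates (target may equal
      // source when the phage stays put inside biomass)
      int tidx = tx + nx * (ty + ny_cap * tz);
      double pint = 1.0 - efac[idx] * efac[tidx];
      if (pint > 0.0 && unif_rand() < pint) {
        stp = true;
        s = step + 1;  // this step was consumed by the interaction
        break;
      }
      xi = tx; yi = ty; zi = tz;
    }
    xo[i] = xi; yo[i] = yi; zo[i] = zi;
    removed[i] = rem; stopped[i] = stp; steps[i] = s;
  }
  return List::create(_["x"] = xo, _["y"] = yo, _["z"] = zo,
                      _["removed"] = removed, _["stopped"] = stopped,
                      _["steps"] = steps);
}

// Squared Euclidean distance (periodic in x) from every node to the nearest
// biomass-containing node, given h2 = squared vertical distance to biomass
// within each column (Inf for empty columns) and dx2 = squared periodic
// lateral distance between column pairs. The nearest occupied node to (x, y)
// lies in some column xp at its minimal vertical offset, so
// d2(x, y) = min_xp dx2(x, xp) + h2(xp, y).
// [[Rcpp::export]]
NumericMatrix dist2_field_cpp(NumericMatrix h2, NumericMatrix dx2) {
  int nx = h2.nrow(), ny = h2.ncol();
  NumericMatrix out(nx, ny);
  for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) {
      double best = R_PosInf;
      for (int xp = 0; xp < nx; ++xp) {
        double v = dx2(x, xp) + h2(xp, y);
        if (v < best) best = v;
      }
      out(x, y) = best;
    }
  }
  return out;
}
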