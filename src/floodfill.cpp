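// Quality-guided floodfill phase unwrapping over a masked 3D volume.
// Returns integer wrap counts k (unwrapped = wrapped + 2*pi*k) so the
// modulo-2*pi identity with the input is exact by construction, plus a
// connected-component label per masked voxel (6-connectivity). Each
// component is seeded at its maximum-quality voxel (k = 0 there) and grown
// by always popping the highest-quality frontier voxel; a popped voxel takes
// its wrap count from its highest-quality already-unwrapped neighbor.

#include <Rcpp.h>
#include <queue>
#include <limits>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List floodfill_unwrap_cpp(NumericVector wrapped, NumericVector quality,
                          LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  const double TWOPI = 2.0 * M_PI;
  IntegerVector kout(n, NA_INTEGER);
  IntegerVector comp(n, NA_INTEGER);
  std::vector<char> state(n, 0);  // 0 untouched, 1 frontier, 2 done
  std::vector<double> unw(n, 0.0);

  const int offs[6] = {-1, 1, -nx, nx, -nx * ny, nx * ny};

  typedef std::pair<double, int> QE;  // (quality, index); ties -> larger idx
  std::priority_queue<QE> pq;

  int ncomp = 0;
  for (;;) {
    // new seed: best-quality untouched masked voxel
    int seed = -1;
    double bestq = -std::numeric_limits<double>::infinity();
    for (int i = 0; i < n; i++)
      if (mask[i] && state[i] == 0 && (seed < 0 || quality[i] > bestq)) {
        bestq = quality[i];
        seed = i;
      }
    if (seed < 0) break;
    ncomp++;
    state[seed] = 2;
    kout[seed] = 0;
    comp[seed] = ncomp;
    unw[seed] = wrapped[seed];
    pq.push(QE(quality[seed], seed));
    // neighbors of seed enter the frontier via the pop below
    int cur = seed;
    bool first = true;
    while (!pq.empty() || first) {
      int j;
      if (first) {
        j = cur;
        first = false;
      } else {
        j = pq.top().second;
        pq.pop();
        if (state[j] == 2) continue;
        // unwrap j from its best done neighbor
        int ib = j % nx, jb = (j / nx) % ny, kb = j / (nx * ny);
        int bestnb = -1;
        double bq = -std::numeric_limits<double>::infinity();
        for (int m = 0; m < 6; m++) {
          int ii = ib + (m == 0 ? -1 : m == 1 ? 1 : 0);
          int jj = jb + (m == 2 ? -1 : m == 3 ? 1 : 0);
          int kk = kb + (m == 4 ? -1 : m == 5 ? 1 : 0);
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          int nb = j + offs[m];
          if (state[nb] == 2 && (bestnb < 0 || quality[nb] > bq)) {
            bq = quality[nb];
            bestnb = nb;
          }
        }
        if (bestnb < 0) continue;  // should not happen
        double d = wrapped[j] - wrapped[bestnb];
        double wd = d - TWOPI * std::round(d / TWOPI);
        double target = unw[bestnb] + wd;
        int kj = (int)std::lround((target - wrapped[j]) / TWOPI);
        kout[j] = kj;
        unw[j] = wrapped[j] + TWOPI * kj;
        comp[j] = ncomp;
        state[j] = 2;
      }
      // push unfinished masked neighbors of j
      int ib = j % nx, jb = (j / nx) % ny, kb = j / (nx * ny);
      for (int m = 0; m < 6; m++) {
        int ii = ib + (m == 0 ? -1 : m == 1 ? 1 : 0);
        int jj = jb + (m == 2 ? -1 : m == 3 ? 1 : 0);
        int kk = kb + (m == 4 ? -1 : m == 5 ? 1 : 0);
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        int nb = j + offs[m];
        if (mask[nb] && state[nb] != 2) {
          state[nb] = 1;
          pq.push(QE(quality[nb], nb));
        }
      }
    }
  }
  return List::create(Named("k") = kout, Named("component") = comp,
                      Named("ncomponents") = ncomp);
}
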