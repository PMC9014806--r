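#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Lattice diffusion-limited aggregation: single seed at the origin, random
// walkers launched from a birth circle (radius = cluster radius + 5), taking
// 4-neighbor unit steps, sticking on 4-contact, killed beyond 3x the birth
// radius. Walkers far outside the cluster take a long radial jump (to a
// uniform angle at the distance that keeps them outside the cluster halo),
// the standard exact acceleration for circularly symmetric re-entry.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix dla_grow_cpp(int n_particles) {
  if (n_particles < 1) stop("n_particles must be >= 1");
  int H = std::max(64, (int)std::ceil(3.2 * std::pow((double)n_particles, 1.0 / 1.6)) + 16);
  int W = 2 * H + 1;
  std::vector<unsigned char> grid((size_t)W * W, 0);
  auto occ = [&](long zi, long xi) -> unsigned char& {
    return grid[(size_t)(zi + H) * W + (xi + H)];
  };
  occ(0, 0) = 1;
  double rmax = 0.0;
  int placed = 1;
  const int dz[4] = {1, -1, 0, 0};
  const int dx[4] = {0, 0, 1, -1};
  while (placed < n_particles) {
    double rb = rmax + 5.0;
    double rk = 3.0 * rb;
    if (rb + 2 >= H) stop("internal grid exhausted");
    double a = 2.0 * M_PI * unif_rand();
    long z = (long)std::lround(rb * std::cos(a));
    long x = (long)std::lround(rb * std::sin(a));
    bool alive = true;
    while (alive) {
      double r = std::sqrt((double)z * z + (double)x * x);
      if (r > rk) break; // killed; relaunch
      if (r > rmax + 6.0) {
        // long jump: stay outside the sticking halo
        double jump = r - rmax - 4.0;
        double b = 2.0 * M_PI * unif_rand();
        z = (long)std::lround(z + jump * std::cos(b));
        x = (long)std::lround(x + jump * std::sin(b));
        continue;
      }
      int s = (int)(unif_rand() * 4.0); if (s > 3) s = 3;
      long nz2 = z + dz[s], nx2 = x + dx[s];
      if (std::labs(nz2) >= H - 1 || std::labs(nx2) >= H - 1) { break; }
      if (occ(nz2, nx2)) continue;       // never step onto the cluster
      z = nz2; x = nx2;
      // stick on contact: arrived at a site 4-adjacent to the cluster
      if (occ(z + 1, x) || occ(z - 1, x) || occ(z, x + 1) || occ(z, x - 1)) {
        occ(z, x) = 1;
        ++placed;
        double rr = std::sqrt((double)z * z + (double)x * x);
        if (rr > rmax) rmax = rr;
        alive = false;
      }
    }
  }
  // crop to the occupied bounding box
  long zlo = H, zhi = -H, xlo = H, xhi = -H;
  for (long zi = -H; zi <= H; ++zi)
    for (long xi = -H; xi <= H; ++xi)
      if (grid[(size_t)(zi + H) * W + (xi + H)]) {
        if (zi < zlo) zlo = zi; if (zi > zhi) zhi = zi;
        if (xi < xlo) xlo = xi; if (xi > xhi) xhi = xi;
      }
  IntegerMatrix out(zhi - zlo + 1, xhi - xlo + 1);
  for (long zi = zlo; zi <= zhi; ++zi)
    for (long xi = xlo; xi <= xhi; ++xi)
      out(zi - zlo, xi - xlo) = grid[(size_t)(zi + H) * W + (xi + H)];
  return out;
}
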