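#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Face conductance between two voxels with (possibly different) diffusion
// coefficients: harmonic mean over the shared face, divided by h^2 so that
// sum_faces g * (c_nb - c) approximates div(D grad c). Reduces to the
// standard 5-point stencil D/h^2 when D is uniform.
static inline double face_g(double Da, double Db, double h2) {
  if (Da <= 0.0 || Db <= 0.0) return 0.0;
  return 2.0 * Da * Db / (Da + Db) / h2;
}

// Successive over-relaxation solve of the pseudo-steady problem
//   div(D grad c) - kappa * c + src = 0
// on a rectangular voxel grid. Voxels with dirichlet == TRUE are held at
// their incoming value; array edges without a neighbour are no-flux
// (mirror). Optionally projects the iterate onto c >= 0.
// Returns the field plus iteration count, final residual, residual scale
// and the number of voxels clipped at zero in the final state.
// [[Rcpp::export]]
List sor_pss_cpp(NumericMatrix conc, NumericMatrix D, NumericMatrix kappa,
                 NumericMatrix src, LogicalMatrix dirichlet, double h,
                 double omega, double tol, int max_iter, bool nonneg,
                 double res_floor) {
  const int nr = conc.nrow(), nc = conc.ncol();
  const double h2 = h * h;
  NumericMatrix c = clone(conc);
  double resid = NA_REAL, scale = res_floor;
  int it = 0;
  bool stagnant = false;
  for (it = 1; it <= max_iter; ++it) {
    double dmax = 0.0, cmax = 0.0;
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        if (dirichlet(i, j)) continue;
        const double Dc = D(i, j);
        double diag = kappa(i, j), rhs = src(i, j);
        if (i > 0)      { double g = face_g(Dc, D(i - 1, j), h2); diag += g; rhs += g * c(i - 1, j); }
        if (i < nr - 1) { double g = face_g(Dc, D(i + 1, j), h2); diag += g; rhs += g * c(i + 1, j); }
        if (j > 0)      { double g = face_g(Dc, D(i, j - 1), h2); diag += g; rhs += g * c(i, j - 1); }
        if (j < nc - 1) { double g = face_g(Dc, D(i, j + 1), h2); diag += g; rhs += g * c(i, j + 1); }
        if (diag <= 0.0) continue;  // isolated voxel: nothing to solve
        double cgs = rhs / diag;
        double cn = (1.0 - omega) * c(i, j) + omega * cgs;
        if (nonneg && cn < 0.0) cn = 0.0;
        double d = std::fabs(cn - c(i, j));
        if (d > dmax) dmax = d;
        if (std::fabs(cn) > cmax) cmax = std::fabs(cn);
        c(i, j) = cn;
      }
    }
    // iterate is stationary to machine precision: nothing further attainable
    stagnant = (dmax <= 1e-13 * std::max(cmax, 1e-30));
    // residual check every few sweeps (it is O(one sweep) itself)
    if (stagnant || it % 4 == 0 || it == max_iter) {
      double r = 0.0, s = res_floor;
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (dirichlet(i, j)) continue;
          const double Dc = D(i, j);
          double flux = 0.0, gsum = 0.0;
          if (i > 0)      { double g = face_g(Dc, D(i - 1, j), h2); flux += g * (c(i - 1, j) - c(i, j)); gsum += g; }
          if (i < nr - 1) { double g = face_g(Dc, D(i + 1, j), h2); flux += g * (c(i + 1, j) - c(i, j)); gsum += g; }
          if (j > 0)      { double g = face_g(Dc, D(i, j - 1), h2); flux += g * (c(i, j - 1) - c(i, j)); gsum += g; }
          if (j < nc - 1) { double g = face_g(Dc, D(i, j + 1), h2); flux += g * (c(i, j + 1) - c(i, j)); gsum += g; }
          if (gsum <= 0.0 && kappa(i, j) <= 0.0) continue;
          double res = flux - kappa(i, j) * c(i, j) + src(i, j);
          // at a clipped voxel (c pinned at 0) a negative residual is
          // admissible: the true rate there is cut off, not balanced
          if (nonneg && c(i, j) == 0.0 && res < 0.0) res = 0.0;
          double sc = std::fabs(src(i, j)) + kappa(i, j) * std::fabs(c(i, j));
          if (sc > s) s = sc;
          if (std::fabs(res) > r) r = std::fabs(res);
        }
      }
      resid = r; scale = s;
      if (r <= tol * s || stagnant) break;
    }
  }
  int clipped = 0;
  if (nonneg) {
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i)
        if (!dirichlet(i, j) && c(i, j) == 0.0 && std::fabs(src(i, j)) > 0.0) ++clipped;
  }
  return List::create(_["conc"] = c, _["iterations"] = it,
                      _["residual"] = resid, _["scale"] = scale,
                      _["clipped"] = clipped,
                      _["converged"] = (resid <= tol * scale || stagnant));
}

// Pairwise overlap relaxation ("shoving"). Cells are hard discs; every
// overlapping pair is displaced apart along the centre line by half the
// overlap each, iterating until the worst overlap is below tol_frac times
// the mean radius or max_iter passes. Fully coincident centres are split
// along a direction drawn from R's RNG (deterministic under set.seed).
// Pair order is the caller's vector order (sort by id for determinism).
// [[Rcpp::export]]
List shove_cpp(NumericVector x0, NumericVector y0, NumericVector r,
               int max_iter, double tol_frac) {
  const int n = x0.size();
  NumericVector x = clone(x0), y = clone(y0);
  double rbar = 0.0, rmax = 0.0;
  for (int i = 0; i < n; ++i) { rbar += r[i]; if (r[i] > rmax) rmax = r[i]; }
  rbar = (n > 0) ? rbar / n : 0.0;
  const double tol = tol_frac * rbar;
  double worst = 0.0;
  int pass = 0;
  if (n < 2 || rmax <= 0.0)
    return List::create(_["x"] = x, _["y"] = y, _["iterations"] = 0,
                        _["max_overlap"] = 0.0);
  // spatial hash with bin edge = one diameter of the largest cell;
  // flat counting-sort layout, buffers reused across passes
  const double bin = 2.0 * rmax;
  std::vector<int> bx(n), by(n), order(n), start;
  for (pass = 1; pass <= max_iter; ++pass) {
    double xmin = x[0], ymin = y[0];
    for (int i = 1; i < n; ++i) {
      if (x[i] < xmin) xmin = x[i];
      if (y[i] < ymin) ymin = y[i];
    }
    int nbx = 1, nby = 1;
    for (int i = 0; i < n; ++i) {
      bx[i] = (int)std::floor((x[i] - xmin) / bin);
      by[i] = (int)std::floor((y[i] - ymin) / bin);
      if (bx[i] + 1 > nbx) nbx = bx[i] + 1;
      if (by[i] + 1 > nby) nby = by[i] + 1;
    }
    const size_t nbins = (size_t)nbx * nby;
    start.assign(nbins + 1, 0);
    for (int i = 0; i < n; ++i) ++start[(size_t)by[i] * nbx + bx[i] + 1];
    for (size_t b = 1; b <= nbins; ++b) start[b] += start[b - 1];
    { std::vector<int> cur(start.begin(), start.end() - 1);
      for (int i = 0; i < n; ++i) order[cur[(size_t)by[i] * nbx + bx[i]]++] = i; }
    worst = 0.0;
    for (int i = 0; i < n; ++i) {
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          int cx = bx[i] + di, cy = by[i] + dj;
          if (cx < 0 || cy < 0 || cx >= nbx || cy >= nby) continue;
          const size_t b = (size_t)cy * nbx + cx;
          for (int k = start[b]; k < start[b + 1]; ++k) {
            int jdx = order[k];
            if (jdx <= i) continue;
            double dx = x[jdx] - x[i], dy = y[jdx] - y[i];
            double sum = r[i] + r[jdx];
            double d2 = dx * dx + dy * dy;
            if (d2 >= sum * sum) continue;
            double d = std::sqrt(d2), ov;
            if (d < 1e-12) {  // coincident: random split direction
              double ang = R::runif(0.0, 2.0 * M_PI);
              dx = std::cos(ang); dy = std::sin(ang); d = 1.0; ov = sum;
            } else {
              ov = sum - d;
            }
            if (ov > worst) worst = ov;
            double push = 0.5 * ov / d;
            x[i] -= dx * push; y[i] -= dy * push;
            x[jdx] += dx * push; y[jdx] += dy * push;
          }
        }
      }
    }
    if (worst <= tol) break;
  }
  return List::create(_["x"] = x, _["y"] = y, _["iterations"] = pass,
                      _["max_overlap"] = worst);
}

// Fused nonlinear relaxation for the micro-environment: solves the coupled
// pseudo-steady problems for NH3 and O2 with per-voxel Monod uptake
//   div(D_s grad c_s) - U_s(c_NH3, c_O2) = 0,
// where U_s sums dual-Monod-with-maintenance uptake over the biomass in the
// voxel. Each SOR update linearizes the local uptake as kappa = U/c, which
// keeps iterates non-negative; rates are re-evaluated from the current
// fields every sweep, so rates and fields co-converge. Residuals are
// checked against the true Monod rates.
// M: (nvox x nsp) biomass per voxel, fmol_X. par: (nsp x 7) columns
// mu_max, K_NH3, K_O2, a_m, yield, |stoich_NH3|, |stoich_O2|.
// [[Rcpp::export]]
List microenv_cpp(NumericMatrix c1, NumericMatrix c2, NumericMatrix D1,
                  NumericMatrix D2, NumericMatrix M, NumericMatrix par,
                  LogicalMatrix dirichlet, double b1, double b2, double h,
                  double vox_L, double omega, double tol, int max_sweeps,
                  double conc_floor) {
  const int nr = c1.nrow(), nc = c1.ncol(), nsp = par.nrow();
  const double h2 = h * h;
  NumericMatrix a1 = clone(c1), a2 = clone(c2);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (dirichlet(i, j)) { a1(i, j) = b1; a2(i, j) = b2; }
  // face conductances, precomputed once (D only changes between calls)
  std::vector<double> gx1((size_t)(nr - 1) * nc), gy1((size_t)nr * (nc - 1));
  std::vector<double> gx2((size_t)(nr - 1) * nc), gy2((size_t)nr * (nc - 1));
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr - 1; ++i) {
      gx1[(size_t)j * (nr - 1) + i] = face_g(D1(i, j), D1(i + 1, j), h2);
      gx2[(size_t)j * (nr - 1) + i] = face_g(D2(i, j), D2(i + 1, j), h2);
    }
  for (int j = 0; j < nc - 1; ++j)
    for (int i = 0; i < nr; ++i) {
      gy1[(size_t)j * nr + i] = face_g(D1(i, j), D1(i, j + 1), h2);
      gy2[(size_t)j * nr + i] = face_g(D2(i, j), D2(i, j + 1), h2);
    }
  #define GX1(i, j) gx1[(size_t)(j) * (nr - 1) + (i)]
  #define GY1(i, j) gy1[(size_t)(j) * nr + (i)]
  #define GX2(i, j) gx2[(size_t)(j) * (nr - 1) + (i)]
  #define GY2(i, j) gy2[(size_t)(j) * nr + (i)]
  // uptake of (NH3, O2) in uM/h at a voxel given local concentrations
  auto uptake = [&](int v, double cn, double co, double& U1, double& U2) {
    U1 = 0.0; U2 = 0.0;
    for (int s = 0; s < nsp; ++s) {
      double m = M(v, s);
      if (m <= 0.0) continue;
      double mu = par(s, 0) * cn / (par(s, 1) + cn) * co / (par(s, 2) + co)
                  - par(s, 3);
      if (mu <= 0.0) continue;
      double rn = mu / par(s, 4) * m * 1e-9 / vox_L;  // fmol -> umol
      U1 += par(s, 5) * rn;
      U2 += par(s, 6) * rn;
    }
  };
  double resid = NA_REAL, scale = 1e-10;
  int it = 0;
  bool stagnant = false;
  for (it = 1; it <= max_sweeps; ++it) {
    double dmax = 0.0, cmax = 0.0;
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        if (dirichlet(i, j)) continue;
        const int v = i + nr * j;
        double U1, U2;
        uptake(v, a1(i, j), a2(i, j), U1, U2);
        double k1 = U1 / std::max(a1(i, j), conc_floor);
        double k2 = U2 / std::max(a2(i, j), conc_floor);
        double diag = k1, rhs = 0.0, g;
        if (i > 0)      { g = GX1(i - 1, j); diag += g; rhs += g * a1(i - 1, j); }
        if (i < nr - 1) { g = GX1(i, j);     diag += g; rhs += g * a1(i + 1, j); }
        if (j > 0)      { g = GY1(i, j - 1); diag += g; rhs += g * a1(i, j - 1); }
        if (j < nc - 1) { g = GY1(i, j);     diag += g; rhs += g * a1(i, j + 1); }
        if (diag > 0.0) {
          double cn = (1.0 - omega) * a1(i, j) + omega * rhs / diag;
          if (cn < 0.0) cn = 0.0;
          double d = std::fabs(cn - a1(i, j));
          if (d > dmax) dmax = d;
          if (cn > cmax) cmax = cn;
          a1(i, j) = cn;
        }
        diag = k2; rhs = 0.0;
        if (i > 0)      { g = GX2(i - 1, j); diag += g; rhs += g * a2(i - 1, j); }
        if (i < nr - 1) { g = GX2(i, j);     diag += g; rhs += g * a2(i + 1, j); }
        if (j > 0)      { g = GY2(i, j - 1); diag += g; rhs += g * a2(i, j - 1); }
        if (j < nc - 1) { g = GY2(i, j);     diag += g; rhs += g * a2(i, j + 1); }
        if (diag > 0.0) {
          double cn = (1.0 - omega) * a2(i, j) + omega * rhs / diag;
          if (cn < 0.0) cn = 0.0;
          double d = std::fabs(cn - a2(i, j));
          if (d > dmax) dmax = d;
          if (cn > cmax) cmax = cn;
          a2(i, j) = cn;
        }
      }
    }
    stagnant = (dmax <= 1e-13 * std::max(cmax, 1e-30));
    if (stagnant || it % 8 == 0 || it == max_sweeps) {
      double r = 0.0, s = 1e-10;
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (dirichlet(i, j)) continue;
          const int v = i + nr * j;
          double U1, U2;
          uptake(v, a1(i, j), a2(i, j), U1, U2);
          double flux = 0.0, g;
          if (i > 0)      { g = GX1(i - 1, j); flux += g * (a1(i - 1, j) - a1(i, j)); }
          if (i < nr - 1) { g = GX1(i, j);     flux += g * (a1(i + 1, j) - a1(i, j)); }
          if (j > 0)      { g = GY1(i, j - 1); flux += g * (a1(i, j - 1) - a1(i, j)); }
          if (j < nc - 1) { g = GY1(i, j);     flux += g * (a1(i, j + 1) - a1(i, j)); }
          double res = std::fabs(flux - U1);
          if (U1 > s) s = U1;
          if (res > r) r = res;
          flux = 0.0;
          if (i > 0)      { g = GX2(i - 1, j); flux += g * (a2(i - 1, j) - a2(i, j)); }
          if (i < nr - 1) { g = GX2(i, j);     flux += g * (a2(i + 1, j) - a2(i, j)); }
          if (j > 0)      { g = GY2(i, j - 1); flux += g * (a2(i, j - 1) - a2(i, j)); }
          if (j < nc - 1) { g = GY2(i, j);     flux += g * (a2(i, j + 1) - a2(i, j)); }
          res = std::fabs(flux - U2);
          if (U2 > s) s = U2;
          if (res > r) r = res;
        }
      }
      resid = r; scale = s;
      if (r <= tol * s || stagnant) break;
    }
  }
  #undef GX1
  #undef GY1
  #undef GX2
  #undef GY2
  return List::create(_["c_nh3"] = a1, _["c_o2"] = a2, _["iterations"] = it,
                      _["residual"] = resid, _["scale"] = scale,
                      _["converged"] = (resid <= tol * scale || stagnant));
}
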