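#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Pixel grid convention (shared with the R side): column-major image matrix
// values[nx, ny]; pixel (ix, iy), 0-based here, has linear index ix + nx*iy,
// lower-left corner at (x0 + ix*px, y0 + iy*px) and center half a pixel up.

namespace {

struct Grid {
  int nx, ny;
  double px, x0, y0;
};

// Incremental (Amanatides-Woo) traversal of the segment (x1,y1)-(x2,y2).
// Appends (linear pixel index, intersection length in mm) pairs.
void trace_segment(double x1, double y1, double x2, double y2, const Grid& g,
                   std::vector<int>& out_idx, std::vector<double>& out_len) {
  const double dx = x2 - x1, dy = y2 - y1;
  const double L = std::sqrt(dx * dx + dy * dy);
  if (L <= 0.0) return;
  const double xmax = g.x0 + g.nx * g.px, ymax = g.y0 + g.ny * g.px;
  double tmin = 0.0, tmax = 1.0;
  if (dx != 0.0) {
    double t1 = (g.x0 - x1) / dx, t2 = (xmax - x1) / dx;
    if (t1 > t2) std::swap(t1, t2);
    tmin = std::max(tmin, t1);
    tmax = std::min(tmax, t2);
  } else if (x1 < g.x0 || x1 > xmax) {
    return;
  }
  if (dy != 0.0) {
    double t1 = (g.y0 - y1) / dy, t2 = (ymax - y1) / dy;
    if (t1 > t2) std::swap(t1, t2);
    tmin = std::max(tmin, t1);
    tmax = std::min(tmax, t2);
  } else if (y1 < g.y0 || y1 > ymax) {
    return;
  }
  const double teps = 1e-12;
  if (tmin >= tmax - teps) return;

  // starting pixel from a probe just inside the clipped range
  const double tp = tmin + std::min(1e-9, 0.5 * (tmax - tmin));
  int ix = (int)std::floor((x1 + tp * dx - g.x0) / g.px);
  int iy = (int)std::floor((y1 + tp * dy - g.y0) / g.px);
  ix = std::min(std::max(ix, 0), g.nx - 1);
  iy = std::min(std::max(iy, 0), g.ny - 1);

  const int stepx = (dx > 0.0) - (dx < 0.0);
  const int stepy = (dy > 0.0) - (dy < 0.0);
  const double inf = std::numeric_limits<double>::infinity();
  const double tdx = (dx != 0.0) ? g.px / std::fabs(dx) : inf;
  const double tdy = (dy != 0.0) ? g.px / std::fabs(dy) : inf;
  double tmx = inf, tmy = inf;
  if (stepx != 0) {
    const double xb = g.x0 + (ix + (stepx > 0 ? 1 : 0)) * g.px;
    tmx = (xb - x1) / dx;
  }
  if (stepy != 0) {
    const double yb = g.y0 + (iy + (stepy > 0 ? 1 : 0)) * g.px;
    tmy = (yb - y1) / dy;
  }

  double t = tmin;
  while (t < tmax - teps) {
    const double tnext = std::min(std::min(tmx, tmy), tmax);
    const double len = (tnext - t) * L;
    if (len > 0.0 && ix >= 0 && ix < g.nx && iy >= 0 && iy < g.ny)
      out_idx.push_back(ix + g.nx * iy), out_len.push_back(len);
    if (tnext >= tmax - teps) break;
    if (tmx <= tnext + teps) { ix += stepx; tmx += tdx; }
    if (tmy <= tnext + teps) { iy += stepy; tmy += tdy; }
    t = tnext;
  }
}

inline double phi(double z) { return 0.5 * std::erfc(-z * M_SQRT1_2); }

// Gaussian (or degenerate) TOF factor machinery shared by sensitivity/EM.
// mass of N(u_j, sigma) over [ulo, uhi]; sigma == 0 -> half-open indicator.
inline double tof_mass(double u, double ulo, double uhi, double sigma) {
  if (sigma > 0.0)
    return phi((uhi - u) / sigma) - phi((ulo - u) / sigma);
  return (u >= ulo && u < uhi) ? 1.0 : 0.0;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = "cpp_siddon")]]
List cpp_siddon(double x1, double y1, double x2, double y2, int nx, int ny,
                double px, double x0, double y0) {
  Grid g{nx, ny, px, x0, y0};
  std::vector<int> idx;
  std::vector<double> len;
  trace_segment(x1, y1, x2, y2, g, idx, len);
  return List::create(_["pixel"] = wrap(idx), _["length"] = wrap(len));
}

// Builds the geometric weights for every crystal pair (LOR), in lexicographic
// order (crystal_a major). For one pair the detection probability from pixel j
// is the integral over the uniform (position, angle) emission measure of the
// lines joining the two crystal faces:
//   p(j; pair) = (1/(pi * A_pix)) * Int_{face_a} Int_{face_b}
//                  chord_j(x_a, x_b) * D^2 / ell^3 dx_a dx_b
// with D the panel separation and ell the length of the sampled line; the
// D^2/ell^3 factor is the Jacobian of the (angle, offset) line measure. The
// double integral is evaluated with a tensor Gauss-Legendre rule, each node
// line traced through the grid with Siddon traversal. Entries are sorted by
// the projection u of the pixel center onto the LOR axis (from the midpoint,
// positive toward the bottom crystal).
// [[Rcpp::export(name = "cpp_build_lor_cache", rng = false)]]
List cpp_build_lor_cache(NumericVector ax, NumericVector bx, double H,
                         double pitch, int nx, int ny, double px, double x0,
                         double y0, NumericVector qnode, NumericVector qweight) {
  const int na = ax.size(), nb = bx.size();
  const int nlor = na * nb;
  const int npix = nx * ny;
  const int nq = qnode.size();
  const double D = 2.0 * H;
  Grid g{nx, ny, px, x0, y0};

  std::vector<double> scratch(npix, 0.0);
  std::vector<int> touched;
  std::vector<int> idx_buf;
  std::vector<double> len_buf;

  std::vector<int> all_pix;
  std::vector<double> all_w, all_u;
  IntegerVector offsets(nlor + 1);
  NumericVector mx(nlor), ux(nlor), uy(nlor), halflen(nlor);

  // pre-scale nodes/weights from [-1,1] to the face width
  std::vector<double> off(nq), wq(nq);
  for (int i = 0; i < nq; ++i) {
    off[i] = 0.5 * pitch * qnode[i];
    wq[i] = 0.5 * pitch * qweight[i];
  }

  long long pos = 0;
  for (int a = 0; a < na; ++a) {
    for (int b = 0; b < nb; ++b) {
      const int l = a * nb + b;
      offsets[l] = (int)pos;
      const double xa = ax[a], xb = bx[b];
      const double dxc = xb - xa;
      const double ell0 = std::sqrt(dxc * dxc + D * D);
      mx[l] = 0.5 * (xa + xb);
      ux[l] = dxc / ell0;
      uy[l] = -D / ell0;
      halflen[l] = 0.5 * ell0;

      touched.clear();
      for (int i = 0; i < nq; ++i) {
        for (int j = 0; j < nq; ++j) {
          const double x1 = xa + off[i], x2 = xb + off[j];
          const double dd = x2 - x1;
          const double ell = std::sqrt(dd * dd + D * D);
          const double f = wq[i] * wq[j] * D * D / (ell * ell * ell) /
                           (M_PI * px * px);
          idx_buf.clear();
          len_buf.clear();
          trace_segment(x1, H, x2, -H, g, idx_buf, len_buf);
          for (size_t k = 0; k < idx_buf.size(); ++k) {
            const int p = idx_buf[k];
            if (scratch[p] == 0.0) touched.push_back(p);
            scratch[p] += len_buf[k] * f;
          }
        }
      }
      std::sort(touched.begin(), touched.end());
      for (size_t k = 0; k < touched.size(); ++k) {
        const int p = touched[k];
        const int pix_ix = p % nx, pix_iy = p / nx;
        const double cx_ = x0 + (pix_ix + 0.5) * px;
        const double cy_ = y0 + (pix_iy + 0.5) * px;
        const double u = (cx_ - mx[l]) * ux[l] + cy_ * uy[l];
        all_pix.push_back(p);
        all_w.push_back(scratch[p]);
        all_u.push_back(u);
        scratch[p] = 0.0;
        ++pos;
      }
      // sort this LOR's entries by u for windowed lookups
      const int lo = offsets[l], hi = (int)pos;
      std::vector<int> ord(hi - lo);
      for (int k = 0; k < hi - lo; ++k) ord[k] = k;
      std::sort(ord.begin(), ord.end(), [&](int p1, int p2) {
        return all_u[lo + p1] < all_u[lo + p2];
      });
      std::vector<int> tp(hi - lo);
      std::vector<double> tw(hi - lo), tu(hi - lo);
      for (int k = 0; k < hi - lo; ++k) {
        tp[k] = all_pix[lo + ord[k]];
        tw[k] = all_w[lo + ord[k]];
        tu[k] = all_u[lo + ord[k]];
      }
      std::copy(tp.begin(), tp.end(), all_pix.begin() + lo);
      std::copy(tw.begin(), tw.end(), all_w.begin() + lo);
      std::copy(tu.begin(), tu.end(), all_u.begin() + lo);
    }
  }
  offsets[nlor] = (int)pos;

  return List::create(
      _["offsets"] = offsets, _["pixel"] = wrap(all_pix),
      _["weight"] = wrap(all_w), _["u"] = wrap(all_u), _["mid_x"] = mx,
      _["ux"] = ux, _["uy"] = uy, _["half_length"] = halflen,
      _["n_lor"] = nlor, _["n_pixels"] = npix);
}

// s_j = sum_lor p_geom(j; lor) * [TOF mass of the included time-bin span].
// ulo/uhi give, per LOR, the u-interval covered by the included bins
// (ulo > uhi means the LOR contributes no bins at all).
// [[Rcpp::export(name = "cpp_sensitivity", rng = false)]]
NumericVector cpp_sensitivity(List cache, NumericVector ulo, NumericVector uhi,
                              double sigma_x) {
  IntegerVector offsets = cache["offsets"];
  IntegerVector pix = cache["pixel"];
  NumericVector w = cache["weight"], u = cache["u"];
  const int nlor = cache["n_lor"], npix = cache["n_pixels"];
  NumericVector s(npix);
  for (int l = 0; l < nlor; ++l) {
    if (!(ulo[l] <= uhi[l])) continue;
    const bool full = !R_finite(ulo[l]) && !R_finite(uhi[l]);
    for (int k = offsets[l]; k < offsets[l + 1]; ++k) {
      const double m = full ? 1.0 : tof_mass(u[k], ulo[l], uhi[l], sigma_x);
      s[pix[k]] += w[k] * m;
    }
  }
  return s;
}

namespace {

// one EM pass over events [ev_lo, ev_hi): accumulates the backprojected
// ratio into numer; returns number of skipped (zero-denominator) events.
int em_accumulate(const int* offsets, const int* pix, const double* w,
                  const double* u, const int* lor_idx, const double* ut,
                  int ev_lo, int ev_hi, const double* lambda, double sigma_x,
                  double trunc_nsig, double pitch_proj_scale,
                  const double* uyv, const double* uxv, double px,
                  double* numer) {
  int skipped = 0;
  const double norm = (sigma_x > 0.0) ? 1.0 / (sigma_x * std::sqrt(2.0 * M_PI))
                                      : 0.0;
  for (int e = ev_lo; e < ev_hi; ++e) {
    const int l = lor_idx[e];
    int lo = offsets[l], hi = offsets[l + 1];
    if (lo == hi) { ++skipped; continue; }
    const double u0 = ut[e];
    double hdeg = 0.0;
    if (sigma_x > 0.0) {
      // restrict to |u - u0| <= trunc_nsig * sigma (entries sorted by u)
      const double ulo = u0 - trunc_nsig * sigma_x;
      const double uhi = u0 + trunc_nsig * sigma_x;
      lo = (int)(std::lower_bound(u + lo, u + hi, ulo) - u);
      hi = (int)(std::upper_bound(u + lo, u + hi, uhi) - u);
      if (lo >= hi) { ++skipped; continue; }
    } else {
      // degenerate kernel: indicator over the pixel's projected extent
      hdeg = 0.5 * px * (std::fabs(uxv[l]) + std::fabs(uyv[l]));
    }
    double denom = 0.0;
    for (int k = lo; k < hi; ++k) {
      double gk;
      if (sigma_x > 0.0) {
        const double z = (u[k] - u0) / sigma_x;
        gk = norm * std::exp(-0.5 * z * z);
      } else {
        gk = (u0 >= u[k] - hdeg && u0 < u[k] + hdeg) ? 1.0 / (2.0 * hdeg) : 0.0;
      }
      denom += w[k] * gk * lambda[pix[k]];
    }
    if (!(denom > 0.0)) { ++skipped; continue; }
    for (int k = lo; k < hi; ++k) {
      double gk;
      if (sigma_x > 0.0) {
        const double z = (u[k] - u0) / sigma_x;
        gk = norm * std::exp(-0.5 * z * z);
      } else {
        gk = (u0 >= u[k] - hdeg && u0 < u[k] + hdeg) ? 1.0 / (2.0 * hdeg) : 0.0;
      }
      numer[pix[k]] += w[k] * gk / denom;
    }
  }
  (void)pitch_proj_scale;
  return skipped;
}

}  // namespace

// List-mode OSEM driver. Events are given by 0-based LOR index and TOF
// coordinate u_t = c*dt/2 (mm, from the LOR midpoint toward the bottom
// crystal). subset_bounds are 0-based event offsets, length n_subsets + 1,
// chronologically contiguous. One full iteration = all subsets in order.
// [[Rcpp::export(name = "cpp_osem", rng = false)]]
List cpp_osem(List cache, IntegerVector lor_idx, NumericVector ut,
              NumericVector sens, NumericVector lambda0, int n_iter,
              IntegerVector subset_bounds, double sigma_x, double trunc_nsig,
              double px, bool keep_snapshots) {
  IntegerVector offsets = cache["offsets"];
  IntegerVector pix = cache["pixel"];
  NumericVector w = cache["weight"], u = cache["u"];
  NumericVector uxv = cache["ux"], uyv = cache["uy"];
  const int npix = cache["n_pixels"];
  const int nsub = subset_bounds.size() - 1;

  std::vector<double> lambda(lambda0.begin(), lambda0.end());
  std::vector<double> numer(npix);
  NumericMatrix snaps(keep_snapshots ? npix : 1,
                      keep_snapshots ? n_iter : 1);
  int skipped = 0;

  for (int it = 0; it < n_iter; ++it) {
    for (int sblock = 0; sblock < nsub; ++sblock) {
      std::fill(numer.begin(), numer.end(), 0.0);
      skipped += em_accumulate(
          INTEGER(offsets), INTEGER(pix), REAL(w), REAL(u), INTEGER(lor_idx),
          REAL(ut), subset_bounds[sblock], subset_bounds[sblock + 1],
          lambda.data(), sigma_x, trunc_nsig, 0.0, REAL(uyv), REAL(uxv), px,
          numer.data());
      for (int j = 0; j < npix; ++j)
        lambda[j] = (sens[j] > 0.0) ? lambda[j] * numer[j] / sens[j] : 0.0;
    }
    if (keep_snapshots)
      for (int j = 0; j < npix; ++j) snaps(j, it) = lambda[j];
    Rcpp::checkUserInterrupt();
  }

  return List::create(_["image"] = wrap(lambda), _["skipped"] = skipped,
                      _["snapshots"] = snaps);
}

// Single EM block update (one sub-iteration on the given events).
// [[Rcpp::export(name = "cpp_em_block", rng = false)]]
List cpp_em_block(List cache, IntegerVector lor_idx, NumericVector ut,
                  NumericVector sens, NumericVector lambda0, double sigma_x,
                  double trunc_nsig, double px) {
  IntegerVector offsets = cache["offsets"];
  IntegerVector pix = cache["pixel"];
  NumericVector w = cache["weight"], u = cache["u"];
  NumericVector uxv = cache["ux"], uyv = cache["uy"];
  const int npix = cache["n_pixels"];
  std::vector<double> numer(npix, 0.0);
  const int skipped = em_accumulate(
      INTEGER(offsets), INTEGER(pix), REAL(w), REAL(u), INTEGER(lor_idx),
      REAL(ut), 0, lor_idx.size(), REAL(lambda0), sigma_x, trunc_nsig, 0.0,
      REAL(uyv), REAL(uxv), px, numer.data());
  NumericVector out(npix);
  for (int j = 0; j < npix; ++j)
    out[j] = (sens[j] > 0.0) ? lambda0[j] * numer[j] / sens[j] : 0.0;
  return List::create(_["image"] = out, _["skipped"] = skipped);
}

// Poisson list-mode log-likelihood: sum_k log(sum_j p_k(j) lambda_j)
//                                   - sum_j s_j lambda_j
// [[Rcpp::export(name = "cpp_loglik", rng = false)]]
List cpp_loglik(List cache, IntegerVector lor_idx, NumericVector ut,
                NumericVector sens, NumericVector lambda, double sigma_x,
                double trunc_nsig, double px) {
  IntegerVector offsets = cache["offsets"];
  IntegerVector pix = cache["pixel"];
  NumericVector w = cache["weight"], u = cache["u"];
  NumericVector uxv = cache["ux"], uyv = cache["uy"];
  const int npix = cache["n_pixels"];
  const int nev = lor_idx.size();
  const double norm = (sigma_x > 0.0) ? 1.0 / (sigma_x * std::sqrt(2.0 * M_PI))
                                      : 0.0;
  double ll = 0.0;
  int first_zero = -1;
  for (int e = 0; e < nev; ++e) {
    const int l = lor_idx[e];
    int lo = offsets[l], hi = offsets[l + 1];
    const double u0 = ut[e];
    double hdeg = 0.0;
    if (sigma_x > 0.0) {
      const double ulo = u0 - trunc_nsig * sigma_x;
      const double uhi = u0 + trunc_nsig * sigma_x;
      lo = (int)(std::lower_bound(u.begin() + lo, u.begin() + hi, ulo) -
                 u.begin());
      hi = (int)(std::upper_bound(u.begin() + lo, u.begin() + hi, uhi) -
                 u.begin());
    } else {
      hdeg = 0.5 * px * (std::fabs(uxv[l]) + std::fabs(uyv[l]));
    }
    double denom = 0.0;
    for (int k = lo; k < hi; ++k) {
      double gk;
      if (sigma_x > 0.0) {
        const double z = (u[k] - u0) / sigma_x;
        gk = norm * std::exp(-0.5 * z * z);
      } else {
        gk = (u0 >= u[k] - hdeg && u0 < u[k] + hdeg) ? 1.0 / (2.0 * hdeg) : 0.0;
      }
      denom += w[k] * gk * lambda[pix[k]];
    }
    if (denom > 0.0) {
      ll += std::log(denom);
    } else {
      ll = R_NegInf;
      if (first_zero < 0) first_zero = e + 1;  // 1-based for R
    }
  }
  double pen = 0.0;
  for (int j = 0; j < npix; ++j) pen += sens[j] * lambda[j];
  return List::create(_["loglik"] = ll - pen, _["first_zero_event"] = first_zero);
}

// Brute-force Monte Carlo estimate of the per-(pixel, crystal-pair) detection
// probability: uniform decay positions in each pixel, uniform emission angle
// on [0, pi), both anti-parallel photons traced to the panel faces.
// Returns an (n_pixels x n_pairs) matrix of hits / n_decays_per_pixel.
// [[Rcpp::export(name = "cpp_mc_oracle")]]
NumericMatrix cpp_mc_oracle(int n_crystals, double pitch, double H, int nx,
                            int ny, double px, double x0, double y0,
                            double n_per_pixel) {
  const double L2 = 0.5 * n_crystals * pitch;
  const int npix = nx * ny, npair = n_crystals * n_crystals;
  NumericMatrix out(npix, npair);
  const long long n = (long long)n_per_pixel;
  for (int iy = 0; iy < ny; ++iy) {
    for (int ix = 0; ix < nx; ++ix) {
      const int j = ix + nx * iy;
      for (long long d = 0; d < n; ++d) {
        const double x = x0 + (ix + unif_rand()) * px;
        const double y = y0 + (iy + unif_rand()) * px;
        const double th = M_PI * unif_rand();
        const double s = std::sin(th);
        if (s <= 0.0) continue;
        const double cot = std::cos(th) / s;
        const double xt = x + (H - y) * cot;
        if (xt < -L2 || xt >= L2) continue;
        const double xb = x - (H + y) * cot;
        if (xb < -L2 || xb >= L2) continue;
        const int ka = (int)std::floor((xt + L2) / pitch);
        const int kb = (int)std::floor((xb + L2) / pitch);
        out(j, ka * n_crystals + kb) += 1.0;
      }
      Rcpp::checkUserInterrupt();
    }
  }
  for (int j = 0; j < npix; ++j)
    for (int p = 0; p < npair; ++p) out(j, p) /= (double)n;
  return out;
}
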