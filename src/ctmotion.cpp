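#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Column-major linear index for a voxel (i,j,k), 0-based.
static inline R_xlen_t lin(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

struct Affine {
  double m[3][4];
  explicit Affine(const NumericMatrix& M) {
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 4; ++c) m[r][c] = M(r, c);
  }
  inline void apply(double x, double y, double z,
                    double& ox, double& oy, double& oz) const {
    ox = m[0][0]*x + m[0][1]*y + m[0][2]*z + m[0][3];
    oy = m[1][0]*x + m[1][1]*y + m[1][2]*z + m[1][3];
    oz = m[2][0]*x + m[2][1]*y + m[2][2]*z + m[2][3];
  }
};

// Smooth occupancy from a signed distance (mm): emulates the scanner's
// finite resolution with a logistic edge profile of 10-90% width ~ `w` mm.
// Evaluated in each structure's local frame, so the profile is rigidly
// attached to the geometry and identical at both time points.
static inline double occ(double d, double inv_w) {
  double t = 4.0 * d * inv_w;
  if (t > 12.0) return 0.0;
  if (t < -12.0) return 1.0;
  return 1.0 / (1.0 + std::exp(t));
}

// Voxelize the tibia + tibial-tray phantom by supersampled analytic
// evaluation of each voxel. All geometry is evaluated in the local frame
// of each structure; `inv_bone` / `inv_implant` map world points into those
// frames, so arbitrary rigid repositioning and implant micromotion are exact
// (never a resampling of a previously voxelized grid). Edges use a smooth
// PSF-like profile (edge_mm), which keeps the partial-volume signal free of
// orientation-dependent quantization bias.
//
// bone_par:    outer_radius, shell_thickness, length, taper_ratio,
//              lobe_amplitude, lobe_freq, lobe_phase
// implant_par: tray_radius_ml, tray_radius_ap, tray_thickness, stem_radius,
//              stem_length, fin_count, fin_length, fin_extent,
//              fin_half_thickness
// hu:          background, trabecular, cortical, implant
// scatter_par: enabled, band_mm, amp_frac, angular_freq, phase,
//              tray_radius_ml, tray_radius_ap
// [[Rcpp::export]]
NumericVector cpp_voxelize_phantom(IntegerVector dims, NumericVector spacing,
                                   NumericVector origin, int supersample,
                                   NumericVector bone_par,
                                   NumericVector implant_par,
                                   NumericVector hu,
                                   NumericMatrix inv_bone,
                                   NumericMatrix inv_implant,
                                   NumericVector scatter_par,
                                   double edge_mm) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const Affine Mb(inv_bone), Mi(inv_implant);

  const double b_rout = bone_par[0], b_shell = bone_par[1];
  const double b_len = bone_par[2], b_taper = bone_par[3];
  const double b_lobe_amp = bone_par[4];
  const double b_lobe_freq = bone_par[5], b_lobe_phase = bone_par[6];
  const double tray_rml = implant_par[0], tray_rap = implant_par[1];
  const double tray_th = implant_par[2];
  const double stem_r = implant_par[3], stem_len = implant_par[4];
  const int fin_n = (int)implant_par[5];
  const double fin_len = implant_par[6], fin_ext = implant_par[7];
  const double fin_half = implant_par[8];
  const double hu_bg = hu[0], hu_trab = hu[1], hu_cort = hu[2], hu_imp = hu[3];
  const bool sc_on = scatter_par[0] != 0;
  const double sc_band = scatter_par[1], sc_amp = scatter_par[2];
  const double sc_freq = scatter_par[3], sc_phase = scatter_par[4];
  const double sc_rml = scatter_par[5], sc_rap = scatter_par[6];

  std::vector<double> fin_c(fin_n), fin_s(fin_n);
  for (int f = 0; f < fin_n; ++f) {
    double a = 2.0 * M_PI * f / std::max(fin_n, 1);
    fin_c[f] = std::cos(a);
    fin_s[f] = std::sin(a);
  }

  const int ss = supersample;
  std::vector<double> offx(ss), offy(ss), offz(ss);
  for (int s = 0; s < ss; ++s) {
    double u = ((s + 0.5) / ss) - 0.5;
    offx[s] = u * dx; offy[s] = u * dy; offz[s] = u * dz;
  }
  const double inv_nss = 1.0 / (double)(ss * ss * ss);
  const double inv_w = 1.0 / edge_mm;

  NumericVector out((R_xlen_t)nx * ny * nz);
  double* o = REAL(out);

  for (int k = 0; k < nz; ++k) {
    double wz0 = oz + k * dz;
    for (int j = 0; j < ny; ++j) {
      double wy0 = oy + j * dy;
      for (int i = 0; i < nx; ++i) {
        double wx0 = ox + i * dx;
        double acc = 0.0;
        for (int sz = 0; sz < ss; ++sz) {
          double wz = wz0 + offz[sz];
          for (int sy = 0; sy < ss; ++sy) {
            double wy = wy0 + offy[sy];
            for (int sx = 0; sx < ss; ++sx) {
              double wx = wx0 + offx[sx];
              // signed distance to the implant (union of plate, stem, fins)
              double px, py, pz;
              Mi.apply(wx, wy, wz, px, py, pz);
              double r2 = px * px + pz * pz;
              double r = std::sqrt(r2);
              // elliptical plate: tibial trays are wider ML than AP;
              // radial distance normalized by the local gradient of the
              // ellipse level function
              double ex = px / tray_rml, ez = pz / tray_rap;
              double e = std::sqrt(ex * ex + ez * ez);
              double ge = std::sqrt(ex * ex / (tray_rml * tray_rml) +
                                    ez * ez / (tray_rap * tray_rap));
              double dr_plate = (ge > 1e-12) ? (e - 1.0) * e / ge
                                             : -std::min(tray_rml, tray_rap);
              double dy_plate = std::max(-py, py - tray_th);
              double d_imp = std::max(dr_plate, dy_plate);
              // stem (welded to the plate: extends into the plate interior
              // so the shared face is not a spurious metal-air edge)
              double d_stem = std::max(r - stem_r,
                                       std::max(py - tray_th, -stem_len - py));
              d_imp = std::min(d_imp, d_stem);
              // fins (likewise welded to the plate underside)
              if (fin_n > 0 && py < tray_th + 0.5 && py > -fin_len - 0.5) {
                double lim = stem_r + fin_ext;
                if (r2 <= (lim + 1.0) * (lim + 1.0)) {
                  for (int f = 0; f < fin_n; ++f) {
                    double u = px * fin_c[f] + pz * fin_s[f];
                    double v = -px * fin_s[f] + pz * fin_c[f];
                    double d_fin = std::fabs(v) - fin_half;
                    d_fin = std::max(d_fin, r - lim);
                    d_fin = std::max(d_fin, -u);
                    d_fin = std::max(d_fin, std::max(py - tray_th,
                                                     -fin_len - py));
                    d_imp = std::min(d_imp, d_fin);
                  }
                }
              }
              double o_imp = occ(d_imp, inv_w);

              // bone: lobed tapered cylinder with a cortical shell
              double bx, by, bz;
              Mb.apply(wx, wy, wz, bx, by, bz);
              double val = hu_bg;
              double rr2 = bx * bx + bz * bz;
              double r_lim = b_rout * (1.0 + b_lobe_amp) + 4.0 * edge_mm;
              if (by > -4.0 * edge_mm && by < b_len + 4.0 * edge_mm &&
                  rr2 < r_lim * r_lim) {
                double rr = std::sqrt(rr2);
                double rout = b_rout * (b_taper + (1.0 - b_taper) *
                                        std::min(std::max(by, 0.0), b_len) / b_len);
                if (b_lobe_amp > 0.0) {
                  // tibia-like lobed cross-section (not rotationally symmetric)
                  rout *= 1.0 + b_lobe_amp *
                    std::cos(b_lobe_freq * std::atan2(bz, bx) + b_lobe_phase);
                }
                double dy_b = std::max(-by, by - b_len);
                double d_out = std::max(rr - rout, dy_b);
                double d_in = std::max(rr - (rout - b_shell), dy_b);
                double o_out = occ(d_out, inv_w);
                double o_in = occ(d_in, inv_w);
                val = hu_bg + o_out * (hu_cort - hu_bg) +
                      o_in * (hu_trab - hu_cort);
              }
              // scatter band directly distal to the tray plate
              if (sc_on && py < 0.0 && py >= -sc_band &&
                  (px / sc_rml) * (px / sc_rml) +
                  (pz / sc_rap) * (pz / sc_rap) <= 1.0) {
                val *= 1.0 + sc_amp * std::cos(sc_freq * std::atan2(pz, px) + sc_phase);
              }
              // metal replaces whatever tissue it occupies
              acc += o_imp * hu_imp + (1.0 - o_imp) * val;
            }
          }
        }
        o[lin(i, j, k, nx, ny)] = acc * inv_nss;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Normalized cross-correlation between `fvals` and `vol` sampled with
// trilinear interpolation at A %*% c(p,1) for each world point p (A is the
// 3x4 world-to-continuous-index map of the candidate transform composed with
// the moving volume's geometry). Returns c(ncc, oob_frac). Out-of-bounds
// samples are excluded from both series.
// [[Rcpp::export]]
NumericVector cpp_ncc_affine(NumericVector fvals, NumericVector vol,
                             IntegerVector dims, NumericMatrix pts,
                             NumericMatrix A) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = pts.nrow();
  const double* v = REAL(vol);
  const Affine M(A);
  double sf = 0, sm = 0, sff = 0, smm = 0, sfm = 0;
  R_xlen_t cnt = 0;
  for (R_xlen_t p = 0; p < n; ++p) {
    double x, y, z;
    M.apply(pts(p, 0), pts(p, 1), pts(p, 2), x, y, z);
    if (x < 0.0 || y < 0.0 || z < 0.0 ||
        x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0) continue;
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 >= nx - 1) i0 = nx - 2;
    if (j0 >= ny - 1) j0 = ny - 2;
    if (k0 >= nz - 1) k0 = nz - 2;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    double c000 = v[lin(i0, j0, k0, nx, ny)], c100 = v[lin(i0+1, j0, k0, nx, ny)];
    double c010 = v[lin(i0, j0+1, k0, nx, ny)], c110 = v[lin(i0+1, j0+1, k0, nx, ny)];
    double c001 = v[lin(i0, j0, k0+1, nx, ny)], c101 = v[lin(i0+1, j0, k0+1, nx, ny)];
    double c011 = v[lin(i0, j0+1, k0+1, nx, ny)], c111 = v[lin(i0+1, j0+1, k0+1, nx, ny)];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double m = (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
               (c01 * (1 - fy) + c11 * fy) * fz;
    double f = fvals[p];
    sf += f; sm += m; sff += f * f; smm += m * m; sfm += f * m;
    ++cnt;
  }
  if (cnt == 0)
    return NumericVector::create(NA_REAL, 1.0);
  double mf = sf / cnt, mm = sm / cnt;
  double vf = sff - cnt * mf * mf, vm = smm - cnt * mm * mm;
  double cov = sfm - cnt * mf * mm;
  double den = std::sqrt(vf * vm);
  double ncc = (den > 0) ? cov / den : 0.0;
  return NumericVector::create(ncc, 1.0 - (double)cnt / (double)n);
}

// Trilinear interpolation of `vol` at continuous 0-based voxel coordinates
// `pts` (n x 3). Returns sampled values and an in-bounds flag per point;
// out-of-bounds samples get NA.
// [[Rcpp::export]]
List cpp_sample_trilinear(NumericVector vol, IntegerVector dims,
                          NumericMatrix pts) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = pts.nrow();
  const double* v = REAL(vol);
  NumericVector val(n);
  LogicalVector inb(n);
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (x < 0.0 || y < 0.0 || z < 0.0 ||
        x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0) {
      val[p] = NA_REAL; inb[p] = false; continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 >= nx - 1) i0 = nx - 2;
    if (j0 >= ny - 1) j0 = ny - 2;
    if (k0 >= nz - 1) k0 = nz - 2;
    if (i0 < 0) i0 = 0;
    if (j0 < 0) j0 = 0;
    if (k0 < 0) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    double c000 = v[lin(i0, j0, k0, nx, ny)], c100 = v[lin(i0+1, j0, k0, nx, ny)];
    double c010 = v[lin(i0, j0+1, k0, nx, ny)], c110 = v[lin(i0+1, j0+1, k0, nx, ny)];
    double c001 = v[lin(i0, j0, k0+1, nx, ny)], c101 = v[lin(i0+1, j0, k0+1, nx, ny)];
    double c011 = v[lin(i0, j0+1, k0+1, nx, ny)], c111 = v[lin(i0+1, j0+1, k0+1, nx, ny)];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    val[p] = c0 * (1 - fz) + c1 * fz;
    inb[p] = true;
  }
  return List::create(_["values"] = val, _["inbounds"] = inb);
}

// Retain the 26-connected components of `mask` that contain at least one
// seed. Seeds are 0-based voxel indices (n x 3).
// [[Rcpp::export]]
LogicalVector cpp_flood26(LogicalVector mask, IntegerVector dims,
                          IntegerMatrix seeds) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);
  std::vector<char> visited((size_t)nx * ny * nz, 0);
  std::queue<R_xlen_t> q;
  for (int s = 0; s < seeds.nrow(); ++s) {
    R_xlen_t idx = lin(seeds(s, 0), seeds(s, 1), seeds(s, 2), nx, ny);
    if (mask[idx] && !visited[idx]) { visited[idx] = 1; q.push(idx); }
  }
  while (!q.empty()) {
    R_xlen_t idx = q.front(); q.pop();
    out[idx] = true;
    int i = (int)(idx % nx);
    int j = (int)((idx / nx) % ny);
    int k = (int)(idx / ((R_xlen_t)nx * ny));
    for (int dk = -1; dk <= 1; ++dk) {
      int kk = k + dk;
      if (kk < 0 || kk >= nz) continue;
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = j + dj;
        if (jj < 0 || jj >= ny) continue;
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0 && dk == 0) continue;
          int ii = i + di;
          if (ii < 0 || ii >= nx) continue;
          R_xlen_t nidx = lin(ii, jj, kk, nx, ny);
          if (mask[nidx] && !visited[nidx]) { visited[nidx] = 1; q.push(nidx); }
        }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Largest 26-connected component of a binary mask.
// [[Rcpp::export]]
LogicalVector cpp_largest_component(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> label(n, 0);
  int next_label = 0;
  R_xlen_t best_size = 0;
  int best_label = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || label[start]) continue;
    ++next_label;
    R_xlen_t size = 0;
    label[start] = next_label;
    q.push(start);
    while (!q.empty()) {
      R_xlen_t idx = q.front(); q.pop();
      ++size;
      int i = (int)(idx % nx);
      int j = (int)((idx / nx) % ny);
      int k = (int)(idx / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk;
        if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj;
          if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int ii = i + di;
            if (ii < 0 || ii >= nx) continue;
            R_xlen_t nidx = lin(ii, jj, kk, nx, ny);
            if (mask[nidx] && !label[nidx]) {
              label[nidx] = next_label;
              q.push(nidx);
            }
          }
        }
      }
    }
    if (size > best_size) { best_size = size; best_label = next_label; }
  }
  LogicalVector out(n);
  for (R_xlen_t idx = 0; idx < n; ++idx)
    out[idx] = label[idx] == best_label && best_label > 0;
  out.attr("dim") = dims;
  return out;
}

// Binary erosion/dilation with an arbitrary offset list (n x 3, voxel units).
// Outside the grid counts as background.
// [[Rcpp::export]]
LogicalVector cpp_morph(LogicalVector mask, IntegerVector dims,
                        IntegerMatrix offsets, bool erode) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int no = offsets.nrow();
  LogicalVector out((R_xlen_t)nx * ny * nz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        bool acc = erode;
        for (int t = 0; t < no; ++t) {
          int ii = i + offsets(t, 0), jj = j + offsets(t, 1), kk = k + offsets(t, 2);
          bool inside = ii >= 0 && ii < nx && jj >= 0 && jj < ny && kk >= 0 && kk < nz;
          bool m = inside ? (bool)mask[lin(ii, jj, kk, nx, ny)] : false;
          if (erode) {
            if (!m) { acc = false; break; }
          } else {
            if (m) { acc = true; break; }
          }
        }
        out[lin(i, j, k, nx, ny)] = acc;
      }
  out.attr("dim") = dims;
  return out;
}

// 6-connectivity boundary: mask voxels with at least one face neighbour that
// is background or outside the grid.
// [[Rcpp::export]]
LogicalVector cpp_boundary6(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);
  const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = lin(i, j, k, nx, ny);
        if (!mask[idx]) continue;
        bool bdry = false;
        for (int t = 0; t < 6; ++t) {
          int ii = i + off[t][0], jj = j + off[t][1], kk = k + off[t][2];
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz ||
              !mask[lin(ii, jj, kk, nx, ny)]) { bdry = true; break; }
        }
        out[idx] = bdry;
      }
  out.attr("dim") = dims;
  return out;
}

// Separable Gaussian smoothing, kernel truncated at 3 sigma, renormalized at
// the edges (zero-gradient behaviour). sigma in voxels per axis; 0 skips.
// [[Rcpp::export]]
NumericVector cpp_smooth_gauss(NumericVector vol, IntegerVector dims,
                               NumericVector sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector cur = clone(vol);
  const int n[3] = {nx, ny, nz};
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0.0) continue;
    int rad = (int)std::ceil(3.0 * s);
    std::vector<double> kern(2 * rad + 1);
    double ksum = 0.0;
    for (int t = -rad; t <= rad; ++t) {
      kern[t + rad] = std::exp(-0.5 * t * t / (s * s));
      ksum += kern[t + rad];
    }
    for (double& kv : kern) kv /= ksum;
    NumericVector nxt((R_xlen_t)nx * ny * nz);
    const double* src = REAL(cur);
    double* dst = REAL(nxt);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int pos[3] = {i, j, k};
          double acc = 0.0, wsum = 0.0;
          for (int t = -rad; t <= rad; ++t) {
            int q = pos[axis] + t;
            if (q < 0 || q >= n[axis]) continue;
            int p2[3] = {i, j, k};
            p2[axis] = q;
            acc += kern[t + rad] * src[lin(p2[0], p2[1], p2[2], nx, ny)];
            wsum += kern[t + rad];
          }
          dst[lin(i, j, k, nx, ny)] = acc / wsum;
        }
    cur = nxt;
  }
  cur.attr("dim") = dims;
  return cur;
}
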