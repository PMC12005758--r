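// Compiled core of the bioassembly simulator: tabulated axisymmetric
// magnet field, cell-grid contact detection, overdamped mobility solve by
// preconditioned conjugate gradients, semi-implicit position update.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Bulirsch's generalized complete elliptic integral cel(kc, p, a, b)
static double cel(double kc, double p, double a, double b) {
  if (kc == 0.0) return NA_REAL;
  const double errtol = 1e-12;
  double k = std::fabs(kc), pp = p, aa = a, bb = b, em = 1.0;
  if (p > 0) {
    pp = std::sqrt(p);
    bb = b / pp;
  } else {
    double f = kc * kc, q = 1.0 - f, g = 1.0 - pp;
    f -= pp;
    q *= (b - a * pp);
    pp = std::sqrt(f / g);
    aa = (a - b) / g;
    bb = -q / (g * g * pp) + aa * pp;
  }
  double f = aa;
  aa += bb / pp;
  double g = k / pp;
  bb = 2.0 * (bb + f * g);
  pp += g;
  g = em;
  em += k;
  double kk = k;
  while (std::fabs(g - k) > g * errtol) {
    k = 2.0 * std::sqrt(kk);
    kk = k * em;
    f = aa;
    aa += bb / pp;
    g = kk / pp;
    bb = 2.0 * (bb + f * g);
    pp += g;
    g = em;
    em += k;
  }
  return (M_PI / 2.0) * (bb + aa * em) / (em * (em + pp));
}

// (B_rho, B_z) of an axially magnetized cylinder, magnet frame
static void cylB(double rho, double z, double a, double hb, double Br,
                 double* Brho, double* Bz) {
  rho = std::fabs(rho);
  double zp = z + hb, zm = z - hb;
  double rp = std::sqrt(zp * zp + (rho + a) * (rho + a));
  double rm = std::sqrt(zm * zm + (rho + a) * (rho + a));
  double gam = (a - rho) / (a + rho);
  double kp = std::sqrt(zp * zp + (a - rho) * (a - rho)) / rp;
  double km = std::sqrt(zm * zm + (a - rho) * (a - rho)) / rm;
  double B0 = Br / M_PI;
  *Brho = B0 * ((a / rp) * cel(kp, 1.0, 1.0, -1.0) -
                (a / rm) * cel(km, 1.0, 1.0, -1.0));
  *Bz = B0 * a / (a + rho) *
        ((zp / rp) * cel(kp, gam * gam, 1.0, gam) -
         (zm / rm) * cel(km, gam * gam, 1.0, gam));
}

static double normB2(double rho, double z, double a, double hb, double Br) {
  double br, bz;
  cylB(rho, z, a, hb, Br, &br, &bz);
  return br * br + bz * bz;
}

// Precompute |H| and 0.5*grad|H|^2 (rho and z components) on a regular
// (rho, z) grid in well coordinates; magnet centre on the axis at z_center.
// [[Rcpp::export]]
List cpp_field_table(double a, double hb, double Br, double mu0,
                     double V_NP, double M_NP, double rho_max,
                     double z_min, double z_max, int nr, int nz,
                     double z_center) {
  NumericMatrix Hmag(nr, nz), Gr(nr, nz), Gz(nr, nz);
  double drho = rho_max / (nr - 1);
  double dz = (z_max - z_min) / (nz - 1);
  double h = 1e-7;  // finite-difference step (m)
  for (int i = 0; i < nr; ++i) {
    double rho = i * drho;
    for (int j = 0; j < nz; ++j) {
      double z = z_min + j * dz - z_center;  // magnet frame
      if (Br == 0.0) continue;
      double br, bz;
      cylB(rho, z, a, hb, Br, &br, &bz);
      Hmag(i, j) = std::sqrt(br * br + bz * bz) / mu0;
      double dUr = (normB2(rho + h, z, a, hb, Br) -
                    normB2(rho - h, z, a, hb, Br)) / (2 * h);
      double dUz = (normB2(rho, z + h, a, hb, Br) -
                    normB2(rho, z - h, a, hb, Br)) / (2 * h);
      Gr(i, j) = 0.5 * dUr / (mu0 * mu0);
      Gz(i, j) = 0.5 * dUz / (mu0 * mu0);
    }
  }
  return List::create(_["Hmag"] = Hmag, _["Gr"] = Gr, _["Gz"] = Gz,
                      _["rho_max"] = rho_max, _["z_min"] = z_min,
                      _["z_max"] = z_max, _["nr"] = nr, _["nz"] = nz,
                      _["mu0"] = mu0, _["V_NP"] = V_NP, _["M_NP"] = M_NP,
                      _["Br"] = Br);
}

struct FieldTab {
  const double *Hmag, *Gr, *Gz;
  double rho_max, z_min, z_max, drho, dz, mu0, V_NP, M_NP, Br;
  int nr, nz;
};

static FieldTab unpack_table(const List& tab) {
  FieldTab t;
  NumericMatrix H = tab["Hmag"], Gr = tab["Gr"], Gz = tab["Gz"];
  t.Hmag = H.begin();
  t.Gr = Gr.begin();
  t.Gz = Gz.begin();
  t.rho_max = tab["rho_max"];
  t.z_min = tab["z_min"];
  t.z_max = tab["z_max"];
  t.nr = tab["nr"];
  t.nz = tab["nz"];
  t.mu0 = tab["mu0"];
  t.V_NP = tab["V_NP"];
  t.M_NP = tab["M_NP"];
  t.Br = tab["Br"];
  t.drho = t.rho_max / (t.nr - 1);
  t.dz = (t.z_max - t.z_min) / (t.nz - 1);
  return t;
}

// bilinear interpolation of the three tabulated fields at (rho, z)
static inline void tab_eval(const FieldTab& t, double rho, double z,
                            double* Hm, double* gr, double* gz) {
  if (t.Br == 0.0) { *Hm = 0; *gr = 0; *gz = 0; return; }
  double fr = rho / t.drho, fz = (z - t.z_min) / t.dz;
  int i = (int)std::floor(fr), j = (int)std::floor(fz);
  if (i < 0) i = 0;
  if (j < 0) j = 0;
  if (i > t.nr - 2) i = t.nr - 2;
  if (j > t.nz - 2) j = t.nz - 2;
  double u = fr - i, v = fz - j;
  u = std::min(std::max(u, 0.0), 1.0);
  v = std::min(std::max(v, 0.0), 1.0);
  int idx00 = i + t.nr * j, idx10 = idx00 + 1;
  int idx01 = idx00 + t.nr, idx11 = idx01 + 1;
  double w00 = (1 - u) * (1 - v), w10 = u * (1 - v);
  double w01 = (1 - u) * v, w11 = u * v;
  *Hm = w00 * t.Hmag[idx00] + w10 * t.Hmag[idx10] +
        w01 * t.Hmag[idx01] + w11 * t.Hmag[idx11];
  *gr = w00 * t.Gr[idx00] + w10 * t.Gr[idx10] +
        w01 * t.Gr[idx01] + w11 * t.Gr[idx11];
  *gz = w00 * t.Gz[idx00] + w10 * t.Gz[idx10] +
        w01 * t.Gz[idx01] + w11 * t.Gz[idx11];
}

// per-NP force at a lab point from the table:
// F = mu0 V f(|H|) * 0.5 grad|H|^2,  f = 3 below M/3 else M/|H|
static inline void np_force_at(const FieldTab& t, double x, double y,
                               double z, double* fx, double* fy,
                               double* fz) {
  double rho = std::sqrt(x * x + y * y);
  double Hm, gr, gz;
  tab_eval(t, rho, z, &Hm, &gr, &gz);
  double f = (Hm < t.M_NP / 3.0) ? 3.0
                                 : t.M_NP / std::max(Hm, 1e-300);
  double s = t.mu0 * t.V_NP * f;
  double rx = (rho > 0) ? x / rho : 0.0, ry = (rho > 0) ? y / rho : 0.0;
  *fx = s * gr * rx;
  *fy = s * gr * ry;
  *fz = s * gz;
}

// [[Rcpp::export]]
NumericMatrix cpp_field_np_force(List tab, NumericMatrix pts) {
  FieldTab t = unpack_table(tab);
  int n = pts.nrow();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double fx, fy, fz;
    np_force_at(t, pts(i, 0), pts(i, 1), pts(i, 2), &fx, &fy, &fz);
    out(i, 0) = fx;
    out(i, 1) = fy;
    out(i, 2) = fz;
  }
  return out;
}

struct Contact {
  int i, j;          // j = -1 for wall
  double nx, ny, nz; // unit normal (from j toward i / wall into well)
  double S;          // contact area
  double k;          // Hertz stiffness dF/ddelta
  double fx, fy, fz; // Hertz force on i
};

struct Params {
  double dt, eta_m, rho_s, rho_m, g, c_t, c_n, E_sph, E_well;
  double well_radius, floor_z, lam, D, cg_tol;
};

struct CellEntry {
  int64_t key;
  int idx;
};

// sorted-cell-list contact detection; entries buffer reused across steps
static void find_contacts(const std::vector<double>& x,
                          const std::vector<double>& y,
                          const std::vector<double>& z,
                          const std::vector<double>& r, const Params& pp,
                          std::vector<CellEntry>& entries,
                          std::vector<Contact>& out) {
  out.clear();
  int n = (int)r.size();
  double rmax = 0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, r[i]);
  double cellsz = 2.0 * rmax;
  auto keyof = [&](double cx, double cy, double cz) {
    int64_t ix = (int64_t)std::floor(cx / cellsz) + (1 << 20);
    int64_t iy = (int64_t)std::floor(cy / cellsz) + (1 << 20);
    int64_t iz = (int64_t)std::floor(cz / cellsz) + (1 << 20);
    return (ix << 42) | (iy << 21) | iz;
  };
  entries.resize(n);
  for (int i = 0; i < n; ++i) entries[i] = {keyof(x[i], y[i], z[i]), i};
  std::sort(entries.begin(), entries.end(),
            [](const CellEntry& a, const CellEntry& b) {
              return a.key < b.key;
            });
  double E_ss = 1.0 / (2.0 * 0.75 / pp.E_sph);
  double E_sw = 1.0 / (0.75 / pp.E_sph + 0.75 / pp.E_well);
  for (int i = 0; i < n; ++i) {
    int64_t ix = (int64_t)std::floor(x[i] / cellsz) + (1 << 20);
    int64_t iy = (int64_t)std::floor(y[i] / cellsz) + (1 << 20);
    int64_t iz = (int64_t)std::floor(z[i] / cellsz) + (1 << 20);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          int64_t key = ((ix + dx) << 42) | ((iy + dy) << 21) | (iz + dz);
          auto lo = std::lower_bound(
              entries.begin(), entries.end(), key,
              [](const CellEntry& e, int64_t k) { return e.key < k; });
          for (auto it = lo; it != entries.end() && it->key == key; ++it) {
            int j = it->idx;
            if (j <= i) continue;
            double ddx = x[i] - x[j], ddy = y[i] - y[j], ddz = z[i] - z[j];
            double dist2 = ddx * ddx + ddy * ddy + ddz * ddz;
            double sum = r[i] + r[j];
            if (dist2 >= sum * sum || dist2 == 0.0) continue;
            double dist = std::sqrt(dist2);
            double delta = sum - dist;
            Contact c;
            c.i = i;
            c.j = j;
            c.nx = ddx / dist;
            c.ny = ddy / dist;
            c.nz = ddz / dist;
            double reff = r[i] * r[j] / sum;
            c.S = M_PI * delta * reff;
            double sq = std::sqrt(reff * delta);
            double fmag = 4.0 / 3.0 * E_ss * sq * delta;
            c.k = 2.0 * E_ss * sq;
            c.fx = fmag * c.nx;
            c.fy = fmag * c.ny;
            c.fz = fmag * c.nz;
            out.push_back(c);
          }
        }
    // floor contact
    double dfl = r[i] - (z[i] - pp.floor_z);
    if (dfl >= 0) {
      Contact c;
      c.i = i;
      c.j = -1;
      c.nx = 0;
      c.ny = 0;
      c.nz = 1;
      c.S = M_PI * dfl * r[i];
      double sq = std::sqrt(r[i] * dfl);
      c.k = 2.0 * E_sw * sq;
      double fmag = 4.0 / 3.0 * E_sw * sq * dfl;
      c.fx = 0;
      c.fy = 0;
      c.fz = fmag;
      out.push_back(c);
    }
    // lateral wall
    double rho = std::sqrt(x[i] * x[i] + y[i] * y[i]);
    double dlat = r[i] - (pp.well_radius - rho);
    if (dlat >= 0 && rho > 0) {
      Contact c;
      c.i = i;
      c.j = -1;
      c.nx = -x[i] / rho;
      c.ny = -y[i] / rho;
      c.nz = 0;
      c.S = M_PI * dlat * r[i];
      double sq = std::sqrt(r[i] * dlat);
      c.k = 2.0 * E_sw * sq;
      double fmag = 4.0 / 3.0 * E_sw * sq * dlat;
      c.fx = fmag * c.nx;
      c.fy = fmag * c.ny;
      c.fz = fmag * c.nz;
      out.push_back(c);
    }
  }
}

// y = C v with C = diag(gamma I) + contact blocks (coefI I + coefN n n^T)
static void apply_C(const std::vector<double>& gamma,
                    const std::vector<Contact>& con, double c_t,
                    double c_n, double lam_dt, const std::vector<double>& v,
                    std::vector<double>& y) {
  int n = (int)gamma.size();
  for (int i = 0; i < n; ++i) {
    y[3 * i] = gamma[i] * v[3 * i];
    y[3 * i + 1] = gamma[i] * v[3 * i + 1];
    y[3 * i + 2] = gamma[i] * v[3 * i + 2];
  }
  for (const Contact& c : con) {
    double coefI = c.S * c_t;
    double coefN = c.S * (c_n - c_t) + lam_dt * c.k;
    int i = c.i, j = c.j;
    double vx = v[3 * i], vy = v[3 * i + 1], vz = v[3 * i + 2];
    if (j >= 0) {
      vx -= v[3 * j];
      vy -= v[3 * j + 1];
      vz -= v[3 * j + 2];
    }
    double vn = vx * c.nx + vy * c.ny + vz * c.nz;
    double wx = coefI * vx + coefN * vn * c.nx;
    double wy = coefI * vy + coefN * vn * c.ny;
    double wz = coefI * vz + coefN * vn * c.nz;
    y[3 * i] += wx;
    y[3 * i + 1] += wy;
    y[3 * i + 2] += wz;
    if (j >= 0) {
      y[3 * j] -= wx;
      y[3 * j + 1] -= wy;
      y[3 * j + 2] -= wz;
    }
  }
}

// Jacobi-preconditioned CG; v holds the warm start on entry
struct CGWork {
  std::vector<double> diag, r, zv, p, Cp;
};

static int solve_cg(const std::vector<double>& gamma,
                    const std::vector<Contact>& con, double c_t, double c_n,
                    double lam_dt, const std::vector<double>& F,
                    std::vector<double>& v, double tol, CGWork& ws) {
  int nd = (int)F.size();
  int n = nd / 3;
  double nF2 = 0;
  for (double f : F) nF2 += f * f;
  if (nF2 == 0) {
    std::fill(v.begin(), v.end(), 0.0);
    return 0;
  }
  double nF = std::sqrt(nF2);
  ws.diag.assign(nd, 0.0);
  std::vector<double>& diag = ws.diag;
  for (int i = 0; i < n; ++i)
    diag[3 * i] = diag[3 * i + 1] = diag[3 * i + 2] = gamma[i];
  for (const Contact& c : con) {
    double coefI = c.S * c_t;
    double coefN = c.S * (c_n - c_t) + lam_dt * c.k;
    double nn[3] = {c.nx, c.ny, c.nz};
    for (int d = 0; d < 3; ++d) {
      double add = coefI + coefN * nn[d] * nn[d];
      diag[3 * c.i + d] += add;
      if (c.j >= 0) diag[3 * c.j + d] += add;
    }
  }
  ws.r.resize(nd); ws.zv.resize(nd); ws.p.resize(nd); ws.Cp.resize(nd);
  std::vector<double>& r = ws.r;
  std::vector<double>& zv = ws.zv;
  std::vector<double>& p = ws.p;
  std::vector<double>& Cp = ws.Cp;
  apply_C(gamma, con, c_t, c_n, lam_dt, v, r);
  double r2 = 0;
  for (int k = 0; k < nd; ++k) {
    r[k] = F[k] - r[k];
    r2 += r[k] * r[k];
  }
  double rz = 0;
  for (int k = 0; k < nd; ++k) {
    zv[k] = r[k] / diag[k];
    p[k] = zv[k];
    rz += r[k] * zv[k];
  }
  int maxit = std::max(200, 10 * nd);
  int it = 0;
  while (std::sqrt(r2) / nF > tol && it < maxit) {
    apply_C(gamma, con, c_t, c_n, lam_dt, p, Cp);
    double pCp = 0;
    for (int k = 0; k < nd; ++k) pCp += p[k] * Cp[k];
    double alpha = rz / pCp;
    r2 = 0;
    for (int k = 0; k < nd; ++k) {
      v[k] += alpha * p[k];
      r[k] -= alpha * Cp[k];
      r2 += r[k] * r[k];
    }
    double rz_new = 0;
    for (int k = 0; k < nd; ++k) {
      zv[k] = r[k] / diag[k];
      rz_new += r[k] * zv[k];
    }
    double beta = rz_new / rz;
    for (int k = 0; k < nd; ++k) p[k] = zv[k] + beta * p[k];
    rz = rz_new;
    ++it;
  }
  if (std::sqrt(r2) / nF > tol)
    stop("conjugate gradient failed to converge");
  return it;
}

// union-of-disks area coverage inside the ROI, by rasterization
static double coverage(const std::vector<double>& x,
                       const std::vector<double>& y,
                       const std::vector<double>& r, double R, double px) {
  int m = (int)std::ceil(2 * R / px);
  std::vector<uint8_t> buf((size_t)m * m, 0);
  int n = (int)r.size();
  for (int i = 0; i < n; ++i) {
    if (std::sqrt(x[i] * x[i] + y[i] * y[i]) - r[i] > R) continue;
    int i0 = std::max(0, (int)std::floor((x[i] - r[i] + R) / px));
    int i1 = std::min(m - 1, (int)std::ceil((x[i] + r[i] + R) / px));
    int j0 = std::max(0, (int)std::floor((y[i] - r[i] + R) / px));
    int j1 = std::min(m - 1, (int)std::ceil((y[i] + r[i] + R) / px));
    for (int ii = i0; ii <= i1; ++ii) {
      double cx = -R + (ii + 0.5) * px;
      for (int jj = j0; jj <= j1; ++jj) {
        double cy = -R + (jj + 0.5) * px;
        double dx = cx - x[i], dy = cy - y[i];
        if (dx * dx + dy * dy <= r[i] * r[i])
          buf[(size_t)ii * m + jj] = 1;
      }
    }
  }
  long covered = 0, roi = 0;
  for (int ii = 0; ii < m; ++ii) {
    double cx = -R + (ii + 0.5) * px;
    for (int jj = 0; jj < m; ++jj) {
      double cy = -R + (jj + 0.5) * px;
      if (cx * cx + cy * cy <= R * R) {
        ++roi;
        if (buf[(size_t)ii * m + jj]) ++covered;
      }
    }
  }
  return roi > 0 ? (double)covered / roi : 0.0;
}

// [[Rcpp::export]]
double cpp_coverage(NumericVector x, NumericVector y, NumericVector r,
                    double roi_radius, double px) {
  std::vector<double> xx(x.begin(), x.end()), yy(y.begin(), y.end()),
      rr(r.begin(), r.end());
  return coverage(xx, yy, rr, roi_radius, px);
}

// [[Rcpp::export]]
List cpp_run_simulation(NumericMatrix positions, NumericVector radii,
                        NumericVector np_counts, List tab, List control,
                        bool verbose) {
  FieldTab ft = unpack_table(tab);
  Params pp;
  pp.dt = control["dt"];
  pp.eta_m = control["eta_m"];
  pp.rho_s = control["rho_s"];
  pp.rho_m = control["rho_m"];
  pp.g = control["g"];
  pp.c_t = control["c_t"];
  pp.c_n = control["c_n"];
  pp.E_sph = control["E_spheroid"];
  pp.E_well = control["E_well"];
  pp.well_radius = control["well_radius"];
  pp.floor_z = control["floor_z"];
  pp.lam = control["lam"];
  pp.D = control["D"];
  pp.cg_tol = control["cg_tol"];
  double t_end = control["t_end"];
  double I_out = control["I_out"];
  double kin_interval = control["kin_interval"];
  double roi_radius = control["roi_radius"];
  double cov_px = control["coverage_px"];
  bool substep_on = as<double>(control["substep"]) != 0.0;

  int n = positions.nrow();
  std::vector<double> x(n), y(n), z(n), r(n), Nnp(n), gamma(n), Fg(n);
  for (int i = 0; i < n; ++i) {
    x[i] = positions(i, 0);
    y[i] = positions(i, 1);
    z[i] = positions(i, 2);
    r[i] = radii[i];
    Nnp[i] = np_counts[i];
    gamma[i] = 6.0 * M_PI * pp.eta_m * r[i];
    Fg[i] = -4.0 / 3.0 * M_PI * r[i] * r[i] * r[i] *
            (pp.rho_s - pp.rho_m) * pp.g;
  }
  double rmin = *std::min_element(r.begin(), r.end());
  long nsteps = (long)std::llround(t_end / pp.dt);
  long out_every = std::max(1L, (long)std::llround(I_out / pp.dt));
  long kin_every = std::max(1L, (long)std::llround(kin_interval / pp.dt));

  std::vector<Contact> con;
  std::vector<CellEntry> cellbuf;
  CGWork cgws;
  std::vector<double> F(3 * n), v(3 * n, 0.0);
  std::vector<double> Fm(3 * n), Fh(3 * n);

  List snapshots;
  std::vector<double> snap_times, kin_times, kin_cov;
  bool use_noise = pp.D > 0;
  if (use_noise) GetRNGstate();

  auto compute_forces = [&]() {
    find_contacts(x, y, z, r, pp, cellbuf, con);
    std::fill(Fh.begin(), Fh.end(), 0.0);
    for (const Contact& c : con) {
      Fh[3 * c.i] += c.fx;
      Fh[3 * c.i + 1] += c.fy;
      Fh[3 * c.i + 2] += c.fz;
      if (c.j >= 0) {
        Fh[3 * c.j] -= c.fx;
        Fh[3 * c.j + 1] -= c.fy;
        Fh[3 * c.j + 2] -= c.fz;
      }
    }
    for (int i = 0; i < n; ++i) {
      double fx, fy, fz;
      np_force_at(ft, x[i], y[i], z[i], &fx, &fy, &fz);
      Fm[3 * i] = Nnp[i] * fx;
      Fm[3 * i + 1] = Nnp[i] * fy;
      Fm[3 * i + 2] = Nnp[i] * fz;
      F[3 * i] = Fm[3 * i] + Fh[3 * i];
      F[3 * i + 1] = Fm[3 * i + 1] + Fh[3 * i + 1];
      F[3 * i + 2] = Fm[3 * i + 2] + Fg[i] + Fh[3 * i + 2];
    }
  };

  auto take_snapshot = [&](double t) {
    NumericMatrix P(n, 3), V(n, 3), FM(n, 3), FH(n, 3);
    NumericVector FGZ(n);
    for (int i = 0; i < n; ++i) {
      P(i, 0) = x[i]; P(i, 1) = y[i]; P(i, 2) = z[i];
      V(i, 0) = v[3 * i]; V(i, 1) = v[3 * i + 1]; V(i, 2) = v[3 * i + 2];
      FM(i, 0) = Fm[3 * i]; FM(i, 1) = Fm[3 * i + 1];
      FM(i, 2) = Fm[3 * i + 2];
      FH(i, 0) = Fh[3 * i]; FH(i, 1) = Fh[3 * i + 1];
      FH(i, 2) = Fh[3 * i + 2];
      FGZ[i] = Fg[i];
    }
    snapshots.push_back(List::create(
        _["positions"] = P, _["velocities"] = V, _["F_mag"] = FM,
        _["F_grav_z"] = FGZ, _["F_hertz"] = FH));
    snap_times.push_back(t);
  };

  auto advance = [&](double dt_eff) {
    for (int i = 0; i < n; ++i) {
      x[i] += dt_eff * v[3 * i];
      y[i] += dt_eff * v[3 * i + 1];
      z[i] += dt_eff * v[3 * i + 2];
      if (use_noise) {
        double s = std::sqrt(2.0 * pp.D * dt_eff);
        x[i] += s * norm_rand();
        y[i] += s * norm_rand();
        z[i] += s * norm_rand();
      }
    }
  };

  // t = 0 record
  compute_forces();
  solve_cg(gamma, con, pp.c_t, pp.c_n, pp.lam * pp.dt, F, v, pp.cg_tol, cgws);
  take_snapshot(0.0);
  kin_times.push_back(0.0);
  kin_cov.push_back(coverage(x, y, r, roi_radius, cov_px));

  long total_cg = 0;
  for (long s = 1; s <= nsteps; ++s) {
    compute_forces();
    total_cg += solve_cg(gamma, con, pp.c_t, pp.c_n, pp.lam * pp.dt, F, v,
                         pp.cg_tol, cgws);
    double vmax2 = 0;
    for (int i = 0; i < n; ++i) {
      double v2 = v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
                  v[3 * i + 2] * v[3 * i + 2];
      vmax2 = std::max(vmax2, v2);
    }
    double maxdisp = std::sqrt(vmax2) * pp.dt;
    if (substep_on && maxdisp > 0.1 * rmin) {
      // adaptive sub-stepping: re-solve at each substate
      int nsub = (int)std::ceil(maxdisp / (0.1 * rmin));
      double dts = pp.dt / nsub;
      advance(dts);
      for (int ss = 1; ss < nsub; ++ss) {
        compute_forces();
        total_cg += solve_cg(gamma, con, pp.c_t, pp.c_n, pp.lam * pp.dt, F,
                             v, pp.cg_tol, cgws);
        advance(dts);
      }
    } else {
      advance(pp.dt);
    }
    double t = s * pp.dt;
    if (s % kin_every == 0) {
      kin_times.push_back(t);
      kin_cov.push_back(coverage(x, y, r, roi_radius, cov_px));
    }
    if (s % out_every == 0) {
      compute_forces();  // snapshot carries forces at the new positions
      take_snapshot(t);
      if (verbose)
        Rcpp::Rcout << "t = " << t << " s, contacts = " << con.size()
                    << ", cg iters = " << total_cg << "\n";
      total_cg = 0;
    }
    if (s % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  if (use_noise) PutRNGstate();

  return List::create(
      _["times"] = NumericVector(snap_times.begin(), snap_times.end()),
      _["snapshots"] = snapshots,
      _["kin_times"] = NumericVector(kin_times.begin(), kin_times.end()),
      _["kin_coverage"] = NumericVector(kin_cov.begin(), kin_cov.end()));
}
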