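// Two-phase (liquid/gas) incompressible VOF solver on a staggered MAC grid,
// with continuum-surface-force surface tension, wall contact angles, an
// optional porous drag layer for unresolved surface texture, and passive
// scalar (protein) transport carried by the liquid phase.
//
// Cells are column-major: id = i + j*nx (i along x, j along y, 0-based).
// u lives on x-faces ((nx+1) x ny), v on y-faces (nx x (ny+1)).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

enum CellType { FLUID = 0, IMPLANT = 1, BONE = 2 };
enum FaceCode { FC_INTERIOR = 0, FC_WALL = 1, FC_INLET = 2, FC_OUTLET = 3,
                FC_SYMM = 4 };

struct MGLevel {
  int nx, ny;
  std::vector<char> act;
  std::vector<int> actlist, red, black; // compressed active-cell indices
  std::vector<double> cE, cW, cN, cS, cO, diag, r, z, tmp, tmp2;
  int idc(int i, int j) const { return i + j * nx; }
  void build_lists() {
    actlist.clear(); red.clear(); black.clear();
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = idc(i, j);
        if (!act[c]) continue;
        actlist.push_back(c);
        if ((i + j) % 2 == 0) red.push_back(c); else black.push_back(c);
      }
  }
};

struct MGHierarchy {
  std::vector<MGLevel> lev;

  static void apply_level(const MGLevel& L, const std::vector<double>& x,
                          std::vector<double>& y) {
    // inactive entries of y stay zero (buffers are kept zeroed there)
    for (int c : L.actlist) {
      double acc = L.diag[c] * x[c];
      if (L.cE[c] != 0) acc -= L.cE[c] * x[c + 1];
      if (L.cW[c] != 0) acc -= L.cW[c] * x[c - 1];
      if (L.cN[c] != 0) acc -= L.cN[c] * x[c + L.nx];
      if (L.cS[c] != 0) acc -= L.cS[c] * x[c - L.nx];
      y[c] = acc;
    }
  }

  // red-black Gauss-Seidel: strong smoother for jumping coefficients
  static void smooth(MGLevel& L, std::vector<double>& x,
                     const std::vector<double>& b, int sweeps,
                     bool reverse = false) {
    auto pass = [&](const std::vector<int>& cells) {
      for (int c : cells) {
        if (L.diag[c] <= 0) continue;
        double acc = b[c];
        if (L.cE[c] != 0) acc += L.cE[c] * x[c + 1];
        if (L.cW[c] != 0) acc += L.cW[c] * x[c - 1];
        if (L.cN[c] != 0) acc += L.cN[c] * x[c + L.nx];
        if (L.cS[c] != 0) acc += L.cS[c] * x[c - L.nx];
        x[c] = acc / L.diag[c];
      }
    };
    for (int s = 0; s < sweeps; ++s) {
      if (reverse) { pass(L.black); pass(L.red); }
      else { pass(L.red); pass(L.black); }
    }
  }

  // Allocate the level hierarchy and coarse activity masks (the masks
  // depend only on the solid geometry, so this runs once per simulation).
  void build_structure() {
    while ((int)lev.size() < 8) {
      MGLevel& F = lev.back();
      if (std::min(F.nx, F.ny) < 8) break;
      MGLevel C;
      C.nx = (F.nx + 1) / 2; C.ny = (F.ny + 1) / 2;
      int nc = C.nx * C.ny;
      C.act.assign(nc, 0);
      C.cE.assign(nc, 0); C.cW.assign(nc, 0); C.cN.assign(nc, 0);
      C.cS.assign(nc, 0); C.cO.assign(nc, 0); C.diag.assign(nc, 0);
      C.r.assign(nc, 0); C.z.assign(nc, 0); C.tmp.assign(nc, 0);
      C.tmp2.assign(nc, 0);
      for (int J = 0; J < C.ny; ++J)
        for (int I = 0; I < C.nx; ++I)
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              int i = 2 * I + di, j = 2 * J + dj;
              if (i >= F.nx || j >= F.ny) continue;
              if (F.act[F.idc(i, j)]) C.act[C.idc(I, J)] = 1;
            }
      C.build_lists();
      lev.push_back(std::move(C));
    }
  }

  // Refill coarse coefficients from the (already filled) fine level:
  // fine faces crossing each coarse-cell boundary are averaged and
  // rediscretized at spacing 2h (hence the factor 1/4).
  void update_values() {
    for (size_t l = 0; l + 1 < lev.size(); ++l) {
      MGLevel& F = lev[l];
      MGLevel& C = lev[l + 1];
      std::fill(C.cE.begin(), C.cE.end(), 0.0);
      std::fill(C.cN.begin(), C.cN.end(), 0.0);
      std::fill(C.cO.begin(), C.cO.end(), 0.0);
      for (int J = 0; J < C.ny; ++J)
        for (int I = 0; I < C.nx; ++I) {
          int cc = C.idc(I, J);
          if (!C.act[cc]) continue;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              int i = 2 * I + di, j = 2 * J + dj;
              if (i >= F.nx || j >= F.ny) continue;
              int fc = F.idc(i, j);
              if (F.act[fc]) C.cO[cc] += F.cO[fc] / 4.0;
            }
          int ie = 2 * I + 1; // east child column
          if (ie < F.nx && I + 1 < C.nx && C.act[cc + 1])
            for (int dj = 0; dj < 2; ++dj) {
              int j = 2 * J + dj;
              if (j < F.ny && F.act[F.idc(ie, j)])
                C.cE[cc] += F.cE[F.idc(ie, j)] / 4.0;
            }
          int jn = 2 * J + 1; // north child row
          if (jn < F.ny && J + 1 < C.ny && C.act[cc + C.nx])
            for (int di = 0; di < 2; ++di) {
              int i = 2 * I + di;
              if (i < F.nx && F.act[F.idc(i, jn)])
                C.cN[cc] += F.cN[F.idc(i, jn)] / 4.0;
            }
        }
      for (int J = 0; J < C.ny; ++J)
        for (int I = 0; I < C.nx; ++I) {
          int cc = C.idc(I, J);
          if (!C.act[cc]) continue;
          C.cW[cc] = (I > 0) ? C.cE[cc - 1] : 0.0;
          C.cS[cc] = (J > 0) ? C.cN[cc - C.nx] : 0.0;
          C.diag[cc] = C.cE[cc] + C.cW[cc] + C.cN[cc] + C.cS[cc] + C.cO[cc];
        }
    }
  }

  void vcycle(size_t l) {
    MGLevel& L = lev[l];
    std::fill(L.z.begin(), L.z.end(), 0.0);
    if (l + 1 == lev.size()) {
      smooth(L, L.z, L.r, 40);
      return;
    }
    smooth(L, L.z, L.r, 2);
    apply_level(L, L.z, L.tmp);
    MGLevel& C = lev[l + 1];
    for (int c = 0; c < L.nx * L.ny; ++c)
      L.tmp[c] = L.act[c] ? (L.r[c] - L.tmp[c]) : 0.0;
    // restrict: average of active children
    for (int J = 0; J < C.ny; ++J)
      for (int I = 0; I < C.nx; ++I) {
        int cc = C.idc(I, J);
        if (!C.act[cc]) { C.r[cc] = 0; continue; }
        double sum = 0; int n = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            int i = 2 * I + di, j = 2 * J + dj;
            if (i >= L.nx || j >= L.ny) continue;
            int fc = L.idc(i, j);
            if (L.act[fc]) { sum += L.tmp[fc]; ++n; }
          }
        C.r[cc] = n ? sum / n : 0.0;
      }
    vcycle(l + 1);
    // prolong (piecewise constant: the adjoint of the averaging
    // restriction, keeping the V-cycle a symmetric preconditioner) and add
    for (int fc : L.actlist)
      L.z[fc] += C.z[C.idc((fc % L.nx) / 2, (fc / L.nx) / 2)];
    smooth(L, L.z, L.r, 2, true); // reversed order: symmetric V-cycle
  }
};


struct Sim {
  int nx, ny;
  double h;
  std::vector<int> type, zone;
  std::vector<double> drag, costh, kap_layer;
  std::vector<int> ucode, vcode;
  std::vector<double> uval, vval;
  // tangential ghost signs at domain edges: +1 slip/zero-gradient,
  // -1 no-slip (wall or inlet)
  double gh_left = 1, gh_right = -1, gh_bottom = -1, gh_top = 1;
  // state
  std::vector<double> u, v, p, alpha, m; // m = c * alpha (species load)
  // properties / numerics
  double rho_l, rho_g, mu_l, mu_g, sigma, D;
  double gx, gy, cfl, dtmax, calpha, ptol, c_in;
  int nsmooth, pmaxit;
  bool species_on;
  // scratch
  std::vector<double> as, nxc, nyc, kap, rho, mu;
  std::vector<char> nvalid, iface;
  std::vector<double> Fx, Fy, Fcx, Fcy, thx, thy, atd;
  std::vector<double> us, vs; // predictor velocities
  std::vector<double> cg_r, cg_z, cg_q, cg_s, cg_d, diag;
  std::vector<double> cE, cW, cN, cS, cO; // Poisson face coefficients
  // persistent pressure-solve machinery
  MGHierarchy mgh;
  bool mgh_built = false;
  std::vector<double> pprev;
  bool have_pprev = false;
  // diagnostics (cumulative)
  double liq_in = 0, liq_out = 0, sp_in = 0, sp_out = 0;
  double amin_ever = 1e300, amax_ever = -1e300;
  double clamp_liq = 0, clamp_sp = 0, maxdiv_ever = 0, maxrelresid_ever = 0;
  long nsteps = 0; long pcg_total = 0; int pcg_last = 0;

  int idc(int i, int j) const { return i + j * nx; }
  int idu(int i, int j) const { return i + j * (nx + 1); }
  int idv(int i, int j) const { return i + j * nx; }
  bool fluid(int i, int j) const { return type[idc(i, j)] == FLUID; }
};

static Sim build_sim(const List& geom, const List& params, const List& state) {
  Sim s;
  s.nx = as<int>(geom["nx"]); s.ny = as<int>(geom["ny"]);
  s.h = as<double>(geom["h"]);
  s.type = as<std::vector<int>>(geom["type"]);
  s.zone = as<std::vector<int>>(geom["zone"]);
  s.drag = as<std::vector<double>>(geom["drag"]);
  s.costh = as<std::vector<double>>(geom["costh"]);
  if (geom.containsElementNamed("kap_layer"))
    s.kap_layer = as<std::vector<double>>(geom["kap_layer"]);
  else s.kap_layer.assign(s.type.size(), 0.0);
  s.ucode = as<std::vector<int>>(geom["ucode"]);
  s.uval = as<std::vector<double>>(geom["uval"]);
  s.vcode = as<std::vector<int>>(geom["vcode"]);
  s.vval = as<std::vector<double>>(geom["vval"]);
  if (geom.containsElementNamed("ghost_signs")) {
    NumericVector gs = geom["ghost_signs"]; // left, right, bottom, top
    s.gh_left = gs[0]; s.gh_right = gs[1];
    s.gh_bottom = gs[2]; s.gh_top = gs[3];
  }
  s.u = as<std::vector<double>>(state["u"]);
  s.v = as<std::vector<double>>(state["v"]);
  s.p = as<std::vector<double>>(state["p"]);
  s.alpha = as<std::vector<double>>(state["alpha"]);
  s.m = as<std::vector<double>>(state["m"]);
  s.rho_l = as<double>(params["rho_l"]); s.rho_g = as<double>(params["rho_g"]);
  s.mu_l = as<double>(params["mu_l"]); s.mu_g = as<double>(params["mu_g"]);
  s.sigma = as<double>(params["sigma"]); s.D = as<double>(params["D"]);
  s.gx = as<double>(params["gx"]); s.gy = as<double>(params["gy"]);
  s.cfl = as<double>(params["cfl"]); s.dtmax = as<double>(params["dtmax"]);
  s.calpha = as<double>(params["calpha"]);
  s.ptol = as<double>(params["ptol"]); s.pmaxit = as<int>(params["pmaxit"]);
  s.nsmooth = as<int>(params["nsmooth"]);
  s.c_in = as<double>(params["c_in"]);
  s.species_on = as<bool>(params["species_on"]);
  int nc = s.nx * s.ny, nu = (s.nx + 1) * s.ny, nv = s.nx * (s.ny + 1);
  s.as.assign(nc, 0); s.nxc.assign(nc, 0); s.nyc.assign(nc, 0);
  s.kap.assign(nc, 0); s.rho.assign(nc, 0); s.mu.assign(nc, 0);
  s.nvalid.assign(nc, 0); s.iface.assign(nc, 0);
  s.Fx.assign(nu, 0); s.Fy.assign(nv, 0);
  s.Fcx.assign(nu, 0); s.Fcy.assign(nv, 0);
  s.thx.assign(nu, 0); s.thy.assign(nv, 0);
  s.atd.assign(nc, 0);
  s.us.assign(nu, 0); s.vs.assign(nv, 0);
  s.cg_r.assign(nc, 0); s.cg_z.assign(nc, 0); s.cg_q.assign(nc, 0);
  s.cg_s.assign(nc, 0); s.cg_d.assign(nc, 0); s.diag.assign(nc, 0);
  s.cE.assign(nc, 0); s.cW.assign(nc, 0); s.cN.assign(nc, 0);
  s.cS.assign(nc, 0); s.cO.assign(nc, 0);
  return s;
}

static inline double clamp01(double x) {
  return x < 0 ? 0 : (x > 1 ? 1 : x);
}

// ---------------------------------------------------------------- BCs ----
static void enforce_bcs(Sim& s) {
  for (int j = 0; j < s.ny; ++j)
    for (int i = 0; i <= s.nx; ++i) {
      int f = s.idu(i, j);
      switch (s.ucode[f]) {
      case FC_WALL: case FC_SYMM: s.u[f] = 0; break;
      case FC_INLET: s.u[f] = s.uval[f]; break;
      case FC_OUTLET:
        s.u[f] = (i == 0) ? s.u[s.idu(1, j)] : s.u[s.idu(s.nx - 1, j)];
        break;
      default: break;
      }
    }
  for (int j = 0; j <= s.ny; ++j)
    for (int i = 0; i < s.nx; ++i) {
      int f = s.idv(i, j);
      switch (s.vcode[f]) {
      case FC_WALL: case FC_SYMM: s.v[f] = 0; break;
      case FC_INLET: s.v[f] = s.vval[f]; break;
      case FC_OUTLET:
        s.v[f] = (j == 0) ? s.v[s.idv(i, 1)] : s.v[s.idv(i, s.ny - 1)];
        break;
      default: break;
      }
    }
}

// Tangential-neighbour access with ghost rules (no-slip at solids and
// domain walls, free slip at the symmetry axis, zero-gradient at outlets).
static inline double uAt(const Sim& s, int i, int j, double uself) {
  if (j < 0) return s.gh_bottom * uself;
  if (j >= s.ny) return s.gh_top * uself;
  int f = s.idu(i, j);
  if (s.ucode[f] == FC_WALL) {
    bool lsolid = (i == 0) || !s.fluid(i - 1, j);
    bool rsolid = (i == s.nx) || !s.fluid(i, j);
    if (lsolid && rsolid) return -uself;       // face embedded in solid
  }
  return s.u[f];
}

static inline double vAt(const Sim& s, int i, int j, double vself) {
  if (i < 0) return s.gh_left * vself;
  if (i >= s.nx) return s.gh_right * vself;
  int f = s.idv(i, j);
  if (s.vcode[f] == FC_WALL) {
    bool bsolid = (j == 0) || !s.fluid(i, j - 1);
    bool tsolid = (j == s.ny) || !s.fluid(i, j);
    if (bsolid && tsolid) return -vself;
  }
  return s.v[f];
}

// ------------------------------------------------- interface geometry ----
static void smooth_alpha(Sim& s) {
  int nc = s.nx * s.ny;
  std::copy(s.alpha.begin(), s.alpha.end(), s.as.begin());
  std::vector<double> tmp(nc);
  for (int pass = 0; pass < s.nsmooth; ++pass) {
    for (int j = 0; j < s.ny; ++j)
      for (int i = 0; i < s.nx; ++i) {
        int c = s.idc(i, j);
        if (s.type[c] != FLUID) { tmp[c] = s.as[c]; continue; }
        double a = s.as[c];
        double aw = (i > 0 && s.fluid(i - 1, j)) ? s.as[c - 1] : a;
        double ae = (i < s.nx - 1 && s.fluid(i + 1, j)) ? s.as[c + 1] : a;
        double asn = (j > 0 && s.fluid(i, j - 1)) ? s.as[c - s.nx] : a;
        double an = (j < s.ny - 1 && s.fluid(i, j + 1)) ? s.as[c + s.nx] : a;
        tmp[c] = 0.5 * a + 0.125 * (aw + ae + asn + an);
      }
    std::swap(tmp, s.as);
  }
}

static void normals_curvature(Sim& s) {
  double h = s.h;
  double gtol = 1e-3 / h;
  // cell normals from the smoothed field, contact angle applied at walls
  for (int j = 0; j < s.ny; ++j)
    for (int i = 0; i < s.nx; ++i) {
      int c = s.idc(i, j);
      s.nvalid[c] = 0; s.iface[c] = 0; s.kap[c] = 0;
      if (s.type[c] != FLUID) continue;
      double a = s.as[c];
      double aw = (i > 0) ? (s.fluid(i - 1, j) ? s.as[c - 1] : a) : a;
      double ae = (i < s.nx - 1) ? (s.fluid(i + 1, j) ? s.as[c + 1] : a) : a;
      double asn = (j > 0) ? (s.fluid(i, j - 1) ? s.as[c - s.nx] : a) : a;
      double an = (j < s.ny - 1) ? (s.fluid(i, j + 1) ? s.as[c + s.nx] : a) : a;
      double gx = (ae - aw) / (2 * h), gy = (an - asn) / (2 * h);
      double g = std::sqrt(gx * gx + gy * gy);
      if (g < gtol) continue;
      // gas-pointing unit normal
      double nxv = -gx / g, nyv = -gy / g;
      // contact-angle correction in wall-adjacent interface cells
      if (a > 0.005 && a < 0.995) {
        double wx = 0, wy = 0, ct = 0; int nsolid = 0;
        if (i > 0 && !s.fluid(i - 1, j)) { wx += 1; ct += s.costh[c - 1]; ++nsolid; }
        if (i < s.nx - 1 && !s.fluid(i + 1, j)) { wx -= 1; ct += s.costh[c + 1]; ++nsolid; }
        if (j > 0 && !s.fluid(i, j - 1)) { wy += 1; ct += s.costh[c - s.nx]; ++nsolid; }
        if (j < s.ny - 1 && !s.fluid(i, j + 1)) { wy -= 1; ct += s.costh[c + s.nx]; ++nsolid; }
        double wn = std::sqrt(wx * wx + wy * wy);
        if (nsolid > 0 && wn > 0) {
          wx /= wn; wy /= wn; ct /= nsolid;
          double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
          double tx = nxv - (nxv * wx + nyv * wy) * wx;
          double ty = nyv - (nxv * wx + nyv * wy) * wy;
          double tn = std::sqrt(tx * tx + ty * ty);
          if (tn > 1e-8) {
            nxv = ct * wx + st * tx / tn;
            nyv = ct * wy + st * ty / tn;
          }
        }
      }
      s.nxc[c] = nxv; s.nyc[c] = nyv; s.nvalid[c] = 1;
      double ar = s.alpha[c];
      if (ar > 1e-4 && ar < 1 - 1e-4) s.iface[c] = 1;
      else if (a > 0.01 && a < 0.99) s.iface[c] = 1;
    }
  // curvature = -div(n) with one-sided fallback at invalid neighbours
  for (int j = 0; j < s.ny; ++j)
    for (int i = 0; i < s.nx; ++i) {
      int c = s.idc(i, j);
      if (!s.iface[c] || !s.nvalid[c]) continue;
      double nE = (i < s.nx - 1 && s.nvalid[c + 1]) ?
        0.5 * (s.nxc[c] + s.nxc[c + 1]) : s.nxc[c];
      double nW = (i > 0 && s.nvalid[c - 1]) ?
        0.5 * (s.nxc[c] + s.nxc[c - 1]) : s.nxc[c];
      double nN = (j < s.ny - 1 && s.nvalid[c + s.nx]) ?
        0.5 * (s.nyc[c] + s.nyc[c + s.nx]) : s.nyc[c];
      double nS = (j > 0 && s.nvalid[c - s.nx]) ?
        0.5 * (s.nyc[c] + s.nyc[c - s.nx]) : s.nyc[c];
      // n is the gas-pointing normal, so kappa = +div(n); a liquid disc
      // (n = +r_hat, div n = 1/R) gets kappa = +1/R and an inward force
      double k = ((nE - nW) + (nN - nS)) / s.h;
      double kmax = 1.0 / s.h;
      k = std::max(-kmax, std::min(kmax, k));
      // inside an unresolved porous texture layer the sub-grid pore
      // curvature replaces the resolved one (imbibition suction)
      s.kap[c] = (s.kap_layer[c] != 0.0) ? s.kap_layer[c] : k;
    }
}

// --------------------------------------------------------------- dt ------
static double stable_dt(const Sim& s) {
  double umax = 0;
  for (double x : s.u) umax = std::max(umax, std::fabs(x));
  for (double x : s.v) umax = std::max(umax, std::fabs(x));
  double dt = s.dtmax;
  if (umax > 1e-12) dt = std::min(dt, s.cfl * s.h / umax);
  if (s.sigma > 0) {
    double rbar = 0.5 * (s.rho_l + s.rho_g);
    dt = std::min(dt, std::sqrt(rbar * s.h * s.h * s.h /
                                (2 * M_PI * s.sigma)));
  }
  double numax = std::max(s.mu_l / s.rho_l, s.mu_g / s.rho_g);
  if (numax > 0) dt = std::min(dt, 0.225 * s.h * s.h / numax);
  if (s.species_on && s.D > 0)
    dt = std::min(dt, 0.225 * s.h * s.h / s.D);
  return dt;
}

// ------------------------------------------------------ VOF advection ----
// Returns fluxes in s.Fx/Fy (upwind) and s.Fcx/Fcy (compressive), then
// applies an FCT (Zalesak) limiter to the compressive part and updates
// alpha and the species load m conservatively.
static void advect_alpha_species(Sim& s, double dt) {
  int nx = s.nx, ny = s.ny;
  double h = s.h;
  const double epsa = 1e-9;
  // upwind + compressive fluxes on x-faces
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i <= nx; ++i) {
      int f = s.idu(i, j);
      s.Fx[f] = 0; s.Fcx[f] = 0; s.thx[f] = 0;
      int code = s.ucode[f];
      double uf = s.u[f];
      if (code == FC_INTERIOR) {
        int cl = s.idc(i - 1, j), cr = s.idc(i, j);
        double aup = uf > 0 ? s.alpha[cl] : s.alpha[cr];
        s.Fx[f] = uf * aup;
        if (s.calpha > 0 && (s.iface[cl] || s.iface[cr])) {
          double nf = 0;
          int nn = 0;
          if (s.nvalid[cl]) { nf += s.nxc[cl]; ++nn; }
          if (s.nvalid[cr]) { nf += s.nxc[cr]; ++nn; }
          if (nn) nf /= nn;
          double af = 0.5 * (s.alpha[cl] + s.alpha[cr]);
          // compression pushes liquid along -n (toward the liquid side)
          s.Fcx[f] = -s.calpha * std::fabs(uf) * nf * af * (1 - af);
        }
      } else if (code == FC_INLET) {
        s.Fx[f] = uf * 1.0;  // liquid enters
      } else if (code == FC_OUTLET) {
        double ain = (i == 0) ? s.alpha[s.idc(0, j)] : s.alpha[s.idc(nx - 1, j)];
        s.Fx[f] = uf * ain;
      }
    }
  for (int j = 0; j <= ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int f = s.idv(i, j);
      s.Fy[f] = 0; s.Fcy[f] = 0; s.thy[f] = 0;
      int code = s.vcode[f];
      double vf = s.v[f];
      if (code == FC_INTERIOR) {
        int cb = s.idc(i, j - 1), ct = s.idc(i, j);
        double aup = vf > 0 ? s.alpha[cb] : s.alpha[ct];
        s.Fy[f] = vf * aup;
        if (s.calpha > 0 && (s.iface[cb] || s.iface[ct])) {
          double nf = 0; int nn = 0;
          if (s.nvalid[cb]) { nf += s.nyc[cb]; ++nn; }
          if (s.nvalid[ct]) { nf += s.nyc[ct]; ++nn; }
          if (nn) nf /= nn;
          double af = 0.5 * (s.alpha[cb] + s.alpha[ct]);
          s.Fcy[f] = -s.calpha * std::fabs(vf) * nf * af * (1 - af);
        }
      } else if (code == FC_INLET) {
        s.Fy[f] = vf * 1.0;
      } else if (code == FC_OUTLET) {
        double ain = (j == 0) ? s.alpha[s.idc(i, 0)] : s.alpha[s.idc(i, ny - 1)];
        s.Fy[f] = vf * ain;
      }
    }
  double r = dt / h;
  // low-order (transported/diffused) solution; the alpha*div(u) term makes
  // the update divergence-consistent, so a uniform alpha is exactly
  // stationary even when the projection leaves a small divergence defect
  std::vector<double>& divu = s.cg_d; // scratch
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int c = s.idc(i, j);
      if (s.type[c] != FLUID) { s.atd[c] = s.alpha[c]; divu[c] = 0; continue; }
      divu[c] = (s.u[s.idu(i + 1, j)] - s.u[s.idu(i, j)] +
                 s.v[s.idv(i, j + 1)] - s.v[s.idv(i, j)]) / h;
      s.atd[c] = s.alpha[c] - r * (s.Fx[s.idu(i + 1, j)] - s.Fx[s.idu(i, j)] +
                                   s.Fy[s.idv(i, j + 1)] - s.Fy[s.idv(i, j)]) +
        dt * s.alpha[c] * divu[c];
    }
  // Zalesak limiter for the compressive fluxes
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int c = s.idc(i, j);
      if (s.type[c] != FLUID) continue;
      double FW = s.Fcx[s.idu(i, j)], FE = s.Fcx[s.idu(i + 1, j)];
      double FS = s.Fcy[s.idv(i, j)], FN = s.Fcy[s.idv(i, j + 1)];
      double Pp = r * (std::max(FW, 0.0) - std::min(FE, 0.0) +
                       std::max(FS, 0.0) - std::min(FN, 0.0));
      double Pm = r * (std::max(FE, 0.0) - std::min(FW, 0.0) +
                       std::max(FN, 0.0) - std::min(FS, 0.0));
      double Qp = 1.0 - s.atd[c], Qm = s.atd[c];
      double Rp = Pp > 1e-300 ? std::min(1.0, Qp / Pp) : 0.0;
      double Rm = Pm > 1e-300 ? std::min(1.0, Qm / Pm) : 0.0;
      // stash per-cell limits in cg scratch (reused as R+/R-)
      s.cg_r[c] = Rp; s.cg_z[c] = Rm;
    }
  for (int j = 0; j < ny; ++j)
    for (int i = 1; i < nx; ++i) {
      int f = s.idu(i, j);
      if (s.ucode[f] != FC_INTERIOR || s.Fcx[f] == 0) continue;
      int cl = s.idc(i - 1, j), cr = s.idc(i, j);
      s.thx[f] = s.Fcx[f] > 0 ? std::min(s.cg_z[cl], s.cg_r[cr])
                              : std::min(s.cg_z[cr], s.cg_r[cl]);
    }
  for (int j = 1; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int f = s.idv(i, j);
      if (s.vcode[f] != FC_INTERIOR || s.Fcy[f] == 0) continue;
      int cb = s.idc(i, j - 1), ct = s.idc(i, j);
      s.thy[f] = s.Fcy[f] > 0 ? std::min(s.cg_z[cb], s.cg_r[ct])
                              : std::min(s.cg_z[ct], s.cg_r[cb]);
    }
  // total fluxes; species rides the same fluxes with upwind concentration
  std::vector<double>& c_of = s.cg_q; // scratch: concentration field
  if (s.species_on)
    for (int c = 0; c < nx * ny; ++c)
      c_of[c] = s.alpha[c] > epsa ? clamp01(s.m[c] / s.alpha[c]) : 0.0;
  // final alpha update + boundary accounting
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int c = s.idc(i, j);
      if (s.type[c] != FLUID) continue;
      double FW = s.Fx[s.idu(i, j)] + s.thx[s.idu(i, j)] * s.Fcx[s.idu(i, j)];
      double FE = s.Fx[s.idu(i + 1, j)] +
        s.thx[s.idu(i + 1, j)] * s.Fcx[s.idu(i + 1, j)];
      double FS = s.Fy[s.idv(i, j)] + s.thy[s.idv(i, j)] * s.Fcy[s.idv(i, j)];
      double FN = s.Fy[s.idv(i, j + 1)] +
        s.thy[s.idv(i, j + 1)] * s.Fcy[s.idv(i, j + 1)];
      s.cg_s[c] = s.alpha[c] - r * (FE - FW + FN - FS) +
        dt * s.alpha[c] * divu[c]; // new alpha
    }
  // species advection on the same (limited) fluxes
  if (s.species_on) {
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = s.idc(i, j);
        if (s.type[c] != FLUID) continue;
        double fl[4]; int fi[4]; double sgn[4];
        fl[0] = s.Fx[s.idu(i, j)] + s.thx[s.idu(i, j)] * s.Fcx[s.idu(i, j)];
        fl[1] = s.Fx[s.idu(i + 1, j)] +
          s.thx[s.idu(i + 1, j)] * s.Fcx[s.idu(i + 1, j)];
        fl[2] = s.Fy[s.idv(i, j)] + s.thy[s.idv(i, j)] * s.Fcy[s.idv(i, j)];
        fl[3] = s.Fy[s.idv(i, j + 1)] +
          s.thy[s.idv(i, j + 1)] * s.Fcy[s.idv(i, j + 1)];
        (void)fi; (void)sgn;
        double dm = 0;
        // west face: positive flux enters cell
        {
          int f = s.idu(i, j);
          double cc;
          if (s.ucode[f] == FC_INLET) cc = s.c_in;
          else if (i == 0) cc = c_of[c];
          else cc = fl[0] > 0 ? c_of[s.idc(i - 1, j)] : c_of[c];
          dm += fl[0] * cc;
        }
        {
          int f = s.idu(i + 1, j);
          double cc;
          if (s.ucode[f] == FC_INLET) cc = s.c_in;
          else if (i == nx - 1) cc = c_of[c];
          else cc = fl[1] > 0 ? c_of[c] : c_of[s.idc(i + 1, j)];
          dm -= fl[1] * cc;
        }
        {
          int f = s.idv(i, j);
          double cc;
          if (s.vcode[f] == FC_INLET) cc = s.c_in;
          else if (j == 0) cc = c_of[c];
          else cc = fl[2] > 0 ? c_of[s.idc(i, j - 1)] : c_of[c];
          dm += fl[2] * cc;
        }
        {
          int f = s.idv(i, j + 1);
          double cc;
          if (s.vcode[f] == FC_INLET) cc = s.c_in;
          else if (j == ny - 1) cc = c_of[c];
          else cc = fl[3] > 0 ? c_of[c] : c_of[s.idc(i, j + 1)];
          dm -= fl[3] * cc;
        }
        s.cg_r[c] = s.m[c] + r * dm + dt * s.m[c] * divu[c]; // new m
      }
  }
  // boundary accounting (inflow positive into the domain)
  double dA = dt * h;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i <= nx; ++i) {
      int f = s.idu(i, j);
      if (s.ucode[f] != FC_INLET && s.ucode[f] != FC_OUTLET) continue;
      bool fluid_right = (i < nx) && s.fluid(i, j);
      double sin_ = fluid_right ? 1.0 : -1.0;
      double F = s.Fx[f];
      double cc = s.ucode[f] == FC_INLET ? s.c_in
        : (fluid_right ? (s.alpha[s.idc(i, j)] > epsa ?
                          clamp01(s.m[s.idc(i, j)] / s.alpha[s.idc(i, j)]) : 0)
           : (s.alpha[s.idc(i - 1, j)] > epsa ?
              clamp01(s.m[s.idc(i - 1, j)] / s.alpha[s.idc(i - 1, j)]) : 0));
      if (s.ucode[f] == FC_INLET) {
        s.liq_in += dA * sin_ * F;
        if (s.species_on) s.sp_in += dA * sin_ * F * cc;
      } else {
        s.liq_out += dA * (-sin_) * F;
        if (s.species_on) s.sp_out += dA * (-sin_) * F * cc;
      }
    }
  for (int j = 0; j <= ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int f = s.idv(i, j);
      if (s.vcode[f] != FC_INLET && s.vcode[f] != FC_OUTLET) continue;
      bool fluid_top = (j < ny) && s.fluid(i, j);
      double sin_ = fluid_top ? 1.0 : -1.0;
      double F = s.Fy[f];
      int cin = fluid_top ? s.idc(i, j) : s.idc(i, j - 1);
      double cc = s.vcode[f] == FC_INLET ? s.c_in
        : (s.alpha[cin] > epsa ? clamp01(s.m[cin] / s.alpha[cin]) : 0);
      if (s.vcode[f] == FC_INLET) {
        s.liq_in += dA * sin_ * F;
        if (s.species_on) s.sp_in += dA * sin_ * F * cc;
      } else {
        s.liq_out += dA * (-sin_) * F;
        if (s.species_on) s.sp_out += dA * (-sin_) * F * cc;
      }
    }
  // commit, clamp, track bounds
  for (int c = 0; c < nx * ny; ++c) {
    if (s.type[c] != FLUID) continue;
    double a = s.cg_s[c];
    s.amin_ever = std::min(s.amin_ever, a);
    s.amax_ever = std::max(s.amax_ever, a);
    double ac = clamp01(a);
    s.clamp_liq += std::fabs(ac - a) * h * h;
    s.alpha[c] = ac;
    if (s.species_on) {
      double mm = s.cg_r[c];
      if (mm < 0) { s.clamp_sp += -mm * h * h; mm = 0; }
      if (mm > ac) { s.clamp_sp += (mm - ac) * h * h; mm = ac; }
      s.m[c] = mm;
    }
  }
}

// --------------------------------------------------- species diffusion ---
static void diffuse_species(Sim& s, double dt) {
  if (!s.species_on || s.D <= 0) return;
  int nx = s.nx, ny = s.ny;
  const double epsc = 1e-6;
  std::vector<double>& c_of = s.cg_q;
  for (int c = 0; c < nx * ny; ++c)
    c_of[c] = s.alpha[c] > epsc ? s.m[c] / s.alpha[c] : 0.0;
  double r = dt / (s.h * s.h);
  std::vector<double>& dm = s.cg_s;
  std::fill(dm.begin(), dm.end(), 0.0);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int c = s.idc(i, j);
      if (s.type[c] != FLUID || s.alpha[c] <= epsc) continue;
      if (i < nx - 1) {
        int cr = s.idc(i + 1, j);
        if (s.type[cr] == FLUID && s.alpha[cr] > epsc) {
          double af = std::min(s.alpha[c], s.alpha[cr]);
          double flux = s.D * af * (c_of[cr] - c_of[c]);
          dm[c] += flux; dm[cr] -= flux;
        }
      }
      if (j < ny - 1) {
        int ct = s.idc(i, j + 1);
        if (s.type[ct] == FLUID && s.alpha[ct] > epsc) {
          double af = std::min(s.alpha[c], s.alpha[ct]);
          double flux = s.D * af * (c_of[ct] - c_of[c]);
          dm[c] += flux; dm[ct] -= flux;
        }
      }
    }
  for (int c = 0; c < nx * ny; ++c)
    if (s.type[c] == FLUID) {
      double mm = s.m[c] + r * dm[c];
      if (mm < 0) { s.clamp_sp += -mm * s.h * s.h; mm = 0; }
      double cap = s.alpha[c];
      if (mm > cap) { s.clamp_sp += (mm - cap) * s.h * s.h; mm = cap; }
      s.m[c] = mm;
    }
}

// ----------------------------------------------------------- momentum ----
static void momentum(Sim& s, double dt) {
  int nx = s.nx, ny = s.ny;
  double h = s.h;
  for (int c = 0; c < nx * ny; ++c) {
    double a = clamp01(s.alpha[c]);
    s.rho[c] = a * s.rho_l + (1 - a) * s.rho_g;
    s.mu[c] = a * s.mu_l + (1 - a) * s.mu_g;
  }
  std::copy(s.u.begin(), s.u.end(), s.us.begin());
  std::copy(s.v.begin(), s.v.end(), s.vs.begin());
  // u faces
  for (int j = 0; j < ny; ++j)
    for (int i = 1; i < nx; ++i) {
      int f = s.idu(i, j);
      if (s.ucode[f] != FC_INTERIOR) continue;
      int cl = s.idc(i - 1, j), cr = s.idc(i, j);
      double uc = s.u[f];
      double uE = s.u[s.idu(i + 1, j)], uW = s.u[s.idu(i - 1, j)];
      double uN = uAt(s, i, j + 1, uc), uS = uAt(s, i, j - 1, uc);
      double vf = 0.25 * (s.v[s.idv(i - 1, j)] + s.v[s.idv(i - 1, j + 1)] +
                          s.v[s.idv(i, j)] + s.v[s.idv(i, j + 1)]);
      double adv = uc * (uc > 0 ? (uc - uW) : (uE - uc)) / h +
                   vf * (vf > 0 ? (uc - uS) : (uN - uc)) / h;
      double muf = 0.5 * (s.mu[cl] + s.mu[cr]);
      double lap = (uE + uW + uN + uS - 4 * uc) / (h * h);
      double rhof = 0.5 * (s.rho[cl] + s.rho[cr]);
      double fsig = 0;
      if (s.sigma > 0 && (s.iface[cl] || s.iface[cr])) {
        double kf = 0; int nk = 0;
        if (s.iface[cl] && s.nvalid[cl]) { kf += s.kap[cl]; ++nk; }
        if (s.iface[cr] && s.nvalid[cr]) { kf += s.kap[cr]; ++nk; }
        if (nk) {
          kf /= nk;
          fsig = s.sigma * kf * (s.alpha[cr] - s.alpha[cl]) / h;
        }
      }
      double dragf = 0.5 * (s.drag[cl] + s.drag[cr]);
      double ustar = uc + dt * (-adv + (muf * lap + fsig) / rhof + s.gx);
      s.us[f] = ustar / (1 + dt * dragf / rhof);
    }
  // v faces
  for (int j = 1; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int f = s.idv(i, j);
      if (s.vcode[f] != FC_INTERIOR) continue;
      int cb = s.idc(i, j - 1), ct = s.idc(i, j);
      double vc = s.v[f];
      double vN = s.v[s.idv(i, j + 1)], vS = s.v[s.idv(i, j - 1)];
      double vE = vAt(s, i + 1, j, vc), vW = vAt(s, i - 1, j, vc);
      double uf = 0.25 * (s.u[s.idu(i, j - 1)] + s.u[s.idu(i + 1, j - 1)] +
                          s.u[s.idu(i, j)] + s.u[s.idu(i + 1, j)]);
      double adv = uf * (uf > 0 ? (vc - vW) : (vE - vc)) / h +
                   vc * (vc > 0 ? (vc - vS) : (vN - vc)) / h;
      double muf = 0.5 * (s.mu[cb] + s.mu[ct]);
      double lap = (vE + vW + vN + vS - 4 * vc) / (h * h);
      double rhof = 0.5 * (s.rho[cb] + s.rho[ct]);
      double fsig = 0;
      if (s.sigma > 0 && (s.iface[cb] || s.iface[ct])) {
        double kf = 0; int nk = 0;
        if (s.iface[cb] && s.nvalid[cb]) { kf += s.kap[cb]; ++nk; }
        if (s.iface[ct] && s.nvalid[ct]) { kf += s.kap[ct]; ++nk; }
        if (nk) {
          kf /= nk;
          fsig = s.sigma * kf * (s.alpha[ct] - s.alpha[cb]) / h;
        }
      }
      double dragf = 0.5 * (s.drag[cb] + s.drag[ct]);
      double vstar = vc + dt * (-adv + (muf * lap + fsig) / rhof + s.gy);
      s.vs[f] = vstar / (1 + dt * dragf / rhof);
    }
  std::swap(s.u, s.us);
  std::swap(s.v, s.vs);
  enforce_bcs(s);
}

// ---------------------------------------------------------- projection ---
// Solves div( (dt/rho) grad p ) = div(u*) with multigrid-preconditioned
// CG, Dirichlet p = 0 at outlet faces, Neumann elsewhere; then corrects
// velocities. The V-cycle uses damped-Jacobi smoothing and rediscretized
// (coefficient-averaged) coarse operators on the masked grid hierarchy.

struct PoissonOp {
  Sim& s;
  double dt;
  std::vector<double>& cE; std::vector<double>& cW;
  std::vector<double>& cN; std::vector<double>& cS;
  std::vector<double>& cO;
  PoissonOp(Sim& s_, double dt_)
    : s(s_), dt(dt_), cE(s_.cE), cW(s_.cW), cN(s_.cN), cS(s_.cS), cO(s_.cO) {
    int nx = s.nx, ny = s.ny;
    std::fill(cE.begin(), cE.end(), 0.0);
    std::fill(cW.begin(), cW.end(), 0.0);
    std::fill(cN.begin(), cN.end(), 0.0);
    std::fill(cS.begin(), cS.end(), 0.0);
    std::fill(cO.begin(), cO.end(), 0.0);
    double h2 = s.h * s.h;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = s.idc(i, j);
        if (s.type[c] != FLUID) continue;
        // east face
        {
          int f = s.idu(i + 1, j);
          if (s.ucode[f] == FC_INTERIOR) {
            double rf = 0.5 * (s.rho[c] + s.rho[s.idc(i + 1, j)]);
            cE[c] = dt / (rf * h2);
          } else if (s.ucode[f] == FC_OUTLET) cO[c] += 2 * dt / (s.rho[c] * h2);
        }
        {
          int f = s.idu(i, j);
          if (s.ucode[f] == FC_INTERIOR) {
            double rf = 0.5 * (s.rho[c] + s.rho[s.idc(i - 1, j)]);
            cW[c] = dt / (rf * h2);
          } else if (s.ucode[f] == FC_OUTLET) cO[c] += 2 * dt / (s.rho[c] * h2);
        }
        {
          int f = s.idv(i, j + 1);
          if (s.vcode[f] == FC_INTERIOR) {
            double rf = 0.5 * (s.rho[c] + s.rho[s.idc(i, j + 1)]);
            cN[c] = dt / (rf * h2);
          } else if (s.vcode[f] == FC_OUTLET) cO[c] += 2 * dt / (s.rho[c] * h2);
        }
        {
          int f = s.idv(i, j);
          if (s.vcode[f] == FC_INTERIOR) {
            double rf = 0.5 * (s.rho[c] + s.rho[s.idc(i, j - 1)]);
            cS[c] = dt / (rf * h2);
          } else if (s.vcode[f] == FC_OUTLET) cO[c] += 2 * dt / (s.rho[c] * h2);
        }
        s.diag[c] = cE[c] + cW[c] + cN[c] + cS[c] + cO[c];
      }
  }
  // y = A x with A = -(L) (positive definite)
  void apply(const std::vector<double>& x, std::vector<double>& y) const {
    int nx = s.nx, ny = s.ny;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = s.idc(i, j);
        if (s.type[c] != FLUID) { y[c] = 0; continue; }
        double acc = s.diag[c] * x[c];
        if (cE[c] != 0) acc -= cE[c] * x[c + 1];
        if (cW[c] != 0) acc -= cW[c] * x[c - 1];
        if (cN[c] != 0) acc -= cN[c] * x[c + nx];
        if (cS[c] != 0) acc -= cS[c] * x[c - nx];
        y[c] = acc;
      }
  }
};

static void project(Sim& s, double dt) {
  int nx = s.nx, ny = s.ny;
  int nc = nx * ny;
  double h = s.h;
  PoissonOp op(s, dt);
  // rhs b = -div(u*) (so that A p = b with A = -L is consistent)
  std::vector<double>& b = s.cg_s;
  double bnorm2 = 0;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int c = s.idc(i, j);
      if (s.type[c] != FLUID) { b[c] = 0; continue; }
      double div = (s.u[s.idu(i + 1, j)] - s.u[s.idu(i, j)] +
                    s.v[s.idv(i, j + 1)] - s.v[s.idv(i, j)]) / h;
      b[c] = -div; // A = -L is SPD; L p = div  <=>  A p = -div
      bnorm2 += div * div;
    }
  if (bnorm2 < 1e-300) { s.pcg_last = 0; return; }
  // multigrid hierarchy: structure built once, coefficients refilled
  MGHierarchy& mg = s.mgh;
  if (!s.mgh_built) {
    MGLevel L0;
    L0.nx = nx; L0.ny = ny;
    L0.act.resize(nc);
    for (int c = 0; c < nc; ++c) L0.act[c] = (s.type[c] == FLUID);
    L0.r.assign(nc, 0); L0.z.assign(nc, 0); L0.tmp.assign(nc, 0);
    L0.tmp2.assign(nc, 0);
    L0.build_lists();
    mg.lev.clear();
    mg.lev.push_back(std::move(L0));
    mg.build_structure();
    s.pprev.assign(nc, 0);
    s.mgh_built = true;
  }
  mg.lev[0].cE = op.cE; mg.lev[0].cW = op.cW;
  mg.lev[0].cN = op.cN; mg.lev[0].cS = op.cS;
  mg.lev[0].cO = op.cO; mg.lev[0].diag = s.diag;
  mg.update_values();
  auto precond = [&](const std::vector<double>& r, std::vector<double>& z) {
    std::copy(r.begin(), r.end(), mg.lev[0].r.begin());
    mg.vcycle(0);
    std::copy(mg.lev[0].z.begin(), mg.lev[0].z.end(), z.begin());
  };
  // warm start: linear extrapolation of the two previous pressures
  if (s.have_pprev) {
    for (int c = 0; c < nc; ++c) {
      double pe = 2 * s.p[c] - s.pprev[c];
      s.pprev[c] = s.p[c];
      s.p[c] = pe;
    }
  } else if (s.mgh_built) {
    std::copy(s.p.begin(), s.p.end(), s.pprev.begin());
    s.have_pprev = true;
  }
  std::vector<double>& r = s.cg_r;
  std::vector<double>& z = s.cg_z;
  std::vector<double>& q = s.cg_q;
  op.apply(s.p, r);
  double rz = 0;
  for (int c = 0; c < nc; ++c) {
    r[c] = b[c] - r[c];
    if (s.type[c] != FLUID) r[c] = 0;
  }
  std::vector<double>& d = s.cg_d;
  precond(r, z);
  for (int c = 0; c < nc; ++c) {
    d[c] = z[c];
    rz += r[c] * z[c];
  }
  double tol2 = s.ptol * s.ptol * bnorm2;
  int it = 0;
  double rn2 = 0;
  for (int c = 0; c < nc; ++c) rn2 += r[c] * r[c];
  while (rn2 > tol2 && it < s.pmaxit) {
    op.apply(d, q);
    double dq = 0;
    for (int c = 0; c < nc; ++c) dq += d[c] * q[c];
    if (dq <= 0) break;
    double alpha_cg = rz / dq;
    rn2 = 0;
    for (int c = 0; c < nc; ++c) {
      s.p[c] += alpha_cg * d[c];
      r[c] -= alpha_cg * q[c];
      rn2 += r[c] * r[c];
    }
    if (rn2 <= tol2) { ++it; break; }
    precond(r, z);
    double rz_new = 0;
    for (int c = 0; c < nc; ++c) rz_new += r[c] * z[c];
    double beta = rz_new / rz;
    rz = rz_new;
    for (int c = 0; c < nc; ++c) d[c] = z[c] + beta * d[c];
    ++it;
  }
  if (it >= s.pmaxit && rn2 > tol2)
    stop("pressure solve did not converge: %d iterations, |r|/|b| = %g",
         it, std::sqrt(rn2 / bnorm2));
  // the CG residual r equals minus the post-correction divergence, so the
  // relative residual is the scaled divergence defect of this step
  s.maxrelresid_ever = std::max(s.maxrelresid_ever,
                                std::sqrt(rn2 / bnorm2));
  s.pcg_last = it;
  s.pcg_total += it;
  // velocity correction
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i <= nx; ++i) {
      int f = s.idu(i, j);
      if (s.ucode[f] == FC_INTERIOR) {
        int cl = s.idc(i - 1, j), cr = s.idc(i, j);
        double rf = 0.5 * (s.rho[cl] + s.rho[cr]);
        s.u[f] -= dt / (rf * h) * (s.p[cr] - s.p[cl]);
      } else if (s.ucode[f] == FC_OUTLET) {
        int cin = (i == 0) ? s.idc(0, j) : s.idc(nx - 1, j);
        double gp = (i == 0) ? (s.p[cin] - (-s.p[cin])) : ((-s.p[cin]) - s.p[cin]);
        s.u[f] -= dt / (s.rho[cin] * h) * gp;
      }
    }
  for (int j = 0; j <= ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int f = s.idv(i, j);
      if (s.vcode[f] == FC_INTERIOR) {
        int cb = s.idc(i, j - 1), ct = s.idc(i, j);
        double rf = 0.5 * (s.rho[cb] + s.rho[ct]);
        s.v[f] -= dt / (rf * h) * (s.p[ct] - s.p[cb]);
      } else if (s.vcode[f] == FC_OUTLET) {
        int cin = (j == 0) ? s.idc(i, 0) : s.idc(i, ny - 1);
        double gp = (j == 0) ? (s.p[cin] - (-s.p[cin])) : ((-s.p[cin]) - s.p[cin]);
        s.v[f] -= dt / (s.rho[cin] * h) * gp;
      }
    }
  // divergence diagnostic
  double mx = 0;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int c = s.idc(i, j);
      if (s.type[c] != FLUID) continue;
      double div = (s.u[s.idu(i + 1, j)] - s.u[s.idu(i, j)] +
                    s.v[s.idv(i, j + 1)] - s.v[s.idv(i, j)]) / h;
      mx = std::max(mx, std::fabs(div));
    }
  s.maxdiv_ever = std::max(s.maxdiv_ever, mx);
}

// ------------------------------------------------------------ stepping ---
static void do_step(Sim& s, double dt) {
  enforce_bcs(s);
  smooth_alpha(s);
  normals_curvature(s);
  advect_alpha_species(s, dt);
  diffuse_species(s, dt);
  momentum(s, dt);
  project(s, dt);
  enforce_bcs(s);
  ++s.nsteps;
}

static List state_as_list(const Sim& s, double t) {
  int nc = s.nx * s.ny;
  NumericVector c(nc);
  for (int i = 0; i < nc; ++i)
    c[i] = s.alpha[i] > 1e-9 ? s.m[i] / s.alpha[i] : 0.0;
  return List::create(
    _["t"] = t, _["u"] = wrap(s.u), _["v"] = wrap(s.v),
    _["p"] = wrap(s.p), _["alpha"] = wrap(s.alpha), _["m"] = wrap(s.m),
    _["c"] = c);
}

static List diag_as_list(const Sim& s) {
  return List::create(
    _["liq_in"] = s.liq_in, _["liq_out"] = s.liq_out,
    _["sp_in"] = s.sp_in, _["sp_out"] = s.sp_out,
    _["alpha_min"] = s.amin_ever == 1e300 ? NA_REAL : s.amin_ever,
    _["alpha_max"] = s.amax_ever == -1e300 ? NA_REAL : s.amax_ever,
    _["clamp_liq"] = s.clamp_liq, _["clamp_sp"] = s.clamp_sp,
    _["max_div"] = s.maxdiv_ever,
    _["max_rel_resid"] = s.maxrelresid_ever,
    _["nsteps"] = (double)s.nsteps,
    _["pcg_total"] = (double)s.pcg_total, _["pcg_last"] = s.pcg_last);
}

// Zone reductions: rows (zone 1..3) x cols (vol, liq, smass, mu, mv, mspeed)
static void zone_reduce(const Sim& s, double out[3][6]) {
  double h2 = s.h * s.h;
  double suma[3] = {0, 0, 0}, sumc[3] = {0, 0, 0}, summ[3] = {0, 0, 0};
  double sumu[3] = {0, 0, 0}, sumv[3] = {0, 0, 0}, sumsp[3] = {0, 0, 0};
  for (int j = 0; j < s.ny; ++j)
    for (int i = 0; i < s.nx; ++i) {
      int c = s.idc(i, j);
      int z = s.zone[c];
      if (z < 1 || z > 3) continue;
      double a = s.alpha[c];
      double uc = 0.5 * (s.u[s.idu(i, j)] + s.u[s.idu(i + 1, j)]);
      double vc = 0.5 * (s.v[s.idv(i, j)] + s.v[s.idv(i, j + 1)]);
      suma[z - 1] += a;
      sumc[z - 1] += 1;
      summ[z - 1] += s.m[c];
      sumu[z - 1] += a * uc;
      sumv[z - 1] += a * vc;
      sumsp[z - 1] += a * std::sqrt(uc * uc + vc * vc);
    }
  for (int z = 0; z < 3; ++z) {
    out[z][0] = sumc[z] * h2;                       // zone volume
    out[z][1] = sumc[z] > 0 ? suma[z] / sumc[z] : NA_REAL; // liquid fraction
    out[z][2] = summ[z] * h2;                       // species mass
    if (suma[z] > 1e-12) {
      out[z][3] = sumu[z] / suma[z];
      out[z][4] = sumv[z] / suma[z];
      out[z][5] = sumsp[z] / suma[z];
    } else {
      out[z][3] = NA_REAL; out[z][4] = NA_REAL; out[z][5] = NA_REAL;
    }
  }
}

// ----------------------------------------------------------- exports -----

// [[Rcpp::export]]
double cpp_compute_dt(List geom, List params, List state) {
  Sim s = build_sim(geom, params, state);
  enforce_bcs(s);
  return stable_dt(s);
}

// [[Rcpp::export]]
List cpp_apply_bcs(List geom, List params, List state) {
  Sim s = build_sim(geom, params, state);
  enforce_bcs(s);
  return state_as_list(s, as<double>(state["t"]));
}

// [[Rcpp::export]]
List cpp_step(List geom, List params, List state, double dt) {
  Sim s = build_sim(geom, params, state);
  do_step(s, dt);
  List out = state_as_list(s, as<double>(state["t"]) + dt);
  out["diag"] = diag_as_list(s);
  return out;
}

// Species-only step: advection by the (frozen) velocity and liquid field,
// plus diffusion. Used for transport verification.
// [[Rcpp::export]]
List cpp_step_species(List geom, List params, List state, double dt) {
  Sim s = build_sim(geom, params, state);
  enforce_bcs(s);
  smooth_alpha(s);
  normals_curvature(s);
  std::vector<double> a0 = s.alpha;
  advect_alpha_species(s, dt);
  s.alpha = a0; // carrier frozen: keep transported m, restore alpha
  diffuse_species(s, dt);
  List out = state_as_list(s, as<double>(state["t"]) + dt);
  out["diag"] = diag_as_list(s);
  return out;
}

// [[Rcpp::export]]
List cpp_advance(List geom, List params, List state, double t_end,
                 NumericVector checkpoint_times, double dt_out) {
  Sim s = build_sim(geom, params, state);
  double t = as<double>(state["t"]);
  enforce_bcs(s);
  std::vector<double> ckpt(checkpoint_times.begin(), checkpoint_times.end());
  std::sort(ckpt.begin(), ckpt.end());
  List checkpoints;
  // series storage
  std::vector<double> ser; // rows of: time, zone, vol, liqfrac, smass, mu, mv, mspeed
  std::vector<double> glob; // time, liq_total, sp_total, in/out cumulatives
  double h2 = s.h * s.h;
  size_t next_ck = 0;
  while (next_ck < ckpt.size() && ckpt[next_ck] <= t + 1e-15) ++next_ck;
  auto record = [&](double tt) {
    double zr[3][6];
    zone_reduce(s, zr);
    for (int z = 0; z < 3; ++z) {
      ser.push_back(tt); ser.push_back(z + 1);
      for (int k = 0; k < 6; ++k) ser.push_back(zr[z][k]);
    }
    double liq = 0, sp = 0;
    for (int c = 0; c < s.nx * s.ny; ++c)
      if (s.type[c] == FLUID) { liq += s.alpha[c]; sp += s.m[c]; }
    glob.push_back(tt); glob.push_back(liq * h2); glob.push_back(sp * h2);
    glob.push_back(s.liq_in); glob.push_back(s.liq_out);
    glob.push_back(s.sp_in); glob.push_back(s.sp_out);
  };
  record(t);
  double t_next_rec = t + dt_out;
  int guard = 0;
  while (t < t_end - 1e-12) {
    double dt = stable_dt(s);
    double lim = t_end;
    if (next_ck < ckpt.size()) lim = std::min(lim, ckpt[next_ck]);
    lim = std::min(lim, t_next_rec);
    if (t + dt > lim) dt = lim - t;
    if (dt <= 0) { if (++guard > 10) stop("time stepping stalled"); t = lim; continue; }
    guard = 0;
    do_step(s, dt);
    t += dt;
    if (next_ck < ckpt.size() && t >= ckpt[next_ck] - 1e-12) {
      checkpoints.push_back(state_as_list(s, t));
      ++next_ck;
    }
    if (t >= t_next_rec - 1e-12) {
      record(t);
      t_next_rec += dt_out;
    }
    if (s.nsteps % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  if (glob.empty() || glob[glob.size() - 7] < t - 1e-12) record(t);
  int nrow = (int)(ser.size() / 8);
  NumericMatrix series(nrow, 8);
  for (int r0 = 0; r0 < nrow; ++r0)
    for (int k = 0; k < 8; ++k) series(r0, k) = ser[r0 * 8 + k];
  colnames(series) = CharacterVector::create(
    "time", "zone", "zone_volume", "liquid_fraction", "species_mass",
    "mean_u", "mean_v", "mean_cell_speed");
  int ng = (int)(glob.size() / 7);
  NumericMatrix globals(ng, 7);
  for (int r0 = 0; r0 < ng; ++r0)
    for (int k = 0; k < 7; ++k) globals(r0, k) = glob[r0 * 7 + k];
  colnames(globals) = CharacterVector::create(
    "time", "liquid_total", "species_total", "liq_in", "liq_out",
    "sp_in", "sp_out");
  return List::create(
    _["series"] = series, _["globals"] = globals,
    _["checkpoints"] = checkpoints,
    _["final_state"] = state_as_list(s, t),
    _["diag"] = diag_as_list(s));
}

// [[Rcpp::export]]
List cpp_zone_reduce(List geom, List params, List state) {
  Sim s = build_sim(geom, params, state);
  double zr[3][6];
  zone_reduce(s, zr);
  NumericMatrix out(3, 6);
  for (int z = 0; z < 3; ++z)
    for (int k = 0; k < 6; ++k) out(z, k) = zr[z][k];
  colnames(out) = CharacterVector::create(
    "zone_volume", "liquid_fraction", "species_mass", "mean_u", "mean_v",
    "mean_cell_speed");
  return List::create(_["zones"] = out);
}
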