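#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// harmonic mean of two cell properties; zero if either side does not conduct
static inline double harm(double a, double b) {
  if (a <= 0.0 || b <= 0.0) return 0.0;
  return 2.0 * a * b / (a + b);
}

// Face conductances of the cell-centred 7-point stencil.
// gx[v] couples cell v=(i,j,k) with (i+1,j,k); value = h * harm(s_v, s_n)
// (face area h^2 over centre distance h).  Faces touching a metal cell
// conduct only where the metal is exposed (the electrode window); faces
// between two metal cells are dropped (both are Dirichlet).
// [[Rcpp::export]]
List face_conductance_cpp(IntegerVector dims, NumericVector sigma,
                          LogicalVector metal, LogicalVector exposed, double h) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz, sy = nx, sz = nx * ny;
  NumericVector gx(n), gy(n), gz(n);
  const double *S = sigma.begin();
  const int *M = metal.begin(), *E = exposed.begin();
  double *Gx = gx.begin(), *Gy = gy.begin(), *Gz = gz.begin();
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        const int v = i + sy * j + sz * k;
        for (int f = 0; f < 3; f++) {
          int w;
          if (f == 0) { if (i + 1 >= nx) continue; w = v + 1; }
          else if (f == 1) { if (j + 1 >= ny) continue; w = v + sy; }
          else { if (k + 1 >= nz) continue; w = v + sz; }
          double g = harm(S[v], S[w]);
          if (g > 0.0) {
            if (M[v] && M[w]) g = 0.0;
            else if (M[v] && !E[v]) g = 0.0;   // coated metal face
            else if (M[w] && !E[w]) g = 0.0;
          }
          double gv = h * g;
          if (f == 0) Gx[v] = gv; else if (f == 1) Gy[v] = gv; else Gz[v] = gv;
        }
      }
  return List::create(_["gx"] = gx, _["gy"] = gy, _["gz"] = gz);
}

// Preconditioned conjugate gradient for div(sigma grad V) = 0 with
// Dirichlet values vfix on fixed (metal) cells, optional half-cell
// conductance gb to a grounded outer boundary, natural (no-flux)
// boundaries elsewhere.  Jacobi preconditioner; deterministic.
// [[Rcpp::export]]
List cg_potential_cpp(IntegerVector dims, NumericVector gx, NumericVector gy,
                      NumericVector gz, NumericVector gb, LogicalVector unknown,
                      NumericVector vfix, NumericVector x0, double tol, int maxit) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz, sy = nx, sz = nx * ny;
  const double *Gx = gx.begin(), *Gy = gy.begin(), *Gz = gz.begin();
  const double *Gb = gb.begin(), *VF = vfix.begin();
  const int *U = unknown.begin();
  std::vector<double> diag(n, 0.0), b(n, 0.0), x(n, 0.0);
  std::vector<char> act(n, 0);

  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        const int v = i + sy * j + sz * k;
        if (!U[v]) { x[v] = VF[v]; continue; }
        double d = Gb[v], bv = 0.0, g;
        if (i > 0      && (g = Gx[v - 1])  > 0) { d += g; if (!U[v - 1])  bv += g * VF[v - 1];  }
        if (i + 1 < nx && (g = Gx[v])      > 0) { d += g; if (!U[v + 1])  bv += g * VF[v + 1];  }
        if (j > 0      && (g = Gy[v - sy]) > 0) { d += g; if (!U[v - sy]) bv += g * VF[v - sy]; }
        if (j + 1 < ny && (g = Gy[v])      > 0) { d += g; if (!U[v + sy]) bv += g * VF[v + sy]; }
        if (k > 0      && (g = Gz[v - sz]) > 0) { d += g; if (!U[v - sz]) bv += g * VF[v - sz]; }
        if (k + 1 < nz && (g = Gz[v])      > 0) { d += g; if (!U[v + sz]) bv += g * VF[v + sz]; }
        if (d > 0.0) { act[v] = 1; diag[v] = d; b[v] = bv; x[v] = x0[v]; }
      }

  double bnorm = 0.0;
  for (int v = 0; v < n; v++) if (act[v]) bnorm += b[v] * b[v];
  bnorm = std::sqrt(bnorm);

  NumericVector V(n);
  if (bnorm == 0.0) {
    for (int v = 0; v < n; v++) V[v] = act[v] ? 0.0 : (U[v] ? 0.0 : VF[v]);
    return List::create(_["V"] = V, _["iterations"] = 0, _["relres"] = 0.0,
                        _["bnorm"] = 0.0);
  }

  std::vector<double> r(n, 0.0), z(n, 0.0), p(n, 0.0), Ap(n, 0.0);
  auto Aop = [&](const std::vector<double> &xv, std::vector<double> &yv) {
    for (int k = 0; k < nz; k++)
      for (int j = 0; j < ny; j++)
        for (int i = 0; i < nx; i++) {
          const int v = i + sy * j + sz * k;
          if (!act[v]) continue;
          double s = diag[v] * xv[v];
          if (i > 0      && act[v - 1])  s -= Gx[v - 1]  * xv[v - 1];
          if (i + 1 < nx && act[v + 1])  s -= Gx[v]      * xv[v + 1];
          if (j > 0      && act[v - sy]) s -= Gy[v - sy] * xv[v - sy];
          if (j + 1 < ny && act[v + sy]) s -= Gy[v]      * xv[v + sy];
          if (k > 0      && act[v - sz]) s -= Gz[v - sz] * xv[v - sz];
          if (k + 1 < nz && act[v + sz]) s -= Gz[v]      * xv[v + sz];
          yv[v] = s;
        }
  };

  Aop(x, Ap);
  double rz = 0.0;
  for (int v = 0; v < n; v++) if (act[v]) {
    r[v] = b[v] - Ap[v];
    z[v] = r[v] / diag[v];
    p[v] = z[v];
    rz += r[v] * z[v];
  }
  double relres = 1.0;
  int it = 0;
  for (; it < maxit; it++) {
    double rn = 0.0;
    for (int v = 0; v < n; v++) if (act[v]) rn += r[v] * r[v];
    relres = std::sqrt(rn) / bnorm;
    if (relres <= tol) break;
    Aop(p, Ap);
    double pAp = 0.0;
    for (int v = 0; v < n; v++) if (act[v]) pAp += p[v] * Ap[v];
    if (pAp <= 0.0) break;  // numerically singular
    const double alpha = rz / pAp;
    for (int v = 0; v < n; v++) if (act[v]) { x[v] += alpha * p[v]; r[v] -= alpha * Ap[v]; }
    double rz_new = 0.0;
    for (int v = 0; v < n; v++) if (act[v]) { z[v] = r[v] / diag[v]; rz_new += r[v] * z[v]; }
    const double beta = rz_new / rz;
    rz = rz_new;
    for (int v = 0; v < n; v++) if (act[v]) p[v] = z[v] + beta * p[v];
  }
  for (int v = 0; v < n; v++) V[v] = x[v];
  return List::create(_["V"] = V, _["iterations"] = it, _["relres"] = relres,
                      _["bnorm"] = bnorm);
}

// Net current out of each driven electrode (sum of face currents from metal
// cells into conducting non-metal cells) plus leakage into the grounded
// outer boundary.
// [[Rcpp::export]]
List terminal_current_cpp(IntegerVector dims, NumericVector gx, NumericVector gy,
                          NumericVector gz, NumericVector gb, NumericVector V,
                          IntegerVector eid, LogicalVector unknown) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int sy = nx, sz = nx * ny;
  const double *Gx = gx.begin(), *Gy = gy.begin(), *Gz = gz.begin();
  const double *Gb = gb.begin(), *Vp = V.begin();
  const int *E = eid.begin(), *U = unknown.begin();
  double I[2] = {0.0, 0.0}, leak = 0.0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        const int v = i + sy * j + sz * k;
        if (U[v]) leak += Gb[v] * Vp[v];
        for (int f = 0; f < 3; f++) {
          int w; double g;
          if (f == 0) { if (i + 1 >= nx) continue; w = v + 1;  g = Gx[v]; }
          else if (f == 1) { if (j + 1 >= ny) continue; w = v + sy; g = Gy[v]; }
          else { if (k + 1 >= nz) continue; w = v + sz; g = Gz[v]; }
          if (g <= 0.0) continue;
          if (E[v] > 0 && E[w] == 0 && U[w]) I[E[v] - 1] += g * (Vp[v] - Vp[w]);
          else if (E[w] > 0 && E[v] == 0 && U[v]) I[E[w] - 1] += g * (Vp[w] - Vp[v]);
        }
      }
  return List::create(_["I"] = NumericVector::create(I[0], I[1]),
                      _["leak"] = leak);
}

// Volumetric Joule heat density (W/m^3) from face currents; dissipation on a
// face between two free cells is split evenly, a face to a Dirichlet metal
// cell deposits entirely on the tissue side (the metal is an ideal conductor).
// [[Rcpp::export]]
NumericVector joule_field_cpp(IntegerVector dims, NumericVector gx, NumericVector gy,
                              NumericVector gz, NumericVector gb, NumericVector V,
                              LogicalVector unknown, double h) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz, sy = nx, sz = nx * ny;
  const double *Gx = gx.begin(), *Gy = gy.begin(), *Gz = gz.begin();
  const double *Gb = gb.begin(), *Vp = V.begin();
  const int *U = unknown.begin();
  NumericVector q(n);
  double *Q = q.begin();
  const double vol = h * h * h;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        const int v = i + sy * j + sz * k;
        if (U[v] && Gb[v] > 0.0) Q[v] += Gb[v] * Vp[v] * Vp[v];
        for (int f = 0; f < 3; f++) {
          int w; double g;
          if (f == 0) { if (i + 1 >= nx) continue; w = v + 1;  g = Gx[v]; }
          else if (f == 1) { if (j + 1 >= ny) continue; w = v + sy; g = Gy[v]; }
          else { if (k + 1 >= nz) continue; w = v + sz; g = Gz[v]; }
          if (g <= 0.0) continue;
          const double dv = Vp[v] - Vp[w], e = g * dv * dv;
          if (U[v] && U[w]) { Q[v] += 0.5 * e; Q[w] += 0.5 * e; }
          else if (U[v]) Q[v] += e;
          else if (U[w]) Q[w] += e;
        }
      }
  for (int v = 0; v < n; v++) Q[v] /= vol;
  return q;
}

// One transient bioheat step.  Explicit update where the local diffusion
// number allows it, point-implicit (unconditionally bounded) on stiff cells
// such as the metal electrode shell.  kx/ky/kz are thermal face conductances
// (W/K), kb a half-cell conductance to a Dirichlet boundary at t_bound,
// cvol the volumetric heat capacity rho*Cp (J/(m^3 K)), q the volumetric
// source (W/m^3), perf the Pennes sink coefficient omega_b*rho_b*Cp_b
// (W/(m^3 K)) toward t_perf.  Cells in clampmask are held at t_clamp.
// Updates the dwell-time and running-maximum trackers in place.
// [[Rcpp::export]]
List thermal_step_cpp(IntegerVector dims, NumericVector told, NumericVector tnew,
                      NumericVector kx, NumericVector ky, NumericVector kz,
                      NumericVector kb, double t_bound,
                      NumericVector cvol, NumericVector q, NumericVector perf,
                      double t_perf, double dt, double h,
                      LogicalVector clampmask, double t_clamp,
                      NumericVector time_above, double t_damage,
                      NumericVector tmax, NumericVector tref) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz, sy = nx, sz = nx * ny;
  const double *To = told.begin(), *Kx = kx.begin(), *Ky = ky.begin(), *Kz = kz.begin();
  const double *Kb = kb.begin(), *C = cvol.begin(), *Q = q.begin(), *P = perf.begin();
  const double *Tr = tref.begin();
  const int *CL = clampmask.begin();
  double *Tn = tnew.begin(), *TA = time_above.begin(), *TM = tmax.begin();
  const double vol = h * h * h;
  double maxT = R_NegInf, drift = 0.0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        const int v = i + sy * j + sz * k;
        if (C[v] <= 0.0) { Tn[v] = To[v]; continue; }
        double t;
        if (CL[v]) {
          t = t_clamp;
        } else {
          double sk = Kb[v], flux = Kb[v] * (t_bound - To[v]), g;
          if (i > 0      && (g = Kx[v - 1])  > 0) { sk += g; flux += g * (To[v - 1]  - To[v]); }
          if (i + 1 < nx && (g = Kx[v])      > 0) { sk += g; flux += g * (To[v + 1]  - To[v]); }
          if (j > 0      && (g = Ky[v - sy]) > 0) { sk += g; flux += g * (To[v - sy] - To[v]); }
          if (j + 1 < ny && (g = Ky[v])      > 0) { sk += g; flux += g * (To[v + sy] - To[v]); }
          if (k > 0      && (g = Kz[v - sz]) > 0) { sk += g; flux += g * (To[v - sz] - To[v]); }
          if (k + 1 < nz && (g = Kz[v])      > 0) { sk += g; flux += g * (To[v + sz] - To[v]); }
          const double Cv = C[v] * vol, Pv = P[v] * vol;
          const double lam = dt * (sk + Pv) / Cv;
          if (lam <= 0.95) {
            t = To[v] + dt * (flux + Q[v] * vol + Pv * (t_perf - To[v])) / Cv;
          } else {
            t = (Cv * To[v] + dt * (flux + sk * To[v] + Q[v] * vol + Pv * t_perf)) /
                (Cv + dt * (sk + Pv));
          }
        }
        Tn[v] = t;
        if (t >= t_damage) TA[v] += dt;
        if (t > TM[v]) TM[v] = t;
        if (t > maxT) maxT = t;
        const double d = std::fabs(t - Tr[v]);
        if (d > drift) drift = d;
      }
  return List::create(_["max_temperature"] = maxT, _["max_drift"] = drift);
}

// Implicit first-order upwind plug-flow advection of the blood cells along
// the x axis (unconditionally stable sweep in the flow direction); t_in is
// the inflow temperature.  Modifies T in place.
// [[Rcpp::export]]
void advect_x_cpp(IntegerVector dims, NumericVector T, LogicalVector blood,
                  double courant, double t_in, int dir) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int sy = nx, sz = nx * ny;
  double *Tp = T.begin();
  const int *B = blood.begin();
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      const int base = sy * j + sz * k;
      if (dir >= 0) {
        for (int i = 0; i < nx; i++) {
          const int v = base + i;
          if (!B[v]) continue;
          const double up = (i > 0 && B[v - 1]) ? Tp[v - 1] : t_in;
          Tp[v] = (Tp[v] + courant * up) / (1.0 + courant);
        }
      } else {
        for (int i = nx - 1; i >= 0; i--) {
          const int v = base + i;
          if (!B[v]) continue;
          const double up = (i + 1 < nx && B[v + 1]) ? Tp[v + 1] : t_in;
          Tp[v] = (Tp[v] + courant * up) / (1.0 + courant);
        }
      }
    }
}

// Largest stable explicit time step over the cells in `soft` (the tissue,
// blood and gel cells; the stiff metal/insulator cells are advanced
// point-implicitly and do not constrain dt).
// [[Rcpp::export]]
double stability_dt_cpp(IntegerVector dims, NumericVector kx, NumericVector ky,
                        NumericVector kz, NumericVector kb, NumericVector cvol,
                        NumericVector perf, double h, LogicalVector soft) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int sy = nx, sz = nx * ny;
  const double *Kx = kx.begin(), *Ky = ky.begin(), *Kz = kz.begin();
  const double *Kb = kb.begin(), *C = cvol.begin(), *P = perf.begin();
  const int *S = soft.begin();
  const double vol = h * h * h;
  double dtmin = R_PosInf;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        const int v = i + sy * j + sz * k;
        if (!S[v] || C[v] <= 0.0) continue;
        double sk = Kb[v];
        if (i > 0) sk += Kx[v - 1];
        if (i + 1 < nx) sk += Kx[v];
        if (j > 0) sk += Ky[v - sy];
        if (j + 1 < ny) sk += Ky[v];
        if (k > 0) sk += Kz[v - sz];
        if (k + 1 < nz) sk += Kz[v];
        sk += P[v] * vol;
        if (sk <= 0.0) continue;
        const double dt = C[v] * vol / sk;
        if (dt < dtmin) dtmin = dt;
      }
  return dtmin;
}

// Face-connected (6-neighbour) component labelling of a voxel mask.
// Components are numbered in order of their smallest linear voxel index
// (deterministic tie-break).  Works for 2D masks with nz = 1.
// [[Rcpp::export]]
List label_components_cpp(IntegerVector dims, LogicalVector mask) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz, sy = nx, sz = nx * ny;
  const int *M = mask.begin();
  IntegerVector labels(n);
  int *L = labels.begin();
  std::vector<int> sizes;
  std::queue<int> qu;
  int lab = 0;
  for (int v0 = 0; v0 < n; v0++) {
    if (!M[v0] || L[v0]) continue;
    lab++;
    int sz_c = 0;
    L[v0] = lab;
    qu.push(v0);
    while (!qu.empty()) {
      const int v = qu.front(); qu.pop();
      sz_c++;
      const int i = v % nx, j = (v / nx) % ny, k = v / sz;
      const int nb[6] = {
        i > 0 ? v - 1 : -1, i + 1 < nx ? v + 1 : -1,
        j > 0 ? v - sy : -1, j + 1 < ny ? v + sy : -1,
        k > 0 ? v - sz : -1, k + 1 < nz ? v + sz : -1 };
      for (int t = 0; t < 6; t++) {
        const int w = nb[t];
        if (w >= 0 && M[w] && !L[w]) { L[w] = lab; qu.push(w); }
      }
    }
    sizes.push_back(sz_c);
  }
  return List::create(_["labels"] = labels, _["sizes"] = wrap(sizes));
}
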