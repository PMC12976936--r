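// Membrane finite-element kernels.
//
// 4-node hyperelastic membrane quad (no bending), total-Lagrangian, 2x2 Gauss.
// Incompressibility is enforced analytically through the plane-stress thickness
// stretch lambda3^2 = det(A)/det(a), so the Yeoh energy is evaluated at
//   I1 = tr(A^{-1} a) + det(A)/det(a)
// where A and a are the reference and current in-plane metric tensors at a
// Gauss point. Energies are in kPa*mm^3 (microjoule); geometry in mm.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct GP { double xi, eta; };
static const GP GPS[4] = {
  {-0.57735026918962573, -0.57735026918962573},
  { 0.57735026918962573, -0.57735026918962573},
  { 0.57735026918962573,  0.57735026918962573},
  {-0.57735026918962573,  0.57735026918962573}
};
static const double SGN[4][2] = {{-1,-1},{1,-1},{1,1},{-1,1}};

// bilinear shape-function derivatives at the four Gauss points (constant)
static double DN[4][4][2];
static bool dn_init = [](){
  for (int gp = 0; gp < 4; ++gp)
    for (int a = 0; a < 4; ++a) {
      DN[gp][a][0] = 0.25 * SGN[a][0] * (1.0 + SGN[a][1] * GPS[gp].eta);
      DN[gp][a][1] = 0.25 * SGN[a][1] * (1.0 + SGN[a][0] * GPS[gp].xi);
    }
  return true;
}();

// energy + gradient for one element; X, x are 3x4 (column = node, current
// coords in x). grad accumulates dPi/dx into a 12-vector (node-major xyz).
// Returns false if the element is degenerate/inverted at any Gauss point.
// strict = true: fail (return false) on inversion. strict = false: clamp the
// current metric determinant at a small positive floor so the energy stays a
// finite barrier usable inside line searches / quasi-Newton minimization.
// ks adds a small convex 2-D compressible neo-Hookean stabilization
//   W_s = ks (tr(A^{-1} a) - 2 - ln(det a / det A))
// that gives wrinkling (compressive) states a mild positive stiffness a bare
// membrane lacks; ks is a small fraction of C10 (see the R-level docs).
inline bool elem_energy_grad(const double X[3][4], const double x[3][4],
                             double C10, double C20, double C30, double ks,
                             double t0, double &energy, double *grad,
                             bool want_grad, bool strict = true) {
  energy = 0.0;
  if (want_grad) for (int k = 0; k < 12; ++k) grad[k] = 0.0;
  for (int gp = 0; gp < 4; ++gp) {
    const double (*dN)[2] = DN[gp];
    // reference and current covariant bases G, g (3x2)
    double G[3][2] = {{0,0},{0,0},{0,0}}, g[3][2] = {{0,0},{0,0},{0,0}};
    for (int k = 0; k < 3; ++k)
      for (int j = 0; j < 2; ++j)
        for (int a = 0; a < 4; ++a) {
          G[k][j] += X[k][a] * dN[a][j];
          g[k][j] += x[k][a] * dN[a][j];
        }
    double A11 = G[0][0]*G[0][0] + G[1][0]*G[1][0] + G[2][0]*G[2][0];
    double A12 = G[0][0]*G[0][1] + G[1][0]*G[1][1] + G[2][0]*G[2][1];
    double A22 = G[0][1]*G[0][1] + G[1][1]*G[1][1] + G[2][1]*G[2][1];
    double a11 = g[0][0]*g[0][0] + g[1][0]*g[1][0] + g[2][0]*g[2][0];
    double a12 = g[0][0]*g[0][1] + g[1][0]*g[1][1] + g[2][0]*g[2][1];
    double a22 = g[0][1]*g[0][1] + g[1][1]*g[1][1] + g[2][1]*g[2][1];
    double detA = A11*A22 - A12*A12;
    double deta = a11*a22 - a12*a12;
    if (detA <= 0.0) return false;
    if (deta <= 1e-6 * detA) {
      if (strict) return false;
      deta = 1e-6 * detA;  // barrier plateau for the minimization stage
    }
    double iA11 =  A22/detA, iA12 = -A12/detA, iA22 =  A11/detA;
    double ia11 =  a22/deta, ia12 = -a12/deta, ia22 =  a11/deta;
    double trAia = iA11*a11 + 2.0*iA12*a12 + iA22*a22;
    double J2 = deta / detA;                  // (lambda1*lambda2)^2
    double I1 = trAia + 1.0 / J2;
    double xI = I1 - 3.0;
    double W  = (C10 + (C20 + C30 * xI) * xI) * xI;
    double Ws = ks * (trAia - 2.0 - std::log(J2));
    double dA = std::sqrt(detA);              // reference area scale (weight 1)
    energy += t0 * dA * (W + Ws);
    if (want_grad) {
      double Wp = C10 + (2.0*C20 + 3.0*C30 * xI) * xI;
      // dPi/dx = 2 t0 dA (g Meff dN^T) with
      // Meff = Wp (A^{-1} - (detA/deta) a^{-1}) + ks (A^{-1} - a^{-1})
      double s = detA / deta;
      double M11 = Wp * (iA11 - s*ia11) + ks * (iA11 - ia11);
      double M12 = Wp * (iA12 - s*ia12) + ks * (iA12 - ia12);
      double M22 = Wp * (iA22 - s*ia22) + ks * (iA22 - ia22);
      double c = 2.0 * t0 * dA;
      for (int a = 0; a < 4; ++a) {
        double m1 = M11*dN[a][0] + M12*dN[a][1];
        double m2 = M12*dN[a][0] + M22*dN[a][1];
        for (int k = 0; k < 3; ++k)
          grad[3*a + k] += c * (g[k][0]*m1 + g[k][1]*m2);
      }
    }
  }
  return true;
}

} // namespace

// [[Rcpp::export(name = ".membrane_assemble")]]
List membrane_assemble(NumericMatrix nodes, IntegerMatrix quads,
                       NumericVector u, NumericVector c10, NumericVector c20,
                       NumericVector c30, NumericVector stab,
                       NumericVector thick, bool want_tangent,
                       bool strict = true) {
  const int n = nodes.nrow(), m = quads.nrow();
  if ((int)u.size() != 3 * n) stop("displacement vector has wrong length");
  NumericVector grad(3 * n);
  double energy = 0.0;
  int bad_elem = 0;

  IntegerVector Ki, Kj;
  NumericVector Kx;
  if (want_tangent) {
    Ki = IntegerVector(m * 144);
    Kj = IntegerVector(m * 144);
    Kx = NumericVector(m * 144);
  }

  double X[3][4], xc[3][4], ge[12], gp_[12], gm[12];
  for (int e = 0; e < m; ++e) {
    int id[4];
    double L = 0.0;
    for (int a = 0; a < 4; ++a) {
      id[a] = quads(e, a) - 1;
      for (int k = 0; k < 3; ++k) {
        X[k][a] = nodes(id[a], k);
        xc[k][a] = X[k][a] + u[3 * id[a] + k];
      }
    }
    for (int k = 0; k < 3; ++k) {
      double d = X[k][0] - X[k][2];
      L += d * d;
    }
    L = std::sqrt(L) + 1.0;
    double ee;
    if (!elem_energy_grad(X, xc, c10[e], c20[e], c30[e], stab[e], thick[e],
                          ee, ge, true, strict)) {
      bad_elem = e + 1;
      break;
    }
    energy += ee;
    for (int a = 0; a < 4; ++a)
      for (int k = 0; k < 3; ++k)
        grad[3 * id[a] + k] += ge[3 * a + k];

    if (want_tangent) {
      // central-difference tangent of the analytic gradient, symmetrized
      double Ke[12][12];
      double h = 1e-5 * L;
      bool ok = true;
      for (int d = 0; d < 12 && ok; ++d) {
        int a = d / 3, k = d % 3;
        double keep = xc[k][a];
        double dum;
        xc[k][a] = keep + h;
        ok = ok && elem_energy_grad(X, xc, c10[e], c20[e], c30[e], stab[e],
                                    thick[e], dum, gp_, true);
        xc[k][a] = keep - h;
        ok = ok && elem_energy_grad(X, xc, c10[e], c20[e], c30[e], stab[e],
                                    thick[e], dum, gm, true);
        xc[k][a] = keep;
        if (ok)
          for (int r = 0; r < 12; ++r) Ke[r][d] = (gp_[r] - gm[r]) / (2.0 * h);
      }
      if (!ok) { bad_elem = e + 1; break; }
      int base = e * 144, q = 0;
      for (int r = 0; r < 12; ++r)
        for (int cdx = 0; cdx < 12; ++cdx, ++q) {
          Ki[base + q] = 3 * id[r / 3] + r % 3 + 1;
          Kj[base + q] = 3 * id[cdx / 3] + cdx % 3 + 1;
          Kx[base + q] = 0.5 * (Ke[r][cdx] + Ke[cdx][r]);
        }
    }
  }

  List out = List::create(_["energy"] = energy, _["grad"] = grad,
                          _["bad_elem"] = bad_elem);
  if (want_tangent) {
    out["Ki"] = Ki; out["Kj"] = Kj; out["Kx"] = Kx;
  }
  return out;
}

// Per-element strain energy (same kinematics), for energy-share diagnostics.
// [[Rcpp::export(name = ".membrane_element_energy")]]
NumericVector membrane_element_energy(NumericMatrix nodes, IntegerMatrix quads,
                                      NumericVector u, NumericVector c10,
                                      NumericVector c20, NumericVector c30,
                                      NumericVector stab,
                                      NumericVector thick) {
  const int m = quads.nrow();
  NumericVector out(m);
  double X[3][4], xc[3][4];
  for (int e = 0; e < m; ++e) {
    for (int a = 0; a < 4; ++a) {
      int id = quads(e, a) - 1;
      for (int k = 0; k < 3; ++k) {
        X[k][a] = nodes(id, k);
        xc[k][a] = X[k][a] + u[3 * id + k];
      }
    }
    double ee;
    if (!elem_energy_grad(X, xc, c10[e], c20[e], c30[e], stab[e], thick[e],
                          ee, nullptr, false))
      ee = NA_REAL;
    out[e] = ee;
  }
  return out;
}

// Fused reduced-coordinate objective: expands the reduced displacement vector
// (free DOFs + eliminated slave DOFs at ramp fraction alpha), assembles the
// membrane energy and gradient, and reduces the gradient back onto the free
// DOFs (slave contributions accumulate onto their masters). One call per
// line-search / quasi-Newton evaluation keeps the R-level overhead out of the
// hot loop.
// [[Rcpp::export(name = ".membrane_obj")]]
List membrane_obj(NumericMatrix nodes, IntegerMatrix quads,
                  NumericVector u_red, IntegerVector map_dof,
                  IntegerVector sd3, NumericVector offs, double alpha,
                  NumericVector c10, NumericVector c20, NumericVector c30,
                  NumericVector stab, NumericVector thick, bool strict) {
  const int ndof = map_dof.size();
  const int m = quads.nrow();
  const int nn = nodes.nrow();
  const double *nd = REAL(nodes);        // column-major: nd[k*nn + i]
  const int *qd = INTEGER(quads);        // column-major: qd[a*m + e]
  const int *md = INTEGER(map_dof);
  const double *ur = REAL(u_red);
  std::vector<double> u(ndof, 0.0);
  for (int d = 0; d < ndof; ++d)
    if (md[d] > 0) u[d] = ur[md[d] - 1];
  for (int k = 0; k < (int)sd3.size(); ++k)
    u[sd3[k] - 1] += alpha * offs[k];

  std::vector<double> gfull(ndof, 0.0);
  double energy = 0.0;
  int bad_elem = 0;
  const double *p10 = REAL(c10), *p20 = REAL(c20), *p30 = REAL(c30);
  const double *pks = REAL(stab), *pth = REAL(thick);
  double X[3][4], xc[3][4], ge[12];
  for (int e = 0; e < m; ++e) {
    int id[4];
    for (int a = 0; a < 4; ++a) {
      id[a] = qd[a * m + e] - 1;
      for (int k = 0; k < 3; ++k) {
        X[k][a] = nd[k * nn + id[a]];
        xc[k][a] = X[k][a] + u[3 * id[a] + k];
      }
    }
    double ee;
    if (!elem_energy_grad(X, xc, p10[e], p20[e], p30[e], pks[e], pth[e],
                          ee, ge, true, strict)) {
      bad_elem = e + 1;
      break;
    }
    energy += ee;
    for (int a = 0; a < 4; ++a)
      for (int k = 0; k < 3; ++k)
        gfull[3 * id[a] + k] += ge[3 * a + k];
  }
  NumericVector gred(u_red.size());
  if (bad_elem == 0)
    for (int d = 0; d < ndof; ++d)
      if (map_dof[d] > 0) gred[map_dof[d] - 1] += gfull[d];
  return List::create(_["energy"] = energy, _["grad"] = gred,
                      _["bad_elem"] = bad_elem);
}
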