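// Point-set and point-to-triangle distance kernels for surface comparison
// and iterative-closest-point registration.

#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

namespace {

// Ericson, "Real-Time Collision Detection": closest point on triangle ABC to P.
inline double pt_tri_d2(const double *p, const double *a, const double *b,
                        const double *c) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k]; ac[k] = c[k] - a[k]; ap[k] = p[k] - a[k];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  double q[3];
  if (d1 <= 0.0 && d2 <= 0.0) { q[0]=a[0]; q[1]=a[1]; q[2]=a[2]; goto done; }
  {
    double bp[3];
    for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
    double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
    double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
    if (d3 >= 0.0 && d4 <= d3) { q[0]=b[0]; q[1]=b[1]; q[2]=b[2]; goto done; }
    double vc = d1*d4 - d3*d2;
    if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
      double v = d1 / (d1 - d3);
      for (int k = 0; k < 3; ++k) q[k] = a[k] + v * ab[k];
      goto done;
    }
    double cp[3];
    for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
    double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
    double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
    if (d6 >= 0.0 && d5 <= d6) { q[0]=c[0]; q[1]=c[1]; q[2]=c[2]; goto done; }
    double vb = d5*d2 - d1*d6;
    if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
      double w = d2 / (d2 - d6);
      for (int k = 0; k < 3; ++k) q[k] = a[k] + w * ac[k];
      goto done;
    }
    double va = d3*d6 - d5*d4;
    if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
      double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
      for (int k = 0; k < 3; ++k) q[k] = b[k] + w * (c[k] - b[k]);
      goto done;
    }
    {
      double denom = 1.0 / (va + vb + vc);
      double v = vb * denom, w = vc * denom;
      for (int k = 0; k < 3; ++k) q[k] = a[k] + v * ab[k] + w * ac[k];
    }
  }
done:
  double dx = p[0]-q[0], dy = p[1]-q[1], dz = p[2]-q[2];
  return dx*dx + dy*dy + dz*dz;
}

} // namespace

// For each row of P: min distance to the triangle soup (V rows of vertices,
// F rows of 1-based vertex triples).
// [[Rcpp::export(name = ".point_tri_min_dist")]]
NumericVector point_tri_min_dist(NumericMatrix P, NumericMatrix V,
                                 IntegerMatrix F) {
  const int np = P.nrow(), nt = F.nrow();
  NumericVector out(np);
  std::vector<double> tv(nt * 9);
  for (int t = 0; t < nt; ++t)
    for (int j = 0; j < 3; ++j)
      for (int k = 0; k < 3; ++k)
        tv[9*t + 3*j + k] = V(F(t, j) - 1, k);
  for (int i = 0; i < np; ++i) {
    double p[3] = {P(i,0), P(i,1), P(i,2)};
    double best = std::numeric_limits<double>::infinity();
    for (int t = 0; t < nt; ++t) {
      double d2 = pt_tri_d2(p, &tv[9*t], &tv[9*t+3], &tv[9*t+6]);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// For each row of A, the index (1-based) of the nearest row of B.
// [[Rcpp::export(name = ".nn_index")]]
IntegerVector nn_index(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  IntegerVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = std::numeric_limits<double>::infinity();
    int bi = 1;
    for (int j = 0; j < nb; ++j) {
      double dx = A(i,0)-B(j,0), dy = A(i,1)-B(j,1), dz = A(i,2)-B(j,2);
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) { best = d2; bi = j + 1; }
    }
    out[i] = bi;
  }
  return out;
}

// Accumulate val into an n-vector at (1-based) positions pos.
// [[Rcpp::export(name = ".accum")]]
NumericVector accum(IntegerVector pos, NumericVector val, int n) {
  NumericVector out(n);
  const int *p = INTEGER(pos);
  const double *v = REAL(val);
  const int m = pos.size();
  double *o = REAL(out);
  for (int k = 0; k < m; ++k) o[p[k] - 1] += v[k];
  return out;
}
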