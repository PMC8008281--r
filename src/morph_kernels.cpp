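#include <Rcpp.h>
using namespace Rcpp;

// Exact point-to-triangle distance (Ericson, Real-Time Collision
// Detection): project onto the triangle's plane and clamp to the closest
// feature (vertex, edge or interior).
static double point_tri_dist2(const double *p, const double *a,
                              const double *b, const double *c) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    return ap[0] * ap[0] + ap[1] * ap[1] + ap[2] * ap[2];
  }
  double bp[3];
  for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    return bp[0] * bp[0] + bp[1] * bp[1] + bp[2] * bp[2];
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    double dx = ap[0] - v * ab[0], dy = ap[1] - v * ab[1],
           dz = ap[2] - v * ab[2];
    return dx * dx + dy * dy + dz * dz;
  }
  double cp[3];
  for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    return cp[0] * cp[0] + cp[1] * cp[1] + cp[2] * cp[2];
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    double dx = ap[0] - w * ac[0], dy = ap[1] - w * ac[1],
           dz = ap[2] - w * ac[2];
    return dx * dx + dy * dy + dz * dz;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    double dx = bp[0] - w * (c[0] - b[0]), dy = bp[1] - w * (c[1] - b[1]),
           dz = bp[2] - w * (c[2] - b[2]);
    return dx * dx + dy * dy + dz * dz;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  double qx = a[0] + v * ab[0] + w * ac[0];
  double qy = a[1] + v * ab[1] + w * ac[1];
  double qz = a[2] + v * ab[2] + w * ac[2];
  double dx = p[0] - qx, dy = p[1] - qy, dz = p[2] - qz;
  return dx * dx + dy * dy + dz * dz;
}

// Minimum Euclidean distance from each row of `points` to the triangulated
// surface (`verts`, 1-based `faces`).
// [[Rcpp::export(name = ".min_dist_to_mesh")]]
NumericVector min_dist_to_mesh(NumericMatrix points, NumericMatrix verts,
                               IntegerMatrix faces) {
  const int n = points.nrow(), m = faces.nrow();
  NumericVector out(n);
  std::vector<double> P(3), A(3), B(3), C(3);
  for (int i = 0; i < n; ++i) {
    P[0] = points(i, 0); P[1] = points(i, 1); P[2] = points(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const int ia = faces(j, 0) - 1, ib = faces(j, 1) - 1,
                ic = faces(j, 2) - 1;
      A[0] = verts(ia, 0); A[1] = verts(ia, 1); A[2] = verts(ia, 2);
      B[0] = verts(ib, 0); B[1] = verts(ib, 1); B[2] = verts(ib, 2);
      C[0] = verts(ic, 0); C[1] = verts(ic, 1); C[2] = verts(ic, 2);
      double d2 = point_tri_dist2(P.data(), A.data(), B.data(), C.data());
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// For each center, total `area` of elements whose `centroid` lies within
// `radius` (the triangle-centroid inclusion rule for patch areas).
// [[Rcpp::export(name = ".ball_area_sum")]]
NumericVector ball_area_sum(NumericMatrix centers, NumericMatrix centroids,
                            NumericVector areas, double radius) {
  const int n = centers.nrow(), m = centroids.nrow();
  const double r2 = radius * radius;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double x = centers(i, 0), y = centers(i, 1), z = centers(i, 2);
    double s = 0.0;
    for (int j = 0; j < m; ++j) {
      const double dx = centroids(j, 0) - x, dy = centroids(j, 1) - y,
                   dz = centroids(j, 2) - z;
      if (dx * dx + dy * dy + dz * dz <= r2) s += areas[j];
    }
    out[i] = s;
  }
  return out;
}
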