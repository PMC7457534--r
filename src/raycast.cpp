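#include <Rcpp.h>
using namespace Rcpp;

// Per-face visibility of a static scene from a set of camera positions.
// V: n x 3 vertices, F: m x 3 one-based face indices, cams: p x 3 camera
// positions (scene frame), cos_min: minimum |cos| of the angle between the
// face normal and the viewing ray (foreshortening cutoff; both lamina sides
// count). A face is visible from a camera when the incidence passes the
// cutoff and no other face blocks the open segment from its centroid to the
// camera (Möller–Trumbore, strict-interior hits so shared edges do not
// self-occlude; a segment/AABB slab test prunes candidate occluders).
// Result: m x p logical matrix.
// [[Rcpp::export]]
LogicalMatrix cpp_face_visibility(NumericMatrix V, IntegerMatrix F,
                                  NumericMatrix cams, double cos_min) {
  const int m = F.nrow(), p = cams.nrow();
  const double eps_t = 1e-6, eps_b = 1e-9;
  LogicalMatrix out(m, p);

  // per-face precomputation: centroid, unit normal, v0/e1/e2, bbox
  std::vector<double> cx(m), cy(m), cz(m), nx(m), ny(m), nz(m);
  std::vector<double> v0(3 * m), e1(3 * m), e2(3 * m), lo(3 * m), hi(3 * m);
  for (int i = 0; i < m; ++i) {
    int a = F(i, 0) - 1, b = F(i, 1) - 1, c = F(i, 2) - 1;
    double ax = V(a, 0), ay = V(a, 1), az = V(a, 2);
    double bx = V(b, 0), by = V(b, 1), bz = V(b, 2);
    double gx = V(c, 0), gy = V(c, 1), gz = V(c, 2);
    cx[i] = (ax + bx + gx) / 3.0;
    cy[i] = (ay + by + gy) / 3.0;
    cz[i] = (az + bz + gz) / 3.0;
    v0[3 * i] = ax; v0[3 * i + 1] = ay; v0[3 * i + 2] = az;
    e1[3 * i] = bx - ax; e1[3 * i + 1] = by - ay; e1[3 * i + 2] = bz - az;
    e2[3 * i] = gx - ax; e2[3 * i + 1] = gy - ay; e2[3 * i + 2] = gz - az;
    lo[3 * i] = std::min(ax, std::min(bx, gx));
    lo[3 * i + 1] = std::min(ay, std::min(by, gy));
    lo[3 * i + 2] = std::min(az, std::min(bz, gz));
    hi[3 * i] = std::max(ax, std::max(bx, gx));
    hi[3 * i + 1] = std::max(ay, std::max(by, gy));
    hi[3 * i + 2] = std::max(az, std::max(bz, gz));
    double nxx = e1[3 * i + 1] * e2[3 * i + 2] - e1[3 * i + 2] * e2[3 * i + 1];
    double nyy = e1[3 * i + 2] * e2[3 * i] - e1[3 * i] * e2[3 * i + 2];
    double nzz = e1[3 * i] * e2[3 * i + 1] - e1[3 * i + 1] * e2[3 * i];
    double nn = std::sqrt(nxx * nxx + nyy * nyy + nzz * nzz);
    if (nn > 0) { nxx /= nn; nyy /= nn; nzz /= nn; }
    nx[i] = nxx; ny[i] = nyy; nz[i] = nzz;
  }

  for (int c = 0; c < p; ++c) {
    double px = cams(c, 0), py = cams(c, 1), pz = cams(c, 2);
    for (int i = 0; i < m; ++i) {
      double O[3] = {cx[i], cy[i], cz[i]};
      double D[3] = {px - O[0], py - O[1], pz - O[2]};
      double dn = std::sqrt(D[0] * D[0] + D[1] * D[1] + D[2] * D[2]);
      if (dn <= 0) { out(i, c) = false; continue; }
      double cosang = std::fabs((D[0] * nx[i] + D[1] * ny[i] + D[2] * nz[i]) / dn);
      if (cosang < cos_min) { out(i, c) = false; continue; }
      double invD[3];
      for (int k = 0; k < 3; ++k)
        invD[k] = (std::fabs(D[k]) > 1e-300) ? 1.0 / D[k] : 1e300;
      bool blocked = false;
      for (int j = 0; j < m && !blocked; ++j) {
        if (j == i) continue;
        // segment/AABB slab overlap on t in (eps_t, 1 - eps_t)
        double t0 = eps_t, t1 = 1.0 - eps_t;
        bool miss = false;
        for (int k = 0; k < 3; ++k) {
          double ta = (lo[3 * j + k] - O[k]) * invD[k];
          double tb = (hi[3 * j + k] - O[k]) * invD[k];
          if (ta > tb) std::swap(ta, tb);
          if (ta > t0) t0 = ta;
          if (tb < t1) t1 = tb;
          if (t0 > t1) { miss = true; break; }
        }
        if (miss) continue;
        // Möller–Trumbore on the open segment, strict-interior barycentrics
        const double *E1 = &e1[3 * j], *E2 = &e2[3 * j], *W0 = &v0[3 * j];
        double pv0 = D[1] * E2[2] - D[2] * E2[1];
        double pv1 = D[2] * E2[0] - D[0] * E2[2];
        double pv2 = D[0] * E2[1] - D[1] * E2[0];
        double det = E1[0] * pv0 + E1[1] * pv1 + E1[2] * pv2;
        if (det > -1e-12 && det < 1e-12) continue;
        double inv = 1.0 / det;
        double tv0 = O[0] - W0[0], tv1 = O[1] - W0[1], tv2 = O[2] - W0[2];
        double u = (tv0 * pv0 + tv1 * pv1 + tv2 * pv2) * inv;
        if (u < eps_b || u > 1.0 - eps_b) continue;
        double qv0 = tv1 * E1[2] - tv2 * E1[1];
        double qv1 = tv2 * E1[0] - tv0 * E1[2];
        double qv2 = tv0 * E1[1] - tv1 * E1[0];
        double v = (D[0] * qv0 + D[1] * qv1 + D[2] * qv2) * inv;
        if (v < eps_b || u + v > 1.0 - eps_b) continue;
        double t = (E2[0] * qv0 + E2[1] * qv1 + E2[2] * qv2) * inv;
        blocked = (t > eps_t && t < 1.0 - eps_t);
      }
      out(i, c) = !blocked;
    }
  }
  return out;
}
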