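#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Analytic collocation integrals over plane triangles with linear shape
// functions.  For a field point r and triangle (r1,r2,r3) we need
//
//   W_k = \int_T N_k(r') dOmega(r')   (shape-weighted solid angle)
//   S_k = \int_T N_k(r') / |r'-r| dS'  (shape-weighted single layer)
//
// Both reduce to closed form: write N_k as its affine extension about the
// in-plane projection q of r, N_k(r') = N_k(q) + g_k . (r'-q), with g_k the
// constant in-plane shape gradient.  The zeroth moments are the
// van Oosterom-Strackee solid angle and the Wilton et al. single-layer
// potential; the first moments come from in-plane divergence identities,
// leaving only per-edge logarithms and arctangents.
//
// Principal values: a field point in the triangle plane subtends zero solid
// angle (guarded by |d| below); single-layer edge terms vanish with the
// in-plane edge distance, guarded where the logarithm degenerates.

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// [[Rcpp::export(name = ".bem_collocation")]]
List bem_collocation(NumericMatrix fieldpts, NumericMatrix verts,
                     IntegerMatrix tris, bool single_layer) {
  const int np = fieldpts.nrow();
  const int nv = verts.nrow();
  const int nt = tris.nrow();
  NumericMatrix W(np, nv);
  NumericMatrix S(single_layer ? np : 1, single_layer ? nv : 1);

  for (int t = 0; t < nt; ++t) {
    const int i1 = tris(t, 0), i2 = tris(t, 1), i3 = tris(t, 2);
    double r1[3], r2[3], r3[3];
    for (int c = 0; c < 3; ++c) {
      r1[c] = verts(i1, c);
      r2[c] = verts(i2, c);
      r3[c] = verts(i3, c);
    }
    double e21[3], e31[3], nvec[3];
    for (int c = 0; c < 3; ++c) { e21[c] = r2[c] - r1[c]; e31[c] = r3[c] - r1[c]; }
    cross3(e21, e31, nvec);
    const double A2 = std::sqrt(dot3(nvec, nvec));  // 2 * area
    if (A2 <= 0.0) continue;                        // degenerate; validator rejects
    double nh[3] = { nvec[0] / A2, nvec[1] / A2, nvec[2] / A2 };
    // in-plane shape gradients g_k = (nh x opposite_edge)/(2A)
    double ek1[3], ek2[3], ek3[3], g1[3], g2[3], g3[3];
    for (int c = 0; c < 3; ++c) {
      ek1[c] = r3[c] - r2[c];
      ek2[c] = r1[c] - r3[c];
      ek3[c] = r2[c] - r1[c];
    }
    cross3(nh, ek1, g1); cross3(nh, ek2, g2); cross3(nh, ek3, g3);
    for (int c = 0; c < 3; ++c) { g1[c] /= A2; g2[c] /= A2; g3[c] /= A2; }
    const double scale = std::sqrt(dot3(ek3, ek3)) + std::sqrt(dot3(ek1, ek1)) +
                         std::sqrt(dot3(ek2, ek2));
    const double eps_d = 1e-12 * scale;

    // in-plane barycentric solve precomputation (Gram matrix of e21,e31)
    const double uu = dot3(e21, e21), vv = dot3(e31, e31), uv = dot3(e21, e31);
    const double gdet = uu * vv - uv * uv;

    const double* vptr[3] = { r1, r2, r3 };
    const double* gptr[3] = { g1, g2, g3 };

    for (int p = 0; p < np; ++p) {
      double r[3] = { fieldpts(p, 0), fieldpts(p, 1), fieldpts(p, 2) };
      double y1[3], y2[3], y3[3];
      for (int c = 0; c < 3; ++c) {
        y1[c] = r1[c] - r[c]; y2[c] = r2[c] - r[c]; y3[c] = r3[c] - r[c];
      }
      const double l1 = std::sqrt(dot3(y1, y1));
      const double l2 = std::sqrt(dot3(y2, y2));
      const double l3 = std::sqrt(dot3(y3, y3));
      double c23[3];
      cross3(y2, y3, c23);
      const double triple = dot3(y1, c23);
      const double ss = l1 * l2 * l3 + dot3(y1, y2) * l3 + dot3(y1, y3) * l2 +
                        dot3(y2, y3) * l1;
      const double d = dot3(y1, nh);
      const bool in_plane = std::fabs(d) < eps_d;
      const double Om = in_plane ? 0.0 : 2.0 * std::atan2(triple, ss);

      // projection q and its affine barycentric coordinates
      double q[3], w[3];
      for (int c = 0; c < 3; ++c) { q[c] = r[c] + d * nh[c]; w[c] = q[c] - r1[c]; }
      const double wu = dot3(w, e21), wvd = dot3(w, e31);
      const double b2 = (vv * wu - uv * wvd) / gdet;
      const double b3 = (uu * wvd - uv * wu) / gdet;
      const double Nq[3] = { 1.0 - b2 - b3, b2, b3 };

      double sgf[3] = { 0.0, 0.0, 0.0 };  // sum_e (g_k . m_e) f_e
      double I0 = 0.0, beta_sum = 0.0;
      double I1[3] = { 0.0, 0.0, 0.0 };

      for (int e = 0; e < 3; ++e) {
        const double* a = vptr[e];
        const double* b = vptr[(e + 1) % 3];
        double tv[3];
        for (int c = 0; c < 3; ++c) tv[c] = b[c] - a[c];
        const double L = std::sqrt(dot3(tv, tv));
        double th[3] = { tv[0] / L, tv[1] / L, tv[2] / L };
        double ya[3], yb[3], ua[3], mh[3];
        for (int c = 0; c < 3; ++c) {
          ya[c] = a[c] - r[c]; yb[c] = b[c] - r[c]; ua[c] = a[c] - q[c];
        }
        const double Ra = std::sqrt(dot3(ya, ya));
        const double Rb = std::sqrt(dot3(yb, yb));
        const double lm = dot3(th, ua);
        const double lp = lm + L;
        cross3(th, nh, mh);
        const double Pe = dot3(mh, ua);
        const double rho2 = Pe * Pe + d * d;
        const double den = lm + Ra, num = lp + Rb;
        double fe = 0.0;
        bool fe_ok = (den > eps_d * 1e-3) && (num > eps_d * 1e-3);
        if (fe_ok) fe = std::log(num / den);
        if (fe_ok) {
          for (int k = 0; k < 3; ++k) sgf[k] += dot3(gptr[k], mh) * fe;
        }
        if (single_layer) {
          if (fe_ok) {
            I0 += Pe * fe;
            // atan2 handles the collinear limit Pe -> 0, rho2 -> 0 (both
            // arguments vanish together and the contribution is 0)
            beta_sum += std::atan2(Pe * lp, rho2 + std::fabs(d) * Rb) -
                        std::atan2(Pe * lm, rho2 + std::fabs(d) * Ra);
          }
          const double edge_lin = 0.5 * (lp * Rb - lm * Ra + (fe_ok ? rho2 * fe : 0.0));
          for (int c = 0; c < 3; ++c) I1[c] += mh[c] * edge_lin;
        }
      }
      if (single_layer) {
        I0 -= std::fabs(d) * beta_sum;
        for (int k = 0; k < 3; ++k) {
          const double sk = Nq[k] * I0 + dot3(gptr[k], I1);
          S(p, tris(t, k)) += sk;
        }
      }
      for (int k = 0; k < 3; ++k) {
        const double ok = in_plane ? 0.0 : (Nq[k] * Om - d * sgf[k]);
        W(p, tris(t, k)) += ok;
      }
    }
  }
  if (single_layer) return List::create(Named("W") = W, Named("S") = S);
  return List::create(Named("W") = W);
}
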