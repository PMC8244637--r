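#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Closest point on triangle (a,b,c) to p (Ericson, Real-Time Collision
// Detection, 5.1.5). Writes result into out[3], returns squared distance.
static double closest_on_triangle(const double *p, const double *a,
                                  const double *b, const double *c,
                                  double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int i = 0; i < 3; ++i) out[i] = a[i];
  } else {
    double bp[3], cp[3];
    for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
    double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
    double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
    if (d3 >= 0.0 && d4 <= d3) {
      for (int i = 0; i < 3; ++i) out[i] = b[i];
    } else {
      double vc = d1*d4 - d3*d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double v = d1 / (d1 - d3);
        for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
      } else {
        for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
        double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
        double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
        if (d6 >= 0.0 && d5 <= d6) {
          for (int i = 0; i < 3; ++i) out[i] = c[i];
        } else {
          double vb = d5*d2 - d1*d6;
          if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
            double w = d2 / (d2 - d6);
            for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
          } else {
            double va = d3*d6 - d5*d4;
            if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
              double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
            } else {
              double denom = 1.0 / (va + vb + vc);
              double v = vb * denom, w = vc * denom;
              for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i]*v + ac[i]*w;
            }
          }
        }
      }
    }
  }
  double dx = p[0]-out[0], dy = p[1]-out[1], dz = p[2]-out[2];
  return dx*dx + dy*dy + dz*dz;
}

// Uniform-grid spatial index over triangles: each triangle is registered in
// every grid cell its bounding box overlaps, so a cell's list is exhaustive
// for queries whose closest point lies in that cell.
struct TriGrid {
  double lo[3], cell;
  int n[3];
  std::vector< std::vector<int> > bins;
  int idx(int ix, int iy, int iz) const {
    return (iz * n[1] + iy) * n[0] + ix;
  }
};

static void build_grid(const NumericMatrix &V, const IntegerMatrix &F,
                       TriGrid &g) {
  double hi[3];
  for (int d = 0; d < 3; ++d) { g.lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int i = 0; i < V.nrow(); ++i)
    for (int d = 0; d < 3; ++d) {
      if (V(i,d) < g.lo[d]) g.lo[d] = V(i,d);
      if (V(i,d) > hi[d]) hi[d] = V(i,d);
    }
  double maxext = 0.0;
  for (int d = 0; d < 3; ++d) maxext = std::max(maxext, hi[d] - g.lo[d]);
  // target ~32 cells along the largest extent, at least 1
  g.cell = std::max(maxext / 32.0, 1e-9);
  for (int d = 0; d < 3; ++d) {
    g.n[d] = std::max(1, (int)std::floor((hi[d] - g.lo[d]) / g.cell) + 1);
  }
  g.bins.assign((size_t)g.n[0] * g.n[1] * g.n[2], std::vector<int>());
  for (int t = 0; t < F.nrow(); ++t) {
    double blo[3], bhi[3];
    for (int d = 0; d < 3; ++d) { blo[d] = R_PosInf; bhi[d] = R_NegInf; }
    for (int k = 0; k < 3; ++k) {
      int vtx = F(t,k) - 1;
      for (int d = 0; d < 3; ++d) {
        blo[d] = std::min(blo[d], V(vtx,d));
        bhi[d] = std::max(bhi[d], V(vtx,d));
      }
    }
    int c0[3], c1[3];
    for (int d = 0; d < 3; ++d) {
      c0[d] = std::min(g.n[d]-1, std::max(0, (int)((blo[d]-g.lo[d]) / g.cell)));
      c1[d] = std::min(g.n[d]-1, std::max(0, (int)((bhi[d]-g.lo[d]) / g.cell)));
    }
    for (int iz = c0[2]; iz <= c1[2]; ++iz)
      for (int iy = c0[1]; iy <= c1[1]; ++iy)
        for (int ix = c0[0]; ix <= c1[0]; ++ix)
          g.bins[g.idx(ix,iy,iz)].push_back(t);
  }
}

static double box_dist2(const double *p, const TriGrid &g,
                        int ix, int iy, int iz) {
  double d2 = 0.0;
  const int ii[3] = {ix, iy, iz};
  for (int d = 0; d < 3; ++d) {
    double lo = g.lo[d] + ii[d] * g.cell, hi = lo + g.cell;
    double v = p[d] < lo ? lo - p[d] : (p[d] > hi ? p[d] - hi : 0.0);
    d2 += v * v;
  }
  return d2;
}

// For each query point, the exact closest point on the triangle mesh
// (vertices V, 1-based triangle index matrix F). Returns list(points, dist).
// [[Rcpp::export]]
List cpp_project_to_mesh(NumericMatrix query, NumericMatrix V, IntegerMatrix F) {
  int nq = query.nrow(), nf = F.nrow();
  NumericMatrix out(nq, 3);
  NumericVector dist(nq);
  TriGrid g;
  build_grid(V, F, g);
  std::vector<int> stamp(nf, -1);
  double p[3], a[3], b[3], c[3], best[3], cand[3];
  int maxring = std::max(g.n[0], std::max(g.n[1], g.n[2]));
  for (int q = 0; q < nq; ++q) {
    p[0] = query(q,0); p[1] = query(q,1); p[2] = query(q,2);
    int cq[3];
    for (int d = 0; d < 3; ++d) {
      int i = (int)((p[d] - g.lo[d]) / g.cell);
      cq[d] = std::min(g.n[d]-1, std::max(0, i));
    }
    double bestsq = R_PosInf;
    best[0] = best[1] = best[2] = NA_REAL;
    for (int r = 0; r <= maxring; ++r) {
      // cells whose Chebyshev distance from the containing cell is exactly r
      bool any_candidate = false;
      int x0 = cq[0]-r, x1 = cq[0]+r;
      int y0 = cq[1]-r, y1 = cq[1]+r;
      int z0 = cq[2]-r, z1 = cq[2]+r;
      for (int iz = std::max(0, z0); iz <= std::min(g.n[2]-1, z1); ++iz)
        for (int iy = std::max(0, y0); iy <= std::min(g.n[1]-1, y1); ++iy)
          for (int ix = std::max(0, x0); ix <= std::min(g.n[0]-1, x1); ++ix) {
            int cheb = std::max(std::abs(ix-cq[0]),
                       std::max(std::abs(iy-cq[1]), std::abs(iz-cq[2])));
            if (cheb != r) continue;
            double bd2 = box_dist2(p, g, ix, iy, iz);
            if (bd2 > bestsq) continue;
            any_candidate = true;
            const std::vector<int> &bin = g.bins[g.idx(ix,iy,iz)];
            for (size_t s = 0; s < bin.size(); ++s) {
              int t = bin[s];
              if (stamp[t] == q) continue;
              stamp[t] = q;
              int i0 = F(t,0)-1, i1 = F(t,1)-1, i2 = F(t,2)-1;
              a[0]=V(i0,0); a[1]=V(i0,1); a[2]=V(i0,2);
              b[0]=V(i1,0); b[1]=V(i1,1); b[2]=V(i1,2);
              c[0]=V(i2,0); c[1]=V(i2,1); c[2]=V(i2,2);
              double sq = closest_on_triangle(p, a, b, c, cand);
              if (sq < bestsq) {
                bestsq = sq;
                best[0]=cand[0]; best[1]=cand[1]; best[2]=cand[2];
              }
            }
          }
      // any farther ring is at least (r * cell) away from the containing
      // cell's boundary; stop once that bound exceeds the best hit
      if (R_finite(bestsq)) {
        double ringmin = (double)r * g.cell;
        if (ringmin * ringmin > bestsq) break;
      } else if (!any_candidate && r > 0) {
        // empty rings so far but nothing found: keep expanding
      }
    }
    out(q,0)=best[0]; out(q,1)=best[1]; out(q,2)=best[2];
    dist[q] = std::sqrt(bestsq);
  }
  return List::create(_["points"] = out, _["dist"] = dist);
}
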