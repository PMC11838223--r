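#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Point-to-segment squared distance.
static inline double pt_seg_d2(double px, double py,
                               double ax, double ay, double bx, double by) {
  double dx = bx - ax, dy = by - ay;
  double len2 = dx * dx + dy * dy;
  double t = 0.0;
  if (len2 > 0.0) {
    t = ((px - ax) * dx + (py - ay) * dy) / len2;
    if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
  }
  double qx = ax + t * dx - px, qy = ay + t * dy - py;
  return qx * qx + qy * qy;
}

static inline double orient(double ax, double ay, double bx, double by,
                            double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

static inline bool on_seg(double ax, double ay, double bx, double by,
                          double px, double py) {
  return std::min(ax, bx) - 1e-12 <= px && px <= std::max(ax, bx) + 1e-12 &&
         std::min(ay, by) - 1e-12 <= py && py <= std::max(ay, by) + 1e-12;
}

// Do segments AB and CD intersect (incl. touching)?
static inline bool seg_intersect(double ax, double ay, double bx, double by,
                                 double cx, double cy, double dx, double dy) {
  double o1 = orient(ax, ay, bx, by, cx, cy);
  double o2 = orient(ax, ay, bx, by, dx, dy);
  double o3 = orient(cx, cy, dx, dy, ax, ay);
  double o4 = orient(cx, cy, dx, dy, bx, by);
  if (((o1 > 0) != (o2 > 0)) && ((o3 > 0) != (o4 > 0)) &&
      o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0)
    return true;
  if (o1 == 0 && on_seg(ax, ay, bx, by, cx, cy)) return true;
  if (o2 == 0 && on_seg(ax, ay, bx, by, dx, dy)) return true;
  if (o3 == 0 && on_seg(cx, cy, dx, dy, ax, ay)) return true;
  if (o4 == 0 && on_seg(cx, cy, dx, dy, bx, by)) return true;
  return false;
}

// Segment-segment minimum distance.
static inline double seg_seg_dist(double ax, double ay, double bx, double by,
                                  double cx, double cy, double dx, double dy) {
  if (seg_intersect(ax, ay, bx, by, cx, cy, dx, dy)) return 0.0;
  double d2 = pt_seg_d2(ax, ay, cx, cy, dx, dy);
  d2 = std::min(d2, pt_seg_d2(bx, by, cx, cy, dx, dy));
  d2 = std::min(d2, pt_seg_d2(cx, cy, ax, ay, bx, by));
  d2 = std::min(d2, pt_seg_d2(dx, dy, ax, ay, bx, by));
  return std::sqrt(d2);
}

// Winding-free even-odd point-in-polygon; returns 2 on boundary, 1 inside,
// 0 outside.
static int pip(double px, double py, const NumericMatrix& poly) {
  int n = poly.nrow();
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    double xi = poly(i, 0), yi = poly(i, 1);
    double xj = poly(j, 0), yj = poly(j, 1);
    if (orient(xj, yj, xi, yi, px, py) == 0 && on_seg(xj, yj, xi, yi, px, py))
      return 2;
    if (((yi > py) != (yj > py)) &&
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi))
      inside = !inside;
  }
  return inside ? 1 : 0;
}

// Minimum distance between the boundaries of two simple polygons;
// 0 if boundaries touch/cross or one polygon contains the other.
static double poly_dist(const NumericMatrix& a, const NumericMatrix& b) {
  int na = a.nrow(), nb = b.nrow();
  double best = std::numeric_limits<double>::infinity();
  for (int i = 0; i < na; i++) {
    int i2 = (i + 1) % na;
    for (int j = 0; j < nb; j++) {
      int j2 = (j + 1) % nb;
      double d = seg_seg_dist(a(i, 0), a(i, 1), a(i2, 0), a(i2, 1),
                              b(j, 0), b(j, 1), b(j2, 0), b(j2, 1));
      if (d < best) {
        best = d;
        if (best == 0.0) return 0.0;
      }
    }
  }
  // boundaries disjoint: containment check (either direction) => overlap
  if (pip(a(0, 0), a(0, 1), b) > 0) return 0.0;
  if (pip(b(0, 0), b(0, 1), a) > 0) return 0.0;
  return best;
}

// [[Rcpp::export(name = ".cpp_poly_dist")]]
double cpp_poly_dist(NumericMatrix a, NumericMatrix b) {
  return poly_dist(a, b);
}

// All unordered pairs with edge-to-edge distance <= cutoff, bbox-pruned.
// polys: list of n x 2 vertex matrices. Returns 3-col matrix (i, j, dist),
// 1-based indices.
// [[Rcpp::export(name = ".cpp_pairwise_dist")]]
NumericMatrix cpp_pairwise_dist(List polys, double cutoff) {
  int n = polys.size();
  std::vector<double> xmin(n), xmax(n), ymin(n), ymax(n);
  std::vector<NumericMatrix> pv;
  pv.reserve(n);
  for (int i = 0; i < n; i++) {
    NumericMatrix p = polys[i];
    pv.push_back(p);
    double x0 = p(0, 0), x1 = p(0, 0), y0 = p(0, 1), y1 = p(0, 1);
    for (int k = 1; k < p.nrow(); k++) {
      x0 = std::min(x0, p(k, 0)); x1 = std::max(x1, p(k, 0));
      y0 = std::min(y0, p(k, 1)); y1 = std::max(y1, p(k, 1));
    }
    xmin[i] = x0; xmax[i] = x1; ymin[i] = y0; ymax[i] = y1;
  }
  std::vector<double> ri, rj, rd;
  for (int i = 0; i < n; i++) {
    for (int j = i + 1; j < n; j++) {
      double gx = std::max(std::max(xmin[i] - xmax[j], xmin[j] - xmax[i]), 0.0);
      double gy = std::max(std::max(ymin[i] - ymax[j], ymin[j] - ymax[i]), 0.0);
      if (std::sqrt(gx * gx + gy * gy) > cutoff) continue;
      double d = poly_dist(pv[i], pv[j]);
      if (d <= cutoff) {
        ri.push_back(i + 1); rj.push_back(j + 1); rd.push_back(d);
      }
    }
  }
  NumericMatrix out(ri.size(), 3);
  for (size_t k = 0; k < ri.size(); k++) {
    out(k, 0) = ri[k]; out(k, 1) = rj[k]; out(k, 2) = rd[k];
  }
  colnames(out) = CharacterVector::create("i", "j", "dist");
  return out;
}

// For each query polygon, minimum edge distance to any reference polygon.
// [[Rcpp::export(name = ".cpp_min_dist_to_ref")]]
NumericVector cpp_min_dist_to_ref(List query, List ref) {
  int nq = query.size(), nr = ref.size();
  std::vector<NumericMatrix> qv, rv;
  std::vector<double> qxmin(nq), qxmax(nq), qymin(nq), qymax(nq);
  std::vector<double> rxmin(nr), rxmax(nr), rymin(nr), rymax(nr);
  for (int i = 0; i < nq; i++) {
    NumericMatrix p = query[i]; qv.push_back(p);
    double x0 = p(0,0), x1 = p(0,0), y0 = p(0,1), y1 = p(0,1);
    for (int k = 1; k < p.nrow(); k++) {
      x0 = std::min(x0, p(k,0)); x1 = std::max(x1, p(k,0));
      y0 = std::min(y0, p(k,1)); y1 = std::max(y1, p(k,1));
    }
    qxmin[i]=x0; qxmax[i]=x1; qymin[i]=y0; qymax[i]=y1;
  }
  for (int i = 0; i < nr; i++) {
    NumericMatrix p = ref[i]; rv.push_back(p);
    double x0 = p(0,0), x1 = p(0,0), y0 = p(0,1), y1 = p(0,1);
    for (int k = 1; k < p.nrow(); k++) {
      x0 = std::min(x0, p(k,0)); x1 = std::max(x1, p(k,0));
      y0 = std::min(y0, p(k,1)); y1 = std::max(y1, p(k,1));
    }
    rxmin[i]=x0; rxmax[i]=x1; rymin[i]=y0; rymax[i]=y1;
  }
  NumericVector out(nq);
  for (int i = 0; i < nq; i++) {
    double best = std::numeric_limits<double>::infinity();
    for (int j = 0; j < nr; j++) {
      double gx = std::max(std::max(qxmin[i]-rxmax[j], rxmin[j]-qxmax[i]), 0.0);
      double gy = std::max(std::max(qymin[i]-rymax[j], rymin[j]-qymax[i]), 0.0);
      if (std::sqrt(gx*gx + gy*gy) >= best) continue;
      double d = poly_dist(qv[i], rv[j]);
      if (d < best) best = d;
      if (best == 0.0) break;
    }
    out[i] = best;
  }
  return out;
}

// Point-in-polygon assignment of transcript points to cell polygons.
// Returns 0 for unassigned; boundary points go to the containing polygon
// with the lowest index (polys assumed ordered by cell id).
// [[Rcpp::export(name = ".cpp_assign_points")]]
IntegerVector cpp_assign_points(NumericVector px, NumericVector py,
                                List polys) {
  int np = px.size(), nc = polys.size();
  std::vector<NumericMatrix> pv;
  std::vector<double> xmin(nc), xmax(nc), ymin(nc), ymax(nc);
  for (int i = 0; i < nc; i++) {
    NumericMatrix p = polys[i]; pv.push_back(p);
    double x0 = p(0,0), x1 = p(0,0), y0 = p(0,1), y1 = p(0,1);
    for (int k = 1; k < p.nrow(); k++) {
      x0 = std::min(x0, p(k,0)); x1 = std::max(x1, p(k,0));
      y0 = std::min(y0, p(k,1)); y1 = std::max(y1, p(k,1));
    }
    xmin[i]=x0; xmax[i]=x1; ymin[i]=y0; ymax[i]=y1;
  }
  IntegerVector out(np);
  for (int k = 0; k < np; k++) {
    int hit = 0;
    for (int i = 0; i < nc; i++) {
      if (px[k] < xmin[i] || px[k] > xmax[i] ||
          py[k] < ymin[i] || py[k] > ymax[i]) continue;
      int r = pip(px[k], py[k], pv[i]);
      if (r == 1) { hit = i + 1; break; }       // strictly inside: unique
      if (r == 2 && hit == 0) hit = i + 1;       // boundary: lowest id wins
    }
    out[k] = hit;
  }
  return out;
}
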