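// Two-stage geodesic distance solver on simplicial meshes:
//  stage 1: nearest-neighbour line-of-sight initialisation (exact Euclidean
//           distances on a subset of the visible nodes),
//  stage 2: mesh-based fast marching with causality-preserving acceptance.
//
// The local update at an unknown node minimises
//     f(lambda) = sum_i lambda_i d_i + | x_u - sum_i lambda_i p_i |
// over the convex hull of the element's known nodes. The interior optimum is
// the plane-wave (Eikonal, unit speed) first arrival; boundary optima are the
// lower-dimensional (edge / single-node) fallbacks used when the plane-wave
// characteristic leaves the simplex. For obtuse configurations this is the
// interpolated-virtual-node update in its exact form: the virtual node at the
// perpendicular foot with linearly interpolated distance is a feasible point
// of the same minimisation.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include "geom.h"

using namespace Rcpp;
using namespace cdtgeom;

static const int FAR = 0, TRIAL = 1, KNOWN = 2, KNOWN_LOS = 3;

// ---- local updates ---------------------------------------------------------

static double update1(const double* u, const double* p, double d, int dim) {
    double w[3];
    subd(u, p, w, dim);
    return d + normd(w, dim);
}

// Exact minimisation over the segment [p1, p0]: lambda = weight on p0.
static double update2(const double* u, const double* p0, const double* p1,
                      double d0, double d1, int dim) {
    double e[3], w[3];
    subd(p0, p1, e, dim);
    subd(u, p1, w, dim);
    double a = dotd(e, e, dim), k = d0 - d1;
    double best = std::min(update1(u, p0, d0, dim), update1(u, p1, d1, dim));
    if (a <= 0 || k * k >= a) return best; // slope >= 1: no interior optimum
    double b = dotd(e, w, dim), c = dotd(w, w, dim);
    double A = a * (a - k * k), B = -2.0 * b * (a - k * k), C = b * b - k * k * c;
    double disc = B * B - 4.0 * A * C;
    if (disc < 0 || A <= 0) return best;
    double sq = std::sqrt(disc);
    for (int s = -1; s <= 1; s += 2) {
        double lam = (-B + s * sq) / (2.0 * A);
        if (lam <= 0 || lam >= 1 || !std::isfinite(lam)) continue;
        double q[3];
        for (int i = 0; i < dim; ++i) q[i] = w[i] - lam * e[i];
        double f = lam * d0 + (1.0 - lam) * d1 + normd(q, dim);
        if (f < best) best = f;
    }
    return best;
}

// Exact minimisation over a known triangular face (3D only).
static double update3(const double* u, const double* const* p, const double* d) {
    // edge and vertex fallbacks
    double best = update2(u, p[0], p[1], d[0], d[1], 3);
    best = std::min(best, update2(u, p[0], p[2], d[0], d[2], 3));
    best = std::min(best, update2(u, p[1], p[2], d[1], d[2], 3));
    // interior stationary point: plane wave through the face
    double e0[3], e1[3], w[3], nrm[3];
    subd(p[0], p[2], e0, 3);
    subd(p[1], p[2], e1, 3);
    subd(u, p[2], w, 3);
    cross3(e0, e1, nrm);
    double nn = normd(nrm, 3);
    if (nn < 1e-300) return best;
    for (int i = 0; i < 3; ++i) nrm[i] /= nn;
    double g00 = dot3(e0, e0), g01 = dot3(e0, e1), g11 = dot3(e1, e1);
    double det = g00 * g11 - g01 * g01;
    if (std::fabs(det) < 1e-300) return best;
    double del0 = d[0] - d[2], del1 = d[1] - d[2];
    double b0 = (g11 * del0 - g01 * del1) / det;
    double b1 = (-g01 * del0 + g00 * del1) / det;
    double mp[3];
    for (int i = 0; i < 3; ++i) mp[i] = b0 * e0[i] + b1 * e1[i];
    double t2 = 1.0 - dot3(mp, mp);
    if (t2 <= 0) return best;
    double t = std::sqrt(t2);
    for (int s = -1; s <= 1; s += 2) {
        double m[3];
        for (int i = 0; i < 3; ++i) m[i] = mp[i] + s * t * nrm[i];
        double nm = dot3(nrm, m);
        if (std::fabs(nm) < 1e-14) continue;
        double tt = dot3(nrm, w) / nm; // backward characteristic u - tt*m hits the plane
        if (tt <= 0) continue;
        double q[3], uq[3];
        for (int i = 0; i < 3; ++i) q[i] = u[i] - tt * m[i];
        const double* v[3] = {p[0], p[1], p[2]};
        // barycentric of q in the face (planar 2x2 solve)
        double qw[3];
        subd(q, p[2], qw, 3);
        double a0 = (g11 * dot3(e0, qw) - g01 * dot3(e1, qw)) / det;
        double a1 = (-g01 * dot3(e0, qw) + g00 * dot3(e1, qw)) / det;
        double a2 = 1.0 - a0 - a1;
        (void)v;
        if (a0 < -1e-9 || a1 < -1e-9 || a2 < -1e-9) continue;
        subd(u, q, uq, 3);
        double f = a0 * d[0] + a1 * d[1] + a2 * d[2] + normd(uq, 3);
        if (f < best) best = f;
    }
    return best;
}

static double simplex_candidate(const double* u, const double* const* p,
                                const double* d, int nk, int dim) {
    if (nk == 1) return update1(u, p[0], d[0], dim);
    if (nk == 2) return update2(u, p[0], p[1], d[0], d[1], dim);
    return update3(u, p, d);
}

// First-arrival candidate at an unknown node from the known nodes of one
// simplex (exported for direct testing of the local solver).
// [[Rcpp::export]]
double cpp_local_update(NumericVector unknown, NumericMatrix known_pts,
                        NumericVector known_dist) {
    int dim = unknown.size(), nk = known_pts.nrow();
    if (nk < 1) stop("no known neighbor");
    if (nk > dim) stop("too many known nodes for the simplex dimension");
    double u[3];
    for (int i = 0; i < dim; ++i) u[i] = unknown[i];
    std::vector<std::vector<double> > pc(nk, std::vector<double>(dim));
    std::vector<const double*> pv(nk);
    std::vector<double> dv(nk);
    for (int j = 0; j < nk; ++j) {
        for (int i = 0; i < dim; ++i) pc[j][i] = known_pts(j, i);
        pv[j] = pc[j].data();
        dv[j] = known_dist[j];
    }
    return simplex_candidate(u, pv.data(), dv.data(), nk, dim);
}

// ---- fast marching ---------------------------------------------------------

// [[Rcpp::export]]
List cpp_fast_march(NumericMatrix nodes, IntegerMatrix elements,
                    IntegerVector star_ptr, IntegerVector star_idx,
                    NumericVector dist0, IntegerVector state0) {
    const int n = nodes.nrow(), dim = nodes.ncol(), k = elements.ncol();
    NumericVector dist = clone(dist0);
    IntegerVector state = clone(state0);
    typedef std::pair<double, int> QE;
    std::priority_queue<QE, std::vector<QE>, std::greater<QE> > heap;

    double u[3];
    const double* pv[3];
    double pvc[3][3], dv[3];

    // candidate at unknown node w from element e
    auto candidate = [&](int e, int w) -> double {
        int nk = 0;
        for (int j = 0; j < k; ++j) {
            int v = elements(e, j) - 1;
            if (v == w || state[v] < KNOWN) continue;
            if (nk >= dim) continue;
            for (int i = 0; i < dim; ++i) pvc[nk][i] = nodes(v, i);
            pv[nk] = pvc[nk];
            dv[nk] = dist[v];
            ++nk;
        }
        if (nk == 0) return R_PosInf;
        for (int i = 0; i < dim; ++i) u[i] = nodes(w, i);
        return simplex_candidate(u, pv, dv, nk, dim);
    };

    auto relax_around = [&](int v) {
        for (int s = star_ptr[v]; s < star_ptr[v + 1]; ++s) {
            int e = star_idx[s] - 1;
            for (int j = 0; j < k; ++j) {
                int w = elements(e, j) - 1;
                if (state[w] >= KNOWN) continue;
                double cand = candidate(e, w);
                if (cand < dist[w]) {
                    dist[w] = cand;
                    state[w] = TRIAL;
                    heap.push(QE(cand, w));
                }
            }
        }
    };

    for (int v = 0; v < n; ++v)
        if (state[v] >= KNOWN) relax_around(v);

    std::vector<double> accepted;
    accepted.reserve(n);
    while (!heap.empty()) {
        QE top = heap.top();
        heap.pop();
        int v = top.second;
        if (state[v] >= KNOWN) continue;
        if (top.first > dist[v] * (1 + 1e-12) + 1e-300) continue; // stale entry
        state[v] = KNOWN;
        accepted.push_back(dist[v]);
        relax_around(v);
    }
    return List::create(_["distance"] = dist, _["state"] = state,
                        _["accepted"] = NumericVector(accepted.begin(), accepted.end()));
}

// ---- line-of-sight initialisation (Algorithm-1 style) ----------------------

// Does the segment from x0 towards the seed leave element e through a facet
// whose opposite element is already LOS-classified?
static bool ray_test(const double* x0, const double* seed,
                     const NumericMatrix& nodes, const IntegerMatrix& elements,
                     const IntegerMatrix& neighbors, const std::vector<char>& elem_los,
                     int e, int dim, int k) {
    double dir[3];
    subd(seed, x0, dir, dim);
    double len = normd(dir, dim);
    if (len < 1e-300) return true; // at the seed itself
    const double tol = 1e-9;
    for (int f = 0; f < k; ++f) { // facet opposite local node f
        int opp = neighbors(e, f);
        if (opp == 0 || !elem_los[opp - 1]) continue;
        // facet node coordinates
        double fc[3][3];
        int t = 0;
        for (int j = 0; j < k; ++j) {
            if (j == f) continue;
            int nn = elements(e, j) - 1;
            for (int i = 0; i < dim; ++i) fc[t][i] = nodes(nn, i);
            ++t;
        }
        if (dim == 2) {
            // segment x0 + t dir vs segment fc0-fc1
            double e1[2] = {fc[1][0] - fc[0][0], fc[1][1] - fc[0][1]};
            double det = dir[0] * (-e1[1]) - dir[1] * (-e1[0]);
            if (std::fabs(det) < 1e-14 * len) continue;
            double rx = fc[0][0] - x0[0], ry = fc[0][1] - x0[1];
            double tt = (rx * (-e1[1]) - ry * (-e1[0])) / det;
            double ss = (dir[0] * ry - dir[1] * rx) / det;
            if (tt > tol && tt <= 1.0 + tol && ss >= -tol && ss <= 1.0 + tol) return true;
        } else {
            double e1[3], e2[3], nrm[3], r0[3];
            subd(fc[1], fc[0], e1, 3);
            subd(fc[2], fc[0], e2, 3);
            cross3(e1, e2, nrm);
            double denom = dot3(nrm, dir);
            if (std::fabs(denom) < 1e-14 * normd(nrm, 3) * len) continue;
            subd(fc[0], x0, r0, 3);
            double tt = dot3(nrm, r0) / denom;
            if (tt <= tol || tt > 1.0 + tol) continue;
            double q[3], qw[3];
            for (int i = 0; i < 3; ++i) q[i] = x0[i] + tt * dir[i];
            subd(q, fc[0], qw, 3);
            double g00 = dot3(e1, e1), g01 = dot3(e1, e2), g11 = dot3(e2, e2);
            double det = g00 * g11 - g01 * g01;
            if (std::fabs(det) < 1e-300) continue;
            double a0 = (g11 * dot3(e1, qw) - g01 * dot3(e2, qw)) / det;
            double a1 = (-g01 * dot3(e1, qw) + g00 * dot3(e2, qw)) / det;
            if (a0 >= -tol && a1 >= -tol && a0 + a1 <= 1.0 + tol) return true;
        }
    }
    return false;
}

// [[Rcpp::export]]
List cpp_los_init(NumericMatrix nodes, IntegerMatrix elements, IntegerMatrix neighbors,
                  NumericVector seed_, int e0) {
    const int n = nodes.nrow(), m = elements.nrow(), dim = nodes.ncol(),
              k = elements.ncol();
    NumericVector dist(n, R_PosInf);
    IntegerVector state(n, FAR);
    std::vector<char> elem_los(m, 0);
    double seed[3];
    for (int i = 0; i < dim; ++i) seed[i] = seed_[i];

    typedef std::pair<double, int> QE;
    std::priority_queue<QE, std::vector<QE>, std::greater<QE> > queue;

    auto euclid_to_seed = [&](int v) {
        double w[3];
        for (int i = 0; i < dim; ++i) w[i] = nodes(v, i) - seed[i];
        return normd(w, dim);
    };
    auto elem_key = [&](int e) {
        double best = R_PosInf;
        bool any = false;
        for (int j = 0; j < k; ++j) {
            int v = elements(e, j) - 1;
            if (state[v] == FAR) {
                any = true;
                best = std::min(best, euclid_to_seed(v));
            }
        }
        if (any) return best;
        double c[3] = {0, 0, 0};
        for (int j = 0; j < k; ++j) {
            int v = elements(e, j) - 1;
            for (int i = 0; i < dim; ++i) c[i] += nodes(v, i);
        }
        for (int i = 0; i < dim; ++i) c[i] = c[i] / k - seed[i];
        return normd(c, dim);
    };
    auto push_neighbors = [&](int e) {
        for (int f = 0; f < k; ++f) {
            int opp = neighbors(e, f);
            if (opp > 0) queue.push(QE(elem_key(opp - 1), opp - 1));
        }
    };

    // seed element: its nodes see the seed through the element interior
    int e0i = e0 - 1;
    elem_los[e0i] = 1;
    for (int j = 0; j < k; ++j) {
        int v = elements(e0i, j) - 1;
        dist[v] = euclid_to_seed(v);
        state[v] = KNOWN_LOS;
    }
    push_neighbors(e0i);

    double x0[3];
    while (!queue.empty()) {
        int e = queue.top().second;
        queue.pop();
        bool changed = false;
        bool has_unset = false;
        for (int j = 0; j < k; ++j) {
            int v = elements(e, j) - 1;
            if (state[v] != FAR) continue;
            has_unset = true;
            for (int i = 0; i < dim; ++i) x0[i] = nodes(v, i);
            if (ray_test(x0, seed, nodes, elements, neighbors, elem_los, e, dim, k)) {
                dist[v] = euclid_to_seed(v);
                state[v] = KNOWN_LOS;
                if (!elem_los[e]) elem_los[e] = 1;
                changed = true;
            }
        }
        if (!has_unset && !elem_los[e]) {
            // all nodes already have distances: classify via the centroid so
            // that visibility growth does not stall behind fully-known elements
            double c[3] = {0, 0, 0};
            for (int j = 0; j < k; ++j) {
                int v = elements(e, j) - 1;
                for (int i = 0; i < dim; ++i) c[i] += nodes(v, i);
            }
            for (int i = 0; i < dim; ++i) c[i] /= k;
            if (ray_test(c, seed, nodes, elements, neighbors, elem_los, e, dim, k)) {
                elem_los[e] = 1;
                changed = true;
            }
        }
        if (changed) push_neighbors(e);
    }

    return List::create(_["distance"] = dist, _["state"] = state,
                        _["elem_los"] = LogicalVector(elem_los.begin(), elem_los.end()));
}
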