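// Mesh adjacency, point location and raster utilities.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <algorithm>
#include "geom.h"

using namespace Rcpp;
using namespace cdtgeom;

// Facet key: sorted node ids packed into 64 bits (supports up to 2^21 nodes in 3D,
// 2^31 in 2D; mesh sizes here stay far below both).
static inline uint64_t facet_key(std::vector<int>& ids) {
    std::sort(ids.begin(), ids.end());
    if (ids.size() == 2) {
        return (static_cast<uint64_t>(ids[0]) << 31) | static_cast<uint64_t>(ids[1]);
    }
    return (static_cast<uint64_t>(ids[0]) << 42) |
           (static_cast<uint64_t>(ids[1]) << 21) |
            static_cast<uint64_t>(ids[2]);
}

// neighbors[e][k] = 1-based index of the element sharing the facet opposite
// node k of element e, or 0 when the facet is on the boundary.
// Errors if a facet is shared by more than two elements (non-conforming).
// [[Rcpp::export]]
IntegerMatrix cpp_build_neighbors(IntegerMatrix elements) {
    const int m = elements.nrow(), k = elements.ncol();
    IntegerMatrix nb(m, k);
    std::unordered_map<uint64_t, std::pair<int, int> > seen; // key -> (elem, local facet)
    seen.reserve(static_cast<size_t>(m) * k);
    std::vector<int> ids(k - 1);
    for (int e = 0; e < m; ++e) {
        for (int f = 0; f < k; ++f) { // facet opposite local node f
            int t = 0;
            for (int j = 0; j < k; ++j) if (j != f) ids[t++] = elements(e, j);
            uint64_t key = facet_key(ids);
            auto it = seen.find(key);
            if (it == seen.end()) {
                seen.emplace(key, std::make_pair(e, f));
            } else {
                if (it->second.first < 0)
                    stop("non-conforming mesh: facet shared by more than two elements");
                nb(e, f) = it->second.first + 1;
                nb(it->second.first, it->second.second) = e + 1;
                it->second.first = -1; // mark consumed
            }
        }
    }
    return nb;
}

// CSR star: for each node, the (1-based) elements incident to it.
// [[Rcpp::export]]
List cpp_node_star(IntegerMatrix elements, int nnodes) {
    const int m = elements.nrow(), k = elements.ncol();
    std::vector<int> cnt(nnodes + 1, 0);
    for (int e = 0; e < m; ++e)
        for (int j = 0; j < k; ++j) cnt[elements(e, j)]++;
    IntegerVector ptr(nnodes + 1);
    ptr[0] = 0;
    for (int i = 1; i <= nnodes; ++i) ptr[i] = ptr[i - 1] + cnt[i];
    IntegerVector idx(ptr[nnodes]);
    std::vector<int> fill(nnodes, 0);
    for (int e = 0; e < m; ++e)
        for (int j = 0; j < k; ++j) {
            int n = elements(e, j) - 1;
            idx[ptr[n] + fill[n]++] = e + 1;
        }
    return List::create(_["ptr"] = ptr, _["idx"] = idx);
}

struct BinGrid {
    double lo[3], cell[3];
    int nb[3], dim;
    std::vector<std::vector<int> > bins;
    int nbin() const { int n = 1; for (int i = 0; i < dim; ++i) n *= nb[i]; return n; }
    int bin_of(const double* p) const {
        int ix[3], lin = 0, stride = 1;
        for (int i = 0; i < dim; ++i) {
            int v = static_cast<int>(std::floor((p[i] - lo[i]) / cell[i]));
            if (v < 0) v = 0; if (v >= nb[i]) v = nb[i] - 1;
            ix[i] = v;
        }
        for (int i = 0; i < dim; ++i) { lin += ix[i] * stride; stride *= nb[i]; }
        return lin;
    }
};

static void build_bingrid(const NumericMatrix& nodes, const IntegerMatrix& elements,
                          int dim, BinGrid& g) {
    const int m = elements.nrow(), k = elements.ncol();
    g.dim = dim;
    double hi[3];
    for (int i = 0; i < dim; ++i) { g.lo[i] = R_PosInf; hi[i] = R_NegInf; }
    for (int n = 0; n < nodes.nrow(); ++n)
        for (int i = 0; i < dim; ++i) {
            double v = nodes(n, i);
            if (v < g.lo[i]) g.lo[i] = v;
            if (v > hi[i]) hi[i] = v;
        }
    double target = std::pow(static_cast<double>(std::max(m, 1)), 1.0 / dim);
    for (int i = 0; i < dim; ++i) {
        g.nb[i] = std::max(1, std::min(512, static_cast<int>(target)));
        double ext = hi[i] - g.lo[i];
        g.cell[i] = (ext > 0 ? ext : 1.0) / g.nb[i] * (1.0 + 1e-12);
    }
    g.bins.assign(g.nbin(), std::vector<int>());
    for (int e = 0; e < m; ++e) {
        int lo_ix[3], hi_ix[3];
        for (int i = 0; i < dim; ++i) { lo_ix[i] = INT_MAX; hi_ix[i] = INT_MIN; }
        for (int j = 0; j < k; ++j) {
            int n = elements(e, j) - 1;
            for (int i = 0; i < dim; ++i) {
                int v = static_cast<int>(std::floor((nodes(n, i) - g.lo[i]) / g.cell[i]));
                if (v < 0) v = 0; if (v >= g.nb[i]) v = g.nb[i] - 1;
                lo_ix[i] = std::min(lo_ix[i], v);
                hi_ix[i] = std::max(hi_ix[i], v);
            }
        }
        int iz0 = (dim == 3) ? lo_ix[2] : 0, iz1 = (dim == 3) ? hi_ix[2] : 0;
        for (int iz = iz0; iz <= iz1; ++iz)
            for (int iy = lo_ix[1]; iy <= hi_ix[1]; ++iy)
                for (int ix = lo_ix[0]; ix <= hi_ix[0]; ++ix) {
                    int lin = ix + iy * g.nb[0];
                    if (dim == 3) lin += iz * g.nb[0] * g.nb[1];
                    g.bins[lin].push_back(e);
                }
    }
    for (auto& b : g.bins) std::sort(b.begin(), b.end());
}

// Locate points in a simplicial mesh. Returns element index (0 = not found,
// ties broken by lowest element index) and barycentric coordinates.
// [[Rcpp::export]]
List cpp_locate_points(NumericMatrix nodes, IntegerMatrix elements,
                       NumericMatrix points, double tol = 1e-9) {
    const int dim = nodes.ncol(), k = elements.ncol(), np = points.nrow();
    BinGrid g;
    build_bingrid(nodes, elements, dim, g);
    IntegerVector elem(np);
    NumericMatrix bary(np, k);
    std::vector<const double*> v(k);
    std::vector<std::vector<double> > vc(k, std::vector<double>(dim));
    double p[3], b[4];
    for (int q = 0; q < np; ++q) {
        for (int i = 0; i < dim; ++i) p[i] = points(q, i);
        const std::vector<int>& cand = g.bins[g.bin_of(p)];
        int found = 0;
        for (int e : cand) {
            for (int j = 0; j < k; ++j) {
                int n = elements(e, j) - 1;
                for (int i = 0; i < dim; ++i) vc[j][i] = nodes(n, i);
                v[j] = vc[j].data();
            }
            if (!barycentric(v.data(), p, dim, b)) continue;
            bool inside = true;
            for (int j = 0; j < k; ++j) if (b[j] < -tol) { inside = false; break; }
            if (inside) {
                found = e + 1;
                double s = 0;
                for (int j = 0; j < k; ++j) { if (b[j] < 0) b[j] = 0; s += b[j]; }
                for (int j = 0; j < k; ++j) bary(q, j) = b[j] / s;
                break; // bins sorted ascending -> lowest element index
            }
        }
        elem[q] = found;
    }
    return List::create(_["element"] = elem, _["bary"] = bary);
}

// Face-connectivity component labelling of a logical raster (2D or 3D).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
    const int nd = dims.size();
    int nx = dims[0], ny = dims[1], nz = (nd == 3) ? dims[2] : 1;
    R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
    IntegerVector lab(n, 0);
    std::vector<R_xlen_t> stack;
    int cur = 0;
    for (R_xlen_t s = 0; s < n; ++s) {
        if (!mask[s] || lab[s] != 0) continue;
        ++cur;
        stack.push_back(s);
        lab[s] = cur;
        while (!stack.empty()) {
            R_xlen_t c = stack.back(); stack.pop_back();
            int x = c % nx, y = (c / nx) % ny, z = c / (static_cast<R_xlen_t>(nx) * ny);
            const int dx[6] = {-1, 1, 0, 0, 0, 0};
            const int dy[6] = {0, 0, -1, 1, 0, 0};
            const int dz[6] = {0, 0, 0, 0, -1, 1};
            int nnb = (nd == 3) ? 6 : 4;
            for (int t = 0; t < nnb; ++t) {
                int xx = x + dx[t], yy = y + dy[t], zz = z + dz[t];
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
                R_xlen_t cc = xx + static_cast<R_xlen_t>(nx) * (yy + static_cast<R_xlen_t>(ny) * zz);
                if (mask[cc] && lab[cc] == 0) { lab[cc] = cur; stack.push_back(cc); }
            }
        }
    }
    return lab;
}

// For each query cell (0-based multi-index rows), the 0-based linear index of
// the nearest TRUE cell within maxr (Chebyshev) rings, or -1.
// [[Rcpp::export]]
IntegerVector cpp_nearest_true_cell(LogicalVector mask, IntegerVector dims,
                                    IntegerMatrix queries, int maxr) {
    const int nd = dims.size();
    int nx = dims[0], ny = dims[1], nz = (nd == 3) ? dims[2] : 1;
    IntegerVector out(queries.nrow(), -1);
    for (int q = 0; q < queries.nrow(); ++q) {
        int qx = queries(q, 0), qy = queries(q, 1), qz = (nd == 3) ? queries(q, 2) : 0;
        double best = R_PosInf;
        R_xlen_t besti = -1;
        for (int r = 0; r <= maxr; ++r) {
            if (besti >= 0 && best <= static_cast<double>(r) * r) break;
            for (int dz = (nd == 3 ? -r : 0); dz <= (nd == 3 ? r : 0); ++dz)
                for (int dy = -r; dy <= r; ++dy)
                    for (int dx = -r; dx <= r; ++dx) {
                        if (std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz))) != r)
                            continue; // ring only
                        int x = qx + dx, y = qy + dy, z = qz + dz;
                        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
                        R_xlen_t c = x + static_cast<R_xlen_t>(nx) * (y + static_cast<R_xlen_t>(ny) * z);
                        if (!mask[c]) continue;
                        double d2 = static_cast<double>(dx) * dx + static_cast<double>(dy) * dy +
                                    static_cast<double>(dz) * dz;
                        if (d2 < best) { best = d2; besti = c; }
                    }
        }
        if (besti >= 0) out[q] = static_cast<int>(besti);
    }
    return out;
}

// Signed areas/volumes for all elements.
// [[Rcpp::export]]
NumericVector cpp_signed_measures(NumericMatrix nodes, IntegerMatrix elements) {
    const int dim = nodes.ncol(), k = elements.ncol(), m = elements.nrow();
    NumericVector out(m);
    std::vector<const double*> v(k);
    std::vector<std::vector<double> > vc(k, std::vector<double>(dim));
    for (int e = 0; e < m; ++e) {
        for (int j = 0; j < k; ++j) {
            int n = elements(e, j) - 1;
            for (int i = 0; i < dim; ++i) vc[j][i] = nodes(n, i);
            v[j] = vc[j].data();
        }
        out[e] = signed_measure(v.data(), dim);
    }
    return out;
}
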