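// Mesh-based image resampling: pull-back (mesh on target, displacements map
// into source space) and forward (mesh on source, displaced elements
// rasterised by per-simplex scanline).
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "geom.h"

using namespace Rcpp;
using namespace cdtgeom;

// Sample a raster (2D/3D) at world position w. Returns false when w falls
// outside the raster.
static bool sample_raster(const NumericVector& vals, const IntegerVector& dims,
                          const NumericVector& origin, const NumericVector& spacing,
                          const double* w, int dim, int interp, double* out) {
    double fi[3];
    int n[3] = {1, 1, 1};
    for (int i = 0; i < dim; ++i) {
        n[i] = dims[i];
        fi[i] = (w[i] - origin[i]) / spacing[i];
    }
    if (interp == 0) { // nearest
        R_xlen_t lin = 0, stride = 1;
        for (int i = 0; i < dim; ++i) {
            int ix = static_cast<int>(std::lround(fi[i]));
            if (ix < 0 || ix >= n[i]) return false;
            lin += ix * stride;
            stride *= n[i];
        }
        *out = vals[lin];
        return true;
    }
    int i0[3];
    double fr[3];
    for (int i = 0; i < dim; ++i) {
        if (fi[i] < -1e-9 || fi[i] > n[i] - 1 + 1e-9) return false;
        double f = std::min(std::max(fi[i], 0.0), static_cast<double>(n[i] - 1));
        i0[i] = std::min(static_cast<int>(std::floor(f)), n[i] - 2 >= 0 ? n[i] - 2 : 0);
        fr[i] = f - i0[i];
    }
    double acc = 0;
    int ncorner = 1 << dim;
    for (int c = 0; c < ncorner; ++c) {
        double wgt = 1;
        R_xlen_t lin = 0, stride = 1;
        for (int i = 0; i < dim; ++i) {
            int bit = (c >> i) & 1;
            int ix = i0[i] + bit;
            if (ix >= n[i]) ix = n[i] - 1;
            wgt *= bit ? fr[i] : (1 - fr[i]);
            lin += ix * stride;
            stride *= n[i];
        }
        acc += wgt * vals[lin];
    }
    *out = acc;
    return true;
}

struct Grid {
    int n[3];
    double origin[3], spacing[3];
    int dim;
    R_xlen_t size() const {
        R_xlen_t s = 1;
        for (int i = 0; i < dim; ++i) s *= n[i];
        return s;
    }
};

// [[Rcpp::export]]
List cpp_pullback(NumericMatrix nodes, IntegerMatrix elements, NumericMatrix disp,
                  IntegerVector out_dims, NumericVector out_origin, NumericVector out_spacing,
                  NumericVector src_vals, IntegerVector src_dims, NumericVector src_origin,
                  NumericVector src_spacing, int interp, double fill, bool has_values) {
    const int dim = nodes.ncol(), k = elements.ncol(), m = elements.nrow();
    Grid g;
    g.dim = dim;
    for (int i = 0; i < dim; ++i) {
        g.n[i] = out_dims[i];
        g.origin[i] = out_origin[i];
        g.spacing[i] = out_spacing[i];
    }
    R_xlen_t sz = g.size();
    NumericVector out(sz, has_values ? fill : NA_REAL);
    LogicalVector mask(sz, false), unmapped(sz, false);

    const double* v[4];
    double vc[4][3], dsp[4][3], b[4], p[3], mapped[3];
    for (int e = 0; e < m; ++e) {
        int lo[3], hi[3];
        for (int i = 0; i < dim; ++i) { lo[i] = INT_MAX; hi[i] = INT_MIN; }
        for (int j = 0; j < k; ++j) {
            int nn = elements(e, j) - 1;
            for (int i = 0; i < dim; ++i) {
                vc[j][i] = nodes(nn, i);
                dsp[j][i] = disp(nn, i);
                double fi = (vc[j][i] - g.origin[i]) / g.spacing[i];
                lo[i] = std::min(lo[i], static_cast<int>(std::floor(fi - 1e-9)));
                hi[i] = std::max(hi[i], static_cast<int>(std::ceil(fi + 1e-9)));
            }
            v[j] = vc[j];
        }
        for (int i = 0; i < dim; ++i) {
            lo[i] = std::max(lo[i], 0);
            hi[i] = std::min(hi[i], g.n[i] - 1);
        }
        int z0 = dim == 3 ? lo[2] : 0, z1 = dim == 3 ? hi[2] : 0;
        for (int iz = z0; iz <= z1; ++iz)
            for (int iy = lo[1]; iy <= hi[1]; ++iy)
                for (int ix = lo[0]; ix <= hi[0]; ++ix) {
                    R_xlen_t lin = ix + static_cast<R_xlen_t>(g.n[0]) *
                                            (iy + static_cast<R_xlen_t>(g.n[1]) * iz);
                    if (mask[lin]) continue; // lowest element index wins
                    p[0] = g.origin[0] + ix * g.spacing[0];
                    p[1] = g.origin[1] + iy * g.spacing[1];
                    if (dim == 3) p[2] = g.origin[2] + iz * g.spacing[2];
                    if (!barycentric(v, p, dim, b)) continue;
                    bool inside = true;
                    for (int j = 0; j < k; ++j) if (b[j] < -1e-9) { inside = false; break; }
                    if (!inside) continue;
                    mask[lin] = true;
                    if (!has_values) continue;
                    for (int i = 0; i < dim; ++i) {
                        mapped[i] = 0;
                        for (int j = 0; j < k; ++j) mapped[i] += b[j] * (vc[j][i] + dsp[j][i]);
                    }
                    double val;
                    if (sample_raster(src_vals, src_dims, src_origin, src_spacing,
                                      mapped, dim, interp, &val)) {
                        out[lin] = val;
                    } else {
                        out[lin] = fill;
                        unmapped[lin] = true;
                    }
                }
    }
    return List::create(_["values"] = out, _["mask"] = mask, _["unmapped"] = unmapped);
}

// [[Rcpp::export]]
List cpp_forward(NumericMatrix nodes, IntegerMatrix elements, NumericMatrix disp,
                 IntegerVector out_dims, NumericVector out_origin, NumericVector out_spacing,
                 NumericVector src_vals, IntegerVector src_dims, NumericVector src_origin,
                 NumericVector src_spacing, int interp, double fill, bool has_values) {
    const int dim = nodes.ncol(), k = elements.ncol(), m = elements.nrow();
    Grid g;
    g.dim = dim;
    for (int i = 0; i < dim; ++i) {
        g.n[i] = out_dims[i];
        g.origin[i] = out_origin[i];
        g.spacing[i] = out_spacing[i];
    }
    R_xlen_t sz = g.size();
    NumericVector out(sz, has_values ? fill : NA_REAL);
    LogicalVector mask(sz, false), unmapped(sz, false);
    int degenerate = 0;

    const double* v[4];
    double vd[4][3], vo[4][3], b[4], p[3], srcp[3];
    for (int e = 0; e < m; ++e) {
        for (int j = 0; j < k; ++j) {
            int nn = elements(e, j) - 1;
            for (int i = 0; i < dim; ++i) {
                vo[j][i] = nodes(nn, i);
                vd[j][i] = vo[j][i] + disp(nn, i);
            }
            v[j] = vd[j];
        }
        double meas = signed_measure(v, dim);
        double scale = 1.0;
        for (int i = 0; i < dim; ++i) scale *= g.spacing[i];
        if (std::fabs(meas) < 1e-12 * scale) { ++degenerate; continue; }
        int lo[3], hi[3];
        for (int i = 0; i < dim; ++i) { lo[i] = INT_MAX; hi[i] = INT_MIN; }
        for (int j = 0; j < k; ++j)
            for (int i = 0; i < dim; ++i) {
                double fi = (vd[j][i] - g.origin[i]) / g.spacing[i];
                lo[i] = std::min(lo[i], static_cast<int>(std::floor(fi - 1e-9)));
                hi[i] = std::max(hi[i], static_cast<int>(std::ceil(fi + 1e-9)));
            }
        for (int i = 0; i < dim; ++i) {
            lo[i] = std::max(lo[i], 0);
            hi[i] = std::min(hi[i], g.n[i] - 1);
        }
        int z0 = dim == 3 ? lo[2] : 0, z1 = dim == 3 ? hi[2] : 0;
        for (int iz = z0; iz <= z1; ++iz)
            for (int iy = lo[1]; iy <= hi[1]; ++iy)
                for (int ix = lo[0]; ix <= hi[0]; ++ix) {
                    p[0] = g.origin[0] + ix * g.spacing[0];
                    p[1] = g.origin[1] + iy * g.spacing[1];
                    if (dim == 3) p[2] = g.origin[2] + iz * g.spacing[2];
                    if (!barycentric(v, p, dim, b)) continue;
                    bool inside = true;
                    for (int j = 0; j < k; ++j) if (b[j] < -1e-9) { inside = false; break; }
                    if (!inside) continue;
                    R_xlen_t lin = ix + static_cast<R_xlen_t>(g.n[0]) *
                                            (iy + static_cast<R_xlen_t>(g.n[1]) * iz);
                    mask[lin] = true; // last written wins (ascending element order)
                    if (!has_values) continue;
                    for (int i = 0; i < dim; ++i) {
                        srcp[i] = 0;
                        for (int j = 0; j < k; ++j) srcp[i] += b[j] * vo[j][i];
                    }
                    double val;
                    if (sample_raster(src_vals, src_dims, src_origin, src_spacing,
                                      srcp, dim, interp, &val)) {
                        out[lin] = val;
                        unmapped[lin] = false;
                    } else {
                        out[lin] = fill;
                        unmapped[lin] = true;
                    }
                }
    }
    return List::create(_["values"] = out, _["mask"] = mask, _["unmapped"] = unmapped,
                        _["degenerate"] = degenerate);
}
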