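#ifndef CDT_GEOM_H
#define CDT_GEOM_H

#include <cmath>
#include <cstdint>

namespace cdtgeom {

inline double dot2(const double* a, const double* b) {
    return a[0] * b[0] + a[1] * b[1];
}
inline double dot3(const double* a, const double* b) {
    return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
inline double dotd(const double* a, const double* b, int d) {
    return d == 2 ? dot2(a, b) : dot3(a, b);
}
inline double normd(const double* a, int d) {
    return std::sqrt(dotd(a, a, d));
}
inline void subd(const double* a, const double* b, double* out, int d) {
    for (int i = 0; i < d; ++i) out[i] = a[i] - b[i];
}
inline void cross3(const double* a, const double* b, double* out) {
    out[0] = a[1] * b[2] - a[2] * b[1];
    out[1] = a[2] * b[0] - a[0] * b[2];
    out[2] = a[0] * b[1] - a[1] * b[0];
}

// Barycentric coordinates of p in simplex with vertices v[0..d] (each length d).
// Returns false if the simplex is degenerate.
inline bool barycentric(const double* const* v, const double* p, int d, double* b) {
    if (d == 2) {
        double e1[2], e2[2], q[2];
        subd(v[1], v[0], e1, 2);
        subd(v[2], v[0], e2, 2);
        subd(p, v[0], q, 2);
        double det = e1[0] * e2[1] - e1[1] * e2[0];
        if (std::fabs(det) < 1e-300) return false;
        double b1 = (q[0] * e2[1] - q[1] * e2[0]) / det;
        double b2 = (e1[0] * q[1] - e1[1] * q[0]) / det;
        b[0] = 1.0 - b1 - b2; b[1] = b1; b[2] = b2;
        return true;
    } else {
        double e1[3], e2[3], e3[3], q[3], c[3];
        subd(v[1], v[0], e1, 3);
        subd(v[2], v[0], e2, 3);
        subd(v[3], v[0], e3, 3);
        subd(p, v[0], q, 3);
        cross3(e2, e3, c);
        double det = dot3(e1, c);
        if (std::fabs(det) < 1e-300) return false;
        double b1 = dot3(q, c) / det;
        cross3(e3, e1, c);
        double b2 = dot3(q, c) / det;
        cross3(e1, e2, c);
        double b3 = dot3(q, c) / det;
        b[0] = 1.0 - b1 - b2 - b3; b[1] = b1; b[2] = b2; b[3] = b3;
        return true;
    }
}

// Signed area (2D) / signed volume (3D) of a simplex.
inline double signed_measure(const double* const* v, int d) {
    if (d == 2) {
        double e1[2], e2[2];
        subd(v[1], v[0], e1, 2);
        subd(v[2], v[0], e2, 2);
        return 0.5 * (e1[0] * e2[1] - e1[1] * e2[0]);
    } else {
        double e1[3], e2[3], e3[3], c[3];
        subd(v[1], v[0], e1, 3);
        subd(v[2], v[0], e2, 3);
        subd(v[3], v[0], e3, 3);
        cross3(e2, e3, c);
        return dot3(e1, c) / 6.0;
    }
}

} // namespace cdtgeom

#endif
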