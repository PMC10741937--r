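#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared-distance transform (lower envelope of parabolas), sample
// positions x_i = i * s so anisotropic spacing is handled exactly.
static void dt1d(const double* f, double* d, int n, double s,
                 std::vector<int>& v, std::vector<double>& z) {
    int k = 0;
    v[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    for (int q = 1; q < n; ++q) {
        if (f[q] == INF) continue;
        if (f[v[0]] == INF && k == 0) { v[0] = q; continue; }
        double xq = q * s;
        while (true) {
            double xp = v[k] * s;
            double sden = 2.0 * (xq - xp);
            double inter = ((f[q] + xq * xq) - (f[v[k]] + xp * xp)) / sden;
            if (inter <= z[k]) {
                --k;
            } else {
                ++k;
                v[k] = q;
                z[k] = inter;
                z[k + 1] = INF;
                break;
            }
        }
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        double xq = q * s;
        while (z[k + 1] < xq) ++k;
        double xp = v[k] * s;
        d[q] = (xq - xp) * (xq - xp) + f[v[k]];
    }
}

// Exact Euclidean distance (mm) from every voxel center to the nearest
// TRUE voxel center, honoring anisotropic spacing. All-FALSE input gives Inf.
// [[Rcpp::export(name = ".edt_mm")]]
NumericVector edt_mm(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    R_xlen_t n = (R_xlen_t)nx * ny * nz;
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // pass along x
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j) {
            R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
            bool any = false;
            for (int i = 0; i < nx; ++i) { f[i] = out[base + i]; if (f[i] < INF) any = true; }
            if (!any) continue;
            dt1d(f.data(), d.data(), nx, spacing[0], v, z);
            for (int i = 0; i < nx; ++i) out[base + i] = d[i];
        }
    // pass along y
    for (int k = 0; k < nz; ++k)
        for (int i = 0; i < nx; ++i) {
            R_xlen_t base = i + (R_xlen_t)nx * ny * k;
            bool any = false;
            for (int j = 0; j < ny; ++j) { f[j] = out[base + (R_xlen_t)nx * j]; if (f[j] < INF) any = true; }
            if (!any) continue;
            dt1d(f.data(), d.data(), ny, spacing[1], v, z);
            for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)nx * j] = d[j];
        }
    // pass along z
    R_xlen_t nxy = (R_xlen_t)nx * ny;
    for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
            R_xlen_t base = i + (R_xlen_t)nx * j;
            bool any = false;
            for (int k = 0; k < nz; ++k) { f[k] = out[base + nxy * k]; if (f[k] < INF) any = true; }
            if (!any) continue;
            dt1d(f.data(), d.data(), nz, spacing[2], v, z);
            for (int k = 0; k < nz; ++k) out[base + nxy * k] = d[k];
        }

    for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
    out.attr("dim") = dims;
    return out;
}

static void conv1(const std::vector<double>& in, std::vector<double>& outv,
                  int n, const NumericVector& ker) {
    int r = ((int)ker.size() - 1) / 2;
    for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int t = -r; t <= r; ++t) {
            int idx = i + t;
            if (idx < 0) idx = -idx - 1;          // reflect
            if (idx >= n) idx = 2 * n - idx - 1;
            acc += in[idx] * ker[t + r];
        }
        outv[i] = acc;
    }
}

// Separable 3D convolution with reflection at the borders.
// [[Rcpp::export(name = ".convolve_sep3")]]
NumericVector convolve_sep3(NumericVector arr, IntegerVector dims,
                            NumericVector kx, NumericVector ky, NumericVector kz) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    R_xlen_t n = (R_xlen_t)nx * ny * nz, nxy = (R_xlen_t)nx * ny;
    NumericVector out(clone(arr));
    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> line(nmax), res(nmax);

    if (kx.size() > 1) {
        for (int k = 0; k < nz; ++k)
            for (int j = 0; j < ny; ++j) {
                R_xlen_t base = (R_xlen_t)nx * j + nxy * k;
                for (int i = 0; i < nx; ++i) line[i] = out[base + i];
                conv1(line, res, nx, kx);
                for (int i = 0; i < nx; ++i) out[base + i] = res[i];
            }
    }
    if (ky.size() > 1) {
        for (int k = 0; k < nz; ++k)
            for (int i = 0; i < nx; ++i) {
                R_xlen_t base = i + nxy * k;
                for (int j = 0; j < ny; ++j) line[j] = out[base + (R_xlen_t)nx * j];
                conv1(line, res, ny, ky);
                for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)nx * j] = res[j];
            }
    }
    if (kz.size() > 1) {
        for (int j = 0; j < ny; ++j)
            for (int i = 0; i < nx; ++i) {
                R_xlen_t base = i + (R_xlen_t)nx * j;
                for (int k = 0; k < nz; ++k) line[k] = out[base + nxy * k];
                conv1(line, res, nz, kz);
                for (int k = 0; k < nz; ++k) out[base + nxy * k] = res[k];
            }
    }
    (void)n;
    out.attr("dim") = dims;
    return out;
}

// 6-connected component labels (0 = background), iterative flood fill.
// [[Rcpp::export(name = ".label_components6")]]
IntegerVector label_components6(LogicalVector mask, IntegerVector dims) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    R_xlen_t n = (R_xlen_t)nx * ny * nz, nxy = (R_xlen_t)nx * ny;
    IntegerVector lab(n, 0);
    std::vector<R_xlen_t> stack;
    int cur = 0;
    for (R_xlen_t s = 0; s < n; ++s) {
        if (!mask[s] || lab[s] != 0) continue;
        ++cur;
        lab[s] = cur;
        stack.clear();
        stack.push_back(s);
        while (!stack.empty()) {
            R_xlen_t p = stack.back();
            stack.pop_back();
            int k = (int)(p / nxy);
            int rem = (int)(p % nxy);
            int j = rem / nx, i = rem % nx;
            const int di[6] = {-1, 1, 0, 0, 0, 0};
            const int dj[6] = {0, 0, -1, 1, 0, 0};
            const int dk[6] = {0, 0, 0, 0, -1, 1};
            for (int t = 0; t < 6; ++t) {
                int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
                if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
                R_xlen_t q = ii + (R_xlen_t)nx * jj + nxy * kk;
                if (mask[q] && lab[q] == 0) { lab[q] = cur; stack.push_back(q); }
            }
        }
    }
    lab.attr("dim") = dims;
    return lab;
}

// Overlap counts for two amplitude-encoded membership fields (see
// encode_membership in R): t == +Inf always member, t == -Inf never,
// t > 0 member iff a < t, finite t <= 0 member iff a > -t.
// Returns c(n1, n2, n_intersection).
// [[Rcpp::export(name = ".tenc_counts")]]
NumericVector tenc_counts(NumericVector t1, NumericVector t2, double a) {
    R_xlen_t n = t1.size();
    double n1 = 0, n2 = 0, ni = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
        double u = t1[i], v = t2[i];
        bool m1 = (u == R_PosInf) || (u > 0 && a < u) ||
                  (u <= 0 && u != R_NegInf && a > -u);
        bool m2 = (v == R_PosInf) || (v > 0 && a < v) ||
                  (v <= 0 && v != R_NegInf && a > -v);
        if (m1) ++n1;
        if (m2) ++n2;
        if (m1 && m2) ++ni;
    }
    return NumericVector::create(n1, n2, ni);
}

// Largest 6-connected component of a char mask, in place.
static void cc_largest(std::vector<char>& m, int nx, int ny, int nz) {
    R_xlen_t n = (R_xlen_t)nx * ny * nz, nxy = (R_xlen_t)nx * ny;
    std::vector<int> lab(n, 0);
    std::vector<R_xlen_t> stack;
    std::vector<R_xlen_t> sizes;
    int cur = 0;
    for (R_xlen_t s = 0; s < n; ++s) {
        if (!m[s] || lab[s] != 0) continue;
        ++cur;
        R_xlen_t sz = 0;
        lab[s] = cur;
        stack.clear();
        stack.push_back(s);
        while (!stack.empty()) {
            R_xlen_t p = stack.back(); stack.pop_back();
            ++sz;
            int k = (int)(p / nxy);
            int rem = (int)(p % nxy);
            int j = rem / nx, i = rem % nx;
            const int di[6] = {-1, 1, 0, 0, 0, 0};
            const int dj[6] = {0, 0, -1, 1, 0, 0};
            const int dk[6] = {0, 0, 0, 0, -1, 1};
            for (int t = 0; t < 6; ++t) {
                int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
                if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
                R_xlen_t q = ii + (R_xlen_t)nx * jj + nxy * kk;
                if (m[q] && lab[q] == 0) { lab[q] = cur; stack.push_back(q); }
            }
        }
        sizes.push_back(sz);
    }
    if (cur <= 1) return;
    int best = 1;
    for (int c = 2; c <= cur; ++c) if (sizes[c - 1] > sizes[best - 1]) best = c;
    for (R_xlen_t s = 0; s < n; ++s) m[s] = (lab[s] == best);
}

static inline bool tenc_member(double t, double a) {
    return (t == R_PosInf) || (t > 0 && a < t) ||
           (t <= 0 && t != R_NegInf && a > -t);
}

// Overlap counts at amplitude `a` after keeping each decoded mask's largest
// 6-connected component — the same post-processing the simulator applies.
// [[Rcpp::export(name = ".cc_tenc_counts")]]
NumericVector cc_tenc_counts(NumericVector t1, NumericVector t2, double a,
                             IntegerVector dims) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    R_xlen_t n = (R_xlen_t)nx * ny * nz;
    std::vector<char> m1(n), m2(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        m1[i] = tenc_member(t1[i], a);
        m2[i] = tenc_member(t2[i], a);
    }
    cc_largest(m1, nx, ny, nz);
    cc_largest(m2, nx, ny, nz);
    double n1 = 0, n2 = 0, ni = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
        if (m1[i]) ++n1;
        if (m2[i]) ++n2;
        if (m1[i] && m2[i]) ++ni;
    }
    return NumericVector::create(n1, n2, ni);
}

// Trilinear resampling of a coarse grid onto a fine grid sharing the same
// origin (voxel centre (0,0,0) aligned), clamped at the coarse border.
// [[Rcpp::export(name = ".resample_trilinear")]]
NumericVector resample_trilinear(NumericVector arr, IntegerVector dims_in,
                                 NumericVector spacing_in,
                                 IntegerVector dims_out,
                                 NumericVector spacing_out) {
    int ax = dims_in[0], ay = dims_in[1], az = dims_in[2];
    int nx = dims_out[0], ny = dims_out[1], nz = dims_out[2];
    R_xlen_t axy = (R_xlen_t)ax * ay;
    NumericVector out((R_xlen_t)nx * ny * nz);
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
            for (int i = 0; i < nx; ++i) {
                double fx = i * spacing_out[0] / spacing_in[0];
                double fy = j * spacing_out[1] / spacing_in[1];
                double fz = k * spacing_out[2] / spacing_in[2];
                if (fx > ax - 1) fx = ax - 1;
                if (fy > ay - 1) fy = ay - 1;
                if (fz > az - 1) fz = az - 1;
                int x0 = (int)fx, y0 = (int)fy, z0 = (int)fz;
                int x1 = std::min(x0 + 1, ax - 1), y1 = std::min(y0 + 1, ay - 1),
                    z1 = std::min(z0 + 1, az - 1);
                double tx = fx - x0, ty = fy - y0, tz = fz - z0;
                double c00 = arr[x0 + (R_xlen_t)ax * y0 + axy * z0] * (1 - tx) +
                             arr[x1 + (R_xlen_t)ax * y0 + axy * z0] * tx;
                double c10 = arr[x0 + (R_xlen_t)ax * y1 + axy * z0] * (1 - tx) +
                             arr[x1 + (R_xlen_t)ax * y1 + axy * z0] * tx;
                double c01 = arr[x0 + (R_xlen_t)ax * y0 + axy * z1] * (1 - tx) +
                             arr[x1 + (R_xlen_t)ax * y0 + axy * z1] * tx;
                double c11 = arr[x0 + (R_xlen_t)ax * y1 + axy * z1] * (1 - tx) +
                             arr[x1 + (R_xlen_t)ax * y1 + axy * z1] * tx;
                double c0 = c00 * (1 - ty) + c10 * ty;
                double c1 = c01 * (1 - ty) + c11 * ty;
                out[i + (R_xlen_t)nx * j + (R_xlen_t)nx * ny * k] =
                    c0 * (1 - tz) + c1 * tz;
            }
    out.attr("dim") = dims_out;
    return out;
}

// Sample a signed-distance field under a similarity transform (uniform scale
// `s` about `center_mm` followed by translation `trans_mm`): the returned
// field at voxel x is s * sdf(center + (x - trans - center)/s), i.e. the SDF
// of the transformed shape. Trilinear interpolation, clamped at the border.
// [[Rcpp::export(name = ".sdf_similarity_sample")]]
NumericVector sdf_similarity_sample(NumericVector sdf, IntegerVector dims,
                                    NumericVector spacing, NumericVector center_mm,
                                    NumericVector trans_mm, double s) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    R_xlen_t nxy = (R_xlen_t)nx * ny;
    NumericVector out((R_xlen_t)nx * ny * nz);
    double sx = spacing[0], sy = spacing[1], sz = spacing[2];

    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
            for (int i = 0; i < nx; ++i) {
                // world mm position of this voxel center (grid-internal frame)
                double wx = i * sx, wy = j * sy, wz = k * sz;
                double ux = center_mm[0] + (wx - trans_mm[0] - center_mm[0]) / s;
                double uy = center_mm[1] + (wy - trans_mm[1] - center_mm[1]) / s;
                double uz = center_mm[2] + (wz - trans_mm[2] - center_mm[2]) / s;
                double fx = ux / sx, fy = uy / sy, fz = uz / sz;
                if (fx < 0) fx = 0; if (fx > nx - 1) fx = nx - 1;
                if (fy < 0) fy = 0; if (fy > ny - 1) fy = ny - 1;
                if (fz < 0) fz = 0; if (fz > nz - 1) fz = nz - 1;
                int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy), z0 = (int)std::floor(fz);
                int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
                    z1 = std::min(z0 + 1, nz - 1);
                double tx = fx - x0, ty = fy - y0, tz = fz - z0;
                double c000 = sdf[x0 + (R_xlen_t)nx * y0 + nxy * z0];
                double c100 = sdf[x1 + (R_xlen_t)nx * y0 + nxy * z0];
                double c010 = sdf[x0 + (R_xlen_t)nx * y1 + nxy * z0];
                double c110 = sdf[x1 + (R_xlen_t)nx * y1 + nxy * z0];
                double c001 = sdf[x0 + (R_xlen_t)nx * y0 + nxy * z1];
                double c101 = sdf[x1 + (R_xlen_t)nx * y0 + nxy * z1];
                double c011 = sdf[x0 + (R_xlen_t)nx * y1 + nxy * z1];
                double c111 = sdf[x1 + (R_xlen_t)nx * y1 + nxy * z1];
                double c00 = c000 * (1 - tx) + c100 * tx;
                double c10 = c010 * (1 - tx) + c110 * tx;
                double c01 = c001 * (1 - tx) + c101 * tx;
                double c11 = c011 * (1 - tx) + c111 * tx;
                double c0 = c00 * (1 - ty) + c10 * ty;
                double c1 = c01 * (1 - ty) + c11 * ty;
                out[i + (R_xlen_t)nx * j + nxy * k] = s * (c0 * (1 - tz) + c1 * tz);
            }
    out.attr("dim") = dims;
    return out;
}
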