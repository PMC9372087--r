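#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Separable squared Euclidean distance transform (Felzenszwalb & Huttenlocher,
// Theory of Computing 2012) extended to anisotropic sample spacing. Distances
// are to the *centers* of feature voxels, in physical units, which is exactly
// what surface-distance metrics on voxel-center point sets require.

static const double BIG = 1e30;

// One 1-D pass over a line of squared distances. `s2` is the squared sample
// spacing along this axis. f: input squared distances, d: output.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n, double s2) {
    int k = 0;
    v[0] = 0;
    z[0] = -1e35;
    z[1] = 1e35;
    for (int q = 1; q < n; ++q) {
        double sq;
        while (true) {
            int p = v[k];
            sq = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) /
                 (2.0 * s2 * (q - p));
            if (k > 0 && sq <= z[k]) {
                --k;
            } else {
                break;
            }
        }
        ++k;
        v[k] = q;
        z[k] = sq;
        z[k + 1] = 1e35;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        while (z[k + 1] < q) ++k;
        int p = v[k];
        d[q] = s2 * (q - p) * (q - p) + f[p];
    }
}

//' @noRd
// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (mask.size() != n) stop("mask length does not match dim");
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) out[i] = (mask[i] == TRUE) ? 0.0 : BIG;

    const int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);
    const R_xlen_t nxy = (R_xlen_t)nx * ny;

    // pass along x
    double s2 = spacing[0] * spacing[0];
    for (int kz = 0; kz < nz; ++kz) {
        for (int ky = 0; ky < ny; ++ky) {
            const R_xlen_t base = kz * nxy + (R_xlen_t)ky * nx;
            for (int q = 0; q < nx; ++q) f[q] = out[base + q];
            dt1d(f, d, v, z, nx, s2);
            for (int q = 0; q < nx; ++q) out[base + q] = d[q];
        }
    }
    // pass along y
    s2 = spacing[1] * spacing[1];
    for (int kz = 0; kz < nz; ++kz) {
        for (int kx = 0; kx < nx; ++kx) {
            const R_xlen_t base = kz * nxy + kx;
            for (int q = 0; q < ny; ++q) f[q] = out[base + (R_xlen_t)q * nx];
            dt1d(f, d, v, z, ny, s2);
            for (int q = 0; q < ny; ++q) out[base + (R_xlen_t)q * nx] = d[q];
        }
    }
    // pass along z
    s2 = spacing[2] * spacing[2];
    for (int ky = 0; ky < ny; ++ky) {
        for (int kx = 0; kx < nx; ++kx) {
            const R_xlen_t base = (R_xlen_t)ky * nx + kx;
            for (int q = 0; q < nz; ++q) f[q] = out[base + q * nxy];
            dt1d(f, d, v, z, nz, s2);
            for (int q = 0; q < nz; ++q) out[base + q * nxy] = d[q];
        }
    }

    for (R_xlen_t i = 0; i < n; ++i) {
        out[i] = (out[i] >= 1e29) ? R_PosInf : std::sqrt(out[i]);
    }
    return out;
}
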