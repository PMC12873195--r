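#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Squared Euclidean distance transforms and connected-component labelling on
// 3-D grids with anisotropic voxel spacing. 2-D inputs are handled as
// degenerate 3-D grids (third dimension of size 1).

static const double BIG = 1e15;

// 1-D lower-envelope distance transform (Felzenszwalb & Huttenlocher) on a
// row of squared distances, sample positions i*w.
static void dt1d(std::vector<double>& f, std::vector<double>& d, int n, double w) {
    std::vector<int> v(n);
    std::vector<double> z(n + 1);
    int k = 0;
    v[0] = 0;
    z[0] = -BIG;
    z[1] = BIG;
    double w2 = w * w;
    for (int q = 1; q < n; ++q) {
        double s = 0.0;
        while (true) {
            int p = v[k];
            s = ((f[q] + q * (double)q * w2) - (f[p] + p * (double)p * w2)) /
                (2.0 * w2 * (q - p));
            if (s <= z[k]) { --k; } else { break; }
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = BIG;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        while (z[k + 1] < q) ++k;
        double dq = (double)(q - v[k]) * w;
        d[q] = dq * dq + f[v[k]];
    }
}

// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
    int nx = dims[0], ny = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
    double dx = spacing[0], dy = spacing[1], dz = spacing.size() > 2 ? spacing[2] : 1.0;
    R_xlen_t n = (R_xlen_t)nx * ny * nz;
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : BIG;

    // pass along x
    {
        std::vector<double> f(nx), d(nx);
        for (int z = 0; z < nz; ++z)
            for (int y = 0; y < ny; ++y) {
                R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
                for (int x = 0; x < nx; ++x) f[x] = out[base + x];
                dt1d(f, d, nx, dx);
                for (int x = 0; x < nx; ++x) out[base + x] = d[x];
            }
    }
    // pass along y
    {
        std::vector<double> f(ny), d(ny);
        for (int z = 0; z < nz; ++z)
            for (int x = 0; x < nx; ++x) {
                R_xlen_t base = (R_xlen_t)z * nx * ny + x;
                for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)y * nx];
                dt1d(f, d, ny, dy);
                for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = d[y];
            }
    }
    // pass along z
    if (nz > 1) {
        std::vector<double> f(nz), d(nz);
        R_xlen_t plane = (R_xlen_t)nx * ny;
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                R_xlen_t base = (R_xlen_t)y * nx + x;
                for (int z = 0; z < nz; ++z) f[z] = out[base + (R_xlen_t)z * plane];
                dt1d(f, d, nz, dz);
                for (int z = 0; z < nz; ++z) out[base + (R_xlen_t)z * plane] = d[z];
            }
    }
    return out;
}

// Connected components with 26-connectivity (8-connectivity for single-slice
// grids). Returns integer labels, 0 = background; labels are assigned in
// scan order of the first voxel reached.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims, int connectivity) {
    int nx = dims[0], ny = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
    R_xlen_t n = (R_xlen_t)nx * ny * nz;
    IntegerVector lab(n, 0);

    std::vector<int> ox, oy, oz;
    for (int dzi = -1; dzi <= 1; ++dzi)
        for (int dyi = -1; dyi <= 1; ++dyi)
            for (int dxi = -1; dxi <= 1; ++dxi) {
                if (dxi == 0 && dyi == 0 && dzi == 0) continue;
                int manh = std::abs(dxi) + std::abs(dyi) + std::abs(dzi);
                if (connectivity == 6 && manh != 1) continue;
                ox.push_back(dxi); oy.push_back(dyi); oz.push_back(dzi);
            }

    std::vector<R_xlen_t> stack;
    int current = 0;
    R_xlen_t plane = (R_xlen_t)nx * ny;
    for (R_xlen_t i = 0; i < n; ++i) {
        if (!mask[i] || lab[i] != 0) continue;
        ++current;
        lab[i] = current;
        stack.push_back(i);
        while (!stack.empty()) {
            R_xlen_t p = stack.back();
            stack.pop_back();
            int z = (int)(p / plane);
            int rem = (int)(p % plane);
            int y = rem / nx;
            int x = rem % nx;
            for (size_t k = 0; k < ox.size(); ++k) {
                int xx = x + ox[k], yy = y + oy[k], zz = z + oz[k];
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
                R_xlen_t q = (R_xlen_t)zz * plane + (R_xlen_t)yy * nx + xx;
                if (mask[q] && lab[q] == 0) {
                    lab[q] = current;
                    stack.push_back(q);
                }
            }
        }
    }
    return lab;
}

// Separable normalized box (mean) filter; near edges the window is clipped to
// the grid and the average taken over the in-bounds samples only.
static void box1d(std::vector<double>& f, std::vector<double>& g, int n, int r) {
    for (int i = 0; i < n; ++i) {
        int lo = std::max(0, i - r), hi = std::min(n - 1, i + r);
        double s = 0.0;
        for (int j = lo; j <= hi; ++j) s += f[j];
        g[i] = s / (hi - lo + 1);
    }
}

// [[Rcpp::export]]
NumericVector box_filter_cpp(NumericVector x, IntegerVector dims, IntegerVector ksize) {
    int nx = dims[0], ny = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
    int rx = (ksize[0] - 1) / 2, ry = (ksize[1] - 1) / 2;
    int rz = ksize.size() > 2 ? (ksize[2] - 1) / 2 : 0;
    R_xlen_t n = (R_xlen_t)nx * ny * nz;
    NumericVector out = clone(x);
    R_xlen_t plane = (R_xlen_t)nx * ny;

    if (rx > 0) {
        std::vector<double> f(nx), g(nx);
        for (int z = 0; z < nz; ++z)
            for (int y = 0; y < ny; ++y) {
                R_xlen_t base = (R_xlen_t)z * plane + (R_xlen_t)y * nx;
                for (int i = 0; i < nx; ++i) f[i] = out[base + i];
                box1d(f, g, nx, rx);
                for (int i = 0; i < nx; ++i) out[base + i] = g[i];
            }
    }
    if (ry > 0) {
        std::vector<double> f(ny), g(ny);
        for (int z = 0; z < nz; ++z)
            for (int x = 0; x < nx; ++x) {
                R_xlen_t base = (R_xlen_t)z * plane + x;
                for (int i = 0; i < ny; ++i) f[i] = out[base + (R_xlen_t)i * nx];
                box1d(f, g, ny, ry);
                for (int i = 0; i < ny; ++i) out[base + (R_xlen_t)i * nx] = g[i];
            }
    }
    if (rz > 0 && nz > 1) {
        std::vector<double> f(nz), g(nz);
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                R_xlen_t base = (R_xlen_t)y * nx + x;
                for (int i = 0; i < nz; ++i) f[i] = out[base + (R_xlen_t)i * plane];
                box1d(f, g, nz, rz);
                for (int i = 0; i < nz; ++i) out[base + (R_xlen_t)i * plane] = g[i];
            }
    }
    (void)n;
    return out;
}
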