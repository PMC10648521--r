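#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

static const double DT_INF = 1e15;

// 1D lower envelope of parabolas (Felzenszwalb & Huttenlocher), spacing^2 = w2
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z,
                 int n, double w2) {
    const double Z_INF = 1e30;
    int k = 0;
    v[0] = 0;
    z[0] = -Z_INF;
    z[1] = Z_INF;
    for (int q = 1; q < n; ++q) {
        double s;
        while (true) {
            s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
                (2.0 * w2 * (q - v[k]));
            if (s <= z[k] && k > 0) {
                --k;
            } else {
                break;
            }
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = Z_INF;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        while (z[k + 1] < q) ++k;
        d[q] = w2 * (double)(q - v[k]) * (q - v[k]) + f[v[k]];
    }
}

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_sqedt3d(LogicalVector mask, IntegerVector dim,
                          NumericVector spacing) {
    const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
    const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
    NumericVector out(n);
    // squared distance (mm^2) from each voxel to the nearest FALSE voxel;
    // out-of-image space counts as TRUE (no boundary erosion).
    for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? DT_INF : 0.0;

    int nmax = std::max(n1, std::max(n2, n3));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // pass along axis 1 (fastest-varying)
    double w2 = spacing[0] * spacing[0];
    for (int k = 0; k < n3; ++k)
        for (int j = 0; j < n2; ++j) {
            R_xlen_t base = (R_xlen_t)k * n1 * n2 + (R_xlen_t)j * n1;
            for (int i = 0; i < n1; ++i) f[i] = out[base + i];
            dt1d(f, d, v, z, n1, w2);
            for (int i = 0; i < n1; ++i) out[base + i] = d[i];
        }
    // axis 2
    w2 = spacing[1] * spacing[1];
    for (int k = 0; k < n3; ++k)
        for (int i = 0; i < n1; ++i) {
            R_xlen_t base = (R_xlen_t)k * n1 * n2 + i;
            for (int j = 0; j < n2; ++j) f[j] = out[base + (R_xlen_t)j * n1];
            dt1d(f, d, v, z, n2, w2);
            for (int j = 0; j < n2; ++j) out[base + (R_xlen_t)j * n1] = d[j];
        }
    // axis 3
    w2 = spacing[2] * spacing[2];
    for (int j = 0; j < n2; ++j)
        for (int i = 0; i < n1; ++i) {
            R_xlen_t base = (R_xlen_t)j * n1 + i;
            R_xlen_t step = (R_xlen_t)n1 * n2;
            for (int k = 0; k < n3; ++k) f[k] = out[base + k * step];
            dt1d(f, d, v, z, n3, w2);
            for (int k = 0; k < n3; ++k) out[base + k * step] = d[k];
        }
    return out;
}

static inline void neighbour_offsets(int conn, int n1, int n2,
                                     std::vector<long long> &off,
                                     std::vector<int> &di, std::vector<int> &dj,
                                     std::vector<int> &dk) {
    off.clear(); di.clear(); dj.clear(); dk.clear();
    for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
            for (int c = -1; c <= 1; ++c) {
                if (a == 0 && b == 0 && c == 0) continue;
                int manhattan = std::abs(a) + std::abs(b) + std::abs(c);
                if (conn == 6 && manhattan != 1) continue;
                off.push_back((long long)a + (long long)b * n1 +
                              (long long)c * n1 * n2);
                di.push_back(a);
                dj.push_back(b);
                dk.push_back(c);
            }
}

//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim, int connectivity) {
    const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
    const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
    IntegerVector lab(n, 0);
    std::vector<long long> off;
    std::vector<int> di, dj, dk;
    neighbour_offsets(connectivity, n1, n2, off, di, dj, dk);
    const int m = (int)off.size();

    std::vector<R_xlen_t> stack;
    int cur = 0;
    for (R_xlen_t s = 0; s < n; ++s) {
        if (!mask[s] || lab[s] != 0) continue;
        ++cur;
        lab[s] = cur;
        stack.push_back(s);
        while (!stack.empty()) {
            R_xlen_t p = stack.back();
            stack.pop_back();
            int pi = (int)(p % n1);
            int pj = (int)((p / n1) % n2);
            int pk = (int)(p / ((R_xlen_t)n1 * n2));
            for (int t = 0; t < m; ++t) {
                int qi = pi + di[t], qj = pj + dj[t], qk = pk + dk[t];
                if (qi < 0 || qi >= n1 || qj < 0 || qj >= n2 ||
                    qk < 0 || qk >= n3) continue;
                R_xlen_t q = p + off[t];
                if (mask[q] && lab[q] == 0) {
                    lab[q] = cur;
                    stack.push_back(q);
                }
            }
        }
    }
    lab.attr("ncomponents") = cur;
    return lab;
}

// Adaptive region growing for the glandular class.  State codes:
// 0 untouched, 1 accepted (gland), 2 pending frontier (adjacent, below the
// current acceptance threshold).  One sweep expands exhaustively at a fixed
// threshold max(floor, alpha * (1 - D)), then the running average density D
// (mean glandular fraction over the grown region) is updated.
//' @noRd
// [[Rcpp::export]]
List cpp_region_grow(NumericVector g, LogicalVector interior, IntegerVector dim,
                     double seed_fraction, double floor_fraction, double alpha,
                     double tol, int max_iterations) {
    const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
    const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
    std::vector<long long> off;
    std::vector<int> di, dj, dk;
    neighbour_offsets(26, n1, n2, off, di, dj, dk);
    const int m = (int)off.size();

    std::vector<unsigned char> state(n, 0);
    std::vector<R_xlen_t> pending, queue;
    double gsum = 0.0;
    R_xlen_t nregion = 0;

    for (R_xlen_t i = 0; i < n; ++i) {
        if (interior[i] && g[i] >= seed_fraction) {
            state[i] = 1;
            gsum += g[i];
            ++nregion;
            queue.push_back(i);
        }
    }

    LogicalVector mask(n, false);
    std::vector<double> trace;
    if (nregion == 0) {
        List out = List::create(_["mask"] = mask,
                                _["trace"] = NumericVector(0),
                                _["iterations"] = 0);
        return out;
    }

    // frontier of the seed set
    std::vector<R_xlen_t> next_pending;
    auto scan_neighbours = [&](R_xlen_t p, double thr,
                               std::vector<R_xlen_t> &accept_queue) {
        int pi = (int)(p % n1);
        int pj = (int)((p / n1) % n2);
        int pk = (int)(p / ((R_xlen_t)n1 * n2));
        for (int t = 0; t < m; ++t) {
            int qi = pi + di[t], qj = pj + dj[t], qk = pk + dk[t];
            if (qi < 0 || qi >= n1 || qj < 0 || qj >= n2 ||
                qk < 0 || qk >= n3) continue;
            R_xlen_t q = p + off[t];
            if (!interior[q] || state[q] != 0) continue;
            if (g[q] >= thr) {
                state[q] = 1;
                gsum += g[q];
                ++nregion;
                accept_queue.push_back(q);
            } else {
                state[q] = 2;
                pending.push_back(q);
            }
        }
    };

    double D = gsum / (double)nregion;
    double Dprev = R_NegInf;
    int iter = 0;
    bool first = true;
    while (iter < max_iterations) {
        ++iter;
        double thr = std::max(floor_fraction, alpha * (1.0 - D));
        R_xlen_t before = nregion;

        std::vector<R_xlen_t> accept;
        if (first) {
            // discover the frontier of the seeds
            for (R_xlen_t idx = 0; idx < (R_xlen_t)queue.size(); ++idx)
                scan_neighbours(queue[idx], thr, accept);
            first = false;
        }
        // re-test pending voxels under the (possibly lowered) threshold
        next_pending.clear();
        std::swap(pending, next_pending);
        for (R_xlen_t idx = 0; idx < (R_xlen_t)next_pending.size(); ++idx) {
            R_xlen_t p = next_pending[idx];
            if (state[p] != 2) continue;
            if (g[p] >= thr) {
                state[p] = 1;
                gsum += g[p];
                ++nregion;
                accept.push_back(p);
            } else {
                pending.push_back(p);
            }
        }
        // exhaustive expansion at this threshold
        for (R_xlen_t idx = 0; idx < (R_xlen_t)accept.size(); ++idx)
            scan_neighbours(accept[idx], thr, accept);

        Dprev = D;
        D = gsum / (double)nregion;
        trace.push_back(D);
        if (nregion == before && std::fabs(D - Dprev) < tol) break;
    }

    for (R_xlen_t i = 0; i < n; ++i)
        if (state[i] == 1) mask[i] = true;
    return List::create(_["mask"] = mask,
                        _["trace"] = NumericVector(trace.begin(), trace.end()),
                        _["iterations"] = iter);
}
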