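#include <Rcpp.h>
using namespace Rcpp;

// Linear interpolation of row u (real index in [0, T-1]) of a T x 2 matrix.
static inline void interp_row(const NumericMatrix& q, double u, double out[2]) {
    int T = q.nrow();
    if (u <= 0) { out[0] = q(0, 0); out[1] = q(0, 1); return; }
    if (u >= T - 1) { out[0] = q(T - 1, 0); out[1] = q(T - 1, 1); return; }
    int lo = (int)std::floor(u);
    double w = u - lo;
    out[0] = (1 - w) * q(lo, 0) + w * q(lo + 1, 0);
    out[1] = (1 - w) * q(lo, 1) + w * q(lo + 1, 1);
}

// Cost of the lattice edge (a,b) -> (a+k, b+l): trapezoid approximation of
// int_{s_a}^{s_{a+k}} | q1(s) - sqrt(l/k) q2(tau(s)) |^2 ds
// with tau linear of slope l/k through (s_a, s_b), on the fine grid points.
static double edge_cost(const NumericMatrix& q1, const NumericMatrix& q2,
                        int a, int b, int k, int l, double ds) {
    double m = (double)l / (double)k;
    double sm = std::sqrt(m);
    double tot = 0.0;
    double q2v[2];
    for (int t = 0; t <= k; ++t) {
        double u = b + m * t;            // real index into q2's grid
        interp_row(q2, u, q2v);
        double d0 = q1(a + t, 0) - sm * q2v[0];
        double d1 = q1(a + t, 1) - sm * q2v[1];
        double w = (t == 0 || t == k) ? 0.5 : 1.0;
        tot += w * (d0 * d0 + d1 * d1);
    }
    return tot * ds;
}

// Dynamic-programming search for the boundary-preserving monotone warping
// minimizing || q1 - (q2 o tau) sqrt(tau') ||^2 over piecewise-linear paths
// on the T x T lattice with local slope set { l/k : 1 <= k,l <= 3, coprime }.
// [[Rcpp::export(name = ".dp_warp_cpp")]]
List dp_warp_cpp(NumericMatrix q1, NumericMatrix q2) {
    const int T = q1.nrow();
    if (q2.nrow() != T) stop("q1 and q2 must share a grid");
    if (T < 5) stop("grid too small for dynamic-programming registration (need T >= 5)");
    const int K[7] = {1, 1, 2, 1, 3, 2, 3};
    const int L[7] = {1, 2, 1, 3, 1, 3, 2};
    const double ds = 1.0 / (T - 1);
    const double INF = std::numeric_limits<double>::infinity();

    std::vector<double> E((size_t)T * T, INF);
    std::vector<int> pred((size_t)T * T, -1);
    E[0] = 0.0;
    for (int i = 1; i < T; ++i) {
        for (int j = 1; j < T; ++j) {
            double best = INF;
            int barg = -1;
            for (int s = 0; s < 7; ++s) {
                int a = i - K[s], b = j - L[s];
                if (a < 0 || b < 0) continue;
                double ep = E[(size_t)a * T + b];
                if (!std::isfinite(ep)) continue;
                double c = ep + edge_cost(q1, q2, a, b, K[s], L[s], ds);
                if (c < best) { best = c; barg = s; }
            }
            E[(size_t)i * T + j] = best;
            pred[(size_t)i * T + j] = barg;
        }
    }

    // back-track the optimal path, then linearly interpolate tau on the grid
    std::vector<int> pi, pj;
    int i = T - 1, j = T - 1;
    while (i > 0 || j > 0) {
        pi.push_back(i); pj.push_back(j);
        int s = pred[(size_t)i * T + j];
        if (s < 0) stop("no admissible warping path found");
        i -= K[s]; j -= L[s];
    }
    pi.push_back(0); pj.push_back(0);
    std::reverse(pi.begin(), pi.end());
    std::reverse(pj.begin(), pj.end());

    NumericVector tau(T);
    size_t seg = 0;
    for (int t = 0; t < T; ++t) {
        while (seg + 1 < pi.size() && pi[seg + 1] < t) ++seg;
        if (pi[seg] == t) { tau[t] = pj[seg] * ds; continue; }
        double w = (double)(t - pi[seg]) / (double)(pi[seg + 1] - pi[seg]);
        tau[t] = ((1 - w) * pj[seg] + w * pj[seg + 1]) * ds;
    }
    tau[0] = 0.0;
    tau[T - 1] = 1.0;
    return List::create(_["tau"] = tau, _["value"] = E[(size_t)(T - 1) * T + (T - 1)]);
}
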