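#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Theta-weighted implicit finite-volume march of the 1D multilayer
// reaction-diffusion system in partial pressure u (mmHg):
//
//   aV_j du_j/dt = sum_faces k_e (u_nbr - u_j) - sum_sides r * (a u)/(km + a u)
//
// aV_j  : solubility-weighted control volume, mol/(cm2 mmHg) per unit area
// k_e   : face conductance D*a/dz, mol/(cm2 s mmHg)
// r     : rho_cell * sOCR * dz_side/2, mol/(cm2 s)  (Michaelis-Menten Vmax
//         integrated over the half-cell); a converts u to mol/cm3; km in
//         mol/cm3.
//
// The Michaelis-Menten sink is solved fully implicitly by Newton iteration
// with an analytic tridiagonal Jacobian (Thomas solve), which keeps the sink
// below its saturation bound and the solution non-negative.
//
// Dirichlet values are imposed as identity rows; bottom_vals holds the
// boundary partial pressure at every time level (length nstep + 1).

// [[Rcpp::export]]
NumericMatrix rd_march_cpp(NumericVector u0,
                           NumericVector dts,
                           NumericVector bottom_vals,
                           bool bottom_dirichlet,
                           bool top_dirichlet,
                           double top_val,
                           NumericVector edge_k,
                           NumericVector aV,
                           NumericVector r_lo, NumericVector a_lo, NumericVector km_lo,
                           NumericVector r_hi, NumericVector a_hi, NumericVector km_hi,
                           double theta,
                           double newton_tol,
                           int newton_max)
{
    const int n = u0.size();
    const int nstep = dts.size();
    if (edge_k.size() != n - 1) stop("edge_k must have length n - 1");
    if (bottom_dirichlet && bottom_vals.size() != nstep + 1)
        stop("bottom_vals must have length nstep + 1");

    NumericMatrix out(n, nstep + 1);
    std::vector<double> u(u0.begin(), u0.end());
    std::vector<double> uold(n), F(n), sub(n), dia(n), sup(n), rhs(n),
        bb(n), cc(n), expl(n);

    const double uscale = 760.0;

    auto sink = [&](int j, double uj) {
        double s = 0.0;
        if (r_lo[j] > 0.0) { double c = a_lo[j] * uj; s += r_lo[j] * c / (km_lo[j] + c); }
        if (r_hi[j] > 0.0) { double c = a_hi[j] * uj; s += r_hi[j] * c / (km_hi[j] + c); }
        return s;
    };
    auto dsink = [&](int j, double uj) {
        double d = 0.0;
        if (r_lo[j] > 0.0) {
            double c = a_lo[j] * uj, km = km_lo[j];
            d += r_lo[j] * a_lo[j] * km / ((km + c) * (km + c));
        }
        if (r_hi[j] > 0.0) {
            double c = a_hi[j] * uj, km = km_hi[j];
            d += r_hi[j] * a_hi[j] * km / ((km + c) * (km + c));
        }
        return d;
    };
    auto Lu = [&](const std::vector<double>& v, int j) {
        double acc = 0.0;
        if (j > 0)     acc += edge_k[j - 1] * (v[j - 1] - v[j]);
        if (j < n - 1) acc += edge_k[j] * (v[j + 1] - v[j]);
        return acc;
    };

    if (bottom_dirichlet) u[0] = bottom_vals[0];
    if (top_dirichlet)    u[n - 1] = top_val;
    for (int j = 0; j < n; ++j) out(j, 0) = u[j];

    for (int m = 0; m < nstep; ++m) {
        const double dt = dts[m];
        uold = u;
        for (int j = 0; j < n; ++j)
            expl[j] = (1.0 - theta) * (Lu(uold, j) - sink(j, uold[j]));
        if (bottom_dirichlet) u[0] = bottom_vals[m + 1];
        if (top_dirichlet)    u[n - 1] = top_val;

        bool conv = false;
        for (int it = 0; it < newton_max; ++it) {
            for (int j = 0; j < n; ++j) {
                const bool fixed = (bottom_dirichlet && j == 0) ||
                                   (top_dirichlet && j == n - 1);
                if (fixed) {
                    const double bc = (j == 0) ? bottom_vals[m + 1] : top_val;
                    F[j] = u[j] - bc;
                    sub[j] = 0.0; dia[j] = 1.0; sup[j] = 0.0;
                    continue;
                }
                F[j] = aV[j] * (u[j] - uold[j]) / dt
                     - theta * (Lu(u, j) - sink(j, u[j])) - expl[j];
                const double klo = (j > 0) ? edge_k[j - 1] : 0.0;
                const double khi = (j < n - 1) ? edge_k[j] : 0.0;
                dia[j] = aV[j] / dt + theta * (klo + khi + dsink(j, u[j]));
                sub[j] = (j > 0) ? -theta * klo : 0.0;
                sup[j] = (j < n - 1) ? -theta * khi : 0.0;
            }
            // Thomas solve of J * delta = -F
            for (int j = 0; j < n; ++j) {
                rhs[j] = -F[j]; bb[j] = dia[j]; cc[j] = sup[j];
            }
            for (int j = 1; j < n; ++j) {
                const double w = sub[j] / bb[j - 1];
                bb[j] -= w * cc[j - 1];
                rhs[j] -= w * rhs[j - 1];
            }
            rhs[n - 1] /= bb[n - 1];
            for (int j = n - 2; j >= 0; --j)
                rhs[j] = (rhs[j] - cc[j] * rhs[j + 1]) / bb[j];
            double dmax = 0.0;
            for (int j = 0; j < n; ++j) {
                u[j] += rhs[j];
                const double ad = std::fabs(rhs[j]);
                if (ad > dmax) dmax = ad;
            }
            if (dmax <= newton_tol * uscale) { conv = true; break; }
        }
        if (!conv)
            stop("Newton iteration did not converge at time step %d", m + 1);
        for (int j = 0; j < n; ++j) {
            if (u[j] < 0.0) {
                if (u[j] < -1e-9)
                    stop("negative partial pressure beyond roundoff at time step %d, node %d",
                         m + 1, j + 1);
                u[j] = 0.0;
            }
            out(j, m + 1) = u[j];
        }
    }
    return out;
}
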