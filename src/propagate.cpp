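#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// One-dimensional Langevin propagation on tabulated fields (uniform grid),
// Bussi-Parrinello splitting: Ornstein-Uhlenbeck thermostat half-step,
// velocity-Verlet drift/kick, second OU half-step. The position-dependent
// friction gamma(x) = Gamma(x)/m is frozen at the pre-step position for the
// whole step. Reflecting walls at x_min/x_max (position mirrored, velocity
// negated). Dissociation/association events are recorded online with a
// two-core scheme: the system is "bound" after visiting x <= x_b and
// "unbound" after visiting x >= x_u; waiting times run from core entry to
// first arrival in the opposite core, so recrossings between the cores do
// not create events.
//
// Uses the R RNG (norm_rand), so trajectories are reproducible from
// set.seed() on the R side.

static inline double lin_interp(const double *tab, double u, int n) {
    if (u <= 0.0) return tab[0];
    if (u >= n - 1.0) return tab[n - 1];
    int i = (int)u;
    double w = u - i;
    return tab[i] * (1.0 - w) + tab[i + 1] * w;
}

// [[Rcpp::export]]
List propagate_core(NumericVector force, NumericVector gamma_tab,
                    double x_lo, double dx_grid, double m, double kBT,
                    double dt, double n_steps_d, double x0, double v0,
                    double x_min, double x_max, int stride,
                    double x_b, double x_u, bool record_traj) {
    const int ng = force.size();
    const double *F = force.begin();
    const double *G = gamma_tab.begin();
    const R_xlen_t n_steps = (R_xlen_t)n_steps_d;
    const double inv_dx = 1.0 / dx_grid;

    double x = x0, v = v0, t = 0.0;
    // 1e4 thermal velocities: unreachable by equilibrium fluctuations,
    // reached almost immediately by velocity-Verlet blow-up
    const double v_limit = 1e4 * std::sqrt(kBT / m);
    std::vector<double> xs, vs;
    if (record_traj) {
        xs.reserve((size_t)(n_steps / stride) + 2);
        vs.reserve((size_t)(n_steps / stride) + 2);
        xs.push_back(x);
        vs.push_back(v);
    }

    // event bookkeeping: state 0 = no core visited yet, 1 = bound, 2 = unbound
    int state = 0;
    double t_entry = 0.0;
    std::vector<double> ev_time, ev_wait;
    std::vector<int> ev_type;  // 1 = dissociation, 2 = association
    if (x <= x_b) { state = 1; t_entry = 0.0; }
    else if (x >= x_u) { state = 2; t_entry = 0.0; }

    for (R_xlen_t s = 1; s <= n_steps; ++s) {
        double u = (x - x_lo) * inv_dx;
        double gam = lin_interp(G, u, ng) / m;  // collision frequency, 1/ps
        double c1 = std::exp(-0.5 * gam * dt);
        double c2 = std::sqrt((1.0 - c1 * c1) * kBT / m);

        v = c1 * v + c2 * norm_rand();
        v += 0.5 * dt * lin_interp(F, u, ng) / m;
        x += dt * v;
        // reflecting walls: fold into [x_min, x_max]; the reflected map is
        // periodic with period 2*span and slope +/-1, so one branch test
        // also gives the velocity sign after any number of reflections
        if (x < x_min || x > x_max) {
            const double span = x_max - x_min;
            const double period = 2.0 * span;
            double y = x - x_min;
            y -= period * std::floor(y / period);   // into [0, 2*span)
            if (y > span) { y = period - y; v = -v; }
            x = x_min + y;
        }
        u = (x - x_lo) * inv_dx;
        v += 0.5 * dt * lin_interp(F, u, ng) / m;
        v = c1 * v + c2 * norm_rand();
        t = s * dt;

        if (!R_FINITE(x) || !R_FINITE(v) || std::fabs(v) > v_limit)
            stop("numerical instability at step %g (t = %g ps): "
                 "reduce dt below 0.25*min(m/Gamma_max, sqrt(m/|G''|_max))",
                 (double)s, t);

        if (x <= x_b) {
            if (state == 2) {             // association: unbound -> bound
                ev_time.push_back(t);
                ev_wait.push_back(t - t_entry);
                ev_type.push_back(2);
                state = 1; t_entry = t;
            } else if (state == 0) { state = 1; t_entry = t; }
        } else if (x >= x_u) {
            if (state == 1) {             // dissociation: bound -> unbound
                ev_time.push_back(t);
                ev_wait.push_back(t - t_entry);
                ev_type.push_back(1);
                state = 2; t_entry = t;
            } else if (state == 0) { state = 2; t_entry = t; }
        }

        if (record_traj && (s % stride == 0)) {
            xs.push_back(x);
            vs.push_back(v);
        }
        if ((s & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    }

    return List::create(
        _["x"] = xs, _["v"] = vs,
        _["event_time"] = ev_time, _["event_type"] = ev_type,
        _["event_wait"] = ev_wait,
        _["x_final"] = x, _["v_final"] = v, _["t_final"] = t);
}
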