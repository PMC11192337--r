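#include <Rcpp.h>
using namespace Rcpp;

// Exact SSA for the 4-state promoter with protein birth/death.
//
// Promoter states: 0 empty, 1 RNAP-bound, 2 TF-bound, 3 co-bound.
// Productive initiation removes the polymerase (1 -> 0 at rate r,
// 3 -> 2 at rate alpha*r), emitting one protein.
//
// Topologies:
//   0 simple          - TF binding propensity is the fixed rate kon_tf
//   1 autoreg_monomer - TF binding propensity kon_tf * n (per free monomer);
//                       binding sequesters one monomer
//   2 autoreg_dimer   - monomers dimerize (k_dim * n*(n-1)/2 <-> k_mon * d);
//                       the dimer is the binding species
//
// DNA-bound TF is sequestered from the free pool; with dilute_bound the
// bound TF can additionally be lost at rate gamma (promoter reverts to the
// TF-free state without returning the molecule).
//
// Uses R's RNG so set.seed() gives bit-identical trajectories.

// [[Rcpp::export]]
List ssa_run_cpp(double kon_p, double koff_p, double kon_tf, double koff_tf,
                 double r, double gamma, double alpha, double beta,
                 bool beta_on_rnap_only,
                 int topology, double k_dim, double k_mon,
                 double horizon, int state0, double n0, double d0,
                 bool dilute_bound, double cap, int max_events) {
  std::vector<double> t_out;
  std::vector<int> s_out;
  std::vector<double> n_out, d_out;
  t_out.reserve(1024); s_out.reserve(1024);
  n_out.reserve(1024); d_out.reserve(1024);

  double t = 0.0, n = n0, d = d0;
  int s = state0;
  const double koff_tf_co = beta_on_rnap_only ? koff_tf : koff_tf / beta;
  const double koff_p_co = koff_p / beta;

  t_out.push_back(t); s_out.push_back(s);
  n_out.push_back(n); d_out.push_back(d);

  // reaction channels (propensity recomputed each step; system is tiny)
  enum {
    BIND_P, UNBIND_P, INIT_P,          // empty <-> RNAP, productive init
    BIND_TF, UNBIND_TF,                // empty <-> TF
    BIND_TF_CO, UNBIND_TF_CO,          // RNAP <-> co-bound
    BIND_P_CO, UNBIND_P_CO, INIT_CO,   // TF <-> co-bound, productive init
    DEATH, DIMERIZE, UNDIMERIZE, DEATH_D, DILUTE_BOUND_TF,
    N_CHANNEL
  };
  double a[N_CHANNEL];

  int ev = 0;
  for (;;) {
    // binder = free count of the DNA-binding species (or 1 for fixed-rate)
    double binder = (topology == 0) ? 1.0 : (topology == 1 ? n : d);
    for (int i = 0; i < N_CHANNEL; ++i) a[i] = 0.0;
    if (s == 0) {
      a[BIND_P] = kon_p;
      a[BIND_TF] = kon_tf * binder;
    } else if (s == 1) {
      a[UNBIND_P] = koff_p;
      a[INIT_P] = r;
      a[BIND_TF_CO] = kon_tf * binder;
    } else if (s == 2) {
      a[UNBIND_TF] = koff_tf;
      a[BIND_P_CO] = kon_p;
    } else {
      a[UNBIND_TF_CO] = koff_tf_co;
      a[UNBIND_P_CO] = koff_p_co;
      a[INIT_CO] = alpha * r;
    }
    a[DEATH] = gamma * n;
    if (topology == 2) {
      a[DIMERIZE] = k_dim * n * (n - 1.0) / 2.0;
      a[UNDIMERIZE] = k_mon * d;
      a[DEATH_D] = gamma * d;
    }
    if (dilute_bound && topology != 0 && (s == 2 || s == 3))
      a[DILUTE_BOUND_TF] = gamma;

    double a0 = 0.0;
    for (int i = 0; i < N_CHANNEL; ++i) a0 += a[i];
    if (a0 <= 0.0) { t = horizon; break; }

    t += R::exp_rand() / a0;
    if (t >= horizon) break;

    double u = R::unif_rand() * a0;
    int ch = 0;
    double acc = a[0];
    while (acc < u && ch < N_CHANNEL - 1) acc += a[++ch];

    switch (ch) {
    case BIND_P: s = 1; break;
    case UNBIND_P: s = 0; break;
    case INIT_P: s = 0; n += 1; break;
    case BIND_TF:
      s = 2;
      if (topology == 1) n -= 1; else if (topology == 2) d -= 1;
      break;
    case UNBIND_TF:
      s = 0;
      if (topology == 1) n += 1; else if (topology == 2) d += 1;
      break;
    case BIND_TF_CO:
      s = 3;
      if (topology == 1) n -= 1; else if (topology == 2) d -= 1;
      break;
    case UNBIND_TF_CO:
      s = 1;
      if (topology == 1) n += 1; else if (topology == 2) d += 1;
      break;
    case BIND_P_CO: s = 3; break;
    case UNBIND_P_CO: s = 2; break;
    case INIT_CO: s = 2; n += 1; break;
    case DEATH: n -= 1; break;
    case DIMERIZE: n -= 2; d += 1; break;
    case UNDIMERIZE: n += 2; d -= 1; break;
    case DEATH_D: d -= 1; break;
    case DILUTE_BOUND_TF: s = (s == 2) ? 0 : 1; break;
    }

    t_out.push_back(t); s_out.push_back(s);
    n_out.push_back(n); d_out.push_back(d);

    if (n + 2.0 * d > cap)
      stop("population exceeded cap (%g molecules at t = %g after %d events); "
           "likely runaway autoregulation", n + 2.0 * d, t, ev);
    if (++ev >= max_events)
      stop("event cap reached (%d events at t = %g of horizon %g); "
           "raise max_events or shorten the horizon", ev, t, horizon);
  }

  return List::create(_["time"] = t_out, _["state"] = s_out,
                      _["protein"] = n_out, _["dimer"] = d_out,
                      _["horizon"] = horizon);
}
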