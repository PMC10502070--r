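#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation (Gillespie direct method) of a small
// mass-action network. All reactions are elementary with unit
// stoichiometry per reactant slot; the propensity of reaction j is
// rate[j] * prod_i x[reactant_i]. Uses R's RNG, so set.seed() on the R
// side makes trajectories reproducible.
//
// reactants: list of 0-based integer vectors (species indices consumed)
// stoich:    n_species x n_reactions integer matrix of net changes
// record:    if true, every jump is stored (times, counts)

// [[Rcpp::export]]
List ssa_core(IntegerVector init, List reactants, IntegerMatrix stoich,
              NumericVector rates, double t_end, double max_events,
              bool record) {
  const int n_sp = init.size();
  const int n_rx = rates.size();
  std::vector<double> x(init.begin(), init.end());
  std::vector<std::vector<int> > rx(n_rx);
  for (int j = 0; j < n_rx; ++j)
    rx[j] = as<std::vector<int> >(reactants[j]);

  std::vector<double> times;
  std::vector<double> traj; // row-major: event x species
  double t = 0.0;
  double n_events = 0.0;
  if (record) {
    times.push_back(t);
    for (int i = 0; i < n_sp; ++i) traj.push_back(x[i]);
  }

  std::vector<double> a(n_rx);
  while (true) {
    double a0 = 0.0;
    for (int j = 0; j < n_rx; ++j) {
      double aj = rates[j];
      for (size_t q = 0; q < rx[j].size(); ++q) aj *= x[rx[j][q]];
      a[j] = aj;
      a0 += aj;
    }
    if (a0 <= 0.0) break;
    t += R::exp_rand() / a0;
    if (t > t_end) break;
    double u = unif_rand() * a0;
    int j = 0;
    double cum = a[0];
    while (cum < u && j < n_rx - 1) cum += a[++j];
    for (int i = 0; i < n_sp; ++i) x[i] += stoich(i, j);
    n_events += 1.0;
    if (record) {
      times.push_back(t);
      for (int i = 0; i < n_sp; ++i) traj.push_back(x[i]);
    }
    if (n_events >= max_events)
      stop("stochastic simulation exceeded the event guard (%.0f)",
           max_events);
  }

  NumericVector final_counts(n_sp);
  for (int i = 0; i < n_sp; ++i) final_counts[i] = x[i];
  List out = List::create(_["final"] = final_counts,
                          _["t_final"] = std::min(t, t_end),
                          _["n_events"] = n_events);
  if (record) {
    int n_rec = times.size();
    NumericMatrix m(n_rec, n_sp);
    for (int r = 0; r < n_rec; ++r)
      for (int i = 0; i < n_sp; ++i) m(r, i) = traj[r * (size_t)n_sp + i];
    out["times"] = NumericVector(times.begin(), times.end());
    out["counts"] = m;
  }
  return out;
}
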