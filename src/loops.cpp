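#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Both loops consume R's global RNG through unif_rand() in exactly the same
// draw order as the exported pure-R single-step functions (learning_step,
// match_pair, interact), so an R-level driver loop reproduces these compiled
// runs bit-for-bit under the same seed. Keep the orders in sync.

// [[Rcpp::export]]
List cpp_run_learning(NumericVector scores0, NumericVector range_low,
                      NumericVector range_high, List adjacency, double theta,
                      int n_periods, int snapshot_every, int window,
                      bool clamp_to_boundary) {
  const int n = scores0.size();
  NumericVector scores = clone(scores0);
  std::vector<std::vector<int> > adj(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector a = adjacency[i];
    adj[i].assign(a.begin(), a.end());  // 1-based neighbor ids
  }
  std::vector<double> pro_frac;
  pro_frac.reserve(n_periods / snapshot_every + 2);
  int n_pro = 0;
  for (int i = 0; i < n; ++i) if (scores[i] > 0) ++n_pro;
  pro_frac.push_back((double)n_pro / n);  // period 0 snapshot

  int since_flip = 0;
  int periods_run = 0;
  for (int t = 1; t <= n_periods; ++t) {
    periods_run = t;
    int i = (int)std::floor(unif_rand() * n);  // 0-based here
    const std::vector<int>& contacts = adj[i];
    if (!contacts.empty()) {
      int jj = (int)std::floor(unif_rand() * contacts.size());
      int j = contacts[jj] - 1;
      double dir = (scores[j] > 0) ? 1.0 : -1.0;
      double proposed = scores[i] + dir * theta;
      bool was_pro = scores[i] > 0;
      if (proposed >= range_low[i] && proposed <= range_high[i]) {
        scores[i] = proposed;
      } else if (clamp_to_boundary) {
        scores[i] = std::min(std::max(proposed, range_low[i]), range_high[i]);
      }
      bool is_pro = scores[i] > 0;
      if (is_pro != was_pro) {
        n_pro += is_pro ? 1 : -1;
        since_flip = 0;
      } else {
        ++since_flip;
      }
    } else {
      ++since_flip;
    }
    if (t % snapshot_every == 0) pro_frac.push_back((double)n_pro / n);
    if (window > 0 && since_flip >= window) break;
  }
  return List::create(_["scores"] = scores,
                      _["pro_fraction"] = NumericVector(pro_frac.begin(), pro_frac.end()),
                      _["periods_run"] = periods_run);
}

static const int UNSUS = 0, SUS = 1, INF = 2, REC = 3;

// [[Rcpp::export]]
List cpp_run_contagion(IntegerVector compartment0, NumericVector rp0,
                       double m, double p0, double reinforcement,
                       double influence, bool cumulative, bool constant_recovery,
                       int n_periods, int n) {
  IntegerVector comp = clone(compartment0);
  NumericVector rp = clone(rp0);
  LogicalVector ever_infected(n);
  std::vector<int> infected;  // ascending 1-based ids of current believers
  int n_sus = 0, n_rec = 0;
  for (int i = 0; i < n; ++i) {
    if (comp[i] == INF) { infected.push_back(i + 1); ever_infected[i] = true; }
    else if (comp[i] == SUS) ++n_sus;
    else if (comp[i] == REC) ++n_rec;
  }

  const int sample_every = std::max(1, n / 2);
  const int n_ticks = n_periods / sample_every;
  NumericVector time(n_ticks + 1);
  IntegerVector S(n_ticks + 1), I(n_ticks + 1), R(n_ticks + 1);
  time[0] = 0.0; S[0] = n_sus; I[0] = (int)infected.size(); R[0] = n_rec;

  long extinction_period = -1;
  long last_change = 0;  // last period with a compartment change
  int t = 0;

  for (t = 1; t <= n_periods; ++t) {
    int i = 1 + (int)std::floor(unif_rand() * n);
    int j;
    if (comp[i - 1] == INF) {
      double u = unif_rand();
      if (u < m && infected.size() >= 2) {
        int len = (int)infected.size() - 1;
        int idx = (int)std::floor(unif_rand() * len);
        // others = infected minus i, ascending
        int seen = 0; j = -1;
        for (size_t k = 0; k < infected.size(); ++k) {
          if (infected[k] == i) continue;
          if (seen == idx) { j = infected[k]; break; }
          ++seen;
        }
      } else {
        j = 1 + (int)std::floor(unif_rand() * (n - 1));
        if (j >= i) ++j;
      }
    } else {
      j = 1 + (int)std::floor(unif_rand() * (n - 1));
      if (j >= i) ++j;
    }

    bool inf_i = comp[i - 1] == INF, inf_j = comp[j - 1] == INF;
    if (inf_i && inf_j) {
      if (!constant_recovery) {
        rp[i - 1] *= reinforcement;
        rp[j - 1] *= reinforcement;
      }
    } else if (inf_i || inf_j) {
      int b = inf_i ? i : j;          // the believer
      int other = inf_i ? j : i;
      int oc = comp[other - 1];
      if (oc == SUS) {
        comp[other - 1] = INF;
        rp[other - 1] = p0;
        ever_infected[other - 1] = true;
        infected.insert(std::lower_bound(infected.begin(), infected.end(), other),
                        other);
        --n_sus;
        last_change = t;
      } else {  // unsusceptible or recovered: challenge
        if (unif_rand() < rp[b - 1]) {
          comp[b - 1] = REC;
          rp[b - 1] = 0.0;
          infected.erase(std::lower_bound(infected.begin(), infected.end(), b));
          ++n_rec;
          last_change = t;
        } else if (cumulative) {
          rp[b - 1] = std::min(1.0, rp[b - 1] * influence);
        }
      }
    }

    if (t % sample_every == 0) {
      int tick = t / sample_every;
      time[tick] = 2.0 * (double)t / n;
      S[tick] = n_sus; I[tick] = (int)infected.size(); R[tick] = n_rec;
    }
    if (infected.empty()) { extinction_period = t; break; }
  }

  // pad the trajectory to the full horizon once the state is absorbing
  if (extinction_period >= 0) {
    int done_tick = (int)(extinction_period / sample_every);
    for (int tick = done_tick + 1; tick <= n_ticks; ++tick) {
      time[tick] = 2.0 * (double)(tick * (long)sample_every) / n;
      S[tick] = n_sus; I[tick] = 0; R[tick] = n_rec;
    }
  }

  bool equilibrium = infected.empty();
  if (!equilibrium) {
    double maxp = 0.0;
    for (size_t k = 0; k < infected.size(); ++k)
      maxp = std::max(maxp, rp[infected[k] - 1]);
    equilibrium = (maxp < 1e-9) &&
      ((long)n_periods - last_change >= 50L * n);
  }

  return List::create(_["time"] = time, _["susceptible"] = S,
                      _["infected"] = I, _["recovered"] = R,
                      _["compartment"] = comp, _["recovery_prob"] = rp,
                      _["ever_infected"] = ever_infected,
                      _["extinction_period"] = (double)extinction_period,
                      _["equilibrium_reached"] = equilibrium);
}
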