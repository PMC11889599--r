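// Monthly-accrual randomization engine for one trial replicate.
//
// Patients arrive Poisson(lambda) per month and are randomized one at a
// time among the open arms with probability proportional to the allocation
// weights (drug arms weight 1; placebo weight 1, a fixed constant, or
// sqrt(k) for k open drug arms under the dynamic square-root rule). An arm
// closes the instant it reaches its cap and the weights are re-evaluated
// before the next patient; the placebo is open only while at least one
// drug arm is open. Uses R's RNG, so results are reproducible under
// set.seed().

#include <Rcpp.h>
using namespace Rcpp;

// mode: 0 = equal, 1 = fixed_unequal, 2 = dynamic sqrt(k)
// rates: per-arm true mortality (drugs then placebo); empty to skip outcomes
// full_overlap: simultaneous-entry designs share one enrollment period, so
// every placebo patient is concurrent with every drug; otherwise each
// drug's concurrent controls are the placebo patients enrolled during its
// own first-to-last enrollment months (inclusive)
// [[Rcpp::export(name = ".engine_replicate")]]
List engine_replicate(int n_drugs, IntegerVector entry_month, int drug_cap,
                      double placebo_cap, int mode, double pw_fixed,
                      double lambda, NumericVector rates,
                      bool keep_counts, bool full_overlap) {
  const int m = n_drugs;
  const int pl = m; // 0-based placebo index
  std::vector<int> enrolled(m + 1, 0);
  std::vector<int> first_mo(m, -1), last_mo(m, -1);
  std::vector<std::vector<int>> month_counts; // per month, m+1 arms
  int month = 0;
  const int max_months = 100000;

  auto any_drug_below_cap = [&]() {
    for (int d = 0; d < m; ++d)
      if (enrolled[d] < drug_cap) return true;
    return false;
  };
  // A capped placebo is a planned enrollment group in its own right and
  // fills to its target even if the drug arms finish first; an uncapped
  // (platform-trial) placebo stops the moment the last drug arm closes.
  const bool placebo_planned = R_finite(placebo_cap);
  auto trial_enrolling = [&]() {
    if (any_drug_below_cap()) return true;
    return placebo_planned && enrolled[pl] < placebo_cap;
  };

  while (trial_enrolling()) {
    if (month >= max_months) stop("enrollment failed to terminate");
    int n_arr = (int)R::rpois(lambda);
    std::vector<int> row(m + 1, 0);
    // open drug arms this instant
    std::vector<int> open;
    open.reserve(m);
    for (int d = 0; d < m; ++d)
      if (entry_month[d] <= month && enrolled[d] < drug_cap) open.push_back(d);
    for (int i = 0; i < n_arr; ++i) {
      int k = (int)open.size();
      bool pl_open = enrolled[pl] < placebo_cap &&
                     (k > 0 || placebo_planned);
      if (k == 0 && !pl_open) break; // no open arm: arrivals not enrolled
      if (k == 0) { // placebo alone finishes its planned group
        enrolled[pl]++;
        row[pl]++;
        continue;
      }
      double pw = (mode == 0) ? 1.0 : (mode == 1) ? pw_fixed : std::sqrt((double)k);
      double total = k + (pl_open ? pw : 0.0);
      double u = unif_rand() * total;
      if (u < (double)k) {
        int j = (int)u; // uniform over open drugs (each weight 1)
        if (j >= k) j = k - 1;
        int d = open[j];
        enrolled[d]++;
        row[d]++;
        if (first_mo[d] < 0) first_mo[d] = month;
        last_mo[d] = month;
        if (enrolled[d] >= drug_cap) open.erase(open.begin() + j);
      } else {
        enrolled[pl]++;
        row[pl]++;
      }
    }
    month_counts.push_back(row);
    ++month;
  }

  List out = List::create(
    _["enrolled"] = IntegerVector(enrolled.begin(), enrolled.end()),
    _["months"] = month,
    _["first_month"] = IntegerVector(first_mo.begin(), first_mo.end()),
    _["last_month"] = IntegerVector(last_mo.begin(), last_mo.end())
  );

  if (keep_counts) {
    IntegerMatrix counts(month, m + 1);
    for (int t = 0; t < month; ++t)
      for (int a = 0; a <= m; ++a) counts(t, a) = month_counts[t][a];
    out["counts"] = counts;
  }

  if (rates.size() == m + 1) {
    // deaths: one binomial draw per drug arm; placebo per month so each
    // drug's concurrent window can be summed
    NumericMatrix per_drug(m, 4); // n_drug, deaths_drug, n_conc, deaths_conc
    std::vector<int> pl_deaths(month, 0);
    for (int t = 0; t < month; ++t)
      pl_deaths[t] = (int)R::rbinom(month_counts[t][pl], rates[pl]);
    for (int d = 0; d < m; ++d) {
      per_drug(d, 0) = enrolled[d];
      per_drug(d, 1) = R::rbinom(enrolled[d], rates[d]);
      int nc = 0, dc = 0;
      int lo = full_overlap ? 0 : first_mo[d];
      int hi = full_overlap ? (month - 1) : last_mo[d];
      if (lo >= 0) {
        for (int t = lo; t <= hi; ++t) {
          nc += month_counts[t][pl];
          dc += pl_deaths[t];
        }
      }
      per_drug(d, 2) = nc;
      per_drug(d, 3) = dc;
    }
    out["per_drug"] = per_drug;
  }
  return out;
}
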