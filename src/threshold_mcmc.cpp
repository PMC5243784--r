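#include <Rcpp.h>
using namespace Rcpp;

// Single-site random-scan Metropolis sampler for node liabilities under the
// liability threshold model. The liability evolves by Brownian motion with
// rate fixed at 1 (rate/threshold are non-identifiable with liability scale
// in the two-state case); the threshold sits at 0 and state 1 <=> liability
// > 0. Tip proposals that would flip the observed sign are rejected, which
// is the constrained posterior's Metropolis kernel. The log-density of a
// configuration factorises into Gaussian increments along edges, so a
// single-site update only touches the parent edge and the child edges of the
// updated node. Per-node step sizes are Robbins-Monro tuned toward a target
// acceptance rate during burn-in and frozen afterwards.
//
// A "generation" is one full sweep: every node is updated once, in an order
// re-randomised each sweep (O(n) likelihood work per sweep thanks to the
// edge factorisation). Samples are recorded every `sample_every` generations
// and the first `burnin` fraction of recorded samples is discarded.

// [[Rcpp::export]]
List threshold_mcmc_cpp(IntegerVector parent,    // 1-based, 0 for root
                        NumericVector blen,      // branch to parent, 0 at root
                        IntegerVector tipstate,  // 0/1 tips, -1 internal
                        NumericVector init,
                        double ngen_d, double sample_every_d, double burnin,
                        double target_acc) {
  const int n = parent.size();
  const long long ngen = (long long)ngen_d;
  const long long sample_every = (long long)sample_every_d;
  // children in CSR layout
  std::vector<int> nchild(n, 0);
  for (int i = 0; i < n; ++i) if (parent[i] > 0) nchild[parent[i] - 1]++;
  std::vector<int> cstart(n + 1, 0);
  for (int i = 0; i < n; ++i) cstart[i + 1] = cstart[i] + nchild[i];
  std::vector<int> clist(cstart[n]);
  std::vector<int> fill(n, 0);
  for (int i = 0; i < n; ++i)
    if (parent[i] > 0) {
      int p = parent[i] - 1;
      clist[cstart[p] + fill[p]++] = i;
    }
  // guard: liability constraints need positive adjacent variance; the tree
  // validator warns on zero branches, here we floor them inside the sampler
  double maxb = 0.0;
  for (int i = 0; i < n; ++i) if (blen[i] > maxb) maxb = blen[i];
  const double bfloor = 1e-8 * (maxb > 0 ? maxb : 1.0);
  std::vector<double> bl(n);
  for (int i = 0; i < n; ++i) bl[i] = (blen[i] > bfloor) ? blen[i] : bfloor;

  std::vector<double> L(init.begin(), init.end());
  std::vector<double> lstep(n, 0.0);            // log step sizes
  std::vector<double> nprop(n, 0.0);
  long long nsamples = ngen / sample_every;
  long long nburn = (long long)std::floor(burnin * (double)nsamples);
  long long nkeep = nsamples - nburn;
  NumericMatrix samples(nkeep, n);
  long long gen_burn = nburn * sample_every;    // adaptation window
  long long acc_ct = 0, prop_ct = 0;            // post burn-in
  long long stored = 0;

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  RNGScope scope;
  for (long long g = 1; g <= ngen; ++g) {
    // re-randomise the node update order each sweep (Fisher-Yates)
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    bool tuning = g <= gen_burn;
    for (int u = 0; u < n; ++u) {
      int i = order[u];
      double step = std::exp(lstep[i]);
      double x = L[i];
      double xp = x + step * norm_rand();
      bool accept;
      // sign constraint at tips
      if (tipstate[i] == 1 && !(xp > 0.0)) accept = false;
      else if (tipstate[i] == 0 && !(xp <= 0.0)) accept = false;
      else {
        double dll = 0.0;
        if (parent[i] > 0) {
          double lp = L[parent[i] - 1];
          dll += (-(xp - lp) * (xp - lp) + (x - lp) * (x - lp)) / (2.0 * bl[i]);
        }
        for (int k = cstart[i]; k < cstart[i + 1]; ++k) {
          int c = clist[k];
          double lc = L[c];
          dll += (-(lc - xp) * (lc - xp) + (lc - x) * (lc - x)) / (2.0 * bl[c]);
        }
        accept = (dll >= 0.0) || (unif_rand() < std::exp(dll));
      }
      if (accept) L[i] = xp;
      if (tuning) {
        nprop[i] += 1.0;
        double gam = 1.0 / std::sqrt(nprop[i]);
        if (gam > 0.25) gam = 0.25;
        lstep[i] += gam * ((accept ? 1.0 : 0.0) - target_acc);
        if (lstep[i] > 6.0) lstep[i] = 6.0;
        if (lstep[i] < -6.0) lstep[i] = -6.0;
      } else {
        prop_ct++;
        if (accept) acc_ct++;
      }
    }
    if (g % sample_every == 0) {
      long long s = g / sample_every;
      if (s > nburn) {
        for (int j = 0; j < n; ++j) samples(stored, j) = L[j];
        stored++;
      }
    }
  }
  NumericVector steps(n);
  for (int i = 0; i < n; ++i) steps[i] = std::exp(lstep[i]);
  return List::create(
    _["samples"] = samples,
    _["acceptance"] = prop_ct > 0 ? (double)acc_ct / (double)prop_ct : NA_REAL,
    _["steps"] = steps,
    _["n_retained"] = (double)nkeep);
}
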