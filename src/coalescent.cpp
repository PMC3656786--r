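#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Structured-coalescent simulator for a finite island model, optionally
// hierarchical (demes partitioned into groups with a higher within-group
// than between-group migration rate). Time is in units of 2N generations
// per deme; migration parameters are on the 4Nm scale (per-lineage rate
// mig/2), mutation on the theta = 4Nu scale (per-lineage rate theta/2).
// Mutations are stepwise: +/-1 with probability p_smm, otherwise a
// geometric multi-step jump (success probability geom_p). Tip allele
// states are returned as integer repeat-score offsets from the root state.
//
// Uses R's RNG so that set.seed() in R makes runs reproducible.

static int geom_step(double geom_p) {
  // geometric on {1, 2, ...} via inversion
  double u = unif_rand();
  int g = (int)std::floor(std::log(u) / std::log1p(-geom_p)) + 1;
  return g < 1 ? 1 : g;
}

static int mut_step(double p_smm, double geom_p) {
  int mag = (unif_rand() < p_smm) ? 1 : geom_step(geom_p);
  return (unif_rand() < 0.5) ? -mag : mag;
}

// [[Rcpp::export(name = ".coalescent_island_cpp")]]
IntegerMatrix coalescent_island_cpp(IntegerVector sample_sizes,
                                    IntegerVector sample_demes,
                                    int n_demes,
                                    IntegerVector deme_group,
                                    double mig_within,
                                    double mig_between,
                                    NumericVector theta,
                                    double p_smm,
                                    double geom_p) {
  int n_samp_demes = sample_sizes.size();
  int n_tips = 0;
  for (int i = 0; i < n_samp_demes; ++i) n_tips += sample_sizes[i];
  int n_loci = theta.size();
  IntegerMatrix out(n_tips, n_loci);

  if (n_demes < 1) stop("n_demes must be >= 1");
  if (deme_group.size() != n_demes) stop("deme_group must have n_demes entries");

  int n_groups = 0;
  for (int d = 0; d < n_demes; ++d) {
    if (deme_group[d] + 1 > n_groups) n_groups = deme_group[d] + 1;
  }
  std::vector<int> group_size(n_groups, 0);
  for (int d = 0; d < n_demes; ++d) group_size[deme_group[d]]++;

  RNGScope scope;

  for (int l = 0; l < n_loci; ++l) {
    std::vector<int> lin_deme;
    std::vector<std::vector<int> > lin_tips;
    int tip = 0;
    for (int s = 0; s < n_samp_demes; ++s) {
      int d = sample_demes[s] - 1;  // 1-based from R
      if (d < 0 || d >= n_demes) stop("sample deme out of range");
      for (int j = 0; j < sample_sizes[s]; ++j) {
        lin_deme.push_back(d);
        lin_tips.push_back(std::vector<int>(1, tip++));
      }
    }
    std::vector<int> state(n_tips, 0);

    std::vector<int> deme_count(n_demes, 0);
    for (size_t i = 0; i < lin_deme.size(); ++i) deme_count[lin_deme[i]]++;

    long guard = 0;
    while (lin_deme.size() > 1) {
      if (++guard > 100000000L) stop("coalescent event limit exceeded");
      int n_lin = (int)lin_deme.size();
      double coal_rate = 0.0;
      for (int d = 0; d < n_demes; ++d) {
        coal_rate += 0.5 * deme_count[d] * (deme_count[d] - 1);
      }
      double mig_rate = 0.0;
      std::vector<double> lin_mig(n_lin);
      for (int i = 0; i < n_lin; ++i) {
        int g = deme_group[lin_deme[i]];
        double rw = (group_size[g] > 1) ? mig_within / 2.0 : 0.0;
        double rb = (n_demes > group_size[g]) ? mig_between / 2.0 : 0.0;
        lin_mig[i] = rw + rb;
        mig_rate += lin_mig[i];
      }
      double mut_rate = n_lin * theta[l] / 2.0;
      double total = coal_rate + mig_rate + mut_rate;
      if (total <= 0.0) stop("zero event rate: isolated lineages cannot coalesce");

      double u = unif_rand() * total;
      if (u < coal_rate) {
        // coalescence: choose deme weighted by pair count, merge two lineages
        double v = unif_rand() * coal_rate;
        int d = -1;
        double acc = 0.0;
        for (int dd = 0; dd < n_demes; ++dd) {
          acc += 0.5 * deme_count[dd] * (deme_count[dd] - 1);
          if (v < acc) { d = dd; break; }
        }
        if (d < 0) d = n_demes - 1;
        int i1 = (int)(unif_rand() * deme_count[d]);
        int i2 = (int)(unif_rand() * (deme_count[d] - 1));
        if (i2 >= i1) i2++;
        // map within-deme indices to lineage indices
        int a = -1, b = -1, seen = 0;
        for (int i = 0; i < n_lin; ++i) {
          if (lin_deme[i] == d) {
            if (seen == i1) a = i;
            if (seen == i2) b = i;
            seen++;
          }
        }
        if (b < a) std::swap(a, b);
        lin_tips[a].insert(lin_tips[a].end(), lin_tips[b].begin(), lin_tips[b].end());
        lin_deme.erase(lin_deme.begin() + b);
        lin_tips.erase(lin_tips.begin() + b);
        deme_count[d]--;
      } else if (u < coal_rate + mig_rate) {
        // migration: choose lineage weighted by its migration rate
        double v = unif_rand() * mig_rate;
        int i = -1;
        double acc = 0.0;
        for (int ii = 0; ii < n_lin; ++ii) {
          acc += lin_mig[ii];
          if (v < acc) { i = ii; break; }
        }
        if (i < 0) i = n_lin - 1;
        int d = lin_deme[i];
        int g = deme_group[d];
        double rw = (group_size[g] > 1) ? mig_within / 2.0 : 0.0;
        double rb = (n_demes > group_size[g]) ? mig_between / 2.0 : 0.0;
        bool within = (unif_rand() * (rw + rb)) < rw;
        // choose a uniform destination deme in the chosen class
        int dest = d;
        if (within) {
          int pick = (int)(unif_rand() * (group_size[g] - 1));
          int seen = 0;
          for (int dd = 0; dd < n_demes; ++dd) {
            if (dd != d && deme_group[dd] == g) {
              if (seen == pick) { dest = dd; break; }
              seen++;
            }
          }
        } else {
          int n_other = n_demes - group_size[g];
          int pick = (int)(unif_rand() * n_other);
          int seen = 0;
          for (int dd = 0; dd < n_demes; ++dd) {
            if (deme_group[dd] != g) {
              if (seen == pick) { dest = dd; break; }
              seen++;
            }
          }
        }
        deme_count[d]--;
        deme_count[dest]++;
        lin_deme[i] = dest;
      } else {
        // mutation on a uniformly chosen lineage: shift all its tips
        int i = (int)(unif_rand() * n_lin);
        if (i >= n_lin) i = n_lin - 1;
        int step = mut_step(p_smm, geom_p);
        for (size_t t = 0; t < lin_tips[i].size(); ++t) {
          state[lin_tips[i][t]] += step;
        }
      }
    }
    for (int t = 0; t < n_tips; ++t) out(t, l) = state[t];
  }
  return out;
}

// Ewens-sampling null simulator: draws allele configurations of n gene
// copies from the Hoppe urn at parameter theta, keeping only draws with
// exactly k alleles (the conditional null of the Ewens-Watterson test).
// Returns the homozygosity F = sum p_i^2 of each accepted configuration.
// [[Rcpp::export(name = ".ewens_urn_F_cpp")]]
NumericVector ewens_urn_F_cpp(int n, int k, double theta, int n_sim,
                              double max_tries) {
  NumericVector out(n_sim);
  RNGScope scope;
  double tries = 0;
  int got = 0;
  std::vector<int> counts;
  while (got < n_sim) {
    if (++tries > max_tries) {
      stop("Ewens urn rejection sampler exceeded %.0f tries (n=%d, k=%d)",
           max_tries, n, k);
    }
    counts.clear();
    for (int i = 0; i < n; ++i) {
      double u = unif_rand() * (theta + i);
      if (u < theta || i == 0) {
        counts.push_back(1);
      } else {
        // join an existing allele with probability proportional to count
        double v = unif_rand() * i;
        double acc = 0.0;
        size_t j = 0;
        for (; j < counts.size(); ++j) {
          acc += counts[j];
          if (v < acc) break;
        }
        if (j >= counts.size()) j = counts.size() - 1;
        counts[j]++;
      }
      if ((int)counts.size() > k) break;  // early reject: too many alleles
    }
    if ((int)counts.size() != k) continue;
    double F = 0.0;
    for (size_t j = 0; j < counts.size(); ++j) {
      double p = (double)counts[j] / n;
      F += p * p;
    }
    out[got++] = F;
  }
  return out;
}
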