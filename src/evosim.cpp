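#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Diminishing-returns epistasis: a mutation with headline effect Dr rescales
// the genotype's remaining gap to the physiological floor by
//   k = max((Dabs - Dfn) / (Dfs - Dfn), 0),
// where Dabs is the absolute doubling time the mutation alone would confer
// on the founder under stress. In the log2 convention Dabs = 2^Dr * Dfs; in
// the absolute convention Dr already is Dabs.
static inline double apply_effect(double DG, double Dr, double Dfs,
                                  double Dfn, bool log2_effects) {
  double Dabs = log2_effects ? std::pow(2.0, Dr) * Dfs : Dr;
  double k = (Dabs - Dfn) / (Dfs - Dfn);
  if (k < 0.0) k = 0.0;
  double Dm = k * (DG - Dfn) + Dfn;
  return Dm < Dfn ? Dfn : Dm;
}

struct Event {
  double t;
  long long seq;  // insertion order breaks ties
  int cell;
};
struct EventCmp {
  bool operator()(const Event& a, const Event& b) const {
    if (a.t != b.t) return a.t > b.t;
    return a.seq > b.seq;
  }
};

struct Pop {
  std::vector<double> dt;               // division time, hours
  std::vector<int> age;                 // divisions used
  std::vector<std::vector<int>> genes;  // 1-based mutated gene ids
  std::vector<int> chrom_mask;          // bitmask of duplicated chromosomes
  std::vector<int> neutral;             // neutral point-mutation count
};

struct MutParams {
  double pm_mean;          // Poisson mean of point mutations per division
  double mu_dup;           // duplication probability per division
  double total_effectual;  // sum of effectual sites over all genes
  double genome_bp;
  const double* cum_effectual;  // cumulative effectual sites, length n_genes
  int n_genes;
  const double* gene_dr;   // per-gene effect (log2 or absolute)
  const double* chrom_dr;  // per-chromosome effect
  int n_chrom;
  double Dfs, Dfn;
  bool log2_effects;
};

static void mutate_cell(Pop& p, int c, const MutParams& mp) {
  int npm = (int) R::rpois(mp.pm_mean);
  for (int i = 0; i < npm; ++i) {
    double u = unif_rand() * mp.genome_bp;
    if (u < mp.total_effectual) {
      const double* hit = std::upper_bound(
        mp.cum_effectual, mp.cum_effectual + mp.n_genes, u);
      int g = (int)(hit - mp.cum_effectual);  // 0-based gene index
      if (g >= mp.n_genes) g = mp.n_genes - 1;
      std::vector<int>& gl = p.genes[c];
      if (std::find(gl.begin(), gl.end(), g + 1) == gl.end()) {
        gl.push_back(g + 1);
        p.dt[c] = apply_effect(p.dt[c], mp.gene_dr[g], mp.Dfs, mp.Dfn,
                               mp.log2_effects);
      } else {
        p.neutral[c] += 1;  // gene already hit in this lineage
      }
    } else {
      p.neutral[c] += 1;  // non-effectual site
    }
  }
  if (unif_rand() < mp.mu_dup) {
    int avail[64]; int na = 0;
    for (int j = 0; j < mp.n_chrom; ++j) {
      if (!((p.chrom_mask[c] >> j) & 1)) avail[na++] = j;
    }
    if (na > 0) {
      int pick = (int)(unif_rand() * na);
      if (pick >= na) pick = na - 1;
      int j = avail[pick];
      p.chrom_mask[c] |= (1 << j);
      p.dt[c] = apply_effect(p.dt[c], mp.chrom_dr[j], mp.Dfs, mp.Dfn,
                             mp.log2_effects);
    }
  }
}

// One serial growth cycle: cells divide asynchronously on an event queue
// ordered by due time (ties by insertion order); each division adds a
// daughter, ages the mother, and draws mutations; growth halts the moment
// the population reaches round(2^Mt * N0) cells; N_out survivors are then
// sampled uniformly without replacement.
// [[Rcpp::export]]
List run_cycle_cpp(NumericVector div_time0, IntegerVector age0, List genes0,
                   IntegerVector chrom_mask0, IntegerVector neutral0,
                   double Mt, int max_divisions,
                   double pm_mean, double mu_dup,
                   double total_effectual, double genome_bp,
                   NumericVector cum_effectual, NumericVector gene_dr,
                   NumericVector chrom_dr,
                   double Dfs, double Dfn, int N_out,
                   bool log2_effects, bool mutate_both) {
  int n0 = div_time0.size();
  long long cap = (long long) std::llround(std::pow(2.0, Mt) * n0);
  if (cap < n0) cap = n0;

  Pop p;
  p.dt.assign(div_time0.begin(), div_time0.end());
  p.age.assign(age0.begin(), age0.end());
  p.chrom_mask.assign(chrom_mask0.begin(), chrom_mask0.end());
  p.neutral.assign(neutral0.begin(), neutral0.end());
  p.genes.resize(n0);
  for (int i = 0; i < n0; ++i) {
    IntegerVector g = genes0[i];
    p.genes[i].assign(g.begin(), g.end());
  }
  size_t reserve = (size_t) std::min<long long>(cap, 1LL << 24);
  p.dt.reserve(reserve); p.age.reserve(reserve);
  p.genes.reserve(reserve); p.chrom_mask.reserve(reserve);
  p.neutral.reserve(reserve);

  MutParams mp;
  mp.pm_mean = pm_mean; mp.mu_dup = mu_dup;
  mp.total_effectual = total_effectual; mp.genome_bp = genome_bp;
  mp.cum_effectual = cum_effectual.begin();
  mp.n_genes = cum_effectual.size();
  mp.gene_dr = gene_dr.begin();
  mp.chrom_dr = chrom_dr.begin(); mp.n_chrom = chrom_dr.size();
  mp.Dfs = Dfs; mp.Dfn = Dfn; mp.log2_effects = log2_effects;

  std::priority_queue<Event, std::vector<Event>, EventCmp> q;
  long long seq = 0;
  for (int i = 0; i < n0; ++i) {
    if (p.age[i] < max_divisions) q.push({p.dt[i], seq++, i});
  }

  long long total = n0;
  double t_final = 0.0;
  while (total < cap && !q.empty()) {
    Event e = q.top(); q.pop();
    int m = e.cell;
    t_final = e.t;
    p.age[m] += 1;

    // daughter inherits the mother's genotype, starts at age 0
    int d = (int) p.dt.size();
    p.dt.push_back(p.dt[m]);
    p.age.push_back(0);
    p.genes.push_back(p.genes[m]);
    p.chrom_mask.push_back(p.chrom_mask[m]);
    p.neutral.push_back(p.neutral[m]);
    mutate_cell(p, d, mp);
    if (mutate_both) mutate_cell(p, m, mp);

    q.push({e.t + p.dt[d], seq++, d});
    if (p.age[m] < max_divisions) q.push({e.t + p.dt[m], seq++, m});
    total += 1;
  }
  bool extinct = total < cap;

  double mean_dt_cap = 0.0;
  for (long long i = 0; i < total; ++i) mean_dt_cap += p.dt[(size_t)i];
  mean_dt_cap /= (double) total;

  int n_keep = (int) std::min<long long>(N_out, total);
  IntegerVector pick = Rcpp::sample((int) total, n_keep, false);  // 1-based

  NumericVector out_dt(n_keep);
  IntegerVector out_age(n_keep), out_mask(n_keep), out_neutral(n_keep);
  List out_genes(n_keep);
  for (int i = 0; i < n_keep; ++i) {
    int j = pick[i] - 1;
    out_dt[i] = p.dt[j];
    out_age[i] = p.age[j];
    out_mask[i] = p.chrom_mask[j];
    out_neutral[i] = p.neutral[j];
    out_genes[i] = IntegerVector(p.genes[j].begin(), p.genes[j].end());
  }

  return List::create(
    _["division_time_h"] = out_dt,
    _["divisions_used"] = out_age,
    _["genes"] = out_genes,
    _["chrom_mask"] = out_mask,
    _["neutral"] = out_neutral,
    _["pop_size_at_halt"] = (double) total,
    _["mean_D_at_halt"] = mean_dt_cap,
    _["extinct"] = extinct,
    _["t_final_h"] = t_final);
}
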