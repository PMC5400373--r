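// Structured-coalescent simulation of a single unlinked locus under a
// backward-time demographic event list, plus generalized stepwise mutation.
//
// Event encoding (rows of the events matrix, sorted by non-decreasing time):
//   col 0: time (generations before sampling)
//   col 1: type  1=SAMPLE  2=DIVERGE  3=ADMIX  4=SIZE_CHANGE
//   col 2: pop   (1-based)  SAMPLE/SIZE_CHANGE target, or derived pop
//   col 3: source1 (1-based; DIVERGE source, ADMIX source1)
//   col 4: source2 (1-based; ADMIX source2)
//   col 5: value  (SAMPLE: n diploids; ADMIX: r = P(lineage -> source1);
//                  SIZE_CHANGE: new diploid Ne)
//
// Within a population of diploid size Ne, each lineage pair coalesces at
// rate 1/(2Ne) per generation (continuous-time approximation). All state
// uses R's RNG so results are reproducible via set.seed().

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static const int EV_SAMPLE = 1, EV_DIVERGE = 2, EV_ADMIX = 3, EV_SIZE = 4;

struct Genealogy {
  std::vector<int> parent;     // parent node index, -1 for root
  std::vector<double> time;    // node time (generations before sampling)
  std::vector<int> leaf_pop;   // population of each leaf (1-based)
  int n_leaves;
  double tmrca;
};

// simulate one genealogy; throws Rcpp::exception on structural failure
static Genealogy simulate_tree(const NumericMatrix& events,
                               const NumericVector& ne0) {
  const int npop = ne0.size();
  std::vector<double> ne(ne0.begin(), ne0.end());
  std::vector< std::vector<int> > active(npop);  // node ids per population

  // count leaves to preallocate
  int n_leaves = 0;
  for (int e = 0; e < events.nrow(); ++e)
    if ((int)events(e, 1) == EV_SAMPLE) n_leaves += 2 * (int)events(e, 5);
  if (n_leaves < 2) stop("scenario samples fewer than 2 gene copies");

  Genealogy g;
  g.n_leaves = n_leaves;
  g.parent.assign(2 * n_leaves - 1, -1);
  g.time.assign(2 * n_leaves - 1, 0.0);
  g.leaf_pop.assign(n_leaves, 0);

  int next_node = 0;                 // leaves first, internals after
  int next_internal = n_leaves;
  double t = 0.0;
  int ei = 0;
  const int n_ev = events.nrow();
  int n_active = 0;
  int samples_left = 0;
  for (int e = 0; e < n_ev; ++e)
    if ((int)events(e, 1) == EV_SAMPLE) ++samples_left;

  while (true) {
    // total coalescence rate
    double total_rate = 0.0;
    for (int p = 0; p < npop; ++p) {
      double k = (double)active[p].size();
      if (k >= 2.0 && ne[p] > 0.0)
        total_rate += k * (k - 1.0) / 2.0 / (2.0 * ne[p]);
    }
    double t_event = (ei < n_ev) ? events(ei, 0) : R_PosInf;

    double t_coal = R_PosInf;
    if (total_rate > 0.0) t_coal = t + exp_rand() / total_rate;

    if (t_coal < t_event) {
      // coalesce a pair in a population chosen proportional to its rate
      t = t_coal;
      double u = unif_rand() * total_rate, acc = 0.0;
      int pop = -1;
      for (int p = 0; p < npop; ++p) {
        double k = (double)active[p].size();
        if (k >= 2.0 && ne[p] > 0.0) {
          acc += k * (k - 1.0) / 2.0 / (2.0 * ne[p]);
          if (u <= acc) { pop = p; break; }
        }
      }
      if (pop < 0) pop = npop - 1;
      std::vector<int>& lin = active[pop];
      int k = (int)lin.size();
      int i = (int)(unif_rand() * k); if (i >= k) i = k - 1;
      int j = (int)(unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
      if (j >= i) ++j;
      int a = lin[i], b = lin[j];
      int node = next_internal++;
      g.parent[a] = node; g.parent[b] = node; g.time[node] = t;
      // remove the two, add the parent
      if (i > j) std::swap(i, j);
      lin.erase(lin.begin() + j); lin.erase(lin.begin() + i);
      lin.push_back(node);
      --n_active;
      if (n_active == 1 && samples_left == 0) { g.tmrca = t; return g; }
    } else {
      if (ei >= n_ev) {
        // no events left and no coalescence possible
        stop("lineages remain in disconnected populations: scenario has no common ancestral population");
      }
      t = t_event;
      int type = (int)events(ei, 1);
      int pop = (int)events(ei, 2) - 1;
      if (pop < 0 || pop >= npop) stop("event population index out of range");
      if (type == EV_SAMPLE) {
        --samples_left;
        int n_dip = (int)events(ei, 5);
        for (int c = 0; c < 2 * n_dip; ++c) {
          int node = next_node++;
          g.time[node] = t;
          g.leaf_pop[node] = pop + 1;
          active[pop].push_back(node);
          ++n_active;
        }
      } else if (type == EV_DIVERGE) {
        int src = (int)events(ei, 3) - 1;
        if (src < 0 || src >= npop) stop("divergence source out of range");
        for (size_t c = 0; c < active[pop].size(); ++c)
          active[src].push_back(active[pop][c]);
        active[pop].clear();
      } else if (type == EV_ADMIX) {
        int s1 = (int)events(ei, 3) - 1, s2 = (int)events(ei, 4) - 1;
        double r = events(ei, 5);
        if (s1 < 0 || s1 >= npop || s2 < 0 || s2 >= npop)
          stop("admixture source out of range");
        for (size_t c = 0; c < active[pop].size(); ++c) {
          if (unif_rand() < r) active[s1].push_back(active[pop][c]);
          else                 active[s2].push_back(active[pop][c]);
        }
        active[pop].clear();
      } else if (type == EV_SIZE) {
        ne[pop] = events(ei, 5);
      } else {
        stop("unknown event type code");
      }
      ++ei;
    }
  }
}

// one GSM mutation step chain along a branch; reflecting allele window
static int mutate_branch(int allele, double len, double mu, double p_geom,
                         int amin, int amax) {
  if (len <= 0.0 || mu <= 0.0) return allele;
  int nmut = (int)R::rpois(mu * len);
  for (int m = 0; m < nmut; ++m) {
    int k = 1;
    if (p_geom > 0.0) k += (int)R::rgeom(1.0 - p_geom);
    if (unif_rand() < 0.5) k = -k;
    allele += k;
    while (allele < amin || allele > amax) {
      if (allele < amin) allele = 2 * amin - allele;
      else               allele = 2 * amax - allele;
    }
  }
  return allele;
}

// [[Rcpp::export(name = ".cpp_sim_tree")]]
List cpp_sim_tree(NumericMatrix events, NumericVector ne) {
  RNGScope scope;
  Genealogy g = simulate_tree(events, ne);
  IntegerVector parent(g.parent.begin(), g.parent.end());
  NumericVector time(g.time.begin(), g.time.end());
  IntegerVector pops(g.leaf_pop.begin(), g.leaf_pop.end());
  return List::create(_["parent"] = parent,
                      _["time"] = time,
                      _["leaf_pop"] = pops,
                      _["n_leaves"] = g.n_leaves,
                      _["tmrca"] = g.tmrca);
}

// [[Rcpp::export(name = ".cpp_drop_mutations")]]
IntegerVector cpp_drop_mutations(IntegerVector parent, NumericVector time,
                                 int n_leaves, double mu, double p_geom,
                                 int amin, int amax, int root_allele) {
  RNGScope scope;
  int n_nodes = parent.size();
  std::vector<int> all(n_nodes, root_allele);
  // nodes were created in increasing time order; root is the last one
  for (int i = n_nodes - 2; i >= 0; --i) {
    int p = parent[i];
    double len = time[p] - time[i];
    all[i] = mutate_branch(all[p], len, mu, p_geom, amin, amax);
  }
  return IntegerVector(all.begin(), all.begin() + n_leaves);
}

// [[Rcpp::export(name = ".cpp_sim_tmrca")]]
NumericVector cpp_sim_tmrca(NumericMatrix events, NumericVector ne,
                            int n_rep) {
  RNGScope scope;
  NumericVector out(n_rep);
  for (int r = 0; r < n_rep; ++r) {
    Genealogy g = simulate_tree(events, ne);
    out[r] = g.tmrca;
  }
  return out;
}
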