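# invasionabc

Reconstructing the introduction routes of invasive populations from
multi-locus microsatellite genotypes, with approximate Bayesian
computation (ABC).

## What it does, for whom

Population geneticists studying biological invasions typically hold
diploid microsatellite genotypes from many sampling sites across the
native and introduced range, plus first-record dates, and want to know:
which population seeded which, how severe the founding bottlenecks were,
and whether some introduced populations are admixtures of distinct
sources. Likelihoods for such models are intractable, so inference is
simulation-based:

1. Competing **introduction scenarios** are declared as backward-time
   demographic event lists (divergences = introductions without
   subsequent gene flow, two-source admixtures with rate r, founding
   bottlenecks of duration d_b at size N_b, optional unsampled "ghost"
   sources). For one target and k candidate sources, the standard
   competing set is the k single-source scenarios plus the C(k,2)
   pairwise admixtures. Introduction times come from first-record dates
   at 12 generations/year.
2. Datasets are simulated under each scenario from prior-drawn
   parameters (structured coalescent + generalized stepwise mutation,
   C++ core) and summarized with the standard microsatellite catalog:
   4 one-population, 8 two-population and 3 three-population statistics
   per population/pair/triplet (allele counts, gene diversity,
   allele-size variance, Garza–Williamson M, Weir–Cockerham FST,
   assignment likelihoods, shared-allele distance, (δμ)², admixture
   estimates) — 4P + 8·C(P,2) + 3·C(P,3) statistics for P populations.
3. **Model choice** is made two ways: ABC-RF (random-forest
   classification votes, out-of-bag prior error rate, posterior
   probability of the winner from a secondary error-regression forest)
   and ABC-LDA (rejection on the closest simulations + polychotomous
   logistic regression on linear discriminant axes).
4. **Parameters** (bottleneck severity d_b/N_b, admixture rates) are
   estimated by local linear regression on logit-transformed draws;
   severities classify as weak (< 0.12), moderate (0.12–0.22) or strong
   (> 0.3).
5. **Model-posterior checking** simulates from the fitted
   scenario-posterior combination and computes tail-area posterior
   predictive p-values over held-out statistics, with
   Benjamini–Hochberg FDR control and a principal-component projection
   of the predictive cloud.

Everything is exercised end-to-end on synthetic invasion histories with
known truth (`make_toy_invasion()`), so the whole pipeline is testable
without any external data.

## Worked example

Build a small synthetic world — two native populations N1/N2, an
invasive I1 founded from N1 through a strong bottleneck, and a focal
invasive I2 that is truly an admixture of N2 and I1 (r = 0.7) — then ask
the random forest where I2 came from:

```r
library(invasionabc)

w <- make_toy_invasion("small", seed = 42)
#> toy_world (small): 4 populations, 10 loci, 3 competing scenarios
#>   (truth: I2-admix-N2-I1)

obs <- compute_stats(w$dataset, "full")   # 76 summary statistics
tab <- build_reference_table(w$competing, w$prior, 1000,
                             w$sample_config, w$n_loci, model = w$model,
                             seed = 42)
rf <- rf_model_choice(tab, obs, n_trees = 500, seed = 42)
rf
#> ABC-RF model choice (500 trees, 1 replicate(s))
#>   votes: I2-from-N2=21, I2-from-I1=23, I2-admix-N2-I1=456
#>   best: I2-admix-N2-I1  P(best) = 0.894  prior error = 0.180
```

The admixture scenario (the truth) takes 456 of 500 votes; the prior
error rate says that with a table of this size a wrong choice would
happen in about 18% of prior draws. Estimating the admixture rate and
the two bottleneck severities under the winning scenario:

```r
est <- build_reference_table(list(w$scenario), w$prior, 4000,
                             w$sample_config, w$n_loci, model = w$model,
                             stat_set = "estimation",
                             triplets = w$triplets, seed = 43)
post <- local_linear_estimate(
  est, compute_stats(w$dataset, "estimation", w$triplets),
  acceptance_fraction = 0.05,
  parameters = c("r_I2", "severity_I1", "severity_I2"),
  derived = c(severity_I1 = "db_I1 / Nb_I1",
              severity_I2 = "db_I2 / Nb_I2"))
post$summaries
#>    parameter   mean median   mode     q5   q95     (truth)
#>         r_I2 0.6206 0.6177 0.5795 0.4337 0.810      0.7
#>  severity_I1 1.1015 1.0170 0.9855 0.5113 1.901      1.0
#>  severity_I2 0.0917 0.0848 0.0673 0.0277 0.179      0.1
```

The posterior medians sit close to the generating values and the 90%
intervals cover them: the admixture rate is recovered to within a
tenth, I1's bottleneck classifies as strong and I2's as weak
(`classify_severity()`). The numbered scripts
under `analysis/` run this workflow stage by stage (simulation, model
choice, engine comparison, estimation, posterior predictive checking)
and write their tables under `results/`.

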