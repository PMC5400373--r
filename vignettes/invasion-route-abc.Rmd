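---
title: "Inferring invasion routes from microsatellites with ABC and random forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring invasion routes from microsatellites with ABC and random forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(invasionabc)
```

## The problem

When an invasive species is sampled at many sites across its native and
introduced range, the genetic data carry a signal of *how* the invasion
happened: which population seeded which, whether founders passed through a
demographic bottleneck, and whether some introduced populations are
admixtures of several genetically distinct sources. `invasionabc`
reconstructs such histories from diploid microsatellite genotypes by
likelihood-free (approximate Bayesian computation, ABC) inference:
candidate introduction scenarios are written down as demographic models,
data are simulated under each from prior-drawn parameters, and the
simulated summary statistics are compared with the observed ones.

Three inferential stages are covered, mirroring how such studies are run
in practice:

1. **Model choice** among competing scenarios, either by a random-forest
   classifier trained on the simulated reference table (ABC-RF) or by the
   standard rejection + polychotomous-logistic-regression method on
   linear discriminant axes (ABC-LDA).
2. **Parameter estimation** under the selected scenario by local linear
   regression, focusing on bottleneck severity and admixture rates.
3. **Model-posterior checking** with posterior predictive p-values over
   held-out statistics, under false discovery rate control.

## The demographic model

A scenario is an ordered, backward-in-time event list over a set of
populations, each with a stable diploid effective size $N_e$:

* `sample(pop, n, t)` — n diploids enter the coalescent at time t
  (usually 0);
* `divergence(derived -> source, t)` — an introduction, modeled as a
  split without subsequent gene flow: at time t all lineages of the
  derived population merge into its source;
* `admixture(derived -> s1 with prob r, else s2, t)` — each lineage of an
  admixed population traces back to source 1 with probability r (the
  admixture rate: the fraction of the admixed gene pool contributed by
  source 1) and to source 2 otherwise;
* `size_change(pop, N, t)` — the effective size switches at t.

An introduction at time $t_{\mathrm{intro}}$ is immediately followed
(forward in time) by a **bottleneck**: a period of $d_b$ generations at a
reduced size $N_b$, then a return to the stable size. Bottleneck
*severity* is defined as the ratio $d_b / N_b$; larger values mean a more
damaging founding event. Posterior median severities are classified as
weak (< 0.12), moderate (0.12–0.22) or strong (> 0.3); the published
cutpoints leave the interval [0.22, 0.3] unassigned, and we surface it
explicitly as `unclassified` rather than silently extending either class.

Introduction times are not free parameters: they are fixed from the date
of first record in the invaded area, converted at 12 generations per year
(the biology of a multivoltine drosophilid), via
`first_record_to_generations()`. Uncertainty about the true source within
a structured native range can be absorbed by *ghost* (unsampled)
populations that split from an ancestral population at a time with a
loose flat prior including zero.

Within populations the coalescent runs in continuous time (pair
coalescence rate $1/(2N_e)$), which is accurate for the large effective
sizes typical here and much faster than generation-by-generation
simulation; the event structure is discrete. The core is implemented in
C++ (`src/coalescent.cpp`), seeded through R's RNG so every dataset is
reproducible from an integer seed.

## Mutation model

Microsatellite alleles are stored directly as repeat counts. Mutations
occur along branches as a Poisson process; each mutation changes the
repeat count by $\pm k$ where $k - 1$ is geometric with parameter
$P_{\mathrm{geom}}$ (the generalized stepwise model; $P_{\mathrm{geom}} =
0$ recovers the strict stepwise model). Alleles are reflected into a
contiguous window of allowed states (default 40, matching common
microsatellite-simulator conventions), and the root allele sits at the
window midpoint — an arbitrary but range-safe choice that tests can rely
on. Per-locus rates are Gamma-distributed around the mean rate $\mu$
(shape 2 by default; `rate_shape = Inf` disables heterogeneity). All of
these are explicit, user-overridable defaults in `gsm_model()`: the exact
mutational calibration used in any particular empirical study belongs to
its supplementary material, so here they are configuration, not claims.

The simulator is validated against independent oracles rather than
against itself: the mean pairwise TMRCA in a panmictic population must be
$2N$; equilibrium gene diversity under the strict stepwise model must
match the closed form $1 - 1/\sqrt{1 + 8N\mu}$; the squared difference in
mean allele size between diverged populations must grow with divergence
time; a degenerate admixture ($r = 1$) must be distributionally identical
to a divergence.

## Summary statistics

The full catalog comprises, averaged over loci:

* per population (4): mean allele count, unbiased gene diversity
  $\tilde n/(\tilde n - 1)(1 - \sum p^2)$, allele-size variance, and the
  Garza–Williamson ratio M = alleles / (allele-size range + 1);
* per unordered pair (8): the three pooled-sample one-population
  statistics, the multi-locus Weir–Cockerham $F_{ST}$ ratio estimator,
  both directions of a mean assignment log-likelihood (genotype
  likelihood under the other sample's frequencies, with add-one
  smoothing so private alleles never produce $\log 0$), the shared-allele
  distance DAS, and $(\delta\mu)^2$;
* per unordered triplet (3): a crude admixture-rate estimate with each
  member in turn as the admixed target, computed per locus as the
  least-squares coefficient of the admixed frequencies on the two source
  frequency profiles, averaged and clipped to [0, 1].

This 4/8/3 decomposition gives $4P + 8\binom{P}{2} + 3\binom{P}{3}$
statistics for $P$ populations — 39, 130, 204, 301 and 424 for $P = 3,
5, 6, 7, 8$ — and is validated by those totals. Assignment-likelihood
and admixture statistics have no single canonical formula across
microsatellite toolkits; the definitions used here are stated precisely
above and validated by the counting rules, estimator-consistency
experiments
(e.g. a true mixture with $r = 0.75$ is recovered to within 0.05 on
average), and an independent nested-ANOVA oracle for $F_{ST}$.

For parameter estimation a reduced expert set is used instead: allele
count and gene diversity per population, all pairwise $F_{ST}$, and one
admixture statistic per declared triplet ($2P + \binom{P}{2} + T$; 95 for
$P = 12$, $T = 5$). Model checking then uses the complement (1141
statistics in that configuration), so that no quantity used for fitting
is reused for criticism.

Missing genotypes (sentinel 0) are excluded locus-wise; loci unusable in
any member of a pair or triplet are dropped from that statistic's
average. Loci whose externally estimated null-allele frequency exceeds
10% in any population are excluded up front
(`filter_loci_by_null_alleles()`); the estimator of those frequencies is
deliberately out of scope — only the exclusion rule is modeled. We read
"exceeds in some sites" as *any* population, with the threshold strict
(exactly 10% is retained).

## Model choice

**ABC-RF.** A classification forest (500 trees by default) is trained on
the reference table, with the linear discriminant axes appended as
additional covariates. The observed dataset receives one vote per tree;
the scenario with most votes wins (ties break to the lowest scenario
index, with a warning — the convention is arbitrary and rare). The
*prior error rate* is the out-of-bag misclassification fraction: the
probability of choosing a wrong scenario when scenario and parameters are
drawn from their priors. We use the out-of-bag estimate rather than a
separate pseudo-observed draw because it is standard random-forest
practice and reuses the table at no extra simulation cost; a held-out
variant is available through the LDA engine's machinery. The posterior
probability of the winning scenario is estimated by a secondary
regression forest fitted to the first forest's out-of-bag
misclassification indicator: one minus its predicted error at the
observed point, clipped to [0, 1].

**ABC-LDA.** Statistics are standardized by median absolute deviation
(falling back to the standard deviation for zero-MAD columns — the
rejection metric's scaling is a design choice, not prescribed), the
nearest `tolerance` fraction (1% by default) of rows by Euclidean
distance is accepted, and a multinomial logistic regression of the
scenario label on the discriminant axes is fitted over the accepted rows
(a small weight decay guards against complete separation). Its prior
error rate is computed over pseudo-observed rows held out of the distance
ranking.

On indistinguishable scenario sets both engines must approach the
symmetric limits (prior error $(K-1)/K$, posterior $1/K$); on separable
sets both must approach perfection; and on a hard set with equally small
tables the forest should keep the lower prior error — all three are
asserted in the test suite at reduced scale (a few hundred simulated
datasets per scenario, chosen to keep the full suite in minutes on one
CPU; the published workflow used $10^4$–$5\times10^5$ per scenario, and
every size here is configurable).

## Parameter estimation

Under the selected scenario, the accepted draws (closest 0.1% by default,
intended for tables of $10^6$–$10^7$ rows; desk-scale analyses should
raise the fraction so that accepted rows comfortably exceed the number of
statistics — the function falls back to rejection-only with a warning
when a regression would be saturated) are weighted with an Epanechnikov
kernel and adjusted by weighted local linear regression after a logit
transformation of each parameter to its prior range, which guarantees
adjusted draws remain inside the prior support. Summaries are the
weighted mean, median, 5% and 95% quantiles, and a mode from a Gaussian
kernel density with Silverman bandwidth (the estimator behind published
"mode" values is rarely stated; ours is explicit). Bottleneck severity is
estimated as the derived ratio $d_b/N_b$ of the sampled draws, not as a
directly sampled parameter; its transform bounds are the empirical range
of the ratio over the table.

The estimator is validated on a linear-Gaussian toy problem with a known
conjugate posterior, on the no-information limit (constant statistics
must return the prior), and on synthetic-truth recovery (admixture rate
within 0.15 of truth in most replicates; tenfold severity contrasts
correctly ordered).

## Model-posterior checking

Given the fitted posterior, full parameter vectors are resampled by
weight from the accepted draws (estimated parameters take their adjusted
values) and `n_ppc` datasets are simulated. For each held-out test
statistic $q$, $p = \Pr(q_{\mathrm{sim}} < q_{\mathrm{obs}})$ with ties
counted half (the strict-inequality convention is ambiguous for discrete
statistics), and the reported tail-area value is $\min(p, 1-p)$, floored
at the Monte-Carlo resolution $1/(n_{\mathrm{ppc}}+1)$. Because these
folded values live in [0, 0.5] while FDR procedures expect ordinary
p-values, Benjamini–Hochberg is applied to $\min(2\,\mathrm{ppp}, 1)$.
Overlap between estimation and test statistics is an error, not a
warning. A principal-component projection of the simulated cloud with
the observed point and a whitened-distance depth rank completes the
check. Calibration is asserted under the true scenario-posterior (the
small-ppp fraction stays near nominal) and power against a gross misfit
(tenfold mutation rate) is asserted after FDR control.

## Synthetic worlds and what they do (not) show

`make_toy_invasion()` builds two reproducible worlds with known truth.
The *small* profile (4 populations, 10 loci, 20 diploids each) has an
old native split, one strongly bottlenecked introduction (severity 1.0)
and one admixed introduction ($r = 0.7$, severity 0.1) — effect sizes
chosen once, large enough that recovery is comfortable at desk scale,
and kept in a single fixtures block so tests are auditable. The
*paper-like* profile mirrors the dimensions of a worldwide survey (8
populations, 25 loci, 15–44 diploids per sample, five admixture/founding
motifs). Both emulate the *structure* of real surveys — they do not
emulate real allele-frequency spectra, marker ascertainment, null
alleles, or genotyping error, so green tests demonstrate correctness of
the machinery and statistical sanity of the estimators, not field
performance on any particular organism.

The sequential workflow (`analysis_plan()` / `run_plan()`) chains
analyses so each consumes the previous winners, replicates them over
alternative representative sample sites, and reports the modal winner
per analysis with disagreements listed verbatim — no automatic
reconciliation is attempted, because disagreement across sample sets is
itself a finding.

## Numerical and design notes

* All randomness flows from one integer root seed; reference-table rows
  use per-row derived seeds, so tables are identical for any worker
  count.
* Rows whose dataset yields non-finite statistics (e.g. zero
  polymorphism making $F_{ST}$ undefined) are resimulated with a fresh
  derived seed and counted; the published methodology is silent on this
  case.
* Reference tables persist as Feather columnar files with a JSON
  metadata sidecar (statistic names, priors, seeds, format version);
  version mismatches and truncated files error explicitly.
* Custom scenario sets that do not follow the k + C(k,2) enumeration
  rule are declared explicitly rather than auto-generated.
* Known limitations: no continuous migration, no overlapping
  generations, no selection, no linked loci; the reflecting allele
  window biases diversity slightly downward if set too narrow for the
  mutation rate (widen it via `gsm_model()` when $8N\mu$ is large).
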