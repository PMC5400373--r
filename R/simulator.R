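# Backward-in-time structured coalescent simulation of unlinked
# microsatellite loci under a bound scenario, with a generalized stepwise
# mutation (GSM) model.

#' Generalized stepwise mutation model
#'
#' Each mutation changes the repeat count by ±k, where k - 1 is geometric
#' with parameter `p_geom` (so `p_geom = 0` is the strict stepwise model)
#' and the sign is equiprobable. Alleles are reflected into a contiguous
#' window of allowed repeat counts. Per-locus mutation rates are drawn from
#' a Gamma distribution with shape `rate_shape` and mean `mu`
#' (`rate_shape = Inf` disables rate heterogeneity). These conventions and
#' the default 40-state window follow common microsatellite simulator
#' practice; all values are user-overridable.
#'
#' @param mu Mean per-locus mutation rate (mutations/locus/generation).
#' @param p_geom Geometric step parameter in `[0, 1)`.
#' @param window_min Smallest allowed repeat count (> 0).
#' @param window_width Number of allowed repeat-count states (>= 2).
#' @param rate_shape Gamma shape for per-locus rate multipliers.
#' @param root_allele Repeat count of the most recent common ancestor;
#'   defaults to the window midpoint.
#' @return An object of class `gsm_model`.
#' @export
gsm_model <- function(mu = 5e-4, p_geom = 0.22, window_min = 11L,
                      window_width = 40L, rate_shape = 2,
                      root_allele = NULL) {
  stopifnot(mu > 0, p_geom >= 0, p_geom < 1, window_width >= 2,
            window_min >= 1)
  window_max <- window_min + window_width - 1L
  if (is.null(root_allele))
    root_allele <- as.integer(floor((window_min + window_max) / 2))
  stopifnot(root_allele >= window_min, root_allele <= window_max)
  structure(list(mu = mu, p_geom = p_geom,
                 window_min = as.integer(window_min),
                 window_max = as.integer(window_max),
                 rate_shape = rate_shape,
                 root_allele = as.integer(root_allele)),
            class = "gsm_model")
}

#' Simulate per-locus genealogies under a scenario
#'
#' Runs the structured coalescent: within each population, any lineage pair
#' coalesces at rate 1/(2Ne) per generation; divergence events move all
#' lineages of the derived population into the source; admixture events send
#' each lineage to source 1 with probability r, else source 2; size changes
#' switch Ne. Loci are independent given the demography.
#'
#' @param s A [scenario].
#' @param params Named parameter vector binding the scenario.
#' @param sample_config Named diploid sample sizes.
#' @param n_loci Number of unlinked loci.
#' @param seed Optional integer seed (`NULL` continues the RNG stream).
#' @return A `genealogy_set`: list of per-locus trees (parent pointers,
#'   node times in generations, leaf populations, TMRCA) plus the
#'   population index.
#' @export
simulate_genealogies <- function(s, params, sample_config, n_loci,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b <- bind_scenario(s, params, sample_config)
  trees <- lapply(seq_len(n_loci), function(i)
    .cpp_sim_tree(b$events, b$ne))
  structure(list(trees = trees, pop_index = b$pop_index,
                 populations = s$populations, ghosts = s$ghosts),
            class = "genealogy_set")
}

#' Drop GSM mutations onto simulated genealogies
#'
#' Mutation counts per branch are Poisson with the per-locus rate; each
#' mutation applies a geometric ± step, reflected into the allowed window.
#' The root allele is the model's `root_allele` (window midpoint by
#' default). Lineage pairs are grouped into diploid individuals per sampled
#' population, in sampling order.
#'
#' @param genealogies A `genealogy_set` from [simulate_genealogies()].
#' @param model A [gsm_model].
#' @param seed Optional integer seed.
#' @return A [genotype_dataset] over the sampled (non-ghost) populations.
#' @export
drop_mutations <- function(genealogies, model, seed = NULL) {
  stopifnot(inherits(genealogies, "genealogy_set"),
            inherits(model, "gsm_model"))
  if (!is.null(seed)) set.seed(seed)
  n_loci <- length(genealogies$trees)
  mus <- locus_rates(model, n_loci)
  allele_mat <- vapply(seq_len(n_loci), function(l) {
    tr <- genealogies$trees[[l]]
    .cpp_drop_mutations(tr$parent, tr$time, tr$n_leaves, mus[l],
                        model$p_geom, model$window_min, model$window_max,
                        model$root_allele)
  }, integer(genealogies$trees[[1L]]$n_leaves))
  leaf_pop <- genealogies$trees[[1L]]$leaf_pop
  sampled <- names(genealogies$pop_index)[
    sort(unique(leaf_pop))]
  genotypes <- list()
  for (p in sampled) {
    idx <- which(leaf_pop == genealogies$pop_index[[p]])
    n_dip <- length(idx) %/% 2L
    g <- array(0L, dim = c(n_dip, n_loci, 2L))
    g[, , 1L] <- allele_mat[idx[seq(1L, by = 2L, length.out = n_dip)], ,
                            drop = FALSE]
    g[, , 2L] <- allele_mat[idx[seq(2L, by = 2L, length.out = n_dip)], ,
                            drop = FALSE]
    genotypes[[p]] <- g
  }
  genotype_dataset(genotypes)
}

locus_rates <- function(model, n_loci) {
  if (is.finite(model$rate_shape))
    rgamma(n_loci, shape = model$rate_shape,
           rate = model$rate_shape / model$mu)
  else rep(model$mu, n_loci)
}

#' Simulate a complete microsatellite dataset under a scenario
#'
#' Composition of [simulate_genealogies()] and [drop_mutations()];
#' deterministic given the seed.
#'
#' @inheritParams simulate_genealogies
#' @param model A [gsm_model].
#' @return A [genotype_dataset].
#' @export
simulate_dataset <- function(s, params, sample_config, n_loci,
                             model = gsm_model(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gen <- simulate_genealogies(s, params, sample_config, n_loci)
  drop_mutations(gen, model)
}

#' Monte-Carlo TMRCA draws for a bound scenario
#'
#' Utility used by the simulator's distributional checks: repeatedly
#' simulates the genealogy and records the time to the most recent common
#' ancestor.
#'
#' @inheritParams simulate_genealogies
#' @param n_rep Number of replicate genealogies.
#' @return Numeric vector of TMRCA values (generations).
#' @export
sample_tmrca <- function(s, params, sample_config, n_rep, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b <- bind_scenario(s, params, sample_config)
  .cpp_sim_tmrca(b$events, b$ne, n_rep)
}
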