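# Shared fixtures and independent oracles. Heavy objects (reference
# tables, toy worlds) are built lazily and cached for the whole run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# hand-built two-population dataset: pop A mostly allele 10, pop B mostly 11
tiny_dataset <- function() {
  A <- array(0L, dim = c(4L, 1L, 2L))
  A[, 1L, 1L] <- c(10L, 10L, 10L, 10L)
  A[, 1L, 2L] <- c(10L, 10L, 11L, 11L)   # 6 copies of 10, 2 of 11
  B <- array(0L, dim = c(4L, 1L, 2L))
  B[, 1L, 1L] <- c(10L, 11L, 11L, 11L)
  B[, 1L, 2L] <- c(10L, 11L, 11L, 11L)   # 2 copies of 10, 6 of 11
  genotype_dataset(list(A = A, B = B), loci = "L1")
}

# a dataset where both populations are fixed for different alleles
fixed_diff_dataset <- function(n = 5L, n_loci = 3L) {
  A <- array(10L, dim = c(n, n_loci, 2L))
  B <- array(20L, dim = c(n, n_loci, 2L))
  genotype_dataset(list(A = A, B = B))
}

random_dataset <- function(n_pops = 2L, n = 6L, n_loci = 2L,
                           n_alleles = 4L, missing_rate = 0) {
  pops <- lapply(seq_len(n_pops), function(i) {
    g <- array(sample(10:(9L + n_alleles), n * n_loci * 2L,
                      replace = TRUE), dim = c(n, n_loci, 2L))
    if (missing_rate > 0) {
      drop <- runif(length(g)) < missing_rate
      g[drop] <- 0L
    }
    g
  })
  names(pops) <- paste0("P", seq_len(n_pops))
  genotype_dataset(pops)
}

# Independent Weir-Cockerham FST oracle via the nested analysis-of-variance
# route: per allele indicator, compute among-population / among-individual /
# within-individual mean squares and the method-of-moments variance
# components, then the multi-locus ratio. This is a different derivation
# from the closed-form components used by the package.
oracle_wc_fst <- function(dataset) {
  pops <- dataset$genotypes
  stopifnot(length(pops) == 2L)
  n_loci <- dim(pops[[1L]])[2L]
  num <- den <- 0
  for (l in seq_len(n_loci)) {
    mats <- lapply(pops, function(g) {
      m <- cbind(g[, l, 1L], g[, l, 2L])
      m[m[, 1L] != 0L & m[, 2L] != 0L, , drop = FALSE]
    })
    ni <- vapply(mats, nrow, integer(1L))
    if (any(ni < 1L)) next
    alleles <- sort(unique(unlist(mats)))
    if (length(alleles) < 2L) next
    r <- 2L; n_tot <- sum(ni)
    nc <- (n_tot - sum(ni^2) / n_tot) / (r - 1L)
    for (u in alleles) {
      y <- lapply(mats, function(m) (m == u) * 1)
      pbar_ij <- lapply(y, rowMeans)
      pbar_i <- vapply(pbar_ij, mean, numeric(1L))
      pbar <- sum(ni * pbar_i) / n_tot
      SSP <- 2 * sum(ni * (pbar_i - pbar)^2)
      SSI <- 2 * sum(unlist(mapply(function(pij, pi) (pij - pi)^2,
                                   pbar_ij, pbar_i, SIMPLIFY = FALSE)))
      SSG <- sum(unlist(mapply(function(yy, pij) (yy - pij)^2,
                               y, pbar_ij, SIMPLIFY = FALSE)))
      MSP <- SSP / (r - 1L)
      MSI <- SSI / (n_tot - r)
      MSG <- SSG / n_tot
      a <- (MSP - MSI) / (2 * nc)
      b <- (MSI - MSG) / 2
      cc <- MSG
      num <- num + a
      den <- den + a + b + cc
    }
  }
  num / den
}

# fast two-scenario worlds used by the model-choice tests ---------------

# two structurally identical single-population scenarios (indistinguishable)
identical_pair <- function(k = 2L) {
  lapply(seq_len(k), function(i)
    scenario(paste0("same", i), "A", list(A = "N_A"),
             ev("sample", "A", 0)))
}

identical_pair_prior <- function() {
  prior_spec(list(prior_param("N_A", "uniform", 500, 5000),
                  prior_param("mu", "loguniform", 1e-4, 1e-3)))
}

# same demography but disjoint mutation-rate priors (fully separable)
separable_pair <- function() {
  list(scenarios = identical_pair(2L),
       priors = list(
         prior_spec(list(prior_param("N_A", "uniform", 500, 5000),
                         prior_param("mu", "loguniform", 5e-4, 2e-3))),
         prior_spec(list(prior_param("N_A", "uniform", 500, 5000),
                         prior_param("mu", "loguniform", 5e-7, 2e-6)))))
}

# hard six-scenario set: three weakly diverged candidate sources for one
# target, singles plus pairwise admixtures with mid-range rates -- the
# "complex analysis" regime where engine differences are expected
hard_set <- function() {
  base <- scenario("base", c("S1", "S2", "S3"),
                   list(S1 = "N_S1", S2 = "N_S2", S3 = "N_S3"),
                   rbind(ev("sample", "S1", 0), ev("sample", "S2", 0),
                         ev("sample", "S3", 0),
                         ev("divergence", "S2", "t_anc", source1 = "S1"),
                         ev("divergence", "S3", "t_anc2",
                            source1 = "S1")))
  competing <- enumerate_target_scenarios(c("S1", "S2", "S3"), "T",
                                          base = base, t_intro = 60)
  prior <- prior_spec(list(
    prior_param("N_S1", "uniform", 1000, 8000),
    prior_param("N_S2", "uniform", 1000, 8000),
    prior_param("N_S3", "uniform", 1000, 8000),
    prior_param("N_T", "uniform", 500, 5000),
    prior_param("t_anc", "uniform", 400, 1500),
    prior_param("t_anc2", "uniform", 400, 1500),
    prior_param("db_T", "uniform", 1, 40),
    prior_param("Nb_T", "uniform", 2, 100),
    prior_param("r_T", "uniform", 0.2, 0.8),
    prior_param("mu", "loguniform", 1e-4, 1e-3)))
  list(scenarios = competing, prior = prior,
       sample_config = c(S1 = 10, S2 = 10, S3 = 10, T = 10))
}

# hard pair: single-source origin versus a balanced two-source admixture
# of weakly diverged sources -- deliberately difficult to tell apart
hard_pair <- function() {
  base <- scenario("base", c("S1", "S2"),
                   list(S1 = "N_S1", S2 = "N_S2"),
                   rbind(ev("sample", "S1", 0), ev("sample", "S2", 0),
                         ev("divergence", "S2", "t_anc", source1 = "S1")))
  competing <- enumerate_target_scenarios(c("S1", "S2"), "T", base = base,
                                          t_intro = 60)
  prior <- prior_spec(list(
    prior_param("N_S1", "uniform", 1000, 8000),
    prior_param("N_S2", "uniform", 1000, 8000),
    prior_param("N_T", "uniform", 500, 5000),
    prior_param("t_anc", "uniform", 400, 1200),
    prior_param("db_T", "uniform", 1, 40),
    prior_param("Nb_T", "uniform", 2, 100),
    prior_param("r_T", "uniform", 0.3, 0.7),
    prior_param("mu", "loguniform", 1e-4, 1e-3)))
  # keep the single-source-from-S1 and the admixture scenario
  list(scenarios = competing[c(1L, 3L)], prior = prior,
       sample_config = c(S1 = 15, S2 = 15, T = 15))
}

toy_small <- function() fixture("toy_small", function()
  make_toy_invasion("small", seed = 42L))

# estimation-subset reference table restricted to the true toy scenario
truth_estimation_table <- function() fixture("truth_est_table", function() {
  w <- toy_small()
  build_reference_table(list(w$scenario), w$prior, 1500L,
                        w$sample_config, w$n_loci, model = w$model,
                        stat_set = "estimation", triplets = w$triplets,
                        seed = 99L)
})
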