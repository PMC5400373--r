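# Toy invasion histories with known truth. These emulate the structure of
# a worldwide multi-site microsatellite survey of an invasive insect —
# several population samples of 15-44 diploid individuals, ~25 unlinked
# microsatellite loci, nested divergences, founding bottlenecks and
# admixture events — so that every pipeline stage can be exercised
# end-to-end without any external data. Effect sizes (divergence times,
# bottleneck severities, admixture rates) are deliberately large so that
# recovery is statistically comfortable at desk scale.

toy_small_config <- function() {
  list(
    # two natives N1/N2 (old split), invasive I1 founded from N1 with a
    # strong bottleneck, invasive I2 an admixture of N2 and I1 with a
    # weaker bottleneck; the focal analysis targets I2
    true_params = c(N_N1 = 5000, N_N2 = 5000, N_I1 = 2000, N_I2 = 2000,
                    t_anc = 2000,
                    db_I1 = 10, Nb_I1 = 10,      # severity 1.0 (strong)
                    db_I2 = 6, Nb_I2 = 60,       # severity 0.1 (weak)
                    r_I2 = 0.7, mu = 5e-4, p_geom = 0.2),
    first_records = c(I1 = 1990, I2 = 2005),
    sampling_year = 2015,
    sample_config = c(N1 = 20, N2 = 20, I1 = 20, I2 = 20),
    n_loci = 10L)
}

toy_base_scenario <- function(t_I1) {
  scenario("base",
           populations = c("N1", "N2", "I1"),
           ne = list(N1 = "N_N1", N2 = "N_N2", I1 = "N_I1"),
           events = rbind(
             ev("sample", "N1", 0), ev("sample", "N2", 0),
             ev("sample", "I1", 0),
             ev("size_change", "I1", paste0(t_I1, " - db_I1"),
                value = "Nb_I1"),
             ev("divergence", "I1", t_I1, source1 = "N1"),
             ev("divergence", "N2", "t_anc", source1 = "N1")))
}

toy_small_prior <- function(t_I1, t_I2, set = "set1") {
  mk <- function(name, min, max, dist = "uniform") {
    if (set == "set2" && dist == "uniform")
      prior_param(name, "truncnorm", min, max)
    else prior_param(name, dist, min, max)
  }
  prior_spec(list(
    mk("N_N1", 1000, 10000), mk("N_N2", 1000, 10000),
    mk("N_I1", 500, 5000), mk("N_I2", 500, 5000),
    mk("t_anc", 500, 5000),
    mk("db_I1", 1, min(60, t_I1 - 1)), mk("Nb_I1", 2, 100),
    mk("db_I2", 1, min(60, t_I2 - 1)), mk("Nb_I2", 2, 100),
    mk("r_I2", 0.01, 0.99),
    mk("mu", 1e-4, 1e-3, "loguniform"),
    mk("p_geom", 0, 0.5)),
    constraints = "t_anc > 500",
    set = set)
}

#' Generate a toy invasion world with known truth
#'
#' `"small"` builds 4 populations (a native pair plus two invasives, the
#' second admixed), 10 loci and 20 diploids per sample — sized for fast
#' tests. `"paper_like"` builds 8 populations, 25 loci and sample sizes
#' drawn in 15-44, with the canonical motifs of a worldwide invasion:
#' an old native split, a strongly bottlenecked island introduction, an
#' admixed continental introduction (native x island), serial
#' intra-continental colonization, and a second admixture between invasive
#' groups.
#'
#' @param profile `"small"` or `"paper_like"`.
#' @param seed Integer seed; the whole world is reproducible from it.
#' @return An object of class `toy_world`: true `scenario` and parameters,
#'   the "observed" [genotype_dataset], first-record dates, the enumerated
#'   competing scenario set containing the truth (`$competing`,
#'   `$truth_index`), a [prior_spec], sampling configuration and the
#'   mutation model used for the observed data.
#' @export
make_toy_invasion <- function(profile = c("small", "paper_like"),
                              seed = 1L) {
  profile <- match.arg(profile)
  if (profile == "small") make_toy_small(seed) else make_toy_paper(seed)
}

make_toy_small <- function(seed) {
  cfg <- toy_small_config()
  t_I1 <- first_record_to_generations(cfg$first_records[["I1"]],
                                      cfg$sampling_year)
  t_I2 <- first_record_to_generations(cfg$first_records[["I2"]],
                                      cfg$sampling_year)
  base <- toy_base_scenario(t_I1)
  competing <- enumerate_target_scenarios(c("N2", "I1"), "I2",
                                          base = base, t_intro = t_I2)
  truth_index <- which(vapply(competing, `[[`, character(1L), "name") ==
                         "I2-admix-N2-I1")
  truth <- competing[[truth_index]]
  model <- gsm_model(mu = cfg$true_params[["mu"]],
                     p_geom = cfg$true_params[["p_geom"]])
  dataset <- simulate_dataset(truth, cfg$true_params, cfg$sample_config,
                              cfg$n_loci, model = model, seed = seed)
  structure(list(profile = "small",
                 scenario = truth, params = cfg$true_params,
                 dataset = dataset,
                 first_records = cfg$first_records,
                 sampling_year = cfg$sampling_year,
                 competing = competing, truth_index = truth_index,
                 prior = toy_small_prior(t_I1, t_I2),
                 sample_config = cfg$sample_config,
                 n_loci = cfg$n_loci, model = model,
                 triplets = list(c("I2", "N2", "I1")),
                 seed = seed),
            class = "toy_world")
}

make_toy_paper <- function(seed) {
  set.seed(seed)
  pops <- c("AS1", "AS2", "HAW", "WUS", "EUS", "SEU", "NEU", "BRA")
  sample_config <- setNames(sample(15:44, length(pops), replace = TRUE),
                            pops)
  first <- c(HAW = 1980, WUS = 2008, EUS = 2010, SEU = 2008, NEU = 2011,
             BRA = 2013)
  t <- vapply(first, first_record_to_generations,
              numeric(1L), sampling_year = 2015)
  ne <- as.list(setNames(paste0("N_", pops), pops))
  bn <- function(p, t_intro) rbind(
    ev("size_change", p, paste0(t_intro, " - db_", p),
       value = paste0("Nb_", p)))
  events <- rbind(
    do.call(rbind, lapply(pops, function(p) ev("sample", p, 0))),
    bn("HAW", t[["HAW"]]),
    ev("divergence", "HAW", t[["HAW"]], source1 = "AS1"),
    bn("WUS", t[["WUS"]]),
    ev("admixture", "WUS", t[["WUS"]], source1 = "AS2", source2 = "HAW",
       value = "r_WUS"),
    bn("EUS", t[["EUS"]]),
    ev("divergence", "EUS", t[["EUS"]], source1 = "WUS"),
    bn("SEU", t[["SEU"]]),
    ev("divergence", "SEU", t[["SEU"]], source1 = "AS2"),
    bn("NEU", t[["NEU"]]),
    ev("admixture", "NEU", t[["NEU"]], source1 = "SEU", source2 = "EUS",
       value = "r_NEU"),
    bn("BRA", t[["BRA"]]),
    ev("admixture", "BRA", t[["BRA"]], source1 = "WUS", source2 = "EUS",
       value = "r_BRA"),
    ev("divergence", "AS2", "t_anc", source1 = "AS1"))
  truth <- scenario("world-truth", pops, ne, events)
  true_params <- c(
    setNames(c(8000, 8000, 3000, 3000, 3000, 3000, 3000, 3000),
             paste0("N_", pops)),
    t_anc = 3000,
    db_HAW = 30, Nb_HAW = 60,    # severity 0.5 (strong)
    db_WUS = 10, Nb_WUS = 70,    # ~0.14 (moderate)
    db_EUS = 5, Nb_EUS = 80,     # ~0.06 (weak)
    db_SEU = 12, Nb_SEU = 65,    # ~0.18 (moderate)
    db_NEU = 8, Nb_NEU = 45,     # ~0.18
    db_BRA = 6, Nb_BRA = 50,     # 0.12
    r_WUS = 0.75, r_NEU = 0.3, r_BRA = 0.5,
    mu = 5e-4, p_geom = 0.2)
  model <- gsm_model(mu = 5e-4, p_geom = 0.2)
  dataset <- simulate_dataset(truth, true_params, sample_config, 25L,
                              model = model, seed = seed + 1L)
  # competing set for the most recent introduction (Brazil)
  base <- truth
  base$populations <- setdiff(pops, "BRA")
  base$ne[["BRA"]] <- NULL
  base$events <- base$events[base$events$pop != "BRA", ]
  competing <- enumerate_target_scenarios(c("WUS", "EUS", "NEU"), "BRA",
                                          base = base,
                                          t_intro = t[["BRA"]])
  truth_index <- which(vapply(competing, `[[`, character(1L), "name") ==
                         "BRA-admix-WUS-EUS")
  prior_params <- c(
    lapply(paste0("N_", pops), prior_param, dist = "uniform",
           min = 1000, max = 12000),
    list(prior_param("t_anc", "uniform", 1000, 8000)),
    unlist(lapply(c("HAW", "WUS", "EUS", "SEU", "NEU", "BRA"),
                  function(p) list(
                    prior_param(paste0("db_", p), "uniform", 1,
                                max(2, min(60, t[[p]] - 1))),
                    prior_param(paste0("Nb_", p), "uniform", 2, 200))),
           recursive = FALSE),
    lapply(c("r_WUS", "r_NEU", "r_BRA"), prior_param, dist = "uniform",
           min = 0.01, max = 0.99),
    list(prior_param("mu", "loguniform", 1e-4, 1e-3),
         prior_param("p_geom", "uniform", 0, 0.5)))
  structure(list(profile = "paper_like",
                 scenario = truth, params = true_params, dataset = dataset,
                 first_records = first, sampling_year = 2015,
                 competing = competing, truth_index = truth_index,
                 prior = prior_spec(prior_params),
                 sample_config = sample_config, n_loci = 25L,
                 model = model,
                 triplets = list(c("WUS", "AS2", "HAW"),
                                 c("NEU", "SEU", "EUS"),
                                 c("BRA", "WUS", "EUS")),
                 seed = seed),
            class = "toy_world")
}

#' @export
print.toy_world <- function(x, ...) {
  cat("toy_world (", x$profile, "): ",
      length(x$sample_config), " populations, ", x$n_loci, " loci, ",
      length(x$competing), " competing scenarios (truth: ",
      x$competing[[x$truth_index]]$name, ")\n", sep = "")
  invisible(x)
}

#' Run the full pipeline once on a toy world
#'
#' Builds a reference table for the competing set, runs random-forest model
#' choice on the observed dataset, estimates the admixture rate and
#' bottleneck severity under the winning scenario, and performs a reduced
#' posterior predictive check — a smoke test of every stage with known
#' truth.
#'
#' @param world A `toy_world`.
#' @param budget Simulated datasets per scenario (>= 500 recommended).
#' @param n_trees Forest size.
#' @param n_ppc Posterior predictive simulations.
#' @param seed Integer seed.
#' @return List with the stage outputs: `truth_won`, `choice`
#'   (model-choice result), `posterior`, `ppc` (NULL when the winning
#'   scenario lacks the estimated parameters), and timing.
#' @export
end_to_end_smoke <- function(world, budget = 500L, n_trees = 200L,
                             n_ppc = 200L, seed = 1L) {
  stopifnot(inherits(world, "toy_world"))
  t0 <- Sys.time()
  obs <- compute_stats(world$dataset, "full")
  tab <- build_reference_table(world$competing, world$prior, budget,
                               world$sample_config, world$n_loci,
                               model = world$model, stat_set = "full",
                               seed = seed)
  choice <- rf_model_choice(tab, obs, n_trees = n_trees, seed = seed)
  winner <- choice$best
  pops <- names(world$dataset$genotypes)
  est_names <- estimation_subset_names(pops, world$triplets)
  sub <- subset_stats(subset_scenario(tab, winner), est_names)
  target <- world$competing[[world$truth_index]]$populations
  target <- target[length(target)]
  est_pars <- intersect(c(paste0("r_", target), paste0("db_", target),
                          paste0("Nb_", target)), names(sub$params))
  derived <- setNames(paste0("db_", target, " / Nb_", target),
                      paste0("severity_", target))
  post <- local_linear_estimate(sub, obs[est_names],
                                acceptance_fraction = 0.25,
                                parameters = c(est_pars, names(derived)),
                                derived = derived)
  ppc <- NULL
  if (identical(winner, world$competing[[world$truth_index]]$name)) {
    test_set <- test_statistic_complement(pops, est_names)
    win_sc <- world$competing[[which(vapply(world$competing, `[[`,
                                            character(1L), "name") ==
                                       winner)]]
    ppc <- posterior_predictive_check(win_sc, post, world$dataset,
                                      test_set, world$sample_config,
                                      world$n_loci, model = world$model,
                                      n_ppc = n_ppc, seed = seed)
  }
  list(truth_won = identical(choice$best,
                             world$competing[[world$truth_index]]$name),
       choice = choice, posterior = post, ppc = ppc,
       elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
}
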