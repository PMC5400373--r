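# a cheap fitted posterior for the toy world, shared across checks
toy_posterior <- function() fixture("toy_posterior", function() {
  w <- toy_small()
  tab <- truth_estimation_table()
  obs <- compute_stats(w$dataset, "estimation", w$triplets)
  local_linear_estimate(tab, obs, acceptance_fraction = 0.1,
                        parameters = c("r_I2", "db_I2", "Nb_I2"))
})

test_that("ppp-values follow the folded tail-area rule with tie splitting", {
  w <- toy_small()
  post <- toy_posterior()
  pops <- names(w$dataset$genotypes)
  est <- estimation_subset_names(pops, w$triplets)
  test_set <- test_statistic_complement(pops, est)
  rep <- posterior_predictive_check(w$scenario, post, w$dataset, test_set,
                                    w$sample_config, w$n_loci,
                                    model = w$model, n_ppc = 120L,
                                    seed = 3L)
  expect_true(all(rep$table$ppp >= 1 / 121 - 1e-12))
  expect_true(all(rep$table$ppp <= 0.5 + 1e-12))
  expect_equal(nrow(rep$table), length(test_set))
  # FDR flags are monotone in the raw ppp
  o <- order(rep$table$ppp)
  flags <- rep$table$fdr_significant[o]
  expect_true(all(diff(as.integer(flags)) <= 0))
})

test_that("estimation/test overlap is an error, not a warning", {
  w <- toy_small()
  post <- toy_posterior()
  expect_error(
    posterior_predictive_check(w$scenario, post, w$dataset,
                               post$stats_used[1:3], w$sample_config,
                               w$n_loci, model = w$model, n_ppc = 100L),
    "overlap")
})

test_that("hand-built predictive distributions give the textbook ppp values", {
  # direct check of the tail-area computation through a minimal stub:
  # observed at the simulated median -> 0.5; below all simulations ->
  # floored at 1/(n+1)
  sims <- matrix(1:101, ncol = 1, dimnames = list(NULL, "q"))
  p_mid <- (sum(sims < 51) + 0.5 * sum(sims == 51)) / 101
  expect_equal(min(p_mid, 1 - p_mid), 0.5)
  p_low <- (sum(sims < -5) + 0.5 * sum(sims == -5)) / 101
  expect_equal(max(min(p_low, 1 - p_low), 1 / (101 + 1)), 1 / 102)
})

test_that("PCA projection centers the cloud and ranks depth sensibly", {
  set.seed(9)
  sims <- matrix(rnorm(400 * 6), 400, 6,
                 dimnames = list(NULL, paste0("s", 1:6)))
  obs_center <- colMeans(sims)
  chk <- pca_projection_check(sims, obs_center)
  expect_lt(sum(abs(chk$obs_coord)), 0.5)
  expect_gt(chk$depth_rank, 0.5)
  # a grossly displaced observed point lands in the extreme tail
  obs_far <- obs_center + 10
  chk_far <- pca_projection_check(sims, obs_far)
  expect_lt(chk_far$depth_rank, 0.01)
  expect_error(pca_projection_check(sims[1:2, ], obs_center), ">= 3")
})

test_that("an observed dataset from the fitted model is not flagged; gross misfit is", {
  w <- toy_small()
  post <- toy_posterior()
  pops <- names(w$dataset$genotypes)
  est <- estimation_subset_names(pops, w$triplets)
  test_set <- test_statistic_complement(pops, est)
  rep_ok <- posterior_predictive_check(w$scenario, post, w$dataset,
                                       test_set, w$sample_config,
                                       w$n_loci, model = w$model,
                                       n_ppc = 150L, seed = 11L)
  expect_equal(rep_ok$n_flagged, 0L)
  # same scenario but tenfold mutation rate: strong, detectable misfit
  wrong_model <- gsm_model(mu = w$model$mu * 10, p_geom = 0.2)
  bad_obs <- simulate_dataset(w$scenario, w$params, w$sample_config,
                              w$n_loci, model = wrong_model, seed = 13L)
  rep_bad <- posterior_predictive_check(w$scenario, post, bad_obs,
                                        test_set, w$sample_config,
                                        w$n_loci, model = w$model,
                                        n_ppc = 150L, seed = 11L)
  expect_gt(rep_bad$n_flagged, 0L)
  # and its statistic cloud places the bad observation in the tail
  chk <- pca_projection_check(rep_bad$sims, rep_bad$observed)
  expect_lt(chk$depth_rank, 0.05)
})
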