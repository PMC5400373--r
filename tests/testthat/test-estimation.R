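test_that("severity classification follows the printed cutpoints", {
  expect_equal(classify_severity(0.500), "strong")
  expect_equal(classify_severity(0.067), "weak")
  expect_equal(classify_severity(0.179), "moderate")
  expect_equal(classify_severity(0), "weak")
  expect_warning(out <- classify_severity(0.25), "unclassified")
  expect_equal(out, "unclassified")
  expect_warning(classify_severity(0.22), "unclassified")
  expect_error(classify_severity(-1), "non-negative")
})

test_that("uninformative statistics return the prior; informative ones concentrate", {
  w <- toy_small()
  tab <- truth_estimation_table()
  obs_d <- simulate_dataset(w$scenario, w$params, w$sample_config,
                            w$n_loci, model = w$model, seed = 123L)
  obs <- compute_stats(obs_d, "estimation", w$triplets)
  # constant statistic columns carry no information: the posterior of r
  # must reproduce its uniform prior within Monte-Carlo error
  flat <- tab
  flat$stats <- matrix(1, nrow(tab$stats), 3L,
                       dimnames = list(NULL, c("c1", "c2", "c3")))
  post_flat <- local_linear_estimate(flat, c(c1 = 1, c2 = 1, c3 = 1),
                                     acceptance_fraction = 1,
                                     parameters = "r_I2")
  s <- post_flat$summaries
  expect_lt(abs(s$mean - 0.5), 0.03)        # U(0.01, 0.99) mean
  expect_lt(abs(s$q5 - 0.059), 0.04)
  expect_lt(abs(s$q95 - 0.941), 0.04)
  # the genuine statistics shrink the interquantile range below the prior's
  post <- local_linear_estimate(tab, obs, acceptance_fraction = 0.2,
                                parameters = "r_I2")
  expect_lt(post$summaries$q95 - post$summaries$q5, s$q95 - s$q5)
  # all adjusted draws respect the prior bounds (logit-transform contract)
  expect_true(all(post$draws[, "r_I2"] > 0.01 &
                    post$draws[, "r_I2"] < 0.99))
  expect_true(with(post$summaries, q5 <= median & median <= q95))
})

test_that("the linear-Gaussian toy matches the analytic conjugate posterior", {
  # theta ~ U(-10, 10), one statistic s = theta + N(0, 1). For observed
  # s0 well inside the support, the posterior is ~ N(s0, 1). The local
  # linear regression with Epanechnikov weights must land close to that.
  set.seed(55)
  n <- 20000
  theta <- runif(n, -10, 10)
  stat <- theta + rnorm(n)
  tab <- structure(list(
    scenario = factor(rep("m", n)),
    params = data.frame(theta = theta),
    stats = matrix(stat, ncol = 1L, dimnames = list(NULL, "s")),
    scenario_names = "m",
    prior = list(prior_spec(list(prior_param("theta", "uniform",
                                             -10, 10)))),
    stat_set = "estimation", triplets = list(),
    sample_config = c(A = 1), n_loci = 1L, model = gsm_model(),
    seed = 1L),
    class = "reference_table")
  s0 <- 2.3
  post <- local_linear_estimate(tab, c(s = s0),
                                acceptance_fraction = 0.05,
                                parameters = "theta")
  mc_se <- 1 / sqrt(0.05 * n)
  expect_lt(abs(post$summaries$mean - s0), 3 * mc_se + 0.05)
  expect_lt(abs(post$summaries$median - s0), 3 * mc_se + 0.05)
  # 90% interval close to +/- 1.645
  expect_lt(abs((post$summaries$q95 - post$summaries$q5) - 2 * 1.645),
            0.35)
})

test_that("admixture rate and severity are recovered from synthetic truth", {
  w <- toy_small()
  tab <- truth_estimation_table()
  rec <- recover_parameters(tab, w$scenario, w$params,
                            parameters = c("r_I2", "severity_I2"),
                            derived = c(severity_I2 = "db_I2 / Nb_I2"),
                            n_replicates = 8L,
                            acceptance_fraction = 0.1, seed = 5L)
  r <- rec[rec$parameter == "r_I2", ]
  expect_gte(mean(abs(r$median - 0.7) <= 0.15), 0.75)
  expect_gte(mean(r$covered), 0.6)
})

test_that("bottleneck severities two orders of magnitude apart are ordered", {
  w <- toy_small()
  tab <- truth_estimation_table()
  # truth: severity_I1 = 10/10 = 1.0, severity_I2 = 6/60 = 0.1
  rec <- recover_parameters(tab, w$scenario, w$params,
                            parameters = c("severity_I1", "severity_I2"),
                            derived = c(severity_I1 = "db_I1 / Nb_I1",
                                        severity_I2 = "db_I2 / Nb_I2"),
                            n_replicates = 8L,
                            acceptance_fraction = 0.1, seed = 6L)
  med <- tapply(rec$median, list(rec$replicate, rec$parameter), mean)
  ordered <- med[, "severity_I1"] > med[, "severity_I2"]
  expect_gte(mean(ordered), 0.9)
})
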