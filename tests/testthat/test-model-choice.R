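# unit-level properties of the two model-choice engines; the heavier
# symmetry/separability suites live in the acceptance tests

sep_table <- function() fixture("sep_table", function() {
  sp <- separable_pair()
  build_reference_table(sp$scenarios, sp$priors, 150L, c(A = 15),
                        n_loci = 8L, seed = 21L)
})

test_that("discriminant augmentation adds K-1 axes and projects consistently", {
  tab <- sep_table()
  aug <- append_lda_axes(tab)
  expect_equal(ncol(aug$stats), ncol(tab$stats) + 1L)  # K = 2
  # a table row used as the observed vector projects to its own axis value
  obs <- tab$stats[7L, ]
  proj <- project_observed(aug, obs)
  expect_equal(unname(proj[["LD1"]]), unname(aug$stats[7L, "LD1"]),
               tolerance = 1e-8)
  # three scenarios give two axes
  hp <- hard_pair()
  sc3 <- enumerate_target_scenarios(c("S1", "S2"), "T", t_intro = 60)
  tab3 <- build_reference_table(sc3, hp$prior, 40L, hp$sample_config,
                                n_loci = 4L, seed = 22L)
  expect_length(tab3$scenario_names, 3L)
  aug3 <- append_lda_axes(tab3)
  expect_equal(ncol(aug3$stats), ncol(tab3$stats) + 2L)
})

test_that("classification votes are conserved and reproducible", {
  tab <- sep_table()
  obs <- tab$stats[1L, ]
  res <- rf_model_choice(tab, obs, n_trees = 500L, seed = 3L)
  expect_equal(sum(res$votes), 500L)
  expect_true(res$posterior_probability >= 0 &&
                res$posterior_probability <= 1)
  res2 <- rf_model_choice(tab, obs, n_trees = 500L, seed = 3L)
  expect_identical(res$votes, res2$votes)
  expect_equal(res$posterior_probability, res2$posterior_probability)
})

test_that("replicate forests report mean and spread of their summaries", {
  tab <- sep_table()
  res <- rf_model_choice(tab, tab$stats[5L, ], n_trees = 200L, seed = 4L,
                         n_replicates = 3L)
  expect_equal(dim(res$replicates$votes), c(3L, 2L))
  expect_false(is.na(res$posterior_sd))
  expect_false(is.na(res$prior_error_sd))
})

test_that("a separable pair is classified nearly perfectly by the forest", {
  sp <- separable_pair()
  tab <- sep_table()
  # held-out observed dataset from scenario 1's prior core
  obs_d <- simulate_dataset(sp$scenarios[[1L]], c(N_A = 2000),
                            c(A = 15), 8L,
                            model = gsm_model(mu = 1e-3), seed = 31L)
  obs <- compute_stats(obs_d, "full")
  res <- rf_model_choice(tab, obs, n_trees = 500L, seed = 5L)
  expect_equal(res$best, "same1")
  expect_gt(res$vote_share[[1L]], 0.9)
  expect_lt(prior_error_rate_rf(tab, n_trees = 300L, seed = 6L), 0.05)
})

test_that("LDA rejection keeps the exact tolerance fraction and a simplex", {
  tab <- sep_table()
  obs <- tab$stats[10L, ]
  # on a fully separable table the far scenario may vanish from the
  # accepted set; that warning is the documented behavior
  res <- suppressWarnings(lda_model_choice(tab, obs, tolerance = 0.1,
                                           seed = 7L))
  expect_equal(res$n_accepted, ceiling(0.1 * nrow(tab$stats)))
  expect_equal(sum(res$probabilities), 1, tolerance = 1e-9)
  expect_true(all(res$probabilities >= 0))
  # 30,000-row bookkeeping contract without simulating 30,000 rows:
  # acceptance count is ceiling(tolerance * rows)
  expect_equal(ceiling(0.01 * 30000), 300)
})

test_that("LDA assigns a separable observed dataset to its scenario", {
  sp <- separable_pair()
  tab <- sep_table()
  obs_d <- simulate_dataset(sp$scenarios[[2L]], c(N_A = 2000),
                            c(A = 15), 8L,
                            model = gsm_model(mu = 1e-6), seed = 32L)
  obs <- compute_stats(obs_d, "full")
  res <- suppressWarnings(lda_model_choice(tab, obs, tolerance = 0.2,
                                           seed = 8L))
  expect_equal(res$best, "same2")
  expect_gt(res$probabilities[["same2"]], 0.9)
})

test_that("a single pseudo-observed dataset gives an error rate of exactly 0 or 1", {
  tab <- sep_table()
  e <- prior_error_rate_lda(tab, tolerance = 0.1, n_pseudo = 1L, seed = 9L)
  expect_true(e %in% c(0, 1))
})

test_that("observed vectors missing table statistics are rejected", {
  tab <- sep_table()
  obs <- tab$stats[1L, 1:3]
  expect_error(rf_model_choice(tab, obs, n_trees = 50L), "missing")
})
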