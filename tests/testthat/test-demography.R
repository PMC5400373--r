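test_that("scenario enumeration follows the single-source-or-pairwise-admixture rule", {
  # printed designs: 2 sources -> 3, 3 -> 6, 4 -> 10, 6 -> 21 scenarios
  for (k in c(2L, 3L, 4L, 6L)) {
    sc <- enumerate_target_scenarios(paste0("S", seq_len(k)), "T",
                                     t_intro = 60)
    expect_length(sc, k + choose(k, 2L))
  }
  expect_length(enumerate_target_scenarios("S1", "T", t_intro = 60), 1L)
  # brute force: count all non-empty source subsets of size <= 2
  for (k in 1:8) {
    n_brute <- ncol(combn(k, 1)) + if (k >= 2) ncol(combn(k, 2)) else 0L
    expect_length(enumerate_target_scenarios(paste0("S", 1:k), "T",
                                             t_intro = 10),
                  n_brute)
  }
  expect_error(enumerate_target_scenarios(c("A", "A"), "T"), "duplicate")
  expect_error(enumerate_target_scenarios(c("A", "B"), "A"),
               "must not be among")
})

test_that("enumerated scenarios are deterministically ordered and well formed", {
  sc <- enumerate_target_scenarios(c("X", "Y", "Z"), "T", t_intro = 120)
  expect_equal(vapply(sc, `[[`, character(1), "name"),
               c("T-from-X", "T-from-Y", "T-from-Z",
                 "T-admix-X-Y", "T-admix-X-Z", "T-admix-Y-Z"))
  pars <- c(N_X = 1000, N_Y = 1000, N_Z = 1000, N_T = 500, t_anc = 500,
            db_T = 10, Nb_T = 5, r_T = 0.5)
  for (s in sc)
    expect_length(validate_scenario(s, pars, c(X = 5, Y = 5, Z = 5,
                                               T = 5)), 0L)
})

test_that("first-record dates convert to generations at 12 per year", {
  expect_equal(first_record_to_generations(2008, 2013, 12), 60)
  expect_equal(first_record_to_generations(2013, 2013, 12), 0)
  expect_equal(first_record_to_generations(1980, 2013, 12), 396)
  expect_equal(first_record_to_generations(2010, 2015), 60)  # default 12
  expect_error(first_record_to_generations(2014, 2013), "predates")
})

test_that("prior draws respect bounds, constraints and seeding", {
  pr <- prior_spec(list(prior_param("a", "uniform", 10, 100),
                        prior_param("b", "loguniform", 1e-4, 1e-2),
                        prior_param("t_intro", "uniform", 10, 50),
                        prior_param("t_ancestral", "uniform", 20, 500)),
                   constraints = "t_ancestral > t_intro")
  set.seed(1)
  draws <- replicate(2000, draw_parameters(pr))
  expect_true(all(draws["a", ] >= 10 & draws["a", ] <= 100))
  expect_true(all(draws["b", ] >= 1e-4 & draws["b", ] <= 1e-2))
  expect_true(all(draws["t_ancestral", ] > draws["t_intro", ]))
  expect_identical(draw_parameters(pr, seed = 7),
                   draw_parameters(pr, seed = 7))
  # law of large numbers for the uniform mean
  pr01 <- prior_spec(list(prior_param("u", "uniform", 0, 1)))
  set.seed(2)
  u <- replicate(1e5, draw_parameters(pr01)[["u"]])
  expect_lt(abs(mean(u) - 0.5), 0.01)
  # unsatisfiable constraints fail loudly
  bad <- prior_spec(list(prior_param("x", "uniform", 0, 1)),
                    constraints = "x > 2")
  expect_error(draw_parameters(bad, seed = 1, max_tries = 50),
               "unsatisfiable")
})

test_that("truncated-normal priors stay inside their bounds", {
  pr <- prior_spec(list(prior_param("s", "truncnorm", 2, 10)), set = "set2")
  set.seed(4)
  x <- replicate(2000, draw_parameters(pr)[["s"]])
  expect_true(all(x >= 2 & x <= 10))
  # peaked: more mass near mid-range than a uniform would give
  expect_gt(mean(x > 4 & x < 8), 0.55)
})

test_that("the scenario validator reports structural defects", {
  pars <- c(N_A = 1000, N_B = 1000, N_C = 500)
  # lineages entering a population after it merged away
  bad <- scenario("bad", c("A", "B", "C"),
                  list(A = "N_A", B = "N_B", C = "N_C"),
                  rbind(ev("sample", "A", 0), ev("sample", "B", 0),
                        ev("sample", "C", 0),
                        ev("divergence", "B", 50, source1 = "A"),
                        ev("divergence", "C", 100, source1 = "B")))
  expect_match(validate_scenario(bad, pars, c(A = 2, B = 2, C = 2)),
               "merged away", all = FALSE)
  # a ghost split from the ancestral population with no size change is fine
  ghost <- scenario("ghost", c("A", "G", "T"),
                    list(A = "N_A", G = "N_A", T = "N_C"),
                    rbind(ev("sample", "A", 0), ev("sample", "T", 0),
                          ev("divergence", "T", 60, source1 = "G"),
                          ev("divergence", "G", 500, source1 = "A")),
                    ghosts = "G")
  expect_length(validate_scenario(ghost, pars,
                                  c(A = 5, T = 5)), 0L)
  # missing sample event
  nosample <- scenario("nos", "A", list(A = "N_A"),
                       ev("size_change", "A", 10, value = 100))
  expect_match(validate_scenario(nosample), "sample events", all = FALSE)
})
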