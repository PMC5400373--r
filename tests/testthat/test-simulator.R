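test_that("pairwise TMRCA matches the single-population coalescent expectation", {
  N <- 1000
  s <- scenario("one", "A", list(A = N), ev("sample", "A", 0, value = 1))
  set.seed(101)
  tm <- sample_tmrca(s, c(unused = 1), c(A = 1), n_rep = 20000)
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 2 * N), 2 * se + 1e-9)
})

test_that("a sample of one diploid yields two-leaf trees", {
  s <- scenario("one", "A", list(A = 500), ev("sample", "A", 0, value = 1))
  g <- simulate_genealogies(s, c(u = 1), c(A = 1), n_loci = 5, seed = 2)
  for (tr in g$trees) {
    expect_equal(tr$n_leaves, 2L)
    expect_length(tr$parent, 3L)
  }
})

test_that("degenerate admixture (r = 1) behaves like a divergence", {
  mk <- function(type) {
    evs <- rbind(ev("sample", "C", 0, value = 5),
                 ev("sample", "A", 0, value = 5),
                 ev("divergence", "B", 2000, source1 = "A"))
    evs <- rbind(evs, if (type == "admix")
      ev("admixture", "C", 100, source1 = "A", source2 = "B", value = 1)
      else ev("divergence", "C", 100, source1 = "A"))
    scenario(type, c("A", "B", "C"),
             list(A = 1000, B = 1000, C = 1000), evs)
  }
  t1 <- sample_tmrca(mk("admix"), c(u = 1), NULL, 8000, seed = 5)
  t2 <- sample_tmrca(mk("div"), c(u = 1), NULL, 8000, seed = 6)
  se <- sqrt(var(t1) / length(t1) + var(t2) / length(t2))
  expect_lt(abs(mean(t1) - mean(t2)), 3 * se)
})

test_that("disconnected populations with no merge event fail loudly", {
  s <- scenario("disc", c("A", "B"), list(A = 500, B = 500),
                rbind(ev("sample", "A", 0, value = 2),
                      ev("sample", "B", 0, value = 2)))
  expect_error(simulate_genealogies(s, c(u = 1), c(A = 2, B = 2), 1,
                                    seed = 1),
               "no common ancestral population")
})

test_that("zero mutation rate leaves every population monomorphic", {
  s <- scenario("one", "A", list(A = 500), ev("sample", "A", 0, value = 10))
  g <- simulate_genealogies(s, c(u = 1), c(A = 10), n_loci = 4, seed = 3)
  m <- gsm_model(mu = 1e-12, p_geom = 0, rate_shape = Inf)
  m$mu <- 0                                # exactly mutation-free
  d <- drop_mutations(g, m, seed = 4)
  for (l in seq_len(4))
    expect_equal(length(unique(as.vector(d$genotypes$A[, l, ]))), 1L)
})

test_that("strict stepwise equilibrium diversity matches the closed form", {
  # expected gene diversity at mutation-drift equilibrium under the strict
  # stepwise model: 1 - 1/sqrt(1 + 8 N mu)
  N <- 500; mu <- 5e-4
  s <- scenario("eq", "A", list(A = N), ev("sample", "A", 0, value = 25))
  m <- gsm_model(mu = mu, p_geom = 0, window_min = 1, window_width = 200,
                 rate_shape = Inf)
  set.seed(21)
  hs <- replicate(250, {
    d <- simulate_dataset(s, c(u = 1), c(A = 25), n_loci = 1, model = m)
    one_sample_stats(d, "A")[["HET"]]
  })
  expected <- 1 - 1 / sqrt(1 + 8 * N * mu)
  expect_lt(abs(mean(hs) - expected), 3 * sd(hs) / sqrt(length(hs)))
})

test_that("mean squared allele-size distance grows with divergence time", {
  ts <- c(200, 1000, 4000, 12000)
  m <- gsm_model(mu = 5e-4, p_geom = 0, window_min = 1,
                 window_width = 400, rate_shape = Inf)
  set.seed(31)
  dm2 <- vapply(ts, function(t) {
    s <- scenario("div", c("A", "B"), list(A = 500, B = 500),
                  rbind(ev("sample", "A", 0), ev("sample", "B", 0),
                        ev("divergence", "B", t, source1 = "A")))
    mean(replicate(60, {
      d <- simulate_dataset(s, c(u = 1), c(A = 10, B = 10), n_loci = 5,
                            model = m)
      two_sample_stats(d, "A", "B")[["DM2"]]
    }))
  }, numeric(1))
  expect_gt(cor(ts, dm2, method = "spearman"), 0)
  expect_true(all(diff(dm2) > 0))
})

test_that("alleles stay inside the allowed window and seeds reproduce datasets", {
  w <- toy_small()
  d1 <- simulate_dataset(w$scenario, w$params, w$sample_config, w$n_loci,
                         model = w$model, seed = 77)
  d2 <- simulate_dataset(w$scenario, w$params, w$sample_config, w$n_loci,
                         model = w$model, seed = 77)
  expect_identical(d1$genotypes, d2$genotypes)
  all_alleles <- unlist(lapply(d1$genotypes, as.vector))
  expect_true(all(all_alleles >= w$model$window_min &
                    all_alleles <= w$model$window_max))
  expect_equal(population_sizes(d1), w$sample_config)
})

test_that("sample configuration (15, 44) produces those population sizes", {
  s <- scenario("two", c("A", "B"), list(A = 2000, B = 2000),
                rbind(ev("sample", "A", 0), ev("sample", "B", 0),
                      ev("divergence", "B", 500, source1 = "A")))
  d <- simulate_dataset(s, c(u = 1), c(A = 15, B = 44), n_loci = 2,
                        model = gsm_model(), seed = 8)
  expect_equal(unname(population_sizes(d)), c(15L, 44L))
})

test_that("stronger bottlenecks lower gene diversity in the founded population", {
  mk <- function(nb) {
    scenario("bn", c("S", "T"), list(S = 5000, T = 2000),
             rbind(ev("sample", "S", 0), ev("sample", "T", 0),
                   ev("size_change", "T", 40, value = nb),
                   ev("divergence", "T", 60, source1 = "S")))
  }
  m <- gsm_model(mu = 5e-4, p_geom = 0.2)
  set.seed(41)
  h <- vapply(c(weak = 2000, strong = 4), function(nb) {
    mean(replicate(80, {
      d <- simulate_dataset(mk(nb), c(u = 1), c(S = 15, T = 15),
                            n_loci = 5, model = m)
      one_sample_stats(d, "T")[["HET"]]
    }))
  }, numeric(1))
  expect_gt(h[["weak"]], h[["strong"]])
})
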