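test_that("one-population statistics match hand-computable cases", {
  # monomorphic locus: 1 allele, zero diversity/variance, M = 1
  g <- array(10L, dim = c(3L, 1L, 2L))
  d <- genotype_dataset(list(A = g))
  expect_equal(unname(one_sample_stats(d, "A")),
               c(1, 0, 0, 1))
  # alleles {10, 12} present: M = 2 / (range 2 + 1)
  g2 <- array(c(10L, 10L, 12L, 12L), dim = c(2L, 1L, 2L))
  expect_equal(one_sample_stats(genotype_dataset(list(A = g2)),
                                "A")[["MGW"]], 2 / 3)
  # a single heterozygous diploid: unbiased diversity 2/(2-1)*(1-1/2) = 1
  g3 <- array(c(10L, 11L), dim = c(1L, 1L, 2L))
  expect_equal(one_sample_stats(genotype_dataset(list(A = g3)),
                                "A")[["HET"]], 1)
  expect_error(one_sample_stats(d, "nope"), "unknown population")
})

test_that("FST equals 1 under complete fixation and ~0 for identical populations", {
  d <- fixed_diff_dataset()
  expect_equal(two_sample_stats(d, "A", "B")[["FST"]], 1)
  set.seed(5)
  dd <- random_dataset(n_pops = 1L, n = 12L, n_loci = 5L, n_alleles = 6L)
  twin <- genotype_dataset(list(A = dd$genotypes$P1, B = dd$genotypes$P1))
  st <- two_sample_stats(twin, "A", "B")
  expect_lt(abs(st[["FST"]]), 0.05)
  expect_equal(st[["DM2"]], 0)
  expect_equal(st[["LIK_AB"]], st[["LIK_BA"]])
})

test_that("Weir-Cockerham FST agrees with the nested-ANOVA oracle", {
  # the hand-specified 2-population 1-locus table
  d <- tiny_dataset()
  expect_equal(two_sample_stats(d, "A", "B")[["FST"]],
               oracle_wc_fst(d), tolerance = 1e-12)
  # randomized sweep over small tables with up to 6 allele states
  set.seed(9)
  for (i in 1:40) {
    d <- random_dataset(n_pops = 2L, n = sample(3:8, 1),
                        n_loci = sample(1:3, 1),
                        n_alleles = sample(2:6, 1))
    got <- two_sample_stats(d, "P1", "P2")[["FST"]]
    want <- oracle_wc_fst(d)
    if (is.finite(want)) expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("delta-mu-squared equals the squared mean-size difference", {
  A <- array(10L, dim = c(4L, 1L, 2L))
  B <- array(13L, dim = c(4L, 1L, 2L))
  d <- genotype_dataset(list(A = A, B = B))
  expect_equal(two_sample_stats(d, "A", "B")[["DM2"]], 9)
})

test_that("the admixture statistic recovers pure, symmetric and simulated mixtures", {
  # sources fixed for different alleles; admixed identical to source1
  S1 <- array(10L, dim = c(10L, 2L, 2L))
  S2 <- array(20L, dim = c(10L, 2L, 2L))
  d1 <- genotype_dataset(list(ADM = S1, S1 = S1, S2 = S2))
  expect_equal(three_sample_stats(d1, "ADM", "S1", "S2"), 1)
  # exact 50:50 mixture of the two fixed sources
  ADM <- array(c(rep(10L, 10L), rep(20L, 10L)), dim = c(10L, 2L, 2L))
  half <- genotype_dataset(list(ADM = ADM, S1 = S1, S2 = S2))
  expect_equal(three_sample_stats(half, "ADM", "S1", "S2"), 0.5)
  # identical sources: degenerate, flagged 0.5
  dg <- genotype_dataset(list(ADM = S1, S1 = S2, S2 = S2))
  v <- three_sample_stats(dg, "ADM", "S1", "S2")
  expect_equal(as.numeric(v), 0.5)
  expect_true(attr(v, "degenerate"))
  expect_error(three_sample_stats(d1, "ADM", "ADM", "S2"), "distinct")
})

test_that("simulated admixture with r = 0.75 is recovered on average", {
  s <- scenario("adm", c("S1", "S2", "T"),
                list(S1 = 5000, S2 = 5000, T = 5000),
                rbind(ev("sample", "S1", 0), ev("sample", "S2", 0),
                      ev("sample", "T", 0),
                      ev("admixture", "T", 10, source1 = "S1",
                         source2 = "S2", value = 0.75),
                      ev("divergence", "S2", 30000, source1 = "S1")))
  m <- gsm_model(mu = 5e-4, p_geom = 0.2, window_width = 60)
  set.seed(13)
  rhat <- replicate(120, {
    d <- simulate_dataset(s, c(u = 1), c(S1 = 40, S2 = 40, T = 40),
                          n_loci = 8, model = m)
    three_sample_stats(d, "T", "S1", "S2")
  })
  expect_lt(abs(mean(rhat) - 0.75), 0.05)
})

test_that("catalog sizes follow 4P + 8C(P,2) + 3C(P,3) for all printed designs", {
  sizes <- c(`3` = 39, `5` = 130, `6` = 204, `7` = 301, `8` = 424)
  for (P in names(sizes))
    expect_length(catalog_names(paste0("P", seq_len(as.integer(P)))),
                  sizes[[P]])
  expect_length(catalog_names("P1"), 4L)
  # estimation subset: 2P + C(P,2) + T
  pops12 <- paste0("P", 1:12)
  tr5 <- lapply(1:5, function(i) pops12[c(i, i + 1, i + 2)])
  expect_length(estimation_subset_names(pops12, tr5), 95L)
  expect_length(estimation_subset_names(c("A", "B"), list()), 5L)
  # checking complement for the 12-population estimation configuration
  expect_length(test_statistic_complement(pops12,
                                          estimation_subset_names(pops12,
                                                                  tr5)),
                1141L)
  expect_length(test_statistic_complement(paste0("P", 1:3), character()),
                39L)
  expect_length(test_statistic_complement(pops12,
                                          catalog_names(pops12)), 0L)
  expect_error(test_statistic_complement(c("A", "B"), "FST_A.C"),
               "not contained")
})

test_that("computed catalogs match their name enumeration and are order-invariant", {
  set.seed(17)
  d <- random_dataset(n_pops = 3L, n = 8L, n_loci = 4L, n_alleles = 5L)
  v <- full_catalog(d)
  expect_identical(names(v), catalog_names(names(d$genotypes)))
  expect_length(v, 39L)
  expect_true(all(is.finite(v)))
  # gene diversity, DAS and AML live in [0, 1]
  expect_true(all(v[grep("^HET", names(v))] >= 0 &
                    v[grep("^HET", names(v))] <= 1))
  expect_true(all(v[grep("^DAS", names(v))] >= 0 &
                    v[grep("^DAS", names(v))] <= 1))
  expect_true(all(v[grep("^AML", names(v))] >= 0 &
                    v[grep("^AML", names(v))] <= 1))
  # permuting individuals within populations changes nothing
  perm <- d
  for (p in names(perm$genotypes)) {
    n <- dim(perm$genotypes[[p]])[1L]
    perm$genotypes[[p]] <- perm$genotypes[[p]][sample(n), , , drop = FALSE]
  }
  expect_equal(full_catalog(perm), v)
  # swapping the two allele columns changes nothing either
  swap <- d
  swap$genotypes$P1 <- swap$genotypes$P1[, , c(2L, 1L), drop = FALSE]
  expect_equal(full_catalog(swap), v)
})

test_that("estimation subset values agree with the full catalog", {
  set.seed(19)
  d <- random_dataset(n_pops = 3L, n = 6L, n_loci = 3L)
  tr <- list(c("P3", "P1", "P2"))
  sub <- estimation_subset(d, tr)
  expect_length(sub, 2 * 3 + 3 + 1)
  v <- full_catalog(d)
  expect_equal(sub[names(sub) %in% names(v)],
               v[names(sub)[names(sub) %in% names(v)]])
})

test_that("missing data is skipped, not propagated", {
  set.seed(23)
  d <- random_dataset(n_pops = 2L, n = 8L, n_loci = 5L,
                      missing_rate = 0.25)
  v <- full_catalog(d)
  expect_true(all(is.finite(v)))
})
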