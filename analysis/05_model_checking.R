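#!/usr/bin/env Rscript
# Stage 5: posterior predictive checking of the fitted scenario-posterior
# combination. Test quantities are the held-out summary statistics (the
# full catalog minus everything used for estimation). A well-fitting
# combination should leave no statistic significant after FDR control and
# should center the observed dataset inside the predictive cloud on the
# principal components.

suppressPackageStartupMessages(library(invasionabc))
dir.create("results", showWarnings = FALSE)

seed <- 42L
w <- make_toy_invasion("small", seed = seed)
obs_d <- read_genepop("results/toy_small.gen")
obs <- compute_stats(obs_d, "estimation", w$triplets)

tab <- build_reference_table(list(w$scenario), w$prior, 2000L,
                             w$sample_config, w$n_loci, model = w$model,
                             stat_set = "estimation",
                             triplets = w$triplets, seed = seed + 3L)
post <- local_linear_estimate(tab, obs, acceptance_fraction = 0.05,
                              parameters = c("r_I2", "db_I2", "Nb_I2"))

pops <- names(obs_d$genotypes)
test_set <- test_statistic_complement(
  pops, estimation_subset_names(pops, w$triplets))
cat(length(test_set), "held-out test statistics\n")

rep <- posterior_predictive_check(w$scenario, post, obs_d, test_set,
                                  w$sample_config, w$n_loci,
                                  model = w$model, n_ppc = 500L,
                                  seed = seed + 4L)
print(rep)
write.csv(rep$table, "results/ppc.csv", row.names = FALSE)

chk <- pca_projection_check(rep$sims, rep$observed)
cat(sprintf("observed point PCA depth rank: %.3f (coordinates %.2f, %.2f)\n",
            chk$depth_rank, chk$obs_coord[1], chk$obs_coord[2]))
coords <- rbind(data.frame(what = "simulated", chk$sim_coords),
                data.frame(what = "observed", PC1 = chk$obs_coord[1],
                           PC2 = chk$obs_coord[2]))
write.csv(coords, "results/ppc_pca.csv", row.names = FALSE)
cat("wrote results/ppc.csv and results/ppc_pca.csv\n")
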