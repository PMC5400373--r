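# Posterior predictive model checking: simulate datasets from the fitted
# scenario-posterior combination, compute tail-area posterior predictive
# p-values (ppp) over held-out test statistics, control the false discovery
# rate, and project simulations and the observed dataset onto principal
# components.

#' Posterior predictive check of a scenario-posterior combination
#'
#' Simulates `n_ppc` datasets with full parameter vectors resampled (with
#' replacement, by posterior weight) from the accepted draws — estimated
#' parameters take their regression-adjusted values — and compares each
#' held-out test statistic of the observed dataset against its posterior
#' predictive distribution. For each test quantity q,
#' `p = Prob(q_sim < q_obs)` with ties counted as half, and
#' `ppp = min(p, 1 - p)`, floored at the Monte-Carlo resolution
#' `1/(n_ppc + 1)`. Benjamini–Hochberg FDR control is applied to
#' `min(2 ppp, 1)`.
#'
#' @param truth A [scenario] (the fitted scenario).
#' @param posterior A `posterior_sample` from [local_linear_estimate()].
#' @param observed_dataset The observed [genotype_dataset].
#' @param test_stat_set Character vector of test statistic names; must be
#'   disjoint from the statistics used for estimation (error otherwise).
#' @param sample_config,n_loci,model Simulation configuration (typically
#'   from the reference table used for estimation).
#' @param n_ppc Number of posterior predictive simulations (>= 100).
#' @param fdr_alpha FDR level for the significance flags.
#' @param seed Integer seed.
#' @return An object of class `ppc_report`: per-statistic ppp-values and
#'   FDR flags, counts below 0.05 and 0.001, and the simulated statistic
#'   matrix (for the PCA projection).
#' @export
posterior_predictive_check <- function(truth, posterior, observed_dataset,
                                       test_stat_set, sample_config,
                                       n_loci, model = gsm_model(),
                                       n_ppc = 500L, fdr_alpha = 0.05,
                                       seed = 1L) {
  stopifnot(inherits(posterior, "posterior_sample"), n_ppc >= 100L)
  overlap <- intersect(test_stat_set, posterior$stats_used)
  if (length(overlap))
    stop("test statistics overlap the estimation statistics (e.g. ",
         overlap[1L], "); model checking must use held-out quantities")
  obs_full <- full_catalog(observed_dataset, triplets = "all")
  bad <- setdiff(test_stat_set, names(obs_full))
  if (length(bad))
    stop("unknown test statistic(s): ", paste(head(bad, 3L), collapse = ", "))
  q_obs <- obs_full[test_stat_set]

  # resample full parameter rows from the weighted posterior; adjusted
  # values replace the raw draws for the estimated parameters
  par_rows <- posterior$accepted_params
  for (p in colnames(posterior$draws))
    if (p %in% names(par_rows)) par_rows[[p]] <- posterior$draws[, p]
  set.seed(seed)
  pick <- sample.int(nrow(par_rows), n_ppc, replace = TRUE,
                     prob = posterior$weights)
  sims <- matrix(NA_real_, n_ppc, length(test_stat_set),
                 dimnames = list(NULL, test_stat_set))
  for (i in seq_len(n_ppc)) {
    par <- unlist(par_rows[pick[i], ])
    mod <- model
    if ("mu" %in% names(par)) mod$mu <- par[["mu"]]
    if ("p_geom" %in% names(par)) mod$p_geom <- par[["p_geom"]]
    d <- simulate_dataset(truth, par, sample_config, n_loci, model = mod)
    sims[i, ] <- full_catalog(d, triplets = "all")[test_stat_set]
  }
  usable <- colSums(is.finite(sims)) > 0
  p <- vapply(seq_along(test_stat_set), function(j) {
    s <- sims[is.finite(sims[, j]), j]
    if (!length(s) || !is.finite(q_obs[j])) return(NA_real_)
    (sum(s < q_obs[j]) + 0.5 * sum(s == q_obs[j])) / length(s)
  }, numeric(1L))
  ppp <- pmin(p, 1 - p)
  ppp <- pmax(ppp, 1 / (n_ppc + 1))     # Monte-Carlo resolution floor
  two_sided <- pmin(2 * ppp, 1)
  flags <- p.adjust(two_sided, method = "BH") <= fdr_alpha
  structure(list(
    table = data.frame(statistic = test_stat_set, ppp = ppp,
                       fdr_significant = flags),
    n_below_05 = sum(ppp < 0.05, na.rm = TRUE),
    n_below_001 = sum(ppp < 0.001, na.rm = TRUE),
    n_flagged = sum(flags, na.rm = TRUE),
    n_ppc = n_ppc, fdr_alpha = fdr_alpha,
    sims = sims, observed = q_obs),
    class = "ppc_report")
}

#' @export
print.ppc_report <- function(x, ...) {
  cat("posterior predictive check over", nrow(x$table),
      "test statistics (", x$n_ppc, "simulations )\n")
  cat("  ppp < 0.05:", x$n_below_05, "  ppp < 0.001:", x$n_below_001,
      "  FDR-significant:", x$n_flagged, "\n")
  invisible(x)
}

#' Principal-component projection check
#'
#' Fits principal components on the simulated statistic vectors (constant
#' statistics dropped), projects the observed vector with the same
#' transform, and reports first-two-axis coordinates plus a depth rank: the
#' fraction of simulations whose whitened distance from the center exceeds
#' the observed one (small values mean the observed point sits in the
#' extreme tail of the predictive cloud).
#'
#' @param sims Numeric matrix of simulated statistic vectors (rows).
#' @param observed Named numeric vector over the same statistics.
#' @return List with `sim_coords` (n x 2), `obs_coord` (length 2) and
#'   `depth_rank` in `(0, 1]`.
#' @export
pca_projection_check <- function(sims, observed) {
  stopifnot(nrow(sims) >= 3L)
  ok_rows <- complete.cases(sims) & apply(is.finite(sims), 1L, all)
  sims <- sims[ok_rows, , drop = FALSE]
  keep <- apply(sims, 2L, function(v) sd(v) > 1e-12) &
    is.finite(observed[colnames(sims)])
  sims <- sims[, keep, drop = FALSE]
  obs <- observed[colnames(sims)]
  pc <- prcomp(sims, center = TRUE, scale. = TRUE)
  use <- pc$sdev > 1e-8
  sim_scores <- pc$x[, use, drop = FALSE]
  obs_scores <- predict(pc, matrix(obs, 1L,
                                   dimnames = list(NULL, names(obs))))[
                                     , use, drop = FALSE]
  sdv <- pc$sdev[use]
  d_sim <- rowSums(sweep(sim_scores, 2L, sdv, "/")^2)
  d_obs <- sum((obs_scores / sdv)^2)
  list(sim_coords = pc$x[, 1:2, drop = FALSE],
       obs_coord = predict(pc, matrix(obs, 1L,
                                      dimnames = list(NULL,
                                                      names(obs))))[1, 1:2],
       depth_rank = (1 + sum(d_sim >= d_obs)) / (nrow(sims) + 1))
}
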