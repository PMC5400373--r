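# Posterior parameter estimation under the selected scenario: rejection on
# the nearest simulated datasets, Epanechnikov weighting, and local linear
# regression adjustment applied to logit-transformed parameter values so
# adjusted draws stay inside the prior support. Includes bottleneck-severity
# classification and a synthetic-truth recovery harness.

logit_map <- function(x, lo, hi) {
  eps <- (hi - lo) * 1e-9
  x <- pmin(pmax(x, lo + eps), hi - eps)
  log((x - lo) / (hi - x))
}

inv_logit_map <- function(z, lo, hi) lo + (hi - lo) / (1 + exp(-z))

weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) x[o][which(cw >= p)[1L]], numeric(1L))
}

density_mode <- function(x, w) {
  if (length(unique(x)) == 1L) return(x[1L])
  d <- density(x, weights = w / sum(w), bw = stats::bw.nrd0(x))
  d$x[which.max(d$y)]
}

#' Local linear regression ABC parameter estimation
#'
#' Keeps the `acceptance_fraction` of reference-table rows closest to the
#' observed statistics (standardized Euclidean distance), weights them with
#' an Epanechnikov kernel in distance, logit-transforms each parameter to
#' its prior range, adjusts the draws by a weighted linear regression on
#' the (simulated - observed) statistics, and back-transforms. The mode is
#' a Gaussian kernel density estimate (Silverman bandwidth) on the adjusted
#' draws.
#'
#' @param table A `reference_table`, typically restricted to the selected
#'   scenario with [subset_scenario()].
#' @param observed Named numeric statistic vector.
#' @param acceptance_fraction Accepted fraction in `(0, 1]`; default 0.001
#'   (intended for tables of millions of rows; raise it for small tables).
#' @param parameters Parameter names to estimate (default: all columns of
#'   the table's parameter block that vary).
#' @param derived Named character vector of derived quantities as
#'   expressions in parameter names, e.g.
#'   `c(severity = "db_X / Nb_X")`; their transform bounds are the range of
#'   the expression over the whole table.
#' @return An object of class `posterior_sample`: adjusted draws, weights,
#'   per-parameter summaries (mean, median, mode, q5, q95), the accepted
#'   rows' full parameter block (for posterior predictive reuse) and the
#'   statistic names used.
#' @export
local_linear_estimate <- function(table, observed,
                                  acceptance_fraction = 0.001,
                                  parameters = NULL, derived = NULL) {
  if (!(acceptance_fraction > 0 && acceptance_fraction <= 1))
    stop("acceptance_fraction must be in (0, 1]")
  par_tab <- table$params
  # derived quantities become extra parameter columns with empirical bounds
  if (!is.null(derived)) {
    for (nm in names(derived)) {
      par_tab[[nm]] <- eval(parse(text = derived[[nm]]),
                            envir = table$params)
    }
  }
  if (is.null(parameters)) {
    varying <- vapply(par_tab, function(v)
      length(unique(v[is.finite(v)])) > 1L, logical(1L))
    parameters <- names(par_tab)[varying]
  }
  bounds <- param_bounds(table, par_tab, parameters, derived)

  sc <- stat_scales(table$stats)
  z <- standardize_stats(table$stats, sc)
  zo <- (observed[colnames(z)] - sc$center[colnames(z)]) /
    sc$scale[colnames(z)]
  if (anyNA(zo)) stop("observed statistics missing table columns")
  dist <- sqrt(rowSums(sweep(z, 2L, zo)^2))
  n_acc <- max(2L, ceiling(acceptance_fraction * nrow(z)))
  acc <- order(dist)[seq_len(n_acc)]
  dmax <- max(dist[acc])
  w <- if (dmax > 0) 1 - (dist[acc] / dmax)^2 else rep(1, n_acc)
  w[w <= 0] <- min(w[w > 0], 1e-6)

  X <- sweep(z[acc, , drop = FALSE], 2L, zo)
  # a (near-)saturated regression would collapse the posterior onto its
  # fitted value; fall back to rejection when too few rows are accepted
  saturated <- n_acc <= ncol(X) + 1L
  if (saturated)
    warning("accepted rows (", n_acc, ") do not exceed the number of ",
            "statistics (", ncol(X), "); using the rejection-only ",
            "posterior — raise acceptance_fraction or the table size")
  draws <- matrix(NA_real_, n_acc, length(parameters),
                  dimnames = list(NULL, parameters))
  for (p in parameters) {
    lo <- bounds[p, 1L]; hi <- bounds[p, 2L]
    th <- logit_map(par_tab[[p]][acc], lo, hi)
    fit <- if (saturated) NULL else
      tryCatch(lm.wfit(cbind(1, X), th, w), error = function(e) NULL)
    if (is.null(fit)) {
      if (!saturated)
        warning("singular local regression for ", p,
                "; falling back to rejection-only posterior")
      adj <- th
    } else {
      beta <- fit$coefficients[-1L]
      beta[is.na(beta)] <- 0
      adj <- th - as.numeric(X %*% beta)
    }
    draws[, p] <- inv_logit_map(adj, lo, hi)
  }
  summaries <- do.call(rbind, lapply(parameters, function(p) {
    x <- draws[, p]
    q <- weighted_quantile(x, w, c(0.05, 0.5, 0.95))
    data.frame(parameter = p,
               mean = sum(w * x) / sum(w),
               median = q[2L], mode = density_mode(x, w),
               q5 = q[1L], q95 = q[3L])
  }))
  structure(list(draws = draws, weights = w, summaries = summaries,
                 accepted_params = table$params[acc, , drop = FALSE],
                 accepted_index = acc,
                 stats_used = colnames(table$stats),
                 scenario_name = if (length(table$scenario_names) == 1L)
                   table$scenario_names else
                     as.character(table$scenario[acc][1L]),
                 bounds = bounds),
            class = "posterior_sample")
}

param_bounds <- function(table, par_tab, parameters, derived) {
  bounds <- matrix(NA_real_, length(parameters), 2L,
                   dimnames = list(parameters, c("min", "max")))
  prior <- if (is.list(table$prior) && length(table$prior))
    table$prior[[1L]] else NULL
  for (p in parameters) {
    if (!is.null(prior) && p %in% names(prior$params)) {
      bounds[p, ] <- c(prior$params[[p]]$min, prior$params[[p]]$max)
    } else {
      r <- range(par_tab[[p]], finite = TRUE)
      pad <- diff(r) * 1e-6 + 1e-12
      bounds[p, ] <- c(r[1L] - pad, r[2L] + pad)
    }
  }
  bounds
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat("posterior_sample:", nrow(x$draws), "weighted draws\n")
  print(x$summaries, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Classify bottleneck severity
#'
#' Severity is the ratio of bottleneck duration (generations) to effective
#' size during the bottleneck. Median severities below 0.12 are `weak`,
#' between 0.12 and 0.22 `moderate`, above 0.3 `strong`; the gap
#' `[0.22, 0.3]` (including the cutpoints themselves) is reported as
#' `unclassified` with a warning.
#'
#' @param median_severity Non-negative posterior median of db/Nb.
#' @return One of `"weak"`, `"moderate"`, `"strong"`, `"unclassified"`.
#' @export
classify_severity <- function(median_severity) {
  if (!is.finite(median_severity) || median_severity < 0)
    stop("median severity must be non-negative")
  if (median_severity < 0.12) return("weak")
  if (median_severity > 0.12 && median_severity < 0.22) return("moderate")
  if (median_severity > 0.3) return("strong")
  warning("median severity ", median_severity,
          " falls between the moderate and strong cutpoints; unclassified")
  "unclassified"
}

#' Parameter-recovery harness on synthetic truth
#'
#' Repeatedly simulates an observed dataset from a known scenario and
#' parameter vector, estimates the requested parameters against the given
#' reference table, and reports per-replicate medians, 90% intervals,
#' coverage of the truth and absolute error.
#'
#' @param table A `reference_table` restricted to the true scenario.
#' @param truth A [scenario].
#' @param true_params Named parameter vector used to simulate the
#'   pseudo-observed datasets.
#' @param parameters Names to estimate (possibly derived; see `derived`).
#' @param derived Passed to [local_linear_estimate()].
#' @param n_replicates Number of pseudo-observed replicates.
#' @param acceptance_fraction Passed to [local_linear_estimate()].
#' @param seed Integer seed.
#' @return Data frame with one row per replicate x parameter and an
#'   attached `summary` attribute (mean error, coverage).
#' @export
recover_parameters <- function(table, truth, true_params, parameters,
                               derived = NULL, n_replicates = 10L,
                               acceptance_fraction = 0.02, seed = 1L) {
  true_vals <- setNames(numeric(length(parameters)), parameters)
  env <- as.list(true_params)
  for (p in parameters) {
    true_vals[p] <- if (!is.null(derived) && p %in% names(derived))
      eval(parse(text = derived[[p]]), envir = env)
    else true_params[[p]]
  }
  rows <- list()
  for (r in seq_len(n_replicates)) {
    obs_d <- simulate_dataset(truth, true_params, table$sample_config,
                              table$n_loci, model = table$model,
                              seed = row_seed(seed, r))
    obs <- compute_stats(obs_d, table$stat_set, table$triplets)
    post <- local_linear_estimate(table, obs, acceptance_fraction,
                                  parameters = parameters,
                                  derived = derived)
    s <- post$summaries
    rows[[r]] <- data.frame(replicate = r, parameter = s$parameter,
                            median = s$median, q5 = s$q5, q95 = s$q95,
                            truth = true_vals[s$parameter],
                            covered = true_vals[s$parameter] >= s$q5 &
                              true_vals[s$parameter] <= s$q95,
                            abs_error = abs(s$median -
                                              true_vals[s$parameter]))
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- do.call(rbind, lapply(parameters, function(p) {
    sub <- out[out$parameter == p, ]
    data.frame(parameter = p, mean_abs_error = mean(sub$abs_error),
               coverage = mean(sub$covered))
  }))
  out
}
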