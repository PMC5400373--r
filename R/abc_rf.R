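# ABC model choice with random forests: classification votes over the
# competing scenarios, out-of-bag prior error rate, and posterior
# probability of the selected scenario from a secondary regression forest
# trained on the first forest's out-of-bag misclassification indicator.

drop_constant_cols <- function(x) {
  keep <- apply(x, 2L, function(v) {
    r <- range(v, finite = TRUE); is.finite(r[1L]) && r[2L] > r[1L]
  })
  x[, keep, drop = FALSE]
}

#' Append linear discriminant axes to a reference table
#'
#' Fits a linear discriminant analysis of the scenario label on the summary
#' statistics and appends the min(K-1, d) discriminant projections as extra
#' columns; the fitted transform is stored so an observed vector can be
#' projected identically. Near-singular within-class scatter triggers a
#' small ridge on the statistic columns, with a warning.
#'
#' @param table A `reference_table` with at least 2 scenarios.
#' @return The table with augmented `stats` and an `lda` attribute.
#' @export
append_lda_axes <- function(table) {
  if (length(table$scenario_names) < 2L)
    stop("discriminant axes require at least 2 scenarios")
  if (!is.null(attr(table, "lda"))) return(table)
  x <- drop_constant_cols(table$stats)
  # collinear statistics are routine here (the catalog is redundant by
  # construction); lda handles them, so that warning is muted
  quiet_lda <- function(...) withCallingHandlers(
    MASS::lda(...),
    warning = function(w) {
      if (grepl("collinear", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  fit <- tryCatch(quiet_lda(x, grouping = table$scenario),
                  error = function(e) NULL)
  if (is.null(fit)) {
    warning("singular within-class scatter; ridge-regularizing before LDA")
    x <- x + matrix(rnorm(length(x), sd = 1e-8), nrow(x))
    fit <- quiet_lda(x, grouping = table$scenario)
  }
  axes <- predict(fit, x)$x
  colnames(axes) <- paste0("LD", seq_len(ncol(axes)))
  out <- table
  out$stats <- cbind(table$stats, axes)
  attr(out, "lda") <- list(fit = fit, cols = colnames(x),
                           n_axes = ncol(axes))
  out
}

project_observed <- function(table, observed) {
  lda_info <- attr(table, "lda")
  raw_names <- if (is.null(lda_info)) colnames(table$stats)
  else setdiff(colnames(table$stats),
               paste0("LD", seq_len(lda_info$n_axes)))
  missing <- setdiff(raw_names, names(observed))
  if (length(missing))
    stop("observed statistics are missing ", length(missing),
         " column(s) present in the table (e.g. ", missing[1L], ")")
  obs <- observed[raw_names]
  if (!is.null(lda_info)) {
    proj <- predict(lda_info$fit,
                    matrix(obs[lda_info$cols], 1L,
                           dimnames = list(NULL, lda_info$cols)))$x
    obs <- c(obs, setNames(as.numeric(proj),
                           paste0("LD", seq_len(ncol(proj)))))
  }
  obs[colnames(table$stats)]
}

train_forest <- function(table, n_trees, seed) {
  df <- as.data.frame(table$stats)
  ranger::ranger(x = df, y = table$scenario, num.trees = n_trees,
                 seed = seed, num.threads = 1L)
}

#' Random-forest ABC model choice
#'
#' Trains a classification forest on the reference table (statistics plus
#' discriminant axes), collects the per-tree classification votes for the
#' observed statistic vector, selects the scenario with most votes, and
#' reports the out-of-bag prior error rate and the posterior probability of
#' the selected scenario from the secondary error-regression forest.
#' Replicate runs differ only by the forest seed; their spread is reported
#' as mean and standard deviation.
#'
#' @param table A `reference_table`.
#' @param observed Named numeric statistic vector for the observed dataset.
#' @param n_trees Trees per forest (default 500).
#' @param seed Integer seed.
#' @param n_replicates Replicate forest runs on the same table.
#' @param add_lda Append discriminant axes first (default TRUE).
#' @return An object of class `model_choice_result`: votes per scenario
#'   (first replicate; all replicates in `$replicates`), best scenario,
#'   posterior probability of the best scenario, prior error rate, and
#'   replicate summaries.
#' @export
rf_model_choice <- function(table, observed, n_trees = 500L, seed = 1L,
                            n_replicates = 1L, add_lda = TRUE) {
  if (length(table$scenario_names) < 2L)
    stop("model choice requires at least 2 scenarios")
  if (add_lda) table <- append_lda_axes(table)
  obs <- project_observed(table, observed)
  obs_df <- as.data.frame(matrix(obs, 1L,
                                 dimnames = list(NULL, names(obs))))
  K <- length(table$scenario_names)
  reps <- lapply(seq_len(n_replicates), function(r) {
    fit <- train_forest(table, n_trees, seed + 1000L * (r - 1L))
    pred <- predict(fit, obs_df, predict.all = TRUE,
                    num.threads = 1L)$predictions
    votes <- tabulate(as.integer(pred), nbins = K)
    names(votes) <- table$scenario_names
    oob_wrong <- as.integer(fit$predictions != table$scenario)
    err <- mean(oob_wrong)
    reg <- ranger::ranger(x = as.data.frame(table$stats), y = oob_wrong,
                          num.trees = n_trees,
                          seed = seed + 1000L * (r - 1L) + 1L,
                          num.threads = 1L)
    local_err <- predict(reg, obs_df, num.threads = 1L)$predictions
    list(votes = votes, prior_error = err,
         posterior = min(max(1 - local_err, 0), 1))
  })
  votes_mat <- t(vapply(reps, `[[`, numeric(K), "votes"))
  mean_votes <- colMeans(votes_mat)
  best_idx <- which(mean_votes == max(mean_votes))
  if (length(best_idx) > 1L) {
    warning("vote tie between scenarios ",
            paste(table$scenario_names[best_idx], collapse = ", "),
            "; keeping the lowest index")
    best_idx <- best_idx[1L]
  }
  post <- vapply(reps, `[[`, numeric(1L), "posterior")
  errs <- vapply(reps, `[[`, numeric(1L), "prior_error")
  structure(list(
    votes = reps[[1L]]$votes,
    vote_share = mean_votes / n_trees,
    best = table$scenario_names[best_idx],
    posterior_probability = mean(post),
    posterior_sd = if (n_replicates > 1L) sd(post) else NA_real_,
    prior_error_rate = mean(errs),
    prior_error_sd = if (n_replicates > 1L) sd(errs) else NA_real_,
    n_trees = n_trees,
    n_replicates = n_replicates,
    replicates = list(votes = votes_mat, posterior = post,
                      prior_error = errs)),
    class = "model_choice_result")
}

#' @export
print.model_choice_result <- function(x, ...) {
  cat("ABC-RF model choice (", x$n_trees, " trees, ", x$n_replicates,
      " replicate(s))\n", sep = "")
  cat("  votes:", paste0(names(x$votes), "=", x$votes, collapse = ", "),
      "\n")
  cat(sprintf("  best: %s  P(best) = %.3f  prior error = %.3f\n",
              x$best, x$posterior_probability, x$prior_error_rate))
  invisible(x)
}

#' Out-of-bag prior error rate of the RF classifier
#'
#' The probability of choosing a wrong scenario when scenario index and
#' parameters are drawn from the priors, estimated as the out-of-bag
#' misclassification fraction of the forest over the reference table.
#'
#' @inheritParams rf_model_choice
#' @return Fraction in `[0, 1]`.
#' @export
prior_error_rate_rf <- function(table, n_trees = 500L, seed = 1L,
                                add_lda = TRUE) {
  if (add_lda) table <- append_lda_axes(table)
  fit <- train_forest(table, n_trees, seed)
  mean(fit$predictions != table$scenario)
}
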