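# Standard ABC model choice: rejection on the nearest simulated datasets
# followed by polychotomous logistic regression of the scenario label on
# linear discriminant axes, evaluated at the observed point.

#' Robust column scales for distance standardization
#'
#' Median absolute deviation per column, falling back to the standard
#' deviation where the MAD is zero; columns constant in both senses get a
#' zero weight (they carry no distance information).
#' @param x Numeric matrix.
#' @return List with `center` (medians) and `scale`.
#' @keywords internal
stat_scales <- function(x) {
  center <- apply(x, 2L, median)
  scale <- apply(x, 2L, mad)
  zero <- scale <= 0
  scale[zero] <- apply(x[, zero, drop = FALSE], 2L, sd)
  list(center = center, scale = scale)
}

standardize_stats <- function(x, sc) {
  keep <- sc$scale > 0
  sweep(sweep(x[, keep, drop = FALSE], 2L, sc$center[keep]),
        2L, sc$scale[keep], "/")
}

#' ABC-LDA model choice
#'
#' Standardizes the statistics by median absolute deviation, ranks
#' simulated datasets by Euclidean distance to the observed vector, keeps
#' the nearest `tolerance` fraction, and fits a multinomial (polychotomous)
#' logistic regression of the scenario label on the discriminant axes over
#' the accepted rows; posterior probabilities are the fitted class
#' probabilities at the observed point.
#'
#' @param table A `reference_table`.
#' @param observed Named numeric statistic vector.
#' @param tolerance Accepted fraction in `(0, 1]`; default 0.01.
#' @param seed Integer seed (regression fitting is deterministic; the seed
#'   is recorded for bookkeeping).
#' @param ridge Weight decay of the multinomial fit; guards against
#'   complete separation.
#' @return An object of class `lda_choice_result` with per-scenario
#'   posterior probabilities (summing to 1), the best scenario, tolerance
#'   and acceptance count.
#' @export
lda_model_choice <- function(table, observed, tolerance = 0.01, seed = 1L,
                             ridge = 1e-4) {
  if (!(tolerance > 0 && tolerance <= 1)) stop("tolerance must be in (0,1]")
  if (length(table$scenario_names) < 2L)
    stop("model choice requires at least 2 scenarios")
  table_lda <- append_lda_axes(table)
  lda_info <- attr(table_lda, "lda")
  n_axes <- lda_info$n_axes
  axes <- table_lda$stats[, paste0("LD", seq_len(n_axes)), drop = FALSE]
  obs_full <- project_observed(table_lda, observed)
  obs_axes <- obs_full[paste0("LD", seq_len(n_axes))]

  sc <- stat_scales(table$stats)
  z <- standardize_stats(table$stats, sc)
  zo <- (observed[colnames(z)] - sc$center[colnames(z)]) /
    sc$scale[colnames(z)]
  d <- sqrt(rowSums(sweep(z, 2L, zo)^2))
  n_acc <- ceiling(tolerance * nrow(z))
  acc <- order(d)[seq_len(n_acc)]

  y <- droplevels(table$scenario[acc])
  absent <- setdiff(table$scenario_names, levels(y))
  if (length(absent))
    warning("scenario(s) absent from the accepted set get probability 0: ",
            paste(absent, collapse = ", "))
  probs <- setNames(rep(0, length(table$scenario_names)),
                    table$scenario_names)
  if (nlevels(y) == 1L) {
    probs[levels(y)] <- 1
  } else {
    df <- data.frame(.y = y, axes[acc, , drop = FALSE])
    fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE,
                          decay = ridge, maxit = 500L)
    newd <- as.data.frame(matrix(obs_axes, 1L,
                                 dimnames = list(NULL, colnames(axes))))
    p <- predict(fit, newdata = newd, type = "probs")
    if (length(p) == 1L) {               # two classes: prob of 2nd level
      probs[levels(y)] <- c(1 - p, p)
    } else probs[names(p)] <- p
  }
  best_idx <- which(probs == max(probs))[1L]
  structure(list(probabilities = probs,
                 best = names(probs)[best_idx],
                 tolerance = tolerance, n_accepted = n_acc,
                 seed = seed),
            class = "lda_choice_result")
}

#' @export
print.lda_choice_result <- function(x, ...) {
  cat("ABC-LDA model choice (tolerance ", x$tolerance, ", ",
      x$n_accepted, " accepted rows)\n", sep = "")
  cat("  P:", paste0(names(x$probabilities), "=",
                     round(x$probabilities, 3), collapse = ", "), "\n")
  cat("  best:", x$best, "\n")
  invisible(x)
}

#' Prior error rate of ABC-LDA over pseudo-observed datasets
#'
#' Draws `n_pseudo` rows of the reference table as pseudo-observed
#' datasets; each is held out of the distance ranking, classified with
#' [lda_model_choice()] machinery, and counted as an error when the
#' highest-probability scenario differs from its generating scenario.
#'
#' @param table A `reference_table`.
#' @param tolerance Accepted fraction.
#' @param n_pseudo Number of pseudo-observed datasets (default 500).
#' @param seed Integer seed for the pseudo-observed draw.
#' @param ridge Weight decay of the multinomial fits.
#' @return Misclassification fraction in `[0, 1]`.
#' @export
prior_error_rate_lda <- function(table, tolerance = 0.01, n_pseudo = 500L,
                                 seed = 1L, ridge = 1e-4) {
  stopifnot(n_pseudo >= 1L)
  table_lda <- append_lda_axes(table)
  n_axes <- attr(table_lda, "lda")$n_axes
  axes <- table_lda$stats[, paste0("LD", seq_len(n_axes)), drop = FALSE]
  sc <- stat_scales(table$stats)
  z <- standardize_stats(table$stats, sc)
  n <- nrow(z)
  set.seed(seed)
  pseudo <- sample.int(n, min(n_pseudo, n))
  wrong <- vapply(pseudo, function(i) {
    d <- sqrt(rowSums(sweep(z, 2L, z[i, ])^2))
    d[i] <- Inf                           # hold the pseudo row out
    n_acc <- ceiling(tolerance * (n - 1L))
    acc <- order(d)[seq_len(n_acc)]
    y <- droplevels(table$scenario[acc])
    if (nlevels(y) <= 1L) {
      best <- levels(y)
    } else {
      df <- data.frame(.y = y, axes[acc, , drop = FALSE])
      fit <- tryCatch(nnet::multinom(.y ~ ., data = df, trace = FALSE,
                                     decay = ridge, maxit = 500L),
                      error = function(e) NULL)
      if (is.null(fit)) {
        best <- names(which.max(table(y)))
      } else {
        newd <- as.data.frame(matrix(axes[i, ], 1L,
                                     dimnames = list(NULL, colnames(axes))))
        p <- predict(fit, newdata = newd, type = "probs")
        best <- if (length(p) == 1L) {
          if (p >= 0.5) levels(y)[2L] else levels(y)[1L]
        } else names(which.max(p))
      }
    }
    as.integer(!identical(best, as.character(table$scenario[i])))
  }, integer(1L))
  mean(wrong)
}
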