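# Orchestration of sequential nested model-choice analyses: each analysis
# consumes the previous winners' history, enumerates its competing set,
# runs model choice across representative sample-site combinations, and
# emits a consolidated report.

#' Declare an ordered plan of nested model-choice analyses
#'
#' Each analysis is a list with fields `name`, `target` (focal population
#' label), `sources` (candidate source labels; the token
#' `"winner:<analysis>"` resolves to a previous analysis' target, carrying
#' its inferred founding history forward), optional `alternates` (named
#' list mapping a source label to alternative representative sample sites,
#' each combination analyzed separately), `t_intro` (generations, or a
#' parameter expression) and optional `engine` (`"rf"`, `"lda"` or
#' `"both"`, default `"rf"`).
#'
#' @param analyses List of analysis declarations.
#' @return An object of class `analysis_plan`.
#' @export
analysis_plan <- function(analyses) {
  stopifnot(is.list(analyses), length(analyses) >= 1L)
  nm <- vapply(analyses, `[[`, character(1L), "name")
  if (anyDuplicated(nm)) stop("analysis names must be unique")
  plan <- structure(list(analyses = setNames(analyses, nm)),
                    class = "analysis_plan")
  err <- validate_plan(plan)
  if (length(err)) stop("invalid plan: ", paste(err, collapse = "; "))
  plan
}

#' Validate an analysis plan without running it
#'
#' Checks that every `winner:` reference points to an earlier analysis
#' (dependency order respected) and that required fields are present.
#'
#' @param plan An `analysis_plan` (or the bare list of analyses).
#' @return Character vector of findings; empty when the plan is valid.
#' @export
validate_plan <- function(plan) {
  analyses <- if (inherits(plan, "analysis_plan")) plan$analyses else plan
  nm <- names(analyses)
  findings <- character()
  for (i in seq_along(analyses)) {
    a <- analyses[[i]]
    for (fld in c("name", "target", "sources", "t_intro"))
      if (is.null(a[[fld]]))
        findings <- c(findings,
                      paste0("analysis ", i, " lacks field '", fld, "'"))
    refs <- grep("^winner:", a$sources, value = TRUE)
    for (rf in sub("^winner:", "", refs)) {
      j <- match(rf, nm)
      if (is.na(j))
        findings <- c(findings, paste0("analysis '", a$name,
                                       "' references unknown analysis '",
                                       rf, "'"))
      else if (j >= i)
        findings <- c(findings, paste0("analysis '", a$name,
                                       "' references analysis '", rf,
                                       "' that has not run yet"))
    }
  }
  findings
}

#' Run a plan of nested model-choice analyses
#'
#' Analyses are executed in order; the whole plan is validated before any
#' simulation starts. After each analysis the winning scenario's
#' target-founding events are appended to the shared base history, so
#' subsequent analyses condition on previous winners. When an analysis
#' declares representative alternates, every combination is analyzed and
#' the consensus winner is the modal winner across combinations
#' (disagreements are listed verbatim in the report).
#'
#' @param plan An `analysis_plan`.
#' @param dataset Observed [genotype_dataset] containing all referenced
#'   sample sites.
#' @param base A [scenario] with the pre-invasion (native) history.
#' @param prior A [prior_spec] covering all parameters used by the
#'   enumerated scenarios.
#' @param n_per_scenario Reference-table rows per scenario.
#' @param n_trees Forest size for the RF engine.
#' @param tolerance Acceptance fraction for the LDA engine.
#' @param n_loci,model Simulation configuration.
#' @param seed Integer root seed; all randomness derives from it.
#' @return An object of class `pipeline_report`: a data frame with one row
#'   per analysis x combination (winner, vote share, posterior
#'   probability, prior error rate) plus the per-analysis consensus.
#' @export
run_plan <- function(plan, dataset, base, prior, n_per_scenario = 500L,
                     n_trees = 200L, tolerance = 0.1, n_loci = 10L,
                     model = gsm_model(), seed = 1L) {
  stopifnot(inherits(plan, "analysis_plan"))
  err <- validate_plan(plan)
  if (length(err)) stop("invalid plan: ", paste(err, collapse = "; "))
  for (a in plan$analyses) {
    known <- c(names(dataset$genotypes))
    plain <- setdiff(a$sources, grep("^winner:", a$sources, value = TRUE))
    miss <- setdiff(c(plain, a$target), c(known, base$populations))
    if (length(miss))
      stop("analysis '", a$name, "': unknown population(s) ",
           paste(miss, collapse = ", "))
  }
  history <- base
  winners <- character()
  rows <- list()
  consensus <- list()
  sample_config <- population_sizes(dataset)
  for (ai in seq_along(plan$analyses)) {
    a <- plan$analyses[[ai]]
    sources <- vapply(a$sources, function(s) {
      if (startsWith(s, "winner:"))
        plan$analyses[[sub("^winner:", "", s)]]$target
      else s
    }, character(1L))
    combos <- list(sources)
    if (!is.null(a$alternates)) {
      grid <- expand.grid(a$alternates, stringsAsFactors = FALSE)
      combos <- lapply(seq_len(nrow(grid)), function(g) {
        s <- sources
        for (lbl in names(a$alternates)) s[s == lbl] <- grid[g, lbl]
        s
      })
    }
    combo_winners <- character()
    winner_objs <- list()
    for (ci in seq_along(combos)) {
      src <- combos[[ci]]
      competing <- enumerate_target_scenarios(src, a$target,
                                              base = history,
                                              t_intro = a$t_intro)
      pops_used <- unique(unlist(lapply(competing, function(s)
        setdiff(s$populations, s$ghosts))))
      pops_used <- intersect(names(dataset$genotypes), pops_used)
      obs <- compute_stats(subset_populations(dataset, pops_used), "full")
      tab <- build_reference_table(competing, prior, n_per_scenario,
                                   sample_config[pops_used], n_loci,
                                   model = model, stat_set = "full",
                                   seed = row_seed(seed, ai * 131L + ci))
      engine <- if (is.null(a$engine)) "rf" else a$engine
      if (engine %in% c("rf", "both")) {
        res <- rf_model_choice(tab, obs, n_trees = n_trees,
                               seed = row_seed(seed, ai * 577L + ci))
        rows[[length(rows) + 1L]] <- data.frame(
          analysis = a$name, combination = ci, engine = "rf",
          winner = res$best,
          support = max(res$vote_share),
          posterior = res$posterior_probability,
          prior_error = res$prior_error_rate)
        combo_winners <- c(combo_winners, res$best)
        winner_objs[[res$best]] <- competing[[
          which(vapply(competing, `[[`, character(1L), "name") ==
                  res$best)]]
      }
      if (engine %in% c("lda", "both")) {
        res <- lda_model_choice(tab, obs, tolerance = tolerance,
                                seed = row_seed(seed, ai * 733L + ci))
        perr <- prior_error_rate_lda(tab, tolerance, n_pseudo = 100L,
                                     seed = row_seed(seed, ai * 881L + ci))
        rows[[length(rows) + 1L]] <- data.frame(
          analysis = a$name, combination = ci, engine = "lda",
          winner = res$best,
          support = max(res$probabilities),
          posterior = max(res$probabilities),
          prior_error = perr)
        if (!(engine == "both")) {
          combo_winners <- c(combo_winners, res$best)
          winner_objs[[res$best]] <- competing[[
            which(vapply(competing, `[[`, character(1L), "name") ==
                    res$best)]]
        }
      }
    }
    tabw <- table(combo_winners)
    consensus_winner <- names(tabw)[which.max(tabw)]
    consensus[[a$name]] <- list(winner = consensus_winner,
                                disagreements = combo_winners[
                                  combo_winners != consensus_winner])
    winners <- c(winners, consensus_winner)
    # fold the winning founding events into the shared history
    history <- winner_objs[[consensus_winner]]
    history$name <- paste0("history-after-", a$name)
  }
  structure(list(results = do.call(rbind, rows), consensus = consensus,
                 seed = seed),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report (seed", x$seed, ")\n")
  print(x$results, row.names = FALSE, digits = 3)
  for (nm in names(x$consensus))
    cat("  consensus[", nm, "]: ", x$consensus[[nm]]$winner, "\n",
        sep = "")
  invisible(x)
}

#' Compare the RF and LDA engines on equally sized reference tables
#'
#' For each seed, builds a reference table of `small_n` rows per scenario
#' for the given competing set and computes the RF out-of-bag prior error
#' and the LDA prior error on the same table; optionally also the LDA
#' prior error on a larger table of `large_n` rows per scenario.
#'
#' @param scenarios Competing [scenario] list.
#' @param prior A [prior_spec] (or list, one per scenario).
#' @param sample_config,n_loci,model Simulation configuration.
#' @param small_n,large_n Rows per scenario (set `large_n = NULL` to skip).
#' @param seeds Integer vector of root seeds (>= 1 entries).
#' @param n_trees Forest size.
#' @param tolerance LDA acceptance fraction.
#' @param n_pseudo Pseudo-observed datasets per LDA error estimate.
#' @return Data frame with one row per seed: `rf_error_small`,
#'   `lda_error_small`, and `lda_error_large` when requested.
#' @export
compare_engines <- function(scenarios, prior, sample_config, n_loci = 10L,
                            model = gsm_model(), small_n = 300L,
                            large_n = NULL, seeds = 1:10,
                            n_trees = 500L, tolerance = 0.01,
                            n_pseudo = 100L) {
  if (!is.null(large_n)) stopifnot(small_n < large_n)
  out <- lapply(seeds, function(s) {
    tab <- build_reference_table(scenarios, prior, small_n, sample_config,
                                 n_loci, model = model, stat_set = "full",
                                 seed = s)
    rf_err <- prior_error_rate_rf(tab, n_trees = n_trees, seed = s)
    lda_err <- prior_error_rate_lda(tab, tolerance = tolerance,
                                    n_pseudo = n_pseudo, seed = s)
    row <- data.frame(seed = s, rf_error_small = rf_err,
                      lda_error_small = lda_err)
    if (!is.null(large_n)) {
      tab_l <- build_reference_table(scenarios, prior, large_n,
                                     sample_config, n_loci, model = model,
                                     stat_set = "full", seed = s + 5000L)
      row$lda_error_large <- prior_error_rate_lda(tab_l, tolerance,
                                                  n_pseudo = n_pseudo,
                                                  seed = s)
    }
    row
  })
  do.call(rbind, out)
}
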