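# Reference tables: scenario index + parameter vectors + summary-statistic
# matrix, the training object for ABC model choice and estimation.

row_seed <- function(root_seed, idx, attempt = 0L) {
  as.integer((as.numeric(root_seed) %% 2147483647 * 1000003 +
                idx * 7919 + attempt * 31) %% 2147483647)
}

#' Build a reference table by simulation
#'
#' Simulates `n_per_scenario` datasets per competing scenario with
#' parameters drawn from the prior, computes the chosen statistic set for
#' each, and stacks everything into a reference table. Every row uses a
#' seed derived from the root seed and the row index, so tables are
#' reproducible and independent of any parallel execution order. Rows whose
#' dataset yields non-finite statistics (e.g. zero polymorphism) are
#' resimulated with a fresh derived seed; the number of such events is
#' recorded.
#'
#' @param scenarios List of [scenario] objects (the competing set).
#' @param prior A [prior_spec], or a list of one per scenario.
#' @param n_per_scenario Simulated datasets per scenario.
#' @param sample_config Named diploid sample sizes.
#' @param n_loci Number of unlinked microsatellite loci.
#' @param model A [gsm_model]; if the prior draws parameters named `mu`
#'   and/or `p_geom`, those override the model's values row-wise.
#' @param stat_set `"full"` or `"estimation"`.
#' @param triplets Declared admixture triplets for the estimation set.
#' @param seed Integer root seed.
#' @param workers Number of worker processes (results are identical for
#'   any value; forked via `parallel::mclapply` when > 1).
#' @param max_retries Resimulation budget per row.
#' @return An object of class `reference_table` with fields `scenario`
#'   (factor), `params` (data frame), `stats` (numeric matrix),
#'   `scenario_names`, `prior`, and the simulation configuration.
#' @export
build_reference_table <- function(scenarios, prior, n_per_scenario,
                                  sample_config, n_loci = 10L,
                                  model = gsm_model(),
                                  stat_set = c("full", "estimation"),
                                  triplets = list(), seed = 1L,
                                  workers = 1L, max_retries = 20L) {
  stat_set <- match.arg(stat_set)
  stopifnot(n_per_scenario >= 1L, length(scenarios) >= 1L)
  priors <- if (inherits(prior, "prior_spec"))
    rep(list(prior), length(scenarios)) else prior
  stopifnot(length(priors) == length(scenarios))
  scen_names <- vapply(scenarios, `[[`, character(1L), "name")

  jobs <- expand.grid(row = seq_len(n_per_scenario),
                      scen = seq_along(scenarios))
  sim_one <- function(k) {
    si <- jobs$scen[k]
    n_retry <- 0L
    for (attempt in 0:max_retries) {
      set.seed(row_seed(seed, k, attempt))
      par <- tryCatch(draw_parameters(priors[[si]], seed = NULL),
                      error = function(e) NULL)
      if (is.null(par)) { n_retry <- n_retry + 1L; next }
      mod <- model
      if ("mu" %in% names(par)) mod$mu <- par[["mu"]]
      if ("p_geom" %in% names(par)) mod$p_geom <- par[["p_geom"]]
      st <- tryCatch({
        d <- simulate_dataset(scenarios[[si]], par, sample_config, n_loci,
                              model = mod)
        compute_stats(d, stat_set, triplets)
      }, error = function(e) NULL)
      if (!is.null(st) && all(is.finite(st)))
        return(list(scen = si, par = par, st = st, retries = n_retry))
      n_retry <- n_retry + 1L
    }
    stop("repeated simulation failure for scenario '", scen_names[si], "'")
  }
  rows <- if (workers > 1L)
    parallel::mclapply(seq_len(nrow(jobs)), sim_one, mc.cores = workers)
  else lapply(seq_len(nrow(jobs)), sim_one)

  par_names <- unique(unlist(lapply(rows, function(r) names(r$par))))
  params <- as.data.frame(t(vapply(rows, function(r) {
    v <- setNames(rep(NA_real_, length(par_names)), par_names)
    v[names(r$par)] <- r$par
    v
  }, numeric(length(par_names)))))
  stats <- t(vapply(rows, `[[`, rows[[1L]]$st, "st"))
  colnames(stats) <- names(rows[[1L]]$st)
  structure(list(
    scenario = factor(scen_names[vapply(rows, `[[`, integer(1L), "scen")],
                      levels = scen_names),
    params = params,
    stats = stats,
    scenario_names = scen_names,
    scenarios = scenarios,
    prior = priors,
    prior_set = priors[[1L]]$set,
    stat_set = stat_set,
    triplets = triplets,
    sample_config = sample_config,
    n_loci = n_loci,
    model = model,
    seed = seed,
    n_resimulated = sum(vapply(rows, `[[`, integer(1L), "retries"))),
    class = "reference_table")
}

#' @export
print.reference_table <- function(x, ...) {
  cat("reference_table:", nrow(x$stats), "rows,",
      ncol(x$stats), "statistics,",
      length(x$scenario_names), "scenario(s)\n")
  print(table(x$scenario))
  invisible(x)
}

#' Restrict a reference table to one scenario
#' @param table A `reference_table`.
#' @param scenario_name Name of the scenario to keep.
#' @export
subset_scenario <- function(table, scenario_name) {
  if (!scenario_name %in% table$scenario_names)
    stop("unknown scenario: ", scenario_name)
  keep <- table$scenario == scenario_name
  out <- table
  out$scenario <- factor(as.character(table$scenario[keep]),
                         levels = scenario_name)
  out$params <- table$params[keep, , drop = FALSE]
  out$stats <- table$stats[keep, , drop = FALSE]
  out$scenario_names <- scenario_name
  keep_sc <- vapply(table$scenarios, function(s)
    s$name == scenario_name, logical(1L))
  out$scenarios <- table$scenarios[keep_sc]
  attr(out, "lda") <- NULL
  out
}

#' Restrict a reference table to a subset of its statistic columns
#' @param table A `reference_table`.
#' @param stat_names Statistic names to keep (must all be present).
#' @export
subset_stats <- function(table, stat_names) {
  missing <- setdiff(stat_names, colnames(table$stats))
  if (length(missing))
    stop("statistics not in table: ", paste(head(missing, 3L),
                                            collapse = ", "))
  out <- table
  out$stats <- table$stats[, stat_names, drop = FALSE]
  attr(out, "lda") <- NULL
  out
}

REFTABLE_FORMAT_VERSION <- 1L

#' Save / load a reference table
#'
#' Rows are stored in a Feather (Arrow) columnar file; metadata (scenario
#' and statistic names, prior declarations, seeds, format version) goes to
#' a JSON sidecar `<path>.json`. The round trip is lossless; a version
#' mismatch or truncated file raises an explicit error.
#'
#' @param table A `reference_table`.
#' @param path File path (the sidecar gets `.json` appended).
#' @return `save_table` returns `path` invisibly; `load_table` the table.
#' @export
save_table <- function(table, path) {
  stopifnot(inherits(table, "reference_table"))
  df <- data.frame(.scenario = as.character(table$scenario),
                   check.names = FALSE)
  for (nm in names(table$params)) df[[paste0(".p.", nm)]] <- table$params[[nm]]
  for (j in seq_len(ncol(table$stats)))
    df[[colnames(table$stats)[j]]] <- table$stats[, j]
  arrow::write_feather(df, path)
  meta <- list(format_version = REFTABLE_FORMAT_VERSION,
               scenario_names = table$scenario_names,
               stat_names = colnames(table$stats),
               param_names = names(table$params),
               prior_set = table$prior_set,
               stat_set = table$stat_set,
               triplets = table$triplets,
               sample_config = as.list(table$sample_config),
               n_loci = table$n_loci,
               # rate_shape may be Inf, which JSON cannot carry as a number
               model = within(unclass(table$model),
                              rate_shape <- as.character(rate_shape)),
               seed = table$seed,
               n_resimulated = table$n_resimulated)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_table
#' @export
load_table <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing metadata sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (!identical(as.integer(meta$format_version), REFTABLE_FORMAT_VERSION))
    stop("reference-table format version mismatch: file has ",
         meta$format_version, ", this build reads ",
         REFTABLE_FORMAT_VERSION)
  df <- tryCatch(as.data.frame(arrow::read_feather(path)),
                 error = function(e)
                   stop("cannot read reference table (corrupt or ",
                        "truncated file): ", conditionMessage(e)))
  pn <- meta$param_names
  params <- df[paste0(".p.", pn)]
  names(params) <- pn
  stats <- as.matrix(df[meta$stat_names])
  model <- gsm_model(mu = meta$model$mu, p_geom = meta$model$p_geom,
                     window_min = meta$model$window_min,
                     window_width = meta$model$window_max -
                       meta$model$window_min + 1L,
                     rate_shape = as.numeric(meta$model$rate_shape),
                     root_allele = meta$model$root_allele)
  structure(list(
    scenario = factor(df$.scenario, levels = meta$scenario_names),
    params = params, stats = stats,
    scenario_names = meta$scenario_names,
    scenarios = NULL, prior = NULL,
    prior_set = meta$prior_set, stat_set = meta$stat_set,
    triplets = meta$triplets,
    sample_config = unlist(meta$sample_config),
    n_loci = meta$n_loci, model = model, seed = meta$seed,
    n_resimulated = meta$n_resimulated),
    class = "reference_table")
}

#' Export a reference table to CSV
#' @param table A `reference_table`.
#' @param path Output CSV path.
#' @export
export_table_csv <- function(table, path) {
  df <- data.frame(scenario = as.character(table$scenario), table$params,
                   table$stats, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
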