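# Invasion scenarios as backward-time demographic event lists, prior
# specifications, and scenario-set enumeration.
#
# Time runs backward from sampling (time 0) in generations. An introduction
# is modeled as a divergence without subsequent gene flow from its source(s),
# immediately preceded (in forward time: followed) by a bottleneck of
# duration db at size Nb, i.e. a SIZE_CHANGE to Nb at time t_intro - db and
# the merge itself at t_intro. Event times, sizes and admixture rates may be
# numbers or character expressions in parameter names ("t_intro - db_X"),
# resolved against a drawn parameter vector.

EVENT_CODES <- c(sample = 1, divergence = 2, admixture = 3, size_change = 4)

#' Declare an invasion scenario
#'
#' @param name Scenario name.
#' @param populations Character vector of population labels (sampled and
#'   ghost populations alike).
#' @param ne Named list/vector giving each population's stable diploid
#'   effective size: a number or a parameter-name expression.
#' @param events Data frame with columns `time`, `type` (one of `sample`,
#'   `divergence`, `admixture`, `size_change`), `pop`, `source1`, `source2`,
#'   `value`. `time` and `value` may be expressions in parameter names.
#'   For `sample` events `value` is the diploid sample size (NA means "take
#'   it from the sample configuration at simulation time"); for `admixture`
#'   it is the probability r that a lineage of `pop` joins `source1` (else
#'   `source2`); for `size_change` the new diploid size.
#' @param ghosts Labels of unsampled (ghost) populations.
#' @return An object of class `scenario`.
#' @export
scenario <- function(name, populations, ne, events,
                     ghosts = character()) {
  stopifnot(is.character(populations), length(populations) >= 1L)
  if (anyDuplicated(populations)) stop("population labels must be unique")
  need <- c("time", "type", "pop", "source1", "source2", "value")
  for (col in setdiff(need, names(events))) events[[col]] <- NA
  events <- events[need]
  events$type <- as.character(events$type)
  if (!all(events$type %in% names(EVENT_CODES)))
    stop("unknown event type(s): ",
         paste(setdiff(events$type, names(EVENT_CODES)), collapse = ", "))
  structure(list(name = name, populations = populations,
                 ne = as.list(ne), events = events,
                 ghosts = ghosts),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("scenario '", x$name, "': ", length(x$populations),
      " population(s), ", nrow(x$events), " event(s)\n", sep = "")
  invisible(x)
}

#' Construct a demographic event row
#'
#' Convenience constructor for one row of a scenario's event table; rows
#' are combined with `rbind()`.
#'
#' @param type One of `"sample"`, `"divergence"`, `"admixture"`,
#'   `"size_change"`.
#' @param pop Population the event applies to (the derived population for
#'   merges).
#' @param time Event time in generations before sampling; a number or a
#'   parameter expression string.
#' @param source1,source2 Source populations for merges.
#' @param value Event value: diploid sample size (`NA` = take from the
#'   sample configuration), admixture rate, or new effective size; may be
#'   a parameter expression.
#' @return One-row data frame.
#' @export
ev <- function(type, pop, time, source1 = NA, source2 = NA, value = NA) {
  data.frame(time = as.character(time), type = type, pop = pop,
             source1 = source1, source2 = source2,
             value = as.character(value), stringsAsFactors = FALSE)
}

resolve_expr <- function(x, env) {
  if (is.na(x)) return(NA_real_)
  v <- suppressWarnings(as.numeric(x))
  if (!is.na(v)) return(v)
  out <- tryCatch(eval(parse(text = x), envir = env),
                  error = function(e)
                    stop("cannot resolve '", x, "': ", conditionMessage(e)))
  as.numeric(out)
}

#' Bind a scenario to a parameter vector
#'
#' Resolves all symbolic times/sizes/rates against `params` and returns the
#' numeric event matrix (sorted by time) and effective-size vector consumed
#' by the simulator.
#'
#' @param s A [scenario].
#' @param params Named numeric parameter vector.
#' @param sample_config Named diploid sample sizes for populations whose
#'   `sample` events have `value = NA`.
#' @return List with `events` (numeric matrix), `ne` (numeric vector) and
#'   `pop_index` (label -> 1-based index).
#' @export
bind_scenario <- function(s, params, sample_config = NULL) {
  stopifnot(inherits(s, "scenario"))
  env <- list2env(as.list(params))
  pop_index <- setNames(seq_along(s$populations), s$populations)
  ne <- vapply(s$populations, function(p) {
    v <- s$ne[[p]]
    if (is.null(v)) stop("no effective size declared for population ", p)
    if (is.character(v)) resolve_expr(v, env) else as.numeric(v)
  }, numeric(1L))
  if (any(!is.finite(ne)) || any(ne < 2))
    stop("effective sizes must be finite and >= 2")
  evd <- s$events
  n <- nrow(evd)
  m <- matrix(0, n, 6L)
  for (i in seq_len(n)) {
    m[i, 1L] <- resolve_expr(evd$time[i], env)
    m[i, 2L] <- EVENT_CODES[[evd$type[i]]]
    m[i, 3L] <- pop_index[[evd$pop[i]]]
    m[i, 4L] <- if (is.na(evd$source1[i])) 0 else pop_index[[evd$source1[i]]]
    m[i, 5L] <- if (is.na(evd$source2[i])) 0 else pop_index[[evd$source2[i]]]
    val <- evd$value[i]
    if (evd$type[i] == "sample" && (is.na(val) || val == "NA")) {
      if (is.null(sample_config) || is.na(sample_config[evd$pop[i]]))
        stop("no sample size for population ", evd$pop[i])
      m[i, 6L] <- sample_config[[evd$pop[i]]]
    } else {
      m[i, 6L] <- resolve_expr(val, env)
    }
  }
  if (any(!is.finite(m[, 1L])) || any(m[, 1L] < 0))
    stop("event times must be finite and non-negative")
  adx <- m[, 2L] == EVENT_CODES[["admixture"]]
  if (any(adx & (m[, 6L] < 0 | m[, 6L] > 1)))
    stop("admixture rates must lie in [0, 1]")
  ord <- order(m[, 1L], m[, 2L])
  list(events = m[ord, , drop = FALSE], ne = ne, pop_index = pop_index)
}

#' Validate a scenario's structural invariants
#'
#' Returns a character vector of human-readable findings; an empty vector
#' means the scenario is well formed. If `params` is supplied, time-ordering
#' checks are run on the bound (numeric) event list as well.
#'
#' @param s A [scenario].
#' @param params Optional parameter vector for the time-consistency checks.
#' @param sample_config Optional sample sizes used during binding.
#' @return Character vector of findings (possibly empty).
#' @export
validate_scenario <- function(s, params = NULL, sample_config = NULL) {
  findings <- character()
  add <- function(msg) findings <<- c(findings, msg)
  if (anyDuplicated(s$populations)) add("duplicate population labels")
  sampled <- setdiff(s$populations, s$ghosts)
  refs <- unique(stats::na.omit(c(s$events$pop, s$events$source1,
                                  s$events$source2)))
  unknown <- setdiff(refs, s$populations)
  if (length(unknown))
    add(paste("event references unknown population(s):",
              paste(unknown, collapse = ", ")))
  for (p in sampled) {
    k <- sum(s$events$type == "sample" & s$events$pop == p)
    if (k != 1L)
      add(paste0("population ", p, " has ", k,
                 " sample events (expected exactly 1)"))
  }
  for (p in s$ghosts) {
    if (any(s$events$type == "sample" & s$events$pop == p))
      add(paste0("ghost population ", p, " must not be sampled"))
  }
  if (!is.null(params)) {
    b <- tryCatch(bind_scenario(s, params, sample_config),
                  error = function(e) {
                    add(paste("binding failed:", conditionMessage(e)))
                    NULL
                  })
    if (!is.null(b)) {
      m <- b$events
      merge_code <- EVENT_CODES[c("divergence", "admixture")]
      # time at which each population merges away (Inf if never)
      gone <- rep(Inf, length(b$pop_index))
      for (i in seq_len(nrow(m)))
        if (m[i, 2L] %in% merge_code)
          gone[m[i, 3L]] <- min(gone[m[i, 3L]], m[i, 1L])
      for (i in seq_len(nrow(m))) {
        t <- m[i, 1L]
        tgt <- switch(as.character(m[i, 2L]),
                      "2" = m[i, 4L],
                      "3" = c(m[i, 4L], m[i, 5L]),
                      "1" = m[i, 3L],
                      numeric())
        for (p in tgt) if (t > gone[p])
          add(paste0("lineages enter population ",
                     names(b$pop_index)[p], " at time ", t,
                     " after it merged away at time ", gone[p]))
      }
    }
  }
  findings
}

#' Convert a first-record date to a divergence time in generations
#'
#' @param first_record_year Calendar year of the first record in the
#'   invaded area.
#' @param sampling_year Calendar year of sampling.
#' @param generations_per_year Generations per year (default 12).
#' @return Number of generations before sampling.
#' @export
first_record_to_generations <- function(first_record_year, sampling_year,
                                        generations_per_year = 12L) {
  if (sampling_year < first_record_year)
    stop("sampling predates the first record")
  if (generations_per_year < 1) stop("generations_per_year must be >= 1")
  (sampling_year - first_record_year) * generations_per_year
}

#' Enumerate the competing scenario set for one target population
#'
#' For k candidate sources, builds the k single-source scenarios plus the
#' C(k,2) two-source admixture scenarios (k + k(k-1)/2 in total), each with a
#' founding bottleneck on the target. Singles come first in source order,
#' then pairs in lexicographic order.
#'
#' @param sources Candidate source population labels (length >= 1, distinct).
#' @param target Target (focal) population label, not among the sources.
#' @param base Optional [scenario] providing the shared history of the
#'   source populations; when `NULL` a minimal standalone history is built in
#'   which every other source diverges from the first at time `t_anc`.
#' @param t_intro Divergence time of the target (generations), typically
#'   fixed from the first-record date via [first_record_to_generations()];
#'   a number or parameter expression.
#' @return List of [scenario] objects with deterministic ordering and names
#'   `<target>-from-<s>` / `<target>-admix-<s1>-<s2>`.
#' @export
enumerate_target_scenarios <- function(sources, target, base = NULL,
                                       t_intro = "t_intro") {
  if (length(sources) < 1L) stop("at least one source is required")
  if (anyDuplicated(sources)) stop("duplicate source labels")
  if (target %in% sources) stop("target must not be among the sources")
  if (is.null(base)) {
    pops <- sources
    ne <- setNames(as.list(paste0("N_", sources)), sources)
    events <- do.call(rbind, lapply(sources, function(p)
      ev("sample", p, 0)))
    if (length(sources) > 1L)
      events <- rbind(events, do.call(rbind, lapply(sources[-1L], function(p)
        ev("divergence", p, "t_anc", source1 = sources[1L]))))
    base <- scenario("base", pops, ne, events)
  } else {
    stopifnot(inherits(base, "scenario"))
    missing <- setdiff(sources, base$populations)
    if (length(missing))
      stop("base scenario lacks source population(s): ",
           paste(missing, collapse = ", "))
  }
  t_bn <- paste0("(", t_intro, ") - db_", target)
  founding <- function(merge_events, tag) {
    sc <- base
    sc$name <- tag
    sc$populations <- c(sc$populations, target)
    sc$ne[[target]] <- paste0("N_", target)
    sc$events <- rbind(sc$events,
                       ev("sample", target, 0),
                       ev("size_change", target, t_bn,
                          value = paste0("Nb_", target)),
                       merge_events)
    sc
  }
  singles <- lapply(sources, function(s)
    founding(ev("divergence", target, t_intro, source1 = s),
             paste0(target, "-from-", s)))
  pairs <- list()
  if (length(sources) >= 2L) {
    cmb <- combn(seq_along(sources), 2L)
    pairs <- lapply(seq_len(ncol(cmb)), function(j) {
      s1 <- sources[cmb[1L, j]]; s2 <- sources[cmb[2L, j]]
      founding(ev("admixture", target, t_intro, source1 = s1,
                  source2 = s2, value = paste0("r_", target)),
               paste0(target, "-admix-", s1, "-", s2))
    })
  }
  c(singles, pairs)
}

#' Declare a prior specification
#'
#' @param params List of parameter declarations created with
#'   [prior_param()].
#' @param constraints Character vector of ordering constraints between
#'   parameters (or against constants), e.g. `"t_anc > t_intro"`; enforced
#'   by rejection resampling.
#' @param set Prior-set label; `"set1"` (rectangular) or `"set2"` (peaked).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(params, constraints = character(), set = "set1") {
  nm <- vapply(params, `[[`, character(1L), "name")
  if (anyDuplicated(nm)) stop("duplicate parameter names in prior")
  structure(list(params = setNames(params, nm),
                 constraints = constraints, set = set),
            class = "prior_spec")
}

#' Declare one parameter's prior distribution
#'
#' @param name Parameter name.
#' @param dist One of `"uniform"`, `"loguniform"`, `"truncnorm"`, `"fixed"`.
#' @param min,max Finite bounds (for `"fixed"`, `min` is the value).
#' @param mean,sd Location and scale for `"truncnorm"`; default to the
#'   mid-range and range/6.
#' @export
prior_param <- function(name, dist = "uniform", min = 0, max = 1,
                        mean = NULL, sd = NULL) {
  dist <- match.arg(dist, c("uniform", "loguniform", "truncnorm", "fixed"))
  if (dist != "fixed") {
    if (!is.finite(min) || !is.finite(max) || min >= max)
      stop("bounds must be finite with min < max for parameter ", name)
    if (dist == "loguniform" && min <= 0)
      stop("log-uniform bounds must be positive for parameter ", name)
  }
  if (is.null(mean)) mean <- (min + max) / 2
  if (is.null(sd)) sd <- (max - min) / 6
  list(name = name, dist = dist, min = min, max = max, mean = mean, sd = sd)
}

#' Prior bounds as a two-column matrix
#' @param prior A [prior_spec].
#' @return Matrix with columns `min`, `max` and one row per parameter.
#' @export
prior_bounds <- function(prior) {
  b <- t(vapply(prior$params, function(p) c(p$min, p$max), numeric(2L)))
  colnames(b) <- c("min", "max")
  b
}

draw_one <- function(p) {
  switch(p$dist,
         uniform = runif(1L, p$min, p$max),
         loguniform = exp(runif(1L, log(p$min), log(p$max))),
         truncnorm = {
           lo <- pnorm(p$min, p$mean, p$sd)
           hi <- pnorm(p$max, p$mean, p$sd)
           qnorm(runif(1L, lo, hi), p$mean, p$sd)
         },
         fixed = p$min)
}

#' Draw a parameter vector from a prior specification
#'
#' Ordering constraints are enforced by rejection resampling; a draw is
#' repeated until all constraints hold (up to `max_tries` rejections).
#'
#' @param prior A [prior_spec].
#' @param seed Optional integer seed; `NULL` continues the current RNG
#'   stream (identical seeds give identical vectors).
#' @param max_tries Rejection budget before failing.
#' @return Named numeric vector with attributes `prior_set` and `seed`.
#' @export
draw_parameters <- function(prior, seed = NULL, max_tries = 1000L) {
  stopifnot(inherits(prior, "prior_spec"))
  if (!is.null(seed)) set.seed(seed)
  for (try in seq_len(max_tries)) {
    x <- vapply(prior$params, draw_one, numeric(1L))
    ok <- TRUE
    if (length(prior$constraints)) {
      env <- list2env(as.list(x))
      for (cn in prior$constraints) {
        if (!isTRUE(eval(parse(text = cn), envir = env))) { ok <- FALSE; break }
      }
    }
    if (ok) {
      attr(x, "prior_set") <- prior$set
      attr(x, "seed") <- seed
      return(x)
    }
  }
  stop("prior constraints unsatisfiable after ", max_tries, " rejections")
}
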