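# One-, two- and three-population microsatellite summary statistics,
# averaged over loci, with exact counting rules for the full catalog
# (4P + 8*C(P,2) + 3*C(P,3) statistics for P populations) and the reduced
# estimation subset (2P + C(P,2) + T).
#
# Missing allele copies (sentinel 0) are excluded locus-wise; a locus with
# no usable copies in any member of a pair/triplet is dropped from that
# statistic's average.

# per-locus allele count tables for one population array (n x L x 2)
locus_counts <- function(g) {
  n_loci <- dim(g)[2L]
  lapply(seq_len(n_loci), function(l) {
    a <- c(g[, l, 1L], g[, l, 2L])
    a <- a[a != MISSING_ALLELE]
    if (!length(a)) return(integer())
    table(a)
  })
}

counts_to_freq <- function(cnt) as.numeric(cnt) / sum(cnt)

# --- one-population statistics ---------------------------------------------

one_stats_from_counts <- function(cnts) {
  nal <- het <- vvar <- mgw <- numeric()
  for (cnt in cnts) {
    n <- sum(cnt)
    if (n < 2L) next
    sizes <- as.integer(names(cnt))
    p <- as.numeric(cnt) / n
    nal <- c(nal, length(cnt))
    het <- c(het, n / (n - 1) * (1 - sum(p^2)))
    mean_sz <- sum(sizes * p)
    vvar <- c(vvar, sum(as.numeric(cnt) * (sizes - mean_sz)^2) / (n - 1))
    mgw <- c(mgw, length(cnt) / (diff(range(sizes)) + 1))
  }
  if (!length(nal)) stop("no locus with at least two non-missing copies")
  c(NAL = mean(nal), HET = mean(het), VAR = mean(vvar), MGW = mean(mgw))
}

#' One-population summary statistics
#'
#' Mean (over usable loci) number of alleles, unbiased gene diversity
#' `n/(n-1) * (1 - sum p^2)` with n the non-missing gene copies, sample
#' variance of allele size, and the M ratio of Garza & Williamson
#' (alleles / (allele-size range + 1)).
#'
#' @param dataset A [genotype_dataset].
#' @param population Population label.
#' @return Named numeric vector `NAL`, `HET`, `VAR`, `MGW`.
#' @export
one_sample_stats <- function(dataset, population) {
  g <- dataset$genotypes[[population]]
  if (is.null(g)) stop("unknown population: ", population)
  if (dim(g)[1L] < 1L) stop("empty population: ", population)
  one_stats_from_counts(locus_counts(g))
}

# --- two-population statistics ---------------------------------------------

wc_fst_components <- function(gA, gB) {
  # Weir & Cockerham (1984) variance components a, b, c summed over loci
  # and alleles; individuals with a missing copy at a locus are dropped
  # there. Returns c(a, a+b+c).
  n_loci <- dim(gA)[2L]
  num <- den <- 0
  for (l in seq_len(n_loci)) {
    ga <- gA[, l, , drop = FALSE]; gb <- gB[, l, , drop = FALSE]
    ga <- ga[ga[, 1L, 1L] != 0L & ga[, 1L, 2L] != 0L, 1L, , drop = FALSE]
    gb <- gb[gb[, 1L, 1L] != 0L & gb[, 1L, 2L] != 0L, 1L, , drop = FALSE]
    n1 <- nrow(ga); n2 <- nrow(gb)
    if (n1 < 1L || n2 < 1L) next
    alleles <- sort(unique(c(ga, gb)))
    if (length(alleles) < 2L) next
    r <- 2; nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    if (nbar <= 1 || nc <= 0) next
    for (u in alleles) {
      p1 <- sum(ga == u) / (2 * n1); p2 <- sum(gb == u) / (2 * n2)
      h1 <- sum(xor(ga[, 1L, 1L] == u, ga[, 1L, 2L] == u)) / n1
      h2 <- sum(xor(gb[, 1L, 1L] == u, gb[, 1L, 2L] == u)) / n2
      pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
      s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
      hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
      a <- nbar / nc *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      b <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 -
           (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  c(num = num, den = den)
}

assignment_loglik <- function(gFrom, gTo) {
  # mean over gFrom individuals of the log-likelihood of their multilocus
  # genotype under gTo's allele frequencies, with add-one smoothing over
  # the union of observed allele states
  n_loci <- dim(gFrom)[2L]
  tot <- numeric(dim(gFrom)[1L])
  for (l in seq_len(n_loci)) {
    to <- c(gTo[, l, 1L], gTo[, l, 2L]); to <- to[to != 0L]
    states <- sort(unique(c(to, gFrom[, l, 1L], gFrom[, l, 2L])))
    states <- states[states != 0L]
    if (!length(states)) next
    cnt <- table(factor(to, levels = states))
    q <- (as.numeric(cnt) + 1) / (sum(cnt) + length(states))
    names(q) <- states
    a1 <- gFrom[, l, 1L]; a2 <- gFrom[, l, 2L]
    ok <- a1 != 0L & a2 != 0L
    ll <- rep(0, length(a1))
    ll[ok] <- ifelse(a1[ok] == a2[ok],
                     2 * log(q[as.character(a1[ok])]),
                     log(2) + log(q[as.character(a1[ok])]) +
                       log(q[as.character(a2[ok])]))
    tot <- tot + ll
  }
  mean(tot)
}

shared_allele_distance <- function(gA, gB) {
  # DAS = 1 - mean proportion of shared alleles across between-population
  # individual pairs, averaged over usable loci within a pair. For 2-allele
  # genotypes the shared-allele count (sum of min multiplicities) equals
  # the better of the two copy pairings, which vectorizes over pairs.
  nA <- dim(gA)[1L]; nB <- dim(gB)[1L]; n_loci <- dim(gA)[2L]
  shared_sum <- matrix(0, nA, nB)
  usable <- matrix(0L, nA, nB)
  for (l in seq_len(n_loci)) {
    a1 <- gA[, l, 1L]; a2 <- gA[, l, 2L]
    b1 <- gB[, l, 1L]; b2 <- gB[, l, 2L]
    ok <- outer(a1 != 0L & a2 != 0L, b1 != 0L & b2 != 0L, "&")
    m11 <- outer(a1, b1, "==") + outer(a2, b2, "==")
    m12 <- outer(a1, b2, "==") + outer(a2, b1, "==")
    sh <- pmax(m11, m12) / 2
    shared_sum <- shared_sum + ifelse(ok, sh, 0)
    usable <- usable + ok
  }
  has <- usable > 0L
  if (!any(has)) return(NA_real_)
  1 - mean(shared_sum[has] / usable[has])
}

delta_mu_sq <- function(cntA, cntB) {
  vals <- numeric()
  for (l in seq_along(cntA)) {
    ca <- cntA[[l]]; cb <- cntB[[l]]
    if (!length(ca) || !length(cb)) next
    ma <- sum(as.integer(names(ca)) * counts_to_freq(ca))
    mb <- sum(as.integer(names(cb)) * counts_to_freq(cb))
    vals <- c(vals, (ma - mb)^2)
  }
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Two-population summary statistics
#'
#' Pooled-sample mean allele count, gene diversity and allele-size variance;
#' the multi-locus Weir–Cockerham FST ratio estimator (raw value, not
#' clamped); directional mean assignment log-likelihoods; the shared-allele
#' distance DAS; and the squared difference in mean allele size (delta-mu
#' squared) averaged over loci.
#'
#' @param dataset A [genotype_dataset].
#' @param popA,popB Population labels.
#' @return Named numeric vector of the 8 pairwise statistics
#'   (`NAL2`, `HET2`, `VAR2`, `FST`, `LIK_AB`, `LIK_BA`, `DAS`, `DM2`).
#' @export
two_sample_stats <- function(dataset, popA, popB) {
  gA <- dataset$genotypes[[popA]]; gB <- dataset$genotypes[[popB]]
  if (is.null(gA) || is.null(gB)) stop("unknown population label")
  pooled <- array(0L, dim = c(dim(gA)[1L] + dim(gB)[1L], dim(gA)[2L], 2L))
  pooled[seq_len(dim(gA)[1L]), , ] <- gA
  pooled[dim(gA)[1L] + seq_len(dim(gB)[1L]), , ] <- gB
  ps <- one_stats_from_counts(locus_counts(pooled))
  comp <- wc_fst_components(gA, gB)
  fst <- if (comp[["den"]] > 0) comp[["num"]] / comp[["den"]] else NA_real_
  cA <- locus_counts(gA); cB <- locus_counts(gB)
  c(NAL2 = ps[["NAL"]], HET2 = ps[["HET"]], VAR2 = ps[["VAR"]],
    FST = fst,
    LIK_AB = assignment_loglik(gA, gB),
    LIK_BA = assignment_loglik(gB, gA),
    DAS = shared_allele_distance(gA, gB),
    DM2 = delta_mu_sq(cA, cB))
}

#' Three-population admixture statistic (AML)
#'
#' Crude maximum-likelihood-style admixture estimate: per locus, the
#' least-squares coefficient of the admixed population's allele frequencies
#' regressed on the two source frequency profiles,
#' r = sum((f_adm - f_s2)(f_s1 - f_s2)) / sum((f_s1 - f_s2)^2),
#' averaged over loci where the sources differ and clipped to `[0, 1]`.
#' Returns the estimated fraction contributed by `source1`.
#'
#' @param dataset A [genotype_dataset].
#' @param admixed,source1,source2 Distinct population labels.
#' @return Estimated admixture fraction in `[0, 1]`; if the sources are
#'   identical at every locus, 0.5 with attribute `degenerate = TRUE`.
#' @export
three_sample_stats <- function(dataset, admixed, source1, source2) {
  if (anyDuplicated(c(admixed, source1, source2)))
    stop("the three populations must be distinct")
  ca <- locus_counts(dataset$genotypes[[admixed]])
  c1 <- locus_counts(dataset$genotypes[[source1]])
  c2 <- locus_counts(dataset$genotypes[[source2]])
  rs <- numeric()
  for (l in seq_along(ca)) {
    if (!length(ca[[l]]) || !length(c1[[l]]) || !length(c2[[l]])) next
    states <- sort(unique(c(as.integer(names(ca[[l]])),
                            as.integer(names(c1[[l]])),
                            as.integer(names(c2[[l]])))))
    f <- function(cnt) {
      x <- setNames(rep(0, length(states)), states)
      x[names(cnt)] <- counts_to_freq(cnt)
      x
    }
    fa <- f(ca[[l]]); f1 <- f(c1[[l]]); f2 <- f(c2[[l]])
    d <- sum((f1 - f2)^2)
    if (d < 1e-12) next
    rs <- c(rs, sum((fa - f2) * (f1 - f2)) / d)
  }
  if (!length(rs)) {
    out <- 0.5
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  min(max(mean(rs), 0), 1)
}

# --- catalog ----------------------------------------------------------------

pair_stat_names <- c("NAL2", "HET2", "VAR2", "FST", "LIK_AB", "LIK_BA",
                     "DAS", "DM2")

#' Names of the full summary-statistic catalog
#'
#' 4 one-sample statistics per population, 8 two-sample statistics per
#' unordered pair (including both directions of the assignment likelihood)
#' and 3 admixture arrangements per unordered triplet: 4P + 8*C(P,2) +
#' 3*C(P,3) names in a deterministic order.
#'
#' @param populations Character vector of population labels.
#' @return Character vector of statistic names.
#' @export
catalog_names <- function(populations) {
  P <- length(populations)
  nm <- unlist(lapply(populations, function(p)
    paste0(c("NAL", "HET", "VAR", "MGW"), "_", p)))
  if (P >= 2L) {
    cmb <- combn(populations, 2L)
    nm <- c(nm, unlist(lapply(seq_len(ncol(cmb)), function(j)
      paste0(pair_stat_names, "_", cmb[1L, j], ".", cmb[2L, j]))))
  }
  if (P >= 3L) {
    trp <- combn(populations, 3L)
    nm <- c(nm, unlist(lapply(seq_len(ncol(trp)), function(j) {
      t3 <- trp[, j]
      vapply(1:3, function(a)
        paste0("AML_", t3[a], ".", paste(t3[-a], collapse = ".")),
        character(1L))
    })))
  }
  nm
}

#' Compute the full summary-statistic catalog for a dataset
#'
#' @param dataset A [genotype_dataset].
#' @param triplets `"all"` (every arrangement of every unordered triplet)
#'   or a list of `c(admixed, source1, source2)` label triplets.
#' @return Named numeric vector (a stat vector) with attribute `arity`
#'   giving each statistic's population arity.
#' @export
full_catalog <- function(dataset, triplets = "all") {
  pops <- names(dataset$genotypes)
  vals <- c()
  for (p in pops) {
    s <- one_sample_stats(dataset, p)
    vals <- c(vals, setNames(s, paste0(names(s), "_", p)))
  }
  if (length(pops) >= 2L) {
    cmb <- combn(pops, 2L)
    for (j in seq_len(ncol(cmb))) {
      s <- two_sample_stats(dataset, cmb[1L, j], cmb[2L, j])
      vals <- c(vals, setNames(s, paste0(names(s), "_", cmb[1L, j], ".",
                                         cmb[2L, j])))
    }
  }
  trip_list <- list()
  if (identical(triplets, "all") && length(pops) >= 3L) {
    trp <- combn(pops, 3L)
    for (j in seq_len(ncol(trp))) for (a in 1:3)
      trip_list[[length(trip_list) + 1L]] <-
        c(trp[a, j], trp[-a, j])
  } else if (is.list(triplets)) {
    trip_list <- triplets
  }
  for (t3 in trip_list) {
    v <- three_sample_stats(dataset, t3[1L], t3[2L], t3[3L])
    vals <- c(vals, setNames(as.numeric(v),
                             paste0("AML_", t3[1L], ".", t3[2L], ".",
                                    t3[3L])))
  }
  arity <- rep(1L, length(vals))
  arity[grepl("\\.", names(vals))] <- 2L
  arity[startsWith(names(vals), "AML_")] <- 3L
  attr(vals, "arity") <- arity
  vals
}

#' Names of the reduced estimation statistic set
#'
#' Mean allele count and gene diversity per population, all pairwise FST
#' values, and one admixture statistic per declared triplet:
#' 2P + C(P,2) + T names.
#'
#' @param populations Character vector of population labels.
#' @param triplets List of `c(admixed, source1, source2)` triplets.
#' @return Character vector of statistic names.
#' @export
estimation_subset_names <- function(populations, triplets = list()) {
  triplets <- lapply(triplets, function(t3) {
    bad <- setdiff(t3, populations)
    if (length(bad))
      stop("triplet references unknown population(s): ",
           paste(bad, collapse = ", "))
    # order the sources as in the population list so names match the
    # catalog's arrangement naming
    c(t3[1L], t3[-1L][order(match(t3[-1L], populations))])
  })
  nm <- unlist(lapply(populations, function(p)
    paste0(c("NAL", "HET"), "_", p)))
  if (length(populations) >= 2L) {
    cmb <- combn(populations, 2L)
    nm <- c(nm, paste0("FST_", cmb[1L, ], ".", cmb[2L, ]))
  }
  c(nm, vapply(triplets, function(t3)
    paste0("AML_", t3[1L], ".", t3[2L], ".", t3[3L]), character(1L)))
}

#' Compute the reduced estimation statistic set
#'
#' @param dataset A [genotype_dataset].
#' @param triplets List of declared `c(admixed, source1, source2)` triplets.
#' @return Named numeric stat vector of length 2P + C(P,2) + T.
#' @export
estimation_subset <- function(dataset, triplets = list()) {
  pops <- names(dataset$genotypes)
  nm <- estimation_subset_names(pops, triplets)
  norm_triplets <- lapply(triplets, function(t3)
    c(t3[1L], t3[-1L][order(match(t3[-1L], pops))]))
  full <- full_catalog(dataset, triplets = norm_triplets)
  out <- full[nm]
  names(out) <- nm
  attr(out, "arity") <- NULL
  out
}

#' Held-out test statistics for posterior predictive checking
#'
#' The full catalog minus the estimation subset, order-stable.
#'
#' @param populations Character vector of population labels.
#' @param estimation_names Names of the statistics used for estimation.
#' @return Character vector of remaining statistic names.
#' @export
test_statistic_complement <- function(populations, estimation_names) {
  full <- catalog_names(populations)
  bad <- setdiff(estimation_names, full)
  if (length(bad))
    stop("estimation subset not contained in the catalog: ",
         paste(head(bad, 5L), collapse = ", "))
  setdiff(full, estimation_names)
}

#' Compute a named statistic set for a dataset
#'
#' Dispatches to the full catalog or the reduced estimation set; this is
#' the computation used for every reference-table row and for observed
#' datasets.
#'
#' @param dataset A [genotype_dataset].
#' @param stat_set `"full"` or `"estimation"`.
#' @param triplets Declared admixture triplets (estimation set only).
#' @return Named numeric stat vector.
#' @export
compute_stats <- function(dataset, stat_set = c("full", "estimation"),
                          triplets = list()) {
  stat_set <- match.arg(stat_set)
  if (stat_set == "full") {
    v <- full_catalog(dataset, triplets = "all")
    attr(v, "arity") <- NULL
    v
  } else {
    estimation_subset(dataset, triplets)
  }
}
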