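# Multi-population diploid microsatellite datasets and GenePop I/O.
#
# Alleles are stored as repeat counts (positive integers); 0 is the reserved
# missing-data sentinel. Each population holds an n x L x 2 integer array
# (individuals x loci x allele copies).

MISSING_ALLELE <- 0L

#' Construct a multi-population microsatellite genotype dataset
#'
#' @param genotypes Named list, one element per population, each an integer
#'   array of dimension `c(n_individuals, n_loci, 2)`. Allele values are
#'   repeat counts; `0` codes a missing allele copy.
#' @param loci Character vector of locus labels (defaults to `L1..Lk`).
#' @param motif Integer repeat-motif length per locus (recycled; default 1).
#'
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(genotypes, loci = NULL, motif = 1L) {
  if (!is.list(genotypes) || length(genotypes) < 1L)
    stop("'genotypes' must be a non-empty named list of populations")
  if (is.null(names(genotypes)) || anyDuplicated(names(genotypes)))
    stop("population labels must be present and unique")
  n_loci <- dim(genotypes[[1L]])[2L]
  if (is.null(n_loci) || n_loci < 1L) stop("at least one locus is required")
  if (is.null(loci)) loci <- paste0("L", seq_len(n_loci))
  if (length(loci) != n_loci) stop("'loci' length must match genotype arrays")
  motif <- as.integer(rep_len(motif, n_loci))
  if (any(motif < 1L)) stop("repeat-motif length must be >= 1")
  for (p in names(genotypes)) {
    g <- genotypes[[p]]
    if (!is.array(g) || length(dim(g)) != 3L || dim(g)[3L] != 2L)
      stop("population '", p, "': genotypes must be an n x L x 2 array")
    if (dim(g)[2L] != n_loci)
      stop("population '", p, "': locus count differs from the rest")
    storage.mode(g) <- "integer"
    if (any(g < 0L, na.rm = TRUE) || anyNA(g))
      stop("population '", p, "': allele sizes must be positive integers ",
           "or the missing sentinel 0")
    genotypes[[p]] <- g
  }
  structure(list(genotypes = genotypes, loci = as.character(loci),
                 motif = motif),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  ns <- vapply(x$genotypes, function(g) dim(g)[1L], integer(1L))
  cat("genotype_dataset:", length(ns), "population(s),",
      length(x$loci), "loci\n")
  cat("  individuals per population:",
      paste0(names(ns), "=", ns, collapse = ", "), "\n")
  invisible(x)
}

#' Population labels and sample sizes
#' @param dataset A `genotype_dataset`.
#' @return Named integer vector of diploid sample sizes.
#' @export
population_sizes <- function(dataset) {
  vapply(dataset$genotypes, function(g) dim(g)[1L], integer(1L))
}

#' Restrict a dataset to a subset of populations
#' @param dataset A `genotype_dataset`.
#' @param populations Labels to keep, in the order given.
#' @export
subset_populations <- function(dataset, populations) {
  missing <- setdiff(populations, names(dataset$genotypes))
  if (length(missing))
    stop("unknown population(s): ", paste(missing, collapse = ", "))
  genotype_dataset(dataset$genotypes[populations], dataset$loci,
                   dataset$motif)
}

#' Read a GenePop file
#'
#' Parses the GenePop text dialect: a title line, one locus name per line (or
#' a single comma-separated line), `POP` separators, and individual lines of
#' the form `id , a1a2 a1a2 ...` with 2- or 3-digit allele codes. The codes
#' `00`/`000` denote a missing allele copy and are mapped to the sentinel 0.
#' Populations are named after the first individual of each block, with a
#' trailing `_<number>` stripped when present.
#'
#' @param path Path to a GenePop file.
#' @return A [genotype_dataset].
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 3L) stop("GenePop parse error: file too short")
  body <- lines[-1L]                      # drop title
  is_pop <- toupper(trimws(body)) == "POP"
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop)) stop("GenePop parse error: no POP separator found")
  locus_lines <- body[seq_len(first_pop - 1L)]
  locus_lines <- locus_lines[nzchar(trimws(locus_lines))]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop("GenePop parse error: no locus names")
  n_loci <- length(loci)

  pops <- list(); ids <- list()
  cur <- NULL; cur_ids <- character()
  flush_pop <- function() {
    if (is.null(cur)) return()
    label <- sub("_[0-9]+$", "", cur_ids[1L])
    if (label %in% names(pops)) label <- cur_ids[1L]
    g <- array(unlist(cur), dim = c(2L, n_loci, length(cur)))
    g <- aperm(g, c(3L, 2L, 1L))          # n x L x 2
    pops[[label]] <<- g
    cur <<- NULL; cur_ids <<- character()
  }
  for (k in seq.int(first_pop, length(body))) {
    line <- body[k]
    lineno <- k + 1L
    if (!nzchar(trimws(line))) next
    if (toupper(trimws(line)) == "POP") { flush_pop(); cur <- list(); next }
    parts <- strsplit(line, ",")[[1L]]
    if (length(parts) < 2L)
      stop("GenePop parse error at line ", lineno, ": missing ',' separator")
    id <- trimws(parts[1L])
    codes <- strsplit(trimws(paste(parts[-1L], collapse = ",")), "\\s+")[[1L]]
    codes <- codes[nzchar(codes)]
    if (length(codes) != n_loci)
      stop("GenePop structural error at line ", lineno, ": ", length(codes),
           " genotypes for ", n_loci, " loci")
    al <- matrix(0L, 2L, n_loci)
    for (j in seq_len(n_loci)) {
      code <- codes[j]
      w <- nchar(code)
      if (!(w %in% c(4L, 6L)) || grepl("[^0-9]", code))
        stop("GenePop parse error at line ", lineno,
             ": bad genotype code '", code, "'")
      half <- w %/% 2L
      al[1L, j] <- as.integer(substr(code, 1L, half))
      al[2L, j] <- as.integer(substr(code, half + 1L, w))
    }
    cur[[length(cur) + 1L]] <- al
    cur_ids <- c(cur_ids, id)
  }
  flush_pop()
  if (!length(pops)) stop("GenePop parse error: no individuals")
  genotype_dataset(pops, loci)
}

#' Write a GenePop file (3-digit dialect)
#'
#' @param dataset A [genotype_dataset].
#' @param path Output path.
#' @param title Title line content.
#' @export
write_genepop <- function(dataset, path, title = "invasionabc export") {
  stopifnot(inherits(dataset, "genotype_dataset"))
  mx <- max(vapply(dataset$genotypes, max, integer(1L)))
  if (mx > 999L)
    stop("GenePop encoding error: allele size ", mx, " exceeds 999")
  out <- c(title, dataset$loci)
  for (p in names(dataset$genotypes)) {
    out <- c(out, "POP")
    g <- dataset$genotypes[[p]]
    for (i in seq_len(dim(g)[1L])) {
      codes <- sprintf("%03d%03d", g[i, , 1L], g[i, , 2L])
      out <- c(out, paste0(p, "_", i, " , ", paste(codes, collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Exclude loci with high null-allele frequencies
#'
#' Removes every locus whose estimated null-allele frequency exceeds
#' `threshold` in any population (strict `>`). Null-allele frequencies are
#' supplied externally as quality-control records; they are not estimated
#' here.
#'
#' @param dataset A [genotype_dataset].
#' @param qc Data frame with columns `locus`, `population`, `null_freq`
#'   (fractions in `[0, 1]`). Every locus in the dataset must appear.
#' @param threshold Exclusion threshold, in `(0, 1]`; default 0.10.
#' @return The filtered [genotype_dataset]; locus order is preserved.
#' @export
filter_loci_by_null_alleles <- function(dataset, qc, threshold = 0.10) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (!all(c("locus", "population", "null_freq") %in% names(qc)))
    stop("qc must have columns locus, population, null_freq")
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  if (any(qc$null_freq < 0 | qc$null_freq > 1))
    stop("null-allele frequencies must lie in [0, 1]")
  no_qc <- setdiff(dataset$loci, qc$locus)
  if (length(no_qc))
    stop("configuration error: no QC record for locus ",
         paste(no_qc, collapse = ", "))
  worst <- tapply(qc$null_freq, qc$locus, max)
  keep <- dataset$loci[worst[dataset$loci] <= threshold]
  keep_idx <- match(keep, dataset$loci)
  if (!length(keep_idx)) stop("all loci excluded by the null-allele filter")
  genotypes <- lapply(dataset$genotypes, function(g)
    g[, keep_idx, , drop = FALSE])
  genotype_dataset(genotypes, dataset$loci[keep_idx],
                   dataset$motif[keep_idx])
}
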