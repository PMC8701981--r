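#' Read and order a pedigree file
#'
#' Reads a pedigree as CSV with columns `animal, sire, dam` and an optional
#' fourth column `birth_year`, then renumbers animals `1..n` in topological
#' order so every parent precedes its offspring. Animals that appear only as
#' parents are added as founders. Unknown parents are written as
#' `unknown_token` on disk and coded `0` internally.
#'
#' @param path Path to a pedigree CSV (header optional; detected when the
#'   first field of the first row is one of `animal`, `id`, `ID`).
#' @param unknown_token Token encoding an unknown parent. Default `"0"`.
#' @return An object of class `ped` (see [as_ped()]).
#' @seealso [as_ped()], [pedigree_A()]
#' @export
read_pedigree <- function(path, unknown_token = "0") {
  stopifnot(file.exists(path))
  raw <- read.table(path, sep = ",", header = FALSE, colClasses = "character",
                    strip.white = TRUE, blank.lines.skip = TRUE)
  if (ncol(raw) < 3L || ncol(raw) > 4L)
    stop("pedigree file must have 3 or 4 columns, found ", ncol(raw))
  if (tolower(raw[1L, 1L]) %in% c("animal", "id"))
    raw <- raw[-1L, , drop = FALSE]
  by <- if (ncol(raw) == 4L) suppressWarnings(as.integer(raw[[4L]])) else
    rep(NA_integer_, nrow(raw))
  as_ped(animal = raw[[1L]], sire = raw[[2L]], dam = raw[[3L]],
         birth_year = by, unknown_token = unknown_token)
}

#' Build an ordered pedigree object
#'
#' Validates and topologically orders a pedigree given as parallel vectors.
#' The result stores dense integer codes `1..n` (parents always smaller than
#' offspring, `0` = unknown) together with the original identifiers.
#'
#' @param animal,sire,dam Character vectors of animal and parent identifiers.
#' @param birth_year Optional integer vector of birth years (`NA` = unknown).
#' @param unknown_token Token encoding an unknown parent.
#' @return A `ped` object: a list with `id` (original identifiers in
#'   topological order), `sire`, `dam` (integer codes, 0 = unknown),
#'   `birth_year`, and `n`.
#' @export
as_ped <- function(animal, sire, dam, birth_year = NULL,
                   unknown_token = "0") {
  animal <- as.character(animal)
  sire <- as.character(sire)
  dam <- as.character(dam)
  n0 <- length(animal)
  stopifnot(length(sire) == n0, length(dam) == n0)
  if (anyDuplicated(animal)) {
    stop("duplicate animal id in pedigree: ",
         animal[duplicated(animal)][1L])
  }
  if (any(animal == sire & animal != unknown_token) ||
      any(animal == dam & animal != unknown_token))
    stop("animal listed as its own parent: ",
         animal[which(animal == sire | animal == dam)][1L])
  if (is.null(birth_year)) birth_year <- rep(NA_integer_, n0)

  # implicit founders: parents never listed as animals
  parents <- setdiff(unique(c(sire, dam)), c(animal, unknown_token))
  if (length(parents)) {
    animal <- c(animal, parents)
    sire <- c(sire, rep(unknown_token, length(parents)))
    dam <- c(dam, rep(unknown_token, length(parents)))
    birth_year <- c(birth_year, rep(NA_integer_, length(parents)))
  }
  n <- length(animal)
  idx <- seq_len(n)
  names(idx) <- animal
  si <- ifelse(sire == unknown_token, 0L, idx[sire])
  di <- ifelse(dam == unknown_token, 0L, idx[dam])

  # Kahn's algorithm: repeatedly emit animals whose parents are all emitted
  indeg <- (si > 0L) + (di > 0L)
  children <- vector("list", n)
  for (i in idx) {
    if (si[i] > 0L) children[[si[i]]] <- c(children[[si[i]]], i)
    if (di[i] > 0L) children[[di[i]]] <- c(children[[di[i]]], i)
  }
  order <- integer(n)
  queue <- which(indeg == 0L)
  k <- 0L
  while (length(queue)) {
    # tie-break on animal id, so numbering depends only on the record set,
    # not on row order in the file
    j <- base::order(animal[queue])[1L]
    v <- queue[j]; queue <- queue[-j]
    k <- k + 1L
    order[k] <- v
    for (w in children[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (k < n) {
    bad <- animal[which(indeg > 0L)[1L]]
    stop("cycle in pedigree involving animal '", bad,
         "' (an animal is its own ancestor)")
  }
  rank <- integer(n)
  rank[order] <- seq_len(n)
  so <- si[order]
  do <- di[order]
  structure(list(
    id = animal[order],
    sire = as.integer(ifelse(so > 0L, rank[pmax(so, 1L)], 0L)),
    dam = as.integer(ifelse(do > 0L, rank[pmax(do, 1L)], 0L)),
    birth_year = birth_year[order],
    n = n
  ), class = "ped")
}

#' @export
print.ped <- function(x, ...) {
  cat("Ordered pedigree:", x$n, "animals\n")
  cat("  founders (both parents unknown):",
      sum(x$sire == 0L & x$dam == 0L), "\n")
  if (!all(is.na(x$birth_year)))
    cat("  birth years:", min(x$birth_year, na.rm = TRUE), "-",
        max(x$birth_year, na.rm = TRUE), "\n")
  invisible(x)
}

#' Write a pedigree to CSV
#'
#' @param ped A `ped` object.
#' @param path Output path.
#' @param unknown_token Token written for unknown parents.
#' @export
write_pedigree <- function(ped, path, unknown_token = "0") {
  sire <- ifelse(ped$sire == 0L, unknown_token, ped$id[pmax(ped$sire, 1L)])
  dam <- ifelse(ped$dam == 0L, unknown_token, ped$id[pmax(ped$dam, 1L)])
  df <- data.frame(animal = ped$id, sire = sire, dam = dam,
                   birth_year = ped$birth_year)
  if (all(is.na(df$birth_year))) df$birth_year <- NULL
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
              col.names = FALSE, na = "")
  invisible(path)
}

#' Read a genotype matrix
#'
#' Reads a PLINK-RAW-style text table: a header row of SNP ids, then one row
#' per animal whose first column is the animal id and remaining cells are
#' allele dosages in `{0, 1, 2, NA}`.
#'
#' @param path Path to the genotype table (comma or whitespace separated).
#' @return An integer matrix (animals x SNPs) with `NA` marking missing
#'   genotypes; animal ids as rownames, SNP ids as colnames.
#' @export
read_genotypes <- function(path) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  tab <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", na.strings = "NA")
  ids <- tab[[1L]]
  cells <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(codes <- matrix(as.integer(cells), nrow = nrow(cells)))
  bad <- which((!is.na(cells) & is.na(codes)) |
                 (!is.na(codes) & !(codes %in% 0:2)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "invalid genotype '%s' at row %d (animal %s), column %d (SNP %s): must be 0, 1, 2 or NA",
      cells[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L], ids[bad[1L, 1L]],
      bad[1L, 2L], colnames(cells)[bad[1L, 2L]]))
  }
  dimnames(codes) <- list(ids, colnames(cells))
  codes
}

#' Write a genotype matrix
#'
#' Inverse of [read_genotypes()]: round-trips exactly, including missingness.
#'
#' @param geno Integer matrix, animals x SNPs, `NA` = missing.
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @export
write_genotypes <- function(geno, path, sep = ",") {
  df <- data.frame(animal = rownames(geno), geno, check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a phenotype table
#'
#' CSV with header `animal,trait,value,slaughter_date,slaughter_age`
#' (optionally `birth_year`). Values must be finite and positive;
#' slaughter age positive.
#'
#' @param path Path to the CSV.
#' @return A data.frame of phenotype records.
#' @export
read_phenotypes <- function(path) {
  stopifnot(file.exists(path))
  ph <- read.table(path, sep = ",", header = TRUE,
                   colClasses = c(animal = "character"))
  need <- c("animal", "trait", "value", "slaughter_date", "slaughter_age")
  miss <- setdiff(need, names(ph))
  if (length(miss)) stop("phenotype file missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(ph$value)) || any(ph$value <= 0))
    stop("phenotype values must be finite and > 0")
  if (any(ph$slaughter_age <= 0))
    stop("slaughter_age must be > 0")
  ph$slaughter_date <- as.character(ph$slaughter_date)
  ph
}

#' Write a phenotype table
#' @param phen Data.frame of phenotype records.
#' @param path Output path.
#' @export
write_phenotypes <- function(phen, path) {
  write.table(phen, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an LR validation report
#'
#' The report is a TSV with one row per (trait, method) carrying the LR
#' estimators (partial and whole accuracy, bias, dispersion, correlation and
#' relative-gain ratios) plus the scalar inputs (mean inbreeding,
#' mean coancestry, equilibrium genetic variance). `read_lr_report()` is the
#' exact inverse.
#'
#' @param report An `lr_report` object (see [lr_validate()]) or a data.frame
#'   with the same columns.
#' @param path Output path.
#' @return `write_lr_report()` returns `path` invisibly; `read_lr_report()`
#'   returns the report data.frame with class `lr_report`.
#' @export
write_lr_report <- function(report, path) {
  df <- as.data.frame(report)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lr_report
#' @export
read_lr_report <- function(path) {
  stopifnot(file.exists(path))
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c(trait = "character", method = "character"))
  class(df) <- c("lr_report", "data.frame")
  df
}

#' Default run configuration
#'
#' Flat key/value settings for a full study run. QC thresholds, the G/A22
#' blend weights and the long MCMC chain default to the published study
#' design; the Gibbs chain actually used by [run_study()] is the desk-scale
#' one unless overridden.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    traits = "cut_weight",
    maf_min = 0.01,
    het_dev_max = 0.15,
    call_rate_min = 0.90,
    w_G = 0.95,
    w_A22 = 0.05,
    tune_G = FALSE,
    chain = 50000L, burn_in = 5000L, thin = 10L,
    nu_a = -2, S2_a = 0, nu_e = -2, S2_e = 0,
    seed = 1L,
    focal_birth_years = 2017L,
    remove_focal = TRUE,
    lr_sign = "minus",
    lr_sqrt = TRUE
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  stopifnot(cfg$w_G > 0, cfg$w_G <= 1, cfg$w_A22 >= 0, cfg$w_A22 <= 1)
  if (abs(cfg$w_G + cfg$w_A22 - 1) > 1e-10)
    stop("blend weights must satisfy w_G + w_A22 = 1")
  if (cfg$burn_in >= cfg$chain) stop("burn_in must be < chain")
  if (cfg$thin < 1L) stop("thin must be >= 1")
  stopifnot(cfg$lr_sign %in% c("plus", "minus"))
  invisible(cfg)
}

#' Read / write a run configuration file
#'
#' Flat `key: value` text (DCF); list-valued keys comma-separated.
#'
#' @param path File path.
#' @param cfg A `run_config` object.
#' @return `read_run_config()` returns a `run_config`.
#' @export
read_run_config <- function(path) {
  stopifnot(file.exists(path))
  dcf <- read.dcf(path)
  vals <- as.list(dcf[1L, ])
  defaults <- run_config()
  out <- list()
  for (k in names(vals)) {
    v <- strsplit(vals[[k]], ",")[[1L]]
    v <- trimws(v)
    proto <- defaults[[k]]
    if (!is.null(proto)) {
      v <- switch(class(proto)[1L],
                  integer = as.integer(v),
                  numeric = as.numeric(v),
                  logical = as.logical(v),
                  v)
    }
    out[[k]] <- v
  }
  do.call(run_config, out)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  flat <- vapply(cfg, function(v) paste(v, collapse = ","), character(1))
  write.dcf(matrix(flat, nrow = 1, dimnames = list(NULL, names(cfg))), path)
  invisible(path)
}
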