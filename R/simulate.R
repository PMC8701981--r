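#' Simulation settings
#'
#' Desk-scale defaults emulating the design of a carcass-trait genomic
#' evaluation in beef cattle: 500 founders, four discrete offspring
#' generations of 600/600/500/300 animals (2,000 phenotyped in total), 5,000
#' SNPs of which 200 are QTL, a bottom-round-like trait (mean 33 kg,
#' phenotypic variance 10.9, heritability 0.5), 40 slaughter-date levels and
#' a slaughter-age covariate, genotypes for all non-founders plus 200
#' founders (so genotyped animals outnumber phenotyped ones, and every
#' combination of phenotyped/genotyped occurs), and a focal cohort formed by
#' the youngest birth year.
#'
#' @param n_founders Number of unrelated, non-inbred founders.
#' @param n_per_gen Integer vector: offspring per generation (its length is
#'   the number of generations).
#' @param offspring_per_mating Full sibs per mating.
#' @param n_sires Sires used per generation.
#' @param n_snps,n_qtl Marker panel size and number of causal loci (QTL are a
#'   subset of the panel).
#' @param founder_maf_range Founder allele frequencies drawn uniformly from
#'   this interval.
#' @param trait_mean Trait mean, kg.
#' @param h2_true True heritability.
#' @param sigma2_p_true True phenotypic variance, kg^2.
#' @param n_slaughter_dates Number of slaughter-date (contemporary group)
#'   levels, allocated to generations proportionally.
#' @param sigma_date SD of the slaughter-date effects, kg.
#' @param age_range Slaughter age window, days.
#' @param age_slope Fixed regression on centred slaughter age, kg/day.
#' @param selection `"none"` (random mating) or `"truncation"` (parents are
#'   the highest-phenotype animals of the previous generation).
#' @param sel_prop Proportion of each sex eligible as parents under
#'   truncation selection.
#' @param founders_genotyped Number of founders included in the genotype
#'   file.
#' @param nongenotyped_fraction Fraction of non-founders left out of the
#'   genotype file, so that phenotyped-but-ungenotyped animals exist (as in
#'   real single-step data).
#' @param missing_rate Genotype missingness applied to the released file.
#' @param final_year Birth year of the last generation; earlier generations
#'   count back one year each.
#' @param focal_birth_years Birth years defining the focal cohort.
#' @param seed RNG seed for the whole dataset.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_founders = 500L,
                       n_per_gen = c(600L, 600L, 500L, 300L),
                       offspring_per_mating = 2L,
                       n_sires = 40L,
                       n_snps = 5000L, n_qtl = 200L,
                       founder_maf_range = c(0.05, 0.5),
                       trait_mean = 33, h2_true = 0.5, sigma2_p_true = 10.9,
                       n_slaughter_dates = 40L, sigma_date = 1,
                       age_range = c(690L, 760L), age_slope = 0.05,
                       selection = c("none", "truncation"), sel_prop = 0.5,
                       founders_genotyped = 200L,
                       nongenotyped_fraction = 0.05, missing_rate = 0.01,
                       final_year = 2017L, focal_birth_years = 2017L,
                       seed = 1L) {
  selection <- match.arg(selection)
  stopifnot(h2_true >= 0, h2_true < 1, n_qtl <= n_snps,
            founder_maf_range[1L] > 0, founder_maf_range[2L] <= 0.5,
            sigma2_p_true > 0, n_founders >= 2L)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a multi-generation pedigree
#'
#' Discrete generations: founders (both parents unknown), then each
#' generation produced by mating sampled sires to sampled dams of the
#' previous generation, `offspring_per_mating` full sibs per mating. Sex is
#' assigned at birth. Birth years count back from `final_year`. With
#' `selection = "truncation"` this is delegated to the full engine
#' ([sim_dataset()]) because parents are chosen on phenotype.
#'
#' @param config A [sim_config()].
#' @return A `ped` object with a `sex` attribute (named vector, "M"/"F")
#'   and a `generation` attribute.
#' @export
sim_pedigree <- function(config = sim_config()) {
  if (config$selection != "none")
    return(sim_dataset(config)$pedigree)
  set.seed(config$seed)
  sim_pedigree_engine(config, select = NULL)
}

# builds the pedigree generation by generation; `select(gen_ids)` (if given)
# returns the ids eligible as parents — hook used for truncation selection
sim_pedigree_engine <- function(config, select = NULL,
                                on_generation = NULL) {
  nf <- config$n_founders
  gens <- config$n_per_gen
  total <- nf + sum(gens)
  id <- sprintf("A%05d", seq_len(total))
  sire <- integer(total); dam <- integer(total)
  sex <- character(total)
  generation <- integer(total)
  year <- integer(total)
  sex[seq_len(nf)] <- rep(c("M", "F"), length.out = nf)
  year[seq_len(nf)] <- config$final_year - length(gens)
  cur <- seq_len(nf)       # indices of the current parent generation
  nxt <- nf
  for (g in seq_along(gens)) {
    pool <- cur
    if (!is.null(select)) pool <- select(pool)
    males <- pool[sex[pool] == "M"]
    females <- pool[sex[pool] == "F"]
    if (!length(males) || !length(females))
      stop("no matings possible in generation ", g,
           ": a sex is missing from the parent pool")
    sires <- sample(males, min(config$n_sires, length(males)))
    n_mat <- ceiling(gens[g] / config$offspring_per_mating)
    mat_s <- sample(sires, n_mat, replace = TRUE)
    mat_d <- sample(females, n_mat, replace = TRUE)
    kids <- nxt + seq_len(gens[g])
    mate_of <- rep(seq_len(n_mat), each = config$offspring_per_mating)[
      seq_len(gens[g])]
    sire[kids] <- mat_s[mate_of]
    dam[kids] <- mat_d[mate_of]
    sex[kids] <- sample(c("M", "F"), gens[g], replace = TRUE)
    generation[kids] <- g
    year[kids] <- config$final_year - (length(gens) - g)
    if (!is.null(on_generation)) on_generation(kids)
    cur <- kids
    nxt <- nxt + gens[g]
  }
  ped <- structure(list(id = id, sire = sire, dam = dam,
                        birth_year = year, n = total), class = "ped")
  attr(ped, "sex") <- setNames(sex, id)
  attr(ped, "generation") <- setNames(generation, id)
  ped
}

#' Simulate SNP genotypes down a pedigree by gene dropping
#'
#' Founder alleles are drawn per locus at a frequency sampled from
#' `founder_maf_range`; every non-founder receives one uniformly chosen
#' allele from each parent per locus (loci unlinked). Returns complete
#' dosages for every pedigree animal (missingness and the genotyped subset
#' are applied later by [sim_dataset()]).
#'
#' @param ped Ordered pedigree (all non-founders with both parents known).
#' @param config A [sim_config()].
#' @return List: `dosage` (integer matrix, all animals x SNPs), `founder_freq`
#'   (the drawn founder allele frequencies), `qtl_idx` (indices of the QTL
#'   columns).
#' @export
sim_genotypes <- function(ped, config = sim_config()) {
  check_ped_order(ped)
  m <- config$n_snps
  founders <- ped$sire == 0L & ped$dam == 0L
  freq <- runif(m, config$founder_maf_range[1L], config$founder_maf_range[2L])
  h1 <- matrix(0L, ped$n, m)
  h2 <- matrix(0L, ped$n, m)
  nf <- sum(founders)
  h1[founders, ] <- rbinom(nf * m, 1L, rep(freq, each = nf))
  h2[founders, ] <- rbinom(nf * m, 1L, rep(freq, each = nf))
  gene_drop_cpp(h1, h2, ped$sire, ped$dam)
  dosage <- h1 + h2
  dimnames(dosage) <- list(ped$id, sprintf("snp%05d", seq_len(m)))
  qtl_idx <- sort(sample.int(m, config$n_qtl))
  list(dosage = dosage, founder_freq = freq, qtl_idx = qtl_idx)
}

#' Simulate phenotypes with known breeding values
#'
#' True breeding values are strictly additive over the QTL:
#' `u_i = sum_q a_q dosage[i, q]`, with effects drawn standard normal and
#' rescaled so that the founder variance of `u` equals
#' `h2_true * sigma2_p_true` (then centred at the founder mean). Records for
#' every non-founder:
#' `y = trait_mean + date_effect + age_slope * (age - mean(age)) + u + e`,
#' `e ~ N(0, (1 - h2_true) * sigma2_p_true)`. Slaughter dates are allocated
#' to generations proportionally, ages uniform over `age_range`.
#'
#' @param ped Pedigree from [sim_pedigree()] (needs the `generation`
#'   attribute).
#' @param geno Result of [sim_genotypes()].
#' @param config A [sim_config()].
#' @param phenotyped Optional indices of animals to phenotype (default: all
#'   non-founders).
#' @return List: `phenotypes` (data frame: animal, trait, value,
#'   slaughter_date, slaughter_age, birth_year), `truth` (true_u per animal,
#'   QTL effects, true variances, date effects, age slope).
#' @export
sim_phenotypes <- function(ped, geno, config = sim_config(),
                           phenotyped = NULL) {
  stopifnot(nrow(geno$dosage) == ped$n)
  founders <- which(ped$sire == 0L & ped$dam == 0L)
  Q <- geno$dosage[, geno$qtl_idx, drop = FALSE]
  poly <- apply(Q[founders, , drop = FALSE], 2L, var) > 0
  if (!any(poly)) stop("all QTL are monomorphic among founders: ",
                       "cannot scale the genetic variance")
  a <- rnorm(ncol(Q))
  u_raw <- as.vector(Q %*% a)
  s2a_target <- config$h2_true * config$sigma2_p_true
  vf <- var(u_raw[founders])
  scale <- if (s2a_target > 0) sqrt(s2a_target / vf) else 0
  u <- scale * (u_raw - mean(u_raw[founders]))
  s2e <- (1 - config$h2_true) * config$sigma2_p_true

  if (is.null(phenotyped)) phenotyped <- which(ped$sire > 0L | ped$dam > 0L)
  np <- length(phenotyped)
  gen <- attr(ped, "generation")
  gsel <- if (is.null(gen)) rep(1L, np) else gen[phenotyped]
  # slaughter dates nested in generations, proportional allocation
  ngen <- max(gsel)
  per <- pmax(1L, round(config$n_slaughter_dates *
                          tabulate(gsel, ngen) / np))
  starts <- cumsum(c(0L, per))[seq_len(ngen)]
  date <- sprintf("d%03d",
                  starts[gsel] + vapply(gsel, function(g) sample.int(per[g], 1L), 1L))
  date_levels <- sort(unique(date))
  date_eff <- setNames(rnorm(length(date_levels), 0, config$sigma_date),
                       date_levels)
  age <- round(runif(np, config$age_range[1L], config$age_range[2L]))
  e <- rnorm(np, 0, sqrt(s2e))
  y <- config$trait_mean + date_eff[date] + config$age_slope * (age - mean(age)) +
    u[phenotyped] + e
  phen <- data.frame(
    animal = ped$id[phenotyped],
    trait = "cut_weight",
    value = as.numeric(y),
    slaughter_date = date,
    slaughter_age = age,
    birth_year = ped$birth_year[phenotyped],
    stringsAsFactors = FALSE)
  truth <- list(true_u = setNames(u, ped$id),
                qtl_effects = a * scale,
                qtl_idx = geno$qtl_idx,
                sigma2_a = s2a_target, sigma2_e = s2e,
                date_effects = date_eff, age_slope = config$age_slope)
  list(phenotypes = phen, truth = truth)
}

#' Simulate a complete evaluation dataset
#'
#' End-to-end generator: pedigree, gene-dropped genotypes, phenotypes with
#' known breeding values, the released genotype file (genotyped subset with
#' missingness) and the focal cohort. With `selection = "truncation"` the
#' engine simulates generation by generation, choosing the parents of each
#' generation among the highest phenotypes of the previous one, so the
#' focal cohort's genetic variance is reduced relative to the base
#' (the Bulmer effect the equilibrium variance must capture).
#'
#' @param config A [sim_config()].
#' @return List of class `sim_data`: `pedigree`, `genotypes` (released
#'   matrix with `NA`s), `phenotypes`, `truth` (incl. complete dosages as
#'   `dosage_full`), `focal_ids`, `config`.
#' @export
sim_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  if (config$selection == "none") {
    ped <- sim_pedigree_engine(config)
    geno <- sim_genotypes(ped, config)
    sp <- sim_phenotypes(ped, geno, config)
  } else {
    # sequential: each generation is phenotyped before its parents' own
    # parents are chosen, so selection operates on the analysed records
    res <- sim_selected(config)
    ped <- res$ped; geno <- res$geno; sp <- res$sp
  }
  released <- release_genotypes(ped, geno$dosage, config)
  focal <- ped$id[ped$birth_year %in% config$focal_birth_years &
                    (ped$sire > 0L | ped$dam > 0L)]
  structure(list(pedigree = ped,
                 genotypes = released,
                 phenotypes = sp$phenotypes,
                 truth = c(sp$truth, list(dosage_full = geno$dosage,
                                          founder_freq = geno$founder_freq)),
                 focal_ids = focal,
                 config = config), class = "sim_data")
}

# genotyped subset (all non-founders + founders_genotyped founders) with
# missingness
release_genotypes <- function(ped, dosage, config) {
  founders <- which(ped$sire == 0L & ped$dam == 0L)
  keep_f <- founders[seq_len(min(config$founders_genotyped, length(founders)))]
  nonf <- which(ped$sire > 0L | ped$dam > 0L)
  n_out <- round(config$nongenotyped_fraction * length(nonf))
  if (n_out > 0L) nonf <- setdiff(nonf, sample(nonf, n_out))
  keep <- sort(c(keep_f, nonf))
  g <- dosage[keep, , drop = FALSE]
  if (config$missing_rate > 0) {
    miss <- runif(length(g)) < config$missing_rate
    g[miss] <- NA_integer_
  }
  g
}

# truncation selection: rebuild the dataset generation by generation,
# phenotyping each cohort and promoting the top sel_prop of each sex
sim_selected <- function(config) {
  gens <- config$n_per_gen
  sel <- function(pool) {
    sx <- attr(ped_env$ped, "sex")[pool]
    sc <- ped_env$score[pool]
    keep <- unlist(lapply(split(seq_along(pool), sx), function(ix) {
      k <- max(1L, ceiling(length(ix) * config$sel_prop))
      ix[order(sc[ix], decreasing = TRUE)[seq_len(k)]]
    }))
    pool[keep]
  }
  ped_env <- new.env()
  ped_env$score <- rep(NA_real_, config$n_founders + sum(gens))
  m <- config$n_snps
  total <- config$n_founders + sum(gens)
  freq <- runif(m, config$founder_maf_range[1L], config$founder_maf_range[2L])
  h1 <- matrix(0L, total, m); h2 <- matrix(0L, total, m)
  nf <- config$n_founders
  h1[seq_len(nf), ] <- rbinom(nf * m, 1L, rep(freq, each = nf))
  h2[seq_len(nf), ] <- rbinom(nf * m, 1L, rep(freq, each = nf))
  qtl_idx <- sort(sample.int(m, config$n_qtl))
  a <- rnorm(config$n_qtl)
  uf <- as.vector((h1[seq_len(nf), qtl_idx] + h2[seq_len(nf), qtl_idx]) %*% a)
  s2a_target <- config$h2_true * config$sigma2_p_true
  scale <- if (s2a_target > 0) sqrt(s2a_target / var(uf)) else 0
  a <- a * scale
  u_center <- mean(uf) * scale
  s2e <- (1 - config$h2_true) * config$sigma2_p_true
  ped_env$score[seq_len(nf)] <- rnorm(nf)  # founders: random merit proxy
  on_gen <- function(kids) {
    ped <- ped_env$ped_partial
    for (i in kids) {
      pick <- runif(m) < 0.5
      h1[i, ] <<- ifelse(pick, h1[ped$sire[i], ], h2[ped$sire[i], ])
      pick <- runif(m) < 0.5
      h2[i, ] <<- ifelse(pick, h1[ped$dam[i], ], h2[ped$dam[i], ])
    }
    u_kids <- as.vector((h1[kids, qtl_idx, drop = FALSE] +
                           h2[kids, qtl_idx, drop = FALSE]) %*% a) - u_center
    ped_env$score[kids] <- u_kids + rnorm(length(kids), 0, sqrt(s2e))
  }
  # engine variant that exposes the growing pedigree to the hook
  ped <- sim_pedigree_engine_sel(config, sel, on_gen, ped_env)
  dosage <- h1 + h2
  dimnames(dosage) <- list(ped$id, sprintf("snp%05d", seq_len(m)))
  geno <- list(dosage = dosage, founder_freq = freq, qtl_idx = qtl_idx)
  # phenotypes: reuse the selection scores as the genetic+residual part so
  # the records the parents were selected on are the records analysed
  phenotyped <- which(ped$sire > 0L | ped$dam > 0L)
  sp <- sim_phenotypes_from_scores(ped, geno, config, phenotyped,
                                   a, u_center, ped_env$score, s2e)
  list(ped = ped, geno = geno, sp = sp)
}

sim_pedigree_engine_sel <- function(config, select, on_generation, ped_env) {
  nf <- config$n_founders
  gens <- config$n_per_gen
  total <- nf + sum(gens)
  id <- sprintf("A%05d", seq_len(total))
  sire <- integer(total); dam <- integer(total)
  sex <- character(total); generation <- integer(total); year <- integer(total)
  sex[seq_len(nf)] <- rep(c("M", "F"), length.out = nf)
  year[seq_len(nf)] <- config$final_year - length(gens)
  cur <- seq_len(nf); nxt <- nf
  for (g in seq_along(gens)) {
    ped_env$ped_partial <- list(sire = sire, dam = dam)
    attr_ped <- structure(list(id = id, sire = sire, dam = dam,
                               birth_year = year, n = total), class = "ped")
    attr(attr_ped, "sex") <- setNames(sex, id)
    ped_env$ped <- attr_ped
    pool <- select(cur)
    males <- pool[sex[pool] == "M"]; females <- pool[sex[pool] == "F"]
    if (!length(males) || !length(females))
      stop("no matings possible in generation ", g)
    sires <- sample(males, min(config$n_sires, length(males)))
    n_mat <- ceiling(gens[g] / config$offspring_per_mating)
    mat_s <- sample(sires, n_mat, replace = TRUE)
    mat_d <- sample(females, n_mat, replace = TRUE)
    kids <- nxt + seq_len(gens[g])
    mate_of <- rep(seq_len(n_mat),
                   each = config$offspring_per_mating)[seq_len(gens[g])]
    sire[kids] <- mat_s[mate_of]; dam[kids] <- mat_d[mate_of]
    sex[kids] <- sample(c("M", "F"), gens[g], replace = TRUE)
    generation[kids] <- g
    year[kids] <- config$final_year - (length(gens) - g)
    ped_env$ped_partial <- list(sire = sire, dam = dam)
    on_generation(kids)
    cur <- kids; nxt <- nxt + gens[g]
  }
  ped <- structure(list(id = id, sire = sire, dam = dam,
                        birth_year = year, n = total), class = "ped")
  attr(ped, "sex") <- setNames(sex, id)
  attr(ped, "generation") <- setNames(generation, id)
  ped
}

sim_phenotypes_from_scores <- function(ped, geno, config, phenotyped,
                                       a, u_center, score, s2e) {
  Q <- geno$dosage[, geno$qtl_idx, drop = FALSE]
  u <- as.vector(Q %*% a) - u_center
  np <- length(phenotyped)
  gen <- attr(ped, "generation")
  gsel <- gen[phenotyped]
  ngen <- max(gsel)
  per <- pmax(1L, round(config$n_slaughter_dates * tabulate(gsel, ngen) / np))
  starts <- cumsum(c(0L, per))[seq_len(ngen)]
  date <- sprintf("d%03d",
                  starts[gsel] + vapply(gsel, function(g) sample.int(per[g], 1L), 1L))
  date_levels <- sort(unique(date))
  date_eff <- setNames(rnorm(length(date_levels), 0, config$sigma_date),
                       date_levels)
  age <- round(runif(np, config$age_range[1L], config$age_range[2L]))
  # score already holds u + e for phenotyped animals (selection operated on it)
  y <- config$trait_mean + date_eff[date] +
    config$age_slope * (age - mean(age)) + score[phenotyped]
  phen <- data.frame(animal = ped$id[phenotyped], trait = "cut_weight",
                     value = as.numeric(y), slaughter_date = date,
                     slaughter_age = age,
                     birth_year = ped$birth_year[phenotyped],
                     stringsAsFactors = FALSE)
  truth <- list(true_u = setNames(u, ped$id), qtl_effects = a,
                qtl_idx = geno$qtl_idx,
                sigma2_a = config$h2_true * config$sigma2_p_true,
                sigma2_e = s2e, date_effects = date_eff,
                age_slope = config$age_slope)
  list(phenotypes = phen, truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Emits exactly the file formats the readers consume: `pedigree.csv`,
#' `genotypes.csv`, `phenotypes.csv` plus `truth.tsv` (animal, true breeding
#' value).
#'
#' @param sim A `sim_data` object.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_sim_data <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pedigree(sim$pedigree, file.path(dir, "pedigree.csv"))
  write_genotypes(sim$genotypes, file.path(dir, "genotypes.csv"))
  write_phenotypes(sim$phenotypes, file.path(dir, "phenotypes.csv"))
  write.table(data.frame(animal = names(sim$truth$true_u),
                         true_u = sim$truth$true_u),
              file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' @export
print.sim_data <- function(x, ...) {
  cat("Simulated evaluation dataset\n")
  cat(sprintf("  pedigree: %d animals   phenotyped: %d   genotyped: %d\n",
              x$pedigree$n, nrow(x$phenotypes), nrow(x$genotypes)))
  cat(sprintf("  SNPs: %d (QTL: %d)   focal cohort: %d animals\n",
              ncol(x$genotypes), length(x$truth$qtl_idx), length(x$focal_ids)))
  cat(sprintf("  true h2 = %.2f, sigma2_p = %.3g, selection = %s\n",
              x$config$h2_true, x$config$sigma2_p_true, x$config$selection))
  invisible(x)
}
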