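# Shared fixtures. Heavy objects are computed once per test run, lazily,
# and cached in this environment so several test files can reuse them.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fun) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- fun()
  .fixtures[[name]]
}

# random but valid ordered pedigree: each non-founder draws parents among
# earlier animals (or unknown), guaranteeing acyclicity
random_pedigree <- function(n, n_founders = max(5L, n %/% 5L), seed = 1L) {
  set.seed(seed)
  id <- sprintf("R%04d", seq_len(n))
  sire <- integer(n); dam <- integer(n)
  for (i in seq_len(n)) {
    if (i <= n_founders) next
    cand <- seq_len(i - 1L)
    sire[i] <- if (runif(1) < 0.9) sample(cand, 1L) else 0L
    dam[i] <- if (runif(1) < 0.9) {
      pick <- setdiff(cand, sire[i])
      if (length(pick)) sample(pick, 1L) else 0L
    } else 0L
  }
  structure(list(id = id, sire = sire, dam = dam,
                 birth_year = rep(NA_integer_, n), n = n), class = "ped")
}

form <- value ~ slaughter_date + slaughter_age

# small-but-structured simulation used by many unit tests
small_sim <- function() fixture("small_sim", function() {
  sim_dataset(sim_config(n_founders = 80L, n_per_gen = c(100L, 100L, 80L),
                         n_snps = 400L, n_qtl = 60L, n_slaughter_dates = 8L,
                         founders_genotyped = 30L, missing_rate = 0.02,
                         seed = 101L))
})

# replicate study used for the LR calibration and qualitative checks and for
# the evaluation-module accuracy invariant; sizes are stated in the methods
# vignette (moderate scale, 10 replicates)
lr_replicate_config <- function(seed) {
  sim_config(n_founders = 250L, n_per_gen = c(350L, 350L, 250L, 200L),
             n_snps = 1500L, n_qtl = 150L, n_slaughter_dates = 25L,
             founders_genotyped = 100L, missing_rate = 0.01,
             h2_true = 0.5, seed = seed)
}

run_lr_replicate <- function(seed) {
  sim <- sim_dataset(lr_replicate_config(seed))
  ped <- sim$pedigree
  qc <- qc_genotypes(sim$genotypes)
  geno <- impute_genotypes(qc$geno)
  set.seed(seed + 1L)
  vc <- vc_gibbs(form, sim$phenotypes, ped,
                 control = gibbs_control(chain = 6000L, burn_in = 1000L,
                                         thin = 5L),
                 focal_ids = sim$focal_ids)
  eq <- equilibrium_variance(vc)
  inb <- inbreeding_summary(ped, sim$focal_ids)
  Ainv <- pedigree_Ainv(ped)
  A22 <- pedigree_A22(ped, rownames(geno))
  Hinv <- hinv(Ainv, A22, blend_grm(grm_vanraden(geno), A22))
  sets <- split_partial(sim$phenotypes, sim$focal_ids)
  ebv <- list()
  for (m in c("PBLUP", "ssGBLUP")) {
    K <- if (m == "PBLUP") Ainv else Hinv
    for (ds in c("whole", "partial")) {
      fit <- blup(form, sets[[ds]], ped, lambda = vc$lambda, K_inv = K,
                  dataset = ds)
      ebv[[m]][[ds]] <- fit$ebv[sim$focal_ids]
    }
  }
  rep <- suppressWarnings(
    lr_report(ebv, inb, eq, trait = "cut_weight", lambda = vc$lambda))
  truth <- sim$truth$true_u[sim$focal_ids]
  list(
    report = rep,
    acc_lr = setNames(rep$acc_partial, rep$method),
    acc_true = c(PBLUP = cor(ebv$PBLUP$partial, truth),
                 ssGBLUP = cor(ebv$ssGBLUP$partial, truth)),
    acc_true_whole = c(PBLUP = cor(ebv$PBLUP$whole, truth),
                       ssGBLUP = cor(ebv$ssGBLUP$whole, truth)),
    bias = setNames(rep$bias, rep$method),
    dispersion = setNames(rep$dispersion, rep$method),
    gain_partial = rep$gain_methods_partial[1L],
    gain_whole = rep$gain_methods_whole[1L],
    sigma2_u_inf = eq$sigma2_u_inf,
    inb = inb[c("F_bar", "f_bar")],
    sigma2_a_true = sim$truth$sigma2_a,
    vc_h2 = vc$h2
  )
}

lr_replicates <- function() fixture("lr_replicates", function() {
  lapply(1:10, function(r) run_lr_replicate(2000L + r))
})

# simulation + Gibbs at the parameter-recovery scale (~2,000 phenotyped);
# genotypes are irrelevant to the pedigree-based sampler, so the SNP panel
# is kept small
gibbs_recovery <- function(h2) {
  key <- paste0("gibbs_recovery_", h2 * 100)
  fixture(key, function() {
    sim <- sim_dataset(sim_config(n_snps = 800L, n_qtl = 200L,
                                  founders_genotyped = 0L,
                                  missing_rate = 0,
                                  h2_true = h2, seed = 300L + h2 * 100))
    set.seed(301L + h2 * 100)
    vc <- vc_gibbs(form, sim$phenotypes, sim$pedigree,
                   control = gibbs_control(chain = 50000L, burn_in = 5000L,
                                           thin = 10L),
                   focal_ids = sim$focal_ids)
    list(sim = sim, vc = vc)
  })
}
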