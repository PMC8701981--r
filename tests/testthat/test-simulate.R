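test_that("pedigree sizes follow the closed form and founders-only works", {
  cfg <- sim_config(n_founders = 100L, n_per_gen = c(60L, 40L),
                    n_snps = 50L, n_qtl = 10L, seed = 5L)
  ped <- sim_pedigree(cfg)
  expect_identical(ped$n, 200L)
  founders <- ped$sire == 0L & ped$dam == 0L
  expect_identical(sum(founders), 100L)
  expect_true(all(which(founders) <= 100L))
  # birth years count back from the final year
  expect_identical(sort(unique(ped$birth_year)), c(2015L, 2016L, 2017L))

  cfg0 <- sim_config(n_founders = 30L, n_per_gen = integer(0),
                     n_snps = 10L, n_qtl = 2L, seed = 6L)
  ped0 <- sim_pedigree(cfg0)
  expect_identical(ped0$n, 30L)
  expect_true(all(ped0$sire == 0L & ped0$dam == 0L))
})

test_that("gene dropping obeys Mendelian certainty", {
  sim <- small_sim()
  dos <- sim$truth$dosage_full
  ped <- sim$pedigree
  kids <- which(ped$sire > 0L & ped$dam > 0L)
  set.seed(8)
  for (i in sample(kids, 20L)) {
    s <- dos[ped$sire[i], ]; d <- dos[ped$dam[i], ]; k <- dos[i, ]
    both0 <- s == 0L & d == 0L
    expect_true(all(k[both0] == 0L))
    both2 <- s == 2L & d == 2L
    expect_true(all(k[both2] == 2L))
    cross <- (s == 2L & d == 0L) | (s == 0L & d == 2L)
    expect_true(all(k[cross] == 1L))
  }
})

test_that("realised founder allele frequencies sit in their binomial bands", {
  cfg <- sim_config(n_founders = 500L, n_per_gen = 100L, n_snps = 400L,
                    n_qtl = 40L, seed = 9L)
  sim <- sim_dataset(cfg)
  founders <- sim$pedigree$id[sim$pedigree$sire == 0L]
  phat <- colMeans(sim$truth$dosage_full[founders, ]) / 2
  p <- sim$truth$founder_freq
  z <- abs(phat - p) / sqrt(p * (1 - p) / (2 * 500))
  expect_gte(mean(z < 3.29), 0.99)  # ~99.9% expected within +-3.29 SE
})

test_that("the generated dataset is byte-identical under a fixed seed", {
  cfg <- sim_config(n_founders = 50L, n_per_gen = c(40L, 30L), n_snps = 80L,
                    n_qtl = 15L, seed = 123L)
  s1 <- sim_dataset(cfg)
  s2 <- sim_dataset(cfg)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$truth$true_u, s2$truth$true_u)
  expect_identical(s1$focal_ids, s2$focal_ids)
})

test_that("founder genetic variance hits its target and h2 limits hold", {
  sim <- small_sim()
  founders <- sim$pedigree$id[sim$pedigree$sire == 0L]
  vf <- var(sim$truth$true_u[founders])
  expect_equal(vf, sim$config$h2_true * sim$config$sigma2_p_true,
               tolerance = 1e-8)  # exact by construction

  # h2 = 0: no genetic variance anywhere
  cfg0 <- sim_config(n_founders = 60L, n_per_gen = 80L, n_snps = 100L,
                     n_qtl = 20L, h2_true = 0, seed = 31L)
  s0 <- sim_dataset(cfg0)
  expect_true(all(s0$truth$true_u == 0))
  # within-date variance is then residual only (sampling error allowed)
  resid <- s0$phenotypes$value -
    s0$config$age_slope * (s0$phenotypes$slaughter_age -
                             mean(s0$phenotypes$slaughter_age))
  v <- mean(tapply(resid, s0$phenotypes$slaughter_date, var), na.rm = TRUE)
  expect_lt(abs(v - s0$truth$sigma2_e) / s0$truth$sigma2_e, 0.35)

  # sigma2_e = 0: records minus fixed effects equal the breeding values
  cfg1 <- sim_config(n_founders = 60L, n_per_gen = 80L, n_snps = 100L,
                     n_qtl = 20L, h2_true = 1 - 1e-9, seed = 32L)
  s1 <- sim_dataset(cfg1)
  ph <- s1$phenotypes
  fixed <- s1$config$trait_mean + s1$truth$date_effects[ph$slaughter_date] +
    s1$config$age_slope * (ph$slaughter_age - mean(ph$slaughter_age))
  expect_equal(ph$value - unname(fixed),
               unname(s1$truth$true_u[ph$animal]), tolerance = 1e-3)
})

test_that("offspring-midparent regression recovers the heritability", {
  sim <- gibbs_recovery(0.5)$sim   # ~2,000 phenotyped, h2 = 0.5
  ped <- sim$pedigree
  ph <- sim$phenotypes
  # remove the known fixed effects first: the regression oracle concerns
  # the genetic part, and date effects would otherwise attenuate the slope
  adj <- ph$value - sim$truth$date_effects[ph$slaughter_date] -
    sim$config$age_slope * (ph$slaughter_age - mean(ph$slaughter_age))
  y <- setNames(adj, ph$animal)
  kids <- which(ped$sire > 0L & ped$dam > 0L &
                  ped$id %in% ph$animal &
                  ped$id[pmax(ped$sire, 1L)] %in% ph$animal &
                  ped$id[pmax(ped$dam, 1L)] %in% ph$animal)
  mid <- (y[ped$id[ped$sire[kids]]] + y[ped$id[ped$dam[kids]]]) / 2
  slope <- coef(lm(y[ped$id[kids]] ~ mid))[2L]
  expect_lt(abs(slope - 0.5), 0.1)
})

test_that("all four phenotyped x genotyped combinations occur", {
  sim <- small_sim()
  phen <- unique(sim$phenotypes$animal)
  geno <- rownames(sim$genotypes)
  all_ids <- sim$pedigree$id
  expect_gt(length(intersect(phen, geno)), 0L)
  expect_gt(length(setdiff(phen, geno)), 0L)
  expect_gt(length(setdiff(geno, phen)), 0L)
  expect_gt(length(setdiff(all_ids, union(geno, phen))), 0L)
})

test_that("mean inbreeding is non-decreasing across generations", {
  # small closed population with few sires so drift accumulates
  deltas <- vapply(1:10, function(s) {
    cfg <- sim_config(n_founders = 30L, n_per_gen = c(40L, 40L, 40L),
                      n_sires = 4L, n_snps = 20L, n_qtl = 5L, seed = 400L + s)
    ped <- sim_pedigree(cfg)
    Fi <- inbreeding(ped)
    gen <- attr(ped, "generation")
    mean(Fi[gen == 3L]) - mean(Fi[gen == 1L])
  }, numeric(1))
  expect_gte(mean(deltas), 0)
})

test_that("simulated files round-trip through the readers", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  write_sim_data(sim, dir)
  ped2 <- read_pedigree(file.path(dir, "pedigree.csv"))
  expect_identical(ped2$n, sim$pedigree$n)
  expect_setequal(ped2$id, sim$pedigree$id)
  g2 <- read_genotypes(file.path(dir, "genotypes.csv"))
  expect_identical(g2, sim$genotypes)
  p2 <- read_phenotypes(file.path(dir, "phenotypes.csv"))
  expect_equal(p2$value, sim$phenotypes$value, tolerance = 1e-10)
})
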