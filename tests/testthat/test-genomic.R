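test_that("QC removes SNPs by the stated rules, in the stated order", {
  # SNP 1: heterozygote deficit (50 AA, 50 aa): p = .5, Hobs = 0, dev = .5
  # SNP 2: singleton minor allele among 100 animals: p = .005 < .01
  # SNP 3: clean
  g <- cbind(snpA = rep(c(0L, 2L), each = 50),
             snpB = c(1L, rep(0L, 99)),
             snpC = rep(c(0L, 1L, 1L, 2L), 25))  # Hardy-Weinberg at p = .5
  rownames(g) <- sprintf("a%03d", 1:100)
  res <- qc_genotypes(g)
  expect_identical(colnames(res$geno), "snpC")
  expect_identical(res$report$n_removed_maf, 1L)
  expect_identical(res$report$n_removed_hwe, 1L)
  expect_identical(res$report$n_retained_snps, 1L)
})

test_that("QC counts reconcile and hand-planted failures are each caught", {
  # 10 animals x 12 SNPs with one planted failure per rule; enough clean
  # SNPs that a single missing cell does not sink an animal's call rate
  g <- matrix(rep(c(0L, 1L, 2L, 1L, 1L, 0L, 2L, 1L, 0L, 1L), 12), 10, 12)
  colnames(g) <- paste0("s", 1:12)
  rownames(g) <- paste0("a", 1:10)
  g[, 2] <- 0L                                # fixed allele -> MAF
  g[, 3] <- rep(c(0L, 2L), 5)                 # no hets at p=.5 -> HWE
  g[c(1, 3), 4] <- NA                         # SNP call rate 8/9 < 0.9
  g[5, ] <- NA; g[5, 1] <- 0L                 # animal call rate 1/12
  res <- qc_genotypes(g)
  r <- res$report
  # animal a5 goes first, then SNP call rate, then MAF, then HWE
  expect_identical(r$n_removed_callrate_animal, 1L)
  expect_identical(r$n_removed_callrate_snp, 1L)
  expect_identical(r$n_removed_maf, 1L)
  expect_identical(r$n_removed_hwe, 1L)
  expect_identical(
    r$n_retained_snps,
    r$n_input_snps - r$n_removed_callrate_snp - r$n_removed_maf -
      r$n_removed_hwe)
  expect_false("a5" %in% rownames(res$geno))

  # idempotence: re-running QC removes nothing further
  res2 <- qc_genotypes(res$geno)
  expect_identical(res2$geno, res$geno)
  expect_identical(res2$report$n_retained_snps, res$report$n_retained_snps)
})

test_that("QC erroring when nothing survives", {
  g <- matrix(0L, 10, 2, dimnames = list(paste0("a", 1:10), c("s1", "s2")))
  expect_error(qc_genotypes(g), "every SNP")
})

test_that("mean imputation fills with rounded 2p and clears missingness", {
  g <- matrix(c(2L, 2L, 2L, 2L, NA, 1L,
                1L, 1L, 0L, NA, 1L, 1L), ncol = 2,
              dimnames = list(paste0("a", 1:6), c("hi", "mid")))
  out <- impute_genotypes(g)
  expect_false(anyNA(out))
  expect_identical(out[5L, "hi"], 2L)   # p = 0.9 -> round(1.8) = 2
  expect_identical(out[4L, "mid"], 1L)  # p = 0.4 -> round(0.8) = 1
  # observed cells untouched
  expect_identical(out[!is.na(g)], g[!is.na(g)])
  # no missingness: identity
  expect_identical(impute_genotypes(out), out)
  g[, 1] <- NA
  expect_error(impute_genotypes(g), "all genotypes missing")
})

test_that("VanRaden G matches the hand-evaluated single-SNP case", {
  g <- matrix(c(0L, 2L), 2, 1, dimnames = list(c("a1", "a2"), "s1"))
  G <- grm_vanraden(g)
  expect_equal(unname(G), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("G entries sum to zero (centring identity) and G is symmetric", {
  sim <- small_sim()
  g <- impute_genotypes(qc_genotypes(sim$genotypes)$geno)
  G <- grm_vanraden(g)
  expect_lt(abs(sum(G)), 1e-6 * nrow(G))
  expect_equal(G, t(G), tolerance = 1e-12)
  mono <- cbind(s1 = rep(0L, 5), s2 = rep(2L, 5))
  rownames(mono) <- paste0("a", 1:5)
  expect_error(grm_vanraden(mono), "monomorphic")
})

test_that("mean G diagonal is ~1 under Hardy-Weinberg sampling", {
  set.seed(11)
  p <- runif(1000, 0.05, 0.5)
  g <- sapply(p, function(pp) rbinom(200, 2, pp))
  storage.mode(g) <- "integer"
  dimnames(g) <- list(sprintf("a%03d", 1:200), sprintf("s%04d", 1:1000))
  G <- grm_vanraden(g)
  expect_lt(abs(mean(diag(G)) - 1), 0.05)
})

test_that("blending is the stated convex combination", {
  sim <- small_sim()
  g <- impute_genotypes(qc_genotypes(sim$genotypes)$geno)
  G <- grm_vanraden(g)
  A22 <- pedigree_A22(sim$pedigree, rownames(g))
  expect_equal(blend_grm(G, A22, 1, 0), G, ignore_attr = "kind")
  expect_equal(blend_grm(G, A22, 0, 1), A22, ignore_attr = "kind")
  Gb <- blend_grm(G, A22)
  expect_equal(unname(Gb), unname(0.95 * G + 0.05 * A22), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_gt(min(eigen(Gb, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_error(blend_grm(G, A22[rev(rownames(A22)), rev(rownames(A22))]),
               "identical order")
  expect_error(blend_grm(G, A22, 0.9, 0.2), "sum to 1")
})

test_that("tuning matches G's mean diagonal and off-diagonal to A22", {
  sim <- small_sim()
  g <- impute_genotypes(qc_genotypes(sim$genotypes)$geno)
  G <- grm_vanraden(g)
  A22 <- pedigree_A22(sim$pedigree, rownames(g))
  Gt <- tune_grm(G, A22)
  n <- nrow(G)
  off <- function(M) (sum(M) - sum(diag(M))) / (n * (n - 1))
  expect_equal(mean(diag(Gt)), mean(diag(A22)), tolerance = 1e-10)
  expect_equal(off(Gt), off(A22), tolerance = 1e-10)
})
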