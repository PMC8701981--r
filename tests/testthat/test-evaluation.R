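# dense construction of the joint single-step H from its definition:
# H11 = A11 + A12 A22i (Gb - A22) A22i A21, H12 = A12 A22i Gb, H22 = Gb
dense_H <- function(A, Gb, gpos) {
  npos <- setdiff(seq_len(nrow(A)), gpos)
  A11 <- A[npos, npos]; A12 <- A[npos, gpos]; A22 <- A[gpos, gpos]
  A22i <- solve(A22)
  H <- matrix(0, nrow(A), ncol(A))
  H[npos, npos] <- A11 + A12 %*% A22i %*% (Gb - A22) %*% A22i %*% t(A12)
  H[npos, gpos] <- A12 %*% A22i %*% Gb
  H[gpos, npos] <- t(H[npos, gpos])
  H[gpos, gpos] <- Gb
  H
}

test_that("H-inverse equals the dense inverse of the joint H (oracle)", {
  ped <- random_pedigree(80L, seed = 31L)
  set.seed(32)
  gids <- sort(sample(ped$id, 30L))
  A <- pedigree_A(ped)
  A22 <- pedigree_A22(ped, gids)
  # a plausible genomic matrix: pedigree relationships plus a random
  # positive semi-definite deviation (keeps the blend positive definite)
  set.seed(33)
  E <- matrix(rnorm(30 * 120, 0, 0.08), 30)
  G <- A22 + tcrossprod(E) - 0.5 * diag(mean(diag(tcrossprod(E))), 30)
  dimnames(G) <- dimnames(A22)
  Gb <- blend_grm(G, A22)
  Hi <- hinv(pedigree_Ainv(ped), A22, Gb)
  H <- dense_H(A, Gb, match(gids, ped$id))
  expect_lt(max(abs(as.matrix(Hi) - solve(H))), 1e-8)
})

test_that("H-inverse collapses to A-inverse in the degenerate cases", {
  ped <- random_pedigree(40L, seed = 8L)
  Ai <- pedigree_Ainv(ped)
  gids <- ped$id[31:40]
  A22 <- pedigree_A22(ped, gids)
  Gb <- A22
  attr(Gb, "kind") <- "G_blend"
  expect_lt(max(abs(as.matrix(hinv(Ai, A22, Gb)) - as.matrix(Ai))), 1e-10)
  # no genotyped animals
  empty <- matrix(0, 0, 0)
  expect_equal(as.matrix(hinv(Ai, empty, empty)), as.matrix(Ai),
               ignore_attr = TRUE)
  # singular inputs are named in the error
  bad <- A22; bad[] <- 1
  expect_error(hinv(Ai, A22, bad), "G_blend")
  expect_error(hinv(Ai, bad, A22), "A22")
})

test_that("MME solutions equal a dense solve on toy data (oracle)", {
  ped <- as_ped(c("s", "d", "x", "y", "z"), c("0", "0", "s", "s", "0"),
                c("0", "0", "d", "d", "0"))
  dat <- data.frame(animal = c("s", "d", "x", "y", "z"),
                    value = c(10.2, 9.1, 11.0, 10.4, 9.8),
                    slaughter_date = "d1",
                    slaughter_age = c(700, 710, 720, 730, 740))
  lambda <- 1.7
  fit <- blup(value ~ slaughter_date + slaughter_age, dat, ped,
              lambda = lambda)
  # oracle: explicit dense MME
  X <- cbind(1, dat$slaughter_age - mean(dat$slaughter_age))
  Z <- diag(5)[match(dat$animal, ped$id), ]  # records x animals (here square)
  Ai <- as.matrix(pedigree_Ainv(ped))
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + lambda * Ai))
  sol <- unname(solve(C, c(crossprod(X, dat$value), crossprod(Z, dat$value))))
  expect_equal(unname(fit$fixef), sol[1:2], tolerance = 1e-9)
  expect_equal(unname(fit$ebv), sol[3:7], tolerance = 1e-9)
})

test_that("infinite shrinkage drives breeding values to zero", {
  sim <- small_sim()
  fit <- blup(form, sim$phenotypes, sim$pedigree, lambda = 1e9)
  expect_lt(max(abs(fit$ebv)), 1e-5 * sd(sim$phenotypes$value))
})

test_that("records constant within levels and huge shrinkage give zero EBV", {
  ped <- as_ped(c("a", "b", "c"), rep("0", 3), rep("0", 3))
  dat <- data.frame(animal = c("a", "b", "c"),
                    value = c(5, 5, 7),
                    slaughter_date = c("d1", "d1", "d2"),
                    slaughter_age = 700)
  fit <- blup(value ~ slaughter_date, dat, ped, lambda = 1)
  # y is exactly explained by the factor: residual rhs for u is zero
  expect_lt(max(abs(fit$ebv)), 1e-10)
})

test_that("solutions are invariant to record permutation", {
  sim <- small_sim()
  fit1 <- blup(form, sim$phenotypes, sim$pedigree, lambda = 1.2)
  set.seed(3)
  perm <- sample(nrow(sim$phenotypes))
  fit2 <- blup(form, sim$phenotypes[perm, ], sim$pedigree, lambda = 1.2)
  expect_equal(fit1$ebv, fit2$ebv, tolerance = 1e-8)
  expect_equal(fit1$fixef, fit2$fixef, tolerance = 1e-8)
})

test_that("unphenotyped terminal progeny EBV is the parent average (PBLUP)", {
  sim <- small_sim()
  ped <- sim$pedigree
  phen <- sim$phenotypes
  # add a childless, recordless progeny of two late animals
  ped2 <- as_ped(c(ped$id, "EXTRA"),
                 c(ifelse(ped$sire > 0L, ped$id[pmax(ped$sire, 1L)], "0"),
                   ped$id[ped$n - 1L]),
                 c(ifelse(ped$dam > 0L, ped$id[pmax(ped$dam, 1L)], "0"),
                   ped$id[ped$n]))
  fit <- blup(form, phen, ped2, lambda = 1.5)
  expect_equal(fit$ebv[["EXTRA"]],
               mean(fit$ebv[c(ped$id[ped$n - 1L], ped$id[ped$n])]),
               tolerance = 1e-8)
})

test_that("ssGBLUP equals PBLUP when the genomic matrix equals A22", {
  sim <- small_sim()
  ped <- sim$pedigree
  gids <- rownames(sim$genotypes)
  Ainv <- pedigree_Ainv(ped)
  A22 <- pedigree_A22(ped, gids)
  Gb <- A22
  attr(Gb, "kind") <- "G_blend"
  Hi <- hinv(Ainv, A22, Gb)
  fitP <- blup(form, sim$phenotypes, ped, lambda = 1.1, K_inv = Ainv)
  fitH <- blup(form, sim$phenotypes, ped, lambda = 1.1, K_inv = Hi)
  expect_equal(fitP$ebv, fitH$ebv, tolerance = 1e-7)
})

test_that("genomic information improves focal accuracy over pedigree alone", {
  reps <- lr_replicates()
  better <- vapply(reps, function(r)
    r$acc_true[["ssGBLUP"]] >= r$acc_true[["PBLUP"]], logical(1))
  expect_gte(sum(better[1:5]), 4L)  # genotyped, unphenotyped focal animals
})

test_that("predict, fitted, residuals and simulate behave coherently", {
  sim <- small_sim()
  fit <- blup(form, sim$phenotypes, sim$pedigree, var_a = 5.45, var_e = 5.45)
  expect_equal(fitted(fit) + residuals(fit), fit$y, tolerance = 1e-12)
  expect_equal(predict(fit), fitted(fit))
  ids <- sim$focal_ids[1:3]
  expect_equal(predict(fit, ids = ids), fit$ebv[ids])
  expect_error(predict(fit, ids = "ghost"), "not in pedigree")
  nd <- sim$phenotypes[1:4, ]
  expect_equal(predict(fit, newdata = nd), unname(fitted(fit)[1:4]),
               tolerance = 1e-10)
  set.seed(1)
  ysim <- simulate(fit, nsim = 3)
  expect_identical(dim(ysim), c(length(fit$y), 3L))
  expect_equal(colMeans(ysim), colMeans(replicate(3, fitted(fit))),
               tolerance = 0.5, ignore_attr = TRUE)
  s <- summary(fit)
  expect_s3_class(s, "summary.blup")
  expect_output(print(s), "animal model")
})
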