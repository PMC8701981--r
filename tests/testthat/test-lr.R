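test_that("LR estimators reduce to hand arithmetic", {
  # accuracy: cov = 0.25, unit denominator -> ratio .25, accuracy .5
  set.seed(1)
  x <- rnorm(200)
  up <- x / sd(x) * 0.5
  uw <- up + 0  # cov(uw, up) = 0.25 exactly up to scaling below
  up <- up - mean(up)
  uw <- up
  scale <- sqrt(0.25 / cov(uw, up))
  up <- up * scale; uw <- uw * scale
  expect_equal(lr_accuracy(up, uw, 0, 0, 1), 0.5, tolerance = 1e-12)
  expect_equal(lr_accuracy(up, uw, 0, 0, 1, sqrt_convention = FALSE), 0.25,
               tolerance = 1e-12)

  # bias is a difference of means
  expect_equal(lr_bias(rep(1.2, 5), rep(1.3, 5)), -0.1)
  expect_equal(lr_bias(up, uw), 0)

  # dispersion is the regression slope of whole on partial
  expect_equal(lr_dispersion(up, uw), 1)
  expect_equal(lr_dispersion(up, 2 * up), 2)

  # ratio estimator
  r <- lr_ratio(up, uw)
  expect_equal(r$correlation, 1)
  expect_equal(r$relative_gain, 0)
  y <- up + rnorm(200, 0, sd(up))  # imperfectly correlated
  r2 <- lr_ratio(up, y)
  expect_equal(r2$relative_gain, 1 / cor(up, y) - 1, tolerance = 1e-12)
})

test_that("accuracy is invariant to shifting both EBV vectors", {
  set.seed(2)
  up <- rnorm(100); uw <- up + rnorm(100, 0, 0.3)
  a1 <- lr_accuracy(up, uw, 0.01, 0.02, 1.3)
  a2 <- lr_accuracy(up + 5, uw + 5, 0.01, 0.02, 1.3)
  expect_equal(a1, a2, tolerance = 1e-12)
  # plus/minus coancestry conventions differ in the stated direction
  am <- lr_accuracy(up, uw, 0.01, 0.02, 1.3, sign = "minus")
  ap <- lr_accuracy(up, uw, 0.01, 0.02, 1.3, sign = "plus")
  expect_gt(am, ap)
})

test_that("uncorrelated partial EBV give ~zero accuracy, clamped at zero", {
  set.seed(3)
  uw <- rnorm(400)
  up <- rnorm(400)
  a <- suppressWarnings(lr_accuracy(up, uw, 0, 0, 1))
  expect_lt(a, 0.15)
  # strongly negative covariance clamps to zero with a warning
  expect_warning(a0 <- lr_accuracy(up, -up, 0, 0, 1), "negative covariance")
  expect_identical(a0, 0)
})

test_that("degenerate inputs are rejected", {
  expect_error(lr_accuracy(rep(1, 5), rnorm(5), 0, 0, 1), "zero variance")
  expect_error(lr_accuracy(rnorm(5), rnorm(5), 0, 0, -1), "denominator")
  expect_error(lr_bias(1:3, 1:4), "length")
  expect_error(lr_dispersion(rep(1, 4), rnorm(4)), "zero variance")
  expect_error(lr_ratio(rep(0, 4), rnorm(4)), "zero variance")
})

test_that("partial/whole splitting removes exactly the focal records", {
  phen <- data.frame(animal = sprintf("a%02d", 1:20), value = rnorm(20) + 30)
  sets <- split_partial(phen, character(0))
  expect_identical(sets$partial, sets$whole)  # empty rule: no removal
  sets <- split_partial(phen, sprintf("a%02d", 16:20))
  expect_identical(nrow(sets$partial), 15L)
  expect_identical(nrow(sets$whole), 20L)
  expect_false(any(sprintf("a%02d", 16:20) %in% sets$partial$animal))
  expect_error(split_partial(phen, "zz"), "disjoint")
  # removing everyone leaves an empty partial set (downstream hard error)
  all_gone <- split_partial(phen, phen$animal)
  expect_identical(nrow(all_gone$partial), 0L)
})

test_that("partial = whole collapses bias, dispersion and correlation", {
  set.seed(4)
  u <- rnorm(50)
  ebv <- list(PBLUP = list(partial = u, whole = u),
              ssGBLUP = list(partial = u, whole = u))
  rep <- lr_report(ebv, list(F_bar = 0, f_bar = 0),
                   list(sigma2_u_inf = var(u)), trait = "t")
  expect_equal(rep$bias, c(0, 0))
  expect_equal(rep$dispersion, c(1, 1))
  expect_equal(rep$cor_partial_whole, c(1, 1))
  expect_equal(rep$gain_partial_whole, c(0, 0))
})

test_that("LR accuracy estimates are calibrated against simulation truth", {
  reps <- lr_replicates()
  for (m in c("PBLUP", "ssGBLUP")) {
    est <- mean(vapply(reps, function(r) r$acc_lr[[m]], numeric(1)))
    tru <- mean(vapply(reps, function(r) r$acc_true[[m]], numeric(1)))
    expect_lt(abs(est - tru), 0.07)
  }
})

test_that("bias and dispersion are calibrated under the correct model", {
  reps <- lr_replicates()
  for (m in c("PBLUP", "ssGBLUP")) {
    b <- vapply(reps, function(r) r$bias[[m]], numeric(1))
    expect_lt(abs(mean(b)), 2 * sd(b) / sqrt(length(b)))
    d <- vapply(reps, function(r) r$dispersion[[m]], numeric(1))
    expect_lt(abs(mean(d) - 1), 0.15)
  }
})

test_that("whole-data information dominates partial-data information", {
  reps <- lr_replicates()
  for (m in c("PBLUP", "ssGBLUP")) {
    viol <- sum(vapply(reps, function(r)
      r$acc_true_whole[[m]] < r$acc_true[[m]], logical(1)))
    expect_lte(viol, 1L)
  }
})

test_that("the full validation wrapper reproduces its building blocks", {
  sim <- small_sim()
  geno <- impute_genotypes(qc_genotypes(sim$genotypes)$geno)
  set.seed(91)
  rep <- lr_validate(form, sim$phenotypes, sim$pedigree, geno, sim$focal_ids,
                     control = gibbs_control(chain = 2000L, burn_in = 500L,
                                             thin = 5L))
  expect_s3_class(rep, "lr_report")
  expect_setequal(rep$method, c("PBLUP", "ssGBLUP"))
  expect_true(all(rep$acc_partial >= 0 & rep$acc_partial <= 1.2))
  expect_true(all(rep$dispersion > 0))
  expect_identical(rep$denominator_sign[1], "minus")
  expect_output(print(rep), "LR-method validation report")
})
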