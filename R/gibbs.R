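#' Gibbs sampler settings
#'
#' Desk-scale defaults (50,000 cycles, 5,000 burn-in, thinning 10). The
#' published long chain is `gibbs_control(chain = 550000, burn_in = 50000,
#' thin = 50)`. Priors are scaled-inverse-chi-square per variance; the
#' default `nu = -2, S2 = 0` is flat on the variances, so posterior means are
#' comparable to REML.
#'
#' @param chain Total Gibbs cycles.
#' @param burn_in Cycles discarded before sampling.
#' @param thin Thinning interval.
#' @param nu_a,S2_a,nu_e,S2_e Prior degrees of freedom and scale for the
#'   genetic and residual variance.
#' @param start_h2 Heritability used to split the phenotypic variance into
#'   starting values.
#' @param seed Optional RNG seed applied at the start of the run.
#' @return List of class `gibbs_control`.
#' @export
gibbs_control <- function(chain = 50000L, burn_in = 5000L, thin = 10L,
                          nu_a = -2, S2_a = 0, nu_e = -2, S2_e = 0,
                          start_h2 = 0.5, seed = NULL) {
  stopifnot(burn_in < chain, thin >= 1L, start_h2 > 0, start_h2 < 1)
  if ((chain - burn_in) / thin < 100)
    stop("settings retain fewer than 100 samples")
  structure(list(chain = as.integer(chain), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), nu_a = nu_a, S2_a = S2_a,
                 nu_e = nu_e, S2_e = S2_e, start_h2 = start_h2, seed = seed),
            class = "gibbs_control")
}

#' Bayesian variance components for an animal model by Gibbs sampling
#'
#' Single-trait animal model `y = X b + Z u + e` with `u ~ N(0, K sigma2_a)`.
#' Location effects are sampled single-site from their Gaussian full
#' conditionals; each variance from its scaled-inverse-chi-square full
#' conditional (scale `u' K^-1 u` resp. `e'e`). Posterior summaries are taken
#' over the retained (post burn-in, thinned) samples. Convergence is checked
#' by the split-chain potential scale reduction factor on both variances.
#'
#' @inheritParams blup
#' @param K_inv Sparse relationship-matrix inverse; defaults to
#'   [pedigree_Ainv()] of the pedigree (the pedigree-based model).
#' @param control A [gibbs_control()] list.
#' @param focal_ids Animal ids whose breeding-value samples are retained
#'   (needed by [equilibrium_variance()]).
#' @return Object of class `vc_gibbs`: posterior means and SDs of
#'   `sigma2_a`, `sigma2_e`, `sigma2_p`, `h2`, `cv_g`; traces; `u_mean`
#'   (posterior-mean breeding values); `u_focal` (retained samples, focal
#'   animals x samples); `psrf`; and the settings used.
#' @export
vc_gibbs <- function(formula, data, pedigree, K_inv = NULL,
                     control = gibbs_control(), id = "animal",
                     focal_ids = character()) {
  stopifnot(inherits(pedigree, "ped"), inherits(control, "gibbs_control"))
  if (!is.null(control$seed)) set.seed(control$seed)
  anim <- as.character(data[[id]])
  code <- match(anim, pedigree$id)
  if (anyNA(code)) stop("phenotyped animals missing from pedigree")
  if (is.null(K_inv)) K_inv <- pedigree_Ainv(pedigree)
  K <- methods::as(K_inv, "CsparseMatrix")
  des <- build_design(formula, data)
  y <- as.numeric(des$y)
  vy <- var(y)
  sa0 <- control$start_h2 * vy
  se0 <- (1 - control$start_h2) * vy
  fpos <- match(as.character(focal_ids), pedigree$id)
  if (anyNA(fpos)) stop("focal animals missing from pedigree")

  res <- gibbs_animal_cpp(y, as.matrix(des$X), as.integer(code),
                          K@i, K@p, K@x, pedigree$n,
                          control$chain, control$burn_in, control$thin,
                          control$nu_a, control$S2_a,
                          control$nu_e, control$S2_e,
                          sa0, se0, as.integer(fpos))
  sa <- res$sigma2_a; se <- res$sigma2_e
  h2s <- sa / (sa + se)
  rownames(res$u_focal) <- as.character(focal_ids)
  out <- structure(list(
    sigma2_a = mean(sa), sd_a = sd(sa),
    sigma2_e = mean(se), sd_e = sd(se),
    sigma2_p = mean(sa + se), sd_p = sd(sa + se),
    h2 = mean(h2s), sd_h2 = sd(h2s),
    trait_mean = mean(y),
    cv_g = cv_genetic(mean(sa), mean(y)),
    lambda = mean(se) / mean(sa),
    trace = data.frame(sample = seq_along(sa), sigma2_a = sa, sigma2_e = se),
    u_mean = setNames(res$u_mean, pedigree$id),
    u_focal = res$u_focal,
    n_kept = res$n_kept,
    psrf = c(sigma2_a = psrf(sa), sigma2_e = psrf(se)),
    control = control,
    trait = des$trait
  ), class = "vc_gibbs")
  if (any(out$psrf > 1.05))
    warning("potential scale reduction factor > 1.05 (",
            paste(sprintf("%s = %.3f", names(out$psrf), out$psrf),
                  collapse = ", "),
            "): chain may not have converged; consider a longer run")
  out
}

# split-chain potential scale reduction factor (two halves of one chain)
psrf <- function(x) {
  k <- length(x) %/% 2L
  if (k < 2L) return(NA_real_)
  halves <- list(x[seq_len(k)], x[k + seq_len(k)])
  n <- k
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Heritability from variance components
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_e)`.
#'
#' @param sigma2_a Additive genetic variance.
#' @param sigma2_e Residual variance.
#' @export
heritability <- function(sigma2_a, sigma2_e) {
  stopifnot(sigma2_a >= 0, sigma2_e >= 0, sigma2_a + sigma2_e > 0)
  sigma2_a / (sigma2_a + sigma2_e)
}

#' Coefficient of genetic variation
#'
#' Genetic standard deviation as a percentage of the trait mean:
#' `100 * sqrt(sigma2_a) / trait_mean`.
#'
#' @param sigma2_a Additive genetic variance (trait units squared).
#' @param trait_mean Trait mean (> 0).
#' @export
cv_genetic <- function(sigma2_a, trait_mean) {
  if (any(trait_mean <= 0)) stop("trait mean must be > 0")
  100 * sqrt(sigma2_a) / trait_mean
}

#' Posterior variance-component summary from retained samples
#'
#' @param sigma2_a,sigma2_e Numeric vectors of retained variance samples
#'   (>= 100 each).
#' @param trait_mean Trait mean used for the coefficient of genetic
#'   variation.
#' @return List with posterior means and SDs of the variances, `sigma2_p`,
#'   `h2` (posterior mean of the per-sample ratio) and `cv_g`.
#' @export
summarize_components <- function(sigma2_a, sigma2_e, trait_mean) {
  stopifnot(length(sigma2_a) >= 100L, length(sigma2_e) == length(sigma2_a))
  if (trait_mean <= 0) stop("trait mean must be > 0")
  h2s <- sigma2_a / (sigma2_a + sigma2_e)
  list(sigma2_a = mean(sigma2_a), sd_a = sd(sigma2_a),
       sigma2_e = mean(sigma2_e), sd_e = sd(sigma2_e),
       sigma2_p = mean(sigma2_a + sigma2_e), sd_p = sd(sigma2_a + sigma2_e),
       h2 = mean(h2s), sd_h2 = sd(h2s),
       cv_g = cv_genetic(mean(sigma2_a), trait_mean))
}

#' Equilibrium genetic variance of a selected cohort
#'
#' For each retained Gibbs sample of the focal animals' breeding values,
#' computes the empirical variance across the cohort; the estimate is the
#' mean over samples, with a Monte-Carlo standard error. Under selection this
#' is the (reduced) genetic variance the LR accuracy denominator requires.
#'
#' @param fit A `vc_gibbs` fit run with `focal_ids`, or a matrix of retained
#'   breeding-value samples (focal animals x samples).
#' @return List with `sigma2_u_inf` and `mc_se`.
#' @export
equilibrium_variance <- function(fit) {
  u <- if (inherits(fit, "vc_gibbs")) fit$u_focal else fit
  stopifnot(is.matrix(u))
  if (nrow(u) < 2L) stop("focal group must contain at least 2 animals")
  if (ncol(u) < 100L) stop("need at least 100 retained samples")
  v <- apply(u, 2L, var)
  out <- list(sigma2_u_inf = mean(v), mc_se = sd(v) / sqrt(length(v)))
  if (out$sigma2_u_inf < .Machine$double.eps^0.5)
    warning("degenerate focal breeding-value samples: equilibrium variance ~ 0")
  out
}

#' @export
print.vc_gibbs <- function(x, ...) {
  cat(sprintf("Gibbs variance components, trait '%s'\n", x$trait))
  cat(sprintf("  chain %d, burn-in %d, thin %d -> %d retained samples\n",
              x$control$chain, x$control$burn_in, x$control$thin, x$n_kept))
  cat(sprintf("  sigma2_a = %.4g (%.3g)   sigma2_e = %.4g (%.3g)\n",
              x$sigma2_a, x$sd_a, x$sigma2_e, x$sd_e))
  cat(sprintf("  h2 = %.3f (%.3f)   CV_g = %.2f%%   lambda = %.4g\n",
              x$h2, x$sd_h2, x$cv_g, x$lambda))
  cat(sprintf("  split-chain PSRF: sigma2_a %.3f, sigma2_e %.3f\n",
              x$psrf[1L], x$psrf[2L]))
  invisible(x)
}

#' @export
summary.vc_gibbs <- function(object, ...) {
  print(object)
  invisible(object[c("sigma2_a", "sd_a", "sigma2_e", "sd_e", "sigma2_p",
                     "sd_p", "h2", "sd_h2", "cv_g", "lambda", "psrf")])
}

#' Trace plot of the variance-component chain
#' @param x A `vc_gibbs` fit.
#' @param ... Passed to `plot()`.
#' @export
plot.vc_gibbs <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(x$trace$sample, x$trace$sigma2_a, type = "l",
       xlab = "retained sample", ylab = "sigma2_a", ...)
  plot(x$trace$sample, x$trace$sigma2_e, type = "l",
       xlab = "retained sample", ylab = "sigma2_e", ...)
  invisible(x)
}

#' Write the variance trace as TSV
#'
#' Columns `sample`, `sigma2_a`, `sigma2_e` for external chain diagnostics.
#'
#' @param fit A `vc_gibbs` fit.
#' @param path Output path.
#' @export
write_trace <- function(fit, path) {
  write.table(fit$trace, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
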