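#' Inverse of the single-step relationship matrix H
#'
#' `H^-1 = A^-1 + [0 0; 0 (G_blend)^-1 - (A22)^-1]`, with the non-zero block
#' on the genotyped animals. The result carries pedigree and genomic
#' information for genotyped and non-genotyped animals simultaneously.
#'
#' @param Ainv Sparse inverse of A over the full pedigree ([pedigree_Ainv()]).
#' @param A22 Pedigree relationships of the genotyped animals
#'   ([pedigree_A22()]).
#' @param G_blend Blended genomic matrix over the same animals in the same
#'   order ([blend_grm()]).
#' @return Sparse symmetric `dgCMatrix` over the full pedigree, attribute
#'   `kind = "H_inv"`.
#' @export
hinv <- function(Ainv, A22, G_blend) {
  ids <- rownames(A22)
  if (length(ids) == 0L) {
    out <- Ainv
    attr(out, "kind") <- "H_inv"
    return(out)
  }
  if (!identical(ids, rownames(G_blend)))
    stop("A22 and G_blend must be over identical animals in identical order")
  pos <- match(ids, rownames(Ainv))
  if (anyNA(pos)) stop("genotyped animals missing from A-inverse: ",
                       paste(head(ids[is.na(pos)], 5L), collapse = ", "))
  Gi <- chol_inverse(G_blend, "G_blend")
  A22i <- chol_inverse(A22, "A22")
  H <- methods::as(Ainv, "TsparseMatrix")
  block <- Gi - A22i
  n_g <- length(ids)
  Hi <- Matrix::sparseMatrix(
    i = c(H@i + 1L, rep(pos, times = n_g)),
    j = c(H@j + 1L, rep(pos, each = n_g)),
    x = c(H@x, as.vector(block)),
    dims = dim(Ainv), dimnames = dimnames(Ainv))
  Hi <- methods::as(Hi, "generalMatrix")
  attr(Hi, "kind") <- "H_inv"
  Hi
}

chol_inverse <- function(K, name) {
  R <- tryCatch(chol(K), error = function(e)
    stop("matrix ", name, " is singular (not positive definite): ",
         conditionMessage(e), call. = FALSE))
  chol2inv(R)
}

#' Solve Henderson's mixed model equations
#'
#' Sparse direct solve of
#' `[X'X  X'Z; Z'X  Z'Z + lambda * K^-1] [b; u] = [X'y; Z'y]`
#' for fixed effects `b` and breeding values `u` over all animals indexed by
#' `K^-1` (phenotyped or not).
#'
#' @param X Fixed-effect design matrix (records x effects), dense or sparse.
#' @param Z Sparse incidence matrix (records x animals).
#' @param y Numeric response vector.
#' @param Kinv Sparse relationship-matrix inverse (A or H).
#' @param lambda Variance ratio `sigma2_e / sigma2_a` (> 0).
#' @return List with `b` (named), `u` (named, all animals), `residual_norm`
#'   (relative residual of the solve).
#' @export
solve_mme <- function(X, Z, y, Kinv, lambda) {
  stopifnot(lambda > 0, nrow(X) == length(y), nrow(Z) == length(y))
  X <- methods::as(methods::as(X, "CsparseMatrix"), "generalMatrix")
  keep <- Matrix::colSums(X != 0) > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " empty fixed-effect column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  C <- rbind(
    cbind(Matrix::crossprod(X), Matrix::crossprod(X, Z)),
    cbind(Matrix::crossprod(Z, X), Matrix::crossprod(Z) + lambda * Kinv))
  rhs <- c(as.vector(Matrix::crossprod(X, y)),
           as.vector(Matrix::crossprod(Z, y)))
  C <- Matrix::forceSymmetric(C)
  sol <- tryCatch(
    as.vector(Matrix::solve(C, rhs)),
    error = function(e) stop("mixed model equations are singular ",
                             "(confounded fixed effects?): ",
                             conditionMessage(e), call. = FALSE))
  res <- sqrt(sum((as.vector(C %*% sol) - rhs)^2)) / max(sqrt(sum(rhs^2)), 1e-300)
  if (!is.finite(res) || res > 1e-10) {
    # one step of iterative refinement, then insist on the tolerance
    corr <- tryCatch(as.vector(Matrix::solve(C, rhs - as.vector(C %*% sol))),
                     error = function(e) 0)
    sol <- sol + corr
    res <- sqrt(sum((as.vector(C %*% sol) - rhs)^2)) /
      max(sqrt(sum(rhs^2)), 1e-300)
    if (!is.finite(res) || res > 1e-10)
      stop("mixed model solve did not reach tolerance: relative residual ",
           format(res))
  }
  p <- ncol(X)
  list(b = setNames(sol[seq_len(p)], colnames(X)),
       u = setNames(sol[-seq_len(p)], colnames(Z)),
       residual_norm = res)
}

#' Fit an animal model by PBLUP or single-step GBLUP
#'
#' Solves the mixed model `y = X b + Z u + e` with `u ~ N(0, K sigma2_a)`,
#' `e ~ N(0, I sigma2_e)`, where K is the pedigree relationship matrix A
#' (PBLUP) or, when genotypes are supplied, the single-step matrix H that
#' combines pedigree and genomic information (ssGBLUP). Fixed effects are
#' fitted without an explicit intercept (the first factor absorbs the mean)
#' and numeric covariates are centred.
#'
#' @param formula Model formula for the record-level fixed effects, e.g.
#'   `value ~ slaughter_date + slaughter_age`. The response is the trait;
#'   the animal term is implicit (see `id`).
#' @param data Data frame of phenotype records; must contain the column named
#'   by `id` linking each record to a pedigree animal.
#' @param pedigree Ordered pedigree ([as_ped()]); breeding values are
#'   predicted for every pedigree animal.
#' @param genotypes Optional complete dosage matrix (animals x SNPs, rownames
#'   = animal ids). When supplied the model is ssGBLUP with
#'   `H^-1` built from `A^-1`, `A22` and the blended VanRaden G.
#' @param lambda Variance ratio `sigma2_e / sigma2_a`. Either `lambda` or a
#'   fitted [vc_gibbs()] object via `vc`, or both variances, must be given.
#' @param vc Optional `vc_gibbs` fit; its posterior means supply the
#'   variances.
#' @param var_a,var_e Optional variance components (override `lambda`).
#' @param id Name of the animal-id column of `data`. Default `"animal"`.
#' @param w_G,w_A Blend weights for `w_G * G + w_A * A22` (default 0.95/0.05).
#' @param tune Logical: rescale G to the mean diagonal/off-diagonal of A22
#'   before blending ([tune_grm()]). Default `FALSE`.
#' @param K_inv Optional precomputed relationship-matrix inverse over the
#'   pedigree (bypasses the internal construction).
#' @param dataset Tag stored on the fit, e.g. `"whole"` or `"partial"`.
#' @return An object of class `blup` with components `ebv` (named, all
#'   pedigree animals), `fixef`, `method`, `dataset`, `trait`, `lambda`,
#'   `var_a`, `var_e`, `fitted`, `residuals`, plus bookkeeping.
#' @examples
#' ped <- as_ped(c("s", "d", "x"), c("0", "0", "s"), c("0", "0", "d"))
#' dat <- data.frame(animal = c("s", "d"), y = c(10.2, 9.1), batch = "b1")
#' fit <- blup(y ~ batch, dat, ped, lambda = 2)
#' coef(fit)
#' @export
blup <- function(formula, data, pedigree, genotypes = NULL, lambda = NULL,
                 vc = NULL, var_a = NULL, var_e = NULL, id = "animal",
                 w_G = 0.95, w_A = 0.05, tune = FALSE, K_inv = NULL,
                 dataset = "whole") {
  stopifnot(inherits(pedigree, "ped"))
  if (!id %in% names(data)) stop("data has no '", id, "' column")
  if (!is.null(vc)) {
    stopifnot(inherits(vc, "vc_gibbs"))
    var_a <- vc$sigma2_a; var_e <- vc$sigma2_e
  }
  if (!is.null(var_a) && !is.null(var_e)) lambda <- var_e / var_a
  if (is.null(lambda)) stop("supply lambda, vc, or var_a and var_e")

  anim <- as.character(data[[id]])
  code <- match(anim, pedigree$id)
  if (anyNA(code))
    stop("phenotyped animals missing from pedigree: ",
         paste(head(unique(anim[is.na(code)]), 5L), collapse = ", "))

  des <- build_design(formula, data)
  n <- length(des$y)
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = code,
                            dims = c(n, pedigree$n),
                            dimnames = list(NULL, pedigree$id))

  method <- if (is.null(genotypes) && is.null(K_inv)) "PBLUP"
            else if (!is.null(K_inv)) attr(K_inv, "method") %||% "custom"
            else "ssGBLUP"
  if (is.null(K_inv)) {
    Ainv <- pedigree_Ainv(pedigree)
    if (is.null(genotypes)) {
      K_inv <- Ainv
    } else {
      gid <- rownames(genotypes)
      A22 <- pedigree_A22(pedigree, gid)
      G <- grm_vanraden(genotypes)
      if (tune) G <- tune_grm(G, A22)
      K_inv <- hinv(Ainv, A22, blend_grm(G, A22, w_G, w_A))
    }
  }
  sol <- solve_mme(des$X, Z, des$y, K_inv, lambda)
  fitted <- as.vector(des$X %*% sol$b) + unname(sol$u[code])
  structure(list(
    ebv = sol$u,
    fixef = sol$b,
    method = method,
    dataset = dataset,
    trait = des$trait,
    lambda = lambda,
    var_a = var_a, var_e = var_e,
    fitted = fitted,
    residuals = des$y - fitted,
    y = des$y,
    animal = anim,
    formula = formula,
    terms = des$terms,
    xlevels = des$xlevels,
    x_center = des$x_center,
    residual_norm = sol$residual_norm,
    call = match.call()
  ), class = "blup")
}

# design matrix without explicit intercept; factors in cell-means coding,
# numeric covariates centred (stored centres reused by predict())
build_design <- function(formula, data, xlevels = NULL, x_center = NULL,
                         drop_response = FALSE) {
  ff <- stats::update(formula, . ~ . + 0)
  if (drop_response) ff <- ff[-2L]
  mf <- stats::model.frame(ff, data, drop.unused.levels = is.null(xlevels),
                           xlev = xlevels)
  tt <- attr(mf, "terms")
  y <- if (drop_response) NULL else stats::model.response(mf)
  num <- vapply(mf, is.numeric, logical(1))
  if (!drop_response && length(num)) num[1L] <- FALSE
  if (is.null(x_center)) {
    x_center <- vapply(mf[num], mean, numeric(1))
  }
  for (v in names(x_center)) mf[[v]] <- mf[[v]] - x_center[[v]]
  # single-level factors (legal in cell-means coding) need a padding level
  # to satisfy model.matrix; the padded column is all-zero and dropped
  isfac <- vapply(mf, function(v) is.character(v) || is.factor(v), logical(1))
  for (v in names(mf)[isfac]) mf[[v]] <- factor(mf[[v]])
  pad <- names(mf)[isfac][vapply(mf[isfac], nlevels, 1L) < 2L]
  for (v in pad) levels(mf[[v]]) <- c(levels(mf[[v]]), "..pad")
  X <- stats::model.matrix(tt, mf)
  X <- X[, !grepl("\\.\\.pad$", colnames(X)), drop = FALSE]
  list(X = X, y = y, terms = tt,
       trait = if (drop_response) NA_character_ else deparse(formula[[2L]]),
       xlevels = stats::.getXlevels(tt, mf), x_center = x_center)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.blup <- function(x, ...) {
  cat(sprintf("%s fit of trait '%s' (%s dataset)\n",
              x$method, x$trait, x$dataset))
  cat(sprintf("  %d records, %d pedigree animals, lambda = %.4g\n",
              length(x$y), length(x$ebv), x$lambda))
  cat(sprintf("  EBV range: [%.3f, %.3f]\n", min(x$ebv), max(x$ebv)))
  invisible(x)
}

#' @export
summary.blup <- function(object, ...) {
  phen <- unique(object$animal)
  out <- list(
    method = object$method, dataset = object$dataset, trait = object$trait,
    n_records = length(object$y), n_animals = length(object$ebv),
    n_phenotyped = length(phen),
    lambda = object$lambda, var_a = object$var_a, var_e = object$var_e,
    fixef = object$fixef,
    ebv_summary = summary(object$ebv),
    sd_ebv = sd(object$ebv),
    residual_sd = sd(object$residuals))
  class(out) <- "summary.blup"
  out
}

#' @export
print.summary.blup <- function(x, ...) {
  cat(sprintf("%s animal model, trait '%s' (%s dataset)\n",
              x$method, x$trait, x$dataset))
  cat(sprintf("  records: %d   phenotyped animals: %d   pedigree animals: %d\n",
              x$n_records, x$n_phenotyped, x$n_animals))
  if (!is.null(x$var_a))
    cat(sprintf("  variance components: sigma2_a = %.4g, sigma2_e = %.4g\n",
                x$var_a, x$var_e))
  cat(sprintf("  lambda (sigma2_e / sigma2_a): %.4g\n", x$lambda))
  cat(sprintf("  EBV sd: %.4g   residual sd: %.4g\n", x$sd_ebv, x$residual_sd))
  cat("  fixed effects (first 6):\n")
  print(head(x$fixef))
  invisible(x)
}

#' @export
coef.blup <- function(object, ...) object$fixef

#' Predicted breeding values or record-level predictions
#'
#' With no arguments, returns fitted values for the training records. With
#' `ids`, returns the (G)EBV of the named pedigree animals — defined for
#' every animal in the pedigree, phenotyped or not. With `newdata`, returns
#' `X b + u` for new records of known animals.
#'
#' @param object A `blup` fit.
#' @param newdata Optional data frame of new records.
#' @param ids Optional character vector of animal ids.
#' @param ... Unused.
#' @export
predict.blup <- function(object, newdata = NULL, ids = NULL, ...) {
  if (!is.null(ids)) {
    miss <- setdiff(ids, names(object$ebv))
    if (length(miss)) stop("animals not in pedigree: ",
                           paste(head(miss, 5L), collapse = ", "))
    return(object$ebv[as.character(ids)])
  }
  if (is.null(newdata)) return(object$fitted)
  des <- build_design(object$formula, newdata, xlevels = object$xlevels,
                      x_center = object$x_center, drop_response = TRUE)
  u <- predict(object, ids = as.character(newdata$animal))
  as.vector(des$X %*% object$fixef[colnames(des$X)]) + unname(u)
}

#' @export
fitted.blup <- function(object, ...) object$fitted

#' @export
residuals.blup <- function(object, ...) object$residuals

#' Simulate phenotypes from a fitted animal model
#'
#' Draws new record vectors conditional on the estimated fixed effects and
#' breeding values: `y* = X b + Z u + e*` with `e* ~ N(0, sigma2_e)`.
#' Requires the residual variance (from `var_e` or the residual mean square).
#'
#' @param object A `blup` fit.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns, one simulated response per column.
#' @export
simulate.blup <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  s2e <- object$var_e %||% mean(object$residuals^2)
  n <- length(object$fitted)
  out <- as.data.frame(replicate(nsim, object$fitted + rnorm(n, 0, sqrt(s2e)),
                                 simplify = FALSE),
                       col.names = paste0("sim_", seq_len(nsim)))
  out
}

#' Diagnostic plot of a BLUP fit
#'
#' Observed vs fitted records and the EBV distribution split by phenotyped
#' status.
#'
#' @param x A `blup` fit.
#' @param ... Passed to `plot()`.
#' @export
plot.blup <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$fitted, x$y, xlab = "fitted", ylab = "observed",
       main = paste(x$method, x$trait), ...)
  graphics::abline(0, 1, lty = 2)
  phen <- names(x$ebv) %in% x$animal
  graphics::boxplot(list(phenotyped = x$ebv[phen],
                         unphenotyped = x$ebv[!phen]),
                    ylab = "EBV", main = "breeding values")
  invisible(x)
}
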