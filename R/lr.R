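#' Split phenotypes into whole and partial datasets
#'
#' The partial dataset removes the phenotype records of the focal (validation)
#' cohort; pedigree and genotypes are untouched, so focal animals remain in
#' the evaluation as unphenotyped candidates.
#'
#' @param phenotypes Data frame of phenotype records with an `animal` column.
#' @param focal_ids Identifiers of the focal cohort.
#' @return List with `whole` and `partial` data frames.
#' @export
split_partial <- function(phenotypes, focal_ids) {
  focal_ids <- as.character(focal_ids)
  if (length(focal_ids) == 0L)   # empty removal rule: partial == whole
    return(list(whole = phenotypes, partial = phenotypes))
  hit <- phenotypes$animal %in% focal_ids
  if (!any(hit))
    stop("focal cohort is disjoint from the phenotyped animals")
  list(whole = phenotypes, partial = phenotypes[!hit, , drop = FALSE])
}

#' Focal cohort by birth year
#'
#' Animals whose pedigree birth year falls in the stated window — the
#' youngest cohorts under the usual forward-validation design.
#'
#' @param ped Ordered pedigree with birth years.
#' @param birth_years Integer vector of birth years.
#' @return Character vector of animal ids.
#' @export
focal_cohort <- function(ped, birth_years) {
  ids <- ped$id[!is.na(ped$birth_year) & ped$birth_year %in% birth_years]
  if (!length(ids)) stop("no animals born in ",
                         paste(birth_years, collapse = ", "))
  ids
}

#' LR estimator of population accuracy
#'
#' `rho2 = cov(u_w, u_p) / ((1 + F_bar +/- 2 f_bar) * sigma2_u_inf)` over the
#' focal animals, where `F_bar` is the mean inbreeding coefficient, `f_bar`
#' the mean pairwise coancestry, and `sigma2_u_inf` the equilibrium genetic
#' variance of the cohort under selection. The ratio estimates the squared
#' accuracy of the partial evaluation; by default its square root is
#' returned. The sign of the coancestry term differs between the original
#' LR-method reference (minus, the default) and some published variants
#' (plus); both are available.
#'
#' @param u_p,u_w Focal-animal EBV from the partial and whole evaluations,
#'   in the same animal order.
#' @param F_bar,f_bar Mean inbreeding and mean coancestry of the cohort
#'   ([inbreeding_summary()]).
#' @param sigma2_u_inf Equilibrium genetic variance
#'   ([equilibrium_variance()]).
#' @param sign `"minus"` (default) or `"plus"`: sign of `2 f_bar` in the
#'   denominator.
#' @param sqrt_convention Return `sqrt(ratio)` (an accuracy, the default) or
#'   the raw ratio (a squared accuracy).
#' @return Accuracy estimate in `[0, 1]`; negative covariance ratios are
#'   clamped to 0 with a warning.
#' @export
lr_accuracy <- function(u_p, u_w, F_bar, f_bar, sigma2_u_inf,
                        sign = c("minus", "plus"), sqrt_convention = TRUE) {
  sign <- match.arg(sign)
  stopifnot(length(u_p) == length(u_w), length(u_p) >= 2L)
  if (sd(u_p) == 0 || sd(u_w) == 0)
    stop("EBV vector with zero variance: accuracy undefined")
  denom <- (1 + F_bar + if (sign == "minus") -2 * f_bar else 2 * f_bar) *
    sigma2_u_inf
  if (denom <= 0) stop("non-positive accuracy denominator")
  ratio <- cov(u_w, u_p) / denom
  if (ratio < 0) {
    warning("negative covariance between partial and whole EBV: ",
            "accuracy reported as 0")
    return(0)
  }
  if (sqrt_convention) sqrt(ratio) else ratio
}

#' LR estimator of bias
#'
#' `mu_wp = mean(u_p) - mean(u_w)` in trait units; 0 for an unbiased
#' evaluation.
#'
#' @inheritParams lr_accuracy
#' @export
lr_bias <- function(u_p, u_w) {
  if (length(u_p) != length(u_w)) stop("EBV vectors differ in length")
  mean(u_p) - mean(u_w)
}

#' LR estimator of dispersion
#'
#' Slope of the regression of the whole-data EBV on the partial-data EBV,
#' `b_wp = cov(u_w, u_p) / var(u_p)`; 1 when predictions are neither
#' inflated (< 1) nor deflated (> 1).
#'
#' @inheritParams lr_accuracy
#' @export
lr_dispersion <- function(u_p, u_w) {
  stopifnot(length(u_p) == length(u_w))
  v <- var(u_p)
  if (v == 0) stop("partial EBV have zero variance: dispersion undefined")
  cov(u_w, u_p) / v
}

#' Correlation ratio between two evaluations
#'
#' Pearson correlation of two focal EBV vectors and the implied relative gain
#' in accuracy `1 / rho - 1` when moving from the less to the more informed
#' evaluation (two methods on one dataset, or partial vs whole for one
#' method).
#'
#' @param u_a,u_b Focal EBV vectors in the same animal order.
#' @return List with `correlation` and `relative_gain`.
#' @export
lr_ratio <- function(u_a, u_b) {
  stopifnot(length(u_a) == length(u_b))
  if (sd(u_a) == 0 || sd(u_b) == 0)
    stop("EBV vector with zero variance: correlation undefined")
  r <- cor(u_a, u_b)
  list(correlation = r, relative_gain = 1 / r - 1)
}

#' Run the full LR-method comparison for one trait
#'
#' Fits PBLUP and ssGBLUP on the whole and the partial dataset (focal
#' phenotypes removed), estimates variance components and the equilibrium
#' genetic variance by Gibbs sampling on the whole data under the
#' pedigree-based model, and assembles all LR estimators.
#'
#' @inheritParams blup
#' @param phenotypes Data frame of phenotype records (one trait).
#' @param focal_ids Focal (validation) cohort; phenotyped in the whole data.
#' @param genotypes Complete dosage matrix of the genotyped animals.
#' @param control [gibbs_control()] for the variance-component chain.
#' @param sign,sqrt_convention Passed to [lr_accuracy()].
#' @param trait Trait label stored in the report.
#' @param vc Optional precomputed `vc_gibbs` fit (must have been run with
#'   `focal_ids`); skips the sampling stage.
#' @return An `lr_report`: data.frame with one row per method carrying
#'   accuracies, bias, dispersion and the ratio estimators, plus the scalar
#'   inputs (`F_bar`, `f_bar`, `sigma2_u_inf`, `lambda`).
#' @export
lr_validate <- function(formula, phenotypes, pedigree, genotypes, focal_ids,
                        control = gibbs_control(), w_G = 0.95, w_A = 0.05,
                        tune = FALSE, sign = "minus", sqrt_convention = TRUE,
                        id = "animal", trait = NULL, vc = NULL) {
  focal_ids <- as.character(focal_ids)
  sets <- split_partial(phenotypes, focal_ids)
  if (nrow(sets$partial) == 0L)
    stop("partial dataset has no records: focal cohort covers all phenotypes")

  if (is.null(vc)) {
    vc <- vc_gibbs(formula, sets$whole, pedigree, control = control, id = id,
                   focal_ids = focal_ids)
  } else if (!all(focal_ids %in% rownames(vc$u_focal))) {
    stop("supplied vc fit lacks breeding-value samples for the focal cohort")
  }
  eq <- equilibrium_variance(vc)
  inb <- inbreeding_summary(pedigree, focal_ids)

  Ainv <- pedigree_Ainv(pedigree)
  A22 <- pedigree_A22(pedigree, rownames(genotypes))
  G <- grm_vanraden(genotypes)
  if (tune) G <- tune_grm(G, A22)
  Hinv <- hinv(Ainv, A22, blend_grm(G, A22, w_G, w_A))
  attr(Ainv, "method") <- "PBLUP"
  attr(Hinv, "method") <- "ssGBLUP"

  ebv <- list()
  for (m in c("PBLUP", "ssGBLUP")) {
    K <- if (m == "PBLUP") Ainv else Hinv
    for (ds in c("whole", "partial")) {
      fit <- blup(formula, sets[[ds]], pedigree, lambda = vc$lambda,
                  K_inv = K, id = id, dataset = ds)
      ebv[[m]][[ds]] <- fit$ebv[focal_ids]
    }
  }
  if (is.null(trait)) trait <- vc$trait
  lr_report(ebv, inb, eq, trait = trait, lambda = vc$lambda, sign = sign,
            sqrt_convention = sqrt_convention)
}

#' Assemble an LR report from focal EBV
#'
#' Lower-level constructor used by [lr_validate()] and [run_study()]: takes
#' the four focal EBV vectors (method x dataset) plus the scalar inputs and
#' computes every estimator.
#'
#' @param ebv Nested list `ebv[[method]][[dataset]]` of focal EBV vectors
#'   (same animal order), methods `PBLUP` and `ssGBLUP`, datasets `whole`
#'   and `partial`.
#' @param inb [inbreeding_summary()] of the focal cohort.
#' @param eq [equilibrium_variance()] result.
#' @param trait Trait label.
#' @param lambda Variance ratio used in the fits (stored for provenance).
#' @inheritParams lr_accuracy
#' @return An `lr_report` data.frame.
#' @export
lr_report <- function(ebv, inb, eq, trait = "trait", lambda = NA_real_,
                      sign = "minus", sqrt_convention = TRUE) {
  methods <- names(ebv)
  rows <- lapply(methods, function(m) {
    up <- ebv[[m]]$partial; uw <- ebv[[m]]$whole
    acc_p <- lr_accuracy(up, uw, inb$F_bar, inb$f_bar, eq$sigma2_u_inf,
                         sign = sign, sqrt_convention = sqrt_convention)
    rp <- lr_ratio(up, uw)
    # whole-data accuracy via the accuracy-ratio property of cor(u_p, u_w)
    acc_w <- min(1, acc_p / rp$correlation)
    data.frame(trait = trait, method = m,
               acc_partial = acc_p, acc_whole = acc_w,
               bias = lr_bias(up, uw),
               dispersion = lr_dispersion(up, uw),
               cor_partial_whole = rp$correlation,
               gain_partial_whole = rp$relative_gain)
  })
  df <- do.call(rbind, rows)
  if (all(c("PBLUP", "ssGBLUP") %in% methods)) {
    mp <- lr_ratio(ebv$PBLUP$partial, ebv$ssGBLUP$partial)
    mw <- lr_ratio(ebv$PBLUP$whole, ebv$ssGBLUP$whole)
    df$cor_methods_partial <- mp$correlation
    df$gain_methods_partial <- mp$relative_gain
    df$cor_methods_whole <- mw$correlation
    df$gain_methods_whole <- mw$relative_gain
  }
  df$F_bar <- inb$F_bar
  df$f_bar <- inb$f_bar
  df$sigma2_u_inf <- eq$sigma2_u_inf
  df$lambda <- lambda
  df$denominator_sign <- sign
  df$sqrt_convention <- sqrt_convention
  viol <- df$acc_partial > df$acc_whole + 1e-12
  if (any(viol))
    warning("partial accuracy exceeds whole accuracy for ",
            paste(df$method[viol], collapse = ", "),
            " (sampling noise or model misfit)")
  class(df) <- c("lr_report", "data.frame")
  df
}

#' @export
print.lr_report <- function(x, ...) {
  cat("LR-method validation report\n")
  cat(sprintf("  focal cohort: F_bar = %.4f, f_bar = %.4f, sigma2_u_inf = %.4g\n",
              x$F_bar[1L], x$f_bar[1L], x$sigma2_u_inf[1L]))
  cat(sprintf("  accuracy denominator uses (1 + F_bar %s 2 f_bar); %s\n",
              if (x$denominator_sign[1L] == "minus") "-" else "+",
              if (x$sqrt_convention[1L]) "accuracies are sqrt(ratio)"
              else "values are the raw covariance ratio"))
  for (tr in unique(x$trait)) {
    sub <- x[x$trait == tr, ]
    cat(sprintf("  trait %s:\n", tr))
    for (i in seq_len(nrow(sub)))
      cat(sprintf(
        "    %-8s acc partial %.3f | whole %.3f   bias %+.3f   dispersion %.3f\n",
        sub$method[i], sub$acc_partial[i], sub$acc_whole[i], sub$bias[i],
        sub$dispersion[i]))
    if (!is.null(sub$gain_methods_partial))
      cat(sprintf(
        "    gain PBLUP -> ssGBLUP: %.0f%% (partial), %.0f%% (whole)\n",
        100 * sub$gain_methods_partial[1L], 100 * sub$gain_methods_whole[1L]))
  }
  invisible(x)
}
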