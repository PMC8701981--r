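#' SNP and animal quality control
#'
#' Filters a genotype matrix in four fixed stages, each applied to the matrix
#' surviving the previous one: (1) animal call rate, (2) SNP call rate,
#' (3) minor allele frequency, (4) departure from Hardy-Weinberg heterozygosity,
#' measured as `|Hobs_j - 2 p_j (1 - p_j)|` for SNP j at observed allele
#' frequency `p_j`. Defaults are call rate > 0.90, MAF >= 0.01 and
#' heterozygosity deviation <= 0.15.
#'
#' @param geno Integer matrix (animals x SNPs), `NA` = missing.
#' @param maf_min Minimum minor allele frequency retained.
#' @param het_dev_max Maximum absolute observed-minus-expected heterozygosity.
#' @param call_rate_min Minimum per-animal and per-SNP call rate.
#' @return A list of class `qc_result`: `geno` (filtered matrix) and `report`
#'   (class `qc_report`) with per-stage removal counts.
#' @export
qc_genotypes <- function(geno, maf_min = 0.01, het_dev_max = 0.15,
                         call_rate_min = 0.90) {
  stopifnot(is.matrix(geno), nrow(geno) > 0L, ncol(geno) > 0L)
  n_input <- ncol(geno)

  cr_animal <- rowMeans(!is.na(geno))
  drop_an <- cr_animal < call_rate_min
  geno <- geno[!drop_an, , drop = FALSE]

  cr_snp <- colMeans(!is.na(geno))
  drop_cr <- cr_snp < call_rate_min
  geno <- geno[, !drop_cr, drop = FALSE]

  p <- allele_freq(geno)
  maf <- pmin(p, 1 - p)
  drop_maf <- maf < maf_min
  geno <- geno[, !drop_maf, drop = FALSE]
  p <- p[!drop_maf]

  hobs <- colMeans(geno == 1L, na.rm = TRUE)
  drop_hwe <- abs(hobs - 2 * p * (1 - p)) > het_dev_max
  geno <- geno[, !drop_hwe, drop = FALSE]

  if (ncol(geno) == 0L)
    stop("quality control removed every SNP")
  report <- structure(list(
    n_input_snps = n_input,
    n_removed_callrate_animal = sum(drop_an),
    n_removed_callrate_snp = sum(drop_cr),
    n_removed_maf = sum(drop_maf),
    n_removed_hwe = sum(drop_hwe),
    n_retained_snps = ncol(geno)
  ), class = "qc_report")
  structure(list(geno = geno, report = report), class = "qc_result")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    paste0("Genotype quality control: %d SNPs in.\n",
           "  animals removed (call rate): %d\n",
           "  SNPs removed: call rate %d, minor allele frequency %d, ",
           "heterozygosity deviation %d\n",
           "  %d SNPs retained for subsequent analyses.\n"),
    x$n_input_snps, x$n_removed_callrate_animal, x$n_removed_callrate_snp,
    x$n_removed_maf, x$n_removed_hwe, x$n_retained_snps))
  invisible(x)
}

#' @export
print.qc_result <- function(x, ...) {
  print(x$report)
  cat("  animals retained:", nrow(x$geno), "\n")
  invisible(x)
}

#' Observed allele frequencies
#'
#' Frequency of the allele counted by the dosage coding, per SNP, from
#' non-missing genotypes.
#'
#' @inheritParams qc_genotypes
#' @return Numeric vector, one frequency per SNP.
#' @export
allele_freq <- function(geno) {
  colMeans(geno, na.rm = TRUE) / 2
}

#' Mean-imputation of missing genotypes
#'
#' Replaces each missing cell by the per-SNP mean dosage `2 p_j` rounded to
#' the nearest of 0/1/2 (round-half-up), leaving observed cells untouched.
#'
#' @inheritParams qc_genotypes
#' @return The completed integer matrix (no `NA`s).
#' @export
impute_genotypes <- function(geno) {
  if (!anyNA(geno)) return(geno)
  allna <- colSums(!is.na(geno)) == 0L
  if (any(allna))
    stop("SNP(s) with all genotypes missing: ",
         paste(head(colnames(geno)[allna], 5L), collapse = ", "))
  fill <- as.integer(pmin(2, floor(2 * allele_freq(geno) + 0.5)))
  idx <- which(is.na(geno), arr.ind = TRUE)
  geno[idx] <- fill[idx[, 2L]]
  geno
}

#' VanRaden genomic relationship matrix
#'
#' Method 1: with dosage matrix M and observed allele frequencies `p`,
#' `Z = M - 2p` (column-centred) and `G = Z Z' / (2 * sum(p_j (1 - p_j)))`.
#'
#' @param geno Complete integer matrix (animals x SNPs), no missing cells.
#' @return Dense symmetric matrix over the animals, attribute `kind = "G"`.
#' @export
grm_vanraden <- function(geno) {
  stopifnot(!anyNA(geno), nrow(geno) >= 2L, ncol(geno) >= 1L)
  p <- allele_freq(geno)
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("all SNPs are monomorphic: VanRaden denominator is zero")
  Z <- sweep(geno, 2L, 2 * p)
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(rownames(geno), rownames(geno))
  attr(G, "kind") <- "G"
  G
}

#' Blend G with the pedigree relationships of genotyped animals
#'
#' `G_blend = w_G * G + w_A * A22`, the standard device that makes the
#' genomic matrix invertible and anchors it to the pedigree base. The
#' published default is `0.95 G + 0.05 A22`.
#'
#' @param G Genomic relationship matrix ([grm_vanraden()]).
#' @param A22 Pedigree relationships of the same animals in the same order
#'   ([pedigree_A22()]).
#' @param w_G,w_A Blend weights, must sum to 1.
#' @return Dense symmetric matrix, attribute `kind = "G_blend"`.
#' @export
blend_grm <- function(G, A22, w_G = 0.95, w_A = 0.05) {
  if (abs(w_G + w_A - 1) > 1e-10) stop("blend weights must sum to 1")
  if (!identical(rownames(G), rownames(A22)))
    stop("G and A22 must be over identical animals in identical order")
  Gb <- w_G * G + w_A * A22
  attr(Gb, "kind") <- "G_blend"
  Gb
}

#' Rescale G to the scale of A22
#'
#' Optional pre-blending adjustment `G* = a + b G` with `a`, `b` solved so
#' that the mean diagonal and mean off-diagonal of `G*` equal those of A22.
#' Some single-step pipelines apply this "tuning" before blending; it is off
#' by default here.
#'
#' @inheritParams blend_grm
#' @return Adjusted G, same dimnames, attribute `kind = "G"`.
#' @export
tune_grm <- function(G, A22) {
  if (!identical(rownames(G), rownames(A22)))
    stop("G and A22 must be over identical animals in identical order")
  n <- nrow(G)
  dG <- mean(diag(G)); dA <- mean(diag(A22))
  oG <- (sum(G) - sum(diag(G))) / (n * (n - 1))
  oA <- (sum(A22) - sum(diag(A22))) / (n * (n - 1))
  b <- (dA - oA) / (dG - oG)
  a <- dA - b * dG
  Gt <- a + b * G
  attr(Gt, "kind") <- "G"
  Gt
}

#' Export a relationship matrix as dense text
#'
#' Whitespace-separated matrix with a header of animal ids.
#'
#' @param K Dense relationship matrix.
#' @param path Output path.
#' @export
write_relmat <- function(K, path) {
  write.table(as.matrix(K), path, sep = " ", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}
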