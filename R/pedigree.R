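#' Numerator relationship matrix A
#'
#' Builds the additive (numerator) relationship matrix by the tabular method:
#' processing animals in pedigree order, `A[i,j] = (A[j,s] + A[j,d]) / 2` for
#' `j < i` with parents `s`, `d` (missing parent contributes 0) and
#' `A[i,i] = 1 + F_i` with the inbreeding coefficient `F_i = A[s,d] / 2`.
#'
#' @param ped An ordered pedigree from [as_ped()] / [read_pedigree()].
#' @return A dense symmetric matrix with animal ids as dimnames and
#'   attribute `kind = "A"`.
#' @export
pedigree_A <- function(ped) {
  check_ped_order(ped)
  n <- ped$n
  A <- matrix(0, n, n)
  s <- ped$sire; d <- ped$dam
  for (i in seq_len(n)) {
    prev <- seq_len(i - 1L)
    if (i > 1L) {
      row <- numeric(i - 1L)
      if (s[i] > 0L) row <- row + A[prev, s[i]]
      if (d[i] > 0L) row <- row + A[prev, d[i]]
      row <- row / 2
      A[i, prev] <- row
      A[prev, i] <- row
    }
    A[i, i] <- if (s[i] > 0L && d[i] > 0L) 1 + 0.5 * A[s[i], d[i]] else 1
  }
  dimnames(A) <- list(ped$id, ped$id)
  attr(A, "kind") <- "A"
  A
}

#' Inbreeding coefficients from a pedigree
#'
#' Exact recursive (tabular) computation: `F_i = A[s,d] / 2`. Returns a named
#' numeric vector over all animals in pedigree order.
#'
#' @inheritParams pedigree_A
#' @return Named numeric vector of inbreeding coefficients.
#' @export
inbreeding <- function(ped) {
  A <- pedigree_A(ped)
  setNames(diag(A) - 1, ped$id)
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Direct construction of `A^-1` from per-animal contributions (Henderson's
#' rules) with Mendelian-sampling variances adjusted for parental inbreeding:
#' `d_i = 0.5 - 0.25 (F_s + F_d)` when both parents are known,
#' `0.75 - 0.25 F_p` with one known parent, and `1` for founders.
#'
#' @inheritParams pedigree_A
#' @param F Optional precomputed inbreeding coefficients ([inbreeding()]);
#'   computed if missing.
#' @return A sparse symmetric `dgCMatrix` with attribute `kind = "A_inv"`.
#' @export
pedigree_Ainv <- function(ped, F = NULL) {
  check_ped_order(ped)
  n <- ped$n
  if (is.null(F)) F <- inbreeding(ped)
  s <- ped$sire; d <- ped$dam
  Fs <- ifelse(s > 0L, F[pmax(s, 1L)], 0)
  Fd <- ifelse(d > 0L, F[pmax(d, 1L)], 0)
  both <- s > 0L & d > 0L
  one <- xor(s > 0L, d > 0L)
  dvar <- rep(1, n)
  dvar[both] <- 0.5 - 0.25 * (Fs[both] + Fd[both])
  dvar[one] <- 0.75 - 0.25 * (Fs + Fd)[one]  # the known parent's F
  alpha <- 1 / dvar

  i <- seq_len(n)
  ii <- list(i = i, j = i, x = alpha)                      # (i, i) += a
  tri <- list(ii)
  for (p in list(s, d)) {
    k <- p > 0L
    tri <- c(tri,
             list(list(i = i[k], j = p[k], x = -alpha[k] / 2),  # (i, p)
                  list(i = p[k], j = i[k], x = -alpha[k] / 2),  # (p, i)
                  list(i = p[k], j = p[k], x = alpha[k] / 4)))  # (p, p)
  }
  k <- both
  tri <- c(tri, list(list(i = s[k], j = d[k], x = alpha[k] / 4),
                     list(i = d[k], j = s[k], x = alpha[k] / 4)))
  Ai <- Matrix::sparseMatrix(
    i = unlist(lapply(tri, `[[`, "i")),
    j = unlist(lapply(tri, `[[`, "j")),
    x = unlist(lapply(tri, `[[`, "x")),
    dims = c(n, n), dimnames = list(ped$id, ped$id))
  Ai <- methods::as(Ai, "generalMatrix")
  attr(Ai, "kind") <- "A_inv"
  Ai
}

#' Pedigree relationships of the genotyped subset (A22)
#'
#' Principal submatrix of A over a stated animal subset, returned in the
#' order of `ids`. The full A is never materialised: the tabular recursion is
#' run on the ancestor closure of the subset only.
#'
#' @inheritParams pedigree_A
#' @param ids Character vector of (typically genotyped) animal identifiers,
#'   a subset of `ped$id`.
#' @return Dense symmetric matrix over `ids` with attribute `kind = "A22"`.
#' @export
pedigree_A22 <- function(ped, ids) {
  ids <- as.character(ids)
  pos <- match(ids, ped$id)
  if (anyNA(pos))
    stop("genotyped ids not in pedigree: ",
         paste(head(ids[is.na(pos)], 5L), collapse = ", "))
  # ancestor closure, walking backwards through the ordered pedigree
  keep <- logical(ped$n)
  keep[pos] <- TRUE
  for (i in rev(seq_len(ped$n))) {
    if (keep[i]) {
      if (ped$sire[i] > 0L) keep[ped$sire[i]] <- TRUE
      if (ped$dam[i] > 0L) keep[ped$dam[i]] <- TRUE
    }
  }
  sel <- which(keep)
  remap <- integer(ped$n)
  remap[sel] <- seq_along(sel)
  sub <- structure(list(
    id = ped$id[sel],
    sire = as.integer(remap[pmax(ped$sire[sel], 1L)] * (ped$sire[sel] > 0L)),
    dam = as.integer(remap[pmax(ped$dam[sel], 1L)] * (ped$dam[sel] > 0L)),
    birth_year = ped$birth_year[sel],
    n = length(sel)
  ), class = "ped")
  A <- pedigree_A(sub)
  A22 <- A[ids, ids, drop = FALSE]
  attr(A22, "kind") <- "A22"
  A22
}

#' Mean inbreeding and mean coancestry of a group
#'
#' Summaries entering the LR accuracy denominator: `F_bar` is the mean
#' inbreeding coefficient over the group (`A[i,i] - 1`), and `f_bar` the mean
#' coancestry `A[i,j] / 2` over unordered distinct pairs (self-pairs
#' excluded; twice `f_bar` is the mean additive relationship).
#'
#' @inheritParams pedigree_A
#' @param ids Identifiers of the group (e.g. the focal validation cohort).
#' @return List with elements `F_bar`, `f_bar`, `F` (per-animal, named).
#' @export
inbreeding_summary <- function(ped, ids) {
  ids <- as.character(ids)
  stopifnot(length(ids) > 0L)
  Ag <- pedigree_A22(ped, ids)   # exact A over the group, ancestors pruned
  Fi <- diag(Ag) - 1
  m <- length(ids)
  if (m == 1L) {
    warning("group of size 1: mean coancestry undefined, reported as 0")
    fbar <- 0
  } else {
    fbar <- (sum(Ag) - sum(diag(Ag))) / (m * (m - 1)) / 2
  }
  list(F_bar = mean(Fi), f_bar = fbar, F = setNames(Fi, ids))
}

#' Export a sparse A-inverse as 1-based triplets
#'
#' Writes `row col value` whitespace-separated text for the lower triangle
#' plus diagonal, rows/cols as 1-based pedigree codes.
#'
#' @param Ainv Sparse matrix from [pedigree_Ainv()].
#' @param path Output path.
#' @export
write_Ainv_triplets <- function(Ainv, path) {
  tr <- Matrix::summary(methods::as(Ainv, "TsparseMatrix"))
  tr <- tr[tr$i >= tr$j, , drop = FALSE]
  tr <- tr[order(tr$i, tr$j), , drop = FALSE]
  write.table(tr, path, sep = " ", quote = FALSE, row.names = FALSE,
              col.names = c("row", "col", "value"))
  invisible(path)
}

check_ped_order <- function(ped) {
  stopifnot(inherits(ped, "ped"))
  i <- seq_len(ped$n)
  if (any(ped$sire >= i) || any(ped$dam >= i))
    stop("pedigree is not topologically ordered (parent code >= animal code); ",
         "build it with as_ped() or read_pedigree()")
  invisible(ped)
}
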