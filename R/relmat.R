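#' Pedigree numerator relationship matrix (A)
#'
#' Tabular (recursive) method: individuals are processed in topological
#' order; `a_ii = 1 + a(sire, dam)/2` and `a_ij = (a(j, sire) + a(j, dam))/2`
#' for `j` preceding `i`. Unknown parents contribute 0 (unrelated,
#' non-inbred founders).
#'
#' @param ped a [pedigree()].
#' @return A `relmat` object: symmetric matrix with individual ids as
#'   dimnames and attribute `kind = "pedigree_A"`.
#' @export
pedigree_A <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  check_acyclic(ped)
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  s <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  d <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    js <- seq_len(i - 1L)
    cs <- if (s[i] > 0L) A[js, s[i]] else numeric(i - 1L)
    cd <- if (d[i] > 0L) A[js, d[i]] else numeric(i - 1L)
    row <- (cs + cd) / 2
    A[js, i] <- A[i, js] <- row
    asd <- if (s[i] > 0L && d[i] > 0L) A[s[i], d[i]] else 0
    A[i, i] <- 1 + asd / 2
  }
  new_relmat(A, "pedigree_A")
}

#' Genomic relationship matrix (G), VanRaden method 1
#'
#' `G = Z Z' / (2 * sum p_j (1 - p_j))` where `Z` is the dosage matrix with
#' each column centred by twice the allele frequency. Frequencies are
#' observed from the input unless supplied.
#'
#' @param g a [geno_matrix()] with no missing calls (impute first).
#' @param freqs optional vector of reference allele frequencies per SNP; by
#'   default observed frequencies are used.
#' @return A `relmat` object with attribute `kind = "genomic_G"`.
#' @export
genomic_G <- function(g, freqs = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  d <- g$dosage
  if (anyNA(d)) stop("genomic_G requires complete genotypes; run impute_missing first")
  p <- if (is.null(freqs)) colMeans(d) / 2 else freqs
  stopifnot(length(p) == ncol(d))
  if (any(p <= 0 | p >= 1)) {
    stop("monomorphic SNPs present; remove them with run_qc before building G")
  }
  Z <- sweep(d, 2, 2 * p)
  G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  new_relmat(G, "genomic_G")
}

new_relmat <- function(m, kind) {
  structure(m, kind = kind, class = c("relmat", "matrix"))
}

#' @export
print.relmat <- function(x, ...) {
  cat(if (identical(attr(x, "kind"), "pedigree_A"))
        "Pedigree relationship matrix A:" else
        "Genomic relationship matrix G:",
      nrow(x), "x", ncol(x), "\n")
  cat("mean diagonal:", round(mean(diag(x)), 4),
      " mean off-diagonal:",
      round((sum(x) - sum(diag(x))) / (length(x) - nrow(x)), 4), "\n")
  invisible(x)
}

#' Blend a relationship matrix towards the identity
#'
#' `K* = (1 - w) K + w I`; guards near-singular genomic matrices before
#' inversion in the mixed-model equations.
#'
#' @param K a `relmat` (or plain symmetric matrix).
#' @param weight identity weight `w` in `[0, 1)`, default 0.01.
#' @return The blended matrix, same class and kind.
#' @export
blend_relmat <- function(K, weight = 0.01) {
  stopifnot(weight >= 0, weight < 1)
  out <- (1 - weight) * unclass(K) + weight * diag(nrow(K))
  dimnames(out) <- dimnames(K)
  new_relmat(out, attr(K, "kind") %||% "unknown")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# inverse with automatic minimal blending for numerically singular K
relmat_inverse <- function(K, blend = 0) {
  Kb <- if (blend > 0) blend_relmat(K, blend) else K
  ch <- try(chol(unclass(Kb)), silent = TRUE)
  if (inherits(ch, "try-error")) {
    stop("relationship matrix is not positive definite; ",
         "blend it first (see blend_relmat)")
  }
  chol2inv(ch)
}
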