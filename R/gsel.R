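#' Breeding values by BLUP / GBLUP
#'
#' Solves Henderson's mixed-model equations for the animal model
#' `y = mu + Z a + e` with the overall mean as the sole fixed effect and
#' `a ~ N(0, K sigma2_a)`. Individuals present in `K` but without a
#' phenotype (masked or non-phenotyped ancestors) receive breeding values
#' through their relationships. With the pedigree matrix A the result is
#' classical BLUP; with the genomic matrix G it is GBLUP.
#'
#' @param y named phenotype vector; every name must be a row of `K`.
#'   Individuals in `K` absent from `y` (or with `NA`) carry no record.
#' @param K relationship matrix ([pedigree_A()] or [genomic_G()]).
#' @param varcomp a [reml_animal()] fit or a numeric `c(Va, Ve)`.
#' @param blend identity blending weight applied to `K` before inversion if
#'   it is not positive definite as given (default 0: error instead, with a
#'   suggestion to blend).
#' @return Object of class `blup_fit`: `mu`, `ebv` (named, all of `K`),
#'   `flavor`, `Va`, `Ve`, ids of the records used.
#' @export
blup <- function(y, K, varcomp, blend = 0) {
  if (inherits(varcomp, "reml_fit")) {
    Va <- varcomp$Va[1]; Ve <- varcomp$Ve[1]
  } else {
    Va <- varcomp[1]; Ve <- varcomp[2]
  }
  if (!is.finite(Va) || !is.finite(Ve) || Va <= 0 || Ve <= 0) {
    stop("need positive variance components Va and Ve")
  }
  if (is.null(names(y))) stop("y must be a named vector")
  all_ids <- rownames(K)
  rec_ids <- intersect(names(y)[!is.na(y)], all_ids)
  if (!length(rec_ids)) stop("no phenotyped individuals present in K")
  yv <- y[rec_ids]
  N <- length(all_ids)
  Kinv <- relmat_inverse(K, blend = blend)
  lambda <- Ve / Va

  # coefficient matrix: [ n   1'Z ; Z'1  Z'Z + lambda K^-1 ]
  zi <- match(rec_ids, all_ids)
  C <- matrix(0, N + 1, N + 1)
  C[1, 1] <- length(rec_ids)
  C[1, 1 + zi] <- C[1 + zi, 1] <- 1
  C[-1, -1] <- lambda * Kinv
  diag(C)[1 + zi] <- diag(C)[1 + zi] + 1
  rhs <- c(sum(yv), numeric(N))
  rhs[1 + zi] <- yv
  sol <- tryCatch(solve(C, rhs), error = function(e) {
    stop("mixed-model equations are singular; blend the relationship ",
         "matrix (blend_relmat or the blend argument)")
  })
  ebv <- sol[-1]
  names(ebv) <- all_ids
  structure(list(mu = sol[1], ebv = ebv,
                 flavor = if (identical(attr(K, "kind"), "genomic_G"))
                   "gblup" else "blup",
                 Va = Va, Ve = Ve, record_ids = rec_ids),
            class = "blup_fit")
}

#' @export
print.blup_fit <- function(x, ...) {
  cat(toupper(x$flavor), "fit:", length(x$ebv), "individuals,",
      length(x$record_ids), "records; mu =", round(x$mu, 4), "\n")
  cat("  EBV range:", paste(round(range(x$ebv), 4), collapse = " .. "), "\n")
  invisible(x)
}

#' @export
coef.blup_fit <- function(object, ...) object$ebv

#' @export
fitted.blup_fit <- function(object, ...) {
  object$mu + object$ebv[object$record_ids]
}

#' @export
residuals.blup_fit <- function(object, y, ...) {
  y[object$record_ids] - fitted(object)
}

#' Accuracy and inflation of predictions in a validation set
#'
#' `accuracy = cor(ebv, y) / sqrt(h2)` and `inflation` is the ordinary
#' least-squares slope (with intercept) of the phenotypes on the predicted
#' values; 1 means unbiased dispersion.
#'
#' @param ebv predicted breeding values of the validation individuals.
#' @param y their (unmasked) phenotypes, same order.
#' @param h2 heritability used in the accuracy denominator (pedigree-based
#'   by convention).
#' @return Named numeric vector `c(accuracy, inflation)`.
#' @export
prediction_metrics <- function(ebv, y, h2) {
  stopifnot(length(ebv) == length(y), h2 > 0)
  c(accuracy = stats::cor(ebv, y) / sqrt(h2),
    inflation = stats::cov(y, ebv) / stats::var(ebv))
}

#' Monte Carlo leave-one-group-out cross-validation of BLUP and GBLUP
#'
#' Per replicate a random validation group is drawn without replacement
#' from the phenotyped-and-genotyped individuals and its phenotypes are
#' masked; breeding values are estimated on the training records by
#' pedigree BLUP (A over the full pedigree) and/or genomic GBLUP (G over the
#' genotyped individuals); accuracy `cor(EBV_v, y_v)/sqrt(h2)` and the
#' inflation coefficient (slope of `y_v` on `EBV_v`) are recorded, then
#' averaged over replicates. Variance components are estimated once on the
#' full data per flavor and reused across replicates (set
#' `reestimate = TRUE` to refit per training set). The `h2` in the accuracy
#' denominator is the pedigree-based estimate.
#'
#' @param y named phenotype vector.
#' @param A pedigree relationship matrix (required for flavor `"blup"` or
#'   `"both"`); may cover non-phenotyped ancestors.
#' @param G genomic relationship matrix (required for `"gblup"`/`"both"`).
#' @param flavor `"both"`, `"blup"` or `"gblup"`.
#' @param n_replicates number of Monte Carlo replicates (default 40).
#' @param n_validation validation group size (default 314, as in a
#'   1,382-fish design with 1,068 training records).
#' @param h2 heritability for the accuracy denominator; defaults to the
#'   pedigree AI-REML estimate on the full data (or the genomic estimate if
#'   no A is supplied).
#' @param varcomp_A,varcomp_G optional precomputed [reml_animal()] fits.
#' @param blend_g identity blending weight for G inversion (default 0.01).
#' @param reestimate refit variance components on each training set.
#' @param seed integer seed; replicate r draws with seed `seed + r`, so any
#'   replicate is reproducible in isolation.
#' @return Object of class `cv_result`: `replicates` (long data frame:
#'   replicate, flavor, accuracy, inflation), `summary` (per-flavor mean and
#'   SD), `h2`, `n_validation`, `n_training`.
#' @export
cross_validate <- function(y, A = NULL, G = NULL,
                           flavor = c("both", "blup", "gblup"),
                           n_replicates = 40, n_validation = 314,
                           h2 = NULL, varcomp_A = NULL, varcomp_G = NULL,
                           blend_g = 0.01, reestimate = FALSE, seed = 1L) {
  flavor <- match.arg(flavor)
  do_blup <- flavor %in% c("both", "blup")
  do_gblup <- flavor %in% c("both", "gblup")
  if (do_blup && is.null(A)) stop("flavor '", flavor, "' requires A")
  if (do_gblup && is.null(G)) stop("flavor '", flavor, "' requires G")
  if (is.null(names(y))) stop("y must be a named vector")

  pool <- names(y)[!is.na(y)]
  if (do_blup) pool <- intersect(pool, rownames(A))
  if (do_gblup) pool <- intersect(pool, rownames(G))
  if (n_validation >= length(pool)) {
    stop("n_validation (", n_validation, ") must be smaller than the ",
         length(pool), " phenotyped-and-genotyped individuals")
  }

  if (do_blup && is.null(varcomp_A)) varcomp_A <- reml_animal(y, A)
  if (do_gblup && is.null(varcomp_G)) {
    varcomp_G <- reml_animal(y, blend_relmat(G, blend_g))
  }
  if (is.null(h2)) {
    h2 <- if (do_blup) varcomp_A$h2 else varcomp_G$h2
  }
  if (!is.finite(h2) || h2 <= 0) {
    stop("heritability estimate is not positive; accuracy is undefined")
  }

  Gb <- if (do_gblup) blend_relmat(G, blend_g) else NULL
  rows <- list()
  for (r in seq_len(n_replicates)) {
    set.seed(seed + r)
    val <- sample(pool, n_validation)
    ytrain <- y
    ytrain[val] <- NA
    if (do_blup) {
      vc <- if (reestimate) reml_animal(ytrain, A) else varcomp_A
      fit <- blup(ytrain, A, vc)
      m <- prediction_metrics(fit$ebv[val], y[val], h2)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, flavor = "blup", accuracy = m["accuracy"],
        inflation = m["inflation"], row.names = NULL)
    }
    if (do_gblup) {
      vc <- if (reestimate) reml_animal(ytrain, Gb) else varcomp_G
      fit <- blup(ytrain, Gb, vc)
      m <- prediction_metrics(fit$ebv[val], y[val], h2)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, flavor = "gblup", accuracy = m["accuracy"],
        inflation = m["inflation"], row.names = NULL)
    }
  }
  reps <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(reps, reps$flavor), function(d) {
    data.frame(flavor = d$flavor[1], n_replicates = nrow(d),
               mean_accuracy = mean(d$accuracy),
               sd_accuracy = stats::sd(d$accuracy),
               mean_inflation = mean(d$inflation),
               sd_inflation = stats::sd(d$inflation), row.names = NULL)
  }))
  structure(list(replicates = reps, summary = summ, h2 = h2,
                 n_validation = n_validation,
                 n_training = length(pool) - n_validation,
                 n_pool = length(pool), seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Monte Carlo cross-validation:",
      max(x$replicates$replicate), "replicates,",
      x$n_training, "training /", x$n_validation, "validation",
      sprintf("(h2 = %.3f)\n", x$h2))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-5s Acc %.2f (%.2f)  b %.2f (%.2f)\n",
                toupper(s$flavor[i]), s$mean_accuracy[i], s$sd_accuracy[i],
                s$mean_inflation[i], s$sd_inflation[i]))
  }
  invisible(x)
}

#' @export
summary.cv_result <- function(object, ...) object$summary
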