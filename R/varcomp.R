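#' Animal-model variance components by AI-REML
#'
#' Fits the animal model `y = mu + a + e` with `a ~ N(0, K sigma2_a)` for one
#' trait, or its two-trait extension with unstructured genetic and residual
#' covariance matrices, by restricted maximum likelihood. Updates use the
#' average-information (AI) algorithm with EM fallback steps and parameter
#' space projection; an update is accepted only if it does not decrease the
#' restricted log-likelihood. The only fixed effect is the overall mean (per
#' trait). Standard errors come from the inverse AI matrix at convergence;
#' heritability and correlation standard errors by the delta method.
#'
#' Internally the kinship matrix is eigendecomposed once; all subsequent
#' iterations cost O(n) (univariate) or O(n) 2x2 block operations
#' (bivariate), so fits are fast even with dense K.
#'
#' @param y named numeric vector of phenotypes; names must appear in
#'   `rownames(K)`. Individuals with missing phenotype are dropped.
#' @param K relationship matrix ([pedigree_A()] or [genomic_G()]) covering
#'   at least the phenotyped individuals.
#' @param y2 optional second trait (named vector) for a bivariate fit;
#'   restricted to individuals phenotyped for both traits.
#' @param transform `"none"` or `"log"` (natural log applied to the raw
#'   values before fitting; non-positive values are rejected).
#' @param init optional initial values: univariate `c(Va, Ve)`; bivariate a
#'   list with matrices `G0` and `R0`. Default `Va = Ve = var(y)/2` (and the
#'   analogous covariance split).
#' @param tol convergence threshold on the change in restricted
#'   log-likelihood (default 1e-8).
#' @param max_iter maximum number of iterations (default 200).
#' @return An object of class `reml_fit` with elements `G0`, `R0` (genetic
#'   and residual (co)variance matrices), `h2`, `se_h2`, and for bivariate
#'   fits `rg`, `se_rg`, `rp`, `se_rp`, `rp_pearson`; plus `converged`,
#'   `iterations`, `logLik_trace`, `boundary`, `vcov_theta`, `n`.
#' @examples
#' sim <- sim_study(n_offspring = 300, n_snps = 200, seed = 42)
#' A <- pedigree_A(sim$pedigree)
#' y <- sim$phenotypes[, 1]
#' fit <- reml_animal(y, A)
#' summary(fit)
#' @export
reml_animal <- function(y, K, y2 = NULL, transform = c("none", "log"),
                        init = NULL, tol = 1e-8, max_iter = 200) {
  transform <- match.arg(transform)
  stopifnot(is.matrix(K) || inherits(K, "relmat"))
  if (is.null(names(y))) stop("y must be a named vector (individual ids)")
  bivariate <- !is.null(y2)
  if (bivariate && is.null(names(y2))) stop("y2 must be a named vector")

  ids <- names(y)[!is.na(y)]
  if (bivariate) ids <- intersect(ids, names(y2)[!is.na(y2)])
  ids <- intersect(ids, rownames(K))
  n <- length(ids)
  if (n < 2) stop("need at least 2 phenotyped individuals present in K")
  Y <- cbind(y[ids])
  if (bivariate) Y <- cbind(Y, y2[ids])
  if (transform == "log") {
    if (any(Y <= 0)) stop("log transform requires strictly positive values")
    Y <- log(Y)
  }
  t <- ncol(Y)

  Ksub <- unclass(K)[ids, ids]
  eg <- eigen((Ksub + t(Ksub)) / 2, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  if (max(d) <= 0) stop("relationship matrix has no variation among the phenotyped individuals")
  U <- eg$vectors
  Yt <- crossprod(U, Y)                      # rotated records, n x t
  xt <- drop(crossprod(U, rep(1, n)))        # rotated mean design

  # initial values
  S <- stats::cov(Y)
  if (is.null(init)) {
    G0 <- S / 2
    R0 <- S / 2
  } else if (bivariate) {
    G0 <- init$G0; R0 <- init$R0
  } else {
    G0 <- matrix(init[1], 1, 1); R0 <- matrix(init[2], 1, 1)
  }
  # variance floor keeps V and the GLS system invertible even for
  # perfectly correlated (duplicated) traits
  floor_v <- 1e-6 * mean(diag(S))
  G0 <- psd_project(as.matrix(G0), floor_v)
  R0 <- psd_project(as.matrix(R0), floor_v)

  basis <- sym_basis(t)
  nk <- length(basis)

  eval_state <- function(G0, R0) reml_core(Yt, xt, d, G0, R0, basis)

  st <- eval_state(G0, R0)
  ll_trace <- st$logL
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    theta <- c(pack_sym(G0), pack_sym(R0))
    step <- tryCatch(solve(st$AI, st$score), error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(step)) {
      fac <- 1
      for (h in 1:9) {                      # AI step with halving
        th_new <- theta + fac * step
        G0n <- psd_project(unpack_sym(th_new[seq_len(nk / 2)], t), floor_v)
        R0n <- psd_project(unpack_sym(th_new[-seq_len(nk / 2)], t), floor_v)
        stn <- eval_state(G0n, R0n)
        if (is.finite(stn$logL) && stn$logL >= st$logL - 1e-10) {
          G0 <- G0n; R0 <- R0n; st <- stn; accepted <- TRUE
          break
        }
        fac <- fac / 2
      }
    }
    if (!accepted) {                        # exact EM fallback step
      em <- em_step(Yt, xt, d, G0, R0)
      G0n <- psd_project(em$G0, floor_v)
      R0n <- psd_project(em$R0, floor_v)
      stn <- eval_state(G0n, R0n)
      if (is.finite(stn$logL) && stn$logL >= st$logL - 1e-10) {
        G0 <- G0n; R0 <- R0n; st <- stn; accepted <- TRUE
      }
    }
    ll_trace <- c(ll_trace, st$logL)
    if (!accepted) { converged <- TRUE; break }
    nll <- length(ll_trace)
    if (abs(ll_trace[nll] - ll_trace[nll - 1]) < tol) {
      converged <- TRUE
      break
    }
  }

  vc <- tryCatch(solve(st$AI), error = function(e) {
    matrix(NA_real_, nk, nk)
  })
  boundary <- any(diag(G0) <= 2 * floor_v) || any(diag(R0) <= 2 * floor_v)

  out <- reml_summaries(G0, R0, vc, t)
  out$rp_pearson <- if (t == 2) stats::cor(Y[, 1], Y[, 2]) else NA_real_
  out$converged <- converged
  out$iterations <- iter
  out$logLik_trace <- ll_trace
  out$boundary <- boundary
  out$vcov_theta <- vc
  out$n <- n
  out$transform <- transform
  out$kind <- attr(K, "kind") %||% "unknown"
  out$ids <- ids
  class(out) <- "reml_fit"
  out
}

# symmetric basis matrices E_k in vech order (11, 21, 22 for t = 2)
sym_basis <- function(t) {
  ks <- list()
  for (j in seq_len(t)) for (i in j:t) {
    E <- matrix(0, t, t)
    E[i, j] <- E[j, i] <- 1
    ks[[length(ks) + 1L]] <- E
  }
  c(ks, ks)   # first half scales K (genetic), second half I (residual)
}

pack_sym <- function(M) M[lower.tri(M, diag = TRUE)]

unpack_sym <- function(v, t) {
  M <- matrix(0, t, t)
  M[lower.tri(M, diag = TRUE)] <- v
  M[upper.tri(M)] <- t(M)[upper.tri(M)]
  M
}

# symmetric inverse with an escalating ridge for near-singular systems
solve_ridged <- function(M) {
  r <- try(solve(M), silent = TRUE)
  eps <- 1e-10 * mean(diag(M))
  while (inherits(r, "try-error") && eps < mean(diag(M))) {
    r <- try(solve(M + eps * diag(nrow(M))), silent = TRUE)
    eps <- eps * 100
  }
  if (inherits(r, "try-error")) stop("GLS system is singular")
  r
}

psd_project <- function(M, floor_v) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  vals <- pmax(e$values, floor_v)
  e$vectors %*% diag(vals, nrow(M)) %*% t(e$vectors)
}

# restricted log-likelihood, score and AI matrix in the rotated basis.
# Yt: n x t rotated records, xt: rotated mean design, d: eigenvalues of K.
reml_core <- function(Yt, xt, d, G0, R0, basis) {
  n <- nrow(Yt); t <- ncol(Yt)
  nk <- length(basis)
  V <- array(0, c(n, t, t))
  for (i in seq_len(t)) for (j in seq_len(t)) {
    V[, i, j] <- d * G0[i, j] + R0[i, j]
  }
  Vi <- arr_inv(V)
  ldet <- arr_logdet(V)

  # GLS mean and residual rotation
  Sxx <- matrix(0, t, t); Sxy <- numeric(t)
  for (i in seq_len(t)) for (j in seq_len(t)) {
    Sxx[i, j] <- sum(xt^2 * Vi[, i, j])
    Sxy[i] <- Sxy[i] + sum(xt * Vi[, i, j] * Yt[, j])
  }
  Sxx_inv <- solve_ridged(Sxx)
  beta <- drop(Sxx_inv %*% Sxy)
  Rres <- Yt - outer(xt, beta)
  Py <- arr_mv(Vi, Rres)
  ypy <- sum(Rres * Py)
  logL <- -0.5 * (sum(ldet) + determinant(Sxx)$modulus[1] + ypy)

  score <- numeric(nk)
  U <- vector("list", nk)      # u_k = W_k P y  (n x t)
  for (k in seq_len(nk)) {
    E <- basis[[k]]
    f <- if (k <= nk / 2) d else rep(1, n)
    # tr(P W_k) = sum_i f_i tr(Vi_i E) - tr(Sxx^-1 M_k)
    trVE <- numeric(n)
    for (i in seq_len(t)) for (j in seq_len(t)) {
      if (E[i, j] != 0) trVE <- trVE + E[i, j] * Vi[, j, i]
    }
    T1 <- sum(f * trVE)
    # M_k = sum_i x_i^2 f_i Vi E Vi
    ViE <- arr_mm_const(Vi, E)           # n x t x t
    ViEVi <- arr_mm(ViE, Vi)
    Mk <- matrix(0, t, t)
    for (i in seq_len(t)) for (j in seq_len(t)) {
      Mk[i, j] <- sum(xt^2 * f * ViEVi[, i, j])
    }
    T2 <- sum(Sxx_inv * t(Mk))
    u <- (Py %*% E) * f                  # f_i E Py_i
    yWy <- sum(Py * u)
    score[k] <- -0.5 * (T1 - T2 - yWy)
    U[[k]] <- u
  }

  # AI_kl = 0.5 u_k' P u_l
  PU <- lapply(U, function(u) apply_P(u, Vi, xt, Sxx_inv))
  AI <- matrix(0, nk, nk)
  for (k in seq_len(nk)) for (l in k:nk) {
    AI[k, l] <- AI[l, k] <- 0.5 * sum(U[[k]] * PU[[l]])
  }
  list(logL = logL, score = score, AI = AI, Vi = Vi, Rres = Rres,
       Py = Py, beta = beta)
}

# P u = V^-1 u - V^-1 X Sxx^-1 X' V^-1 u  for block-diagonal V
apply_P <- function(u, Vi, xt, Sxx_inv) {
  Viu <- arr_mv(Vi, u)
  cvec <- drop(crossprod(Viu, xt))       # X' V^-1 u
  corr <- drop(Sxx_inv %*% cvec)
  Viu - arr_mv(Vi, outer(xt, corr))
}

# exact EM-REML update conditional on the GLS mean
em_step <- function(Yt, xt, d, G0, R0) {
  n <- nrow(Yt); t <- ncol(Yt)
  V <- array(0, c(n, t, t))
  for (i in seq_len(t)) for (j in seq_len(t)) {
    V[, i, j] <- d * G0[i, j] + R0[i, j]
  }
  Vi <- arr_inv(V)
  Sxx <- matrix(0, t, t); Sxy <- numeric(t)
  for (i in seq_len(t)) for (j in seq_len(t)) {
    Sxx[i, j] <- sum(xt^2 * Vi[, i, j])
    Sxy[i] <- Sxy[i] + sum(xt * Vi[, i, j] * Yt[, j])
  }
  beta <- drop(solve_ridged(Sxx) %*% Sxy)
  Rres <- Yt - outer(xt, beta)
  Vir <- arr_mv(Vi, Rres)

  keep <- d > 1e-10
  q <- sum(keep)
  Gn <- matrix(0, t, t); Rn <- matrix(0, t, t)
  for (i in seq_len(n)) {
    vi <- matrix(Vi[i, , ], t, t)
    ri <- Vir[i, ]
    ahat <- d[i] * (G0 %*% ri)
    ehat <- R0 %*% ri
    if (keep[i]) {
      Gn <- Gn + (tcrossprod(ahat) / d[i]) + G0 - d[i] * G0 %*% vi %*% G0
    }
    Rn <- Rn + tcrossprod(ehat) + R0 - R0 %*% vi %*% R0
  }
  list(G0 = if (q > 0) Gn / q else G0, R0 = Rn / n)
}

# ---- small array helpers (n stacks of t x t blocks, t <= 2) ----

arr_inv <- function(V) {
  t <- dim(V)[2]
  out <- array(0, dim(V))
  if (t == 1) {
    out[, 1, 1] <- 1 / V[, 1, 1]
  } else {
    det <- V[, 1, 1] * V[, 2, 2] - V[, 1, 2]^2
    out[, 1, 1] <- V[, 2, 2] / det
    out[, 2, 2] <- V[, 1, 1] / det
    out[, 1, 2] <- out[, 2, 1] <- -V[, 1, 2] / det
  }
  out
}

arr_logdet <- function(V) {
  t <- dim(V)[2]
  if (t == 1) log(V[, 1, 1]) else
    log(V[, 1, 1] * V[, 2, 2] - V[, 1, 2]^2)
}

arr_mv <- function(V, x) {
  t <- dim(V)[2]
  out <- matrix(0, dim(V)[1], t)
  for (i in seq_len(t)) for (j in seq_len(t)) {
    out[, i] <- out[, i] + V[, i, j] * x[, j]
  }
  out
}

arr_mm_const <- function(V, E) {
  t <- dim(V)[2]
  out <- array(0, dim(V))
  for (i in seq_len(t)) for (j in seq_len(t)) for (k in seq_len(t)) {
    if (E[k, j] != 0) out[, i, j] <- out[, i, j] + V[, i, k] * E[k, j]
  }
  out
}

arr_mm <- function(A, B) {
  t <- dim(A)[2]
  out <- array(0, dim(A))
  for (i in seq_len(t)) for (j in seq_len(t)) for (k in seq_len(t)) {
    out[, i, j] <- out[, i, j] + A[, i, k] * B[, k, j]
  }
  out
}

# ---- summaries, SEs by the delta method on the inverse AI matrix ----

reml_summaries <- function(G0, R0, vc, t) {
  grad_se <- function(grad) {
    if (anyNA(vc)) return(NA_real_)
    v <- drop(t(grad) %*% vc %*% grad)
    if (is.finite(v) && v >= 0) sqrt(v) else NA_real_
  }
  if (t == 1) {
    Va <- G0[1, 1]; Ve <- R0[1, 1]; Vp <- Va + Ve
    h2 <- Va / Vp
    g <- c(Ve, -Va) / Vp^2             # d h2 / d (Va, Ve)
    se_h2 <- grad_se(g)
    se_Va <- if (anyNA(vc)) NA_real_ else sqrt(max(vc[1, 1], 0))
    se_Ve <- if (anyNA(vc)) NA_real_ else sqrt(max(vc[2, 2], 0))
    return(list(G0 = G0, R0 = R0, Va = Va, Ve = Ve, se_Va = se_Va,
                se_Ve = se_Ve, h2 = h2, se_h2 = se_h2,
                rg = NA_real_, se_rg = NA_real_,
                rp = NA_real_, se_rp = NA_real_))
  }
  # theta order: g11, g21, g22, r11, r21, r22
  g11 <- G0[1, 1]; g12 <- G0[1, 2]; g22 <- G0[2, 2]
  r11 <- R0[1, 1]; r12 <- R0[1, 2]; r22 <- R0[2, 2]
  h2 <- c(g11 / (g11 + r11), g22 / (g22 + r22))
  se_h2 <- c(
    grad_se(c(r11 / (g11 + r11)^2, 0, 0, -g11 / (g11 + r11)^2, 0, 0)),
    grad_se(c(0, 0, r22 / (g22 + r22)^2, 0, 0, -g22 / (g22 + r22)^2)))
  rg_raw <- g12 / sqrt(g11 * g22)
  rg <- max(-1, min(1, rg_raw))
  dr <- c(-g12 / (2 * g11^1.5 * sqrt(g22)), 1 / sqrt(g11 * g22),
          -g12 / (2 * g22^1.5 * sqrt(g11)), 0, 0, 0)
  se_rg <- grad_se(dr)
  p11 <- g11 + r11; p12 <- g12 + r12; p22 <- g22 + r22
  rp_raw <- p12 / sqrt(p11 * p22)
  rp <- max(-1, min(1, rp_raw))
  dp <- c(-p12 / (2 * p11^1.5 * sqrt(p22)), 1 / sqrt(p11 * p22),
          -p12 / (2 * p22^1.5 * sqrt(p11)))
  se_rp <- grad_se(c(dp, dp))
  list(G0 = G0, R0 = R0, Va = c(g11, g22), Ve = c(r11, r22),
       se_Va = NA_real_, se_Ve = NA_real_, h2 = h2, se_h2 = se_h2,
       rg = rg, se_rg = se_rg, rp = rp, se_rp = se_rp,
       rg_clamped = rg != rg_raw, rp_clamped = rp != rp_raw)
}

#' @export
print.reml_fit <- function(x, ...) {
  t <- nrow(x$G0)
  cat("AI-REML animal model fit (", if (t == 1) "univariate" else "bivariate",
      ", K = ", x$kind, ", n = ", x$n, ")\n", sep = "")
  if (t == 1) {
    cat(sprintf("  Va = %.4g  Ve = %.4g  h2 = %.3f (SE %.3f)\n",
                x$Va, x$Ve, x$h2, x$se_h2))
  } else {
    cat(sprintf("  h2 = %.3f (SE %.3f), %.3f (SE %.3f)\n",
                x$h2[1], x$se_h2[1], x$h2[2], x$se_h2[2]))
    cat(sprintf("  rg = %.3f (SE %.3f)  rp = %.3f (SE %.3f)\n",
                x$rg, x$se_rg, x$rp, x$se_rp))
  }
  cat("  converged:", x$converged, "in", x$iterations, "iterations")
  if (x$boundary) cat("  [boundary estimate]")
  cat("\n")
  invisible(x)
}

#' @export
summary.reml_fit <- function(object, ...) {
  print(object)
  cat("  restricted logLik:", utils::tail(object$logLik_trace, 1), "\n")
  if (nrow(object$G0) == 2) {
    cat("  Pearson phenotypic correlation:",
        round(object$rp_pearson, 3), "\n")
  }
  invisible(object)
}

#' @export
coef.reml_fit <- function(object, ...) {
  if (nrow(object$G0) == 1) {
    c(Va = object$Va, Ve = object$Ve, h2 = object$h2)
  } else {
    c(Va1 = object$G0[1, 1], Cov_a = object$G0[1, 2],
      Va2 = object$G0[2, 2], Ve1 = object$R0[1, 1],
      Cov_e = object$R0[1, 2], Ve2 = object$R0[2, 2],
      h2_1 = object$h2[1], h2_2 = object$h2[2],
      rg = object$rg, rp = object$rp)
  }
}

#' @export
vcov.reml_fit <- function(object, ...) object$vcov_theta

#' @export
logLik.reml_fit <- function(object, ...) {
  structure(utils::tail(object$logLik_trace, 1),
            df = length(pack_sym(object$G0)) * 2, class = "logLik")
}
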