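#' BayesCpi genome-wide association
#'
#' Gibbs sampler for the mixture model in which each SNP has a non-zero
#' effect (drawn from a common normal with variance `sigma2_a`) with
#' probability `pi`, itself given a Beta(`alpha`, `beta`) prior. Defaults
#' follow a 57K-array trout analysis: 200,000 cycles, 5,000 burn-in,
#' samples saved every 20 cycles, and `alpha = 300`, `beta = `number of
#' SNPs, so the prior mean inclusion probability is about 1% (roughly 300
#' SNPs in the model per cycle on a 29,652-SNP panel).
#'
#' Per-SNP output: posterior inclusion probability `pip` (mean of the
#' indicator over saved samples), posterior mean effect, Bayes factor
#' against the prior odds at `pi = alpha/(alpha+beta)`, `2 ln BF`, and the
#' posterior-mean variance contribution `2 p (1-p) E[(delta a)^2]` used for
#' QTL variance decomposition.
#'
#' @param g a [geno_matrix()] with no missing calls.
#' @param y named numeric phenotype vector covering the genotyped ids.
#' @param n_cycles,burn_in,thin MCMC schedule (defaults 200000 / 5000 / 20).
#' @param alpha,beta Beta prior parameters for the inclusion probability;
#'   `beta` defaults to the number of SNPs.
#' @param nu_a,nu_e inverse chi-square prior degrees of freedom for the
#'   effect and residual variances (default 4 each). The effect-variance
#'   prior scale is set so the prior genetic variance at the prior mean
#'   model size is half the phenotypic variance.
#' @param fix_pi if `TRUE`, `pi` is held at its prior mean rather than
#'   sampled (with `alpha/(alpha+beta) = 1` this reduces the model to
#'   SNP-BLUP/ridge).
#' @param seed integer seed for the chain.
#' @return An object of class `bayescpi`: `snp` data frame (`snp`, `chr`,
#'   `pos`, `maf`, `pip`, `effect`, `bf`, `two_ln_bf`, `var_contrib`),
#'   `samples` data frame of saved variance/pi/model-size draws, `gebv`
#'   (genomic values from posterior-mean effects), `pi_prior_mean`, `mu`,
#'   `total_gvar` and the call configuration.
#' @export
bayescpi <- function(g, y, n_cycles = 200000, burn_in = 5000, thin = 20,
                     alpha = 300, beta = NULL, nu_a = 4, nu_e = 4,
                     fix_pi = FALSE, seed = 1L) {
  stopifnot(inherits(g, "geno_matrix"))
  if (anyNA(g$dosage)) stop("genotypes contain missing calls; impute first")
  if (is.null(names(y))) stop("y must be a named vector")
  ids <- intersect(rownames(g$dosage), names(y)[!is.na(y)])
  n <- length(ids)
  m <- ncol(g$dosage)
  if (m < 2) stop("need at least 2 SNPs")
  yv <- y[ids]
  if (stats::var(yv) <= 0) stop("phenotype has zero variance")
  if (is.null(beta)) beta <- m
  stopifnot(alpha > 0, beta > 0, burn_in < n_cycles, thin >= 1)

  dos <- g$dosage[ids, , drop = FALSE]
  p <- colMeans(dos) / 2
  Z <- sweep(dos, 2, 2 * p)
  pi_mean <- alpha / (alpha + beta)

  # effect-variance prior scale: prior genetic variance at the prior mean
  # model size equals half the phenotypic variance
  sum_2pq <- sum(2 * p * (1 - p))
  vy <- stats::var(yv)
  s2_a_prior <- 0.5 * vy / max(pi_mean * sum_2pq, 1e-12) *
    (nu_a - 2) / nu_a
  s2_e_prior <- 0.5 * vy * (nu_e - 2) / nu_e

  set.seed(seed)
  res <- .bayescpi_mcmc(Z, yv, as.integer(n_cycles), as.integer(burn_in),
                        as.integer(thin), alpha, beta, nu_a, s2_a_prior,
                        nu_e, s2_e_prior, fix_pi, pi_mean)

  n_saved <- res$n_saved
  pip <- res$pip
  # cap so a SNP included in every saved sample keeps a finite Bayes factor
  pip_cap <- pmin(pip, (n_saved - 0.5) / n_saved)
  bf <- bayes_factor(pip_cap, pi_mean)
  var_contrib <- 2 * p * (1 - p) * res$mean_effect2
  snp <- data.frame(snp = g$map$snp, chr = g$map$chr, pos = g$map$pos,
                    maf = pmin(p, 1 - p), pip = pip,
                    effect = res$mean_effect,
                    bf = bf$bf, two_ln_bf = bf$two_ln_bf,
                    var_contrib = var_contrib,
                    stringsAsFactors = FALSE)
  gebv <- drop(Z %*% res$mean_effect)
  names(gebv) <- ids
  structure(list(
    snp = snp,
    samples = data.frame(s2a = res$s2a, s2e = res$s2e, pi = res$pi,
                         model_size = res$model_size),
    gebv = gebv, mu = res$mu, pi_prior_mean = pi_mean,
    total_gvar = sum(var_contrib),
    config = list(n_cycles = n_cycles, burn_in = burn_in, thin = thin,
                  alpha = alpha, beta = beta, nu_a = nu_a, nu_e = nu_e,
                  fix_pi = fix_pi, seed = seed, n_saved = n_saved,
                  n = n, m = m)),
    class = "bayescpi")
}

#' Run several BayesCpi chains
#'
#' Identical input, different seeds; use [check_convergence()] on the
#' result.
#'
#' @inheritParams bayescpi
#' @param n_chains number of chains (default 3).
#' @param ... passed to [bayescpi()].
#' @return List of `bayescpi` fits.
#' @export
bayescpi_chains <- function(g, y, n_chains = 3, seed = 1L, ...) {
  lapply(seq_len(n_chains), function(k) {
    bayescpi(g, y, seed = seed + (k - 1L) * 1000L, ...)
  })
}

#' @export
print.bayescpi <- function(x, ...) {
  cfg <- x$config
  cat("BayesCpi fit:", cfg$n, "individuals x", cfg$m, "SNPs;",
      cfg$n_cycles, "cycles (burn-in", cfg$burn_in, ", thin", cfg$thin,
      ",", cfg$n_saved, "saved)\n")
  cat(sprintf("  prior inclusion Beta(%g, %g), mean %.4f\n",
              cfg$alpha, cfg$beta, x$pi_prior_mean))
  cat(sprintf("  posterior: mean model size %.1f, s2a %.4g, s2e %.4g\n",
              mean(x$samples$model_size), mean(x$samples$s2a),
              mean(x$samples$s2e)))
  cat("  top SNP:", x$snp$snp[which.max(x$snp$two_ln_bf)],
      sprintf("(2lnBF = %.2f)", max(x$snp$two_ln_bf)), "\n")
  invisible(x)
}

#' @export
summary.bayescpi <- function(object, ...) {
  print(object)
  hits <- object$snp[object$snp$two_ln_bf >= 5, , drop = FALSE]
  cat(" ", nrow(hits), "SNP(s) with 2lnBF >= 5\n")
  invisible(object)
}

#' @export
coef.bayescpi <- function(object, ...) {
  stats::setNames(object$snp$effect, object$snp$snp)
}

#' Manhattan / trace plots for a BayesCpi fit
#'
#' @param x a `bayescpi` fit.
#' @param type `"manhattan"` (2 ln BF by position) or `"trace"` (posterior
#'   draws of the genetic and residual variances).
#' @param ... further graphical parameters.
#' @export
plot.bayescpi <- function(x, type = c("manhattan", "trace"), ...) {
  type <- match.arg(type)
  if (type == "manhattan") {
    s <- x$snp
    chrs <- unique(s$chr)
    offset <- stats::setNames(numeric(length(chrs)), chrs)
    run <- 0
    for (cc in chrs) {
      offset[cc] <- run
      run <- run + max(s$pos[s$chr == cc]) + 1e6
    }
    xs <- s$pos + offset[s$chr]
    cols <- (match(s$chr, chrs) %% 2) + 1
    graphics::plot(xs, s$two_ln_bf, pch = 20, cex = 0.5,
                   col = c("grey40", "steelblue")[cols],
                   xlab = "genome position", ylab = "2 ln BF", ...)
    graphics::abline(h = c(6, 5), lty = 2, col = c("red", "blue"))
  } else {
    old <- graphics::par(mfrow = c(2, 1))
    on.exit(graphics::par(old))
    graphics::plot(x$samples$s2a, type = "l", ylab = "sigma2_a",
                   xlab = "saved sample", ...)
    graphics::plot(x$samples$s2e, type = "l", ylab = "sigma2_e",
                   xlab = "saved sample", ...)
  }
  invisible(x)
}

#' Bayes factor from posterior and prior inclusion probabilities
#'
#' `BF = (P/(1-P)) / (pi/(1-pi))`; `2 ln BF` is the QTL evidence score.
#' `P = 1` maps to +Inf and is reported capped at `cap`; `P = 0` gives
#' `BF = 0` and `2 ln BF = -Inf`.
#'
#' @param p posterior inclusion probability in `[0, 1]`.
#' @param pi prior inclusion probability in (0, 1).
#' @param cap upper bound for the reported Bayes factor (default `exp(50)`).
#' @return List with `bf` and `two_ln_bf`.
#' @export
bayes_factor <- function(p, pi, cap = exp(50)) {
  if (any(pi <= 0 | pi >= 1)) stop("pi must lie strictly in (0, 1)")
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  prior_odds <- pi / (1 - pi)
  post_odds <- ifelse(p >= 1, Inf, p / (1 - p))
  bf <- pmin(post_odds / prior_odds, cap)
  list(bf = bf, two_ln_bf = 2 * log(bf))
}

#' Call QTL regions from per-SNP evidence scores
#'
#' Peaks are SNPs with `2 ln BF >= putative_threshold` processed in
#' decreasing score order (ties broken by lower bp). Around each peak a
#' credibility interval is grown outward with a sliding window: any SNP with
#' `2 ln BF >= support_threshold` lying within `window_bp` of the interval's
#' current edge is admitted, until a window adds none. A peak with
#' `2 ln BF >= evidence_threshold` is called `evidence`; peaks between the
#' putative and evidence thresholds are `putative` and retained only if the
#' region explains at least `min_pct_variance` percent of the additive
#' genetic variance or overlaps a region called for another trait.
#' Overlapping same-trait regions are merged and re-peaked.
#'
#' @param fit a [bayescpi()] fit (or a data frame with columns `snp`,
#'   `chr`, `pos`, `two_ln_bf` and optionally `var_contrib`).
#' @param trait trait label recorded on the regions.
#' @param evidence_threshold,putative_threshold,support_threshold score
#'   thresholds (defaults 6, 5, 3).
#' @param window_bp sliding-window width on either side (default 1 Mb).
#' @param min_pct_variance retention floor for putative regions (default
#'   0.5 percent).
#' @param other_trait_regions optional `qtl_regions` result for other
#'   traits; putative regions overlapping one of them are retained.
#' @return Data frame of class `qtl_regions`: `trait`, `chr`, `peak_snp`,
#'   `peak_pos`, `peak_mb`, `two_ln_bf`, `maf`, `start`, `end`, `start_mb`,
#'   `end_mb`, `status`, `pct_variance`, `n_snps`.
#' @export
call_qtls <- function(fit, trait = "trait", evidence_threshold = 6,
                      putative_threshold = 5, support_threshold = 3,
                      window_bp = 1e6, min_pct_variance = 0.5,
                      other_trait_regions = NULL) {
  s <- if (inherits(fit, "bayescpi")) fit$snp else fit
  stopifnot(all(c("snp", "chr", "pos", "two_ln_bf") %in% names(s)))
  total_gvar <- if (inherits(fit, "bayescpi")) fit$total_gvar else
    sum(s$var_contrib %||% 0)

  regions <- list()
  for (cc in unique(s$chr)) {
    sc <- s[s$chr == cc, , drop = FALSE]
    sc <- sc[order(sc$pos), , drop = FALSE]
    used <- rep(FALSE, nrow(sc))
    cand <- order(-sc$two_ln_bf, sc$pos)
    for (k in cand) {
      if (used[k] || sc$two_ln_bf[k] < putative_threshold) next
      lo <- hi <- sc$pos[k]
      support <- sc$two_ln_bf >= support_threshold
      repeat {
        inwin <- support & sc$pos >= lo - window_bp & sc$pos <= hi + window_bp
        nlo <- min(sc$pos[inwin]); nhi <- max(sc$pos[inwin])
        if (nlo == lo && nhi == hi) break
        lo <- nlo; hi <- nhi
      }
      inreg <- sc$pos >= lo & sc$pos <= hi
      used <- used | inreg
      regions[[length(regions) + 1L]] <- data.frame(
        trait = trait, chr = cc, peak_snp = sc$snp[k],
        peak_pos = sc$pos[k], two_ln_bf = sc$two_ln_bf[k],
        maf = if ("maf" %in% names(sc)) sc$maf[k] else NA_real_,
        start = lo, end = hi,
        pct_variance = if (total_gvar > 0 && "var_contrib" %in% names(sc))
          100 * sum(sc$var_contrib[inreg]) / total_gvar else NA_real_,
        n_snps = sum(inreg), stringsAsFactors = FALSE)
    }
  }
  if (!length(regions)) return(empty_qtl_regions())
  out <- do.call(rbind, regions)

  # merge overlapping same-trait regions, keep the stronger peak
  out <- out[order(out$chr, out$start), , drop = FALSE]
  merged <- list()
  for (i in seq_len(nrow(out))) {
    r <- out[i, ]
    if (length(merged)) {
      last <- merged[[length(merged)]]
      if (last$chr == r$chr && r$start <= last$end) {
        last$end <- max(last$end, r$end)
        last$start <- min(last$start, r$start)
        last$n_snps <- NA_integer_  # recomputed below
        if (r$two_ln_bf > last$two_ln_bf ||
            (r$two_ln_bf == last$two_ln_bf && r$peak_pos < last$peak_pos)) {
          last[c("peak_snp", "peak_pos", "two_ln_bf", "maf")] <-
            r[c("peak_snp", "peak_pos", "two_ln_bf", "maf")]
        }
        merged[[length(merged)]] <- last
        next
      }
    }
    merged[[length(merged) + 1L]] <- r
  }
  out <- do.call(rbind, merged)
  # recompute per-region quantities after merging
  for (i in seq_len(nrow(out))) {
    inreg <- s$chr == out$chr[i] & s$pos >= out$start[i] &
      s$pos <= out$end[i]
    out$n_snps[i] <- sum(inreg)
    if (total_gvar > 0 && "var_contrib" %in% names(s)) {
      out$pct_variance[i] <- 100 * sum(s$var_contrib[inreg]) / total_gvar
    }
  }
  out$status <- ifelse(out$two_ln_bf >= evidence_threshold,
                       "evidence", "putative")

  keep <- out$status == "evidence"
  if (any(!keep)) {
    put <- which(!keep)
    pct_ok <- !is.na(out$pct_variance[put]) &
      out$pct_variance[put] >= min_pct_variance
    multi <- rep(FALSE, length(put))
    if (!is.null(other_trait_regions) && nrow(other_trait_regions)) {
      for (j in seq_along(put)) {
        i <- put[j]
        multi[j] <- any(other_trait_regions$chr == out$chr[i] &
                          other_trait_regions$start <= out$end[i] &
                          other_trait_regions$end >= out$start[i])
      }
    }
    keep[put] <- pct_ok | multi
  }
  out <- out[keep, , drop = FALSE]
  if (!nrow(out)) return(empty_qtl_regions())
  out$peak_mb <- round(out$peak_pos / 1e6, 2)
  out$start_mb <- round(out$start / 1e6, 2)
  out$end_mb <- round(out$end / 1e6, 2)
  rownames(out) <- NULL
  class(out) <- c("qtl_regions", "data.frame")
  out
}

empty_qtl_regions <- function() {
  out <- data.frame(trait = character(), chr = character(),
                    peak_snp = character(), peak_pos = numeric(),
                    two_ln_bf = numeric(), maf = numeric(),
                    start = numeric(), end = numeric(),
                    pct_variance = numeric(), n_snps = integer(),
                    status = character(), peak_mb = numeric(),
                    start_mb = numeric(), end_mb = numeric(),
                    stringsAsFactors = FALSE)
  class(out) <- c("qtl_regions", "data.frame")
  out
}

#' Percent of additive genetic variance explained by a QTL region
#'
#' Sums the per-SNP posterior-mean variance contributions
#' `2 p (1-p) E[(delta a)^2]` over the SNPs inside the region and expresses
#' the sum as a percentage of the total marker-derived additive genetic
#' variance.
#'
#' @param fit a [bayescpi()] fit.
#' @param chr chromosome of the region.
#' @param start,end region bounds in bp (inclusive).
#' @return Percentage (0-100).
#' @export
qtl_variance <- function(fit, chr, start, end) {
  stopifnot(inherits(fit, "bayescpi"))
  if (fit$total_gvar <= 0) {
    stop("total marker-derived genetic variance is zero")
  }
  s <- fit$snp
  inreg <- s$chr == chr & s$pos >= start & s$pos <= end
  100 * sum(s$var_contrib[inreg]) / fit$total_gvar
}

#' MCMC convergence check across chains
#'
#' Pairwise correlations between the genomic estimated breeding values from
#' chains run on the same data with different seeds; passes when every pair
#' exceeds `r_threshold` (0.99 by default).
#'
#' @param chains list of at least two [bayescpi()] fits on identical input.
#' @param r_threshold pass threshold for every pairwise GEBV correlation.
#' @return List of class `convergence_report` with the correlation matrix
#'   and a logical `pass`.
#' @export
check_convergence <- function(chains, r_threshold = 0.99) {
  if (!is.list(chains) || length(chains) < 2) {
    stop("need at least 2 chains to check convergence")
  }
  stopifnot(all(vapply(chains, inherits, logical(1), "bayescpi")))
  gebvs <- vapply(chains, function(f) f$gebv, numeric(length(chains[[1]]$gebv)))
  cm <- stats::cor(gebvs)
  pairs <- cm[upper.tri(cm)]
  structure(list(correlations = cm, min_correlation = min(pairs),
                 pass = all(pairs > r_threshold),
                 r_threshold = r_threshold),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("Chain convergence:", if (x$pass) "PASS" else "FAIL",
      sprintf("(min pairwise GEBV correlation %.4f, threshold %.2f)\n",
              x$min_correlation, x$r_threshold))
  invisible(x)
}
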