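test_that("bayes_factor implements the posterior/prior odds ratio", {
  # prior = posterior gives BF 1
  expect_equal(bayes_factor(0.01, 0.01)$bf, 1)
  expect_equal(bayes_factor(0.01, 0.01)$two_ln_bf, 0)
  # boundary: zero posterior support
  b0 <- bayes_factor(0, 0.01)
  expect_equal(b0$bf, 0)
  expect_equal(b0$two_ln_bf, -Inf)
  # full posterior support is capped, not infinite
  b1 <- bayes_factor(1, 0.01, cap = exp(50))
  expect_equal(b1$two_ln_bf, 100)
  # algebraic inversion: at pi = 0.01, 2lnBF = 6 corresponds to
  # P = e^3 (1/99) / (1 + e^3 (1/99)); verified by numeric inversion
  p_star <- uniroot(function(p) bayes_factor(p, 0.01)$two_ln_bf - 6,
                    c(1e-6, 1 - 1e-6), tol = 1e-12)$root
  expect_equal(p_star, exp(3) / 99 / (1 + exp(3) / 99), tolerance = 1e-8)
  expect_equal(p_star, 0.1687, tolerance = 1e-3)
  expect_error(bayes_factor(0.5, 1), "pi")
})

test_that("the sampler is deterministic and honours the BF identity", {
  sim <- sim_study(n_offspring = 150, n_snps = 200, h2 = 0.3,
                   qtl_frac = 0.3, seed = 41)
  y <- offspring_y(sim)
  f1 <- bayescpi(sim$genotypes, y, n_cycles = 2000, burn_in = 200,
                 thin = 10, alpha = 2, beta = 198, seed = 9)
  f2 <- bayescpi(sim$genotypes, y, n_cycles = 2000, burn_in = 200,
                 thin = 10, alpha = 2, beta = 198, seed = 9)
  expect_identical(f1$snp, f2$snp)
  expect_identical(f1$samples, f2$samples)
  # BF identity at every SNP, to machine precision
  ns <- f1$config$n_saved
  pip_cap <- pmin(f1$snp$pip, (ns - 0.5) / ns)
  prior_odds <- f1$pi_prior_mean / (1 - f1$pi_prior_mean)
  expect_equal(f1$snp$bf, (pip_cap / (1 - pip_cap)) / prior_odds,
               tolerance = 1e-12)
})

test_that("on null data the model size tracks the prior mean", {
  set.seed(1002)
  dos <- matrix(rbinom(600 * 150, 2, 0.3), 600, 150,
                dimnames = list(sprintf("i%03d", 1:600), NULL))
  g <- toy_geno(dos)
  y <- setNames(rnorm(600), rownames(dos))
  fit <- bayescpi(g, y, n_cycles = 6000, burn_in = 1000, thin = 5,
                  alpha = 1.5, beta = 148.5, seed = 3)
  # on pure noise the sampled model size stays in the neighbourhood of the
  # prior mean (the point-null Occam factor pulls it somewhat below)
  prior_size <- 150 * 1.5 / 150
  expect_lt(mean(fit$samples$model_size), 2.5 * prior_size)
  expect_gt(mean(fit$samples$model_size), 0.05 * prior_size)
  # inclusion probabilities concentrate near the prior mean
  expect_lt(stats::median(fit$snp$pip), 3 * fit$pi_prior_mean)
  # no spurious strong evidence on noise (putative-tier calls against the
  # near-zero variance denominator are possible and are not evidence)
  expect_lt(max(fit$snp$two_ln_bf), 6)
  expect_equal(sum(call_qtls(fit)$status == "evidence"), 0)
})

test_that("a planted major QTL is ranked first, matching a single-marker scan", {
  sim <- sim_study(n_offspring = 400, n_snps = 500, h2 = 0.4,
                   qtl_frac = 0.5, seed = 47)
  y <- offspring_y(sim)
  fit <- bayescpi(sim$genotypes, y, n_cycles = 8000, burn_in = 1000,
                  thin = 10, alpha = 5, beta = 495, seed = 7)
  true_j <- which(sim$qtl_effects[, 1] != 0)
  true_chr <- sim$genotypes$map$chr[true_j]
  true_pos <- sim$genotypes$map$pos[true_j]
  top <- fit$snp[which.max(fit$snp$two_ln_bf), ]
  expect_equal(top$chr, true_chr)
  expect_lt(abs(top$pos - true_pos), 1e6)
  # independent oracle: single-marker regression F statistics rank the
  # same region first
  dos <- sim$genotypes$dosage[names(y), ]
  r2 <- apply(dos, 2, function(z) suppressWarnings(cor(z, y)))^2
  Fstat <- r2 * (length(y) - 2) / (1 - r2)
  top_f <- which.max(Fstat)
  expect_equal(sim$genotypes$map$chr[top_f], true_chr)
  expect_lt(abs(sim$genotypes$map$pos[top_f] - true_pos), 1e6)
})

test_that("with inclusion forced on, effects match the SNP-BLUP solution", {
  sim <- sim_study(n_offspring = 200, n_snps = 80, h2 = 0.5,
                   qtl_frac = 0.6, n_qtl = 10, seed = 53)
  y <- offspring_y(sim)
  fit <- bayescpi(sim$genotypes, y, n_cycles = 6000, burn_in = 1000,
                  thin = 5, alpha = 1e8, beta = 1e-4, fix_pi = TRUE,
                  seed = 11)
  expect_true(all(fit$snp$pip == 1))
  # ridge solution at the posterior-mean shrinkage
  dos <- sim$genotypes$dosage[names(y), ]
  Z <- sweep(dos, 2, colMeans(dos))
  lam <- mean(fit$samples$s2e) / mean(fit$samples$s2a)
  ridge <- solve(crossprod(Z) + lam * diag(ncol(Z)),
                 crossprod(Z, y - mean(y)))
  expect_gt(cor(fit$snp$effect, drop(ridge)), 0.98)
})

test_that("credibility intervals follow the sliding-window rule", {
  # worked 7-SNP track
  pos <- c(0.1, 0.6, 1.1, 1.6, 2.1, 2.6, 3.0) * 1e6
  score <- c(2, 4, 6.2, 4.5, 3.2, 1, 3.9)
  df <- data.frame(snp = paste0("s", 1:7), chr = "chr1", pos = pos,
                   two_ln_bf = score)
  q <- call_qtls(df)
  expect_equal(nrow(q), 1)
  expect_equal(q$status, "evidence")
  expect_equal(q$peak_pos, 1.1e6)
  oracle <- oracle_window(pos, score, peak_pos = 1.1e6)
  expect_equal(c(q$start, q$end), oracle)
  expect_equal(c(q$start, q$end), c(0.6e6, 3.0e6))

  # single isolated peak: interval collapses to the peak position
  lone <- data.frame(snp = paste0("s", 1:3), chr = "chr3",
                     pos = c(70e6, 75.82e6, 80e6),
                     two_ln_bf = c(1, 6.45, 0.5))
  q1 <- call_qtls(lone)
  expect_equal(q1$start, 75.82e6)
  expect_equal(q1$end, 75.82e6)
  expect_equal(q1$start_mb, 75.82)
  expect_equal(q1$status, "evidence")

  # sub-threshold track yields no calls
  expect_equal(nrow(call_qtls(transform(df, two_ln_bf = score / 2))), 0)

  # random window instances against the gap-walk oracle
  for (seed in 1:6) {
    set.seed(seed)
    pos_r <- sort(sample.int(30e6, 25))
    sc_r <- runif(25, 0, 8)
    dfr <- data.frame(snp = paste0("r", 1:25), chr = "chrX", pos = pos_r,
                      two_ln_bf = sc_r)
    qs <- call_qtls(dfr, min_pct_variance = 0)
    if (nrow(qs)) {
      top <- qs[which.max(qs$two_ln_bf), ]
      o <- oracle_window(pos_r, sc_r, top$peak_pos)
      expect_equal(c(top$start, top$end), o)
    }
  }
})

test_that("qtl calling is invariant to row order of the association table", {
  set.seed(5)
  df <- data.frame(snp = paste0("s", 1:40), chr = rep(c("chr2", "chr1"), 20),
                   pos = sample.int(50e6, 40), two_ln_bf = runif(40, 0, 9))
  q1 <- call_qtls(df, min_pct_variance = 0)
  q2 <- call_qtls(df[sample.int(40), ], min_pct_variance = 0)
  key <- function(q) {
    q <- q[order(q$chr, q$start), ]
    q[, c("chr", "peak_snp", "start", "end", "status")]
  }
  expect_equal(key(q1), key(q2), ignore_attr = TRUE)
})

test_that("putative peaks need variance or multi-trait support to be kept", {
  df <- data.frame(snp = paste0("s", 1:3), chr = "chr1",
                   pos = c(1e6, 10e6, 20e6),
                   two_ln_bf = c(5.5, 1, 1),
                   var_contrib = c(0.001, 0.5, 0.5))
  # region explains ~0.1% < 0.5%: dropped
  expect_equal(nrow(call_qtls(df)), 0)
  # same region overlapping another trait's region: kept
  other <- call_qtls(data.frame(snp = "t", chr = "chr1", pos = 1.0e6,
                                two_ln_bf = 7))
  q <- call_qtls(df, other_trait_regions = other)
  expect_equal(nrow(q), 1)
  expect_equal(q$status, "putative")
})

test_that("region variance decomposition sums the per-SNP contributions", {
  fake <- structure(list(
    snp = data.frame(snp = c("a", "b", "c"), chr = "chr1",
                     pos = c(1e6, 2e6, 30e6),
                     var_contrib = c(0.03, 0.01, 0.06)),
    total_gvar = 0.1), class = "bayescpi")
  expect_equal(qtl_variance(fake, "chr1", 0.5e6, 2.5e6), 40)
  expect_equal(qtl_variance(fake, "chr1", 5e6, 6e6), 0)
  bad <- structure(list(snp = fake$snp, total_gvar = 0),
                   class = "bayescpi")
  expect_error(qtl_variance(bad, "chr1", 0, 1), "zero")
})

test_that("convergence checks compare GEBVs across chains", {
  sim <- sim_study(n_offspring = 150, n_snps = 150, h2 = 0.3,
                   qtl_frac = 0.4, seed = 59)
  y <- offspring_y(sim)
  run <- function(seed) bayescpi(sim$genotypes, y, n_cycles = 2000,
                                 burn_in = 200, thin = 10, alpha = 2,
                                 beta = 148, seed = seed)
  a <- run(5); b <- run(5)
  rep_same <- check_convergence(list(a, b))
  expect_equal(rep_same$min_correlation, 1)
  expect_true(rep_same$pass)
  expect_error(check_convergence(list(a)), "at least 2")
  # pure-noise phenotype: chains disagree and the check fails
  set.seed(61)
  ynoise <- setNames(rnorm(length(y)), names(y))
  n1 <- bayescpi(sim$genotypes, ynoise, n_cycles = 2000, burn_in = 200,
                 thin = 10, alpha = 2, beta = 148, seed = 1)
  n2 <- bayescpi(sim$genotypes, ynoise, n_cycles = 2000, burn_in = 200,
                 thin = 10, alpha = 2, beta = 148, seed = 2)
  expect_false(check_convergence(list(n1, n2))$pass)
})

test_that("degenerate gwas inputs are rejected", {
  g <- toy_geno(cbind(c(0, 1, 2, 1), c(1, 1, 0, 2)))
  y <- setNames(rep(1, 4), rownames(g$dosage))
  expect_error(bayescpi(g, y), "zero variance")
  gm <- toy_geno(cbind(c(0, NA, 2, 1), c(1, 1, 0, 2)))
  expect_error(bayescpi(gm, setNames(rnorm(4), rownames(gm$dosage))),
               "missing")
})
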