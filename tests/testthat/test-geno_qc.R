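test_that("per-SNP summaries give exact call rate, MAF and HWE p-values", {
  # SNP1: perfect HWE at MAF 0.5; SNP2: (90, 0, 10) hard HWE failure;
  # SNP3: 3 missing of 100
  d1 <- c(rep(0, 25), rep(1, 50), rep(2, 25))
  d2 <- c(rep(0, 90), rep(2, 10))
  d3 <- c(rep(NA, 3), rep(1, 48), rep(0, 24), rep(2, 25))
  g <- toy_geno(cbind(d1, d2, d3))
  ss <- snp_summary(g)
  expect_equal(ss$maf[1], 0.5)
  expect_equal(ss$hwe_p[1], 1)
  # counts (90, 0, 10): p = 0.1, expected (81, 18, 1), chi-square = 100
  expect_equal(ss$hwe_p[2], pchisq(100, 1, lower.tail = FALSE))
  expect_lt(ss$hwe_p[2], 1e-4)
  expect_equal(ss$call_rate[3], 0.97)
  # all-missing SNP: representable, not an error
  d4 <- cbind(d1, rep(NA_real_, 100))
  ss4 <- snp_summary(toy_geno(d4))
  expect_equal(ss4$call_rate[2], 0)
  expect_true(is.na(ss4$maf[2]))
})

test_that("qc filters remove exactly the offending records", {
  set.seed(1)
  n <- 25
  clean1 <- rbinom(n, 2, 0.5)
  clean2 <- rbinom(n, 2, 0.4)
  low_maf <- c(1, rep(0, n - 1))                   # MAF 0.02
  low_cr <- c(rep(NA, 10), rbinom(n - 10, 2, 0.4)) # call rate 0.6
  hwe_bad <- c(rep(0, 15), rep(2, 10))             # no heterozygotes
  dos <- cbind(low_maf, low_cr, hwe_bad, clean1, clean2)
  dos[n, 4] <- NA                                  # sample n misses SNP4
  g <- toy_geno(dos)
  res <- run_qc(g, snp_call_rate = 0.7, hwe_p = 1e-4, maf = 0.05,
                sample_call_rate = 0.9)
  expect_equal(res$report$snps_removed[["snp_call_rate"]], 1)
  expect_equal(res$report$snps_removed[["hwe"]], 1)
  expect_equal(res$report$snps_removed[["maf"]], 1)
  expect_equal(res$report$samples_removed, 1)
  expect_equal(colnames(res$genotypes$dosage), c("S004", "S005"))
  expect_equal(nrow(res$genotypes$dosage), n - 1)

  # brute-force re-filter oracle on the same matrix
  keep_snp <- logical(5)
  for (j in 1:5) {
    x <- dos[, j]
    cr <- mean(!is.na(x))
    p <- mean(x, na.rm = TRUE) / 2
    maf <- min(p, 1 - p)
    cnt <- c(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
             sum(x == 2, na.rm = TRUE))
    exp_cnt <- sum(cnt) * c((1 - p)^2, 2 * p * (1 - p), p^2)
    chi <- if (p > 0 && p < 1) sum((cnt - exp_cnt)^2 / exp_cnt) else 0
    keep_snp[j] <- cr >= 0.7 &&
      pchisq(chi, 1, lower.tail = FALSE) > 1e-4 && maf > 0.05
  }
  expect_equal(which(keep_snp), c(4, 5))
  keep_samp <- rowMeans(!is.na(dos[, keep_snp, drop = FALSE])) >= 0.9
  expect_equal(sum(!keep_samp), 1)

  # all-pass matrix is untouched
  ok <- toy_geno(cbind(clean1, clean2))
  res2 <- run_qc(ok, snp_call_rate = 0.9, hwe_p = 1e-4, maf = 0.05,
                 sample_call_rate = 0.9)
  expect_equal(dim(res2$genotypes$dosage), dim(ok$dosage))
  expect_true(all(res2$report$snps_removed == 0))
})

test_that("default thresholds echo the standard array-QC values", {
  g <- toy_geno(cbind(rbinom(50, 2, 0.5), rbinom(50, 2, 0.4)))
  res <- run_qc(g)
  expect_equal(unname(res$report$thresholds),
               c(0.97, 1e-4, 0.05, 0.90))
})

test_that("qc is idempotent and monotone in its thresholds on clean data", {
  ped <- sim_pedigree(breeding_design(10, 10, 50, 6, n_crosses = 1),
                      seed = 11)
  g <- sim_genotypes(ped, n_snps = 400, missing_rate = 0.02, seed = 11)
  r1 <- run_qc(g)
  r2 <- run_qc(r1$genotypes)
  expect_identical(r1$genotypes$dosage, r2$genotypes$dosage)
  # loosening the MAF threshold never removes more SNPs
  loose <- run_qc(g, maf = 0.01)
  expect_gte(ncol(loose$genotypes$dosage), ncol(r1$genotypes$dosage))
  # report reconciles with matrix dimensions
  expect_equal(r1$report$snps_initial - sum(r1$report$snps_removed),
               ncol(r1$genotypes$dosage))
  expect_equal(r1$report$samples_initial - r1$report$samples_removed,
               nrow(r1$genotypes$dosage))
})

test_that("an exclusion list removes named SNPs before the filters", {
  g <- toy_geno(cbind(rbinom(60, 2, 0.5), rbinom(60, 2, 0.4),
                      rbinom(60, 2, 0.3)))
  res <- run_qc(g, exclude = c("S001", "S003"), sample_call_rate = 0)
  expect_equal(res$report$snps_removed[["excluded"]], 2)
  expect_equal(colnames(res$genotypes$dosage), "S002")
})

test_that("imputation fills every missing call sensibly", {
  # unanimous SNP imputes to the unanimous value
  d <- cbind(c(0, 0, 0, NA), c(2, 2, NA, 2), c(1, 0, 2, 1))
  g <- impute_missing(toy_geno(d))
  expect_false(anyNA(g$dosage))
  expect_equal(g$dosage[4, 1], 0)
  expect_equal(g$dosage[3, 2], 2)
  # matrix with no missing entries is returned unchanged
  full <- toy_geno(cbind(c(0, 1, 2), c(2, 1, 0)))
  expect_identical(impute_missing(full)$dosage, full$dosage)
  # Mendelian-certain call from homozygous parents
  ped <- pedigree(c("s", "d", "o"), c(NA, NA, "s"), c(NA, NA, "d"),
                  c(0, 0, 1))
  dos <- matrix(c(0, 2, NA, 1, 1, 1), 3, 2,
                dimnames = list(c("s", "d", "o"), NULL))
  gm <- toy_geno(dos)
  out <- impute_missing(gm, mode = "family_mendelian", ped = ped)
  expect_equal(out$dosage["o", 1], 1)
  # all-missing SNP is a precondition violation
  bad <- toy_geno(cbind(c(0, 1), c(NA_real_, NA_real_)))
  expect_error(impute_missing(bad), "all calls missing")
})
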