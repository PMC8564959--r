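#' Per-SNP summary statistics
#'
#' Call rate, minor allele frequency (on non-missing calls) and a
#' one-degree-of-freedom Pearson chi-square test of Hardy-Weinberg
#' equilibrium per SNP. SNPs with all calls missing get call rate 0 and NA
#' for MAF and the HWE p-value.
#'
#' @param g a [geno_matrix()].
#' @return A data frame with columns `snp`, `chr`, `pos`, `call_rate`,
#'   `maf`, `hwe_p`.
#' @export
snp_summary <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  d <- g$dosage
  n <- nrow(d)
  n0 <- colSums(d == 0, na.rm = TRUE)
  n1 <- colSums(d == 1, na.rm = TRUE)
  n2 <- colSums(d == 2, na.rm = TRUE)
  nn <- n0 + n1 + n2
  call_rate <- nn / n
  p <- ifelse(nn > 0, (2 * n2 + n1) / (2 * nn), NA_real_)
  maf <- pmin(p, 1 - p)
  # expected genotype counts under HWE from the estimated allele frequency
  e0 <- nn * (1 - p)^2
  e1 <- nn * 2 * p * (1 - p)
  e2 <- nn * p^2
  chisq <- rep(NA_real_, ncol(d))
  poly <- !is.na(p) & p > 0 & p < 1
  chisq[poly] <- (n0[poly] - e0[poly])^2 / e0[poly] +
    (n1[poly] - e1[poly])^2 / e1[poly] +
    (n2[poly] - e2[poly])^2 / e2[poly]
  hwe_p <- ifelse(is.na(chisq),
                  ifelse(is.na(p), NA_real_, 1),  # monomorphic: no deviation
                  stats::pchisq(chisq, df = 1, lower.tail = FALSE))
  data.frame(snp = g$map$snp, chr = g$map$chr, pos = g$map$pos,
             call_rate = call_rate, maf = maf, hwe_p = hwe_p,
             stringsAsFactors = FALSE)
}

#' SNP and sample quality control
#'
#' Applies, in order: SNP call rate, Hardy-Weinberg equilibrium, minor
#' allele frequency, then sample call rate. SNP summaries are computed once
#' on the input (single pass; they are not recomputed after sample removal).
#' An optional exclusion list removes named SNPs first (e.g. probe-level
#' failures established upstream).
#'
#' @param g a [geno_matrix()].
#' @param snp_call_rate minimum SNP call rate (default 0.97).
#' @param hwe_p minimum HWE p-value (default 1e-4).
#' @param maf minimum minor allele frequency (default 0.05).
#' @param sample_call_rate minimum per-sample call rate (default 0.90).
#' @param exclude optional character vector of SNP ids removed before the
#'   statistical filters.
#' @return A list of class `qc_result`: `genotypes` (filtered
#'   [geno_matrix()]) and `report` (a `qc_report` with per-filter removal
#'   counts in application order and the thresholds used).
#' @export
run_qc <- function(g, snp_call_rate = 0.97, hwe_p = 1e-4, maf = 0.05,
                   sample_call_rate = 0.90, exclude = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  thr <- c(snp_call_rate = snp_call_rate, hwe_p = hwe_p, maf = maf,
           sample_call_rate = sample_call_rate)
  if (any(thr < 0) || any(thr > 1)) stop("thresholds must lie in [0, 1]")

  n_snps0 <- ncol(g$dosage)
  n_samp0 <- nrow(g$dosage)
  keep <- rep(TRUE, n_snps0)
  removed <- c(excluded = 0L, snp_call_rate = 0L, hwe = 0L, maf = 0L)
  if (!is.null(exclude)) {
    drop <- keep & g$map$snp %in% exclude
    removed["excluded"] <- sum(drop)
    keep <- keep & !drop
  }
  ss <- snp_summary(g)
  drop <- keep & !(ss$call_rate >= snp_call_rate)
  removed["snp_call_rate"] <- sum(drop)
  keep <- keep & !drop
  drop <- keep & !(is.na(ss$hwe_p) | ss$hwe_p > hwe_p)
  removed["hwe"] <- sum(drop)
  keep <- keep & !drop
  drop <- keep & !(!is.na(ss$maf) & ss$maf > maf)
  removed["maf"] <- sum(drop)
  keep <- keep & !drop
  if (!any(keep)) stop("no SNPs pass quality control; relax the thresholds")

  d <- g$dosage[, keep, drop = FALSE]
  samp_cr <- rowMeans(!is.na(d))
  keep_s <- samp_cr >= sample_call_rate
  removed_samples <- sum(!keep_s)
  if (!any(keep_s)) stop("no samples pass quality control")
  d <- d[keep_s, , drop = FALSE]

  out <- geno_matrix(d, g$map[keep, , drop = FALSE])
  report <- structure(list(
    thresholds = thr,
    snps_initial = n_snps0, snps_removed = removed,
    snps_final = ncol(d),
    samples_initial = n_samp0, samples_removed = removed_samples,
    samples_final = nrow(d)), class = "qc_report")
  stopifnot(report$snps_initial - sum(report$snps_removed) ==
              report$snps_final)
  stopifnot(report$samples_initial - report$samples_removed ==
              report$samples_final)
  structure(list(genotypes = out, report = report), class = "qc_result")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Quality control (thresholds: SNP call rate >=",
      x$thresholds["snp_call_rate"], ", HWE p >", x$thresholds["hwe_p"],
      ", MAF >", x$thresholds["maf"], ", sample call rate >=",
      x$thresholds["sample_call_rate"], ")\n")
  cat("SNPs:", x$snps_initial, "->", x$snps_final, "removed:",
      paste(names(x$snps_removed), x$snps_removed, sep = "=",
            collapse = ", "), "\n")
  cat("Samples:", x$samples_initial, "->", x$samples_final,
      "(", x$samples_removed, "removed )\n")
  invisible(x)
}

#' @export
print.qc_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Impute missing genotype calls
#'
#' Two deliberately simple imputers. `rounded_mean` fills each missing call
#' with the SNP's mean dosage rounded to the nearest of 0/1/2.
#' `family_mendelian` first fills calls that are certain from the parents'
#' genotypes (both parents homozygous), then falls back to `rounded_mean`.
#'
#' @param g a [geno_matrix()].
#' @param mode `"rounded_mean"` or `"family_mendelian"`.
#' @param ped a [pedigree()]; required for `family_mendelian`.
#' @return A [geno_matrix()] with no missing calls.
#' @export
impute_missing <- function(g, mode = c("rounded_mean", "family_mendelian"),
                           ped = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  mode <- match.arg(mode)
  d <- g$dosage
  if (!anyNA(d)) return(g)
  nn <- colSums(!is.na(d))
  if (any(nn == 0)) {
    stop("SNPs with all calls missing cannot be imputed: ",
         paste(utils::head(g$map$snp[nn == 0], 5), collapse = ", "))
  }
  if (mode == "family_mendelian") {
    if (is.null(ped)) stop("family_mendelian imputation requires a pedigree")
    idx <- match(ped$id, rownames(d))
    for (i in seq_len(nrow(ped))) {
      ri <- idx[i]
      if (is.na(ri) || is.na(ped$sire[i]) || is.na(ped$dam[i])) next
      rs <- match(ped$sire[i], rownames(d))
      rm_ <- match(ped$dam[i], rownames(d))
      if (is.na(rs) || is.na(rm_)) next
      miss <- which(is.na(d[ri, ]))
      if (!length(miss)) next
      ps <- d[rs, miss]; pm <- d[rm_, miss]
      certain <- !is.na(ps) & !is.na(pm) & ps != 1 & pm != 1
      if (any(certain)) {
        d[ri, miss[certain]] <- (ps[certain] + pm[certain]) / 2
      }
    }
  }
  mu <- colMeans(d, na.rm = TRUE)
  fill <- pmin(pmax(round(mu), 0), 2)
  na_idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(na_idx)) d[na_idx] <- fill[na_idx[, 2]]
  geno_matrix(d, g$map)
}
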