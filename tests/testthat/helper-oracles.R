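# Independent oracles used across the suite. Each reimplements the target
# quantity by a different route than the package (recursive kinship descent,
# direct MME assembly, gap-walk window enumeration), so agreement is a real
# cross-check rather than a tautology.

# additive relationship by memoised coancestry recursion (path-counting
# equivalent): A_ij = 2 f_ij, f_ii = (1 + f_sd)/2
oracle_A <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  s <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  d <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  memo <- new.env(parent = emptyenv())
  f <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i > j) { k <- i; i <- j; j <- k }
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- if (i == j) {
      0.5 * (1 + f(s[i], d[i]))
    } else {
      # j is the later-born individual by pedigree order
      0.5 * (f(i, s[j]) + f(i, d[j]))
    }
    memo[[key]] <- val
    val
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in i:n) {
    A[i, j] <- A[j, i] <- 2 * f(i, j)
  }
  A
}

# direct assembly and inversion of Henderson's MME for y = mu + Za + e
oracle_mme <- function(y, K, Va, Ve) {
  all_ids <- rownames(K)
  rec <- names(y)[!is.na(y)]
  X <- matrix(1, length(rec), 1)
  Z <- matrix(0, length(rec), length(all_ids),
              dimnames = list(rec, all_ids))
  Z[cbind(seq_along(rec), match(rec, all_ids))] <- 1
  lam <- Ve / Va
  Kinv <- solve(unclass(K))
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + lam * Kinv))
  rhs <- rbind(crossprod(X, y[rec]), crossprod(Z, y[rec]))
  sol <- solve(C, rhs)
  list(mu = sol[1], ebv = setNames(sol[-1], all_ids))
}

# credibility interval by gap-walking the sorted support SNPs outward from
# the peak: extend while the next support SNP is within window of the edge
oracle_window <- function(pos, score, peak_pos, support = 3, window = 1e6) {
  sup <- sort(pos[score >= support | pos == peak_pos])
  lo <- hi <- peak_pos
  repeat {
    left <- sup[sup < lo & sup >= lo - window]
    right <- sup[sup > hi & sup <= hi + window]
    if (!length(left) && !length(right)) break
    if (length(left)) lo <- min(left)
    if (length(right)) hi <- max(right)
  }
  c(lo, hi)
}

# one-way sire-model ANOVA estimate of heritability for balanced half-sib
# data: sigma2_s = (MSB - MSW)/k, h2 = 4 sigma2_s / (sigma2_s + sigma2_w)
oracle_halfsib_h2 <- function(y, sire) {
  k <- unique(table(sire))
  stopifnot(length(k) == 1)
  means <- tapply(y, sire, mean)
  msb <- k * var(means)
  msw <- mean(tapply(y, sire, var))
  s2s <- (msb - msw) / k
  4 * s2s / (s2s + msw)
}

# small helper: geno_matrix from a dosage matrix with an evenly spaced map
toy_geno <- function(dos, chr = "chr1", spacing = 1e6) {
  m <- ncol(dos)
  if (is.null(rownames(dos))) rownames(dos) <- paste0("i", seq_len(nrow(dos)))
  colnames(dos) <- sprintf("S%03d", seq_len(m))
  geno_matrix(dos, data.frame(snp = colnames(dos),
                              chr = rep_len(chr, m),
                              pos = seq_len(m) * spacing))
}

# offspring cohort phenotype vector of a sim_result
offspring_y <- function(sim, trait = 1) {
  off <- sim$pedigree$id[!is.na(sim$pedigree$sire)]
  sim$phenotypes[off, trait]
}
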