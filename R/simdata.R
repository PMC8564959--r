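#' Breeding design for a factorial-cross cohort
#'
#' Describes a mating design in which dams and sires are partitioned into
#' factorial cross blocks and full-sib families are drawn from the
#' within-block dam x sire grid. The default emulates a commercial rainbow
#' trout design: 10 factorial crosses of 84 dams x 99 sires giving 831
#' families and roughly 1.7 phenotyped offspring per family.
#'
#' @param n_dams,n_sires number of founder dams and sires.
#' @param n_families number of full-sib families to create; must not exceed
#'   the number of dam x sire pairs available within the cross blocks.
#' @param offspring_per_family either a single whole number (exact family
#'   size), a non-integer mean (offspring are allocated to families
#'   uniformly at random, multinomial sizes), or a function of the number of
#'   families returning an integer vector of sizes.
#' @param n_crosses number of factorial cross blocks the parents are split
#'   into; 1 means a single full factorial.
#' @param n_generations number of parent generations preceding the
#'   phenotyped cohort (1 = founders are the parents).
#' @return An object of class `breeding_design`.
#' @export
breeding_design <- function(n_dams = 84, n_sires = 99, n_families = 831,
                            offspring_per_family = 1.7, n_crosses = 10,
                            n_generations = 1) {
  stopifnot(n_dams >= 1, n_sires >= 1, n_families >= 1,
            n_crosses >= 1, n_generations >= 1)
  if (n_families > n_dams * n_sires) {
    stop("infeasible design: n_families (", n_families,
         ") exceeds the dam x sire grid (", n_dams * n_sires, " pairs)")
  }
  structure(list(n_dams = n_dams, n_sires = n_sires,
                 n_families = n_families,
                 offspring_per_family = offspring_per_family,
                 n_crosses = n_crosses, n_generations = n_generations),
            class = "breeding_design")
}

#' @export
print.breeding_design <- function(x, ...) {
  cat("Breeding design:", x$n_dams, "dams x", x$n_sires, "sires,",
      x$n_families, "families in", x$n_crosses, "cross block(s)\n")
  invisible(x)
}

# split n items into k balanced groups; returns group index per item
balanced_blocks <- function(n, k) sort(rep_len(seq_len(k), n))

#' Simulate a factorial-cross pedigree
#'
#' Founder dams and sires are partitioned into cross blocks; full-sib
#' families are sampled without replacement from the within-block dam x sire
#' grids, and offspring are allocated to families per the design's family
#' size rule. With `n_generations > 1`, ancestral parent generations are
#' first produced by random both-parent mating from the base population.
#'
#' @param design a [breeding_design()].
#' @param seed integer seed; the result is reproducible bit-for-bit.
#' @return A [pedigree()] with a `family` column on the phenotyped cohort.
#' @export
sim_pedigree <- function(design, seed = 1L) {
  stopifnot(inherits(design, "breeding_design"))
  set.seed(seed)
  n_d <- design$n_dams
  n_s <- design$n_sires

  id <- character(0); sire <- character(0); dam <- character(0)
  gen <- integer(0); fam <- character(0)
  dam_ids <- sprintf("D%04d", seq_len(n_d))
  sire_ids <- sprintf("S%04d", seq_len(n_s))
  add <- function(ids, s, d, g, f = NA_character_) {
    id <<- c(id, ids)
    sire <<- c(sire, rep_len(s, length(ids)))
    dam <<- c(dam, rep_len(d, length(ids)))
    gen <<- c(gen, rep(g, length(ids)))
    fam <<- c(fam, rep_len(f, length(ids)))
  }
  # ancestral generations: generation 0 founders, then random matings until
  # the parents of the phenotyped cohort
  add(paste0("G0", dam_ids), NA_character_, NA_character_, 0L)
  add(paste0("G0", sire_ids), NA_character_, NA_character_, 0L)
  for (g in seq_len(design$n_generations - 1L)) {
    prev_d <- paste0("G", g - 1L, dam_ids)
    prev_s <- paste0("G", g - 1L, sire_ids)
    new_ids <- paste0("G", g, c(dam_ids, sire_ids))
    add(new_ids,
        sample(prev_s, n_d + n_s, replace = TRUE),
        sample(prev_d, n_d + n_s, replace = TRUE), g)
  }
  top <- design$n_generations - 1L
  par_d <- paste0("G", top, dam_ids)
  par_s <- paste0("G", top, sire_ids)

  # within-block factorial grid of candidate pairs
  bd <- balanced_blocks(n_d, design$n_crosses)
  bs <- balanced_blocks(n_s, design$n_crosses)
  cand <- do.call(rbind, lapply(seq_len(design$n_crosses), function(b) {
    expand.grid(dam = par_d[bd == b], sire = par_s[bs == b],
                stringsAsFactors = FALSE)
  }))
  if (design$n_families > nrow(cand)) {
    stop("infeasible design: n_families (", design$n_families,
         ") exceeds the ", nrow(cand),
         " dam x sire pairs available within ", design$n_crosses,
         " cross block(s); reduce n_families or n_crosses")
  }
  pairs <- cand[sample.int(nrow(cand), design$n_families), , drop = FALSE]

  sizes <- family_sizes(design$offspring_per_family, design$n_families)
  fam_lab <- sprintf("F%04d", seq_len(design$n_families))
  off_fam <- rep(seq_len(design$n_families), sizes)
  n_off <- length(off_fam)
  add(sprintf("O%05d", seq_len(n_off)),
      pairs$sire[off_fam], pairs$dam[off_fam],
      design$n_generations, fam_lab[off_fam])

  pedigree(id, sire, dam, gen, family = fam)
}

family_sizes <- function(spec, n_families) {
  if (is.function(spec)) {
    sizes <- as.integer(spec(n_families))
    stopifnot(length(sizes) == n_families, all(sizes >= 0))
    return(sizes)
  }
  stopifnot(is.numeric(spec), length(spec) == 1, spec > 0)
  if (abs(spec - round(spec)) < 1e-12) {
    return(rep(as.integer(round(spec)), n_families))
  }
  total <- round(spec * n_families)
  tabulate(sample.int(n_families, total, replace = TRUE), nbins = n_families)
}

#' Genotype matrix container
#'
#' Dosage matrix (individuals x SNPs, values 0/1/2 or NA) with a marker map.
#'
#' @param dosage numeric matrix with individual ids as rownames and SNP ids
#'   as colnames; entries in `{0, 1, 2, NA}`.
#' @param map data frame with columns `snp`, `chr`, `pos` (bp, 1-based),
#'   one row per dosage column, in column order.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, map) {
  stopifnot(is.matrix(dosage), !is.null(rownames(dosage)),
            !is.null(colnames(dosage)))
  stopifnot(is.data.frame(map), all(c("snp", "chr", "pos") %in% names(map)))
  if (nrow(map) != ncol(dosage)) {
    stop("marker map has ", nrow(map), " rows but dosage has ",
         ncol(dosage), " SNPs")
  }
  if (!identical(as.character(map$snp), colnames(dosage))) {
    stop("marker map snp ids must match dosage column names in order")
  }
  if (any(map$pos < 0)) stop("map positions must be non-negative")
  if (anyDuplicated(rownames(dosage))) stop("duplicated individual ids")
  ok <- dosage %in% c(0, 1, 2) | is.na(dosage)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  structure(list(dosage = dosage,
                 map = data.frame(snp = as.character(map$snp),
                                  chr = as.character(map$chr),
                                  pos = as.numeric(map$pos),
                                  stringsAsFactors = FALSE)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  d <- x$dosage
  cat("Genotypes:", nrow(d), "individuals x", ncol(d), "SNPs on",
      length(unique(x$map$chr)), "chromosome(s);",
      sprintf("%.2f%%", 100 * mean(is.na(d))), "missing\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Simulate SNP genotypes by gene dropping
#'
#' Founder haplotypes are drawn at Hardy-Weinberg proportions with allele
#' frequencies uniform over `maf_range`; descendant gametes are produced by
#' Mendelian transmission with Haldane (no-interference) recombination at
#' `morgans_per_bp` (default 1 cM/Mb). Both parents must be known, or both
#' unknown (founder).
#'
#' @param ped a [pedigree()].
#' @param n_snps total number of SNPs, split nearly equally over chromosomes.
#' @param n_chr number of chromosomes.
#' @param chr_length_bp chromosome length in bp.
#' @param maf_range founder allele-frequency interval, within (0, 0.5].
#' @param missing_rate proportion of calls set to missing at random.
#' @param morgans_per_bp genetic map density; 1e-8 is 1 cM per Mb.
#' @param seed integer seed.
#' @return A [geno_matrix()].
#' @export
sim_genotypes <- function(ped, n_snps = 2000, n_chr = 5,
                          chr_length_bp = 5e7, maf_range = c(0.05, 0.5),
                          missing_rate = 0, morgans_per_bp = 1e-8,
                          seed = 1L) {
  stopifnot(inherits(ped, "pedigree"))
  stopifnot(length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  stopifnot(missing_rate >= 0, missing_rate < 1)
  single <- xor(is.na(ped$sire), is.na(ped$dam))
  if (any(single)) {
    stop("individuals with exactly one known parent cannot be gene-dropped: ",
         paste(utils::head(ped$id[single], 5), collapse = ", "))
  }
  set.seed(seed)

  chr_of <- balanced_blocks(n_snps, n_chr)
  pos <- unlist(lapply(seq_len(n_chr), function(c) {
    sort(sample.int(chr_length_bp, sum(chr_of == c)))
  }), use.names = FALSE)
  map <- data.frame(snp = sprintf("SNP%05d", seq_len(n_snps)),
                    chr = paste0("chr", chr_of), pos = pos,
                    stringsAsFactors = FALSE)

  # recombination fraction between adjacent SNPs; 0.5 at chromosome starts
  d <- c(0, diff(pos)) * morgans_per_bp
  rfrac <- 0.5 * (1 - exp(-2 * d))
  rfrac[c(TRUE, diff(chr_of) != 0)] <- 0.5

  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  H1 <- matrix(0L, n, n_snps)
  H2 <- matrix(0L, n, n_snps)
  p <- runif(n_snps, maf_range[1], maf_range[2])

  gamete <- function(hA, hB) {
    sw <- runif(n_snps) < rfrac
    use_b <- cumsum(sw) %% 2L == 1L
    ifelse(use_b, hB, hA)
  }
  for (i in seq_len(n)) {
    if (is.na(ped$sire[i])) {
      H1[i, ] <- rbinom(n_snps, 1L, p)
      H2[i, ] <- rbinom(n_snps, 1L, p)
    } else {
      s <- idx[[ped$sire[i]]]; m <- idx[[ped$dam[i]]]
      H1[i, ] <- gamete(H1[s, ], H2[s, ])
      H2[i, ] <- gamete(H1[m, ], H2[m, ])
    }
  }
  dos <- H1 + H2
  storage.mode(dos) <- "double"
  if (missing_rate > 0) {
    dos[runif(length(dos)) < missing_rate] <- NA_real_
  }
  dimnames(dos) <- list(ped$id, map$snp)
  geno_matrix(dos, map)
}

#' Trait model for phenotype simulation
#'
#' Defines per-trait heritabilities, phenotypic scale, the genetic
#' correlation structure and optionally planted QTLs.
#'
#' @param h2 numeric vector of narrow-sense heritabilities in `[0, 1]`.
#' @param means per-trait phenotypic means (percent units for
#'   compositional traits).
#' @param sds per-trait phenotypic standard deviations.
#' @param genetic_corr trait x trait genetic correlation matrix (symmetric,
#'   positive semi-definite, unit diagonal). Default identity.
#' @param residual_corr residual correlation matrix; defaults to
#'   `genetic_corr`, giving phenotypic correlations of the same sign and
#'   similar size as the genetic ones.
#' @param qtls optional data frame of planted QTLs with columns `chr`,
#'   `pos` (bp), `trait` (index), `frac` (fraction of that trait's additive
#'   genetic variance); per-trait fractions must sum to < 1.
#' @param names optional trait names.
#' @return An object of class `trait_model`.
#' @export
trait_model <- function(h2, means = NULL, sds = NULL, genetic_corr = NULL,
                        residual_corr = NULL, qtls = NULL, names = NULL) {
  t <- length(h2)
  stopifnot(t >= 1, all(h2 >= 0), all(h2 <= 1))
  if (is.null(means)) means <- rep(0, t)
  if (is.null(sds)) sds <- rep(1, t)
  stopifnot(length(means) == t, length(sds) == t, all(sds > 0))
  if (is.null(genetic_corr)) genetic_corr <- diag(t)
  check_corr(genetic_corr, t, "genetic_corr")
  if (is.null(residual_corr)) residual_corr <- genetic_corr
  check_corr(residual_corr, t, "residual_corr")
  if (is.null(names)) names <- paste0("trait", seq_len(t))
  stopifnot(length(names) == t)
  if (!is.null(qtls)) {
    stopifnot(is.data.frame(qtls),
              all(c("chr", "pos", "trait", "frac") %in% colnames(qtls)))
    stopifnot(all(qtls$frac > 0), all(qtls$trait %in% seq_len(t)))
    fr <- tapply(qtls$frac, qtls$trait, sum)
    if (any(fr >= 1)) {
      stop("planted QTL variance fractions must sum to < 1 per trait")
    }
  }
  structure(list(h2 = h2, means = means, sds = sds,
                 genetic_corr = genetic_corr, residual_corr = residual_corr,
                 qtls = qtls, names = names),
            class = "trait_model")
}

check_corr <- function(m, t, what) {
  if (!is.matrix(m) || nrow(m) != t || ncol(m) != t) {
    stop(what, " must be a ", t, " x ", t, " matrix")
  }
  if (max(abs(m - t(m))) > 1e-8) stop(what, " must be symmetric")
  if (max(abs(diag(m) - 1)) > 1e-8) stop(what, " must have unit diagonal")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop(what, " is not positive semi-definite")
  invisible(TRUE)
}

#' Twelve-trait fatty-acid composition preset
#'
#' Trait model emulating a fillet fatty-acid composition panel in rainbow
#' trout: 12 compositional traits (percent of total fatty acids) with
#' pedigree heritabilities in the 0.03-0.24 range, means and SDs typical of
#' a plant-based-diet production cohort, and block-structured genetic
#' correlations (strongly positive within the saturated/monounsaturated
#' block and within the polyunsaturated block, strongly negative between
#' the blocks).
#'
#' @return A [trait_model()] with 12 traits.
#' @export
fa_trait_model <- function() {
  nm <- c("SFA", "MUFA", "PUFA", "n3PUFA", "n6PUFA", "OA",
          "LA", "ALA", "ARA", "EPA", "DHA", "EPA_DHA")
  h2 <- c(0.08, 0.12, 0.16, 0.03, 0.24, 0.10,
          0.18, 0.05, 0.21, 0.16, 0.03, 0.08)
  means <- c(22.69, 49.6, 27.05, 8.87, 17.19, 43.76,
             16.08, 4.62, 0.21, 1.11, 0.75, 1.97)
  sds <- c(1.06, 0.9, 1.37, 1.18, 0.59, 1.51,
           0.68, 1.08, 0.03, 0.16, 0.12, 0.61)
  # block structure: SFA/MUFA/OA vs PUFA group antagonism
  sat <- c(1, 2, 6)              # SFA, MUFA, OA
  pufa <- c(3, 4, 5, 7, 8, 9, 10, 11, 12)
  g <- matrix(0.2, 12, 12)
  g[sat, sat] <- 0.85
  g[pufa, pufa] <- 0.7
  g[sat, pufa] <- g[pufa, sat] <- -0.6
  diag(g) <- 1
  # nudge to the nearest PSD correlation matrix
  e <- eigen(g, symmetric = TRUE)
  vals <- pmax(e$values, 1e-6)
  g <- e$vectors %*% diag(vals) %*% t(e$vectors)
  s <- diag(1 / sqrt(diag(g)))
  g <- s %*% g %*% s
  g <- (g + t(g)) / 2
  trait_model(h2 = h2, means = means, sds = sds, genetic_corr = g,
              names = nm)
}

#' Simulate phenotypes under the additive animal model
#'
#' Per trait, the breeding value is the sum of planted-QTL marker effects
#' (centred dosages times allele substitution effects sized to the requested
#' fraction of additive variance) and an infinitesimal polygenic term
#' simulated down the pedigree by the recursive rule child = (sire + dam)/2
#' plus a Mendelian-sampling deviate. Residual variance is scaled to the
#' realised breeding-value variance so realised heritability targets the
#' model's `h2`.
#'
#' @param ped a [pedigree()].
#' @param model a [trait_model()].
#' @param genotypes a [geno_matrix()]; may be `NULL` when the model plants
#'   no QTLs.
#' @param seed integer seed.
#' @return An object of class `sim_result`: list with `pedigree`,
#'   `genotypes`, `phenotypes` (individual x trait matrix), `tbv` (true
#'   breeding values), `qtl_effects` (per-SNP x trait allele substitution
#'   effects, zero off the planted QTLs) and the `model`.
#' @export
sim_phenotypes <- function(ped, model, genotypes = NULL, seed = 1L) {
  stopifnot(inherits(ped, "pedigree"), inherits(model, "trait_model"))
  if (!is.null(model$qtls) && is.null(genotypes)) {
    stop("genotypes are required when the trait model plants QTLs")
  }
  if (!is.null(genotypes)) {
    stopifnot(inherits(genotypes, "geno_matrix"))
    if (!all(ped$id %in% rownames(genotypes$dosage))) {
      stop("every pedigree individual must be genotyped for simulation")
    }
  }
  set.seed(seed)
  n <- nrow(ped)
  t <- length(model$h2)
  Va <- model$h2 * model$sds^2

  # planted QTL effects on centred dosages
  qtl_eff <- NULL
  qtl_part <- matrix(0, n, t)
  if (!is.null(model$qtls)) {
    m <- ncol(genotypes$dosage)
    qtl_eff <- matrix(0, m, t,
                      dimnames = list(genotypes$map$snp, model$names))
    dos <- genotypes$dosage[ped$id, , drop = FALSE]
    for (k in seq_len(nrow(model$qtls))) {
      q <- model$qtls[k, ]
      on_chr <- which(genotypes$map$chr == as.character(q$chr))
      if (!length(on_chr)) stop("no SNPs on chromosome '", q$chr, "'")
      j <- on_chr[which.min(abs(genotypes$map$pos[on_chr] - q$pos))]
      z <- dos[, j]
      if (anyNA(z)) stop("planted QTL SNP has missing calls; impute first")
      vz <- stats::var(z)
      if (vz <= 0) stop("planted QTL SNP is monomorphic")
      a <- sqrt(q$frac * Va[q$trait] / vz) * sample(c(-1, 1), 1)
      qtl_eff[j, q$trait] <- qtl_eff[j, q$trait] + a
      qtl_part[, q$trait] <- qtl_part[, q$trait] + (z - mean(z)) * a
    }
  }

  # polygenic term down the pedigree; Mendelian sampling variance G0/2
  frac_qtl <- rep(0, t)
  if (!is.null(model$qtls)) {
    frac_qtl <- vapply(seq_len(t), function(j) {
      sum(model$qtls$frac[model$qtls$trait == j])
    }, numeric(1))
  }
  sd_poly <- sqrt((1 - frac_qtl) * Va)
  G0p <- diag(sd_poly, t) %*% model$genetic_corr %*% diag(sd_poly, t)
  L <- chol_psd(G0p)
  Lms <- chol_psd(G0p / 2)
  idx <- seq_len(n); names(idx) <- ped$id
  poly <- matrix(0, n, t)
  for (i in seq_len(n)) {
    if (is.na(ped$sire[i])) {
      poly[i, ] <- drop(rnorm(t) %*% L)
    } else {
      mid <- (poly[idx[[ped$sire[i]]], ] + poly[idx[[ped$dam[i]]], ]) / 2
      poly[i, ] <- mid + drop(rnorm(t) %*% Lms)
    }
  }

  tbv <- poly + qtl_part
  # residual variance scaled to realised TBV variance so realised h2 hits
  # the target; traits with h2 = 0 fall back to the nominal phenotypic SD
  v_tbv <- apply(tbv, 2, stats::var)
  Ve <- ifelse(model$h2 > 0, v_tbv * (1 - model$h2) / model$h2,
               model$sds^2)
  sd_e <- sqrt(Ve)
  R0 <- diag(sd_e, t) %*% model$residual_corr %*% diag(sd_e, t)
  e <- matrix(rnorm(n * t), n, t) %*% chol_psd(R0)
  ymat <- sweep(tbv + e, 2, model$means, `+`)
  dimnames(ymat) <- list(ped$id, model$names)
  dimnames(tbv) <- list(ped$id, model$names)

  structure(list(pedigree = ped, genotypes = genotypes, phenotypes = ymat,
                 tbv = tbv, qtl_effects = qtl_eff, model = model),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Simulated cohort:", nrow(x$phenotypes), "individuals,",
      ncol(x$phenotypes), "trait(s)")
  if (!is.null(x$genotypes)) cat(",", ncol(x$genotypes$dosage), "SNPs")
  cat("\n")
  invisible(x)
}

# upper-triangular factor tolerant of PSD (zero-variance) components
chol_psd <- function(S) {
  r <- try(chol(S), silent = TRUE)
  if (!inherits(r, "try-error")) return(r)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  t(e$vectors %*% diag(sqrt(vals), nrow(S)))
}

#' Desk-scale study preset
#'
#' One call producing pedigree, genotypes and a single additive trait with
#' the factorial-cross family structure: a scaled-down version of a
#' 831-family trout cohort. Intended for examples and method checks.
#'
#' @param n_offspring approximate number of phenotyped offspring.
#' @param n_snps number of SNPs.
#' @param n_chr number of chromosomes.
#' @param h2 heritability of the simulated trait.
#' @param qtl_frac total fraction of additive variance carried by planted
#'   marker QTLs (0 = fully pedigree-polygenic trait).
#' @param n_qtl number of planted QTLs sharing `qtl_frac` equally. One QTL
#'   gives a mappable major locus; several hundred give the marker-linked
#'   polygenic architecture under which genomic prediction is the correctly
#'   specified model.
#' @param seed integer seed.
#' @return A `sim_result` restricted to a single trait.
#' @export
sim_study <- function(n_offspring = 1000, n_snps = 2000, n_chr = 5,
                      h2 = 0.25, qtl_frac = 0, n_qtl = 1, seed = 1L) {
  n_fam <- max(10L, round(n_offspring / 1.7))
  n_d <- max(4L, round(n_fam / 10))
  n_s <- max(4L, round(n_fam / 8.4))
  n_fam <- min(n_fam, n_d * n_s)
  # as many cross blocks as the within-block grids can support
  n_crosses <- max(1L, min(10L, n_d, n_s, (n_d * n_s) %/% n_fam))
  des <- breeding_design(n_dams = n_d, n_sires = n_s, n_families = n_fam,
                         offspring_per_family = n_offspring / n_fam,
                         n_crosses = n_crosses)
  ped <- sim_pedigree(des, seed = seed)
  gen <- sim_genotypes(ped, n_snps = n_snps, n_chr = n_chr,
                       seed = seed + 1L)
  qtls <- NULL
  if (qtl_frac > 0) {
    if (n_qtl == 1) {
      qtls <- data.frame(chr = "chr1", pos = 2.5e7, trait = 1,
                         frac = qtl_frac)
    } else {
      set.seed(seed + 3L)
      poly <- which(apply(gen$dosage, 2, stats::var) > 0)
      pick <- sort(sample(poly, min(n_qtl, length(poly))))
      qtls <- data.frame(chr = gen$map$chr[pick], pos = gen$map$pos[pick],
                         trait = 1, frac = qtl_frac / length(pick))
    }
  }
  tm <- trait_model(h2 = h2, means = 20, sds = 2, qtls = qtls,
                    names = "trait1")
  sim_phenotypes(ped, tm, genotypes = gen, seed = seed + 2L)
}
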