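test_that("factorial-cross pedigree matches the design counts", {
  des <- breeding_design()  # 84 x 99, 831 families, ~1.7 offspring/family
  ped <- sim_pedigree(des, seed = 1)
  founders <- sum(is.na(ped$sire) & is.na(ped$dam))
  expect_equal(founders, 84 + 99)
  n_off <- sum(!is.na(ped$sire))
  expect_equal(n_off, round(1.7 * 831))           # ~1,410 offspring
  expect_equal(length(unique(ped$family[!is.na(ped$family)])) <= 831, TRUE)
})

test_that("degenerate single-family cross gives one full-sib pair", {
  ped <- sim_pedigree(breeding_design(1, 1, 1, 2, n_crosses = 1), seed = 1)
  expect_equal(nrow(ped), 4)
  off <- ped[!is.na(ped$sire), ]
  expect_equal(nrow(off), 2)
  expect_equal(off$sire[1], off$sire[2])
  expect_equal(off$dam[1], off$dam[2])
})

test_that("offspring-per-dam tallies reconcile with sampled family sizes", {
  des <- breeding_design(12, 15, 40, 2.3, n_crosses = 2)
  ped <- sim_pedigree(des, seed = 7)
  off <- ped[!is.na(ped$sire), ]
  # brute-force recount: per-dam totals equal the summed sizes of that
  # dam's families
  fam_size <- table(off$family)
  fam_dam <- tapply(off$dam, off$family, function(d) unique(d))
  expect_true(all(lengths(tapply(off$dam, off$family, unique)) == 1))
  per_dam_from_fams <- tapply(as.integer(fam_size), unlist(fam_dam), sum)
  per_dam_direct <- table(off$dam)
  expect_equal(as.integer(per_dam_from_fams[names(per_dam_direct)]),
               as.integer(per_dam_direct))
})

test_that("infeasible designs are rejected with an explanation", {
  expect_error(breeding_design(2, 2, 5), "infeasible")
  expect_error(sim_pedigree(breeding_design(10, 10, 90, n_crosses = 5)),
               "infeasible")
})

test_that("gene dropping is Mendelian-consistent and deterministic", {
  ped <- pedigree(
    id = c("s", "d", "o1", "o2", "g1"),
    sire = c(NA, NA, "s", "s", "o1"),
    dam = c(NA, NA, "d", "d", "o2"),
    generation = c(0, 0, 1, 1, 2))
  g <- sim_genotypes(ped, n_snps = 400, n_chr = 2, seed = 3)
  d <- g$dosage
  # exhaustive check: child dosage compatible with parental dosages
  compatible <- function(child, p1, p2) {
    half <- function(p) switch(as.character(p), "0" = 0, "2" = 1, c(0, 1))
    child %in% outer(half(p1), half(p2), `+`)
  }
  for (i in which(!is.na(ped$sire))) {
    ok <- vapply(seq_len(ncol(d)), function(j) {
      compatible(d[ped$id[i], j], d[ped$sire[i], j], d[ped$dam[i], j])
    }, logical(1))
    expect_true(all(ok))
  }
  # homozygous-opposite parents always give heterozygous offspring
  fixed <- d["s", ] + d["d", ] == 2 & d["s", ] != 1
  expect_true(all(d["o1", fixed] == 1))
  # determinism
  g2 <- sim_genotypes(ped, n_snps = 400, n_chr = 2, seed = 3)
  expect_identical(g$dosage, g2$dosage)
  expect_identical(g$map, g2$map)
})

test_that("founder minor allele frequencies respect the requested range", {
  founders <- pedigree(id = sprintf("f%04d", 1:2000),
                       sire = rep(NA_character_, 2000),
                       dam = rep(NA_character_, 2000),
                       generation = rep(0, 2000))
  g <- sim_genotypes(founders, n_snps = 2000, n_chr = 5,
                     maf_range = c(0.05, 0.5), seed = 5)
  p <- colMeans(g$dosage) / 2
  maf <- pmin(p, 1 - p)
  expect_gte(mean(maf > 0.05 & maf <= 0.5), 0.99)
})

test_that("missing-call injection matches the requested rate", {
  ped <- sim_pedigree(breeding_design(5, 5, 20, 4, n_crosses = 1), seed = 2)
  g0 <- sim_genotypes(ped, n_snps = 300, missing_rate = 0, seed = 2)
  expect_false(anyNA(g0$dosage))
  g1 <- sim_genotypes(ped, n_snps = 300, missing_rate = 0.1, seed = 2)
  expect_equal(mean(is.na(g1$dosage)), 0.1, tolerance = 0.1)
})

test_that("single known parents are rejected by the gene dropper", {
  ped <- pedigree(id = c("s", "o"), sire = c(NA, "s"), dam = c(NA, NA),
                  generation = c(0, 1))
  expect_error(sim_genotypes(ped, n_snps = 10), "one known parent")
})

test_that("trait model validation rejects invalid correlation structures", {
  bad <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3, 3)
  expect_error(trait_model(h2 = c(0.2, 0.2, 0.2), genetic_corr = bad),
               "positive semi-definite")
  expect_error(trait_model(h2 = 1.2), "h2")
  expect_error(trait_model(h2 = 0.3,
                           qtls = data.frame(chr = "chr1", pos = 1e6,
                                             trait = 1, frac = 1.2)),
               "sum to < 1")
})

test_that("simulated phenotypes realise the target genetic architecture", {
  # large cohort: realised h2 within +/-0.03, parent-offspring BV
  # covariance ~ Va/2, and bit-for-bit seed reproducibility
  des <- breeding_design(150, 150, 2000, 2.5, n_crosses = 1)
  ped <- sim_pedigree(des, seed = 9)
  tm <- trait_model(h2 = 0.25, means = 10, sds = 2)
  sim <- sim_phenotypes(ped, tm, seed = 9)
  off <- ped$id[!is.na(ped$sire)]
  h2_real <- var(sim$tbv[off, 1]) / var(sim$phenotypes[off, 1])
  expect_lt(abs(h2_real - 0.25), 0.03)
  offd <- ped[!is.na(ped$sire), ]
  # pooled parent-offspring pairs (both sires and dams)
  cov_po <- cov(c(sim$tbv[offd$sire, 1], sim$tbv[offd$dam, 1]),
                rep(sim$tbv[offd$id, 1], 2))
  Va <- var(sim$tbv[off, 1])
  expect_lt(abs(cov_po - Va / 2), 0.25 * Va / 2)
  sim2 <- sim_phenotypes(ped, tm, seed = 9)
  expect_identical(sim$phenotypes, sim2$phenotypes)
  expect_identical(sim$tbv, sim2$tbv)
})

test_that("a zero-heritability trait is independent of the pedigree", {
  ped <- sim_pedigree(breeding_design(20, 20, 100, 3, n_crosses = 1),
                      seed = 4)
  tm <- trait_model(h2 = 0, means = 5, sds = 1)
  sim <- sim_phenotypes(ped, tm, seed = 4)
  expect_true(all(sim$tbv == 0))
  off <- ped[!is.na(ped$sire), ]
  # full-sib phenotypic correlation ~ 0
  sibs <- split(off$id, off$family)
  sibs <- sibs[lengths(sibs) >= 2]
  pairs <- t(vapply(sibs, function(s) s[1:2], character(2)))
  r <- cor(sim$phenotypes[pairs[, 1], 1], sim$phenotypes[pairs[, 2], 1])
  expect_lt(abs(r), 0.25)
})

test_that("a planted QTL contributes its stated variance fraction", {
  sim <- sim_study(n_offspring = 800, n_snps = 500, h2 = 0.3,
                   qtl_frac = 0.05, seed = 21)
  j <- which(sim$qtl_effects[, 1] != 0)
  expect_length(j, 1)
  z <- sim$genotypes$dosage[, j]
  contrib <- var((z - mean(z)) * sim$qtl_effects[j, 1])
  Va <- var(sim$tbv[, 1])
  expect_lt(abs(contrib / Va - 0.05), 0.015)
})

test_that("the fatty-acid preset is a valid 12-trait model", {
  tm <- fa_trait_model()
  expect_length(tm$h2, 12)
  expect_true(all(tm$h2 >= 0.03 - 1e-9 & tm$h2 <= 0.24 + 1e-9))
  ev <- eigen(tm$genetic_corr, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 0)
  # antagonistic saturated-vs-polyunsaturated block structure
  expect_lt(tm$genetic_corr[1, 3], 0)   # SFA vs PUFA
  expect_gt(tm$genetic_corr[1, 2], 0)   # SFA vs MUFA
})
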