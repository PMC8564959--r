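#' Pipeline configuration
#'
#' Flat configuration for [run_pipeline()]. Stage parameters default to the
#' study's analysis constants (QC thresholds 0.97 / 1e-4 / 0.05 / 0.90,
#' BayesCpi prior Beta(300, n_snps), 40 cross-validation replicates) at
#' desk-scale problem sizes. Stage seeds are derived from the global seed
#' as `seed + 1000 * stage_index` (simulate = 1, gwas = 5, predict = 6).
#'
#' @param out_dir output directory for stage artifacts.
#' @param seed global seed.
#' @param stages character vector of stages to run, in pipeline order:
#'   `simulate`, `qc`, `relmat`, `varcomp`, `gwas`, `predict`, `report`.
#' @param ... overrides for any default listed by `pipeline_config()`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("fishqg_run"), seed = 1L,
                            stages = c("simulate", "qc", "relmat",
                                       "varcomp", "gwas", "predict",
                                       "report"),
                            ...) {
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed), stages = stages,
    # simulate
    n_offspring = 500, n_snps = 1000, n_chr = 5, h2 = 0.25, qtl_frac = 0.1,
    missing_rate = 0.01,
    # qc
    snp_call_rate = 0.97, hwe_p = 1e-4, maf = 0.05,
    sample_call_rate = 0.90, impute_mode = "rounded_mean",
    # gwas
    n_cycles = 20000, burn_in = 2000, thin = 20, alpha = 300, beta = NULL,
    # predict
    n_replicates = 40, n_validation = NULL, blend_g = 0.01)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown pipeline_config fields: ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration (YAML)
#'
#' The on-disk representation round-trips losslessly.
#'
#' @param cfg a [pipeline_config()].
#' @param path YAML file path.
#' @return `path` (write) or the configuration (read).
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  do.call(pipeline_config, cfg)
}

stage_seed <- function(cfg, stage) {
  idx <- match(stage, c("simulate", "qc", "relmat", "varcomp", "gwas",
                        "predict", "report"))
  cfg$seed + 1000L * idx
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order: simulate (pedigree, genotypes,
#' phenotype), qc (SNP/sample filters + imputation), relmat (A and G),
#' varcomp (AI-REML heritability), gwas (BayesCpi + QTL calling), predict
#' (BLUP vs GBLUP cross-validation) and report (trait summary, QTL and
#' accuracy tables). Stage artifacts are written to `cfg$out_dir` as TSV /
#' PLINK-style text; the returned report carries parameter echoes, per-file
#' md5 digests, warnings (non-convergence, boundary estimates) and
#' runtimes. Positions are 1-based bp; reported Mb values are bp/1e6
#' rounded to 2 decimals.
#'
#' @param cfg a [pipeline_config()].
#' @return A list of class `run_report`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = unclass(cfg), stages = list())
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    files <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    report$stages[[name]] <<- list(
      files = files,
      digests = if (length(files)) tools::md5sum(files) else character(),
      runtime = proc.time()[["elapsed"]] - t0)
  }

  run_stage("simulate", function() {
    sim <- sim_study(n_offspring = cfg$n_offspring, n_snps = cfg$n_snps,
                     n_chr = cfg$n_chr, h2 = cfg$h2,
                     qtl_frac = cfg$qtl_frac,
                     seed = stage_seed(cfg, "simulate"))
    if (cfg$missing_rate > 0) {
      set.seed(stage_seed(cfg, "simulate") + 1L)
      d <- sim$genotypes$dosage
      d[runif(length(d)) < cfg$missing_rate] <- NA_real_
      sim$genotypes <- geno_matrix(d, sim$genotypes$map)
    }
    state$sim <- sim
    off <- sim$pedigree$id[!is.na(sim$pedigree$sire)]
    state$y <- sim$phenotypes[off, 1]
    f <- file.path(cfg$out_dir, c("pedigree.tsv", "phenotypes.tsv"))
    write_pedigree(sim$pedigree, f[1])
    write_phenotypes(sim$phenotypes, f[2])
    pl <- write_plink(sim$genotypes, file.path(cfg$out_dir, "genotypes"),
                      ped = sim$pedigree)
    c(f, pl)
  })

  run_stage("qc", function() {
    qc <- run_qc(state$sim$genotypes, snp_call_rate = cfg$snp_call_rate,
                 hwe_p = cfg$hwe_p, maf = cfg$maf,
                 sample_call_rate = cfg$sample_call_rate)
    state$geno <- impute_missing(qc$genotypes, mode = cfg$impute_mode,
                                 ped = state$sim$pedigree)
    state$qc_report <- qc$report
    f <- file.path(cfg$out_dir, "qc_report.tsv")
    rep <- qc$report
    utils::write.table(
      data.frame(filter = c("excluded", names(rep$snps_removed)[-1],
                            "sample_call_rate"),
                 removed = c(rep$snps_removed, rep$samples_removed)),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  })

  run_stage("relmat", function() {
    state$A <- pedigree_A(state$sim$pedigree)
    state$G <- genomic_G(state$geno)
    f <- file.path(cfg$out_dir, c("A.tsv", "G.tsv"))
    write_relmat(state$A, f[1])
    write_relmat(state$G, f[2])
    f
  })

  run_stage("varcomp", function() {
    state$vc_A <- reml_animal(state$y, state$A)
    state$vc_G <- reml_animal(state$y, blend_relmat(state$G, cfg$blend_g))
    if (!state$vc_A$converged || state$vc_A$boundary) {
      report$warnings <<- c(report$warnings,
                            "pedigree variance components at boundary or unconverged")
    }
    f <- file.path(cfg$out_dir, "varcomp.tsv")
    utils::write.table(
      data.frame(kinship = c("A", "G"),
                 Va = c(state$vc_A$Va, state$vc_G$Va),
                 Ve = c(state$vc_A$Ve, state$vc_G$Ve),
                 h2 = c(state$vc_A$h2, state$vc_G$h2),
                 se_h2 = c(state$vc_A$se_h2, state$vc_G$se_h2),
                 converged = c(state$vc_A$converged, state$vc_G$converged)),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  })

  run_stage("gwas", function() {
    fit <- bayescpi(state$geno, state$y, n_cycles = cfg$n_cycles,
                    burn_in = cfg$burn_in, thin = cfg$thin,
                    alpha = cfg$alpha, beta = cfg$beta,
                    seed = stage_seed(cfg, "gwas"))
    state$gwas <- fit
    state$qtls <- call_qtls(fit, trait = colnames(state$sim$phenotypes)[1])
    f <- file.path(cfg$out_dir, c("gwas_snps.tsv", "qtls.tsv"))
    utils::write.table(fit$snp, f[1], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(as.data.frame(state$qtls), f[2], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    f
  })

  run_stage("predict", function() {
    n_val <- cfg$n_validation
    if (is.null(n_val)) n_val <- max(2L, round(length(state$y) * 314 / 1382))
    cv <- cross_validate(state$y, A = state$A, G = state$G,
                         n_replicates = cfg$n_replicates,
                         n_validation = n_val,
                         varcomp_A = state$vc_A, varcomp_G = state$vc_G,
                         blend_g = cfg$blend_g,
                         seed = stage_seed(cfg, "predict"))
    state$cv <- cv
    f <- file.path(cfg$out_dir, c("cv_replicates.tsv", "cv_summary.tsv"))
    utils::write.table(cv$replicates, f[1], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(cv$summary, f[2], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f
  })

  run_stage("report", function() {
    f <- file.path(cfg$out_dir, "trait_summary.tsv")
    ts <- trait_summary(state$sim$phenotypes)
    ts[, c("mean", "sd", "cv")] <- round(ts[, c("mean", "sd", "cv")], 2)
    utils::write.table(ts, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  })

  report$results <- list(
    varcomp_A = state$vc_A, varcomp_G = state$vc_G,
    qtls = state$qtls, cv = state$cv, qc = state$qc_report)
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run:", length(x$stages), "stage(s) in '",
      x$config$out_dir, "'\n", sep = "")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-9s %5.1fs  %s\n", nm, st$runtime,
                paste(basename(st$files), collapse = ", ")))
  }
  if (!is.null(x$warnings)) {
    cat("warnings:\n"); for (w in x$warnings) cat("  -", w, "\n")
  }
  invisible(x)
}
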