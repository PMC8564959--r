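#' Write genotypes as PLINK-style text (.ped/.map)
#'
#' Alleles are coded `A` (reference) and `B` (alternate); dosage is the
#' count of `B`. Missing calls are written `0 0`. The .map file has the
#' standard four columns (chromosome, SNP id, genetic position set to 0,
#' bp position).
#'
#' @param g a [geno_matrix()].
#' @param prefix output path prefix; `<prefix>.ped` and `<prefix>.map` are
#'   written.
#' @param ped optional [pedigree()] supplying sire/dam columns; unknown
#'   parents are written `0`.
#' @return The two file paths, invisibly.
#' @export
write_plink <- function(g, prefix, ped = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  map <- data.frame(chr = g$map$chr, snp = g$map$snp, cm = 0,
                    pos = g$map$pos)
  map_path <- paste0(prefix, ".map")
  utils::write.table(map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  d <- g$dosage
  ids <- rownames(d)
  sire <- dam <- rep("0", length(ids))
  if (!is.null(ped)) {
    i <- match(ids, ped$id)
    sire <- ifelse(is.na(ped$sire[i]), "0", ped$sire[i])
    dam <- ifelse(is.na(ped$dam[i]), "0", ped$dam[i])
  }
  a1 <- matrix("A", nrow(d), ncol(d))
  a2 <- matrix("A", nrow(d), ncol(d))
  a1[d >= 1] <- "B"
  a2[d == 2] <- "B"
  a1[is.na(d)] <- "0"
  a2[is.na(d)] <- "0"
  geno_cols <- matrix("", nrow(d), 2 * ncol(d))
  geno_cols[, seq(1, 2 * ncol(d), 2)] <- a1
  geno_cols[, seq(2, 2 * ncol(d), 2)] <- a2
  lines <- paste(ids, ids, sire, dam, "0", "-9",
                 apply(geno_cols, 1, paste, collapse = " "))
  ped_path <- paste0(prefix, ".ped")
  writeLines(lines, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read PLINK-style text genotypes
#'
#' Inverse of [write_plink()]: dosage is the count of the `B` allele;
#' `0 0` becomes missing.
#'
#' @param prefix path prefix of `<prefix>.ped` and `<prefix>.map`.
#' @return A [geno_matrix()].
#' @export
read_plink <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"), sep = "\t",
                           col.names = c("chr", "snp", "cm", "pos"),
                           stringsAsFactors = FALSE)
  lines <- readLines(paste0(prefix, ".ped"))
  parts <- strsplit(lines, " ", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 2)
  m <- nrow(map)
  dos <- matrix(NA_real_, length(ids), m,
                dimnames = list(ids, map$snp))
  for (r in seq_along(parts)) {
    al <- parts[[r]][-(1:6)]
    a1 <- al[seq(1, 2 * m, 2)]
    a2 <- al[seq(2, 2 * m, 2)]
    val <- (a1 == "B") + (a2 == "B")
    val[a1 == "0" | a2 == "0"] <- NA_real_
    dos[r, ] <- val
  }
  geno_matrix(dos, map[, c("snp", "chr", "pos")])
}

#' Write / read a pedigree as TSV
#'
#' Columns: id, sire, dam, generation and (if present) family; unknown
#' parents are written as `NA`.
#'
#' @param ped a [pedigree()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.table(as.data.frame(ped), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE,
                         colClasses = "character")
  pedigree(d$id, d$sire, d$dam, as.integer(d$generation),
           family = if ("family" %in% names(d)) d$family)
}

#' Write / read a phenotype table as TSV
#'
#' First column `id`, one column per trait.
#'
#' @param phenotypes matrix or data frame with individual ids as rownames.
#' @param path output file.
#' @return `path` (write) or a numeric matrix (read).
#' @export
write_phenotypes <- function(phenotypes, path) {
  d <- data.frame(id = rownames(phenotypes), phenotypes,
                  check.names = FALSE, row.names = NULL)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- as.character(d$id)
  m
}

#' Write a relationship matrix as TSV
#'
#' @param K a `relmat`.
#' @param path output file.
#' @param format `"full"` (square table with ids) or `"triplet"` (row id,
#'   column id, value; lower triangle including diagonal).
#' @return `path`, invisibly.
#' @export
write_relmat <- function(K, path, format = c("full", "triplet")) {
  format <- match.arg(format)
  if (format == "full") {
    d <- data.frame(id = rownames(K), unclass(K), check.names = FALSE)
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    lt <- which(lower.tri(K, diag = TRUE), arr.ind = TRUE)
    d <- data.frame(row = rownames(K)[lt[, 1]],
                    col = colnames(K)[lt[, 2]],
                    value = K[lt])
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Trait summary table
#'
#' Per-trait N, mean, SD, min, max and coefficient of variation
#' (CV = SD/mean x 100).
#'
#' @param phenotypes matrix or data frame, individuals x traits.
#' @return Data frame with one row per trait.
#' @export
trait_summary <- function(phenotypes) {
  m <- as.matrix(phenotypes)
  out <- data.frame(
    trait = colnames(m),
    n = colSums(!is.na(m)),
    mean = colMeans(m, na.rm = TRUE),
    sd = apply(m, 2, stats::sd, na.rm = TRUE),
    min = apply(m, 2, min, na.rm = TRUE),
    max = apply(m, 2, max, na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE)
  out$cv <- out$sd / out$mean * 100
  out
}
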