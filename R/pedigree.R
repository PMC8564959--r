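#' Pedigree container
#'
#' A pedigree is a data frame with columns `id`, `sire`, `dam`,
#' `generation` and optionally `family`. Unknown parents are coded `NA`.
#' Records must be topologically ordered (parents before offspring); the
#' constructor reorders by generation and verifies acyclicity.
#'
#' @param id character or integer vector of unique individual ids.
#' @param sire,dam parent ids; `NA` for unknown. Parents must either both be
#'   known or both unknown for genotype simulation, but the container itself
#'   allows single unknowns (treated as unrelated founders in the A matrix).
#' @param generation integer generation label, 0 for founders.
#' @param family optional family label for full-sib groups.
#' @return An object of class `pedigree` (a data frame).
#' @examples
#' ped <- pedigree(id = c("s1", "d1", "o1"),
#'                 sire = c(NA, NA, "s1"),
#'                 dam = c(NA, NA, "d1"),
#'                 generation = c(0, 0, 1))
#' @export
pedigree <- function(id, sire, dam, generation = NULL, family = NULL) {
  id <- as.character(id)
  sire <- as.character(sire)
  dam <- as.character(dam)
  if (anyDuplicated(id)) {
    stop("duplicated ids in pedigree: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  known <- function(p) !is.na(p)
  for (p in c(sire[known(sire)], dam[known(dam)])) {
    if (!p %in% id) stop("parent '", p, "' has no pedigree record")
  }
  if (is.null(generation)) generation <- infer_generations(id, sire, dam)
  ped <- data.frame(id = id, sire = sire, dam = dam,
                    generation = as.integer(generation),
                    stringsAsFactors = FALSE)
  if (!is.null(family)) ped$family <- as.character(family)
  ped <- ped[order(ped$generation), , drop = FALSE]
  rownames(ped) <- NULL
  check_acyclic(ped)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree:", nrow(x), "individuals,",
      sum(is.na(x$sire) & is.na(x$dam)), "founders,",
      max(x$generation) + 1L, "generation(s)\n")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

# longest-path generation labels; errors on cycles
infer_generations <- function(id, sire, dam) {
  idx <- seq_along(id)
  names(idx) <- id
  gen <- rep(NA_integer_, length(id))
  visiting <- logical(length(id))
  visit <- function(i) {
    if (!is.na(gen[i])) return(gen[i])
    if (visiting[i]) stop("pedigree cycle detected at id '", id[i], "'")
    visiting[i] <<- TRUE
    gs <- if (is.na(sire[i])) -1L else visit(idx[[sire[i]]])
    gd <- if (is.na(dam[i])) -1L else visit(idx[[dam[i]]])
    visiting[i] <<- FALSE
    gen[i] <<- max(gs, gd) + 1L
    gen[i]
  }
  for (i in idx) visit(i)
  gen
}

check_acyclic <- function(ped) {
  pos <- seq_len(nrow(ped))
  names(pos) <- ped$id
  for (i in pos) {
    for (p in c(ped$sire[i], ped$dam[i])) {
      if (!is.na(p) && pos[[p]] >= i) {
        stop("pedigree cycle or ordering violation between '",
             ped$id[i], "' and its parent '", p, "'")
      }
    }
  }
  invisible(TRUE)
}

#' @export
summary.pedigree <- function(object, ...) {
  tab <- table(object$generation)
  cat("Pedigree with", nrow(object), "individuals\n")
  cat("Individuals per generation:\n")
  print(tab)
  invisible(tab)
}

is_founder <- function(ped) is.na(ped$sire) & is.na(ped$dam)
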