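#' Diploid multiallelic genotype table
#'
#' The central data container of the package: unordered diploid calls for a set
#' of individuals at a set of codominant multiallelic loci (microsatellites),
#' together with a population label and an ecotype label per individual.
#' Allele codes are opaque positive integers (typically fragment sizes); no
#' size binning is performed. Missingness is per individual-locus: both gene
#' copies are missing together.
#'
#' @param ids Character vector of unique individual labels.
#' @param loci Character vector of unique locus names.
#' @param a1,a2 Integer matrices (individuals x loci) holding the two allele
#'   codes of each call; `NA` in both marks a missing call. The pair is
#'   unordered; the constructor stores `pmin`/`pmax` so equal genotypes
#'   compare equal.
#' @param pop Character vector, one population label per individual.
#' @param ecotype Character vector per individual, each one of `"savanna"`,
#'   `"forest"`, `"unknown"`. Defaults to `"unknown"`.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(ids, loci, a1, a2, pop,
                           ecotype = rep("unknown", length(ids))) {
  ids <- as.character(ids)
  loci <- as.character(loci)
  if (anyDuplicated(ids)) stop("individual ids must be unique")
  if (anyDuplicated(loci)) stop("locus names must be unique")
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  n <- length(ids); L <- length(loci)
  if (!all(dim(a1) == c(n, L)) || !all(dim(a2) == c(n, L)))
    stop("allele matrices must be individuals x loci")
  if (xor_any(is.na(a1), is.na(a2)))
    stop("half-missing calls: both gene copies must be missing together")
  if (any(a1 <= 0L, na.rm = TRUE) || any(a2 <= 0L, na.rm = TRUE))
    stop("allele codes must be positive integers")
  if (length(pop) != n) stop("one population label per individual required")
  ecotype <- as.character(ecotype)
  bad <- setdiff(unique(ecotype), c("savanna", "forest", "unknown"))
  if (length(bad))
    stop("unknown ecotype token(s): ", paste(bad, collapse = ", "),
         " (allowed: savanna, forest, unknown)")
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  dimnames(lo) <- dimnames(hi) <- list(ids, loci)
  structure(list(ids = ids, loci = loci, a1 = lo, a2 = hi,
                 pop = as.character(pop), ecotype = ecotype),
            class = "genotype_table")
}

xor_any <- function(x, y) any(xor(x, y))

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals x %d loci\n",
              length(x$ids), length(x$loci)))
  cat(sprintf("  populations: %s\n",
              paste(unique(x$pop), collapse = ", ")))
  et <- table(factor(x$ecotype, c("savanna", "forest", "unknown")))
  cat(sprintf("  ecotypes: savanna %d, forest %d, unknown %d\n",
              et[["savanna"]], et[["forest"]], et[["unknown"]]))
  miss <- mean(is.na(x$a1))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
summary.genotype_table <- function(object, ...) {
  nall <- vapply(seq_along(object$loci), function(l) {
    length(unique(stats::na.omit(c(object$a1[, l], object$a2[, l]))))
  }, integer(1))
  data.frame(locus = object$loci,
             n_alleles = nall,
             missing = colSums(is.na(object$a1)),
             row.names = NULL)
}

#' Subset a genotype table by individuals and/or loci
#'
#' @param gt A `genotype_table`.
#' @param individuals Indices or ids of individuals to keep (default all).
#' @param loci Indices or names of loci to keep (default all).
#' @return A `genotype_table`.
#' @export
gt_subset <- function(gt, individuals = NULL, loci = NULL) {
  i <- if (is.null(individuals)) seq_along(gt$ids)
       else if (is.character(individuals)) match(individuals, gt$ids)
       else individuals
  l <- if (is.null(loci)) seq_along(gt$loci)
       else if (is.character(loci)) match(loci, gt$loci)
       else loci
  if (anyNA(i)) stop("unknown individual id(s)")
  if (anyNA(l)) stop("unknown locus name(s)")
  genotype_table(gt$ids[i], gt$loci[l],
                 gt$a1[i, l, drop = FALSE], gt$a2[i, l, drop = FALSE],
                 gt$pop[i], gt$ecotype[i])
}

#' Combine genotype tables sharing the same loci
#'
#' @param ... `genotype_table` objects with identical locus vectors.
#' @return A `genotype_table` stacking all individuals.
#' @export
gt_rbind <- function(...) {
  gts <- list(...)
  if (length(gts) == 1 && is.list(gts[[1]]) &&
      !inherits(gts[[1]], "genotype_table")) gts <- gts[[1]]
  loci <- gts[[1]]$loci
  for (g in gts) if (!identical(g$loci, loci)) stop("loci differ across tables")
  ids <- unlist(lapply(gts, `[[`, "ids"))
  if (anyDuplicated(ids)) {
    # suffix rule: duplicated ids get .2, .3, ... in order of appearance
    ids <- make.unique(ids, sep = ".")
  }
  genotype_table(ids, loci,
                 do.call(rbind, lapply(gts, `[[`, "a1")),
                 do.call(rbind, lapply(gts, `[[`, "a2")),
                 unlist(lapply(gts, `[[`, "pop")),
                 unlist(lapply(gts, `[[`, "ecotype")))
}
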