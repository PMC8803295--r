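#' Per-group, per-locus allele frequencies
#'
#' Counts alleles within groups of individuals (complete-case per locus) and
#' returns relative frequencies together with the number of non-missing gene
#' copies used. Group-locus cells with no data are left undefined (`NULL`),
#' never zero-filled.
#'
#' @param gt A [genotype_table()].
#' @param grouping `"population"`, `"ecotype"`, or a vector of group labels,
#'   one per individual.
#' @return An `allele_freq_table`: list with `groups`, `loci`, `freq` (nested
#'   list `freq[[group]][[locus]]` of named frequency vectors summing to 1),
#'   and `gene_copies` (groups x loci integer matrix).
#' @export
allele_frequencies <- function(gt, grouping = "population") {
  g <- resolve_grouping(gt, grouping)
  groups <- unique(g)
  for (grp in groups) if (!any(g == grp)) stop("empty group: ", grp)
  L <- length(gt$loci)
  freq <- stats::setNames(vector("list", length(groups)), groups)
  gc <- matrix(0L, length(groups), L, dimnames = list(groups, gt$loci))
  for (k in seq_along(groups)) {
    idx <- which(g == groups[k])
    per_locus <- stats::setNames(vector("list", L), gt$loci)
    for (l in seq_len(L)) {
      alleles <- c(gt$a1[idx, l], gt$a2[idx, l])
      alleles <- alleles[!is.na(alleles)]
      gc[k, l] <- length(alleles)
      if (length(alleles)) {
        tab <- table(alleles)
        per_locus[[l]] <- stats::setNames(as.numeric(tab) / length(alleles),
                                          names(tab))
      }
    }
    freq[[k]] <- per_locus
  }
  structure(list(groups = groups, loci = gt$loci, freq = freq,
                 gene_copies = gc),
            class = "allele_freq_table")
}

resolve_grouping <- function(gt, grouping) {
  if (is.character(grouping) && length(grouping) == 1) {
    switch(grouping,
           population = gt$pop,
           ecotype = gt$ecotype,
           stop("grouping must be 'population', 'ecotype', or a label vector"))
  } else {
    if (length(grouping) != length(gt$ids))
      stop("grouping vector must have one label per individual")
    as.character(grouping)
  }
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat(sprintf("allele_freq_table: %d group(s) x %d loci\n",
              length(x$groups), length(x$loci)))
  invisible(x)
}

#' Extract the per-locus frequency list of one group
#'
#' @param ft An `allele_freq_table`.
#' @param group Group label.
#' @return Named list (by locus) of named frequency vectors; undefined loci
#'   are `NULL`.
#' @export
freq_slice <- function(ft, group) {
  if (!group %in% ft$groups) stop("unknown group: ", group)
  ft$freq[[group]]
}

#' Pool allele frequencies of several groups
#'
#' Gene-copy-weighted merge of group frequencies, equal to recomputing the
#' frequencies on the merged group.
#'
#' @param ft An `allele_freq_table`.
#' @param groups Group labels to pool.
#' @param name Label of the pooled group.
#' @return An `allele_freq_table` with the single pooled group.
#' @export
pool_frequencies <- function(ft, groups, name = "pooled") {
  stopifnot(all(groups %in% ft$groups))
  L <- length(ft$loci)
  per_locus <- stats::setNames(vector("list", L), ft$loci)
  gc <- matrix(0L, 1, L, dimnames = list(name, ft$loci))
  for (l in seq_len(L)) {
    counts <- numeric()
    for (g in groups) {
      f <- ft$freq[[g]][[l]]
      if (is.null(f)) next
      cnt <- f * ft$gene_copies[g, l]
      for (a in names(cnt)) {
        cur <- if (a %in% names(counts)) counts[[a]] else 0
        counts[a] <- cur + cnt[[a]]
      }
    }
    gc[1, l] <- as.integer(round(sum(counts)))
    if (length(counts)) per_locus[[l]] <- counts / sum(counts)
  }
  structure(list(groups = name, loci = ft$loci,
                 freq = stats::setNames(list(per_locus), name),
                 gene_copies = gc),
            class = "allele_freq_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
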