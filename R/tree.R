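#' Nei's standard genetic distance between populations
#'
#' `D = -ln( Jxy / sqrt(Jx * Jy) )` with per-locus gene identities averaged
#' across loci before forming the ratio. With `bias_corrected = TRUE`
#' (default) the within-population identity uses the sample-size correction
#' `Jx = (2n * sum(p^2) - 1) / (2n - 1)`.
#'
#' @param gt A [genotype_table()].
#' @param bias_corrected Apply the small-sample correction to within-
#'   population identities.
#' @return Symmetric matrix of distances (attribute `infinite_pairs` lists
#'   pairs with no shared alleles anywhere, reported as `Inf`).
#' @export
nei_distance <- function(gt, bias_corrected = TRUE) {
  ft <- allele_frequencies(gt, "population")
  pops <- ft$groups
  k <- length(pops)
  if (k < 2) stop("need at least 2 populations")
  D <- matrix(0, k, k, dimnames = list(pops, pops))
  inf_pairs <- character()
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    jx <- jy <- jxy <- nl <- 0
    for (l in seq_along(ft$loci)) {
      fx <- ft$freq[[pops[i]]][[l]]; fy <- ft$freq[[pops[j]]][[l]]
      if (is.null(fx) || is.null(fy)) next
      jx_l <- sum(fx^2); jy_l <- sum(fy^2)
      if (bias_corrected) {
        cx <- ft$gene_copies[pops[i], l]; cy <- ft$gene_copies[pops[j], l]
        jx_l <- (cx * jx_l - 1) / (cx - 1)
        jy_l <- (cy * jy_l - 1) / (cy - 1)
      }
      shared <- intersect(names(fx), names(fy))
      jxy_l <- sum(fx[shared] * fy[shared])
      jx <- jx + jx_l; jy <- jy + jy_l; jxy <- jxy + jxy_l
      nl <- nl + 1
    }
    if (nl == 0) { D[i, j] <- D[j, i] <- NA_real_; next }
    if (jxy == 0) {
      D[i, j] <- D[j, i] <- Inf
      inf_pairs <- c(inf_pairs, paste(pops[i], pops[j], sep = ":"))
    } else {
      D[i, j] <- D[j, i] <- -log((jxy / nl) / sqrt((jx / nl) * (jy / nl)))
    }
  }
  attr(D, "infinite_pairs") <- inf_pairs
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via `ape::nj`). Negative branch lengths are
#' clamped to zero with the deficit transferred to the adjacent branch so
#' path lengths between tips are preserved as far as possible.
#'
#' @param d Symmetric distance matrix with labels (>= 3 taxa, finite).
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("need at least 3 labels")
  if (any(!is.finite(d)))
    stop("non-finite distances: prune the offending populations first")
  tr <- ape::nj(stats::as.dist(d))
  clamp_negative_edges(tr)
}

clamp_negative_edges <- function(tr) {
  repeat {
    neg <- which(tr$edge.length < 0)
    if (!length(neg)) break
    e <- neg[1]
    child <- tr$edge[e, 2]
    parent <- tr$edge[e, 1]
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    adj <- which(tr$edge[, 2] == parent)   # edge into the same internal node
    if (length(adj)) tr$edge.length[adj] <- tr$edge.length[adj] + deficit
    else {
      sib <- setdiff(which(tr$edge[, 1] == parent), e)
      if (length(sib)) tr$edge.length[sib[1]] <-
          max(tr$edge.length[sib[1]] + deficit, 0)
      else break
    }
    if (all(tr$edge.length >= 0)) break
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Locus-bootstrap support for the NJ population tree
#'
#' Resamples loci with replacement, recomputes the Nei distance and NJ tree,
#' and reports for each internal edge of the original tree the percentage of
#' replicates containing the same bipartition (as integer node labels).
#'
#' @param gt A [genotype_table()] (>= 2 loci).
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param bias_corrected Passed to [nei_distance()].
#' @param seed Optional seed.
#' @return The original NJ `phylo` tree with `node.label` holding percent
#'   support; attribute `n_effective` counts replicates with finite
#'   distances actually used.
#' @export
bootstrap_support <- function(gt, n_boot = 1000, bias_corrected = TRUE,
                              seed = NULL) {
  if (length(gt$loci) < 2) stop("bootstrap refused: single-locus data")
  stopifnot(n_boot >= 100)
  if (!is.null(seed)) set.seed(seed)
  d0 <- nei_distance(gt, bias_corrected)
  if (any(!is.finite(d0))) stop("non-finite distances in original data")
  tr0 <- nj_tree(d0)
  boots <- list()
  for (b in seq_len(n_boot)) {
    pick <- sample(length(gt$loci), replace = TRUE)
    gtb <- gt
    gtb$loci <- paste0("L", seq_along(pick))
    gtb$a1 <- gt$a1[, pick, drop = FALSE]
    gtb$a2 <- gt$a2[, pick, drop = FALSE]
    colnames(gtb$a1) <- colnames(gtb$a2) <- gtb$loci
    db <- nei_distance(gtb, bias_corrected)
    if (any(!is.finite(db))) next
    boots[[length(boots) + 1L]] <- nj_tree(db)
  }
  cnt <- ape::prop.clades(tr0, boots, rooted = FALSE)
  cnt[is.na(cnt)] <- 0
  tr0$node.label <- as.character(round(100 * cnt / length(boots)))
  attr(tr0, "n_effective") <- length(boots)
  tr0
}
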