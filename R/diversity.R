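#' Per-population diversity table
#'
#' Computes, per group: sample size N, mean number of alleles per locus (A),
#' allelic richness rarefied to g gene copies (A_R), mean observed
#' heterozygosity (H_O), mean unbiased expected heterozygosity (H_E, Nei's
#' small-sample correction 2n/(2n-1)), and the multi-locus Weir-Cockerham
#' inbreeding coefficient f (F_IS, ratio of sums over loci and alleles;
#' monomorphic loci contribute H = 0 and are excluded from F_IS).
#'
#' @param gt A [genotype_table()].
#' @param grouping `"population"`, `"ecotype"`, or a label vector.
#' @param g Rarefaction size in gene copies: `"auto"` (per-locus minimum of
#'   the non-missing gene-copy counts across the compared groups) or a fixed
#'   integer applied at every locus.
#' @param n_perm If > 0, runs [fis_permutation_test()] with this many
#'   permutations and appends `p_fis` and `holm_significant` columns.
#' @param seed Optional seed for the permutation test.
#' @return data.frame, one row per group, with attribute `rarefaction_g`
#'   recording the gene-copy size(s) used.
#' @export
diversity_table <- function(gt, grouping = "population", g = "auto",
                            n_perm = 0, seed = NULL) {
  grp <- resolve_grouping(gt, grouping)
  groups <- unique(grp)
  for (gname in groups)
    if (sum(grp == gname) < 2) stop("group smaller than 2: ", gname)
  L <- length(gt$loci)

  copies <- sapply(groups, function(gname) {
    idx <- grp == gname
    colSums(!is.na(gt$a1[idx, , drop = FALSE])) * 2L
  })  # L x G
  copies <- matrix(copies, nrow = L, dimnames = list(gt$loci, groups))
  if (identical(g, "auto")) {
    g_l <- apply(copies, 1, min)
  } else {
    g <- as.integer(g)
    if (any(copies < g)) stop("rarefaction size g exceeds available gene ",
                              "copies in some group x locus")
    g_l <- rep(g, L)
  }

  rows <- lapply(groups, function(gname) {
    idx <- which(grp == gname)
    a1 <- gt$a1[idx, , drop = FALSE]; a2 <- gt$a2[idx, , drop = FALSE]
    A <- ar <- ho <- he <- rep(NA_real_, L)
    for (l in seq_len(L)) {
      ok <- !is.na(a1[, l])
      if (!any(ok)) next
      al <- c(a1[ok, l], a2[ok, l])
      cnt <- table(al); Ncop <- length(al)
      A[l] <- length(cnt)
      # rarefied allele count at g_l[l] gene copies
      ar[l] <- sum(1 - exp(lchoose(Ncop - as.numeric(cnt), g_l[l]) -
                           lchoose(Ncop, g_l[l])))
      ho[l] <- mean(a1[ok, l] != a2[ok, l])
      p <- as.numeric(cnt) / Ncop
      he[l] <- Ncop / (Ncop - 1) * (1 - sum(p^2))
    }
    data.frame(population = gname, N = length(idx),
               A = mean(A, na.rm = TRUE), A_R = mean(ar, na.rm = TRUE),
               H_O = mean(ho, na.rm = TRUE), H_E = mean(he, na.rm = TRUE),
               F_IS = fis_wc(a1, a2))
  })
  out <- do.call(rbind, rows)
  if (n_perm > 0) {
    pt <- fis_permutation_test(gt, grouping, n_perm = n_perm, seed = seed)
    out$p_fis <- pt$p[match(out$population, pt$population)]
    out$holm_significant <- pt$holm_significant[match(out$population,
                                                      pt$population)]
  }
  attr(out, "rarefaction_g") <- g_l
  rownames(out) <- NULL
  out
}

# Weir-Cockerham within-population f, multi-locus ratio of sums.
# b = (n/(n-1)) [p(1-p) - (2n-1)/(4n) hbar], c = hbar/2, f = 1 - Sc/S(b+c).
fis_wc <- function(a1, a2) {
  num <- den <- 0
  for (l in seq_len(ncol(a1))) {
    ok <- !is.na(a1[, l])
    n <- sum(ok)
    if (n < 2) next
    al <- c(a1[ok, l], a2[ok, l])
    alleles <- unique(al)
    if (length(alleles) < 2) next       # monomorphic: excluded
    for (a in alleles) {
      p <- mean(al == a)
      hbar <- mean((a1[ok, l] == a) != (a2[ok, l] == a))
      b <- n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * hbar)
      cc <- hbar / 2
      num <- num + cc
      den <- den + b + cc
    }
  }
  if (den == 0) NA_real_ else 1 - num / den
}

#' Permutation test for heterozygote deficit (F_IS > 0)
#'
#' The null distribution is generated by permuting gene copies among
#' individuals within each group at every locus (destroying the association
#' between the two copies of an individual, hence any heterozygote deficit,
#' while keeping allele frequencies and missingness fixed). One-tailed p for
#' positive F_IS with the (n_greater + 1)/(n_perm + 1) estimator; Holm
#' (sequential Bonferroni) adjustment across groups.
#'
#' @inheritParams diversity_table
#' @param n_perm Number of permutations (>= 100).
#' @param alpha Significance level for the Holm decision column.
#' @return data.frame with columns `population`, `F_IS`, `p`, `p_holm`,
#'   `holm_significant`.
#' @export
fis_permutation_test <- function(gt, grouping = "population", n_perm = 1000,
                                 alpha = 0.05, seed = NULL) {
  stopifnot(n_perm >= 100)
  if (!is.null(seed)) set.seed(seed)
  grp <- resolve_grouping(gt, grouping)
  groups <- unique(grp)
  res <- lapply(groups, function(gname) {
    idx <- which(grp == gname)
    a1 <- gt$a1[idx, , drop = FALSE]; a2 <- gt$a2[idx, , drop = FALSE]
    obs <- fis_wc(a1, a2)
    if (is.na(obs))
      return(data.frame(population = gname, F_IS = NA_real_, p = NA_real_))
    ge <- 0L
    for (b in seq_len(n_perm)) {
      p1 <- a1; p2 <- a2
      for (l in seq_len(ncol(a1))) {
        ok <- which(!is.na(a1[, l]))
        if (length(ok) < 2) next
        copies <- sample(c(a1[ok, l], a2[ok, l]))
        p1[ok, l] <- copies[seq_along(ok)]
        p2[ok, l] <- copies[length(ok) + seq_along(ok)]
      }
      if (fis_wc(p1, p2) >= obs) ge <- ge + 1L
    }
    data.frame(population = gname, F_IS = obs,
               p = (ge + 1) / (n_perm + 1))
  })
  out <- do.call(rbind, res)
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out$holm_significant <- !is.na(out$p_holm) & out$p_holm < alpha
  out
}

#' Monte-Carlo null-allele check
#'
#' Simplified analog of the Micro-Checker homozygote-excess test: for each
#' group x locus, simulates `n_sim` Hardy-Weinberg datasets at the observed
#' allele frequencies and sample size and flags the locus when the observed
#' homozygote count strictly exceeds the 97.5th percentile of the simulated
#' counts. No size-stutter model and no null-allele frequency estimator are
#' included; the statistic is a QC gate only.
#'
#' @inheritParams diversity_table
#' @param n_sim Number of simulated datasets (>= 100).
#' @param seed Optional seed.
#' @return data.frame with columns `group`, `locus`, `n`, `obs_hom`,
#'   `sim_q975`, `excess` (observed minus simulated mean), `flagged`
#'   (NA for monomorphic, untestable loci).
#' @export
null_allele_check <- function(gt, grouping = "population", n_sim = 1000,
                              seed = NULL) {
  stopifnot(n_sim >= 100)
  if (!is.null(seed)) set.seed(seed)
  grp <- resolve_grouping(gt, grouping)
  groups <- unique(grp)
  out <- list()
  for (gname in groups) {
    idx <- which(grp == gname)
    for (l in seq_along(gt$loci)) {
      ok <- which(!is.na(gt$a1[idx, l]))
      n <- length(ok)
      row <- data.frame(group = gname, locus = gt$loci[l], n = n,
                        obs_hom = NA_integer_, sim_q975 = NA_real_,
                        excess = NA_real_, flagged = NA)
      if (n >= 2) {
        a1 <- gt$a1[idx[ok], l]; a2 <- gt$a2[idx[ok], l]
        al <- c(a1, a2)
        p <- table(al) / length(al)
        if (length(p) >= 2) {
          obs <- sum(a1 == a2)
          sims <- vapply(seq_len(n_sim), function(b) {
            x1 <- sample(names(p), n, replace = TRUE, prob = p)
            x2 <- sample(names(p), n, replace = TRUE, prob = p)
            sum(x1 == x2)
          }, numeric(1))
          q <- stats::quantile(sims, 0.975, names = FALSE)
          row$obs_hom <- obs
          row$sim_q975 <- q
          row$excess <- obs - mean(sims)
          row$flagged <- obs > q
        }
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}
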