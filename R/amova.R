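#' Hierarchical AMOVA (groups / populations / within)
#'
#' Method-of-moments variance components from allele-indicator sums of
#' squares at three levels: among groups (ecotypes), among populations within
#' groups, and among gene copies within populations. Per-locus components are
#' combined with weights proportional to typed gene copies, then the fixation
#' indices are formed: `F_CT = s2_a / total`, `F_SC = s2_b / (s2_b + s2_c)`,
#' `F_ST = (s2_a + s2_b) / total`. Components may be negative (method of
#' moments). Missing calls are excluded per locus.
#'
#' Permutation p-values: F_CT permutes whole populations among groups, F_SC
#' permutes individuals among populations within groups, F_ST permutes
#' individuals among populations; estimator `(n_greater + 1)/(n_perm + 1)`.
#'
#' @param gt A [genotype_table()].
#' @param group_of Either `"ecotype"` (default: each population's group is
#'   the ecotype of its members, which must be unambiguous) or a named
#'   character vector mapping population labels to group labels.
#' @param n_perm Number of permutations for p-values (0 = none).
#' @param seed Optional seed for the permutations.
#' @return An object of class `amova_result`: list with `components`
#'   (named s2_a, s2_b, s2_c), `F` (F_CT, F_SC, F_ST), `p` (permutation
#'   p-values or NA) and `design` (populations per group).
#' @export
hierarchical_amova <- function(gt, group_of = "ecotype", n_perm = 0,
                               seed = NULL) {
  pops <- gt$pop
  upops <- unique(pops)
  if (identical(group_of, "ecotype")) {
    group_of <- vapply(upops, function(p) {
      e <- unique(gt$ecotype[pops == p])
      e <- setdiff(e, "unknown")
      if (length(e) != 1)
        stop("population ", p, " has ambiguous ecotype; supply group_of")
      e
    }, "")
  }
  if (is.null(names(group_of)) || !all(upops %in% names(group_of)))
    stop("group_of must name every population")
  grp_ind <- unname(group_of[pops])
  one_group <- length(unique(grp_ind)) < 2   # degenerate: F_CT undefined

  obs <- amova_components(gt$a1, gt$a2, pops, grp_ind)
  if (all(abs(unlist(obs$comp)) < 1e-300))
    stop("monomorphic dataset: all variance components zero")
  Fobs <- amova_F(obs$comp)

  p <- c(F_CT = NA_real_, F_SC = NA_real_, F_ST = NA_real_)
  if (n_perm > 0 && !one_group) {
    if (!is.null(seed)) set.seed(seed)
    ge <- c(0L, 0L, 0L)
    for (b in seq_len(n_perm)) {
      # F_CT: permute whole populations among groups
      pg <- stats::setNames(sample(unname(group_of[upops])), upops)
      Fct <- amova_F(amova_components(gt$a1, gt$a2, pops,
                                      unname(pg[pops]))$comp)["F_CT"]
      # F_SC: permute individuals among populations within groups
      pop_sc <- pops
      for (gl in unique(grp_ind)) {
        i <- which(grp_ind == gl)
        pop_sc[i] <- sample(pops[i])
      }
      Fsc <- amova_F(amova_components(gt$a1, gt$a2, pop_sc,
                                      grp_ind)$comp)["F_SC"]
      # F_ST: permute individuals among populations (groups follow pops)
      ord <- sample(length(pops))
      pop_st <- pops[ord]
      Fst <- amova_F(amova_components(gt$a1, gt$a2, pop_st,
                                      unname(group_of[pop_st]))$comp)["F_ST"]
      ge <- ge + c(Fct >= Fobs["F_CT"], Fsc >= Fobs["F_SC"],
                   Fst >= Fobs["F_ST"])
    }
    p <- (ge + 1) / (n_perm + 1)
    names(p) <- c("F_CT", "F_SC", "F_ST")
  }
  structure(list(components = obs$comp, F = Fobs, p = p,
                 design = table(group = group_of)),
            class = "amova_result")
}

amova_F <- function(comp) {
  tot <- comp$s2_a + comp$s2_b + comp$s2_c
  c(F_CT = if (comp$df_a > 0) comp$s2_a / tot else NA_real_,
    F_SC = if (comp$df_b > 0) comp$s2_b / (comp$s2_b + comp$s2_c) else NA_real_,
    F_ST = (comp$s2_a + comp$s2_b) / tot)
}

# three-level nested ANOVA on gene-copy allele indicators, per locus,
# gene-copy-weighted combination across loci
amova_components <- function(a1, a2, pops, grps) {
  L <- ncol(a1)
  s2a <- s2b <- s2c <- w <- numeric(L)
  df_a_tot <- df_b_tot <- 0
  for (l in seq_len(L)) {
    ok <- which(!is.na(a1[, l]))
    if (length(ok) < 2) next
    al <- c(a1[ok, l], a2[ok, l])
    pp <- rep(pops[ok], 2); gg <- rep(grps[ok], 2)
    upop <- unique(pp); ugrp <- unique(gg)
    P <- length(upop); G <- length(ugrp)
    if (P < 2) next
    N <- length(al)
    n_p <- as.numeric(table(pp)[upop])
    n_g <- as.numeric(table(gg)[ugrp])
    pop_of_grp <- vapply(upop, function(p) gg[match(p, pp)], "")
    # nested design coefficients (unbalanced)
    sum_np2_by_g <- vapply(ugrp, function(g)
      sum(n_p[pop_of_grp == g]^2), numeric(1))
    n_prime <- (N - sum(sum_np2_by_g / n_g)) / max(P - G, 1)

    SSa <- SSb <- SSc <- 0
    for (a in unique(al)) {
      y <- as.numeric(al == a)
      ybar <- mean(y)
      y_p <- vapply(upop, function(p) mean(y[pp == p]), numeric(1))
      y_g <- vapply(ugrp, function(g) mean(y[gg == g]), numeric(1))
      SSa <- SSa + sum(n_g * (y_g - ybar)^2)
      SSb <- SSb + sum(n_p * (y_p - y_g[match(pop_of_grp, ugrp)])^2)
      SSc <- SSc + sum((y - y_p[match(pp, upop)])^2)
    }
    MSc <- SSc / (N - P)
    sc <- MSc
    if (P - G > 0) {
      MSb <- SSb / (P - G)
      sb <- (MSb - MSc) / n_prime
      df_b_tot <- df_b_tot + (P - G)
    } else sb <- 0
    if (G > 1) {
      n_dprime <- (sum(sum_np2_by_g / n_g) - sum(n_p^2) / N) / (G - 1)
      n_tprime <- (N - sum(n_g^2) / N) / (G - 1)
      MSa <- SSa / (G - 1)
      sa <- (MSa - MSc - n_dprime * sb) / n_tprime
      df_a_tot <- df_a_tot + (G - 1)
    } else sa <- 0
    s2a[l] <- sa; s2b[l] <- sb; s2c[l] <- sc
    w[l] <- N
  }
  if (sum(w) == 0) stop("no typed locus with at least two populations")
  wt <- w / sum(w)
  list(comp = list(s2_a = sum(wt * s2a), s2_b = sum(wt * s2b),
                   s2_c = sum(wt * s2c),
                   df_a = df_a_tot, df_b = df_b_tot))
}

#' @export
print.amova_result <- function(x, ...) {
  cat("hierarchical AMOVA\n")
  cat(sprintf("  s2 among groups        : %+.5f\n", x$components$s2_a))
  cat(sprintf("  s2 among pops in groups: %+.5f\n", x$components$s2_b))
  cat(sprintf("  s2 within populations  : %+.5f\n", x$components$s2_c))
  for (f in names(x$F))
    cat(sprintf("  %s = %.4f%s\n", f, x$F[[f]],
                if (!is.na(x$p[[f]])) sprintf(" (p = %.4g)", x$p[[f]]) else ""))
  invisible(x)
}

#' Pairwise Weir-Cockerham F_ST
#'
#' Weir-Cockerham theta for every population pair, multi-locus ratio of sums
#' over loci and alleles (the a, b, c variance components with the observed-
#' heterozygosity correction). Negative estimates are reported as computed
#' unless `truncate = TRUE`. P-values, when requested, permute individuals
#' between the two populations.
#'
#' @param gt A [genotype_table()].
#' @param n_perm Permutations per pair for one-tailed p (0 = none).
#' @param truncate Truncate negative estimates to 0.
#' @param seed Optional seed.
#' @return List with `theta` (symmetric matrix) and `p` (matrix or NULL).
#' @export
pairwise_fst <- function(gt, n_perm = 0, truncate = FALSE, seed = NULL) {
  pops <- unique(gt$pop)
  if (length(pops) < 2) stop("need at least 2 populations")
  if (any(table(gt$pop) < 2)) stop("each population needs >= 2 individuals")
  if (!is.null(seed)) set.seed(seed)
  k <- length(pops)
  th <- matrix(0, k, k, dimnames = list(pops, pops))
  pm <- if (n_perm > 0) matrix(NA_real_, k, k, dimnames = list(pops, pops))
        else NULL
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    idx <- which(gt$pop %in% c(pops[i], pops[j]))
    obs <- wc_theta(gt$a1[idx, , drop = FALSE], gt$a2[idx, , drop = FALSE],
                    gt$pop[idx])
    th[i, j] <- th[j, i] <- if (truncate) max(obs, 0) else obs
    if (n_perm > 0) {
      ge <- 0L
      for (b in seq_len(n_perm)) {
        perm <- sample(gt$pop[idx])
        if (wc_theta(gt$a1[idx, , drop = FALSE],
                     gt$a2[idx, , drop = FALSE], perm) >= obs) ge <- ge + 1L
      }
      pm[i, j] <- pm[j, i] <- (ge + 1) / (n_perm + 1)
    }
  }
  list(theta = th, p = pm)
}

#' Multi-population Weir-Cockerham theta
#'
#' @param a1,a2 Allele matrices (individuals x loci).
#' @param pops Population label per individual.
#' @return Scalar theta (NA when no locus is informative).
#' @export
wc_theta <- function(a1, a2, pops) {
  upop <- unique(pops)
  r <- length(upop)
  num <- den <- 0
  for (l in seq_len(ncol(a1))) {
    ok <- !is.na(a1[, l])
    pp <- pops[ok]
    ni <- as.numeric(table(factor(pp, upop)))
    if (sum(ni > 0) < 2) next
    keep <- ni > 0
    ni <- ni[keep]; pl <- upop[keep]
    x1 <- a1[ok, l]; x2 <- a2[ok, l]
    alleles <- unique(c(x1, x2))
    if (length(alleles) < 2) next
    nbar <- mean(ni)
    rr <- length(ni)
    nc <- (rr * nbar - sum(ni^2) / (rr * nbar)) / (rr - 1)
    for (a in alleles) {
      pi <- vapply(pl, function(p)
        mean(c(x1[pp == p], x2[pp == p]) == a), numeric(1))
      hi <- vapply(pl, function(p)
        mean((x1[pp == p] == a) != (x2[pp == p] == a)), numeric(1))
      pbar <- sum(ni * pi) / (rr * nbar)
      s2 <- sum(ni * (pi - pbar)^2) / ((rr - 1) * nbar)
      hbar <- sum(ni * hi) / (rr * nbar)
      A <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
             (pbar * (1 - pbar) - ((rr - 1) / rr) * s2 - hbar / 4))
      B <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
             ((rr - 1) / rr) * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
      C <- hbar / 2
      num <- num + A
      den <- den + A + B + C
    }
  }
  if (den == 0) NA_real_ else num / den
}

#' Among-population F_ST from the two-level gene-copy ANOVA
#'
#' The degenerate (single-group) form of the AMOVA estimator; used as the
#' cross-check that the hierarchical machinery collapses correctly.
#'
#' @inheritParams wc_theta
#' @return Scalar F_ST.
#' @export
global_theta <- function(a1, a2, pops) {
  L <- ncol(a1)
  s2b <- s2c <- w <- numeric(L)
  for (l in seq_len(L)) {
    ok <- which(!is.na(a1[, l]))
    if (length(ok) < 2) next
    al <- c(a1[ok, l], a2[ok, l])
    pp <- rep(pops[ok], 2)
    upop <- unique(pp)
    P <- length(upop)
    if (P < 2) next
    N <- length(al)
    n_p <- as.numeric(table(pp)[upop])
    n_prime <- (N - sum(n_p^2) / N) / (P - 1)
    SSb <- SSc <- 0
    for (a in unique(al)) {
      y <- as.numeric(al == a)
      y_p <- vapply(upop, function(p) mean(y[pp == p]), numeric(1))
      SSb <- SSb + sum(n_p * (y_p - mean(y))^2)
      SSc <- SSc + sum((y - y_p[match(pp, upop)])^2)
    }
    MSb <- SSb / (P - 1); MSc <- SSc / (N - P)
    s2b[l] <- (MSb - MSc) / n_prime
    s2c[l] <- MSc
    w[l] <- N
  }
  wt <- w / sum(w)
  sum(wt * s2b) / (sum(wt * s2b) + sum(wt * s2c))
}
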