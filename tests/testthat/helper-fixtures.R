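# fixtures are built in code; nothing is read from disk

# fully diagnostic parental pools: allele 1 fixed in A, allele 2 fixed in B
diagnostic_freqs <- function(L = 20) {
  loci <- sprintf("L%02d", seq_len(L))
  fa <- stats::setNames(rep(list(c("1" = 1)), L), loci)
  fb <- stats::setNames(rep(list(c("2" = 1)), L), loci)
  gc <- matrix(20000L, 2, L, dimnames = list(c("A", "B"), loci))
  structure(list(groups = c("A", "B"), loci = loci,
                 freq = list(A = fa, B = fb), gene_copies = gc),
            class = "allele_freq_table")
}

# genotype table where every individual has the same call at every locus
uniform_gt <- function(ids, L, a1, a2, pop = "p1") {
  genotype_table(ids, sprintf("L%02d", seq_len(L)),
                 matrix(a1, length(ids), L), matrix(a2, length(ids), L),
                 rep(pop, length(ids)))
}

# reference pure individuals on the diagnostic pools, for label anchoring
diagnostic_reference_gt <- function(L = 20, n_each = 5) {
  gt_rbind(uniform_gt(paste0("refA", seq_len(n_each)), L, 1L, 1L, "refA"),
           uniform_gt(paste0("refB", seq_len(n_each)), L, 2L, 2L, "refB"))
}

reference_labels <- function(n_each = 5) {
  stats::setNames(rep(c("P1", "P2"), each = n_each),
                  c(paste0("refA", seq_len(n_each)),
                    paste0("refB", seq_len(n_each))))
}

# random genotype table for round-trip tests
random_gt <- function(n_pops = 3, n_per_pop = 4, L = 11, missing_rate = 0.1,
                      seed = 42) {
  set.seed(seed)
  n <- n_pops * n_per_pop
  a1 <- matrix(sample(1:9, n * L, TRUE), n, L)
  a2 <- matrix(sample(1:9, n * L, TRUE), n, L)
  drop <- matrix(runif(n * L) < missing_rate, n, L)
  a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
  genotype_table(sprintf("ind%02d", seq_len(n)), sprintf("loc%02d", seq_len(L)),
                 a1, a2, rep(paste0("pop", seq_len(n_pops)), each = n_per_pop))
}

# independent brute-force oracle: nested indicator ANOVA written from the
# textbook formulas, one allele at a time, without reusing package internals
oracle_amova <- function(gt, grp_of_pop) {
  tot <- list(a = 0, b = 0, c = 0)
  wsum <- 0
  for (l in seq_along(gt$loci)) {
    ok <- which(!is.na(gt$a1[, l]))
    copies <- c(gt$a1[ok, l], gt$a2[ok, l])
    pops <- rep(gt$pop[ok], 2)
    grps <- unname(grp_of_pop[pops])
    N <- length(copies)
    upop <- unique(pops); ugrp <- unique(grps)
    P <- length(upop); G <- length(ugrp)
    n_p <- sapply(upop, function(p) sum(pops == p))
    n_g <- sapply(ugrp, function(g) sum(grps == g))
    gofp <- sapply(upop, function(p) grps[match(p, pops)])
    SSa <- SSb <- SSc <- 0
    for (a in unique(copies)) {
      y <- as.numeric(copies == a)
      gm <- mean(y)
      for (g in ugrp) SSa <- SSa + n_g[g] * (mean(y[grps == g]) - gm)^2
      for (p in upop) SSb <- SSb +
          n_p[p] * (mean(y[pops == p]) - mean(y[grps == gofp[p]]))^2
      for (p in upop) SSc <- SSc + sum((y[pops == p] - mean(y[pops == p]))^2)
    }
    MSc <- SSc / (N - P); MSb <- SSb / (P - G); MSa <- SSa / (G - 1)
    npr <- (N - sum(sapply(ugrp, function(g) sum(n_p[gofp == g]^2) / n_g[g]))) /
      (P - G)
    ndp <- (sum(sapply(ugrp, function(g) sum(n_p[gofp == g]^2) / n_g[g])) -
              sum(n_p^2) / N) / (G - 1)
    ntp <- (N - sum(n_g^2) / N) / (G - 1)
    sc <- MSc
    sb <- (MSb - MSc) / npr
    sa <- (MSa - MSc - ndp * sb) / ntp
    tot$a <- tot$a + N * sa; tot$b <- tot$b + N * sb; tot$c <- tot$c + N * sc
    wsum <- wsum + N
  }
  lapply(tot, function(x) unname(x) / wsum)
}
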