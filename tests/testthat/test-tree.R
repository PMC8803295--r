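test_that("Nei distance matches direct formula evaluation", {
  # two populations, two loci, frequencies chosen by hand
  mk <- function(f1, f2) list(L1 = f1, L2 = f2)
  pA <- mk(c("1" = 0.7, "2" = 0.3), c("1" = 0.5, "2" = 0.5))
  pB <- mk(c("1" = 0.2, "2" = 0.8), c("1" = 0.9, "2" = 0.1))
  # genotype table realizing those exact frequencies (10 individuals each):
  # lay out the 20 gene copies per population x locus, then pair them up
  copies <- function(p) rep(1:2, round(20 * c(p, 1 - p)))
  col_for <- function(pX, pY, half) c(copies(pX)[half], copies(pY)[half])
  h1 <- 1:10; h2 <- 11:20
  gt <- genotype_table(
    paste0("i", 1:20), c("L1", "L2"),
    cbind(col_for(0.7, 0.2, h1), col_for(0.5, 0.9, h1)),
    cbind(col_for(0.7, 0.2, h2), col_for(0.5, 0.9, h2)),
    rep(c("X", "Y"), each = 10))
  ftX <- allele_frequencies(gt)$freq[["X"]]
  expect_equal(ftX$L1, c("1" = 0.7, "2" = 0.3))
  d <- nei_distance(gt, bias_corrected = FALSE)
  jx <- mean(c(sum(pA$L1^2), sum(pA$L2^2)))
  jy <- mean(c(sum(pB$L1^2), sum(pB$L2^2)))
  jxy <- mean(c(sum(pA$L1 * pB$L1), sum(pA$L2 * pB$L2)))
  expect_equal(d["X", "Y"], -log(jxy / sqrt(jx * jy)), tolerance = 1e-12)
})

test_that("identical populations are at distance zero, disjoint at infinity", {
  gt <- gt_rbind(uniform_gt(paste0("a", 1:5), 2, 1L, 2L, "X"),
                 uniform_gt(paste0("b", 1:5), 2, 1L, 2L, "Y"))
  d <- nei_distance(gt, bias_corrected = FALSE)
  expect_equal(d["X", "Y"], 0, tolerance = 1e-12)
  gt2 <- gt_rbind(uniform_gt(paste0("a", 1:5), 2, 1L, 1L, "X"),
                  uniform_gt(paste0("b", 1:5), 2, 2L, 2L, "Y"))
  d2 <- nei_distance(gt2)
  expect_true(is.infinite(d2["X", "Y"]))
  expect_equal(attr(d2, "infinite_pairs"), "X:Y")
  expect_error(nj_tree(rbind(cbind(d2, X2 = 1), X2 = 1)), "prune")
})

test_that("three-taxon NJ solves the pairwise equations exactly", {
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  co <- ape::cophenetic.phylo(tr)
  expect_equal(co[rownames(d), colnames(d)], d, tolerance = 1e-9)
})

test_that("NJ recovers random additive metrics exactly", {
  set.seed(61)
  for (ntax in c(4, 5, 7)) {
    for (rep in 1:5) {
      tr0 <- ape::rtree(ntax, rooted = FALSE)
      tr0$edge.length <- stats::runif(nrow(tr0$edge), 0.2, 2)
      d <- ape::cophenetic.phylo(tr0)
      tr <- nj_tree(d)
      expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr0), tr)), 0)
      co <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
      expect_equal(co, d, tolerance = 1e-8)
    }
  }
})

test_that("equidistant taxa resolve deterministically", {
  d <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  t1 <- nj_tree(d); t2 <- nj_tree(d)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(all(t1$edge.length >= 0))
})

test_that("bootstrap support is 100 when loci are exact duplicates", {
  set.seed(62)
  base <- random_gt(n_pops = 4, n_per_pop = 6, L = 1, missing_rate = 0,
                    seed = 62)
  L <- 8
  gt <- base
  gt$loci <- paste0("L", 1:L)
  gt$a1 <- matrix(base$a1[, 1], length(base$ids), L)
  gt$a2 <- matrix(base$a2[, 1], length(base$ids), L)
  colnames(gt$a1) <- colnames(gt$a2) <- gt$loci
  tr <- bootstrap_support(gt, n_boot = 100, seed = 1)
  expect_true(all(as.numeric(tr$node.label) == 100))
  expect_error(bootstrap_support(base, n_boot = 100), "single-locus")
})

test_that("star-like data never reach high support", {
  set.seed(63)
  # four populations drawn from one common pool: no true structure
  n <- 48; L <- 6
  a1 <- matrix(sample(1:6, n * L, TRUE), n, L)
  a2 <- matrix(sample(1:6, n * L, TRUE), n, L)
  gt <- genotype_table(paste0("i", 1:n), paste0("L", 1:L), a1, a2,
                       rep(paste0("p", 1:4), each = 12))
  tr <- bootstrap_support(gt, n_boot = 200, seed = 2)
  # drop the root node: its trivial bipartition is present in every tree
  expect_true(all(as.numeric(tr$node.label[-1]) < 95))
})
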