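# closed-form oracle on fully diagnostic loci: with theta known, the
# likelihood of a genotype given class c is prod_l phi-term, so for an
# all-heterozygous individual posterior(F1) = 1 / (1 + 3 * (1/2)^L + (1/4)^L...)
# which exceeds 0.999 at L = 20; the MCMC should come close.

test_that("diagnostic loci identify parentals and F1 with near-certainty", {
  L <- 20
  ref <- diagnostic_reference_gt(L, n_each = 5)
  gt <- gt_rbind(ref,
                 uniform_gt("het", L, 1L, 2L, "test"),
                 uniform_gt("homA", L, 1L, 1L, "test"),
                 uniform_gt("homB", L, 2L, 2L, "test"))
  fit <- hybrid_classify(gt, standard_class_sets("six"),
                         iterations = 8000, burn_in = 1000, seed = 11,
                         reference = reference_labels(5))
  expect_equal(unname(rowSums(fit$posterior)), rep(1, nrow(fit$posterior)),
               tolerance = 1e-6)
  expect_gt(fit$posterior["het", "F1"], 0.99)
  expect_gt(fit$posterior["homA", "P1"], 0.99)
  expect_gt(fit$posterior["homB", "P2"], 0.99)
})

test_that("relabeling the parental pools swaps the mirrored posteriors", {
  set.seed(21)
  par <- make_parental_frequencies(sim_config(n_loci = 11), seed = 22)
  reg <- class_registry()
  gt <- gt_rbind(simulate_class(par, reg$P1, 8, "P1"),
                 simulate_class(par, reg$P2, 8, "P2"),
                 simulate_class(par, reg$B1, 8, "B1"))
  # swapped dataset: ecotype anchors exchanged
  gt$ecotype <- rep(c("savanna", "forest", "unknown"), each = 8)
  gt_sw <- gt
  gt_sw$ecotype <- rep(c("forest", "savanna", "unknown"), each = 8)
  fit <- hybrid_classify(gt, standard_class_sets("six"),
                         iterations = 15000, burn_in = 3000, seed = 33)
  fit_sw <- hybrid_classify(gt_sw, standard_class_sets("six"),
                            iterations = 15000, burn_in = 3000, seed = 34)
  swap <- c(P1 = "P2", P2 = "P1", F1 = "F1", F2 = "F2", B1 = "B2", B2 = "B1")
  for (cl in colnames(fit$posterior))
    expect_equal(unname(fit$posterior[, cl]),
                 unname(fit_sw$posterior[, swap[[cl]]]),
                 tolerance = 0.05, label = cl)
})

test_that("runs are reproducible for a fixed seed", {
  gt <- gt_rbind(diagnostic_reference_gt(10, 3), uniform_gt("x", 10, 1L, 2L))
  f1 <- hybrid_classify(gt, standard_class_sets("six"), iterations = 3000,
                        burn_in = 500, seed = 77, reference = reference_labels(3))
  f2 <- hybrid_classify(gt, standard_class_sets("six"), iterations = 3000,
                        burn_in = 500, seed = 77, reference = reference_labels(3))
  expect_identical(f1$posterior, f2$posterior)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("all-missing individuals are flagged and follow the prior", {
  L <- 10
  gt <- gt_rbind(diagnostic_reference_gt(L, 4),
                 genotype_table("void", sprintf("L%02d", 1:L),
                                matrix(NA_integer_, 1, L),
                                matrix(NA_integer_, 1, L), "test"))
  fit <- hybrid_classify(gt, standard_class_sets("six"), iterations = 4000,
                         burn_in = 1000, seed = 5,
                         reference = reference_labels(4))
  expect_equal(fit$diagnostics$all_missing, "void")
  expect_equal(sum(fit$posterior["void", ]), 1, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected", {
  gt <- uniform_gt(c("a", "b"), 5, 1L, 1L)  # monomorphic everywhere
  expect_error(hybrid_classify(gt, standard_class_sets("six"),
                               iterations = 100, burn_in = 10),
               "polymorphic")
  gt2 <- diagnostic_reference_gt(5, 2)
  expect_error(hybrid_classify(gt2, standard_class_sets("six"),
                               iterations = 100, burn_in = 10,
                               reference = c(refA1 = "nope")),
               "unknown class")
})

test_that("purity_call thresholds, ties, and monotonicity behave", {
  m <- rbind(a = c(P1 = 0.9, P2 = 0.05, F1 = 0.05),
             b = c(P1 = 0.6, P2 = 0.4, F1 = 0.0),
             c = c(P1 = 1/3, P2 = 1/3, F1 = 1/3))
  expect_equal(unname(purity_call(m, 0.85)["a"]), "P1")
  expect_equal(unname(purity_call(m, 0.75)["b"]), "unassigned")
  # ties go to the earliest class (parentals first)
  expect_equal(unname(suppressWarnings(purity_call(m, 0.2))["c"]), "P1")
  expect_warning(purity_call(m, 0.4), "not be unique")
  expect_silent(purity_call(m, 0.5))
  counts <- vapply(c(0.5, 0.75, 0.85, 0.9),
                   function(th) sum(purity_call(m, th) != "unassigned"),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})
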