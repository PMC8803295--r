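test_that("diagnostic genotypes pin the hybrid index to the boundaries", {
  L <- 10
  par <- diagnostic_freqs(L)
  gt <- gt_rbind(uniform_gt("pureB", L, 2L, 2L),
                 uniform_gt("pureA", L, 1L, 1L),
                 uniform_gt("f1", L, 1L, 2L))
  est <- hybrid_index(gt, par, "A", "B")
  expect_equal(est$h_hat[est$individual == "pureB"], 1)
  expect_equal(est$ci_high[est$individual == "pureB"], 1)
  expect_equal(est$h_hat[est$individual == "pureA"], 0)
  expect_equal(est$h_hat[est$individual == "f1"], 0.5, tolerance = 1e-6)
  # Q12: F1-type = 1, pure = 0 on diagnostic loci
  expect_equal(est$q12[est$individual == "f1"], 1)
  expect_equal(est$q12[est$individual == "pureA"], 0)
  expect_equal(est$q12[est$individual == "pureB"], 0)
})

test_that("identical parental pools give the flat-likelihood contract", {
  L <- 5
  loci <- sprintf("L%02d", seq_len(L))
  f <- stats::setNames(rep(list(c("1" = 0.5, "2" = 0.5)), L), loci)
  par <- structure(list(groups = c("A", "B"), loci = loci,
                        freq = list(A = f, B = f),
                        gene_copies = matrix(100L, 2, L,
                                             dimnames = list(c("A", "B"), loci))),
                   class = "allele_freq_table")
  est <- hybrid_index(uniform_gt("x", L, 1L, 2L), par, "A", "B")
  expect_true(est$flat)
  expect_equal(est$h_hat, 0.5)
  expect_equal(c(est$ci_low, est$ci_high), c(0, 1))
})

test_that("F1 profile CI matches an independent dense-grid evaluation", {
  L <- 10
  par <- diagnostic_freqs(L)
  est <- hybrid_index(uniform_gt("f1", L, 1L, 2L), par, "A", "B")
  # oracle: l(h) = L * log(h (1-h)) + const, evaluated on an independent grid
  hs <- seq(1e-6, 1 - 1e-6, length.out = 200001)
  ll <- L * log(hs * (1 - hs))
  keep <- hs[ll >= max(ll) - 1.92]
  expect_equal(est$ci_low, min(keep), tolerance = 1e-3)
  expect_equal(est$ci_high, max(keep), tolerance = 1e-3)
})

test_that("Q12 posterior matches the three-state Bayes oracle", {
  loci <- "L01"
  par <- structure(list(groups = c("A", "B"), loci = loci,
                        freq = list(A = list(L01 = c("1" = 0.9, "2" = 0.1)),
                                    B = list(L01 = c("1" = 0.1, "2" = 0.9))),
                        gene_copies = matrix(1000L, 2, 1,
                                             dimnames = list(c("A", "B"), loci))),
                   class = "allele_freq_table")
  est <- hybrid_index(uniform_gt("het", 1, 1L, 2L), par, "A", "B")
  L2 <- 2 * 0.9 * 0.1; L0 <- 2 * 0.1 * 0.9
  L1 <- 0.9 * 0.9 + 0.1 * 0.1
  expect_equal(est$q12, L1 / (L0 + L1 + L2), tolerance = 1e-12)
})

test_that("swapping the pools reflects h and leaves Q12 unchanged", {
  set.seed(3)
  par <- make_parental_frequencies(sim_config(), seed = 13)
  gt <- simulate_class(par, class_registry()$B2, 10, "B2")
  e1 <- hybrid_index(gt, par, "A", "B")
  e2 <- hybrid_index(gt, par, "A", "B", orientation = "savanna")
  expect_equal(e1$h_hat, 1 - e2$h_hat, tolerance = 1e-6)
  expect_equal(e1$q12, e2$q12, tolerance = 1e-12)
})

test_that("triangle excess is zero at the apex and positive off the bound", {
  est <- data.frame(individual = c("apex", "off"), h_hat = c(0.5, 0),
                    ci_low = 0, ci_high = 1, q12 = c(1, 0.3),
                    n_loci_used = 10, flat = FALSE)
  class(est) <- c("hybrid_index_est", "data.frame")
  tr <- triangle_report(est)
  expect_equal(tr$triangle_excess, c(0, 0.3))
  expect_equal(attr(tr, "above_bound"), "off")
})

test_that("simulated F2 cohorts sit inside the triangle on average", {
  set.seed(8)
  par <- diagnostic_freqs(11)
  gt <- simulate_class(par, class_registry()$F2, 200, "F2")
  tr <- triangle_report(hybrid_index(gt, par, "A", "B"))
  expect_lt(mean(tr$triangle_excess), 0.02)
})

test_that("zero usable loci is an error", {
  L <- 3
  gt <- genotype_table("void", sprintf("L%02d", 1:L),
                       matrix(NA_integer_, 1, L), matrix(NA_integer_, 1, L),
                       "p")
  expect_error(hybrid_index(gt, diagnostic_freqs(L), "A", "B"),
               "zero usable loci")
})
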