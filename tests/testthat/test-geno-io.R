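test_that("GenePop dialect is decoded correctly", {
  path <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("toy file", "locA", "locB", "POP",
               "ind1 , 0102 0101", "ind2 , 0202 0000"), path)
  gt <- read_genepop(path)
  expect_equal(gt$loci, c("locA", "locB"))
  expect_equal(unname(gt$a1["ind1", ]), c(1L, 1L))
  expect_equal(unname(gt$a2["ind1", ]), c(2L, 1L))
  expect_equal(unname(gt$a1["ind2", ]), c(2L, NA_integer_))
  expect_equal(gt$pop, c("pop1", "pop1"))

  # comma-separated locus names, 3-digit coding, multiple POP blocks
  writeLines(c("t", "locA, locB", "POP", "a1 , 101102 000000",
               "POP", "b1 , 103103 104105"), path)
  gt3 <- read_genepop(path)
  expect_equal(unname(gt3$a2["a1", ]), c(102L, NA_integer_))
  expect_equal(gt3$pop, c("pop1", "pop2"))
})

test_that("all-missing GenePop file yields an all-missing mask", {
  path <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("t", "locA", "locB", "POP", "i1 , 0000 0000"), path)
  gt <- read_genepop(path)
  expect_true(all(is.na(gt$a1)))
  ft <- allele_frequencies(gt)
  expect_true(all(ft$gene_copies == 0))
  expect_null(ft$freq[["pop1"]][["locA"]])
})

test_that("malformed GenePop input is rejected with line numbers", {
  path <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("t", "locA", "POP", "no_comma_here 0101"), path)
  expect_error(read_genepop(path), "line 4")
  writeLines(c("t", "locA", "locB", "POP", "i1 , 0101 010101"), path)
  expect_error(read_genepop(path), "width")
  writeLines(c("t", "locA", "POP"), path)
  expect_error(read_genepop(path), "zero individuals")
})

test_that("write/read round-trip preserves a synthetic table bit-exactly", {
  gt <- random_gt(n_pops = 3, L = 11)
  path <- withr::local_tempfile(fileext = ".gen")
  write_genepop(gt, path)
  back <- read_genepop(path)
  expect_identical(back$ids, gt$ids)
  expect_identical(back$loci, gt$loci)
  expect_identical(back$a1, gt$a1)
  expect_identical(back$a2, gt$a2)
  expect_identical(back$pop, gt$pop)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_genotype_csv(gt, csv)
  back2 <- read_genotype_csv(csv)
  expect_identical(back2$a1, gt$a1)
  expect_identical(back2$ecotype, gt$ecotype)
})

test_that("sample sheet attaches labels and reports discrepancies", {
  gt <- random_gt(n_pops = 1, n_per_pop = 4, L = 2, missing_rate = 0)
  sheet <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual,population,ecotype",
               "ind01,s-SUE,savanna", "ind02,s-SUE,savanna",
               "ind03,f-SUE,forest", "ghost,f-SUE,forest"), sheet)
  expect_warning(out <- read_sample_sheet(sheet, gt), "absent from sample")
  expect_equal(out$ecotype, c("savanna", "savanna", "forest", "unknown"))
  expect_equal(out$pop[1:3], c("s-SUE", "s-SUE", "f-SUE"))
  expect_equal(attr(out, "discrepancies"), "ghost")

  writeLines(c("individual,ecotype", "ind01,savanna", "ind01,forest"), sheet)
  expect_error(read_sample_sheet(sheet, gt), "duplicate")
  writeLines(c("individual,ecotype", "ind01,cerrado"), sheet)
  expect_error(read_sample_sheet(sheet, gt), "savanna, forest, unknown")
})

test_that("allele frequencies count gene copies and respect missingness", {
  gt <- genotype_table(c("i1", "i2"), "L1", matrix(c(1L, 1L)),
                       matrix(c(1L, 2L)), c("p", "p"))
  ft <- allele_frequencies(gt)
  expect_equal(ft$freq[["p"]][["L1"]], c("1" = 0.75, "2" = 0.25))
  expect_equal(unname(ft$gene_copies["p", "L1"]), 4L)

  gt2 <- genotype_table(c("i1", "i2"), "L1", matrix(c(1L, NA)),
                        matrix(c(1L, NA)), c("p", "p"))
  expect_equal(unname(allele_frequencies(gt2)$gene_copies["p", "L1"]), 2L)
})

test_that("frequencies sum to one and pooling equals merged-group counting", {
  gt <- random_gt(n_pops = 3, n_per_pop = 6, L = 5, missing_rate = 0.2)
  ft <- allele_frequencies(gt)
  for (g in ft$groups) for (l in seq_along(ft$loci)) {
    f <- ft$freq[[g]][[l]]
    if (!is.null(f)) expect_equal(sum(f), 1, tolerance = 1e-9)
  }
  pooled <- pool_frequencies(ft, c("pop1", "pop2"), "m")
  merged <- allele_frequencies(
    gt, ifelse(gt$pop %in% c("pop1", "pop2"), "m", gt$pop))
  for (l in seq_along(ft$loci)) {
    a <- pooled$freq[["m"]][[l]]; b <- merged$freq[["m"]][[l]]
    expect_equal(a[sort(names(a))], b[sort(names(b))], tolerance = 1e-9)
  }
})

test_that("sample frequencies converge to the sampling distribution", {
  set.seed(99)
  n <- 5000   # 10,000 gene copies
  a1 <- matrix(sample(1:2, n, TRUE, prob = c(0.3, 0.7)), n, 1)
  a2 <- matrix(sample(1:2, n, TRUE, prob = c(0.3, 0.7)), n, 1)
  gt <- genotype_table(paste0("i", seq_len(n)), "L1", a1, a2, rep("p", n))
  f <- allele_frequencies(gt)$freq[["p"]][["L1"]]
  expect_lt(abs(f[["1"]] - 0.3), 0.02)
})
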