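test_that("geographic distances behave like a metric on the sphere", {
  env <- data.frame(population = c("a", "b", "c"),
                    latitude = c(0, 0, 0), longitude = c(10, 10, 11))
  d <- geo_distance(env)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 111.3, tolerance = 0.005)  # 1 deg lon at equator
  set.seed(71)
  env2 <- data.frame(population = paste0("p", 1:10),
                     latitude = runif(10, -60, 60),
                     longitude = runif(10, -170, 170))
  d2 <- geo_distance(env2)
  expect_equal(d2, t(d2))
  for (i in 1:10) for (j in 1:10) for (k in 1:10)
    expect_lte(d2[i, j], d2[i, k] + d2[k, j] + 1e-6)
  expect_error(geo_distance(data.frame(population = "x", latitude = 100,
                                       longitude = 0)), "out of range")
})

test_that("Mahalanobis distance equals Euclidean under identity covariance", {
  # columns constructed to have exactly unit variance and zero correlation
  X <- scale(cbind(v1 = c(-1.5, -0.5, 0.5, 1.5),
                   v2 = c(-0.5, 1.5, -1.5, 0.5)))
  stopifnot(abs(cov(X)[1, 2]) < 1e-12, abs(var(X[, 1]) - 1) < 1e-12)
  env <- data.frame(population = paste0("p", 1:4), v1 = X[, 1], v2 = X[, 2])
  d <- env_distance(env)
  de <- as.matrix(dist(X))
  dimnames(de) <- dimnames(d)
  expect_equal(d, de, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("perfect collinearity takes the pseudo-inverse path consistently", {
  set.seed(72)
  v <- rnorm(6)
  env <- data.frame(population = paste0("p", 1:6), v1 = v, v2 = v)
  expect_silent(d2 <- env_distance(env))
  expect_true(attr(d2, "pseudo_inverse"))
  expect_equal(attr(d2, "rank"), 1)
  # equals the single-variable Mahalanobis distance |dx| / sd
  d1 <- abs(outer(v, v, "-")) / sd(v)
  expect_equal(unname(unclass(d2)), unname(d1), tolerance = 1e-9,
               ignore_attr = TRUE)
  # identical rows are at distance zero
  env$v2 <- rnorm(6); env[2, -1] <- env[1, -1]
  d3 <- env_distance(env)
  expect_equal(d3["p1", "p2"], 0, tolerance = 1e-9)
  # constant variables are dropped with a warning
  env$v3 <- 5
  expect_warning(env_distance(env), "constant")
})

test_that("PCA reduction honours count and variance-fraction semantics", {
  set.seed(73)
  x <- rnorm(8)
  env <- data.frame(population = paste0("p", 1:8), v1 = x, v2 = 2 * x + 3)
  out <- env_pca_reduce(env, retain = 1)
  expect_equal(attr(out, "explained")[1], 1, tolerance = 1e-12)
  expect_error(env_pca_reduce(env, retain = 2), "rank")
  # correlated 19-variable table: smallest k reaching the target fraction
  Z <- matrix(rnorm(12 * 4), 12, 4) %*% matrix(rnorm(4 * 19), 4, 19) +
    0.1 * matrix(rnorm(12 * 19), 12, 19)
  env2 <- data.frame(population = paste0("p", 1:12), Z)
  out2 <- env_pca_reduce(env2, retain = 0.955)
  k <- ncol(out2) - 1
  cum <- cumsum(attr(out2, "explained"))
  expect_gte(cum[k], 0.955)
  if (k > 1) expect_lt(cum[k - 1], 0.955)
})

test_that("Mantel self-test gives r = 1 and the minimal p", {
  set.seed(74)
  m <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
  dimnames(m) <- list(paste0("p", 1:10), paste0("p", 1:10))
  out <- mantel(m, m, n_perm = 999, seed = 1)
  expect_equal(out$r, 1)
  expect_equal(out$p, 1 / 1000)
})

test_that("exhaustive Mantel p equals full enumeration by independent code", {
  set.seed(75)
  d1 <- as.matrix(dist(matrix(rnorm(8), 4, 2)))
  d2 <- as.matrix(dist(matrix(rnorm(8), 4, 2)))
  out <- mantel(d1, d2, exhaustive = TRUE)
  # oracle: enumerate the 24 permutations with nested loops
  v1 <- d1[upper.tri(d1)]
  rs <- c()
  for (a in 1:4) for (b in 1:4) for (cc in 1:4) for (dd in 1:4) {
    p <- c(a, b, cc, dd)
    if (length(unique(p)) < 4) next
    rs <- c(rs, cor(v1, d2[p, p][upper.tri(d2)]))
  }
  expect_equal(out$n_perm, 24)
  expect_equal(out$p, mean(rs >= out$r - 1e-12), tolerance = 1e-12)
})

test_that("Mantel r agrees with vegan and is scale-invariant", {
  skip_if_not_installed("vegan")
  set.seed(76)
  d1 <- as.matrix(dist(matrix(rnorm(18), 9, 2)))
  d2 <- as.matrix(dist(matrix(rnorm(18), 9, 2)))
  ours <- mantel(d1, d2, n_perm = 499, seed = 2)
  ref <- vegan::mantel(d1, d2, permutations = 499)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p - ref$signif), 0.06)
  scaled <- mantel(d1 * 3 + 1, d2 * 0.5, n_perm = 499, seed = 2)
  expect_equal(scaled$r, ours$r, tolerance = 1e-12)
  expect_equal(scaled$p, ours$p)
})

test_that("partial Mantel identities hold", {
  set.seed(77)
  d1 <- as.matrix(dist(matrix(rnorm(16), 8, 2)))
  d2 <- as.matrix(dist(matrix(rnorm(16), 8, 2)))
  ctl <- as.matrix(dist(matrix(rnorm(16), 8, 2)))
  # d2 == control: partial correlation is exactly zero
  out <- partial_mantel(d1, ctl, ctl, n_perm = 99, seed = 1)
  expect_equal(out$r, 0, tolerance = 1e-12)
  # d1 == d2 given an unrelated control: partial r = 1
  out2 <- partial_mantel(d1, d1, ctl, n_perm = 99, seed = 1)
  expect_equal(out2$r, 1, tolerance = 1e-12)
  expect_error(partial_mantel(d1, d2, d1, n_perm = 99), "degenerate")
  # independent control barely changes the simple correlation
  reps <- replicate(40, {
    a <- as.matrix(dist(rnorm(8))); b <- as.matrix(dist(rnorm(8)))
    cc <- as.matrix(dist(rnorm(8)))
    mantel(a, b, n_perm = 1)$r - partial_mantel(a, b, cc, n_perm = 1)$r
  })
  expect_lt(abs(mean(reps)), 0.05)
})
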