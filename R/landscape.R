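#' Great-circle distance matrix between populations
#'
#' Geodesic (WGS84) distances in kilometres from decimal-degree coordinates.
#'
#' @param env data.frame with columns `population`, `latitude`, `longitude`.
#' @return Symmetric km distance matrix labelled by population.
#' @export
geo_distance <- function(env) {
  stopifnot(all(c("population", "latitude", "longitude") %in% names(env)))
  lat <- as.numeric(env$latitude); lon <- as.numeric(env$longitude)
  if (any(abs(lat) > 90) || any(abs(lon) > 180))
    stop("coordinates out of range (lat within 90, lon within 180)")
  n <- nrow(env)
  D <- matrix(0, n, n, dimnames = list(env$population, env$population))
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    D[i, j] <- D[j, i] <-
      geosphere::distGeo(c(lon[i], lat[i]), c(lon[j], lat[j])) / 1000
  }
  D
}

#' Mahalanobis environmental distance between populations
#'
#' Pairwise Mahalanobis distances using the covariance of the variables
#' across populations. Constant variables are dropped with a warning; a
#' singular covariance falls back to the Moore-Penrose pseudo-inverse, with
#' the rank reported as an attribute.
#'
#' @param env data.frame with a `population` column and numeric variables.
#' @param variables Character vector of variable columns (default: all
#'   numeric columns except coordinates).
#' @return Symmetric distance matrix; attributes `rank` and `pseudo_inverse`.
#' @export
env_distance <- function(env, variables = NULL) {
  if (is.null(variables))
    variables <- setdiff(names(env)[vapply(env, is.numeric, TRUE)],
                         c("latitude", "longitude"))
  if (length(variables) < 2) stop("need at least 2 variables")
  X <- as.matrix(env[, variables, drop = FALSE])
  if (anyNA(X)) stop("missing values in environmental variables")
  const <- apply(X, 2, function(v) stats::var(v) == 0)
  if (any(const)) {
    warning("dropping constant variable(s): ",
            paste(variables[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  S <- stats::cov(X)
  rk <- qr(S)$rank
  pseudo <- rk < ncol(S)
  Sinv <- if (pseudo) MASS::ginv(S) else solve(S)
  n <- nrow(X)
  D <- matrix(0, n, n, dimnames = list(env$population, env$population))
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    dx <- X[i, ] - X[j, ]
    D[i, j] <- D[j, i] <- sqrt(max(drop(t(dx) %*% Sinv %*% dx), 0))
  }
  attr(D, "rank") <- rk
  attr(D, "pseudo_inverse") <- pseudo
  D
}

#' PCA reduction of environmental variables
#'
#' Standardized-variable principal components, retaining either a fixed
#' number of components or the smallest number reaching a target fraction of
#' explained variance.
#'
#' @inheritParams env_distance
#' @param retain Integer (>= 1) number of components, or a fraction in (0, 1)
#'   of variance to reach.
#' @return data.frame `population` + component scores; attribute
#'   `explained` holds the per-component explained-variance fractions.
#' @export
env_pca_reduce <- function(env, variables = NULL, retain = 0.955) {
  if (is.null(variables))
    variables <- setdiff(names(env)[vapply(env, is.numeric, TRUE)],
                         c("latitude", "longitude"))
  if (length(variables) < 2) stop("need at least 2 variables")
  X <- as.matrix(env[, variables, drop = FALSE])
  keep <- apply(X, 2, function(v) stats::var(v) > 0)
  X <- X[, keep, drop = FALSE]
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  rank <- sum(pc$sdev > 1e-12)
  if (retain >= 1) {
    k <- as.integer(retain)
    if (k > rank) stop("retain exceeds rank (", rank, ")")
  } else {
    k <- which(cumsum(expl) >= retain)[1]
    if (is.na(k)) k <- rank
  }
  out <- data.frame(population = env$population,
                    pc$x[, seq_len(k), drop = FALSE])
  attr(out, "explained") <- expl
  out
}

upper_tri_vec <- function(d) d[upper.tri(d)]

align_matrices <- function(...) {
  ms <- lapply(list(...), as.matrix)
  labs <- rownames(ms[[1]])
  if (!is.null(labs)) {
    for (k in seq_along(ms)) {
      if (is.null(rownames(ms[[k]])) ||
          !setequal(rownames(ms[[k]]), labs))
        stop("distance matrices have mismatched labels")
      ms[[k]] <- ms[[k]][labs, labs]
    }
  } else {
    n <- nrow(ms[[1]])
    for (m in ms) if (nrow(m) != n) stop("distance matrices differ in size")
  }
  ms
}

#' Simple Mantel test
#'
#' Pearson correlation of the off-diagonal upper triangles, with one-tailed
#' (upper) significance from joint row/column permutations of the second
#' matrix. The sampled estimator is `(n_greater + 1)/(n_perm + 1)`; in
#' exhaustive mode all `n!` label permutations are enumerated and p is the
#' proportion (identity included) with `r_perm >= r_obs`.
#'
#' @param d1,d2 Symmetric distance matrices with matching labels (n >= 4).
#' @param n_perm Number of permutations (ignored in exhaustive mode).
#' @param exhaustive Enumerate all permutations (n <= 8).
#' @param seed Optional seed.
#' @return List `(r, p, n_perm)` of class `mantel_test`.
#' @export
mantel <- function(d1, d2, n_perm = 9999, exhaustive = FALSE, seed = NULL) {
  ms <- align_matrices(d1, d2)
  d1 <- ms[[1]]; d2 <- ms[[2]]
  n <- nrow(d1)
  if (n < 4) stop("need at least 4 labels")
  v1 <- upper_tri_vec(d1); v2 <- upper_tri_vec(d2)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("constant distance matrix: r undefined")
  r_obs <- stats::cor(v1, v2)
  if (exhaustive) {
    if (n > 8) stop("exhaustive mode limited to n <= 8")
    perms <- all_permutations(n)
    rs <- vapply(perms, function(p)
      stats::cor(v1, upper_tri_vec(d2[p, p])), numeric(1))
    p <- mean(rs >= r_obs - 1e-12)
    np <- length(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    ge <- 0L
    for (b in seq_len(n_perm)) {
      pm <- sample(n)
      if (stats::cor(v1, upper_tri_vec(d2[pm, pm])) >= r_obs - 1e-12)
        ge <- ge + 1L
    }
    p <- (ge + 1) / (n_perm + 1)
    np <- n_perm
  }
  structure(list(r = r_obs, p = p, n_perm = np), class = "mantel_test")
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1)
  out <- vector("list", n * length(sub))
  k <- 1L
  for (s in sub) for (pos in seq_len(n)) {
    out[[k]] <- append(s, n, after = pos - 1L)
    k <- k + 1L
  }
  out
}

#' Partial Mantel test
#'
#' Partial correlation of `d1` and `d2` given `control`, computed from the
#' three pairwise Mantel correlations
#' `r12.3 = (r12 - r13 r23) / sqrt((1 - r13^2)(1 - r23^2))`. Significance by
#' permuting `d2`'s rows/columns and recomputing the partial statistic
#' (`r13` stays fixed).
#'
#' @inheritParams mantel
#' @param control Controlling distance matrix.
#' @return List `(r, p, n_perm)` of class `mantel_test`.
#' @export
partial_mantel <- function(d1, d2, control, n_perm = 9999, seed = NULL) {
  ms <- align_matrices(d1, d2, control)
  v1 <- upper_tri_vec(ms[[1]]); v2 <- upper_tri_vec(ms[[2]])
  v3 <- upper_tri_vec(ms[[3]])
  n <- nrow(ms[[1]])
  if (n < 4) stop("need at least 4 labels")
  r13 <- stats::cor(v1, v3)
  if (abs(r13) >= 1 - 1e-12)
    stop("degenerate: |r(d1, control)| = 1")
  part <- function(v2p) {
    r12 <- stats::cor(v1, v2p); r23 <- stats::cor(v2p, v3)
    num <- r12 - r13 * r23
    den <- sqrt((1 - r13^2) * (1 - r23^2))
    if (den < 1e-12) {               # d2 collinear with control
      if (abs(num) < 1e-12) 0 else sign(num)
    } else num / den
  }
  r_obs <- part(v2)
  if (!is.null(seed)) set.seed(seed)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    pm <- sample(n)
    if (part(upper_tri_vec(ms[[2]][pm, pm])) >= r_obs - 1e-12) ge <- ge + 1L
  }
  structure(list(r = r_obs, p = (ge + 1) / (n_perm + 1), n_perm = n_perm),
            class = "mantel_test")
}

#' @export
print.mantel_test <- function(x, ...) {
  cat(sprintf("Mantel: r = %.4f, p = %.4g (%d permutations)\n",
              x$r, x$p, x$n_perm))
  invisible(x)
}
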