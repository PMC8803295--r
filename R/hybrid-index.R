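#' Maximum-likelihood hybrid index and interecotypic heterozygosity
#'
#' For each individual, estimates the hybrid index h — the proportion of its
#' genome derived from parental pool B (the forest pool under the default
#' orientation, so savanna-pure individuals sit near 0 and forest-pure near 1)
#' — by maximizing the log-likelihood
#' `l(h) = sum over gene copies of log((1 - h) pA(allele) + h pB(allele))`
#' on a grid with golden-section refinement. The 95% interval is the profile-
#' likelihood set `{h : l(h) >= l(h_hat) - 1.92}` (chi-square 1 df cutoff).
#' Interecotypic heterozygosity Q12 is the mean over usable loci of the
#' posterior probability that the locus carries one gene copy from each pool,
#' under a uniform prior over the three ancestry states and Hardy-Weinberg
#' per-state genotype likelihoods.
#'
#' Loci missing in an individual or with undefined parental frequencies are
#' excluded and counted. An allele unseen in both parental pools receives a
#' floor frequency `1 / (2 * gene_copies + 1)` in both pools (keeps the
#' likelihood finite without biasing either pool); a warning reports it.
#'
#' @param gt A [genotype_table()] of the individuals to score.
#' @param parental An `allele_freq_table` holding both parental pools (e.g.
#'   from [allele_frequencies()] on pure individuals).
#' @param pool_a,pool_b Group labels of the savanna-side (A) and forest-side
#'   (B) pools within `parental`.
#' @param grid_step Grid resolution for the likelihood scan (<= 0.001).
#' @param orientation `"forest"` (default, h = forest proportion) or
#'   `"savanna"` (h = savanna proportion; swaps the pools).
#' @return An object of class `hybrid_index_est`: a data.frame with columns
#'   `individual`, `h_hat`, `ci_low`, `ci_high`, `q12`, `n_loci_used`,
#'   `flat` (TRUE when the likelihood is flat; such rows report h = 0.5 with
#'   CI [0, 1]).
#' @export
hybrid_index <- function(gt, parental, pool_a, pool_b, grid_step = 0.001,
                         orientation = c("forest", "savanna")) {
  orientation <- match.arg(orientation)
  stopifnot(grid_step <= 0.001, grid_step > 0)
  if (orientation == "savanna") { tmp <- pool_a; pool_a <- pool_b; pool_b <- tmp }
  pa <- freq_slice(parental, pool_a)
  pb <- freq_slice(parental, pool_b)
  gca <- parental$gene_copies[pool_a, ]
  gcb <- parental$gene_copies[pool_b, ]

  grid <- seq(0, 1, by = grid_step)
  n <- length(gt$ids)
  out <- data.frame(individual = gt$ids, h_hat = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, q12 = NA_real_,
                    n_loci_used = NA_integer_, flat = FALSE)
  floored <- FALSE
  for (i in seq_len(n)) {
    fa <- numeric(); fb <- numeric()   # per gene copy
    q12sum <- 0; used <- 0L
    for (l in seq_along(gt$loci)) {
      a <- gt$a1[i, l]; b <- gt$a2[i, l]
      if (is.na(a) || is.null(pa[[l]]) || is.null(pb[[l]])) next
      lk <- function(al) {
        xa <- unname(pa[[l]][as.character(al)]); if (is.na(xa)) xa <- 0
        xb <- unname(pb[[l]][as.character(al)]); if (is.na(xb)) xb <- 0
        if (xa == 0 && xb == 0) {
          floored <<- TRUE
          xa <- 1 / (2 * gca[l] + 1); xb <- 1 / (2 * gcb[l] + 1)
        }
        c(xa, xb)
      }
      va <- lk(a); vb <- lk(b)
      fa <- c(fa, va[1], vb[1]); fb <- c(fb, va[2], vb[2])
      # ancestry-state likelihoods for Q12
      L2 <- if (a == b) va[1]^2 else 2 * va[1] * vb[1]
      L0 <- if (a == b) va[2]^2 else 2 * va[2] * vb[2]
      L1 <- if (a == b) va[1] * va[2] else va[1] * vb[2] + vb[1] * va[2]
      q12sum <- q12sum + L1 / (L0 + L1 + L2)
      used <- used + 1L
    }
    if (used == 0L)
      stop("zero usable loci for individual ", gt$ids[i])
    out$n_loci_used[i] <- used
    out$q12[i] <- q12sum / used

    ll <- function(h) sum(log((1 - h) * fa + h * fb))
    lg <- vapply(grid, ll, numeric(1))
    if (max(lg) - min(lg) < 1e-12) {          # flat likelihood contract
      out$h_hat[i] <- 0.5; out$ci_low[i] <- 0; out$ci_high[i] <- 1
      out$flat[i] <- TRUE
      next
    }
    k <- which.max(lg)
    lo <- max(grid[k] - grid_step, 0); hi <- min(grid[k] + grid_step, 1)
    opt <- stats::optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-9)
    hhat <- opt$maximum; lmax <- opt$objective
    if (ll(0) >= lmax) { hhat <- 0; lmax <- ll(0) }
    if (ll(1) >= lmax) { hhat <- 1; lmax <- ll(1) }
    cut <- lmax - 1.92
    inside <- lg >= cut
    lo_i <- which(inside)[1]; hi_i <- rev(which(inside))[1]
    ci_lo <- if (lo_i == 1) 0 else
      stats::uniroot(function(h) ll(h) - cut, c(grid[lo_i - 1], grid[lo_i]),
                     tol = 1e-9)$root
    ci_hi <- if (hi_i == length(grid)) 1 else
      stats::uniroot(function(h) ll(h) - cut, c(grid[hi_i], grid[hi_i + 1]),
                     tol = 1e-9)$root
    out$h_hat[i] <- hhat
    out$ci_low[i] <- min(ci_lo, hhat)
    out$ci_high[i] <- max(ci_hi, hhat)
  }
  if (floored)
    warning("allele(s) unseen in both parental pools: floor frequency used")
  class(out) <- c("hybrid_index_est", "data.frame")
  out
}

#' Triangle-bound diagnostics for hybrid index vs Q12
#'
#' Under pedigree expectations Q12 cannot exceed `1 - |2h - 1|` (the triangle
#' with apex at (0.5, 1)); per-individual excess above the bound indicates
#' marker homoplasy (alleles shared by the pools beyond parental sampling).
#'
#' @param est A `hybrid_index_est` from [hybrid_index()].
#' @return `est` with column `triangle_excess = max(0, q12 - (1 - |2h - 1|))`;
#'   attribute `above_bound` lists individuals with positive excess.
#' @export
triangle_report <- function(est) {
  bound <- 1 - abs(2 * est$h_hat - 1)
  est$triangle_excess <- pmax(0, est$q12 - bound)
  attr(est, "above_bound") <- est$individual[est$triangle_excess > 0]
  est
}

#' @export
print.hybrid_index_est <- function(x, ...) {
  cat(sprintf("hybrid index estimates for %d individuals (%d flat)\n",
              nrow(x), sum(x$flat)))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 3)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' @export
plot.hybrid_index_est <- function(x, ...) {
  graphics::plot(x$h_hat, x$q12, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "hybrid index h", ylab = expression(Q[12]),
                 main = "hybrid index vs interecotypic heterozygosity", ...)
  graphics::segments(0, 0, 0.5, 1, lty = 2)
  graphics::segments(0.5, 1, 1, 0, lty = 2)
  invisible(x)
}
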