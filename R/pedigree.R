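#' Pedigrees for genotypic classes
#'
#' A genotypic class (P1, F1, F2, backcrosses, ...) is defined by an explicit
#' cross pedigree whose founders are drawn from parental pool A (savanna) or
#' pool B (forest). Pedigrees are binary trees: each terminal denotes a fresh,
#' independent founder, so loops and shared founders cannot be expressed —
#' which is exactly the assumption under which per-locus ancestry is an
#' independent draw for the two parental gametes.
#'
#' `founder()` and `cross()` build pedigrees programmatically;
#' [parse_pedigree()] reads the small cross DSL, e.g. `"A x (F1 x A)"`.
#'
#' @param pool `"A"` or `"B"`.
#' @return A `pedigree` object.
#' @export
founder <- function(pool) {
  pool <- match.arg(pool, c("A", "B"))
  structure(list(leaf = pool), class = "pedigree")
}

#' @rdname founder
#' @param p1,p2 Parent pedigrees.
#' @export
cross <- function(p1, p2) {
  stopifnot(inherits(p1, "pedigree"), inherits(p2, "pedigree"))
  structure(list(p1 = p1, p2 = p2), class = "pedigree")
}

#' Parse a cross expression
#'
#' Grammar: `expr := term | term "x" term`; `term := name | "(" expr ")"`.
#' Names resolve against a registry of shorthands which by default contains
#' the standard classes (`A`, `B`, `P1`, `P2`, `F1`, `F2`, `F3`, `F4`,
#' `B1`–`B8`); every occurrence of a shorthand expands to an independent copy
#' of its pedigree.
#'
#' @param text A cross expression such as `"A x (A x (F1 x F1))"`.
#' @param registry Named list of `pedigree` objects used to resolve names.
#' @return A `pedigree`.
#' @export
parse_pedigree <- function(text, registry = class_registry()) {
  toks <- regmatches(text, gregexpr("\\(|\\)|x|[A-Za-z][A-Za-z0-9]*", text))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_term <- function() {
    t <- take()
    if (is.na(t)) stop("unexpected end of cross expression: ", text)
    if (t == "(") {
      e <- parse_expr()
      if (!identical(take(), ")")) stop("missing ')' in: ", text)
      return(e)
    }
    if (t %in% c(")", "x")) stop("unexpected '", t, "' in: ", text)
    if (!t %in% names(registry)) stop("unknown class name '", t, "' in: ", text)
    registry[[t]]
  }
  parse_expr <- function() {
    left <- parse_term()
    if (identical(peek(), "x")) { take(); return(cross(left, parse_term())) }
    left
  }
  out <- parse_expr()
  if (!is.na(peek())) stop("trailing tokens in cross expression: ", text)
  out
}

#' Registry of standard genotypic classes
#'
#' @return Named list of `pedigree` objects for `A`, `B`, `P1`, `P2`,
#'   `F1`–`F4` and `B1`–`B8`, with `B1 = F1 x A`, `B2 = F1 x B`,
#'   `B3 = F2 x A`, `B4 = F2 x B`, `B5 = A x (F1 x A)`, `B6 = B x (F1 x B)`,
#'   `B7 = A x (F2 x A)`, `B8 = B x (F2 x B)`.
#' @export
class_registry <- function() {
  A <- founder("A"); B <- founder("B")
  F1 <- cross(A, B)
  F2 <- cross(F1, F1)
  F3 <- cross(F2, F2)
  F4 <- cross(F3, F3)
  list(A = A, B = B, P1 = A, P2 = B,
       F1 = F1, F2 = F2, F3 = F3, F4 = F4,
       B1 = cross(F1, A), B2 = cross(F1, B),
       B3 = cross(F2, A), B4 = cross(F2, B),
       B5 = cross(A, cross(F1, A)), B6 = cross(B, cross(F1, B)),
       B7 = cross(A, cross(F2, A)), B8 = cross(B, cross(F2, B)))
}

#' Standard class sets
#'
#' The fixed, documented orders are: `six` = P1, P2, F1, F2, B1, B2;
#' `twelve` = six plus B3-B8; `fourteen` = twelve plus F3, F4.
#'
#' Under the per-locus-independent ancestry model several classes share an
#' identical profile and are therefore unidentifiable from unlinked markers:
#' \{B1, B3\}, \{B5, B7\}, \{B6, B8\} and \{F2, F3, F4\} (and symmetrically
#' \{B2, B4\}). See [class_equivalences()].
#'
#' @param which `"six"`, `"twelve"` or `"fourteen"`.
#' @return Named list of `pedigree` objects in the documented order.
#' @export
standard_class_sets <- function(which = c("six", "twelve", "fourteen")) {
  which <- match.arg(which)
  reg <- class_registry()
  six <- reg[c("P1", "P2", "F1", "F2", "B1", "B2")]
  twelve <- c(six, reg[paste0("B", 3:8)])
  switch(which,
         six = six,
         twelve = twelve,
         fourteen = c(twelve, reg[c("F3", "F4")]))
}

#' Model-indistinguishable class groups
#'
#' @return List of character vectors of class names whose ancestry profiles
#'   coincide, the mechanistic reason backcross resolution is low with
#'   unlinked markers.
#' @export
class_equivalences <- function() {
  list(c("B1", "B3"), c("B2", "B4"), c("B5", "B7"), c("B6", "B8"),
       c("F2", "F3", "F4"))
}

gamete_A_prob <- function(ped) {
  if (!is.null(ped$leaf)) return(if (ped$leaf == "A") 1 else 0)
  (gamete_A_prob(ped$p1) + gamete_A_prob(ped$p2)) / 2
}

#' Exact per-locus ancestry profile of a pedigree
#'
#' Computes phi = (P(2 A-copies), P(1 A-copy), P(0 A-copies)) at an autosomal
#' locus for the focal individual by recursion on gamete ancestry: a founder-A
#' gamete carries A with probability 1, founder-B with 0, and a child's gamete
#' with the mean of its parents'. The two gametes of the focal individual are
#' independent because every terminal is a distinct founder. All intermediate
#' values are dyadic rationals, exactly representable in doubles at these
#' depths, so the arithmetic is exact and `phi2 + phi1 + phi0 == 1` holds
#' without tolerance.
#'
#' @param ped A `pedigree`.
#' @return An `ancestry_profile`: named numeric `c(phi2, phi1, phi0)`.
#' @export
expected_ancestry_profile <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  if (!is.null(ped$leaf)) {
    phi <- if (ped$leaf == "A") c(1, 0, 0) else c(0, 0, 1)
  } else {
    g1 <- gamete_A_prob(ped$p1)
    g2 <- gamete_A_prob(ped$p2)
    phi <- c(g1 * g2, g1 * (1 - g2) + (1 - g1) * g2, (1 - g1) * (1 - g2))
  }
  structure(stats::setNames(phi, c("phi2", "phi1", "phi0")),
            class = "ancestry_profile")
}

#' @export
print.ancestry_profile <- function(x, ...) {
  cat(sprintf("ancestry profile: P(2A) = %s, P(1A+1B) = %s, P(2B) = %s\n",
              format(x[["phi2"]]), format(x[["phi1"]]), format(x[["phi0"]])))
  invisible(x)
}

#' Monte-Carlo gene-dropping of ancestry states
#'
#' Independent check of [expected_ancestry_profile()]: drops ancestry
#' indicators (A = 1, B = 0) down the pedigree `n` times at a single locus
#' and tallies the focal individual's A-copy count.
#'
#' @param ped A `pedigree`.
#' @param n Number of replicate drops.
#' @return Numeric `c(phi2, phi1, phi0)` of observed proportions.
#' @export
drop_ancestry <- function(ped, n) {
  drop_node <- function(nd) {
    if (!is.null(nd$leaf)) {
      v <- rep(if (nd$leaf == "A") 1L else 0L, n)
      return(cbind(v, v))
    }
    g1 <- drop_node(nd$p1); g2 <- drop_node(nd$p2)
    pick <- function(g) ifelse(stats::runif(n) < 0.5, g[, 1], g[, 2])
    cbind(pick(g1), pick(g2))
  }
  copies <- drop_node(ped)
  k <- copies[, 1] + copies[, 2]
  c(phi2 = mean(k == 2L), phi1 = mean(k == 1L), phi0 = mean(k == 0L))
}

#' Export a class set's ancestry profiles as a data frame
#'
#' @param classes Named list of pedigrees, e.g. from [standard_class_sets()].
#' @return data.frame with columns class, phi2, phi1, phi0.
#' @export
profile_table <- function(classes) {
  phis <- t(vapply(classes, function(p) unclass(expected_ancestry_profile(p)),
                   numeric(3)))
  data.frame(class = names(classes), phi2 = phis[, 1], phi1 = phis[, 2],
             phi0 = phis[, 3], row.names = NULL)
}
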