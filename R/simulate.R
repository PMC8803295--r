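#' Simulation configuration
#'
#' Defaults mirror the reference study design: 11 multiallelic loci, parental
#' pools diverged at F-model parameter 0.35 (the observed between-biome
#' pairwise F_ST range is 0.33-0.40), 100 individuals per genotypic class and
#' 5 replicate datasets.
#'
#' @param n_loci Number of loci.
#' @param alleles_per_locus Alleles segregating per locus.
#' @param divergence F-model differentiation parameter in (0, 1).
#' @param n_per_class Individuals simulated per genotypic class.
#' @param class_set `"six"`, `"twelve"` or `"fourteen"`.
#' @param n_datasets Number of replicate datasets.
#' @param missing_rate Per-call missingness probability in \[0, 1).
#' @param null_allele_freq Frequency of a hidden null allele in \[0, 1).
#' @param seed Optional integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_loci = 11, alleles_per_locus = 8, divergence = 0.35,
                       n_per_class = 100, class_set = "six", n_datasets = 5,
                       missing_rate = 0, null_allele_freq = 0, seed = NULL) {
  stopifnot(divergence > 0, divergence < 1,
            missing_rate >= 0, missing_rate < 1,
            null_allele_freq >= 0, null_allele_freq < 1,
            n_per_class >= 1)
  structure(list(n_loci = n_loci, alleles_per_locus = alleles_per_locus,
                 divergence = divergence, n_per_class = n_per_class,
                 class_set = class_set, n_datasets = n_datasets,
                 missing_rate = missing_rate,
                 null_allele_freq = null_allele_freq, seed = seed),
            class = "sim_config")
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), alpha, 1)
  x / sum(x)
}

#' Draw diverged parental allele-frequency pools (F-model)
#'
#' Per locus, an ancestral frequency vector is drawn from a flat Dirichlet
#' and each parental pool independently from
#' `Dirichlet(ancestral * (1 - F) / F)`, so the expected pairwise
#' differentiation between the pools is about F.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional seed (overrides `cfg$seed`).
#' @return An `allele_freq_table` with groups `"A"` (savanna side) and
#'   `"B"` (forest side). `gene_copies` is set to a nominal large value:
#'   these are population frequencies, not sample estimates.
#' @export
make_parental_frequencies <- function(cfg = sim_config(), seed = NULL) {
  seed <- seed %||% cfg$seed
  if (!is.null(seed)) set.seed(seed)
  L <- cfg$n_loci; K <- cfg$alleles_per_locus
  Fv <- cfg$divergence
  loci <- sprintf("L%02d", seq_len(L))
  codes <- as.character(seq_len(K))
  mk <- stats::setNames(vector("list", L), loci)
  fa <- fb <- mk
  for (l in seq_len(L)) {
    anc <- rdirichlet1(rep(1, K))
    alpha <- anc * (1 - Fv) / Fv
    fa[[l]] <- stats::setNames(rdirichlet1(alpha), codes)
    fb[[l]] <- stats::setNames(rdirichlet1(alpha), codes)
  }
  gc <- matrix(20000L, 2, L, dimnames = list(c("A", "B"), loci))
  structure(list(groups = c("A", "B"), loci = loci,
                 freq = list(A = fa, B = fb), gene_copies = gc),
            class = "allele_freq_table")
}

#' Derive per-population frequencies within an ecotype (nested F-model)
#'
#' @param parental An `allele_freq_table` with the two pools.
#' @param pool `"A"` or `"B"`: which pool the populations descend from.
#' @param n_pops Number of populations.
#' @param f_within Within-ecotype F-model divergence (the observed
#'   within-biome pairwise F_ST range is roughly 0.07-0.10).
#' @param names_prefix Prefix of the population labels.
#' @return An `allele_freq_table` with `n_pops` groups.
#' @export
make_population_frequencies <- function(parental, pool, n_pops = 3,
                                        f_within = 0.08,
                                        names_prefix = pool) {
  base <- freq_slice(parental, pool)
  loci <- parental$loci
  pops <- paste0(names_prefix, seq_len(n_pops))
  freq <- stats::setNames(vector("list", n_pops), pops)
  for (k in seq_len(n_pops)) {
    per <- stats::setNames(vector("list", length(loci)), loci)
    for (l in seq_along(loci)) {
      alpha <- base[[l]] * (1 - f_within) / f_within
      per[[l]] <- stats::setNames(rdirichlet1(alpha), names(base[[l]]))
    }
    freq[[k]] <- per
  }
  gc <- matrix(20000L, n_pops, length(loci), dimnames = list(pops, loci))
  structure(list(groups = pops, loci = loci, freq = freq, gene_copies = gc),
            class = "allele_freq_table")
}

#' Gene-dropping simulation of a genotypic class
#'
#' Founders' gene copies are drawn from their pool's frequencies under
#' Hardy-Weinberg equilibrium; every transmission picks one of the parent's
#' two copies uniformly at random, independently per locus. The focal
#' individual's genotype is recorded.
#'
#' @param parental `allele_freq_table` with groups `"A"` and `"B"`.
#' @param ped A `pedigree`.
#' @param n Number of individuals.
#' @param class_name Population/truth label attached to the individuals.
#' @param seed Optional seed.
#' @param id_prefix Prefix for individual ids.
#' @return A [genotype_table()] with `pop = class_name`; allele codes are the
#'   integer codes of the frequency table.
#' @export
simulate_class <- function(parental, ped, n, class_name = "sim",
                           seed = NULL, id_prefix = class_name) {
  if (!is.null(seed)) set.seed(seed)
  fa <- freq_slice(parental, "A")
  fb <- freq_slice(parental, "B")
  loci <- parental$loci
  L <- length(loci)
  draw_pool <- function(fr) {
    g <- matrix(0L, n, L)
    for (l in seq_len(L)) {
      if (is.null(fr[[l]])) stop("undefined parental frequency at ", loci[l])
      g[, l] <- as.integer(sample(names(fr[[l]]), n, replace = TRUE,
                                  prob = fr[[l]]))
    }
    g
  }
  drop_node <- function(nd) {
    if (!is.null(nd$leaf)) {
      fr <- if (nd$leaf == "A") fa else fb
      return(list(g1 = draw_pool(fr), g2 = draw_pool(fr)))
    }
    p1 <- drop_node(nd$p1); p2 <- drop_node(nd$p2)
    pick <- function(p) {
      m <- matrix(stats::runif(n * L) < 0.5, n, L)
      ifelse(m, p$g1, p$g2)
    }
    list(g1 = pick(p1), g2 = pick(p2))
  }
  g <- drop_node(ped)
  genotype_table(paste0(id_prefix, "_", seq_len(n)), loci, g$g1, g$g2,
                 rep(class_name, n))
}

#' Simulate a structured two-ecotype sampling layout
#'
#' Emulates the study's population design: `n_pops` populations per ecotype,
#' each with frequencies diverged from its ecotype pool by a nested F-model,
#' and `n_per_pop` Hardy-Weinberg individuals per population.
#'
#' @inheritParams make_population_frequencies
#' @param cfg A [sim_config()] (pools drawn from it unless given).
#' @param parental Optional pre-drawn parental `allele_freq_table`.
#' @param n_pops Populations per ecotype.
#' @param n_per_pop Individuals per population.
#' @param seed Optional seed.
#' @return A [genotype_table()] with populations `sav1..., for1...` and
#'   ecotype labels set.
#' @export
simulate_structured_populations <- function(cfg = sim_config(),
                                            parental = NULL, n_pops = 3,
                                            n_per_pop = 20, f_within = 0.08,
                                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(parental)) parental <- make_parental_frequencies(cfg, seed = NULL)
  popA <- make_population_frequencies(parental, "A", n_pops, f_within, "sav")
  popB <- make_population_frequencies(parental, "B", n_pops, f_within, "for")
  out <- list()
  one_pool_ft <- function(popft, p) {
    gc <- matrix(20000L, 2, length(popft$loci),
                 dimnames = list(c("A", "B"), popft$loci))
    structure(list(groups = c("A", "B"), loci = popft$loci,
                   freq = list(A = popft$freq[[p]], B = popft$freq[[p]]),
                   gene_copies = gc),
              class = "allele_freq_table")
  }
  for (p in popA$groups) {
    g <- simulate_class(one_pool_ft(popA, p), founder("A"), n_per_pop, p,
                        id_prefix = p)
    g$ecotype <- rep("savanna", n_per_pop)
    out[[p]] <- g
  }
  for (p in popB$groups) {
    g <- simulate_class(one_pool_ft(popB, p), founder("B"), n_per_pop, p,
                        id_prefix = p)
    g$ecotype <- rep("forest", n_per_pop)
    out[[p]] <- g
  }
  gt_rbind(out)
}

#' Build replicate evaluation datasets with truth labels
#'
#' For each of `cfg$n_datasets` replicates, simulates `cfg$n_per_class`
#' individuals of every class in `cfg$class_set` by gene dropping, then
#' applies optional call-wise missingness and null-allele corruption (a
#' hidden null allele segregating at `cfg$null_allele_freq`: null homozygotes
#' become missing calls, null heterozygotes appear as visible-allele
#' homozygotes).
#'
#' @param parental `allele_freq_table` with groups `"A"` and `"B"` (e.g.
#'   [make_parental_frequencies()], or frequencies of empirically pure
#'   individuals).
#' @param cfg A [sim_config()].
#' @param seed Optional seed (overrides `cfg$seed`).
#' @return List of [genotype_table()]s; each has attribute `truth`, the
#'   per-individual true class labels, and `pop` set to the true class.
#' @export
build_evaluation_datasets <- function(parental, cfg = sim_config(),
                                      seed = NULL) {
  seed <- seed %||% cfg$seed
  if (!is.null(seed)) set.seed(seed)
  classes <- standard_class_sets(cfg$class_set)
  lapply(seq_len(cfg$n_datasets), function(d) {
    parts <- lapply(names(classes), function(cl)
      simulate_class(parental, classes[[cl]], cfg$n_per_class, cl,
                     id_prefix = sprintf("d%d_%s", d, cl)))
    gt <- gt_rbind(parts)
    if (cfg$null_allele_freq > 0)
      gt <- corrupt_null_alleles(gt, cfg$null_allele_freq)
    if (cfg$missing_rate > 0) {
      drop <- matrix(stats::runif(length(gt$ids) * length(gt$loci)) <
                       cfg$missing_rate,
                     length(gt$ids), length(gt$loci))
      gt$a1[drop] <- NA_integer_
      gt$a2[drop] <- NA_integer_
    }
    attr(gt, "truth") <- gt$pop
    gt
  })
}

#' Null-allele corruption of a genotype table
#'
#' @param gt A [genotype_table()].
#' @param q Null-allele frequency.
#' @param loci Locus names or indices to corrupt (default: all).
#' @return The corrupted [genotype_table()].
#' @export
corrupt_null_alleles <- function(gt, q, loci = NULL) {
  l_idx <- if (is.null(loci)) seq_along(gt$loci)
           else if (is.character(loci)) match(loci, gt$loci) else loci
  n <- length(gt$ids)
  for (l in l_idx) {
    null1 <- stats::runif(n) < q
    null2 <- stats::runif(n) < q
    both <- null1 & null2 & !is.na(gt$a1[, l])
    one1 <- null1 & !null2 & !is.na(gt$a1[, l])
    one2 <- null2 & !null1 & !is.na(gt$a1[, l])
    gt$a1[both, l] <- NA_integer_; gt$a2[both, l] <- NA_integer_
    gt$a1[one1, l] <- gt$a2[one1, l]       # visible allele appears homozygous
    gt$a2[one2, l] <- gt$a1[one2, l]
  }
  gt
}
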