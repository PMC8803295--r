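#' Score class assignments against simulation truth
#'
#' Applies [purity_call()] at each threshold and tallies, per true class, the
#' proportions correctly assigned, misassigned (with the predicted class) and
#' unassigned. "Correct" means the posterior probability of the true class
#' reaches the threshold (for thresholds above 0.5 this is the same as the
#' arg-max rule, since at most one class can reach the threshold).
#'
#' With `equivalence = TRUE` the model-indistinguishable groups
#' ([class_equivalences()]) are merged — posteriors summed within a group and
#' truth labels mapped to the group's canonical name — before thresholding,
#' which can only increase correct proportions.
#'
#' @param post A `hybrid_classify` fit or posterior matrix.
#' @param truth Character vector of true class labels, one per individual
#'   (names, if present, must match the posterior row names).
#' @param thresholds Numeric thresholds in (0, 1\] (the reference set is
#'   0.5, 0.75, 0.85, 0.9).
#' @param equivalence Merge model-indistinguishable classes before scoring.
#' @return An `evaluation_report`: list with `per_class` (data.frame:
#'   true_class, threshold, n, correct, misassigned, unassigned),
#'   `confusion` (per-threshold contingency matrices) and `parental_average`
#'   (mean of the P1 and P2 correct proportions per threshold).
#' @export
evaluate_assignments <- function(post, truth,
                                 thresholds = c(0.5, 0.75, 0.85, 0.9),
                                 equivalence = FALSE) {
  m <- if (inherits(post, "hybrid_classify")) post$posterior else as.matrix(post)
  stopifnot(all(thresholds > 0), all(thresholds <= 1))
  if (length(truth) != nrow(m))
    stop("truth must cover all ", nrow(m), " individuals")
  if (!is.null(names(truth)) && !is.null(rownames(m))) {
    off <- names(truth)[names(truth) != rownames(m)]
    if (length(off))
      stop("truth labels mismatch posterior rows: ",
           paste(utils::head(off, 5), collapse = ", "))
  }
  truth <- as.character(truth)
  if (equivalence) {
    map <- canonical_class_map()
    truth <- ifelse(truth %in% names(map), map[truth], truth)
    cols <- colnames(m)
    canon <- ifelse(cols %in% names(map), map[cols], cols)
    m <- vapply(unique(canon), function(g)
      rowSums(m[, canon == g, drop = FALSE]), numeric(nrow(m)))
    colnames(m) <- unique(canon)
  }
  classes <- unique(truth)
  per <- list(); conf <- list(); par_avg <- numeric(0)
  for (th in thresholds) {
    pred <- purity_call(m, th)
    tab <- table(true = factor(truth, classes),
                 predicted = factor(pred, c(colnames(m), "unassigned")))
    conf[[as.character(th)]] <- tab
    for (cl in classes) {
      i <- truth == cl
      corr <- mean(pred[i] == cl)
      unas <- mean(pred[i] == "unassigned")
      per[[length(per) + 1L]] <- data.frame(
        true_class = cl, threshold = th, n = sum(i), correct = corr,
        misassigned = 1 - corr - unas, unassigned = unas)
    }
    pp <- c(if ("P1" %in% classes) mean(pred[truth == "P1"] == "P1"),
            if ("P2" %in% classes) mean(pred[truth == "P2"] == "P2"))
    par_avg <- c(par_avg, stats::setNames(mean(pp), as.character(th)))
  }
  structure(list(per_class = do.call(rbind, per), confusion = conf,
                 parental_average = par_avg, equivalence = equivalence),
            class = "evaluation_report")
}

canonical_class_map <- function() {
  out <- character(0)
  for (grp in class_equivalences())
    for (nm in grp[-1]) out[nm] <- grp[1]
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("assignment evaluation",
      if (x$equivalence) "(equivalence-aware)", "\n")
  wide <- stats::reshape(x$per_class[, c("true_class", "threshold", "correct")],
                         idvar = "true_class", timevar = "threshold",
                         direction = "wide")
  names(wide) <- sub("^correct\\.", "thr ", names(wide))
  print(wide, digits = 3, row.names = FALSE)
  cat("parental average correct:",
      paste(sprintf("%s: %.3f", names(x$parental_average),
                    x$parental_average), collapse = ", "), "\n")
  invisible(x)
}

# posterior-column swap under the A/B relabeling symmetry
swap_symmetric_classes <- function(m) {
  swap <- c(P1 = "P2", P2 = "P1", B1 = "B2", B2 = "B1", B3 = "B4",
            B4 = "B3", B5 = "B6", B6 = "B5", B7 = "B8", B8 = "B7")
  cols <- colnames(m)
  new <- ifelse(cols %in% names(swap), swap[cols], cols)
  m[, match(cols, new), drop = FALSE]
}

#' Replicate the simulation-based assignment evaluation design
#'
#' Runs the three experimental arms of the reference evaluation: datasets of
#' the six genotypic classes classified with six classes (`"6x6"`), datasets
#' of fourteen classes classified with six (`"14x6"`), and fourteen classified
#' with twelve (`"14x12"`); aggregates per-class correct-assignment
#' proportions across replicate datasets both as the unweighted mean and
#' pooled over individuals (replicates share n, so the two coincide up to
#' rounding of counts).
#'
#' Pool labels are anchored by initialization from the most divergent
#' simulated classes; if the label-swap diagnostic fires on a run, the
#' posterior columns are reflected through the A/B symmetry before scoring.
#'
#' @param parental `allele_freq_table` with groups `"A"` and `"B"`.
#' @param cfg A [sim_config()]; `class_set` is overridden per arm.
#' @param arms Subset of `c("6x6", "14x6", "14x12")`.
#' @param iterations,burn_in MCMC budget per run.
#' @param thresholds Assignment thresholds.
#' @param equivalence Score with model-indistinguishable classes merged.
#' @param seed Optional seed.
#' @return Named list (by arm) of lists with `mean_correct` (true class x
#'   threshold matrix of mean correct proportions across datasets), `pooled`
#'   (an `evaluation_report` over all datasets) and `n_datasets`.
#' @export
replicate_study_design <- function(parental, cfg = sim_config(),
                                   arms = c("6x6", "14x6", "14x12"),
                                   iterations = 50000, burn_in = 5000,
                                   thresholds = c(0.5, 0.75, 0.85, 0.9),
                                   equivalence = FALSE, seed = NULL) {
  arms <- match.arg(arms, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  sim_sets <- list()
  get_sets <- function(class_set) {
    if (is.null(sim_sets[[class_set]])) {
      cfg2 <- cfg; cfg2$class_set <- class_set; cfg2$seed <- NULL
      sim_sets[[class_set]] <<- build_evaluation_datasets(parental, cfg2,
                                                          seed = NULL)
    }
    sim_sets[[class_set]]
  }
  out <- list()
  for (arm in arms) {
    sim_set <- if (arm == "6x6") "six" else "fourteen"
    model_set <- if (arm == "14x12") "twelve" else "six"
    datasets <- get_sets(sim_set)
    classes <- standard_class_sets(model_set)
    reports <- list(); posts <- list(); truths <- list()
    for (d in seq_along(datasets)) {
      gt <- datasets[[d]]
      fit <- hybrid_classify(gt, classes, iterations = iterations,
                             burn_in = burn_in, thin = max(iterations %/% 200, 1),
                             seed = NULL)
      post <- fit$posterior
      if (isTRUE(fit$diagnostics$label_swapped))
        post <- swap_symmetric_classes(post)
      truth <- attr(gt, "truth")
      reports[[d]] <- evaluate_assignments(post, truth, thresholds,
                                           equivalence)
      posts[[d]] <- post; truths[[d]] <- truth
    }
    all_classes <- unique(unlist(lapply(reports, function(r)
      unique(r$per_class$true_class))))
    mean_correct <- matrix(0, length(all_classes), length(thresholds),
                           dimnames = list(all_classes, thresholds))
    for (r in reports) {
      pc <- r$per_class
      for (k in seq_len(nrow(pc)))
        mean_correct[pc$true_class[k], as.character(pc$threshold[k])] <-
          mean_correct[pc$true_class[k], as.character(pc$threshold[k])] +
          pc$correct[k] / length(reports)
    }
    pooled <- evaluate_assignments(do.call(rbind, posts),
                                   unlist(truths), thresholds, equivalence)
    out[[arm]] <- list(mean_correct = mean_correct, pooled = pooled,
                       n_datasets = length(datasets))
  }
  out
}
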