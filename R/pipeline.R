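#' Run an end-to-end analysis pipeline
#'
#' Executes the requested stages in dependency order on a genotype file and
#' writes tab-separated result tables plus a provenance manifest (package
#' version, seed, config hash) to the output directory. This is the
#' programmatic orchestration layer; every stage is also available as an
#' individual function.
#'
#' @param config Named list with elements:
#'   `genotypes` (path to a GenePop or genotype CSV; `.csv` is auto-detected),
#'   `samples` (optional sample-sheet path), `env` (optional environmental CSV
#'   with coordinates), `out_dir` (output directory), `seed` (integer),
#'   `stages` (subset of `c("diversity", "amova", "fst", "tree", "classify",
#'   "ancestry", "mantel")`), and optional per-stage parameter lists
#'   `classify` (e.g. `iterations`, `burn_in`, `class_set`), `ancestry`
#'   (`pool_a`, `pool_b` population sets), `tree` (`n_boot`), `amova`/`fst`/
#'   `mantel` (`n_perm`). Unknown keys are rejected.
#' @return Invisibly, a named list of the written file paths.
#' @export
run_pipeline <- function(config) {
  allowed <- c("genotypes", "samples", "env", "out_dir", "seed", "stages",
               "classify", "ancestry", "tree", "amova", "fst", "mantel",
               "diversity")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$genotypes)) stop("config$genotypes is required")
  if (!file.exists(config$genotypes))
    stop("genotype file not found: ", config$genotypes)
  out_dir <- config$out_dir %||% "hybridzone_results"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  stages <- config$stages %||% c("diversity", "amova", "fst", "tree")

  gt <- if (grepl("\\.csv$", config$genotypes, ignore.case = TRUE))
    read_genotype_csv(config$genotypes) else read_genepop(config$genotypes)
  if (!is.null(config$samples)) gt <- read_sample_sheet(config$samples, gt)

  written <- list()
  emit <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written[[name]] <<- path
  }

  if ("diversity" %in% stages) {
    par <- config$diversity %||% list()
    emit(diversity_table(gt, n_perm = par$n_perm %||% 0, seed = seed),
         "diversity")
  }
  fst <- NULL
  if (any(c("fst", "mantel") %in% stages)) {
    par <- config$fst %||% list()
    fst <- pairwise_fst(gt, n_perm = par$n_perm %||% 0, seed = seed)
    emit(as.data.frame(fst$theta), "pairwise_fst")
  }
  if ("amova" %in% stages) {
    par <- config$amova %||% list()
    am <- hierarchical_amova(gt, n_perm = par$n_perm %||% 0, seed = seed)
    emit(data.frame(statistic = names(am$F), value = unname(am$F),
                    p = unname(am$p)), "amova")
  }
  if ("tree" %in% stages) {
    par <- config$tree %||% list()
    tr <- bootstrap_support(gt, n_boot = par$n_boot %||% 100, seed = seed)
    path <- file.path(out_dir, "nj_tree.nwk")
    ape::write.tree(tr, path)
    written[["nj_tree"]] <- path
  }
  if ("classify" %in% stages) {
    par <- config$classify %||% list()
    fit <- hybrid_classify(gt,
                           standard_class_sets(par$class_set %||% "six"),
                           iterations = par$iterations %||% 1e5,
                           burn_in = par$burn_in %||% 1e4, seed = seed)
    post <- as.data.frame(fit$posterior)
    post <- cbind(individual = rownames(post), post)
    post$max_class <- fit$classes[max.col(fit$posterior, ties.method = "first")]
    post$assigned_0.85 <- purity_call(fit, threshold = 0.85)
    emit(post, "class_posterior")
  }
  if ("ancestry" %in% stages) {
    par <- config$ancestry %||% list()
    if (is.null(par$pool_a) || is.null(par$pool_b))
      stop("ancestry stage needs config$ancestry$pool_a and $pool_b")
    grouping <- ifelse(gt$pop %in% par$pool_a, "A",
                       ifelse(gt$pop %in% par$pool_b, "B", "other"))
    ft <- allele_frequencies(gt_subset(gt, which(grouping != "other")),
                             grouping[grouping != "other"])
    est <- triangle_report(hybrid_index(gt, ft, "A", "B"))
    emit(as.data.frame(est), "ancestry")
  }
  if ("mantel" %in% stages) {
    if (is.null(config$env)) stop("mantel stage needs config$env")
    env <- utils::read.csv(config$env, check.names = FALSE)
    par <- config$mantel %||% list()
    dgen <- fst$theta[env$population, env$population]
    dgeo <- geo_distance(env)
    denv <- env_distance(env)
    m1 <- mantel(dgen, dgeo, n_perm = par$n_perm %||% 999, seed = seed)
    m2 <- mantel(dgen, denv, n_perm = par$n_perm %||% 999, seed = seed)
    m3 <- partial_mantel(dgen, denv, dgeo, n_perm = par$n_perm %||% 999,
                         seed = seed)
    m4 <- partial_mantel(dgen, dgeo, denv, n_perm = par$n_perm %||% 999,
                         seed = seed)
    emit(data.frame(test = c("gen_x_geo", "gen_x_env", "gen_x_env.geo",
                             "gen_x_geo.env"),
                    r = c(m1$r, m2$r, m3$r, m4$r),
                    p = c(m1$p, m2$p, m3$p, m4$p)), "mantel")
  }

  manifest <- list(package = "hybridzone",
                   version = as.character(utils::packageVersion("hybridzone")),
                   seed = seed,
                   config_hash = config_hash(config),
                   stages = stages,
                   files = written,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  written[["manifest"]] <- mpath
  invisible(written)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config[order(names(config))], tmp)
  unname(tools::md5sum(tmp))
}
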