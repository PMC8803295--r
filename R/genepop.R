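#' Read a GenePop file
#'
#' Parses the GenePop 4.x text dialect: a title line, locus names (one per
#' line or comma-separated), `POP` separators, and `id , a1a2 a1a2 ...` rows
#' with 2- or 3-digit allele coding. A call of `0000`/`000000` (or any call
#' containing a zero allele) is missing. The coding width is auto-detected per
#' file; mixed widths are rejected.
#'
#' @param path Path to a GenePop file.
#' @param pop_names Optional character vector naming the `POP` blocks in file
#'   order; defaults to `pop1`, `pop2`, ...
#' @return A [genotype_table()] with populations in `POP`-block order and
#'   ecotype `"unknown"`. Duplicated individual ids are made unique by
#'   appending `.2`, `.3`, ... in order of appearance.
#' @export
read_genepop <- function(path, pop_names = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (length(lines) < 3) stop("empty or truncated GenePop file")
  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no POP separator found")
  loc_lines <- lines[2:(first_pop - 1)]
  loci <- unlist(strsplit(loc_lines, ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop("no locus names found")
  L <- length(loci)

  ids <- character(); pops <- integer()
  a1 <- NULL; a2 <- NULL
  rows1 <- list(); rows2 <- list()
  width <- NA_integer_
  pop_idx <- 0L
  for (i in seq(first_pop, length(lines))) {
    ln <- lines[i]
    if (is_pop[i]) { pop_idx <- pop_idx + 1L; next }
    if (!nzchar(trimws(ln))) next
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2)
      stop(sprintf("line %d: expected 'id , calls' (no comma found)", i))
    id <- trimws(parts[1])
    calls <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    if (length(calls) != L)
      stop(sprintf("line %d: %d calls found, %d loci declared",
                   i, length(calls), L))
    if (!all(grepl("^[0-9]+$", calls)))
      stop(sprintf("line %d: non-numeric call string", i))
    w <- unique(nchar(calls)) / 2
    if (length(w) > 1 || !w %in% c(2, 3) ||
        (!is.na(width) && w != width))
      stop(sprintf("line %d: inconsistent allele-code width", i))
    width <- as.integer(w)
    x1 <- as.integer(substr(calls, 1, width))
    x2 <- as.integer(substr(calls, width + 1, 2 * width))
    miss <- x1 == 0L | x2 == 0L
    x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
    ids <- c(ids, id); pops <- c(pops, pop_idx)
    rows1[[length(rows1) + 1L]] <- x1
    rows2[[length(rows2) + 1L]] <- x2
  }
  if (!length(ids)) stop("zero individuals in GenePop file")
  if (is.null(pop_names)) pop_names <- paste0("pop", seq_len(max(pops)))
  if (length(pop_names) < max(pops)) stop("too few pop_names for POP blocks")
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = ".")
  genotype_table(ids, loci, do.call(rbind, rows1), do.call(rbind, rows2),
                 pop_names[pops])
}

#' Write a GenePop file
#'
#' @param gt A [genotype_table()]. Individuals are grouped into `POP` blocks
#'   by population, in order of first appearance.
#' @param path Output path.
#' @param title Title line.
#' @param digits Allele-code width, 2 or 3; auto-selected from the largest
#'   allele code when `NULL`.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(gt, path, title = "hybridzone export",
                          digits = NULL) {
  mx <- suppressWarnings(max(gt$a2, na.rm = TRUE))
  if (!is.finite(mx)) mx <- 1L
  if (is.null(digits)) digits <- if (mx > 99) 3L else 2L
  if (mx >= 10^digits)
    stop("allele codes too large for ", digits, "-digit GenePop coding")
  fmt <- function(m) {
    out <- sprintf(paste0("%0", digits, "d"), m)
    out[is.na(m)] <- strrep("0", digits)
    out
  }
  s1 <- matrix(fmt(gt$a1), nrow = length(gt$ids))
  s2 <- matrix(fmt(gt$a2), nrow = length(gt$ids))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(gt$loci, con)
  for (p in unique(gt$pop)) {
    writeLines("POP", con)
    for (i in which(gt$pop == p)) {
      writeLines(paste0(gt$ids[i], " ,  ",
                        paste0(s1[i, ], s2[i, ], collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read/write a CSV genotype table
#'
#' Columns: `individual`, `population`, `ecotype`, then one column per locus
#' holding `a1/a2` (empty for missing).
#'
#' @param path File path.
#' @return For the reader, a [genotype_table()].
#' @export
read_genotype_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("individual", "population", "ecotype")
  if (!all(need %in% names(d)))
    stop("genotype CSV must have columns individual, population, ecotype")
  loci <- setdiff(names(d), need)
  if (!length(loci)) stop("no locus columns in genotype CSV")
  n <- nrow(d)
  a1 <- a2 <- matrix(NA_integer_, n, length(loci))
  for (j in seq_along(loci)) {
    v <- d[[loci[j]]]
    ok <- !is.na(v) & nzchar(v)
    parts <- strsplit(v[ok], "/", fixed = TRUE)
    if (any(lengths(parts) != 2))
      stop("locus column ", loci[j], ": calls must be 'a1/a2'")
    a1[ok, j] <- as.integer(vapply(parts, `[`, "", 1))
    a2[ok, j] <- as.integer(vapply(parts, `[`, "", 2))
  }
  eco <- d$ecotype
  eco[is.na(eco) | !nzchar(eco)] <- "unknown"
  genotype_table(d$individual, loci, a1, a2, d$population, eco)
}

#' @rdname read_genotype_csv
#' @param gt A [genotype_table()].
#' @export
write_genotype_csv <- function(gt, path) {
  calls <- matrix("", length(gt$ids), length(gt$loci))
  ok <- !is.na(gt$a1)
  calls[ok] <- paste0(gt$a1[ok], "/", gt$a2[ok])
  d <- data.frame(individual = gt$ids, population = gt$pop,
                  ecotype = gt$ecotype, check.names = FALSE)
  for (j in seq_along(gt$loci)) d[[gt$loci[j]]] <- calls[, j]
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Attach sample-sheet metadata to a genotype table
#'
#' Reads a delimited sheet with columns `individual`, `population`, `ecotype`
#' and optional `latitude`/`longitude`, and attaches the labels to a genotype
#' table. Individuals present in the sheet but absent from the genotypes are
#' reported in the `discrepancies` attribute; genotyped individuals missing
#' from the sheet keep ecotype `"unknown"` (with a warning).
#'
#' @param path Path to a CSV or TSV sheet (delimiter auto-detected from the
#'   header line).
#' @param gt A [genotype_table()].
#' @return `gt` with labels attached; attribute `discrepancies` holds sheet
#'   individuals not found in the genotypes, and attribute `coords` a
#'   data.frame of coordinates when present.
#' @export
read_sample_sheet <- function(path, gt) {
  hdr <- readLines(path, n = 1)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  d <- utils::read.table(path, sep = sep, header = TRUE,
                         colClasses = "character", check.names = FALSE)
  if (!"individual" %in% names(d)) stop("sample sheet needs column 'individual'")
  if (anyDuplicated(d$individual))
    stop("duplicate individual rows in sample sheet: ",
         paste(unique(d$individual[duplicated(d$individual)]), collapse = ", "))
  if ("ecotype" %in% names(d)) {
    eco <- d$ecotype
    eco[is.na(eco) | !nzchar(eco)] <- "unknown"
    bad <- setdiff(unique(eco), c("savanna", "forest", "unknown"))
    if (length(bad))
      stop("unknown ecotype token(s) in sheet: ", paste(bad, collapse = ", "),
           " (allowed: savanna, forest, unknown)")
  } else eco <- rep("unknown", nrow(d))
  m <- match(gt$ids, d$individual)
  if (anyNA(m))
    warning(sum(is.na(m)), " genotyped individual(s) absent from sample sheet",
            " keep ecotype 'unknown'")
  pop <- gt$pop
  if ("population" %in% names(d)) pop[!is.na(m)] <- d$population[m[!is.na(m)]]
  ecot <- gt$ecotype
  ecot[!is.na(m)] <- eco[m[!is.na(m)]]
  out <- genotype_table(gt$ids, gt$loci, gt$a1, gt$a2, pop, ecot)
  attr(out, "discrepancies") <- setdiff(d$individual, gt$ids)
  if (all(c("latitude", "longitude") %in% names(d))) {
    attr(out, "coords") <- data.frame(
      individual = d$individual,
      latitude = as.numeric(d$latitude),
      longitude = as.numeric(d$longitude))
  }
  out
}
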