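#' @keywords internal
"_PACKAGE"

MISSING <- -1L

#' Construct a validated STR genotype matrix
#'
#' A genotype matrix holds one haploid-coded multilocus STR profile per
#' sample: integer allele codes (>= 0) with missing values coded as -1.
#' Allele labels are arbitrary integers and are never recoded.
#'
#' @param values integer matrix, samples x loci; entries >= -1.
#' @param sample_ids character vector of unique sample identifiers
#'   (defaults to rownames of `values`).
#' @param locus_ids character vector of unique locus identifiers
#'   (defaults to colnames of `values`).
#' @return an object of class `genotype_matrix` (an integer matrix with
#'   sample ids as rownames and locus ids as colnames).
#' @export
genotype_matrix <- function(values, sample_ids = rownames(values),
                            locus_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(sample_ids) || is.null(locus_ids))
    stop("sample_ids and locus_ids are required", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(locus_ids))
    stop("duplicate locus ids", call. = FALSE)
  if (length(sample_ids) != nrow(values) || length(locus_ids) != ncol(values))
    stop("id lengths do not match matrix dimensions", call. = FALSE)
  storage.mode(values) <- "integer"
  if (anyNA(values) || any(values < MISSING))
    stop("allele codes must be integers >= -1 (missing = -1)", call. = FALSE)
  dimnames(values) <- list(as.character(sample_ids), as.character(locus_ids))
  class(values) <- c("genotype_matrix", class(matrix()))
  values
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci, %d missing (%.2f%%)\n",
              nrow(x), ncol(x), sum(x == MISSING),
              100 * mean(x == MISSING)))
  invisible(x)
}

#' Read an STR genotype matrix from TSV
#'
#' The file has a header row of locus ids; the first column holds sample
#' ids, the remaining columns integer allele codes or a missing token.
#'
#' @param path path to a tab-separated text file.
#' @param missing_token tokens to read as missing; any cell equal to one
#'   of these becomes -1. Default accepts both `"?"` and `"-9"`
#'   (STRUCTURE-format convention).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, missing_token = c("?", "-9")) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2L) stop("genotype file needs >= 1 locus column", call. = FALSE)
  sample_ids <- raw[[1L]]
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  locus_ids <- colnames(cells)
  is_missing <- cells %in% missing_token
  dim(is_missing) <- dim(cells)
  parsed <- suppressWarnings(as.integer(cells))
  dim(parsed) <- dim(cells)
  bad <- !is_missing & (is.na(parsed) | cells != as.character(parsed))
  if (any(bad)) {
    stop(sprintf("non-integer genotype cell(s), e.g. '%s'", cells[bad][1L]),
         call. = FALSE)
  }
  parsed[is_missing] <- MISSING
  if (any(parsed < MISSING, na.rm = TRUE))
    stop("allele codes must be >= 0", call. = FALSE)
  genotype_matrix(parsed, sample_ids, locus_ids)
}

#' Write a genotype matrix to TSV
#'
#' Inverse of [read_genotypes()]; missing entries are written as
#' `missing_token`.
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @param missing_token token written for missing entries.
#' @export
write_genotypes <- function(g, path, missing_token = "?") {
  out <- matrix(as.character(g), nrow(g), ncol(g))
  out[g == MISSING] <- missing_token
  df <- data.frame(sample_id = rownames(g), out, check.names = FALSE)
  colnames(df) <- c("sample_id", colnames(g))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a chromosome map
#'
#' Assigns every locus to a linkage group (chromosome) with a position;
#' positions must be strictly increasing within a chromosome.
#'
#' @param locus_id character vector of locus ids (unique).
#' @param chrom character vector of chromosome ids, parallel to `locus_id`.
#' @param pos numeric positions, strictly increasing within each chromosome.
#' @return an object of class `chromosome_map`: a data.frame with columns
#'   `locus_id`, `chrom`, `pos` and an attribute `chrom_order` listing the
#'   chromosomes in order of first appearance.
#' @export
chromosome_map <- function(locus_id, chrom, pos) {
  if (anyDuplicated(locus_id)) stop("duplicate locus ids in map", call. = FALSE)
  df <- data.frame(locus_id = as.character(locus_id),
                   chrom = as.character(chrom),
                   pos = as.numeric(pos), stringsAsFactors = FALSE)
  chrom_order <- unique(df$chrom)
  if (length(chrom_order) < 1L) stop("map needs >= 1 chromosome", call. = FALSE)
  for (cc in chrom_order) {
    p <- df$pos[df$chrom == cc]
    if (any(diff(p) <= 0))
      stop(sprintf("positions not strictly increasing on chromosome %s", cc),
           call. = FALSE)
  }
  attr(df, "chrom_order") <- chrom_order
  class(df) <- c("chromosome_map", "data.frame")
  df
}

#' Read a chromosome map from TSV (columns locus_id, chrom, pos)
#' @param path path to a tab-separated file with a header.
#' @return a [chromosome_map()].
#' @export
read_chromosome_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "numeric"))
  chromosome_map(df[[1L]], df[[2L]], df[[3L]])
}

#' Write a chromosome map to TSV
#' @param map a [chromosome_map()].
#' @param path output path.
#' @export
write_chromosome_map <- function(map, path) {
  utils::write.table(as.data.frame(map)[c("locus_id", "chrom", "pos")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_map_covers <- function(g, map) {
  if (!setequal(colnames(g), map$locus_id) ||
      length(map$locus_id) != ncol(g))
    stop("chromosome map does not cover exactly the matrix loci", call. = FALSE)
}

map_loci <- function(map, chrom) {
  map$locus_id[map$chrom == chrom][order(map$pos[map$chrom == chrom])]
}

#' Impute missing genotypes from the most common compatible haplotype
#'
#' Missing entries of a sample on a chromosome are filled from the most
#' frequent complete per-chromosome haplotype (among samples with no
#' missing value on that chromosome) that agrees with the sample at all of
#' its observed loci there. When no compatible complete haplotype exists,
#' each missing locus falls back to the per-locus modal allele. All ties
#' are broken by a seeded uniform draw, so a seed fully determines the
#' result. Observed cells are never changed, and the operation is
#' idempotent.
#'
#' @param g a [genotype_matrix()], possibly with -1 entries.
#' @param map a [chromosome_map()] covering the loci of `g`.
#' @param seed integer seed for tie-breaking.
#' @return a [genotype_matrix()] with no missing entries.
#' @export
impute_missing <- function(g, map, seed = 1L) {
  check_map_covers(g, map)
  if (!any(g == MISSING)) return(g)
  rng <- make_rng(seed)
  out <- unclass(g)
  for (cc in attr(map, "chrom_order")) {
    loci <- map_loci(map, cc)
    sub <- out[, loci, drop = FALSE]
    complete <- rowSums(sub == MISSING) == 0L
    keys <- apply(sub[complete, , drop = FALSE], 1L, paste, collapse = ",")
    counts <- sort(table(keys), decreasing = TRUE)
    haps <- unique(sub[complete, , drop = FALSE])
    hap_keys <- apply(haps, 1L, paste, collapse = ",")
    hap_count <- as.integer(counts[hap_keys])
    needs <- which(!complete & rowSums(sub == MISSING) > 0L)
    for (s in needs) {
      obs <- sub[s, ] != MISSING
      if (nrow(haps) > 0L) {
        if (any(obs)) {
          ok <- rowSums(haps[, obs, drop = FALSE] !=
                          matrix(sub[s, obs], nrow(haps), sum(obs),
                                 byrow = TRUE)) == 0L
        } else {
          ok <- rep(TRUE, nrow(haps))
        }
      } else ok <- logical(0L)
      if (any(ok)) {
        best <- which(ok & hap_count == max(hap_count[ok]))
        pick <- if (length(best) > 1L) best[rng$draw(length(best))] else best
        fill <- haps[pick, !obs]
      } else {
        fill <- vapply(which(!obs), function(j) {
          col <- sub[, j]
          col <- col[col != MISSING]
          if (length(col) == 0L)
            stop(sprintf("locus %s missing in every sample", loci[j]),
                 call. = FALSE)
          tab <- table(col)
          modes <- as.integer(names(tab)[tab == max(tab)])
          if (length(modes) > 1L) modes[rng$draw(length(modes))] else modes
        }, integer(1L))
      }
      sub[s, !obs] <- fill
    }
    # loci with no complete haplotype at all still need the modal fallback
    still <- which(colSums(sub == MISSING) > 0L)
    for (j in still) {
      col <- sub[, j]
      obs_col <- col[col != MISSING]
      if (length(obs_col) == 0L)
        stop(sprintf("locus %s missing in every sample", loci[j]),
             call. = FALSE)
      tab <- table(obs_col)
      modes <- as.integer(names(tab)[tab == max(tab)])
      m <- if (length(modes) > 1L) modes[rng$draw(length(modes))] else modes
      sub[col == MISSING, j] <- m
    }
    out[, loci] <- sub
  }
  genotype_matrix(out, rownames(g), colnames(g))
}

#' Summarize an STR panel
#'
#' Per-locus distinct-allele and missing counts (distinct alleles computed
#' on non-missing entries only), per-chromosome locus counts, and the
#' overall missing fraction.
#'
#' @param g a [genotype_matrix()].
#' @param map a [chromosome_map()] covering the loci of `g`.
#' @return an object of class `panel_summary`: a list with elements
#'   `distinct_alleles`, `missing_per_locus` (named integer vectors),
#'   `loci_per_chromosome` and `missing_fraction`.
#' @export
summarize_panel <- function(g, map) {
  check_map_covers(g, map)
  distinct <- apply(g, 2L, function(col) length(unique(col[col != MISSING])))
  missing <- colSums(g == MISSING)
  per_chrom <- vapply(attr(map, "chrom_order"),
                      function(cc) sum(map$chrom == cc), integer(1L))
  out <- list(distinct_alleles = distinct,
              missing_per_locus = missing,
              loci_per_chromosome = per_chrom,
              missing_fraction = sum(g == MISSING) / length(g))
  class(out) <- "panel_summary"
  out
}

#' @export
print.panel_summary <- function(x, ...) {
  cat(sprintf("STR panel: %d loci over %d chromosomes\n",
              length(x$distinct_alleles), length(x$loci_per_chromosome)))
  cat(sprintf("distinct alleles per locus: %d-%d (median %.0f)\n",
              min(x$distinct_alleles), max(x$distinct_alleles),
              stats::median(x$distinct_alleles)))
  cat(sprintf("missing fraction: %.4f\n", x$missing_fraction))
  invisible(x)
}

#' Subset a genotype matrix to a set of samples
#'
#' @param g a [genotype_matrix()].
#' @param ids sample ids to keep, in the requested order.
#' @return a row-subset [genotype_matrix()] in the given order.
#' @export
subset_samples <- function(g, ids) {
  ids <- as.character(ids)
  unknown <- setdiff(ids, rownames(g))
  if (length(unknown) > 0L)
    stop(sprintf("unknown sample id(s): %s",
                 paste(utils::head(unknown, 3L), collapse = ", ")),
         call. = FALSE)
  genotype_matrix(unclass(g)[ids, , drop = FALSE], ids, colnames(g))
}

# Small counter-based RNG wrapper: isolates tie-break draws from the
# global RNG state so callers' streams are not perturbed.
make_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed) %% .Machine$integer.max)
    st <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    st
  })
  env$draw <- function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    k <- sample.int(n, 1L)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    k
  }
  env
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(expr)
}
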