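#' Draw a randomized ensemble layout of chromosomes
#'
#' The ensemble method concatenates all chromosomes into one staged
#' sequence: chromosomes are placed in a uniformly random order on a
#' circular ring, each is independently flipped (locus order reversed)
#' with probability 1/2, and the ring is cut at a position drawn
#' uniformly over the inter-locus boundaries, then flattened 5' to 3'.
#'
#' @param map a [chromosome_map()].
#' @param seed integer; the layout is deterministic given the seed.
#' @param chrom_order,flipped,cut_index optional overrides forcing a
#'   specific layout component (used for replay and testing); any that is
#'   `NULL` is drawn randomly.
#' @return an object of class `ensemble_layout`: list with
#'   `chrom_order` (permutation of chromosome ids), `flipped` (named
#'   logical), `cut_index` (0-based ring boundary in `[0, n_loci)`),
#'   `staged_locus_order` and `seed`.
#' @export
build_ensemble <- function(map, seed = 1L, chrom_order = NULL,
                           flipped = NULL, cut_index = NULL) {
  chroms <- attr(map, "chrom_order")
  with_seed(seed, {
    if (is.null(chrom_order))
      chrom_order <- chroms[sample.int(length(chroms))]
    if (is.null(flipped)) {
      flipped <- stats::runif(length(chrom_order)) < 0.5
      names(flipped) <- chrom_order
    }
    n_loci <- length(map$locus_id)
    if (is.null(cut_index))
      cut_index <- sample.int(n_loci, 1L) - 1L
  })
  if (!setequal(chrom_order, chroms))
    stop("chrom_order must be a permutation of the map's chromosomes",
         call. = FALSE)
  flipped <- flipped[chrom_order]
  ring <- unlist(lapply(chrom_order, function(cc) {
    loci <- map_loci(map, cc)
    if (flipped[[cc]]) rev(loci) else loci
  }), use.names = FALSE)
  n <- length(ring)
  if (cut_index < 0L || cut_index >= n)
    stop("cut_index must lie in [0, n_loci)", call. = FALSE)
  staged <- if (cut_index == 0L) ring else
    c(ring[(cut_index + 1L):n], ring[1L:cut_index])
  structure(list(chrom_order = chrom_order,
                 flipped = flipped,
                 cut_index = as.integer(cut_index),
                 staged_locus_order = staged,
                 seed = as.integer(seed)),
            class = "ensemble_layout")
}

#' @export
print.ensemble_layout <- function(x, ...) {
  cat(sprintf("ensemble_layout: %d chromosomes, %d loci, cut at %d\n",
              length(x$chrom_order), length(x$staged_locus_order),
              x$cut_index))
  cat("order:", paste0(x$chrom_order, ifelse(x$flipped, "'", ""),
                       collapse = " "), "\n")
  invisible(x)
}

#' Serialize / restore an ensemble layout as JSON
#' @param layout an `ensemble_layout`.
#' @param path file path.
#' @export
write_layout <- function(layout, path) {
  jsonlite::write_json(list(chrom_order = layout$chrom_order,
                            flipped = as.list(layout$flipped),
                            cut_index = layout$cut_index,
                            staged_locus_order = layout$staged_locus_order,
                            seed = layout$seed),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(chrom_order = x$chrom_order,
                 flipped = unlist(x$flipped),
                 cut_index = as.integer(x$cut_index),
                 staged_locus_order = x$staged_locus_order,
                 seed = as.integer(x$seed)),
            class = "ensemble_layout")
}

#' Reorder a genotype matrix by an ensemble layout
#'
#' @param g an imputed [genotype_matrix()] (no missing values).
#' @param layout an `ensemble_layout` over the same loci.
#' @return a column-reordered [genotype_matrix()] following
#'   `layout$staged_locus_order`.
#' @export
stage_ensemble <- function(g, layout) {
  if (!setequal(colnames(g), layout$staged_locus_order) ||
      ncol(g) != length(layout$staged_locus_order))
    stop("layout loci do not match matrix loci", call. = FALSE)
  genotype_matrix(unclass(g)[, layout$staged_locus_order, drop = FALSE],
                  rownames(g), layout$staged_locus_order)
}

#' Stage chromosomes separately (solo method)
#'
#' @param g a [genotype_matrix()].
#' @param map a [chromosome_map()] covering the loci of `g`.
#' @param chroms chromosome ids to stage, or `"all"`.
#' @return a named list of per-chromosome [genotype_matrix()] objects,
#'   loci in map order.
#' @export
stage_solo <- function(g, map, chroms = "all") {
  check_map_covers(g, map)
  all_chroms <- attr(map, "chrom_order")
  if (identical(chroms, "all")) chroms <- all_chroms
  unknown <- setdiff(chroms, all_chroms)
  if (length(unknown) > 0L)
    stop(sprintf("unknown chromosome(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  if (length(chroms) == 0L) stop("no chromosomes requested", call. = FALSE)
  out <- lapply(chroms, function(cc) {
    loci <- map_loci(map, cc)
    genotype_matrix(unclass(g)[, loci, drop = FALSE], rownames(g), loci)
  })
  names(out) <- chroms
  out
}

#' Pick the longest chromosomes by locus count
#'
#' "Length" is the chromosome's locus count; ties are broken by map
#' order.
#'
#' @param map a [chromosome_map()].
#' @param n how many chromosomes.
#' @return character vector of chromosome ids.
#' @export
longest_chromosomes <- function(map, n = 3L) {
  chroms <- attr(map, "chrom_order")
  sizes <- vapply(chroms, function(cc) sum(map$chrom == cc), integer(1L))
  chroms[order(-sizes)][seq_len(min(n, length(chroms)))]
}
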