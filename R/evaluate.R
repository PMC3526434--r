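#' Contingency table of a reference vs a computed partition
#'
#' `m[i, j]` counts samples in reference cluster `i` and computed
#' cluster `j`.
#'
#' @param ref named vector: sample -> reference cluster label.
#' @param comp named vector: sample -> computed cluster label, same
#'   sample set.
#' @return an object of class `contingency_table`: an integer count
#'   matrix with reference labels as rownames and computed labels as
#'   colnames.
#' @export
contingency <- function(ref, comp) {
  if (!setequal(names(ref), names(comp)) || length(ref) != length(comp))
    stop("reference and computed partitions cover different samples",
         call. = FALSE)
  comp <- comp[names(ref)]
  tab <- table(factor(as.character(ref)), factor(as.character(comp)))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  structure(m, class = c("contingency_table", class(matrix())))
}

#' Build a contingency table directly from counts
#' @param counts integer matrix of intersection counts.
#' @param ref_labels,comp_labels row / column labels.
#' @return a `contingency_table`.
#' @export
contingency_from_counts <- function(counts, ref_labels = rownames(counts),
                                    comp_labels = colnames(counts)) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (any(counts < 0L)) stop("counts must be >= 0", call. = FALSE)
  dimnames(counts) <- list(ref_labels, comp_labels)
  structure(counts, class = c("contingency_table", class(matrix())))
}

#' Diagonal-maximizing label assignment
#'
#' Permutes the columns of a square contingency table so that the
#' diagonal sum is maximal (exact maximum-weight assignment, solved by
#' dynamic programming over column subsets); ties are broken by the
#' lexicographically smallest column permutation. Column labels inherit
#' the row labels through the mapping, defining the one-to-one
#' correspondence of computed clusters to reference clusters.
#'
#' @param m_prime a square `contingency_table`.
#' @return the column-permuted table, with attributes `permutation`
#'   (original column index assigned to each row) and
#'   `original_labels`.
#' @export
assign_labels <- function(m_prime) {
  k <- nrow(m_prime)
  if (k != ncol(m_prime)) stop("table must be square", call. = FALSE)
  if (k > 25L) stop("assignment DP limited to k <= 25", call. = FALSE)
  m <- unclass(m_prime)
  n_mask <- bitwShiftL(1L, k)
  popcount <- integer(n_mask)
  for (mask in seq_len(n_mask - 1L))
    popcount[mask + 1L] <- popcount[bitwShiftR(mask, 1L) + 1L] +
      bitwAnd(mask, 1L)
  # suffix[mask + 1]: best diagonal sum for rows popcount(mask)+1 .. k
  # over the columns NOT in `mask`
  suffix <- rep(-Inf, n_mask)
  suffix[n_mask] <- 0
  for (mask in (n_mask - 2L):0L) {
    row <- popcount[mask + 1L] + 1L
    best <- -Inf
    for (j in seq_len(k)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) == 0L) {
        cand <- m[row, j] + suffix[bitwOr(mask, bit) + 1L]
        if (cand > best) best <- cand
      }
    }
    suffix[mask + 1L] <- best
  }
  # greedy reconstruction = lexicographically smallest optimal permutation
  perm <- integer(k)
  mask <- 0L
  for (row in seq_len(k)) {
    for (j in seq_len(k)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) != 0L) next
      if (m[row, j] + suffix[bitwOr(mask, bit) + 1L] == suffix[mask + 1L]) {
        perm[row] <- j
        mask <- bitwOr(mask, bit)
        break
      }
    }
  }
  out <- m[, perm, drop = FALSE]
  colnames(out) <- rownames(m)
  out <- structure(out, class = c("contingency_table", class(matrix())))
  attr(out, "permutation") <- perm
  attr(out, "original_labels") <- colnames(m_prime)[perm]
  out
}

#' Per-pair precision and recall of a labeled contingency table
#'
#' `Prec[i, j] = m[i, j] / p_j` (column sum) and
#' `Rec[i, j] = m[i, j] / c_i` (row sum); an empty cluster yields 0 with
#' a warning rather than an error, so degenerate clusterings remain
#' scorable.
#'
#' @param m a `contingency_table` (typically labeled via
#'   [assign_labels()]).
#' @return list with matrices `precision` and `recall` and vectors
#'   `row_sums` (`c_i`), `col_sums` (`p_j`) and total `n`.
#' @export
precision_recall <- function(m) {
  m <- unclass(m)
  ci <- rowSums(m)
  pj <- colSums(m)
  if (any(ci == 0) || any(pj == 0))
    warning("empty cluster: precision/recall set to 0")
  prec <- sweep(m, 2L, ifelse(pj == 0, 1, pj), "/")
  prec[, pj == 0] <- 0
  rec <- sweep(m, 1L, ifelse(ci == 0, 1, ci), "/")
  rec[ci == 0, ] <- 0
  list(precision = prec, recall = rec, row_sums = ci, col_sums = pj,
       n = sum(m))
}

#' Overall F-index of a labeled contingency table
#'
#' Per-pair `F[i, j]` is the weighted harmonic mean of precision and
#' recall with weight `alpha2`
#' (`(alpha2 + 1) Prec Rec / (alpha2 Prec + Rec)`, 0 when the cell is
#' empty); the overall index is the cluster-size-weighted best match
#' `F = sum_i (c_i / n) max_j F[i, j]`, in `[0, 1]`.
#'
#' @param m a labeled `contingency_table`.
#' @param alpha2 precision/recall weight (1 = equal weighting).
#' @return list with `F` (overall index), `F_pair` (per-pair matrix)
#'   and the [precision_recall()] report.
#' @export
f_index <- function(m, alpha2 = 1.0) {
  if (alpha2 <= 0) stop("alpha2 must be > 0", call. = FALSE)
  pr <- precision_recall(m)
  if (pr$n == 0L) stop("empty contingency table", call. = FALSE)
  num <- (alpha2 + 1) * pr$precision * pr$recall
  den <- alpha2 * pr$precision + pr$recall
  Fp <- ifelse(den == 0, 0, num / den)
  Fv <- sum(pr$row_sums / pr$n * apply(Fp, 1L, max))
  list(F = Fv, F_pair = Fp, precision = pr$precision, recall = pr$recall,
       row_sums = pr$row_sums, col_sums = pr$col_sums, n = pr$n)
}

# non-trivial splits (bipartitions) of an unrooted tree, one per
# internal edge, canonicalized as sorted label strings of the side not
# containing the lexicographically smallest tip (so representations
# agree across trees regardless of their internal tip order)
tree_splits <- function(tr) {
  internal <- tree_internal_edges(tr)
  if (length(internal) == 0L) return(character(0L))
  ref <- min(tr$tip.label)
  vapply(internal, function(e) {
    node <- tr$edge[e, 2L]
    tips <- tr$tip.label[tips_below(tr, node)]
    side <- if (ref %in% tips) setdiff(tr$tip.label, tips) else tips
    paste(sort(side), collapse = "|")
  }, character(1L))
}

tips_below <- function(tr, node) {
  n <- length(tr$tip.label)
  if (node <= n) return(node)
  kids <- tr$edge[tr$edge[, 1L] == node, 2L]
  unlist(lapply(kids, function(k) tips_below(tr, k)))
}

#' Partition metric between two classification trees
#'
#' `d_p(T1, T2) = E(T1) + E(T2) - 2 v(T1, T2)`, where `E(T)` counts the
#' edges of `T` not incident on a leaf and `v` counts identical
#' leaf-set splits induced by deleting an internal edge from each tree.
#' Lies in `[0, E(T1) + E(T2)]`.
#'
#' @param t1,t2 `ape::phylo` trees over the same leaf set.
#' @return integer distance.
#' @export
partition_metric <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets", call. = FALSE)
  s1 <- tree_splits(t1)
  s2 <- tree_splits(t2)
  E1 <- length(s1); E2 <- length(s2)
  v <- length(intersect(unique(s1), unique(s2)))
  as.integer(E1 + E2 - 2L * v)
}

#' Agreement index between two classification trees
#'
#' `A = 1 - d_p(T1, T2) / (E(T1) + E(T2))`, in `[0, 1]`; 1 means
#' identical split sets. When partitions are supplied, each tree is
#' first reduced by the majority-class rule: for every reference class,
#' only the samples falling in that tree's plurality cluster for the
#' class are kept (classes split across subtrees are represented by
#' their largest subset only), both trees are pruned to the common kept
#' leaves, and the index is computed on the reduced trees.
#'
#' @param t1,t2 `ape::phylo` trees over the same leaf set.
#' @param ref optional named reference class vector (sample -> class).
#' @param part1,part2 optional named cluster vectors for `t1` and `t2`
#'   (e.g. from [cut_to_k()]) used by the majority-class reduction;
#'   required when `ref` is given.
#' @return agreement index in `[0, 1]`.
#' @export
agreement_index <- function(t1, t2, ref = NULL, part1 = NULL, part2 = NULL) {
  if (!is.null(ref)) {
    if (is.null(part1) || is.null(part2))
      stop("majority-class reduction needs part1 and part2", call. = FALSE)
    keep1 <- majority_class_samples(ref, part1)
    keep2 <- majority_class_samples(ref, part2)
    keep <- intersect(keep1, keep2)
    if (length(keep) < 3L)
      stop("empty (or too small) taxon intersection after reduction",
           call. = FALSE)
    t1 <- ape::keep.tip(t1, keep)
    t2 <- ape::keep.tip(t2, keep)
  }
  s1 <- tree_splits(t1)
  s2 <- tree_splits(t2)
  E <- length(s1) + length(s2)
  if (E == 0L) return(1)
  v <- length(intersect(unique(s1), unique(s2)))
  1 - (E - 2 * v) / E
}

# samples in each reference class's plurality cluster of `part`
majority_class_samples <- function(ref, part) {
  part <- part[names(ref)]
  unlist(lapply(split(names(ref), as.character(ref)), function(ids) {
    tab <- sort(table(as.character(part[ids])), decreasing = TRUE)
    major <- names(tab)[1L]
    ids[as.character(part[ids]) == major]
  }), use.names = FALSE)
}

#' Round half-up for display
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded values (half-way cases away from zero).
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Write / read a contingency table as CSV with labels
#' @param m a `contingency_table`.
#' @param path file path.
#' @export
write_contingency <- function(m, path) {
  utils::write.csv(as.data.frame(unclass(m)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_contingency
#' @export
read_contingency <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  contingency_from_counts(as.matrix(df))
}
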