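#' Relaxed neighbor-joining classification tree
#'
#' Standard neighbor joining (Q-criterion agglomeration) on the
#' consolidated distance matrix, with negative branch lengths clamped to
#' zero — the "relaxed" reading used throughout this package.
#'
#' @param d symmetric distance matrix with sample ids as dimnames,
#'   n >= 3.
#' @return an unrooted `ape::phylo` tree with non-negative branch
#'   lengths.
#' @export
nnj_tree <- function(d) {
  if (nrow(d) < 3L) stop("need >= 3 samples for a tree", call. = FALSE)
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

tree_internal_edges <- function(tr) {
  n <- length(tr$tip.label)
  which(tr$edge[, 1L] > n & tr$edge[, 2L] > n)
}

#' Cut a classification tree into k clusters
#'
#' Prunes the tree at its internal edges, splitting the leaf set into
#' the tree's local subtrees (leaves grouped around a common internal
#' node), then iteratively merges the two parts with smallest average
#' inter-part distance until exactly k clusters remain. For k larger
#' than the number of subtrees, multi-leaf parts are split by removing
#' their longest pendant edges first.
#'
#' @param tr an `ape::phylo` tree over the samples.
#' @param d the distance matrix used to build the tree (for merging).
#' @param k number of clusters, `1 <= k <= n`.
#' @return a partition: named integer vector (sample -> cluster index in
#'   `0..k-1`), every cluster non-empty.
#' @export
cut_to_k <- function(tr, d, k) {
  n <- length(tr$tip.label)
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k == 1L) {
    out <- rep(0L, n); names(out) <- tr$tip.label
    return(out)
  }
  cut_edges <- tree_internal_edges(tr)
  parts <- leaf_components(tr, cut_edges)
  # too few parts (k near n): split by longest pendant edges
  while (length(parts) < k) {
    pend <- which(tr$edge[, 2L] <= n)
    multi <- vapply(parts, length, integer(1L)) > 1L
    cand <- pend[tr$edge[pend, 2L] %in%
                   unlist(lapply(which(multi), function(i)
                     match(parts[[i]], tr$tip.label)))]
    best <- cand[order(-tr$edge.length[cand], cand)][1L]
    cut_edges <- c(cut_edges, best)
    parts <- leaf_components(tr, cut_edges)
  }
  # merge the closest pair by average inter-part distance until k remain
  P <- length(parts)
  sz <- vapply(parts, length, integer(1L))
  pd <- matrix(Inf, P, P)
  for (i in seq_len(P - 1L)) for (j in (i + 1L):P)
    pd[i, j] <- pd[j, i] <- mean(d[parts[[i]], parts[[j]]])
  alive <- rep(TRUE, P)
  while (sum(alive) > k) {
    idx <- which(alive)
    sub <- pd[idx, idx, drop = FALSE]
    pos <- which(sub == min(sub), arr.ind = TRUE)[1L, ]
    i <- idx[min(pos)]; j <- idx[max(pos)]
    # weighted average-linkage update
    for (o in idx) {
      if (o == i || o == j) next
      pd[i, o] <- pd[o, i] <-
        (sz[i] * pd[i, o] + sz[j] * pd[j, o]) / (sz[i] + sz[j])
    }
    parts[[i]] <- c(parts[[i]], parts[[j]])
    sz[i] <- sz[i] + sz[j]
    alive[j] <- FALSE
  }
  parts <- parts[alive]
  out <- integer(n); names(out) <- tr$tip.label
  for (i in seq_along(parts)) out[parts[[i]]] <- i - 1L
  out
}

# leaf label sets of the components left after deleting `cut_edges`
leaf_components <- function(tr, cut_edges) {
  n <- length(tr$tip.label)
  keep <- setdiff(seq_len(nrow(tr$edge)), cut_edges)
  nn <- max(tr$edge)
  parent_of <- rep(NA_integer_, nn)
  comp <- seq_len(nn)
  find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
  for (e in keep) {
    a <- find(tr$edge[e, 1L]); b <- find(tr$edge[e, 2L])
    if (a != b) comp[b] <- a
  }
  roots <- vapply(seq_len(n), function(i) find(i), integer(1L))
  unname(lapply(split(seq_len(n), roots), function(i) tr$tip.label[i]))
}

#' Agglomerative linkage partition of a distance matrix
#'
#' @param d symmetric distance matrix with sample ids as dimnames.
#' @param method `"average"` or `"complete"` linkage.
#' @param k number of clusters.
#' @return a partition: named integer vector (sample -> `0..k-1`).
#' @export
linkage_partition <- function(d, method = c("average", "complete"), k) {
  method <- match.arg(method)
  if (k > nrow(d)) stop("k exceeds the number of samples", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(d), method = method)
  cl <- stats::cutree(hc, k = k)
  out <- cl - 1L
  names(out) <- rownames(d)
  out
}

#' Classical (Torgerson) MDS embedding of a distance matrix
#'
#' Double-centers the squared-distance matrix and takes the top
#' eigenpairs. Negative eigenvalue mass is reported as a
#' non-Euclidean-ness diagnostic.
#'
#' @param d symmetric distance matrix, `n >= dims + 1`.
#' @param dims embedding dimension (default 2, the first two
#'   components).
#' @return list with `points` (n x dims coordinate matrix),
#'   `eigenvalues` and `negative_mass` (sum of |negative eigenvalues| /
#'   sum of |eigenvalues|).
#' @export
mds_embed <- function(d, dims = 2L) {
  n <- nrow(d)
  if (n < dims + 1L) stop("need n >= dims + 1", call. = FALSE)
  if (all(d == 0)) {
    pts <- matrix(0, n, dims, dimnames = list(rownames(d), NULL))
    return(list(points = pts, eigenvalues = rep(0, n - 1L),
                negative_mass = 0))
  }
  fit <- stats::cmdscale(stats::as.dist(d), k = dims, eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < dims) # degenerate: pad with zero coordinates
    pts <- cbind(pts, matrix(0, n, dims - ncol(pts)))
  rownames(pts) <- rownames(d)
  ev <- fit$eig
  neg <- sum(abs(ev[ev < 0])) / max(sum(abs(ev)), .Machine$double.eps)
  list(points = pts, eigenvalues = ev, negative_mass = neg)
}

#' Write a partition as TSV (sample_id, cluster)
#' @param part named integer vector from [cut_to_k()] or
#'   [linkage_partition()].
#' @param path file path.
#' @export
write_partition <- function(part, path) {
  utils::write.table(data.frame(sample_id = names(part),
                                cluster = as.integer(part)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a partition from TSV (sample_id, cluster/label columns)
#' @param path file path.
#' @return named vector (sample -> cluster label).
#' @export
read_partition <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  out <- df[[2L]]
  names(out) <- df[[1L]]
  out
}
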