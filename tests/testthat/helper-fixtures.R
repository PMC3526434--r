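# fixtures and independent oracles shared across tests

# tiny genotype matrix with explicit values
toy_genotypes <- function(values, ids = NULL, loci = NULL) {
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(values)))
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(values)))
  genotype_matrix(values, ids, loci)
}

toy_map <- function(loci, chrom = rep("chr1", length(loci))) {
  pos <- stats::ave(seq_along(loci), chrom, FUN = seq_along)
  chromosome_map(loci, chrom, pos)
}

# the planted-recombinant panel: s5 = prefix(s1, 3 loci) + suffix(s2, 2),
# s3 the reverse mosaic, s1/s2 divergent at every locus
planted_recombinant <- function() {
  m <- rbind(s1 = c(1, 1, 1, 1, 1), s2 = c(2, 2, 2, 2, 2),
             s3 = c(2, 2, 2, 1, 1), s4 = c(1, 1, 1, 1, 1),
             s5 = c(1, 1, 1, 2, 2), s6 = c(2, 2, 2, 2, 2))
  genotype_matrix(m, rownames(m), paste0("L", 1:5))
}

# exhaustive max-diagonal assignment (independent oracle)
brute_force_assignment <- function(m) {
  k <- nrow(m)
  perms <- perms_of(k)
  best <- -Inf; best_perm <- NULL
  for (p in perms) {
    s <- sum(m[cbind(seq_len(k), p)])
    if (s > best) { best <- s; best_perm <- p }
  }
  list(value = best, perm = best_perm)
}

perms_of <- function(n) {
  if (n == 1L) return(list(1L))
  out <- vector("list", factorial(n))
  i <- 0L
  for (first in seq_len(n)) {
    for (rest in perms_of(n - 1L)) {
      i <- i + 1L
      tail <- seq_len(n)[-first][rest]
      out[[i]] <- c(first, tail)
    }
  }
  out
}

# independent split enumeration via ape::prop.part (different code path
# from argstr's own tree_splits)
oracle_splits <- function(tr) {
  tips <- tr$tip.label
  ref <- min(tips)
  pp <- ape::prop.part(tr)
  labs <- attr(pp, "labels")
  out <- character(0L)
  for (cl in pp) {
    side <- labs[cl]
    if (length(side) <= 1L || length(side) >= length(tips) - 1L) next
    if (ref %in% side) side <- setdiff(tips, side)
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

oracle_partition_metric <- function(t1, t2) {
  e1 <- sum(t1$edge[, 1L] > length(t1$tip.label) &
              t1$edge[, 2L] > length(t1$tip.label))
  e2 <- sum(t2$edge[, 1L] > length(t2$tip.label) &
              t2$edge[, 2L] > length(t2$tip.label))
  v <- length(intersect(oracle_splits(t1), oracle_splits(t2)))
  e1 + e2 - 2L * v
}

# least-squares additive fit of a topology to a distance matrix; the
# residual is ~0 only for the generating topology
topology_residual <- function(tr, d) {
  tips <- tr$tip.label
  n <- length(tips)
  pairs <- utils::combn(n, 2L)
  # edge incidence: an edge separates a pair iff they lie on opposite
  # sides of its bipartition
  n_edge <- nrow(tr$edge)
  A <- matrix(0, ncol(pairs), n_edge)
  for (e in seq_len(n_edge)) {
    below <- tr$tip.label[unlist(tips_below_oracle(tr, tr$edge[e, 2L]))]
    for (pidx in seq_len(ncol(pairs))) {
      i <- tips[pairs[1L, pidx]]; j <- tips[pairs[2L, pidx]]
      if (xor(i %in% below, j %in% below)) A[pidx, e] <- 1
    }
  }
  y <- d[cbind(tips[pairs[1L, ]], tips[pairs[2L, ]])]
  fit <- stats::lm.fit(A, y)
  sum(fit$residuals^2)
}

tips_below_oracle <- function(tr, node) {
  n <- length(tr$tip.label)
  if (node <= n) return(node)
  kids <- tr$edge[tr$edge[, 1L] == node, 2L]
  unlist(lapply(kids, function(k) tips_below_oracle(tr, k)))
}

# brute-force per-segment LCA distance (independent of the class-based
# computation in pairwise_distances)
oracle_subarg_distance <- function(a, x, y) {
  parents_of <- split(a$edges$parent, a$edges$child)
  ancestors <- function(v) {
    seen <- integer(0L)
    stack <- v
    while (length(stack) > 0L) {
      u <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      for (p in parents_of[[as.character(u)]]) {
        if (!(p %in% seen)) { seen <- c(seen, p); stack <- c(stack, p) }
      }
    }
    c(v, seen)
  }
  ax <- ancestors(x); ay <- ancestors(y)
  common <- intersect(ax, ay)
  vapply(seq_len(nrow(a$segments)), function(si) {
    s0 <- a$segments$start[si]; e0 <- a$segments$end[si]
    cover <- common[a$carries$start[common] <= s0 &
                      a$carries$end[common] >= e0]
    cover <- cover[a$nodes$kind[cover] != "genetic_exchange"]
    if (length(cover) == 0L) return(NA_real_)
    min(a$carries$age[cover])
  }, numeric(1L))
}

# small deterministic distance matrix with two well-separated blocks
two_block_distance <- function(n1 = 4L, n2 = 4L, within = 1, between = 10) {
  n <- n1 + n2
  d <- matrix(between, n, n)
  d[seq_len(n1), seq_len(n1)] <- within
  d[(n1 + 1L):n, (n1 + 1L):n] <- within
  diag(d) <- 0
  dimnames(d) <- list(paste0("s", seq_len(n)), paste0("s", seq_len(n)))
  d
}

# pure-R additive (path-length) distances of a tree: for every edge, the
# bipartition it induces separates a set of pairs; sum edge lengths over
# separating edges
additive_distances <- function(tr) {
  tips <- tr$tip.label
  n <- length(tips)
  d <- matrix(0, n, n, dimnames = list(tips, tips))
  for (e in seq_len(nrow(tr$edge))) {
    below <- tips %in% tips[tips_below_oracle(tr, tr$edge[e, 2L])]
    sep <- outer(below, !below, "&") | outer(!below, below, "&")
    d[sep] <- d[sep] + tr$edge.length[e]
  }
  d
}
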