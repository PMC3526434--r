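#' Detection parameters for the recombination detector
#'
#' @param grain_size loci per flanking analysis window (>= 1).
#' @param peak_distance minimum spacing, in inter-locus boundaries,
#'   between accepted breakpoints (>= 1).
#' @param threshold minimum summed consensus score for a sample/boundary
#'   entry to survive (>= 1).
#' @return an object of class `dsr_params`.
#' @export
dsr_params <- function(grain_size = 1L, peak_distance = 2L, threshold = 5L) {
  stopifnot(grain_size >= 1L, peak_distance >= 1L, threshold >= 1L)
  structure(list(grain_size = as.integer(grain_size),
                 peak_distance = as.integer(peak_distance),
                 threshold = as.integer(threshold)),
            class = "dsr_params")
}

#' Default multi-setting consensus set
#'
#' The detector is run once per setting and scores are summed before
#' thresholding. Each setting is a (window grain, window offset) pair;
#' the default uses grains `{g, g+1}` crossed with offsets `{0, 1}`,
#' where `g` is the base grain size.
#'
#' @param params a [dsr_params()].
#' @return list of `list(grain, offset)` settings.
#' @export
dsr_settings <- function(params = dsr_params()) {
  g <- params$grain_size
  out <- list()
  for (grain in c(g, g + 1L)) for (off in 0:1)
    out[[length(out) + 1L]] <- list(grain = grain, offset = off)
  out
}

# haplotype class ids for a window of columns: integer class per row,
# classes numbered by first appearance
window_classes <- function(m) {
  keys <- do.call(paste, c(as.data.frame(m), sep = ","))
  match(keys, unique(keys))
}

#' Detect recombination breakpoints and build the recomatrix
#'
#' A multi-allelic generalization of the four-gamete test. For every
#' inter-locus boundary and every consensus setting, haplotype classes
#' are counted over flanking windows: `L` classes on the left window,
#' `R` on the right, `J` jointly. Under a recombination-free (tree-like)
#' history `J <= L + R - 1`, so the incompatibility evidence is
#' `ev = J - (L + R - 1)` when positive. The samples charged are the
#' members of the `ev` smallest joint classes (ties broken by
#' lexicographically smallest joint haplotype), each receiving score
#' `ev` for that setting. Scores are summed across settings, entries
#' below `threshold` are zeroed, and non-maximal boundaries within
#' `peak_distance` of a stronger one are suppressed (ties keep the
#' leftmost).
#'
#' @param g a staged [genotype_matrix()] with no missing values,
#'   >= 4 samples and >= 2 loci.
#' @param params a [dsr_params()].
#' @param settings consensus settings from [dsr_settings()]; each a
#'   `list(grain, offset)`.
#' @return an object of class `recomatrix`: an integer matrix samples x
#'   boundaries (boundary `b` sits between staged loci `b` and `b + 1`).
#' @export
detect_recombinations <- function(g, params = dsr_params(),
                                  settings = dsr_settings(params)) {
  n <- nrow(g); L <- ncol(g)
  if (L < 2L) stop("need >= 2 loci to have a boundary", call. = FALSE)
  if (n < 4L) stop("need >= 4 samples", call. = FALSE)
  if (any(g == MISSING)) stop("matrix must be imputed first", call. = FALSE)
  score <- matrix(0L, n, L - 1L)
  gm <- unclass(g)
  for (st in settings) {
    grain <- st$grain; off <- st$offset
    for (b in seq_len(L - 1L)) {
      l_to <- b - off
      l_from <- max(1L, l_to - grain + 1L)
      r_from <- b + 1L + off
      r_to <- min(L, r_from + grain - 1L)
      if (l_to < 1L || r_from > L) next
      lc <- window_classes(gm[, l_from:l_to, drop = FALSE])
      rc <- window_classes(gm[, r_from:r_to, drop = FALSE])
      joint_key <- paste(lc, rc)
      ju <- unique(joint_key)
      ev <- length(ju) - (max(lc) + max(rc) - 1L)
      if (ev <= 0L) next
      sizes <- table(joint_key)[ju]
      # lexicographic order on the joint haplotype itself for ties
      hap_key <- do.call(paste, c(as.data.frame(
        gm[match(ju, joint_key), c(l_from:l_to, r_from:r_to), drop = FALSE]),
        sep = ","))
      ord <- order(as.integer(sizes), hap_key)
      charged_classes <- ju[ord][seq_len(min(ev, length(ju)))]
      charged <- joint_key %in% charged_classes
      score[charged, b] <- score[charged, b] + as.integer(ev)
    }
  }
  score[score < params$threshold] <- 0L
  # non-maximal suppression: accepted boundaries >= peak_distance apart
  tot <- colSums(score)
  if (params$peak_distance > 1L && any(tot > 0)) {
    ord <- order(-tot, seq_along(tot))
    accepted <- integer(0L)
    for (b in ord) {
      if (tot[b] == 0) next
      if (length(accepted) == 0L ||
          all(abs(accepted - b) >= params$peak_distance))
        accepted <- c(accepted, b)
    }
    score[, setdiff(which(tot > 0), accepted)] <- 0L
  }
  dimnames(score) <- list(rownames(g), paste0("b", seq_len(L - 1L)))
  structure(score, class = c("recomatrix", class(matrix())),
            params = params)
}

#' Expected standard-coalescent depth of a k-carrier node
#'
#' `f(k) = sum_{j=2..k} 2 / (j (j - 1)) = 2 (1 - 1/k)`, in coalescent
#' units; `f(1) = 0`. Used as the age of a node whose material on a
#' non-mixing segment is inherited by `k` extant samples.
#'
#' @param k integer vector of carrier counts (>= 1).
#' @return numeric vector of ages.
#' @export
coalescent_depth <- function(k) {
  stopifnot(all(k >= 1L))
  2 * (1 - 1 / k)
}

#' Build a subARG from a staged matrix and its recomatrix
#'
#' The staged loci are segmented at every boundary with surviving
#' support. Within each segment, samples with identical haplotypes are
#' merged under a coalescent node (largest class first, ties by
#' lexicographic haplotype); the remaining lineage roots of the segment
#' are joined under a single root coalescent node. Samples flagged in
#' the recomatrix at a boundary receive a genetic-exchange node whose
#' two parents carry the material on either side of the breakpoint. The
#' result is a subgraph-style estimate of the true ARG.
#'
#' @param g a staged [genotype_matrix()] with no missing values.
#' @param r a [detect_recombinations()] recomatrix from the same matrix.
#' @return an object of class `subarg`; see [estimate_ages()] and
#'   [pairwise_distances()].
#' @export
build_subarg <- function(g, r) {
  n <- nrow(g); L <- ncol(g)
  if (nrow(r) != n || ncol(r) != L - 1L)
    stop("recomatrix dimensions do not match the staged matrix", call. = FALSE)
  gm <- unclass(g)
  active <- which(colSums(r) > 0)
  starts <- c(1L, active + 1L)
  ends <- c(active, L)
  n_seg <- length(starts)

  kind <- rep("leaf", n)
  c_start <- rep(1L, n); c_end <- rep(L, n)
  c_bp <- rep(NA_integer_, n)
  e_child <- vector("list", n_seg + 2L)
  e_parent <- vector("list", n_seg + 2L)
  membership <- matrix(0L, n, n_seg)
  class_members <- vector("list", n_seg)
  class_nodes <- vector("list", n_seg)
  root_id <- integer(n_seg)
  attach_of <- matrix(NA_integer_, n, n_seg) # node a sample's lineage joins

  for (si in seq_len(n_seg)) {
    cols <- starts[si]:ends[si]
    keys <- do.call(paste, c(as.data.frame(gm[, cols, drop = FALSE]), sep = ","))
    ids <- match(keys, unique(keys))
    members <- split(seq_len(n), ids)
    sizes <- lengths(members)
    hapk <- unique(keys)
    # deterministic merge order: largest class first, ties lexicographic
    ord <- order(-sizes, hapk)
    members <- members[ord]
    membership[, si] <- match(ids, as.integer(names(members)))
    class_members[[si]] <- unname(members)
    sizes <- lengths(members)
    big <- which(sizes >= 2L)
    cn <- rep(NA_integer_, length(members))
    cn[big] <- length(kind) + seq_along(big)
    kind <- c(kind, rep("coalescent", length(big)))
    c_start <- c(c_start, rep(starts[si], length(big)))
    c_end <- c(c_end, rep(ends[si], length(big)))
    c_bp <- c(c_bp, rep(NA_integer_, length(big)))
    ch <- unlist(members[big], use.names = FALSE)
    pa <- rep(cn[big], sizes[big])
    for (ci in big) attach_of[members[[ci]], si] <- cn[ci]
    singles <- unlist(members[sizes == 1L], use.names = FALSE)
    seg_roots <- c(cn[big], singles)
    if (length(seg_roots) > 1L) {
      rt <- length(kind) + 1L
      kind <- c(kind, "coalescent")
      c_start <- c(c_start, starts[si]); c_end <- c(c_end, ends[si])
      c_bp <- c(c_bp, NA_integer_)
      ch <- c(ch, seg_roots)
      pa <- c(pa, rep(rt, length(seg_roots)))
      root_id[si] <- rt
      attach_of[singles, si] <- rt
    } else {
      root_id[si] <- seg_roots # single class covering every sample
    }
    class_nodes[[si]] <- cn
    e_child[[si]] <- ch
    e_parent[[si]] <- pa
  }
  edges_child <- unlist(e_child, use.names = FALSE)
  edges_parent <- unlist(e_parent, use.names = FALSE)

  # genetic-exchange nodes for flagged samples at active boundaries
  fl <- which(r[, active, drop = FALSE] > 0, arr.ind = TRUE)
  if (length(active) > 0L && nrow(fl) > 0L) {
    s_v <- fl[, 1L]; bi_v <- fl[, 2L]
    ge_ids <- length(kind) + seq_len(nrow(fl))
    kind <- c(kind, rep("genetic_exchange", nrow(fl)))
    c_start <- c(c_start, starts[bi_v])
    c_end <- c(c_end, ends[bi_v + 1L])
    c_bp <- c(c_bp, active[bi_v])
    pl <- attach_of[cbind(s_v, bi_v)]       # segment ending at the boundary
    pr <- attach_of[cbind(s_v, bi_v + 1L)]  # segment starting after it
    drop_keys <- c(paste(s_v, pl), paste(s_v, pr))
    keep <- !(paste(edges_child, edges_parent) %in% drop_keys)
    edges_child <- c(edges_child[keep], s_v, ge_ids, ge_ids)
    edges_parent <- c(edges_parent[keep], ge_ids, pl, pr)
    ge <- data.frame(sample = s_v, boundary = active[bi_v], node = ge_ids)
  } else {
    ge <- data.frame(sample = integer(0L), boundary = integer(0L),
                     node = integer(0L))
  }
  structure(list(
    nodes = data.frame(id = seq_along(kind), kind = kind),
    edges = unique(data.frame(child = edges_child, parent = edges_parent)),
    carries = data.frame(start = c_start, end = c_end, age = NA_real_,
                         breakpoint = c_bp),
    segments = data.frame(start = starts, end = ends),
    membership = membership,
    class_members = class_members,
    class_nodes = class_nodes,
    root_id = root_id,
    ge = ge,
    sample_ids = rownames(g),
    n_loci = L,
    boundaries = active
  ), class = "subarg")
}

#' @export
print.subarg <- function(x, ...) {
  cat(sprintf(
    "subARG: %d leaves, %d nodes (%d coalescent, %d genetic exchange), %d segments\n",
    length(x$sample_ids), nrow(x$nodes), sum(x$nodes$kind == "coalescent"),
    sum(x$nodes$kind == "genetic_exchange"), nrow(x$segments)))
  invisible(x)
}

# leaves whose material on the node's carried interval reaches the node
node_carriers <- function(a, v) {
  children <- split(a$edges$child, a$edges$parent)
  descend <- function(u) {
    if (a$nodes$kind[u] == "leaf") return(u)
    kids <- children[[as.character(u)]]
    if (is.null(kids)) return(integer(0L))
    unique(unlist(lapply(kids, descend)))
  }
  descend(v)
}

#' Estimate node ages over non-mixing segments
#'
#' For every node and every non-mixing segment it carries, the age is
#' `f(k)` ([coalescent_depth()]) where `k` is the number of extant
#' samples inheriting that node's material on that segment. Ages are
#' non-decreasing toward the roots along every path, per segment.
#'
#' @param a a [build_subarg()] result.
#' @return the subARG with ages filled in (`carries[[node]]$age` and a
#'   `class_ages` / `root_age` summary used by [pairwise_distances()]).
#' @export
estimate_ages <- function(a) {
  n_nodes <- nrow(a$nodes)
  n_seg <- nrow(a$segments)
  class_ages <- vector("list", n_seg)
  root_age <- numeric(n_seg)
  # descendant-leaf sets in one topological pass (children before parents)
  leafsets <- vector("list", n_nodes)
  is_leaf <- a$nodes$kind == "leaf"
  for (v in which(is_leaf)) leafsets[[v]] <- v
  indeg <- tabulate(a$edges$parent, n_nodes)
  parents_of <- split(a$edges$parent, a$edges$child)
  children_of <- split(a$edges$child, a$edges$parent)
  remaining <- indeg
  topo <- integer(n_nodes)
  head <- 1L; tail <- 0L
  for (v in which(indeg == 0L)) { tail <- tail + 1L; topo[tail] <- v }
  while (head <= tail) {
    v <- topo[head]; head <- head + 1L
    for (p in parents_of[[as.character(v)]]) {
      remaining[p] <- remaining[p] - 1L
      if (remaining[p] == 0L) { tail <- tail + 1L; topo[tail] <- p }
    }
  }
  topo <- topo[seq_len(tail)]
  for (v in topo) {
    if (is_leaf[v]) { a$carries$age[v] <- 0; next }
    kids <- children_of[[as.character(v)]]
    leafsets[[v]] <- unique(unlist(leafsets[kids], use.names = FALSE))
    k <- length(leafsets[[v]])
    if (k == 0L)
      stop(sprintf("node %d carries material reaching no leaf", v),
           call. = FALSE)
    a$carries$age[v] <- coalescent_depth(k)
  }
  for (si in seq_len(n_seg)) {
    cn <- a$class_nodes[[si]]
    sizes <- lengths(a$class_members[[si]])
    class_ages[[si]] <- ifelse(is.na(cn), 0, coalescent_depth(sizes))
    rt <- a$root_id[si]
    root_age[si] <- if (a$nodes$kind[rt] == "leaf") 0 else
      a$carries$age[rt]
  }
  a$class_ages <- class_ages
  a$root_age <- root_age
  a
}

#' Pairwise MRCA-age distances from a subARG
#'
#' The distance between two samples is the mean, over non-mixing
#' segments, of the age of their lowest common ancestor on that segment.
#' On segments where the subARG leaves a pair un-joined, the oldest age
#' present on the segment plus one coalescent unit is used as a finite
#' "beyond the graph" distance.
#'
#' @param a an age-annotated subARG from [estimate_ages()].
#' @return a symmetric, zero-diagonal numeric matrix with sample ids as
#'   dimnames.
#' @export
pairwise_distances <- function(a) {
  if (is.null(a$class_ages))
    stop("run estimate_ages() first", call. = FALSE)
  n <- length(a$sample_ids)
  n_seg <- nrow(a$segments)
  D <- matrix(0, n, n)
  for (si in seq_len(n_seg)) {
    base <- a$root_age[si]
    if (is.na(base)) { # un-joined fallback (no segment root)
      base <- max(a$class_ages[[si]]) + 1
    }
    contrib <- matrix(base, n, n)
    sizes <- lengths(a$class_members[[si]])
    for (ci in which(sizes >= 2L)) {
      mem <- a$class_members[[si]][[ci]]
      contrib[mem, mem] <- a$class_ages[[si]][ci]
    }
    D <- D + contrib
  }
  D <- D / n_seg
  diag(D) <- 0
  dimnames(D) <- list(a$sample_ids, a$sample_ids)
  D
}

#' Structural validity checks for a subARG
#'
#' Verifies acyclicity, leaf/coalescent/genetic-exchange degree rules,
#' breakpoint-splitting of genetic-exchange intervals, and (when ages
#' are present) per-segment non-decreasing ages toward the roots.
#'
#' @param a a subARG.
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_subarg <- function(a) {
  nn <- nrow(a$nodes)
  indeg <- tabulate(a$edges$parent, nn)  # children counts
  outdeg <- tabulate(a$edges$child, nn)  # parent counts
  for (v in a$nodes$id) {
    kd <- a$nodes$kind[v]
    if (kd == "leaf") {
      if (indeg[v] != 0L) stop("leaf with incoming edge", call. = FALSE)
      if (outdeg[v] < 1L) stop("leaf with no parent", call. = FALSE)
    } else if (kd == "coalescent") {
      if (indeg[v] < 2L) stop("coalescent node with < 2 children", call. = FALSE)
    } else if (kd == "genetic_exchange") {
      if (outdeg[v] != 2L)
        stop("genetic-exchange node without exactly 2 parents", call. = FALSE)
      if (is.na(a$carries$breakpoint[v]) ||
          a$carries$breakpoint[v] < a$carries$start[v] ||
          a$carries$breakpoint[v] >= a$carries$end[v])
        stop("genetic-exchange breakpoint does not split its interval",
             call. = FALSE)
    }
  }
  # acyclicity via Kahn's algorithm on child -> parent edges
  deg <- tabulate(a$edges$parent, nn)
  parents <- split(a$edges$parent, a$edges$child)
  q <- which(deg == 0L)
  seen <- 0L
  while (length(q) > 0L) {
    v <- q[[1L]]; q <- q[-1L]; seen <- seen + 1L
    for (p in parents[[as.character(v)]]) {
      deg[p] <- deg[p] - 1L
      if (deg[p] == 0L) q <- c(q, p)
    }
  }
  if (seen != nn) stop("subARG contains a cycle", call. = FALSE)
  # age monotonicity on carried-interval overlaps along child -> parent edges
  if (!anyNA(a$carries$age)) {
    ch <- a$edges$child; pa <- a$edges$parent
    overlap <- a$carries$start[ch] <= a$carries$end[pa] &
      a$carries$start[pa] <= a$carries$end[ch]
    if (any(overlap & a$carries$age[pa] < a$carries$age[ch]))
      stop("age decreases toward root", call. = FALSE)
  }
  invisible(TRUE)
}

#' Serialize a subARG to JSON
#' @param a a subARG.
#' @param path file path.
#' @export
write_subarg <- function(a, path) {
  nodes <- lapply(a$nodes$id, function(v) {
    out <- list(id = v, kind = a$nodes$kind[v],
                # 0-based half-open interval on the staged locus axis
                start = a$carries$start[v] - 1L,
                end = a$carries$end[v],
                age = a$carries$age[v])
    if (!is.na(a$carries$breakpoint[v]))
      out$breakpoint <- a$carries$breakpoint[v]
    out
  })
  jsonlite::write_json(list(sample_ids = a$sample_ids, nodes = nodes,
                            edges = a$edges),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a lower-triangle PHYLIP distance matrix
#' @param d symmetric numeric matrix with dimnames.
#' @param path file path.
#' @export
write_dist_phylip <- function(d, path) {
  n <- nrow(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", n), con)
  for (i in seq_len(n)) {
    row <- if (i == 1L) "" else
      paste(formatC(d[i, seq_len(i - 1L)], format = "g", digits = 10),
            collapse = " ")
    writeLines(trimws(sprintf("%-10s %s", rownames(d)[i], row), "right"), con)
  }
  invisible(path)
}

#' @rdname write_dist_phylip
#' @export
read_dist_phylip <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  d <- matrix(0, n, n)
  ids <- character(n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1L]), "[[:space:]]+")[[1L]]
    ids[i] <- parts[1L]
    if (i > 1L) d[i, seq_len(i - 1L)] <- as.numeric(parts[-1L])
  }
  d <- d + t(d)
  dimnames(d) <- list(ids, ids)
  d
}
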