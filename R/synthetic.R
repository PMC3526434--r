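#' Configuration for the STR panel simulator
#'
#' Defaults emulate the cacao panel: 10 source populations whose sizes
#' follow the published panel composition (952 samples in all), 96 STR
#' loci over 10 chromosomes with the three largest linkage groups
#' first, third and fifth, ~2.8% missing values, and population
#' divergence of 5 coalescent units.
#'
#' @param n_populations number of source populations.
#' @param samples_per_population scalar or vector of per-population
#'   sample counts.
#' @param loci_per_chromosome vector of per-chromosome locus counts
#'   (sums to 96 by default).
#' @param divergence depth, in coalescent units, at which populations
#'   join a common ancestral pool (pairwise divergence depth).
#' @param mutation_rate stepwise-mutation rate per locus per coalescent
#'   unit of branch length.
#' @param recombination_rate probability of a genealogy switch between
#'   adjacent loci within a chromosome.
#' @param bottleneck probability that a chromosome reuses the shared
#'   genome-wide genealogy rather than an independent one; induces
#'   linkage disequilibrium between physically unlinked loci.
#' @param missing_fraction fraction of cells set missing (default
#'   2562/91392, the published panel's missing count at its shape).
#' @param seed integer seed; one seeded generator drives all
#'   randomness.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_populations = 10L,
                       samples_per_population = c(94L, 69L, 39L, 117L, 59L,
                                                  117L, 143L, 52L, 152L, 110L),
                       loci_per_chromosome = c(15L, 9L, 14L, 6L, 13L,
                                               7L, 11L, 6L, 9L, 6L),
                       divergence = 5,
                       mutation_rate = 0.35,
                       recombination_rate = 0.1,
                       bottleneck = 0.5,
                       missing_fraction = 2562 / 91392,
                       seed = 1L) {
  if (length(samples_per_population) == 1L)
    samples_per_population <- rep(samples_per_population, n_populations)
  if (length(samples_per_population) != n_populations)
    stop("samples_per_population must have length n_populations",
         call. = FALSE)
  if (any(samples_per_population < 1L))
    stop("every population needs >= 1 sample", call. = FALSE)
  if (sum(samples_per_population) < n_populations)
    stop("more populations than samples", call. = FALSE)
  stopifnot(divergence >= 0, mutation_rate >= 0,
            recombination_rate >= 0, recombination_rate <= 1,
            bottleneck >= 0, bottleneck <= 1,
            missing_fraction >= 0, missing_fraction < 1)
  structure(list(n_populations = as.integer(n_populations),
                 samples_per_population = as.integer(samples_per_population),
                 loci_per_chromosome = as.integer(loci_per_chromosome),
                 divergence = min(divergence, 1e6),
                 mutation_rate = mutation_rate,
                 recombination_rate = recombination_rate,
                 bottleneck = bottleneck,
                 missing_fraction = missing_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# structured coalescent genealogy: Kingman within each population until
# `divergence`, then one panmictic ancestral pool. Returns parent
# pointers and node times (leaves 1..n at time 0).
sim_genealogy <- function(pop, divergence) {
  n <- length(pop)
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  time <- numeric(n_nodes)
  nxt <- n + 1L
  pool <- integer(0L)
  for (p in unique(pop)) {
    lineages <- which(pop == p)
    t <- 0
    while (length(lineages) >= 2L) {
      k <- length(lineages)
      dt <- stats::rexp(1L, k * (k - 1) / 2)
      if (t + dt > divergence) break
      t <- t + dt
      pick <- sample.int(k, 2L)
      v <- nxt; nxt <- nxt + 1L
      parent[lineages[pick]] <- v
      time[v] <- t
      lineages <- c(lineages[-pick], v)
    }
    pool <- c(pool, lineages)
  }
  t <- divergence
  while (length(pool) >= 2L) {
    k <- length(pool)
    t <- t + stats::rexp(1L, k * (k - 1) / 2)
    pick <- sample.int(k, 2L)
    v <- nxt; nxt <- nxt + 1L
    parent[pool[pick]] <- v
    time[v] <- t
    pool <- c(pool[-pick], v)
  }
  list(parent = parent, time = time, n = n)
}

# pairwise TMRCA matrix of a genealogy
genealogy_tmrca <- function(tree) {
  n <- tree$n
  n_nodes <- length(tree$parent)
  D <- matrix(0, n, n)
  below <- vector("list", n_nodes)
  for (i in seq_len(n)) below[[i]] <- i
  ord <- order(tree$time[(n + 1L):n_nodes]) + n
  kids <- split(seq_len(n_nodes)[tree$parent > 0L],
                tree$parent[tree$parent > 0L])
  for (v in ord) {
    ch <- kids[[as.character(v)]]
    sets <- below[ch]
    acc <- sets[[1L]]
    for (j in 2:length(sets)) {
      D[acc, sets[[j]]] <- tree$time[v]
      D[sets[[j]], acc] <- tree$time[v]
      acc <- c(acc, sets[[j]])
    }
    below[[v]] <- acc
  }
  D
}

# stepwise-mutation alleles for `n_loci` loci sharing one genealogy:
# Poisson(mu * branch) +/-1 steps, reflecting at 0, root allele 15
sim_alleles <- function(tree, n_loci, mu, root_allele = 15L) {
  n_nodes <- length(tree$parent)
  n <- tree$n
  allele <- matrix(NA_real_, n_nodes, n_loci)
  root <- which(tree$parent == 0L)
  allele[root, ] <- root_allele
  ord <- order(tree$time, decreasing = TRUE) # parents before children
  for (v in setdiff(ord, root)) {
    p <- tree$parent[v]
    len <- tree$time[p] - tree$time[v]
    steps <- stats::rpois(n_loci, mu * len)
    net <- 2 * stats::rbinom(n_loci, steps, 0.5) - steps
    allele[v, ] <- abs(allele[p, ] + net) # reflect at 0
  }
  allele[seq_len(n), , drop = FALSE]
}

#' Simulate an STR panel with known truth
#'
#' Populations split from a common ancestral pool at the configured
#' divergence; per-chromosome genealogies are either the shared
#' genome-wide genealogy (with probability `bottleneck`) or
#' independent, and switch along the loci of a chromosome at the
#' within-chromosome recombination rate. Stepwise mutation (allele
#' +/- 1, reflecting at 0) acts on every branch, and missing values are
#' injected uniformly at the configured fraction.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `sim_panel`: list with `genotypes`
#'   (a [genotype_matrix()], missing injected), `map`
#'   (a [chromosome_map()]), `truth` (named vector sample ->
#'   population) and `true_tmrca` (matrix of mean pairwise TMRCA over
#'   loci).
#' @export
simulate_panel <- function(cfg = sim_config()) {
  with_seed(cfg$seed, {
    sizes <- cfg$samples_per_population
    n <- sum(sizes)
    pop_names <- sprintf("pop%02d", seq_len(cfg$n_populations))
    pop <- rep(pop_names, sizes)
    sample_ids <- sprintf("s%04d", seq_len(n))
    n_chrom <- length(cfg$loci_per_chromosome)
    locus_ids <- unlist(lapply(seq_len(n_chrom), function(ci)
      sprintf("chr%02d_L%02d", ci, seq_len(cfg$loci_per_chromosome[ci]))))
    map <- chromosome_map(locus_ids,
                          rep(sprintf("chr%02d", seq_len(n_chrom)),
                              cfg$loci_per_chromosome),
                          unlist(lapply(cfg$loci_per_chromosome, seq_len)))
    shared <- sim_genealogy(pop, cfg$divergence)
    trees <- list(shared)
    tree_of_locus <- integer(0L)
    for (ci in seq_len(n_chrom)) {
      cur <- if (stats::runif(1L) < cfg$bottleneck) 1L else {
        trees[[length(trees) + 1L]] <- sim_genealogy(pop, cfg$divergence)
        length(trees)
      }
      for (l in seq_len(cfg$loci_per_chromosome[ci])) {
        if (l > 1L && stats::runif(1L) < cfg$recombination_rate) {
          trees[[length(trees) + 1L]] <- sim_genealogy(pop, cfg$divergence)
          cur <- length(trees)
        }
        tree_of_locus <- c(tree_of_locus, cur)
      }
    }
    L <- length(tree_of_locus)
    values <- matrix(NA_integer_, n, L)
    for (ti in unique(tree_of_locus)) {
      cols <- which(tree_of_locus == ti)
      values[, cols] <- as.integer(
        sim_alleles(trees[[ti]], length(cols), cfg$mutation_rate))
    }
    tmrca <- matrix(0, n, n)
    tab <- table(tree_of_locus)
    for (ti in unique(tree_of_locus))
      tmrca <- tmrca + genealogy_tmrca(trees[[ti]]) *
        (tab[[as.character(ti)]] / L)
    dimnames(tmrca) <- list(sample_ids, sample_ids)
    n_missing <- round(cfg$missing_fraction * length(values))
    if (n_missing > 0L)
      values[sample.int(length(values), n_missing)] <- MISSING
    g <- genotype_matrix(values, sample_ids, locus_ids)
    truth <- pop
    names(truth) <- sample_ids
    structure(list(genotypes = g, map = map, truth = truth,
                   true_tmrca = tmrca, config = cfg),
              class = "sim_panel")
  })
}

#' Write a simulated panel as a plain-text fixture directory
#'
#' Writes `genotypes.tsv`, `map.tsv`, `truth.tsv` and
#' `true_tmrca.phy`; byte-identical for identical seeds.
#'
#' @param pack a [simulate_panel()] result.
#' @param dir writable directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_fixture <- function(pack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(pack$genotypes, file.path(dir, "genotypes.tsv"))
  write_chromosome_map(pack$map, file.path(dir, "map.tsv"))
  utils::write.table(data.frame(sample_id = names(pack$truth),
                                population = pack$truth),
                     file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_dist_phylip(pack$true_tmrca, file.path(dir, "true_tmrca.phy"))
  invisible(dir)
}
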