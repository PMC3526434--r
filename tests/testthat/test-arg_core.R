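test_that("identical samples yield an all-zero recomatrix and a star subARG", {
  g <- toy_genotypes(matrix(3L, 5, 4))
  r <- detect_recombinations(g, dsr_params(threshold = 1))
  expect_true(all(r == 0L))
  a <- estimate_ages(build_subarg(g, r))
  expect_silent(validate_subarg(a))
  expect_equal(sum(a$nodes$kind == "coalescent"), 1L)
  expect_equal(nrow(a$segments), 1L)
  # the single coalescent node joins all 5 leaves at depth f(5)
  expect_equal(a$root_age, coalescent_depth(5))
})

test_that("the four-gamete configuration charges the minority carrier", {
  m <- rbind(a = c(0L, 0L), b = c(0L, 0L), c = c(0L, 1L), d = c(0L, 1L),
             e = c(1L, 0L), f = c(1L, 0L), g = c(1L, 1L))
  g <- toy_genotypes(m, ids = rownames(m))
  r <- detect_recombinations(g, dsr_params(threshold = 1),
                             settings = list(list(grain = 1L, offset = 0L)))
  expect_equal(ncol(r), 1L)
  expect_true(r["g", 1L] > 0L)
  expect_true(all(r[c("a", "b", "c", "d", "e", "f"), 1L] == 0L))
  # three gametes are tree-compatible: no signal without the fourth
  g3 <- toy_genotypes(m[1:6, ], ids = rownames(m)[1:6])
  r3 <- detect_recombinations(g3, dsr_params(threshold = 1),
                              settings = list(list(grain = 1L, offset = 0L)))
  expect_true(all(r3 == 0L))
})

test_that("the planted breakpoint is the maximal-support boundary", {
  g <- planted_recombinant()
  r <- detect_recombinations(g, dsr_params(threshold = 2))
  expect_equal(which.max(colSums(r)), 3L, ignore_attr = TRUE)
  expect_gt(r["s5", 3L], 0L)
  # peak-distance suppression leaves no competing boundary within radius 2
  expect_true(all(colSums(r)[c(2L, 4L)] == 0L))
  # the recombinant's genetic-exchange node carries [0,3) and [3,5)
  a <- estimate_ages(build_subarg(g, r))
  expect_silent(validate_subarg(a))
  ge <- a$ge
  expect_equal(a$sample_ids[ge$sample], "s5")
  expect_equal(ge$boundary, 3L)
  expect_equal(a$carries$start[ge$node], 1L)
  expect_equal(a$carries$end[ge$node], 5L)
  expect_equal(a$carries$breakpoint[ge$node], 3L)
  parents <- a$edges$parent[a$edges$child == ge$node]
  expect_equal(sort(a$carries$end[parents]), c(3L, 5L))
})

test_that("fewer than two loci is an error, as is an unimputed matrix", {
  g <- toy_genotypes(matrix(1L, 4, 1))
  expect_error(detect_recombinations(g), "boundary")
  g2 <- toy_genotypes(rbind(c(1L, -1L), c(1L, 2L), c(1L, 2L), c(1L, 2L)))
  expect_error(detect_recombinations(g2), "imputed")
})

test_that("two haplotype classes coalesce separately then join at a root", {
  m <- rbind(c(1L, 1L), c(1L, 1L), c(2L, 5L), c(2L, 5L), c(2L, 5L))
  g <- toy_genotypes(m)
  r <- detect_recombinations(g, dsr_params(threshold = 1))
  expect_true(all(r == 0L))
  a <- estimate_ages(build_subarg(g, r))
  expect_silent(validate_subarg(a))
  expect_equal(sum(a$nodes$kind == "coalescent"), 3L) # 2 classes + root
  # class ages from carrier counts: f(3) for the large class, f(2), root f(5)
  expect_equal(sort(a$class_ages[[1L]]),
               sort(coalescent_depth(c(3, 2))))
  expect_equal(a$root_age[1L], coalescent_depth(5))
})

test_that("coalescent depths match the closed form", {
  expect_equal(coalescent_depth(1), 0)
  expect_equal(coalescent_depth(2), 1.0)
  expect_equal(coalescent_depth(4), 1 + 1 / 3 + 1 / 6)
  # against the explicit sum
  for (k in 2:12)
    expect_equal(coalescent_depth(k), sum(2 / ((2:k) * ((2:k) - 1))))
  # a cherry of two identical samples sits at age 1.0
  g <- toy_genotypes(rbind(c(1L, 1L), c(1L, 1L), c(2L, 2L), c(3L, 3L)))
  a <- estimate_ages(build_subarg(g, detect_recombinations(
    g, dsr_params(threshold = 1))))
  cherry <- which(a$nodes$kind == "coalescent" &
                    vapply(a$nodes$id, function(v)
                      sum(a$edges$parent == v) == 2L, logical(1L)))
  expect_true(1.0 %in% a$carries$age[cherry])
})

test_that("pairwise distances equal brute-force per-segment LCA ages", {
  set.seed(8)
  for (rep in 1:25) {
    n <- sample(4:8, 1L)
    L <- sample(4:8, 1L)
    vals <- matrix(sample(1:3, n * L, replace = TRUE), n, L)
    g <- toy_genotypes(vals)
    r <- detect_recombinations(g, dsr_params(threshold = 1))
    a <- estimate_ages(build_subarg(g, r))
    d <- pairwise_distances(a)
    expect_true(all(diag(d) == 0))
    expect_equal(d, t(d))
    for (pair in list(c(1L, 2L), c(1L, n), c(2L, n))) {
      seg_ages <- oracle_subarg_distance(a, pair[1L], pair[2L])
      expect_equal(d[pair[1L], pair[2L]], mean(seg_ages))
    }
  }
})

test_that("identical samples attain the minimal pairwise distance and are equidistant from others", {
  m <- rbind(c(1L, 4L, 2L), c(1L, 4L, 2L), c(3L, 5L, 9L), c(7L, 8L, 2L))
  g <- toy_genotypes(m)
  a <- estimate_ages(build_subarg(g, detect_recombinations(
    g, dsr_params(threshold = 1))))
  d <- pairwise_distances(a)
  # an identical pair coalesces in its own cherry on every segment, the
  # youngest age the estimator can assign
  expect_equal(d[1L, 2L], coalescent_depth(2))
  expect_equal(d[1L, 2L], min(d[upper.tri(d)]))
  expect_equal(d[1L, 3L], d[2L, 3L])
  expect_equal(d[1L, 4L], d[2L, 4L])
})

test_that("closer pairs have smaller MRCA-age distance", {
  # x,y identical; z differs everywhere: x,y coalesce first on every segment
  m <- rbind(x = c(1L, 1L, 1L, 1L), y = c(1L, 1L, 1L, 1L),
             z = c(2L, 2L, 2L, 2L), w = c(3L, 3L, 3L, 3L),
             v = c(4L, 4L, 4L, 4L))
  g <- toy_genotypes(m, ids = rownames(m))
  a <- estimate_ages(build_subarg(g, detect_recombinations(
    g, dsr_params(threshold = 1))))
  d <- pairwise_distances(a)
  expect_lt(d["x", "y"], d["x", "z"])
  expect_equal(d["x", "z"], d["y", "z"])
})

test_that("random small subARGs always satisfy the structural invariants", {
  set.seed(99)
  for (rep in 1:150) {
    n <- sample(4:9, 1L)
    L <- sample(3:7, 1L)
    vals <- matrix(sample(1:4, n * L, replace = TRUE), n, L)
    g <- toy_genotypes(vals)
    thr <- sample(1:3, 1L)
    r <- detect_recombinations(g, dsr_params(threshold = thr))
    a <- estimate_ages(build_subarg(g, r))
    expect_silent(validate_subarg(a))
  }
})

test_that("recombination signal needs locus order: shuffled columns score no higher", {
  set.seed(21)
  totals <- replicate(12, {
    cfg <- sim_config(n_populations = 2, samples_per_population = 8,
                      loci_per_chromosome = 20, divergence = 2,
                      recombination_rate = 0.3, missing_fraction = 0,
                      seed = sample.int(1e6, 1))
    g <- simulate_panel(cfg)$genotypes
    r1 <- detect_recombinations(g, dsr_params(threshold = 1))
    shuf <- genotype_matrix(unclass(g)[, sample(ncol(g))],
                            rownames(g), paste0("S", seq_len(ncol(g))))
    r2 <- detect_recombinations(shuf, dsr_params(threshold = 1))
    c(sum(r1), sum(r2))
  })
  # paired comparison: shuffling must not systematically inflate support
  p <- stats::wilcox.test(totals[1, ], totals[2, ], paired = TRUE,
                          exact = FALSE)$p.value
  expect_gt(p, 0.01)
})

test_that("distances rank-correlate with true TMRCA on recombination-free panels", {
  rhos <- vapply(c(11L, 12L, 13L), function(seed) {
    cfg <- sim_config(n_populations = 2, samples_per_population = 10,
                      loci_per_chromosome = rep(10L, 4L), divergence = 5,
                      recombination_rate = 0, bottleneck = 1,
                      missing_fraction = 0, seed = seed)
    pack <- simulate_panel(cfg)
    r <- detect_recombinations(pack$genotypes, dsr_params(threshold = 1))
    d <- pairwise_distances(estimate_ages(build_subarg(pack$genotypes, r)))
    lt <- lower.tri(d)
    stats::cor(d[lt], pack$true_tmrca[lt], method = "spearman")
  }, numeric(1L))
  expect_true(all(rhos >= 0.7))
})

test_that("subARG JSON and PHYLIP distance files round-trip", {
  g <- planted_recombinant()
  a <- estimate_ages(build_subarg(g, detect_recombinations(
    g, dsr_params(threshold = 2))))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_subarg(a, tmp)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(back$sample_ids, a$sample_ids)
  expect_equal(nrow(back$nodes), nrow(a$nodes))

  d <- pairwise_distances(a)
  phy <- withr::local_tempfile(fileext = ".phy")
  write_dist_phylip(d, phy)
  d2 <- read_dist_phylip(phy)
  expect_equal(d2, d, tolerance = 1e-8)
})
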