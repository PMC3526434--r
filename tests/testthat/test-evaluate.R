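test_that("contingency tables count reference/computed intersections", {
  ref <- c(a = "X", b = "X", c = "Y", d = "Y", e = "Y", f = "Z")
  comp <- c(a = "1", b = "1", c = "1", d = "2", e = "2", f = "2")
  tab <- contingency(ref, comp)
  expect_equal(unclass(tab),
               matrix(c(2L, 1L, 0L, 0L, 2L, 1L), 3, 2,
                      dimnames = list(c("X", "Y", "Z"), c("1", "2"))),
               ignore_attr = TRUE)
  # identity: diagonal table with the class sizes
  tid <- contingency(ref, ref)
  expect_equal(unname(diag(unclass(tid))), c(2L, 3L, 1L))
  expect_equal(sum(tid) - sum(diag(unclass(tid))), 0L)
  # one giant cluster: a single column holding the c_i vector
  tgiant <- contingency(ref, setNames(rep("g", 6), names(ref)))
  expect_equal(dim(tgiant), c(3L, 1L))
  expect_equal(unname(unclass(tgiant)[, 1L]), c(2L, 3L, 1L))
  expect_error(contingency(ref, comp[1:5]), "different samples")
})

test_that("label assignment maximizes the diagonal, matching exhaustive search", {
  # diagonal-dominant table: identity permutation
  m <- contingency_from_counts(rbind(c(9, 1, 0), c(0, 8, 2), c(1, 0, 7)),
                               letters[1:3], LETTERS[1:3])
  lab <- assign_labels(m)
  expect_equal(attr(lab, "permutation"), 1:3)
  expect_equal(colnames(lab), rownames(lab))
  # 2-cycle of maxima
  m2 <- contingency_from_counts(rbind(c(0, 9, 0), c(9, 0, 0), c(0, 0, 5)),
                                letters[1:3], LETTERS[1:3])
  expect_equal(attr(assign_labels(m2), "permutation"), c(2L, 1L, 3L))
  # random tables k = 4..6 against brute force over all k! permutations
  set.seed(31)
  for (k in 4:6) {
    for (rep in 1:6) {
      cnt <- matrix(sample(0:20, k * k, replace = TRUE), k, k)
      tab <- contingency_from_counts(cnt, paste0("r", 1:k), paste0("c", 1:k))
      lab <- assign_labels(tab)
      bf <- brute_force_assignment(cnt)
      expect_equal(sum(diag(unclass(lab))), bf$value)
    }
  }
  expect_error(assign_labels(contingency_from_counts(
    matrix(1L, 2, 3), c("a", "b"), c("x", "y", "z"))), "square")
})

test_that("assignment ties break to the lexicographically smallest permutation", {
  m <- contingency_from_counts(rbind(c(5, 5, 0), c(5, 5, 0), c(0, 0, 5)),
                               letters[1:3], LETTERS[1:3])
  expect_equal(attr(assign_labels(m), "permutation"), c(1L, 2L, 3L))
})

test_that("precision and recall follow the contingency sums", {
  tab <- contingency_from_counts(rbind(c(2, 0), c(1, 1)),
                                 c("r1", "r2"), c("r1", "r2"))
  pr <- precision_recall(tab)
  expect_equal(pr$precision, rbind(c(2 / 3, 0), c(1 / 3, 1)),
               ignore_attr = TRUE)
  expect_equal(pr$recall, rbind(c(1, 0), c(1 / 2, 1 / 2)),
               ignore_attr = TRUE)
  # recalls across a row sum to one
  expect_equal(unname(rowSums(pr$recall)), c(1, 1))
  # an empty column yields precision 0 with a warning
  tab0 <- contingency_from_counts(rbind(c(2, 0), c(3, 0)),
                                  c("r1", "r2"), c("c1", "c2"))
  expect_warning(pr0 <- precision_recall(tab0), "empty cluster")
  expect_true(all(pr0$precision[, 2L] == 0))
})

test_that("the F-index matches hand-computed and closed-form cases", {
  # perfect diagonal agreement
  perfect <- contingency_from_counts(diag(c(4L, 6L, 2L)),
                                     letters[1:3], letters[1:3])
  expect_equal(f_index(perfect)$F, 1.0)
  # [[2,0],[1,1]] by hand: row1 max F = 0.8, row2 max F = 2/3
  tab <- contingency_from_counts(rbind(c(2, 0), c(1, 1)),
                                 c("r1", "r2"), c("r1", "r2"))
  expect_equal(f_index(tab)$F, 0.5 * 0.8 + 0.5 * (2 / 3))
  # one giant cluster vs balanced 2-class reference: F = 2/3
  giant <- contingency_from_counts(cbind(c(10L, 10L)),
                                   c("r1", "r2"), "all")
  expect_equal(suppressWarnings(f_index(giant)$F), 2 / 3)
  # invariant under simultaneous identical row/column permutation
  set.seed(7)
  cnt <- matrix(sample(0:9, 25, replace = TRUE), 5, 5)
  tab5 <- contingency_from_counts(cnt, paste0("r", 1:5), paste0("r", 1:5))
  p <- sample(5)
  tab5p <- contingency_from_counts(cnt[p, p], paste0("r", 1:5)[p],
                                   paste0("r", 1:5)[p])
  expect_equal(f_index(tab5)$F, f_index(tab5p)$F)
  expect_error(suppressWarnings(
    f_index(contingency_from_counts(matrix(0L, 2, 2),
                                    c("a", "b"), c("a", "b")))), "empty")
})

test_that("the partition metric matches exhaustive split enumeration", {
  skip_if_not_installed("phangorn")
  t1 <- ape::read.tree(text = "((A,B),C,(D,E));")
  expect_equal(partition_metric(t1, t1), 0L)
  t2 <- ape::read.tree(text = "((A,C),B,(D,E));")
  expect_equal(partition_metric(t1, t2), 2L)
  # random binary trees on <= 6 leaves: oracle + phangorn cross-check;
  # symmetry and identity hold throughout
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(4:6, 1L)
    ta <- ape::rtree(n, rooted = FALSE, tip.label = letters[1:n])
    tb <- ape::rtree(n, rooted = FALSE, tip.label = letters[1:n])
    expect_equal(partition_metric(ta, tb), oracle_partition_metric(ta, tb))
    expect_equal(partition_metric(ta, tb), partition_metric(tb, ta))
    expect_equal(partition_metric(ta, ta), 0L)
    expect_equal(partition_metric(ta, tb),
                 as.integer(phangorn::RF.dist(ta, tb)))
  }
  expect_error(partition_metric(t1, ape::read.tree(text = "((A,B),C,(D,F));")),
               "leaf sets")
})

test_that("the agreement index complements the normalized partition metric", {
  t1 <- ape::read.tree(text = "((A,B),C,(D,E));")
  expect_equal(agreement_index(t1, t1), 1.0)
  t2 <- ape::read.tree(text = "((A,C),B,(D,E));")
  expect_equal(agreement_index(t1, t2), 1 - 2 / 4)
  # disjoint split sets give zero agreement
  c1 <- ape::read.tree(text = "((A,B),(C,D),(E,F));")
  c2 <- ape::read.tree(text = "((A,F),(C,B),(E,D));")
  expect_equal(agreement_index(c1, c2), 0)
  expect_equal(partition_metric(c1, c2),
               length(tree_internal_edges(c1)) +
                 length(tree_internal_edges(c2)))
})

test_that("the majority-class reduction keeps each class's plurality cluster", {
  tr <- ape::read.tree(text = "(((a1,a2),(a3,b3)),((b1,b2),(c1,c2)));")
  tr <- ape::unroot(tr)
  ref <- c(a1 = "A", a2 = "A", a3 = "A", b3 = "B", b1 = "B", b2 = "B",
           c1 = "C", c2 = "C")
  part <- c(a1 = 0L, a2 = 0L, a3 = 0L, b3 = 0L, b1 = 1L, b2 = 1L,
            c1 = 2L, c2 = 2L)
  kept <- argstr:::majority_class_samples(ref, part)
  # class B splits 1 + 2 across clusters; only its pair is kept
  expect_setequal(kept, c("a1", "a2", "a3", "b1", "b2", "c1", "c2"))
  a <- agreement_index(tr, tr, ref = ref, part1 = part, part2 = part)
  expect_equal(a, 1.0)
})

test_that("contingency tables round-trip through CSV", {
  tab <- cacao_contingency("complete")
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_contingency(tab, tmp)
  back <- read_contingency(tmp)
  expect_equal(unclass(back), unclass(tab), ignore_attr = TRUE)
  expect_equal(rownames(back), rownames(tab))
})

test_that("half-up rounding rounds .5 away from zero", {
  expect_equal(round_half_up(0.965), 0.97)
  expect_equal(round_half_up(0.125), 0.13)
  expect_equal(round_half_up(c(0.72, 0.9649)), c(0.72, 0.96))
})
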