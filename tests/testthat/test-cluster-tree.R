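make_D <- function(vals, labels) {
  m <- length(labels)
  D <- matrix(0, m, m, dimnames = list(labels, labels))
  D[upper.tri(D)] <- vals
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  D
}

test_that("complete linkage reproduces hand agglomerations", {
  # D(a,b)=2, D(a,c)=5, D(b,c)=5: {a,b} at 2, then root at 5
  D <- make_D(c(2, 5, 5), c("a", "b", "c"))
  tree <- complete_linkage(D)
  expect_equal(sort(tree$hclust$height), c(2, 5))
  expect_equal(unname(tree$leaf_heights[c("a", "b", "c")]), c(2, 2, 5))
  expect_equal(tree$lca_heights["a", "c"], 5)

  # m = 2: one merge at D(a,b)
  tree2 <- complete_linkage(make_D(3.5, c("x", "y")))
  expect_equal(tree2$hclust$height, 3.5)

  # all distances equal: all merge heights equal
  tree3 <- complete_linkage(make_D(rep(7, 6), letters[1:4]))
  expect_equal(tree3$hclust$height, rep(7, 3))

  expect_error(complete_linkage(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_error(complete_linkage(make_D(-1, c("a", "b"))), "non-negative")
})

test_that("complete linkage merge heights match a naive agglomeration oracle", {
  set.seed(55)
  for (i in 1:100) {
    m <- sample(3:9, 1)
    pts <- matrix(runif(m * 3), m)
    D <- as.matrix(dist(pts))
    dimnames(D) <- list(letters[1:m], letters[1:m])
    tree <- complete_linkage(D)
    expect_equal(sort(tree$hclust$height),
                 sort(complete_linkage_oracle(D)), tolerance = 1e-12)
    # merge heights are non-decreasing (monotone linkage)
    expect_true(all(diff(tree$hclust$height) >= -1e-12))
  }
})

test_that("tree distance implements the four height cases", {
  # siblings: Hmax = H1 = H2 -> 0
  D <- make_D(c(2, 5, 5), c("a", "b", "c"))
  tree <- complete_linkage(D)
  expect_equal(tree_distance(tree, "a", "b"), 0)
  # Hmax = H2 -> |Hmax - H1| = |5 - 2| = 3
  expect_equal(tree_distance(tree, "a", "c"), 3)
  expect_equal(tree_distance(tree, "c", "a"), 3)  # symmetry

  # 4 leaves: a,b merge at 2; c,d at 3; root at 10 -> |10 - 2 - 3| = 5
  D4 <- make_D(c(2, 10, 10, 10, 10, 3), c("a", "b", "c", "d"))
  tree4 <- complete_linkage(D4)
  expect_equal(sort(tree4$hclust$height), c(2, 3, 10))
  expect_equal(tree_distance(tree4, "a", "c"), 5)
  expect_equal(tree_distance(tree4, "a", "d"), 5)
  expect_equal(tree_distance(tree4, "a", "b"), 0)

  expect_error(tree_distance(tree4, "a", "zz"), "unknown leaf")
})

test_that("tree distance is symmetric and bounded by t_n on survival families", {
  for (seed in c(3, 19, 41)) {
    fam <- random_family(seed, n = 60)
    tree <- complete_linkage(distance_matrix(fam))
    lab <- tree$labels
    for (i in seq_along(lab)) {
      for (j in seq_along(lab)) {
        d <- tree_distance(tree, lab[i], lab[j])
        expect_equal(d, tree_distance(tree, lab[j], lab[i]))
        expect_gte(d, 0)
        expect_lte(d, fam$t_n + 1e-9)
      }
    }
  }
})

test_that("equivalence classes partition the family by shared feature", {
  g2 <- cbind(m1 = rep("BB", 6), m2 = rep(c("AA", "AB"), 3))
  rownames(g2) <- sprintf("t%d", 1:6)
  surv2 <- data.frame(sample = rownames(g2), time = 10 * (1:6),
                      event = rep(1L, 6))
  fam <- build_family(g2, surv2)
  cls1 <- equivalence_classes(fam, 1)
  expect_length(cls1, 1L)
  expect_setequal(cls1[[1]]$members, c("BB,AA", "BB,AB"))
  expect_equal(cls1[[1]]$feature, "BB")
  cls2 <- equivalence_classes(fam, 2)
  expect_length(cls2, 2L)
  expect_true(all(lengths(lapply(cls2, `[[`, "members")) == 1L))

  # full 9-curve family: attribute 1 gives three classes of three
  combos <- expand.grid(a = c("AA", "AB", "BB"), b = c("AA", "AB", "BB"),
                        stringsAsFactors = FALSE)
  g9 <- as.matrix(combos[rep(1:9, each = 2), ])
  dimnames(g9) <- list(sprintf("u%02d", 1:18), c("m1", "m2"))
  s9 <- data.frame(sample = rownames(g9), time = seq_len(18) * 7,
                   event = rep(1L, 18))
  fam9 <- build_family(g9, s9)
  cls9 <- equivalence_classes(fam9, 1)
  expect_length(cls9, 3L)
  expect_true(all(lengths(lapply(cls9, `[[`, "members")) == 3L))
  # partition: classes are disjoint and cover all curves
  members <- unlist(lapply(cls9, `[[`, "members"))
  expect_setequal(members, apply(fam9$labels, 1, paste, collapse = ","))
  expect_equal(anyDuplicated(members), 0L)

  expect_error(equivalence_classes(fam9, 3), "out of range")
})

test_that("class distance equals the brute-force maximum over member pairs", {
  for (seed in c(7, 23)) {
    fam <- random_family(seed, n = 80)
    tree <- complete_linkage(distance_matrix(fam))
    for (j in 1:2) {
      for (cls in equivalence_classes(fam, j)) {
        members <- cls$members
        brute <- 0
        if (length(members) >= 2) {
          pairs <- combn(members, 2)
          brute <- max(apply(pairs, 2, function(p)
            tree_distance(tree, p[1], p[2])))
        }
        expect_equal(class_distance(cls, tree), brute)
      }
    }
  }
  # singleton class -> 0
  fam <- random_family(7, n = 80)
  tree <- complete_linkage(distance_matrix(fam))
  singleton <- structure(list(attribute = 1L, feature = "AA",
                              members = tree$labels[1]),
                         class = "equivalence_class")
  expect_equal(class_distance(singleton, tree), 0)
})
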