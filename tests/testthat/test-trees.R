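test_that("rooted Faith's PD matches hand-enumerated edge sums", {
  tr <- balanced4()
  expect_equal(faith_pd(tr, c("A", "B")), 3)
  expect_equal(faith_pd(tr, c("A", "B", "C", "D")), 6)
  expect_equal(faith_pd(tr, character(0)), 0)
  expect_equal(faith_pd(tr, "A"), 2)        # tip edge + stem to root
  expect_error(faith_pd(tr, c("A", "Z")), "Z")
})

test_that("branch partition follows the PD inclusion-exclusion identities", {
  tr <- balanced4()
  expect_equal(branch_partition(tr, c("A", "B"), c("C", "D")),
               list(a = 0, b = 3, c = 3))
  expect_equal(branch_partition(tr, c("A", "B"), c("A", "C")),
               list(a = 2, b = 1, c = 2))
  bp <- branch_partition(tr, c("A", "C"), c("A", "C"))
  expect_equal(bp, list(a = faith_pd(tr, c("A", "C")), b = 0, c = 0))
  # a + b + c = PD(union) on random trees and subsets
  set.seed(11)
  for (rep in 1:20) {
    rt <- ape::rtree(10)
    c1 <- sample(rt$tip.label, sample(2:6, 1))
    c2 <- sample(rt$tip.label, sample(2:6, 1))
    bp <- branch_partition(rt, c1, c2)
    expect_equal(bp$a + bp$b + bp$c, faith_pd(rt, union(c1, c2)),
                 tolerance = 1e-12)
  }
  expect_error(branch_partition(tr, character(0), "A"), "non-empty")
})

test_that("phylo_simpson matches examples, oracle, symmetry and range", {
  tr <- balanced4()
  expect_equal(phylo_simpson(tr, c("A", "B"), c("C", "D")), 1)
  expect_equal(phylo_simpson(tr, c("A", "B"), c("A", "C")), 1 / 3)
  expect_equal(phylo_simpson(tr, c("A", "C"), c("A", "C")), 0)
  set.seed(7)
  for (rep in 1:30) {
    rt <- ape::rtree(8)
    c1 <- sample(rt$tip.label, sample(1:6, 1))
    c2 <- sample(rt$tip.label, sample(1:6, 1))
    b12 <- phylo_simpson(rt, c1, c2)
    expect_equal(b12, oracle_beta_sim(rt, c1, c2), tolerance = 1e-12)
    expect_equal(b12, phylo_simpson(rt, c2, c1))
    expect_gte(b12, 0); expect_lte(b12, 1)
  }
})

test_that("vectorized all-pairs turnover agrees with the scalar API", {
  set.seed(21)
  rt <- ape::rtree(12)
  pa <- matrix(runif(8 * 12) < 0.5, 8, 12,
               dimnames = list(NULL, rt$tip.label))
  pa[rowSums(pa) == 0, 1] <- TRUE
  B <- pairwise_phylo_simpson(rt, pa)
  expect_equal(B, t(B))
  expect_equal(diag(B), rep(0, 8))
  for (i in 1:7) for (j in (i + 1):8) {
    expect_equal(B[i, j],
                 phylo_simpson(rt, rt$tip.label[pa[i, ]],
                               rt$tip.label[pa[j, ]]),
                 tolerance = 1e-12)
  }
})

test_that("delta transform: identity, fixed endpoints, example, monotonicity", {
  tr <- balanced4()
  d1 <- delta_transform(tr, 1)
  expect_equal(ape::cophenetic.phylo(d1), ape::cophenetic.phylo(tr),
               tolerance = 1e-9)
  cherry <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(delta_transform(cherry, 10)$edge.length, cherry$edge.length)
  ex <- delta_transform(ape::read.tree(text = "((A:0.5,B:0.5):0.5);"), 3)
  expect_equal(sort(ex$edge.length), c(0.125, 0.875, 0.875))
  set.seed(3)
  for (delta in c(0.1, 0.3, 3, 10)) {
    rt <- ape::rcoal(10)
    out <- delta_transform(rt, delta)
    h <- max(ape::node.depth.edgelength(rt))
    expect_equal(max(ape::node.depth.edgelength(out)), h, tolerance = 1e-9)
    nd_in <- ape::node.depth.edgelength(rt)[-(1:10)] / h
    nd_out <- ape::node.depth.edgelength(out)[-(1:10)] / h
    if (delta > 1) expect_true(all(nd_out <= nd_in + 1e-12))
    else expect_true(all(nd_out >= nd_in - 1e-12))
  }
  expect_error(delta_transform(tr, 0), "positive")
})

test_that("truncation collapses crossing branches and partitions the tips", {
  tr <- balanced4()
  deep <- truncate_tree(tr, 1.5)
  expect_equal(length(deep$tree$tip.label), 4)
  expect_equal(length(unique(deep$mapping)), 4)
  shallow <- truncate_tree(tr, 0.5)
  expect_equal(length(shallow$tree$tip.label), 2)
  expect_equal(shallow$mapping[["A"]], shallow$mapping[["B"]])
  expect_equal(shallow$mapping[["C"]], shallow$mapping[["D"]])
  expect_false(shallow$mapping[["A"]] == shallow$mapping[["C"]])
  basal <- truncate_tree(tr, 0)        # cut at the root: two basal clades
  expect_equal(length(basal$tree$tip.label), 2)
  # random trees: groups partition the tips at any depth
  set.seed(5)
  for (rep in 1:10) {
    rt <- ape::rcoal(12)
    h <- max(ape::node.depth.edgelength(rt))
    for (d in runif(3, 0, h * 0.999)) {
      res <- truncate_tree(rt, d)
      expect_setequal(names(res$mapping), rt$tip.label)
      expect_setequal(unique(res$mapping), res$tree$tip.label)
    }
    near_top <- truncate_tree(rt, h * (1 - 1e-9))
    expect_equal(length(near_top$tree$tip.label), 12)
  }
  expect_error(truncate_tree(tr, 2), "height")
})

test_that("collapse_communities ORs occurrence columns per group", {
  tr <- balanced4()
  res <- truncate_tree(tr, 0.5)
  pa <- rbind(c(A = TRUE, B = FALSE, C = FALSE, D = FALSE),
              c(A = FALSE, B = FALSE, C = TRUE, D = TRUE),
              c(A = TRUE, B = TRUE, C = TRUE, D = FALSE))
  cc <- collapse_communities(pa, res$mapping)
  g_ab <- res$mapping[["A"]]; g_cd <- res$mapping[["C"]]
  expect_equal(unname(cc[, g_ab]), c(TRUE, FALSE, TRUE))
  expect_equal(unname(cc[, g_cd]), c(FALSE, TRUE, TRUE))
})

test_that("newick IO round-trips multi-tree files", {
  set.seed(9)
  trees <- list(ape::rcoal(6), ape::rcoal(6))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_trees(trees, path)
  expect_equal(length(readLines(path)), 2)
  back <- read_trees(path)
  expect_equal(ape::cophenetic.phylo(back[[1]]),
               ape::cophenetic.phylo(trees[[1]]), tolerance = 1e-8)
})
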