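test_that("Yule simulation: tip count, unit height, determinism", {
  tr2 <- simulate_tree(2, seed = 1)
  d <- ape::node.depth.edgelength(tr2)
  expect_equal(d[1:2], c(1, 1))                 # both tips at depth 1
  tr <- simulate_tree(50, seed = 4)
  expect_equal(length(tr$tip.label), 50)
  expect_equal(tr$Nnode, 49)                    # binary tree property
  expect_equal(max(ape::node.depth.edgelength(tr)), 1, tolerance = 1e-12)
  expect_identical(ape::write.tree(simulate_tree(20, seed = 9)),
                   ape::write.tree(simulate_tree(20, seed = 9)))
  expect_false(identical(ape::write.tree(simulate_tree(20, seed = 9)),
                         ape::write.tree(simulate_tree(20, seed = 10))))
  expect_error(simulate_tree(1), "at least 2")
})

test_that("Brownian niches: degenerate rate, determinism, variance identity", {
  tr <- simulate_tree(6, seed = 11)
  flat <- evolve_niches(tr, 0, c(0.3, 0.7), seed = 1)
  expect_true(all(flat[, 1] == 0.3) && all(flat[, 2] == 0.7))
  expect_identical(evolve_niches(tr, 0.1, seed = 2),
                   evolve_niches(tr, 0.1, seed = 2))
  # Monte-Carlo check of Var(x_i - x_j) = 2 * sigma2 * (1 - depth(mrca))
  sigma2 <- 0.5
  pair <- tr$tip.label[1:2]
  mrca <- ape::getMRCA(tr, pair)
  t_shared <- ape::node.depth.edgelength(tr)[mrca]
  expected <- 2 * sigma2 * (1 - t_shared)
  sq <- vapply(1:1000, function(i) {
    z <- evolve_niches(tr, sigma2, c(0, 0), seed = 10000 + i)
    (z[pair[1], 1] - z[pair[2], 1])^2
  }, numeric(1))
  expect_equal(mean(sq), expected, tolerance = 0.05)
})

test_that("Gaussian ranges: limits, center presence, enumeration oracle", {
  g <- crossed_gradients(20)
  centers <- rbind(sp1 = c(10, 10), sp2 = c(3, 17))
  breadths <- rbind(c(4, 4), c(2, 6))
  occ <- build_ranges(centers, breadths, g$env1, g$env2, threshold = 0.5)
  # brute-force cell-by-cell oracle
  for (s in 1:2) {
    expected <- logical(400)
    for (cell in 1:400) {
      e1 <- g$env1$values[cell]; e2 <- g$env2$values[cell]
      suit <- exp(-((e1 - centers[s, 1])^2 / (2 * breadths[s, 1]^2) +
                    (e2 - centers[s, 2])^2 / (2 * breadths[s, 2]^2)))
      expected[cell] <- suit >= 0.5
    }
    expect_equal(unname(occ$pa[, s]), expected)
  }
  # threshold -> 0+: species occupies every land cell
  occ_all <- build_ranges(centers, breadths, g$env1, g$env2, threshold = 1e-100)
  expect_true(all(occ_all$pa))
  # cell exactly at the center is always present
  center_cell <- which(g$env1$values == 10 & g$env2$values == 10)
  expect_true(all(occ$pa[center_cell, "sp1"]))
  expect_error(build_ranges(centers, breadths, g$env1, g$env2, threshold = 2),
               "threshold")
  expect_warning(
    occ_drop <- build_ranges(rbind(sp1 = c(10, 10), sp_far = c(1e6, 1e6)),
                             rbind(c(4, 4), c(1, 1)), g$env1, g$env2, 0.5),
    "empty ranges")
  expect_equal(colnames(occ_drop$pa), "sp1")
})

test_that("simulate_dataset is reproducible and internally consistent", {
  cfg <- synthetic_config(rows = 20, cols = 20, n_species = 15, n_trees = 3,
                          seed = 21)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$occ$pa, b$occ$pa)
  expect_identical(ape::write.tree(a$trees[[2]]), ape::write.tree(b$trees[[2]]))
  expect_equal(length(a$trees), 3)
  expect_true(all(colnames(a$occ$pa) %in% a$tree$tip.label))
  expect_equal(mean(a$land), 0.9, tolerance = 0.02)
  # candidate trees keep the tip set and unit height
  expect_setequal(a$trees[[1]]$tip.label, a$tree$tip.label)
  expect_equal(max(ape::node.depth.edgelength(a$trees[[3]])), 1,
               tolerance = 1e-12)
})

test_that("barrier scenarios split niche centers across the env1 midline", {
  cfg <- synthetic_config(rows = 20, cols = 20, n_species = 16, n_trees = 2,
                          scenario = "basal_barrier", seed = 31)
  ds <- simulate_dataset(cfg)
  r1 <- range(ds$env1$values[ds$land])
  midline <- mean(r1)
  side <- ds$centers[, 1] > midline
  expect_gt(sum(side), 0); expect_gt(sum(!side), 0)
  # basal scenario: sides coincide with the two basal clades
  root_kids <- ds$tree$edge[ds$tree$edge[, 1] == 17, 2]
  clade1 <- if (root_kids[1] <= 16) ds$tree$tip.label[root_kids[1]] else
    ape::extract.clade(ds$tree, root_kids[1])$tip.label
  expect_true(all(side[clade1] == side[clade1][1]))
  expect_true(all(side[setdiff(ds$tree$tip.label, clade1)] != side[clade1][1]))
  # recent scenario: cherries straddle the midline
  cfg2 <- synthetic_config(rows = 20, cols = 20, n_species = 16, n_trees = 2,
                           scenario = "recent_barrier", seed = 31)
  ds2 <- simulate_dataset(cfg2)
  side2 <- ds2$centers[, 1] > mean(range(ds2$env1$values[ds2$land]))
  tr <- ds2$tree
  for (node in 17:max(tr$edge)) {
    kids <- tr$edge[tr$edge[, 1] == node, 2]
    if (all(kids <= 16))
      expect_false(side2[tr$tip.label[kids[1]]] == side2[tr$tip.label[kids[2]]])
  }
})

test_that("halving niche breadths does not decrease mean raw turnover", {
  for (seed in c(101, 202)) {
    vals <- sapply(c(0.2, 0.1), function(br) {
      cfg <- synthetic_config(rows = 22, cols = 22, n_species = 24,
                              n_trees = 2, niche_breadth = br, seed = seed)
      run <- run_pipeline(run_config(synthetic = cfg, k = 5, deltas = 1,
                                     n_trees = 2, sea_penalty = "euclidean",
                                     grid_shape = c(8, 8), seed = seed))
      pairs <- neighboring_strata_means(run$variants$delta_1$records,
                                        run$sites, run$strata,
                                        value = "beta_raw")
      mean(pairs$mean_residual)
    })
    expect_gte(vals[2], vals[1])
  }
})
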