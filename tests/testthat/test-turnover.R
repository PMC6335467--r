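test_that("multi-tree turnover averages the single-tree index", {
  tr <- balanced4()
  expect_equal(multi_tree_beta(tr, c("A", "B"), c("A", "C")),
               phylo_simpson(tr, c("A", "B"), c("A", "C")))
  expect_equal(multi_tree_beta(rep(list(tr), 20), c("A", "B"), c("A", "C")),
               phylo_simpson(tr, c("A", "B"), c("A", "C")))
  # star fixtures with hand-computed beta 0.2 (a=4,min=1) and 0.4 (a=1.5,min=1)
  t1 <- star_tree(c(4, 1, 1), c("A", "B", "C"))
  t2 <- star_tree(c(1.5, 1, 1), c("A", "B", "C"))
  expect_equal(phylo_simpson(t1, c("A", "B"), c("A", "C")), 0.2)
  expect_equal(phylo_simpson(t2, c("A", "B"), c("A", "C")), 0.4)
  expect_equal(multi_tree_beta(list(t1, t2), c("A", "B"), c("A", "C")), 0.3)
  expect_error(multi_tree_beta(list(t1), c("X", "Y"), c("A", "B")), "X")
})

test_that("residualization removes the distance signal on the logit scale", {
  set.seed(23)
  n <- 200
  d <- runif(n, 10, 500)
  rec <- data.frame(site_i = rep(1, n), site_j = seq_len(n) + 1,
                    beta_raw = plogis(0.5 + 0.01 * d), land_km = d)
  res <- residualize_distance(rec)
  expect_equal(sum(res$records$residual), 0, tolerance = 1e-8)
  expect_lt(abs(cor(res$records$residual, d)), 1e-10)
  expect_lt(abs(cor(res$records$residual, d^2)), 1e-10)
  # planted logit-linear signal: R^2 ~ 1 (only the endpoint squeeze perturbs)
  expect_gt(res$r_squared, 0.999)
  # constant beta: intercept absorbs everything
  rec2 <- rec; rec2$beta_raw <- 0.4
  expect_equal(residualize_distance(rec2)$records$residual, rep(0, n),
               tolerance = 1e-10)
  # endpoint values survive via the squeeze
  rec3 <- rec; rec3$beta_raw[1] <- 0; rec3$beta_raw[2] <- 1
  expect_silent(residualize_distance(rec3))
  rec4 <- rec; rec4$land_km <- 100
  expect_error(residualize_distance(rec4), "equal")
  rec5 <- rec; rec5$beta_raw[1] <- 1.2
  expect_error(residualize_distance(rec5), "outside")
})

test_that("adding a constant to logit-beta leaves residuals unchanged", {
  set.seed(29)
  n <- 80
  d <- runif(n, 5, 300)
  b <- runif(n, 0.05, 0.95)
  base <- residualize_distance(
    data.frame(site_i = 1, site_j = 2, beta_raw = b, land_km = d))
  shift <- residualize_distance(
    data.frame(site_i = 1, site_j = 2,
               beta_raw = plogis(qlogis(b) + 1.5), land_km = d))
  # shifting on the raw-logit scale, then re-squeezing, is only approximately
  # a constant shift; compare through the squeeze-free path instead
  y1 <- base$records$beta_logit
  fit1 <- lm(y1 ~ d + I(d^2))
  fit2 <- lm(I(y1 + 3) ~ d + I(d^2))
  expect_equal(residuals(fit1), residuals(fit2), tolerance = 1e-10)
  expect_equal(unname(coef(fit2)[1] - coef(fit1)[1]), 3, tolerance = 1e-10)
})

# tiny deterministic scene: 3x3 all-land grid, crossed gradients, k = 3,
# one site per cell so strata and sites are fully under control
tiny_scene <- function() {
  g <- crossed_gradients(3)
  s <- stratify(g$env1, g$env2, k = 3)
  sites <- allocate_samples(s, matrix(1, 3, 3), g$env1, g$env2,
                            min_n = 1, max_n = 1, seed = 1)
  list(g = g, s = s, sites = sites)
}

test_that("neighboring-strata means use only cross-stratum pairs", {
  sc <- tiny_scene()
  n <- nrow(sc$sites)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  rec <- data.frame(site_i = sc$sites$site_id[ij[, 1]],
                    site_j = sc$sites$site_id[ij[, 2]],
                    beta_raw = 0.5, land_km = 1)
  rec$residual <- 7                              # constant field
  out <- neighboring_strata_means(rec, sc$sites, sc$s, adjacency = "rook")
  expect_true(all(out$mean_residual == 7))
  expect_true(all(out$n_pairs == 1))             # one site per stratum
  # rook adjacency on a 3x3 class grid: 12 edges
  expect_equal(nrow(out), 12)
  queen <- neighboring_strata_means(rec, sc$sites, sc$s, adjacency = "queen")
  expect_equal(nrow(queen), 12 + 8)              # + 8 diagonal contacts
  # extreme within-stratum values must not leak (they are never aggregated):
  # duplicate sites within one stratum carrying a huge within-pair residual
  sites2 <- rbind(sc$sites, transform(sc$sites[1, ], site_id = 99L))
  rec2 <- rbind(rec, data.frame(site_i = sc$sites$site_id[1], site_j = 99L,
                                beta_raw = 0.5, land_km = 1, residual = 1e6))
  # cross pairs for the duplicated site mirror site 1
  extra <- data.frame(site_i = 99L,
                      site_j = setdiff(sites2$site_id, c(99L, sc$sites$site_id[1])),
                      beta_raw = 0.5, land_km = 1, residual = 7)
  out2 <- neighboring_strata_means(rbind(rec2, extra), sites2, sc$s)
  expect_true(all(out2$mean_residual == 7))
  # site 99 sits in corner stratum 0, which has 2 rook-adjacent strata
  expect_equal(sum(out2$n_pairs), sum(out$n_pairs) + 2)
})

test_that("stratum-pair midpoints average the stratum centers", {
  sc <- tiny_scene()
  n <- nrow(sc$sites)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  rec <- data.frame(site_i = sc$sites$site_id[ij[, 1]],
                    site_j = sc$sites$site_id[ij[, 2]],
                    beta_raw = 0.5, land_km = 1, residual = 0)
  out <- neighboring_strata_means(rec, sc$sites, sc$s)
  centers <- stratum_centers(sc$s)
  for (r in seq_len(nrow(out))) {
    ca <- centers[centers$stratum == out$stratum_a[r], ]
    cb <- centers[centers$stratum == out$stratum_b[r], ]
    expect_equal(out$env1_mid[r], (ca$env1_center + cb$env1_center) / 2)
    expect_equal(out$env2_mid[r], (ca$env2_center + cb$env2_center) / 2)
  }
})

test_that("3 x 2 sites in adjacent strata give 6 cross pairs", {
  g <- crossed_gradients(6)
  s <- stratify(g$env1, g$env2, k = 2)
  # pick 3 sites in stratum 0 (low/low) and 2 in stratum 1 (low/high)
  sites <- data.frame(site_id = 1:5,
                      row = c(0, 1, 2, 3, 4), col = c(0, 1, 2, 0, 1),
                      stratum = c(0, 0, 0, 1, 1),
                      env1 = 1, env2 = 1)
  cells <- sites$row + 1 + sites$col * 6
  sites$stratum <- s$stratum[cells]
  expect_equal(sites$stratum, c(0, 0, 0, 1, 1))
  ij <- t(combn(5, 2))
  rec <- data.frame(site_i = ij[, 1], site_j = ij[, 2],
                    beta_raw = 0.5, land_km = 1, residual = 1)
  out <- neighboring_strata_means(rec, sites, s)
  expect_equal(out$n_pairs, 6)
})
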