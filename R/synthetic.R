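# Synthetic inputs with known structure: a gridded land/sea study area with
# two correlated environmental gradients, a dated (Yule) phylogeny, Brownian
# niche evolution on the tree, and Gaussian-suitability species ranges.
# Stands in for real range maps, climate layers and dated phylogenies so the
# whole pipeline is testable offline.

#' Occurrence data container
#'
#' Presence/absence of every species in every grid cell, stored as a logical
#' matrix with one row per cell (column-major cell order) and one column per
#' species.
#'
#' @param pa logical cells x species matrix with species column names.
#' @param nrow,ncol grid dimensions (`nrow * ncol == nrow(pa)`).
#' @return object of class `occurrence_data`.
#' @export
occurrence_data <- function(pa, nrow, ncol) {
  pa <- as.matrix(pa)
  if (nrow * ncol != base::nrow(pa)) stop("pa rows must equal nrow * ncol")
  if (is.null(colnames(pa))) stop("species column names required")
  structure(list(pa = pa, nrow = nrow, ncol = ncol),
            class = "occurrence_data")
}

#' @export
print.occurrence_data <- function(x, ...) {
  cat(sprintf("<occurrence_data> %d x %d grid, %d species, mean occupancy %.1f cells\n",
              x$nrow, x$ncol, ncol(x$pa), mean(colSums(x$pa))))
  invisible(x)
}

#' Site communities from occurrence data
#'
#' Extracts the species lists of the sampled cells as a logical site x
#' species matrix.
#'
#' @param sites a `sample_sites` data.frame.
#' @param occ an [occurrence_data()].
#' @return logical matrix, rows named by `site_id`.
#' @export
site_communities <- function(sites, occ) {
  stopifnot(inherits(occ, "occurrence_data"))
  cells <- sites$row + 1L + sites$col * occ$nrow
  m <- occ$pa[cells, , drop = FALSE]
  rownames(m) <- sites$site_id
  m
}

#' Synthetic scenario configuration
#'
#' Bundles the generator parameters. Defaults describe a mid-sized temperate
#' study system: a 40 x 40 grid at the 15 km resolution of the source layers,
#' about 10% sea, 40 species on a unit-height Yule tree, Brownian niche
#' evolution with per-axis rate 0.04 (in squared normalized env units per
#' unit tree height) and niche breadths of 0.2 of each gradient's range,
#' which yields ranges spanning a few environmental strata.
#'
#' @param rows,cols grid dimensions.
#' @param sea_fraction fraction of cells that are sea, in `[0, 1)`.
#' @param n_species number of tips (>= 2).
#' @param birth_rate Yule speciation rate (shape only; height is normalized).
#' @param sigma2 Brownian rate per axis in normalized (0-1) env units^2.
#' @param niche_breadth per-axis niche standard deviation as a fraction of
#'   each gradient's range (length 1 or 2).
#' @param threshold suitability cutoff in (0, 1) for presence.
#' @param n_trees number of candidate phylogenies (branch-length jittered
#'   copies of the generating tree) emulating phylogenetic uncertainty.
#' @param res_km cell size in km.
#' @param env_cor target correlation between the two gradients.
#' @param scenario `"none"`, `"basal_barrier"` (the two basal clades are
#'   confined to opposite ends of the env1 gradient) or `"recent_barrier"`
#'   (sister species straddle the env1 midline, so the barrier is carried by
#'   recent branches only).
#' @param seed integer seed fixing every stochastic draw.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(rows = 40, cols = 40, sea_fraction = 0.1,
                             n_species = 40, birth_rate = 1, sigma2 = 0.04,
                             niche_breadth = 0.2, threshold = 0.5,
                             n_trees = 20, res_km = 15, env_cor = 0.3,
                             scenario = c("none", "basal_barrier",
                                          "recent_barrier"),
                             seed = 1) {
  scenario <- match.arg(scenario)
  if (sea_fraction < 0 || sea_fraction >= 1) stop("sea_fraction in [0, 1)")
  if (n_species < 2) stop("need at least 2 species")
  if (threshold <= 0 || threshold >= 1) stop("threshold in (0, 1)")
  if (sigma2 < 0 || birth_rate <= 0 || any(niche_breadth <= 0))
    stop("rates and breadths must be positive")
  structure(as.list(environment()), class = "synthetic_config")
}

# smooth random field: standard normal matrix passed through repeated 3x3
# box blur, then re-standardized
.smooth_field <- function(rows, cols, passes = 4) {
  m <- matrix(stats::rnorm(rows * cols), rows, cols)
  for (i in seq_len(passes)) {
    p <- rbind(m[1, ], m, m[rows, ])
    p <- cbind(p[, 1], p, p[, cols])
    m <- (p[1:rows, 1:cols] + p[1:rows, 2:(cols + 1)] + p[1:rows, 3:(cols + 2)] +
          p[2:(rows + 1), 1:cols] + p[2:(rows + 1), 2:(cols + 1)] +
          p[2:(rows + 1), 3:(cols + 2)] +
          p[3:(rows + 2), 1:cols] + p[3:(rows + 2), 2:(cols + 1)] +
          p[3:(rows + 2), 3:(cols + 2)]) / 9
  }
  (m - mean(m)) / stats::sd(m)
}

#' Simulate a synthetic landscape
#'
#' Sea cells are the lowest `sea_fraction` quantile of a smooth random field
#' (so they form clumped seas and straits). env1 ("temperature", 0-25 units)
#' follows the column axis, env2 ("moisture", -50 to 100 units) follows the
#' row axis with an `env_cor` admixture of env1; both carry smooth noise.
#'
#' @param config a [synthetic_config()].
#' @return list with `env1`, `env2` ([env_raster()]) and `land` matrix.
#' @export
make_landscape <- function(config) {
  .with_seed(config$seed, {
    rows <- config$rows; cols <- config$cols
    sea_field <- .smooth_field(rows, cols)
    land <- matrix(TRUE, rows, cols)
    if (config$sea_fraction > 0)
      land <- sea_field > stats::quantile(sea_field, config$sea_fraction)
    colfrac <- matrix(rep((seq_len(cols) - 1) / (cols - 1), each = rows),
                      rows, cols)
    rowfrac <- matrix(rep((seq_len(rows) - 1) / (rows - 1), cols), rows, cols)
    g1 <- colfrac + 0.15 * .smooth_field(rows, cols)
    g2 <- (1 - abs(config$env_cor)) * rowfrac +
      config$env_cor * colfrac + 0.15 * .smooth_field(rows, cols)
    unit <- function(m) (m - min(m)) / (max(m) - min(m))
    e1 <- 25 * unit(g1)
    e2 <- -50 + 150 * unit(g2)
    e1[!land] <- NA; e2[!land] <- NA
    list(env1 = env_raster(e1, land, config$res_km),
         env2 = env_raster(e2, land, config$res_km),
         land = land)
  })
}

#' Simulate a Yule phylogeny with unit height
#'
#' Pure-birth tree with exactly `n_species` tips, rescaled so the root-to-tip
#' height is 1; deterministic given the seed.
#'
#' @param n_species number of tips (>= 2).
#' @param birth_rate speciation rate.
#' @param seed integer seed.
#' @return an ultrametric `phylo` with tips `sp001, sp002, ...`.
#' @export
simulate_tree <- function(n_species, birth_rate = 1, seed = 1) {
  if (n_species < 2) stop("need at least 2 species")
  .with_seed(seed, {
    tr <- ape::rphylo(n_species, birth = birth_rate, death = 0)
    h <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length / h
    tr$tip.label <- sprintf("sp%03d", seq_len(n_species))
    tr
  })
}

#' Evolve bivariate niche centers by Brownian motion on a tree
#'
#' Independent Brownian motion along branches on each environmental axis,
#' starting from `root_center`. With `sigma2 = 0` every species inherits the
#' root center exactly.
#'
#' @param tree a `phylo` object.
#' @param sigma2 per-axis Brownian rate (variance per unit branch length);
#'   length 1 or 2.
#' @param root_center numeric length-2 ancestral niche center.
#' @param seed integer seed.
#' @return numeric matrix, tips x 2, rownames = tip labels.
#' @export
evolve_niches <- function(tree, sigma2, root_center = c(0.5, 0.5), seed = 1) {
  if (any(sigma2 < 0)) stop("sigma2 must be >= 0")
  sigma2 <- rep(sigma2, length.out = 2)
  .with_seed(seed, {
    centers <- vapply(1:2, function(axis) {
      if (sigma2[axis] == 0) rep(root_center[axis], length(tree$tip.label))
      else ape::rTraitCont(tree, model = "BM", sigma = sqrt(sigma2[axis]),
                           root.value = root_center[axis])
    }, numeric(length(tree$tip.label)))
    rownames(centers) <- tree$tip.label
    colnames(centers) <- c("env1", "env2")
    centers
  })
}

#' Build species ranges from Gaussian environmental suitability
#'
#' A species is present in a land cell iff its axis-aligned Gaussian
#' suitability `exp(-[(e1 - c1)^2 / (2 b1^2) + (e2 - c2)^2 / (2 b2^2)])`
#' reaches `threshold`. Species left with no occupied cell are dropped with a
#' warning.
#'
#' @param centers tips x 2 matrix of niche centers (env units).
#' @param breadths tips x 2 matrix (or length-2 vector) of niche standard
#'   deviations (env units).
#' @param env1,env2 [env_raster()] layers.
#' @param threshold suitability cutoff in (0, 1).
#' @return an [occurrence_data()].
#' @export
build_ranges <- function(centers, breadths, env1, env2, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  n_sp <- nrow(centers)
  if (is.null(dim(breadths)))
    breadths <- matrix(rep(breadths, length.out = 2), n_sp, 2, byrow = TRUE)
  if (any(breadths <= 0)) stop("breadths must be positive")
  land <- c(env1$land & env2$land)
  e1 <- c(env1$values); e2 <- c(env2$values)
  pa <- vapply(seq_len(n_sp), function(s) {
    suit <- exp(-((e1 - centers[s, 1])^2 / (2 * breadths[s, 1]^2) +
                  (e2 - centers[s, 2])^2 / (2 * breadths[s, 2]^2)))
    land & !is.na(suit) & suit >= threshold
  }, logical(length(e1)))
  colnames(pa) <- rownames(centers)
  empty <- colSums(pa) == 0
  if (any(empty)) {
    warning("dropping species with empty ranges: ",
            paste(colnames(pa)[empty], collapse = ", "))
    pa <- pa[, !empty, drop = FALSE]
  }
  if (ncol(pa) == 0) stop("no species has an occupied cell")
  occurrence_data(pa, nrow(env1$values), ncol(env1$values))
}

# assign each tip to one side of the env1 barrier
.barrier_sides <- function(tree, scenario, seed) {
  tips <- tree$tip.label
  if (scenario == "basal_barrier") {
    root <- length(tips) + 1L
    kids <- tree$edge[tree$edge[, 1] == root, 2]
    clade1 <- if (kids[1] <= length(tips)) tips[kids[1]]
              else ape::extract.clade(tree, kids[1])$tip.label
    stats::setNames(ifelse(tips %in% clade1, 0L, 1L), tips)
  } else {
    # recent_barrier: sister species in each cherry go to opposite sides,
    # so the turnover signal is carried by terminal branches only
    side <- stats::setNames(rep(NA_integer_, length(tips)), tips)
    ntip <- length(tips)
    for (node in (ntip + 1L):max(tree$edge)) {
      kids <- tree$edge[tree$edge[, 1] == node, 2]
      if (all(kids <= ntip)) side[tips[kids]] <- c(0L, 1L)[seq_along(kids)]
    }
    leftover <- names(side)[is.na(side)]
    side[leftover] <- .with_seed(seed + 7L,
      sample(0:1, length(leftover), replace = TRUE))
    side
  }
}

#' Generate a complete synthetic dataset
#'
#' Runs the whole generator: landscape, Yule tree (plus `n_trees` branch-
#' length-jittered copies emulating phylogenetic uncertainty), Brownian niche
#' centers, and Gaussian-suitability ranges. Barrier scenarios override the
#' env1 niche centers: the two sides are placed at 0.25 and 0.75 of the env1
#' range with narrow env1 breadths (0.12 of range), so species ranges do not
#' cross the midline and turnover is concentrated there.
#'
#' @param config a [synthetic_config()].
#' @return list with `config`, `env1`, `env2`, `land`, `tree` (the generating
#'   tree), `trees` (list of candidate trees), `centers`, `breadths`, `occ`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  ls <- make_landscape(config)
  tree <- simulate_tree(config$n_species, config$birth_rate, config$seed + 1L)
  r1 <- range(ls$env1$values[ls$land]); r2 <- range(ls$env2$values[ls$land])
  span1 <- diff(r1); span2 <- diff(r2)
  # niches evolve on normalized axes, then map to env units
  cn <- evolve_niches(tree, config$sigma2, c(0.5, 0.5), config$seed + 2L)
  centers <- cbind(r1[1] + span1 * cn[, 1], r2[1] + span2 * cn[, 2])
  rownames(centers) <- rownames(cn)
  breadth <- rep(config$niche_breadth, length.out = 2)
  breadths <- cbind(rep(breadth[1] * span1, nrow(centers)),
                    rep(breadth[2] * span2, nrow(centers)))
  if (config$scenario != "none") {
    side <- .barrier_sides(tree, config$scenario, config$seed)
    jit <- .with_seed(config$seed + 3L,
                      stats::rnorm(length(side), 0, 0.04 * span1))
    centers[, 1] <- r1[1] + span1 * ifelse(side[rownames(centers)] == 0L,
                                           0.25, 0.75) + jit
    breadths[, 1] <- 0.12 * span1
  }
  trees <- lapply(seq_len(config$n_trees), function(i) {
    .with_seed(config$seed + 100L + i, {
      tr <- tree
      tr$edge.length <- tr$edge.length * stats::rlnorm(length(tr$edge.length),
                                                       0, 0.1)
      tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
      tr
    })
  })
  occ <- suppressWarnings(
    build_ranges(centers, breadths, ls$env1, ls$env2, config$threshold))
  list(config = config, env1 = ls$env1, env2 = ls$env2, land = ls$land,
       tree = tree, trees = trees, centers = centers, breadths = breadths,
       occ = occ)
}
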