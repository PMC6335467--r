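# Pairwise phylogenetic turnover over sites and trees, logit-scale
# residualization against land distance, and aggregation to neighboring
# environmental strata.

#' Mean phylogenetic Simpson turnover over a set of trees
#'
#' Accounts for phylogenetic uncertainty by averaging `beta_sim` over a set of
#' candidate phylogenies (tips matched by name on every tree).
#'
#' @param trees list of `phylo` objects (>= 1).
#' @param comm1,comm2 non-empty character vectors of tip labels.
#' @return arithmetic mean of [phylo_simpson()] across trees.
#' @export
multi_tree_beta <- function(trees, comm1, comm2) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) < 1L) stop("need at least one tree")
  for (tr in trees) {
    missing <- setdiff(union(comm1, comm2), tr$tip.label)
    if (length(missing) == length(comm1) || length(missing) == length(comm2))
      stop("community empty after name matching; unmatched: ",
           paste(missing, collapse = ", "))
  }
  mean(vapply(trees, phylo_simpson, numeric(1), comm1 = comm1, comm2 = comm2))
}

#' All-pairs turnover averaged over trees
#'
#' Fast path for the pipeline: [pairwise_phylo_simpson()] per tree, averaged
#' elementwise.
#'
#' @param trees list of `phylo` objects.
#' @param pa logical site x species matrix (all sites non-empty on all trees).
#' @return symmetric matrix of mean `beta_sim`.
#' @export
pairwise_multi_tree_beta <- function(trees, pa) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  mats <- lapply(trees, pairwise_phylo_simpson, pa = pa)
  Reduce(`+`, mats) / length(mats)
}

#' Build turnover records for all unordered site pairs
#'
#' @param beta symmetric matrix of raw turnover (site order = rows of `sites`).
#' @param dist_km symmetric matrix of land distances (same order).
#' @param sites a `sample_sites` data.frame.
#' @return data.frame with `site_i`, `site_j`, `beta_raw`, `land_km`.
#' @export
turnover_records <- function(beta, dist_km, sites) {
  n <- nrow(sites)
  stopifnot(nrow(beta) == n, nrow(dist_km) == n)
  ij <- which(upper.tri(beta), arr.ind = TRUE)
  data.frame(site_i = sites$site_id[ij[, 1]],
             site_j = sites$site_id[ij[, 2]],
             beta_raw = beta[ij], land_km = dist_km[ij])
}

#' Remove the land-distance effect from turnover (logit-scale residuals)
#'
#' Regresses logit-transformed raw turnover on land distance (linear and
#' quadratic terms) by OLS; the residuals are the turnover fraction
#' independent of geographic land distance. Turnover values of exactly 0 or 1
#' are squeezed into (0, 1) by the Smithson-Verkuilen map
#' `(y * (n - 1) + 0.5) / n` before the logit.
#'
#' @param records a [turnover_records()] data.frame (>= 3 pairs, distances not
#'   all equal).
#' @return list with `records` (input plus `beta_logit` and `residual`
#'   columns), `coefficients` (intercept, distance, distance^2) and
#'   `r_squared`.
#' @export
residualize_distance <- function(records) {
  if (nrow(records) < 3) stop("need at least 3 site pairs")
  b <- records$beta_raw
  if (any(b < 0 | b > 1)) stop("beta_raw outside [0, 1]")
  d <- records$land_km
  if (max(d) - min(d) <= 0) stop("all distances equal: rank-deficient fit")
  n <- length(b)
  y <- stats::qlogis((b * (n - 1) + 0.5) / n)
  fit <- stats::lm(y ~ d + I(d^2))
  records$beta_logit <- y
  records$residual <- stats::residuals(fit)
  # R^2 computed directly (summary.lm warns on near-perfect planted fits)
  r2 <- 1 - sum(records$residual^2) / sum((y - mean(y))^2)
  list(records = records,
       coefficients = stats::coef(fit),
       r_squared = r2)
}

# adjacency of strata in the k x k class grid
.strata_adjacent <- function(id_a, id_b, k, adjacency) {
  d1 <- abs(id_a %/% k - id_b %/% k)
  d2 <- abs(id_a %% k - id_b %% k)
  if (adjacency == "rook") (d1 + d2) == 1 else (pmax(d1, d2) == 1)
}

#' Mean residual turnover between neighboring environmental strata
#'
#' For every pair of strata adjacent in the k x k stratification grid with
#' sample sites on both sides, averages the distance-corrected turnover
#' residuals over all cross-stratum site pairs (within-stratum pairs are never
#' used). The pair is placed in environmental space at the mean of the two
#' stratum centers.
#'
#' @param records residual-filled records (the `records` element of
#'   [residualize_distance()]).
#' @param sites the `sample_sites` data.frame.
#' @param strata the [stratify()] result.
#' @param adjacency `"rook"` (4-neighborhood, default) or `"queen"`.
#' @param value column of `records` to aggregate (default `"residual"`).
#' @return data.frame with `stratum_a`, `stratum_b`, `env1_mid`, `env2_mid`,
#'   `mean_residual`, `n_pairs`.
#' @export
neighboring_strata_means <- function(records, sites, strata,
                                     adjacency = c("rook", "queen"),
                                     value = "residual") {
  adjacency <- match.arg(adjacency)
  if (is.null(records[[value]])) stop("records lack a '", value, "' column")
  k <- strata$k
  centers <- stratum_centers(strata)
  stratum_of <- stats::setNames(sites$stratum, sites$site_id)
  # residual lookup keyed on site pair
  key <- paste(pmin(records$site_i, records$site_j),
               pmax(records$site_i, records$site_j))
  val <- stats::setNames(records[[value]], key)
  occupied <- sort(unique(sites$stratum))
  out <- list()
  for (i in seq_along(occupied)) {
    for (j in seq_len(i - 1L)) {
      sa <- occupied[j]; sb <- occupied[i]
      if (!.strata_adjacent(sa, sb, k, adjacency)) next
      sites_a <- sites$site_id[sites$stratum == sa]
      sites_b <- sites$site_id[sites$stratum == sb]
      pairs <- expand.grid(a = sites_a, b = sites_b)
      pk <- paste(pmin(pairs$a, pairs$b), pmax(pairs$a, pairs$b))
      ca <- centers[centers$stratum == sa, ]
      cb <- centers[centers$stratum == sb, ]
      out[[length(out) + 1L]] <- data.frame(
        stratum_a = sa, stratum_b = sb,
        env1_mid = (ca$env1_center + cb$env1_center) / 2,
        env2_mid = (ca$env2_center + cb$env2_center) / 2,
        mean_residual = mean(val[pk]),
        n_pairs = nrow(pairs))
    }
  }
  if (!length(out)) stop("no adjacent stratum pair has sites on both sides")
  do.call(rbind, out)
}

#' Turnover contrast across an environmental barrier
#'
#' Summary used in synthetic-scenario checks: mean of `mean_residual` for
#' stratum pairs whose env1 midpoint falls in the middle third of the env1
#' range, minus the mean over all other pairs.
#'
#' @param strata_pairs a [neighboring_strata_means()] data.frame.
#' @param env1_range numeric length-2 range of the env1 axis.
#' @return numeric contrast (positive = elevated turnover at the midline).
#' @export
barrier_contrast <- function(strata_pairs, env1_range) {
  lo <- env1_range[1] + diff(env1_range) / 3
  hi <- env1_range[1] + 2 * diff(env1_range) / 3
  mid <- strata_pairs$env1_mid >= lo & strata_pairs$env1_mid <= hi
  if (!any(mid) || all(mid)) return(NA_real_)
  mean(strata_pairs$mean_residual[mid]) - mean(strata_pairs$mean_residual[!mid])
}
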