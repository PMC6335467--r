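# Per-site macroecological characteristics: species richness, Faith's PD,
# relative phylogenetic diversity (PD residual on richness) and realized
# niche size (95% bivariate data-ellipse area in environmental space).

#' Relative phylogenetic diversity
#'
#' Residuals of an OLS regression of PD on species richness (linear and
#' quadratic terms). Positive values mark assemblages of more divergent
#' lineages than expected for their richness; negative values mark radiations
#' of close relatives.
#'
#' @param sr integer vector of species richness (not constant, length >= 4).
#' @param pd numeric vector of phylogenetic diversity, same length.
#' @return numeric residuals in input order (they sum to 0).
#' @export
relative_pd <- function(sr, pd) {
  if (length(sr) < 4 || length(pd) != length(sr))
    stop("need >= 4 paired SR/PD values")
  if (stats::sd(sr) == 0) stop("constant species richness: rank-deficient fit")
  fit <- stats::lm(pd ~ sr + I(sr^2))
  unname(stats::residuals(fit))
}

#' Area of the bivariate data ellipse covering a given fraction of points
#'
#' The covariance-based data ellipse: `area = pi * sqrt(det(S)) * q` where `S`
#' is the sample covariance of the points and `q` the chi-square(2 df)
#' quantile at `coverage` (about 5.9915 at 0.95). Under bivariate normality
#' the ellipse contains `coverage` of the data in expectation.
#'
#' @param points two-column matrix/data.frame of (env1, env2) values for a
#'   species' occupied cells.
#' @param coverage fraction of points to encompass (default 0.95).
#' @return ellipse area in env1-unit x env2-unit; `NA` with a warning for
#'   fewer than 3 points or a singular (collinear) covariance.
#' @export
niche_ellipse_area <- function(points, coverage = 0.95) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2) stop("'points' must have two columns")
  if (coverage <= 0 || coverage >= 1) stop("'coverage' must be in (0, 1)")
  if (nrow(pts) < 3) {
    warning("fewer than 3 points: niche size undefined")
    return(NA_real_)
  }
  S <- stats::cov(pts)
  dS <- det(S)
  if (!is.finite(dS) || dS <= 0) {
    warning("singular covariance (collinear points): niche size undefined")
    return(NA_real_)
  }
  pi * sqrt(dS) * stats::qchisq(coverage, df = 2)
}

#' Site-level niche size
#'
#' Aggregates per-species niche sizes over the species present at a site.
#'
#' @param community character vector of species present.
#' @param per_species_area named numeric vector of [niche_ellipse_area()]
#'   values (may contain `NA` for undefined species, which are skipped).
#' @param method `"mean"` (default) or `"median"`.
#' @return aggregated niche size; `NA` with a warning if no member has a
#'   defined area.
#' @export
site_niche_size <- function(community, per_species_area,
                            method = c("mean", "median")) {
  method <- match.arg(method)
  if (length(community) == 0) stop("empty community")
  a <- per_species_area[community]
  a <- a[!is.na(a)]
  if (!length(a)) {
    warning("no community member with a defined niche area")
    return(NA_real_)
  }
  if (method == "mean") mean(a) else stats::median(a)
}

#' Per-species niche sizes from occupied cells
#'
#' Evaluates the 95% data-ellipse area of each species' occupied land cells in
#' (env1, env2) space.
#'
#' @param occ an occurrence object (see [occurrence_data()]).
#' @param env1,env2 [env_raster()] layers.
#' @param coverage passed to [niche_ellipse_area()].
#' @return named numeric vector, one entry per species (`NA` if undefined).
#' @export
species_niche_sizes <- function(occ, env1, env2, coverage = 0.95) {
  stopifnot(inherits(occ, "occurrence_data"))
  e1 <- c(env1$values); e2 <- c(env2$values)
  vapply(colnames(occ$pa), function(sp) {
    cells <- which(occ$pa[, sp])
    suppressWarnings(niche_ellipse_area(cbind(e1[cells], e2[cells]), coverage))
  }, numeric(1))
}

#' Macroecological characteristics of the sample sites
#'
#' Computes, per site: species richness (SR), rooted Faith's PD (averaged over
#' the supplied trees), relative phylogenetic diversity (relPD, the residual
#' of PD on SR + SR^2) and niche size (NS, mean 95% ellipse area of the
#' species present).
#'
#' @param sites a `sample_sites` data.frame.
#' @param site_pa logical site x species matrix (site communities).
#' @param trees list of `phylo` objects used for PD.
#' @param per_species_area named vector from [species_niche_sizes()].
#' @return data.frame with `site_id`, `SR`, `PD`, `relPD`, `NS`.
#' @export
macroeco_table <- function(sites, site_pa, trees, per_species_area) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  sp <- colnames(site_pa)
  sr <- rowSums(site_pa)
  pd_per_tree <- vapply(trees, function(tr) {
    E <- community_edge_matrix(tr, site_pa)
    as.numeric(E %*% tr$edge.length)
  }, numeric(nrow(site_pa)))
  pd <- rowMeans(matrix(pd_per_tree, nrow = nrow(site_pa)))
  ns <- vapply(seq_len(nrow(site_pa)), function(i) {
    suppressWarnings(site_niche_size(sp[site_pa[i, ]], per_species_area))
  }, numeric(1))
  data.frame(site_id = sites$site_id, SR = as.integer(sr), PD = pd,
             relPD = relative_pd(sr, pd), NS = ns)
}
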