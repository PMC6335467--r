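# Least-cost land distances over the study grid. Sea is expensive (default
# 10x), not forbidden; paths are 8-connected with the standard average-of-
# endpoints edge cost and a sqrt(2) diagonal factor.

#' Construct a traversal-cost surface
#'
#' Per-cell cost multipliers for least-cost paths: 1 on land, `sea_penalty`
#' on sea. `sea_penalty = "euclidean"` switches [land_distance()] and
#' [pairwise_land_distances()] to plain straight-line cell-center distance.
#'
#' @param land logical matrix; `TRUE` = land.
#' @param res_km cell size in km.
#' @param sea_penalty cost multiplier for sea cells (>= 1), or `"euclidean"`.
#' @return object of class `cost_surface`.
#' @export
cost_surface <- function(land, res_km = 15, sea_penalty = 10) {
  land <- as.matrix(land)
  euclid <- identical(sea_penalty, "euclidean")
  if (!euclid) {
    if (!is.numeric(sea_penalty) || sea_penalty < 1)
      stop("'sea_penalty' must be >= 1 (or \"euclidean\")")
  }
  cost <- matrix(1, nrow(land), ncol(land))
  if (!euclid) cost[!land] <- sea_penalty
  structure(list(cost = cost, land = land, res_km = res_km,
                 sea_penalty = sea_penalty, euclidean = euclid),
            class = "cost_surface")
}

# grid graph with 8-connectivity; vertex id = column-major cell index
.cost_graph <- function(cs) {
  nr <- nrow(cs$cost); nc <- ncol(cs$cost)
  idx <- matrix(seq_len(nr * nc), nr, nc)
  edges <- list(); w <- list(); e <- 0L
  add <- function(a, b, sf) {
    e <<- e + 1L
    edges[[e]] <<- rbind(a, b)
    w[[e]] <<- cs$res_km * sf * (cs$cost[a] + cs$cost[b]) / 2
  }
  add(c(idx[-nr, ]), c(idx[-1, ]), 1)                  # vertical rook
  add(c(idx[, -nc]), c(idx[, -1]), 1)                  # horizontal rook
  add(c(idx[-nr, -nc]), c(idx[-1, -1]), sqrt(2))       # diagonal down-right
  add(c(idx[-1, -nc]), c(idx[-nr, -1]), sqrt(2))       # diagonal up-right
  el <- do.call(cbind, edges)
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(el))
  igraph::E(g)$weight <- unlist(w)
  g
}

.cell_id <- function(cs, cell) {
  # cell = c(row, col), 0-based
  nr <- nrow(cs$cost); nc <- ncol(cs$cost)
  if (any(cell < 0) || cell[1] >= nr || cell[2] >= nc)
    stop(sprintf("cell (%d, %d) outside the %d x %d grid",
                 cell[1], cell[2], nr, nc))
  cell[1] + 1L + cell[2] * nr
}

#' Least-cost land distance between two cells
#'
#' Minimal accumulated cost over 8-connected paths; a step between cells `u`
#' and `v` costs `res_km * step_factor * (cost_u + cost_v) / 2` with
#' `step_factor = sqrt(2)` for diagonal moves. Symmetric; zero iff the cells
#' coincide. In Euclidean mode, straight-line cell-center distance.
#'
#' @param cs a [cost_surface()].
#' @param site_a,site_b integer `c(row, col)` cell coordinates, 0-based.
#' @return distance in km.
#' @export
land_distance <- function(cs, site_a, site_b) {
  stopifnot(inherits(cs, "cost_surface"))
  a <- .cell_id(cs, site_a); b <- .cell_id(cs, site_b)
  if (cs$euclidean)
    return(cs$res_km * sqrt(sum((site_a - site_b)^2)))
  if (a == b) return(0)
  g <- .cost_graph(cs)
  as.numeric(igraph::distances(g, v = a, to = b))
}

#' Pairwise least-cost land distances among sample sites
#'
#' @param cs a [cost_surface()].
#' @param sites a `sample_sites` data.frame (or any data.frame with 0-based
#'   `row`, `col` columns).
#' @return symmetric matrix of distances in km with zero diagonal.
#' @export
pairwise_land_distances <- function(cs, sites) {
  stopifnot(inherits(cs, "cost_surface"))
  if (nrow(sites) < 2) stop("need at least 2 sites")
  if (cs$euclidean) {
    d <- as.matrix(stats::dist(cbind(sites$row, sites$col))) * cs$res_km
    dimnames(d) <- list(sites$site_id, sites$site_id)
    return(d)
  }
  ids <- mapply(function(r, c) .cell_id(cs, c(r, c)), sites$row, sites$col)
  g <- .cost_graph(cs)
  d <- igraph::distances(g, v = ids, to = ids)
  dimnames(d) <- list(sites$site_id, sites$site_id)
  d
}
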