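# Phylogenetic primitives: rooted Faith's PD, shared/unique branch partition,
# Simpson true turnover, Pagel-delta depth rescaling, depth truncation.
#
# Trees are ape "phylo" objects: rooted, unique tip labels, branch lengths >= 0.

#' Validate a phylogeny for use in turnover calculations
#'
#' Checks that `tree` is a rooted `phylo` object with branch lengths,
#' non-negative edge lengths and unique tip labels.
#'
#' @param tree an [ape::phylo] object.
#' @return `tree`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("'tree' must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths are not allowed")
  if (anyDuplicated(tree$tip.label)) stop("tip labels must be unique")
  # rooted = exactly one node without a parent (ape::is.rooted would reject
  # star phylogenies, which are legitimate here)
  roots <- setdiff(tree$edge[, 1], tree$edge[, 2])
  if (length(unique(roots)) != 1L) stop("tree must have exactly one root")
  invisible(tree)
}

# parent lookup: parent[node] = parent node id, NA for root
.parents <- function(tree) {
  n_node <- max(tree$edge)
  p <- rep(NA_integer_, n_node)
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}

# edge index reaching each node from its parent (NA for root)
.edge_to_node <- function(tree) {
  n_node <- max(tree$edge)
  idx <- rep(NA_integer_, n_node)
  idx[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  idx
}

# logical vector over edges: TRUE if the edge lies on some root-to-tip path
# of a community member. Community given as tip indices.
.community_edges <- function(tree, tip_idx) {
  on_path <- logical(nrow(tree$edge))
  parent <- .parents(tree)
  e2n <- .edge_to_node(tree)
  for (t in tip_idx) {
    v <- t
    while (!is.na(parent[v])) {
      e <- e2n[v]
      if (on_path[e]) break      # path above already marked
      on_path[e] <- TRUE
      v <- parent[v]
    }
  }
  on_path
}

.match_tips <- function(tree, members, what = "community") {
  if (length(members) == 0L) return(integer(0))
  idx <- match(members, tree$tip.label)
  if (anyNA(idx)) {
    stop(sprintf("unknown tip label(s) in %s: %s", what,
                 paste(members[is.na(idx)], collapse = ", ")))
  }
  idx
}

#' Rooted Faith's phylogenetic diversity
#'
#' Total branch length of the union of root-to-tip paths over all community
#' members. PD is *rooted*: the path from the community's MRCA up to the tree
#' root is included, which makes the shared/unique branch partition exact
#' (`a + b + c = PD(union)`).
#'
#' @param tree an [ape::phylo] object (rooted, with branch lengths).
#' @param comm character vector of tip labels (a community); may be empty.
#' @return non-negative numeric; `0` for an empty community.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' faith_pd(tr, c("A", "B"))   # 3
#' faith_pd(tr, c("A", "B", "C", "D"))  # 6
#' @export
faith_pd <- function(tree, comm) {
  validate_phylogeny(tree)
  comm <- unique(as.character(comm))
  if (length(comm) == 0L) return(0)
  idx <- .match_tips(tree, comm)
  sum(tree$edge.length[.community_edges(tree, idx)])
}

#' Shared/unique branch-length partition of two communities
#'
#' Decomposes the branch lengths spanned by two communities into the shared
#' component `a` and the components `b`, `c` unique to each community, via PD
#' inclusion-exclusion: `a = PD1 + PD2 - PD(union)`, `b = PD(union) - PD2`,
#' `c = PD(union) - PD1`.
#'
#' @inheritParams faith_pd
#' @param comm1,comm2 non-empty character vectors of tip labels.
#' @return a list with components `a`, `b`, `c` (non-negative numerics).
#' @export
branch_partition <- function(tree, comm1, comm2) {
  if (length(comm1) == 0L || length(comm2) == 0L)
    stop("both communities must be non-empty (turnover undefined)")
  pd1 <- faith_pd(tree, comm1)
  pd2 <- faith_pd(tree, comm2)
  pdu <- faith_pd(tree, union(comm1, comm2))
  list(a = max(0, pd1 + pd2 - pdu), b = max(0, pdu - pd2), c = max(0, pdu - pd1))
}

#' Phylogenetic Simpson dissimilarity (true turnover)
#'
#' The turnover component of phylogenetic beta diversity,
#' `beta_sim = min(b, c) / (a + min(b, c))`, computed on shared vs unique
#' branch lengths rather than species counts. Insensitive to richness
#' differences; symmetric; 0 for identical communities.
#'
#' @inheritParams branch_partition
#' @return numeric in `[0, 1]`.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' phylo_simpson(tr, c("A", "B"), c("C", "D"))  # 1
#' phylo_simpson(tr, c("A", "B"), c("A", "C"))  # 1/3
#' @export
phylo_simpson <- function(tree, comm1, comm2) {
  bp <- branch_partition(tree, comm1, comm2)
  m <- min(bp$b, bp$c)
  if (m == 0) return(0)
  if (bp$a + m == 0) {
    warning("degenerate pair with no shared structure; returning 0")
    return(0)
  }
  m / (bp$a + m)
}

#' Edge incidence matrix for a set of communities
#'
#' For each community (row of a logical presence/absence matrix) marks which
#' tree edges lie on the union of root-to-tip paths of its members. Used by
#' [pairwise_phylo_simpson()] to vectorize all-pairs turnover.
#'
#' @param tree an [ape::phylo] object.
#' @param pa logical/0-1 matrix, communities x species; column names must match
#'   tip labels (extra tips in the tree are allowed, extra columns are not).
#' @return logical matrix communities x edges.
#' @export
community_edge_matrix <- function(tree, pa) {
  validate_phylogeny(tree)
  pa <- as.matrix(pa)
  sp <- colnames(pa)
  if (is.null(sp)) stop("'pa' must have species column names")
  tip_of_col <- .match_tips(tree, sp, "occurrence matrix")
  ne <- nrow(tree$edge)
  out <- matrix(FALSE, nrow(pa), ne)
  parent <- .parents(tree)
  e2n <- .edge_to_node(tree)
  for (i in seq_len(nrow(pa))) {
    tips <- tip_of_col[pa[i, ] > 0]
    on_path <- logical(ne)
    for (t in tips) {
      v <- t
      while (!is.na(parent[v])) {
        e <- e2n[v]
        if (on_path[e]) break
        on_path[e] <- TRUE
        v <- parent[v]
      }
    }
    out[i, ] <- on_path
  }
  rownames(out) <- rownames(pa)
  out
}

#' All-pairs phylogenetic Simpson turnover
#'
#' Vectorized equivalent of calling [phylo_simpson()] on every unordered pair
#' of rows of `pa`: shared branch length is `E diag(len) E'` for the edge
#' incidence matrix `E`, from which `a`, `b`, `c` follow.
#'
#' @inheritParams community_edge_matrix
#' @return symmetric numeric matrix of `beta_sim` values with zero diagonal.
#' @export
pairwise_phylo_simpson <- function(tree, pa) {
  E <- community_edge_matrix(tree, pa)
  len <- tree$edge.length
  S <- (E * rep(len, each = nrow(E))) %*% t(E)   # shared length a_ij
  pd <- diag(S)
  if (any(pd == 0)) stop("empty community (zero PD) in 'pa'")
  B <- pd - t(t(S))            # b_ij = PD_i - a_ij
  C <- t(B)                    # c_ij
  M <- pmin(B, C)
  denom <- S + M
  beta <- ifelse(M <= 0, 0, M / denom)
  diag(beta) <- 0
  dimnames(beta) <- list(rownames(pa), rownames(pa))
  beta
}

#' Pagel's delta transformation of node depths
#'
#' Rescales a tree by raising node depths (distance from the root), normalized
#' by tree height, to the power `delta`: `delta > 1` stretches recent branches,
#' `delta < 1` stretches deep branches. With `preserve_height` (default) the
#' transformed tree keeps the original height, so `delta = 1` is an exact
#' identity on pairwise tip distances.
#'
#' @param tree an [ape::phylo] object with positive height.
#' @param delta positive real exponent.
#' @param preserve_height rescale so the maximum root-to-tip depth equals the
#'   input height (default `TRUE`).
#' @return a `phylo` object with identical topology and tip set.
#' @export
delta_transform <- function(tree, delta, preserve_height = TRUE) {
  validate_phylogeny(tree)
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0)
    stop("'delta' must be a single positive number")
  d <- ape::node.depth.edgelength(tree)
  h <- max(d)
  if (h <= 0) stop("tree has zero height")
  nd <- (d / h)^delta
  if (preserve_height) nd <- nd * h
  new_len <- nd[tree$edge[, 2]] - nd[tree$edge[, 1]]
  stopifnot(all(new_len > -1e-12))   # monotone transform cannot flip depths
  out <- tree
  out$edge.length <- pmax(new_len, 0)
  out
}

#' Truncate a phylogeny at a fixed depth from the root
#'
#' Every branch crossing the cut (parent depth `<= depth <` child depth)
#' becomes a single tip; the subtree below it is collapsed and its tips are
#' assigned to that branch. A node sitting exactly at the cut has its child
#' branches cut (half-open convention). For an ultrametric tree measured in
#' time, a cut at depth `d` corresponds to age `height - d` before present.
#' Occurrence data are aggregated by OR-ing columns within mapping groups
#' (see [collapse_communities()]).
#'
#' @param tree an [ape::phylo] object.
#' @param depth cut depth from the root, in `[0, height)`.
#' @return list with `tree` (the collapsed phylogeny, tips named
#'   `branch_1, branch_2, ...`) and `mapping` (named character vector,
#'   original tip label -> collapsed branch id).
#' @export
truncate_tree <- function(tree, depth) {
  validate_phylogeny(tree)
  d <- ape::node.depth.edgelength(tree)
  h <- max(d[seq_along(tree$tip.label)])
  if (depth < 0 || depth >= h) stop("'depth' must lie in [0, tree height)")
  dp <- d[tree$edge[, 1]]
  dc <- d[tree$edge[, 2]]
  cut_edges <- which(dp <= depth & depth < dc)
  ntip <- length(tree$tip.label)
  # tips per cut branch (clade of the child node)
  groups <- lapply(tree$edge[cut_edges, 2], function(node) {
    if (node <= ntip) tree$tip.label[node]
    else ape::extract.clade(tree, node)$tip.label
  })
  grouped <- unlist(groups, use.names = FALSE)
  # tips shallower than the cut (possible on non-ultrametric trees) survive
  loose <- setdiff(tree$tip.label, grouped)
  groups <- c(groups, as.list(loose))
  branch_ids <- sprintf("branch_%d", seq_along(groups))
  mapping <- stats::setNames(rep(branch_ids, lengths(groups)),
                             unlist(groups, use.names = FALSE))
  # collapse: keep one representative tip per group, then rename
  reps <- vapply(groups, `[[`, character(1), 1L)
  drop <- setdiff(tree$tip.label, reps)
  new_tree <- if (length(drop)) ape::drop.tip(tree, drop) else tree
  new_tree$tip.label <- branch_ids[match(new_tree$tip.label, reps)]
  list(tree = new_tree, mapping = mapping[tree$tip.label])
}

#' Aggregate occurrence columns after tree truncation
#'
#' ORs the presence/absence columns of each truncation group, realizing the
#' rule that a collapsed branch's distribution is the union of its descendant
#' tips' distributions.
#'
#' @param pa logical/0-1 matrix, rows = communities/cells, columns = species.
#' @param mapping named character vector from [truncate_tree()].
#' @return logical matrix with one column per collapsed branch.
#' @export
collapse_communities <- function(pa, mapping) {
  pa <- as.matrix(pa)
  sp <- colnames(pa)
  if (is.null(sp) || !all(sp %in% names(mapping)))
    stop("all occurrence columns must appear in 'mapping'")
  gids <- unique(unname(mapping))
  out <- vapply(gids, function(g) {
    cols <- sp[mapping[sp] == g]
    rowSums(pa[, cols, drop = FALSE]) > 0
  }, logical(nrow(pa)))
  out <- matrix(out, nrow = nrow(pa), dimnames = list(rownames(pa), gids))
  out
}

#' Read trees from a Newick file (one tree per line)
#'
#' @param path file path.
#' @return a list of `phylo` objects (class `multiPhylo`).
#' @export
read_trees <- function(path) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "phylo")) tr <- c(tr)   # promote to multiPhylo
  for (t in tr) validate_phylogeny(t)
  tr
}

#' Write trees to a Newick file (one per line)
#'
#' @param trees a `phylo` or list of `phylo` objects.
#' @param path file path.
#' @export
write_trees <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  ape::write.tree(trees, file = path)
  invisible(path)
}
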