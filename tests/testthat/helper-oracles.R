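# Independent oracles and small fixtures shared across tests.

# four-tip balanced reference tree used in many examples
balanced4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

# star phylogeny with given tip branch lengths
star_tree <- function(lens, labels = sprintf("t%d", seq_along(lens))) {
  ape::read.tree(text = paste0(
    "(", paste(sprintf("%s:%g", labels, lens), collapse = ","), ");"))
}

# edges x tips descendant incidence: D[e, t] = TRUE iff tip t descends from
# edge e's child. Built from clade tip lists, independently of the parent-walk
# used by the package.
edge_descendants <- function(tree) {
  ntip <- length(tree$tip.label)
  D <- matrix(FALSE, nrow(tree$edge), ntip)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    tips <- if (child <= ntip) child
            else match(ape::extract.clade(tree, child)$tip.label,
                       tree$tip.label)
    D[e, tips] <- TRUE
  }
  D
}

# brute-force Simpson turnover by explicit edge classification: every edge is
# shared / unique-to-1 / unique-to-2 / absent depending on which community has
# a member below it
oracle_beta_sim <- function(tree, comm1, comm2) {
  D <- edge_descendants(tree)
  m1 <- tree$tip.label %in% comm1
  m2 <- tree$tip.label %in% comm2
  in1 <- D %*% m1 > 0
  in2 <- D %*% m2 > 0
  len <- tree$edge.length
  a <- sum(len[in1 & in2])
  b <- sum(len[in1 & !in2])
  c <- sum(len[!in1 & in2])
  m <- min(b, c)
  if (m == 0) 0 else m / (a + m)
}

# all-pairs oracle over every non-empty tip subset (bitmask order);
# returns the 255 x 255 (for 8 tips) beta matrix
oracle_beta_all_subsets <- function(tree) {
  ntip <- length(tree$tip.label)
  D <- edge_descendants(tree)
  n_sub <- 2^ntip - 1
  M <- t(vapply(seq_len(n_sub), function(m)
    bitwAnd(m, 2^(seq_len(ntip) - 1)) > 0, logical(ntip)))
  P <- tcrossprod(M, D) > 0                    # subset x edge incidence
  len <- tree$edge.length
  A <- (P * rep(len, each = n_sub)) %*% t(P)   # shared length
  pd <- diag(A)
  B <- pd - A
  Cm <- t(B)
  Mn <- pmin(B, Cm)
  beta <- ifelse(Mn == 0, 0, Mn / (A + Mn))
  diag(beta) <- 0
  beta
}

# plain O(V^2) Dijkstra over the 8-connected grid with the same edge-cost
# convention (average endpoint cost, sqrt(2) diagonals); independent of igraph
oracle_dijkstra <- function(cs, src) {
  nr <- nrow(cs$cost); nc <- ncol(cs$cost)
  n <- nr * nc
  dist <- rep(Inf, n); dist[src] <- 0
  done <- logical(n)
  moves <- cbind(dr = c(-1, 1, 0, 0, -1, -1, 1, 1),
                 dc = c(0, 0, -1, 1, -1, 1, -1, 1),
                 sf = c(1, 1, 1, 1, rep(sqrt(2), 4)))
  for (iter in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    ur <- (u - 1) %% nr; uc <- (u - 1) %/% nr
    for (k in 1:8) {
      vr <- ur + moves[k, 1]; vc <- uc + moves[k, 2]
      if (vr < 0 || vr >= nr || vc < 0 || vc >= nc) next
      v <- vr + 1 + vc * nr
      w <- cs$res_km * moves[k, 3] * (cs$cost[u] + cs$cost[v]) / 2
      if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
    }
  }
  dist
}

# LMG by explicit enumeration of all p! orderings (subset R^2 cached by mask)
oracle_lmg <- function(y, X) {
  p <- ncol(X)
  r2_cache <- new.env()
  r2 <- function(S) {
    key <- paste0("m", sum(2^(S - 1)))
    if (!is.null(r2_cache[[key]])) return(r2_cache[[key]])
    v <- if (!length(S)) 0 else {
      f <- stats::lm.fit(cbind(1, X[, S, drop = FALSE]), y)
      1 - sum(f$residuals^2) / sum((y - mean(y))^2)
    }
    r2_cache[[key]] <- v
    v
  }
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(rest) c(v[i], rest))))
  }
  shares <- numeric(p)
  all_orders <- perms(seq_len(p))
  for (ord in all_orders) {
    for (pos in seq_len(p)) {
      before <- ord[seq_len(pos - 1)]
      shares[ord[pos]] <- shares[ord[pos]] +
        r2(c(before, ord[pos])) - r2(before)
    }
  }
  stats::setNames(shares / length(all_orders), colnames(X))
}

# small all-land landscape fixture with crossed gradients
crossed_gradients <- function(n = 9, res_km = 15) {
  e1 <- env_raster(matrix(rep(seq_len(n), each = n) + 0, n, n),
                   matrix(TRUE, n, n), res_km)
  e2 <- env_raster(matrix(rep(seq_len(n), times = n) + 0, n, n),
                   matrix(TRUE, n, n), res_km)
  list(env1 = e1, env2 = e2)
}
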