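# Scattered-data linear interpolation onto a regular grid over environmental
# space. Delaunay triangulation (Bowyer-Watson) + barycentric interpolation:
# exact on planar fields, convex-combination bounded, undefined outside the
# input hull. On a regular input lattice this reduces to bilinear
# interpolation up to the (value-identical) choice of cell diagonal.

# circumcircle of triangle (p1, p2, p3); returns c(cx, cy, r2) or NULL if
# the points are (numerically) collinear
.circumcircle <- function(x, y) {
  ax <- x[1]; ay <- y[1]; bx <- x[2]; by <- y[2]; cx <- x[3]; cy <- y[3]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-14) return(NULL)
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
}

#' Delaunay triangulation of scattered points (Bowyer-Watson)
#'
#' Incremental insertion with a super-triangle; coordinates are rescaled to
#' the unit box internally for numerical stability. Cocircular point sets
#' (e.g. regular lattices) are triangulated with an arbitrary but valid
#' diagonal choice.
#'
#' @param x,y point coordinates (>= 3 points, not all collinear).
#' @return integer matrix, one row per triangle, columns = vertex indices.
#' @export
delaunay_triangulate <- function(x, y) {
  n <- length(x)
  if (n < 3 || length(y) != n) stop("need >= 3 (x, y) points")
  rx <- range(x); ry <- range(y)
  sx <- max(rx[2] - rx[1], 1e-12); sy <- max(ry[2] - ry[1], 1e-12)
  px <- (x - rx[1]) / sx
  py <- (y - ry[1]) / sy
  # super-triangle well outside the unit box
  px <- c(px, -10, 10, 0.5)
  py <- c(py, -10, -10, 30)
  tri <- list(c(n + 1L, n + 2L, n + 3L))
  circ <- list(.circumcircle(px[tri[[1]]], py[tri[[1]]]))
  for (p in seq_len(n)) {
    bad <- which(vapply(seq_along(tri), function(t) {
      cc <- circ[[t]]
      !is.null(cc) && (px[p] - cc[1])^2 + (py[p] - cc[2])^2 < cc[3] * (1 - 1e-12)
    }, logical(1)))
    if (!length(bad)) next   # duplicate point: skip
    # boundary of the cavity = edges used by exactly one bad triangle
    edges <- do.call(rbind, lapply(tri[bad], function(v)
      rbind(sort(v[c(1, 2)]), sort(v[c(2, 3)]), sort(v[c(1, 3)]))))
    key <- paste(edges[, 1], edges[, 2])
    boundary <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    tri[bad] <- NULL; circ[bad] <- NULL
    for (e in seq_len(nrow(boundary))) {
      v <- c(boundary[e, ], p)
      tri[[length(tri) + 1L]] <- v
      circ[[length(circ) + 1L]] <- .circumcircle(px[v], py[v])
    }
  }
  keep <- vapply(tri, function(v) all(v <= n), logical(1))
  out <- do.call(rbind, tri[keep])
  if (is.null(out) || nrow(out) == 0)
    stop("input points are collinear: no triangulation exists")
  out
}

#' Interpolate scattered values at query points (piecewise linear)
#'
#' Locates each query in the Delaunay triangulation of the inputs and applies
#' barycentric interpolation; queries outside the convex hull return `NA`.
#'
#' @param x,y,value scattered input points and their values.
#' @param xq,yq query coordinates.
#' @return numeric vector of interpolated values (`NA` outside the hull).
#' @export
interp_linear <- function(x, y, value, xq, yq) {
  tri <- delaunay_triangulate(x, y)
  # work in the same normalized coordinates used for triangulation
  rx <- range(x); ry <- range(y)
  sx <- max(rx[2] - rx[1], 1e-12); sy <- max(ry[2] - ry[1], 1e-12)
  nx <- (x - rx[1]) / sx; ny <- (y - ry[1]) / sy
  qx <- (xq - rx[1]) / sx; qy <- (yq - ry[1]) / sy
  out <- rep(NA_real_, length(xq))
  for (t in seq_len(nrow(tri))) {
    v <- tri[t, ]
    x1 <- nx[v[1]]; y1 <- ny[v[1]]
    x2 <- nx[v[2]]; y2 <- ny[v[2]]
    x3 <- nx[v[3]]; y3 <- ny[v[3]]
    det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    if (abs(det) < 1e-14) next   # degenerate sliver
    todo <- which(is.na(out))
    if (!length(todo)) break
    l1 <- ((y2 - y3) * (qx[todo] - x3) + (x3 - x2) * (qy[todo] - y3)) / det
    l2 <- ((y3 - y1) * (qx[todo] - x3) + (x1 - x3) * (qy[todo] - y3)) / det
    l3 <- 1 - l1 - l2
    tol <- -1e-9
    inside <- l1 >= tol & l2 >= tol & l3 >= tol
    if (any(inside)) {
      i <- todo[inside]
      out[i] <- l1[inside] * value[v[1]] + l2[inside] * value[v[2]] +
        l3[inside] * value[v[3]]
    }
  }
  out
}

#' Rasterize scattered environmental-space values onto a regular grid
#'
#' Builds a regular `grid_shape` grid spanning the input range of (env1, env2)
#' and fills it by piecewise-linear interpolation on the scattered inputs.
#' Nodes outside the convex hull of the inputs are left undefined (`NA`):
#' the surface never extrapolates.
#'
#' @param points data.frame with columns `env1`, `env2`, `value` (>= 3
#'   non-collinear points).
#' @param grid_shape integer length-2, nodes along (env1, env2); both >= 2.
#' @return object of class `env_surface`: `axis1`, `axis2` node coordinate
#'   vectors and a `values` matrix (`length(axis1)` x `length(axis2)`).
#' @export
rasterize_env <- function(points, grid_shape = c(25, 25)) {
  stopifnot(all(c("env1", "env2", "value") %in% names(points)))
  if (any(grid_shape < 2)) stop("'grid_shape' must be >= (2, 2)")
  axis1 <- seq(min(points$env1), max(points$env1), length.out = grid_shape[1])
  axis2 <- seq(min(points$env2), max(points$env2), length.out = grid_shape[2])
  nodes <- expand.grid(env1 = axis1, env2 = axis2)
  vals <- interp_linear(points$env1, points$env2, points$value,
                        nodes$env1, nodes$env2)
  # exact reproduction at coincident input coordinates
  hit <- match(paste(signif(nodes$env1, 12), signif(nodes$env2, 12)),
               paste(signif(points$env1, 12), signif(points$env2, 12)))
  vals[!is.na(hit)] <- points$value[hit[!is.na(hit)]]
  structure(list(axis1 = axis1, axis2 = axis2,
                 values = matrix(vals, grid_shape[1], grid_shape[2])),
            class = "env_surface")
}

#' @export
print.env_surface <- function(x, ...) {
  v <- x$values
  cat(sprintf("<env_surface> %d x %d nodes, %d defined (%.0f%%)\n",
              nrow(v), ncol(v), sum(!is.na(v)), 100 * mean(!is.na(v))))
  if (any(!is.na(v)))
    cat(sprintf("  values: [%.4g, %.4g]\n", min(v, na.rm = TRUE),
                max(v, na.rm = TRUE)))
  invisible(x)
}

#' Long-format export of an environmental surface
#'
#' @param surface an [rasterize_env()] result.
#' @return data.frame with `env1`, `env2`, `value` (undefined nodes omitted).
#' @export
surface_to_long <- function(surface) {
  d <- expand.grid(env1 = surface$axis1, env2 = surface$axis2)
  d$value <- c(surface$values)
  d[!is.na(d$value), ]
}
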