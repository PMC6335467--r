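# Standardized regression of residual turnover on macroecological predictors
# and LMG (Shapley) decomposition of model R-squared into per-variable
# relative importances.

#' Standardize a vector to zero mean and unit standard deviation
#'
#' @param x numeric vector (not constant).
#' @return standardized vector.
#' @export
standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant vector")
  (x - mean(x)) / s
}

# R^2 of OLS of y on columns S of X (with intercept); S may be empty
.r2_subset <- function(y, X, S) {
  if (!length(S)) return(0)
  fit <- stats::lm.fit(cbind(1, X[, S, drop = FALSE]), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' LMG relative variable importance (Shapley decomposition of R-squared)
#'
#' The LMG share of a regressor is its sequential contribution to R-squared
#' averaged over all orderings of regressor entry. Computed here by the
#' subset-aggregation identity: for column `j`,
#' `share_j = sum over S not containing j of w(|S|) * (R2(S + j) - R2(S))`
#' with Shapley weights `w(s) = s! (p - 1 - s)! / p!`. Shares are
#' non-negative and sum exactly to the full-model R-squared. Columns can be
#' grouped (e.g. linear + quadratic term of one variable); grouped shares are
#' rescaled to sum to 1.
#'
#' @param y numeric response.
#' @param X numeric matrix/data.frame of named regressor columns (full rank,
#'   `n > 2 * ncol`).
#' @param groups optional character vector, one entry per column, naming the
#'   variable each column belongs to; default: each column its own group.
#' @return list of class `importance_result` with `r_squared`, `raw_shares`
#'   (per column), `importance` (per group, rescaled to sum to 1).
#' @export
lmg_importance <- function(y, X, groups = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(colnames(X))) stop("'X' must have column names")
  if (length(y) != nrow(X)) stop("length(y) must match nrow(X)")
  if (length(y) <= 2 * p) stop("need n > 2 * number of regressors")
  if (qr(cbind(1, X))$rank < p + 1) {
    stop("rank-deficient design; check collinearity among: ",
         paste(colnames(X), collapse = ", "))
  }
  if (is.null(groups)) groups <- colnames(X)
  if (length(groups) != p) stop("'groups' must have one entry per column")
  # R^2 for every subset, indexed by bitmask
  r2 <- numeric(2^p)
  for (m in seq_len(2^p - 1)) {
    S <- which(bitwAnd(m, 2^(seq_len(p) - 1)) > 0)
    r2[m + 1] <- .r2_subset(y, X, S)
  }
  wt <- factorial(0:(p - 1)) * factorial((p - 1):0) / factorial(p)
  shares <- numeric(p)
  for (j in seq_len(p)) {
    others <- setdiff(seq_len(p), j)
    for (m in 0:(2^(p - 1) - 1)) {   # subsets of the other columns
      S <- others[which(bitwAnd(m, 2^(seq_len(p - 1) - 1)) > 0)]
      mask <- sum(2^(S - 1))
      shares[j] <- shares[j] +
        wt[length(S) + 1] * (r2[mask + 2^(j - 1) + 1] - r2[mask + 1])
    }
  }
  names(shares) <- colnames(X)
  grouped <- tapply(shares, groups, sum)
  grouped <- stats::setNames(as.numeric(grouped), names(grouped))
  grouped <- grouped[unique(groups)]
  structure(list(r_squared = r2[2^p],
                 raw_shares = shares,
                 importance = grouped / sum(grouped)),
            class = "importance_result")
}

#' @export
print.importance_result <- function(x, ...) {
  cat(sprintf("Standardized model R-squared: %.3f\n", x$r_squared))
  cat("Relative importance (rescaled to sum 1):\n")
  for (g in names(x$importance))
    cat(sprintf("  %-8s %.3f\n", g, x$importance[[g]]))
  invisible(x)
}

#' Explain residual turnover with macroecological characteristics
#'
#' Builds the standardized design for the turnover-importance regression:
#' response = mean residual turnover per neighboring stratum pair; regressors
#' = per-pair means (average of the two strata's site means) of SR, relPD and
#' NS, standardized, plus their squares (squares of the standardized terms,
#' themselves standardized). Returns the LMG decomposition with linear and
#' quadratic shares added per variable.
#'
#' @param strata_pairs a [neighboring_strata_means()] data.frame.
#' @param macro a [macroeco_table()] data.frame.
#' @param sites the `sample_sites` data.frame (links sites to strata).
#' @return an `importance_result` (see [lmg_importance()]) with an extra
#'   `table` element (`variable`, `raw_linear`, `raw_quadratic`, `rescaled`).
#' @export
turnover_importance <- function(strata_pairs, macro, sites) {
  vars <- c("SR", "relPD", "NS")
  m <- merge(macro, sites[, c("site_id", "stratum")], by = "site_id")
  stratum_means <- aggregate(m[, vars], by = list(stratum = m$stratum),
                             FUN = mean, na.rm = TRUE)
  a <- match(strata_pairs$stratum_a, stratum_means$stratum)
  b <- match(strata_pairs$stratum_b, stratum_means$stratum)
  X <- sapply(vars, function(v)
    standardize((stratum_means[[v]][a] + stratum_means[[v]][b]) / 2))
  Xq <- sapply(vars, function(v) standardize(X[, v]^2))
  colnames(Xq) <- paste0(vars, "_sq")
  design <- cbind(X, Xq)
  res <- lmg_importance(strata_pairs$mean_residual, design,
                        groups = rep(vars, 2))
  res$table <- data.frame(
    variable = vars,
    raw_linear = unname(res$raw_shares[vars]),
    raw_quadratic = unname(res$raw_shares[paste0(vars, "_sq")]),
    rescaled = unname(res$importance[vars]))
  res
}
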