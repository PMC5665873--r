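#' Column standardization for canonical correlation inputs
#'
#' Centers every column to mean 0 and scales to unit *population* standard
#' deviation (`sqrt(mean((x - xbar)^2))`). Constant columns carry no
#' correlation information and are removed with a warning; their names are
#' attached as `attr(, "dropped")`.
#'
#' @param x numeric matrix with >= 2 rows (samples x variables).
#' @return standardized matrix.
#' @export
standardize_columns <- function(x) {
  if (!is.matrix(x) || nrow(x) < 2) stop("need a matrix with >= 2 rows")
  ctr <- scale(x, center = TRUE, scale = FALSE)
  sds <- sqrt(colMeans(ctr^2))
  keep <- sds > 0
  if (!any(keep)) stop("all columns are constant")
  if (!all(keep))
    warning(sum(!keep), " constant column(s) removed")
  out <- sweep(ctr[, keep, drop = FALSE], 2, sds[keep], "/")
  attr(out, "dropped") <- colnames(x)[!keep]
  attr(out, "scaled:center") <- NULL
  out
}

#' Soft-thresholding operator
#'
#' `S(a, lambda) = sign(a) * max(|a| - lambda, 0)`, applied element-wise.
#'
#' @param a numeric vector.
#' @param lambda threshold, >= 0.
#' @export
soft_threshold <- function(a, lambda) {
  if (length(lambda) != 1 || !is.finite(lambda) || lambda < 0)
    stop("lambda must be a single value >= 0")
  sign(a) * pmax(abs(a) - lambda, 0)
}

#' L1-bounded unit vector by soft-thresholding and binary search
#'
#' Returns `w = S(a, lambda) / ||S(a, lambda)||_2` with the smallest
#' `lambda >= 0` such that `||w||_1 <= c` (lambda = 0 when the plain unit
#' vector already satisfies the budget). This maximizes `a' w` subject to
#' `||w||_2 = 1, ||w||_1 <= c`. Budgets live on the `[1, sqrt(dim)]` scale:
#' `c = 1` forces all mass onto the largest |a_i|, `c >= sqrt(dim)` leaves
#' the constraint inactive.
#'
#' @param a nonzero numeric vector.
#' @param c L1 budget, `>= 1`.
#' @param tol tolerance on `||w||_1` for the binary search.
#' @param max_steps bisection steps (default 60).
#' @return unit vector with `||w||_1 <= c + tol`.
#' @export
l1_bounded_unit_vector <- function(a, c, tol = 1e-8, max_steps = 60) {
  if (all(a == 0)) stop("a must be nonzero")
  if (length(c) != 1 || !is.finite(c) || c < 1)
    stop("the L1 budget must be >= 1 (||w||_2 = 1 is infeasible otherwise)")
  unit <- function(v) v / sqrt(sum(v^2))
  w <- unit(a)
  if (sum(abs(w)) <= c + tol) return(w)
  lo <- 0; hi <- max(abs(a))
  for (step in seq_len(max_steps)) {
    mid <- (lo + hi) / 2
    s <- soft_threshold(a, mid)
    l1 <- if (any(s != 0)) sum(abs(unit(s))) else Inf
    if (l1 > c) lo <- mid else hi <- mid
    if (hi - lo < tol * max(abs(a))) break
  }
  s <- soft_threshold(a, hi)
  if (all(s == 0) || sum(abs(unit(s))) > c + tol) {
    # degenerate ties near max|a|: place all mass on the first argmax
    w <- numeric(length(a))
    i <- which.max(abs(a))
    w[i] <- sign(a[i])
    return(w)
  }
  unit(s)
}

#' One pair of sparse canonical loadings
#'
#' Alternating maximization of `u' M v` with `M = X'Y`, under
#' `||u||_2 <= 1, ||v||_2 <= 1, ||u||_1 <= c1, ||v||_1 <= c2`:
#' `u <- l1_bounded_unit_vector(M v, c1)`,
#' `v <- l1_bounded_unit_vector(M' u, c2)`, iterated until the objective
#' stabilizes. Each update solves its subproblem exactly, so the objective
#' never decreases. Initialization is the leading right singular vector of
#' `M` (deterministic, computed by power iteration). The sign convention
#' makes the first nonzero entry of `u` positive.
#'
#' @param X,Y standardized matrices with equal row counts, or `M` directly
#'   via `crossprod_m`.
#' @param c1,c2 L1 budgets on the `[1, sqrt(dim)]` scale.
#' @param tol relative objective tolerance.
#' @param max_iter iteration cap; reaching it sets `converged = FALSE`.
#' @param crossprod_m optional precomputed `X'Y` (overrides X, Y).
#' @param v_init optional starting `v`.
#' @return list: `u`, `v`, `d = u' M v`, `converged`, `iterations`,
#'   `objective_trajectory`.
#' @export
sparse_cca_pair <- function(X = NULL, Y = NULL, c1, c2, tol = 1e-10,
                            max_iter = 500, crossprod_m = NULL,
                            v_init = NULL) {
  M <- if (is.null(crossprod_m)) {
    stopifnot(nrow(X) == nrow(Y))
    crossprod(X, Y)
  } else crossprod_m
  if (all(M == 0)) stop("X'Y is identically zero")
  v <- if (is.null(v_init)) leading_right_sv(M) else v_init / sqrt(sum(v_init^2))
  d_old <- -Inf
  traj <- numeric(0)
  converged <- FALSE
  it <- 0
  u <- NULL
  for (it in seq_len(max_iter)) {
    u <- l1_bounded_unit_vector(as.vector(M %*% v), c1)
    v <- l1_bounded_unit_vector(as.vector(crossprod(M, u)), c2)
    d <- as.numeric(crossprod(u, M %*% v))
    traj <- c(traj, d)
    if (is.finite(d_old) && abs(d - d_old) < tol * max(1, abs(d))) {
      converged <- TRUE
      break
    }
    d_old <- d
  }
  # sign convention for reproducibility
  nz <- which(u != 0)[1]
  if (!is.na(nz) && u[nz] < 0) { u <- -u; v <- -v }
  d <- as.numeric(crossprod(u, M %*% v))
  list(u = as.vector(u), v = as.vector(v), d = d, converged = converged,
       iterations = it, objective_trajectory = traj)
}

# leading right singular vector of M by power iteration on M'M
leading_right_sv <- function(M, iters = 100, tol = 1e-12) {
  v <- sqrt(colSums(M^2))
  if (all(v == 0)) v <- rep(1, ncol(M))
  v <- v / sqrt(sum(v^2))
  for (i in seq_len(iters)) {
    w <- as.vector(crossprod(M, M %*% v))
    nw <- sqrt(sum(w^2))
    if (nw == 0) break
    w <- w / nw
    if (sum((w - v)^2) < tol) { v <- w; break }
    v <- w
  }
  v
}

#' Deflate a cross-product matrix
#'
#' `M' = M - d * u v'`; after deflation `u' M' v = 0` (for unit u, v), so a
#' second component can be extracted from `M'`.
#'
#' @param M cross-product matrix.
#' @param u,v loading vectors of the converged pair.
#' @param d objective value `u' M v`.
#' @export
deflate <- function(M, u, v, d) {
  if (length(u) != nrow(M) || length(v) != ncol(M))
    stop("dimension mismatch between M and (u, v)")
  M - d * tcrossprod(u, v)
}

#' Sparse canonical correlation analysis of two datasets
#'
#' Standardizes both matrices, maps penalty fractions
#' `(c1, c2) in (0, 1)` affinely onto the feasible L1 range
#' `1 + c * (sqrt(dim) - 1)`, extracts `K` loading pairs by alternating
#' soft-thresholded updates with deflation between components, and returns
#' loadings, sample scores and the unpenalized correlation of each score
#' pair.
#'
#' @param X,Y samples x variables matrices, same samples in the same order.
#' @param c1,c2 penalty fractions in (0, 1) (or exact budgets if
#'   `fractions = FALSE`).
#' @param K number of components (default 2).
#' @param fractions interpret `c1`, `c2` as fractions (default) or budgets.
#' @param standardize standardize columns first (default TRUE).
#' @param ... passed to [sparse_cca_pair()].
#' @return `exfo_scca`: matrices `u` (p x K), `v` (q x K), objective values
#'   `d`, score matrices `scores_x`, `scores_y`, per-component score
#'   correlations, budgets used.
#' @export
sparse_cca <- function(X, Y, c1 = 0.3, c2 = 0.3, K = 2, fractions = TRUE,
                       standardize = TRUE, ...) {
  if (standardize) {
    X <- standardize_columns(X)
    Y <- standardize_columns(Y)
  }
  b1 <- if (fractions) penalty_to_budget(c1, ncol(X)) else c1
  b2 <- if (fractions) penalty_to_budget(c2, ncol(Y)) else c2
  M <- crossprod(X, Y)
  u <- matrix(0, ncol(X), K, dimnames = list(colnames(X), NULL))
  v <- matrix(0, ncol(Y), K, dimnames = list(colnames(Y), NULL))
  d <- numeric(K)
  conv <- logical(K)
  for (k in seq_len(K)) {
    fit <- sparse_cca_pair(c1 = b1, c2 = b2, crossprod_m = M, ...)
    u[, k] <- fit$u; v[, k] <- fit$v; d[k] <- fit$d; conv[k] <- fit$converged
    M <- deflate(M, fit$u, fit$v, fit$d)
  }
  sx <- X %*% u
  sy <- Y %*% v
  cors <- vapply(seq_len(K), function(k) {
    if (stats::sd(sx[, k]) == 0 || stats::sd(sy[, k]) == 0) 0
    else stats::cor(sx[, k], sy[, k])
  }, numeric(1))
  res <- list(u = u, v = v, d = d, scores_x = sx, scores_y = sy,
              score_correlation = cors, budgets = c(c1 = b1, c2 = b2),
              penalties = c(c1 = c1, c2 = c2), converged = conv)
  class(res) <- "exfo_scca"
  res
}

# affine map of a penalty fraction in (0,1) onto the feasible L1 range
penalty_to_budget <- function(frac, dim) {
  if (any(frac <= 0 | frac >= 1)) stop("penalty fractions must lie in (0, 1)")
  1 + frac * (sqrt(dim) - 1)
}

#' @export
#' @method print exfo_scca
print.exfo_scca <- function(x, ...) {
  K <- length(x$d)
  cat(sprintf("sparse CCA: %d component(s), budgets c1 = %.2f, c2 = %.2f\n",
              K, x$budgets["c1"], x$budgets["c2"]))
  for (k in seq_len(K))
    cat(sprintf("  comp %d: objective %.4f, score correlation %.3f, %d/%d nonzero loadings\n",
                k, x$d[k], x$score_correlation[k],
                sum(x$u[, k] != 0), sum(x$v[, k] != 0)))
  invisible(x)
}

#' Leave-one-out tuning of the sparsity penalties
#'
#' For each grid point `(c1, c2)` and each sample `i`: standardize the
#' training rows, fit one sparse component, score the held-out sample with
#' the training standardization, and pool the `n` held-out score pairs; the
#' criterion is the absolute *unpenalized* correlation of the pooled
#' held-out scores. Fold loadings are sign-aligned to a full-data reference
#' fit before pooling (the objective is sign-invariant in `(u, v)` jointly,
#' so alignment prevents artificial decorrelation). Ties take the first
#' grid point with `c1` varying slowest.
#'
#' @param X,Y samples x variables matrices (>= 3 samples).
#' @param grid1,grid2 penalty-fraction grids for c1 and c2 in (0, 1).
#' @param ... passed to [sparse_cca_pair()].
#' @return list: `c1`, `c2` (selected fractions), `criterion` matrix
#'   (rows = grid1, cols = grid2), `best` value.
#' @export
loo_cv_tune <- function(X, Y, grid1 = seq(0.1, 0.9, by = 0.2),
                        grid2 = grid1, ...) {
  n <- nrow(X)
  if (n < 3) stop("need >= 3 samples for leave-one-out tuning")
  if (nrow(Y) != n) stop("X and Y must have the same samples")
  crit <- matrix(NA_real_, length(grid1), length(grid2),
                 dimnames = list(paste0("c1=", grid1), paste0("c2=", grid2)))
  fx <- std_full(X); fy <- std_full(Y)
  for (a in seq_along(grid1)) for (b in seq_along(grid2)) {
    b1 <- penalty_to_budget(grid1[a], ncol(X))
    b2 <- penalty_to_budget(grid2[b], ncol(Y))
    ref <- sparse_cca_pair(fx$mat, fy$mat, c1 = b1, c2 = b2, ...)
    ref_u <- numeric(ncol(X)); ref_u[fx$keep] <- ref$u
    ref_v <- numeric(ncol(Y)); ref_v[fy$keep] <- ref$v
    sx <- numeric(n); sy <- numeric(n)
    ok <- TRUE
    for (i in seq_len(n)) {
      tr <- std_train_test(X, i); te <- std_train_test(Y, i)
      shared_ok <- length(tr$test) > 0 && length(te$test) > 0
      if (!shared_ok) { ok <- FALSE; break }
      fit <- sparse_cca_pair(tr$train, te$train, c1 = b1, c2 = b2, ...)
      flip <- sum(fit$u * ref_u[tr$keep]) + sum(fit$v * ref_v[te$keep])
      if (flip < 0) { fit$u <- -fit$u; fit$v <- -fit$v }
      sx[i] <- sum(tr$test * fit$u)
      sy[i] <- sum(te$test * fit$v)
    }
    crit[a, b] <- if (!ok || stats::sd(sx) == 0 || stats::sd(sy) == 0) 0
      else abs(stats::cor(sx, sy))
  }
  best <- which(crit == max(crit), arr.ind = TRUE)[1, ]
  list(c1 = grid1[best[1]], c2 = grid2[best[2]], criterion = crit,
       best = max(crit))
}

standardize_quiet <- function(x) suppressWarnings(standardize_columns(x))

# full-data population standardization keeping track of retained columns
std_full <- function(x) {
  mu <- colMeans(x)
  sd <- sqrt(colMeans(sweep(x, 2, mu)^2))
  keep <- sd > 0
  list(mat = sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2,
                   sd[keep], "/"),
       keep = keep)
}

# standardize training rows (population SD) and scale the held-out row with
# the training statistics; columns constant in training are dropped from both
std_train_test <- function(x, i) {
  tr <- x[-i, , drop = FALSE]
  mu <- colMeans(tr)
  sd <- sqrt(colMeans(sweep(tr, 2, mu)^2))
  keep <- sd > 0
  list(train = sweep(sweep(tr[, keep, drop = FALSE], 2, mu[keep]), 2,
                     sd[keep], "/"),
       test = (x[i, keep] - mu[keep]) / sd[keep],
       keep = keep)
}

#' Per-sample component score table
#'
#' Tabulates each sample's first- and second-component scores in its own
#' source together with the partner source's first-component score (used as
#' the coloring variable when the two ordinations are compared).
#'
#' @param result `exfo_scca` with >= 2 components.
#' @param metadata data frame with one row per sample (same order as the
#'   score matrices), including `sample_id` and `group`.
#' @return data frame: sample_id, group, source role (`x` or `y`),
#'   comp1, comp2, partner_comp1.
#' @export
cca_score_table <- function(result, metadata) {
  if (!inherits(result, "exfo_scca")) stop("result must be an exfo_scca fit")
  if (length(result$d) < 2) stop("need >= 2 fitted components")
  n <- nrow(result$scores_x)
  if (nrow(result$scores_y) != n) stop("score matrices disagree in samples")
  if (!is.data.frame(metadata) || nrow(metadata) != n ||
      !all(c("sample_id", "group") %in% names(metadata)))
    stop("metadata must have one row per sample with sample_id and group")
  rbind(
    data.frame(sample_id = metadata$sample_id, group = metadata$group,
               role = "x", comp1 = result$scores_x[, 1],
               comp2 = result$scores_x[, 2],
               partner_comp1 = result$scores_y[, 1],
               stringsAsFactors = FALSE),
    data.frame(sample_id = metadata$sample_id, group = metadata$group,
               role = "y", comp1 = result$scores_y[, 1],
               comp2 = result$scores_y[, 2],
               partner_comp1 = result$scores_x[, 1],
               stringsAsFactors = FALSE))
}
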