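#' Bray-Curtis dissimilarity
#'
#' `d(i, j) = sum |x_i - x_j| / sum (x_i + x_j)` over features, for every
#' pair of samples. Entries lie in `[0, 1]` for non-negative input.
#'
#' @param x abundance matrix; samples are columns by default.
#' @param samples `"columns"` or `"rows"`.
#' @return symmetric n x n matrix with zero diagonal and sample dimnames.
#' @export
bray_curtis <- function(x, samples = c("columns", "rows")) {
  samples <- match.arg(samples)
  if (samples == "columns") x <- t(x)
  if (any(x < 0)) stop("abundances must be non-negative")
  tot <- rowSums(x)
  if (any(tot == 0))
    stop("all-zero sample(s): ",
         paste(rownames(x)[tot == 0], collapse = ", "))
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- sum(abs(x[i, ] - x[j, ])) / (tot[i] + tot[j])
  }
  d
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of whether between-group dissimilarities exceed
#' within-group dissimilarities:
#' `R = (mean between-group rank - mean within-group rank) / (M / 2)` with
#' `M = n(n-1)/2` pairs (ties get average ranks). Significance comes from
#' permuting group labels; with random permutations the p-value uses the
#' add-one rule `p = (1 + #(R_perm >= R_obs)) / (1 + n_perm)`, and with
#' `exhaustive = TRUE` every distinct label permutation is enumerated and
#' `p = #(R_perm >= R_obs) / #permutations` (the identity is included).
#'
#' @param d symmetric dissimilarity matrix.
#' @param groups factor; every level needs >= 2 members.
#' @param n_perm number of random permutations (default 999).
#' @param seed optional integer seed for the permutations.
#' @param exhaustive enumerate all label permutations (small n only).
#' @return `exfo_anosim`: `statistic` (R), `p`, `n_perm`, `seed`.
#' @export
anosim <- function(d, groups, n_perm = 999, seed = NULL, exhaustive = FALSE) {
  groups <- as.factor(groups)
  n <- nrow(d)
  if (length(groups) != n) stop("groups must match the distance matrix")
  if (any(table(groups) < 2)) stop("every group needs >= 2 members")
  lower <- lower.tri(d)
  rk <- rank(d[lower])
  pair_i <- row(d)[lower]; pair_j <- col(d)[lower]
  stat <- function(g) {
    within <- g[pair_i] == g[pair_j]
    (mean(rk[!within]) - mean(rk[within])) / (n * (n - 1) / 4)
  }
  r_obs <- stat(groups)
  if (exhaustive) {
    perms <- all_permutations(n)
    r_perm <- apply(perms, 1, function(idx) stat(groups[idx]))
    p <- mean(r_perm >= r_obs - 1e-12)
    n_perm <- nrow(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    r_perm <- replicate(n_perm, stat(sample(groups)))
    p <- (1 + sum(r_perm >= r_obs - 1e-12)) / (1 + n_perm)
  }
  res <- list(statistic = r_obs, p = p, n_perm = n_perm, seed = seed,
              exhaustive = exhaustive)
  class(res) <- "exfo_anosim"
  res
}

all_permutations <- function(n) {
  if (n > 8) stop("exhaustive enumeration limited to n <= 8")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    ins <- cbind(sub[, seq_len(k - 1), drop = FALSE],
                 rep(n, nrow(sub)),
                 sub[, if (k <= n - 1) k:(n - 1) else integer(0), drop = FALSE])
    out <- rbind(out, ins)
  }
  out
}

#' @export
#' @method print exfo_anosim
print.exfo_anosim <- function(x, ...) {
  cat(sprintf("ANOSIM R = %.3f, p = %.4g (%s%d permutations)\n",
              x$statistic, x$p, if (x$exhaustive) "exhaustive " else "",
              x$n_perm))
  invisible(x)
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Minimizes stress-1 `sqrt(sum (d - dhat)^2 / sum d^2)` by alternating
#' monotone (isotonic) regression of configuration distances on the
#' dissimilarity order with a Guttman majorization update of the
#' configuration. Ties in the dissimilarities use Kruskal's primary
#' treatment (tied dissimilarities impose no order constraint). The best of
#' `n_restarts` random starts plus one classical-MDS start is returned.
#'
#' @param d symmetric dissimilarity matrix.
#' @param k embedding dimension (`k < n`).
#' @param seed integer seed for the random starts.
#' @param n_restarts random restarts in addition to the metric start.
#' @param max_iter,tol majorization loop controls.
#' @return `exfo_nmds`: `points` (n x k), `stress`, `converged`,
#'   `stress_trajectory` of the winning start.
#' @export
nmds <- function(d, k = 2, seed = 1, n_restarts = 20, max_iter = 300,
                 tol = 1e-9) {
  n <- nrow(d)
  if (k >= n) stop("k must be < number of points")
  lowr <- lower.tri(d)
  delta <- d[lowr]
  set.seed(seed)
  starts <- c(list(metric_start(d, k)),
              replicate(n_restarts, matrix(stats::rnorm(n * k), n, k),
                        simplify = FALSE))
  best <- NULL
  for (X0 in starts) {
    fit <- nmds_one(X0, delta, lowr, n, k, max_iter, tol)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  rownames(best$points) <- rownames(d)
  class(best) <- "exfo_nmds"
  best
}

metric_start <- function(d, k) {
  # k can exceed the configuration's intrinsic rank; pad with zero axes
  cm <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = k))
  if (ncol(cm) < k) cm <- cbind(cm, matrix(0, nrow(cm), k - ncol(cm)))
  cm
}

nmds_one <- function(X, delta, lowr, n, k, max_iter, tol) {
  denom0 <- sum(delta^2)
  if (denom0 == 0) return(list(points = X, stress = 0, converged = TRUE,
                               stress_trajectory = 0))
  stress_of <- function(dist_vec, dhat)
    sqrt(sum((dist_vec - dhat)^2) / sum(dist_vec^2))
  traj <- numeric(0)
  prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dx <- as.matrix(stats::dist(X))
    dv <- dx[lowr]
    # primary tie treatment: ties in delta broken by ascending current
    # distance, so tied pairs never violate monotonicity
    o <- order(delta, dv)
    dhat <- numeric(length(dv))
    dhat[o] <- stats::isoreg(dv[o])$yf
    s <- stress_of(dv, dhat)
    traj <- c(traj, s)
    if (is.finite(prev) && prev - s < tol) { converged <- TRUE; break }
    prev <- s
    # Guttman transform with weights 1
    B <- matrix(0, n, n)
    ratio <- ifelse(dx[lowr] > 0, dhat / dx[lowr], 0)
    B[lowr] <- -ratio
    B <- B + t(B)
    diag(B) <- -rowSums(B)
    X <- B %*% X / n
    X <- scale(X, center = TRUE, scale = FALSE)
  }
  dx <- as.matrix(stats::dist(X))
  dv <- dx[lowr]
  o <- order(delta, dv)
  dhat <- numeric(length(dv))
  dhat[o] <- stats::isoreg(dv[o])$yf
  list(points = X, stress = stress_of(dv, dhat), converged = converged,
       stress_trajectory = traj)
}

#' @export
#' @method print exfo_nmds
print.exfo_nmds <- function(x, ...) {
  cat(sprintf("NMDS in %d dimensions: stress-1 = %.4f%s\n", ncol(x$points),
              x$stress, if (!x$converged) " (not converged)" else ""))
  invisible(x)
}

#' Leading-logFC metric MDS
#'
#' The distance between two samples is the root-mean-square of the `top_n`
#' largest absolute log2 fold changes (differences of log2-CPM) between
#' them; classical metric MDS of that matrix gives the coordinates. This is
#' the treatment-oriented "MDS plot" convention of count-based differential
#' expression workflows.
#'
#' @param logcpm genes x samples log2-CPM matrix (>= 3 samples).
#' @param k embedding dimension.
#' @param top_n number of leading genes per pair (clipped with a warning if
#'   it exceeds the gene count).
#' @return list with `points` (n x k) and `distance` (n x n).
#' @export
mds_leading_logfc <- function(logcpm, k = 2, top_n = 500) {
  n <- ncol(logcpm)
  if (n < 3) stop("need >= 3 samples")
  if (top_n > nrow(logcpm)) {
    warning("top_n exceeds gene count; clipped to ", nrow(logcpm))
    top_n <- nrow(logcpm)
  }
  d <- matrix(0, n, n, dimnames = list(colnames(logcpm), colnames(logcpm)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sq <- (logcpm[, i] - logcpm[, j])^2
    top <- sort(sq, decreasing = TRUE)[seq_len(top_n)]
    d[i, j] <- d[j, i] <- sqrt(mean(top))
  }
  pts <- stats::cmdscale(stats::as.dist(d), k = k)
  if (ncol(pts) < k) pts <- cbind(pts, matrix(0, nrow(pts), k - ncol(pts)))
  list(points = pts, distance = d)
}
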