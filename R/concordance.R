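#' Marker-panel scores per sample and category
#'
#' For each sample and each cell type (or anatomic site) in the panel:
#' total reads over the panel genes, number of panel genes detected
#' (count > 0), and a presence flag requiring at least 2 detected markers.
#' Panel genes absent from the matrix are reported with a warning and score
#' zero, so presence stays monotone in the data.
#'
#' @param counts gene x sample matrix with rownames.
#' @param panel data frame with columns `cell_type`, `gene`.
#' @return data frame: sample, cell_type, total_counts, detected, present.
#' @export
marker_scores <- function(counts, panel) {
  check_counts(counts)
  if (!is.data.frame(panel) || nrow(panel) == 0 ||
      !all(c("cell_type", "gene") %in% names(panel)))
    stop("panel must be a non-empty data frame with cell_type and gene")
  missing <- setdiff(panel$gene, rownames(counts))
  if (length(missing))
    warning(length(missing), " panel gene(s) absent from the matrix; scored 0")
  out <- do.call(rbind, lapply(split(panel$gene, panel$cell_type), function(gs) {
    gs <- intersect(gs, rownames(counts))
    if (length(gs) == 0) {
      data.frame(sample = colnames(counts), total_counts = 0,
                 detected = 0L, stringsAsFactors = FALSE)
    } else {
      sub <- counts[gs, , drop = FALSE]
      data.frame(sample = colnames(counts), total_counts = colSums(sub),
                 detected = colSums(sub > 0), stringsAsFactors = FALSE)
    }
  }))
  out$cell_type <- rep(names(split(panel$gene, panel$cell_type)),
                       each = ncol(counts))
  out$present <- out$detected >= 2
  rownames(out) <- NULL
  out[, c("sample", "cell_type", "total_counts", "detected", "present")]
}

#' Proportion as a rounded integer percentage
#' @param k,n counts with `0 <= k <= n`, `n > 0`.
#' @return `round(100 * k / n)`.
#' @export
proportion_percent <- function(k, n) {
  if (length(k) != 1 || length(n) != 1 || !is.finite(k) || !is.finite(n) ||
      n <= 0 || k < 0 || k > n)
    stop("need 0 <= k <= n with n > 0")
  as.integer(round(100 * k / n))
}

#' Pooled two-sample z-test for proportions
#'
#' `z = (p1 - p2) / sqrt(p_pool (1 - p_pool) (1/n1 + 1/n2))` with the
#' pooled success probability, two-sided p-value from the normal.
#'
#' @param k1,n1,k2,n2 successes and totals of the two samples.
#' @return list with `z`, `p`, and the two proportions.
#' @export
two_proportion_test <- function(k1, n1, k2, n2) {
  for (v in list(k1, n1, k2, n2))
    if (length(v) != 1 || !is.finite(v) || v < 0) stop("counts must be finite and >= 0")
  if (n1 == 0 || n2 == 0) stop("totals must be > 0")
  if (k1 > n1 || k2 > n2) stop("successes cannot exceed totals")
  p1 <- k1 / n1; p2 <- k2 / n2
  pool <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)), p1 = p1, p2 = p2)
}

#' McNemar's test from the discordant cells
#'
#' Exact binomial version (`2 * pbinom(min(b, c), b + c, 1/2)`, capped at 1)
#' when `b + c < 25`; chi-squared with continuity correction
#' (`(|b - c| - 1)^2 / (b + c)`) otherwise. `b = c = 0` returns p = 1 with
#' a warning.
#'
#' @param b,c discordant pair counts.
#' @return list: `statistic`, `p`, `method`.
#' @export
mcnemar_test <- function(b, c) {
  if (length(b) != 1 || length(c) != 1 || b < 0 || c < 0 ||
      b != round(b) || c != round(c))
    stop("b and c must be non-negative integers")
  n <- b + c
  if (n == 0) {
    warning("no discordant pairs; p = 1 by definition")
    return(list(statistic = NA_real_, p = 1, method = "exact"))
  }
  if (n < 25) {
    p <- min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
    list(statistic = min(b, c), p = p, method = "exact")
  } else {
    stat <- (abs(b - c) - 1)^2 / n
    list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE),
         method = "chisq_cc")
  }
}

#' Correlation of pathway Z-scores between two datasets
#'
#' Pearson (default) or Spearman correlation over the rows shared by two
#' named Z-score vectors, with a two-sided p-value. This is how agreement
#' between, e.g., stool-derived and tissue-derived pathway activation
#' scores is quantified without recomputing the pathway scores themselves.
#'
#' @param za,zb named numeric vectors (pathway -> Z).
#' @param method `"pearson"` or `"spearman"`.
#' @return list: `r`, `p`, `n` shared rows.
#' @export
zscore_correlation <- function(za, zb, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.null(names(za)) || is.null(names(zb)))
    stop("za and zb must be named by pathway")
  shared <- intersect(names(za), names(zb))
  if (length(shared) < 3) stop("fewer than 3 shared rows")
  ct <- suppressWarnings(stats::cor.test(za[shared], zb[shared],
                                         method = method, exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(shared))
}
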