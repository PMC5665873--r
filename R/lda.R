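# Single-feature linear discriminant classification with bolstered
# resubstitution error. With n = 10 samples, plain resubstitution error is
# wildly optimistic; bolstering replaces each training point by a Gaussian
# kernel and integrates the kernel mass falling on the wrong side of the
# decision boundary, which is available in closed form in one dimension.

# kernel-size calibration: mean within-class nearest-neighbor distance is
# treated as the median of the kernel's inter-point distance, whose scale is
# sqrt(2) * sigma * z with z = qnorm(0.75) the 1-D Gaussian median factor
BOLSTER_CALIBRATION <- sqrt(2) * stats::qnorm(0.75)

#' One-dimensional linear discriminant
#'
#' Equal-prior, equal-variance LDA on a single feature: the decision
#' boundary is the midpoint of the class means and samples classify by
#' side (the class with the larger mean owns the upper side).
#'
#' @param values numeric vector, one expression value per sample.
#' @param labels two-level factor, >= 2 samples per level.
#' @return list: `boundary`, `means` (named), `pooled_sd`, `upper_class`.
#' @export
fit_lda_1d <- function(values, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("exactly two classes are required")
  if (any(table(labels) < 2)) stop("need >= 2 samples per class")
  m <- tapply(values, labels, mean)
  ss <- sum(tapply(values, labels, function(v) sum((v - mean(v))^2)))
  pooled <- sqrt(ss / (length(values) - 2))
  if (pooled == 0) stop("pooled variance is zero; feature is degenerate")
  list(boundary = unname(mean(m)), means = m, pooled_sd = pooled,
       upper_class = names(m)[which.max(m)])
}

#' Bolstering kernel standard deviations
#'
#' Per class, the kernel SD is the mean nearest-neighbor distance within the
#' class divided by the calibration constant
#' `sqrt(2) * qnorm(0.75)` (~0.954): the mean NN distance estimates the
#' median distance between two draws of the kernel, which for a 1-D
#' Gaussian is `sqrt(2) * sigma * qnorm(0.75)`. Classes whose points all
#' coincide get a machine-epsilon-scale floor with a warning.
#'
#' @param values numeric vector.
#' @param labels two-level factor, >= 2 samples per level.
#' @param calibration divisor constant (documented default above).
#' @return named numeric vector, one SD per class.
#' @export
bolster_sigma <- function(values, labels,
                          calibration = BOLSTER_CALIBRATION) {
  labels <- as.factor(labels)
  if (any(table(labels) < 2)) stop("need >= 2 samples per class")
  floor_sd <- sqrt(.Machine$double.eps) * (1 + mean(abs(values)))
  out <- vapply(levels(labels), function(cl) {
    v <- values[labels == cl]
    nn <- vapply(seq_along(v), function(i) min(abs(v[i] - v[-i])), numeric(1))
    s <- mean(nn) / calibration
    if (s == 0) {
      warning("class '", cl, "' has coincident points; kernel SD floored")
      s <- floor_sd
    }
    s
  }, numeric(1))
  out
}

#' Bolstered resubstitution error of the 1-D LDA
#'
#' `error = (1/n) * sum_i P(N(value_i, sigma_class(i)) on wrong side of
#' boundary)`, in closed form through the normal CDF.
#'
#' @param values,labels as in [fit_lda_1d()].
#' @param fit optional precomputed [fit_lda_1d()] result.
#' @param sigmas optional precomputed [bolster_sigma()] result.
#' @param calibration passed to [bolster_sigma()].
#' @return error estimate in `[0, 1]`.
#' @export
bolstered_error <- function(values, labels, fit = NULL, sigmas = NULL,
                            calibration = BOLSTER_CALIBRATION) {
  labels <- as.factor(labels)
  if (is.null(fit)) fit <- fit_lda_1d(values, labels)
  if (is.null(sigmas)) sigmas <- bolster_sigma(values, labels, calibration)
  # a point of the upper class errs on mass below the boundary and vice versa
  sgn <- ifelse(labels == fit$upper_class, 1, -1)
  mean(stats::pnorm(sgn * (fit$boundary - values) / sigmas[as.character(labels)]))
}

#' Rank genes by bolstered single-feature classification error
#'
#' Runs the 1-feature LDA with bolstered resubstitution on every listed
#' gene (typically the differentially expressed set at FDR < 0.05), sorts
#' by ascending error with ties broken by gene id, and flags genes whose
#' error beats `threshold` (default 5%).
#'
#' @param expr genes x samples matrix of log2-CPM (or counts).
#' @param labels two-level factor over the samples.
#' @param genes gene ids to rank; default all rows.
#' @param threshold selection threshold on the error.
#' @param calibration kernel calibration constant.
#' @return `exfo_ranking` data frame: gene, error, rank, selected. Genes
#'   with zero pooled variance get `NA` error and rank last.
#' @export
rank_features <- function(expr, labels, genes = rownames(expr),
                          threshold = 0.05,
                          calibration = BOLSTER_CALIBRATION) {
  if (length(genes) == 0) {
    warning("empty gene list; returning empty ranking")
    out <- data.frame(gene = character(), error = numeric(),
                      rank = integer(), selected = logical())
    class(out) <- c("exfo_ranking", "data.frame")
    return(out)
  }
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    stop("gene(s) absent from the matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  err <- vapply(genes, function(g) {
    v <- expr[g, ]
    tryCatch(suppressWarnings(bolstered_error(v, labels,
                                              calibration = calibration)),
             error = function(e) NA_real_)
  }, numeric(1))
  o <- order(err, genes, na.last = TRUE)
  out <- data.frame(gene = genes[o], error = err[o],
                    rank = seq_along(genes),
                    selected = !is.na(err[o]) & err[o] < threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("exfo_ranking", "data.frame")
  out
}
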