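#' Two-group negative-binomial exact test
#'
#' Library sizes are first equalized by scaling each sample's counts to the
#' geometric mean of the effective library sizes (a documented
#' approximation). For each gene, the two group sums (s1, s2) of these
#' pseudo-counts are rounded to integers; under a common per-sample mean and
#' common dispersion phi, the conditional distribution of s1 given the total
#' t = s1 + s2 is
#' `P(k) \propto dnbinom(k, size = n1/phi, mu = n1*t/n) *
#'            dnbinom(t - k, size = n2/phi, mu = n2*t/n)`.
#' The two-sided p-value doubles the smaller tail (observed value included)
#' and is capped at 1. The log2 fold change compares normalized group means
#' with a prior count added to each (second factor level vs first).
#'
#' @param counts filtered gene x sample count matrix.
#' @param groups two-level factor; the *second* level is the treatment, so
#'   positive `logFC` means higher in treatment.
#' @param dispersion common dispersion phi (scalar or `exfo_dispersion`).
#' @param norm optional `exfo_norm`.
#' @param prior_count pseudo-count per group mean for the fold change.
#' @return `exfo_de` data frame: gene, logFC, logCPM, pvalue, fdr, ordered
#'   by increasing p-value (ties by gene id).
#' @export
exact_test <- function(counts, groups, dispersion, norm = NULL,
                       prior_count = 0.125) {
  check_counts(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  if (any(table(groups) < 1)) stop("each group needs >= 1 sample")
  if (inherits(dispersion, "exfo_dispersion"))
    dispersion <- dispersion$common_dispersion
  phi <- dispersion
  eff <- if (is.null(norm)) colSums(counts) else norm$effective_lib
  geo <- exp(mean(log(eff)))
  pseudo <- sweep(counts, 2, geo / eff, "*")
  i1 <- groups == levels(groups)[1]
  n1 <- sum(i1); n2 <- sum(!i1)
  s1 <- round(rowSums(pseudo[, i1, drop = FALSE]))
  s2 <- round(rowSums(pseudo[, !i1, drop = FALSE]))
  pv <- vapply(seq_along(s1), function(i)
    nb_exact_pvalue(s1[i], s2[i], n1, n2, phi), numeric(1))
  logFC <- log2((s2 / n2 + prior_count) / (s1 / n1 + prior_count))
  logCPM <- log2(((s1 + s2) / (n1 + n2) + 2 * prior_count) / geo * 1e6)
  res <- data.frame(gene = rownames(counts), logFC = logFC, logCPM = logCPM,
                    pvalue = pv, fdr = bh_adjust(pv),
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[order(res$pvalue, res$gene), ]
  rownames(res) <- NULL
  class(res) <- c("exfo_de", "data.frame")
  res
}

# conditional NB exact p for one gene; doubled smaller tail capped at 1
nb_exact_pvalue <- function(s1, s2, n1, n2, phi) {
  t <- s1 + s2
  if (t == 0) return(1)
  k <- 0:t
  mu <- t / (n1 + n2)
  if (phi <= 1e-12) {
    # Poisson limit: conditional law is binomial(t, n1/(n1+n2))
    lp <- stats::dbinom(k, t, n1 / (n1 + n2), log = TRUE)
  } else {
    lp <- stats::dnbinom(k, size = n1 / phi, mu = n1 * mu, log = TRUE) +
      stats::dnbinom(t - k, size = n2 / phi, mu = n2 * mu, log = TRUE)
  }
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  lower <- sum(p[k <= s1])
  upper <- sum(p[k >= s1])
  min(1, 2 * min(lower, upper))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return q-values (monotone, `q >= p` component-wise).
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(p)
  if (n <= 1) return(p)
  o <- order(p, decreasing = TRUE)
  q <- numeric(n)
  q[o] <- pmin(1, cummin(n / (n:1) * p[o]))
  q
}

#' MA table with DE provenance flags
#'
#' One row per gene with its average log2-CPM, log2 fold change, and a flag
#' recording whether it is differentially expressed in this dataset, only in
#' another source's dataset, or in neither -- the tabular form of an MA plot
#' overlaying another source's DE calls.
#'
#' @param de `exfo_de` result for this dataset.
#' @param de_here gene ids called DE in this dataset.
#' @param de_other gene ids called DE in the other source.
#' @return data frame: gene, logCPM, logFC,
#'   flag in `{DE_here, DE_in_other_source_only, not_DE}`.
#' @export
ma_table <- function(de, de_here = character(), de_other = character()) {
  unknown <- setdiff(c(de_here, de_other), de$gene)
  if (length(unknown))
    stop("unknown gene id(s) in flag sets: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  flag <- ifelse(de$gene %in% de_here, "DE_here",
                 ifelse(de$gene %in% de_other, "DE_in_other_source_only",
                        "not_DE"))
  data.frame(gene = de$gene, logCPM = de$logCPM, logFC = de$logFC,
             flag = flag, stringsAsFactors = FALSE)
}

#' Intersections of named gene sets
#'
#' Computes the counts of every disjoint Venn region and the pairwise
#' overlap percentages `100 * |A n B| / |A u B|`.
#'
#' @param sets named list (>= 2) of character vectors.
#' @return list with `regions` (named counts, names like `"A&B"`),
#'   `pairwise` (data frame: set_a, set_b, intersection, union,
#'   overlap_percent).
#' @export
intersect_gene_sets <- function(sets) {
  if (!is.list(sets) || length(sets) < 2 || is.null(names(sets)) ||
      any(names(sets) == ""))
    stop("need a named list of >= 2 sets")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  if (length(universe) == 0) stop("the union of the sets is empty")
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  sig <- apply(member, 1, function(r) paste(names(sets)[r], collapse = "&"))
  regions <- table(sig)
  pairs <- utils::combn(names(sets), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- sets[[pairs[1, j]]]; b <- sets[[pairs[2, j]]]
    ints <- length(intersect(a, b)); uni <- length(union(a, b))
    data.frame(set_a = pairs[1, j], set_b = pairs[2, j],
               intersection = ints, union = uni,
               overlap_percent = if (uni > 0) 100 * ints / uni else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(regions = stats::setNames(as.integer(regions), names(regions)),
       pairwise = pw)
}
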