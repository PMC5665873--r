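#' Remove genes present in low abundance
#'
#' A gene is removed when it is nonzero in at most `min_samples` samples OR
#' its total count across all samples is at most `min_total`; the defaults
#' (4 samples, 50 reads) are the conventional thresholds for this assay.
#' Both conditions use "<=", so the boundary values themselves are removed.
#'
#' @param counts non-negative integer gene x sample matrix.
#' @param min_samples,min_total removal thresholds (inclusive).
#' @return list with `counts` (filtered matrix) and `report`
#'   (`exfo_filter_report`: gene/read totals before and after, rounded
#'   percent reductions).
#' @export
filter_low_abundance <- function(counts, min_samples = 4L, min_total = 50L) {
  check_counts(counts)
  nonzero <- rowSums(counts > 0)
  total <- rowSums(counts)
  keep <- !(nonzero <= min_samples | total <= min_total)
  out <- counts[keep, , drop = FALSE]
  rep <- list(genes_before = nrow(counts), genes_after = nrow(out),
              reads_before = sum(counts), reads_after = sum(out),
              percent_gene_reduction =
                if (nrow(counts) > 0) percent_reduction(nrow(counts), nrow(out)) else 0,
              percent_read_reduction =
                if (sum(counts) > 0)
                  100 * (sum(counts) - sum(out)) / sum(counts) else 0)
  class(rep) <- "exfo_filter_report"
  list(counts = out, report = rep)
}

check_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix")
  if (any(counts < 0)) stop("counts must be non-negative")
  invisible(TRUE)
}

#' Percent reduction, rounded to the nearest integer
#'
#' @param before,after counts with `before > 0` and `0 <= after <= before`.
#' @return `round(100 * (before - after) / before)` as an integer.
#' @export
percent_reduction <- function(before, after) {
  if (length(before) != 1 || length(after) != 1 || !is.finite(before) ||
      !is.finite(after) || before <= 0 || after < 0 || after > before)
    stop("need before > 0 and 0 <= after <= before")
  as.integer(round(100 * (before - after) / before))
}

#' Upper-quartile normalization factors
#'
#' The raw factor for a sample is the 75th percentile of the counts of genes
#' *nonzero in that sample*, divided by the sample's library size; raw
#' factors are then rescaled so their geometric mean is exactly 1.
#' Percentiles use linear interpolation between order statistics
#' (`quantile(type = 7)`) -- quartile dialects change factors, so the
#' convention is fixed here and exposed via `probs`.
#'
#' @param counts gene x sample count matrix.
#' @param probs quantile used (default 0.75).
#' @return `exfo_norm` object: `library_size`, `norm_factor`,
#'   `effective_lib = library_size * norm_factor`, per sample.
#' @export
upper_quartile_factors <- function(counts, probs = 0.75) {
  check_counts(counts)
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  raw <- vapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    stats::quantile(x[x > 0], probs = probs, names = FALSE, type = 7) / lib[j]
  }, numeric(1))
  f <- raw / exp(mean(log(raw)))
  res <- list(library_size = lib, norm_factor = stats::setNames(f, colnames(counts)),
              effective_lib = lib * f)
  class(res) <- "exfo_norm"
  res
}

#' Counts per million
#'
#' `cpm = count / effective_library * 1e6`. With `log = TRUE`,
#' `log2((count + prior) / (effective_library + 2 * prior) * 1e6)`.
#'
#' @param counts gene x sample matrix.
#' @param norm optional `exfo_norm`; if absent, effective libraries are the
#'   raw column sums (all norm factors 1).
#' @param log return log2-CPM.
#' @param prior_count pseudo-count used only when `log = TRUE`.
#' @return numeric matrix, same dimnames as `counts`.
#' @export
cpm <- function(counts, norm = NULL, log = FALSE, prior_count = 0.5) {
  check_counts(counts)
  eff <- if (is.null(norm)) colSums(counts) else norm$effective_lib
  if (length(eff) != ncol(counts)) stop("normalization does not match counts")
  if (any(eff <= 0)) stop("effective library sizes must be > 0")
  if (!log) {
    sweep(counts, 2, eff, "/") * 1e6
  } else {
    log2(sweep(counts + prior_count, 2, eff + 2 * prior_count, "/") * 1e6)
  }
}

#' Per-sample housekeeping-gene read fraction
#'
#' Library-size diagnostic: the share of each sample's reads falling in a
#' housekeeping set. Similar fractions across samples indicate that total
#' count differences reflect library size (e.g., microbial displacement of
#' host reads in stool), not assay failure.
#'
#' @param counts gene x sample matrix with rownames.
#' @param hk_gene_ids character vector of housekeeping gene ids.
#' @return named numeric vector of fractions in `[0, 1]`, one per sample.
#' @export
housekeeping_fraction <- function(counts, hk_gene_ids) {
  check_counts(counts)
  if (length(hk_gene_ids) == 0) stop("housekeeping set is empty")
  hit <- intersect(hk_gene_ids, rownames(counts))
  if (length(hit) == 0)
    stop("no housekeeping ids found in the matrix; missing: ",
         paste(utils::head(hk_gene_ids, 5), collapse = ", "), " ...")
  miss <- setdiff(hk_gene_ids, rownames(counts))
  if (length(miss))
    warning(length(miss), " housekeeping id(s) absent from the matrix")
  tot <- colSums(counts)
  frac <- colSums(counts[hit, , drop = FALSE]) / ifelse(tot > 0, tot, 1)
  frac[tot == 0] <- 0
  frac
}

#' Cross-source correlation of mean expression
#'
#' Spearman rank correlation of per-gene mean log2-CPM between two sources,
#' restricted to one treatment group and the shared (post-filter) gene
#' universe. High rank correlation (R > 0.8) indicates that the stool
#' signature mirrors the tissue signature.
#'
#' @param logcpm_a,logcpm_b log2-CPM matrices (genes x samples) for the two
#'   sources, already subset to the same treatment group's samples.
#' @return list with `rho`, `p` (two-sided) and `n_genes` used.
#' @export
cross_source_correlation <- function(logcpm_a, logcpm_b) {
  shared <- intersect(rownames(logcpm_a), rownames(logcpm_b))
  if (length(shared) < 3) stop("fewer than 3 shared genes")
  ma <- rowMeans(logcpm_a[shared, , drop = FALSE])
  mb <- rowMeans(logcpm_b[shared, , drop = FALSE])
  ct <- suppressWarnings(stats::cor.test(ma, mb, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n_genes = length(shared))
}

#' @export
#' @method print exfo_filter_report
print.exfo_filter_report <- function(x, ...) {
  cat(sprintf("low-abundance filter: %d -> %d genes (%d%% reduction), %s -> %s reads (%.3f%% reduction)\n",
              x$genes_before, x$genes_after, x$percent_gene_reduction,
              format(x$reads_before, big.mark = ","),
              format(x$reads_after, big.mark = ","),
              x$percent_read_reduction))
  invisible(x)
}

#' @export
#' @method print exfo_norm
print.exfo_norm <- function(x, ...) {
  cat("upper-quartile normalization for", length(x$norm_factor), "samples\n")
  print(data.frame(library_size = x$library_size,
                   norm_factor = round(x$norm_factor, 4),
                   effective_lib = round(x$effective_lib, 1)))
  invisible(x)
}
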