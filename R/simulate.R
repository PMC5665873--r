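#' Simulation parameters for the three-source count generator
#'
#' Builds and validates the parameter set for [simulate_counts()]. The
#' defaults describe the experiment the package targets: two treatment groups
#' (control vs NSAID) of `n_per_group` subjects, each measured in three
#' sources -- small-intestinal mucosa (`SI`), colonic mucosa (`colon`) and
#' stool exfoliated cells (`exfoliome`). Per-source mean library sizes follow
#' the observed mapped-read totals (27e6, 39e6 and 3.8e6 reads per sample,
#' divided by `lib_scale` so simulations run at desk scale), and per-source
#' negative-binomial dispersions use the observed common dispersions
#' (0.143, 0.126, 0.592). A fraction `de_fraction` of genes carries a
#' treatment effect of `lfc_magnitude` log2 units, expressed only in
#' `shared_effect_sources` (small intestine and exfoliome by default --
#' the colon is untouched by the treatment).
#'
#' @param n_genes number of genes in the shared universe.
#' @param n_per_group subjects per treatment group (default 5).
#' @param sources character vector of source labels.
#' @param lib_size_mean named numeric, mean mapped reads per sample for each
#'   source *before* division by `lib_scale`.
#' @param lib_scale divisor applied to `lib_size_mean` so that desk-scale
#'   matrices keep the real data's relative depths.
#' @param dispersion named numeric, NB dispersion phi per source (>= 0).
#' @param de_fraction fraction of genes given a treatment effect.
#' @param lfc_magnitude absolute log2 fold change of affected genes; signs
#'   are split evenly between up- and down-regulation.
#' @param shared_effect_sources sources in which the effect is expressed.
#' @param contamination_fraction fraction of the exfoliome library displaced
#'   by non-host reads. The default 0 reflects that `lib_size_mean` already
#'   encodes the displacement (3.8e6 vs 27e6/39e6); raising it shrinks the
#'   exfoliome library further without emitting microbial reads.
#' @param dropout_quantile fraction of lowest-abundance genes zeroed out in
#'   the exfoliome, emulating genes detectable in tissue but not in stool.
#' @param hk_gene_count number of housekeeping genes to label (default 532).
#' @param lib_cv coefficient of variation of per-sample library sizes
#'   (log-normal, default 20%).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of per-gene
#'   baseline means (long-tailed abundance distribution).
#' @param marker_panel optional data frame (`cell_type`, `gene`) overriding
#'   the default panel built by [make_marker_panel()].
#' @param seed integer seed controlling every random draw.
#'
#' @return a validated list of class `exfo_sim_params`.
#' @export
simulation_params <- function(n_genes = 2000L,
                              n_per_group = 5L,
                              sources = c("SI", "colon", "exfoliome"),
                              lib_size_mean = c(SI = 27e6, colon = 39e6,
                                                exfoliome = 3.8e6),
                              lib_scale = 100,
                              dispersion = c(SI = 0.143, colon = 0.126,
                                             exfoliome = 0.592),
                              de_fraction = 0.10,
                              lfc_magnitude = 2,
                              shared_effect_sources = c("SI", "exfoliome"),
                              contamination_fraction = 0,
                              dropout_quantile = 0.30,
                              hk_gene_count = 532L,
                              lib_cv = 0.20,
                              baseline_meanlog = 0,
                              baseline_sdlog = 1.5,
                              marker_panel = NULL,
                              seed = 1L) {
  stopifnot(length(sources) >= 1, !anyDuplicated(sources))
  num_ok <- function(x) all(is.finite(x))
  if (!num_ok(c(n_genes, n_per_group, lib_size_mean, lib_scale, dispersion,
                de_fraction, lfc_magnitude, contamination_fraction,
                dropout_quantile, hk_gene_count, lib_cv,
                baseline_meanlog, baseline_sdlog, seed)))
    stop("all numeric parameters must be finite")
  if (any(dispersion < 0)) stop("dispersion must be >= 0")
  if (any(lib_size_mean <= 0) || lib_scale <= 0) stop("library sizes must be > 0")
  frac <- c(de_fraction, contamination_fraction, dropout_quantile)
  if (any(frac < 0 | frac > 1)) stop("fractions must lie in [0, 1]")
  if (lib_cv < 0) stop("lib_cv must be >= 0")
  if (!all(sources %in% names(lib_size_mean)) ||
      !all(sources %in% names(dispersion)))
    stop("lib_size_mean and dispersion must be named for every source")
  if (!all(shared_effect_sources %in% sources))
    stop("shared_effect_sources must be a subset of sources")
  if (n_genes < 2 || n_per_group < 2) stop("need n_genes >= 2 and n_per_group >= 2")
  if (hk_gene_count >= n_genes) stop("hk_gene_count must be < n_genes")
  p <- list(n_genes = as.integer(n_genes), n_per_group = as.integer(n_per_group),
            sources = sources, lib_size_mean = lib_size_mean[sources],
            lib_scale = lib_scale, dispersion = dispersion[sources],
            de_fraction = de_fraction, lfc_magnitude = lfc_magnitude,
            shared_effect_sources = shared_effect_sources,
            contamination_fraction = contamination_fraction,
            dropout_quantile = dropout_quantile,
            hk_gene_count = as.integer(hk_gene_count), lib_cv = lib_cv,
            baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
            marker_panel = marker_panel, seed = as.integer(seed))
  class(p) <- "exfo_sim_params"
  p
}

# NB sampler that degrades gracefully to Poisson as phi -> 0.
rnb <- function(n, mu, phi) {
  if (phi <= 0) stats::rpois(n, mu) else stats::rnbinom(n, size = 1 / phi, mu = mu)
}

#' Simulate coupled three-source count matrices
#'
#' Draws gene-by-sample negative-binomial counts for each source from a
#' shared long-tailed baseline abundance profile. Sample `j` of source `s`
#' has mean `rel_g * L_sj * 2^(lfc_g)` for gene `g`, where `rel` is the
#' normalized baseline profile, `L_sj` a log-normal library size around the
#' source mean, and `lfc_g` the treatment log2 fold change (nonzero only for
#' affected genes, in treated samples, in `shared_effect_sources`).
#' Counts have NB variance `mu + phi_s * mu^2`. The exfoliome library is
#' shrunk by `1 - contamination_fraction`, and its lowest-abundance
#' `dropout_quantile` of genes is zeroed (genes lost in stool transit).
#' Subjects are matched across sources, so treatment structure couples the
#' sources at the sample level.
#'
#' @param params an `exfo_sim_params` object from [simulation_params()].
#' @return a list with elements
#'   `counts` (named list of gene x sample integer matrices, one per source),
#'   `metadata` (data frame: sample_id, source, group, subject),
#'   `truth` (ground truth: per-source DE gene ids and true log2FC,
#'    baseline means, housekeeping ids, marker panel).
#' @export
simulate_counts <- function(params) {
  if (!inherits(params, "exfo_sim_params"))
    params <- do.call(simulation_params, params)
  p <- params
  set.seed(p$seed)
  genes <- sprintf("g%05d", seq_len(p$n_genes))
  n <- 2L * p$n_per_group
  group <- factor(rep(c("control", "NSAID"), each = p$n_per_group),
                  levels = c("control", "NSAID"))
  subject <- paste0(ifelse(group == "control", "C", "N"),
                    rep(seq_len(p$n_per_group), times = 2))

  base_mu <- stats::rlnorm(p$n_genes, p$baseline_meanlog, p$baseline_sdlog)
  rel <- base_mu / sum(base_mu)
  names(rel) <- genes

  n_de <- round(p$de_fraction * p$n_genes)
  de_genes <- if (n_de > 0) sort(sample(genes, n_de)) else character()
  lfc <- stats::setNames(numeric(p$n_genes), genes)
  if (n_de > 0) {
    sgn <- rep_len(c(1, -1), n_de)
    lfc[de_genes] <- sample(sgn) * p$lfc_magnitude
  }

  # housekeeping genes: stably expressed, so drawn from non-DE genes in the
  # upper half of baseline abundance
  hk_pool <- setdiff(genes[rank(-base_mu) <= ceiling(p$n_genes / 2)], de_genes)
  if (length(hk_pool) < p$hk_gene_count) hk_pool <- setdiff(genes, de_genes)
  hk_genes <- sort(sample(hk_pool, p$hk_gene_count))

  sdlog_lib <- sqrt(log(1 + p$lib_cv^2))
  counts <- list()
  de_by_source <- list()
  lfc_by_source <- list()
  dropped <- character()
  for (s in p$sources) {
    lmean <- p$lib_size_mean[[s]] / p$lib_scale
    if (s == "exfoliome") lmean <- lmean * (1 - p$contamination_fraction)
    libs <- stats::rlnorm(n, log(lmean) - sdlog_lib^2 / 2, sdlog_lib)
    eff_lfc <- if (s %in% p$shared_effect_sources) lfc else lfc * 0
    fc <- outer(eff_lfc, as.numeric(group == "NSAID"), function(l, g) 2^(l * g))
    mu <- (rel %o% libs) * fc
    y <- matrix(rnb(length(mu), as.vector(mu), p$dispersion[[s]]),
                nrow = p$n_genes)
    if (s == "exfoliome" && p$dropout_quantile > 0) {
      k <- floor(p$dropout_quantile * p$n_genes)
      if (k > 0) {
        dropped <- genes[order(base_mu)][seq_len(k)]
        y[match(dropped, genes), ] <- 0L
      }
    }
    dimnames(y) <- list(genes, paste(s, subject, sep = "_"))
    storage.mode(y) <- "integer"
    counts[[s]] <- y
    de_by_source[[s]] <- if (s %in% p$shared_effect_sources) de_genes else character()
    lfc_by_source[[s]] <- eff_lfc
  }

  metadata <- do.call(rbind, lapply(p$sources, function(s)
    data.frame(sample_id = colnames(counts[[s]]), source = s,
               group = as.character(group), subject = subject,
               stringsAsFactors = FALSE)))
  rownames(metadata) <- NULL

  panel <- if (is.null(p$marker_panel)) make_marker_panel(p, genes) else {
    validate_marker_panel(p$marker_panel, genes)
    p$marker_panel
  }
  truth <- list(genes = genes, baseline_mean = rel,
                de_gene_ids = de_by_source, true_lfc = lfc_by_source,
                hk_gene_ids = hk_genes, exfoliome_dropout = dropped,
                marker_panel = panel)
  list(counts = counts, metadata = metadata, truth = truth)
}

validate_marker_panel <- function(panel, genes) {
  stopifnot(is.data.frame(panel), all(c("cell_type", "gene") %in% names(panel)))
  if (nrow(panel) == 0) stop("marker panel is empty")
  missing <- setdiff(panel$gene, genes)
  if (length(missing))
    stop("marker panel genes absent from the gene universe: ",
         paste(utils::head(missing, 5), collapse = ", "))
  cnt <- table(panel$cell_type[!duplicated(panel[c("cell_type", "gene")])])
  bad <- names(cnt)[cnt < 2]
  if (length(bad))
    stop("cell types with fewer than 2 marker genes: ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Build a default marker-gene panel
#'
#' Assigns three distinct genes from the simulated universe to each of the
#' mucosal cell types the analysis screens for (a category is later called
#' "present" in a sample when at least 2 of its markers are detected).
#'
#' @param params `exfo_sim_params` (used for its seed) or a list with `$seed`.
#' @param genes gene universe; defaults to the ids [simulate_counts()] makes.
#' @param cell_types character vector of categories.
#' @param genes_per_type markers per category (must be >= 2).
#' @return data frame with columns `cell_type`, `gene`.
#' @export
make_marker_panel <- function(params, genes = NULL,
                              cell_types = c("stem", "enterocyte",
                                             "crypt_base_columnar", "Paneth",
                                             "tuft", "goblet", "macrophage",
                                             "lymphocyte", "neutrophil",
                                             "smooth_muscle"),
                              genes_per_type = 3L) {
  if (genes_per_type < 2) stop("each cell type needs at least 2 marker genes")
  if (is.null(genes)) {
    ng <- if (!is.null(params$n_genes)) params$n_genes else 2000L
    genes <- sprintf("g%05d", seq_len(ng))
  }
  need <- length(cell_types) * genes_per_type
  if (need > length(genes)) stop("gene universe too small for the panel")
  seed <- if (!is.null(params$seed)) params$seed else 1L
  picked <- withr_seed(seed + 7L, sample(genes, need))
  panel <- data.frame(cell_type = rep(cell_types, each = genes_per_type),
                      gene = picked, stringsAsFactors = FALSE)
  validate_marker_panel(panel, genes)
  panel
}

# run expr under a temporary seed without disturbing the caller's RNG stream
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
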