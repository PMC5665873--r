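#' Pipeline configuration
#'
#' Flat configuration for [run_pipeline()]. All defaults are the analysis'
#' canonical values: filter thresholds (4 samples / 50 reads), FDR 0.05,
#' LDA error threshold 0.05, ANOSIM with 999 permutations, sparse CCA with
#' 2 components.
#'
#' @param input_dir directory holding `counts_<source>.tsv` and
#'   `metadata.tsv` (as written by the `simulate` stage); ignored when
#'   `simulate = TRUE`.
#' @param output_dir where stage outputs are written.
#' @param simulate generate inputs with [simulate_counts()] first.
#' @param sim list of overrides for [simulation_params()].
#' @param min_samples,min_total low-abundance filter thresholds.
#' @param fdr_threshold DE significance threshold on the BH q-value.
#' @param lda_threshold bolstered-error selection threshold.
#' @param anosim_permutations permutation count.
#' @param cca_c1,cca_c2 sparse CCA penalty fractions in (0, 1).
#' @param cca_components number of CCA components.
#' @param cca_tune run leave-one-out penalty tuning (slower).
#' @param cca_grid penalty grid used when `cca_tune = TRUE`.
#' @param seed master seed recorded in every provenance sidecar.
#' @return validated `exfo_config` list.
#' @export
pipeline_config <- function(input_dir = NULL, output_dir = tempfile("exfo_run_"),
                            simulate = is.null(input_dir), sim = list(),
                            min_samples = 4L, min_total = 50L,
                            fdr_threshold = 0.05, lda_threshold = 0.05,
                            anosim_permutations = 999L,
                            cca_c1 = 0.3, cca_c2 = 0.3, cca_components = 2L,
                            cca_tune = FALSE,
                            cca_grid = seq(0.2, 0.8, by = 0.3),
                            seed = 1L) {
  stopifnot(fdr_threshold > 0, fdr_threshold < 1,
            lda_threshold > 0, lda_threshold < 1,
            cca_c1 > 0, cca_c1 < 1, cca_c2 > 0, cca_c2 < 1,
            anosim_permutations >= 1, cca_components >= 1,
            min_samples >= 0, min_total >= 0)
  cfg <- list(input_dir = input_dir, output_dir = output_dir,
              simulate = simulate, sim = sim,
              min_samples = as.integer(min_samples),
              min_total = as.integer(min_total),
              fdr_threshold = fdr_threshold, lda_threshold = lda_threshold,
              anosim_permutations = as.integer(anosim_permutations),
              cca_c1 = cca_c1, cca_c2 = cca_c2,
              cca_components = as.integer(cca_components),
              cca_tune = cca_tune, cca_grid = cca_grid,
              seed = as.integer(seed))
  class(cfg) <- "exfo_config"
  cfg
}

#' Read a pipeline configuration from JSON
#' @param path JSON file with keys matching [pipeline_config()] arguments.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

stage_msg <- function(...) message(format(Sys.time(), "%H:%M:%S "), ...)

provenance <- function(cfg, stage, params, inputs = character()) {
  sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  list(stage = stage, seed = cfg$seed, parameters = params,
       input_md5 = sums,
       package_version = as.character(utils::packageVersion("exfoliomics")),
       r_version = paste(R.version$major, R.version$minor, sep = "."))
}

#' Run the full workflow
#'
#' Orchestrates the analysis in its canonical order: (optional) simulation,
#' low-abundance filtering, upper-quartile normalization, CPM, housekeeping
#' diagnostics, common dispersion/BCV, Bray-Curtis ordination (NMDS +
#' ANOSIM), exact-test differential expression, gene-set intersections, MA
#' tables, sparse CCA between the exfoliome and each tissue, bolstered
#' 1-feature LDA ranking, and marker-panel scores. Every stage writes a
#' plain-text table plus a JSON provenance sidecar (parameters, seed,
#' input checksums, versions); a stage failure aborts with the stage name.
#'
#' @param config `exfo_config` from [pipeline_config()] or [read_config()].
#' @return the output directory, invisibly; a `run_summary.json` there
#'   indexes every artifact.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  if (!inherits(cfg, "exfo_config")) cfg <- do.call(pipeline_config, config)
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  run_stage <- function(name, expr) {
    stage_msg("stage ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  summary <- list(seed = cfg$seed, stages = character())
  note <- function(s) summary$stages <<- c(summary$stages, s)

  ## inputs ---------------------------------------------------------------
  sim_truth <- NULL
  if (isTRUE(cfg$simulate)) {
    dat <- run_stage("simulate", {
      sp <- do.call(simulation_params, utils::modifyList(list(seed = cfg$seed),
                                                         as.list(cfg$sim)))
      simulate_counts(sp)
    })
    for (s in names(dat$counts))
      write_counts_tsv(dat$counts[[s]], file.path(out, paste0("counts_", s, ".tsv")))
    write_metadata_tsv(dat$metadata, file.path(out, "metadata.tsv"))
    write_json_file(list(de_gene_ids = dat$truth$de_gene_ids,
                         hk_gene_ids = dat$truth$hk_gene_ids),
                    file.path(out, "ground_truth.json"))
    utils::write.table(dat$truth$marker_panel, file.path(out, "marker_panel.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_json_file(provenance(cfg, "simulate", cfg$sim),
                    file.path(out, "simulate.provenance.json"))
    counts <- dat$counts; metadata <- dat$metadata
    sim_truth <- dat$truth
    note("simulate")
  } else {
    metadata <- run_stage("load",
      read_metadata_tsv(file.path(cfg$input_dir, "metadata.tsv")))
    counts <- run_stage("load", {
      src <- unique(metadata$source)
      stats::setNames(lapply(src, function(s)
        read_counts_tsv(file.path(cfg$input_dir, paste0("counts_", s, ".tsv")))),
        src)
    })
    note("load")
  }
  sources <- names(counts)

  ## per-source preprocessing, dispersion, ordination, DE -----------------
  filtered <- list(); norms <- list(); logcpms <- list(); des <- list()
  for (s in sources) {
    md <- metadata[metadata$source == s, ]
    grp <- factor(md$group, levels = unique(metadata$group))
    fl <- run_stage(paste0("filter:", s),
                    filter_low_abundance(counts[[s]][, md$sample_id],
                                         cfg$min_samples, cfg$min_total))
    filtered[[s]] <- fl$counts
    write_json_file(unclass(fl$report),
                    file.path(out, paste0("filter_report_", s, ".json")))
    nm <- run_stage(paste0("normalize:", s), upper_quartile_factors(fl$counts))
    norms[[s]] <- nm
    utils::write.table(
      data.frame(sample_id = names(nm$norm_factor),
                 library_size = nm$library_size,
                 norm_factor = nm$norm_factor,
                 effective_lib = nm$effective_lib),
      file.path(out, paste0("norm_factors_", s, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    lc <- run_stage(paste0("cpm:", s), cpm(fl$counts, nm, log = TRUE))
    logcpms[[s]] <- lc
    if (!is.null(sim_truth)) {
      hk <- run_stage(paste0("hkdiag:", s),
                      suppressWarnings(housekeeping_fraction(counts[[s]],
                                                             sim_truth$hk_gene_ids)))
      utils::write.table(data.frame(sample_id = names(hk), hk_fraction = hk),
                         file.path(out, paste0("hk_fraction_", s, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    disp <- run_stage(paste0("dispersion:", s),
                      estimate_common_dispersion(fl$counts, grp, nm))
    write_json_file(list(common_dispersion = disp$common_dispersion,
                         bcv = disp$bcv),
                    file.path(out, paste0("dispersion_", s, ".json")))
    bc <- run_stage(paste0("ordinate:", s), bray_curtis(cpm(fl$counts, nm)))
    an <- run_stage(paste0("anosim:", s),
                    anosim(bc, grp, cfg$anosim_permutations,
                           seed = cfg$seed + match(s, sources)))
    nm2 <- run_stage(paste0("nmds:", s),
                     nmds(bc, seed = cfg$seed, n_restarts = 5))
    write_json_file(list(anosim_R = an$statistic, anosim_p = an$p,
                         n_perm = an$n_perm, nmds_stress = nm2$stress),
                    file.path(out, paste0("ordination_", s, ".json")))
    utils::write.table(
      data.frame(sample_id = rownames(nm2$points), nm2$points),
      file.path(out, paste0("nmds_", s, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    de <- run_stage(paste0("de:", s), exact_test(fl$counts, grp, disp, nm))
    des[[s]] <- de
    utils::write.table(de, file.path(out, paste0("de_", s, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_json_file(provenance(cfg, paste0("per_source:", s),
                               list(min_samples = cfg$min_samples,
                                    min_total = cfg$min_total,
                                    fdr = cfg$fdr_threshold)),
                    file.path(out, paste0("per_source_", s, ".provenance.json")))
    note(paste0("per_source:", s))
  }

  ## cross-source stages --------------------------------------------------
  de_sets <- lapply(des, function(d) d$gene[d$fdr < cfg$fdr_threshold])
  venn <- run_stage("venn", intersect_gene_sets(
    lapply(filtered, rownames)))
  de_nonempty <- de_sets[vapply(de_sets, length, 1L) > 0]
  venn_de <- if (length(de_nonempty) >= 2)
    run_stage("venn_de", intersect_gene_sets(de_nonempty)) else NULL
  write_json_file(list(gene_universe = venn,
                       de = venn_de,
                       de_counts = lapply(de_sets, length)),
                  file.path(out, "venn.json"))
  note("venn")

  for (s in sources) {
    other <- setdiff(sources, s)[1]
    ma <- run_stage(paste0("ma:", s),
                    ma_table(des[[s]], de_sets[[s]],
                             intersect(setdiff(de_sets[[other]], de_sets[[s]]),
                                       des[[s]]$gene)))
    utils::write.table(ma, file.path(out, paste0("ma_", s, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  note("ma")

  if ("exfoliome" %in% sources && length(sources) >= 2) {
    for (s in setdiff(sources, "exfoliome")) {
      pair <- run_stage(paste0("cca:exfoliome-", s), {
        shared <- intersect(rownames(logcpms$exfoliome), rownames(logcpms[[s]]))
        X <- t(logcpms$exfoliome[shared, , drop = FALSE])
        Y <- t(logcpms[[s]][shared, , drop = FALSE])
        c1 <- cfg$cca_c1; c2 <- cfg$cca_c2
        if (isTRUE(cfg$cca_tune)) {
          tuned <- loo_cv_tune(X, Y, cfg$cca_grid, cfg$cca_grid)
          c1 <- tuned$c1; c2 <- tuned$c2
        }
        fit <- sparse_cca(X, Y, c1, c2, K = cfg$cca_components)
        md <- metadata[metadata$source == "exfoliome", ]
        list(fit = fit, table = cca_score_table(fit, md),
             c1 = c1, c2 = c2)
      })
      utils::write.table(pair$table,
                         file.path(out, paste0("cca_scores_exfoliome_", s, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_json_file(list(c1 = pair$c1, c2 = pair$c2,
                           objective = pair$fit$d,
                           score_correlation = pair$fit$score_correlation),
                      file.path(out, paste0("cca_exfoliome_", s, ".json")))
    }
    note("cca")
  }

  for (s in sources) {
    md <- metadata[metadata$source == s, ]
    grp <- factor(md$group, levels = unique(metadata$group))
    genes <- intersect(de_sets[[s]], rownames(logcpms[[s]]))
    rk <- run_stage(paste0("lda:", s),
                    suppressWarnings(rank_features(logcpms[[s]], grp, genes,
                                                   cfg$lda_threshold)))
    utils::write.table(rk, file.path(out, paste0("lda_ranking_", s, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  note("lda")

  if (!is.null(sim_truth)) {
    for (s in sources) {
      ms <- run_stage(paste0("markers:", s),
                      suppressWarnings(marker_scores(counts[[s]],
                                                     sim_truth$marker_panel)))
      utils::write.table(ms, file.path(out, paste0("marker_scores_", s, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    note("markers")
  }

  write_json_file(summary, file.path(out, "run_summary.json"))
  invisible(out)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `filter`, `normalize`, `cpm`,
#' `hkdiag`, `dispersion`, `de`, `venn`, `ma`, `ordinate`, `anosim`, `cca`,
#' `lda-rank`, `markers`, `concordance` and `run`. Flags are `--key value`
#' pairs mirroring the configuration fields; `run` additionally accepts
#' `--config config.json` with flags overriding the file.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return invisibly, the main output path of the subcommand.
#' @export
exfo_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0)
    stop("usage: exfoliomics <subcommand> [--key value ...]")
  cmd <- args[1]
  opts <- parse_cli_flags(args[-1])
  need <- function(key) {
    if (is.null(opts[[key]])) stop("missing required flag --", key)
    opts[[key]]
  }
  num <- function(key, default) if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
  counts_in <- function() read_counts_tsv(need("counts"))
  out_path <- function(default) if (is.null(opts$out)) default else opts$out

  switch(cmd,
    simulate = {
      cfg <- pipeline_config(output_dir = need("out"),
                             simulate = TRUE, seed = num("seed", 1))
      ng <- num("n-genes", 2000)
      sp <- simulation_params(n_genes = ng,
                              hk_gene_count = num("hk-genes",
                                                  min(532, ng %/% 4)),
                              seed = as.integer(num("seed", 1)))
      dat <- simulate_counts(sp)
      dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
      for (s in names(dat$counts))
        write_counts_tsv(dat$counts[[s]],
                         file.path(cfg$output_dir, paste0("counts_", s, ".tsv")))
      write_metadata_tsv(dat$metadata, file.path(cfg$output_dir, "metadata.tsv"))
      write_json_file(list(de_gene_ids = dat$truth$de_gene_ids,
                           hk_gene_ids = dat$truth$hk_gene_ids),
                      file.path(cfg$output_dir, "ground_truth.json"))
      invisible(cfg$output_dir)
    },
    filter = {
      fl <- filter_low_abundance(counts_in(), num("min-samples", 4),
                                 num("min-total", 50))
      write_counts_tsv(fl$counts, out_path("filtered.tsv"))
      write_json_file(unclass(fl$report), paste0(out_path("filtered.tsv"),
                                                 ".report.json"))
      invisible(out_path("filtered.tsv"))
    },
    normalize = {
      nm <- upper_quartile_factors(counts_in())
      p <- out_path("norm_factors.tsv")
      utils::write.table(data.frame(sample_id = names(nm$norm_factor),
                                    library_size = nm$library_size,
                                    norm_factor = nm$norm_factor,
                                    effective_lib = nm$effective_lib),
                         p, sep = "\t", quote = FALSE, row.names = FALSE)
      invisible(p)
    },
    cpm = {
      m <- counts_in()
      nm <- upper_quartile_factors(m)
      lc <- cpm(m, nm, log = !is.null(opts$log))
      p <- out_path("cpm.tsv")
      write_counts_tsv(round(lc, 6), p)
      invisible(p)
    },
    hkdiag = {
      hk <- readLines(need("hk-genes"))
      frac <- housekeeping_fraction(counts_in(), hk)
      p <- out_path("hk_fraction.tsv")
      utils::write.table(data.frame(sample_id = names(frac), hk_fraction = frac),
                         p, sep = "\t", quote = FALSE, row.names = FALSE)
      invisible(p)
    },
    dispersion = {
      m <- counts_in()
      md <- read_metadata_tsv(need("metadata"))
      grp <- md$group[match(colnames(m), md$sample_id)]
      d <- estimate_common_dispersion(m, grp)
      p <- out_path("dispersion.json")
      write_json_file(list(common_dispersion = d$common_dispersion, bcv = d$bcv), p)
      invisible(p)
    },
    de = {
      m <- counts_in()
      md <- read_metadata_tsv(need("metadata"))
      grp <- factor(md$group[match(colnames(m), md$sample_id)],
                    levels = unique(md$group))
      nm <- upper_quartile_factors(m)
      d <- estimate_common_dispersion(m, grp, nm)
      res <- exact_test(m, grp, d, nm)
      p <- out_path("de.tsv")
      utils::write.table(res, p, sep = "\t", quote = FALSE, row.names = FALSE)
      invisible(p)
    },
    venn = {
      files <- strsplit(need("sets"), ",")[[1]]
      sets <- stats::setNames(lapply(files, readLines),
                              tools::file_path_sans_ext(basename(files)))
      p <- out_path("venn.json")
      write_json_file(intersect_gene_sets(sets), p)
      invisible(p)
    },
    ma = {
      de <- utils::read.delim(need("de"), stringsAsFactors = FALSE)
      class(de) <- c("exfo_de", "data.frame")
      here <- if (is.null(opts$`de-here`)) character() else readLines(opts$`de-here`)
      other <- if (is.null(opts$`de-other`)) character() else readLines(opts$`de-other`)
      p <- out_path("ma.tsv")
      utils::write.table(ma_table(de, here, other), p, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      invisible(p)
    },
    ordinate = {
      m <- counts_in()
      nm <- upper_quartile_factors(m)
      bc <- bray_curtis(cpm(m, nm))
      fit <- nmds(bc, seed = as.integer(num("seed", 1)))
      p <- out_path("nmds.tsv")
      utils::write.table(data.frame(sample_id = rownames(fit$points),
                                    fit$points, stress = fit$stress),
                         p, sep = "\t", quote = FALSE, row.names = FALSE)
      invisible(p)
    },
    anosim = {
      m <- counts_in()
      md <- read_metadata_tsv(need("metadata"))
      grp <- md$group[match(colnames(m), md$sample_id)]
      nm <- upper_quartile_factors(m)
      bc <- bray_curtis(cpm(m, nm))
      a <- anosim(bc, grp, n_perm = as.integer(num("n-perm", 999)),
                  seed = as.integer(num("seed", 1)))
      p <- out_path("anosim.json")
      write_json_file(list(R = a$statistic, p = a$p, n_perm = a$n_perm), p)
      invisible(p)
    },
    cca = {
      mx <- read_counts_tsv(need("x"))
      my <- read_counts_tsv(need("y"))
      shared <- intersect(rownames(mx), rownames(my))
      X <- t(cpm(mx, upper_quartile_factors(mx), log = TRUE)[shared, ])
      Y <- t(cpm(my, upper_quartile_factors(my), log = TRUE)[shared, ])
      K <- as.integer(num("components", 2))
      fit <- sparse_cca(X, Y, num("c1", 0.3), num("c2", 0.3), K = K)
      p <- out_path("cca_loadings.tsv")
      utils::write.table(data.frame(gene = shared,
                                    u = fit$u[, 1], v = fit$v[, 1]),
                         p, sep = "\t", quote = FALSE, row.names = FALSE)
      write_json_file(list(objective = fit$d,
                           score_correlation = fit$score_correlation),
                      paste0(p, ".json"))
      invisible(p)
    },
    `lda-rank` = {
      m <- counts_in()
      md <- read_metadata_tsv(need("metadata"))
      grp <- factor(md$group[match(colnames(m), md$sample_id)],
                    levels = unique(md$group))
      genes <- if (is.null(opts$genes)) rownames(m) else readLines(opts$genes)
      lc <- cpm(m, upper_quartile_factors(m), log = TRUE)
      rk <- rank_features(lc, grp, intersect(genes, rownames(lc)),
                          threshold = num("threshold", 0.05))
      p <- out_path("lda_ranking.tsv")
      utils::write.table(rk, p, sep = "\t", quote = FALSE, row.names = FALSE)
      invisible(p)
    },
    markers = {
      panel <- utils::read.delim(need("panel"), stringsAsFactors = FALSE)
      p <- out_path("marker_scores.tsv")
      utils::write.table(marker_scores(counts_in(), panel), p, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      invisible(p)
    },
    concordance = {
      k1 <- num("k1", NA); n1 <- num("n1", NA)
      k2 <- num("k2", NA); n2 <- num("n2", NA)
      res <- list(prop1_percent = proportion_percent(k1, n1),
                  prop2_percent = proportion_percent(k2, n2),
                  two_proportion = two_proportion_test(k1, n1, k2, n2))
      if (!is.null(opts$b) && !is.null(opts$c))
        res$mcnemar <- mcnemar_test(as.numeric(opts$b), as.numeric(opts$c))
      p <- out_path("concordance.json")
      write_json_file(res, p)
      invisible(p)
    },
    run = {
      cfg <- if (!is.null(opts$config)) read_config(opts$config)
             else pipeline_config()
      if (!is.null(opts$out)) cfg$output_dir <- opts$out
      if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
      if (!is.null(opts$input)) { cfg$input_dir <- opts$input; cfg$simulate <- FALSE }
      run_pipeline(cfg)
    },
    stop("unknown subcommand '", cmd, "'")
  )
}

parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument '", a, "'")
    key <- substring(a, 3)
    if (i + 1 <= length(args) && !startsWith(args[i + 1], "--")) {
      opts[[key]] <- args[i + 1]
      i <- i + 2
    } else {
      opts[[key]] <- TRUE
      i <- i + 1
    }
  }
  opts
}
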