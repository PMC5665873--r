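test_that("parameter validation rejects invalid worlds", {
  expect_error(simulation_params(dispersion = c(SI = -1, colon = 0.1,
                                                exfoliome = 0.1)),
               "dispersion")
  expect_error(simulation_params(de_fraction = 1.5), "fractions")
  expect_error(simulation_params(lib_size_mean = c(SI = Inf, colon = 1,
                                                   exfoliome = 1)), "finite")
  expect_error(simulation_params(n_genes = 300), "hk_gene_count")
})

test_that("same seed gives bit-identical output, different seed does not", {
  a <- small_sim(seed = 5, n_genes = 200, hk = 30)
  b <- small_sim(seed = 5, n_genes = 200, hk = 30)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  c <- small_sim(seed = 6, n_genes = 200, hk = 30)
  expect_false(identical(a$counts$SI, c$counts$SI))
})

test_that("counts recover the stated NB moments", {
  # phi = 0 (Poisson limit), flat baseline, no library noise: sample means
  # within Monte-Carlo error of the theoretical mean
  p <- simulation_params(n_genes = 100, n_per_group = 100,
                         sources = "SI", lib_size_mean = c(SI = 1e4),
                         lib_scale = 1, dispersion = c(SI = 0),
                         de_fraction = 0, lib_cv = 0, baseline_sdlog = 0,
                         hk_gene_count = 10, shared_effect_sources = "SI",
                         seed = 21)
  dat <- simulate_counts(p)
  mu <- 1e4 / 100                       # flat profile: every gene mean 100
  z <- (rowMeans(dat$counts$SI) - mu) / sqrt(mu / 200)
  expect_gt(mean(abs(z) < 3), 0.97)
  expect_lt(max(abs(z)), 6)

  # phi = 0.5, mu = 100: variance follows mu + phi * mu^2 within 10%
  # at 10,000 draws per gene
  p2 <- simulation_params(n_genes = 40, n_per_group = 5000,
                          sources = "SI", lib_size_mean = c(SI = 4000),
                          lib_scale = 1, dispersion = c(SI = 0.5),
                          de_fraction = 0, lib_cv = 0, baseline_sdlog = 0,
                          hk_gene_count = 5, shared_effect_sources = "SI",
                          seed = 22)
  dat2 <- simulate_counts(p2)
  v <- apply(dat2$counts$SI, 1, var)
  expect_true(all(abs(v / (100 + 0.5 * 100^2) - 1) < 0.10))
})

test_that("treatment effect is coupled to exactly the shared sources", {
  dat <- small_sim(seed = 9, n_genes = 300, hk = 40)
  tr <- dat$truth
  de <- tr$de_gene_ids
  expect_identical(de$SI, de$exfoliome)
  expect_length(de$colon, 0)
  expect_true(all(tr$true_lfc$SI[de$SI] != 0))
  expect_true(all(tr$true_lfc$SI[setdiff(tr$genes, de$SI)] == 0))
  expect_true(all(tr$true_lfc$colon == 0))
  expect_length(tr$hk_gene_ids, 40)
  expect_true(all(unlist(de) %in% tr$genes))
  # exfoliome library is smaller than the tissues, as in the assay
  expect_lt(sum(dat$counts$exfoliome), sum(dat$counts$SI))
})

test_that("marker panels enforce the >= 2 genes per cell type rule", {
  genes <- sprintf("g%05d", 1:50)
  expect_error(make_marker_panel(list(seed = 1), genes, genes_per_type = 1),
               "at least 2")
  bad <- data.frame(cell_type = c("Paneth", "goblet", "goblet"),
                    gene = genes[1:3])
  expect_error(exfoliomics:::validate_marker_panel(bad, genes), "Paneth")
  alien <- data.frame(cell_type = rep("tuft", 2), gene = c("gX", "gY"))
  expect_error(exfoliomics:::validate_marker_panel(alien, genes), "absent")
  panel <- make_marker_panel(list(seed = 1), genes,
                             cell_types = c("tuft", "goblet"))
  expect_true(all(table(panel$cell_type) >= 2))
  expect_true(all(panel$gene %in% genes))
})
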