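test_that("Bray-Curtis hits its defining cases and agrees with vegan", {
  x <- cbind(s1 = c(2, 2), s2 = c(1, 1), s3 = c(0, 5))
  d <- bray_curtis(x)
  expect_equal(d["s1", "s1"], 0)
  expect_equal(d["s1", "s2"], 1 / 3)
  disj <- cbind(a = c(3, 0), b = c(0, 7))
  expect_equal(bray_curtis(disj)["a", "b"], 1)
  expect_error(bray_curtis(cbind(a = c(1, 2), dead = c(0, 0))), "dead")
  expect_error(bray_curtis(cbind(a = c(-1, 2), b = c(1, 1))), "non-negative")

  skip_if_not_installed("vegan")
  set.seed(4)
  m <- matrix(rpois(80, 20), 10, 8,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:8)))
  expect_equal(as.dist(bray_curtis(m)),
               vegan::vegdist(t(m), "bray"), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("ANOSIM reaches its definitional maximum and matches vegan's R", {
  pts <- c(0, 0.1, 0.2, 10, 10.1, 10.2)
  d <- as.matrix(dist(pts))
  g <- factor(rep(c("a", "b"), each = 3))
  a <- anosim(d, g, n_perm = 99, seed = 1)
  expect_equal(a$statistic, 1)
  expect_gt(a$p, 0)          # add-one rule keeps p positive
  expect_lte(a$p, 1)
  expect_error(anosim(d, factor(c("a", rep("b", 5)))), ">= 2")

  # rank-based, so invariant to monotone transformation of the distances
  a2 <- anosim(d^2, g, n_perm = 99, seed = 1)
  expect_equal(a2$statistic, a$statistic)

  skip_if_not_installed("vegan")
  set.seed(12)
  dr <- as.matrix(dist(matrix(rnorm(16), 8, 2)))
  g8 <- factor(rep(c("a", "b"), each = 4))
  expect_equal(anosim(dr, g8, n_perm = 9, seed = 1)$statistic,
               unname(vegan::anosim(as.dist(dr), g8,
                                    permutations = 9)$statistic),
               tolerance = 1e-12)
})

test_that("NMDS embeds embeddable configurations and is monotone", {
  set.seed(3)
  pts <- matrix(rnorm(20), 10, 2)
  d <- as.matrix(dist(pts))
  fit <- nmds(d, k = 2, seed = 1, n_restarts = 5)
  expect_lt(fit$stress, 0.01)
  expect_true(all(diff(fit$stress_trajectory) <= 1e-8))
  fit2 <- nmds(d, k = 2, seed = 1, n_restarts = 5)
  expect_identical(fit$points, fit2$points)     # deterministic under seed
  full <- nmds(d, k = nrow(d) - 1, seed = 1, n_restarts = 2)
  expect_lt(full$stress, 1e-3)
  expect_error(nmds(d, k = 10), "k must be")
})

test_that("leading-logFC MDS distances reduce to the RMS oracle", {
  set.seed(5)
  lc <- matrix(rnorm(60), 12, 5,
               dimnames = list(paste0("g", 1:12), paste0("s", 1:5)))
  lc[, 5] <- lc[, 4]                       # duplicate sample
  expect_warning(fit <- mds_leading_logfc(lc, top_n = 50), "clipped")
  expect_equal(fit$distance["s4", "s5"], 0)
  expect_equal(max(abs(fit$points["s4", ] - fit$points["s5", ])), 0,
               tolerance = 1e-9)
  # top_n = all genes equals the plain RMS log-fold-change distance
  rms <- sqrt(mean((lc[, 1] - lc[, 2])^2))
  expect_equal(fit$distance["s1", "s2"], rms, tolerance = 1e-12)
  # with top_n < all, distances only keep the largest contrasts
  fit2 <- mds_leading_logfc(lc, top_n = 3)
  expect_gte(fit2$distance["s1", "s2"], fit$distance["s1", "s2"])
  expect_error(mds_leading_logfc(lc[, 1:2]), ">= 3")
})

test_that("group separation appears in ordination of simulated data", {
  dat <- small_sim(seed = 11)
  fl <- filter_low_abundance(dat$counts$SI)
  nm <- upper_quartile_factors(fl$counts)
  md <- dat$metadata[dat$metadata$source == "SI", ]
  g <- factor(md$group, levels = c("control", "NSAID"))
  lc <- cpm(fl$counts, nm, log = TRUE)
  fit <- mds_leading_logfc(lc, top_n = 100)
  between <- fit$distance[g == "control", g == "NSAID"]
  within <- fit$distance[g == "control", g == "control"]
  expect_gt(mean(between), mean(within[within > 0]))
})
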