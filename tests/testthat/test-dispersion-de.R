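test_that("bcv is the square root of the dispersion", {
  expect_equal(bcv_from_dispersion(0), 0)
  expect_equal(bcv_from_dispersion(0.25), 0.5)
  expect_error(bcv_from_dispersion(-0.1), ">= 0")
  d <- list(common_dispersion = 0.3, bcv = sqrt(0.3))
  expect_equal(d$bcv^2, d$common_dispersion, tolerance = 1e-12)
})

test_that("common dispersion recovers truth and hits the floor when exact", {
  set.seed(31)
  ng <- 500; grp <- factor(rep(c("a", "b"), each = 5))
  y <- matrix(rnbinom(ng * 10, size = 1 / 0.3, mu = 80), ng, 10,
              dimnames = list(paste0("g", 1:ng), paste0("s", 1:10)))
  d <- estimate_common_dispersion(y, grp)
  expect_gt(d$common_dispersion, 0.2)
  expect_lt(d$common_dispersion, 0.45)
  expect_equal(d$bcv, sqrt(d$common_dispersion))
  # counts constant within groups: no overdispersion signal
  const <- matrix(rep(c(10L, 30L), each = 5), 4, 10, byrow = TRUE,
                  dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  dc <- estimate_common_dispersion(const, grp)
  expect_true(dc$at_lower_bound)
  expect_error(estimate_common_dispersion(y[, 1, drop = FALSE], grp[1]),
               ">= 2 samples")
  # the profile variant exists and also lands in a sane range here
  dp <- estimate_common_dispersion(y, grp, method = "profile")
  expect_gt(dp$common_dispersion, 0.1)
  expect_lt(dp$common_dispersion, 0.45)
})

test_that("exact test matches the enumeration oracle and its conventions", {
  grp <- factor(rep(c("control", "NSAID"), each = 3),
                levels = c("control", "NSAID"))
  # balanced libraries so equalization is the identity
  m <- balanced_counts(c(0, 0, 0, 50, 55, 60), filler_total = 1000)
  de <- exact_test(m, grp, dispersion = 0.1)
  expect_equal(de$pvalue[de$gene == "gA"],
               oracle_exact_p(0, 165, 3, 3, 0.1), tolerance = 1e-10)
  # sign convention: higher in NSAID means positive logFC
  expect_gt(de$logFC[de$gene == "gA"], 0)
  # identical group totals give p = 1 under the symmetric two-sided rule
  m2 <- balanced_counts(c(10, 20, 30, 30, 20, 10))
  de2 <- exact_test(m2, grp, dispersion = 0.1)
  expect_equal(de2$pvalue[de2$gene == "gA"], 1)
  expect_error(exact_test(m, factor(rep("a", 6)), 0.1), "two groups")
  expect_true(all(de$fdr >= de$pvalue - 1e-12))
})

test_that("BH adjustment matches closed forms and stats::p.adjust", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.4, 5)), rep(0.4, 5))
  set.seed(8)
  p <- runif(200)^2
  q <- bh_adjust(p)
  expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))   # monotone in sorted p
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("MA tables partition genes by DE provenance", {
  grp <- factor(rep(c("control", "NSAID"), each = 3),
                levels = c("control", "NSAID"))
  m <- balanced_counts(c(5, 6, 7, 50, 52, 54))
  de <- exact_test(m, grp, 0.1)
  tab <- ma_table(de, de_here = "gA", de_other = "gB")
  expect_setequal(tab$flag[tab$gene == "gA"], "DE_here")
  expect_setequal(tab$flag[tab$gene == "gB"], "DE_in_other_source_only")
  expect_equal(nrow(tab), nrow(de))
  empty <- ma_table(de)
  expect_true(all(empty$flag == "not_DE"))
  # a gene in both sets takes the local flag (rows are never double-flagged)
  both <- ma_table(de, de_here = "gA", de_other = "gA")
  expect_equal(both$flag[both$gene == "gA"], "DE_here")
  expect_error(ma_table(de, de_here = "ghost"), "unknown")
})

test_that("gene-set intersections count regions and overlaps", {
  v <- intersect_gene_sets(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
  expect_equal(v$pairwise$overlap_percent, 50)
  expect_equal(unname(v$regions[c("A", "A&B", "B")]), c(1L, 2L, 1L))
  same <- intersect_gene_sets(list(A = letters[1:3], B = letters[1:3]))
  expect_equal(same$pairwise$overlap_percent, 100)
  disj <- intersect_gene_sets(list(A = "a", B = "b"))
  expect_equal(disj$pairwise$overlap_percent, 0)
  expect_error(intersect_gene_sets(list(A = "a")), ">= 2")
  expect_error(intersect_gene_sets(list(A = character(), B = character())),
               "empty")
})
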