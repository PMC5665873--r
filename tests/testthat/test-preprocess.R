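test_that("low-abundance filter applies the <=4-samples-or-<=50-reads rule", {
  m <- rbind(
    boundary_samples = c(50, 50, 50, 50, 0, 0, 0, 0, 0, 0),  # 4 samples, 200 reads
    boundary_total   = c(11, 10, 10, 10, 10, 0, 0, 0, 0, 0), # 5 samples, 51 reads
    both_low         = c(50, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    all_zero         = rep(0, 10),
    abundant         = rep(20, 10))
  colnames(m) <- paste0("s", 1:10)
  fl <- filter_low_abundance(m)
  expect_setequal(rownames(fl$counts), c("boundary_total", "abundant"))
  expect_equal(fl$report$genes_before, 5)
  expect_equal(fl$report$genes_after, 2)
  expect_equal(fl$report$reads_after, sum(m["boundary_total", ]) + 200)
  # filtering removes genes, never samples; reads shrink by what was removed
  expect_equal(ncol(fl$counts), ncol(m))
  expect_equal(fl$report$reads_before - fl$report$reads_after,
               sum(m[c("boundary_samples", "both_low", "all_zero"), ]))
  expect_error(filter_low_abundance(m - 1), "non-negative")
})

test_that("percent reduction reproduces the dataset-level arithmetic", {
  expect_equal(percent_reduction(19324, 17229), 11L)
  expect_equal(percent_reduction(20743, 17244), 17L)
  expect_equal(percent_reduction(13944, 10865), 22L)
  expect_equal(percent_reduction(100, 100), 0L)
  expect_error(percent_reduction(0, 0))
  expect_error(percent_reduction(10, 11))
})

test_that("upper-quartile factors match a hand oracle and stay geo-mean 1", {
  toy <- cbind(s1 = c(10, 20, 0), s2 = c(5, 5, 40))
  rownames(toy) <- paste0("g", 1:3)
  nm <- upper_quartile_factors(toy)
  # hand calculation: q75(10,20)/30 = 0.58333, q75(5,5,40)/50 = 0.45,
  # rescaled by their geometric mean sqrt(0.2625)
  expect_equal(unname(nm$norm_factor), c(1.1385500851, 0.8783100657),
               tolerance = 1e-9)
  expect_equal(nm$effective_lib, nm$library_size * nm$norm_factor)

  m <- matrix(rpois(200, 30), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  nm2 <- upper_quartile_factors(m)
  expect_equal(exp(mean(log(nm2$norm_factor))), 1, tolerance = 1e-12)
  # identical samples -> all factors 1; doubling a sample leaves its factor
  # unchanged (q75 and library size scale together)
  same <- m[, c(1, 1, 1)]; colnames(same) <- paste0("s", 1:3)
  expect_equal(unname(upper_quartile_factors(same)$norm_factor), rep(1, 3))
  scaled <- cbind(m, double_of_1 = 2L * m[, 1])
  nm3 <- upper_quartile_factors(scaled)
  expect_equal(unname(nm3$norm_factor[1]), unname(nm3$norm_factor[11]),
               tolerance = 1e-12)
  zero <- cbind(m, dead = 0L)
  expect_error(upper_quartile_factors(zero), "dead")
})

test_that("cpm and log-cpm follow their definitions", {
  m <- cbind(s1 = c(10, 1999990), s2 = c(3, 7))
  rownames(m) <- c("gA", "gB")
  expect_equal(cpm(m)["gA", "s1"], 5)           # 10 / 2e6 * 1e6
  expect_true(all(abs(colSums(cpm(m)) - 1e6) < 1e-6))
  # effective library exactly 1e6 with unit factor -> CPM equals counts
  one <- matrix(c(999999, 1), 2, 1, dimnames = list(c("gA", "gB"), "s"))
  expect_equal(unname(cpm(one)[, 1]), c(999999, 1))
  toy <- matrix(c(2, 8, 4, 16), 2, 2,
                dimnames = list(c("gA", "gB"), c("s1", "s2")))
  expect_equal(as.vector(cpm(toy, log = TRUE)),
               c(17.79406505, 19.55959979, 17.70917615, 19.58364527),
               tolerance = 1e-8)
})

test_that("housekeeping fractions hit their bounds and hand values", {
  m <- cbind(s1 = c(5, 5, 0), s2 = c(0, 0, 8))
  rownames(m) <- c("hk1", "hk2", "other")
  expect_equal(unname(housekeeping_fraction(m, c("hk1", "hk2"))), c(1, 0))
  expect_equal(unname(housekeeping_fraction(m, "hk1")), c(0.5, 0))
  expect_warning(f <- housekeeping_fraction(m, c("hk1", "gone")), "absent")
  expect_equal(unname(f), c(0.5, 0))
  expect_error(housekeeping_fraction(m, c("no1", "no2")), "no housekeeping")
  expect_error(housekeeping_fraction(m, character()), "empty")
})

test_that("cross-source correlation behaves at the extremes and on synthetic data", {
  a <- matrix(1:12, 4, 3, dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  expect_equal(cross_source_correlation(a, a)$rho, 1)
  rev <- a[4:1, ]; rownames(rev) <- rownames(a)
  expect_equal(cross_source_correlation(a, rev)$rho, -1)
  expect_error(cross_source_correlation(a[1:2, ], a[1:2, ]), "3 shared")

  dat <- small_sim(seed = 11)
  lc <- lapply(dat$counts, function(m) {
    fl <- filter_low_abundance(m)
    cpm(fl$counts, upper_quartile_factors(fl$counts), log = TRUE)
  })
  ctrl <- function(m) m[, grepl("_C", colnames(m)), drop = FALSE]
  cs <- cross_source_correlation(ctrl(lc$exfoliome), ctrl(lc$SI))
  expect_gt(cs$rho, 0.8)
  expect_lt(cs$p, 1e-4)
})
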