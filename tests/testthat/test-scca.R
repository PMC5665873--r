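test_that("column standardization uses the population-SD convention", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(0, 1, 0))
  expect_warning(s <- standardize_columns(x), "constant")
  expect_equal(attr(s, "dropped"), "b")
  expect_equal(unname(s[, "a"]), c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  expect_equal(colMeans(s), c(a = 0, c = 0), tolerance = 1e-12)
  expect_equal(standardize_columns(s[, , drop = FALSE]), s,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(standardize_columns(cbind(a = c(1, 1))), "constant")
})

test_that("soft-thresholding follows its closed form", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-0.5, 1), 0)
  a <- c(-2, 0.3, 4)
  expect_equal(soft_threshold(a, 0), a)
  expect_equal(soft_threshold(a, 1), c(-1, 0, 3))
  expect_error(soft_threshold(a, -1), ">= 0")
})

test_that("the L1-bounded unit vector solves its projection problem", {
  set.seed(2)
  a <- rnorm(30)
  # inactive budget: plain normalization
  expect_equal(l1_bounded_unit_vector(a, sqrt(30)), a / sqrt(sum(a^2)),
               tolerance = 1e-9)
  # maximal sparsity: all mass on the largest |a_i|
  w1 <- l1_bounded_unit_vector(a, 1)
  expect_equal(sum(w1 != 0), 1)
  expect_equal(which(w1 != 0), which.max(abs(a)))
  expect_error(l1_bounded_unit_vector(a, 0.5), ">= 1")
  expect_error(l1_bounded_unit_vector(numeric(3), 1), "nonzero")
  for (seed in 1:5) {
    set.seed(seed)
    a <- rnorm(40)
    c_budget <- 0.5 * sqrt(40)
    w <- l1_bounded_unit_vector(a, c_budget)
    expect_equal(sum(w^2), 1, tolerance = 1e-10)
    expect_lte(sum(abs(w)), c_budget + 1e-6)
    # the active constraint is tight
    expect_equal(sum(abs(w)), c_budget, tolerance = 1e-4)
  }
})

test_that("the alternating solver equals the SVD at inactive budgets", {
  set.seed(14)
  X <- standardize_columns(matrix(rnorm(200), 10, 20))
  Y <- standardize_columns(matrix(rnorm(300), 10, 30))
  fit <- sparse_cca_pair(X, Y, c1 = sqrt(20), c2 = sqrt(30),
                         tol = 1e-14, max_iter = 5000)
  sv <- svd(crossprod(X, Y))
  expect_equal(fit$d, sv$d[1], tolerance = 1e-8)
  expect_equal(abs(sum(fit$u * sv$u[, 1])), 1, tolerance = 1e-6)
  expect_true(all(diff(fit$objective_trajectory) >= -1e-10))  # ascent
  expect_gt(fit$u[which(fit$u != 0)[1]], 0)                   # sign rule
  # degenerate but well-defined: X = Y = a single column
  one <- standardize_columns(matrix(c(1, 4, 2, 7), 4, 1))
  f1 <- sparse_cca_pair(one, one, c1 = 1, c2 = 1)
  expect_equal(abs(f1$u), 1)
  expect_equal(f1$u, f1$v)
})

test_that("deflation annihilates the extracted component", {
  set.seed(6)
  M <- matrix(rnorm(35), 5, 7)
  fit <- sparse_cca_pair(crossprod_m = M, c1 = sqrt(5), c2 = sqrt(7),
                         tol = 1e-13, max_iter = 2000)
  M2 <- deflate(M, fit$u, fit$v, fit$d)
  expect_equal(as.numeric(t(fit$u) %*% M2 %*% fit$v), 0, tolerance = 1e-8)
  # rank-1 matrix deflates to zero
  u <- c(1, 0, 0, 0, 0); v <- c(0, 1, 0, 0, 0, 0, 0)
  expect_equal(deflate(3 * tcrossprod(u, v), u, v, 3),
               matrix(0, 5, 7))
  expect_error(deflate(M, u[1:3], v, 1), "mismatch")
  # later components never beat earlier ones
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(80), 8, 10); Y <- matrix(rnorm(96), 8, 12)
    f <- sparse_cca(X, Y, 0.5, 0.5, K = 2)
    expect_lte(f$d[2], f$d[1] + 1e-8)
    # every returned loading satisfies the constraint set
    expect_lte(max(colSums(f$u^2)), 1 + 1e-8)
    expect_lte(max(colSums(abs(f$u))), f$budgets["c1"] + 1e-6)
    expect_lte(max(colSums(abs(f$v))), f$budgets["c2"] + 1e-6)
  }
})

test_that("leave-one-out tuning and score tables are wired correctly", {
  set.seed(9)
  n <- 12
  z <- rnorm(n)
  X <- cbind(z + rnorm(n, sd = 0.2), matrix(rnorm(n * 5), n))
  Y <- cbind(z + rnorm(n, sd = 0.2), matrix(rnorm(n * 5), n))
  one <- loo_cv_tune(X, Y, grid1 = 0.4, grid2 = 0.4)
  expect_equal(one$c1, 0.4)
  expect_equal(one$c2, 0.4)
  expect_gt(one$best, 0.5)     # the shared signal survives holding out

  fit <- sparse_cca(X, Y, 0.4, 0.4, K = 2)
  md <- data.frame(sample_id = paste0("s", 1:n),
                   group = rep_len(c("a", "b"), n))
  tab <- cca_score_table(fit, md)
  expect_equal(nrow(tab), 2 * n)
  expect_equal(tab$comp1[tab$role == "x"], unname(fit$scores_x[, 1]))
  expect_equal(tab$partner_comp1[tab$role == "x"], unname(fit$scores_y[, 1]))
  expect_equal(mean(tab$comp1[tab$role == "x"]), 0, tolerance = 1e-9)
  expect_error(cca_score_table(fit, md[1:3, ]), "one row per sample")
  expect_error(loo_cv_tune(X[1:2, ], Y[1:2, ]), ">= 3")
})
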